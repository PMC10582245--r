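#' Exact matching rate of a reference within a query
#'
#' The discrimination statistic: the fraction of the target sample's super
#' high-quality reference keys found exactly (reverse complements included,
#' via canonical keys) in the query sample's comprehensive set. The
#' denominator is the TARGET's reference size, so the statistic is asymmetric
#' in query and target. A sample queried against itself always scores 1.0,
#' because its comprehensive set contains its reference by construction.
#'
#' @param query a [comprehensive_set()].
#' @param target a [super_high_quality_set()] reference.
#' @return a number in `[0, 1]`, with attributes `n_matched` and
#'   `n_target_shq`.
#' @export
similarity <- function(query, target) {
  stopifnot(inherits(query, "comprehensive_set"),
            inherits(target, "reference_set"))
  if (length(target$shq) == 0) {
    stop(sprintf("target '%s' has no super high-quality reference reads",
                 target$sample_id))
  }
  n_matched <- sum(target$shq %in% query$keys)
  structure(n_matched / length(target$shq),
            n_matched = n_matched, n_target_shq = length(target$shq))
}

#' All-pairs similarity matrix
#'
#' Computes the exact matching rate for every ordered (query, target) pair of
#' samples, including the diagonal. Rows are queries (comprehensive sets),
#' columns are targets (references); the matrix is generally asymmetric
#' because the denominator follows the target.
#'
#' @param comp_list list of [comprehensive_set()]s, one per sample.
#' @param ref_list list of [super_high_quality_set()] references, same
#'   samples in the same order.
#' @param cultivars named character vector mapping sample_id to cultivar
#'   label (used by [group_summary()]); defaults to each sample being its own
#'   cultivar.
#' @return a `similarity_matrix`: list with `values` (numeric matrix with
#'   sample ids as dimnames), `cultivars`, and `long` (data.frame with one
#'   row per ordered pair: query, target, cultivar labels, similarity,
#'   n_matched, n_target_shq).
#' @export
similarity_matrix <- function(comp_list, ref_list, cultivars = NULL) {
  stopifnot(length(comp_list) == length(ref_list), length(comp_list) >= 2)
  ids_c <- vapply(comp_list, `[[`, "", "sample_id")
  ids_r <- vapply(ref_list, `[[`, "", "sample_id")
  if (!identical(ids_c, ids_r)) {
    stop("similarity_matrix: comprehensive and reference sets must list the same samples in the same order")
  }
  empty <- ids_r[vapply(ref_list, function(r) length(r$shq) == 0, logical(1))]
  if (length(empty) > 0) {
    stop(sprintf("sample(s) with empty super high-quality reference: %s",
                 paste(empty, collapse = ", ")))
  }
  if (is.null(cultivars)) cultivars <- stats::setNames(ids_c, ids_c)
  n <- length(ids_c)
  vals <- matrix(NA_real_, n, n, dimnames = list(query = ids_c, target = ids_c))
  long <- vector("list", n * n)
  k <- 0L
  for (q in seq_len(n)) {
    for (t in seq_len(n)) {
      s <- similarity(comp_list[[q]], ref_list[[t]])
      vals[q, t] <- as.numeric(s)
      k <- k + 1L
      long[[k]] <- data.frame(
        query = ids_c[q], target = ids_c[t],
        query_cultivar = unname(cultivars[ids_c[q]]),
        target_cultivar = unname(cultivars[ids_c[t]]),
        similarity = as.numeric(s),
        n_matched = attr(s, "n_matched"),
        n_target_shq = attr(s, "n_target_shq"))
    }
  }
  out <- list(values = vals, cultivars = cultivars,
              long = do.call(rbind, long))
  class(out) <- "similarity_matrix"
  out
}

#' @export
print.similarity_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("similarity_matrix: %d samples (rows = query, columns = target)\n",
              nrow(x$values)))
  print(round(x$values, digits))
  invisible(x)
}

#' Group summary of a similarity matrix
#'
#' Mean and sample (n-1) standard deviation of the off-diagonal exact
#' matching rates in a group of ordered sample pairs: all pairs, pairs of
#' samples of the same cultivar, pairs of different cultivars, or pairs
#' between two named cultivars (both orientations). The diagonal is always
#' excluded — self-comparisons are definitionally 1.0 and carry no
#' information.
#'
#' @param m a [similarity_matrix()].
#' @param mode one of `"all"`, `"same_cultivar"`, `"different_cultivar"`,
#'   `"pair"`.
#' @param pair for `mode = "pair"`, a length-2 character vector of cultivar
#'   labels.
#' @return one-row data.frame: `group`, `n_pairs`, `mean`, `sd` (`NA` when a
#'   single pair).
#' @export
group_summary <- function(m, mode = c("all", "same_cultivar",
                                      "different_cultivar", "pair"),
                          pair = NULL) {
  stopifnot(inherits(m, "similarity_matrix"))
  mode <- match.arg(mode)
  d <- m$long[m$long$query != m$long$target, , drop = FALSE]
  sel <- switch(mode,
    all = rep(TRUE, nrow(d)),
    same_cultivar = d$query_cultivar == d$target_cultivar,
    different_cultivar = d$query_cultivar != d$target_cultivar,
    pair = {
      stopifnot(length(pair) == 2)
      (d$query_cultivar == pair[1] & d$target_cultivar == pair[2]) |
        (d$query_cultivar == pair[2] & d$target_cultivar == pair[1])
    })
  v <- d$similarity[sel]
  if (length(v) == 0) stop("no pairs in group")
  label <- if (mode == "pair") paste(pair, collapse = " vs ") else mode
  data.frame(group = label, n_pairs = length(v), mean = mean(v),
             sd = if (length(v) > 1) stats::sd(v) else 0)
}

#' Write tabular (and optional graphical) outputs for a similarity matrix
#'
#' Produces the standard result files: a wide TSV of the matrix (optionally
#' with `-` on the diagonal, the conventional presentation), a long TSV with
#' one ordered pair per row including the matched/total counts that recompute
#' each rate, and a group-summary TSV covering all / same-cultivar /
#' different-cultivar groups (same/different rows are omitted when the group
#' is empty). Re-running on identical inputs yields byte-identical TSVs.
#'
#' @param m a [similarity_matrix()].
#' @param out_dir output directory (created if needed).
#' @param diagonal_dash render diagonal entries as `-` in the wide TSV
#'   (values remain 1.0 in the object and the long TSV).
#' @param heatmap also write `similarity_heatmap.png` (requires the pheatmap
#'   package).
#' @param digits rounding for the wide matrix TSV (default 2, matching how
#'   such tables are usually printed); the long TSV keeps full precision.
#' @return invisibly, a character vector of the files written.
#' @export
render_outputs <- function(m, out_dir, diagonal_dash = TRUE, heatmap = FALSE,
                           digits = 2) {
  stopifnot(inherits(m, "similarity_matrix"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot create output directory '%s'", out_dir))

  wide <- format(round(m$values, digits), nsmall = digits, trim = TRUE)
  if (diagonal_dash) diag(wide) <- "-"
  wide_df <- data.frame(sample = rownames(m$values), wide,
                        check.names = FALSE, stringsAsFactors = FALSE)
  files <- character(0)
  write_tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    con <- file(path, "wb")
    on.exit(close(con))
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                       eol = "\n")
    path
  }
  files <- c(files, write_tsv(wide_df, "similarity_matrix.tsv"))
  files <- c(files, write_tsv(m$long, "similarity_pairs.tsv"))

  sums <- list(group_summary(m, "all"))
  for (mo in c("same_cultivar", "different_cultivar")) {
    s <- tryCatch(group_summary(m, mo), error = function(e) NULL)
    if (!is.null(s)) sums <- c(sums, list(s))
  }
  files <- c(files, write_tsv(do.call(rbind, sums), "group_summary.tsv"))

  if (heatmap) {
    if (!requireNamespace("pheatmap", quietly = TRUE)) {
      warning("pheatmap not available; skipping heatmap")
    } else {
      path <- file.path(out_dir, "similarity_heatmap.png")
      grDevices::png(path, width = 1200, height = 1000, res = 150)
      pheatmap::pheatmap(m$values, cluster_rows = FALSE, cluster_cols = FALSE,
                         display_numbers = TRUE, number_format = "%.2f",
                         main = "Exact matching rate (rows: query, cols: target)")
      grDevices::dev.off()
      files <- c(files, path)
    }
  }
  invisible(files)
}
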