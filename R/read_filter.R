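#' Filtering configuration
#'
#' Houses the stringent-filter constants of the discrimination pipeline's
#' first step. The defaults are deliberately strict: zero barcode mismatches
#' (stricter than the usual one-mismatch demultiplexing), every barcode base
#' at QV >= 30, and removal of any pair carrying a 4-base sliding window whose
#' mean quality falls below 30. Exact whole-length matching downstream makes
#' trimming useless, so failing pairs are removed outright.
#'
#' @param barcode_mismatches_allowed maximum Hamming distance between the
#'   sequenced index and the expected barcode (default 0).
#' @param barcode_min_qv minimum QV required at every barcode base (default 30).
#' @param window_len sliding-window width in bases (default 4).
#' @param window_min_mean_qv minimum mean QV over every window (default 30).
#' @param adapters character vector of adapter sequences to screen for
#'   (default none; screening is then a no-op).
#' @param min_overlap minimum length of an adapter prefix anchored at a read's
#'   3' end to count as adapter contamination (default 8); a full adapter
#'   occurring anywhere always counts.
#' @param headcrop,tailcrop bases to crop from each mate after filtering
#'   (default 0; nonzero values exist for parity experiments with
#'   trimming-based pipelines, not for the matching branch).
#' @return a `filter_config` list.
#' @export
filter_config <- function(barcode_mismatches_allowed = 0L,
                          barcode_min_qv = 30L,
                          window_len = 4L,
                          window_min_mean_qv = 30,
                          adapters = character(0),
                          min_overlap = 8L,
                          headcrop = 0L,
                          tailcrop = 0L) {
  stopifnot(window_len >= 1, barcode_mismatches_allowed >= 0,
            barcode_min_qv >= 0, window_min_mean_qv >= 0,
            min_overlap >= 1, headcrop >= 0, tailcrop >= 0)
  structure(list(barcode_mismatches_allowed = as.integer(barcode_mismatches_allowed),
                 barcode_min_qv = as.integer(barcode_min_qv),
                 window_len = as.integer(window_len),
                 window_min_mean_qv = as.numeric(window_min_mean_qv),
                 adapters = toupper(as.character(adapters)),
                 min_overlap = as.integer(min_overlap),
                 headcrop = as.integer(headcrop),
                 tailcrop = as.integer(tailcrop)),
            class = "filter_config")
}

#' Assign a read pair to its expected barcode
#'
#' Demultiplexing check for a single read: the sequenced index must match the
#' expected barcode within `barcode_mismatches_allowed` (default: exactly),
#' and every index base must reach `barcode_min_qv` — one QV 29 base is enough
#' to reject.
#'
#' @param index_seq sequenced index (barcode) string.
#' @param index_qual integer vector of index base qualities (see
#'   [decode_quality()]).
#' @param expected_barcode the sample's barcode.
#' @param config a [filter_config()].
#' @return one of `"assigned"`, `"rejected_mismatch"`, `"rejected_quality"`.
#' @export
barcode_assign <- function(index_seq, index_qual, expected_barcode,
                           config = filter_config()) {
  stopifnot(nzchar(expected_barcode))
  if (nchar(index_seq) != nchar(expected_barcode)) {
    stop("barcode length mismatch")
  }
  d <- barcode_mismatch_count(index_seq, expected_barcode)
  if (d > config$barcode_mismatches_allowed) return("rejected_mismatch")
  if (any(index_qual < config$barcode_min_qv)) return("rejected_quality")
  "assigned"
}

# Hamming distance between equal-length index sequences and one barcode,
# vectorised over the indices.
barcode_mismatch_count <- function(index_seq, barcode) {
  bl <- nchar(barcode)
  d <- integer(length(index_seq))
  for (j in seq_len(bl)) {
    d <- d + (substr(index_seq, j, j) != substr(barcode, j, j))
  }
  d
}

#' Does a read carry adapter sequence?
#'
#' A read is adapter-contaminated when any adapter occurs in full as a
#' substring, or when an adapter prefix of at least `min_overlap` bases sits
#' at the read's 3' end (read-through into the adapter).
#'
#' @param seq DNA string (or character vector of them).
#' @param adapters character vector of adapter sequences.
#' @param min_overlap minimum 3'-anchored prefix length.
#' @return logical, one value per element of `seq`.
#' @export
has_adapter <- function(seq, adapters, min_overlap = 8L) {
  hit <- logical(length(seq))
  if (length(adapters) == 0) {
    message("adapter screening skipped: no adapter sequences configured")
    return(hit)
  }
  L <- nchar(seq)
  for (ad in adapters) {
    hit <- hit | grepl(ad, seq, fixed = TRUE)
    kmax <- min(nchar(ad) - 1L, max(L))
    if (kmax >= min_overlap) {
      for (k in min_overlap:kmax) {
        pre <- substr(ad, 1L, k)
        hit <- hit | (substr(seq, L - k + 1L, L) == pre)
      }
    }
  }
  hit
}

#' Sliding-window quality check
#'
#' Passes iff no contiguous window of `window_len` bases (step 1) has mean
#' quality below `window_min_mean_qv`. A read shorter than the window is
#' evaluated on its single full-length window.
#'
#' @param qual integer vector of per-base qualities.
#' @param config a [filter_config()].
#' @return `TRUE` if the read passes.
#' @export
window_quality_pass <- function(qual, config = filter_config()) {
  stopifnot(length(qual) > 0)
  w <- min(config$window_len, length(qual))
  cs <- cumsum(c(0, qual))
  sums <- cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]
  all(sums / w >= config$window_min_mean_qv)
}

# Vectorised window check over Phred+33 strings; TRUE = pass.
# Groups reads by length so the common fixed-length case is one matrix pass.
window_pass_many <- function(qual_strings, config) {
  n <- length(qual_strings)
  pass <- logical(n)
  for (L in unique(nchar(qual_strings))) {
    idx <- which(nchar(qual_strings) == L)
    M <- phred_matrix(qual_strings[idx])
    w <- min(config$window_len, L)
    # running column cumsum, then min window sum across start positions
    cs <- matrix(0, nrow = length(idx), ncol = L + 1L)
    for (j in seq_len(L)) cs[, j + 1L] <- cs[, j] + M[, j]
    minsum <- rep(Inf, length(idx))
    for (s in seq_len(L - w + 1L)) {
      minsum <- pmin(minsum, cs[, s + w] - cs[, s])
    }
    pass[idx] <- (minsum / w) >= config$window_min_mean_qv
  }
  pass
}

#' Filter a collection of read pairs
#'
#' Applies the stringent filters in fixed order — barcode mismatch, barcode
#' quality, adapter (either mate), sliding-window quality (either mate) — and
#' removes a pair wholesale at its first failing check. Surviving pairs are
#' optionally head/tail-cropped. The returned report satisfies the
#' conservation identity
#' `input_pairs == kept_pairs + sum(removed_*)`.
#'
#' @param pairs a [read_pairs()] collection.
#' @param expected_barcode the sample's barcode; `NULL` or `""` disables the
#'   barcode checks (reads are then taken as already demultiplexed).
#' @param config a [filter_config()].
#' @return a list with elements `kept` (a `read_pairs`), `reason` (character
#'   vector over the input: `"kept"` or the removal reason), and `report`
#'   (one-row data.frame of counters).
#' @export
filter_read_pairs <- function(pairs, expected_barcode = NULL,
                              config = filter_config()) {
  stopifnot(inherits(pairs, "read_pairs"), inherits(config, "filter_config"))
  n <- length(pairs)
  reason <- rep("kept", n)
  active <- rep(TRUE, n)

  if (!is.null(expected_barcode) && nzchar(expected_barcode)) {
    bl <- nchar(expected_barcode)
    if (any(nchar(pairs$index_seq) != bl)) {
      stop("barcode length mismatch")
    }
    mm <- barcode_mismatch_count(pairs$index_seq, expected_barcode)
    bad <- active & (mm > config$barcode_mismatches_allowed)
    reason[bad] <- "barcode_mismatch"
    active <- active & !bad
    if (any(active)) {
      Q <- phred_matrix(pairs$index_qual[active])
      lowq <- apply(Q < config$barcode_min_qv, 1, any)
      idx <- which(active)[lowq]
      reason[idx] <- "barcode_quality"
      active[idx] <- FALSE
    }
  }

  if (length(config$adapters) > 0 && any(active)) {
    idx <- which(active)
    hit <- has_adapter(pairs$r1_seq[idx], config$adapters, config$min_overlap) |
      has_adapter(pairs$r2_seq[idx], config$adapters, config$min_overlap)
    reason[idx[hit]] <- "adapter"
    active[idx[hit]] <- FALSE
  }

  if (any(active)) {
    idx <- which(active)
    ok <- window_pass_many(pairs$r1_qual[idx], config) &
      window_pass_many(pairs$r2_qual[idx], config)
    reason[idx[!ok]] <- "window_quality"
    active[idx[!ok]] <- FALSE
  }

  kept <- pairs[active]
  if (config$headcrop > 0 || config$tailcrop > 0) {
    crop <- function(s) substr(s, 1L + config$headcrop,
                               nchar(s) - config$tailcrop)
    kept$r1_seq <- crop(kept$r1_seq); kept$r1_qual <- crop(kept$r1_qual)
    kept$r2_seq <- crop(kept$r2_seq); kept$r2_qual <- crop(kept$r2_qual)
  }

  report <- data.frame(
    input_pairs = n,
    removed_barcode_mismatch = sum(reason == "barcode_mismatch"),
    removed_barcode_quality = sum(reason == "barcode_quality"),
    removed_adapter = sum(reason == "adapter"),
    removed_window_quality = sum(reason == "window_quality"),
    kept_pairs = sum(reason == "kept"))
  stopifnot(report$input_pairs ==
              report$kept_pairs + sum(unlist(report[grep("^removed_", names(report))])))
  list(kept = kept, reason = reason, report = report)
}

#' Filter a single read pair
#'
#' Convenience scalar form of [filter_read_pairs()].
#'
#' @inheritParams filter_read_pairs
#' @param pair a one-element `read_pairs`.
#' @return `"kept"` or the removal reason.
#' @export
filter_pair <- function(pair, expected_barcode = NULL, config = filter_config()) {
  stopifnot(length(pair) == 1L)
  filter_read_pairs(pair, expected_barcode, config)$reason
}
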