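#' Simulation configuration for a synthetic amplicon cohort
#'
#' Describes a MIG-seq-like cohort with known ground truth: a cultivar
#' genealogy (clones, bud mutants, distinct lines, diverged cultivars as
#' branches of a tree with per-base divergence rates), samples assigned to
#' cultivars, and a sequencing model. Every read from a locus is the
#' identical primer-anchored fragment before errors — the property that makes
#' ">10 identical whole-length copies" attainable — with negative-binomial
#' per-locus depth, two-level base qualities, optional adapter read-through
#' and a fraction of pairs emitted in flipped orientation to exercise strand
#' folding.
#'
#' @param n_loci number of amplified loci per genome.
#' @param locus_len locus length in bases; must cover both read lengths.
#' @param r1_len,r2_len sequenced lengths of the two mates (mate 1 reads the
#'   locus start, mate 2 the reverse complement of the locus end).
#' @param cultivar_tree data.frame with columns `cultivar_id`, `parent_id`
#'   (`NA` for the single root), `divergence` (per-base substitution
#'   probability on the branch from the parent).
#' @param samples data.frame with columns `sample_id`, `cultivar_id`, and
#'   optionally `n_duplicates` (default 2 PCR duplicates per sample).
#' @param depth_mean expected reads per locus per duplicate.
#' @param depth_dispersion negative-binomial size parameter; `Inf` gives
#'   Poisson depth.
#' @param depth_floor minimum reads per retained locus per duplicate
#'   (default 0; raise to guarantee loci clear the copy threshold).
#' @param locus_dropout_prob probability a locus is absent from a sample
#'   (shared across its duplicates — amplification failure of the extract).
#' @param dup_dropout_prob additional per-duplicate locus dropout.
#' @param seq_error_rate iid per-base substitution error probability.
#' @param base_qv_high,base_qv_low quality assigned to clean / erroneous
#'   bases.
#' @param barcode_len index (barcode) length in bases.
#' @param adapter adapter sequence used for read-through contamination.
#' @param adapter_contam_prob probability a pair has the adapter appended to
#'   one mate.
#' @param flip_fraction fraction of pairs emitted mate-swapped and
#'   reverse-complemented.
#' @param rng_seed integer seed; all randomness derives from it (per-library
#'   substreams are derived from seed, sample and duplicate ids, so any one
#'   file can be regenerated in isolation).
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_loci = 500L,
                              locus_len = 150L,
                              r1_len = 75L,
                              r2_len = 75L,
                              cultivar_tree = data.frame(
                                cultivar_id = "C1", parent_id = NA_character_,
                                divergence = 0),
                              samples = data.frame(
                                sample_id = c("C1a", "C1b"),
                                cultivar_id = "C1"),
                              depth_mean = 20,
                              depth_dispersion = 10,
                              depth_floor = 0L,
                              locus_dropout_prob = 0.05,
                              dup_dropout_prob = 0,
                              seq_error_rate = 0.001,
                              base_qv_high = 40L,
                              base_qv_low = 20L,
                              barcode_len = 8L,
                              adapter = "AGATCGGAAGAGC",
                              adapter_contam_prob = 0.01,
                              flip_fraction = 0.2,
                              rng_seed = 1L) {
  stopifnot(n_loci > 0, locus_len > 0, r1_len > 0, r2_len > 0,
            r1_len <= locus_len, r2_len <= locus_len,
            depth_mean > 0, depth_dispersion > 0, depth_floor >= 0,
            barcode_len >= 1)
  for (p in c(locus_dropout_prob, dup_dropout_prob, seq_error_rate,
              adapter_contam_prob, flip_fraction)) {
    stopifnot(p >= 0, p <= 1)
  }
  tree <- as.data.frame(cultivar_tree, stringsAsFactors = FALSE)
  stopifnot(all(c("cultivar_id", "parent_id", "divergence") %in% names(tree)))
  validate_tree(tree)
  stopifnot(all(tree$divergence >= 0 & tree$divergence < 1))
  samp <- as.data.frame(samples, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "cultivar_id") %in% names(samp)))
  if (!"n_duplicates" %in% names(samp)) samp$n_duplicates <- 2L
  stopifnot(!anyDuplicated(samp$sample_id),
            all(samp$cultivar_id %in% tree$cultivar_id))
  structure(list(n_loci = as.integer(n_loci), locus_len = as.integer(locus_len),
                 r1_len = as.integer(r1_len), r2_len = as.integer(r2_len),
                 cultivar_tree = tree, samples = samp,
                 depth_mean = depth_mean, depth_dispersion = depth_dispersion,
                 depth_floor = as.integer(depth_floor),
                 locus_dropout_prob = locus_dropout_prob,
                 dup_dropout_prob = dup_dropout_prob,
                 seq_error_rate = seq_error_rate,
                 base_qv_high = as.integer(base_qv_high),
                 base_qv_low = as.integer(base_qv_low),
                 barcode_len = as.integer(barcode_len),
                 adapter = toupper(adapter),
                 adapter_contam_prob = adapter_contam_prob,
                 flip_fraction = flip_fraction,
                 rng_seed = as.integer(rng_seed)),
            class = "simulation_config")
}

validate_tree <- function(tree) {
  roots <- is.na(tree$parent_id)
  if (sum(roots) != 1) stop("cultivar_tree must have exactly one root (parent_id = NA)")
  known <- tree$cultivar_id
  if (anyDuplicated(known)) stop("cultivar_tree: duplicated cultivar_id")
  if (!all(tree$parent_id[!roots] %in% known)) {
    stop("cultivar_tree: parent_id not present among cultivar_id")
  }
  # acyclicity: walking parent pointers must reach the root within n steps
  n <- nrow(tree)
  parent <- stats::setNames(tree$parent_id, tree$cultivar_id)
  for (cv in known) {
    cur <- cv; steps <- 0L
    while (!is.na(parent[[cur]])) {
      cur <- parent[[cur]]; steps <- steps + 1L
      if (steps > n) stop("cultivar_tree contains a cycle")
    }
  }
  invisible(TRUE)
}

# Deterministic 31-bit substream seed from the master seed and string labels,
# so each (sample, duplicate) library draws from its own reproducible stream.
substream_seed <- function(seed, ...) {
  s <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(paste(..., sep = ":"))) {
    s <- (s * 31 + code) %% 2147483647
  }
  as.integer(s)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# Per-base substitution at rate d; substituted bases become one of the other
# three nucleotides uniformly.
mutate_loci <- function(loci, d) {
  if (d == 0 || length(loci) == 0) return(loci)
  chars <- strsplit(loci, "", fixed = TRUE)
  lens <- lengths(chars)
  flat <- unlist(chars, use.names = FALSE)
  hit <- which(stats::runif(length(flat)) < d)
  if (length(hit) > 0) {
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
    flat[hit] <- vapply(flat[hit], function(b) sample(alt[[b]], 1L), character(1))
  }
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  vapply(seq_along(loci), function(i) {
    paste(flat[starts[i]:ends[i]], collapse = "")
  }, character(1))
}

#' Simulate cultivar genomes along a genealogy
#'
#' The root cultivar's loci are uniform random sequences; each child copies
#' its parent with independent per-base substitutions at the branch
#' divergence rate. Deterministic given `rng_seed`.
#'
#' @param config a [simulation_config()].
#' @return named list mapping cultivar_id to a character vector of locus
#'   sequences.
#' @export
simulate_genomes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(substream_seed(config$rng_seed, "genomes"))
  tree <- config$cultivar_tree
  genomes <- list()
  pending <- tree
  root <- pending$cultivar_id[is.na(pending$parent_id)]
  genomes[[root]] <- random_dna(config$n_loci, config$locus_len)
  done <- root
  pending <- pending[pending$cultivar_id != root, , drop = FALSE]
  while (nrow(pending) > 0) {
    ready <- pending$parent_id %in% done
    if (!any(ready)) stop("cultivar_tree is not connected")
    for (i in which(ready)) {
      genomes[[pending$cultivar_id[i]]] <-
        mutate_loci(genomes[[pending$parent_id[i]]], pending$divergence[i])
    }
    done <- c(done, pending$cultivar_id[ready])
    pending <- pending[!ready, , drop = FALSE]
  }
  genomes
}

# Introduce iid base errors into reads; returns sequences and Phred+33
# quality strings (clean bases qv_high, erroneous bases qv_low).
apply_errors <- function(seqs, rate, qv_high, qv_low) {
  n <- length(seqs)
  lens <- nchar(seqs)
  hi <- intToUtf8(qv_high + 33L)
  lo <- intToUtf8(qv_low + 33L)
  quals <- strrep(hi, lens)
  if (rate > 0 && n > 0) {
    n_err <- stats::rbinom(n, lens, rate)
    for (i in which(n_err > 0)) {
      pos <- sample.int(lens[i], n_err[i])
      alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                  G = c("A", "C", "T"), T = c("A", "C", "G"))
      for (p in pos) {
        b <- substr(seqs[i], p, p)
        substr(seqs[i], p, p) <- sample(alt[[b]], 1L)
        substr(quals[i], p, p) <- lo
      }
    }
  }
  list(seq = seqs, qual = quals)
}

str_rev <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

#' Simulate one PCR-duplicate library for a sample
#'
#' Draws per-locus depth (negative binomial), materialises identical
#' primer-anchored read pairs per locus, applies base errors, adapter
#' read-through and orientation flips, attaches the sample barcode as an
#' index read, and writes R1/R2/I1 FASTQ files. Deterministic given the
#' config seed, sample and duplicate ids.
#'
#' @param genomes output of [simulate_genomes()].
#' @param sample_id,cultivar_id,duplicate_id identifiers for this library.
#' @param barcode the sample's index sequence.
#' @param loci_idx integer vector of loci retained for this sample (after
#'   sample-level dropout).
#' @param config a [simulation_config()].
#' @param out_prefix path prefix; files are written as
#'   `<prefix>_R1.fastq`, `<prefix>_R2.fastq`, `<prefix>_I1.fastq`.
#' @return invisibly, a list with the three paths and the number of pairs.
#' @export
simulate_library <- function(genomes, sample_id, cultivar_id, duplicate_id,
                             barcode, loci_idx, config, out_prefix) {
  stopifnot(inherits(config, "simulation_config"),
            cultivar_id %in% names(genomes))
  set.seed(substream_seed(config$rng_seed, "library", sample_id, duplicate_id))
  loci <- genomes[[cultivar_id]][loci_idx]
  keep <- stats::runif(length(loci)) >= config$dup_dropout_prob
  loci <- loci[keep]
  L <- config$locus_len
  r1 <- substr(loci, 1L, config$r1_len)
  r2 <- revcomp(substr(loci, L - config$r2_len + 1L, L))
  depth <- if (is.finite(config$depth_dispersion)) {
    stats::rnbinom(length(loci), size = config$depth_dispersion,
                   mu = config$depth_mean)
  } else {
    stats::rpois(length(loci), config$depth_mean)
  }
  depth <- pmax(depth, config$depth_floor)
  r1_reads <- rep(r1, depth)
  r2_reads <- rep(r2, depth)
  n <- length(r1_reads)

  e1 <- apply_errors(r1_reads, config$seq_error_rate,
                     config$base_qv_high, config$base_qv_low)
  e2 <- apply_errors(r2_reads, config$seq_error_rate,
                     config$base_qv_high, config$base_qv_low)
  r1_seq <- e1$seq; r1_qual <- e1$qual
  r2_seq <- e2$seq; r2_qual <- e2$qual

  if (config$flip_fraction > 0 && n > 0) {
    fl <- which(stats::runif(n) < config$flip_fraction)
    if (length(fl) > 0) {
      new_r1 <- revcomp(r2_seq[fl]); new_r1q <- str_rev(r2_qual[fl])
      new_r2 <- revcomp(r1_seq[fl]); new_r2q <- str_rev(r1_qual[fl])
      r1_seq[fl] <- new_r1; r1_qual[fl] <- new_r1q
      r2_seq[fl] <- new_r2; r2_qual[fl] <- new_r2q
    }
  }

  # read-through contamination shows the adapter at the 3' end of the mate as
  # sequenced, so it is applied after orientation flipping
  if (config$adapter_contam_prob > 0 && n > 0) {
    contam <- stats::runif(n) < config$adapter_contam_prob
    mate1 <- stats::runif(n) < 0.5
    adq <- strrep(intToUtf8(config$base_qv_high + 33L), nchar(config$adapter))
    i1 <- which(contam & mate1)
    r1_seq[i1] <- paste0(r1_seq[i1], config$adapter)
    r1_qual[i1] <- paste0(r1_qual[i1], adq)
    i2 <- which(contam & !mate1)
    r2_seq[i2] <- paste0(r2_seq[i2], config$adapter)
    r2_qual[i2] <- paste0(r2_qual[i2], adq)
  }

  ids <- sprintf("%s.%s.%07d", sample_id, duplicate_id, seq_len(n))
  bq <- strrep(intToUtf8(config$base_qv_high + 33L), config$barcode_len)
  pairs <- read_pairs(id = ids, r1_seq = r1_seq, r1_qual = r1_qual,
                      r2_seq = r2_seq, r2_qual = r2_qual,
                      index_seq = rep(barcode, n),
                      index_qual = rep(bq, n))
  paths <- paste0(out_prefix, c("_R1.fastq", "_R2.fastq", "_I1.fastq"))
  if (n == 0) {
    # write empty but valid FASTQ files
    for (p in paths) writeLines(character(0), p)
  } else {
    write_paired_fastq(pairs, paths[1], paths[2], paths[3])
  }
  invisible(list(r1_path = paths[1], r2_path = paths[2], index_path = paths[3],
                 n_pairs = n))
}

#' Simulate a full cohort with manifest and truth table
#'
#' Generates genomes along the configured genealogy, distinct per-sample
#' barcodes, per-sample locus dropout shared across duplicates, and one
#' FASTQ trio per (sample, duplicate). Writes `manifest.tsv` (consumable by
#' the pipeline), `truth_samples.tsv` (sample, cultivar, barcode, loci
#' retained) and `truth_divergence.tsv` (per ordered cultivar pair, the
#' summed per-base divergence along the tree path).
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `manifest` (path), `truth_samples`,
#'   `truth_divergence` (data.frames), and `genomes`.
#' @export
simulate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genomes <- simulate_genomes(config)

  set.seed(substream_seed(config$rng_seed, "barcodes"))
  samp <- config$samples
  repeat {
    barcodes <- random_dna(nrow(samp), config$barcode_len)
    if (!anyDuplicated(barcodes)) break
  }

  rows <- list(); truth_rows <- list()
  for (i in seq_len(nrow(samp))) {
    sid <- samp$sample_id[i]; cv <- samp$cultivar_id[i]
    set.seed(substream_seed(config$rng_seed, "dropout", sid))
    retained <- which(stats::runif(config$n_loci) >= config$locus_dropout_prob)
    truth_rows[[i]] <- data.frame(sample_id = sid, cultivar = cv,
                                  barcode = barcodes[i],
                                  n_loci_retained = length(retained))
    for (d in seq_len(samp$n_duplicates[i])) {
      did <- paste0("dup", d)
      prefix <- file.path(out_dir, paste(sid, did, sep = "_"))
      simulate_library(genomes, sid, cv, did, barcodes[i], retained,
                       config, prefix)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, cultivar = cv, duplicate_id = did,
        r1_path = basename(paste0(prefix, "_R1.fastq")),
        r2_path = basename(paste0(prefix, "_R2.fastq")),
        index_path = basename(paste0(prefix, "_I1.fastq")),
        barcode = barcodes[i])
    }
  }
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(out_dir, "manifest.tsv")
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_samples <- do.call(rbind, truth_rows)
  utils::write.table(truth_samples, file.path(out_dir, "truth_samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth_div <- tree_divergence_table(config$cultivar_tree)
  utils::write.table(truth_div, file.path(out_dir, "truth_divergence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(manifest = manifest_path, truth_samples = truth_samples,
                 truth_divergence = truth_div, genomes = genomes))
}

# Summed per-branch divergence along the tree path between every ordered
# cultivar pair.
tree_divergence_table <- function(tree) {
  parent <- stats::setNames(tree$parent_id, tree$cultivar_id)
  div <- stats::setNames(tree$divergence, tree$cultivar_id)
  path_to_root <- function(cv) {
    path <- c(); cur <- cv
    while (!is.na(cur)) { path <- c(path, cur); cur <- parent[[cur]] }
    path
  }
  ids <- tree$cultivar_id
  out <- expand.grid(cultivar_a = ids, cultivar_b = ids,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$divergence <- mapply(function(a, b) {
    pa <- path_to_root(a); pb <- path_to_root(b)
    common <- intersect(pa, pb)[1]
    branches <- c(pa[seq_len(match(common, pa) - 1L)],
                  pb[seq_len(match(common, pb) - 1L)])
    sum(div[branches])
  }, out$cultivar_a, out$cultivar_b)
  out
}

#' Expected exact-match probability between diverged cultivars
#'
#' Closed-form oracle for the similarity statistic in the error-free,
#' saturating-depth, no-dropout limit: a read pair spanning
#' `r1_len + r2_len` bases from one cultivar matches the other cultivar's
#' locus exactly with probability `(1 - d)^(r1_len + r2_len)` at per-base
#' divergence `d`.
#'
#' @param d per-base divergence in `[0, 1)`.
#' @param r1_len,r2_len mate lengths in bases.
#' @return expected similarity in `[0, 1]`.
#' @examples
#' expected_pair_similarity(0.01, 75, 75)  # ~0.2215
#' @export
expected_pair_similarity <- function(d, r1_len, r2_len) {
  stopifnot(d >= 0, d < 1)
  (1 - d)^(r1_len + r2_len)
}
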