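# In-memory fixture builders and independent brute-force oracles used across
# the suite. The oracles deliberately avoid the package's canonical-key path:
# reverse complements are compared explicitly, pair by pair.

qv <- function(q, len) strrep(intToUtf8(q + 33L), len)

# one read_pairs collection from parallel sequence vectors, uniform quality
mk_pairs <- function(r1, r2, q = 40L, index = NULL, index_q = 40L) {
  n <- length(r1)
  if (is.null(index)) index <- character(n)
  read_pairs(id = sprintf("read%03d", seq_len(n)),
             r1_seq = r1, r1_qual = qv(q, nchar(r1)),
             r2_seq = r2, r2_qual = qv(q, nchar(r2)),
             index_seq = index,
             index_qual = ifelse(nzchar(index), qv(index_q, nchar(index)), ""))
}

rand_dna <- function(len, n = 1) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# character-level reverse complement, independent of Biostrings
oracle_revcomp <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# quadratic all-vs-all unique-pair counting with explicit reverse-complement
# comparison and no canonicalization; returns multiplicities in arbitrary
# group order plus one representative (r1, r2) per group
oracle_count_pairs <- function(r1, r2) {
  n <- length(r1)
  group <- integer(n)
  ng <- 0L
  rep_r1 <- character(0); rep_r2 <- character(0)
  for (i in seq_len(n)) {
    assigned <- FALSE
    g <- 0L
    while (g < ng && !assigned) {
      g <- g + 1L
      same <- (r1[i] == rep_r1[g] && r2[i] == rep_r2[g]) ||
        (r1[i] == oracle_revcomp(rep_r2[g]) && r2[i] == oracle_revcomp(rep_r1[g]))
      if (same) { group[i] <- g; assigned <- TRUE }
    }
    if (!assigned) {
      ng <- ng + 1L
      rep_r1[ng] <- r1[i]; rep_r2[ng] <- r2[i]
      group[i] <- ng
    }
  }
  list(counts = tabulate(group, ng), rep_r1 = rep_r1, rep_r2 = rep_r2)
}

# similarity by naive string search: for every target reference pair, scan
# the query's pairs for an exact or reverse-complement match
oracle_similarity <- function(target_r1, target_r2, query_r1, query_r2) {
  hit <- vapply(seq_along(target_r1), function(i) {
    any((query_r1 == target_r1[i] & query_r2 == target_r2[i]) |
          (query_r1 == oracle_revcomp(target_r2[i]) &
             query_r2 == oracle_revcomp(target_r1[i])))
  }, logical(1))
  mean(hit)
}

# small two-cultivar cohort simulated to disk; returns the cohort list
sim_small_cohort <- function(dir, seed = 1L, n_loci = 60L, divergence = 0.02,
                             samples = NULL, error = 0, dropout = 0,
                             adapter_p = 0, depth_mean = 20, flip = 0.2) {
  tree <- data.frame(cultivar_id = c("CA", "CB"),
                     parent_id = c(NA, "CA"),
                     divergence = c(0, divergence))
  if (is.null(samples)) {
    samples <- data.frame(sample_id = c("CA1", "CB1"),
                          cultivar_id = c("CA", "CB"))
  }
  cfg <- simulation_config(n_loci = n_loci, locus_len = 150L,
                           r1_len = 75L, r2_len = 75L,
                           cultivar_tree = tree, samples = samples,
                           depth_mean = depth_mean, locus_dropout_prob = dropout,
                           seq_error_rate = error,
                           adapter_contam_prob = adapter_p,
                           flip_fraction = flip, rng_seed = seed)
  list(config = cfg, cohort = simulate_cohort(cfg, dir))
}
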