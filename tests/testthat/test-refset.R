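test_that("canonical keys fold a pair with its reverse-complemented twin", {
  # revcomp of ("ACGT","TTTT") swapped is ("AAAA","ACGT"): same fragment
  expect_equal(canonical_key("ACGT", "TTTT"), canonical_key("AAAA", "ACGT"))
  # palindromic pair: forward and folded forms coincide
  expect_equal(canonical_key("ACGT", "ACGT"), "ACGT#ACGT")
  expect_equal(revcomp("ACGTN"), "NACGT")
  expect_error(canonical_key("ACGU", "ACGT"), "invalid nucleotide")
  set.seed(5)
  r1 <- rand_dna(20, 50); r2 <- rand_dna(20, 50)
  k <- canonical_key(r1, r2)
  # strand invariance and idempotence on every random pair
  expect_equal(canonical_key(oracle_revcomp(r2), oracle_revcomp(r1)), k)
  parts <- strsplit(k, "#", fixed = TRUE)
  expect_equal(canonical_key(vapply(parts, `[`, "", 1),
                             vapply(parts, `[`, "", 2)), k)
  expect_true(all(vapply(gregexpr("#", k, fixed = TRUE), length, 1L) == 1L))
})

test_that("count_unique pools copies across orientations and conserves reads", {
  r1 <- "ACGTACGTAC"; r2 <- "GGGGTTTTCC"
  p <- mk_pairs(c(rep(r1, 3), rep(oracle_revcomp(r2), 2)),
                c(rep(r2, 3), rep(oracle_revcomp(r1), 2)))
  cu <- count_unique(p, "S", "dup1")
  expect_length(cu$counts, 1L)
  expect_equal(unname(cu$counts), 5L)
  expect_equal(sum(cu$counts), length(p))
  expect_length(count_unique(mk_pairs(character(0), character(0)))$counts, 0L)
  # without strand pooling the two orientations are thresholded separately
  cu2 <- count_unique(p, "S", "dup1", strand_pool = FALSE)
  expect_equal(unname(cu2$counts), 3L)
})

test_that("hashed counting matches the quadratic all-vs-all oracle", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(20:60, 1)
    pool_r1 <- rand_dna(12, 6); pool_r2 <- rand_dna(12, 6)
    idx <- sample(6, n, replace = TRUE)
    flip <- runif(n) < 0.4
    r1 <- ifelse(flip, oracle_revcomp(pool_r2[idx]), pool_r1[idx])
    r2 <- ifelse(flip, oracle_revcomp(pool_r1[idx]), pool_r2[idx])
    cu <- count_unique(mk_pairs(r1, r2))
    oc <- oracle_count_pairs(r1, r2)
    expect_equal(sort(unname(cu$counts)), sort(oc$counts))
    expect_equal(names(cu$counts),
                 sort(canonical_key(oc$rep_r1, oc$rep_r2)))
  }
})

test_that("high-quality sets require strictly more than ten copies by default", {
  p <- mk_pairs(c(rep("ACGT", 11), rep("TTTT", 10)),
                c(rep("GGGG", 11), rep("CCCC", 10)))
  hq <- high_quality_set(count_unique(p))
  expect_equal(hq, canonical_key("ACGT", "GGGG"))
  expect_length(high_quality_set(count_unique(mk_pairs("ACGT", "GGGG"))), 0L)
  # antitone in the threshold
  cu <- count_unique(p)
  expect_true(all(high_quality_set(cu, 12L) %in% high_quality_set(cu, 11L)))
  expect_true(all(high_quality_set(cu, 11L) %in% high_quality_set(cu, 2L)))
})

test_that("the reference is the intersection across duplicates", {
  expect_equal(super_high_quality_set(list(c("a", "b"), c("a", "b")))$shq,
               c("a", "b"))
  expect_length(super_high_quality_set(list("a", "b"))$shq, 0L)
  expect_equal(super_high_quality_set(list(c("k1", "k2", "k3"),
                                           c("k2", "k3", "k4")))$shq,
               c("k2", "k3"))
  expect_error(super_high_quality_set(list(c("a"))), ">=2 PCR duplicates")
  expect_warning(s <- super_high_quality_set(list(c("a")), allow_single = TRUE),
                 "single duplicate")
  expect_equal(s$shq, "a")
})

test_that("comprehensive sets union duplicates and contain the reference", {
  d1 <- count_unique(mk_pairs(c("ACGT", "ACGT"), c("GGGG", "GGGG")), "S", "dup1")
  d2 <- count_unique(mk_pairs("TTTT", "CCCC"), "S", "dup2")
  comp <- comprehensive_set(list(d1, d2))
  expect_setequal(comp$keys, c(canonical_key("ACGT", "GGGG"),
                               canonical_key("TTTT", "CCCC")))
  expect_length(comprehensive_set(list(count_unique(
    mk_pairs(character(0), character(0)), "S", "dup1")))$keys, 0L)
  other <- count_unique(mk_pairs("AAAA", "TTTT"), "OTHER", "dup1")
  expect_error(comprehensive_set(list(d1, other)), "multiple samples")
})

test_that("set containments hold on simulated libraries with errors", {
  td <- withr::local_tempdir()
  sim <- sim_small_cohort(td, seed = 9, n_loci = 40, error = 0.01,
                          dropout = 0.1, depth_mean = 25)
  m <- read_manifest(sim$cohort$manifest)
  rows <- m[m$sample_id == "CA1", ]
  counts <- lapply(seq_len(nrow(rows)), function(i) {
    count_unique(read_paired_fastq(rows$r1_path[i], rows$r2_path[i],
                                   rows$index_path[i]),
                 "CA1", rows$duplicate_id[i])
  })
  hq <- lapply(counts, high_quality_set)
  ref <- super_high_quality_set(hq, "CA1")
  comp <- comprehensive_set(counts)
  for (h in hq) expect_true(all(ref$shq %in% h))
  expect_true(all(ref$shq %in% comp$keys))
  for (i in seq_along(counts)) {
    expect_true(all(hq[[i]] %in% names(counts[[i]]$counts)))
  }
})

test_that("reverse-complementing a whole library changes no set", {
  set.seed(31)
  r1 <- rand_dna(15, 80); r2 <- rand_dna(15, 80)
  idx <- sample(80, 200, replace = TRUE)
  a <- mk_pairs(r1[idx], r2[idx])
  b <- mk_pairs(oracle_revcomp(r2[idx]), oracle_revcomp(r1[idx]))
  ca <- count_unique(a, "S", "d1"); cb <- count_unique(b, "S", "d1")
  expect_equal(ca$counts, cb$counts)
  expect_equal(high_quality_set(ca, 2L), high_quality_set(cb, 2L))
})

test_that("key sets serialize to sorted plain text and round-trip", {
  td <- withr::local_tempdir()
  ref <- super_high_quality_set(list(c("TT#GG", "AA#CC"), c("AA#CC", "TT#GG")),
                                sample_id = "S7", provenance = c("dup1", "dup2"))
  comp <- comprehensive_set(list(count_unique(mk_pairs("ACGT", "GGGG"),
                                              "S7", "dup1")))
  pr <- file.path(td, "S7.shq.keys"); pc <- file.path(td, "S7.comprehensive.keys")
  write_key_set(ref, pr, min_copies = 11L)
  write_key_set(comp, pc)
  expect_equal(read_key_set(pr)$shq, c("AA#CC", "TT#GG"))
  expect_equal(read_key_set(pr)$provenance, c("dup1", "dup2"))
  expect_equal(read_key_set(pc)$keys, comp$keys)
  first <- readBin(pr, "raw", file.size(pr))
  write_key_set(ref, pr, min_copies = 11L)
  expect_identical(readBin(pr, "raw", file.size(pr)), first)  # byte-stable
})
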