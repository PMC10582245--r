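mk_ref <- function(keys, id = "T") {
  structure(list(sample_id = id, shq = sort(keys), provenance = c("dup1", "dup2")),
            class = "reference_set")
}
mk_comp <- function(keys, id = "Q") {
  structure(list(sample_id = id, keys = sort(keys)), class = "comprehensive_set")
}

test_that("similarity is the matched fraction of the target's reference", {
  t4 <- mk_ref(c("k1", "k2", "k3", "k4"))
  expect_equal(as.numeric(similarity(mk_comp(c("k1", "k3")), t4)), 0.5)
  expect_equal(as.numeric(similarity(mk_comp(c("k1", "k2", "k3", "k4", "k9")),
                                     t4)), 1.0)
  expect_equal(as.numeric(similarity(mk_comp(c("x", "y")), t4)), 0)
  s <- similarity(mk_comp(c("k1", "k3")), t4)
  expect_equal(attr(s, "n_matched"), 2L)
  expect_equal(attr(s, "n_target_shq"), 4L)
  expect_error(similarity(mk_comp("k1"), mk_ref(character(0))),
               "no super high-quality reference reads")
})

test_that("similarity matches the naive string-search oracle with revcomps", {
  set.seed(13)
  for (rep in 1:20) {
    n_t <- sample(5:40, 1); n_q <- sample(5:60, 1)
    t_r1 <- rand_dna(10, n_t); t_r2 <- rand_dna(10, n_t)
    keep <- runif(n_t) < 0.5
    # query holds some target pairs (randomly strand-flipped) plus noise
    q_r1 <- c(ifelse(runif(sum(keep)) < 0.5, t_r1[keep],
                     oracle_revcomp(t_r2[keep])), rand_dna(10, n_q))
    q_r2 <- c(ifelse(q_r1[seq_len(sum(keep))] == t_r1[keep], t_r2[keep],
                     oracle_revcomp(t_r1[keep])), rand_dna(10, n_q))
    got <- as.numeric(similarity(
      mk_comp(unique(canonical_key(q_r1, q_r2))),
      mk_ref(unique(canonical_key(t_r1, t_r2)))))
    # oracle works on deduplicated pairs, never canonicalizing
    oc <- oracle_count_pairs(t_r1, t_r2)
    expect_equal(got, oracle_similarity(oc$rep_r1, oc$rep_r2, q_r1, q_r2))
  }
})

test_that("the matrix has unit diagonal, is asymmetric, and stays in [0,1]", {
  refs <- list(mk_ref(c("a", "b", "c", "d"), "S1"), mk_ref(c("a", "e"), "S2"))
  comps <- list(mk_comp(c("a", "b", "c", "d"), "S1"),
                mk_comp(c("a", "e", "b"), "S2"))
  m <- similarity_matrix(comps, refs,
                         cultivars = c(S1 = "CU1", S2 = "CU2"))
  expect_equal(diag(m$values), c(S1 = 1, S2 = 1))
  expect_equal(m$values["S1", "S2"], 0.5)   # S1 query holds a of {a,e}
  expect_equal(m$values["S2", "S1"], 0.5)   # S2 query holds a,b of {a,b,c,d}
  expect_true(all(m$values >= 0 & m$values <= 1))
  # constructed asymmetric instance
  refs2 <- list(mk_ref(c("a", "b"), "S1"), mk_ref(c("a", "x", "y", "z"), "S2"))
  comps2 <- list(mk_comp(c("a", "b"), "S1"), mk_comp(c("a", "b", "x", "y", "z"), "S2"))
  m2 <- similarity_matrix(comps2, refs2)
  expect_false(isSymmetric(m2$values))
  expect_error(similarity_matrix(comps[1], refs[1]), "length")
  expect_error(similarity_matrix(comps, list(mk_ref(character(0), "S1"),
                                             refs[[2]])),
               "empty super high-quality")
})

test_that("adding query keys never decreases similarity", {
  set.seed(17)
  t <- mk_ref(paste0("k", 1:30))
  keys <- character(0)
  last <- 0
  for (step in 1:6) {
    keys <- union(keys, sample(c(paste0("k", 1:30), paste0("x", 1:30)), 10))
    s <- as.numeric(similarity(mk_comp(keys), t))
    expect_gte(s, last)
    last <- s
  }
})

test_that("group summaries average ordered off-diagonal entries by cultivar", {
  vals <- matrix(c(1, 0.2, 0.3,
                   0.4, 1, 0.5,
                   0.6, 0.7, 1), 3, 3, byrow = TRUE,
                 dimnames = list(c("A1", "A2", "B1"), c("A1", "A2", "B1")))
  cultivars <- c(A1 = "A", A2 = "A", B1 = "B")
  long <- expand.grid(query = rownames(vals), target = colnames(vals),
                      stringsAsFactors = FALSE)
  long$query_cultivar <- cultivars[long$query]
  long$target_cultivar <- cultivars[long$target]
  long$similarity <- vals[cbind(long$query, long$target)]
  long$n_matched <- NA_integer_; long$n_target_shq <- NA_integer_
  m <- structure(list(values = vals, cultivars = cultivars, long = long),
                 class = "similarity_matrix")
  g_all <- group_summary(m, "all")
  expect_equal(g_all$n_pairs, 6L)
  expect_equal(g_all$mean, mean(c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7)))
  g_same <- group_summary(m, "same_cultivar")
  expect_equal(g_same$n_pairs, 2L)
  expect_equal(g_same$mean, mean(c(0.2, 0.4)))
  expect_equal(g_same$sd, sd(c(0.2, 0.4)))
  g_diff <- group_summary(m, "different_cultivar")
  expect_equal(g_diff$n_pairs, 4L)
  g_pair <- group_summary(m, "pair", pair = c("A", "B"))
  expect_equal(g_pair$n_pairs, 4L)
  expect_equal(g_pair$mean, mean(c(0.3, 0.5, 0.6, 0.7)))
  # every cultivar a singleton: same-cultivar selection is empty
  m$long$query_cultivar <- m$long$query
  m$long$target_cultivar <- m$long$target
  expect_error(group_summary(m, "same_cultivar"), "no pairs in group")
})

test_that("two clones of one cultivar give mean 1 and sd 0", {
  refs <- list(mk_ref(c("a", "b"), "S1"), mk_ref(c("a", "b"), "S2"))
  comps <- list(mk_comp(c("a", "b"), "S1"), mk_comp(c("a", "b"), "S2"))
  m <- similarity_matrix(comps, refs, cultivars = c(S1 = "C", S2 = "C"))
  g <- group_summary(m, "same_cultivar")
  expect_equal(g$mean, 1)
  expect_equal(g$sd, 0)
})

test_that("rendered TSVs are complete, cross-consistent and byte-stable", {
  td <- withr::local_tempdir()
  set.seed(23)
  n <- 7
  ids <- sprintf("S%d", 1:n)
  keysets <- lapply(1:n, function(i) paste0("k", sample(40, 25)))
  refs <- lapply(1:n, function(i) mk_ref(keysets[[i]], ids[i]))
  comps <- lapply(1:n, function(i)
    mk_comp(union(keysets[[i]], paste0("k", sample(40, 10))), ids[i]))
  m <- similarity_matrix(comps, refs)
  files <- render_outputs(m, td)
  wide <- read.delim(file.path(td, "similarity_matrix.tsv"),
                     check.names = FALSE)
  expect_equal(dim(wide), c(n, n + 1))
  expect_true(all(diag(as.matrix(wide[, -1])) == "-"))
  long <- read.delim(file.path(td, "similarity_pairs.tsv"))
  expect_equal(nrow(long), n * n)
  expect_equal(long$similarity, long$n_matched / long$n_target_shq)
  bytes1 <- readBin(file.path(td, "similarity_pairs.tsv"), "raw", 1e6)
  render_outputs(m, td)
  expect_identical(readBin(file.path(td, "similarity_pairs.tsv"), "raw", 1e6),
                   bytes1)
})
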