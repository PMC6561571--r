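test_that("partition function matches closed forms on tiny sequences", {
  m <- energy_model()
  rt <- 1.98717e-3 * (37 + 273.15)
  expect_equal(partition_function("AAAAAA", fold_constraints(), m)$z, 1)
  expect_equal(partition_function("GAAAC", fold_constraints(), m)$z,
               1 + exp(3 / rt), tolerance = 1e-12)
  expect_equal(
    partition_function("GAAAC", fold_constraints(excluded = rbind(c(1, 5))),
                       m)$z, 1)
  p <- basepair_probabilities("GAAAC", fold_constraints(), m)
  w <- exp(3 / rt)
  expect_equal(p$prob[1, 5], w / (1 + w), tolerance = 1e-12)
  p0 <- basepair_probabilities("GAAAC",
                               fold_constraints(excluded = rbind(c(1, 5))), m)
  expect_true(all(p0$prob == 0))
})

test_that("DP engine agrees with the enumeration oracle under all constraint kinds", {
  m <- energy_model()
  set.seed(2024)
  n_checked <- 0L
  for (k in 1:60) {
    n <- sample(5:16, 1L)
    seq <- random_rna(n, gc_rich = k %% 2 == 0)
    enum <- enumerate_all_structures(seq, m)
    cons <- list(fold_constraints())
    # random exclusion set
    all_ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    ex <- all_ij[sample(nrow(all_ij), min(5L, nrow(all_ij))), , drop = FALSE]
    cons <- c(cons, list(fold_constraints(excluded = ex)))
    # random feasible forced pair drawn from an enumerated structure
    sizes <- vapply(enum$structures, function(s) nrow(s$pairs), integer(1L))
    if (any(sizes > 0L)) {
      src <- enum$structures[[sample(which(sizes > 0L), 1L)]]
      f <- src$pairs[sample(nrow(src$pairs), 1L), , drop = FALSE]
      cons <- c(cons, list(fold_constraints(forced = f)))
    }
    for (cn in cons) {
      zo <- oracle_z(enum, m, cn)
      pf <- partition_function(seq, cn, m)
      expect_equal(pf$z, zo, tolerance = 1e-9)
      p <- basepair_probabilities(seq, cn, m)
      po <- oracle_probs(enum, m, n, cn)
      expect_lt(max(abs(p$prob - po)), 1e-9)
      mfe <- constrained_mfe(seq, cn, m)
      expect_equal(mfe$energy, oracle_min_energy(enum, cn),
                   tolerance = 1e-9)
      # the traceback structure itself must be admissible and attain it
      expect_equal(structure_energy(seq, mfe$structure, m), mfe$energy)
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 150L)
})

test_that("enumeration oracle identities hold", {
  m <- energy_model()
  expect_length(enumerate_all_structures("GAAAC", m)$structures, 2L)
  expect_length(enumerate_all_structures("AAAA", m)$structures, 1L)
  expect_error(enumerate_all_structures(strrep("A", 23), m), "too long")
  # dot-bracket representations are unique (each structure exactly once)
  enum <- enumerate_all_structures("GGCAAAAGUCC", m)
  dbs <- vapply(enum$structures, write_dotbracket, character(1L))
  expect_false(anyDuplicated(dbs) > 0L)
})

test_that("probability matrices satisfy single-occupancy and support rules", {
  m <- energy_model()
  set.seed(5)
  for (k in 1:10) {
    seq <- random_rna(sample(10:25, 1L), gc_rich = TRUE)
    p <- basepair_probabilities(seq, fold_constraints(), m)
    expect_true(all(p$prob >= 0 & p$prob <= 1))
    expect_true(all(rowSums(p$prob) <= 1 + 1e-9))
    b <- strsplit(seq, "")[[1L]]
    idx <- which(p$prob > 0 & upper.tri(p$prob), arr.ind = TRUE)
    if (nrow(idx)) {
      expect_true(all(idx[, 2L] - idx[, 1L] - 1L >= 3L))
      expect_false(anyNA(rnaswitch:::pair_class(b[idx[, 1L]], b[idx[, 2L]])))
    }
  }
})

test_that("forced pairs condition probabilities to 1", {
  m <- energy_model()
  p <- basepair_probabilities("GGGAAAACCCC",
                              fold_constraints(forced = rbind(c(2, 10))), m)
  expect_equal(p$prob[2, 10], 1)
  expect_error(
    partition_function("GAAAC",
                       fold_constraints(excluded = rbind(c(1, 5)),
                                        forced = rbind(c(1, 5))), m),
    "contradictory")
  expect_error(
    partition_function("GAAAG", fold_constraints(forced = rbind(c(1, 5))), m),
    "not admissible")
})

test_that("constrained MFE honours forced pairs and reports infeasibility", {
  m <- energy_model()
  r <- constrained_mfe("AAAA", fold_constraints(), m)
  expect_equal(write_dotbracket(r$structure), "....")
  expect_equal(r$energy, 0)
  r2 <- constrained_mfe("GAAAC", fold_constraints(forced = rbind(c(1, 5))), m)
  expect_equal(write_dotbracket(r2$structure), "(...)")
  expect_equal(r2$energy, -3)
  expect_error(
    constrained_mfe("GAAC", fold_constraints(forced = rbind(c(1, 4))), m),
    "not admissible")
})

test_that("MFE traceback is deterministic under energy ties", {
  # two equal hairpins compete; repeated runs must agree exactly
  m <- energy_model()
  seq <- "GGGAAACCCAAAGGGAAACCC"
  outs <- replicate(5, write_dotbracket(
    constrained_mfe(seq, fold_constraints(), m)$structure))
  expect_length(unique(outs), 1L)
})

test_that("stochastic traceback reproduces ensemble frequencies", {
  m <- energy_model()
  # every sample from an unpairable sequence is the open chain
  s0 <- sample_structures("AAAAAA", 20L, fold_constraints(), m, seed = 1L)
  expect_true(all(vapply(s0, function(s) nrow(s$pairs) == 0L, logical(1L))))
  # two-state sequence: frequency within 3 binomial SDs of the closed form
  rt <- 1.98717e-3 * (37 + 273.15)
  p1 <- exp(3 / rt) / (1 + exp(3 / rt))
  draws <- sample_structures("GAAAC", 10000L, fold_constraints(), m,
                             seed = 7L)
  freq <- mean(vapply(draws, function(s) nrow(s$pairs) == 1L, logical(1L)))
  expect_lt(abs(freq - p1), 3 * sqrt(p1 * (1 - p1) / 10000))
  # determinism contract
  a <- sample_structures("GGCAAAAGUCC", 50L, fold_constraints(), m, seed = 3L)
  b <- sample_structures("GGCAAAAGUCC", 50L, fold_constraints(), m, seed = 3L)
  expect_identical(lapply(a, write_dotbracket), lapply(b, write_dotbracket))
})

test_that("sampled frequencies pass a chi-square test against the oracle", {
  m <- energy_model()
  seq <- "GGCAAAAGUCC"
  enum <- enumerate_all_structures(seq, m)
  w <- exp(-enum$energies / oracle_rt(m))
  pr <- w / sum(w)
  dbo <- vapply(enum$structures, write_dotbracket, character(1L))
  draws <- sample_structures(seq, 10000L, fold_constraints(), m, seed = 11L)
  obs <- table(factor(vapply(draws, write_dotbracket, character(1L)),
                      levels = dbo))
  # pool rare structures so every expected count is at least 5
  expd <- 10000 * pr
  pool <- expd < 5
  o <- c(as.numeric(obs)[!pool], sum(obs[pool]))
  e <- c(expd[!pool], sum(expd[pool]))
  chi <- sum((o - e)^2 / e)
  pval <- stats::pchisq(chi, df = length(e) - 1L, lower.tail = FALSE)
  expect_gt(pval, 0.001)
})

test_that("probability matrices serialise to TSV in both layouts", {
  p <- basepair_probabilities("GGGAAAACCCC")
  f1 <- tempfile(fileext = ".tsv")
  write_bpp_tsv(p, f1)
  tab <- utils::read.delim(f1)
  expect_named(tab, c("i", "j", "prob"))
  expect_equal(tab$prob, p$prob[cbind(tab$i, tab$j)])
  f2 <- tempfile(fileext = ".tsv")
  write_bpp_tsv(p, f2, square = TRUE)
  mat <- as.matrix(utils::read.delim(f2, header = FALSE))
  expect_equal(unname(mat), unname(p$prob), tolerance = 1e-12)
})
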