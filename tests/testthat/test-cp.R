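test_that("exclusion sets realise the distance-threshold definition", {
  # tau = 0 recovers the reference pairs exactly
  set.seed(31)
  for (k in 1:20) {
    n <- sample(12:20, 1L)
    s <- random_structure(n)
    e0 <- build_excluded_set(s, 0L, n)
    expect_identical(struct_keys(s), pair_key_strings(e0$pairs))
  }
  # direct enumeration of the tau = 1 ball around [2.9] on n = 10
  s <- rna_structure(10, rbind(c(2, 9)))
  e1 <- build_excluded_set(s, 1L, 10L)
  direct <- expand.grid(i = 1:3, j = 8:10)
  direct <- direct[direct$j - direct$i - 1L >= 3L, ]
  expect_equal(nrow(e1$pairs), nrow(direct))
  expect_setequal(pair_key_strings(e1$pairs), paste(direct$i, direct$j))
  # empty reference: empty set at every tau
  expect_equal(nrow(build_excluded_set(rna_structure(10), 7L, 10L)$pairs), 0L)
  # membership agrees with the base-pair-to-structure distance itself
  set.seed(32)
  for (k in 1:10) {
    n <- sample(10:15, 1L)
    s <- random_structure(n)
    tau <- sample(0:4, 1L)
    es <- build_excluded_set(s, tau, n)
    keys <- pair_key_strings(es$pairs)
    all_ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    for (r in seq_len(nrow(all_ij))) {
      p <- all_ij[r, ]
      if (p[2L] - p[1L] - 1L < 3L) next
      expect_identical(paste(p[1L], p[2L]) %in% keys,
                       basepair_to_structure_distance(p, s) <= tau)
    }
  }
})

test_that("exclusion sets grow monotonically with tau", {
  set.seed(33)
  for (k in 1:15) {
    n <- sample(10:15, 1L)
    s <- random_structure(n)
    taus <- sort(sample(0:8, 3L))
    sets <- lapply(taus, function(t)
      pair_key_strings(build_excluded_set(s, t, n)$pairs))
    expect_true(all(sets[[1L]] %in% sets[[2L]]))
    expect_true(all(sets[[2L]] %in% sets[[3L]]))
  }
})

test_that("seed selection follows the threshold and step rules", {
  mk_probs <- function(n, vals) {
    prob <- matrix(0, n, n)
    for (v in vals) prob[v[1L], v[2L]] <- prob[v[2L], v[1L]] <- v[3L]
    structure(list(n = n, prob = prob, constraints = fold_constraints()),
              class = "bpp_matrix")
  }
  # plain stacked stem above threshold
  p <- mk_probs(12, list(c(2, 9, 0.8), c(3, 8, 0.7), c(4, 7, 0.4)))
  seed <- select_seed(p, "stem")
  expect_equal(seed_keys(seed), c("2 9", "3 8"))
  # 5' bulge step (2,1)
  p2 <- mk_probs(12, list(c(2, 9, 0.9), c(4, 8, 0.8)))
  expect_equal(seed_keys(select_seed(p2, "stem")), c("2 9", "4 8"))
  # 3' bulge step (1,2)
  p3 <- mk_probs(12, list(c(2, 10, 0.9), c(3, 8, 0.8)))
  expect_equal(seed_keys(select_seed(p3, "stem")), c("2 10", "3 8"))
  # 1x1 internal loops are not stem steps
  p4 <- mk_probs(14, list(c(2, 12, 0.9), c(4, 10, 0.9)))
  expect_length(seed_keys(select_seed(p4, "stem")), 1L)
  # threshold is strict
  p5 <- mk_probs(12, list(c(2, 9, 0.5)))
  expect_equal(nrow(select_seed(p5, "stem")$chain), 0L)
  expect_equal(nrow(select_seed(p5, "stem", threshold = 0.49)$chain), 1L)
  # all below threshold: empty seed is a reportable outcome, not an error
  p6 <- mk_probs(12, list(c(2, 9, 0.3)))
  expect_equal(nrow(select_seed(p6, "stem")$chain), 0L)
  # single-bp takes the argmax; all-above-threshold takes every survivor
  p7 <- mk_probs(12, list(c(2, 9, 0.8), c(3, 8, 0.7), c(5, 9, 0.6)))
  expect_equal(seed_keys(select_seed(p7, "single-bp")), "2 9")
  expect_setequal(seed_keys(select_seed(p7, "all-above-threshold")),
                  c("2 9", "3 8", "5 9"))
  # length ties resolved by larger probability sum
  p8 <- mk_probs(16, list(c(2, 13, 0.6), c(3, 12, 0.6),
                          c(6, 16, 0.9), c(7, 15, 0.9)))
  expect_equal(seed_keys(select_seed(p8, "stem")), c("6 16", "7 15"))
})

test_that("normalized seed length matches its worked examples", {
  expect_equal(normalized_seed_length(8, 100), 4)
  expect_equal(normalized_seed_length(7, 100), 3.5)
  expect_equal(normalized_seed_length(0, 250), 0)
  expect_error(normalized_seed_length(3, 1), "at least 2")
})

test_that("CP pipeline invariants hold on designed and plain sequences", {
  set.seed(41)
  inputs <- c(
    vapply(1:6, function(k) generate_bistable(seed = 500 + k)$sequence,
           character(1L)),
    "GGGGAAAACCCC",
    vapply(1:4, function(k) generate_monostable(seed = 600 + k)$sequence,
           character(1L)))
  for (seq in inputs) {
    res <- predict_alternative(seq)
    # E(0) of the MFE structure is exactly its pair set
    e0 <- build_excluded_set(res$s1, 0L, nchar(seq))
    expect_identical(pair_key_strings(e0$pairs), struct_keys(res$s1))
    # every seed pair exceeds the threshold and avoids E
    if (nrow(res$seed$chain)) {
      expect_true(all(res$seed$probs > res$threshold))
      expect_false(any(seed_keys(res$seed) %in%
                         pair_key_strings(res$exclusion$pairs)))
      # the alternative structure contains the seed and differs from S1*
      expect_true(all(seed_keys(res$seed) %in% struct_keys(res$s_alt)))
      expect_gt(hamming_distance(res$s_alt, res$s1), 0L)
      expect_gte(res$energy_alt, res$energy_s1)
    } else {
      expect_null(res$s_alt)
      expect_match(res$empty_seed_reason, "conditional probability")
    }
    # excluded pairs have conditional probability zero
    ex <- res$exclusion$pairs
    if (nrow(ex)) expect_true(all(res$cond_probs$prob[ex] == 0))
  }
})

test_that("CP pipeline is deterministic and respects tau", {
  d <- generate_bistable(seed = 77L)
  r1 <- predict_alternative(d$sequence)
  r2 <- predict_alternative(d$sequence)
  expect_identical(r1[names(r1) != "cond_probs"], r2[names(r2) != "cond_probs"])
  expect_identical(r1$cond_probs$prob, r2$cond_probs$prob)
  r0 <- predict_alternative(d$sequence, tau = 0L)
  expect_identical(pair_key_strings(r0$exclusion$pairs),
                   struct_keys(r0$s1))
})

test_that("the stem seed recovers the designed alternative helix", {
  hits <- vapply(1:12, function(k) {
    d <- generate_bistable(seed = 900 + k)
    res <- predict_alternative(d$sequence)
    ks <- seed_keys(res$seed)
    length(ks) > 0 && all(ks %in% struct_keys(d$helixB))
  }, logical(1L))
  expect_gte(mean(hits), 0.9)
})

test_that("iterated prediction excludes all previous neighbourhoods", {
  d <- generate_bistable(seed = 55L)
  r3 <- predict_alternative(d$sequence, iteration = 3L)
  r2 <- predict_alternative(d$sequence)
  # iteration 3 excludes the union of the S1* and S2* neighbourhoods
  exp_pairs <- unique(rbind(
    build_excluded_set(r2$s1, 5L, nchar(d$sequence))$pairs,
    build_excluded_set(r2$s_alt, 5L, nchar(d$sequence))$pairs))
  expect_setequal(pair_key_strings(r3$exclusion$pairs),
                  pair_key_strings(exp_pairs))
  if (!is.null(r3$s_alt)) {
    expect_gte(r3$energy_alt, r3$energy_s1)
    expect_true(all(seed_keys(r3$seed) %in% struct_keys(r3$s_alt)))
  }
})

test_that("alternative seed kinds and temperatures feed the same pipeline", {
  d <- generate_bistable(seed = 66L)
  for (kind in c("single-bp", "all-above-threshold")) {
    r <- predict_alternative(d$sequence, seed_kind = kind)
    if (nrow(r$seed$chain)) {
      expect_true(all(seed_keys(r$seed) %in% struct_keys(r$s_alt)))
      expect_gte(r$energy_alt, r$energy_s1)
    }
  }
  # S1* stays the 37-degree MFE when probabilities are computed hot
  rhot <- predict_alternative(d$sequence, temperature = 70)
  r37 <- predict_alternative(d$sequence)
  expect_identical(struct_keys(rhot$s1), struct_keys(r37$s1))
})
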