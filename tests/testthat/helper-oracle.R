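# Brute-force reference computations over the exhaustive enumeration.
# These sum Boltzmann weights directly over the enumerated structure list,
# independently of the dynamic-programming recursions they validate.

oracle_rt <- function(m) m$gas_constant * (m$temperature + 273.15)

pair_key_strings <- function(pairs) {
  if (!nrow(pairs)) character(0) else paste(pairs[, 1L], pairs[, 2L])
}

# keeps only enumerated structures compatible with the constraints
oracle_admissible <- function(enum, constraints) {
  ex <- pair_key_strings(constraints$excluded)
  fo <- pair_key_strings(constraints$forced)
  vapply(enum$structures, function(s) {
    k <- pair_key_strings(s$pairs)
    (!length(ex) || !any(k %in% ex)) && (!length(fo) || all(fo %in% k))
  }, logical(1L))
}

oracle_z <- function(enum, m, constraints = fold_constraints()) {
  keep <- oracle_admissible(enum, constraints)
  sum(exp(-enum$energies[keep] / oracle_rt(m)))
}

oracle_probs <- function(enum, m, n, constraints = fold_constraints()) {
  keep <- oracle_admissible(enum, constraints)
  w <- exp(-enum$energies / oracle_rt(m))
  p <- matrix(0, n, n)
  for (k in which(keep)) {
    pr <- enum$structures[[k]]$pairs
    if (nrow(pr)) p[pr] <- p[pr] + w[k]
  }
  p <- p / sum(w[keep])
  p + t(p)
}

oracle_min_energy <- function(enum, constraints = fold_constraints()) {
  keep <- oracle_admissible(enum, constraints)
  if (!any(keep)) return(Inf)
  min(enum$energies[keep])
}

random_rna <- function(n, gc_rich = FALSE) {
  probs <- if (gc_rich) c(0.15, 0.35, 0.35, 0.15) else rep(0.25, 4)
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE, prob = probs),
        collapse = "")
}

# uniformly-ish random valid structure for property tests: repeatedly adds
# a random admissible pair
random_structure <- function(n, tries = 3L * n) {
  pairs <- matrix(integer(0), ncol = 2L)
  used <- rep(FALSE, n)
  for (k in seq_len(tries)) {
    i <- sample.int(n, 1L)
    j <- sample.int(n, 1L)
    if (i > j) { t <- i; i <- j; j <- t }
    if (j - i - 1L < 3L || used[i] || used[j]) next
    cand <- rbind(pairs, c(i, j))
    cand <- cand[order(cand[, 1L]), , drop = FALSE]
    if (rnaswitch:::pairs_cross(cand)) next
    pairs <- cand
    used[c(i, j)] <- TRUE
  }
  rna_structure(n, pairs)
}

seed_keys <- function(seed) pair_key_strings(seed$chain)
struct_keys <- function(s) pair_key_strings(s$pairs)
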