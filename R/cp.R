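#' Exclusion set around a reference structure
#'
#' The set `E(tau)` of all index pairs whose base-pair-to-structure
#' distance to the reference structure is at most `tau`, restricted to
#' `i < j` with the minimum hairpin size respected. Membership is purely
#' positional (independent of sequence content): a positionally excluded
#' pair that is non-canonical anyway is simply never formed. `E(0)` is
#' exactly the reference structure's own pair set, and `E(tau)` grows
#' monotonically with `tau`; for a reference with no pairs the set is empty
#' at every `tau`.
#'
#' @param s_ref Reference [rna_structure] (typically the MFE structure).
#' @param tau Non-negative integer dissimilarity threshold.
#' @param n Sequence length (defaults to the reference's length).
#' @param min_hairpin_unpaired Minimum hairpin size used to restrict the
#'   index-pair universe.
#' @return An object of class `exclusion_set` with fields `tau`, `pairs`
#'   and `n`.
#' @export
build_excluded_set <- function(s_ref, tau, n = s_ref$n,
                               min_hairpin_unpaired = 3L) {
  stopifnot(inherits(s_ref, "rna_structure"), tau >= 0, n >= s_ref$n)
  tau <- as.integer(tau)
  mask <- matrix(FALSE, n, n)
  ref <- s_ref$pairs
  for (r in seq_len(nrow(ref))) {
    ii <- max(1L, ref[r, 1L] - tau):min(n, ref[r, 1L] + tau)
    jj <- max(1L, ref[r, 2L] - tau):min(n, ref[r, 2L] + tau)
    mask[ii, jj] <- TRUE
  }
  idx <- which(mask, arr.ind = TRUE)
  ok <- idx[, 1L] < idx[, 2L] &
    idx[, 2L] - idx[, 1L] - 1L >= min_hairpin_unpaired
  structure(list(tau = tau, pairs = normalize_pairs(idx[ok, , drop = FALSE]),
                 n = as.integer(n)),
            class = "exclusion_set")
}

#' @export
print.exclusion_set <- function(x, ...) {
  cat("Exclusion set E(tau = ", x$tau, "): ", nrow(x$pairs),
      " index pair(s) over ", x$n, " nt\n", sep = "")
  invisible(x)
}

#' Select a seed from a conditional probability matrix
#'
#' The default seed is a longest bulge-tolerant stem: a nested chain of
#' pairs in which consecutive pairs `[i.j] -> [i'.j']` step by
#' `(i'-i, j-j') in {(1,1), (2,1), (1,2)}` (a stack, a 5' bulge, or a 3'
#' bulge; 1x1 internal loops are not stem steps), every pair of which
#' individually has conditional probability strictly above the threshold.
#' Ties in chain length are broken by the larger sum of conditional
#' probabilities, then by the smallest 5' start. Alternative seed kinds:
#' the single pair of highest probability, or every pair above the
#' threshold. An empty seed (nothing above the threshold) is a valid,
#' reportable outcome, not an error.
#'
#' @param p A `bpp_matrix` of conditional probabilities.
#' @param kind One of `"stem"`, `"single-bp"`, `"all-above-threshold"`.
#' @param threshold Probability threshold in (0, 1); comparison is strict.
#' @return An object of class `cp_seed` with fields `chain` (two-column
#'   pair matrix, ordered outermost first), `kind`, and `probs`.
#' @export
select_seed <- function(p, kind = c("stem", "single-bp",
                                    "all-above-threshold"),
                        threshold = 0.5) {
  stopifnot(inherits(p, "bpp_matrix"), threshold > 0, threshold < 1)
  kind <- match.arg(kind)
  n <- p$n
  up <- upper.tri(p$prob)
  idx <- which(up & p$prob > threshold, arr.ind = TRUE)
  mk <- function(chain) {
    chain <- normalize_pairs(chain)
    structure(list(chain = chain, kind = kind,
                   probs = if (nrow(chain)) p$prob[chain] else numeric(0)),
              class = "cp_seed")
  }
  if (!nrow(idx)) return(mk(NULL))
  if (kind == "all-above-threshold") return(mk(idx))
  if (kind == "single-bp") {
    pr <- p$prob[idx]
    best <- order(-pr, idx[, 1L], idx[, 2L])[1L]
    return(mk(idx[best, , drop = FALSE]))
  }
  # stem: longest chain under the (1,1)/(2,1)/(1,2) step rule
  span <- idx[, 2L] - idx[, 1L]
  ord <- order(span)
  key <- function(i, j) (i - 1L) * n + j
  len <- sums <- stats::setNames(numeric(0), character(0))
  nxt <- stats::setNames(character(0), character(0))
  keys <- as.character(key(idx[, 1L], idx[, 2L]))
  in_set <- stats::setNames(seq_len(nrow(idx)), keys)
  for (r in ord) {
    i <- idx[r, 1L]; j <- idx[r, 2L]
    kk <- keys[r]
    best_len <- 1; best_sum <- p$prob[i, j]; best_nxt <- NA_character_
    steps <- rbind(c(i + 1L, j - 1L), c(i + 2L, j - 1L), c(i + 1L, j - 2L))
    for (st in seq_len(3L)) {
      qi <- steps[st, 1L]; qj <- steps[st, 2L]
      if (qi >= qj) next
      qk <- as.character(key(qi, qj))
      if (is.na(in_set[qk])) next
      cand_len <- 1 + len[[qk]]
      cand_sum <- p$prob[i, j] + sums[[qk]]
      if (cand_len > best_len ||
          (cand_len == best_len && cand_sum > best_sum + 1e-12)) {
        best_len <- cand_len; best_sum <- cand_sum; best_nxt <- qk
      }
    }
    len[kk] <- best_len; sums[kk] <- best_sum; nxt[kk] <- best_nxt
  }
  starts <- keys
  best <- starts[order(-len[starts], -sums[starts],
                       idx[, 1L], idx[, 2L])][1L]
  chain <- NULL
  k <- best
  while (!is.na(k)) {
    r <- in_set[[k]]
    chain <- rbind(chain, idx[r, ])
    k <- nxt[[k]]
  }
  mk(chain)
}

#' @export
print.cp_seed <- function(x, ...) {
  if (!nrow(x$chain)) {
    cat("Empty", x$kind, "seed (no pair above threshold)\n")
  } else {
    cat(x$kind, " seed, ", nrow(x$chain), " base pair(s): ",
        paste0("[", x$chain[, 1L], ".", x$chain[, 2L], "]",
               collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Normalised seed length
#'
#' Seed length in base pairs divided by `log10` of the sequence length, the
#' score used to classify sequences as switch-like: bistable sequences tend
#' to yield longer seeds than monostable ones.
#'
#' @param seed_len Number of base pairs in the seed.
#' @param seq_len Sequence length in nucleotides (>= 2).
#' @return A dimensionless score.
#' @examples
#' normalized_seed_length(8, 100) # 4
#' @export
normalized_seed_length <- function(seed_len, seq_len) {
  if (any(seq_len < 2))
    stop("seq_len must be at least 2 (log10 would be <= 0)")
  seed_len / log10(seq_len)
}

#' Predict the alternative structure by conditional probabilities
#'
#' The conditional-probability pipeline: (1) compute the MFE structure S1*
#' at 37 degC; (2) build the exclusion set `E(tau)` around it; (3) compute
#' base-pair probabilities at the requested temperature conditional on no
#' pair of `E(tau)` forming; (4) select a seed (by default a longest
#' bulge-tolerant stem of pairs with conditional probability above the
#' threshold); (5) fold the alternative structure S2* as the lowest-energy
#' structure containing the seed. The exclusion set constrains only the
#' probability computation, not the final fold, so S2* may incidentally
#' contain excluded pairs; because the seed itself avoids E (excluded pairs
#' have conditional probability 0), S2* always differs from S1* whenever
#' the seed is non-empty. For `iteration > 2` the pipeline repeats, each
#' round excluding the union of the `E(tau)` neighbourhoods of all
#' previously predicted structures.
#'
#' @param seq RNA sequence string.
#' @param tau Non-negative exclusion threshold (default 5).
#' @param temperature Temperature (degC) for the conditional probabilities
#'   (default 37); S1* is always computed at 37 degC.
#' @param seed_kind Seed type passed to [select_seed()].
#' @param threshold Conditional-probability threshold (default 0.5,
#'   strict).
#' @param iteration Iteration number >= 2; 2 is the plain pipeline.
#' @param m An [energy_model]; its temperature field is overridden as
#'   described above.
#' @return An object of class `cp_result` with fields `s1`, `s_alt` (NULL
#'   when the seed is empty), `seed`, `exclusion`, `cond_probs`,
#'   `energy_s1`, `energy_alt`, `normalized_seed_length`, `iteration`,
#'   `temperature`, `tau`, and `empty_seed_reason`.
#' @export
predict_alternative <- function(seq, tau = 5L, temperature = 37,
                                seed_kind = "stem", threshold = 0.5,
                                iteration = 2L, m = energy_model()) {
  stopifnot(iteration >= 2L, tau >= 0)
  seq <- normalize_rna(seq)
  n <- nchar(seq)
  s1 <- constrained_mfe(seq, fold_constraints(), at_temperature(m, 37))
  preds <- list(s1$structure)
  excl <- cond <- seed <- s_alt <- NULL
  reason <- NULL
  for (it in 2L:iteration) {
    pair_union <- do.call(rbind, lapply(preds, function(s)
      build_excluded_set(s, tau, n, m$min_hairpin_unpaired)$pairs))
    excl <- structure(list(tau = as.integer(tau),
                           pairs = normalize_pairs(pair_union),
                           n = as.integer(n)),
                      class = "exclusion_set")
    cond <- basepair_probabilities(seq, fold_constraints(excluded = excl$pairs),
                                   at_temperature(m, temperature))
    seed <- select_seed(cond, seed_kind, threshold)
    if (!nrow(seed$chain)) {
      s_alt <- NULL
      reason <- paste0("no base pair has conditional probability above ",
                       threshold, " at iteration ", it)
      break
    }
    s_alt <- constrained_mfe(seq, fold_constraints(forced = seed$chain),
                             at_temperature(m, temperature))
    preds <- c(preds, list(s_alt$structure))
  }
  res <- list(
    s1 = s1$structure,
    s_alt = if (is.null(s_alt)) NULL else s_alt$structure,
    seed = seed,
    exclusion = excl,
    cond_probs = cond,
    energy_s1 = s1$energy,
    energy_alt = if (is.null(s_alt)) NA_real_ else s_alt$energy,
    normalized_seed_length = normalized_seed_length(nrow(seed$chain), n),
    iteration = as.integer(iteration),
    temperature = temperature,
    tau = as.integer(tau),
    threshold = threshold,
    seed_kind = seed$kind,
    empty_seed_reason = reason,
    sequence = seq
  )
  class(res) <- "cp_result"
  res
}

#' @export
print.cp_result <- function(x, ...) {
  cat("Conditional-probability alternative-structure prediction (",
      nchar(x$sequence), " nt, tau = ", x$tau, ", T = ", x$temperature,
      " degC, ", x$seed_kind, " seed, iteration ", x$iteration, ")\n",
      sep = "")
  cat("S1* (", format(x$energy_s1), " kcal/mol): ",
      write_dotbracket(x$s1), "\n", sep = "")
  if (is.null(x$s_alt)) {
    cat("No alternative structure: ", x$empty_seed_reason, "\n", sep = "")
  } else {
    cat("S", x$iteration, "* (", format(x$energy_alt), " kcal/mol): ",
        write_dotbracket(x$s_alt), "\n", sep = "")
    cat("Seed: ", nrow(x$seed$chain), " bp; normalized seed length ",
        round(x$normalized_seed_length, 3), "\n", sep = "")
  }
  invisible(x)
}
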