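#' Folding constraints
#'
#' Hard constraints for the ensemble engine: `excluded` pairs must not occur
#' in any admissible structure, `forced` pairs must occur in every one.
#' Forced pairs must be mutually non-crossing and position-disjoint and must
#' not appear in the excluded set; canonicity against the sequence is
#' checked when the constraints meet a sequence.
#'
#' @param excluded,forced Two-column integer matrices of base pairs (or
#'   `NULL`).
#' @return An object of class `fold_constraints`.
#' @export
fold_constraints <- function(excluded = NULL, forced = NULL) {
  excluded <- normalize_pairs(excluded)
  forced <- normalize_pairs(forced)
  if (nrow(forced)) {
    if (anyDuplicated(as.vector(forced)))
      stop("forced pairs must be position-disjoint")
    if (pairs_cross(forced))
      stop("forced pairs must be mutually non-crossing")
    if (nrow(excluded)) {
      ke <- paste(excluded[, 1L], excluded[, 2L])
      kf <- paste(forced[, 1L], forced[, 2L])
      if (any(kf %in% ke))
        stop("contradictory constraints: a forced pair is also excluded")
    }
  }
  structure(list(excluded = excluded, forced = forced),
            class = "fold_constraints")
}

# Shared pre-computation for all DP passes: pairability matrix, per-base
# unpaired permission, and Boltzmann pair weights. Errors on contradictory
# or non-canonical forced pairs.
dp_context <- function(seq, constraints, m) {
  seq <- normalize_rna(seq)
  stopifnot(inherits(constraints, "fold_constraints"),
            inherits(m, "energy_model"))
  n <- nchar(seq)
  b <- strsplit(seq, "", fixed = TRUE)[[1L]]
  minhp <- m$min_hairpin_unpaired
  can <- matrix(FALSE, n, n)
  epair <- matrix(0, n, n)
  if (n >= minhp + 2L) {
    for (i in seq_len(n - minhp - 1L)) {
      js <- (i + minhp + 1L):n
      cls <- pair_class(b[i], b[js])
      ok <- !is.na(cls)
      can[i, js[ok]] <- TRUE
      epair[i, js[ok]] <- m$pair_energy[cls[ok]]
    }
  }
  if (nrow(constraints$excluded))
    can[constraints$excluded] <- FALSE
  unpaired_ok <- rep(TRUE, n)
  forced <- constraints$forced
  if (nrow(forced)) {
    bad <- !can[forced]
    if (any(bad)) {
      fp <- forced[which(bad)[1L], ]
      stop("forced pair [", fp[1L], ".", fp[2L],
           "] is not admissible (non-canonical, excluded, or violates the ",
           "minimum hairpin size)")
    }
    unpaired_ok[as.vector(forced)] <- FALSE
    # a position in a forced pair may pair only with its forced partner
    for (r in seq_len(nrow(forced))) {
      i <- forced[r, 1L]; j <- forced[r, 2L]
      can[i, ] <- FALSE; can[, i] <- FALSE
      can[j, ] <- FALSE; can[, j] <- FALSE
      can[i, j] <- TRUE
    }
  }
  rt <- rt_of(m)
  list(seq = seq, n = n, bases = b, can = can, epair = epair,
       unpaired_ok = unpaired_ok, minhp = minhp, rt = rt,
       w_stack = exp(-m$stack_bonus / rt), model = m,
       constraints = constraints)
}

# Minimum-energy DP tables. M: min energy over interval; Mb: with the
# closing pair [i.j]; Mx: without it. Inf = no admissible structure.
mfe_tables <- function(ctx) {
  n <- ctx$n
  M <- Mb <- Mx <- matrix(Inf, n, n)
  es <- ctx$model$stack_bonus
  for (len in seq_len(n)) {
    for (i in seq_len(n - len + 1L)) {
      j <- i + len - 1L
      if (ctx$can[i, j]) {
        inner_x <- Mx[i + 1L, j - 1L]
        inner_b <- Mb[i + 1L, j - 1L]
        Mb[i, j] <- ctx$epair[i, j] + min(inner_x, es + inner_b)
      }
      best <- Inf
      if (ctx$unpaired_ok[j])
        best <- if (j - 1L >= i) M[i, j - 1L] else 0
      if (len >= 3L) {
        ks <- (i + 1L):(j - 1L)
        v <- M[cbind(i, ks - 1L)] + Mb[cbind(ks, j)]
        best <- min(best, v)
      }
      Mx[i, j] <- best
      M[i, j] <- min(Mx[i, j], Mb[i, j])
    }
  }
  list(M = M, Mb = Mb, Mx = Mx)
}

#' Constrained minimum-free-energy structure
#'
#' Returns an admissible structure of minimum energy under the given hard
#' constraints. With empty constraints this is the MFE structure; with
#' forced pairs it is the lowest-energy structure containing them all,
#' which is how an alternative structure is folded around a seed. Among
#' equal-energy structures the traceback prefers pairing over not pairing,
#' then the smallest 5' index, then the largest 3' index, so the output is
#' deterministic.
#'
#' @param seq RNA sequence string.
#' @param constraints A [fold_constraints] object.
#' @param m An [energy_model].
#' @return A list with `structure` (an [rna_structure]) and `energy`
#'   (kcal/mol).
#' @export
constrained_mfe <- function(seq, constraints = fold_constraints(),
                            m = energy_model()) {
  ctx <- dp_context(seq, constraints, m)
  tb <- mfe_tables(ctx)
  n <- ctx$n
  if (!is.finite(tb$M[1L, n]))
    stop("no admissible structure satisfies the constraints")
  eps <- 1e-9
  es <- m$stack_bonus
  pairs <- matrix(integer(0), ncol = 2L)
  trace_m <- function(i, j) {
    if (j < i) return()
    if (ctx$can[i, j] && tb$Mb[i, j] <= tb$M[i, j] + eps) trace_b(i, j)
    else trace_x(i, j)
  }
  trace_b <- function(i, j) {
    pairs <<- rbind(pairs, c(i, j))
    ii <- i + 1L; jj <- j - 1L
    if (is.finite(tb$Mb[ii, jj]) &&
        es + tb$Mb[ii, jj] <= tb$Mx[ii, jj] + eps) trace_b(ii, jj)
    else trace_x(ii, jj)
  }
  trace_x <- function(i, j) {
    if (j <= i) return()
    target <- tb$Mx[i, j]
    if (j - i >= 2L) {
      for (k in (i + 1L):(j - 1L)) {
        if (is.finite(tb$Mb[k, j]) &&
            tb$M[i, k - 1L] + tb$Mb[k, j] <= target + eps) {
          trace_b(k, j)
          trace_m(i, k - 1L)
          return()
        }
      }
    }
    trace_m(i, j - 1L)
  }
  trace_m(1L, n)
  s <- rna_structure(n, pairs)
  list(structure = s, energy = structure_energy(ctx$seq, s, m))
}

#' Constrained partition function
#'
#' Computes the McCaskill-style inside tables for the Boltzmann ensemble
#' restricted to structures satisfying the constraints, with per-base
#' rescaling against overflow (the scale factor is derived from the
#' constrained MFE). `Z` is the sum of `exp(-E(S)/RT)` over all admissible
#' structures; `log_z` remains finite when `Z` itself overflows.
#'
#' @inheritParams constrained_mfe
#' @return An object of class `partition_result` with elements `z`,
#'   `log_z`, and the inside tables (used by [basepair_probabilities()] and
#'   [sample_structures()]).
#' @export
partition_function <- function(seq, constraints = fold_constraints(),
                               m = energy_model()) {
  ctx <- dp_context(seq, constraints, m)
  tb <- mfe_tables(ctx)
  n <- ctx$n
  if (!is.finite(tb$M[1L, n]))
    stop("no admissible structure satisfies the constraints")
  sigma <- exp(max(0, -tb$M[1L, n] / ctx$rt) / n)
  wpair <- exp(-ctx$epair / ctx$rt) * ctx$can
  ws <- ctx$w_stack
  Q <- Qb <- Qx <- matrix(0, n, n)
  for (len in seq_len(n)) {
    for (i in seq_len(n - len + 1L)) {
      j <- i + len - 1L
      if (ctx$can[i, j])
        Qb[i, j] <- wpair[i, j] / sigma^2 *
          (Qx[i + 1L, j - 1L] + ws * Qb[i + 1L, j - 1L])
      acc <- 0
      if (ctx$unpaired_ok[j])
        acc <- (if (j - 1L >= i) Q[i, j - 1L] else 1) / sigma
      if (len >= 3L) {
        ks <- (i + 1L):(j - 1L)
        acc <- acc + sum(Q[cbind(i, ks - 1L)] * Qb[cbind(ks, j)])
      }
      Qx[i, j] <- acc
      Q[i, j] <- acc + Qb[i, j]
    }
  }
  log_z <- log(Q[1L, n]) + n * log(sigma)
  structure(list(z = exp(log_z), log_z = log_z, n = n, sigma = sigma,
                 Q = Q, Qb = Qb, Qx = Qx, wpair = wpair, ctx = ctx),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat("Partition function over", x$n, "nt: Z =", signif(x$z, 6),
      "(log Z =", signif(x$log_z, 6), ")\n")
  invisible(x)
}

#' Base-pair probabilities, optionally conditioned on excluded pairs
#'
#' The probability that the ensemble structure contains each pair `[i.j]`,
#' computed exactly by an inside-outside pass over the constrained
#' partition-function tables. With an exclusion set `E` in the constraints
#' this is the conditional probability that `[i.j]` occurs given that no
#' pair of `E` occurs; with forced pairs it conditions on their inclusion.
#'
#' @inheritParams constrained_mfe
#' @return An object of class `bpp_matrix`: a list with `n`, the symmetric
#'   probability matrix `prob`, and the `constraints` that conditioned it.
#' @export
basepair_probabilities <- function(seq, constraints = fold_constraints(),
                                   m = energy_model()) {
  pf <- partition_function(seq, constraints, m)
  n <- pf$n
  ctx <- pf$ctx
  sigma <- pf$sigma
  ws <- ctx$w_stack
  OQ <- OQx <- OQb <- matrix(0, n, n)
  OQ[1L, n] <- 1
  for (len in n:1) {
    for (i in seq_len(n - len + 1L)) {
      j <- i + len - 1L
      oq <- OQ[i, j]
      if (oq != 0) {
        OQx[i, j] <- OQx[i, j] + oq
        if (ctx$can[i, j]) OQb[i, j] <- OQb[i, j] + oq
      }
      oqx <- OQx[i, j]
      if (oqx != 0) {
        if (ctx$unpaired_ok[j] && j - 1L >= i)
          OQ[i, j - 1L] <- OQ[i, j - 1L] + oqx / sigma
        if (len >= 3L) {
          ks <- (i + 1L):(j - 1L)
          OQ[cbind(i, ks - 1L)] <- OQ[cbind(i, ks - 1L)] +
            oqx * pf$Qb[cbind(ks, j)]
          OQb[cbind(ks, j)] <- OQb[cbind(ks, j)] +
            oqx * pf$Q[cbind(i, ks - 1L)]
        }
      }
      oqb <- OQb[i, j]
      if (oqb != 0 && ctx$can[i, j]) {
        f <- oqb * pf$wpair[i, j] / sigma^2
        OQx[i + 1L, j - 1L] <- OQx[i + 1L, j - 1L] + f
        OQb[i + 1L, j - 1L] <- OQb[i + 1L, j - 1L] + f * ws
      }
    }
  }
  prob <- pf$Qb * OQb / pf$Q[1L, n]
  prob[prob < 0] <- 0
  prob[prob > 1] <- 1
  prob <- prob + t(prob)
  structure(list(n = n, prob = prob, constraints = pf$ctx$constraints),
            class = "bpp_matrix")
}

#' @export
print.bpp_matrix <- function(x, ...) {
  k <- sum(x$prob[upper.tri(x$prob)] > 0.5)
  cat("Base-pair probability matrix over", x$n, "nt;",
      k, "pair(s) above probability 0.5\n")
  invisible(x)
}

#' Write a base-pair probability matrix as TSV
#'
#' @param p A `bpp_matrix` from [basepair_probabilities()].
#' @param path Output path.
#' @param square Write the full square matrix instead of sparse
#'   `i, j, prob` rows (which omit zero entries).
#' @export
write_bpp_tsv <- function(p, path, square = FALSE) {
  stopifnot(inherits(p, "bpp_matrix"))
  if (square) {
    utils::write.table(p$prob, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  } else {
    idx <- which(upper.tri(p$prob) & p$prob > 0, arr.ind = TRUE)
    df <- data.frame(i = idx[, 1L], j = idx[, 2L], prob = p$prob[idx])
    df <- df[order(df$i, df$j), ]
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Sample structures from the constrained Boltzmann ensemble
#'
#' Independent draws by stochastic traceback over the inside tables;
#' reproducible for a given seed (the caller's RNG state is restored on
#' exit).
#'
#' @inheritParams constrained_mfe
#' @param count Number of samples (>= 1).
#' @param seed Integer RNG seed (required; every stochastic operation in
#'   the package takes an explicit seed).
#' @return A list of [rna_structure] objects of length `count`.
#' @export
sample_structures <- function(seq, count, constraints = fold_constraints(),
                              m = energy_model(), seed) {
  stopifnot(count >= 1L)
  if (missing(seed)) stop("an integer RNG seed is required")
  pf <- partition_function(seq, constraints, m)
  ctx <- pf$ctx
  n <- pf$n
  sigma <- pf$sigma
  ws <- ctx$w_stack
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  pick <- function(w) {
    u <- stats::runif(1L) * sum(w)
    cw <- cumsum(w)
    which(u <= cw & w > 0)[1L]
  }
  draw_one <- function() {
    pairs <- matrix(integer(0), ncol = 2L)
    sample_q <- function(i, j) {
      while (j >= i) {
        w0 <- if (ctx$unpaired_ok[j])
          (if (j - 1L >= i) pf$Q[i, j - 1L] else 1) / sigma else 0
        ks <- i:(j - 1L)
        if (j == i) ks <- integer(0)
        wk <- if (length(ks))
          ifelse(ks - 1L >= i, pf$Q[cbind(i, pmax(ks - 1L, i))], 1) *
            pf$Qb[cbind(ks, j)]
        else numeric(0)
        # guard: Q[i, i-1] slots above are masked to 1 via ifelse
        sel <- pick(c(w0, wk))
        if (sel == 1L) { j <- j - 1L; next }
        k <- ks[sel - 1L]
        sample_b(k, j)
        j <- k - 1L
      }
    }
    sample_b <- function(i, j) {
      repeat {
        pairs <<- rbind(pairs, c(i, j))
        ii <- i + 1L; jj <- j - 1L
        w_open <- pf$Qx[ii, jj]
        w_stk <- ws * pf$Qb[ii, jj]
        if (pick(c(w_open, w_stk)) == 2L) { i <- ii; j <- jj; next }
        sample_x(ii, jj)
        return()
      }
    }
    sample_x <- function(i, j) {
      while (j > i) {
        w0 <- if (ctx$unpaired_ok[j]) pf$Q[i, j - 1L] / sigma else 0
        ks <- (i + 1L):(j - 1L)
        if (j - 1L < i + 1L) ks <- integer(0)
        wk <- if (length(ks))
          pf$Q[cbind(i, ks - 1L)] * pf$Qb[cbind(ks, j)] else numeric(0)
        sel <- pick(c(w0, wk))
        if (sel == 1L) {
          sample_q(i, j - 1L)
          return()
        }
        k <- ks[sel - 1L]
        sample_b(k, j)
        sample_q(i, k - 1L)
        return()
      }
    }
    sample_q(1L, n)
    rna_structure(n, pairs)
  }
  lapply(seq_len(count), function(dummy) draw_one())
}

#' Exhaustively enumerate all secondary structures
#'
#' The brute-force test oracle: every structure valid for the sequence
#' (canonical pairs, non-crossing, minimum hairpin size), each exactly
#' once, with its energy. Guarded to short sequences because the count
#' grows exponentially.
#'
#' @param seq RNA sequence string of length at most `max_len`.
#' @param m An [energy_model].
#' @param max_len Guard on sequence length (22).
#' @return A list with `structures` (list of [rna_structure]) and
#'   `energies` (numeric vector).
#' @export
enumerate_all_structures <- function(seq, m = energy_model(),
                                     max_len = 22L) {
  seq <- normalize_rna(seq)
  n <- nchar(seq)
  if (n > max_len)
    stop("sequence too long for exhaustive enumeration (", n, " > ",
         max_len, " nt)")
  ctx <- dp_context(seq, fold_constraints(), m)
  memo <- new.env(parent = emptyenv())
  empty <- list(matrix(integer(0), ncol = 2L))
  enum <- function(i, j) {
    if (j - i < ctx$minhp + 1L) return(empty)
    key <- paste0(i, ",", j)
    got <- get0(key, envir = memo)
    if (!is.null(got)) return(got)
    out <- enum(i, j - 1L)
    for (k in i:(j - 1L)) {
      if (!ctx$can[k, j]) next
      outer <- if (k - 1L >= i) enum(i, k - 1L) else empty
      inner <- enum(k + 1L, j - 1L)
      for (o in outer)
        for (w in inner)
          out <- c(out, list(rbind(o, c(k, j), w)))
    }
    assign(key, out, envir = memo)
    out
  }
  all_pairs <- enum(1L, n)
  structures <- lapply(all_pairs, function(p) rna_structure(n, p))
  energies <- vapply(structures, function(s)
    structure_energy(seq, s, m), numeric(1L))
  list(structures = structures, energies = energies)
}
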