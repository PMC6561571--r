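#' Sampling protocol for the sampling-clustering baseline
#'
#' Defaults follow the standard protocol: 300 structures at 37 degC plus
#' 150 structures at each of 6 temperatures spaced at decile intervals from
#' 37 degC towards the melting temperature, totalling 1200 samples.
#'
#' @param n_base Samples at 37 degC.
#' @param n_step Samples per elevated-temperature step.
#' @param n_steps Number of elevated-temperature steps.
#' @return A list of class `sc_protocol`.
#' @export
sc_protocol <- function(n_base = 300L, n_step = 150L, n_steps = 6L) {
  stopifnot(n_base >= 1L, n_step >= 1L, n_steps >= 1L)
  structure(list(n_base = as.integer(n_base), n_step = as.integer(n_step),
                 n_steps = as.integer(n_steps)), class = "sc_protocol")
}

#' Multi-temperature Boltzmann sampling
#'
#' Draws `n_base` structures at 37 degC and `n_step` structures at each of
#' the temperatures `37 + k (Tm - 37)/10`, `k = 1..n_steps`, where `Tm` is
#' the operational melting temperature (see
#' [estimate_melting_temperature()]; overridable via `t_melt`). Structure
#' energies are evaluated under the reference model, which has no
#' enthalpy/entropy split, so temperature changes the sampling distribution
#' but not the recorded energies.
#'
#' @param seq RNA sequence string.
#' @param m An [energy_model].
#' @param protocol An [sc_protocol].
#' @param seed Integer RNG seed (required); the per-temperature draws use
#'   seeds `seed + 0..n_steps`.
#' @param t_melt Optional melting-temperature override (degC).
#' @return An object of class `sc_sample_set`: `structures`, `energies`,
#'   `temperatures` (one per sample), `sequence`, `protocol`, `seed`.
#' @export
sc_sample <- function(seq, m = energy_model(), protocol = sc_protocol(),
                      seed, t_melt = NULL) {
  if (missing(seed)) stop("an integer RNG seed is required")
  seq <- normalize_rna(seq)
  tm <- if (is.null(t_melt)) estimate_melting_temperature(seq, m) else t_melt
  temps <- c(37, 37 + seq_len(protocol$n_steps) * (tm - 37) / 10)
  counts <- c(protocol$n_base, rep(protocol$n_step, protocol$n_steps))
  structures <- list()
  temp_of <- numeric(0)
  for (k in seq_along(temps)) {
    draws <- sample_structures(seq, counts[k], fold_constraints(),
                               at_temperature(m, temps[k]),
                               seed = seed + k - 1L)
    structures <- c(structures, draws)
    temp_of <- c(temp_of, rep(temps[k], counts[k]))
  }
  energies <- vapply(structures, function(s) structure_energy(seq, s, m),
                     numeric(1L))
  structure(list(structures = structures, energies = energies,
                 temperatures = temp_of, sequence = seq,
                 protocol = protocol, seed = seed, t_melt = tm, model = m),
            class = "sc_sample_set")
}

#' @export
print.sc_sample_set <- function(x, ...) {
  cat("Boltzmann sample set:", length(x$structures), "structures over",
      nchar(x$sequence), "nt at", length(unique(x$temperatures)),
      "temperature(s); Tm =", x$t_melt, "degC\n")
  invisible(x)
}

#' Write a sample set as TSV
#'
#' Columns: dot-bracket structure, energy (kcal/mol), temperature (degC).
#'
#' @param ss An [sc_sample_set].
#' @param path Output path.
#' @export
write_samples_tsv <- function(ss, path) {
  df <- data.frame(
    structure = vapply(ss$structures, write_dotbracket, character(1L)),
    energy = ss$energies, temperature = ss$temperatures)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# indicator matrix of samples over the union of observed pairs; squared
# Euclidean distance between rows equals base-pair Hamming distance
indicator_matrix <- function(structures, n) {
  keys <- lapply(structures, function(s) pair_keys(s$pairs, n))
  vocab <- sort(unique(unlist(keys)))
  x <- matrix(0, nrow = length(structures), ncol = length(vocab))
  for (r in seq_along(keys))
    x[r, match(keys[[r]], vocab)] <- 1
  vocab_pairs <- cbind(i = (vocab - 1) %/% n + 1, j = (vocab - 1) %% n + 1)
  list(x = x, vocab = vocab, vocab_pairs = vocab_pairs)
}

#' Two-way clustering of a sample set
#'
#' k-means with k = 2 on binary base-pair indicator vectors, for which
#' squared Euclidean distance equals the base-pair Hamming distance between
#' structures. Ten seeded restarts keep the outcome deterministic for a
#' given seed. If all samples are identical (or there are fewer than two
#' distinct structures) the result is flagged degenerate.
#'
#' @param ss An [sc_sample_set].
#' @param seed Integer RNG seed (required).
#' @return An object of class `sc_clustering`: `assignment` (1/2 per
#'   sample), `centers`, `vocab_pairs`, `degenerate`, and per-cluster
#'   lowest-energy member indices `best_member`.
#' @export
cluster_two <- function(ss, seed) {
  if (missing(seed)) stop("an integer RNG seed is required")
  stopifnot(inherits(ss, "sc_sample_set"))
  n <- nchar(ss$sequence)
  ind <- indicator_matrix(ss$structures, n)
  distinct <- nrow(unique(ind$x))
  if (ncol(ind$x) == 0L || distinct < 2L) {
    return(structure(list(assignment = rep(1L, length(ss$structures)),
                          centers = NULL, vocab_pairs = ind$vocab_pairs,
                          degenerate = TRUE, best_member = NA_integer_),
                     class = "sc_clustering"))
  }
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  km <- stats::kmeans(ind$x, centers = 2L, nstart = 10L, iter.max = 100L)
  assignment <- as.integer(km$cluster)
  best <- vapply(1:2, function(cl) {
    members <- which(assignment == cl)
    members[which.min(ss$energies[members])]
  }, integer(1L))
  structure(list(assignment = assignment, centers = km$centers,
                 vocab_pairs = ind$vocab_pairs, degenerate = FALSE,
                 best_member = best, indicator = ind$x),
            class = "sc_clustering")
}

#' @export
print.sc_clustering <- function(x, ...) {
  if (x$degenerate) {
    cat("Degenerate clustering: all samples identical\n")
  } else {
    cat("2-means clustering: cluster sizes",
        paste(tabulate(x$assignment, 2L), collapse = " / "), "\n")
  }
  invisible(x)
}

#' Sampled alternative structure
#'
#' The lowest-energy sample in the cluster that does not contain the MFE
#' structure; the MFE structure's cluster is determined by assigning its
#' own indicator vector to the nearest centroid (the MFE structure is not
#' injected into the sample set). Ties are broken by first occurrence.
#'
#' @param ss An [sc_sample_set].
#' @param cl An [cluster_two()] result (must not be degenerate).
#' @param s1 The MFE [rna_structure].
#' @return A list with `structure`, `energy`, `cluster` (the alternative
#'   cluster label) and `index` (sample index).
#' @export
sc_alternative <- function(ss, cl, s1) {
  stopifnot(inherits(cl, "sc_clustering"))
  if (cl$degenerate)
    stop("degenerate clustering: cannot identify an alternative cluster")
  n <- nchar(ss$sequence)
  keys1 <- pair_keys(s1$pairs, n)
  vkeys <- (cl$vocab_pairs[, 1L] - 1) * n + cl$vocab_pairs[, 2L]
  v1 <- as.numeric(vkeys %in% keys1)
  d2 <- rowSums(sweep(cl$centers, 2L, v1)^2)
  mfe_cluster <- which.min(d2)
  alt <- 3L - mfe_cluster
  members <- which(cl$assignment == alt)
  idx <- members[which.min(ss$energies[members])]
  list(structure = ss$structures[[idx]], energy = ss$energies[idx],
       cluster = alt, index = idx)
}

#' Mean silhouette of a two-way clustering
#'
#' The standard silhouette under base-pair Hamming distance, averaged over
#' all samples; members of singleton clusters score 0, as do samples whose
#' intra- and inter-cluster mean distances are both 0. Used as the
#' sampling-clustering switch-classification score.
#'
#' @param ss An [sc_sample_set].
#' @param cl A non-degenerate [cluster_two()] result.
#' @return A real in [-1, 1].
#' @export
mean_silhouette <- function(ss, cl) {
  stopifnot(inherits(cl, "sc_clustering"))
  if (cl$degenerate)
    stop("degenerate clustering: silhouette undefined")
  x <- cl$indicator
  if (is.null(x))
    x <- indicator_matrix(ss$structures, nchar(ss$sequence))$x
  d <- as.matrix(stats::dist(x))^2  # squared Euclidean = Hamming
  g <- cl$assignment
  sizes <- tabulate(g, 2L)
  s <- vapply(seq_along(g), function(i) {
    own <- g[i]
    if (sizes[own] == 1L) return(0)
    a <- sum(d[i, g == own]) / (sizes[own] - 1L)
    b <- mean(d[i, g != own])
    if (max(a, b) == 0) return(0)
    (b - a) / max(a, b)
  }, numeric(1L))
  mean(s)
}

#' Run the full sampling-clustering pipeline
#'
#' MFE prediction, multi-temperature sampling, two-way clustering,
#' alternative-structure pick, and silhouette score.
#'
#' @param seq RNA sequence string.
#' @param m An [energy_model].
#' @param protocol An [sc_protocol].
#' @param seed Integer RNG seed (required).
#' @return An object of class `sc_result` with fields `s1`, `s2hat` (NULL
#'   when the clustering is degenerate), `silhouette`, `samples`,
#'   `clustering`, `energy_s1`, `energy_alt`, `degenerate`.
#' @export
run_sc_pipeline <- function(seq, m = energy_model(),
                            protocol = sc_protocol(), seed) {
  if (missing(seed)) stop("an integer RNG seed is required")
  seq <- normalize_rna(seq)
  mfe <- constrained_mfe(seq, fold_constraints(), at_temperature(m, 37))
  ss <- sc_sample(seq, m, protocol, seed = seed)
  cl <- cluster_two(ss, seed = seed)
  if (cl$degenerate) {
    res <- list(s1 = mfe$structure, s2hat = NULL, silhouette = NA_real_,
                samples = ss, clustering = cl, energy_s1 = mfe$energy,
                energy_alt = NA_real_, degenerate = TRUE)
  } else {
    alt <- sc_alternative(ss, cl, mfe$structure)
    res <- list(s1 = mfe$structure, s2hat = alt$structure,
                silhouette = mean_silhouette(ss, cl), samples = ss,
                clustering = cl, energy_s1 = mfe$energy,
                energy_alt = alt$energy, degenerate = FALSE)
  }
  class(res) <- "sc_result"
  res
}

#' @export
print.sc_result <- function(x, ...) {
  cat("Sampling-clustering prediction (", nchar(x$samples$sequence),
      " nt, ", length(x$samples$structures), " samples)\n", sep = "")
  cat("S1* (", format(x$energy_s1), " kcal/mol): ",
      write_dotbracket(x$s1), "\n", sep = "")
  if (x$degenerate) {
    cat("Degenerate sample set: no alternative cluster\n")
  } else {
    cat("S^2* (", format(x$energy_alt), " kcal/mol): ",
        write_dotbracket(x$s2hat), "\n", sep = "")
    cat("Mean silhouette: ", round(x$silhouette, 4), "\n", sep = "")
  }
  invisible(x)
}
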