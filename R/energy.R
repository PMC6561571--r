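#' Reference thermodynamic model
#'
#' An additive pair-plus-stack energy model over canonical base pairs. Each
#' pair contributes by class (GC/CG, AU/UA, GU/UG) and each stacked adjacent
#' pair (`[i.j]` directly enclosing `[i+1.j-1]`) contributes a stacking
#' bonus. The model preserves the GC > AU > GU stability ordering and
#' stacking cooperativity while keeping energies exactly additive, so the
#' dynamic-programming engine and the exhaustive-enumeration oracle share
#' one energy function. Loop-size, dangle and multiloop terms are omitted by
#' design (only the hard minimum hairpin size applies); a full
#' nearest-neighbour parameter set can be substituted through the same
#' interface since every engine entry point takes the model as an argument.
#'
#' Temperature enters the ensemble only through `RT` in the Boltzmann
#' weights; structure energies themselves are temperature independent
#' (no enthalpy/entropy split).
#'
#' @param pair_gc,pair_au,pair_gu Pair energies (kcal/mol, must be <= 0)
#'   for the three canonical pair classes.
#' @param stack_bonus Energy (kcal/mol, <= 0) per stacked adjacent pair.
#' @param temperature Folding temperature in degrees Celsius, in [0, 100].
#' @param gas_constant Gas constant R in kcal/(mol K).
#' @param min_hairpin_unpaired Minimum unpaired bases in a hairpin loop.
#' @return An object of class `energy_model`.
#' @examples
#' m <- energy_model()
#' structure_energy("GGAAACC", rna_structure(7, rbind(c(1, 7), c(2, 6))), m)
#' @export
energy_model <- function(pair_gc = -3.0, pair_au = -2.0, pair_gu = -1.0,
                         stack_bonus = -1.0, temperature = 37,
                         gas_constant = 1.98717e-3,
                         min_hairpin_unpaired = 3L) {
  pe <- c(GC = pair_gc, AU = pair_au, GU = pair_gu)
  if (any(pe > 0) || stack_bonus > 0)
    stop("pair energies and stack_bonus must be <= 0 kcal/mol")
  if (temperature < 0 || temperature > 100)
    stop("temperature must lie in [0, 100] degrees C")
  if (gas_constant <= 0) stop("gas_constant must be positive")
  if (min_hairpin_unpaired < 1)
    stop("min_hairpin_unpaired must be at least 1")
  structure(list(pair_energy = pe, stack_bonus = stack_bonus,
                 temperature = temperature, gas_constant = gas_constant,
                 min_hairpin_unpaired = as.integer(min_hairpin_unpaired)),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat("Additive pair/stack RNA energy model\n")
  cat("  pair energies (kcal/mol): GC", x$pair_energy[["GC"]],
      " AU", x$pair_energy[["AU"]], " GU", x$pair_energy[["GU"]], "\n")
  cat("  stack bonus:", x$stack_bonus, "kcal/mol\n")
  cat("  temperature:", x$temperature, "degC  RT =", round(rt_of(x), 5),
      "kcal/mol\n")
  invisible(x)
}

rt_of <- function(m) m$gas_constant * (m$temperature + 273.15)

at_temperature <- function(m, temp) {
  m$temperature <- temp
  m
}

#' Normalise an RNA sequence string
#'
#' Uppercases, transliterates DNA T to U (with a warning), and rejects any
#' character outside ACGU.
#'
#' @param seq A sequence string.
#' @return The normalised RNA string.
#' @export
normalize_rna <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(seq)
  if (grepl("T", s, fixed = TRUE)) {
    warning("DNA alphabet detected: transliterating T to U")
    s <- gsub("T", "U", s, fixed = TRUE)
  }
  if (grepl("[^ACGU]", s))
    stop("illegal character in sequence: ",
         regmatches(s, regexpr("[^ACGU]", s)))
  s
}

# canonical pair class lookup: "GC", "AU", "GU" or NA
PAIR_CLASS <- local({
  cl <- matrix(NA_character_, 4, 4, dimnames = list(c("A", "C", "G", "U"),
                                                    c("A", "C", "G", "U")))
  cl["G", "C"] <- cl["C", "G"] <- "GC"
  cl["A", "U"] <- cl["U", "A"] <- "AU"
  cl["G", "U"] <- cl["U", "G"] <- "GU"
  cl
})

pair_class <- function(b1, b2) PAIR_CLASS[cbind(b1, b2)]

#' Free energy of a structure
#'
#' `E(S)` = sum of pair-class energies plus `stack_bonus` for every pair
#' `[i.j]` whose immediate neighbour `[i+1.j-1]` is also in the structure.
#'
#' @param seq RNA sequence string.
#' @param s An [rna_structure] whose pairs must all be canonical for `seq`.
#' @param m An [energy_model].
#' @return Energy in kcal/mol (0 for the open chain).
#' @export
structure_energy <- function(seq, s, m = energy_model()) {
  seq <- normalize_rna(seq)
  stopifnot(inherits(s, "rna_structure"), nchar(seq) == s$n)
  pairs <- s$pairs
  if (!nrow(pairs)) return(0.0)
  b <- strsplit(seq, "", fixed = TRUE)[[1L]]
  cls <- pair_class(b[pairs[, 1L]], b[pairs[, 2L]])
  if (anyNA(cls)) {
    bad <- which(is.na(cls))[1L]
    stop("non-canonical base pair [", pairs[bad, 1L], ".", pairs[bad, 2L],
         "] (", b[pairs[bad, 1L]], "-", b[pairs[bad, 2L]], ")")
  }
  e <- sum(m$pair_energy[cls])
  keys <- pair_keys(pairs, s$n)
  inner <- (pairs[, 1L] + 1L - 1L) * s$n + (pairs[, 2L] - 1L)
  e + m$stack_bonus * sum(inner %in% keys)
}

#' Boltzmann weight of a structure
#'
#' `exp(-E(S)/RT)`; the open chain has weight exactly 1.
#'
#' @inheritParams structure_energy
#' @return A positive real.
#' @export
boltzmann_weight <- function(seq, s, m = energy_model()) {
  exp(-structure_energy(seq, s, m) / rt_of(m))
}

#' Operational melting temperature of a sequence
#'
#' Scans temperatures from 37 to 100 degC in 1-degree steps and returns the
#' smallest temperature at which the ensemble's expected base-pair count
#' (the sum of all base-pair probabilities) drops to at most half of its
#' value at 37 degC; returns 100 if that never happens and 37 for sequences
#' that cannot form any canonical pair. This is an ensemble-probability
#' notion of melting: the model has no enthalpy/entropy split, so
#' temperature acts only through RT.
#'
#' @param seq RNA sequence string.
#' @param m An [energy_model]; its `temperature` field is ignored during
#'   the scan.
#' @param t_max Upper end of the scan (default 100 degC).
#' @return Temperature in degrees Celsius.
#' @export
estimate_melting_temperature <- function(seq, m = energy_model(),
                                         t_max = 100) {
  seq <- normalize_rna(seq)
  base <- expected_pair_count(seq, at_temperature(m, 37))
  if (base <= 0) return(37)
  for (temp in 37:t_max) {
    if (expected_pair_count(seq, at_temperature(m, temp)) <= base / 2)
      return(temp)
  }
  t_max
}

expected_pair_count <- function(seq, m) {
  p <- basepair_probabilities(seq, fold_constraints(), m)
  sum(p$prob[upper.tri(p$prob)])
}

#' Load energy-model parameters from a flat key = value file
#'
#' Recognised keys: `pair_gc`, `pair_au`, `pair_gu`, `stack_bonus`,
#' `temperature`, `gas_constant`, `min_hairpin_unpaired`. Missing keys keep
#' their defaults; unknown keys are an error. Lines starting with `#` are
#' comments.
#'
#' @param path Path to the parameter file.
#' @return An [energy_model].
#' @export
load_energy_params <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L)) stop("malformed key = value line in ", path)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(trimws(vapply(kv, `[`, "", 2L)))
  known <- c("pair_gc", "pair_au", "pair_gu", "stack_bonus", "temperature",
             "gas_constant", "min_hairpin_unpaired")
  if (any(!keys %in% known))
    stop("unknown parameter key: ", keys[!keys %in% known][1L])
  do.call(energy_model, as.list(stats::setNames(vals, keys)))
}
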