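#' Base-pair confusion counts between a prediction and a reference
#'
#' Base-pair matches are exact index identity (no slippage tolerance):
#' TP = pairs in both structures, FP = predicted-only, FN = reference-only.
#'
#' @param pred,actual [rna_structure] objects of equal length.
#' @return An object of class `pair_confusion`: a list with `tp`, `fp`,
#'   `fn`.
#' @export
pair_confusion <- function(pred, actual) {
  stopifnot(inherits(pred, "rna_structure"),
            inherits(actual, "rna_structure"))
  if (pred$n != actual$n)
    stop("structures have different lengths (", pred$n, " vs ",
         actual$n, ")")
  kp <- pair_keys(pred$pairs, pred$n)
  ka <- pair_keys(actual$pairs, actual$n)
  structure(list(tp = length(intersect(kp, ka)),
                 fp = length(setdiff(kp, ka)),
                 fn = length(setdiff(ka, kp))),
            class = "pair_confusion")
}

#' Pooled base-pair accuracy over a dataset
#'
#' total-SEN and total-PPV pool the confusion counts over all structures
#' before forming ratios: `SEN = 100 sum(TP)/(sum(TP) + sum(FN))`,
#' `PPV = 100 sum(TP)/(sum(TP) + sum(FP))`. `F` is the F1 score, the
#' harmonic mean `2 sen ppv / (sen + ppv)` of the two proportions.
#' An all-zero denominator yields `NA` for that metric.
#'
#' @param confusions A `pair_confusion` or a list of them.
#' @return A list with `total_sen` (%), `total_ppv` (%), and `f1`.
#' @export
total_metrics <- function(confusions) {
  if (inherits(confusions, "pair_confusion"))
    confusions <- list(confusions)
  stopifnot(length(confusions) >= 1L,
            all(vapply(confusions, inherits, logical(1L),
                       "pair_confusion")))
  tp <- sum(vapply(confusions, `[[`, numeric(1L), "tp"))
  fp <- sum(vapply(confusions, `[[`, numeric(1L), "fp"))
  fn <- sum(vapply(confusions, `[[`, numeric(1L), "fn"))
  sen <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(sen) && !is.na(ppv) && sen + ppv > 0)
    2 * sen * ppv / (sen + ppv) else NA_real_
  list(total_sen = 100 * sen, total_ppv = 100 * ppv, f1 = f1)
}

#' Rank-based ROC AUC
#'
#' The Mann-Whitney formulation: the probability that a random positive
#' scores above a random negative, with ties counted half.
#'
#' @param scores Numeric classification scores (higher = more positive).
#' @param labels 0/1 class labels, both classes present.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute an AUC")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Energy-vs-distance landscape referenced to a chosen structure
#'
#' One row per sample giving its base-pair Hamming distance to the
#' reference and its energy, plus a final row for the reference itself at
#' distance 0. With the MFE structure as reference this is the standard
#' landscape; with the alternative structure it is the
#' alternative-structure-referenced (ASR) landscape, which shows how close
#' predictions come to the alternative state.
#'
#' @param ss An [sc_sample_set].
#' @param reference An [rna_structure] of matching length.
#' @param cl Optional [cluster_two()] result supplying cluster labels.
#' @return A data frame with columns `distance`, `energy`, `cluster`
#'   (NA without `cl`), `kind` (`"sample"` or `"reference"`).
#' @export
asr_landscape <- function(ss, reference, cl = NULL) {
  stopifnot(inherits(ss, "sc_sample_set"),
            inherits(reference, "rna_structure"))
  if (reference$n != nchar(ss$sequence))
    stop("reference length does not match the sampled sequence")
  dist <- vapply(ss$structures, hamming_distance, numeric(1L),
                 b = reference)
  labels <- if (is.null(cl)) rep(NA_integer_, length(dist))
            else cl$assignment
  ref_energy <- tryCatch(
    structure_energy(ss$sequence, reference, ss$model %||% energy_model()),
    error = function(e) NA_real_)
  rbind(
    data.frame(distance = dist, energy = ss$energies, cluster = labels,
               kind = "sample", stringsAsFactors = FALSE),
    data.frame(distance = 0, energy = ref_energy, cluster = NA_integer_,
               kind = "reference", stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
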