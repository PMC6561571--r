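# longest "helix" a copy of the segment can form against itself:
# seg[x+d] complementary to seg[y-d] for d = 0..r-1, any x, y
max_self_complementary_run <- function(seg) {
  L <- length(seg)
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  best <- 0L
  for (x in seq_len(L)) {
    for (y in seq_len(L)) {
      r <- 0L
      while (x + r <= L && y - r >= 1L &&
             seg[x + r] == comp[[seg[y - r]]])
        r <- r + 1L
      best <- max(best, r)
    }
  }
  best
}

revcomp_chars <- function(seg) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  rev(unname(comp[seg]))
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

#' Generate a designed bistable (switch-like) sequence
#'
#' Builds `a . l1 . b . l2 . c` where the core `b` is a random segment over
#' \{G, U\}, both arms `a` and `c` are its reverse complement (over
#' \{A, C\}), and the linkers are adenosine runs. Helix A pairs arm `a`
#' with the core; helix B pairs the core with arm `c`; the two helices
#' share the core and are therefore mutually exclusive, giving the sequence
#' two well-defined competing states with known ground truth.
#'
#' The alphabet is chosen so that no parasitic structure can compete with
#' the designed states: \{A, C\} arms have no self-complementarity at all,
#' so arm-arm and intra-arm pairs are impossible (a purely G/C design does
#' not have this property, and its minimum-energy structure splits the
#' core between both arms instead of forming either designed helix), and
#' every base the arms or linkers could pair with lies in the core, which
#' is fully occupied in both designed states. With `bias = TRUE` (the
#' default) helix B is made strictly weaker by knocking out one of its two
#' terminal pairs: the corresponding arm-`c` base is mutated to the letter
#' that pairs with nothing accessible (C to A under a G core base, A to C
#' under a U core base), so no new pairing partner is introduced anywhere.
#' The stored `helixB` ground truth is the remaining contiguous helix of
#' `core_len - 1` pairs. The generator verifies its own ground truth by
#' redrawing the core until the designed stable state is exactly the MFE
#' structure under the reference model (the usual inverse-folding design
#' discipline).
#'
#' @param core_len Core segment length in nt (>= 4, default 8).
#' @param linker_len Linker length in nt (>= 3, default 4).
#' @param bias Weaken helix B so the two states are strictly ordered?
#' @param seed Integer RNG seed (required).
#' @param m Reference [energy_model] used for the design check.
#' @param u_prob Per-position probability of U in the core (default 0.25).
#' @param max_tries Redraw budget for the design check.
#' @return An object of class `bistable_design`: `sequence`, `helixA` and
#'   `helixB` ([rna_structure] ground truths), `core_len`, `linker_len`,
#'   `bias`, `mutated_pos` (NA without bias), `seed`.
#' @export
generate_bistable <- function(core_len = 8L, linker_len = 4L, bias = TRUE,
                              seed, m = energy_model(), u_prob = 0.25,
                              max_tries = 200L) {
  if (missing(seed)) stop("an integer RNG seed is required")
  core_len <- as.integer(core_len); linker_len <- as.integer(linker_len)
  if (core_len < 4L) stop("core_len must be at least 4")
  if (linker_len < 3L) stop("linker_len must be at least 3")
  L <- core_len; ll <- linker_len
  n <- 3L * L + 2L * ll
  helixA <- rna_structure(n, cbind(seq_len(L), 2L * L + ll + 1L - seq_len(L)))
  helixB_full <- cbind(L + ll + seq_len(L), 3L * L + 2L * ll + 1L - seq_len(L))
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      core <- sample(c("G", "U"), L, replace = TRUE,
                     prob = c(1 - u_prob, u_prob))
      arm <- revcomp_chars(core)
      a <- arm; cc <- arm
      mutated_pos <- NA_integer_
      keep <- seq_len(L)
      if (bias) {
        # Knock out a terminal helix-B pair (m = 1, outer, or m = L,
        # inner). The freed core base must be a G whose inward neighbour
        # is U: a freed U would re-pair with a linker adenosine, and a
        # G-run at the knockout end would allow an iso-energetic shifted
        # register of helix B, either of which blurs the designed state.
        ends <- c(1L, L)[c(core[1L] == "G" && core[2L] == "U",
                           core[L] == "G" && core[L - 1L] == "U")]
        if (!length(ends)) next
        mm <- if (length(ends) == 1L) ends else sample(ends, 1L)
        ci <- L + 1L - mm  # partner index within arm c; a C facing a G
        cc[ci] <- "A"
        mutated_pos <- 2L * L + 2L * ll + ci
        keep <- setdiff(keep, mm)
      }
      helixB <- rna_structure(n, helixB_full[keep, , drop = FALSE])
      seqc <- c(a, rep("A", ll), core, rep("A", ll), cc)
      sequence <- paste(seqc, collapse = "")
      # design check: the intended stable state must be the exact MFE
      mfe <- constrained_mfe(sequence, fold_constraints(), m)$structure
      ok <- if (bias) hamming_distance(mfe, helixA) == 0L
            else min(hamming_distance(mfe, helixA),
                     hamming_distance(mfe, helixB)) == 0L
      if (!ok) next
      return(structure(list(sequence = sequence,
                            helixA = helixA, helixB = helixB,
                            core_len = L, linker_len = ll, bias = bias,
                            mutated_pos = mutated_pos, seed = seed),
                       class = "bistable_design"))
    }
    stop("no admissible bistable design found in ", max_tries, " tries")
  })
}

#' @export
print.bistable_design <- function(x, ...) {
  cat("Designed bistable sequence (", nchar(x$sequence), " nt, core ",
      x$core_len, " nt, linkers ", x$linker_len, " nt",
      if (x$bias) ", biased" else "", ")\n", sep = "")
  cat(x$sequence, "\n")
  cat("helix A: ", write_dotbracket(x$helixA), "\n", sep = "")
  cat("helix B: ", write_dotbracket(x$helixB), "\n", sep = "")
  invisible(x)
}

#' Generate a designed monostable (single-hairpin) sequence
#'
#' A single strong hairpin: a random G/C 5' arm, an adenosine loop, and the
#' arm's reverse complement. Arms are redrawn until they contain no
#' self-complementary run of 3 or more bases, so no competing helix of more
#' than 2 pairs exists; the sequence has one designed state and no designed
#' alternative. Serves as the negative class for switch classification.
#'
#' @param stem_len Stem length in bp (>= 3, default 8).
#' @param loop_len Loop length in nt (>= 3, default 4).
#' @param seed Integer RNG seed (required).
#' @return An object of class `monostable_design`: `sequence`, `structure`
#'   (the hairpin ground truth), `stem_len`, `loop_len`, `seed`.
#' @export
generate_monostable <- function(stem_len = 8L, loop_len = 4L, seed) {
  if (missing(seed)) stop("an integer RNG seed is required")
  stem_len <- as.integer(stem_len); loop_len <- as.integer(loop_len)
  if (stem_len < 3L) stop("stem_len must be at least 3")
  if (loop_len < 3L) stop("loop_len must be at least 3")
  with_seed(seed, {
    repeat {
      arm <- sample(c("G", "C"), stem_len, replace = TRUE)
      if (max_self_complementary_run(arm) < 3L) break
    }
    seqc <- c(arm, rep("A", loop_len), revcomp_chars(arm))
    n <- 2L * stem_len + loop_len
    hairpin <- rna_structure(n, cbind(seq_len(stem_len),
                                      n + 1L - seq_len(stem_len)))
    structure(list(sequence = paste(seqc, collapse = ""),
                   structure = hairpin, stem_len = stem_len,
                   loop_len = loop_len, seed = seed),
              class = "monostable_design")
  })
}

#' @export
print.monostable_design <- function(x, ...) {
  cat("Designed monostable hairpin (", nchar(x$sequence), " nt)\n",
      sep = "")
  cat(x$sequence, "\n")
  cat(write_dotbracket(x$structure), "\n", sep = "")
  invisible(x)
}

#' Write synthetic designs as FASTA plus dot-bracket ground truth
#'
#' Emits `<name>.fa` with the sequences and `<name>.dbn` with one Vienna
#' record per design and ground-truth structure (two records per bistable
#' design: helices A and B).
#'
#' @param designs A list of `bistable_design` / `monostable_design`
#'   objects.
#' @param dir Output directory (created if missing).
#' @param name Basename for the two files.
#' @return The two file paths, invisibly.
#' @export
write_designs <- function(designs, dir, name = "designs") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fa <- file.path(dir, paste0(name, ".fa"))
  dbn <- file.path(dir, paste0(name, ".dbn"))
  unlink(c(fa, dbn))
  for (k in seq_along(designs)) {
    d <- designs[[k]]
    id <- if (inherits(d, "bistable_design"))
      paste0("bistable_", k) else paste0("monostable_", k)
    cat(">", id, "\n", d$sequence, "\n", sep = "", file = fa, append = TRUE)
    if (inherits(d, "bistable_design")) {
      write_vienna(paste0(id, "_helixA"), d$sequence, d$helixA, dbn,
                   append = TRUE)
      write_vienna(paste0(id, "_helixB"), d$sequence, d$helixB, dbn,
                   append = TRUE)
    } else {
      write_vienna(id, d$sequence, d$structure, dbn, append = TRUE)
    }
  }
  invisible(c(fa, dbn))
}
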