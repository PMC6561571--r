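#' RNA secondary structure
#'
#' A secondary structure is a set of base pairs `[i.j]` (1-based, `i < j`)
#' over a sequence of given length. Pairs must be position-disjoint (no base
#' triples) and non-crossing (no pseudoknots); every hairpin loop must
#' enclose at least `min_hairpin_unpaired` unpaired bases (a violation only
#' warns, so experimentally derived reference structures still load).
#'
#' @param length Sequence length in nucleotides (positive integer).
#' @param pairs Two-column integer matrix of base pairs, one row per pair;
#'   `NULL` or a zero-row matrix means the open chain. Rows are normalised
#'   to `i < j` and sorted by `i`.
#' @param min_hairpin_unpaired Minimum number of unpaired bases enclosed by
#'   a hairpin loop (default 3).
#' @return An object of class `rna_structure` with fields `n` and `pairs`.
#' @examples
#' rna_structure(7, rbind(c(1, 7), c(2, 6)))
#' @export
rna_structure <- function(length, pairs = NULL, min_hairpin_unpaired = 3L) {
  n <- as.integer(length)
  if (is.na(n) || n < 1L) stop("structure length must be a positive integer")
  pairs <- normalize_pairs(pairs)
  if (nrow(pairs)) {
    if (any(pairs < 1L) || any(pairs > n))
      stop("base-pair index outside 1..", n)
    idx <- as.vector(pairs)
    if (anyDuplicated(idx))
      stop("position ", idx[duplicated(idx)][1L],
           " occurs in more than one base pair (base triples not allowed)")
    if (pairs_cross(pairs))
      stop("crossing base pairs (pseudoknots) are not allowed")
    small <- pairs[, 2L] - pairs[, 1L] - 1L < min_hairpin_unpaired
    if (any(small))
      warning(sum(small), " base pair(s) enclose fewer than ",
              min_hairpin_unpaired, " unpaired bases")
  }
  structure(list(n = n, pairs = pairs), class = "rna_structure")
}

# i < j per row, sorted by i, integer storage, duplicates removed
normalize_pairs <- function(pairs) {
  if (is.null(pairs) || length(pairs) == 0L)
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j"))))
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  swap <- pairs[, 1L] > pairs[, 2L]
  pairs[swap, ] <- pairs[swap, 2:1]
  if (any(pairs[, 1L] == pairs[, 2L])) stop("a base cannot pair with itself")
  pairs <- unique(pairs)
  pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  dimnames(pairs) <- list(NULL, c("i", "j"))
  pairs
}

# any two rows [i,j],[k,l] with i < k < j < l?
pairs_cross <- function(pairs) {
  m <- nrow(pairs)
  if (m < 2L) return(FALSE)
  for (a in seq_len(m - 1L)) {
    i <- pairs[a, 1L]; j <- pairs[a, 2L]
    k <- pairs[(a + 1L):m, 1L]; l <- pairs[(a + 1L):m, 2L]
    if (any(i < k & k < j & j < l)) return(TRUE)
  }
  FALSE
}

#' @export
print.rna_structure <- function(x, ...) {
  cat("RNA secondary structure: ", x$n, " nt, ", nrow(x$pairs),
      " base pair(s)\n", sep = "")
  cat(write_dotbracket(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.rna_structure <- function(x, ...) write_dotbracket(x)

#' Parse a dot-bracket string
#'
#' Round brackets denote base pairs, dots unpaired bases. Pseudoknot
#' alphabets (`[]`, `{}`, letters) are not supported.
#'
#' @param text A string over the alphabet `".()"`.
#' @return An [rna_structure].
#' @examples
#' parse_dotbracket("((...))")
#' @export
parse_dotbracket <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c(".", "(", ")"))
  if (length(bad))
    stop("illegal character '", chars[bad[1L]], "' at position ", bad[1L])
  open <- integer(0)
  pairs <- matrix(integer(0), ncol = 2L)
  for (p in seq_along(chars)) {
    if (chars[p] == "(") {
      open <- c(open, p)
    } else if (chars[p] == ")") {
      if (!length(open))
        stop("unbalanced bracket: unmatched ')' at position ", p)
      pairs <- rbind(pairs, c(open[length(open)], p))
      open <- open[-length(open)]
    }
  }
  if (length(open))
    stop("unbalanced bracket: unmatched '(' at position ", open[1L])
  rna_structure(length(chars), pairs)
}

#' Write a structure as a dot-bracket string
#'
#' Exact inverse of [parse_dotbracket()] on valid structures.
#'
#' @param s An [rna_structure].
#' @return A dot-bracket string of length `s$n`.
#' @export
write_dotbracket <- function(s) {
  stopifnot(inherits(s, "rna_structure"))
  out <- rep(".", s$n)
  out[s$pairs[, 1L]] <- "("
  out[s$pairs[, 2L]] <- ")"
  paste(out, collapse = "")
}

pair_keys <- function(pairs, n) (pairs[, 1L] - 1) * n + pairs[, 2L]

#' Base-pair Hamming distance between two structures
#'
#' The size of the symmetric difference of the two base-pair sets: the
#' number of pairs present in exactly one of the structures.
#'
#' @param a,b [rna_structure] objects of equal length.
#' @return A non-negative integer.
#' @export
hamming_distance <- function(a, b) {
  stopifnot(inherits(a, "rna_structure"), inherits(b, "rna_structure"))
  if (a$n != b$n)
    stop("structures have different lengths (", a$n, " vs ", b$n, ")")
  ka <- pair_keys(a$pairs, a$n)
  kb <- pair_keys(b$pairs, b$n)
  length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}

#' Distance between two base pairs
#'
#' `max(|i - i'|, |j - j'|)` for pairs `[i.j]` and `[i'.j']`: the larger of
#' the two strand-wise coordinate offsets. A metric on index pairs.
#'
#' @param p,q Base pairs as length-2 integer vectors `c(i, j)` with `i < j`.
#' @return A non-negative integer.
#' @examples
#' basepair_distance(c(2, 9), c(5, 12)) # 3
#' @export
basepair_distance <- function(p, q) {
  p <- as_basepair(p); q <- as_basepair(q)
  max(abs(p[1L] - q[1L]), abs(p[2L] - q[2L]))
}

as_basepair <- function(p) {
  p <- as.integer(p)
  if (length(p) != 2L || anyNA(p) || p[1L] >= p[2L])
    stop("a base pair is a length-2 integer vector c(i, j) with i < j")
  p
}

#' Distance from a base pair to a structure
#'
#' The minimum [basepair_distance()] from `p` to any pair of `s`. For a
#' structure with no pairs the empty minimum is `Inf`, so the exclusion
#' neighbourhood of an open chain is empty.
#'
#' @param p A base pair `c(i, j)`.
#' @param s An [rna_structure].
#' @return A non-negative integer, or `Inf` when `s` has no pairs.
#' @export
basepair_to_structure_distance <- function(p, s) {
  p <- as_basepair(p)
  stopifnot(inherits(s, "rna_structure"))
  if (!nrow(s$pairs)) return(Inf)
  min(pmax(abs(s$pairs[, 1L] - p[1L]), abs(s$pairs[, 2L] - p[2L])))
}

#' Read records in Vienna (dot-bracket) format
#'
#' Each record is `">name"`, a sequence line, and a structure line.
#'
#' @param path Path to a Vienna-format file.
#' @return A list of records, each a list with `name`, `sequence` and
#'   `structure` (an [rna_structure]).
#' @export
read_vienna <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no '>' record headers in ", path)
  lapply(starts, function(st) {
    if (st + 2L > length(lines))
      stop("truncated record '", lines[st], "' in ", path)
    list(name = sub("^>\\s*", "", lines[st]),
         sequence = normalize_rna(trimws(lines[st + 1L])),
         structure = parse_dotbracket(trimws(lines[st + 2L])))
  })
}

#' Write a record in Vienna (dot-bracket) format
#'
#' @param name Record name.
#' @param sequence RNA sequence.
#' @param s An [rna_structure] for the sequence.
#' @param path Output file path.
#' @param append Append to an existing file?
#' @export
write_vienna <- function(name, sequence, s, path, append = FALSE) {
  stopifnot(nchar(sequence) == s$n)
  cat(">", name, "\n", sequence, "\n", write_dotbracket(s), "\n",
      sep = "", file = path, append = append)
}

#' Read a reference structure in CT format
#'
#' Standard 6-column connectivity table. Crossing pairs (pseudoknots) are
#' resolved greedily, keeping the 5'-most pair of each crossing conflict,
#' with a warning; the thermodynamic model is pseudoknot-free.
#'
#' @param path Path to a CT file.
#' @return A list with `sequence` and `structure` (an [rna_structure]).
#' @export
read_ct <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  n <- suppressWarnings(as.integer(header[1L]))
  if (is.na(n) || n < 1L) stop("malformed CT header in ", path)
  if (length(lines) < n + 1L) stop("CT file has fewer than ", n, " rows")
  body <- do.call(rbind, lapply(lines[2L:(n + 1L)], function(l)
    strsplit(trimws(l), "\\s+")[[1L]][1:6]))
  seq <- paste(body[, 2L], collapse = "")
  partner <- as.integer(body[, 5L])
  idx <- as.integer(body[, 1L])
  paired <- which(partner > 0L & partner > idx)
  pairs <- cbind(idx[paired], partner[paired])
  # greedy pseudoknot removal: keep the 5'-most pair of each conflict
  if (nrow(pairs) > 1L) {
    pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
    keep <- logical(nrow(pairs))
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1L]; j <- pairs[r, 2L]
      kept <- pairs[keep, , drop = FALSE]
      crosses <- nrow(kept) &&
        any((kept[, 1L] < i & i < kept[, 2L] & kept[, 2L] < j) |
            (i < kept[, 1L] & kept[, 1L] < j & j < kept[, 2L]))
      keep[r] <- !crosses
    }
    if (!all(keep))
      warning(sum(!keep), " crossing pair(s) dropped while reading ", path)
    pairs <- pairs[keep, , drop = FALSE]
  }
  list(sequence = normalize_rna(seq),
       structure = rna_structure(n, pairs))
}
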