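# Position weight matrix model: frequency matrix -> log2-odds scoring matrix.

DNA_BASES <- c("A", "C", "G", "T")

# Reverse complement of a plain character word (A/C/G/T/N only).
revcomp_chr <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(toupper(s), "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# Encode a sequence as indices into DNA_BASES; N (or any ambiguity) -> NA.
encode_dna <- function(s) {
  match(strsplit(toupper(s), "")[[1]], DNA_BASES)
}

check_background <- function(background) {
  if (is.null(names(background))) names(background) <- DNA_BASES
  background <- background[DNA_BASES]
  if (anyNA(background) || any(background <= 0))
    stop("background must give a strictly positive probability for each of A, C, G, T")
  if (abs(sum(background) - 1) > 1e-9)
    stop("background probabilities must sum to 1")
  background
}

#' Construct a base-frequency matrix for a DNA motif
#'
#' A frequency matrix stores, for each motif position, the probability of
#' observing each of A, C, G, T. It is the input representation for
#' [build_scoring_matrix()] and the sampling model used by
#' [generate_study_like_set()] in `mode = "sample"`.
#'
#' @param probs Numeric matrix with 4 rows (A, C, G, T, in that order or named)
#'   and one column per motif position. Columns must each sum to 1 (tolerance
#'   `1e-6`); pass counts through [read_jaspar()] instead, which normalizes.
#' @param source_id Free-text provenance tag (e.g. a motif-database
#'   identifier).
#' @return An object of class `frequency_matrix`: a list with elements
#'   `probs` (4 x width matrix, rows A/C/G/T), `width`, `source_id`.
#' @examples
#' fm <- frequency_matrix(matrix(0.25, 4, 6), source_id = "uniform-6")
#' fm
#' @seealso [build_scoring_matrix()], [read_jaspar()], [read_meme()]
#' @export
frequency_matrix <- function(probs, source_id = "unknown") {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4)
    stop("a frequency matrix needs 4 rows (A, C, G, T); got ", nrow(probs))
  if (ncol(probs) < 1) stop("motif width must be at least 1")
  if (is.null(rownames(probs))) {
    rownames(probs) <- DNA_BASES
  } else {
    rn <- toupper(rownames(probs))
    if (!setequal(rn, DNA_BASES))
      stop("row names must be A, C, G, T")
    probs <- probs[match(DNA_BASES, rn), , drop = FALSE]
    rownames(probs) <- DNA_BASES
  }
  if (any(probs < 0)) stop("probabilities must be nonnegative")
  cs <- colSums(probs)
  if (any(abs(cs - 1) > 1e-6))
    stop("every column must sum to 1; offending position(s): ",
         paste(which(abs(cs - 1) > 1e-6), collapse = ", "))
  structure(
    list(probs = probs, width = ncol(probs), source_id = as.character(source_id)),
    class = "frequency_matrix"
  )
}

#' @export
print.frequency_matrix <- function(x, ...) {
  cat("Frequency matrix '", x$source_id, "' (width ", x$width,
      ", consensus ", consensus_word(x), ")\n", sep = "")
  print(round(x$probs, 3))
  invisible(x)
}

#' Build a log2-odds scoring matrix from a frequency matrix
#'
#' Converts per-position base probabilities into additive log2-odds scores
#' against a background model. Probabilities are first regularized with a
#' pseudocount distributed proportionally to the background:
#' `p' = (p + pseudocount * bg) / (1 + pseudocount)`, so that regularized
#' columns still sum to 1. Each cell is then `log2(p' / bg)` (bits). The
#' maximum attainable score (`max_score`, the sum over positions of the
#' per-column maximum, attained by the consensus word) is stored and used as
#' the normalization denominator by [call_sites()].
#'
#' With `pseudocount = 0`, a zero-probability cell yields `-Inf` (a window
#' containing that base can never score above 0, hence is never a hit); a
#' column that is zero everywhere is an error, since no consensus base exists.
#'
#' @param freqs A [frequency_matrix()].
#' @param pseudocount Nonnegative regularization weight (default `0.01`).
#' @param background Named (A/C/G/T) probability vector summing to 1, all
#'   entries strictly positive. Default uniform.
#' @return An object of class `scoring_matrix`: list with `cells` (4 x width
#'   log2-odds matrix), `width`, `background`, `max_score` (bits),
#'   `source_id`.
#' @examples
#' sm <- build_scoring_matrix(crz1_like_freqs())
#' sm$max_score
#' consensus_word(sm)
#' @export
build_scoring_matrix <- function(freqs, pseudocount = 0.01,
                                 background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  stopifnot(inherits(freqs, "frequency_matrix"))
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount < 0)
    stop("pseudocount must be a single nonnegative number")
  background <- check_background(background)
  p_reg <- (freqs$probs + pseudocount * background) / (1 + pseudocount)
  zero_cols <- which(colSums(p_reg) == 0 | apply(p_reg, 2, max) == 0)
  if (length(zero_cols))
    stop("position(s) ", paste(zero_cols, collapse = ", "),
         " have zero probability for every base; no consensus is definable")
  cells <- log2(p_reg / background)
  dimnames(cells) <- list(DNA_BASES, NULL)
  structure(
    list(cells = cells, width = ncol(cells),
         background = background,
         max_score = sum(apply(cells, 2, max)),
         source_id = freqs$source_id),
    class = "scoring_matrix"
  )
}

#' Maximum attainable matrix score
#'
#' The sum over columns of the per-column maximum log2-odds cell, i.e. the
#' score of the consensus word. This is the denominator of the
#' score-normalization used throughout site calling.
#'
#' @param m A `scoring_matrix`.
#' @return Maximum score in bits.
#' @export
max_score <- function(m) {
  stopifnot(inherits(m, "scoring_matrix"))
  m$max_score
}

#' Consensus word of a motif matrix
#'
#' Per-position argmax base (ties broken towards A < C < G < T).
#'
#' @param m A `scoring_matrix` or `frequency_matrix`.
#' @return Single character string of length `width`.
#' @export
consensus_word <- function(m) {
  vals <- if (inherits(m, "scoring_matrix")) m$cells
          else if (inherits(m, "frequency_matrix")) m$probs
          else stop("need a scoring_matrix or frequency_matrix")
  paste(DNA_BASES[apply(vals, 2, which.max)], collapse = "")
}

#' Reverse-complement a scoring matrix
#'
#' Produces the matrix that scores the opposite strand: column order is
#' reversed and base rows complemented, so scanning a sequence with the
#' reverse-complement matrix is equivalent to scoring the reverse complement
#' of each window with the original. `max_score` is preserved exactly, and the
#' operation is an involution.
#'
#' @param m A `scoring_matrix`.
#' @return A `scoring_matrix` for the opposite strand.
#' @export
reverse_complement_matrix <- function(m) {
  stopifnot(inherits(m, "scoring_matrix"))
  # rows are ordered A,C,G,T: complementing = reversing the row order
  cells <- m$cells[4:1, m$width:1, drop = FALSE]
  dimnames(cells) <- list(DNA_BASES, NULL)
  bg <- m$background[4:1]
  names(bg) <- DNA_BASES
  structure(
    list(cells = cells, width = m$width, background = bg,
         max_score = m$max_score, source_id = m$source_id),
    class = "scoring_matrix"
  )
}

#' Score a single sequence window
#'
#' Sums the per-position log2-odds cells matching the window's bases. Windows
#' containing `N` are unscorable and return `NA_real_` (never a numeric
#' score); any other non-ACGT character, or a window of the wrong length, is
#' an error.
#'
#' @param m A `scoring_matrix`.
#' @param window Character string of length `m$width` over A/C/G/T/N.
#' @return Score in bits, or `NA_real_` for an N-containing window.
#' @examples
#' sm <- build_scoring_matrix(crz1_like_freqs())
#' score_window(sm, consensus_word(sm)) == max_score(sm)
#' @export
score_window <- function(m, window) {
  stopifnot(inherits(m, "scoring_matrix"))
  if (!is.character(window) || length(window) != 1)
    stop("window must be a single character string")
  if (nchar(window) != m$width)
    stop("window length ", nchar(window), " does not match matrix width ", m$width)
  chars <- strsplit(toupper(window), "")[[1]]
  idx <- match(chars, DNA_BASES)
  bad <- is.na(idx) & chars != "N"
  if (any(bad))
    stop("window contains non-ACGTN character(s): ",
         paste(unique(chars[bad]), collapse = ", "))
  if (anyNA(idx)) return(NA_real_)
  sum(m$cells[cbind(idx, seq_len(m$width))])
}

#' @export
print.scoring_matrix <- function(x, ...) {
  cat("Log2-odds scoring matrix '", x$source_id, "' (width ", x$width,
      ")\n  consensus ", consensus_word(x),
      ", max score ", format(x$max_score, digits = 4), " bits\n", sep = "")
  invisible(x)
}

#' Synthetic CRZ1/CDRE-like motif fixture
#'
#' An eight-position, high-information frequency matrix with consensus
#' `GAGGCTCA`, built in code for tests and demonstrations. It mimics the
#' information scale of a CDRE-class motif but is *synthetic* — it is not a
#' database matrix and carries no biological claim. The consensus is not a
#' reverse-complement palindrome, so sense and antisense calls are
#' unambiguous.
#'
#' @param dominant Probability of the consensus base at each position
#'   (default `0.85`; the other three bases share the remainder equally).
#' @return A [frequency_matrix()].
#' @export
crz1_like_freqs <- function(dominant = 0.85) {
  stopifnot(dominant > 0.25, dominant < 1)
  word <- strsplit("GAGGCTCA", "")[[1]]
  off <- (1 - dominant) / 3
  probs <- matrix(off, nrow = 4, ncol = length(word),
                  dimnames = list(DNA_BASES, NULL))
  probs[cbind(match(word, DNA_BASES), seq_along(word))] <- dominant
  frequency_matrix(probs, source_id = "synthetic-crz1-like")
}
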