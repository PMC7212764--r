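# Study-like synthetic promoter sets with a known planted-site truth table.

#' Sample an i.i.d. background sequence
#'
#' @param length Sequence length (0 gives an empty string).
#' @param composition Named or positional (A, C, G, T) probability vector
#'   summing to 1.
#' @param seed Optional integer seed; when `NULL`, the current RNG state is
#'   used (so callers that seed once stay reproducible).
#' @return A single character string.
#' @export
sample_background_sequence <- function(length,
                                       composition = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                                       seed = NULL) {
  if (!is.numeric(length) || length(length) != 1 || length < 0)
    stop("length must be a single nonnegative integer")
  if (length(composition) != 4 || any(composition < 0) ||
      abs(sum(composition) - 1) > 1e-9)
    stop("composition must be 4 nonnegative probabilities summing to 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (length == 0) return("")
  paste(sample(DNA_BASES, length, replace = TRUE, prob = composition), collapse = "")
}

# Uniform draw of k non-overlapping width-w window starts (0-based) in a
# sequence of given length: sorted uniform draw on the shrunk interval,
# then shift by cumulative widths. Exact, no rejection loop.
place_nonoverlapping <- function(k, width, length) {
  if (k == 0L) return(integer(0))
  slack <- length - k * width
  if (slack < 0)
    stop("cannot place ", k, " non-overlapping sites of width ", width,
         " in a sequence of length ", length)
  sort(sample.int(slack + 1L, k, replace = TRUE) - 1L) + (seq_len(k) - 1L) * width
}

sample_word_from_matrix <- function(freqs) {
  paste(vapply(seq_len(freqs$width), function(j) {
    sample(DNA_BASES, 1, prob = freqs$probs[, j])
  }, character(1)), collapse = "")
}

# 0-based start offsets of exact occurrences of `word` in `seq`.
word_offsets <- function(seq, word) {
  m <- gregexpr(word, seq, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

#' Generate a study-like synthetic promoter set with planted sites
#'
#' Emulates the design of the in-silico promoter survey: `n_genes` promoters
#' of `length` nt with 0-7 motif instances each, planted in sense or
#' antisense orientation (an antisense site is written as the reverse
#' complement of the drawn word), either as the matrix consensus word or
#' sampled position-wise from the frequency matrix. Planted sites never
#' overlap one another. A complete truth table records every planted site in
#' the same 0-based-offset convention used by [call_sites()].
#'
#' By default (`clean_background = TRUE`) chance occurrences of the consensus
#' word (or its reverse complement) arising in the random background are
#' scrubbed by point mutation outside planted intervals, so the truth table
#' is exhaustive: at threshold 1.0 the scan recovers exactly the planted
#' sites. With `clean_background = FALSE` the background is left untouched
#' and chance hits count as false positives relative to the truth table
#' ([compare_to_truth()] classifies them).
#'
#' @param n_genes Number of promoters (default 30).
#' @param length Promoter length in nt (default 1000).
#' @param site_counts Either `NULL` (per gene: total sites drawn uniformly
#'   from 0..7, each site sense/antisense with probability 1/2) or a data
#'   frame with columns `sense` and `antisense`, one row per gene.
#' @param matrix A [frequency_matrix()] (default [crz1_like_freqs()]).
#' @param mode `"consensus"` (plant the consensus word) or `"sample"`
#'   (draw each planted word position-wise from the matrix).
#' @param seed Integer seed; same seed, same promoter set and truth table.
#' @param composition Background base composition (default uniform).
#' @param clean_background Scrub chance consensus occurrences (default
#'   `TRUE`; see Details).
#' @return Object of class `synthetic_study`: list with `promoters` (a
#'   `promoter_set` data frame: `gene_id`, `sequence`, `length`), `truth`
#'   (data frame `gene_id`, `offset`, `strand_label`, `planted_word`,
#'   `drawn_from`), `matrix`, `mode`, `seed`.
#' @examples
#' study <- generate_study_like_set(n_genes = 5, seed = 11)
#' table(study$truth$strand_label)
#' @export
generate_study_like_set <- function(n_genes = 30L, length = 1000L,
                                    site_counts = NULL,
                                    matrix = crz1_like_freqs(),
                                    mode = c("consensus", "sample"),
                                    seed = 1L,
                                    composition = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                                    clean_background = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(matrix, "frequency_matrix"))
  n_genes <- as.integer(n_genes)
  length <- as.integer(length)
  w <- matrix$width
  cons <- consensus_word(matrix)
  cons_rc <- revcomp_chr(cons)
  set.seed(as.integer(seed))

  if (is.null(site_counts)) {
    total <- sample(0:7, n_genes, replace = TRUE)
    sense_n <- stats::rbinom(n_genes, total, 0.5)
    site_counts <- data.frame(sense = sense_n, antisense = total - sense_n)
  } else {
    stopifnot(is.data.frame(site_counts),
              all(c("sense", "antisense") %in% names(site_counts)),
              nrow(site_counts) == n_genes)
  }

  gene_ids <- sprintf("gene%02d", seq_len(n_genes))
  seqs <- character(n_genes)
  truth_rows <- vector("list", n_genes)

  for (i in seq_len(n_genes)) {
    k_s <- site_counts$sense[i]
    k_a <- site_counts$antisense[i]
    k <- k_s + k_a
    seq <- sample_background_sequence(length, composition)
    offs <- place_nonoverlapping(k, w, length)
    strands <- resample(c(rep("sense", k_s), rep("antisense", k_a)))
    words <- character(k)
    if (k > 0) {
      for (j in seq_len(k)) {
        words[j] <- if (mode == "consensus") cons else sample_word_from_matrix(matrix)
        written <- if (strands[j] == "sense") words[j] else revcomp_chr(words[j])
        substr(seq, offs[j] + 1L, offs[j] + w) <- written
      }
    }
    if (clean_background) {
      planted <- offs  # planted window starts, 0-based
      for (pass in 1:50) {
        chance <- setdiff(c(word_offsets(seq, cons), word_offsets(seq, cons_rc)),
                          if (mode == "consensus") planted else integer(0))
        # in sample mode a drawn word can itself equal the consensus; those
        # planted offsets are truth, not chance
        if (mode == "sample" && length(chance)) {
          chance <- setdiff(chance, planted)
        }
        if (!length(chance)) break
        for (off in chance) {
          pos <- (off + 1L):(off + w)  # 1-based candidate positions
          in_planted <- vapply(pos, function(p) {
            any(p >= planted + 1L & p <= planted + w)
          }, logical(1))
          free <- pos[!in_planted]
          if (!length(free)) next  # fully inside a planted site: leave it
          p <- pick_one(free)
          old <- substr(seq, p, p)
          substr(seq, p, p) <- pick_one(setdiff(DNA_BASES, old))
        }
      }
    }
    seqs[i] <- seq
    truth_rows[[i]] <- if (k > 0) {
      data.frame(gene_id = gene_ids[i], offset = offs, strand_label = strands,
                 planted_word = words,
                 drawn_from = if (mode == "consensus") "consensus" else "matrix-sampled",
                 stringsAsFactors = FALSE)
    } else NULL
  }

  truth <- do.call(rbind, truth_rows)
  if (is.null(truth))
    truth <- data.frame(gene_id = character(0), offset = integer(0),
                        strand_label = character(0), planted_word = character(0),
                        drawn_from = character(0))
  rownames(truth) <- NULL
  promoters <- data.frame(gene_id = gene_ids, sequence = seqs,
                          length = nchar(seqs), stringsAsFactors = FALSE)
  class(promoters) <- c("promoter_set", "data.frame")
  structure(
    list(promoters = promoters, truth = truth, matrix = matrix,
         mode = mode, seed = as.integer(seed)),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic promoter study: ", nrow(x$promoters), " promoters x ",
      x$promoters$length[1], " nt, ", nrow(x$truth), " planted site(s) (",
      x$mode, " mode, seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Compare called hits against a planted truth table
#'
#' Matches hits to planted sites by (gene, offset, strand). Returns recall
#' (fraction of planted sites recovered), the count of false positives
#' (hits with no planted counterpart — chance background hits or, in
#' `"sample"` mode, planted-word windows scoring below threshold elsewhere),
#' and the strand-label agreement among matched hits.
#'
#' @param hits Hit data frame (e.g. `scan$hits`).
#' @param truth Truth table from [generate_study_like_set()].
#' @return List: `n_truth`, `n_hits`, `true_positives`, `false_positives`,
#'   `false_negatives`, `recall`, `strand_agreement`.
#' @export
compare_to_truth <- function(hits, truth) {
  key <- function(d, with_strand = TRUE) {
    if (with_strand) paste(d$gene_id, d$offset, d$strand_label)
    else paste(d$gene_id, d$offset)
  }
  tp <- sum(key(hits) %in% key(truth))
  pos_match <- key(hits, FALSE) %in% key(truth, FALSE)
  strand_agree <- if (any(pos_match)) {
    mean(key(hits)[pos_match] %in% key(truth))
  } else NA_real_
  list(n_truth = nrow(truth), n_hits = nrow(hits),
       true_positives = tp,
       false_positives = nrow(hits) - sum(pos_match),
       false_negatives = nrow(truth) - sum(key(truth) %in% key(hits)),
       recall = if (nrow(truth)) sum(key(truth) %in% key(hits)) / nrow(truth) else NA_real_,
       strand_agreement = strand_agree)
}

#' Exact pass rate of matrix-sampled words at a threshold
#'
#' Enumerates all `4^width` words (so width must be modest, <= 10) and sums
#' the sampling probability of those whose normalized score under the
#' derived scoring matrix reaches `threshold`. This is the exact expected
#' recall of `mode = "sample"` planting.
#'
#' @param freqs A [frequency_matrix()].
#' @param threshold Normalized-score cutoff in `(0, 1]`.
#' @param pseudocount,background Passed to [build_scoring_matrix()].
#' @return Probability in `[0, 1]`.
#' @export
planted_word_pass_rate <- function(freqs, threshold = 0.8, pseudocount = 0.01,
                                   background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  stopifnot(inherits(freqs, "frequency_matrix"))
  w <- freqs$width
  if (w > 10) stop("enumeration limited to width <= 10")
  m <- build_scoring_matrix(freqs, pseudocount = pseudocount, background = background)
  # enumerate words as index grids; accumulate score and probability
  grid <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- numeric(nrow(grid))
  probs <- rep(1, nrow(grid))
  for (j in seq_len(w)) {
    scores <- scores + m$cells[cbind(grid[, j], j)]
    probs <- probs * freqs$probs[cbind(grid[, j], j)]
  }
  sum(probs[scores > 0 & scores / m$max_score >= threshold])
}

#' Write synthetic-study fixtures
#'
#' Materializes a [generate_study_like_set()] result as a promoters FASTA
#' and a truth TSV (the `make-fixtures` CLI subcommand).
#'
#' @param study A `synthetic_study` object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the two paths, invisibly.
#' @export
write_study_fixtures <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "promoters.fasta")
  tsv <- file.path(dir, "truth.tsv")
  write_promoter_fasta(study$promoters, fasta)
  utils::write.table(study$truth, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(promoters = fasta, truth = tsv))
}
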