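# Random-sequence control sets and empirical calibration of the
# normalized-score threshold.

resample <- function(x) if (length(x) == 1L) x else sample(x)
pick_one <- function(x) if (length(x) == 1L) x else x[sample.int(length(x), 1L)]

shuffle_mono_chr <- function(seq) {
  paste(resample(strsplit(seq, "")[[1]]), collapse = "")
}

# Altschul-Erickson dinucleotide-preserving shuffle: draw a uniform random
# Eulerian path through the dinucleotide multigraph (random last-edge
# arborescence check, then independent permutation of the remaining edges).
shuffle_di_chr <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (n < 3L || length(unique(chars)) == 1L) return(paste(resample(chars), collapse = ""))
  last <- chars[n]
  out_edges <- split(chars[-1L], chars[-n])  # successors per vertex
  verts <- names(out_edges)
  inner <- setdiff(verts, last)
  repeat {
    last_edge <- vapply(inner, function(v) pick_one(out_edges[[v]]), character(1))
    # arborescence test: following chosen last edges from every inner vertex
    # must reach `last`
    ok <- all(vapply(inner, function(v) {
      for (hop in seq_len(length(verts) + 1L)) {
        if (v == last) return(TRUE)
        if (!v %in% inner) return(FALSE)
        v <- last_edge[[v]]
      }
      FALSE
    }, logical(1)))
    if (ok) break
  }
  ordered <- lapply(verts, function(v) {
    e <- out_edges[[v]]
    if (v %in% inner) {
      e <- e[-match(last_edge[[v]], e)]
      c(resample(e), last_edge[[v]])
    } else resample(e)
  })
  names(ordered) <- verts
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  res <- character(n)
  res[1L] <- chars[1L]
  cur <- chars[1L]
  for (i in 2:n) {
    nxt <- ordered[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    res[i] <- nxt
    cur <- nxt
  }
  paste(res, collapse = "")
}

iid_background_chr <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  tabs <- table(factor(chars, levels = DNA_BASES))
  tot <- sum(tabs)
  if (tot == 0L) return(seq)
  paste(sample(DNA_BASES, length(chars), replace = TRUE, prob = tabs / tot),
        collapse = "")
}

#' Generate a random-sequence control set
#'
#' Builds `replicates` randomized controls of each input promoter. Shuffle
#' methods preserve per-sequence length and mono- (`shuffle_mono`) or
#' dinucleotide (`shuffle_di`, Altschul-Erickson Eulerian-walk) composition;
#' `iid_background` draws i.i.d. letters from each promoter's own base
#' composition. Fully reproducible from `seed`.
#'
#' @param promoters A `promoter_set` data frame or character vector of
#'   sequences.
#' @param method One of `"shuffle_mono"`, `"shuffle_di"`,
#'   `"iid_background"`.
#' @param replicates Number of controls per promoter (>= 1).
#' @param seed Integer RNG seed.
#' @return Named character vector (`<gene>|rep<k>`) of control sequences,
#'   with attributes `method`, `replicates`, `seed`.
#' @export
generate_null_set <- function(promoters,
                              method = c("shuffle_mono", "shuffle_di", "iid_background"),
                              replicates = 10L, seed = 1L) {
  method <- match.arg(method)
  if (!is.numeric(replicates) || replicates < 1)
    stop("replicates must be >= 1")
  seqs <- if (is.character(promoters)) promoters else promoters$sequence
  ids <- if (is.character(promoters)) {
    if (is.null(names(promoters))) sprintf("seq%03d", seq_along(promoters)) else names(promoters)
  } else promoters$gene_id
  fun <- switch(method,
                shuffle_mono = shuffle_mono_chr,
                shuffle_di = shuffle_di_chr,
                iid_background = iid_background_chr)
  set.seed(as.integer(seed))
  out <- character(0)
  nms <- character(0)
  for (r in seq_len(replicates)) {
    out <- c(out, vapply(seqs, fun, character(1), USE.NAMES = FALSE))
    nms <- c(nms, paste0(ids, "|rep", r))
  }
  names(out) <- nms
  structure(out, method = method, replicates = as.integer(replicates),
            seed = as.integer(seed))
}

#' Collect the normalized-score sample of a sequence set
#'
#' Scans every sequence on both strands and returns the normalized scores
#' (`raw / max_score`) of all scorable windows with raw score > 0 — the same
#' selection rule applied to real promoters before thresholding.
#'
#' @param seqs Character vector of sequences (or a `promoter_set`).
#' @param m A `scoring_matrix`.
#' @return Numeric vector of normalized scores in `(0, 1]`, with attribute
#'   `n_windows` (total scorable windows, both strands).
#' @export
normalized_score_sample <- function(seqs, m) {
  if (is.data.frame(seqs)) seqs <- seqs$sequence
  vals <- numeric(0)
  n_win <- 0L
  for (s in seqs) {
    sc <- scan_sequence(s, m)
    raw <- c(sc$sense, sc$antisense)
    raw <- raw[!is.na(raw)]
    n_win <- n_win + length(raw)
    vals <- c(vals, raw[raw > 0] / m$max_score)
  }
  attr(vals, "n_windows") <- n_win
  vals
}

#' Build a null distribution of normalized scores
#'
#' Convenience wrapper: [generate_null_set()] then
#' [normalized_score_sample()], packaged with its generation metadata.
#'
#' @inheritParams generate_null_set
#' @param m A `scoring_matrix`.
#' @return Object of class `null_distribution`: list with `values`
#'   (normalized scores of positive-raw-score windows), `n_windows` (all
#'   scorable windows, both strands — the false-positive-rate denominator),
#'   `method`, `replicates`, `seed`, `n_sequences`.
#' @export
null_distribution <- function(promoters, m,
                              method = c("shuffle_mono", "shuffle_di", "iid_background"),
                              replicates = 10L, seed = 1L) {
  method <- match.arg(method)
  nulls <- generate_null_set(promoters, method = method,
                             replicates = replicates, seed = seed)
  vals <- normalized_score_sample(nulls, m)
  structure(
    list(values = as.numeric(vals), n_windows = attr(vals, "n_windows"),
         method = method, replicates = as.integer(replicates),
         seed = as.integer(seed), n_sequences = length(nulls)),
    class = "null_distribution"
  )
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("Null score distribution (", x$method, ", ", x$replicates,
      " replicate(s), seed ", x$seed, ")\n  ", length(x$values),
      " positive-score windows of ", x$n_windows, " scanned\n", sep = "")
  invisible(x)
}

#' Paired real/null histogram of normalized scores
#'
#' Bins both samples over `(0, 1]` with shared edges and reports the
#' proportion of each sample per bin (each column sums to 1).
#'
#' @param real_scores,null_scores Nonempty numeric vectors of normalized
#'   scores in `(0, 1]` (a `null_distribution` is accepted for either).
#' @param bins Numeric vector of bin edges spanning `[0, 1]` (default 20
#'   bins of width 0.05).
#' @return `data.frame` with `bin_lower`, `bin_upper`, `real_density`,
#'   `null_density`.
#' @export
score_histograms <- function(real_scores, null_scores, bins = seq(0, 1, by = 0.05)) {
  if (inherits(real_scores, "null_distribution")) real_scores <- real_scores$values
  if (inherits(null_scores, "null_distribution")) null_scores <- null_scores$values
  if (!length(real_scores) || !length(null_scores))
    stop("both score samples must be nonempty")
  bins <- sort(unique(bins))
  if (length(bins) < 2) stop("need at least two bin edges")
  prop <- function(x) {
    cts <- tabulate(findInterval(x, bins, left.open = TRUE, all.inside = TRUE),
                    nbins = length(bins) - 1L)
    cts / length(x)
  }
  data.frame(bin_lower = bins[-length(bins)], bin_upper = bins[-1],
             real_density = prop(real_scores), null_density = prop(null_scores))
}

#' Select a normalized-score threshold from an empirical null
#'
#' Chooses the smallest threshold on a fixed grid whose null
#' false-positive rate — the fraction of the null normalized-score sample at
#' or above the threshold — does not exceed `target_fpr`. Also reports the
#' empirical null FPR and real hit rate at a fixed reference threshold (0.8
#' by default) for comparison with a pre-set cutoff.
#'
#' Rates are fractions of the normalized-score samples, i.e. of the windows
#' with positive raw score: the candidates that survive the selection rule
#' and could become calls.
#'
#' @param real_scores Normalized scores from the real promoters (vector, or
#'   anything [normalized_score_sample()] returns).
#' @param null_scores A `null_distribution`, or a numeric vector of null
#'   normalized scores (then the vector length is the denominator).
#' @param target_fpr Target per-window false-positive rate in `(0, 1)`.
#' @param grid_step Threshold grid spacing (default 0.005).
#' @param reference_threshold Fixed cutoff to report rates at (default 0.8).
#' @return Object of class `threshold_report`: list with `threshold`
#'   (`NA` when even a threshold of 1 exceeds `target_fpr` — a sentinel, with
#'   `attainable = FALSE` and a `diagnostic` message), `target_fpr`,
#'   `fpr_at_threshold`, `real_rate_at_threshold`, `fpr_at_reference`,
#'   `real_rate_at_reference`, `reference_threshold`, `no_enrichment` flag
#'   (real rate not above null FPR at the selected threshold), `grid_step`,
#'   and null metadata when available.
#' @export
select_threshold <- function(real_scores, null_scores, target_fpr = 0.01,
                             grid_step = 0.005, reference_threshold = 0.8) {
  if (!is.numeric(target_fpr) || length(target_fpr) != 1 ||
      target_fpr <= 0 || target_fpr >= 1)
    stop("target_fpr must be a single number in (0, 1)")
  null_meta <- NULL
  if (inherits(null_scores, "null_distribution")) {
    null_meta <- null_scores[c("method", "replicates", "seed")]
    null_vals <- null_scores$values
  } else {
    null_vals <- as.numeric(null_scores)
  }
  n_null <- length(null_vals)
  real_vals <- as.numeric(real_scores)
  n_real <- length(real_vals)
  if (!n_null || !n_real) stop("both score samples must be nonempty")

  grid <- round(seq(grid_step, 1, by = grid_step), 10)
  if (grid[length(grid)] < 1) grid <- c(grid, 1)
  fpr <- vapply(grid, function(t) sum(null_vals >= t) / n_null, numeric(1))
  rate_real <- function(t) sum(real_vals >= t) / n_real
  rate_null <- function(t) sum(null_vals >= t) / n_null

  ok <- which(fpr <= target_fpr)
  if (!length(ok)) {
    res <- list(threshold = NA_real_, attainable = FALSE,
                diagnostic = sprintf(
                  "even a threshold of 1 has null FPR %.3g > target %.3g",
                  fpr[length(fpr)], target_fpr))
  } else {
    t_sel <- grid[ok[1]]
    res <- list(threshold = t_sel, attainable = TRUE, diagnostic = NA_character_)
  }
  t_eval <- if (isTRUE(res$attainable)) res$threshold else 1
  res <- c(res, list(
    target_fpr = target_fpr,
    fpr_at_threshold = rate_null(t_eval),
    real_rate_at_threshold = rate_real(t_eval),
    fpr_at_reference = rate_null(reference_threshold),
    real_rate_at_reference = rate_real(reference_threshold),
    reference_threshold = reference_threshold,
    no_enrichment = rate_real(t_eval) <= rate_null(t_eval) + 1e-12,
    grid_step = grid_step,
    n_real_windows = n_real,
    n_null_windows = n_null))
  if (!is.null(null_meta)) res$null <- null_meta
  structure(res, class = "threshold_report")
}

#' @export
print.threshold_report <- function(x, ...) {
  if (isTRUE(x$attainable)) {
    cat("Selected threshold: ", x$threshold,
        " (null FPR ", signif(x$fpr_at_threshold, 3),
        " <= target ", x$target_fpr, ")\n", sep = "")
  } else {
    cat("No attainable threshold: ", x$diagnostic, "\n", sep = "")
  }
  cat("At reference ", x$reference_threshold, ": null FPR ",
      signif(x$fpr_at_reference, 3), ", real hit rate ",
      signif(x$real_rate_at_reference, 3), "\n", sep = "")
  if (isTRUE(x$no_enrichment))
    cat("Note: real hit rate does not exceed the null at the selected threshold",
        "(no enrichment)\n")
  invisible(x)
}

#' Write calibration outputs
#'
#' `write_histogram_tsv()` writes a [score_histograms()] table;
#' `write_threshold_json()` serializes a `threshold_report`.
#'
#' @param x The object to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_histogram_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_histogram_tsv
#' @export
write_threshold_json <- function(x, path) {
  stopifnot(inherits(x, "threshold_report"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
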