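# Both-strand PWM scanning, Score/MaxScore normalization, site calling and
# per-gene sense/antisense site maps.

#' Score every window of a sequence on both strands
#'
#' Slides the scoring matrix over the sequence (sense) and its opposite
#' strand (antisense, implemented as a reverse-complement-matrix scan of the
#' same sequence, so both strands share promoter coordinates). Offsets are
#' 0-based window starts in the 5'->3' promoter orientation. Windows
#' containing `N` score `NA` (unscorable).
#'
#' @param region A promoter: either a single character string, or a one-row
#'   `promoter_set` slice / list with a `sequence` element.
#' @param m A `scoring_matrix`.
#' @return A `data.frame` with columns `offset` (0-based), `sense`,
#'   `antisense` (raw scores in bits, `NA` where unscorable); zero rows when
#'   the sequence is shorter than the matrix width.
#' @export
scan_sequence <- function(region, m) {
  stopifnot(inherits(m, "scoring_matrix"))
  seq <- if (is.character(region) && length(region) == 1) region
         else if (!is.null(region$sequence)) as.character(region$sequence[1])
         else stop("region must be a sequence string or carry a 'sequence' field")
  w <- m$width
  idx <- encode_dna(seq)
  chars_ok <- !is.na(idx) | strsplit(toupper(seq), "")[[1]] == "N"
  if (nchar(seq) && !all(chars_ok))
    stop("sequence contains non-ACGTN characters")
  n_off <- length(idx) - w + 1L
  if (n_off < 1L)
    return(data.frame(offset = integer(0), sense = numeric(0), antisense = numeric(0)))
  rc <- reverse_complement_matrix(m)
  sense <- numeric(n_off)
  anti <- numeric(n_off)
  for (p in seq_len(w)) {
    b <- idx[p:(p + n_off - 1L)]
    sense <- sense + m$cells[cbind(b, p)]
    anti <- anti + rc$cells[cbind(b, p)]
  }
  data.frame(offset = 0:(n_off - 1L), sense = sense, antisense = anti)
}

#' Call sites from per-window scores
#'
#' Applies the selection and normalization rules: raw log2-odds scores
#' greater than zero are normalized by the matrix maximum
#' (`normalized = raw / max_score`) and kept when the normalized score
#' reaches `threshold`. Overlapping and nested hits are all retained. Hits
#' are ordered by offset, sense before antisense at ties.
#'
#' @param scores A data frame from [scan_sequence()].
#' @param m The `scoring_matrix` used to produce `scores` (supplies
#'   `max_score`).
#' @param threshold Normalized-score cutoff in `(0, 1]` (default 0.8).
#' @param gene_id Gene identifier stamped onto the hits.
#' @return A `data.frame` of site hits: `gene_id`, `offset` (0-based),
#'   `strand_label` (`"sense"`/`"antisense"`), `raw_score`,
#'   `normalized_score`.
#' @export
call_sites <- function(scores, m, threshold = 0.8, gene_id = NA_character_) {
  stopifnot(inherits(m, "scoring_matrix"))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      is.na(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must be a single number in (0, 1]")
  empty <- data.frame(gene_id = character(0), offset = integer(0),
                      strand_label = character(0), raw_score = numeric(0),
                      normalized_score = numeric(0))
  if (!nrow(scores) || m$max_score <= 0) return(empty)
  pick <- function(raw, label) {
    keep <- which(!is.na(raw) & raw > 0 & raw / m$max_score >= threshold)
    data.frame(gene_id = rep(gene_id, length(keep)),
               offset = scores$offset[keep],
               strand_label = rep(label, length(keep)),
               raw_score = raw[keep],
               normalized_score = raw[keep] / m$max_score)
  }
  hits <- rbind(pick(scores$sense, "sense"), pick(scores$antisense, "antisense"))
  hits <- hits[order(hits$offset, match(hits$strand_label, c("sense", "antisense"))), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Summarize hits into a per-gene sense/antisense site map
#'
#' One row per input gene (zero-hit genes included), with counts by strand
#' label — the per-promoter occurrence table conventionally drawn as rows of
#' sense/antisense dots.
#'
#' @param hits A hit data frame (from [call_sites()] or [scan_promoters()]).
#' @param gene_ids Character vector defining the rows and their order; every
#'   hit's `gene_id` must appear here (an orphan hit is an error).
#' @return A `data.frame`: `gene_id`, `sense_count`, `antisense_count`,
#'   `total`.
#' @export
summarize_site_map <- function(hits, gene_ids) {
  gene_ids <- as.character(gene_ids)
  orphan <- setdiff(unique(hits$gene_id), gene_ids)
  if (length(orphan))
    stop("hit(s) for gene(s) absent from gene_ids: ", paste(orphan, collapse = ", "))
  tab <- function(label) {
    h <- hits[hits$strand_label == label, , drop = FALSE]
    as.integer(table(factor(h$gene_id, levels = gene_ids)))
  }
  out <- data.frame(gene_id = gene_ids,
                    sense_count = tab("sense"),
                    antisense_count = tab("antisense"))
  out$total <- out$sense_count + out$antisense_count
  out
}

#' Scan a promoter set for motif sites
#'
#' The package's central fitting-style function: scores every promoter on
#' both strands, applies the `Score/MaxScore` normalization and the
#' normalized-score threshold, and assembles per-gene sense/antisense site
#' counts. Returns a classed object with `print`, `summary`,
#' `as.data.frame` and `plot` methods.
#'
#' @param promoters A `promoter_set` data frame (see
#'   [extract_upstream_regions()], [read_promoter_fasta()],
#'   [generate_study_like_set()]), or a named character vector of sequences.
#' @param matrix A [frequency_matrix()] or prebuilt `scoring_matrix`.
#' @param threshold Normalized-score cutoff in `(0, 1]` (default 0.8).
#' @param pseudocount,background Passed to [build_scoring_matrix()] when
#'   `matrix` is a frequency matrix.
#' @return An object of class `site_scan`: list with `hits` (site table),
#'   `site_map` (per-gene counts), `matrix` (the `scoring_matrix` used),
#'   `threshold`, `promoters` (the input metadata without sequences).
#' @examples
#' study <- generate_study_like_set(n_genes = 4, seed = 7)
#' fit <- scan_promoters(study$promoters, crz1_like_freqs())
#' summary(fit)
#' @export
scan_promoters <- function(promoters, matrix, threshold = 0.8,
                           pseudocount = 0.01,
                           background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (is.character(promoters)) {
    ids <- names(promoters)
    if (is.null(ids)) ids <- sprintf("seq%03d", seq_along(promoters))
    promoters <- data.frame(gene_id = ids, sequence = unname(promoters),
                            stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(promoters), all(c("gene_id", "sequence") %in% names(promoters)))
  m <- if (inherits(matrix, "scoring_matrix")) matrix
       else build_scoring_matrix(matrix, pseudocount = pseudocount, background = background)
  hit_list <- lapply(seq_len(nrow(promoters)), function(i) {
    sc <- scan_sequence(promoters$sequence[i], m)
    call_sites(sc, m, threshold = threshold, gene_id = promoters$gene_id[i])
  })
  hits <- do.call(rbind, hit_list)
  if (is.null(hits))
    hits <- data.frame(gene_id = character(0), offset = integer(0),
                       strand_label = character(0), raw_score = numeric(0),
                       normalized_score = numeric(0))
  rownames(hits) <- NULL
  structure(
    list(hits = hits,
         site_map = summarize_site_map(hits, promoters$gene_id),
         matrix = m,
         threshold = threshold,
         promoters = promoters[, setdiff(names(promoters), "sequence"), drop = FALSE]),
    class = "site_scan"
  )
}

#' @export
print.site_scan <- function(x, ...) {
  cat("Promoter motif scan (", nrow(x$site_map), " promoters, matrix '",
      x$matrix$source_id, "', width ", x$matrix$width, ")\n", sep = "")
  cat("  threshold ", x$threshold, " on Score/MaxScore (MaxScore ",
      format(x$matrix$max_score, digits = 4), " bits)\n", sep = "")
  cat("  ", nrow(x$hits), " site(s) in ", sum(x$site_map$total > 0), " promoter(s): ",
      sum(x$site_map$sense_count), " sense, ",
      sum(x$site_map$antisense_count), " antisense\n", sep = "")
  invisible(x)
}

#' @export
summary.site_scan <- function(object, ...) {
  print(object)
  cat("\nPer-gene site map:\n")
  print(object$site_map, row.names = FALSE)
  invisible(object$site_map)
}

#' @export
as.data.frame.site_scan <- function(x, ...) x$hits

#' Plot a per-gene site map
#'
#' Dot-per-site display: one row per promoter, sense sites as filled blue
#' points and antisense sites as orange points, positioned at their promoter
#' offset (0 = distal end of the window, right edge = translation start).
#'
#' @param x A `site_scan` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.site_scan <- function(x, ...) {
  sm <- x$site_map
  n <- nrow(sm)
  width <- max(c(x$hits$offset + x$matrix$width, 1000))
  graphics::plot(NA, xlim = c(0, width), ylim = c(0.5, n + 0.5),
                 yaxt = "n", xlab = "offset in promoter (nt)", ylab = "",
                 main = "Motif sites per promoter", ...)
  graphics::axis(2, at = seq_len(n), labels = rev(sm$gene_id), las = 2, cex.axis = 0.7)
  if (nrow(x$hits)) {
    y <- (n + 1) - match(x$hits$gene_id, sm$gene_id)
    col <- ifelse(x$hits$strand_label == "sense", "#2166ac", "#e08214")
    graphics::points(x$hits$offset, y, pch = 19, col = col)
  }
  graphics::legend("topleft", legend = c("sense", "antisense"),
                   col = c("#2166ac", "#e08214"), pch = 19, bty = "n")
  invisible(x)
}

#' Write hit and site-map tables
#'
#' `write_hits_tsv()` writes the flat hit table; `write_hits_bed()` writes
#' promoter-relative BED (0-based half-open; gene id as chrom) and, when the
#' promoter set carries genomic intervals, genome-projected BED lines
#' alongside; `write_site_map_tsv()`/`write_site_map_json()` write the
#' per-gene count table.
#'
#' @param scan A `site_scan` object.
#' @param path Output path.
#' @param promoters Optional `promoter_set` with genomic intervals for
#'   genome projection.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(scan, path) {
  utils::write.table(scan$hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hits_tsv
#' @export
write_hits_bed <- function(scan, path, promoters = NULL) {
  h <- scan$hits
  w <- scan$matrix$width
  bed <- data.frame(chrom = h$gene_id, start = h$offset, end = h$offset + w,
                    name = h$strand_label,
                    score = as.integer(round(h$normalized_score * 1000)),
                    strand = ifelse(h$strand_label == "sense", "+", "-"))
  if (!is.null(promoters) && all(c("contig", "start", "strand") %in% names(promoters)) &&
      nrow(h) && !all(is.na(promoters$contig))) {
    i <- match(h$gene_id, promoters$gene_id)
    ok <- !is.na(i) & !is.na(promoters$contig[i])
    gstart <- ifelse(promoters$strand[i] == "+",
                     promoters$start[i] - 1L + h$offset,
                     promoters$end[i] - h$offset - w)
    gbed <- data.frame(chrom = promoters$contig[i], start = gstart, end = gstart + w,
                       name = paste0(h$gene_id, ":", h$strand_label),
                       score = bed$score,
                       strand = ifelse((promoters$strand[i] == "+") ==
                                         (h$strand_label == "sense"), "+", "-"))
    bed <- rbind(bed, gbed[ok, , drop = FALSE])
  }
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_hits_tsv
#' @export
write_site_map_tsv <- function(scan, path) {
  utils::write.table(scan$site_map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hits_tsv
#' @export
write_site_map_json <- function(scan, path) {
  sm <- scan$site_map
  obj <- list(
    threshold = scan$threshold,
    matrix = scan$matrix$source_id,
    max_score_bits = scan$matrix$max_score,
    genes = lapply(seq_len(nrow(sm)), function(i) {
      list(gene_id = sm$gene_id[i],
           sense = sm$sense_count[i],
           antisense = sm$antisense_count[i])
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
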