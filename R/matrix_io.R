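# Motif matrix readers/writers: JASPAR counts, MEME minimal probabilities,
# and a canonical JSON serialization.

#' Read a JASPAR-style count matrix
#'
#' Accepts the common JASPAR text dialects: an optional `>ID name` header
#' followed by four rows, either `A [ 4 19 0 ... ]` (bracketed) or plain
#' whitespace-separated counts, one row per base. Counts are normalized
#' column-wise to probabilities.
#'
#' @param path Path to the matrix file.
#' @return A [frequency_matrix()]; `source_id` is taken from the header when
#'   present, otherwise the file name.
#' @export
read_jaspar <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  source_id <- tools::file_path_sans_ext(basename(path))
  if (length(lines) && startsWith(lines[1], ">")) {
    source_id <- trimws(sub("^>", "", lines[1]))
    lines <- lines[-1]
  }
  if (length(lines) < 4)
    stop("JASPAR matrix needs 4 base rows; found ", length(lines))
  rows <- lapply(lines[1:4], function(ln) {
    ln <- gsub("[][]", " ", ln)
    parts <- strsplit(ln, "[[:space:]]+")[[1]]
    parts <- parts[nzchar(parts)]
    base <- NA_character_
    if (toupper(parts[1]) %in% DNA_BASES) {
      base <- toupper(parts[1])
      parts <- parts[-1]
    }
    vals <- suppressWarnings(as.numeric(parts))
    if (anyNA(vals)) stop("could not parse counts in line: ", ln)
    list(base = base, vals = vals)
  })
  bases <- vapply(rows, `[[`, character(1), "base")
  if (all(!is.na(bases))) {
    ord <- match(DNA_BASES, bases)
    if (anyNA(ord)) stop("base labels must cover A, C, G, T")
    rows <- rows[ord]
  }
  counts <- do.call(rbind, lapply(rows, `[[`, "vals"))
  if (length(unique(vapply(rows, function(r) length(r$vals), integer(1)))) != 1)
    stop("rows have differing numbers of positions")
  cs <- colSums(counts)
  if (any(cs <= 0)) stop("column(s) with zero total count: ",
                         paste(which(cs <= 0), collapse = ", "))
  frequency_matrix(sweep(counts, 2, cs, "/"), source_id = source_id)
}

#' Read a MEME minimal-format probability matrix
#'
#' Parses the first motif of a MEME minimal file: the `MOTIF` line, the
#' `letter-probability matrix:` header and its `w=` width, and one row of four
#' probabilities per position. A `background letter frequencies` section, if
#' present, is attached as attribute `"background"`.
#'
#' @param path Path to the MEME minimal file.
#' @return A [frequency_matrix()] (rows A/C/G/T), with optional
#'   `"background"` attribute (named numeric vector).
#' @export
read_meme <- function(path) {
  lines <- readLines(path, warn = FALSE)
  bg <- NULL
  bg_at <- grep("^background letter frequencies", lines)
  if (length(bg_at)) {
    parts <- strsplit(trimws(lines[bg_at[1] + 1]), "[[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    bg <- stats::setNames(vals[!is.na(vals)], toupper(parts[is.na(vals)]))
    bg <- bg[DNA_BASES]
  }
  motif_at <- grep("^MOTIF", lines)
  if (!length(motif_at)) stop("no MOTIF line found in ", path)
  name <- trimws(sub("^MOTIF", "", lines[motif_at[1]]))
  hdr_at <- grep("^letter-probability matrix:", lines)
  hdr_at <- hdr_at[hdr_at > motif_at[1]][1]
  if (is.na(hdr_at)) stop("no letter-probability matrix header after MOTIF")
  w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr_at]))
  if (is.na(w)) stop("could not parse motif width from: ", lines[hdr_at])
  body <- lines[(hdr_at + 1):(hdr_at + w)]
  probs <- t(vapply(body, function(ln) {
    vals <- as.numeric(strsplit(trimws(ln), "[[:space:]]+")[[1]])
    if (length(vals) != 4 || anyNA(vals)) stop("bad probability row: ", ln)
    vals
  }, numeric(4), USE.NAMES = FALSE))
  # MEME rows are positions, columns A C G T; renormalize rounded rows
  probs <- sweep(probs, 1, rowSums(probs), "/")
  fm <- frequency_matrix(t(probs), source_id = if (nzchar(name)) name else basename(path))
  if (!is.null(bg) && !anyNA(bg)) attr(fm, "background") <- bg
  fm
}

#' Write / read the canonical JSON matrix serialization
#'
#' The package's internal interchange format: a JSON object with `width`,
#' `alphabet`, per-position probability `columns`, `source_id`, and
#' optionally a `background` vector.
#'
#' @param freqs A [frequency_matrix()].
#' @param path Output (or input) file path.
#' @param background Optional named background vector to embed.
#' @return `write_matrix_json()` returns `path` invisibly; `read_matrix_json()`
#'   returns a [frequency_matrix()].
#' @export
write_matrix_json <- function(freqs, path, background = NULL) {
  stopifnot(inherits(freqs, "frequency_matrix"))
  obj <- list(
    width = freqs$width,
    alphabet = DNA_BASES,
    columns = lapply(seq_len(freqs$width), function(j) unname(freqs$probs[, j])),
    source_id = freqs$source_id
  )
  if (!is.null(background)) obj$background <- unname(check_background(background))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_matrix_json
#' @export
read_matrix_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  probs <- if (is.list(obj$columns)) do.call(cbind, obj$columns) else t(obj$columns)
  rownames(probs) <- DNA_BASES
  fm <- frequency_matrix(probs, source_id = obj$source_id %||% "json")
  if (!is.null(obj$background))
    attr(fm, "background") <- stats::setNames(obj$background, DNA_BASES)
  fm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a motif matrix, dispatching on format
#'
#' Sniffs the file content: JSON (`{`), MEME minimal (`MEME version` or
#' `letter-probability matrix`), otherwise JASPAR-style counts.
#'
#' @param path Path to a matrix file.
#' @param format One of `"auto"`, `"jaspar"`, `"meme"`, `"json"`.
#' @return A [frequency_matrix()].
#' @export
read_motif_matrix <- function(path, format = c("auto", "jaspar", "meme", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("matrix file not found: ", path)
  if (format == "auto") {
    head <- paste(readLines(path, n = 20, warn = FALSE), collapse = "\n")
    format <- if (grepl("^\\s*\\{", head)) "json"
              else if (grepl("MEME version|letter-probability matrix", head)) "meme"
              else "jaspar"
  }
  switch(format,
         jaspar = read_jaspar(path),
         meme = read_meme(path),
         json = read_matrix_json(path))
}
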