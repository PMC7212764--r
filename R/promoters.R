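# Strand-aware extraction of fixed-length upstream regulatory regions.

#' Extract upstream regulatory regions (promoters) for a set of genes
#'
#' For each requested gene, takes the `window` bases immediately upstream of
#' the translation start (the annotated CDS start on the gene's strand,
#' excluding the ATG itself) and returns the sequence in 5'->3' gene
#' orientation (reverse-complemented for minus-strand genes). When a gene has
#' several mRNAs, the 5'-most CDS start on the gene's strand anchors the
#' window; when no CDS is annotated, the gene feature's own start is used.
#' Regions running off the contig edge are truncated and flagged, never
#' silently padded.
#'
#' Genomic coordinates in the result are 1-based inclusive (GFF3 convention);
#' [write_regions_bed()] converts to 0-based half-open.
#'
#' @param genome A `Biostrings::DNAStringSet` or path to a FASTA file.
#' @param annotations A `GenomicRanges::GRanges` (as returned by
#'   `rtracklayer::import`) or path to a GFF3 file.
#' @param gene_ids Character vector of gene IDs (matched against the `ID`
#'   attribute of `gene` features, falling back to `gene_id`/`Name`).
#' @param window Upstream window length in bases (default 1000).
#' @return A `data.frame` of class `promoter_set`, one row per requested gene
#'   in input order: `gene_id`, `contig`, `start`, `end`, `strand`,
#'   `length`, `truncated`, `sequence`.
#' @examples
#' \dontrun{
#' proms <- extract_upstream_regions("genome.fa", "genes.gff3",
#'                                   c("gene1", "gene2"), window = 1000)
#' }
#' @export
extract_upstream_regions <- function(genome, annotations, gene_ids, window = 1000L) {
  if (!is.numeric(window) || length(window) != 1 || window < 1)
    stop("window must be a single positive integer")
  window <- as.integer(window)
  gene_ids <- as.character(gene_ids)

  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  stopifnot(methods::is(genome, "DNAStringSet"))
  # FASTA headers may carry descriptions; key on the first word
  names(genome) <- sub("\\s.*$", "", names(genome))

  if (is.character(annotations)) annotations <- rtracklayer::import(annotations)
  stopifnot(methods::is(annotations, "GRanges"))

  anchors <- resolve_cds_anchors(annotations, gene_ids)

  rows <- lapply(seq_along(gene_ids), function(k) {
    a <- anchors[[k]]
    if (!a$contig %in% names(genome))
      stop("contig '", a$contig, "' (gene ", a$gene_id, ") not present in genome")
    clen <- length(genome[[a$contig]])
    if (a$strand == "+") {
      end <- a$anchor - 1L
      start <- a$anchor - window
      truncated <- start < 1L
      start <- max(start, 1L)
      empty <- end < start
    } else {
      start <- a$anchor + 1L
      end <- a$anchor + window
      truncated <- end > clen
      end <- min(end, clen)
      empty <- end < start
    }
    if (empty) {
      seq <- ""
      len <- 0L
      start <- a$anchor
      end <- a$anchor - 1L  # degenerate, zero-width
      truncated <- TRUE
    } else {
      sub <- Biostrings::subseq(genome[[a$contig]], start, end)
      if (a$strand == "-") sub <- Biostrings::reverseComplement(sub)
      seq <- as.character(sub)
      len <- end - start + 1L
    }
    data.frame(gene_id = a$gene_id, contig = a$contig,
               start = start, end = end, strand = a$strand,
               length = len, truncated = truncated, sequence = seq,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("promoter_set", "data.frame")
  out
}

# For each gene id, locate its translation-start anchor: the 5'-most CDS
# start on the gene's strand (gene feature start as fallback).
resolve_cds_anchors <- function(gr, gene_ids) {
  md <- S4Vectors::mcols(gr)
  feat_id <- if ("ID" %in% names(md)) as.character(md$ID) else rep(NA_character_, length(gr))
  type <- as.character(md$type)
  genes_at <- which(type == "gene")
  gene_key <- feat_id[genes_at]
  if ("gene_id" %in% names(md)) {
    alt <- as.character(md$gene_id)[genes_at]
    gene_key[is.na(gene_key)] <- alt[is.na(gene_key)]
  }
  if ("Name" %in% names(md)) {
    alt <- as.character(md$Name)[genes_at]
    gene_key[is.na(gene_key)] <- alt[is.na(gene_key)]
  }
  missing <- setdiff(gene_ids, gene_key)
  if (length(missing))
    stop("gene id(s) not found in annotation: ", paste(missing, collapse = ", "))

  parents <- if ("Parent" %in% names(md)) md$Parent else NULL
  parent1 <- if (is.null(parents)) rep(NA_character_, length(gr))
             else vapply(as.list(parents), function(p) if (length(p)) as.character(p[1]) else NA_character_, character(1))

  lapply(gene_ids, function(gid) {
    gi <- genes_at[match(gid, gene_key)]
    contig <- as.character(GenomicRanges::seqnames(gr))[gi]
    strand <- as.character(GenomicRanges::strand(gr))[gi]
    if (!strand %in% c("+", "-"))
      stop("gene ", gid, " has no usable strand ('", strand, "')")
    # children: mRNAs parented to the gene; CDS parented to those or directly
    mrna_ids <- feat_id[type %in% c("mRNA", "transcript") & !is.na(parent1) & parent1 == feat_id[gi]]
    cds_at <- which(type == "CDS" & !is.na(parent1) &
                      (parent1 == feat_id[gi] | parent1 %in% mrna_ids))
    if (length(cds_at)) {
      anchor <- if (strand == "+") min(GenomicRanges::start(gr)[cds_at])
                else max(GenomicRanges::end(gr)[cds_at])
    } else {
      anchor <- if (strand == "+") GenomicRanges::start(gr)[gi]
                else GenomicRanges::end(gr)[gi]
    }
    list(gene_id = gid, contig = contig, strand = strand, anchor = as.integer(anchor))
  })
}

#' Read promoters from a FASTA file
#'
#' Accepts FASTA produced by [write_promoter_fasta()] (headers
#' `gene_id|contig:start-end(strand)`) or any FASTA whose record names serve
#' as gene ids.
#'
#' @param path FASTA file path.
#' @return A `promoter_set` data frame (genomic columns `NA` when the header
#'   carries no interval).
#' @export
read_promoter_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  hdr <- names(ss)
  m <- regmatches(hdr, regexec("^([^|]+)\\|([^:]+):(\\d+)-(\\d+)\\(([-+])\\)", hdr))
  rows <- lapply(seq_along(ss), function(i) {
    g <- m[[i]]
    if (length(g) == 6) {
      data.frame(gene_id = g[2], contig = g[3],
                 start = as.integer(g[4]), end = as.integer(g[5]), strand = g[6],
                 length = Biostrings::width(ss)[i], truncated = NA,
                 sequence = as.character(ss[[i]]), stringsAsFactors = FALSE)
    } else {
      data.frame(gene_id = sub("\\s.*$", "", hdr[i]), contig = NA_character_,
                 start = NA_integer_, end = NA_integer_, strand = NA_character_,
                 length = Biostrings::width(ss)[i], truncated = NA,
                 sequence = as.character(ss[[i]]), stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("promoter_set", "data.frame")
  out
}

#' Write promoters to FASTA / genomic intervals to BED
#'
#' FASTA headers are `gene_id|contig:start-end(strand)` (1-based inclusive);
#' the BED file is 0-based half-open with the truncation flag in the score
#' column position left as 0 and the name column carrying the gene id.
#'
#' @param promoters A `promoter_set` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_promoter_fasta <- function(promoters, path) {
  has_iv <- if (is.null(promoters$contig)) rep(FALSE, nrow(promoters))
            else !is.na(promoters$contig)
  hdr <- promoters$gene_id
  if (any(has_iv))
    hdr[has_iv] <- sprintf("%s|%s:%d-%d(%s)",
                           promoters$gene_id[has_iv], promoters$contig[has_iv],
                           promoters$start[has_iv], promoters$end[has_iv],
                           promoters$strand[has_iv])
  ss <- Biostrings::DNAStringSet(promoters$sequence)
  names(ss) <- hdr
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname write_promoter_fasta
#' @export
write_regions_bed <- function(promoters, path) {
  keep <- if (is.null(promoters$contig)) rep(FALSE, nrow(promoters))
          else !is.na(promoters$contig) & promoters$length > 0
  bed <- data.frame(chrom = promoters$contig[keep],
                    start = promoters$start[keep] - 1L,
                    end = promoters$end[keep],
                    name = promoters$gene_id[keep],
                    score = 0L,
                    strand = promoters$strand[keep])
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
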