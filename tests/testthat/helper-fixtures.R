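# Shared fixtures and independent oracles used across the suite.

# Random column-normalized frequency matrix of a given width.
random_freqs <- function(width, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- matrix(stats::runif(4 * width, min = 0.01), nrow = 4)
  frequency_matrix(sweep(p, 2, colSums(p), "/"),
                   source_id = paste0("random-", width))
}

# Independent reverse complement (no package code).
oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# Brute-force both-strand re-scorer: extracts every window and scores it
# through score_window with the sense and reverse-complement matrices.
oracle_scan <- function(seq, m) {
  w <- m$width
  n_off <- nchar(seq) - w + 1L
  if (n_off < 1L)
    return(data.frame(offset = integer(0), sense = numeric(0), antisense = numeric(0)))
  rc <- reverse_complement_matrix(m)
  windows <- vapply(0:(n_off - 1L), function(j) substr(seq, j + 1L, j + w), character(1))
  data.frame(offset = 0:(n_off - 1L),
             sense = vapply(windows, function(x) score_window(m, x), numeric(1), USE.NAMES = FALSE),
             antisense = vapply(windows, function(x) score_window(rc, x), numeric(1), USE.NAMES = FALSE))
}

# Independent dinucleotide count vector over the 16 ordered pairs.
oracle_dinuc_counts <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  if (length(chars) < 2) return(table(factor(character(0), levels = "AA")))
  pairs <- paste0(chars[-length(chars)], chars[-1])
  lv <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0))
  table(factor(pairs, levels = lv))
}

random_dna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob), collapse = "")
}

# Toy two-contig genome + GFF3 annotation written to dir; plants `word`
# immediately upstream of a + gene and a - gene. Returns paths and truth.
write_toy_genome <- function(dir, word = "GAGGCTCA", seed = 99) {
  set.seed(seed)
  chr1 <- strsplit(random_dna(3000), "")[[1]]
  # + strand gene with CDS start 1501: upstream window 501..1500; plant word
  # ending at 1500 (immediately upstream of the ATG)
  w <- nchar(word)
  chr1[(1501 - w):1500] <- strsplit(word, "")[[1]]
  # - strand gene with CDS end 1500 on chr2: upstream is 1501..2500
  # (reverse-complemented); plant so the extracted sense sequence ends with
  # `word` at its 3' end, i.e. genomic revcomp(word) at 1501..1500+w
  chr2 <- strsplit(random_dna(3000), "")[[1]]
  chr2[1501:(1500 + w)] <- strsplit(oracle_revcomp(word), "")[[1]]
  fasta <- file.path(dir, "toy_genome.fa")
  writeLines(c(">chr1", paste(chr1, collapse = ""),
               ">chr2", paste(chr2, collapse = "")), fasta)
  gff <- file.path(dir, "toy_genes.gff3")
  lines <- c(
    "##gff-version 3",
    "chr1\ttoy\tgene\t1501\t2400\t.\t+\t.\tID=gplus",
    "chr1\ttoy\tmRNA\t1501\t2400\t.\t+\t.\tID=gplus.t1;Parent=gplus",
    "chr1\ttoy\tCDS\t1501\t2400\t.\t+\t0\tID=gplus.c1;Parent=gplus.t1",
    # two isoforms: CDS starts 1600 and 1550; the 5'-most (1550) anchors
    "chr1\ttoy\tgene\t1550\t2600\t.\t+\t.\tID=giso",
    "chr1\ttoy\tmRNA\t1550\t2600\t.\t+\t.\tID=giso.t1;Parent=giso",
    "chr1\ttoy\tCDS\t1600\t2600\t.\t+\t0\tID=giso.c1;Parent=giso.t1",
    "chr1\ttoy\tmRNA\t1550\t2600\t.\t+\t.\tID=giso.t2;Parent=giso",
    "chr1\ttoy\tCDS\t1550\t2500\t.\t+\t0\tID=giso.c2;Parent=giso.t2",
    "chr1\ttoy\tgene\t1\t900\t.\t+\t.\tID=gedge",
    "chr1\ttoy\tmRNA\t1\t900\t.\t+\t.\tID=gedge.t1;Parent=gedge",
    "chr1\ttoy\tCDS\t1\t900\t.\t+\t0\tID=gedge.c1;Parent=gedge.t1",
    "chr1\ttoy\tgene\t300\t1200\t.\t+\t.\tID=gnear",
    "chr1\ttoy\tmRNA\t300\t1200\t.\t+\t.\tID=gnear.t1;Parent=gnear",
    "chr1\ttoy\tCDS\t400\t1200\t.\t+\t0\tID=gnear.c1;Parent=gnear.t1",
    "chr2\ttoy\tgene\t600\t1500\t.\t-\t.\tID=gminus",
    "chr2\ttoy\tmRNA\t600\t1500\t.\t-\t.\tID=gminus.t1;Parent=gminus",
    "chr2\ttoy\tCDS\t600\t1500\t.\t-\t0\tID=gminus.c1;Parent=gminus.t1"
  )
  writeLines(lines, gff)
  list(fasta = fasta, gff = gff, word = word,
       chr1 = paste(chr1, collapse = ""), chr2 = paste(chr2, collapse = ""))
}
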