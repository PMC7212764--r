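test_that("sequences shorter than the matrix width yield no admissible offsets", {
  sm <- build_scoring_matrix(crz1_like_freqs())
  expect_equal(nrow(scan_sequence("GAGG", sm)), 0L)
  expect_equal(nrow(scan_sequence("", sm)), 0L)
})

test_that("a consensus-word sequence scores max at its single sense offset", {
  sm <- build_scoring_matrix(crz1_like_freqs())
  sc <- scan_sequence(consensus_word(sm), sm)
  expect_equal(nrow(sc), 1L)
  expect_equal(sc$sense, max_score(sm))
  expect_lt(sc$antisense, max_score(sm))
})

test_that("the scanner agrees exactly with the window-by-window oracle", {
  set.seed(1234)
  for (rep in 1:12) {
    width <- sample(4:12, 1)
    m <- build_scoring_matrix(random_freqs(width))
    len <- sample(20:600, 1)
    seq <- random_dna(len)
    # sprinkle Ns into a few sequences to exercise unscorable windows
    if (rep %% 3 == 0) {
      pos <- sample(len, 3)
      for (p in pos) substr(seq, p, p) <- "N"
    }
    expect_equal(scan_sequence(seq, m), oracle_scan(seq, m), tolerance = 1e-12)
  }
})

test_that("call_sites keeps exactly the positive-raw, above-threshold windows", {
  sm <- build_scoring_matrix(crz1_like_freqs())
  study <- generate_study_like_set(n_genes = 3, length = 400, seed = 8)
  for (i in 1:3) {
    seq <- study$promoters$sequence[i]
    sc <- scan_sequence(seq, sm)
    hits <- call_sites(sc, sm, threshold = 0.3, gene_id = study$promoters$gene_id[i])
    # independent reconstruction of the rule
    expect_true(all(hits$raw_score > 0))
    expect_true(all(hits$normalized_score >= 0.3))
    expect_equal(hits$normalized_score, hits$raw_score / max_score(sm))
    for (lbl in c("sense", "antisense")) {
      raw <- if (lbl == "sense") sc$sense else sc$antisense
      want <- sc$offset[!is.na(raw) & raw > 0 & raw / max_score(sm) >= 0.3]
      expect_equal(sort(hits$offset[hits$strand_label == lbl]), sort(want))
    }
  }
})

test_that("threshold 1.0 with one planted consensus word yields exactly that hit", {
  sm <- build_scoring_matrix(crz1_like_freqs())
  counts <- data.frame(sense = 1, antisense = 0)
  study <- generate_study_like_set(n_genes = 1, length = 500,
                                   site_counts = counts, seed = 21)
  sc <- scan_sequence(study$promoters$sequence[1], sm)
  hits <- call_sites(sc, sm, threshold = 1.0, gene_id = "gene01")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$offset, study$truth$offset)
  expect_equal(hits$strand_label, "sense")
  expect_equal(hits$normalized_score, 1)
})

test_that("hit counts are monotone non-increasing in the threshold", {
  sm <- build_scoring_matrix(crz1_like_freqs())
  study <- generate_study_like_set(n_genes = 2, length = 800, seed = 31)
  sc <- scan_sequence(study$promoters$sequence[1], sm)
  grid <- seq(0.05, 1, by = 0.05)
  counts <- vapply(grid, function(t) nrow(call_sites(sc, sm, threshold = t)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(call_sites(sc, sm, threshold = 0), "threshold")
  expect_error(call_sites(sc, sm, threshold = 1.2), "threshold")
})

test_that("site maps cover every gene and reject orphan hits", {
  genes <- sprintf("g%02d", 1:30)
  empty <- data.frame(gene_id = character(0), offset = integer(0),
                      strand_label = character(0), raw_score = numeric(0),
                      normalized_score = numeric(0))
  sm_map <- summarize_site_map(empty, genes)
  expect_equal(nrow(sm_map), 30L)
  expect_true(all(sm_map$sense_count == 0L & sm_map$antisense_count == 0L))
  orphan <- data.frame(gene_id = "ghost", offset = 0L, strand_label = "sense",
                       raw_score = 1, normalized_score = 0.9)
  expect_error(summarize_site_map(orphan, genes), "ghost")
})

test_that("scan_promoters recovers the planted truth table at threshold 1.0", {
  study <- generate_study_like_set(n_genes = 10, length = 1000, seed = 77)
  fit <- scan_promoters(study$promoters, crz1_like_freqs(), threshold = 1.0)
  truth_counts <- summarize_site_map(
    transform(study$truth, raw_score = NA, normalized_score = NA),
    study$promoters$gene_id)
  expect_equal(fit$site_map, truth_counts)
  cmp <- compare_to_truth(fit$hits, study$truth)
  expect_equal(cmp$recall, 1)
  expect_equal(cmp$false_positives, 0L)
  expect_equal(cmp$strand_agreement, 1)
})

test_that("scanning the reverse complement swaps strand labels and mirrors offsets", {
  study <- generate_study_like_set(n_genes = 5, length = 600, seed = 55)
  fm <- crz1_like_freqs()
  sm <- build_scoring_matrix(fm)
  fit_fwd <- scan_promoters(study$promoters, fm, threshold = 0.8)
  rc_proms <- study$promoters
  rc_proms$sequence <- vapply(rc_proms$sequence, oracle_revcomp, character(1),
                              USE.NAMES = FALSE)
  fit_rc <- scan_promoters(rc_proms, fm, threshold = 0.8)
  expect_equal(sum(fit_rc$site_map$total), sum(fit_fwd$site_map$total))
  expect_equal(fit_rc$site_map$sense_count, fit_fwd$site_map$antisense_count)
  expect_equal(fit_rc$site_map$antisense_count, fit_fwd$site_map$sense_count)
  # offsets mirror: j' = L - w - j, with labels exchanged
  L <- nchar(study$promoters$sequence[1])
  w <- sm$width
  key <- function(h, flip) paste(
    h$gene_id,
    if (flip) L - w - h$offset else h$offset,
    if (flip) ifelse(h$strand_label == "sense", "antisense", "sense") else h$strand_label)
  expect_setequal(key(fit_rc$hits, TRUE), key(fit_fwd$hits, FALSE))
})

test_that("site_scan objects print, summarize, plot and export", {
  study <- generate_study_like_set(n_genes = 3, length = 300, seed = 2)
  fit <- scan_promoters(study$promoters, crz1_like_freqs())
  expect_output(print(fit), "Promoter motif scan")
  expect_output(s <- summary(fit), "Per-gene site map")
  expect_s3_class(s, "data.frame")
  expect_identical(as.data.frame(fit), fit$hits)
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
  dir <- withr::local_tempdir()
  write_hits_tsv(fit, file.path(dir, "hits.tsv"))
  got <- read.delim(file.path(dir, "hits.tsv"))
  expect_equal(nrow(got), nrow(fit$hits))
})
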