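test_that("background sampling honors length, composition and seeds", {
  expect_identical(sample_background_sequence(0), "")
  expect_identical(sample_background_sequence(50, c(1, 0, 0, 0)),
                   paste(rep("A", 50), collapse = ""))
  expect_error(sample_background_sequence(10, c(0.5, 0.5, 0.5, -0.5)),
               "composition")
  expect_error(sample_background_sequence(10, c(0.3, 0.3, 0.3, 0.3)),
               "composition")
  a <- sample_background_sequence(200, seed = 4)
  b <- sample_background_sequence(200, seed = 4)
  expect_identical(a, b)
  # base frequencies of a long uniform draw sit within binomial 3 sigma
  s <- sample_background_sequence(1e5, seed = 6)
  chars <- strsplit(s, "")[[1]]
  sigma <- sqrt(0.25 * 0.75 / 1e5)
  for (b in c("A", "C", "G", "T"))
    expect_lt(abs(mean(chars == b) - 0.25), 3 * sigma)
})

test_that("the same seed reproduces the promoter set and truth table exactly", {
  a <- generate_study_like_set(n_genes = 8, length = 500, seed = 13)
  b <- generate_study_like_set(n_genes = 8, length = 500, seed = 13)
  expect_identical(a$promoters, b$promoters)
  expect_identical(a$truth, b$truth)
  c <- generate_study_like_set(n_genes = 8, length = 500, seed = 14)
  expect_false(identical(a$promoters$sequence, c$promoters$sequence))
})

test_that("zero planted sites with a clean background means zero consensus hits", {
  counts <- data.frame(sense = rep(0L, 10), antisense = rep(0L, 10))
  study <- generate_study_like_set(n_genes = 10, length = 1000,
                                   site_counts = counts, seed = 3)
  expect_equal(nrow(study$truth), 0L)
  fit <- scan_promoters(study$promoters, study$matrix, threshold = 1.0)
  expect_equal(nrow(fit$hits), 0L)
})

test_that("without background cleaning, chance consensus hits are classified as false positives", {
  # closed-form expectation: (L - w + 1) * P(word) per strand, summed over
  # strands and genes; with enough sequence some chance hits are near-certain
  counts <- data.frame(sense = rep(0L, 60), antisense = rep(0L, 60))
  study <- generate_study_like_set(n_genes = 60, length = 5000,
                                   site_counts = counts, seed = 101,
                                   clean_background = FALSE)
  expected_chance <- 60 * (5000 - 8 + 1) * 2 * (1 / 4^8)  # ~2.3
  fit <- scan_promoters(study$promoters, study$matrix, threshold = 1.0)
  cmp <- compare_to_truth(fit$hits, study$truth)
  expect_equal(cmp$false_positives, nrow(fit$hits))
  # loose sanity band around the Poisson expectation (not a calibrated test)
  expect_lte(cmp$false_positives, qpois(0.999, expected_chance))
})

test_that("consensus planting is recovered exactly, strands included", {
  study <- generate_study_like_set(n_genes = 30, length = 1000, seed = 22)
  expect_true(all(study$truth$offset >= 0))
  expect_true(all(study$truth$offset <= 1000 - 8))
  # planted intervals never overlap within a gene
  for (g in unique(study$truth$gene_id)) {
    offs <- sort(study$truth$offset[study$truth$gene_id == g])
    if (length(offs) > 1) expect_true(all(diff(offs) >= 8))
  }
  fit <- scan_promoters(study$promoters, study$matrix, threshold = 1.0)
  cmp <- compare_to_truth(fit$hits, study$truth)
  expect_equal(cmp$recall, 1)
  expect_equal(cmp$strand_agreement, 1)
  expect_equal(cmp$false_positives, 0L)
})

test_that("matrix-sampled planting recovers at least the words scoring above threshold", {
  study <- generate_study_like_set(n_genes = 20, length = 1000, seed = 35,
                                   mode = "sample")
  sm <- build_scoring_matrix(study$matrix)
  fit <- scan_promoters(study$promoters, study$matrix, threshold = 0.8)
  # every planted word whose own normalized score reaches 0.8 must be found
  word_pass <- vapply(study$truth$planted_word, function(wd) {
    s <- score_window(sm, wd)
    s > 0 && s / max_score(sm) >= 0.8
  }, logical(1))
  key <- paste(study$truth$gene_id, study$truth$offset, study$truth$strand_label)
  hit_key <- paste(fit$hits$gene_id, fit$hits$offset, fit$hits$strand_label)
  expect_true(all(key[word_pass] %in% hit_key))
  cmp <- compare_to_truth(fit$hits, study$truth)
  expect_gte(cmp$recall, mean(word_pass))
})

test_that("the exact word-pass rate matches a direct enumeration and brackets sampling", {
  fm <- crz1_like_freqs()
  # threshold 1: only the consensus word passes
  expect_equal(planted_word_pass_rate(fm, threshold = 1), 0.85^8,
               tolerance = 1e-9)
  # a very low threshold keeps every positive-scoring word: up to 3 of 8
  # mismatches stay above 0, i.e. P(Binom(8, 0.15) <= 3) plus rounding from
  # the pseudocount
  expect_equal(planted_word_pass_rate(fm, threshold = 1e-3),
               pbinom(3, 8, 0.15), tolerance = 0.02)
  # at 0.8 a single mismatch already drops below threshold: only the
  # consensus word passes
  expect_equal(planted_word_pass_rate(fm, threshold = 0.8), 0.85^8,
               tolerance = 1e-9)
  # independent oracle at width 3: enumerate words by hand
  small <- frequency_matrix(matrix(c(0.7, 0.1, 0.1, 0.1,
                                     0.1, 0.7, 0.1, 0.1,
                                     0.1, 0.1, 0.7, 0.1), nrow = 4),
                            source_id = "small")
  sm <- build_scoring_matrix(small)
  bases <- c("A", "C", "G", "T")
  words <- do.call(paste0, expand.grid(rep(list(bases), 3)))
  probs <- vapply(words, function(wd) {
    ch <- strsplit(wd, "")[[1]]
    prod(small$probs[cbind(match(ch, bases), 1:3)])
  }, numeric(1))
  scores <- vapply(words, function(wd) score_window(sm, wd), numeric(1))
  expect_equal(planted_word_pass_rate(small, threshold = 0.5),
               sum(probs[scores > 0 & scores / max_score(sm) >= 0.5]),
               tolerance = 1e-12)
})

test_that("impossible placements fail loudly", {
  counts <- data.frame(sense = 100L, antisense = 100L)
  expect_error(generate_study_like_set(n_genes = 1, length = 100,
                                       site_counts = counts, seed = 1),
               "cannot place")
})

test_that("fixtures are written as FASTA + TSV and read back", {
  dir <- withr::local_tempdir()
  study <- generate_study_like_set(n_genes = 4, length = 300, seed = 12)
  paths <- write_study_fixtures(study, dir)
  proms <- read_promoter_fasta(paths[["promoters"]])
  expect_identical(proms$sequence, study$promoters$sequence)
  truth <- read.delim(paths[["truth"]])
  expect_equal(nrow(truth), nrow(study$truth))
})
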