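test_that("mononucleotide shuffling preserves length and composition", {
  nulls <- generate_null_set(c(x = "AAACCC"), method = "shuffle_mono",
                             replicates = 5, seed = 3)
  expect_length(nulls, 5L)
  for (s in nulls) {
    expect_equal(nchar(s), 6L)
    tab <- table(strsplit(s, "")[[1]])
    expect_equal(as.integer(tab[c("A", "C")]), c(3L, 3L))
  }
})

test_that("null generation is bit-identical under the same seed", {
  study <- generate_study_like_set(n_genes = 3, length = 200, seed = 9)
  for (method in c("shuffle_mono", "shuffle_di", "iid_background")) {
    a <- generate_null_set(study$promoters, method = method, replicates = 2, seed = 11)
    b <- generate_null_set(study$promoters, method = method, replicates = 2, seed = 11)
    expect_identical(a, b)
    c <- generate_null_set(study$promoters, method = method, replicates = 2, seed = 12)
    expect_false(identical(as.character(a), as.character(c)))
  }
  expect_error(generate_null_set(study$promoters, method = "bogus"), "arg")
  expect_error(generate_null_set(study$promoters, replicates = 0), ">= 1")
})

test_that("dinucleotide shuffles preserve the dinucleotide count vector", {
  set.seed(17)
  sources <- c(random_dna(300),
               random_dna(200, prob = c(0.5, 0.1, 0.1, 0.3)),
               "AAACCCGGGTTTAAACCC",
               paste(rep("AC", 50), collapse = ""))
  nulls <- generate_null_set(sources, method = "shuffle_di",
                             replicates = 3, seed = 29)
  for (k in seq_along(nulls)) {
    src <- sources[(k - 1) %% length(sources) + 1]
    expect_equal(oracle_dinuc_counts(nulls[[k]]), oracle_dinuc_counts(src))
    # Eulerian-path shuffles keep the endpoints
    expect_identical(substr(nulls[[k]], 1, 1), substr(src, 1, 1))
    n <- nchar(src)
    expect_identical(substr(nulls[[k]], n, n), substr(src, n, n))
  }
})

test_that("iid_background controls are length-matched draws from the source composition", {
  src <- paste(c(rep("A", 700), rep("C", 300)), collapse = "")
  nulls <- generate_null_set(src, method = "iid_background",
                             replicates = 20, seed = 5)
  expect_true(all(nchar(nulls) == 1000L))
  freq_a <- mean(vapply(nulls, function(s) {
    mean(strsplit(s, "")[[1]] == "A")
  }, numeric(1)))
  # 20 x 1000 draws at p = 0.7: 3-sigma band
  expect_lt(abs(freq_a - 0.7), 3 * sqrt(0.7 * 0.3 / 20000))
  expect_false(any(grepl("[GT]", nulls)))
})

test_that("score histograms align bins and normalize to unit mass", {
  set.seed(7)
  x <- runif(500, 0.01, 1)
  h <- score_histograms(x, x)
  expect_equal(h$real_density, h$null_density)
  expect_equal(sum(h$real_density), 1, tolerance = 1e-9)
  expect_equal(sum(h$null_density), 1, tolerance = 1e-9)
  expect_error(score_histograms(numeric(0), x), "nonempty")
  expect_error(score_histograms(x, numeric(0)), "nonempty")
})

test_that("planted promoters put histogram mass in the top bin where the null has none", {
  study <- generate_study_like_set(n_genes = 10, length = 1000, seed = 19)
  sm <- build_scoring_matrix(study$matrix)
  real <- normalized_score_sample(study$promoters$sequence, sm)
  nd <- null_distribution(study$promoters, sm, replicates = 2, seed = 23)
  expect_true(all(nd$values > 0 & nd$values <= 1))
  h <- score_histograms(real, nd)
  top <- nrow(h)
  expect_gt(h$real_density[top], 0)
  expect_equal(h$null_density[top], 0)
})

test_that("threshold selection respects separation, monotonicity and sentinel cases", {
  set.seed(3)
  null_low <- runif(2000, 0.05, 0.5)
  real <- c(runif(500, 0.05, 0.5), runif(40, 0.9, 1))
  rep1 <- select_threshold(real, null_low, target_fpr = 0.01)
  expect_true(rep1$attainable)
  expect_lte(rep1$threshold, 0.5 + 0.005)
  expect_lte(rep1$fpr_at_threshold, 0.01)
  # monotone: tighter target never lowers the threshold
  t_prev <- 0
  for (fpr in c(0.2, 0.1, 0.05, 0.01, 0.001)) {
    t_now <- select_threshold(real, null_low, target_fpr = fpr)$threshold
    expect_gte(t_now, t_prev)
    t_prev <- t_now
  }
  # real == null: still controls FPR but flags the absence of enrichment
  rep2 <- select_threshold(null_low, null_low, target_fpr = 0.05)
  expect_true(rep2$no_enrichment)
  expect_lte(rep2$fpr_at_threshold, 0.05)
  # unattainable: all null mass at 1.0
  rep3 <- select_threshold(real, rep(1, 100), target_fpr = 0.05)
  expect_false(rep3$attainable)
  expect_true(is.na(rep3$threshold))
  expect_match(rep3$diagnostic, "target")
  expect_error(select_threshold(real, null_low, target_fpr = 0), "target_fpr")
})

test_that("on a planted study the selected threshold keeps planted sites and controls the null", {
  study <- generate_study_like_set(n_genes = 30, length = 1000, seed = 47)
  sm <- build_scoring_matrix(study$matrix)
  real <- normalized_score_sample(study$promoters$sequence, sm)
  nd <- null_distribution(study$promoters, sm, replicates = 5, seed = 53)
  rep <- select_threshold(real, nd, target_fpr = 0.01)
  expect_true(rep$attainable)
  expect_lte(rep$fpr_at_threshold, 0.01)
  # every planted consensus window scores 1.0 >= the selected threshold
  fit <- scan_promoters(study$promoters, study$matrix, threshold = rep$threshold)
  cmp <- compare_to_truth(fit$hits, study$truth)
  expect_gte(cmp$recall, 0.95)
})
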