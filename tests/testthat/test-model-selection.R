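test_that("confusion metrics match their closed forms and degrade gracefully", {
  perfect <- compute_metrics(tp = 5, fp = 0, tn = 5, fn = 0)
  expect_equal(unlist(perfect),
               c(precision = 1, recall = 1, f_score = 1, mcc = 1))
  m <- compute_metrics(tp = 3, fp = 1, tn = 4, fn = 2)
  expect_equal(m$mcc, 10 / sqrt(600))        # direct formula evaluation
  expect_equal(m$precision, 3 / 4)
  expect_equal(m$recall, 3 / 5)
  expect_equal(m$f_score, 2 * (3 / 4) * (3 / 5) / (3 / 4 + 3 / 5))
  w <- capture_warnings(deg <- compute_metrics(tp = 0, fp = 0, tn = 5,
                                               fn = 3))
  expect_match(w, "degenerate", all = TRUE)
  expect_identical(deg$precision, 0)
  expect_error(compute_metrics(0, 0, 0, 0), "all-zero")
  expect_error(compute_metrics(-1, 0, 1, 0), "negative")
})

test_that("MCC is symmetric under simultaneous label/prediction swap and bounded", {
  set.seed(4)
  for (i in 1:20) {
    cnt <- sample(0:10, 4, replace = TRUE)
    if (sum(cnt) == 0) next
    a <- suppressWarnings(
      compute_metrics(cnt[1], cnt[2], cnt[3], cnt[4]))$mcc
    b <- suppressWarnings(   # swap positive and negative roles
      compute_metrics(cnt[3], cnt[4], cnt[1], cnt[2]))$mcc
    expect_equal(a, b)
    expect_true(a >= -1 && a <= 1)
  }
})

test_that("AUC equals the brute-force pair statistic and is rank-invariant", {
  expect_equal(compute_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 1, 0, 0)), 1)
  expect_equal(compute_auc(rep(0.5, 8), rep(c(0, 1), 4)), 0.5)
  set.seed(11)
  for (i in 1:10) {
    scores <- round(runif(20), 2)   # rounding forces some ties
    labels <- rbinom(20, 1, 0.5)
    if (sum(labels) %in% c(0, 20)) next
    auc <- compute_auc(scores, labels)
    expect_equal(auc, oracle_auc(scores, labels))
    # strictly monotone transform leaves AUC unchanged
    expect_equal(compute_auc(exp(3 * scores) + 1, labels), auc)
  }
  expect_error(compute_auc(1:4, c(1, 1, 1, 1)), "both label values")
})

test_that("bootstrap CV produces the full fold grid with signal-dependent AUC", {
  sim <- separable_sim(seed = 2)
  cfg <- build_encoding_config(sim$records, min_pfam_freq = 5)
  feats <- encode_tf_matrix(sim$records, cfg)
  y <- sim$truth == "P"
  cv <- bootstrap_cv(feats, y, classifier_spec("RF", ntree = 100),
                     n_runs = 10, n_folds = 5, seed = 21)
  expect_identical(nrow(cv), 50L)
  expect_identical(unique(cv$run), 1:10)
  expect_true(all(cv[, c("precision", "recall", "f_score", "auc")] >= 0 &
                    cv[, c("precision", "recall", "f_score", "auc")] <= 1))
  expect_gte(mean(cv$auc), 0.95)   # separable by construction
  # permuted labels destroy the signal
  set.seed(31)
  cv0 <- bootstrap_cv(feats, sample(y), classifier_spec("RF", ntree = 100),
                      n_runs = 4, n_folds = 5, seed = 22)
  expect_lt(abs(mean(cv0$auc) - 0.5), 0.1)
})

test_that("grid-searched classifier families run through bootstrap CV", {
  sim <- separable_sim(seed = 6)
  cfg <- build_encoding_config(sim$records, min_pfam_freq = 5)
  feats <- encode_tf_matrix(sim$records, cfg)
  y <- sim$truth == "S"
  for (fam in c("SVC-linear", "kNN", "GNB")) {
    spec <- classifier_spec(fam)
    cv <- bootstrap_cv(feats, y, spec, n_runs = 2, n_folds = 5, seed = 5)
    expect_identical(nrow(cv), 10L)
    expect_gte(mean(cv$auc), 0.9)
  }
  expect_error(classifier_spec("kNN", grid = list(cost = 1)),
               "not valid")
})

test_that("Wilcoxon comparison matches exact sign-assignment enumeration", {
  expect_warning(p <- wilcoxon_compare(rep(1, 6), rep(1, 6)), "zero")
  expect_identical(p, 1)
  # all-positive differences over 10 pairs: p = 2 / 2^10
  a <- seq(0.6, 0.9, length.out = 10)
  d <- seq(0.01, 0.10, by = 0.01)   # distinct magnitudes keep the test exact
  expect_equal(wilcoxon_compare(a + d, a), 2 / 1024)
  set.seed(13)
  for (n in c(6, 8, 10, 12)) {
    x <- runif(n)
    y <- x + rnorm(n, sd = 0.3)
    expect_equal(wilcoxon_compare(y, x), oracle_signed_rank(y - x))
  }
})

test_that("property importance ranks a planted informative block first", {
  set.seed(17)
  y <- rep(c(TRUE, FALSE), each = 40)
  feats <- make_block_features(y, n_informative = 4, n_noise_blocks = 2,
                               flip = 0.05)
  imp <- property_importance(feats, y, classifier_spec("RF", ntree = 200),
                             n_runs = 3, n_folds = 5, seed = 3)
  expect_identical(imp$property[1], "INFO")
  expect_identical(imp$property[which.max(imp$importance)], "INFO")
  expect_equal(sum(imp$importance), 1)
  expect_gte(imp$mean_auc[imp$property == "INFO"], 0.9)
  noise_auc <- imp$mean_auc[imp$property != "INFO"]
  expect_true(all(abs(noise_auc - 0.5) < 0.12))
  # non-forest family still yields AUCs
  expect_message(
    imp2 <- property_importance(feats, y, classifier_spec("GNB"),
                                n_runs = 2, n_folds = 5, seed = 3),
    "importance unavailable")
  expect_true(all(is.na(imp2$importance)))
  expect_gte(imp2$mean_auc[imp2$property == "INFO"], 0.9)
})

test_that("forward best-first search picks the dominant block and records the full trace", {
  set.seed(23)
  y <- rep(c(TRUE, FALSE), each = 40)
  feats <- make_block_features(y, n_informative = 4, n_noise_blocks = 2,
                               flip = 0.05)
  # single property: trace of length one
  single <- forward_best_first(feats, y, properties = "INFO",
                               spec = classifier_spec("RF", ntree = 150),
                               n_runs = 2, n_folds = 5, seed = 9)
  expect_identical(nrow(single), 1L)
  expect_identical(attr(single, "selected"), "INFO")
  # full search: dominant block first, trace covers every property
  trace <- forward_best_first(feats, y,
                              spec = classifier_spec("RF", ntree = 150),
                              n_runs = 2, n_folds = 5, seed = 9)
  expect_identical(nrow(trace), 3L)
  expect_identical(trace$property[1], "INFO")
  expect_true("INFO" %in% attr(trace, "selected"))
  expect_true(all(!is.na(trace$p_vs_prev[-1])))
})

test_that("adding a redundant copy of the dominant block is not significant", {
  set.seed(29)
  y <- rep(c(TRUE, FALSE), each = 40)
  feats <- make_block_features(y, n_informative = 4, n_noise_blocks = 0,
                               flip = 0.05)
  x2 <- cbind(unclass(feats), unclass(feats)[, 1:4])
  colnames(x2) <- paste0("c", seq_len(ncol(x2)))
  feats2 <- structure(x2, blocks = list(INFO = 1:4, COPY = 5:8),
                      class = c("tf_features", class(x2)))
  trace <- forward_best_first(feats2, y,
                              spec = classifier_spec("RF", ntree = 150),
                              n_runs = 3, n_folds = 5, seed = 9)
  expect_identical(nrow(trace), 2L)
  expect_gt(trace$p_vs_prev[2], 0.05)
})
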