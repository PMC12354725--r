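test_that("the every-fourth split is deterministic with the documented counts", {
  rec <- tiny_records(8, yield = rep(80, 8))
  s <- stratified_split(rec)
  expect_equal(sum(s$split_label == "t"), 6)
  expect_equal(sum(s$split_label == "v"), 2)
  # uniform yields: ordering falls back to original index, so v sits at
  # sorted positions 4 and 8
  expect_equal(which(s$split_label == "v"), c(4L, 8L))

  s3 <- stratified_split(tiny_records(3))
  expect_equal(s3$split_label, rep("t", 3))

  # ties resolved by original index: split is reproducible
  rec2 <- tiny_records(6, yield = c(90, 90, 90, 90, 50, 50))
  expect_identical(stratified_split(rec2)$split_label,
                   stratified_split(rec2)$split_label)
})

test_that("split proportions hold globally and within reaction types", {
  set.seed(41)
  for (n in c(10, 37, 100)) {
    rec <- tiny_records(n, yield = runif(n, 10, 99),
                        rtype = sample(c("suzuki_miyaura", "kumada", "negishi"),
                                       n, TRUE))
    rec$c_8 <- rec$reaction_type
    s <- stratified_split(rec)
    expect_equal(sum(s$split_label == "v"), floor(n / 4))
    for (ty in unique(rec$reaction_type)) {
      nt <- sum(rec$reaction_type == ty)
      if (nt >= 4) {
        nv <- sum(s$split_label == "v" & s$reaction_type == ty)
        expect_lt(abs(nv - nt / 4), 1)
      }
    }
  }
})

test_that("yield binarization follows the strict threshold rule", {
  expect_equal(binarize_yield(c(80, 79, 0), threshold = 79), c(1L, 0L, 0L))
  y <- c(10, 60, 79, 85, 99)
  lab <- binarize_yield(y, threshold = 79)
  expect_equal(sum(lab == 0) + sum(lab == 1), length(y))
  # default threshold is the mean
  expect_equal(binarize_yield(c(10, 90)), c(0L, 1L))
})

test_that("regression metrics match hand arithmetic and stratify by band", {
  m <- regression_metrics(c(70, 90), c(70, 90))
  expect_equal(m$r, 1)
  expect_equal(m$mae, 0)
  m2 <- regression_metrics(c(0, 100), c(100, 0))
  expect_equal(m2$r, -1)
  m3 <- regression_metrics(c(70, 90), c(75, 85))
  expect_equal(m3$mae, 5)
  expect_equal(m3$rmse, 5)
  m4 <- regression_metrics(c(70, 90, 85), c(75, 85, 88), threshold = 79)
  expect_equal(m4$stratified$low$mae, 5)
  expect_equal(m4$stratified$high$n, 2L)
  expect_warning(mz <- regression_metrics(c(5, 5), c(1, 2)))
  expect_true(is.na(mz$r))
  expect_true(m4$mae <= m4$rmse)
})

test_that("rank-statistic AUC equals brute-force pairwise comparison", {
  expect_equal(auc_rank(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(auc_rank(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_equal(auc_rank(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1)), 0.75)
  set.seed(42)
  for (trial in 1:6) {
    n <- sample(10:100, 1)
    lab <- rbinom(n, 1, 0.4)
    if (length(unique(lab)) < 2) next
    pr <- round(runif(n), 2)  # rounding forces ties
    expect_equal(auc_rank(lab, pr), auc_brute(lab, pr))
  }
  expect_warning(expect_true(is.na(auc_rank(rep(1, 5), runif(5)))))
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(43)
  lab <- rbinom(60, 1, 0.5)
  pr <- runif(60)
  expect_equal(auc_rank(lab, pr),
               as.numeric(pROC::auc(pROC::roc(lab, pr, quiet = TRUE))))
})

test_that("classification metrics are internally consistent", {
  lab <- c(1, 1, 1, 0, 0, 0, 1, 0)
  pr <- c(0.9, 0.8, 0.3, 0.2, 0.6, 0.1, 0.7, 0.4)
  cm <- classification_metrics(lab, pr)
  expect_equal(sum(cm$confusion), length(lab))
  tp <- cm$confusion["1", "1"]; fn <- cm$confusion["1", "0"]
  tn <- cm$confusion["0", "0"]; fp <- cm$confusion["0", "1"]
  expect_equal(cm$tpr_pct, 100 * tp / (tp + fn))
  expect_equal(cm$tnr_pct, 100 * tn / (tn + fp))
  expect_equal(cm$accuracy, (tp + tn) / 8)
  expect_equal(cm$auc, auc_brute(lab, pr))
  # perfect probabilities
  perf <- classification_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(perf$auc, 1)
  expect_equal(perf$accuracy, 1)
  # ROC endpoints
  expect_equal(cm$roc$tpr[1], 0)
  expect_equal(cm$roc$tpr[nrow(cm$roc)], 1)
  expect_error(classification_metrics(lab, pr * 2), "probabilities")
})

test_that("permutation importance ranks planted signal first", {
  set.seed(44)
  f <- random_features(200, 4, seed = 44)
  y <- 30 + 5 * f$t2 + rnorm(200, sd = 0.5)
  fit <- fit_mlr(f, y)
  imp <- feature_importance(fit, f, y, n_repeats = 10, seed = 3)
  expect_equal(imp$feature[1], "t2")
  # a pure-noise column carries ~zero importance
  noise_imp <- imp$importance[imp$feature == "t4"]
  expect_lt(abs(noise_imp), 0.05)
  imp2 <- feature_importance(fit, f, y, n_repeats = 10, seed = 3)
  expect_identical(imp, imp2)
})
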