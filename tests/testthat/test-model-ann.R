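test_that("architecture codes parse and enforce the family bounds", {
  sp <- network_spec("9:9-20-9-1:1", family = "MLP", task = "regression")
  expect_equal(sp$n_in, 9)
  expect_equal(sp$hidden, c(20L, 9L))
  sp2 <- network_spec("9:9-70-1:1", family = "RBF")
  expect_equal(sp2$hidden, 70L)
  expect_error(network_spec("9:9-21-1:1", family = "MLP"), "capped")
  expect_error(network_spec("9:9-301-1:1", family = "RBF"), "capped")
  expect_error(network_spec("9-20-1", family = "MLP"))
  expect_error(network_spec("9:8-20-1:1", family = "MLP"), "start with A")
})

test_that("the MLP regressor learns a noise-free linear map", {
  f <- random_features(500, 8, seed = 20)
  b <- c(2, -1, 0.5, 1.5, -0.8, 0.3, 1, -2)
  y <- 40 + 0.5 * f$yield_ref +
    drop(as.matrix(f[paste0("t", 1:8)]) %*% b)
  split <- rep(c("t", "t", "t", "v"), length.out = 500)
  spec <- network_spec("9:9-20-9-1:1", family = "MLP", task = "regression")
  reg <- train_regressor(f, y, spec, seed = 3, split = split)
  expect_gte(reg$metrics$r[reg$metrics$subset == "test"], 0.99)

  # input-width contract
  bad <- network_spec("5:5-10-1:1", family = "MLP")
  expect_error(train_regressor(f, y, bad, seed = 1), "inputs")
})

test_that("a constant target trains to a constant prediction", {
  f <- random_features(80, 3, seed = 21)
  y <- rep(55, 80)
  spec <- network_spec("4:4-5-1:1", family = "MLP", task = "regression",
                       epochs = 200)
  reg <- suppressWarnings(train_regressor(f, y, spec, seed = 2))
  expect_lt(reg$metrics$rmse[1], 0.5)
  expect_lt(sd(reg$predictions), 0.5)
})

test_that("training is a pure function of the seed", {
  f <- random_features(120, 4, seed = 22)
  y <- 30 + f$t1 * 3 + rnorm(120)
  spec <- network_spec("5:5-8-1:1", family = "MLP", task = "regression",
                       epochs = 80)
  r1 <- train_regressor(f, y, spec, seed = 9)
  r2 <- train_regressor(f, y, spec, seed = 9)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$predictions, r2$predictions)

  lab <- as.integer(y > median(y))
  csp <- network_spec("5:5-8-1:1", family = "MLP", task = "classification",
                      epochs = 80)
  c1 <- train_classifier(f, lab, csp, seed = 4)
  c2 <- train_classifier(f, lab, csp, seed = 4)
  expect_identical(c1$metrics$train$confusion, c2$metrics$train$confusion)
})

test_that("classifier outputs probabilities and rejects degenerate labels", {
  f <- random_features(100, 4, seed = 23)
  lab <- as.integer(f$t1 + f$t2 > 0)
  spec <- network_spec("5:5-8-1:1", family = "MLP", task = "classification",
                       epochs = 120)
  clf <- train_classifier(f, lab, spec, seed = 1)
  expect_true(all(clf$probabilities >= 0 & clf$probabilities <= 1))
  expect_error(train_classifier(f, rep(1L, 100), spec, seed = 1),
               class = "ptml_degenerate_label_error")
})

test_that("RBF uses the centers/widths/least-squares stages and interpolates", {
  set.seed(24)
  x <- matrix(rnorm(60 * 4), 60, 4)
  y <- sin(x[, 1]) + 0.5 * x[, 2]
  # centers = rows: exact interpolation regime
  full <- rbf_fit(x, y, centers = 60, seed = 5)
  expect_lt(sqrt(mean((predict(full, x) - y)^2)), 1e-6)
  # train error is non-increasing with capacity
  rmse_at <- vapply(c(3, 15, 60), function(k) {
    m <- rbf_fit(x, y, centers = k, seed = 5)
    sqrt(mean((predict(m, x) - y)^2))
  }, double(1))
  expect_true(all(diff(rmse_at) <= 1e-8))
  expect_error(rbf_fit(x, y, centers = 61, seed = 1),
               class = "ptml_config_error")
})

test_that("GRNN and LNN families slot into the same training surface", {
  f <- random_features(150, 3, seed = 25)
  y <- 20 + 0.6 * f$yield_ref + 2 * f$t1 + rnorm(150, sd = 0.5)
  lnn <- train_regressor(f, y, network_spec("4:4-1:1", family = "LNN"),
                         seed = 1)
  expect_gte(lnn$metrics$r[1], 0.99)
  # the linear network is OLS: predictions match fit_mlr
  mlr <- fit_mlr(f, y)
  expect_equal(unname(lnn$predictions), unname(predict(mlr, f)),
               tolerance = 1e-8)
  grnn <- train_regressor(f, y, network_spec("4:4-1:1", family = "GRNN"),
                          seed = 1)
  expect_gte(grnn$metrics$r[1], 0.9)
})

test_that("the per-cycle prevalence reference tracks cohort class rates", {
  rec <- tiny_records(6, cycle = c(0L, 0L, 0L, 1L, 1L, 1L))
  lab <- c(1L, 1L, 0L, 0L, 0L, 1L)
  ref <- reference_class_probability(rec, lab)
  expect_equal(ref, c(2 / 3, 2 / 3, 2 / 3, 1 / 3, 1 / 3, 1 / 3))
})
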