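test_that("OLS recovers a planted linear model and honors the reference", {
  f <- random_features(60, 3, seed = 2)
  y <- 5 + 0.9 * f$yield_ref + 2 * f$t1 - 1.5 * f$t2 + 0.3 * f$t3
  fit <- suppressWarnings(fit_mlr(f, y))  # noise-free: summary() grumbles
  expect_equal(fit$a0, 5, tolerance = 1e-6)
  expect_equal(fit$a1, 0.9, tolerance = 1e-6)
  expect_equal(unname(fit$b), c(2, -1.5, 0.3), tolerance = 1e-6)

  # yields identical to the reference: slope one, everything else zero
  fit2 <- suppressWarnings(fit_mlr(f, f$yield_ref))
  expect_equal(fit2$a0, 0, tolerance = 1e-8)
  expect_equal(fit2$a1, 1, tolerance = 1e-8)
  expect_equal(max(abs(fit2$b)), 0, tolerance = 1e-8)

  # saturated fit: as many parameters as rows interpolates exactly
  f3 <- random_features(3, 1, seed = 3)
  y3 <- c(10, 50, 90)
  fit3 <- suppressWarnings(fit_mlr(f3, y3))
  expect_equal(unname(predict(fit3, f3)), y3, tolerance = 1e-8)
})

test_that("rank-deficient designs raise a singularity error naming the term", {
  f <- random_features(30, 2, seed = 4)
  f$t2 <- 2 * f$t1
  y <- rnorm(30)
  expect_error(fit_mlr(f, y), "t2", class = "ptml_singularity_error")
})

test_that("OLS residuals are orthogonal to the design", {
  f <- random_features(80, 4, seed = 6)
  y <- 3 + 0.8 * f$yield_ref + f$t1 - f$t3 + rnorm(80, sd = 4)
  fit <- fit_mlr(f, y)
  res <- stats::residuals(fit$fit)
  for (cc in c("yield_ref", paste0("t", 1:4))) {
    expect_lt(abs(sum(res * f[[cc]])), 1e-8)
  }
})

test_that("tidy and glance expose coefficients and fit quality", {
  f <- random_features(40, 2, seed = 8)
  y <- 1 + f$yield_ref + 2 * f$t1 + rnorm(40)
  fit <- fit_mlr(f, y)
  td <- tidy(fit)
  expect_equal(td$term[1:2], c("(Intercept)", "yield_ref"))
  expect_true(all(c("estimate", "p.value") %in% names(td)))
  gl <- glance(fit)
  expect_true(gl$r > 0.9)
  expect_true(gl$mae <= gl$rmse)
})

test_that("forward stepwise picks planted signal first and respects bounds", {
  set.seed(10)
  f <- random_features(120, 6, seed = 10)
  y <- 50 + 0.5 * f$yield_ref + 4 * f$t3 + rnorm(120, sd = 1)
  sel <- forward_stepwise(f, y)
  expect_equal(sel[1], "t3")

  # pure noise with a strict entry threshold selects nothing
  ynoise <- rnorm(120, 50, 5)
  expect_length(forward_stepwise(f, ynoise, enter_p = 1e-8), 0)

  expect_lte(length(forward_stepwise(f, y, max_steps = 1)), 1)

  # unbounded entry admits every term, and the fit equals the full fit
  sel_all <- forward_stepwise(f, y, max_steps = 6, enter_p = Inf)
  expect_setequal(sel_all, paste0("t", 1:6))
  fit_sel <- fit_mlr(f, y, terms = sel_all)
  fit_all <- fit_mlr(f, y)
  expect_equal(fit_sel$b[paste0("t", 1:6)], fit_all$b[paste0("t", 1:6)],
               tolerance = 1e-10)
})

test_that("expert-guided selection unions without duplicates", {
  expect_equal(expert_guided_selection("t1", "t2"), c("t1", "t2"))
  expect_equal(expert_guided_selection(c("t1", "t2"), "t2"), c("t1", "t2"))
  expect_equal(expert_guided_selection(character(), c("t3", "t4")),
               c("t3", "t4"))
  rcp <- feature_recipe(c("t1", "t2"), c("A", "B"), "b")
  expect_error(expert_guided_selection("t1", "zz", recipe = rcp), "zz")
})

test_that("the published equations evaluate exactly as printed", {
  m6 <- published_model("eq6")
  expect_equal(unname(predict(m6, zero_feature_row(m6))), 1.7555)
  expect_equal(unname(predict(m6, zero_feature_row(m6, yield_ref = 1)) -
                        predict(m6, zero_feature_row(m6))), 0.9731)
  row <- zero_feature_row(m6)
  row$d_V30 <- 1
  expect_equal(unname(predict(m6, row) - predict(m6, zero_feature_row(m6))),
               1.0987)
  m5 <- published_model("eq5")
  expect_equal(unname(predict(m5, zero_feature_row(m5))), 2.0103)
  expect_length(m6$b, 8)
  expect_length(m5$b, 8)
  # closed form: a trial sitting at all its group means with reference y*
  ystar <- 63.7
  expect_equal(unname(predict(m6, zero_feature_row(m6, yield_ref = ystar))),
               1.7555 + 0.9731 * ystar)

  expect_error(predict(m6, zero_feature_row(m6)[, -3]),
               class = "ptml_contract_error")
})

test_that("model JSON serialization round-trips the coefficients", {
  m <- published_model("eq6")
  f <- withr::local_tempfile(fileext = ".json")
  write_model(m, f)
  back <- read_model(f)
  expect_equal(back$a0, m$a0)
  expect_equal(back$a1, m$a1)
  expect_equal(back$b, m$b)
  row <- zero_feature_row(m, 50)
  expect_equal(predict(back, row), predict(m, row))
})

test_that("leave-one-out cross-validation isolates gross outliers", {
  f <- random_features(20, 2, seed = 12)
  y <- 10 + 0.5 * f$yield_ref + 2 * f$t1 - f$t2
  cv <- suppressWarnings(loo_cv(f, y))  # noise-free folds: summary() grumbles
  expect_lt(max(abs(cv$predictions$observed - cv$predictions$predicted)),
            1e-6)

  y_out <- y
  y_out[7] <- y_out[7] + 60
  cv2 <- suppressWarnings(loo_cv(f, y_out))
  expect_equal(which.max(cv2$predictions$rel_error), 7L)

  f3 <- random_features(3, 0, seed = 13)
  cv3 <- loo_cv(f3, c(10, 20, 30))
  expect_equal(sum(!is.na(cv3$predictions$predicted)), 3)
})

test_that("leave-group-out improves fit when one group follows another regime", {
  set.seed(14)
  n <- 160
  f <- random_features(n, 3, seed = 14)
  grp <- rep(c("main", "odd"), c(120, 40))
  y <- 20 + 0.7 * f$yield_ref + 3 * f$t1 + rnorm(n, sd = 2)
  odd <- grp == "odd"
  y[odd] <- 80 - 0.7 * f$yield_ref[odd] - 3 * f$t1[odd] + rnorm(40, sd = 2)
  full <- fit_mlr(f, y)
  lgo <- leave_group_out_cv(f, y, grp, "odd")
  expect_gt(lgo$metrics$r, full$diagnostics$r)
  expect_equal(lgo$excluded_n, 40)

  # excluding a group with no members reproduces the full fit
  lgo0 <- leave_group_out_cv(f, y, grp, "absent")
  expect_equal(lgo0$model$b, full$b)
  expect_equal(lgo0$excluded_n, 0)
  expect_error(leave_group_out_cv(f, y, rep("g", n), "g"),
               class = "ptml_empty_fit_error")
})
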