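test_that("the four standard partition schemes have the documented structure", {
  sch <- default_partition_schemes()
  expect_named(sch, paste0("PTML", 1:4))
  expect_length(sch$PTML1$blocks, 3)
  expect_length(sch$PTML3$blocks, 2)
  expect_length(sch$PTML4$blocks, 1)
  # the reuse-aware scheme swaps the support-treatment label for the
  # nucleophile addition step
  expect_false("c_6" %in% sch$PTML2$blocks$c_II)
  expect_true("nucleophile_step_code" %in% sch$PTML2$blocks$c_II)
  expect_identical(sch$PTML1$blocks[c("c_I", "c_III")],
                   sch$PTML2$blocks[c("c_I", "c_III")])
  expect_error(partition_scheme("PTML9"))
  expect_error(partition_scheme("x", blocks = list(b = "not_a_var")))
})

test_that("group keys are deterministic tuples of block values", {
  rec <- tiny_records(3, metal = c("Pd", "Pd", "Fe"))
  k1 <- group_key(rec, "c_4")
  expect_equal(k1, c("Pd", "Pd", "Fe"))
  k2 <- group_key(rec, c("c_4", "c_2"))
  expect_equal(k2[1], k2[2])
  expect_false(k2[1] == k2[3])
  rec$c_4[2] <- NA
  expect_error(group_key(rec, "c_4"), "c_4", class = "ptml_keying_error")
})

test_that("moving averages match hand arithmetic and a brute-force oracle", {
  ma <- moving_averages(c(a = 2, b = 4, c = 6), rep("g", 3))
  expect_equal(ma$mean, 4)
  expect_equal(ma$count, 3L)
  ma2 <- moving_averages(7, "solo")
  expect_equal(ma2$mean, 7)
  expect_equal(ma2$count, 1L)
  ma3 <- moving_averages(c(1, 3), c("g1", "g2"))
  expect_equal(sort(ma3$mean), c(1, 3))
  expect_equal(nrow(moving_averages(numeric(), character())), 0)

  set.seed(11)
  for (trial in 1:5) {
    n <- sample(10:80, 1)
    v <- rnorm(n)
    g <- sample(letters[1:4], n, replace = TRUE)
    ma <- moving_averages(v, g)
    for (lab in unique(g)) {
      expect_equal(ma$mean[ma$label == lab], mean(v[g == lab]),
                   tolerance = 1e-12)
      expect_equal(ma$count[ma$label == lab], sum(g == lab))
    }
  }
})

test_that("the perturbation operator is deviation from the group mean", {
  expect_equal(compute_pto(6, mean(c(2, 4, 6))), 2)
  expect_equal(compute_pto(4, 4), 0)
  expect_equal(compute_pto(7, 7), 0)  # singleton group: own mean
})

test_that("the reference function averages yields within reuse cohorts", {
  rec <- tiny_records(3, yield = c(80, 80, 80))
  expect_equal(unname(reference_yield(rec)), rep(80, 3))

  rec2 <- tiny_records(3, cycle = c(0L, 0L, 1L), yield = c(70, 90, 50))
  expect_equal(unname(reference_yield(rec2)), c(80, 80, 50))

  rec3 <- tiny_records(1, yield = 63)
  expect_equal(unname(reference_yield(rec3)), 63)

  # cohort unseen by the fit population falls back to the global mean
  expect_warning(r <- reference_yield(rec2, fit_rows = 1:2))
  expect_equal(unname(r[3]), 80)
})

test_that("assembled delta columns center, combine-then-center, and split by block", {
  # single-group centering: column sums to zero
  rec <- tiny_records(5)
  vt <- tibble::tibble(reaction_id = rec$reaction_id, V1 = c(1, 2, 3, 4, 10))
  sch <- partition_scheme("m", blocks = list(blk = "c_4"))
  f <- assemble_features(rec, vt, sch, feature_recipe("d_V1", "V1", "blk"))
  expect_equal(sum(f$d_V1), 0)

  # product term: combine first, then subtract the group mean of the product
  vt2 <- tibble::tibble(reaction_id = rec$reaction_id,
                        D = c(2, 1, 3, 2, 2), V = c(3, 4, 2, 1, 5))
  f2 <- assemble_features(rec, vt2, sch,
                          feature_recipe("d_DV", "D * V", "blk"))
  expect_equal(f2$d_DV, vt2$D * vt2$V - mean(vt2$D * vt2$V))
  # a record whose product equals the product's group mean centers to zero
  vt3 <- tibble::tibble(reaction_id = rec$reaction_id,
                        D = c(2, 2, 2, 2, 2), V = c(3, 3, 3, 3, 3))
  f3 <- assemble_features(rec, vt3, sch,
                          feature_recipe("d_DV", "D * V", "blk"))
  expect_equal(f3$d_DV, rep(0, 5))

  # the same variable under two blocks gives two distinct columns
  rec4 <- tiny_records(4, metal = c("Pd", "Pd", "Fe", "Fe"),
                       cycle = c(0L, 1L, 0L, 1L))
  vt4 <- tibble::tibble(reaction_id = rec4$reaction_id, V1 = c(1, 2, 3, 4))
  sch2 <- partition_scheme("m2", blocks = list(by_metal = "c_4",
                                               by_cycle = "reuse_cycle"))
  rcp <- feature_recipe(c("d_m", "d_c"), c("V1", "V1"),
                        c("by_metal", "by_cycle"))
  f4 <- assemble_features(rec4, vt4, sch2, rcp)
  expect_equal(f4$d_m, c(-0.5, 0.5, -0.5, 0.5))
  expect_equal(f4$d_c, c(-1, -1, 1, 1))
  expect_false(isTRUE(all.equal(f4$d_m, f4$d_c)))
})

test_that("assembled features match a naive double-loop oracle", {
  set.seed(23)
  n <- 50
  rec <- tiny_records(n, metal = sample(c("Pd", "Fe", "Ni"), n, TRUE),
                      cycle = sample(0:3, n, TRUE),
                      yield = runif(n, 20, 99))
  vt <- tibble::tibble(reaction_id = rec$reaction_id,
                       A = rnorm(n), B = rnorm(n, 5, 2))
  sch <- partition_scheme("m", blocks = list(b1 = c("c_4"),
                                             b2 = c("reuse_cycle")))
  rcp <- feature_recipe(c("dA", "dAB"), c("A", "A * B"), c("b1", "b2"))
  f <- assemble_features(rec, vt, sch, rcp)
  expect_equal(f$dA, delta_brute(vt$A, rec$c_4))
  expect_equal(f$dAB, delta_brute(vt$A * vt$B, as.character(rec$reuse_cycle)))
  # reference column equals brute-force cohort means
  expect_equal(f$yield_ref,
               delta_brute(rec$yield_pct, as.character(rec$reuse_cycle)) * -1 +
                 rec$yield_pct)
})

test_that("delta features are shift-invariant and vanish on singletons", {
  set.seed(7)
  n <- 30
  rec <- tiny_records(n, metal = sample(c("Pd", "Fe"), n, TRUE))
  vt <- tibble::tibble(reaction_id = rec$reaction_id, A = rnorm(n))
  sch <- partition_scheme("m", blocks = list(b = "c_4"))
  rcp <- feature_recipe("dA", "A", "b")
  f1 <- assemble_features(rec, vt, sch, rcp)
  # adding a constant within a group leaves every delta unchanged
  vt2 <- vt
  vt2$A[rec$c_4 == "Pd"] <- vt2$A[rec$c_4 == "Pd"] + 17
  f2 <- assemble_features(rec, vt2, sch, rcp)
  expect_equal(f1$dA, f2$dA)

  solo <- tiny_records(3, metal = c("Pd", "Fe", "Ru"))
  vs <- tibble::tibble(reaction_id = solo$reaction_id, A = c(5, -2, 9))
  fs <- assemble_features(solo, vs, sch, rcp)
  expect_equal(fs$dA, rep(0, 3))
})

test_that("train-only moving averages warn on unseen validation groups", {
  rec <- tiny_records(4, metal = c("Pd", "Pd", "Pd", "Fe"))
  rec$split_label <- c("t", "t", "v", "v")
  vt <- tibble::tibble(reaction_id = rec$reaction_id, A = c(1, 3, 5, 7))
  sch <- partition_scheme("m", blocks = list(b = "c_4"))
  expect_warning(
    f <- assemble_features(rec, vt, sch, feature_recipe("dA", "A", "b"),
                           fit_population = "train"),
    "unseen"
  )
  expect_equal(f$dA[1:2], c(-1, 1))     # Pd mean over training rows = 2
  expect_equal(f$dA[4], 7 - mean(c(1, 3)))  # Fe unseen: global training mean
})

test_that("the published recipe lists the printed terms with unit labels", {
  for (id in c("eq5", "eq6")) {
    rcp <- published_recipe(id)
    expect_equal(nrow(rcp), 8)  # eight delta terms + the reference = 9 inputs
    expect_equal(rcp$term_id[1], "d_D2V2")
    expect_equal(rcp$unit[2], "h")
    expect_equal(rcp$unit[8], "°C")
    expect_true(all(rcp$block %in% c("c_I", "c_II")))
  }
  expect_error(published_recipe("eq7"))
  # unresolvable term names the term
  rec <- tiny_records(3)
  vt <- tibble::tibble(reaction_id = rec$reaction_id, A = 1:3)
  sch <- partition_scheme("m", blocks = list(b = "c_4"))
  expect_error(
    assemble_features(rec, vt, sch, feature_recipe("dZ", "Zmissing", "b")),
    "dZ", class = "ptml_recipe_error"
  )
})
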