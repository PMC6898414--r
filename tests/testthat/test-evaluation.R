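test_that("year-blocked folds have the documented block structure", {
  # 37 years into 10 folds: seven 4-year and three 3-year blocks
  for (seed in c(1L, 2L, 99L)) {
    f <- make_year_folds(1981:2017, k = 10L, seed = seed)
    sizes <- sort(as.integer(table(f$assignment$fold)))
    expect_identical(sizes, c(3L, 3L, 3L, 4L, 4L, 4L, 4L, 4L, 4L, 4L))
    expect_setequal(f$assignment$year, 1981:2017)
  }
  f20 <- make_year_folds(2001:2020, k = 10L, seed = 1L)
  expect_true(all(table(f20$assignment$fold) == 2L))
  expect_identical(make_year_folds(1981:2017, 10L, seed = 5L),
                   make_year_folds(1981:2017, 10L, seed = 5L))
  expect_error(make_year_folds(2001:2005, k = 10L, seed = 1L), "years")
})

test_that("skill score and accuracy measures follow their formulas", {
  expect_equal(skill_score(0.04, 0.04), 0)
  expect_equal(skill_score(0.02, 0.04), 0.5)
  expect_equal(skill_score(0.06, 0.04), -0.5)
  expect_error(skill_score(0.1, 0), "mse_ref")

  m <- compute_metrics(c(2, 4), c(1, 5))
  expect_equal(m$mape, 37.5)
  expect_equal(m$rmse, 1)

  x <- sin(1:50)
  mp <- compute_metrics(x, x, mse_ref = 0.3)
  expect_equal(mp$rmse, 0)
  expect_equal(mp$mape, 0)
  expect_equal(mp$pcc, 1)
  expect_equal(mp$skill, 1)

  set.seed(6)
  a <- rnorm(100); b <- a + rnorm(100)
  mm <- compute_metrics(a, b)
  # textbook covariance / variance computation
  pcc_oracle <- (mean(a * b) - mean(a) * mean(b)) /
    sqrt((mean(a^2) - mean(a)^2) * (mean(b^2) - mean(b)^2))
  expect_equal(mm$pcc, pcc_oracle, tolerance = 1e-12)
  # permutation invariance of every measure
  perm <- sample(100)
  expect_equal(compute_metrics(a[perm], b[perm], mse_ref = 1),
               compute_metrics(a, b, mse_ref = 1))

  expect_error(compute_metrics(c(0, 1), c(1, 1)), "MAPE")
  expect_error(compute_metrics(c(1, 1), c(1, 2)), "PCC")
})

test_that("cross-validation never leaks years and self-skill is zero", {
  s <- small_sim(2L, 3L, 2001:2012)
  folds <- make_year_folds(2001:2012, k = 4L, seed = 3L)
  a <- folds$assignment
  for (f in 1:4) {
    expect_length(intersect(a$year[a$fold == f], a$year[a$fold != f]), 0)
  }
  cv <- cross_validate(s$panel, s$monthly, "M1", methods = "ols",
                       folds = folds)
  expect_equal(cv$summary$skill, 0)
  expect_equal(cv$per_fold$skill, rep(0, 4))
  expect_true(all(cv$per_fold$rmse >= 0))
})

test_that("two-fold metrics equal a hand-computed out-of-sample loop", {
  s <- small_sim(1L, 3L, 2001:2008)
  folds <- make_year_folds(2001:2008, k = 2L, seed = 11L)
  cv <- cross_validate(s$panel, s$monthly, "M1", methods = "ols",
                       folds = folds)

  d <- build_design(s$panel, s$monthly, "M1")
  a <- folds$assignment
  hand <- lapply(1:2, function(f) {
    te_years <- a$year[a$fold == f]
    te <- s$panel$year %in% te_years
    fit <- ols_fit(design_subset(d, !te))
    pred <- predict(fit, design_subset(d, te))
    act <- d$y[te]
    c(rmse = sqrt(mean((act - pred)^2)),
      mape = 100 * mean(abs((act - pred) / act)),
      pcc = cor(act, pred))
  })
  for (f in 1:2) {
    row <- cv$per_fold[cv$per_fold$fold == f, ]
    expect_equal(row$rmse, hand[[f]][["rmse"]], tolerance = 1e-12)
    expect_equal(row$mape, hand[[f]][["mape"]], tolerance = 1e-12)
    expect_equal(row$pcc, hand[[f]][["pcc"]], tolerance = 1e-12)
  }
  expect_equal(cv$summary$rmse, mean(vapply(hand, `[[`, 0, "rmse")),
               tolerance = 1e-12)
})

test_that("a supplied benchmark drives the skill score per fold", {
  s <- small_sim(2L, 3L, 2001:2012)
  folds <- make_year_folds(2001:2012, k = 3L, seed = 2L)
  bench <- cross_validate(s$panel, s$monthly, "M1", methods = "ols",
                          folds = folds)
  cv4 <- cross_validate(s$panel, s$monthly, "M2", methods = "ols",
                        folds = folds, benchmark = bench)
  ref <- bench$per_fold$mse[order(bench$per_fold$fold)]
  got <- cv4$per_fold[order(cv4$per_fold$fold), ]
  expect_equal(got$skill, -(got$mse - ref) / ref, tolerance = 1e-12)
  # mismatched folds are rejected
  other <- make_year_folds(2001:2012, k = 3L, seed = 99L)
  bench2 <- cross_validate(s$panel, s$monthly, "M1", methods = "ols",
                           folds = other)
  expect_error(cross_validate(s$panel, s$monthly, "M2", methods = "ols",
                              folds = folds, benchmark = bench2),
               "different folds")
})
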