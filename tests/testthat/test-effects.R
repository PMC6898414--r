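test_that("precipitation percentiles use linear interpolation", {
  m <- data.frame(county_id = "a", state_id = "s", year = 1:4,
                  month = 7L, gdd = 0, hdd = 0, prec = c(1, 2, 3, 4))
  expect_equal(precipitation_percentile(m, 7, 25), 1.75)
  expect_equal(precipitation_percentile(m, 7, 75), 3.25)
  m$prec <- 5
  expect_equal(precipitation_percentile(m, 7, 10), 5)
  expect_equal(precipitation_percentile(m, 7, 90), 5)
  expect_error(precipitation_percentile(m, 8, 50), "month 8")

  set.seed(12)
  v <- rgamma(1000, 4, scale = 22)
  mg <- data.frame(county_id = "a", state_id = "s", year = seq_along(v),
                   month = 6L, gdd = 0, hdd = 0, prec = v)
  # independent sort-based computation (type-7 definition)
  h <- (1000 - 1) * 0.75
  sv <- sort(v)
  oracle <- sv[floor(h) + 1] + (h - floor(h)) * (sv[floor(h) + 2] - sv[floor(h) + 1])
  expect_equal(precipitation_percentile(mg, 6, 75), oracle, tolerance = 1e-12)
})

# Noiseless panel with known July HDD main and interaction coefficients;
# OLS recovers them exactly, so the conditional effect must equal the
# hand-computed affine combination b_main + b1 prec + b2 prec^2.
effect_toy <- function(b_main = -0.01, b_int1 = 2e-5, b_int2 = -1e-8) {
  w <- small_weather(2L, 4L, 2001:2010, seed = 44L)
  m <- monthly_features(w)
  keys <- unique(m[, c("county_id", "state_id", "year")])
  val <- vapply(seq_len(nrow(keys)), function(i) {
    sel <- m$county_id == keys$county_id[i] & m$year == keys$year[i] &
      m$month == 7L
    b_main * m$hdd[sel] + b_int1 * m$hdd[sel] * m$prec[sel] +
      b_int2 * m$hdd[sel] * m$prec[sel]^2
  }, 0)
  panel <- data.frame(county_id = keys$county_id, state_id = keys$state_id,
                      year = keys$year, log_yield = val,
                      stringsAsFactors = FALSE)
  list(weather = w, monthly = m, panel = panel)
}

test_that("conditional effects combine main and interaction coefficients", {
  b <- c(-0.01, 2e-5, -1e-8)
  toy <- effect_toy(b[1], b[2], b[3])
  d <- build_design(toy$panel, toy$monthly, "M4")
  g <- integer(56)
  g[match(c("HDD_7", "HDDxPrec_7", "HDDxPrec2_7"), colnames(d$X))] <- 1L
  fit <- single_model_set(d, g)  # noiseless: recovers b exactly
  for (prec in c(0, 2, 80)) {
    ce <- conditional_marginal_effect(fit, d, family = "HDD", month = 7L,
                                      prec_value = prec, draws = 200L,
                                      seed = 1L)
    expect_equal(ce$effect, b[1] + b[2] * prec + b[3] * prec^2,
                 tolerance = 1e-6)
  }
  # the documented hand-arithmetic case
  ce2 <- conditional_marginal_effect(fit, d, family = "HDD", month = 7L,
                                     prec_value = 2, draws = 200L, seed = 1L)
  expect_equal(ce2$effect, -0.01 + 2 * 2e-5 + 4 * -1e-8, tolerance = 1e-6)

  # affine in prec with curvature given by the squared-interaction sign
  eff_at <- function(p) conditional_marginal_effect(
    fit, d, "HDD", 7L, p, draws = 200L, seed = 1L)$effect
  second_diff <- eff_at(100) - 2 * eff_at(50) + eff_at(0)
  expect_lt(second_diff, 0)  # b_int2 < 0

  expect_error(conditional_marginal_effect(fit, d, "HDD", month = 3L,
                                           prec_value = 1), "month")
})

test_that("the OLS delta-method path matches the same affine formula seasonally", {
  # seasonal analogue: log yield built from seasonal HDD, HDD x Prec and
  # HDD x Prec^2 with known coefficients; M2-OLS recovers them exactly
  b <- c(-2e-3, 1e-6, -4e-10)
  w <- small_weather(2L, 4L, 2001:2010, seed = 44L)
  m <- monthly_features(w)
  keys <- unique(m[, c("county_id", "state_id", "year")])
  val <- vapply(seq_len(nrow(keys)), function(i) {
    sel <- m$county_id == keys$county_id[i] & m$year == keys$year[i] &
      m$month %in% 4:10
    h <- sum(m$hdd[sel]); p <- sum(m$prec[sel])
    b[1] * h + b[2] * h * p + b[3] * h * p^2
  }, 0)
  panel <- data.frame(county_id = keys$county_id, state_id = keys$state_id,
                      year = keys$year, log_yield = val,
                      stringsAsFactors = FALSE)
  d2 <- build_design(panel, m, "M2")
  fit <- ols_fit(d2)
  for (prec in c(0, 300, 700)) {
    ce <- conditional_marginal_effect(fit, d2, family = "HDD", month = NULL,
                                      prec_value = prec)
    expect_equal(ce$effect, b[1] + b[2] * prec + b[3] * prec^2,
                 tolerance = 1e-6)
    expect_true(ce$interval["lower"] <= ce$effect &&
                  ce$effect <= ce$interval["upper"])
  }
})

test_that("without interactions the effect is the main coefficient at any precipitation", {
  toy <- effect_toy(-0.008, 0, 0)
  d <- build_design(toy$panel, toy$monthly, "M4")
  g <- integer(56); g[match("HDD_7", colnames(d$X))] <- 1L
  set1 <- single_model_set(d, g)
  e_lo <- conditional_marginal_effect(set1, d, "HDD", 7L, prec_value = 10,
                                      draws = 500L, seed = 3L)
  e_hi <- conditional_marginal_effect(set1, d, "HDD", 7L, prec_value = 200,
                                      draws = 500L, seed = 3L)
  expect_equal(e_lo$effect, e_hi$effect, tolerance = 1e-10)
  expect_equal(e_lo$effect, -0.008, tolerance = 1e-6)
})

test_that("seasonal specifications reject a month argument and use season-wide effects", {
  s <- small_sim(spec = "M1")
  fit <- ols_fit(s$design)
  expect_error(conditional_marginal_effect(fit, s$design, "GDD", month = 7L,
                                           prec_value = 1), "seasonal")
  ce <- conditional_marginal_effect(fit, s$design, "GDD", month = NULL,
                                    prec_value = 100)
  expect_true(is.finite(ce$effect))
})

test_that("a true positive HDD x precipitation interaction is recovered in sign", {
  # known July interaction: wetter conditions damp the heat penalty, so
  # the estimated high-precipitation effect should exceed the
  # low-precipitation effect in most replicates
  w <- small_weather(3L, 3L, 1981:2010, seed = 50L)
  m <- monthly_features(w)
  gamma_labels <- c("HDD_7", "HDDxPrec_7")
  beta <- c(-0.02, 1.2e-4)
  hits <- 0L
  nrep <- 10L
  for (r in seq_len(nrep)) {
    sim <- generate_panel(w, panel_sim_config(
      true_gamma = gamma_labels, true_beta = beta, noise_sd = 0.08,
      seed = 500L + r))
    d <- build_design(sim$panel, m, "M4")
    tr <- mc3_search(d, n_iter = 3000L, burn_in = 750L, seed = r)
    win <- occams_window(tr)
    post <- coefficient_posterior(d, win, draws = 2000L, seed = r)
    p_lo <- precipitation_percentile(m, 7L, 25)
    p_hi <- precipitation_percentile(m, 7L, 75)
    e_lo <- conditional_marginal_effect(win, d, "HDD", 7L, p_lo, post = post)
    e_hi <- conditional_marginal_effect(win, d, "HDD", 7L, p_hi, post = post)
    if (e_hi$effect > e_lo$effect) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("the effects table mirrors the month-by-family panel layout", {
  toy <- effect_toy()
  d <- build_design(toy$panel, toy$monthly, "M4")
  g <- integer(56)
  g[match(c("HDD_7", "HDDxPrec_7", "GDD_5"), colnames(d$X))] <- 1L
  fit <- single_model_set(d, g)
  tab <- conditional_effects_table(fit, d, toy$monthly, draws = 500L,
                                   seed = 2L)
  expect_identical(nrow(tab), 2L * 7L * 2L)
  expect_setequal(unique(tab$family), c("GDD", "HDD"))
  expect_setequal(unique(tab$month), 4:10)
  expect_true(all(tab$lower <= tab$effect & tab$effect <= tab$upper))
})
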