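test_that("log marginal likelihood matches the explicit-projector oracle", {
  d <- ml_fixture()
  gammas <- list(c(0L, 0L, 0L), c(1L, 0L, 0L), c(0L, 1L, 1L), c(1L, 1L, 1L))
  for (g in gammas) {
    W <- cbind(d$X[, which(g == 1L), drop = FALSE], d$Z)
    expect_equal(log_marginal_likelihood(d, g), oracle_logml(d$y, W),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("log marginal likelihood is invariant to weather-column order", {
  d <- ml_fixture()
  v1 <- log_marginal_likelihood(d, c(1L, 0L, 1L))
  d_perm <- raw_design(d$y, d$X[, c(3, 2, 1)], d$Z)
  v2 <- log_marginal_likelihood(d_perm, c(1L, 0L, 1L))
  expect_equal(v1, v2, tolerance = 1e-10)
})

test_that("exact collinearity raises a singularity error naming columns", {
  d <- ml_fixture()
  X_dup <- cbind(d$X, w3_copy = d$X[, 3])
  d_dup <- raw_design(d$y, X_dup, d$Z)
  expect_error(log_marginal_likelihood(d_dup, c(0L, 0L, 1L, 1L)),
               "collinear")
  # n <= p is a dimension error
  d_small <- raw_design(d$y[1:5], d$X[1:5, ], d$Z[1:5, 1:2, drop = FALSE])
  expect_error(log_marginal_likelihood(d_small, c(1L, 1L, 1L)), "rows")
})

test_that("posterior model probabilities are a stable softmax", {
  expect_equal(posterior_model_probs(0), 1)
  expect_equal(posterior_model_probs(c(-5, -5)), c(0.5, 0.5))
  expect_equal(posterior_model_probs(c(0, -log(3))), c(0.75, 0.25))
  # invariant to constant shifts, stable at extreme magnitudes
  lm1 <- c(-3001, -3000, -3002)
  expect_equal(posterior_model_probs(lm1), posterior_model_probs(lm1 + 5000))
  expect_error(posterior_model_probs(numeric(0)), "nonempty")
  expect_error(posterior_model_probs(c(0, Inf)), "finite")
})

test_that("selection and the window reproduce exhaustive enumeration on a small space", {
  set.seed(9)
  n <- 80L
  Z <- cbind(rep(1, n))  # single always-in column
  X <- matrix(rnorm(n * 8L), n, 8L)
  y <- 0.8 * X[, 2] - 0.6 * X[, 5] + rnorm(n)
  d <- raw_design(y, X, Z)
  tr <- enumerate_models(d)
  expect_identical(nrow(tr$visited), 256L)

  # brute-force argmax over the enumeration table
  brute_best <- tr$visited$key[which.max(tr$visited$log_marginal)]
  expect_identical(gamma_key(unname(select_best(tr))), brute_best)

  # brute-force Occam's window at c = 3
  keep <- tr$visited$log_marginal >= max(tr$visited$log_marginal) - log(3)
  win <- occams_window(tr, c = 3)
  expect_setequal(win$keys, tr$visited$key[keep])
  expect_equal(sum(win$weights), 1)
  expect_true(all(win$weights > 0))
  # every member within factor c of the best
  expect_true(all(max(win$log_marginal) - win$log_marginal <= log(3) + 1e-12))
  # c = 1 keeps only the best model (and exact ties)
  expect_identical(occams_window(tr, c = 1)$keys, brute_best)
  expect_error(occams_window(tr, c = 0.5), "c")
})

test_that("select_best breaks ties toward smaller then lexicographic models", {
  tr <- structure(list(
    visited = data.frame(key = c("110", "100", "010"),
                         log_marginal = c(-10, -10 + 1e-12, -10)),
    chain = character(0), n_iter = 0L, burn_in = 0L,
    acceptance_rate = NA_real_, seed = NA_integer_, n_vars = 3L,
    x_labels = c("a", "b", "c")), class = "mc3_trace")
  expect_identical(unname(select_best(tr)), c(0L, 1L, 0L))
  # direct arithmetic example: log marginals {0, -1, -2}, c = 3 keeps two
  tr2 <- structure(list(
    visited = data.frame(key = c("100", "010", "001"),
                         log_marginal = c(0, -1, -2)),
    chain = character(0), n_iter = 0L, burn_in = 0L,
    acceptance_rate = NA_real_, seed = NA_integer_, n_vars = 3L,
    x_labels = c("a", "b", "c")), class = "mc3_trace")
  w2 <- occams_window(tr2, c = 3)
  expect_setequal(w2$keys, c("100", "010"))
  expect_equal(w2$weights, posterior_model_probs(c(0, -1)))
})

test_that("the MC3 chain is seeded-deterministic and matches enumeration", {
  set.seed(17)
  n <- 120L
  Z <- cbind(rep(1, n))
  X <- scale(matrix(rnorm(n * 6L), n, 6L))
  y <- 0.7 * X[, 1] - 0.5 * X[, 4] + rnorm(n, 0, 0.8)
  d <- raw_design(y, X, Z)

  tr1 <- mc3_search(d, n_iter = 30000L, burn_in = 3000L, seed = 77L)
  tr2 <- mc3_search(d, n_iter = 30000L, burn_in = 3000L, seed = 77L)
  expect_identical(tr1$chain, tr2$chain)
  expect_identical(tr1$visited, tr2$visited)

  enum <- enumerate_models(d)
  probs <- posterior_model_probs(enum$visited$log_marginal)
  names(probs) <- enum$visited$key
  freq <- visit_frequencies(tr1)
  post <- tr1$chain[(tr1$burn_in + 1L):tr1$n_iter]
  # per-model batch-means MC standard error of the visit share
  for (k in names(probs)[probs > 0.01]) {
    se <- max(batch_se(as.numeric(post == k)), 1e-4)
    share <- if (k %in% names(freq)) freq[[k]] else 0
    expect_lt(abs(share - probs[[k]]), 3 * se + 1e-12)
  }
})

test_that("a zero-signal design yields no dominant model", {
  set.seed(23)
  n <- 150L
  Z <- cbind(rep(1, n))
  X <- scale(matrix(rnorm(n * 6L), n, 6L))
  y <- rnorm(n)
  d <- raw_design(y, X, Z)
  enum <- enumerate_models(d)
  probs <- posterior_model_probs(enum$visited$log_marginal)
  names(probs) <- enum$visited$key
  tr <- mc3_search(d, n_iter = 30000L, burn_in = 3000L, seed = 3L)
  freq <- visit_frequencies(tr)
  top_key <- names(freq)[which.max(freq)]
  post <- tr$chain[(tr$burn_in + 1L):tr$n_iter]
  se <- batch_se(as.numeric(post == top_key))
  # the chain's top share cannot exceed the enumerated posterior's
  # corresponding mass by more than Monte-Carlo noise
  expect_lt(max(freq), probs[[top_key]] + 3 * se + 1e-12)
})

test_that("adding a pure-noise column does not raise the log marginal", {
  set.seed(41)
  n <- 200L
  Z <- cbind(rep(1, n))
  X <- scale(matrix(rnorm(n * 5L), n, 5L))
  y <- 1.2 * X[, 1] + rnorm(n, 0, 0.1)
  d <- raw_design(y, X, Z)
  base <- c(1L, 0L, 0L, 0L, 0L)
  lm_base <- log_marginal_likelihood(d, base)
  for (j in 2:5) {
    g <- base; g[j] <- 1L
    expect_lt(log_marginal_likelihood(d, g), lm_base)
  }
})

test_that("coefficient posterior reduces to least squares for one model", {
  s <- small_sim(spec = "M4")
  d <- s$design
  g <- integer(56); g[match(c("GDD_6", "HDD_7"), colnames(d$X))] <- 1L
  set1 <- single_model_set(d, g)
  post <- coefficient_posterior(d, set1, draws = 2000L, seed = 10L)
  # natural-unit center equals the least-squares estimate on natural columns
  dn <- build_design(s$panel, s$monthly, "M4", standardize = FALSE)
  W <- cbind(dn$X[, which(g == 1L)], dn$Z)
  ls <- stats::lm.fit(W, dn$y)$coefficients[1:2]
  act <- post$table[post$table$pip > 0, ]
  expect_equal(act$mean, unname(ls), tolerance = 1e-8)
  # intervals bracket the center, variables never active pinned at zero
  expect_true(all(act$lower < act$mean & act$mean < act$upper))
  inact <- post$table[post$table$pip == 0, ]
  expect_true(all(inact$mean == 0 & inact$lower == 0 & inact$upper == 0))
})

test_that("averaged predictions are convex combinations of member predictions", {
  s <- small_sim(spec = "M4")
  d <- s$design
  g1 <- integer(56); g1[match("GDD_4", colnames(d$X))] <- 1L
  g2 <- integer(56); g2[match(c("GDD_5", "Prec_7"), colnames(d$X))] <- 1L
  lm1 <- log_marginal_likelihood(d, g1)
  lm2 <- log_marginal_likelihood(d, g2)
  mk_set <- function(gammas, weights) {
    structure(list(keys = vapply(gammas, gamma_key, ""), gammas = gammas,
                   log_marginal = c(lm1, lm2)[seq_along(gammas)],
                   weights = weights, best = gammas[[1]], c = 3,
                   x_labels = colnames(d$X), n_vars = 56L),
              class = "posterior_model_set")
  }
  ms <- mk_set(list(g1, g2), c(0.3, 0.7))
  idx <- 1:20
  d_new <- design_subset(d, idx)
  p1 <- predict(mk_set(list(g1), 1), d_new, d)
  p2 <- predict(mk_set(list(g2), 1), d_new, d)
  pb <- predict(ms, d_new, d)
  expect_equal(pb, 0.3 * p1 + 0.7 * p2, tolerance = 1e-10)
  expect_true(all(pb >= pmin(p1, p2) - 1e-10 & pb <= pmax(p1, p2) + 1e-10))
  # degenerate weights reduce to the member's prediction
  expect_equal(predict(mk_set(list(g1, g2), c(1, 0)), d_new, d), p1,
               tolerance = 1e-12)
})

test_that("noiseless saturated interpolation is reproduced by prediction", {
  d0 <- ml_fixture()
  beta <- c(0.3, -0.2, 0.1, 0.05, -0.01, 1, 1.5)
  y_exact <- drop(cbind(d0$X, d0$Z) %*% beta)
  d <- raw_design(y_exact, d0$X, d0$Z)
  set1 <- single_model_set(d, c(1L, 1L, 1L))
  expect_equal(predict(set1, d, d), y_exact, tolerance = 1e-8)
})
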