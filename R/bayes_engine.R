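#' @title Closed-form marginal likelihood of a weather-variable subset
#'
#' @description Under the reference (improper) prior on the regression
#' coefficients and error variance, the integrated likelihood of the model
#' that includes the weather columns flagged by `gamma` (with the trend
#' and fixed-effect columns `Z` always included) has the closed form
#' \deqn{m(data | \gamma) = \Gamma((n-p_\gamma)/2)\,
#'       |W_\gamma^\top W_\gamma|^{-1/2}\,
#'       [\pi\, RSS_\gamma]^{-(n-p_\gamma)/2},}
#' where \eqn{W_\gamma = (X_\gamma, Z)}, \eqn{p_\gamma} is its column
#' count and \eqn{RSS_\gamma} the residual sum of squares of `y` projected
#' off its column space. The value is returned on the natural-log scale
#' and computed via orthogonal (QR) decompositions: `Z` is factored once
#' per design, the selected `X` columns are residualised against it, and
#' the determinant splits as
#' \eqn{|W^\top W| = |Z^\top Z| \cdot |\tilde X_\gamma^\top \tilde X_\gamma|}.
#' The \eqn{n \times n} projector is never formed.
#'
#' Under the uniform model prior \eqn{p(\gamma) = 2^{-56}} the prior
#' cancels from every posterior ratio, so it never appears explicitly.
#'
#' @param design A `crop_design` from [build_design()].
#' @param gamma 0/1 inclusion vector over the design's weather columns.
#' @return Log marginal likelihood (natural log), a single number.
#' @export
log_marginal_likelihood <- function(design, gamma) {
  gamma <- check_gamma(design, gamma)
  prep <- ml_prepare(design)
  ml_log_marginal(prep, gamma, design)
}

check_gamma <- function(design, gamma) {
  stopifnot(inherits(design, "crop_design"))
  gamma <- as.integer(gamma)
  if (length(gamma) != ncol(design$X) || !all(gamma %in% 0:1))
    stop(sprintf("`gamma` must be a 0/1 vector of length %d", ncol(design$X)),
         call. = FALSE)
  gamma
}

# tolerance for rank decisions in QR factorisations
RANK_TOL <- 1e-10

# factor Z once and residualise y and X against it; memoised on the design
ml_prepare <- function(design) {
  if (!is.null(design$cache$prep)) return(design$cache$prep)
  Z <- design$Z
  qz <- qr(Z, tol = RANK_TOL)
  if (qz$rank < ncol(Z)) {
    drop_cols <- colnames(Z)[qz$pivot[(qz$rank + 1L):ncol(Z)]]
    stop("fixed columns Z are rank deficient (collinear or empty: ",
         paste(drop_cols, collapse = ", "),
         "); is every county and state represented?", call. = FALSE)
  }
  logdet_zz <- 2 * sum(log(abs(diag(qr.R(qz)))))
  prep <- list(
    n = length(design$y),
    pz = ncol(Z),
    logdet_zz = logdet_zz,
    y_res = qr.resid(qz, design$y),
    X_res = qr.resid(qz, design$X),
    qz = qz)
  design$cache$prep <- prep
  prep
}

ml_log_marginal <- function(prep, gamma, design) {
  act <- which(gamma == 1L)
  p <- prep$pz + length(act)
  n <- prep$n
  if (n <= p)
    stop(sprintf("model has p = %d columns but only n = %d rows", p, n),
         call. = FALSE)
  if (length(act) == 0L) {
    rss <- sum(prep$y_res^2)
    logdet <- prep$logdet_zz
  } else {
    Xa <- prep$X_res[, act, drop = FALSE]
    qx <- qr(Xa, tol = RANK_TOL)
    if (qx$rank < length(act)) {
      bad <- colnames(design$X)[act][qx$pivot[(qx$rank + 1L):length(act)]]
      stop("selected weather columns are collinear (with each other or Z): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    logdet <- prep$logdet_zz + 2 * sum(log(abs(diag(qr.R(qx)))))
    rss <- sum(qr.resid(qx, prep$y_res)^2)
  }
  lgamma((n - p) / 2) - 0.5 * logdet - ((n - p) / 2) * (log(pi) + log(rss))
}

#' Normalized posterior model probabilities from log marginals
#'
#' Softmax of the log marginal likelihoods (computed with max
#' subtraction), i.e. \eqn{p(\gamma|data) = m(data|\gamma) / \sum_\gamma
#' m(data|\gamma)} under the uniform model prior.
#'
#' @param log_marginals Numeric vector of finite log marginal likelihoods.
#' @return Probabilities summing to 1, same length and names.
#' @export
posterior_model_probs <- function(log_marginals) {
  if (length(log_marginals) == 0L)
    stop("`log_marginals` must be nonempty", call. = FALSE)
  if (any(!is.finite(log_marginals)))
    stop("`log_marginals` must be finite", call. = FALSE)
  w <- exp(log_marginals - max(log_marginals))
  w / sum(w)
}

gamma_key <- function(gamma) paste(gamma, collapse = "")
key_to_gamma <- function(key) as.integer(strsplit(key, "", fixed = TRUE)[[1]])

#' Markov chain Monte Carlo model composition over the weather columns
#'
#' Metropolis random walk on the space of inclusion vectors: each
#' iteration proposes flipping one uniformly chosen indicator (a symmetric
#' proposal) and accepts with probability
#' `min(1, exp(log m(proposed) - log m(current)))`. Proposals whose design
#' is rank deficient or has `n <= p` are rejected outright. Every log
#' marginal evaluated is cached by indicator bitstring, so the set of
#' visited models doubles as an estimate of the model space's mass.
#'
#' @param design A `crop_design`.
#' @param n_iter Total iterations (default 20000).
#' @param burn_in Iterations discarded from visit-frequency summaries
#'   (default 2000); the cache keeps all evaluated models regardless.
#' @param seed Integer seed (required; the chain is deterministic given it).
#' @param gamma_init Optional starting inclusion vector (default: empty
#'   model).
#' @return An object of class `mc3_trace`: list with `visited` (data frame
#'   `key`, `log_marginal`), `chain` (accepted-state keys, one per
#'   iteration), `n_iter`, `burn_in`, `acceptance_rate`, `seed`,
#'   `n_vars`, `x_labels`.
#' @export
mc3_search <- function(design, n_iter = 20000L, burn_in = 2000L, seed,
                       gamma_init = NULL) {
  stopifnot(inherits(design, "crop_design"))
  if (missing(seed)) stop("`seed` is required for mc3_search", call. = FALSE)
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in)
  if (!(n_iter > burn_in && burn_in >= 0L))
    stop("need n_iter > burn_in >= 0", call. = FALSE)
  p <- ncol(design$X)
  gamma <- if (is.null(gamma_init)) integer(p) else check_gamma(design, gamma_init)
  prep <- ml_prepare(design)

  cache <- new.env(parent = emptyenv())
  eval_ml <- function(g) {
    k <- gamma_key(g)
    if (!is.null(cache[[k]])) return(cache[[k]])
    v <- tryCatch(ml_log_marginal(prep, g, design), error = function(e) NA_real_)
    cache[[k]] <- v
    v
  }

  lm_cur <- eval_ml(gamma)
  if (is.na(lm_cur))
    stop("initial model is not estimable (rank deficient or n <= p)",
         call. = FALSE)
  chain <- character(n_iter)
  accepted <- 0L
  with_seed(seed, {
    flips <- sample.int(p, n_iter, replace = TRUE)
    logu <- log(stats::runif(n_iter))
    for (it in seq_len(n_iter)) {
      prop <- gamma
      j <- flips[it]
      prop[j] <- 1L - prop[j]
      lm_prop <- eval_ml(prop)
      if (!is.na(lm_prop) && logu[it] < (lm_prop - lm_cur)) {
        gamma <- prop
        lm_cur <- lm_prop
        accepted <- accepted + 1L
      }
      chain[it] <- gamma_key(gamma)
    }
  })
  keys <- ls(cache)
  vals <- vapply(keys, function(k) cache[[k]], 0)
  ok <- !is.na(vals)
  structure(list(
    visited = data.frame(key = keys[ok], log_marginal = unname(vals[ok]),
                         stringsAsFactors = FALSE),
    chain = chain, n_iter = n_iter, burn_in = burn_in,
    acceptance_rate = accepted / n_iter, seed = seed,
    n_vars = p, x_labels = colnames(design$X)),
    class = "mc3_trace")
}

#' @export
print.mc3_trace <- function(x, ...) {
  cat(sprintf("MC3 trace: %d iterations (%d burn-in), %d models visited, acceptance rate %.3f\n",
              x$n_iter, x$burn_in, nrow(x$visited), x$acceptance_rate))
  invisible(x)
}

#' Exhaustive enumeration of a small model space
#'
#' Evaluates the log marginal likelihood of all `2^p` inclusion vectors.
#' Intended for model spaces of at most ~15 variables, as an exact
#' counterpart to [mc3_search()] on small designs.
#'
#' @param design A `crop_design` with at most `max_vars` weather columns.
#' @param max_vars Safety cap on the number of weather columns.
#' @return An `mc3_trace` with every estimable model in `visited` and an
#'   empty chain.
#' @export
enumerate_models <- function(design, max_vars = 15L) {
  stopifnot(inherits(design, "crop_design"))
  p <- ncol(design$X)
  if (p > max_vars)
    stop(sprintf("refusing to enumerate 2^%d models (max_vars = %d)",
                 p, max_vars), call. = FALSE)
  prep <- ml_prepare(design)
  n_mod <- 2^p
  keys <- character(n_mod)
  vals <- numeric(n_mod)
  for (i in seq_len(n_mod)) {
    g <- as.integer(intToBits(i - 1L)[seq_len(p)])
    keys[i] <- gamma_key(g)
    vals[i] <- tryCatch(ml_log_marginal(prep, g, design),
                        error = function(e) NA_real_)
  }
  ok <- !is.na(vals)
  structure(list(visited = data.frame(key = keys[ok], log_marginal = vals[ok],
                                      stringsAsFactors = FALSE),
                 chain = character(0), n_iter = 0L, burn_in = 0L,
                 acceptance_rate = NA_real_, seed = NA_integer_,
                 n_vars = p, x_labels = colnames(design$X)),
            class = "mc3_trace")
}

#' Post-burn-in visit frequencies of an MC3 chain
#'
#' @param trace An `mc3_trace` with a nonempty chain.
#' @return Named numeric vector of visit shares (keys as names), summing
#'   to 1 over the post-burn-in chain.
#' @export
visit_frequencies <- function(trace) {
  stopifnot(inherits(trace, "mc3_trace"))
  post <- trace$chain[(trace$burn_in + 1L):trace$n_iter]
  tab <- table(post)
  stats::setNames(as.numeric(tab) / length(post), names(tab))
}

#' Highest-marginal-likelihood model of a trace
#'
#' The Bayesian variable selection estimate: the visited model maximizing
#' the marginal likelihood (equivalently the posterior model probability
#' under the uniform prior). Ties within numerical tolerance go to the
#' model with fewest active variables, then to the lexicographically
#' smallest indicator.
#'
#' @param trace An `mc3_trace`.
#' @param tie_tol Absolute log tolerance within which models count as tied.
#' @return 0/1 inclusion vector (with the trace's labels as names).
#' @export
select_best <- function(trace, tie_tol = 1e-9) {
  stopifnot(inherits(trace, "mc3_trace"))
  v <- trace$visited
  if (nrow(v) == 0L) stop("trace contains no visited models", call. = FALSE)
  top <- max(v$log_marginal)
  cand <- v$key[v$log_marginal >= top - tie_tol]
  sizes <- vapply(cand, function(k) sum(key_to_gamma(k)), 0L)
  cand <- sort(cand[sizes == min(sizes)])
  g <- key_to_gamma(cand[1L])
  names(g) <- trace$x_labels
  g
}

#' Occam's window over visited models
#'
#' Retains the visited models whose marginal likelihood is within a factor
#' `c` of the best visited model's -- on the log scale, those with
#' `log m >= log m(best) - log(c)` -- and renormalizes the posterior model
#' probabilities over the retained window.
#'
#' @param trace An `mc3_trace`.
#' @param c Window constant (default 3, so models at least a third as
#'   probable as the best are kept); must be >= 1.
#' @return An object of class `posterior_model_set`: list with `keys`,
#'   `gammas` (list of 0/1 vectors), `log_marginal`, `weights` (positive,
#'   summing to 1), `best`, `c`, `x_labels`, `n_vars`.
#' @export
occams_window <- function(trace, c = 3) {
  stopifnot(inherits(trace, "mc3_trace"))
  if (!is.numeric(c) || length(c) != 1L || c < 1)
    stop("window constant `c` must be >= 1", call. = FALSE)
  v <- trace$visited
  if (nrow(v) == 0L) stop("trace contains no visited models", call. = FALSE)
  v <- v[!duplicated(v$key), , drop = FALSE]
  keep <- v$log_marginal >= max(v$log_marginal) - log(c)
  v <- v[keep, , drop = FALSE]
  v <- v[order(-v$log_marginal, v$key), , drop = FALSE]
  best <- select_best(trace)
  structure(list(
    keys = v$key,
    gammas = lapply(v$key, key_to_gamma),
    log_marginal = v$log_marginal,
    weights = posterior_model_probs(v$log_marginal),
    best = best, c = c,
    x_labels = trace$x_labels, n_vars = trace$n_vars),
    class = "posterior_model_set")
}

#' @export
print.posterior_model_set <- function(x, ...) {
  cat(sprintf("Occam's window (c = %g): %d models; best model has %d active variables; top weight %.3f\n",
              x$c, length(x$keys), sum(x$best), max(x$weights)))
  invisible(x)
}

#' Single-model posterior set
#'
#' Wraps one inclusion vector as a degenerate `posterior_model_set` with
#' weight 1 -- the form Bayesian variable selection takes after
#' [select_best()], so that prediction and inference share one code path
#' with model averaging.
#'
#' @param design A `crop_design`.
#' @param gamma 0/1 inclusion vector.
#' @return A `posterior_model_set` containing only `gamma`.
#' @export
single_model_set <- function(design, gamma) {
  gamma <- check_gamma(design, gamma)
  lm1 <- log_marginal_likelihood(design, gamma)
  g <- gamma
  names(g) <- colnames(design$X)
  structure(list(keys = gamma_key(gamma), gammas = list(gamma),
                 log_marginal = lm1, weights = 1, best = g, c = 1,
                 x_labels = colnames(design$X), n_vars = length(gamma)),
            class = "posterior_model_set")
}

# Least-squares stats for one model on a design: coefficient center,
# scale matrix s^2 (W'W)^-1, residual df. The multivariate-t posterior
# implied by the reference prior underlying the marginal likelihood.
model_fit_stats <- function(design, gamma) {
  gamma <- check_gamma(design, gamma)
  act <- which(gamma == 1L)
  W <- cbind(design$X[, act, drop = FALSE], design$Z)
  n <- length(design$y)
  p <- ncol(W)
  if (n <= p) stop(sprintf("n = %d <= p = %d", n, p), call. = FALSE)
  qw <- qr(W, tol = RANK_TOL)
  if (qw$rank < p)
    stop("rank-deficient model design: ",
         paste(colnames(W)[qw$pivot[(qw$rank + 1L):p]], collapse = ", "),
         call. = FALSE)
  coef <- qr.coef(qw, design$y)
  rss <- sum(qr.resid(qw, design$y)^2)
  s2 <- rss / (n - p)
  R <- qr.R(qw)
  piv <- qw$pivot
  Rinv <- backsolve(R, diag(p))
  V <- tcrossprod(Rinv)              # (W'W)^-1 in pivoted order
  V[piv, piv] <- V                   # undo pivoting
  dimnames(V) <- list(colnames(W), colnames(W))
  list(gamma = gamma, active = act, coef = coef, cov_unit = V, s2 = s2,
       scale = s2 * V, df = n - p, rss = rss,
       n_x = length(act), labels = colnames(W))
}

#' Posterior distribution of the regression coefficients
#'
#' Per model, the coefficients have a multivariate-t posterior centered at
#' the least-squares estimate with scale `s^2 (W'W)^-1` and `n - p`
#' degrees of freedom; weather variables excluded from a model are exactly
#' zero within it. The model-averaged posterior is the mixture over the
#' window, summarised by seeded Monte-Carlo draws (posterior means, 95%
#' credible intervals, posterior inclusion probabilities). For a
#' single-model window the interval endpoints are the analytic t
#' quantiles. All summaries and draws are reported in natural units (per
#' degree day, per mm), undoing any column standardization of the design.
#'
#' @param design A `crop_design` (the one the models were searched on).
#' @param model_set A `posterior_model_set`.
#' @param draws Number of Monte-Carlo mixture draws (default 10000).
#' @param seed Integer seed for the mixture draws (required when the
#'   window has more than one model).
#' @param level Credible level (default 0.95).
#' @return An object of class `coef_posterior`: list with `table` (one row
#'   per weather column: mean, lower, upper, pip), `z_table` (trend and
#'   fixed-effect coefficients, weighted means), `x_draws` (draws x weather
#'   columns matrix), `weights`, `level`.
#' @export
coefficient_posterior <- function(design, model_set, draws = 10000L,
                                  seed = NULL, level = 0.95) {
  stopifnot(inherits(design, "crop_design"),
            inherits(model_set, "posterior_model_set"))
  n_mod <- length(model_set$keys)
  if (n_mod > 1L && is.null(seed))
    stop("`seed` is required for mixture draws over a multi-model window",
         call. = FALSE)
  fits <- lapply(model_set$gammas, function(g) model_fit_stats(design, g))
  p_x <- ncol(design$X)
  labels <- colnames(design$X)
  alpha <- (1 - level) / 2

  # per-model draw of the X-part coefficients (zeros where inactive)
  draw_model <- function(fit, m) {
    out <- matrix(0, m, p_x)
    if (fit$n_x > 0L) {
      idx <- seq_len(fit$n_x)
      L <- chol(fit$scale[idx, idx, drop = FALSE])
      z <- matrix(stats::rnorm(m * fit$n_x), m, fit$n_x)
      g <- stats::rchisq(m, df = fit$df)
      out[, fit$active] <- rep(fit$coef[idx], each = m) +
        (z %*% L) / sqrt(g / fit$df)
    }
    out
  }

  if (n_mod == 1L) {
    x_draws <- with_seed(if (is.null(seed)) 1L else seed,
                         draw_model(fits[[1L]], as.integer(draws)))
  } else {
    x_draws <- with_seed(seed, {
      counts <- drop(stats::rmultinom(1L, as.integer(draws),
                                      model_set$weights))
      blocks <- vector("list", n_mod)
      for (mi in seq_len(n_mod))
        blocks[[mi]] <- if (counts[mi] > 0L) draw_model(fits[[mi]], counts[mi])
                        else matrix(0, 0L, p_x)
      do.call(rbind, blocks)
    })
  }
  colnames(x_draws) <- labels

  pip <- numeric(p_x)
  mean_x <- numeric(p_x)
  for (mi in seq_len(n_mod)) {
    w <- model_set$weights[mi]
    act <- fits[[mi]]$active
    pip[act] <- pip[act] + w
    if (length(act) > 0L)
      mean_x[act] <- mean_x[act] +
        w * fits[[mi]]$coef[seq_along(act)]
  }

  lower <- upper <- numeric(p_x)
  ever_active <- pip > 0
  if (n_mod == 1L) {
    fit <- fits[[1L]]
    se <- sqrt(diag(fit$scale))[seq_len(fit$n_x)]
    tq <- stats::qt(1 - alpha, df = fit$df)
    lower[fit$active] <- fit$coef[seq_len(fit$n_x)] - tq * se
    upper[fit$active] <- fit$coef[seq_len(fit$n_x)] + tq * se
  } else {
    qs <- apply(x_draws, 2L, stats::quantile, probs = c(alpha, 1 - alpha),
                names = FALSE)
    lower <- qs[1L, ]
    upper <- qs[2L, ]
  }
  lower[!ever_active] <- 0
  upper[!ever_active] <- 0

  # report in natural units (per degree day, per mm) regardless of any
  # column standardization used for model comparison
  sc <- design$x_scale
  mean_x <- mean_x / sc
  lower <- lower / sc
  upper <- upper / sc
  x_draws <- sweep(x_draws, 2L, sc, "/")

  z_labels <- colnames(design$Z)
  z_mean <- numeric(ncol(design$Z))
  for (mi in seq_len(n_mod)) {
    fit <- fits[[mi]]
    z_mean <- z_mean + model_set$weights[mi] * fit$coef[fit$n_x + seq_along(z_mean)]
  }

  structure(list(
    table = data.frame(label = labels, mean = mean_x, lower = lower,
                       upper = upper, pip = pip, stringsAsFactors = FALSE),
    z_table = data.frame(label = z_labels, mean = z_mean,
                         stringsAsFactors = FALSE),
    x_draws = x_draws, fits = fits, weights = model_set$weights,
    level = level, seed = seed),
    class = "coef_posterior")
}

#' @export
print.coef_posterior <- function(x, ...) {
  cat(sprintf("Coefficient posterior over %d model(s); %d of %d weather variables ever active\n",
              length(x$weights), sum(x$table$pip > 0), nrow(x$table)))
  act <- x$table[x$table$pip > 0, , drop = FALSE]
  if (nrow(act) > 0L) print(utils::head(act[order(-act$pip), ], 10L), row.names = FALSE)
  invisible(x)
}

#' Model-averaged prediction of log yields
#'
#' Per-model prediction is `W_new %*% coef` with coefficients estimated on
#' the fitting design; the averaged prediction weights the per-model
#' predictions by the window's posterior model probabilities. The new
#' design must be column-aligned with the fitting design (same weather
#' labels, same fixed columns), which [design_subset()] and a rebuild of
#' the same panel under counterfactual weather both guarantee; every
#' county in the new rows must carry observations in the fitting rows so
#' its fixed effect is estimable.
#'
#' @param object A `posterior_model_set`.
#' @param design_new Design rows to predict (a `crop_design`).
#' @param design_fit Design the models were fit on.
#' @param ... Unused.
#' @return Numeric vector of predicted log yields, one per row of
#'   `design_new`.
#' @export
predict.posterior_model_set <- function(object, design_new, design_fit, ...) {
  stopifnot(inherits(design_new, "crop_design"),
            inherits(design_fit, "crop_design"))
  if (!identical(colnames(design_new$X), colnames(design_fit$X)) ||
      !identical(colnames(design_new$Z), colnames(design_fit$Z)))
    stop("`design_new` columns do not align with `design_fit`", call. = FALSE)
  fe_cols <- grep("^FE_", colnames(design_fit$Z))
  seen <- colSums(design_fit$Z[, fe_cols, drop = FALSE]) > 0
  used <- colSums(design_new$Z[, fe_cols, drop = FALSE]) > 0
  if (any(used & !seen))
    stop("counties absent from the fitting design: ",
         paste(sub("^FE_", "", colnames(design_fit$Z)[fe_cols][used & !seen]),
               collapse = ", "), call. = FALSE)
  pred <- numeric(nrow(design_new$X))
  for (mi in seq_along(object$keys)) {
    fit <- model_fit_stats(design_fit, object$gammas[[mi]])
    W_new <- cbind(design_new$X[, fit$active, drop = FALSE], design_new$Z)
    pred <- pred + object$weights[mi] * drop(W_new %*% fit$coef)
  }
  pred
}
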