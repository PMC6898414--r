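#' Predicted yield impact of a uniform warming scenario
#'
#' Shifts every daily minimum and maximum temperature by `delta` degrees C
#' (precipitation unchanged), rebuilds monthly degree days and the design
#' under both baseline and warmed weather, and reports the change in
#' predicted log yield. Because the trend and fixed-effect columns are
#' identical under both weather sets, they cancel exactly: the impact per
#' county-year is `(X_warm - X_base) %*% beta_X`, a linear functional of
#' the weather coefficients. The overall impact is the mean over all
#' county-years (counties equally weighted); per-county means are reported
#' for mapping. Intervals (default 95%): quantiles over posterior
#' coefficient draws for selection/averaging fits, delta-method normal
#' intervals from the coefficient covariance for OLS.
#'
#' @param daily Baseline daily weather covering all panel county-years.
#' @param panel Yield panel the model was fit on.
#' @param fit An `ols_fit`, or a `posterior_model_set` from
#'   [single_model_set()] / [occams_window()] fit on the same
#'   panel/weather/spec.
#' @param spec Specification the fit corresponds to.
#' @param delta Uniform warming in degrees C.
#' @param draws Posterior draws for interval construction (Bayesian fits).
#' @param seed Seed for the posterior draws.
#' @param level Interval level (default 0.95).
#' @param thresholds Degree-day thresholds.
#' @return An object of class `warming_impact`: list with `delta`,
#'   `overall` (mean change in log yield), `interval` (lower/upper),
#'   `per_county` (data frame `county_id`, `mean_delta_log_yield`),
#'   `per_row` (county-year changes), `method`.
#' @export
warming_impact <- function(daily, panel, fit, spec, delta, draws = 4000L,
                           seed = 1L, level = 0.95,
                           thresholds = degree_day_thresholds()) {
  monthly_base <- monthly_features(daily, thresholds)
  monthly_warm <- monthly_features(apply_uniform_warming(daily, delta),
                                   thresholds)
  # natural-unit columns here: the weather difference and the fit's
  # natural-unit coefficients pair up regardless of how the fitting
  # design was scaled for model comparison
  d_base <- build_design(panel, monthly_base, spec, standardize = FALSE)
  d_warm <- build_design(panel, monthly_warm, spec, standardize = FALSE)
  stopifnot(identical(d_base$Z, d_warm$Z))  # fixed part cancels exactly
  dX <- d_warm$X - d_base$X

  alpha <- (1 - level) / 2
  if (inherits(fit, "ols_fit")) {
    if (!identical(fit$x_labels, colnames(dX)))
      stop("`fit` does not correspond to specification ", spec, call. = FALSE)
    beta_x <- fit$coef[seq_len(fit$n_x)] / fit$x_scale
    d_row <- drop(dX %*% beta_x)
    dbar <- colMeans(dX) / fit$x_scale
    v <- drop(t(dbar) %*% fit$cov[seq_len(fit$n_x), seq_len(fit$n_x)] %*% dbar)
    overall <- mean(d_row)
    halfw <- stats::qnorm(1 - alpha) * sqrt(v)
    interval <- c(lower = overall - halfw, upper = overall + halfw)
    method <- "ols"
  } else if (inherits(fit, "posterior_model_set")) {
    if (!identical(fit$x_labels, colnames(dX)))
      stop("`fit` does not correspond to specification ", spec, call. = FALSE)
    post <- coefficient_posterior(d_base, fit, draws = draws, seed = seed,
                                  level = level)
    d_row <- drop(dX %*% post$table$mean)
    overall <- mean(d_row)
    dbar <- colMeans(dX)
    delta_draws <- drop(post$x_draws %*% dbar)
    interval <- stats::quantile(delta_draws, c(alpha, 1 - alpha), names = FALSE)
    names(interval) <- c("lower", "upper")
    method <- if (length(fit$keys) == 1L) "bvs" else "bma"
  } else {
    stop("`fit` must be an `ols_fit` or a `posterior_model_set`",
         call. = FALSE)
  }

  pc <- rowsum(d_row, group = d_base$row_keys$county_id, reorder = TRUE)
  cnt <- as.vector(table(d_base$row_keys$county_id)[rownames(pc)])
  per_county <- data.frame(county_id = rownames(pc),
                           mean_delta_log_yield = pc[, 1L] / cnt,
                           stringsAsFactors = FALSE, row.names = NULL)
  structure(list(delta = delta, overall = overall, interval = interval,
                 per_county = per_county, per_row = d_row,
                 method = method, level = level, spec = spec),
            class = "warming_impact")
}

#' @export
print.warming_impact <- function(x, ...) {
  cat(sprintf("Uniform +%g C warming, %s (%s): mean change in log yield %.4f [%.4f, %.4f]\n",
              x$delta, x$spec, x$method, x$overall,
              x$interval["lower"], x$interval["upper"]))
  invisible(x)
}
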