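#' Empirical precipitation percentile for a month
#'
#' Linear-interpolation (type 7) percentile of monthly precipitation
#' pooled over all county-years in the fitting sample.
#'
#' @param monthly Monthly features data frame.
#' @param month Calendar month (integer).
#' @param q Percentile in [0, 100].
#' @return Precipitation value in mm.
#' @export
#' @examples
#' m <- data.frame(county_id = "a", state_id = "s", year = 1,
#'                 month = 7, gdd = 0, hdd = 0, prec = c(1, 2, 3, 4))
#' precipitation_percentile(m, 7, 25)  # 1.75
precipitation_percentile <- function(monthly, month, q) {
  v <- monthly$prec[monthly$month == month]
  if (length(v) == 0L)
    stop("no monthly features for month ", month, call. = FALSE)
  unname(stats::quantile(v, probs = q / 100, type = 7))
}

#' Conditional marginal effect of a monthly degree-day variable
#'
#' In the interaction specifications the effect of one more degree day of
#' family `family` in month `m` on log yield, holding precipitation at
#' `prec_value`, is
#' `b_main + b_xPrec * prec_value + b_xPrec2 * prec_value^2`,
#' combining the main coefficient with the precipitation and squared-
#' precipitation interaction coefficients (coefficients absent from the
#' specification, or from every model in a posterior window, contribute
#' exactly 0). For seasonal specifications (M1/M2) `month` must be `NULL`
#' and the seasonal analogue applies. Intervals: posterior draws for
#' Bayesian fits, delta method for OLS.
#'
#' @param fit An `ols_fit` or `posterior_model_set`.
#' @param design The fitting `crop_design` (needed for posterior draws and
#'   label lookup).
#' @param family `"GDD"` or `"HDD"`.
#' @param month Month 4-10 for monthly specifications, `NULL` for
#'   seasonal ones.
#' @param prec_value Precipitation level in mm (e.g. from
#'   [precipitation_percentile()]).
#' @param draws,seed Posterior draw settings (Bayesian fits).
#' @param level Interval level (default 0.95).
#' @param post Optional precomputed [coefficient_posterior()] for `fit`,
#'   to reuse draws across calls.
#' @return An object of class `conditional_effect`: list with `effect`
#'   (change in log yield per degree day), `interval`, `family`, `month`,
#'   `prec_value`, `method`.
#' @export
conditional_marginal_effect <- function(fit, design, family = c("GDD", "HDD"),
                                        month = NULL, prec_value,
                                        draws = 4000L, seed = 1L,
                                        level = 0.95, post = NULL) {
  stopifnot(inherits(design, "crop_design"))
  family <- match.arg(family)
  monthly_spec <- design$spec %in% c("M3", "M4")
  if (monthly_spec) {
    if (is.null(month) || !(month %in% season_months()))
      stop("`month` must be in 4..10 for specification ", design$spec,
           call. = FALSE)
    suffix <- paste0("_", month)
  } else {
    if (!is.null(month))
      stop("`month` is not applicable to seasonal specification ",
           design$spec, "; the effect is season-wide", call. = FALSE)
    suffix <- ""
  }
  labels <- colnames(design$X)
  targets <- paste0(c(family, paste0(family, "xPrec"),
                      paste0(family, "xPrec2")), suffix)
  mult <- c(1, prec_value, prec_value^2)
  a <- numeric(length(labels))
  present <- match(targets, labels)
  a[present[!is.na(present)]] <- mult[!is.na(present)]

  alpha <- (1 - level) / 2
  if (inherits(fit, "ols_fit")) {
    a_std <- a / fit$x_scale  # natural-unit functional of scaled coefficients
    eff <- sum(a_std * fit$coef[seq_len(fit$n_x)])
    v <- drop(t(a_std) %*% fit$cov[seq_len(fit$n_x), seq_len(fit$n_x)] %*% a_std)
    halfw <- stats::qnorm(1 - alpha) * sqrt(v)
    interval <- c(lower = eff - halfw, upper = eff + halfw)
    method <- "ols"
  } else if (inherits(fit, "posterior_model_set")) {
    if (is.null(post))
      post <- coefficient_posterior(design, fit, draws = draws, seed = seed,
                                    level = level)
    eff <- sum(a * post$table$mean)
    eff_draws <- drop(post$x_draws %*% a)
    interval <- stats::quantile(eff_draws, c(alpha, 1 - alpha), names = FALSE)
    names(interval) <- c("lower", "upper")
    method <- if (length(fit$keys) == 1L) "bvs" else "bma"
  } else {
    stop("`fit` must be an `ols_fit` or a `posterior_model_set`",
         call. = FALSE)
  }
  structure(list(effect = eff, interval = interval, family = family,
                 month = month, prec_value = prec_value, method = method,
                 level = level),
            class = "conditional_effect")
}

#' @export
print.conditional_effect <- function(x, ...) {
  cat(sprintf("%s%s effect at %.1f mm: %.5f log yield per degree day [%.5f, %.5f] (%s)\n",
              x$family, if (is.null(x$month)) " (season)" else
                paste0(" month ", x$month),
              x$prec_value, x$effect,
              x$interval["lower"], x$interval["upper"], x$method))
  invisible(x)
}

#' Table of conditional effects across months and precipitation levels
#'
#' Convenience wrapper evaluating [conditional_marginal_effect()] for both
#' degree-day families over months 4-10 at the stated precipitation
#' percentiles of the fitting sample (low = 25th, high = 75th by
#' default), mirroring the month-by-month effect panels of the analysis.
#'
#' @param fit An `ols_fit` or `posterior_model_set`.
#' @param design The fitting `crop_design` (a monthly specification).
#' @param monthly Monthly features the percentiles are computed on.
#' @param levels Percentiles in [0, 100] (default `c(25, 75)`).
#' @param draws,seed,level See [conditional_marginal_effect()].
#' @return Data frame with one row per (family, month, level):
#'   `family`, `month`, `percentile`, `prec_value`, `effect`, `lower`,
#'   `upper`.
#' @export
conditional_effects_table <- function(fit, design, monthly,
                                      levels = c(25, 75), draws = 4000L,
                                      seed = 1L, level = 0.95) {
  stopifnot(design$spec %in% c("M3", "M4"))
  post <- if (inherits(fit, "posterior_model_set"))
    coefficient_posterior(design, fit, draws = draws, seed = seed,
                          level = level)
  rows <- list()
  for (fam in c("GDD", "HDD")) {
    for (m in season_months()) {
      for (q in levels) {
        pv <- precipitation_percentile(monthly, m, q)
        ce <- conditional_marginal_effect(fit, design, family = fam,
                                          month = m, prec_value = pv,
                                          draws = draws, seed = seed,
                                          level = level, post = post)
        rows[[length(rows) + 1L]] <- data.frame(
          family = fam, month = m, percentile = q, prec_value = pv,
          effect = ce$effect, lower = ce$interval["lower"],
          upper = ce$interval["upper"], stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
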