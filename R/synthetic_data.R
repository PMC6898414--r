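#' Configuration for the synthetic daily-weather generator
#'
#' Describes a balanced multi-state, multi-county, multi-year panel of
#' daily weather with the statistical structure the yield analysis
#' assumes: an annual sinusoid in the daily mean temperature peaking in
#' midsummer, a time-invariant county offset (a latitude proxy: colder
#' counties are "northern"), a constant mean diurnal range shared by tmin
#' and tmax, AR(1) day-to-day noise, and monthly precipitation totals
#' drawn from a gamma law and spread uniformly over the month's days.
#' Defaults emulate a Corn-Belt county panel over 1981-2017.
#'
#' @param n_states Number of states.
#' @param counties_per_state Counties per state (balanced).
#' @param years Integer vector of consecutive years, e.g. `1981:2017`.
#' @param annual_mean_temp Panel-wide annual mean temperature, degrees C.
#' @param seasonal_mean_amplitude Half-range of the annual cycle of daily
#'   mean temperature, degrees C.
#' @param seasonal_peak_doy Day of year at which the cycle peaks.
#' @param county_offset_sd SD of the per-county temperature offset, degrees C.
#' @param diurnal_range_mean Mean tmax - tmin, degrees C.
#' @param daily_noise_sd Stationary SD of the AR(1) daily noise, degrees C.
#' @param daily_noise_autocorr AR(1) coefficient, in [0, 1).
#' @param precip_shape,precip_scale Gamma shape (> 0, unitless) and scale
#'   (> 0, mm) of the monthly precipitation total.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return An object of class `weather_sim_config`.
#' @export
weather_sim_config <- function(n_states = 3L,
                               counties_per_state = 5L,
                               years = 1981:2017,
                               annual_mean_temp = 10,
                               seasonal_mean_amplitude = 14,
                               seasonal_peak_doy = 200,
                               county_offset_sd = 1.5,
                               diurnal_range_mean = 10,
                               daily_noise_sd = 3,
                               daily_noise_autocorr = 0.6,
                               precip_shape = 4,
                               precip_scale = 22,
                               seed = 1L) {
  cfg <- list(n_states = as.integer(n_states),
              counties_per_state = as.integer(counties_per_state),
              years = as.integer(years),
              annual_mean_temp = annual_mean_temp,
              seasonal_mean_amplitude = seasonal_mean_amplitude,
              seasonal_peak_doy = seasonal_peak_doy,
              county_offset_sd = county_offset_sd,
              diurnal_range_mean = diurnal_range_mean,
              daily_noise_sd = daily_noise_sd,
              daily_noise_autocorr = daily_noise_autocorr,
              precip_shape = precip_shape,
              precip_scale = precip_scale,
              seed = as.integer(seed))
  check_field <- function(ok, field, what) {
    if (!ok) stop(sprintf("invalid `%s`: %s", field, what), call. = FALSE)
  }
  check_field(cfg$n_states >= 1L, "n_states", "must be >= 1")
  check_field(cfg$counties_per_state >= 1L, "counties_per_state", "must be >= 1")
  check_field(length(cfg$years) >= 1L && !anyNA(cfg$years), "years",
              "must be a nonempty integer vector")
  check_field(cfg$seasonal_mean_amplitude >= 0, "seasonal_mean_amplitude",
              "must be >= 0")
  check_field(cfg$seasonal_peak_doy >= 1 && cfg$seasonal_peak_doy <= 366,
              "seasonal_peak_doy", "must lie in 1..366")
  check_field(cfg$county_offset_sd >= 0, "county_offset_sd", "must be >= 0")
  check_field(cfg$diurnal_range_mean >= 0, "diurnal_range_mean", "must be >= 0")
  check_field(cfg$daily_noise_sd >= 0, "daily_noise_sd", "must be >= 0")
  check_field(cfg$daily_noise_autocorr >= 0 && cfg$daily_noise_autocorr < 1,
              "daily_noise_autocorr", "must lie in [0, 1)")
  check_field(cfg$precip_shape > 0, "precip_shape", "must be > 0")
  check_field(cfg$precip_scale > 0, "precip_scale", "must be > 0")
  structure(cfg, class = "weather_sim_config")
}

#' Generate a synthetic daily weather panel
#'
#' One record per county per calendar day (Gregorian, with leap days) per
#' year. The daily mean temperature is
#' `annual_mean_temp + county offset + amplitude * cos(2 pi (doy - peak) / 365.25)`
#' plus stationary AR(1) noise shared by tmin and tmax; tmin/tmax sit a
#' half diurnal range below/above the mean, so `tmax >= tmin` always.
#' Monthly precipitation totals are gamma draws split equally over the
#' month's days.
#'
#' @param config A [weather_sim_config()].
#' @return Data frame with columns `county_id`, `state_id`, `date`,
#'   `tmin`, `tmax`, `prec` (mm/day).
#' @export
generate_weather <- function(config) {
  stopifnot(inherits(config, "weather_sim_config"))
  with_seed(config$seed, {
    states <- sprintf("S%d", seq_len(config$n_states))
    counties <- as.vector(t(outer(states, seq_len(config$counties_per_state),
                                  function(s, k) sprintf("%s_C%02d", s, k))))
    county_state <- rep(states, each = config$counties_per_state)
    offsets <- stats::rnorm(length(counties), 0, config$county_offset_sd)

    dates <- seq.Date(as.Date(sprintf("%d-01-01", min(config$years))),
                      as.Date(sprintf("%d-12-31", max(config$years))),
                      by = "day")
    dates <- dates[as.integer(format(dates, "%Y")) %in% config$years]
    doy <- as.integer(format(dates, "%j"))
    seasonal <- config$annual_mean_temp + config$seasonal_mean_amplitude *
      cos(2 * pi * (doy - config$seasonal_peak_doy) / 365.25)
    nd <- length(dates)
    month_key <- format(dates, "%Y-%m")
    month_runs <- rle(month_key)$lengths

    pieces <- vector("list", length(counties))
    for (ci in seq_along(counties)) {
      rho <- config$daily_noise_autocorr
      innov_sd <- config$daily_noise_sd * sqrt(1 - rho^2)
      z <- stats::rnorm(nd, 0, 1)
      e <- numeric(nd)
      if (nd > 0L) {
        e[1L] <- config$daily_noise_sd * z[1L]
        if (nd > 1L)
          for (t in 2:nd) e[t] <- rho * e[t - 1L] + innov_sd * z[t]
      }
      daily_mean <- seasonal + offsets[ci] + e
      half_range <- config$diurnal_range_mean / 2
      monthly_prec <- stats::rgamma(length(month_runs),
                                    shape = config$precip_shape,
                                    scale = config$precip_scale)
      prec <- rep(monthly_prec / month_runs, times = month_runs)
      pieces[[ci]] <- data.frame(
        county_id = counties[ci], state_id = county_state[ci],
        date = dates,
        tmin = daily_mean - half_range, tmax = daily_mean + half_range,
        prec = prec, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, pieces)
    rownames(out) <- NULL
    out
  })
}

#' Configuration for the synthetic yield panel
#'
#' Ground-truth parameters of the log-yield data-generating process: a
#' sparse coefficient vector on the 56 monthly weather regressors of the
#' full monthly-interaction specification (M4), county fixed effects,
#' state-specific quadratic time trends and i.i.d. Gaussian noise.
#'
#' @param true_gamma 0/1 vector of length 56 over the M4 weather columns
#'   (order given by [m4_labels()]), or a character vector of active
#'   column labels. Default: a sparse 5-variable truth with beneficial
#'   spring/early-summer GDD, harmful July/August HDD and beneficial July
#'   rainfall.
#' @param true_beta Coefficients (log-yield units per regressor unit) for
#'   the active columns, in label order.
#' @param fe_sd SD of county fixed effects, log-yield units.
#' @param trend_coefs Matrix with one row per state and columns
#'   `(linear, quadratic)` for the per-state time trend, or `NULL` for a
#'   common 1.5 percent/year trend with mild curvature.
#' @param noise_sd SD of the idiosyncratic error, log-yield units (> 0).
#' @param seed Integer seed.
#' @return An object of class `panel_sim_config`.
#' @export
panel_sim_config <- function(true_gamma = NULL,
                             true_beta = NULL,
                             fe_sd = 0.2,
                             trend_coefs = NULL,
                             noise_sd = 0.10,
                             seed = 1L) {
  labels <- m4_labels()
  if (is.null(true_gamma)) {
    active <- default_true_active()
    true_gamma <- as.integer(labels %in% names(active))
    if (is.null(true_beta)) true_beta <- unname(active[labels[true_gamma == 1L]])
  } else if (is.character(true_gamma)) {
    bad <- setdiff(true_gamma, labels)
    if (length(bad) > 0L)
      stop("unknown M4 labels in `true_gamma`: ", paste(bad, collapse = ", "),
           call. = FALSE)
    true_gamma <- as.integer(labels %in% true_gamma)
  } else {
    true_gamma <- as.integer(true_gamma)
    if (length(true_gamma) != length(labels) || !all(true_gamma %in% 0:1))
      stop("`true_gamma` must be a 0/1 vector over the 56 M4 columns",
           call. = FALSE)
  }
  if (is.null(true_beta))
    stop("`true_beta` must be supplied with a custom `true_gamma`",
         call. = FALSE)
  if (length(true_beta) != sum(true_gamma))
    stop("`true_beta` length must equal the number of active entries in `true_gamma`",
         call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be >= 0", call. = FALSE)
  if (fe_sd < 0) stop("`fe_sd` must be >= 0", call. = FALSE)
  structure(list(true_gamma = true_gamma, true_beta = as.numeric(true_beta),
                 fe_sd = fe_sd, trend_coefs = trend_coefs,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "panel_sim_config")
}

# Default sparse truth over the M4 columns. Magnitudes are paper-scale
# (log-yield per degree-day or per mm) and sized to be identifiable at the
# default panel dimensions; see the methods vignette.
default_true_active <- function() {
  c(GDD_5 = 1.6e-3, GDD_6 = 1.4e-3, HDD_7 = -1e-2, HDD_8 = -1.4e-2,
    Prec_7 = 2e-3)
}

#' Generate a synthetic log-yield panel from daily weather
#'
#' Builds the 56 monthly weather regressors of the full specification from
#' the supplied daily weather, then generates
#' `log yield = county effect + state quadratic trend + X_active beta + noise`.
#' The returned ground truth records everything needed for
#' parameter-recovery checks and zero-noise round-trip identities.
#'
#' @param weather Daily weather data frame (e.g. from [generate_weather()]).
#' @param config A [panel_sim_config()].
#' @param thresholds Degree-day thresholds used to build the true features.
#' @return List with elements `panel` (data frame `county_id`, `state_id`,
#'   `year`, `log_yield`) and `truth` (list: `true_gamma`, `true_beta`,
#'   `labels`, `fixed_effects`, `trend_coefs`, `noise_sd`, `thresholds`).
#' @export
generate_panel <- function(weather, config = panel_sim_config(),
                           thresholds = degree_day_thresholds()) {
  stopifnot(inherits(config, "panel_sim_config"))
  monthly <- monthly_features(weather, thresholds)
  keys <- unique(monthly[, c("county_id", "state_id", "year")])
  keys <- keys[order(keys$county_id, keys$year), ]
  rownames(keys) <- NULL

  X <- weather_design_columns(monthly, keys, spec = "M4")
  labels <- colnames(X)
  act <- which(config$true_gamma == 1L)
  xb <- if (length(act) > 0L) drop(X[, act, drop = FALSE] %*% config$true_beta)
        else numeric(nrow(keys))

  states <- sort(unique(keys$state_id))
  trend_coefs <- config$trend_coefs
  if (is.null(trend_coefs))
    trend_coefs <- matrix(c(rep(0.015, length(states)), rep(-5e-5, length(states))),
                          ncol = 2, dimnames = list(states, c("linear", "quadratic")))
  if (nrow(trend_coefs) != length(states))
    stop("`trend_coefs` must have one row per state (",
         length(states), " states present)", call. = FALSE)
  time_t <- keys$year - min(keys$year) + 1L
  si <- match(keys$state_id, states)
  trend <- trend_coefs[si, 1L] * time_t + trend_coefs[si, 2L] * time_t^2

  counties <- sort(unique(keys$county_id))
  with_seed(config$seed, {
    fe <- stats::rnorm(length(counties), 0, config$fe_sd)
    names(fe) <- counties
    eps <- stats::rnorm(nrow(keys), 0, config$noise_sd)
    panel <- data.frame(county_id = keys$county_id, state_id = keys$state_id,
                        year = keys$year,
                        log_yield = fe[keys$county_id] + trend + xb + eps,
                        stringsAsFactors = FALSE, row.names = NULL)
    truth <- list(true_gamma = config$true_gamma,
                  true_beta = config$true_beta,
                  labels = labels,
                  active_labels = labels[act],
                  fixed_effects = fe,
                  trend_coefs = trend_coefs,
                  noise_sd = config$noise_sd,
                  thresholds = thresholds)
    list(panel = panel, truth = truth)
  })
}

# evaluate an expression under a temporary RNG seed, restoring global state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
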