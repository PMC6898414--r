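#' Degree-day thresholds
#'
#' Bundle of the base and cap temperatures used for growing degree days
#' (GDD) and heating degree days (HDD). The defaults (base 10 degrees C,
#' cap 29 degrees C) are the standard maize thresholds: GDD accumulates
#' between base and cap, HDD accumulates above the cap.
#'
#' @param base Base temperature in degrees C (default 10).
#' @param upper Cap temperature in degrees C (default 29); must exceed `base`.
#' @return An object of class `dd_thresholds`.
#' @export
#' @examples
#' degree_day_thresholds()
degree_day_thresholds <- function(base = 10, upper = 29) {
  if (!is.numeric(base) || length(base) != 1L || !is.finite(base))
    stop("`base` must be a single finite number", call. = FALSE)
  if (!is.numeric(upper) || length(upper) != 1L || !is.finite(upper))
    stop("`upper` must be a single finite number", call. = FALSE)
  if (upper <= base)
    stop("`upper` must exceed `base`", call. = FALSE)
  structure(list(base = base, upper = upper), class = "dd_thresholds")
}

#' @export
print.dd_thresholds <- function(x, ...) {
  cat(sprintf("Degree-day thresholds: base %g C, cap %g C\n", x$base, x$upper))
  invisible(x)
}

# Degree days above a single threshold for a single-sine day.
#
# The within-day temperature is modelled as one symmetric sine wave
# through tmin and tmax: T(t) = M + A sin(t), M = (tmax + tmin)/2,
# A = (tmax - tmin)/2.  The time-average of max(0, T(t) - L) has the
# closed form (Baskerville-Emin):
#   0                                        if tmax <= L
#   M - L                                    if tmin >= L
#   [ (M - L)(pi/2 - theta) + A cos(theta) ] / pi   otherwise,
# with theta = asin((L - M)/A).  Vectorised over tmin/tmax.
dd_above <- function(tmin, tmax, threshold) {
  m <- (tmax + tmin) / 2
  a <- (tmax - tmin) / 2
  out <- numeric(length(m))
  below <- tmax <= threshold
  above <- tmin >= threshold
  mid <- !below & !above
  out[above] <- m[above] - threshold
  if (any(mid)) {
    theta <- asin((threshold - m[mid]) / a[mid])
    out[mid] <- ((m[mid] - threshold) * (pi / 2 - theta) +
                   a[mid] * cos(theta)) / pi
  }
  out
}

#' Degree days for one day from min/max temperature
#'
#' Integrates thermal time over a single day whose temperature course is a
#' single sine wave through `tmin` and `tmax`. With a cap (`upper` given)
#' the integrand is `max(0, min(T, upper) - lower)` -- capped GDD
#' semantics, temperatures above the cap accrue at the cap rate. Without a
#' cap (`upper = NULL`) it is `max(0, T - lower)` -- HDD semantics for the
#' excess above `lower`. A degenerate day with `tmin == tmax` is treated
#' as constant temperature (the analytic limit of the sine).
#'
#' @param tmin,tmax Daily minimum and maximum temperature, degrees C.
#'   Vectorised; `tmax >= tmin` required elementwise.
#' @param lower Lower threshold, degrees C.
#' @param upper Optional cap, degrees C (`> lower`), or `NULL` for no cap.
#' @return Numeric vector of degree days (degrees C x day).
#' @export
#' @examples
#' daily_degree_days(20, 20, lower = 10, upper = 29)  # 10
#' daily_degree_days(30, 36, lower = 29)              # mean(30,36) - 29 = 4
daily_degree_days <- function(tmin, tmax, lower, upper = NULL) {
  if (length(tmin) != length(tmax))
    stop("`tmin` and `tmax` must have equal length", call. = FALSE)
  if (any(tmax < tmin))
    stop("`tmax` must be >= `tmin` for every day", call. = FALSE)
  if (!is.null(upper) && upper <= lower)
    stop("`upper` must exceed `lower`", call. = FALSE)
  dd <- dd_above(tmin, tmax, lower)
  if (!is.null(upper)) dd <- dd - dd_above(tmin, tmax, upper)
  dd
}

#' Aggregate daily weather to monthly degree days and precipitation
#'
#' Computes, for every county-year-month, the monthly growing degree days
#' (sum of daily capped degree days between base and cap), heating degree
#' days (sum of daily degree days above the cap) and total precipitation.
#' Every calendar day of a month must be present; partial months are an
#' error, not a silent truncation.
#'
#' @param daily Data frame of daily weather with columns `county_id`,
#'   `state_id`, `date` (Date or ISO-8601 string), `tmin`, `tmax`, `prec`.
#' @param thresholds A [degree_day_thresholds()] object.
#' @return Data frame with columns `county_id`, `state_id`, `year`,
#'   `month`, `gdd`, `hdd`, `prec`, one row per county-year-month, sorted
#'   by county, year, month.
#' @export
monthly_features <- function(daily, thresholds = degree_day_thresholds()) {
  stopifnot(inherits(thresholds, "dd_thresholds"))
  daily <- validate_daily_weather(daily)
  date <- daily$date
  year <- as.integer(format(date, "%Y"))
  month <- as.integer(format(date, "%m"))

  key <- paste(daily$county_id, year, month, sep = "\r")
  n_days <- tabulate(factor(key, levels = unique(key)))
  names(n_days) <- unique(key)
  expected <- days_in_month(
    as.integer(sub("\r.*", "", sub("^[^\r]*\r", "", names(n_days)))),
    as.integer(sub(".*\r", "", names(n_days))))
  bad <- names(n_days)[n_days != expected]
  if (length(bad) > 0L) {
    stop("incomplete months (county/year/month): ",
         paste(gsub("\r", "/", utils::head(bad, 5L)), collapse = ", "),
         if (length(bad) > 5L) sprintf(" and %d more", length(bad) - 5L),
         call. = FALSE)
  }

  gdd_day <- daily_degree_days(daily$tmin, daily$tmax,
                               lower = thresholds$base,
                               upper = thresholds$upper)
  hdd_day <- daily_degree_days(daily$tmin, daily$tmax,
                               lower = thresholds$upper)
  f <- factor(key, levels = unique(key))
  agg <- rowsum(cbind(gdd = gdd_day, hdd = hdd_day, prec = daily$prec),
                group = f, reorder = FALSE)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  state_of <- county_state_map(daily)
  out <- data.frame(
    county_id = vapply(parts, `[`, "", 1L),
    year = as.integer(vapply(parts, `[`, "", 2L)),
    month = as.integer(vapply(parts, `[`, "", 3L)),
    gdd = agg[, "gdd"], hdd = agg[, "hdd"], prec = agg[, "prec"],
    stringsAsFactors = FALSE, row.names = NULL)
  out$state_id <- unname(state_of[out$county_id])
  out <- out[order(out$county_id, out$year, out$month),
             c("county_id", "state_id", "year", "month", "gdd", "hdd", "prec")]
  rownames(out) <- NULL
  out
}

#' Uniform warming counterfactual on daily weather
#'
#' Adds a constant temperature shift to every daily minimum and maximum;
#' precipitation and record order are unchanged. Degree days under the
#' scenario are obtained by re-running [monthly_features()] on the result,
#' so the nonlinear response of HDD/GDD to warming emerges from the
#' within-day sine integral rather than from shifting monthly totals.
#'
#' @param daily Data frame of daily weather (see [monthly_features()]).
#' @param delta Temperature shift in degrees C.
#' @return The daily weather data frame with shifted `tmin` and `tmax`.
#' @export
apply_uniform_warming <- function(daily, delta) {
  stopifnot(is.numeric(delta), length(delta) == 1L, is.finite(delta))
  daily$tmin <- daily$tmin + delta
  daily$tmax <- daily$tmax + delta
  daily
}

# number of days in (month, year) pairs, Gregorian with leap days
days_in_month <- function(year, month) {
  base <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  leap <- (year %% 4L == 0L & year %% 100L != 0L) | year %% 400L == 0L
  out <- base[month]
  out[month == 2L & leap] <- 29L
  out
}

# county -> state lookup; errors if a county maps to two states
county_state_map <- function(df) {
  m <- unique(df[, c("county_id", "state_id")])
  dup <- unique(m$county_id[duplicated(m$county_id)])
  if (length(dup) > 0L)
    stop("county mapped to more than one state: ",
         paste(dup, collapse = ", "), call. = FALSE)
  stats::setNames(m$state_id, m$county_id)
}

validate_daily_weather <- function(daily) {
  need <- c("county_id", "state_id", "date", "tmin", "tmax", "prec")
  miss <- setdiff(need, names(daily))
  if (length(miss) > 0L)
    stop("daily weather is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!inherits(daily$date, "Date")) daily$date <- as.Date(daily$date)
  if (anyNA(daily$date))
    stop("unparseable dates in daily weather", call. = FALSE)
  bad <- which(daily$tmax < daily$tmin)
  if (length(bad) > 0L)
    stop("tmax < tmin at rows: ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  if (any(daily$prec < 0))
    stop("negative precipitation in daily weather", call. = FALSE)
  daily
}
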