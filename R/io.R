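#' Read and write the package's CSV artifacts
#'
#' Daily weather tables carry columns `county_id, state_id, date, tmin_c,
#' tmax_c, prec_mm` (ISO-8601 dates); yield panels carry `county_id,
#' state_id, year, log_yield`; monthly feature tables carry `county_id,
#' state_id, year, month, gdd, hdd, prec`. Readers validate on load and
#' report offending line numbers; write-then-read round trips are
#' lossless up to floating-point text representation.
#'
#' @param path File path.
#' @param daily,panel,monthly Data frames in the package's internal
#'   schemas (as produced by [generate_weather()], [generate_panel()],
#'   [monthly_features()]).
#' @return Readers return validated data frames in the internal schemas;
#'   writers return `path` invisibly.
#' @name cropbma_io
NULL

#' @rdname cropbma_io
#' @export
write_daily_weather <- function(daily, path) {
  out <- data.frame(county_id = daily$county_id, state_id = daily$state_id,
                    date = format(as.Date(daily$date), "%Y-%m-%d"),
                    tmin_c = daily$tmin, tmax_c = daily$tmax,
                    prec_mm = daily$prec)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname cropbma_io
#' @export
read_daily_weather <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("county_id", "state_id", "date", "tmin_c", "tmax_c", "prec_mm")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("daily weather CSV missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in c("tmin_c", "tmax_c", "prec_mm"))
    if (!is.numeric(df[[col]]))
      stop("non-numeric values in column ", col, call. = FALSE)
  date <- as.Date(df$date, format = "%Y-%m-%d")
  if (anyNA(date))
    stop("unparseable ISO-8601 dates at lines: ",
         paste(utils::head(which(is.na(date)) + 1L, 5L), collapse = ", "),
         call. = FALSE)
  bad <- which(df$tmax_c < df$tmin_c)
  if (length(bad) > 0L)
    stop("tmax < tmin at lines: ",
         paste(utils::head(bad + 1L, 5L), collapse = ", "), call. = FALSE)
  bad <- which(df$prec_mm < 0)
  if (length(bad) > 0L)
    stop("negative precipitation at lines: ",
         paste(utils::head(bad + 1L, 5L), collapse = ", "), call. = FALSE)
  data.frame(county_id = df$county_id, state_id = df$state_id, date = date,
             tmin = df$tmin_c, tmax = df$tmax_c, prec = df$prec_mm,
             stringsAsFactors = FALSE)
}

#' @rdname cropbma_io
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(panel[, c("county_id", "state_id", "year", "log_yield")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname cropbma_io
#' @export
read_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("county_id", "state_id", "year", "log_yield")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("panel CSV missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(df$log_yield) || !is.numeric(df$year))
    stop("non-numeric year or log_yield in panel CSV", call. = FALSE)
  key <- paste(df$county_id, df$year)
  if (anyDuplicated(key))
    stop("duplicate (county, year) at lines: ",
         paste(utils::head(which(duplicated(key)) + 1L, 5L), collapse = ", "),
         call. = FALSE)
  county_state_map(df)
  df[, need]
}

#' @rdname cropbma_io
#' @export
write_monthly_features <- function(monthly, path) {
  utils::write.csv(monthly[, c("county_id", "state_id", "year", "month",
                               "gdd", "hdd", "prec")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname cropbma_io
#' @export
read_monthly_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("county_id", "state_id", "year", "month", "gdd", "hdd", "prec")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("monthly features CSV missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  df[, need]
}

#' Run the full synthetic-analysis pipeline
#'
#' Executes simulate, features, fit, cross-validation, warming scenarios
#' and conditional effects as requested and writes every artifact (CSV /
#' JSON) plus a manifest (configuration echo, seed, package version, file
#' checksums) into `out_dir`. All randomness derives from `config$seed`
#' through fixed per-stage offsets, so a rerun with the same configuration
#' reproduces every artifact.
#'
#' @param config Named list: `seed` (required); optional
#'   `weather_config` ([weather_sim_config()]), `panel_config`
#'   ([panel_sim_config()]), `spec` (default `"M4"`), `methods` (default
#'   `c("ols", "bvs", "bma")`), `n_iter`, `burn_in`, `c`, `k` (CV folds,
#'   default 10), `cv_n_iter`, `deltas` (default `c(1, 2)`), `draws`,
#'   `run_cv`, `run_scenarios`, `run_effects` (logical switches, default
#'   `TRUE`).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.null(config$seed))
    stop("`config$seed` is required: every stochastic stage is seeded from it",
         call. = FALSE)
  seed <- as.integer(config$seed)
  spec <- config$spec %||% "M4"
  methods <- config$methods %||% c("ols", "bvs", "bma")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- character(0)
  record <- function(p) { art[[length(art) + 1L]] <<- p; p }

  wcfg <- config$weather_config %||% weather_sim_config(seed = seed)
  pcfg <- config$panel_config %||% panel_sim_config(seed = seed + 1L)
  daily <- generate_weather(wcfg)
  sim <- generate_panel(daily, pcfg)
  write_daily_weather(daily, record(file.path(out_dir, "daily_weather.csv")))
  write_panel(sim$panel, record(file.path(out_dir, "panel.csv")))
  truth <- sim$truth
  truth$thresholds <- unclass(truth$thresholds)
  jsonlite::write_json(truth, record(file.path(out_dir, "ground_truth.json")),
                       auto_unbox = TRUE, digits = NA)

  monthly <- monthly_features(daily)
  write_monthly_features(monthly,
                         record(file.path(out_dir, "monthly_features.csv")))

  design <- build_design(sim$panel, monthly, spec)
  trace <- mc3_search(design, n_iter = config$n_iter %||% 20000L,
                      burn_in = config$burn_in %||% 2000L, seed = seed + 2L)
  best <- select_best(trace)
  window <- occams_window(trace, c = config$c %||% 3)
  post <- coefficient_posterior(design, window,
                                draws = config$draws %||% 10000L,
                                seed = seed + 3L)
  fit_json <- list(
    spec = spec,
    best_model = gamma_key(unname(best)),
    best_active = names(best)[best == 1L],
    window_size = length(window$keys),
    window_weights = stats::setNames(window$weights, window$keys),
    acceptance_rate = trace$acceptance_rate,
    coefficients = post$table)
  jsonlite::write_json(fit_json, record(file.path(out_dir, "fit.json")),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  if (isTRUE(config$run_cv %||% TRUE)) {
    folds <- make_year_folds(unique(sim$panel$year), k = config$k %||% 10L,
                             seed = seed + 4L)
    cv <- cross_validate(sim$panel, monthly, spec, methods = methods,
                         folds = folds, c = config$c %||% 3,
                         n_iter = config$cv_n_iter %||% 2000L,
                         burn_in = config$cv_burn_in %||% 500L,
                         seed = seed + 5L)
    utils::write.csv(cv$summary, record(file.path(out_dir, "cv_summary.csv")),
                     row.names = FALSE)
    utils::write.csv(cv$per_fold, record(file.path(out_dir, "cv_per_fold.csv")),
                     row.names = FALSE)
  }

  if (isTRUE(config$run_scenarios %||% TRUE)) {
    for (delta in config$deltas %||% c(1, 2)) {
      wi <- warming_impact(daily, sim$panel, window, spec, delta = delta,
                           draws = config$draws %||% 4000L, seed = seed + 6L)
      jsonlite::write_json(
        list(delta = delta, overall = wi$overall,
             lower = unname(wi$interval["lower"]),
             upper = unname(wi$interval["upper"]), method = wi$method),
        record(file.path(out_dir, sprintf("warming_%gC.json", delta))),
        auto_unbox = TRUE, digits = NA)
      utils::write.csv(wi$per_county,
                       record(file.path(out_dir,
                                        sprintf("warming_%gC_by_county.csv", delta))),
                       row.names = FALSE)
    }
  }

  if (isTRUE(config$run_effects %||% TRUE) && spec %in% c("M3", "M4")) {
    eff <- conditional_effects_table(window, design, monthly,
                                     draws = config$draws %||% 4000L,
                                     seed = seed + 7L)
    utils::write.csv(eff, record(file.path(out_dir, "conditional_effects.csv")),
                     row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("cropbma")),
    seed = seed, spec = spec, methods = methods,
    weather_config = unclass(wcfg), panel_config = unclass(pcfg),
    artifacts = stats::setNames(as.list(unname(tools::md5sum(unlist(art)))),
                                basename(unlist(art))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
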