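#' Year-blocked fold assignment
#'
#' Randomly deals whole years into `k` folds: years are permuted under the
#' seed and assigned round-robin, so fold sizes differ by at most one year
#' and every observation of a year shares its fold. With 37 years and
#' `k = 10` this always yields seven 4-year folds and three 3-year folds.
#'
#' @param years Integer vector of distinct panel years (`length >= k`).
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return An object of class `fold_assignment`: list with `assignment`
#'   (data frame `year`, `fold`), `k`, `seed`.
#' @export
make_year_folds <- function(years, k = 10L, seed) {
  years <- sort(unique(as.integer(years)))
  k <- as.integer(k)
  if (length(years) < k)
    stop(sprintf("need at least k = %d distinct years, got %d",
                 k, length(years)), call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  with_seed(seed, {
    perm <- sample(years)
    fold <- rep(seq_len(k), length.out = length(years))
    a <- data.frame(year = perm, fold = fold)
    a <- a[order(a$year), ]
    rownames(a) <- NULL
    structure(list(assignment = a, k = k, seed = as.integer(seed)),
              class = "fold_assignment")
  })
}

#' @export
print.fold_assignment <- function(x, ...) {
  sizes <- table(x$assignment$fold)
  cat(sprintf("%d year-blocked folds over %d years (sizes %s)\n",
              x$k, nrow(x$assignment),
              paste(as.integer(sizes), collapse = ", ")))
  invisible(x)
}

#' Skill score relative to a benchmark mean squared error
#'
#' `-(mse_m - mse_ref) / mse_ref`: positive when the model beats the
#' benchmark, 0 when it matches it, negative when it is worse.
#'
#' @param mse_m Model mean squared error.
#' @param mse_ref Benchmark mean squared error (> 0).
#' @return Unitless skill score.
#' @export
skill_score <- function(mse_m, mse_ref) {
  if (any(mse_ref <= 0))
    stop("`mse_ref` must be > 0", call. = FALSE)
  -(mse_m - mse_ref) / mse_ref
}

#' Out-of-sample accuracy measures
#'
#' RMSE, MAPE (in percent, on the model's response scale -- log yields
#' throughout this package), Pearson correlation, and optionally the skill
#' score against a benchmark MSE.
#'
#' @param actual,predicted Equal-length numeric vectors (`length >= 2`).
#' @param mse_ref Optional benchmark MSE for the skill score.
#' @return List with `rmse`, `mape`, `pcc`, `mse` and (if `mse_ref` given)
#'   `skill`.
#' @export
compute_metrics <- function(actual, predicted, mse_ref = NULL) {
  if (length(actual) != length(predicted) || length(actual) < 2L)
    stop("`actual` and `predicted` must be equal-length vectors of length >= 2",
         call. = FALSE)
  if (any(actual == 0))
    stop("MAPE undefined: zero value(s) in `actual`", call. = FALSE)
  if (stats::sd(actual) == 0 || stats::sd(predicted) == 0)
    stop("PCC undefined: constant vector", call. = FALSE)
  err <- actual - predicted
  mse <- mean(err^2)
  out <- list(rmse = sqrt(mse),
              mape = 100 * mean(abs(err / actual)),
              pcc = stats::cor(actual, predicted),
              mse = mse)
  if (!is.null(mse_ref)) out$skill <- skill_score(mse, mse_ref)
  out
}

#' Year-blocked cross-validation of specifications and estimators
#'
#' For each fold: fit on the remaining folds' rows, predict the held-out
#' fold, and compute per-fold RMSE, MAPE, PCC and skill score; across-fold
#' averages are reported per method. The skill score is computed per fold
#' against the benchmark's MSE on the same fold, then averaged. The
#' benchmark is the seasonal specification M1 estimated by OLS (computed
#' internally on the same folds unless a previous result is supplied), so
#' evaluating M1-OLS against itself gives an average skill of exactly 0.
#'
#' `"bvs"` and `"bma"` share one MC3 run per fold: selection takes the
#' highest-marginal-likelihood visited model, averaging takes the Occam's
#' window.
#'
#' @param panel Yield panel data frame.
#' @param monthly Monthly features covering the panel.
#' @param spec Specification to evaluate.
#' @param methods Subset of `c("ols", "bvs", "bma")`.
#' @param folds A [make_year_folds()] assignment covering the panel years.
#' @param benchmark Optional `cv_result` for the benchmark (its per-fold
#'   MSEs are reused; folds must match), or `NULL` to compute M1-OLS
#'   internally.
#' @param c Occam's window constant.
#' @param n_iter,burn_in MC3 chain settings per fold (reduced defaults for
#'   cross-validation; see [mc3_search()]).
#' @param seed Integer seed; fold `f` uses `seed + f` for its chain.
#' @return An object of class `cv_result`: list with `summary` (one row
#'   per method: averaged rmse, mape, pcc, skill), `per_fold`, `spec`,
#'   `folds`.
#' @export
cross_validate <- function(panel, monthly, spec, methods = "ols", folds,
                           benchmark = NULL, c = 3,
                           n_iter = 2000L, burn_in = 500L, seed = 1L) {
  stopifnot(inherits(folds, "fold_assignment"))
  methods <- match.arg(methods, c("ols", "bvs", "bma"), several.ok = TRUE)
  a <- folds$assignment
  miss <- setdiff(unique(panel$year), a$year)
  if (length(miss) > 0L)
    stop("panel years missing from fold assignment: ",
         paste(miss, collapse = ", "), call. = FALSE)
  design <- build_design(panel, monthly, spec)
  fold_of <- a$fold[match(panel$year, a$year)]

  ref_mse <- NULL
  if (!is.null(benchmark)) {
    stopifnot(inherits(benchmark, "cv_result"))
    if (!identical(benchmark$folds$assignment, a))
      stop("`benchmark` was computed on different folds", call. = FALSE)
    bm <- benchmark$per_fold
    bm <- bm[bm$method == benchmark$summary$method[1L], ]
    ref_mse <- bm$mse[order(bm$fold)]
  } else if (spec == "M1" && identical(methods, "ols")) {
    ref_mse <- NA  # self-benchmark, filled per fold below
  }
  design_m1 <- if (is.null(ref_mse)) build_design(panel, monthly, "M1") else NULL

  per <- list()
  for (f in seq_len(folds$k)) {
    train <- which(fold_of != f)
    test <- which(fold_of == f)
    if (length(test) == 0L) next
    d_tr <- design_subset(design, train)
    d_te <- design_subset(design, test)

    preds <- list()
    if ("ols" %in% methods)
      preds$ols <- predict(ols_fit(d_tr), d_te)
    if (any(c("bvs", "bma") %in% methods)) {
      trace <- mc3_search(d_tr, n_iter = n_iter, burn_in = burn_in,
                          seed = seed + f)
      if ("bvs" %in% methods)
        preds$bvs <- predict(single_model_set(d_tr, select_best(trace)),
                             d_te, d_tr)
      if ("bma" %in% methods)
        preds$bma <- predict(occams_window(trace, c), d_te, d_tr)
    }

    mse_ref_f <- if (is.null(ref_mse)) {
      m1_pred <- predict(ols_fit(design_subset(design_m1, train)),
                         design_subset(design_m1, test))
      mean((design$y[test] - m1_pred)^2)
    } else if (all(is.na(ref_mse))) {
      mean((design$y[test] - preds$ols)^2)  # M1-OLS against itself
    } else ref_mse[f]

    for (m in names(preds)) {
      met <- compute_metrics(design$y[test], preds[[m]], mse_ref = mse_ref_f)
      per[[length(per) + 1L]] <- data.frame(
        spec = spec, method = m, fold = f, n_test = length(test),
        rmse = met$rmse, mape = met$mape, pcc = met$pcc, mse = met$mse,
        skill = met$skill, stringsAsFactors = FALSE)
    }
  }
  per_fold <- do.call(rbind, per)
  summ <- do.call(rbind, lapply(methods, function(m) {
    pm <- per_fold[per_fold$method == m, ]
    data.frame(spec = spec, method = m, rmse = mean(pm$rmse),
               mape = mean(pm$mape), pcc = mean(pm$pcc),
               skill = mean(pm$skill), stringsAsFactors = FALSE)
  }))
  structure(list(summary = summ, per_fold = per_fold, spec = spec,
                 folds = folds, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Year-blocked %d-fold cross-validation, specification %s\n",
              x$folds$k, x$spec))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
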