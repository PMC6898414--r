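#' Weather-column labels of the four specifications
#'
#' The four nested model specifications share a common column vocabulary:
#' M1 uses growing-season (April-October) sums of GDD, HDD and
#' precipitation plus squared seasonal precipitation; M2 adds the four
#' degree-day x precipitation interaction families; M3 disaggregates M1 by
#' month (7 months x 4 families = 28 columns); M4 disaggregates M2
#' (7 x 8 = 56 columns) and is the specification over which Bayesian
#' variable selection operates.
#'
#' @return Character vector of column labels, in canonical order
#'   (family-major, months 4..10 within family for monthly specs).
#' @export
#' @examples
#' length(m4_labels())  # 56
m4_labels <- function() spec_labels("M4")

#' @rdname m4_labels
#' @param spec One of `"M1"`, `"M2"`, `"M3"`, `"M4"`.
#' @export
spec_labels <- function(spec) {
  spec <- match.arg(spec, c("M1", "M2", "M3", "M4"))
  fam_main <- c("GDD", "HDD", "Prec", "Prec2")
  fam_int <- c("GDDxPrec", "GDDxPrec2", "HDDxPrec", "HDDxPrec2")
  fams <- if (spec %in% c("M2", "M4")) c(fam_main, fam_int) else fam_main
  if (spec %in% c("M1", "M2")) return(fams)
  as.vector(t(outer(fams, 4:10, paste, sep = "_")))
}

# growing-season months
season_months <- function() 4:10

# Build the weather regressor matrix for `spec` over the county-years in
# `keys` (data.frame county_id, state_id, year, in output row order).
# Shared by build_design() and the synthetic panel generator, so the
# generator's ground truth and the fitted design use one code path for
# labels but the generator's X is still checked against an independent
# construction in the tests.
weather_design_columns <- function(monthly, keys, spec) {
  spec <- match.arg(spec, c("M1", "M2", "M3", "M4"))
  mon <- season_months()
  sub <- monthly[monthly$month %in% mon, , drop = FALSE]
  ck <- paste(keys$county_id, keys$year, sep = "\r")
  getm <- function(var) {
    out <- matrix(NA_real_, nrow(keys), length(mon),
                  dimnames = list(NULL, paste0(var, "_", mon)))
    for (j in seq_along(mon)) {
      mj <- sub[sub$month == mon[j], , drop = FALSE]
      idx <- match(ck, paste(mj$county_id, mj$year, sep = "\r"))
      out[, j] <- mj[[var]][idx]
    }
    out
  }
  gdd <- getm("gdd"); hdd <- getm("hdd"); prec <- getm("prec")
  colnames(gdd) <- paste0("GDD_", mon)
  colnames(hdd) <- paste0("HDD_", mon)
  colnames(prec) <- paste0("Prec_", mon)
  if (anyNA(gdd) || anyNA(hdd) || anyNA(prec)) {
    miss <- ck[!stats::complete.cases(cbind(gdd, hdd, prec))]
    stop("monthly features missing for months 4-10 of county-years: ",
         paste(gsub("\r", "/", utils::head(unique(miss), 5L)), collapse = ", "),
         call. = FALSE)
  }
  if (spec %in% c("M3", "M4")) {
    prec2 <- prec^2
    colnames(prec2) <- paste0("Prec2_", mon)
    X <- cbind(gdd, hdd, prec, prec2)
    if (spec == "M4") {
      ints <- cbind(gdd * prec, gdd * prec2, hdd * prec, hdd * prec2)
      colnames(ints) <- as.vector(t(outer(
        c("GDDxPrec", "GDDxPrec2", "HDDxPrec", "HDDxPrec2"), mon,
        paste, sep = "_")))
      X <- cbind(X, ints)
    }
  } else {
    g <- rowSums(gdd); h <- rowSums(hdd); p <- rowSums(prec)
    X <- cbind(GDD = g, HDD = h, Prec = p, Prec2 = p^2)
    if (spec == "M2")
      X <- cbind(X, GDDxPrec = g * p, GDDxPrec2 = g * p^2,
                 HDDxPrec = h * p, HDDxPrec2 = h * p^2)
  }
  X[, spec_labels(spec), drop = FALSE]
}

#' Build the regression design for a specification
#'
#' Assembles the response `y` (log yields), the selectable weather matrix
#' `X` and the always-included matrix `Z` for one of the four
#' specifications. `Z` holds, per state, `D_s x Time` and `D_s x Time^2`
#' (with `Time = year - first_year + 1`) plus one indicator column per
#' county and no global intercept, so it is full column rank. Rows follow
#' the input panel order exactly.
#'
#' @param panel Data frame with columns `county_id`, `state_id`, `year`,
#'   `log_yield`; `(county_id, year)` must be unique and each county must
#'   belong to exactly one state.
#' @param monthly Monthly features from [monthly_features()], covering
#'   months 4-10 of every panel county-year.
#' @param spec `"M1"`, `"M2"`, `"M3"` or `"M4"`.
#' @param standardize If `TRUE` (default), scale each weather column to
#'   unit sample SD; the scaling factors are kept in `x_scale` and every
#'   reported coefficient, interval, marginal effect and warming impact is
#'   converted back to natural units (per degree day, per mm). The
#'   closed-form marginal likelihood is not invariant to column rescaling:
#'   its determinant term subtracts the log column norms, so in natural
#'   units it spuriously rewards near-zero-variance regressors (April or
#'   October HDD). Standardizing puts all 56 columns on one scale before
#'   model comparison; set `FALSE` for literal natural-unit columns.
#' @return An object of class `crop_design`: list with `y`, `X`, `Z`,
#'   `spec`, `row_keys`, `x_info` (label/family/month table), `counties`,
#'   `states`, `first_year`, `x_scale`.
#' @export
build_design <- function(panel, monthly, spec = c("M4", "M1", "M2", "M3"),
                         standardize = TRUE) {
  spec <- match.arg(spec)
  need <- c("county_id", "state_id", "year", "log_yield")
  miss <- setdiff(need, names(panel))
  if (length(miss) > 0L)
    stop("panel is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  key <- paste(panel$county_id, panel$year, sep = "/")
  if (anyDuplicated(key))
    stop("duplicate (county_id, year) keys in panel: ",
         paste(utils::head(key[duplicated(key)], 5L), collapse = ", "),
         call. = FALSE)
  county_state_map(panel)  # errors if a county maps to two states

  keys <- panel[, c("county_id", "state_id", "year")]
  X <- weather_design_columns(monthly, keys, spec)
  x_scale <- rep(1, ncol(X))
  names(x_scale) <- colnames(X)
  if (standardize) {
    sds <- apply(X, 2L, stats::sd)
    sds[sds == 0] <- 1
    X <- sweep(X, 2L, sds, "/")
    x_scale <- sds
  }

  states <- sort(unique(panel$state_id))
  counties <- sort(unique(panel$county_id))
  first_year <- min(panel$year)
  time_t <- panel$year - first_year + 1L
  Z_trend <- matrix(0, nrow(panel), 2L * length(states))
  cn <- character(2L * length(states))
  for (s in seq_along(states)) {
    d <- as.numeric(panel$state_id == states[s])
    Z_trend[, 2L * s - 1L] <- d * time_t
    Z_trend[, 2L * s] <- d * time_t^2
    cn[2L * s - 1L] <- paste0("Time_", states[s])
    cn[2L * s] <- paste0("Time2_", states[s])
  }
  colnames(Z_trend) <- cn
  Z_fe <- matrix(0, nrow(panel), length(counties),
                 dimnames = list(NULL, paste0("FE_", counties)))
  Z_fe[cbind(seq_len(nrow(panel)), match(panel$county_id, counties))] <- 1
  Z <- cbind(Z_trend, Z_fe)

  mon <- sub("^.*_", "", colnames(X))
  x_info <- data.frame(
    label = colnames(X),
    family = sub("_[0-9]+$", "", colnames(X)),
    month = ifelse(grepl("_[0-9]+$", colnames(X)), suppressWarnings(as.integer(mon)), NA_integer_),
    stringsAsFactors = FALSE)

  structure(list(y = panel$log_yield, X = X, Z = Z, spec = spec,
                 row_keys = keys, x_info = x_info,
                 counties = counties, states = states,
                 first_year = first_year, x_scale = x_scale,
                 cache = new.env(parent = emptyenv())),
            class = "crop_design")
}

#' @export
print.crop_design <- function(x, ...) {
  cat(sprintf("Design (%s): n = %d rows, %d weather columns, %d fixed columns (%d counties, %d states)\n",
              x$spec, length(x$y), ncol(x$X), ncol(x$Z),
              length(x$counties), length(x$states)))
  invisible(x)
}

#' Row subset of a design
#'
#' Keeps the full column layout (including fixed-effect columns and the
#' time origin) while restricting to a subset of rows, so that designs for
#' training and held-out folds, or for baseline and counterfactual
#' weather, stay column-aligned.
#'
#' @param design A `crop_design`.
#' @param idx Integer or logical row index.
#' @return A `crop_design` on the selected rows.
#' @export
design_subset <- function(design, idx) {
  stopifnot(inherits(design, "crop_design"))
  out <- design
  out$y <- design$y[idx]
  out$X <- design$X[idx, , drop = FALSE]
  out$Z <- design$Z[idx, , drop = FALSE]
  out$row_keys <- design$row_keys[idx, , drop = FALSE]
  out$cache <- new.env(parent = emptyenv())
  out
}
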