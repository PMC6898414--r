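#' Ordinary least squares fit of a full specification
#'
#' Fits the specification with every weather column active (plus the
#' always-included trend and fixed-effect columns), the non-Bayesian
#' comparator to variable selection and model averaging. Classical
#' covariance `s^2 (W'W)^-1` by default; a county-clustered robust
#' covariance is available for sensitivity checks.
#'
#' @param design A `crop_design` from [build_design()].
#' @param cluster `"none"` (classical) or `"county"` (CR0 cluster-robust
#'   covariance, clustering on the county key).
#' @return An object of class `ols_fit`: list with `coef` (named, X then Z
#'   columns), `cov`, `sigma2`, `df`, `n`, `p`, `n_x`, `x_labels`,
#'   `fitted`, `residuals`, `cluster`.
#' @export
ols_fit <- function(design, cluster = c("none", "county")) {
  stopifnot(inherits(design, "crop_design"))
  cluster <- match.arg(cluster)
  W <- cbind(design$X, design$Z)
  n <- length(design$y)
  p <- ncol(W)
  if (n <= p)
    stop(sprintf("n = %d <= p = %d: specification not estimable by OLS", n, p),
         call. = FALSE)
  qw <- qr(W, tol = RANK_TOL)
  if (qw$rank < p)
    stop("rank-deficient design: ",
         paste(colnames(W)[qw$pivot[(qw$rank + 1L):p]], collapse = ", "),
         call. = FALSE)
  coef <- qr.coef(qw, design$y)
  res <- qr.resid(qw, design$y)
  rss <- sum(res^2)
  s2 <- rss / (n - p)
  R <- qr.R(qw)
  piv <- qw$pivot
  Rinv <- backsolve(R, diag(p))
  V <- tcrossprod(Rinv)
  V[piv, piv] <- V
  dimnames(V) <- list(colnames(W), colnames(W))
  covm <- if (cluster == "none") {
    s2 * V
  } else {
    # CR0 sandwich: bread (W'W)^-1, meat summed over county score blocks
    groups <- split(seq_len(n), design$row_keys$county_id)
    meat <- matrix(0, p, p)
    for (idx in groups) {
      sc <- crossprod(W[idx, , drop = FALSE], res[idx])
      meat <- meat + tcrossprod(sc)
    }
    V %*% meat %*% V
  }
  structure(list(coef = coef, cov = covm, sigma2 = s2, df = n - p,
                 n = n, p = p, n_x = ncol(design$X),
                 x_labels = colnames(design$X), x_scale = design$x_scale,
                 fitted = design$y - res, residuals = res,
                 cluster = cluster, spec = design$spec),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS fit (%s): n = %d, p = %d (%d weather columns), residual SD %.4f\n",
              x$spec, x$n, x$p, x$n_x, sqrt(x$sigma2)))
  invisible(x)
}

#' Predict log yields from an OLS fit
#'
#' @param object An `ols_fit`.
#' @param design_new A `crop_design` column-aligned with the fitting
#'   design (see [design_subset()]).
#' @param ... Unused.
#' @return Numeric vector of predicted log yields.
#' @export
predict.ols_fit <- function(object, design_new, ...) {
  stopifnot(inherits(design_new, "crop_design"))
  W_new <- cbind(design_new$X, design_new$Z)
  if (!identical(colnames(W_new), names(object$coef)))
    stop("`design_new` columns do not align with the fitted design",
         call. = FALSE)
  drop(W_new %*% object$coef)
}
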