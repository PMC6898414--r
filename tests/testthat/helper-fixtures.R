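# Shared fixtures and independent oracles. Oracles here deliberately use
# naive formulations (dense quadrature, explicit projectors, full-matrix
# inverses) so they share no code path with the implementation.

# trapezoid average of the thresholded single-sine curve
quad_dd <- function(tmin, tmax, lower, upper = NULL, npts = 10000L) {
  m <- (tmax + tmin) / 2
  a <- (tmax - tmin) / 2
  t <- seq(0, 1, length.out = npts)
  temp <- m + a * sin(2 * pi * t)
  f <- if (is.null(upper)) pmax(0, temp - lower)
       else pmax(0, pmin(temp, upper) - lower)
  # trapezoid rule over one period
  sum((f[-1] + f[-npts]) / 2) / (npts - 1)
}

# log marginal likelihood by explicit full-matrix operations, projector
# formed directly
oracle_logml <- function(y, W) {
  n <- length(y)
  p <- ncol(W)
  WtW <- t(W) %*% W
  P <- W %*% solve(WtW) %*% t(W)
  rss <- drop(t(y) %*% (diag(n) - P) %*% y)
  lgamma((n - p) / 2) - 0.5 * determinant(WtW, logarithm = TRUE)$modulus -
    ((n - p) / 2) * log(pi * rss)
}

# assemble a crop_design directly from raw matrices (for linear-algebra
# fixtures that do not come from a weather panel)
raw_design <- function(y, X, Z, spec = "M4") {
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(colnames(Z))) colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  structure(list(y = y, X = X, Z = Z, spec = spec,
                 row_keys = data.frame(county_id = "c1",
                                       state_id = "s1",
                                       year = seq_along(y)),
                 x_info = data.frame(label = colnames(X),
                                     family = colnames(X),
                                     month = NA_integer_),
                 counties = "c1", states = "s1", first_year = 1L,
                 x_scale = stats::setNames(rep(1, ncol(X)), colnames(X)),
                 cache = new.env(parent = emptyenv())),
            class = "crop_design")
}

# the spec fixture for marginal-likelihood checks: n = 24 rows, 3 weather
# columns, 2 counties in 1 state (Z = 2 trend cols + 2 county indicators)
ml_fixture <- function(seed = 42L) {
  set.seed(seed)
  n <- 24L
  county <- rep(c("c1", "c2"), each = 12L)
  time_t <- rep(1:12, 2L)
  Z <- cbind(Time_s1 = time_t, Time2_s1 = time_t^2,
             FE_c1 = as.numeric(county == "c1"),
             FE_c2 = as.numeric(county == "c2"))
  X <- matrix(rnorm(n * 3L), n, 3L,
              dimnames = list(NULL, c("w1", "w2", "w3")))
  y <- 0.02 * time_t + (county == "c2") * 0.5 + 0.3 * X[, 1] + rnorm(n, 0, 0.4)
  raw_design(y, X, Z)
}

# small synthetic weather panel shared across tests (built once per run)
small_weather_cache <- new.env()
small_weather <- function(n_states = 2L, counties_per_state = 3L,
                          years = 2001:2008, seed = 7L) {
  key <- paste(n_states, counties_per_state, paste(range(years), collapse = "-"),
               seed, sep = "_")
  if (is.null(small_weather_cache[[key]])) {
    cfg <- weather_sim_config(n_states = n_states,
                              counties_per_state = counties_per_state,
                              years = years, seed = seed)
    small_weather_cache[[key]] <- generate_weather(cfg)
  }
  small_weather_cache[[key]]
}

# weather + panel + monthly features + design in one go
small_sim <- function(n_states = 2L, counties_per_state = 3L,
                      years = 2001:2008, weather_seed = 7L,
                      panel_seed = 9L, spec = "M4", ...) {
  w <- small_weather(n_states, counties_per_state, years, weather_seed)
  m <- monthly_features(w)
  sim <- generate_panel(w, panel_sim_config(seed = panel_seed, ...))
  d <- build_design(sim$panel, m, spec)
  list(weather = w, monthly = m, panel = sim$panel, truth = sim$truth,
       design = d)
}

# one year of daily weather for a single county, hand-rolled dates
one_county_year <- function(year = 2003L, tmin = 12, tmax = 24, prec = 2,
                            county = "c1", state = "s1") {
  dates <- seq.Date(as.Date(sprintf("%d-01-01", year)),
                    as.Date(sprintf("%d-12-31", year)), by = "day")
  data.frame(county_id = county, state_id = state, date = dates,
             tmin = tmin, tmax = tmax, prec = prec,
             stringsAsFactors = FALSE)
}

# batch-means Monte-Carlo standard error of the mean of a 0/1 chain
batch_se <- function(z, n_batches = 50L) {
  n <- length(z)
  size <- floor(n / n_batches)
  means <- vapply(seq_len(n_batches),
                  function(b) mean(z[((b - 1L) * size + 1L):(b * size)]), 0)
  stats::sd(means) / sqrt(n_batches)
}
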