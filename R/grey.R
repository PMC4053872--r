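#' Grey series constructor
#'
#' A positive time sequence `x_0 ... x_n` suitable for GM(1,1) modelling; the
#' sequence must hold at least four values (n at least 3).
#'
#' @param values Ordered positive values.
#' @param label Optional identifier.
#' @param .relax Internal: skip the length check (used by low-level helpers).
#' @return Object of class `grey_series`.
#' @export
grey_series <- function(values, label = "series", .relax = FALSE) {
  values <- as.numeric(values)
  if (!.relax && length(values) < 4L)
    stop_domain("a grey series needs at least 4 values")
  if (any(!is.finite(values)) || any(values <= 0))
    stop_domain("grey series values must be positive and finite")
  structure(list(values = values, label = label), class = "grey_series")
}

as_grey_values <- function(series) {
  if (inherits(series, "grey_series")) series$values else as.numeric(series)
}

#' Accumulated generating operation (AGO)
#'
#' Cumulative sum of the series; the first GM(1,1) transformation, smoothing
#' the raw sequence before the exponential fit.
#'
#' @param series A `grey_series` or numeric vector.
#' @return Numeric vector `y_t = sum(x_0..x_t)`.
#' @export
accumulated_generation <- function(series) {
  cumsum(as_grey_values(series))
}

#' Consecutive-mean sequence of an accumulated series
#'
#' @param accumulated Numeric vector `y_0 ... y_n` (length at least 2).
#' @return `z_t = (y_t + y_(t-1)) / 2` for `t = 1 ... n` (length n).
#' @export
mean_sequence <- function(accumulated) {
  if (length(accumulated) < 2L) stop_domain("need at least 2 accumulated values")
  (accumulated[-1] + accumulated[-length(accumulated)]) / 2
}

#' Fit a GM(1,1) grey model
#'
#' Least-squares solution of the grey difference equation `x_t + alpha * z_t =
#' mu` over `t = 1 ... n`, where `z` is the consecutive-mean of the accumulated
#' series. The fitted accumulated trajectory is the exponential
#' `y_hat_t = (x_0 - mu/alpha) * exp(-alpha * t) + mu/alpha`, and the fitted
#' original values are its first differences (with `x_hat_0 = x_0`). When
#' `|alpha|` falls below 1e-10 the degenerate linear limit
#' `y_hat_t = x_0 + mu * t` is used, so a constant series is fitted exactly.
#'
#' @param series A `grey_series` or positive numeric vector (length >= 4).
#' @return Object of class `gm11`: `alpha`, `mu`, `x0`, `accumulated`,
#'   `mean_seq`, `fitted`, `residuals`, `s1`, `s2`, `c`, `p`, `degree`,
#'   `label`, `n`.
#' @export
fit_gm11 <- function(series) {
  if (!inherits(series, "grey_series")) series <- grey_series(series)
  x <- series$values
  n <- length(x) - 1L
  y <- accumulated_generation(x)
  z <- mean_sequence(y)
  xt <- x[-1]
  ## normal equations for x_t = -alpha * z_t + mu
  B <- cbind(-z, 1)
  sol <- tryCatch(solve(crossprod(B), crossprod(B, xt)),
                  error = function(e) stop_domain(
                    "singular grey system (no variation in the mean sequence)"))
  alpha <- sol[1]
  mu <- sol[2]
  fitted_y <- gm11_accumulated(alpha, mu, x[1], 0:n)
  fitted <- c(x[1], diff(fitted_y))
  model <- structure(
    list(alpha = alpha, mu = mu, x0 = x[1], accumulated = y, mean_seq = z,
         fitted = fitted, residuals = x - fitted, label = series$label, n = n),
    class = "gm11"
  )
  val <- validate_gm11(model, series)
  model[names(val)] <- val
  model$degree <- classify_degree(model$c, model$p)
  model
}

## Fitted accumulated trajectory at integer times t (>= 0).
gm11_accumulated <- function(alpha, mu, x0, t) {
  if (abs(alpha) < 1e-10) x0 + mu * t
  else (x0 - mu / alpha) * exp(-alpha * t) + mu / alpha
}

#' @export
print.gm11 <- function(x, ...) {
  cat(sprintf("<gm11> %s: alpha = %.6g, mu = %.6g, c = %.4f, p = %.4f (%s)\n",
              x$label, x$alpha, x$mu, x$c %||% NA, x$p, x$degree))
  invisible(x)
}

#' Posterior-deviation validation of a GM(1,1) fit
#'
#' Residuals `delta_t = x_t - x_hat_t` are taken over `t = 0 ... n` (the
#' construction forces `delta_0 = 0`). `s1` is the population standard
#' deviation of the original series, `s2` that of the residuals; the posterior
#' deviation ratio is `c = s2 / s1` and the small error probability `p` is the
#' fraction of residuals within `0.6745 * s1` of the mean residual.
#'
#' @param model A `gm11` fit.
#' @param series The series the model was fitted to.
#' @return List with `s1`, `s2`, `c`, `p`, `degenerate`.
#' @export
validate_gm11 <- function(model, series) {
  x <- as_grey_values(series)
  delta <- x - model$fitted
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  s1 <- pop_sd(x)
  s2 <- pop_sd(delta)
  if (s1 == 0) {
    warning("constant series: posterior deviation ratio undefined")
    return(list(s1 = s1, s2 = s2, c = NA_real_, p = 1, degenerate = TRUE))
  }
  list(s1 = s1, s2 = s2, c = s2 / s1,
       p = mean(abs(delta - mean(delta)) < 0.6745 * s1),
       degenerate = FALSE)
}

#' Grade a GM(1,1) fit from its validation statistics
#'
#' Excellent when `p > 0.95` and `c < 0.35`; otherwise good when `p > 0.80`
#' and `c < 0.50`; otherwise marginal when `p > 0.70` and `c < 0.65`;
#' otherwise unreliable. A constant-series fit (c undefined, perfect fit) is
#' graded excellent.
#'
#' @param c Posterior deviation ratio (>= 0, or NA for a degenerate fit).
#' @param p Small error probability in \[0, 1\].
#' @return One of `"excellent"`, `"good"`, `"marginal"`, `"unreliable"`.
#' @export
classify_degree <- function(c, p) {
  if (is.na(c)) return("excellent")
  if (c < 0) stop_domain("c must be non-negative")
  if (p < 0 || p > 1) stop_domain("p must lie in [0, 1]")
  if (p > 0.95 && c < 0.35) "excellent"
  else if (p > 0.80 && c < 0.50) "good"
  else if (p > 0.70 && c < 0.65) "marginal"
  else "unreliable"
}

#' Forecast future values from a GM(1,1) fit
#'
#' Extends the fitted accumulated exponential beyond the sample and returns
#' its first differences: `x_hat_(n+h) = y_hat_(n+h) - y_hat_(n+h-1)` for
#' `h = 1 ... horizon`.
#'
#' @param model A `gm11` fit.
#' @param horizon Number of steps ahead (>= 1).
#' @return Numeric vector of length `horizon`.
#' @export
forecast_gm11 <- function(model, horizon) {
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon < 1)
    stop_domain("horizon must be a positive integer")
  t <- model$n + seq_len(horizon)
  gm11_accumulated(model$alpha, model$mu, model$x0, t) -
    gm11_accumulated(model$alpha, model$mu, model$x0, t - 1)
}

#' Per-hospital admission burden
#'
#' Elementwise division of forecast admissions by the district's number of
#' hospitals: a per-hospital service-load proxy.
#'
#' @param forecast_admissions Named numeric vector (or matrix with districts
#'   in rows) of forecast admission counts.
#' @param hospitals Named count of hospitals per district.
#' @return Forecast admissions per hospital, same shape as the input.
#' @export
burden <- function(forecast_admissions, hospitals) {
  districts <- if (is.matrix(forecast_admissions)) rownames(forecast_admissions)
               else names(forecast_admissions)
  if (!is.null(districts) && !is.null(names(hospitals)))
    hospitals <- hospitals[districts]
  any_fc <- if (is.matrix(forecast_admissions))
    apply(forecast_admissions, 1, function(r) any(r != 0))
  else forecast_admissions != 0
  bad <- which(hospitals < 1 & any_fc)
  if (length(bad))
    stop_domain("district(s) with admissions but no hospitals: ",
                paste(districts[bad] %||% bad, collapse = ", "))
  forecast_admissions / as.numeric(hospitals)
}

#' Fit and forecast grey models for every district in a panel
#'
#' Fits one GM(1,1) per district to the chosen annual series and forecasts
#' `horizon` years ahead, returning the forecasts alongside the validation
#' grade of each fit.
#'
#' @param panel data.frame `district, year, population, admissions`.
#' @param what `"ir"` (admissions per 1,000) or `"admissions"`.
#' @param horizon Forecast horizon in years (default 3).
#' @return List with `forecasts` (data.frame `district, year, value`) and
#'   `validation` (data.frame `district, s1, s2, c, p, degree`).
#' @export
grey_forecast_panel <- function(panel, what = c("ir", "admissions"), horizon = 3L) {
  what <- match.arg(what)
  years <- sort(unique(panel$year))
  districts <- sort(unique(panel$district))
  fc_rows <- list(); val_rows <- list()
  for (d in districts) {
    sl <- panel[panel$district == d, ]
    sl <- sl[order(sl$year), ]
    v <- if (what == "ir") incidence_rate(sl$admissions, sl$population)
         else sl$admissions
    v <- pmax(v, 1e-6)          # grey models need strictly positive input
    m <- fit_gm11(grey_series(v, label = d))
    fc <- forecast_gm11(m, horizon)
    fc <- if (what == "ir") round(fc, 2) else round(fc)
    fc_rows[[d]] <- data.frame(district = d,
                               year = max(years) + seq_len(horizon),
                               value = fc, stringsAsFactors = FALSE)
    val_rows[[d]] <- data.frame(district = d, s1 = m$s1, s2 = m$s2,
                                c = m$c, p = m$p, degree = m$degree,
                                stringsAsFactors = FALSE)
  }
  list(forecasts = do.call(rbind, c(fc_rows, make.row.names = FALSE)),
       validation = do.call(rbind, c(val_rows, make.row.names = FALSE)))
}
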