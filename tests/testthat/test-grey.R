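test_that("accumulation and mean sequences round-trip", {
  expect_equal(accumulated_generation(c(1, 2, 3)), c(1, 3, 6))
  expect_equal(accumulated_generation(grey_series(5, .relax = TRUE)), 5)
  expect_equal(mean_sequence(c(1, 3, 6)), c(2, 4.5))
  expect_error(mean_sequence(1), "at least 2")
  set.seed(2)
  for (rep in 1:10) {
    x <- runif(sample(4:12, 1), 0.1, 50)
    y <- accumulated_generation(x)
    expect_equal(c(y[1], diff(y)), x)          # inverse accumulation
    expect_length(mean_sequence(y), length(x) - 1)
  }
  ## constant increments give an arithmetic progression of means
  z <- mean_sequence(accumulated_generation(rep(2, 6)))
  expect_equal(diff(z), rep(2, 4))
})

test_that("geometric series are fitted exactly in closed form", {
  m <- fit_gm11(grey_series(c(1, 2, 4, 8)))
  expect_equal(m$alpha, -2 / 3, tolerance = 1e-10)
  expect_equal(m$mu, 2 / 3, tolerance = 1e-10)
  ## the difference equation itself is satisfied with zero residual
  expect_equal(c(2, 4, 8) + m$alpha * m$mean_seq, rep(m$mu, 3),
               tolerance = 1e-10)

  set.seed(5)
  for (rep in 1:10) {
    a <- runif(1, 0.5, 20)
    q <- runif(1, 0.3, 2.5)
    if (abs(q - 1) < 0.05) next
    x <- a * q^(0:5)
    m <- fit_gm11(grey_series(x))
    expect_equal(m$alpha, -2 * (q - 1) / (q + 1), tolerance = 1e-8)
    expect_equal(m$mu, 2 * a / (q + 1), tolerance = 1e-8)
  }
})

test_that("constant series hit the degenerate linear limit", {
  expect_warning(m <- fit_gm11(grey_series(c(5, 5, 5, 5))), "constant series")
  expect_equal(m$alpha, 0, tolerance = 1e-12)
  expect_equal(m$mu, 5, tolerance = 1e-12)
  expect_equal(m$fitted, rep(5, 4))
  expect_equal(forecast_gm11(m, 3), c(5, 5, 5))
  expect_identical(m$degree, "excellent")
})

test_that("normal equations agree with an independent minimizer", {
  x <- c(3, 5, 4, 7)
  m <- fit_gm11(grey_series(x))
  z <- mean_sequence(accumulated_generation(x))
  obj <- function(par) sum((x[-1] + par[1] * z - par[2])^2)
  opt <- optim(c(0, mean(x)), obj, method = "BFGS",
               control = list(reltol = 1e-14))
  expect_equal(m$alpha, opt$par[1], tolerance = 1e-6)
  expect_equal(m$mu, opt$par[2], tolerance = 1e-6)
  expect_lte(obj(c(m$alpha, m$mu)), opt$value + 1e-9)
})

test_that("model-generated series recover their parameters", {
  ## a series built from the grey difference equation
  ## x_t = (mu - alpha * y_(t-1)) / (1 + alpha/2) satisfies it with zero
  ## residual, so least squares must return the generating (alpha, mu)
  set.seed(9)
  for (rep in 1:10) {
    alpha <- runif(1, -0.4, 0.4)
    if (abs(alpha) < 1e-3) next
    mu <- runif(1, 1, 10)
    x0 <- runif(1, 1, 10)
    x <- x0
    y <- x0
    for (t in 1:7) {
      xt <- (mu - alpha * y) / (1 + alpha / 2)
      x <- c(x, xt)
      y <- y + xt
    }
    if (any(x <= 0)) next
    m <- fit_gm11(grey_series(x))
    expect_equal(m$alpha, alpha, tolerance = 1e-6)
    expect_equal(m$mu, mu, tolerance = 1e-6)
  }
})

test_that("posterior-deviation validation and degree grading", {
  ## a perfect fit (residuals identically zero) validates as c = 0, p = 1
  x <- c(1, 2, 4, 8)
  perfect <- list(fitted = x)
  v <- validate_gm11(perfect, x)
  expect_equal(v$s2, 0)
  expect_equal(v$c, 0)
  expect_equal(v$p, 1)
  expect_identical(classify_degree(v$c, v$p), "excellent")

  rows <- gm_validation_rows()
  for (i in seq_len(nrow(rows))) {
    expect_equal(rows$s2[i] / rows$s1[i], rows$c[i], tolerance = 1e-4)
    expect_identical(classify_degree(rows$c[i], rows$p[i]), rows$degree[i])
  }

  expect_identical(classify_degree(0.7, 0.5), "unreliable")
  expect_identical(classify_degree(0.55, 0.75), "marginal")
  expect_error(classify_degree(-0.1, 0.5), "non-negative")

  ## monotone: decreasing c or increasing p never worsens the grade
  lvl <- c(unreliable = 1, marginal = 2, good = 3, excellent = 4)
  cs <- seq(0, 0.8, by = 0.05)
  ps <- seq(0, 1, by = 0.05)
  for (p in ps) {
    g <- lvl[vapply(cs, classify_degree, character(1), p = p)]
    expect_true(all(diff(g) <= 0))
  }
  for (cc in cs) {
    g <- lvl[vapply(ps, function(p) classify_degree(cc, p), character(1))]
    expect_true(all(diff(g) >= 0))
  }
})

test_that("forecasts extend the fitted exponential", {
  grow <- fit_gm11(grey_series(c(10, 12, 15, 18, 23)))
  f <- forecast_gm11(grow, 3)
  expect_length(f, 3)
  expect_true(all(f > 0))
  expect_true(grow$alpha < 0 && all(diff(f) > 0))

  decay <- fit_gm11(grey_series(c(100, 80, 65, 52, 42)))
  fd <- forecast_gm11(decay, 4)
  expect_true(decay$alpha > 0 && all(diff(fd) < 0))
  expect_error(forecast_gm11(grow, 0), "horizon")

  ## first forecast step continues the fitted trajectory
  t <- grow$n + 1
  yhat <- function(tt) (grow$x0 - grow$mu / grow$alpha) *
    exp(-grow$alpha * tt) + grow$mu / grow$alpha
  expect_equal(f[1], yhat(t) - yhat(t - 1))
})

test_that("per-hospital burden divides and can reorder districts", {
  expect_equal(burden(c(a = 100), c(a = 4)), c(a = 25))
  expect_equal(unname(burden(c(a = 0), c(a = 3))), 0)
  expect_error(burden(c(a = 10, b = 5), c(a = 2, b = 0)), "b")
  ## ranking by burden can differ from ranking by raw admissions
  adm <- c(x = 900, y = 600, z = 300)
  hosp <- c(x = 30, y = 10, z = 3)
  b <- burden(adm, hosp)
  expect_identical(names(sort(adm, decreasing = TRUE))[1], "x")
  expect_identical(names(sort(b, decreasing = TRUE))[1], "z")
})

test_that("panel-level grey forecasting fits one model per district", {
  p <- generate_panel(panel_config(seed = 23L), case_points = FALSE)
  fc <- grey_forecast_panel(p$records, "admissions", horizon = 3)
  nd <- length(unique(p$records$district))
  expect_identical(nrow(fc$forecasts), nd * 3L)
  expect_identical(nrow(fc$validation), nd)
  expect_true(all(fc$validation$degree %in%
                  c("excellent", "good", "marginal", "unreliable")))
  expect_true(all(fc$forecasts$year > max(p$records$year)))
  expect_equal(fc$forecasts$value, round(fc$forecasts$value))
  fir <- grey_forecast_panel(p$records, "ir", horizon = 2)
  expect_equal(fir$forecasts$value, round(fir$forecasts$value, 2))
})
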