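#' Mean center of a point set
#'
#' The (optionally weighted) average coordinate of a planar point cloud; the
#' geographic center of mass of the cases.
#'
#' @param points data.frame with columns `x`, `y` and optionally `weight`
#'   (non-negative, default 1).
#' @return A list of class `mean_center` with `x`, `y`, `n_points`.
#' @export
mean_center <- function(points) {
  if (NROW(points) == 0L) stop_domain("mean_center needs at least one point")
  w <- points$weight %||% rep(1, nrow(points))
  if (any(w < 0)) stop_domain("weights must be non-negative")
  W <- sum(w)
  if (W <= 0) stop_domain("total weight must be positive")
  structure(list(x = sum(w * points$x) / W, y = sum(w * points$y) / W,
                 n_points = nrow(points)),
            class = "mean_center")
}

#' @export
print.mean_center <- function(x, ...) {
  cat(sprintf("<mean_center> (%.3f, %.3f), m = %d\n", x$x, x$y, x$n_points))
  invisible(x)
}

#' Standard deviational ellipse of a point set
#'
#' Summarizes the dispersion and orientation of a point cloud around its mean
#' center: two standard-distance axes (root-mean-square of the deviations
#' projected onto the rotated axes, denominator m) and the rotation angle of
#' the major axis, measured counterclockwise from the positive x-axis and
#' reduced modulo 180 degrees. Collinear clouds yield a zero minor axis; a
#' perfectly isotropic second-moment matrix is reported with `theta = 0` and
#' flagged degenerate.
#'
#' No square-root-of-two axis inflation is applied by default; `scale = sqrt(2)`
#' reproduces the convention of some GIS products.
#'
#' @param points data.frame with `x`, `y`, optional `weight`.
#' @param scale Constant multiplier applied to both axes (default 1).
#' @return A list of class `sd_ellipse` with `center`, `sde_x` (major),
#'   `sde_y` (minor), `theta` (degrees in \[0, 180)), `degenerate`.
#' @export
standard_deviational_ellipse <- function(points, scale = 1) {
  ctr <- mean_center(points)
  w <- points$weight %||% rep(1, nrow(points))
  W <- sum(w)
  dx <- points$x - ctr$x
  dy <- points$y - ctr$y
  sxx <- sum(w * dx * dx)
  syy <- sum(w * dy * dy)
  sxy <- sum(w * dx * dy)
  A <- sxx - syy
  degenerate <- FALSE
  tot <- sxx + syy
  if (abs(A) <= 1e-12 * max(tot, 1) && abs(sxy) <= 1e-12 * max(tot, 1)) {
    ## isotropic: orientation undefined, use theta = 0 by convention
    theta <- 0
    l_major <- l_minor <- tot / 2
    degenerate <- TRUE
  } else {
    ## principal axes of the centered second-moment matrix; the major-axis
    ## angle solves tan(theta) = (A + sqrt(A^2 + 4*Sxy^2)) / (2*Sxy)
    theta <- 0.5 * atan2(2 * sxy, A)
    disc <- sqrt(A^2 + 4 * sxy^2)
    l_major <- (tot + disc) / 2
    l_minor <- (tot - disc) / 2
  }
  theta_deg <- (theta * 180 / pi) %% 180
  structure(list(center = ctr,
                 sde_x = scale * sqrt(max(l_major, 0) / W),
                 sde_y = scale * sqrt(max(l_minor, 0) / W),
                 theta = theta_deg,
                 degenerate = degenerate),
            class = "sd_ellipse")
}

#' @export
print.sd_ellipse <- function(x, ...) {
  cat(sprintf("<sd_ellipse> center (%.3f, %.3f), axes %.3f x %.3f, theta %.2f deg\n",
              x$center$x, x$center$y, x$sde_x, x$sde_y, x$theta))
  invisible(x)
}

#' Convert between mathematical and geographic angle conventions
#'
#' Mathematical: counterclockwise from the positive x-axis. Geographic (GIS):
#' clockwise from north. Both reduced to \[0, 180).
#'
#' @param theta Angle(s) in degrees.
#' @return Converted angle(s) in degrees.
#' @export
theta_to_geographic <- function(theta) (90 - theta) %% 180

point_in_ellipse <- function(px, py, e) {
  th <- e$theta * pi / 180
  dx <- px - e$center$x
  dy <- py - e$center$y
  u <- cos(th) * dx + sin(th) * dy
  v <- -sin(th) * dx + cos(th) * dy
  (u / e$sde_x)^2 + (v / e$sde_y)^2 <= 1
}

#' Monte-Carlo overlap fraction of two ellipses
#'
#' Estimates intersection area over union area by uniform sampling on the
#' joint bounding box of the two ellipses. Seeded and reproducible; the
#' estimate is symmetric in its arguments under the same seed.
#'
#' @param e1,e2 `sd_ellipse` objects.
#' @param n_samples Number of Monte-Carlo samples (default 1e5).
#' @param seed Integer seed.
#' @return Fraction in \[0, 1\].
#' @export
ellipse_overlap_fraction <- function(e1, e2, n_samples = 1e5, seed = 1L) {
  if (n_samples < 1) stop_domain("n_samples must be at least 1")
  if (e1$sde_x <= 0 || e1$sde_y <= 0 || e2$sde_x <= 0 || e2$sde_y <= 0) {
    warning("degenerate (zero-area) ellipse; overlap reported as 0")
    return(0)
  }
  bbox_of <- function(e) {
    th <- e$theta * pi / 180
    hw <- sqrt((e$sde_x * cos(th))^2 + (e$sde_y * sin(th))^2)
    hh <- sqrt((e$sde_x * sin(th))^2 + (e$sde_y * cos(th))^2)
    c(e$center$x - hw, e$center$x + hw, e$center$y - hh, e$center$y + hh)
  }
  b1 <- bbox_of(e1); b2 <- bbox_of(e2)
  box <- c(min(b1[1], b2[1]), max(b1[2], b2[2]),
           min(b1[3], b2[3]), max(b1[4], b2[4]))
  withr::with_seed(sub_seed(seed, "ellipse_overlap"), {
    px <- stats::runif(n_samples, box[1], box[2])
    py <- stats::runif(n_samples, box[3], box[4])
    in1 <- point_in_ellipse(px, py, e1)
    in2 <- point_in_ellipse(px, py, e2)
    union_n <- sum(in1 | in2)
    if (union_n == 0) return(0)
    sum(in1 & in2) / union_n
  })
}

#' Year-by-year trajectory of mean centers
#'
#' For case clouds, the unweighted annual mean centers; for population
#' trajectories, pass district centroids with annual populations as weights.
#'
#' @param points_by_year Named list (names = years) of point data.frames.
#' @param weights_by_year Optional named list of weight vectors.
#' @return data.frame `year, x, y, n_points`, ordered by year.
#' @export
center_trajectory <- function(points_by_year, weights_by_year = NULL) {
  if (length(points_by_year) == 0L) stop_domain("need at least one year")
  years <- names(points_by_year)
  rows <- lapply(years, function(yr) {
    pts <- points_by_year[[yr]]
    if (!is.null(weights_by_year)) pts$weight <- weights_by_year[[yr]]
    mc <- mean_center(pts)
    data.frame(year = as.integer(yr), x = mc$x, y = mc$y,
               n_points = mc$n_points)
  })
  out <- do.call(rbind, rows)
  out[order(out$year), ]
}

#' Annual ellipse table for a case point cloud
#'
#' @param case_points data.frame `district, year, x, y`.
#' @param scale Axis scale passed to [standard_deviational_ellipse()].
#' @return data.frame `year, cx, cy, sde_x, sde_y, theta_deg, n_points`.
#' @export
annual_ellipses <- function(case_points, scale = 1) {
  years <- sort(unique(case_points$year))
  rows <- lapply(years, function(yr) {
    pts <- case_points[case_points$year == yr, , drop = FALSE]
    e <- standard_deviational_ellipse(pts, scale = scale)
    data.frame(year = yr, cx = e$center$x, cy = e$center$y,
               sde_x = e$sde_x, sde_y = e$sde_y, theta_deg = e$theta,
               n_points = nrow(pts))
  })
  do.call(rbind, rows)
}

#' Discretize an ellipse as a closed polygon
#'
#' @param e An `sd_ellipse`.
#' @param n Number of vertices (default 64; first vertex repeated to close).
#' @return Matrix with columns `x`, `y`.
#' @export
ellipse_polygon <- function(e, n = 64L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)
  th <- e$theta * pi / 180
  u <- e$sde_x * cos(t)
  v <- e$sde_y * sin(t)
  cbind(x = e$center$x + cos(th) * u - sin(th) * v,
        y = e$center$y + sin(th) * u + cos(th) * v)
}
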