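# Independent oracles and in-code fixtures shared across the suite.
# Everything here is written with plain loops, deliberately avoiding the
# package's vectorized code paths.

## ---- published GM(1,1) validation rows (S1, S2, c, p, degree) -------------
## Two ten-district validation tables: one for rate series, one for admission
## count series.
gm_validation_rows <- function() {
  rbind(
    data.frame(table = "rates", district = c(
      "A", "B", "C", "D", "E", "F", "G", "H", "I", "J"),
      s1 = c(0.2509, 0.3704, 0.4803, 0.2585, 0.3451,
             0.0938, 0.4903, 0.3005, 0.1775, 0.341),
      s2 = c(0.0757, 0.1053, 0.1176, 0.059, 0.112,
             0.0373, 0.1273, 0.1163, 0.0729, 0.0802),
      c = c(0.301714, 0.284287, 0.244847, 0.22824, 0.324544,
            0.397655, 0.259637, 0.387022, 0.410704, 0.235191),
      p = c(1, 1, 1, 1, 1, 0.8889, 1, 0.8889, 0.8889, 1),
      degree = c("excellent", "excellent", "excellent", "excellent",
                 "excellent", "good", "excellent", "good", "good",
                 "excellent"),
      stringsAsFactors = FALSE),
    data.frame(table = "admissions", district = c(
      "A", "B", "C", "D", "E", "F", "G", "H", "I", "J"),
      s1 = c(739.5386, 51.1903, 773.7296, 144.2794, 762.7598,
             182.3981, 492.6384, 415.7689, 81.8777, 73.9185),
      s2 = c(157.6849, 12.7783, 164.6242, 35.003, 168.6213,
             37.1975, 112.5286, 85.9678, 17.2176, 16.0493),
      c = c(0.213221, 0.249623, 0.212767, 0.242606, 0.221067,
            0.203936, 0.22842, 0.206768, 0.210284, 0.217122),
      p = rep(1, 10),
      degree = rep("excellent", 10),
      stringsAsFactors = FALSE)
  )
}

## ---- scan oracles ---------------------------------------------------------

oracle_llr <- function(o, e, total) {
  if (o <= e) return(0)
  t1 <- if (o > 0) o * log(o / e) else 0
  rem <- total - o
  t2 <- if (rem > 0) rem * log(rem / (total - e)) else 0
  t1 + t2
}

oracle_expected <- function(panel) {
  g <- sum(panel$admissions) / sum(panel$population)
  g * panel$population
}

## every non-empty district subset crossed with every contiguous year interval
oracle_all_subsets <- function(panel) {
  districts <- sort(unique(panel$district))
  years <- sort(unique(panel$year))
  expected <- oracle_expected(panel)
  total <- sum(panel$admissions)
  rows <- list()
  n <- length(districts)
  for (mask in 1:(2^n - 1)) {
    members <- districts[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    for (ys in years) for (ye in years[years >= ys]) {
      sel <- panel$district %in% members & panel$year >= ys & panel$year <= ye
      o <- sum(panel$admissions[sel]); e <- sum(expected[sel])
      if (e <= 0 || total - e <= 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        key = paste(members, collapse = ","), year_start = ys, year_end = ye,
        observed = o, expected = e, llr = oracle_llr(o, e, total),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

## member-set keys realizable as centroid-in-circle balls
oracle_ball_keys <- function(district_info) {
  keys <- character(0)
  for (i in seq_len(nrow(district_info))) {
    d2 <- (district_info$x - district_info$x[i])^2 +
      (district_info$y - district_info$y[i])^2
    for (r2 in sort(unique(d2))) {
      members <- sort(district_info$district[d2 <= r2])
      keys <- union(keys, paste(members, collapse = ","))
    }
  }
  keys
}

## plain-loop cylinder enumeration following the same window rules
oracle_count_cylinders <- function(district_info, panel,
                                   max_pop_fraction = 0.5,
                                   max_time_fraction = 0.5) {
  districts <- district_info$district
  avg <- sapply(districts, function(d)
    mean(panel$population[panel$district == d]))
  years <- sort(unique(panel$year))
  max_len <- max(1, floor(max_time_fraction * length(years)))
  keys <- character(0)
  for (i in seq_along(districts)) {
    d2 <- (district_info$x - district_info$x[i])^2 +
      (district_info$y - district_info$y[i])^2
    for (r2 in sort(unique(d2))) {
      members <- sort(districts[d2 <= r2])
      if (sum(avg[members]) / sum(avg) > max_pop_fraction) next
      keys <- union(keys, paste(members, collapse = ","))
    }
  }
  n_int <- sum(sapply(seq_len(max_len), function(l) length(years) - l + 1))
  length(keys) * n_int
}

## ---- spatial oracle -------------------------------------------------------

## literal tan-theta ellipse formula; returns the major-axis azimuth measured
## clockwise from north, plus RMS axis lengths
sde_literal <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  A <- sum(dx^2) - sum(dy^2); B <- sum(dx * dy)
  m <- length(x)
  if (abs(B) < 1e-12) {
    theta_north <- if (A >= 0) 90 else 0
  } else {
    theta_north <- atan((A + sqrt(A^2 + 4 * B^2)) / (2 * B)) * 180 / pi
  }
  phi <- (90 - theta_north) * pi / 180          # math convention, radians
  u <- cos(phi) * dx + sin(phi) * dy
  v <- -sin(phi) * dx + cos(phi) * dy
  list(theta_north = theta_north %% 180,
       axis_major = sqrt(mean(u^2)), axis_minor = sqrt(mean(v^2)))
}

rotate_points <- function(pts, deg, about = c(0, 0)) {
  th <- deg * pi / 180
  dx <- pts$x - about[1]; dy <- pts$y - about[2]
  data.frame(x = about[1] + cos(th) * dx - sin(th) * dy,
             y = about[2] + sin(th) * dx + cos(th) * dy)
}

## ---- small panel builders -------------------------------------------------

make_panel <- function(admissions, populations, years, district_xy) {
  d <- nrow(district_xy)
  data.frame(
    district = rep(district_xy$district, times = length(years)),
    year = rep(years, each = d),
    population = rep(populations, times = length(years)),
    admissions = as.vector(admissions),
    stringsAsFactors = FALSE)
}

## homogeneous-risk configuration matching the scan's null model
null_config <- function(seed) {
  panel_config(baseline_rate = 0.001, rate_trend = 1, seed = seed)
}

## districts forming the ball around the first district and its two nearest
## neighbours, in a given geometry
nearest_ball3 <- function(district_info) {
  d2 <- (district_info$x - district_info$x[1])^2 +
    (district_info$y - district_info$y[1])^2
  district_info$district[order(d2)][1:3]
}

## squared normalized ellipse radius (1 on the boundary)
point_in_ellipse_dist <- function(px, py, e) {
  th <- e$theta * pi / 180
  dx <- px - e$center$x; dy <- py - e$center$y
  u <- cos(th) * dx + sin(th) * dy
  v <- -sin(th) * dx + cos(th) * dy
  (u / e$sde_x)^2 + (v / e$sde_y)^2
}
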