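#' Enumerate cylindrical scan windows
#'
#' For each center district, the radius sweeps the sorted centroid-to-centroid
#' distances (including zero); a circular base is kept when its share of the
#' study-average population is at most `max_pop_fraction`. Each retained base
#' is crossed with every contiguous year interval of length at most
#' `max_time_fraction` times the study length. Duplicate windows (identical
#' member set and interval) are removed.
#'
#' @param district_info data.frame `district, x, y`.
#' @param panel data.frame `district, year, population, admissions`.
#' @param max_pop_fraction Maximum base population share (default 0.5).
#' @param max_time_fraction Maximum interval length as a fraction of the study
#'   period (default 0.5).
#' @return List of cylinders; each a list with `center_district`, `radius`,
#'   `member_districts`, `year_start`, `year_end`.
#' @export
enumerate_cylinders <- function(district_info, panel,
                                max_pop_fraction = 0.5,
                                max_time_fraction = 0.5) {
  if (nrow(panel) == 0L) stop_domain("empty panel")
  if (max_pop_fraction <= 0 || max_pop_fraction > 1)
    stop_domain("max_pop_fraction must lie in (0, 1]")
  if (max_time_fraction <= 0 || max_time_fraction > 1)
    stop_domain("max_time_fraction must lie in (0, 1]")

  districts <- district_info$district
  avg_pop <- tapply(panel$population, panel$district, mean)[districts]
  total_pop <- sum(avg_pop)
  years <- sort(unique(panel$year))
  max_len <- max(1L, floor(max_time_fraction * length(years)))
  intervals <- do.call(rbind, lapply(seq_len(max_len), function(len) {
    starts <- seq_len(length(years) - len + 1L)
    cbind(years[starts], years[starts + len - 1L])
  }))

  dist_mat <- as.matrix(stats::dist(district_info[, c("x", "y")]))
  dimnames(dist_mat) <- list(districts, districts)

  bases <- list()
  seen <- character(0)
  for (ctr in districts) {
    radii <- sort(unique(dist_mat[ctr, ]))
    for (r in radii) {
      members <- districts[dist_mat[ctr, ] <= r]
      if (sum(avg_pop[members]) / total_pop > max_pop_fraction) break
      key <- paste(sort(members), collapse = "|")
      if (key %in% seen) next
      seen <- c(seen, key)
      bases[[length(bases) + 1L]] <- list(center = ctr, radius = r,
                                          members = sort(members))
    }
  }

  out <- vector("list", length(bases) * nrow(intervals))
  k <- 0L
  for (b in bases) {
    for (i in seq_len(nrow(intervals))) {
      k <- k + 1L
      out[[k]] <- list(center_district = b$center, radius = b$radius,
                       member_districts = b$members,
                       year_start = intervals[i, 1], year_end = intervals[i, 2])
    }
  }
  out[seq_len(k)]
}

## Expected counts per district-year under whole-study indirect
## standardization: total cases allocated proportionally to person-years.
scan_expected <- function(panel) {
  g <- sum(panel$admissions) / sum(panel$population)
  expected_cases(g, panel$population)
}

## Vectorized Kulldorff discrete-Poisson log likelihood ratio, high-rate
## windows only; 0 * log(0/...) taken as 0.
llr_poisson <- function(o_in, e_in, total) {
  out_o <- total - o_in
  out_e <- total - e_in
  t1 <- ifelse(o_in > 0, o_in * log(o_in / e_in), 0)
  t2 <- ifelse(out_o > 0, out_o * log(out_o / out_e), 0)
  llr <- t1 + t2
  llr[o_in <= e_in] <- 0
  llr
}

#' Observed, expected, LLR and relative risk of one window
#'
#' Expected counts use the whole-study-period general rate applied to
#' district-year populations, so they are purely population-proportional
#' across space-time. The log likelihood ratio is the discrete-Poisson scan
#' statistic for high-rate windows (zero when the window rate is at or below
#' the outside rate); the relative risk compares the rate inside the window
#' with the rate outside it.
#'
#' @param cylinder A cylinder from [enumerate_cylinders()].
#' @param panel data.frame `district, year, population, admissions`.
#' @return List with `observed`, `expected`, `llr`, `relative_risk`.
#' @export
window_stats <- function(cylinder, panel) {
  expected <- scan_expected(panel)
  total <- sum(panel$admissions)
  sel <- panel$district %in% cylinder$member_districts &
    panel$year >= cylinder$year_start & panel$year <= cylinder$year_end
  o_in <- sum(panel$admissions[sel])
  e_in <- sum(expected[sel])
  if (e_in <= 0) stop_domain("window has zero expected count")
  if (total - e_in <= 0) stop_domain("window must not cover all expected cases")
  rr_out <- (total - o_in) / (total - e_in)
  rr <- if (rr_out > 0) (o_in / e_in) / rr_out else Inf
  list(observed = o_in, expected = e_in,
       llr = llr_poisson(o_in, e_in, total),
       relative_risk = rr)
}

## Indicator matrix (cylinders x panel rows) for fast replicate scoring.
cylinder_matrix <- function(cylinders, panel) {
  m <- matrix(0, nrow = length(cylinders), ncol = nrow(panel))
  for (i in seq_along(cylinders)) {
    cy <- cylinders[[i]]
    m[i, panel$district %in% cy$member_districts &
        panel$year >= cy$year_start & panel$year <= cy$year_end] <- 1
  }
  m
}

#' Monte-Carlo p-values for candidate clusters
#'
#' Replicate datasets redistribute the observed case total across district-year
#' cells multinomially with probabilities proportional to the expected counts
#' (the standard conditioning of the discrete-Poisson scan). Each candidate's
#' p-value is `(1 + number of replicate maximum LLRs >= the candidate's LLR) /
#' (1 + n_replicates)`.
#'
#' @param panel data.frame `district, year, population, admissions`.
#' @param cylinders Output of [enumerate_cylinders()].
#' @param n_replicates Number of Monte-Carlo replicates (default 999).
#' @param seed Integer seed.
#' @return Numeric p-value per cylinder, in (0, 1].
#' @export
monte_carlo_pvalues <- function(panel, cylinders, n_replicates = 999L, seed = 1L) {
  if (n_replicates < 1) stop_domain("n_replicates must be at least 1")
  expected <- scan_expected(panel)
  total <- sum(panel$admissions)
  M <- cylinder_matrix(cylinders, panel)
  e_in <- as.numeric(M %*% expected)
  o_in <- as.numeric(M %*% panel$admissions)
  obs_llr <- llr_poisson(o_in, e_in, total)
  if (total == 0) return(rep(1, length(cylinders)))
  rep_max <- withr::with_seed(sub_seed(seed, "scan_mc"), {
    reps <- stats::rmultinom(n_replicates, total, prob = expected)
    O <- M %*% reps                          # cylinders x replicates
    L <- llr_poisson(O, e_in, total)         # recycles e_in down columns
    apply(L, 2, max)
  })
  vapply(obs_llr, function(l) (1 + sum(rep_max >= l)) / (1 + n_replicates),
         numeric(1))
}

#' Detect most-likely and secondary space-time clusters
#'
#' Runs the full retrospective scan: window enumeration, discrete-Poisson LLR,
#' Monte-Carlo inference. The most likely cluster maximizes the LLR (ties go
#' to the smaller member set, then lexicographic district ids); secondary
#' clusters are significant windows sharing no district with any better-ranked
#' reported cluster.
#'
#' @param panel data.frame `district, year, population, admissions`.
#' @param district_info data.frame `district, x, y`.
#' @param max_pop_fraction,max_time_fraction Window caps
#'   (see [enumerate_cylinders()]).
#' @param n_replicates Monte-Carlo replicates (default 999).
#' @param alpha Significance level for secondary clusters (default 0.05).
#' @param seed Integer seed.
#' @return data.frame of class `cluster_results`, one row per reported
#'   cluster: `rank, districts, year_start, year_end, observed, expected, llr,
#'   rr, p`. Zero rows when the panel has no admissions.
#' @export
detect_clusters <- function(panel, district_info,
                            max_pop_fraction = 0.5, max_time_fraction = 0.5,
                            n_replicates = 999L, alpha = 0.05, seed = 1L) {
  empty <- data.frame(rank = integer(), districts = character(),
                      year_start = integer(), year_end = integer(),
                      observed = numeric(), expected = numeric(),
                      llr = numeric(), rr = numeric(), p = numeric(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("cluster_results", "data.frame")
  if (sum(panel$admissions) == 0) return(empty)

  cylinders <- enumerate_cylinders(district_info, panel,
                                   max_pop_fraction, max_time_fraction)
  expected <- scan_expected(panel)
  total <- sum(panel$admissions)
  M <- cylinder_matrix(cylinders, panel)
  e_in <- as.numeric(M %*% expected)
  o_in <- as.numeric(M %*% panel$admissions)
  llr <- llr_poisson(o_in, e_in, total)
  p <- monte_carlo_pvalues(panel, cylinders, n_replicates, seed)

  n_members <- vapply(cylinders, function(cy) length(cy$member_districts),
                      integer(1))
  member_key <- vapply(cylinders, function(cy)
    paste(cy$member_districts, collapse = ","), character(1))
  ord <- order(-llr, n_members, member_key,
               vapply(cylinders, `[[`, numeric(1), "year_start"))

  reported <- integer(0)
  used_districts <- character(0)
  for (i in ord) {
    if (llr[i] <= 0) break
    if (length(reported) > 0 &&
        (p[i] > alpha ||
         any(cylinders[[i]]$member_districts %in% used_districts))) next
    reported <- c(reported, i)
    used_districts <- union(used_districts, cylinders[[i]]$member_districts)
  }
  if (length(reported) == 0) return(empty)

  out <- data.frame(
    rank = seq_along(reported),
    districts = member_key[reported],
    year_start = vapply(cylinders[reported], `[[`, numeric(1), "year_start"),
    year_end = vapply(cylinders[reported], `[[`, numeric(1), "year_end"),
    observed = o_in[reported],
    expected = e_in[reported],
    llr = llr[reported],
    rr = (o_in[reported] / e_in[reported]) /
      ((total - o_in[reported]) / (total - e_in[reported])),
    p = p[reported],
    stringsAsFactors = FALSE
  )
  class(out) <- c("cluster_results", "data.frame")
  out
}

#' @export
print.cluster_results <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("<cluster_results> no clusters detected\n")
    return(invisible(x))
  }
  cat(sprintf("<cluster_results> %d cluster(s); most likely: {%s} %d-%d, LLR %.3f, RR %.2f, p %.3g\n",
              nrow(x), x$districts[1], x$year_start[1], x$year_end[1],
              x$llr[1], x$rr[1], x$p[1]))
  invisible(x)
}
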