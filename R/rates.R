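#' Crude admission rate per 1,000 residents
#'
#' @param admissions Non-negative case count(s).
#' @param population Positive population(s) at risk.
#' @return Admissions per 1,000 residents (vectorized).
#' @export
incidence_rate <- function(admissions, population) {
  if (any(!is.finite(population)) || any(population <= 0))
    stop_domain("population must be positive")
  if (any(admissions < 0)) stop_domain("admissions must be non-negative")
  1000 * admissions / population
}

#' City-wide (general) admission rate for one year
#'
#' Pooled rate per person-year: total admissions over total population across
#' the districts present in that year. This is the rate used for indirect
#' standardization.
#'
#' @param panel data.frame with `district, year, population, admissions`.
#' @param year Study year.
#' @return Rate per person (not per 1,000).
#' @export
general_rate <- function(panel, year) {
  slice <- panel[panel$year == year, , drop = FALSE]
  if (nrow(slice) == 0L) stop_domain("no districts observed in year ", year)
  sum(slice$admissions) / sum(slice$population)
}

#' Expected cases under indirect standardization
#'
#' @param general_rate City-wide rate per person.
#' @param population District population.
#' @return Expected case count `general_rate * population`.
#' @export
expected_cases <- function(general_rate, population) {
  if (any(general_rate < 0) || any(population < 0))
    stop_domain("inputs must be non-negative")
  general_rate * population
}

#' Standardized admission ratio
#'
#' Observed over expected admissions; values above 1 mark districts with
#' above-average relative risk.
#'
#' @param observed Observed case count.
#' @param expected Expected case count (> 0).
#' @return The ratio observed / expected.
#' @export
standardized_ratio <- function(observed, expected) {
  if (any(expected <= 0)) stop_domain("expected cases must be positive")
  observed / expected
}

#' Classify average rates into four ranks by standard deviation
#'
#' Z-scores each district's value against the mean and (population-convention)
#' standard deviation of all values and bins them at the z cut points
#' (default -0.29, 0.61, 1.5), using left-open/right-closed intervals. With
#' `on = "value"` the cut points are applied to the raw values instead, which
#' reproduces published fixed-interval classifications directly.
#'
#' @param values Average rate per district (length >= 2 for z-scoring).
#' @param breaks Three increasing cut points; z-scores by default.
#' @param on Either `"z"` (default) or `"value"`.
#' @return Integer ranks 1-4.
#' @export
classify_ir_rank <- function(values, breaks = c(-0.29, 0.61, 1.5),
                             on = c("z", "value")) {
  on <- match.arg(on)
  if (length(breaks) != 3L || is.unsorted(breaks, strictly = TRUE))
    stop_domain("breaks must be three strictly increasing cut points")
  if (on == "z") {
    if (length(values) < 2L) stop_domain("need at least 2 districts to z-score")
    s <- sqrt(mean((values - mean(values))^2))
    if (s == 0) {
      warning("zero variance across districts; assigning all to rank 2")
      return(rep(2L, length(values)))
    }
    scores <- (values - mean(values)) / s
  } else {
    scores <- values
  }
  ranks <- 1L + findInterval(scores, breaks, left.open = TRUE)
  as.integer(ranks)
}

#' Classify a standardized ratio into five ranks
#'
#' Rank = 1 + number of breakpoints strictly below the value. The default
#' breakpoints are the published k-means-derived bounds
#' \{0.580, 0.890, 1.270, 1.840, 2.500\}; values above the last bound are
#' capped at rank 5 with a warning.
#'
#' @param sr Standardized ratio(s), non-negative.
#' @param breakpoints Strictly increasing cut points.
#' @return Integer rank(s) 1-5.
#' @export
classify_sr_rank <- function(sr, breakpoints = c(0.580, 0.890, 1.270, 1.840, 2.500)) {
  if (any(sr < 0)) stop_domain("standardized ratio must be non-negative")
  if (is.unsorted(breakpoints, strictly = TRUE))
    stop_domain("breakpoints must be strictly increasing")
  k <- length(breakpoints)
  rank <- 1L + vapply(sr, function(v) sum(breakpoints < v), integer(1))
  if (any(rank > k)) {
    warning("value(s) above the top breakpoint; capped at the highest rank")
    rank <- pmin(rank, k)
  }
  ## with k breakpoints the usable ranks are 1..k; the published scheme uses
  ## five bounds whose last (2.500) caps the top class
  pmin(as.integer(rank), 5L)
}

#' One-dimensional k-means cluster boundaries
#'
#' Lloyd's iteration (via [stats::kmeans()]) from deterministic quantile-based
#' initial centers, returning the midpoints between adjacent sorted cluster
#' extremes. These boundaries regenerate data-driven rank breakpoints.
#'
#' @param values Numeric vector.
#' @param k Number of clusters (1 <= k <= number of distinct values).
#' @param seed Unused (initialization is deterministic); kept for interface
#'   stability.
#' @return k - 1 increasing boundaries.
#' @export
kmeans_1d <- function(values, k, seed = 0L) {
  if (k < 1) stop_domain("k must be at least 1")
  ux <- sort(unique(values))
  if (k > length(ux)) stop_domain("k exceeds the number of distinct values")
  if (k == 1L) return(numeric(0))
  if (k == length(ux)) {
    ## every distinct value its own cluster
    return((ux[-1] + ux[-length(ux)]) / 2)
  }
  centers <- stats::quantile(values, probs = (seq_len(k) - 0.5) / k,
                             names = FALSE, type = 7)
  centers <- centers + seq_len(k) * 1e-9 * max(abs(centers), 1)  # break ties
  fit <- stats::kmeans(values, centers = matrix(centers, ncol = 1),
                       algorithm = "Lloyd", iter.max = 100L)
  groups <- split(values, fit$cluster)
  ord <- order(vapply(groups, min, numeric(1)))
  groups <- groups[ord]
  upper <- vapply(groups[-length(groups)], max, numeric(1))
  lower <- vapply(groups[-1], min, numeric(1))
  unname((upper + lower) / 2)
}

#' Direction of a rank change between two periods
#'
#' @param rank_start,rank_end Ranks in 1-5.
#' @return One of `"higher"`, `"lower"`, `"invariant"` (vectorized).
#' @export
sr_change_pattern <- function(rank_start, rank_end) {
  if (any(rank_start < 1 | rank_start > 5 | rank_end < 1 | rank_end > 5))
    stop_domain("ranks must lie in 1..5")
  ifelse(rank_end > rank_start, "higher",
         ifelse(rank_end < rank_start, "lower", "invariant"))
}

#' Full rate table for a panel
#'
#' For every district-year: crude rate per 1,000, expected cases under the
#' year's city-wide rate, standardized ratio, and rank classifications. IR
#' ranks are computed once per district from the study-average crude rate;
#' SR ranks are annual.
#'
#' @param panel data.frame `district, year, population, admissions`.
#' @param sr_breakpoints Breakpoints passed to [classify_sr_rank()].
#' @param ir_breaks,ir_on Passed to [classify_ir_rank()].
#' @return data.frame `district, year, ir, expected, sr, ir_rank, sr_rank`.
#' @export
rate_table <- function(panel, sr_breakpoints = c(0.580, 0.890, 1.270, 1.840, 2.500),
                       ir_breaks = c(-0.29, 0.61, 1.5), ir_on = "z") {
  out <- panel[order(panel$year, panel$district),
               c("district", "year", "population", "admissions")]
  out$ir <- incidence_rate(out$admissions, out$population)
  g <- vapply(out$year, function(y) general_rate(panel, y), numeric(1))
  out$expected <- expected_cases(g, out$population)
  out$sr <- standardized_ratio(out$admissions, out$expected)
  avg_ir <- tapply(out$ir, out$district, mean)
  ir_rank <- classify_ir_rank(as.numeric(avg_ir), breaks = ir_breaks, on = ir_on)
  names(ir_rank) <- names(avg_ir)
  out$ir_rank <- ir_rank[out$district]
  out$sr_rank <- suppressWarnings(classify_sr_rank(out$sr, sr_breakpoints))
  rownames(out) <- NULL
  out[, c("district", "year", "ir", "expected", "sr", "ir_rank", "sr_rank")]
}

#' Rank change patterns over sub-intervals of the study
#'
#' Splits the study years into consecutive windows of `every` years and labels
#' each district's SR-rank transition between the first and last year of each
#' window, plus the whole study period.
#'
#' @param rates A [rate_table()] result.
#' @param every Window length in years (default 3).
#' @return data.frame `district, interval, pattern`.
#' @export
sr_change_table <- function(rates, every = 3L) {
  years <- sort(unique(rates$year))
  starts <- years[seq(1, length(years) - 1, by = every)]
  wins <- lapply(starts, function(s) c(s, min(s + every, max(years))))
  wins <- c(wins, list(c(min(years), max(years))))
  rows <- lapply(wins, function(w) {
    a <- rates[rates$year == w[1], c("district", "sr_rank")]
    b <- rates[rates$year == w[2], c("district", "sr_rank")]
    m <- merge(a, b, by = "district", suffixes = c("_start", "_end"))
    data.frame(district = m$district,
               interval = sprintf("%d-%d", w[1], w[2]),
               pattern = sr_change_pattern(m$sr_rank_start, m$sr_rank_end),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[!duplicated(out[c("district", "interval")]), ]
}
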