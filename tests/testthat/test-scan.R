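two_by_two <- function() {
  dinfo <- data.frame(district = c("d1", "d2"), x = c(0, 10000),
                      y = c(0, 0), hospitals = 1, stringsAsFactors = FALSE)
  panel <- make_panel(admissions = c(10, 10, 10, 30),
                      populations = c(1000, 1000),
                      years = c(2003, 2004), district_xy = dinfo)
  list(panel = panel, dinfo = dinfo)
}

test_that("cylinder enumeration respects the population and time caps", {
  tt <- two_by_two()
  cyl <- enumerate_cylinders(tt$dinfo, tt$panel)
  ## two equal-population districts: the joint base exceeds 50%, and the
  ## two-year interval exceeds half the study length, leaving 2 x 2 windows
  expect_length(cyl, 4)
  expect_true(all(vapply(cyl, function(cy)
    length(cy$member_districts) == 1 && cy$year_start == cy$year_end,
    logical(1))))

  one <- enumerate_cylinders(
    data.frame(district = "a", x = 0, y = 0),
    data.frame(district = "a", year = 2003, population = 10, admissions = 1),
    max_pop_fraction = 1, max_time_fraction = 1)
  expect_length(one, 1)

  expect_error(enumerate_cylinders(tt$dinfo, tt$panel[0, ]), "empty panel")

  ## brute-force count on 3 districts x 3 years with no caps
  dinfo3 <- data.frame(district = c("a", "b", "c"),
                       x = c(0, 1, 5), y = c(0, 0, 0))
  panel3 <- make_panel(rpois(9, 20) + 1, c(100, 200, 300), 2003:2005, dinfo3)
  for (frac in list(c(1, 1), c(0.5, 0.5), c(0.7, 1))) {
    expect_length(
      enumerate_cylinders(dinfo3, panel3, frac[1], frac[2]),
      oracle_count_cylinders(dinfo3, panel3, frac[1], frac[2]))
  }
})

test_that("window statistics reproduce the hand-computed example", {
  tt <- two_by_two()
  win <- list(center_district = "d2", radius = 0, member_districts = "d2",
              year_start = 2004, year_end = 2004)
  ws <- window_stats(win, tt$panel)
  expect_equal(ws$observed, 30)
  expect_equal(ws$expected, 15)
  expect_equal(ws$llr, 30 * log(2) + 30 * log(30 / 45))
  expect_equal(ws$llr, 8.630462, tolerance = 1e-6)
  expect_equal(ws$relative_risk, 3)

  ## a balanced window scores zero
  win1 <- list(member_districts = "d1", year_start = 2003, year_end = 2003)
  ws1 <- window_stats(win1, tt$panel)
  expect_equal(ws1$observed, 10)
  expect_equal(ws1$llr, 0)

  ## low-rate windows score zero under the high-rate convention
  win_low <- list(member_districts = "d1", year_start = 2003, year_end = 2004)
  expect_equal(window_stats(win_low, tt$panel)$llr, 0)

  ## the whole study area has relative risk 1 and llr 0
  win_all <- list(member_districts = c("d1", "d2"),
                  year_start = 2003, year_end = 2004)
  expect_error(window_stats(win_all, tt$panel), "all expected")
})

test_that("llr is non-negative and zero exactly when O <= E", {
  set.seed(44)
  total <- 500
  for (rep in 1:50) {
    e <- runif(1, 1, total - 1)
    o <- sample(0:total, 1)
    l <- citysurv:::llr_poisson(o, e, total)
    expect_gte(l, 0)
    if (o <= e) expect_equal(l, 0) else expect_gt(l, 0)
    expect_equal(l, oracle_llr(o, e, total))
  }
})

test_that("the most likely cluster matches brute-force enumeration", {
  set.seed(99)
  geoms <- list(
    data.frame(district = c("a", "b", "c"), x = c(0, 800, 5000), y = c(0, 0, 0)),
    data.frame(district = c("a", "b", "c", "d"),
               x = c(0, 1000, 4000, 9000), y = c(0, 500, -300, 200))
  )
  for (dinfo in geoms) {
    for (rep in 1:8) {
      d <- nrow(dinfo)
      panel <- make_panel(rpois(d * 3, lambda = sample(5:40, 1)) + 1,
                          populations = runif(d, 500, 2000),
                          years = 2003:2005, district_xy = dinfo)
      res <- detect_clusters(panel, dinfo, max_pop_fraction = 1,
                             max_time_fraction = 1, n_replicates = 19,
                             seed = rep)
      oracle <- oracle_all_subsets(panel)
      balls <- oracle_ball_keys(dinfo)
      windowed <- oracle[oracle$key %in% balls, ]
      best <- windowed[which.max(windowed$llr), ]
      if (best$llr == 0) {
        expect_identical(nrow(res), 0L)
      } else {
        expect_equal(res$llr[1], best$llr, tolerance = 1e-12)
        expect_identical(res$districts[1], best$key)
        expect_equal(res$year_start[1], best$year_start)
        expect_equal(res$year_end[1], best$year_end)
      }
    }
  }
})

test_that("monte carlo p-values are sane and order-invariant", {
  tt <- two_by_two()
  cyl <- enumerate_cylinders(tt$dinfo, tt$panel)
  p <- monte_carlo_pvalues(tt$panel, cyl, n_replicates = 99, seed = 12)
  expect_true(all(p > 0 & p <= 1))
  llr0 <- vapply(cyl, function(cy) window_stats(cy, tt$panel)$llr, numeric(1))
  expect_true(all(p[llr0 == 0] == 1))

  perm <- rev(cyl)
  p_perm <- monte_carlo_pvalues(tt$panel, perm, n_replicates = 99, seed = 12)
  expect_equal(p_perm, rev(p))
})

test_that("detect_clusters handles empty panels and reports disjoint secondaries", {
  tt <- two_by_two()
  none <- tt$panel
  none$admissions <- 0
  expect_identical(nrow(detect_clusters(none, tt$dinfo)), 0L)

  res <- detect_clusters(tt$panel, tt$dinfo, n_replicates = 99, seed = 1)
  expect_identical(res$districts[1], "d2")
  expect_identical(res$year_start[1], 2004)
  if (nrow(res) > 1) {
    sets <- strsplit(res$districts, ",")
    for (i in 2:nrow(res)) {
      expect_lte(res$p[i], 0.05)
      for (j in seq_len(i - 1))
        expect_length(intersect(sets[[i]], sets[[j]]), 0)
    }
  }
})

test_that("an injected cluster is found in a full-size panel", {
  base <- generate_panel(null_config(seed = 77L), case_points = FALSE)
  members <- nearest_ball3(base$district_info)
  inj <- inject_cluster(base, members, 2008:2012, 3, seed = 1L)
  res <- detect_clusters(inj$records, inj$district_info,
                         n_replicates = 99, seed = 2L)
  expect_identical(sort(strsplit(res$districts[1], ",")[[1]]), sort(members))
  expect_identical(c(res$year_start[1], res$year_end[1]), c(2008, 2012))
  expect_equal(res$p[1], 1 / 100)
  expect_gt(res$rr[1], 2)
})
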