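test_that("climate aligns as previous-year plus current-year month slots", {
  cl <- random_climate("tmax", 1963:1965, seed = 3)
  al <- align_climate(cl, 1964:1966)
  expect_equal(dim(al), c(3L, 24L))
  expect_equal(unname(al["1964", 1:12]), unname(cl$values["1963", ]))
  expect_equal(unname(al["1964", 13:24]), unname(cl$values["1964", ]))
  # chronology year with no previous-year climate: slots 1-12 missing
  al2 <- align_climate(cl, 1963:1965)
  expect_true(all(is.na(al2["1963", 1:12])))
  expect_false(anyNA(al2["1963", 13:24]))
  # constant climate gives a constant matrix
  cl0 <- qwa_climate("tmax", 1963:1965, matrix(7, 3, 12))
  expect_true(all(align_climate(cl0, 1964:1965) == 7))
  expect_error(align_climate(cl, 2100:2105), "no overlap")
})

test_that("monthly correlations recover a planted single-month signal", {
  cl <- random_climate("precip", 1962:2019, seed = 6, mean = 50, sd = 15)
  yrs <- 1963:2019
  chron <- data.frame(year = yrs,
                      LD = cl$values[match(yrs, cl$years), 5])  # current May
  mc <- monthly_correlations(chron, cl)
  hit <- mc[mc$slot == 17L, ]
  expect_equal(hit$r, 1)
  expect_lt(hit$p, 1e-10)
  expect_equal(hit$month, "May")
  expect_true(hit$significant)

  # negation antisymmetry
  neg <- cl
  neg$values <- -neg$values
  mcn <- monthly_correlations(chron, neg)
  expect_equal(mcn$r, -mc$r)
  expect_equal(mcn$p, mc$p)
})

test_that("a signal-free chronology yields near-nominal false positives", {
  cl <- random_climate("tmax", 1962:2019, seed = 7)
  set.seed(8)
  chron <- data.frame(year = 1963:2019, LD = stats::rnorm(57))
  mc <- monthly_correlations(chron, cl)
  expect_equal(nrow(mc), 20L)
  expect_lte(sum(mc$significant), 5L)
})

test_that("the seasonal scan at L = 1 is the monthly grid, bit for bit", {
  cl <- random_climate("spei", 1962:2019, seed = 9, mean = 0, sd = 1)
  set.seed(10)
  chron <- data.frame(year = 1963:2019, LD = stats::rnorm(57))
  mc <- monthly_correlations(chron, cl)
  sc <- seasonal_scan(chron, cl, lengths = 1:5)
  l1 <- sc[sc$length == 1L, ]
  expect_identical(l1$r, mc$r)
  expect_identical(l1$p, mc$p)
  expect_identical(l1$n, mc$n)
})

test_that("seasonal aggregates recover a planted multi-month window", {
  cl <- random_climate("tmax", 1962:2019, seed = 11)
  yrs <- 1963:2019
  chron <- data.frame(year = yrs,
                      LD = rowMeans(cl$values[match(yrs, cl$years), 4:6]))
  sc <- seasonal_scan(chron, cl, lengths = 1:6)
  top <- sc[which.max(abs(sc$r)), ]
  expect_equal(top$end_slot, 18L)  # current June
  expect_equal(top$length, 3L)
  expect_equal(top$r, 1)

  # precipitation uses totals: planting a sum is recovered exactly
  pr <- random_climate("precip", 1962:2019, seed = 12, mean = 60, sd = 20)
  chron2 <- data.frame(year = yrs,
                       P = rowSums(pr$values[match(yrs, pr$years), 5:6]))
  sc2 <- seasonal_scan(chron2, pr, lengths = 1:4)
  top2 <- sc2[which.max(abs(sc2$r)), ]
  expect_equal(top2$aggregate, "sum")
  expect_equal(top2$window, "May-Jun")
  expect_equal(top2$r, 1)

  # windows reaching before the axis start are missing
  early <- sc[sc$end_slot == 3L & sc$length == 6L, ]
  expect_true(is.na(early$r))
})

test_that("best_season maximizes |r| with shorter-then-later tie-breaking", {
  scan <- data.frame(chronology = "LD", variable = "tmax",
                     end_slot = c(17L, 18L, 19L, 20L),
                     window = c("a", "b", "c", "d"),
                     length = c(1L, 5L, 2L, 2L),
                     aggregate = "mean",
                     r = c(0.5, -0.6, NA, 0.5),
                     p = c(0.01, 0.005, NA, 0.01),
                     n = 57L, significant = TRUE)
  expect_equal(best_season(scan)$r, -0.6)        # |r| rule, sign retained
  scan$r[2] <- 0.5                               # three-way tie at |r| = 0.5
  b <- best_season(scan)
  expect_equal(b$length, 1L)                     # shortest wins
  scan$length[1] <- 2L
  b2 <- best_season(scan)
  expect_equal(b2$end_slot, 20L)                 # then the later end month
  expect_equal(best_season(scan[1, ])$end_slot, 17L)
  expect_error(best_season(scan[is.na(scan$r), ]), "no non-missing")
})

test_that("critical correlation thresholds invert the t-transform", {
  expect_equal(critical_r(57), 0.2609, tolerance = 1e-3)
  # oracle: simulate the null at small n and compare rejection quantile
  expect_equal(critical_r(12, 0.05),
               sqrt(stats::qt(0.975, 10)^2 / (stats::qt(0.975, 10)^2 + 10)))
  expect_lt(critical_r(57, 0.999), 0.01)
  ns <- c(10, 20, 50, 100, 500)
  expect_true(all(diff(sapply(ns, critical_r)) < 0))
  expect_error(critical_r(3), "n >= 4")
})

test_that("spatial fields reproduce planted and uniform structure", {
  p <- qwa_params(seed = 90L)
  cl <- gen_climate(p)
  g <- gen_grid(cl$tmax, p, lats = c(33, 34.2, 36), lons = c(35, 36.1, 38))
  yrs <- p$years
  # chronology equal to one cell's July value: r = 1 at that cell
  cell_jul <- g$values[match(yrs, g$years), 7, 2, 2]
  chron <- data.frame(year = yrs, LD = cell_jul)
  sc <- spatial_correlation(chron, g, end_slot = 19L, win_length = 1L)
  expect_equal(sc$r[sc$lat == 34.2 & sc$lon == 36.1], 1)
  expect_true(all(abs(sc$r) <= 1))

  # spatially uniform grid: constant map equal to the site correlation
  arr <- array(rep(cl$tmax$values, 4), c(length(cl$tmax$years), 12, 2, 2))
  gu <- qwa_grid("tmax", cl$tmax$years, c(33, 34), c(35, 36), arr)
  set.seed(91)
  chron2 <- data.frame(year = yrs, LD = stats::rnorm(length(yrs)))
  scu <- spatial_correlation(chron2, gu, end_slot = 19L, win_length = 3L)
  expect_equal(length(unique(round(scu$r, 12))), 1L)
  site <- seasonal_scan(chron2, cl["tmax"], lengths = 3L, slots = 19L)
  expect_equal(scu$r[1], site$r[site$length == 3L], tolerance = 1e-12)
})

test_that("first-difference filtering strips shared trends from correlations", {
  yrs <- 1963:2019
  set.seed(13)
  trend <- 0.05 * seq_along(yrs)
  clv <- matrix(stats::rnorm(58 * 12, 15, 1), 58, 12)
  clv[, 7] <- clv[, 7] + c(0, trend)     # trending current July
  cl <- qwa_climate("tmax", 1962:2019, clv)
  chron <- data.frame(year = yrs, LD = trend + stats::rnorm(57, 0, 0.3))
  raw <- monthly_correlations(chron, cl)
  dif <- monthly_correlations(chron, cl, filter = "first_diff")
  jul <- function(m) m$r[m$slot == 19L]
  expect_gt(abs(jul(raw)), abs(jul(dif)))
  expect_equal(dif$n[1], 56L)
})
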