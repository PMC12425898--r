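test_that("z-transform standardizes to mean 0, SD 1 over the scaling period", {
  expect_equal(ztransform(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(5)
  x <- stats::rnorm(57, 10, 3)
  z <- ztransform(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(stats::sd(z) - 1), 1e-12)
  expect_error(ztransform(rep(4, 20)), "constant")

  # values outside the period are scaled with the period's mean/SD
  yrs <- 2000:2056
  zp <- ztransform(x, yrs, period = c(2000, 2029))
  expect_lt(abs(mean(zp[1:30])), 1e-12)
  expect_lt(abs(stats::sd(zp[1:30]) - 1), 1e-12)
  expect_equal(zp[31], (x[31] - mean(x[1:30])) / stats::sd(x[1:30]))
})

test_that("first differences drop persistence and carry the later year", {
  expect_equal(first_difference(c(1, 3, 2)), c(2, -1))
  expect_equal(first_difference(rep(5, 10)), rep(0, 9))
  d <- first_difference(c(a = 1, b = 2, c = 4), years = 2000:2002)
  expect_equal(names(d), c("2001", "2002"))
  expect_error(first_difference(1), "at least 2")

  set.seed(11)
  x <- as.numeric(stats::arima.sim(list(ar = 0.7), 500))
  expect_lt(ar1(first_difference(x)), ar1(x))
})

test_that("biweight mean matches an independent objective-minimization oracle", {
  expect_equal(biweight_mean(c(5, 5, 5)), 5)
  expect_equal(biweight_mean(c(1, 2, 3)), 2)
  # all-but-one identical: MAD = 0 guard returns the median
  expect_equal(biweight_mean(c(1, 1, 1, 1, 100)), 1)

  # independent oracle: minimize the biweight rho objective over the
  # median's basin (the objective is non-convex; the far-outlier basin is
  # not the estimate either method targets)
  bi_rho_argmin <- function(x, c = 9) {
    S <- stats::mad(x, constant = 1)
    med <- stats::median(x)
    obj <- function(T0) {
      u <- (x - T0) / (c * S)
      sum(ifelse(abs(u) < 1, 1 - (1 - u^2)^3, 1))
    }
    stats::optimize(obj, med + c(-1, 1) * c * S / 2, tol = 1e-10)$minimum
  }
  set.seed(12)
  for (i in 1:5) {
    x <- c(stats::rnorm(20, 10, 1), 40)
    expect_equal(biweight_mean(x), bi_rho_argmin(x), tolerance = 1e-5)
  }
})

test_that("power transform homogenizes level-dependent spread", {
  spread_slope <- function(x) {
    s <- abs(diff(x))
    l <- (x[-1] + x[-length(x)]) / 2
    ok <- s > 0
    stats::coef(stats::lm(log(s[ok]) ~ log(l[ok])))[[2]]
  }
  # additive noise on a drifting level: spread independent of level, p ~ 1
  set.seed(31)
  lev <- seq(5, 50, length.out = 300)
  x_add <- lev + stats::rnorm(300)
  ta <- power_transform(x_add)
  expect_lt(abs(attr(ta, "power") - 1), 0.15)
  expect_false(attr(ta, "log"))

  # exactly geometric growth: spread proportional to level, p = 0, log
  x_geo <- 10 * 1.05^(1:50)
  tg <- power_transform(x_geo)
  expect_lt(abs(attr(tg, "power")), 0.05)
  expect_true(attr(tg, "log"))

  # noisy multiplicative series: small estimated power, and the transform
  # homogenizes (smaller |slope| of log spread on log level)
  x_mult <- lev * exp(stats::rnorm(300, 0, 0.15))
  tm <- power_transform(x_mult)
  expect_lt(abs(attr(tm, "power")), 0.3)
  expect_lt(abs(spread_slope(as.numeric(tm))), abs(spread_slope(x_mult)))
  expect_error(power_transform(rep(2, 20)), "positive-spread")
})

test_that("spline detrending reproduces linear trends and the cutoff response", {
  n <- 100
  t <- 1:n
  lin <- spline_detrend(10 + 0.05 * t)
  expect_true(all(abs(lin$index - 1) < 0.01))

  # response at the cutoff wavelength ~ 0.5 (measured on the interior to
  # keep natural-spline boundary leakage out of the estimate)
  wv <- 0.66 * n
  x <- 10 + 0.05 * t + 2 * sin(2 * pi * t / wv)
  d <- spline_detrend(x)
  i <- 26:75
  ratio <- sin_amplitude(d$fit[i], t[i], wv) / 2
  expect_gt(ratio, 0.45)
  expect_lt(ratio, 0.55)

  # high-frequency variability survives in the index nearly intact
  xh <- 30 + 0.05 * t + 2 * sin(2 * pi * t / (n / 10))
  dh <- spline_detrend(xh)
  amp_idx <- sin_amplitude((dh$index - 1) * mean(dh$fit), t, n / 10)
  expect_gt(amp_idx / 2, 0.9)

  expect_error(spline_detrend(sin(1:50) - 2), "non-positive")
})

test_that("ring-width indices average to ~1 on multiplicative synthetic growth", {
  p <- qwa_params(seed = 14L)
  rwl <- gen_ringwidths(gen_climate(p), p)
  rc <- rw_chronology(rwl)
  expect_lt(abs(mean(rc$chronology$index) - 1), 0.05)
  per_core <- tapply(rc$indices$index, rc$indices$core, mean)
  expect_true(all(abs(per_core - 1) < 0.1))
})

test_that("rbar equals the brute-force mean of pairwise correlations", {
  yrs <- 1963:2019
  set.seed(41)
  common <- stats::rnorm(57)
  m <- sapply(1:4, function(i) common + stats::rnorm(57, 0, 1.2))
  rownames(m) <- yrs
  pairwise <- combn(4, 2, function(ij) stats::cor(m[, ij[1]], m[, ij[2]]))
  expect_equal(rbar(m), mean(pairwise))

  expect_equal(rbar(cbind(m[, 1], m[, 1])), 1)
  expect_equal(rbar(cbind(m[, 1], -m[, 1])), -1)

  # pairs with short overlap are excluded with a warning; all-excluded errors
  m2 <- m
  m2[1:50, 2] <- NA
  expect_warning(r2 <- rbar(m2), "excluded")
  expect_equal(r2, mean(pairwise[-c(1, 4, 5)]))
  expect_error(suppressWarnings(rbar(m2[, 1:2])), "no series pair")
})

test_that("EPS and SNR follow the common-signal algebra", {
  expect_equal(snr(0.5, 6), 6)
  expect_equal(snr(0, 6), 0)
  expect_equal(eps(1, 2), 1)
  expect_equal(eps(1, 17), 1)
  expect_error(eps(-0.9, 11), "undefined")  # n*r + (1-r) <= 0
  expect_error(snr(1, 6), "infinite")

  # identity eps = snr/(1+snr) across a parameter sweep
  for (n in c(2, 3, 6, 19, 50)) {
    for (r in seq(0.01, 0.99, by = 0.07)) {
      expect_equal(eps(r, n), snr(r, n) / (1 + snr(r, n)), tolerance = 1e-12)
    }
  }
  # monotone in both arguments
  rs <- seq(0.05, 0.9, 0.05)
  expect_true(all(diff(sapply(rs, eps, n_trees = 6)) > 0))
  expect_true(all(diff(sapply(c(2, 4, 8, 16), function(n) eps(0.3, n))) > 0))
})

test_that("lag-1 autocorrelation behaves on constructed and simulated series", {
  expect_lt(ar1(rep(c(1, -1), 25)), -0.95)
  set.seed(51)
  expect_lt(abs(ar1(stats::rnorm(2000))), 0.05)
  x <- as.numeric(stats::arima.sim(list(ar = 0.6), 2000))
  expect_gt(ar1(x), 0.55)
  expect_lt(ar1(x), 0.65)
  expect_error(ar1(rep(3, 20)), "constant")
})

test_that("sector chronologies are cross-tree means of z-scores", {
  yrs <- 2000:2019
  set.seed(61)
  # 6 trees, 2 sectors, known arrays
  arr <- array(stats::runif(6 * 20 * 2, 5, 25), c(6, 20, 2),
               dimnames = list(paste0("T", 1:6), yrs, c("I", "II")))
  sm <- manual_sector_matrix(arr, trees = paste0("T", 1:6), years = yrs)
  ch <- sector_chronology(sm, "ld")
  zmat <- apply(arr[, , 1], 1, function(tree) as.numeric(scale(tree)))
  expect_equal(ch$index[ch$sector == "I"], rowMeans(zmat), tolerance = 1e-12)

  # two identical trees: chronology equals either tree's z-scores
  arr2 <- array(rep(arr[1, , 1], each = 2), c(2, 20, 1),
                dimnames = list(c("A", "B"), yrs, "I"))
  sm2 <- manual_sector_matrix(arr2, trees = c("A", "B"), years = yrs)
  ch2 <- sector_chronology(sm2, "ld")
  expect_equal(ch2$index, as.numeric(scale(arr[1, , 1])), tolerance = 1e-12)
  expect_equal(ch2$depth, rep(2L, 20))

  # biweight stays close to arithmetic on outlier-free data, and equals it
  # (to 1e-6) on exactly symmetric value sets
  chb <- sector_chronology(sm, "ld", method = "biweight")
  cha <- sector_chronology(sm, "ld", method = "arithmetic")
  expect_gt(stats::cor(chb$index, cha$index), 0.95)
  for (vals in list(c(-2, -1, 0, 1, 2), c(4, 6), c(1, 3, 5) + 0.25)) {
    expect_equal(biweight_mean(vals), mean(vals), tolerance = 1e-6)
  }
})

test_that("opposite-signed trees cancel to a zero chronology", {
  yrs <- 2000:2019
  set.seed(62)
  base <- stats::rnorm(20)
  arr <- array(NA_real_, c(2, 20, 1), dimnames = list(c("A", "B"), yrs, "I"))
  arr[1, , 1] <- base
  arr[2, , 1] <- -base
  sm <- manual_sector_matrix(arr, trees = c("A", "B"), years = yrs)
  ch <- sector_chronology(sm, "ld")
  expect_true(all(abs(ch$index) < 1e-12))
})

test_that("chronology statistics table is internally consistent", {
  p <- qwa_params(years = 1963:2019, seed = 71L, signal_share = 0.5)
  cells <- gen_anatomy(gen_climate(p), p)
  sm <- suppressWarnings(build_sector_matrix(cells))
  st <- chronology_stats(sm, "ld")
  expect_equal(nrow(st), 11L)
  # Mean row is the arithmetic mean of the per-sector entries
  num <- c("mean", "sd", "ar1", "rbar", "eps", "snr")
  expect_equal(unlist(st[11, num]), colMeans(st[1:10, num]), tolerance = 1e-12)
  # rbar close to the generator's analytic common-signal share s = 0.5
  expect_lt(abs(st$rbar[11] - 0.5), 0.1)
  # eps consistent with rbar and n within the table itself
  expect_equal(st$eps[1:10], mapply(eps, st$rbar[1:10], st$n_trees[1:10]),
               tolerance = 1e-12)
})

test_that("two independent-noise trees express little population signal", {
  yrs <- 1963:2019
  set.seed(81)
  arr <- array(stats::rnorm(2 * 57, 15, 2), c(2, 57, 1),
               dimnames = list(c("A", "B"), yrs, "I"))
  sm <- manual_sector_matrix(arr, trees = c("A", "B"), years = yrs)
  st <- chronology_stats(sm, "ld")
  expect_lt(st$eps[1], 0.5)
})

test_that("split-group ANOVA matches the hand-computed oracle", {
  # {1,2,3} vs {4,5,6}: SSB = 13.5, SSW = 4, df = (1,4) -> F = 13.5
  st <- split_group_test(c(1, 2, 3, 4, 5, 6), 1990:1995, split_year = 1993)
  expect_equal(st$F, 13.5)
  expect_equal(st$p, stats::pf(13.5, 1, 4, lower.tail = FALSE))
  expect_equal(unname(st$means), c(2, 5))
  expect_equal(st$n, c(3L, 3L))

  # identical group means: F = 0, p = 1
  st0 <- split_group_test(rep(c(1, 2, 3), 2), 1990:1995, split_year = 1993)
  expect_equal(st0$F, 0)
  expect_equal(st0$p, 1)

  expect_error(split_group_test(1:5, 1990:1994, split_year = 1993),
               "at least 3 years")
})
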