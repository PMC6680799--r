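test_that("autocorrelation is normalized and periodic structure shows at daily lags", {
  t <- 0:4319
  r <- autocorrelate(2 + sin(2 * pi * t / 1440))
  expect_equal(r[1], 1)
  # peaks at 24 h and 48 h lags
  expect_equal(r[1441], 1, tolerance = 1e-9)
  expect_equal(r[2881], 1, tolerance = 1e-9)
  expect_lt(r[721], 0)  # trough at half period
  # white noise: almost all lags within the large-sample band
  set.seed(30)
  n <- 4320
  rw <- autocorrelate(rnorm(n))
  expect_gte(mean(abs(rw[-1]) <= 3 / sqrt(n)), 0.99)
  expect_error(autocorrelate(rep(1, 100)), "zero-variance")
})

test_that("the ACF spectrum spans 3 days to 2 min with harmonics flagged", {
  t <- 0:4319
  sp <- dfc_spectrum(autocorrelate(2 + sin(2 * pi * t / 1440)))
  expect_equal(max(sp$period_min), 3 * 1440)
  expect_equal(min(sp$period_min), 2)
  # single dominant line at the 24-h bin
  expect_equal(sp$period_min[which.max(sp$power)], 1440)
  expect_gt(max(sp$power) / sum(sp$power), 0.999)
  # harmonic flags are exactly the 24/k-hour bins
  expect_true(sp$harmonic[sp$period_min == 1440])
  expect_true(sp$harmonic[sp$period_min == 720])
  # bins around the non-harmonic 10-h period are not flagged
  expect_false(any(sp$harmonic[sp$period_min > 500 & sp$period_min < 650]))
  # two equal sinusoids -> two comparable lines
  sp2 <- dfc_spectrum(autocorrelate(
    sin(2 * pi * t / 1440) + sin(2 * pi * t / 600)))
  top2 <- sort(sp2$power, decreasing = TRUE)[1:2]
  expect_gt(top2[2] / top2[1], 0.5)
})

test_that("DFC anchors: harmonic series give 1, off-harmonics near 0, noise degrades monotonically", {
  t <- 0:4319
  expect_equal(dfc(2 + sin(2 * pi * t / 1440))$dfc, 1, tolerance = 1e-9)
  # any finite sum of 24/k-hour sinusoids is fully coupled
  x <- 3 + sin(2 * pi * t / 1440) + 0.5 * sin(2 * pi * t / 720) +
    0.2 * cos(2 * pi * t / 480)
  expect_equal(dfc(x)$dfc, 1, tolerance = 1e-9)
  # 10-h sinusoid is not a 24-h harmonic
  expect_lte(dfc(2 + sin(2 * pi * t / 600))$dfc, 0.05)
  # scale invariance
  y <- 2 + sin(2 * pi * t / 1440) + 0.1 * sin(2 * pi * t / 600)
  expect_equal(dfc(3 * y)$dfc, dfc(y)$dfc, tolerance = 1e-12)
  # monotone degradation with noise gain
  set.seed(31)
  eps <- rnorm(4320)
  dfcs <- vapply(c(0, 0.3, 0.8, 1.5), function(g) {
    dfc(2 + sin(2 * pi * t / 1440) + g * eps)$dfc
  }, numeric(1))
  expect_true(all(diff(dfcs) < 0))
  expect_true(all(dfcs >= 0 & dfcs <= 1))
})

test_that("DFC from the ACF equals the direct periodogram ratio (Wiener-Khinchin)", {
  set.seed(32)
  t <- 0:4319
  x <- 2 + sin(2 * pi * t / 1440) + 0.5 * rnorm(4320)
  # independent oracle: harmonic share of the raw periodogram
  xc <- x - mean(x)
  P <- (Mod(fft(xc))^2)[2:2161]
  harm <- seq_len(2160) %% 3 == 0
  oracle <- sum(P[harm]) / sum(P)
  expect_equal(dfc(x)$dfc, oracle, tolerance = 1e-10)
})

test_that("DFC window contracts: length, gaps, degenerate input", {
  t <- 0:4319
  x <- 2 + sin(2 * pi * t / 1440)
  expect_error(dfc(x[1:4000]), "4320")
  # small gaps interpolated
  xg <- x
  xg[sample(4320, 100)] <- NA
  expect_equal(dfc(xg)$dfc, 1, tolerance = 0.01)
  xg2 <- x
  xg2[1:400] <- NA
  expect_error(dfc(xg2), "missing")
  expect_error(dfc(rep(2, 4320)), "zero-variance")
})

test_that("moving windows step by one day and land on the window's last day", {
  tz <- "Etc/GMT-2"
  t0 <- as.POSIXct("2016-08-10 00:00:00", tz = tz)
  mk_series <- function(days) {
    tt <- 0:(days * 1440 - 1)
    tibble::tibble(individual_id = "H01", timestamp = t0 + tt * 60,
                   asd = 2 + sin(2 * pi * tt / 1440) + 0.05 * rnorm(length(tt)))
  }
  set.seed(33)
  d19 <- moving_dfc(mk_series(19))
  expect_lte(nrow(d19), 17)
  expect_equal(d19$date[1], as.Date("2016-08-12"))
  expect_true(all(diff(d19$date) == 1))
  d3 <- moving_dfc(mk_series(3))
  expect_equal(nrow(d3), 1)
  expect_true(all(d19$dfc >= 0 & d19$dfc <= 1, na.rm = TRUE))
  expect_warning(moving_dfc(mk_series(2)), "fewer than 3 days")
})

test_that("festival circadian disruption lowers the DFC", {
  cfg <- study_config(n_individuals = 2, pre_days = 6, festival_days = 6,
                      post_days = 0, dfc_noise_gain = 0.6)
  st <- simulate_study(cfg, seed = 34)
  d <- moving_dfc(st$burst_summary)
  cal <- phase_calendar(cfg)
  d <- dplyr::left_join(d, cal, by = "date")
  # compare windows fully inside each phase (skip the mixed-phase windows)
  pre <- d$dfc[d$date <= cfg$start_date + 5]
  fest <- d$dfc[d$date >= cfg$start_date + 8]
  expect_lt(mean(fest, na.rm = TRUE), mean(pre, na.rm = TRUE))
})
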