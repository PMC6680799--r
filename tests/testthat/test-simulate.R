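test_that("study dimensions follow the configuration", {
  cfg <- study_config(n_individuals = 1, pre_days = 1, festival_days = 1,
                      post_days = 0, burst_dropout_rate = 0)
  st <- simulate_study(cfg, seed = 1)
  expect_equal(nrow(st$burst_summary), 2 * 1440)
  expect_true(all(st$burst_summary$label_true %in%
                    c("immobile", "balling", "locomotion", "other")))
  # complete day: 1440 bursts between 00:00 and 23:59
  per_day <- table(as.Date(st$burst_summary$timestamp, tz = "Etc/GMT-2"))
  expect_true(all(per_day == 1440))
  # twilight covers every study date
  expect_true(all(phase_calendar(cfg)$date %in% st$twilight$date))
  # GPS fixes fall in the 19:00-07:00 window only
  hr <- as.numeric(format(st$gps$timestamp, "%H"))
  expect_true(all(hr >= 19 | hr < 7))
})

test_that("identical config and seed give byte-identical CSV output", {
  cfg <- study_config(n_individuals = 1, pre_days = 2, festival_days = 1,
                      post_days = 1)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_study(cfg, seed = 5, out_dir = d1)
  simulate_study(cfg, seed = 5, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("invalid configurations error naming the offending field", {
  expect_error(study_config(n_individuals = 0), "n_individuals")
  expect_error(study_config(area_scale = 0), "area_scale")
  expect_error(study_config(area_scale = 1.2), "area_scale")
  expect_error(study_config(burst_dropout_rate = 1), "burst_dropout_rate")
  expect_error(study_config(dfc_noise_gain = 2), "dfc_noise_gain")
})

test_that("burst waveforms carry the behavior signatures", {
  set.seed(3)
  # noise-free immobile burst equals the posture vector at every sample
  b <- synthesize_burst("immobile", posture = c(0, 0, 1), n = 100,
                        noise_sd = 0)
  expect_equal(unname(b), matrix(rep(c(0, 0, 1), each = 100), ncol = 3))
  # locomotion with amplitude A and no noise: per-axis peak-to-peak ~ 2A
  b <- synthesize_burst("locomotion", n = 250, hz = 100, dyn_amp = 0.4,
                        dyn_freq = 2, noise_sd = 0)
  ptp <- apply(b, 2, function(v) diff(range(v)))
  expect_equal(unname(ptp), rep(0.8, 3), tolerance = 0.02)
  # balling rests on a distinctly rotated static vector
  bb <- synthesize_burst("balling", n = 100, noise_sd = 0)
  expect_gt(sum(abs(colMeans(bb) - c(0, 0, 1))), 0.5)
  expect_error(synthesize_burst("flying"), "unknown behavior")
})

test_that("generated behavior classes separate in feature space", {
  lf <- labeled_features()
  X <- scale(as.matrix(lf[, predictor_names()]))
  expect_gt(silhouette_mean(X, lf$label), 0)
})

test_that("generated locomotion is nocturnal", {
  st <- small_study()
  loco <- st$burst_summary[st$burst_summary$label_true == "locomotion", ]
  dusk_of <- stats::setNames(st$twilight$civil_dusk,
                             as.character(st$twilight$date))
  dawn_of <- stats::setNames(st$twilight$civil_dawn,
                             as.character(st$twilight$date))
  d <- as.Date(loco$timestamp, tz = "Etc/GMT-2")
  night <- loco$timestamp >= dusk_of[as.character(d)] |
    loco$timestamp < dawn_of[as.character(d)]
  expect_gte(mean(night), 0.9)
})

test_that("festival onset delay is monotone in the configured effect", {
  shift <- function(delay) {
    cfg <- study_config(n_individuals = 2, pre_days = 4, festival_days = 4,
                        post_days = 0, onset_delay_min = delay,
                        het_delay_sd_min = 0, dfc_noise_gain = 0)
    st <- simulate_study(cfg, seed = 8)
    on <- st$truth$onsets
    mean(on$tsdusk_true_min[on$phase == "festival"], na.rm = TRUE) -
      mean(on$tsdusk_true_min[on$phase == "pre"], na.rm = TRUE)
  }
  s <- vapply(c(0, 30, 60), shift, numeric(1))
  expect_true(all(diff(s) > 0))
  expect_equal(s[3], 60, tolerance = 15)
})

test_that("GPS artifact injection flags what it corrupts", {
  st <- small_study()
  fx <- st$gps[st$gps$individual_id == "H01", ][1:100, ]
  fx$artifact <- NULL
  # rate zero leaves coordinates untouched
  out0 <- inject_gps_artifacts(fx, 0)
  expect_equal(out0$x_m, fx$x_m)
  expect_equal(out0$y_m, fx$y_m)
  # rate 0.1 on 100 fixes corrupts ~10, all flagged
  set.seed(11)
  out <- inject_gps_artifacts(fx, 0.1)
  moved <- out$x_m != fx$x_m | out$y_m != fx$y_m
  expect_true(all(out$artifact[moved] != "none"))
  n_flag <- sum(out$artifact != "none")
  expect_gte(n_flag, 5)
  expect_lte(n_flag, 25)
})

test_that("cleaning removes nearly all injected GPS artifacts", {
  st <- small_study()
  flagged <- st$truth$gps_artifacts[st$truth$gps_artifacts$artifact != "none", ]
  expect_gt(nrow(flagged), 0)
  ev <- clean_fixes(st$gps, site_center = c(0, 0))
  # a flagged artifact survives if a cleaned event remains within the
  # event interval of its timestamp and near its corrupted position
  gps_flag <- dplyr::left_join(
    flagged, st$gps[, c("individual_id", "timestamp", "x_m", "y_m")],
    by = c("individual_id", "timestamp"))
  survived <- vapply(seq_len(nrow(gps_flag)), function(i) {
    near <- ev$individual_id == gps_flag$individual_id[i] &
      abs(as.numeric(ev$timestamp) - as.numeric(gps_flag$timestamp[i])) < 300 &
      sqrt((ev$x_m - gps_flag$x_m[i])^2 + (ev$y_m - gps_flag$y_m[i])^2) < 100
    any(near)
  }, logical(1))
  expect_gte(mean(!survived), 0.95)
})
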