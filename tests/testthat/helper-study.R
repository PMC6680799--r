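# fixtures are generated in code and cached per test run
.fixture_cache <- new.env(parent = emptyenv())

# a small but complete study: 2 animals, 3 + 3 days (+2 nest-only days)
small_study <- function() {
  if (is.null(.fixture_cache$small)) {
    cfg <- study_config(n_individuals = 2, pre_days = 3, festival_days = 3,
                        post_days = 2)
    .fixture_cache$small <- simulate_study(cfg, seed = 42)
  }
  .fixture_cache$small
}

# balanced labeled calibration features for classifier tests
labeled_features <- function() {
  if (is.null(.fixture_cache$labfeat)) {
    lab <- simulate_labeled_bursts(n_per_class = 30, n = 250, hz = 100,
                                   seed = 99)
    fe <- featurize(lab$bursts, expected_n = 250, hz = 100)
    .fixture_cache$labfeat <- dplyr::left_join(lab$labels, fe, by = "burst_id")
  }
  .fixture_cache$labfeat
}

# long-format burst table from a list of sample matrices
as_burst_table <- function(mats, t0 = as.POSIXct("2016-08-10 12:00:00",
                                                 tz = "Etc/GMT-2")) {
  dplyr::bind_rows(lapply(seq_along(mats), function(i) {
    m <- mats[[i]]
    tibble::tibble(
      individual_id = "T01",
      burst_id = sprintf("t%03d", i),
      timestamp = t0 + (i - 1) * 60,
      sample_idx = seq_len(nrow(m)),
      ax_g = m[, 1], ay_g = m[, 2], az_g = m[, 3]
    )
  }))
}

# mean silhouette width, computed from first principles
silhouette_mean <- function(X, groups) {
  D <- as.matrix(stats::dist(X))
  s <- vapply(seq_len(nrow(X)), function(i) {
    own <- groups == groups[i]
    a <- mean(D[i, own & seq_len(nrow(X)) != i])
    b <- min(vapply(unique(groups[!own]), function(g) {
      mean(D[i, groups == g])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# one synthetic dawn-to-dawn activity day at 1-min resolution
synthetic_day <- function(active_from_min = NULL, active_to_min = NULL,
                          dawn_min = 270, dusk_min = 1290, level = 1,
                          base = 0) {
  # minutes indexed from civil dawn (minute 0) to next dawn (minute 1439)
  tz <- "Etc/GMT-2"
  d0 <- as.POSIXct("2016-08-15 00:00:00", tz = tz)
  dawn <- d0 + dawn_min * 60
  dusk <- d0 + dusk_min * 60
  ts <- dawn + (0:1439) * 60
  asd <- rep(base, 1440)
  if (!is.null(active_from_min)) {
    asd[(active_from_min:active_to_min) + 1] <- level
  }
  list(timestamps = ts, asd = asd, dawn = dawn, dusk = dusk,
       is_day = ts < dusk)
}
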