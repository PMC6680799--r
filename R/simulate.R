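# per-behavior calibration of the burst-level activity proxies (aSD, ODBA).
# Values are free parameters of the generator (the field protocol publishes
# no per-behavior signal amplitudes); chosen so that locomotion sits an
# order of magnitude above rest and "other" in between, with the deployment
# mean aSD falling cleanly between rest and active levels.
.asd_pars <- list(
  mean = c(immobile = 0.06, balling = 0.10, locomotion = 1.00, other = 0.45),
  sd   = c(immobile = 0.02, balling = 0.03, locomotion = 0.25, other = 0.15)
)
.odba_pars <- list(
  mean = c(immobile = 0.05, balling = 0.08, locomotion = 0.75, other = 0.35),
  sd   = c(immobile = 0.02, balling = 0.03, locomotion = 0.20, other = 0.12)
)

# bout-structured label sequence: geometric dwell times (>= 1 min) with
# label marginals `probs`; gives autocorrelated, budget-realistic behavior
.bout_labels <- function(n, probs, mean_dwell) {
  if (n <= 0) return(character(0))
  out <- character(0)
  while (length(out) < n) {
    k <- max(8L, ceiling(2 * n / mean_dwell))
    lens <- 1L + stats::rgeom(k, 1 / mean_dwell)
    labs <- sample(names(probs), k, replace = TRUE, prob = probs)
    out <- c(out, rep(labs, lens))
  }
  out[seq_len(n)]
}

# rotation of a posture vector about the x axis, used for the balled-up
# static signature
.rotate_x <- function(v, deg) {
  a <- deg * pi / 180
  c(v[1], cos(a) * v[2] - sin(a) * v[3], sin(a) * v[2] + cos(a) * v[3])
}

#' Synthesize one accelerometer burst
#'
#' Generates a triaxial burst (in g) carrying the waveform signature of a
#' behavior class: `immobile` is the gravity posture plus small Gaussian
#' noise; `balling` is a distinctly rotated gravity vector plus noise;
#' `locomotion` adds a periodic 1-3 Hz dynamic component of per-axis
#' amplitude `dyn_amp`; `other` adds an irregular broadband (AR-filtered
#' noise) component.
#'
#' @param behavior one of `"immobile"`, `"balling"`, `"locomotion"`, `"other"`.
#' @param posture unit gravity vector (length 3, in g) of the carried logger.
#' @param n samples per axis.
#' @param hz sampling frequency (Hz).
#' @param dyn_amp per-axis sinusoid amplitude (g) for locomotion; recycled
#'   to length 3.
#' @param dyn_freq locomotion stride frequency in Hz; drawn uniformly from
#'   1-3 Hz when `NULL`.
#' @param noise_sd sensor noise SD (g); behavior-specific default when `NULL`.
#' @return an `n` x 3 matrix with columns `ax_g`, `ay_g`, `az_g`.
#' @examples
#' b <- synthesize_burst("locomotion", n = 250, hz = 100)
#' dim(b)
#' @export
synthesize_burst <- function(behavior,
                             posture = c(0, 0, 1),
                             n = 250,
                             hz = 100,
                             dyn_amp = c(0.6, 0.4, 0.3),
                             dyn_freq = NULL,
                             noise_sd = NULL) {
  if (!behavior %in% .hog_labels) {
    stop(sprintf("unknown behavior label: '%s'", behavior), call. = FALSE)
  }
  if (abs(sqrt(sum(posture^2)) - 1) > 0.2) {
    warning("posture vector is far from unit length (1 g)")
  }
  if (is.null(noise_sd)) {
    noise_sd <- c(immobile = 0.02, balling = 0.03,
                  locomotion = 0.05, other = 0.05)[[behavior]]
  }
  dyn_amp <- rep_len(dyn_amp, 3)
  static <- switch(behavior,
    balling = .rotate_x(posture, 70),
    posture
  )
  tt <- (seq_len(n) - 1) / hz
  base <- matrix(rep(static, each = n), ncol = 3)
  dyn <- switch(behavior,
    locomotion = {
      f <- if (is.null(dyn_freq)) runif(1, 1, 3) else dyn_freq
      phi <- runif(3, 0, 2 * pi)
      sapply(1:3, function(j) dyn_amp[j] * sin(2 * pi * f * tt + phi[j]))
    },
    other = {
      sapply(1:3, function(j) {
        as.numeric(stats::filter(rnorm(n, 0, 0.3), 0.55, method = "recursive"))
      })
    },
    matrix(0, n, 3)
  )
  noise <- if (noise_sd > 0) matrix(rnorm(3 * n, 0, noise_sd), n, 3) else 0
  out <- base + dyn + noise
  colnames(out) <- c("ax_g", "ay_g", "az_g")
  out
}

#' Generate a labeled burst set for classifier training
#'
#' Emulates a preliminary calibration study in which bursts of known
#' behavior are collected: balanced classes, randomized logger postures
#' (small tilts for upright behaviors, large rotations for balling).
#'
#' @param n_per_class bursts per class.
#' @param classes behavior labels to include.
#' @param n,hz samples per axis and sampling frequency.
#' @param seed optional RNG seed.
#' @return a list with `bursts` (long tibble: `burst_id`, `sample_idx`,
#'   `ax_g`, `ay_g`, `az_g`) and `labels` (tibble: `burst_id`, `label`).
#' @examples
#' lab <- simulate_labeled_bursts(n_per_class = 3, n = 50)
#' nrow(lab$labels)
#' @export
simulate_labeled_bursts <- function(n_per_class = 197,
                                    classes = .hog_model_classes,
                                    n = 250, hz = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  labels <- list()
  k <- 0L
  for (cl in classes) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      tilt <- rnorm(2, 0, 6)
      p <- .rotate_x(c(0, 0, 1), tilt[1])
      p <- c(cos(tilt[2] * pi / 180) * p[1] - sin(tilt[2] * pi / 180) * p[3],
             p[2],
             sin(tilt[2] * pi / 180) * p[1] + cos(tilt[2] * pi / 180) * p[3])
      m <- synthesize_burst(cl, posture = p, n = n, hz = hz)
      id <- sprintf("cal_%04d", k)
      rows[[k]] <- tibble::tibble(
        burst_id = id, sample_idx = seq_len(n),
        ax_g = m[, 1], ay_g = m[, 2], az_g = m[, 3]
      )
      labels[[k]] <- tibble::tibble(burst_id = id, label = cl)
    }
  }
  list(bursts = dplyr::bind_rows(rows), labels = dplyr::bind_rows(labels))
}

#' Inject GPS artifacts into a fix table
#'
#' Corrupts a fraction of 5-min GPS events to emulate the two failure modes
#' the cleaning stage removes: events displaced far (> 1000 m) from the
#' site, and events whose displacement from the neighboring event implies a
#' speed above 2 m/s. All fixes of a corrupted event are flagged in the
#' returned `artifact` column (`"far"`, `"jump"`, else `"none"`).
#'
#' @param fixes tibble with `individual_id`, `timestamp`, `x_m`, `y_m`.
#' @param rate fraction of events corrupted, in `[0, 1)`.
#' @param site_center planar site coordinates (m).
#' @param event_interval_min GPS event spacing (minutes).
#' @return `fixes` with modified coordinates and an `artifact` column.
#' @export
inject_gps_artifacts <- function(fixes, rate, site_center = c(0, 0),
                                 event_interval_min = 5) {
  stopifnot(rate >= 0, rate < 1)
  if (!"artifact" %in% names(fixes)) fixes$artifact <- "none"
  if (rate == 0 || nrow(fixes) == 0) return(fixes)
  ev <- paste(fixes$individual_id,
              floor(as.numeric(fixes$timestamp) / (event_interval_min * 60)))
  events <- unique(ev)
  hit <- events[runif(length(events)) < rate]
  for (e in hit) {
    idx <- which(ev == e)
    kind <- sample(c("far", "jump"), 1)
    ang <- runif(1, 0, 2 * pi)
    if (kind == "far") {
      d <- runif(1, 1100, 1800)
      fixes$x_m[idx] <- site_center[1] + d * cos(ang)
      fixes$y_m[idx] <- site_center[2] + d * sin(ang)
    } else {
      # > 2 m/s over one event interval requires > 600 m at 5-min spacing;
      # overshoot so the jump stays super-threshold despite track scatter
      d <- runif(1, 1.4, 1.8) * 2 * event_interval_min * 60
      fixes$x_m[idx] <- fixes$x_m[idx] + d * cos(ang)
      fixes$y_m[idx] <- fixes$y_m[idx] + d * sin(ang)
    }
    fixes$artifact[idx] <- kind
  }
  fixes
}

#' Simulate a complete bio-logging study with known ground truth
#'
#' Generates every input stream of the analysis pipeline for a baseline
#' ("pre") phase and a disturbance ("festival") phase: a per-minute burst
#' table (raw triaxial waveforms optional), nightly GPS fixes in 5-min
#' events, daily nest checks (continuing `post_days` past the festival), a
#' civil-twilight table, and a ground-truth record of every injected
#' quantity (true behavior labels, realized nightly activity onsets, true
#' nightly space-use scatter and core areas, GPS artifact flags).
#'
#' The nocturnal activity schedule is a bout-structured (time-inhomogeneous
#' Markov) label sequence: rest with occasional balling bouts by day,
#' locomotion-dominated activity between a nightly onset (civil dusk plus an
#' individual offset) and shortly before civil dawn. Disturbance effects on
#' festival dates: activity onset delayed by `onset_delay_min` (with
#' individual heterogeneity), nightly GPS scatter scaled so that core areas
#' shrink by `area_scale`, circadian coupling degraded by `dfc_noise_gain`
#' (inflated onset jitter plus within-window scrambling), and an elevated
#' male nest-change hazard.
#'
#' @param cfg a [study_config()].
#' @param seed RNG seed; defaults to `cfg$seed`. Identical `(cfg, seed)`
#'   give identical output.
#' @param raw if `TRUE`, also synthesize raw waveforms for every burst
#'   (feasible for scaled-down configs; a full-size study is ~115 million
#'   samples and should be streamed via `out_dir` instead of held in memory).
#' @param out_dir optional directory; when given, all tables are written as
#'   CSV (ISO-8601 timestamps) and the paths returned in the result.
#' @return a list of class `hog_study` with elements `burst_summary`,
#'   `bursts` (NULL unless `raw`), `gps`, `nests`, `twilight`, `calendar`,
#'   `truth` (list: `individuals`, `onsets`, `nights`, `gps_artifacts`),
#'   and `config`.
#' @examples
#' st <- simulate_study(study_config(n_individuals = 1, pre_days = 2,
#'                                   festival_days = 0, post_days = 0))
#' nrow(st$burst_summary)  # 2 days x 1440 bursts
#' @export
simulate_study <- function(cfg = study_config(), seed = cfg$seed,
                           raw = FALSE, out_dir = NULL) {
  validate_study_config(cfg)
  if (!is.null(seed)) set.seed(seed)
  if (1440 %% cfg$bursts_per_day != 0) {
    stop("invalid configuration: `bursts_per_day` must divide 1440", call. = FALSE)
  }
  interval_min <- 1440 / cfg$bursts_per_day
  tz <- cfg$tz
  cal <- phase_calendar(cfg)
  acc_cal <- cal[cal$phase %in% c("pre", "festival"), ]
  n_days <- nrow(acc_cal)
  twl <- twilight_table(c(cal$date, max(cal$date) + 1), tz = tz)

  sexes <- rep(c("f", "m"), length.out = cfg$n_individuals)
  ids <- sprintf("H%02d", seq_len(cfg$n_individuals))
  indiv <- tibble::tibble(
    individual_id = ids,
    sex = sexes,
    onset_base_min = rnorm(cfg$n_individuals, 15, cfg$het_onset_sd_min),
    onset_delay_min = cfg$onset_delay_min +
      rnorm(cfg$n_individuals, 0, cfg$het_delay_sd_min),
    home_x = runif(cfg$n_individuals, -250, 250),
    home_y = runif(cfg$n_individuals, -250, 250),
    sigma_mult = exp(rnorm(cfg$n_individuals, 0, 0.15))
  )

  rest_probs <- c(immobile = 0.8, balling = 0.2)
  active_probs <- c(locomotion = 0.7, other = 0.15, immobile = 0.15)
  g <- cfg$dfc_noise_gain
  jitter_sd_fest <- cfg$onset_jitter_sd_min + 45 * g
  p_scramble <- 0.5 * g

  summary_rows <- list()
  onset_rows <- list()
  gps_rows <- list()
  night_rows <- list()
  origin <- as.POSIXct(paste(cfg$start_date, "00:00:00"), tz = tz)
  n_min <- n_days * cfg$bursts_per_day
  dawn_of <- stats::setNames(twl$civil_dawn, as.character(twl$date))
  dusk_of <- stats::setNames(twl$civil_dusk, as.character(twl$date))

  for (r in seq_len(cfg$n_individuals)) {
    id <- ids[r]
    ts <- origin + (seq_len(n_min) - 1) * interval_min * 60
    lab <- .bout_labels(n_min, rest_probs, 25 / interval_min)

    for (d in seq_len(n_days)) {
      date_d <- acc_cal$date[d]
      fest <- acc_cal$phase[d] == "festival"
      dusk <- dusk_of[[as.character(date_d)]]
      dawn_next <- dawn_of[[as.character(date_d + 1)]]
      jit_sd <- if (fest) jitter_sd_fest else cfg$onset_jitter_sd_min
      offset <- indiv$onset_base_min[r] +
        (if (fest) indiv$onset_delay_min[r] else 0) + rnorm(1, 0, jit_sd)
      onset_t <- dusk + offset * 60
      end_t <- dawn_next - max(5, rnorm(1, 20, 8)) * 60
      if (onset_t > end_t - 30 * 60) onset_t <- end_t - 30 * 60
      i1 <- which(ts >= onset_t)[1]
      i2 <- max(which(ts <= end_t))
      realized_onset <- as.POSIXct(NA_character_, tz = tz)
      if (!is.na(i1) && i1 <= i2 && i2 <= n_min) {
        len <- i2 - i1 + 1
        night_lab <- .bout_labels(len, active_probs, 4 / interval_min)
        if (fest && p_scramble > 0) {
          flip <- runif(len) < p_scramble
          if (any(flip)) {
            night_lab[flip] <- sample(c("immobile", "balling", "other"),
                                      sum(flip), replace = TRUE,
                                      prob = c(0.6, 0.2, 0.2))
          }
        }
        lab[i1:i2] <- night_lab
        act <- which(night_lab %in% c("locomotion", "other"))
        if (length(act) > 0) realized_onset <- ts[i1 + act[1] - 1]
      }
      onset_rows[[length(onset_rows) + 1]] <- tibble::tibble(
        individual_id = id, date = date_d, phase = acc_cal$phase[d],
        onset_true = realized_onset, civil_dusk = dusk,
        tsdusk_true_min = as.numeric(difftime(realized_onset, dusk, units = "mins"))
      )

      # GPS for the night of date_d
      sigma <- cfg$gps_sigma_m * indiv$sigma_mult[r] *
        (if (fest) sqrt(cfg$area_scale) else 1)
      cx <- indiv$home_x[r] + rnorm(1, 0, 20)
      cy <- indiv$home_y[r] + rnorm(1, 0, 20)
      night_hours <- (24 - cfg$night_start_hour) + cfg$night_end_hour
      n_ev <- floor(night_hours * 60 / cfg$gps_interval_min)
      ev_t <- as.POSIXct(paste(date_d, sprintf("%02d:00:00", cfg$night_start_hour)),
                         tz = tz) + (seq_len(n_ev) - 1) * cfg$gps_interval_min * 60
      ex <- cx + rnorm(n_ev, 0, sigma)
      ey <- cy + rnorm(n_ev, 0, sigma)
      B <- cfg$gps_burst_size
      gps_rows[[length(gps_rows) + 1]] <- tibble::tibble(
        individual_id = id,
        timestamp = rep(ev_t, each = B) + rep(seq_len(B) - 1, n_ev) * 1.1,
        x_m = rep(ex, each = B) + rnorm(n_ev * B, 0, cfg$gps_noise_sd_m),
        y_m = rep(ey, each = B) + rnorm(n_ev * B, 0, cfg$gps_noise_sd_m)
      )
      night_rows[[length(night_rows) + 1]] <- tibble::tibble(
        individual_id = id, night = date_d, phase = acc_cal$phase[d],
        sigma_m = sigma, center_x = cx, center_y = cy,
        core_area_ha_true = 2 * pi * log(2) * sigma^2 / 1e4
      )
    }

    keep <- if (cfg$burst_dropout_rate > 0) {
      runif(n_min) >= cfg$burst_dropout_rate
    } else rep(TRUE, n_min)
    summary_rows[[r]] <- tibble::tibble(
      individual_id = id,
      burst_id = sprintf("%s_b%06d", id, seq_len(n_min)),
      timestamp = ts,
      label_true = lab,
      asd = pmax(0.005, rnorm(n_min, .asd_pars$mean[lab], .asd_pars$sd[lab])),
      odba = pmax(0.001, rnorm(n_min, .odba_pars$mean[lab], .odba_pars$sd[lab]))
    )[keep, ]
  }

  burst_summary <- dplyr::bind_rows(summary_rows)
  gps <- dplyr::bind_rows(gps_rows)
  gps <- inject_gps_artifacts(gps, cfg$gps_artifact_rate, cfg$site_center,
                              cfg$gps_interval_min)

  # daily nest checks over pre + festival + post days
  q0 <- cfg$nest_change_prob
  nest_rows <- list()
  for (r in seq_len(cfg$n_individuals)) {
    q <- if (sexes[r] == "m") q0[["male"]] else q0[["female"]]
    qs <- ifelse(cal$phase == "festival" & sexes[r] == "m",
                 1 - (1 - q)^cfg$male_nest_hazard_mult, q)
    changed <- c(FALSE, runif(nrow(cal) - 1) < qs[-nrow(cal)])
    nest_idx <- 1L + cumsum(changed)
    nest_rows[[r]] <- tibble::tibble(
      individual_id = ids[r], sex = sexes[r], date = cal$date,
      nest_id = sprintf("%s-N%03d", ids[r], nest_idx)
    )
  }
  nests <- dplyr::bind_rows(nest_rows)

  bursts <- NULL
  if (raw) {
    n_samp <- round(cfg$burst_len_s * cfg$burst_hz)
    mats <- vector("list", nrow(burst_summary))
    for (i in seq_len(nrow(burst_summary))) {
      tilt <- rnorm(1, 0, 5)
      m <- synthesize_burst(burst_summary$label_true[i],
                            posture = .rotate_x(c(0, 0, 1), tilt),
                            n = n_samp, hz = cfg$burst_hz)
      mats[[i]] <- tibble::tibble(
        individual_id = burst_summary$individual_id[i],
        burst_id = burst_summary$burst_id[i],
        timestamp = burst_summary$timestamp[i],
        sample_idx = seq_len(n_samp),
        ax_g = m[, 1], ay_g = m[, 2], az_g = m[, 3]
      )
    }
    bursts <- dplyr::bind_rows(mats)
  }

  truth <- list(
    individuals = indiv,
    onsets = dplyr::bind_rows(onset_rows),
    nights = dplyr::bind_rows(night_rows),
    gps_artifacts = gps[, c("individual_id", "timestamp", "artifact")]
  )
  st <- list(
    burst_summary = burst_summary, bursts = bursts, gps = gps,
    nests = nests, twilight = twl, calendar = cal, truth = truth,
    config = cfg
  )
  class(st) <- "hog_study"
  if (!is.null(out_dir)) st$paths <- write_study_csv(st, out_dir)
  st
}

# ISO-8601 with explicit offset, the package's single timestamp format
.iso8601 <- function(t) format(t, "%Y-%m-%dT%H:%M:%S%z")

#' Write a simulated study to CSV files
#'
#' @param st a `hog_study` from [simulate_study()].
#' @param out_dir output directory (created if missing).
#' @return named character vector of file paths, invisibly.
#' @export
write_study_csv <- function(st, out_dir) {
  stopifnot(inherits(st, "hog_study"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  wr <- function(df, f) {
    df <- as.data.frame(df)
    for (cn in names(df)) {
      if (inherits(df[[cn]], "POSIXct")) df[[cn]] <- .iso8601(df[[cn]])
    }
    utils::write.csv(df, p(f), row.names = FALSE)
    p(f)
  }
  paths <- c(
    burst_summary = wr(st$burst_summary, "burst_summary.csv"),
    gps = wr(st$gps, "gps.csv"),
    nests = wr(st$nests, "nests.csv"),
    twilight = wr(st$twilight, "twilight.csv"),
    truth_onsets = wr(st$truth$onsets, "truth_onsets.csv"),
    truth_nights = wr(st$truth$nights, "truth_nights.csv")
  )
  if (!is.null(st$bursts)) {
    paths["bursts"] <- wr(st$bursts, "bursts.csv")
  }
  invisible(paths)
}
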