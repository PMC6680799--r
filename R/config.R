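#' Study configuration for the synthetic generator
#'
#' Builds the configuration object that fully determines a simulated
#' deployment: eight logged animals (sexes balanced) observed over a 19-day
#' baseline phase and a 19-day disturbance ("festival") phase, with
#' accelerometer bursts once per minute (100 Hz, 2.5 s), GPS fixes in 5-min
#' events of five points between 19:00 and 07:00, and daily nest checks that
#' continue 5 days past the festival. Defaults mirror the field protocol the
#' package models; scaled-down configurations (fewer animals/days, shorter
#' bursts) are first-class and are what the test-suite uses.
#'
#' The `effect` block controls the injected disturbance:
#' \describe{
#'   \item{onset_delay_min}{mean delay (minutes) of nightly activity onset
#'     during the festival phase.}
#'   \item{area_scale}{multiplier in (0, 1] on nightly space-use *area*
#'     during the festival (positions are scaled by its square root).}
#'   \item{dfc_noise_gain}{gain in [0, 1] of circadian disruption: inflates
#'     nightly onset jitter and scrambles minutes inside the active window,
#'     monotonically degrading the 24-h coupling (DFC).}
#'   \item{male_nest_hazard_mult}{discrete-hazard multiplier on the daily
#'     nest-change probability of males during the festival. The default
#'     1.44 reproduces a drop in next-day re-use probability from about 58%
#'     to about 46%.}
#' }
#'
#' @param n_individuals number of logged animals (sexes alternate f/m).
#' @param pre_days,festival_days days in the baseline and disturbance phases.
#' @param post_days extra post-festival days on which only nest checks run.
#' @param start_date first study date (ISO string or Date).
#' @param burst_hz accelerometer sampling frequency per axis (Hz).
#' @param burst_len_s burst duration in seconds (2.5 or 2.64 in the field).
#' @param bursts_per_day bursts recorded per complete day (one per minute).
#' @param gps_interval_min minutes between GPS events.
#' @param gps_burst_size fixes per GPS event.
#' @param gps_noise_sd_m per-fix GPS error SD (m).
#' @param gps_sigma_m SD (m) of the nightly space-use scatter at baseline.
#' @param gps_artifact_rate fraction of GPS events turned into artifacts.
#' @param site_center numeric length-2, planar site coordinates (m).
#' @param night_start_hour,night_end_hour GPS duty-cycle window (local hours).
#' @param onset_delay_min,area_scale,dfc_noise_gain,male_nest_hazard_mult
#'   disturbance effects, see Details.
#' @param nest_change_prob named numeric, baseline daily probability that an
#'   animal occupies a different nest the next day, per sex.
#' @param het_onset_sd_min SD (min) of between-individual baseline onset
#'   offsets after civil dusk.
#' @param het_delay_sd_min SD (min) of between-individual variation in the
#'   festival onset delay.
#' @param onset_jitter_sd_min SD (min) of night-to-night onset jitter.
#' @param burst_dropout_rate fraction of scheduled bursts that go missing.
#' @param seed default RNG seed used by [simulate_study()].
#' @param tz study-local timezone (fixed offset; no DST inside the window).
#'
#' @return an object of class `study_config` (a named list).
#' @seealso [simulate_study()], [phase_calendar()]
#' @examples
#' cfg <- study_config(n_individuals = 2, pre_days = 3, festival_days = 3)
#' cfg$n_individuals
#' @export
study_config <- function(n_individuals = 8,
                         pre_days = 19,
                         festival_days = 19,
                         post_days = 5,
                         start_date = "2016-08-10",
                         burst_hz = 100,
                         burst_len_s = 2.5,
                         bursts_per_day = 1440,
                         gps_interval_min = 5,
                         gps_burst_size = 5,
                         gps_noise_sd_m = 15,
                         gps_sigma_m = 50,
                         gps_artifact_rate = 0.02,
                         site_center = c(0, 0),
                         night_start_hour = 19,
                         night_end_hour = 7,
                         onset_delay_min = 45,
                         area_scale = 0.5,
                         dfc_noise_gain = 0.25,
                         male_nest_hazard_mult = 1.44,
                         nest_change_prob = c(female = 0.34, male = 0.42),
                         het_onset_sd_min = 8,
                         het_delay_sd_min = 5,
                         onset_jitter_sd_min = 3,
                         burst_dropout_rate = 0,
                         seed = 1L,
                         tz = .hog_tz) {
  cfg <- list(
    n_individuals = n_individuals, pre_days = pre_days,
    festival_days = festival_days, post_days = post_days,
    start_date = as.Date(start_date), burst_hz = burst_hz,
    burst_len_s = burst_len_s, bursts_per_day = bursts_per_day,
    gps_interval_min = gps_interval_min, gps_burst_size = gps_burst_size,
    gps_noise_sd_m = gps_noise_sd_m, gps_sigma_m = gps_sigma_m,
    gps_artifact_rate = gps_artifact_rate, site_center = site_center,
    night_start_hour = night_start_hour, night_end_hour = night_end_hour,
    onset_delay_min = onset_delay_min, area_scale = area_scale,
    dfc_noise_gain = dfc_noise_gain,
    male_nest_hazard_mult = male_nest_hazard_mult,
    nest_change_prob = nest_change_prob,
    het_onset_sd_min = het_onset_sd_min,
    het_delay_sd_min = het_delay_sd_min,
    onset_jitter_sd_min = onset_jitter_sd_min,
    burst_dropout_rate = burst_dropout_rate, seed = seed, tz = tz
  )
  class(cfg) <- "study_config"
  validate_study_config(cfg)
  cfg
}

#' Validate a study configuration
#'
#' Checks every field of a [study_config()]; the error message names the
#' offending field.
#'
#' @param cfg a `study_config`.
#' @return `cfg`, invisibly, if valid.
#' @export
validate_study_config <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  chk_count <- function(field, min = 1) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < min) {
      stop(sprintf("invalid configuration: `%s` must be a number >= %s", field, min),
           call. = FALSE)
    }
  }
  for (f in c("n_individuals", "pre_days", "festival_days", "burst_hz",
              "bursts_per_day", "gps_interval_min", "gps_burst_size")) {
    chk_count(f)
  }
  chk_count("post_days", min = 0)
  if (!is.numeric(cfg$burst_len_s) || cfg$burst_len_s <= 0) {
    stop("invalid configuration: `burst_len_s` must be positive", call. = FALSE)
  }
  if (!(cfg$area_scale > 0 && cfg$area_scale <= 1)) {
    stop("invalid configuration: `area_scale` must lie in (0, 1]", call. = FALSE)
  }
  if (cfg$dfc_noise_gain < 0 || cfg$dfc_noise_gain > 1) {
    stop("invalid configuration: `dfc_noise_gain` must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$male_nest_hazard_mult <= 0) {
    stop("invalid configuration: `male_nest_hazard_mult` must be positive", call. = FALSE)
  }
  for (f in c("burst_dropout_rate", "gps_artifact_rate")) {
    if (cfg[[f]] < 0 || cfg[[f]] >= 1) {
      stop(sprintf("invalid configuration: `%s` must lie in [0, 1)", f), call. = FALSE)
    }
  }
  if (length(cfg$site_center) != 2 || !is.numeric(cfg$site_center)) {
    stop("invalid configuration: `site_center` must be numeric length 2", call. = FALSE)
  }
  invisible(cfg)
}

#' Phase calendar of a study
#'
#' Expands a configuration into one row per study date with its phase label:
#' `"pre"` for the baseline days, `"festival"` for the disturbance days and
#' `"post"` for the trailing nest-monitoring days. With the default calendar
#' (start 2016-08-10, 19 + 19 days) the festival phase starts on 29 August.
#'
#' @param cfg a [study_config()], or arguments to build one.
#' @return a tibble with columns `date`, `phase`.
#' @examples
#' cal <- phase_calendar(study_config())
#' table(cal$phase)
#' @export
phase_calendar <- function(cfg = study_config()) {
  validate_study_config(cfg)
  dates <- seq(cfg$start_date,
               by = "day",
               length.out = cfg$pre_days + cfg$festival_days + cfg$post_days)
  phase <- rep(c("pre", "festival", "post"),
               times = c(cfg$pre_days, cfg$festival_days, cfg$post_days))
  tibble::tibble(date = dates, phase = phase)
}

#' Civil twilight table from a smooth seasonal template
#'
#' The pipeline treats civil dawn and civil dusk as an external input table.
#' For simulations this helper provides a smooth seasonal template for
#' Berlin-like latitudes: a sinusoid in day-of-year anchored at the
#' solstices (civil dawn ~03:55 midsummer / ~07:35 midwinter, civil dusk
#' ~22:30 / ~16:55, local fixed-offset time). It is a plausible template,
#' not an ephemeris.
#'
#' @param dates vector of `Date`s.
#' @param tz timezone of the returned instants.
#' @return tibble with `date`, `civil_dawn`, `civil_dusk` (POSIXct).
#' @examples
#' twilight_table(as.Date("2016-08-10") + 0:2)
#' @export
twilight_table <- function(dates, tz = .hog_tz) {
  dates <- as.Date(dates)
  doy <- as.integer(strftime(dates, "%j"))
  dawn_min <- 345 - 110 * cos(2 * pi * (doy - 172) / 365)
  dusk_min <- 1182.5 + 167.5 * cos(2 * pi * (doy - 172) / 365)
  midnight <- as.POSIXct(paste(dates, "00:00:00"), tz = tz)
  tibble::tibble(
    date = dates,
    civil_dawn = midnight + round(dawn_min) * 60,
    civil_dusk = midnight + round(dusk_min) * 60
  )
}
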