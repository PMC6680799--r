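#' Diurnality index of one activity day
#'
#' Rate-normalized contrast of daylight versus night activity:
#' `DI = (Ad/Td - An/Tn) / (Ad/Td + An/Tn)`, where `Ad`/`An` are the summed
#' per-minute aSD values in daylight and night and `Td`/`Tn` the respective
#' durations, so the different lengths of day and night are taken into
#' account. DI is -1 for strictly nocturnal activity, +1 for strictly
#' diurnal activity, and 0 when the activity *rates* are equal.
#'
#' @param asd per-minute aSD values of one dawn-to-dawn day.
#' @param is_day logical, same length: minute falls between civil dawn and
#'   civil dusk.
#' @return DI in `[-1, 1]`, or `NA` (with a warning) when total activity is
#'   zero or a segment is empty.
#' @export
diurnality_index <- function(asd, is_day) {
  stopifnot(length(asd) == length(is_day))
  td <- sum(is_day)
  tn <- sum(!is_day)
  if (td == 0 || tn == 0) {
    warning("day or night segment empty; DI undefined")
    return(NA_real_)
  }
  rd <- sum(asd[is_day]) / td
  rn <- sum(asd[!is_day]) / tn
  if (rd + rn == 0) {
    warning("zero total activity; DI undefined")
    return(NA_real_)
  }
  (rd - rn) / (rd + rn)
}

#' Activity onset of one dawn-to-dawn day
#'
#' The onset is the first timestamp of a run of at least `k` consecutive
#' minutes whose aSD exceeds the threshold (the individual's deployment
#' mean aSD, which separates generally active from passive behavior).
#'
#' @param timestamps ordered POSIXct minutes of the day.
#' @param asd matching aSD values.
#' @param threshold activity threshold.
#' @param k minimum run length in minutes (default 1).
#' @return POSIXct onset, or `NA` when the day has no qualifying run.
#' @export
activity_onset <- function(timestamps, asd, threshold, k = 1) {
  stopifnot(length(timestamps) == length(asd), k >= 1)
  active <- asd > threshold
  if (!any(active)) return(timestamps[NA_integer_])
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- which(r$values & r$lengths >= k)
  if (length(ok) == 0) return(timestamps[NA_integer_])
  timestamps[starts[ok[1]]]
}

#' Signed minutes between activity onset and civil dusk
#'
#' Zero marks civil dusk; negative values are onsets before dusk, positive
#' values onsets after dusk.
#'
#' @param onset POSIXct activity onset.
#' @param civil_dusk POSIXct civil dusk of the same day.
#' @return minutes (numeric).
#' @export
tsdusk <- function(onset, civil_dusk) {
  as.numeric(difftime(onset, civil_dusk, units = "mins"))
}

# assign each timestamp to its dawn-anchored activity day and flag daylight
.dawn_days <- function(timestamps, twilight, tz = .hog_tz) {
  dawns <- twilight$civil_dawn[order(twilight$civil_dawn)]
  ddates <- twilight$date[order(twilight$civil_dawn)]
  idx <- findInterval(as.numeric(timestamps), as.numeric(dawns))
  aday <- as.Date(ifelse(idx == 0, NA, as.character(ddates[pmax(idx, 1)])))
  dusk_of <- stats::setNames(twilight$civil_dusk, as.character(twilight$date))
  dusk <- dusk_of[as.character(aday)]
  is_day <- !is.na(aday) & timestamps < dusk
  list(aday = aday, is_day = is_day)
}

#' Per-day circadian summary: DI, activity onset, TSdusk
#'
#' Builds per-minute activity days anchored at civil dawn and computes, for
#' every individual and activity day, the diurnality index, the activity
#' onset (aSD above the individual's deployment-mean threshold for at least
#' `k` consecutive minutes), and TSdusk. Minutes before the first civil
#' dawn in the twilight table are discarded.
#'
#' @param asd_table tibble with `individual_id`, `timestamp`, `asd` (one
#'   row per burst/minute), e.g. [featurize()] output or the generator's
#'   `burst_summary`.
#' @param twilight tibble with `date`, `civil_dawn`, `civil_dusk` covering
#'   every study date.
#' @param k onset run length in minutes.
#' @param threshold_scope `"deployment"` (default; the mean aSD is taken
#'   over each individual's full deployment) or `"global"` (all
#'   individuals pooled).
#' @param tz study-local timezone.
#' @return tibble: `individual_id`, `date` (activity day), `n_minutes`,
#'   `di`, `onset`, `tsdusk_min`, `threshold`.
#' @export
rhythm_summary <- function(asd_table, twilight, k = 1,
                           threshold_scope = c("deployment", "global"),
                           tz = .hog_tz) {
  threshold_scope <- match.arg(threshold_scope)
  stopifnot(all(c("individual_id", "timestamp", "asd") %in% names(asd_table)))
  df <- dplyr::arrange(asd_table, .data$individual_id, .data$timestamp)
  dd <- .dawn_days(df$timestamp, twilight, tz = tz)
  df$aday <- dd$aday
  df$is_day <- dd$is_day
  df <- df[!is.na(df$aday), ]
  global_thr <- mean(df$asd)
  dusk_of <- stats::setNames(twilight$civil_dusk, as.character(twilight$date))

  out <- list()
  for (id in unique(df$individual_id)) {
    sub <- df[df$individual_id == id, ]
    thr <- if (threshold_scope == "deployment") mean(sub$asd) else global_thr
    for (ad in unique(as.character(sub$aday))) {
      day <- sub[as.character(sub$aday) == ad, ]
      di <- suppressWarnings(diurnality_index(day$asd, day$is_day))
      onset <- activity_onset(day$timestamp, day$asd, thr, k = k)
      dusk <- dusk_of[[ad]]
      out[[length(out) + 1]] <- tibble::tibble(
        individual_id = id, date = as.Date(ad), n_minutes = nrow(day),
        di = di, onset = onset,
        tsdusk_min = if (is.na(onset)) NA_real_ else tsdusk(onset, dusk),
        threshold = thr
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Daily ODBA sums with completeness filter
#'
#' Sums per-burst ODBA over each civil calendar day (00:00-23:59) and
#' individual; days with fewer than `min_bursts` kept bursts are excluded
#' so that partial days cannot bias the comparison.
#'
#' @param features tibble with `individual_id`, `timestamp`, `odba`.
#' @param min_bursts completeness threshold (default 1430 of 1440).
#' @param tz study-local timezone.
#' @return tibble: `individual_id`, `date`, `n_bursts`, `odba_sum`.
#' @export
daily_odba <- function(features, min_bursts = 1430, tz = .hog_tz) {
  stopifnot(all(c("individual_id", "timestamp", "odba") %in% names(features)))
  df <- features
  df$date <- as.Date(df$timestamp, tz = tz)
  out <- df %>%
    dplyr::group_by(.data$individual_id, .data$date) %>%
    dplyr::summarise(n_bursts = dplyr::n(), odba_sum = sum(.data$odba),
                     .groups = "drop")
  out[out$n_bursts >= min_bursts, ]
}
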