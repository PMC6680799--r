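#' Normalized autocorrelation of an activity series
#'
#' Periodic (circular) autocorrelation, normalized to 1 at lag zero, used
#' to filter noise and enhance rhythmic components before the Fourier
#' step. The circular form is chosen because its discrete Fourier
#' transform equals the periodogram of the series exactly
#' (Wiener-Khinchin), so a strictly 24-h-periodic window yields a harmonic
#' power ratio of exactly 1; the linear biased estimator's triangular
#' taper would leak line power into non-harmonic bins.
#'
#' @param x numeric series at regular spacing (no NAs).
#' @param max_lag number of lags returned (default `length(x)`, i.e. lags
#'   `0 .. length(x) - 1`).
#' @return numeric vector of autocorrelations, `r[1] = 1`.
#' @export
autocorrelate <- function(x, max_lag = length(x)) {
  n <- length(x)
  stopifnot(n >= 2, max_lag >= 1, max_lag <= n)
  xc <- x - mean(x)
  c0 <- sum(xc^2) / n
  if (c0 == 0) stop("zero-variance window", call. = FALSE)
  S <- Mod(stats::fft(xc))^2 / n
  r <- Re(stats::fft(S, inverse = TRUE)) / n / c0
  r[seq_len(max_lag)]
}

#' Fourier power spectrum of an autocorrelation function
#'
#' Discrete Fourier spectrum of the ACF. Because the (circular)
#' autocorrelation already lives on the power scale, its Fourier
#' coefficients are real, non-negative, and equal the normalized power
#' spectral density of the underlying series (Wiener-Khinchin); that power
#' is what the DFC ratios. (Squaring these coefficients again would
#' quadratically suppress everything but the dominant peak and saturate
#' the DFC near 1.) With an ACF of `N` points at `dt`-minute sampling, the
#' tested periods run from the whole window length (`N * dt`, here three
#' days) down to twice the sampling interval (here 2 min); the DC
#' component is excluded. Bins whose period is `24/k` hours (integer `k`)
#' are flagged as harmonics of the 24-h rhythm.
#'
#' @param r autocorrelation values (lags 0 .. N-1).
#' @param dt_min sampling interval in minutes.
#' @return tibble: `period_min`, `power`, `harmonic`.
#' @export
dfc_spectrum <- function(r, dt_min = 1) {
  N <- length(r)
  stopifnot(N >= 4)
  P <- pmax(Re(stats::fft(r)), 0)
  jj <- seq_len(floor(N / 2))
  period_min <- N * dt_min / jj
  # period 24/k h  <=>  bin index j = k * (N * dt / 1440); harmonic bins are
  # the exact integer multiples (half-bin tolerance for non-integer grids)
  step <- N * dt_min / 1440
  kk <- jj / step
  harmonic <- abs(kk - round(kk)) < (0.5 / step) & round(kk) >= 1
  tibble::tibble(period_min = period_min, power = P[jj + 1],
                 harmonic = harmonic)
}

#' Degree of Functional Coupling of one 3-day window
#'
#' The activity series is autocorrelated, the ACF is Fourier-transformed,
#' and the DFC is the summed spectral power at harmonics of the 24-h
#' rhythm (periods 24/k hours) divided by the total spectral power: 1 when
#' the behavior is maximally synchronized with the 24-h day, 0 when no
#' power lies on the daily harmonics.
#'
#' @param x per-minute aSD series covering exactly `window_days` days
#'   (default 3 x 1440 = 4320 points). Small gaps (`NA`s, at most
#'   `max_gap_frac` of the window) are linearly interpolated; larger gaps
#'   invalidate the window.
#' @param dt_min sampling interval in minutes.
#' @param window_days window length in days.
#' @param max_gap_frac largest tolerated fraction of missing minutes.
#' @return list of class `dfc_result`: `dfc`, `total_power`,
#'   `harmonic_power`, `n_harmonic`, `n`.
#' @examples
#' t <- 0:4319
#' dfc(2 + sin(2 * pi * t / 1440))$dfc  # exactly 1
#' @export
dfc <- function(x, dt_min = 1, window_days = 3, max_gap_frac = 0.05) {
  expected <- window_days * 1440 / dt_min
  if (length(x) != expected) {
    stop(sprintf("window must have %d points (%g days at %g-min sampling)",
                 expected, window_days, dt_min), call. = FALSE)
  }
  if (anyNA(x)) {
    frac <- mean(is.na(x))
    if (frac > max_gap_frac) {
      stop(sprintf("window has %.1f%% missing minutes (max %.1f%%)",
                   100 * frac, 100 * max_gap_frac), call. = FALSE)
    }
    idx <- seq_along(x)
    x <- stats::approx(idx[!is.na(x)], x[!is.na(x)], xout = idx,
                       rule = 2)$y
  }
  r <- autocorrelate(x)
  sp <- dfc_spectrum(r, dt_min = dt_min)
  tot <- sum(sp$power)
  if (tot == 0) stop("zero total spectral power", call. = FALSE)
  harm <- sum(sp$power[sp$harmonic])
  structure(
    list(dfc = harm / tot, total_power = tot, harmonic_power = harm,
         n_harmonic = sum(sp$harmonic), n = length(x)),
    class = "dfc_result"
  )
}

#' @export
print.dfc_result <- function(x, ...) {
  cat(sprintf("DFC %.4f (harmonic/total power %.3g/%.3g over %d harmonic bins)\n",
              x$dfc, x$harmonic_power, x$total_power, x$n_harmonic))
  invisible(x)
}

#' Moving 3-day DFC over a deployment
#'
#' Slides a `window_days`-day window in 1-day steps over each individual's
#' per-minute aSD series and assigns each DFC to the last day of its
#' window (the first value lands on day 3). Windows containing excluded
#' days (more missing minutes than `max_gap_frac`) are reported with
#' `window_ok = FALSE` and `NA` DFC.
#'
#' @param asd_table tibble with `individual_id`, `timestamp`, `asd`.
#' @param dt_min sampling interval in minutes.
#' @param window_days window length in days.
#' @param max_gap_frac largest tolerated fraction of missing minutes.
#' @param tz study-local timezone.
#' @return tibble: `individual_id`, `date` (window end), `dfc`,
#'   `harmonic_power`, `total_power`, `window_ok`.
#' @export
moving_dfc <- function(asd_table, dt_min = 1, window_days = 3,
                       max_gap_frac = 0.05, tz = .hog_tz) {
  stopifnot(all(c("individual_id", "timestamp", "asd") %in% names(asd_table)))
  per_day <- 1440 / dt_min
  out <- list()
  for (id in unique(asd_table$individual_id)) {
    sub <- dplyr::arrange(asd_table[asd_table$individual_id == id, ],
                          .data$timestamp)
    dates <- sort(unique(as.Date(sub$timestamp, tz = tz)))
    if (length(dates) < window_days) {
      warning(sprintf("individual %s has fewer than %d days; no DFC computed",
                      id, window_days))
      next
    }
    d0 <- dates[1]
    # regular minute grid over the deployment; missing bursts become NAs
    all_days <- seq(d0, max(dates), by = "day")
    grid0 <- as.POSIXct(paste(d0, "00:00:00"), tz = tz)
    n_grid <- length(all_days) * per_day
    slot <- as.integer(round(as.numeric(difftime(sub$timestamp, grid0,
                                                 units = "mins")) / dt_min)) + 1L
    ok <- slot >= 1 & slot <= n_grid
    series <- rep(NA_real_, n_grid)
    series[slot[ok]] <- sub$asd[ok]
    for (w in seq_len(length(all_days) - window_days + 1)) {
      i1 <- (w - 1) * per_day + 1
      win <- series[i1:(i1 + window_days * per_day - 1)]
      end_day <- all_days[w + window_days - 1]
      res <- tryCatch(dfc(win, dt_min = dt_min, window_days = window_days,
                          max_gap_frac = max_gap_frac),
                      error = function(e) NULL)
      out[[length(out) + 1]] <- tibble::tibble(
        individual_id = id, date = end_day,
        dfc = if (is.null(res)) NA_real_ else res$dfc,
        harmonic_power = if (is.null(res)) NA_real_ else res$harmonic_power,
        total_power = if (is.null(res)) NA_real_ else res$total_power,
        window_ok = !is.null(res)
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(individual_id = character(0), date = as.Date(character(0)),
                          dfc = numeric(0), harmonic_power = numeric(0),
                          total_power = numeric(0), window_ok = logical(0)))
  }
  dplyr::bind_rows(out)
}
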