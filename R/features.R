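# fixed, documented order of the 25 model predictors
.predictor_cols <- c(
  paste0("mean_", c("x", "y", "z")),
  paste0("sd_", c("x", "y", "z")),
  paste0("icv_", c("x", "y", "z")),
  paste0("var_", c("x", "y", "z")),
  paste0("kurt_", c("x", "y", "z")),
  paste0("skew_", c("x", "y", "z")),
  paste0("swm_", c("x", "y", "z")),
  "q", "pitch", "roll", "odba"
)

#' Names of the 25 burst predictors, in canonical column order
#'
#' Seven per-axis statistics (mean, standard deviation, inverse coefficient
#' of variation, variance, kurtosis, skewness, weighted mean of the
#' autocorrelated power spectrum) for each of the three axes, plus four
#' cross-axis quantities: the static vector norm `q`, `pitch`, `roll`, and
#' ODBA.
#'
#' @return character vector of length 25.
#' @export
predictor_names <- function() .predictor_cols

#' Validate burst completeness
#'
#' A burst is dropped when any axis carries fewer samples than expected
#' under the logger settings; over-length bursts are kept and truncated to
#' `expected_n` (with a warning in [featurize()]).
#'
#' @param bursts long burst table (`burst_id`, `sample_idx`, `ax_g`,
#'   `ay_g`, `az_g`, plus optional identifiers).
#' @param expected_n expected samples per axis (250 or 264 in the field
#'   protocol).
#' @return tibble with one row per burst: `burst_id`, `n_samples`, and
#'   `decision` (`"keep"`, `"truncate"`, `"drop"`). Validation never errors
#'   on data content.
#' @export
validate_bursts <- function(bursts, expected_n) {
  stopifnot(is.numeric(expected_n), expected_n >= 2)
  cnt <- dplyr::count(bursts, .data$burst_id, name = "n_samples")
  cnt$decision <- ifelse(cnt$n_samples < expected_n, "drop",
                         ifelse(cnt$n_samples > expected_n, "truncate", "keep"))
  cnt
}

#' Per-axis summary statistics of one burst axis
#'
#' @param x numeric samples of one axis (n >= 2).
#' @return named vector: `mean`, `sd` (denominator n-1), `icv` (mean/sd;
#'   `NA` when sd is zero), `var`, `kurt` (raw standardized fourth moment,
#'   ~3 for a normal), `skew`. Central moments use the 1/n convention.
#' @examples
#' per_axis_stats(c(1, 2, 3))  # mean 2, var 1, sd 1, icv 2
#' @export
per_axis_stats <- function(x) {
  n <- length(x)
  stopifnot(n >= 2)
  m <- mean(x)
  v <- stats::var(x)
  s <- sqrt(v)
  c2 <- sum((x - m)^2) / n
  if (c2 == 0) {
    kurt <- NA_real_; skew <- NA_real_; icv <- NA_real_
  } else {
    kurt <- (sum((x - m)^4) / n) / c2^2
    skew <- (sum((x - m)^3) / n) / c2^1.5
    icv <- m / s
  }
  c(mean = m, sd = s, icv = icv, var = v, kurt = kurt, skew = skew)
}

# circular (periodic) autocovariance of each column of X, lags 0..n-1;
# its DFT is exactly the periodogram, so spectral lines stay lines
.acov_mat <- function(X) {
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  S <- Mod(stats::mvfft(Xc))^2 / n
  Re(stats::mvfft(S, inverse = TRUE))[seq_len(n), , drop = FALSE] / n
}

# spectral weighted mean for each column of X (samples x bursts)
.swm_mat <- function(X, hz) {
  n <- nrow(X)
  ac <- .acov_mat(X)
  c0 <- ac[1, ]
  r <- sweep(ac, 2, ifelse(c0 == 0, 1, c0), "/")
  r[, c0 == 0] <- 0
  P <- Mod(stats::mvfft(r))
  jj <- seq_len(floor(n / 2))
  P <- P[jj + 1, , drop = FALSE]
  f <- jj * hz / n
  tot <- colSums(P)
  out <- colSums(P * f) / ifelse(tot == 0, 1, tot)
  out[tot == 0] <- 0
  out
}

#' Weighted mean frequency of the autocorrelated power spectrum
#'
#' The axis signal is autocorrelated (periodic/circular estimator,
#' normalized to 1 at lag zero), the magnitude spectrum of the
#' autocorrelation is taken by discrete Fourier transform - because the
#' autocorrelation is a power-domain quantity this equals the signal's
#' periodogram (Wiener-Khinchin), so a pure tone stays a single spectral
#' line - and the power-weighted mean frequency over the
#' positive-frequency bins (DC excluded) is returned. A constant signal
#' returns 0 by convention.
#'
#' @param x numeric samples (n >= 4).
#' @param hz sampling frequency.
#' @return frequency in Hz.
#' @examples
#' t <- (0:249) / 100
#' spectral_wmean(sin(2 * pi * 2 * t), 100)  # ~2 Hz
#' @export
spectral_wmean <- function(x, hz) {
  stopifnot(length(x) >= 4)
  as.numeric(.swm_mat(matrix(x, ncol = 1), hz))
}

#' Static attitude of a burst
#'
#' The static vector is the per-axis mean over the burst. `q` is its
#' Euclidean norm (g); `pitch = atan2(sx, sqrt(sy^2 + sz^2))` and
#' `roll = atan2(sy, sz)`, both in degrees (x forward, z up convention).
#'
#' @param burst numeric matrix, samples x 3 axes.
#' @return named vector `q`, `pitch`, `roll` (degrees); pitch/roll are `NA`
#'   when the static vector is zero.
#' @examples
#' attitude(matrix(rep(c(0, 0, 1), each = 10), ncol = 3))
#' @export
attitude <- function(burst) {
  s <- colMeans(burst)
  q <- sqrt(sum(s^2))
  if (q == 0) {
    return(c(q = 0, pitch = NA_real_, roll = NA_real_))
  }
  c(q = q,
    pitch = atan2(s[[1]], sqrt(s[[2]]^2 + s[[3]]^2)) * 180 / pi,
    roll = atan2(s[[2]], s[[3]]) * 180 / pi)
}

#' Overall dynamic body acceleration of one burst
#'
#' The static component is the per-axis mean over the whole burst (bursts
#' are too short for a running-mean window); the dynamic component is the
#' sample minus the static. ODBA is the mean over samples of the summed
#' absolute dynamic acceleration of the three axes, hence invariant to any
#' constant (gravity) offset.
#'
#' @param burst numeric matrix, samples x 3 axes, in g.
#' @return ODBA in g.
#' @examples
#' burst_odba(matrix(1, 10, 3))  # constant burst -> 0
#' @export
burst_odba <- function(burst) {
  d <- abs(sweep(burst, 2, colMeans(burst)))
  mean(rowSums(d))
}

#' Compute the 25-predictor feature table from raw bursts
#'
#' Validates bursts against the expected sample count (under-length bursts
#' dropped and logged, over-length truncated with a warning), then computes
#' the canonical 25 predictors per burst (see [predictor_names()]) plus the
#' accumulated standard deviation `asd = sd_x + sd_y + sd_z` used by the
#' rhythm metrics. Bursts with degenerate axes (zero variance) get `NA`
#' predictors and are flagged via `missing_flag`; they are excluded from
#' model training but retained for aSD.
#'
#' @param bursts long burst table: `burst_id`, `sample_idx`, `ax_g`, `ay_g`,
#'   `az_g`, and optionally `individual_id`, `timestamp`.
#' @param expected_n expected samples per axis; inferred as the most common
#'   count when `NULL`.
#' @param hz sampling frequency (Hz).
#' @return tibble, one row per kept burst: identifiers, `n_samples`, the 25
#'   predictors, `asd`, `missing_flag`. Dropped burst ids are attached as
#'   `attr(, "dropped")`.
#' @export
featurize <- function(bursts, expected_n = NULL, hz = 100) {
  need <- c("burst_id", "sample_idx", "ax_g", "ay_g", "az_g")
  miss <- setdiff(need, names(bursts))
  if (length(miss) > 0) {
    stop("burst table is missing columns: ", paste(miss, collapse = ", "))
  }
  if (nrow(bursts) == 0) {
    out <- tibble::tibble(burst_id = character(0))
    attr(out, "dropped") <- character(0)
    return(out)
  }
  cnt <- dplyr::count(bursts, .data$burst_id, name = "n")
  if (is.null(expected_n)) {
    tab <- table(cnt$n)
    expected_n <- as.integer(names(tab)[which.max(tab)])
  }
  dropped <- cnt$burst_id[cnt$n < expected_n]
  if (length(dropped) > 0) {
    message(sprintf("dropping %d under-length burst(s): %s", length(dropped),
                    paste(utils::head(dropped, 5), collapse = ", ")))
  }
  if (any(cnt$n > expected_n)) {
    warning(sprintf("%d over-length burst(s) truncated to %d samples",
                    sum(cnt$n > expected_n), expected_n))
  }
  keep <- bursts[!bursts$burst_id %in% dropped & bursts$sample_idx <= expected_n, ]
  keep <- dplyr::arrange(keep, .data$burst_id, .data$sample_idx)
  ids <- unique(keep$burst_id)
  B <- length(ids)
  if (B == 0) {
    out <- tibble::tibble(burst_id = character(0))
    attr(out, "dropped") <- dropped
    return(out)
  }
  n <- expected_n
  ax <- matrix(keep$ax_g, nrow = n)
  ay <- matrix(keep$ay_g, nrow = n)
  az <- matrix(keep$az_g, nrow = n)

  stat_axis <- function(X) {
    m <- colMeans(X)
    Xc <- sweep(X, 2, m)
    v <- colSums(Xc^2) / (n - 1)
    s <- sqrt(v)
    c2 <- colSums(Xc^2) / n
    zero <- c2 == 0
    kurt <- ifelse(zero, NA_real_, (colSums(Xc^4) / n) / c2^2)
    skew <- ifelse(zero, NA_real_, (colSums(Xc^3) / n) / c2^1.5)
    icv <- ifelse(zero, NA_real_, m / s)
    list(mean = m, sd = s, icv = icv, var = v, kurt = kurt, skew = skew)
  }
  sx <- stat_axis(ax); sy <- stat_axis(ay); sz <- stat_axis(az)
  swm_x <- .swm_mat(ax, hz); swm_y <- .swm_mat(ay, hz); swm_z <- .swm_mat(az, hz)

  mx <- sx$mean; my <- sy$mean; mz <- sz$mean
  q <- sqrt(mx^2 + my^2 + mz^2)
  pitch <- ifelse(q == 0, NA_real_, atan2(mx, sqrt(my^2 + mz^2)) * 180 / pi)
  roll <- ifelse(q == 0, NA_real_, atan2(my, mz) * 180 / pi)
  odba <- colMeans(abs(sweep(ax, 2, mx)) + abs(sweep(ay, 2, my)) +
                     abs(sweep(az, 2, mz)))

  out <- tibble::tibble(
    burst_id = ids,
    n_samples = n,
    mean_x = mx, mean_y = my, mean_z = mz,
    sd_x = sx$sd, sd_y = sy$sd, sd_z = sz$sd,
    icv_x = sx$icv, icv_y = sy$icv, icv_z = sz$icv,
    var_x = sx$var, var_y = sy$var, var_z = sz$var,
    kurt_x = sx$kurt, kurt_y = sy$kurt, kurt_z = sz$kurt,
    skew_x = sx$skew, skew_y = sy$skew, skew_z = sz$skew,
    swm_x = swm_x, swm_y = swm_y, swm_z = swm_z,
    q = q, pitch = pitch, roll = roll, odba = odba
  )
  out$asd <- out$sd_x + out$sd_y + out$sd_z
  out$missing_flag <- !stats::complete.cases(out[, .predictor_cols])
  meta_cols <- intersect(c("individual_id", "timestamp"), names(bursts))
  if (length(meta_cols) > 0) {
    meta <- dplyr::distinct(keep[, c("burst_id", meta_cols)])
    out <- dplyr::left_join(meta, out, by = "burst_id")
  }
  out <- tibble::as_tibble(out)
  attr(out, "dropped") <- dropped
  out
}
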