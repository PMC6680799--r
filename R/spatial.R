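#' Clean raw GPS fixes
#'
#' Three-step cleaning pipeline for high-fluctuation GPS data, in fixed
#' order: (1) drop fixes more than `max_dist` (1000 m) from the site
#' center; (2) average the remaining fixes of each 5-min event to a single
#' position; (3) a single forward pass per individual drops an event when
#' the speed from the last *retained* event strictly exceeds `max_speed`
#' (2 m/s; a speed of exactly 2 m/s is kept).
#'
#' @param fixes tibble with `individual_id`, `timestamp`, `x_m`, `y_m`.
#' @param site_center planar site coordinates (m).
#' @param max_dist distance cutoff from the site center (m).
#' @param max_speed speed cutoff between consecutive events (m/s).
#' @param event_interval_min GPS event spacing (minutes).
#' @return tibble of cleaned events: `individual_id`, `timestamp` (mean
#'   fix time), `x_m`, `y_m`, `n_fixes`.
#' @export
clean_fixes <- function(fixes, site_center = c(0, 0), max_dist = 1000,
                        max_speed = 2, event_interval_min = 5) {
  stopifnot(all(c("individual_id", "timestamp", "x_m", "y_m") %in% names(fixes)))
  d <- sqrt((fixes$x_m - site_center[1])^2 + (fixes$y_m - site_center[2])^2)
  fx <- fixes[d <= max_dist, ]
  if (nrow(fx) == 0) return(tibble::tibble(
    individual_id = character(0),
    timestamp = as.POSIXct(character(0)),
    x_m = numeric(0), y_m = numeric(0), n_fixes = integer(0)))
  fx$event <- floor(as.numeric(fx$timestamp) / (event_interval_min * 60))
  ev <- fx %>%
    dplyr::group_by(.data$individual_id, .data$event) %>%
    dplyr::summarise(
      timestamp = mean(.data$timestamp),
      x_m = mean(.data$x_m), y_m = mean(.data$y_m),
      n_fixes = dplyr::n(), .groups = "drop"
    ) %>%
    dplyr::arrange(.data$individual_id, .data$timestamp)
  keep <- logical(nrow(ev))
  for (id in unique(ev$individual_id)) {
    ix <- which(ev$individual_id == id)
    last <- NA_integer_
    for (i in ix) {
      if (is.na(last)) {
        keep[i] <- TRUE
        last <- i
      } else {
        dt <- as.numeric(difftime(ev$timestamp[i], ev$timestamp[last],
                                  units = "secs"))
        dist <- sqrt((ev$x_m[i] - ev$x_m[last])^2 +
                       (ev$y_m[i] - ev$y_m[last])^2)
        sp <- if (dt > 0) dist / dt else Inf
        if (sp <= max_speed) {
          keep[i] <- TRUE
          last <- i
        }
      }
    }
  }
  ev <- ev[keep, ]
  ev$event <- NULL
  ev
}

#' Group cleaned events into individual-nights
#'
#' The GPS duty cycle runs from the evening of one day (19:00) to the next
#' morning (07:00); events are assigned to the night of the *evening*
#' date. Events outside the window are discarded; nights with fewer than
#' `min_fixes` events are flagged unusable.
#'
#' @param events cleaned events from [clean_fixes()].
#' @param night_start_hour,night_end_hour duty-cycle window (local hours).
#' @param min_fixes minimum events for a usable night.
#' @param tz study-local timezone.
#' @return tibble: `individual_id`, `night` (Date of the evening),
#'   `timestamp`, `x_m`, `y_m`, `usable`.
#' @export
group_nights <- function(events, night_start_hour = 19, night_end_hour = 7,
                         min_fixes = 5, tz = .hog_tz) {
  hr <- as.numeric(format(events$timestamp, "%H", tz = tz)) +
    as.numeric(format(events$timestamp, "%M", tz = tz)) / 60
  date <- as.Date(events$timestamp, tz = tz)
  in_evening <- hr >= night_start_hour
  in_morning <- hr < night_end_hour
  sel <- in_evening | in_morning
  ev <- events[sel, ]
  night <- date[sel]
  morn <- in_morning[sel]
  night[morn] <- night[morn] - 1
  ev$night <- night
  ev <- ev %>%
    dplyr::group_by(.data$individual_id, .data$night) %>%
    dplyr::mutate(usable = dplyr::n() >= min_fixes) %>%
    dplyr::ungroup()
  ev[, c("individual_id", "night", "timestamp", "x_m", "y_m", "usable")]
}

#' Kernel-density isopleth area of a point set
#'
#' Bivariate Gaussian product-kernel density with per-axis reference
#' bandwidth `h = sd * n^(-1/6)`, evaluated on a regular grid extended by
#' `margin_mult * h` beyond the data range. The area is the total area of
#' the smallest set of grid cells containing `iso` (default 50%) of the
#' density mass - the core area for `iso = 0.5`.
#'
#' @param x,y planar coordinates (m).
#' @param iso isopleth level in (0, 1).
#' @param grid_n grid cells per axis.
#' @param margin_mult grid margin in bandwidths.
#' @param bw optional fixed per-axis bandwidth (length 1 or 2, m),
#'   overriding the reference rule.
#' @param bw_floor lower bandwidth bound (m) guarding degenerate point
#'   sets (all points identical triggers a warning).
#' @return area in hectares.
#' @examples
#' set.seed(1)
#' kde_area(rnorm(500, sd = 50), rnorm(500, sd = 50))  # ~1.1 ha
#' @export
kde_area <- function(x, y, iso = 0.5, grid_n = 200, margin_mult = 3,
                     bw = NULL, bw_floor = 1) {
  stopifnot(length(x) == length(y), length(x) >= 1, iso > 0, iso < 1)
  n <- length(x)
  if (is.null(bw)) {
    bw <- c(stats::sd(x), stats::sd(y)) * n^(-1 / 6)
    if (any(is.na(bw)) || all(bw < bw_floor)) {
      warning("degenerate point set; area reflects the bandwidth floor")
    }
    bw[is.na(bw) | bw < bw_floor] <- bw_floor
  }
  bw <- rep_len(bw, 2)
  gx <- seq(min(x) - margin_mult * bw[1], max(x) + margin_mult * bw[1],
            length.out = grid_n)
  gy <- seq(min(y) - margin_mult * bw[2], max(y) + margin_mult * bw[2],
            length.out = grid_n)
  # product kernel as an outer product of per-axis Gaussian matrices
  A <- outer(gx, x, function(g, p) stats::dnorm(g, p, bw[1]))
  B <- outer(gy, y, function(g, p) stats::dnorm(g, p, bw[2]))
  dens <- (A %*% t(B)) / n
  cell <- diff(gx)[1] * diff(gy)[1]
  mass <- sort(as.numeric(dens), decreasing = TRUE) * cell
  total <- sum(mass)
  n_cells <- which(cumsum(mass) >= iso * total)[1]
  n_cells * cell / 1e4
}

#' Nightly 50% kernel-density core areas
#'
#' Computes [kde_area()] at the 50% isopleth for every usable
#' individual-night.
#'
#' @param nights output of [group_nights()].
#' @param iso isopleth level.
#' @param ... passed to [kde_area()].
#' @return tibble: `individual_id`, `night`, `n_fixes`, `kde_area_ha`
#'   (`NA` for unusable nights).
#' @export
nightly_kde <- function(nights, iso = 0.5, ...) {
  out <- list()
  grp <- dplyr::distinct(nights[, c("individual_id", "night")])
  for (i in seq_len(nrow(grp))) {
    sub <- nights[nights$individual_id == grp$individual_id[i] &
                    nights$night == grp$night[i], ]
    area <- if (sub$usable[1]) {
      kde_area(sub$x_m, sub$y_m, iso = iso, ...)
    } else NA_real_
    out[[i]] <- tibble::tibble(
      individual_id = grp$individual_id[i], night = grp$night[i],
      n_fixes = nrow(sub), kde_area_ha = area
    )
  }
  dplyr::bind_rows(out)
}

#' Label nightly areas with study phases
#'
#' Joins nightly core areas to the phase calendar; every night of the pre
#' and festival phases gets a row, with `NA` area for missing or unusable
#' nights, ready for the pairwise-difference comparison.
#'
#' @param areas output of [nightly_kde()].
#' @param calendar a [phase_calendar()] tibble.
#' @return tibble: `individual_id`, `night`, `phase`, `kde_area_ha`.
#' @export
phase_area_table <- function(areas, calendar) {
  cal <- calendar[calendar$phase %in% c("pre", "festival"), ]
  grid <- tidyr::expand_grid(
    individual_id = unique(areas$individual_id),
    night = cal$date
  )
  grid <- dplyr::left_join(grid, cal, by = c(night = "date"))
  out <- dplyr::left_join(
    grid, areas[, c("individual_id", "night", "kde_area_ha")],
    by = c("individual_id", "night")
  )
  out
}
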