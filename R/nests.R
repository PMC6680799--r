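#' Build nest-utilization spells from daily nest checks
#'
#' A spell is a maximal run of consecutive monitored days an individual
#' spends in the same day-nest. A spell ends with `event = 1` when the
#' next consecutive day's nest differs; spells reaching a phase boundary,
#' a gap in monitoring, or the end of the study are right-censored there
#' (`event = 0`) and a new spell opens afterwards. Phases pool the pre-
#' and post-festival days into `"non_festival"` versus `"festival"`.
#'
#' @param checks tibble with `individual_id`, `sex`, `date`, `nest_id`
#'   (one check per individual-day; conflicting duplicates error, listing
#'   the dates).
#' @param calendar a [phase_calendar()] tibble.
#' @param boundary `"censor"` (default: split spells at the phase
#'   boundary) or `"carry"` (assign a boundary-spanning spell to the phase
#'   of its start).
#' @return tibble of spells: `individual_id`, `sex`, `nest_id`, `start`,
#'   `duration` (days), `event`, `phase`, `gap_flag`.
#' @export
build_spells <- function(checks, calendar, boundary = c("censor", "carry")) {
  boundary <- match.arg(boundary)
  stopifnot(all(c("individual_id", "sex", "date", "nest_id") %in% names(checks)))
  dup <- checks %>%
    dplyr::distinct(.data$individual_id, .data$date, .data$nest_id) %>%
    dplyr::count(.data$individual_id, .data$date) %>%
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("conflicting duplicate nest checks on: ",
         paste(sprintf("%s %s", dup$individual_id, dup$date), collapse = "; "),
         call. = FALSE)
  }
  checks <- dplyr::distinct(checks) %>%
    dplyr::arrange(.data$individual_id, .data$date)
  phase_of <- stats::setNames(
    ifelse(calendar$phase == "festival", "festival", "non_festival"),
    as.character(calendar$date)
  )
  out <- list()
  for (id in unique(checks$individual_id)) {
    sub <- checks[checks$individual_id == id, ]
    n <- nrow(sub)
    gap_next <- c(as.numeric(diff(sub$date)) > 1, TRUE)   # TRUE after last day
    phase <- phase_of[as.character(sub$date)]
    change_next <- c(sub$nest_id[-n] != sub$nest_id[-1], FALSE)
    # a spell breaks after day i when: nest changes (event), monitoring gap,
    # phase boundary (censor mode), or the study ends
    boundary_next <- c(phase[-n] != phase[-1], FALSE)
    brk <- change_next | gap_next |
      (if (boundary == "censor") boundary_next else FALSE)
    start_i <- 1
    for (i in seq_len(n)) {
      if (brk[i]) {
        ev <- as.integer(change_next[i] && !gap_next[i])
        out[[length(out) + 1]] <- tibble::tibble(
          individual_id = id, sex = sub$sex[1],
          nest_id = sub$nest_id[start_i],
          start = sub$date[start_i],
          duration = i - start_i + 1L,
          event = ev,
          phase = unname(phase[start_i]),
          gap_flag = gap_next[i] && i < n
        )
        start_i <- i + 1
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Kaplan-Meier nest-utilization curve
#'
#' Product-limit estimate of the probability that a nest spell exceeds a
#' given duration, with right-censoring.
#'
#' @param spells tibble from [build_spells()] (needs `duration`, `event`).
#' @param ... passed on to [survival::survfit()].
#' @return tibble: `time`, `n_risk`, `n_event`, `n_censor`, `surv`.
#' @export
km_curve <- function(spells, ...) {
  stopifnot(nrow(spells) >= 1)
  fit <- survival::survfit(survival::Surv(duration, event) ~ 1,
                           data = spells, ...)
  tibble::tibble(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, surv = fit$surv
  )
}

#' Log-rank (Mantel) test between two spell groups
#'
#' Standard log-rank statistic comparing the utilization-period
#' distributions, with `Z` signed as observed minus expected events in
#' group A and a two-sided p from the normal approximation.
#'
#' @param spells_a,spells_b spell tibbles (needs `duration`, `event`).
#' @return list: `z`, `p`, `observed`, `expected` (group A), `n` (spells
#'   per group).
#' @export
logrank_test <- function(spells_a, spells_b) {
  stopifnot(nrow(spells_a) > 0, nrow(spells_b) > 0)
  df <- rbind(
    data.frame(duration = spells_a$duration, event = spells_a$event, grp = "A"),
    data.frame(duration = spells_b$duration, event = spells_b$event, grp = "B")
  )
  if (sum(df$event) == 0) stop("no events in either group", call. = FALSE)
  sd_ <- survival::survdiff(survival::Surv(duration, event) ~ grp, data = df)
  z <- sign(sd_$obs[1] - sd_$exp[1]) * sqrt(sd_$chisq)
  list(
    z = unname(z),
    p = unname(stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)),
    observed = unname(sd_$obs[1]), expected = unname(sd_$exp[1]),
    n = c(A = nrow(spells_a), B = nrow(spells_b))
  )
}

#' Nest-survival phase comparison per sex
#'
#' Convenience wrapper reproducing the survival analysis of the nest
#' checks: per sex, the non-festival (pre + post pooled) spells are
#' compared with the festival spells by [logrank_test()], and next-day
#' re-use probabilities (1 - daily change hazard at day 1) are reported.
#'
#' @param spells tibble from [build_spells()].
#' @return tibble: `sex`, `n_spells`, `n_nest_days`, `z`, `p`,
#'   `reuse_prob_nonfest`, `reuse_prob_fest`.
#' @export
nest_phase_comparison <- function(spells) {
  out <- list()
  reuse1 <- function(sp) {
    # probability a nest in use is still used the next day
    if (nrow(sp) == 0) return(NA_real_)
    km <- km_curve(sp)
    if (!1 %in% km$time) return(1)
    km$surv[km$time == 1]
  }
  for (sx in unique(spells$sex)) {
    sub <- spells[spells$sex == sx, ]
    a <- sub[sub$phase == "non_festival", ]
    b <- sub[sub$phase == "festival", ]
    lr <- tryCatch(logrank_test(a, b), error = function(e) NULL)
    out[[length(out) + 1]] <- tibble::tibble(
      sex = sx, n_spells = nrow(sub), n_nest_days = sum(sub$duration),
      z = if (is.null(lr)) NA_real_ else lr$z,
      p = if (is.null(lr)) NA_real_ else lr$p,
      reuse_prob_nonfest = reuse1(a), reuse_prob_fest = reuse1(b)
    )
  }
  dplyr::bind_rows(out)
}
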