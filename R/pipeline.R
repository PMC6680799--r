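.with_phase <- function(df, calendar, date_col) {
  cal <- calendar[, c("date", "phase")]
  names(cal) <- c(date_col, "phase")
  dplyr::left_join(df, cal, by = date_col)
}

#' Run the full disturbance-analysis pipeline on a simulated study
#'
#' Composes every stage end to end: simulate -> (featurize -> train ->
#' classify) -> daily budgets -> circadian metrics -> moving DFC -> GPS
#' cleaning and nightly core areas -> nest spells and survival comparison
#' -> pairwise-difference random-intercept change estimates for every
#' parameter (core area, the four behavior budgets, DI, TSdusk, daily
#' ODBA, DFC).
#'
#' With `raw = TRUE` the classification stage runs on synthesized
#' waveforms: a labeled calibration set is generated, an SVM trained, and
#' budgets built from gated predictions. With `raw = FALSE` (default;
#' appropriate for full-length studies where waveform synthesis is
#' prohibitive) budgets are built from the generator's true labels and the
#' burst-level aSD/ODBA summaries feed the rhythm stages directly.
#'
#' @param cfg a [study_config()].
#' @param seed RNG seed (defaults to `cfg$seed`).
#' @param raw run the waveform-level classification stage.
#' @param train_per_class calibration bursts per class when `raw = TRUE`.
#' @param min_bursts daily completeness threshold; default scales the
#'   full-size rule (1430 of 1440) to `cfg$bursts_per_day`.
#' @param out_dir optional output directory for all stage CSVs and a
#'   `manifest.json` (versions, seed, parameters, row counts, file
#'   checksums). Reruns with the same seed produce identical files.
#' @return list of class `hog_pipeline` with all stage tables (`study`,
#'   `features`, `predictions`, `budgets`, `rhythm`, `dfc`, `areas`,
#'   `spells`, `nest_comparison`, `fits`, `changes`, `manifest`).
#' @export
run_pipeline <- function(cfg = study_config(), seed = cfg$seed, raw = FALSE,
                         train_per_class = 40, min_bursts = NULL,
                         out_dir = NULL) {
  validate_study_config(cfg)
  if (is.null(min_bursts)) {
    min_bursts <- round(1430 / 1440 * cfg$bursts_per_day)
  }
  stage <- "simulate"
  result <- tryCatch({
    st <- simulate_study(cfg, seed = seed, raw = raw)
    n_samp <- round(cfg$burst_len_s * cfg$burst_hz)

    features <- NULL; predictions <- NULL; model <- NULL
    if (raw) {
      stage <- "features"
      features <- featurize(st$bursts, expected_n = n_samp, hz = cfg$burst_hz)
      stage <- "train"
      calib <- simulate_labeled_bursts(train_per_class, n = n_samp,
                                       hz = cfg$burst_hz)
      calib_feats <- featurize(calib$bursts, expected_n = n_samp,
                               hz = cfg$burst_hz)
      calib_feats <- dplyr::left_join(calib$labels, calib_feats, by = "burst_id")
      model <- train_behavior_model(calib_feats, calib_feats$label)
      stage <- "classify"
      predictions <- predict_gated(model, features)
      asd_table <- features
    } else {
      predictions <- st$burst_summary[, c("individual_id", "burst_id",
                                          "timestamp", "label_true")]
      names(predictions)[4] <- "label"
      asd_table <- st$burst_summary
    }

    stage <- "budget"
    budgets <- daily_budget(predictions, min_bursts = min_bursts, tz = cfg$tz)
    stage <- "rhythm"
    rhythm <- rhythm_summary(asd_table, st$twilight, tz = cfg$tz)
    odba_daily <- daily_odba(asd_table, min_bursts = min_bursts, tz = cfg$tz)
    stage <- "dfc"
    dfc_tab <- moving_dfc(asd_table, dt_min = 1440 / cfg$bursts_per_day,
                          tz = cfg$tz)
    stage <- "spatial"
    events <- clean_fixes(st$gps, site_center = cfg$site_center,
                          event_interval_min = cfg$gps_interval_min)
    nights <- group_nights(events, night_start_hour = cfg$night_start_hour,
                           night_end_hour = cfg$night_end_hour, tz = cfg$tz)
    areas <- nightly_kde(nights)
    area_tab <- phase_area_table(areas, st$calendar)
    stage <- "nests"
    spells <- build_spells(st$nests, st$calendar)
    nest_cmp <- nest_phase_comparison(spells)

    stage <- "compare"
    daily_tabs <- list(
      kde50 = stats::setNames(
        area_tab[, c("individual_id", "phase", "kde_area_ha")],
        c("individual_id", "phase", "kde50")),
      di = .with_phase(rhythm, st$calendar, "date")[, c("individual_id", "phase", "di")],
      tsdusk_min = .with_phase(rhythm, st$calendar,
                               "date")[, c("individual_id", "phase", "tsdusk_min")],
      odba_sum = .with_phase(odba_daily, st$calendar,
                             "date")[, c("individual_id", "phase", "odba_sum")],
      dfc = .with_phase(dfc_tab[dfc_tab$window_ok, ], st$calendar,
                        "date")[, c("individual_id", "phase", "dfc")]
    )
    bud_ph <- .with_phase(budgets, st$calendar, "date")
    for (lb in .hog_labels) {
      key <- paste0("budget_", lb)
      tb <- bud_ph[, c("individual_id", "phase", lb)]
      names(tb)[3] <- key
      daily_tabs[[key]] <- tb
    }
    fits <- list()
    for (p in names(daily_tabs)) {
      tb <- daily_tabs[[p]]
      tb <- tb[!is.na(tb$phase) & tb$phase %in% c("pre", "festival"), ]
      f <- tryCatch({
        d <- suppressWarnings(build_diffs(tb, p))
        fit_random_intercept(d)
      }, error = function(e) NULL)
      if (!is.null(f)) fits[[p]] <- f
    }
    changes <- summarize_changes(fits)

    manifest <- list(
      package = as.character(utils::packageVersion("hoglog")),
      seed = seed,
      raw = raw,
      min_bursts = min_bursts,
      config = lapply(unclass(cfg), function(v) {
        if (inherits(v, "Date")) as.character(v) else v
      }),
      rows = list(
        burst_summary = nrow(st$burst_summary),
        bursts = if (is.null(st$bursts)) 0L else nrow(st$bursts),
        gps = nrow(st$gps), nests = nrow(st$nests),
        budgets = nrow(budgets), rhythm = nrow(rhythm),
        dfc = nrow(dfc_tab), areas = nrow(areas), spells = nrow(spells)
      )
    )
    list(study = st, features = features, predictions = predictions,
         model = model, budgets = budgets, rhythm = rhythm,
         odba_daily = odba_daily, dfc = dfc_tab, events = events,
         nights = nights, areas = areas, area_tab = area_tab,
         spells = spells, nest_comparison = nest_cmp, fits = fits,
         changes = changes, manifest = manifest)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, f) {
      if (is.null(df) || nrow(df) == 0) return(NULL)
      df <- as.data.frame(df)
      for (cn in names(df)) {
        if (inherits(df[[cn]], "POSIXct")) df[[cn]] <- .iso8601(df[[cn]])
      }
      utils::write.csv(df, file.path(out_dir, f), row.names = FALSE)
      f
    }
    files <- c(
      wr(result$budgets, "budgets.csv"), wr(result$rhythm, "rhythm.csv"),
      wr(result$odba_daily, "odba_daily.csv"), wr(result$dfc, "dfc.csv"),
      wr(result$areas, "areas.csv"), wr(result$spells, "spells.csv"),
      wr(result$predictions, "predictions.csv"),
      wr(dplyr::bind_rows(lapply(names(result$fits), function(p) {
        est <- result$fits[[p]]$estimates
        est$parameter <- p
        est
      })), "changes.csv"),
      wr(result$changes, "change_summary.csv")
    )
    sums <- tools::md5sum(file.path(out_dir, files))
    names(sums) <- files
    result$manifest$files <- as.list(sums)
    jsonlite::write_json(result$manifest,
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  class(result) <- "hog_pipeline"
  result
}

#' @export
print.hog_pipeline <- function(x, ...) {
  cat("hoglog pipeline result:",
      x$manifest$rows$burst_summary, "bursts,",
      x$manifest$rows$areas, "nightly areas,",
      x$manifest$rows$spells, "nest spells\n")
  print(x$changes)
  invisible(x)
}

#' Validate pipeline input tables
#'
#' Diagnostics-only checks of the standard input tables: required columns,
#' per-individual timestamp monotonicity, duplicate nest checks, and
#' twilight coverage of the burst dates. Never errors; returns one row per
#' finding.
#'
#' @param tables named list with any of `bursts`, `burst_summary`, `gps`,
#'   `nests`, `twilight`.
#' @param tz study-local timezone.
#' @return tibble: `table`, `check`, `status` (`"ok"`/`"error"`), `detail`.
#' @export
validate_inputs <- function(tables, tz = .hog_tz) {
  out <- list()
  add <- function(tbl, check, ok, detail = "") {
    out[[length(out) + 1]] <<- tibble::tibble(
      table = tbl, check = check, status = if (ok) "ok" else "error",
      detail = detail
    )
  }
  schemas <- list(
    bursts = c("individual_id", "burst_id", "timestamp", "sample_idx",
               "ax_g", "ay_g", "az_g"),
    burst_summary = c("individual_id", "burst_id", "timestamp", "asd"),
    gps = c("individual_id", "timestamp", "x_m", "y_m"),
    nests = c("individual_id", "sex", "date", "nest_id"),
    twilight = c("date", "civil_dawn", "civil_dusk")
  )
  for (nm in names(tables)) {
    tb <- tables[[nm]]
    if (nm %in% names(schemas)) {
      miss <- setdiff(schemas[[nm]], names(tb))
      extra_axes <- grep("^a[a-z]_g$", names(tb), value = TRUE)
      add(nm, "schema", length(miss) == 0,
          if (length(miss) > 0) paste("missing:", paste(miss, collapse = ", ")) else "")
      if (nm == "bursts" && length(setdiff(extra_axes, c("ax_g", "ay_g", "az_g"))) > 0) {
        add(nm, "axes", FALSE,
            paste("unexpected axis columns:",
                  paste(setdiff(extra_axes, c("ax_g", "ay_g", "az_g")),
                        collapse = ", ")))
      }
    }
    if ("timestamp" %in% names(tb) && "individual_id" %in% names(tb) &&
        nrow(tb) > 1) {
      mono <- all(tapply(as.numeric(tb$timestamp), tb$individual_id,
                         function(v) !is.unsorted(v)))
      add(nm, "timestamp_monotone", mono,
          if (!mono) "timestamps not sorted within individual" else "")
    }
  }
  if (!is.null(tables$nests)) {
    dup <- tables$nests %>%
      dplyr::count(.data$individual_id, .data$date) %>%
      dplyr::filter(.data$n > 1)
    add("nests", "duplicates", nrow(dup) == 0,
        if (nrow(dup) > 0) {
          paste("duplicated checks:",
                paste(sprintf("%s %s", dup$individual_id, dup$date),
                      collapse = "; "))
        } else "")
  }
  src <- if (!is.null(tables$burst_summary)) tables$burst_summary else tables$bursts
  if (!is.null(tables$twilight) && !is.null(src)) {
    dts <- unique(as.Date(src$timestamp, tz = tz))
    cov <- all(dts %in% tables$twilight$date)
    add("twilight", "coverage", cov,
        if (!cov) sprintf("%d burst date(s) missing from twilight table",
                          sum(!dts %in% tables$twilight$date)) else "")
  }
  dplyr::bind_rows(out)
}
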