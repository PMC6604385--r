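# integrate_report: joins the exposure, location, lung-function and
# wristband streams into one record per participant-day, and computes the
# study-level compliance table, location-variable correlation matrix and
# activity-log summaries.

#' Build participant-day records
#'
#' Joins all study streams into one row per participant and local day:
#' time-weighted daily exposures from the GPS trace (the exposure day is the
#' wristband wear interval when a band exists and `cfg$day_alignment` is
#' `"wristband"`, otherwise the local calendar day), chronic concentrations
#' at the residence, per-slot best FEV1 and percent-predicted values, and
#' wristband detection counts (missing for non-compliant bands).
#'
#' @param study An `elf_study` bundle from [read_study_bundle()] or
#'   [generate_study()].
#' @param cfg An `elf_config`.
#' @return List with `records` (tibble, one row per participant-day),
#'   `band_values` (long tibble of corrected analyte values for compliant
#'   bands), `spiro_qc` and `bands_qc` (the per-session / per-band QC
#'   tables).
#' @export
build_daily_records <- function(study, cfg = study_config()) {
  bands_qc <- qc_wristbands(study$wristbands, cfg)
  check_band_overlap(bands_qc)
  spiro_qc <- qc_spirometry(study$spirometry, cfg)
  analytes <- process_analytes(study$analytes, study$qc$blanks, cfg)

  participants <- study$participants
  gps_days <- study$gps |>
    dplyr::mutate(day = as.Date(.data$t, tz = cfg$tz)) |>
    dplyr::distinct(.data$participant_id, .data$day)
  all_days <- dplyr::bind_rows(
    gps_days,
    spiro_qc[c("participant_id", "day")],
    bands_qc[c("participant_id", "day")]
  ) |>
    dplyr::filter(!is.na(.data$day)) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$participant_id, .data$day)

  det <- analytes |>
    dplyr::group_by(.data$band_id) |>
    dplyr::summarise(band_detections = sum(.data$detected), .groups = "drop")

  rec_rows <- vector("list", nrow(all_days))
  for (i in seq_len(nrow(all_days))) {
    pid <- all_days$participant_id[i]
    day <- all_days$day[i]
    prof <- participants[participants$participant_id == pid, ]
    band <- bands_qc[bands_qc$participant_id == pid & !is.na(bands_qc$day) &
                     bands_qc$day == day, ]
    window <- day_window(day, band, cfg)
    trace <- study$gps[study$gps$participant_id == pid &
                       study$gps$t >= window[1] & study$gps$t < window[2], ]
    exp_row <- daily_exposure(trace, study$env, cfg, day = day)

    slots <- lapply(SPIRO_SLOTS, function(sl) {
      s <- spiro_qc[spiro_qc$participant_id == pid & spiro_qc$day == day &
                    spiro_qc$slot == sl, ]
      bf <- if (nrow(s) == 1L) s$best_fev1 else NA_real_
      pp <- if (!is.na(bf) && nrow(prof) == 1L) {
        percent_predicted(bf, hankinson_fev1_pred(prof$age, prof$sex,
                                                  prof$height_cm,
                                                  prof$ethnicity_group))
      } else NA_real_
      stats::setNames(list(bf, pp), paste0(c("best_fev1_", "pct_pred_"), sl))
    })

    band_id <- if (nrow(band) == 1L) band$band_id else NA_character_
    band_ok <- if (nrow(band) == 1L) band$compliant else NA
    nd <- if (nrow(band) == 1L && band$compliant) {
      det$band_detections[match(band$band_id, det$band_id)]
    } else NA_integer_

    chron_no2 <- chron_pm <- NA_real_
    if (nrow(prof) == 1L) {
      chron_no2 <- suppressWarnings(
        chronic_at_residence(prof$home_lon, prof$home_lat, study$env$chronic_no2))
      chron_pm <- suppressWarnings(
        chronic_at_residence(prof$home_lon, prof$home_lat, study$env$chronic_pm25))
    }

    rec_rows[[i]] <- tibble::as_tibble(c(
      list(participant_id = pid, day = day),
      as.list(exp_row),
      list(chronic_no2 = chron_no2, chronic_pm25 = chron_pm),
      do.call(c, slots),
      list(band_id = band_id, band_compliant = band_ok,
           band_detections = nd)
    ))
  }
  records <- dplyr::bind_rows(rec_rows)

  band_values <- analytes |>
    dplyr::inner_join(bands_qc[c("band_id", "participant_id", "day", "compliant")],
                      by = "band_id") |>
    dplyr::filter(.data$compliant) |>
    dplyr::select("participant_id", "day", "analyte", "value", "detected")

  list(records = records, band_values = band_values,
       spiro_qc = spiro_qc, bands_qc = bands_qc)
}

day_window <- function(day, band, cfg) {
  w <- if (cfg$day_alignment == "wristband" && nrow(band) == 1L &&
           !is.na(band$t_on) && !is.na(band$t_off)) {
    c(band$t_on, band$t_off)
  } else {
    start <- as.POSIXct(paste(day, "00:00:00"), tz = cfg$tz)
    c(start, start + 86400)
  }
  attr(w, "tzone") <- "UTC" # instants are tz-free; keep comparisons quiet
  w
}

check_band_overlap <- function(bands) {
  comp <- bands[!is.na(bands$t_on) & !is.na(bands$t_off), ]
  for (pid in unique(comp$participant_id)) {
    b <- comp[comp$participant_id == pid, ]
    b <- b[order(b$t_on), ]
    if (nrow(b) > 1L && any(b$t_on[-1] < b$t_off[-nrow(b)])) {
      stop("overlapping wristband wear intervals for participant ", pid,
           call. = FALSE)
    }
  }
  invisible(bands)
}

#' Study-level compliance table
#'
#' For each protocol metric, the share of expected items satisfied:
#' wristbands returned, returned wristbands compliant with the wear
#' protocol, spirometry sessions performed (three per day), performed
#' sessions in triplicate, sessions meeting the full validity criteria, and
#' activity logs filled out daily. Raw fractions are retained alongside the
#' rounded display percent.
#'
#' @param study An `elf_study`.
#' @param bands_qc,spiro_qc QC tables from [build_daily_records()] (computed
#'   if omitted).
#' @param expectations List with `n_participants`, `n_days` and
#'   `sessions_per_day` (defaults: cohort size, distinct band days, 3).
#' @param cfg An `elf_config`.
#' @return Tibble with `metric`, `numerator`, `denominator`, `fraction`,
#'   `percent`, `percent_display`.
#' @export
compliance_table <- function(study, bands_qc = NULL, spiro_qc = NULL,
                             expectations = NULL, cfg = study_config()) {
  if (is.null(bands_qc)) bands_qc <- qc_wristbands(study$wristbands, cfg)
  if (is.null(spiro_qc)) spiro_qc <- qc_spirometry(study$spirometry, cfg)
  n_part <- expectations$n_participants %||%
    length(unique(study$participants$participant_id))
  # study length: one deployed band per participant-day (robust to wear-time
  # drift across calendar dates)
  n_days <- expectations$n_days %||% max(1L, round(nrow(bands_qc) / n_part))
  spd <- expectations$sessions_per_day %||% 3L
  if (n_part <= 0 || n_days <= 0 || spd <= 0) {
    stop("expectations must be positive", call. = FALSE)
  }

  returned <- if ("returned" %in% names(bands_qc)) {
    sum(bands_qc$returned)
  } else {
    nrow(bands_qc)
  }
  bands_in <- if ("returned" %in% names(bands_qc)) {
    bands_qc[bands_qc$returned, ]
  } else bands_qc

  n_sessions_expected <- n_part * n_days * spd
  performed <- nrow(spiro_qc)
  act_days <- study$activity |>
    dplyr::filter(!is.na(.data$response)) |>
    dplyr::distinct(.data$participant_id, .data$day) |>
    nrow()

  metric_row <- function(metric, num, den) {
    tibble::tibble(metric = metric, numerator = num, denominator = den,
                   fraction = ifelse(den > 0, num / den, NA_real_),
                   percent = ifelse(den > 0, 100 * num / den, NA_real_),
                   percent_display = round(ifelse(den > 0, 100 * num / den,
                                                  NA_real_)))
  }
  dplyr::bind_rows(
    metric_row("wristbands_returned", returned, n_part * n_days),
    metric_row("wristbands_compliant", sum(bands_in$compliant), nrow(bands_in)),
    metric_row("spiro_sessions_performed", performed, n_sessions_expected),
    metric_row("spiro_sessions_triplicate", sum(spiro_qc$triplicate_ok), performed),
    metric_row("spiro_sessions_valid", sum(spiro_qc$valid), performed),
    metric_row("activity_log_days", act_days, n_part * n_days)
  )
}

#' Correlation matrix of daily location variables
#'
#' Pairwise-complete Pearson correlations over participant-day rows, with a
#' display ordering from average-linkage hierarchical clustering on `1 - r`
#' so blocks of same-sign correlation sit together. Variables with zero
#' variance are dropped with a warning.
#'
#' @param daily Tibble of numeric location variables, one row per
#'   participant-day (id columns are ignored).
#' @param vars Optional character vector restricting the variables.
#' @return List with `matrix` (symmetric, unit diagonal, rows/cols in
#'   display order), `order` (variable names) and `dropped`.
#' @export
correlation_matrix <- function(daily, vars = NULL) {
  num <- daily[vapply(daily, is.numeric, logical(1))]
  if (!is.null(vars)) num <- num[intersect(vars, names(num))]
  if (nrow(num) < 3L) stop("need at least 3 participant-day rows", call. = FALSE)
  sds <- vapply(num, stats::sd, numeric(1), na.rm = TRUE)
  dropped <- names(num)[is.na(sds) | sds == 0]
  if (length(dropped)) {
    warning("dropping zero-variance variable(s): ", paste(dropped, collapse = ", "))
    num <- num[setdiff(names(num), dropped)]
  }
  r <- stats::cor(as.matrix(num), use = "pairwise.complete.obs")
  diag(r) <- 1
  ord <- if (ncol(r) > 2L) {
    d <- stats::as.dist(1 - r)
    d[is.na(d)] <- 2
    stats::hclust(d, method = "average")$order
  } else {
    seq_len(ncol(r))
  }
  list(matrix = r[ord, ord, drop = FALSE], order = colnames(r)[ord],
       dropped = dropped)
}

#' Summarise the daily activity log
#'
#' Per-source share of participant-days reporting exposure, and the mean
#' number of reported sources per participant-day.
#'
#' @param logs Activity-log tibble (`participant_id`, `day`, `source`,
#'   `response` in yes/no/missing).
#' @return List with `per_source` (source, n_yes, n_days, proportion) and
#'   `mean_sources_per_day`.
#' @export
summarize_activity <- function(logs) {
  bad <- !(logs$response %in% c("yes", "no")) & !is.na(logs$response)
  if (any(bad)) {
    stop("activity response must be yes/no/missing; got '",
         logs$response[bad][1], "'", call. = FALSE)
  }
  per_source <- logs |>
    dplyr::group_by(.data$source) |>
    dplyr::summarise(n_yes = sum(.data$response == "yes", na.rm = TRUE),
                     n_days = sum(!is.na(.data$response)),
                     proportion = ifelse(.data$n_days > 0,
                                         .data$n_yes / .data$n_days, NA_real_),
                     .groups = "drop")
  per_day <- logs |>
    dplyr::group_by(.data$participant_id, .data$day) |>
    dplyr::summarise(n_yes = sum(.data$response == "yes", na.rm = TRUE),
                     .groups = "drop")
  list(per_source = per_source,
       mean_sources_per_day = mean(per_day$n_yes))
}
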