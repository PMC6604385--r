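# wristband: compliance filtering against the wear protocol, half-LOD
# nondetect substitution, background (blank) and surrogate-recovery
# correction, CCV batch QC, and detection summaries.

#' Wristband compliance check
#'
#' A band is compliant when all protocol rules hold: wear duration within the
#' nominal window (24 h +/- 8 h by default, bounds inclusive), both on and
#' off timestamps recorded, worn singly, and returned in an air-tight seal.
#' Reason codes enumerate every failed rule.
#'
#' @param t_on,t_off POSIXct wear timestamps (`t_off` may be `NA`).
#' @param sealed,worn_singly Logicals from the return protocol.
#' @param cfg An `elf_config`.
#' @return List with `compliant` (logical) and `reasons` (character vector,
#'   empty iff compliant; codes `missing-times`, `wear-window`,
#'   `not-worn-singly`, `not-sealed`).
#' @export
check_compliance <- function(t_on, t_off, sealed, worn_singly,
                             cfg = study_config()) {
  reasons <- character(0)
  if (is.na(t_on) || is.na(t_off)) {
    reasons <- c(reasons, "missing-times")
  } else {
    wear_h <- as.numeric(difftime(t_off, t_on, units = "hours"))
    lo <- cfg$wear_nominal_h - cfg$wear_tol_h
    hi <- cfg$wear_nominal_h + cfg$wear_tol_h
    if (wear_h < lo || wear_h > hi) reasons <- c(reasons, "wear-window")
  }
  if (!isTRUE(worn_singly)) reasons <- c(reasons, "not-worn-singly")
  if (!isTRUE(sealed)) reasons <- c(reasons, "not-sealed")
  list(compliant = length(reasons) == 0L, reasons = reasons)
}

#' Substitute nondetects at half the LOD
#'
#' Results below the instrumental limit of detection (nondetect marker `"ND"`
#' or a numeric value strictly below the LOD) are assigned one-half the LOD
#' and flagged; detected values pass through unchanged. A value exactly at
#' the LOD is a detection.
#'
#' @param results Tibble with columns `analyte`, `raw` (character: number or
#'   `"ND"`), `lod`.
#' @return `results` with numeric `value` and logical `substituted`,
#'   `detected` columns added.
#' @export
substitute_nondetects <- function(results) {
  if (any(is.na(results$lod))) {
    stop("missing LOD for analyte '",
         results$analyte[which(is.na(results$lod))[1]], "'", call. = FALSE)
  }
  num <- suppressWarnings(as.numeric(results$raw))
  nd <- results$raw == "ND" | (!is.na(num) & num < results$lod)
  results$detected <- !nd
  results$value <- ifelse(nd, results$lod / 2, num)
  results$substituted <- nd
  results
}

#' Background (blank) correction
#'
#' Subtracts the batch blank level (mean of detected blank values for the
#' analyte; median optional via config) from a detected value, floored at 0.
#' If the corrected value falls below the LOD it is re-flagged as a nondetect
#' and re-substituted at half the LOD. Analytes with no detected blank values
#' are unchanged.
#'
#' @param value Numeric concentration (ng/wristband), already substituted.
#' @param analyte Analyte name.
#' @param lod The analyte's LOD.
#' @param blanks Tibble of blank results (`analyte`, `raw`, `lod`).
#' @param statistic `"mean"` or `"median"` of detected blank values.
#' @return List with `value` and `substituted` (TRUE when re-substituted).
#' @export
blank_correct <- function(value, analyte, lod, blanks,
                          statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  bl <- blanks[blanks$analyte == analyte, , drop = FALSE]
  if (nrow(bl)) {
    bl <- substitute_nondetects(bl)
    bl <- bl[bl$detected, , drop = FALSE]
  }
  if (nrow(bl) == 0L) return(list(value = value, substituted = FALSE))
  level <- if (statistic == "mean") mean(bl$value) else stats::median(bl$value)
  corrected <- max(value - level, 0)
  if (corrected < lod) {
    list(value = lod / 2, substituted = TRUE)
  } else {
    list(value = corrected, substituted = FALSE)
  }
}

#' Surrogate-recovery correction
#'
#' Divides a concentration by the band's surrogate recovery fraction,
#' correcting for extraction losses.
#'
#' @param value Concentration (ng/wristband).
#' @param recovery Recovery fraction, must be positive.
#' @return Corrected concentration.
#' @export
surrogate_correct <- function(value, recovery) {
  if (any(is.na(recovery)) || any(recovery <= 0)) {
    stop("surrogate recovery must be positive", call. = FALSE)
  }
  value / recovery
}

#' Continuing calibration verification check
#'
#' A CCV batch passes when at least `ccv_frac` (80% by default) of its
#' analytes are measured within `ccv_tol` (20%) of the true concentration.
#'
#' @param measured,true Numeric vectors of measured and true concentrations.
#' @param cfg An `elf_config`.
#' @return List with `fraction_within` and `pass`.
#' @export
ccv_pass <- function(measured, true, cfg = study_config()) {
  if (length(measured) == 0L) stop("empty CCV batch", call. = FALSE)
  if (any(true <= 0)) stop("CCV true concentration must be positive", call. = FALSE)
  within <- abs(measured - true) <= cfg$ccv_tol * true
  fraction <- mean(within)
  list(fraction_within = fraction, pass = fraction >= cfg$ccv_frac)
}

#' Run the full analyte correction pipeline for a study
#'
#' Per band and analyte: half-LOD substitution of nondetects, blank
#' (background) subtraction of detected values with re-substitution when the
#' corrected value drops below the LOD, then surrogate-recovery division.
#' Detection status is decided on the raw value against the LOD and is
#' unaffected by the corrections. The pipeline is idempotent: re-running it
#' on its own output changes nothing.
#'
#' @param analytes Long tibble (`band_id`, `analyte`, `raw`, `lod`,
#'   `recovery`).
#' @param blanks Tibble of batch blanks (`analyte`, `raw`, `lod`).
#' @param cfg An `elf_config` (supplies the blank statistic).
#' @return `analytes` with `value`, `detected`, `substituted` columns.
#' @export
process_analytes <- function(analytes, blanks, cfg = study_config()) {
  res <- substitute_nondetects(analytes)
  # batch blank levels, one per analyte
  blank_level <- numeric(0)
  if (!is.null(blanks) && nrow(blanks)) {
    bl <- substitute_nondetects(blanks)
    bl <- bl[bl$detected, , drop = FALSE]
    if (nrow(bl)) {
      agg <- bl |>
        dplyr::group_by(.data$analyte) |>
        dplyr::summarise(level = if (cfg$blank_statistic == "mean") {
          mean(.data$value)
        } else {
          stats::median(.data$value)
        }, .groups = "drop")
      blank_level <- stats::setNames(agg$level, agg$analyte)
    }
  }
  lvl <- blank_level[res$analyte]
  lvl[is.na(lvl)] <- 0
  corrected <- pmax(res$value - ifelse(res$detected, lvl, 0), 0)
  resub <- res$detected & corrected < res$lod
  res$value <- ifelse(resub, res$lod / 2, corrected)
  res$substituted <- res$substituted | resub
  res$value <- surrogate_correct(res$value, res$recovery)
  res
}

#' Detection summaries across a cohort of wristbands
#'
#' Computes per-band detection counts, per-analyte detection frequency and
#' median concentration (over all bands, half-LOD substitutions included),
#' and the participant-day x analyte concentration matrix on a log10 scale
#' (missing where the band was non-compliant or the analyte undetected).
#'
#' @param analytes Processed analyte tibble from [process_analytes()].
#' @param bands Wristband metadata with `band_id`, `participant_id`, `day`
#'   and logical `compliant`.
#' @return List with `per_band` (band_id, detections), `per_analyte`
#'   (analyte, detection_frequency, median_value), and `log_matrix`
#'   (rows participant-day, columns analytes).
#' @export
summarize_detections <- function(analytes, bands) {
  per_band <- analytes |>
    dplyr::group_by(.data$band_id) |>
    dplyr::summarise(detections = sum(.data$detected), .groups = "drop")
  per_analyte <- analytes |>
    dplyr::group_by(.data$analyte) |>
    dplyr::summarise(detection_frequency = mean(.data$detected),
                     median_value = stats::median(.data$value),
                     .groups = "drop")
  compliant <- bands[bands$compliant, , drop = FALSE]
  wide <- analytes |>
    dplyr::filter(.data$band_id %in% compliant$band_id, .data$detected) |>
    dplyr::left_join(compliant[c("band_id", "participant_id", "day")],
                     by = "band_id") |>
    dplyr::mutate(row = paste(.data$participant_id, .data$day, sep = "_"),
                  logv = log10(.data$value))
  rows <- sort(unique(paste(compliant$participant_id, compliant$day, sep = "_")))
  cols <- sort(unique(analytes$analyte))
  m <- matrix(NA_real_, nrow = length(rows), ncol = length(cols),
              dimnames = list(rows, cols))
  if (nrow(wide)) m[cbind(match(wide$row, rows), match(wide$analyte, cols))] <- wide$logv
  list(per_band = per_band, per_analyte = per_analyte, log_matrix = m)
}

#' Compliance report for all wristbands of a study
#'
#' Applies [check_compliance()] to each band and attaches the local wear day
#' (date of `t_on` in the study time zone).
#'
#' @param wristbands Tibble as read by [read_study_bundle()].
#' @param cfg An `elf_config`.
#' @return `wristbands` with `day`, `compliant` and `reasons` (character,
#'   `;`-separated) columns.
#' @export
qc_wristbands <- function(wristbands, cfg = study_config()) {
  res <- lapply(seq_len(nrow(wristbands)), function(i) {
    check_compliance(wristbands$t_on[i], wristbands$t_off[i],
                     wristbands$sealed[i], wristbands$worn_singly[i], cfg)
  })
  wristbands$day <- as.Date(wristbands$t_on, tz = cfg$tz)
  wristbands$compliant <- vapply(res, `[[`, logical(1), "compliant")
  wristbands$reasons <- vapply(res, function(r) paste(r$reasons, collapse = ";"),
                               character(1))
  wristbands
}
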