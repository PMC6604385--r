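# spirometry: blow- and session-level quality control following ATS-style
# rules (minimum 6 s blow, FEV1/FVC < 1.00, 0.150 L repeatability of the two
# largest values, triplicate sessions), 3 L-syringe calibration checks, and
# percent-predicted FEV1 against NHANES III reference equations.

#' Verify spirometer calibration against a known syringe volume
#'
#' Two rules are evaluated on three repeated controlled-volume measurements:
#' the absolute rule (every measurement within +/- `cal_tol_l` of the syringe
#' volume, i.e. 2.85-3.15 L for a 3 L syringe) and the percent rule (within
#' `cal_tol_pct` percent). Both results are reported; the overall pass
#' follows the absolute rule.
#'
#' @param measured_volumes Numeric vector of exactly 3 measured volumes (L).
#' @param true_volume_l Syringe volume (default 3.0 L).
#' @param cfg An `elf_config` supplying `cal_tol_l` and `cal_tol_pct`.
#' @return List with `abs_pass`, `pct_pass`, `overall` (logicals) and the
#'   absolute interval bounds `lower`/`upper`.
#' @export
check_calibration <- function(measured_volumes, true_volume_l = 3.0,
                              cfg = study_config()) {
  if (length(measured_volumes) != 3L) {
    stop("calibration requires exactly 3 measurements", call. = FALSE)
  }
  lower <- true_volume_l - cfg$cal_tol_l
  upper <- true_volume_l + cfg$cal_tol_l
  abs_pass <- all(measured_volumes >= lower & measured_volumes <= upper)
  rel <- abs(measured_volumes - true_volume_l) / true_volume_l
  pct_pass <- all(rel <= cfg$cal_tol_pct / 100)
  list(abs_pass = abs_pass, pct_pass = pct_pass, overall = abs_pass,
       lower = lower, upper = upper)
}

#' Per-blow quality flags
#'
#' `duration_ok` requires at least `min_blow_s` seconds of exhalation
#' (inclusive bound: the test completes when 6 s have passed); `ratio_ok`
#' requires a positive FVC and FEV1/FVC strictly below 1.00.
#'
#' @param fev1,fvc Litres.
#' @param duration Seconds.
#' @param cfg An `elf_config`.
#' @return List with logicals `duration_ok` and `ratio_ok`.
#' @export
validate_blow <- function(fev1, fvc, duration, cfg = study_config()) {
  list(duration_ok = duration >= cfg$min_blow_s,
       ratio_ok = !is.na(fvc) && fvc > 0 && fev1 / fvc < 1.00)
}

#' Session-level quality flags
#'
#' A session is valid when it holds at least three blows (`triplicate_ok`),
#' the two largest FEV1 values agree within `repeatability_l` (inclusive;
#' likewise FVC), and the blows contributing those two largest FEV1 values
#' each pass the per-blow duration and ratio checks.
#'
#' @param blows Tibble with columns `fev1_l`, `fvc_l`, `duration_s` (one row
#'   per blow of one session).
#' @param cfg An `elf_config`.
#' @return List of class `qc_flags`: `triplicate_ok`, `repeatable_fev1`,
#'   `repeatable_fvc`, `duration_ok`, `ratio_ok`, `valid`.
#' @export
validate_session <- function(blows, cfg = study_config()) {
  n <- nrow(blows)
  triplicate_ok <- n >= 3L
  top2 <- function(x) sort(x, decreasing = TRUE)[1:2]
  if (n >= 2L) {
    f2 <- top2(blows$fev1_l)
    v2 <- top2(blows$fvc_l)
    repeatable_fev1 <- (f2[1] - f2[2]) <= cfg$repeatability_l
    repeatable_fvc <- (v2[1] - v2[2]) <= cfg$repeatability_l
    contributing <- order(blows$fev1_l, decreasing = TRUE)[1:2]
    per_blow <- lapply(contributing, function(i) {
      validate_blow(blows$fev1_l[i], blows$fvc_l[i], blows$duration_s[i], cfg)
    })
    duration_ok <- all(vapply(per_blow, `[[`, logical(1), "duration_ok"))
    ratio_ok <- all(vapply(per_blow, `[[`, logical(1), "ratio_ok"))
  } else {
    repeatable_fev1 <- repeatable_fvc <- duration_ok <- ratio_ok <- FALSE
  }
  flags <- list(triplicate_ok = triplicate_ok,
                repeatable_fev1 = repeatable_fev1,
                repeatable_fvc = repeatable_fvc,
                duration_ok = duration_ok, ratio_ok = ratio_ok)
  flags$valid <- all(unlist(flags))
  class(flags) <- "qc_flags"
  flags
}

#' Best FEV1 of a session
#'
#' The largest FEV1 over the session's blows if the session passed QC, else
#' missing.
#'
#' @param blows Tibble of the session's blows (`fev1_l`, `fvc_l`,
#'   `duration_s`).
#' @param flags Result of [validate_session()]; computed if omitted.
#' @param cfg An `elf_config`.
#' @return Litres, or `NA_real_` for an invalid session.
#' @export
best_fev1 <- function(blows, flags = NULL, cfg = study_config()) {
  if (is.null(flags)) flags <- validate_session(blows, cfg)
  if (!isTRUE(flags$valid) || nrow(blows) == 0L) return(NA_real_)
  max(blows$fev1_l)
}

# NHANES III reference coefficients for predicted FEV1 (L):
#   FEV1 = b0 + b1*age + b2*age^2 + bh2*height_cm^2,
# by sex, ethnicity group and age band (males split at 20 y, females at 18 y).
# Embedded as a versioned data table; consumers should treat the values as
# data, not API.
HANKINSON_FEV1 <- tibble::tribble(
  ~sex,     ~ethnicity_group,   ~age_band, ~b0,     ~b1,      ~b2,        ~bh2,
  "male",   "caucasian",        "youth",  -0.7453, -0.04106,  0.004477,  0.00014098,
  "male",   "caucasian",        "adult",   0.5536, -0.01303, -0.000172,  0.00014098,
  "female", "caucasian",        "youth",  -0.8710,  0.06537,  0.000000,  0.00011496,
  "female", "caucasian",        "adult",   0.4333, -0.00361, -0.000194,  0.00011496,
  "male",   "african_american", "youth",  -0.7048, -0.05711,  0.004316,  0.00013194,
  "male",   "african_american", "adult",   0.3411, -0.02309,  0.000000,  0.00013194,
  "female", "african_american", "youth",  -0.9630,  0.05799,  0.000000,  0.00010846,
  "female", "african_american", "adult",   0.3433, -0.01111, -0.000109,  0.00010846,
  "male",   "mexican_american", "youth",  -0.8218, -0.04248,  0.004291,  0.00015104,
  "male",   "mexican_american", "adult",   0.6306, -0.02928,  0.000000,  0.00015104,
  "female", "mexican_american", "youth",  -0.9641,  0.06490,  0.000000,  0.00012154,
  "female", "mexican_american", "adult",   0.4529, -0.01178, -0.000113,  0.00012154
)

#' NHANES III FEV1 reference coefficient table
#'
#' The embedded coefficient table used by [hankinson_fev1_pred()]: one row
#' per sex x ethnicity group x age band with intercept, age, age-squared and
#' height-squared terms.
#'
#' @return A tibble of coefficients.
#' @export
hankinson_coefficients <- function() HANKINSON_FEV1

#' Predicted FEV1 from demographic reference equations
#'
#' Evaluates the NHANES III reference polynomial
#' `b0 + b1*age + b2*age^2 + bh2*height^2` for the profile's sex, ethnicity
#' group and age band (males split at 20 years, females at 18).
#'
#' @param age Years (> 0).
#' @param sex `"male"` or `"female"`.
#' @param height_cm Standing height in cm.
#' @param ethnicity_group One of the groups in [hankinson_coefficients()].
#' @return Predicted FEV1 in litres.
#' @export
hankinson_fev1_pred <- function(age, sex, height_cm, ethnicity_group) {
  groups <- unique(HANKINSON_FEV1$ethnicity_group)
  if (!ethnicity_group %in% groups) {
    stop("unknown ethnicity_group '", ethnicity_group, "'; supported groups: ",
         paste(groups, collapse = ", "), call. = FALSE)
  }
  split_age <- if (sex == "male") 20 else 18
  band <- if (age < split_age) "youth" else "adult"
  row <- HANKINSON_FEV1[HANKINSON_FEV1$sex == sex &
                        HANKINSON_FEV1$ethnicity_group == ethnicity_group &
                        HANKINSON_FEV1$age_band == band, ]
  if (nrow(row) != 1L) stop("unknown sex '", sex, "'", call. = FALSE)
  row$b0 + row$b1 * age + row$b2 * age^2 + row$bh2 * height_cm^2
}

#' Percent-predicted FEV1
#'
#' `100 * measured / predicted`; the standard normalisation that makes lung
#' function comparable across people of different sex, age, height and
#' ethnicity.
#'
#' @param fev1_test Measured FEV1 (L).
#' @param fev1_pred Predicted FEV1 (L), must be positive.
#' @return Percent of predicted.
#' @export
percent_predicted <- function(fev1_test, fev1_pred) {
  if (any(is.na(fev1_pred)) || any(fev1_pred <= 0)) {
    stop("predicted FEV1 must be positive", call. = FALSE)
  }
  100 * fev1_test / fev1_pred
}

#' Session-level QC report for a spirometry table
#'
#' Groups the long blow table into sessions (participant x local day x slot),
#' applies [validate_session()] and [best_fev1()] to each, and returns one
#' row per session with all QC flags.
#'
#' @param spirometry Long tibble as read by [read_study_bundle()]
#'   (`participant_id`, `slot`, `blow_index`, `fev1_l`, `fvc_l`, `pef_lmin`,
#'   `duration_s`, `t`).
#' @param cfg An `elf_config`; its `tz` defines the local day.
#' @return Tibble with one row per session: ids, day, slot, `n_blows`, the
#'   five QC flags, `valid` and `best_fev1`.
#' @export
qc_spirometry <- function(spirometry, cfg = study_config()) {
  spirometry |>
    dplyr::mutate(day = as.Date(.data$t, tz = cfg$tz)) |>
    dplyr::group_by(.data$participant_id, .data$day, .data$slot) |>
    dplyr::group_modify(function(blows, key) {
      fl <- validate_session(blows, cfg)
      tibble::tibble(
        n_blows = nrow(blows),
        triplicate_ok = fl$triplicate_ok,
        repeatable_fev1 = fl$repeatable_fev1,
        repeatable_fvc = fl$repeatable_fvc,
        duration_ok = fl$duration_ok,
        ratio_ok = fl$ratio_ok,
        valid = fl$valid,
        best_fev1 = best_fev1(blows, fl, cfg)
      )
    }) |>
    dplyr::ungroup()
}
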