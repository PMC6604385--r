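#' Study configuration
#'
#' Bundles every tunable constant of the pipeline: GPS gap handling, IDW
#' exponent and distance floor, buffer radii, wristband wear window,
#' spirometry QC thresholds, wristband batch-QC rules and the smoke density
#' class-to-concentration map. Defaults follow the study protocol constants:
#' a 100 m road buffer, a 250 m NDVI buffer, a 24 h +/- 8 h wear window,
#' 0.150 L FEV1/FVC repeatability, a +/- 0.15 L (and 2.5%) 3 L-syringe
#' calibration check, 6 s minimum blow, the CCV 80%-within-20% rule and smoke
#' densities low/medium/high = 5/16/17 ug/m3.
#'
#' @param max_gap_s Longest GPS inter-fix interval (s) still counted as
#'   observed time; longer gaps are treated as unobserved.
#' @param idw_power Exponent of the inverse-distance weighting of point-source
#'   emissions.
#' @param idw_floor_m Distance floor (m) that keeps the IDW term finite when a
#'   fix sits on a source.
#' @param idw_normalized If `TRUE`, divide the IDW sum by the sum of inverse
#'   distances (normalized variant); default is the plain weighted sum.
#' @param road_radius_m Buffer radius for road length (m).
#' @param ndvi_radius_m Buffer radius for NDVI-by-land-class sums (m).
#' @param wear_nominal_h,wear_tol_h Nominal wristband wear duration and
#'   tolerance (h); the compliance window is nominal +/- tolerance, inclusive.
#' @param repeatability_l FEV1/FVC repeatability threshold (L) between the two
#'   largest values of a session.
#' @param cal_tol_l Absolute calibration tolerance (L) around the syringe
#'   volume.
#' @param cal_tol_pct Percent calibration tolerance around the syringe volume.
#' @param min_blow_s Minimum blow duration (s) for a valid test.
#' @param ccv_frac Minimum fraction of CCV analytes that must be within
#'   tolerance.
#' @param ccv_tol Relative CCV tolerance around the true concentration.
#' @param smoke_map Named numeric vector mapping smoke density classes
#'   (exactly `low`, `medium`, `high`) to concentrations (ug/m3).
#' @param smoke_max_dist_m Maximum distance (m) at which the nearest smoke
#'   polygon is still assigned to a fix outside all polygons.
#' @param driving_speed_ms Speed threshold (m/s) above which an interval
#'   counts as driving.
#' @param blank_statistic Statistic of detected blank values used for
#'   background correction: `"mean"` (default) or `"median"`.
#' @param day_alignment `"wristband"` (exposure day = wear interval, default)
#'   or `"calendar"` (local calendar day).
#' @param fire_daily_stat Daily wildfire-distance summary: `"min"` (default)
#'   or `"mean"` (time-weighted). Both are always emitted; this picks the one
#'   reported in the `fire_km` column.
#' @param tz IANA time zone defining local day boundaries.
#' @param seed Root seed for the synthetic-data generator.
#' @return A list of class `elf_config`.
#' @export
study_config <- function(max_gap_s = 3600,
                         idw_power = 1,
                         idw_floor_m = 10,
                         idw_normalized = FALSE,
                         road_radius_m = 100,
                         ndvi_radius_m = 250,
                         wear_nominal_h = 24,
                         wear_tol_h = 8,
                         repeatability_l = 0.150,
                         cal_tol_l = 0.15,
                         cal_tol_pct = 2.5,
                         min_blow_s = 6,
                         ccv_frac = 0.80,
                         ccv_tol = 0.20,
                         smoke_map = c(low = 5, medium = 16, high = 17),
                         smoke_max_dist_m = 50000,
                         driving_speed_ms = 8,
                         blank_statistic = c("mean", "median"),
                         day_alignment = c("wristband", "calendar"),
                         fire_daily_stat = c("min", "mean"),
                         tz = "America/Los_Angeles",
                         seed = 1L) {
  cfg <- list(
    max_gap_s = max_gap_s, idw_power = idw_power, idw_floor_m = idw_floor_m,
    idw_normalized = idw_normalized, road_radius_m = road_radius_m,
    ndvi_radius_m = ndvi_radius_m, wear_nominal_h = wear_nominal_h,
    wear_tol_h = wear_tol_h, repeatability_l = repeatability_l,
    cal_tol_l = cal_tol_l, cal_tol_pct = cal_tol_pct, min_blow_s = min_blow_s,
    ccv_frac = ccv_frac, ccv_tol = ccv_tol, smoke_map = smoke_map,
    smoke_max_dist_m = smoke_max_dist_m, driving_speed_ms = driving_speed_ms,
    blank_statistic = match.arg(blank_statistic),
    day_alignment = match.arg(day_alignment),
    fire_daily_stat = match.arg(fire_daily_stat),
    tz = tz, seed = as.integer(seed)
  )
  class(cfg) <- "elf_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  pos <- c("max_gap_s", "idw_power", "idw_floor_m", "road_radius_m",
           "ndvi_radius_m", "wear_nominal_h", "wear_tol_h", "repeatability_l",
           "cal_tol_l", "cal_tol_pct", "min_blow_s", "ccv_frac", "ccv_tol",
           "driving_speed_ms")
  for (nm in pos) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || !is.finite(cfg[[nm]]) ||
        cfg[[nm]] <= 0) {
      stop("config field '", nm, "' must be a single positive number", call. = FALSE)
    }
  }
  if (!setequal(names(cfg$smoke_map), c("low", "medium", "high"))) {
    stop("smoke_map must have keys exactly {low, medium, high}", call. = FALSE)
  }
  invisible(cfg)
}

#' Read a study configuration from JSON
#'
#' Unknown keys are rejected; missing keys fall back to [study_config()]
#' defaults.
#'
#' @param path Path to a JSON file of configuration fields.
#' @return An `elf_config` list.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(study_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown config field(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(raw$smoke_map)) raw$smoke_map <- unlist(raw$smoke_map)
  do.call(study_config, raw)
}

#' Write a study configuration to JSON
#'
#' @param cfg An `elf_config` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$smoke_map <- as.list(out$smoke_map) # keep class names in the JSON object
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
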