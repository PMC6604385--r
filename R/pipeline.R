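# Study serialisation and end-to-end pipeline orchestration: the programmatic
# equivalents of the `elf simulate` and `elf run` command-line entry points.

fmt_utc <- function(t) {
  out <- format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  out[is.na(t)] <- ""
  out
}

#' Write a study bundle to disk
#'
#' Serialises an `elf_study` to the exact file set [read_study_bundle()]
#' reads (CSV tables, GeoJSON vector layers, ASCII-grid rasters) plus, when
#' the study carries generator ground truth, a `truth.json`.
#'
#' @param study An `elf_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)

  readr::write_csv(study$participants, p("participants.csv"), na = "")

  gps <- study$gps
  readr::write_csv(tibble::tibble(participant_id = gps$participant_id,
                                  timestamp = fmt_utc(gps$t),
                                  lat = gps$lat, lon = gps$lon),
                   p("gps.csv"))

  sp <- study$spirometry
  readr::write_csv(tibble::tibble(
    participant_id = sp$participant_id, slot = sp$slot,
    blow_index = sp$blow_index, fev1_l = sp$fev1_l, fvc_l = sp$fvc_l,
    pef_lmin = sp$pef_lmin, duration_s = sp$duration_s,
    timestamp = fmt_utc(sp$t)), p("spirometry.csv"))

  wb <- study$wristbands
  readr::write_csv(tibble::tibble(
    participant_id = wb$participant_id, band_id = wb$band_id,
    t_on = fmt_utc(wb$t_on), t_off = fmt_utc(wb$t_off),
    sealed = wb$sealed, worn_singly = wb$worn_singly,
    returned = if ("returned" %in% names(wb)) wb$returned else TRUE),
    p("wristbands.csv"), na = "")

  readr::write_csv(study$analytes, p("analytes.csv"))
  readr::write_csv(study$activity, p("activity_log.csv"), na = "")
  readr::write_csv(study$qc$blanks, p("qc_blanks.csv"))
  readr::write_csv(study$qc$ccvs, p("qc_ccvs.csv"))

  env <- study$env
  write_geojson_points(env$monitors, p("monitors.geojson"))
  ms <- env$monitor_series
  readr::write_csv(tibble::tibble(monitor_id = ms$monitor_id,
                                  timestamp = fmt_utc(ms$t), pm25 = ms$pm25),
                   p("monitors_hourly.csv"))
  write_geojson_points(env$sources, p("sources.geojson"))
  write_geojson_lines(env$roads, p("roads.geojson"))
  smoke <- env$smoke
  if (nrow(smoke)) smoke$day <- as.character(smoke$day)
  write_geojson_polygons(smoke, p("smoke.geojson"))
  fires <- env$fires
  if (nrow(fires)) fires$day <- as.character(fires$day)
  write_geojson_points(fires, p("fires.geojson"))

  write_ascii_grid(env$landcover, p("landcover.asc"))
  readr::write_csv(tibble::tibble(class = names(env$landcover$classes),
                                  code = as.integer(env$landcover$classes)),
                   p("landcover_classes.csv"))
  write_ascii_grid(env$ndvi, p("ndvi.asc"))
  write_ascii_grid(env$chronic_no2, p("chronic_no2.asc"))
  write_ascii_grid(env$chronic_pm25, p("chronic_pm25.asc"))

  if (!is.null(study$truth)) {
    jsonlite::write_json(study$truth, p("truth.json"), auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE,
                         Date = "ISO8601", POSIXt = "ISO8601", matrix = "rowmajor")
  }
  invisible(dir)
}

#' Simulate a synthetic study to disk
#'
#' Generates a complete seeded synthetic study and writes it as the file set
#' the pipeline reads, plus `truth.json` with the planted ground truth.
#' The same seed reproduces the files byte-for-byte.
#'
#' @param out_dir Output directory.
#' @param seed Root seed.
#' @param scfg An `elf_sim_config`.
#' @param cfg An `elf_config`.
#' @return The generated `elf_study`, invisibly.
#' @export
simulate_study <- function(out_dir, seed = 1L, scfg = sim_config(),
                           cfg = study_config(seed = seed)) {
  study <- generate_study(scfg, seed, cfg)
  write_study(study, out_dir)
  invisible(study)
}

LOCATION_VARS <- function(records) {
  c("pm25", "tri_idw", "road_m",
    grep("^ndvi_", names(records), value = TRUE),
    "smoke", "fire_km_min", "fire_km_mean", "driving_fraction",
    "chronic_no2", "chronic_pm25")
}

#' Run the full analysis pipeline
#'
#' Executes every stage on a study bundle: wristband compliance QC and
#' analyte correction, spirometry session QC with percent-predicted FEV1,
#' time-weighted daily exposure aggregation, participant-day record
#' assembly, the study compliance table, the location-variable correlation
#' matrix and the detection/activity summaries. Optionally writes all
#' outputs as CSV.
#'
#' @param study An `elf_study`, or a directory to read with
#'   [read_study_bundle()].
#' @param cfg An `elf_config`.
#' @param out_dir Optional output directory for [write_outputs()].
#' @return List with `records`, `band_values`, `spiro_qc`, `bands_qc`,
#'   `compliance`, `correlation`, `detections`, `activity`.
#' @export
run_study <- function(study, cfg = study_config(), out_dir = NULL) {
  if (is.character(study)) study <- read_study_bundle(study)
  built <- build_daily_records(study, cfg)
  compliance <- compliance_table(study, bands_qc = built$bands_qc,
                                 spiro_qc = built$spiro_qc, cfg = cfg)
  correlation <- if (nrow(built$records) >= 3L) {
    suppressWarnings(
      correlation_matrix(built$records, vars = LOCATION_VARS(built$records))
    )
  } else NULL
  analytes <- process_analytes(study$analytes, study$qc$blanks, cfg)
  detections <- summarize_detections(analytes, built$bands_qc)
  activity <- summarize_activity(study$activity)
  if (!is.null(out_dir)) {
    write_outputs(built$records, out_dir, compliance = compliance,
                  correlation = correlation, band_values = built$band_values)
    readr::write_csv(detections$per_analyte,
                     file.path(out_dir, "analyte_summary.csv"))
    readr::write_csv(built$spiro_qc, file.path(out_dir, "spiro_qc.csv"), na = "")
    readr::write_csv(built$bands_qc[c("participant_id", "band_id", "day",
                                      "compliant", "reasons")],
                     file.path(out_dir, "band_qc.csv"), na = "")
  }
  list(records = built$records, band_values = built$band_values,
       spiro_qc = built$spiro_qc, bands_qc = built$bands_qc,
       compliance = compliance, correlation = correlation,
       detections = detections, activity = activity)
}
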