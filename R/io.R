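# core_io: CSV/GeoJSON/ASCII-grid readers, schema validation and the
# daily-record output writer. Timestamps are stored as POSIXct UTC
# internally; the study config's time zone defines local day boundaries.

SMOKE_CLASSES <- c("low", "medium", "high")
LAND_CLASSES <- c("urban", "hay", "grass", "trees", "wetlands", "crops")
SPIRO_SLOTS <- c("morning", "afternoon", "evening")

require_cols <- function(df, cols, file) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop("schema error in ", file, ": missing column '", miss[1], "'", call. = FALSE)
  }
  invisible(df)
}

parse_utc <- function(x, file, allow_na = FALSE) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  out <- .POSIXct(rep(NA_real_, length(x)), tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = "UTC"))
  }
  bad <- is.na(out) & !(allow_na & (is.na(x) | x == ""))
  if (any(bad)) {
    stop("unparseable timestamp in ", file, " at line(s) ",
         paste(utils::head(which(bad) + 1L, 5), collapse = ", "),
         " (data line numbers include the header)", call. = FALSE)
  }
  out
}

read_csv_quiet <- function(path, ...) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE, ...)
}

# ---- validators (one per domain type) --------------------------------------

#' Validate study tables against their type invariants
#'
#' Each validator checks the invariants of one domain type (coordinate
#' ranges, ordering, positivity, closed vocabularies) and errors with a
#' message naming the offending field. They are applied automatically by
#' [read_study_bundle()] and exposed for direct use on programmatically built
#' tables.
#'
#' @param df The table to validate.
#' @return `df`, invisibly, if valid.
#' @name validators
NULL

#' @rdname validators
#' @export
validate_participants <- function(df) {
  require_cols(df, c("participant_id", "age", "sex", "height_cm",
                     "ethnicity_group", "home_lat", "home_lon"), "participants")
  if (any(df$age <= 0)) stop("participant age must be > 0", call. = FALSE)
  if (any(df$height_cm <= 0)) stop("participant height must be > 0", call. = FALSE)
  if (!all(df$sex %in% c("male", "female"))) {
    stop("participant sex must be 'male' or 'female'", call. = FALSE)
  }
  if (anyDuplicated(df$participant_id)) stop("duplicate participant_id", call. = FALSE)
  invisible(df)
}

#' @rdname validators
#' @export
validate_gps <- function(df) {
  require_cols(df, c("participant_id", "t", "lat", "lon"), "gps")
  if (any(!is.finite(as.numeric(df$t)))) stop("GPS fix time must be finite", call. = FALSE)
  if (any(df$lat < -90 | df$lat > 90)) stop("GPS lat outside [-90, 90]", call. = FALSE)
  if (any(df$lon < -180 | df$lon > 180)) stop("GPS lon outside [-180, 180]", call. = FALSE)
  ok <- df |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(sorted = !is.unsorted(.data$t, strictly = TRUE), .groups = "drop")
  if (!all(ok$sorted)) {
    stop("GPS fixes must be strictly increasing in time for participant(s) ",
         paste(ok$participant_id[!ok$sorted], collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' @rdname validators
#' @export
validate_spirometry <- function(df) {
  require_cols(df, c("participant_id", "slot", "blow_index", "fev1_l", "fvc_l",
                     "pef_lmin", "duration_s", "t"), "spirometry")
  if (!all(df$slot %in% SPIRO_SLOTS)) {
    stop("spirometry slot must be one of ", paste(SPIRO_SLOTS, collapse = ", "), call. = FALSE)
  }
  vols <- c("fev1_l", "fvc_l", "pef_lmin", "duration_s")
  for (v in vols) {
    if (any(df[[v]] < 0, na.rm = TRUE)) stop("spirometry ", v, " must be >= 0", call. = FALSE)
  }
  invisible(df)
}

#' @rdname validators
#' @export
validate_wristbands <- function(df) {
  require_cols(df, c("participant_id", "band_id", "t_on", "t_off", "sealed",
                     "worn_singly"), "wristbands")
  both <- !is.na(df$t_on) & !is.na(df$t_off)
  if (any(both & df$t_off <= df$t_on)) {
    stop("wristband t_off must be after t_on", call. = FALSE)
  }
  if (anyDuplicated(df$band_id)) stop("duplicate band_id", call. = FALSE)
  invisible(df)
}

#' @rdname validators
#' @export
validate_analytes <- function(df) {
  require_cols(df, c("band_id", "analyte", "raw", "lod", "recovery"), "analytes")
  if (any(is.na(df$lod) | df$lod <= 0)) stop("analyte lod must be > 0", call. = FALSE)
  num <- suppressWarnings(as.numeric(df$raw))
  bad <- is.na(num) & df$raw != "ND"
  if (any(bad)) {
    stop("analyte raw must be a number or 'ND' (line ",
         which(bad)[1] + 1L, ")", call. = FALSE)
  }
  if (any(df$recovery <= 0 | df$recovery > 1.5, na.rm = TRUE)) {
    stop("surrogate recovery must be in (0, 1.5]", call. = FALSE)
  }
  invisible(df)
}

#' @rdname validators
#' @export
validate_activity <- function(df) {
  require_cols(df, c("participant_id", "day", "source", "response"), "activity_log")
  if (!all(df$response %in% c("yes", "no") | is.na(df$response))) {
    stop("activity response must be 'yes', 'no' or missing", call. = FALSE)
  }
  invisible(df)
}

validate_smoke <- function(df) {
  bad <- setdiff(unique(df$class), SMOKE_CLASSES)
  if (length(bad)) {
    stop("unknown smoke density class '", bad[1], "'; allowed classes: ",
         paste(SMOKE_CLASSES, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

# ---- bundle reader ---------------------------------------------------------

STUDY_FILES <- c(
  participants = "participants.csv", gps = "gps.csv",
  spirometry = "spirometry.csv", wristbands = "wristbands.csv",
  analytes = "analytes.csv", activity = "activity_log.csv",
  qc_blanks = "qc_blanks.csv", qc_ccvs = "qc_ccvs.csv",
  monitors = "monitors.geojson", monitors_hourly = "monitors_hourly.csv",
  sources = "sources.geojson", roads = "roads.geojson",
  smoke = "smoke.geojson", fires = "fires.geojson",
  landcover = "landcover.asc", landcover_classes = "landcover_classes.csv",
  ndvi = "ndvi.asc", chronic_no2 = "chronic_no2.asc",
  chronic_pm25 = "chronic_pm25.asc"
)

#' Read a complete study bundle from disk
#'
#' Reads, validates and assembles every input stream of a study: participant
#' profiles, GPS traces, spirometry blows, wristband metadata and analyte
#' results, activity logs, batch QC samples and the environment layers
#' (monitors + hourly series, point sources, roads, smoke polygons, fire
#' points, land cover / NDVI / chronic-pollutant rasters).
#'
#' @param dir Directory holding the study files under their standard names.
#' @param manifest Optional named character vector overriding individual file
#'   paths (names as in the standard file set, e.g. `gps`, `smoke`).
#' @return A list of class `elf_study` with elements `participants`, `gps`,
#'   `spirometry`, `wristbands`, `analytes`, `activity`, `qc` and `env`.
#' @export
read_study_bundle <- function(dir, manifest = NULL) {
  paths <- file.path(dir, STUDY_FILES)
  names(paths) <- names(STUDY_FILES)
  if (!is.null(manifest)) paths[names(manifest)] <- manifest
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("study bundle file not found: ", missing[1], call. = FALSE)
  }

  participants <- read_csv_quiet(paths["participants"], col_types = readr::cols(
    participant_id = readr::col_character(), age = readr::col_double(),
    sex = readr::col_character(), height_cm = readr::col_double(),
    ethnicity_group = readr::col_character(), home_lat = readr::col_double(),
    home_lon = readr::col_double()))
  participants <- validate_participants(participants)

  gps <- read_csv_quiet(paths["gps"], col_types = readr::cols(
    participant_id = readr::col_character(), timestamp = readr::col_character(),
    lat = readr::col_double(), lon = readr::col_double()))
  require_cols(gps, c("participant_id", "timestamp", "lat", "lon"), "gps.csv")
  gps$t <- parse_utc(gps$timestamp, "gps.csv")
  gps <- validate_gps(gps[c("participant_id", "t", "lat", "lon")])

  spiro <- read_csv_quiet(paths["spirometry"], col_types = readr::cols(
    participant_id = readr::col_character(), slot = readr::col_character(),
    timestamp = readr::col_character()))
  require_cols(spiro, c("participant_id", "slot", "blow_index", "fev1_l",
                        "fvc_l", "pef_lmin", "duration_s", "timestamp"),
               "spirometry.csv")
  spiro$t <- parse_utc(spiro$timestamp, "spirometry.csv")
  spiro <- validate_spirometry(spiro[c("participant_id", "slot", "blow_index",
                                       "fev1_l", "fvc_l", "pef_lmin",
                                       "duration_s", "t")])

  bands <- read_csv_quiet(paths["wristbands"], col_types = readr::cols(
    participant_id = readr::col_character(), band_id = readr::col_character(),
    t_on = readr::col_character(), t_off = readr::col_character(),
    sealed = readr::col_logical(), worn_singly = readr::col_logical()))
  require_cols(bands, c("participant_id", "band_id", "t_on", "t_off",
                        "sealed", "worn_singly"), "wristbands.csv")
  bands$t_on <- parse_utc(bands$t_on, "wristbands.csv")
  bands$t_off <- parse_utc(bands$t_off, "wristbands.csv", allow_na = TRUE)
  bands <- validate_wristbands(bands)

  analytes <- read_csv_quiet(paths["analytes"], col_types = readr::cols(
    band_id = readr::col_character(), analyte = readr::col_character(),
    raw = readr::col_character(), lod = readr::col_double(),
    recovery = readr::col_double()))
  analytes <- validate_analytes(analytes)

  activity <- read_csv_quiet(paths["activity"], col_types = readr::cols(
    participant_id = readr::col_character(), day = readr::col_date(),
    source = readr::col_character(), response = readr::col_character()))
  activity <- validate_activity(activity)

  qc_blanks <- read_csv_quiet(paths["qc_blanks"], col_types = readr::cols(
    analyte = readr::col_character(), raw = readr::col_character(),
    lod = readr::col_double()))
  qc_ccvs <- read_csv_quiet(paths["qc_ccvs"], col_types = readr::cols(
    position = readr::col_integer(), analyte = readr::col_character(),
    measured = readr::col_double(), true = readr::col_double()))

  env <- read_environment(paths)

  structure(list(
    participants = participants, gps = gps, spirometry = spiro,
    wristbands = bands, analytes = analytes, activity = activity,
    qc = list(blanks = qc_blanks, ccvs = qc_ccvs), env = env
  ), class = "elf_study")
}

read_environment <- function(paths) {
  monitors <- read_geojson_points(paths["monitors"], "monitor_id")
  hourly <- read_csv_quiet(paths["monitors_hourly"], col_types = readr::cols(
    monitor_id = readr::col_character(), timestamp = readr::col_character(),
    pm25 = readr::col_double()))
  require_cols(hourly, c("monitor_id", "timestamp", "pm25"), "monitors_hourly.csv")
  hourly$t <- parse_utc(hourly$timestamp, "monitors_hourly.csv")
  hourly <- hourly[c("monitor_id", "t", "pm25")]

  sources <- read_geojson_points(paths["sources"], c("source_id", "emissions"))
  roads <- read_geojson_lines(paths["roads"], c("road_id", "class"))
  smoke <- read_geojson_polygons(paths["smoke"], c("smoke_id", "day", "class"))
  if (nrow(smoke)) {
    smoke$day <- as.Date(smoke$day)
    validate_smoke(smoke)
  }
  fires <- read_geojson_points(paths["fires"], c("fire_id", "day"))
  if (nrow(fires)) fires$day <- as.Date(fires$day)

  classes_df <- read_csv_quiet(paths["landcover_classes"], col_types = readr::cols(
    class = readr::col_character(), code = readr::col_integer()))
  classes <- stats::setNames(classes_df$code, classes_df$class)

  landcover <- read_ascii_grid(paths["landcover"])
  landcover$classes <- classes
  ndvi <- read_ascii_grid(paths["ndvi"])
  if (!identical(dim(landcover$values), dim(ndvi$values))) {
    stop("ndvi raster is not co-registered with landcover", call. = FALSE)
  }

  environment_bundle(
    monitors = monitors, monitor_series = hourly, sources = sources,
    roads = roads, smoke = smoke, fires = fires, landcover = landcover,
    ndvi = ndvi, chronic_no2 = read_ascii_grid(paths["chronic_no2"]),
    chronic_pm25 = read_ascii_grid(paths["chronic_pm25"])
  )
}

#' Assemble an environment bundle
#'
#' Container for the environmental layers consumed by the exposure
#' estimators. See [read_study_bundle()] for the expected shapes.
#'
#' @param monitors Tibble of monitor locations (`monitor_id`, `lon`, `lat`).
#' @param monitor_series Tibble of hourly PM2.5 (`monitor_id`, `t`, `pm25`).
#' @param sources Tibble of point sources (`source_id`, `lon`, `lat`,
#'   `emissions` in mass/yr).
#' @param roads Tibble with `road_id`, `class` and `geometry` list-column.
#' @param smoke Tibble with `smoke_id`, `day`, `class` and `rings`
#'   list-column.
#' @param fires Tibble of fire points (`fire_id`, `day`, `lon`, `lat`).
#' @param landcover,ndvi Co-registered `elf_raster`s; `landcover` categorical
#'   with a `classes` map.
#' @param chronic_no2,chronic_pm25 Chronic pollutant `elf_raster`s.
#' @return A list of class `elf_environment`.
#' @export
environment_bundle <- function(monitors, monitor_series, sources, roads,
                               smoke, fires, landcover, ndvi,
                               chronic_no2, chronic_pm25) {
  if (nrow(smoke)) validate_smoke(smoke)
  structure(list(
    monitors = monitors, monitor_series = monitor_series, sources = sources,
    roads = roads, smoke = smoke, fires = fires, landcover = landcover,
    ndvi = ndvi, chronic_no2 = chronic_no2, chronic_pm25 = chronic_pm25
  ), class = "elf_environment")
}

# ---- outputs ---------------------------------------------------------------

#' Write pipeline outputs
#'
#' Writes the daily participant-day records (one CSV row per participant-day,
#' wristband analyte values in a separate long table), the compliance report
#' and the correlation matrix with its display ordering. The write -> read
#' round trip is lossless to full double precision.
#'
#' @param records Tibble of daily records (one row per participant-day).
#' @param dir Output directory (created if needed).
#' @param compliance Optional compliance report tibble.
#' @param correlation Optional result of [correlation_matrix()].
#' @param band_values Optional long tibble (`participant_id`, `day`,
#'   `analyte`, `value`).
#' @return `dir`, invisibly.
#' @export
write_outputs <- function(records, dir, compliance = NULL, correlation = NULL,
                          band_values = NULL) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("no daily records to write", call. = FALSE)
  }
  dup <- records |>
    dplyr::count(.data$participant_id, .data$day) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    stop("duplicate participant-day record(s): ",
         paste(paste0(dup$participant_id, "/", dup$day), collapse = ", "),
         call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(records, file.path(dir, "daily_records.csv"), na = "")
  if (!is.null(band_values)) {
    readr::write_csv(band_values, file.path(dir, "band_values.csv"), na = "")
  }
  if (!is.null(compliance)) {
    readr::write_csv(compliance, file.path(dir, "compliance_report.csv"), na = "")
  }
  if (!is.null(correlation)) {
    m <- correlation$matrix
    mat_df <- tibble::as_tibble(m, rownames = "variable")
    readr::write_csv(mat_df, file.path(dir, "correlation_matrix.csv"), na = "")
    readr::write_csv(tibble::tibble(position = seq_along(correlation$order),
                                    variable = correlation$order),
                     file.path(dir, "correlation_order.csv"))
  }
  invisible(dir)
}

#' Read back pipeline outputs
#'
#' Inverse of [write_outputs()]; used for round-trip checks and downstream
#' analysis of a finished run.
#'
#' @param dir Directory written by [write_outputs()].
#' @return A list with `records` and, when present, `band_values`,
#'   `compliance` and `correlation`.
#' @export
read_outputs <- function(dir) {
  out <- list(records = read_csv_quiet(file.path(dir, "daily_records.csv")))
  bv <- file.path(dir, "band_values.csv")
  if (file.exists(bv)) out$band_values <- read_csv_quiet(bv)
  cp <- file.path(dir, "compliance_report.csv")
  if (file.exists(cp)) out$compliance <- read_csv_quiet(cp)
  cm <- file.path(dir, "correlation_matrix.csv")
  if (file.exists(cm)) {
    df <- read_csv_quiet(cm)
    m <- as.matrix(df[-1])
    rownames(m) <- df$variable
    ord <- read_csv_quiet(file.path(dir, "correlation_order.csv"))
    out$correlation <- list(matrix = m, order = ord$variable)
  }
  out
}
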