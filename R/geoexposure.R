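# geoexposure: per-fix spatial exposure estimators and time-weighted daily
# aggregation. Every estimator is vectorised over fixes; daily_exposure()
# strings them together with interval weights derived from the GPS schedule.

#' Duration weights for a GPS trace
#'
#' Each fix represents the time until the next fix, capped at `max_gap_s`
#' (longer gaps are phone-off periods and contribute only the cap). The last
#' fix inherits the previous (capped) interval, or `max_gap_s` for a
#' single-fix trace, so total wear-time mass is preserved without inventing
#' future data.
#'
#' @param t POSIXct (or numeric seconds) fix times, strictly increasing.
#' @param max_gap_s Gap cap in seconds.
#' @return Numeric vector of per-fix weights (seconds).
#' @export
interval_weights <- function(t, max_gap_s = 3600) {
  t <- as.numeric(t)
  n <- length(t)
  if (n == 0L) return(numeric(0))
  if (is.unsorted(t, strictly = TRUE)) stop("trace must be strictly increasing in time", call. = FALSE)
  if (n == 1L) return(max_gap_s)
  w <- pmin(diff(t), max_gap_s)
  c(w, w[n - 1L])
}

#' Time-weighted average
#'
#' Weighted mean over pairs with a non-missing value; missing values drop
#' both the value and its weight. All-missing input yields `NA`, never 0.
#'
#' @param values Numeric vector (may contain `NA`).
#' @param weights Non-negative weights, same length.
#' @return Scalar weighted mean, or `NA_real_`.
#' @export
time_weighted_average <- function(values, weights) {
  stopifnot(length(values) == length(weights))
  ok <- !is.na(values) & !is.na(weights)
  if (!any(ok) || sum(weights[ok]) <= 0) return(NA_real_)
  sum(values[ok] * weights[ok]) / sum(weights[ok])
}

#' Hourly PM2.5 at each fix from the nearest monitor
#'
#' Assigns each fix the hourly concentration of the great-circle-nearest
#' monitor (ties broken by lowest monitor id) at the hour containing the fix
#' time (floored). If that hour is absent from the series, the nearest
#' available hour within +/- 3 h is used (earlier hour wins a tie); otherwise
#' the fix value is missing.
#'
#' @param lon,lat,t Fix coordinates and POSIXct times.
#' @param monitors Tibble with `monitor_id`, `lon`, `lat`.
#' @param monitor_series Tibble with `monitor_id`, `t` (hourly POSIXct),
#'   `pm25`.
#' @return Numeric vector of concentrations (ug/m3).
#' @export
fix_pm25 <- function(lon, lat, t, monitors, monitor_series) {
  if (nrow(monitors) == 0L) stop("no monitors available", call. = FALSE)
  mon <- monitors[order(monitors$monitor_id), ]
  d <- vapply(seq_len(nrow(mon)), function(j) {
    haversine_m(lon, lat, mon$lon[j], mon$lat[j])
  }, numeric(length(lon)))
  d <- matrix(d, nrow = length(lon))
  nearest <- mon$monitor_id[apply(d, 1L, which.min)] # which.min: first = lowest id
  hour <- floor(as.numeric(t) / 3600) * 3600
  key <- paste(nearest, hour)
  series_key <- paste(monitor_series$monitor_id,
                      floor(as.numeric(monitor_series$t) / 3600) * 3600)
  hit <- match(key, series_key)
  out <- monitor_series$pm25[hit]
  for (i in which(is.na(hit))) {
    offsets <- c(-1, 1, -2, 2, -3, 3) * 3600
    for (off in offsets) {
      j <- match(paste(nearest[i], hour[i] + off), series_key)
      if (!is.na(j)) { out[i] <- monitor_series$pm25[j]; break }
    }
  }
  out
}

#' Inverse-distance-weighted point-source emissions at each fix
#'
#' Sums annual emissions over all sources weighted by inverse great-circle
#' distance, `sum(E_s / max(d_s, floor_m)^power)`. The distance floor keeps
#' the term finite when a fix sits on a source. The normalized variant
#' divides by `sum(1 / max(d_s, floor_m)^power)`.
#'
#' @param lon,lat Fix coordinates.
#' @param sources Tibble with `lon`, `lat`, `emissions`.
#' @param power IDW exponent (> 0).
#' @param floor_m Distance floor in metres (> 0).
#' @param normalized Use the normalized IDW mean instead of the plain sum.
#' @return Numeric vector of weighted emissions (0 when no sources).
#' @export
fix_tri_idw <- function(lon, lat, sources, power = 1, floor_m = 10,
                        normalized = FALSE) {
  stopifnot(power > 0, floor_m > 0)
  n <- length(lon)
  if (nrow(sources) == 0L) return(rep(0, n))
  num <- den <- rep(0, n)
  for (j in seq_len(nrow(sources))) {
    d <- pmax(haversine_m(lon, lat, sources$lon[j], sources$lat[j]), floor_m)
    num <- num + sources$emissions[j] / d^power
    den <- den + 1 / d^power
  }
  if (normalized) num / den else num
}

#' Road length within a buffer of each fix
#'
#' Total length (m) of road geometry clipped to the disc of radius
#' `radius_m` about each fix, computed in a local azimuthal equidistant
#' projection centred on the fix. Callers restrict `roads` to the road
#' classes of interest (highways/expressways) beforehand.
#'
#' @param lon,lat Fix coordinates.
#' @param roads Tibble with a `geometry` list-column (each element a list of
#'   lon/lat vertex matrices).
#' @param radius_m Buffer radius in metres.
#' @return Numeric vector of clipped lengths (m).
#' @export
fix_road_length <- function(lon, lat, roads, radius_m = 100) {
  n <- length(lon)
  out <- numeric(n)
  if (nrow(roads) == 0L) return(out)
  parts <- unlist(roads$geometry, recursive = FALSE)
  # quick-reject bounding boxes in degrees, padded by the radius
  pad_lat <- radius_m / 111320 * 1.1
  bbs <- lapply(parts, function(m) {
    c(min(m[, 1]), max(m[, 1]), min(m[, 2]), max(m[, 2]))
  })
  for (i in seq_len(n)) {
    pad_lon <- pad_lat / max(cos(lat[i] * pi / 180), 1e-6)
    total <- 0
    for (k in seq_along(parts)) {
      bb <- bbs[[k]]
      if (lon[i] < bb[1] - pad_lon || lon[i] > bb[2] + pad_lon ||
          lat[i] < bb[3] - pad_lat || lat[i] > bb[4] + pad_lat) next
      m <- parts[[k]]
      xy <- local_aeq(m[, 1], m[, 2], lon[i], lat[i])
      for (s in seq_len(nrow(xy) - 1L)) {
        total <- total + clip_segment_to_disc(xy[s, 1], xy[s, 2],
                                              xy[s + 1L, 1], xy[s + 1L, 2],
                                              radius_m)
      }
    }
    out[i] <- total
  }
  out
}

#' NDVI sum over one land class within a buffer of each fix
#'
#' Sums NDVI over raster cells whose centres lie within `radius_m` of the fix
#' and whose land-cover code equals `landclass` (element-wise product of NDVI
#' with the binary class mask). Fixes outside the raster extent yield `NA`.
#'
#' @param lon,lat Fix coordinates.
#' @param ndvi,landcover Co-registered `elf_raster`s; `landcover` carries a
#'   `classes` name-to-code map.
#' @param landclass Land class name (e.g. `"hay"`) or integer code.
#' @param radius_m Buffer radius in metres.
#' @return Numeric vector of unitless NDVI sums.
#' @export
fix_ndvi_class <- function(lon, lat, ndvi, landcover, landclass, radius_m = 250) {
  code <- landclass_code(landcover, landclass)
  vapply(seq_along(lon), function(i) {
    w <- raster_disc_cells(ndvi, lon[i], lat[i], radius_m)
    if (is.null(w)) return(NA_real_)
    sum(ndvi$values[w$idx] * (landcover$values[w$idx] == code))
  }, numeric(1))
}

# Single-pass variant: NDVI sums for every land class at once (same pixel
# window as fix_ndvi_class, one row per fix).
fix_ndvi_multi <- function(lon, lat, ndvi, landcover, radius_m = 250) {
  classes <- landcover$classes
  out <- matrix(NA_real_, nrow = length(lon), ncol = length(classes),
                dimnames = list(NULL, names(classes)))
  for (i in seq_along(lon)) {
    w <- raster_disc_cells(ndvi, lon[i], lat[i], radius_m)
    if (is.null(w)) next
    nv <- ndvi$values[w$idx]
    lc <- landcover$values[w$idx]
    for (k in seq_along(classes)) {
      out[i, k] <- sum(nv[lc == classes[[k]]])
    }
  }
  out
}

landclass_code <- function(landcover, landclass) {
  if (is.numeric(landclass)) return(landclass)
  if (is.null(landcover$classes) || !landclass %in% names(landcover$classes)) {
    stop("unknown land class '", landclass, "'", call. = FALSE)
  }
  landcover$classes[[landclass]]
}

# Cells of `x` whose centres are within radius_m of (lon, lat); NULL when the
# point lies outside the raster extent.
raster_disc_cells <- function(x, lon, lat, radius_m) {
  nr <- nrow(x$values); nc <- ncol(x$values)
  lon_max <- x$xll + nc * x$cellsize
  lat_max <- x$yll + nr * x$cellsize
  if (lon < x$xll || lon > lon_max || lat < x$yll || lat > lat_max) return(NULL)
  dlat <- radius_m / 111320 * 1.05
  dlon <- dlat / max(cos(lat * pi / 180), 1e-6)
  col_lo <- max(1L, floor((lon - dlon - x$xll) / x$cellsize) + 1L)
  col_hi <- min(nc, floor((lon + dlon - x$xll) / x$cellsize) + 1L)
  row_s_lo <- max(0L, floor((lat - dlat - x$yll) / x$cellsize))
  row_s_hi <- min(nr - 1L, floor((lat + dlat - x$yll) / x$cellsize))
  if (col_hi < col_lo || row_s_hi < row_s_lo) {
    return(list(idx = matrix(integer(0), ncol = 2)))
  }
  rows <- nr - (row_s_lo:row_s_hi) # matrix rows, row 1 = north
  cols <- col_lo:col_hi
  grid <- expand.grid(row = rows, col = cols)
  ctr <- raster_cell_centre(x, grid$row, grid$col)
  d <- haversine_m(ctr[, "lon"], ctr[, "lat"], lon, lat)
  keep <- d <= radius_m
  list(idx = cbind(grid$row[keep], grid$col[keep]))
}

#' Smoke-plume density at each fix
#'
#' A fix inside one or more smoke polygons takes the mapped concentration of
#' the highest density class containing it (containment beats proximity;
#' overlapping plumes resolve conservatively upward). A fix outside all
#' polygons takes the mapped value of the nearest polygon if within
#' `max_dist_m`, else 0 (no smoke).
#'
#' @param lon,lat Fix coordinates.
#' @param smoke Tibble with `class` and `rings` list-column (polygons already
#'   filtered to the relevant day).
#' @param smoke_map Named concentrations for classes low/medium/high (ug/m3).
#' @param max_dist_m Maximum assignment distance outside all polygons.
#' @return Numeric vector of concentrations (ug/m3).
#' @export
fix_smoke_density <- function(lon, lat, smoke, smoke_map,
                              max_dist_m = 50000) {
  n <- length(lon)
  if (nrow(smoke) == 0L) return(rep(0, n))
  bad <- setdiff(unique(smoke$class), names(smoke_map))
  if (length(bad)) stop("unknown smoke density class '", bad[1], "'", call. = FALSE)
  rank <- match(smoke$class, c("low", "medium", "high"))
  out <- numeric(n)
  for (i in seq_len(n)) {
    inside <- vapply(smoke$rings, function(r) point_in_polygon(lon[i], lat[i], r),
                     logical(1))
    if (any(inside)) {
      cls <- smoke$class[inside][which.max(rank[inside])]
      out[i] <- smoke_map[[cls]]
    } else {
      d <- vapply(smoke$rings, function(r) dist_to_polygon_m(lon[i], lat[i], r),
                  numeric(1))
      if (min(d) <= max_dist_m) out[i] <- smoke_map[[smoke$class[which.min(d)]]]
    }
  }
  out
}

#' Distance to the nearest active wildfire
#'
#' @param lon,lat Fix coordinates.
#' @param fires Tibble of fire points (`lon`, `lat`), already filtered to the
#'   relevant day.
#' @return Numeric vector of great-circle distances in km; `NA` when no
#'   fires are active.
#' @export
fix_fire_distance <- function(lon, lat, fires) {
  n <- length(lon)
  if (nrow(fires) == 0L) return(rep(NA_real_, n))
  d <- vapply(seq_len(nrow(fires)), function(j) {
    haversine_m(lon, lat, fires$lon[j], fires$lat[j])
  }, numeric(n))
  d <- matrix(d, nrow = n)
  apply(d, 1L, min) / 1000
}

#' Chronic pollutant concentration at a residence
#'
#' Nearest-cell extraction from an annual chronic-pollutant surface at the
#' home location. Homes outside the raster extent yield `NA` with a warning.
#'
#' @param home_lon,home_lat Residence coordinates.
#' @param raster An `elf_raster` (e.g. chronic NO2 at 100 m or PM2.5 at 1 km).
#' @return Scalar concentration, or `NA`.
#' @export
chronic_at_residence <- function(home_lon, home_lat, raster) {
  v <- raster_extract(raster, home_lon, home_lat)
  if (is.na(v)) warning("residence outside raster extent; chronic value missing")
  v
}

#' Classify driving intervals and the daily driving fraction
#'
#' Interval speed is great-circle distance over duration. An interval counts
#' as driving when its speed exceeds the threshold and it belongs to a run of
#' at least two consecutive over-threshold intervals (a single fast interval
#' is GPS jitter, not a trip). Intervals longer than `max_gap_s` are
#' unobserved: they join neither numerator nor denominator and break runs.
#'
#' @param trace Tibble with `t`, `lat`, `lon` (single participant-day,
#'   sorted).
#' @param speed_threshold_ms Driving speed threshold (m/s).
#' @param max_gap_s Observed-time gap cap (s).
#' @return List with `intervals` (tibble: `duration_s`, `speed_ms`,
#'   `observed`, `driving`) and `fraction` (driving time / observed time).
#' @export
classify_driving <- function(trace, speed_threshold_ms = 8, max_gap_s = 3600) {
  n <- nrow(trace)
  if (n < 2L) {
    return(list(intervals = tibble::tibble(duration_s = numeric(0),
                                           speed_ms = numeric(0),
                                           observed = logical(0),
                                           driving = logical(0)),
                fraction = 0))
  }
  dt <- diff(as.numeric(trace$t))
  dist <- haversine_m(trace$lon[-n], trace$lat[-n], trace$lon[-1], trace$lat[-1])
  speed <- dist / dt
  observed <- dt <= max_gap_s
  fast <- speed > speed_threshold_ms & observed
  runs <- rle(fast)
  driving <- inverse.rle(list(lengths = runs$lengths,
                              values = runs$values & runs$lengths >= 2L))
  denom <- sum(dt[observed])
  frac <- if (denom > 0) sum(dt[driving]) / denom else 0
  list(intervals = tibble::tibble(duration_s = dt, speed_ms = speed,
                                  observed = observed, driving = driving),
       fraction = frac)
}

#' Time-weighted daily exposure for one participant-day trace
#'
#' Applies every fix-level estimator to the trace, then aggregates with
#' [time_weighted_average()] under [interval_weights()]. Wildfire distance is
#' summarised both as the daily minimum and the time-weighted mean; NDVI sums
#' are reported per land class. An empty trace yields a record of missings.
#'
#' @param trace Tibble with `t`, `lat`, `lon` for one local day, sorted.
#' @param env An `elf_environment`.
#' @param cfg An `elf_config`.
#' @param day Local date of the trace; used to select the day's smoke
#'   polygons and fire points when those layers carry a `day` column.
#' @return One-row tibble of daily metrics (`pm25`, `tri_idw`, `road_m`,
#'   `ndvi_*`, `smoke`, `fire_km_min`, `fire_km_mean`, `driving_fraction`).
#' @export
daily_exposure <- function(trace, env, cfg = study_config(), day = NULL) {
  classes <- names(env$landcover$classes)
  empty <- tibble::as_tibble(c(
    list(pm25 = NA_real_, tri_idw = NA_real_, road_m = NA_real_),
    stats::setNames(as.list(rep(NA_real_, length(classes))),
                    paste0("ndvi_", classes)),
    list(smoke = NA_real_, fire_km_min = NA_real_, fire_km_mean = NA_real_,
         driving_fraction = NA_real_)
  ))
  if (is.null(trace) || nrow(trace) == 0L) return(empty)

  w <- interval_weights(trace$t, cfg$max_gap_s)
  smoke <- env$smoke
  if (!is.null(day) && nrow(smoke) && "day" %in% names(smoke)) {
    smoke <- smoke[smoke$day == day, , drop = FALSE]
  }
  fires <- env$fires
  if (!is.null(day) && nrow(fires) && "day" %in% names(fires)) {
    fires <- fires[fires$day == day, , drop = FALSE]
  }
  roads <- env$roads[env$roads$class %in% c("highway", "expressway"), , drop = FALSE]

  pm <- fix_pm25(trace$lon, trace$lat, trace$t, env$monitors, env$monitor_series)
  tri <- fix_tri_idw(trace$lon, trace$lat, env$sources,
                     power = cfg$idw_power, floor_m = cfg$idw_floor_m,
                     normalized = cfg$idw_normalized)
  road <- fix_road_length(trace$lon, trace$lat, roads, cfg$road_radius_m)
  smk <- fix_smoke_density(trace$lon, trace$lat, smoke, cfg$smoke_map,
                           cfg$smoke_max_dist_m)
  fire <- fix_fire_distance(trace$lon, trace$lat, fires)

  ndvi_mat <- fix_ndvi_multi(trace$lon, trace$lat, env$ndvi, env$landcover,
                             cfg$ndvi_radius_m)
  ndvi_vals <- lapply(classes, function(cl) ndvi_mat[, cl])
  names(ndvi_vals) <- paste0("ndvi_", classes)

  drv <- classify_driving(trace, cfg$driving_speed_ms, cfg$max_gap_s)

  tibble::as_tibble(c(
    list(pm25 = time_weighted_average(pm, w),
         tri_idw = time_weighted_average(tri, w),
         road_m = time_weighted_average(road, w)),
    lapply(ndvi_vals, time_weighted_average, weights = w),
    list(smoke = time_weighted_average(smk, w),
         fire_km_min = if (all(is.na(fire))) NA_real_ else min(fire, na.rm = TRUE),
         fire_km_mean = time_weighted_average(fire, w),
         driving_fraction = drv$fraction)
  ))
}
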