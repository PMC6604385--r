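# Shared fixture builders: a minimal in-code environment bundle and trace
# constructors. Everything is built programmatically; no data files.

CENTRE_LON <- -123.09
CENTRE_LAT <- 44.05

# metres per degree of latitude on the sphere the package uses (R = 6371.0088 km)
M_PER_DEG <- 6371008.8 * pi / 180

# destination point on that sphere: start (lon, lat), bearing (deg), distance (m)
dest_pt <- function(lon, lat, bearing_deg, dist_m) {
  as.numeric(geosphere::destPoint(c(lon, lat), bearing_deg, dist_m,
                                  r = 6371008.8))
}

mk_trace <- function(offsets_s, lon = CENTRE_LON, lat = CENTRE_LAT,
                     day = as.Date("2015-08-17"), tz = "UTC") {
  t0 <- as.POSIXct(paste(day, "00:00:00"), tz = tz)
  n <- length(offsets_s)
  tibble::tibble(t = t0 + offsets_s,
                 lon = rep_len(lon, n), lat = rep_len(lat, n))
}

square_ring <- function(lon, lat, half_deg) {
  rbind(c(lon - half_deg, lat - half_deg), c(lon + half_deg, lat - half_deg),
        c(lon + half_deg, lat + half_deg), c(lon - half_deg, lat + half_deg),
        c(lon - half_deg, lat - half_deg))
}

const_raster <- function(value, nr = 20, nc = 20, cell = 0.003,
                         xll = CENTRE_LON - nc / 2 * 0.003,
                         yll = CENTRE_LAT - nr / 2 * 0.003, classes = NULL) {
  elf_raster(matrix(value, nr, nc), xll, yll, cell, classes = classes)
}

# A small, fully constant environment: one monitor at a fixed level, no
# sources, one N-S highway through the centre, one medium smoke polygon over
# everything, one fire, flat rasters of class "grass".
tiny_env <- function(pm25 = 10, smoke_class = "medium",
                     day = as.Date("2015-08-17"),
                     with_fire = TRUE, ndvi = 0.5) {
  classes <- stats::setNames(1:6, c("urban", "hay", "grass", "trees",
                                    "wetlands", "crops"))
  hours <- seq(as.POSIXct(paste(day - 1, "00:00:00"), tz = "UTC"),
               by = 3600, length.out = 96)
  monitors <- tibble::tibble(monitor_id = "M01", lon = CENTRE_LON + 0.01,
                             lat = CENTRE_LAT + 0.01)
  series <- tibble::tibble(monitor_id = "M01", t = hours,
                           pm25 = rep(pm25, length(hours)))
  road <- tibble::tibble(
    road_id = "H1", class = "highway",
    geometry = list(list(rbind(c(CENTRE_LON, CENTRE_LAT - 0.5),
                               c(CENTRE_LON, CENTRE_LAT + 0.5)))))
  smoke <- tibble::tibble(smoke_id = "K1", day = day, class = smoke_class,
                          rings = list(list(square_ring(CENTRE_LON, CENTRE_LAT, 1))))
  fires <- if (with_fire) {
    tibble::tibble(fire_id = "F1", day = day,
                   lon = CENTRE_LON, lat = CENTRE_LAT + 25 / 111.31949)
  } else {
    tibble::tibble(fire_id = character(0), day = as.Date(character(0)),
                   lon = numeric(0), lat = numeric(0))
  }
  environment_bundle(
    monitors = monitors, monitor_series = series,
    sources = tibble::tibble(source_id = character(0), emissions = numeric(0),
                             lon = numeric(0), lat = numeric(0)),
    roads = road, smoke = smoke, fires = fires,
    landcover = const_raster(classes[["grass"]], classes = classes),
    ndvi = const_raster(ndvi),
    chronic_no2 = const_raster(12), chronic_pm25 = const_raster(7)
  )
}

# small simulation config used across tests (coarser rasters than the
# default study for speed; resolution does not enter any asserted quantity)
test_sim_config <- function(...) {
  sim_config(landcover_cell_deg = 0.003, chronic_no2_cell_deg = 0.003, ...)
}

mk_session <- function(fev1, fvc = fev1 / 0.8, duration = 8) {
  n <- length(fev1)
  tibble::tibble(fev1_l = fev1, fvc_l = rep_len(fvc, n),
                 duration_s = rep_len(duration, n))
}

road_through <- function(offset_m, bearing_deg = 0) {
  # a straight 4 km road whose endpoints sit, in the local plane about the
  # fix, at perpendicular offset offset_m from the centre (built by inverse
  # azimuthal-equidistant construction, so the planar chord geometry is exact)
  p <- function(x, y) dest_pt(CENTRE_LON, CENTRE_LAT,
                              atan2(x, y) * 180 / pi, sqrt(x^2 + y^2))
  th <- bearing_deg * pi / 180
  ox <- cos(th) * offset_m; oy <- -sin(th) * offset_m
  a <- p(ox - 2000 * sin(th), oy - 2000 * cos(th))
  b <- p(ox + 2000 * sin(th), oy + 2000 * cos(th))
  tibble::tibble(road_id = "r", class = "highway",
                 geometry = list(list(rbind(a, b))))
}
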