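# synthetic_data: a fully seeded generator for a complete synthetic study
# (participants, GPS traces, environment layers, spirometry, wristband
# chemistry, activity logs) with recorded ground truth for every pipeline
# stage. All randomness flows from one root seed through a documented
# stream-splitting scheme (sub_seed), so any sub-fixture can be regenerated
# in isolation.

#' Derive a reproducible sub-stream seed
#'
#' Hashes a root seed together with a path of stream labels (e.g.
#' `"gps", participant, day`) into a 31-bit seed, so each generator stream is
#' reproducible in isolation.
#'
#' @param root Integer root seed.
#' @param ... Stream labels (coerced to character).
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
sub_seed <- function(root, ...) {
  key <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- 17
  for (cc in utf8ToInt(key)) h <- (h * 131 + cc) %% 2147483562
  as.integer((as.numeric(root) %% 2147483562 + h) %% 2147483562) + 1L
}

#' Synthetic-study generator configuration
#'
#' Parameters of the synthetic cohort and town. Defaults mirror the
#' feasibility-study conditions: 10 participants over 7 days in a 40 x 40 km
#' town on real WGS84 coordinates, a 15-min GPS schedule with densification
#' bursts while driving, two in-town monitors plus one ~40 km south,
#' triplicate spirometry with a 6% planted invalid-session rate (94% valid),
#' a ~10% planted wristband non-compliance rate with one lost band expected
#' per 70, and a 62-analyte panel in which 9 core analytes are always
#' detected, 22 are variably detected and the rest stay below the LOD.
#'
#' @param n_participants,n_days Cohort size and study length.
#' @param start_date First local study day (a Monday by default).
#' @param centre_lon,centre_lat Town centre (degrees WGS84).
#' @param domain_km Side of the square study domain (km).
#' @param landcover_cell_deg Land-cover/NDVI cell size in degrees (~30 m
#'   default).
#' @param chronic_no2_cell_deg,chronic_pm25_cell_deg Chronic raster cell
#'   sizes (~100 m and ~1 km).
#' @param gps_interval_s Base GPS schedule (s).
#' @param burst_interval_s Densified schedule while driving (s).
#' @param p_gap Daily probability of an hour-plus phone-off gap.
#' @param gap_len_s Length of a planted gap (s).
#' @param commute_speed_ms Driving speed along commutes (m/s).
#' @param gps_noise_m Positional jitter applied to each fix (m, sd).
#' @param p_session_skip Probability a scheduled spirometry session is not
#'   performed.
#' @param p_invalid Probability a performed session is planted invalid.
#' @param sigma_blow_l Within-session blow-to-blow shortfall range (L).
#' @param severity_range Range of the participant severity factor scaling
#'   predicted FEV1.
#' @param band_noncompliance Planted wristband non-compliance rate.
#' @param p_lost Probability a wristband is never returned.
#' @param n_variable_analytes Number of non-core analytes with intermediate
#'   detection probability.
#' @param ccv_every CCV cadence (samples).
#' @param ccv_fail_rate Planted CCV batch failure rate.
#' @param n_sources_range Range of the number of emission point sources.
#' @param n_monitors Number of PM2.5 monitors.
#' @param pm25_base,ar1_phi,ar1_sd Hourly PM2.5 AR(1) parameters (ug/m3).
#' @param smoke_max_per_day Maximum smoke polygons per day (0-3 drawn).
#' @param fires_max_per_day Maximum wildfire points per day.
#' @param fire_min_km Minimum wildfire distance from the town centre (km).
#' @param constant_environment If `TRUE`, every environmental field is
#'   spatially and temporally constant (constant monitor series, one
#'   domain-wide medium smoke polygon, constant rasters, no sources, no
#'   highways, no fires); the constants become recorded truth.
#' @param planted_sigma Correlation matrix planted in the latent daily
#'   location factors (default two +0.9 blocks anti-correlated at -0.9).
#' @return A list of class `elf_sim_config`.
#' @export
sim_config <- function(n_participants = 10L, n_days = 7L,
                       start_date = as.Date("2015-08-17"),
                       centre_lon = -123.09, centre_lat = 44.05,
                       domain_km = 40,
                       landcover_cell_deg = 0.00027,
                       chronic_no2_cell_deg = 0.0009,
                       chronic_pm25_cell_deg = 0.009,
                       gps_interval_s = 900, burst_interval_s = 60,
                       p_gap = 0.05, gap_len_s = 5400,
                       commute_speed_ms = 20, gps_noise_m = 8,
                       p_session_skip = 0.07, p_invalid = 0.06,
                       sigma_blow_l = 0.05,
                       severity_range = c(0.6, 1.1),
                       band_noncompliance = 0.10, p_lost = 1 / 70,
                       n_variable_analytes = 22L,
                       ccv_every = 10L, ccv_fail_rate = 0.10,
                       n_sources_range = c(5L, 20L), n_monitors = 3L,
                       pm25_base = 8, ar1_phi = 0.8, ar1_sd = 2,
                       smoke_max_per_day = 3L, fires_max_per_day = 2L,
                       fire_min_km = 25,
                       constant_environment = FALSE,
                       planted_sigma = NULL) {
  if (is.null(planted_sigma)) {
    u <- c(1, 1, -1, -1)
    planted_sigma <- 0.1 * diag(4) + 0.9 * tcrossprod(u)
    dimnames(planted_sigma) <- list(paste0("factor_", 1:4), paste0("factor_", 1:4))
  }
  structure(as.list(environment()), class = "elf_sim_config")
}

deg_per_m_lat <- function() 1 / 111319.49
deg_per_m_lon <- function(lat) 1 / (111319.49 * cos(lat * pi / 180))

# ---- environment -----------------------------------------------------------

#' Generate the synthetic environment layers
#'
#' Builds an [environment_bundle()]: monitors with AR(1) hourly PM2.5
#' series, log-normally distributed emission point sources, a highway/other
#' road grid, a blocky land-cover raster over the six land classes with a
#' smooth NDVI surface, 0-3 smoke polygons per day, 0-2 wildfire points per
#' day at least `fire_min_km` from the town centre, and smooth chronic NO2
#' and PM2.5 surfaces.
#'
#' @param scfg An `elf_sim_config`.
#' @param seed Root seed.
#' @return An `elf_environment`.
#' @export
generate_environment <- function(scfg = sim_config(), seed = 1L) {
  half_deg_lat <- scfg$domain_km * 500 * deg_per_m_lat()
  half_deg_lon <- scfg$domain_km * 500 * deg_per_m_lon(scfg$centre_lat)
  xll <- scfg$centre_lon - half_deg_lon
  yll <- scfg$centre_lat - half_deg_lat
  days <- scfg$start_date + seq_len(scfg$n_days) - 1L

  # monitors: two in town, one ~40 km south
  monitors <- tibble::tibble(
    monitor_id = c("M01", "M02", "M03")[seq_len(scfg$n_monitors)],
    lon = c(scfg$centre_lon - 0.02, scfg$centre_lon + 0.03,
            scfg$centre_lon + 0.01)[seq_len(scfg$n_monitors)],
    lat = c(scfg$centre_lat + 0.01, scfg$centre_lat - 0.015,
            scfg$centre_lat - 0.36)[seq_len(scfg$n_monitors)]
  )
  hours <- seq(from = as.POSIXct(paste(scfg$start_date - 1, "00:00:00"), tz = "UTC"),
               by = 3600, length.out = (scfg$n_days + 3) * 24)
  monitor_series <- dplyr::bind_rows(lapply(seq_len(nrow(monitors)), function(j) {
    v <- if (scfg$constant_environment) {
      rep(scfg$pm25_base, length(hours))
    } else {
      withr::with_seed(sub_seed(seed, "monitor", j), {
        e <- stats::rnorm(length(hours), 0, scfg$ar1_sd)
        x <- stats::filter(e, scfg$ar1_phi, method = "recursive")
        pmax(scfg$pm25_base + as.numeric(x), 0.5)
      })
    }
    tibble::tibble(monitor_id = monitors$monitor_id[j], t = hours, pm25 = v)
  }))

  sources <- if (scfg$constant_environment) {
    tibble::tibble(source_id = character(0), emissions = numeric(0),
                   lon = numeric(0), lat = numeric(0))
  } else {
    withr::with_seed(sub_seed(seed, "sources"), {
      ns <- sample(scfg$n_sources_range[1]:scfg$n_sources_range[2], 1L)
      tibble::tibble(
        source_id = sprintf("S%02d", seq_len(ns)),
        emissions = stats::rlnorm(ns, meanlog = 8, sdlog = 1),
        lon = stats::runif(ns, xll, xll + 2 * half_deg_lon),
        lat = stats::runif(ns, yll, yll + 2 * half_deg_lat)
      )
    })
  }

  roads <- synth_roads(scfg, xll, yll, half_deg_lon, half_deg_lat)

  rasters <- synth_rasters(scfg, seed, xll, yll, half_deg_lon, half_deg_lat)

  smoke <- synth_smoke(scfg, seed, days, xll, yll, half_deg_lon, half_deg_lat)
  fires <- synth_fires(scfg, seed, days)

  environment_bundle(
    monitors = monitors, monitor_series = monitor_series, sources = sources,
    roads = roads, smoke = smoke, fires = fires,
    landcover = rasters$landcover, ndvi = rasters$ndvi,
    chronic_no2 = rasters$no2, chronic_pm25 = rasters$pm25
  )
}

synth_roads <- function(scfg, xll, yll, half_deg_lon, half_deg_lat) {
  if (scfg$constant_environment) {
    return(tibble::tibble(road_id = character(0), class = character(0),
                          geometry = list()))
  }
  mk <- function(m) list(m)
  lon0 <- scfg$centre_lon; lat0 <- scfg$centre_lat
  rows <- list(
    list("H1", "highway", rbind(c(xll, lat0 + 0.004), c(xll + 2 * half_deg_lon, lat0 + 0.004))),
    list("H2", "highway", rbind(c(lon0 - 0.006, yll), c(lon0 - 0.006, yll + 2 * half_deg_lat))),
    list("H3", "expressway", rbind(c(xll, yll + 0.05), c(xll + 2 * half_deg_lon, yll + 0.28))),
    list("R1", "other", rbind(c(lon0 + 0.03, yll), c(lon0 + 0.03, yll + 2 * half_deg_lat))),
    list("R2", "other", rbind(c(xll, lat0 - 0.05), c(xll + 2 * half_deg_lon, lat0 - 0.05)))
  )
  tibble::tibble(
    road_id = vapply(rows, `[[`, character(1), 1L),
    class = vapply(rows, `[[`, character(1), 2L),
    geometry = lapply(rows, function(r) mk(r[[3]]))
  )
}

synth_rasters <- function(scfg, seed, xll, yll, half_deg_lon, half_deg_lat) {
  classes <- stats::setNames(seq_along(LAND_CLASSES), LAND_CLASSES)
  mk_grid <- function(cell) {
    nc <- ceiling(2 * half_deg_lon / cell)
    nr <- ceiling(2 * half_deg_lat / cell)
    list(nr = nr, nc = nc)
  }
  g <- mk_grid(scfg$landcover_cell_deg)
  if (scfg$constant_environment) {
    lc_m <- matrix(classes[["grass"]], g$nr, g$nc)
    nd_m <- matrix(0.5, g$nr, g$nc)
  } else {
    withr::with_seed(sub_seed(seed, "landcover"), {
      # blocky land-cover: ~1.5 km super-blocks, urban core in the centre
      nb <- 32L
      block_class <- matrix(sample(seq_along(LAND_CLASSES), nb * nb, replace = TRUE,
                                   prob = c(0.15, 0.15, 0.2, 0.25, 0.1, 0.15)),
                            nb, nb)
      core <- (nb %/% 2 - 3):(nb %/% 2 + 4)
      block_class[core, core] <- classes[["urban"]]
      bi <- pmin(nb, 1L + (seq_len(g$nr) - 1L) * nb %/% g$nr)
      bj <- pmin(nb, 1L + (seq_len(g$nc) - 1L) * nb %/% g$nc)
      lc_m <- block_class[bi, bj]
      ndvi_base <- c(urban = 0.15, hay = 0.55, grass = 0.6, trees = 0.8,
                     wetlands = 0.5, crops = 0.65)
      nd_m <- matrix(ndvi_base[LAND_CLASSES][lc_m], g$nr, g$nc) +
        matrix(stats::rnorm(g$nr * g$nc, 0, 0.05), g$nr, g$nc)
      nd_m <- pmin(pmax(nd_m, 0), 1)
    })
  }
  landcover <- elf_raster(lc_m, xll, yll, scfg$landcover_cell_deg, classes = classes)
  ndvi <- elf_raster(nd_m, xll, yll, scfg$landcover_cell_deg)

  smooth_field <- function(cell, base, amp, stream) {
    gg <- mk_grid(cell)
    if (scfg$constant_environment) {
      m <- matrix(base, gg$nr, gg$nc)
    } else {
      withr::with_seed(sub_seed(seed, stream), {
        px <- stats::runif(1, 0, 2 * pi); py <- stats::runif(1, 0, 2 * pi)
        i <- matrix(seq_len(gg$nr), gg$nr, gg$nc)
        j <- matrix(seq_len(gg$nc), gg$nr, gg$nc, byrow = TRUE)
        m <- base + amp * sin(2 * pi * i / gg$nr + px) * cos(2 * pi * j / gg$nc + py)
      })
    }
    elf_raster(m, xll, yll, cell)
  }
  list(landcover = landcover, ndvi = ndvi,
       no2 = smooth_field(scfg$chronic_no2_cell_deg, 12, 5, "chronic_no2"),
       pm25 = smooth_field(scfg$chronic_pm25_cell_deg, 7, 2, "chronic_pm25"))
}

synth_smoke <- function(scfg, seed, days, xll, yll, half_deg_lon, half_deg_lat) {
  circle_ring <- function(lon, lat, radius_m, n = 24L) {
    th <- seq(0, 2 * pi, length.out = n + 1L)
    cbind(lon + radius_m * sin(th) * deg_per_m_lon(lat),
          lat + radius_m * cos(th) * deg_per_m_lat())
  }
  if (scfg$constant_environment) {
    big <- rbind(c(xll - 1, yll - 1), c(xll + 2 * half_deg_lon + 1, yll - 1),
                 c(xll + 2 * half_deg_lon + 1, yll + 2 * half_deg_lat + 1),
                 c(xll - 1, yll + 2 * half_deg_lat + 1), c(xll - 1, yll - 1))
    return(tibble::tibble(
      smoke_id = sprintf("K%02d", seq_along(days)),
      day = days, class = "medium",
      rings = replicate(length(days), list(big), simplify = FALSE)
    ))
  }
  rows <- list()
  for (d in seq_along(days)) {
    withr::with_seed(sub_seed(seed, "smoke", d), {
      np <- sample(0:scfg$smoke_max_per_day, 1L)
      if (np > 0) {
        for (k in seq_len(np)) {
          lon <- stats::runif(1, xll, xll + 2 * half_deg_lon)
          lat <- stats::runif(1, yll, yll + 2 * half_deg_lat)
          ring <- circle_ring(lon, lat, stats::runif(1, 2000, 8000))
          rows[[length(rows) + 1L]] <- tibble::tibble(
            smoke_id = sprintf("K%02d_%d", d, k), day = days[d],
            class = sample(SMOKE_CLASSES, 1L, prob = c(0.5, 0.35, 0.15)),
            rings = list(list(ring)))
        }
      }
    })
  }
  if (!length(rows)) {
    return(tibble::tibble(smoke_id = character(0), day = as.Date(character(0)),
                          class = character(0), rings = list()))
  }
  dplyr::bind_rows(rows)
}

synth_fires <- function(scfg, seed, days) {
  if (scfg$constant_environment) {
    return(tibble::tibble(fire_id = character(0), day = as.Date(character(0)),
                          lon = numeric(0), lat = numeric(0)))
  }
  rows <- list()
  for (d in seq_along(days)) {
    withr::with_seed(sub_seed(seed, "fires", d), {
      nf <- sample(0:scfg$fires_max_per_day, 1L)
      if (nf > 0) {
        dist_m <- stats::runif(nf, scfg$fire_min_km * 1000, scfg$fire_min_km * 4000)
        bearing <- stats::runif(nf, 0, 2 * pi)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          fire_id = sprintf("F%02d_%d", d, seq_len(nf)), day = days[d],
          lon = scfg$centre_lon + dist_m * sin(bearing) * deg_per_m_lon(scfg$centre_lat),
          lat = scfg$centre_lat + dist_m * cos(bearing) * deg_per_m_lat())
      }
    })
  }
  if (!length(rows)) {
    return(tibble::tibble(fire_id = character(0), day = as.Date(character(0)),
                          lon = numeric(0), lat = numeric(0)))
  }
  dplyr::bind_rows(rows)
}

# ---- participants and traces ----------------------------------------------

#' Generate participant profiles, GPS traces and activity logs
#'
#' Demographics echo the feasibility cohort margins (9 female / 1 male,
#' middle-aged, one non-Caucasian participant mapped to the Caucasian
#' reference group). Traces are home-anchored on the 15-min base schedule,
#' with weekday commutes to a workplace at driving speed sampled on a
#' densified schedule, occasional phone-off gaps and positional jitter;
#' roughly 80% of weighted time is spent at the home or workplace.
#'
#' @param scfg An `elf_sim_config`.
#' @param seed Root seed.
#' @param tz Local time zone for day boundaries.
#' @return List with `participants`, `gps`, `activity` and `truth` (planted
#'   commute days).
#' @export
generate_participants <- function(scfg = sim_config(), seed = 1L,
                                  tz = "America/Los_Angeles") {
  stopifnot(scfg$n_participants >= 1L)
  n <- scfg$n_participants
  participants <- withr::with_seed(sub_seed(seed, "profiles"), {
    sex <- c("male", rep("female", n - 1L))[seq_len(n)]
    tibble::tibble(
      participant_id = sprintf("P%02d", seq_len(n)),
      age = round(pmin(pmax(stats::rnorm(n, 49, 14), 25), 75), 1),
      sex = sex,
      height_cm = round(ifelse(sex == "male", stats::rnorm(n, 177, 6),
                               stats::rnorm(n, 163, 6)), 1),
      ethnicity_group = "caucasian",
      home_lon = scfg$centre_lon + stats::runif(n, -0.05, 0.05),
      home_lat = scfg$centre_lat + stats::runif(n, -0.04, 0.04),
      employed = stats::runif(n) < 0.9
    )
  })
  work <- withr::with_seed(sub_seed(seed, "workplaces"), {
    ang <- stats::runif(n, 0, 2 * pi)
    dist <- stats::runif(n, 4000, 12000)
    tibble::tibble(
      work_lon = participants$home_lon + dist * sin(ang) * deg_per_m_lon(scfg$centre_lat),
      work_lat = participants$home_lat + dist * cos(ang) * deg_per_m_lat()
    )
  })

  days <- scfg$start_date + seq_len(scfg$n_days) - 1L
  gps_rows <- list()
  commute_truth <- list()
  for (i in seq_len(n)) {
    for (d in seq_along(days)) {
      is_weekday <- as.integer(format(days[d], "%u")) <= 5L
      commute <- participants$employed[i] && is_weekday
      tr <- synth_day_trace(
        home = c(participants$home_lon[i], participants$home_lat[i]),
        workplace = c(work$work_lon[i], work$work_lat[i]),
        day = days[d], commute = commute, scfg = scfg, tz = tz,
        seed = sub_seed(seed, "gps", i, d))
      tr$participant_id <- participants$participant_id[i]
      gps_rows[[length(gps_rows) + 1L]] <- tr
      commute_truth[[length(commute_truth) + 1L]] <- tibble::tibble(
        participant_id = participants$participant_id[i], day = days[d],
        commute = commute)
    }
  }
  gps <- dplyr::bind_rows(gps_rows)[c("participant_id", "t", "lat", "lon")]

  activity_sources <- c("candles_incense", "burnt_food", "frying_grilling",
                        "wood_heat", "caulks_sealants", "spray_lubricant",
                        "moth_balls", "gasoline_exhaust", "cosmetics_lotions",
                        "household_cleaners", "hair_spray")
  rates <- c(0.10, 0.15, 0.20, 0.05, 0.05, 0.05, 0.02, 0.75, 0.90, 0.85, 0.80)
  activity <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    withr::with_seed(sub_seed(seed, "activity", i), {
      dplyr::bind_rows(lapply(seq_along(days), function(d) {
        if (stats::runif(1) > 0.99) return(NULL) # unfilled log day
        tibble::tibble(participant_id = participants$participant_id[i],
                       day = days[d], source = activity_sources,
                       response = ifelse(stats::runif(length(rates)) < rates,
                                         "yes", "no"))
      }))
    })
  }))

  list(participants = participants[setdiff(names(participants), "employed")],
       gps = gps, activity = activity,
       truth = list(commutes = dplyr::bind_rows(commute_truth),
                    employed = participants$employed))
}

synth_day_trace <- function(home, workplace, day, commute, scfg, tz, seed) {
  day_start <- as.POSIXct(paste(day, "00:00:00"), tz = tz)
  base_off <- c((0:95) * scfg$gps_interval_s, 86399)
  withr::with_seed(seed, {
    t_off <- base_off
    pos_t <- function(off) {
      # position (lon, lat) at each second-offset of the day
      if (!commute) {
        return(matrix(rep(home, each = length(off)), ncol = 2))
      }
      d_hw <- haversine_m(home[1], home[2], workplace[1], workplace[2])
      dur <- d_hw / scfg$commute_speed_ms
      t_leave1 <- 7.75 * 3600; t_arr1 <- t_leave1 + dur
      t_leave2 <- 17.25 * 3600; t_arr2 <- t_leave2 + dur
      frac <- rep(0, length(off))
      frac[off >= t_arr1 & off < t_leave2] <- 1
      mid1 <- off >= t_leave1 & off < t_arr1
      frac[mid1] <- (off[mid1] - t_leave1) / dur
      mid2 <- off >= t_leave2 & off < t_arr2
      frac[mid2] <- 1 - (off[mid2] - t_leave2) / dur
      cbind(home[1] + frac * (workplace[1] - home[1]),
            home[2] + frac * (workplace[2] - home[2]))
    }
    if (commute) {
      d_hw <- haversine_m(home[1], home[2], workplace[1], workplace[2])
      dur <- d_hw / scfg$commute_speed_ms
      burst1 <- seq(7.75 * 3600, 7.75 * 3600 + dur, by = scfg$burst_interval_s)
      burst2 <- seq(17.25 * 3600, 17.25 * 3600 + dur, by = scfg$burst_interval_s)
      t_off <- sort(unique(round(c(t_off, burst1 + stats::runif(length(burst1), 0, 5),
                                   burst2 + stats::runif(length(burst2), 0, 5)))))
      t_off <- t_off[t_off <= 86399]
      t_off <- t_off[c(TRUE, diff(t_off) >= 5)]
    }
    if (stats::runif(1) < scfg$p_gap) {
      g0 <- stats::runif(1, 0, 86399 - scfg$gap_len_s)
      t_off <- t_off[t_off < g0 | t_off > g0 + scfg$gap_len_s]
      if (!length(t_off)) t_off <- base_off[1]
    }
    xy <- pos_t(t_off)
    noise <- matrix(stats::rnorm(2 * length(t_off), 0, scfg$gps_noise_m), ncol = 2)
    tibble::tibble(
      t = day_start + t_off,
      lon = xy[, 1] + noise[, 1] * deg_per_m_lon(home[2]),
      lat = xy[, 2] + noise[, 2] * deg_per_m_lat()
    )
  })
}

# ---- full study ------------------------------------------------------------

#' Generate a complete synthetic study with ground truth
#'
#' Assembles all input streams the pipeline reads, plus a `truth` record of
#' every planted quantity: per-session validity labels, the below-LOD
#' (nondetect) set per band, wristband compliance labels and reason codes,
#' CCV batch outcomes, the planted latent correlation structure (drawn with
#' an in-sample-exact multivariate normal so the planted blocks hold at the
#' generated sample size), and - in constant-environment mode - the constant
#' daily exposure values the pipeline must recover.
#'
#' @param scfg An `elf_sim_config`.
#' @param seed Root seed; the same seed reproduces the study bit-for-bit.
#' @param cfg An `elf_config` (time zone, QC thresholds used to shape valid
#'   sessions).
#' @return A list of class `elf_study` (same shape as
#'   [read_study_bundle()]'s result) with an extra `truth` element.
#' @export
generate_study <- function(scfg = sim_config(), seed = 1L,
                           cfg = study_config(seed = seed)) {
  env <- generate_environment(scfg, seed)
  pp <- generate_participants(scfg, seed, tz = cfg$tz)
  days <- scfg$start_date + seq_len(scfg$n_days) - 1L
  n <- scfg$n_participants

  spiro <- synth_spirometry(pp$participants, days, scfg, cfg, seed)
  bands <- synth_wristbands(pp$participants, days, scfg, cfg, seed)
  chem <- synth_chemistry(bands$wristbands, scfg, seed)

  factors <- withr::with_seed(sub_seed(seed, "location_factors"), {
    p <- ncol(scfg$planted_sigma)
    # in-sample-exact draws need more rows than factors; tiny studies fall
    # back to plain multivariate normal draws
    f <- MASS::mvrnorm(n * scfg$n_days, mu = rep(0, p),
                       Sigma = scfg$planted_sigma,
                       empirical = n * scfg$n_days > p + 1L)
    f <- matrix(f, ncol = p)
    colnames(f) <- colnames(scfg$planted_sigma)
    grid <- expand.grid(day = days, participant_id = pp$participants$participant_id)
    dplyr::bind_cols(tibble::tibble(participant_id = as.character(grid$participant_id),
                                    day = grid$day),
                     tibble::as_tibble(f))
  })

  truth <- list(
    seed = seed,
    constant_environment = scfg$constant_environment,
    constants = if (scfg$constant_environment) list(
      pm25 = scfg$pm25_base, smoke = 16, tri_idw = 0, road_m = 0,
      chronic_no2 = 12, chronic_pm25 = 7
    ) else NULL,
    commutes = pp$truth$commutes,
    sessions = spiro$truth,
    band_compliance = bands$truth,
    nondetects = chem$truth$nondetects,
    ccv_batches = chem$truth$ccv_batches,
    planted_sigma = scfg$planted_sigma,
    location_factors = factors,
    severity = spiro$severity
  )

  # timestamps are instants; store them as UTC like the file readers do
  to_utc <- function(df) {
    for (nm in names(df)) {
      if (inherits(df[[nm]], "POSIXct")) attr(df[[nm]], "tzone") <- "UTC"
    }
    df
  }
  pp$gps <- to_utc(pp$gps)
  spiro$spirometry <- to_utc(spiro$spirometry)
  bands$wristbands <- to_utc(bands$wristbands)

  structure(list(
    participants = pp$participants, gps = pp$gps, spirometry = spiro$spirometry,
    wristbands = bands$wristbands, analytes = chem$analytes,
    activity = pp$activity,
    qc = list(blanks = chem$blanks, ccvs = chem$ccvs), env = env,
    truth = truth
  ), class = "elf_study")
}

synth_spirometry <- function(participants, days, scfg, cfg, seed) {
  slot_hours <- c(morning = 7.5, afternoon = 12.5, evening = 19.5)
  rows <- list()
  truth <- list()
  severity <- withr::with_seed(sub_seed(seed, "severity"), {
    stats::runif(nrow(participants), scfg$severity_range[1], scfg$severity_range[2])
  })
  for (i in seq_len(nrow(participants))) {
    p <- participants[i, ]
    pred <- hankinson_fev1_pred(p$age, p$sex, p$height_cm, p$ethnicity_group)
    true_base <- pred * severity[i]
    for (d in seq_along(days)) {
      for (sl in names(slot_hours)) {
        res <- withr::with_seed(sub_seed(seed, "spiro", i, d, sl), {
          if (stats::runif(1) < scfg$p_session_skip) NULL else {
          true_fev1 <- true_base * (1 + stats::rnorm(1, 0, 0.02))
          invalid <- stats::runif(1) < scfg$p_invalid
          mode <- if (invalid) sample(c("short-duration", "excess-gap"), 1L) else NA_character_
          shortfall <- stats::runif(3, 0, min(scfg$sigma_blow_l, 0.8 * cfg$repeatability_l / 2))
          fev1 <- true_fev1 - shortfall
          dur <- stats::runif(3, cfg$min_blow_s + 0.5, cfg$min_blow_s + 4)
          if (invalid && mode == "short-duration") {
            dur <- stats::runif(3, 3, cfg$min_blow_s - 1)
          }
          if (invalid && mode == "excess-gap") {
            top <- which.max(fev1)
            fev1[top] <- fev1[top] + cfg$repeatability_l + 0.1 + stats::runif(1, 0, 0.2)
          }
          # session-level FEV1/FVC ratio with a tightly clamped per-blow
          # jitter: keeps the top-two FVC gap within the repeatability rule
          # for sessions planted as valid
          ratio <- stats::runif(1, 0.75, 0.92) +
            pmin(pmax(stats::rnorm(3, 0, 0.001), -0.003), 0.003)
          t0 <- as.POSIXct(paste(days[d], "00:00:00"), tz = cfg$tz) +
            slot_hours[[sl]] * 3600 + stats::runif(1, -600, 600)
          list(blows = tibble::tibble(
            participant_id = p$participant_id, slot = sl,
            blow_index = 1:3, fev1_l = round(fev1, 3),
            fvc_l = round(fev1 / ratio, 3),
            pef_lmin = round(stats::runif(3, 300, 600), 0),
            duration_s = round(dur, 1), t = t0 + (0:2) * 40),
            label = tibble::tibble(
              participant_id = p$participant_id, day = days[d], slot = sl,
              planted_invalid = invalid, mode = mode,
              true_fev1 = true_fev1))
          }
        })
        if (is.null(res)) next
        rows[[length(rows) + 1L]] <- res$blows
        truth[[length(truth) + 1L]] <- res$label
      }
    }
  }
  list(spirometry = dplyr::bind_rows(rows), truth = dplyr::bind_rows(truth),
       severity = severity)
}

synth_wristbands <- function(participants, days, scfg, cfg, seed) {
  rows <- list()
  truth <- list()
  for (i in seq_len(nrow(participants))) {
    pid <- participants$participant_id[i]
    t_next <- as.POSIXct(paste(days[1], "08:00:00"), tz = cfg$tz)
    for (d in seq_along(days)) {
      res <- withr::with_seed(sub_seed(seed, "band", i, d), {
        lost <- stats::runif(1) < scfg$p_lost
        noncomp <- !lost && stats::runif(1) < scfg$band_noncompliance
        mode <- if (noncomp) {
          sample(c("wear-window", "wear-window", "wear-window", "missing-times",
                   "not-sealed", "not-worn-singly"), 1L)
        } else NA_character_
        wear_h <- if (noncomp && mode == "wear-window") {
          if (stats::runif(1) < 0.7) stats::runif(1, 32.5, 38) else stats::runif(1, 10, 15.5)
        } else {
          min(max(stats::rnorm(1, 24, 1.5), 17), 31)
        }
        t_on <- t_next
        t_off <- t_on + wear_h * 3600
        sealed <- !(noncomp && mode == "not-sealed")
        worn_singly <- !(noncomp && mode == "not-worn-singly")
        if (lost) { t_off <- t_on + NA_real_; sealed <- NA; worn_singly <- NA }
        if (noncomp && mode == "missing-times") t_off <- t_on + NA_real_
        list(row = tibble::tibble(
          participant_id = pid, band_id = sprintf("B_%s_%d", pid, d),
          t_on = t_on, t_off = t_off,
          sealed = sealed, worn_singly = worn_singly, returned = !lost),
          label = tibble::tibble(
            participant_id = pid, day = days[d],
            band_id = sprintf("B_%s_%d", pid, d),
            lost = lost, planted_noncompliant = noncomp | lost,
            mode = if (lost) "lost" else mode, wear_h = wear_h),
          t_end = if (is.na(t_off)) t_on + wear_h * 3600 else t_off)
      })
      rows[[length(rows) + 1L]] <- res$row
      truth[[length(truth) + 1L]] <- res$label
      nominal_next <- as.POSIXct(paste(days[min(d + 1L, length(days))], "07:30:00"),
                                 tz = cfg$tz)
      t_next <- max(res$t_end + 900, nominal_next)
    }
  }
  list(wristbands = dplyr::bind_rows(rows), truth = dplyr::bind_rows(truth))
}

synth_chemistry <- function(wristbands, scfg, seed) {
  panel <- pah_panel()
  n_a <- nrow(panel)
  det_p <- withr::with_seed(sub_seed(seed, "detection_probs"), {
    p <- numeric(n_a)
    names(p) <- panel$analyte
    p[PAH_CORE_NAMES] <- 1
    rest <- setdiff(panel$analyte, PAH_CORE_NAMES)
    varies <- sample(rest, scfg$n_variable_analytes)
    p[varies] <- stats::runif(length(varies), 0.1, 0.8)
    p
  })
  bands <- wristbands$band_id
  analyte_rows <- list()
  nd_rows <- list()
  for (b in seq_along(bands)) {
    withr::with_seed(sub_seed(seed, "chem", bands[b]), {
      detected <- unname(stats::runif(n_a) < det_p)
      conc <- ifelse(detected,
                     panel$lod * 10^stats::runif(n_a, 0.15, 1.6),
                     panel$lod * 10^-stats::runif(n_a, 0.1, 1))
      recovery <- round(stats::runif(1, 0.7, 1.2), 3)
      analyte_rows[[b]] <- tibble::tibble(
        band_id = bands[b], analyte = panel$analyte,
        raw = ifelse(detected, as.character(signif(conc, 6)), "ND"),
        lod = panel$lod, recovery = recovery)
      nd_rows[[b]] <- tibble::tibble(
        band_id = bands[b], analyte = panel$analyte[!detected])
    })
  }
  analytes <- dplyr::bind_rows(analyte_rows)

  blanks <- withr::with_seed(sub_seed(seed, "blanks"), {
    det_bl <- sample(panel$analyte[panel$analyte %in% PAH_CORE_NAMES], 6L)
    dplyr::bind_rows(lapply(1:3, function(k) {
      tibble::tibble(
        analyte = panel$analyte,
        raw = ifelse(panel$analyte %in% det_bl,
                     as.character(signif(panel$lod * stats::runif(n_a, 1.05, 1.6), 6)),
                     "ND"),
        lod = panel$lod)
    }))
  })

  n_batches <- max(1L, nrow(wristbands) %/% scfg$ccv_every)
  ccv_rows <- list()
  batch_truth <- list()
  for (k in seq_len(n_batches)) {
    withr::with_seed(sub_seed(seed, "ccv", k), {
      true <- panel$lod * 20
      fail <- stats::runif(1) < scfg$ccv_fail_rate
      err <- stats::runif(n_a, -0.15, 0.15)
      if (fail) {
        off <- sample(n_a, ceiling(0.25 * n_a))
        err[off] <- 0.5
      }
      ccv_rows[[k]] <- tibble::tibble(
        position = k * scfg$ccv_every, analyte = panel$analyte,
        measured = round(true * (1 + err), 4), true = true)
      batch_truth[[k]] <- tibble::tibble(position = k * scfg$ccv_every,
                                         planted_fail = fail)
    })
  }

  list(analytes = analytes, blanks = blanks, ccvs = dplyr::bind_rows(ccv_rows),
       truth = list(nondetects = dplyr::bind_rows(nd_rows),
                    ccv_batches = dplyr::bind_rows(batch_truth)))
}
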