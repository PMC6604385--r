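# Per-fix estimators and time-weighted aggregation.

test_that("interval weights follow the capped-interval rule", {
  t0 <- as.POSIXct("2015-08-17 00:00:00", tz = "UTC")
  expect_equal(interval_weights(t0 + c(0, 900, 1800), 3600), c(900, 900, 900))
  w <- interval_weights(t0 + c(0, 900, 8100), 3600)
  expect_equal(w, c(900, 3600, 3600)) # 7200 s gap capped at the max gap
  expect_equal(interval_weights(t0, 3600), 3600) # single fix
  expect_error(interval_weights(t0 + c(900, 0), 3600), "increasing")
})

test_that("time-weighted average handles constants, weights and missings", {
  expect_equal(time_weighted_average(c(7, 7, 7), c(1, 5, 2)), 7)
  expect_equal(time_weighted_average(c(10, 20), c(1, 3)), 17.5)
  expect_equal(time_weighted_average(c(5, NA), c(10, 10)), 5)
  expect_true(is.na(time_weighted_average(c(NA_real_, NA_real_), c(1, 1))))
})

test_that("nearest-monitor PM2.5 uses hour flooring and distance tie-breaks", {
  day <- as.Date("2015-08-17")
  hours <- seq(as.POSIXct(paste(day, "00:00:00"), tz = "UTC"), by = 3600,
               length.out = 24)
  monitors <- tibble::tibble(
    monitor_id = c("M02", "M01"),
    lon = c(CENTRE_LON + 0.01, CENTRE_LON + 0.1), # ~1 km and ~10 km east
    lat = c(CENTRE_LAT, CENTRE_LAT))
  series <- dplyr::bind_rows(
    tibble::tibble(monitor_id = "M02", t = hours, pm25 = 100 + seq_along(hours)),
    tibble::tibble(monitor_id = "M01", t = hours, pm25 = 200 + seq_along(hours)))
  t_fix <- as.POSIXct(paste(day, "10:07:00"), tz = "UTC")
  # nearer monitor wins; 10:07 floors to the hour-10 value (index 11)
  expect_equal(fix_pm25(CENTRE_LON, CENTRE_LAT, t_fix, monitors, series), 111)
  # equidistant monitors: lowest monitor id wins
  mon_tie <- tibble::tibble(monitor_id = c("M02", "M01"),
                            lon = CENTRE_LON + c(0.01, -0.01),
                            lat = c(CENTRE_LAT, CENTRE_LAT))
  expect_equal(fix_pm25(CENTRE_LON, CENTRE_LAT, t_fix, mon_tie, series), 211)
  # missing hour falls back to the nearest hour within 3 h
  series_gap <- series[!(series$monitor_id == "M02" &
                           format(series$t, "%H") == "10"), ]
  expect_equal(fix_pm25(CENTRE_LON, CENTRE_LAT, t_fix, monitors, series_gap), 110)
  expect_error(fix_pm25(CENTRE_LON, CENTRE_LAT, t_fix, monitors[0, ], series),
               "no monitors")
})

test_that("inverse-distance emissions weighting matches the closed form", {
  # one source 100 m north, E = 1000, power 1 -> 10
  src <- tibble::tibble(source_id = "S1", emissions = 1000,
                        lon = CENTRE_LON, lat = CENTRE_LAT + 100 / M_PER_DEG)
  v1 <- fix_tri_idw(CENTRE_LON, CENTRE_LAT, src, power = 1, floor_m = 10)
  expect_equal(v1, 10, tolerance = 1e-4)
  # two equal equidistant sources double the value
  src2 <- dplyr::bind_rows(src, dplyr::mutate(src, lat = CENTRE_LAT - 100 / M_PER_DEG))
  expect_equal(fix_tri_idw(CENTRE_LON, CENTRE_LAT, src2), 2 * v1, tolerance = 1e-9)
  # fix on top of a source: clamped distance, matches explicit-loop oracle
  on_top <- fix_tri_idw(src$lon, src$lat, src2, power = 1.5, floor_m = 10)
  oracle <- 0
  for (j in 1:2) {
    d <- max(haversine_m(src$lon, src$lat, src2$lon[j], src2$lat[j]), 10)
    oracle <- oracle + src2$emissions[j] / d^1.5
  }
  expect_equal(on_top, oracle, tolerance = 1e-12)
  expect_true(is.finite(on_top))
  expect_equal(fix_tri_idw(CENTRE_LON, CENTRE_LAT, src[0, ]), 0)
})

test_that("IDW is non-increasing in distance and linear in emissions", {
  withr::with_seed(41, {
    for (rep in 1:10) {
      dists <- sort(runif(8, 50, 20000))
      pw <- runif(1, 0.5, 2)
      vals <- vapply(dists, function(d) {
        src <- tibble::tibble(source_id = "S", emissions = 500,
                              lon = CENTRE_LON, lat = CENTRE_LAT + d / M_PER_DEG)
        fix_tri_idw(CENTRE_LON, CENTRE_LAT, src, power = pw)
      }, numeric(1))
      expect_true(all(diff(vals) <= 1e-12))
      src <- tibble::tibble(source_id = "S", emissions = 500,
                            lon = CENTRE_LON + 0.01, lat = CENTRE_LAT)
      expect_equal(fix_tri_idw(CENTRE_LON, CENTRE_LAT, dplyr::mutate(src, emissions = 1000)),
                   2 * fix_tri_idw(CENTRE_LON, CENTRE_LAT, src), tolerance = 1e-12)
    }
  })
})

test_that("road length in buffer matches the chord geometry", {
  expect_equal(fix_road_length(CENTRE_LON, CENTRE_LAT, road_through(0), 100),
               200, tolerance = 1e-3)
  expect_equal(fix_road_length(CENTRE_LON, CENTRE_LAT, road_through(101), 100), 0)
  expect_equal(fix_road_length(CENTRE_LON, CENTRE_LAT, road_through(60), 100),
               2 * sqrt(100^2 - 60^2), tolerance = 1e-3)
  expect_equal(fix_road_length(CENTRE_LON, CENTRE_LAT,
                               road_through(0)[0, ], 100), 0)
})

test_that("road length is additive over disjoint segments and rotation-invariant", {
  r <- 100
  two <- dplyr::bind_rows(road_through(40), road_through(-55, bearing_deg = 90))
  total <- fix_road_length(CENTRE_LON, CENTRE_LAT, two, r)
  parts <- fix_road_length(CENTRE_LON, CENTRE_LAT, road_through(40), r) +
    fix_road_length(CENTRE_LON, CENTRE_LAT, road_through(-55, 90), r)
  expect_equal(total, parts, tolerance = 1e-6 * r)
  withr::with_seed(42, {
    for (ang in runif(6, 0, 360)) {
      expect_equal(fix_road_length(CENTRE_LON, CENTRE_LAT, road_through(60, ang), r),
                   2 * sqrt(r^2 - 60^2), tolerance = 1e-6 * r + 1e-3)
    }
  })
})

test_that("NDVI-by-class sums match constant fields and a brute-force pixel loop", {
  classes <- stats::setNames(1:6, c("urban", "hay", "grass", "trees",
                                    "wetlands", "crops"))
  lc <- const_raster(classes[["hay"]], classes = classes)
  nd <- const_raster(0.5)
  # constant field: value is 0.5 x number of pixel centres in the disc
  got <- fix_ndvi_class(CENTRE_LON, CENTRE_LAT, nd, lc, "hay", 250)
  ctr <- expand.grid(row = 1:20, col = 1:20)
  cc <- cbind(lc$xll + (ctr$col - 0.5) * lc$cellsize,
              lc$yll + (20 - ctr$row + 0.5) * lc$cellsize)
  n_in <- sum(haversine_m(cc[, 1], cc[, 2], CENTRE_LON, CENTRE_LAT) <= 250)
  expect_gt(n_in, 0)
  expect_equal(got, 0.5 * n_in)
  # no pixels of the class in the disc -> 0
  expect_equal(fix_ndvi_class(CENTRE_LON, CENTRE_LAT, nd, lc, "trees", 250), 0)
  # outside the raster extent -> missing
  expect_true(is.na(fix_ndvi_class(CENTRE_LON + 5, CENTRE_LAT, nd, lc, "hay", 250)))
  # random rasters against an explicit pixel loop (exact match)
  withr::with_seed(43, {
    for (rep in 1:20) {
      vals <- matrix(runif(400), 20, 20)
      cls <- matrix(sample(1:6, 400, replace = TRUE), 20, 20)
      ndr <- const_raster(0); ndr$values <- vals
      lcr <- const_raster(0, classes = classes); lcr$values <- cls
      fx_lon <- CENTRE_LON + runif(1, -0.02, 0.02)
      fx_lat <- CENTRE_LAT + runif(1, -0.02, 0.02)
      target <- sample(1:6, 1)
      radius <- runif(1, 100, 600)
      brute <- 0
      for (rr in 1:20) for (cc2 in 1:20) {
        plon <- ndr$xll + (cc2 - 0.5) * ndr$cellsize
        plat <- ndr$yll + (20 - rr + 0.5) * ndr$cellsize
        if (haversine_m(plon, plat, fx_lon, fx_lat) <= radius &&
            cls[rr, cc2] == target) {
          brute <- brute + vals[rr, cc2]
        }
      }
      expect_identical(fix_ndvi_class(fx_lon, fx_lat, ndr, lcr, target, radius),
                       brute)
    }
  })
})

test_that("smoke assignment maps classes and resolves overlaps upward", {
  smap <- c(low = 5, medium = 16, high = 17)
  med <- tibble::tibble(smoke_id = "a", class = "medium",
                        rings = list(list(square_ring(CENTRE_LON, CENTRE_LAT, 0.1))))
  expect_equal(fix_smoke_density(CENTRE_LON, CENTRE_LAT, med, smap), 16)
  both <- dplyr::bind_rows(med, tibble::tibble(
    smoke_id = "b", class = "low",
    rings = list(list(square_ring(CENTRE_LON, CENTRE_LAT, 0.2)))))
  both$class <- c("low", "high")
  expect_equal(fix_smoke_density(CENTRE_LON, CENTRE_LAT, both, smap), 17)
  expect_equal(fix_smoke_density(CENTRE_LON, CENTRE_LAT, med[0, ], smap), 0)
  # outside every polygon: nearest within range, else no smoke
  far <- CENTRE_LON + 1.2
  expect_equal(fix_smoke_density(far, CENTRE_LAT, med, smap, max_dist_m = 2e5), 16)
  expect_equal(fix_smoke_density(far, CENTRE_LAT, med, smap, max_dist_m = 1e4), 0)
  bad <- dplyr::mutate(med, class = "severe")
  expect_error(fix_smoke_density(CENTRE_LON, CENTRE_LAT, bad, smap), "severe")
})

test_that("wildfire distance is the great-circle minimum in km", {
  fires <- tibble::tibble(fire_id = "F1", lon = CENTRE_LON,
                          lat = CENTRE_LAT + 25 / 111.31949)
  expect_equal(fix_fire_distance(CENTRE_LON, CENTRE_LAT, fires), 25,
               tolerance = 0.1 / 25)
  expect_equal(fix_fire_distance(fires$lon, fires$lat, fires), 0)
  two <- dplyr::bind_rows(fires, tibble::tibble(fire_id = "F2", lon = CENTRE_LON,
                                                lat = CENTRE_LAT + 1))
  expect_equal(fix_fire_distance(CENTRE_LON, CENTRE_LAT, two),
               min(fix_fire_distance(CENTRE_LON, CENTRE_LAT, fires),
                   fix_fire_distance(CENTRE_LON, CENTRE_LAT, two[2, ])))
  expect_true(is.na(fix_fire_distance(CENTRE_LON, CENTRE_LAT, fires[0, ])))
})

test_that("chronic extraction uses the half-open cell convention", {
  r <- elf_raster(matrix(1:4, 2, 2, byrow = TRUE), 0, 0, 1)
  # cells: row1 (north, lat in [1,2)) = 1,2; row2 (lat in [0,1)) = 3,4
  expect_equal(chronic_at_residence(0.5, 0.5, r), 3)
  expect_equal(chronic_at_residence(1.5, 1.5, r), 2)
  expect_equal(chronic_at_residence(1, 1, r), 2) # boundary: floor on both axes
  expect_equal(chronic_at_residence(CENTRE_LON, CENTRE_LAT, const_raster(9)), 9)
  expect_warning(v <- chronic_at_residence(10, 10, r), "outside")
  expect_true(is.na(v))
})

test_that("driving needs sustained speed over consecutive intervals", {
  day <- as.Date("2015-08-17")
  stationary <- mk_trace(c(0, 900, 1800), day = day)
  expect_equal(classify_driving(stationary, 8)$fraction, 0)
  # constant 20 m/s northbound at 60 s spacing
  n <- 10
  fast <- mk_trace(seq(0, by = 60, length.out = n),
                   lat = CENTRE_LAT + (0:(n - 1)) * 1200 / 111319.49, day = day)
  expect_equal(classify_driving(fast, 8)$fraction, 1)
  # one isolated fast interval among slow ones is not driving
  lat_seq <- CENTRE_LAT + c(0, 1, 2, 1202, 1203, 1204) / 111319.49
  mixed <- mk_trace(seq(0, by = 60, length.out = 6), lat = lat_seq, day = day)
  res <- classify_driving(mixed, 8)
  expect_false(any(res$intervals$driving))
  expect_equal(res$fraction, 0)
})

test_that("daily metrics equal fix-level values in a constant environment", {
  env <- tiny_env(pm25 = 10)
  cfg <- study_config()
  trace <- mk_trace(seq(0, 86399, by = 900),
                    lon = CENTRE_LON + 0.002, lat = CENTRE_LAT + 0.002)
  rec <- daily_exposure(trace, env, cfg, day = as.Date("2015-08-17"))
  expect_equal(rec$pm25, 10)
  expect_equal(rec$smoke, 16)
  expect_equal(rec$tri_idw, 0)
  expect_equal(rec$fire_km_min, rec$fire_km_mean, tolerance = 1e-6)
  expect_equal(rec$driving_fraction, 0)
  # half the day at PM2.5 = 10, half at 20 -> 15
  env2 <- tiny_env(pm25 = 10)
  series <- env2$monitor_series
  half <- as.POSIXct("2015-08-17 12:00:00", tz = "UTC")
  series$pm25[series$t >= half] <- 20
  env2$monitor_series <- series
  tr2 <- mk_trace(seq(0, 86399, by = 900))
  rec2 <- daily_exposure(tr2, env2, cfg, day = as.Date("2015-08-17"))
  w <- interval_weights(tr2$t, cfg$max_gap_s)
  vals <- ifelse(tr2$t < half, 10, 20)
  expect_equal(rec2$pm25, sum(w * vals) / sum(w), tolerance = 1e-12)
  # empty trace -> all missing
  rec3 <- daily_exposure(tr2[0, ], env, cfg)
  expect_true(all(is.na(unlist(rec3))))
})

test_that("daily exposure equals an explicit fix-by-fix loop oracle", {
  env <- tiny_env()
  # make the environment heterogeneous so the check is non-trivial
  env$sources <- tibble::tibble(source_id = c("S1", "S2"),
                                emissions = c(2000, 5000),
                                lon = CENTRE_LON + c(0.01, -0.02),
                                lat = CENTRE_LAT + c(0.015, -0.01))
  env$ndvi$values <- matrix(seq(0, 1, length.out = 400), 20, 20)
  env$landcover$values <- matrix(rep(1:6, length.out = 400), 20, 20)
  series <- env$monitor_series
  series$pm25 <- 5 + seq_along(series$pm25) %% 7
  env$monitor_series <- series
  cfg <- study_config()
  day <- as.Date("2015-08-17")
  withr::with_seed(44, {
    for (rep in 1:10) {
      offs <- sort(sample(0:86000, 20))
      offs <- offs[c(TRUE, diff(offs) > 0)]
      trace <- mk_trace(offs, lon = CENTRE_LON + runif(length(offs), -0.02, 0.02),
                        lat = CENTRE_LAT + runif(length(offs), -0.02, 0.02))
      got <- daily_exposure(trace, env, cfg, day = day)
      w <- interval_weights(trace$t, cfg$max_gap_s)
      agg <- function(f) {
        per_fix <- vapply(seq_len(nrow(trace)), function(i) f(i), numeric(1))
        ok <- !is.na(per_fix)
        sum(per_fix[ok] * w[ok]) / sum(w[ok])
      }
      expect_equal(got$pm25, agg(function(i) {
        fix_pm25(trace$lon[i], trace$lat[i], trace$t[i], env$monitors,
                 env$monitor_series)
      }), tolerance = 1e-9)
      expect_equal(got$tri_idw, agg(function(i) {
        fix_tri_idw(trace$lon[i], trace$lat[i], env$sources,
                    cfg$idw_power, cfg$idw_floor_m)
      }), tolerance = 1e-9)
      expect_equal(got$road_m, agg(function(i) {
        fix_road_length(trace$lon[i], trace$lat[i],
                        env$roads[env$roads$class %in% c("highway", "expressway"), ],
                        cfg$road_radius_m)
      }), tolerance = 1e-9)
      expect_equal(got$ndvi_trees, agg(function(i) {
        fix_ndvi_class(trace$lon[i], trace$lat[i], env$ndvi, env$landcover,
                       "trees", cfg$ndvi_radius_m)
      }), tolerance = 1e-9)
      expect_equal(got$smoke, agg(function(i) {
        fix_smoke_density(trace$lon[i], trace$lat[i],
                          env$smoke[env$smoke$day == day, ], cfg$smoke_map,
                          cfg$smoke_max_dist_m)
      }), tolerance = 1e-9)
    }
  })
})

test_that("outputs are invariant to fix order after re-sorting", {
  env <- tiny_env()
  cfg <- study_config()
  withr::with_seed(45, {
    trace <- mk_trace(sort(sample(0:86000, 15)),
                      lon = CENTRE_LON + runif(15, -0.01, 0.01),
                      lat = CENTRE_LAT + runif(15, -0.01, 0.01))
    shuffled <- trace[sample(nrow(trace)), ]
    resorted <- shuffled[order(shuffled$t), ]
    expect_equal(daily_exposure(trace, env, cfg, day = as.Date("2015-08-17")),
                 daily_exposure(resorted, env, cfg, day = as.Date("2015-08-17")))
  })
})
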