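# Readers, writers, schema validation and round trips.

test_that("a written study round-trips through the bundle reader", {
  scfg <- test_sim_config(n_participants = 1, n_days = 2)
  st <- generate_study(scfg, seed = 13)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  back <- read_study_bundle(dir)
  expect_equal(nrow(back$participants), 1)
  expect_equal(back$participants$home_lat, st$participants$home_lat,
               tolerance = 1e-9)
  expect_equal(nrow(back$gps), nrow(st$gps))
  expect_equal(as.numeric(back$gps$t), round(as.numeric(st$gps$t)))
  expect_equal(back$gps$lat, st$gps$lat, tolerance = 1e-9)
  expect_equal(back$analytes$raw, st$analytes$raw)
  expect_equal(back$env$ndvi$values, st$env$ndvi$values, tolerance = 1e-9)
  expect_equal(back$env$landcover$classes, st$env$landcover$classes)
  expect_equal(nrow(back$env$smoke), nrow(st$env$smoke))
  # missing t_off (lost band) survives as missing
  expect_identical(is.na(back$wristbands$t_off), is.na(st$wristbands$t_off))
})

test_that("a no-gap no-burst schedule yields 97 fixes per day, 679 per week", {
  scfg <- test_sim_config(n_participants = 1, n_days = 7, p_gap = 0)
  pp <- generate_participants(scfg, seed = 2)
  profile_employed <- pp$truth$employed[1]
  trace <- pp$gps
  per_day <- trace |>
    dplyr::mutate(day = as.Date(t, tz = "America/Los_Angeles")) |>
    dplyr::count(day)
  if (!profile_employed) {
    expect_equal(nrow(trace), 679)
    expect_true(all(per_day$n == 97))
  } else {
    expect_true(all(per_day$n >= 97)) # commute bursts densify
  }
  # median inter-fix interval on a burst-free day is the 15-min schedule
  weekend <- trace |>
    dplyr::mutate(day = as.Date(t, tz = "America/Los_Angeles")) |>
    dplyr::filter(format(day, "%u") == "6")
  expect_equal(stats::median(diff(as.numeric(weekend$t))), 900)
})

test_that("schema violations are rejected with named errors", {
  expect_error(validate_participants(tibble::tibble(participant_id = "P1")),
               "missing column 'age'")
  good <- tibble::tibble(participant_id = "P1", age = 40, sex = "female",
                         height_cm = 165, ethnicity_group = "caucasian",
                         home_lat = 44, home_lon = -123)
  expect_silent(validate_participants(good))
  expect_error(validate_participants(dplyr::mutate(good, age = -1)), "age")
  expect_error(validate_participants(dplyr::mutate(good, height_cm = 0)), "height")
  t0 <- as.POSIXct("2015-08-17 00:00:00", tz = "UTC")
  gps <- tibble::tibble(participant_id = "P1", t = t0 + c(0, 900),
                        lat = c(44, 44), lon = c(-123, -123))
  expect_silent(validate_gps(gps))
  expect_error(validate_gps(dplyr::mutate(gps, lat = c(44, 91))), "lat")
  expect_error(validate_gps(dplyr::mutate(gps, lon = c(-181, -123))), "lon")
  expect_error(validate_gps(gps[c(2, 1), ]), "increasing")
  wb <- tibble::tibble(participant_id = "P1", band_id = "b1", t_on = t0,
                       t_off = t0 + 3600, sealed = TRUE, worn_singly = TRUE)
  expect_error(validate_wristbands(dplyr::mutate(wb, t_off = t0 - 1)), "after")
  an <- tibble::tibble(band_id = "b", analyte = "x", raw = "oops", lod = 1,
                       recovery = 1)
  expect_error(validate_analytes(an), "number or 'ND'")
  expect_error(validate_analytes(dplyr::mutate(an, raw = "1", lod = 0)), "lod")
  act <- tibble::tibble(participant_id = "P1", day = as.Date("2015-08-17"),
                        source = "candles_incense", response = "maybe")
  expect_error(validate_activity(act), "yes")
})

test_that("an unknown smoke density class is rejected by name", {
  scfg <- test_sim_config(n_participants = 1, n_days = 1)
  st <- generate_study(scfg, seed = 3)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  smoke <- read_geojson_polygons(file.path(dir, "smoke.geojson"),
                                 c("smoke_id", "day", "class"))
  if (nrow(smoke) == 0L) {
    smoke <- tibble::tibble(smoke_id = "k", day = "2015-08-17", class = "low",
                            rings = list(list(square_ring(CENTRE_LON, CENTRE_LAT, 0.1))))
  }
  smoke$class[1] <- "severe"
  write_geojson_polygons(smoke, file.path(dir, "smoke.geojson"))
  expect_error(read_study_bundle(dir), "low, medium, high")
})

test_that("unparseable timestamps carry line numbers", {
  scfg <- test_sim_config(n_participants = 1, n_days = 1)
  st <- generate_study(scfg, seed = 3)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  gps <- readr::read_csv(file.path(dir, "gps.csv"), show_col_types = FALSE,
                         col_types = readr::cols(timestamp = readr::col_character()))
  gps$timestamp[3] <- "not-a-time"
  readr::write_csv(gps, file.path(dir, "gps.csv"))
  expect_error(read_study_bundle(dir), "line\\(s\\) 4")
})

test_that("daily-record outputs round-trip losslessly and reject duplicates", {
  scfg <- test_sim_config(n_participants = 2, n_days = 2)
  st <- generate_study(scfg, seed = 5)
  res <- run_study(st, study_config(seed = 5))
  dir <- withr::local_tempdir()
  write_outputs(res$records, dir, compliance = res$compliance,
                correlation = res$correlation, band_values = res$band_values)
  back <- read_outputs(dir)
  num <- vapply(res$records, is.numeric, logical(1))
  for (v in names(res$records)[num]) {
    expect_equal(back$records[[v]], res$records[[v]], tolerance = 1e-9)
  }
  expect_equal(nrow(back$records), 4) # participants x days
  expect_equal(back$correlation$order, res$correlation$order)
  expect_equal(unname(back$correlation$matrix), unname(res$correlation$matrix),
               tolerance = 1e-9)
  dup <- dplyr::bind_rows(res$records, res$records[1, ])
  expect_error(write_outputs(dup, dir), "duplicate")
  expect_error(write_outputs(res$records[0, ], dir), "no daily records")
})

test_that("ASCII grid rasters and GeoJSON layers round-trip", {
  r <- elf_raster(matrix(stats::runif(35), 5, 7), -123.5, 44.0, 0.01)
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(r, path)
  back <- read_ascii_grid(path)
  expect_equal(back$values, r$values, tolerance = 1e-12)
  expect_equal(back$cellsize, r$cellsize)
  expect_equal(back$xll, r$xll)
  pts <- tibble::tibble(lon = c(-123.1, -123.2), lat = c(44.1, 44.2),
                        source_id = c("S1", "S2"), emissions = c(10.5, 2e4))
  pj <- withr::local_tempfile(fileext = ".geojson")
  write_geojson_points(pts, pj)
  expect_equal(read_geojson_points(pj, c("source_id", "emissions")), pts)
  poly <- tibble::tibble(rings = list(list(square_ring(-123, 44, 0.1))),
                         smoke_id = "k", class = "low")
  write_geojson_polygons(poly, pj)
  back_p <- read_geojson_polygons(pj, c("smoke_id", "class"))
  expect_equal(back_p$rings[[1]][[1]], poly$rings[[1]][[1]])
})

test_that("config JSON round-trips and rejects unknown fields", {
  cfg <- study_config(idw_power = 2, road_radius_m = 150)
  path <- withr::local_tempfile(fileext = ".json")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$idw_power, 2)
  expect_equal(back$road_radius_m, 150)
  expect_equal(back$smoke_map, cfg$smoke_map)
  jsonlite::write_json(list(bogus_field = 1), path, auto_unbox = TRUE)
  expect_error(read_config(path), "bogus_field")
  expect_error(study_config(ccv_tol = -1), "ccv_tol")
  expect_error(study_config(smoke_map = c(low = 5, medium = 16)), "smoke_map")
})
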