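# Participant-day joining, compliance metrics, correlation structure and
# activity summaries.

test_that("daily records join all streams losslessly", {
  scfg <- test_sim_config(n_participants = 3, n_days = 3, p_gap = 0,
                          p_session_skip = 0, band_noncompliance = 0, p_lost = 0)
  st <- generate_study(scfg, seed = 31)
  cfg <- study_config(seed = 31)
  built <- build_daily_records(st, cfg)
  expect_equal(nrow(built$records), 9)
  # every compliant band appears in exactly one record
  expect_setequal(built$records$band_id, st$wristbands$band_id)
  expect_false(any(duplicated(built$records$band_id)))
  # a valid session feeds a percent-predicted value for its slot
  q <- built$spiro_qc
  for (i in seq_len(nrow(built$records))) {
    r <- built$records[i, ]
    for (sl in c("morning", "afternoon", "evening")) {
      s <- q[q$participant_id == r$participant_id & q$day == r$day &
               q$slot == sl, ]
      if (nrow(s) == 1 && s$valid) {
        expect_false(is.na(r[[paste0("pct_pred_", sl)]]))
      } else {
        expect_true(is.na(r[[paste0("pct_pred_", sl)]]))
      }
    }
  }
})

test_that("non-compliant bands keep location data but lose band fields", {
  scfg <- test_sim_config(n_participants = 2, n_days = 3, band_noncompliance = 0.9,
                          p_lost = 0, p_gap = 0)
  st <- generate_study(scfg, seed = 33)
  cfg <- study_config(seed = 33)
  res <- build_daily_records(st, cfg)
  bad_days <- res$records[!res$records$band_compliant, ]
  expect_gt(nrow(bad_days), 0)
  expect_true(all(is.na(bad_days$band_detections)))
  # location data survives wherever the day has GPS coverage (long wear can
  # drift a band's day past the end of the GPS record)
  gps_days <- unique(as.Date(st$gps$t, tz = cfg$tz))
  covered <- bad_days[bad_days$day %in% gps_days, ]
  expect_gt(nrow(covered), 0)
  expect_true(all(!is.na(covered$pm25)))
  # non-compliant bands contribute no band_values rows
  bad_ids <- res$bands_qc$band_id[!res$bands_qc$compliant]
  joined <- dplyr::semi_join(
    res$band_values,
    res$bands_qc[res$bands_qc$band_id %in% bad_ids,
                 c("participant_id", "day")],
    by = c("participant_id", "day"))
  expect_equal(nrow(joined), 0)
})

test_that("overlapping wristband wear intervals are rejected", {
  scfg <- test_sim_config(n_participants = 1, n_days = 2)
  st <- generate_study(scfg, seed = 35)
  st$wristbands$t_on[2] <- st$wristbands$t_off[1] - 3600
  expect_error(build_daily_records(st, study_config(seed = 35)), "overlapping")
})

test_that("compliance percentages match hand-computed fractions", {
  scfg <- test_sim_config(n_participants = 2, n_days = 2)
  st <- generate_study(scfg, seed = 37)
  tab <- compliance_table(st, cfg = study_config(seed = 37))
  expect_true(all(tab$percent >= 0 & tab$percent <= 100, na.rm = TRUE))
  expect_equal(tab$percent, 100 * tab$numerator / tab$denominator)
  # the display convention rounds to the nearest integer percent
  row196 <- 100 * 196 / 210
  expect_equal(round(row196), 93)
  # all-satisfied study reports 100 everywhere
  scfg0 <- test_sim_config(n_participants = 2, n_days = 2, p_session_skip = 0,
                           p_invalid = 0, band_noncompliance = 0, p_lost = 0)
  st0 <- generate_study(scfg0, seed = 39)
  tab0 <- compliance_table(st0, cfg = study_config(seed = 39))
  expect_true(all(tab0$percent[tab0$metric != "activity_log_days"] == 100))
  # zero questionnaires answered -> 0%
  st0$activity <- st0$activity[0, ]
  tab_none <- compliance_table(st0, cfg = study_config(seed = 39))
  expect_equal(tab_none$percent[tab_none$metric == "activity_log_days"], 0)
})

test_that("compliance metrics are invariant to participant order", {
  scfg <- test_sim_config(n_participants = 3, n_days = 2)
  st <- generate_study(scfg, seed = 41)
  cfg <- study_config(seed = 41)
  tab1 <- compliance_table(st, cfg = cfg)
  st2 <- st
  st2$wristbands <- st2$wristbands[rev(seq_len(nrow(st2$wristbands))), ]
  st2$spirometry <- st2$spirometry[sample(nrow(st2$spirometry)), ]
  tab2 <- compliance_table(st2, cfg = cfg)
  expect_equal(tab1, tab2)
})

test_that("correlation matrix is symmetric with unit diagonal and groups duplicates", {
  withr::with_seed(43, {
    df <- tibble::tibble(a = rnorm(40), b = rnorm(40), c = rnorm(40))
    df$a_copy <- df$a
    cm <- correlation_matrix(df)
    expect_equal(cm$matrix, t(cm$matrix))
    expect_equal(unname(diag(cm$matrix)), rep(1, 4))
    expect_equal(cm$matrix["a", "a_copy"], 1)
    pos <- match(c("a", "a_copy"), cm$order)
    expect_equal(abs(diff(pos)), 1) # duplicates adjacent in the ordering
  })
  expect_error(correlation_matrix(tibble::tibble(a = 1:2, b = 2:3)), "at least 3")
  withr::with_seed(44, {
    expect_warning(correlation_matrix(tibble::tibble(a = rnorm(10), z = rep(1, 10))),
                   "zero-variance")
  })
})

test_that("planted correlation blocks are recovered with sign-contiguous order", {
  u <- c(1, 1, -1, -1)
  sigma <- 0.1 * diag(4) + 0.9 * tcrossprod(u)
  dimnames(sigma) <- list(paste0("v", 1:4), paste0("v", 1:4))
  withr::with_seed(45, {
    x <- MASS::mvrnorm(70, rep(0, 4), sigma, empirical = TRUE)
  })
  cm <- correlation_matrix(tibble::as_tibble(x))
  r <- cm$matrix[paste0("v", 1:4), paste0("v", 1:4)]
  expect_true(max(abs(r - sigma)) < 0.05)
  pos <- match(paste0("v", 1:4), cm$order)
  expect_equal(abs(pos[1] - pos[2]), 1) # +0.9 block contiguous
  expect_equal(abs(pos[3] - pos[4]), 1)
})

test_that("activity summaries match a hand tally", {
  day <- as.Date("2015-08-17")
  logs <- tibble::tibble(
    participant_id = c("P1", "P1", "P1", "P2", "P2"),
    day = c(day, day, day + 1, day, day),
    source = c("candles_incense", "hair_spray", "hair_spray",
               "candles_incense", "hair_spray"),
    response = c("yes", "no", "yes", "no", "yes"))
  s <- summarize_activity(logs)
  expect_equal(s$per_source$proportion[s$per_source$source == "candles_incense"],
               1 / 2)
  expect_equal(s$per_source$proportion[s$per_source$source == "hair_spray"],
               2 / 3)
  # participant-days: P1/d1 (1 yes), P1/d2 (1 yes), P2/d1 (1 yes)
  expect_equal(s$mean_sources_per_day, 1)
  expect_error(summarize_activity(dplyr::mutate(logs, response = "maybe")),
               "maybe")
  all_no <- dplyr::mutate(logs, response = "no")
  expect_equal(summarize_activity(all_no)$mean_sources_per_day, 0)
  g <- expand.grid(day = day + 0:2, source = c("a", "b", "c", "d"),
                   stringsAsFactors = FALSE)
  same4 <- tibble::tibble(participant_id = "P1", day = g$day,
                          source = g$source, response = "yes")
  expect_equal(summarize_activity(same4)$mean_sources_per_day, 4)
})
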