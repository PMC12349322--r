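# Synthetic cohort generator.

test_that("switching every effect off yields a constant trace at basal glucose", {
  cfg <- cohort_config("cgm_only_15min", n_subjects = 1, duration_days = 365,
                       seed = 1)
  tr <- simulate_subject(flat_profile(), cfg, seed = 1)
  expect_equal(nrow(tr$cgm), 365 * 96)
  expect_lt(max(abs(tr$cgm$glucose - 120)), 1e-4)
  expect_equal(nrow(tr$carbs), 0)
})

test_that("carb events push glucose up and boluses push it down", {
  cfg <- cohort_config("multivariate_5min", n_subjects = 1, duration_days = 14,
                       seed = 2)
  # impulse-response kernels: a carb event is a delayed positive bump, a
  # bolus a delayed negative one (sign applied at assembly)
  grid_min <- seq(0, 360, by = 5)
  carb_bump <- glucast:::event_effect(grid_min, 60, 2.5 * 40, glucast:::carb_kernel)
  expect_true(all(carb_bump >= 0) && max(carb_bump) > 0)
  expect_equal(max(carb_bump), 2.5 * 40, tolerance = 0.05)  # peak ~ sens x grams
  # rises after the event and peaks ~45 min later
  expect_true(all(carb_bump[grid_min <= 60] == 0))
  expect_equal(grid_min[which.max(carb_bump)] - 60, 45, tolerance = 5)
  bol_bump <- glucast:::event_effect(grid_min, 60, 45 * 2, glucast:::bolus_kernel)
  expect_true(all(bol_bump >= 0) && max(bol_bump) > 0)
  expect_true(all(bol_bump[grid_min <= 75] == 0))  # ~15 min onset delay

  # a full simulation with meals and boluses shows excursions in both
  # directions around the basal level
  tr <- simulate_subject(flat_profile(carb_sensitivity = 2.5,
                                      insulin_sensitivity = 45,
                                      noise_sd = 0.5), cfg, seed = 2)
  dev <- tr$cgm$glucose - 120
  expect_gt(max(dev), 20)
  expect_lt(min(dev), -10)
})

test_that("simulation is deterministic under a fixed seed and clamped to 40-400", {
  cfg <- cohort_config("multivariate_5min", n_subjects = 2, duration_days = 14,
                       seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  for (tr in a) {
    expect_true(all(tr$cgm$glucose >= 40 & tr$cgm$glucose <= 400))
    expect_true(all(diff(as.numeric(tr$cgm$time)) > 0))
    for (s in c("carbs", "bolus", "basal")) {
      if (nrow(tr[[s]]))
        expect_true(all(tr[[s]]$time >= tr$cgm$time[1] &
                          tr[[s]]$time <= tr$cgm$time[nrow(tr$cgm)]))
    }
  }
})

test_that("year-long CGM-only traces cover all months and weekdays", {
  cfg <- cohort_config("cgm_only_15min", n_subjects = 1, seed = 5)
  tr <- simulate_subject(sample_profiles(cfg)[[1]], cfg, seed = 5)
  lt <- as.POSIXlt(tr$cgm$time, tz = "UTC")
  expect_setequal(unique(lt$mon), 0:11)
  expect_setequal(unique(lt$wday), 0:6)
})

test_that("monthly effects are recoverable from monthly means at low noise", {
  cfg <- cohort_config("cgm_only_15min", n_subjects = 1, duration_days = 365,
                       seed = 3)
  me <- c(5, -8, 2, 12, -3, 0, 7, -10, 4, -6, 9, -1)
  pr <- flat_profile(noise_sd = 1)
  pr$monthly_effect <- me
  tr <- simulate_subject(pr, cfg, seed = 3)
  mm <- tapply(tr$cgm$glucose, as.POSIXlt(tr$cgm$time, tz = "UTC")$mon, mean)
  expect_gte(cor(as.numeric(mm), me, method = "spearman"), 0.9)
})

test_that("duration constraints per style are enforced", {
  expect_error(simulate_subject(flat_profile(),
                                cohort_config("multivariate_5min",
                                              duration_days = 10, seed = 1)),
               ">= 14")
  expect_error(simulate_subject(flat_profile(),
                                cohort_config("cgm_only_15min",
                                              duration_days = 100, seed = 1)),
               ">= 365")
})

test_that("interruption injection matches its nominal rate and gap geometry", {
  cfg <- cohort_config("multivariate_5min", n_subjects = 1, duration_days = 14,
                       seed = 4, interruption_rate = 1.5)
  tr <- simulate_subject(flat_profile(noise_sd = 1), cfg, seed = 4)

  # rate 0 leaves the trace untouched
  cfg0 <- cohort_config("multivariate_5min", n_subjects = 1, duration_days = 14,
                        seed = 4, interruption_rate = 0)
  expect_identical(inject_interruptions(tr, cfg0, seed = 1), tr)

  weeks <- (nrow(tr$cgm) - 1) * 5 / (7 * 24 * 60)
  counts <- vapply(1:600, function(s) {
    out <- inject_interruptions(tr, cfg, seed = s)
    max(detect_gaps(out$cgm$time, 5)) - 1L
  }, 1L)
  target <- 1.5 * weeks
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - target), 3 * se + 1e-9)

  # every injected gap spans more than 2 sampling periods
  out <- inject_interruptions(tr, cfg, seed = 99)
  dt <- diff(as.numeric(out$cgm$time))
  expect_true(all(dt == 300 | dt > 600))
  # event streams untouched
  expect_identical(out$carbs, tr$carbs)
})

test_that("event jitter perturbs, clamps and re-sorts without touching cgm", {
  cfg <- cohort_config("multivariate_5min", n_subjects = 1, duration_days = 14,
                       seed = 6)
  tr <- simulate_subject(sample_profiles(cfg)[[1]], cfg, seed = 6)
  expect_identical(jitter_event_timestamps(tr, sd = 0), tr)
  jt <- jitter_event_timestamps(tr, sd = 30, seed = 8)
  expect_identical(jt$cgm, tr$cgm)
  rng <- range(as.numeric(tr$cgm$time))
  for (s in c("carbs", "bolus", "basal")) {
    tt <- as.numeric(jt[[s]]$time)
    expect_true(all(tt >= rng[1] & tt <= rng[2]))
    expect_true(!is.unsorted(tt))
  }
  # with sub-minute jitter no event timestamp coincides with a cgm timestamp
  expect_false(any(as.numeric(jt$carbs$time) %in% as.numeric(tr$cgm$time)))
})

test_that("cohorts round-trip through the CSV/JSON writer", {
  cfg <- cohort_config("multivariate_5min", n_subjects = 2, duration_days = 14,
                       seed = 9)
  co <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  for (i in seq_along(co)) {
    expect_equal(back[[i]]$cgm$glucose, co[[i]]$cgm$glucose)
    expect_equal(as.numeric(back[[i]]$cgm$time), as.numeric(co[[i]]$cgm$time))
    expect_equal(back[[i]]$carbs$grams, co[[i]]$carbs$grams)
    expect_equal(back[[i]]$basal$rate, co[[i]]$basal$rate)
  }
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  expect_equal(manifest$seed, cfg$seed)

  # a trace without events writes header-only CSVs that read back empty
  tr <- toy_trace(as.POSIXct("2023-01-01", tz = "UTC") + (0:299) * 300,
                  rep(100, 300))
  dir2 <- withr::local_tempdir()
  write_cohort(list(tr), dir2)
  expect_equal(nrow(utils::read.csv(file.path(dir2, "T001_carbs.csv"))), 0)
  expect_equal(nrow(read_cohort(dir2)[[1]]$carbs), 0)
})
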