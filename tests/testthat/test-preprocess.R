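# Gap detection, common-grid harmonization, instance generation, splitting,
# normalization and feature encoding.

t0 <- as.POSIXct("2023-01-05 00:00:00", tz = "UTC")

test_that("gap threshold is 2 x sampling period minus one second", {
  # 45-min jump on a 15-min grid starts a new segment
  seg <- detect_gaps(t0 + c(0, 15, 30, 75, 90) * 60, 15)
  expect_equal(seg, c(1, 1, 1, 2, 2))
  # a 29-min jump (< 29:59) is not an interruption
  expect_equal(detect_gaps(t0 + c(0, 15, 44) * 60, 15), c(1, 1, 1))
  # exactly 2 periods (30:00 > 29:59) is one
  expect_equal(max(detect_gaps(t0 + c(0, 15, 45) * 60, 15)), 2)
  # 29:59 itself is not
  expect_equal(max(detect_gaps(t0 + c(0, 900, 900 + 1799), 15)), 1)
  expect_identical(detect_gaps(as.POSIXct(character(), tz = "UTC"), 15),
                   integer(0))
  expect_error(detect_gaps(t0 + c(0, 900, 600), 15), "increasing")
})

test_that("events map to their closest grid slot, zero-filled elsewhere", {
  tr <- toy_trace(t0 + c(0, 5, 10) * 60, c(100, 110, 120),
                  carbs = data.frame(time = t0 + 6.2 * 60, grams = 30))
  g <- build_common_grid(tr)
  expect_equal(g$carbs, c(0, 30, 0))
  expect_equal(g$bolus, c(0, 0, 0))
  expect_equal(g$cgm, c(100, 110, 120))
  expect_equal(g$segment, c(1, 1, 1))
})

test_that("a duplicated closest match is declared an interruption", {
  tr <- toy_trace(t0 + c(0, 0.5, 5, 10, 15) * 60, c(100, 101, 110, 120, 125))
  g <- build_common_grid(tr)
  # the two samples 30 s apart share slot 1; the sequence breaks after it
  expect_equal(length(unique(g$segment)), 2)
  expect_equal(g$segment[1], 1)
  expect_true(all(g$segment[-1] == 2))
  expect_error(build_common_grid(toy_trace(t0, 100)), ">= 2")
})

test_that("basal is carried forward and an event-free grid is all zeros", {
  tr <- toy_trace(t0 + (0:5) * 300, 100 + 0:5,
                  basal = data.frame(time = t0 + c(0, 11) * 60, rate = c(0.8, 1.2)))
  g <- build_common_grid(tr)
  expect_equal(g$basal, c(0.8, 0.8, 1.2, 1.2, 1.2, 1.2))
  g2 <- build_common_grid(toy_trace(t0 + (0:5) * 300, 100 + 0:5))
  expect_true(all(g2$carbs == 0) && all(g2$bolus == 0) && all(g2$basal == 0))
  # event-free, gap-free trace reproduces the cgm series exactly
  expect_equal(g2$cgm, 100 + 0:5)
  expect_equal(as.numeric(diff(g2$time)), rep(5, 5))
})

test_that("sliding windows yield L - N - H + 1 instances per segment", {
  expect_equal(nrow(generate_instances(toy_grid(100), 96, 4)), 1)
  expect_equal(nrow(generate_instances(toy_grid(99), 96, 4)), 0)
  g2 <- toy_grid(200, segment = rep(1:2, each = 100))
  inst <- generate_instances(g2, 96, 4)
  expect_equal(nrow(inst), 2)
  # naive enumeration oracle on random segment layouts
  set.seed(42)
  for (r in 1:5) {
    lens <- sample(80:140, 3)
    g <- toy_grid(sum(lens), segment = rep(1:3, times = lens))
    expect_equal(nrow(generate_instances(g, 96, 4)),
                 sum(pmax(0, lens - 96 - 4 + 1)))
  }
})

test_that("no emitted instance spans an interruption", {
  cfg <- cohort_config("multivariate_5min", n_subjects = 1, duration_days = 14,
                       seed = 13, interruption_rate = 3)
  ds <- prepare_dataset(simulate_cohort(cfg), seed = 13)
  g <- ds$grids[[1]]
  thresh <- 2 * 5 * 60 - 1
  for (i in seq_len(nrow(ds$instances))) {
    rows <- ds$instances$start[i] + 0:(96 + 12 - 1)
    expect_true(all(diff(as.numeric(g$time[rows])) <= thresh))
    expect_equal(length(unique(g$segment[rows])), 1)
  }
})

test_that("trimester split realizes 60/20/20 per stratum and excludes boundary spans", {
  # 10 instances in one stratum split exactly 6/2/2
  inst <- generate_instances(toy_grid(96 + 4 + 9, period = 15), 96, 4)
  inst$cross_trimester <- FALSE
  sp <- split_instances(inst, "trimester", seed = 1)
  expect_equal(as.numeric(table(sp$set)[c("train", "validation", "test")]),
               c(6, 2, 2))

  # an instance crossing March -> April is excluded from every set
  gq <- toy_grid(110, period = 15, start = "2023-03-31 00:00:00")
  iq <- generate_instances(gq, 96, 4)
  expect_true(any(iq$cross_trimester))
  sq <- split_instances(iq, "trimester", seed = 1)
  expect_true(all(sq$set[sq$cross_trimester] == "excluded"))

  # partition property: union of sets plus exclusions is everything, disjoint
  expect_false(any(is.na(sq$set)))
  expect_equal(sum(table(sq$set)), nrow(sq))

  expect_error(split_instances(inst, "trimester", fractions = c(0.5, 0.2, 0.2)),
               "sum to 1")
})

test_that("chronological split is ordered in time per subject", {
  ds <- small_mv_dataset()
  inst <- ds$instances
  for (id in unique(inst$subject_id)) {
    sub <- inst[inst$subject_id == id, ]
    expect_lt(max(as.numeric(sub$anchor_time[sub$set == "train"])),
              min(as.numeric(sub$anchor_time[sub$set == "validation"])))
    expect_lt(max(as.numeric(sub$anchor_time[sub$set == "validation"])),
              min(as.numeric(sub$anchor_time[sub$set == "test"])))
  }
  prop <- prop.table(table(inst$set))[c("train", "validation", "test")]
  expect_equal(as.numeric(prop), c(0.65, 0.16, 0.19), tolerance = 0.01)
})

test_that("z-score normalization round-trips and is fitted on train only", {
  ds <- small_mv_dataset()
  enc <- encode_features(ds, c("cgm", "hour", "carbs"))
  st <- fit_normalization(enc)
  tr <- enc$instances$set == "train"
  expect_equal(st$mean[["cgm"]], mean(enc$enc_real[tr, , "cgm"]))
  encn <- apply_normalization(enc, st)
  expect_equal(mean(encn$enc_real[tr, , "cgm"]), 0, tolerance = 1e-10)
  expect_equal(sd(encn$enc_real[tr, , "cgm"]), 1, tolerance = 1e-6)
  back <- denormalize_glucose(encn$target, st)
  expect_equal(max(abs(back - enc$target)) / max(abs(enc$target)), 0,
               tolerance = 1e-9)
  # zero-variance features are rejected by name
  enc2 <- enc
  enc2$enc_real[, , "carbs"] <- 5
  expect_error(fit_normalization(enc2), "carbs")
})

test_that("feature encoding follows the per-style variable typing", {
  ds <- small_mv_dataset()
  enc <- encode_features(ds, "cgm")
  expect_equal(enc$enc_real_names, c("cgm", "time_index", "relative_time_index"))
  expect_null(enc$enc_cat)
  expect_equal(enc$n_static_levels, 0L)
  enc3 <- encode_features(ds, c("cgm", "id", "hour"))
  expect_equal(sum(c("cgm", "hour") %in% enc3$enc_real_names), 2)
  expect_gt(enc3$n_static_levels, 0L)
  # month is not available in the 5-min multivariate style
  expect_error(encode_features(ds, c("cgm", "month")), "month")
  # hour is a real in [0, 24)
  expect_true(all(enc3$enc_real[, , "hour"] >= 0 & enc3$enc_real[, , "hour"] < 24))
})

test_that("day-of-week uses the Monday = 0 convention end to end", {
  # 2023-01-02 is a Monday
  g <- toy_grid(120, period = 15, start = "2023-01-02 00:00:00")
  ds <- structure(list(grids = list(T001 = g),
                       instances = {
                         ii <- generate_instances(g, 96, 4)
                         ii$set <- "train"; ii
                       },
                       input_len = 96L, horizon = 4L, sampling_period = 15L,
                       style = "cgm_only_15min", subjects = "T001"),
                  class = "glucast_dataset")
  enc <- encode_features(ds, c("cgm", "day_of_week"), sets = "train")
  # Monday stored as level 1 (index 0 + 1); the window runs into Tuesday (2)
  expect_equal(unname(enc$enc_cat[1, 1, "day_of_week"]), 1L)
  expect_setequal(unique(as.vector(enc$enc_cat[, , "day_of_week"])), c(1L, 2L))

  # 2023-01-01 is a Sunday -> level 7 under Monday = 0
  gs <- toy_grid(120, period = 15, start = "2023-01-01 00:00:00")
  ds$grids <- list(T001 = gs)
  ds$instances <- { ii <- generate_instances(gs, 96, 4); ii$set <- "train"; ii }
  enc_s <- encode_features(ds, c("cgm", "day_of_week"), sets = "train")
  expect_equal(unname(enc_s$enc_cat[1, 1, "day_of_week"]), 7L)
})
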