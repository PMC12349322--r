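# Interpretability exports.

test_that("attention profiles stay on the simplex and map positions to lead times", {
  fc <- small_forecast()
  pr <- attention_profile(fc$bundle, tau = 1)
  expect_equal(sum(pr$weights), 1, tolerance = 1e-6)
  expect_true(all(pr$weights >= 0))
  expect_equal(length(pr$weights), 96)
  # position 96 is one sampling period before the prediction
  expect_equal(pr$lead_time_min[96], 0)
  expect_equal(pr$lead_time_min[1], -95 * 5)
  expect_error(attention_profile(fc$bundle, tau = 99), "horizon")
  # a mean of simplex vectors is itself on the simplex, for every tau
  for (tau in seq_len(fc$horizon))
    expect_equal(sum(attention_profile(fc$bundle, tau)$weights), 1,
                 tolerance = 1e-6)
})

test_that("single-instance attention requires full extraction and equals the raw row", {
  fit <- small_fit()
  ds <- small_mv_dataset()
  fc <- predict(fit, ds, set = "validation", return_attention = "full")
  pr <- attention_profile(fc$bundle, tau = 2, instance = 3)
  expect_equal(pr$weights, as.numeric(fc$bundle$attention_full[3, 2, ]))
  expect_equal(pr$aggregation, "single_instance")
  expect_error(attention_profile(small_forecast()$bundle, instance = 1),
               "full")
})

test_that("feature importances are percentages with the right exclusions", {
  fc <- small_forecast()
  enc_imp <- feature_importance(fc$bundle, "encoder")
  dec_imp <- feature_importance(fc$bundle, "decoder")
  expect_equal(sum(enc_imp$importance), 100, tolerance = 0.1)
  expect_equal(sum(dec_imp$importance), 100, tolerance = 0.1)
  expect_true(all(enc_imp$importance >= 0))
  # the static id never appears among time-varying importances
  expect_false("id" %in% names(enc_imp$importance))
  # the decoder does not see the target variable
  expect_false("cgm" %in% names(dec_imp$importance))
  expect_true("cgm" %in% names(enc_imp$importance))
  # the auxiliary position channels are reported in both parts
  expect_true(all(c("time_index", "relative_time_index") %in%
                    names(enc_imp$importance)))
  expect_true(all(c("time_index", "relative_time_index") %in%
                    names(dec_imp$importance)))
})

test_that("importances do not depend on the order features are requested in", {
  ds <- small_mv_dataset()
  ctl <- glucast_control(hidden_size = 8L, continuous_hidden = 4L,
                         max_epochs = 1L, max_train_instances = 300L)
  f1 <- glucast(ds, c("cgm", "hour", "carbs"), control = ctl, seed = 3)
  f2 <- glucast(ds, c("carbs", "cgm", "hour"), control = ctl, seed = 3)
  i1 <- feature_importance(predict(f1, ds, set = "validation")$bundle, "encoder")
  i2 <- feature_importance(predict(f2, ds, set = "validation")$bundle, "encoder")
  expect_equal(i1$importance, i2$importance)
})

test_that("instance records are plot-ready and JSON round-trippable", {
  fc <- small_forecast()
  rec <- export_instance(fc, instance = 2, dataset = small_mv_dataset())
  expect_true(all(rec$interval_width >= 0))
  expect_equal(rec$interval_width, rec$p_hi - rec$p_lo)
  expect_equal(length(rec$input_cgm), 96)
  expect_equal(length(rec$truth), fc$horizon)
  json <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::fromJSON(json)
  expect_equal(back$p50, rec$p50)
  expect_equal(back$subject_id, rec$subject_id)
})

test_that("attention reflects recency on short-memory AR(1) glucose", {
  # pure AR(1) noise around a constant level: only the most recent samples
  # carry signal. The recurrent decoder state covers recency at the first
  # predicted step, so the attention stage is probed at the farthest horizon
  # step, where the recurrent carry is weakest.
  cfg <- cohort_config("multivariate_5min", n_subjects = 1, duration_days = 14,
                       seed = 41, interruption_rate = 0)
  pr <- flat_profile(noise_sd = 20, ar_coefficient = 0.95,
                     carb_sensitivity = 1e-6, insulin_sensitivity = 1e-6)
  ds <- prepare_dataset(list(simulate_subject(pr, cfg, seed = 41)), seed = 41)
  ctl <- glucast_control(hidden_size = 16L, continuous_hidden = 8L,
                         max_epochs = 10L, patience = 10L,
                         max_train_instances = 2000L)
  fit <- glucast(ds, "cgm", control = ctl, seed = 2)
  fc <- predict(fit, ds, set = "test")
  w <- attention_profile(fc$bundle, tau = fc$horizon)$weights
  expect_gt(sum(w[87:96]), 10 / 96)
})

test_that("noisier cohorts produce wider predicted intervals", {
  mk <- function(noise, seed) {
    cfg <- cohort_config("multivariate_5min", n_subjects = 1,
                         duration_days = 14, seed = seed,
                         interruption_rate = 0)
    pr <- flat_profile(noise_sd = noise, circadian_amplitude = 10)
    prepare_dataset(list(simulate_subject(pr, cfg, seed = seed)), seed = seed)
  }
  ctl <- glucast_control(hidden_size = 8L, continuous_hidden = 4L,
                         max_epochs = 3L, max_train_instances = 600L)
  ds_lo <- mk(2, 31); ds_hi <- mk(12, 31)
  f_lo <- glucast(ds_lo, "cgm", control = ctl, seed = 4)
  f_hi <- glucast(ds_hi, "cgm", control = ctl, seed = 4)
  w_lo <- predict(f_lo, ds_lo, set = "test", return_attention = "none")
  w_hi <- predict(f_hi, ds_hi, set = "test", return_attention = "none")
  width <- function(fc) mean(fc$quantiles[, , 3] - fc$quantiles[, , 1])
  expect_gt(width(w_hi), width(w_lo))
})
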