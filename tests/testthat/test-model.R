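# The quantile forecaster: loss, fitting, prediction invariants.

test_that("quantile loss matches hand-evaluated cases and rejects bad levels", {
  expect_equal(quantile_loss(100, 100, 0.5), 0)
  expect_equal(quantile_loss(100, 90, 0.9), 9)    # q (y - yhat)+
  expect_equal(quantile_loss(90, 100, 0.9), 1)    # (1-q)(yhat - y)+
  expect_equal(quantile_loss(100, 90, 0.1), 1)
  expect_true(all(quantile_loss(rnorm(20), rnorm(20), 0.3) >= 0))
  expect_error(quantile_loss(1, 1, 0), "inside")
  expect_error(quantile_loss(1, 1, 1.2), "inside")
})

test_that("control validates its invariants", {
  expect_error(glucast_control(quantiles = c(0.5, 0.1, 0.9)), "increasing")
  expect_error(glucast_control(quantiles = c(0.1, 0.9)), "0.5")
  expect_error(glucast:::build_forecaster(
    list(enc_real_names = "cgm", enc_cat_names = character(),
         dec_real_names = character(), dec_cat_names = character(),
         cat_levels = integer(), n_static_levels = 0L),
    glucast_control(hidden_size = 10L, n_heads = 3L)), "divisible")
})

test_that("two builds from the same seed give identical initial weights", {
  spec <- list(enc_real_names = c("cgm", "time_index"),
               enc_cat_names = character(), dec_real_names = "time_index",
               dec_cat_names = character(), cat_levels = integer(),
               n_static_levels = 2L)
  ctl <- glucast_control(hidden_size = 8L, continuous_hidden = 4L)
  m1 <- glucast:::with_seed(42, glucast:::build_forecaster(spec, ctl))
  m2 <- glucast:::with_seed(42, glucast:::build_forecaster(spec, ctl))
  p1 <- glucast:::param_values(glucast:::collect_params(m1))
  p2 <- glucast:::param_values(glucast:::collect_params(m2))
  expect_identical(p1, p2)
})

test_that("near-constant glucose is learned to within 2 mg/dL at the median", {
  cfg <- cohort_config("multivariate_5min", n_subjects = 1, duration_days = 14,
                       seed = 21, interruption_rate = 0)
  pr <- flat_profile(noise_sd = 0.5, carb_sensitivity = 1e-6,
                     insulin_sensitivity = 1e-6)
  tr <- simulate_subject(pr, cfg, seed = 21)
  ds <- prepare_dataset(list(tr), seed = 21)
  ctl <- glucast_control(hidden_size = 8L, continuous_hidden = 4L,
                         max_epochs = 3L, max_train_instances = 600L)
  fit <- glucast(ds, "cgm", control = ctl, seed = 1)
  fc <- predict(fit, ds, set = "validation", return_attention = "none")
  expect_lt(mean(abs(fc$quantiles[, , "p50"] - 120)), 2)
})

test_that("fitting is reproducible end to end under a fixed seed", {
  ds <- small_mv_dataset()
  ctl <- glucast_control(hidden_size = 8L, continuous_hidden = 4L,
                         max_epochs = 2L, max_train_instances = 400L)
  f1 <- glucast(ds, "cgm", control = ctl, seed = 9)
  f2 <- glucast(ds, "cgm", control = ctl, seed = 9)
  expect_equal(f1$best_val_loss, f2$best_val_loss)
  expect_identical(glucast:::param_values(f1$params),
                   glucast:::param_values(f2$params))
  p1 <- predict(f1, ds, set = "test", return_attention = "none")
  p2 <- predict(f2, ds, set = "test", return_attention = "none")
  expect_identical(p1$quantiles, p2$quantiles)
})

test_that("prediction enforces quantile monotonicity and simplex weights", {
  fc <- small_forecast()
  qa <- fc$quantiles
  expect_true(all(qa[, , 1] <= qa[, , 2] + 1e-9))
  expect_true(all(qa[, , 2] <= qa[, , 3] + 1e-9))
  expect_equal(rowSums(fc$bundle$attention_mean),
               rep(1, fc$horizon), tolerance = 1e-6)
  expect_true(all(fc$bundle$attention_mean >= 0))
  expect_equal(sum(fc$bundle$vsn_encoder), 1, tolerance = 1e-6)
  expect_equal(sum(fc$bundle$vsn_decoder), 1, tolerance = 1e-6)
})

test_that("a model without static covariates has no static branch and ignores ids", {
  fit0 <- fixture("cgm_only_fit", function() {
    ctl <- glucast_control(hidden_size = 8L, continuous_hidden = 4L,
                           max_epochs = 1L, max_train_instances = 300L)
    glucast(small_mv_dataset(), "cgm", control = ctl, seed = 2)
  })
  expect_false(any(grepl("static", names(fit0$params))))
  # outputs are invariant to any would-be static input
  enc <- encode_features(small_mv_dataset(), "cgm", sets = "test")
  enc <- apply_normalization(enc, fit0$norm)
  b <- glucast:::batch_slice(enc, 1:16)
  b2 <- b
  b2$static <- rep(1L, 16)
  f1 <- glucast:::forward_forecaster(fit0$model, b)
  f2 <- glucast:::forward_forecaster(fit0$model, b2)
  expect_identical(f1$yhat, f2$yhat)
})

test_that("predicting with mismatched inputs is rejected", {
  fit <- small_fit()
  ds <- small_mv_dataset()
  ds_bad <- ds
  ds_bad$style <- "cgm_only_15min"
  expect_error(predict(fit, ds_bad), "style")
  ds_bad2 <- ds
  ds_bad2$subjects <- c("X001", "X002")
  expect_error(predict(fit, ds_bad2), "roster")
})

test_that("random search returns the best-of-k fit with a trial table", {
  ds <- small_mv_dataset()
  ctl <- glucast_control(hidden_size = 8L, continuous_hidden = 4L,
                         max_epochs = 1L, max_train_instances = 200L)
  best <- random_search(ds, "cgm", k = 2L, control = ctl, seed = 6)
  tr <- attr(best, "trials")
  expect_equal(nrow(tr), 2)
  expect_equal(best$best_val_loss, min(tr$val_loss))
})

test_that("training improves on the untrained model and persistence", {
  fit <- small_fit()
  ds <- small_mv_dataset()
  # untrained reference: same architecture and initialization seed
  enc <- encode_features(ds, fit$features)
  enc <- apply_normalization(enc, fit$norm)
  m0 <- glucast:::with_seed(glucast:::child_seed(5, "init"),
                            glucast:::build_forecaster(fit$spec, fit$control))
  val_idx <- which(enc$instances$set == "validation")
  untrained <- glucast:::eval_loss(m0, enc, val_idx, 256L)
  expect_lt(fit$best_val_loss, untrained)
  expect_lt(fit$best_val_loss, persistence_loss(fit, ds))
  # the log is complete and the training loss broadly decreases
  expect_true(all(c("epoch", "train_loss", "val_loss") %in% names(fit$log)))
  expect_lt(fit$log$train_loss[nrow(fit$log)], fit$log$train_loss[1])
})
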