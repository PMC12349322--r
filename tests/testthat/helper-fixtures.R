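# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# Small multivariate cohort + dataset shared by model/interpretability tests.
small_mv_dataset <- function() {
  fixture("small_mv", function() {
    cfg <- cohort_config("multivariate_5min", n_subjects = 2,
                         duration_days = 14, seed = 11)
    prepare_dataset(simulate_cohort(cfg), seed = 11)
  })
}

# A quick compact fit on the small cohort (used by several suites).
small_fit <- function() {
  fixture("small_fit", function() {
    ctl <- glucast_control(hidden_size = 16L, continuous_hidden = 8L,
                           max_epochs = 3L, max_train_instances = 1200L)
    glucast(small_mv_dataset(), c("cgm", "id", "hour"), control = ctl, seed = 5)
  })
}

small_forecast <- function() {
  fixture("small_forecast", function()
    predict(small_fit(), small_mv_dataset(), set = "test"))
}

# A subject profile with every systematic effect switched off (overridable).
flat_profile <- function(noise_sd = 1e-6, ...) {
  args <- utils::modifyList(
    list(subject_id = "F001", basal_glucose = 120, circadian_amplitude = 0,
         circadian_phase = 0, weekly_effect = rep(0, 7),
         monthly_effect = rep(0, 12), noise_sd = noise_sd,
         ar_coefficient = 0),
    list(...))
  do.call(subject_profile, args)
}

# Hand-built common grid with regular timestamps (single segment).
toy_grid <- function(n, period = 15L, start = "2023-01-05 00:00:00",
                     subject = "T001", segment = rep(1L, n)) {
  t0 <- as.POSIXct(start, tz = "UTC")
  structure(data.frame(time = t0 + (seq_len(n) - 1L) * period * 60,
                       cgm = 100 + sin(seq_len(n) / 7),
                       carbs = 0, bolus = 0, basal = 0, segment = segment),
            class = c("common_grid", "data.frame"),
            subject_id = subject, sampling_period = period)
}

# Raw trace constructor for hand-crafted cases.
toy_trace <- function(times, glucose, period = 5L, subject = "T001",
                      carbs = NULL, bolus = NULL, basal = NULL,
                      style = "multivariate_5min") {
  empty_t <- as.POSIXct(character(), tz = "UTC")
  structure(list(
    subject_id = subject,
    cgm = data.frame(time = times, glucose = glucose),
    carbs = if (is.null(carbs)) data.frame(time = empty_t, grams = numeric()) else carbs,
    bolus = if (is.null(bolus)) data.frame(time = empty_t, units = numeric()) else bolus,
    basal = if (is.null(basal)) data.frame(time = empty_t, rate = numeric()) else basal,
    style = style, sampling_period = period), class = "raw_trace")
}
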