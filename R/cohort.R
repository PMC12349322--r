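# Synthetic CGM cohort simulator.
#
# Two regimes are emulated: long CGM-only records at 15-min sampling with
# circadian / weekly / seasonal structure (one year, so every calendar month is
# represented), and short multivariate records at 5-min sampling carrying
# carbohydrate, bolus and basal-insulin event streams on their own (jittered)
# timestamps, plus sensor reading interruptions.

#' Cohort simulation configuration
#'
#' Describes one synthetic CGM cohort. Defaults follow the two study regimes:
#' the CGM-only style simulates 29 subjects over one year at 15-min sampling;
#' the multivariate style simulates 12 subjects over two weeks at 5-min
#' sampling with meal/bolus/basal event streams.
#'
#' @param style `"cgm_only_15min"` or `"multivariate_5min"`.
#' @param n_subjects Number of subjects (>= 1).
#' @param duration_days Length of each record in days. The CGM-only style
#'   requires >= 365 days (so all 12 months occur); the multivariate style
#'   requires >= 14 days.
#' @param seed Integer seed; the cohort is a deterministic function of
#'   (config, seed).
#' @param interruption_rate Expected number of reading interruptions per
#'   subject-week (>= 0).
#' @param event_jitter_sd Standard deviation, in seconds, of the Gaussian
#'   perturbation applied to event timestamps (multivariate style only).
#' @param start First timestamp of every record (timezone-naive local time,
#'   stored as UTC).
#' @return An object of class `cohort_config`.
#' @examples
#' cohort_config("multivariate_5min", n_subjects = 2, duration_days = 14, seed = 1)
#' @export
cohort_config <- function(style = c("cgm_only_15min", "multivariate_5min"),
                          n_subjects = NULL,
                          duration_days = NULL,
                          seed = 1L,
                          interruption_rate = 1.5,
                          event_jitter_sd = 60,
                          start = NULL) {
  style <- match.arg(style)
  sampling_period <- if (style == "cgm_only_15min") 15L else 5L
  if (is.null(n_subjects))
    n_subjects <- if (style == "cgm_only_15min") 29L else 12L
  if (is.null(duration_days))
    duration_days <- if (style == "cgm_only_15min") 365L else 14L
  if (is.null(start))
    start <- as.POSIXct("2023-01-01 00:00:00", tz = "UTC")
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  if (duration_days < 2L) stop("duration_days must be >= 2")
  if (interruption_rate < 0) stop("interruption_rate must be >= 0")
  structure(list(style = style,
                 n_subjects = as.integer(n_subjects),
                 duration_days = as.integer(duration_days),
                 sampling_period = sampling_period,
                 seed = as.integer(seed),
                 interruption_rate = interruption_rate,
                 event_jitter_sd = event_jitter_sd,
                 start = start),
            class = "cohort_config")
}

#' Subject-level generative profile
#'
#' Fixed per-subject parameters of the glucose generator. Glucose is modelled
#' as a basal level plus a circadian sinusoid, day-of-week and month offsets,
#' meal and bolus impulse responses, and AR(1) sensor noise, clamped to the
#' sensor range 40-400 mg/dL.
#'
#' @param subject_id Subject identifier string.
#' @param basal_glucose Baseline glucose, mg/dL (must lie in [80, 180]).
#' @param circadian_amplitude Amplitude of the 24-h sinusoid, mg/dL.
#' @param circadian_phase Acrophase of the sinusoid, hours.
#' @param weekly_effect Length-7 offset vector, mg/dL (Monday first).
#' @param monthly_effect Length-12 offset vector, mg/dL (January first).
#' @param carb_sensitivity Peak glucose rise per gram of carbohydrate,
#'   mg/dL per g.
#' @param insulin_sensitivity Peak glucose drop per unit of bolus insulin,
#'   mg/dL per U.
#' @param noise_sd Stationary standard deviation of the AR(1) sensor noise,
#'   mg/dL (> 0).
#' @param ar_coefficient AR(1) coefficient of the noise, in [0, 1).
#' @param meal_time_offset Per-subject shift of habitual meal times, minutes.
#' @return An object of class `subject_profile`.
#' @seealso [sample_profiles()] to draw a cohort of profiles.
#' @export
subject_profile <- function(subject_id,
                            basal_glucose = 130,
                            circadian_amplitude = 15,
                            circadian_phase = 16,
                            weekly_effect = rep(0, 7),
                            monthly_effect = rep(0, 12),
                            carb_sensitivity = 2.5,
                            insulin_sensitivity = 45,
                            noise_sd = 6,
                            ar_coefficient = 0.8,
                            meal_time_offset = 0) {
  if (basal_glucose < 80 || basal_glucose > 180)
    stop("basal_glucose must lie in [80, 180] mg/dL")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (ar_coefficient < 0 || ar_coefficient >= 1)
    stop("ar_coefficient must lie in [0, 1)")
  stopifnot(length(weekly_effect) == 7L, length(monthly_effect) == 12L)
  structure(list(subject_id = as.character(subject_id),
                 basal_glucose = basal_glucose,
                 circadian_amplitude = circadian_amplitude,
                 circadian_phase = circadian_phase,
                 weekly_effect = weekly_effect,
                 monthly_effect = monthly_effect,
                 carb_sensitivity = carb_sensitivity,
                 insulin_sensitivity = insulin_sensitivity,
                 noise_sd = noise_sd,
                 ar_coefficient = ar_coefficient,
                 meal_time_offset = meal_time_offset),
            class = "subject_profile")
}

#' Draw a cohort of subject profiles
#'
#' Samples heterogeneous per-subject generator parameters from ranges a CGM
#' study population would plausibly span.
#'
#' @param config A [cohort_config()].
#' @return A list of [subject_profile()] objects, one per subject.
#' @export
sample_profiles <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(child_seed(config$seed, "profiles"), {
    lapply(seq_len(config$n_subjects), function(i) {
      subject_profile(
        subject_id = sprintf("S%03d", i),
        basal_glucose = stats::runif(1, 110, 160),
        circadian_amplitude = stats::runif(1, 8, 25),
        circadian_phase = stats::runif(1, 0, 24),
        weekly_effect = stats::rnorm(7, 0, 4),
        monthly_effect = stats::rnorm(12, 0, 9),
        carb_sensitivity = stats::runif(1, 1.5, 3),
        insulin_sensitivity = stats::runif(1, 35, 55),
        noise_sd = stats::runif(1, 4, 8),
        ar_coefficient = stats::runif(1, 0.6, 0.9),
        meal_time_offset = stats::rnorm(1, 0, 40))
    })
  })
}

# Carbohydrate impulse response: gamma-shaped bump peaking 1 at `peak_min`
# minutes after intake (rise over ~30-60 min, decay over ~2-3 h).
#' @noRd
carb_kernel <- function(minutes, peak_min = 45, shape = 2) {
  k <- numeric(length(minutes))
  pos <- minutes > 0
  r <- minutes[pos] / peak_min
  k[pos] <- (r^shape) * exp(shape * (1 - r))
  k
}

# Bolus insulin impulse response: onset ~15 min, peak ~75 min, tail ~4 h,
# normalized to peak 1 (applied with negative sign).
#' @noRd
bolus_kernel <- function(minutes, onset_min = 15, peak_min = 60, shape = 1.5) {
  k <- numeric(length(minutes))
  s <- minutes - onset_min
  pos <- s > 0
  r <- s[pos] / peak_min
  k[pos] <- (r^shape) * exp(shape * (1 - r))
  k
}

# Habitual meal slots (minutes from midnight) and the probability each is
# taken on a given day; chosen to create an hour-of-day signal.
.meal_slots <- c(breakfast = 8 * 60, lunch = 13 * 60, dinner = 20 * 60,
                 snack1 = 16.5 * 60, snack2 = 23 * 60)
.meal_prob <- c(0.95, 0.95, 0.95, 0.45, 0.25)

#' Simulate one subject's raw sensor record
#'
#' Generates the CGM series (and, in the multivariate style, carbohydrate,
#' bolus and basal event streams) on a regular sampling grid. Glucose is the
#' sum of basal level, circadian sinusoid, day-of-week and month offsets,
#' carb/bolus impulse responses and AR(1) noise, clamped to [40, 400] mg/dL.
#' The multivariate style places 2-5 meals per day around habitual times,
#' a bolus within +/-20 min of most meals, and a piecewise-constant basal
#' profile.
#'
#' @param profile A [subject_profile()].
#' @param config A [cohort_config()]; its style decides which event streams
#'   are produced. The CGM-only style requires `duration_days >= 365`, the
#'   multivariate style `>= 14`.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return An object of class `raw_trace`: a list with `subject_id`, `cgm`
#'   (data frame `time`, `glucose`), `carbs`, `bolus`, `basal` event data
#'   frames (empty in the CGM-only style), plus the style and sampling period.
#' @examples
#' cfg <- cohort_config("multivariate_5min", n_subjects = 1, duration_days = 14,
#'                      seed = 7)
#' tr <- simulate_subject(sample_profiles(cfg)[[1]], cfg, seed = 7)
#' range(tr$cgm$glucose)
#' @export
simulate_subject <- function(profile, config, seed = NULL) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(config, "cohort_config"))
  if (config$style == "multivariate_5min" && config$duration_days < 14)
    stop("multivariate_5min style needs duration_days >= 14")
  if (config$style == "cgm_only_15min" && config$duration_days < 365)
    stop("cgm_only_15min style needs duration_days >= 365 so all 12 months occur")
  with_seed(seed, simulate_subject_impl(profile, config))
}

#' @noRd
simulate_subject_impl <- function(profile, config) {
  period <- config$sampling_period
  n <- config$duration_days * 24L * (60L / period)
  times <- config$start + (seq_len(n) - 1L) * period * 60
  minutes <- as.numeric(times - config$start, units = "mins")

  hr <- hour_real(times)
  base <- profile$basal_glucose +
    profile$circadian_amplitude * sin(2 * pi * (hr - profile$circadian_phase) / 24) +
    profile$weekly_effect[dow_index(times) + 1L] +
    profile$monthly_effect[month_index(times)]

  carbs <- data.frame(time = as.POSIXct(character(), tz = "UTC"), grams = numeric())
  bolus <- data.frame(time = as.POSIXct(character(), tz = "UTC"), units = numeric())
  basal <- data.frame(time = as.POSIXct(character(), tz = "UTC"), rate = numeric())
  effect <- numeric(n)

  if (config$style == "multivariate_5min") {
    ev <- simulate_events(profile, config)
    carbs <- ev$carbs; bolus <- ev$bolus; basal <- ev$basal
    effect <- effect + event_effect(minutes,
                                    as.numeric(carbs$time - config$start, units = "mins"),
                                    profile$carb_sensitivity * carbs$grams,
                                    carb_kernel)
    effect <- effect - event_effect(minutes,
                                    as.numeric(bolus$time - config$start, units = "mins"),
                                    profile$insulin_sensitivity * bolus$units,
                                    bolus_kernel)
  }

  # AR(1) noise with stationary sd = noise_sd.
  innov_sd <- profile$noise_sd * sqrt(1 - profile$ar_coefficient^2)
  noise <- as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd),
                                    profile$ar_coefficient,
                                    method = "recursive",
                                    init = stats::rnorm(1, 0, profile$noise_sd)))

  glucose <- clamp(base + effect + noise, 40, 400)
  structure(list(subject_id = profile$subject_id,
                 cgm = data.frame(time = times, glucose = glucose),
                 carbs = carbs, bolus = bolus, basal = basal,
                 style = config$style,
                 sampling_period = period),
            class = "raw_trace")
}

# Sum impulse responses of events (event_min: minutes of each event;
# amp: peak amplitude of each) onto the sampling grid, within a 6-h window.
#' @noRd
event_effect <- function(grid_min, event_min, amp, kernel) {
  out <- numeric(length(grid_min))
  if (length(event_min) == 0L) return(out)
  step <- if (length(grid_min) > 1L) grid_min[2L] - grid_min[1L] else 1
  win <- ceiling(360 / step)
  for (j in seq_along(event_min)) {
    i0 <- max(1L, ceiling(event_min[j] / step))
    idx <- i0:min(length(grid_min), i0 + win)
    out[idx] <- out[idx] + amp[j] * kernel(grid_min[idx] - event_min[j])
  }
  out
}

#' @noRd
simulate_events <- function(profile, config) {
  end_min <- config$duration_days * 24 * 60 - config$sampling_period
  carb_t <- numeric(); carb_g <- numeric()
  bol_t <- numeric(); bol_u <- numeric()
  for (d in seq_len(config$duration_days) - 1L) {
    take <- stats::runif(length(.meal_slots)) < .meal_prob
    # Guarantee 2-5 meals/day: keep at least breakfast and dinner.
    take[c(1L, 3L)] <- take[c(1L, 3L)] | sum(take) < 2L
    tt <- d * 24 * 60 + .meal_slots[take] + profile$meal_time_offset +
      stats::rnorm(sum(take), 0, 20)
    gg <- stats::runif(sum(take), 20, 90)
    carb_t <- c(carb_t, tt); carb_g <- c(carb_g, gg)
    with_bolus <- stats::runif(sum(take)) < 0.85
    bt <- tt[with_bolus] + stats::runif(sum(with_bolus), -20, 20)
    # Bolus sized so its peak glucose drop covers 70-105% of the meal's rise:
    # keeps excursions realistic instead of clamping at the sensor floor.
    bu <- gg[with_bolus] * profile$carb_sensitivity / profile$insulin_sensitivity *
      stats::runif(sum(with_bolus), 0.7, 1.05)
    bol_t <- c(bol_t, bt); bol_u <- c(bol_u, bu)
  }
  keep_c <- carb_t >= 0 & carb_t <= end_min
  keep_b <- bol_t >= 0 & bol_t <= end_min
  # Piecewise-constant basal profile: a new rate every 4-8 h, starting at t0.
  seg_start <- 0
  bas_t <- numeric(); bas_r <- numeric()
  while (seg_start <= end_min) {
    bas_t <- c(bas_t, seg_start)
    bas_r <- c(bas_r, stats::runif(1, 0.5, 1.5))
    seg_start <- seg_start + stats::runif(1, 4, 8) * 60
  }
  ord_c <- order(carb_t[keep_c]); ord_b <- order(bol_t[keep_b])
  list(carbs = data.frame(time = config$start + carb_t[keep_c][ord_c] * 60,
                          grams = carb_g[keep_c][ord_c]),
       bolus = data.frame(time = config$start + bol_t[keep_b][ord_b] * 60,
                          units = bol_u[keep_b][ord_b]),
       basal = data.frame(time = config$start + bas_t * 60, rate = bas_r))
}

#' Remove contiguous CGM runs to emulate reading interruptions
#'
#' Draws a Poisson number of interruptions with mean
#' `interruption_rate * weeks`, and removes, for each, a contiguous run of
#' at least 2 CGM samples, so every resulting timestamp jump exceeds twice the
#' sampling period. Event streams are untouched.
#'
#' @param trace A `raw_trace` with at least 200 CGM samples.
#' @param config The [cohort_config()] that produced it.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return The trace with CGM rows removed.
#' @export
inject_interruptions <- function(trace, config, seed = NULL) {
  stopifnot(inherits(trace, "raw_trace"), inherits(config, "cohort_config"))
  if (nrow(trace$cgm) < 200L) stop("trace must have >= 200 cgm samples")
  if (config$interruption_rate == 0) return(trace)
  with_seed(seed, {
    n <- nrow(trace$cgm)
    weeks <- (n - 1L) * config$sampling_period / (7 * 24 * 60)
    k <- stats::rpois(1L, config$interruption_rate * weeks)
    if (k == 0L) return(trace)
    drop <- logical(n)
    placed <- 0L
    tries <- 0L
    while (placed < k && tries < 200L * k) {
      tries <- tries + 1L
      len <- 2L + stats::rpois(1L, 3)
      s <- sample.int(n - len - 2L, 1L) + 1L  # keep first and last sample
      idx <- s:(s + len - 1L)
      # avoid touching an existing gap so gap count stays exactly k
      if (!any(drop[max(1L, s - 1L):min(n, s + len)])) {
        drop[idx] <- TRUE
        placed <- placed + 1L
      }
    }
    trace$cgm <- trace$cgm[!drop, , drop = FALSE]
    rownames(trace$cgm) <- NULL
    trace
  })
}

#' Perturb event timestamps with Gaussian jitter
#'
#' Emulates the heterogeneous clocks of real event streams, whose timestamps
#' rarely coincide with CGM timestamps. Jittered times are clamped inside the
#' CGM time range and each stream is re-sorted.
#'
#' @param trace A multivariate-style `raw_trace`.
#' @param sd Jitter standard deviation in seconds.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return The trace with perturbed event timestamps.
#' @export
jitter_event_timestamps <- function(trace, sd = 60, seed = NULL) {
  stopifnot(inherits(trace, "raw_trace"))
  if (trace$style != "multivariate_5min")
    stop("event jitter applies to multivariate style traces only")
  if (sd == 0) return(trace)
  with_seed(seed, {
    rng <- range(trace$cgm$time)
    for (stream in c("carbs", "bolus", "basal")) {
      df <- trace[[stream]]
      if (nrow(df) == 0L) next
      tt <- df$time + stats::rnorm(nrow(df), 0, sd)
      tt <- as.POSIXct(clamp(as.numeric(tt), as.numeric(rng[1]), as.numeric(rng[2])),
                       origin = "1970-01-01", tz = "UTC")
      df$time <- tt
      trace[[stream]] <- df[order(df$time), , drop = FALSE]
      rownames(trace[[stream]]) <- NULL
    }
    trace
  })
}

#' Simulate a full cohort
#'
#' Draws per-subject profiles and runs [simulate_subject()],
#' [inject_interruptions()] and (multivariate style) [jitter_event_timestamps()]
#' for each subject, all deterministically from `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A list of `raw_trace` objects with attribute `config`.
#' @examples
#' cohort <- simulate_cohort(cohort_config("multivariate_5min", n_subjects = 2,
#'                                         duration_days = 14, seed = 3))
#' length(cohort)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  profiles <- sample_profiles(config)
  traces <- lapply(seq_along(profiles), function(i) {
    tr <- simulate_subject(profiles[[i]], config,
                           seed = child_seed(config$seed, paste0("trace", i)))
    tr <- inject_interruptions(tr, config,
                               seed = child_seed(config$seed, paste0("gaps", i)))
    if (config$style == "multivariate_5min" && config$event_jitter_sd > 0)
      tr <- jitter_event_timestamps(tr, config$event_jitter_sd,
                                    seed = child_seed(config$seed, paste0("jit", i)))
    tr
  })
  attr(traces, "config") <- config
  attr(traces, "profiles") <- profiles
  traces
}

#' Write a cohort to CSV files plus a JSON manifest
#'
#' One CSV per stream per subject (columns `subject_id`, ISO-8601 `timestamp`,
#' `value`), and `manifest.json` recording the configuration and seed. The
#' file set round-trips losslessly through [read_cohort()].
#'
#' @param traces A list of `raw_trace` objects (e.g. from [simulate_cohort()]).
#' @param directory Output directory (created if missing).
#' @param config Optional [cohort_config()]; defaults to the cohort attribute.
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(traces, directory, config = attr(traces, "config")) {
  if (!dir.exists(directory) && !dir.create(directory, recursive = TRUE))
    stop("cannot create directory: ", directory)
  value_col <- c(cgm = "glucose", carbs = "grams", bolus = "units", basal = "rate")
  for (tr in traces) {
    for (stream in names(value_col)) {
      df <- tr[[stream]]
      out <- data.frame(subject_id = rep(tr$subject_id, nrow(df)),
                        timestamp = fmt_time(df$time),
                        value = format(df[[value_col[[stream]]]], digits = 17,
                                       scientific = FALSE, trim = TRUE))
      if (nrow(df) == 0L) out <- out[0L, ]
      utils::write.csv(out,
                       file.path(directory, paste0(tr$subject_id, "_", stream, ".csv")),
                       row.names = FALSE, quote = FALSE)
    }
  }
  manifest <- list(subjects = vapply(traces, `[[`, "", "subject_id"),
                   style = traces[[1L]]$style,
                   sampling_period = traces[[1L]]$sampling_period)
  if (!is.null(config)) {
    manifest$seed <- config$seed
    manifest$n_subjects <- config$n_subjects
    manifest$duration_days <- config$duration_days
    manifest$interruption_rate <- config$interruption_rate
    manifest$event_jitter_sd <- config$event_jitter_sd
    manifest$start <- fmt_time(config$start)
  }
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(directory)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param directory Directory containing the per-stream CSVs and
#'   `manifest.json`.
#' @return A list of `raw_trace` objects with attribute `manifest`.
#' @export
read_cohort <- function(directory) {
  manifest <- jsonlite::read_json(file.path(directory, "manifest.json"),
                                  simplifyVector = TRUE)
  value_col <- c(cgm = "glucose", carbs = "grams", bolus = "units", basal = "rate")
  traces <- lapply(manifest$subjects, function(id) {
    streams <- lapply(names(value_col), function(stream) {
      df <- utils::read.csv(file.path(directory, paste0(id, "_", stream, ".csv")),
                            colClasses = c("character", "character", "numeric"))
      out <- data.frame(time = parse_time(df$timestamp), value = df$value)
      names(out)[2L] <- value_col[[stream]]
      out
    })
    names(streams) <- names(value_col)
    structure(c(list(subject_id = id), streams,
                list(style = manifest$style,
                     sampling_period = as.integer(manifest$sampling_period))),
              class = "raw_trace")
  })
  attr(traces, "manifest") <- manifest
  traces
}

#' @export
print.raw_trace <- function(x, ...) {
  cat(sprintf("<raw_trace> subject %s, style %s, %d CGM samples (%s .. %s)\n",
              x$subject_id, x$style, nrow(x$cgm),
              fmt_time(x$cgm$time[1L]), fmt_time(x$cgm$time[nrow(x$cgm)])))
  if (x$style == "multivariate_5min")
    cat(sprintf("  events: %d carbs, %d bolus, %d basal\n",
                nrow(x$carbs), nrow(x$bolus), nrow(x$basal)))
  invisible(x)
}
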