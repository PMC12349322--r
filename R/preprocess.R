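# Preprocessing: gap detection, common-time-grid harmonization, sliding-window
# sequence generation, stratified splitting, z-score normalization and feature
# encoding.

#' Segment timestamps at reading interruptions
#'
#' Consecutive timestamps whose difference exceeds 2 x sampling period minus
#' one second (29:59 min at 15-min sampling) mark a reading interruption; a
#' new segment starts there.
#'
#' @param timestamps Strictly increasing POSIXct vector.
#' @param sampling_period Nominal sampling period, minutes.
#' @return Integer vector of segment ids (1-based), one per timestamp;
#'   `integer(0)` for an empty input.
#' @examples
#' t0 <- as.POSIXct("2023-01-01", tz = "UTC")
#' detect_gaps(t0 + c(0, 15, 30, 75, 90) * 60, 15)  # 45-min jump -> 2 segments
#' @export
detect_gaps <- function(timestamps, sampling_period) {
  n <- length(timestamps)
  if (n == 0L) return(integer(0))
  dt <- diff(as.numeric(timestamps))
  if (n > 1L && any(dt <= 0)) stop("timestamps must be strictly increasing")
  threshold <- 2 * sampling_period * 60 - 1  # seconds
  cumsum(c(1L, as.integer(dt > threshold)))
}

#' Harmonize a raw trace onto a common time grid
#'
#' Builds the regular grid spanning the first to last CGM timestamp at the
#' sampling period, assigns every CGM sample and every event to its closest
#' grid slot (ties break toward the earlier slot), zero-fills carb/bolus slots
#' with no event, carries the basal rate forward until updated, and declares a
#' reading interruption wherever two consecutive CGM samples share the same
#' closest slot or a slot receives no CGM sample.
#'
#' @param trace A `raw_trace` with at least 2 CGM samples.
#' @return An object of class `common_grid`: a data frame with columns
#'   `time`, `cgm`, `carbs`, `bolus`, `basal`, `segment`, and attributes
#'   `subject_id` and `sampling_period`. Rows are only the slots that received
#'   a CGM sample; `segment` increments at every declared interruption.
#' @export
build_common_grid <- function(trace) {
  stopifnot(inherits(trace, "raw_trace"))
  if (nrow(trace$cgm) < 2L) stop("trace needs >= 2 cgm samples")
  period_s <- trace$sampling_period * 60
  t0 <- as.numeric(trace$cgm$time[1L])
  t1 <- as.numeric(trace$cgm$time[nrow(trace$cgm)])
  n_slot <- floor((t1 - t0) / period_s) + 1L

  nearest_slot <- function(tt) {
    # round to nearest slot, exact midpoints toward the earlier slot
    idx <- ceiling((as.numeric(tt) - t0) / period_s - 0.5) + 1L
    clamp(idx, 1L, n_slot)
  }

  slot <- nearest_slot(trace$cgm$time)
  dup <- c(FALSE, diff(slot) == 0L)  # same closest match for two consecutive samples
  cgm_val <- rep(NA_real_, n_slot)
  cgm_val[slot[!dup]] <- trace$cgm$glucose[!dup]
  dup_break <- rep(FALSE, n_slot)
  dup_break[slot[dup]] <- TRUE

  carbs <- numeric(n_slot); bolus <- numeric(n_slot)
  if (nrow(trace$carbs)) {
    s <- nearest_slot(trace$carbs$time)
    for (j in seq_along(s)) carbs[s[j]] <- carbs[s[j]] + trace$carbs$grams[j]
  }
  if (nrow(trace$bolus)) {
    s <- nearest_slot(trace$bolus$time)
    for (j in seq_along(s)) bolus[s[j]] <- bolus[s[j]] + trace$bolus$units[j]
  }
  basal <- numeric(n_slot)
  if (nrow(trace$basal)) {
    s <- nearest_slot(trace$basal$time)
    # last value carried forward; before the first event, its value backwards
    val <- rep(NA_real_, n_slot)
    val[s] <- trace$basal$rate  # later events win on slot collision
    filled <- !is.na(val)
    idx <- cummax(ifelse(filled, seq_len(n_slot), 0L))
    basal <- ifelse(idx > 0L, val[pmax(idx, 1L)], trace$basal$rate[1L])
  }

  keep <- !is.na(cgm_val)
  times <- as.POSIXct(t0 + (seq_len(n_slot) - 1L) * period_s,
                      origin = "1970-01-01", tz = "UTC")
  slot_gap <- c(FALSE, diff(which(keep)) > 1L)
  # a duplicate match interrupts the sequence after the affected slot
  dup_prev <- c(FALSE, utils::head(dup_break[keep], -1L))
  segment <- cumsum(as.integer(slot_gap | dup_prev)) + 1L
  grid <- data.frame(time = times[keep], cgm = cgm_val[keep],
                     carbs = carbs[keep], bolus = bolus[keep],
                     basal = basal[keep], segment = segment)
  rownames(grid) <- NULL
  structure(grid, class = c("common_grid", "data.frame"),
            subject_id = trace$subject_id,
            sampling_period = trace$sampling_period)
}

#' Generate supervised sequence instances by sliding windows
#'
#' Sweeps a stride-1 window of `input_len` past samples plus `horizon` future
#' samples through every gap-free segment of a common grid. A segment of
#' length L yields `max(0, L - input_len - horizon + 1)` instances. Each
#' instance is annotated with the calendar trimester (quarter) of its anchor
#' (the last input sample) and whether its full span crosses a trimester
#' boundary.
#'
#' @param grid A `common_grid` (from [build_common_grid()]).
#' @param input_len Number of past samples per instance (default 96).
#' @param horizon Number of future samples to predict, `H = PH /
#'   sampling_period`.
#' @return A data frame with one row per instance: `subject_id`, `start` (row
#'   index into `grid` of the first input sample), `anchor_time`, `trimester`
#'   (`"Q1"`..`"Q4"`), and `cross_trimester`.
#' @export
generate_instances <- function(grid, input_len = 96L, horizon) {
  stopifnot(inherits(grid, "common_grid"), input_len >= 1L, horizon >= 1L)
  span <- input_len + horizon
  out <- list()
  for (seg in unique(grid$segment)) {
    idx <- which(grid$segment == seg)
    L <- length(idx)
    n_inst <- L - span + 1L
    if (n_inst < 1L) next
    start <- idx[seq_len(n_inst)]
    anchor <- grid$time[start + input_len - 1L]
    q_first <- quarter_of(grid$time[start])
    q_last <- quarter_of(grid$time[start + span - 1L])
    out[[length(out) + 1L]] <- data.frame(
      subject_id = attr(grid, "subject_id"),
      start = start,
      anchor_time = anchor,
      trimester = paste0("Q", quarter_of(anchor)),
      cross_trimester = q_first != q_last)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(subject_id = character(), start = integer(),
               anchor_time = as.POSIXct(character(), tz = "UTC"),
               trimester = character(), cross_trimester = logical())
  rownames(res) <- NULL
  res
}

# Largest-remainder apportionment of n into proportions f.
#' @noRd
largest_remainder <- function(n, f) {
  raw <- n * f
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    # ties in fractional parts break toward earlier entries (train > val > test)
    ord <- order(-(raw - base), seq_along(f))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
  }
  as.integer(base)
}

#' Split sequence instances into train / validation / test sets
#'
#' Two conventions are supported. `"trimester"` (the CGM-only, year-long
#' regime): within each (subject, trimester) stratum instances are randomly
#' partitioned in the given proportions with largest-remainder rounding, after
#' excluding instances whose span crosses a trimester boundary.
#' `"chronological"` (the short multivariate regime, emulating a fixed
#' pre-made partition): each subject's instances are split in time order.
#'
#' @param instances Instance table from [generate_instances()] (rows from
#'   several subjects may be concatenated).
#' @param method `"trimester"` or `"chronological"`.
#' @param fractions Train/validation/test proportions; must sum to 1. Defaults
#'   to (0.6, 0.2, 0.2) for `"trimester"` and (0.65, 0.16, 0.19) for
#'   `"chronological"`.
#' @param seed Optional integer seed for the random partition.
#' @return The instance table with a `set` column (`"train"`, `"validation"`,
#'   `"test"`, or `"excluded"` for cross-trimester instances) and attribute
#'   `split_counts`.
#' @export
split_instances <- function(instances,
                            method = c("trimester", "chronological"),
                            fractions = NULL,
                            seed = NULL) {
  method <- match.arg(method)
  if (is.null(fractions))
    fractions <- if (method == "trimester") c(0.6, 0.2, 0.2) else c(0.65, 0.16, 0.19)
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  stopifnot(length(fractions) == 3L)
  set <- rep(NA_character_, nrow(instances))
  labels <- c("train", "validation", "test")
  with_seed(seed, {
    if (method == "trimester") {
      excl <- instances$cross_trimester
      set[excl] <- "excluded"
      strata <- interaction(instances$subject_id, instances$trimester, drop = TRUE)
      for (st in levels(strata)) {
        idx <- which(strata == st & !excl)
        if (!length(idx)) next
        counts <- largest_remainder(length(idx), fractions)
        perm <- sample(idx)
        set[perm] <- rep(labels, counts)
      }
    } else {
      for (id in unique(instances$subject_id)) {
        idx <- which(instances$subject_id == id)
        idx <- idx[order(instances$anchor_time[idx])]
        counts <- largest_remainder(length(idx), fractions)
        set[idx] <- rep(labels, counts)
      }
    }
  })
  instances$set <- set
  attr(instances, "split_counts") <- table(factor(set, levels = c(labels, "excluded")))
  instances
}

#' Prepare a modelling dataset from raw traces
#'
#' Convenience pipeline: builds the common grid for every trace, generates
#' sliding-window instances, and splits them by the convention matching the
#' cohort style (trimester-stratified 60/20/20 for the CGM-only style,
#' chronological 65/16/19 for the multivariate style).
#'
#' @param traces List of `raw_trace` objects (e.g. [simulate_cohort()]).
#' @param input_len Input window length in samples (default 96).
#' @param ph Prediction horizon in minutes (default 60); must be divisible by
#'   the sampling period. The target length is `H = ph / sampling_period`.
#' @param seed Optional seed for the random split.
#' @param split_method Override the style-implied split convention.
#' @return An object of class `glucast_dataset`: list with `grids` (named list
#'   of `common_grid`), `instances` (with `set` column), `input_len`,
#'   `horizon`, `sampling_period`, `style`, `subjects`.
#' @examples
#' cohort <- simulate_cohort(cohort_config("multivariate_5min", n_subjects = 2,
#'                                         duration_days = 14, seed = 3))
#' ds <- prepare_dataset(cohort, seed = 3)
#' table(ds$instances$set)
#' @export
prepare_dataset <- function(traces, input_len = 96L, ph = 60L, seed = NULL,
                            split_method = NULL) {
  style <- traces[[1L]]$style
  period <- traces[[1L]]$sampling_period
  if (ph %% period != 0L) stop("ph must be divisible by the sampling period")
  horizon <- as.integer(ph / period)
  grids <- lapply(traces, build_common_grid)
  names(grids) <- vapply(traces, `[[`, "", "subject_id")
  inst <- do.call(rbind, lapply(grids, generate_instances,
                                input_len = input_len, horizon = horizon))
  rownames(inst) <- NULL
  if (is.null(split_method))
    split_method <- if (style == "cgm_only_15min") "trimester" else "chronological"
  inst <- split_instances(inst, method = split_method, seed = seed)
  structure(list(grids = grids, instances = inst,
                 input_len = as.integer(input_len), horizon = horizon,
                 sampling_period = period, style = style,
                 subjects = names(grids)),
            class = "glucast_dataset")
}

#' @export
print.glucast_dataset <- function(x, ...) {
  cat(sprintf("<glucast_dataset> style %s, %d subjects, N=%d, H=%d\n",
              x$style, length(x$subjects), x$input_len, x$horizon))
  print(table(x$instances$set))
  invisible(x)
}

# ---- feature encoding -------------------------------------------------------

# Incremental feature orders per style (the order variables were added in the
# incremental study; a model's feature set must be drawn from its style's set).
.feature_order <- list(
  cgm_only_15min = c("cgm", "id", "hour", "day_of_week", "day_of_month", "month"),
  multivariate_5min = c("cgm", "id", "hour", "day_of_week", "basal", "carbs", "bolus"))

.feature_types <- c(cgm = "real", id = "static", hour = "real",
                    day_of_week = "categorical", day_of_month = "real",
                    month = "categorical", basal = "real", carbs = "real",
                    bolus = "real")

#' Incremental feature order for a cohort style
#'
#' @param style `"cgm_only_15min"` or `"multivariate_5min"`.
#' @return Character vector of feature names in the order they are added in
#'   the incremental study.
#' @export
feature_order <- function(style = c("cgm_only_15min", "multivariate_5min")) {
  .feature_order[[match.arg(style)]]
}

#' Encode sequence instances as model input arrays
#'
#' Materializes a feature set into numeric arrays: time-varying real channels
#' (CGM; hour in [0, 24); day-of-month 1-31; basal/carbs/bolus) and the two
#' auxiliary position channels `time_index` and `relative_time_index`;
#' time-varying categorical channels (day-of-week, Monday = 0; month 1-12);
#' the static categorical subject id. Decoder (known-future) inputs are the
#' calendar channels plus the position channels. The target is the future CGM
#' vector.
#'
#' @param dataset A `glucast_dataset`.
#' @param features Character vector of feature names; must belong to the
#'   dataset style's feature set ([feature_order()]). `"cgm"` is always
#'   required.
#' @param sets Which split sets to encode (default train/validation/test).
#' @return An object of class `glucast_encoded`: arrays `enc_real`
#'   (n x N x C_real), `enc_cat` (n x N x C_cat, integer levels),
#'   `dec_real`, `dec_cat`, `static` (integer subject index or NULL),
#'   `target` (n x H), plus channel names, level counts, instance metadata
#'   and the split assignment.
#' @export
encode_features <- function(dataset, features,
                            sets = c("train", "validation", "test")) {
  stopifnot(inherits(dataset, "glucast_dataset"))
  allowed <- feature_order(dataset$style)
  bad <- setdiff(features, allowed)
  if (length(bad))
    stop("feature(s) not available in style ", dataset$style, ": ",
         paste(bad, collapse = ", "))
  if (!"cgm" %in% features) stop("'cgm' must be part of every feature set")

  inst <- dataset$instances[dataset$instances$set %in% sets, , drop = FALSE]
  n <- nrow(inst)
  N <- dataset$input_len; H <- dataset$horizon
  enc_real_names <- intersect(c("cgm", "hour", "day_of_month", "basal",
                                "carbs", "bolus"), features)
  enc_real_names <- c(enc_real_names, "time_index", "relative_time_index")
  enc_cat_names <- intersect(c("day_of_week", "month"), features)
  dec_real_names <- c(intersect(c("hour", "day_of_month"), features),
                      "time_index", "relative_time_index")
  dec_cat_names <- enc_cat_names
  has_static <- "id" %in% features

  enc_real <- array(0, c(n, N, length(enc_real_names)),
                    dimnames = list(NULL, NULL, enc_real_names))
  enc_cat <- if (length(enc_cat_names))
    array(0L, c(n, N, length(enc_cat_names)),
          dimnames = list(NULL, NULL, enc_cat_names)) else NULL
  dec_real <- array(0, c(n, H, length(dec_real_names)),
                    dimnames = list(NULL, NULL, dec_real_names))
  dec_cat <- if (length(dec_cat_names))
    array(0L, c(n, H, length(dec_cat_names)),
          dimnames = list(NULL, NULL, dec_cat_names)) else NULL
  target <- matrix(0, n, H)

  # position channels are the same for every instance
  tidx <- (seq_len(N + H) - 1) / (N + H - 1)            # absolute position in window
  ridx <- (seq_len(N + H) - N) / H                      # relative to prediction point
  enc_real[, , "time_index"] <- matrix(tidx[1:N], n, N, byrow = TRUE)
  enc_real[, , "relative_time_index"] <- matrix(ridx[1:N], n, N, byrow = TRUE)
  dec_real[, , "time_index"] <- matrix(tidx[N + 1:H], n, H, byrow = TRUE)
  dec_real[, , "relative_time_index"] <- matrix(ridx[N + 1:H], n, H, byrow = TRUE)

  subj_levels <- dataset$subjects
  static <- if (has_static) integer(n) else NULL

  for (id in unique(inst$subject_id)) {
    rows <- which(inst$subject_id == id)
    g <- dataset$grids[[id]]
    # per-grid feature columns, computed once then window-indexed
    cols <- list(cgm = g$cgm)
    if ("hour" %in% dec_real_names) cols$hour <- hour_real(g$time)
    if ("day_of_month" %in% dec_real_names) cols$day_of_month <- day_of_month(g$time)
    for (ch in intersect(c("basal", "carbs", "bolus"), enc_real_names))
      cols[[ch]] <- g[[ch]]
    if ("day_of_week" %in% enc_cat_names) cols$day_of_week <- dow_index(g$time) + 1L
    if ("month" %in% enc_cat_names) cols$month <- month_index(g$time)

    idx_in <- outer(inst$start[rows], 0:(N - 1L), `+`)
    idx_out <- outer(inst$start[rows], N + 0:(H - 1L), `+`)
    grab <- function(v, idx) matrix(v[idx], nrow(idx), ncol(idx))

    enc_real[rows, , "cgm"] <- grab(cols$cgm, idx_in)
    target[rows, ] <- grab(cols$cgm, idx_out)
    for (ch in setdiff(enc_real_names, c("cgm", "time_index", "relative_time_index")))
      enc_real[rows, , ch] <- grab(cols[[ch]], idx_in)
    for (ch in setdiff(dec_real_names, c("time_index", "relative_time_index")))
      dec_real[rows, , ch] <- grab(cols[[ch]], idx_out)
    for (ch in enc_cat_names) {
      enc_cat[rows, , ch] <- grab(cols[[ch]], idx_in)
      dec_cat[rows, , ch] <- grab(cols[[ch]], idx_out)
    }
    if (has_static) static[rows] <- match(id, subj_levels)
  }

  cat_levels <- c(day_of_week = 7L, month = 12L)
  structure(list(enc_real = enc_real, enc_cat = enc_cat,
                 dec_real = dec_real, dec_cat = dec_cat,
                 static = static, target = target,
                 enc_real_names = enc_real_names, enc_cat_names = enc_cat_names,
                 dec_real_names = dec_real_names, dec_cat_names = dec_cat_names,
                 cat_levels = cat_levels[enc_cat_names],
                 n_static_levels = if (has_static) length(subj_levels) else 0L,
                 features = features, instances = inst,
                 input_len = N, horizon = H,
                 sampling_period = dataset$sampling_period,
                 style = dataset$style, subjects = subj_levels),
            class = "glucast_encoded")
}

# Real channels subject to z-scoring (position channels are already on a
# fixed bounded scale and are left untouched).
#' @noRd
norm_channels <- function(encoded)
  setdiff(encoded$enc_real_names, c("time_index", "relative_time_index"))

#' Fit z-score normalization statistics on the training set
#'
#' Per-channel mean and standard deviation of every real-valued feature,
#' computed over all training instances and time steps. The target shares the
#' CGM channel's statistics. Categorical and position channels are untouched.
#'
#' @param encoded A `glucast_encoded` object.
#' @return An object of class `norm_stats`: named vectors `mean` and `sd`.
#' @export
fit_normalization <- function(encoded) {
  stopifnot(inherits(encoded, "glucast_encoded"))
  train <- encoded$instances$set == "train"
  if (!any(train)) stop("training set is empty")
  chans <- norm_channels(encoded)
  mu <- sd <- stats::setNames(numeric(length(chans)), chans)
  for (ch in chans) {
    v <- as.numeric(encoded$enc_real[train, , ch])
    mu[ch] <- mean(v)
    sd[ch] <- stats::sd(v)
    if (!is.finite(sd[ch]) || sd[ch] <= 0)
      stop("zero-variance feature cannot be z-scored: ", ch)
  }
  structure(list(mean = mu, sd = sd), class = "norm_stats")
}

#' Apply (or invert) z-score normalization
#'
#' @param encoded A `glucast_encoded` object.
#' @param stats A `norm_stats` from [fit_normalization()] (fitted on the
#'   training set and reused unchanged for validation/test).
#' @return The encoded object with real channels and target transformed;
#'   attribute `normalized` set.
#' @export
apply_normalization <- function(encoded, stats) {
  stopifnot(inherits(encoded, "glucast_encoded"), inherits(stats, "norm_stats"))
  if (isTRUE(attr(encoded, "normalized"))) stop("already normalized")
  for (ch in norm_channels(encoded))
    encoded$enc_real[, , ch] <- (encoded$enc_real[, , ch] - stats$mean[ch]) / stats$sd[ch]
  for (ch in intersect(encoded$dec_real_names, names(stats$mean)))
    encoded$dec_real[, , ch] <- (encoded$dec_real[, , ch] - stats$mean[ch]) / stats$sd[ch]
  encoded$target <- (encoded$target - stats$mean["cgm"]) / stats$sd["cgm"]
  attr(encoded, "normalized") <- TRUE
  encoded
}

#' Invert the target/CGM normalization
#'
#' @param x Numeric vector/matrix/array in normalized units.
#' @param stats The `norm_stats` used for normalization.
#' @return `x` back in mg/dL (exact to numerical precision).
#' @export
denormalize_glucose <- function(x, stats) {
  stopifnot(inherits(stats, "norm_stats"))
  x * stats$sd[["cgm"]] + stats$mean[["cgm"]]
}
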