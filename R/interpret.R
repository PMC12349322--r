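# Interpretability exports: attention-over-input profiles, encoder/decoder
# feature-importance percentages, and instance-wise prediction/uncertainty
# records.

#' Attention profile over the input sequence
#'
#' Mean attention weight over the N input positions for one predicted step
#' (by default the first predicted sample, whose attention is representative
#' of the whole output sequence). Position N-1 is the most recent input
#' sample, one sampling period before the prediction.
#'
#' @param bundle An `interpretability_bundle` (from [predict.glucast()]).
#' @param tau Predicted step, 1..H.
#' @param instance With a bundle holding full per-instance attention
#'   (`return_attention = "full"`), pick a single instance instead of the
#'   test-set mean.
#' @return An object of class `attention_profile`: weights (length N, summing
#'   to 1), `tau`, `lead_time_min` per position (negative = past).
#' @export
attention_profile <- function(bundle, tau = 1L, instance = NULL) {
  stopifnot(inherits(bundle, "interpretability_bundle"))
  if (tau > bundle$horizon) stop("tau exceeds the horizon H = ", bundle$horizon)
  if (is.null(bundle$attention_mean)) stop("bundle carries no attention")
  w <- if (is.null(instance)) bundle$attention_mean[tau, ] else {
    if (is.null(bundle$attention_full))
      stop("bundle was not built with return_attention = 'full'")
    bundle$attention_full[instance, tau, ]
  }
  N <- bundle$input_len
  structure(list(weights = as.numeric(w), tau = as.integer(tau),
                 aggregation = if (is.null(instance)) "mean_over_test" else "single_instance",
                 lead_time_min = (seq_len(N) - N) * bundle$sampling_period),
            class = "attention_profile")
}

#' @export
plot.attention_profile <- function(x, ...) {
  graphics::plot(x$lead_time_min, x$weights, type = "l",
                 xlab = "lead time of input position (min)",
                 ylab = "attention weight",
                 main = sprintf("Attention over input sequence (tau = %d)", x$tau),
                 ...)
  graphics::abline(h = 1 / length(x$weights), lty = 3)
  invisible(x)
}

#' Feature importance from the variable selection networks
#'
#' Per-feature selection weights averaged over time steps and instances,
#' renormalized to percentages. The encoder report covers the time-varying
#' input features plus the auxiliary position channels (`time_index`,
#' `relative_time_index`); the static subject id is excluded, as its
#' selection weight is not comparable with time-varying features. The decoder
#' report covers the known-future inputs and therefore never contains the
#' CGM reading (the target variable itself).
#'
#' @param bundle An `interpretability_bundle`.
#' @param part `"encoder"` or `"decoder"`.
#' @return An object of class `feature_importance`: named percentages summing
#'   to 100.
#' @export
feature_importance <- function(bundle, part = c("encoder", "decoder")) {
  part <- match.arg(part)
  stopifnot(inherits(bundle, "interpretability_bundle"))
  w <- if (part == "encoder") bundle$vsn_encoder else bundle$vsn_decoder
  pct <- 100 * w / sum(w)
  structure(list(part = part, importance = pct),
            class = "feature_importance")
}

#' @export
print.feature_importance <- function(x, ...) {
  cat(sprintf("<feature_importance> %s\n", x$part))
  imp <- sort(x$importance, decreasing = TRUE)
  for (nm in names(imp)) cat(sprintf("  %-20s %6.2f%%\n", nm, imp[[nm]]))
  invisible(x)
}

#' Export one instance as a plot-ready record
#'
#' Bundles the input CGM window, the true future values, the predicted
#' quantiles and the interval width per horizon step into a plain list that
#' round-trips through JSON — sufficient to reproduce instance-wise
#' prediction/uncertainty panels.
#'
#' @param forecast A `glucast_forecast`.
#' @param instance Instance row index.
#' @param dataset Optional `glucast_dataset` to include the input CGM window.
#' @return A list with `input_cgm` (when dataset given), `truth`, `p_lo`,
#'   `p50`, `p_hi`, `interval_width`, `lead_time_min`, `subject_id`,
#'   `anchor_time`.
#' @export
export_instance <- function(forecast, instance = 1L, dataset = NULL) {
  stopifnot(inherits(forecast, "glucast_forecast"))
  qa <- forecast$quantiles
  nq <- dim(qa)[3L]
  lo <- qa[instance, , 1L]; hi <- qa[instance, , nq]
  rec <- list(subject_id = forecast$instances$subject_id[instance],
              anchor_time = fmt_time(forecast$instances$anchor_time[instance]),
              lead_time_min = seq_len(forecast$horizon) * forecast$sampling_period,
              truth = as.numeric(forecast$truth[instance, ]),
              p_lo = as.numeric(lo),
              p50 = as.numeric(qa[instance, , "p50"]),
              p_hi = as.numeric(hi),
              interval_width = as.numeric(hi - lo))
  if (!is.null(dataset)) {
    g <- dataset$grids[[rec$subject_id]]
    inst <- forecast$instances[instance, ]
    idx <- which(dataset$instances$subject_id == inst$subject_id &
                   dataset$instances$anchor_time == inst$anchor_time)[1L]
    start <- dataset$instances$start[idx]
    rec$input_cgm <- g$cgm[start + 0:(dataset$input_len - 1L)]
  }
  rec
}
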