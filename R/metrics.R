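# Evaluation surface: deterministic errors at the prediction horizon,
# ISO 15197:2015 accuracy zone, Consensus (Parkes) Error Grid A+B rate,
# normalized quantile risk (q-risk), and empirical interval coverage.

#' Deterministic forecast errors (RMSE, MAE, MAPE)
#'
#' Errors between the median (p50) forecast and the truth, in mg/dL (MAPE in
#' percent of the true value). `mode = "last_sample"` evaluates only the last
#' horizon step (the full prediction horizon, e.g. 60 min ahead);
#' `"full_sequence"` uses every horizon step.
#'
#' @param forecast A `glucast_forecast`, or an n x H matrix of p50 values.
#' @param truth n x H matrix of true glucose (taken from the forecast object
#'   when omitted).
#' @param mode `"last_sample"` or `"full_sequence"`.
#' @return Named vector `rmse`, `mae`, `mape`.
#' @export
deterministic_errors <- function(forecast, truth = NULL,
                                 mode = c("last_sample", "full_sequence")) {
  mode <- match.arg(mode)
  if (inherits(forecast, "glucast_forecast")) {
    if (is.null(truth)) truth <- forecast$truth
    p50 <- forecast$quantiles[, , "p50"]
  } else p50 <- forecast
  p50 <- as.matrix(p50); truth <- as.matrix(truth)
  if (!nrow(p50)) stop("empty forecast set")
  stopifnot(identical(dim(p50), dim(truth)))
  if (mode == "last_sample") {
    H <- ncol(p50)
    p50 <- p50[, H]; truth <- truth[, H]
  }
  err <- as.numeric(p50) - as.numeric(truth)
  c(rmse = sqrt(mean(err^2)),
    mae = mean(abs(err)),
    mape = 100 * mean(abs(err) / as.numeric(truth)))
}

#' ISO 15197:2015 accuracy-zone percentage
#'
#' Percentage of (reference, predicted) pairs within +/-15 mg/dL when the
#' reference is below 100 mg/dL, or within +/-15% of the reference at or
#' above 100 mg/dL (boundaries inclusive). The standard's criterion requires
#' 95% of points within.
#'
#' @param ref Reference glucose values, mg/dL (positive).
#' @param pred Predicted glucose values, mg/dL (same length).
#' @return Percentage in [0, 100].
#' @examples
#' iso_zone(c(90, 100), c(105, 116))  # first inside, second outside -> 50
#' @export
iso_zone <- function(ref, pred) {
  if (length(ref) != length(pred)) stop("ref and pred must have equal length")
  if (any(ref <= 0)) stop("reference glucose must be positive")
  within <- ifelse(ref < 100, abs(pred - ref) <= 15,
                   abs(pred - ref) <= 0.15 * ref)
  100 * mean(within)
}

# Consensus (Parkes) Error Grid for type 1 diabetes: zone-boundary polylines
# in (reference, predicted) mg/dL coordinates. Coordinates follow the
# published construction table of the grid (Pfutzner, Klonoff, Pardo &
# Parkes, J Diabetes Sci Technol 7(5):1275-1281, 2013, type 1 diabetes).
# "upper_A" is the upper limit of zone A, etc.; below "lower_C" is zone D,
# above "upper_D" is zone E (no E region below the identity line for T1D).
.ceg_t1 <- list(
  upper_A = cbind(c(0, 30, 140, 280, 430), c(50, 50, 170, 380, 550)),
  lower_A = cbind(c(50, 50, 170, 385, 550), c(0, 30, 145, 300, 450)),
  upper_B = cbind(c(0, 30, 50, 70, 260), c(60, 60, 80, 110, 550)),
  lower_B = cbind(c(120, 120, 260, 550), c(0, 30, 130, 250)),
  upper_C = cbind(c(0, 25, 50, 80, 125), c(100, 100, 125, 215, 550)),
  lower_C = cbind(c(250, 250, 550), c(0, 40, 150)),
  upper_D = cbind(c(0, 35, 50), c(150, 155, 550)))

#' Consensus Error Grid geometry (type 1 diabetes)
#'
#' @return Named list of zone-boundary polylines, each a two-column matrix of
#'   (reference, predicted) vertices in mg/dL.
#' @export
ceg_geometry <- function() .ceg_t1

# Piecewise-linear boundary value at reference x. Upper boundaries that end
# before x continue off the top of the grid (+Inf); lower boundaries that
# start after x are below the grid (-Inf).
#' @noRd
boundary_y <- function(poly, x, side) {
  xs <- poly[, 1L]; ys <- poly[, 2L]
  # vertical segments (duplicated x) collapse to their extreme vertex
  keep <- if (side == "lower") !duplicated(xs, fromLast = TRUE) else !duplicated(xs)
  xs <- xs[keep]; ys <- ys[keep]
  out <- stats::approx(xs, ys, xout = x, rule = 1L)$y
  off <- if (side == "upper") Inf else -Inf
  out[x < xs[1L] | x > xs[length(xs)]] <- off
  out
}

#' Classify points on the Consensus (Parkes) Error Grid for T1D
#'
#' Zones A (clinically accurate) through E. Band membership is inclusive of
#' its boundary, checked from A outward, so every point in the plane receives
#' exactly one zone.
#'
#' @param ref Reference glucose, mg/dL (non-negative).
#' @param pred Predicted glucose, mg/dL (non-negative).
#' @return Factor of zone labels `A`..`E`.
#' @examples
#' ceg_zone(c(100, 100, 300), c(100, 180, 50))
#' @export
ceg_zone <- function(ref, pred) {
  if (length(ref) != length(pred)) stop("ref and pred must have equal length")
  if (any(ref < 0) || any(pred < 0)) stop("glucose values must be non-negative")
  g <- .ceg_t1
  zone <- rep("E", length(ref))
  in_band <- function(lo, hi) pred >= lo & pred <= hi
  uA <- boundary_y(g$upper_A, ref, "upper"); lA <- boundary_y(g$lower_A, ref, "lower")
  uB <- boundary_y(g$upper_B, ref, "upper"); lB <- boundary_y(g$lower_B, ref, "lower")
  uC <- boundary_y(g$upper_C, ref, "upper"); lC <- boundary_y(g$lower_C, ref, "lower")
  uD <- boundary_y(g$upper_D, ref, "upper")
  zone[pred > uC & pred <= uD] <- "D"
  zone[pred < lC] <- "D"
  zone[in_band(lC, uC)] <- "C"
  zone[in_band(lB, uB)] <- "B"
  zone[in_band(lA, uA)] <- "A"
  factor(zone, levels = c("A", "B", "C", "D", "E"))
}

#' Percentage of points in Consensus Error Grid zones A or B
#'
#' Zones A and B are considered clinically safe; the associated criterion
#' requires 99% of points within A union B.
#'
#' @inheritParams ceg_zone
#' @return Percentage in [0, 100].
#' @export
parkes_ab <- function(ref, pred) {
  z <- ceg_zone(ref, pred)
  100 * mean(z %in% c("A", "B"))
}

#' Normalized quantile risk (q-risk)
#'
#' `q-risk = 2 * sum QL(y, yhat_q, q) / sum |y|`, summed over every test
#' instance and every horizon step. Dimensionless; lower means less
#' uncertainty in the predicted quantile. At q = 0.5 it reduces to
#' `sum |y - yhat| / sum |y|`.
#'
#' @param truth n x H matrix of true glucose.
#' @param pred n x H matrix of the q-th predicted quantile.
#' @param q Quantile level in (0, 1).
#' @return The q-risk.
#' @examples
#' q_risk(matrix(100), matrix(90), 0.5)  # 2 * (0.5 * 10) / 100 = 0.1
#' @export
q_risk <- function(truth, pred, q) {
  truth <- as.matrix(truth); pred <- as.matrix(pred)
  stopifnot(identical(dim(truth), dim(pred)))
  denom <- sum(abs(truth))
  if (denom <= 0) stop("q-risk undefined: zero total |y| over the test domain")
  2 * sum(quantile_loss(truth, pred, q)) / denom
}

#' Empirical coverage of the predicted interval
#'
#' Percentage of (instance, horizon step) pairs whose true value falls inside
#' the band between the lowest and highest predicted quantiles (nominally
#' 80% for the 10th/90th percentiles).
#'
#' @param forecast A `glucast_forecast`, or an n x H x k quantile array.
#' @param truth n x H truth matrix (taken from the forecast when omitted).
#' @return Percentage in [0, 100].
#' @export
interval_coverage <- function(forecast, truth = NULL) {
  if (inherits(forecast, "glucast_forecast")) {
    if (is.null(truth)) truth <- forecast$truth
    qa <- forecast$quantiles
  } else qa <- forecast
  lo <- qa[, , 1L]; hi <- qa[, , dim(qa)[3L]]
  100 * mean(truth >= lo & truth <= hi)
}

#' Full evaluation report for one experiment
#'
#' Computes the deterministic metrics (on the median forecast, by default at
#' the last horizon sample only), the ISO-based metrics (ISOZone and
#' ParkesAB), the q-risk for every predicted quantile (over the whole output
#' sequence), and interval coverage, plus the ISO criteria flags
#' (ISOZone >= 95%, ParkesAB >= 99%).
#'
#' @param forecast A `glucast_forecast`.
#' @param mode Evaluation mode for the deterministic and ISO-based metrics:
#'   `"last_sample"` (default) or `"full_sequence"`.
#' @return An object of class `metrics_report` (also a one-row data frame
#'   via [as.data.frame.metrics_report()]).
#' @export
metrics_report <- function(forecast, mode = c("last_sample", "full_sequence")) {
  mode <- match.arg(mode)
  stopifnot(inherits(forecast, "glucast_forecast"))
  det <- deterministic_errors(forecast, mode = mode)
  H <- forecast$horizon
  sel <- if (mode == "last_sample") H else seq_len(H)
  ref <- as.numeric(forecast$truth[, sel])
  med <- as.numeric(forecast$quantiles[, sel, "p50"])
  qr <- vapply(seq_along(forecast$quantile_levels), function(j)
    q_risk(forecast$truth, forecast$quantiles[, , j], forecast$quantile_levels[j]),
    1)
  names(qr) <- paste0("p", forecast$quantile_levels * 100)
  structure(list(rmse = det[["rmse"]], mae = det[["mae"]], mape = det[["mape"]],
                 iso_zone = iso_zone(ref, med),
                 parkes_ab = parkes_ab(ref, med),
                 q_risk = qr,
                 coverage = interval_coverage(forecast),
                 iso_zone_criterion = iso_zone(ref, med) >= 95,
                 parkes_ab_criterion = parkes_ab(ref, med) >= 99,
                 evaluation_mode = mode,
                 n_instances = nrow(forecast$truth)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> (%s, %d instances)\n", x$evaluation_mode,
              x$n_instances))
  cat(sprintf("  RMSE %.2f  MAE %.2f  MAPE %.2f%%  (mg/dL, p50)\n",
              x$rmse, x$mae, x$mape))
  cat(sprintf("  ISOZone %.2f%% (>=95: %s)   ParkesAB %.2f%% (>=99: %s)\n",
              x$iso_zone, x$iso_zone_criterion,
              x$parkes_ab, x$parkes_ab_criterion))
  cat(sprintf("  q-risk: %s\n",
              paste(sprintf("%s=%.4f", names(x$q_risk), x$q_risk), collapse = "  ")))
  cat(sprintf("  interval coverage %.1f%% (nominal 80%%)\n", x$coverage))
  invisible(x)
}

#' @rdname metrics_report
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @export
as.data.frame.metrics_report <- function(x, ...) {
  df <- data.frame(rmse = x$rmse, mae = x$mae, mape = x$mape,
                   parkes_ab = x$parkes_ab, iso_zone = x$iso_zone,
                   coverage = x$coverage, mode = x$evaluation_mode,
                   n = x$n_instances)
  for (nm in names(x$q_risk)) df[[paste0("qrisk_", nm)]] <- x$q_risk[[nm]]
  df
}
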