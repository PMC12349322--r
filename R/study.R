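# Incremental input-feature study: train one forecaster per growing feature
# set (each experiment's features strictly extend the previous experiment's)
# on a shared simulated cohort, and collect the full evaluation surface per
# experiment.

#' Run the incremental feature-addition study
#'
#' For each prefix of the style's feature order (CGM-only regime: CGM, +ID,
#' +hour, +day of week, +day of month, +month — 6 experiments; multivariate
#' regime: CGM, +ID, +hour, +day of week, +basal, +carbs, +bolus — 7
#' experiments) the pipeline simulates (once), prepares, trains, evaluates
#' and extracts interpretability. The baseline is the model trained solely
#' on CGM readings. The whole study is deterministic given (config, seed).
#'
#' @param config A [cohort_config()] describing the cohort (simulated once
#'   and shared by all experiments), or a pre-built `glucast_dataset`.
#' @param ph Prediction horizon in minutes (default 60).
#' @param control A [glucast_control()] shared by all experiments.
#' @param seed Study seed (defaults to the cohort config seed).
#' @param features_list Optional list of feature sets overriding the default
#'   incremental prefixes (each must strictly extend the previous).
#' @param mode Evaluation mode for deterministic/ISO metrics.
#' @return An object of class `glucast_study`: `results` (one row per
#'   experiment), `reports`, `importance` (per-experiment encoder/decoder
#'   feature importances), `attention` (per-experiment mean profile at the
#'   first predicted sample), `models`, `seed`.
#' @export
run_study <- function(config, ph = 60L, control = glucast_control(),
                      seed = NULL, features_list = NULL,
                      mode = "last_sample") {
  if (inherits(config, "cohort_config")) {
    if (is.null(seed)) seed <- config$seed
    dataset <- prepare_dataset(simulate_cohort(config), ph = ph,
                               seed = child_seed(seed, "split"))
  } else if (inherits(config, "glucast_dataset")) {
    dataset <- config
    if (is.null(seed)) seed <- 1L
  } else stop("config must be a cohort_config or a glucast_dataset")

  order_all <- feature_order(dataset$style)
  if (is.null(features_list))
    features_list <- lapply(seq_along(order_all), function(k) order_all[1:k])
  for (k in seq_along(features_list)[-1L])
    if (!all(features_list[[k - 1L]] %in% features_list[[k]]) ||
        length(features_list[[k]]) <= length(features_list[[k - 1L]]))
      stop("each experiment's feature set must strictly extend the previous")

  rows <- list(); reports <- list(); importance <- list()
  attention <- list(); models <- list()
  for (k in seq_along(features_list)) {
    feats <- features_list[[k]]
    label <- paste(feats, collapse = "+")
    res <- tryCatch({
      fit <- glucast(dataset, feats, control = control,
                     seed = child_seed(seed, paste0("fit", k)))
      fc <- predict(fit, dataset, set = "test")
      rep <- metrics_report(fc, mode = mode)
      imp <- list(encoder = feature_importance(fc$bundle, "encoder"),
                  decoder = feature_importance(fc$bundle, "decoder"))
      att <- attention_profile(fc$bundle, tau = 1L)
      row <- as.data.frame(rep)
      row <- cbind(data.frame(experiment = k, features = label,
                              n_parameters = fit$n_parameters,
                              seed = fit$seed), row)
      list(row = row, rep = rep, imp = imp, att = att, fit = fit)
    }, error = function(e) {
      warning("experiment '", label, "' failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) next
    rows[[label]] <- res$row
    reports[[label]] <- res$rep
    importance[[label]] <- res$imp
    attention[[label]] <- res$att
    models[[label]] <- res$fit
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  structure(list(results = results, reports = reports,
                 importance = importance, attention = attention,
                 models = models, style = dataset$style, seed = seed),
            class = "glucast_study")
}

#' @export
print.glucast_study <- function(x, ...) {
  cat(sprintf("<glucast_study> %s, %d experiments\n", x$style,
              nrow(x$results)))
  cols <- c("experiment", "features", "rmse", "mae", "mape", "parkes_ab",
            "iso_zone", "coverage", "n_parameters")
  print(x$results[, intersect(cols, names(x$results))], row.names = FALSE,
        digits = 4)
  invisible(x)
}

#' Compare study rows against the CGM-only baseline
#'
#' Reports per-metric deltas of every experiment against the baseline (first
#' row), flags the best experiment per metric, and checks the qualitative
#' coupling between accuracy and uncertainty: the Spearman rank correlation
#' between RMSE and the median (p50) q-risk across experiments.
#'
#' @param study A `glucast_study` (or its `results` data frame).
#' @return A list: `deltas` (experiment x metric, baseline-relative), `best`
#'   (named vector of best experiment per metric), `rmse_qrisk_spearman`.
#' @export
compare_rows <- function(study) {
  results <- if (inherits(study, "glucast_study")) study$results else study
  if (nrow(results) < 2L) stop("need at least 2 experiment rows to compare")
  metrics <- intersect(c("rmse", "mae", "mape", "parkes_ab", "iso_zone",
                         "coverage", "qrisk_p10", "qrisk_p50", "qrisk_p90"),
                       names(results))
  deltas <- results[, metrics, drop = FALSE]
  deltas[] <- lapply(metrics, function(mc) results[[mc]] - results[[mc]][1L])
  rownames(deltas) <- results$features
  higher_better <- c("parkes_ab", "iso_zone")
  best <- vapply(metrics, function(mc) {
    v <- results[[mc]]
    results$features[if (mc %in% higher_better) which.max(v) else which.min(v)]
  }, "")
  rho <- if ("qrisk_p50" %in% metrics)
    suppressWarnings(stats::cor(results$rmse, results$qrisk_p50,
                                method = "spearman")) else NA_real_
  list(deltas = deltas, best = best, rmse_qrisk_spearman = rho)
}
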