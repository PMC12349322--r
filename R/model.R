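# Model fitting surface: quantile loss, training control, the glucast() fit
# function and its S3 methods.

#' Quantile (pinball) loss
#'
#' `QL(y, yhat, q) = q (y - yhat)_+ + (1 - q) (yhat - y)_+`. Its minimizer in
#' expectation is the q-th conditional quantile; training minimizes this loss
#' summed across all predicted quantiles and horizon steps.
#'
#' @param y True values.
#' @param yhat Predicted values (recycled against `y`).
#' @param q Quantile level, strictly inside (0, 1).
#' @return Elementwise non-negative losses.
#' @examples
#' quantile_loss(100, 90, 0.9)  # 0.9 * 10
#' quantile_loss(90, 100, 0.9)  # 0.1 * 10
#' @export
quantile_loss <- function(y, yhat, q) {
  if (!is.numeric(q) || any(q <= 0) || any(q >= 1))
    stop("q must lie strictly inside (0, 1)")
  d <- y - yhat
  q * pmax(d, 0) + (1 - q) * pmax(-d, 0)
}

#' Training control for the glucose forecaster
#'
#' Fixed defaults stand in for a per-experiment hyperparameter search: hidden
#' size 32 across layers, hidden size 16 for processing continuous variables,
#' 2 attention heads, dropout 0.1, learning rate 1e-3, gradient-norm clipping
#' at 1.0, batch size 128, and at most 50 epochs with best-validation-epoch
#' selection.
#'
#' @param hidden_size Width of all hidden layers (must be divisible by
#'   `n_heads`).
#' @param continuous_hidden Hidden width of the gated residual networks.
#' @param n_heads Number of attention heads (values shared across heads).
#' @param dropout Dropout rate during training.
#' @param learning_rate Adam learning rate.
#' @param max_gradient_norm Global gradient-norm clip (0 disables).
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum training epochs.
#' @param patience Epochs without validation improvement before stopping.
#' @param quantiles Predicted quantile levels; strictly increasing in (0, 1)
#'   and containing 0.5.
#' @param max_train_instances Cap on training instances (a seeded subsample
#'   is drawn when the training set is larger); `Inf` uses all.
#' @return A `glucast_control` list.
#' @export
glucast_control <- function(hidden_size = 32L,
                            continuous_hidden = 16L,
                            n_heads = 2L,
                            dropout = 0.1,
                            learning_rate = 1e-3,
                            max_gradient_norm = 1.0,
                            batch_size = 128L,
                            max_epochs = 50L,
                            patience = 5L,
                            quantiles = c(0.1, 0.5, 0.9),
                            max_train_instances = Inf) {
  if (any(diff(quantiles) <= 0) || any(quantiles <= 0) || any(quantiles >= 1))
    stop("quantiles must be strictly increasing inside (0, 1)")
  if (!0.5 %in% quantiles) stop("quantiles must contain the median 0.5")
  stopifnot(hidden_size >= 1L, continuous_hidden >= 1L, n_heads >= 1L,
            batch_size >= 1L, max_epochs >= 1L)
  structure(list(hidden_size = as.integer(hidden_size),
                 continuous_hidden = as.integer(continuous_hidden),
                 n_heads = as.integer(n_heads),
                 dropout = dropout,
                 learning_rate = learning_rate,
                 max_gradient_norm = max_gradient_norm,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 quantiles = quantiles,
                 max_train_instances = max_train_instances),
            class = "glucast_control")
}

#' @noRd
batch_slice <- function(encoded, idx) {
  list(enc_real = encoded$enc_real[idx, , , drop = FALSE],
       enc_cat = if (!is.null(encoded$enc_cat)) encoded$enc_cat[idx, , , drop = FALSE],
       dec_real = encoded$dec_real[idx, , , drop = FALSE],
       dec_cat = if (!is.null(encoded$dec_cat)) encoded$dec_cat[idx, , , drop = FALSE],
       static = if (!is.null(encoded$static)) encoded$static[idx],
       target = encoded$target[idx, , drop = FALSE])
}

#' @noRd
feature_spec_of <- function(encoded) {
  list(enc_real_names = encoded$enc_real_names,
       enc_cat_names = encoded$enc_cat_names,
       dec_real_names = encoded$dec_real_names,
       dec_cat_names = encoded$dec_cat_names,
       cat_levels = encoded$cat_levels,
       n_static_levels = encoded$n_static_levels)
}

# Mean loss (per instance, summed over quantiles/horizon) over a set, without
# dropout and without gradient bookkeeping.
#' @noRd
eval_loss <- function(model, encoded, idx, batch_size) {
  tot <- 0
  for (chunk in split(idx, ceiling(seq_along(idx) / batch_size))) {
    fw <- forward_forecaster(model, batch_slice(encoded, chunk), train = FALSE)
    tot <- tot + as.numeric(fw$loss$val) * length(chunk)
  }
  tot / length(idx)
}

#' Fit the interpretable quantile glucose forecaster
#'
#' Trains a compact temporal-fusion forecaster: per-feature embeddings, a
#' softmax variable selection network over features at each time step
#' (optionally conditioned on the subject embedding), a static covariate
#' encoder when the subject id is among the features, an LSTM
#' encoder-decoder for short-range structure, interpretable multi-head
#' attention over the input window for long-range structure, gated residual
#' connections throughout, and a linear head emitting one value per quantile
#' level and horizon step. Training minimizes the pinball loss summed across
#' quantiles and horizon with Adam and gradient clipping; the epoch with the
#' best validation loss is kept.
#'
#' @param dataset A `glucast_dataset` from [prepare_dataset()].
#' @param features Feature set, e.g. `c("cgm", "id", "hour")`; see
#'   [feature_order()].
#' @param control A [glucast_control()].
#' @param seed Integer seed controlling initialization, batch order, dropout
#'   and any training subsample; fitting is deterministic given
#'   (dataset, features, control, seed).
#' @return An object of class `glucast` with methods `print`, `summary`,
#'   `coef`, `predict`, `residuals` and `plot`.
#' @seealso [predict.glucast()], [metrics_report()]
#' @export
glucast <- function(dataset, features = c("cgm"),
                    control = glucast_control(), seed = 1L) {
  stopifnot(inherits(dataset, "glucast_dataset"),
            inherits(control, "glucast_control"))
  encoded <- encode_features(dataset, features)
  norm <- fit_normalization(encoded)
  encoded <- apply_normalization(encoded, norm)

  train_idx <- which(encoded$instances$set == "train")
  val_idx <- which(encoded$instances$set == "validation")
  if (!length(train_idx) || !length(val_idx))
    stop("both train and validation sets must be non-empty")
  if (length(train_idx) > control$max_train_instances)
    train_idx <- with_seed(child_seed(seed, "subsample"),
                           sort(sample(train_idx, control$max_train_instances)))

  spec <- feature_spec_of(encoded)
  model <- with_seed(child_seed(seed, "init"), build_forecaster(spec, control))
  params <- collect_params(model)
  n_par <- param_count(params)

  log_rows <- list()
  best <- list(val = Inf, epoch = 0L, values = param_values(params))
  with_seed(child_seed(seed, "train"), {
    step <- 0L
    stale <- 0L
    for (epoch in seq_len(control$max_epochs)) {
      perm <- sample(train_idx)
      batches <- split(perm, ceiling(seq_along(perm) / control$batch_size))
      tr_loss <- 0
      for (bi in batches) {
        param_zero_grads(params)
        fw <- forward_forecaster(model, batch_slice(encoded, bi), train = TRUE)
        lv <- as.numeric(fw$loss$val)
        if (!is.finite(lv))
          stop("training diverged (non-finite loss) at epoch ", epoch)
        ad_backward(fw$tape, fw$loss)
        step <- step + 1L
        adam_step(params, control$learning_rate, control$max_gradient_norm,
                  t_step = step)
        tr_loss <- tr_loss + lv * length(bi)
      }
      tr_loss <- tr_loss / length(perm)
      va_loss <- eval_loss(model, encoded, val_idx, control$batch_size)
      log_rows[[epoch]] <- data.frame(epoch = epoch, train_loss = tr_loss,
                                      val_loss = va_loss)
      if (va_loss < best$val) {
        best <- list(val = va_loss, epoch = epoch, values = param_values(params))
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= control$patience) break
      }
    }
  })
  param_restore(params, best$values)

  structure(list(model = model, params = params, control = control,
                 features = features, spec = spec, norm = norm,
                 style = dataset$style, input_len = dataset$input_len,
                 horizon = dataset$horizon,
                 sampling_period = dataset$sampling_period,
                 subjects = dataset$subjects,
                 n_parameters = n_par,
                 log = do.call(rbind, log_rows),
                 best_epoch = best$epoch,
                 best_val_loss = best$val,
                 n_train = length(train_idx),
                 seed = seed,
                 call = match.call()),
            class = "glucast")
}

#' Predict quantile forecasts and interpretability weights
#'
#' Runs the fitted forecaster over a split set of a dataset, denormalizes the
#' predicted quantiles back to mg/dL, enforces quantile monotonicity by
#' per-step sorting, and extracts the attention and variable-selection
#' weights of the forward pass.
#'
#' @param object A fitted `glucast` model.
#' @param dataset A `glucast_dataset` of the same style and subject roster the
#'   model was trained on.
#' @param set Which split set to predict (default `"test"`).
#' @param return_attention `"mean"` keeps the test-set mean attention per
#'   horizon step (H x N); `"full"` additionally keeps per-instance attention
#'   (memory: n x H x N); `"none"` skips it.
#' @param ... Unused.
#' @return An object of class `glucast_forecast`: `quantiles` (n x H x
#'   n_quantiles array, mg/dL), `truth` (n x H, mg/dL), `instances` metadata,
#'   and `bundle`, an `interpretability_bundle` with mean attention per
#'   predicted step, encoder/decoder variable-selection weights, and the
#'   quantile levels.
#' @export
predict.glucast <- function(object, dataset, set = "test",
                            return_attention = c("mean", "full", "none"), ...) {
  return_attention <- match.arg(return_attention)
  stopifnot(inherits(dataset, "glucast_dataset"))
  if (dataset$style != object$style)
    stop("dataset style differs from the training style")
  if (!identical(dataset$subjects, object$subjects))
    stop("dataset subjects differ from the training roster")
  encoded <- encode_features(dataset, object$features, sets = set)
  encoded <- apply_normalization(encoded, object$norm)
  n <- nrow(encoded$instances)
  if (!n) stop("no instances in set '", set, "'")
  H <- encoded$horizon
  N <- encoded$input_len
  nq <- length(object$control$quantiles)

  qarr <- array(0, c(n, H, nq),
                dimnames = list(NULL, NULL, paste0("p", object$control$quantiles * 100)))
  attn_full <- if (return_attention == "full") array(0, c(n, H, N))
  attn_sum <- matrix(0, H, N)
  Fe <- length(object$spec$enc_real_names) + length(object$spec$enc_cat_names)
  Fd <- length(object$spec$dec_real_names) + length(object$spec$dec_cat_names)
  vsn_enc_sum <- numeric(Fe)
  vsn_dec_sum <- numeric(Fd)

  idx_all <- seq_len(n)
  for (chunk in split(idx_all, ceiling(idx_all / object$control$batch_size))) {
    fw <- forward_forecaster(object$model, batch_slice(encoded, chunk),
                             train = FALSE)
    B <- length(chunk)
    # yhat rows are time-major (tau-1)*B + b
    for (j in seq_len(nq))
      qarr[chunk, , j] <- matrix(fw$yhat[, j], B, H)
    if (return_attention != "none") {
      attn_sum <- attn_sum + apply(fw$attn, c(2L, 3L), sum)
      if (return_attention == "full") attn_full[chunk, , ] <- fw$attn
    }
    vsn_enc_sum <- vsn_enc_sum + colSums(fw$vsn_enc) / N
    vsn_dec_sum <- vsn_dec_sum + colSums(fw$vsn_dec) / H
  }

  qarr <- denormalize_glucose(qarr, object$norm)
  # enforce non-crossing quantiles per (instance, step)
  qarr <- aperm(apply(qarr, c(1L, 2L), sort), c(2L, 3L, 1L))
  dimnames(qarr)[[3L]] <- paste0("p", object$control$quantiles * 100)
  truth <- denormalize_glucose(encoded$target, object$norm)

  enc_names <- c(object$spec$enc_real_names, object$spec$enc_cat_names)
  dec_names <- c(object$spec$dec_real_names, object$spec$dec_cat_names)
  bundle <- structure(list(
    attention_mean = if (return_attention != "none") attn_sum / n,
    attention_full = attn_full,
    vsn_encoder = stats::setNames(vsn_enc_sum / n, enc_names),
    vsn_decoder = stats::setNames(vsn_dec_sum / n, dec_names),
    n_instances = n, input_len = N, horizon = H,
    sampling_period = object$sampling_period),
    class = "interpretability_bundle")

  structure(list(quantiles = qarr, truth = truth,
                 quantile_levels = object$control$quantiles,
                 instances = encoded$instances,
                 bundle = bundle,
                 features = object$features,
                 horizon = H, sampling_period = object$sampling_period),
            class = "glucast_forecast")
}

#' Small random hyperparameter search
#'
#' Samples `k` configurations (attention heads, hidden sizes, dropout,
#' learning rate, gradient clip) in the spirit of a trial-based search, fits
#' each, and returns the fit with the best validation loss. A lightweight
#' stand-in for a full Bayesian search, which is out of scope at desk scale.
#'
#' @param dataset A `glucast_dataset`.
#' @param features Feature set (see [feature_order()]).
#' @param k Number of sampled configurations.
#' @param control Base [glucast_control()] supplying everything not sampled
#'   (epochs, batch size, quantiles, instance cap).
#' @param seed Search seed.
#' @return The best `glucast` fit; attribute `trials` holds the sampled
#'   configurations and their validation losses.
#' @export
random_search <- function(dataset, features, k = 5L,
                          control = glucast_control(), seed = 1L) {
  stopifnot(k >= 1L)
  trials <- with_seed(child_seed(seed, "hyper"), {
    lapply(seq_len(k), function(i) {
      heads <- sample(c(1L, 2L, 4L), 1L)
      list(n_heads = heads,
           hidden_size = heads * sample(c(8L, 16L, 24L), 1L),
           continuous_hidden = sample(c(8L, 16L), 1L),
           dropout = stats::runif(1, 0, 0.3),
           learning_rate = 10^stats::runif(1, -3.5, -2),
           max_gradient_norm = stats::runif(1, 0.5, 2))
    })
  })
  best <- NULL
  losses <- numeric(k)
  for (i in seq_len(k)) {
    ctl <- control
    ctl[names(trials[[i]])] <- trials[[i]]
    fit <- glucast(dataset, features, control = ctl,
                   seed = child_seed(seed, paste0("trial", i)))
    losses[i] <- fit$best_val_loss
    if (is.null(best) || fit$best_val_loss < best$best_val_loss) best <- fit
  }
  attr(best, "trials") <- data.frame(
    trial = seq_len(k),
    n_heads = vapply(trials, `[[`, 1L, "n_heads"),
    hidden_size = vapply(trials, `[[`, 1L, "hidden_size"),
    dropout = vapply(trials, `[[`, 0, "dropout"),
    learning_rate = vapply(trials, `[[`, 0, "learning_rate"),
    val_loss = losses)
  best
}

#' Pinball loss of a persistence baseline
#'
#' The persistence forecast repeats the last observed CGM value for every
#' horizon step and quantile. Returns the mean per-instance loss (summed over
#' quantiles and horizon, normalized units), directly comparable to the
#' model's validation loss.
#'
#' @param object A fitted `glucast` model (for its normalization and
#'   quantiles).
#' @param dataset The `glucast_dataset`.
#' @param set Split set (default `"validation"`).
#' @return Mean pinball loss of persistence.
#' @export
persistence_loss <- function(object, dataset, set = "validation") {
  encoded <- encode_features(dataset, object$features, sets = set)
  encoded <- apply_normalization(encoded, object$norm)
  last <- encoded$enc_real[, encoded$input_len, "cgm"]
  tot <- 0
  for (q in object$control$quantiles)
    tot <- tot + sum(quantile_loss(encoded$target, last, q))
  tot / nrow(encoded$target)
}

#' @export
print.glucast_forecast <- function(x, ...) {
  cat(sprintf("<glucast_forecast> %d instances x H=%d, quantiles %s (mg/dL)\n",
              nrow(x$truth), x$horizon,
              paste(x$quantile_levels, collapse = "/")))
  cat(sprintf("  coverage of [p%g, p%g]: %.1f%%\n",
              100 * min(x$quantile_levels), 100 * max(x$quantile_levels),
              interval_coverage(x)))
  invisible(x)
}

#' @export
print.glucast <- function(x, ...) {
  cat(sprintf("<glucast> quantile forecaster (%s)\n", x$style))
  cat(sprintf("  features: %s\n", paste(x$features, collapse = ", ")))
  cat(sprintf("  N=%d, H=%d, quantiles %s\n", x$input_len, x$horizon,
              paste(x$control$quantiles, collapse = "/")))
  cat(sprintf("  parameters: %d; trained %d epochs (best %d, val loss %.4f)\n",
              x$n_parameters, nrow(x$log), x$best_epoch, x$best_val_loss))
  invisible(x)
}

#' @export
summary.glucast <- function(object, ...) {
  structure(list(features = object$features,
                 style = object$style,
                 n_parameters = object$n_parameters,
                 control = object$control,
                 log = object$log,
                 best_epoch = object$best_epoch,
                 best_val_loss = object$best_val_loss,
                 n_train = object$n_train,
                 norm = object$norm),
            class = "summary.glucast")
}

#' @export
print.summary.glucast <- function(x, ...) {
  cat("Interpretable quantile glucose forecaster\n")
  cat(sprintf("  style: %s\n  features: %s\n", x$style,
              paste(x$features, collapse = ", ")))
  cat(sprintf("  parameters: %d (hidden %d, heads %d)\n", x$n_parameters,
              x$control$hidden_size, x$control$n_heads))
  cat(sprintf("  trained on %d instances; best epoch %d, validation loss %.4f\n",
              x$n_train, x$best_epoch, x$best_val_loss))
  print(utils::tail(x$log, 5L), row.names = FALSE)
  invisible(x)
}

#' @export
coef.glucast <- function(object, ...) {
  vapply(object$params, function(p) length(p$val), 1)
}

#' Residuals of the median forecast
#'
#' @param object A fitted `glucast` model.
#' @param dataset The `glucast_dataset`.
#' @param set Split set (default `"validation"`).
#' @param ... Unused.
#' @return Matrix (instances x horizon) of `y - p50` in mg/dL.
#' @export
residuals.glucast <- function(object, dataset, set = "validation", ...) {
  fc <- predict(object, dataset, set = set, return_attention = "none")
  fc$truth - fc$quantiles[, , "p50"]
}

#' @export
plot.glucast <- function(x, ...) {
  graphics::matplot(x$log$epoch, cbind(x$log$train_loss, x$log$val_loss),
                    type = "b", pch = c(1, 19), lty = 1,
                    xlab = "epoch", ylab = "pinball loss (normalized)",
                    main = "Training history", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), pch = c(1, 19))
  invisible(x)
}

#' Plot one forecast instance with its prediction interval
#'
#' Draws the input CGM window, the true future values, the median forecast
#' and the shaded band between the lower and upper predicted quantiles.
#'
#' @param x A `glucast_forecast`.
#' @param instance Row index of the instance to draw.
#' @param dataset Optional `glucast_dataset` to recover the input window.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.glucast_forecast <- function(x, instance = 1L, dataset = NULL, ...) {
  H <- x$horizon
  steps <- seq_len(H) * x$sampling_period
  lo <- x$quantiles[instance, , 1L]
  hi <- x$quantiles[instance, , dim(x$quantiles)[3L]]
  med <- x$quantiles[instance, , "p50"]
  ylim <- range(lo, hi, x$truth[instance, ])
  graphics::plot(steps, x$truth[instance, ], type = "b", pch = 19,
                 ylim = ylim, xlab = "lead time (min)", ylab = "glucose (mg/dL)",
                 main = "Quantile forecast", ...)
  graphics::polygon(c(steps, rev(steps)), c(lo, rev(hi)),
                    col = grDevices::adjustcolor("darkgreen", 0.25), border = NA)
  graphics::lines(steps, med, col = "darkgreen", lwd = 2)
  invisible(x)
}
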