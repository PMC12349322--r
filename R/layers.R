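# Building blocks of the temporal-fusion forecaster: gated linear units,
# gated residual networks (GRN), variable selection networks (VSN), an LSTM
# sequence encoder-decoder, and interpretable multi-head attention with
# value weights shared across heads and additive head aggregation.
#
# Builders create parameter leaves (environments) and return a list holding
# them plus a forward closure operating on an autodiff tape.

#' @noRd
make_linear <- function(n_in, n_out) {
  prm <- list(W = ad_param(glorot(n_in, n_out)),
              b = ad_param(matrix(0, 1L, n_out)))
  prm$fwd <- function(tape, x) ad_add_bias(tape, ad_matmul(tape, x, prm$W), prm$b)
  prm
}

# Gated linear unit: sigmoid(x Wg + bg) * (x Wv + bv).
#' @noRd
make_glu <- function(d_in, d_out) {
  prm <- list(Wg = ad_param(glorot(d_in, d_out)),
              bg = ad_param(matrix(0, 1L, d_out)),
              Wv = ad_param(glorot(d_in, d_out)),
              bv = ad_param(matrix(0, 1L, d_out)))
  prm$fwd <- function(tape, x)
    ad_mul(tape,
           ad_sigmoid(tape, ad_add_bias(tape, ad_matmul(tape, x, prm$Wg), prm$bg)),
           ad_add_bias(tape, ad_matmul(tape, x, prm$Wv), prm$bv))
  prm
}

# Gated residual network (compact variant, no layer normalization):
#   a  = ELU(x W1 [+ c Wc] + b1);  out = skip(x) + GLU(a W2 + b2)
# with an optional external context c and a linear skip when dims differ.
#' @noRd
make_grn <- function(d_in, d_hidden, d_out, d_context = 0L) {
  prm <- list(W1 = ad_param(glorot(d_in, d_hidden)),
              b1 = ad_param(matrix(0, 1L, d_hidden)),
              W2 = ad_param(glorot(d_hidden, d_out)),
              b2 = ad_param(matrix(0, 1L, d_out)),
              glu = make_glu(d_out, d_out))
  if (d_context > 0L) prm$Wc <- ad_param(glorot(d_context, d_hidden))
  if (d_in != d_out) prm$Ws <- ad_param(glorot(d_in, d_out))
  prm$fwd <- function(tape, x, context = NULL, dropout = 0) {
    a <- ad_matmul(tape, x, prm$W1)
    if (!is.null(context)) a <- ad_add(tape, a, ad_matmul(tape, context, prm$Wc))
    a <- ad_elu(tape, ad_add_bias(tape, a, prm$b1))
    a2 <- ad_add_bias(tape, ad_matmul(tape, a, prm$W2), prm$b2)
    if (dropout > 0) a2 <- ad_dropout(tape, a2, dropout)
    skip <- if (is.null(prm$Ws)) x else ad_matmul(tape, x, prm$Ws)
    ad_add(tape, skip, prm$glu$fwd(tape, a2))
  }
  prm
}

# Variable selection network over F feature embeddings of width d: a GRN on
# the flattened embeddings (optionally conditioned on a static context) emits
# softmax weights, and the selected representation is the weighted sum of the
# per-feature embeddings. The softmax weights are the feature importances.
#' @noRd
make_vsn <- function(n_features, d, d_hidden, d_context = 0L) {
  prm <- list(grn = make_grn(n_features * d, d_hidden, n_features, d_context))
  prm$fwd <- function(tape, embeddings, context = NULL, dropout = 0) {
    flat <- ad_concat_cols(tape, embeddings)
    w <- ad_softmax(tape, prm$grn$fwd(tape, flat, context, dropout))
    parts <- lapply(seq_along(embeddings), function(f)
      ad_mul_col(tape, ad_slice_cols(tape, w, f), embeddings[[f]]))
    list(selected = ad_sum_list(tape, parts), weights = w)
  }
  prm
}

# Standard LSTM over a time-major input ((B*T) x d_in, row (t-1)*B + b),
# executed as one fused tape node (forget-gate bias initialized at 1).
#' @noRd
make_lstm <- function(d_in, d_hidden) {
  prm <- list(Wx = ad_param(glorot(d_in, 4L * d_hidden)),
              Wh = ad_param(glorot(d_hidden, 4L * d_hidden)),
              b = ad_param(matrix(rep(c(0, 1, 0, 0), each = d_hidden), 1L)))
  prm$fwd <- function(tape, x_big, B, T, h0, c0)
    ad_lstm(tape, x_big, B, T, h0, c0, prm$Wx, prm$Wh, prm$b)
  prm
}

# Collect every ad_param leaf from a nested builder structure into a flat
# named list (names are dotted paths), for the optimizer and introspection.
#' @noRd
collect_params <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    el <- x[[nm]]
    path <- if (nchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.environment(el) && isTRUE(el$leaf)) out[[path]] <- el
    else if (is.list(el)) out <- c(out, collect_params(el, path))
  }
  out
}

# ---- full forecaster --------------------------------------------------------

# Assemble all parameters of the forecaster for a given feature specification.
# When the feature set has no static covariate, the static encoder branch is
# absent: unused components are skipped rather than zeroed.
#' @noRd
build_forecaster <- function(spec, control) {
  d <- control$hidden_size
  dh <- control$continuous_hidden
  nh <- control$n_heads
  if (d %% nh != 0L) stop("hidden_size must be divisible by n_heads")
  dk <- d %/% nh
  nq <- length(control$quantiles)
  has_static <- spec$n_static_levels > 0L
  Fe <- length(spec$enc_real_names) + length(spec$enc_cat_names)
  Fd <- length(spec$dec_real_names) + length(spec$dec_cat_names)

  m <- list(
    enc_emb = lapply(stats::setNames(spec$enc_real_names, spec$enc_real_names),
                     function(nm) make_linear(1L, d)),
    dec_emb = lapply(stats::setNames(spec$dec_real_names, spec$dec_real_names),
                     function(nm) make_linear(1L, d)),
    cat_emb = lapply(stats::setNames(nm = spec$enc_cat_names),
                     function(nm) list(table = ad_param(glorot(spec$cat_levels[[nm]], d)))),
    vsn_enc = make_vsn(Fe, d, dh, if (has_static) d else 0L),
    vsn_dec = make_vsn(Fd, d, dh, if (has_static) d else 0L),
    lstm_enc = make_lstm(d, d),
    lstm_dec = make_lstm(d, d),
    glu_lstm = make_glu(d, d),
    grn_enrich = make_grn(d, dh, d, if (has_static) d else 0L),
    heads = lapply(seq_len(nh), function(h)
      list(Wq = ad_param(glorot(d, dk)), Wk = ad_param(glorot(d, dk)))),
    Wv = ad_param(glorot(d, dk)),
    Wo = ad_param(glorot(dk, d)),
    glu_att = make_glu(d, d),
    grn_pos = make_grn(d, dh, d),
    glu_final = make_glu(d, d),
    head = list(W = ad_param(glorot(d, nq)),
                # start the quantile outputs apart, at mild normal quantiles
                b = ad_param(matrix(stats::qnorm(control$quantiles) * 0.5, 1L))))
  if (has_static) {
    m$static_emb <- list(table = ad_param(glorot(spec$n_static_levels, d)))
    m$grn_c_vs <- make_grn(d, dh, d)       # context for variable selection
    m$grn_c_e <- make_grn(d, dh, d)        # context for static enrichment
    m$grn_c_h <- make_grn(d, dh, d)        # LSTM initial hidden state
    m$grn_c_c <- make_grn(d, dh, d)        # LSTM initial cell state
  }
  m$spec <- spec
  m$control <- control
  m
}

# One forward pass over a batch. `batch` carries plain arrays; `train` enables
# dropout (mask RNG from the caller's stream). Returns the loss node plus the
# raw predictions and interpretability weights of the pass.
#' @noRd
forward_forecaster <- function(m, batch, train = FALSE, tape = ad_tape()) {
  spec <- m$spec; ctl <- m$control
  B <- dim(batch$enc_real)[1L]
  N <- dim(batch$enc_real)[2L]
  H <- dim(batch$dec_real)[2L]
  d <- ctl$hidden_size
  drop <- if (train) ctl$dropout else 0

  tm <- function(a) matrix(as.vector(a), ncol = 1L)  # (B x T) -> time-major col

  # per-feature embeddings
  enc_xi <- c(
    lapply(spec$enc_real_names, function(nm)
      m$enc_emb[[nm]]$fwd(tape, ad_const(tm(batch$enc_real[, , nm])))),
    lapply(spec$enc_cat_names, function(nm)
      ad_embed(tape, m$cat_emb[[nm]]$table, as.vector(batch$enc_cat[, , nm]))))
  dec_xi <- c(
    lapply(spec$dec_real_names, function(nm)
      m$dec_emb[[nm]]$fwd(tape, ad_const(tm(batch$dec_real[, , nm])))),
    lapply(spec$dec_cat_names, function(nm)
      ad_embed(tape, m$cat_emb[[nm]]$table, as.vector(batch$dec_cat[, , nm]))))

  # static covariate encoder (absent when no static feature is configured)
  has_static <- spec$n_static_levels > 0L
  if (has_static) {
    es <- ad_embed(tape, m$static_emb$table, batch$static)
    c_vs <- m$grn_c_vs$fwd(tape, es)
    c_e <- m$grn_c_e$fwd(tape, es)
    h0 <- m$grn_c_h$fwd(tape, es)
    c0 <- m$grn_c_c$fwd(tape, es)
  } else {
    c_vs <- c_e <- NULL
    h0 <- ad_const(matrix(0, B, d))
    c0 <- ad_const(matrix(0, B, d))
  }

  vs_enc <- m$vsn_enc$fwd(tape, enc_xi,
                          if (has_static) ad_tile_rows(tape, c_vs, N), drop)
  vs_dec <- m$vsn_dec$fwd(tape, dec_xi,
                          if (has_static) ad_tile_rows(tape, c_vs, H), drop)

  enc <- m$lstm_enc$fwd(tape, vs_enc$selected, B, N, h0, c0)
  dec <- m$lstm_dec$fwd(tape, vs_dec$selected, B, H, enc$h_final, enc$c_final)

  lstm_all <- ad_concat_rows(tape, list(enc$h_big, dec$h_big))
  sel_all <- ad_concat_rows(tape, list(vs_enc$selected, vs_dec$selected))
  if (drop > 0) lstm_all <- ad_dropout(tape, lstm_all, drop)
  phi <- ad_add(tape, m$glu_lstm$fwd(tape, lstm_all), sel_all)

  theta <- m$grn_enrich$fwd(tape, phi,
                            if (has_static) ad_tile_rows(tape, c_e, N + H), drop)
  enc_rows <- seq_len(B * N)
  dec_rows <- B * N + seq_len(B * H)
  theta_enc <- ad_slice_rows(tape, theta, enc_rows)
  theta_dec <- ad_slice_rows(tape, theta, dec_rows)

  # interpretable multi-head attention: shared values, additive aggregation
  V <- ad_matmul(tape, theta_enc, m$Wv)
  ctxs <- lapply(m$heads, function(hd)
    ad_attend(tape,
              ad_matmul(tape, theta_dec, hd$Wq),
              ad_matmul(tape, theta_enc, hd$Wk),
              V, B, H, N))
  att <- ad_matmul(tape,
                   ad_scale(tape, ad_sum_list(tape, ctxs), 1 / length(ctxs)),
                   m$Wo)
  if (drop > 0) att <- ad_dropout(tape, att, drop)
  delta <- ad_add(tape, m$glu_att$fwd(tape, att), theta_dec)
  psi <- m$grn_pos$fwd(tape, delta, dropout = drop)
  phi_dec <- ad_slice_rows(tape, phi, dec_rows)
  final <- ad_add(tape, m$glu_final$fwd(tape, psi), phi_dec)
  yhat <- ad_add_bias(tape, ad_matmul(tape, final, m$head$W), m$head$b)

  # pinball loss summed across quantiles and horizon steps, averaged over
  # the batch (targets in normalized units)
  y_big <- matrix(as.vector(batch$target), ncol = 1L)
  losses <- lapply(seq_along(ctl$quantiles), function(j)
    ad_pinball(tape, ad_slice_cols(tape, yhat, j), y_big, ctl$quantiles[j], B))
  loss <- ad_sum_list(tape, losses)

  attn <- Reduce(`+`, lapply(ctxs, `[[`, "attn")) / length(ctxs)  # B x H x N
  list(tape = tape, loss = loss, yhat = yhat$val,
       attn = attn,
       vsn_enc = vs_enc$weights$val,   # (B*N) x Fe
       vsn_dec = vs_dec$weights$val)   # (B*H) x Fd
}
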