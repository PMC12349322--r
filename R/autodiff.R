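# Minimal tape-based reverse-mode automatic differentiation over matrices.
#
# Every value is a numeric matrix. A "node" is an environment with fields
# $val (matrix), $grad (matrix or NULL), and, for non-leaves, $bw (a function
# accumulating gradients into its parents). Operations append nodes to a tape
# in creation order, which is a topological order, so the backward sweep is a
# single reverse loop. Parameters are leaf environments reused across tapes.
# Gradient correctness is pinned down by finite-difference tests.

#' @noRd
ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 4096L)
  t$n <- 0L
  t
}

#' @noRd
ad_push <- function(tape, node) {
  if (!is.null(tape)) {
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes))
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    tape$nodes[[tape$n]] <- node
  }
  node
}

#' @noRd
ad_node <- function(tape, val, bw = NULL) {
  n <- new.env(parent = emptyenv())
  n$val <- val
  n$grad <- NULL
  n$bw <- bw
  ad_push(tape, n)
}

#' @noRd
ad_const <- function(val) {
  n <- new.env(parent = emptyenv())
  n$val <- val
  n$grad <- NULL
  n$bw <- NULL
  n
}

# A trainable parameter leaf (carries Adam state once training starts).
#' @noRd
ad_param <- function(val) {
  n <- new.env(parent = emptyenv())
  n$val <- val
  n$grad <- NULL
  n$bw <- NULL
  n$leaf <- TRUE
  n
}

#' @noRd
ad_acc <- function(p, g) p$grad <- if (is.null(p$grad)) g else p$grad + g

#' @noRd
ad_backward <- function(tape, loss) {
  loss$grad <- matrix(1, 1L, 1L)
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$bw)) nd$bw(nd)
  }
  invisible(NULL)
}

# ---- primitives -------------------------------------------------------------

#' @noRd
ad_matmul <- function(tape, a, b) {
  out <- ad_node(tape, a$val %*% b$val)
  out$bw <- function(n) {
    ad_acc(a, n$grad %*% t(b$val))
    ad_acc(b, crossprod(a$val, n$grad))
  }
  out
}

#' @noRd
ad_add <- function(tape, a, b) {
  out <- ad_node(tape, a$val + b$val)
  out$bw <- function(n) { ad_acc(a, n$grad); ad_acc(b, n$grad) }
  out
}

#' @noRd
ad_sub <- function(tape, a, b) {
  out <- ad_node(tape, a$val - b$val)
  out$bw <- function(n) { ad_acc(a, n$grad); ad_acc(b, -n$grad) }
  out
}

# bias: 1 x k, broadcast over rows of a (n x k)
#' @noRd
ad_add_bias <- function(tape, a, bias) {
  out <- ad_node(tape, a$val + rep(bias$val, each = nrow(a$val)))
  out$bw <- function(n) {
    ad_acc(a, n$grad)
    ad_acc(bias, matrix(colSums(n$grad), 1L))
  }
  out
}

#' @noRd
ad_mul <- function(tape, a, b) {
  out <- ad_node(tape, a$val * b$val)
  out$bw <- function(n) {
    ad_acc(a, n$grad * b$val)
    ad_acc(b, n$grad * a$val)
  }
  out
}

# column vector (n x 1) scaling every column of m (n x k)
#' @noRd
ad_mul_col <- function(tape, cvec, m) {
  out <- ad_node(tape, m$val * as.vector(cvec$val))
  out$bw <- function(n) {
    ad_acc(cvec, matrix(rowSums(n$grad * m$val), ncol = 1L))
    ad_acc(m, n$grad * as.vector(cvec$val))
  }
  out
}

#' @noRd
ad_scale <- function(tape, a, s) {
  out <- ad_node(tape, a$val * s)
  out$bw <- function(n) ad_acc(a, n$grad * s)
  out
}

#' @noRd
ad_sigmoid <- function(tape, a) {
  out <- ad_node(tape, 1 / (1 + exp(-a$val)))
  out$bw <- function(n) ad_acc(a, n$grad * n$val * (1 - n$val))
  out
}

#' @noRd
ad_tanh <- function(tape, a) {
  out <- ad_node(tape, tanh(a$val))
  out$bw <- function(n) ad_acc(a, n$grad * (1 - n$val^2))
  out
}

#' @noRd
ad_elu <- function(tape, a) {
  pos <- a$val > 0
  v <- a$val * pos + (exp(pmin(a$val, 0)) - 1) * !pos
  out <- ad_node(tape, v)
  out$bw <- function(n) ad_acc(a, n$grad * (pos + (n$val + 1) * !pos))
  out
}

#' @noRd
rowmax <- function(m) m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]

# row-wise softmax
#' @noRd
ad_softmax <- function(tape, a) {
  z <- a$val - rowmax(a$val)
  e <- exp(z)
  out <- ad_node(tape, e / rowSums(e))
  out$bw <- function(n) {
    s <- n$val
    ad_acc(a, s * (n$grad - rowSums(n$grad * s)))
  }
  out
}

#' @noRd
ad_slice_cols <- function(tape, a, idx) {
  out <- ad_node(tape, a$val[, idx, drop = FALSE])
  out$bw <- function(n) {
    g <- matrix(0, nrow(a$val), ncol(a$val))
    g[, idx] <- n$grad
    ad_acc(a, g)
  }
  out
}

#' @noRd
ad_slice_rows <- function(tape, a, idx) {
  out <- ad_node(tape, a$val[idx, , drop = FALSE])
  out$bw <- function(n) {
    g <- matrix(0, nrow(a$val), ncol(a$val))
    g[idx, ] <- n$grad
    ad_acc(a, g)
  }
  out
}

#' @noRd
ad_concat_cols <- function(tape, parts) {
  out <- ad_node(tape, do.call(cbind, lapply(parts, `[[`, "val")))
  widths <- vapply(parts, function(p) ncol(p$val), 1L)
  out$bw <- function(n) {
    at <- 0L
    for (j in seq_along(parts)) {
      ad_acc(parts[[j]], n$grad[, at + seq_len(widths[j]), drop = FALSE])
      at <- at + widths[j]
    }
  }
  out
}

#' @noRd
ad_concat_rows <- function(tape, parts) {
  out <- ad_node(tape, do.call(rbind, lapply(parts, `[[`, "val")))
  heights <- vapply(parts, function(p) nrow(p$val), 1L)
  out$bw <- function(n) {
    at <- 0L
    for (j in seq_along(parts)) {
      ad_acc(parts[[j]], n$grad[at + seq_len(heights[j]), , drop = FALSE])
      at <- at + heights[j]
    }
  }
  out
}

# stack `times` copies of a (n x k) row-blocks: block t = a (time-major tiling)
#' @noRd
ad_tile_rows <- function(tape, a, times) {
  nr <- nrow(a$val)
  out <- ad_node(tape, a$val[rep(seq_len(nr), times), , drop = FALSE])
  out$bw <- function(n) {
    grp <- rep(seq_len(nr), times)
    ad_acc(a, rowsum(n$grad, grp))
  }
  out
}

#' @noRd
ad_sum_list <- function(tape, parts) {
  v <- parts[[1L]]$val
  for (j in seq_along(parts)[-1L]) v <- v + parts[[j]]$val
  out <- ad_node(tape, v)
  out$bw <- function(n) for (p in parts) ad_acc(p, n$grad)
  out
}

# inverted dropout; the mask is drawn from the current RNG stream
#' @noRd
ad_dropout <- function(tape, a, rate) {
  if (rate <= 0) return(a)
  mask <- (matrix(stats::runif(length(a$val)), nrow(a$val)) >= rate) / (1 - rate)
  out <- ad_node(tape, a$val * mask)
  out$bw <- function(n) ad_acc(a, n$grad * mask)
  out
}

# embedding lookup: table (L x d) param, idx integer vector
#' @noRd
ad_embed <- function(tape, table, idx) {
  out <- ad_node(tape, table$val[idx, , drop = FALSE])
  out$bw <- function(n) {
    rs <- rowsum(n$grad, idx)
    g <- matrix(0, nrow(table$val), ncol(table$val))
    g[as.integer(rownames(rs)), ] <- rs
    ad_acc(table, g)
  }
  out
}

# Pinball (quantile) loss node: sum over elements of QL(y, pred, q) / denom.
# y is a plain numeric matrix, pred a node of the same shape.
#' @noRd
ad_pinball <- function(tape, pred, y, q, denom) {
  d <- y - pred$val
  val <- sum(q * pmax(d, 0) + (1 - q) * pmax(-d, 0)) / denom
  out <- ad_node(tape, matrix(val, 1L, 1L))
  out$bw <- function(n) {
    g <- ((pred$val > y) - q) * (pred$val != y) / denom
    ad_acc(pred, g * as.numeric(n$grad))
  }
  out
}

# Fused LSTM over a time-major input x ((B*T) x d_in, row (t-1)*B + b) with
# hand-coded backpropagation through time: one tape node carries the whole
# recurrence, avoiding per-step graph overhead. Returns the node of all hidden
# states plus "hollow" nodes for the final hidden/cell state; their gradients
# (accumulated by later consumers) are read during the fused backward pass.
#' @noRd
ad_lstm <- function(tape, x, B, T, h0, c0, Wx, Wh, b) {
  d <- ncol(Wh$val)  %/% 4L
  ii <- seq_len(d); ff <- d + ii; gg <- 2L * d + ii; oo <- 3L * d + ii
  gates <- vector("list", T)
  cs <- vector("list", T)
  tc <- vector("list", T)
  h_all <- matrix(0, B * T, d)
  h <- h0$val; cc <- c0$val
  rows <- function(t) (t - 1L) * B + seq_len(B)
  for (t in seq_len(T)) {
    z <- x$val[rows(t), , drop = FALSE] %*% Wx$val + h %*% Wh$val
    z <- z + rep(b$val, each = B)
    i <- 1 / (1 + exp(-z[, ii, drop = FALSE]))
    f <- 1 / (1 + exp(-z[, ff, drop = FALSE]))
    g <- tanh(z[, gg, drop = FALSE])
    o <- 1 / (1 + exp(-z[, oo, drop = FALSE]))
    cprev <- cc
    cc <- f * cprev + i * g
    tch <- tanh(cc)
    h <- o * tch
    gates[[t]] <- list(i = i, f = f, g = g, o = o, cprev = cprev)
    cs[[t]] <- cc
    tc[[t]] <- tch
    h_all[rows(t), ] <- h
  }
  out <- ad_node(tape, h_all)
  h_fin <- ad_node(tape, h)   # hollow: gradient filled by later consumers
  c_fin <- ad_node(tape, cc)
  out$bw <- function(n) {
    gWx <- Wx$val * 0; gWh <- Wh$val * 0; gb <- b$val * 0
    gX <- x$val * 0
    dh <- if (is.null(h_fin$grad)) matrix(0, B, d) else h_fin$grad
    dc <- if (is.null(c_fin$grad)) matrix(0, B, d) else c_fin$grad
    tWx <- t(Wx$val); tWh <- t(Wh$val)
    for (t in rev(seq_len(T))) {
      gt <- gates[[t]]
      dh <- dh + n$grad[rows(t), , drop = FALSE]
      do <- dh * tc[[t]]
      dc <- dc + dh * gt$o * (1 - tc[[t]]^2)
      di <- dc * gt$g
      dg <- dc * gt$i
      df <- dc * gt$cprev
      dZ <- cbind(di * gt$i * (1 - gt$i),
                  df * gt$f * (1 - gt$f),
                  dg * (1 - gt$g^2),
                  do * gt$o * (1 - gt$o))
      hprev <- if (t == 1L) h0$val else h_all[rows(t - 1L), , drop = FALSE]
      gWx <- gWx + crossprod(x$val[rows(t), , drop = FALSE], dZ)
      gWh <- gWh + crossprod(hprev, dZ)
      gb <- gb + colSums(dZ)
      gX[rows(t), ] <- dZ %*% tWx
      dh <- dZ %*% tWh
      dc <- dc * gt$f
    }
    ad_acc(Wx, gWx); ad_acc(Wh, gWh); ad_acc(b, matrix(gb, 1L))
    ad_acc(x, gX); ad_acc(h0, dh); ad_acc(c0, dc)
  }
  list(h_big = out, h_final = h_fin, c_final = c_fin)
}

# Scaled-dot-product attention with a batched (per-instance) forward/backward.
# Q: (B*Tq) x dk, K: (B*Tk) x dk, V: (B*Tk) x dv, all time-major (row
# (t-1)*B + b). Returns the context node ((B*Tq) x dv); the attention weights
# (B x Tq x Tk array) are stored on the node as $attn for interpretability.
#' @noRd
ad_attend <- function(tape, Q, K, V, B, Tq, Tk) {
  dk <- ncol(Q$val)
  sc <- 1 / sqrt(dk)
  A <- array(0, c(B, Tq, Tk))
  ctx <- matrix(0, B * Tq, ncol(V$val))
  rowsQ <- lapply(seq_len(B), function(b) seq(b, by = B, length.out = Tq))
  rowsK <- lapply(seq_len(B), function(b) seq(b, by = B, length.out = Tk))
  for (b in seq_len(B)) {
    S <- (Q$val[rowsQ[[b]], , drop = FALSE] %*%
            t(K$val[rowsK[[b]], , drop = FALSE])) * sc
    S <- exp(S - apply(S, 1L, max))
    Ab <- S / rowSums(S)
    A[b, , ] <- Ab
    ctx[rowsQ[[b]], ] <- Ab %*% V$val[rowsK[[b]], , drop = FALSE]
  }
  out <- ad_node(tape, ctx)
  out$attn <- A
  out$bw <- function(n) {
    gQ <- matrix(0, nrow(Q$val), ncol(Q$val))
    gK <- matrix(0, nrow(K$val), ncol(K$val))
    gV <- matrix(0, nrow(V$val), ncol(V$val))
    for (b in seq_len(B)) {
      qi <- rowsQ[[b]]; ki <- rowsK[[b]]
      Ab <- matrix(A[b, , ], Tq, Tk)
      gC <- n$grad[qi, , drop = FALSE]
      gA <- gC %*% t(V$val[ki, , drop = FALSE])
      gV[ki, ] <- gV[ki, ] + crossprod(Ab, gC)
      gS <- Ab * (gA - rowSums(gA * Ab)) * sc
      gQ[qi, ] <- gQ[qi, ] + gS %*% K$val[ki, , drop = FALSE]
      gK[ki, ] <- gK[ki, ] + crossprod(gS, Q$val[qi, , drop = FALSE])
    }
    ad_acc(Q, gQ); ad_acc(K, gK); ad_acc(V, gV)
  }
  out
}

# ---- parameter utilities ----------------------------------------------------

# Glorot-uniform initial weight matrix.
#' @noRd
glorot <- function(n_in, n_out) {
  r <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -r, r), n_in, n_out)
}

#' @noRd
param_zero_grads <- function(params) for (p in params) p$grad <- NULL

#' @noRd
param_values <- function(params) lapply(params, function(p) p$val)

#' @noRd
param_restore <- function(params, values)
  for (nm in names(values)) params[[nm]]$val <- values[[nm]]

#' @noRd
param_count <- function(params)
  sum(vapply(params, function(p) length(p$val), 1))

# Global-norm gradient clipping followed by one Adam step.
#' @noRd
adam_step <- function(params, lr, clip, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, t_step) {
  gn2 <- 0
  for (p in params) if (!is.null(p$grad)) gn2 <- gn2 + sum(p$grad^2)
  scale <- if (clip > 0 && sqrt(gn2) > clip) clip / sqrt(gn2) else 1
  for (p in params) {
    if (is.null(p$grad)) next
    g <- p$grad * scale
    if (is.null(p$m)) { p$m <- g * 0; p$v <- g * 0 }
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$v <- beta2 * p$v + (1 - beta2) * g^2
    mhat <- p$m / (1 - beta1^t_step)
    vhat <- p$v / (1 - beta2^t_step)
    p$val <- p$val - lr * mhat / (sqrt(vhat) + eps)
  }
  sqrt(gn2)
}
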