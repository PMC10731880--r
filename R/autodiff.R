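# Reverse-mode automatic differentiation on a flat tape of matrix ops.
# Every op pushes a node (value, parent ids, backward closure) and returns the
# node id; ad_backward() sweeps the tape in reverse accumulating gradients.
# This is deliberately minimal: just the ops the GPNN forward pass needs.

#' Create an empty autodiff tape
#'
#' The tape records every matrix operation of a forward pass so that
#' [ad_backward()] can accumulate gradients for the training loop. Users of
#' the fitted model never touch tapes; they exist for the optimizer and for
#' gradient tests.
#'
#' @return an environment of class `ad_tape`.
#' @export
ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$values <- vector("list", 256)
  tp$parents <- vector("list", 256)
  tp$backs <- vector("list", 256)
  tp$n <- 0L
  class(tp) <- "ad_tape"
  tp
}

.nd <- function(tp, value, parents = integer(0), back = NULL) {
  n <- tp$n + 1L
  if (n > length(tp$values)) {
    grow <- function(x) { length(x) <- 2L * length(x); x }
    tp$values <- grow(tp$values)
    tp$parents <- grow(tp$parents)
    tp$backs <- grow(tp$backs)
  }
  tp$values[[n]] <- value
  tp$parents[[n]] <- parents
  tp$backs[[n]] <- back
  tp$n <- n
  n
}

#' Tape node constructors and accessors
#'
#' `ad_const` records a value with no gradient; `ad_input` records a leaf
#' whose gradient is wanted (parameters and trainable inputs); `ad_val`
#' reads a node's value; `ad_grad` reads its accumulated gradient after
#' [ad_backward()].
#'
#' @param tp an [ad_tape()].
#' @param value numeric matrix (vectors are treated as 1-row matrices).
#' @param id node id returned by an op.
#' @export
ad_const <- function(tp, value) {
  if (!is.matrix(value)) value <- matrix(value, nrow = 1)
  .nd(tp, value)
}

#' @rdname ad_const
#' @export
ad_input <- function(tp, value) {
  if (!is.matrix(value)) value <- matrix(value, nrow = 1)
  .nd(tp, value, integer(0), back = function(g, v) list())
}

#' @rdname ad_const
#' @export
ad_val <- function(tp, id) {
  force(id)
  tp$values[[id]]
}

#' @rdname ad_const
#' @export
ad_grad <- function(tp, id) {
  force(id)
  g <- tp$grads[[id]]
  if (is.null(g)) array(0, dim(tp$values[[id]])) else g
}

#' Differentiable matrix operations
#'
#' The op set covers the GPNN forward pass: matrix product, broadcast add
#' (bias rows), elementwise product/difference, tanh/relu/sigmoid, column
#' binding and slicing, row gather with scatter-add backward, row softmax,
#' elementwise max over a list (position-wise max pooling), zero-padded
#' row-major flatten, stop-gradient, and fused softmax cross-entropy.
#'
#' @param tp an [ad_tape()].
#' @param a,b node ids.
#' @name ad_ops
#' @export
ad_matmul <- function(tp, a, b) {
  force(a); force(b)
  va <- tp$values[[a]]; vb <- tp$values[[b]]
  .nd(tp, va %*% vb, c(a, b), function(g, v)
    list(g %*% t(vb), t(va) %*% g))
}

#' @rdname ad_ops
#' @export
ad_add <- function(tp, a, b) {
  force(a); force(b)
  va <- tp$values[[a]]; vb <- tp$values[[b]]
  if (nrow(vb) == 1L && nrow(va) > 1L) {
    .nd(tp, sweep(va, 2, vb[1, ], "+"), c(a, b), function(g, v)
      list(g, matrix(colSums(g), 1)))
  } else {
    .nd(tp, va + vb, c(a, b), function(g, v) list(g, g))
  }
}

#' @rdname ad_ops
#' @export
ad_sub <- function(tp, a, b) {
  force(a); force(b)
  .nd(tp, tp$values[[a]] - tp$values[[b]], c(a, b),
      function(g, v) list(g, -g))
}

#' @rdname ad_ops
#' @export
ad_mul <- function(tp, a, b) {
  force(a); force(b)
  va <- tp$values[[a]]; vb <- tp$values[[b]]
  if (ncol(vb) == 1L && ncol(va) > 1L) {
    # column-vector broadcast across columns of a
    .nd(tp, va * as.vector(vb), c(a, b), function(g, v)
      list(g * as.vector(vb), matrix(rowSums(g * va), ncol = 1)))
  } else {
    .nd(tp, va * vb, c(a, b), function(g, v) list(g * vb, g * va))
  }
}

#' @rdname ad_ops
#' @param s numeric scalar.
#' @export
ad_scale <- function(tp, a, s) {
  force(a)
  .nd(tp, tp$values[[a]] * s, a, function(g, v) list(g * s))
}

#' @rdname ad_ops
#' @export
ad_tanh <- function(tp, a) {
  force(a)
  y <- tanh(tp$values[[a]])
  .nd(tp, y, a, function(g, v) list(g * (1 - y * y)))
}

#' @rdname ad_ops
#' @export
ad_relu <- function(tp, a) {
  force(a)
  va <- tp$values[[a]]
  y <- pmax(va, 0)
  .nd(tp, y, a, function(g, v) list(g * (va > 0)))
}

#' @rdname ad_ops
#' @export
ad_sigmoid <- function(tp, a) {
  force(a)
  y <- 1 / (1 + exp(-tp$values[[a]]))
  .nd(tp, y, a, function(g, v) list(g * y * (1 - y)))
}

#' @rdname ad_ops
#' @param ids vector of node ids holding same-shaped matrices.
#' @export
ad_cbind <- function(tp, ids) {
  ids <- as.integer(ids)
  vals <- tp$values[ids]
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, ends[-length(ends)] + 1L)
  .nd(tp, do.call(cbind, vals), ids, function(g, v)
    lapply(seq_along(ids), function(i) g[, starts[i]:ends[i], drop = FALSE]))
}

#' @rdname ad_ops
#' @param idx integer index vector.
#' @export
ad_cols <- function(tp, a, idx) {
  force(a)
  va <- tp$values[[a]]
  .nd(tp, va[, idx, drop = FALSE], a, function(g, v) {
    out <- array(0, dim(va))
    out[, idx] <- out[, idx] + g
    list(out)
  })
}

#' @rdname ad_ops
#' @export
ad_rows <- function(tp, a, idx) {
  force(a)
  va <- tp$values[[a]]
  .nd(tp, va[idx, , drop = FALSE], a, function(g, v) {
    out <- matrix(0, nrow(va), ncol(va))
    acc <- rowsum(g, group = idx)
    out[as.integer(rownames(acc)), ] <- acc
    list(out)
  })
}

#' @rdname ad_ops
#' @export
ad_softmax_rows <- function(tp, a) {
  force(a)
  va <- tp$values[[a]]
  z <- exp(va - apply(va, 1, max))
  y <- z / rowSums(z)
  .nd(tp, y, a, function(g, v) {
    dot <- rowSums(g * y)
    list(y * (g - dot))
  })
}

#' @rdname ad_ops
#' @export
ad_pmax_list <- function(tp, ids) {
  ids <- as.integer(ids)
  vals <- tp$values[ids]
  y <- Reduce(pmax, vals)
  which_max <- array(1L, dim(y))
  cur <- vals[[1]]
  for (i in seq_along(vals)[-1]) {
    upd <- vals[[i]] > cur
    which_max[upd] <- i
    cur <- pmax(cur, vals[[i]])
  }
  .nd(tp, y, ids, function(g, v)
    lapply(seq_along(ids), function(i) g * (which_max == i)))
}

#' @rdname ad_ops
#' @export
ad_mean_list <- function(tp, ids) {
  ids <- as.integer(ids)
  k <- length(ids)
  y <- Reduce(`+`, tp$values[ids]) / k
  .nd(tp, y, ids, function(g, v)
    rep(list(g / k), k))
}

#' @rdname ad_ops
#' @param pad_rows total row count after zero padding.
#' @export
ad_flatten_pad <- function(tp, a, pad_rows) {
  force(a)
  va <- tp$values[[a]]
  m <- nrow(va); d <- ncol(va)
  if (m > pad_rows) stop("more rows (", m, ") than pad_rows (", pad_rows, ")")
  padded <- rbind(va, matrix(0, pad_rows - m, d))
  .nd(tp, matrix(as.vector(t(padded)), nrow = 1), a, function(g, v) {
    gm <- matrix(as.vector(g), nrow = pad_rows, byrow = TRUE)
    list(gm[seq_len(m), , drop = FALSE])
  })
}

#' @rdname ad_ops
#' @export
ad_rbind <- function(tp, ids) {
  ids <- as.integer(ids)
  vals <- tp$values[ids]
  heights <- vapply(vals, nrow, integer(1))
  ends <- cumsum(heights)
  starts <- c(1L, ends[-length(ends)] + 1L)
  .nd(tp, do.call(rbind, vals), ids, function(g, v)
    lapply(seq_along(ids), function(i) g[starts[i]:ends[i], , drop = FALSE]))
}

#' @rdname ad_ops
#' @export
ad_detach <- function(tp, a) {
  force(a)
  .nd(tp, tp$values[[a]])
}

#' @rdname ad_ops
#' @param target 1-based index of the gold class.
#' @export
ad_ce_loss <- function(tp, a, target) {
  force(a)
  logits <- tp$values[[a]]
  z <- exp(logits - max(logits))
  p <- z / sum(z)
  loss <- -log(max(p[target], 1e-12))
  .nd(tp, matrix(loss, 1, 1), a, function(g, v) {
    d <- p
    d[target] <- d[target] - 1
    list(g[1, 1] * d)
  })
}

#' Fused recurrent-sequence operations
#'
#' These run a whole recurrence as one tape node with a hand-derived
#' backward-through-time, which keeps tapes short. `ad_rnn_tanh` is a
#' unidirectional `h_t = tanh(W [h_{t-1}, x_t] + b)` recurrence over the
#' rows of `x` (optionally reversed), emitting all hidden states.
#' `ad_lstm_seq` and `ad_tanh_seq` run an LSTM (respectively simplified
#' tanh) recurrence over a stacked input of `T` blocks of `m` rows
#' (row `(t-1)*m + i` is step t of batch element i), with a 0/1 `mask`
#' (m x T); masked steps copy the previous state. `ad_lstm_step` is a
#' single LSTM step returning the concatenated `[h, c]` state.
#' `ad_attn_mix` computes the attention-weighted mixture
#' `sum_q attn[, q] * x_q` over the same stacked layout.
#'
#' @param tp an [ad_tape()].
#' @param x,xstack,h,c,attn node ids.
#' @param W,b node ids of the recurrence weights; for the LSTM ops, `W` is
#'   `(h + d_in) x 4h` with gate blocks ordered input, forget, cell,
#'   output.
#' @param reverse run the recurrence from the last row to the first.
#' @param mask numeric m x T matrix (not a node id).
#' @name ad_seq_ops
#' @export
ad_rnn_tanh <- function(tp, x, W, b, reverse = FALSE) {
  force(x); force(W); force(b)
  X <- tp$values[[x]]; Wv <- tp$values[[W]]; bv <- tp$values[[b]]
  m <- nrow(X); din <- ncol(X); h <- ncol(Wv)
  ord <- if (reverse) rev(seq_len(m)) else seq_len(m)
  H <- matrix(0, m, h)
  prev <- matrix(0, 1, h)
  for (t in ord) {
    prev <- tanh(cbind(prev, X[t, , drop = FALSE]) %*% Wv + bv)
    H[t, ] <- prev
  }
  .nd(tp, H, c(x, W, b), function(g, v) {
    dX <- matrix(0, m, din); dW <- matrix(0, nrow(Wv), ncol(Wv))
    db <- matrix(0, 1, h)
    dh <- matrix(0, 1, h)
    for (t in rev(ord)) {
      dht <- g[t, , drop = FALSE] + dh
      dz <- dht * (1 - H[t, ]^2)
      hp <- if (t == ord[1]) matrix(0, 1, h) else {
        tprev <- ord[match(t, ord) - 1]
        H[tprev, , drop = FALSE]
      }
      inp <- cbind(hp, X[t, , drop = FALSE])
      dW <- dW + t(inp) %*% dz
      db <- db + dz
      dinp <- dz %*% t(Wv)
      dh <- dinp[, seq_len(h), drop = FALSE]
      dX[t, ] <- dinp[1, h + seq_len(din)]
    }
    list(dX, dW, db)
  })
}

.sigm <- function(x) 1 / (1 + exp(-x))

#' @rdname ad_seq_ops
#' @export
ad_lstm_seq <- function(tp, xstack, W, b, mask) {
  force(xstack); force(W); force(b)
  X <- tp$values[[xstack]]; Wv <- tp$values[[W]]; bv <- tp$values[[b]]
  m <- nrow(mask); T <- ncol(mask)
  h <- ncol(Wv) %/% 4L; din <- ncol(X)
  Hs <- vector("list", T); Cs <- vector("list", T)
  gates <- vector("list", T)
  hprev <- matrix(0, m, h); cprev <- matrix(0, m, h)
  for (t in seq_len(T)) {
    xt <- X[(t - 1L) * m + seq_len(m), , drop = FALSE]
    z <- sweep(cbind(hprev, xt) %*% Wv, 2, bv[1, ], "+")
    i <- .sigm(z[, seq_len(h), drop = FALSE])
    f <- .sigm(z[, h + seq_len(h), drop = FALSE])
    gg <- tanh(z[, 2 * h + seq_len(h), drop = FALSE])
    o <- .sigm(z[, 3 * h + seq_len(h), drop = FALSE])
    cn <- f * cprev + i * gg
    hn <- o * tanh(cn)
    mu <- mask[, t]
    hcur <- mu * hn + (1 - mu) * hprev
    ccur <- mu * cn + (1 - mu) * cprev
    gates[[t]] <- list(i = i, f = f, g = gg, o = o, cn = cn,
                       hp = hprev, cp = cprev, xt = xt)
    Hs[[t]] <- hcur; Cs[[t]] <- ccur
    hprev <- hcur; cprev <- ccur
  }
  .nd(tp, do.call(rbind, Hs), c(xstack, W, b), function(g, v) {
    dX <- matrix(0, nrow(X), din)
    dW <- matrix(0, nrow(Wv), ncol(Wv)); db <- matrix(0, 1, 4 * h)
    dh <- matrix(0, m, h); dc <- matrix(0, m, h)
    for (t in seq(T, 1L)) {
      gt <- gates[[t]]
      mu <- mask[, t]
      dht <- g[(t - 1L) * m + seq_len(m), , drop = FALSE] + dh
      dhn <- mu * dht
      dcn_mix <- mu * dc
      dhp <- (1 - mu) * dht
      dcp <- (1 - mu) * dc
      tc <- tanh(gt$cn)
      do_ <- dhn * tc
      dcn <- dcn_mix + dhn * gt$o * (1 - tc^2)
      df <- dcn * gt$cp
      di <- dcn * gt$g
      dg <- dcn * gt$i
      dcp <- dcp + dcn * gt$f
      dz <- cbind(di * gt$i * (1 - gt$i), df * gt$f * (1 - gt$f),
                  dg * (1 - gt$g^2), do_ * gt$o * (1 - gt$o))
      dW <- dW + t(cbind(gt$hp, gt$xt)) %*% dz
      db <- db + colSums(dz)
      dinp <- dz %*% t(Wv)
      dh <- dhp + dinp[, seq_len(h), drop = FALSE]
      dc <- dcp
      dX[(t - 1L) * m + seq_len(m), ] <- dinp[, h + seq_len(din)]
    }
    list(dX, dW, db)
  })
}

#' @rdname ad_seq_ops
#' @export
ad_tanh_seq <- function(tp, xstack, W, b, mask) {
  force(xstack); force(W); force(b)
  X <- tp$values[[xstack]]; Wv <- tp$values[[W]]; bv <- tp$values[[b]]
  m <- nrow(mask); T <- ncol(mask)
  h <- ncol(Wv); din <- ncol(X)
  Hs <- vector("list", T); pres <- vector("list", T)
  hprev <- matrix(0, m, h)
  for (t in seq_len(T)) {
    xt <- X[(t - 1L) * m + seq_len(m), , drop = FALSE]
    hn <- tanh(sweep(cbind(hprev, xt) %*% Wv, 2, bv[1, ], "+"))
    mu <- mask[, t]
    pres[[t]] <- list(hn = hn, hp = hprev, xt = xt)
    hprev <- mu * hn + (1 - mu) * hprev
    Hs[[t]] <- hprev
  }
  .nd(tp, do.call(rbind, Hs), c(xstack, W, b), function(g, v) {
    dX <- matrix(0, nrow(X), din)
    dW <- matrix(0, nrow(Wv), h); db <- matrix(0, 1, h)
    dh <- matrix(0, m, h)
    for (t in seq(T, 1L)) {
      pt <- pres[[t]]
      mu <- mask[, t]
      dht <- g[(t - 1L) * m + seq_len(m), , drop = FALSE] + dh
      dhn <- mu * dht
      dhp <- (1 - mu) * dht
      dz <- dhn * (1 - pt$hn^2)
      dW <- dW + t(cbind(pt$hp, pt$xt)) %*% dz
      db <- db + colSums(dz)
      dinp <- dz %*% t(Wv)
      dh <- dhp + dinp[, seq_len(h), drop = FALSE]
      dX[(t - 1L) * m + seq_len(m), ] <- dinp[, h + seq_len(din)]
    }
    list(dX, dW, db)
  })
}

#' @rdname ad_seq_ops
#' @export
ad_lstm_step <- function(tp, h, c, x, W, b) {
  force(h); force(c); force(x); force(W); force(b)
  hv <- tp$values[[h]]; cv <- tp$values[[c]]; xv <- tp$values[[x]]
  Wv <- tp$values[[W]]; bv <- tp$values[[b]]
  hh <- ncol(hv); din <- ncol(xv)
  z <- sweep(cbind(hv, xv) %*% Wv, 2, bv[1, ], "+")
  i <- .sigm(z[, seq_len(hh), drop = FALSE])
  f <- .sigm(z[, hh + seq_len(hh), drop = FALSE])
  gg <- tanh(z[, 2 * hh + seq_len(hh), drop = FALSE])
  o <- .sigm(z[, 3 * hh + seq_len(hh), drop = FALSE])
  cn <- f * cv + i * gg
  hn <- o * tanh(cn)
  .nd(tp, cbind(hn, cn), c(h, c, x, W, b), function(g, v) {
    gh <- g[, seq_len(hh), drop = FALSE]
    gc <- g[, hh + seq_len(hh), drop = FALSE]
    tc <- tanh(cn)
    do_ <- gh * tc
    dcn <- gc + gh * o * (1 - tc^2)
    df <- dcn * cv; di <- dcn * gg; dg <- dcn * i
    dz <- cbind(di * i * (1 - i), df * f * (1 - f),
                dg * (1 - gg^2), do_ * o * (1 - o))
    dinp <- dz %*% t(Wv)
    list(dinp[, seq_len(hh), drop = FALSE], dcn * f,
         dinp[, hh + seq_len(din), drop = FALSE],
         t(cbind(hv, xv)) %*% dz, matrix(colSums(dz), 1))
  })
}

#' @rdname ad_seq_ops
#' @export
ad_attn_mix <- function(tp, attn, xstack) {
  force(attn); force(xstack)
  av <- tp$values[[attn]]; Xv <- tp$values[[xstack]]
  m <- nrow(av); L <- ncol(av); d <- ncol(Xv)
  out <- matrix(0, m, d)
  for (q in seq_len(L)) {
    out <- out + av[, q] * Xv[(q - 1L) * m + seq_len(m), , drop = FALSE]
  }
  .nd(tp, out, c(attn, xstack), function(g, v) {
    da <- matrix(0, m, L)
    dX <- matrix(0, nrow(Xv), d)
    for (q in seq_len(L)) {
      rows <- (q - 1L) * m + seq_len(m)
      da[, q] <- rowSums(g * Xv[rows, , drop = FALSE])
      dX[rows, ] <- av[, q] * g
    }
    list(da, dX)
  })
}

#' Reverse sweep: accumulate gradients from a scalar output node
#'
#' @param tp an [ad_tape()].
#' @param loss_id node id of a 1x1 output.
#' @export
ad_backward <- function(tp, loss_id) {
  tp$grads <- vector("list", tp$n)
  tp$grads[[loss_id]] <- matrix(1, 1, 1)
  for (i in seq(loss_id, 1L)) {
    g <- tp$grads[[i]]
    if (is.null(g)) next
    back <- tp$backs[[i]]
    if (is.null(back)) next
    pids <- tp$parents[[i]]
    if (length(pids) == 0) next
    pg <- back(g, tp$values[[i]])
    for (k in seq_along(pids)) {
      p <- pids[k]
      tp$grads[[p]] <- if (is.null(tp$grads[[p]])) pg[[k]] else
        tp$grads[[p]] + pg[[k]]
    }
  }
  invisible(tp)
}
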