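#' Graph pointer network configuration
#'
#' @param d1 dimension of the input node attributes (encoder output).
#' @param d2 dimension of the GCN-encoded node features; defaults to `d1` so
#'   the later three-stream fusion concatenates to `3 * d1`.
#' @param L input neighbors: length of each sampled neighbor sequence.
#' @param M output neighbors: how many of the L are screened out by the
#'   pointer decoder.
#' @param layers number of stacked GPNN layers (1 or 2).
#' @param conv_kernel width of the 1D convolution over the M selected
#'   neighbors (same-padded).
#' @param activation GCN activation; `"relu"` by default.
#' @param cell recurrence used by the pointer encoder/decoder: `"lstm"`
#'   (default) or the printed single-gate `"tanh"` simplification
#'   (strict-equations mode, handy for hand-checked tests).
#' @param aggregation reduction over the convolved M positions: `"max"`
#'   (default) or `"mean"`.
#' @export
gpnn_config <- function(d1, d2 = d1, L = 32, M = 4, layers = 1,
                        conv_kernel = 3,
                        activation = c("relu", "identity", "tanh"),
                        cell = c("lstm", "tanh"),
                        aggregation = c("max", "mean")) {
  stopifnot(M >= 1, M <= L, layers %in% c(1, 2), conv_kernel >= 1)
  structure(list(d1 = d1, d2 = d2, L = as.integer(L), M = as.integer(M),
                 layers = as.integer(layers),
                 conv_kernel = as.integer(conv_kernel),
                 activation = match.arg(activation),
                 cell = match.arg(cell),
                 aggregation = match.arg(aggregation)),
            class = "gpnn_config")
}

.glorot <- function(nr, nc) {
  r <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -r, r), nr, nc)
}

.cell_cols <- function(cfg) if (cfg$cell == "lstm") 4L * cfg$d2 else cfg$d2

#' Initialize GPNN parameters
#'
#' Returns a named list of weight matrices (one set per layer): GCN weight
#' and bias, encoder and decoder recurrence weights, pointer-attention
#' weights `v`, `W1`, `W2`, the trainable start sentinel, and the 1D
#' convolution kernel.
#'
#' @param cfg a [gpnn_config()].
#' @param seed RNG seed.
#' @param prefix name prefix for the parameter keys.
#' @export
gpnn_params <- function(cfg, seed = 1L, prefix = "gpnn") {
  .with_seed(seed, {
    P <- list()
    for (l in seq_len(cfg$layers)) {
      din <- if (l == 1) cfg$d1 else cfg$d2
      nm <- function(x) sprintf("%s%d.%s", prefix, l, x)
      cc <- .cell_cols(cfg)
      P[[nm("W_gcn")]] <- .glorot(din, cfg$d2)
      P[[nm("b_gcn")]] <- matrix(0, 1, cfg$d2)
      P[[nm("W_enc")]] <- .glorot(2 * cfg$d2, cc)
      P[[nm("b_enc")]] <- matrix(0, 1, cc)
      P[[nm("W_dec")]] <- .glorot(2 * cfg$d2, cc)
      P[[nm("b_dec")]] <- matrix(0, 1, cc)
      P[[nm("W1")]] <- .glorot(cfg$d2, cfg$d2)
      P[[nm("W2")]] <- .glorot(cfg$d2, cfg$d2)
      P[[nm("v")]] <- .glorot(cfg$d2, 1)
      P[[nm("x_start")]] <- .glorot(1, cfg$d2)
      for (j in seq_len(cfg$conv_kernel)) {
        P[[nm(sprintf("W_conv%d", j))]] <- .glorot(cfg$d2, cfg$d2)
      }
      P[[nm("b_conv")]] <- matrix(0, 1, cfg$d2)
    }
    P
  })
}

# symmetric normalization D^-1/2 A D^-1/2 with no self-loops;
# zero degrees are clamped to 1 so isolated nodes contribute sigma(0)
.gcn_norm <- function(A) {
  d <- pmax(rowSums(A), 1)
  s <- 1 / sqrt(d)
  A * outer(s, s)
}

.act_t <- function(tp, id, activation) {
  switch(activation,
         relu = ad_relu(tp, id),
         tanh = ad_tanh(tp, id),
         identity = id)
}

# ---- tape-level building blocks (batched over the m graph nodes) ----------

.gcn_t <- function(tp, Xid, A, Wid, bid, activation) {
  N <- ad_const(tp, .gcn_norm(A))
  h <- ad_matmul(tp, N, Xid)
  h <- ad_matmul(tp, h, Wid)
  h <- ad_add(tp, h, bid)
  .act_t(tp, h, activation)
}

# one decoder recurrence step; state is list(h) or list(h, c)
.cell_t <- function(tp, state, xid, Wid, bid, cfg) {
  if (cfg$cell == "tanh") {
    z <- ad_add(tp, ad_matmul(tp, ad_cbind(tp, c(state$h, xid)), Wid), bid)
    list(h = ad_tanh(tp, z))
  } else {
    d <- cfg$d2
    st <- ad_lstm_step(tp, state$h, state$c, xid, Wid, bid)
    list(h = ad_cols(tp, st, seq_len(d)), c = ad_cols(tp, st, d + seq_len(d)))
  }
}

.zero_state <- function(tp, m, cfg) {
  z <- ad_const(tp, matrix(0, m, cfg$d2))
  if (cfg$cell == "lstm") list(h = z, c = z) else list(h = z)
}

# reinterpret an (L*m) x 1 score column as an m x L matrix (column-major)
.reshape_ml <- function(tp, a, m, L) {
  force(a)
  va <- tp$values[[a]]
  .nd(tp, matrix(as.vector(va), m, L), a, function(g, v)
    list(matrix(as.vector(g), ncol = 1)))
}

# Xstack: (L*m) x d2 node (block q holds sequence position q for every
# center, zeroed where padded); mask: m x L 0/1 numeric
.encode_t <- function(tp, Xstack, mask, cfg, P, nm) {
  if (cfg$cell == "lstm") {
    ad_lstm_seq(tp, Xstack, P[[nm("W_enc")]], P[[nm("b_enc")]], mask)
  } else {
    ad_tanh_seq(tp, Xstack, P[[nm("W_enc")]], P[[nm("b_enc")]], mask)
  }
}

.decode_t <- function(tp, Estack, Xstack, Xhat_id, seq_mat, mask, cfg, P, nm) {
  m <- nrow(mask)
  EW1 <- ad_matmul(tp, Estack, P[[nm("W1")]])
  tile_idx <- rep(seq_len(m), cfg$L)
  ones <- ad_const(tp, matrix(1, m, 1))
  x_in <- ad_matmul(tp, ones, P[[nm("x_start")]])  # broadcast start sentinel
  state <- .zero_state(tp, m, cfg)
  blocked <- 1 - mask                      # m x L; 1 = cannot be selected
  choices <- matrix(0L, m, cfg$M)
  attn_list <- vector("list", cfg$M)
  sel <- vector("list", cfg$M)
  for (p in seq_len(cfg$M)) {
    state <- .cell_t(tp, state, x_in, P[[nm("W_dec")]], P[[nm("b_dec")]], cfg)
    dW2 <- ad_matmul(tp, state$h, P[[nm("W2")]])
    scr <- ad_matmul(tp, ad_tanh(tp, ad_add(
      tp, EW1, ad_rows(tp, dW2, tile_idx))), P[[nm("v")]])
    S <- ad_add(tp, .reshape_ml(tp, scr, m, cfg$L),
                ad_const(tp, -1e9 * blocked))
    attn <- ad_softmax_rows(tp, S)
    av <- ad_val(tp, attn)
    # hard argmax among unblocked positions; rows with none left stay padded
    pick <- integer(m); valid <- numeric(m)
    for (i in seq_len(m)) {
      open <- which(blocked[i, ] == 0)
      if (length(open) > 0) {
        pick[i] <- open[which.max(av[i, open])]
        valid[i] <- 1
      }
    }
    safe_pos <- ifelse(pick == 0L, 1L, pick)
    safe_node <- seq_mat[cbind(seq_len(m), safe_pos)]
    safe_node[safe_node == 0L] <- 1L
    hard <- ad_mul(tp, ad_rows(tp, Xhat_id, safe_node),
                   ad_const(tp, matrix(valid, ncol = 1)))
    soft <- ad_attn_mix(tp, attn, Xstack)
    sel[[p]] <- ad_add(tp, hard, ad_sub(tp, soft, ad_detach(tp, soft)))
    choices[, p] <- pick
    attn_list[[p]] <- av
    blocked[cbind(which(pick > 0L), pick[pick > 0L])] <- 1
    x_in <- sel[[p]]
  }
  list(sel = sel, choices = choices, attention = attn_list)
}

.aggregate_t <- function(tp, sel, cfg, P, nm) {
  w <- cfg$conv_kernel
  off <- (w - 1L) %/% 2L
  conv <- vector("list", cfg$M)
  for (t in seq_len(cfg$M)) {
    acc <- NULL
    for (j in seq_len(w)) {
      src <- t + j - 1L - off
      if (src < 1L || src > cfg$M) next
      term <- ad_matmul(tp, sel[[src]], P[[nm(sprintf("W_conv%d", j))]])
      acc <- if (is.null(acc)) term else ad_add(tp, acc, term)
    }
    conv[[t]] <- ad_add(tp, acc, P[[nm("b_conv")]])
  }
  if (cfg$aggregation == "max") ad_pmax_list(tp, unlist(conv))
  else ad_mean_list(tp, unlist(conv))
}

# full layer stack on the tape. seqs: list of neighbor_seq (one per node).
# Returns ids of Xhat and Z plus the selection bookkeeping of the last layer.
.gpnn_t <- function(tp, Xid, A, seqs, cfg, pids, prefix = "gpnn") {
  m <- nrow(A)
  seq_mat <- matrix(0L, m, cfg$L)
  mask <- matrix(0, m, cfg$L)
  for (i in seq_len(m)) {
    nodes <- seqs[[i]]$entries$node
    if (length(nodes) > 0) {
      seq_mat[i, seq_along(nodes)] <- nodes
      mask[i, seq_along(nodes)] <- 1
    }
  }
  attr_id <- Xid
  out <- NULL
  safe <- seq_mat; safe[safe == 0L] <- 1L
  idxvec <- as.vector(safe)
  maskcol <- ad_const(tp, matrix(as.vector(mask), ncol = 1))
  for (l in seq_len(cfg$layers)) {
    nm <- function(x) sprintf("%s%d.%s", prefix, l, x)
    Xhat <- .gcn_t(tp, attr_id, A, pids[[nm("W_gcn")]], pids[[nm("b_gcn")]],
                   cfg$activation)
    Xstack <- ad_mul(tp, ad_rows(tp, Xhat, idxvec), maskcol)
    Estack <- .encode_t(tp, Xstack, mask, cfg, pids, nm)
    dec <- .decode_t(tp, Estack, Xstack, Xhat, seq_mat, mask, cfg, pids, nm)
    Z <- .aggregate_t(tp, dec$sel, cfg, pids, nm)
    out <- list(Xhat = Xhat, Z = Z, choices = dec$choices,
                attention = dec$attention)
    attr_id <- Z
  }
  out
}

.inject_params <- function(tp, P) {
  ids <- lapply(P, function(v) ad_input(tp, v))
  names(ids) <- names(P)
  ids
}

# ---- numeric wrappers: the user-facing module surface ---------------------

#' GCN forward pass with symmetric no-self-loop normalization
#'
#' Computes `sigma(D^-1/2 A D^-1/2 X W + b)` where degrees of isolated nodes
#' are clamped to 1 (their row is `sigma(0 + b)`). The diagonal of `A` must
#' be zero: self-information re-enters later through the feature fusion, not
#' through self-loops.
#'
#' @param X m x d1 attribute matrix.
#' @param A symmetric 0/1 adjacency with zero diagonal.
#' @param W d1 x d2 weight matrix.
#' @param bias optional 1 x d2 bias (default zero).
#' @param activation `"identity"`, `"relu"` or `"tanh"`.
#' @return m x d2 matrix.
#' @export
gcn_forward <- function(X, A, W, bias = NULL,
                        activation = c("identity", "relu", "tanh")) {
  activation <- match.arg(activation)
  if (!isTRUE(all.equal(A, t(A)))) stop("adjacency must be symmetric")
  if (any(diag(A) != 0)) stop("adjacency must have a zero diagonal")
  if (is.null(bias)) bias <- matrix(0, 1, ncol(W))
  tp <- ad_tape()
  out <- .gcn_t(tp, ad_const(tp, X), A, ad_const(tp, W),
                ad_const(tp, bias), activation)
  ad_val(tp, out)
}

.single_center_setup <- function(Xhat, seq, cfg) {
  nodes <- seq$entries$node
  list(seq_mat = matrix(c(nodes, rep(0L, cfg$L - length(nodes))), 1),
       mask = matrix(c(rep(1, length(nodes)), rep(0, cfg$L - length(nodes))),
                     1))
}

#' Encode one node's neighbor sequence
#'
#' Runs the pointer encoder recurrence over the ordered sampled neighbors of
#' a single center node (state starts at zero; padded steps carry the state
#' forward). With `cfg$cell = "tanh"` this is the plain
#' `e_t = tanh(W [e_{t-1}, x_t] + b)` recurrence; the default is an LSTM
#' cell.
#'
#' @param Xhat m x d2 GCN-encoded node features.
#' @param seq a [sample_neighbor_sequence()] result.
#' @param cfg a [gpnn_config()].
#' @param params a [gpnn_params()] list (layer 1 weights are used).
#' @return L x d2 matrix of encoder states.
#' @export
encode_neighbors <- function(Xhat, seq, cfg, params) {
  s <- .single_center_setup(Xhat, seq, cfg)
  tp <- ad_tape()
  pids <- .inject_params(tp, params)
  Xid <- ad_const(tp, Xhat)
  safe <- s$seq_mat; safe[safe == 0L] <- 1L
  Xstack <- ad_mul(tp, ad_rows(tp, Xid, as.vector(safe)),
                   ad_const(tp, matrix(as.vector(s$mask), ncol = 1)))
  E <- .encode_t(tp, Xstack, s$mask, cfg, pids,
                 function(x) paste0("gpnn1.", x))
  ad_val(tp, E)
}

#' Pointer-attention decoding: rank and select M neighbors
#'
#' Runs the decoder recurrence from the trainable start sentinel; at each of
#' the M steps, attention logits `v' tanh(W1 e_q + W2 d_p)` are computed over
#' all L encoder positions, pad slots and already-selected positions are
#' masked out, the softmax row is renormalized over what remains, and the
#' argmax position is selected. If every position is exhausted before M
#' selections, the remaining selections are the zero sentinel (index 0).
#'
#' @inheritParams encode_neighbors
#' @return list of class `pointer_selection`: `indices` (length M, positions
#'   into the neighbor sequence; 0 = pad) and `attention` (M x L
#'   row-stochastic matrix).
#' @export
pointer_decode <- function(Xhat, seq, cfg, params) {
  s <- .single_center_setup(Xhat, seq, cfg)
  tp <- ad_tape()
  pids <- .inject_params(tp, params)
  Xid <- ad_const(tp, Xhat)
  safe <- s$seq_mat; safe[safe == 0L] <- 1L
  Xstack <- ad_mul(tp, ad_rows(tp, Xid, as.vector(safe)),
                   ad_const(tp, matrix(as.vector(s$mask), ncol = 1)))
  nm <- function(x) paste0("gpnn1.", x)
  E <- .encode_t(tp, Xstack, s$mask, cfg, pids, nm)
  dec <- .decode_t(tp, E, Xstack, Xid, s$seq_mat, s$mask, cfg, pids, nm)
  structure(list(indices = as.integer(dec$choices[1, ]),
                 attention = do.call(rbind, lapply(dec$attention,
                                                   function(a) a[1, ]))),
            class = "pointer_selection")
}

#' Aggregate the selected neighbor representations
#'
#' Same-padded 1D convolution over the ordered M selected vectors followed
#' by the configured reduction (elementwise max by default) into one d2
#' vector.
#'
#' @param selected M x d2 matrix of selected neighbor representations, in
#'   selection order.
#' @param cfg a [gpnn_config()].
#' @param params a [gpnn_params()] list.
#' @return numeric d2 vector.
#' @export
aggregate_selected <- function(selected, cfg, params) {
  stopifnot(nrow(selected) == cfg$M)
  tp <- ad_tape()
  pids <- .inject_params(tp, params)
  sel <- lapply(seq_len(cfg$M), function(t)
    ad_const(tp, selected[t, , drop = FALSE]))
  z <- .aggregate_t(tp, sel, cfg, pids, function(x) paste0("gpnn1.", x))
  as.vector(ad_val(tp, z))
}

#' Full GPNN layer over a sentence graph
#'
#' Composition of the GCN encoding, per-node neighbor encoding, pointer
#' decoding and aggregation; with `layers = 2` the first layer's output
#' vectors become the second layer's node attributes (same neighbor
#' sequences).
#'
#' @param graph a [build_sentence_graph()] result carrying attributes.
#' @param seqs neighbor sequences from [batch_sample()].
#' @param cfg a [gpnn_config()].
#' @param params a [gpnn_params()] list.
#' @return list with `Xhat` (m x d2), `Z` (m x d2), `choices` (m x M
#'   selected sequence positions) and `attention`.
#' @export
gpnn_layer <- function(graph, seqs, cfg, params) {
  tp <- ad_tape()
  pids <- .inject_params(tp, params)
  Xid <- ad_const(tp, graph$attributes)
  out <- .gpnn_t(tp, Xid, graph$adjacency, seqs, cfg, pids)
  list(Xhat = ad_val(tp, out$Xhat), Z = ad_val(tp, out$Z),
       choices = out$choices, attention = out$attention)
}
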