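#' Head operations: fusion, sentence representation, classification
#'
#' `fuse_features` maps the row-wise concatenation of the three token
#' streams (contextual `X`, GCN-local `Xhat`, pointer-aggregated `Z`)
#' through an affine layer and nonlinearity; `sentence_representation`
#' zero-pads the fused token matrix to `max_len` rows, flattens it
#' row-major, and maps it to a fixed-size sentence vector;
#' `classify` turns a sentence vector into a softmax probability
#' distribution over the labels.
#'
#' @param X,Xhat,Z numeric matrices with equal row counts.
#' @param W,bias affine weights.
#' @param activation `"relu"` (default) or `"identity"`.
#' @export
fuse_features <- function(X, Xhat, Z, W, bias = NULL,
                          activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  if (nrow(X) != nrow(Xhat) || nrow(X) != nrow(Z)) {
    stop("X, Xhat and Z must have equal row counts")
  }
  if (is.null(bias)) bias <- matrix(0, 1, ncol(W))
  h <- sweep(cbind(X, Xhat, Z) %*% W, 2, bias[1, ], "+")
  if (activation == "relu") pmax(h, 0) else h
}

#' @rdname fuse_features
#' @param fused token matrix from `fuse_features`.
#' @param max_len padded row count the flatten assumes.
#' @export
sentence_representation <- function(fused, W, bias = NULL, max_len,
                                    activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  if (nrow(fused) > max_len) stop("more tokens than max_len")
  if (is.null(bias)) bias <- matrix(0, 1, ncol(W))
  padded <- rbind(fused, matrix(0, max_len - nrow(fused), ncol(fused)))
  flat <- matrix(as.vector(t(padded)), nrow = 1)
  h <- flat %*% W + bias
  if (activation == "relu") pmax(h, 0) else h
}

#' @rdname fuse_features
#' @param sentence_vec 1 x d_s sentence vector (or plain vector).
#' @param labels optional label names for the result.
#' @export
classify <- function(sentence_vec, W, bias = NULL, labels = NULL) {
  v <- matrix(as.numeric(sentence_vec), nrow = 1)
  if (is.null(bias)) bias <- matrix(0, 1, ncol(W))
  logits <- v %*% W + bias
  z <- exp(logits - max(logits))
  p <- as.vector(z / sum(z))
  if (!is.null(labels)) names(p) <- labels
  p
}

#' Training configuration
#'
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param lr peak learning rate for all trainable weights (the toy encoder
#'   trains at the same rate; a fine-tuned transformer backbone would use a
#'   much smaller one, conventionally 2e-5).
#' @param warmup_proportion fraction of steps with linearly increasing
#'   learning rate; linear decay to zero afterwards.
#' @param seed master seed: parameter init, shuffling and neighbor
#'   resampling all derive from it.
#' @param max_len maximum word-piece count; sizes the sentence-level affine.
#' @param d_f fused token dimension (default: the encoder dimension d1).
#' @param d_s sentence representation dimension.
#' @param dropout classifier dropout rate on the fused features (0 is the
#'   tuned optimum on CHEMPROT-style data).
#' @param k sampler hop depth.
#' @param resample resample neighbor sequences each epoch (regularization);
#'   inference always uses a fixed stream.
#' @param sentence_mode how fused tokens become a sentence vector:
#'   `"flatten"` stacks them in the token dimension (position-aware,
#'   the default) or `"mean"` pools them (position-free).
#' @param ablate_gpnn force the pointer stream Z to zero (ablation studies).
#' @export
train_config <- function(epochs = 10, batch_size = 16, lr = 1e-3,
                         warmup_proportion = 0.1, seed = 1L, max_len = 128L,
                         d_f = NULL, d_s = 64L, dropout = 0, k = 2L,
                         resample = TRUE,
                         sentence_mode = c("flatten", "mean"),
                         ablate_gpnn = FALSE) {
  stopifnot(warmup_proportion >= 0, warmup_proportion <= 1,
            dropout >= 0, dropout < 1)
  structure(list(epochs = epochs, batch_size = batch_size, lr = lr,
                 warmup_proportion = warmup_proportion,
                 seed = as.integer(seed), max_len = as.integer(max_len),
                 d_f = d_f, d_s = as.integer(d_s), dropout = dropout,
                 k = as.integer(k), resample = resample,
                 sentence_mode = match.arg(sentence_mode),
                 ablate_gpnn = ablate_gpnn),
            class = "train_config")
}

# ---- static per-instance preparation --------------------------------------

# returns an empty list with a reason attribute when the instance drops out
.prepare_instance <- function(id, text, parse, encoder, max_len) {
  fail <- function(reason) structure(list(), reason = reason, dropped = TRUE)
  if (is.null(parse)) return(fail("no parse for instance"))
  if (encoder$backend == "toy") {
    input <- tryCatch(.encoder_input(text, encoder), error = function(e) e)
    if (inherits(input, "error")) return(fail(conditionMessage(input)))
  } else {
    if (!id %in% names(encoder$store)) return(fail("no precomputed vectors"))
    rec <- encoder$store[[id]]
    sm <- tryCatch(.split_marked(text), error = function(e) e)
    if (inherits(sm, "error")) return(fail(conditionMessage(sm)))
    wop <- tryCatch(.pieces_to_words(rec$pieces, sm$words),
                    error = function(e) e)
    if (inherits(wop, "error")) return(fail(conditionMessage(wop)))
    input <- list(pieces = rec$pieces, word_of_piece = wop,
                  flags = as.numeric(sm$marked[wop]), ids = NA_integer_,
                  words = sm$words, vectors = rec$vectors)
  }
  if (!identical(tolower(parse$words), tolower(input$words))) {
    return(fail("parse words disagree with sentence words"))
  }
  align <- align_wordpieces(parse$words, input$pieces)
  g <- build_sentence_graph(parse, align)
  m <- g$node_count
  keep <- seq_len(min(m, max_len))
  if (m > max_len && any(input$flags[-keep] > 0)) {
    return(fail("truncation would drop an entity mention"))
  }
  A <- g$adjacency[keep, keep, drop = FALSE]
  out <- list(id = id, ids = input$ids[keep], flags = input$flags[keep],
              pieces = input$pieces[keep], A = A, m = length(keep))
  if (!is.null(input$vectors)) {
    out$vectors <- input$vectors[keep, , drop = FALSE]
  }
  out
}

.prepare_corpus <- function(instances, parses, encoder, max_len) {
  preps <- vector("list", nrow(instances))
  reasons <- character(0)
  for (i in seq_len(nrow(instances))) {
    id <- instances$instance_id[i]
    p <- .prepare_instance(id, instances$text[i], parses[[id]], encoder,
                           max_len)
    if (isTRUE(attr(p, "dropped"))) {
      reasons <- c(reasons, sprintf("%s: %s", id, attr(p, "reason")))
      preps[[i]] <- NULL
    } else preps[[i]] <- p
  }
  keep <- !vapply(preps, is.null, logical(1))
  list(preps = preps[keep], labels = instances$label[keep],
       ids = instances$instance_id[keep], dropped = reasons)
}

# ---- tape forward for one prepared instance -------------------------------

.head_dims <- function(encoder_d1, gcfg, control) {
  d_f <- if (is.null(control$d_f)) encoder_d1 else control$d_f
  list(d_f = d_f,
       fuse_in = encoder_d1 + 2 * gcfg$d2,
       sent_in = if (identical(control$sentence_mode, "mean")) d_f else
         control$max_len * d_f)
}

.head_params <- function(encoder_d1, gcfg, control, n_labels, seed) {
  hd <- .head_dims(encoder_d1, gcfg, control)
  .with_seed(seed + 7L, list(
    head.W_fuse = .glorot(hd$fuse_in, hd$d_f),
    head.b_fuse = matrix(0, 1, hd$d_f),
    head.W_sent = .glorot(hd$sent_in, control$d_s),
    head.b_sent = matrix(0, 1, control$d_s),
    head.W_cls = .glorot(control$d_s, n_labels),
    head.b_cls = matrix(0, 1, n_labels)))
}

.forward_instance <- function(tp, pids, prep, seqs, model, drop_mask = NULL) {
  enc <- model$encoder
  Xid <- if (enc$backend == "toy") {
    .encode_toy_t(tp, pids, prep, enc$d1)
  } else {
    ad_const(tp, prep$vectors)
  }
  gcfg <- model$gpnn
  if (model$control$ablate_gpnn) {
    Xhat <- .gcn_t(tp, Xid, prep$A, pids[["gpnn1.W_gcn"]],
                   pids[["gpnn1.b_gcn"]], gcfg$activation)
    Z <- ad_const(tp, matrix(0, prep$m, gcfg$d2))
  } else {
    g <- .gpnn_t(tp, Xid, prep$A, seqs, gcfg, pids)
    Xhat <- g$Xhat; Z <- g$Z
  }
  fused <- ad_relu(tp, ad_add(tp, ad_matmul(
    tp, ad_cbind(tp, c(Xid, Xhat, Z)), pids[["head.W_fuse"]]),
    pids[["head.b_fuse"]]))
  if (!is.null(drop_mask)) fused <- ad_mul(tp, fused, ad_const(tp, drop_mask))
  pooled <- if (identical(model$control$sentence_mode, "mean")) {
    ad_matmul(tp, ad_const(tp, matrix(1 / prep$m, 1, prep$m)), fused)
  } else {
    ad_flatten_pad(tp, fused, model$control$max_len)
  }
  sent <- ad_relu(tp, ad_add(tp, ad_matmul(
    tp, pooled, pids[["head.W_sent"]]), pids[["head.b_sent"]]))
  ad_add(tp, ad_matmul(tp, sent, pids[["head.W_cls"]]), pids[["head.b_cls"]])
}

.sample_for_instance <- function(prep, inst_index, gcfg, control, epoch) {
  g <- list(node_count = prep$m, adjacency = prep$A)
  scfg <- sampler_config(k = control$k, L = gcfg$L,
                         seed = (control$seed * 131L + epoch) %% 2147483647L)
  batch_sample(g, scfg, sentence_key = inst_index)
}

# ---- optimizer ------------------------------------------------------------

.adam_new <- function(P) {
  list(m = lapply(P, function(p) array(0, dim(p))),
       v = lapply(P, function(p) array(0, dim(p))), t = 0L)
}

.adam_step <- function(P, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0.01) {
  state$t <- state$t + 1L
  for (nmv in names(grads)) {
    g <- grads[[nmv]]
    if (is.null(g)) next
    state$m[[nmv]] <- beta1 * state$m[[nmv]] + (1 - beta1) * g
    state$v[[nmv]] <- beta2 * state$v[[nmv]] + (1 - beta2) * g * g
    mhat <- state$m[[nmv]] / (1 - beta1^state$t)
    vhat <- state$v[[nmv]] / (1 - beta2^state$t)
    P[[nmv]] <- P[[nmv]] - lr * (mhat / (sqrt(vhat) + eps) +
                                   weight_decay * P[[nmv]])
  }
  list(P = P, state = state)
}

.lr_at <- function(step, total, lr, warmup) {
  w <- max(1, floor(total * warmup))
  if (step <= w) lr * step / w else lr * max(0, (total - step) / (total - w))
}

# ---- fitting --------------------------------------------------------------

#' Fit a sentence-graph pointer relation-extraction model
#'
#' The full pipeline: encode each marked sentence into word-piece vectors,
#' build the dependency sentence graph, sample multi-hop neighbor sequences,
#' run the graph pointer layer (GCN + LSTM pointer selection + 1D
#' convolution), fuse the three token streams, flatten to a sentence
#' representation and classify with softmax, trained end to end by AdamW on
#' the cross-entropy with linear warmup/decay. Neighbor sequences are
#' resampled every epoch during training and fixed at inference. When a
#' development set is given, the best-dev-micro-F1 epoch's parameters are
#' retained; otherwise the final parameters are.
#'
#' @param instances data frame from [read_instances()] / [expand_pairs()].
#' @param parses named list of [dep_parse()] keyed by `instance_id`.
#' @param scheme a [label_scheme()].
#' @param encoder a [toy_encoder()] or [precomputed_encoder()].
#' @param gpnn a [gpnn_config()].
#' @param control a [train_config()].
#' @param dev_instances,dev_parses optional development split for model
#'   selection.
#' @return object of class `gpnre` with `print`, `summary`, `coef`,
#'   `predict`, `plot`, `residuals` and `simulate` methods.
#' @export
gpnre_fit <- function(instances, parses, scheme = chemprot_scheme(),
                      encoder, gpnn = gpnn_config(d1 = encoder$d1),
                      control = train_config(),
                      dev_instances = NULL, dev_parses = NULL) {
  if (nrow(instances) == 0) stop("empty corpus")
  labels <- scheme_labels(scheme)
  bad <- setdiff(unique(instances$label), labels)
  if (length(bad) > 0) stop("labels outside scheme: ", paste(bad, collapse = ", "))
  corp <- .prepare_corpus(instances, parses, encoder, control$max_len)
  if (length(corp$preps) == 0) stop("no usable instances after preparation")
  y <- match(corp$labels, labels)

  P <- c(if (encoder$backend == "toy") encoder$params,
         gpnn_params(gpnn, seed = control$seed + 3L),
         .head_params(encoder$d1, gpnn, control, length(labels),
                      control$seed))
  model <- list(encoder = encoder, gpnn = gpnn, control = control,
                scheme = scheme, labels = labels)

  n <- length(corp$preps)
  steps_per_epoch <- ceiling(n / control$batch_size)
  total_steps <- control$epochs * steps_per_epoch
  opt <- .adam_new(P)
  log <- data.frame(epoch = integer(), loss = numeric(),
                    dev_f1 = numeric(), dev_acc = numeric())
  best <- list(metric = -Inf, P = P, epoch = 0L)
  step <- 0L

  for (epoch in seq_len(control$epochs)) {
    order <- .with_seed(control$seed + 1000L + epoch, sample.int(n))
    seq_epoch <- if (control$resample) epoch else 1L
    epoch_loss <- 0
    for (b in seq_len(steps_per_epoch)) {
      idx <- order[(((b - 1) * control$batch_size + 1)):min(b * control$batch_size, n)]
      grads <- list()
      for (i in idx) {
        prep <- corp$preps[[i]]
        seqs <- if (control$ablate_gpnn) NULL else
          .sample_for_instance(prep, i, gpnn, control, seq_epoch)
        dm <- NULL
        if (control$dropout > 0) {
          hd <- .head_dims(encoder$d1, gpnn, control)
          dm <- .with_seed(.stream_seed(control$seed, epoch * 100000 + i, 1),
                           matrix(stats::rbinom(prep$m * hd$d_f, 1,
                                                1 - control$dropout),
                                  prep$m, hd$d_f) / (1 - control$dropout))
        }
        tp <- ad_tape()
        pids <- .inject_params(tp, P)
        logits <- .forward_instance(tp, pids, prep, seqs, model, dm)
        loss <- ad_ce_loss(tp, logits, y[i])
        ad_backward(tp, loss)
        epoch_loss <- epoch_loss + ad_val(tp, loss)[1, 1]
        for (nmv in names(pids)) {
          g <- tp$grads[[pids[[nmv]]]]
          if (is.null(g)) next
          grads[[nmv]] <- if (is.null(grads[[nmv]])) g else grads[[nmv]] + g
        }
      }
      grads <- lapply(grads, function(g) g / length(idx))
      step <- step + 1L
      lr <- .lr_at(step, total_steps, control$lr, control$warmup_proportion)
      upd <- .adam_step(P, grads, opt, lr)
      P <- upd$P; opt <- upd$state
    }
    epoch_loss <- epoch_loss / n
    dev_f1 <- NA_real_; dev_acc <- NA_real_
    if (!is.null(dev_instances)) {
      fitted_now <- .as_gpnre(P, model, corp, log, best)
      pr <- predict(fitted_now, dev_instances, dev_parses, type = "class")
      keep <- !is.na(pr)
      # early epochs may predict no instance of some class; the metric is
      # defined as 0 there and the warning is expected
      rep <- suppressWarnings(
        eval_report(pr[keep], dev_instances$label[keep], scheme = scheme))
      dev_f1 <- rep$micro[["f1"]]
      dev_acc <- mean(pr[keep] == dev_instances$label[keep])
      if (dev_f1 > best$metric) best <- list(metric = dev_f1, P = P,
                                             epoch = epoch)
    } else {
      best <- list(metric = -epoch_loss, P = P, epoch = epoch)
    }
    log <- rbind(log, data.frame(epoch = epoch, loss = epoch_loss,
                                 dev_f1 = dev_f1, dev_acc = dev_acc))
  }
  fit <- .as_gpnre(best$P, model, corp, log, best)
  fit
}

.as_gpnre <- function(P, model, corp, log, best) {
  structure(list(params = P, encoder = model$encoder, gpnn = model$gpnn,
                 control = model$control, scheme = model$scheme,
                 labels = model$labels, log = log,
                 best_epoch = best$epoch, dropped = corp$dropped,
                 n_train = length(corp$preps)),
            class = "gpnre")
}

#' Predict relation labels or class probabilities
#'
#' Neighbor sequences at prediction time come from fixed RNG streams, so
#' predictions are deterministic for a given model. When a node's 2-hop
#' neighborhood exceeds the sampling cap L, one BFS draw can miss
#' informative neighbors; `draws > 1` averages the class probabilities
#' over that many fixed-stream sample draws (a deterministic Monte Carlo
#' average over the sampler's randomness). Instances that cannot be
#' prepared (no parse, unalignable) yield `NA` rows.
#'
#' @param object a fitted [gpnre_fit()] model.
#' @param instances,parses data to predict on.
#' @param type `"class"` for labels, `"prob"` for the full softmax matrix.
#' @param draws number of neighbor-sample draws to average over.
#' @param ... unused.
#' @export
predict.gpnre <- function(object, instances, parses,
                          type = c("class", "prob"), draws = 1L, ...) {
  type <- match.arg(type)
  probs <- matrix(NA_real_, nrow(instances), length(object$labels),
                  dimnames = list(instances$instance_id, object$labels))
  enc <- object$encoder
  model <- list(encoder = enc, gpnn = object$gpnn, control = object$control,
                scheme = object$scheme, labels = object$labels)
  for (i in seq_len(nrow(instances))) {
    id <- instances$instance_id[i]
    prep <- .prepare_instance(id, instances$text[i], parses[[id]], enc,
                              object$control$max_len)
    if (isTRUE(attr(prep, "dropped"))) next
    acc <- 0
    for (d in seq_len(draws)) {
      seqs <- if (object$control$ablate_gpnn) NULL else
        .sample_for_instance(prep, i, object$gpnn, object$control,
                             1000000L + d)
      tp <- ad_tape()
      pids <- .inject_params(tp, object$params)
      logits <- ad_val(tp, .forward_instance(tp, pids, prep, seqs, model))
      z <- exp(logits - max(logits))
      acc <- acc + z / sum(z)
      if (object$control$ablate_gpnn) break
    }
    probs[i, ] <- acc / if (object$control$ablate_gpnn) 1 else draws
  }
  if (type == "prob") return(probs)
  out <- object$labels[apply(probs, 1, function(r)
    if (anyNA(r)) NA_integer_ else which.max(r))]
  names(out) <- instances$instance_id
  out
}

#' @export
print.gpnre <- function(x, ...) {
  cat("Sentence-graph pointer relation-extraction model\n")
  cat(sprintf("  labels: %s\n", paste(x$labels, collapse = ", ")))
  cat(sprintf("  encoder: %s (d1 = %d)\n", x$encoder$backend, x$encoder$d1))
  cat(sprintf("  GPNN: layers %d, L %d, M %d, d2 %d, cell %s%s\n",
              x$gpnn$layers, x$gpnn$L, x$gpnn$M, x$gpnn$d2, x$gpnn$cell,
              if (x$control$ablate_gpnn) " [Z ablated]" else ""))
  cat(sprintf("  trained on %d instances, %d epochs (best epoch %d)\n",
              x$n_train, nrow(x$log), x$best_epoch))
  if (any(!is.na(x$log$dev_f1))) {
    cat(sprintf("  best dev micro-F1: %.2f%%\n",
                max(x$log$dev_f1, na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
summary.gpnre <- function(object, ...) {
  print(object)
  cat(sprintf("  parameters: %d tensors, %d values\n",
              length(object$params),
              sum(vapply(object$params, length, numeric(1)))))
  if (length(object$dropped) > 0) {
    cat(sprintf("  dropped during preparation: %d instance(s)\n",
                length(object$dropped)))
  }
  cat("  epoch log:\n")
  print(object$log, row.names = FALSE)
  invisible(object)
}

#' @export
coef.gpnre <- function(object, ...) object$params

#' @export
plot.gpnre <- function(x, ...) {
  graphics::par(mfrow = c(1, if (any(!is.na(x$log$dev_f1))) 2 else 1))
  graphics::plot(x$log$epoch, x$log$loss, type = "b", xlab = "epoch",
                 ylab = "mean training loss", main = "training loss", ...)
  if (any(!is.na(x$log$dev_f1))) {
    graphics::plot(x$log$epoch, x$log$dev_f1, type = "b", xlab = "epoch",
                   ylab = "dev micro-F1 (%)", main = "model selection", ...)
    graphics::abline(v = x$best_epoch, lty = 2)
  }
  invisible(x)
}

#' @export
residuals.gpnre <- function(object, instances, parses, ...) {
  probs <- predict(object, instances, parses, type = "prob")
  gold <- match(instances$label, object$labels)
  r <- 1 - probs[cbind(seq_len(nrow(probs)), gold)]
  names(r) <- instances$instance_id
  r
}

#' @export
simulate.gpnre <- function(object, nsim = 1, seed = NULL, instances, parses,
                           ...) {
  probs <- predict(object, instances, parses, type = "prob")
  draw <- function() apply(probs, 1, function(p)
    if (anyNA(p)) NA_character_ else sample(object$labels, 1, prob = p))
  out <- .with_seed(if (is.null(seed)) object$control$seed else seed,
                    replicate(nsim, draw()))
  as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
}

# ---- checkpoints ----------------------------------------------------------

#' Save / load a fitted model as JSON
#'
#' The checkpoint holds every parameter tensor (with shapes), the
#' configuration, the label scheme and the epoch log; `gpnre_load` restores
#' a model whose predictions equal the saved one's.
#'
#' @param object a fitted `gpnre` model (toy or precomputed encoder; the
#'   precomputed store itself is not serialized).
#' @param path output JSON path.
#' @export
gpnre_save <- function(object, path) {
  enc <- object$encoder
  ser <- list(
    params = lapply(object$params, function(p)
      list(dim = dim(p), data = as.vector(p))),
    labels = object$labels,
    scheme = list(evaluated_labels = object$scheme$evaluated_labels,
                  negative_label = object$scheme$negative_label,
                  raw_to_evaluated = as.list(object$scheme$raw_to_evaluated)),
    gpnn = unclass(object$gpnn),
    control = unclass(object$control),
    encoder = list(backend = enc$backend, d1 = enc$d1,
                   max_len = enc$max_len,
                   vocab = if (enc$backend == "toy") enc$vocab),
    log = object$log, best_epoch = object$best_epoch,
    n_train = object$n_train, version = 1L)
  writeLines(jsonlite::toJSON(ser, auto_unbox = TRUE, digits = NA, null = "null"),
             path)
  invisible(path)
}

#' @rdname gpnre_save
#' @export
gpnre_load <- function(path) {
  ser <- jsonlite::fromJSON(readLines(path), simplifyVector = TRUE)
  P <- lapply(ser$params, function(p) matrix(p$data, p$dim[1], p$dim[2]))
  scheme <- label_scheme(ser$scheme$evaluated_labels,
                         ser$scheme$negative_label,
                         unlist(ser$scheme$raw_to_evaluated))
  gcfg <- do.call(gpnn_config, ser$gpnn[c("d1", "d2", "L", "M", "layers",
                                          "conv_kernel", "activation",
                                          "cell", "aggregation")])
  ctl <- do.call(train_config, ser$control[setdiff(names(ser$control), NULL)])
  enc <- if (ser$encoder$backend == "toy") {
    e <- toy_encoder(ser$encoder$vocab, d1 = ser$encoder$d1,
                     max_len = ser$encoder$max_len)
    e$params <- P[grep("^enc\\.", names(P), value = TRUE)]
    e
  } else {
    structure(list(backend = "precomputed", store = list(),
                   d1 = ser$encoder$d1, max_len = ser$encoder$max_len),
              class = "gpnre_encoder")
  }
  structure(list(params = P, encoder = enc, gpnn = gcfg, control = ctl,
                 scheme = scheme, labels = ser$labels,
                 log = as.data.frame(ser$log),
                 best_epoch = ser$best_epoch, dropped = character(0),
                 n_train = ser$n_train),
            class = "gpnre")
}
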