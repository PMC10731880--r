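# finite-difference oracle for gradients of a scalar-valued tape
fd_worst <- function(build, P, probes = 4, eps = 1e-6) {
  tp <- ad_tape()
  pids <- lapply(P, function(p) ad_input(tp, p))
  out <- build(tp, pids)
  ad_backward(tp, out)
  f0 <- ad_val(tp, out)[1, 1]
  worst <- 0
  for (nm in names(P)) {
    g <- ad_grad(tp, pids[[nm]])
    for (k in sample(length(P[[nm]]), min(probes, length(P[[nm]])))) {
      P2 <- P
      P2[[nm]][k] <- P2[[nm]][k] + eps
      tp2 <- ad_tape()
      pid2 <- lapply(P2, function(p) ad_input(tp2, p))
      f1 <- ad_val(tp2, build(tp2, pid2))[1, 1]
      fd <- (f1 - f0) / eps
      worst <- max(worst, abs(fd - g[k]) / max(1e-5, abs(fd) + abs(g[k])))
    }
  }
  worst
}

test_that("elementwise and structural ops match finite differences", {
  set.seed(5)
  P <- list(A = matrix(rnorm(12), 3, 4), W = matrix(rnorm(8), 4, 2),
            b = matrix(rnorm(2), 1))
  worst <- fd_worst(function(tp, p) {
    h <- ad_relu(tp, ad_add(tp, ad_matmul(tp, ad_tanh(tp, p$A), p$W), p$b))
    s <- ad_sigmoid(tp, ad_mul(tp, h, h))
    f <- ad_flatten_pad(tp, s, 5)
    ad_ce_loss(tp, ad_cols(tp, f, 1:4), 2)
  }, P, probes = 6)
  expect_lt(worst, 1e-4)
})

test_that("row gather accumulates gradient over duplicate indices", {
  tp <- ad_tape()
  X <- ad_input(tp, matrix(1:6, 3, 2) * 1.0)
  g <- ad_rows(tp, X, c(1L, 1L, 3L))
  s <- ad_ce_loss(tp, ad_flatten_pad(tp, g, 3), 1)
  ad_backward(tp, s)
  grad <- ad_grad(tp, X)
  expect_equal(dim(grad), c(3, 2))
  expect_equal(grad[2, ], c(0, 0))       # never gathered
  expect_false(all(grad[1, ] == 0))      # gathered twice
})

test_that("softmax rows are stochastic and cross-entropy grad is p minus onehot", {
  set.seed(6)
  A <- matrix(rnorm(15), 3, 5)
  tp <- ad_tape()
  a <- ad_input(tp, A)
  sm <- ad_softmax_rows(tp, a)
  expect_equal(rowSums(ad_val(tp, sm)), rep(1, 3), tolerance = 1e-12)

  logits <- matrix(c(2, 1, 0.5), 1)
  tp2 <- ad_tape()
  l <- ad_input(tp2, logits)
  loss <- ad_ce_loss(tp2, l, 3)
  ad_backward(tp2, loss)
  p <- exp(logits) / sum(exp(logits))
  expect_equal(as.vector(ad_grad(tp2, l)), as.vector(p) - c(0, 0, 1),
               tolerance = 1e-12)
})

test_that("position-wise max pooling routes gradient to the argmax", {
  tp <- ad_tape()
  a <- ad_input(tp, matrix(c(1, 5), 1))
  b <- ad_input(tp, matrix(c(3, 2), 1))
  mx <- ad_pmax_list(tp, c(a, b))
  expect_equal(as.vector(ad_val(tp, mx)), c(3, 5))
  loss <- ad_ce_loss(tp, mx, 1)
  ad_backward(tp, loss)
  ga <- ad_grad(tp, a); gb <- ad_grad(tp, b)
  expect_equal(ga[1, 1], 0)   # a lost position 1
  expect_equal(gb[1, 2], 0)   # b lost position 2
  expect_false(ga[1, 2] == 0)
  expect_false(gb[1, 1] == 0)
})

test_that("fused recurrences match finite differences, with masking", {
  set.seed(7)
  m <- 4; d <- 3; L <- 3; h <- 2
  mask <- matrix(c(1, 1, 1, 1, 1, 0, 1, 0, 0, 0, 0, 0), m, L, byrow = TRUE)
  X <- matrix(rnorm(L * m * d), L * m, d)
  red <- matrix(1, 1, L * m)

  P <- list(W = matrix(rnorm((h + d) * 4 * h) * 0.4, h + d, 4 * h),
            b = matrix(rnorm(4 * h) * 0.1, 1))
  expect_lt(fd_worst(function(tp, p) {
    s <- ad_lstm_seq(tp, ad_const(tp, X), p$W, p$b, mask)
    ad_ce_loss(tp, ad_matmul(tp, ad_const(tp, red), s), 1)
  }, P), 1e-4)

  P2 <- list(W = matrix(rnorm((h + d) * h) * 0.4, h + d, h),
             b = matrix(rnorm(h) * 0.1, 1))
  expect_lt(fd_worst(function(tp, p) {
    s <- ad_tanh_seq(tp, ad_const(tp, X), p$W, p$b, mask)
    ad_ce_loss(tp, ad_matmul(tp, ad_const(tp, red), s), 2)
  }, P2), 1e-4)

  P3 <- list(X = matrix(rnorm(5 * d), 5, d),
             W = matrix(rnorm((h + d) * h) * 0.4, h + d, h),
             b = matrix(rnorm(h) * 0.1, 1))
  expect_lt(fd_worst(function(tp, p) {
    f <- ad_rnn_tanh(tp, p$X, p$W, p$b)
    r <- ad_rnn_tanh(tp, p$X, p$W, p$b, reverse = TRUE)
    ad_ce_loss(tp, ad_matmul(tp, ad_const(tp, matrix(1, 1, 5)),
                             ad_cbind(tp, c(f, r))), 1)
  }, P3), 1e-4)

  P4 <- list(hs = matrix(rnorm(m * h) * 0.5, m, h),
             cs = matrix(rnorm(m * h) * 0.5, m, h),
             x = matrix(rnorm(m * d), m, d),
             W = matrix(rnorm((h + d) * 4 * h) * 0.4, h + d, 4 * h),
             b = matrix(rnorm(4 * h) * 0.1, 1))
  expect_lt(fd_worst(function(tp, p) {
    st <- ad_lstm_step(tp, p$hs, p$cs, p$x, p$W, p$b)
    ad_ce_loss(tp, ad_matmul(tp, ad_const(tp, matrix(1, 1, m)), st), 2)
  }, P4), 1e-4)

  P5 <- list(A = matrix(abs(rnorm(m * L)), m, L),
             X = matrix(rnorm(L * m * d), L * m, d))
  expect_lt(fd_worst(function(tp, p) {
    mx <- ad_attn_mix(tp, p$A, p$X)
    ad_ce_loss(tp, ad_matmul(tp, ad_const(tp, matrix(1, 1, m)), mx), 2)
  }, P5), 1e-4)
})

test_that("detach blocks gradient while preserving the forward value", {
  tp <- ad_tape()
  a <- ad_input(tp, matrix(c(1, 2), 1))
  d <- ad_detach(tp, a)
  expr <- ad_add(tp, a, ad_sub(tp, a, d))  # value = a, grad = 2 via both paths
  expect_equal(ad_val(tp, expr), ad_val(tp, a))
  loss <- ad_ce_loss(tp, expr, 1)
  ad_backward(tp, loss)
  p <- exp(c(1, 2)) / sum(exp(c(1, 2)))
  expect_equal(as.vector(ad_grad(tp, a)), 2 * (p - c(1, 0)), tolerance = 1e-10)
})
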