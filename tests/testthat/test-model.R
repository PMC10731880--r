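test_that("feature fusion is the documented affine map of the concatenation", {
  X <- matrix(0, 3, 2); W <- matrix(rnorm(12), 6, 2)
  expect_equal(fuse_features(X, X, X, W), matrix(0, 3, 2))

  # identity block on the X columns recovers X
  W_id <- rbind(diag(2), matrix(0, 4, 2))
  Xr <- matrix(abs(rnorm(6)), 3, 2)
  expect_equal(fuse_features(Xr, matrix(rnorm(6), 3, 2),
                             matrix(rnorm(6), 3, 2), W_id), Xr)

  # scalar streams with hand-set 3x1 weights
  w <- matrix(c(2, -1, 0.5), 3, 1)
  out <- fuse_features(matrix(1), matrix(3), matrix(4), w,
                       activation = "identity")
  expect_equal(out[1, 1], 2 * 1 - 1 * 3 + 0.5 * 4)
  expect_error(fuse_features(matrix(0, 2, 1), matrix(0, 3, 1),
                             matrix(0, 2, 1), w), "equal row counts")
})

test_that("the sentence map is pad-invariant but position-sensitive", {
  set.seed(12)
  d_f <- 2; max_len <- 5; d_s <- 3
  W <- matrix(rnorm(max_len * d_f * d_s), max_len * d_f, d_s)
  b <- matrix(rnorm(d_s), 1)
  # all-pad input: bias-only output
  empty <- matrix(0, 0, d_f)
  expect_equal(sentence_representation(empty, W, b, max_len,
                                       activation = "identity"), b)
  # extra zero rows change nothing (they are the padding)
  f2 <- matrix(rnorm(2 * d_f), 2, d_f)
  expect_equal(sentence_representation(f2, W, b, max_len),
               sentence_representation(rbind(f2, 0), W, b, max_len))
  # swapping two real token rows changes the output
  f_swap <- f2[c(2, 1), ]
  expect_false(isTRUE(all.equal(
    sentence_representation(f2, W, b, max_len),
    sentence_representation(f_swap, W, b, max_len))))
  expect_error(sentence_representation(matrix(0, 9, d_f), W, b, max_len),
               "max_len")
})

test_that("classification is a proper softmax with fixed tie-breaking", {
  W <- diag(4); labels <- c("False", "CPR:3", "CPR:4", "CPR:5")
  p0 <- classify(rep(0, 4), W, labels = labels)
  expect_equal(unname(p0), rep(0.25, 4))
  set.seed(14)
  for (i in 1:1000) {
    p <- classify(rnorm(4), W)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-9)
  }
  # monotone in the logits
  p <- classify(c(2, 1, 0, -1), W, labels = labels)
  expect_equal(names(sort(p, decreasing = TRUE)), labels)
})

test_that("training overfits one instance and is seed-reproducible", {
  corp <- synth_small()
  enc <- tiny_encoder(corp)
  gcfg <- gpnn_config(d1 = 8, L = 4, M = 2)
  ctl <- train_config(epochs = 8, batch_size = 1, max_len = 32, seed = 2)
  one <- corp$instances[3, , drop = FALSE]
  fit <- gpnre_fit(one, corp$parses, corp$scheme, enc, gcfg, ctl)
  expect_lt(fit$log$loss[8], fit$log$loss[1])
  expect_equal(as.character(predict(fit, one, corp$parses)), one$label)

  ctl2 <- train_config(epochs = 2, batch_size = 8, max_len = 32, seed = 5)
  sub <- corp$instances[1:16, ]
  fa <- gpnre_fit(sub, corp$parses, corp$scheme, enc, gcfg, ctl2)
  fb <- gpnre_fit(sub, corp$parses, corp$scheme, enc, gcfg, ctl2)
  expect_identical(fa$log$loss, fb$log$loss)
  expect_identical(predict(fa, sub, corp$parses, type = "prob"),
                   predict(fb, sub, corp$parses, type = "prob"))
})

test_that("checkpoints round-trip the model", {
  corp <- synth_small()
  enc <- tiny_encoder(corp)
  gcfg <- gpnn_config(d1 = 8, L = 4, M = 2)
  ctl <- train_config(epochs = 1, batch_size = 8, max_len = 32, seed = 3)
  sub <- corp$instances[1:10, ]
  fit <- gpnre_fit(sub, corp$parses, corp$scheme, enc, gcfg, ctl)
  f <- withr::local_tempfile(fileext = ".json")
  gpnre_save(fit, f)
  back <- gpnre_load(f)
  expect_equal(back$labels, fit$labels)
  expect_equal(coef(back), coef(fit), tolerance = 1e-12)
  expect_equal(predict(back, sub, corp$parses, type = "prob"),
               predict(fit, sub, corp$parses, type = "prob"),
               tolerance = 1e-12)
})

test_that("the fitted-model methods behave like a classical model object", {
  corp <- synth_small()
  enc <- tiny_encoder(corp)
  gcfg <- gpnn_config(d1 = 8, L = 4, M = 2)
  ctl <- train_config(epochs = 2, batch_size = 8, max_len = 32, seed = 4)
  sub <- corp$instances[1:20, ]
  dev <- corp$instances[21:30, ]
  fit <- gpnre_fit(sub, corp$parses, corp$scheme, enc, gcfg, ctl,
                   dev, corp$parses)
  expect_s3_class(fit, "gpnre")
  expect_output(print(fit), "pointer relation-extraction")
  expect_output(summary(fit), "epoch log")
  expect_type(coef(fit), "list")
  r <- residuals(fit, sub, corp$parses)
  expect_true(all(r >= 0 & r <= 1))
  probs <- predict(fit, sub, corp$parses, type = "prob")
  expect_equal(unname(rowSums(probs)), rep(1, nrow(sub)), tolerance = 1e-9)
  sims <- simulate(fit, nsim = 2, seed = 1, instances = sub,
                   parses = corp$parses)
  expect_equal(dim(sims), c(nrow(sub), 2))
  expect_true(all(unlist(sims) %in% fit$labels))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("training rejects empty corpora and labels outside the scheme", {
  corp <- synth_small()
  enc <- tiny_encoder(corp)
  empty <- corp$instances[0, ]
  expect_error(gpnre_fit(empty, corp$parses, corp$scheme, enc), "empty")
  bad <- corp$instances[1:2, ]
  bad$label <- c("REL:A", "NOPE")
  expect_error(gpnre_fit(bad, corp$parses, corp$scheme, enc,
                         gpnn_config(d1 = 8, L = 4, M = 2),
                         train_config(epochs = 1, max_len = 32)),
               "outside scheme")
})
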