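test_that("NLL loss matches an explicitly normalized PMF oracle", {
  set.seed(30)
  logits <- matrix(rnorm(6 * 4, sd = 2), 6, 4)
  targets <- sample(0:3, 6, replace = TRUE)

  # brute-force oracle: normalize rows explicitly, pick target probabilities
  P <- exp(logits) / rowSums(exp(logits))
  oracle <- -log(P[cbind(1:6, targets + 1)])
  expect_equal(nll_loss(logits, targets), mean(oracle), tolerance = 1e-10)
  expect_equal(nll_loss(logits, targets, "sum"), sum(oracle),
               tolerance = 1e-10)

  # uniform logits: log p per position
  expect_equal(nll_loss(matrix(0, 5, 8), rep(3L, 5)), log(8))

  # one-hot-correct logits with a large margin: loss near zero
  hot <- matrix(-50, 4, 4)
  hot[cbind(1:4, 1:4)] <- 50
  expect_lt(nll_loss(hot, 0:3), 1e-10)

  expect_error(nll_loss(logits, c(0L, 1L)), "length")
  expect_error(nll_loss(logits, rep(9L, 6)), "targets")
})

test_that("per-image NLL from the joint product equals the per-pixel sum", {
  m <- micro_model(seed = 31)
  r <- m$config$r
  set.seed(32)
  x <- sample(0:(m$config$p - 1), r, replace = TRUE)
  out <- model_forward(m, x[-r], n = 2)
  # chain rule: -log prod_i q(x_i | .) computed from the PMF rows
  joint <- -sum(log(out$pmf[cbind(1:r, x + 1)]))
  expect_equal(nll_loss(out$logits, x, "sum"), joint, tolerance = 1e-8)

  # and the C++ training-path evaluation agrees with the R forward pass
  nidx <- match(2, m$config$numerosities) - 1L
  cpp <- numerogen:::cpp_tf_eval_nll(m$params,
                                     numerogen:::cpp_config(m$config),
                                     matrix(x, 1), nidx)
  expect_equal(cpp, joint / r, tolerance = 1e-10)
})

test_that("untrained models start near the maximum-entropy baseline", {
  m <- micro_model(seed = 33)
  b <- withr::with_seed(34, {
    n <- 64
    x <- matrix(sample(0:(m$config$p - 1), n * m$config$r, replace = TRUE),
                n, m$config$r)
    nidx <- sample(0:2, n, replace = TRUE)
    numerogen:::cpp_tf_eval_nll(m$params, numerogen:::cpp_config(m$config),
                                x, nidx)
  })
  expect_lt(abs(b - log(m$config$p)) / log(m$config$p), 0.1)
})

test_that("training is deterministic, inert at zero learning rate, and improves on the baseline", {
  bundle <- micro_bundle()
  spec <- micro_spec()
  model <- init_model(model_config(spec$width, spec$height, spec$levels,
                                   numerosities = 1:2, d = 16, n_heads = 2,
                                   L = 1, ff_width = 32, dropout = 0),
                      seed = 40)

  # zero learning rate: parameters bit-identical, loss flat at baseline
  f0 <- train(model, bundle, train_config(lr = 0, epochs = 2,
                                          batch_size = 32, seed = 41))
  expect_identical(f0$model$params, model$params)

  # same seed twice: identical epoch-1 losses
  fa <- train(model, bundle, train_config(epochs = 1, batch_size = 32,
                                          seed = 42))
  fb <- train(model, bundle, train_config(epochs = 1, batch_size = 32,
                                          seed = 42))
  expect_identical(fa$record$train_nll_px, fb$record$train_nll_px)

  # one epoch strictly beats the untrained log(p) baseline
  expect_lt(fa$record$val_nll_px[1], log(spec$levels))

  # labels outside the model's numerosity set are rejected
  bad <- bundle
  bad$train$n[1] <- 9L
  expect_error(train(model, bad, train_config(epochs = 1, seed = 1)),
               "numerosity set")
})

test_that("more training data does not hurt validation NLL", {
  bundle <- micro_bundle()
  spec <- micro_spec()
  model <- init_model(model_config(spec$width, spec$height, spec$levels,
                                   numerosities = 1:2, d = 16, n_heads = 2,
                                   L = 1, ff_width = 32, dropout = 0),
                      seed = 50)

  expect_equal(nrow(loss_vs_train_size(model, bundle, integer(0))), 0L)

  wins <- 0L
  for (rep in 1:5) {
    tab <- loss_vs_train_size(model, bundle, c(40, 200),
                              train_config(epochs = 2, batch_size = 20,
                                           lr = 1e-3, seed = 50 + rep))
    expect_equal(tab$train_size, c(40, 200))
    if (tab$best_val_nll_px[2] <= tab$best_val_nll_px[1]) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})
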