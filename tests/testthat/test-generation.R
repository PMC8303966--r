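test_that("seed algebra: trained rows are copied, midpoints and attribute vectors are exact", {
  m <- micro_model(seed = 60)

  s1 <- sos_trained(m, 1)
  expect_equal(as.numeric(s1), m$params$Ws[1, ])
  # copy contract: mutating the returned seed leaves Ws untouched
  before <- m$params$Ws[1, 1]
  s1[1] <- s1[1] + 100
  expect_identical(m$params$Ws[1, 1], before)
  expect_error(sos_trained(m, 7), "not in the trained set")

  # interpolation: exact midpoint, idempotent on equal neighbors
  m2 <- micro_model(seed = 61, numerosities = c(1, 3))
  si <- sos_interpolated(m2, 2)
  expect_equal(as.numeric(si),
               (m2$params$Ws[1, ] + m2$params$Ws[2, ]) / 2)
  expect_equal(si - m2$params$Ws[1, ], m2$params$Ws[2, ] - si,
               ignore_attr = TRUE)
  m2$params$Ws[2, ] <- m2$params$Ws[1, ]
  expect_equal(as.numeric(sos_interpolated(m2, 2)), m2$params$Ws[1, ])
  expect_error(sos_interpolated(micro_model(seed = 62), 5), "neighbors")
  expect_warning(sos_interpolated(micro_model(seed = 63), 2),
                 "trained set")

  mm <- micro_model(seed = 64)
  w1 <- matrix(0, 1, mm$config$d)
  w3 <- matrix(2, 1, mm$config$d)
  mm$params$Ws <- rbind(w1, w3)
  mm$config$numerosities <- c(1L, 3L)
  mm$config$n_numerosities <- 2L
  expect_equal(as.numeric(sos_interpolated(mm, 2)), rep(1, mm$config$d))

  # extrapolation: alpha = 0 is the top seed; alpha = 0.5 is the midpoint
  # of the top seed and the alpha = 1 seed (collinearity)
  m3 <- micro_model(seed = 65)
  e0 <- sos_extrapolated(m3, 0)
  e1 <- sos_extrapolated(m3, 1)
  eh <- sos_extrapolated(m3, 0.5)
  wmax <- m3$params$Ws[3, ]
  w2nd <- m3$params$Ws[2, ]
  expect_equal(as.numeric(e0), wmax)
  expect_equal(as.numeric(e1), 2 * wmax - w2nd)
  expect_equal(as.numeric(eh), (as.numeric(e0) + as.numeric(e1)) / 2)
  m1only <- micro_model(seed = 66, numerosities = 1)
  expect_error(sos_extrapolated(m1only, 1), "at least two")
})

test_that("PCA-reduced seeds reconstruct exactly at full rank and nest with k", {
  m <- micro_model(seed = 67, numerosities = 1:5)
  full_k <- length(m$config$numerosities) - 1L
  for (n in m$config$numerosities) {
    sr <- sos_pca_reduced(m, full_k, n)
    expect_equal(as.numeric(sr), m$params$Ws[n, ], tolerance = 1e-8)
  }
  # reconstruction error is non-increasing in k
  errs <- vapply(seq_len(full_k), function(k) {
    sum((as.numeric(sos_pca_reduced(m, k, 3)) - m$params$Ws[3, ])^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-10))

  # k = 1 reconstructions are collinear about the mean
  rec <- t(vapply(m$config$numerosities, function(n)
    as.numeric(sos_pca_reduced(m, 1, n)), numeric(m$config$d)))
  centered <- sweep(rec, 2, colMeans(m$params$Ws))
  expect_equal(qr(centered)$rank, 1L)

  expect_error(sos_pca_reduced(m, 0, 1), "k must be")
  expect_error(sos_pca_reduced(m, 5, 1), "k must be")
})

test_that("teacher-forced generation reaches ceiling agreement for deterministic PMFs and chance for uniform ones", {
  m <- micro_model(seed = 68)
  r <- m$config$r
  set.seed(69)
  x <- matrix(sample(0:(m$config$p - 1), r, replace = TRUE),
              nrow = m$config$height, byrow = TRUE)

  # uniform-PMF model: agreement has expectation 1/p
  mu <- m
  mu$params$head_W[] <- 0
  mu$params$head_b[] <- 0
  agree <- mean(replicate(30, {
    xx <- matrix(sample(0:(m$config$p - 1), r, replace = TRUE),
                 nrow = m$config$height, byrow = TRUE)
    conditional_generate(mu, xx, 2)$agreement
  }))
  expect_lt(abs(agree - 1 / m$config$p), 0.1)

  # a head biased hard toward intensity 0 reconstructs an all-zero image
  mh <- m
  mh$params$head_W[] <- 0
  mh$params$head_b <- c(1000, rep(-1000, m$config$p - 1))
  zero_img <- matrix(0L, m$config$height, m$config$width)
  out <- conditional_generate(mh, zero_img, 1)
  expect_equal(out$agreement, 1.0)
  expect_true(all(out$image == 0))

  expect_error(conditional_generate(m, x, 99), "not in the trained set")
})

test_that("spontaneous generation is reproducible and the KV cache matches full recomputation", {
  m <- micro_model(seed = 70)

  b1 <- spontaneous_generate(m, sos_trained(m, 2), count = 5, seed = 71)
  b2 <- spontaneous_generate(m, sos_trained(m, 2), count = 5, seed = 71)
  expect_identical(b1$x, b2$x)
  expect_equal(b1$count, 5)
  expect_true(all(b1$x >= 0 & b1$x < m$config$p))

  # default batch size is 64 images per seed
  expect_equal(spontaneous_generate(m, sos_trained(m, 1), seed = 1)$count,
               64)

  # incremental sampling equals full-prefix recomputation, same RNG stream
  br <- spontaneous_generate(m, sos_trained(m, 2), count = 3, seed = 72,
                             method = "recompute")
  bc <- spontaneous_generate(m, sos_trained(m, 2), count = 3, seed = 72,
                             method = "cached")
  expect_identical(br$x, bc$x)

  expect_error(spontaneous_generate(m, rep(0, 3)), "expected d")
})

test_that("checkpoints round-trip exactly", {
  m <- micro_model(seed = 73)
  path <- tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(m2$config, m$config)
  expect_equal(m2$params, m$params, tolerance = 0)
  a <- spontaneous_generate(m, sos_trained(m, 1), count = 3, seed = 74)
  b <- spontaneous_generate(m2, sos_trained(m2, 1), count = 3, seed = 74)
  expect_identical(a$x, b$x)
  unlink(path)
})
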