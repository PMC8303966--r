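test_that("sequence embedding composes seed, intensity and position tables", {
  m <- micro_model(seed = 11)
  d <- m$config$d

  # empty prefix: single row s + first positional encoding
  H0 <- embed_sequence(m, integer(0), n = 2)
  expect_equal(dim(H0), c(1L, d))
  expect_equal(H0[1, ], m$params$Ws[2, ] + m$params$WE[1, ])

  # additivity: zero seed + zero intensity table leaves the positional rows
  m0 <- m
  m0$params$Wx[] <- 0
  H0z <- embed_sequence(m0, c(0L, 1L, 2L), sos = rep(0, d))
  expect_equal(H0z, m0$params$WE[1:4, ], ignore_attr = TRUE)

  # swapping two prefix pixels changes exactly those two rows
  a <- embed_sequence(m, c(0L, 1L, 2L, 3L), n = 1)
  b <- embed_sequence(m, c(0L, 2L, 1L, 3L), n = 1)
  changed <- which(rowSums(abs(a - b)) > 0)
  expect_equal(changed, c(3L, 4L))

  expect_error(embed_sequence(m, rep(0L, m$config$r), n = 1), "exceeds")
  expect_error(embed_sequence(m, c(0L, 99L), n = 1), "intensities")
  expect_error(embed_sequence(m, integer(0)), "exactly one")
})

test_that("causal mask is lower-triangular permission reused across layers", {
  expect_identical(causal_mask(1), matrix(TRUE, 1, 1))
  m3 <- causal_mask(3)
  expect_equal(sum(m3), 6L)            # pairs with query >= key
  expect_true(all(m3[lower.tri(m3, diag = TRUE)]))
  expect_false(any(m3[upper.tri(m3)]))
})

test_that("encoder output at position i never depends on later pixels", {
  m <- micro_model(seed = 12)
  r <- m$config$r
  p <- m$config$p
  set.seed(13)
  x <- sample(0:(p - 1), r - 1, replace = TRUE)
  base <- model_forward(m, x, n = 2)$pmf
  for (j in seq_len(r - 1)) {
    x2 <- x
    x2[j] <- (x2[j] + 1L) %% p
    pert <- model_forward(m, x2, n = 2)$pmf
    # PMF rows 1..j condition only on pixels before j
    expect_lt(max(abs(pert[1:j, ] - base[1:j, ])), 1e-10)
    expect_gt(max(abs(pert[j + 1, ] - base[j + 1, ])), 0)
  }
})

test_that("incremental and teacher-forced passes agree on shared positions", {
  m <- micro_model(seed = 14)
  set.seed(15)
  x <- sample(0:(m$config$p - 1), m$config$r - 1, replace = TRUE)
  full <- model_forward(m, x, n = 1)$pmf
  for (k in 0:(length(x) - 1)) {
    part <- model_forward(m, head(x, k), n = 1)$pmf
    expect_lt(max(abs(part[k + 1, ] - full[k + 1, ])), 1e-9)
  }
})

test_that("unmasked self-attention is permutation-equivariant (order enters only via mask and positions)", {
  m <- micro_model(seed = 16)
  q <- 6
  set.seed(17)
  H0 <- matrix(rnorm(q * m$config$d), q, m$config$d)
  full <- matrix(TRUE, q, q)
  HL <- encoder_forward(m, H0, mask = full)
  perm <- sample(q)
  HLp <- encoder_forward(m, H0[perm, ], mask = full)
  expect_equal(HLp, HL[perm, ], tolerance = 1e-10)
})

test_that("encoder respects the empty-stack and shape contracts", {
  m0 <- micro_model(seed = 18, L = 0)
  H0 <- embed_sequence(m0, c(0L, 1L), n = 1)
  expect_identical(encoder_forward(m0, H0), H0)

  m <- micro_model(seed = 19)
  expect_error(encoder_forward(m, matrix(0, 3, m$config$d + 1)), "columns")
  expect_error(encoder_forward(m, matrix(0, 3, m$config$d),
                               mask = matrix(TRUE, 2, 2)), "mask")
})

test_that("output head produces row-stochastic PMFs consistent with its logits", {
  for (seed in 20:23) {
    m <- micro_model(seed = seed)
    set.seed(seed)
    x <- sample(0:(m$config$p - 1), 7, replace = TRUE)
    out <- model_forward(m, x, n = 3)
    expect_true(all(out$pmf >= 0))
    expect_equal(rowSums(out$pmf), rep(1, nrow(out$pmf)), tolerance = 1e-6)
    expect_equal(max.col(out$pmf), max.col(out$logits))
  }

  # zero head weights: exactly uniform over the p intensities
  m <- micro_model(seed = 24)
  m$params$head_W[] <- 0
  m$params$head_b[] <- 0
  out <- model_forward(m, c(0L, 1L), n = 1)
  expect_equal(out$pmf, matrix(1 / m$config$p, 3, m$config$p),
               ignore_attr = TRUE)
})
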