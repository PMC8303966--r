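test_that("per-dot areas follow the truncated normal with constant expected total", {
  par <- dot_params()

  # zero-variance case: areas are exactly mu_frame / n
  set.seed(1)
  expect_equal(sample_dot_areas(3, dot_params(sigma_dot = 0)), rep(50, 3))

  # n = 1: mean ~ 150, SD ~ 8 (truncation negligible at this mean)
  set.seed(2)
  a1 <- replicate(10000, sample_dot_areas(1, par))
  expect_lt(abs(mean(a1) - 150), 2 * 8 / sqrt(10000))
  expect_lt(abs(sd(a1) - 8), 3 * 8 / sqrt(2 * 10000))

  # n = 8: per-frame totals match the truncated-normal oracle within 2 SE
  mom <- truncnorm_moments(150 / 8, 8)
  set.seed(3)
  tot <- replicate(5000, sum(sample_dot_areas(8, par)))
  se <- mom$sd * sqrt(8) / sqrt(5000)
  expect_lt(abs(mean(tot) - 8 * mom$mean), 2 * se)

  # edge cases
  expect_identical(sample_dot_areas(0, par), numeric(0))
  expect_error(sample_dot_areas(-1, par), "non-negative")
  expect_true(all(replicate(50, sample_dot_areas(8, par)) >= pi))
})

test_that("placement respects frame bounds and the non-overlap policy", {
  spec <- frame_spec()
  par <- dot_params()
  set.seed(4)
  c1 <- place_items(1, 2, spec, par)
  expect_true(all(c1 >= par$margin + 2) &&
                all(c1 <= spec$width - 1 - par$margin - 2))

  # n = 8 uniform dots: all 28 pairwise distances >= radius sum + separation
  for (rep in 1:5) {
    cc <- place_items(8, rep(2, 8), spec, par)
    d <- as.matrix(dist(cc))
    expect_true(all(d[upper.tri(d)] >= 4 + par$separation))
  }

  expect_error(place_items(50, rep(10, 50), spec, par), "does not fit|packing")
  expect_error(place_items(6, rep(6.2, 6), spec, par), "packing failure")
})

test_that("uniform dots render with label = component count and area strictly proportional to n", {
  spec <- frame_spec()
  par <- dot_params()
  expect_true(all(render_uniform_dots(0, spec, par)$pixels == spec$background))

  set.seed(6)
  for (n in 1:8) {
    im <- render_uniform_dots(n, spec, par)
    expect_identical(im$n, as.integer(n))
    mask <- binarize_frame(im, spec)
    expect_equal(component_count(mask), n)
    # integer-lattice centers make every dot rasterize to exactly 13 px
    expect_equal(sum(mask), 13 * n)
  }
})

test_that("non-uniform dots record sampled areas and keep expected cumulative area constant", {
  spec <- frame_spec()
  par <- dot_params()

  set.seed(7)
  im <- withr::with_seed(8, render_nonuniform_dots(2, spec,
                                                   dot_params(sigma_dot = 0)))
  expect_equal(im$areas, rep(75, 2))

  set.seed(9)
  for (n in c(1, 4, 8)) {
    mom <- truncnorm_moments(150 / n, 8)
    tot <- replicate(1000, sum(render_nonuniform_dots(n, spec, par)$areas))
    se <- mom$sd * sqrt(n) / sqrt(1000)
    expect_lt(abs(mean(tot) - n * mom$mean), 3 * se)
    im <- render_nonuniform_dots(n, spec, par)
    expect_equal(component_count(binarize_frame(im, spec)), n)
  }
})

test_that("smoothed squares stay countable and populate intermediate gray levels", {
  spec <- frame_spec()
  par <- dot_params()
  expect_true(all(render_smoothed_squares(0, spec, par)$pixels ==
                    spec$background))
  set.seed(10)
  for (n in c(1, 3)) {
    im <- render_smoothed_squares(n, spec, par)
    expect_equal(component_count(binarize_frame(im, spec)), n)
    expect_gt(length(unique(as.vector(im$pixels))), 2)
    expect_true(all(im$pixels >= 0 & im$pixels <= spec$levels - 1))
  }
  # smoothing dilates each item by one pixel, so on dense frames nearby
  # items can merge at the mid threshold; thresholding above the dilation
  # ring (one foreground neighbor -> (1/9)^0.25 of full scale) recovers the
  # original squares and the exact count
  ring <- (1 / 9)^0.25 * (spec$levels - 1)
  for (n in c(6, 8)) {
    im <- render_smoothed_squares(n, spec, par)
    expect_equal(component_count(im$pixels > ring + 1), n)
  }
})

test_that("dataset builder allocates labels uniformly and is a pure function of the seed", {
  spec <- tiny_spec()
  par <- tiny_params()
  b <- build_dataset("uniform", 1:3, c(60, 30, 30), seed = 5, spec = spec,
                     params = par)
  expect_equal(dim(b$train$x), c(60, spec$r))
  expect_equal(unname(table(b$train$n)), rep(20L, 3), ignore_attr = TRUE)
  expect_equal(unname(table(b$validation$n)), rep(10L, 3),
               ignore_attr = TRUE)

  b2 <- build_dataset("uniform", 1:3, c(60, 30, 30), seed = 5, spec = spec,
                      params = par)
  expect_identical(b$train$x, b2$train$x)
  expect_identical(b$test$x, b2$test$x)

  b3 <- build_dataset("uniform", 1:3, c(60, 30, 30), seed = 6, spec = spec,
                      params = par)
  expect_false(identical(b$train$x, b3$train$x))

  expect_error(build_dataset("voronoi", 1:3, c(10, 5, 5), seed = 1,
                             spec = spec, params = par))

  bm <- build_dataset("mixed", 1:3, c(12, 6, 6), seed = 2, spec = spec,
                      params = par)
  expect_equal(bm$train$family,
               rep(c("squares", "uniform"), length.out = 12))
})
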