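#' Frame geometry and intensity quantization
#'
#' Describes the raster canvas on which stimuli are rendered: its size in
#' pixels and the categorical intensity support. Pixels take integer values in
#' `0 .. levels - 1`; dot stimuli are rendered binary (background/foreground),
#' while smoothed squares populate intermediate levels.
#'
#' @param width,height Frame size in pixels.
#' @param levels Number of categorical gray levels `p` (at least 2). The
#'   default 256 corresponds to standard 8-bit grayscale.
#' @param background,foreground Intensity indices used for empty canvas and
#'   rendered items. Must differ and lie in `[0, levels - 1]`.
#' @return An object of class `frame_spec`.
#' @examples
#' frame_spec()                 # 32 x 32, 8-bit
#' frame_spec(12, 12, levels = 2)  # binary frames for quick experiments
#' @export
frame_spec <- function(width = 32, height = 32, levels = 256,
                       background = 0, foreground = levels - 1) {
  stopifnot(is_count(width), width > 0, is_count(height), height > 0,
            is_count(levels), levels >= 2)
  if (background == foreground)
    stop("background and foreground intensities must differ")
  if (background < 0 || background >= levels || foreground < 0 ||
      foreground >= levels)
    stop("background/foreground must lie in [0, levels - 1]")
  structure(list(width = as.integer(width), height = as.integer(height),
                 levels = as.integer(levels),
                 background = as.integer(background),
                 foreground = as.integer(foreground),
                 r = as.integer(width * height)),
            class = "frame_spec")
}

#' Dot magnitude parameters
#'
#' Parameters controlling item sizes and placement. For the non-uniform
#' family, per-dot areas are drawn from Normal(`mu_frame / n`, `sigma_dot`^2)
#' so that the expected cumulative area per frame equals `mu_frame` at every
#' numerosity; draws are truncated below at `pi` square pixels (a dot must
#' cover at least a 1-pixel-radius disk to be visible).
#'
#' Centers are placed by rejection sampling on the integer pixel lattice, and
#' two items are accepted only if their center distance is at least the sum of
#' their radii plus `separation`. A separation above `sqrt(2)` guarantees that
#' rasterized items are never 8-adjacent, so the numerosity label always
#' equals the connected-component count of the binarized frame.
#'
#' @param mu_frame Expected cumulative dot area per frame, square pixels.
#' @param sigma_dot Per-dot area standard deviation, square pixels.
#' @param uniform_radius Dot radius in pixels for the uniform-dot family.
#' @param margin Minimum distance (pixels) between any item and the border.
#' @param separation Extra center-distance gap (pixels) beyond radius sum.
#' @param max_retries Rejection-sampling budget per item before a packing
#'   failure is raised.
#' @return An object of class `dot_params`.
#' @export
dot_params <- function(mu_frame = 150, sigma_dot = 8, uniform_radius = 2,
                       margin = 1, separation = 1.5, max_retries = 10000) {
  stopifnot(mu_frame > 0, sigma_dot >= 0, uniform_radius >= 1, margin >= 0,
            separation >= 0, max_retries >= 1)
  structure(list(mu_frame = mu_frame, sigma_dot = sigma_dot,
                 uniform_radius = uniform_radius, margin = margin,
                 separation = separation,
                 max_retries = as.integer(max_retries)),
            class = "dot_params")
}

#' Sample per-dot areas with constant expected cumulative area
#'
#' Draws `n` individual dot areas from Normal(`mu_frame / n`, `sigma_dot`^2),
#' truncated below at `pi` square pixels, so the expected per-frame total is
#' `mu_frame` regardless of `n`.
#'
#' @param n Numerosity (number of dots). `n = 0` returns an empty vector
#'   (blank frames used by the classifier-counter dataset).
#' @param params A [dot_params()] object.
#' @return Numeric vector of `n` areas in square pixels.
#' @examples
#' set.seed(1)
#' mean(replicate(1000, sum(sample_dot_areas(4, dot_params()))))  # ~150
#' @export
sample_dot_areas <- function(n, params = dot_params()) {
  stopifnot(inherits(params, "dot_params"))
  if (!is_count(n) || n < 0) stop("n must be a non-negative integer")
  if (n == 0) return(numeric(0))
  mu <- params$mu_frame / n
  a <- rnorm(n, mean = mu, sd = params$sigma_dot)
  bad <- which(a < pi)
  while (length(bad) > 0) {
    a[bad] <- rnorm(length(bad), mean = mu, sd = params$sigma_dot)
    bad <- which(a < pi)
  }
  a
}

#' Place item centers on the pixel lattice without overlap
#'
#' Sequential rejection sampling: each center is drawn uniformly over the
#' integer lattice positions at which the item (radius + margin) fits the
#' frame, and is accepted when its distance to every already placed center is
#' at least the sum of the two radii plus the configured separation.
#'
#' @param n Number of items; must equal `length(radii)`.
#' @param radii Item radii in pixels.
#' @param spec A [frame_spec()].
#' @param params A [dot_params()] (margin, separation, retry budget).
#' @return An `n x 2` matrix of 0-based `(x, y)` centers.
#' @export
place_items <- function(n, radii, spec = frame_spec(), params = dot_params()) {
  stopifnot(inherits(spec, "frame_spec"), inherits(params, "dot_params"))
  if (!is_count(n) || n < 0) stop("n must be a non-negative integer")
  if (length(radii) != n) stop("length(radii) must equal n")
  if (n == 0) return(matrix(numeric(0), 0, 2))
  lo <- ceiling(params$margin + radii)
  hi_x <- floor(spec$width - 1 - params$margin - radii)
  hi_y <- floor(spec$height - 1 - params$margin - radii)
  bad <- which(lo > hi_x | lo > hi_y)
  if (length(bad) > 0)
    stop(sprintf("item %d with radius %.2f does not fit a %dx%d frame",
                 bad[1], radii[bad[1]], spec$width, spec$height))
  # A greedy sequence can paint itself into a corner (an early central item
  # may leave no legal position for later ones), so the whole configuration
  # is restarted when an item exhausts its per-item budget; the total draw
  # budget stays bounded by max_retries.
  per_item <- min(200L, params$max_retries)
  draws_left <- params$max_retries
  while (draws_left > 0) {
    centers <- matrix(NA_real_, n, 2)
    ok_all <- TRUE
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(min(per_item, draws_left))) {
        cx <- lo[i] + sample.int(hi_x[i] - lo[i] + 1, 1) - 1
        cy <- lo[i] + sample.int(hi_y[i] - lo[i] + 1, 1) - 1
        ok <- if (i == 1) TRUE else {
          d <- sqrt((centers[seq_len(i - 1), 1] - cx)^2 +
                      (centers[seq_len(i - 1), 2] - cy)^2)
          all(d >= radii[seq_len(i - 1)] + radii[i] + params$separation)
        }
        if (ok) {
          centers[i, ] <- c(cx, cy)
          placed <- TRUE
          break
        }
      }
      draws_left <- draws_left - try
      if (!placed) { ok_all <- FALSE; break }
    }
    if (ok_all) return(centers)
  }
  stop(sprintf(
    "packing failure: could not place %d items (radii: %s) within %d draws",
    n, paste(sprintf("%.2f", radii), collapse = ", "), params$max_retries))
}

# Rasterize disks onto a background canvas: pixel (x, y) belongs to item i
# when its center distance is <= radii[i].
rasterize_disks <- function(centers, radii, spec) {
  px <- matrix(spec$background, nrow = spec$height, ncol = spec$width)
  if (nrow(centers) == 0) return(px)
  xs <- matrix(rep(0:(spec$width - 1), each = spec$height),
               nrow = spec$height)
  ys <- matrix(rep(0:(spec$height - 1), times = spec$width),
               nrow = spec$height)
  for (i in seq_len(nrow(centers))) {
    inside <- (xs - centers[i, 1])^2 + (ys - centers[i, 2])^2 <= radii[i]^2
    px[inside] <- spec$foreground
  }
  px
}

new_stimulus_image <- function(pixels, n, family, centers, radii,
                               areas = NULL) {
  structure(list(pixels = pixels, n = as.integer(n), family = family,
                 centers = centers, radii = radii, areas = areas),
            class = "stimulus_image")
}

#' @export
print.stimulus_image <- function(x, ...) {
  cat(sprintf("<stimulus_image> %dx%d, family %s, n = %d\n",
              nrow(x$pixels), ncol(x$pixels), x$family, x$n))
  invisible(x)
}

#' Render a frame of identical-radius dots
#'
#' All items share `params$uniform_radius`, so cumulative foreground area is
#' exactly proportional to numerosity (perfect area-number correlation).
#'
#' @inheritParams place_items
#' @param n Numerosity label; `n = 0` yields an all-background frame.
#' @return A `stimulus_image`: the `height x width` integer pixel matrix plus
#'   the label and render metadata (centers, radii).
#' @export
render_uniform_dots <- function(n, spec = frame_spec(),
                                params = dot_params()) {
  radii <- rep(params$uniform_radius, n)
  centers <- place_items(n, radii, spec, params)
  new_stimulus_image(rasterize_disks(centers, radii, spec), n,
                     "uniform_dots", centers, radii)
}

#' Render a frame of variable-size dots with constant expected total area
#'
#' Per-dot areas come from [sample_dot_areas()]; radii are `sqrt(area / pi)`.
#' Items are placed largest-first, which makes tight packings feasible. The
#' sampled areas are recorded in the returned object (`$areas`) so that
#' cumulative-area statistics can be computed without rasterization bias.
#'
#' @inheritParams render_uniform_dots
#' @return A `stimulus_image` with the sampled per-dot areas attached.
#' @export
render_nonuniform_dots <- function(n, spec = frame_spec(),
                                   params = dot_params()) {
  areas <- sample_dot_areas(n, params)
  ord <- order(areas, decreasing = TRUE)
  areas <- areas[ord]
  radii <- sqrt(areas / pi)
  centers <- place_items(n, radii, spec, params)
  new_stimulus_image(rasterize_disks(centers, radii, spec), n,
                     "nonuniform_dots", centers, radii, areas = areas)
}

# 3x3 mean filter with zero (background) padding, on a numeric matrix.
mean_filter3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(0, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  out <- matrix(0, h, w)
  for (dy in 0:2) for (dx in 0:2)
    out <- out + pad[dy + 1:h, dx + 1:w]
  out / 9
}

#' Render smoothed squares
#'
#' Squares are inscribed in the circles the uniform-dot renderer would draw
#' (half-side `radius / sqrt(2)`), then the frame is passed through a 3x3
#' average filter and the gamma map `x^0.25` on normalized `[0, 1]`
#' intensities, and finally re-quantized to the frame's `levels` gray levels.
#' Because `x^0.25 >= x` on `[0, 1]`, smoothing+gamma never darkens a pixel.
#'
#' @inheritParams render_uniform_dots
#' @return A `stimulus_image` with graded intensity values.
#' @export
render_smoothed_squares <- function(n, spec = frame_spec(),
                                    params = dot_params()) {
  radii <- rep(params$uniform_radius, n)
  centers <- place_items(n, radii, spec, params)
  px <- matrix(0, nrow = spec$height, ncol = spec$width)
  if (n > 0) {
    xs <- matrix(rep(0:(spec$width - 1), each = spec$height),
                 nrow = spec$height)
    ys <- matrix(rep(0:(spec$height - 1), times = spec$width),
                 nrow = spec$height)
    half <- params$uniform_radius / sqrt(2)
    for (i in seq_len(n)) {
      inside <- abs(xs - centers[i, 1]) <= half &
        abs(ys - centers[i, 2]) <= half
      px[inside] <- 1
    }
  }
  sm <- mean_filter3(px)^0.25
  quant <- matrix(as.integer(round(sm * (spec$levels - 1))),
                  nrow = spec$height)
  new_stimulus_image(quant, n, "smoothed_squares", centers, radii)
}

# Row-major (raster-order) flattening: left-to-right, top-to-bottom. This
# fixed order is the autoregression order everywhere downstream.
#' Flatten / restore a frame in raster order
#'
#' @param m A `height x width` pixel matrix (or a `stimulus_image`).
#' @return `flatten_frame`: integer vector of length `width * height`.
#' @export
flatten_frame <- function(m) {
  if (inherits(m, "stimulus_image")) m <- m$pixels
  as.integer(t(m))
}

#' @rdname flatten_frame
#' @param v Flat raster-order vector.
#' @param spec A [frame_spec()] giving the frame size.
#' @export
unflatten_frame <- function(v, spec) {
  matrix(as.integer(v), nrow = spec$height, ncol = spec$width, byrow = TRUE)
}

# Foreground mask at the mid-intensity threshold.
binarize_frame <- function(m, spec) {
  if (inherits(m, "stimulus_image")) m <- m$pixels
  m > (spec$levels - 1) / 2
}

render_one <- function(family, n, spec, params) {
  switch(family,
         uniform = render_uniform_dots(n, spec, params),
         nonuniform = render_nonuniform_dots(n, spec, params),
         squares = render_smoothed_squares(n, spec, params),
         stop(sprintf("unknown stimulus family '%s'", family)))
}

# Uniform label allocation: equal shares plus deterministic remainder.
allocate_labels <- function(numerosities, size) {
  k <- length(numerosities)
  base <- size %/% k
  rem <- size %% k
  labels <- rep(numerosities, times = base + c(rep(1, rem), rep(0, k - rem)))
  labels[sample.int(length(labels))]
}

#' Build reproducible train/validation/test stimulus splits
#'
#' Generates three disjoint splits of stimulus frames with labels uniformly
#' distributed over `numerosities`. The whole bundle is a pure function of its
#' arguments and `seed`. The `"mixed"` family interleaves smoothed squares and
#' uniform dots image-by-image.
#'
#' @param family One of `"uniform"`, `"nonuniform"`, `"squares"`, `"mixed"`.
#' @param numerosities Set of numerosity labels (default `1:8`).
#' @param sizes Split sizes `c(train, validation, test)`; defaults
#'   `c(16000, 3200, 3200)`.
#' @param seed Master seed; same seed implies bit-identical pixel arrays.
#' @param spec A [frame_spec()].
#' @param params A [dot_params()].
#' @return A `dataset_bundle`: `train`, `validation`, `test` splits (each a
#'   list with flat pixel matrix `x` (one raster-order row per image), label
#'   vector `n`, per-image `family`, and for the non-uniform family the
#'   sampled per-dot `areas`), plus a generation `manifest`.
#' @export
build_dataset <- function(family = c("uniform", "nonuniform", "squares",
                                     "mixed"),
                          numerosities = 1:8,
                          sizes = c(16000, 3200, 3200),
                          seed = 1,
                          spec = frame_spec(),
                          params = dot_params()) {
  family <- match.arg(family)
  stopifnot(length(numerosities) >= 1, all(numerosities >= 0),
            length(sizes) == 3, all(sizes >= 1))
  numerosities <- sort(unique(as.integer(numerosities)))
  sizes <- as.integer(sizes)
  make_split <- function(size) {
    labels <- allocate_labels(numerosities, size)
    fams <- if (family == "mixed") {
      rep(c("squares", "uniform"), length.out = size)
    } else rep(family, size)
    x <- matrix(0L, nrow = size, ncol = spec$r)
    areas <- if (family == "nonuniform") vector("list", size) else NULL
    for (i in seq_len(size)) {
      im <- render_one(fams[i], labels[i], spec, params)
      x[i, ] <- flatten_frame(im)
      if (!is.null(areas)) areas[[i]] <- im$areas
    }
    list(x = x, n = labels, family = fams, areas = areas)
  }
  bundle <- withr::with_seed(as.integer(seed), list(
    train = make_split(sizes[1]),
    validation = make_split(sizes[2]),
    test = make_split(sizes[3])))
  bundle$spec <- spec
  bundle$params <- params
  bundle$family <- family
  bundle$numerosities <- numerosities
  bundle$sizes <- sizes
  bundle$seed <- as.integer(seed)
  bundle$manifest <- list(family = family, numerosities = numerosities,
                          sizes = sizes, seed = as.integer(seed),
                          width = spec$width, height = spec$height,
                          levels = spec$levels,
                          mu_frame = params$mu_frame,
                          sigma_dot = params$sigma_dot,
                          uniform_radius = params$uniform_radius,
                          margin = params$margin,
                          separation = params$separation)
  class(bundle) <- "dataset_bundle"
  bundle
}

#' @export
print.dataset_bundle <- function(x, ...) {
  cat(sprintf(
    "<dataset_bundle> family %s, N = {%s}, splits %s, %dx%d px, seed %d\n",
    x$family, paste(x$numerosities, collapse = ","),
    paste(x$sizes, collapse = "/"), x$spec$width, x$spec$height, x$seed))
  invisible(x)
}
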