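new_sos_vector <- function(values, mode, n = NA, alpha = NA, k = NA) {
  structure(as.numeric(values), class = "sos_vector",
            provenance = list(mode = mode, n = n, alpha = alpha, k = k))
}

#' @export
print.sos_vector <- function(x, ...) {
  pv <- attr(x, "provenance")
  extras <- c(if (!is.na(pv$n)) sprintf("n = %s", pv$n),
              if (!is.na(pv$alpha)) sprintf("alpha = %s", pv$alpha),
              if (!is.na(pv$k)) sprintf("k = %s", pv$k))
  cat(sprintf("<sos_vector> %s%s, d = %d\n", pv$mode,
              if (length(extras)) paste0(" (", paste(extras, collapse = ", "),
                                         ")") else "",
              length(x)))
  invisible(x)
}

#' Conditioning seeds for generation
#'
#' The four ways of constructing the d-dimensional seed that starts the
#' generative process:
#' \describe{
#'   \item{`sos_trained`}{the learned seed of a trained numerosity: a copy of
#'     the corresponding row of `Ws`.}
#'   \item{`sos_interpolated`}{the midpoint `(w_{n-1} + w_{n+1}) / 2` of the
#'     two closest trained seeds, probing numerosities inside the training
#'     interval that were never seen.}
#'   \item{`sos_extrapolated`}{`w_max + alpha * (w_max - w_second)`: the
#'     attribute-vector direction along which the largest numerosities grow,
#'     probing numerosities beyond the training range.}
#'   \item{`sos_pca_reduced`}{the trained seed of `n` reconstructed from its
#'     first `k` principal-component scores (components fitted on the rows of
#'     `Ws`, centered), probing whether a 1- or 2-dimensional "number line"
#'     subspace suffices to drive generation.}
#' }
#'
#' @param model A trained `ng_model` (or an `ng_fit`'s `$model`).
#' @param n Target numerosity.
#' @return An object of class `sos_vector` (a numeric d-vector with a
#'   provenance attribute).
#' @export
sos_trained <- function(model, n) {
  stopifnot(inherits(model, "ng_model"))
  v <- model$params$Ws[ws_row(model, n), ]
  new_sos_vector(v, "trained", n = n)
}

#' @rdname sos_trained
#' @export
sos_interpolated <- function(model, n) {
  stopifnot(inherits(model, "ng_model"))
  N <- model$config$numerosities
  if (n %in% N)
    warning(sprintf("numerosity %d is in the trained set; interpolating anyway",
                    n))
  if (!((n - 1) %in% N) || !((n + 1) %in% N))
    stop(sprintf(
      "interpolation for n = %d needs trained neighbors %d and %d (trained: {%s})",
      n, n - 1, n + 1, paste(N, collapse = ",")))
  v <- (model$params$Ws[ws_row(model, n - 1), ] +
          model$params$Ws[ws_row(model, n + 1), ]) / 2
  new_sos_vector(v, "interpolated", n = n)
}

#' @rdname sos_trained
#' @param alpha Step size along the attribute vector (`alpha = 0` returns the
#'   largest trained seed itself).
#' @export
sos_extrapolated <- function(model, alpha) {
  stopifnot(inherits(model, "ng_model"), is.numeric(alpha),
            length(alpha) == 1)
  N <- model$config$numerosities
  if (length(N) < 2)
    stop("extrapolation needs at least two trained numerosities")
  w_max <- model$params$Ws[ws_row(model, max(N)), ]
  w_2nd <- model$params$Ws[ws_row(model, sort(N, decreasing = TRUE)[2]), ]
  v <- w_max + alpha * (w_max - w_2nd)
  new_sos_vector(v, "extrapolated", alpha = alpha)
}

# Centered PCA of the numerosity-seed rows with a reproducible sign
# convention: each component's largest-magnitude loading is made positive.
ws_pca <- function(Ws) {
  pc <- prcomp(Ws, center = TRUE, scale. = FALSE)
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  pc
}

#' @rdname sos_trained
#' @param k Number of leading principal components kept for reconstruction
#'   (at most `|N| - 1`, the rank of the centered seed matrix).
#' @export
sos_pca_reduced <- function(model, k, n) {
  stopifnot(inherits(model, "ng_model"))
  N <- model$config$numerosities
  if (!is_count(k) || k < 1 || k > length(N) - 1)
    stop(sprintf("k must be an integer in [1, %d]", length(N) - 1))
  pc <- ws_pca(model$params$Ws)
  idx <- ws_row(model, n)
  v <- pc$center + pc$x[idx, seq_len(k), drop = FALSE] %*%
    t(pc$rotation[, seq_len(k), drop = FALSE])
  new_sos_vector(drop(v), "pca_reduced", n = n, k = k)
}

#' Teacher-forced conditional generation
#'
#' Rebuilds an image pixel-by-pixel, choosing at each position the argmax of
#' the conditional PMF given the TRUE preceding pixels (one forward pass
#' suffices). Used only to monitor learning progress: one-step-ahead
#' prediction is much easier than full self-generation.
#'
#' @param model A trained `ng_model`.
#' @param image A `stimulus_image`, pixel matrix, or flat raster vector.
#' @param n The image's numerosity (must be in the trained set).
#' @return `list(image, agreement)`: the greedy reconstruction as a pixel
#'   matrix and the fraction of pixels agreeing with the ground truth.
#' @export
conditional_generate <- function(model, image, n) {
  stopifnot(inherits(model, "ng_model"))
  cfg <- model$config
  x <- if (inherits(image, "stimulus_image") || is.matrix(image)) {
    flatten_frame(image)
  } else as.integer(image)
  if (length(x) != cfg$r)
    stop(sprintf("image has %d pixels, model expects r = %d", length(x),
                 cfg$r))
  fwd <- model_forward(model, prefix = x[-cfg$r], n = n)
  xhat <- max.col(fwd$pmf, ties.method = "first") - 1L
  list(image = matrix(xhat, nrow = cfg$height, ncol = cfg$width,
                      byrow = TRUE),
       agreement = mean(xhat == x))
}

#' Spontaneous (fully autoregressive) generation
#'
#' Builds entire novel images from scratch: pixel `i` is sampled from the
#' categorical conditional PMF given the seed and the previously SAMPLED
#' pixels (the first step conditions on the seed alone). Plain temperature-1
#' categorical sampling; one uniform RNG draw per pixel.
#'
#' The default `"cached"` method runs one incremental forward step per pixel
#' with a key/value cache; `"recompute"` re-runs a full forward pass on the
#' growing prefix at every step (r passes per image). Both consume the RNG
#' stream identically and produce the same samples; `"recompute"` exists as
#' the reference implementation.
#'
#' @param model A trained `ng_model` (or `ng_fit`).
#' @param sos An [sos_trained()]-style seed (any numeric d-vector accepted).
#' @param count Images per seed (default 64, the batch size over which
#'   generation statistics are collected).
#' @param seed Optional RNG seed; same checkpoint + same seed gives
#'   bit-identical batches.
#' @param method `"cached"` or `"recompute"`.
#' @return A `sample_batch`: `list(x, sos, provenance, count, seed)` with `x`
#'   a `count x r` matrix of raster-order intensities.
#' @export
spontaneous_generate <- function(model, sos, count = 64, seed = NULL,
                                 method = c("cached", "recompute")) {
  if (inherits(model, "ng_fit")) model <- model$model
  stopifnot(inherits(model, "ng_model"), is_count(count), count >= 1)
  method <- match.arg(method)
  cfg <- model$config
  v <- as.numeric(sos)
  if (length(v) != cfg$d)
    stop(sprintf("SoS vector has length %d, expected d = %d", length(v),
                 cfg$d))
  x <- with_seed_opt(seed, {
    if (method == "cached") {
      cpp_tf_sample(model$params, cpp_config(cfg), v, count, cfg$r)
    } else {
      out <- matrix(0L, count, cfg$r)
      for (b in seq_len(count)) {
        pref <- integer(0)
        for (t in seq_len(cfg$r)) {
          pmf <- model_forward(model, prefix = pref, sos = v)$pmf
          pr <- pmf[t, ]
          u <- runif(1)
          xi <- min(sum(u >= cumsum(pr)), cfg$p - 1L)
          pref <- c(pref, xi)
        }
        out[b, ] <- pref
      }
      out
    }
  })
  structure(list(x = x, sos = v,
                 provenance = if (inherits(sos, "sos_vector"))
                   attr(sos, "provenance")
                 else list(mode = "external", n = NA, alpha = NA, k = NA),
                 count = count, seed = seed,
                 width = cfg$width, height = cfg$height),
            class = "sample_batch")
}

#' @export
print.sample_batch <- function(x, ...) {
  cat(sprintf("<sample_batch> %d images of %dx%d px, seed mode %s\n",
              x$count, x$height, x$width, x$provenance$mode))
  invisible(x)
}

#' Extract one generated frame as a pixel matrix
#'
#' @param batch A `sample_batch`.
#' @param i Image index.
#' @return `height x width` integer matrix.
#' @export
batch_frame <- function(batch, i) {
  stopifnot(inherits(batch, "sample_batch"), i >= 1, i <= batch$count)
  matrix(batch$x[i, ], nrow = batch$height, ncol = batch$width, byrow = TRUE)
}
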