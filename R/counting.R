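# Dataset-specific numerosity counters: the area-ratio heuristic for
# uniform-size items and a compact convolutional classifier for items of
# variable size (where area alone carries no numerosity information).

# Accepts a dataset split, a sample_batch, a list of stimulus_images, a
# single image, or a flat-pixel matrix; returns an n_images x r matrix.
as_pixel_matrix <- function(images) {
  if (is.list(images) && !is.null(images$x)) return(images$x)
  if (inherits(images, "stimulus_image"))
    return(matrix(flatten_frame(images), nrow = 1))
  if (is.list(images))
    return(do.call(rbind, lapply(images, flatten_frame)))
  if (is.matrix(images)) return(images)
  matrix(as.integer(images), nrow = 1)
}

#' Fit the area-ratio counter
#'
#' Estimates the mean single-item area as the average over frames of
#' (foreground pixel count) / (numerosity label); foreground is everything
#' above the mid-intensity threshold. Estimated from a validation split of
#' uniform-size stimuli, where the estimate is exact up to rasterization.
#'
#' @param validation A dataset split (list with pixel matrix `x` and labels
#'   `n`), or a list of labelled `stimulus_image`s.
#' @param spec The [frame_spec()] the frames were rendered with.
#' @return An object of class `area_counter`.
#' @export
fit_area_counter <- function(validation, spec = frame_spec()) {
  x <- as_pixel_matrix(validation)
  labels <- if (!is.null(validation$n)) validation$n
  else vapply(validation, function(im) im$n, integer(1))
  if (nrow(x) == 0) stop("validation set is empty")
  if (length(labels) != nrow(x)) stop("labels do not match frames")
  if (any(labels < 1))
    stop("area-counter fitting needs labels >= 1")
  thr <- (spec$levels - 1) / 2
  fg <- rowSums(x > thr)
  mean_area <- mean(fg / labels)
  if (mean_area <= 0)
    stop("degenerate fit: validation frames contain no foreground pixels")
  structure(list(mean_dot_area = mean_area, threshold = thr,
                 n_frames = nrow(x), family = "uniform_dots"),
            class = "area_counter")
}

#' @export
print.area_counter <- function(x, ...) {
  cat(sprintf("<area_counter> mean item area %.2f px^2 (fit on %d frames)\n",
              x$mean_dot_area, x$n_frames))
  invisible(x)
}

#' Count items by the area ratio
#'
#' Estimated numerosity = foreground area / mean item area, rounded to the
#' nearest integer (ties away from zero) and clipped below at 0. Blank
#' frames count 0. Monotone non-decreasing in foreground area.
#'
#' @param image A frame (matrix, `stimulus_image` or flat vector).
#' @param counter A fitted [fit_area_counter()] object.
#' @return Estimated numerosity (non-negative integer).
#' @export
area_count <- function(image, counter) {
  stopifnot(inherits(counter, "area_counter"))
  x <- as_pixel_matrix(image)
  fg <- rowSums(x > counter$threshold)
  as.integer(pmax(0, floor(fg / counter$mean_dot_area + 0.5)))
}

#' Generate the classifier-counter dataset
#'
#' Non-uniform dot frames with labels drawn uniformly from `labels`
#' (including 0 = blank frames), the stimulus space on which the supervised
#' counter is trained. Defaults follow the counter's training recipe: 22,000
#' frames with labels 0..10.
#'
#' @param n_frames Total number of frames.
#' @param labels Label set (must include every value the counter should
#'   output).
#' @param spec,params Frame and dot parameters.
#' @param seed Master seed.
#' @return `list(x, n)`: flat pixel matrix and labels.
#' @export
counting_dataset <- function(n_frames = 22000, labels = 0:10,
                             spec = frame_spec(), params = dot_params(),
                             seed = 1) {
  stopifnot(n_frames >= length(labels))
  withr::with_seed(as.integer(seed), {
    lab <- allocate_labels(sort(unique(as.integer(labels))), n_frames)
    x <- matrix(0L, n_frames, spec$r)
    for (i in seq_len(n_frames))
      x[i, ] <- flatten_frame(render_nonuniform_dots(lab[i], spec, params))
    list(x = x, n = lab)
  })
}

#' Classifier-counter configuration
#'
#' A compact convolutional network: blocks of 3x3 convolution + per-channel
#' batch normalization + ReLU with optional identity skip and 2x2 max
#' pooling, global average pooling and a softmax head. The default ("desk")
#' preset is a 4-conv-block network whose last two blocks keep an 8x8
#' feature map (items stay spatially separable up to 10 per frame) and which
#' reaches ceiling accuracy on the non-uniform dot counting task within a
#' few CPU-minutes; `channels`/`pool`/`skip` allow deeper residual variants.
#'
#' @param channels Output channels per block.
#' @param pool Logical per block: apply 2x2 pooling after the block.
#' @param avg_pool Use average pooling instead of max pooling (average
#'   pooling preserves the total activation mass a count readout sums).
#' @param skip Logical per block: identity skip connection (requires equal
#'   in/out channels).
#' @param lr,batch_size,epochs,patience Adam optimization settings; the
#'   learning rate is cut to `lr_decay * lr` after 60% of the epoch budget
#'   (coarse features learn fast at the high rate, the final count
#'   boundaries need the low one).
#' @param lr_decay Multiplicative decay applied late in training.
#' @param val_fraction Fraction of the training frames held out for early
#'   stopping.
#' @param seed Master seed for initialization, splitting and shuffling.
#' @param verbose Print per-epoch progress.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(channels = c(8, 16, 32, 32),
                              pool = c(TRUE, TRUE, FALSE, FALSE),
                              skip = c(FALSE, FALSE, FALSE, TRUE),
                              avg_pool = TRUE,
                              lr = 3e-3, lr_decay = 0.1, batch_size = 100,
                              epochs = 12,
                              patience = 6, val_fraction = 0.05, seed = 1,
                              verbose = FALSE) {
  stopifnot(length(channels) >= 1, length(pool) == length(channels),
            length(skip) == length(channels), lr > 0, epochs >= 1)
  structure(list(channels = as.integer(channels), pool = pool, skip = skip,
                 avg_pool = isTRUE(avg_pool),
                 lr = lr, lr_decay = lr_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = patience,
                 val_fraction = val_fraction, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "classifier_config")
}

init_cnn_params <- function(cfg, n_classes) {
  he <- function(nout, nin) matrix(rnorm(nout * nin, sd = sqrt(2 / nin)),
                                   nout, nin)
  chans <- c(1L, cfg$channels)
  list(conv_W = lapply(seq_along(cfg$channels),
                       function(l) he(chans[l + 1], chans[l] * 9L)),
       bn_g = lapply(cfg$channels, function(ch) rep(1, ch)),
       bn_b = lapply(cfg$channels, function(ch) numeric(ch)),
       fc_W = matrix(rnorm(utils::tail(cfg$channels, 1) * n_classes,
                           sd = 0.05),
                     utils::tail(cfg$channels, 1), n_classes),
       fc_b = numeric(n_classes))
}

init_cnn_stats <- function(cfg) {
  list(bn_rm = lapply(cfg$channels, function(ch) numeric(ch)),
       bn_rv = lapply(cfg$channels, function(ch) rep(1, ch)))
}

# Stratified index split: per label, proportional allocation.
stratified_split <- function(labels, n_train) {
  n <- length(labels)
  train_idx <- integer(0)
  shares <- table(labels) / n * n_train
  for (lv in names(shares)) {
    idx <- which(labels == as.integer(lv))
    take <- round(shares[[lv]])
    train_idx <- c(train_idx, idx[sample.int(length(idx), min(take,
                                                              length(idx)))])
  }
  # adjust to the exact requested size
  extra <- n_train - length(train_idx)
  pool <- setdiff(seq_len(n), train_idx)
  if (extra > 0) train_idx <- c(train_idx, pool[sample.int(length(pool),
                                                           extra)])
  if (extra < 0) train_idx <- train_idx[sample.int(length(train_idx),
                                                   n_train)]
  sort(train_idx)
}

#' Train the supervised classifier counter
#'
#' Splits the supplied frames stratified 20,000/2,000 (by default), trains
#' the convolutional counter with Adam and cross-entropy on normalized
#' intensities, early-stops on a held-out carve-out of the training portion,
#' and reports accuracy on the untouched test portion.
#'
#' @param data `list(x, n)` from [counting_dataset()] (labels must cover the
#'   full output set, typically 0..10).
#' @param cfg A [classifier_config()].
#' @param n_train Number of frames in the training portion; the remainder is
#'   the held-out test portion.
#' @param spec The [frame_spec()] of the frames (for intensity scaling).
#' @return A `cnn_counter`: network parameters, architecture, label set,
#'   held-out `test_accuracy`, and the training history.
#' @export
train_classifier_counter <- function(data, cfg = classifier_config(),
                                     n_train = 20000,
                                     spec = frame_spec()) {
  stopifnot(inherits(cfg, "classifier_config"), !is.null(data$x),
            !is.null(data$n))
  labels <- sort(unique(as.integer(data$n)))
  if (!all(diff(labels) == 1))
    stop(sprintf("label set {%s} must be contiguous integers",
                 paste(labels, collapse = ",")))
  n_classes <- length(labels)
  n <- nrow(data$x)
  if (n_train >= n) stop("n_train must leave a non-empty test portion")
  Xall <- data$x / (spec$levels - 1)
  yall <- as.integer(data$n - labels[1])  # 0-based classes
  ccfg <- list(channels = cfg$channels, pool = cfg$pool, skip = cfg$skip,
               avg_pool = cfg$avg_pool,
               n_classes = as.integer(n_classes), height = spec$height,
               width = spec$width)

  withr::with_seed(cfg$seed, {
    tr <- stratified_split(data$n, n_train)
    te <- setdiff(seq_len(n), tr)
    nval <- max(1L, floor(length(tr) * cfg$val_fraction))
    vi <- tr[sample.int(length(tr), nval)]
    ti <- setdiff(tr, vi)
    params <- init_cnn_params(cfg, n_classes)
    stats <- init_cnn_stats(cfg)
    st <- adam_init(params)
    best <- list(acc = -1, params = params, stats = stats, epoch = 0L)
    hist <- vector("list", cfg$epochs)
    stall <- 0L
    acc_of <- function(p, s_, idx) {
      pred <- integer(length(idx))
      for (s in seq(1, length(idx), by = 500)) {
        ii <- idx[s:min(s + 499, length(idx))]
        pr <- cpp_cnn_probs(p, s_, ccfg, Xall[ii, , drop = FALSE])
        pred[s:(s + length(ii) - 1)] <- max.col(pr, ties.method = "first") - 1L
      }
      mean(pred == yall[idx])
    }
    for (ep in seq_len(cfg$epochs)) {
      lr_ep <- cfg$lr * if (ep > ceiling(0.6 * cfg$epochs)) cfg$lr_decay else 1
      ord <- ti[sample.int(length(ti))]
      ep_loss <- 0; nb <- 0L
      for (s in seq(1, length(ord), by = cfg$batch_size)) {
        ii <- ord[s:min(s + cfg$batch_size - 1L, length(ord))]
        res <- cpp_cnn_grad(params, stats, ccfg, Xall[ii, , drop = FALSE],
                            yall[ii], 0.1)
        stats <- res$stats
        upd <- adam_step(params, res$grads, st, lr_ep)
        params <- upd$params
        st <- upd$state
        ep_loss <- ep_loss + res$loss
        nb <- nb + 1L
      }
      # refresh BN running statistics for the current weights before any
      # evaluation (running averages lag when weights move quickly)
      calib <- ti[seq_len(min(2000L, length(ti)))]
      for (s2 in seq(1, length(calib), by = cfg$batch_size)) {
        ii <- calib[s2:min(s2 + cfg$batch_size - 1L, length(calib))]
        stats <- cpp_cnn_calibrate(params, stats, ccfg,
                                   Xall[ii, , drop = FALSE], 0.1)
      }
      vacc <- acc_of(params, stats, vi)
      hist[[ep]] <- data.frame(epoch = ep, train_loss = ep_loss / nb,
                               val_accuracy = vacc)
      if (cfg$verbose)
        message(sprintf("cnn epoch %d: loss %.4f, val acc %.4f", ep,
                        ep_loss / nb, vacc))
      if (vacc > best$acc) {
        best <- list(acc = vacc, params = params, stats = stats, epoch = ep)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$patience) break
      }
      if (vacc == 1 && ep >= 2) break
    }
    test_acc <- acc_of(best$params, best$stats, te)
    structure(list(params = best$params, stats = best$stats, arch = ccfg,
                   labels = labels,
                   test_accuracy = test_acc,
                   history = do.call(rbind,
                                     hist[!vapply(hist, is.null,
                                                  logical(1))]),
                   levels = spec$levels,
                   manifest = list(n_total = n, n_train = n_train,
                                   n_test = length(te), seed = cfg$seed)),
              class = "cnn_counter")
  })
}

#' @export
print.cnn_counter <- function(x, ...) {
  cat(sprintf(
    "<cnn_counter> labels %d..%d, blocks [%s], held-out accuracy %.4f\n",
    min(x$labels), max(x$labels), paste(x$arch$channels, collapse = ","),
    x$test_accuracy))
  invisible(x)
}

#' Count a batch of frames
#'
#' Applies a fitted counter to every frame, returning one estimate per frame.
#' A warning is issued when the area counter is applied to frames known to
#' come from a variable-size family (the area heuristic is only valid when
#' all items share one size).
#'
#' @param images A `sample_batch`, dataset split, list of `stimulus_image`s
#'   or flat pixel matrix.
#' @param counter An `area_counter` or `cnn_counter`.
#' @return Integer vector of estimated numerosities.
#' @export
count_batch <- function(images, counter) UseMethod("count_batch", counter)

#' @export
count_batch.area_counter <- function(images, counter) {
  fam <- NULL
  if (is.list(images) && !is.null(images$family)) fam <- images$family
  if (inherits(images, "stimulus_image")) fam <- images$family
  if (!is.null(fam) && any(fam %in% c("nonuniform", "nonuniform_dots")))
    warning("area counter applied to variable-size items; estimates unreliable")
  x <- as_pixel_matrix(images)
  if (nrow(x) == 0) return(integer(0))
  area_count(x, counter)
}

#' @export
count_batch.cnn_counter <- function(images, counter) {
  x <- as_pixel_matrix(images)
  if (nrow(x) == 0) return(integer(0))
  X <- x / (counter$levels - 1)
  out <- integer(nrow(X))
  for (s in seq(1, nrow(X), by = 500)) {
    ii <- s:min(s + 499, nrow(X))
    pr <- cpp_cnn_probs(counter$params, counter$stats, counter$arch,
                        X[ii, , drop = FALSE])
    out[ii] <- counter$labels[max.col(pr, ties.method = "first")]
  }
  out
}
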