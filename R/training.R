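#' Training configuration
#'
#' Optimization settings for teacher-forced maximum-likelihood training.
#' Defaults are robust small-transformer settings: Adam at learning rate
#' 3e-4, batch 64, up to 50 epochs with early stopping on validation NLL.
#'
#' @param lr Adam learning rate.
#' @param lr_decay Multiplicative factor applied to the learning rate after
#'   60% of the epoch budget (1 = constant rate). A late step-down lets the
#'   per-pixel densities sharpen after the coarse structure is learned.
#' @param batch_size Minibatch size (full images).
#' @param epochs Epoch budget.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement); `Inf` disables early stopping.
#' @param seed Master seed for shuffling, dropout and initialization-free
#'   reproducibility of a run.
#' @param max_val Cap on the number of validation images scored per epoch
#'   (validation NLL is always computed with dropout disabled).
#' @param verbose Print per-epoch losses.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 3e-4, lr_decay = 1, batch_size = 64,
                         epochs = 50,
                         patience = 10, seed = 1, max_val = 512,
                         verbose = FALSE) {
  stopifnot(lr >= 0, lr_decay > 0, lr_decay <= 1,
            is_count(batch_size), batch_size > 0,
            is_count(epochs), epochs >= 1, patience >= 1)
  structure(list(lr = lr, lr_decay = lr_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = patience,
                 seed = as.integer(seed), max_val = as.integer(max_val),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Autoregressive negative log-likelihood
#'
#' Cross-entropy of target intensities under the model logits: the mean (or
#' sum) over positions of `-log softmax(logits)[i, target_i]`. The per-image
#' sum of per-pixel terms equals the negative log of the product of the
#' conditional densities (the chain-rule factorization), which is what
#' training minimizes.
#'
#' @param logits `q x p` matrix of unnormalized scores.
#' @param targets Integer vector of `q` 0-based target intensities.
#' @param reduction `"mean"` (per position, the optimizer scale) or `"sum"`
#'   (the per-image total in nats).
#' @return Scalar NLL in nats.
#' @export
nll_loss <- function(logits, targets, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  stopifnot(is.matrix(logits), length(targets) == nrow(logits))
  targets <- as.integer(targets)
  if (any(targets < 0) || any(targets >= ncol(logits)))
    stop("targets must lie in [0, p - 1]")
  mx <- apply(logits, 1, max)
  lse <- mx + log(rowSums(exp(logits - mx)))
  picked <- logits[cbind(seq_len(nrow(logits)), targets + 1L)]
  val <- lse - picked
  if (reduction == "mean") mean(val) else sum(val)
}

# Map dataset labels to 0-based Ws row indices, erroring on unseen labels.
label_indices <- function(model, labels) {
  idx <- match(labels, model$config$numerosities)
  if (anyNA(idx))
    stop(sprintf("labels {%s} are outside the model's numerosity set {%s}",
                 paste(sort(unique(labels[is.na(idx)])), collapse = ","),
                 paste(model$config$numerosities, collapse = ",")))
  as.integer(idx - 1L)
}

#' Train the model by teacher forcing
#'
#' Minimizes the mean per-pixel NLL over full images with Adam. Every image
#' contributes the sequence (seed, x_1 .. x_{r-1}) as input and
#' (x_1 .. x_r) as targets: the final pixel is never consumed by the
#' autoregression, only predicted. The checkpoint with the best validation
#' NLL (dropout disabled) is returned.
#'
#' @param model An [init_model()] object (defines the starting parameters).
#' @param bundle A [build_dataset()] bundle whose labels are a subset of the
#'   model's numerosity set.
#' @param cfg A [train_config()].
#' @return An `ng_fit`: `list(model, record, best_epoch)` where `record` is a
#'   per-epoch data frame of train/validation NLL in nats per pixel and per
#'   image.
#' @export
train <- function(model, bundle, cfg = train_config()) {
  stopifnot(inherits(model, "ng_model"), inherits(cfg, "train_config"))
  X <- bundle$train$x
  nidx <- label_indices(model, bundle$train$n)
  nval <- min(nrow(bundle$validation$x), cfg$max_val)
  Xv <- bundle$validation$x[seq_len(nval), , drop = FALSE]
  nv <- label_indices(model, bundle$validation$n[seq_len(nval)])
  ccfg <- cpp_config(model$config)
  dropout <- model$config$dropout
  r <- model$config$r

  withr::with_seed(cfg$seed, {
    params <- model$params
    st <- adam_init(params)
    best <- list(nll = Inf, params = params, epoch = 0L)
    rec <- vector("list", cfg$epochs)
    stall <- 0L
    for (ep in seq_len(cfg$epochs)) {
      lr_ep <- cfg$lr *
        if (ep > ceiling(0.6 * cfg$epochs)) cfg$lr_decay else 1
      ord <- sample.int(nrow(X))
      tr_loss <- 0; nb <- 0L
      for (s in seq(1, length(ord), by = cfg$batch_size)) {
        ii <- ord[s:min(s + cfg$batch_size - 1L, length(ord))]
        res <- cpp_tf_batch_grad(params, ccfg, X[ii, , drop = FALSE],
                                 nidx[ii], dropout)
        if (cfg$lr > 0) {
          upd <- adam_step(params, res$grads, st, lr_ep)
          params <- upd$params
          st <- upd$state
        }
        tr_loss <- tr_loss + res$loss
        nb <- nb + 1L
      }
      val <- cpp_tf_eval_nll(params, ccfg, Xv, nv)
      rec[[ep]] <- data.frame(epoch = ep, train_nll_px = tr_loss / nb,
                              val_nll_px = val,
                              train_nll_img = tr_loss / nb * r,
                              val_nll_img = val * r)
      if (cfg$verbose)
        message(sprintf("epoch %d: train %.4f, val %.4f nats/px", ep,
                        tr_loss / nb, val))
      if (val < best$nll) {
        best <- list(nll = val, params = params, epoch = ep)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$patience) break
      }
    }
    fitted <- model
    fitted$params <- best$params
    structure(list(model = fitted,
                   record = do.call(rbind, rec[!vapply(rec, is.null,
                                                       logical(1))]),
                   best_epoch = best$epoch, best_val_nll_px = best$nll),
              class = "ng_fit")
  })
}

#' @export
print.ng_fit <- function(x, ...) {
  cat(sprintf("<ng_fit> %d epochs run, best epoch %d (val %.4f nats/px)\n",
              nrow(x$record), x$best_epoch, x$best_val_nll_px))
  invisible(x)
}

#' Validation loss as a function of training-set size
#'
#' Runs one independent training per requested size on nested subsets of the
#' training split (smaller sets are prefixes of larger ones under the same
#' permutation), reporting the best validation NLL per size. The monotone
#' trend is reported, not asserted.
#'
#' @param model Untrained starting model (same initialization reused per run).
#' @param bundle A dataset bundle.
#' @param sizes Ascending vector of training-set sizes; empty gives an empty
#'   table.
#' @param cfg A [train_config()].
#' @return Data frame with columns `train_size` and `best_val_nll_px`.
#' @export
loss_vs_train_size <- function(model, bundle, sizes, cfg = train_config()) {
  if (length(sizes) == 0)
    return(data.frame(train_size = integer(0), best_val_nll_px = numeric(0)))
  stopifnot(all(diff(sizes) >= 0), all(sizes >= 1),
            max(sizes) <= nrow(bundle$train$x))
  perm <- withr::with_seed(cfg$seed, sample.int(nrow(bundle$train$x)))
  out <- lapply(sizes, function(sz) {
    sub <- bundle
    keep <- perm[seq_len(sz)]
    sub$train$x <- bundle$train$x[keep, , drop = FALSE]
    sub$train$n <- bundle$train$n[keep]
    fit <- train(model, sub, cfg)
    data.frame(train_size = sz, best_val_nll_px = fit$best_val_nll_px)
  })
  do.call(rbind, out)
}
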