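#' Transformer configuration
#'
#' Sizing of the encoder-only self-attention network. The encoder stack has
#' `L` attention sub-layers and `L` position-wise feed-forward sub-layers
#' (2L sub-layers in total), each followed by a residual connection and layer
#' normalization (post-norm). The learned tables are `Wx` (`p x d` intensity
#' embeddings), `Ws` (`|N| x d` numerosity seeds, rows ordered by ascending
#' numerosity) and `WE` (`r x d` positional encodings); `WE` is what
#' constrains the input resolution to `width x height = r` pixels.
#'
#' @param width,height Frame size the model accepts; `r = width * height`.
#' @param levels Intensity vocabulary size `p`.
#' @param numerosities Integer vector of trained numerosities; rows of `Ws`
#'   are ordered by ascending numerosity.
#' @param d Embedding width (divisible by `n_heads`).
#' @param n_heads Number of attention heads.
#' @param L Encoder depth (attention + feed-forward sub-layer pairs).
#' @param ff_width Hidden width of the feed-forward sub-layers.
#' @param dropout Residual-path dropout rate used during training.
#' @return An object of class `model_config`.
#' @seealso [tiny_model_config()] for the small preset used in quick
#'   experiments and tests.
#' @export
model_config <- function(width = 32, height = 32, levels = 256,
                         numerosities = 1:8, d = 128, n_heads = 8, L = 4,
                         ff_width = 512, dropout = 0.1) {
  stopifnot(is_count(width), width > 0, is_count(height), height > 0,
            is_count(levels), levels >= 2, length(numerosities) >= 1,
            is_count(d), d > 0, is_count(n_heads), n_heads > 0,
            is_count(L), L >= 0, is_count(ff_width), ff_width > 0,
            dropout >= 0, dropout < 1)
  if (d %% n_heads != 0) stop("d must be divisible by n_heads")
  numerosities <- sort(unique(as.integer(numerosities)))
  structure(list(width = as.integer(width), height = as.integer(height),
                 r = as.integer(width * height), p = as.integer(levels),
                 numerosities = numerosities,
                 n_numerosities = length(numerosities),
                 d = as.integer(d), n_heads = as.integer(n_heads),
                 L = as.integer(L), ff_width = as.integer(ff_width),
                 dropout = dropout),
            class = "model_config")
}

#' Small-model preset
#'
#' A reduced configuration (L = 2, d = 32, 4 heads, ff 128) that trains in
#' minutes on a CPU at reduced resolution; used throughout the examples and
#' the scaled-down behavioral checks.
#'
#' @inheritParams model_config
#' @export
tiny_model_config <- function(width = 12, height = 12, levels = 2,
                              numerosities = 1:3, dropout = 0.1) {
  model_config(width, height, levels, numerosities, d = 32, n_heads = 4,
               L = 2, ff_width = 128, dropout = dropout)
}

# Config fields consumed by the C++ kernels.
cpp_config <- function(config) {
  list(L = config$L, d = config$d, n_heads = config$n_heads, p = config$p,
       r = config$r, ff_width = config$ff_width)
}

rtruncnorm2 <- function(n, sd) {
  x <- rnorm(n, 0, sd)
  bad <- which(abs(x) > 2 * sd)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), 0, sd)
    bad <- which(abs(x) > 2 * sd)
  }
  x
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialize model parameters
#'
#' Embedding tables (`Wx`, `Ws`, `WE`) use truncated-normal initialization
#' (sd 0.02, clipped at two standard deviations); encoder projection and
#' feed-forward weights use Glorot-uniform; the softmax head starts near
#' zero; biases at zero; layer-norm gains at one. With this initialization
#' the untrained per-pixel NLL sits at the maximum-entropy baseline
#' `log(p)` nats.
#'
#' @param config A [model_config()].
#' @param seed Optional seed for reproducible initialization.
#' @return An object of class `ng_model`: `list(config, params)`.
#' @export
init_model <- function(config, seed = NULL) {
  stopifnot(inherits(config, "model_config"))
  d <- config$d; ff <- config$ff_width
  params <- with_seed_opt(seed, {
    mk_layer <- function() list(
      Wq = glorot(d, d), bq = numeric(d),
      Wk = glorot(d, d), bk = numeric(d),
      Wv = glorot(d, d), bv = numeric(d),
      Wo = glorot(d, d), bo = numeric(d),
      ln1_g = rep(1, d), ln1_b = numeric(d),
      W1 = glorot(d, ff), b1 = numeric(ff),
      W2 = glorot(ff, d), b2 = numeric(d),
      ln2_g = rep(1, d), ln2_b = numeric(d))
    list(
      Wx = matrix(rtruncnorm2(config$p * d, 0.02), config$p, d),
      Ws = matrix(rtruncnorm2(config$n_numerosities * d, 0.02),
                  config$n_numerosities, d),
      WE = matrix(rtruncnorm2(config$r * d, 0.02), config$r, d),
      layers = lapply(seq_len(config$L), function(i) mk_layer()),
      # near-zero head: the untrained model emits near-uniform PMFs, so its
      # per-pixel NLL starts at the maximum-entropy baseline log(p)
      head_W = matrix(rnorm(d * config$p, sd = 0.01), d, config$p),
      head_b = numeric(config$p))
  })
  structure(list(config = config, params = params), class = "ng_model")
}

#' @export
print.ng_model <- function(x, ...) {
  c <- x$config
  cat(sprintf(
    "<ng_model> %dx%d px, p = %d, N = {%s}, L = %d, d = %d, heads = %d\n",
    c$width, c$height, c$p, paste(c$numerosities, collapse = ","),
    c$L, c$d, c$n_heads))
  invisible(x)
}

ws_row <- function(model, n) {
  idx <- match(n, model$config$numerosities)
  if (is.na(idx))
    stop(sprintf("numerosity %s is not in the trained set {%s}", n,
                 paste(model$config$numerosities, collapse = ",")))
  idx
}

#' Embed a conditioning seed and a pixel prefix
#'
#' Builds the encoder input `H0`: row 1 is the conditioning seed (a trained
#' numerosity row of `Ws`, or any externally supplied d-vector, e.g. an
#' interpolated seed) plus the first positional encoding; row `i + 1` is the
#' intensity embedding of prefix pixel `i` plus positional encoding `i + 1`.
#'
#' @param model An [init_model()] object.
#' @param prefix Integer vector of 0-based pixel intensities already
#'   generated/observed, in raster order (may be empty).
#' @param n A trained numerosity whose `Ws` row seeds the sequence.
#' @param sos Alternatively, an arbitrary numeric d-vector seed (used by the
#'   interpolation/extrapolation/PCA probes). Exactly one of `n`, `sos`.
#' @return A `(1 + length(prefix)) x d` matrix `H0`.
#' @export
embed_sequence <- function(model, prefix = integer(0), n = NULL, sos = NULL) {
  stopifnot(inherits(model, "ng_model"))
  cfg <- model$config
  if (is.null(n) == is.null(sos))
    stop("supply exactly one of `n` (trained numerosity) or `sos` (d-vector)")
  if (!is.null(n)) sos <- model$params$Ws[ws_row(model, n), ]
  sos <- as.numeric(sos)
  if (length(sos) != cfg$d)
    stop(sprintf("SoS vector has length %d, expected d = %d", length(sos),
                 cfg$d))
  q <- length(prefix) + 1L
  if (q > cfg$r)
    stop(sprintf("prefix of %d pixels exceeds the model's r = %d (max prefix %d)",
                 length(prefix), cfg$r, cfg$r - 1L))
  if (length(prefix) > 0 && (any(prefix < 0) || any(prefix >= cfg$p)))
    stop("prefix intensities must lie in [0, p - 1]")
  H0 <- matrix(0, q, cfg$d)
  H0[1, ] <- sos + model$params$WE[1, ]
  if (q > 1)
    H0[2:q, ] <- model$params$Wx[prefix + 1L, , drop = FALSE] +
      model$params$WE[2:q, , drop = FALSE]
  H0
}

#' Causal attention-permission mask
#'
#' Lower-triangular permission matrix: sequence position `i` may attend to
#' positions `1..i` (itself, earlier pixels and the conditioning seed at
#' position 1, which attends only to itself). The same mask is reused on
#' every encoder layer.
#'
#' @param q Sequence length.
#' @return A logical `q x q` matrix, `TRUE` = attention allowed.
#' @export
causal_mask <- function(q) {
  stopifnot(is_count(q), q >= 1)
  m <- matrix(FALSE, q, q)
  m[lower.tri(m, diag = TRUE)] <- TRUE
  m
}

#' Run the encoder stack
#'
#' Applies `L` masked multi-head scaled dot-product attention sub-layers and
#' `L` position-wise feed-forward sub-layers, each with residual connection
#' followed by layer normalization (post-norm). `L = 0` returns `H0`
#' unchanged.
#'
#' @param model An `ng_model`.
#' @param H0 Encoder input from [embed_sequence()].
#' @param mask Attention-permission matrix (default: causal).
#' @return The final activations `HL`, same shape as `H0`.
#' @export
encoder_forward <- function(model, H0, mask = causal_mask(nrow(H0))) {
  stopifnot(inherits(model, "ng_model"), is.matrix(H0))
  if (ncol(H0) != model$config$d)
    stop(sprintf("H0 has %d columns, expected d = %d", ncol(H0),
                 model$config$d))
  if (!is.matrix(mask) || nrow(mask) != nrow(H0) || ncol(mask) != nrow(H0))
    stop("mask must be a q x q matrix with q = nrow(H0)")
  if (model$config$L == 0) return(H0)
  m <- mask * 1L
  storage.mode(m) <- "integer"
  cpp_encoder_forward(model$params, cpp_config(model$config), H0, m)
}

#' Per-position conditional PMFs
#'
#' Applies the linear head and a row-wise softmax to the encoder output. Row
#' `i` of the PMF matrix is the conditional density of pixel `i` given the
#' seed and pixels `1..i-1`.
#'
#' @param model An `ng_model`.
#' @param HL Encoder output from [encoder_forward()].
#' @return `list(pmf, logits)`: a row-stochastic `q x p` matrix and the raw
#'   logits feeding the training criterion.
#' @export
output_pmfs <- function(model, HL) {
  stopifnot(inherits(model, "ng_model"), is.matrix(HL))
  logits <- HL %*% model$params$head_W +
    matrix(model$params$head_b, nrow(HL), model$config$p, byrow = TRUE)
  list(pmf = softmax_rows(logits), logits = logits)
}

#' Full forward pass
#'
#' Convenience wrapper chaining [embed_sequence()], [encoder_forward()] and
#' [output_pmfs()].
#'
#' @inheritParams embed_sequence
#' @return `list(H0, HL, pmf, logits)`.
#' @export
model_forward <- function(model, prefix = integer(0), n = NULL, sos = NULL) {
  H0 <- embed_sequence(model, prefix, n = n, sos = sos)
  HL <- encoder_forward(model, H0)
  out <- output_pmfs(model, HL)
  list(H0 = H0, HL = HL, pmf = out$pmf, logits = out$logits)
}
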