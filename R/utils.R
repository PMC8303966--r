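# Internal helpers: parameter-tree flattening, Adam, seeded evaluation.

# Flatten a nested list of numeric arrays into one vector (unlist order).
flatten_params <- function(p) unlist(p, use.names = FALSE)

# Inverse of flatten_params for a skeleton with identical structure.
unflatten_params <- function(v, skel) {
  pos <- 0L
  rec <- function(s) {
    if (is.list(s)) return(lapply(s, rec))
    n <- length(s)
    out <- v[(pos + 1L):(pos + n)]
    pos <<- pos + n
    attributes(out) <- attributes(s)
    out
  }
  rec(skel)
}

# Reorder a gradient tree to the exact structure/order of the parameter tree,
# so that flatten_params() aligns elementwise.
align_params <- function(g, skel) {
  if (!is.list(skel)) return(g)
  nm <- names(skel)
  if (!is.null(nm) && all(nzchar(nm))) {
    out <- lapply(nm, function(k) align_params(g[[k]], skel[[k]]))
    names(out) <- nm
  } else {
    out <- lapply(seq_along(skel), function(i) align_params(g[[i]], skel[[i]]))
  }
  out
}

adam_init <- function(params) {
  n <- length(flatten_params(params))
  list(m = numeric(n), v = numeric(n), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  g <- flatten_params(align_params(grads, params))
  p <- flatten_params(params)
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g * g
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  p <- p - lr * mhat / (sqrt(vhat) + eps)
  list(params = unflatten_params(p, params), state = state)
}

# Evaluate expr under a temporary RNG seed (NULL = use the current stream).
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

# Deterministic sub-seed derivation, kept inside 32-bit integer range.
derive_seed <- function(master, k) {
  as.integer((as.numeric(master) * 7919 + as.numeric(k) * 104729) %% 2147483647)
}

softmax_rows <- function(m) {
  mx <- apply(m, 1, max)
  e <- exp(m - mx)
  e / rowSums(e)
}

is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) &&
  x == as.integer(x)
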