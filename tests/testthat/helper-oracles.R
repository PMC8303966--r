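# Independent oracles used across the suite.

# Connected-component count of a binarized frame (independent labelling
# implementation from EBImage; 4- and 8-connectivity agree for our stimuli
# because rendered items are separated by construction).
component_count <- function(mask) {
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow = nrow(mask)))
  max(lab)
}

# Mean and SD of a Normal(mu, sigma^2) truncated below at `lo` -- the
# distribution the per-dot area sampler actually draws from.
truncnorm_moments <- function(mu, sigma, lo = pi) {
  a <- (lo - mu) / sigma
  z <- 1 - pnorm(a)
  lam <- dnorm(a) / z
  m <- mu + sigma * lam
  v <- sigma^2 * (1 + a * lam - lam^2)
  list(mean = m, sd = sqrt(v))
}

# Micro transformer for exact property tests: 4x4 frames, random weights.
micro_model <- function(seed = 1, width = 4, height = 4, levels = 4,
                        numerosities = 1:3, d = 16, n_heads = 2, L = 2,
                        ff_width = 32) {
  init_model(model_config(width, height, levels, numerosities, d = d,
                          n_heads = n_heads, L = L, ff_width = ff_width,
                          dropout = 0),
             seed = seed)
}

# Micro stimulus setting small enough for seconds-scale training runs.
micro_spec <- function() frame_spec(8, 8, levels = 2)
micro_params <- function() dot_params(uniform_radius = 1, margin = 0)
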