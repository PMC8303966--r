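# Result surfaces: per-seed numerosity histograms, target-vs-generated 2D
# histograms, scalar-variability summaries, the PCA view of the numerosity
# embedding space, and end-to-end experiment orchestration.

#' Histograms of generated numerosities
#'
#' Turns counted sample batches into the per-seed relative-frequency
#' histograms and the target-by-estimate 2D histogram. Estimates are binned
#' over `bins` (default 0..12, the classifier's label range plus slack);
#' out-of-range estimates are clipped into the edge bins and the clipped
#' count is recorded.
#'
#' @param batches List of [spontaneous_generate()] batches.
#' @param counts List of integer vectors: the estimated numerosity of each
#'   image of each batch (aligned with `batches`).
#' @param targets Optional numeric vector of intended numerosities per batch;
#'   defaults to each batch's seed provenance (`NA` where the provenance
#'   carries no target, e.g. extrapolated seeds).
#' @param bins Integer support of the histograms.
#' @return A `generation_report`: per-seed summaries (target, mean, SD,
#'   exact-match rate), a `n_batches x length(bins)` relative-frequency
#'   matrix `freq` (rows sum to 1), and the 2D count matrix `hist2d` whose
#'   row sums equal the per-batch sample counts.
#' @export
histogram_report <- function(batches, counts, targets = NULL, bins = 0:12) {
  stopifnot(is.list(batches), is.list(counts))
  if (length(batches) != length(counts))
    stop("batches and counts are misaligned (different lengths)")
  nb <- length(batches)
  if (is.null(targets))
    targets <- vapply(batches, function(b) {
      pv <- b$provenance
      if (!is.null(pv$n) && !is.na(pv$n)) as.numeric(pv$n) else NA_real_
    }, numeric(1))
  stopifnot(length(targets) == nb)
  freq <- matrix(0, nb, length(bins),
                 dimnames = list(NULL, as.character(bins)))
  hist2d <- freq
  per_seed <- vector("list", nb)
  clipped <- 0L
  for (i in seq_len(nb)) {
    ci <- counts[[i]]
    if (length(ci) != batches[[i]]$count)
      stop(sprintf("batch %d: %d counts for %d images", i, length(ci),
                   batches[[i]]$count))
    clipped <- clipped + sum(ci < min(bins) | ci > max(bins))
    cc <- pmin(pmax(ci, min(bins)), max(bins))
    tab <- tabulate(cc - min(bins) + 1L, nbins = length(bins))
    hist2d[i, ] <- tab
    freq[i, ] <- tab / length(ci)
    per_seed[[i]] <- data.frame(
      target = targets[i], mode = batches[[i]]$provenance$mode,
      n_samples = length(ci), mean = mean(ci), sd = sd(ci),
      exact_match = if (is.na(targets[i])) NA_real_
      else mean(ci == targets[i]))
  }
  structure(list(summary = do.call(rbind, per_seed), freq = freq,
                 hist2d = hist2d, bins = bins, targets = targets,
                 clipped = clipped),
            class = "generation_report")
}

#' @export
print.generation_report <- function(x, ...) {
  cat(sprintf("<generation_report> %d seeds, bins %d..%d\n",
              nrow(x$freq), min(x$bins), max(x$bins)))
  print(x$summary)
  invisible(x)
}

#' Scalar-variability summary
#'
#' Per-target mean and SD of the estimated numerosities, plus the Spearman
#' correlation between target and SD. A positive correlation echoes scalar
#' variability (estimate spread growing with target numerosity); the trend is
#' reported, never asserted. With fewer than two targets, or when every SD is
#' identical (e.g. all-perfect generation), the correlation is undefined and
#' reported as `NA` with an explanatory note.
#'
#' @param report A [histogram_report()].
#' @return `list(table, spearman_target_sd, note)`.
#' @export
scalar_variability_summary <- function(report) {
  stopifnot(inherits(report, "generation_report"))
  tab <- report$summary[, c("target", "mean", "sd")]
  ok <- !is.na(tab$target)
  rho <- NA_real_
  note <- NULL
  if (sum(ok) < 2) {
    note <- "correlation undefined: fewer than two targets"
  } else if (length(unique(tab$sd[ok])) < 2 ||
             length(unique(tab$target[ok])) < 2) {
    note <- "correlation undefined: zero variance in targets or SDs"
  } else {
    rho <- cor(tab$target[ok], tab$sd[ok], method = "spearman")
  }
  list(table = tab, spearman_target_sd = rho, note = note)
}

#' Principal-component view of the numerosity embeddings
#'
#' Centered PCA of the rows of `Ws` (the learned numerosity seeds), with a
#' reproducible sign convention (each component's largest-magnitude loading
#' is positive). Includes the "number line" diagnostic: whether the PC1
#' scores, ordered by ascending numerosity, are strictly monotone. For a
#' trained model the diagnostic is expected to hold; for a randomly
#' initialized model it fails with high probability (the control condition).
#'
#' @param model An `ng_model` (or `ng_fit`).
#' @return An `embedding_map`: score matrix (rows = numerosities ascending),
#'   explained-variance ratios (summing to 1), the PC1 monotonicity flag and
#'   the sign convention identifier.
#' @export
pca_view <- function(model) {
  if (inherits(model, "ng_fit")) model <- model$model
  stopifnot(inherits(model, "ng_model"))
  N <- model$config$numerosities
  if (length(N) < 2) stop("PCA view needs at least two numerosities")
  pc <- ws_pca(model$params$Ws)
  scores <- pc$x
  rownames(scores) <- as.character(N)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  d1 <- diff(scores[, 1])
  structure(list(scores = scores, explained_variance_ratio = evr,
                 pc1_monotone = all(d1 > 0) || all(d1 < 0),
                 numerosities = N,
                 sign_convention = "max-abs-loading-positive"),
            class = "embedding_map")
}

#' @export
print.embedding_map <- function(x, ...) {
  cat(sprintf(
    "<embedding_map> %d seeds; PC1/PC2 explain %.1f%% / %.1f%%; PC1 %s\n",
    nrow(x$scores), 100 * x$explained_variance_ratio[1],
    100 * x$explained_variance_ratio[2],
    if (x$pc1_monotone) "monotone in numerosity" else "not monotone"))
  invisible(x)
}

#' Experiment configuration
#'
#' Declarative description of one end-to-end run: stimulus family and
#' numerosity set (with optional holdout excluded from training, used by the
#' interpolation regime), dataset sizes, model/training settings, the probe
#' list and the counter kind.
#'
#' @param family Stimulus family passed to [build_dataset()].
#' @param numerosities Full numerosity set of interest.
#' @param holdout Numerosities excluded from training (e.g. `2` when probing
#'   interpolation between 1 and 3).
#' @param sizes Dataset split sizes.
#' @param spec,params Frame and dot parameters.
#' @param model_args Named list overriding [model_config()] defaults.
#' @param train_cfg A [train_config()].
#' @param probes List of probe descriptors: `list(mode = "trained", n = 1)`,
#'   `list(mode = "interpolated", n = 2)`, `list(mode = "extrapolated",
#'   alpha = 1)`, `list(mode = "pca_reduced", k = 1, n = 3)`.
#' @param counter `"area"` or `"cnn"`.
#' @param count Images generated per probe seed.
#' @param seed Master seed; every stage derives its own stream from it.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(family = "uniform", numerosities = 1:3,
                              holdout = integer(0),
                              sizes = c(1500, 300, 300),
                              spec = frame_spec(12, 12, levels = 2),
                              params = dot_params(uniform_radius = 1.5),
                              model_args = list(),
                              train_cfg = train_config(),
                              probes = list(list(mode = "trained", n = 1)),
                              counter = c("area", "cnn"),
                              count = 64, seed = 1) {
  counter <- match.arg(counter)
  trained <- sort(setdiff(numerosities, holdout))
  if (length(trained) < 1) stop("holdout removes every numerosity")
  for (pr in probes) {
    if (is.null(pr$mode) ||
        !pr$mode %in% c("trained", "interpolated", "extrapolated",
                        "pca_reduced"))
      stop(sprintf("unknown probe mode '%s'", pr$mode %||% "<missing>"))
  }
  structure(list(family = family, numerosities = numerosities,
                 holdout = holdout, trained = trained, sizes = sizes,
                 spec = spec, params = params, model_args = model_args,
                 train_cfg = train_cfg, probes = probes, counter = counter,
                 count = count, seed = as.integer(seed)),
            class = "experiment_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

probe_seed_vector <- function(model, pr) {
  switch(pr$mode,
         trained = sos_trained(model, pr$n),
         interpolated = sos_interpolated(model, pr$n),
         extrapolated = sos_extrapolated(model, pr$alpha %||% 1),
         pca_reduced = sos_pca_reduced(model, pr$k %||% 1, pr$n))
}

#' Run a full experiment
#'
#' Executes the whole pipeline under one master seed: dataset construction,
#' model training, counter fitting, probe sampling, counting, and report
#' writing. All artifacts (manifest, loss curve, per-seed counts, histogram
#' report, scalar-variability summary, PCA view) are written as JSON/CSV into
#' `out_dir`.
#'
#' @param config An [experiment_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the fitted model, counter, batches, counts,
#'   report, summary, PCA view and file paths.
#' @export
run_experiment <- function(config, out_dir = tempfile("ng_run_")) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  bundle <- build_dataset(config$family, config$trained, config$sizes,
                          seed = derive_seed(config$seed, 1),
                          spec = config$spec, params = config$params)
  margs <- utils::modifyList(
    list(width = config$spec$width, height = config$spec$height,
         levels = config$spec$levels, numerosities = config$trained),
    config$model_args)
  model <- init_model(do.call(model_config, margs),
                      seed = derive_seed(config$seed, 2))
  fit <- train(model, bundle, config$train_cfg)
  counter <- if (config$counter == "area") {
    fit_area_counter(bundle$validation, config$spec)
  } else {
    train_classifier_counter(
      counting_dataset(spec = config$spec, params = config$params,
                       seed = derive_seed(config$seed, 3)),
      spec = config$spec)
  }
  batches <- list()
  counts <- list()
  for (i in seq_along(config$probes)) {
    sv <- probe_seed_vector(fit$model, config$probes[[i]])
    batches[[i]] <- spontaneous_generate(fit$model, sv, config$count,
                                         seed = derive_seed(config$seed,
                                                            100 + i))
    counts[[i]] <- count_batch(batches[[i]], counter)
  }
  report <- histogram_report(batches, counts)
  sv_summary <- scalar_variability_summary(report)
  emb <- pca_view(fit$model)

  paths <- list(
    manifest = file.path(out_dir, "manifest.json"),
    loss = file.path(out_dir, "loss_curve.csv"),
    counts = file.path(out_dir, "counts.csv"),
    report = file.path(out_dir, "report.json"),
    summary = file.path(out_dir, "scalar_variability.csv"),
    pca = file.path(out_dir, "pca_scores.csv"))
  jsonlite::write_json(
    list(family = config$family, numerosities = config$numerosities,
         holdout = config$holdout, trained = config$trained,
         sizes = config$sizes, seed = config$seed, counter = config$counter,
         count = config$count,
         probes = lapply(config$probes, function(p) p[!vapply(p, is.null,
                                                              logical(1))])),
    paths$manifest, auto_unbox = TRUE, digits = NA)
  utils::write.csv(fit$record, paths$loss, row.names = FALSE)
  utils::write.csv(
    data.frame(probe = rep(seq_along(counts),
                           vapply(counts, length, integer(1))),
               estimate = unlist(counts)),
    paths$counts, row.names = FALSE)
  jsonlite::write_json(
    list(summary = report$summary, freq = report$freq,
         hist2d = report$hist2d, bins = report$bins,
         clipped = report$clipped,
         spearman_target_sd = sv_summary$spearman_target_sd,
         note = sv_summary$note,
         pc1_monotone = emb$pc1_monotone,
         explained_variance_ratio = emb$explained_variance_ratio),
    paths$report, auto_unbox = TRUE, digits = NA, na = "null")
  utils::write.csv(sv_summary$table, paths$summary, row.names = FALSE)
  utils::write.csv(
    data.frame(numerosity = emb$numerosities, emb$scores,
               check.names = FALSE),
    paths$pca, row.names = FALSE)
  invisible(list(bundle_manifest = bundle$manifest, fit = fit,
                 counter = counter, batches = batches, counts = counts,
                 report = report, scalar_variability = sv_summary,
                 embedding = emb, paths = paths, out_dir = out_dir))
}
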