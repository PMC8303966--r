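# Text checkpoints: JSON with a format header, the configuration and every
# parameter table at 17 significant digits (exact IEEE double round trip).

CHECKPOINT_FORMAT <- "numerogen-checkpoint-1"

#' Save / load a model checkpoint
#'
#' Serializes the model configuration and all learned tables (`Wx`, `Ws`,
#' `WE`, encoder layers, head) to a single JSON file and restores them
#' exactly.
#'
#' @param model An `ng_model` (or `ng_fit`, in which case the fitted model is
#'   saved).
#' @param path File path.
#' @return `load_model` returns the restored `ng_model`.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "ng_fit")) model <- model$model
  stopifnot(inherits(model, "ng_model"))
  jsonlite::write_json(
    list(format = CHECKPOINT_FORMAT,
         config = unclass(model$config),
         params = model$params),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = TRUE)
  if (!identical(obj$format, CHECKPOINT_FORMAT))
    stop(sprintf("not a %s file", CHECKPOINT_FORMAT))
  cfg <- obj$config
  config <- model_config(width = cfg$width, height = cfg$height,
                         levels = cfg$p, numerosities = cfg$numerosities,
                         d = cfg$d, n_heads = cfg$n_heads, L = cfg$L,
                         ff_width = cfg$ff_width, dropout = cfg$dropout)
  structure(list(config = config, params = obj$params), class = "ng_model")
}

#' Save / load a fitted counter
#'
#' Counters (area or convolutional) round-trip through JSON alongside their
#' fitting manifest.
#'
#' @param counter An `area_counter` or `cnn_counter`.
#' @param path File path.
#' @return `load_counter` returns the restored counter.
#' @export
save_counter <- function(counter, path) {
  kind <- class(counter)[1]
  stopifnot(kind %in% c("area_counter", "cnn_counter"))
  jsonlite::write_json(list(format = "numerogen-counter-1", kind = kind,
                            payload = unclass(counter)),
                       path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_counter
#' @export
load_counter <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = TRUE)
  if (!identical(obj$format, "numerogen-counter-1"))
    stop("not a numerogen counter file")
  structure(obj$payload, class = obj$kind)
}
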