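# Dataset container and run configuration.
#
# Datasets are stored with R's native serialization plus strict schema
# validation on read: the container is a single file holding the epoch
# array, the parallel label/subject/session vectors, the sampling rate,
# class names and full generator/preprocessing provenance, so a run can be
# reproduced bit-for-bit. Configuration documents are YAML with every
# field defaulting to the pipeline's standard values.

dataset_schema <- c("epochs", "labels", "subjects", "sessions", "fs",
                    "class_names")

#' Write a dataset container
#'
#' @param dataset a `semg_dataset`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "semg_dataset"))
  saveRDS(unclass(dataset), path)
  invisible(path)
}

#' Read a dataset container
#'
#' Validates the schema: all required fields present, the epoch array 3-D,
#' parallel vectors of matching length, labels inside the class range.
#' Malformed files raise distinct errors.
#'
#' @param path file path written by [write_dataset()].
#' @return a `semg_dataset`.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("malformed dataset file: ", path))
  if (!is.list(obj)) stop("malformed dataset file: not a container")
  missing <- setdiff(dataset_schema, names(obj))
  if (length(missing))
    stop("dataset schema error: missing field(s) ",
         paste(missing, collapse = ", "))
  if (length(dim(obj$epochs)) != 3)
    stop("dataset schema error: epochs must be a 3-D array")
  n <- dim(obj$epochs)[1]
  if (length(obj$labels) != n || length(obj$subjects) != n ||
      length(obj$sessions) != n)
    stop("dataset schema error: parallel vectors do not match epoch count")
  new_semg_dataset(obj$epochs, obj$labels, obj$subjects, obj$sessions,
                   fs = obj$fs, class_names = obj$class_names,
                   provenance = obj$provenance)
}

#' Write / read a feature set
#'
#' @param features a `feature_set`.
#' @param path file path.
#' @return `path` invisibly / the `feature_set`.
#' @export
write_features <- function(features, path) {
  stopifnot(inherits(features, "feature_set"))
  saveRDS(unclass(features), path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("feature file not found: ", path)
  obj <- readRDS(path)
  need <- c("x", "labels", "method", "n_classes")
  missing <- setdiff(need, names(obj))
  if (length(missing))
    stop("feature schema error: missing field(s) ",
         paste(missing, collapse = ", "))
  if (length(dim(obj$x)) != 4)
    stop("feature schema error: x must be a 4-D array")
  structure(obj, class = "feature_set")
}

#' Save / load a fitted model
#'
#' The layer-graph environments are converted to plain lists for
#' serialization and rebuilt on load.
#'
#' @param net an `ssr_net`.
#' @param path file path.
#' @return `path` invisibly / the `ssr_net`.
#' @export
write_model <- function(net, path) {
  stopifnot(inherits(net, "ssr_net"))
  nn_clear_cache(net$graph)
  net$graph <- node_to_list(net$graph)
  saveRDS(net, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  net <- readRDS(path)
  if (!inherits(net, "ssr_net") || is.null(net$graph))
    stop("model schema error: not a serialized ssr_net")
  net$graph <- list_to_node(net$graph)
  net
}

node_to_list <- function(node) {
  out <- mget(ls(node), envir = node)
  for (nm in c("nodes", "branches", "mods"))
    if (!is.null(out[[nm]])) out[[nm]] <- lapply(out[[nm]], node_to_list)
  out
}

list_to_node <- function(lst) {
  e <- new.env(parent = emptyenv())
  for (nm in names(lst)) {
    v <- lst[[nm]]
    if (nm %in% c("nodes", "branches", "mods")) v <- lapply(v, list_to_node)
    assign(nm, v, envir = e)
  }
  class(e) <- "nn_node"
  e
}

# ---- run configuration -------------------------------------------------

default_run_config <- function() {
  list(
    synthetic = list(n_classes = 101L, n_channels = 6L, fs = 1000,
                     epoch_s = 2, n_subjects = 1L, n_sessions = 10L,
                     separation = 1, noise_sd = 0.2, powerline_amp = 0.5,
                     dc_offset_range = c(-0.5, 0.5), seed = 1L),
    filter = list(notch_freq = 50, notch_q = 30, band_low = 10,
                  band_high = 400, order = 4L),
    window = list(win_ms = 200, hop_ms = 50, trim_ms = 250),
    stft = list(fft_len = 200L, hop = 50L, n_mels = 36L, n_coeff = 12L,
                log_floor = 1e-10),
    model = list(n_channels = 6L, n_classes = 101L,
                 input_shape = c(36L, 36L), dimensionality = "2d",
                 conv_widths = c(128L, 128L, 256L, 256L, 512L, 512L),
                 pool_after = c(1L, 2L, 4L, 6L), dropout_rate = 0.25,
                 leaky_slope = 0.01),
    train = list(epochs = 30L, batch_size = 16L, lr = 1e-3,
                 validation_split = 0.1, split_fraction = 0.8, seed = 1L),
    transfer = list(k_range = 1:8, epochs = 10L, lr_scale = 0.1,
                    batch_size = 16L, seed = 1L)
  )
}

#' Load a run configuration
#'
#' Reads a YAML document, rejects unknown keys, fills defaults for any
#' omitted field, and validates the result by constructing each module's
#' specification object. An empty file yields all defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return a nested list of class `run_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    bad <- setdiff(names(user), names(cfg))
    if (length(bad))
      stop("unknown configuration section(s): ", paste(bad, collapse = ", "))
    for (sec in names(user)) {
      badk <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
      if (length(badk))
        stop("unknown key(s) in section '", sec, "': ",
             paste(badk, collapse = ", "))
      cfg[[sec]][names(user[[sec]])] <- user[[sec]]
    }
  }
  # validate by construction
  do.call(synthetic_spec, cfg$synthetic)
  do.call(filter_spec, cfg$filter)
  do.call(window_plan, cfg$window)
  do.call(stft_config, cfg$stft)
  do.call(model_spec, cfg$model)
  structure(cfg, class = "run_config")
}

#' Save a run configuration as YAML
#'
#' Round-trips losslessly through [load_config()].
#'
#' @param cfg a `run_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
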