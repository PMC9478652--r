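# Model architectures and training harness.
#
# The headline architecture is the Parallel Inception Convolutional Neural
# Network (PICNN): one inception module per sEMG channel, with independent
# (non-shared) weights so each muscle's regional features are learned
# separately; the six module outputs are concatenated across channels
# (6 x 96 = 576 feature maps at the defaults) and fed to a shared VGG-style
# convolution block ending in a global max pool and a softmax head. Two
# baselines share the engine: a halved-width VGG-style CNN and a
# single-trunk inception network that concatenates the channels first.
# Every convolution is followed by batch normalization and Leaky ReLU, and
# every max-pooling layer carries dropout.

#' Inception module hyperparameters
#'
#' Three parallel convolution paths with square kernels 1, 3 and 5 (their
#' 1-D counterparts for time-domain input), 32 feature maps each, with 1x1
#' dimension reductions in front of the 3x3 and 5x5 paths; outputs are
#' concatenated (3 x 32 = 96 maps) and max-pooled.
#'
#' @param kernel_sizes odd kernel sizes of the parallel paths.
#' @param maps_per_kernel feature maps per path (default 32).
#' @param reduction_width maps in the 1x1 reductions (default 32).
#' @param pool_after_concat add a max pool after concatenation (default
#'   TRUE).
#' @return an object of class `inception_spec`.
#' @export
inception_spec <- function(kernel_sizes = c(1, 3, 5), maps_per_kernel = 32,
                           reduction_width = 32, pool_after_concat = TRUE) {
  stopifnot(all(kernel_sizes %% 2 == 1), maps_per_kernel >= 1,
            reduction_width >= 1)
  structure(list(kernel_sizes = kernel_sizes,
                 maps_per_kernel = as.integer(maps_per_kernel),
                 reduction_width = as.integer(reduction_width),
                 pool_after_concat = isTRUE(pool_after_concat)),
            class = "inception_spec")
}

#' Model hyperparameters
#'
#' Fully determines a PICNN or baseline topology. The convolution block is
#' six 3x3 convolutions with VGG-style doubling widths, four interleaved
#' max-pooling layers (after convolutions 1, 2, 4 and 6) and one global max
#' pool; widths are configurable since smaller problems need smaller
#' blocks.
#'
#' @param n_channels number of sEMG channels (default 6).
#' @param n_classes number of output classes (default 101).
#' @param input_shape per-channel feature shape `c(d1, d2)`, e.g.
#'   `c(36, 36)` for MFSC or `c(32, 4)` for TD4.
#' @param dimensionality `"2d"` for spectral input (d1 x d2 spatial grid)
#'   or `"1d"` for windowed time-domain input (d1 time steps, d2 feature
#'   columns on the channel axis).
#' @param inception an [inception_spec()].
#' @param conv_widths widths of the six convolution-block layers.
#' @param pool_after indices of conv layers followed by a max pool
#'   (must name four of them).
#' @param dropout_rate dropout fraction on every max-pooling layer
#'   (default 0.25).
#' @param leaky_slope negative slope of the Leaky ReLU (default 0.01).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(n_channels = 6L, n_classes = 101L,
                       input_shape = c(36, 36),
                       dimensionality = c("2d", "1d"),
                       inception = inception_spec(),
                       conv_widths = c(128, 128, 256, 256, 512, 512),
                       pool_after = c(1, 2, 4, 6),
                       dropout_rate = 0.25, leaky_slope = 0.01) {
  dimensionality <- match.arg(dimensionality)
  stopifnot(is_count(n_channels), is_count(n_classes), n_classes >= 2,
            length(input_shape) == 2, length(conv_widths) == 6,
            length(pool_after) == 4, all(pool_after %in% seq_along(conv_widths)),
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(n_channels = as.integer(n_channels),
                 n_classes = as.integer(n_classes),
                 input_shape = as.integer(input_shape),
                 dimensionality = dimensionality,
                 inception = inception,
                 conv_widths = as.integer(conv_widths),
                 pool_after = as.integer(pool_after),
                 dropout_rate = dropout_rate,
                 leaky_slope = leaky_slope),
            class = "model_spec")
}

#' Derive a model specification from a feature set
#'
#' Picks 2-D convolutions for the spectral methods (STFT/MFCC/MFSC) and
#' 1-D convolutions for windowed time-domain features, and sizes the input
#' and output layers from the data.
#'
#' @param features a `feature_set` from [extract_features()].
#' @param ... overrides passed on to [model_spec()].
#' @return a [model_spec()].
#' @export
model_spec_for <- function(features, ...) {
  stopifnot(inherits(features, "feature_set"))
  d <- dim(features$x)
  dims <- if (features$method %in% c("STFT", "MFCC", "MFSC")) "2d" else "1d"
  args <- list(n_channels = d[2], n_classes = features$n_classes,
               input_shape = c(d[3], d[4]), dimensionality = dims)
  override <- list(...)
  args[names(override)] <- override
  do.call(model_spec, args)
}

# conv + batch norm + leaky ReLU; kernels are (k, k) in 2-D and (k, 1)
# in 1-D (the engine keeps 1-D tensors as height x 1).
conv_bn_act <- function(k, in_c, out_c, mode, slope, tag = NULL) {
  kw <- if (mode == "2d") k else 1
  list(nn_conv(k, kw, in_c, out_c, tag = tag), nn_bn(out_c), nn_act(slope))
}

#' Build one inception module
#'
#' Three parallel convolution paths (1x1 direct; 1x1 reduction then 3x3;
#' 1x1 reduction then 5x5), each followed by batch normalization and Leaky
#' ReLU, concatenated on the feature-map axis and max-pooled. At the
#' defaults the concatenation holds 96 feature maps.
#'
#' @param spec an [inception_spec()].
#' @param in_shape per-channel input shape `c(d1, d2)`.
#' @param in_c input feature maps (1 for a raw spectral channel).
#' @param mode `"2d"` or `"1d"`.
#' @param slope Leaky ReLU negative slope.
#' @param dropout_rate dropout on the trailing max pool.
#' @return an `nn_node` sequence tagged `"inception"`.
#' @export
build_inception_module <- function(spec = inception_spec(),
                                   in_shape = c(36, 36), in_c = 1,
                                   mode = c("2d", "1d"), slope = 0.01,
                                   dropout_rate = 0.25) {
  mode <- match.arg(mode)
  kmax <- max(spec$kernel_sizes)
  spatial <- if (mode == "2d") in_shape else in_shape[1]
  if (any(spatial < kmax))
    stop("input spatial dimensions are smaller than the largest kernel")
  branches <- lapply(spec$kernel_sizes, function(k) {
    layers <- if (k == 1) {
      conv_bn_act(1, in_c, spec$maps_per_kernel, mode, slope)
    } else {
      c(conv_bn_act(1, in_c, spec$reduction_width, mode, slope),
        conv_bn_act(k, spec$reduction_width, spec$maps_per_kernel, mode,
                    slope))
    }
    nn_seq(layers)
  })
  concat_maps <- length(spec$kernel_sizes) * spec$maps_per_kernel
  parts <- list(nn_branches(branches, tag = "inception_concat",
                            meta = list(out_maps = concat_maps)))
  if (spec$pool_after_concat) {
    parts <- c(parts,
               list(if (mode == "2d") nn_pool(2, 2) else nn_pool(2, 1),
                    nn_drop(dropout_rate)))
  }
  nn_seq(parts, tag = "inception")
}

# Shared convolution block + head used by all three architectures.
conv_block_head <- function(spec, in_c) {
  mode <- spec$dimensionality
  layers <- list()
  cur <- in_c
  for (i in seq_along(spec$conv_widths)) {
    w <- spec$conv_widths[i]
    layers <- c(layers, conv_bn_act(3, cur, w, mode, spec$leaky_slope,
                                    tag = "block_conv"))
    cur <- w
    if (i %in% spec$pool_after) {
      layers <- c(layers,
                  list(if (mode == "2d") nn_pool(2, 2, tag = "block_pool")
                       else nn_pool(2, 1, tag = "block_pool"),
                       nn_drop(spec$dropout_rate)))
    }
  }
  layers <- c(layers, list(nn_gpool(tag = "global_pool"),
                           nn_dense(cur, spec$n_classes, tag = "head")))
  layers
}

new_ssr_net <- function(graph, spec, arch) {
  structure(list(graph = graph, spec = spec, arch = arch,
                 norm = NULL, history = NULL, trained = FALSE,
                 control = NULL),
            class = c(arch, "ssr_net"))
}

#' Build an untrained PICNN
#'
#' One independently weighted inception module per channel; module outputs
#' concatenated across channels (576 maps at the defaults), followed by the
#' convolution block (six convolutions, four max pools, one global max
#' pool) and a softmax head of width `n_classes`.
#'
#' @param spec a [model_spec()].
#' @return an untrained model of class `c("picnn", "ssr_net")`.
#' @examples
#' net <- build_picnn(model_spec(n_classes = 10, input_shape = c(32, 4),
#'                               dimensionality = "1d",
#'                               conv_widths = c(32, 32, 64, 64, 96, 96)))
#' model_audit(net)$concat_maps
#' @export
build_picnn <- function(spec = model_spec()) {
  stopifnot(inherits(spec, "model_spec"))
  mode <- spec$dimensionality
  in_c <- if (mode == "2d") 1 else spec$input_shape[2]
  mods <- lapply(seq_len(spec$n_channels), function(ch)
    build_inception_module(spec$inception, spec$input_shape, in_c, mode,
                           spec$leaky_slope, spec$dropout_rate))
  maps_per <- length(spec$inception$kernel_sizes) *
    spec$inception$maps_per_kernel
  concat <- nn_channels(mods, mode, tag = "channel_concat",
                        meta = list(out_maps = maps_per * spec$n_channels))
  graph <- nn_seq(c(list(concat), conv_block_head(spec,
                                                  maps_per * spec$n_channels)))
  new_ssr_net(graph, spec, "picnn")
}

# VGG16 reference widths, grouped by pooling block.
vgg_blocks <- list(c(64, 64), c(128, 128), c(256, 256, 256),
                   c(512, 512, 512), c(512, 512, 512))

#' Build the VGG-style CNN baseline
#'
#' Stacked 3x3 convolution blocks patterned on VGG16 with every width
#' halved (`width_scale = 0.5`) and trailing blocks dropped once the
#' spatial extent of the input is exhausted, ending in a global max pool
#' and softmax head. Channels are concatenated into one input.
#'
#' @param spec a [model_spec()].
#' @param width_scale multiplier on the reference widths (default 0.5).
#' @return an untrained model of class `c("cnn_vgg", "ssr_net")`.
#' @export
build_cnn_baseline <- function(spec = model_spec(), width_scale = 0.5) {
  stopifnot(inherits(spec, "model_spec"), width_scale > 0)
  mode <- spec$dimensionality
  in_c <- if (mode == "2d") spec$n_channels
          else spec$n_channels * spec$input_shape[2]
  layers <- list(nn_concat_input(mode))
  spatial <- spec$input_shape[1]
  cur <- in_c
  for (blk in vgg_blocks) {
    if (spatial < 2) break  # truncated to fit the input extent
    for (w in blk) {
      w <- max(1L, as.integer(round(w * width_scale)))
      layers <- c(layers, conv_bn_act(3, cur, w, mode, spec$leaky_slope,
                                      tag = "vgg_conv"))
      cur <- w
    }
    layers <- c(layers,
                list(if (mode == "2d") nn_pool(2, 2, tag = "vgg_pool")
                     else nn_pool(2, 1, tag = "vgg_pool"),
                     nn_drop(spec$dropout_rate)))
    spatial <- spatial %/% 2
  }
  layers <- c(layers, list(nn_gpool(tag = "global_pool"),
                           nn_dense(cur, spec$n_classes, tag = "head")))
  new_ssr_net(nn_seq(layers), spec, "cnn_vgg")
}

#' Build the single-trunk inception baseline
#'
#' Channels are first concatenated into one larger input, fed through a
#' single inception stage (1x1 / 3x3 / 5x5 paths, 96 concatenated maps at
#' the defaults) and then the same deep convolution block and softmax head
#' as the PICNN.
#'
#' @param spec a [model_spec()].
#' @return an untrained model of class `c("inception_net", "ssr_net")`.
#' @export
build_inception_baseline <- function(spec = model_spec()) {
  stopifnot(inherits(spec, "model_spec"))
  mode <- spec$dimensionality
  in_c <- if (mode == "2d") spec$n_channels
          else spec$n_channels * spec$input_shape[2]
  stage <- build_inception_module(spec$inception, spec$input_shape, in_c,
                                  mode, spec$leaky_slope, spec$dropout_rate)
  maps <- length(spec$inception$kernel_sizes) *
    spec$inception$maps_per_kernel
  graph <- nn_seq(c(list(nn_concat_input(mode), stage),
                    conv_block_head(spec, maps)))
  new_ssr_net(graph, spec, "inception_net")
}

#' Structural audit of a built network
#'
#' Walks the layer graph and counts the printed structural facts of the
#' architecture: inception modules and their concatenated maps, the
#' cross-channel concatenation width, convolution-block layers, pooling
#' layers, and the width of the softmax head.
#'
#' @param net an `ssr_net`.
#' @return a list with `n_inception_modules`, `maps_per_module`,
#'   `concat_maps`, `n_block_conv`, `n_block_pool`, `n_global_pool`,
#'   `head_width`, `n_params`.
#' @export
model_audit <- function(net) {
  stopifnot(inherits(net, "ssr_net"))
  nodes <- nn_collect(net$graph)
  tagged <- function(tg) Filter(function(e) identical(e$tag, tg), nodes)
  inc <- tagged("inception_concat")
  chan <- tagged("channel_concat")
  head <- tagged("head")
  list(
    n_inception_modules = length(inc),
    maps_per_module = if (length(inc)) inc[[1]]$meta$out_maps else 0L,
    concat_maps = if (length(chan)) chan[[1]]$meta$out_maps
                  else if (length(inc)) inc[[1]]$meta$out_maps else 0L,
    n_block_conv = length(tagged("block_conv")),
    n_block_pool = length(tagged("block_pool")),
    n_global_pool = length(tagged("global_pool")),
    head_width = if (length(head)) head[[1]]$n_out else NA_integer_,
    n_params = nn_count_params(net$graph)
  )
}

#' Count trainable parameters
#'
#' @param net an `ssr_net`.
#' @return integer parameter count.
#' @export
count_params <- function(net) nn_count_params(net$graph)

#' Training configuration
#'
#' The optimizer is Adam with categorical cross-entropy loss; none of these
#' settings are dictated by the recognition problem itself, so they are all
#' recorded on the fitted model for reproducibility.
#'
#' @param epochs training epochs (default 30).
#' @param batch_size minibatch size (default 16).
#' @param lr Adam learning rate (default 1e-3).
#' @param validation_split fraction of the training data held out for
#'   per-epoch validation metrics (default 0.1).
#' @param patience early-stopping patience on validation loss; `Inf`
#'   (default) disables early stopping so the epoch count is exact.
#' @param split_fraction train share of the utterance-level 80/20 split
#'   used by [split_dataset()].
#' @param seed integer seed controlling weight initialization, shuffling
#'   and dropout.
#' @param verbose print per-epoch progress.
#' @return an object of class `train_control`.
#' @export
train_control <- function(epochs = 30, batch_size = 16, lr = 1e-3,
                          validation_split = 0.1, patience = Inf,
                          split_fraction = 0.8, seed = 1L, verbose = FALSE) {
  stopifnot(epochs >= 1, batch_size >= 1, lr >= 0,
            validation_split >= 0, validation_split < 1,
            split_fraction > 0, split_fraction < 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 validation_split = validation_split, patience = patience,
                 split_fraction = split_fraction, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "train_control")
}

# Subset a feature_set by epoch indices.
feature_subset <- function(fs, idx) {
  structure(list(x = fs$x[idx, , , , drop = FALSE], labels = fs$labels[idx],
                 subjects = fs$subjects[idx], sessions = fs$sessions[idx],
                 method = fs$method, n_classes = fs$n_classes),
            class = "feature_set")
}

#' Shuffled utterance-level train/test split
#'
#' Shuffles all utterances (mixing subjects and sessions, since the goal is
#' overall recognition ability rather than per-subject scores) and splits
#' `round(frac * N)` (round-half-up) into the training portion.
#'
#' @param features a `feature_set`.
#' @param control a [train_control()]; supplies `split_fraction` and
#'   `seed`.
#' @return list with `train` and `test` feature sets.
#' @export
split_dataset <- function(features, control = train_control()) {
  stopifnot(inherits(features, "feature_set"))
  n <- dim(features$x)[1]
  idx <- with_seed(stable_seed(control$seed, 555L), sample.int(n))
  n_train <- round_half_up(control$split_fraction * n)
  list(train = feature_subset(features, idx[seq_len(n_train)]),
       test = feature_subset(features, idx[-seq_len(n_train)]))
}

# Per-cell standardization statistics over the training epochs.
norm_stats <- function(x) {
  mu <- apply(x, c(2, 3, 4), mean)
  sd <- apply(x, c(2, 3, 4), stats::sd)
  sd[!is.finite(sd) | sd < 1e-8] <- 1
  list(mu = mu, sd = sd)
}

apply_norm <- function(x, norm) {
  n <- dim(x)[1]
  mu <- array(rep(norm$mu, each = n), dim(x))
  sd <- array(rep(norm$sd, each = n), dim(x))
  (x - mu) / sd
}

#' Train a network
#'
#' Minibatch Adam on softmax cross-entropy. Input features are
#' standardized cell-wise with statistics of the training set (stored on
#' the model and reapplied at prediction time). Deterministic for a fixed
#' seed in single-threaded execution.
#'
#' @param net an `ssr_net` from one of the `build_*` functions (an
#'   already-trained net continues training from its current weights).
#' @param features a `feature_set`, or a bare `n x channels x d1 x d2`
#'   array when `labels` is given.
#' @param labels optional 0-based integer labels (taken from `features`
#'   when it is a `feature_set`).
#' @param control a [train_control()].
#' @param lr_scale multiplier on `control$lr` (used by fine-tuning).
#' @return the trained `ssr_net`, with a `history` data frame of per-epoch
#'   train/validation loss and accuracy.
#' @export
train_net <- function(net, features, labels = NULL,
                      control = train_control(), lr_scale = 1) {
  stopifnot(inherits(net, "ssr_net"))
  if (inherits(features, "feature_set")) {
    labels <- labels %||% features$labels
    x <- features$x
  } else x <- features
  if (is.null(labels) || length(labels) != dim(x)[1])
    stop("labels are missing or do not match the number of epochs")
  n <- dim(x)[1]
  if (n == 0) stop("empty training set")
  if (max(labels) >= net$spec$n_classes || min(labels) < 0)
    stop("labels outside the model's class range")

  set.seed(control$seed)
  if (is.null(net$norm)) net$norm <- norm_stats(x)
  x <- apply_norm(x, net$norm)

  n_val <- floor(control$validation_split * n)
  val_idx <- if (n_val > 0) sample.int(n, n_val) else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)

  lr <- control$lr * lr_scale
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     acc = numeric(0), val_loss = numeric(0),
                     val_acc = numeric(0))
  best_val <- Inf; wait <- 0; step <- 0L
  for (ep in seq_len(control$epochs)) {
    ord <- sample(tr_idx)
    ep_loss <- 0; ep_hits <- 0
    for (s in seq(1, length(ord), by = control$batch_size)) {
      bi <- ord[s:min(s + control$batch_size - 1, length(ord))]
      xb <- x[bi, , , , drop = FALSE]
      yb <- labels[bi]
      nn_zero_grads(net$graph)
      logits <- nn_forward(net$graph, xb, train = TRUE)
      lo <- nn_softmax_ce(logits, yb)
      nn_backward(net$graph, lo$grad)
      step <- step + 1L
      nn_adam_step(net$graph, lr, t = step)
      ep_loss <- ep_loss + lo$loss * length(bi)
      ep_hits <- ep_hits + sum(max.col(lo$prob) - 1L == yb)
    }
    val <- c(NA_real_, NA_real_)
    if (length(val_idx) > 0) {
      vlogit <- nn_forward(net$graph, x[val_idx, , , , drop = FALSE],
                           train = FALSE)
      vl <- nn_softmax_ce(vlogit, labels[val_idx])
      val <- c(vl$loss, mean(max.col(vl$prob) - 1L == labels[val_idx]))
    }
    hist <- rbind(hist, data.frame(
      epoch = ep, loss = ep_loss / length(ord),
      acc = ep_hits / length(ord), val_loss = val[1], val_acc = val[2]))
    if (control$verbose)
      message(sprintf("epoch %d  loss %.4f  acc %.3f  val_acc %.3f",
                      ep, ep_loss / length(ord), ep_hits / length(ord),
                      val[2]))
    if (is.finite(control$patience) && length(val_idx) > 0) {
      if (val[1] < best_val - 1e-6) { best_val <- val[1]; wait <- 0 }
      else {
        wait <- wait + 1
        if (wait >= control$patience) break
      }
    }
  }
  nn_clear_cache(net$graph)
  net$history <- hist
  net$trained <- TRUE
  net$control <- control
  net
}

#' Fit a PICNN to a feature set
#'
#' Convenience wrapper: derives the model specification from the features,
#' seeds weight initialization, builds the network and trains it.
#'
#' @param features a `feature_set`.
#' @param spec a [model_spec()] (default derived with [model_spec_for()]).
#' @param control a [train_control()].
#' @return a trained `c("picnn", "ssr_net")` model.
#' @export
picnn <- function(features, spec = NULL, control = train_control()) {
  stopifnot(inherits(features, "feature_set"))
  spec <- spec %||% model_spec_for(features)
  set.seed(control$seed)
  net <- build_picnn(spec)
  train_net(net, features, control = control)
}

#' Predict class probabilities or labels
#'
#' Inference mode: batch normalization uses running statistics and dropout
#' is inactive, so predictions are deterministic for fixed weights.
#'
#' @param object an `ssr_net`.
#' @param newdata a `feature_set` or feature array.
#' @param type `"prob"` for the class-probability matrix (rows on the
#'   simplex) or `"class"` for 0-based predicted labels.
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @return probability matrix or integer label vector.
#' @export
predict.ssr_net <- function(object, newdata, type = c("prob", "class"),
                            batch_size = 64, ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "feature_set")) newdata$x else newdata
  if (length(dim(x)) == 3) x <- array(x, c(1, dim(x)))
  if (!is.null(object$norm)) x <- apply_norm(x, object$norm)
  n <- dim(x)[1]
  probs <- matrix(0, n, object$spec$n_classes)
  for (s in seq(1, n, by = batch_size)) {
    bi <- s:min(s + batch_size - 1, n)
    logits <- nn_forward(object$graph, x[bi, , , , drop = FALSE],
                         train = FALSE)
    probs[bi, ] <- nn_softmax(logits)
  }
  if (type == "prob") probs else as.integer(max.col(probs) - 1L)
}

#' @export
print.ssr_net <- function(x, ...) {
  au <- model_audit(x)
  cat(sprintf("<%s> %s input %s, %d classes, %s parameters%s\n",
              x$arch, x$spec$dimensionality,
              paste(x$spec$input_shape, collapse = "x"),
              x$spec$n_classes, format(au$n_params, big.mark = ","),
              if (x$trained) " (trained)" else " (untrained)"))
  if (au$n_inception_modules > 0)
    cat(sprintf("  %d inception module(s) x %d maps -> %d concatenated\n",
                au$n_inception_modules, au$maps_per_module, au$concat_maps))
  invisible(x)
}

#' @export
summary.ssr_net <- function(object, ...) {
  print(object)
  au <- model_audit(object)
  cat(sprintf("  conv block: %d conv / %d pool / %d global pool; head %d\n",
              au$n_block_conv, au$n_block_pool, au$n_global_pool,
              au$head_width))
  if (!is.null(object$history)) {
    h <- utils::tail(object$history, 1)
    cat(sprintf("  final epoch %d: loss %.4f acc %.3f val_acc %s\n",
                h$epoch, h$loss, h$acc,
                ifelse(is.na(h$val_acc), "-", sprintf("%.3f", h$val_acc))))
  }
  invisible(au)
}

#' @export
plot.ssr_net <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  h <- x$history
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch", ylab = "loss",
                 main = paste(x$arch, "training history"), ...)
  if (any(!is.na(h$val_loss)))
    graphics::lines(h$epoch, h$val_loss, lty = 2)
  graphics::legend("topright", c("train", "validation"), lty = c(1, 2),
                   bty = "n")
  invisible(h)
}
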