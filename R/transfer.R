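# Subject-based transfer learning: fine-tune a pretrained network on the
# leading k sessions of a new subject and evaluate on the remaining
# sessions. Sessions are the adaptation unit (chronological, not random
# utterances), mimicking deployment where early sessions are labelled.

#' Transfer-learning configuration
#'
#' @param k_range session counts used for fine-tuning (default 1..8).
#' @param epochs fine-tuning epochs per k (default 10).
#' @param lr_scale learning-rate multiplier relative to pretraining
#'   (default 0.1).
#' @param freeze character vector of layer tags to freeze (default none:
#'   all layers are updated).
#' @param batch_size fine-tuning minibatch size.
#' @param seed integer seed for fine-tuning shuffling/dropout.
#' @return an object of class `transfer_control`.
#' @export
transfer_control <- function(k_range = 1:8, epochs = 10, lr_scale = 0.1,
                             freeze = character(0), batch_size = 16,
                             seed = 1L) {
  stopifnot(all(k_range >= 0), epochs >= 0, lr_scale >= 0, batch_size >= 1)
  structure(list(k_range = as.integer(k_range), epochs = as.integer(epochs),
                 lr_scale = lr_scale, freeze = freeze,
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "transfer_control")
}

#' Split a subject's data by leading sessions
#'
#' The fine-tuning set is the first `k` sessions (by session index); the
#' test set is every remaining session. Because each session contains
#' every class once, the fine-tuning set covers all classes whenever
#' `k >= 1`.
#'
#' @param features a `feature_set` holding one subject's data.
#' @param k number of leading sessions for fine-tuning (0 for none).
#' @return list with `tune` and `test` feature sets and the session index
#'   vectors `tune_sessions`, `test_sessions`.
#' @export
session_split <- function(features, k) {
  stopifnot(inherits(features, "feature_set"), is_count(k))
  sess <- sort(unique(features$sessions))
  if (k >= length(sess))
    stop("k must leave at least one session for testing")
  tune_s <- sess[seq_len(k)]
  test_s <- setdiff(sess, tune_s)
  list(tune = feature_subset(features, which(features$sessions %in% tune_s)),
       test = feature_subset(features, which(features$sessions %in% test_s)),
       tune_sessions = tune_s, test_sessions = test_s)
}

#' Fine-tune a pretrained network
#'
#' Clones the pretrained model (the original is never mutated), optionally
#' freezes layers by tag, resets the optimizer state, and continues
#' training on the new data at `lr_scale` times the pretraining learning
#' rate. The pretrained feature normalization is kept so new data is
#' mapped into the same input space. With `epochs = 0` (or an empty
#' tuning set and `k = 0` workflows) the clone equals the original.
#'
#' @param net a trained `ssr_net`.
#' @param features a `feature_set` of new-subject data.
#' @param control a [transfer_control()].
#' @return the adapted `ssr_net`.
#' @export
fine_tune <- function(net, features, control = transfer_control()) {
  stopifnot(inherits(net, "ssr_net"), inherits(features, "feature_set"))
  d <- dim(features$x)
  if (!identical(as.integer(d[2:4]),
                 as.integer(c(net$spec$n_channels, net$spec$input_shape))))
    stop("feature shape does not match the pretrained model specification")
  adapted <- net
  adapted$graph <- nn_clone(net$graph)
  nn_reset_optimizer(adapted$graph)
  if (length(control$freeze))
    for (e in nn_collect(adapted$graph))
      if (!is.null(e$tag) && e$tag %in% control$freeze) e$trainable <- FALSE
  if (control$epochs == 0 || dim(features$x)[1] == 0) return(adapted)
  base <- net$control %||% train_control()
  ctl <- train_control(epochs = control$epochs,
                       batch_size = control$batch_size,
                       lr = base$lr, validation_split = 0,
                       seed = control$seed)
  train_net(adapted, features, control = ctl, lr_scale = control$lr_scale)
}

#' Fit a logarithmic trendline a*ln(k) + b
#'
#' @param k positive session counts.
#' @param acc accuracies at each k.
#' @return named vector `c(a, b)`.
#' @export
log_trendline <- function(k, acc) {
  stopifnot(all(k > 0), length(k) == length(acc))
  if (length(unique(k)) < 2) return(c(a = NA_real_, b = mean(acc)))
  co <- stats::coef(stats::lm(acc ~ log(k)))
  c(a = unname(co[2]), b = unname(co[1]))
}

#' Transfer-learning accuracy curve
#'
#' For each `k` in `k_range`: split the subject's sessions, fine-tune the
#' pretrained model on the first `k`, and evaluate on the rest (for
#' `k = 0` the unadapted model is evaluated on all sessions' remainder
#' split, i.e. all sessions). Fine-tune and test session indices are
#' asserted disjoint, and the pretrained model's weights are verified
#' unchanged afterwards. A logarithmic trendline `a*ln(k) + b` is fitted
#' to the k >= 1 points.
#'
#' @param net a trained `ssr_net`.
#' @param features a `feature_set` with one subject's data.
#' @param control a [transfer_control()].
#' @return object of class `transfer_curve`: data frame `points`
#'   (`k`, `accuracy`, `n_test`) plus `trendline`.
#' @export
transfer_curve <- function(net, features, control = transfer_control()) {
  stopifnot(inherits(net, "ssr_net"))
  before <- nn_flatten_params(net$graph)
  pts <- lapply(control$k_range, function(k) {
    sp <- session_split(features, k)
    stopifnot(length(intersect(sp$tune_sessions, sp$test_sessions)) == 0)
    model <- if (k == 0) net else fine_tune(net, sp$tune, control)
    rep_k <- evaluate_model(model, sp$test)
    data.frame(k = k, accuracy = rep_k$accuracy,
               n_test = dim(sp$test$x)[1])
  })
  pts <- do.call(rbind, pts)
  after <- nn_flatten_params(net$graph)
  if (!isTRUE(all.equal(before, after)))
    stop("internal error: pretrained model was mutated during the curve")
  pos <- pts$k > 0
  structure(list(points = pts,
                 trendline = log_trendline(pts$k[pos], pts$accuracy[pos])),
            class = "transfer_curve")
}

#' @export
print.transfer_curve <- function(x, ...) {
  cat("<transfer_curve>\n")
  print(x$points, row.names = FALSE)
  if (!is.na(x$trendline["a"]))
    cat(sprintf("  trendline: %.4f * ln(k) + %.4f\n",
                x$trendline["a"], x$trendline["b"]))
  invisible(x)
}

#' @export
plot.transfer_curve <- function(x, ...) {
  p <- x$points
  graphics::plot(p$k, p$accuracy, type = "b", xlab = "fine-tuning sessions k",
                 ylab = "held-out accuracy", ...)
  if (!is.na(x$trendline["a"])) {
    ks <- seq(max(1, min(p$k)), max(p$k), length.out = 50)
    graphics::lines(ks, x$trendline["a"] * log(ks) + x$trendline["b"],
                    lty = 2)
  }
  invisible(p)
}
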