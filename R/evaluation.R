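# Evaluation statistics: confusion matrix, overall accuracy, per-class
# recognition rates (recall), dispersion summary and worst-k listing.

#' Confusion matrix from label pairs
#'
#' @param truth 0-based true labels.
#' @param pred 0-based predicted labels, same length.
#' @param n_classes number of classes.
#' @return `n_classes x n_classes` count matrix, rows = true class,
#'   columns = predicted class; dimnames are the 0-based labels.
#' @export
confusion_matrix <- function(truth, pred, n_classes) {
  stopifnot(length(truth) == length(pred), is_count(n_classes))
  if (length(truth) &&
      (min(truth, pred) < 0 || max(truth, pred) >= n_classes))
    stop("label out of range [0, n_classes)")
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(true = 0:(n_classes - 1),
                               pred = 0:(n_classes - 1)))
  for (i in seq_along(truth))
    cm[truth[i] + 1L, pred[i] + 1L] <- cm[truth[i] + 1L, pred[i] + 1L] + 1L
  cm
}

#' Overall classification accuracy
#'
#' Number of correctly predicted labels over the total number of labels;
#' equivalently the trace of the confusion matrix over its sum.
#'
#' @param truth 0-based true labels, or a confusion matrix (then `pred`
#'   is ignored).
#' @param pred 0-based predicted labels.
#' @return fraction in \[0, 1\].
#' @export
accuracy <- function(truth, pred = NULL) {
  if (is.matrix(truth)) return(sum(diag(truth)) / sum(truth))
  stopifnot(length(truth) == length(pred))
  mean(truth == pred)
}

#' Per-class recognition rates
#'
#' Recognition rate of class i is `TP / (TP + FN)` — the diagonal entry
#' over the row sum, i.e. per-class recall. Classes absent from the test
#' data (empty rows) get `NA` and are flagged, not errors.
#'
#' @param confusion a confusion matrix (rows = true class).
#' @return numeric vector of rates, `NA` for empty rows; names are the
#'   0-based labels.
#' @export
recognition_rates <- function(confusion) {
  rs <- rowSums(confusion)
  r <- ifelse(rs > 0, diag(confusion) / rs, NA_real_)
  names(r) <- rownames(confusion) %||% as.character(0:(nrow(confusion) - 1))
  r
}

#' Min / mean / population-SD summary of recognition rates
#'
#' The standard deviation is the population form (divide by the number of
#' classes, not n-1): a descriptive dispersion over the fixed class set.
#' `NA` rates (classes absent from the test data) are excluded.
#'
#' @param rates vector from [recognition_rates()].
#' @return list with `min`, `mean`, `sd`, `n_classes` (number summarized).
#' @export
rate_summary <- function(rates) {
  r <- rates[!is.na(rates)]
  if (length(r) == 0) return(list(min = NA_real_, mean = NA_real_,
                                  sd = NA_real_, n_classes = 0L))
  list(min = min(r), mean = mean(r),
       sd = sqrt(mean((r - mean(r))^2)), n_classes = length(r))
}

#' Worst-k classes report
#'
#' The `k` classes with the lowest recognition rate (ascending, ties broken
#' by label index), each with its list of misclassification targets
#' `(wrong label, count)` for counts > 0, sorted by wrong-label index
#' descending. Classes absent from the test data are excluded.
#'
#' @param confusion a confusion matrix.
#' @param k number of classes to list.
#' @return a list of `k` entries, each with `label` (0-based), `rate`, and
#'   `misclassified` (named integer vector, names = 0-based wrong labels).
#' @export
worst_k_report <- function(confusion, k) {
  n <- nrow(confusion)
  if (k > n) stop("k exceeds the number of classes")
  rates <- recognition_rates(confusion)
  present <- which(!is.na(rates))
  if (k > length(present))
    stop("k exceeds the number of classes present in the data")
  ord <- unname(present[order(rates[present], present)])
  lapply(ord[seq_len(k)], function(i) {
    row <- confusion[i, ]
    row[i] <- 0
    wrong <- which(row > 0)
    wrong <- wrong[order(wrong, decreasing = TRUE)]
    mis <- as.integer(row[wrong])
    names(mis) <- as.character(wrong - 1L)
    list(label = i - 1L, rate = unname(rates[i]), misclassified = mis)
  })
}

#' Full evaluation report
#'
#' @param truth 0-based true labels.
#' @param pred 0-based predicted labels.
#' @param n_classes number of classes.
#' @param k number of worst classes to list (default `min(10, n_classes)`).
#' @return object of class `ssr_eval`: list with `confusion`, `accuracy`,
#'   `rates`, `summary`, `worst_k`.
#' @export
eval_report <- function(truth, pred, n_classes,
                        k = min(10L, n_classes)) {
  cm <- confusion_matrix(truth, pred, n_classes)
  rates <- recognition_rates(cm)
  k <- min(k, sum(!is.na(rates)))
  structure(list(confusion = cm, accuracy = accuracy(cm), rates = rates,
                 summary = rate_summary(rates),
                 worst_k = worst_k_report(cm, k)),
            class = "ssr_eval")
}

#' @export
print.ssr_eval <- function(x, ...) {
  cat(sprintf("<ssr_eval> accuracy %.4f over %d items, %d classes\n",
              x$accuracy, sum(x$confusion), nrow(x$confusion)))
  s <- x$summary
  cat(sprintf("  recognition rates: min %.3f  mean %.3f  sd %.3f (%d classes)\n",
              s$min, s$mean, s$sd, s$n_classes))
  if (length(x$worst_k)) {
    w <- x$worst_k[[1]]
    cat(sprintf("  worst class: %d (rate %.3f)\n", w$label, w$rate))
  }
  invisible(x)
}

#' Evaluate a model on a feature set
#'
#' @param net a trained `ssr_net`.
#' @param features a `feature_set` with labels.
#' @param ... passed to [eval_report()].
#' @return an `ssr_eval` report.
#' @export
evaluate_model <- function(net, features, ...) {
  pred <- predict(net, features, type = "class")
  eval_report(features$labels, pred, net$spec$n_classes, ...)
}
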