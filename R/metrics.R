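#' Balanced accuracy from a confusion matrix
#'
#' Mean over classes of per-class recall (correct / total per true class),
#' robust to class imbalance in the test set.
#'
#' @param confusion `[K x K]` matrix of counts, rows = true class,
#'   columns = predicted class.
#' @return fraction in `[0, 1]`.
#' @export
balanced_accuracy <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion))
    stop("confusion matrix must be square")
  if (any(confusion < 0)) stop("confusion counts must be nonnegative")
  rs <- rowSums(confusion)
  if (any(rs == 0)) stop("every class needs at least one test sample")
  mean(diag(confusion) / rs)
}

#' Information transfer rate
#'
#' `(60/T) * [log2 N + P log2 P + (1-P) log2((1-P)/(N-1))]` bits per minute,
#' with the `0 * log 0 := 0` convention at `P = 0` and `P = 1`. Accuracies
#' below chance (`P < 1/N`) are floored to 0 bits/min, since the formula
#' would otherwise rise again for adversarially wrong classifiers.
#'
#' @param N number of stimuli (>= 2).
#' @param P classification accuracy in `[0, 1]`.
#' @param T_sec time per selection in seconds (> 0).
#' @return bits per minute.
#' @export
itr <- function(N, P, T_sec) {
  if (N < 2) stop("N must be >= 2")
  if (P < 0 || P > 1) stop("P must lie in [0, 1]")
  if (T_sec <= 0) stop("T_sec must be > 0")
  if (P < 1 / N) return(0)
  xlx <- function(p) if (p <= 0) 0 else p * log2(p)
  bits <- log2(N) + xlx(P) +
    if (P >= 1) 0 else (1 - P) * log2((1 - P) / (N - 1))
  max(0, 60 / T_sec * bits)
}

#' Evaluate per-fold models on held-out trials
#'
#' Accumulates a confusion matrix over the test trials of every fold,
#' then reports balanced accuracy and the information transfer rate with
#' selection time `T = window length + overhead`.
#'
#' @param models list of fitted models, one per fold; each must have a
#'   `predict` method returning 0-based labels for an `epoched_eeg`.
#' @param split a [kfold_trial_split()] plan.
#' @param data the `epoched_eeg` the plan indexes into.
#' @param selection_time_overhead gaze-shift overhead added to the data
#'   window when computing ITR (seconds, default 0.5).
#' @return an `eval_report`: confusion matrix, `balanced_accuracy`, `itr`
#'   (bits/min), selection time and per-fold accuracies.
#' @export
evaluate <- function(models, split, data, selection_time_overhead = 0.5) {
  stopifnot(inherits(split, "split_plan"), inherits(data, "epoched_eeg"))
  if (length(models) != length(split$folds))
    stop(sprintf("%d models for %d folds", length(models),
                 length(split$folds)))
  K <- data$n_classes
  confusion <- matrix(0L, K, K)
  fold_acc <- numeric(length(models))
  for (f in seq_along(models)) {
    test <- subset_trials(data, split$folds[[f]]$test)
    pred <- predict(models[[f]], test)
    for (i in seq_len(n_trials(test)))
      confusion[test$labels[i] + 1L, pred[i] + 1L] <-
        confusion[test$labels[i] + 1L, pred[i] + 1L] + 1L
    fold_acc[f] <- mean(pred == test$labels)
  }
  t_sel <- n_samples(data) / data$fs + selection_time_overhead
  structure(list(confusion = confusion,
                 balanced_accuracy = balanced_accuracy(confusion),
                 itr = itr(K, sum(diag(confusion)) / sum(confusion), t_sel),
                 selection_time = t_sel,
                 fold_accuracy = fold_acc),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "eval_report: BA %.3f | ITR %.1f bits/min (T = %.2f s) | %d folds\n",
    x$balanced_accuracy, x$itr, x$selection_time, length(x$fold_accuracy)))
  invisible(x)
}
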