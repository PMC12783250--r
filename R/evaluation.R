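# Threshold-based classification metrics and continuous Boyce validation.

confusion_metrics <- function(threshold, predictions, truth) {
  pos <- predictions >= threshold
  tp <- sum(pos & truth == 1); fp <- sum(pos & truth == 0)
  fn <- sum(!pos & truth == 1); tn <- sum(!pos & truth == 0)
  n <- tp + fp + fn + tn
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  p_o <- (tp + tn) / n
  p_e <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (abs(1 - p_e) < 1e-15) 0 else (p_o - p_e) / (1 - p_e)
  data.frame(threshold = threshold, tp = tp, fp = fp, tn = tn, fn = fn,
             sensitivity = sens, specificity = spec,
             tss = sens + spec - 1, binary_auc = (sens + spec) / 2,
             kappa = kappa)
}

#' Sweep classification thresholds over model predictions
#'
#' Classifies test predictions as presence when `prediction >= t` for each of
#' `n_thresholds` thresholds `t_i = i / (n_thresholds + 1)` (an even grid
#' strictly inside (0, 1)), and computes the confusion matrix and derived
#' metrics at each: sensitivity, specificity, the true skill statistic
#' `TSS = sensitivity + specificity - 1`, the binarised AUC
#' `(sensitivity + specificity) / 2` (the AUC of the one-threshold
#' classifier), and Cohen's kappa.
#'
#' @param predictions predicted probabilities in `[0, 1]` (test rows).
#' @param truth binary 0/1 observed vector; both classes must occur.
#' @param n_thresholds number of thresholds (default 30).
#' @return data frame of class `threshold_metrics`, one row per threshold.
#' @export
sweep_thresholds <- function(predictions, truth, n_thresholds = 30) {
  stopifnot(all(predictions >= 0 & predictions <= 1), all(truth %in% c(0, 1)))
  if (length(unique(truth)) < 2)
    stop("truth contains a single class; metrics are undefined", call. = FALSE)
  ts <- seq_len(n_thresholds) / (n_thresholds + 1)
  out <- do.call(rbind, lapply(ts, confusion_metrics, predictions = predictions,
                               truth = truth))
  class(out) <- c("threshold_metrics", "data.frame")
  out
}

#' Pick the optimal classification threshold
#'
#' Returns the threshold row maximizing the binarised AUC; ties break by
#' higher kappa, then by lower threshold.
#'
#' @param metrics a `threshold_metrics` table from [sweep_thresholds()].
#' @return single-row data frame (the winning `ThresholdMetrics`).
#' @export
select_optimal_threshold <- function(metrics) {
  stopifnot(nrow(metrics) >= 1)
  ord <- order(-metrics$binary_auc, -metrics$kappa, metrics$threshold)
  out <- metrics[ord[1], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pick the best bootstrap replicate by test performance
#'
#' Given each replicate's optimal-threshold metrics (computed on its own
#' test split), returns the replicate with the highest binarised AUC, ties
#' broken by higher kappa then lower replicate id. The final suitability map
#' comes from this replicate's top model.
#'
#' @param optima data frame with one row per replicate, containing
#'   `replicate_id`, `binary_auc` and `kappa` (e.g. row-bound
#'   [select_optimal_threshold()] outputs).
#' @return the winning row.
#' @export
select_best_replicate <- function(optima) {
  stopifnot(nrow(optima) >= 1,
            all(c("replicate_id", "binary_auc", "kappa") %in% names(optima)))
  ord <- order(-optima$binary_auc, -optima$kappa, optima$replicate_id)
  out <- optima[ord[1], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Continuous Boyce index for presence-only validation
#'
#' Assesses whether independent presence points concentrate where the model
#' predicts high suitability. A moving window of width
#' `window_width * range(background)` slides across the suitability range at
#' `n_windows` evenly spaced midpoints; in each window `P` is the fraction of
#' validation values inside and `E` the fraction of background (all valid
#' cells) values inside. The index is the Spearman rank correlation between
#' the predicted-to-expected ratio `F = P / E` and the window midpoint, over
#' windows with `E > 0`: 1 means suitability ranks encounter density
#' perfectly, 0 means no better than chance. Being rank-based, the index is
#' invariant under monotone transformations of the suitability values.
#'
#' @param validation suitability values at the independent presence points
#'   (at least 10).
#' @param background suitability values of all valid raster cells.
#' @param window_width window width as a fraction of the background range
#'   (default 0.1).
#' @param n_windows number of window midpoints (default 101).
#' @return object of class `boyce_result`: `$index` and `$windows`
#'   (midpoint, P, E, F for windows with E > 0).
#' @export
continuous_boyce <- function(validation, background, window_width = 0.1,
                             n_windows = 101) {
  validation <- validation[is.finite(validation)]
  background <- background[is.finite(background)]
  if (length(validation) < 10)
    stop("need at least 10 validation points", call. = FALSE)
  rng <- range(background)
  if (diff(rng) == 0) stop("background suitability is constant", call. = FALSE)
  w <- window_width * diff(rng)
  mids <- seq(rng[1] + w / 2, rng[2] - w / 2, length.out = n_windows)
  P <- vapply(mids, function(m)
    mean(validation >= m - w / 2 & validation <= m + w / 2), 0)
  E <- vapply(mids, function(m)
    mean(background >= m - w / 2 & background <= m + w / 2), 0)
  keep <- E > 0
  Fr <- P[keep] / E[keep]
  index <- if (length(Fr) < 2 || stats::sd(Fr) == 0) 0 else
    suppressWarnings(stats::cor(Fr, mids[keep], method = "spearman"))
  structure(list(index = index,
                 windows = data.frame(midpoint = mids[keep], P = P[keep],
                                      E = E[keep], F = Fr)),
            class = "boyce_result")
}

#' @export
print.boyce_result <- function(x, ...) {
  cat(sprintf("<boyce_result> index = %.3f over %d windows\n",
              x$index, nrow(x$windows)))
  invisible(x)
}
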