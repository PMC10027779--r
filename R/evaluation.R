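#' Aggregate tile-level probabilities into one sample probability
#'
#' @param tile_probs non-empty numeric vector of per-tile probabilities.
#' @return their arithmetic mean.
#' @export
aggregate_tile_predictions <- function(tile_probs) {
  if (length(tile_probs) == 0L)
    abort_validation("cannot aggregate an empty set of tile predictions")
  mean(tile_probs)
}

#' Matthews correlation coefficient
#'
#' Thresholds probabilities at `>= threshold` and computes
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with the
#' usual convention that a zero factor in the denominator yields MCC = 0
#' (e.g. an all-negative predictor).
#'
#' @param truth binary labels.
#' @param prob predicted probabilities (or scores).
#' @param threshold classification threshold (default 0.5).
#' @return MCC in \[-1, 1\].
#' @export
mcc <- function(truth, prob, threshold = 0.5) {
  pred <- as.integer(prob >= threshold)
  tp <- sum(pred == 1 & truth == 1); tn <- sum(pred == 0 & truth == 0)
  fp <- sum(pred == 1 & truth == 0); fn <- sum(pred == 0 & truth == 1)
  denom2 <- prod(c(tp + fp, tp + fn, tn + fp, tn + fn))
  if (denom2 == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom2)
}

#' Area under the ROC curve
#'
#' Computed by the rank (Mann-Whitney) construction with ties handled by
#' midranks, which equals the trapezoidal area under the empirical ROC
#' curve.
#'
#' @param truth binary labels (both classes required).
#' @param prob predicted scores.
#' @return AUROC in \[0, 1\], or `NA` with a warning for a single-class
#'   input.
#' @export
auroc <- function(truth, prob) {
  n_pos <- sum(truth == 1); n_neg <- sum(truth == 0)
  if (n_pos == 0 || n_neg == 0) {
    warning("AUROC undefined for a single-class set; recorded as NA")
    return(NA_real_)
  }
  r <- rank(prob)
  (sum(r[truth == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise (non-interpolated) average precision:
#' `AP = sum_k (R_k - R_{k-1}) * P_k` over score thresholds in decreasing
#' order, with tied scores processed as one block.
#'
#' @inheritParams auroc
#' @return AUPRC in \[0, 1\], or `NA` with a warning for a single-class
#'   input.
#' @export
auprc <- function(truth, prob) {
  n_pos <- sum(truth == 1); n_neg <- sum(truth == 0)
  if (n_pos == 0 || n_neg == 0) {
    warning("AUPRC undefined for a single-class set; recorded as NA")
    return(NA_real_)
  }
  ord <- order(prob, decreasing = TRUE)
  t_sorted <- truth[ord]; p_sorted <- prob[ord]
  block_end <- cumsum(rle(p_sorted)$lengths)
  tp <- cumsum(t_sorted)[block_end]
  fp <- block_end - tp
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Per-split evaluation of sample-level predictions
#'
#' Pools all sample predictions of a test set and computes MCC, AUROC and
#' AUPRC.
#'
#' @param preds data.frame with `response` and `probability` columns
#'   (e.g. from [predict.pdx_fit()]).
#' @param threshold MCC classification threshold.
#' @return one-row data.frame: `n`, `n_pos`, `mcc`, `auroc`, `auprc`.
#' @export
evaluate_predictions <- function(preds, threshold = 0.5) {
  data.frame(n = nrow(preds), n_pos = sum(preds$response == 1),
             mcc = mcc(preds$response, preds$probability, threshold),
             auroc = auroc(preds$response, preds$probability),
             auprc = auprc(preds$response, preds$probability))
}

#' Compare models across shared cross-validation splits
#'
#' For every model pair and metric: mean paired difference, two-sided
#' paired t-test and Wilcoxon signed-rank p-values (zero differences
#' dropped, normal approximation), per-split win counts, and a
#' significance flag at 0.05 (both tests). Splits where either model's
#' metric is missing (e.g. a single-class test fold) are excluded
#' pairwise; `n` reports the pairs used. A zero-variance difference
#' vector short-circuits the t-test: p = 1 for an all-zero difference,
#' p = 0 for a constant nonzero shift (flagged `degenerate`).
#'
#' @param metrics data.frame with columns `split_id`, `model`, and one
#'   column per metric (default `mcc`, `auprc`, `auroc`).
#' @param metric_cols metric column names to compare.
#' @param alpha significance level (default 0.05).
#' @return data.frame with one row per (metric, model pair).
#' @export
compare_models <- function(metrics, metric_cols = c("mcc", "auprc", "auroc"),
                           alpha = 0.05) {
  models <- unique(metrics$model)
  if (length(models) < 2L)
    abort_validation("need metrics for at least 2 models")
  pairs <- utils::combn(models, 2)
  rows <- list()
  for (metric in metric_cols) {
    for (j in seq_len(ncol(pairs))) {
      a <- metrics[metrics$model == pairs[1, j], ]
      b <- metrics[metrics$model == pairs[2, j], ]
      shared <- intersect(a$split_id, b$split_id)
      if (length(shared) < 2L)
        abort_validation("models must share at least 2 splits")
      xa <- a[[metric]][match(shared, a$split_id)]
      xb <- b[[metric]][match(shared, b$split_id)]
      ok <- !is.na(xa) & !is.na(xb)
      d <- xa[ok] - xb[ok]
      # mirror t.test's internal degeneracy guard (essentially-constant d)
      stderr_d <- stats::sd(d) / sqrt(length(d))
      degenerate <- stderr_d == 0 ||
        stderr_d < 10 * .Machine$double.eps * abs(mean(d))
      t_p <- if (degenerate) {
        if (mean(d) == 0) 1 else 0
      } else stats::t.test(d)$p.value
      nz <- d[d != 0]
      w_p <- if (length(nz) == 0L) 1 else
        suppressWarnings(stats::wilcox.test(nz, exact = FALSE)$p.value)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = metric, model_a = pairs[1, j], model_b = pairs[2, j],
        n = sum(ok), n_missing = sum(!ok),
        mean_a = mean(xa[ok]), mean_b = mean(xb[ok]), mean_diff = mean(d),
        wins_a = sum(d > 0), wins_b = sum(d < 0),
        t_p = t_p, wilcoxon_p = w_p,
        significant = t_p < alpha & w_p < alpha,
        degenerate = degenerate)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
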