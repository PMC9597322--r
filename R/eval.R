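# ROC/AUC evaluation with non-parametric bootstrap confidence intervals.

#' Area under the ROC curve
#'
#' Computed as the normalised Mann-Whitney U statistic via mid-ranks, so
#' tied scores count one half: AUC is the probability that a random positive
#' outscores a random negative, plus half the probability of a tie.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels logical or 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present to compute AUC", call. = FALSE)
  r <- rank(scores)                      # mid-ranks handle ties
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Operating-point metrics at a decision threshold
#'
#' The decision rule is `score >= th` (closed at the threshold). Metrics
#' with a zero denominator (e.g. PPV when nothing is called positive) are
#' returned as `NA` and listed in the `undefined` element rather than
#' propagated as NaN.
#'
#' @inheritParams roc_auc
#' @param th decision threshold.
#' @return list: `sensitivity`, `specificity`, `ppv`, `npv`, `tp`, `fp`,
#'   `fn`, `tn`, `undefined` (character vector of undefined metrics).
#' @export
operating_metrics <- function(scores, labels, th) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    stop("both classes must be present", call. = FALSE)
  pred <- scores >= th
  tp <- sum(pred & labels); fp <- sum(pred & !labels)
  fn <- sum(!pred & labels); tn <- sum(!pred & !labels)
  sf <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- list(sensitivity = sf(tp, tp + fn), specificity = sf(tn, tn + fp),
              ppv = sf(tp, tp + fp), npv = sf(tn, tn + fn),
              tp = tp, fp = fp, fn = fn, tn = tn)
  out$undefined <- names(which(vapply(out[1:4], is.na, logical(1))))
  out
}

#' Percentile bootstrap confidence interval for a performance metric
#'
#' Resamples (score, label) pairs with replacement at the nodule level;
#' resamples containing a single class are discarded and redrawn (their
#' count is reported). Percentile interval, default 95%.
#'
#' @inheritParams roc_auc
#' @param metric_fn function(scores, labels) -> scalar.
#' @param B number of bootstrap resamples (default 2000; < 100 warns).
#' @param level confidence level.
#' @param seed integer seed.
#' @param max_redraw_factor give up (error) after `B * max_redraw_factor`
#'   single-class redraws: the data cannot be resampled.
#' @return list: `lo`, `hi`, `level`, `B`, `n_redrawn`.
#' @export
bootstrap_ci <- function(scores, labels, metric_fn, B = 2000, level = 0.95,
                         seed = 1L, max_redraw_factor = 10) {
  labels <- as.logical(labels)
  n <- length(scores)
  if (n < 10) stop("need at least 10 observations to bootstrap", call. = FALSE)
  if (B < 100) warning("B < 100 gives unstable percentile intervals")
  if (!any(labels) || all(labels))
    stop("both classes must be present", call. = FALSE)
  stats_b <- numeric(B)
  n_redrawn <- 0L
  with_seed(seed, {
    b <- 1L
    while (b <= B) {
      idx <- sample.int(n, n, replace = TRUE)
      lb <- labels[idx]
      if (!any(lb) || all(lb)) {
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > B * max_redraw_factor)
          stop("bootstrap impossible: resamples almost surely single-class",
               call. = FALSE)
        next
      }
      stats_b[b] <- metric_fn(scores[idx], lb)
      b <- b + 1L
    }
  })
  alpha <- (1 - level) / 2
  q <- stats::quantile(stats_b, c(alpha, 1 - alpha), names = FALSE)
  list(lo = q[1], hi = q[2], level = level, B = B, n_redrawn = n_redrawn)
}

#' Full evaluation report at an operating point
#'
#' AUC plus threshold metrics, each with a percentile-bootstrap CI, laid out
#' like a standard model-performance table.
#'
#' @inheritParams roc_auc
#' @param th decision threshold, or `"auto"` to choose it by Youden's J
#'   ([select_threshold()]).
#' @param B,level,seed bootstrap parameters (see [bootstrap_ci()]).
#' @return An `eval_result`: list of per-metric `(point, lo, hi)`, plus
#'   `threshold`, `n_pos`, `n_neg`.
#' @export
eval_report <- function(scores, labels, th = "auto", B = 2000, level = 0.95,
                        seed = 1L) {
  labels <- as.logical(labels)
  if (identical(th, "auto")) th <- select_threshold(scores, labels)
  metrics <- list(
    auc = function(s, l) roc_auc(s, l),
    sensitivity = function(s, l) operating_metrics(s, l, th)$sensitivity,
    specificity = function(s, l) operating_metrics(s, l, th)$specificity,
    ppv = function(s, l) operating_metrics(s, l, th)$ppv,
    npv = function(s, l) operating_metrics(s, l, th)$npv)
  out <- lapply(seq_along(metrics), function(i) {
    fn <- metrics[[i]]
    point <- fn(scores, labels)
    ci <- bootstrap_ci(scores, labels,
                       function(s, l) fn(s, l), B = B, level = level,
                       seed = seed + i)
    c(point = point, lo = ci$lo, hi = ci$hi)
  })
  names(out) <- names(metrics)
  structure(c(out, list(threshold = th, n_pos = sum(labels),
                        n_neg = sum(!labels), level = level)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> n = %d pos / %d neg, threshold = %.4g\n",
              x$n_pos, x$n_neg, x$threshold))
  for (m in c("auc", "sensitivity", "specificity", "ppv", "npv")) {
    v <- x[[m]]
    cat(sprintf("  %-12s %.3f (%.0f%% CI %.3f-%.3f)\n", m, v["point"],
                100 * x$level, v["lo"], v["hi"]))
  }
  invisible(x)
}

#' Write an evaluation report as CSV and JSON
#'
#' @param result an `eval_result`.
#' @param csv_path,json_path output paths (either may be NULL to skip).
#' @export
write_eval_report <- function(result, csv_path = NULL, json_path = NULL) {
  rows <- do.call(rbind, lapply(c("auc", "sensitivity", "specificity",
                                  "ppv", "npv"), function(m) {
    v <- result[[m]]
    data.frame(metric = m, point = v["point"], ci_lo = v["lo"],
               ci_hi = v["hi"], row.names = NULL)
  }))
  if (!is.null(csv_path)) utils::write.csv(rows, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(threshold = result$threshold, n_pos = result$n_pos,
           n_neg = result$n_neg, level = result$level, metrics = rows),
      json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(rows)
}
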