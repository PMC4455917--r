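# Confusion-matrix statistics, exact binomial CIs, diagnostic likelihood
# ratios with log-method CIs, ROC/AUROC and rank-sum p-values.
#
# The positive class is always NR: sensitivity is the fraction of true
# non-responders flagged, precision the fraction of flagged patients who
# are truly non-responders, LR+ = sensitivity / (1 - specificity).

#' Confusion counts from predictions
#'
#' @param predicted,actual Vectors of `"R"`/`"NR"` labels, same length.
#' @return One-row tibble (`tp`, `fp`, `fn`, `tn`) with NR positive.
#' @export
confusion_counts <- function(predicted, actual) {
  predicted <- as_response(predicted)
  actual <- as_response(actual)
  tibble::tibble(
    tp = sum(predicted == "NR" & actual == "NR"),
    fp = sum(predicted == "NR" & actual == "R"),
    fn = sum(predicted == "R" & actual == "NR"),
    tn = sum(predicted == "R" & actual == "R")
  )
}

#' Confusion-matrix statistics
#'
#' @param tp,fp,fn,tn Non-negative integer counts (NR positive). `tp` may
#'   also be a one-row tibble as returned by [confusion_counts()].
#' @return One-row tibble: `sensitivity`, `specificity`, `precision`
#'   (`NA` when nothing was flagged), `likelihood_ratio` (`Inf` when
#'   `fp = 0` and `tp > 0`).
#' @export
#' @examples
#' confusion_stats(3, 2, 4, 21) # LR+ = (3/7)/(2/23) = 4.93
confusion_stats <- function(tp, fp = NULL, fn = NULL, tn = NULL) {
  if (is.data.frame(tp)) {
    fp <- tp$fp; fn <- tp$fn; tn <- tp$tn; tp <- tp$tp
  }
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("confusion counts must be non-negative integers")
  }
  if (sum(counts) == 0) abort("all-zero confusion counts")
  if (tp + fn < 1 || fp + tn < 1) abort("need at least one sample of each class")
  sens <- tp / (tp + fn)
  spec <- tn / (fp + tn)
  prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  lr <- if (fp == 0) {
    if (tp > 0) Inf else NaN
  } else {
    sens / (1 - spec)
  }
  tibble::tibble(
    sensitivity = sens, specificity = spec,
    precision = prec, likelihood_ratio = lr
  )
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact interval via Beta quantiles: lower is 0 when `k = 0`, upper is 1
#' when `k = n`.
#'
#' @param k Number of successes, `0 <= k <= n`.
#' @param n Number of trials, `n >= 1`.
#' @param level Confidence level in (0, 1), default 0.95.
#' @return One-row tibble (`lower`, `upper`).
#' @export
#' @examples
#' clopper_pearson_ci(1, 7) # (0.004, 0.579)
clopper_pearson_ci <- function(k, n, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    abort("`level` must be in (0, 1)")
  }
  if (n < 1 || k < 0 || k > n) abort("need 0 <= k <= n and n >= 1")
  alpha <- 1 - level
  lower <- if (k == 0) 0 else qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else qbeta(1 - alpha / 2, k + 1, n - k)
  tibble::tibble(lower = lower, upper = upper)
}

#' Log-method confidence interval for the positive likelihood ratio
#'
#' `exp(log LR +/- z * sqrt(1/tp - 1/(tp+fn) + 1/fp - 1/(fp+tn)))`.
#' Undefined (all-`NA`) when `fp = 0` (infinite LR) or `tp = 0`.
#'
#' @inheritParams confusion_stats
#' @param level Confidence level, default 0.95.
#' @return One-row tibble (`lower`, `upper`), `NA`s when undefined.
#' @export
#' @examples
#' lr_ci(3, 2, 4, 21) # (1.0, 23.8) to printed precision
lr_ci <- function(tp, fp = NULL, fn = NULL, tn = NULL, level = 0.95) {
  if (is.data.frame(tp)) {
    fp <- tp$fp; fn <- tp$fn; tn <- tp$tn; tp <- tp$tp
  }
  if (tp == 0 || fp == 0) {
    return(tibble::tibble(lower = NA_real_, upper = NA_real_))
  }
  lr <- (tp / (tp + fn)) / (fp / (fp + tn))
  se <- sqrt(1 / tp - 1 / (tp + fn) + 1 / fp - 1 / (fp + tn))
  z <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(lower = lr * exp(-z * se), upper = lr * exp(z * se))
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a random non-responder scores above a random
#' responder, ties counting one half:
#' `(#\{NR > R\} + 0.5 * #\{NR = R\}) / (n_nr * n_r)`.
#'
#' @param scores_nr,scores_r Numeric classifier scores for the NR and R
#'   samples (both non-empty).
#' @return The AUROC in \[0, 1\].
#' @export
auroc <- function(scores_nr, scores_r) {
  if (length(scores_nr) == 0L || length(scores_r) == 0L) {
    abort("both classes must be non-empty")
  }
  pooled <- c(scores_nr, scores_r)
  r <- rank(pooled)
  n1 <- length(scores_nr)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * length(scores_r))
}

#' One-sided AUROC p-value (Wilcoxon rank-sum)
#'
#' Tests whether NR scores are stochastically greater than R scores.
#' Exact null distribution when the total sample size is at most 20 and
#' there are no ties; otherwise the normal approximation with tie
#' correction (and continuity correction).
#'
#' @inheritParams auroc
#' @return One-sided p-value.
#' @export
auroc_pvalue <- function(scores_nr, scores_r) {
  if (length(scores_nr) == 0L || length(scores_r) == 0L) {
    abort("both classes must be non-empty")
  }
  n <- length(scores_nr) + length(scores_r)
  ties <- anyDuplicated(c(scores_nr, scores_r)) > 0
  use_exact <- n <= 20 && !ties
  suppressWarnings(
    wilcox.test(scores_nr, scores_r,
      alternative = "greater",
      exact = use_exact, correct = TRUE
    )$p.value
  )
}

#' ROC curve points
#'
#' One (FPR, TPR) point per distinct score threshold, descending, with
#' (0, 0) prepended and (1, 1) guaranteed; a sample is called NR when its
#' score is >= the threshold. The trapezoidal area under these points
#' equals [auroc()] exactly.
#'
#' @inheritParams auroc
#' @return Tibble (`threshold`, `fpr`, `tpr`), starting at (0, 0).
#' @export
roc_curve <- function(scores_nr, scores_r) {
  if (length(scores_nr) == 0L || length(scores_r) == 0L) {
    abort("both classes must be non-empty")
  }
  thr <- sort(unique(c(scores_nr, scores_r)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores_nr >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores_r >= t), 0)
  tibble::tibble(
    threshold = c(Inf, thr),
    fpr = c(0, fpr),
    tpr = c(0, tpr)
  )
}

# trapezoid area under a roc_curve() tibble
roc_auc <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
}

#' DeLong confidence interval for a single AUROC
#'
#' Placement-value (DeLong) variance estimate with a normal interval,
#' truncated to \[0, 1\]. Used for single-shot (non-resampled)
#' evaluations.
#'
#' @inheritParams auroc
#' @param level Confidence level, default 0.95.
#' @return One-row tibble (`auroc`, `lower`, `upper`).
#' @export
auroc_ci_delong <- function(scores_nr, scores_r, level = 0.95) {
  a <- auroc(scores_nr, scores_r)
  v10 <- vapply(scores_nr, function(x) {
    mean((x > scores_r) + 0.5 * (x == scores_r))
  }, 0)
  v01 <- vapply(scores_r, function(y) {
    mean((scores_nr > y) + 0.5 * (scores_nr == y))
  }, 0)
  se <- sqrt(
    stats::var(v10) / length(v10) + stats::var(v01) / length(v01)
  )
  if (!is.finite(se)) se <- 0
  z <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(
    auroc = a,
    lower = max(0, a - z * se),
    upper = min(1, a + z * se)
  )
}

#' Full performance report for scored, labeled samples
#'
#' Assembles the table-style summary used throughout: confusion counts at
#' the model's decision threshold, proportions with Clopper-Pearson 95%
#' CIs, LR+ with its log-method CI, AUROC with DeLong CI, and the
#' one-sided rank-sum AUROC p-value.
#'
#' @param scored Tibble with columns `score`, `predicted`, `response`.
#' @param level Confidence level for all intervals, default 0.95.
#' @return A one-row tibble of statistics.
#' @export
performance_report <- function(scored, level = 0.95) {
  need <- c("score", "predicted", "response")
  if (!all(need %in% names(scored))) {
    abort(paste0("`scored` needs columns: ", paste(need, collapse = ", ")))
  }
  actual <- as_response(scored$response)
  cc <- confusion_counts(scored$predicted, actual)
  st <- confusion_stats(cc)
  s_nr <- scored$score[actual == "NR"]
  s_r <- scored$score[actual == "R"]
  sens_ci <- clopper_pearson_ci(cc$tp, cc$tp + cc$fn, level)
  spec_ci <- clopper_pearson_ci(cc$tn, cc$fp + cc$tn, level)
  prec_ci <- if (cc$tp + cc$fp == 0) {
    tibble::tibble(lower = NA_real_, upper = NA_real_)
  } else {
    clopper_pearson_ci(cc$tp, cc$tp + cc$fp, level)
  }
  lrci <- lr_ci(cc, level = level)
  auc <- auroc_ci_delong(s_nr, s_r, level)
  tibble::tibble(
    n_nr = cc$tp + cc$fn, n_r = cc$fp + cc$tn,
    tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn,
    sensitivity = st$sensitivity,
    sensitivity_lo = sens_ci$lower, sensitivity_hi = sens_ci$upper,
    specificity = st$specificity,
    specificity_lo = spec_ci$lower, specificity_hi = spec_ci$upper,
    precision = st$precision,
    precision_lo = prec_ci$lower, precision_hi = prec_ci$upper,
    likelihood_ratio = st$likelihood_ratio,
    likelihood_ratio_lo = lrci$lower, likelihood_ratio_hi = lrci$upper,
    auroc = auc$auroc, auroc_lo = auc$lower, auroc_hi = auc$upper,
    auroc_p = auroc_pvalue(s_nr, s_r)
  )
}

#' Plot ROC curves
#'
#' @param roc A [roc_curve()] tibble, or a named list of them (one curve
#'   per classifier).
#' @return A ggplot object.
#' @export
plot_roc <- function(roc) {
  if (is.data.frame(roc)) roc <- list(classifier = roc)
  df <- dplyr::bind_rows(roc, .id = "classifier")
  ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr, colour = .data$classifier)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity") +
    ggplot2::theme_minimal()
}
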