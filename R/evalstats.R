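#' Default power constant for minimum sample size
#'
#' `(z_{1-alpha/2} + z_{power})^2`, the standard multiplier for the
#' sample size needed to detect a mean longitudinal change at two-sided
#' level `alpha` with the given power. The conventional 80% power,
#' alpha = 0.05 choice gives approximately 7.849.
#'
#' @param power target power (default 0.80)
#' @param alpha two-sided significance level (default 0.05)
#' @return scalar constant
#' @export
power_constant <- function(power = 0.80, alpha = 0.05) {
  (stats::qnorm(1 - alpha / 2) + stats::qnorm(power))^2
}

#' Minimum sample size for a longitudinal biomarker
#'
#' `N = ceil(C * sigma^2 / (m - b)^2)`, where `m - b` is the mean
#' per-subject biomarker change between follow-up and baseline and
#' `sigma` the standard deviation of that change. A more sensitive
#' biomarker (larger mean change relative to its variability) needs
#' fewer subjects.
#'
#' @param baseline,followup paired per-subject biomarker totals; or pass
#'   `sigma` and `delta` directly and leave these NULL
#' @param C power constant (default [power_constant()], about 7.849)
#' @param sigma,delta optional direct inputs: SD of change and mean
#'   change `m - b`
#' @return list with `n` (integer sample size), `sigma`, `delta`, `C`
#' @examples
#' min_sample_size(sigma = 1, delta = 0.5, C = 7.849)$n  # 32
#' @export
min_sample_size <- function(baseline = NULL, followup = NULL,
                            C = power_constant(), sigma = NULL, delta = NULL) {
  if (is.null(sigma) || is.null(delta)) {
    if (is.null(baseline) || is.null(followup)) {
      abort_fmt("supply paired baseline/followup values or sigma and delta")
    }
    if (length(baseline) != length(followup) || length(baseline) < 2L) {
      abort_fmt("baseline and followup must be paired with n >= 2")
    }
    change <- followup - baseline
    sigma <- stats::sd(change)
    delta <- mean(change)
  }
  if (delta == 0) abort_fmt("mean change is zero: sample size undefined")
  list(n = as.integer(ceiling(C * sigma^2 / delta^2)),
       sigma = sigma, delta = delta, C = C)
}

#' Relative change rate
#'
#' `(second - first) / first`: the dimensionless rate of change of a
#' total biomarker or clinical score between two visits.
#'
#' @param first,second values at the earlier and later visit
#' @return numeric rate(s), sign = sign of the change
#' @examples
#' change_rate(10, 12)  # 0.2
#' @export
change_rate <- function(first, second) {
  if (any(first == 0)) abort_fmt("change rate undefined when the first value is 0")
  (second - first) / first
}

#' Paired comparison of baseline and follow-up
#'
#' Two-sided paired t-test p-value together with the paired Cohen's d
#' effect size, `mean(diff) / sd(diff)` with `diff = followup - baseline`.
#'
#' @param baseline,followup paired numeric vectors, n >= 2
#' @return list with `p_value`, `effect_size`, `mean_change`, `n`
#' @export
paired_test <- function(baseline, followup) {
  if (length(baseline) != length(followup) || length(baseline) < 2L) {
    abort_fmt("paired_test needs paired vectors with n >= 2")
  }
  d <- followup - baseline
  if (stats::sd(d) == 0) {
    abort_fmt("zero change variance: paired effect size undefined")
  }
  tt <- stats::t.test(followup, baseline, paired = TRUE)
  list(p_value = tt$p.value, effect_size = mean(d) / stats::sd(d),
       mean_change = mean(d), n = length(d))
}

#' Pearson correlation with significance
#'
#' Correlation coefficient and two-sided p-value from the t transform
#' of the coefficient, for relating biomarker change rates to clinical
#' rating-score change rates.
#'
#' @param x,y numeric vectors, n >= 3, nonconstant
#' @return list with `cc`, `p_value`, `n`
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    abort_fmt("pearson_corr needs paired vectors with n >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_fmt("zero variance input: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(cc = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' ROC curve and AUC with bootstrap confidence interval
#'
#' AUC via the rank (Mann-Whitney) formulation -- the probability that a
#' positive-class score exceeds a negative-class score, ties counted one
#' half -- plus ROC curve points and, optionally, a stratified bootstrap
#' 95% confidence interval (positives and negatives resampled
#' separately).
#'
#' @param scores per-subject statistic, higher = more positive-like
#' @param labels binary labels
#' @param positive_class label value treated as positive (default:
#'   first factor level)
#' @param n_boot bootstrap resamples for the CI (default 2000)
#' @param conf confidence level (default 0.95)
#' @param seed seed for the bootstrap
#' @param ci compute the bootstrap CI?
#' @return list with `auc`, `ci` (length-2 vector or NULL), `curve`
#'   (data.frame fpr/tpr/threshold), `n_pos`, `n_neg`
#' @export
roc_auc <- function(scores, labels, positive_class = NULL,
                    n_boot = 2000L, conf = 0.95, seed = 1L, ci = TRUE) {
  labels <- as.factor(labels)
  if (is.null(positive_class)) positive_class <- levels(labels)[1L]
  pos <- labels == positive_class
  if (!any(pos) || all(pos)) abort_fmt("both classes must be present")
  if (length(scores) != length(labels)) abort_fmt("scores/labels length mismatch")

  auc_rank <- function(s, p) {
    r <- rank(s)
    np <- sum(p); nn <- sum(!p)
    (sum(r[p]) - np * (np + 1) / 2) / (np * nn)
  }
  auc <- auc_rank(scores, pos)

  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- data.frame(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(scores[pos] >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  )

  ci_out <- NULL
  if (ci) {
    ipos <- which(pos); ineg <- which(!pos)
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        ip <- sample(ipos, length(ipos), replace = TRUE)
        ineg_b <- sample(ineg, length(ineg), replace = TRUE)
        s <- c(scores[ip], scores[ineg_b])
        p <- rep(c(TRUE, FALSE), c(length(ip), length(ineg_b)))
        auc_rank(s, p)
      }, numeric(1))
    })
    a <- (1 - conf) / 2
    ci_out <- unname(stats::quantile(boots, c(a, 1 - a)))
  }
  list(auc = auc, ci = ci_out, curve = curve,
       n_pos = sum(pos), n_neg = sum(!pos))
}

#' Confusion counts and derived classification metrics
#'
#' TP/TN/FP/FN relative to a declared positive class, with
#' `ACC = (TP+TN)/n`, `SEN = TP/(TP+FN)` and `SPE = TN/(TN+FP)`.
#'
#' @param predicted,truth label vectors of equal length
#' @param positive_class label treated as positive
#' @return list with `TP`, `TN`, `FP`, `FN`, `ACC`, `SEN`, `SPE`
#' @export
classification_report <- function(predicted, truth, positive_class) {
  if (length(predicted) != length(truth)) {
    abort_fmt("predicted and truth must have equal length")
  }
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (!positive_class %in% truth) {
    abort_fmt("positive class '%s' absent from truth", positive_class)
  }
  tp <- sum(predicted == positive_class & truth == positive_class)
  tn <- sum(predicted != positive_class & truth != positive_class)
  fp <- sum(predicted == positive_class & truth != positive_class)
  fn <- sum(predicted != positive_class & truth == positive_class)
  list(TP = tp, TN = tn, FP = fp, FN = fn,
       ACC = (tp + tn) / length(truth),
       SEN = tp / (tp + fn),
       SPE = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Head-size adjustment of regional volumes
#'
#' Divides regional volumes by the subject's intracranial vault volume,
#' yielding dimensionless head-size-normalized volumes for the volume
#' baseline biomarker.
#'
#' @param volumes numeric vector/matrix of regional volumes (mm^3)
#' @param icv intracranial vault volume (mm^3), > 0
#' @return volumes / icv
#' @export
icv_adjust <- function(volumes, icv) {
  if (any(icv <= 0)) abort_fmt("ICV must be positive")
  volumes / icv
}
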