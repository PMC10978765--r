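#' Volumetric DESH, Venthi and Sylhi indices
#'
#' The DESH index is the combined volume of the total ventricles and the
#' Sylvian fissure + basal cistern divided by the high-convexity
#' subarachnoid-space volume. The Venthi index is the ventricular volume over
#' the high-convexity volume, the Sylhi index the Sylvian/basal volume over
#' the high-convexity volume. The DESH index is computed as the sum
#' `venthi + sylhi`, which is algebraically identical to its ratio
#' definition and makes the identity exact in floating point.
#'
#' @param v Compartment volumes: a list or [compartment_volumes()] result
#'   with elements `total_ventricles_ml`, `sylvian_basal_ml` and
#'   `high_convexity_sas_ml` (mL).
#' @return List of class `desh_indices` with `desh_index`, `venthi_index`
#'   and `sylhi_index`.
#' @examples
#' compute_indices(list(total_ventricles_ml = 129.2, sylvian_basal_ml = 90.2,
#'                      high_convexity_sas_ml = 17.9))
#' @export
compute_indices <- function(v) {
  vent <- v$total_ventricles_ml
  syl <- v$sylvian_basal_ml
  hc <- v$high_convexity_sas_ml
  if (is.null(vent) || is.null(syl) || is.null(hc))
    stop("compartment volumes must supply ventricles, sylvian_basal and high_convexity_sas")
  if (!is.finite(hc) || hc <= 0)
    stop("high-convexity SAS volume must be strictly positive (got ", hc,
         " mL); the index ratios are undefined otherwise")
  venthi <- vent / hc
  sylhi <- syl / hc
  structure(list(desh_index = venthi + sylhi, venthi_index = venthi,
                 sylhi_index = sylhi), class = "desh_indices")
}

#' Smoothed Dice coefficient of two binary masks
#'
#' `(2|X intersect Y| + eps) / (|X| + |Y| + eps)`. The epsilon smoothing
#' (default 1e-4) makes the score of two empty masks 1 rather than 0/0.
#'
#' @param x,y Binary masks (logical or 0/1 arrays) on a shared grid.
#' @param epsilon Smoothing constant.
#' @return Dice score in (0, 1].
#' @export
dice_score <- function(x, y, epsilon = 1e-4) {
  if (!identical(dim(x), dim(y)) || length(x) != length(y))
    stop("masks must share the same grid")
  x <- as.logical(x); y <- as.logical(y)
  (2 * sum(x & y) + epsilon) / (sum(x) + sum(y) + epsilon)
}

# Empirical AUC with ties counted one half, via the rank statistic.
auc_rank <- function(scores, labels) {
  n_pos <- sum(labels); n_neg <- sum(!labels)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Youden-optimal cut over midpoints of consecutive unique sorted scores with
# -Inf/+Inf sentinels; positive call is score >= threshold. Ties are broken
# toward the smaller threshold (higher sensitivity).
youden_threshold <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  sens <- vapply(cand, function(t) sum(scores[labels] >= t) / n_pos, 0)
  spec <- vapply(cand, function(t) sum(scores[!labels] < t) / n_neg, 0)
  j <- sens + spec
  best <- which(j == max(j))
  tie <- length(best) > 1
  pick <- best[1]
  list(threshold = cand[pick], sensitivity = sens[pick],
       specificity = spec[pick], youden_tie = tie)
}

#' ROC analysis with Youden-optimal threshold and bootstrap CIs
#'
#' The AUC is the area under the empirical ROC curve (equivalently the
#' concordant-pair rank statistic with ties counted one half). The optimal
#' threshold maximizes sensitivity + specificity over all cut candidates
#' (midpoints between consecutive unique sorted scores, with infinite
#' sentinels); a subject is called positive when its score is at or above
#' the threshold. 95% confidence intervals come from a seeded nonparametric
#' percentile bootstrap over subjects.
#'
#' @param scores Numeric per-subject index values (higher = more DESH-like).
#' @param labels Logical (or 0/1) ground-truth class, `TRUE` = positive.
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Integer seed for the bootstrap substream.
#' @return List of class `desh_roc`: `auc`, `threshold`, `sensitivity`,
#'   `specificity`, each with a `*_ci` 2-vector, plus `youden_tie`.
#' @export
roc_analysis <- function(scores, labels, n_boot = 2000, seed = 1L) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (anyNA(scores) || anyNA(labels)) stop("scores and labels must be complete")
  if (!any(labels) || all(labels))
    stop("both classes must be present for ROC analysis")
  auc <- auc_rank(scores, labels)
  yj <- youden_threshold(scores, labels)
  if (yj$youden_tie)
    message("Youden criterion tied between thresholds; smaller threshold kept")
  boot <- with_seed(substream_seed(seed, "bootstrap"), {
    n <- length(scores)
    reps <- matrix(NA_real_, n_boot, 4)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      tries <- 0
      while ((!any(labels[idx]) || all(labels[idx])) && tries < 100) {
        idx <- sample.int(n, n, replace = TRUE); tries <- tries + 1
      }
      if (!any(labels[idx]) || all(labels[idx])) next
      yb <- youden_threshold(scores[idx], labels[idx])
      reps[b, ] <- c(auc_rank(scores[idx], labels[idx]), yb$threshold,
                     yb$sensitivity, yb$specificity)
    }
    reps
  })
  ci <- function(col) unname(quantile(boot[, col], c(0.025, 0.975),
                                      na.rm = TRUE, names = FALSE))
  structure(list(auc = auc, auc_ci = ci(1),
                 threshold = yj$threshold, threshold_ci = ci(2),
                 sensitivity = yj$sensitivity, sensitivity_ci = ci(3),
                 specificity = yj$specificity, specificity_ci = ci(4),
                 youden_tie = yj$youden_tie, n_boot = n_boot),
            class = "desh_roc")
}

#' @export
print.desh_roc <- function(x, ...) {
  cat(sprintf("<desh_roc> AUC %.3f (%.3f-%.3f), threshold %.4g, sens %.3f, spec %.3f\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$threshold, x$sensitivity,
              x$specificity))
  invisible(x)
}

#' Pearson correlation with a Fisher-z 95% confidence interval
#'
#' @param x,y Numeric vectors, `n >= 3`, with nonzero variance.
#' @return List with `r` and `ci` (2-vector).
#' @export
pearson_with_ci <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance input")
  ct <- cor.test(x, y, method = "pearson", conf.level = 0.95)
  r <- unname(ct$estimate)
  ci <- if (!is.null(ct$conf.int)) as.numeric(ct$conf.int) else c(NA_real_, NA_real_)
  list(r = r, ci = ci)
}
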