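#' ROC curve, AUC and Youden-optimal operating point
#'
#' Builds the receiver operating characteristic of a continuous risk score
#' against a dichotomous outcome. The AUC is the tie-corrected
#' Mann-Whitney statistic (ties between a positive and a negative score
#' count one half), which equals the trapezoidal area under the empirical
#' ROC. The default operating point maximises Youden's J =
#' sensitivity + specificity - 1.
#'
#' @param scores Numeric risk scores (higher = more likely positive).
#' @param labels 0/1, logical, or two-level factor outcome; both classes
#'   must be present.
#'
#' @return An object of class `"roc_curve"`: list with `thresholds`, `fpr`,
#'   `tpr`, `auc`, `sensitivity`, `specificity`, `threshold` (the
#'   Youden-optimal cutoff), `n_pos`, `n_neg`.
#' @seealso [auc_ci()], [delong_test()]
#' @export
#' @examples
#' r <- roc_curve(c(.1, .4, .35, .8), c(0, 0, 1, 1))
#' r$auc  # 0.75
roc_curve <- function(scores, labels) {
  labels <- as_binary(labels, "labels")
  if (length(scores) != length(labels))
    stop_("scores and labels differ in length")
  if (anyNA(scores) || anyNA(labels)) stop_("missing values not allowed")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L)
    stop_("both outcome classes must be present to build a ROC")
  thr <- sort(unique(scores))
  ## predict positive when score >= t; prepend a cutoff above all scores
  cuts <- c(Inf, rev(thr))
  tpr <- vapply(cuts, function(t) mean(scores[labels == 1] >= t), 0)
  fpr <- vapply(cuts, function(t) mean(scores[labels == 0] >= t), 0)
  auc <- auc_mw(scores, labels)
  j <- tpr - fpr
  jbest <- which(j >= max(j) - 1e-12)[1L]
  structure(list(thresholds = cuts, fpr = fpr, tpr = tpr, auc = auc,
                 sensitivity = tpr[jbest], specificity = 1 - fpr[jbest],
                 threshold = cuts[jbest], n_pos = n1, n_neg = n0),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, digits = 4, ...) {
  cat(sprintf("ROC curve: %d positives / %d negatives\n", x$n_pos, x$n_neg))
  cat(sprintf("  AUC = %s", format(x$auc, digits = digits)))
  if (!is.null(x$ci))
    cat(sprintf("  (95%% CI %s-%s)", format(x$ci[1], digits = digits),
                format(x$ci[2], digits = digits)))
  cat("\n")
  cat(sprintf("  Youden operating point: threshold %s, sensitivity %s, specificity %s\n",
              format(x$threshold, digits = digits),
              format(x$sensitivity, digits = digits),
              format(x$specificity, digits = digits)))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  plot(x$fpr, x$tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  abline(0, 1, lty = 3)
  invisible(x)
}

#' Stratified-bootstrap confidence interval for an AUC
#'
#' Percentile bootstrap interval for the Mann-Whitney AUC. Resampling is
#' stratified by outcome class by default, so every replicate preserves the
#' case/control counts and no replicate can degenerate to a single class.
#'
#' @param scores,labels As in [roc_curve()].
#' @param B Number of bootstrap replicates (default 10000).
#' @param stratified Resample within outcome classes (default `TRUE`).
#' @param seed Optional seed for reproducible resampling.
#' @param conf Confidence level (default 0.95).
#' @param method `"percentile"` (default) or `"bca"` (bias-corrected and
#'   accelerated, jackknife acceleration).
#'
#' @return Numeric `c(lower, upper)` with attributes `auc` (point estimate)
#'   and `B`.
#' @export
auc_ci <- function(scores, labels, B = 10000L, stratified = TRUE,
                   seed = NULL, conf = 0.95, method = c("percentile", "bca")) {
  method <- match.arg(method)
  labels <- as_binary(labels, "labels")
  if (B < 100L) stop_("`B` must be at least 100")
  est <- auc_mw(scores, labels)
  ipos <- which(labels == 1); ineg <- which(labels == 0)
  n <- length(scores)
  boots <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- if (stratified)
        c(sample(ipos, length(ipos), replace = TRUE),
          sample(ineg, length(ineg), replace = TRUE))
      else {
        repeat {
          cand <- sample.int(n, n, replace = TRUE)
          if (length(unique(labels[cand])) == 2L) break
        }
        cand
      }
      auc_mw(scores[idx], labels[idx])
    }, 0)
  })
  a <- (1 - conf) / 2
  if (method == "percentile") {
    ci <- unname(quantile(boots, c(a, 1 - a), type = 7))
  } else {
    z0 <- qnorm(mean(boots < est) + 0.5 * mean(boots == est))
    jack <- vapply(seq_len(n), function(i)
      auc_mw(scores[-i], labels[-i]), 0)
    jm <- mean(jack)
    num <- sum((jm - jack)^3); den <- 6 * sum((jm - jack)^2)^1.5
    acc <- if (den > 0) num / den else 0
    zl <- qnorm(a); zu <- qnorm(1 - a)
    p1 <- pnorm(z0 + (z0 + zl) / (1 - acc * (z0 + zl)))
    p2 <- pnorm(z0 + (z0 + zu) / (1 - acc * (z0 + zu)))
    ci <- unname(quantile(boots, c(p1, p2), type = 7))
  }
  ci <- c(min(ci[1], est), max(ci[2], est))
  structure(ci, auc = est, B = B)
}

#' DeLong test comparing two correlated AUCs
#'
#' Nonparametric comparison of the AUCs of two risk scores evaluated on the
#' same subjects, using DeLong's structural components: for each positive
#' (negative) subject the placement value against all negatives (positives)
#' is computed, and the variance of the AUC difference is assembled from the
#' empirical covariance matrices of those placements. The two-sided p-value
#' comes from the asymptotic normal distribution of the difference.
#'
#' @param scores_a,scores_b Paired risk scores on identical subjects.
#' @param labels Dichotomous outcome shared by both score vectors.
#'
#' @return List with `auc` (length 2), `difference`, `statistic` (z),
#'   `p.value`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as_binary(labels, "labels")
  if (length(scores_a) != length(labels) ||
      length(scores_b) != length(labels))
    stop_("scores and labels must have identical length (paired design)")
  pos <- labels == 1
  m <- sum(pos); n <- sum(!pos)
  if (m == 0L || n == 0L) stop_("both outcome classes must be present")
  psi <- function(x_pos, x_neg) {
    ## placement matrix: psi[i, j] = 1, 1/2, 0 as pos_i >, ==, < neg_j
    outer(x_pos, x_neg, function(a, b)
      (a > b) + 0.5 * (a == b))
  }
  comp <- function(s) {
    P <- psi(s[pos], s[!pos])
    list(v10 = rowMeans(P), v01 = colMeans(P), auc = mean(P))
  }
  ca <- comp(scores_a); cb <- comp(scores_b)
  s10 <- cov(cbind(ca$v10, cb$v10))
  s01 <- cov(cbind(ca$v01, cb$v01))
  var_d <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
           (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- ca$auc - cb$auc
  if (var_d <= 0) {
    z <- if (abs(d) < 1e-12) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(var_d)
  }
  p <- if (is.infinite(z)) 0 else 2 * pnorm(-abs(z))
  list(auc = c(ca$auc, cb$auc), difference = d, statistic = z, p.value = p)
}
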