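#' Classical group-comparison tests with multiplicity adjustment
#'
#' Convenience wrapper around the classical tests used alongside the
#' early-warning system when comparing biomarker levels across diagnostic
#' or A/T groups: Wilcoxon rank-sum (two groups), Kruskal-Wallis, one-way
#' ANOVA, and Holm-adjusted pairwise Wilcoxon comparisons.
#'
#' @param values Numeric measurements (e.g. plasma biomarker levels).
#' @param groups Group labels, coerced to factor.
#' @param adjust Multiplicity adjustment method for the pairwise
#'   comparisons, passed to [stats::p.adjust()] (default `"holm"`).
#'
#' @return A list with elements `wilcoxon` (two-group case, else `NA`),
#'   `kruskal_wallis`, `anova`, and `pairwise` (matrix of adjusted
#'   Wilcoxon p-values).
#' @export
classical_tests <- function(values, groups, adjust = "holm") {
  groups <- factor(groups)
  if (anyNA(values) || anyNA(groups)) stop_("missing values not allowed")
  if (any(table(groups) == 0L) || nlevels(groups) < 2L)
    stop_("every group must be non-empty and at least two groups present")
  k <- nlevels(groups)
  wil <- if (k == 2L)
    suppressWarnings(wilcox.test(values ~ groups)$p.value) else NA_real_
  kw <- kruskal.test(values, groups)$p.value
  an <- summary(aov(values ~ groups))[[1]][["Pr(>F)"]][1]
  pw <- suppressWarnings(
    pairwise.wilcox.test(values, groups, p.adjust.method = adjust)$p.value)
  list(wilcoxon = wil, kruskal_wallis = kw, anova = an, pairwise = pw)
}

#' Spearman rank correlation
#'
#' @param x,y Paired numeric vectors.
#' @return List with `rho` and `p.value`.
#' @export
spearman_rank_corr <- function(x, y) {
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p.value = ct$p.value)
}

#' Exact test on a proportion against one half
#'
#' Two-sided exact binomial test of whether a proportion differs from 0.5
#' (used per risk zone to ask whether classification within the zone beats
#' chance).
#'
#' @param successes Number of successes.
#' @param n Number of trials.
#' @param p Null proportion (default 0.5).
#' @return The p-value.
#' @export
proportion_test <- function(successes, n, p = 0.5) {
  if (n < 1L) stop_("`n` must be positive")
  binom.test(successes, n, p = p)$p.value
}

#' Fisher's exact test on a contingency table
#'
#' @param tab A 2x2 (or r x c) contingency table or matrix.
#' @return The two-sided p-value.
#' @export
fisher_exact <- function(tab) {
  if (any(tab < 0)) stop_("counts must be non-negative")
  fisher.test(tab)$p.value
}

#' Conversion-rate report for a cohort
#'
#' Tabulates, per baseline diagnosis, how many subjects progressed to AD by
#' their last visit, and the conversion percentage. This is the cohort
#' arithmetic on which the power calculation of the study design rests
#' (conversion rates among the source population's CN and MCI subjects).
#'
#' @param cohort A long-format cohort table (see [read_cohort()]) with
#'   columns `subject_id`, `visit_time`, `diagnosis`; or a per-subject data
#'   frame with columns `baseline_dx` and `final_dx`.
#'
#' @return Data frame with columns `baseline_dx`, `n`, `n_converted`,
#'   `pct_converted` (in percent).
#' @export
#' @examples
#' subjects <- data.frame(
#'   baseline_dx = rep(c("CN", "MCI"), c(1039, 101)),
#'   final_dx = c(rep(c("AD", "CN"), c(10, 1029)),
#'                rep(c("AD", "MCI"), c(10, 91))))
#' conversion_report(subjects)
conversion_report <- function(cohort) {
  if (all(c("baseline_dx", "final_dx") %in% names(cohort))) {
    subj <- cohort[, c("baseline_dx", "final_dx")]
  } else if (all(c("subject_id", "visit_time", "diagnosis") %in%
                 names(cohort))) {
    ord <- order(cohort$subject_id, cohort$visit_time)
    ch <- cohort[ord, ]
    first <- !duplicated(ch$subject_id)
    last <- !duplicated(ch$subject_id, fromLast = TRUE)
    subj <- data.frame(baseline_dx = ch$diagnosis[first],
                       final_dx = ch$diagnosis[last])
  } else {
    stop_("cohort must carry subject_id/visit_time/diagnosis or baseline_dx/final_dx")
  }
  if (nrow(subj) == 0L) stop_("empty cohort")
  sp <- split(subj$final_dx, subj$baseline_dx)
  out <- do.call(rbind, lapply(names(sp), function(g) {
    n <- length(sp[[g]]); nc <- sum(sp[[g]] == "AD")
    data.frame(baseline_dx = g, n = n, n_converted = nc,
               pct_converted = 100 * nc / n, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
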