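#' Risk-zone bands on terminal-node prevalence
#'
#' Terminal nodes of the early-warning tree are mapped to low / middle /
#' high AD-likelihood zones by their prevalence \eqn{\hat y}: below the low
#' bound is low risk, at or above the high bound is high risk, otherwise
#' middle. The defaults (0.20, 0.70) reproduce the published node labels
#' (prevalences 0.25 and 0.50 labelled middle; 0.78 and 1.00 high); the
#' band edges themselves are a modelling choice, not a published constant.
#'
#' @param low Upper bound (exclusive) of the low zone, in \eqn{[0, 1)}.
#' @param high Lower bound (inclusive) of the high zone.
#'
#' @return A list of class `"risk_bands"`.
#' @export
risk_bands <- function(low = 0.20, high = 0.70) {
  if (!(low >= 0 && low < high && high <= 1))
    stop_("bands must satisfy 0 <= low < high <= 1")
  structure(list(low = low, high = high), class = "risk_bands")
}

#' Risk zone of a vector of prevalences or risk scores
#'
#' @param yhat Prevalences / risk scores in \eqn{[0, 1]}.
#' @param bands A [risk_bands()] object.
#' @return Factor with levels low/middle/high.
#' @export
zone_of <- function(yhat, bands = risk_bands()) {
  z <- ifelse(yhat < bands$low, "low",
              ifelse(yhat >= bands$high, "high", "middle"))
  factor(z, levels = c("low", "middle", "high"))
}

#' Map terminal nodes of a tree to risk zones
#'
#' @param tree A fitted [rtree()].
#' @param bands A [risk_bands()] object.
#'
#' @return Named factor (low/middle/high) over terminal-node ids.
#' @export
#' @examples
#' d <- data.frame(up53 = c(1, 2, 9, 10), y = c(0, 0, 1, 1))
#' fit <- rtree(y ~ up53, d, rtree_control(minsplit = 2, minbucket = 1))
#' assign_risk_zones(fit)
assign_risk_zones <- function(tree, bands = risk_bands()) {
  stopifnot(inherits(tree, "rtree"), inherits(bands, "risk_bands"))
  fr <- tree$frame
  leaves <- fr[fr$var == "<leaf>", , drop = FALSE]
  z <- zone_of(leaves$yhat, bands)
  names(z) <- leaves$node
  z
}

#' Agreement of the risk stratification with clinical diagnosis
#'
#' Compares per-subject risk zones with the dichotomous clinical outcome
#' (AD = 1). Under the default rule a subject agrees with the clinic when
#' it is high-risk and converted, low-risk and did not, or middle-risk and
#' converted (middle is an at-risk call, vindicated by conversion).
#' Alternative rules treat middle-zone subjects as always wrong
#' (`"middle-wrong"`) or drop them (`"middle-excluded"`). The report
#' includes, per zone and overall, an exact binomial test of the
#' within-zone agreement proportion against 0.5, and Fisher's exact test on
#' the 2x2 high/low x AD/non-AD collapse.
#'
#' @param zones Factor (or character) of per-subject zones
#'   (low/middle/high).
#' @param outcomes 0/1 (or logical) conversion outcome, aligned with
#'   `zones`.
#' @param rule Agreement rule, see Details.
#'
#' @return A list of class `"stratification_report"`: `counts` (per-zone n,
#'   converters, agreeing), `agreement` (percent), `proportion_p`
#'   (per-zone and overall exact binomial p-values vs 0.5),
#'   `fisher_p` (high/low collapse), `rule`, `n`.
#' @export
agreement_report <- function(zones, outcomes,
                             rule = c("middle-converter", "middle-wrong",
                                      "middle-excluded")) {
  rule <- match.arg(rule)
  if (length(zones) == 0L) stop_("empty input")
  if (length(zones) != length(outcomes))
    stop_("zones and outcomes must be aligned by subject")
  zones <- factor(as.character(zones), levels = c("low", "middle", "high"))
  if (anyNA(zones)) stop_("zones must be low/middle/high")
  y <- as_binary(outcomes, "outcomes")

  agree <- (zones == "high" & y == 1) | (zones == "low" & y == 0)
  keep <- rep(TRUE, length(zones))
  if (rule == "middle-converter") {
    agree <- agree | (zones == "middle" & y == 1)
  } else if (rule == "middle-excluded") {
    keep <- zones != "middle"
  }
  counts <- do.call(rbind, lapply(levels(zones), function(z) {
    sel <- zones == z
    data.frame(zone = z, n = sum(sel), converters = sum(y[sel]),
               agreeing = sum(agree[sel & keep]),
               stringsAsFactors = FALSE)
  }))
  agreement <- 100 * sum(agree[keep]) / sum(keep)

  prop_p <- vapply(levels(zones), function(z) {
    sel <- zones == z & keep
    if (!any(sel)) return(NA_real_)
    proportion_test(sum(agree[sel]), sum(sel))
  }, 0)
  prop_p <- c(prop_p, overall = proportion_test(sum(agree[keep]), sum(keep)))

  hi_lo <- zones %in% c("high", "low")
  fish <- if (sum(hi_lo) > 0L && length(unique(zones[hi_lo])) == 2L) {
    tab <- table(factor(zones[hi_lo], c("high", "low")),
                 factor(y[hi_lo], c(1, 0)))
    fisher_exact(tab)
  } else NA_real_

  structure(list(counts = counts, agreement = agreement,
                 proportion_p = prop_p, fisher_p = fish, rule = rule,
                 n = length(zones)),
            class = "stratification_report")
}

#' @export
print.stratification_report <- function(x, ...) {
  cat("Risk-stratification report\n")
  print(x$counts, row.names = FALSE)
  cat(sprintf("\nOverall agreement with clinical diagnosis: %.2f%% (rule: %s)\n",
              x$agreement, x$rule))
  cat(sprintf("Exact binomial vs 0.5: low p=%.3g, high p=%.3g, overall p=%.3g\n",
              x$proportion_p[["low"]], x$proportion_p[["high"]],
              x$proportion_p[["overall"]]))
  cat(sprintf("Fisher exact (high/low x AD/non-AD): p=%.3g\n", x$fisher_p))
  invisible(x)
}

#' A/T classification of CSF profiles
#'
#' Dichotomises CSF amyloid and tau status by the published cutoffs: A+
#' if and only if amyloid-beta 42 < 550 pg/mL, T+ if and only if
#' phosphorylated tau > 52 pg/mL (both strict). Total tau is an annotation
#' only and plays no part in the classification. Profiles with a missing
#' required value are returned as `"unclassifiable"`.
#'
#' @param abeta42 CSF amyloid-beta 42, pg/mL (vectorised).
#' @param ptau CSF phosphorylated tau, pg/mL.
#' @param abeta_cutoff,ptau_cutoff Published cutoffs (550, 52 pg/mL).
#'
#' @return Factor with levels `A-/T-`, `A+/T-`, `A+/T+`, `A-/T+`,
#'   `unclassifiable`.
#' @export
#' @examples
#' classify_at(c(500, 676.41, 550), c(60, 70.31, 52))
classify_at <- function(abeta42, ptau, abeta_cutoff = 550, ptau_cutoff = 52) {
  if (length(abeta42) != length(ptau))
    stop_("abeta42 and ptau must be the same length")
  a <- abeta42 < abeta_cutoff
  t <- ptau > ptau_cutoff
  cls <- ifelse(is.na(a) | is.na(t), "unclassifiable",
                ifelse(a & t, "A+/T+",
                       ifelse(a & !t, "A+/T-",
                              ifelse(!a & t, "A-/T+", "A-/T-"))))
  factor(cls, levels = c("A-/T-", "A+/T-", "A+/T+", "A-/T+",
                         "unclassifiable"))
}
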