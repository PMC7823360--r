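#' Linear mixed-effects biomarker trajectory model
#'
#' Models the plasma biomarker across time and diagnostic trajectory for
#' two groups at a time (stable vs converter), with fixed effects for
#' intercept, time (years from baseline), group, and the time-by-group
#' interaction — the interaction being the slope difference of interest —
#' and per-subject random intercept and slope. Estimation delegates to
#' [nlme::lme()]. If the random-slope structure is singular or fails to
#' converge, the fit falls back to a random-intercept-only model with a
#' warning; if that also fails (e.g. noise-free data), to pooled ordinary
#' least squares, whose fixed effects are the zero-variance limit of the
#' mixed model.
#'
#' @param cohort Long-format cohort table.
#' @param groups Character vector of exactly two trajectory groups; the
#'   first is the reference (stable) level.
#' @param value,time,group,subject Column names.
#' @param method `"ML"` (default) or `"REML"`.
#'
#' @return Object of class `"trajectory_lme"`: list with `fixed` (estimate,
#'   SE, p per fixed effect), `interaction` (the slope-difference
#'   estimate), `slopes` (fitted per-group slopes), `varcomp`, `engine`
#'   (`"lme-slope"`, `"lme-intercept"` or `"ols"`), and `fit`.
#' @export
#' @examples
#' coh <- generate_longitudinal_cohort(seed = 1)
#' fit <- trajectory_lme(coh, c("StableCN", "CNtoAD"))
#' fit$interaction
trajectory_lme <- function(cohort, groups = c("StableCN", "CNtoAD"),
                           value = "up53", time = "visit_time",
                           group = "group", subject = "subject_id",
                           method = c("ML", "REML")) {
  method <- match.arg(method)
  if (length(groups) != 2L) stop_("exactly two groups are compared")
  d <- cohort[cohort[[group]] %in% groups, , drop = FALSE]
  if (nrow(d) == 0L) stop_("no rows in the requested groups")
  d <- data.frame(y = d[[value]], t = d[[time]],
                  g = factor(d[[group]], levels = groups),
                  id = d[[subject]])
  if (mean(table(d$id) >= 2) < 1)
    warn_("some subjects have fewer than 2 visits")

  engine <- "lme-slope"
  fit <- tryCatch(
    nlme::lme(y ~ t * g, random = ~ t | id, data = d, method = method,
              control = nlme::lmeControl(returnObject = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    engine <- "lme-intercept"
    fit <- tryCatch({
      warn_("singular random-slope structure; falling back to random intercept only")
      nlme::lme(y ~ t * g, random = ~ 1 | id, data = d, method = method)
    }, error = function(e) NULL)
  }
  if (is.null(fit)) {
    engine <- "ols"
    fit <- lm(y ~ t * g, data = d)
  }

  if (engine == "ols") {
    sm <- summary(fit)$coefficients
    fixed <- data.frame(term = rownames(sm), estimate = sm[, 1],
                        se = sm[, 2], p = sm[, 4], row.names = NULL)
    varcomp <- c(residual = summary(fit)$sigma^2)
  } else {
    tt <- summary(fit)$tTable
    fixed <- data.frame(term = rownames(tt), estimate = tt[, "Value"],
                        se = tt[, "Std.Error"], p = tt[, "p-value"],
                        row.names = NULL)
    vc <- nlme::VarCorr(fit)
    varcomp <- suppressWarnings(as.numeric(vc[, "Variance"]))
    names(varcomp) <- rownames(vc)
  }
  est <- fixed$estimate
  names(est) <- fixed$term
  inter <- unname(est[grep("^t:", names(est))][1])
  slope_ref <- unname(est["t"])
  structure(list(fixed = fixed, interaction = inter,
                 slopes = c(stable = slope_ref,
                            converter = slope_ref + inter),
                 varcomp = varcomp, groups = groups, engine = engine,
                 method = method, fit = fit),
            class = "trajectory_lme")
}

#' @export
print.trajectory_lme <- function(x, digits = 4, ...) {
  cat(sprintf("Biomarker trajectory LME (%s vs %s, engine %s)\n",
              x$groups[1], x$groups[2], x$engine))
  print(x$fixed, digits = digits, row.names = FALSE)
  cat(sprintf("\nFitted slopes: stable %.3f, converter %.3f (difference %.3f a.u./year)\n",
              x$slopes["stable"], x$slopes["converter"], x$interaction))
  invisible(x)
}

#' @export
coef.trajectory_lme <- function(object, ...) {
  est <- object$fixed$estimate
  names(est) <- object$fixed$term
  est
}
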