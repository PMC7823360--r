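#' Specification for a multiple-regression power analysis
#'
#' Bundles the quantities entering a fixed-effects multiple-regression power
#' calculation: the number of predictors `u` (numerator degrees of freedom),
#' Cohen's effect size `f2` (\eqn{f^2 = R^2/(1-R^2)}), the significance
#' level and the target power.
#'
#' @param u Number of predictors (numerator df), a positive integer.
#' @param f2 Cohen's \eqn{f^2} effect size, positive.
#' @param alpha Significance level in (0, 1).
#' @param power Target power in (0, 1) (used by [min_sample_size()]).
#'
#' @return A list of class `"power_spec"`.
#' @seealso [power_given_n()], [min_sample_size()]
#' @export
#' @examples
#' power_spec(u = 6, f2 = 0.666)
power_spec <- function(u = 6L, f2, alpha = 0.05, power = 0.80) {
  if (!is.numeric(u) || length(u) != 1L || u < 1 || u != round(u))
    stop_("`u` must be a positive integer")
  if (!is.numeric(f2) || length(f2) != 1L || f2 <= 0)
    stop_("`f2` must be a positive number")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop_("`alpha` must lie in (0, 1)")
  if (!is.numeric(power) || power <= 0 || power >= 1)
    stop_("`power` must lie in (0, 1)")
  structure(list(u = as.integer(u), f2 = f2, alpha = alpha, power = power),
            class = "power_spec")
}

#' Power of the multiple-regression F test at a given total sample size
#'
#' Computes the power of the overall F test of a multiple regression with
#' `u` predictors at total sample size `n_total`. The denominator degrees of
#' freedom are \eqn{v = n - u - 1} and the test statistic under the
#' alternative follows a noncentral F distribution with noncentrality
#' \eqn{\lambda = f^2 (u + v + 1)}:
#' \deqn{power = P[F'(u, v, \lambda) > F_{1-\alpha}(u, v)].}
#'
#' Fractional `n_total` is accepted (the noncentral F is defined for
#' non-integer df), which is what makes the inverse problem in
#' [min_sample_size()] well posed.
#'
#' @param spec A [power_spec()].
#' @param n_total Total sample size; must exceed `u + 1`.
#'
#' @return The power, a number in (0, 1).
#' @export
#' @examples
#' power_given_n(power_spec(u = 6, f2 = 0.666), n_total = 27.45)
power_given_n <- function(spec, n_total) {
  stopifnot(inherits(spec, "power_spec"))
  if (!is.numeric(n_total) || any(n_total <= spec$u + 1))
    stop_("`n_total` must exceed u + 1 = %d (denominator df would be <= 0)",
          spec$u + 1L)
  v <- n_total - spec$u - 1
  lambda <- spec$f2 * (spec$u + v + 1)
  fcrit <- qf(1 - spec$alpha, spec$u, v)
  1 - pf(fcrit, spec$u, v, ncp = lambda)
}

#' Minimum sample size achieving a target power
#'
#' Solves \eqn{power(n) = } target power for the multiple-regression F test
#' by bracketing and root finding on the (monotone) power curve of
#' [power_given_n()]. Reports both the fractional total sample size
#' `n_total` and the residual degrees of freedom `subjects`
#' (\eqn{v = n - u - 1}): power tools in this field conventionally quote
#' \eqn{v} as "the number of subjects" on top of the model parameters, and
#' that is the group size a study protocol quotes.
#'
#' @param spec A [power_spec()] carrying the target power.
#' @param max_n Upper cap on the search bracket; if the target power is not
#'   attainable below the cap an error is raised naming it.
#'
#' @return An object of class `"sample_size"`: a list with elements
#'   `n_total` (fractional), `subjects` (fractional \eqn{v}),
#'   `subjects_rounded` (to the nearest integer, the "approximately equal"
#'   convention), `subjects_ceiling` (strict ceiling), `power_achieved`, and
#'   the `spec`.
#' @export
#' @examples
#' min_sample_size(power_spec(u = 6, f2 = 0.666, power = 0.8))
min_sample_size <- function(spec, max_n = 1e6) {
  stopifnot(inherits(spec, "power_spec"))
  lo <- spec$u + 1 + 1e-6
  if (power_given_n(spec, max_n) < spec$power)
    stop_("target power %.2f not attainable with n_total <= %g", spec$power, max_n)
  root <- uniroot(function(n) power_given_n(spec, n) - spec$power,
                  lower = lo, upper = max_n, tol = 1e-10)$root
  v <- root - spec$u - 1
  structure(list(
    n_total          = root,
    subjects         = v,
    subjects_rounded = round(v),
    subjects_ceiling = ceiling(v),
    power_achieved   = power_given_n(spec, root),
    spec             = spec
  ), class = "sample_size")
}

#' @export
print.sample_size <- function(x, ...) {
  s <- x$spec
  cat("Multiple-regression sample size\n")
  cat(sprintf("  u = %d predictors, f2 = %g, alpha = %g, target power = %g\n",
              s$u, s$f2, s$alpha, s$power))
  cat(sprintf("  minimum subjects (residual df v): %.2f (~ %d; ceiling %d)\n",
              x$subjects, x$subjects_rounded, x$subjects_ceiling))
  cat(sprintf("  total n (v + u + 1): %.2f\n", x$n_total))
  invisible(x)
}
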