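#' Logistic-regression comparator model
#'
#' Fits the parametric comparator to the tree-based early-warning system: a
#' logistic regression of the dichotomous conversion outcome on the same
#' covariates, exposing the same prediction contract (probabilities in
#' (0, 1)) so that tree and Logit can be compared on identical subjects
#' with ROC/AUC metrics and the DeLong test.
#'
#' Estimation delegates to [stats::glm()] with a binomial family (i.e.
#' iteratively reweighted least squares). A rank-deficient design is
#' tolerated: aliased columns are dropped with a warning, which is the
#' minimum-norm resolution `glm` applies.
#'
#' @param formula Model formula with a 0/1 (or logical/two-level factor)
#'   response.
#' @param data Data frame.
#'
#' @return An object of class `"logit_model"` wrapping the `glm` fit.
#' @export
logit_model <- function(formula, data) {
  mf <- model.frame(formula, data)
  y <- as_binary(model.response(mf), "response")
  mf[[1L]] <- y
  fit <- suppressWarnings(glm(formula, data = data, family = binomial()))
  if (anyNA(coef(fit)))
    warn_("rank-deficient design; aliased columns dropped from the fit")
  structure(list(fit = fit, formula = formula, call = match.call()),
            class = "logit_model")
}

#' @export
predict.logit_model <- function(object, newdata, ...) {
  p <- predict(object$fit, newdata = newdata, type = "response")
  as.numeric(pmin(pmax(p, .Machine$double.eps), 1 - .Machine$double.eps))
}

#' @export
coef.logit_model <- function(object, ...) coef(object$fit)

#' @export
print.logit_model <- function(x, ...) {
  cat("Logit comparator model\n")
  print(coef(x$fit))
  invisible(x)
}
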