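## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warn_ <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## run expr with a locally seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_("`seed` must be a single finite number")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

## truncated normal draw by CDF inversion; bounds may be -Inf/Inf
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

## coerce a 0/1-like outcome (logical, factor with 2 levels, numeric) to 0/1
as_binary <- function(y, what = "outcome") {
  if (is.logical(y)) return(as.numeric(y))
  if (is.factor(y)) {
    if (nlevels(y) > 2L) stop_("%s has more than two levels", what)
    return(as.numeric(y) - 1)
  }
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop_("%s must contain only 0 and 1", what)
  y
}

## fast tie-corrected Mann-Whitney AUC on a 0/1 label vector
auc_mw <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop_("both outcome classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
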