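## cost-complexity pruning: weakest-link collapse and cross-validated
## subtree selection

## number of leaves and total leaf deviance below each node
subtree_stats <- function(node) {
  if (is.null(node$split)) return(list(nleaves = 1L, leafdev = node$dev))
  l <- subtree_stats(node$left); r <- subtree_stats(node$right)
  list(nleaves = l$nleaves + r$nleaves, leafdev = l$leafdev + r$leafdev)
}

## link strength g(t) = (R(t) - R(T_t)) / (|leaves(T_t)| - 1) of every
## internal node; Inf when there are none
min_link <- function(node) {
  best <- Inf
  walk <- function(nd) {
    if (is.null(nd$split)) return(invisible())
    st <- subtree_stats(nd)
    g <- (nd$dev - st$leafdev) / (st$nleaves - 1L)
    if (g < best) best <<- g
    walk(nd$left); walk(nd$right)
  }
  walk(node)
  best
}

collapse_links <- function(node, gmax) {
  if (is.null(node$split)) return(node)
  st <- subtree_stats(node)
  g <- (node$dev - st$leafdev) / (st$nleaves - 1L)
  if (g <= gmax + 1e-12) {
    node$split <- NULL; node$left <- NULL; node$right <- NULL
    return(node)
  }
  node$left <- collapse_links(node$left, gmax)
  node$right <- collapse_links(node$right, gmax)
  node
}

#' Prune a regression tree at a complexity penalty
#'
#' Repeatedly collapses the weakest links — internal nodes whose
#' per-terminal deviance gain \eqn{g(t) = (R(t) - R(T_t))/(|T_t| - 1)} does
#' not exceed `alpha` — until every remaining internal node is worth its
#' penalty.
#'
#' @param tree A fitted [rtree()].
#' @param alpha Non-negative cost-complexity penalty.
#'
#' @return The pruned `"rtree"`.
#' @export
prune <- function(tree, alpha) {
  stopifnot(inherits(tree, "rtree"), alpha >= 0)
  root <- tree$root
  repeat {
    m <- min_link(root)
    if (!is.finite(m) || m > alpha + 1e-12) break
    root <- collapse_links(root, m)
  }
  tree$root <- root
  tree$frame <- tree_frame(tree)
  tree
}

#' Cost-complexity subtree sequence
#'
#' Computes the nested sequence of optimally pruned subtrees of a grown
#' tree: starting from the full tree at penalty 0, the weakest link(s) are
#' collapsed at each step, yielding subtrees indexed by a nondecreasing
#' sequence of penalties and ending at the root-only tree. These are the
#' candidate models among which [rtree_cv()] selects by cross-validation.
#'
#' @param tree A fitted [rtree()].
#'
#' @return A list with one element per subtree: `list(alpha =, tree =,
#'   nleaves =)`, ordered by increasing `alpha`.
#' @export
prune_sequence <- function(tree) {
  stopifnot(inherits(tree, "rtree"))
  out <- list()
  cur <- tree
  st <- subtree_stats(cur$root)
  out[[1L]] <- list(alpha = 0, tree = cur, nleaves = st$nleaves)
  while (!is.null(cur$root$split)) {
    m <- min_link(cur$root)
    cur$root <- collapse_links(cur$root, m)
    cur$frame <- tree_frame(cur)
    st <- subtree_stats(cur$root)
    out[[length(out) + 1L]] <- list(alpha = max(m, 0), tree = cur,
                                    nleaves = st$nleaves)
  }
  out
}

#' Fit a regression tree with v-fold cross-validated pruning
#'
#' Grows the tree on all the data, derives its cost-complexity subtree
#' sequence, and selects the penalty by v-fold cross-validation: the data
#' are partitioned into `v` nearly equally sized folds and, in each of `v`
#' rounds, one fold is held out for validation while the remaining `v - 1`
#' folds are used for learning. The held-out deviance
#' \eqn{\sum (y_i - \hat p_i)^2} is accumulated at each candidate penalty
#' (geometric means of consecutive sequence penalties) and the subtree
#' minimising it is returned — or, under the one-standard-error rule, the
#' smallest subtree within one SE of the minimum.
#'
#' @param formula,data,controls As in [rtree()].
#' @param v Number of folds (default 10); must satisfy `2 <= v <= n`.
#' @param seed Optional integer making the fold assignment reproducible.
#' @param rule `"min"` (minimum CV deviance, default) or `"1se"`.
#'
#' @return A pruned `"rtree"` with an extra component `cv`: a data frame
#'   with columns `alpha`, `nleaves`, `cvdev`, `se`, and attribute `chosen`.
#' @export
rtree_cv <- function(formula, data, controls = rtree_control(), v = 10L,
                     seed = NULL, rule = c("min", "1se")) {
  rule <- match.arg(rule)
  n <- nrow(data)
  if (v < 2L || v > n) stop_("`v` must satisfy 2 <= v <= n (= %d)", n)
  full <- rtree(formula, data, controls)
  sq <- prune_sequence(full)
  alphas <- vapply(sq, `[[`, numeric(1), "alpha")
  K <- length(alphas)
  ## representative penalty for subtree k, optimal on [alpha_k, alpha_{k+1}):
  ## the geometric mean of the interval endpoints; the full tree is probed
  ## at 0 and the root-only subtree (interval [alpha_K, Inf)) at Inf, so
  ## fold trees genuinely collapse to their roots for that candidate
  eval_alpha <- numeric(K)
  if (K > 1L) {
    if (K > 2L)
      for (k in 2:(K - 1L)) eval_alpha[k] <- sqrt(alphas[k] * alphas[k + 1L])
    eval_alpha[K] <- Inf
  }
  mf <- model.frame(formula, data, na.action = na.pass)
  y <- as_binary(model.response(mf), "response")

  folds <- with_seed(seed, sample(rep(seq_len(v), length.out = n)))
  errs <- matrix(NA_real_, n, length(eval_alpha))
  root_dev_full <- full$root$dev
  for (f in seq_len(v)) {
    hold <- folds == f
    fit_f <- rtree(formula, data[!hold, , drop = FALSE], controls)
    ## penalties are applied on the relative-complexity scale (alpha per
    ## unit of root deviance), so fold trees grown on ~(v-1)/v of the data
    ## are pruned commensurately with the full tree
    scale_f <- if (root_dev_full > 0) fit_f$root$dev / root_dev_full else 1
    for (k in seq_along(eval_alpha)) {
      pk <- prune(fit_f, eval_alpha[k] * scale_f)
      p <- predict(pk, data[hold, , drop = FALSE])
      errs[hold, k] <- (y[hold] - p)^2
    }
  }
  cvdev <- colSums(errs)
  se <- apply(errs, 2L, sd) * sqrt(n)
  ## ties toward the smaller tree (larger alpha)
  kmin <- max(which(cvdev <= min(cvdev) + 1e-12))
  k <- if (rule == "1se") max(which(cvdev <= cvdev[kmin] + se[kmin])) else kmin
  chosen <- prune(full, eval_alpha[k])
  chosen$cv <- structure(
    data.frame(alpha = eval_alpha,
               nleaves = vapply(sq, `[[`, integer(1), "nleaves"),
               cvdev = cvdev, se = se),
    chosen = k, rule = rule, v = v, seed = seed)
  chosen
}
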