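# Independent oracles used to check the implementation by a different route.

# deviance about the mean, computed directly (not by cumulative sums)
oracle_dev <- function(y) sum((y - mean(y))^2)

# exhaustive best split: every (feature, midpoint-threshold) candidate is
# scored by direct deviance computation; ties within 1e-9 resolved by
# lowest feature index, then smallest threshold
oracle_best_split <- function(X, y, minbucket = 1L) {
  cand <- NULL
  for (j in seq_len(ncol(X))) {
    vals <- sort(unique(X[, j]))
    if (length(vals) < 2L) next
    for (thr in (vals[-1] + vals[-length(vals)]) / 2) {
      left <- X[, j] < thr
      if (sum(left) < minbucket || sum(!left) < minbucket) next
      red <- oracle_dev(y) - oracle_dev(y[left]) - oracle_dev(y[!left])
      cand <- rbind(cand, data.frame(feature = j, threshold = thr,
                                     reduction = red))
    }
  }
  if (is.null(cand)) return(NULL)
  mx <- max(cand$reduction)
  tied <- cand[cand$reduction >= mx - 1e-9, , drop = FALSE]
  tied <- tied[order(tied$feature, tied$threshold), , drop = FALSE]
  tied[1L, ]
}

# recursive brute-force tree growth under the same controls; returns the
# preorder list of (feature, threshold) split decisions
oracle_grow <- function(X, y, minsplit = 20L, minbucket = 7L, cp = 0.01,
                        maxdepth = 30L) {
  root_dev <- oracle_dev(y)
  splits <- list()
  recurse <- function(idx, depth) {
    if (length(idx) < minsplit || oracle_dev(y[idx]) <= 1e-12 ||
        depth >= maxdepth) return(invisible())
    best <- oracle_best_split(X[idx, , drop = FALSE], y[idx], minbucket)
    if (is.null(best) || best$reduction < cp * root_dev ||
        best$reduction <= 1e-12) return(invisible())
    splits[[length(splits) + 1L]] <<-
      c(feature = best$feature, threshold = best$threshold)
    left <- X[idx, best$feature] < best$threshold
    recurse(idx[left], depth + 1L)
    recurse(idx[!left], depth + 1L)
  }
  recurse(seq_along(y), 0L)
  splits
}

# preorder split decisions of a fitted rtree, as (feature index, threshold)
tree_splits <- function(tree) {
  splits <- list()
  walk <- function(node) {
    if (is.null(node$split)) return(invisible())
    splits[[length(splits) + 1L]] <<-
      c(feature = node$split$feature, threshold = node$split$threshold)
    walk(node$left); walk(node$right)
  }
  walk(tree$root)
  splits
}

# trapezoidal area under the empirical ROC (independent of the
# Mann-Whitney implementation)
oracle_auc_trapezoid <- function(scores, labels) {
  cuts <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- sapply(cuts, function(t) mean(scores[labels == 1] >= t))
  fpr <- sapply(cuts, function(t) mean(scores[labels == 0] >= t))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# logistic regression by hand-rolled iteratively reweighted least squares
oracle_irls <- function(X, y, tol = 1e-12, maxit = 100L) {
  X <- cbind(1, X)
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X, w * X), crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new; break
    }
    beta <- beta_new
  }
  drop(beta)
}

# two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration
oracle_fisher_2x2 <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  supp <- max(0, k - n):min(k, m)
  probs <- dhyper(supp, m, n, k)
  pobs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# random mixed-type fixture mimicking the six study covariates
make_fixture <- function(n, seed) {
  set.seed(seed)
  d <- data.frame(
    sex = factor(sample(c("F", "M"), n, replace = TRUE)),
    education = sample(0:3, n, replace = TRUE),
    age = rnorm(n, 73, 2),
    mmse = sample(20:30, n, replace = TRUE),
    apoe4 = runif(n) < 0.3,
    up53 = rnorm(n, 8, 2))
  p <- plogis(-8 + 1 * d$up53)
  d$y <- as.numeric(runif(n) < p)
  d
}

# numeric design matrix matching rtree's internal feature coercion
fixture_X <- function(d) {
  cbind(sex = as.numeric(d$sex) - 1, education = d$education, age = d$age,
        mmse = d$mmse, apoe4 = as.numeric(d$apoe4), up53 = d$up53)
}

# enumerate every pruned subtree of a tree (for pruning-optimality checks):
# returns a list of subtrees, each as its set of retained internal node ids
enumerate_pruned <- function(tree) {
  internals <- tree$frame$node[tree$frame$var != "<leaf>"]
  out <- list()
  walk_sets <- function(node) {
    # sets of internal ids kept in the subtree rooted here
    if (is.null(node$split)) return(list(integer(0)))
    l <- walk_sets(node$left); r <- walk_sets(node$right)
    sets <- list(integer(0))  # collapsed at this node
    for (a in l) for (b in r)
      sets[[length(sets) + 1L]] <- c(node$id, a, b)
    sets
  }
  walk_sets(tree$root)
}

# in-sample deviance and leaf count of the subtree defined by the retained
# internal-node id set
subtree_cost <- function(tree, keep) {
  walk <- function(node) {
    if (is.null(node$split) || !(node$id %in% keep))
      return(c(dev = node$dev, leaves = 1))
    walk(node$left) + walk(node$right)
  }
  walk(tree$root)
}
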