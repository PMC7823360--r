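#' Growth controls for a regression tree
#'
#' @param minsplit Minimum number of observations a node must contain before
#'   a split is attempted.
#' @param minbucket Minimum number of observations in a terminal node.
#' @param cp Complexity parameter: a split must reduce the deviance by at
#'   least `cp` times the root-node deviance to be accepted.
#' @param maxdepth Maximum tree depth (root at depth 0).
#'
#' @return A list of class `"rtree_control"`.
#' @export
rtree_control <- function(minsplit = 20L, minbucket = 7L, cp = 0.01,
                          maxdepth = 30L) {
  if (minsplit < 2L) stop_("`minsplit` must be at least 2")
  if (minbucket < 1L) stop_("`minbucket` must be at least 1")
  if (cp < 0) stop_("`cp` must be non-negative")
  if (maxdepth < 1L) stop_("`maxdepth` must be at least 1")
  structure(list(minsplit = as.integer(minsplit),
                 minbucket = as.integer(minbucket),
                 cp = cp, maxdepth = as.integer(maxdepth)),
            class = "rtree_control")
}

## deviance of a 0/1 (or numeric) vector about its mean
node_dev <- function(y) sum((y - mean(y))^2)

## coerce one feature column to numeric, recording how, so that predict()
## can apply the identical coercion
coerce_feature <- function(x, name) {
  if (is.numeric(x)) return(list(x = as.numeric(x), type = "numeric"))
  if (is.logical(x)) return(list(x = as.numeric(x), type = "logical"))
  if (is.ordered(x)) return(list(x = as.numeric(x), type = "ordered",
                                 levels = levels(x)))
  if (is.character(x)) x <- factor(x)
  if (is.factor(x)) {
    if (nlevels(x) > 2L)
      stop_("feature '%s' is an unordered factor with >2 levels; recode it",
            name)
    return(list(x = as.numeric(x) - 1, type = "binary", levels = levels(x)))
  }
  stop_("feature '%s' has unsupported type", name)
}

apply_coercion <- function(x, info, name) {
  switch(info$type,
    numeric = as.numeric(x),
    logical = as.numeric(x),
    ordered = as.numeric(factor(as.character(x), levels = info$levels,
                                ordered = TRUE)),
    binary  = {
      if (is.logical(x)) as.numeric(x)
      else as.numeric(factor(as.character(x), levels = info$levels)) - 1
    })
}

## all candidate splits of one node: for each feature, midpoints between
## consecutive distinct sorted values honouring minbucket; returns the
## deviance reduction of every candidate
node_candidates <- function(X, y, idx, minbucket) {
  n <- length(idx)
  ynode <- y[idx]
  parent_dev <- node_dev(ynode)
  out <- vector("list", ncol(X))
  for (j in seq_len(ncol(X))) {
    x <- X[idx, j]
    ord <- order(x)
    xs <- x[ord]; ys <- ynode[ord]
    cs <- cumsum(ys); cs2 <- cumsum(ys^2)
    tot <- cs[n]; tot2 <- cs2[n]
    i <- seq_len(n - 1L)
    ok <- (xs[i] < xs[i + 1L]) & (i >= minbucket) & ((n - i) >= minbucket)
    if (!any(ok)) next
    i <- i[ok]
    devL <- cs2[i] - cs[i]^2 / i
    devR <- (tot2 - cs2[i]) - (tot - cs[i])^2 / (n - i)
    out[[j]] <- data.frame(feature = j,
                           threshold = (xs[i] + xs[i + 1L]) / 2,
                           reduction = parent_dev - (devL + devR))
  }
  do.call(rbind, out)
}

## deterministic selection: best reduction; ties (within 1e-9) broken by
## lowest feature index, then smallest threshold
select_split <- function(cand) {
  if (is.null(cand) || nrow(cand) == 0L) return(NULL)
  mx <- max(cand$reduction)
  tied <- cand[cand$reduction >= mx - 1e-9, , drop = FALSE]
  tied <- tied[order(tied$feature, tied$threshold), , drop = FALSE]
  tied[1L, ]
}

#' Fit a binary regression tree for a dichotomous outcome
#'
#' Grows a binary regression tree by recursive partitioning. At every node
#' the split chosen is the one, over all features and all candidate
#' thresholds (midpoints between consecutive distinct sorted values), that
#' maximally reduces the node deviance \eqn{\sum_i (y_i - \bar y)^2}. With a
#' 0/1 outcome the prediction in each terminal node is the relative
#' frequency of 1 in that node, so the tree is an AD-prevalence (risk)
#' estimator with leaf values in \eqn{[0,1]}.
#'
#' Rows with feature value below the threshold go left; a value exactly at
#' the threshold routes right (thresholds are midpoints of distinct observed
#' values, so this arises only for new data). Ties in deviance reduction are
#' broken by the declared feature order, then by the smaller threshold, so
#' refitting on a row-permuted table yields the identical tree. There is no
#' surrogate-split machinery: missing feature values are an error at
#' prediction time and must be handled upstream.
#'
#' @param formula Model formula, e.g. `converted ~ sex + education + age +
#'   mmse + apoe4 + up53`. The response must be 0/1 (or logical / two-level
#'   factor).
#' @param data A data frame.
#' @param controls A [rtree_control()] object.
#'
#' @return An object of class `"rtree"` with components `root` (the nested
#'   node structure), `frame` (a flat per-node table), `features`,
#'   `controls` and `call`. Methods: [predict.rtree()], `print`, `summary`,
#'   `plot`.
#' @seealso [rtree_cv()] for cross-validated pruning, [prune_sequence()]
#' @export
#' @examples
#' d <- data.frame(up53 = c(1, 2, 9, 10), y = c(0, 0, 1, 1))
#' fit <- rtree(y ~ up53, d, rtree_control(minsplit = 2, minbucket = 1))
#' predict(fit, data.frame(up53 = c(3, 8)))
rtree <- function(formula, data, controls = rtree_control()) {
  stopifnot(inherits(controls, "rtree_control"))
  mf <- model.frame(formula, data, na.action = na.pass)
  if (nrow(mf) == 0L) stop_("empty table: no rows to fit")
  y <- as_binary(model.response(mf), "response")
  feats <- attr(terms(mf), "term.labels")
  if (length(feats) == 0L) stop_("no features on the right-hand side")
  coercions <- list()
  X <- matrix(NA_real_, nrow(mf), length(feats),
              dimnames = list(NULL, feats))
  for (k in seq_along(feats)) {
    ci <- coerce_feature(mf[[feats[k]]], feats[k])
    X[, k] <- ci$x
    coercions[[feats[k]]] <- ci[-1L]
  }
  if (anyNA(X) || anyNA(y))
    stop_("missing values in features or response; handle them upstream")
  if (nrow(X) < 2L * controls$minbucket && var(y) > 0)
    if (nrow(X) < 2L) stop_("need at least 2 rows")

  root_dev <- node_dev(y)
  min_improve <- controls$cp * root_dev

  build <- function(idx, depth, id) {
    n <- length(idx)
    yhat <- mean(y[idx])
    dev <- node_dev(y[idx])
    node <- list(id = id, n = n, dev = dev, yhat = yhat,
                 split = NULL, left = NULL, right = NULL)
    if (n < controls$minsplit || dev <= 1e-12 ||
        depth >= controls$maxdepth) return(node)
    best <- select_split(node_candidates(X, y, idx, controls$minbucket))
    if (is.null(best) || best$reduction < min_improve ||
        best$reduction <= 1e-12) return(node)
    j <- best$feature
    node$split <- list(var = feats[j], feature = j,
                       threshold = best$threshold,
                       improvement = best$reduction)
    go_left <- X[idx, j] < best$threshold
    node$left <- build(idx[go_left], depth + 1L, 2L * id)
    node$right <- build(idx[!go_left], depth + 1L, 2L * id + 1L)
    node
  }

  root <- build(seq_along(y), 0L, 1L)
  obj <- structure(list(root = root, features = feats,
                        coercions = coercions, controls = controls,
                        formula = formula, call = match.call()),
                   class = "rtree")
  obj$frame <- tree_frame(obj)
  obj
}

## flatten the nested tree into a per-node table (depth-first, left first)
tree_frame <- function(tree) {
  rows <- list()
  walk <- function(node, depth) {
    rows[[length(rows) + 1L]] <<- data.frame(
      node = node$id, depth = depth,
      var = if (is.null(node$split)) "<leaf>" else node$split$var,
      threshold = if (is.null(node$split)) NA_real_ else node$split$threshold,
      n = node$n, dev = node$dev, yhat = node$yhat,
      stringsAsFactors = FALSE)
    if (!is.null(node$split)) {
      walk(node$left, depth + 1L)
      walk(node$right, depth + 1L)
    }
  }
  walk(tree$root, 0L)
  do.call(rbind, rows)
}

#' Predict AD-likelihood risk scores from a fitted regression tree
#'
#' Routes each row of `newdata` down the tree ("value < threshold" goes
#' left, values at or above the threshold go right) and returns the relative
#' frequency of the outcome in the terminal node reached — a risk score in
#' \eqn{[0, 1]}.
#'
#' @param object A fitted [rtree()].
#' @param newdata Data frame supplying every fitted feature.
#' @param type `"risk"` returns the leaf prevalence; `"leaf"` returns the
#'   terminal-node id.
#' @param ... Unused.
#'
#' @return Numeric vector of risk scores (or integer leaf ids).
#' @export
predict.rtree <- function(object, newdata, type = c("risk", "leaf"), ...) {
  type <- match.arg(type)
  missing_feats <- setdiff(object$features, names(newdata))
  if (length(missing_feats))
    stop_("newdata lacks fitted feature(s): %s",
          paste(missing_feats, collapse = ", "))
  X <- matrix(NA_real_, nrow(newdata), length(object$features),
              dimnames = list(NULL, object$features))
  for (k in seq_along(object$features)) {
    f <- object$features[k]
    X[, k] <- apply_coercion(newdata[[f]], object$coercions[[f]], f)
  }
  if (anyNA(X)) {
    bad <- which(apply(X, 1L, anyNA))[1L]
    stop_("missing feature value in row %d; no surrogate splits are used",
          bad)
  }
  out <- numeric(nrow(X)); leaf <- integer(nrow(X))
  for (i in seq_len(nrow(X))) {
    node <- object$root
    while (!is.null(node$split)) {
      node <- if (X[i, node$split$feature] < node$split$threshold)
        node$left else node$right
    }
    out[i] <- node$yhat; leaf[i] <- node$id
  }
  if (type == "leaf") leaf else out
}

#' @export
print.rtree <- function(x, digits = 4, ...) {
  cat("Regression tree (dichotomous outcome)\n")
  cat(sprintf("  %d terminal node(s), root n = %d, root deviance = %s\n\n",
              sum(x$frame$var == "<leaf>"), x$root$n,
              format(x$root$dev, digits = digits)))
  cat("node), split, n, deviance, yhat  (* = terminal)\n")
  show <- function(node, depth, label) {
    ind <- paste(rep("  ", depth), collapse = "")
    star <- if (is.null(node$split)) " *" else ""
    cat(sprintf("%s%d) %s  n=%d dev=%s yhat=%s%s\n", ind, node$id, label,
                node$n, format(node$dev, digits = digits),
                format(node$yhat, digits = digits), star))
    if (!is.null(node$split)) {
      s <- node$split
      show(node$left, depth + 1L,
           sprintf("%s < %s", s$var, format(s$threshold, digits = digits)))
      show(node$right, depth + 1L,
           sprintf("%s >= %s", s$var, format(s$threshold, digits = digits)))
    }
  }
  show(x$root, 0L, "root")
  invisible(x)
}

#' @export
summary.rtree <- function(object, ...) {
  fr <- object$frame
  leaves <- fr[fr$var == "<leaf>", ]
  structure(list(frame = fr, leaves = leaves, controls = object$controls,
                 cv = object$cv), class = "summary.rtree")
}

#' @export
print.summary.rtree <- function(x, ...) {
  cat("Regression tree summary\n\nPer-node table:\n")
  print(x$frame, row.names = FALSE)
  if (!is.null(x$cv)) {
    cat("\nCross-validation pruning table:\n")
    print(x$cv, row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.rtree <- function(x, ...) {
  fr <- x$frame
  depth <- fr$depth
  xpos <- seq_len(nrow(fr))
  plot(xpos, -depth, type = "n", axes = FALSE, xlab = "", ylab = "depth",
       main = "Regression tree", ...)
  lab <- ifelse(fr$var == "<leaf>",
                sprintf("n=%d\nyhat=%.2f", fr$n, fr$yhat),
                sprintf("%s<%.3g", fr$var, fr$threshold))
  text(xpos, -depth, lab, cex = 0.8)
  axis(2, at = -unique(depth), labels = unique(depth))
  invisible(x)
}
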