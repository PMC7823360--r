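## Two-step rolling-window early-warning procedure: calibrate the tree on
## an expanding window of visits, forecast conversion at the next visit out
## of sample, augment the first window when the AD class is absent there,
## and bootstrap the out-of-sample predictions.

#' Augmentation of a training window lacking the AD class
#'
#' At baseline no subject carries the AD diagnosis, so the first training
#' window contains no outcome-1 row and a prevalence tree cannot learn a
#' split. A small-scale training set is therefore injected:
#' `"borrow-labeled"` draws `k` AD-labelled rows (with replacement if
#' needed) from a user-supplied reference pool; `"synthetic-positive"`
#' generates `k` AD-labelled rows from the converter-group trajectory
#' generator at the final visit; `"none"` disables augmentation (an error
#' is then raised if the window has no positive row).
#'
#' @param strategy One of `"borrow-labeled"`, `"synthetic-positive"`,
#'   `"none"`.
#' @param k Number of injected AD-labelled records (default 5).
#' @param pool Data frame of AD-labelled rows for `"borrow-labeled"` (must
#'   contain the covariates used by the tree).
#' @param seed Optional seed for the draw.
#'
#' @return A list of class `"augmentation_spec"`.
#' @export
augmentation_spec <- function(strategy = c("borrow-labeled",
                                           "synthetic-positive", "none"),
                              k = 5L, pool = NULL, seed = NULL) {
  strategy <- match.arg(strategy)
  if (strategy != "none" && k < 1L) stop_("`k` must be >= 1")
  structure(list(strategy = strategy, k = as.integer(k), pool = pool,
                 seed = seed), class = "augmentation_spec")
}

## draw k synthetic AD-labelled covariate rows from the converter-group
## generator (final-visit CN-to-AD law)
synthetic_positive_rows <- function(k, params = trajectory_params(),
                                    seed = NULL) {
  sizes <- c(StableCN = 1L, CNtoMCI = 1L, CNtoAD = max(k, 1L),
             StableMCI = 1L, MCItoAD = 1L)
  coh <- generate_longitudinal_cohort(params, group_sizes = sizes,
                                      seed = seed)
  rows <- coh[coh$group == "CNtoAD" & coh$visit == "T2", , drop = FALSE]
  rows[seq_len(k), , drop = FALSE]
}

#' Run the rolling-window early-warning procedure
#'
#' Implements the two-step expanding-window scheme: the regression tree is
#' calibrated on the baseline visit (augmented when the AD class is absent)
#' and used to forecast each subject's conversion at the next visit, out of
#' sample; the window is then widened to baseline plus the first follow-up
#' and the refitted tree forecasts the final visit. Augmented rows injected
#' into an earlier window remain part of every later (expanding) training
#' window, since later windows are formed by joining the reinforced earlier
#' training set with the next visit. Subjects missing at a
#' test visit receive the carried-forward score from the previous window,
#' flagged in the output. The out-of-sample outcome of a subject at a test
#' visit is its clinical diagnosis at that visit (AD = 1, otherwise 0); for
#' carried-forward subjects it is the last observed diagnosis (AD is
#' absorbing).
#'
#' @param cohort A long-format cohort table ([generate_longitudinal_cohort()]
#'   or [read_cohort()]).
#' @param covariates Character vector of feature columns (default the six
#'   study covariates).
#' @param controls [rtree_control()] growth controls.
#' @param cv `NULL` for a plain [rtree()] fit, or a list
#'   `list(v =, seed =, rule =)` to select the tree by [rtree_cv()].
#' @param augmentation An [augmentation_spec()].
#'
#' @return An object of class `"rolling_window"`: list with `plan` (the
#'   (train-visits, test-visit) pairs), `windows` (per-step fitted tree and
#'   training metadata), and `predictions` (data frame: `subject_id`,
#'   `visit`, `score`, `outcome`, `carried`, `window`).
#' @export
rolling_window <- function(cohort,
                           covariates = c("sex", "education", "age",
                                          "mmse", "apoe4", "up53"),
                           controls = rtree_control(),
                           cv = list(v = 10L, seed = 1L, rule = "min"),
                           augmentation = augmentation_spec(
                             "synthetic-positive")) {
  stopifnot(is.data.frame(cohort))
  need <- c("subject_id", "visit", "visit_time", "diagnosis", covariates)
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop_("cohort lacks column(s): %s", paste(miss, collapse = ", "))
  vt <- unique(cohort[, c("visit", "visit_time")])
  vt <- vt[order(vt$visit_time), ]
  if (nrow(vt) < 2L) stop_("rolling window needs at least 2 visits")
  visits <- vt$visit
  plan <- lapply(seq_len(nrow(vt) - 1L), function(k)
    list(train = visits[seq_len(k)], test = visits[k + 1L]))

  fml <- as.formula(paste(".y ~", paste(covariates, collapse = " + ")))
  windows <- vector("list", length(plan))
  preds <- list()
  aug_rows <- NULL  # augmentation persists: later windows join the
                    # reinforced earlier training set
  for (k in seq_along(plan)) {
    step <- plan[[k]]
    train <- cohort[cohort$visit %in% step$train, , drop = FALSE]
    test <- cohort[cohort$visit == step$test, , drop = FALSE]
    if (nrow(test) == 0L)
      stop_("test visit %s has zero subjects", step$test)
    ## leakage guard: no (subject, visit) key may appear on both sides
    tk <- paste(train$subject_id, train$visit)
    sk <- paste(test$subject_id, test$visit)
    stopifnot(length(intersect(tk, sk)) == 0L)

    train$.y <- as.numeric(train$diagnosis == "AD")
    if (!is.null(aug_rows))
      train <- rbind(train, aug_rows[, names(train), drop = FALSE])
    aug_k <- if (is.null(aug_rows)) 0L else nrow(aug_rows)
    if (sum(train$.y) == 0L) {
      if (augmentation$strategy == "none")
        stop_("training window {%s} contains no AD-labelled row and augmentation is 'none'",
              paste(step$train, collapse = ","))
      extra <- if (augmentation$strategy == "borrow-labeled") {
        if (is.null(augmentation$pool))
          stop_("borrow-labeled augmentation requires a reference `pool`")
        pool <- augmentation$pool
        idx <- with_seed(augmentation$seed,
                         sample.int(nrow(pool), augmentation$k,
                                    replace = nrow(pool) < augmentation$k))
        pool[idx, , drop = FALSE]
      } else {
        synthetic_positive_rows(augmentation$k,
                                attr(cohort, "params") %||% trajectory_params(),
                                seed = augmentation$seed)
      }
      extra <- extra[, intersect(names(train), names(extra)), drop = FALSE]
      extra$.y <- 1
      for (cc in setdiff(names(train), names(extra))) extra[[cc]] <- NA
      ## synthetic ids and the first train visit, so augmented rows can
      ## never collide with an out-of-sample (subject, visit) key
      extra$subject_id <- sprintf("AUG%03d", seq_len(nrow(extra)))
      extra$visit <- step$train[1L]
      extra$visit_time <- min(train$visit_time)
      extra$diagnosis <- "AD"
      aug_rows <- extra[, names(train), drop = FALSE]
      train <- rbind(train, aug_rows)
      aug_k <- nrow(aug_rows)
    }
    tree <- if (is.null(cv)) rtree(fml, train, controls)
            else rtree_cv(fml, train, controls, v = min(cv$v, nrow(train)),
                          seed = cv$seed, rule = cv$rule %||% "min")
    score <- predict(tree, test)
    windows[[k]] <- list(step = k, train_visits = step$train,
                         test_visit = step$test, tree = tree,
                         n_train = nrow(train), n_augmented = aug_k,
                         n_test = nrow(test))
    preds[[k]] <- data.frame(subject_id = test$subject_id,
                             visit = step$test, score = score,
                             outcome = as.numeric(test$diagnosis == "AD"),
                             carried = FALSE, window = k,
                             stringsAsFactors = FALSE)
  }
  predictions <- do.call(rbind, preds)

  ## carry-forward: subjects scored at an earlier test visit but absent at a
  ## later one keep their previous score, flagged; their outcome is the
  ## last observed diagnosis
  for (k in seq_along(plan)[-1L]) {
    tv <- plan[[k]]$test
    seen_before <- unique(predictions$subject_id[predictions$window < k])
    present <- predictions$subject_id[predictions$window == k]
    missing_ids <- setdiff(seen_before, present)
    for (id in missing_ids) {
      prev <- predictions[predictions$subject_id == id &
                          predictions$window < k, , drop = FALSE]
      prev <- prev[which.max(prev$window), , drop = FALSE]
      last_dx <- cohort[cohort$subject_id == id, , drop = FALSE]
      last_dx <- last_dx$diagnosis[which.max(last_dx$visit_time)]
      predictions <- rbind(predictions, data.frame(
        subject_id = id, visit = tv, score = prev$score,
        outcome = as.numeric(last_dx == "AD"), carried = TRUE,
        window = k, stringsAsFactors = FALSE))
    }
  }
  rownames(predictions) <- NULL
  structure(list(plan = plan, windows = windows, predictions = predictions,
                 covariates = covariates,
                 augmentation = augmentation[c("strategy", "k", "seed")]),
            class = "rolling_window")
}

#' @export
print.rolling_window <- function(x, ...) {
  cat("Rolling-window early-warning procedure\n")
  for (w in x$windows)
    cat(sprintf("  step %d: train {%s} (n=%d, +%d augmented) -> test %s (n=%d)\n",
                w$step, paste(w$train_visits, collapse = ","), w$n_train,
                w$n_augmented, w$test_visit, w$n_test))
  cat(sprintf("  %d out-of-sample predictions (%d carried forward)\n",
              nrow(x$predictions), sum(x$predictions$carried)))
  invisible(x)
}

#' @export
summary.rolling_window <- function(object, ...) {
  pr <- object$predictions
  per_window <- lapply(split(pr, pr$window), function(d) {
    auc <- if (length(unique(d$outcome)) == 2L) auc_mw(d$score, d$outcome)
           else NA_real_
    data.frame(window = d$window[1], visit = d$visit[1], n = nrow(d),
               n_pos = sum(d$outcome), auc = auc)
  })
  out <- do.call(rbind, per_window)
  rownames(out) <- NULL
  out
}

#' Stratified bootstrap of rolling-window predictions
#'
#' Percentile 95% confidence intervals, over `B` outcome-stratified
#' resamples of the scored subjects at a test visit, for (i) the percent
#' agreement of the risk-zone classification with clinical diagnosis and
#' (ii) the out-of-sample AUC. Stratification preserves the class counts,
#' so no resample degenerates to a single class.
#'
#' @param result A `"rolling_window"` object (its final test window is
#'   used) or a data frame with columns `score` and `outcome`.
#' @param B Number of bootstrap replicates (>= 100).
#' @param seed Optional seed.
#' @param bands [risk_bands()] used for the agreement statistic.
#' @param rule Agreement rule, see [agreement_report()].
#' @param conf Confidence level (default 0.95).
#'
#' @return List with elements `agreement` and `auc`, each
#'   `c(estimate, lower, upper)`; agreement is in percent.
#' @export
bootstrap_predictions <- function(result, B = 1000L, seed = NULL,
                                  bands = risk_bands(),
                                  rule = "middle-converter", conf = 0.95) {
  if (inherits(result, "rolling_window")) {
    pr <- result$predictions
    pr <- pr[pr$window == max(pr$window), , drop = FALSE]
  } else pr <- result
  if (B < 100L) stop_("`B` must be at least 100")
  score <- pr$score; y <- as_binary(pr$outcome, "outcome")
  if (length(unique(y)) < 2L) stop_("both outcome classes required")
  agree_of <- function(s, yy)
    agreement_report(zone_of(s, bands), yy, rule = rule)$agreement
  est_ag <- agree_of(score, y)
  est_auc <- auc_mw(score, y)
  ipos <- which(y == 1); ineg <- which(y == 0)
  stats <- with_seed(seed, {
    t(vapply(seq_len(B), function(b) {
      idx <- c(sample(ipos, length(ipos), replace = TRUE),
               sample(ineg, length(ineg), replace = TRUE))
      c(agree_of(score[idx], y[idx]), auc_mw(score[idx], y[idx]))
    }, c(0, 0)))
  })
  a <- (1 - conf) / 2
  qa <- unname(quantile(stats[, 1], c(a, 1 - a)))
  qu <- unname(quantile(stats[, 2], c(a, 1 - a)))
  list(agreement = c(estimate = est_ag,
                     lower = min(qa[1], est_ag), upper = max(qa[2], est_ag)),
       auc = c(estimate = est_auc,
               lower = min(qu[1], est_auc), upper = max(qu[2], est_auc)))
}
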