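test_that("the window plan is ({Baseline}->T1), ({Baseline,T1}->T2)", {
  coh <- generate_longitudinal_cohort(seed = 1)
  rw <- rolling_window(coh, cv = NULL)
  expect_length(rw$plan, 2)
  expect_equal(rw$plan[[1]]$train, "Baseline")
  expect_equal(rw$plan[[1]]$test, "T1")
  expect_equal(rw$plan[[2]]$train, c("Baseline", "T1"))
  expect_equal(rw$plan[[2]]$test, "T2")
  # expanding windows: training size strictly increases
  expect_lt(rw$windows[[1]]$n_train, rw$windows[[2]]$n_train)
})

test_that("no out-of-sample (subject, visit) pair was seen in its training window", {
  coh <- generate_longitudinal_cohort(seed = 2)
  rw <- rolling_window(coh, cv = NULL)
  for (k in seq_along(rw$plan)) {
    train_keys <- with(coh[coh$visit %in% rw$plan[[k]]$train, ],
                       paste(subject_id, visit))
    pred_k <- rw$predictions[rw$predictions$window == k &
                             !rw$predictions$carried, ]
    test_keys <- paste(pred_k$subject_id, pred_k$visit)
    expect_length(intersect(train_keys, test_keys), 0)
  }
})

test_that("the procedure is deterministic under fixed seeds", {
  coh <- generate_longitudinal_cohort(seed = 3)
  rw1 <- rolling_window(coh, cv = list(v = 10, seed = 5, rule = "min"),
                        augmentation = augmentation_spec(
                          "synthetic-positive", seed = 9))
  rw2 <- rolling_window(coh, cv = list(v = 10, seed = 5, rule = "min"),
                        augmentation = augmentation_spec(
                          "synthetic-positive", seed = 9))
  expect_identical(rw1$predictions, rw2$predictions)
})

test_that("with no converters and synthetic positives, no forecast reaches 1", {
  p <- trajectory_params()
  coh <- generate_longitudinal_cohort(p, seed = 4)
  # keep only never-converting subjects
  coh <- coh[coh$group %in% c("StableCN", "StableMCI"), ]
  rw <- rolling_window(coh, cv = NULL,
                       augmentation = augmentation_spec(
                         "synthetic-positive", k = 5, seed = 1))
  expect_true(all(rw$predictions$score < 1))
  # augmented class frequency bounds every leaf prevalence
  expect_gt(rw$windows[[1]]$n_augmented, 0)
})

test_that("borrow-labeled augmentation draws from the supplied pool", {
  coh <- generate_longitudinal_cohort(seed = 6)
  stable <- coh[coh$group %in% c("StableCN", "StableMCI"), ]
  pool <- coh[coh$diagnosis == "AD", ]
  rw <- rolling_window(stable, cv = NULL,
                       augmentation = augmentation_spec(
                         "borrow-labeled", k = 5, pool = pool, seed = 2))
  expect_equal(rw$windows[[1]]$n_augmented, 5L)
  expect_error(
    rolling_window(stable, cv = NULL,
                   augmentation = augmentation_spec("borrow-labeled", k = 5)),
    "pool")
  expect_error(
    rolling_window(stable, cv = NULL,
                   augmentation = augmentation_spec("none")),
    "no AD-labelled row")
})

test_that("subjects missing at a test visit get a flagged carry-forward score", {
  p <- trajectory_params(missing_pattern = TRUE)
  coh <- generate_longitudinal_cohort(p, seed = 7)
  rw <- rolling_window(coh, cv = NULL)
  carried <- rw$predictions[rw$predictions$carried, ]
  expect_equal(nrow(carried), 3L)  # the T1-converted MCI-to-AD
  expect_true(all(carried$visit == "T2"))
  expect_true(all(carried$outcome == 1))
  # carried scores equal the subject's previous-window score
  for (i in seq_len(nrow(carried))) {
    prev <- rw$predictions[rw$predictions$subject_id ==
                             carried$subject_id[i] &
                           rw$predictions$window == 1, ]
    expect_equal(carried$score[i], prev$score)
  }
})

test_that("degenerate inputs are rejected", {
  coh <- generate_longitudinal_cohort(seed = 8)
  expect_error(rolling_window(coh[coh$visit == "Baseline", ], cv = NULL),
               "at least 2 visits")
  expect_error(rolling_window(coh[, setdiff(names(coh), "mmse")], cv = NULL),
               "mmse")
})

test_that("bootstrap of all-correct predictions yields a [100, 100] agreement CI", {
  pr <- data.frame(score = rep(c(0.05, 0.95), each = 20),
                   outcome = rep(c(0, 1), each = 20))
  ci <- bootstrap_predictions(pr, B = 200, seed = 1)
  expect_equal(unname(ci$agreement), c(100, 100, 100))
  expect_equal(unname(ci$auc), c(1, 1, 1))
})

test_that("bootstrap CI width shrinks with sample size at fixed B", {
  make_preds <- function(n, seed) {
    set.seed(seed)
    y <- rep(c(0, 1), length.out = n)
    data.frame(score = plogis(rnorm(n, 1.5 * y)), outcome = y)
  }
  ci_small <- bootstrap_predictions(make_preds(50, 1), B = 400, seed = 2)
  ci_big <- bootstrap_predictions(make_preds(500, 1), B = 400, seed = 2)
  width <- function(ci) unname(ci$auc["upper"] - ci$auc["lower"])
  expect_lt(width(ci_big), width(ci_small))
})
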