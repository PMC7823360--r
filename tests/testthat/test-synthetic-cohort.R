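test_that("default cohort reproduces the configured group sizes and marginals", {
  coh <- generate_longitudinal_cohort(seed = 101)
  base <- coh[coh$visit == "Baseline", ]
  sizes <- table(base$group)
  expect_equal(unname(sizes[c("StableCN", "CNtoMCI", "CNtoAD",
                              "StableMCI", "MCItoAD")]),
               as.table(c(37L, 17L, 10L, 17L, 9L)), ignore_attr = TRUE)
  # CN marginals within 3 SE of the configured values
  cn <- base[base$diagnosis == "CN", ]
  expect_lt(abs(mean(cn$age) - 73), 3 * 1.22 / sqrt(nrow(cn)))
  expect_lt(abs(mean(cn$mmse) - 27.56),
            3 * 2.28 / sqrt(nrow(cn)) + 0.5)  # rounding to integer MMSE
  mci <- base[base$diagnosis == "MCI", ]
  expect_lt(abs(mean(mci$age) - 73.28), 3 * 1.36 / sqrt(nrow(mci)))
  expect_true(all(coh$up53 > 0))
  expect_true(all(coh$mmse >= 0 & coh$mmse <= 30))
})

test_that("per-group biomarker means converge to the configured trajectory", {
  p <- trajectory_params()
  big <- c(StableCN = 400L, CNtoMCI = 400L, CNtoAD = 400L,
           StableMCI = 400L, MCItoAD = 400L)
  coh <- generate_longitudinal_cohort(p, group_sizes = big, seed = 7)
  sdm <- sqrt(p$sd_intercept^2 + p$sd_residual^2)
  for (g in names(big)) {
    for (v in c("Baseline", "T2")) {
      t <- p$visit_times[[v]]
      target <- p$up53_baseline_mean[[g]] + p$up53_slope[[g]] * t
      got <- coh$up53[coh$group == g & coh$visit == v]
      expect_lt(abs(mean(got) - target), 3 * sdm / sqrt(length(got)) + 3e-2)
    }
  }
})

test_that("zero-noise parameters place every subject exactly on the group line", {
  p <- trajectory_params(sd_intercept = 0, sd_slope = 0, sd_residual = 0)
  coh <- generate_longitudinal_cohort(p, seed = 5)
  expected <- p$up53_baseline_mean[coh$group] +
    p$up53_slope[coh$group] * coh$visit_time
  expect_equal(coh$up53, unname(expected))
})

test_that("generation is seed-deterministic down to the CSV bytes", {
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(generate_longitudinal_cohort(seed = 99), f1, meta = FALSE)
  write_cohort(generate_longitudinal_cohort(seed = 99), f2, meta = FALSE)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(
    readLines(f1),
    {
      f3 <- tempfile(fileext = ".csv")
      write_cohort(generate_longitudinal_cohort(seed = 100), f3, meta = FALSE)
      readLines(f3)
    }))
})

test_that("diagnosis sequences are monotone and AD is absorbing", {
  coh <- generate_longitudinal_cohort(seed = 8)
  sev <- c(CN = 1, MCI = 2, AD = 3)
  for (sp in split(coh, coh$subject_id)) {
    sp <- sp[order(sp$visit_time), ]
    expect_true(all(diff(sev[sp$diagnosis]) >= 0))
  }
})

test_that("group labels are consistent with the per-visit diagnoses", {
  coh <- generate_longitudinal_cohort(seed = 12)
  last <- coh[coh$visit == "T2", ]
  expect_true(all(last$diagnosis[last$group %in%
                                 c("CNtoAD", "MCItoAD")] == "AD"))
  expect_true(all(last$diagnosis[last$group == "StableCN"] == "CN"))
  expect_true(all(last$diagnosis[last$group %in%
                                 c("StableMCI", "CNtoMCI")] == "MCI"))
})

test_that("the missing-visit switch drops the documented records", {
  p <- trajectory_params(missing_pattern = TRUE)
  coh <- generate_longitudinal_cohort(p, seed = 44)
  full <- generate_longitudinal_cohort(trajectory_params(), seed = 44)
  expect_equal(nrow(full) - nrow(coh), 6L)  # 3 at T1 + 3 at T2
  t1 <- table(coh$group[coh$visit == "T1"])
  expect_equal(unname(t1[["StableMCI"]]), 15L)
  expect_equal(unname(t1[["MCItoAD"]]), 8L)
  t2 <- table(coh$group[coh$visit == "T2"])
  expect_equal(unname(t2[["MCItoAD"]]), 6L)
})

test_that("invalid generator parameters are rejected", {
  expect_error(trajectory_params(sd_residual = -1), ">= 0")
  expect_error(trajectory_params(group_sizes = c(StableCN = 0L)), "positive")
  expect_error(
    trajectory_params(up53_slope = c(StableCN = 1, CNtoMCI = 0.3,
                                     CNtoAD = 0.5, StableMCI = 0.1,
                                     MCItoAD = 0.8)),
    "converter-group slopes")
})

test_that("under identical group parameters the group test rejects at the nominal rate", {
  p <- trajectory_params(
    up53_baseline_mean = c(StableCN = 7, CNtoMCI = 7, CNtoAD = 7,
                           StableMCI = 7, MCItoAD = 7),
    up53_slope = c(StableCN = 0.2, CNtoMCI = 0.2, CNtoAD = 0.2,
                   StableMCI = 0.2, MCItoAD = 0.2))
  reps <- 400; rej <- 0L
  for (s in seq_len(reps)) {
    coh <- generate_longitudinal_cohort(p, seed = 5000 + s)
    base <- coh[coh$visit == "Baseline", ]
    if (kruskal.test(base$up53, factor(base$group))$p.value < 0.05)
      rej <- rej + 1L
  }
  expect_gte(rej / reps, 0.03)
  expect_lte(rej / reps, 0.07)
})

## ---- A/T cohort ----------------------------------------------------------

test_that("the A/T cohort passes its own invariant audit", {
  am <- generate_at_cohort(seed = 21)
  cls <- table(am$at_class)
  expect_equal(unname(cls[c("A-/T-", "A+/T-", "A+/T+", "A-/T+")]),
               as.table(c(30L, 8L, 36L, 36L)), ignore_attr = TRUE)
  expect_equal(sum(is.na(am$at_class)), 1L)
  # CSF values sit on the correct side of the published cutoffs
  ok <- !is.na(am$at_class)
  recls <- classify_at(am$abeta42[ok], am$ptau[ok])
  expect_equal(as.character(recls), am$at_class[ok])
  # converters: 18 total, 10 in amyloid-positive strata, times in [6, 30]
  expect_equal(sum(am$converter), 18L)
  expect_equal(sum(am$converter & am$at_class %in% c("A+/T-", "A+/T+")), 10L)
  expect_true(all(am$conversion_months[am$converter] >= 6 &
                  am$conversion_months[am$converter] <= 30))
  expect_error(at_params(converters = c("A-/T-" = 31L, "A+/T-" = 0L,
                                        "A+/T+" = 0L, "A-/T+" = 0L)),
               "exceeds stratum size")
})

test_that("between-stratum biomarker shifts drive the downstream AUC as designed", {
  flat <- at_params(up53_mean = c("A-/T-" = 9, "A+/T-" = 9, "A+/T+" = 9,
                                  "A-/T+" = 9))
  strong <- at_params(up53_mean = c("A-/T-" = 9, "A+/T-" = 16.5,
                                    "A+/T+" = 16.5, "A-/T+" = 16.5),
                      up53_sd = 1.5)  # 5 within-group SDs
  auc_of <- function(params, seed) {
    am <- generate_at_cohort(params, seed = seed)
    ok <- !is.na(am$at_class)
    auc <- roc_curve(am$up53[ok], am$at_class[ok] != "A-/T-")$auc
    auc
  }
  reps <- 200
  a_null <- vapply(seq_len(reps), function(s) auc_of(flat, s), 0)
  a_strong <- vapply(seq_len(reps), function(s) auc_of(strong, 10000 + s), 0)
  expect_lt(abs(mean(a_null) - 0.5), 0.02)
  expect_gt(mean(a_strong), 0.95)
})

## ---- I/O -----------------------------------------------------------------

test_that("cohort CSV round-trips to an identical table", {
  coh <- generate_longitudinal_cohort(seed = 3)
  f <- tempfile(fileext = ".csv")
  write_cohort(coh, f)
  back <- read_cohort(f)
  expect_equal(as.data.frame(back), as.data.frame(coh), ignore_attr = TRUE)
  # metadata sidecar records the seed
  meta <- jsonlite::read_json(paste0(f, ".meta.json"))
  expect_equal(meta$seed, 3)
})

test_that("schema violations are reported by column and row", {
  coh <- generate_longitudinal_cohort(seed = 3)
  f <- tempfile(fileext = ".csv")
  write_cohort(coh[, setdiff(names(coh), "mmse")], f, meta = FALSE)
  expect_error(read_cohort(f), "mmse")
  coh2 <- as.data.frame(coh)
  coh2$up53 <- as.character(coh2$up53)
  coh2$up53[5] <- "not-a-number"
  utils::write.csv(coh2, f, row.names = FALSE)
  expect_error(read_cohort(f), "up53.*row 5")
})

test_that("visit labels map to years 0/2/4 when visit_time is absent", {
  coh <- generate_longitudinal_cohort(seed = 3)
  f <- tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(coh)[, setdiff(names(coh), "visit_time")],
                   f, row.names = FALSE)
  back <- read_cohort(f)
  expect_equal(unique(back$visit_time[back$visit == "Baseline"]), 0)
  expect_equal(unique(back$visit_time[back$visit == "T1"]), 2)
  expect_equal(unique(back$visit_time[back$visit == "T2"]), 4)
})

test_that("trajectory parameters round-trip through YAML", {
  p <- trajectory_params(sd_residual = 0.7, missing_pattern = TRUE)
  f <- tempfile(fileext = ".yaml")
  write_trajectory_params(p, f)
  q <- read_trajectory_params(f)
  expect_equal(q$sd_residual, 0.7)
  expect_true(q$missing_pattern)
  expect_equal(q$up53_slope, p$up53_slope)
  expect_equal(q$group_sizes, p$group_sizes)
})
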