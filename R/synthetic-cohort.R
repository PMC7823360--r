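## Synthetic longitudinal cohort generator
##
## Emulates the statistical structure of a three-visit (0/2/4 years)
## population cohort with five retrospectively defined trajectory groups
## (Stable-CN, CN-to-MCI, CN-to-AD, Stable-MCI, MCI-to-AD), and of a
## cross-sectional aMCI cohort stratified by CSF A/T status. Group sizes
## and covariate marginals default to the published cohort profile; the
## per-group biomarker means and slopes are NOT published (they appear only
## graphically) and the defaults here are documented assumptions anchored
## to the printed tree cutoffs.

.groups <- c("StableCN", "CNtoMCI", "CNtoAD", "StableMCI", "MCItoAD")
.at_strata <- c("A-/T-", "A+/T-", "A+/T+", "A-/T+")

#' Parameters of the longitudinal trajectory generator
#'
#' The plasma biomarker of subject i in group g at time t (years from
#' baseline) follows a linear mixed-effects law:
#' \deqn{u(i, t) = \mu_g + \beta_g t + b_{0i} + b_{1i} t + \epsilon_{it}}
#' with subject random intercept/slope and Gaussian residual. Converter
#' groups must have slopes at least as steep as their stable counterpart
#' (the generative assumption the downstream trajectory analysis tests).
#' With `lognormal = TRUE` the law applies to the log of the biomarker,
#' guaranteeing positivity.
#'
#' @param group_sizes Named integer vector over the five trajectory groups.
#' @param up53_baseline_mean,up53_slope Named per-group intercepts (a.u.)
#'   and slopes (a.u./year).
#' @param sd_intercept,sd_slope,sd_residual Random-effect and residual SDs.
#' @param lognormal Interpret the trajectory law on the log scale.
#' @param age_mean,age_sd Baseline age moments per baseline diagnosis.
#' @param mmse_baseline_mean,mmse_baseline_sd MMSE moments per baseline
#'   diagnosis; `mmse_drift` gives the per-group decline (points/year) and
#'   `mmse_visit_sd` the occasion-level noise.
#' @param apoe4_prev Per-group APOE-e4 carrier prevalence.
#' @param sex_f_prop Female proportion per baseline diagnosis.
#' @param education_probs Per-diagnosis probabilities over the ordinal
#'   education levels 0-3 (0 = illiterate, 1 = 3-12 y, 2 = 13-18 y,
#'   3 = >18 y).
#' @param n_t1_converters_mci How many MCI-to-AD subjects already carry the
#'   AD diagnosis at the middle visit.
#' @param missing_pattern Reproduce the study's missing-visit pattern (two
#'   Stable-MCI and one MCI-to-AD absent at the middle visit; the
#'   already-converted MCI-to-AD absent at the final visit).
#' @param visit_times Named numeric vector of visit times in years.
#'
#' @return A list of class `"trajectory_params"`.
#' @export
trajectory_params <- function(
    group_sizes = c(StableCN = 37L, CNtoMCI = 17L, CNtoAD = 10L,
                    StableMCI = 17L, MCItoAD = 9L),
    up53_baseline_mean = c(StableCN = 6.2, CNtoMCI = 6.6, CNtoAD = 7.6,
                           StableMCI = 6.9, MCItoAD = 7.9),
    up53_slope = c(StableCN = 0.05, CNtoMCI = 0.35, CNtoAD = 0.90,
                   StableMCI = 0.10, MCItoAD = 0.80),
    sd_intercept = 0.8, sd_slope = 0.10, sd_residual = 0.5,
    lognormal = FALSE,
    age_mean = c(CN = 73, MCI = 73.28), age_sd = c(CN = 1.22, MCI = 1.36),
    mmse_baseline_mean = c(CN = 27.56, MCI = 26.5),
    mmse_baseline_sd = c(CN = 2.28, MCI = 2.11),
    mmse_drift = c(StableCN = -0.1, CNtoMCI = -0.5, CNtoAD = -0.9,
                   StableMCI = -0.2, MCItoAD = -1.0),
    mmse_visit_sd = 0.8,
    apoe4_prev = c(StableCN = 0.15, CNtoMCI = 0.25, CNtoAD = 0.40,
                   StableMCI = 0.25, MCItoAD = 0.45),
    sex_f_prop = c(CN = 0.5781, MCI = 0.3077),
    education_probs = list(CN = c(0.10, 0.68, 0.20, 0.02),
                           MCI = c(0.06, 0.74, 0.18, 0.02)),
    n_t1_converters_mci = 3L,
    missing_pattern = FALSE,
    visit_times = c(Baseline = 0, T1 = 2, T2 = 4)) {
  p <- list(group_sizes = group_sizes,
            up53_baseline_mean = up53_baseline_mean,
            up53_slope = up53_slope,
            sd_intercept = sd_intercept, sd_slope = sd_slope,
            sd_residual = sd_residual, lognormal = lognormal,
            age_mean = age_mean, age_sd = age_sd,
            mmse_baseline_mean = mmse_baseline_mean,
            mmse_baseline_sd = mmse_baseline_sd,
            mmse_drift = mmse_drift, mmse_visit_sd = mmse_visit_sd,
            apoe4_prev = apoe4_prev, sex_f_prop = sex_f_prop,
            education_probs = education_probs,
            n_t1_converters_mci = as.integer(n_t1_converters_mci),
            missing_pattern = isTRUE(missing_pattern),
            visit_times = visit_times)
  validate_trajectory_params(p)
  structure(p, class = "trajectory_params")
}

validate_trajectory_params <- function(p) {
  for (nm in .groups) {
    if (is.na(p$group_sizes[nm]) || p$group_sizes[nm] <= 0)
      stop_("group size for %s must be positive", nm)
    if (is.na(p$up53_baseline_mean[nm]) || is.na(p$up53_slope[nm]))
      stop_("trajectory parameters missing for group %s", nm)
  }
  sds <- c(p$sd_intercept, p$sd_slope, p$sd_residual, p$mmse_visit_sd)
  if (any(sds < 0)) stop_("all standard deviations must be >= 0")
  if (p$up53_slope["CNtoAD"] < p$up53_slope["StableCN"] ||
      p$up53_slope["MCItoAD"] < p$up53_slope["StableMCI"])
    stop_("converter-group slopes must be >= the matching stable-group slope")
  if (any(p$apoe4_prev < 0 | p$apoe4_prev > 1))
    stop_("APOE-e4 prevalences must lie in [0, 1]")
  invisible(p)
}

## per-group diagnosis sequence over the three visits; AD is absorbing and
## sequences are monotone CN -> MCI -> AD
diagnosis_schedule <- function(group, idx_in_group, n_t1) {
  switch(group,
    StableCN  = c("CN", "CN", "CN"),
    CNtoMCI   = c("CN", "CN", "MCI"),
    CNtoAD    = c("CN", "MCI", "AD"),
    StableMCI = c("MCI", "MCI", "MCI"),
    MCItoAD   = if (idx_in_group <= n_t1) c("MCI", "AD", "AD")
                else c("MCI", "MCI", "AD"))
}

#' Generate a three-visit longitudinal cohort
#'
#' Draws a complete long-format cohort (one row per subject-visit) under
#' the mixed-effects trajectory law of [trajectory_params()], with
#' covariate marginals (age, sex, education, MMSE, APOE-e4) set per group
#' and baseline diagnosis. Diagnosis sequences are monotone (AD is
#' absorbing) and the trajectory group of every subject is consistent with
#' its per-visit diagnoses. Identical seeds produce identical tables.
#'
#' @param params A [trajectory_params()] object.
#' @param group_sizes Optional override of `params$group_sizes`.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#'
#' @return A `data.frame` of class `"cohort_table"` with columns
#'   `subject_id`, `group`, `visit`, `visit_time`, `sex`, `education`,
#'   `age`, `mmse`, `apoe4`, `up53`, `diagnosis`, `conversion_time`
#'   (months to AD, `NA` for non-AD subjects).
#' @export
#' @examples
#' coh <- generate_longitudinal_cohort(seed = 1)
#' table(coh$group[coh$visit == "Baseline"])
generate_longitudinal_cohort <- function(params = trajectory_params(),
                                         group_sizes = NULL, seed = NULL) {
  stopifnot(inherits(params, "trajectory_params"))
  if (!is.null(group_sizes)) {
    params$group_sizes[names(group_sizes)] <- group_sizes
    validate_trajectory_params(params)
  }
  with_seed(seed, {
    vt <- params$visit_times
    nv <- length(vt)
    rows <- vector("list", length(.groups))
    sid0 <- 0L
    for (gi in seq_along(.groups)) {
      g <- .groups[gi]
      n <- params$group_sizes[[g]]
      base_dx <- if (g %in% c("StableCN", "CNtoMCI", "CNtoAD")) "CN" else "MCI"
      ids <- sprintf("S%04d", sid0 + seq_len(n)); sid0 <- sid0 + n
      ## per-subject draws
      age0 <- rnorm(n, params$age_mean[[base_dx]], params$age_sd[[base_dx]])
      sex <- ifelse(runif(n) < params$sex_f_prop[[base_dx]], "F", "M")
      edu <- sample(0:3, n, replace = TRUE,
                    prob = params$education_probs[[base_dx]])
      apoe <- runif(n) < params$apoe4_prev[[g]]
      mmse0 <- rnorm(n, params$mmse_baseline_mean[[base_dx]],
                     params$mmse_baseline_sd[[base_dx]])
      b0 <- rnorm(n, 0, params$sd_intercept)
      b1 <- rnorm(n, 0, params$sd_slope)
      dxm <- t(vapply(seq_len(n), function(i)
        diagnosis_schedule(g, i, params$n_t1_converters_mci),
        character(nv)))
      conv <- apply(dxm, 1L, function(d)
        if ("AD" %in% d) vt[[which(d == "AD")[1L]]] * 12 else NA_real_)
      ## expand subject x visit (visit varies fastest)
      sub <- rep(seq_len(n), each = nv)
      tk <- rep(unname(vt), times = n)
      eta <- params$up53_baseline_mean[[g]] + params$up53_slope[[g]] * tk +
        b0[sub] + b1[sub] * tk + rnorm(n * nv, 0, params$sd_residual)
      up53 <- if (params$lognormal) exp(eta) else pmax(eta, 1e-6)
      mm <- mmse0[sub] + params$mmse_drift[[g]] * tk +
        rnorm(n * nv, 0, params$mmse_visit_sd)
      rows[[gi]] <- data.frame(
        subject_id = ids[sub], group = g,
        visit = rep(names(vt), times = n), visit_time = tk,
        sex = sex[sub], education = as.integer(edu[sub]),
        age = age0[sub] + tk,
        mmse = as.integer(pmin(pmax(round(mm), 0), 30)),
        apoe4 = apoe[sub], up53 = up53,
        diagnosis = as.vector(t(dxm)),
        conversion_time = conv[sub], stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    if (params$missing_pattern) out <- apply_missing_pattern(out, params)
    rownames(out) <- NULL
    structure(out, params = params, seed = seed,
              class = c("cohort_table", "data.frame"))
  })
}

## drop visits following the published missing-sample pattern: two
## Stable-MCI and one (late-converting) MCI-to-AD at T1; the MCI-to-AD who
## had already converted at T1 are absent at T2
apply_missing_pattern <- function(out, params) {
  smci <- unique(out$subject_id[out$group == "StableMCI"])[1:2]
  late <- unique(out$subject_id[out$group == "MCItoAD" &
                                out$visit == "T1" & out$diagnosis != "AD"])[1]
  early <- unique(out$subject_id[out$group == "MCItoAD" &
                                 out$visit == "T1" & out$diagnosis == "AD"])
  drop_t1 <- out$visit == "T1" & out$subject_id %in% c(smci, late)
  drop_t2 <- out$visit == "T2" & out$subject_id %in% early
  out[!(drop_t1 | drop_t2), , drop = FALSE]
}

#' Parameters of the cross-sectional A/T cohort generator
#'
#' Defaults mirror the published aMCI cohort profile: strata sizes 30/8/36/36
#' over A-/T-, A+/T-, A+/T+, A-/T+, one subject with missing CSF, and 18
#' AD converters (9 in A+/T+, 1 in A+/T-, 8 in A-/T+) converting uniformly
#' within 6-30 months. CSF values are drawn from truncated normals on the
#' correct side of the published cutoffs (amyloid-beta 42 < 550 pg/mL for
#' A+, p-tau > 52 pg/mL for T+); total tau is generated as an annotation
#' correlated with p-tau. Plasma biomarker means rise with A and T
#' positivity (an assumption, anchored to the printed tree cutoff).
#'
#' @param strata_sizes Named sizes of the four A/T strata.
#' @param n_missing_csf Subjects with unclassifiable (missing) CSF.
#' @param converters Named count of AD converters per stratum.
#' @param conversion_window Months; converters' times are uniform in it.
#' @param up53_mean,up53_sd Per-stratum plasma biomarker moments (a.u.).
#' @param abeta_cutoff,ptau_cutoff Classification cutoffs (pg/mL).
#' @param abeta_neg,abeta_pos,ptau_neg,ptau_pos `c(mean, sd)` of the CSF
#'   values on each side of the cutoffs.
#' @param mmse_mean,mmse_sd,age_mean,age_sd,sex_f_prop,apoe4_prev,
#'   education_probs Covariate marginals.
#'
#' @return A list of class `"at_params"`.
#' @export
at_params <- function(
    strata_sizes = c("A-/T-" = 30L, "A+/T-" = 8L, "A+/T+" = 36L,
                     "A-/T+" = 36L),
    n_missing_csf = 1L,
    converters = c("A-/T-" = 0L, "A+/T-" = 1L, "A+/T+" = 9L, "A-/T+" = 8L),
    conversion_window = c(6, 30),
    up53_mean = c("A-/T-" = 8.8, "A+/T-" = 10.2, "A+/T+" = 11.3,
                  "A-/T+" = 10.5),
    up53_sd = 1.3,
    abeta_cutoff = 550, ptau_cutoff = 52,
    abeta_neg = c(850, 200), abeta_pos = c(420, 80),
    ptau_neg = c(38, 8), ptau_pos = c(85, 30),
    mmse_mean = 26.41, mmse_sd = 1.83,
    age_mean = 69.12, age_sd = 7.55,
    sex_f_prop = 0.5766,
    apoe4_prev = c("A-/T-" = 0.30, "A+/T-" = 0.55, "A+/T+" = 0.55,
                   "A-/T+" = 0.55),
    education_probs = c(0.02, 0.62, 0.33, 0.03)) {
  p <- as.list(environment())
  if (any(p$strata_sizes <= 0)) stop_("strata sizes must be positive")
  if (any(p$converters < 0) ||
      any(p$converters[.at_strata] > p$strata_sizes[.at_strata]))
    stop_("converter count exceeds stratum size")
  if (p$up53_sd < 0) stop_("up53_sd must be >= 0")
  structure(p, class = "at_params")
}

#' Generate a cross-sectional aMCI cohort with CSF A/T strata
#'
#' @param params An [at_params()] object.
#' @param seed Optional integer seed.
#'
#' @return A `data.frame` of class `"at_cohort"`, one row per subject:
#'   `subject_id`, `at_class`, `abeta42`, `ptau`, `ttau`, `up53`, `mmse`,
#'   `apoe4`, `age`, `sex`, `education`, `converter`, `conversion_months`.
#'   Subjects with missing CSF have `NA` in the CSF columns and an `NA`
#'   `at_class`.
#' @export
#' @examples
#' amci <- generate_at_cohort(seed = 1)
#' table(amci$at_class, useNA = "ifany")
generate_at_cohort <- function(params = at_params(), seed = NULL) {
  stopifnot(inherits(params, "at_params"))
  with_seed(seed, {
    rows <- list()
    sid <- 0L
    for (s in .at_strata) {
      n <- params$strata_sizes[[s]]
      a_pos <- grepl("A\\+", s); t_pos <- grepl("T\\+", s)
      ab <- if (a_pos)
        rtruncnorm(n, params$abeta_pos[1], params$abeta_pos[2],
                   lower = 1, upper = params$abeta_cutoff - 1e-9)
      else rtruncnorm(n, params$abeta_neg[1], params$abeta_neg[2],
                      lower = params$abeta_cutoff)
      pt <- if (t_pos)
        rtruncnorm(n, params$ptau_pos[1], params$ptau_pos[2],
                   lower = params$ptau_cutoff + 1e-9)
      else rtruncnorm(n, params$ptau_neg[1], params$ptau_neg[2],
                      lower = 1, upper = params$ptau_cutoff)
      tt <- pmax(150 + 5 * pt + rnorm(n, 0, 120), 50)
      conv <- rep(FALSE, n)
      conv[sample.int(n, params$converters[[s]])] <- TRUE
      rows[[s]] <- data.frame(
        subject_id = sprintf("M%04d", sid + seq_len(n)),
        at_class = s, abeta42 = ab, ptau = pt, ttau = tt,
        up53 = pmax(rnorm(n, params$up53_mean[[s]], params$up53_sd), 1e-6),
        mmse = as.integer(pmin(pmax(round(
          rnorm(n, params$mmse_mean, params$mmse_sd)), 0), 30)),
        apoe4 = runif(n) < params$apoe4_prev[[s]],
        age = rnorm(n, params$age_mean, params$age_sd),
        sex = ifelse(runif(n) < params$sex_f_prop, "F", "M"),
        education = sample(0:3, n, replace = TRUE,
                           prob = params$education_probs),
        converter = conv,
        conversion_months = ifelse(conv,
          runif(n, params$conversion_window[1], params$conversion_window[2]),
          NA_real_),
        stringsAsFactors = FALSE)
      sid <- sid + n
    }
    if (params$n_missing_csf > 0) {
      n <- params$n_missing_csf
      rows[["missing"]] <- data.frame(
        subject_id = sprintf("M%04d", sid + seq_len(n)),
        at_class = NA_character_, abeta42 = NA_real_, ptau = NA_real_,
        ttau = NA_real_,
        up53 = pmax(rnorm(n, mean(params$up53_mean), params$up53_sd), 1e-6),
        mmse = as.integer(pmin(pmax(round(
          rnorm(n, params$mmse_mean, params$mmse_sd)), 0), 30)),
        apoe4 = runif(n) < mean(params$apoe4_prev),
        age = rnorm(n, params$age_mean, params$age_sd),
        sex = ifelse(runif(n) < params$sex_f_prop, "F", "M"),
        education = sample(0:3, n, replace = TRUE,
                           prob = params$education_probs),
        converter = FALSE, conversion_months = NA_real_,
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    structure(out, params = params, seed = seed,
              class = c("at_cohort", "data.frame"))
  })
}

## ---- cohort I/O ----------------------------------------------------------

.cohort_cols <- c("subject_id", "visit", "visit_time", "sex", "education",
                  "age", "mmse", "apoe4", "up53", "diagnosis")

#' Write a cohort table to CSV (with a JSON metadata sidecar)
#'
#' @param cohort A cohort table (long format).
#' @param path Output CSV path. A sidecar `<path>.meta.json` recording the
#'   generator seed and parameters is written when the cohort carries them
#'   and `meta = TRUE`.
#' @param meta Write the metadata sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, meta = TRUE) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  if (meta && !is.null(attr(cohort, "params"))) {
    jsonlite::write_json(
      list(seed = attr(cohort, "seed"),
           params = unclass(attr(cohort, "params"))),
      paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA,
      null = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read a long-format cohort table from CSV
#'
#' Validates the schema (every required column present, numeric biomarker
#' parseable) and maps the visit labels Baseline/T1/T2 to times 0/2/4 years
#' when `visit_time` is absent.
#'
#' @param path CSV path with a mandatory header.
#' @return A `data.frame` of class `"cohort_table"`.
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  need <- setdiff(.cohort_cols, "visit_time")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop_("cohort file lacks required column(s): %s",
          paste(miss, collapse = ", "))
  num_col <- function(col, integer = FALSE) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & nzchar(raw[[col]]) & !is.na(raw[[col]]))
    if (length(bad))
      stop_("non-numeric value in column '%s' at row %d", col, bad[1L])
    if (integer) as.integer(v) else v
  }
  out <- raw
  out$age <- num_col("age")
  out$mmse <- num_col("mmse", integer = TRUE)
  out$education <- num_col("education", integer = TRUE)
  out$up53 <- num_col("up53")
  if (any(out$up53 <= 0, na.rm = TRUE))
    stop_("biomarker column 'up53' must be positive")
  out$apoe4 <- as.logical(raw$apoe4)
  if ("visit_time" %in% names(raw)) {
    out$visit_time <- num_col("visit_time")
  } else {
    map <- c(Baseline = 0, T1 = 2, T2 = 4)
    unknown <- setdiff(unique(raw$visit), names(map))
    if (length(unknown))
      stop_("unknown visit label(s): %s", paste(unknown, collapse = ", "))
    out$visit_time <- unname(map[raw$visit])
  }
  if ("conversion_time" %in% names(out))
    out$conversion_time <- suppressWarnings(as.numeric(out$conversion_time))
  if (anyDuplicated(out[, c("subject_id", "visit")]))
    stop_("duplicate (subject_id, visit) records")
  out <- out[, union(intersect(c("subject_id", "group", .cohort_cols,
                                 "conversion_time"), names(out)),
                     names(out)), drop = FALSE]
  structure(out, class = c("cohort_table", "data.frame"))
}

#' Read / write trajectory-generator parameters as YAML
#'
#' @param path YAML file path.
#' @return For `read_trajectory_params`, a validated
#'   [trajectory_params()] object.
#' @export
read_trajectory_params <- function(path) {
  lst <- yaml::read_yaml(path)
  known <- names(formals(trajectory_params))
  extra <- setdiff(names(lst), known)
  if (length(extra))
    stop_("unknown parameter(s) in YAML: %s", paste(extra, collapse = ", "))
  lst <- lapply(lst, function(x) if (is.list(x) &&
    all(vapply(x, is.numeric, TRUE)) &&
    all(lengths(x) == 1L) && !is.null(names(x))) unlist(x) else x)
  do.call(trajectory_params, lst)
}

#' @rdname read_trajectory_params
#' @param params A [trajectory_params()] object to serialise.
#' @export
write_trajectory_params <- function(params, path) {
  stopifnot(inherits(params, "trajectory_params"))
  yaml::write_yaml(lapply(unclass(params), function(x)
    if (!is.null(names(x)) && !is.list(x)) as.list(x) else x), path)
  invisible(path)
}
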