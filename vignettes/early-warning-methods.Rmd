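---
title: "Methods: a regression-tree early-warning system for AD risk"
author: "adews"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a regression-tree early-warning system for AD risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adews)
```

# The problem

A plasma biomarker measured repeatedly in an ageing cohort — together with
sex, education, age, MMSE and APOEε4 carrier status — should flag, years
before the clinical diagnosis, which cognitively normal (CN) and mildly
impaired (MCI) subjects are on an Alzheimer's disease (AD) trajectory.
`adews` implements the full analysis chain for that question: a regression
tree whose terminal nodes are AD-prevalence risk zones, validated
prospectively with a rolling window over the cohort's visits, supported by
mixed-effects trajectory models, ROC machinery and a power calculation for
the study design. Because cohort plasma data of this kind are generally
not public, the package carries a synthetic-cohort generator whose
defaults encode the structure such studies report, so every stage is
testable end to end.

# The tree model

For a dichotomous outcome $y_i \in \{0,1\}$ (AD at the test visit), each
node $t$ carries the deviance $D(t) = \sum_{i \in t} (y_i - \bar y_t)^2$.
A split on feature $x$ at threshold $c$ sends $x < c$ left and $x \ge c$
right; the split chosen at a node maximises
$D(t) - D(t_L) - D(t_R)$ over all features and all thresholds placed
midway between consecutive distinct observed values. The prediction of a
terminal node is $\hat y_t = \bar y_t$, the relative frequency of
converters — directly interpretable as the node's AD risk, from 0 (no
risk) to 1 (maximum risk).

Numerical choices that matter:

* **Tie-breaking.** Two candidate splits whose deviance reductions differ
  by less than $10^{-9}$ are treated as tied; ties resolve to the earlier
  feature in the declared covariate order (sex, education, age, MMSE,
  APOEε4, biomarker), then to the smaller threshold. This makes the fit
  invariant to row order, which the tests assert.
* **Boundary routing.** A prediction-time value exactly at a threshold
  routes right (the "$\ge$" branch). Thresholds are midpoints of distinct
  training values, so this can only occur on new data.
* **Growth controls.** Defaults follow the conventions of recursive
  partitioning software: `minsplit = 20`, `minbucket = 7`, `cp = 0.01`
  (minimum deviance improvement as a fraction of root deviance),
  `maxdepth = 30`. All are configurable; analyses of 90-subject visits are
  insensitive to `maxdepth`.
* **Missing values.** There are no surrogate splits. Missing covariates
  are an error at both fit and prediction time; longitudinal missingness
  is handled upstream by the rolling window's carry-forward rule.
* **Degenerate inputs.** A constant outcome yields a single-leaf tree (the
  prevalence estimator), not an error; an empty table is an error.

## Pruning and cross-validation

Weakest-link cost-complexity pruning produces the nested subtree sequence:
at penalty $\alpha$, an internal node $t$ survives only if its subtree
earns its leaves, $g(t) = (D(t) - \sum_{\ell \in T_t} D(\ell)) /
(|T_t| - 1) > \alpha$. The sequence is selected over by $v$-fold
cross-validation ($v = 10$ by default): each candidate subtree $k$,
optimal on the penalty interval $[\alpha_k, \alpha_{k+1})$, is probed at
the geometric mean of its interval endpoints; the full tree at $0$; the
root-only subtree at $\infty$, so fold trees genuinely collapse to their
roots for that candidate. Penalties are applied to fold trees on the
*relative* complexity scale (scaled by the fold's root deviance), so trees
grown on $(v-1)/v$ of the data are pruned commensurately. Both choices
matter in practice: probing the root candidate at a finite penalty leaves
fold trees partially unpruned, the root candidate's cross-validated
deviance then duplicates its neighbours', and on pure-noise outcomes a
non-trivial tree survives far too often. With the conventions above, a
pure-noise outcome ($n = 200$) is pruned back to the root in about 94% of
replicates, in line with reference implementations of the same algorithm.

Selection is by minimum cross-validated deviance (exact ties go to the
smaller tree); the one-standard-error rule is available
(`rule = "1se"`), which is markedly more conservative.

# The rolling window

The cohort has three visits at 0, 2 and 4 years. Step 1 calibrates the
tree on baseline and forecasts each subject's diagnosis at the first
follow-up — a true out-of-sample prediction, since no follow-up row enters
the training window (the leakage guard is asserted at run time). Step 2
expands the window to baseline plus first follow-up and forecasts the
final visit. A subject's outcome at a test visit is its clinical diagnosis
at that visit (AD = 1); the same subject legitimately appears in training
at earlier visits and in test at later ones — that is the forecasting
design, not leakage.

**Augmentation.** No subject is demented at baseline, so the first
training window has no outcome-1 row and a prevalence tree cannot learn.
A small-scale training set of $k$ AD-labelled records (default $k = 5$) is
therefore injected: either borrowed from a user-supplied reference pool of
AD records, or drawn synthetically from the converter-group generator at
the final visit. The injected rows carry synthetic subject ids and the
first window's visit label, so they can never collide with an
out-of-sample key. They remain part of every later training window: the
expanding window joins the *reinforced* earlier training set with the next
visit. This persistence is load-bearing. The middle visit typically
contributes only ~3 genuine AD rows out of ~180; without the reinforcement
the cross-validated pruning (correctly) judges a 3-positive split
ungeneralisable and collapses the second-window tree to its root, and the
procedure loses all discrimination (median out-of-sample AUC 0.5 in our
simulations). With it, the second window has both moderate (real,
early-converter) and high (reinforced) positive biomarker levels to learn
from.

**Carry-forward.** Subjects scored at an earlier test visit but absent at
a later one keep their previous window's score, flagged `carried`, with
the outcome taken from their last observed diagnosis (AD is absorbing).
The generator's `missing_pattern` switch reproduces the documented
missing-visit pattern for testing this rule.

**Uncertainty.** `bootstrap_predictions()` resamples the scored subjects
within outcome classes (so no replicate degenerates to one class) and
reports percentile 95% intervals for the zone-agreement percentage and
the AUC. The interval is widened, if necessary, to contain the point
estimate. Coverage of the AUC interval is checked by simulation
(~95% ± 3% at $n = 60$, $B = 500$).

# Risk zones and agreement

Terminal nodes map to zones by prevalence: $\hat y <$ `low` → low risk,
$\hat y \ge$ `high` → high risk, otherwise middle. The default bands
(0.20, 0.70) are a modelling choice that reproduces the node labels
reported for trees of this kind (prevalences 0.25 and 0.50 labelled
middle, 0.78 and 1.00 high); they are configurable and zone assignment is
monotone in $\hat y$ by construction.

Agreement with the clinic counts a subject as correctly stratified when it
is high-risk and converted, low-risk and did not convert, or — under the
default rule — middle-risk and converted (a middle call is an at-risk
call, vindicated by conversion). This is the only rule that reproduces the
published overall agreement of 86.67% from the published stratum counts
(13 high / 65 low / 12 middle with 11, 3 and 5 converters); the
alternatives (middle always wrong; middle excluded) are available behind
the `rule` argument. The report includes per-zone exact binomial tests
against 0.5 and Fisher's exact test on the high/low collapse, two-sided.

# A/T classification

CSF profiles are dichotomised by the published cutoffs: amyloid-positive
iff Aβ42 < 550 pg/mL, tau-positive iff p-Tau > 52 pg/mL, both strict, so a
value exactly at a cutoff is negative. Total tau is carried as an
annotation only. A profile with a missing required value is
"unclassifiable" rather than an error, matching how such cohorts report a
subject with missing CSF.

# Trajectory model

`trajectory_lme()` fits, for one stable/converter pair at a time,
$$u_{it} = \beta_0 + \beta_1 t + \beta_2 g_i + \beta_3 (t \times g_i)
+ b_{0i} + b_{1i} t + \varepsilon_{it},$$
with time in years from baseline and the stable group as reference, so
$\beta_3$ is the slope difference of interest. Estimation delegates to
`nlme::lme` (maximum likelihood by default; REML available) — this stage
is supporting analysis, not the package's bespoke computation; what the
module owns is the contract, enforced by parameter-recovery tests. If the
random-slope structure is singular the fit falls back to a random
intercept with a warning, and failing that to pooled OLS — the exact
zero-variance limit, which is also what makes the noise-free
identifiability test exact to $10^{-8}$. Recovery: with a generating slope
difference of 1 a.u./year and 60 subjects the mean estimate over 200
replicates is within 0.1 of truth.

# Power calculation

The overall F test of a multiple regression with $u$ predictors at total
sample size $n$ has denominator df $v = n - u - 1$ and, under effect size
$f^2$, noncentrality $\lambda = f^2(u + v + 1)$:
$$\mathrm{power}(n) = P\!\left[F'(u, v, \lambda) > F_{1-\alpha}(u, v)\right].$$
`min_sample_size()` inverts the (monotone) power curve by bracketed root
finding to $10^{-10}$ and reports both the fractional total $n$ and the
fractional residual df $v$. Power tools in this field conventionally quote
$v$ as "the number of subjects" beyond the parameters, and that is the
number a protocol cites: with $u = 6$, $\alpha = 0.05$, power 0.8, effect
sizes 0.666 and 0.5882 give $v = 20.45$ and $v = 23.09$. The alternative
noncentrality convention $\lambda = f^2 v$ does not reproduce those
figures and is not used. The noncentral-F tail itself is cross-checked
against Monte Carlo in the tests.

# The synthetic cohort generator

`generate_longitudinal_cohort()` emulates a three-visit population cohort
with five retrospectively defined trajectory groups of sizes 37/17/10/17/9
(Stable-CN, CN→MCI, CN→AD, Stable-MCI, MCI→AD). The biomarker follows
$$u_{it} = \mu_g + \beta_g t + b_{0i} + b_{1i} t + \varepsilon_{it},$$
the same law the trajectory module fits — chosen deliberately so that
parameter recovery is a well-posed check. A log-normal variant
(`lognormal = TRUE`) applies the law on the log scale for strict
positivity.

What is anchored to reported cohort characteristics: group sizes; age
(CN 73 ± 1.22, MCI 73.28 ± 1.36), MMSE (27.56 ± 2.28, 26.5 ± 2.11), sex
(57.8% / 30.8% female) and education marginals; APOEε4 prevalences per
group set so the CN/MCI marginals match the reported 21.9% / 30.8%, with
higher prevalence in converter groups; a conversion schedule in which
CN→AD subjects pass through MCI, three MCI→AD subjects already carry the
AD diagnosis at the middle visit, and the `missing_pattern` switch removes
two Stable-MCI and one MCI→AD record at the middle visit plus the
early-converted MCI→AD at the final one.

What is *assumption*, not fact: the per-group biomarker intercepts
(6.2–7.9 a.u.) and slopes (0.05–0.9 a.u./year), and the noise SDs (random
intercept 0.8, random slope 0.1, residual 0.5). Cohort studies of this
biomarker report its levels only graphically; the defaults were chosen
once so that stable subjects sit below and converters rise through the
decision thresholds such trees report (≈7.7–10 a.u.), with converter
slopes steeper than stable slopes — the generative assumption the
trajectory analysis is designed to detect, and one the parameter validator
enforces. Group assignment is by design (fixed labels, as the groups are
defined retrospectively at the final visit), not by a hazard model.

`generate_at_cohort()` emulates a cross-sectional aMCI cohort of 111
subjects: A/T strata 30/8/36/36 plus one subject with missing CSF; CSF
values drawn from truncated normals on the correct side of the cutoffs;
18 AD converters (9 A+/T+, 1 A+/T−, 8 A−/T+) with conversion times uniform
on 6–30 months; biomarker means rising with A and T positivity.

**What passing tests do and do not show.** The generator produces Gaussian
within-group variation, exact group sizes, and noise-free group membership
labels; real cohorts have heavier-tailed assay noise, diagnostic
misclassification, informative dropout and batch effects, none of which
are modelled. Tests on generated cohorts therefore validate the
*procedure* — splitting, pruning, windowing, augmentation, the arithmetic
of agreement and the calibration of the inferential machinery — not the
clinical performance of any real biomarker, and the package makes no
attempt to reproduce real plasma distributions in absolute units.

# Simulation scale and scenario choices

The test suite's Monte-Carlo checks run at sizes chosen to give stable
rates with desk-scale runtimes: 50 brute-force oracle fixtures of 30–60
rows; 200 replicates for LME recovery at 60 subjects; 100 rolling-window
replicates of the 90-subject cohort; 1000 null replicates for the DeLong
size at $n = 100$; 300 replicates at $B = 500$ for bootstrap coverage.

The rolling-window performance criterion (out-of-sample AUC ≥ 0.90 in at
least 90% of replicates) is evaluated under a *strong-separation
scenario*: the converter–stable gap at the forecast visit (~4.8 a.u.) is
about ten residual SDs, with subject-level heterogeneity kept small
(random intercept 0.3 a.u.) relative to the gap. That scenario is stated
in residual-SD units precisely because it is meant to isolate procedure
correctness. The *default* generator intentionally carries more
between-subject heterogeneity (random intercept 0.8 a.u.) to resemble a
realistic cohort; under it the same pipeline attains a median
out-of-sample AUC around 0.95 with occasional dips to ~0.85 when the
learned threshold falls inside the converter distribution — behaviour the
pipeline reports rather than asserts.

# Design choices in brief

* Augmentation default is `synthetic-positive` (self-contained);
  `borrow-labeled` reproduces the design of reinforcing with real AD
  records when a reference pool exists. Size, source and seed are logged
  in the run manifest because the reinforcement is an undocumented degree
  of freedom in analyses of this kind.
* Bootstrap CIs are percentile (BCa available); the operating point is
  Youden-optimal; score ties get Mann–Whitney half-credit.
* Multiplicity adjustment defaults to Holm.
* The command-line wrapper is a thin dispatcher over exported functions;
  every artifact (CSV/JSON only) is reproducible from its JSON manifest.

# Known limitations

* No surrogate splits: covariate missingness must be resolved upstream.
* The tree handles unordered categorical features only up to two levels
  (the study covariates need no more).
* With very few positives the high-risk zone may be unreachable under the
  default bands (a leaf of minimum size 7 caps its prevalence), which is a
  property of the data, not a failure of the bands.
* `trajectory_lme` compares exactly two groups per fit, mirroring the
  paired stable/converter analyses it supports.
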