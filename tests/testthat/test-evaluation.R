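test_that("AUC matches pairwise enumeration on the canonical fixtures", {
  # perfect separation
  r <- roc_curve(c(1, 2, 9, 10), c(0, 0, 1, 1))
  expect_equal(r$auc, 1.0)
  expect_equal(r$sensitivity, 1.0)
  expect_equal(r$specificity, 1.0)
  # all ties
  expect_equal(roc_curve(rep(0.3, 8), rep(c(0, 1), 4))$auc, 0.5)
  # 3 wins + 1 loss out of 4 positive-negative pairs = 0.75
  expect_equal(roc_curve(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
})

test_that("Mann-Whitney AUC equals the trapezoidal area on random fixtures", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 40
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- round(rnorm(n, y), 1)  # rounding induces ties
    r <- roc_curve(s, y)
    expect_equal(r$auc, oracle_auc_trapezoid(s, y), tolerance = 1e-12)
  }
})

test_that("ROC invariances hold: score negation and monotone transforms", {
  set.seed(4)
  y <- rep(c(0, 1), each = 25)
  s <- rnorm(50)  # tie-free
  expect_equal(roc_curve(s, y)$auc + roc_curve(-s, y)$auc, 1)
  expect_equal(roc_curve(s, y)$auc, roc_curve(exp(2 * s), y)$auc)
})

test_that("AUC and ROC agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(8)
  y <- rep(c(0, 1), each = 30)
  s <- rnorm(60, y)
  r <- roc_curve(s, y)
  pr <- pROC::roc(y, s, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
})

test_that("single-class labels are rejected", {
  expect_error(roc_curve(1:5, rep(1, 5)), "both outcome classes")
  expect_error(auc_ci(1:5, rep(0, 5), B = 200), "both outcome classes")
})

test_that("bootstrap CI: perfect separation pins the interval at 1", {
  s <- c(1, 2, 3, 11, 12, 13); y <- c(0, 0, 0, 1, 1, 1)
  ci <- auc_ci(s, y, B = 200, seed = 1)
  expect_equal(as.numeric(ci), c(1, 1))
})

test_that("bootstrap CI is seed-reproducible and contains the point AUC", {
  set.seed(9)
  y <- rep(c(0, 1), each = 20)
  s <- rnorm(40, y)
  c1 <- auc_ci(s, y, B = 300, seed = 42)
  c2 <- auc_ci(s, y, B = 300, seed = 42)
  expect_identical(as.numeric(c1), as.numeric(c2))
  a <- attr(c1, "auc")
  expect_true(c1[1] <= a && a <= c1[2])
  expect_error(auc_ci(s, y, B = 50), "at least 100")
})

test_that("DeLong: identical scores give zero difference and p = 1", {
  set.seed(2)
  y <- rep(c(0, 1), each = 15)
  s <- rnorm(30, y)
  dl <- delong_test(s, s, y)
  expect_equal(dl$difference, 0)
  expect_equal(dl$p.value, 1)
})

test_that("DeLong statistic and p-value match pROC's implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  y <- rep(c(0, 1), each = 40)
  s1 <- rnorm(80, y); s2 <- 0.5 * s1 + rnorm(80, 0.3 * y)
  dl <- delong_test(s1, s2, y)
  pr <- pROC::roc.test(pROC::roc(y, s1, quiet = TRUE, direction = "<"),
                       pROC::roc(y, s2, quiet = TRUE, direction = "<"),
                       method = "delong", paired = TRUE)
  expect_equal(dl$p.value, pr$p.value, tolerance = 1e-9)
  expect_equal(unname(dl$statistic), unname(pr$statistic), tolerance = 1e-9)
})

test_that("DeLong AUC variance approaches the two-normal-populations form", {
  # for continuous scores, Var(AUC_hat) from the structural components
  # should match the closed-form binormal expression at large n
  mu <- 1; m <- 4000; n <- 4000
  set.seed(77)
  pos <- rnorm(m, mu); neg <- rnorm(n)
  s <- c(neg, pos); y <- rep(c(0, 1), c(n, m))
  dl_var <- local({
    psi <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    var(rowMeans(psi)) / m + var(colMeans(psi)) / n
  })
  auc_true <- pnorm(mu / sqrt(2))
  # closed form via the placement-value variances of the binormal model
  q1 <- integrate(function(x) pnorm(x - 0)^2 * dnorm(x, mu), -8, 12)$value
  q2 <- integrate(function(x) (1 - pnorm(x, mu))^2 * dnorm(x), -8, 12)$value
  var_cf <- (q1 - auc_true^2) / m + (q2 - auc_true^2) / n
  expect_equal(dl_var, var_cf, tolerance = 0.15)
})

test_that("classical tests behave on canonical fixtures", {
  # identical groups: Wilcoxon p near 1
  g <- rep(c("a", "b"), each = 6)
  v <- rep(c(1, 2, 3, 4, 5, 6), 2)
  ct <- classical_tests(v, g)
  expect_gt(ct$wilcoxon, 0.9)
  # Kruskal-Wallis with k = 2 equals the squared rank-sum z (tie-free)
  set.seed(6)
  v2 <- rnorm(24); g2 <- rep(c("a", "b"), each = 12)
  kw <- kruskal.test(v2, factor(g2))$statistic
  r1 <- sum(rank(v2)[g2 == "a"])
  n1 <- 12; n2 <- 12; N <- 24
  z <- (r1 - n1 * (N + 1) / 2) / sqrt(n1 * n2 * (N + 1) / 12)
  expect_equal(unname(kw), z^2, tolerance = 1e-10)
  expect_equal(classical_tests(v2, g2)$kruskal_wallis, unname(
    kruskal.test(v2, factor(g2))$p.value))
  expect_error(classical_tests(v2, rep("a", 24)), "two groups")
})

test_that("Fisher exact matches hypergeometric enumeration", {
  tab <- matrix(c(0, 10, 10, 0), 2)
  expect_equal(fisher_exact(tab), oracle_fisher_2x2(tab), tolerance = 1e-12)
  tab2 <- matrix(c(11, 3, 2, 62), 2)
  expect_equal(fisher_exact(tab2), oracle_fisher_2x2(tab2), tolerance = 1e-9)
  expect_lt(fisher_exact(tab2), 0.001)
})

test_that("conversion report recovers per-group conversion percentages", {
  subjects <- data.frame(
    baseline_dx = rep(c("CN", "MCI"), c(20, 10)),
    final_dx = c(rep("AD", 2), rep("CN", 18), rep("AD", 1), rep("MCI", 9)))
  rep_ <- conversion_report(subjects)
  expect_equal(rep_$pct_converted[rep_$baseline_dx == "CN"], 10)
  expect_equal(rep_$pct_converted[rep_$baseline_dx == "MCI"], 10)
  # long-format route
  coh <- generate_longitudinal_cohort(seed = 3)
  cr <- conversion_report(coh)
  expect_equal(cr$n_converted[cr$baseline_dx == "CN"], 10)
  expect_equal(cr$n_converted[cr$baseline_dx == "MCI"], 9)
})

test_that("logit comparator matches a hand-rolled IRLS fit", {
  d <- data.frame(x1 = c(0.1, 0.8, 0.3, 0.9, 0.2, 0.7, 0.5, 0.4),
                  x2 = c(1, 0, 1, 1, 0, 0, 1, 0),
                  y = c(0, 1, 1, 0, 0, 1, 1, 0))
  fit <- logit_model(y ~ x1 + x2, d)
  beta <- oracle_irls(as.matrix(d[, c("x1", "x2")]), d$y)
  expect_equal(unname(coef(fit)), unname(beta), tolerance = 1e-6)
  p <- predict(fit, d)
  expect_true(all(p > 0 & p < 1))
})

test_that("logit warns on a rank-deficient design and still predicts", {
  d <- make_fixture(40, 12)
  d$dup <- d$up53  # aliased column
  expect_warning(fit <- logit_model(y ~ up53 + dup, d), "rank-deficient")
  expect_length(predict(fit, d), 40)
})

test_that("tree and logit scores feed the same DeLong comparison", {
  d <- make_fixture(80, 30)
  tr <- rtree(y ~ age + mmse + up53, d,
              rtree_control(minsplit = 20, minbucket = 7, cp = 0.01))
  lg <- logit_model(y ~ age + mmse + up53, d)
  dl <- delong_test(predict(tr, d), predict(lg, d), d$y)
  expect_true(is.finite(dl$p.value) && dl$p.value >= 0 && dl$p.value <= 1)
})
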