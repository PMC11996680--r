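# The reference statistics on `fixed_groups` (see helper-oracles.R) were
# computed with an independent implementation (scipy.stats.normaltest /
# kruskal, plus a standalone rank-based Conover/Dunn computation) on exactly
# those values and are frozen here.

dp_fixed_sample <- function() {
  set.seed(42)
  round(rnorm(50), 6)
}

test_that("D'Agostino-Pearson K2 matches the reference implementation", {
  r <- dagostino_pearson(dp_fixed_sample())
  expect_equal(r$statistic, 0.686399983232, tolerance = 1e-10)
  expect_equal(r$p_value, 0.709496304058, tolerance = 1e-10)

  set.seed(7)
  y <- round(rlnorm(60, 0, 1), 6)
  r2 <- dagostino_pearson(y)
  expect_equal(r2$statistic, 57.290514237815, tolerance = 1e-9)
  expect_lt(r2$p_value, 0.001)
})

test_that("normality test refuses unreliable inputs", {
  expect_error(dagostino_pearson(rep(1, 30)), "constant")
  expect_error(dagostino_pearson(rnorm(12)), "force")
  expect_warning(dagostino_pearson(c(1:11, 2.5), force = TRUE), "unreliable")
  expect_error(dagostino_pearson(rnorm(5), force = TRUE), "n >= 8")
})

test_that("a strongly lognormal sample is rejected on nearly all seeds", {
  set.seed(401)
  p <- replicate(20, dagostino_pearson(rlnorm(200))$p_value)
  expect_true(all(p < 0.001))
})

test_that("normality test holds its size on normal samples", {
  set.seed(402)
  p <- replicate(1000, dagostino_pearson(rnorm(100))$p_value)
  rej <- mean(p < 0.05)
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.08)
})

test_that("Kruskal-Wallis matches hand-computed rank arithmetic", {
  # groups (1,2,3), (4,5,6), (7,8,9): ranks are 1..9, no ties; mean ranks
  # 2, 5, 8 give H = 12/(9*10) * 3*((2-5)^2 + 0 + (8-5)^2) = 7.2
  r <- kruskal_wallis(list(1:3, 4:6, 7:9))
  expect_equal(r$statistic, 7.2)
  expect_equal(r$df, 2)
  expect_equal(r$p_value, pchisq(7.2, 2, lower.tail = FALSE))

  # tie-corrected H on the fixed sample, frozen from the reference
  kw <- kruskal_wallis(fixed_groups)
  expect_equal(kw$statistic, 13.066944825009, tolerance = 1e-10)
  expect_equal(kw$p_value, 1.453948365547e-03, tolerance = 1e-8)
})

test_that("degenerate all-identical data gives H = 0, p = 1", {
  r <- kruskal_wallis(list(rep(2, 5), rep(2, 7)))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))$statistic, 0,
               tolerance = 1e-12)
})

test_that("Conover post hoc matches the reference implementation", {
  co <- conover_posthoc(fixed_groups)
  expect_equal(co$statistic,
               c(-3.026358609145, 2.224597902654, 5.252973202802),
               tolerance = 1e-8)
  expect_equal(co$p_value,
               c(6.422592267822e-03, 3.720421690823e-02, 3.306262416198e-05),
               tolerance = 1e-8)
  expect_equal(co$df, rep(21, 3))
})

test_that("Dunn post hoc matches the reference implementation", {
  du <- dunn_posthoc(fixed_groups)
  expect_equal(du$statistic,
               c(-2.081383776651, 1.529971355729, 3.612742115378),
               tolerance = 1e-8)
  expect_equal(du$p_value,
               c(3.739879242046e-02, 1.260238192731e-01, 3.029759889491e-04),
               tolerance = 1e-8)
})

test_that("post hocs are symmetric under group permutation", {
  perm <- fixed_groups[c("c", "a", "b")]
  for (fn in list(conover_posthoc, dunn_posthoc)) {
    orig <- fn(fixed_groups)
    p <- fn(perm)
    get <- function(d, g1, g2) {
      i <- (d$group1 == g1 & d$group2 == g2) |
        (d$group1 == g2 & d$group2 == g1)
      c(abs(d$statistic[i]), d$p_value[i])
    }
    for (pair in list(c("a", "b"), c("a", "c"), c("b", "c")))
      expect_equal(get(p, pair[1], pair[2]), get(orig, pair[1], pair[2]))
  }
})

test_that("identical groups yield p = 1 in both post hocs", {
  g <- list(rep(3, 6), rep(3, 6))
  expect_equal(conover_posthoc(g)$p_value, 1)
  expect_equal(dunn_posthoc(g)$p_value, 1)
  expect_error(conover_posthoc(list(1:3, numeric())), "empty group")
})

test_that("rank-based tests are invariant under monotone transforms", {
  tf <- function(x) exp(x / 3)
  gt <- lapply(fixed_groups, tf)
  expect_equal(kruskal_wallis(gt)$statistic,
               kruskal_wallis(fixed_groups)$statistic)
  expect_equal(conover_posthoc(gt)$statistic,
               conover_posthoc(fixed_groups)$statistic)
  expect_equal(dunn_posthoc(gt)$p_value, dunn_posthoc(fixed_groups)$p_value)
})

test_that("Holm-Bonferroni reproduces the step-down hand computation", {
  expect_equal(holm_bonferroni(0.04), 0.04)
  expect_equal(holm_bonferroni(c(0.01, 0.02, 0.04)), c(0.03, 0.04, 0.04))
  expect_error(holm_bonferroni(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(holm_bonferroni(c(0.1, -0.1)), "\\[0, 1\\]")
  set.seed(403)
  p <- runif(20)
  adj <- holm_bonferroni(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  # step-down monotonicity: adjusted values are non-decreasing in raw order
  expect_true(all(diff(adj[order(p)]) >= 0))
})

test_that("the gated battery routes by normality", {
  set.seed(404)
  normal <- list(a = rnorm(40, 5), b = rnorm(40, 5.2), c = rnorm(40, 6))
  r <- compare_groups(normal)
  expect_equal(r$path, "parametric")
  expect_true(all(r$pairwise$p_adjusted >= r$pairwise$p_value))

  skewed <- list(a = rlnorm(40), b = rlnorm(40, 0.3), c = rlnorm(40, 1))
  r2 <- compare_groups(skewed)
  expect_equal(r2$path, "nonparametric")
  expect_equal(attr(r2$pairwise, "method"), "Conover-Iman post hoc")
  expect_s3_class(r2$omnibus, "motility_test")

  # groups too small for the gate fall through to the nonparametric path
  small <- list(a = rnorm(10), b = rnorm(10))
  r3 <- compare_groups(small)
  expect_equal(r3$path, "nonparametric")
  r4 <- compare_groups(skewed, posthoc = "dunn")
  expect_equal(attr(r4$pairwise, "method"), "Dunn post hoc")
})

test_that("all reported p values lie in the unit interval", {
  set.seed(405)
  for (i in 1:20) {
    g <- lapply(1:3, function(j) rnorm(sample(5:30, 1)))
    expect_true(kruskal_wallis(g)$p_value >= 0 &&
                kruskal_wallis(g)$p_value <= 1)
    expect_true(all(conover_posthoc(g)$p_value >= 0 &
                    conover_posthoc(g)$p_value <= 1))
    expect_true(all(dunn_posthoc(g)$p_value >= 0 &
                    dunn_posthoc(g)$p_value <= 1))
  }
})
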