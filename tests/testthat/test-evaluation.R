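test_that("ROC summary ranks exons by p-value against the truth labels", {
  r <- rocFromPvalues(c(0.01, 0.2, 0.3, 0.9), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  expect_equal(unname(r$tprAt["0.05"]), 1)

  # AUC is invariant under strictly monotone transforms of the score
  set.seed(3)
  p <- runif(500); lab <- rbinom(500, 1, 0.4)
  expect_equal(rocFromPvalues(p, lab)$auc, rocFromPvalues(p^3, lab)$auc)

  # labels independent of p: AUC near 1/2
  expect_equal(rocFromPvalues(p, lab)$auc, 0.5, tolerance = 0.07)

  # step convention: TPR at the largest threshold with FPR <= level;
  # at level 0.2 only the first threshold (FPR 0) is achievable
  r2 <- rocFromPvalues(c(0.01, 0.02, 0.5, 0.6, 0.7), c(1, 0, 1, 0, 0),
                       fprLevels = c(0.2, 0.4))
  expect_equal(unname(r2$tprAt["0.2"]), 1/2)
  expect_equal(unname(r2$tprAt["0.4"]), 1)
  expect_error(rocFromPvalues(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("Harrell's C-index counts concordant comparable pairs", {
  expect_equal(concordanceIndex(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1)), 1)
  expect_equal(concordanceIndex(c(3, 1, 2), c(1, 2, 3), c(1, 1, 1)), 2/3)
  # random scores on a large cohort: C near 1/2
  set.seed(5)
  t <- rexp(800); e <- rbinom(800, 1, 0.7)
  expect_equal(concordanceIndex(runif(800), t, e), 0.5, tolerance = 0.04)
  # complement symmetry without score ties
  s <- runif(800)
  expect_equal(concordanceIndex(s, t, e) + concordanceIndex(-s, t, e), 1)
  # agreement with the reference implementation (continuous times)
  cref <- survival::concordance(survival::Surv(t, e) ~ s, reverse = TRUE)
  expect_equal(concordanceIndex(s, t, e), unname(cref$concordance),
               tolerance = 1e-10)
  expect_error(concordanceIndex(c(1, 2), c(5, 6), c(0, 0)), "comparable")
})

test_that("Kaplan-Meier product-limit curve steps only at event times", {
  km <- kaplanMeier(c(1, 2), c(1, 1))
  expect_equal(km$time, c(1, 2))
  expect_equal(km$surv, c(1/2, 0))
  # all censored: flat at 1 (no steps)
  expect_equal(nrow(kaplanMeier(c(1, 2, 3), c(0, 0, 0))), 0L)
  # censoring before the first event shrinks the risk set only
  km2 <- kaplanMeier(c(0.5, 1, 2), c(0, 1, 1))
  expect_equal(km2$surv, c(1/2, 0))
  # against the reference product-limit fit
  set.seed(8)
  t <- rexp(200); e <- rbinom(200, 1, 0.6)
  km3 <- kaplanMeier(t, e)
  sf <- survival::survfit(survival::Surv(t, e) ~ 1)
  expect_equal(km3$surv, summary(sf, times = km3$time)$surv,
               tolerance = 1e-10)
})

test_that("two-means stratification finds the exact 1-D optimum", {
  expect_equal(twoMeansStratify(c(0.1, 0.1, 0.9, 0.9)), c(1L, 1L, 2L, 2L))
  # enumerating the 3 sorted splits: {0 | .4 .5 1} SSE .42 vs
  # {0 .4 | .5 1} SSE .205 vs {0 .4 .5 | 1} SSE .14 -> last wins
  expect_equal(twoMeansStratify(c(0, 0.4, 0.5, 1)), c(1L, 1L, 1L, 2L))
  # label invariance under permutation of values
  v <- c(0.2, 0.8, 0.1, 0.9, 0.15)
  perm <- c(4, 2, 5, 1, 3)
  expect_equal(twoMeansStratify(v)[perm], twoMeansStratify(v[perm]))
  expect_error(twoMeansStratify(rep(1, 5)), "distinct")

  # exact optimum: never worse than seeded Lloyd iterations
  set.seed(11)
  for (i in 1:10) {
    v <- rbeta(60, 0.5, 0.5)
    g <- twoMeansStratify(v)
    sse <- sum(tapply(v, g, function(z) sum((z - mean(z))^2)))
    km <- kmeans(v, centers = 2, nstart = 25)
    expect_lte(sse, km$tot.withinss + 1e-8)
  }
})

test_that("log-rank test matches the reference implementation", {
  set.seed(14)
  t <- rexp(120); e <- rbinom(120, 1, 0.6)
  g <- rep(1:2, each = 60)
  mine <- logrankTest(g, t, e)
  ref <- survival::survdiff(survival::Surv(t, e) ~ g)
  expect_equal(mine$chisq, ref$chisq, tolerance = 1e-8)
  expect_equal(mine$pvalue,
               pchisq(ref$chisq, 1, lower.tail = FALSE),
               tolerance = 1e-8)

  # relabelled duplicated cohort: statistic 0, p = 1
  dup <- logrankTest(rep(1:2, times = 5), rep(rexp(5), each = 2),
                     rep(rbinom(5, 1, 1), each = 2))
  expect_equal(dup$chisq, 0, tolerance = 1e-12)
  expect_equal(dup$pvalue, 1)

  # strongly separated survival
  t1 <- rexp(100, 5); t2 <- rexp(100, 0.5)
  sep <- logrankTest(rep(1:2, each = 100), c(t1, t2), rep(1, 200))
  expect_lt(sep$pvalue, 1e-4)
  expect_error(logrankTest(rep(1, 10), rexp(10), rep(1, 10)), "two")
})
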