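# shared small cohort with one informative splicing exon and noise
# gene-expression features
makeCvFixture <- function(n = 90, nExons = 12, seed = 21) {
  set.seed(seed)
  psi <- pmin(pmax(rnorm(n, 0.5, 0.25), 0), 1)
  surv <- simulateSurvival(psi, beta = -3)
  cens <- applyCensoring(surv$time, surv$event, 0.3)
  ic <- matrix(rpois(nExons * n, 10), nExons, n,
               dimnames = list(paste0("ex", seq_len(nExons)),
                               paste0("p", seq_len(n))))
  sc <- matrix(rpois(nExons * n, 5), nExons, n, dimnames = dimnames(ic))
  # exon 1 tracks the informative inclusion level
  depth <- ic[1, ] + sc[1, ]
  ic[1, ] <- rbinom(n, depth, lengthNormalization(psi, 2, 1))
  sc[1, ] <- depth - ic[1, ]
  genes <- matrix(rnorm(5 * n), 5, n,
                  dimnames = list(paste0("g", 1:5), colnames(ic)))
  list(sds = SpliceSurvDataSet(ic, sc, time = cens$time,
                               event = cens$event),
       genes = genes, psi = psi)
}

test_that("univariate screening keeps features passing the p threshold", {
  fx <- makeCvFixture()
  # threshold 1 keeps every testable feature
  allSel <- univariateScreen(fx$genes, survivalTimes(fx$sds),
                             eventStatus(fx$sds), threshold = 1)
  expect_setequal(allSel, rownames(fx$genes))
  # the informative exon is found by the splicing screen
  sel <- univariateScreen(fx$sds, threshold = 0.01)
  expect_true("ex1" %in% sel)
  # pure-noise features are selected at about the nominal rate
  set.seed(2)
  hits <- 0; tot <- 0
  for (r in 1:10) {
    noise <- matrix(rnorm(40 * 60), 40, 60)
    t0 <- rexp(60); e0 <- rbinom(60, 1, 0.6)
    hits <- hits + length(univariateScreen(noise, t0, e0,
                                           threshold = 0.01))
    tot <- tot + 40
  }
  expect_lt(hits / tot, 0.05)
  expect_error(univariateScreen(fx$genes, rexp(90), rbinom(90, 1, 1),
                                threshold = 2), "threshold")
})

test_that("z-scoring uses training statistics only and drops constants", {
  train <- rbind(a = c(0, 2), b = c(1, 1))
  test <- rbind(a = c(4, -2), b = c(3, 5))
  expect_message(z <- zscoreNormalize(train, test), "constant")
  expect_equal(z$dropped, "b")
  # n - 1 denominator: sd(c(0,2)) = sqrt(2)
  expect_equal(unname(z$train["a", ]), c(-1, 1) / sqrt(2))
  expect_equal(unname(z$test["a", ]), (c(4, -2) - 1) / sqrt(2))
  expect_equal(mean(z$train["a", ]), 0)
})

test_that("penalized Cox model shrinks, matches the unpenalized oracle,
           and is invariant to feature duplication", {
  set.seed(31)
  n <- 120
  x <- cbind(f1 = runif(n), f2 = runif(n))
  time <- rexp(n) * exp(-1.5 * x[, 1])
  event <- rbinom(n, 1, 0.7)

  # full shrinkage at a huge penalty
  m0 <- fitPenalizedCox(x, time, event, penalty = 1e4)
  expect_true(all(m0$coef == 0))

  # near-zero penalty approaches the unpenalized two-covariate fit
  m1 <- fitPenalizedCox(x, time, event, penalty = 1e-8)
  ref <- survival::coxph(survival::Surv(time, event) ~ x,
                         ties = "breslow")
  expect_equal(unname(m1$coef), unname(coef(ref)), tolerance = 1e-3)

  # single-feature route reduces to the scalar fit
  ms <- fitPenalizedCox(x[, 1, drop = FALSE], time, event)
  expect_equal(unname(ms$coef), coxFit(x[, 1], time, event)$beta,
               tolerance = 1e-6)

  # duplicated feature leaves risk scores essentially unchanged
  mdup <- fitPenalizedCox(cbind(x, f1b = x[, 1]), time, event,
                          penalty = 0.05)
  msing <- fitPenalizedCox(x, time, event, penalty = 0.05)
  expect_equal(riskScore(mdup, cbind(x, f1b = x[, 1])),
               riskScore(msing, x), tolerance = 0.05)

  expect_warning(mEmpty <- fitPenalizedCox(x[, 0], time, event),
                 "null model")
  expect_equal(riskScore(mEmpty, x[, 0]), rep(0, n))
})

test_that("Monte Carlo cross-validation is paired, deterministic and
           honest about information content", {
  fx <- makeCvFixture()
  models <- list(splicing = "splicing", gene = "gene",
                 both = c("gene", "splicing"))
  rep1 <- monteCarloCV(fx$sds, features = list(gene = fx$genes),
                       models = models, rounds = 6, seed = 7L,
                       threshold = 0.05)
  rep2 <- monteCarloCV(fx$sds, features = list(gene = fx$genes),
                       models = models, rounds = 6, seed = 7L,
                       threshold = 0.05)
  expect_identical(cvConcordance(rep1), cvConcordance(rep2))
  expect_equal(dim(cvConcordance(rep1)), c(6L, 3L))
  expect_true(all(cvConcordance(rep1) >= 0 & cvConcordance(rep1) <= 1))

  med <- apply(cvConcordance(rep1), 2, median)
  # informative splicing features predict; pure-noise genes do not
  expect_gt(med["splicing"], med["gene"])
  # noise-only model hovers at the random-guess C-index
  expect_lt(abs(med["gene"] - 0.5), 0.15)

  # the leaky full-cohort screening mode is explicitly flagged
  expect_warning(monteCarloCV(fx$sds, features = list(gene = fx$genes),
                              models = list(gene = "gene"), rounds = 1,
                              seed = 1L, screenFullCohort = TRUE),
                 "leak")
})

test_that("model comparison is a paired two-sided signed-rank test", {
  cidx <- cbind(a = seq(0.55, 0.75, length.out = 20),
                b = seq(0.55, 0.75, length.out = 20))
  rep <- new("CvReport", cindex = cidx, seed = 1L, split = 0.5)
  expect_equal(compareModels(rep, c("a", "b")), 1)

  cidx2 <- cidx; cidx2[, "b"] <- cidx2[, "b"] - 0.02
  rep2 <- new("CvReport", cindex = cidx2, seed = 1L, split = 0.5)
  p <- compareModels(rep2, c("a", "b"))
  expect_lt(p, 1e-4)
  expect_equal(p, compareModels(rep2, c("b", "a")))
  expect_equal(p, suppressWarnings(
    wilcox.test(cidx2[, "a"], cidx2[, "b"], paired = TRUE)$p.value))
  expect_error(compareModels(rep2, c("a", "zzz")), "unknown")
})

test_that("a trained model scores at chance on outcome-permuted test data", {
  set.seed(41)
  n <- 160
  x <- cbind(f1 = runif(n), f2 = runif(n), f3 = runif(n))
  time <- rexp(n) * exp(-2 * x[, 1])
  event <- rbinom(n, 1, 0.7)
  train <- 1:80; test <- 81:160
  model <- fitPenalizedCox(x[train, ], time[train], event[train],
                           penalty = 0.01)
  sc <- riskScore(model, x[test, ])
  # real test outcome: informative
  expect_gt(concordanceIndex(sc, time[test], event[test]), 0.6)
  # permuted test outcome: chance level
  cs <- replicate(20, {
    perm <- sample(80)
    concordanceIndex(sc, time[test][perm], event[test][perm])
  })
  expect_lt(abs(median(cs) - 0.5), 0.05)
})
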