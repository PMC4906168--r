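test_that("length normalization maps inclusion level to read proportion", {
  expect_equal(lengthNormalization(0.5, 2, 1), 2/3)
  psi <- seq(0, 1, by = 0.1)
  expect_equal(lengthNormalization(psi, 3, 3), psi)
  expect_equal(lengthNormalization(c(0, 1), 2, 1), c(0, 1))
  expect_error(lengthNormalization(1.2, 2, 1), "0, 1")
  # inverse of the PSI estimator's mapping
  p <- lengthNormalization(0.37, 2, 1)
  expect_equal(estimatePsi(p * 1e6, (1 - p) * 1e6, 2, 1), 0.37,
               tolerance = 1e-9)
})

test_that("survival terms give the proportional-hazards log-density", {
  # beta = -1, constant unit baseline, censored at t = 1, psi = 0:
  # log S = -exp(0) * 1 = -1
  ch <- constantHazard(1)
  expect_equal(survivalLogTerms(1, 0, 0, -1, ch), -1)
  # beta = 0: contribution independent of psi
  expect_equal(survivalLogTerms(2, 1, 0.2, 0, ch),
               survivalLogTerms(2, 1, 0.9, 0, ch))
  # psi = 1 vs psi = 0 at beta = -1: higher inclusion, higher survival
  d <- survivalLogTerms(1, 0, 1, -1, ch) - survivalLogTerms(1, 0, 0, -1, ch)
  expect_equal(d, 1 * (1 - exp(-1)))
  expect_gt(d, 0)
})

test_that("exon likelihood factorizes at beta = 0", {
  # single censored patient, equal lengths, uniform prior:
  # binomial factor integrates to C(10,5) * B(6,6) = 1/11
  ctrl <- survivControl(prior = "uniform")
  ll <- exonLogLik(5, 5, time = 1, event = 0, beta = 0, lenInc = 1,
                   lenSkip = 1, baseline = constantHazard(1),
                   control = ctrl)
  expect_equal(ll, log(1/11) - 1, tolerance = 1e-10)

  # multi-patient factorization: survival part + marginal binomial part
  d <- makeExonData(n = 12, beta = 0, seed = 3)
  bh <- nelsonAalen(d$time, d$event)
  ll <- exonLogLik(d$ic, d$sc, d$time, d$event, beta = 0,
                   baseline = bh, control = ctrl)
  survPart <- sum(survivalLogTerms(d$time, d$event, 0.5, 0, bh))
  binPart <- sum(vapply(seq_along(d$ic), function(k) {
    log(integrate(function(psi)
      dbinom(d$ic[k], d$ic[k] + d$sc[k],
             lengthNormalization(psi, 2, 1)),
      0, 1, rel.tol = 1e-12)$value)
  }, numeric(1)))
  expect_equal(ll, survPart + binPart, tolerance = 1e-6)
})

test_that("quadrature is converged at the default node count", {
  for (s in 1:5) {
    d <- makeExonData(n = 15, beta = -1, seed = s)
    bh <- nelsonAalen(d$time, d$event)
    ll64 <- exonLogLik(d$ic, d$sc, d$time, d$event, beta = -0.7,
                       baseline = bh,
                       control = survivControl(quadPoints = 64,
                                               prior = "uniform"))
    ll512 <- exonLogLik(d$ic, d$sc, d$time, d$event, beta = -0.7,
                        baseline = bh,
                        control = survivControl(quadPoints = 512,
                                                prior = "uniform"))
    expect_equal(ll64, ll512, tolerance = 1e-6)
  }
})

test_that("exon likelihood matches a brute-force Riemann integrator", {
  for (s in 1:6) {
    d <- makeExonData(n = 12, beta = s %% 3 - 1, meanDepth = 10, seed = s)
    bh <- nelsonAalen(d$time, d$event)
    beta <- c(-2, 0, 1.5)[s %% 3 + 1]
    ll <- exonLogLik(d$ic, d$sc, d$time, d$event, beta, baseline = bh,
                     control = survivControl(prior = "uniform"))
    oracle <- riemannExonLogLik(d$ic, d$sc, d$time, d$event, beta,
                                baseline = bh)
    expect_equal(ll, oracle, tolerance = 1e-5)
  }
})

test_that("likelihood-ratio test uses the chi-squared(1) tail", {
  lp <- lrtPvalue(-10, -10)
  expect_equal(lp$stat, 0)
  expect_equal(lp$pvalue, 1)
  expect_equal(lrtPvalue(-8.0792705, -10)$pvalue, 0.05, tolerance = 1e-6)
  expect_equal(lrtPvalue(-4.5862, -10)$pvalue, 0.001, tolerance = 1e-4)
  expect_error(lrtPvalue(-11, -10), "below null")
})

test_that("BH adjustment is the standard step-up procedure", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bhAdjust(0.7), 0.7)
  expect_error(bhAdjust(c(0.5, 0)), "0, 1")
  expect_error(bhAdjust(numeric(0)), "empty")
})

test_that("single-exon fit recovers the effect sign and respects bounds", {
  d <- makeExonData(n = 250, beta = -2.5, meanDepth = 60, psiSd = 0.25,
                    censorFraction = 0.3, seed = 11)
  fit <- fitExon(d$ic, d$sc, d$time, d$event)
  expect_lt(fit$beta, -0.5)
  expect_gte(fit$logLikAlt, fit$logLikNull)
  expect_lt(fit$pvalue, 0.05)

  # degenerate bounds pin the fit at the null
  fit0 <- fitExon(d$ic, d$sc, d$time, d$event,
                  control = survivControl(betaBounds = c(0, 0)))
  expect_equal(fit0$beta, 0)
  expect_equal(fit0$logLikAlt, fit0$logLikNull)
  expect_equal(fit0$pvalue, 1)
})

test_that("profile-baseline LRT matches the Cox partial-likelihood LRT
           when inclusion levels are read without error", {
  set.seed(42)
  for (s in 1:5) {
    n <- 120
    psi <- pmin(pmax(rnorm(n, 0.5, 0.25), 0), 1)
    time <- rexp(n) * exp(1.5 * psi)
    event <- rbinom(n, 1, 0.5)
    big <- 1e6
    ic <- round(big * lengthNormalization(psi, 2, 1))
    fit <- fitExon(ic, big - ic, time, event)
    cf <- coxFit(psi, time, event)
    expect_equal(fit$lrt, cf$lrt, tolerance = 0.05)
  }
})

test_that("cohort-level fit is deterministic, order-equivariant and
           filters uncovered exons", {
  sds <- makeDataSet(nExons = 8, n = 50, seed = 5)
  res <- fitSplicingSurvival(sds)
  expect_equal(res$exon_id, rownames(sds))
  expect_equal(res$fdr, bhAdjust(res$pvalue))

  # permuting exons permutes results only
  perm <- c(3, 1, 2, 8, 5, 4, 7, 6)
  res2 <- fitSplicingSurvival(sds[perm, ])
  expect_equal(res2$pvalue, res$pvalue[perm])

  # duplicated exon gives identical statistics; m = 2 equal p => fdr = p
  dup <- sds[c(1, 1), ]
  rownames(dup) <- c("a", "b")
  resDup <- fitSplicingSurvival(dup)
  expect_equal(resDup$pvalue[1], resDup$pvalue[2])
  expect_equal(resDup$fdr, resDup$pvalue)

  # an exon with no reads anywhere fails the coverage filter
  ic <- inclusionCounts(sds); sc <- skippingCounts(sds)
  ic[1, ] <- 0L; sc[1, ] <- 0L
  sds0 <- SpliceSurvDataSet(ic, sc, time = survivalTimes(sds),
                            event = eventStatus(sds))
  expect_message(res0 <- fitSplicingSurvival(sds0), "coverage")
  expect_false(rownames(sds)[1] %in% res0$exon_id)
})

test_that("estimation error shrinks as read depth grows", {
  medErr <- function(depth) {
    co <- simulateCohort(simScenario(nSubjects = 300L, nExons = 60L,
                                     altFraction = 1, meanDepth = depth,
                                     betaPool = c(-2), censoring = FALSE,
                                     seed = 71L))
    res <- fitSimulatedCohort(co, "me")
    median(abs(res$beta - res$true_beta), na.rm = TRUE)
  }
  errs <- vapply(c(5, 20, 100), medErr, numeric(1))
  expect_true(all(diff(errs) <= 0))
})
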