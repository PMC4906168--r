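# small in-code fixtures shared across test files

# one exon's worth of data with a strong (or null) survival effect
makeExonData <- function(n = 80, beta = 0, meanDepth = 30, psiMean = 0.5,
                         psiSd = 0.2, censorFraction = 0.5, seed = 1) {
  set.seed(seed)
  psi <- pmin(pmax(rnorm(n, psiMean, psiSd), 0), 1)
  depth <- simulateDepths(n, meanDepth)
  cnt <- simulateCounts(psi, depth)
  surv <- simulateSurvival(psi, beta)
  cens <- applyCensoring(surv$time, surv$event, censorFraction)
  list(ic = cnt$ic, sc = cnt$sc, psi = psi,
       time = cens$time, event = cens$event)
}

makeDataSet <- function(nExons = 10, n = 40, seed = 1) {
  set.seed(seed)
  ic <- matrix(rpois(nExons * n, 8), nExons, n,
               dimnames = list(paste0("ex", seq_len(nExons)),
                               paste0("p", seq_len(n))))
  sc <- matrix(rpois(nExons * n, 4), nExons, n, dimnames = dimnames(ic))
  SpliceSurvDataSet(ic, sc, time = rexp(n) + 0.1,
                    event = rbinom(n, 1, 0.5))
}

# independent midpoint-rule integrator for the exon likelihood
# (the brute-force oracle: no quadrature, no C++)
riemannExonLogLik <- function(ic, sc, time, event, beta, lenInc = 2,
                              lenSkip = 1, baseline, nGrid = 10001,
                              priorParams = NULL) {
  h <- 1 / nGrid
  psi <- (seq_len(nGrid) - 0.5) * h
  f <- lenInc * psi / (lenInc * psi + lenSkip * (1 - psi))
  logPrior <- if (is.null(priorParams)) 0
  else dbeta(f, priorParams[1], priorParams[2], log = TRUE) +
    log(lenInc * lenSkip) - 2 * log(lenInc * psi + lenSkip * (1 - psi))
  ch <- cumHazardAt(baseline, time)
  lh <- log(hazardIncrementAt(baseline, time))
  total <- 0
  for (k in seq_along(ic)) {
    lint <- dbinom(ic[k], ic[k] + sc[k], f, log = TRUE) + logPrior +
      event[k] * (lh[k] + beta * psi) - ch[k] * exp(beta * psi)
    m <- max(lint)
    total <- total + m + log(sum(exp(lint - m))) + log(h)
  }
  total
}
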