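#' Default pool of survival coefficients for alternative exons
#'
#' A fixed, evenly spaced pool covering both signs with magnitudes
#' between 1 and 4 (hazard log-ratio per unit PSI); stands in for
#' effect sizes estimated from real cohorts so that fully synthetic
#' scenarios need no external data.
#'
#' @param size pool size (split evenly between signs).
#' @export
defaultBetaPool <- function(size = 100L) {
  half <- seq(1, 4, length.out = size %/% 2L)
  c(half, -half)
}

#' Construct a simulation scenario
#'
#' See [SimScenario-class] for the meaning and provenance of the
#' defaults.
#'
#' @param nSubjects,nExons cohort dimensions.
#' @param altFraction fraction of exons with nonzero survival coefficient.
#' @param meanDepth mean total junction-read count.
#' @param gammaRate Gamma mixing rate for the Gamma-Poisson depth model.
#' @param psiMeanBetaParams,psiSdGammaParams PSI hierarchy parameters.
#' @param betaPool coefficient pool for alternative exons.
#' @param censoring,censorFraction censoring switch and fraction.
#' @param lenInc,lenSkip effective lengths for all simulated exons.
#' @param baseline generating [BaselineHazard-class].
#' @param seed RNG seed.
#' @export
simScenario <- function(nSubjects = 600L, nExons = 20000L,
                        altFraction = 0.10, meanDepth = 20,
                        gammaRate = 0.05,
                        psiMeanBetaParams = c(0.51, 0.36),
                        psiSdGammaParams = c(1.31, 15.04),
                        betaPool = defaultBetaPool(),
                        censoring = TRUE, censorFraction = 0.85,
                        lenInc = 2, lenSkip = 1,
                        baseline = constantHazard(1), seed = 1L) {
  new("SimScenario", nSubjects = as.integer(nSubjects),
      nExons = as.integer(nExons), altFraction = altFraction,
      meanDepth = meanDepth, gammaRate = gammaRate,
      psiMeanBetaParams = psiMeanBetaParams,
      psiSdGammaParams = psiSdGammaParams, betaPool = betaPool,
      censoring = censoring, censorFraction = censorFraction,
      lenInc = lenInc, lenSkip = lenSkip, baseline = baseline,
      seed = as.integer(seed))
}

#' Simulate per-patient total junction-read counts
#'
#' Gamma-Poisson (negative binomial) model: the Poisson mean of patient
#' \eqn{k} is \eqn{\lambda_k \sim} Gamma(shape = rate x meanDepth,
#' rate), so that \eqn{E[n_k] =} `meanDepth` and \eqn{Var[n_k] =}
#' `meanDepth (1 + 1/rate)` -- strongly overdispersed at the default
#' rate 0.05.
#'
#' @param n number of draws.
#' @param meanDepth mean total count.
#' @param gammaRate Gamma rate parameter.
#' @param seed optional seed (`NULL` = use current RNG state).
#' @export
simulateDepths <- function(n, meanDepth, gammaRate = 0.05, seed = NULL) {
  if (meanDepth <= 0 || gammaRate <= 0)
    stop("meanDepth and gammaRate must be positive")
  if (!is.null(seed)) set.seed(seed)
  lambda <- stats::rgamma(n, shape = gammaRate * meanDepth,
                          rate = gammaRate)
  stats::rpois(n, lambda)
}

# Normal(mean, sd) truncated to [0, 1] by inverse-CDF sampling
.rtruncnorm01 <- function(n, mean, sd) {
  out <- rep(mean, length.out = n)
  pos <- sd > 0
  if (any(pos)) {
    mean <- rep(mean, length.out = n)[pos]
    sd <- rep(sd, length.out = n)[pos]
    lo <- stats::pnorm((0 - mean) / sd)
    hi <- stats::pnorm((1 - mean) / sd)
    u <- stats::runif(sum(pos), lo, hi)
    out[pos] <- stats::qnorm(u) * sd + mean
  }
  pmin(pmax(out, 0), 1)
}

#' Simulate an exon's inclusion levels across patients
#'
#' Hierarchy: exon-level mean \eqn{\psi \sim} Beta(a, b); variance
#' \eqn{\sigma^2 \sim} Gamma(shape, rate); per-patient
#' \eqn{\psi_k \sim N(\psi, \sigma^2)} truncated to \[0, 1\].
#'
#' @param n number of patients.
#' @param psiMeanBetaParams,psiSdGammaParams hierarchy parameters.
#' @param seed optional seed.
#' @return list with `psiMean`, `psiSd` and the per-patient vector `psi`.
#' @export
simulateExonPsi <- function(n, psiMeanBetaParams = c(0.51, 0.36),
                            psiSdGammaParams = c(1.31, 15.04),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- stats::rbeta(1, psiMeanBetaParams[1], psiMeanBetaParams[2])
  s <- sqrt(stats::rgamma(1, shape = psiSdGammaParams[1],
                          rate = psiSdGammaParams[2]))
  list(psiMean = m, psiSd = s, psi = .rtruncnorm01(n, m, s))
}

#' Simulate junction read counts given inclusion levels and depths
#'
#' \eqn{IC_k \sim} Binomial(\eqn{n_k}, \eqn{f(\psi_k)}),
#' \eqn{SC_k = n_k - IC_k}.
#'
#' @param psi per-patient inclusion levels.
#' @param n per-patient total counts.
#' @param lenInc,lenSkip effective lengths.
#' @param seed optional seed.
#' @return list with integer vectors `ic` and `sc`.
#' @export
simulateCounts <- function(psi, n, lenInc = 2, lenSkip = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ic <- stats::rbinom(length(psi), n,
                      lengthNormalization(psi, lenInc, lenSkip))
  list(ic = ic, sc = n - ic)
}

#' Simulate (uncensored) survival times from the proportional-hazards
#' model
#'
#' Inverse-transform sampling: with \eqn{U \sim} Uniform(0, 1), the
#' survival time solves \eqn{\Lambda_0(t) = -\log U \, e^{-\beta\psi_k}}
#' (closed form for a constant-rate baseline; step-function inverse for a
#' Nelson-Aalen baseline, with targets beyond the support mapped to the
#' largest event time and flagged administratively censored).
#'
#' @param psi per-patient inclusion levels (the covariate).
#' @param beta survival coefficient.
#' @param baseline generating [BaselineHazard-class].
#' @param seed optional seed.
#' @return data.frame with `time`, `event` (1, or 0 for administrative
#'   censoring) and `admin` flag.
#' @export
simulateSurvival <- function(psi, beta, baseline = constantHazard(1),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  target <- -log(stats::runif(length(psi))) * exp(-beta * psi)
  inv <- .invCumHazard(baseline, target)
  data.frame(time = inv$time, event = as.numeric(!inv$admin),
             admin = inv$admin)
}

#' Apply random censoring to simulated survival records
#'
#' Exactly `round(fraction * n)` subjects, chosen uniformly at random,
#' are censored: their event indicator is set to 0 and their time
#' replaced by Uniform(0.10, 0.90) times the death time.
#'
#' @param time,event uncensored records (`event` all 1 except
#'   administrative censoring).
#' @param fraction censoring fraction in \[0, 1\].
#' @param seed optional seed.
#' @return list with censored `time` and `event`.
#' @export
applyCensoring <- function(time, event, fraction, seed = NULL) {
  if (fraction < 0 || fraction > 1)
    stop("censor fraction must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- length(time)
  k <- round(fraction * n)
  if (k > 0) {
    idx <- sample.int(n, k)
    time[idx] <- stats::runif(k, 0.10, 0.90) * time[idx]
    event[idx] <- 0
  }
  list(time = time, event = event)
}

#' Simulate a full cohort under a scenario
#'
#' Composes the depth, inclusion-level, count, survival and censoring
#' generators.  A fraction `altFraction` of exons (chosen at random)
#' draw their survival coefficient uniformly from `betaPool`; the rest
#' are null (\eqn{\beta = 0}).  Each exon's survival outcome is
#' generated from its own inclusion levels, so `time`/`event` are
#' exon x patient matrices.  Fully reproducible from `scenario@seed`.
#'
#' @param scenario a [simScenario()].
#' @return a [SimulatedCohort-class].
#' @export
simulateCohort <- function(scenario) {
  validObject(scenario)
  set.seed(scenario@seed)
  nE <- scenario@nExons
  nS <- scenario@nSubjects
  beta <- rep(0, nE)
  nAlt <- round(scenario@altFraction * nE)
  if (nAlt > 0) {
    altIdx <- sample.int(nE, nAlt)
    beta[altIdx] <- sample(scenario@betaPool, nAlt, replace = TRUE)
  }
  dn <- list(paste0("exon", seq_len(nE)), paste0("patient", seq_len(nS)))
  lambda <- matrix(stats::rgamma(nE * nS,
                                 shape = scenario@gammaRate *
                                   scenario@meanDepth,
                                 rate = scenario@gammaRate), nE, nS)
  n <- matrix(stats::rpois(nE * nS, lambda), nE, nS, dimnames = dn)
  psiMean <- stats::rbeta(nE, scenario@psiMeanBetaParams[1],
                          scenario@psiMeanBetaParams[2])
  psiSd <- sqrt(stats::rgamma(nE, shape = scenario@psiSdGammaParams[1],
                              rate = scenario@psiSdGammaParams[2]))
  psi <- matrix(.rtruncnorm01(nE * nS, rep(psiMean, nS),
                              rep(psiSd, nS)), nE, nS, dimnames = dn)
  f <- lengthNormalization(psi, scenario@lenInc, scenario@lenSkip)
  ic <- matrix(stats::rbinom(nE * nS, n, f), nE, nS, dimnames = dn)
  sc <- n - ic
  target <- -log(matrix(stats::runif(nE * nS), nE, nS)) *
    exp(-beta * psi)
  inv <- .invCumHazard(scenario@baseline, as.numeric(target))
  time <- matrix(inv$time, nE, nS, dimnames = dn)
  admin <- matrix(inv$admin, nE, nS, dimnames = dn)
  event <- matrix(as.numeric(!admin), nE, nS, dimnames = dn)
  if (scenario@censoring && scenario@censorFraction > 0) {
    k <- round(scenario@censorFraction * nS)
    for (e in seq_len(nE)) {
      idx <- sample.int(nS, k)
      time[e, idx] <- stats::runif(k, 0.10, 0.90) * time[e, idx]
      event[e, idx] <- 0
    }
  }
  new("SimulatedCohort", inclusion = ic, skipping = sc, time = time,
      event = event, truePsi = psi, trueBeta = beta,
      adminCensored = admin, scenario = scenario)
}

#' Resample read depths from an empirical count table
#'
#' Samples total counts with replacement from any user-supplied
#' empirical depth distribution and rescales them by a factor between
#' 10\% and 300\% to emulate shallower or deeper sequencing.
#'
#' @param empiricalCounts nonnegative integer counts to resample from.
#' @param n number of draws.
#' @param scale depth multiplier in (0, 3\].
#' @param seed optional seed.
#' @export
resampleDepths <- function(empiricalCounts, n, scale = 1, seed = NULL) {
  if (!length(empiricalCounts)) stop("empty empirical count table")
  if (any(empiricalCounts < 0)) stop("counts must be nonnegative")
  if (scale <= 0 || scale > 3) stop("scale must lie in (0, 3]")
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(length(empiricalCounts), n, replace = TRUE)
  round(empiricalCounts[idx] * scale)
}

#' Extract one exon of a simulated cohort as a dataset
#'
#' Convenience coercion pairing exon `i`'s counts with its own simulated
#' survival outcome.
#'
#' @param cohort a [SimulatedCohort-class].
#' @param i exon index or name.
#' @return a [SpliceSurvDataSet-class] with a single exon.
#' @export
cohortExonDataSet <- function(cohort, i) {
  SpliceSurvDataSet(cohort@inclusion[i, , drop = FALSE],
                    cohort@skipping[i, , drop = FALSE],
                    time = cohort@time[i, ], event = cohort@event[i, ],
                    lenInc = cohort@scenario@lenInc,
                    lenSkip = cohort@scenario@lenSkip)
}
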