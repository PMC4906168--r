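#' Control parameters for the measurement-error survival fit
#'
#' @param quadPoints number of Gauss-Legendre quadrature nodes on
#'   \[0, 1\] used to integrate over the latent inclusion level
#'   (minimum 8; default 64).
#' @param prior prior on the latent inclusion level: `"beta"` (default),
#'   an empirical Beta prior fitted per exon by moment deconvolution on
#'   the read-proportion scale (the known binomial sampling variance is
#'   subtracted before matching), or `"uniform"` on \[0, 1\].
#' @param betaBounds finite search interval for the survival coefficient,
#'   containing 0.
#' @param tol optimizer tolerance on the coefficient.
#' @param maxIter maximum optimizer iterations.
#' @param minPatients coverage filter: exons with fewer than this many
#'   patients having at least one junction read are dropped.
#' @return a list of class `survivControl`.
#' @export
survivControl <- function(quadPoints = 64L, prior = c("beta", "uniform"),
                          betaBounds = c(-10, 10), tol = 1e-6,
                          maxIter = 200L, minPatients = 5L) {
  prior <- match.arg(prior)
  quadPoints <- as.integer(quadPoints)
  if (quadPoints < 8L) stop("quadPoints must be >= 8")
  if (length(betaBounds) != 2L || any(!is.finite(betaBounds)) ||
      betaBounds[1] > 0 || betaBounds[2] < 0)
    stop("betaBounds must be a finite interval containing 0")
  if (tol <= 0) stop("tol must be positive")
  structure(list(quadPoints = quadPoints, prior = prior,
                 betaBounds = betaBounds, tol = tol,
                 maxIter = as.integer(maxIter),
                 minPatients = as.integer(minPatients)),
            class = "survivControl")
}

# Gauss-Legendre nodes/weights on [0, 1] (weights sum to 1)
.quadNodes <- function(n) {
  gl <- pracma::gaussLegendre(n, 0, 1)
  list(x = gl$x, w = gl$w)
}

# Moment-matched empirical Beta prior, fitted on the read-proportion
# scale p = f(psi) where the binomial sampling variance is known and can
# be deconvolved: Var(phat) = Var(p) + E[p(1-p)/n], so with
# H = mean(1/n_k) over covered patients,
#   Var(p) = (var(phat) - m(1-m) H) / (1 - H).
# Returns Beta parameters for p, or NULL for a uniform prior when too
# few patients carry reads or the moments are unusable.
.empiricalBetaParams <- function(ic, sc) {
  n <- ic + sc
  keep <- n >= 1
  if (sum(keep) < 3L) return(NULL)
  phat <- ic[keep] / n[keep]
  m <- mean(phat)
  if (m <= 0 || m >= 1) return(NULL)
  H <- mean(1 / n[keep])
  vp <- (stats::var(phat) - m * (1 - m) * H) / max(1 - H, 0.05)
  vp <- min(max(vp, 1e-4), 0.95 * m * (1 - m))
  common <- m * (1 - m) / vp - 1
  if (!is.finite(common) || common <= 0) return(NULL)
  a <- max(min(m * common, 500), 0.05)
  b <- max(min((1 - m) * common, 500), 0.05)
  c(a, b)
}

# per-exon quadrature prep shared by exonLogLik / fitExon.  The prior is
# specified on the read-proportion scale; the change of variables to psi
# contributes the Jacobian f'(psi).
.exonPrep <- function(lenInc, lenSkip, control, priorParams = NULL) {
  q <- .quadNodes(control$quadPoints)
  f <- lengthNormalization(q$x, lenInc, lenSkip)
  logPrior <- if (is.null(priorParams)) 0
  else stats::dbeta(f, priorParams[1], priorParams[2], log = TRUE) +
    log(lenInc * lenSkip) -
    2 * log(lenInc * q$x + lenSkip * (1 - q$x))
  list(psi = q$x, logWPrior = log(q$w) + logPrior,
       logf = log(f), log1mf = log1p(-f))
}

# hazard-weighted centring constant for the covariate; centring profiles
# out the overall hazard-scale direction that a fixed plug-in baseline
# would otherwise confound with beta (the null model is unaffected)
.psiCenter <- function(psiHat, cumHaz) {
  ok <- is.finite(psiHat) & cumHaz > 0
  if (any(ok)) return(sum(cumHaz[ok] * psiHat[ok]) / sum(cumHaz[ok]))
  if (any(is.finite(psiHat))) return(mean(psiHat, na.rm = TRUE))
  0.5
}

#' Proportional-hazards log-likelihood terms for one patient
#'
#' Returns the survival part of the log-likelihood at a known inclusion
#' level: \eqn{\delta\,(\log\lambda_0(t) + \beta\psi) - \Lambda_0(t)
#' e^{\beta\psi}}, i.e. the log density for an observed death and the
#' log survival probability \eqn{\log S(t) = -\Lambda_0(t) e^{\beta\psi}}
#' for a censored record.  For a step baseline the event term uses the
#' Nelson-Aalen increment at the event's own time.
#'
#' @param time,event follow-up times and indicators (vectorized).
#' @param psi inclusion levels in \[0, 1\].
#' @param beta survival coefficient.
#' @param baseline a [BaselineHazard-class].
#' @export
survivalLogTerms <- function(time, event, psi, beta, baseline) {
  if (any(psi < 0 | psi > 1)) stop("psi must lie in [0, 1]")
  rel <- exp(beta * psi)
  event * (log(hazardIncrementAt(baseline, time)) + beta * psi) -
    cumHazardAt(baseline, time) * rel
}

#' Integrated log-likelihood of one exon
#'
#' Sums over patients the log of the latent-inclusion integral
#' \deqn{\int_0^1 e^{\ell_k(\psi;\beta)}\,
#'   \mathrm{Binom}(IC_k \mid n_k, f(\psi))\, \pi(\psi)\, d\psi,}
#' where \eqn{\ell_k} are the proportional-hazards terms of
#' [survivalLogTerms()] and \eqn{f} the length normalization.  The
#' integral is evaluated by fixed Gauss-Legendre quadrature in log space;
#' patients with zero total count contribute the survival term averaged
#' over the prior.
#'
#' @param ic,sc junction read counts, one per patient.
#' @param time,event the patients' survival records.
#' @param beta survival coefficient at which to evaluate.
#' @param lenInc,lenSkip effective lengths.
#' @param baseline a [BaselineHazard-class]; defaults to the Nelson-Aalen
#'   estimate from `time`/`event`.
#' @param control a [survivControl()] list.
#' @param psiCenter constant subtracted from the inclusion level in the
#'   hazard exponent (0 = none); fitting functions centre the covariate
#'   to decouple the coefficient from the overall hazard scale.
#' @return the exon log-likelihood (a scalar).
#' @export
exonLogLik <- function(ic, sc, time, event, beta, lenInc = 2, lenSkip = 1,
                       baseline = NULL, control = survivControl(),
                       psiCenter = 0) {
  if (is.null(baseline)) baseline <- nelsonAalen(time, event)
  priorParams <- if (control$prior == "beta")
    .empiricalBetaParams(ic, sc) else NULL
  prep <- .exonPrep(lenInc, lenSkip, control, priorParams)
  ll <- .cppExonLoglik(beta, as.numeric(ic), as.numeric(sc),
                       as.numeric(event),
                       log(hazardIncrementAt(baseline, time)),
                       cumHazardAt(baseline, time),
                       prep$psi - psiCenter, prep$logf, prep$log1mf,
                       prep$logWPrior)
  if (!is.finite(ll))
    stop(sprintf("non-finite exon log-likelihood at beta = %g", beta))
  ll
}

#' Fit the survival coefficient of one exon
#'
#' Maximizes the integrated exon likelihood over the bounded coefficient
#' interval with Brent's method.  By default the cumulative baseline
#' hazard is profiled out alongside the coefficient (EM-style Breslow
#' updates in which each risk-set contribution is the posterior
#' expectation of \eqn{e^{\beta\psi}}); at \eqn{\beta = 0} the profile
#' baseline is exactly the Nelson-Aalen estimate from all patients, so
#' the null model is the plug-in null, and with exactly observed
#' inclusion levels the profile likelihood-ratio test coincides with the
#' Cox partial-likelihood test.  `profileBaseline = FALSE` instead holds
#' the Nelson-Aalen baseline fixed while maximizing (with the covariate
#' centred at a hazard-weighted mean of the PSI point estimates to
#' decouple the coefficient from the overall hazard scale); this
#' two-stage variant yields a conservative test under measurement
#' uncertainty and is retained for comparison.  Non-convergence or a
#' boundary solution is flagged in the result, not raised as an error.
#'
#' @inheritParams exonLogLik
#' @param profileBaseline profile the baseline hazard within the
#'   alternative fit (default) or hold it fixed at the Nelson-Aalen
#'   estimate.
#' @return list with `beta`, `logLikAlt`, `logLikNull`, `lrt`, `pvalue`
#'   and `flag`.
#' @export
fitExon <- function(ic, sc, time, event, lenInc = 2, lenSkip = 1,
                    baseline = NULL, control = survivControl(),
                    profileBaseline = TRUE) {
  priorParams <- if (control$prior == "beta")
    .empiricalBetaParams(ic, sc) else NULL
  prep <- .exonPrep(lenInc, lenSkip, control, priorParams)
  if (profileBaseline) {
    ord <- order(time)
    fit <- .cppFitExonProfile(as.numeric(ic[ord]), as.numeric(sc[ord]),
                              as.numeric(event[ord]),
                              as.numeric(time[ord]), prep$psi,
                              prep$logf, prep$log1mf, prep$logWPrior,
                              control$betaBounds[1],
                              control$betaBounds[2], control$tol,
                              control$maxIter, 20L)
  } else {
    if (is.null(baseline)) baseline <- nelsonAalen(time, event)
    cumHaz <- cumHazardAt(baseline, time)
    ctr <- .psiCenter(estimatePsi(ic, sc, lenInc, lenSkip), cumHaz)
    fit <- .cppFitExon(as.numeric(ic), as.numeric(sc), as.numeric(event),
                       log(hazardIncrementAt(baseline, time)), cumHaz,
                       prep$psi - ctr, prep$logf, prep$log1mf,
                       prep$logWPrior, control$betaBounds[1],
                       control$betaBounds[2], control$tol,
                       control$maxIter)
  }
  lp <- lrtPvalue(fit$logLikAlt, fit$logLikNull)
  list(beta = fit$beta, logLikAlt = fit$logLikAlt,
       logLikNull = fit$logLikNull, lrt = lp$stat, pvalue = lp$pvalue,
       flag = fit$flag)
}

#' Likelihood-ratio test against the chi-squared(1) reference
#'
#' @param logLikAlt,logLikNull maximized and null log-likelihoods
#'   (vectorized).
#' @param tol internal-consistency tolerance: `logLikAlt` may fall below
#'   `logLikNull` by at most this much (optimizer slack) before an error
#'   is raised.
#' @return list with `stat` (floored at 0) and `pvalue` in (0, 1\].
#' @export
lrtPvalue <- function(logLikAlt, logLikNull, tol = 1e-6) {
  bad <- logLikAlt < logLikNull - pmax(tol, tol * abs(logLikNull))
  if (any(bad))
    stop("alternative log-likelihood below null beyond tolerance")
  stat <- pmax(0, 2 * (logLikAlt - logLikNull))
  list(stat = stat, pvalue = stats::pchisq(stat, df = 1,
                                           lower.tail = FALSE))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment, order-preserving and
#' capped at 1.
#'
#' @param pvalues p-values in (0, 1\].
#' @export
bhAdjust <- function(pvalues) {
  if (!length(pvalues)) stop("empty p-value vector")
  if (any(!is.finite(pvalues) | pvalues <= 0 | pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Fit the measurement-error survival model across all exons
#'
#' The cumulative baseline hazard is estimated once from the survival
#' data of all patients and held fixed while each exon's coefficient is
#' maximized.  Exons failing the coverage filter (fewer than
#' `control$minPatients` patients with at least one read) are dropped
#' with a message.  FDR is computed across the retained exons.
#'
#' @param sds a [SpliceSurvDataSet-class].
#' @param control a [survivControl()] list.
#' @param profileBaseline see [fitExon()].
#' @return a [S4Vectors::DataFrame] with one row per retained exon:
#'   `exon_id`, `beta`, `loglik_alt`, `loglik_null`, `lrt`, `pvalue`,
#'   `fdr`, `flag`.
#' @export
fitSplicingSurvival <- function(sds, control = survivControl(),
                                profileBaseline = TRUE) {
  stopifnot(is(sds, "SpliceSurvDataSet"))
  time <- survivalTimes(sds)
  event <- eventStatus(sds)
  baseline <- nelsonAalen(time, event)
  ic <- inclusionCounts(sds)
  sc <- skippingCounts(sds)
  covered <- rowSums(ic + sc >= 1) >= control$minPatients
  if (!all(covered))
    message(sum(!covered), " exon(s) dropped by the coverage filter (< ",
            control$minPatients, " patients with reads)")
  if (!any(covered)) {
    warning("no exons pass the coverage filter")
    return(DataFrame(exon_id = character(0), beta = numeric(0),
                     loglik_alt = numeric(0), loglik_null = numeric(0),
                     lrt = numeric(0), pvalue = numeric(0),
                     fdr = numeric(0), flag = character(0)))
  }
  keep <- which(covered)
  li <- rowData(sds)$lenInc
  ls <- rowData(sds)$lenSkip
  logHaz <- log(hazardIncrementAt(baseline, time))
  cumHaz <- cumHazardAt(baseline, time)
  ord <- order(time)
  n <- length(keep)
  beta <- llA <- llN <- numeric(n)
  flag <- character(n)
  for (j in seq_len(n)) {
    e <- keep[j]
    icE <- as.numeric(ic[e, ]); scE <- as.numeric(sc[e, ])
    priorParams <- if (control$prior == "beta")
      .empiricalBetaParams(icE, scE) else NULL
    prep <- .exonPrep(li[e], ls[e], control, priorParams)
    fit <- if (profileBaseline)
      .cppFitExonProfile(icE[ord], scE[ord], as.numeric(event[ord]),
                         as.numeric(time[ord]), prep$psi, prep$logf,
                         prep$log1mf, prep$logWPrior,
                         control$betaBounds[1], control$betaBounds[2],
                         control$tol, control$maxIter, 20L)
    else
      .cppFitExon(icE, scE, as.numeric(event), logHaz, cumHaz,
                  prep$psi - .psiCenter(estimatePsi(icE, scE, li[e],
                                                    ls[e]), cumHaz),
                  prep$logf, prep$log1mf, prep$logWPrior,
                  control$betaBounds[1], control$betaBounds[2],
                  control$tol, control$maxIter)
    beta[j] <- fit$beta; llA[j] <- fit$logLikAlt; llN[j] <- fit$logLikNull
    flag[j] <- fit$flag
  }
  lp <- lrtPvalue(llA, llN)
  DataFrame(exon_id = rownames(sds)[keep], beta = beta, loglik_alt = llA,
            loglik_null = llN, lrt = lp$stat, pvalue = lp$pvalue,
            fdr = bhAdjust(lp$pvalue), flag = flag)
}

#' Fit each exon of a simulated cohort
#'
#' In a [SimulatedCohort-class] every exon carries its own simulated
#' survival outcome, so each exon is fitted against its own survival
#' vector (with a per-exon Nelson-Aalen baseline for the
#' measurement-error model, or the Breslow partial likelihood for the
#' Cox comparator on PSI point estimates).
#'
#' @param cohort a [SimulatedCohort-class].
#' @param method `"me"` for the measurement-error model, `"cox"` for the
#'   comparator on PSI point estimates.
#' @param control a [survivControl()] list (measurement-error model).
#' @param profileBaseline see [fitExon()].
#' @return a [S4Vectors::DataFrame] with per-exon `beta`, `pvalue`,
#'   `true_beta` and `flag`; exons failing the coverage filter get
#'   `NA` p-values.
#' @export
fitSimulatedCohort <- function(cohort, method = c("me", "cox"),
                               control = survivControl(),
                               profileBaseline = TRUE) {
  method <- match.arg(method)
  stopifnot(is(cohort, "SimulatedCohort"))
  ic <- cohort@inclusion
  sc <- cohort@skipping
  nE <- nrow(ic)
  li <- cohort@scenario@lenInc
  ls <- cohort@scenario@lenSkip
  prep <- if (method == "me" && control$prior == "uniform")
    .exonPrep(li, ls, control) else NULL
  beta <- pval <- rep(NA_real_, nE)
  flag <- rep("dropped", nE)
  for (e in seq_len(nE)) {
    icE <- ic[e, ]; scE <- sc[e, ]
    tE <- cohort@time[e, ]; dE <- cohort@event[e, ]
    if (sum(icE + scE >= 1) < control$minPatients || sum(dE) < 2) next
    if (method == "cox") {
      fit <- tryCatch(coxFit(estimatePsi(icE, scE, li, ls), tE, dE),
                      error = function(e) NULL)
      if (is.null(fit)) next
      beta[e] <- fit$beta; pval[e] <- fit$pvalue; flag[e] <- fit$flag
    } else {
      pp <- prep
      if (is.null(pp))
        pp <- .exonPrep(li, ls, control,
                        .empiricalBetaParams(icE, scE))
      if (profileBaseline) {
        ord <- order(tE)
        fit <- .cppFitExonProfile(as.numeric(icE[ord]),
                                  as.numeric(scE[ord]),
                                  as.numeric(dE[ord]),
                                  as.numeric(tE[ord]), pp$psi,
                                  pp$logf, pp$log1mf, pp$logWPrior,
                                  control$betaBounds[1],
                                  control$betaBounds[2], control$tol,
                                  control$maxIter, 20L)
      } else {
        baseline <- nelsonAalen(tE, dE)
        cumHaz <- cumHazardAt(baseline, tE)
        psiHat <- estimatePsi(icE, scE, li, ls)
        fit <- .cppFitExon(as.numeric(icE), as.numeric(scE),
                           as.numeric(dE),
                           log(hazardIncrementAt(baseline, tE)), cumHaz,
                           pp$psi - .psiCenter(psiHat, cumHaz),
                           pp$logf, pp$log1mf, pp$logWPrior,
                           control$betaBounds[1], control$betaBounds[2],
                           control$tol, control$maxIter)
      }
      lp <- lrtPvalue(fit$logLikAlt, fit$logLikNull)
      beta[e] <- fit$beta; pval[e] <- lp$pvalue; flag[e] <- fit$flag
    }
  }
  DataFrame(exon_id = rownames(ic), beta = beta, pvalue = pval,
            true_beta = cohort@trueBeta, flag = flag)
}
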