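#' Cox proportional-hazards regression on a single covariate
#'
#' The conventional comparator: Newton-Raphson maximization of the
#' Breslow partial likelihood for one covariate (here, a PSI point
#' estimate per patient), with a likelihood-ratio test against
#' \eqn{\beta = 0}.  Patients with missing covariate values are dropped.
#' A monotone partial likelihood (perfect separation) is flagged and the
#' coefficient capped rather than raised as an error; a constant
#' covariate yields \eqn{\hat\beta = 0}, p = 1 with flag `"degenerate"`.
#'
#' @param x per-patient covariate values (missing allowed).
#' @param time,event survival records.
#' @param tol Newton-Raphson convergence tolerance on the score.
#' @param maxIter maximum Newton-Raphson iterations.
#' @param cap absolute bound on the coefficient used to detect and flag
#'   separation.
#' @return list with `beta`, `se`, `loglik`, `loglik0`, `lrt`, `pvalue`,
#'   `flag` (`"ok"`, `"degenerate"`, `"separation"` or `"noconv"`) and
#'   the number of patients used (`n`).
#' @export
coxFit <- function(x, time, event, tol = 1e-8, maxIter = 50L, cap = 15) {
  keep <- is.finite(x)
  x <- x[keep]; time <- time[keep]; event <- event[keep]
  if (sum(event) < 2) stop("coxFit needs at least 2 events")
  out <- list(beta = 0, se = Inf, loglik = NA_real_, loglik0 = NA_real_,
              lrt = 0, pvalue = 1, flag = "degenerate", n = length(x))
  if (length(unique(x)) < 2L) return(out)

  ord <- order(time)
  x <- x[ord]; time <- time[ord]; event <- event[ord]
  first <- match(time, time)  # first index of each tie group
  evIdx <- which(event == 1)

  partial <- function(beta) {
    w <- exp(beta * x)
    s0 <- rev(cumsum(rev(w)))[first]
    s1 <- rev(cumsum(rev(w * x)))[first]
    s2 <- rev(cumsum(rev(w * x * x)))[first]
    mu <- s1[evIdx] / s0[evIdx]
    list(ll = sum(beta * x[evIdx] - log(s0[evIdx])),
         U = sum(x[evIdx] - mu),
         I = sum(s2[evIdx] / s0[evIdx] - mu^2))
  }

  ll0 <- partial(0)$ll
  beta <- 0
  cur <- partial(beta)
  flag <- "noconv"
  for (iter in seq_len(maxIter)) {
    if (!is.finite(cur$I) || cur$I <= 0) break
    step <- cur$U / cur$I
    newBeta <- beta + step
    new <- partial(newBeta)
    halvings <- 0L
    while ((!is.finite(new$ll) || new$ll < cur$ll) && halvings < 20L) {
      step <- step / 2
      newBeta <- beta + step
      new <- partial(newBeta)
      halvings <- halvings + 1L
    }
    beta <- newBeta
    cur <- new
    if (abs(cur$U) < tol || abs(step) < tol) { flag <- "ok"; break }
    if (abs(beta) > cap) { flag <- "separation"; break }
  }
  if (flag == "separation") {
    beta <- sign(beta) * cap
    cur <- partial(beta)
  }
  lrt <- max(0, 2 * (cur$ll - ll0))
  list(beta = beta, se = if (cur$I > 0) 1 / sqrt(cur$I) else Inf,
       loglik = cur$ll, loglik0 = ll0, lrt = lrt,
       pvalue = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
       flag = flag, n = length(x))
}

#' Cox comparator across all exons of a dataset
#'
#' Runs [coxFit()] on the PSI point estimates of every exon, dropping
#' per exon the patients whose PSI is missing (zero reads).  Exons with
#' all-missing PSI are dropped with a message.
#'
#' @param sds a [SpliceSurvDataSet-class].
#' @param minPatients minimum patients with observed PSI for an exon to
#'   be fitted.
#' @return a [S4Vectors::DataFrame] with `exon_id`, `beta`, `se`, `lrt`,
#'   `pvalue`, `fdr`, `flag`.
#' @export
coxFitAll <- function(sds, minPatients = 5L) {
  stopifnot(is(sds, "SpliceSurvDataSet"))
  psi <- psiValues(sds)
  time <- survivalTimes(sds)
  event <- eventStatus(sds)
  covered <- rowSums(is.finite(psi)) >= minPatients
  if (!all(covered))
    message(sum(!covered),
            " exon(s) dropped (too few patients with observed PSI)")
  keep <- which(covered)
  res <- lapply(keep, function(e) coxFit(psi[e, ], time, event))
  DataFrame(exon_id = rownames(sds)[keep],
            beta = vapply(res, `[[`, numeric(1), "beta"),
            se = vapply(res, `[[`, numeric(1), "se"),
            lrt = vapply(res, `[[`, numeric(1), "lrt"),
            pvalue = vapply(res, `[[`, numeric(1), "pvalue"),
            fdr = bhAdjust(vapply(res, `[[`, numeric(1), "pvalue")),
            flag = vapply(res, `[[`, character(1), "flag"))
}
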