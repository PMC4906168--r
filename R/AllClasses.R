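#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   rowData rowData<- colData colData<-
#' @importFrom stats setNames
#' @importFrom Rcpp sourceCpp
#' @useDynLib spliceSurv, .registration = TRUE
NULL

#' BaselineHazard: cumulative baseline hazard as a step or constant-rate
#' function
#'
#' A step-function baseline (from [nelsonAalen()]) stores the distinct
#' event times, the per-time hazard increments \eqn{d_i/n_i} and their
#' cumulative sum \eqn{\Lambda_0(t)}.  A constant-rate baseline (from
#' [constantHazard()]) has \eqn{\Lambda_0(t) = \rho t}.
#'
#' @slot type `"step"` or `"constant"`.
#' @slot eventTimes strictly increasing positive event times (step type).
#' @slot increments hazard increments at the event times (step type).
#' @slot cumHazard cumulative hazard at the event times (step type).
#' @slot rate constant hazard rate (constant type).
#' @aliases BaselineHazard
#' @exportClass BaselineHazard
setClass("BaselineHazard",
         representation(type = "character", eventTimes = "numeric",
                        increments = "numeric", cumHazard = "numeric",
                        rate = "numeric"))

setValidity("BaselineHazard", function(object) {
  if (!object@type %in% c("step", "constant"))
    return("type must be 'step' or 'constant'")
  if (object@type == "constant") {
    if (length(object@rate) != 1L || !is.finite(object@rate) ||
        object@rate <= 0)
      return("constant baseline needs a single positive rate")
    return(TRUE)
  }
  tt <- object@eventTimes
  if (length(tt) < 1L) return("step baseline needs at least one event time")
  if (any(tt <= 0) || is.unsorted(tt, strictly = TRUE))
    return("event times must be strictly increasing and positive")
  if (length(object@increments) != length(tt) ||
      length(object@cumHazard) != length(tt))
    return("increments/cumHazard must match eventTimes")
  if (any(object@increments < 0))
    return("hazard increments must be nonnegative")
  if (max(abs(object@cumHazard - cumsum(object@increments))) > 1e-8)
    return("cumHazard must be the cumulative sum of the increments")
  TRUE
})

#' SpliceSurvDataSet: exon-skipping junction counts joined to a survival
#' cohort
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with two assays,
#' `"inclusion"` and `"skipping"`, holding the per-exon, per-patient
#' splice-junction read counts for the exon-inclusion and exon-skipping
#' isoforms.  `rowData` carries the isoform effective lengths (`lenInc`,
#' `lenSkip`, the numbers of unique isoform-specific read positions);
#' `colData` carries the follow-up time (`time`, days) and the event
#' indicator (`event`, 1 = death observed, 0 = censored).
#'
#' @aliases SpliceSurvDataSet-class
#' @exportClass SpliceSurvDataSet
setClass("SpliceSurvDataSet", contains = "SummarizedExperiment")

setValidity("SpliceSurvDataSet", function(object) {
  an <- names(assays(object))
  if (!all(c("inclusion", "skipping") %in% an))
    return("assays 'inclusion' and 'skipping' are required")
  ic <- assay(object, "inclusion")
  sc <- assay(object, "skipping")
  if (any(ic < 0, na.rm = TRUE) || any(sc < 0, na.rm = TRUE))
    return("junction read counts must be nonnegative")
  if (any(ic != round(ic), na.rm = TRUE) || any(sc != round(sc), na.rm = TRUE))
    return("junction read counts must be integers")
  rd <- rowData(object)
  if (!all(c("lenInc", "lenSkip") %in% colnames(rd)))
    return("rowData must contain effective lengths 'lenInc' and 'lenSkip'")
  if (any(rd$lenInc < 1) || any(rd$lenSkip < 1))
    return("effective lengths must be >= 1")
  cd <- colData(object)
  if (!all(c("time", "event") %in% colnames(cd)))
    return("colData must contain 'time' and 'event'")
  if (any(!is.finite(cd$time)) || any(cd$time <= 0))
    return("follow-up times must be positive and finite")
  if (!all(cd$event %in% c(0, 1)))
    return("event indicator must be 0 (censored) or 1 (death)")
  if (anyDuplicated(colnames(object)))
    return("patient identifiers must be unique")
  TRUE
})

#' Construct a SpliceSurvDataSet
#'
#' @param inclusion,skipping integer matrices (exons x patients) of
#'   inclusion- and skipping-junction read counts, with matching
#'   dimensions.  Row names identify exons, column names patients.
#' @param time positive follow-up times (days), one per patient.
#' @param event event indicators (1 = death observed, 0 = censored).
#' @param lenInc,lenSkip effective lengths of the inclusion and skipping
#'   isoforms; scalars are recycled across exons.  For junction-only
#'   counting of an exon-skipping event the defaults are 2 (two inclusion
#'   junctions) and 1 (one skipping junction).
#' @return A [SpliceSurvDataSet-class] object.
#' @examples
#' ic <- matrix(rpois(20, 8), nrow = 2,
#'              dimnames = list(c("ex1", "ex2"), paste0("p", 1:10)))
#' sc <- matrix(rpois(20, 4), nrow = 2, dimnames = dimnames(ic))
#' sds <- SpliceSurvDataSet(ic, sc, time = rexp(10) + 1,
#'                          event = rbinom(10, 1, 0.5))
#' @export
SpliceSurvDataSet <- function(inclusion, skipping, time, event,
                              lenInc = 2L, lenSkip = 1L) {
  inclusion <- as.matrix(inclusion)
  skipping <- as.matrix(skipping)
  if (!identical(dim(inclusion), dim(skipping)))
    stop("'inclusion' and 'skipping' must have identical dimensions")
  if (is.null(rownames(inclusion)))
    rownames(inclusion) <- rownames(skipping) <-
      paste0("exon", seq_len(nrow(inclusion)))
  if (is.null(colnames(inclusion)))
    colnames(inclusion) <- colnames(skipping) <-
      paste0("patient", seq_len(ncol(inclusion)))
  nr <- nrow(inclusion)
  rd <- DataFrame(lenInc = rep_len(as.numeric(lenInc), nr),
                  lenSkip = rep_len(as.numeric(lenSkip), nr))
  cd <- DataFrame(time = as.numeric(time), event = as.numeric(event),
                  row.names = colnames(inclusion))
  se <- SummarizedExperiment(
    assays = list(inclusion = inclusion, skipping = skipping),
    rowData = rd, colData = cd)
  new("SpliceSurvDataSet", se)
}

#' SimScenario: parameterization of one simulation experiment
#'
#' Defaults reproduce the reference simulation design: 600 subjects,
#' 20,000 exons with 10\% drawn from the alternative hypothesis,
#' Gamma-Poisson junction-read depths (rate 0.05), exon-level mean
#' inclusion \eqn{\psi \sim} Beta(0.51, 0.36), inclusion-level variance
#' \eqn{\sigma^2 \sim} Gamma(1.31, rate 15.04), a unit constant baseline
#' hazard, and 85\% censoring with censor times drawn uniformly from
#' 10--90\% of the death time.
#'
#' @slot nSubjects,nExons cohort dimensions.
#' @slot altFraction fraction of exons with a nonzero survival coefficient.
#' @slot meanDepth mean total junction-read count per exon and patient.
#' @slot gammaRate rate of the Gamma mixing distribution for read depths.
#' @slot psiMeanBetaParams Beta parameters for the exon-level mean PSI.
#' @slot psiSdGammaParams Gamma (shape, rate) for the per-exon PSI
#'   variance.
#' @slot betaPool pool of survival coefficients for alternative exons.
#' @slot censoring,censorFraction censoring switch and fraction.
#' @slot lenInc,lenSkip effective lengths used for all simulated exons.
#' @slot baseline a [BaselineHazard-class] used to generate survival times.
#' @slot seed integer RNG seed.
#' @aliases SimScenario
#' @exportClass SimScenario
setClass("SimScenario",
         representation(nSubjects = "integer", nExons = "integer",
                        altFraction = "numeric", meanDepth = "numeric",
                        gammaRate = "numeric", psiMeanBetaParams = "numeric",
                        psiSdGammaParams = "numeric", betaPool = "numeric",
                        censoring = "logical", censorFraction = "numeric",
                        lenInc = "numeric", lenSkip = "numeric",
                        baseline = "BaselineHazard", seed = "integer"))

setValidity("SimScenario", function(object) {
  if (object@nSubjects < 1L || object@nExons < 1L)
    return("nSubjects and nExons must be positive")
  if (object@altFraction < 0 || object@altFraction > 1)
    return("altFraction must lie in [0, 1]")
  if (object@meanDepth <= 0) return("meanDepth must be positive")
  if (object@gammaRate <= 0) return("gammaRate must be positive")
  if (length(object@psiMeanBetaParams) != 2L ||
      any(object@psiMeanBetaParams <= 0))
    return("psiMeanBetaParams must be two positive reals")
  if (length(object@psiSdGammaParams) != 2L ||
      any(object@psiSdGammaParams <= 0))
    return("psiSdGammaParams must be two positive reals")
  if (object@censorFraction < 0 || object@censorFraction > 1)
    return("censorFraction must lie in [0, 1]")
  if (object@altFraction > 0 && length(object@betaPool) == 0L)
    return("betaPool must be nonempty when altFraction > 0")
  if (object@lenInc < 1 || object@lenSkip < 1)
    return("effective lengths must be >= 1")
  TRUE
})

#' SimulatedCohort: one simulated exon-by-patient survival experiment
#'
#' Each exon carries its own simulated survival outcome (the survival
#' times are generated from the proportional-hazards model with that
#' exon's inclusion levels as the covariate), so `time` and `event` are
#' exon x patient matrices like the count matrices.
#'
#' @slot inclusion,skipping simulated junction-count matrices.
#' @slot time,event per-exon survival times and event indicators.
#' @slot truePsi latent per-patient inclusion levels.
#' @slot trueBeta per-exon survival coefficients (0 for null exons).
#' @slot adminCensored patients administratively censored because the
#'   step-baseline support was exhausted during inverse sampling.
#' @slot scenario the generating [SimScenario-class].
#' @aliases SimulatedCohort
#' @exportClass SimulatedCohort
setClass("SimulatedCohort",
         representation(inclusion = "matrix", skipping = "matrix",
                        time = "matrix", event = "matrix",
                        truePsi = "matrix", trueBeta = "numeric",
                        adminCensored = "matrix", scenario = "SimScenario"))

#' CvReport: Monte Carlo cross-validation concordance report
#'
#' @slot cindex matrix of Harrell C-indexes, rounds x models.
#' @slot seed RNG seed used for the split sequence.
#' @slot split training fraction.
#' @aliases CvReport
#' @exportClass CvReport
setClass("CvReport",
         representation(cindex = "matrix", seed = "integer",
                        split = "numeric"))
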