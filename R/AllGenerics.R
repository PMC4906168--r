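#' @rdname SpliceSurvDataSet
#' @param object,x a package object.
#' @export
setGeneric("inclusionCounts", function(object) standardGeneric("inclusionCounts"))
#' @rdname SpliceSurvDataSet
#' @export
setGeneric("skippingCounts", function(object) standardGeneric("skippingCounts"))
#' @rdname SpliceSurvDataSet
#' @export
setGeneric("totalCounts", function(object) standardGeneric("totalCounts"))
#' @rdname SpliceSurvDataSet
#' @export
setGeneric("survivalTimes", function(object) standardGeneric("survivalTimes"))
#' @rdname SpliceSurvDataSet
#' @export
setGeneric("eventStatus", function(object) standardGeneric("eventStatus"))
#' @rdname SpliceSurvDataSet
#' @export
setGeneric("effectiveLengths", function(object) standardGeneric("effectiveLengths"))
#' @rdname SpliceSurvDataSet
#' @export
setGeneric("psiValues", function(object) standardGeneric("psiValues"))

#' @rdname cumHazardAt
#' @export
setGeneric("cumHazardAt", function(object, t) standardGeneric("cumHazardAt"))
#' @rdname cumHazardAt
#' @export
setGeneric("hazardIncrementAt",
           function(object, t) standardGeneric("hazardIncrementAt"))

#' @rdname SimulatedCohort
#' @export
setGeneric("trueBeta", function(object) standardGeneric("trueBeta"))
#' @rdname SimulatedCohort
#' @export
setGeneric("truePsi", function(object) standardGeneric("truePsi"))

setMethod("inclusionCounts", "SpliceSurvDataSet",
          function(object) assay(object, "inclusion"))
setMethod("skippingCounts", "SpliceSurvDataSet",
          function(object) assay(object, "skipping"))
setMethod("totalCounts", "SpliceSurvDataSet",
          function(object) assay(object, "inclusion") + assay(object, "skipping"))
setMethod("survivalTimes", "SpliceSurvDataSet",
          function(object) setNames(colData(object)$time, colnames(object)))
setMethod("eventStatus", "SpliceSurvDataSet",
          function(object) setNames(colData(object)$event, colnames(object)))
setMethod("effectiveLengths", "SpliceSurvDataSet", function(object)
  DataFrame(lenInc = rowData(object)$lenInc,
            lenSkip = rowData(object)$lenSkip,
            row.names = rownames(object)))

#' @describeIn SpliceSurvDataSet matrix of per-patient PSI point
#'   estimates; `NA` where a patient has no reads for that exon.
setMethod("psiValues", "SpliceSurvDataSet", function(object) {
  ic <- assay(object, "inclusion")
  sc <- assay(object, "skipping")
  li <- rowData(object)$lenInc
  ls <- rowData(object)$lenSkip
  num <- ic / li
  den <- num + sc / ls
  out <- num / den
  out[den == 0] <- NA_real_
  out
})

setMethod("inclusionCounts", "SimulatedCohort", function(object) object@inclusion)
setMethod("skippingCounts", "SimulatedCohort", function(object) object@skipping)
setMethod("totalCounts", "SimulatedCohort",
          function(object) object@inclusion + object@skipping)
setMethod("trueBeta", "SimulatedCohort", function(object) object@trueBeta)
setMethod("truePsi", "SimulatedCohort", function(object) object@truePsi)

setMethod("show", "SpliceSurvDataSet", function(object) {
  cat("SpliceSurvDataSet with", nrow(object), "exons and",
      ncol(object), "patients\n")
  cat("  events:", sum(colData(object)$event), "of", ncol(object),
      sprintf("(censoring %.1f%%)\n",
              100 * mean(colData(object)$event == 0)))
  callNextMethod()
})

setMethod("show", "BaselineHazard", function(object) {
  if (object@type == "constant") {
    cat("BaselineHazard: constant rate", object@rate, "\n")
  } else {
    cat("BaselineHazard: step function with", length(object@eventTimes),
        "event times;", sprintf("Lambda0(max) = %.4f\n",
                                max(object@cumHazard)))
  }
})

setMethod("show", "SimScenario", function(object) {
  cat("SimScenario:", object@nExons, "exons x", object@nSubjects,
      "subjects\n")
  cat(sprintf("  mean depth %.3g (Gamma rate %.3g), alt fraction %.2f\n",
              object@meanDepth, object@gammaRate, object@altFraction))
  cat(sprintf("  censoring %s (fraction %.2f); seed %d\n",
              if (object@censoring) "on" else "off",
              object@censorFraction, object@seed))
})

setMethod("show", "SimulatedCohort", function(object) {
  cat("SimulatedCohort:", nrow(object@inclusion), "exons x",
      ncol(object@inclusion), "patients;",
      sum(object@trueBeta != 0), "alternative exons\n")
})

setMethod("show", "CvReport", function(object) {
  cat("CvReport:", nrow(object@cindex), "cross-validation rounds\n")
  med <- apply(object@cindex, 2, stats::median)
  for (m in colnames(object@cindex))
    cat(sprintf("  %-28s median C-index %.3f\n", m, med[[m]]))
})

#' @rdname CvReport
#' @export
setGeneric("cvConcordance", function(object) standardGeneric("cvConcordance"))
#' @describeIn CvReport rounds x models matrix of test-set C-indexes.
setMethod("cvConcordance", "CvReport", function(object) object@cindex)
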