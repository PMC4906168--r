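#' Estimate the exon-inclusion level (PSI) from junction read counts
#'
#' The inclusion level is the effective-length-normalized read ratio
#' \deqn{\hat\psi = \frac{IC/l_I}{IC/l_I + SC/l_S},}
#' where \eqn{IC} and \eqn{SC} are the inclusion- and skipping-junction
#' read counts and \eqn{l_I}, \eqn{l_S} the numbers of unique
#' isoform-specific read positions.  With junction-only counting of an
#' exon-skipping event, \eqn{l_I = 2} and \eqn{l_S = 1}.
#'
#' @param ic,sc nonnegative read counts (vectorized).
#' @param lenInc,lenSkip effective lengths, \eqn{\ge 1}.
#' @return PSI estimates in \[0, 1\]; `NA` where `ic + sc == 0`.
#' @examples
#' estimatePsi(20, 10, lenInc = 2, lenSkip = 1)  # 0.5
#' @export
estimatePsi <- function(ic, sc, lenInc = 2, lenSkip = 1) {
  if (any(lenInc < 1) || any(lenSkip < 1))
    stop("effective lengths must be >= 1")
  if (any(ic < 0) || any(sc < 0)) stop("read counts must be nonnegative")
  num <- ic / lenInc
  den <- num + sc / lenSkip
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Length-normalization from inclusion level to read proportion
#'
#' Maps the exon-inclusion level \eqn{\psi} to the expected proportion of
#' inclusion-isoform reads,
#' \deqn{f(\psi) = \frac{l_I \psi}{l_I \psi + l_S (1 - \psi)},}
#' the inverse of the mapping used by [estimatePsi()].  This is the
#' success probability of the binomial read model.
#'
#' @param psi inclusion levels in \[0, 1\] (vectorized).
#' @param lenInc,lenSkip effective lengths.
#' @return read proportions in \[0, 1\].
#' @examples
#' lengthNormalization(0.5, 2, 1)  # 2/3
#' @export
lengthNormalization <- function(psi, lenInc = 2, lenSkip = 1) {
  if (any(psi < 0 | psi > 1, na.rm = TRUE))
    stop("psi must lie in [0, 1]")
  if (any(lenInc < 1) || any(lenSkip < 1))
    stop("effective lengths must be >= 1")
  lenInc * psi / (lenInc * psi + lenSkip * (1 - psi))
}

#' Read a patient survival table
#'
#' Expects a tab-separated file with a header and (by default) columns
#' `patient_id`, `time` and `event`; other column names can be mapped via
#' `dialect`.
#'
#' @param path path to the TSV file.
#' @param dialect optional named character vector remapping any of
#'   `id`, `time`, `event` to the column names used in the file, e.g.
#'   `c(event = "status")`.
#' @return a `data.frame` with columns `patient_id`, `time`, `event`,
#'   row order preserved.
#' @export
readSurvivalTable <- function(path, dialect = NULL) {
  cols <- c(id = "patient_id", time = "time", event = "event")
  if (!is.null(dialect)) cols[names(dialect)] <- dialect
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  missing <- setdiff(unname(cols), names(tab))
  if (length(missing))
    stop("survival table is missing column(s): ",
         paste(missing, collapse = ", "))
  out <- data.frame(patient_id = as.character(tab[[cols["id"]]]),
                    time = as.numeric(tab[[cols["time"]]]),
                    event = as.numeric(tab[[cols["event"]]]),
                    stringsAsFactors = FALSE)
  bad <- which(!is.finite(out$time) | out$time <= 0)
  if (length(bad))
    stop("nonpositive or missing follow-up time in row(s): ",
         paste(bad, collapse = ", "))
  bad <- which(!out$event %in% c(0, 1))
  if (length(bad))
    stop("event indicator not 0/1 in row(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(out$patient_id))
    stop("duplicated patient_id: ",
         paste(unique(out$patient_id[duplicated(out$patient_id)]),
               collapse = ", "))
  out
}

#' Read an exon-skipping junction-count table
#'
#' Expects a tab-separated file with one row per exon and columns
#' `exon_id`, `l_inc`, `l_skip`, then paired `<patient>_IC` and
#' `<patient>_SC` columns.
#'
#' @param path path to the TSV file.
#' @return a list with integer matrices `inclusion` and `skipping`
#'   (exons x patients) and numeric vectors `lenInc`, `lenSkip`.
#' @export
readCountsTable <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("exon_id", "l_inc", "l_skip")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("counts table is missing column(s): ",
         paste(missing, collapse = ", "))
  icCols <- grep("_IC$", names(tab), value = TRUE)
  scCols <- grep("_SC$", names(tab), value = TRUE)
  patients <- sub("_IC$", "", icCols)
  if (!setequal(patients, sub("_SC$", "", scCols)))
    stop("IC/SC columns are not paired per patient")
  scCols <- paste0(patients, "_SC")
  exonId <- as.character(tab$exon_id)
  parse <- function(colnames, kind) {
    m <- matrix(NA_real_, nrow(tab), length(patients),
                dimnames = list(exonId, patients))
    for (j in seq_along(colnames)) {
      v <- tab[[colnames[j]]]
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(!is.finite(vn) | vn < 0 | vn != round(vn))
      if (length(bad))
        stop(sprintf("invalid %s count for exon '%s', patient '%s'",
                     kind, exonId[bad[1]], patients[j]))
      m[, j] <- vn
    }
    storage.mode(m) <- "integer"
    m
  }
  list(inclusion = parse(icCols, "inclusion"),
       skipping = parse(scCols, "skipping"),
       lenInc = as.numeric(tab$l_inc), lenSkip = as.numeric(tab$l_skip))
}

#' Read counts and survival tables and join them into a dataset
#'
#' Patients present in only one of the two tables are dropped with a
#' warning; the analysis cohort is the inner join on patient identifier.
#'
#' @param countsPath,survivalPath paths to the two TSV files.
#' @param dialect passed to [readSurvivalTable()].
#' @return a [SpliceSurvDataSet-class].
#' @export
readSpliceSurvDataSet <- function(countsPath, survivalPath, dialect = NULL) {
  counts <- readCountsTable(countsPath)
  surv <- readSurvivalTable(survivalPath, dialect = dialect)
  shared <- intersect(colnames(counts$inclusion), surv$patient_id)
  dropC <- setdiff(colnames(counts$inclusion), shared)
  dropS <- setdiff(surv$patient_id, shared)
  if (length(dropC))
    warning(length(dropC), " patient(s) in counts but not in survival ",
            "table dropped: ", paste(utils::head(dropC, 5), collapse = ", "))
  if (length(dropS))
    warning(length(dropS), " patient(s) in survival table but not in ",
            "counts dropped: ", paste(utils::head(dropS, 5), collapse = ", "))
  if (!length(shared)) stop("no patients shared between the two tables")
  surv <- surv[match(shared, surv$patient_id), ]
  SpliceSurvDataSet(counts$inclusion[, shared, drop = FALSE],
                    counts$skipping[, shared, drop = FALSE],
                    time = surv$time, event = surv$event,
                    lenInc = counts$lenInc, lenSkip = counts$lenSkip)
}

.resultCols <- c("exon_id", "beta", "loglik_alt", "loglik_null",
                 "lrt", "pvalue", "fdr")

#' Write / read a per-exon results table
#'
#' The TSV has a stable column order (`exon_id`, `beta`, `loglik_alt`,
#' `loglik_null`, `lrt`, `pvalue`, `fdr`) and numbers are written with
#' enough digits to round-trip at 1e-10 relative precision.
#'
#' @param results a `data.frame`/`DataFrame` with the columns above
#'   (extra columns are dropped with a note).
#' @param path output path.
#' @export
writeResultsTable <- function(results, path) {
  results <- as.data.frame(results)
  missing <- setdiff(.resultCols, names(results))
  if (length(missing))
    stop("results are missing column(s): ", paste(missing, collapse = ", "))
  out <- results[, .resultCols, drop = FALSE]
  for (j in setdiff(.resultCols, "exon_id"))
    out[[j]] <- sprintf("%.15g", out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeResultsTable
#' @export
readResultsTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(.resultCols, names(tab))
  if (length(missing))
    stop("results table is missing column(s): ",
         paste(missing, collapse = ", "))
  tab$exon_id <- as.character(tab$exon_id)
  tab
}

#' Write a simulated (or real) cohort back to the TSV contract
#'
#' `writeCountsTable` writes the `exon_id, l_inc, l_skip, <patient>_IC,
#' <patient>_SC` layout read by [readCountsTable()]; `writeSurvivalTable`
#' writes `patient_id, time, event`.
#'
#' @param inclusion,skipping count matrices (exons x patients).
#' @param lenInc,lenSkip effective lengths, recycled over exons.
#' @param path output path.
#' @export
writeCountsTable <- function(inclusion, skipping, lenInc, lenSkip, path) {
  patients <- colnames(inclusion)
  out <- data.frame(exon_id = rownames(inclusion),
                    l_inc = rep_len(lenInc, nrow(inclusion)),
                    l_skip = rep_len(lenSkip, nrow(inclusion)),
                    check.names = FALSE)
  for (p in patients) {
    out[[paste0(p, "_IC")]] <- inclusion[, p]
    out[[paste0(p, "_SC")]] <- skipping[, p]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeCountsTable
#' @param patientId,time,event survival columns.
#' @export
writeSurvivalTable <- function(patientId, time, event, path) {
  utils::write.table(
    data.frame(patient_id = patientId, time = time, event = event),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
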