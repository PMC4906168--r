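#' Univariate screening of candidate survival predictors
#'
#' Each feature is tested one at a time against survival and kept when
#' its p-value is at or below `threshold` (default 0.01).  Splicing
#' features (a [SpliceSurvDataSet-class]) are screened with the
#' measurement-error model ([fitSplicingSurvival()]); plain numeric
#' feature matrices (clinical parameters, gene expression) are screened
#' with the single-covariate Cox fit ([coxFit()]).
#'
#' @param x a `SpliceSurvDataSet` or a features x patients numeric
#'   matrix.
#' @param time,event survival records (ignored for a
#'   `SpliceSurvDataSet`, which carries its own).
#' @param threshold p-value threshold in (0, 1\].
#' @param control a [survivControl()] (splicing screening only).
#' @return character vector of selected feature identifiers (possibly
#'   empty).
#' @export
setGeneric("univariateScreen",
           function(x, time = NULL, event = NULL, threshold = 0.01, ...)
             standardGeneric("univariateScreen"))

#' @rdname univariateScreen
#' @param ... passed on to methods.
setMethod("univariateScreen", "SpliceSurvDataSet",
          function(x, time = NULL, event = NULL, threshold = 0.01,
                   control = survivControl()) {
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  res <- fitSplicingSurvival(x, control = control)
  res$exon_id[res$pvalue <= threshold]
})

#' @rdname univariateScreen
setMethod("univariateScreen", "matrix",
          function(x, time = NULL, event = NULL, threshold = 0.01, ...) {
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  if (is.null(rownames(x)))
    rownames(x) <- paste0("feature", seq_len(nrow(x)))
  p <- vapply(seq_len(nrow(x)),
              function(i) coxFit(x[i, ], time, event)$pvalue, numeric(1))
  rownames(x)[p <= threshold]
})

#' Z-score features using training-set statistics only
#'
#' Each feature (row) is centred and scaled by its training mean and
#' standard deviation (n - 1 denominator); the same training statistics
#' are applied to the test matrix, so no test information leaks into the
#' scaling.  Features with zero training variance are dropped.
#'
#' @param train,test features x patients matrices sharing row names.
#' @return list with scaled `train` and `test` matrices and the names of
#'   `dropped` constant features.
#' @export
zscoreNormalize <- function(train, test) {
  m <- rowMeans(train)
  s <- apply(train, 1, stats::sd)
  keep <- is.finite(s) & s > 0
  dropped <- rownames(train)[!keep]
  if (length(dropped))
    message(length(dropped), " constant feature(s) dropped in z-scoring")
  list(train = (train[keep, , drop = FALSE] - m[keep]) / s[keep],
       test = (test[keep, , drop = FALSE] - m[keep]) / s[keep],
       dropped = dropped)
}

#' L1-penalized Cox regression risk model
#'
#' Fits a lasso-penalized Cox model over the selected predictors; the
#' penalty is chosen by internal k-fold cross-validated partial
#' likelihood over a 50-point log grid unless given explicitly.  With
#' one predictor the unpenalized single-covariate fit is used; with no
#' predictors a null model (constant risk score) is returned with a
#' warning.
#'
#' @param x patients x features design matrix.
#' @param time,event training survival records.
#' @param penalty optional fixed penalty value; `NULL` (default) selects
#'   by internal cross-validation.
#' @param nfolds,nlambda internal cross-validation folds and grid size.
#' @return list with `coef` (named coefficient vector over `colnames(x)`)
#'   and `penalty`; score new data with [riskScore()].
#' @export
fitPenalizedCox <- function(x, time, event, penalty = NULL, nfolds = 5L,
                            nlambda = 50L) {
  if (sum(event) < 2) stop("need at least 2 events to fit")
  p <- ncol(x)
  if (is.null(colnames(x)) && p > 0)
    colnames(x) <- paste0("feature", seq_len(p))
  if (p == 0L) {
    warning("no predictors: returning null model")
    return(structure(list(coef = numeric(0), penalty = NA_real_),
                     class = "penalizedCox"))
  }
  if (p == 1L) {
    fit <- coxFit(x[, 1], time, event)
    cf <- stats::setNames(fit$beta, colnames(x))
    return(structure(list(coef = cf, penalty = 0), class = "penalizedCox"))
  }
  y <- survival::Surv(time, event)
  if (is.null(penalty)) {
    cv <- glmnet::cv.glmnet(x, y, family = "cox", alpha = 1,
                            nfolds = nfolds, nlambda = nlambda,
                            standardize = FALSE)
    penalty <- cv$lambda.min
    fit <- cv$glmnet.fit
  } else {
    # a short decreasing path ending exactly at the requested penalty
    # keeps the warm-started coordinate descent accurate there
    grid <- sort(unique(c(max(penalty, 1e-8) * 2^(8:0), penalty)),
                 decreasing = TRUE)
    fit <- glmnet::glmnet(x, y, family = "cox", alpha = 1,
                          lambda = grid, thresh = 1e-12,
                          standardize = FALSE)
  }
  cf <- as.numeric(stats::coef(fit, s = penalty, exact = FALSE))
  structure(list(coef = stats::setNames(cf, colnames(x)),
                 penalty = penalty), class = "penalizedCox")
}

#' Linear risk score of a penalized Cox model
#'
#' @param model a model from [fitPenalizedCox()].
#' @param x patients x features matrix containing the model's features.
#' @export
riskScore <- function(model, x) {
  if (!length(model$coef)) return(rep(0, nrow(x)))
  as.numeric(x[, names(model$coef), drop = FALSE] %*% model$coef)
}

# assemble the patients x features design for one model class set.
# Screening and scaling statistics come from the training patients only
# (unless screenFullCohort, a deliberately flagged leaky mode).
.buildDesign <- function(classes, sds, features, trainIdx, threshold,
                         control, screenFullCohort) {
  time <- survivalTimes(sds)
  event <- eventStatus(sds)
  n <- ncol(sds)
  blocksTrain <- list(); blocksTest <- list()
  testIdx <- setdiff(seq_len(n), trainIdx)
  for (cl in classes) {
    if (cl == "splicing") {
      scr <- if (screenFullCohort) sds else sds[, trainIdx]
      sel <- univariateScreen(scr, threshold = threshold,
                              control = control)
      if (!length(sel)) next
      psi <- psiValues(sds)[sel, , drop = FALSE]
      # impute missing PSI (zero-read patients) with the training mean
      trMean <- rowMeans(psi[, trainIdx, drop = FALSE], na.rm = TRUE)
      trMean[!is.finite(trMean)] <- 0.5
      for (i in seq_len(nrow(psi)))
        psi[i, !is.finite(psi[i, ])] <- trMean[i]
      z <- zscoreNormalize(psi[, trainIdx, drop = FALSE],
                           psi[, testIdx, drop = FALSE])
      blocksTrain[[cl]] <- z$train; blocksTest[[cl]] <- z$test
    } else {
      mat <- features[[cl]]
      if (is.null(mat)) stop("no feature table supplied for class ", cl)
      scrIdx <- if (screenFullCohort) seq_len(n) else trainIdx
      sel <- univariateScreen(mat[, scrIdx, drop = FALSE],
                              time[scrIdx], event[scrIdx],
                              threshold = threshold)
      if (!length(sel)) next
      sub <- mat[sel, , drop = FALSE]
      if (cl == "clinical") {
        blocksTrain[[cl]] <- sub[, trainIdx, drop = FALSE]
        blocksTest[[cl]] <- sub[, testIdx, drop = FALSE]
      } else {
        z <- zscoreNormalize(sub[, trainIdx, drop = FALSE],
                             sub[, testIdx, drop = FALSE])
        blocksTrain[[cl]] <- z$train; blocksTest[[cl]] <- z$test
      }
    }
  }
  if (!length(blocksTrain))
    return(list(train = matrix(0, length(trainIdx), 0),
                test = matrix(0, n - length(trainIdx), 0)))
  list(train = t(do.call(rbind, blocksTrain)),
       test = t(do.call(rbind, blocksTest)))
}

#' Monte Carlo cross-validation of survival predictors
#'
#' Repeated random-split cross-validation comparing predictor classes
#' (clinical parameters, gene expression, splicing) and their
#' combinations.  Per round: patients are split at random into training
#' and testing halves (identical splits across model classes, so rounds
#' are paired); candidate features are screened univariately on the
#' training half; molecular features are z-scored with training
#' statistics; an L1-penalized Cox model is fitted on the training half;
#' and Harrell's C-index of its risk score is computed on the held-out
#' half.  Rounds whose test half has fewer than 2 events are redrawn.
#'
#' @param sds a [SpliceSurvDataSet-class] providing the splicing counts
#'   and the survival outcome.
#' @param features named list of additional features x patients matrices
#'   (`clinical`, `gene`), columns aligned with `colnames(sds)`.
#' @param models named list of model definitions, each a character
#'   vector of classes among `"clinical"`, `"gene"`, `"splicing"`.
#' @param rounds number of cross-validation rounds.
#' @param split training fraction (default 0.5, two-fold).
#' @param seed RNG seed for the split sequence.
#' @param threshold univariate screening p-value threshold.
#' @param control a [survivControl()] for splicing screening.
#' @param screenFullCohort flagged leaky mode screening on the full
#'   cohort (for diagnosing selection bias only; default `FALSE`).
#' @param maxRetries redraw cap for rounds with too few test events.
#' @return a [CvReport-class].
#' @export
monteCarloCV <- function(sds, features = list(),
                         models = list(splicing = "splicing"),
                         rounds = 100L, split = 0.5, seed = 1L,
                         threshold = 0.01, control = survivControl(),
                         screenFullCohort = FALSE, maxRetries = 20L) {
  stopifnot(is(sds, "SpliceSurvDataSet"), rounds >= 1)
  if (screenFullCohort)
    warning("screening on the full cohort leaks test labels into ",
            "feature selection; use for diagnostics only")
  n <- ncol(sds)
  time <- survivalTimes(sds)
  event <- eventStatus(sds)
  if (is.null(names(models)))
    names(models) <- vapply(models, paste, character(1), collapse = "+")
  set.seed(seed)
  cidx <- matrix(NA_real_, rounds, length(models),
                 dimnames = list(NULL, names(models)))
  for (r in seq_len(rounds)) {
    trainIdx <- NULL
    for (try in seq_len(maxRetries)) {
      cand <- sample.int(n, round(split * n))
      testCand <- setdiff(seq_len(n), cand)
      if (sum(event[cand]) >= 2 && sum(event[testCand]) >= 2) {
        trainIdx <- cand
        break
      }
      message("round ", r, ": too few events in a fold, redrawing split")
    }
    if (is.null(trainIdx))
      stop("could not draw a split with enough events in both folds")
    testIdx <- setdiff(seq_len(n), trainIdx)
    for (m in names(models)) {
      des <- .buildDesign(models[[m]], sds, features, trainIdx,
                          threshold, control, screenFullCohort)
      model <- if (ncol(des$train) == 0L)
        structure(list(coef = numeric(0), penalty = NA_real_),
                  class = "penalizedCox")
      else
        fitPenalizedCox(des$train, time[trainIdx], event[trainIdx])
      sc <- riskScore(model, des$test)
      cidx[r, m] <- concordanceIndex(sc, time[testIdx], event[testIdx])
    }
  }
  new("CvReport", cindex = cidx, seed = as.integer(seed), split = split)
}

#' Paired comparison of two cross-validated models
#'
#' Two-sided Wilcoxon signed-rank test on the paired per-round
#' C-indexes of two models from the same [monteCarloCV()] report (the
#' splits are shared across models within a round, so rounds are
#' paired).
#'
#' @param report a [CvReport-class].
#' @param pair character vector of two model names.
#' @return the two-sided p-value.
#' @export
compareModels <- function(report, pair) {
  stopifnot(is(report, "CvReport"), length(pair) == 2L)
  if (!all(pair %in% colnames(report@cindex)))
    stop("unknown model name(s): ",
         paste(setdiff(pair, colnames(report@cindex)), collapse = ", "))
  d <- report@cindex[, pair[1]] - report@cindex[, pair[2]]
  if (all(d == 0)) return(1)
  suppressWarnings(
    stats::wilcox.test(report@cindex[, pair[1]],
                       report@cindex[, pair[2]],
                       paired = TRUE)$p.value)
}
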