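#' Empirical ROC summary from per-exon p-values
#'
#' Treats \eqn{-p} as the detection score against binary truth labels.
#' The AUC is computed by the trapezoid rule over the full empirical
#' curve; `tprAt` reports, for each requested false-positive-rate level,
#' the true-positive rate at the largest score threshold whose empirical
#' FPR does not exceed the level (step-function convention, no
#' interpolation).
#'
#' @param pvalues per-exon p-values (or any score where smaller means
#'   more significant).
#' @param labels binary truth labels (1 = alternative, 0 = null).
#' @param fprLevels FPR levels in (0, 1) at which to report the TPR.
#' @return list with `auc`, `tprAt` (named by level), and the full
#'   `curve` (data.frame of FPR/TPR).
#' @export
rocFromPvalues <- function(pvalues, labels, fprLevels = 0.05) {
  keep <- is.finite(pvalues) & !is.na(labels)
  pvalues <- pvalues[keep]; labels <- labels[keep]
  if (length(unique(labels)) < 2L)
    stop("both classes must be present in the truth labels")
  if (any(fprLevels <= 0 | fprLevels >= 1))
    stop("fprLevels must lie in (0, 1)")
  score <- -pvalues
  ord <- order(score, decreasing = TRUE)
  lab <- labels[ord]
  sc <- score[ord]
  # cumulative counts at the end of each tied-score block
  last <- rev(!duplicated(rev(sc)))
  tp <- cumsum(lab == 1)[last]
  fp <- cumsum(lab == 0)[last]
  tpr <- c(0, tp / sum(labels == 1))
  fpr <- c(0, fp / sum(labels == 0))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  tprAt <- vapply(fprLevels, function(lev) max(tpr[fpr <= lev]),
                  numeric(1))
  names(tprAt) <- as.character(fprLevels)
  list(auc = auc, tprAt = tprAt, curve = data.frame(fpr = fpr, tpr = tpr))
}

#' Harrell's concordance index
#'
#' The probability that, of a comparable patient pair, the patient with
#' the higher risk score fails first.  A pair is comparable when the
#' earlier time is an observed death (or, at tied times, exactly one of
#' the two died); pairs with equal times and both events are ignored.
#' Score ties count 0.5.
#'
#' @param scores per-patient risk scores (higher = predicted earlier
#'   death).
#' @param time,event survival records.
#' @return C-index in \[0, 1\].
#' @export
concordanceIndex <- function(scores, time, event) {
  keep <- is.finite(scores)
  scores <- scores[keep]; time <- time[keep]; event <- event[keep]
  n <- length(scores)
  if (n < 2L) stop("need at least two patients")
  dt <- outer(time, time, "<")
  dd <- matrix(event == 1, n, n)           # row patient died
  tie <- outer(time, time, "==")
  comparable <- (dt & dd) | (tie & dd & !t(dd))
  if (!any(comparable)) stop("no comparable pairs")
  ds <- outer(scores, scores, "-")
  conc <- sum(comparable & ds > 0) + 0.5 * sum(comparable & ds == 0)
  conc / sum(comparable)
}

#' Kaplan-Meier product-limit survival curve
#'
#' @param time,event survival records (right censoring).
#' @return data.frame with the distinct event times and the survival
#'   probability just after each (steps only at event times; the curve
#'   starts at 1).
#' @export
kaplanMeier <- function(time, event) {
  if (!length(time)) stop("empty cohort")
  ut <- sort(unique(time[event == 1]))
  if (!length(ut))
    return(data.frame(time = numeric(0), surv = numeric(0)))
  nrisk <- vapply(ut, function(x) sum(time >= x), numeric(1))
  d <- vapply(ut, function(x) sum(time == x & event == 1), numeric(1))
  data.frame(time = ut, surv = cumprod(1 - d / nrisk))
}

#' Exact two-means stratification of a 1-D feature
#'
#' Solves k-means with k = 2 in one dimension exactly: the optimal
#' clusters are intervals of the sorted values, so the split minimizing
#' the within-group sum of squares is found by enumerating all sorted
#' splits (splits between tied values are not valid partitions and are
#' skipped).  Deterministic, unlike seeded Lloyd iterations.
#'
#' @param values per-patient values (e.g. one exon's inclusion levels).
#' @return integer labels: 2 for the higher-mean group, 1 for the lower.
#' @export
twoMeansStratify <- function(values) {
  n <- length(values)
  if (n < 2L || length(unique(values)) < 2L)
    stop("need at least two distinct values")
  s <- sort(values)
  cs <- cumsum(s)
  css <- cumsum(s^2)
  k <- seq_len(n - 1L)
  sse <- (css[k] - cs[k]^2 / k) +
    (css[n] - css[k] - (cs[n] - cs[k])^2 / (n - k))
  valid <- s[k] < s[k + 1L]
  kBest <- k[valid][which.min(sse[valid])]
  cut <- (s[kBest] + s[kBest + 1L]) / 2
  ifelse(values > cut, 2L, 1L)
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank chi-squared test with one degree of
#' freedom, with the hypergeometric variance at each event time.
#'
#' @param groups two-level group labels.
#' @param time,event survival records.
#' @return list with `chisq`, `pvalue` and the observed/expected event
#'   counts per group.
#' @export
logrankTest <- function(groups, time, event) {
  g <- as.integer(factor(groups))
  if (length(unique(g)) != 2L)
    stop("exactly two nonempty groups are required")
  ut <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ut) {
    at1 <- time >= t & g == 1L
    at <- time >= t
    n1 <- sum(at1); nt <- sum(at)
    d1 <- sum(time == t & event == 1 & g == 1L)
    dt <- sum(time == t & event == 1)
    O <- O + d1
    E <- E + dt * n1 / nt
    if (nt > 1)
      V <- V + dt * (n1 / nt) * (1 - n1 / nt) * (nt - dt) / (nt - 1)
  }
  chisq <- if (V > 0) (O - E)^2 / V else 0
  list(chisq = chisq,
       pvalue = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       observed = O, expected = E)
}
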