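#' Nelson-Aalen estimator of the cumulative baseline hazard
#'
#' At each distinct event time \eqn{t_i} with \eqn{d_i} deaths among
#' \eqn{n_i} patients at risk, the cumulative hazard increases by
#' \eqn{d_i/n_i} (Breslow convention for ties: all tied deaths share the
#' same risk set).  Censored patients contribute to the risk sets only.
#'
#' @param time positive follow-up times.
#' @param event event indicators (1 = death, 0 = censored).
#' @return a [BaselineHazard-class] step function.
#' @examples
#' bh <- nelsonAalen(c(1, 2, 3), c(1, 1, 1))
#' cumHazardAt(bh, 2.5)  # 1/3 + 1/2
#' @export
nelsonAalen <- function(time, event) {
  if (length(time) != length(event) || !length(time))
    stop("time and event must be nonempty and of equal length")
  if (any(!is.finite(time)) || any(time <= 0))
    stop("follow-up times must be positive")
  if (sum(event == 1) == 0)
    stop("baseline hazard undefined: no events observed")
  ut <- sort(unique(time[event == 1]))
  nrisk <- vapply(ut, function(x) sum(time >= x), numeric(1))
  d <- vapply(ut, function(x) sum(time == x & event == 1), numeric(1))
  inc <- d / nrisk
  new("BaselineHazard", type = "step", eventTimes = ut, increments = inc,
      cumHazard = cumsum(inc), rate = NA_real_)
}

#' Constant-rate baseline hazard
#'
#' \eqn{\Lambda_0(t) = \rho t}; used for fully synthetic cohorts.
#'
#' @param rate positive hazard rate.
#' @export
constantHazard <- function(rate = 1) {
  new("BaselineHazard", type = "constant", eventTimes = numeric(0),
      increments = numeric(0), cumHazard = numeric(0), rate = rate)
}

#' Evaluate a baseline hazard
#'
#' `cumHazardAt` evaluates the cumulative hazard \eqn{\Lambda_0(t)} (for a
#' step baseline: the value at the largest event time \eqn{\le t}, 0
#' before the first event).  `hazardIncrementAt` returns the hazard mass
#' used in the event term of the likelihood: the Nelson-Aalen increment
#' \eqn{d_i/n_i} at the largest event time \eqn{\le t} (the first
#' increment when `t` precedes all event times), or the rate for a
#' constant baseline.
#'
#' @param object a [BaselineHazard-class].
#' @param t evaluation times (vectorized).
#' @name cumHazardAt
NULL

setMethod("cumHazardAt", "BaselineHazard", function(object, t) {
  if (object@type == "constant") return(object@rate * t)
  idx <- findInterval(t, object@eventTimes)
  c(0, object@cumHazard)[idx + 1L]
})

setMethod("hazardIncrementAt", "BaselineHazard", function(object, t) {
  if (object@type == "constant") return(rep(object@rate, length(t)))
  idx <- pmax(findInterval(t, object@eventTimes), 1L)
  object@increments[idx]
})

# inverse of the cumulative hazard, used by the simulator's
# inverse-transform sampling.  For a step baseline the inverse jumps to
# the smallest event time whose cumulative hazard reaches the target;
# targets beyond the support are mapped to the largest event time and
# flagged (administrative censoring at the support edge).
.invCumHazard <- function(baseline, target) {
  if (baseline@type == "constant")
    return(list(time = target / baseline@rate,
                admin = rep(FALSE, length(target))))
  ch <- baseline@cumHazard
  tt <- baseline@eventTimes
  admin <- target > ch[length(ch)]
  idx <- findInterval(target, ch, left.open = TRUE) + 1L
  idx[admin] <- length(tt)
  list(time = tt[idx], admin = admin)
}
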