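#' Construct an individual survival curve
#'
#' A survival curve is a non-increasing function `P(D >= t)` starting at 1
#' at `t = 0`. The constructor validates those invariants (with a small
#' numerical slack on monotonicity).
#'
#' @param time Non-negative, strictly increasing time points; if the first
#'   point is not 0 a leading (0, 1) point is added.
#' @param surv Survival probabilities at `time`, in `[0, 1]`.
#' @return An object of class `survival_curve`.
#' @export
survival_curve <- function(time, surv) {
  if (length(time) != length(surv)) stop("time and surv lengths differ")
  if (any(diff(time) <= 0)) stop("time points must be strictly increasing")
  if (any(time < 0)) stop("time points must be non-negative")
  if (time[1] > 0) {
    time <- c(0, time)
    surv <- c(1, surv)
  }
  if (abs(surv[1] - 1) > 1e-8) stop("survival at t = 0 must be 1")
  surv[1] <- 1
  if (any(surv < -1e-10) || any(surv > 1 + 1e-10)) stop("survival values must lie in [0, 1]")
  surv <- pmin(pmax(surv, 0), 1)
  if (any(diff(surv) > 1e-8)) stop("survival curve must be non-increasing")
  surv <- cummin(surv)
  structure(list(time = time, surv = surv), class = "survival_curve")
}

#' Evaluate a survival curve at arbitrary times
#'
#' Linear interpolation between curve points; beyond the last point the
#' curve is held at its final value.
#'
#' @param curve A `survival_curve`.
#' @param t Times at which to evaluate.
#' @return Numeric vector of probabilities.
#' @export
eval_curve <- function(curve, t) {
  stopifnot(inherits(curve, "survival_curve"))
  if (length(curve$time) == 1) return(rep(curve$surv, length(t)))
  stats::approx(curve$time, curve$surv, xout = t, rule = 2)$y
}

#' Risk score from a survival curve
#'
#' The negative of the expected survival time implied by the curve,
#' approximated as the trapezoidal area under the curve up to its last
#' point. Higher risk means predicted earlier death.
#'
#' @param curve A `survival_curve`.
#' @return A single number (the risk score).
#' @export
risk_from_curve <- function(curve) {
  stopifnot(inherits(curve, "survival_curve"))
  t <- curve$time
  s <- curve$surv
  if (length(t) == 1) return(0)
  -sum(diff(t) * (s[-length(s)] + s[-1]) / 2)
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("Survival curve: %d points, t in [%g, %g], final P = %.4f\n",
              length(x$time), min(x$time), max(x$time), x$surv[length(x$surv)]))
  invisible(x)
}

#' @export
plot.survival_curve <- function(x, ..., xlab = "Time (days)",
                                ylab = "P(D >= t)", type = "s") {
  graphics::plot(x$time, x$surv, type = type, ylim = c(0, 1),
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}
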