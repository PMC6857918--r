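#' Concordance index for right-censored survival data
#'
#' The fraction of comparable ordered pairs whose predicted risk ordering
#' matches the observed death ordering. An ordered pair (i, j) with patient
#' i dying first is comparable when both patients are uncensored with
#' different times, or when i is uncensored and j's censoring time exceeds
#' i's death time. A pair is counted as correct when `risk[i] > risk[j]`
#' (strict); tied risks score 0 by default, or 0.5 with
#' `ties = "half"` for comparison with other software.
#'
#' @param risk Numeric risk scores (higher = predicted earlier death).
#' @param labels A `survival_labels` object.
#' @param ties `"strict"` (tied risks count 0) or `"half"` (count 0.5).
#' @return Concordance in `[0, 1]`.
#' @export
concordance_index <- function(risk, labels, ties = c("strict", "half")) {
  ties <- match.arg(ties)
  stopifnot(inherits(labels, "survival_labels"))
  if (length(risk) != length(labels$time)) stop("risk and labels are misaligned")
  time <- labels$time
  event <- labels$event
  n <- length(time)
  # comparable[i, j]: i dies first
  dies_first <- outer(time, time, "<")
  both_unc <- outer(event == 1L, event == 1L, "&")
  i_unc_j_cens <- outer(event == 1L, event == 0L, "&")
  comparable <- (both_unc | i_unc_j_cens) & dies_first
  n_pairs <- sum(comparable)
  if (n_pairs == 0) stop("no comparable pairs; concordance is undefined")
  correct <- outer(risk, risk, ">") & comparable
  ci <- sum(correct) / n_pairs
  if (ties == "half") {
    tied <- outer(risk, risk, "==") & comparable
    ci <- ci + 0.5 * sum(tied) / n_pairs
  }
  ci
}

#' D-calibration of individual survival distributions
#'
#' Tests whether predicted survival probabilities at observed death times
#' are uniform. For each uncensored patient, the predicted
#' `P(D >= d_i)` is read off that patient's own curve (linear interpolation
#' between grid points; held beyond the last point) and binned into `G`
#' equal-width probability bins. Under a calibrated model each bin should
#' hold `N/G` patients; departure is measured by a Hosmer-Lemeshow
#' chi-square statistic with `G - 2` degrees of freedom,
#' `HL = sum_g (E_g - N/G)^2 / (N * pi_g * (1 - pi_g))` with `pi_g = 1/G`.
#' Censored patients are excluded.
#'
#' @param curves List of `survival_curve` objects, one per patient (aligned
#'   with `labels`).
#' @param labels A `survival_labels` object.
#' @param n_bins Number of probability bins G (>= 3; default 20).
#' @return An object of class `dcalibration`: `statistic`, `df`, `p_value`,
#'   `table` (per-bin observed/expected), `probabilities` (the per-patient
#'   predicted values), `n`.
#' @export
d_calibration <- function(curves, labels, n_bins = 20) {
  stopifnot(inherits(labels, "survival_labels"))
  if (n_bins < 3) stop("need at least 3 bins (df = G - 2 >= 1)")
  if (inherits(curves, "survival_curve")) curves <- list(curves)
  if (length(curves) != length(labels$time)) stop("curves and labels are misaligned")
  unc <- which(labels$event == 1L)
  if (length(unc) == 0) stop("no uncensored patients; D-calibration is undefined")
  probs <- vapply(unc, function(i) eval_curve(curves[[i]], labels$time[i]), numeric(1))
  hl_from_probs(probs, n_bins = n_bins)
}

#' Hosmer-Lemeshow uniformity statistic on probability values
#'
#' The binning/statistic core of [d_calibration()], usable directly on a
#' vector of predicted probabilities at death times.
#'
#' @param probs Values in `[0, 1]`.
#' @param n_bins Number of equal-width bins G.
#' @return A `dcalibration` object.
#' @export
hl_from_probs <- function(probs, n_bins = 20) {
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  n <- length(probs)
  # bins [0, 1/G), ..., [(G-1)/G, 1]
  bin <- pmin(floor(probs * n_bins), n_bins - 1) + 1
  observed <- tabulate(bin, nbins = n_bins)
  expected <- n / n_bins
  pi_g <- 1 / n_bins
  statistic <- sum((observed - expected)^2) / (n * pi_g * (1 - pi_g))
  df <- n_bins - 2
  p <- stats::pchisq(statistic, df = df, lower.tail = FALSE)
  tab <- data.frame(
    bin = sprintf("[%.2f,%.2f%s", (seq_len(n_bins) - 1) / n_bins,
                  seq_len(n_bins) / n_bins,
                  c(rep(")", n_bins - 1), "]")),
    observed = observed, expected = expected, proportion = pi_g)
  structure(list(statistic = statistic, df = df, p_value = p, table = tab,
                 probabilities = probs, n = n, n_bins = n_bins),
            class = "dcalibration")
}

#' @export
print.dcalibration <- function(x, ...) {
  cat(sprintf("D-calibration (Hosmer-Lemeshow): HL = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  cat(sprintf("  %d uncensored patients in %d bins; %s at the 0.05 level\n",
              x$n, x$n_bins,
              if (x$p_value > 0.05) "calibrated" else "NOT calibrated"))
  invisible(x)
}
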