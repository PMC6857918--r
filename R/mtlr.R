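#' Build the MTLR time grid
#'
#' `m` defaults to `floor(sqrt(n))`; the grid points sit at `m` evenly
#' spaced quantiles of the observed (event or censoring) times,
#' deduplicated. Non-positive points are dropped (the grid starts after the
#' implicit `t0 = 0`).
#'
#' @param labels A `survival_labels` object.
#' @param m Optional number of grid points.
#' @return Strictly increasing numeric vector of time points.
#' @export
build_time_grid <- function(labels, m = NULL) {
  stopifnot(inherits(labels, "survival_labels"))
  n <- length(labels$time)
  if (is.null(m)) m <- max(1L, floor(sqrt(n)))
  probs <- seq_len(m) / (m + 1)
  grid <- unname(stats::quantile(labels$time, probs = probs))
  grid <- unique(grid[grid > 0])
  if (length(grid) < m) {
    warning("time grid shrank to ", length(grid), " distinct positive points (requested ", m, ")")
  }
  if (length(grid) == 0) stop("no positive time points available for the grid")
  grid
}

# Interval bookkeeping. Intervals are [t_k, t_{k+1}) for k = 0..m with
# t_0 = 0 and t_{m+1} = Inf. The label vector y(d) has y_j(d) = 1 iff
# t_j >= d, so an uncensored death at d selects the single interval
# k(d) = #{j : t_j < d}; a patient censored at c is consistent with every
# interval k >= #{j : t_j <= c}.
.mtlr_event_interval <- function(d, grid) vapply(d, function(v) sum(grid < v), integer(1))
.mtlr_censor_lower <- function(c0, grid) vapply(c0, function(v) sum(grid <= v), integer(1))

# Scores: theta is m x (r+1), columns = features then bias.
# F[i, j] = f_W(x_i, k = j - 1) = sum_{l >= j} (w_l' x_i + b_l), j = 1..m+1.
.mtlr_scores <- function(theta, x) {
  s <- cbind(x, 1) %*% t(theta)            # n x m
  m <- ncol(s)
  f <- cbind(s, 0)
  for (j in m:1) f[, j] <- f[, j + 1] + s[, j]
  f
}

.row_logsumexp <- function(f) {
  mx <- apply(f, 1, max)
  mx + log(rowSums(exp(f - mx)))
}

#' MTLR objective (negative penalized log-likelihood)
#'
#' The minimized objective: `C/2 * sum_j ||w_j||^2` (biases unpenalized)
#' minus the log-likelihood. Uncensored patients contribute the score of
#' their death interval; a patient censored at `c` contributes the
#' log-sum over every label vector consistent with death after `c`
#' (exact marginalization), both normalized by the same partition function.
#'
#' @param theta Parameter matrix, `m x (r+1)` (last column = biases), or a
#'   vector that will be reshaped.
#' @param x Feature matrix (patients x r).
#' @param labels A `survival_labels` object.
#' @param grid Time grid from [build_time_grid()].
#' @param C Regularization weight.
#' @return The objective value, with the analytic gradient (same shape as
#'   `theta`) attached as attribute `"gradient"`.
#' @export
mtlr_objective <- function(theta, x, labels, grid, C = 1) {
  x <- as.matrix(x)
  m <- length(grid)
  r <- ncol(x)
  theta <- matrix(theta, nrow = m, ncol = r + 1)
  f <- .mtlr_scores(theta, x)                       # n x (m+1)
  logz <- .row_logsumexp(f)
  n <- nrow(x)
  kd <- .mtlr_event_interval(labels$time, grid)
  kc <- .mtlr_censor_lower(labels$time, grid)
  event <- labels$event == 1L
  loglik_terms <- numeric(n)
  # responsibilities under the restricted (numerator) distribution
  P_full <- exp(f - logz)                            # n x (m+1), rows sum to 1
  P_num <- matrix(0, n, m + 1)
  if (any(event)) {
    idx <- cbind(which(event), kd[event] + 1L)
    loglik_terms[event] <- f[idx] - logz[event]
    P_num[idx] <- 1
  }
  if (any(!event)) {
    for (i in which(!event)) {
      cols <- (kc[i] + 1L):(m + 1L)
      lse <- .row_logsumexp(f[i, cols, drop = FALSE])
      loglik_terms[i] <- lse - logz[i]
      P_num[i, cols] <- exp(f[i, cols] - lse)
    }
  }
  w <- theta[, seq_len(r), drop = FALSE]
  obj <- C / 2 * sum(w^2) - sum(loglik_terms)
  # d(-loglik)/d theta_j = sum_i (Pfull(k <= j-1) - Pnum(k <= j-1)) * [x_i, 1]
  cum_full <- t(apply(P_full, 1, cumsum))[, seq_len(m), drop = FALSE]
  cum_num <- t(apply(P_num, 1, cumsum))[, seq_len(m), drop = FALSE]
  Q <- cum_full - cum_num                            # n x m
  grad <- t(Q) %*% cbind(x, 1)
  grad[, seq_len(r)] <- grad[, seq_len(r)] + C * w
  attr(obj, "gradient") <- grad
  obj
}

#' Fit an MTLR individual survival distribution model
#'
#' Minimizes [mtlr_objective()] by BFGS with the analytic gradient, starting
#' from `W = 0` (the objective is convex, so the optimum is unique). The
#' regularization weight `C` is chosen from `c_grid` by event-stratified
#' internal cross-validation on concordance of the risk scores (negative
#' expected survival time); a single-element grid skips the search.
#'
#' @param x Feature matrix (patients x r).
#' @param labels A `survival_labels` object.
#' @param c_grid Candidate regularization weights.
#' @param grid Optional time grid; defaults to [build_time_grid()].
#' @param n_folds Folds for the C search.
#' @param seed Integer seed (fold assignment).
#' @param init Optional starting parameter matrix (for optimization checks).
#' @param max_iter BFGS iteration cap.
#' @return An object of class `mtlr_fit`: `theta` (m x (r+1)), `grid`, `C`,
#'   `feature_names`, `objective`, `convergence`, `cv` (C-search table or
#'   `NULL`).
#' @export
fit_mtlr <- function(x, labels, c_grid = c(0.01, 0.1, 1, 10), grid = NULL,
                     n_folds = 5, seed = 1, init = NULL, max_iter = 500) {
  stopifnot(inherits(labels, "survival_labels"))
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least two patients")
  if (length(c_grid) == 0) stop("c_grid must be nonempty")
  if (is.null(grid)) grid <- build_time_grid(labels)
  cv <- NULL
  C_best <- c_grid[1]
  if (length(c_grid) > 1) {
    folds <- .stratified_folds(labels$event, n_folds, seed)
    scores <- matrix(NA_real_, length(c_grid), n_folds)
    for (ci in seq_along(c_grid)) {
      for (f in seq_len(max(folds))) {
        te <- which(folds == f)
        tr <- setdiff(seq_len(nrow(x)), te)
        lbl_tr <- survival_labels(labels$time[tr], labels$event[tr])
        lbl_te <- survival_labels(labels$time[te], labels$event[te])
        fit_f <- .mtlr_solve(x[tr, , drop = FALSE], lbl_tr, grid, c_grid[ci],
                             init = NULL, max_iter = max_iter)
        risks <- vapply(te, function(i) {
          risk_from_curve(.mtlr_curve_theta(fit_f$theta, grid, x[i, ]))
        }, numeric(1))
        scores[ci, f] <- tryCatch(concordance_index(risks, lbl_te),
                                  error = function(e) NA_real_)
      }
    }
    mean_scores <- rowMeans(scores, na.rm = TRUE)
    C_best <- c_grid[which.max(mean_scores)]
    cv <- data.frame(C = c_grid, concordance = mean_scores)
  }
  sol <- .mtlr_solve(x, labels, grid, C_best, init = init, max_iter = max_iter)
  if (sol$convergence != 0) {
    warning("MTLR optimizer did not fully converge (code ", sol$convergence,
            ", final gradient norm ", format(sol$grad_norm), ")")
  }
  structure(list(theta = sol$theta, grid = grid, C = C_best,
                 feature_names = colnames(x), objective = sol$value,
                 grad_norm = sol$grad_norm, convergence = sol$convergence,
                 cv = cv, n = nrow(x)),
            class = "mtlr_fit")
}

.mtlr_solve <- function(x, labels, grid, C, init = NULL, max_iter = 500) {
  m <- length(grid)
  r <- ncol(x)
  theta0 <- if (is.null(init)) matrix(0, m, r + 1) else matrix(init, m, r + 1)
  fn <- function(par) as.numeric(mtlr_objective(par, x, labels, grid, C))
  gr <- function(par) as.numeric(attr(mtlr_objective(par, x, labels, grid, C), "gradient"))
  opt <- stats::optim(as.numeric(theta0), fn, gr, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-12))
  theta <- matrix(opt$par, m, r + 1)
  gnorm <- sqrt(sum(gr(opt$par)^2))
  list(theta = theta, value = opt$value, convergence = opt$convergence,
       grad_norm = gnorm)
}

.mtlr_curve_theta <- function(theta, grid, x_row) {
  f <- .mtlr_scores(theta, matrix(x_row, nrow = 1))
  pmf <- drop(exp(f - .row_logsumexp(f)))           # length m+1
  surv_at_grid <- rev(cumsum(rev(pmf)))[-1]         # P(D >= t_j), j = 1..m
  # the last interval [t_m, Inf) carries mass P(D >= t_m); the emitted curve
  # releases it over one further mean grid spacing so the distribution is
  # complete (ends at 0) and probability evaluation inverts exactly
  t_ext <- grid[length(grid)] + grid[length(grid)] / length(grid)
  survival_curve(c(0, grid, t_ext), c(1, surv_at_grid, 0))
}

#' Individual survival curve from a fitted MTLR model
#'
#' Normalizes the interval scores into a PMF over the `m + 1` intervals and
#' accumulates it in reverse, so the curve starts at exactly 1 at `t = 0`.
#'
#' @param model An `mtlr_fit`.
#' @param x A single feature vector or matrix of patients.
#' @return A `survival_curve`, or a list of them for a matrix input.
#' @export
mtlr_survival_curve <- function(model, x) {
  stopifnot(inherits(model, "mtlr_fit"))
  if (is.matrix(x) && nrow(x) > 1) {
    return(lapply(seq_len(nrow(x)), function(i) mtlr_survival_curve(model, x[i, ])))
  }
  x <- drop(as.matrix(x))
  if (length(x) != ncol(model$theta) - 1) {
    stop("feature vector has length ", length(x), "; model expects ",
         ncol(model$theta) - 1)
  }
  .mtlr_curve_theta(model$theta, model$grid, x)
}

#' Interval PMF implied by an MTLR model for one patient
#'
#' @param model An `mtlr_fit`.
#' @param x Feature vector.
#' @return Probabilities over the `m + 1` intervals (sums to 1).
#' @export
mtlr_interval_pmf <- function(model, x) {
  stopifnot(inherits(model, "mtlr_fit"))
  f <- .mtlr_scores(model$theta, matrix(drop(as.matrix(x)), nrow = 1))
  drop(exp(f - .row_logsumexp(f)))
}

#' @export
print.mtlr_fit <- function(x, ...) {
  cat(sprintf("MTLR fit: %d time points, %d features, C = %g\n",
              length(x$grid), ncol(x$theta) - 1, x$C))
  cat(sprintf("  objective %.4f, gradient norm %.2e\n", x$objective, x$grad_norm))
  invisible(x)
}

#' @export
coef.mtlr_fit <- function(object, ...) object$theta

#' @export
predict.mtlr_fit <- function(object, newdata, type = c("risk", "curve"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(x))) {
    x <- x[, object$feature_names, drop = FALSE]
  }
  curves <- lapply(seq_len(nrow(x)), function(i) mtlr_survival_curve(object, x[i, ]))
  if (type == "curve") {
    if (length(curves) == 1) curves[[1]] else curves
  } else {
    vapply(curves, risk_from_curve, numeric(1))
  }
}
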