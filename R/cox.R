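#' Cox partial log-likelihood
#'
#' The log partial likelihood of a coefficient vector: the sum over
#' uncensored patients of the linear predictor minus the log-sum of
#' exponentiated predictors over the risk set (all patients with follow-up
#' time at or after the event time). Tied event times share the full risk
#' set (Breslow convention).
#'
#' @param w Coefficient vector.
#' @param x Covariate matrix (patients x features).
#' @param labels A `survival_labels` object.
#' @return The log partial likelihood (0 when no events).
#' @export
cox_partial_loglik <- function(w, x, labels) {
  stopifnot(inherits(labels, "survival_labels"))
  x <- as.matrix(x)
  lp <- drop(x %*% w)
  m <- max(lp)
  events <- which(labels$event == 1L)
  if (length(events) == 0) return(0)
  ll <- 0
  for (i in events) {
    at_risk <- labels$time >= labels$time[i]
    ll <- ll + lp[i] - (m + log(sum(exp(lp[at_risk] - m))))
  }
  ll
}

# Pseudo-inverse Newton step: one-hot blocks (all levels encoded) and
# simplex-constrained loadings make the information matrix rank-deficient
# along directions the partial likelihood is flat in; the gradient has no
# component there, so the minimum-norm step is well defined.
.solve_psd <- function(H, g) {
  eg <- eigen(H, symmetric = TRUE)
  tol <- max(eg$values, 0) * 1e-10 + 1e-300
  inv <- ifelse(eg$values > tol, 1 / eg$values, 0)
  drop(eg$vectors %*% (inv * crossprod(eg$vectors, g)))
}

# Sorted-accumulation pass shared by the likelihood/score/information
# computation: O(n r^2) after an O(n log n) sort.
.cox_quantities <- function(w, x, time, event) {
  n <- nrow(x)
  r <- ncol(x)
  lp <- drop(x %*% w)
  shift <- max(lp)
  e <- exp(lp - shift)
  ord <- order(time, decreasing = TRUE)
  A <- 0
  B <- numeric(r)
  C <- matrix(0, r, r)
  ll <- 0
  grad <- numeric(r)
  info <- matrix(0, r, r)
  i <- 1
  while (i <= n) {
    t_i <- time[ord[i]]
    j <- i
    while (j <= n && time[ord[j]] == t_i) j <- j + 1
    block <- ord[i:(j - 1)]
    for (b in block) {         # enter the risk set (ties enter together)
      A <- A + e[b]
      B <- B + e[b] * x[b, ]
      C <- C + e[b] * tcrossprod(x[b, ])
    }
    for (b in block[event[block] == 1L]) {
      ll <- ll + (lp[b] - shift) - log(A)
      grad <- grad + x[b, ] - B / A
      info <- info + C / A - tcrossprod(B) / A^2
    }
    i <- j
  }
  list(loglik = ll, grad = grad, info = info, exp_lp = e * exp(shift), lp = lp)
}

#' Fit a Cox proportional hazards model (optionally ridge-penalized)
#'
#' Maximizes the log partial likelihood minus `lambda * ||w||^2` by Newton's
#' method from `w = 0`, with step halving, until the penalized gradient norm
#' falls below `tol`. Tied event times use the Breslow convention. The
#' Kalbfleisch-Prentice baseline survival function is fitted on the training
#' data so the model can emit individual survival curves.
#'
#' @param x Covariate matrix (patients x features).
#' @param labels A `survival_labels` object.
#' @param lambda Ridge weight (>= 0); the penalty is `lambda * ||w||^2`.
#' @param tol Gradient-norm convergence threshold.
#' @param max_iter Maximum Newton iterations.
#' @return An object of class `cox_fit`: `coefficients`, `lambda`, `se`,
#'   `vcov`, `loglik`, `baseline` (times + survival of the KP estimator),
#'   `feature_names`, `iterations`.
#' @export
fit_cox <- function(x, labels, lambda = 0, tol = 1e-8, max_iter = 100) {
  stopifnot(inherits(labels, "survival_labels"))
  x <- as.matrix(x)
  if (nrow(x) != length(labels$time)) stop("covariates and labels are misaligned")
  if (lambda < 0) stop("lambda must be >= 0")
  if (sum(labels$event) == 0 && lambda == 0) {
    # flat likelihood: any w is a maximizer; ridge selects 0, so does plain Cox by convention
    w <- numeric(ncol(x))
  } else {
    w <- numeric(ncol(x))
    obj <- function(w, q) q$loglik - lambda * sum(w^2)
    q <- .cox_quantities(w, x, labels$time, labels$event)
    f <- obj(w, q)
    for (it in seq_len(max_iter)) {
      g <- q$grad - 2 * lambda * w
      if (sqrt(sum(g^2)) < tol) break
      H <- q$info + diag(2 * lambda, ncol(x))
      step <- .solve_psd(H, g)
      sz <- 1
      repeat {
        w_new <- w + sz * step
        q_new <- .cox_quantities(w_new, x, labels$time, labels$event)
        f_new <- obj(w_new, q_new)
        if (is.finite(f_new) && f_new >= f - 1e-12) break
        sz <- sz / 2
        if (sz < 1e-10) break
      }
      if (sz < 1e-10) break
      w <- w_new; q <- q_new; f <- f_new
      if (lambda == 0 && (any(!is.finite(w)) || max(abs(w)) > 1e3)) {
        stop("Cox fit diverged (likely separable risk sets); refit with lambda > 0")
      }
    }
    g <- q$grad - 2 * lambda * w
    if (sqrt(sum(g^2)) >= max(tol, 1e-6)) {
      if (lambda == 0) stop("Cox fit did not converge (gradient norm ",
                            format(sqrt(sum(g^2))), "); consider lambda > 0")
      warning("Cox fit stopped with gradient norm ", format(sqrt(sum(g^2))))
    }
    # a monotone (separable) likelihood lets the coefficients run away while
    # the gradient still vanishes; on standardized features this scale is
    # far outside anything identifiable
    if (lambda == 0 && max(abs(w)) > 15) {
      stop("Cox fit diverged (monotone partial likelihood, likely separation); ",
           "refit with lambda > 0")
    }
  }
  q <- .cox_quantities(w, x, labels$time, labels$event)
  H <- q$info + diag(2 * lambda, ncol(x))
  vc <- tryCatch({
    eg <- eigen(H, symmetric = TRUE)
    tol <- max(eg$values, 0) * 1e-10 + 1e-300
    inv <- ifelse(eg$values > tol, 1 / eg$values, 0)
    eg$vectors %*% (inv * t(eg$vectors))
  }, error = function(e) matrix(NA_real_, ncol(x), ncol(x)))
  names(w) <- colnames(x)
  baseline <- .kp_baseline(q$exp_lp, labels$time, labels$event)
  structure(list(coefficients = w, lambda = lambda,
                 se = sqrt(pmax(diag(vc), 0)), vcov = vc,
                 loglik = q$loglik, baseline = baseline,
                 feature_names = colnames(x), n = nrow(x),
                 n_events = sum(labels$event)),
            class = "cox_fit")
}

# Kalbfleisch-Prentice baseline survival: at each distinct event time the
# multiplicative survival factor a solves
#   sum_{i in D} e_i / (1 - a^{e_i}) = sum_{k in R} e_k
# (closed form for a single event; root-finding for ties). At w = 0 this
# reduces exactly to the Kaplan-Meier estimator.
.kp_baseline <- function(exp_lp, time, event) {
  ev_times <- sort(unique(time[event == 1L]))
  if (length(ev_times) == 0) {
    return(list(time = numeric(0), surv = numeric(0)))
  }
  surv <- numeric(length(ev_times))
  s <- 1
  for (j in seq_along(ev_times)) {
    tj <- ev_times[j]
    D <- which(event == 1L & time == tj)
    R <- which(time >= tj)
    risk_sum <- sum(exp_lp[R])
    if (length(D) == 1) {
      ei <- exp_lp[D]
      base <- 1 - ei / risk_sum
      a <- if (base <= 0) 0 else base^(1 / ei)
    } else {
      eD <- exp_lp[D]
      fn <- function(a) sum(eD / (1 - a^eD)) - risk_sum
      # fn is decreasing in a on (0,1); fn(0+) = sum(eD) - risk_sum <= 0 possible
      lo <- 1e-12; hi <- 1 - 1e-12
      if (fn(lo) >= 0) {
        a <- 0
      } else {
        a <- stats::uniroot(fn, c(lo, hi), tol = 1e-12)$root
      }
    }
    s <- s * a
    surv[j] <- s
  }
  list(time = ev_times, surv = surv)
}

#' Individual survival curve from a fitted Cox model
#'
#' `S(t | x) = S0(t)^(exp(x'w))` with `S0` the Kalbfleisch-Prentice baseline
#' fitted on the training data.
#'
#' @param model A `cox_fit`.
#' @param x A single covariate vector or a matrix of patients.
#' @return A `survival_curve` (or a list of them for a matrix input).
#' @export
cox_survival_curve <- function(model, x) {
  stopifnot(inherits(model, "cox_fit"))
  if (is.null(model$baseline) || length(model$baseline$time) == 0) {
    stop("model has no fitted baseline (no events in training data)")
  }
  if (is.matrix(x) && nrow(x) > 1) {
    return(lapply(seq_len(nrow(x)), function(i) cox_survival_curve(model, x[i, ])))
  }
  x <- drop(as.matrix(x))
  lp <- sum(x * model$coefficients)
  s <- model$baseline$surv^exp(lp)
  survival_curve(c(0, model$baseline$time), c(1, s))
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional hazards fit (%s): %d patients, %d events\n",
              if (x$lambda > 0) sprintf("ridge lambda = %g", x$lambda) else "unpenalized",
              x$n, x$n_events))
  tab <- data.frame(coef = x$coefficients, `exp(coef)` = exp(x$coefficients),
                    se = x$se, check.names = FALSE)
  print(round(tab, 4))
  invisible(x)
}

#' @export
coef.cox_fit <- function(object, ...) object$coefficients

#' @export
predict.cox_fit <- function(object, newdata, type = c("risk", "lp", "curve"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(x))) {
    x <- x[, object$feature_names, drop = FALSE]
  }
  lp <- drop(x %*% object$coefficients)
  if (type == "lp" || type == "risk") return(lp)
  if (nrow(x) == 1) cox_survival_curve(object, x[1, ]) else cox_survival_curve(object, x)
}
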