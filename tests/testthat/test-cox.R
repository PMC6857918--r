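test_that("partial log-likelihood matches the exhaustive risk-set oracle", {
  set.seed(14)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    x <- matrix(rnorm(n * 2), n, 2)
    time <- runif(n, 1, 10)
    event <- rbinom(n, 1, 0.7)
    w <- rnorm(2)
    lbl <- survival_labels(time, event)
    expect_equal(cox_partial_loglik(w, x, lbl),
                 cox_loglik_oracle(w, x, time, event), tolerance = 1e-10)
  }
})

test_that("degenerate likelihood cases are exact", {
  x <- matrix(rnorm(8), 4, 2)
  all_cens <- survival_labels(c(3, 1, 4, 2), c(0, 0, 0, 0))
  expect_equal(cox_partial_loglik(c(1.3, -2), x, all_cens), 0)
  expect_equal(cox_partial_loglik(c(0, 0), x, all_cens), 0)
  # single uncensored patient with the latest time: risk set of one
  one <- survival_labels(c(1, 2, 3), c(0, 0, 1))
  x3 <- matrix(rnorm(6), 3, 2)
  expect_equal(cox_partial_loglik(c(2, 1), x3, one), 0, tolerance = 1e-12)
})

test_that("partial likelihood is invariant to shifting one covariate", {
  set.seed(15)
  n <- 12
  x <- matrix(rnorm(n * 2), n, 2)
  lbl <- random_labels(n, seed = 3)
  w <- c(0.7, -0.4)
  x_shift <- x
  x_shift[, 1] <- x_shift[, 1] + 5
  # shifting covariate 1 by a constant changes every linear predictor by the
  # same amount, which cancels in each risk-set ratio
  expect_equal(cox_partial_loglik(w, x, lbl), cox_partial_loglik(w, x_shift, lbl),
               tolerance = 1e-9)
})

test_that("ridge-penalized fit matches a 1-D golden-section oracle", {
  x <- matrix(c(0, 1, 0, 1, 1, 0), ncol = 1)
  lbl <- survival_labels(c(2, 5, 3, 9, 7, 4), c(1, 1, 0, 1, 1, 1))
  lambda <- 0.5
  fit <- fit_cox(x, lbl, lambda = lambda)
  # independent 1-D optimizer on the penalized objective
  obj <- function(w) cox_loglik_oracle(w, x, lbl$time, lbl$event) - lambda * w^2
  oracle <- stats::optimize(obj, c(-5, 5), maximum = TRUE, tol = 1e-10)$maximum
  expect_equal(unname(fit$coefficients), oracle, tolerance = 1e-4)
})

test_that("all-censored data with ridge gives zero coefficients", {
  x <- matrix(rnorm(10), 5, 2)
  lbl <- survival_labels(1:5, rep(0, 5))
  fit <- fit_cox(x, lbl, lambda = 1)
  expect_equal(unname(fit$coefficients), c(0, 0))
})

test_that("hazard ratios are reciprocal and time-free", {
  set.seed(16)
  x <- matrix(rnorm(40), 20, 2)
  lbl <- random_labels(20, seed = 5)
  fit <- fit_cox(x, lbl, lambda = 0.1)
  hr <- function(x1, x2) exp(sum((x1 - x2) * fit$coefficients))
  expect_equal(hr(x[1, ], x[2, ]) * hr(x[2, ], x[1, ]), 1, tolerance = 1e-12)
})

test_that("coefficients agree with an independent Cox implementation", {
  set.seed(17)
  n <- 80
  x <- matrix(rnorm(n * 3), n, 3)
  lbl <- random_labels(n, seed = 6)
  fit <- fit_cox(x, lbl, lambda = 0)
  ref <- survival::coxph(survival::Surv(lbl$time, lbl$event) ~ x,
                         ties = "breslow")
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$loglik, unname(ref$loglik[2]), tolerance = 1e-6)
})

test_that("two-group exponential simulation recovers the true log-hazard ratio", {
  set.seed(18)
  n <- 1000
  g <- rbinom(n, 1, 0.5)
  beta_true <- 0.7
  t_death <- rexp(n, 0.01 * exp(beta_true * g))
  cens <- rexp(n, 0.004)
  lbl <- survival_labels(pmin(t_death, cens), as.integer(t_death <= cens))
  fit <- fit_cox(matrix(g, ncol = 1), lbl, lambda = 0)
  expect_lt(abs(fit$coefficients[1] - beta_true), 3 * fit$se[1])
})

test_that("Kalbfleisch-Prentice baseline equals Kaplan-Meier at w = 0", {
  lbl <- random_labels(40, seed = 7)
  # w = 0 exactly: fit on a covariate with no effect, then force w to 0
  fit <- fit_cox(matrix(0, 40, 1), lbl, lambda = 1)
  expect_equal(unname(fit$coefficients), 0)
  km <- survival::survfit(survival::Surv(lbl$time, lbl$event) ~ 1)
  km_at <- summary(km, times = fit$baseline$time)$surv
  expect_equal(fit$baseline$surv, km_at, tolerance = 1e-10)
})

test_that("KP baseline handles tied event times like Kaplan-Meier at w = 0", {
  time <- c(1, 2, 2, 2, 3, 3, 4, 5, 5, 6)
  event <- c(1, 1, 1, 0, 1, 1, 0, 1, 1, 1)
  lbl <- survival_labels(time, event)
  fit <- fit_cox(matrix(0, 10, 1), lbl, lambda = 1)
  km <- survival::survfit(survival::Surv(time, event) ~ 1)
  km_at <- summary(km, times = fit$baseline$time)$surv
  expect_equal(fit$baseline$surv, km_at, tolerance = 1e-10)
})

test_that("individual Cox curves respect the proportional-hazards ordering", {
  set.seed(19)
  x <- matrix(rnorm(60), 30, 2)
  lbl <- random_labels(30, seed = 8)
  fit <- fit_cox(x, lbl, lambda = 0.05)
  # x with zero linear predictor reproduces the baseline
  x0 <- rep(0, 2)
  c0 <- cox_survival_curve(fit, x0)
  expect_equal(c0$surv[-1], fit$baseline$surv, tolerance = 1e-12)
  expect_equal(c0$surv[1], 1)
  # larger linear predictor -> pointwise lower curve
  direction <- fit$coefficients / sqrt(sum(fit$coefficients^2))
  hi <- cox_survival_curve(fit, 2 * direction)
  expect_true(all(hi$surv <= c0$surv + 1e-12))
  expect_true(all(diff(hi$surv) <= 1e-12))
})

test_that("separation without regularization is reported as an error", {
  # perfectly separated risk sets: the earliest deaths all have the largest x
  x <- matrix(c(5, 4, 3, 2, 1, 0), ncol = 1)
  lbl <- survival_labels(1:6, rep(1, 6))
  expect_error(fit_cox(x, lbl, lambda = 0), "lambda")
  fit <- fit_cox(x, lbl, lambda = 0.5)
  expect_true(is.finite(fit$coefficients[1]))
})
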