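test_that("the time grid follows the square-root rule and quantile placement", {
  lbl <- random_labels(100, seed = 1)
  grid <- build_time_grid(lbl)
  expect_length(grid, 10)                        # floor(sqrt(100))
  # quantile oracle: m = 4 over times 1..100 -> 20/40/60/80% quantiles
  lbl2 <- survival_labels(1:100, rep(1, 100))
  g4 <- build_time_grid(lbl2, m = 4)
  expect_equal(g4, unname(stats::quantile(1:100, c(0.2, 0.4, 0.6, 0.8))))
  # identical times collapse to a single point with a warning
  lbl3 <- survival_labels(rep(7, 9), rep(1, 9))
  expect_warning(g1 <- build_time_grid(lbl3), "shrank")
  expect_equal(g1, 7)
})

test_that("W = 0 gives a uniform interval PMF and a curve starting at 1", {
  lbl <- random_labels(30, seed = 2)
  grid <- build_time_grid(lbl, m = 3)
  model <- structure(list(theta = matrix(0, 3, 3), grid = grid,
                          C = 1, feature_names = NULL), class = "mtlr_fit")
  pmf <- mtlr_interval_pmf(model, c(1, 5))
  expect_equal(pmf, rep(1 / 4, 4), tolerance = 1e-12)
  curve <- mtlr_survival_curve(model, c(1, 5))
  expect_equal(curve$surv[1], 1)                 # P(D >= 0) = 1 exactly
  expect_equal(curve$time[1], 0)
  expect_true(all(diff(curve$surv) <= 1e-12))
  # grid values are the reverse-cumulative PMF; a terminal point releases
  # the last interval's mass so the curve ends at 0
  expect_equal(curve$surv[-1], c(c(3, 2, 1) / 4, 0), tolerance = 1e-12)
})

test_that("analytic gradient matches central finite differences", {
  set.seed(20)
  worst <- 0
  for (rep in 1:50) {
    n <- sample(5:9, 1); r <- sample(1:3, 1); m <- sample(2:4, 1)
    x <- matrix(rnorm(n * r), n, r)
    lbl <- random_labels(n, seed = 1000 + rep, censor_frac = 0.4, max_time = 20)
    grid <- sort(runif(m, 1, 19))
    C <- runif(1, 0.01, 2)
    theta <- matrix(rnorm(m * (r + 1), 0, 0.5), m, r + 1)
    obj <- mtlr_objective(theta, x, lbl, grid, C)
    g <- attr(obj, "gradient")
    h <- 1e-5
    fd <- matrix(0, m, r + 1)
    for (idx in seq_len(m * (r + 1))) {
      tp <- theta; tp[idx] <- tp[idx] + h
      tm <- theta; tm[idx] <- tm[idx] - h
      fd[idx] <- (as.numeric(mtlr_objective(tp, x, lbl, grid, C)) -
                    as.numeric(mtlr_objective(tm, x, lbl, grid, C))) / (2 * h)
    }
    denom <- pmax(abs(fd), 1)
    worst <- max(worst, max(abs(g - fd) / denom))
  }
  expect_lt(worst, 1e-5)
})

test_that("censoring contributes the marginalized consistent label vectors", {
  # patient censored at 0 is consistent with every interval: contributes log 1
  x <- matrix(1, 1, 1)
  grid <- c(2, 4)
  lbl0 <- survival_labels(0, 0)
  theta <- matrix(rnorm(4), 2, 2)
  set.seed(3)
  val <- as.numeric(mtlr_objective(theta, x, lbl0, grid, C = 0))
  expect_equal(val, 0, tolerance = 1e-12)
  # a patient censored beyond the last grid point only allows the last interval
  lbl_late <- survival_labels(5, 0)
  val_late <- as.numeric(mtlr_objective(theta, x, lbl_late, grid, C = 0))
  f <- survtopics:::.mtlr_scores(theta, x)
  logz <- log(sum(exp(f)))
  expect_equal(val_late, -(f[3] - logz), tolerance = 1e-10)
})

test_that("heavy regularization drives the weights toward zero", {
  set.seed(21)
  n <- 40
  x <- matrix(rnorm(n), n, 1)
  lbl <- random_labels(n, seed = 4)
  grid <- build_time_grid(lbl, m = 4)
  small <- fit_mtlr(x, lbl, c_grid = 0.01, grid = grid)
  big <- fit_mtlr(x, lbl, c_grid = 1e6, grid = grid)
  expect_lt(max(abs(big$theta[, 1])), 1e-3)
  expect_gt(max(abs(small$theta[, 1])), max(abs(big$theta[, 1])))
})

test_that("the objective is convex: seeded restarts reach the same optimum", {
  set.seed(22)
  n <- 30
  x <- matrix(rnorm(n * 2), n, 2)
  lbl <- random_labels(n, seed = 5)
  grid <- build_time_grid(lbl, m = 4)
  vals <- vapply(1:3, function(s) {
    set.seed(s)
    init <- matrix(rnorm(4 * 3, 0, 2), 4, 3)
    fit_mtlr(x, lbl, c_grid = 0.5, grid = grid, init = init)$objective
  }, numeric(1))
  expect_lt(max(vals) - min(vals), 1e-6)
})

test_that("fitting is deterministic given the seed", {
  set.seed(23)
  n <- 40
  x <- matrix(rnorm(n * 2), n, 2)
  lbl <- random_labels(n, seed = 6)
  f1 <- fit_mtlr(x, lbl, c_grid = c(0.1, 1), seed = 9)
  f2 <- fit_mtlr(x, lbl, c_grid = c(0.1, 1), seed = 9)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$C, f2$C)
})

test_that("a strong single-feature effect yields discriminative curves", {
  set.seed(24)
  n <- 500
  x <- matrix(rnorm(n), n, 1)
  t_death <- rexp(n, 0.01 * exp(1.2 * x[, 1]))
  cens <- rexp(n, 0.004)
  lbl <- survival_labels(pmin(t_death, cens), as.integer(t_death <= cens))
  split <- train_test_split(lbl, 0.3, seed = 1)
  lbl_tr <- survival_labels(lbl$time[split$train], lbl$event[split$train])
  lbl_te <- survival_labels(lbl$time[split$test], lbl$event[split$test])
  fit <- fit_mtlr(x[split$train, , drop = FALSE], lbl_tr, c_grid = 1)
  risks <- predict(fit, x[split$test, , drop = FALSE], type = "risk")
  expect_gt(concordance_index(risks, lbl_te), 0.7)
})

test_that("PMF normalizes and risk integrates the curve", {
  set.seed(25)
  n <- 30
  x <- matrix(rnorm(n * 2), n, 2)
  lbl <- random_labels(n, seed = 7)
  fit <- fit_mtlr(x, lbl, c_grid = 1)
  pmf <- mtlr_interval_pmf(fit, x[1, ])
  expect_equal(sum(pmf), 1, tolerance = 1e-10)
  curve <- mtlr_survival_curve(fit, x[1, ])
  expect_true(all(curve$surv >= 0 & curve$surv <= 1))
  # trapezoid oracle on the curve's own points
  tr <- -sum(diff(curve$time) * (head(curve$surv, -1) + tail(curve$surv, -1)) / 2)
  expect_equal(risk_from_curve(curve), tr, tolerance = 1e-12)
})

test_that("risk respects curve dominance and simple shapes", {
  # step curve (1 until T = 10, then 0) carries its pre-jump corner
  step <- survival_curve(c(0, 10 - 1e-9, 10), c(1, 1, 0))
  expect_equal(risk_from_curve(step), -10, tolerance = 1e-6)
  flat <- survival_curve(c(0, 10), c(1, 1))
  expect_equal(risk_from_curve(flat), -10)
  a <- survival_curve(c(0, 5, 10), c(1, 0.9, 0.8))
  b <- survival_curve(c(0, 5, 10), c(1, 0.5, 0.2))
  expect_lte(risk_from_curve(a), risk_from_curve(b))
  # piecewise-linear toy curve vs direct trapezoid evaluation
  pl <- survival_curve(c(0, 2, 6, 9), c(1, 0.7, 0.4, 0.1))
  direct <- -((1 + 0.7) / 2 * 2 + (0.7 + 0.4) / 2 * 4 + (0.4 + 0.1) / 2 * 3)
  expect_equal(risk_from_curve(pl), direct, tolerance = 1e-12)
})
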