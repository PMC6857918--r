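test_that("a single topic recovers the smoothed pooled word frequencies", {
  set.seed(5)
  counts <- matrix(rpois(60, 2), 10, 6, dimnames = list(NULL, paste0("w", 1:6)))
  fit <- fit_lda(counts, k = 1, seed = 1, estimate_alpha = FALSE)
  # closed-form single-topic M-step: phi = 1, so beta = pooled counts (+ smoothing)
  pooled <- colSums(counts)
  oracle <- (pooled + fit$beta_smooth) / sum(pooled + fit$beta_smooth)
  expect_equal(drop(fit$beta_bar), oracle, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("topic rows are probability vectors and the bound is monotone", {
  pc <- planted_corpus(n = 80, seed = 2)
  fit <- fit_lda(pc$counts, k = 3, seed = 3)
  expect_equal(rowSums(fit$beta_bar), rep(1, 3), tolerance = 1e-8)
  expect_true(all(fit$beta_bar >= 0))
  expect_true(all(diff(fit$bound_trace) > -1e-8))
})

test_that("well-separated planted topics are recovered up to permutation", {
  pc <- planted_corpus(n = 150, seed = 7)
  fit1 <- fit_lda(pc$counts, k = 3, seed = 10)
  fit2 <- fit_lda(pc$counts, k = 3, seed = 99)
  expect_gt(matched_min_cor(fit1$beta_bar, pc$beta), 0.95)
  # two seeds agree on the topic set up to permutation
  cors <- cor(t(fit1$beta_bar), t(fit2$beta_bar))
  expect_true(all(apply(cors, 1, max) > 0.95))
})

test_that("loadings are posterior proportions with sensible edge cases", {
  pc <- planted_corpus(n = 60, seed = 4)
  fit <- fit_lda(pc$counts, k = 3, seed = 1)
  th <- infer_loadings(pc$counts, fit)
  expect_true(all(th >= 0))
  expect_equal(rowSums(th), rep(1, nrow(th)), tolerance = 1e-8)
  # empty document -> posterior equals the symmetric prior
  empty <- matrix(0, 1, ncol(pc$counts), dimnames = list(NULL, colnames(pc$counts)))
  expect_equal(drop(infer_loadings(empty, fit)), rep(1 / 3, 3),
               tolerance = 1e-10, ignore_attr = TRUE)
  raw <- infer_loadings(empty, fit, raw = TRUE)
  expect_equal(drop(raw), rep(fit$alpha, 3), tolerance = 1e-8, ignore_attr = TRUE)
  # identical documents get identical loadings; permutation is equivariant
  two <- pc$counts[c(5, 5, 9), ]
  th2 <- infer_loadings(two, fit)
  expect_equal(th2[1, ], th2[2, ])
  perm <- c(3, 1, 2)
  expect_equal(infer_loadings(pc$counts[perm, ], fit),
               infer_loadings(pc$counts, fit)[perm, ], tolerance = 1e-5,
               ignore_attr = TRUE)  # grouped sums reorder floating-point adds
})

test_that("a document drawn from one planted topic loads onto it", {
  pc <- planted_corpus(n = 150, seed = 7)
  fit <- fit_lda(pc$counts, k = 3, seed = 10)
  set.seed(31)
  pure <- drop(rmultinom(1, 60, pc$beta[2, ]))
  names(pure) <- colnames(pc$counts)
  th <- drop(infer_loadings(pure, fit))
  # match fitted topic to planted topic 2, then check dominance
  match2 <- which.max(cor(t(fit$beta_bar), pc$beta[2, ]))
  expect_gt(th[match2], 0.9)
})

test_that("held-out bound has its analytic values in the degenerate cases", {
  V <- 12
  uniform <- structure(list(
    beta_bar = matrix(1 / V, 1, V), alpha = 0.1, k = 1,
    vocabulary = paste0("w", 1:V), encoding = NULL, beta_smooth = 0,
    bound_trace = numeric(0), elbo = NA), class = "lda_basis")
  one_word <- matrix(c(1, rep(0, V - 1)), 1, V, dimnames = list(NULL, paste0("w", 1:V)))
  # K = 1: the variational family is exact and the bound equals -log V
  expect_equal(heldout_likelihood(one_word, uniform), -log(V), tolerance = 1e-10)
  # empty document: bound is exactly 0
  empty <- matrix(0, 1, V, dimnames = list(NULL, paste0("w", 1:V)))
  expect_equal(heldout_likelihood(empty, uniform), 0, tolerance = 1e-12)
  # K > 1 mean-field bound can only fall below the exact -log V
  uniform3 <- uniform
  uniform3$beta_bar <- matrix(1 / V, 3, V)
  uniform3$k <- 3
  expect_lte(heldout_likelihood(one_word, uniform3), -log(V) + 1e-10)
})

test_that("the held-out bound prefers the true topic count over one topic", {
  pc <- planted_corpus(n = 150, seed = 8)
  train <- pc$counts[1:100, ]
  test <- pc$counts[101:150, ]
  fit3 <- fit_lda(train, k = 3, seed = 2)
  fit1 <- fit_lda(train, k = 1, seed = 2)
  expect_gt(heldout_likelihood(test, fit3), heldout_likelihood(test, fit1))
})

test_that("fit_lda validates input and warns when topics exceed documents", {
  expect_error(fit_lda(matrix(0, 3, 4), k = 2), "empty")
  counts <- matrix(rpois(12, 3), 3, 4)
  expect_warning(fit_lda(counts, k = 5, seed = 1, max_em = 5), "more topics")
  pc <- planted_corpus(n = 40, seed = 9)
  bad <- pc$counts[, 1:10]
  fit <- fit_lda(pc$counts, k = 2, seed = 1, max_em = 5)
  expect_error(infer_loadings(bad, fit), "mismatch")
})

test_that("identical seeds give identical fits", {
  pc <- planted_corpus(n = 60, seed = 12)
  f1 <- fit_lda(pc$counts, k = 3, seed = 5)
  f2 <- fit_lda(pc$counts, k = 3, seed = 5)
  expect_identical(f1$beta_bar, f2$beta_bar)
  expect_identical(f1$alpha, f2$alpha)
})

test_that("singleton grids skip the search and return the requested basis", {
  ch <- generate_cohort(simulation_config(n = 60, p = 40, signature_size = 8,
                                          doc_length = 25, seed = 21))
  st <- fit_preprocess(ch$expression, ch$clinical)
  sel <- select_basis(st$z, st$clinical_x, ch$labels,
                      k_grid = 2, encodings = "enc_b", seed = 1)
  expect_equal(sel$encoding, "enc_b")
  expect_equal(sel$k, 2)
  expect_s3_class(sel$basis, "lda_basis")
  expect_equal(sel$basis$k, 2)
})

test_that("cross-validation folds are event-stratified and balanced", {
  lbl <- random_labels(53, seed = 2)
  folds <- survtopics:::.stratified_folds(lbl$event, 5, seed = 1)
  sizes <- table(folds)
  expect_lte(max(sizes) - min(sizes), 2)  # one per stratum
  for (s in 0:1) {
    sub <- table(folds[lbl$event == s])
    expect_lte(max(sub) - min(sub), 1)
  }
})
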