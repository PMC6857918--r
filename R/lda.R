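# Variational EM for latent Dirichlet allocation on dGEV count corpora.
# Batch mean-field updates: q(theta_d) = Dirichlet(gamma_d), q(z_dn) = phi.
# phi is never materialized; with E[d,k] = exp(digamma(gamma_dk) -
# digamma(sum_k gamma_dk)) and S = E %*% beta, the word-level terms of the
# bound collapse to sum_v x_dv log S_dv.

# Triplet view of the corpus: only the nonzero (document, word) cells enter
# the variational updates, so everything is computed on the nnz triplets
# with grouped sums (rowsum) instead of dense n x V products.
.sparse_corpus <- function(counts) {
  nz <- which(counts != 0)
  n <- nrow(counts)
  ii <- ((nz - 1L) %% n) + 1L
  jj <- ((nz - 1L) %/% n) + 1L
  list(i = ii, j = jj, x = as.numeric(counts[nz]),
       rows_present = sort(unique(ii)), cols_present = sort(unique(jj)),
       n = n, V = ncol(counts), doc_len = rowSums(counts))
}

.lda_estep_sparse <- function(sc, beta, alpha, max_iter = 100, tol = 1e-6,
                              gamma_init = NULL) {
  K <- nrow(beta)
  n <- sc$n
  tbeta_j <- t(beta)[sc$j, , drop = FALSE]     # nnz x K, fixed within the E-step
  gamma <- if (is.null(gamma_init)) matrix(alpha + sc$doc_len / K, n, K) else gamma_init
  G <- matrix(0, n, K)
  for (it in seq_len(max_iter)) {
    E <- exp(digamma(gamma) - digamma(.rowSums(gamma, n, K)))
    s_vals <- .rowSums(E[sc$i, , drop = FALSE] * tbeta_j, length(sc$x), K)
    r <- sc$x / s_vals
    agg <- rowsum(r * tbeta_j, sc$i)
    G[sc$rows_present, ] <- agg
    gamma_new <- alpha + E * G
    delta <- max(abs(gamma_new - gamma))
    gamma <- gamma_new
    if (delta < tol * (1 + max(gamma))) break
  }
  gamma
}

.lda_estep <- function(counts, beta, alpha, max_iter = 100, tol = 1e-6) {
  .lda_estep_sparse(.sparse_corpus(counts), beta, alpha, max_iter, tol)
}

# Per-document evidence lower bound given gamma (no topic-prior term).
.lda_elbo_docs_sparse <- function(sc, beta, alpha, gamma) {
  K <- nrow(beta)
  gsum <- rowSums(gamma)
  E <- exp(digamma(gamma) - digamma(gsum))
  tbeta_j <- t(beta)[sc$j, , drop = FALSE]
  s_vals <- .rowSums(E[sc$i, , drop = FALSE] * tbeta_j, length(sc$x), K)
  word_term <- numeric(sc$n)
  wt <- sc$x * .safe_log(s_vals)
  if (length(wt) > 0) {
    agg <- rowsum(wt, group = sc$i)
    word_term[sc$rows_present] <- agg[, 1]
  }
  dig <- digamma(gamma) - digamma(gsum)
  word_term +
    (lgamma(K * alpha) - K * lgamma(alpha)) +
    rowSums((alpha - gamma) * dig) -
    lgamma(gsum) + rowSums(lgamma(gamma))
}

.lda_elbo_docs <- function(counts, beta, alpha, gamma) {
  .lda_elbo_docs_sparse(.sparse_corpus(counts), beta, alpha, gamma)
}

.safe_log <- function(x) {
  out <- log(pmax(x, .Machine$double.xmin))
  out
}

# Newton step for the symmetric document-topic prior alpha, maximizing the
# alpha-dependent part of the bound; falls back to the current value when the
# step would not improve it (keeps the tracked bound monotone).
.lda_update_alpha <- function(alpha, gamma, K, max_iter = 20) {
  n <- nrow(gamma)
  ss <- sum(digamma(gamma) - digamma(rowSums(gamma)))
  obj <- function(a) n * (lgamma(K * a) - K * lgamma(a)) + (a - 1) * ss
  a <- alpha
  for (it in seq_len(max_iter)) {
    d1 <- n * K * (digamma(K * a) - digamma(a)) + ss
    d2 <- n * K * (K * trigamma(K * a) - trigamma(a))
    # Newton in log-space keeps a > 0
    log_step <- d1 / (d2 * a + d1)
    if (!is.finite(log_step)) break
    a_new <- exp(log(a) - log_step)
    # keep the concentration in a plausible range; the MLE diverges while
    # the topics are still symmetric and the mixture weights uninformative
    if (!is.finite(a_new) || a_new < 1e-4 || a_new > 5) break
    if (abs(a_new - a) < 1e-8) { a <- a_new; break }
    a <- a_new
  }
  if (is.finite(obj(a)) && obj(a) >= obj(alpha)) a else alpha
}

#' Fit an LDA topic model by variational EM
#'
#' Blei-style batch variational EM with a symmetric Dirichlet document-topic
#' prior (initialized at `alpha`, re-estimated during EM by Newton updates
#' unless `estimate_alpha = FALSE`). Topic-word rows are initialized at
#' `1/V + delta` with `delta ~ U[0, 1/V^2]` drawn from `seed`, then
#' normalized. The M-step adds a small pseudocount (`beta_smooth`) to the
#' expected word counts so no word has probability exactly zero; the tracked
#' `bound_trace` is the evidence lower bound plus the corresponding
#' log-prior term, and is non-decreasing across EM iterations.
#'
#' @param corpus A `dgev_corpus` from [encode_counts()], or a plain
#'   non-negative count matrix (documents x words).
#' @param k Number of topics (>= 1).
#' @param alpha Initial symmetric document-topic concentration.
#' @param seed Integer seed for the topic-word initialization.
#' @param estimate_alpha Re-estimate `alpha` during EM.
#' @param beta_smooth Pseudocount added to expected word counts in the M-step.
#' @param max_em,tol EM stopping rule: stop when the relative change of the
#'   tracked bound drops below `tol` or after `max_em` iterations.
#' @param estep_max_iter,estep_tol Per-E-step (document inference) stopping rule.
#' @param estep_warm_iter Inner-iteration cap for warm-started E-steps after
#'   the first EM iteration (partial E-steps; generalized EM).
#' @param alpha_delay EM iteration from which the prior is re-estimated.
#' @return An object of class `lda_basis`: `beta_bar` (k x V row-stochastic),
#'   `alpha`, `k`, `vocabulary`, `encoding` (if the corpus carried one),
#'   `bound_trace`, `elbo` (final per-document average bound).
#' @export
fit_lda <- function(corpus, k, alpha = 0.1, seed = 1, estimate_alpha = TRUE,
                    beta_smooth = 0.01, max_em = 200, tol = 1e-6, alpha_delay = 10,
                    estep_max_iter = 100, estep_tol = 1e-6,
                    estep_warm_iter = 10) {
  counts <- .corpus_counts(corpus)
  if (k < 1) stop("k must be >= 1")
  if (nrow(counts) == 0 || sum(counts) == 0) stop("corpus is empty")
  if (k > nrow(counts)) warning("more topics than documents (k = ", k, ", n = ", nrow(counts), ")")
  V <- ncol(counts)
  set.seed(as.integer(seed %% .Machine$integer.max))
  beta <- matrix(1 / V, k, V) + matrix(stats::runif(k * V, 0, 1 / V^2), k, V)
  beta <- beta / rowSums(beta)
  sc <- .sparse_corpus(counts)
  bound_trace <- numeric(0)
  prev <- -Inf
  gamma <- NULL
  for (em in seq_len(max_em)) {
    # warm-started coordinate ascent: the previous iteration's gamma is a
    # valid starting point, and a capped (partial) E-step still increases the
    # bound, so the overall procedure is a monotone generalized EM
    gamma <- .lda_estep_sparse(sc, beta, alpha,
                               if (em == 1) estep_max_iter else estep_warm_iter,
                               estep_tol, gamma_init = gamma)
    bound <- sum(.lda_elbo_docs_sparse(sc, beta, alpha, gamma)) +
      beta_smooth * sum(.safe_log(beta))
    bound_trace <- c(bound_trace, bound)
    converged <- is.finite(prev) && abs(bound - prev) < tol * abs(prev)
    prev <- bound
    # M-step sufficient statistics: stats_kv = sum_d x_dv phi_dvk
    E <- exp(digamma(gamma) - digamma(rowSums(gamma)))
    Ei <- E[sc$i, , drop = FALSE]
    tbeta_j <- t(beta)[sc$j, , drop = FALSE]
    s_vals <- .rowSums(Ei * tbeta_j, length(sc$x), k)
    r <- sc$x / s_vals
    SM <- matrix(0, k, V)
    SM[, sc$cols_present] <- t(rowsum(r * Ei, sc$j))
    beta <- beta * SM + beta_smooth
    beta <- beta / rowSums(beta)
    # the prior is only identifiable once the topics have broken symmetry;
    # estimating it from the start locks the model at the uniform saddle
    if (estimate_alpha && (em >= alpha_delay || converged)) {
      alpha <- .lda_update_alpha(alpha, gamma, k)
    }
    if (converged) break
  }
  structure(list(beta_bar = beta, alpha = alpha, k = k,
                 vocabulary = colnames(counts),
                 encoding = if (inherits(corpus, "dgev_corpus")) corpus$encoding else NULL,
                 beta_smooth = beta_smooth,
                 bound_trace = bound_trace,
                 elbo = bound_trace[length(bound_trace)] / nrow(counts)),
            class = "lda_basis")
}

.corpus_counts <- function(corpus) {
  counts <- if (inherits(corpus, "dgev_corpus")) corpus$counts else as.matrix(corpus)
  if (any(counts < 0)) stop("counts must be non-negative")
  storage.mode(counts) <- "double"
  counts
}

.check_vocab <- function(counts, basis) {
  if (ncol(counts) != ncol(basis$beta_bar)) {
    stop("vocabulary mismatch: corpus has ", ncol(counts), " words, basis has ",
         ncol(basis$beta_bar))
  }
  if (!is.null(colnames(counts)) && !is.null(basis$vocabulary) &&
      !identical(colnames(counts), basis$vocabulary)) {
    if (!setequal(colnames(counts), basis$vocabulary)) stop("vocabulary mismatch")
    counts <- counts[, basis$vocabulary, drop = FALSE]
  }
  counts
}

#' Infer per-patient topic loadings under a fitted basis
#'
#' Runs variational inference for each document with the topic-word matrix
#' held fixed and returns the patient-topic representation: by default the
#' normalized posterior proportions `gamma / sum(gamma)`; `raw = TRUE`
#' returns the Dirichlet parameters `gamma` themselves. An empty document
#' has posterior equal to the prior, i.e. uniform proportions.
#'
#' @param corpus Count matrix or `dgev_corpus` over the basis vocabulary
#'   (a single document may be given as a vector).
#' @param basis An `lda_basis`.
#' @param raw Return raw Dirichlet parameters instead of proportions.
#' @return Numeric matrix, documents x topics.
#' @export
infer_loadings <- function(corpus, basis, raw = FALSE) {
  stopifnot(inherits(basis, "lda_basis"))
  counts <- if (inherits(corpus, "dgev_corpus")) corpus$counts else corpus
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1, dimnames = list(NULL, names(counts)))
  counts <- .check_vocab(.corpus_counts(counts), basis)
  gamma <- .lda_estep(counts, basis$beta_bar, basis$alpha)
  colnames(gamma) <- paste0("topic", seq_len(basis$k))
  rownames(gamma) <- rownames(counts)
  if (raw) gamma else gamma / rowSums(gamma)
}

#' Average held-out variational bound per document
#'
#' Scores a corpus under a fitted basis with the mean per-document evidence
#' lower bound (the tractable proxy for held-out log-likelihood). An empty
#' document contributes exactly 0.
#'
#' @inheritParams infer_loadings
#' @return A single number (mean per-document bound).
#' @export
heldout_likelihood <- function(corpus, basis) {
  stopifnot(inherits(basis, "lda_basis"))
  counts <- .check_vocab(.corpus_counts(corpus), basis)
  gamma <- .lda_estep(counts, basis$beta_bar, basis$alpha)
  mean(.lda_elbo_docs(counts, basis$beta_bar, basis$alpha, gamma))
}

#' @export
print.lda_basis <- function(x, ...) {
  cat(sprintf("dLDA topic basis: %d topics over %d words%s, alpha = %.4f\n",
              x$k, ncol(x$beta_bar),
              if (!is.null(x$encoding)) paste0(" (", x$encoding, ")") else "",
              x$alpha))
  if (!is.null(x$elbo)) cat(sprintf("  final per-document bound: %.3f\n", x$elbo))
  invisible(x)
}

#' Select the dGEV encoding and topic count by cross-validation
#'
#' Grid search over encodings and topic counts with event-stratified
#' k-fold cross-validation. For each fold the topic model is fitted on the
#' training portion, the held-out fifth is projected onto it, a Cox model is
#' fitted on [loadings, clinical] and scored by held-out concordance; the
#' held-out per-document bound is recorded as the likelihood score. The
#' encoding with the best mean concordance over the whole grid wins. Along
#' the likelihood path, `k_hat` is the likelihood-best K; the chosen `k_star`
#' is the concordance-best K among `K <= k_hat` whose mean likelihood is
#' within one standard deviation of `k_hat`'s (ties broken toward smaller K).
#' The final basis is refitted on all patients at the winning setting.
#'
#' @param z Z-scored expression over retained genes (patients x genes).
#' @param clinical_x Numeric clinical design matrix (or `NULL`).
#' @param labels A `survival_labels` object.
#' @param k_grid Candidate topic counts (default 5, 10, ..., 150).
#' @param encodings Candidate encodings.
#' @param n_folds Number of cross-validation folds.
#' @param seed Integer seed controlling fold assignment and LDA starts.
#' @param alpha Initial document-topic concentration for each fit.
#' @param bins Optional pre-fitted `dgev_bins`; fitted on `z` when `NULL`.
#' @param ... Passed through to [fit_lda()].
#' @return A `basis_selection` object: `encoding` (t*), `k` (K*), `k_hat`,
#'   `concordance` and `likelihood` tables (grid x folds), `basis` (the
#'   refitted `lda_basis`), `bins`.
#' @export
select_basis <- function(z, clinical_x, labels, k_grid = seq(5, 150, by = 5),
                         encodings = c("enc_a", "enc_b"), n_folds = 5,
                         seed = 1, alpha = 0.1, bins = NULL, ...) {
  stopifnot(inherits(labels, "survival_labels"))
  z <- as.matrix(z)
  n <- nrow(z)
  if (!is.null(clinical_x)) clinical_x <- as.matrix(clinical_x)
  if (is.null(bins)) bins <- fit_discretizer(z)
  b <- discretize_expression(z, bins)
  folds <- .stratified_folds(labels$event, n_folds, seed)
  grid <- expand.grid(encoding = encodings, k = k_grid,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (nrow(grid) == 1) {   # no search needed
    corpus <- encode_counts(b, grid$encoding[1])
    final_seed <- (seed * 1000L + 999L) %% 2147483647L
    basis <- fit_lda(corpus, grid$k[1], alpha = alpha, seed = final_seed, ...)
    return(structure(list(encoding = grid$encoding[1], k = grid$k[1],
                          k_hat = grid$k[1], grid = grid,
                          concordance = matrix(NA_real_, 1, n_folds),
                          likelihood = matrix(NA_real_, 1, n_folds),
                          mean_concordance = NA_real_, mean_likelihood = NA_real_,
                          folds = NULL, basis = basis, bins = bins),
                     class = "basis_selection"))
  }
  cmat <- matrix(NA_real_, nrow(grid), n_folds)
  lmat <- matrix(NA_real_, nrow(grid), n_folds)
  for (g in seq_len(nrow(grid))) {
    t_enc <- grid$encoding[g]
    K <- grid$k[g]
    corpus <- encode_counts(b, t_enc)
    for (f in seq_len(n_folds)) {
      test_idx <- which(folds == f)
      train_idx <- setdiff(seq_len(n), test_idx)
      fit_seed <- (seed * 1000L + g * 37L + f) %% 2147483647L
      basis_f <- fit_lda(corpus$counts[train_idx, , drop = FALSE], K,
                         alpha = alpha, seed = fit_seed, ...)
      load_tr <- infer_loadings(corpus$counts[train_idx, , drop = FALSE], basis_f)
      load_te <- infer_loadings(corpus$counts[test_idx, , drop = FALSE], basis_f)
      x_tr <- cbind(load_tr, if (!is.null(clinical_x)) clinical_x[train_idx, , drop = FALSE])
      x_te <- cbind(load_te, if (!is.null(clinical_x)) clinical_x[test_idx, , drop = FALSE])
      lbl_tr <- survival_labels(labels$time[train_idx], labels$event[train_idx])
      lbl_te <- survival_labels(labels$time[test_idx], labels$event[test_idx])
      cox <- tryCatch(fit_cox(x_tr, lbl_tr, lambda = 0),
                      error = function(e) fit_cox(x_tr, lbl_tr, lambda = 0.1))
      risks <- drop(x_te %*% cox$coefficients)
      cmat[g, f] <- tryCatch(concordance_index(risks, lbl_te), error = function(e) {
        warning("fold ", f, ": no comparable pairs; concordance excluded")
        NA_real_
      })
      lmat[g, f] <- heldout_likelihood(corpus$counts[test_idx, , drop = FALSE], basis_f)
    }
  }
  cbar <- rowMeans(cmat, na.rm = TRUE)
  lbar <- rowMeans(lmat, na.rm = TRUE)
  t_star <- grid$encoding[which.max(cbar)]
  in_t <- which(grid$encoding == t_star)
  k_hat_row <- in_t[which.max(lbar[in_t])]
  k_hat <- grid$k[k_hat_row]
  thresh <- lbar[k_hat_row] - stats::sd(lmat[k_hat_row, ], na.rm = TRUE)
  cand <- in_t[grid$k[in_t] <= k_hat & lbar[in_t] >= thresh]
  if (length(cand) == 0) cand <- k_hat_row
  # "essentially the highest concordance" among the candidates, preferring
  # small K: the smallest candidate within one standard error of the best
  best_cand <- cand[which.max(cbar[cand])]
  c_tol <- stats::sd(cmat[best_cand, ], na.rm = TRUE) /
    sqrt(sum(!is.na(cmat[best_cand, ])))
  if (!is.finite(c_tol)) c_tol <- 0
  near <- cand[cbar[cand] >= cbar[best_cand] - c_tol]
  best_row <- near[which.min(grid$k[near])]
  k_star <- grid$k[best_row]
  final_corpus <- encode_counts(b, t_star)
  final_seed <- (seed * 1000L + 999L) %% 2147483647L
  basis <- fit_lda(final_corpus, k_star, alpha = alpha, seed = final_seed, ...)
  structure(list(encoding = t_star, k = k_star, k_hat = k_hat,
                 grid = grid, concordance = cmat, likelihood = lmat,
                 mean_concordance = cbar, mean_likelihood = lbar,
                 folds = folds, basis = basis, bins = bins),
            class = "basis_selection")
}

#' @export
print.basis_selection <- function(x, ...) {
  cat(sprintf("dLDA basis selection: encoding %s, K* = %d (likelihood-best K = %d)\n",
              x$encoding, x$k, x$k_hat))
  tab <- data.frame(encoding = x$grid$encoding, k = x$grid$k,
                    concordance = round(x$mean_concordance, 4),
                    likelihood = round(x$mean_likelihood, 2))
  print(tab, row.names = FALSE)
  invisible(x)
}

# Event-status-stratified fold assignment; sizes differ by at most one
# within each stratum.
.stratified_folds <- function(event, n_folds, seed) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  folds <- integer(length(event))
  for (s in unique(event)) {
    idx <- which(event == s)
    folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  folds
}
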