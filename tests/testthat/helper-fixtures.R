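# Shared fixtures, built in code at test time.

# tiny deterministic expression matrix with obvious structure
tiny_expression <- function() {
  matrix(c(0, 2,
           2, 4), nrow = 2, byrow = TRUE,
         dimnames = list(c("p1", "p2"), c("gA", "gB")))
}

# small random labels with mixed censoring
random_labels <- function(n, seed, censor_frac = 0.3, max_time = 100) {
  set.seed(seed)
  time <- stats::runif(n, 1, max_time)
  event <- as.integer(stats::runif(n) > censor_frac)
  survival_labels(time, event)
}

# brute-force concordance: nested loops straight off the comparability rule
ci_oracle <- function(risk, time, event) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      comparable <- (event[i] == 1 && event[j] == 1 && time[i] < time[j]) ||
        (event[i] == 1 && event[j] == 0 && time[i] < time[j])
      if (comparable) {
        den <- den + 1
        if (risk[i] > risk[j]) num <- num + 1
      }
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

# brute-force Cox partial log-likelihood: materialize every risk set
cox_loglik_oracle <- function(w, x, time, event) {
  lp <- drop(as.matrix(x) %*% w)
  total <- 0
  for (i in which(event == 1)) {
    rs <- which(time >= time[i])
    total <- total + lp[i] - log(sum(exp(lp[rs])))
  }
  total
}

# planted three-topic corpus with disjoint signatures (pure count level)
planted_corpus <- function(n = 150, v = 60, seed = 1, doc_len = 40,
                           alpha = 0.25, mass = 0.92) {
  set.seed(seed)
  k <- 3
  beta <- matrix((1 - mass) / v, k, v)
  sig <- split(seq_len(k * 15), rep(seq_len(k), each = 15))
  for (t in seq_len(k)) beta[t, sig[[t]]] <- beta[t, sig[[t]]] + mass / 15
  beta <- beta / rowSums(beta)
  theta <- matrix(stats::rgamma(n * k, alpha), n, k)
  theta <- theta / rowSums(theta)
  counts <- t(vapply(seq_len(n), function(i) {
    drop(stats::rmultinom(1, doc_len, drop(theta[i, ] %*% beta)))
  }, numeric(v)))
  colnames(counts) <- paste0("w", seq_len(v))
  list(counts = counts, beta = beta, theta = theta)
}

# best minimum matched row-correlation over topic permutations (k = 3)
matched_min_cor <- function(fitted_beta, true_beta) {
  cors <- stats::cor(t(fitted_beta), t(true_beta))
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  max(vapply(perms, function(p) min(cors[cbind(1:3, p)]), numeric(1)))
}

# hand-rolled Kaplan-Meier product-limit estimator
km_oracle <- function(time, event) {
  ev <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ev))
  for (j in seq_along(ev)) {
    d <- sum(event == 1 & time == ev[j])
    nrisk <- sum(time >= ev[j])
    s <- s * (1 - d / nrisk)
    surv[j] <- s
  }
  list(time = ev, surv = surv)
}

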