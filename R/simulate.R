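#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a mid-sized expression cohort with a planted topic
#' structure: each of `k_true` topics concentrates most of its mass on its
#' own signature set of over-/under-expressed genes, patients mix topics via
#' a Dirichlet, and the death hazard is log-linear in the topic proportions
#' and clinical covariates with an independent exponential censoring time
#' calibrated to the target censoring fraction.
#'
#' @param n Number of patients.
#' @param p Number of genes.
#' @param k_true Number of planted topics.
#' @param alpha_theta Dirichlet concentration of the patient-topic mixtures.
#' @param signature_size Signature gene-words per topic.
#' @param signature_mass Probability mass a topic puts on its signature.
#' @param doc_length Mean total dGEV count per patient (Poisson).
#' @param topic_weights Topic log-hazard weights (length `k_true`).
#' @param clinical_age_effect Log-hazard per year of age (age ~ N(60, 10)).
#' @param clinical_sex_effect Log-hazard for male vs female.
#' @param baseline_median Median survival (days) at the average log-hazard.
#' @param censoring_fraction Target fraction of censored patients.
#' @param clinical_missing_rate Fraction of clinical entries blanked to NA.
#' @param seed Integer seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n = 400, p = 200, k_true = 3, alpha_theta = 0.3,
                              signature_size = 20, signature_mass = 0.9,
                              doc_length = 50,
                              topic_weights = seq(-1.5, 1.5, length.out = k_true),
                              clinical_age_effect = 0.02,
                              clinical_sex_effect = 0.1,
                              baseline_median = 2000,
                              censoring_fraction = 0.3,
                              clinical_missing_rate = 0.05,
                              seed = 1) {
  if (k_true > p) stop("k_true cannot exceed the number of genes")
  if (k_true * signature_size > 2 * p) stop("topic signatures exceed the vocabulary")
  if (censoring_fraction <= 0 || censoring_fraction >= 1) {
    stop("censoring_fraction must lie in (0, 1)")
  }
  if (length(topic_weights) != k_true) stop("topic_weights must have length k_true")
  if (n < 2 || p < 2 || doc_length <= 0) stop("counts must be positive")
  structure(as.list(environment()), class = "simulation_config")
}

#' Generate a synthetic topic-structured survival cohort
#'
#' Samples patient-topic mixtures from a Dirichlet, draws per-patient dGEV
#' word counts from the mixture of planted topic-word distributions (over
#' the two-words-per-gene over/under vocabulary), inverts the encoding and
#' binning to z-score-like expression values (bin midpoints plus jitter,
#' then de-standardized to a microarray-like range), and samples survival
#' times from an exponential hazard that is log-linear in the topic
#' proportions and clinical covariates. Censoring is an independent
#' exponential whose rate is calibrated so the expected censored fraction
#' matches the target.
#'
#' @param config A `simulation_config`.
#' @return List with `expression` (patients x genes matrix), `clinical`
#'   (data.frame with `age`, `sex`, possibly with NAs), `labels`
#'   (`survival_labels`), and `truth` (theta, beta, weights, hazards, the
#'   planted discretized matrix, and the censoring rate).
#' @export
generate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(as.integer(config$seed %% .Machine$integer.max))
  n <- config$n; p <- config$p; K <- config$k_true
  vocab_genes <- sprintf("gene%03d", seq_len(p))
  vocab <- c(paste0("OVER-", vocab_genes), paste0("UNDER-", vocab_genes))
  V <- 2 * p

  # planted topic-word distributions: disjoint signatures + uniform floor
  beta <- matrix((1 - config$signature_mass) / V, K, V,
                 dimnames = list(paste0("topic", 1:K), vocab))
  sig_words <- sample(V, K * config$signature_size)
  for (k in seq_len(K)) {
    words <- sig_words[((k - 1) * config$signature_size + 1):(k * config$signature_size)]
    wts <- 1 / seq_along(words)               # mild Zipf within the signature
    beta[k, words] <- beta[k, words] + config$signature_mass * wts / sum(wts)
  }
  beta <- beta / rowSums(beta)

  theta <- .rdirichlet(n, rep(config$alpha_theta, K))
  counts <- matrix(0L, n, V, dimnames = list(sprintf("P%04d", 1:n), vocab))
  doc_len <- stats::rpois(n, config$doc_length)
  for (i in seq_len(n)) {
    if (doc_len[i] == 0) next
    mix <- drop(theta[i, ] %*% beta)
    counts[i, ] <- stats::rmultinom(1, doc_len[i], mix)
  }

  # invert encoding + binning into expression values
  over <- counts[, 1:p, drop = FALSE]
  under <- counts[, (p + 1):V, drop = FALSE]
  b <- ifelse(over >= under, pmin(over, 10L), -pmin(under, 10L))
  b[over == under] <- ifelse(over[over == under] > 0, pmin(over[over == under], 10L), 0L)
  width <- 3 / 10                              # synthetic band: |z| in [1, 4]
  u <- matrix(stats::runif(n * p), n, p)
  z <- matrix(0, n, p)
  pos <- b > 0; neg <- b < 0
  z[pos] <- 1 + (b[pos] - 1 + u[pos]) * width
  z[neg] <- -1 - (-b[neg] - 1 + u[neg]) * width
  triv <- !pos & !neg
  z[triv] <- pmax(pmin(stats::rnorm(sum(triv), 0, 0.35), 0.999), -0.999)
  expression <- z * 1.5 + 8                    # microarray-like log2 range
  dimnames(expression) <- list(rownames(counts), vocab_genes)

  age <- stats::rnorm(n, 60, 10)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  log_hazard <- drop(theta %*% config$topic_weights) +
    config$clinical_age_effect * (age - 60) +
    config$clinical_sex_effect * (sex == "M")
  log_hazard <- log_hazard - mean(log_hazard)
  rate0 <- log(2) / config$baseline_median
  rates <- rate0 * exp(log_hazard)
  death <- stats::rexp(n, rates)
  # censoring rate c solves mean_i c/(c + r_i) = target
  target <- config$censoring_fraction
  fr <- function(cc) mean(cc / (cc + rates)) - target
  crate <- stats::uniroot(fr, c(1e-12, 1e6 * rate0), extendInt = "upX")$root
  cens <- stats::rexp(n, crate)
  time <- pmin(death, cens)
  event <- as.integer(death <= cens)

  clinical <- data.frame(age = age, sex = sex, stringsAsFactors = FALSE,
                         row.names = rownames(counts))
  if (config$clinical_missing_rate > 0) {
    for (cn in names(clinical)) {
      miss <- stats::runif(n) < config$clinical_missing_rate
      clinical[[cn]][miss] <- NA
    }
  }
  labels <- survival_labels(time, event, patient_ids = rownames(counts))
  list(expression = expression, clinical = clinical, labels = labels,
       truth = list(theta = theta, beta = beta,
                    topic_weights = config$topic_weights,
                    log_hazard = log_hazard, rates = rates,
                    censoring_rate = crate, dgev = b, counts = counts))
}

.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), n, length(alpha),
              byrow = TRUE)
  g / rowSums(g)
}

#' Sample survival labels consistent with predicted survival curves
#'
#' For each patient, draws a death time from that patient's own predicted
#' survival distribution by inverse-transform sampling on the curve
#' (linear interpolation between curve points; draws landing beyond the last
#' point are placed just after it). With a calibrated model the predicted
#' probabilities at these death times are uniform by construction, which is
#' the null the distributional-calibration test checks.
#'
#' @param curves List of `survival_curve` objects (one per patient).
#' @param censoring_fraction Optional fraction of patients to right-censor
#'   uniformly before their sampled death (0 = none).
#' @param seed Integer seed.
#' @return A `survival_labels` object.
#' @export
generate_mtlr_consistent <- function(curves, censoring_fraction = 0, seed = 1) {
  if (inherits(curves, "survival_curve")) curves <- list(curves)
  set.seed(as.integer(seed %% .Machine$integer.max))
  n <- length(curves)
  u <- stats::runif(n)
  time <- vapply(seq_len(n), function(i) .invert_curve(curves[[i]], u[i]), numeric(1))
  event <- rep(1L, n)
  if (censoring_fraction > 0) {
    cens <- which(stats::runif(n) < censoring_fraction)
    time[cens] <- time[cens] * stats::runif(length(cens))
    event[cens] <- 0L
  }
  survival_labels(time, event)
}

# earliest t with S(t) <= u under linear interpolation; u below the final
# curve value lands just beyond the last point (where the curve is held)
.invert_curve <- function(curve, u) {
  t <- curve$time; s <- curve$surv
  last <- length(s)
  if (u <= s[last]) return(t[last] * 1.0001 + 1e-9)
  j <- which(s <= u)[1]                       # first index where S drops to <= u
  if (j == 1) return(0)
  if (s[j - 1] == s[j]) return(t[j])
  t[j - 1] + (s[j - 1] - u) / (s[j - 1] - s[j]) * (t[j] - t[j - 1])
}

#' Write a generated cohort to the delimited-text input formats
#'
#' Emits the expression TSV (patients as rows), the clinical CSV plus a
#' schema CSV, the labels CSV, and a ground-truth RDS, in the formats the
#' readers in this package expect.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  expr_path <- file.path(dir, "expression.tsv")
  expr_df <- data.frame(patient_id = rownames(cohort$expression),
                        cohort$expression, check.names = FALSE)
  utils::write.table(expr_df, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  clin_path <- file.path(dir, "clinical.csv")
  clin_df <- data.frame(patient_id = rownames(cohort$expression),
                        cohort$clinical, check.names = FALSE)
  utils::write.csv(clin_df, clin_path, row.names = FALSE, quote = FALSE)
  schema_path <- file.path(dir, "clinical_schema.csv")
  types <- vapply(cohort$clinical, function(col) if (is.numeric(col)) "numeric" else "categorical",
                  character(1))
  utils::write.csv(data.frame(feature = names(types), type = unname(types)),
                   schema_path, row.names = FALSE, quote = FALSE)
  labels_path <- file.path(dir, "labels.csv")
  utils::write.csv(data.frame(patient_id = cohort$labels$patient_ids,
                              time = cohort$labels$time,
                              event = cohort$labels$event),
                   labels_path, row.names = FALSE, quote = FALSE)
  truth_path <- file.path(dir, "truth.rds")
  saveRDS(cohort$truth, truth_path)
  invisible(c(expr_path, clin_path, schema_path, labels_path, truth_path))
}
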