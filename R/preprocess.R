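#' Global z-score normalization of an expression matrix
#'
#' Standardizes every entry of a patients x genes expression matrix with a
#' single global mean and standard deviation computed over all `n * p`
#' entries (denominator `n*p - 1`). A per-gene z-score would erase the
#' between-gene variation that the downstream invariant-gene filter and
#' discretizer rely on, so the global transform is deliberate.
#'
#' @param x Numeric matrix, patients in rows, genes in columns. Dimnames are
#'   preserved. Missing values are rejected.
#' @param log2_transform If `TRUE`, apply `log2()` to the entries first
#'   (intensities not already on the log scale).
#' @return A list with `z` (the standardized matrix), `mean` and `sd` (the
#'   global statistics needed to reproduce the transform on novel patients).
#' @export
normalize_expression <- function(x, log2_transform = FALSE) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("expression matrix must be numeric")
  if (anyNA(x)) stop("expression matrix contains missing values; complete matrices are required")
  if (log2_transform) {
    if (any(x <= 0)) stop("log2 transform requires strictly positive expression values")
    x <- log2(x)
  }
  mu <- mean(x)
  n_entries <- length(x)
  if (n_entries < 2) stop("need at least two expression entries")
  sigma2 <- sum((x - mu)^2) / (n_entries - 1)
  if (sigma2 <= 0) stop("expression matrix is constant (global variance is zero); cannot z-score")
  sigma <- sqrt(sigma2)
  list(z = (x - mu) / sigma, mean = mu, sd = sigma)
}

#' Remove genes that never leave the one-standard-deviation band
#'
#' After global z-scoring, a gene whose values sit entirely inside
#' `[-1, 1]` (closed interval) is considered uninformative and dropped.
#'
#' @param z Globally z-scored matrix (patients x genes).
#' @return Integer vector of retained column indices (named if `z` has
#'   column names).
#' @export
filter_invariant_genes <- function(z) {
  z <- as.matrix(z)
  max_abs <- apply(abs(z), 2, max)
  keep <- which(max_abs > 1)
  if (length(keep) == 0) stop("all genes fall inside [-1, 1]; no features left after filtering")
  keep
}

#' Impute and one-hot encode a clinical table
#'
#' Numeric features are mean-imputed; categorical features are mode-imputed
#' and then expanded to one binary column per observed level. The returned
#' state fragment carries the imputation values and level orders so the
#' identical mapping can be replayed on novel patients.
#'
#' @param clinical A data.frame of clinical features (no patient-id column).
#' @param types Named character vector mapping each feature to `"numeric"` or
#'   `"categorical"`. Defaults to the column classes.
#' @return List with `x` (numeric design matrix), `impute_values`,
#'   `category_levels`, `types`, and `feature_names` (source column per
#'   design column).
#' @export
prepare_clinical <- function(clinical, types = NULL) {
  clinical <- as.data.frame(clinical, stringsAsFactors = FALSE)
  if (nrow(clinical) < 1) stop("clinical table must contain at least one patient")
  if (is.null(types)) {
    types <- vapply(clinical, function(col) {
      if (is.numeric(col)) "numeric" else "categorical"
    }, character(1))
  }
  if (!all(names(clinical) %in% names(types))) {
    stop("types must name every clinical feature")
  }
  impute_values <- list()
  category_levels <- list()
  blocks <- list()
  feature_names <- character(0)
  for (f in names(clinical)) {
    col <- clinical[[f]]
    if (identical(types[[f]], "numeric")) {
      col <- as.numeric(col)
      obs <- col[!is.na(col)]
      if (length(obs) == 0) stop(sprintf("clinical feature '%s' has no observed values", f))
      m <- mean(obs)
      col[is.na(col)] <- m
      impute_values[[f]] <- m
      blocks[[f]] <- matrix(col, ncol = 1, dimnames = list(NULL, f))
      feature_names <- c(feature_names, f)
    } else {
      col <- as.character(col)
      col[!is.na(col) & col == ""] <- NA
      obs <- col[!is.na(col)]
      if (length(obs) == 0) stop(sprintf("clinical feature '%s' has no observed values", f))
      tab <- table(obs)
      mode_level <- names(tab)[which.max(tab)]  # ties -> first alphabetically
      col[is.na(col)] <- mode_level
      levs <- sort(unique(obs))
      impute_values[[f]] <- mode_level
      category_levels[[f]] <- levs
      onehot <- matrix(0, nrow = length(col), ncol = length(levs),
                       dimnames = list(NULL, paste(f, levs, sep = "=")))
      for (k in seq_along(levs)) onehot[col == levs[k], k] <- 1
      blocks[[f]] <- onehot
      feature_names <- c(feature_names, rep(f, length(levs)))
    }
  }
  x <- do.call(cbind, blocks)
  rownames(x) <- rownames(clinical)
  list(x = x, impute_values = impute_values, category_levels = category_levels,
       types = types, feature_names = feature_names)
}

#' Fit the full preprocessing state on a training cohort
#'
#' Runs the training-time preprocessing: global z-scoring of expression
#' (optionally after log2), invariant-gene filtering, and clinical
#' imputation + one-hot encoding. Returns the normalized matrices together
#' with the reusable state needed to preprocess novel patients.
#'
#' @param expression Patients x genes numeric matrix with dimnames.
#' @param clinical Optional data.frame of clinical features aligned with the
#'   expression rows (may be `NULL`).
#' @param clinical_types Optional named type vector for [prepare_clinical()].
#' @param log2_transform Passed to [normalize_expression()].
#' @return An object of class `preprocess_state` with elements `z` (filtered
#'   z-score matrix), `clinical_x`, and the state fields (`mean`, `sd`,
#'   `retained_genes`, `impute_values`, `category_levels`, `bins` slot filled
#'   later by [fit_discretizer()]).
#' @export
fit_preprocess <- function(expression, clinical = NULL, clinical_types = NULL,
                           log2_transform = FALSE) {
  norm <- normalize_expression(expression, log2_transform = log2_transform)
  keep <- filter_invariant_genes(norm$z)
  z <- norm$z[, keep, drop = FALSE]
  clin <- NULL
  clinical_x <- NULL
  if (!is.null(clinical)) {
    clin <- prepare_clinical(clinical, types = clinical_types)
    clinical_x <- clin$x
  }
  state <- list(
    mean = norm$mean,
    sd = norm$sd,
    log2_transform = log2_transform,
    all_genes = colnames(as.matrix(expression)),
    retained_genes = colnames(z),
    retained_idx = unname(keep),
    impute_values = if (is.null(clin)) NULL else clin$impute_values,
    category_levels = if (is.null(clin)) NULL else clin$category_levels,
    clinical_types = if (is.null(clin)) NULL else clin$types,
    clinical_columns = if (is.null(clin)) NULL else colnames(clin$x),
    bins = NULL,
    z = z,
    clinical_x = clinical_x
  )
  class(state) <- "preprocess_state"
  state
}

#' Apply a fitted preprocessing state to novel patients
#'
#' Replays the stored transform: log2 (if used), global z-score with the
#' *training* mean/sd, restriction to the retained genes, and clinical
#' imputation/one-hot with the training imputation values and level order.
#' A categorical level never seen in training maps to an all-zero block for
#' that feature, with a warning.
#'
#' @param state A `preprocess_state` from [fit_preprocess()].
#' @param expression Patients x genes matrix over the training gene set
#'   (any column order; matched by name when dimnames are present).
#' @param clinical Optional clinical data.frame with the training schema.
#' @return List with `z` (retained-gene z-scores) and `clinical_x`.
#' @export
apply_preprocess <- function(state, expression, clinical = NULL) {
  stopifnot(inherits(state, "preprocess_state"))
  x <- as.matrix(expression)
  if (anyNA(x)) stop("expression matrix contains missing values")
  if (!is.null(colnames(x)) && !is.null(state$all_genes)) {
    missing_genes <- setdiff(state$all_genes, colnames(x))
    extra <- setdiff(colnames(x), state$all_genes)
    if (length(extra) > 0) stop("unknown gene IDs: ", paste(utils::head(extra, 5), collapse = ", "))
    if (length(missing_genes) > 0) stop("missing gene IDs: ", paste(utils::head(missing_genes, 5), collapse = ", "))
    x <- x[, state$all_genes, drop = FALSE]
  } else if (ncol(x) != length(state$all_genes)) {
    stop("expression matrix has ", ncol(x), " genes; training had ", length(state$all_genes))
  }
  if (state$log2_transform) {
    if (any(x <= 0)) stop("log2 transform requires strictly positive values")
    x <- log2(x)
  }
  z <- (x - state$mean) / state$sd
  z <- z[, state$retained_idx, drop = FALSE]
  clinical_x <- NULL
  if (!is.null(clinical)) {
    if (is.null(state$clinical_types)) stop("state was fitted without clinical features")
    clinical <- as.data.frame(clinical, stringsAsFactors = FALSE)
    need <- names(state$clinical_types)
    if (!all(need %in% names(clinical))) {
      stop("clinical table is missing features: ",
           paste(setdiff(need, names(clinical)), collapse = ", "))
    }
    blocks <- list()
    for (f in need) {
      col <- clinical[[f]]
      if (identical(state$clinical_types[[f]], "numeric")) {
        col <- as.numeric(col)
        col[is.na(col)] <- state$impute_values[[f]]
        blocks[[f]] <- matrix(col, ncol = 1, dimnames = list(NULL, f))
      } else {
        col <- as.character(col)
        col[!is.na(col) & col == ""] <- NA
        col[is.na(col)] <- state$impute_values[[f]]
        levs <- state$category_levels[[f]]
        unseen <- setdiff(unique(col), levs)
        if (length(unseen) > 0) {
          warning(sprintf("feature '%s': unseen level(s) %s map to all-zero encoding",
                          f, paste(unseen, collapse = ", ")))
        }
        onehot <- matrix(0, nrow = length(col), ncol = length(levs),
                         dimnames = list(NULL, paste(f, levs, sep = "=")))
        for (k in seq_along(levs)) onehot[col == levs[k], k] <- 1
        blocks[[f]] <- onehot
      }
    }
    clinical_x <- do.call(cbind, blocks)
    rownames(clinical_x) <- rownames(clinical)
  }
  list(z = z, clinical_x = clinical_x)
}

#' @export
print.preprocess_state <- function(x, ...) {
  cat("Preprocessing state\n")
  cat(sprintf("  global mean %.4f, sd %.4f%s\n", x$mean, x$sd,
              if (x$log2_transform) " (after log2)" else ""))
  cat(sprintf("  genes: %d retained of %d\n",
              length(x$retained_genes), length(x$all_genes)))
  if (!is.null(x$clinical_columns)) {
    cat(sprintf("  clinical design: %d columns from %d features\n",
                length(x$clinical_columns), length(x$clinical_types)))
  }
  if (!is.null(x$bins)) cat("  discretizer bins: fitted\n")
  invisible(x)
}

#' Read an expression table from delimited text
#'
#' Expects a TSV whose first column holds IDs and whose header row holds the
#' other axis' IDs. Internally the canonical orientation is patients x genes;
#' use `transpose = TRUE` when the file stores genes as rows.
#'
#' @param path File path.
#' @param transpose If `TRUE`, rows of the file are genes and columns are
#'   patients.
#' @return Numeric matrix, patients in rows, genes in columns.
#' @export
read_expression <- function(path, transpose = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate IDs in first column of ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (transpose) m <- t(m)
  if (anyNA(m)) stop("missing expression entries are not supported")
  m
}

#' Read a clinical table with a column-type schema
#'
#' @param path CSV with header; one column must be `patient_id`.
#' @param schema_path Optional CSV with columns `feature,type` where type is
#'   `numeric` or `categorical`; unlisted columns fall back to their R class.
#' @return List with `patient_ids`, `data` (data.frame of features), and
#'   `types` (named character vector).
#' @export
read_clinical <- function(path, schema_path = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(df)) stop("clinical table needs a patient_id column")
  ids <- as.character(df$patient_id)
  df <- df[, setdiff(names(df), "patient_id"), drop = FALSE]
  types <- vapply(df, function(col) if (is.numeric(col)) "numeric" else "categorical",
                  character(1))
  if (!is.null(schema_path)) {
    sch <- utils::read.csv(schema_path, stringsAsFactors = FALSE)
    if (!all(c("feature", "type") %in% names(sch))) {
      stop("schema file needs columns feature,type")
    }
    bad <- setdiff(sch$feature, names(df))
    if (length(bad) > 0) stop("schema names unknown features: ", paste(bad, collapse = ", "))
    types[sch$feature] <- sch$type
  }
  list(patient_ids = ids, data = df, types = types)
}

#' Read survival labels (time in days, event indicator)
#'
#' @param path CSV with columns `patient_id`, `time`, `event`.
#' @return A `survival_labels` list with `patient_ids`, `time`, `event`.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("patient_id", "time", "event") %in% names(df))) {
    stop("labels file needs columns patient_id, time, event")
  }
  survival_labels(df$time, df$event, patient_ids = as.character(df$patient_id))
}

#' Construct survival labels
#'
#' @param time Non-negative follow-up times (days).
#' @param event Event indicator: 1 = death observed, 0 = right-censored.
#' @param patient_ids Optional IDs.
#' @return A `survival_labels` list.
#' @export
survival_labels <- function(time, event, patient_ids = NULL) {
  time <- as.numeric(time)
  event <- as.integer(event)
  if (any(time < 0) || anyNA(time)) stop("times must be non-negative and non-missing")
  if (!all(event %in% c(0L, 1L))) stop("event must be 0 (censored) or 1 (death)")
  if (length(time) != length(event)) stop("time and event lengths differ")
  structure(list(patient_ids = patient_ids, time = time, event = event),
            class = "survival_labels")
}
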