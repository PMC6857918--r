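BUNDLE_VERSION <- 1L

#' Fit a survival model with topic and/or component expression features
#'
#' The main fitting function. Runs training-time preprocessing (global
#' z-scoring, invariant-gene filtering, clinical imputation + one-hot),
#' computes the requested expression bases — a dLDA topic basis (with
#' cross-validated encoding and topic count unless the grids are singletons)
#' and/or a SuperPC+ component basis — assembles the feature matrix
#' `[clinical | PC scores | topic loadings]`, and fits the requested
#' survival learner: `"mtlr"` (individual survival distributions), `"cox"`
#' (partial likelihood), or `"rcox"` (ridge Cox with cross-validated
#' penalty).
#'
#' @param expression Patients x genes numeric matrix with row/column names.
#' @param clinical Optional clinical data.frame aligned with the expression
#'   rows (matched by `patient_id` row names when present).
#' @param labels A `survival_labels` object.
#' @param features Subset of `c("clinical", "dlda", "pca")`.
#' @param learner `"mtlr"`, `"cox"`, or `"rcox"`.
#' @param k_grid Topic-count grid for the dLDA search.
#' @param encodings dGEV encoding grid.
#' @param eta_grid p-value thresholds for SuperPC+.
#' @param c_grid MTLR regularization grid.
#' @param lambda_grid Ridge grid for `"rcox"`.
#' @param n_folds Internal cross-validation folds.
#' @param seed Integer seed for every stochastic step.
#' @param log2_transform Apply log2 to expression first.
#' @param clinical_types Optional named type vector for the clinical table.
#' @param exclude_clinical Clinical features to drop before fitting.
#' @return An object of class `survtopic` carrying the preprocessing state,
#'   fitted bases, learner fit, feature-column order, and training data
#'   summaries. Supports `print`, `summary`, `coef`, `predict`, `plot`,
#'   and `simulate`.
#' @export
survtopic <- function(expression, clinical = NULL, labels,
                      features = c("clinical", "dlda"),
                      learner = c("mtlr", "cox", "rcox"),
                      k_grid = seq(5, 150, by = 5),
                      encodings = c("enc_a", "enc_b"),
                      eta_grid = c(5e-4, 5e-3, 5e-2),
                      c_grid = c(0.01, 0.1, 1, 10),
                      lambda_grid = c(0.01, 0.1, 1, 10),
                      n_folds = 5, seed = 1, log2_transform = FALSE,
                      clinical_types = NULL, exclude_clinical = NULL) {
  learner <- match.arg(learner)
  features <- match.arg(features, c("clinical", "dlda", "pca"), several.ok = TRUE)
  stopifnot(inherits(labels, "survival_labels"))
  expression <- as.matrix(expression)
  if (!is.null(labels$patient_ids) && !is.null(rownames(expression))) {
    mism <- union(setdiff(rownames(expression), labels$patient_ids),
                  setdiff(labels$patient_ids, rownames(expression)))
    if (length(mism) > 0) {
      stop("patient IDs disagree between expression and labels: ",
           paste(utils::head(mism, 5), collapse = ", "))
    }
    expression <- expression[labels$patient_ids, , drop = FALSE]
  }
  if (!is.null(clinical)) {
    clinical <- as.data.frame(clinical, stringsAsFactors = FALSE)
    if (!is.null(exclude_clinical)) {
      clinical <- clinical[, setdiff(names(clinical), exclude_clinical), drop = FALSE]
      if (!is.null(clinical_types)) {
        clinical_types <- clinical_types[setdiff(names(clinical_types), exclude_clinical)]
      }
    }
    if (!is.null(labels$patient_ids) && !is.null(rownames(clinical)) &&
        !all(rownames(clinical) == as.character(seq_len(nrow(clinical))))) {
      mism <- union(setdiff(rownames(clinical), labels$patient_ids),
                    setdiff(labels$patient_ids, rownames(clinical)))
      if (length(mism) > 0) {
        stop("patient IDs disagree between clinical table and labels: ",
             paste(utils::head(mism, 5), collapse = ", "))
      }
      clinical <- clinical[labels$patient_ids, , drop = FALSE]
    }
  }
  if (nrow(expression) != length(labels$time)) stop("expression and labels are misaligned")

  use_clin <- "clinical" %in% features && !is.null(clinical)
  state <- fit_preprocess(expression, clinical = if (use_clin) clinical else NULL,
                          clinical_types = clinical_types,
                          log2_transform = log2_transform)
  z <- state$z
  blocks <- list()
  if (use_clin) blocks$clinical <- state$clinical_x

  pc_basis <- NULL
  if ("pca" %in% features) {
    pc_basis <- fit_superpc(z, labels, eta_grid = eta_grid,
                            n_folds = n_folds, seed = seed)
    blocks$pca <- project_superpc(z, pc_basis)
  }

  topic_basis <- NULL
  bins <- NULL
  selection <- NULL
  if ("dlda" %in% features) {
    selection <- select_basis(z, if (use_clin) state$clinical_x else NULL, labels,
                              k_grid = k_grid, encodings = encodings,
                              n_folds = n_folds, seed = seed)
    topic_basis <- selection$basis
    bins <- selection$bins
    state$bins <- bins
    corpus <- encode_counts(discretize_expression(z, bins), topic_basis$encoding)
    blocks$dlda <- infer_loadings(corpus, topic_basis)
  }
  if (length(blocks) == 0) stop("no feature groups requested (or clinical table absent)")
  x <- do.call(cbind, blocks)
  rownames(x) <- rownames(z)

  model <- switch(learner,
    mtlr = fit_mtlr(x, labels, c_grid = c_grid, n_folds = n_folds, seed = seed),
    cox = tryCatch(fit_cox(x, labels, lambda = 0),
                   error = function(e) {
                     warning("unpenalized Cox failed (", conditionMessage(e),
                             "); refitting with lambda = 0.1")
                     fit_cox(x, labels, lambda = 0.1)
                   }),
    rcox = .fit_rcox_cv(x, labels, lambda_grid, n_folds, seed))

  structure(list(
    version = BUNDLE_VERSION,
    state = .strip_state(state),
    topic_basis = topic_basis,
    pc_basis = pc_basis,
    selection = selection,
    learner = learner,
    model = model,
    feature_groups = names(blocks),
    feature_columns = colnames(x),
    features = x,
    labels = labels,
    seed = seed,
    call = match.call()
  ), class = "survtopic")
}

# drop the training matrices from the stored state; the bundle keeps only
# what prediction needs
.strip_state <- function(state) {
  state$z <- NULL
  state$clinical_x <- NULL
  state
}

.fit_rcox_cv <- function(x, labels, lambda_grid, n_folds, seed) {
  if (length(lambda_grid) == 1) return(fit_cox(x, labels, lambda = lambda_grid))
  folds <- .stratified_folds(labels$event, n_folds, seed)
  scores <- vapply(lambda_grid, function(lam) {
    ci <- vapply(seq_len(max(folds)), function(f) {
      te <- which(folds == f)
      tr <- setdiff(seq_len(nrow(x)), te)
      fit <- fit_cox(x[tr, , drop = FALSE],
                     survival_labels(labels$time[tr], labels$event[tr]), lambda = lam)
      risks <- drop(x[te, , drop = FALSE] %*% fit$coefficients)
      tryCatch(concordance_index(risks, survival_labels(labels$time[te], labels$event[te])),
               error = function(e) NA_real_)
    }, numeric(1))
    mean(ci, na.rm = TRUE)
  }, numeric(1))
  best <- lambda_grid[which.max(scores)]
  fit <- fit_cox(x, labels, lambda = best)
  fit$cv <- data.frame(lambda = lambda_grid, concordance = scores)
  fit
}

#' Predict survival curves and risk scores for novel patients
#'
#' Replays the stored preprocessing on the raw inputs, projects onto the
#' stored bases, assembles features in the recorded column order, and emits
#' each patient's survival curve and risk score (negative expected survival
#' time). Requires no training data.
#'
#' @param object A fitted `survtopic` model.
#' @param expression Patients x genes matrix over the training gene set.
#' @param clinical Clinical data.frame with the training schema (if the
#'   model used clinical features).
#' @param type `"risk"` (vector), `"curve"` (list of `survival_curve`), or
#'   `"both"` (list with both).
#' @param ... Unused.
#' @return Per `type`.
#' @export
predict.survtopic <- function(object, expression, clinical = NULL,
                              type = c("both", "risk", "curve"), ...) {
  type <- match.arg(type)
  pre <- apply_preprocess(object$state, expression,
                          clinical = if ("clinical" %in% object$feature_groups) clinical else NULL)
  blocks <- list()
  if ("clinical" %in% object$feature_groups) blocks$clinical <- pre$clinical_x
  if ("pca" %in% object$feature_groups) {
    blocks$pca <- project_superpc(pre$z, object$pc_basis)
  }
  if ("dlda" %in% object$feature_groups) {
    if (is.null(object$topic_basis)) stop("bundle flags dLDA features but has no topic basis")
    corpus <- encode_counts(discretize_expression(pre$z, object$state$bins),
                            object$topic_basis$encoding)
    blocks$dlda <- infer_loadings(corpus, object$topic_basis)
  }
  x <- do.call(cbind, blocks)
  if (!identical(colnames(x), object$feature_columns)) {
    if (!setequal(colnames(x), object$feature_columns)) {
      stop("assembled feature columns do not match the trained model")
    }
    x <- x[, object$feature_columns, drop = FALSE]
  }
  curves <- switch(object$learner,
    mtlr = lapply(seq_len(nrow(x)), function(i) mtlr_survival_curve(object$model, x[i, ])),
    cox = ,
    rcox = lapply(seq_len(nrow(x)), function(i) cox_survival_curve(object$model, x[i, ])))
  risks <- vapply(curves, risk_from_curve, numeric(1))
  names(risks) <- rownames(as.matrix(expression))
  switch(type,
         risk = risks,
         curve = curves,
         both = list(risk = risks, curves = curves, features = x))
}

#' Save a fitted model bundle
#'
#' Writes a versioned, self-contained bundle; [load_bundle()] restores it
#' and validates the format version and internal consistency.
#'
#' @param object A `survtopic` model.
#' @param path Destination file.
#' @return Invisibly, `path`.
#' @export
save_bundle <- function(object, path) {
  stopifnot(inherits(object, "survtopic"))
  saveRDS(list(format = "survtopics_bundle", version = BUNDLE_VERSION,
               object = object), path)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  raw <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot read bundle at ", path, ": ", conditionMessage(e))
  })
  if (!is.list(raw) || !identical(raw$format, "survtopics_bundle")) {
    stop("file is not a survtopics bundle")
  }
  if (!identical(raw$version, BUNDLE_VERSION)) {
    stop("bundle format version ", raw$version, " is not supported (expected ",
         BUNDLE_VERSION, ")")
  }
  object <- raw$object
  if ("dlda" %in% object$feature_groups && is.null(object$topic_basis)) {
    stop("corrupt bundle: dLDA features flagged but no topic basis stored")
  }
  if ("pca" %in% object$feature_groups && is.null(object$pc_basis)) {
    stop("corrupt bundle: PCA features flagged but no component basis stored")
  }
  object
}

#' @export
print.survtopic <- function(x, ...) {
  cat("Survival model with expression-derived features\n")
  cat(sprintf("  learner: %s; feature groups: %s (%d columns)\n",
              toupper(x$learner), paste(x$feature_groups, collapse = " + "),
              length(x$feature_columns)))
  if (!is.null(x$topic_basis)) {
    cat(sprintf("  dLDA basis: K = %d, encoding %s\n",
                x$topic_basis$k, x$topic_basis$encoding))
  }
  if (!is.null(x$pc_basis)) {
    cat(sprintf("  SuperPC+: %d components at eta = %g\n",
                length(x$pc_basis$selected), x$pc_basis$eta))
  }
  cat(sprintf("  training: %d patients, %d events\n",
              length(x$labels$time), sum(x$labels$event)))
  invisible(x)
}

#' @export
summary.survtopic <- function(object, ...) {
  risks <- vapply(seq_len(nrow(object$features)), function(i) {
    curve <- switch(object$learner,
      mtlr = mtlr_survival_curve(object$model, object$features[i, ]),
      cox = ,
      rcox = cox_survival_curve(object$model, object$features[i, ]))
    risk_from_curve(curve)
  }, numeric(1))
  ci <- concordance_index(risks, object$labels)
  out <- list(object = object, training_concordance = ci,
              risk_summary = summary(risks))
  class(out) <- "summary.survtopic"
  out
}

#' @export
print.summary.survtopic <- function(x, ...) {
  print(x$object)
  cat(sprintf("  apparent (training) concordance: %.4f\n", x$training_concordance))
  cat("  risk score distribution:\n")
  print(x$risk_summary)
  invisible(x)
}

#' @export
coef.survtopic <- function(object, ...) coef(object$model)

#' @export
plot.survtopic <- function(x, expression = NULL, clinical = NULL,
                           max_curves = 10, ...) {
  if (is.null(expression)) {
    idx <- seq_len(min(max_curves, nrow(x$features)))
    curves <- lapply(idx, function(i) {
      switch(x$learner,
        mtlr = mtlr_survival_curve(x$model, x$features[i, ]),
        cox = ,
        rcox = cox_survival_curve(x$model, x$features[i, ]))
    })
  } else {
    curves <- predict(x, expression, clinical, type = "curve")
    curves <- curves[seq_len(min(max_curves, length(curves)))]
  }
  plot(curves[[1]], col = 1, ...)
  if (length(curves) > 1) {
    for (i in 2:length(curves)) {
      graphics::lines(curves[[i]]$time, curves[[i]]$surv, type = "s", col = i)
    }
  }
  invisible(x)
}

#' Simulate survival labels from a fitted model's own predictions
#'
#' Draws death times from each training patient's predicted survival curve
#' (see [generate_mtlr_consistent()]); useful for calibration diagnostics.
#'
#' @param object A `survtopic` model.
#' @param nsim Number of label sets to simulate.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of `survival_labels` (or a single one when `nsim = 1`).
#' @export
simulate.survtopic <- function(object, nsim = 1, seed = 1, ...) {
  curves <- lapply(seq_len(nrow(object$features)), function(i) {
    switch(object$learner,
      mtlr = mtlr_survival_curve(object$model, object$features[i, ]),
      cox = ,
      rcox = cox_survival_curve(object$model, object$features[i, ]))
  })
  out <- lapply(seq_len(nsim), function(s) {
    generate_mtlr_consistent(curves, seed = seed + s - 1)
  })
  if (nsim == 1) out[[1]] else out
}

#' Event-stratified train/test split
#'
#' Random split keeping the censored-versus-uncensored ratio comparable
#' between the two parts.
#'
#' @param labels A `survival_labels` object.
#' @param test_fraction Fraction held out.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
train_test_split <- function(labels, test_fraction = 0.2, seed = 1) {
  stopifnot(inherits(labels, "survival_labels"))
  set.seed(as.integer(seed %% .Machine$integer.max))
  test <- integer(0)
  for (s in unique(labels$event)) {
    idx <- which(labels$event == s)
    n_test <- round(length(idx) * test_fraction)
    test <- c(test, sample(idx, n_test))
  }
  test <- sort(test)
  list(train = setdiff(seq_along(labels$time), test), test = test)
}
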