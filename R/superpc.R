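#' Fit a supervised principal-component basis (SuperPC+)
#'
#' PCA is run on the full filtered, globally z-scored expression matrix
#' (centered, not re-scaled), then each component's score vector is tested
#' for univariate association with survival via a one-covariate Cox fit
#' (Wald test). Components with p-value below the threshold `eta` are
#' retained; `eta` itself is chosen from `eta_grid` by event-stratified
#' cross-validation maximizing held-out concordance of a Cox model on the
#' selected components. If no component passes any threshold, the single
#' best-p component is kept with a warning.
#'
#' @param z Filtered z-scored expression matrix (patients x genes).
#' @param labels A `survival_labels` object.
#' @param eta_grid Candidate p-value thresholds.
#' @param n_folds Cross-validation folds for the eta search.
#' @param seed Integer seed (fold assignment).
#' @param max_components Optional cap on the number of components examined.
#' @return An object of class `pc_basis`: `rotation` (genes x components,
#'   orthonormal), `center`, `p_values`, `selected` (component indices),
#'   `eta`, `cv` (eta-search table), `gene_ids`.
#' @export
fit_superpc <- function(z, labels, eta_grid = c(5e-4, 5e-3, 5e-2),
                        n_folds = 5, seed = 1, max_components = NULL) {
  stopifnot(inherits(labels, "survival_labels"))
  z <- as.matrix(z)
  n <- nrow(z)
  if (n < 2) stop("need at least two patients")
  center <- colMeans(z)
  zc <- sweep(z, 2, center)
  sv <- svd(zc)
  keep <- which(sv$d > max(sv$d[1], 1) * 1e-10)
  if (!is.null(max_components)) keep <- keep[seq_len(min(length(keep), max_components))]
  rotation <- sv$v[, keep, drop = FALSE]
  scores <- zc %*% rotation                        # n x n_comp, = u * d
  colnames(rotation) <- colnames(scores) <- paste0("PC", seq_along(keep))
  rownames(rotation) <- colnames(z)
  p_values <- apply(scores, 2, function(s) .cox_wald_p(s, labels))
  cv_tab <- NULL
  if (length(eta_grid) > 1) {
    folds <- .stratified_folds(labels$event, n_folds, seed)
    cv_scores <- vapply(eta_grid, function(eta) {
      sel <- which(p_values < eta)
      if (length(sel) == 0) return(NA_real_)
      fold_ci <- vapply(seq_len(max(folds)), function(f) {
        te <- which(folds == f)
        tr <- setdiff(seq_len(n), te)
        lbl_tr <- survival_labels(labels$time[tr], labels$event[tr])
        lbl_te <- survival_labels(labels$time[te], labels$event[te])
        cox <- tryCatch(fit_cox(scores[tr, sel, drop = FALSE], lbl_tr, lambda = 0),
                        error = function(e) fit_cox(scores[tr, sel, drop = FALSE],
                                                    lbl_tr, lambda = 0.1))
        risks <- drop(scores[te, sel, drop = FALSE] %*% cox$coefficients)
        tryCatch(concordance_index(risks, lbl_te), error = function(e) NA_real_)
      }, numeric(1))
      mean(fold_ci, na.rm = TRUE)
    }, numeric(1))
    cv_tab <- data.frame(eta = eta_grid, concordance = cv_scores)
    eta <- if (all(is.na(cv_scores))) eta_grid[length(eta_grid)] else eta_grid[which.max(cv_scores)]
  } else {
    eta <- eta_grid[1]
  }
  selected <- which(p_values < eta)
  if (length(selected) == 0) {
    warning("no component passes eta = ", eta, "; keeping the single best-p component")
    selected <- which.min(p_values)
  }
  structure(list(rotation = rotation, center = center, p_values = p_values,
                 selected = unname(selected), eta = eta, cv = cv_tab,
                 gene_ids = colnames(z)),
            class = "pc_basis")
}

.cox_wald_p <- function(s, labels) {
  fit <- tryCatch(fit_cox(matrix(s, ncol = 1), labels, lambda = 0),
                  error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$se[1]) || fit$se[1] == 0) return(1)
  z <- fit$coefficients[1] / fit$se[1]
  stats::pchisq(z^2, df = 1, lower.tail = FALSE)
}

#' Project expression onto the selected supervised components
#'
#' Centers with the training means and projects onto the retained
#' orthonormal directions. Deterministic.
#'
#' @param z Z-scored expression vector or matrix over the basis gene set.
#' @param basis A `pc_basis`.
#' @return Matrix of component scores (patients x selected components).
#' @export
project_superpc <- function(z, basis) {
  stopifnot(inherits(basis, "pc_basis"))
  if (is.null(dim(z))) z <- matrix(z, nrow = 1, dimnames = list(NULL, names(z)))
  z <- as.matrix(z)
  if (ncol(z) != length(basis$center)) {
    stop("gene set mismatch: input has ", ncol(z), " genes, basis expects ",
         length(basis$center))
  }
  if (!is.null(colnames(z)) && !is.null(basis$gene_ids) &&
      !identical(colnames(z), basis$gene_ids)) {
    if (!setequal(colnames(z), basis$gene_ids)) stop("gene set mismatch")
    z <- z[, basis$gene_ids, drop = FALSE]
  }
  zc <- sweep(z, 2, basis$center)
  zc %*% basis$rotation[, basis$selected, drop = FALSE]
}

#' @export
print.pc_basis <- function(x, ...) {
  cat(sprintf("SuperPC+ basis: %d of %d components retained at eta = %g\n",
              length(x$selected), ncol(x$rotation), x$eta))
  invisible(x)
}
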