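#' Fit per-gene discretization bins
#'
#' For each gene, the non-trivial positive z-scores (z >= 1) define ten
#' equal-width bins spanning `[min+, min+ + delta+]` with
#' `delta+ = max - min` of that side; the negative side (z <= -1) is handled
#' symmetrically. A side with no non-trivial values is marked absent; a side
#' with a single value has width zero and maps to bin 1 (resp. -1).
#'
#' @param z Z-scored matrix over the retained genes (patients x genes).
#' @return A `dgev_bins` object: per-gene `min_pos`, `delta_pos`, `min_neg`,
#'   `delta_neg` (NA where the side is absent), with gene names.
#' @export
fit_discretizer <- function(z) {
  z <- as.matrix(z)
  p <- ncol(z)
  min_pos <- delta_pos <- min_neg <- delta_neg <- rep(NA_real_, p)
  for (i in seq_len(p)) {
    v <- z[, i]
    pos <- v[v >= 1]
    if (length(pos) > 0) {
      min_pos[i] <- min(pos)
      delta_pos[i] <- max(pos) - min(pos)
    }
    neg <- v[v <= -1]
    if (length(neg) > 0) {
      min_neg[i] <- max(neg)          # side entry closest to -1
      delta_neg[i] <- max(neg) - min(neg)
    }
  }
  structure(list(gene_ids = colnames(z), min_pos = min_pos, delta_pos = delta_pos,
                 min_neg = min_neg, delta_neg = delta_neg),
            class = "dgev_bins")
}

#' Discretize z-scores into integer bins (dGEVs)
#'
#' Maps each z-score to an integer in `{-10, ..., 10}`: values inside the
#' open band `(-1, 1)` map to 0; a positive non-trivial value maps to
#' `min(10, 1 + floor((z - min+) / (delta+/10)))` so the top edge is
#' inclusive; the negative side mirrors this. Values beyond the training
#' range clamp to the extreme bin (below the training minimum, to bin 1).
#'
#' @param z Z-scored matrix (or vector treated as one patient).
#' @param bins A `dgev_bins` object fitted on training data.
#' @return Integer matrix of the same shape, entries in -10..10.
#' @export
discretize_expression <- function(z, bins) {
  stopifnot(inherits(bins, "dgev_bins"))
  if (is.null(dim(z))) z <- matrix(z, nrow = 1, dimnames = list(NULL, names(z)))
  z <- as.matrix(z)
  if (ncol(z) != length(bins$min_pos)) {
    stop("z has ", ncol(z), " genes but bins were fitted for ", length(bins$min_pos))
  }
  if (!is.null(colnames(z)) && !is.null(bins$gene_ids) &&
      !identical(colnames(z), bins$gene_ids)) {
    if (!setequal(colnames(z), bins$gene_ids)) stop("gene set does not match fitted bins")
    z <- z[, bins$gene_ids, drop = FALSE]
  }
  b <- matrix(0L, nrow = nrow(z), ncol = ncol(z), dimnames = dimnames(z))
  for (i in seq_len(ncol(z))) {
    v <- z[, i]
    pos <- which(v >= 1)
    if (length(pos) > 0) {
      if (is.na(bins$min_pos[i])) stop("gene ", i, " has positive values but no fitted positive bins")
      b[pos, i] <- .bin_side(v[pos], bins$min_pos[i], bins$delta_pos[i])
    }
    neg <- which(v <= -1)
    if (length(neg) > 0) {
      if (is.na(bins$min_neg[i])) stop("gene ", i, " has negative values but no fitted negative bins")
      # mirror: distance from the edge entry closest to -1, growing downwards
      b[neg, i] <- -.bin_side(-v[neg], -bins$min_neg[i], bins$delta_neg[i])
    }
  }
  b
}

.bin_side <- function(v, side_min, side_delta) {
  if (side_delta <= 0) return(rep(1L, length(v)))
  width <- side_delta / 10
  idx <- 1L + as.integer(floor((v - side_min) / width))
  idx[idx < 1L] <- 1L      # below training range
  idx[idx > 10L] <- 10L    # top edge inclusive + clamp above range
  idx
}

#' Encode discretized expression as non-negative word counts
#'
#' Two encodings turn signed bin indices into the non-negative counts a
#' topic model needs. `enc_a` uses one word per gene with count `|b|`
#' (magnitude only, sign discarded). `enc_b` uses two words per gene,
#' `OVER-<gene>` and `UNDER-<gene>`: bin +2 becomes (OVER = 2, UNDER = 0)
#' and bin -3 becomes (OVER = 0, UNDER = 3).
#'
#' @param b Integer matrix of dGEVs from [discretize_expression()].
#' @param encoding `"enc_a"` or `"enc_b"`.
#' @return A `dgev_corpus` object: `counts` (patients x vocabulary integer
#'   matrix), `vocabulary`, `encoding`.
#' @export
encode_counts <- function(b, encoding = c("enc_b", "enc_a")) {
  encoding <- match.arg(encoding)
  b <- as.matrix(b)
  if (any(abs(b) > 10)) stop("corrupt discretized matrix: |bin| > 10")
  genes <- colnames(b)
  if (is.null(genes)) genes <- paste0("g", seq_len(ncol(b)))
  if (encoding == "enc_a") {
    counts <- abs(b)
    vocab <- genes
  } else {
    over <- pmax(b, 0L)
    under <- pmax(-b, 0L)
    counts <- cbind(over, under)
    vocab <- c(paste0("OVER-", genes), paste0("UNDER-", genes))
  }
  storage.mode(counts) <- "integer"
  colnames(counts) <- vocab
  structure(list(counts = counts, vocabulary = vocab, encoding = encoding),
            class = "dgev_corpus")
}

#' @export
print.dgev_corpus <- function(x, ...) {
  cat(sprintf("dGEV corpus: %d documents, vocabulary %d (%s), total count %d\n",
              nrow(x$counts), length(x$vocabulary), x$encoding, sum(x$counts)))
  invisible(x)
}
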