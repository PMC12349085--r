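#' Principal component analysis of a landmark matrix
#'
#' Covariance PCA (column centring, no per-landmark rescaling): the rows are
#' already standardised spectra, so rescaling each landmark would distort
#' relative peak-height information. Loadings column signs are fixed so that
#' each column's largest-magnitude entry is positive, making results
#' deterministic up to nothing.
#'
#' @param matrix An `xrf_landmarks` object, or a plain numeric matrix of
#'   row-vectors.
#' @param row_filter Optional logical or integer vector selecting rows
#'   (e.g. to reproduce a sub-PCA on sediment + one clade only).
#' @return An `xrf_pca` object: `scores`, `loadings` (columns orthonormal),
#'   `explained_variance_ratio`, `center`, `meta` (filtered row metadata,
#'   when available).
#' @export
fit_pca <- function(matrix, row_filter = NULL) {
  meta <- NULL
  if (inherits(matrix, "xrf_landmarks")) {
    meta <- matrix$meta
    x <- matrix$values
  } else {
    x <- as.matrix(matrix)
  }
  if (!is.null(row_filter)) {
    x <- x[row_filter, , drop = FALSE]
    if (!is.null(meta)) {
      meta <- meta[row_filter, , drop = FALSE]
      rownames(meta) <- NULL
    }
  }
  if (nrow(x) < 2L) stopf("PCA needs at least 2 rows (got %d)", nrow(x))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  loadings <- pc$rotation
  scores <- pc$x
  # sign convention: largest-|loading| entry of each component positive
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  var_j <- pc$sdev^2
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_ratio = var_j / sum(var_j),
                 center = pc$center, meta = meta),
            class = "xrf_pca")
}

#' @export
print.xrf_pca <- function(x, ...) {
  evr <- x$explained_variance_ratio
  cat(sprintf("<xrf_pca> %d rows, %d components; PC1 %.1f%%, PC1-4 %.1f%%\n",
              nrow(x$scores), ncol(x$scores), 100 * evr[1L],
              100 * sum(evr[seq_len(min(4L, length(evr)))])))
  invisible(x)
}

#' Project new landmark rows into an existing ordination
#'
#' @param pca An `xrf_pca` object.
#' @param new_rows Numeric matrix (or single vector) on the same landmark
#'   grid as the training data.
#' @return Score matrix `(new_rows - center) %*% loadings`.
#' @export
project_pca <- function(pca, new_rows) {
  stopifnot(inherits(pca, "xrf_pca"))
  if (is.null(dim(new_rows))) new_rows <- matrix(new_rows, nrow = 1L)
  new_rows <- as.matrix(new_rows)
  if (ncol(new_rows) != length(pca$center)) {
    stopf("new rows have %d landmarks; ordination expects %d",
          ncol(new_rows), length(pca$center))
  }
  sweep(new_rows, 2L, pca$center, `-`) %*% pca$loadings
}

#' Per-landmark contributions to principal components
#'
#' The contribution of landmark `l` to component `c` is the squared loading
#' `loadings[l, c]^2`; with orthonormal loadings each column sums to 1.
#'
#' @param pca An `xrf_pca` object.
#' @param components Number of leading components to return.
#' @return An 831 x `components` matrix of contributions.
#' @export
landmark_contributions <- function(pca, components = ncol(pca$loadings)) {
  stopifnot(inherits(pca, "xrf_pca"))
  if (components > ncol(pca$loadings)) {
    stopf("requested %d components but only %d available",
          components, ncol(pca$loadings))
  }
  pca$loadings[, seq_len(components), drop = FALSE]^2
}
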