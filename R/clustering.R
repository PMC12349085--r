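#' k-means clustering of ordination scores
#'
#' Lloyd iterations from k-means++ starting centres; the best of `n_init`
#' initialisations by total within-cluster sum of squares is kept.
#' Deterministic given `seed`.
#'
#' @param scores Numeric matrix of observations.
#' @param k Number of clusters (`k <= n`).
#' @param n_init Number of initialisations.
#' @param seed Integer seed.
#' @return An `xrf_cluster` object with `labels`, `method = "kmeans"`, `k`,
#'   and `diagnostics` (total within-cluster SS, centres).
#' @export
kmeans_cluster <- function(scores, k, n_init = 10, seed = 1L) {
  x <- as.matrix(scores)
  n <- nrow(x)
  if (k > n) stopf("k = %d exceeds the number of rows (%d)", k, n)
  with_seed(seed, {
    best <- NULL
    for (i in seq_len(n_init)) {
      centers <- kmeanspp_centers(x, k)
      km <- suppressWarnings(
        stats::kmeans(x, centers = centers, iter.max = 100L,
                      algorithm = "Lloyd"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    structure(list(labels = as.integer(best$cluster), method = "kmeans",
                   k = k,
                   diagnostics = list(inertia = best$tot.withinss,
                                      centers = best$centers)),
              class = "xrf_cluster")
  })
}

# k-means++ seeding: first centre uniform, then proportional to squared
# distance to the nearest chosen centre.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- rowSums(sweep(x, 2L, x[idx[1L], ], `-`)^2)
    for (j in 2:k) {
      if (sum(d2) <= 0) {
        # all remaining points coincide with chosen centres
        idx[j] <- sample(setdiff(seq_len(n), idx[seq_len(j - 1L)]), 1L)
      } else {
        idx[j] <- sample.int(n, 1L, prob = d2)
      }
      d2 <- pmin(d2, rowSums(sweep(x, 2L, x[idx[j], ], `-`)^2))
    }
  }
  x[idx, , drop = FALSE]
}

#' Ward hierarchical clustering of ordination scores
#'
#' Agglomerative merging minimising the Ward variance increase (`ward.D2`
#' on Euclidean distances); the dendrogram is cut at `k` clusters and the
#' full merge history retained.
#'
#' @param scores Numeric matrix of observations.
#' @param k Number of clusters after cutting.
#' @return An `xrf_cluster` object with `labels`, `method = "ward"`, `k`,
#'   and `diagnostics` (merge heights and the `hclust` tree).
#' @export
ward_cluster <- function(scores, k) {
  x <- as.matrix(scores)
  if (k > nrow(x)) stopf("k = %d exceeds the number of rows (%d)", k, nrow(x))
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  structure(list(labels = as.integer(stats::cutree(hc, k = k)),
                 method = "ward", k = k,
                 diagnostics = list(merge_heights = hc$height, tree = hc)),
            class = "xrf_cluster")
}

#' @export
print.xrf_cluster <- function(x, ...) {
  cat(sprintf("<xrf_cluster> %s, k = %d, sizes: %s\n", x$method, x$k,
              paste(table(x$labels), collapse = ", ")))
  invisible(x)
}

#' Match predicted cluster labels to reference labels
#'
#' Finds the one-to-one relabelling of predicted clusters maximising
#' agreement with the reference, by exhaustive search over permutations for
#' up to 8 classes (exact) and greedy confusion-matrix matching beyond.
#'
#' @param predicted Predicted cluster labels.
#' @param truth Reference labels, same length.
#' @return A list: `agreement` (fraction matched under the best
#'   relabelling), `mapping` (named vector predicted level -> truth level)
#'   and `confusion` (contingency table).
#' @export
match_labels <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stopf("label lengths differ")
  p <- factor(predicted)
  t_ <- factor(truth)
  conf <- table(predicted = p, truth = t_)
  m <- max(nlevels(p), nlevels(t_))
  sq <- matrix(0, m, m)
  sq[seq_len(nlevels(p)), seq_len(nlevels(t_))] <- conf
  if (m <= 8L) {
    perms <- all_permutations(m)
    agree <- vapply(seq_len(nrow(perms)), function(i) {
      sum(sq[cbind(seq_len(m), perms[i, ])])
    }, 0)
    best <- perms[which.max(agree), ]
    n_agree <- max(agree)
  } else {
    best <- integer(m)
    free <- rep(TRUE, m)
    work <- sq
    n_agree <- 0
    for (step in seq_len(m)) {
      i <- arrayInd(which.max(work), dim(work))
      best[i[1L]] <- i[2L]
      n_agree <- n_agree + work[i[1L], i[2L]]
      work[i[1L], ] <- -1
      work[, i[2L]] <- -1
      free[i[2L]] <- FALSE
    }
  }
  mapping_idx <- best[seq_len(nlevels(p))]
  mapping <- ifelse(mapping_idx <= nlevels(t_), levels(t_)[mapping_idx],
                    NA_character_)
  names(mapping) <- levels(p)
  list(agreement = n_agree / length(predicted), mapping = mapping,
       confusion = conf)
}

all_permutations <- function(m) {
  if (m == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(m - 1L)
  out <- matrix(0L, m * nrow(sub), m)
  r <- 0L
  for (pos in seq_len(m)) {
    left <- sub[, seq_len(pos - 1L), drop = FALSE]
    right <- if (pos <= m - 1L) sub[, pos:(m - 1L), drop = FALSE] else
      sub[, 0L, drop = FALSE]
    out[r + seq_len(nrow(sub)), ] <- cbind(left, m, right)
    r <- r + nrow(sub)
  }
  out
}
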