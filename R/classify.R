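#' Derive analysis class labels from zone metadata
#'
#' Sediment zones are labelled `"sediment"`; fossil zones carry their clade.
#' An optional mapping then collapses manifest clades to the analysis
#' granularity (e.g. order-level groups vs high-level clades).
#'
#' @param meta Manifest-style metadata data frame.
#' @param label_mapping Optional named character vector
#'   `manifest clade -> analysis class`; unmapped labels pass through.
#' @return Character vector of class labels, one per row.
#' @export
analysis_classes <- function(meta, label_mapping = NULL) {
  labels <- ifelse(meta$zone_type == "sediment", "sediment", meta$clade)
  if (!is.null(label_mapping)) {
    label_mapping <- unlist(label_mapping)
    hit <- labels %in% names(label_mapping)
    labels[hit] <- unname(label_mapping[labels[hit]])
  }
  labels
}

#' Linear discriminant analysis on ordination scores
#'
#' Classical LDA with pooled within-class covariance on the leading
#' `n_pcs` PCA scores. Classes represented by a single spectrum make the
#' pooled estimate fragile and are rejected by default; drop them from the
#' data (the robust variant of the analysis) or set
#' `allow_singleton = TRUE`.
#'
#' @param scores Numeric score matrix (rows = spectra).
#' @param labels Class label per row.
#' @param n_pcs Number of leading score columns to use (default: the lesser
#'   of 21 and the available columns).
#' @param priors `"proportional"` (class frequencies), `"uniform"`, or a
#'   numeric vector over the sorted class levels.
#' @param label_mapping Optional mapping applied to `labels` first (see
#'   [analysis_classes()]).
#' @param allow_singleton Permit single-row classes.
#' @return An `xrf_lda` object: the fitted `MASS::lda` model plus class
#'   means, discriminant scalings, axis singular values, priors, the pooled
#'   within-class covariance and `n_pcs`.
#' @export
fit_lda <- function(scores, labels, n_pcs = NULL, priors = "proportional",
                    label_mapping = NULL, allow_singleton = FALSE) {
  x <- as.matrix(scores)
  if (is.null(n_pcs)) n_pcs <- min(21L, ncol(x))
  if (n_pcs > ncol(x)) {
    stopf("n_pcs = %d exceeds available components (%d)", n_pcs, ncol(x))
  }
  x <- x[, seq_len(n_pcs), drop = FALSE]
  labels <- as.character(labels)
  if (!is.null(label_mapping)) {
    labels <- analysis_classes(
      data.frame(zone_type = "fossil", clade = labels), label_mapping)
  }
  g <- factor(labels)
  if (nlevels(g) < 2L) stopf("need at least 2 classes")
  counts <- table(g)
  if (any(counts < 2L) && !allow_singleton) {
    stopf(paste0("class(es) with a single spectrum: %s; drop them (the ",
                 "singleton-free analysis) or set allow_singleton = TRUE"),
          paste(names(counts)[counts < 2L], collapse = ", "))
  }
  prior <- if (identical(priors, "proportional")) {
    as.numeric(counts) / length(g)
  } else if (identical(priors, "uniform")) {
    rep(1 / nlevels(g), nlevels(g))
  } else {
    as.numeric(priors)
  }
  fit <- MASS::lda(x, grouping = g, prior = prior)
  # pooled within-class covariance (divide by n - k), kept for attribution
  # and posterior geometry
  k <- nlevels(g)
  xc <- x - fit$means[as.integer(g), , drop = FALSE]
  pooled <- crossprod(xc) / (nrow(x) - k)
  structure(list(lda = fit, classes = levels(g), means = fit$means,
                 scaling = fit$scaling, svd = fit$svd, priors = fit$prior,
                 pooled_cov = pooled, n_pcs = n_pcs, counts = counts,
                 label_mapping = label_mapping),
            class = "xrf_lda")
}

#' @export
print.xrf_lda <- function(x, ...) {
  cat(sprintf("<xrf_lda> %d classes on %d scores; %d discriminant axes\n",
              length(x$classes), x$n_pcs, ncol(x$scaling)))
  invisible(x)
}

#' Posterior class probabilities for new score rows
#'
#' Gaussian class-conditional posteriors under the pooled within-class
#' covariance; rows sum to 1. The hard label is the posterior argmax, with
#' exact ties broken by class order (with a warning).
#'
#' @param model An `xrf_lda` object.
#' @param scores Score matrix (or single row) on the same components the
#'   model was fitted on; extra trailing columns are dropped.
#' @return A list: `posterior` (rows x classes), `class` (hard labels).
#' @export
predict_posterior <- function(model, scores) {
  stopifnot(inherits(model, "xrf_lda"))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  scores <- as.matrix(scores)
  if (ncol(scores) < model$n_pcs) {
    stopf("scores have %d columns; model needs %d", ncol(scores),
          model$n_pcs)
  }
  scores <- scores[, seq_len(model$n_pcs), drop = FALSE]
  colnames(scores) <- colnames(model$means)
  post <- stats::predict(model$lda, newdata = scores)$posterior
  hard <- max.col(post, ties.method = "first")
  n_max <- rowSums(post == post[cbind(seq_len(nrow(post)), hard)])
  if (any(n_max > 1L)) {
    warnf("%d observation(s) with tied posteriors; first class by order kept",
          sum(n_max > 1L))
  }
  list(posterior = post, class = model$classes[hard])
}

#' Leave-one-out cross-validation of the LDA classifier
#'
#' For every spectrum, refit the LDA without it and classify it. Two modes:
#' `"pca_outside"` computes the PCA once on all rows and cross-validates
#' only the LDA (the headline procedure, a known source of mild optimism);
#' `"pca_inside"` also refits the PCA within each fold (leakage-free).
#' Both are reported by default.
#'
#' @param matrix An `xrf_landmarks` object (or a plain landmark-row
#'   matrix).
#' @param labels Class label per row.
#' @param n_pcs Number of leading principal components fed to the LDA.
#' @param modes Character vector among `"pca_outside"`, `"pca_inside"`.
#' @return An `xrf_loocv` object: per mode, `accuracy`, `confusion`
#'   (truth x predicted), `per_class_recall` and the predicted labels.
#' @export
loocv <- function(matrix, labels, n_pcs = 21L,
                  modes = c("pca_outside", "pca_inside")) {
  x <- if (inherits(matrix, "xrf_landmarks")) matrix$values else
    as.matrix(matrix)
  labels <- as.character(labels)
  n <- nrow(x)
  if (length(labels) != n) stopf("labels length %d != rows %d",
                                 length(labels), n)
  modes <- match.arg(modes, several.ok = TRUE)
  out <- list()
  for (mode in modes) {
    pred <- character(n)
    if (mode == "pca_outside") {
      pca <- fit_pca(x)
      sc <- pca$scores[, seq_len(min(n_pcs, ncol(pca$scores))), drop = FALSE]
      for (i in seq_len(n)) {
        pred[i] <- loocv_fold(sc[-i, , drop = FALSE], labels[-i],
                              sc[i, , drop = FALSE], labels[i])
      }
    } else {
      for (i in seq_len(n)) {
        pca_i <- fit_pca(x[-i, , drop = FALSE])
        kk <- min(n_pcs, ncol(pca_i$scores))
        sc_tr <- pca_i$scores[, seq_len(kk), drop = FALSE]
        sc_te <- project_pca(pca_i, x[i, ])[, seq_len(kk), drop = FALSE]
        pred[i] <- loocv_fold(sc_tr, labels[-i], sc_te, labels[i])
      }
    }
    truth_f <- factor(labels)
    conf <- table(truth = truth_f,
                  predicted = factor(pred, levels = union(levels(truth_f),
                                                          unique(pred))))
    acc <- mean(pred == labels)
    recall <- diag(conf[, levels(truth_f), drop = FALSE]) /
      rowSums(conf)
    out[[mode]] <- list(accuracy = acc, confusion = conf,
                        per_class_recall = recall, predictions = pred)
  }
  structure(c(out, list(n_pcs = n_pcs)), class = "xrf_loocv")
}

# One LOOCV fold; a fold whose training set loses a whole class (the held
# out row was a singleton) is counted as an error and logged.
loocv_fold <- function(x_train, y_train, x_test, y_test) {
  if (!y_test %in% y_train) {
    message(sprintf("loocv: class '%s' lost by its own fold; counted as error",
                    y_test))
    return("<failed>")
  }
  fit <- tryCatch(fit_lda(x_train, y_train, n_pcs = ncol(x_train),
                          allow_singleton = TRUE),
                  error = function(e) e)
  if (inherits(fit, "error")) {
    message(sprintf("loocv: fold failed (%s); counted as error",
                    conditionMessage(fit)))
    return("<failed>")
  }
  predict_posterior(fit, x_test)$class
}

#' @export
print.xrf_loocv <- function(x, ...) {
  for (mode in intersect(c("pca_outside", "pca_inside"), names(x))) {
    cat(sprintf("<xrf_loocv> %s: accuracy %.1f%% (%d PCs)\n", mode,
                100 * x[[mode]]$accuracy, x$n_pcs))
  }
  invisible(x)
}
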