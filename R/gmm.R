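# Gaussian mixture models with constrained covariance families.
#
# Families follow the volume/shape/orientation decomposition of covariance
# matrices Sigma_g = lambda_g * D_g %*% A_g %*% t(D_g):
#   EII  spherical, equal across components          Sigma_g = sigma^2 I
#   EEE  one full covariance shared by all           Sigma_g = Sigma
#   EEV  equal volume and shape, free orientation    Sigma_g = D_g L t(D_g)
#   VVV  unconstrained per component                 Sigma_g free
# EEV components share the eigenvalue spectrum L (pooled across components)
# but keep their own eigenvectors D_g.

gmm_families <- c("EII", "EEE", "EEV", "VVV")

#' Free-parameter count of a Gaussian mixture family
#'
#' Mixing weights contribute `k - 1`, means `k * d`, and the covariance
#' structure 1 (EII), `d(d+1)/2` (EEE), `d + k d(d-1)/2` (EEV) or
#' `k d(d+1)/2` (VVV) parameters.
#'
#' @param family One of `"EII", "EEE", "EEV", "VVV"`.
#' @param k Number of components.
#' @param d Data dimension.
#' @return Integer parameter count.
#' @export
gmm_n_params <- function(family, k, d) {
  family <- match.arg(family, gmm_families)
  base <- (k - 1) + k * d
  cov_p <- switch(family,
                  EII = 1,
                  EEE = d * (d + 1) / 2,
                  EEV = d + k * d * (d - 1) / 2,
                  VVV = k * d * (d + 1) / 2)
  as.integer(base + cov_p)
}

log_dmvnorm <- function(x, mean, sigma) {
  d <- length(mean)
  ch <- chol(sigma)  # caller handles failure
  z <- forwardsolve(t(ch), t(x) - mean)
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))) + colSums(z^2))
}

# Family-specific covariance M-step from weighted scatters W_g and counts Ng.
gmm_mstep_cov <- function(W, Ng, family, d, reg) {
  n <- sum(Ng)
  k <- length(W)
  covs <- switch(
    family,
    EII = {
      s2 <- sum(vapply(W, function(w) sum(diag(w)), 0)) / (n * d)
      rep(list(diag(s2, d)), k)
    },
    EEE = {
      S <- Reduce(`+`, W) / n
      rep(list(S), k)
    },
    VVV = lapply(seq_len(k), function(g) W[[g]] / Ng[g]),
    EEV = {
      eigs <- lapply(W, function(w) eigen(w, symmetric = TRUE))
      pooled <- Reduce(`+`, lapply(eigs, `[[`, "values")) / n
      pooled <- pmax(pooled, 0)
      lapply(eigs, function(e) {
        e$vectors %*% (pooled * t(e$vectors))
      })
    })
  if (reg > 0) covs <- lapply(covs, function(s) s + diag(reg, d))
  covs
}

gmm_em_once <- function(x, k, family, z0, tol, max_iter, reg) {
  n <- nrow(x)
  d <- ncol(x)
  z <- z0
  ll_prev <- -Inf
  ll_trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    Ng <- colSums(z)
    if (any(Ng < 1e-8)) stop("empty mixture component", call. = FALSE)
    w <- Ng / n
    means <- crossprod(z, x) / Ng
    W <- lapply(seq_len(k), function(g) {
      xc <- sweep(x, 2L, means[g, ], `-`)
      crossprod(xc * z[, g], xc)
    })
    covs <- gmm_mstep_cov(W, Ng, family, d, reg)
    ldens <- vapply(seq_len(k), function(g) {
      log_dmvnorm(x, means[g, ], covs[[g]])
    }, numeric(n))
    lw <- sweep(ldens, 2L, log(w), `+`)
    ll <- sum(logsumexp_rows(lw))
    if (ll < ll_prev - 1e-8 * (1 + abs(ll_prev))) {
      warnf("EM log-likelihood decreased (%.6g -> %.6g)", ll_prev, ll)
    }
    ll_trace <- c(ll_trace, ll)
    z <- exp(lw - logsumexp_rows(lw))
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * (1 + abs(ll))) break
    ll_prev <- ll
  }
  list(weights = w, means = means, covariances = covs, posterior = z,
       loglik = ll, ll_trace = ll_trace, iterations = iter)
}

# One (k, family) fit with multistart and a regularised retry on degenerate
# covariances.
gmm_fit <- function(x, k, family, n_init = 5, tol = 1e-6, max_iter = 500,
                    seed = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- ncol(x)
  if (k > n) stopf("k = %d exceeds n = %d", k, n)
  with_seed(seed, {
    best <- NULL
    for (init in seq_len(n_init)) {
      labels0 <- if (k == 1L) {
        rep(1L, n)
      } else {
        stats::kmeans(x, centers = k, nstart = 1L, iter.max = 50L)$cluster
      }
      z0 <- matrix(1e-10, n, k)
      z0[cbind(seq_len(n), labels0)] <- 1
      z0 <- z0 / rowSums(z0)
      fit <- tryCatch(gmm_em_once(x, k, family, z0, tol, max_iter, reg = 0),
                      error = function(e) e)
      if (inherits(fit, "error")) {
        message(sprintf(
          "gmm: %s k=%d init %d degenerate (%s); retrying with 1e-6 I ridge",
          family, k, init, conditionMessage(fit)))
        fit <- tryCatch(gmm_em_once(x, k, family, z0, tol, max_iter,
                                    reg = 1e-6),
                        error = function(e) e)
      }
      if (inherits(fit, "error")) next
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    if (is.null(best)) {
      stopf("all EM restarts failed for family %s, k = %d", family, k)
    }
    df <- gmm_n_params(family, k, d)
    structure(c(best[c("weights", "means", "covariances", "posterior",
                       "loglik", "ll_trace", "iterations")],
                list(family = family, k = k, df = df,
                     bic = 2 * best$loglik - df * log(n))),
              class = "xrf_gmm")
  })
}

#' Gaussian mixture clustering with BIC model selection
#'
#' Fits an EM Gaussian mixture for every combination of component count in
#' `k_range` and covariance family, initialised from k-means, and selects
#' the fit maximising `BIC = 2 loglik - p log(n)` (larger is better).
#'
#' @param scores Numeric matrix of observations (e.g. leading PCA scores).
#' @param k_range Integer vector of component counts to try.
#' @param families Covariance families to try, subset of
#'   `c("EII", "EEE", "EEV", "VVV")`.
#' @param seed Integer seed controlling the k-means initialisations.
#' @param n_init Number of EM restarts per model.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @return An `xrf_cluster` object with `labels` (argmax posterior),
#'   `posterior`, `model` (winning `xrf_gmm`), `bic_table`, `method = "gmm"`
#'   and `k`.
#' @export
gmm_cluster_bic <- function(scores, k_range = 1:9, families = gmm_families,
                            seed = 1L, n_init = 5, tol = 1e-6,
                            max_iter = 500) {
  scores <- as.matrix(scores)
  if (!all(is.finite(scores))) stopf("scores contain non-finite values")
  if (length(k_range) == 0L) stopf("empty k_range")
  families <- match.arg(families, gmm_families, several.ok = TRUE)
  fits <- list()
  rows <- list()
  i <- 0L
  for (k in sort(unique(as.integer(k_range)))) {
    for (fam in families) {
      i <- i + 1L
      fit <- tryCatch(
        gmm_fit(scores, k, fam, n_init = n_init, tol = tol,
                max_iter = max_iter, seed = seed + 1000L * i),
        error = function(e) e)
      if (inherits(fit, "error")) {
        rows[[i]] <- data.frame(k = k, family = fam, df = NA_integer_,
                                loglik = NA_real_, bic = NA_real_)
        next
      }
      fits[[paste(fam, k)]] <- fit
      rows[[i]] <- data.frame(k = k, family = fam, df = fit$df,
                              loglik = fit$loglik, bic = fit$bic)
    }
  }
  bic_table <- do.call(rbind, rows)
  if (length(fits) == 0L) stopf("no GMM fit succeeded")
  best <- fits[[which.max(vapply(fits, `[[`, 0, "bic"))]]
  labels <- max.col(best$posterior, ties.method = "first")
  structure(list(labels = labels, posterior = best$posterior, model = best,
                 bic_table = bic_table, method = "gmm", k = best$k,
                 diagnostics = bic_table),
            class = "xrf_cluster")
}

#' @export
print.xrf_gmm <- function(x, ...) {
  cat(sprintf("<xrf_gmm> %s, k = %d, loglik = %.2f, BIC = %.2f (df = %d)\n",
              x$family, x$k, x$loglik, x$bic, x$df))
  invisible(x)
}
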