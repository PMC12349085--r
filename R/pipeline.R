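#' Default pipeline configuration
#'
#' @param ... Overrides for individual keys; unknown keys are rejected.
#' @return A named list of pipeline settings.
#' @export
default_config <- function(...) {
  cfg <- list(
    manifest = NULL,          # path to manifest.csv (or in-memory dataset)
    spectra_dir = NULL,       # directory the manifest's file column points to
    out_dir = NULL,           # run directory; NULL keeps results in memory
    reference_session = "DiffAbs-2018",
    n_pcs_cluster = 6L,       # ~85% of variance in the target design
    n_pcs_lda = 21L,          # >98% of variance in the target design
    cluster_k = 2L,
    gmm_k_range = 1:4,
    gmm_families = c("EII", "EEE", "EEV", "VVV"),
    label_mapping = NULL,     # manifest clade -> analysis class
    singletons = "drop",      # or "error": classes with one specimen
    attribution_tolerance = 0.06,
    attribution_top_fraction = 0.1,
    loocv_modes = c("pca_outside", "pca_inside"),
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stopf("unknown config key(s): %s",
                         paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with any subset of the [default_config()] keys.
#' @return A validated config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  over <- yaml::read_yaml(path)
  do.call(default_config, over)
}

validate_config <- function(config, dataset = NULL) {
  cfg <- do.call(default_config, config)  # rejects unknown keys, fills rest
  if (is.null(dataset)) {
    if (is.null(cfg$manifest)) stopf("config: manifest path is required")
    if (!file.exists(cfg$manifest)) {
      stopf("config: manifest not found: %s", cfg$manifest)
    }
  }
  if (!cfg$singletons %in% c("drop", "error")) {
    stopf("config: singletons must be 'drop' or 'error'")
  }
  cfg
}

#' Run the whole analysis pipeline
#'
#' Stages: read/format spectra into the landmark matrix, PCA before
#' alignment (setup-shift diagnostic), session realignment on homologous
#' control spectra, pseudo-replicate averaging, PCA, clustering (k-means,
#' Ward, GMM with BIC selection) on the leading scores, LDA with
#' leave-one-out cross-validation on clade classes, and landmark-level
#' discriminance attribution to emission lines. Classes represented by a
#' single specimen are dropped before the LDA (with a log entry) unless the
#' config demands an error.
#'
#' @param config Config list (see [default_config()]) or path to a YAML
#'   file.
#' @param dataset Optional in-memory `xrf_dataset` replacing
#'   `manifest`/`spectra_dir`.
#' @return An `xrf_run` object with every stage's result and the log;
#'   written to `config$out_dir` when set.
#' @export
run_pipeline <- function(config = default_config(), dataset = NULL) {
  if (is.character(config)) config <- read_config(config)
  cfg <- validate_config(config, dataset)
  log <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    log <<- c(log, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  note("stage format: building landmark matrix")
  lm0 <- stage("format", {
    if (!is.null(dataset)) dataset_landmarks(dataset) else
      build_landmark_matrix(cfg$manifest, cfg$spectra_dir %||% ".")
  })
  note("formatted %d spectra x %d landmarks", nrow(lm0$values),
       ncol(lm0$values))

  pca0 <- stage("pca0", fit_pca(lm0))
  note("pre-alignment PCA: PC1 %.1f%%",
       100 * pca0$explained_variance_ratio[1L])

  aligned <- lm0
  deltas <- list()
  if (length(unique(lm0$meta$session)) > 1L) {
    al <- stage("align", align_sessions(lm0, cfg$reference_session))
    aligned <- al$matrix
    deltas <- al$deltas
    for (d in deltas) {
      note("aligned %s -> %s on %d homologous pairs", d$session,
           d$reference_session, d$n_pairs)
    }
  } else {
    note("single session; no alignment needed")
  }

  averaged <- stage("average", average_pseudoreplicates(aligned))
  note("averaged pseudo-replicates: %d -> %d spectra", nrow(aligned$values),
       nrow(averaged$values))

  pca1 <- stage("pca1", fit_pca(averaged))
  evr <- pca1$explained_variance_ratio
  note("PCA: PC1 %.1f%%, PC1-4 %.1f%%", 100 * evr[1L],
       100 * sum(evr[1:min(4, length(evr))]))

  k_sc <- min(cfg$n_pcs_cluster, ncol(pca1$scores))
  sc_cluster <- pca1$scores[, seq_len(k_sc), drop = FALSE]
  clust <- stage("cluster", list(
    kmeans = kmeans_cluster(sc_cluster, cfg$cluster_k, seed = cfg$seed),
    ward = ward_cluster(sc_cluster, cfg$cluster_k),
    gmm = gmm_cluster_bic(sc_cluster, k_range = cfg$gmm_k_range,
                          families = cfg$gmm_families, seed = cfg$seed)))
  note("clustering done; GMM selected %s with k = %d",
       clust$gmm$model$family, clust$gmm$k)

  labels <- analysis_classes(averaged$meta, cfg$label_mapping)
  # singleton classes: all spectra of one specimen only
  cls_spec <- tapply(averaged$meta$specimen_id, labels,
                     function(s) length(unique(s)))
  singles <- names(cls_spec)[cls_spec == 1L & names(cls_spec) != "sediment"]
  keep <- rep(TRUE, nrow(averaged$values))
  if (length(singles)) {
    if (cfg$singletons == "error") {
      stopf("singleton class(es): %s", paste(singles, collapse = ", "))
    }
    keep <- !(labels %in% singles & averaged$meta$zone_type == "fossil")
    note("dropped %d fossil spectra of singleton class(es): %s",
         sum(!keep), paste(singles, collapse = ", "))
  }
  lm_lda <- landmark_matrix(averaged$values[keep, , drop = FALSE],
                            averaged$meta[keep, , drop = FALSE])
  labels_lda <- labels[keep]
  pca_lda <- stage("pca_lda", fit_pca(lm_lda))
  n_pcs <- min(cfg$n_pcs_lda, ncol(pca_lda$scores))
  lda <- stage("lda", fit_lda(pca_lda$scores, labels_lda, n_pcs = n_pcs))
  cv <- stage("loocv", loocv(lm_lda, labels_lda, n_pcs = n_pcs,
                             modes = cfg$loocv_modes))
  for (mode in intersect(cfg$loocv_modes, names(cv))) {
    note("LOOCV (%s): %.1f%% correct", mode, 100 * cv[[mode]]$accuracy)
  }

  profile <- stage("attribution", discriminance_profile(pca_lda, lda))
  regions <- stage("attribution", report_discriminant_regions(
    profile, top_fraction = cfg$attribution_top_fraction,
    tolerance = cfg$attribution_tolerance))
  note("attribution: %d discriminant interval(s)", nrow(regions))

  run <- structure(list(config = cfg, landmarks_raw = lm0, pca0 = pca0,
                        deltas = deltas, landmarks = averaged, pca1 = pca1,
                        clusters = clust, labels = labels_lda,
                        landmarks_lda = lm_lda, pca_lda = pca_lda,
                        lda = lda, loocv = cv, profile = profile,
                        regions = regions, log = log),
                   class = "xrf_run")
  if (!is.null(cfg$out_dir)) write_run(run, cfg$out_dir)
  run
}

#' @export
print.xrf_run <- function(x, ...) {
  cat(sprintf("<xrf_run> %d spectra; LOOCV %.1f%%; GMM %s k=%d\n",
              nrow(x$landmarks$values), 100 * x$loocv$pca_outside$accuracy,
              x$clusters$gmm$model$family, x$clusters$gmm$k))
  invisible(x)
}

write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  evr <- run$pca1$explained_variance_ratio
  w(data.frame(component = seq_along(evr), explained_variance_ratio = evr),
    "pca_variance.csv")
  w(cbind(run$landmarks$meta,
          as.data.frame(run$pca1$scores[, 1:min(6, ncol(run$pca1$scores)),
                                        drop = FALSE])),
    "pca_scores.csv")
  w(run$clusters$gmm$bic_table, "gmm_bic_table.csv")
  w(as.data.frame(run$loocv$pca_outside$confusion), "loocv_confusion.csv")
  w(data.frame(mode = intersect(c("pca_outside", "pca_inside"),
                                names(run$loocv)),
               accuracy = vapply(intersect(c("pca_outside", "pca_inside"),
                                           names(run$loocv)),
                                 function(m) run$loocv[[m]]$accuracy, 0)),
    "loocv_accuracy.csv")
  w(data.frame(energy_kev = run$profile$grid, score = run$profile$score),
    "discriminance_profile.csv")
  w(run$regions, "discriminant_regions.csv")
  writeLines(run$log, file.path(dir, "run.log"))
  saveRDS(run[c("config", "pca_lda", "lda", "labels")],
          file.path(dir, "model.rds"))
  invisible(dir)
}

#' Classify unknown spectra with a completed run's model
#'
#' Formats the new spectra exactly as the training data (subset,
#' log-standardise, landmark), projects them into the run's ordination and
#' returns clade posteriors. New spectra are assumed to come from the
#' reference setup (or to have been acquired alongside controls and
#' realigned beforehand).
#'
#' @param run An `xrf_run` object, or a run directory containing
#'   `model.rds`.
#' @param spectra A list of [xrf_spectrum()] objects or file paths.
#' @return A data frame of posteriors with `zone_id` and the hard
#'   `predicted` class.
#' @export
classify_unknown <- function(run, spectra) {
  if (is.character(run) && length(run) == 1L && dir.exists(run)) {
    run <- readRDS(file.path(run, "model.rds"))
  }
  if (!is.list(spectra) || inherits(spectra, "xrf_spectrum")) {
    spectra <- list(spectra)
  }
  spectra <- lapply(spectra, function(s) {
    if (is.character(s)) read_spectrum(s) else s
  })
  vecs <- do.call(rbind, lapply(spectra, format_spectrum))
  scores <- project_pca(run$pca_lda, vecs)
  pred <- predict_posterior(run$lda, scores)
  out <- data.frame(zone_id = vapply(spectra, `[[`, "", "zone_id"),
                    predicted = pred$class, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(pred$posterior))
}
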