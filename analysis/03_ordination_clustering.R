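#!/usr/bin/env Rscript
# Ordination of the aligned landmark matrix and unsupervised structure:
# k-means and Ward at k = 2-3, and a Gaussian mixture over four covariance
# families with BIC selection, all on the six leading principal components.

library(xrfmorph)

lm <- read_landmark_matrix("results/landmarks_aligned")
pca1 <- fit_pca(lm)
evr <- pca1$explained_variance_ratio
cat(sprintf("PCA: PC1 %.1f%%, PC1-4 %.1f%%, PC1-6 %.1f%%, PC1-21 %.1f%%\n",
            100 * evr[1], 100 * sum(evr[1:4]), 100 * sum(evr[1:6]),
            100 * sum(evr[1:21])))
write.csv(data.frame(component = seq_along(evr),
                     explained_variance_ratio = evr),
          "results/pca_variance.csv", row.names = FALSE)
write.csv(cbind(lm$meta, as.data.frame(pca1$scores[, 1:6])),
          "results/pca_scores.csv", row.names = FALSE)

scores6 <- pca1$scores[, 1:6]
km <- kmeans_cluster(scores6, 2, seed = 1)
wd2 <- ward_cluster(scores6, 2)
wd3 <- ward_cluster(scores6, 3)
gmm <- gmm_cluster_bic(scores6, k_range = 1:4, seed = 1)
cat(sprintf("GMM selects %s with k = %d\n", gmm$model$family, gmm$k))
write.csv(gmm$bic_table, "results/gmm_bic_table.csv", row.names = FALSE)

is_sed <- lm$meta$zone_type == "sediment"
for (res in list(kmeans = km, ward2 = wd2, gmm = gmm)) {
  m <- match_labels(res$labels, ifelse(is_sed, "sediment", "fossil"))
  cat(sprintf("%-6s k=%d: agreement with fossil/sediment split %.2f\n",
              res$method, res$k, m$agreement))
}
write.csv(data.frame(zone_id = lm$meta$zone_id, kmeans2 = km$labels,
                     ward2 = wd2$labels, ward3 = wd3$labels,
                     gmm = gmm$labels),
          "results/cluster_labels.csv", row.names = FALSE)
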