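#!/usr/bin/env Rscript
# Clade-level linear discriminant analysis on the 21 leading PCA scores,
# after dropping the fossil zones of the singleton clade, with leave-one-out
# cross-validation in both flavours (PCA outside the loop - the headline
# figure - and the leakage-free PCA-inside variant).

library(xrfmorph)

lm <- read_landmark_matrix("results/landmarks_aligned")
labels <- analysis_classes(lm$meta)
per_class <- tapply(lm$meta$specimen_id, labels,
                    function(s) length(unique(s)))
singles <- names(per_class)[per_class == 1 & names(per_class) != "sediment"]
keep <- !(labels %in% singles & lm$meta$zone_type == "fossil")
cat(sprintf("dropping %d fossil spectra of singleton clade(s): %s\n",
            sum(!keep), paste(singles, collapse = ", ")))
lm2 <- landmark_matrix(lm$values[keep, , drop = FALSE], lm$meta[keep, ])
labels2 <- labels[keep]

pca <- fit_pca(lm2)
lda <- fit_lda(pca$scores, labels2, n_pcs = 21)
cv <- loocv(lm2, labels2, n_pcs = 21)
print(cv)
write.csv(as.data.frame(cv$pca_outside$confusion),
          "results/loocv_confusion.csv", row.names = FALSE)
write.csv(data.frame(class = names(cv$pca_outside$per_class_recall),
                     recall = cv$pca_outside$per_class_recall),
          "results/loocv_recall.csv", row.names = FALSE)
saveRDS(list(pca = pca, lda = lda), "results/classifier.rds")
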