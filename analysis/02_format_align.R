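#!/usr/bin/env Rscript
# Format every spectrum into the 831-landmark representation, quantify the
# setup-specific morphological shift (pre-alignment PCA), realign the two
# PUMA sessions onto DiffAbs-2018 using the homologous control spectra, and
# average the control pseudo-replicates to one spectrum per zone.

library(xrfmorph)

manifest <- read_manifest("results/dataset/manifest.csv")
lm0 <- build_landmark_matrix(manifest, dir = "results/dataset/spectra")

pca0 <- fit_pca(lm0)
cat(sprintf("before alignment: PC1 carries %.1f%% of the variance\n",
            100 * pca0$explained_variance_ratio[1]))
session_means <- tapply(pca0$scores[, 1], lm0$meta$session, mean)
print(round(session_means, 2))

al <- align_sessions(lm0, "DiffAbs-2018")
for (d in al$deltas) print(d)
averaged <- average_pseudoreplicates(al$matrix)
cat(sprintf("averaged pseudo-replicates: %d -> %d spectra\n",
            nrow(lm0$values), nrow(averaged$values)))

dir.create("results", showWarnings = FALSE)
write_landmark_matrix(averaged, "results/landmarks_aligned")
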