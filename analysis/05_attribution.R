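#!/usr/bin/env Rscript
# Map the discrimination back onto the spectrum: per-landmark discriminance
# score from the PCA loadings and LDA scalings, top-decile discriminant
# intervals, and candidate emission lines for each interval.

library(xrfmorph)

model <- readRDS("results/classifier.rds")
profile <- discriminance_profile(model$pca, model$lda)
regions <- report_discriminant_regions(profile)

write.csv(data.frame(energy_kev = profile$grid, score = profile$score),
          "results/discriminance_profile.csv", row.names = FALSE)
write.csv(regions, "results/discriminant_regions.csv", row.names = FALSE)

cat("top-decile discriminant intervals and candidate lines:\n")
print(regions[order(-regions$peak_score),
              c("start_kev", "end_kev", "peak_kev", "elements")],
      row.names = FALSE)
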