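#!/usr/bin/env Rscript
# Generate the default synthetic study: 38 specimens across 8 clades and 7
# sites, 6 zones each (3 fossil, 3 sediment), three acquisition sessions
# with distinct setup signatures, and 2 control specimens measured in every
# session. Writes 252 delimited spectra plus manifest and ground truth.

library(xrfmorph)

scenario <- default_scenario()
dataset <- simulate_dataset(scenario, dir = "results/dataset")

cat(sprintf("wrote %d spectra for %d specimens to results/dataset\n",
            length(dataset$spectra), nrow(dataset$truth$specimens)))
cat(sprintf("control specimens: %s\n",
            paste(dataset$truth$specimens$specimen_id[
              dataset$truth$specimens$control], collapse = ", ")))
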