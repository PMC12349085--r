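# xrfmorph — whole-spectrum morphometric chemotaxonomy for µXRF spectra

`xrfmorph` identifies the high-level clade of a fossil from the *shape* of
its whole micro X-ray fluorescence (µXRF) spectrum, sidestepping absolute
elemental quantification entirely. It is aimed at palaeontologists and
archaeometrists with multi-session synchrotron (or lab) XRF campaigns:
many specimens, each with several zone-mean spectra of the fossil and of
its encasing sediment, acquired on different setups.

The method treats each spectrum as a 1-D morphometric object:

1. **Format** — calibrate in energy (Ca/Fe/Y Kα1 anchors), reconstruct the
   continuous curve, subset to 1.7–18.3 keV, log10-normalise, standardise
   (mean 0, sd 1), and sample **831 landmarks** every 0.02 keV.
2. **Realign** — remove the setup-specific spectral morphology by
   subtracting, per session, the mean landmark-wise difference Δ between
   homologous control spectra (the same zones re-measured in every
   session), then average the resulting pseudo-replicates.
3. **Ordinate & cluster** — covariance PCA of the landmark matrix;
   k-means, Ward (ward.D2) and Gaussian-mixture clustering on the leading
   scores, with mixture selection by `BIC = 2·loglik − p·log n` over the
   EII/EEE/EEV/VVV covariance families.
4. **Classify** — linear discriminant analysis of clade labels on the 21
   leading scores, validated by leave-one-out cross-validation (both with
   the PCA outside the loop — the conventional figure — and the
   leakage-free PCA-inside variant).
5. **Attribute** — score every landmark's contribution to the
   discrimination (squared PCA loadings weighted by squared LDA scalings
   and axis separation shares), merge the top decile into energy
   intervals, and annotate each interval with candidate Kα1/Kβ1/Lα1
   emission lines.

A synthetic µXRF generator (`default_scenario()`, `simulate_dataset()`)
reproduces the statistical structure this analysis assumes — emission and
Si escape peaks, session offsets, a calcitic-to-ferruginous sediment
gradient, clade-specific element profiles, fossil/sediment blending,
Poisson noise — so the entire pipeline is testable end to end without any
instrument data.

## Worked example

The `analysis/` scripts run the whole workflow on the bundled synthetic
study design (38 specimens, 8 clades, 3 sessions, 252 spectra):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_format_align.R
Rscript analysis/03_ordination_clustering.R
Rscript analysis/04_classify.R
Rscript analysis/05_attribution.R
```

which prints, stage by stage:

```
wrote 252 spectra for 38 specimens to results/dataset
control specimens: ech01, art01

before alignment: PC1 carries 37.5% of the variance
DiffAbs-2018    PUMA-2021    PUMA-2024
        0.26         0.39        -0.65
<xrf_batch_delta> PUMA-2021 -> DiffAbs-2018: 12 pairs, |delta| in [1.77e-05, 0.326]
<xrf_batch_delta> PUMA-2024 -> DiffAbs-2018: 12 pairs, |delta| in [0.000155, 0.276]
averaged pseudo-replicates: 252 -> 228 spectra

PCA: PC1 40.5%, PC1-4 76.2%, PC1-6 80.3%, PC1-21 87.0%

dropping 3 fossil spectra of singleton clade(s): sarcopterygian
<xrf_loocv> pca_outside: accuracy 96.9% (21 PCs)
<xrf_loocv> pca_inside: accuracy 96.9% (21 PCs)
```

Reading this: the pre-alignment PCA separates acquisition sessions (the
PC1 session means differ), the 24 control acquisitions collapse onto their
12 zones after realignment and averaging, and the clade-level classifier
identifies 96.9% of spectra correctly under leave-one-out
cross-validation — with the leakage-free variant agreeing, so the figure
is not an artefact of fitting the PCA on all rows. The attribution step
then lists the discriminant energy intervals with their candidate
elements, e.g.

```
 start_kev end_kev peak_kev      elements
      3.64    3.78     3.70        Ca Ka1
      5.82    5.96     5.88        Mn Ka1
      6.34    6.44     6.38        Fe Ka1
     14.88   15.04    14.94 Y Ka1, Rb Kb1
```

— the planted between-class elements re-emerge, and the 14.9 keV interval
shows the genuine Y Kα1 / Rb Kβ1 ambiguity that energy-dispersive
detection cannot resolve.

The same pipeline runs on real exported spectra via a manifest
(`read_manifest()` + `build_landmark_matrix()` or `run_pipeline()` with a
YAML config), and `classify_unknown()` projects new spectra into a
completed run to obtain clade posteriors.

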