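---
title: "Whole-spectrum morphometric chemotaxonomy of µXRF spectra"
author: "xrfmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-spectrum morphometric chemotaxonomy of µXRF spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xrfmorph)
```

## The problem

A micro X-ray fluorescence (µXRF) map of a fossil embedded in sediment
yields, for every analysed zone, a spectrum of photon counts against
emission energy. Deriving absolute elemental concentrations from such
spectra is setup-dependent and fragile, especially when data come from
different beamlines and sessions. `xrfmorph` takes the alternative route:
it treats the *whole spectrum* as a 1-D morphometric object, in the same
way landmark-based geometric morphometrics treats an outline. If different
fossil clades incorporate and preserve elements differently, their spectra
differ in shape, and that shape difference can be quantified, classified
and finally mapped back to candidate chemical elements — without ever
quantifying a single concentration.

The intended data layout mirrors a multi-session synchrotron campaign:
several dozen specimens, each with six zone-mean spectra (three from the
biomineralised fossil, three from the encasing sediment), acquired over
multiple sessions with different setups, and a small number of control
specimens re-measured in every session.

## The processing model

Every spectrum passes through a fixed formatting chain
(`format_spectrum()`):

1. **Energy calibration** (`calibrate_energy()`), when spectra arrive in
   detector channels: an affine (optionally quadratic) least-squares map
   anchored on reference peaks — Ca Kα1 at 3.692 keV, Fe Kα1 at 6.405 keV,
   Y Kα1 at 14.958 keV.
2. **Continuous reconstruction** (`reconstruct_continuous()`): linear
   interpolation between the exported points. Linear is the simplest
   shape-preserving choice; splines would add curvature not present in the
   exported data and are deliberately not offered as a default.
3. **Energy subsetting** to 1.7–18.3 keV (`subset_energy()`): below ~1.7
   keV and above ~18.3 keV the signal is unreliable (outside the P K-edge
   to U L3-edge detection design, and close to the 18 keV excitation where
   scattering dominates). Window endpoints are synthesised by
   interpolation so every spectrum shares exactly the same support.
4. **Log-normalisation and standardisation** (`log_standardize()`):
   `log10(counts + 1)`, then centring and scaling to mean 0 and
   *population* (divide-by-`n`) standard deviation 1 over the subset
   channels. The `+ 1` offset keeps empty channels finite while leaving
   large counts essentially untouched; the population convention is an
   explicit, documented choice (either convention would do, but it must be
   fixed for bit-reproducibility).
5. **Landmark sampling** (`extract_landmarks()`): the standardised curve is
   sampled every 0.02 keV from 1.7 to 18.3 keV, giving exactly
   `(18.3 - 1.7)/0.02 + 1 = 831` landmarks. Standardisation happens on the
   channel representation *before* sampling; landmark vectors are samples
   of the standardised curve, not re-standardised.

Calibrated energy axes are observed to wander by ~20–25 eV between
samples, i.e. about one landmark step and well under the detector
resolution (>120 eV FWHM at Mn Kα1). No per-sample re-registration is
attempted; the fixed grid absorbs shifts of this size, and the simulator
injects exactly this jitter so the tests exercise the assumption.

## Session realignment and pseudo-replicate averaging

Different beamline setups impose different spectral morphologies
(sensitivity curves, scattering above ~17.5 keV). The correction uses
*homologous spectra*: the same physical zone of a control specimen
measured in several sessions. For each non-reference session,
`compute_mean_delta()` averages the landmark-wise differences between each
homologous pair and the reference acquisition, and `apply_realignment()`
subtracts that mean difference Δ from every spectrum of the session. Each
session is aligned directly to the reference (no chaining). Two exact
algebraic properties are unit-tested: a constant per-session offset
cancels exactly, and the mean homologous residual is zero to machine
precision for arbitrary offsets. Within-session geometry is untouched —
realignment subtracts one common curve per session.

Control zones measured in all sessions would afterwards be
over-represented, so `average_pseudoreplicates()` collapses rows sharing a
zone to their landmark-wise mean (session recorded as `"merged"`).

## Ordination, clustering, classification

- **PCA** (`fit_pca()`) is covariance PCA: column centring, no
  per-landmark rescaling. The rows are already standardised spectra;
  rescaling each landmark would equalise peak heights and destroy exactly
  the information the method relies on. Loading signs are fixed (largest
  absolute entry positive) so results are fully deterministic.
- **Clustering** operates on the leading scores (default 6 components).
  `kmeans_cluster()` is Lloyd's algorithm from k-means++ starts;
  `ward_cluster()` is Ward.D2 agglomeration on Euclidean distances;
  `gmm_cluster_bic()` fits Gaussian mixtures by EM over four covariance
  families — spherical-equal (EII), shared (EEE), equal volume and shape
  with free orientation (EEV), and unconstrained (VVV) — and selects the
  model maximising `BIC = 2 loglik − p log n`. The four families bracket
  the equal-volume/equal-shape/variable-orientation structure that
  elongated compositional gradients produce; the full 14-family taxonomy
  would add nothing to this use. The EEV M-step eigendecomposes each
  component's weighted scatter and pools the eigenvalues across components
  while keeping per-component eigenvectors — the standard estimator for
  that constraint. Degenerate covariances trigger one logged retry with a
  `1e-6` diagonal ridge. The in-package EM is cross-checked in the test
  suite against an independent mixture implementation and against the
  closed-form single-Gaussian likelihood.
- **Classification** (`fit_lda()`, `loocv()`) is classical LDA with pooled
  within-class covariance on the leading scores (default 21 components),
  priors proportional to class frequencies (the classes are strongly
  unbalanced, and proportional priors are the standard default in that
  situation). Numerical stabilisation is delegated to the underlying
  solver's collinearity tolerance rather than an explicit ridge, since the
  inputs are already decorrelated PCA scores. Classes represented by a
  single specimen are rejected by default — with one specimen the pooled
  covariance receives no usable within-class information — which is why
  the pipeline drops singleton clades (logging the exclusion) before the
  final discriminant model.
- **Leave-one-out cross-validation** is reported in two flavours.
  `pca_outside` computes the PCA once on all rows and cross-validates only
  the LDA; this is the conventional procedure in morphometrics but lets
  the held-out row influence the ordination, a known source of mild
  optimism. `pca_inside` refits the PCA within every fold and is
  leakage-free. Both are computed by default so the optimism is visible
  rather than hidden; on the default synthetic scenario the two agree to
  within a percentage point.

## Attribution of the discrimination to elements

No closed formula for "how much does landmark *l* matter to the
discrimination" follows automatically from PCA + LDA, so the package
declares one (`discriminance_profile()`), built from the two contribution
notions it combines:

- contribution of landmark *l* to component *k*: squared loading
  `L[l,k]^2` (columns sum to 1 for orthonormal loadings);
- contribution of component *k* to the discrimination:
  `w_k = Σ_j λ_j a[k,j]^2`, where `a[k,j]` is the LDA scaling coefficient
  of component *k* on discriminant axis *j* and `λ_j` is the axis's
  normalised share of between-class separation (squared singular value).

The profile `score_l = Σ_k L[l,k]^2 w_k` is rescaled to max 1. It is
invariant to the order of discriminant axes and, by construction, peaks
exactly on the landmark that carries a single informative component in the
degenerate test case. `report_discriminant_regions()` thresholds the
profile at the (1 − top_fraction) quantile (default: top decile), merges
contiguous landmarks into intervals, and annotates each interval's peak
with candidate emission lines from the packaged Kα1/Kβ1/Lα1 table
(`emission_lines()`; a provenance column separates the rounded values
conventionally reported with µXRF analyses from full-precision
standard-table values). The default assignment tolerance of 0.06 keV is
about half the detector resolution.

## What the synthetic generator emulates — and what it does not

`default_scenario()` fixes the study conditions every recovery test runs
under:

- **Design**: 38 specimens in 8 clades across 7 sites, 6 zones each
  (3 fossil, 3 sediment), three sessions (`DiffAbs-2018` as reference,
  `PUMA-2021`, `PUMA-2024`), two control specimens (first echinoderm,
  first arthropod) measured in all sessions: 252 acquired spectra, 228
  zones.
- **Physics caricature**: Gaussian peaks at tabulated line energies with
  `FWHM(E) = 0.06 + 0.028 √E` keV, Kβ/Kα ratio 0.135, Lα-only L-series, Si
  escape peaks at `E − 1.742` keV with fraction 0.02 (so Ca Kα/Kβ produce
  the familiar features near 1.95 and 2.27 keV), an exponential-plus-
  constant continuum, and a scatter feature at 17.8 keV below the 18 keV
  excitation (no lines above it). Counts are Poisson; the default exposure
  is high because zone-mean spectra integrate many map pixels.
- **Sessions**: additive offset curves (background and scatter changes)
  plus a smooth multiplicative sensitivity curve per session, and a
  uniform ±0.025 keV energy jitter per (specimen, session).
- **Composition**: sediment interpolates between a calcitic pole (Ca, Sr
  high) and a ferruginous pole (Fe with correlated Zn, Ga, As, Rb) at a
  per-specimen gradient position `g`; each clade has its own element
  profile; fossil zones blend clade and sediment composition (thin or
  poorly preserved fossils blend more — the two poorly preserved ammonoids
  use blend 0.85). The echinoderm profile deliberately resembles the
  calcitic sediment endmember (Sr/Mn-enriched, detrital K/Ti/trace
  content, essentially no P), because the phenomenon the unsupervised
  analyses must reproduce is precisely that the calcitic clade lies on the
  carbonate gradient with the sediment. Lognormal perturbations act at
  site (sd 0.05), specimen (sd 0.15) and zone (sd 0.07) level.
- **Truth labels**: the scenario declares which elements carry *between-
  class* contrasts (`discriminant_elements`: P, K, Ca, Ti, Mn, Zn, Sr, Y)
  and which are constant everywhere (`nondiscriminant_elements`: Cr, Cu,
  Se, Br). Fe, Rb, Ga and As are deliberately in neither set: they carry
  the within-sediment gradient, so their variance is predominantly
  within-class and a correctly working discriminant analysis should (and
  does) down-weight them.

Not emulated: peak-shape asymmetry and pile-up, absorption edges and
matrix effects, inter-element fluorescence, spatial structure within a
zone, and any real mineralogical chemistry. Passing recovery tests
therefore show that the *pipeline* recovers structure it is designed to
detect under its own assumptions — they are not evidence about any real
fossil assemblage.

## Numerical choices and degenerate inputs

- Quantities with exact identities (realignment algebra, landmark count,
  z-scoring) are tested to machine precision (`1e-12`), linear-algebra
  agreements to `1e-8`.
- Zero-variance spectra, non-monotone energy axes, negative counts,
  missing manifest columns, singleton classes, empty mixture components
  and out-of-support queries all raise immediate, named errors rather
  than propagating.
- Posterior ties in classification are broken by class order with a
  warning.
- All stochastic steps (k-means starts, EM restarts, simulation) are
  seeded; identical inputs give bit-identical outputs, which the tests
  assert for the full formatting chain, the PCA and the written run
  tables.

## Problem sizes used in tests

The packaged tests run the full 38-specimen design for the end-to-end
recovery checks and a 16-specimen reduction of the same scenario for the
per-module tests; mixture and classifier oracles use a few hundred
observations in 2–6 dimensions, which is ample for the closed-form
comparisons they make. `scripts/acceptance.R` reruns the full design once
for the headline quantities and a five-dataset ensemble for the
attribution recovery and false-positive rates.

## Known limitations

- The realignment removes the *mean* setup morphology; composition-
  dependent setup effects (e.g. detector nonlinearity interacting with
  count rate) would leave residuals that only a richer control design
  could expose.
- LDA posteriors assume Gaussian classes with a shared covariance in score
  space; with 9 unbalanced classes on 21 scores the model is usable but
  the per-class recalls for the rare clades rest on few specimens.
- The attribution formula is a declared convention, not an estimate of
  variable importance with sampling theory attached; intervals should be
  read as candidate regions for element-specific follow-up.
- Classifying unknowns (`classify_unknown()`) assumes the new spectra
  share the reference setup or have been realigned with their own
  controls; projecting a spectrum from an uncorrected new setup will bias
  the posteriors.
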