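---
title: "LIBS ionomic profiling of fungal biomass: models and methods"
author: "libsionome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LIBS ionomic profiling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(libsionome)
```

# Scope

`libsionome` implements an end-to-end chemometrics pipeline for
laser-induced breakdown spectroscopy (LIBS) elemental profiling of axenic
fungal cultures: two species (*Hyaloscypha finlandica*, Hf; *Mucor
hiemalis*, Mh) crossed with two growth media (potato dextrose broth, PDB;
glucose minimal medium, GMM). Raw instrument spectra for this system are not
publicly available, so the package pairs the analysis pipeline with a
synthetic-spectrum generator that plants the qualitatively reported class
structure with known ground truth. Everything downstream — preprocessing,
background-corrected peak extraction, element identification, correlation
profiling, PCA, linear classification — operates identically on simulated or
ingested spectra (`readSpectra`).

# The signal model

Each laser shot is simulated on the spectrometer grid (178–1,022 nm, step
0.1 nm) as

$$I(\lambda) \;=\; B(\lambda)
  \;+\; \sum_{\ell} c_{e(\ell)}\, w_\ell\,
        e^{-(\lambda-\lambda_\ell)^2 / 2\sigma^2}
  \;+\; \varepsilon(\lambda), \qquad I(\lambda) \ge 0,$$

* $B(\lambda) = B_0\, e^{-(\lambda - \lambda_{\min})/\tau}$: broadband plasma
  continuum. Defaults $B_0 = 10$ counts, $\tau = 300$ nm. An exponential
  decay is the simplest smooth, monotone background that exercises the
  baseline-correction stage (a flat background would make it trivial).
* Emission lines: Gaussian profiles with FWHM 0.15 nm
  ($\sigma = \mathrm{FWHM}/2\sqrt{2\ln 2}$), peak height = concentration
  $c_e$ × line weight $w_\ell$. The line list (1–3 strong persistent NIST
  lines per element, CN violet band head at 388.34 nm as one pseudo-line) is
  a versioned TSV shipped in `inst/extdata/`, so the assignment conventions
  are inspectable and user-replaceable. Peak response is exactly linear in
  concentration at zero noise, which the proportionality tests exploit.
* Noise: $\varepsilon \sim N(0,\, a + b\,\cdot\,\mathrm{signal})$,
  independent per grid point and shot. The variance floor $a$ models
  detector read noise, the proportional term $b$ photon statistics.
  Defaults $a = 0.02$ counts², $b = 0.002$ counts. These were calibrated
  once against the intended operating regime of the synthetic study — shot
  noise visible on single shots (per-channel SNR of a few for trace lines)
  but a sub-percent share of total variance after 4-shot averaging and
  area normalization, so that five principal components carry essentially
  all structure — and then frozen.
* Not modeled (out of scope by design): Stark broadening, plasma temperature
  and Saha–Boltzmann physics, self-absorption, matrix effects, instrument
  drift, detector stitching artifacts between the 8 spectrometer channels.

## Class structure and replicate hierarchy

Species and media enter as multiplicative fold effects (default 2.0) on the
element concentrations: Zn, P, Mn, Mg, Fe, H, O (and Al) elevated in Hf; Li
and Ca elevated in Mh; Ca and Al elevated in PDB; C elevated in GMM; all
other features neutral. Species and media effects compose, so e.g. Ca in
(Mh, PDB) is $2 \times 2 = 4$-fold the base value.

Each biological specimen draws one lognormal multiplier
($\mathrm{sdlog} = 0.1$) applied to its whole biological profile; shots then
add independent noise. The shared multiplier induces the within-class
common-mode correlation that makes element–element correlation matrices
nontrivial: all biological lines co-vary through it. Ambient H/N/O
(moisture plus entrained air when no cover gas is used) is added unscaled,
so those emissions are present in every class.

One consequence worth stating explicitly: with media pooled inside a
species, carbon's planted 2× media fold dominates its variance, so C
correlates only weakly with the Zn/P/Mn/Mg block at default settings; once
the medium is fixed, C joins that block with large positive coefficients.
This is a necessary property of the planted effect structure, not a free
parameter, and the test suite asserts exactly that pattern.

## Replicate-count presets

The replicate structure of the original experiment admits two readings,
which the package exposes as presets rather than resolving silently:
`paper_n80` (one mount per biological specimen; 20 mounts × 16 shots = 320
raw shots → 80 analysis spectra after 4-shot averaging) and `specimen20`
(five mounts per specimen → 20 averaged spectra per specimen, 400 in total).
`paper_n80` is the default everywhere because the classification experiment
is described on n = 80 spectra.

# Preprocessing

The order is fixed: **crop → aggregate → normalize**, applied exactly once
(re-preprocessing a preprocessed set is an error).

* Crop to 190–900 nm (closed interval): the window within which element
  signatures are parsed.
* Aggregate: consecutive disjoint groups of k = 4 shots per mount, in
  acquisition order (rows of the 4 × 4 grid), averaged pointwise; k = 8 in
  the ablation. Averaging raw counts before any rescaling reflects that
  shot averaging is a detector-level operation; white-noise variance drops
  by 1/k (tested within 20 %).
* Normalize: per-spectrum total-area normalization over the cropped grid
  (sum of intensities = 1). The normalization method is a declared
  convention: total area removes shot-energy variation without privileging
  any single line; `max_peak` and `none` are selectable alternatives, and
  several exactness tests (fold-change recovery) deliberately run with
  `none`.

# Peak extraction and element identification

The background under each line is estimated locally: medians of two flanking
windows (width 1.0 nm each, separated from the line center by an exclusion
half-width of 0.45 nm) linearly interpolated to the query wavelength.
Medians keep the estimate robust when a neighboring line (e.g. Ca II 393.37
vs Al I 394.40) lands inside a flank; no global polynomial fit and no
deconvolution is attempted. The extracted statistic is the peak **maximum**
within ±0.3 nm of the line center minus the interpolated baseline at the
argmax, floored at 0; for multi-line elements the strongest extracted line
wins. The 0.3 nm match tolerance is below half the closest inter-species
line separation in the default library, so assignments cannot cross over.
Extraction is invariant to a constant offset of the whole spectrum, which
covers both readings of "background-corrected" (detector dark level or
spectral continuum).

`identifyElements` reports a feature when any of its lines exceeds
`snr_threshold` (default 3) × the local noise σ, estimated as 1.4826 × the
median absolute deviation of the flank residuals around the interpolated
baseline. When the local σ is exactly zero (noise-free flat continuum), any
strictly positive corrected intensity counts; a pure continuum therefore
yields the empty set. The rule is monotone in the threshold.

# Correlation analysis

Pearson coefficients are computed over analysis spectra, either pooled or
within a subset (the per-species matrices pool both media; this pooling is a
declared convention, with per-species-and-medium subsets available through
`subset`). Magnitude bins follow the standard verbal categories — |r| < 0.1
none, 0.1–0.3 small, 0.3–0.5 medium, 0.5–1.0 large — implemented as
half-open intervals [lo, hi) with 1.0 included in "large", so categorization
is total and deterministic at the published bin edges. Zero-variance
features produce an explicit undefined marker (`NA` plus an attribute),
never a silent 0. Feature–PC correlations (`pcCorrelations`) append the PC
scores to the data matrix and correlate them directly with the emission
intensities.

# PCA and linear classification

PCA is applied to the entire preprocessed spectrum (7,101 grid points per
spectrum in the default study; the 16-column intensity table is an optional
faster input mode), mean-centered, unscaled, via singular value
decomposition. Explained-variance ratios are reported for the full
decomposition (they sum to 1 over full rank); five components are retained
by default. Loading signs follow a largest-element-positive convention so
scores are reproducible across linear-algebra backends.

The classifier is the canonical linear model on PCA scores: an
equal-covariance linear discriminant (class means, pooled within-class
covariance, equal priors), with no hyperparameters. A singular pooled
covariance — which arises by construction in zero-noise simulations — is
ridge-regularized with a declared epsilon (10⁻⁸ × mean diagonal) and a
warning that run manifests surface. The train/test protocol is a stratified
random thirds split: per class, round(n/3) spectra (at least 1) to training,
the rest to testing, reproducible by seed. Stratification guarantees every
class is represented in training; the rounding rule is a declared
convention, giving 28 train / 52 test for the 80-spectrum default study.
The shot-averaging ablation reruns preprocessing, PCA and the combined
four-class task on the same raw shots at k = 4 and k = 8 with the same split
policy.

# Problem sizes and numerical conventions

The default synthetic study used throughout the tests and the acceptance
script is the `paper_n80` design at the default grid: 320 raw shots × 8,441
grid points, reduced to 80 spectra × 7,101 points after preprocessing —
small enough that every stage runs in seconds while preserving the full
spectral resolution of the design. Unit and property tests use narrower
grids (e.g. 640–700 nm around the H-α/Li region) where only single-line
behavior matters. Other conventions: Gaussian lines are evaluated within
±8σ of their centers (truncation below 10⁻¹³ of peak height); intensities
are clipped at zero after noise; all study-level randomness (biological
multipliers, shot noise, splits) derives from a single integer seed, and
identical configuration plus seed reproduces byte-identical artifacts.

# What passing tests do and do not show

The generator reproduces the *structure* of the experiment — grid geometry,
shot hierarchy, effect directions, always-present ambient H/N/O, shared
within-specimen variation — with a deliberately simple signal model. Passing
the pipeline's recovery tests therefore demonstrates that the analysis
correctly inverts the planted structure at realistic signal-to-noise; it
does not certify performance on real instrument data, where line
interference, self-absorption, matrix effects and drift can degrade every
stage. Quantities tied to the specific plasma physics of the original
measurements (per-PC variance ratios, individual correlation coefficients)
are not reproducible from simulation and are not claimed; the package's
study-level checks target the structural and classification results that the
planted design does determine.
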