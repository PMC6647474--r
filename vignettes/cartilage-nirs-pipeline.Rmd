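---
title: "Estimating cartilage properties from arthroscopic NIR spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating cartilage properties from arthroscopic NIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirscart)
```

This vignette walks through the methods implemented in **nirscart** and the
reasoning behind its default parameters. The package models a common
workflow in quantitative arthroscopy: near-infrared (NIR) diffuse
reflectance spectra are collected from articular cartilage both ex vivo
(controlled probe contact, "in vitro") and during arthroscopy ("in vivo",
where probe-contact failures contaminate a fraction of repeats), and
machine-learning models map the spectra to histologically measured tissue
properties.

Because no measurement data ship with the package, every stage runs against
a synthetic cohort whose ground truth is fully known. That is a deliberate
design decision: it turns the pipeline into a closed loop that can be tested
quantitatively (parameter recovery, outlier sensitivity/specificity,
bit-exact determinism) rather than only inspected visually.

## 1. The synthetic cohort

`cohort_config()` describes a study of 10 ponies (7 "experimental" animals
carrying surgically induced cartilage lesions and their repair response, 3
untreated controls). Per animal, two legs x three joint sites x four
measurement locations give 24 locations per animal, 240 in total. Each
location is measured `in_vitro_repeats = 3` times under ideal contact and
`in_vivo_repeats = 15` times arthroscopically, of which a configurable
fraction `contamination = 0.1` receives a contact-loss artifact.

### Latent tissue state and depth profiles

Each location draws a latent state: cartilage thickness (truncated normal,
mean 0.65 mm, bounds 0.15-1.8 mm), a degeneration score in [0, 1] (elevated
at lesion-adjacent locations of experimental animals), and smooth
animal-level and location-level random effects. The latent state is
expanded by `latent_to_profiles()` into 500-point depth profiles:

* **Proteoglycan (PG) content** rises with depth as a power law,
  `baseline * (0.35 + 0.65 * d^1.4)` in optical-density (OD) units of a
  digital-densitometry readout — superficial cartilage is PG-poor, deep
  cartilage PG-rich. Degeneration depletes PG preferentially near the
  surface.
* **Collagen orientation angle** follows the classical arcade structure:
  near 0 degrees (parallel to the surface) superficially, rising smoothly
  towards 90 degrees (perpendicular) in the deep zone, as measured by
  polarized light microscopy. Degeneration flattens the deep-zone angle.

`extract_references()` reduces profiles to the five regression targets:
thickness (mm), PG content averaged over the full thickness and over the
superficial 25% (OD), and orientation angle averaged the same two ways
(degrees). Averaging is exact trapezoidal integration over the covered
depth span, so constant and linear profiles are reproduced to machine
precision — one of the unit-test oracles.

### The spectral forward model

`forward_spectrum()` generates absorbance on two detector grids that mirror
a dual-spectrometer instrument: detector A, 0.35-1.1 um at 0.6 nm spacing
(1251 points), and detector B, 1.0-2.5 um at 6.4 nm spacing (235 points).
The clean spectrum is a power-law scattering baseline `1.2 * lambda^-1.3`
plus Gaussian absorption bands (water/overtone-like features at fixed center
wavelengths) whose amplitudes are affine in the tissue targets through a
small band-link matrix. This is intentionally a *caricature* of tissue
optics: it is not meant to be radiative-transfer accurate, only to give the
regression problem the structure that matters — smooth broad features,
target information distributed across overlapping bands, multiplicative
baseline variation, heteroscedastic noise, and a low-dimensional latent
cause. Claims the package can support are therefore about the *pipeline*
(preprocessing, outlier screening, validation design, ensemble behavior),
not about real cartilage spectroscopy.

Contact-loss artifacts (`inject_artifact()`) scale the spectrum towards a
saline-like background and add low-frequency distortion, producing the
off-manifold spectra the outlier stage must catch.

## 2. Preprocessing

`preprocess()` applies per-detector Savitzky-Golay (SG) first-derivative
filtering with a 3rd-degree polynomial: window 139 points on the dense
detector A, 41 points on the coarse detector B (both odd; roughly comparable
bandwidth in wavelength units). Derivatives suppress the multiplicative
baseline; the long windows act as strong smoothers. Filtering is
*interior-only* — no padded edge values ever enter the analysis — and the
retained region is then cropped to 0.80-1.90 um, with detector A used below
the 1.0 um crossover and detector B above. After cropping, the analysis
vector has 334 detector-A plus 121 detector-B features (455 total). Note
that because half a filter window is consumed at each detector edge, the
first retained detector-B wavelength is 1.128 um, not 1.0 um: the 1.0-1.128
um stretch is covered by neither detector after interior-only filtering.
This gap is accepted rather than papered over with edge-padded filter
values.

The SG implementation is hand-rolled as a single sparse linear operator
(exactness on cubics is tested to 1e-9, and it is cross-checked against
both a brute-force local polynomial regression and `signal::sgolayfilt`).

## 3. Outlier screening with a minimum volume enclosing ellipsoid

In-vitro spectra define what "good contact" looks like. `fit_pca()` (3
components) followed by `fit_mvee()` fits Khachiyan's minimum volume
enclosing ellipsoid (MVEE) around the in-vitro scores; the algorithm runs to
tolerance 1e-6 and the shape matrix is rescaled post hoc so enclosure of the
fitting points is exact, not approximate. An in-vivo spectrum is rejected
when its Mahalanobis-type distance exceeds `(radius_pct / 100)^2` with the
default operating radius of 105% — slightly outside the training hull, to
absorb benign in-vivo variation. `radius_sweep()` reports outlier counts at
75/100/105/125/150% so the operating point can be judged against the
ground-truth artifact flags (sensitivity/specificity) and against downstream
test error (`sweep_performance()`).

The MVEE is the one genuinely nontrivial numerical routine in the package,
so the test suite validates it against an *independent* optimizer: direct
BFGS maximization of the log-determinant dual over softmax-parameterized
simplex weights, with volumes required to agree within 1%.

## 4. Cross-validation design

Repeats of one location, and locations of one animal, are strongly
correlated; random row-level splits would leak. `make_folds()` therefore
splits at the *animal* level, and pairs animals by rank of their mean target
value: with `n` animals sorted by that mean, fold `k` validates animals at
ranks `k` and `k + ceiling(n/2)`. Every fold then sees one lower-range and
one upper-range animal, keeping validation target ranges comparable across
folds. The construction generalizes to any animal count (an odd count makes
the last fold a singleton); ties are broken alphabetically by animal id so
the plan is deterministic. Each animal is validated exactly once, and pooled
validation predictions cover every location exactly once.

Targets are min-max scaled and features standardized with statistics from
the calibration animals only (`fit_scalers()`).

## 5. Ensemble neural networks

Per target and fold, `train_ensemble()` trains six members — two
architectures x three initialization seeds (7, 14, 21):

* **Convolutional**: two 1-D convolution layers (kernel 8, 64 filters,
  ReLU; kernel 64, 16 filters, ReLU), flatten, dropout 0.75, dense 128
  (ReLU), linear output. The convolution forward/backward passes are the
  performance bottleneck and are implemented in C++ (RcppArmadillo) with a
  channels-first layout so each kernel offset becomes one dense matrix
  product.
* **Dense**: 120 (sigmoid) - 60 (ReLU) - dropout 0.2 - 15 (ReLU) - linear.

Training uses Adam (initial learning rate 1e-3, batch 32, MSE loss),
learning-rate halving on a 20-epoch validation plateau (floor 1e-5), early
stopping after 25 epochs without improvement, and restoration of the best
validation weights. Gradients for both architectures are verified against
central finite differences to 1e-6. The ensemble prediction is the plain
member mean; averaging across independent initializations and architectures
is what stabilizes the small-data fits.

### Runtime-driven problem sizes

On a single CPU a conv member costs about 8 seconds per epoch at full
cohort size, so the package's own default epoch caps are deliberately small
and asymmetric: `max_epochs = c(conv = 2, dense = 60)` for full-cohort runs.
The dense members (cheap, and the main accuracy carriers on this synthetic
problem) train to early stopping; the conv members contribute architecture
diversity at bounded cost. With that budget a two-target full-cohort run
completes in roughly ten minutes. Nothing prevents raising the caps when
more compute is available; the cap is a runtime choice, not a statistical
one.

## 6. Evaluation

`evaluate_sets()` aggregates repeat-level predictions to location level
(in vivo: non-outlier repeats only; a location whose repeats are all
rejected yields `NA` with a warning) and reports, per target and per set
(calibration / pooled validation / in-vivo test):

* **Spearman's rho**, computed from mid-ranks with exact tie handling
  (tested against brute-force pairwise enumeration);
* **RMSE** in target units;
* **NRMSE**, the RMSE normalized by the observed target *range* of the set
  and expressed in percent. Range normalization is the convention used
  here because the targets have very different units and spans; note it
  makes NRMSE sensitive to single extreme locations, so RMSE is always
  reported alongside.

Group contrasts (experimental vs control animal means) use an exact
Mann-Whitney U test for small samples, and in-vitro-vs-in-vivo location
pairs a Wilcoxon signed-rank test — both validated against
`stats::wilcox.test` with exact p-values.

## 7. The orchestrator

`run_pipeline(pipeline_config(...))` chains all stages, times them, and
optionally persists every intermediate artifact (spectra, analysis matrix,
outlier counts, per-repeat and per-location records, metrics, statistical
tests, radius sweep, a config echo and a log) as CSV/JSON into
`out_dir`. A failing stage reports its name (`stage 'preprocess' failed:
...`) while artifacts of completed stages remain on disk. Reruns of the
same configuration are bit-identical: the cohort derives from the single
global seed, and member training from the fixed seeds 7/14/21.

The package exposes no command-line interface of its own; the orchestrator
is an ordinary R function so that configurations remain first-class,
inspectable R objects, and a two-line `Rscript` call (see
`scripts/acceptance.R` in the source tree) covers unattended batch use.

## 8. Scope and limitations

* The forward model is a structural caricature; absolute performance
  numbers on synthetic data say nothing about real instruments.
* The outlier stage learns "good contact" only from in-vitro spectra, so
  benign in-vivo variation beyond the in-vitro hull is necessarily flagged
  at rates the operating radius controls; a zero false-positive rate is not
  achievable by construction.
* Networks are intentionally small and training budgets deliberately
  short; the defaults optimize testability on one CPU, not accuracy.
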