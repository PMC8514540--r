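---
title: "Methods: nuclei segmentation, γH2AX quantification and dose-response analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nuclei segmentation, γH2AX quantification and dose-response analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models and
procedures, the parameters that matter, the numerical choices behind them,
what the synthetic-data generator does and does not emulate, and the known
limitations. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The segmentation model

Nuclei are detected by supervised per-pixel classification of the DAPI
channel followed by morphological post-processing:

1. **Feature bank.** Every pixel is described by 65 responses from six
   linear/derivative filter families: Gaussian smoothing at
   σ₀ = 0.3 px and at σ ∈ {0.7, 1, 1.6, 3.5, 5, 10, 20, 35} px, and — at
   the eight larger scales only — Laplacian of Gaussian (LoG), Gaussian
   gradient magnitude, difference of Gaussians (DoG), the two
   structure-tensor eigenvalues, and the two Hessian-of-Gaussian
   eigenvalues (1 + 8 + 8·7 = 65 planes). σ₀ is listed with the smoothing
   family only; whether the original interactive tool also produced
   σ₀ variants of the derivative families is not determinable, so the
   conservative reading (smoothing only) is implemented.
2. **Classifier.** A probability random forest (`ranger`, 100 trees,
   explicit seed, single-threaded prediction for determinism) is trained on
   labeled pixels only, with no class reweighting — mirroring a
   sparse-annotation workflow where the user paints a few nucleus and
   background strokes. Densely annotated fields are deterministically
   subsampled to `max_pixels_per_class` (default 10 000) pixels per class;
   beyond that size the forest's decision surface no longer changes
   appreciably while training cost grows linearly.
3. **Post-processing.** The nucleus-probability map is binarized at 0.5,
   components are labeled under 8-connectivity, and components smaller than
   200 px are removed. Nucleus masks are then transferred unchanged to the
   γH2AX channel, where mean and total raw intensities are measured.

### Assumptions

* Nuclei are compact, roughly convex bright blobs on a darker background;
  the largest feature scale (35 px ≈ 11 µm at the default pitch) spans a
  whole nucleus, so the classifier can use regional context.
* Intensities are used raw. No flat-field correction, background
  subtraction or normalization is applied anywhere in the measurement
  path; analyses that compare intensities across plates therefore rely on
  the within-plate control normalization described in §4.
* Touching nuclei are **not** split: the pipeline is threshold →
  connected components → size filter, with no watershed. Dense confluent
  fields will under-count.

## 2. Parameters and their defaults

| parameter | default | units | rationale |
|---|---|---|---|
| `sigma0`, `sigmas` | 0.3; 0.7–35 | px | the eight-scale bank above |
| probability threshold | 0.5 | – | the maximum-probability rule for two classes; a pixel exactly at 0.5 counts as nucleus (inclusive lower bound, documented and tested) |
| `min_area_px` | 200 | px | objects below ≈20.8 µm² are fixation/imaging artifacts, not G1 nuclei; the inequality is strict (area 200 survives) |
| `connectivity` | 8 | – | standard for blob-like objects; 4 available |
| `pixel_pitch` | 0.3225 | µm/px | chosen so that 200 px ↔ 20.8 µm² (√(20.8/200) ≈ 0.3225); configurable |
| `n_trees` | 100 | – | the customary random-forest default of interactive pixel-classification tools; forest depth unrestricted |
| DoG inner scale | 0.66·σ | px | the common pixel-classification convention for the DoG pair |
| structure-tensor outer scale | 0.5·σ | px | same convention; gradient (inner) scale is σ itself |
| IoU match threshold | 0.5 | – | standard object-detection convention |
| `min_nuclei_floor` | 50 | nuclei/well | wells with fewer nuclei keep their count but report no γH2AX mean — an intensity average over a handful of nuclei is dominated by single-cell variability. A declared default, not a recovered value |

Border-touching nuclei are retained (no border exclusion is part of the
procedure), and no hole-filling is applied.

## 3. Detection quality metrics

Object matching is greedy one-to-one by descending IoU among candidate
pairs with IoU ≥ 0.5, ties broken by (ground-truth label, predicted label)
order, which makes scoring deterministic. Precision, recall and F1 are
computed from the matched counts; undefined ratios (empty denominators)
propagate as `NA`, never silently as 0. The Matthews correlation
coefficient is computed at **pixel** level on the pooled post-filter
foreground masks: object-level true negatives are ill-defined, and a pixel
MCC is the natural companion to object F1 for a segmentation whose errors
are partial-overlap errors. The conventional value 0 is returned when any
denominator factor vanishes.

## 4. Dose-response analysis

Responses are normalized within each plate to the mean of that plate's
vehicle-control wells (the control mean maps to exactly 100%), *then*
pooled across replicate experiments — so a global intensity or seeding
gain applied to one plate cancels. The four-parameter logistic is fitted
on the log₁₀ concentration axis with the **top fixed at 100%**: the data
are control-normalized, which pins the top, while the bottom plateau must
stay free because a nonzero bottom (growth arrest without kill) is a
finding, reported with its CI. The Hill slope is free (variable-slope
fit); constraining it is a modeling choice the data should make, not the
software. Zero-dose wells anchor the normalization but are excluded from
the fit (log 0 is undefined).

Numerical choices:

* Engine: Levenberg–Marquardt least squares (`minpack.lm::nlsLM`) with box
  bounds (bottom ∈ [−100, top], hill ∈ [0.05, 20], log IC50 within the
  sampled range ± 3 decades) and a small multi-start over Hill slopes
  {1, 0.5, 2, 4}, keeping the lowest residual sum of squares. The 4PL
  surface has flat valleys when a plateau is barely sampled, and a single
  start can stall there.
* A fit that ends on a bound, fails, or faces responses with no dose
  effect is reported as `converged = FALSE` with an explanatory `status`
  — never as fabricated parameters.
* 95% CIs are asymptotic normal intervals from the fit covariance
  (±1.96·SE). Profile-likelihood intervals are a non-goal.
* `compare_pIC50()` is a two-sided z-test on the difference using the two
  fits' standard errors — the plumbing used to ask whether a fixed-ratio
  mixture is more potent than either component.

When the dilution series does not bracket the IC50 (e.g. the IC50 sits
within a factor of ~3 of the top concentration and the lower plateau is
never approached), bottom and Hill become jointly unidentifiable and the
fit will honestly report enormous intervals or non-convergence; the
package's own recovery studies therefore use **potency-matched** series —
an 8-point sixfold dilution whose midpoint sits near the true IC50 —
exactly as screening practice matches each compound's top concentration to
its expected potency.

## 5. The synthetic-scene generator

`generate_scene()` emulates the statistical structure of two-channel
(DAPI + γH2AX) fluorescence fields with exact ground truth:

* ellipse-shaped nuclei with semi-axes drawn uniformly from 3.5–6.5 µm
  (areas ≈ 40–130 µm², comfortably above the 20.8 µm² artifact cutoff),
  random orientation, placed uniformly with a minimum 4 px separation by
  rejection sampling (bounded attempts, error on failure) — or with
  overlap if requested;
* per-nucleus DAPI fill intensities uniform in 9 000–15 000 camera units
  over a 300-unit background, so foreground is strictly brighter than
  background pre-noise;
* γH2AX rendered **only inside nuclei** (nuclear staining): basal mean
  600 units, a `gh2ax_positive_fraction` (default 0.2) of nuclei elevated
  by a gain of 5, extranuclear level near zero (50);
* optics and camera: Gaussian PSF (σ = 1 px), Poisson photon noise
  (scale 0.05, i.e. ≈4% shot noise at nuclear intensities), additive
  Gaussian read noise (SD 40), quantization to integers in [0, 65535].

The ground-truth label map is rendered *before* blur and noise, so truth
is exact by construction. `generate_dose_plate()` places wells on a
4PL count-versus-concentration curve (controls at the zero-dose
asymptote, per-field counts Poisson-sampled) and switches wells at or
above a configurable concentration threshold to a "damaged" γH2AX-positive
fraction.

The generator deliberately does **not** emulate: textured chromatin,
nucleoli, mitotic figures, out-of-focus fields, illumination gradients,
debris, or cell clumping with genuinely touching nuclei. Synthetic
benchmark results are therefore an upper bound on real-data performance:
they validate the pipeline's correctness (the chain recovers what the
generative model put in), not its robustness to every real-world artifact.
That is also why the published-quality floors are applied to the synthetic
benchmark as minimums — a correct implementation should do *at least* this
well on the easier domain.

## 6. Problem sizes used by the test suite

Chosen as the package's own desk-scale defaults:

* segmentation benchmark: 12 fields of 200×200 px with 13 nuclei each
  (~150 nuclei), train 4 / test 8, full ground-truth annotation subsampled
  to 8 000 px per class;
* 4PL recovery grid: pIC50 ∈ {4.5, 5.5, 6.5} × bottom ∈ {0, 20, 50}%,
  Hill 1, 4 replicates, 5% Gaussian noise, 100 seeds per cell,
  potency-matched series;
* end-to-end image→count→fit recovery: 3 replicate plates, 2 control + 8
  treated wells each, 3 fields/well of 288×288 px, expected 25 nuclei per
  control field, generating curve pIC50 5.5 / Hill 2 / bottom 0. The
  design was sized by a count-level power analysis so that Poisson
  counting noise leaves the pooled fit within ±0.1 log units of the truth
  with high probability; with fewer fields or shallower slopes the ±0.1
  recovery becomes a coin flip, which would test luck, not code.

## 7. Numerical notes

* Gaussian and Gaussian-derivative kernels are sampled on an integer grid
  with radius ⌈4σ⌉ and then *calibrated on the grid*: the smoothing kernel
  sums to exactly 1, first-derivative kernels respond to a unit ramp with
  exactly 1, and second-derivative kernels annihilate constants exactly
  and respond to x²/2 with exactly 1. This makes the analytic identities
  (constants preserved, ramps differentiated exactly, LoG = trace of the
  Hessian) hold to float precision and be testable at tight tolerances.
* Boundary handling is half-sample symmetric reflection, which preserves
  the image mean and avoids the dark rims at field edges that zero padding
  would produce (and that would bias border nuclei toward background).
* Filters are applied as separable dense operators (one n×n matrix per
  axis), which is exact and fast at field sizes up to a few hundred pixels;
  very large fields would warrant an FFT path, a known limitation.
* Structure-tensor eigenvalues are clamped at 0 against floating-point
  undershoot (they are non-negative in exact arithmetic); Hessian
  eigenvalue pairs are ordered descending.
* Connected components are found via the pixel-adjacency graph
  (`igraph::components`) and relabeled 1..K in column-major first-pixel
  order, making label assignment deterministic; the test suite checks the
  partition against an independent brute-force flood-fill oracle.

## 8. Known limitations

* No splitting of touching nuclei; confluent cultures under-count.
* Intensity readouts are raw camera units; cross-instrument comparisons
  require the control normalization and identical acquisition settings.
* The asymptotic CIs of the 4PL undercover slightly in small samples
  compared to profile likelihood; the recovery tests bound this empirically
  (coverage within [90%, 99%] at the default design).
* The classifier is a pixel classifier: it does not learn object-level
  shape priors, so unusual debris that locally resembles chromatin will be
  segmented if it survives the 200 px filter.
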