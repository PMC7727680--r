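---
title: "Lung field segmentation by Parzen-window boundary refinement: models and methods"
author: "pulmoseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lung field segmentation by Parzen-window boundary refinement: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulmoseg)
```

## The problem

Axial chest CT slices show the lung fields as large dark (low-attenuation)
regions inside a bright soft-tissue body on a dark air background. Many
quantitative analyses (airway measurement, density scoring, diaphragm
tracking) start from a pixel-accurate lung mask. Object detectors are good at
*finding* the lungs but typically deliver a coarse mask that bounds the organ
without hugging its wall. `pulmoseg` implements a two-phase pipeline around
that observation:

1. **Phase 1 — gate.** A slice-level classifier decides whether a slice shows
   lung at all. Scans contain apical and abdominal slices with no lung; a gate
   keeps them out of the segmentation stage entirely, which both saves time
   and prevents fabricated masks on slices where there is nothing to segment.
2. **Phase 2 — refinement.** A coarse lung mask (from any detector) is shrunk
   into a seed, the seed's intensity distribution defines a nonparametric
   lung-membership model, and the region boundary then grows or contracts,
   pixel ring by pixel ring, until the movement dies out on the lung wall.

Everything is testable without patient data through a synthetic thoracic
phantom with exact, constructive ground truth.

## Phase 2: the membership model

### Parzen-window density estimate

Given samples $z_1, \dots, z_n$ of a feature (by default the normalised pixel
intensity), the Parzen-window estimate of their density at a query $z$ is

$$\hat p(z) = \frac{1}{n h^d} \sum_{i=1}^{n} \delta\!\left(\frac{z - z_i}{h}\right),$$

where $\delta$ is the structuring-element (kernel) function and $h > 0$ the
bandwidth. Three kernels are provided: Gaussian, uniform (indicator of
$|u_j| \le 1/2$ per axis) and triangular. For the Gaussian kernel two
normalisation conventions are implemented:

* `"as_printed"`: $\delta(u) = \frac{1}{(2\pi)^d\,|C|}\,
  e^{-\frac{1}{2} u^\top C^{-1} u}$ — the form some sources print, whose
  constant differs from the multivariate-normal constant;
* `"standard"`: $\delta(u) = \frac{1}{(2\pi)^{d/2}\,|C|^{1/2}}\,
  e^{-\frac{1}{2} u^\top C^{-1} u}$, for which the 1-D kernel density
  estimate integrates to 1 (checked by a trapezoid-integration test).

Both are first-class citizens: they differ only by a global constant, and
because the pipeline uses densities only inside the ratio below, the two
conventions produce *identical* segmentations — a property asserted by a
test rather than assumed.

### Two-class posterior

A density for the lung class alone cannot decide membership; a calibrated
posterior needs a background model. The membership probability of a pixel
with feature $z$ is

$$p(z) = \frac{f(z)}{f(z) + b(z)},$$

with $f$ the Parzen density of the foreground (seed) samples and $b$ the
background density. Where both densities vanish (possible for
compact-support kernels) $p = 1/2$. Swapping the two sample sets maps
$p \mapsto 1 - p$ exactly.

**Sampling the two classes.** The seed is the coarse mask eroded by
`shrink_radius` (default 3 px) with a disc structuring element
$\{(dr, dc) : dr^2 + dc^2 \le r^2\}$; its interior supplies the foreground
samples. A guard band of width `2 * shrink_radius` around the seed is
excluded from both classes, because pixels near the putative boundary have
uncertain class. The background is modelled as the equal-weight average of
two stratum densities:

* the **near band** — the annulus of width `max(shrink_radius, 2)` px just
  outside the guard band, i.e. the tissue the region actually abuts;
* the **far field** — everything beyond.

The stratification matters. Background area is dominated by the air outside
the body, so a pooled background model underweights the soft tissue adjacent
to the lung. When a detector *overshoots* the wall (a dilated coarse mask),
the eroded seed still contains a thin ring of body pixels; with a pooled
background that contamination can outweigh the body evidence and the region
floods into the body. Giving the near band half the background mass keeps
$p(\text{body}) < 0.5$ in that regime while the far field keeps air firmly
in the background class. Each stratum is capped at half of `sample_cap`
(default 5000 per class) by seeded subsampling, so estimation cost is bounded
on full 512×512 slices.

### Boundary movement

Starting from the coarse mask (not the seed — an exact coarse mask should be
a fixed point), each pass

1. adds every frontier pixel (background pixel 8-connected to the region)
   with $p \ge \tau$;
2. removes every region-boundary pixel with $p < \tau$;
3. records the number of changed pixels.

The movement stops when at most `stability_tolerance` pixels change in one
pass (default 0 — full stabilisation) or after `max_iterations` passes
(default 100). The membership map is estimated once from the seed;
re-estimation from the current region at every pass is available behind the
`reestimate` flag but is not the default, since a single estimation followed
by edge movement matches the intended procedure and is an order of magnitude
cheaper. After the loop, only connected components intersecting the seed are
kept (noise speckles reachable through the background are discarded) and
interior holes — vessels inside the lung — are filled (`fill_holes = TRUE`),
because the segmentation target is the whole lung field, vessels included.

Ties at $p = \tau$ count as inside; on the default threshold $\tau = 0.5$
this also makes the "no evidence" value $p = 1/2$ expansionary only when a
pixel is already adjacent to the region.

### Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `h` | 0.05 | normalised intensity | kernel bandwidth; small = noisy estimate, large = oversmoothed boundary |
| `tau` | 0.5 | probability | membership threshold for frontier/removal decisions |
| `shrink_radius` | 3 | px | seed erosion; also sets the guard band (2x) and near-band width |
| `max_iterations` | 100 | passes | hard stop for the boundary movement |
| `stability_tolerance` | 0 | px/pass | changed-pixel count at which the movement is declared stable |
| `sample_cap` | 5000 | samples/class | bounds estimation cost; seeded subsampling above it |
| `feature_mode` | `"intensity"` | — | 1-D intensity, or intensity plus scaled (row, col) coordinates |

The defaults were chosen once on phantom data and are all overridable through
`parzen_config()`. `h = 0.05` resolves the lung/body contrast (about 0.7 in
normalised units, or 14 bandwidths) while tolerating the phantom's default
noise (sd about 0.03, i.e. 0.65 bandwidths).

## Phase 1: the gate protocol

The gate follows a strict model-selection protocol:

* **Features.** Extractors are plugins; the built-in `histo32` extractor
  returns a 32-bin normalised intensity histogram plus mean, sd, skewness,
  excess kurtosis, histogram entropy and the fraction of pixels below a
  quarter of the intensity range (lung fields fall below it, soft tissue does
  not). Deep feature extractors can be registered with
  `register_extractor()`; the package ships no network weights.
* **Normalisation.** Features are z-scored with mean and *population*
  standard deviation learned on the training set only; the test set is
  transformed with the same training statistics. Constant features are
  dropped and recorded. Inside cross-validation each fold fits its own
  normaliser on the fold's training portion, so no validation information
  leaks.
* **Tuning.** Random search with stratified 5-fold cross-validation
  (80%/20% train/validation per fold). Hyperparameter ranges: MLP hidden
  neurons in [2, 1001] (at most 4000 iterations, absolute tolerance 1e-3),
  KNN neighbours in {1, 3, 5, 7, 9}, at most 1500 random-forest trees, SVM
  cost $C \in [2^{-5}, 2^{15}]$ and RBF $\gamma \in [2^{-15}, 2^{3}]$ (both
  sampled log-uniformly, since the ranges span decades), polynomial degree in
  {3, 5, 7, 9}. The draw with the highest mean validation accuracy wins; ties
  go to the earliest draw. The default budget is 60 draws per family;
  the test suite and the acceptance script use smaller budgets (3–10 draws)
  and the fast families, which already saturate phantom separability.
* **Selection.** The extractor/classifier combination with the highest test
  F1 wins; ties break by accuracy, then lexicographically. F1 is the
  harmonic mean of **precision and sensitivity** — published per-combination
  score tables are numerically consistent only with that definition, even
  where surrounding prose says "sensitivity and specificity" — and undefined
  ratios (no positive predictions; single-class test sets) are reported as
  missing, never as 0.

## The synthetic phantom

`phantom_spec()` emulates what the refinement actually relies on: a bright
elliptical body (mean 1100) on a dark background (0), two dark elliptical
lung fields (mean 250) with bright vessel-like inclusions (mean 1000) that
*belong to the ground truth*, and additive Gaussian noise (sd 40, clipped at
0). The default contrast satisfies the documented assumption
`mu_body - mu_lung >= 4 * sigma_noise`. The default image size is 128 px
(full geometry at desk scale; everything scales to 512). Non-lung
(abdomen-like) slices keep the body and inclusions but have no dark fields.
Ground truth is constructive — the union of the two lung ellipses — so
pixel-exact scoring needs no annotation. The corruptor
(`corruption_spec()`) emulates a detector's output: disc erosion or
dilation, a diagonal shift, or a blocky bounding-box mask.

What the phantom does **not** emulate: real airway trees and fissures,
pathology (consolidation, effusion, nodules abutting the wall), partial
volume effects at the wall, bed/table structures, and Hounsfield-calibrated
intensities. Passing the phantom suite therefore demonstrates the machinery
— the estimator, the boundary movement, the protocol, the metrics — under
the stated contrast assumptions, not clinical performance. On real data the
critical assumption is that the coarse detector localises the lung and that
lung/soft-tissue contrast dominates noise at the wall.

## Evaluation suite

Six pixel-level scores: accuracy, sensitivity, Matthews correlation
coefficient (0 by convention when a denominator factor vanishes), Jaccard,
Dice (the identity `dice = 2*jaccard/(1 + jaccard)` is asserted in tests) and
the symmetric Hausdorff distance between mask boundaries (4-connected
boundary pixels, Euclidean metric, **pixel units** — no millimetre conversion
is attempted unless spacing is carried by the caller). A pair of empty masks
scores a vacuous Dice/Jaccard of 1 with a warning. Method comparison uses
the Friedman rank test in its untied chi-square form
$\chi^2_F = \frac{12}{nk(k+1)}\sum_j R_j^2 - 3n(k+1)$ (mid-ranks on ties; a
fully tied table scores exactly 0) with Nemenyi critical-difference flags at
$\alpha = 0.05$, reported as the conventional circle (difference) and
triangle (equality) marks.

## Numerical and design choices

* **Coordinates** are (row, col) from the top-left; discs are exact integer
  discs, so morphology matches brute-force oracles pixel for pixel.
* **Min-max normalisation of a constant image** returns all zeros rather than
  NaN, keeping the density machinery defined on degenerate inputs.
* **MONOCHROME1 DICOM** slices are inverted on load so larger always means
  brighter; the reader applies rescale slope/intercept when present and
  records whether it did (`calibrated`). Whether intensities are
  Hounsfield-calibrated before estimation is deliberately left visible to the
  caller — the membership model is invariant to affine intensity maps
  after min-max normalisation, which the pipeline applies per slice.
* **Determinism.** Every stochastic step (noise, jitter, subsampling, search
  draws, fold assignment, classifier fits) derives from explicit seeds;
  pipeline runs with equal seeds produce byte-identical JSON reports.
* **Problem sizes.** The shipped tests use 96–128 px phantoms, 20-phantom
  recovery sweeps, 100-slice gate datasets and 500 random 16×16 mask pairs
  against brute-force oracles; these sizes exercise every code path at full
  fidelity while keeping the default suite around a minute.

## Known limitations

* The refinement assumes the coarse mask overlaps the true lung and the seed
  survives erosion; a detector miss (no overlap) cannot be repaired.
* With intensity-only features, the posterior is a function of intensity
  alone: disconnected dark structures adjacent to the region (bowel gas,
  trachea) can be annexed if they touch the growing front; the
  seed-component filter removes only what stays disconnected.
* The Hausdorff distance is reported in pixels; comparisons across datasets
  with different spacing need external conversion.
* Blocky (bounding-box) coarse masks violate the "seed is mostly lung"
  assumption badly; they are supported as a corruption mode but recovery is
  not claimed for them.
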