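---
title: "Tracking neurons across days in the growing brain: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking neurons across days in the growing brain: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trackdev)
```

## The problem

Longitudinal two-photon calcium imaging follows the same field of view
(FOV) over consecutive days, one segmentation per day. To say anything
about how *individual* neurons change, the per-day ROI indices must be
chained into tracks. In adults this is hard enough (brain motion, day to
day optical changes); in developing animals the tissue additionally
*grows* between sessions — pairwise distances between neurons expand by
roughly 15 % over the second postnatal week — so the mapping between two
days' coordinate frames is not rigid. Tools that register every session
to one fixed reference accumulate this non-linearity and fail.

`trackdev` implements the sequential alternative: align only
*consecutive* days, where growth is small (≈2–3 %) and well approximated
by a single affine transform, and chain the resulting pairwise matches.

## The pipeline

For each consecutive pair $(s_k, s_{k+1})$:

1. **Registration.** A 2-D affine transform $T$ (or rigid, for ablation)
   is estimated from the two mean FOV images, mapping $s_{k+1}$
   coordinates into the $s_k$ frame. Affine = shift + rotation + scale +
   shear; the scale/shear degrees of freedom are what absorb growth.
2. **ROI warping.** Every ROI mask of $s_{k+1}$ is expressed in the
   $s_k$ frame by inverse-mapped nearest-neighbour lookup (binary
   occupancy; no holes, no fractional pixels).
3. **Matching.** A cost matrix $M_{ij} = 1 - \mathrm{IoU}(r_{s_k,i},
   r'_{s_{k+1},j})$ is built over all ROI pairs and a one-to-one
   assignment minimising total cost (equivalently maximising summed IoU)
   is found by linear sum assignment.
4. **Filtering.** Because the two days detect different cell sets,
   some assigned pairs are false matches. Their IoU distribution is
   bimodal — true matches overlap strongly, false ones barely — and an
   Otsu threshold on the assigned pairs' IoU histogram separates the two
   modes; pairs below the threshold are rejected.
5. **Propagation.** Tracks are seeded one per ROI of the first session
   and extended by accepted matches; a track with no accepted match at
   some step is terminated and never resumes.

Transforms are never chained: matching always happens in the local
$s_k$ frame, which is what makes the approach robust over long series.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `channel` | `"anatomical"` | which mean image drives registration; `"functional"` (dense indicator) works comparably when no sparse structural channel exists |
| `mode` | `"affine"` | `"rigid"` disables scale/shear (ablation; fails under growth) |
| `iou_floor` | 0.10 | minimum IoU an accepted match may have, whatever the threshold |
| `n_bins` | 256 | histogram bins for the Otsu threshold, over [0, 1] |
| `max_reject_iou` | 0.3 | unimodality guard (below) |
| `cell_prob_threshold` | 0.5 | segmentation-classifier probability below which ROIs are dropped at load time |

Registration defaults (three-level pyramid 4/2/1, normalised
cross-correlation, percentile intensity clipping at 1–99 %, Nelder–Mead
from identity with a BFGS polish at full resolution) are exposed via
`reg_control()`. The original toolchain's registration parameter set is
not published; these defaults are this package's own documented choice,
selected for same-modality mean images and for bit-for-bit determinism
(fixed initialisation, no stochastic optimiser component).

## Numerical choices and degenerate inputs

* **Coordinates.** 0-based `(row, col)` integer pixels, continuous
  coordinates with pixel centres at integers, transforms acting on
  `(x = col, y = row)`. One convention everywhere prevents silent
  transposes.
* **Otsu ties.** With 256 fixed bins over [0, 1], every split of an
  empty gap between two modes scores identically; the middle tied edge
  is returned so the threshold sits centrally in the gap.
* **Unimodality guard.** Otsu *assumes* bimodality. When nearly all
  assigned matches are true (e.g. two near-identical sessions), the IoU
  distribution is a single high mode and a raw Otsu threshold would
  slice it in half, terminating half of all tracks for no reason. False
  matches pair different cells, so their IoU clusters near zero: if the
  mean IoU of the class *below* the threshold exceeds `max_reject_iou`
  (default 0.3), the split is deemed to be cutting true matches and the
  floor alone applies. In measured regimes the rejected class means are
  0.00–0.13 when genuine false matches exist versus 0.82+ when not, so
  the default has wide margins on both sides. The rigid ablation keeps
  its Otsu threshold under this rule (rejected-class mean ≈ 0.11–0.13),
  which preserves the qualitative affine ≫ rigid ordering.
* **Assignment ties.** The Hungarian solver is deterministic for
  identical input; total cost is checked against brute-force enumeration
  in the tests, pair identity only where the optimum is unique.
* **Empty warped masks.** A mask mapping entirely outside the FOV (a
  cell that grew out of view) gets IoU 0 against everything and its
  track terminates via the floor.
* **Constant images** abort registration with a degenerate-input error;
  an optimiser that hits its iteration cap returns the best-found
  transform with `converged = FALSE` and a warning.

## Evaluation

Ground truth is built by manual annotation of a candidate subset: an
8×8 grid of equidistant FOV points, each mapped to the ROI whose median
pixel is nearest (duplicates collapsed). Only candidates tracked across
*all* sessions enter the ground-truth set. Against it,

$$\mathrm{CT} = \frac{2\,T_{rc}}{T_c + T_{gt}}$$

where $T_{rc}$ counts predicted tracks identical to a ground-truth row
at every session (no partial credit), $T_c$ counts complete
candidate-seeded predictions, and $T_{gt}$ the ground-truth tracks. CT
is the F1 score over perfectly reconstructed tracks: false positives
(complete but wrong) and false negatives (missed or terminated) both
pull it down. An early-terminated prediction counts as a false negative
but not a false positive, consistent with a ground truth that contains
only full-length tracks. The per-horizon proportion-correct curve uses
the fixed denominator $T_{gt}$, so it is non-increasing and its final
value is $T_{rc}/T_{gt}$.

## The synthetic benchmark

The generator (`synthetic_spec()`, `simulate_dataset()`) is the test bed
for every other module: elliptical Gaussian cells placed by seeded
rejection sampling, per-day geometry = isotropic scaling about the FOV
centre (default 1.025/day, compounding to ≈16 % over six day-steps — the
growth scale of the second postnatal week) composed with small uniform
rotation/translation jitter (±1°, ±2 px), i.i.d. per-cell-per-day
detection dropout (default 5 %), and Gaussian image noise. ROI masks are
the half-peak footprints of the noiseless cells, so segmentation noise
and detection failure are controlled separately; dropped cells stay
visible in the mean image (a segmentation miss, not an optical one). An
optional `permanent_loss` emulates cell death. Activity is private
Poisson spiking plus, on early days, shared synchronous events, and from
`transition_session` onwards motion-coupled rate modulation with
weights fixed across days; spikes are convolved with an exponential
calcium kernel (τ = 0.3 s). The motion trace is a rectified smoothed
Gaussian process. Defaults for sizes follow the study conditions
(512×512 px ≙ 720×720 µm, 30 Hz); default trace length is 3000 frames
(100 s) — long enough for the statistics used here while keeping the
benchmark fast.

What passing synthetic tests does **not** show: robustness to
non-affine (deformable) growth fields, segmentation noise on mask
shapes, neuropil contamination, optical PSF effects, or z-drift. The
generator's geometry is exactly the model class the method assumes, so
synthetic results are an upper bound on real-data performance; the
benchmark's role is to verify the machinery, not to re-estimate
real-world accuracy.

## Longitudinal analyses

All analyses operate on the aligned traces of completely tracked cells
(`extract_tracked_traces()`):

* **Event rates** — boxcar-binned (10 frames) traces; local maxima with
  height and prominence ≥ 1 SD of the binned trace; events/minute.
* **Functional connectivity (FC)** — Pearson correlation of full
  traces; distance profiles average FC in 30-µm bins and the
  neighbour correlation is the intercept of an
  $a\,e^{-d/\lambda} + c$ fit (the additive offset is this package's
  choice; the pure-exponential alternative is recoverable by reading
  off `a + c` versus `a`).
* **FC similarity** — Pearson correlation over strict upper triangles
  of two days' FC matrices (unit diagonals excluded — they would
  inflate r); the within-day split-half similarity serves as the noise
  ceiling and as the fixed upper asymptote of the transition fit.
* **Transition fit** — decreasing logistic $y(t) = b + (U - b)/(1 +
  e^{k(t - t_0)})$ with $U$ fixed; bounded least squares from a
  deterministic multi-start grid. Transition age = $t_0$; transition
  time = distance between the two fourth-derivative extrema flanking
  $t_0$, located numerically on a dense grid (the closed-form logistic
  locations act as the test oracle for this numerical reading).
* **Dimensionality** — number of principal components reaching 90 %
  cumulative variance, computed on raw dF/F (binning exposed as
  config).
* **Decoding** — ridge regression $\|y - X\beta\|^2 +
  \lambda\|\beta\|^2$ solved in closed form on z-scored features
  (training-fold statistics only), with nested five-fold
  cross-validation on contiguous temporal blocks; $\lambda$ grid
  log-spaced $10^{-3}..10^5$. Cross-day decoding applies each day's
  model (with its stored standardisation) to every other day's aligned
  activity; diagonal entries are always the cross-validated same-day
  values. Test $R^2 = 1 - SS_{res}/SS_{tot}$ on the held-out segment
  and may be negative.

## Known limitations

* Tracks only extend forward from the first session; cells absent one
  day are lost even if re-detected later (no gap re-linking), and
  matching is strictly one-to-one (no splits/merges).
* Order sensitivity is inherent to sequential linkage: tracking
  $s_0 \to s_N$ makes no claim of reverse-order equality.
* Sessions are treated as consecutive in the order given; skipped days
  simply mean a larger inter-session transform.
* The loader's canonical dialects are TIFF + CSV (+ JSON sidecars); a
  reader for the common Python segmentation tool's binary per-plane
  output is not included, since no installed reader for that format
  exists here and the arrays it holds map 1:1 onto the CSV dialect.

## A minimal run

```{r example, eval = FALSE}
spec <- synthetic_spec(n_cells = 100, n_sessions = 4,
                       fov_shape = c(256L, 256L), min_distance = 14)
ds <- simulate_dataset(spec, seed = 1)

res <- link_sessions(ds$sessions, track_control(verbose = FALSE))
report <- compute_ct(ds$ground_truth$tracks, res$track_table)
report

tracked <- extract_tracked_traces(res$track_table, ds$sessions)
pairwise_distance_growth(tracked)   # recovers ~1.025^d per day
```
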