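---
title: "Measuring pressure-injury area from 16-band hyperspectral cubes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring pressure-injury area from 16-band hyperspectral cubes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsiwound)
```

## The measurement problem

Bedside practice records pressure-injury size as ruler length × width
(the LW rule). Wounds are irregular, and the inflamed erythema surrounding
them is easily included in the measurement, so the LW rule overestimates —
reported overestimation for ruler planimetry is on the order of 40%. This
package implements an imaging alternative: a snapshot-mosaic hyperspectral
camera records a reflectance spectrum (16 visible bands, 465–630 nm) at
every pixel; unsupervised clustering separates wound tissue from healthy
skin by spectral shape rather than by a human's visual boundary judgment;
and the wound area follows from pixel counting at a known pixel pitch.

The pipeline is deliberately close to what a clinical study would run:
white-reference calibration, a user-framed ROI (the operator still decides
*where* the wound is, not *how big* it is), k-means with `k = 2`, and a
short, fixed morphology chain before planimetry.

## Reflectance calibration

Raw counts are converted by flat-field normalization,
`R = f (raw − dark) / (white − dark)`, with `f` the known reflectance of
the white calibration board (default 0.98, the board the acquisition
protocol specifies; images taken at 70 cm working distance). The dark
frame is optional — whether the camera already subtracts dark current is
device-dependent, so the package exposes it as an input rather than
guessing. Calibrated values are clipped to [0, 1.10]: bedside lighting is
not controlled, and small specular excursions above 1 are expected noise,
not errors. A non-positive `white − dark` anywhere is a hard error that
reports the number of offending entries, since it means the reference
frame is unusable.

Calibrating an already-calibrated cube against a constant-0.98 white is
the identity, which is the invariant the unit tests pin.

## Segmentation and the wound-selection rule

Pixel spectra are clustered with k-means written for this package:
greedy k-means++ initialization (several distance-weighted candidates per
step, keeping the one that most reduces the potential), Lloyd iterations
to a centroid-shift tolerance of 1e-6, and then a Hartigan-style polish
that applies single-point reassignments while any strictly reduces the
total within-cluster sum of squares. The polish is there because Lloyd
alone, even restarted, sticks in fixed points on small or nearly tied
configurations; single-point moves escape exactly those. Both stages are
strictly inertia-decreasing, so the recorded inertia trace is monotone.
Ten seeded restarts are kept by lowest inertia; everything is
deterministic given the seed. The test suite and the acceptance script
verify the fit against an exhaustive enumeration of all bipartitions on
batches of seeded 8-point instances, requiring at least a 95% optimality
rate.

If a cluster empties mid-iteration its centroid is re-seeded at the point
farthest from its current centroid; `k` is never silently reduced.

`k` defaults to 2 because the ROI step has already removed non-skin
content, leaving a wound-vs-skin contrast. For `k > 2` the wound cluster
is chosen by the **hemoglobin-dip rule**: minimize mean centroid
reflectance over 534–586 nm divided by mean over 600–630 nm. Granulation
tissue and erythema are perfused; oxy-hemoglobin absorbs strongly in the
green-yellow window and much less in red, so the wound centroid has the
smaller ratio. The study data this design follows does not state a
labeling rule, so the rule (and an alternative `"darkest"` rule) is an
explicit, recorded choice. All 16 bands enter the distance; an optional
per-spectrum mean normalization makes the clustering invariant to global
brightness scaling, but is off by default because absolute darkness is
itself discriminative here.

Coordinates are 1-based and ROIs inclusive, matching R matrix indexing;
cluster labels are likewise 1-based.

## Two areas per wound

* **Machine LW** — the axis-aligned bounding box of the raw wound mask,
  `(row extent × pitch) · (col extent × pitch)`. This mirrors the ruler
  convention, so nurse and machine LW are directly comparable. No rotated
  rectangle is fitted.
* **Machine morphology** — pixel count × pitch² after cleaning: binary
  opening with a cross of radius 1 (speckle removal), the single largest
  4-connected component (the study design has one wound per case; ties
  break toward the smaller top-left bounding-box corner), then filling of
  fully enclosed holes. Opening is anti-extensive and hole filling only
  adds enclosed background, so the result is a subset of the hole-filled
  opened input. The chain is the minimal standard one; the source study
  names an "image morphology algorithm" without specifying operators, so
  the chain here is this package's documented choice.

The LW area computed on the *raw* mask and the planimetric area on the
*cleaned* mask are an explicit pairing decision: the clinical table this
package bundles contains cases where the morphology area exceeds the LW
area, which is only possible if the two columns came from different
masks. Bounding-box dominance (`planimetric ≤ LW`) therefore holds per
mask, not necessarily across the two reported numbers.

An empty wound mask is an error at every stage (with the stage named),
never area 0 — every study case had a wound, so emptiness means
segmentation failure and silence would hide it. Pixel pitch is a
configuration input (derivable from a fiducial grid); both areas scale
exactly as pitch².

## Agreement statistics

All statistics operate on the bundled 30-case table (`pi_case_table()`),
transcribed from the study's published per-case areas and stages, with
the seven cases flagged there for inconsistent wound localization carried
as an `outlier` column.

* Pearson *r* and Spearman ρ delegate to `stats::cor` (midranks for
  ties) behind precondition checks.
* Single-measure ICC is computed from ANOVA mean squares; both ICC(1,1)
  and absolute-agreement ICC(A,1) are reported because the study does not
  say which form it used, and the two differ exactly when the methods are
  offset.
* `icc_mixed()` estimates the variance-components ICC
  σ²_subject / (σ²_subject + σ²_residual) by ANOVA method of moments
  (unbalanced designs via the effective replicate count; negative
  between-subject components truncated at 0). The study's triplicate raw
  data are not published, so this estimator is validated by parameter
  recovery on simulated replicates (true ICC 0.8, 30 subjects × 3), not
  against the study's printed mixed-model values.
* Kappa needs categories; the binning behind the study's κ values is not
  recoverable, so the default here is pooled-quintile binning over the
  union of both methods' values, recorded in every report, with
  `fixed_edges` as the alternative. Weighted κ uses quadratic weights;
  CIs use the Fleiss–Cohen–Everitt large-sample variance. The printed κ
  cells of the study are consequently *not* reproduction targets here.
* Reports keep full precision; printing rounds to 2 decimals. Comparisons
  against the study's printed correlation cells are made at printed
  precision by truncation, which is the convention those printed values
  follow.

`reproduce_table4()` emits the full 3-pairing × 2-subset table. On the
bundled data, removing the seven flagged cases raises Spearman ρ for all
three pairings — the study's qualitative claim, which the acceptance
tests re-verify.

## The phantom generator

`generate_phantom()` builds scenes the pipeline can be validated on
without any image deposit: a wound region (digital disk, default radius
20 px at 0.05 cm pitch, or an irregular blob from thresholded smoothed
noise) carrying a wound spectrum, skin elsewhere, an optional erythema
halo ring blending the two spectra with weight decaying outward, a planar
multiplicative illumination gradient (±5% by default — bedside lighting
is uneven), and additive Gaussian noise (default σ = 0.01 reflectance).
The truth mask is discrete, so the true area is exact by construction
regardless of shape realism.

The spectral models are fixed documented constants: skin rises
piecewise-linearly from 0.35 at 465 nm to 0.60 at 630 nm; wound equals
skin minus a smooth dip of depth 0.25 centered at 560 nm with compact
support 508–612 nm (zero at 465 nm, floor 0.05). They provide the
hemoglobin-like contrast the selection rule keys on; they are not
radiative-transfer skin models, and passing tests on phantoms shows the
pipeline's numerics are right, not that real wounds are this separable.
Real data add specular glints, shadows, staging heterogeneity and
camera PSF effects the generator deliberately omits.

`simulate_nurse_measurement()` closes the loop on the overestimation
mechanism: the simulated nurse measures the LW box of the wound *plus
halo* (optionally with seeded uniform ruler jitter), the machine measures
the wound only. With a 9 px halo on the default disk the mean
nurse/machine-morphology ratio is ≈ 2.4 — the same direction and beyond
the ≈ 44% overestimation regime reported for ruler planimetry.

All phantom randomness flows from one integer seed; no global RNG state
is touched (`withr::with_seed` throughout).

## Problem sizes and determinism

Defaults used by the tests and the acceptance script: 96 × 96 px scenes
(50 seeds for area recovery), 20 eight-point instances for the exhaustive
k-means oracle, 200 simulations for ICC recovery, 1000 draws for kappa
calibration. These sizes give stable estimates while keeping a full run
in tens of seconds. Same cube + same seed yields an identical mask, and the CLI's
JSON reports are byte-identical across reruns.

## Known limitations

* Depth is not measured; a 2-D planimetric area understates full wound
  extent for undermined wounds.
* One wound per scene: multi-wound cases would need the
  largest-component rule relaxed.
* The ENVI reader covers the flat uncompressed rasters this pipeline
  produces and consumes (bil/bip/bsq, int16/uint16/float32/float64,
  little-endian), not the full header dialect.
* The wound-selection rule presumes a visible-range sensor with coverage
  of both the hemoglobin window and a red reference band; sensors without
  600–630 nm bands need the `"darkest"` rule.
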