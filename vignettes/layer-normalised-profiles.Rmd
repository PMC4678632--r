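---
title: "Layer-normalised depth profiles of stratified epidermis: methods and design"
author: "epidepth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Layer-normalised depth profiles of stratified epidermis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 6, fig.height = 4)
library(epidepth)
```

## The measurement problem

Interfollicular keratinocytes proliferate in the basal layer of the
epidermis and differentiate as they migrate towards the skin surface over
roughly two weeks, so a cell's depth within the tissue is a proxy for its
differentiation stage. Confocal immunofluorescence of skin cross-sections
therefore encodes "expression versus differentiation" as "intensity versus
depth" — but raw depth in micrometres is not comparable across tissue
samples, because total epidermal thickness and the thickness of individual
layers vary substantially between samples and even along a single section.

`epidepth` addresses this with a *layer-normalised* coordinate. Operators
supply four boundary polylines that segment a cross-section, deep to
superficial:

* `b0` — the dermal–basal junction (recognisable from the juxtaposition of
  basal keratinocytes and dermis),
* `b1` — the top of the basal layer,
* `b2` — the top of the merged spinous/granular compartment (the two
  cannot be told apart without additional histological markers, so they
  carry a single label),
* `b3` — the surface of the transitional layer, where keratinocytes have
  flattened and above which lies the cornified layer.

Boundary detection is deliberately out of scope: the morphological criteria
above are an operator's judgement, not an algorithm, so the package treats
boundaries as curated inputs and validates them (full-width span,
single-valued depth per column, strict non-crossing ordering).

## The normalised-distance transform

For a pixel at position $p$ inside a quantified layer bounded by the deeper
polyline $B_{in}$ and the more superficial polyline $B_{out}$, the
fractional position is the linear interpolation

$$ f(p) = \frac{d(p, B_{in})}{d(p, B_{in}) + d(p, B_{out})}, $$

with $d$ the exact Euclidean point-to-polyline distance (minimum over
segments, computed in compiled code). The normalised distance is then

$$ u(p) = \ell + f(p), \qquad \ell \in \{0, 1, 2\} $$

for the basal, spinous/granular and transitional layers respectively, so
$u$ spans $[0, 3]$ with one unit per quantified layer. Pixels in the dermis
($u$ undefined below $b0$) and in the cornified layer or exterior (above
$b3$) are excluded from quantification — the cornified layer commonly
carries autofluorescence and non-specific signal — and are always reported
with a reason code rather than silently dropped.

Design choices worth stating explicitly:

* **Why $d_{in}/(d_{in}+d_{out})$.** Any monotone map anchored at both
  boundaries would do; this one is invariant under rigid motions of image
  and boundaries together and under scaling of the layer thickness, which
  is the entire point of the coordinate (profiles from thick and thin
  tissue become directly comparable). Both anchor properties ($f = 0$ on
  the inner boundary, $f = 1$ on the outer) are exact.
* **Per-layer units rather than a global $[0,1]$.** Keeping one unit per
  layer pins the layer boundaries at $u = 1, 2$ regardless of the layers'
  relative thicknesses, so phenotypically distinct compartments never mix
  across samples. A convenience flag (`rescale_unit`) divides by 3 for
  consumers who want $[0, 1]$.
* **Tie rules.** A point exactly on a boundary belongs to the layer on its
  superficial side, with two anchoring exceptions: on `b0` it is basal
  ($u = 0$), and on `b3` it is transitional ($u = 3$), so the coordinate's
  endpoints are attained.
* **Distances are 2D Euclidean in the imaging plane.** The z-position of a
  slice never enters $u$; stacks are transformed per slice (policies:
  middle slice, every slice, or z-mean of intensities).

## From samples to profiles

Sampled intensities are **mean-normalised** — divided by the mean intensity
of the quantified pixel set of one (target, patient, stack) — which removes
detector gain. The scope is per stack because no cross-file bookkeeping is
required and the factor is recorded in the profile metadata. Profiles are
then **LOESS-smoothed** (degree-1 local polynomials, tricube weights over
the span-fraction nearest neighbours; the standard `stats::loess`
implementation with an exact direct surface) and evaluated on a fixed grid,
by default 151 nodes on $[0, 3]$. The span default of 0.3 is exposed as a
parameter and recorded in output metadata; it trades variance against bias
near sharp features, and constant or exactly linear signals are reproduced
to numerical precision by construction of local linear fits. At least 10
points, and at least 3 points per local window, are required.

Profiles are compared by re-evaluating both on the intersection of their
grid ranges and reporting RMSE (in mean-normalised units) and Pearson
correlation; replicate tissues are pooled node-wise into a mean and a
min–max envelope.

## The synthetic-tissue generator

No public numerical ground truth exists for this kind of measurement, so
the package ships a generator whose outputs stand in for acquired data with
a known truth channel. Its default preset reproduces the acquisition
geometry the pipeline targets: 1,024 × 1,024-pixel frames at 160 nm/pixel
(near the diffraction limit of a 63×/NA 1.32 oil objective), 8-bit
uncompressed TIFF, 4× frame averaging, and 5 slices at a 2.5 µm z-step
spanning a 10 µm z-interval. (Slice spacing within the z-interval is a free
choice; 4 × 2.5 µm was fixed once so the interval is ~10 µm.) Default layer
thicknesses are realistic for interfollicular epidermis — basal 12 µm,
spinous/granular 45 µm, transitional 12 µm, cornified 15 µm — and a
`patient_presets()` helper produces three replicates with all thicknesses
multiplied by 1.0, 1.6 and 0.6, mimicking the pronounced
thick/typical/thin variation seen across real skin samples.

Generation proceeds in three seeded, individually testable stages:

1. **Boundaries.** The dermal–basal junction undulates as a sinusoid of
   configurable amplitude (default 6 µm) and wavelength (60 µm) plus three
   low-amplitude random harmonics; superficial boundaries follow the same
   undulation damped by 0.5, 0.25 and 0.1, so the surface is flatter than
   the junction, and the set is validated as non-crossing. Amplitudes at
   or above the basal thickness are rejected up front. Zero amplitude
   degenerates to straight horizontal lines.
2. **Compartments and truth.** Each quantified layer is tiled with cells by
   a seeded Voronoi-like tessellation (jittered seed grid,
   nearest-seed assignment): roughly isotropic cells in the basal and
   spinous/granular layers, and cells flattened to an aspect ratio above
   3:1 in the transitional layer. Each cell gets a membrane band (default
   2 px), a nucleus of default radius 2.5 µm (flattened with the cell;
   radius 0 suppresses nuclei) and cytoplasm elsewhere. The cornified
   layer is anuclear with a high constant "autofluorescence" intensity, so
   the exclusion logic is genuinely exercised. The ground-truth depth of
   every epidermal pixel uses the same fractional-distance formula as the
   production transform applied to the analytic boundaries; the
   *independent* oracle for tests is the closed form for straight
   horizontal boundaries, which avoids circular testing.
3. **Noise.** Each slice is the average of `n_frames_averaged` simulated
   frames: Poisson shot noise with variance intensity/`photon_gain`
   (default gain 0.5, i.e. shot-noise s.d. ≈ 14 at intensity 100) plus
   additive Gaussian read noise (s.d. 2). The averaged frame is mapped
   affinely so its 0.1–99.9 percentiles span the quantisation range
   (emulating gain/offset adjusted to use the full dynamic range with
   minimal underflow and saturation), then rounded to the bit depth.

What the generator does *not* emulate — and hence what green tests do not
show about real data: optical point-spread blur, fluorophore spectra,
depth-dependent attenuation, tissue tilted relative to the imaging plane,
and the irregular, operator-curated geometry of real boundary tracings.
The generator validates the computational pipeline, not the biology.

```{r tissue, eval = FALSE}
sp <- tissue_spec()                  # the default acquisition preset
gs <- generate_stack(sp, seed = 1)
gs$stack
```

## Numerical choices and degenerate inputs

* Point-to-polyline distance is exact point-to-segment projection; for
  per-column boundaries the scan is pruned by the horizontal gap, giving
  near-linear cost in sampled pixels.
* A point with zero distance to *both* bounding polylines (crossing
  geometry) is a contract error, not a 0/0.
* The quantisation rescale falls back to plain round-and-clamp when the
  percentile range is degenerate (constant images stay constant).
* Boundary validation lists every violated column, so operators can repair
  tracings rather than bisect failures.
* All randomness is seeded; identical (spec, seed) pairs give bit-identical
  stacks, and pipeline runs are byte-for-byte reproducible from their
  provenance records (which deliberately contain no timestamps).
* Reals in text outputs carry 6 significant digits — more than 8-bit
  source data can meaningfully support.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script validate the pipeline end to end
on scaled-down frames chosen once: 192–512-pixel-wide tissues for unit
properties, and 256 × 704 frames at 160 nm/pixel (three "patients" of
thickness multipliers 1.0/1.6/0.6, ~8,000 sampled pixels each) for
full-pipeline recovery, with the imposed piecewise-linear depth-intensity
function low in the basal layer, peaking at $u = 2$ and declining through
the transitional layer. These sizes give statistically stable results
(recovery RMSE well under 5 % of the imposed range; thickness-invariance
RMSE around 0.01 in mean-normalised units) while keeping a full run in the
low minutes on one CPU. The noise-model check estimates variances from
10,000 replicate measurements of a flat-intensity pixel.

## Known limitations

* Boundaries must be single-valued in depth per column; dermal papillae
  that fold back over themselves cannot be represented.
* Whole-cell masks are treated as 2D per-slice labellings.
* Real microscope settings exports need converting into the documented
  `KEY<TAB>VALUE` dialect; no native vendor formats are parsed.
* Statistical comparison across samples is limited to RMSE, correlation
  and envelopes; no inferential testing is provided.
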