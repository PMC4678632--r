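# epidepth

Layer-normalised depth profiles of protein expression in stratified
epidermis, from confocal immunofluorescence image stacks.

## The problem

Keratinocytes proliferate in the basal layer of the epidermis and
differentiate as they migrate to the surface, so depth within the tissue is
a proxy for differentiation stage. Quantifying "expression versus
differentiation" from confocal cross-sections is confounded by the fact
that epidermal thickness — total and per layer — varies widely between and
within tissue samples. `epidepth` is for microscopists and systems
biologists who want to turn single-channel image stacks of skin
cross-sections into depth-expression profiles that are comparable across
samples of different thicknesses.

## The coordinate at its core

Operator-drawn boundary polylines `b0..b3` segment a cross-section into
dermis, basal layer, merged spinous/granular compartment, transitional
layer and cornified layer/exterior. A pixel `p` inside a quantified layer
bounded by the deeper polyline `B_in` and the shallower `B_out` gets the
fractional position

    f(p) = d(p, B_in) / ( d(p, B_in) + d(p, B_out) )

(`d` = exact Euclidean point-to-polyline distance), and the normalised
distance

    u(p) = layer + f(p),   layer ∈ {0 basal, 1 spinous/granular, 2 transitional}

so `u` spans [0, 3] with one unit per layer and layer boundaries pinned at
u = 1, 2 regardless of thickness. Dermis and cornified/exterior pixels are
excluded from quantification and reported with reason codes. Sampled
intensities are mean-normalised per stack and LOESS-smoothed (degree-1
local fits, tricube weights, default span 0.3) onto a fixed grid; profiles
are compared via RMSE/Pearson correlation and pooled with min–max
envelopes.

A seeded synthetic-tissue generator (boundary undulation, Voronoi-like cell
tessellation with nuclei and membranes, Poisson + Gaussian noise under
frame averaging, full-dynamic-range quantisation) provides image stacks
with per-pixel ground truth for validating the whole pipeline; its default
preset emits 1,024 × 1,024-pixel 8-bit frames at 160 nm/pixel with 4×
frame averaging over a 10 µm z-interval.

## Worked example

Three synthetic "patients" share the same imposed depth-intensity function
but have all layer thicknesses multiplied by 1.0, 1.6 and 0.6:

```r
library(epidepth)
specs <- patient_presets(tissue_spec(
  frame_width_px = 256, frame_height_px = 704,
  layer_thicknesses_um = c(basal = 8, spinous_granular = 20,
                           transitional = 6, cornified = 8),
  undulation_amplitude_um = 4, undulation_wavelength_um = 40,
  n_slices = 3))
profiles <- Map(function(sp, seed) {
  gs  <- generate_stack(sp, seed = seed)
  tbl <- quantified_points(transform_stack(gs$stack, gs$boundaries))
  set.seed(seed); tbl <- tbl[sample(nrow(tbl), 8000), ]
  fit_profile(tbl, span = 0.3)
}, specs, c(101, 102, 103))

profiles$Pat1
#> LOESS depth profile: 8000 points, span 0.30, grid 0..3 (151 nodes)
#>   mean-normalisation factor 118.133; fitted range 0.478..1.662
compare_profiles(profiles$Pat1, profiles$Pat2)
#> Profile comparison on u in 0.00..3.00 (151 nodes): rmse 0.04228, Pearson r 0.9954
aggregate_profiles(profiles)
#> Pooled profile of 3 samples on u in 0.00..3.00 (151 nodes); max envelope width 0.104
```

Although Pat2's epidermis is 2.7× thicker than Pat3's, their
layer-normalised profiles agree to an RMSE of a few percent of the mean
level (Pearson r > 0.99) — the thickness variation that the coordinate is
designed to remove. `plot(aggregate_profiles(profiles))` draws the pooled
mean with its envelope.

A command-line interface wraps the same functions
(`exec/epidepth simulate|transform|profile|compare|extract-cells`, YAML
configs, JSON provenance records); see `?pipeline_main`.

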