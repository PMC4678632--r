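Package: epidepth
Title: Layer-Normalised Depth Profiles from Confocal Images of Stratified Epidermis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Transforms confocal immunofluorescence image stacks of human
    epidermis into one-dimensional, layer-normalised expression profiles along
    the keratinocyte differentiation gradient. Operator-drawn tissue-layer
    boundaries (dermal junction, basal, merged spinous/granular, transitional,
    cornified surface) define a normalised-distance coordinate in which each
    sampled pixel receives its layer index plus its fractional position within
    the layer, computed by linear interpolation between bounding polylines.
    Sampled intensities are mean-normalised and LOESS-smoothed into
    depth-expression profiles that can be compared and pooled across tissue
    samples of different thicknesses. A synthetic-tissue generator produces
    confocal-like stacks of layered epidermis with per-pixel ground truth
    (compartment labels, true normalised depth, imposed intensity functions)
    under a Poisson-Gaussian noise model with frame averaging, enabling
    end-to-end validation of the pipeline. Includes readers and writers for
    uncompressed multipage TIFF stacks, microscope-settings text files,
    sampled-record tables, boundary polylines and labelled cell masks, plus a
    command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
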