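#' Default per-compartment intensity functions
#'
#' Imposed intensity (arbitrary detector units, before noise and
#' quantisation) as a function of normalised depth `u` in \[0, 3\] for each
#' compartment. The epidermal defaults qualitatively mimic a
#' phosphoprotein-like target: low basal signal rising to a peak around the
#' top of the spinous/granular compartment (`u = 2`) and declining through
#' the transitional layer; the cornified layer carries a high constant
#' "autofluorescence" signal independent of the target (so exclusion logic
#' is exercised), the dermis a low constant background and the exterior
#' near-zero.
#'
#' @return named list of functions of `u`, one per compartment
#'   (`dermis`, `nucleus`, `cytoplasm`, `membrane`, `cornified`,
#'   `exterior`).
#' @export
default_intensity_profiles <- function() {
  list(
    dermis    = function(u) rep_len(15, length(u)),
    nucleus   = function(u) 30 + 25 * u,
    cytoplasm = function(u) 40 + 140 * pmax(0, 1 - abs(u - 2)),
    membrane  = function(u) 120 - 20 * u,
    cornified = function(u) rep_len(180, length(u)),
    exterior  = function(u) rep_len(2, length(u))
  )
}

#' Uniform intensity functions for recovery experiments
#'
#' Imposes the same depth-intensity function `g(u)` on every epidermal
#' compartment (nucleus, cytoplasm, membrane), so the pipeline's smoothed
#' profile should recover `g` directly rather than a compartment mixture.
#'
#' @param g function of normalised depth `u` on \[0, 3\].
#' @param dermis,cornified,exterior constant intensities for the
#'   non-quantified compartments.
#' @return named list of compartment intensity functions.
#' @export
uniform_intensity_profiles <- function(g, dermis = 15, cornified = 180,
                                       exterior = 2) {
  list(dermis = function(u) rep_len(dermis, length(u)),
       nucleus = g, cytoplasm = g, membrane = g,
       cornified = function(u) rep_len(cornified, length(u)),
       exterior = function(u) rep_len(exterior, length(u)))
}

#' Synthetic-tissue specification
#'
#' Parameters of the synthetic epidermis generator. The defaults reproduce
#' the acquisition geometry the pipeline targets: 1,024 x 1,024 pixel
#' frames at 160 nm/pixel (near the diffraction limit of a 63x/1.32 NA
#' objective), 8-bit quantisation, 4x frame averaging, and 5 slices at a
#' 2.5 um z-step spanning a 10 um z-interval. Layer thicknesses are
#' realistic for interfollicular epidermis; the dermal-basal junction
#' undulates (rete-ridge-like) with the given amplitude and wavelength.
#'
#' @param frame_width_px,frame_height_px frame size in pixels.
#' @param n_slices number of z-slices.
#' @param pixel_size_nm lateral pixel pitch, nanometres.
#' @param z_step_um z spacing between slices, micrometres.
#' @param layer_thicknesses_um named positive reals for `basal`,
#'   `spinous_granular`, `transitional` and `cornified` layer thicknesses
#'   (micrometres).
#' @param undulation_amplitude_um amplitude of the dermal-basal undulation
#'   (micrometres); must be smaller than the basal thickness so boundaries
#'   cannot cross. 0 gives straight boundaries.
#' @param undulation_wavelength_um dominant undulation wavelength.
#' @param nucleus_radius_um nuclear radius; 0 suppresses nuclei.
#' @param membrane_width_px width of the rendered plasma-membrane band.
#' @param intensity_profiles per-compartment intensity functions of `u`,
#'   see [default_intensity_profiles()].
#' @param photon_gain photoelectrons detected per intensity unit; shot
#'   noise has variance `intensity / photon_gain`.
#' @param read_noise_sd standard deviation of additive Gaussian read noise
#'   per frame (intensity units).
#' @param n_frames_averaged frames averaged per slice.
#' @param bit_depth quantisation bit depth.
#' @param noise logical; `FALSE` disables shot and read noise (noiseless
#'   limit).
#' @param seed default RNG seed for generation.
#' @return An object of class `tissue_spec`.
#' @export
tissue_spec <- function(frame_width_px = 1024L, frame_height_px = 1024L,
                        n_slices = 5L, pixel_size_nm = 160, z_step_um = 2.5,
                        layer_thicknesses_um = c(basal = 12,
                                                 spinous_granular = 45,
                                                 transitional = 12,
                                                 cornified = 15),
                        undulation_amplitude_um = 6,
                        undulation_wavelength_um = 60,
                        nucleus_radius_um = 2.5, membrane_width_px = 2L,
                        intensity_profiles = default_intensity_profiles(),
                        photon_gain = 0.5, read_noise_sd = 2,
                        n_frames_averaged = 4L, bit_depth = 8L,
                        noise = TRUE, seed = 1L) {
  spec <- structure(list(
    frame_width_px = as.integer(frame_width_px),
    frame_height_px = as.integer(frame_height_px),
    n_slices = as.integer(n_slices),
    pixel_size_nm = pixel_size_nm, z_step_um = z_step_um,
    layer_thicknesses_um = layer_thicknesses_um,
    undulation_amplitude_um = undulation_amplitude_um,
    undulation_wavelength_um = undulation_wavelength_um,
    nucleus_radius_um = nucleus_radius_um,
    membrane_width_px = as.integer(membrane_width_px),
    intensity_profiles = intensity_profiles,
    photon_gain = photon_gain, read_noise_sd = read_noise_sd,
    n_frames_averaged = as.integer(n_frames_averaged),
    bit_depth = as.integer(bit_depth), noise = isTRUE(noise),
    seed = as.integer(seed)), class = "tissue_spec")
  validate_tissue_spec(spec)
}

validate_tissue_spec <- function(spec) {
  th <- spec$layer_thicknesses_um
  need <- c("basal", "spinous_granular", "transitional", "cornified")
  if (!all(need %in% names(th)))
    abort_validation("layer_thicknesses_um needs entries: ",
                     paste(need, collapse = ", "))
  if (any(th <= 0)) abort_validation("all layer thicknesses must be positive")
  if (spec$undulation_amplitude_um < 0)
    abort_validation("undulation amplitude must be nonnegative")
  if (spec$undulation_amplitude_um >= th[["basal"]])
    abort_validation(sprintf(
      "undulation amplitude %.1f um >= basal thickness %.1f um would force boundaries to cross",
      spec$undulation_amplitude_um, th[["basal"]]))
  if (spec$undulation_wavelength_um <= 0)
    abort_validation("undulation wavelength must be positive")
  if (spec$pixel_size_nm <= 0 || spec$z_step_um <= 0)
    abort_validation("pixel_size_nm and z_step_um must be positive")
  if (spec$nucleus_radius_um < 0)
    abort_validation("nucleus_radius_um must be nonnegative")
  if (spec$membrane_width_px < 1)
    abort_validation("membrane_width_px must be a positive integer")
  if (spec$photon_gain <= 0) abort_validation("photon_gain must be positive")
  if (spec$read_noise_sd < 0) abort_validation("read_noise_sd must be nonnegative")
  if (spec$n_frames_averaged < 1)
    abort_validation("n_frames_averaged must be >= 1")
  need_c <- compartment_levels
  if (!all(need_c %in% names(spec$intensity_profiles)))
    abort_validation("intensity_profiles needs a function per compartment: ",
                     paste(need_c, collapse = ", "))
  probe <- c(0, 1.5, 3)
  for (cn in need_c) {
    v <- spec$intensity_profiles[[cn]](probe)
    if (length(v) != length(probe) || any(!is.finite(v)) || any(v < 0))
      abort_validation("intensity profile for '", cn,
                       "' must return finite nonnegative values on u in [0, 3]")
  }
  spec
}

#' @export
print.tissue_spec <- function(x, ...) {
  th <- x$layer_thicknesses_um
  cat(sprintf("Synthetic tissue spec: %d x %d px, %d slice(s), %.0f nm/px, %d-bit\n",
              x$frame_height_px, x$frame_width_px, x$n_slices,
              x$pixel_size_nm, x$bit_depth))
  cat(sprintf("  layers (um): basal %.1f, spinous/granular %.1f, transitional %.1f, cornified %.1f\n",
              th[["basal"]], th[["spinous_granular"]], th[["transitional"]],
              th[["cornified"]]))
  cat(sprintf("  undulation %.1f um @ %.0f um; noise %s (gain %.2f, read sd %.1f, %dx averaging)\n",
              x$undulation_amplitude_um, x$undulation_wavelength_um,
              if (x$noise) "on" else "off", x$photon_gain, x$read_noise_sd,
              x$n_frames_averaged))
  invisible(x)
}

#' Rescale the epidermal layer thicknesses of a spec
#'
#' @param spec a [tissue_spec()].
#' @param factor positive multiplier applied to every layer thickness.
#' @return the modified spec.
#' @export
scale_thicknesses <- function(spec, factor) {
  stopifnot(factor > 0)
  spec$layer_thicknesses_um <- spec$layer_thicknesses_um * factor
  validate_tissue_spec(spec)
}

#' Patient-variation presets
#'
#' Three replicate tissue specs sharing every parameter but the layer
#' thicknesses, which are scaled by the given multipliers to mimic
#' pronounced thickness differences between skin samples (one very thick,
#' one very thin).
#'
#' @param spec base [tissue_spec()].
#' @param multipliers named thickness multipliers, one per synthetic
#'   patient.
#' @return named list of [tissue_spec()] objects.
#' @export
patient_presets <- function(spec = tissue_spec(),
                            multipliers = c(Pat1 = 1.0, Pat2 = 1.6, Pat3 = 0.6)) {
  out <- lapply(multipliers, function(f) scale_thicknesses(spec, f))
  names(out) <- names(multipliers)
  out
}

um_to_px <- function(spec) 1000 / spec$pixel_size_nm

#' Generate layer boundaries for a synthetic tissue
#'
#' Lays down the four tissue-layer boundary polylines across the full
#' frame width. The dermal-basal junction undulates as a seeded sinusoid
#' plus smooth harmonic noise of the requested amplitude and wavelength;
#' the more superficial boundaries follow the same undulation progressively
#' damped (factors 1, 0.5, 0.25, 0.1), so the surface is flatter than the
#' dermal junction. Boundaries are guaranteed non-crossing; amplitude /
#' thickness combinations that would force a crossing raise an error.
#' Deterministic for a fixed seed.
#'
#' @param spec a [tissue_spec()].
#' @param seed RNG seed (defaults to the spec's).
#' @return a validated [layer_boundaries()] object.
#' @export
generate_boundaries <- function(spec, seed = spec$seed) {
  spec <- validate_tissue_spec(spec)
  ppu <- um_to_px(spec)
  th <- spec$layer_thicknesses_um
  w <- spec$frame_width_px; h <- spec$frame_height_px
  a_px <- spec$undulation_amplitude_um * ppu
  epi_px <- (th[["basal"]] + th[["spinous_granular"]] + th[["transitional"]]) * ppu
  corn_px <- th[["cornified"]] * ppu
  dermis_px <- max(0.08 * h, 1.5 * a_px + 2)
  m0 <- h - 1 - dermis_px
  m <- c(m0, m0 - th[["basal"]] * ppu,
         m0 - (th[["basal"]] + th[["spinous_granular"]]) * ppu,
         m0 - epi_px)
  if (m[4] - corn_px - 0.2 * a_px - 1 < 0)
    abort_validation(sprintf(
      "tissue does not fit the frame: epidermis+cornified span %.0f px but the frame has %d rows",
      epi_px + corn_px + dermis_px, h))
  xs <- 0:(w - 1)
  wl_px <- spec$undulation_wavelength_um * ppu
  und <- if (a_px > 0) {
    with_seed(seed, {
      phase <- runif(1, 0, 2 * pi)
      base <- sin(2 * pi * xs / wl_px + phase)
      noise <- 0
      for (j in 1:3)
        noise <- noise + runif(1, 0, 0.1) *
          sin(2 * pi * runif(1, 1.5, 4) * xs / wl_px + runif(1, 0, 2 * pi))
      a_px * (base + noise)
    })
  } else rep(0, w)
  damp <- c(1, 0.5, 0.25, 0.1)
  polys <- lapply(1:4, function(k) data.frame(x = xs, y = m[k] + damp[k] * und))
  b <- layer_boundaries(polys, c(h, w))
  validate_boundaries(b)
}

# smallest per-column gap between consecutive boundaries, used to size cells
layer_thickness_px <- function(spec, layer) {
  spec$layer_thicknesses_um[[layer]] * um_to_px(spec)
}

#' Render compartments and ground-truth depth for a synthetic tissue
#'
#' Tiles each quantified layer with cells via a seeded Voronoi-like
#' tessellation (jittered seed grid, nearest-seed assignment): roughly
#' isotropic cells in the basal and spinous/granular layers and flattened
#' cells (aspect ratio >= 3:1) in the transitional layer, mimicking
#' keratinocyte flattening. Each cell gets a plasma-membrane band of the
#' configured width, a circular (or flattened) nucleus around its seed and
#' cytoplasm elsewhere. The cornified layer is rendered anuclear, the
#' dermis and exterior as uniform compartments. The ground-truth normalised
#' depth of every epidermal pixel is computed with the same fractional
#' Euclidean-distance formula as the production transform, applied to the
#' analytic boundary polylines.
#'
#' @param boundaries a validated [layer_boundaries()] from
#'   [generate_boundaries()].
#' @param spec the [tissue_spec()] used to generate them.
#' @param seed RNG seed for the tessellation.
#' @return An object of class `ground_truth` with elements `compartments`
#'   (integer matrix, levels in `attr(, "levels")`), `cell_labels`
#'   (integer matrix, 0 outside cells), `true_depth` (numeric matrix, `NA`
#'   outside the quantified epidermis), `boundaries` and
#'   `intensity_profiles`.
#' @export
render_tissue <- function(boundaries, spec, seed = spec$seed) {
  spec <- validate_tissue_spec(spec)
  b <- validate_boundaries(boundaries)
  h <- spec$frame_height_px; w <- spec$frame_width_px
  ppu <- um_to_px(spec)
  d <- attr(b, "depths")
  # per-pixel layer codes: 1 dermis, 2 basal, 3 sg, 4 trans, 5 corn/ext
  Y <- matrix(0:(h - 1), h, w)
  D0 <- matrix(d[1, ], h, w, byrow = TRUE)
  D1 <- matrix(d[2, ], h, w, byrow = TRUE)
  D2 <- matrix(d[3, ], h, w, byrow = TRUE)
  D3 <- matrix(d[4, ], h, w, byrow = TRUE)
  code <- matrix(5L, h, w)
  code[Y >= D3] <- 4L
  code[Y > D2] <- 3L
  code[Y > D1] <- 2L
  code[Y > D0] <- 1L

  # ground-truth normalised depth
  true_depth <- matrix(NA_real_, h, w)
  for (k in 1:3) {
    i <- which(code == k + 1L)
    if (!length(i)) next
    y0 <- (i - 1L) %% h
    x0 <- (i - 1L) %/% h
    true_depth[i] <- (k - 1) +
      fractional_position(x0, y0, b$boundaries[[k]], b$boundaries[[k + 1L]])
  }

  # cell tessellation of the three quantified layers
  cells <- matrix(0L, h, w)
  nucleus <- matrix(FALSE, h, w)
  layer_geom <- list(
    list(code = 2L, target_h = layer_thickness_px(spec, "basal"), aspect = 1),
    list(code = 3L, target_h = 14 * ppu, aspect = 1),
    list(code = 4L, target_h = 4 * ppu, aspect = 3.2))
  next_id <- 1L
  r_px <- spec$nucleus_radius_um * ppu
  with_seed(seed, {
    for (lg in layer_geom) {
      k <- lg$code - 1L            # boundary index (1-based inner boundary)
      th_px <- mean(d[k, ] - d[k + 1L, ])
      n_rows <- max(1L, round(th_px / lg$target_h))
      ch <- th_px / n_rows
      cw <- lg$aspect * ch
      xc <- seq(cw / 2, w - 1, by = cw)
      seeds <- do.call(rbind, lapply(seq_len(n_rows), function(i) {
        sx <- pmin(pmax(xc + runif(length(xc), -0.3 * cw, 0.3 * cw), 0), w - 1)
        frac <- (i - 0.5) / n_rows
        din <- approx(0:(w - 1), d[k, ], xout = sx)$y
        dout <- approx(0:(w - 1), d[k + 1L, ], xout = sx)$y
        sy <- din - frac * (din - dout) + runif(length(sx), -0.2 * ch, 0.2 * ch)
        cbind(sx, sy)
      }))
      seeds <- seeds[order(seeds[, 1]), , drop = FALSE]
      i <- which(code == lg$code)
      if (!length(i)) next
      y0 <- (i - 1L) %% h
      x0 <- (i - 1L) %/% h
      yscale <- cw / ch
      ns <- nearest_seed_cpp(as.numeric(x0), as.numeric(y0),
                             seeds[, 1], seeds[, 2], yscale)
      cells[i] <- next_id - 1L + ns
      if (r_px > 0) {
        # elliptical nucleus: semi-axis r_px along x, r_px/yscale along y
        # (flattened together with the cell in the transitional layer)
        dx <- x0 - seeds[ns, 1]
        dy <- yscale * (y0 - seeds[ns, 2])
        nucleus[i] <- (dx * dx + dy * dy) <= r_px^2
      }
      next_id <- next_id + nrow(seeds)
    }
  })

  # membrane: pixels adjacent to a different cell id (or to a non-cell
  # pixel), dilated to the configured width
  memb <- matrix(FALSE, h, w)
  pad <- function(mm, dr, dc) {
    out <- matrix(0L, h, w)
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    out[rs, cs] <- mm[rs - dr, cs - dc]
    out
  }
  for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
    memb <- memb | (cells != pad(cells, sh[1], sh[2]))
  memb <- memb & cells > 0L
  extra <- ceiling((spec$membrane_width_px - 2L) / 2)
  if (extra > 0) for (e in seq_len(extra)) {
    grown <- memb
    for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
      grown <- grown | pad(memb, sh[1], sh[2]) > 0
    memb <- grown & cells > 0L
  }

  comp <- matrix(match("cytoplasm", compartment_levels), h, w)
  comp[nucleus] <- match("nucleus", compartment_levels)
  comp[memb] <- match("membrane", compartment_levels)
  comp[code == 1L] <- match("dermis", compartment_levels)
  corn_px <- layer_thickness_px(spec, "cornified")
  ext <- code == 5L & Y < (D3 - corn_px)
  comp[code == 5L] <- match("cornified", compartment_levels)
  comp[ext] <- match("exterior", compartment_levels)
  attr(comp, "levels") <- compartment_levels

  structure(list(compartments = comp, cell_labels = cells,
                 true_depth = true_depth, boundaries = b,
                 intensity_profiles = spec$intensity_profiles),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  d <- dim(x$compartments)
  tab <- table(factor(compartment_levels[x$compartments],
                      levels = compartment_levels))
  cat(sprintf("Synthetic ground truth: %d x %d px, %d cells\n",
              d[1], d[2], max(x$cell_labels)))
  cat("  compartment pixels:",
      paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Noiseless intensity image implied by a ground truth
#'
#' Evaluates the imposed per-compartment intensity function at each
#' pixel's true normalised depth (constants outside the epidermis).
#'
#' @param truth a `ground_truth` from [render_tissue()].
#' @return numeric matrix of noiseless intensities.
#' @export
clean_image <- function(truth) {
  comp <- truth$compartments
  out <- matrix(0, nrow(comp), ncol(comp))
  for (ci in seq_along(compartment_levels)) {
    i <- which(comp == ci)
    if (!length(i)) next
    out[i] <- truth$intensity_profiles[[compartment_levels[ci]]](truth$true_depth[i])
  }
  out
}

#' Affine rescale and quantisation of an averaged image
#'
#' Maps the 0.1-99.9 intensity percentiles of the image onto the
#' quantisation range (emulating gain/offset adjusted to use the full
#' dynamic range while minimising underflow and saturation), then clamps
#' and rounds to the bit depth. Degenerate (constant) images are rounded
#' and clamped unchanged.
#'
#' @param img numeric matrix or array.
#' @param bit_depth integer bit depth.
#' @return quantised image, same shape, values in \[0, 2^bit_depth - 1\].
#' @export
quantise_image <- function(img, bit_depth = 8L) {
  top <- 2^bit_depth - 1
  q <- quantile(img, c(0.001, 0.999), names = FALSE)
  out <- if (diff(q) > sqrt(.Machine$double.eps)) {
    (img - q[1]) / (q[2] - q[1]) * top
  } else img
  out <- round(out)
  out[out < 0] <- 0
  out[out > top] <- top
  out
}

#' Apply the confocal noise model to a noiseless image
#'
#' Simulates `n_frames_averaged` independent frames, each with Poisson shot
#' noise (variance `intensity / photon_gain`) and additive zero-mean
#' Gaussian read noise, averages them, and by default rescales and
#' quantises the average with [quantise_image()]. Deterministic for a
#' fixed seed. With `spec$noise = FALSE` the input passes through the
#' averaging unchanged (noiseless limit).
#'
#' @param clean nonnegative numeric matrix (noiseless intensities).
#' @param spec a [tissue_spec()] supplying the noise parameters.
#' @param seed RNG seed.
#' @param quantise if `FALSE`, return the averaged frame before affine
#'   rescaling and quantisation (useful for noise diagnostics).
#' @return numeric matrix, quantised to `spec$bit_depth` unless
#'   `quantise = FALSE`.
#' @export
apply_noise <- function(clean, spec, seed = spec$seed, quantise = TRUE) {
  if (any(!is.finite(clean)) || any(clean < 0))
    abort_validation("clean image must be finite and nonnegative")
  g <- spec$photon_gain
  n <- spec$n_frames_averaged
  avg <- if (!spec$noise || !is.finite(g)) {
    clean
  } else {
    with_seed(seed, {
      acc <- 0
      len <- length(clean)
      for (f in seq_len(n))
        acc <- acc + rpois(len, clean * g) / g +
          rnorm(len, 0, spec$read_noise_sd)
      m <- acc / n
      dim(m) <- dim(clean)
      m
    })
  }
  if (quantise) quantise_image(avg, spec$bit_depth) else avg
}

#' Generate a full synthetic stack with matching ground truth
#'
#' Composes [generate_boundaries()], [render_tissue()] and [apply_noise()]:
#' the imposed intensity at each pixel is the compartment's intensity
#' function evaluated at the pixel's true normalised depth; each z-slice is
#' an independent noise realisation of the same clean image. Optionally
#' writes the stack (multipage uncompressed TIFF + settings text file),
#' boundary polylines and truth rasters to a directory.
#'
#' @param spec a [tissue_spec()].
#' @param seed RNG seed; boundary generation, tessellation and each slice's
#'   noise use deterministic offsets of it.
#' @param dir optional output directory (created if needed).
#' @return list with elements `stack` ([image_stack()]), `truth`
#'   (`ground_truth`) and `boundaries`.
#' @export
generate_stack <- function(spec, seed = spec$seed, dir = NULL) {
  spec <- validate_tissue_spec(spec)
  b <- generate_boundaries(spec, seed)
  truth <- render_tissue(b, spec, seed + 1L)
  clean <- clean_image(truth)
  vox <- array(0, c(spec$n_slices, spec$frame_height_px, spec$frame_width_px))
  for (s in seq_len(spec$n_slices))
    vox[s, , ] <- apply_noise(clean, spec, seed + 10L + s)
  stack <- image_stack(vox, pixel_size_nm = spec$pixel_size_nm,
                       z_step_um = spec$z_step_um,
                       bit_depth = spec$bit_depth,
                       channel_name = "synthetic")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_stack(stack, file.path(dir, "stack.tif"))
    meta <- acquisition_metadata(
      frame_averaging = spec$n_frames_averaged,
      pixel_size_nm = spec$pixel_size_nm,
      z_interval_um = (spec$n_slices - 1L) * spec$z_step_um)
    write_settings(meta, file.path(dir, "settings.txt"))
    write_boundaries(b, file.path(dir, "boundaries.tsv"))
    write_mask(truth$compartments - 1L, file.path(dir, "truth_compartments.tif"))
    write_mask(truth$cell_labels, file.path(dir, "truth_cells.tif"))
    # depth scaled to 16-bit: u in [0, 3] -> 1..65535, 0 = outside epidermis
    du <- truth$true_depth
    d16 <- matrix(0L, nrow(du), ncol(du))
    inside <- !is.na(du)
    d16[inside] <- 1L + as.integer(round(du[inside] / 3 * 65534))
    write_mask(d16, file.path(dir, "truth_depth16.tif"))
  }
  list(stack = stack, truth = truth, boundaries = b)
}
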