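# shared fixtures built in code

# scaled-down tissue spec used throughout the tests: same physics as the
# default preset, smaller frame so suites stay fast
small_spec <- function(..., seed = 7L) {
  args <- list(frame_width_px = 192L, frame_height_px = 224L,
               pixel_size_nm = 320,
               layer_thicknesses_um = c(basal = 8, spinous_granular = 24,
                                        transitional = 8, cornified = 8),
               undulation_amplitude_um = 4, undulation_wavelength_um = 40,
               nucleus_radius_um = 2, n_slices = 3L, seed = seed)
  do.call(tissue_spec, utils::modifyList(args, list(...)))
}

# piecewise-linear depth-intensity function: low basal, peak at the top of
# the spinous/granular compartment, declining transitional
g_peak <- function(u) 40 + 140 * pmax(0, 1 - abs(u - 2))

# smooth depth-intensity function (low curvature, so smoothing bias is
# negligible relative to noise at the default span)
g_smooth <- function(u) 100 + 80 * sin(pi * u / 3)

# closed-form normalised distance for straight horizontal boundaries
# rows = c(b0, b1, b2, b3), strictly decreasing
analytic_u <- function(y, rows) {
  ifelse(y > rows[1] | y < rows[4], NA_real_,
  ifelse(y > rows[2], (rows[1] - y) / (rows[1] - rows[2]),
  ifelse(y > rows[3], 1 + (rows[2] - y) / (rows[2] - rows[3]),
                      2 + (rows[3] - y) / (rows[3] - rows[4]))))
}

# brute-force point-to-polyline distance: minimum distance to a dense
# resampling of the polyline (independent of the segment-projection code)
brute_polyline_dist <- function(x, y, poly, step = 0.02) {
  xs <- seq(min(poly$x), max(poly$x), by = step)
  ys <- approx(poly$x, poly$y, xout = xs)$y
  vapply(seq_along(x), function(i)
    sqrt(min((xs - x[i])^2 + (ys - y[i])^2)), 0)
}
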