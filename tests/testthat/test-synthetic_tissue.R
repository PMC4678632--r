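test_that("tissue specs validate their parameters", {
  expect_s3_class(tissue_spec(), "tissue_spec")
  expect_error(small_spec(layer_thicknesses_um = c(basal = -1,
                                                   spinous_granular = 24,
                                                   transitional = 8,
                                                   cornified = 8)),
               "positive")
  expect_error(small_spec(photon_gain = 0), "photon_gain")
  # amplitude >= basal thickness would force crossing boundaries
  expect_error(tissue_spec(undulation_amplitude_um = 15,
                           layer_thicknesses_um = c(basal = 10,
                                                    spinous_granular = 45,
                                                    transitional = 12,
                                                    cornified = 15)),
               "cross")
})

test_that("boundary generation is deterministic, ordered and degenerates to straight lines", {
  sp <- small_spec(seed = 5L)
  b1 <- generate_boundaries(sp, seed = 9L)
  b2 <- generate_boundaries(sp, seed = 9L)
  expect_identical(b1, b2)
  b3 <- generate_boundaries(sp, seed = 10L)
  expect_false(identical(attr(b1, "depths"), attr(b3, "depths")))
  d <- attr(b1, "depths")
  expect_true(all(d[1, ] > d[2, ] & d[2, ] > d[3, ] & d[3, ] > d[4, ]))
  expect_identical(ncol(d), sp$frame_width_px)

  # zero amplitude: four straight horizontal lines at the stated spacings
  b0 <- generate_boundaries(small_spec(undulation_amplitude_um = 0))
  d0 <- attr(b0, "depths")
  expect_true(all(apply(d0, 1, function(r) diff(range(r)) == 0)))
  ppu <- 1000 / 320
  expect_equal(d0[1, 1] - d0[2, 1], 8 * ppu)
  expect_equal(d0[2, 1] - d0[3, 1], 24 * ppu)
  expect_equal(d0[3, 1] - d0[4, 1], 8 * ppu)
})

test_that("rendered tissue has coherent compartments and depth anchors", {
  sp <- small_spec(seed = 19L)
  b <- generate_boundaries(sp)
  truth <- render_tissue(b, sp)
  comp <- truth$compartments
  lev <- attr(comp, "levels")
  expect_setequal(lev[sort(unique(as.integer(comp)))],
                  c("dermis", "nucleus", "cytoplasm", "membrane",
                    "cornified", "exterior"))
  # depth defined exactly on the quantified epidermis
  epidermal <- comp %in% match(c("nucleus", "cytoplasm", "membrane"), lev)
  expect_true(all(!is.na(truth$true_depth[epidermal])))
  expect_true(all(is.na(truth$true_depth[!epidermal])))
  expect_true(all(truth$true_depth[epidermal] >= 0 &
                    truth$true_depth[epidermal] <= 3))
  # cells tile the epidermis
  expect_identical(as.vector(truth$cell_labels > 0), as.vector(epidermal))

  # pixels on the dermal-basal junction anchor at depth 0
  d <- attr(b, "depths")
  on_b0 <- which(abs(outer(0:(sp$frame_height_px - 1), d[1, ], `-`)) < 1e-9,
                 arr.ind = TRUE)
  if (nrow(on_b0)) {
    expect_lt(max(truth$true_depth[on_b0]), 1e-9)
  }

  # transitional cells are flattened: pooled aspect ratio >= 3
  trans <- truth$cell_labels
  code4 <- which(comp %in% match(c("nucleus", "cytoplasm", "membrane"), lev) &
                   row(comp) - 1 < matrix(d[3, ], nrow(comp), ncol(comp),
                                          byrow = TRUE))
  ids <- unique(trans[code4])
  widths <- heights <- numeric(0)
  for (id in ids) {
    px <- which(trans == id, arr.ind = TRUE)
    if (nrow(px) < 20) next
    widths <- c(widths, diff(range(px[, 2])))
    heights <- c(heights, diff(range(px[, 1])))
  }
  expect_gt(median(widths / pmax(heights, 1)), 3)
})

test_that("nucleus radius zero suppresses nuclei", {
  sp <- small_spec(nucleus_radius_um = 0, seed = 23L)
  truth <- render_tissue(generate_boundaries(sp), sp)
  lev <- attr(truth$compartments, "levels")
  expect_identical(sum(truth$compartments == match("nucleus", lev)), 0L)
})

test_that("closed-form depth holds for straight horizontal boundaries", {
  b <- straight_boundaries(c(300, 240, 140, 110), frame_shape = c(400, 64))
  sp <- small_spec(frame_width_px = 64L, frame_height_px = 400L,
                   undulation_amplitude_um = 0, seed = 3L)
  truth <- render_tissue(b, sp)
  expect_equal(truth$true_depth[201, 11], 1.4)        # row 200, 0-based
  expect_equal(truth$true_depth[301, 11], 0)          # on b0
  expect_equal(truth$true_depth[111, 11], 3)          # on b3
})

test_that("the noise model averages, clamps and stays deterministic", {
  sp <- small_spec(seed = 1L)
  expect_error(apply_noise(matrix(-1, 4, 4), sp), "nonnegative")

  # noiseless limit: constant input -> constant quantised output
  spq <- small_spec(noise = FALSE)
  out <- apply_noise(matrix(42.4, 8, 8), spq)
  expect_true(all(out == out[1, 1]))

  # determinism and quantisation bounds
  img <- matrix(runif(64 * 64, 0, 200), 64, 64)
  n1 <- apply_noise(img, sp, seed = 4L)
  n2 <- apply_noise(img, sp, seed = 4L)
  expect_identical(n1, n2)
  expect_true(all(n1 >= 0 & n1 <= 255))
  expect_true(all(n1 == round(n1)))

  # the affine rescale uses the full dynamic range
  expect_gt(max(n1), 250)
  expect_lt(min(n1), 5)
})

test_that("frame averaging divides the single-frame variance by n", {
  sp4 <- small_spec(seed = 1L)                 # 4x averaging (default)
  sp1 <- small_spec(n_frames_averaged = 1L)
  img <- matrix(100, 2, 2)
  reps <- 4000
  v1 <- vapply(seq_len(reps), function(i)
    apply_noise(img, sp1, seed = i, quantise = FALSE)[1, 1], 0)
  v4 <- vapply(seq_len(reps), function(i)
    apply_noise(img, sp4, seed = 200000L + i, quantise = FALSE)[1, 1], 0)
  ratio <- var(v1) / var(v4)
  expect_gt(ratio, 4 * 0.92)
  expect_lt(ratio, 4 * 1.08)
  # and the single-frame variance matches shot + read theory
  theory <- 100 / sp1$photon_gain + sp1$read_noise_sd^2
  expect_lt(abs(var(v1) / theory - 1), 0.08)
})

test_that("generated stacks compose boundaries, truth and noise coherently", {
  # flat per-compartment intensities, noise off -> piecewise-constant stack
  flat <- list(dermis = function(u) rep_len(10, length(u)),
               nucleus = function(u) rep_len(50, length(u)),
               cytoplasm = function(u) rep_len(100, length(u)),
               membrane = function(u) rep_len(150, length(u)),
               cornified = function(u) rep_len(200, length(u)),
               exterior = function(u) rep_len(0, length(u)))
  sp <- small_spec(intensity_profiles = flat, noise = FALSE, seed = 8L)
  gs <- generate_stack(sp, seed = 8L)
  sl <- gs$stack$voxels[1, , ]
  for (ci in seq_along(epidepth:::compartment_levels)) {
    px <- gs$truth$compartments == ci
    if (!any(px)) next
    expect_identical(length(unique(sl[px])), 1L)
  }

  # identical seeds give identical stacks; different seeds differ
  gs2 <- generate_stack(sp, seed = 8L)
  expect_identical(gs2$stack$voxels, gs$stack$voxels)

  # stack files are written alongside truth and settings
  dir <- file.path(tempdir(), "synth_out")
  unlink(dir, recursive = TRUE)
  gs3 <- generate_stack(small_spec(seed = 9L, n_slices = 2L), seed = 9L,
                        dir = dir)
  expect_true(all(file.exists(file.path(dir,
    c("stack.tif", "settings.txt", "boundaries.tsv",
      "truth_compartments.tif", "truth_cells.tif", "truth_depth16.tif")))))
  rt <- read_stack(file.path(dir, "stack.tif"))
  expect_identical(rt$voxels, gs3$stack$voxels)
  meta <- parse_settings(file.path(dir, "settings.txt"))
  expect_identical(meta$frame_averaging, 4L)
})

test_that("patient presets scale thicknesses as one thick and one thin replicate", {
  ps <- patient_presets(small_spec())
  expect_named(ps, c("Pat1", "Pat2", "Pat3"))
  th <- vapply(ps, function(s) sum(s$layer_thicknesses_um[1:3]), 0)
  expect_equal(unname(th / th[["Pat1"]]), c(1.0, 1.6, 0.6))
})
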