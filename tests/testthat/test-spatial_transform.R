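test_that("fractional position anchors boundaries and interpolates linearly", {
  inner <- data.frame(x = c(0, 63), y = c(240, 240))
  outer <- data.frame(x = c(0, 63), y = c(140, 140))
  expect_equal(fractional_position(10, 240, inner, outer), 0)
  expect_equal(fractional_position(10, 140, inner, outer), 1)
  expect_equal(fractional_position(10, 190, inner, outer), 0.5)
  expect_equal(fractional_position(10, 200, inner, outer), 0.4)
  # degenerate geometry: crossing polylines meeting at the point
  meet <- data.frame(x = c(0, 63), y = c(10, 10))
  expect_error(fractional_position(5, 10, meet, meet), "degenerate")
})

test_that("fractional position is invariant under rigid motions", {
  set.seed(9)
  xs <- 0:63
  inner <- data.frame(x = xs, y = 220 + 8 * sin(xs / 7))
  outer <- data.frame(x = xs, y = 150 + 4 * sin(xs / 9 + 1))
  px <- runif(50, 5, 58); py <- runif(50, 165, 210)
  f0 <- fractional_position(px, py, inner, outer)
  for (theta in c(0.3, -1.1)) {
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    rot <- function(x, y) cbind(x, y) %*% R
    tr <- c(12.5, -40)
    pr <- sweep(rot(px, py), 2, tr, `+`)
    ir <- sweep(rot(inner$x, inner$y), 2, tr, `+`)
    or_ <- sweep(rot(outer$x, outer$y), 2, tr, `+`)
    f1 <- fractional_position(pr[, 1], pr[, 2],
                              data.frame(x = ir[, 1], y = ir[, 2]),
                              data.frame(x = or_[, 1], y = or_[, 2]))
    expect_lt(max(abs(f1 - f0)), 1e-6)
  }
})

test_that("normalised distance matches the closed form for straight boundaries", {
  rows <- c(300, 240, 140, 110)
  b <- straight_boundaries(rows, frame_shape = c(400, 64))
  expect_equal(normalised_distance(10, 200, b)$u, 1.4)
  expect_equal(normalised_distance(10, 110, b)$u, 3)    # top anchor
  expect_equal(normalised_distance(10, 300, b)$u, 0)    # bottom anchor
  nd <- normalised_distance(10, 350, b)
  expect_true(is.na(nd$u))
  expect_identical(nd$reason, "dermis")

  # randomised closed-form agreement
  set.seed(13)
  for (case in 1:20) {
    r <- sort(runif(4, 10, 390), decreasing = TRUE)
    bb <- straight_boundaries(r, frame_shape = c(400, 64))
    y <- runif(50, r[4], r[1])
    x <- runif(50, 0, 63)
    u <- normalised_distance(x, y, bb)$u
    expect_lt(max(abs(u - analytic_u(y, r))), 1e-9)
  }
})

test_that("normalised distance is translation-invariant with the boundaries", {
  sp <- small_spec(seed = 21L)
  b <- generate_boundaries(sp)
  set.seed(1)
  x <- runif(100, 0, sp$frame_width_px - 1)
  y <- runif(100, 60, 170)
  u0 <- normalised_distance(x, y, b)$u
  dy <- 15.5
  shifted <- layer_boundaries(lapply(b$boundaries, function(p)
    data.frame(x = p$x, y = p$y + dy)), b$frame_shape)
  u1 <- normalised_distance(x, y + dy, shifted)$u
  keep <- !is.na(u0) & !is.na(u1)
  expect_gt(sum(keep), 50)
  expect_lt(max(abs(u0[keep] - u1[keep])), 1e-6)
})

test_that("u is monotone along transects and consistent with the layer label", {
  sp <- small_spec(seed = 5L)
  gs <- generate_stack(sp, seed = 5L)
  tbl <- quantified_points(transform_stack(gs$stack, gs$boundaries))
  expect_true(all(tbl$u >= 0 & tbl$u <= 3))
  expect_identical(as.character(tbl$layer),
                   c("BASAL", "SPINOUS_GRANULAR", "TRANSITIONAL")[
                     pmin(floor(tbl$u), 2) + 1])
  # vertical transects from deep to superficial: u nondecreasing
  for (col in c(10L, 90L, 180L)) {
    tr <- tbl[tbl$x_px == col & tbl$z_index == tbl$z_index[1], ]
    tr <- tr[order(-tr$y_px), ]                   # deep to superficial
    expect_true(all(diff(tr$u) >= 0))
  }
})

test_that("transform recovers the generator's ground-truth depth", {
  # straight boundaries: exact equality against the analytic truth
  sp0 <- small_spec(undulation_amplitude_um = 0, seed = 31L)
  gs0 <- generate_stack(sp0, seed = 31L)
  tbl0 <- quantified_points(transform_stack(gs0$stack, gs0$boundaries))
  d <- attr(validate_boundaries(gs0$boundaries), "depths")
  rows <- d[, 1]
  expect_lt(max(abs(tbl0$u - analytic_u(tbl0$y_px, rows))), 1e-9)

  # undulating boundaries: agreement with the rendered truth raster
  sp <- small_spec(seed = 32L)
  gs <- generate_stack(sp, seed = 32L)
  tbl <- quantified_points(transform_stack(gs$stack, gs$boundaries))
  tru <- gs$truth$true_depth[cbind(tbl$y_px + 1L, tbl$x_px + 1L)]
  expect_lt(max(abs(tbl$u - tru)), 0.02)
})

test_that("sampling masks drive the transform and exclusions are reported", {
  sp <- small_spec(seed = 41L)
  gs <- generate_stack(sp, seed = 41L)
  h <- sp$frame_height_px; w <- sp$frame_width_px
  # mask selecting only dermis pixels -> no quantified output
  dermis <- matrix(0L, h, w)
  dermis[gs$truth$compartments == 1L] <- 1L
  out <- transform_stack(gs$stack, gs$boundaries, mask = dermis)
  expect_identical(nrow(quantified_points(out)), 0L)
  expect_true(all(out$reason == "dermis"))

  empty <- matrix(0L, h, w)
  expect_warning(res <- transform_stack(gs$stack, gs$boundaries, mask = empty),
                 "empty sampling mask")
  expect_identical(nrow(res), 0L)

  # deterministic row-major order within a slice
  mask <- matrix(0L, h, w); mask[101:110, 21:40] <- 1L
  t1 <- transform_stack(gs$stack, gs$boundaries, mask = mask)
  t2 <- transform_stack(gs$stack, gs$boundaries, mask = mask)
  expect_identical(t1, t2)
  expect_true(all(diff(order(t1$y_px * w + t1$x_px)) == 1))

  # z policies: per-slice emits one record per pixel per slice, z-mean
  # averages intensities over slices at unchanged u
  ps <- transform_stack(gs$stack, gs$boundaries, mask = mask,
                        cfg = transform_config("per_slice"))
  expect_identical(nrow(ps), nrow(t1) * dim(gs$stack)[1])
  expect_setequal(unique(ps$z_index), 0:(dim(gs$stack)[1] - 1))
  zm <- transform_stack(gs$stack, gs$boundaries, mask = mask,
                        cfg = transform_config("z_mean"))
  expect_equal(zm$u, t1$u)
  byz <- split(ps$intensity, ps$z_index)
  expect_equal(zm$intensity, Reduce(`+`, byz) / length(byz))
})

test_that("scaling all layer thicknesses leaves the u-distribution unchanged", {
  sp1 <- small_spec(frame_width_px = 512L, frame_height_px = 448L,
                    seed = 51L, n_slices = 1L)
  sp2 <- scale_thicknesses(sp1, 2)
  g1 <- generate_stack(sp1, seed = 51L)
  g2 <- generate_stack(sp2, seed = 51L)
  u1 <- quantified_points(transform_stack(g1$stack, g1$boundaries))$u
  u2 <- quantified_points(transform_stack(g2$stack, g2$boundaries))$u
  ks <- suppressWarnings(stats::ks.test(u1, u2)$statistic)
  expect_lt(ks, 0.02)
})
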