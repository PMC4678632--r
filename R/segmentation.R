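#' Tissue-layer boundary set
#'
#' Bundles the four operator-supplied polylines that partition an epidermal
#' cross-section into tissue layers, ordered from deep to superficial:
#' `b0` the dermal-basal junction, `b1` the basal to spinous/granular
#' interface, `b2` the spinous/granular to transitional interface and `b3`
#' the surface of the transitional layer (base of the cornified layer).
#' Coordinates are 0-based pixels, `x` the column and `y` the row; by
#' convention the row index increases with tissue depth, so `b0` has the
#' largest `y` values.
#'
#' @param boundaries list of four polylines (each a data frame or matrix
#'   with columns `x`, `y`), ordered `b0`, `b1`, `b2`, `b3`.
#' @param frame_shape integer vector `c(rows, columns)` of the image frame
#'   the boundaries refer to.
#' @return An object of class `layer_boundaries`.
#' @seealso [validate_boundaries()], [assign_layer()], [normalised_distance()]
#' @export
layer_boundaries <- function(boundaries, frame_shape) {
  if (length(boundaries) != 4L)
    abort_validation("a layer boundary set needs exactly 4 polylines, got ",
                     length(boundaries))
  boundaries <- lapply(boundaries, function(p) {
    p <- as.data.frame(p)
    if (!all(c("x", "y") %in% names(p)))
      abort_validation("each polyline needs columns 'x' and 'y'")
    if (nrow(p) < 1L) abort_validation("empty polyline")
    p[, c("x", "y")]
  })
  frame_shape <- as.integer(frame_shape)
  if (length(frame_shape) != 2L || any(frame_shape < 1L))
    abort_validation("frame_shape must be two positive integers (rows, columns)")
  structure(list(boundaries = boundaries, frame_shape = frame_shape),
            class = "layer_boundaries")
}

#' @export
print.layer_boundaries <- function(x, ...) {
  cat("Layer boundary set:", x$frame_shape[1], "x", x$frame_shape[2],
      "frame (rows x columns)\n")
  nm <- c("b0 dermal-basal", "b1 basal-spinous/granular",
          "b2 spinous/granular-transitional", "b3 transitional surface")
  for (k in 1:4) {
    yr <- range(x$boundaries[[k]]$y)
    cat(sprintf("  %-34s %4d vertices, depth (row) %.1f .. %.1f\n",
                nm[k], nrow(x$boundaries[[k]]), yr[2], yr[1]))
  }
  if (isTRUE(attr(x, "validated"))) cat("  validated, resampled per column\n")
  invisible(x)
}

#' Validate and per-column resample a boundary set
#'
#' Checks that every polyline spans the full column range of the frame and
#' that, after resampling the depth of each boundary at every integer
#' column, the four boundaries are strictly ordered (deep to superficial)
#' and never cross. On success the returned set carries the per-column
#' resampled polylines; on failure the error lists every violated column.
#'
#' @param b a [layer_boundaries()] object.
#' @return The validated boundary set (resampled, with a depth matrix
#'   attached as attribute `depths`, one row per boundary, one column per
#'   image column).
#' @export
validate_boundaries <- function(b) {
  if (!inherits(b, "layer_boundaries"))
    abort_validation("expected a 'layer_boundaries' object")
  if (isTRUE(attr(b, "validated"))) return(b)
  w <- b$frame_shape[2]
  xs <- 0:(w - 1L)
  depths <- matrix(NA_real_, 4L, w)
  for (k in 1:4) {
    p <- b$boundaries[[k]]
    if (min(p$x) > 0 || max(p$x) < w - 1L)
      abort_validation(sprintf(
        "boundary b%d spans columns %.1f..%.1f but the frame has columns 0..%d",
        k - 1L, min(p$x), max(p$x), w - 1L))
    depths[k, ] <- approx(p$x, p$y, xout = xs, ties = mean)$y
    b$boundaries[[k]] <- data.frame(x = xs, y = depths[k, ])
  }
  bad <- which(!(depths[1, ] > depths[2, ] & depths[2, ] > depths[3, ] &
                   depths[3, ] > depths[4, ]))
  if (length(bad)) {
    shown <- paste(head(bad - 1L, 20L), collapse = ", ")
    more <- if (length(bad) > 20L) sprintf(" (and %d more)", length(bad) - 20L) else ""
    abort_validation(sprintf(
      "boundaries cross or touch at %d column(s): %s%s", length(bad), shown, more))
  }
  attr(b, "depths") <- depths
  attr(b, "validated") <- TRUE
  b
}

# depth (row) of boundary k at real-valued columns x, by linear interpolation
boundary_depth_at <- function(b, k, x) {
  d <- attr(b, "depths")
  w <- ncol(d)
  x <- pmin(pmax(x, 0), w - 1L)
  i0 <- pmin(floor(x), w - 2L)
  f <- x - i0
  d[k, i0 + 1L] * (1 - f) + d[k, i0 + 2L] * f
}

#' Assign image points to tissue layers
#'
#' Points deeper than the dermal-basal junction are `DERMIS`; points
#' superficial to the transitional surface are `CORNIFIED_EXTERIOR`;
#' everything in between gets the enclosing layer. A point lying exactly on
#' a boundary belongs to the layer on its superficial side, with two
#' anchoring exceptions: on `b0` it is `BASAL` and on `b3` it is
#' `TRANSITIONAL` (so the normalised distance at `b3` is exactly 3).
#'
#' @param x,y numeric vectors of 0-based pixel coordinates (column, row).
#' @param b a validated [layer_boundaries()] object.
#' @return factor with levels `DERMIS`, `BASAL`, `SPINOUS_GRANULAR`,
#'   `TRANSITIONAL`, `CORNIFIED_EXTERIOR`.
#' @examples
#' b <- straight_boundaries(c(300, 240, 140, 110), frame_shape = c(400, 64))
#' assign_layer(10, 200, b)   # SPINOUS_GRANULAR
#' @export
assign_layer <- function(x, y, b) {
  b <- validate_boundaries(b)
  d0 <- boundary_depth_at(b, 1L, x)
  d1 <- boundary_depth_at(b, 2L, x)
  d2 <- boundary_depth_at(b, 3L, x)
  d3 <- boundary_depth_at(b, 4L, x)
  code <- ifelse(y > d0, 1L,
          ifelse(y > d1, 2L,
          ifelse(y > d2, 3L,
          ifelse(y >= d3, 4L, 5L))))
  factor(layer_levels[code], levels = layer_levels)
}

#' Straight horizontal boundary set
#'
#' Convenience constructor for a boundary set of four horizontal lines,
#' mainly useful for tests and worked examples where the closed-form
#' normalised distance is known.
#'
#' @param rows numeric vector of four row depths, deep to superficial
#'   (`b0` to `b3`), strictly decreasing.
#' @param frame_shape integer `c(rows, columns)`.
#' @return A validated [layer_boundaries()] object.
#' @export
straight_boundaries <- function(rows, frame_shape) {
  stopifnot(length(rows) == 4L)
  w <- frame_shape[2]
  b <- layer_boundaries(lapply(rows, function(r)
    data.frame(x = c(0, w - 1L), y = c(r, r))), frame_shape)
  validate_boundaries(b)
}

#' Minimum distance from points to a boundary polyline
#'
#' Exact Euclidean point-to-segment distance, minimised over all segments
#' of the polyline. This is the geometric primitive behind the linear
#' interpolation of the normalised-distance transform.
#'
#' @param x,y numeric vectors of point coordinates (0-based pixels).
#' @param polyline a data frame or matrix with columns `x`, `y`, or one of
#'   the polylines of a [layer_boundaries()] object.
#' @return numeric vector of distances in pixels.
#' @examples
#' distance_to_boundary(5, 10, data.frame(x = c(0, 63), y = c(30, 30)))  # 20
#' @export
distance_to_boundary <- function(x, y, polyline) {
  p <- as.data.frame(polyline)
  if (!nrow(p)) abort_validation("empty polyline")
  dist_to_polyline_cpp(as.numeric(x), as.numeric(y),
                       as.numeric(p$x), as.numeric(p$y))
}

#' Per-cell intensity statistics from a labelled mask
#'
#' Given a labelled whole-cell segmentation mask (0 = background, positive
#' integers = cell identifiers) and an image stack, computes one record per
#' cell: centroid, area, mean and median intensity, and the tissue layer of
#' its centroid.
#'
#' @param mask integer matrix, same frame shape as the stack.
#' @param stack an [image_stack()] object or a single-slice numeric matrix.
#' @param b a [layer_boundaries()] object for layer assignment.
#' @param z_policy how to collapse the z-dimension: `"middle_slice"`
#'   (default) uses the central slice, `"z_mean"` averages intensities over
#'   slices, `"per_slice"` emits one record per cell and slice (with a
#'   `z_index` column).
#' @return data frame with columns `cell_id`, `centroid_x`, `centroid_y`,
#'   `area_px`, `mean_intensity`, `median_intensity`, `layer` (and
#'   `z_index` for `"per_slice"`).
#' @export
per_cell_statistics <- function(mask, stack, b,
                                z_policy = c("middle_slice", "per_slice", "z_mean")) {
  z_policy <- match.arg(z_policy)
  vox <- if (inherits(stack, "image_stack")) stack$voxels else stack
  if (is.matrix(vox)) vox <- array(vox, c(1L, dim(vox)))
  if (!identical(dim(mask), dim(vox)[2:3]))
    abort_validation(sprintf(
      "mask frame %d x %d does not match stack frame %d x %d",
      nrow(mask), ncol(mask), dim(vox)[2], dim(vox)[3]))
  b <- validate_boundaries(b)
  ids <- sort(unique(as.integer(mask[mask > 0])))
  if (!length(ids))
    return(data.frame(cell_id = integer(), centroid_x = numeric(),
                      centroid_y = numeric(), area_px = integer(),
                      mean_intensity = numeric(), median_intensity = numeric(),
                      layer = factor(character(), levels = layer_levels)))
  sel <- which(mask > 0)
  lab <- as.integer(mask[sel])
  rows0 <- (sel - 1L) %% nrow(mask)         # 0-based row
  cols0 <- (sel - 1L) %/% nrow(mask)        # 0-based column
  f <- factor(lab, levels = ids)
  area <- as.integer(table(f))
  cx <- tapply(cols0, f, mean)
  cy <- tapply(rows0, f, mean)
  layer <- assign_layer(as.numeric(cx), as.numeric(cy), b)

  one_slice <- function(sl, z = NA_integer_) {
    v <- sl[cbind(rows0 + 1L, cols0 + 1L)]
    out <- data.frame(cell_id = ids,
                      centroid_x = as.numeric(cx), centroid_y = as.numeric(cy),
                      area_px = area,
                      mean_intensity = as.numeric(tapply(v, f, mean)),
                      median_intensity = as.numeric(tapply(v, f, median)),
                      layer = layer, row.names = NULL)
    if (!is.na(z)) out$z_index <- z
    out
  }
  nz <- dim(vox)[1]
  switch(z_policy,
    middle_slice = one_slice(vox[ceiling(nz / 2), , ]),
    z_mean = one_slice(apply(vox, c(2, 3), mean)),
    per_slice = do.call(rbind, lapply(seq_len(nz), function(z)
      one_slice(vox[z, , ], z - 1L))))
}
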