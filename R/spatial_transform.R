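#' Transform configuration
#'
#' Fixed conventions of the normalised-distance transform: the quantified
#' layers map to one unit each (`BASAL` to \[0,1), `SPINOUS_GRANULAR` to
#' \[1,2), `TRANSITIONAL` to \[2,3\]), dermis and cornified/exterior points
#' are excluded from quantification, and a z policy chooses how slices of a
#' stack are sampled.
#'
#' @param z_policy `"middle_slice"` (default), `"per_slice"` or `"z_mean"`.
#' @param rescale_unit if `TRUE`, normalised distances are divided by 3 so
#'   they span \[0,1\] instead of one unit per layer.
#' @return An object of class `transform_config`.
#' @export
transform_config <- function(z_policy = c("middle_slice", "per_slice", "z_mean"),
                             rescale_unit = FALSE) {
  structure(list(z_policy = match.arg(z_policy),
                 rescale_unit = isTRUE(rescale_unit),
                 excluded_labels = c("DERMIS", "CORNIFIED_EXTERIOR")),
            class = "transform_config")
}

#' Fractional position of points between two boundary polylines
#'
#' Linear interpolation of a point's position within a tissue layer:
#' `d_inner / (d_inner + d_outer)`, where `d_inner` is the Euclidean
#' distance to the deeper (inner) boundary and `d_outer` the distance to
#' the more superficial (outer) boundary. The result is 0 on the inner
#' boundary and 1 on the outer one, and is invariant under rigid motions
#' of points and boundaries together and under scaling of the layer
#' thickness.
#'
#' @param x,y numeric point coordinates (0-based pixels).
#' @param inner,outer the bounding polylines (data frames with `x`, `y`),
#'   inner = deeper.
#' @return numeric vector in \[0, 1\].
#' @export
fractional_position <- function(x, y, inner, outer) {
  di <- distance_to_boundary(x, y, inner)
  do <- distance_to_boundary(x, y, outer)
  both0 <- di == 0 & do == 0
  if (any(both0))
    abort_validation("degenerate geometry: point equidistant at 0 from both boundaries")
  di / (di + do)
}

#' Normalised distance of points along the differentiation gradient
#'
#' Maps points to the layer-normalised coordinate `u`: the index of the
#' enclosing quantified layer (0 basal, 1 spinous/granular, 2 transitional)
#' plus the fractional position within that layer. Dermis and
#' cornified/exterior points are excluded from quantification and reported
#' with a reason code rather than silently dropped.
#'
#' @param x,y numeric point coordinates (0-based pixels).
#' @param b a [layer_boundaries()] object.
#' @param cfg a [transform_config()].
#' @return data frame with columns `x_px`, `y_px`, `layer`, `u` (`NA` for
#'   excluded points) and `reason` (`NA` for quantified points).
#' @examples
#' b <- straight_boundaries(c(300, 240, 140, 110), frame_shape = c(400, 64))
#' normalised_distance(10, 200, b)$u   # 1.4
#' @export
normalised_distance <- function(x, y, b, cfg = transform_config()) {
  b <- validate_boundaries(b)
  x <- as.numeric(x); y <- as.numeric(y)
  layer <- assign_layer(x, y, b)
  u <- rep(NA_real_, length(x))
  reason <- rep(NA_character_, length(x))
  reason[layer == "DERMIS"] <- "dermis"
  reason[layer == "CORNIFIED_EXTERIOR"] <- "cornified_or_exterior"
  for (ln in quantified_layers) {
    i <- which(layer == ln)
    if (!length(i)) next
    k <- layer_bases[[ln]]                 # 0, 1, 2
    inner <- b$boundaries[[k + 1L]]        # deeper polyline
    outer <- b$boundaries[[k + 2L]]
    u[i] <- k + fractional_position(x[i], y[i], inner, outer)
  }
  if (cfg$rescale_unit) u <- u / 3
  data.frame(x_px = x, y_px = y, layer = layer, u = u, reason = reason)
}

#' Sample an image stack into normalised-distance records
#'
#' The workhorse of the pipeline: samples pixel intensities from an image
#' stack (optionally restricted to a binary sampling mask), assigns each
#' pixel a tissue layer and its normalised distance `u`, and returns one
#' record per sampled pixel per selected slice in deterministic order
#' (row-major within a slice, slices in z order). Excluded pixels (dermis,
#' cornified/exterior) are retained with a `reason` code and `u = NA`; use
#' [quantified_points()] to keep only quantified records.
#'
#' @param stack an [image_stack()] object (or numeric matrix / 3D array).
#' @param b a [layer_boundaries()] object.
#' @param mask optional binary matrix; non-zero pixels are sampled. `NULL`
#'   samples every pixel.
#' @param cfg a [transform_config()]; its `z_policy` picks the slices.
#' @param target,patient labels carried into the record table.
#' @return data frame with columns `target`, `patient`, `x_px`, `y_px`,
#'   `z_index`, `intensity`, `layer`, `u`, `reason`.
#' @export
transform_stack <- function(stack, b, mask = NULL, cfg = transform_config(),
                            target = "target", patient = "patient") {
  vox <- if (inherits(stack, "image_stack")) stack$voxels else stack
  if (is.matrix(vox)) vox <- array(vox, c(1L, dim(vox)))
  nz <- dim(vox)[1]; nr <- dim(vox)[2]; nc <- dim(vox)[3]
  b <- validate_boundaries(b)
  if (!identical(as.integer(b$frame_shape), as.integer(c(nr, nc))))
    abort_validation("boundary frame_shape does not match stack frame")
  if (!is.null(mask)) {
    if (!identical(dim(mask), c(nr, nc)))
      abort_validation("sampling mask shape does not match stack frame")
    sel <- which(t(mask) != 0)             # row-major order
  } else {
    sel <- seq_len(nr * nc)
  }
  empty <- data.frame(target = character(), patient = character(),
                      x_px = integer(), y_px = integer(), z_index = integer(),
                      intensity = numeric(),
                      layer = factor(character(), levels = layer_levels),
                      u = numeric(), reason = character())
  if (!length(sel)) {
    warning("empty sampling mask: no pixels sampled")
    return(empty)
  }
  # sel indexes the transposed frame: row-major over (row, column)
  y0 <- (sel - 1L) %/% nc                  # 0-based row
  x0 <- (sel - 1L) %% nc                   # 0-based column
  nd <- normalised_distance(x0, y0, b, cfg)

  slices <- switch(cfg$z_policy,
    middle_slice = ceiling(nz / 2),
    per_slice = seq_len(nz),
    z_mean = NA_integer_)
  grab <- function(z) vox[z, , ][cbind(y0 + 1L, x0 + 1L)]
  out <- lapply(slices, function(z) {
    inten <- if (is.na(z)) {
      m <- apply(vox, c(2, 3), mean)
      m[cbind(y0 + 1L, x0 + 1L)]
    } else grab(z)
    data.frame(target = target, patient = patient,
               x_px = as.integer(x0), y_px = as.integer(y0),
               z_index = if (is.na(z)) NA_integer_ else as.integer(z - 1L),
               intensity = as.numeric(inten),
               layer = nd$layer, u = nd$u, reason = nd$reason)
  })
  do.call(rbind, out)
}

#' Keep only quantified sampled records
#'
#' Drops records excluded by tissue segmentation (dermis, cornified layer
#' and exterior), i.e. those with an exclusion reason and no normalised
#' distance.
#'
#' @param tbl a sampled-record data frame from [transform_stack()].
#' @return the quantified subset, row indices reset.
#' @export
quantified_points <- function(tbl) {
  out <- tbl[!is.na(tbl$u), , drop = FALSE]
  rownames(out) <- NULL
  out
}
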