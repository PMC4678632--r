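#' Confocal image stack
#'
#' A single-channel image stack: a 3D voxel array indexed (slice, row,
#' column) with its physical calibration. Integer stacks must fit the
#' declared bit depth.
#'
#' @param voxels numeric matrix (single slice) or 3D array
#'   (slice, row, column).
#' @param pixel_size_nm lateral pixel pitch in nanometres.
#' @param z_step_um spacing between slices in micrometres.
#' @param bit_depth integer bit depth of the detector quantisation (8 or 16
#'   for on-disk stacks).
#' @param channel_name free-text channel / target name.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, pixel_size_nm = 160, z_step_um = 2.5,
                        bit_depth = 8L, channel_name = "unknown") {
  if (is.matrix(voxels)) voxels <- array(voxels, c(1L, dim(voxels)))
  if (length(dim(voxels)) != 3L)
    abort_validation("voxels must be a matrix or a 3D array (slice, row, column)")
  if (pixel_size_nm <= 0 || z_step_um <= 0)
    abort_validation("pixel_size_nm and z_step_um must be positive")
  if (any(voxels < 0) || any(voxels > 2^bit_depth - 1))
    abort_validation(sprintf("voxel values outside [0, %d]", 2^bit_depth - 1))
  structure(list(voxels = voxels, pixel_size_nm = pixel_size_nm,
                 z_step_um = z_step_um, bit_depth = as.integer(bit_depth),
                 channel_name = channel_name),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "Image stack '%s': %d slice(s) of %d x %d px, %d-bit, %.0f nm/px, z-step %.2f um\n",
    x$channel_name, d[1], d[2], d[3], x$bit_depth, x$pixel_size_nm, x$z_step_um))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".txt")

#' Write / read an image stack as uncompressed multipage TIFF
#'
#' One TIFF page per z-slice, grayscale, 8- or 16-bit, no compression.
#' Physical calibration travels in a sidecar settings text file next to the
#' TIFF (same base name, `.txt` extension) in the `KEY<TAB>VALUE` dialect.
#' The round trip `read_stack(write_stack(s))` reproduces the voxel array
#' bit-exactly and the calibration to full stored precision.
#'
#' @param stack an [image_stack()] with integer-valued voxels.
#' @param path TIFF file path.
#' @return `write_stack` returns `path` invisibly; `read_stack` returns an
#'   [image_stack()].
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  if (!stack$bit_depth %in% c(8L, 16L))
    abort_validation("on-disk stacks must be 8- or 16-bit")
  vox <- stack$voxels
  if (any(vox != round(vox)))
    abort_validation("on-disk stacks must hold integer voxel values")
  scale <- 2^stack$bit_depth - 1
  pages <- lapply(seq_len(dim(vox)[1]), function(z) vox[z, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth,
                  compression = "none", reduce = FALSE)
  keys <- c(PIXEL_SIZE_NM = format(stack$pixel_size_nm, digits = 15),
            Z_STEP_UM = format(stack$z_step_um, digits = 15),
            BIT_DEPTH = stack$bit_depth,
            CHANNEL = stack$channel_name)
  writeLines(paste(names(keys), keys, sep = "\t"), sidecar_path(path))
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) abort_validation("no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) stop(
                      "TIFF format error in '", path, "': ",
                      conditionMessage(e), call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  shp <- dim(pages[[1]])
  for (z in seq_along(pages)) {
    if (!is.matrix(pages[[z]]))
      stop("TIFF format error in '", path, "', page ", z,
           ": expected a single-channel grayscale page", call. = FALSE)
    if (!identical(dim(pages[[z]]), shp))
      stop("TIFF format error in '", path, "', page ", z,
           ": page shape differs from page 1", call. = FALSE)
  }
  vox <- array(0, c(length(pages), shp))
  for (z in seq_along(pages)) vox[z, , ] <- pages[[z]]
  meta <- list(PIXEL_SIZE_NM = "160", Z_STEP_UM = "2.5",
               BIT_DEPTH = if (max(vox) > 255) "16" else "8",
               CHANNEL = "unknown")
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    kv <- read_key_values(sc)
    meta[names(kv)] <- kv
  }
  image_stack(vox, pixel_size_nm = as.numeric(meta$PIXEL_SIZE_NM),
              z_step_um = as.numeric(meta$Z_STEP_UM),
              bit_depth = as.integer(meta$BIT_DEPTH),
              channel_name = meta$CHANNEL)
}

read_key_values <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 2L
  if (any(bad))
    stop("settings parse error in '", path, "': line(s) without KEY<TAB>VALUE: ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  stats::setNames(vapply(parts, function(p) paste(p[-1], collapse = "\t"), ""),
                  toupper(vapply(parts, `[[`, "", 1L)))
}

#' Microscope acquisition metadata
#'
#' Settings of a confocal acquisition as recorded in the settings text file
#' accompanying each stack. Defaults reproduce the acquisition geometry the
#' pipeline targets: a 63x oil-immersion objective of numerical aperture
#' 1.32, 160 nm lateral pixel pitch near the diffraction limit, 4x frame
#' averaging and a z-interval of about 10 micrometres.
#'
#' @param objective_magnification,numerical_aperture,gain,offset,frame_averaging,pixel_size_nm,z_interval_um
#'   numeric settings; see field names.
#' @param extra named character vector of unknown keys passed through
#'   unharmed by the parser.
#' @return An object of class `acquisition_metadata`.
#' @export
acquisition_metadata <- function(objective_magnification = 63,
                                 numerical_aperture = 1.32,
                                 gain = 1, offset = 0,
                                 frame_averaging = 4L,
                                 pixel_size_nm = 160,
                                 z_interval_um = 10,
                                 extra = character()) {
  if (!(numerical_aperture > 0 && numerical_aperture <= 2))
    abort_validation("numerical_aperture must lie in (0, 2]")
  if (frame_averaging < 1)
    abort_validation("frame_averaging must be >= 1")
  structure(list(objective_magnification = objective_magnification,
                 numerical_aperture = numerical_aperture,
                 gain = gain, offset = offset,
                 frame_averaging = as.integer(frame_averaging),
                 pixel_size_nm = pixel_size_nm,
                 z_interval_um = z_interval_um,
                 extra = extra),
            class = "acquisition_metadata")
}

#' @export
print.acquisition_metadata <- function(x, ...) {
  cat(sprintf(
    "Acquisition: %gx objective (NA %.2f), %.0f nm/px, %dx frame averaging, z-interval %g um\n",
    x$objective_magnification, x$numerical_aperture, x$pixel_size_nm,
    x$frame_averaging, x$z_interval_um))
  invisible(x)
}

settings_keys <- c(objective_magnification = "OBJECTIVE_MAGNIFICATION",
                   numerical_aperture = "NUMERICAL_APERTURE",
                   gain = "GAIN", offset = "OFFSET",
                   frame_averaging = "FRAME_AVERAGING",
                   pixel_size_nm = "PIXEL_SIZE_NM",
                   z_interval_um = "Z_INTERVAL_UM")

#' Parse / write a microscope-settings text file
#'
#' The settings dialect is one `KEY<TAB>VALUE` pair per line. Mandatory
#' keys: `OBJECTIVE_MAGNIFICATION`, `NUMERICAL_APERTURE`, `PIXEL_SIZE_NM`,
#' `FRAME_AVERAGING`, `Z_INTERVAL_UM`. `GAIN` and `OFFSET` default to 1 and
#' 0 when absent. Unknown keys are preserved in the `extra` field. Settings
#' exported by real microscope software need converting into this dialect.
#'
#' @param path settings text file.
#' @param meta an [acquisition_metadata()] object (for writing).
#' @return `parse_settings` returns an [acquisition_metadata()];
#'   `write_settings` returns `path` invisibly.
#' @export
parse_settings <- function(path) {
  if (!file.exists(path)) abort_validation("no such file: ", path)
  kv <- read_key_values(path)
  mandatory <- settings_keys[!names(settings_keys) %in% c("gain", "offset")]
  missing <- setdiff(mandatory, names(kv))
  if (length(missing))
    stop("settings parse error in '", path, "': missing mandatory key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  num <- function(key, default = NULL) {
    if (!key %in% names(kv)) return(default)
    v <- suppressWarnings(as.numeric(kv[[key]]))
    if (is.na(v)) stop("settings parse error in '", path, "': key ", key,
                       " has non-numeric value '", kv[[key]], "'", call. = FALSE)
    v
  }
  acquisition_metadata(
    objective_magnification = num("OBJECTIVE_MAGNIFICATION"),
    numerical_aperture = num("NUMERICAL_APERTURE"),
    gain = num("GAIN", 1), offset = num("OFFSET", 0),
    frame_averaging = num("FRAME_AVERAGING"),
    pixel_size_nm = num("PIXEL_SIZE_NM"),
    z_interval_um = num("Z_INTERVAL_UM"),
    extra = kv[!names(kv) %in% settings_keys])
}

#' @rdname parse_settings
#' @export
write_settings <- function(meta, path) {
  stopifnot(inherits(meta, "acquisition_metadata"))
  vals <- vapply(names(settings_keys), function(f)
    format(meta[[f]], digits = 15), "")
  lines <- paste(settings_keys, vals, sep = "\t")
  if (length(meta$extra))
    lines <- c(lines, paste(names(meta$extra), meta$extra, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

sampled_columns <- c("target", "patient", "x_px", "y_px", "z_index",
                     "intensity", "layer", "u")

fmt_real <- function(x) {
  out <- sprintf("%.6g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write / read sampled-record tables
#'
#' Tab-separated text with one header row. The `xy` format carries columns
#' `target patient x_px y_px z_index intensity layer`; the `normalised`
#' format appends the normalised-distance column `u` and requires it to be
#' present for every record. Reals are serialised at 6 significant digits
#' (8-bit source data carry no more precision than that).
#'
#' @param table a sampled-record data frame (see [transform_stack()]).
#' @param path output text file.
#' @param format `"normalised"` (default) or `"xy"`.
#' @return `write_sampled` returns `path` invisibly; `read_sampled` returns
#'   the table as a data frame.
#' @export
write_sampled <- function(table, path, format = c("normalised", "xy")) {
  format <- match.arg(format)
  cols <- if (format == "xy") sampled_columns[1:7] else sampled_columns
  missing <- setdiff(setdiff(cols, "u"), names(table))
  if (length(missing))
    abort_validation("sampled table lacks column(s): ",
                     paste(missing, collapse = ", "))
  if (format == "normalised") {
    if (!"u" %in% names(table) || anyNA(table$u))
      abort_validation(
        "normalised format requires a complete 'u' column; ",
        "filter excluded records with quantified_points() first")
  }
  out <- table[, cols, drop = FALSE]
  out$intensity <- fmt_real(out$intensity)
  if ("u" %in% cols) out$u <- fmt_real(out$u)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sampled
#' @export
read_sampled <- function(path) {
  if (!file.exists(path)) abort_validation("no such file: ", path)
  tbl <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = list(target = "character",
                                      patient = "character",
                                      layer = "character"))
  missing <- setdiff(sampled_columns[1:7], names(tbl))
  if (length(missing))
    stop("sampled-table parse error in '", path, "': missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  tbl$layer <- factor(tbl$layer, levels = layer_levels)
  tbl
}

#' Read / write binary and labelled mask images
#'
#' Masks are integer TIFF rasters: zero marks background; for labelled
#' whole-cell masks, positive integers are cell identifiers.
#'
#' @param path TIFF file.
#' @param mask integer matrix (for writing).
#' @return `read_mask` returns an integer matrix; `write_mask` returns
#'   `path` invisibly.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) abort_validation("no such file: ", path)
  img <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                  error = function(e) stop("TIFF format error in '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  if (!is.matrix(img))
    stop("mask format error in '", path,
         "': expected a single grayscale page", call. = FALSE)
  if (any(img != round(img)))
    stop("mask format error in '", path, "': non-integer pixel values",
         call. = FALSE)
  storage.mode(img) <- "integer"
  img
}

#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  if (any(mask != round(mask)) || any(mask < 0))
    abort_validation("masks must hold nonnegative integers")
  bits <- if (max(mask) > 255) 16L else 8L
  tiff::writeTIFF(mask / (2^bits - 1), path, bits.per.sample = bits,
                  compression = "none", reduce = FALSE)
  invisible(path)
}

#' Write / read layer-boundary polylines as TSV
#'
#' One vertex per line with columns `boundary_index` (0..3, deep to
#' superficial), `vertex_index`, `x_px`, `y_px`; reals at 6 significant
#' digits.
#'
#' @param b a [layer_boundaries()] object.
#' @param path TSV file.
#' @param frame_shape `c(rows, columns)` of the frame the boundaries belong
#'   to (for reading).
#' @return `write_boundaries` returns `path` invisibly; `read_boundaries` a
#'   [layer_boundaries()] object.
#' @export
write_boundaries <- function(b, path) {
  stopifnot(inherits(b, "layer_boundaries"))
  rows <- do.call(rbind, lapply(1:4, function(k) {
    p <- b$boundaries[[k]]
    data.frame(boundary_index = k - 1L, vertex_index = seq_len(nrow(p)) - 1L,
               x_px = fmt_real(p$x), y_px = fmt_real(p$y))
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_boundaries
#' @export
read_boundaries <- function(path, frame_shape) {
  if (!file.exists(path)) abort_validation("no such file: ", path)
  tbl <- read.delim(path)
  need <- c("boundary_index", "vertex_index", "x_px", "y_px")
  missing <- setdiff(need, names(tbl))
  if (length(missing))
    stop("boundary parse error in '", path, "': missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  polys <- lapply(0:3, function(k) {
    p <- tbl[tbl$boundary_index == k, ]
    p <- p[order(p$vertex_index), ]
    data.frame(x = p$x_px, y = p$y_px)
  })
  layer_boundaries(polys, frame_shape)
}
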