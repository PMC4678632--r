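#' Mean-normalise sampled intensities
#'
#' Divides every intensity by the mean intensity of the set, so profiles
#' are comparable across acquisitions with different detector gain. The
#' scope of the normalisation is the table passed in — conventionally one
#' (target, patient, stack) set of quantified pixels.
#'
#' @param points sampled-record data frame with an `intensity` column, or a
#'   bare numeric vector.
#' @return list with `points` (input with intensities scaled to mean 1) and
#'   `factor` (the pre-normalisation mean, in detector units).
#' @examples
#' mean_normalise(c(2, 4, 6))   # 0.5 1.0 1.5, factor 4
#' @export
mean_normalise <- function(points) {
  vec <- if (is.data.frame(points)) points$intensity else as.numeric(points)
  if (!length(vec)) abort_validation("cannot mean-normalise an empty set")
  m <- mean(vec)
  if (!is.finite(m) || m <= 0)
    abort_validation("mean intensity must be positive (all-zero input?)")
  if (is.data.frame(points)) points$intensity <- points$intensity / m
  else points <- points / m
  list(points = points, factor = m)
}

#' LOESS depth-expression profile
#'
#' Fits a locally weighted regression (LOESS, degree-1 local polynomials
#' with tricube weights over the span-fraction nearest neighbours) of
#' mean-normalised intensity against normalised distance `u`, evaluated on
#' a fixed grid. The fit uses exact local regression (no interpolation
#' surface), so constant and exactly linear inputs are reproduced to
#' numerical precision.
#'
#' @param points quantified sampled-record data frame with columns `u` and
#'   `intensity` (see [transform_stack()], [quantified_points()]).
#' @param span LOESS span: fraction of points in each local window.
#' @param grid ordered evaluation grid in \[0, 3\].
#' @param normalise mean-normalise intensities first (default). With
#'   `FALSE`, intensities are used as-is and the recorded normalisation
#'   factor is 1.
#' @return An object of class `depth_profile` with fields `grid`, `fitted`,
#'   `span`, `n_points` and `normalisation_factor`.
#' @export
fit_profile <- function(points, span = 0.3,
                        grid = seq(0, 3, length.out = 151),
                        normalise = TRUE) {
  if (is.data.frame(points)) {
    if (anyNA(points$u))
      abort_validation("points contain excluded records (u = NA); ",
                       "apply quantified_points() first")
    u <- points$u; y <- points$intensity
  } else abort_validation("points must be a sampled-record data frame")
  n <- length(u)
  if (n < 10L)
    abort_validation("need at least 10 points to fit a profile, got ", n)
  if (is.unsorted(grid, strictly = TRUE))
    abort_validation("grid must be strictly increasing")
  if (span <= 0 || span > 1) abort_validation("span must lie in (0, 1]")
  if (ceiling(span * n) < 3L)
    abort_validation(sprintf(
      "span %.3f gives local windows of %d point(s) (< 3) at every grid node",
      span, ceiling(span * n)))
  factor <- 1
  if (normalise) {
    mn <- mean_normalise(y)
    y <- mn$points; factor <- mn$factor
  }
  fit <- loess(y ~ u, data = data.frame(u = u, y = y), span = span,
               degree = 1, family = "gaussian",
               control = loess.control(surface = "direct"))
  fitted <- as.numeric(predict(fit, newdata = data.frame(u = grid)))
  structure(list(grid = grid, fitted = fitted, span = span, n_points = n,
                 normalisation_factor = factor),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf(
    "LOESS depth profile: %d points, span %.2f, grid %g..%g (%d nodes)\n",
    x$n_points, x$span, min(x$grid), max(x$grid), length(x$grid)))
  cat(sprintf("  mean-normalisation factor %.6g; fitted range %.3f..%.3f\n",
              x$normalisation_factor, min(x$fitted), max(x$fitted)))
  invisible(x)
}

#' @export
as.data.frame.depth_profile <- function(x, ...) {
  data.frame(u = x$grid, fitted = x$fitted)
}

#' Evaluate a depth profile between grid nodes
#'
#' Linear interpolation of the fitted profile at new normalised distances.
#'
#' @param object a `depth_profile`.
#' @param u numeric locations within the fitted grid range.
#' @param ... unused.
#' @return numeric vector of interpolated fitted values.
#' @export
predict.depth_profile <- function(object, u, ...) {
  approx(object$grid, object$fitted, xout = u)$y
}

#' @export
plot.depth_profile <- function(x, ..., xlab = "normalised distance u",
                               ylab = "mean-normalised intensity") {
  plot(x$grid, x$fitted, type = "l", xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Compare two depth profiles
#'
#' Re-evaluates both profiles on the intersection of their grid ranges and
#' reports the root-mean-square difference and Pearson correlation —
#' a quantitative notion of "agreement" between samples.
#'
#' @param p1,p2 `depth_profile` objects with overlapping grid ranges.
#' @return An object of class `profile_comparison` with fields `rmse`,
#'   `pearson_r` and `common_grid`.
#' @export
compare_profiles <- function(p1, p2) {
  lo <- max(min(p1$grid), min(p2$grid))
  hi <- min(max(p1$grid), max(p2$grid))
  if (lo >= hi) abort_validation("profiles have disjoint grid ranges")
  common <- sort(unique(c(p1$grid, p2$grid)))
  common <- common[common >= lo & common <= hi]
  f1 <- predict(p1, common)
  f2 <- predict(p2, common)
  r <- suppressWarnings(cor(f1, f2))
  structure(list(rmse = sqrt(mean((f1 - f2)^2)), pearson_r = r,
                 common_grid = common),
            class = "profile_comparison")
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat(sprintf(
    "Profile comparison on u in %.2f..%.2f (%d nodes): rmse %.4g, Pearson r %.4f\n",
    min(x$common_grid), max(x$common_grid), length(x$common_grid),
    x$rmse, x$pearson_r))
  invisible(x)
}

#' Pool depth profiles across samples
#'
#' Node-wise mean and min-max envelope of two or more profiles on the
#' intersection of their grid ranges — the cross-patient summary used to
#' compare replicate tissues.
#'
#' @param profiles list of `depth_profile` objects (>= 2, overlapping
#'   grids).
#' @return An object of class `pooled_profile` with fields `grid`, `mean`,
#'   `lo`, `hi` and `n_profiles`.
#' @export
aggregate_profiles <- function(profiles) {
  if (length(profiles) < 2L)
    abort_validation("need at least two profiles to aggregate")
  lo <- max(vapply(profiles, function(p) min(p$grid), 0))
  hi <- min(vapply(profiles, function(p) max(p$grid), 0))
  if (lo >= hi) abort_validation("profiles have disjoint grid ranges")
  common <- sort(unique(unlist(lapply(profiles, `[[`, "grid"))))
  common <- common[common >= lo & common <= hi]
  vals <- vapply(profiles, function(p) predict(p, common),
                 numeric(length(common)))
  structure(list(grid = common, mean = rowMeans(vals),
                 lo = apply(vals, 1, min), hi = apply(vals, 1, max),
                 n_profiles = length(profiles)),
            class = "pooled_profile")
}

#' @export
print.pooled_profile <- function(x, ...) {
  cat(sprintf(
    "Pooled profile of %d samples on u in %.2f..%.2f (%d nodes); max envelope width %.4g\n",
    x$n_profiles, min(x$grid), max(x$grid), length(x$grid),
    max(x$hi - x$lo)))
  invisible(x)
}

#' @export
plot.pooled_profile <- function(x, ..., xlab = "normalised distance u",
                                ylab = "mean-normalised intensity") {
  plot(x$grid, x$mean, type = "n", ylim = range(c(x$lo, x$hi)),
       xlab = xlab, ylab = ylab, ...)
  polygon(c(x$grid, rev(x$grid)), c(x$lo, rev(x$hi)),
          col = grey(0.85), border = NA)
  lines(x$grid, x$mean)
  invisible(x)
}

#' Write / read a smoothed profile as TSV
#'
#' Header block of `# KEY<TAB>VALUE` lines (span, n_points, normalisation
#' factor) followed by a two-column table of `u` and `fitted`.
#'
#' @param profile a `depth_profile`.
#' @param path output text file.
#' @return `write_profile` returns `path` invisibly; `read_profile` a
#'   `depth_profile`.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "depth_profile"))
  hdr <- c(paste0("# SPAN\t", fmt_real(profile$span)),
           paste0("# N_POINTS\t", profile$n_points),
           paste0("# NORMALISATION_FACTOR\t",
                  format(profile$normalisation_factor, digits = 15)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("u\tfitted", con)
  writeLines(paste(format(profile$grid, digits = 15, trim = TRUE),
                   format(profile$fitted, digits = 15, trim = TRUE),
                   sep = "\t"), con)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) abort_validation("no such file: ", path)
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  kv <- read_header_kv(hdr)
  body <- lines[!grepl("^# ", lines)]
  tbl <- read.delim(text = paste(body, collapse = "\n"))
  structure(list(grid = tbl$u, fitted = tbl$fitted,
                 span = as.numeric(kv[["SPAN"]]),
                 n_points = as.integer(kv[["N_POINTS"]]),
                 normalisation_factor = as.numeric(kv[["NORMALISATION_FACTOR"]])),
            class = "depth_profile")
}

read_header_kv <- function(hdr) {
  parts <- strsplit(sub("^# ", "", hdr), "\t", fixed = TRUE)
  stats::setNames(vapply(parts, `[[`, "", 2L), vapply(parts, `[[`, "", 1L))
}
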