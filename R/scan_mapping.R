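# Spatially resolved scattering maps from raster scans.

#' A 2D scattering map
#'
#' Grid of area-under-peak (AUP) values, one per raster position.
#'
#' @param values Numeric `scan_rows x scan_cols` matrix of AUP values.
#' @param q_range Numeric `(q_min, q_max)` nm^-1 used for the AUP.
#' @param ordering Placement of the frame sequence into the grid:
#'   `"row-major"` or `"serpentine"`.
#' @return An object of class `scan_map`.
#' @export
scan_map <- function(values, q_range, ordering = c("row-major", "serpentine")) {
  ordering <- match.arg(ordering)
  stopifnot(is.matrix(values), is.numeric(values))
  if (any(!is.finite(values))) stop("map values must be finite")
  stopifnot(is.numeric(q_range), length(q_range) == 2L, q_range[1] < q_range[2])
  structure(list(values = values, q_range = as.numeric(q_range),
                 ordering = ordering),
            class = "scan_map")
}

#' @export
print.scan_map <- function(x, ...) {
  cat(sprintf(
    "<scan_map> %d x %d positions, AUP over [%.6g, %.6g) nm^-1, %s order\n",
    nrow(x$values), ncol(x$values), x$q_range[1], x$q_range[2], x$ordering))
  invisible(x)
}

#' Area under the peak of a scattering pattern
#'
#' Sum of the pattern's counts over the q bins whose center lies in the
#' half-open range `[q_min, q_max)`. No baseline is subtracted: for
#' histogram data the plain sum is the natural "area" and is invariant
#' to re-binning within the range.
#'
#' @param pattern A [scattering_pattern()].
#' @param q_min,q_max q-range of interest in nm^-1, `q_min < q_max`.
#' @return Scalar AUP value.
#' @export
area_under_peak <- function(pattern, q_min, q_max) {
  stopifnot(inherits(pattern, "scattering_pattern"))
  if (q_min >= q_max) stop("q_min must be < q_max")
  centers <- pattern_q_centers(pattern)
  sel <- centers >= q_min & centers < q_max
  if (!any(sel))
    stop(sprintf("q-range [%.6g, %.6g) contains no q-bin centers of the pattern",
                 q_min, q_max))
  sum(pattern$counts[sel])
}

#' Build a scattering map from a raster scan
#'
#' Each measurement is (optionally) background-subtracted with the one
#' shared background frame, reduced with identical geometry, energy
#' window and q-grid, scored by [area_under_peak()] over the q-range of
#' interest, and placed into the output grid. In `"row-major"` order,
#' frame `f` (1-based) lands at row `(f-1) %/% scan_cols + 1`, column
#' `(f-1) %% scan_cols + 1`; `"serpentine"` reverses every even row.
#'
#' No energy windowing is applied within the map: the single `window` is
#' the pre-selected energy range shared by every position.
#'
#' @param frames Ordered list of [detector_frame()] objects (e.g. from
#'   [load_scan_folder()]).
#' @param scan_rows,scan_cols Grid dimensions; their product must equal
#'   `length(frames)`.
#' @param geom A [geometry_config()] shared by all positions.
#' @param window Numeric `(lo, hi)` keV energy range.
#' @param q_edges q-bin edges shared by all positions.
#' @param q_range Numeric `(q_min, q_max)` nm^-1 for the AUP.
#' @param background Optional shared background [detector_frame()].
#' @param const A [physical_constants()].
#' @param ordering `"row-major"` (default) or `"serpentine"`.
#' @return A [scan_map()].
#' @export
build_scan_map <- function(frames, scan_rows, scan_cols, geom, window,
                           q_edges, q_range, background = NULL,
                           const = physical_constants(),
                           ordering = c("row-major", "serpentine")) {
  ordering <- match.arg(ordering)
  scan_rows <- as.integer(scan_rows); scan_cols <- as.integer(scan_cols)
  if (scan_rows < 1L || scan_cols < 1L)
    stop("scan_rows and scan_cols must be positive")
  if (length(frames) != scan_rows * scan_cols)
    stop(sprintf("scan has %d measurements but the grid declares %d x %d = %d",
                 length(frames), scan_rows, scan_cols,
                 scan_rows * scan_cols))
  q_map <- precompute_q_map(geom, frames[[1]]$energy_axis, const)
  aup <- vapply(frames, function(f) {
    if (!is.null(background)) f <- subtract_background(f, background)
    p <- reduce_to_pattern(f, geom, q_edges, window, const, q_map = q_map)
    area_under_peak(p, q_range[1], q_range[2])
  }, numeric(1))
  values <- matrix(0, scan_rows, scan_cols)
  for (f in seq_along(aup)) {
    r <- (f - 1L) %/% scan_cols + 1L
    c0 <- (f - 1L) %% scan_cols + 1L
    if (ordering == "serpentine" && r %% 2L == 0L)
      c0 <- scan_cols + 1L - c0
    values[r, c0] <- aup[f]
  }
  scan_map(values, q_range, ordering)
}
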