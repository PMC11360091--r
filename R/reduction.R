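# Reduction of a 3D detector frame to energy-windowed 1D q-patterns and
# 2D detector images.
#
# All intervals in this module are half-open [lo, hi): energy windows,
# energy selection and q bins. That convention makes window partitions
# tile the analysis range exactly, with no double counting at the seams.

#' Energy-range and windowing parameters
#'
#' The analysis energy range `[bin_start, bin_end)` is subdivided into
#' contiguous, non-overlapping energy windows of width
#' `window_width_keV`; each window is reduced to its own 1D pattern.
#' `bin_width_keV` optionally coarsens the detector's native energy axis
#' before reduction (see [rebin_energy()]); it must be an integer
#' multiple of the native bin width.
#'
#' The defaults reproduce a typical single-window configuration: range
#' 30-50 keV analyzed as one 20 keV window with 4 keV energy points.
#'
#' @param bin_start_keV,bin_end_keV Analysis range `[start, end)` in keV.
#' @param bin_width_keV Energy-point spacing in keV (re-binning width).
#' @param window_width_keV Width of each analysis window in keV.
#' @return An object of class `energy_window_spec`.
#' @export
energy_window_spec <- function(bin_start_keV = 30, bin_end_keV = 50,
                               bin_width_keV = 4, window_width_keV = 20) {
  stopifnot(is.numeric(bin_start_keV), is.numeric(bin_end_keV),
            is.numeric(bin_width_keV), is.numeric(window_width_keV))
  if (bin_start_keV >= bin_end_keV) stop("bin_start must be < bin_end")
  if (bin_width_keV <= 0 || window_width_keV <= 0)
    stop("bin_width and window_width must be positive")
  if (bin_width_keV > window_width_keV + 1e-12)
    stop("bin_width must not exceed window_width")
  if (window_width_keV > bin_end_keV - bin_start_keV + 1e-12)
    stop("window_width must not exceed the analysis range")
  structure(list(bin_start_keV = as.numeric(bin_start_keV),
                 bin_end_keV = as.numeric(bin_end_keV),
                 bin_width_keV = as.numeric(bin_width_keV),
                 window_width_keV = as.numeric(window_width_keV)),
            class = "energy_window_spec")
}

#' Partition the analysis range into energy windows
#'
#' Returns the contiguous half-open windows `[lo, hi)` covering
#' `[bin_start, bin_end)`. The range must be an integer multiple of the
#' window width; e.g. 30-45 keV with 5 keV windows gives
#' `[30,35), [35,40), [40,45)`.
#'
#' @param spec An [energy_window_spec()].
#' @return A list of numeric length-2 vectors `(lo, hi)` in ascending
#'   order.
#' @export
partition_windows <- function(spec) {
  stopifnot(inherits(spec, "energy_window_spec"))
  span <- spec$bin_end_keV - spec$bin_start_keV
  n <- span / spec$window_width_keV
  if (abs(n - round(n)) > 1e-9)
    stop(sprintf(
      "analysis range %.6g keV is not a multiple of the window width %.6g keV (remainder %.6g keV)",
      span, spec$window_width_keV,
      span - floor(n) * spec$window_width_keV))
  n <- as.integer(round(n))
  lapply(seq_len(n) - 1L, function(m)
    spec$bin_start_keV + c(m, m + 1L) * spec$window_width_keV)
}

#' Restrict a frame to an energy range
#'
#' Zeroes the counts of every energy bin whose center lies outside the
#' half-open range `[lo, hi)`. The array shape is preserved so geometry
#' lookups remain valid.
#'
#' @param frame A [detector_frame()].
#' @param lo_keV,hi_keV Energy range in keV, `lo < hi`.
#' @return A [detector_frame()] with out-of-range bins zeroed. Raw input
#'   stays raw (zeroing cannot create non-integer counts).
#' @export
select_energy_range <- function(frame, lo_keV, hi_keV) {
  stopifnot(inherits(frame, "detector_frame"))
  if (lo_keV >= hi_keV) stop("lo_keV must be < hi_keV")
  centers <- energy_bin_centers(frame$energy_axis)
  drop <- centers < lo_keV | centers >= hi_keV
  counts <- frame$counts
  counts[drop, , ] <- 0
  detector_frame(counts, frame$energy_axis, is_raw = frame$is_raw,
                 provenance = frame$provenance,
                 exposure_s = frame$exposure_s)
}

#' Coarsen the energy axis by integer aggregation
#'
#' Sums adjacent detector bins so the axis step becomes `bin_width_keV`,
#' which must be an integer multiple of the native width dividing the
#' bin count. Used to honour the energy-point spacing parameter of
#' [energy_window_spec()] before reduction.
#'
#' @param frame A [detector_frame()].
#' @param bin_width_keV Target energy-bin width in keV.
#' @return A [detector_frame()] on the coarsened axis.
#' @export
rebin_energy <- function(frame, bin_width_keV) {
  stopifnot(inherits(frame, "detector_frame"))
  ax <- frame$energy_axis
  f <- bin_width_keV / ax$bin_width_keV
  if (abs(f - round(f)) > 1e-9 || round(f) < 1)
    stop(sprintf(
      "target width %.6g keV is not an integer multiple of the native %.6g keV",
      bin_width_keV, ax$bin_width_keV))
  f <- as.integer(round(f))
  if (f == 1L) return(frame)
  if (ax$n_bins %% f != 0L)
    stop(sprintf("%d native bins cannot be grouped by %d", ax$n_bins, f))
  d <- dim(frame$counts)
  grouped <- array(frame$counts, dim = c(f, d[1] %/% f, d[2], d[3]))
  counts <- colSums(grouped, dims = 1L)
  detector_frame(counts,
                 energy_axis(ax$n_bins %/% f, bin_width_keV, ax$offset_keV),
                 is_raw = frame$is_raw, provenance = frame$provenance,
                 exposure_s = frame$exposure_s)
}

#' Subtract a background measurement
#'
#' Element-wise difference of two frames on identical axes. Negative
#' values are retained in the numeric result (clamping, if any, is a
#' rendering concern only); the result is flagged as corrected.
#' Counts are subtracted as measured, with no exposure normalization.
#'
#' @param sample,background [detector_frame()] objects with identical
#'   shape and energy axis.
#' @return A corrected [detector_frame()] (`is_raw = FALSE`).
#' @export
subtract_background <- function(sample, background) {
  stopifnot(inherits(sample, "detector_frame"),
            inherits(background, "detector_frame"))
  if (!identical(dim(sample$counts), dim(background$counts)))
    stop(sprintf("shape mismatch: sample %s vs background %s",
                 paste(dim(sample$counts), collapse = "x"),
                 paste(dim(background$counts), collapse = "x")))
  if (!same_axis(sample$energy_axis, background$energy_axis))
    stop(sprintf(
      "energy-axis mismatch: sample (%d bins, %.6g keV, offset %.6g) vs background (%d bins, %.6g keV, offset %.6g)",
      sample$energy_axis$n_bins, sample$energy_axis$bin_width_keV,
      sample$energy_axis$offset_keV, background$energy_axis$n_bins,
      background$energy_axis$bin_width_keV,
      background$energy_axis$offset_keV))
  detector_frame(sample$counts - background$counts, sample$energy_axis,
                 is_raw = FALSE,
                 provenance = paste0(sample$provenance, " - ",
                                     background$provenance),
                 exposure_s = sample$exposure_s)
}

#' A 1D scattering pattern
#'
#' Histogram of counts over half-open momentum-transfer bins
#' `[e_m, e_{m+1})`, produced from one energy window.
#'
#' @param q_edges Strictly ascending bin edges in nm^-1.
#' @param counts Numeric vector, one per bin.
#' @param window_label Numeric `(lo, hi)` keV window that produced the
#'   pattern.
#' @return An object of class `scattering_pattern`.
#' @export
scattering_pattern <- function(q_edges, counts, window_label = c(NA_real_, NA_real_)) {
  stopifnot(is.numeric(q_edges), is.numeric(counts))
  if (length(q_edges) < 2L || any(diff(q_edges) <= 0))
    stop("q_edges must be strictly ascending with at least 2 values")
  if (length(counts) != length(q_edges) - 1L)
    stop("counts must have one value per q bin")
  if (any(!is.finite(counts))) stop("counts must be finite")
  structure(list(q_edges = as.numeric(q_edges),
                 counts = as.numeric(counts),
                 window_label = as.numeric(window_label)),
            class = "scattering_pattern")
}

#' Bin-center q values of a pattern
#'
#' @param pattern A [scattering_pattern()].
#' @return Numeric vector of bin centers in nm^-1.
#' @export
pattern_q_centers <- function(pattern) {
  stopifnot(inherits(pattern, "scattering_pattern"))
  e <- pattern$q_edges
  (e[-length(e)] + e[-1]) / 2
}

#' @export
print.scattering_pattern <- function(x, ...) {
  cat(sprintf(
    "<scattering_pattern> %d q bins over [%.6g, %.6g) nm^-1, window [%.6g, %.6g) keV, total %.6g counts\n",
    length(x$counts), x$q_edges[1], x$q_edges[length(x$q_edges)],
    x$window_label[1], x$window_label[2], sum(x$counts)))
  invisible(x)
}

#' Default q-bin edges for a geometry
#'
#' Bins of width `q_bin` (default 0.1 nm^-1) from 0 to just past the
#' geometric maximum q reachable on the detector at energy `E_max_keV`,
#' so that every recorded count falls inside the grid.
#'
#' @param geom A [geometry_config()].
#' @param E_max_keV Highest energy of interest in keV.
#' @param q_bin Bin width in nm^-1.
#' @param const A [physical_constants()].
#' @return Numeric vector of ascending bin edges.
#' @export
default_q_edges <- function(geom, E_max_keV, q_bin = 0.1,
                            const = physical_constants()) {
  q_max <- max_attainable_q(geom, E_max_keV, const)
  seq(0, (floor(q_max / q_bin) + 1) * q_bin, by = q_bin)
}

#' Maximum momentum transfer reachable on the detector
#'
#' The largest q of any unmasked pixel center at energy `E_keV`.
#'
#' @param geom A [geometry_config()].
#' @param E_keV Photon energy in keV.
#' @param const A [physical_constants()].
#' @return Maximum q in nm^-1.
#' @export
max_attainable_q <- function(geom, E_keV, const = physical_constants()) {
  dr <- (seq_len(geom$n_rows) - 0.5) - geom$beam_center[1]
  dc <- (seq_len(geom$n_cols) - 0.5) - geom$beam_center[2]
  r2 <- outer(dr * dr, dc * dc, `+`)
  if (!is.null(geom$mask)) {
    if (all(geom$mask)) stop("all pixels are masked")
    r2[geom$mask] <- -Inf
  }
  r_mm <- geom$pixel_pitch_mm * sqrt(max(r2))
  momentum_transfer(E_keV, atan(r_mm / geom$sdd_mm), const)
}

#' Reduce a frame to a 1D scattering pattern
#'
#' For every unmasked pixel and every energy bin whose center lies in the
#' half-open window `[lo, hi)`, the momentum transfer `q(k, i, j)` is
#' evaluated from the bin-center energy and the pixel's scattering angle,
#' and the recorded count is added to the q bin containing it. Counts
#' whose q falls outside `[min(q_edges), max(q_edges))` are dropped, as
#' are masked pixels.
#'
#' @param frame A [detector_frame()].
#' @param geom A [geometry_config()] matching the frame's pixel grid.
#' @param q_edges Strictly ascending q-bin edges in nm^-1.
#' @param window Numeric `(lo, hi)` energy window in keV.
#' @param const A [physical_constants()].
#' @param q_map Optional precomputed [precompute_q_map()] array for this
#'   geometry/axis (an optimization for scans; recomputed when absent).
#' @return A [scattering_pattern()].
#' @export
reduce_to_pattern <- function(frame, geom, q_edges, window,
                              const = physical_constants(), q_map = NULL) {
  stopifnot(inherits(frame, "detector_frame"),
            inherits(geom, "geometry_config"))
  check_frame_geom(frame, geom)
  if (length(q_edges) < 2L || any(diff(q_edges) <= 0))
    stop("q_edges must be strictly ascending")
  if (is.null(q_map))
    q_map <- precompute_q_map(geom, frame$energy_axis, const)
  if (!identical(dim(q_map), dim(frame$counts)))
    stop("q_map shape does not match the frame")
  centers <- energy_bin_centers(frame$energy_axis)
  sel <- which(centers >= window[1] & centers < window[2])
  n_bins_q <- length(q_edges) - 1L
  acc <- numeric(n_bins_q)
  if (length(sel) > 0L) {
    q <- q_map[sel, , , drop = FALSE]
    w <- frame$counts[sel, , , drop = FALSE]
    idx <- findInterval(q, q_edges)          # m: e_m <= q < e_{m+1}
    keep <- !is.na(idx) & idx >= 1L & idx <= n_bins_q & w != 0
    if (any(keep)) {
      sums <- rowsum(w[keep], group = idx[keep])
      acc[as.integer(rownames(sums))] <- sums[, 1]
    }
  }
  scattering_pattern(q_edges, acc, window_label = as.numeric(window))
}

#' 2D detector image for an energy window
#'
#' Per-pixel sum of counts over the energy bins whose center lies in the
#' half-open window `[lo, hi)`. The returned array is unclamped; negative
#' values from background subtraction are kept (clamp only for display).
#'
#' @param frame A [detector_frame()].
#' @param window Numeric `(lo, hi)` energy window in keV.
#' @return Numeric `n_rows x n_cols` matrix.
#' @export
detector_image <- function(frame, window) {
  stopifnot(inherits(frame, "detector_frame"))
  centers <- energy_bin_centers(frame$energy_axis)
  sel <- centers >= window[1] & centers < window[2]
  d <- dim(frame$counts)
  if (!any(sel)) return(matrix(0, d[2], d[3]))
  colSums(frame$counts[sel, , , drop = FALSE], dims = 1L)
}

#' Full reduction of one frame across all energy windows
#'
#' Convenience wrapper chaining the standard workflow: optional
#' background subtraction, optional energy re-binning, energy-range
#' selection, then one [reduce_to_pattern()] and one [detector_image()]
#' per window of the partition.
#'
#' @param frame A [detector_frame()].
#' @param geom A [geometry_config()].
#' @param spec An [energy_window_spec()].
#' @param q_edges q-bin edges; default from [default_q_edges()] at
#'   `bin_end_keV`.
#' @param background Optional background [detector_frame()].
#' @param const A [physical_constants()].
#' @param rebin If `TRUE` (default), coarsen the energy axis to
#'   `spec$bin_width_keV` before reduction.
#' @return List with elements `patterns` (list of [scattering_pattern()])
#'   and `images` (list of matrices), one per window, plus `windows`.
#' @export
reduce_frame <- function(frame, geom, spec, q_edges = NULL,
                         background = NULL, const = physical_constants(),
                         rebin = TRUE) {
  stopifnot(inherits(spec, "energy_window_spec"))
  if (!is.null(background)) frame <- subtract_background(frame, background)
  if (rebin) frame <- rebin_energy(frame, spec$bin_width_keV)
  frame <- select_energy_range(frame, spec$bin_start_keV, spec$bin_end_keV)
  if (is.null(q_edges))
    q_edges <- default_q_edges(geom, spec$bin_end_keV, const = const)
  windows <- partition_windows(spec)
  q_map <- precompute_q_map(geom, frame$energy_axis, const)
  patterns <- lapply(windows, function(w)
    reduce_to_pattern(frame, geom, q_edges, w, const, q_map = q_map))
  images <- lapply(windows, function(w) detector_image(frame, w))
  list(patterns = patterns, images = images, windows = windows)
}
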