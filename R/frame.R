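# Detector frames and their energy axis.

#' Energy axis of a spectroscopic detector
#'
#' Uniform energy binning of the detector spectrum. Bin `k` (1-based)
#' spans the half-open interval
#' `[offset + (k-1) w, offset + k w)` and is represented by its center
#' `offset + (k - 0.5) w`. A HEXITEC-class acquisition typically uses 200
#' bins of 1 keV.
#'
#' @param n_bins Number of energy bins.
#' @param bin_width_keV Width of each bin in keV.
#' @param offset_keV Energy of the lower edge of the first bin, in keV.
#' @return An object of class `energy_axis`.
#' @export
energy_axis <- function(n_bins = 200L, bin_width_keV = 1, offset_keV = 0) {
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 1L) stop("n_bins must be a positive integer")
  stopifnot(is.numeric(bin_width_keV), length(bin_width_keV) == 1L,
            is.finite(bin_width_keV),
            is.numeric(offset_keV), length(offset_keV) == 1L,
            is.finite(offset_keV))
  if (bin_width_keV <= 0) stop("bin_width_keV must be positive")
  structure(list(n_bins = n_bins,
                 bin_width_keV = as.numeric(bin_width_keV),
                 offset_keV = as.numeric(offset_keV)),
            class = "energy_axis")
}

#' Representative (center) energies of all bins
#'
#' @param axis An [energy_axis()].
#' @return Numeric vector of length `n_bins` with the bin-center energies
#'   in keV.
#' @export
energy_bin_centers <- function(axis) {
  stopifnot(inherits(axis, "energy_axis"))
  axis$offset_keV + (seq_len(axis$n_bins) - 0.5) * axis$bin_width_keV
}

#' @export
print.energy_axis <- function(x, ...) {
  cat(sprintf("<energy_axis> %d bins of %.6g keV from %.6g to %.6g keV\n",
              x$n_bins, x$bin_width_keV, x$offset_keV,
              x$offset_keV + x$n_bins * x$bin_width_keV))
  invisible(x)
}

#' A spectroscopic detector frame
#'
#' The raw measurement unit of the tool: a 3D count array indexed
#' `(energy bin k, pixel row i, pixel column j)` together with its energy
#' axis. Raw frames (`is_raw = TRUE`, i.e. unmodified detector output)
#' must hold non-negative integer counts; corrected frames (e.g. after
#' background subtraction) may hold any finite real values, including
#' negatives.
#'
#' @param counts Numeric 3D array with dim `(n_bins, n_rows, n_cols)`.
#' @param axis The [energy_axis()] of the first array dimension.
#' @param is_raw Logical; `TRUE` for unmodified detector output.
#' @param provenance Free-text source identifier carried through I/O.
#' @param exposure_s Optional positive exposure time in seconds. Carried
#'   as metadata only; no count scaling is derived from it.
#' @return An object of class `detector_frame`.
#' @export
detector_frame <- function(counts, axis, is_raw = TRUE,
                           provenance = "", exposure_s = NULL) {
  stopifnot(inherits(axis, "energy_axis"))
  if (!is.array(counts) || length(dim(counts)) != 3L)
    stop("counts must be a 3D array (energy bin, row, col)")
  if (dim(counts)[1] != axis$n_bins)
    stop(sprintf("counts has %d energy planes but the axis declares %d bins",
                 dim(counts)[1], axis$n_bins))
  storage.mode(counts) <- "double"
  if (anyNA(counts) || any(!is.finite(counts)))
    stop("counts must be finite")
  is_raw <- isTRUE(is_raw)
  if (is_raw && (any(counts < 0) || any(counts != floor(counts))))
    stop("a raw frame must contain non-negative integer counts")
  if (!is.null(exposure_s)) {
    stopifnot(is.numeric(exposure_s), length(exposure_s) == 1L)
    if (!is.finite(exposure_s) || exposure_s <= 0)
      stop("exposure_s must be positive")
    exposure_s <- as.numeric(exposure_s)
  }
  structure(list(counts = counts, energy_axis = axis, is_raw = is_raw,
                 provenance = as.character(provenance)[1],
                 exposure_s = exposure_s),
            class = "detector_frame")
}

#' @export
print.detector_frame <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "<detector_frame> %d energy bins x %d x %d pixels, %s, total %.6g counts\n",
    d[1], d[2], d[3], if (x$is_raw) "raw" else "corrected", sum(x$counts)))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Total counts in a frame
#'
#' @param frame A [detector_frame()].
#' @return Scalar sum of all counts.
#' @export
frame_total <- function(frame) {
  stopifnot(inherits(frame, "detector_frame"))
  sum(frame$counts)
}

# shared shape check used by reduction and subtraction
check_frame_geom <- function(frame, geom) {
  d <- dim(frame$counts)
  if (d[2] != geom$n_rows || d[3] != geom$n_cols)
    stop(sprintf("frame is %d x %d pixels but geometry declares %d x %d",
                 d[2], d[3], geom$n_rows, geom$n_cols))
  invisible(TRUE)
}

same_axis <- function(a, b) {
  isTRUE(all.equal(a$n_bins, b$n_bins)) &&
    isTRUE(all.equal(a$bin_width_keV, b$bin_width_keV)) &&
    isTRUE(all.equal(a$offset_keV, b$offset_keV))
}
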