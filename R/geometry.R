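# Pixel -> scattering angle -> momentum transfer mapping for a flat
# 2D detector at small angles.
#
# Conventions used throughout the package:
#   * pixel indices are 1-based (R convention); pixel (i, j) occupies the
#     square [i-1, i) x [j-1, j) in pixel-pitch units, so its center sits at
#     (i - 0.5, j - 0.5);
#   * the transmitted-beam center is given in the same fractional pitch
#     coordinate system and may lie off the detector (e.g. behind a beam
#     stop just beyond a corner);
#   * the scattering angle of a pixel is the full angle 2-theta between the
#     primary beam axis and the sample->pixel direction; the Bragg-type
#     momentum-transfer relation uses the half angle theta = 2theta / 2.

#' Physical constants used in the momentum-transfer relation
#'
#' The only constant the reduction needs is the product `hc` expressed in
#' keV nm. The default is the rounded value 1.24 keV nm commonly used in
#' X-ray work; pass `hc_keV_nm = 1.239841984` for the CODATA value.
#'
#' @param hc_keV_nm Planck constant times speed of light, in keV nm.
#' @return An object of class `physical_constants`.
#' @export
physical_constants <- function(hc_keV_nm = 1.24) {
  stopifnot(is.numeric(hc_keV_nm), length(hc_keV_nm) == 1L, is.finite(hc_keV_nm))
  if (hc_keV_nm <= 0) stop("hc_keV_nm must be positive")
  structure(list(hc_keV_nm = as.numeric(hc_keV_nm)),
            class = "physical_constants")
}

#' Detector and beam geometry
#'
#' Describes the flat-detector geometry needed to assign a scattering angle
#' to every pixel: sample-to-detector distance (SDD), the location of the
#' transmitted primary beam on the detector plane, the pixel pitch and the
#' sensor dimensions. An optional logical mask flags pixels to exclude from
#' reduction (dead pixels, beam-stop shadow, ...).
#'
#' @param sdd_mm Sample-to-detector distance in mm (typically 220-300 for
#'   the geometry this tool targets).
#' @param beam_center Numeric length-2 `(row, col)` position of the
#'   transmitted beam in fractional pitch coordinates (pixel `(i, j)` has
#'   center `(i - 0.5, j - 0.5)`); may lie outside the array.
#' @param pixel_pitch_mm Pixel pitch in mm (0.25 for an 80x80 HEXITEC-class
#'   CdTe sensor).
#' @param n_rows,n_cols Sensor dimensions in pixels.
#' @param mask Optional logical `n_rows x n_cols` matrix; `TRUE` excludes
#'   the pixel from all reductions.
#' @return An object of class `geometry_config`.
#' @export
geometry_config <- function(sdd_mm, beam_center, pixel_pitch_mm,
                            n_rows, n_cols, mask = NULL) {
  stopifnot(is.numeric(sdd_mm), length(sdd_mm) == 1L, is.finite(sdd_mm),
            is.numeric(beam_center), length(beam_center) == 2L,
            all(is.finite(beam_center)),
            is.numeric(pixel_pitch_mm), length(pixel_pitch_mm) == 1L,
            is.finite(pixel_pitch_mm))
  if (sdd_mm <= 0) stop("sdd_mm must be positive")
  if (pixel_pitch_mm <= 0) stop("pixel_pitch_mm must be positive")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || n_rows < 1L || is.na(n_cols) || n_cols < 1L)
    stop("n_rows and n_cols must be positive integers")
  if (!is.null(mask)) {
    if (!is.logical(mask) || !identical(dim(mask), c(n_rows, n_cols)))
      stop(sprintf("mask must be a logical %d x %d matrix", n_rows, n_cols))
    if (anyNA(mask)) stop("mask must not contain NA")
  }
  structure(list(sdd_mm = as.numeric(sdd_mm),
                 beam_center = as.numeric(beam_center),
                 pixel_pitch_mm = as.numeric(pixel_pitch_mm),
                 n_rows = n_rows, n_cols = n_cols, mask = mask),
            class = "geometry_config")
}

#' @export
print.geometry_config <- function(x, ...) {
  cat(sprintf(
    "<geometry_config> SDD %.6g mm, pitch %.6g mm, %d x %d pixels,\n  beam center (%.6g, %.6g)%s\n",
    x$sdd_mm, x$pixel_pitch_mm, x$n_rows, x$n_cols,
    x$beam_center[1], x$beam_center[2],
    if (is.null(x$mask)) "" else sprintf(", %d masked pixels", sum(x$mask))))
  invisible(x)
}

#' Scattering angle of a detector pixel
#'
#' Returns the full scattering angle `2theta = atan(r / SDD)` where `r` is
#' the in-plane distance from the transmitted-beam center to the pixel
#' center.
#'
#' @param geom A [geometry_config()].
#' @param row,col 1-based pixel indices (vectorized, recycled together).
#' @return Scattering angle(s) `2theta` in radians, in `[0, pi/2)`.
#' @export
pixel_scattering_angle <- function(geom, row, col) {
  stopifnot(inherits(geom, "geometry_config"))
  row <- as.numeric(row); col <- as.numeric(col)
  if (any(row < 1 | row > geom$n_rows | row != floor(row)) ||
      any(col < 1 | col > geom$n_cols | col != floor(col)))
    stop("pixel index out of range")
  dr <- (row - 0.5) - geom$beam_center[1]
  dc <- (col - 0.5) - geom$beam_center[2]
  r_mm <- geom$pixel_pitch_mm * sqrt(dr * dr + dc * dc)
  atan(r_mm / geom$sdd_mm)
}

#' Momentum transfer from energy and scattering angle
#'
#' Computes `q = 4 pi E sin(theta) / hc` with `theta = two_theta / 2`
#' (the half scattering angle, as in the Bragg relation). Units: `E` in
#' keV, `hc` in keV nm, so `q` is in reciprocal nanometres.
#'
#' @param E_keV Photon energy in keV (vectorized).
#' @param two_theta Full scattering angle in radians, in `[0, pi)`.
#' @param const A [physical_constants()].
#' @return Momentum transfer in nm^-1.
#' @export
momentum_transfer <- function(E_keV, two_theta, const = physical_constants()) {
  stopifnot(inherits(const, "physical_constants"))
  if (any(!is.finite(E_keV)) || any(E_keV <= 0))
    stop("E_keV must be positive and finite")
  if (any(two_theta < 0) || any(two_theta >= pi))
    stop("two_theta must lie in [0, pi)")
  4 * pi * E_keV * sin(two_theta / 2) / const$hc_keV_nm
}

#' Peak position from a lattice d-spacing
#'
#' The Bragg peak of a lattice plane family with repeat distance `d` sits
#' at `q = 2 pi / d`.
#'
#' @param d_nm d-spacing in nm (vectorized).
#' @return Peak position in nm^-1.
#' @export
q_from_dspacing <- function(d_nm) {
  if (any(!is.finite(d_nm)) || any(d_nm <= 0))
    stop("d_nm must be positive and finite")
  2 * pi / d_nm
}

#' Momentum-transfer lookup table for a whole frame
#'
#' Precomputes `q(k, i, j)` for every energy bin `k` and pixel `(i, j)`,
#' using the energy-bin center as the representative energy. Masked pixels
#' are set to `NA` so downstream binning drops them.
#'
#' @param geom A [geometry_config()].
#' @param axis An [energy_axis()].
#' @param const A [physical_constants()].
#' @return Numeric array with dim `(axis$n_bins, geom$n_rows, geom$n_cols)`.
#' @export
precompute_q_map <- function(geom, axis, const = physical_constants()) {
  stopifnot(inherits(geom, "geometry_config"), inherits(axis, "energy_axis"))
  rows <- seq_len(geom$n_rows); cols <- seq_len(geom$n_cols)
  dr <- (rows - 0.5) - geom$beam_center[1]
  dc <- (cols - 0.5) - geom$beam_center[2]
  r_mm <- geom$pixel_pitch_mm * sqrt(outer(dr * dr, dc * dc, `+`))
  sin_theta <- sin(atan(r_mm / geom$sdd_mm) / 2)          # n_rows x n_cols
  if (!is.null(geom$mask)) sin_theta[geom$mask] <- NA_real_
  E <- energy_bin_centers(axis)
  pref <- 4 * pi * E / const$hc_keV_nm                    # length n_bins
  # outer product pref (k) x sin_theta (i,j), k varying fastest
  q <- array(pref %o% sin_theta,
             dim = c(axis$n_bins, geom$n_rows, geom$n_cols))
  q
}

#' Ring radius on the detector for a given q and energy
#'
#' Inverts the momentum-transfer relation: the Debye-Scherrer ring of a
#' reflection at `q` illuminated at energy `E` has in-plane radius
#' `r = SDD * tan(2 * asin(q hc / (4 pi E)))` around the transmitted-beam
#' center. Errors if the requested `q` is not reachable at this energy.
#'
#' @param geom A [geometry_config()].
#' @param q Momentum transfer in nm^-1 (vectorized with `E_keV`).
#' @param E_keV Photon energy in keV.
#' @param const A [physical_constants()].
#' @return Ring radius in mm.
#' @export
ring_radius <- function(geom, q, E_keV, const = physical_constants()) {
  stopifnot(inherits(geom, "geometry_config"),
            inherits(const, "physical_constants"))
  if (any(!is.finite(E_keV)) || any(E_keV <= 0))
    stop("E_keV must be positive and finite")
  if (any(q < 0)) stop("q must be non-negative")
  s <- q * const$hc_keV_nm / (4 * pi * E_keV)
  if (any(s > 1))
    stop("requested q is unreachable: energy too low for this momentum transfer")
  geom$sdd_mm * tan(2 * asin(s))
}
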