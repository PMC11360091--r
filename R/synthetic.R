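# Forward simulation of spectroscopic detector frames containing
# Debye-Scherrer rings, used as ground truth for validating the
# reduction chain.
#
# The forward model works directly in q-space: each ring is a Gaussian
# profile in q (not in detector radius), so the injected peak position
# lives in the same coordinate the reduction measures and recovery tests
# compare like with like.

#' A simulated Bragg reflection
#'
#' @param q_peak Peak position in nm^-1.
#' @param sigma_q Gaussian width of the peak in q, nm^-1.
#' @param intensity Expected total counts this ring contributes over the
#'   full spectrum (its Poisson mean, summed over reachable detector
#'   cells).
#' @return An object of class `ring_spec`.
#' @export
ring_spec <- function(q_peak, sigma_q, intensity) {
  stopifnot(is.numeric(q_peak), is.numeric(sigma_q), is.numeric(intensity))
  if (q_peak <= 0) stop("q_peak must be positive")
  if (sigma_q <= 0) stop("sigma_q must be positive")
  if (intensity < 0) stop("intensity must be non-negative")
  structure(list(q_peak = as.numeric(q_peak), sigma_q = as.numeric(sigma_q),
                 intensity = as.numeric(intensity)),
            class = "ring_spec")
}

#' A polychromatic source spectrum
#'
#' Tabulated relative weights over photon energy. Each table row is
#' assigned to the energy bin containing its energy; rows falling
#' outside the detector axis are ignored at simulation time. Weights are
#' normalized internally to sum 1.
#'
#' @param energy_keV Numeric vector of energies in keV.
#' @param weight Non-negative relative weights, at least one positive.
#' @return An object of class `source_spectrum`.
#' @export
source_spectrum <- function(energy_keV, weight) {
  stopifnot(is.numeric(energy_keV), is.numeric(weight),
            length(energy_keV) == length(weight))
  if (any(weight < 0)) stop("spectrum weights must be non-negative")
  if (!any(weight > 0)) stop("spectrum must have at least one positive weight")
  structure(list(energy_keV = as.numeric(energy_keV),
                 weight = as.numeric(weight)),
            class = "source_spectrum")
}

#' Flat spectrum over an energy range
#'
#' Equal weight at every energy-bin center of `axis` inside the
#' half-open range `[lo, hi)`; a convenient stand-in for an unfiltered
#' tube spectrum when the spectral shape is irrelevant to the question
#' at hand.
#'
#' @param lo_keV,hi_keV Energy range in keV.
#' @param axis An [energy_axis()].
#' @return A [source_spectrum()].
#' @export
flat_spectrum <- function(lo_keV, hi_keV, axis) {
  centers <- energy_bin_centers(axis)
  sel <- centers >= lo_keV & centers < hi_keV
  if (!any(sel)) stop("no energy-bin centers inside the requested range")
  source_spectrum(centers[sel], rep(1, sum(sel)))
}

# per-bin spectral weights on the detector axis, normalized to sum 1
spectrum_bin_weights <- function(spectrum, axis) {
  stopifnot(inherits(spectrum, "source_spectrum"),
            inherits(axis, "energy_axis"))
  edges <- axis$offset_keV + (0:axis$n_bins) * axis$bin_width_keV
  idx <- findInterval(spectrum$energy_keV, edges)
  keep <- idx >= 1L & idx <= axis$n_bins
  w <- numeric(axis$n_bins)
  if (any(keep)) {
    sums <- rowsum(spectrum$weight[keep], group = idx[keep])
    w[as.integer(rownames(sums))] <- sums[, 1]
  }
  tot <- sum(w)
  if (tot <= 0)
    stop("spectrum has no weight inside the detector energy axis")
  w / tot
}

#' Expected count rate of the simulator's forward model
#'
#' The Poisson mean for every `(energy bin, row, col)` cell:
#' `lambda(k,i,j) = background_rate +
#'   sum_rings intensity * weight_k * N(q(k,i,j); q_peak, sigma_q) / Z`,
#' where `Z` normalizes each ring's profile over all unmasked cells so
#' that the ring's expected total equals its `intensity`.
#'
#' @param geom A [geometry_config()].
#' @param axis An [energy_axis()].
#' @param spectrum A [source_spectrum()].
#' @param rings List of [ring_spec()] objects (possibly empty).
#' @param background_rate Expected counts per (bin, pixel) of flat
#'   background.
#' @param const A [physical_constants()].
#' @return List with `lambda` (3D array of Poisson means) and
#'   `ring_totals` (expected total counts per ring).
#' @export
expected_rate <- function(geom, axis, spectrum, rings, background_rate = 0,
                          const = physical_constants()) {
  stopifnot(background_rate >= 0)
  if (inherits(rings, "ring_spec")) rings <- list(rings)
  stopifnot(all(vapply(rings, inherits, logical(1), "ring_spec")))
  w <- spectrum_bin_weights(spectrum, axis)
  q_map <- precompute_q_map(geom, axis, const)
  lambda <- array(background_rate, dim = dim(q_map))
  if (!is.null(geom$mask)) {
    masked <- is.na(q_map)
    lambda[masked] <- 0
  }
  ring_totals <- numeric(length(rings))
  for (s in seq_along(rings)) {
    rg <- rings[[s]]
    prof <- w * stats::dnorm(q_map, mean = rg$q_peak, sd = rg$sigma_q)
    prof[is.na(prof)] <- 0
    z <- sum(prof)
    if (z > 0) {
      lambda <- lambda + rg$intensity * prof / z
      ring_totals[s] <- rg$intensity
    }                        # unreachable ring: contributes nothing
  }
  list(lambda = lambda, ring_totals = ring_totals)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate one spectroscopic detector frame
#'
#' Draws Poisson counts around the forward model of [expected_rate()]:
#' Debye-Scherrer rings with Gaussian q-profiles under a tabulated
#' source spectrum, on top of a flat background. Reproducible: the same
#' seed yields identical counts. The per-ring expected totals are
#' attached as attribute `"ring_expected_totals"`.
#'
#' @inheritParams expected_rate
#' @param seed Integer RNG seed; `NULL` uses (and advances) the current
#'   RNG state.
#' @param provenance Free-text tag stored in the frame.
#' @return A raw [detector_frame()].
#' @export
simulate_frame <- function(geom, axis, spectrum, rings,
                           background_rate = 0, seed = NULL,
                           const = physical_constants(),
                           provenance = "simulated frame") {
  er <- expected_rate(geom, axis, spectrum, rings, background_rate, const)
  n <- length(er$lambda)
  draw <- function() stats::rpois(n, er$lambda)
  counts <- if (is.null(seed)) draw() else with_seed(seed, draw())
  frame <- detector_frame(array(as.double(counts), dim = dim(er$lambda)),
                          axis, is_raw = TRUE, provenance = provenance)
  attr(frame, "ring_expected_totals") <- er$ring_totals
  frame
}

#' Simulate a raster scan
#'
#' One frame per grid cell in row-major order, with every ring's
#' intensity scaled by that cell's multiplier (emulating, e.g., wells
#' holding different mass fractions of the same powder). Deterministic
#' under `seed`: the seed fixes the whole sequence of frames.
#'
#' @inheritParams simulate_frame
#' @param intensity_multipliers Numeric matrix of non-negative scale
#'   factors, one per scan position.
#' @return List of raw [detector_frame()] objects, length
#'   `length(intensity_multipliers)`, row-major over the grid.
#' @export
simulate_scan <- function(geom, axis, spectrum, rings,
                          intensity_multipliers, background_rate = 0,
                          seed = NULL, const = physical_constants()) {
  stopifnot(is.matrix(intensity_multipliers),
            is.numeric(intensity_multipliers))
  if (length(intensity_multipliers) == 0L) stop("empty multiplier grid")
  if (any(intensity_multipliers < 0))
    stop("intensity multipliers must be non-negative")
  if (inherits(rings, "ring_spec")) rings <- list(rings)
  gen <- function() {
    frames <- vector("list", length(intensity_multipliers))
    f <- 0L
    for (r in seq_len(nrow(intensity_multipliers))) {
      for (c0 in seq_len(ncol(intensity_multipliers))) {
        f <- f + 1L
        m <- intensity_multipliers[r, c0]
        scaled <- lapply(rings, function(rg)
          ring_spec(rg$q_peak, rg$sigma_q, rg$intensity * m))
        frames[[f]] <- simulate_frame(
          geom, axis, spectrum, scaled, background_rate, seed = NULL,
          const = const,
          provenance = sprintf("simulated scan position (%d, %d)", r, c0))
      }
    }
    frames
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Reference simulation geometry
#'
#' The package's standard validation geometry: SDD 250 mm, 0.25 mm
#' pitch, 80 x 80 pixels, transmitted beam just off one corner at
#' fractional pixel position (-2, -2) — emulating a beam-stop
#' arrangement where the primary beam is excluded from the sensor while
#' both caffeine rings (8.4 and 18.6 nm^-1) stay on-detector for
#' energies in the 30-45 keV range.
#'
#' @return A [geometry_config()].
#' @export
reference_geometry <- function() {
  geometry_config(sdd_mm = 250, beam_center = c(-2, -2),
                  pixel_pitch_mm = 0.25, n_rows = 80L, n_cols = 80L)
}
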