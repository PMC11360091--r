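# Shared fixtures and independent oracles.

# small geometry for fast exhaustive checks
small_geometry <- function(mask = NULL) {
  geometry_config(sdd_mm = 250, beam_center = c(-1, -1),
                  pixel_pitch_mm = 0.25, n_rows = 8L, n_cols = 8L,
                  mask = mask)
}

small_axis <- function() energy_axis(n_bins = 10L, bin_width_keV = 1.5,
                                     offset_keV = 30)

# random raw frame with Poisson-like occupancy
random_frame <- function(axis = small_axis(), n_rows = 8L, n_cols = 8L,
                         lambda = 2) {
  counts <- array(stats::rpois(axis$n_bins * n_rows * n_cols, lambda),
                  dim = c(axis$n_bins, n_rows, n_cols))
  detector_frame(array(as.double(counts), dim = dim(counts)), axis)
}

# Independent reduction oracle: naive triple loop over (k, i, j) using the
# scalar geometry operations and a linear scan for the q bin.
naive_reduce <- function(frame, geom, q_edges, window,
                         const = physical_constants()) {
  centers <- energy_bin_centers(frame$energy_axis)
  acc <- numeric(length(q_edges) - 1L)
  for (k in seq_along(centers)) {
    if (centers[k] < window[1] || centers[k] >= window[2]) next
    for (i in seq_len(geom$n_rows)) {
      for (j in seq_len(geom$n_cols)) {
        if (!is.null(geom$mask) && geom$mask[i, j]) next
        w <- frame$counts[k, i, j]
        if (w == 0) next
        q <- momentum_transfer(centers[k],
                               pixel_scattering_angle(geom, i, j), const)
        for (m in seq_len(length(q_edges) - 1L)) {
          if (q >= q_edges[m] && q < q_edges[m + 1L]) {
            acc[m] <- acc[m] + w
            break
          }
        }
      }
    }
  }
  acc
}

# standard simulation setup used by recovery tests: reference 80x80
# geometry, 1 keV bins, flat 30-45 keV spectrum
recovery_setup <- function() {
  geom <- reference_geometry()
  axis <- energy_axis(200L, 1, 0)
  list(geom = geom, axis = axis,
       spectrum = flat_spectrum(30, 45, axis),
       q_edges = default_q_edges(geom, 45))
}
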