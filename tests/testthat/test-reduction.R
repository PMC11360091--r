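test_that("energy windows tile the analysis range", {
  # 30-50 keV with 20 keV windows: the single-window configuration
  one <- partition_windows(energy_window_spec(30, 50, 4, 20))
  expect_length(one, 1)
  expect_equal(one[[1]], c(30, 50))

  # 30-45 keV with 5 keV windows: three contiguous windows
  three <- partition_windows(energy_window_spec(30, 45, 5, 5))
  expect_equal(three, list(c(30, 35), c(35, 40), c(40, 45)))

  # window equal to the whole range
  expect_length(partition_windows(energy_window_spec(10, 60, 1, 50)), 1)

  # non-divisible range reports the remainder
  expect_error(partition_windows(energy_window_spec(30, 45, 4, 4)),
               "remainder")
  expect_error(energy_window_spec(50, 30), "bin_start")
  expect_error(energy_window_spec(30, 50, 25, 20), "bin_width")
})

test_that("energy selection zeroes bins by center, half-open", {
  ax <- energy_axis(200, 1, 0)          # centers 0.5, 1.5, ..., 199.5
  fr <- detector_frame(array(1, c(200, 4, 4)), ax)

  # full range: unchanged
  expect_identical(select_energy_range(fr, 0, 200)$counts, fr$counts)
  # empty range: all zero
  expect_identical(frame_total(select_energy_range(fr, 300, 301)), 0)

  # [30, 45): centers 30.5 .. 44.5 retained, i.e. bins 31..45 -> 15 bins
  sel <- select_energy_range(fr, 30, 45)
  kept <- which(apply(sel$counts, 1, sum) > 0)
  expect_identical(kept, 31:45)
  expect_identical(frame_total(sel), 15 * 16)
  expect_lte(frame_total(sel), frame_total(fr))
  expect_error(select_energy_range(fr, 45, 30), "lo_keV")
})

test_that("energy re-binning aggregates adjacent bins exactly", {
  set.seed(21)
  fr <- random_frame(energy_axis(12, 1, 30), 4, 4)
  rb <- rebin_energy(fr, 4)
  expect_identical(rb$energy_axis$n_bins, 3L)
  expect_identical(rb$energy_axis$bin_width_keV, 4)
  expect_identical(rb$energy_axis$offset_keV, 30)
  expect_identical(frame_total(rb), frame_total(fr))
  expect_equal(rb$counts[1, 2, 3], sum(fr$counts[1:4, 2, 3]))
  expect_identical(rebin_energy(fr, 1), fr)
  expect_error(rebin_energy(fr, 2.5), "integer multiple")
  expect_error(rebin_energy(fr, 5), "grouped")
})

test_that("background subtraction is element-wise, unclamped, and linear under reduction", {
  set.seed(31)
  geom <- small_geometry()
  ax <- small_axis()
  s <- random_frame(ax, 8, 8, lambda = 3)
  b <- random_frame(ax, 8, 8, lambda = 2)

  # frame minus itself vanishes
  expect_identical(frame_total(subtract_background(s, s)), 0)

  d <- subtract_background(s, b)
  expect_false(d$is_raw)
  expect_identical(d$counts, s$counts - b$counts)
  expect_true(any(d$counts < 0))        # negatives retained

  # reduce(sample - bg) == reduce(sample) - reduce(bg), bin by bin
  qe <- default_q_edges(geom, 45)
  w <- c(30, 45)
  pd <- reduce_to_pattern(d, geom, qe, w)
  ps <- reduce_to_pattern(s, geom, qe, w)
  pb <- reduce_to_pattern(b, geom, qe, w)
  expect_equal(pd$counts, ps$counts - pb$counts, tolerance = 1e-12)

  # mismatches are reported with both offending descriptions
  other <- random_frame(energy_axis(10, 1.5, 31), 8, 8)
  expect_error(subtract_background(s, other), "offset 30.*offset 31")
  small <- random_frame(ax, 4, 8)
  expect_error(subtract_background(s, small), "10x8x8.*10x4x8")
})

test_that("reduction equals the naive per-cell loop exactly", {
  set.seed(41)
  geom <- small_geometry()
  for (rep in 1:20) {
    ax <- energy_axis(sample(5:10, 1), runif(1, 0.8, 2), runif(1, 25, 35))
    fr <- random_frame(ax, 8, 8, lambda = 1)
    q_edges <- seq(0, 8, by = runif(1, 0.05, 0.3))
    window <- sort(runif(2, ax$offset_keV,
                         ax$offset_keV + ax$n_bins * ax$bin_width_keV))
    fast <- reduce_to_pattern(fr, geom, q_edges, window)
    expect_identical(fast$counts, naive_reduce(fr, geom, q_edges, window))
  }

  # with a mask, masked pixels are excluded identically
  mask <- matrix(FALSE, 8, 8); mask[2, 5] <- TRUE; mask[7, 7] <- TRUE
  gm <- small_geometry(mask)
  fr <- random_frame(small_axis(), 8, 8, lambda = 2)
  qe <- seq(0, 8, by = 0.1)
  expect_identical(reduce_to_pattern(fr, gm, qe, c(30, 45))$counts,
                   naive_reduce(fr, gm, qe, c(30, 45)))
})

test_that("full-range reduction conserves every count", {
  set.seed(51)
  # small frame
  geom <- small_geometry()
  ax <- small_axis()
  fr <- random_frame(ax, 8, 8, lambda = 5)
  qe <- default_q_edges(geom, ax$offset_keV + ax$n_bins * ax$bin_width_keV)
  pat <- reduce_to_pattern(fr, geom, qe, c(-Inf, Inf))
  expect_identical(sum(pat$counts), frame_total(fr))

  # full-size frame: 200 x 80 x 80
  geom80 <- reference_geometry()
  ax200 <- energy_axis(200, 1, 0)
  big <- detector_frame(array(as.double(rpois(200 * 80 * 80, 0.5)),
                              c(200, 80, 80)), ax200)
  qe_big <- default_q_edges(geom80, 200)
  pat_big <- reduce_to_pattern(big, geom80, qe_big, c(0, 200))
  expect_identical(sum(pat_big$counts), frame_total(big))

  # single photon lands in exactly the bin containing its q
  a <- array(0, c(10, 8, 8)); a[4, 6, 2] <- 1
  one <- detector_frame(a, ax)
  p1 <- reduce_to_pattern(one, geom, qe, c(-Inf, Inf))
  qhit <- momentum_transfer(energy_bin_centers(ax)[4],
                            pixel_scattering_angle(geom, 6, 2))
  expect_identical(sum(p1$counts), 1)
  expect_identical(which(p1$counts == 1),
                   findInterval(qhit, qe))
})

test_that("patterns over a tiling window partition sum to the full-range pattern", {
  set.seed(61)
  geom <- small_geometry()
  ax <- energy_axis(15, 1, 30)
  fr <- random_frame(ax, 8, 8, lambda = 3)
  qe <- default_q_edges(geom, 45)
  full <- reduce_to_pattern(fr, geom, qe, c(30, 45))
  parts <- lapply(partition_windows(energy_window_spec(30, 45, 5, 5)),
                  function(w) reduce_to_pattern(fr, geom, qe, w)$counts)
  expect_identical(Reduce(`+`, parts), full$counts)

  # ascending windows reach strictly higher maximum q
  reach <- vapply(list(c(30, 35), c(35, 40), c(40, 45)), function(w)
    max_attainable_q(geom, w[2] - 0.5), numeric(1))
  expect_true(all(diff(reach) > 0))
})

test_that("detector images sum windows per pixel and respect additivity", {
  ax <- small_axis()
  zero <- detector_frame(array(0, c(10, 8, 8)), ax)
  expect_identical(detector_image(zero, c(-Inf, Inf)), matrix(0, 8, 8))

  a <- array(0, c(10, 8, 8)); a[4, 3, 5] <- 1   # center 35.25 keV
  one <- detector_frame(a, ax)
  img <- detector_image(one, c(30, 40))
  expect_identical(img[3, 5], 1)
  expect_identical(sum(img), 1)
  expect_identical(sum(detector_image(one, c(40, 50))), 0)

  set.seed(71)
  fr <- random_frame(energy_axis(15, 1, 30), 8, 8)
  tiles <- lapply(partition_windows(energy_window_spec(30, 45, 5, 5)),
                  function(w) detector_image(fr, w))
  expect_identical(Reduce(`+`, tiles), detector_image(fr, c(30, 45)))
})
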