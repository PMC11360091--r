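test_that("frames round-trip exactly through the native format", {
  dir <- withr::local_tempdir()

  # zero frame
  z <- detector_frame(array(0, c(200, 8, 8)), energy_axis(200, 1, 0))
  p <- save_frame(z, file.path(dir, "zero"))
  expect_true(file.exists(p) && file.exists(sub("bin$", "json", p)))
  rz <- load_frame(p)
  expect_identical(frame_total(rz), 0)
  expect_identical(rz$energy_axis$n_bins, 200L)

  # a single count in a specific (k, i, j) cell survives the round trip
  a <- array(0, c(40, 12, 15))
  a[36, 11, 8] <- 1
  f1 <- detector_frame(a, energy_axis(40, 1, 0), provenance = "single")
  r1 <- load_frame(save_frame(f1, file.path(dir, "one")))
  expect_identical(r1$counts, f1$counts)
  expect_identical(r1$provenance, "single")
  expect_true(r1$is_raw)

  # saving is deterministic byte-for-byte
  p2 <- save_frame(f1, file.path(dir, "one_again"))
  expect_identical(readBin(p2, "raw", file.size(p2)),
                   readBin(file.path(dir, "one.bin"), "raw",
                           file.size(file.path(dir, "one.bin"))))

  # property check: seeded random frames round-trip exactly, raw and
  # corrected alike
  set.seed(3)
  for (rep in 1:20) {
    fr <- random_frame(energy_axis(sample(3:12, 1), runif(1, 0.5, 2),
                                   runif(1, 0, 30)),
                       n_rows = sample(2:9, 1), n_cols = sample(2:9, 1))
    if (rep %% 2 == 0)
      fr <- detector_frame(fr$counts - 0.5, fr$energy_axis, is_raw = FALSE)
    back <- load_frame(save_frame(fr, file.path(dir, sprintf("r%02d", rep))))
    expect_identical(back$counts, fr$counts)
    expect_identical(back$energy_axis, fr$energy_axis)
    expect_identical(back$is_raw, fr$is_raw)
  }
})

test_that("frame loading validates existence, shape, and rawness", {
  dir <- withr::local_tempdir()
  expect_error(load_frame(file.path(dir, "nope.bin")), "not found")

  f <- detector_frame(array(1, c(4, 3, 2)), energy_axis(4, 1, 0))
  p <- save_frame(f, file.path(dir, "f"))

  # sidecar declaring the wrong shape names both shapes
  side <- sub("bin$", "json", p)
  meta <- jsonlite::fromJSON(side)
  meta$n_rows <- 5
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE), side)
  expect_error(load_frame(p), "24 values.*4 x 5 x 2")

  # negative counts in a file marked raw are rejected
  g <- detector_frame(array(-1, c(2, 2, 2)), energy_axis(2, 1, 0),
                      is_raw = FALSE)
  pg <- save_frame(g, file.path(dir, "neg"))
  sideg <- sub("bin$", "json", pg)
  metag <- jsonlite::fromJSON(sideg)
  metag$is_raw <- TRUE
  writeLines(jsonlite::toJSON(metag, auto_unbox = TRUE), sideg)
  expect_error(load_frame(pg), "negative")
})

test_that("scan folders load in natural-sort order", {
  expect_identical(natural_order(c("a_1", "a_10", "a_2")), c(1L, 3L, 2L))
  expect_identical(natural_order(c("pos_2", "pos_10", "pos_1")),
                   c(3L, 1L, 2L))

  dir <- withr::local_tempdir()
  expect_error(load_scan_folder(dir), "no frame files")

  ax <- energy_axis(3, 1, 0)
  for (nm in c("pos_1", "pos_10", "pos_2", "pos_3")) {
    a <- array(0, c(3, 2, 2)); a[1, 1, 1] <- nchar(nm)  # distinguishable
    save_frame(detector_frame(a, ax, provenance = nm), file.path(dir, nm))
  }
  frames <- load_scan_folder(dir)
  expect_length(frames, 4)
  expect_identical(vapply(frames, `[[`, "", "provenance"),
                   c("pos_1", "pos_2", "pos_3", "pos_10"))

  # single file folder
  dir2 <- withr::local_tempdir()
  save_frame(detector_frame(array(0, c(3, 2, 2)), ax), file.path(dir2, "only"))
  expect_length(load_scan_folder(dir2), 1)

  # an unreadable member aborts with its name
  file.remove(file.path(dir, "pos_2.json"))
  expect_error(load_scan_folder(dir), "pos_2")
})

test_that("pattern export writes full-precision CSV that re-parses exactly", {
  dir <- withr::local_tempdir()
  p3 <- scattering_pattern(c(0, 1, 2, 3), c(0, 1, 2), c(30, 45))
  path <- export_pattern(p3, file.path(dir, "p3.csv"))
  lines <- readLines(path)
  expect_identical(lines[1], "q_nm_inv,counts")
  expect_length(lines, 4)            # header + one row per bin

  # irrational counts round-trip to double precision
  pat <- scattering_pattern(seq(0, 2, by = 0.1), sqrt(2) * (1:20), c(30, 45))
  back <- read_pattern_csv(export_pattern(pat, file.path(dir, "pi.csv")))
  expect_equal(back$counts, pat$counts, tolerance = 1e-12)
  expect_equal(back$q_nm_inv, pattern_q_centers(pat), tolerance = 1e-12)
})

test_that("exported pattern from a ring simulation peaks at the injected q", {
  setup <- recovery_setup()
  fr <- simulate_frame(setup$geom, setup$axis, setup$spectrum,
                       list(ring_spec(8.4, 0.15, 8000)), seed = 5)
  pat <- reduce_to_pattern(fr, setup$geom, setup$q_edges, c(30, 45))
  dir <- withr::local_tempdir()
  tab <- read_pattern_csv(export_pattern(pat, file.path(dir, "ring.csv")))
  expect_lt(abs(tab$q_nm_inv[which.max(tab$counts)] - 8.4), 0.1 + 1e-9)
})
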