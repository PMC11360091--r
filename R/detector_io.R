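# Frame and pattern I/O.
#
# Native frame format: <name>.bin + <name>.json sidecar.
#   * .bin  — the 3D count array as IEEE-754 float64, little endian,
#     C order with axis order energy -> row -> col (column index varies
#     fastest). Counts are integer-valued for raw frames and stored
#     exactly (double precision is exact up to 2^53).
#   * .json — {n_bins, bin_width_keV, offset_keV, n_rows, n_cols, is_raw,
#     provenance, exposure_s}.
# The layout is deliberately open and minimal so that data from any
# detector whose per-pixel spectra fit a 3D array can be converted to it.

sidecar_path <- function(path) {
  sub("\\.bin$", ".json", path)
}

norm_frame_path <- function(path) {
  if (!grepl("\\.bin$", path)) path <- paste0(path, ".bin")
  path
}

#' Save a detector frame
#'
#' Writes the native two-file format (see the package format notes):
#' `<name>.bin` holding the count array as little-endian float64 in C
#' order (energy, row, col), plus a `<name>.json` sidecar with the energy
#' axis and flags. Writing is deterministic: identical frames produce
#' identical bytes.
#'
#' @param frame A [detector_frame()].
#' @param path Destination path; `.bin` is appended if absent.
#' @return The `.bin` path, invisibly.
#' @export
save_frame <- function(frame, path) {
  stopifnot(inherits(frame, "detector_frame"))
  path <- norm_frame_path(path)
  d <- dim(frame$counts)
  ax <- frame$energy_axis
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot write frame file: ", path))
  on.exit(close(con), add = TRUE)
  # C order (k, i, j) = column index fastest: permute so R's column-major
  # serialization emits j, then i, then k slowest.
  writeBin(as.vector(aperm(frame$counts, c(3L, 2L, 1L))), con,
           size = 8L, endian = "little")
  # the sidecar is emitted by hand at %.17g so axis parameters round-trip
  # bit-exactly (generic JSON writers truncate to 15 significant digits)
  jstr <- function(s) paste0("\"", gsub("\"", "\\\\\"", s), "\"")
  writeLines(paste0(
    "{\n",
    "  \"format\": \"ssaxs-frame-v1\",\n",
    "  \"n_bins\": ", ax$n_bins, ",\n",
    "  \"bin_width_keV\": ", fmt_full(ax$bin_width_keV), ",\n",
    "  \"offset_keV\": ", fmt_full(ax$offset_keV), ",\n",
    "  \"n_rows\": ", d[2], ",\n",
    "  \"n_cols\": ", d[3], ",\n",
    "  \"is_raw\": ", tolower(frame$is_raw), ",\n",
    "  \"provenance\": ", jstr(frame$provenance), ",\n",
    "  \"exposure_s\": ",
    if (is.null(frame$exposure_s)) "null" else fmt_full(frame$exposure_s),
    "\n}"), sidecar_path(path))
  invisible(path)
}

#' Load a detector frame
#'
#' Reads the native `.bin` + `.json` format written by [save_frame()].
#' A load/save round trip reproduces counts, energy-axis parameters and
#' the raw flag exactly.
#'
#' @param path Path to the `.bin` file (the `.json` sidecar must sit next
#'   to it); `.bin` is appended if absent.
#' @return A [detector_frame()].
#' @export
load_frame <- function(path) {
  path <- norm_frame_path(path)
  side <- sidecar_path(path)
  if (!file.exists(path)) stop("frame file not found: ", path)
  if (!file.exists(side)) stop("frame sidecar not found: ", side)
  meta <- tryCatch(jsonlite::fromJSON(side),
                   error = function(e)
                     stop("corrupt frame sidecar ", side, ": ",
                          conditionMessage(e)))
  need <- c("n_bins", "bin_width_keV", "offset_keV", "n_rows", "n_cols",
            "is_raw")
  if (!all(need %in% names(meta)))
    stop("frame sidecar ", side, " is missing fields: ",
         paste(setdiff(need, names(meta)), collapse = ", "))
  n_expect <- as.numeric(meta$n_bins) * as.numeric(meta$n_rows) *
    as.numeric(meta$n_cols)
  n_bytes <- file.info(path)$size
  if (n_bytes != 8 * n_expect)
    stop(sprintf(
      "frame %s holds %d values but sidecar declares %d x %d x %d = %d",
      path, n_bytes %/% 8, meta$n_bins, meta$n_rows, meta$n_cols,
      as.integer(n_expect)))
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  raw_vec <- readBin(con, what = "double", n = n_expect, size = 8L,
                     endian = "little")
  if (length(raw_vec) != n_expect)
    stop("truncated frame file: ", path)
  counts <- aperm(array(raw_vec,
                        dim = c(meta$n_cols, meta$n_rows, meta$n_bins)),
                  c(3L, 2L, 1L))
  axis <- energy_axis(meta$n_bins, meta$bin_width_keV, meta$offset_keV)
  if (isTRUE(meta$is_raw) && any(counts < 0))
    stop("file marked raw contains negative counts: ", path)
  detector_frame(counts, axis, is_raw = isTRUE(meta$is_raw),
                 provenance = if (is.null(meta$provenance)) "" else meta$provenance,
                 exposure_s = meta$exposure_s)
}

#' Natural-sort order of character strings
#'
#' Orders strings so that embedded integers compare numerically:
#' `"pos_2"` precedes `"pos_10"`. Ties on the numeric key fall back to
#' plain lexicographic order, making the order total and independent of
#' how the filesystem enumerates files.
#'
#' @param x Character vector.
#' @return Integer permutation ordering `x`.
#' @export
natural_order <- function(x) {
  key <- vapply(x, function(s) {
    m <- gregexpr("\\d+", s)
    regmatches(s, m) <- lapply(regmatches(s, m), function(v)
      formatC(sub("^0+(?=\\d)", "", v, perl = TRUE), width = 24, flag = "0"))
    s
  }, character(1), USE.NAMES = FALSE)
  order(key, x, method = "radix")
}

#' Load a folder of raster-scan measurements
#'
#' Reads every frame file in `folder` and returns the frames in
#' natural-sort order of filename, the order in which raster positions
#' are conventionally numbered. Any unreadable member aborts the load
#' with an error naming the file; nothing is skipped silently.
#'
#' @param folder Directory containing `.bin` + `.json` frame pairs.
#' @return List of [detector_frame()] objects, natural-sorted by name.
#' @export
load_scan_folder <- function(folder) {
  if (!dir.exists(folder)) stop("scan folder not found: ", folder)
  files <- list.files(folder, pattern = "\\.bin$", full.names = TRUE)
  if (length(files) == 0L)
    stop("scan folder contains no frame files: ", folder)
  files <- files[natural_order(basename(files))]
  lapply(files, function(f)
    tryCatch(load_frame(f),
             error = function(e)
               stop("failed to load scan member ", f, ": ",
                    conditionMessage(e), call. = FALSE)))
}

fmt_full <- function(x) {
  # shortest decimal round-tripping a double (>= 9 significant digits
  # required by the pattern export contract; %.17g guarantees exactness)
  sub("^-0$", "0", sprintf("%.17g", x))
}

#' Export a 1D scattering pattern to CSV
#'
#' Writes one data row per q bin: the bin-center momentum transfer in
#' nm^-1 and the summed counts, at full double precision.
#'
#' @param pattern A [scattering_pattern()].
#' @param path Destination `.csv` path.
#' @return `path`, invisibly.
#' @export
export_pattern <- function(pattern, path) {
  stopifnot(inherits(pattern, "scattering_pattern"))
  centers <- pattern_q_centers(pattern)
  lines <- c("q_nm_inv,counts",
             paste(vapply(centers, fmt_full, character(1)),
                   vapply(pattern$counts, fmt_full, character(1)),
                   sep = ","))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("cannot write pattern file: ", path)
  invisible(path)
}

#' Read back a pattern CSV written by [export_pattern()]
#'
#' @param path Path to the CSV file.
#' @return Data frame with columns `q_nm_inv` and `counts`.
#' @export
read_pattern_csv <- function(path) {
  if (!file.exists(path)) stop("pattern file not found: ", path)
  utils::read.csv(path, colClasses = "numeric")
}

#' Export a scan map to CSV
#'
#' Writes the area-under-peak matrix as a headerless CSV with one row per
#' scan row, at full double precision.
#'
#' @param map A [scan_map()].
#' @param path Destination `.csv` path.
#' @return `path`, invisibly.
#' @export
export_map <- function(map, path) {
  stopifnot(inherits(map, "scan_map"))
  lines <- apply(map$values, 1L, function(r)
    paste(vapply(r, fmt_full, character(1)), collapse = ","))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("cannot write map file: ", path)
  invisible(path)
}
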