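# File I/O. The package's native container is a plain-text single file:
# a short header (format tag, JSON metadata, grid, pixel size), the
# wavenumber axis, then one line per channel with n pixel values, all numbers
# printed with 17 significant digits so that the double -> text -> double
# round trip is exact.

fmt_num <- function(x) sprintf("%.17g", x)

CONTAINER_TAG <- "ramanmark-map 1"

write_map_container <- function(map, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(CONTAINER_TAG, con)
  writeLines(paste0("meta\t", jsonlite::toJSON(map$meta, auto_unbox = TRUE)),
             con)
  writeLines(paste("grid", map$n_rows, map$n_cols, sep = "\t"), con)
  writeLines(paste("pixel_size_um", fmt_num(map$pixel_size_um[1]),
                   fmt_num(map$pixel_size_um[2]), sep = "\t"), con)
  writeLines(paste0("wavenumber\t",
                    paste(fmt_num(map$wavenumber), collapse = " ")), con)
  writeLines("data", con)
  writeLines(apply(map$data, 1, function(r) paste(fmt_num(r), collapse = " ")),
             con)
}

read_map_container <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 6L || lines[1] != CONTAINER_TAG) {
    rm_abort(sprintf("'%s' is not a ramanmark map container", path),
             "bad_container")
  }
  fields <- list()
  i <- 2L
  while (i <= length(lines) && lines[i] != "data") {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    fields[[parts[1]]] <- parts[-1]
    i <- i + 1L
  }
  if (is.null(fields$wavenumber)) {
    rm_abort("container has no wavenumber axis record", "missing_axis")
  }
  if (i > length(lines)) rm_abort("container has no data section",
                                  "bad_container")
  axis <- as.numeric(strsplit(fields$wavenumber, " ", fixed = TRUE)[[1]])
  grid <- as.integer(fields$grid)
  px <- as.numeric(fields$pixel_size_um)
  meta <- jsonlite::fromJSON(paste(fields$meta, collapse = "\t"))
  data_lines <- lines[(i + 1L):length(lines)]
  if (length(data_lines) != length(axis)) {
    rm_abort(sprintf("container has %d data rows but %d axis channels",
                     length(data_lines), length(axis)), "channel_mismatch")
  }
  vals <- scan(text = data_lines, quiet = TRUE)
  data <- matrix(vals, nrow = length(axis), byrow = TRUE)
  raman_map(axis, data, grid[1], grid[2], px, meta)
}

write_map_csv <- function(map, path) {
  rows <- rep(seq_len(map$n_rows), each = map$n_cols)
  cols <- rep(seq_len(map$n_cols), times = map$n_rows)
  header <- paste(c("row", "col", fmt_num(map$wavenumber)), collapse = ",")
  body <- vapply(seq_len(ncol(map$data)), function(p) {
    paste(c(rows[p], cols[p], fmt_num(map$data[, p])), collapse = ",")
  }, character(1))
  writeLines(c(header, body), path)
}

read_map_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) rm_abort("CSV map needs a header and pixels",
                                   "bad_container")
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (length(header) < 4L || header[1] != "row" || header[2] != "col") {
    rm_abort("CSV map header must be row,col,<wavenumbers>", "missing_axis")
  }
  axis <- suppressWarnings(as.numeric(header[-(1:2)]))
  if (anyNA(axis)) rm_abort("CSV map header wavenumbers are not numeric",
                            "missing_axis")
  m <- length(axis)
  cells <- strsplit(lines[-1], ",", fixed = TRUE)
  nvals <- lengths(cells)
  if (any(nvals != m + 2L)) {
    rm_abort(sprintf(
      "CSV pixel rows have %s values but the header has %d wavenumbers",
      paste(unique(nvals - 2L), collapse = "/"), m), "channel_mismatch")
  }
  tab <- matrix(as.numeric(unlist(cells)), ncol = m + 2L, byrow = TRUE)
  rows <- as.integer(tab[, 1]); cols <- as.integer(tab[, 2])
  n_rows <- max(rows); n_cols <- max(cols)
  data <- matrix(NA_real_, m, n_rows * n_cols)
  data[, (rows - 1L) * n_cols + cols] <- t(tab[, -(1:2), drop = FALSE])
  if (anyNA(data)) rm_abort("CSV map does not cover the full pixel grid",
                            "grid_mismatch")
  raman_map(axis, data, n_rows, n_cols)
}

#' Write a hyperspectral map to disk
#'
#' Two explicit formats are supported (never sniffed from the file name):
#' `container`, the package's lossless plain-text container carrying data,
#' grid, pixel size and metadata; and `csv`, a `row,col,<wavenumbers>` table
#' with one pixel per row (no metadata).
#'
#' @param map A `raman_map`.
#' @param path Output file path.
#' @param format `"container"` or `"csv"`.
#' @return Invisibly, `path`.
#' @seealso [read_map()]
#' @export
write_map <- function(map, path, format = c("container", "csv")) {
  format <- match.arg(format)
  if (!inherits(map, "raman_map")) rm_abort("map must be a raman_map",
                                            "bad_input")
  dir <- dirname(path)
  if (!dir.exists(dir)) rm_abort(sprintf("directory '%s' does not exist", dir),
                                 "unwritable_path")
  switch(format,
         container = write_map_container(map, path),
         csv = write_map_csv(map, path))
  invisible(path)
}

#' Read a hyperspectral map from disk
#'
#' @param path File produced by [write_map()].
#' @param format `"container"` or `"csv"` (explicit; formats are never
#'   sniffed).
#' @return A validated `raman_map`. CSV carries no metadata, so metadata
#'   fields default to `"n/a"`.
#' @export
read_map <- function(path, format = c("container", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) rm_abort(sprintf("file '%s' not found", path),
                                   "missing_file")
  switch(format,
         container = read_map_container(path),
         csv = read_map_csv(path))
}

#' Read a two-column spectrum table
#'
#' Plain text, whitespace- or comma-delimited, two numeric columns
#' (wavenumber, intensity); lines starting with `#` are ignored.
#'
#' @param path File path.
#' @return A `raman_spectrum`.
#' @export
read_spectrum_table <- function(path) {
  if (!file.exists(path)) rm_abort(sprintf("file '%s' not found", path),
                                   "missing_file")
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 2L) {
    rm_abort("a spectrum table needs at least 2 data rows", "axis_too_short")
  }
  parts <- strsplit(gsub(",", " ", lines, fixed = TRUE), "[[:space:]]+")
  if (any(lengths(parts) != 2L)) {
    rm_abort("spectrum table rows must have exactly 2 values",
             "bad_table_row")
  }
  vals <- suppressWarnings(as.numeric(unlist(parts)))
  if (anyNA(vals)) rm_abort("spectrum table contains non-numeric values",
                            "bad_table_row")
  tab <- matrix(vals, ncol = 2L, byrow = TRUE)
  raman_spectrum(tab[, 1], tab[, 2])
}

#' Write a two-column spectrum table
#'
#' @param spectrum A `raman_spectrum`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_spectrum_table <- function(spectrum, path) {
  if (!inherits(spectrum, "raman_spectrum")) {
    rm_abort("spectrum must be a raman_spectrum", "bad_input")
  }
  writeLines(c("# wavenumber_cm1 intensity",
               paste(fmt_num(spectrum$wavenumber),
                     fmt_num(spectrum$intensity))), path)
  invisible(path)
}
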