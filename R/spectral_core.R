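#' Validate a wavenumber axis
#'
#' A wavenumber axis is a strictly increasing, finite numeric vector of Raman
#' shifts in cm^-1 with at least two channels. Most biomolecular work uses the
#' fingerprint region, 400-1800 cm^-1.
#'
#' @param values Numeric vector of Raman shifts (cm^-1).
#' @return The validated numeric vector (invisibly usable as an axis).
#' @export
wavenumber_axis <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    rm_abort("a wavenumber axis needs at least 2 channels", "axis_too_short")
  }
  check_finite(values, "wavenumber axis")
  if (any(diff(values) <= 0)) {
    rm_abort("wavenumber axis must be strictly increasing",
             "axis_not_increasing")
  }
  values
}

#' Construct a single Raman spectrum
#'
#' @param wavenumber Wavenumber axis (cm^-1), strictly increasing.
#' @param intensity Non-negative intensities (arbitrary counts), one per
#'   channel.
#' @return An object of class `raman_spectrum` with fields `wavenumber` and
#'   `intensity`.
#' @export
raman_spectrum <- function(wavenumber, intensity) {
  wavenumber <- wavenumber_axis(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(intensity) != length(wavenumber)) {
    rm_abort(sprintf("intensity has %d values but axis has %d channels",
                     length(intensity), length(wavenumber)),
             "channel_mismatch")
  }
  check_finite(intensity, "spectrum intensity")
  structure(list(wavenumber = wavenumber, intensity = intensity),
            class = "raman_spectrum")
}

map_meta_defaults <- function(meta = list()) {
  defaults <- list(group = "n/a", region = "n/a", species = "n/a",
                   animal_id = "n/a", scan_kind = "n/a")
  for (nm in names(meta)) {
    if (!is.null(meta[[nm]])) defaults[[nm]] <- as.character(meta[[nm]])
  }
  ok_region <- c("ascending", "descending", "n/a")
  if (!defaults$region %in% ok_region) {
    rm_abort(sprintf("region must be one of %s",
                     paste(ok_region, collapse = ", ")), "bad_metadata")
  }
  ok_scan <- c("large_area", "high_res", "n/a")
  if (!defaults$scan_kind %in% ok_scan) {
    rm_abort(sprintf("scan_kind must be one of %s",
                     paste(ok_scan, collapse = ", ")), "bad_metadata")
  }
  defaults
}

#' Construct a hyperspectral Raman map
#'
#' A map holds one spectrum per pixel of a rectangular scan. Pixels are
#' linearized row-major from the top-left pixel: the pixel at (row r, col c)
#' of an `n_rows` x `n_cols` grid is column `(r - 1) * n_cols + c` of `data`.
#'
#' @param wavenumber Shared wavenumber axis (m channels, cm^-1).
#' @param data Numeric matrix, m channels x n pixels (n = n_rows * n_cols).
#' @param n_rows,n_cols Pixel grid dimensions.
#' @param pixel_size_um Numeric length-2, pixel size (dy, dx) in micrometres.
#' @param meta Named list of metadata: `group`, `region` (`ascending`,
#'   `descending` or `n/a`), `species`, `animal_id`, `scan_kind`
#'   (`large_area`, `high_res` or `n/a`). Missing entries default to "n/a".
#' @return An object of class `raman_map`.
#' @export
raman_map <- function(wavenumber, data, n_rows, n_cols,
                      pixel_size_um = c(1, 1), meta = list()) {
  wavenumber <- wavenumber_axis(wavenumber)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) {
    rm_abort("grid dimensions must be >= 1", "bad_grid")
  }
  if (nrow(data) != length(wavenumber)) {
    rm_abort(sprintf("data has %d channels but axis has %d",
                     nrow(data), length(wavenumber)), "channel_mismatch")
  }
  if (ncol(data) != n_rows * n_cols) {
    rm_abort(sprintf("data has %d pixels but grid is %d x %d = %d",
                     ncol(data), n_rows, n_cols, n_rows * n_cols),
             "grid_mismatch")
  }
  check_finite(data, "map data")
  pixel_size_um <- as.numeric(pixel_size_um)
  if (length(pixel_size_um) != 2L || any(!is.finite(pixel_size_um)) ||
      any(pixel_size_um <= 0)) {
    rm_abort("pixel_size_um must be two positive numbers (dy, dx)",
             "bad_grid")
  }
  structure(list(wavenumber = wavenumber, data = data,
                 n_rows = n_rows, n_cols = n_cols,
                 pixel_size_um = pixel_size_um,
                 meta = map_meta_defaults(meta)),
            class = "raman_map")
}

#' @export
print.raman_map <- function(x, ...) {
  cat(sprintf(
    "<raman_map> %d x %d pixels (%g x %g um), %d channels [%g, %g] cm-1\n",
    x$n_rows, x$n_cols, x$pixel_size_um[1], x$pixel_size_um[2],
    length(x$wavenumber), min(x$wavenumber), max(x$wavenumber)))
  cat(sprintf("  group=%s region=%s species=%s animal=%s scan=%s\n",
              x$meta$group, x$meta$region, x$meta$species, x$meta$animal_id,
              x$meta$scan_kind))
  invisible(x)
}

#' Linear pixel index of a (row, col) position
#'
#' Row-major from the top-left pixel, matching the column order of
#' `raman_map$data`.
#'
#' @param map A `raman_map` (or any list with `n_rows`, `n_cols`).
#' @param row,col 1-based pixel coordinates.
#' @return Integer linear index into the pixel columns.
#' @export
pixel_index <- function(map, row, col) {
  (as.integer(row) - 1L) * map$n_cols + as.integer(col)
}

#' Construct a named set of component spectra
#'
#' Columns of `spectra` are the component spectra W (m x k). By convention
#' every column is rescaled to maximum 1; the physical scale lives in the
#' abundances. This fixes the W.H scale indeterminacy once, globally.
#'
#' @param wavenumber Wavenumber axis shared by all components.
#' @param spectra Non-negative m x k matrix; column j is component j.
#' @param names Unique component names (length k).
#' @param fixed Logical length k: components held fixed during fitting
#'   (reference signatures). Default all `TRUE`.
#' @return An object of class `component_set`.
#' @export
component_set <- function(wavenumber, spectra, names,
                          fixed = rep(TRUE, ncol(spectra))) {
  wavenumber <- wavenumber_axis(wavenumber)
  spectra <- as.matrix(spectra)
  storage.mode(spectra) <- "double"
  if (nrow(spectra) != length(wavenumber)) {
    rm_abort("component spectra and axis channel counts differ",
             "channel_mismatch")
  }
  check_finite(spectra, "component spectra")
  if (any(spectra < 0)) {
    rm_abort("component spectra must be non-negative", "negative_values")
  }
  names <- as.character(names)
  if (length(names) != ncol(spectra) || anyDuplicated(names)) {
    rm_abort("component names must be unique, one per column", "bad_names")
  }
  mx <- apply(spectra, 2, max)
  if (any(mx == 0)) {
    rm_abort("component spectra must not be all-zero", "zero_component")
  }
  spectra <- sweep(spectra, 2, mx, "/")
  colnames(spectra) <- names
  fixed <- as.logical(fixed)
  if (length(fixed) == 1L) fixed <- rep(fixed, ncol(spectra))
  if (length(fixed) != ncol(spectra) || anyNA(fixed)) {
    rm_abort("fixed mask must be logical, one per component", "bad_names")
  }
  structure(list(wavenumber = wavenumber, spectra = spectra,
                 names = names, fixed = fixed),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("<component_set> %d components, %d channels\n",
              length(x$names), length(x$wavenumber)))
  cat(" ", paste0(x$names, ifelse(x$fixed, " [fixed]", ""), collapse = ", "),
      "\n")
  invisible(x)
}

#' Construct a stack of per-component abundance heatmaps
#'
#' @param names Component names (length k).
#' @param maps 3-d array (n_rows, n_cols, k) of non-negative abundances, or a
#'   list of k matrices.
#' @return An object of class `abundance_stack`.
#' @export
abundance_stack <- function(names, maps) {
  if (is.list(maps)) {
    dims <- dim(maps[[1]])
    maps <- array(unlist(maps), dim = c(dims, length(maps)))
  }
  if (length(dim(maps)) != 3L) {
    rm_abort("maps must be an (n_rows, n_cols, k) array", "bad_stack")
  }
  names <- as.character(names)
  if (dim(maps)[3] != length(names) || anyDuplicated(names)) {
    rm_abort("need one unique name per heatmap", "bad_names")
  }
  check_finite(maps, "abundance maps")
  if (any(maps < 0)) rm_abort("abundances must be non-negative",
                              "negative_values")
  dimnames(maps) <- list(NULL, NULL, names)
  structure(list(names = names, maps = maps), class = "abundance_stack")
}

#' Convert an abundance stack to an H matrix (k x n, row-major pixels)
#'
#' Inverse of [stack_from_h()]; the pixel order matches `raman_map$data`.
#'
#' @param stack An `abundance_stack`.
#' @return k x n numeric matrix with component names as rownames.
#' @export
stack_to_h <- function(stack) {
  d <- dim(stack$maps)
  k <- d[3]
  H <- matrix(0, k, d[1] * d[2], dimnames = list(stack$names, NULL))
  for (j in seq_len(k)) {
    H[j, ] <- as.vector(t(stack$maps[, , j]))  # row-major linearization
  }
  H
}

#' Reshape an H matrix into an abundance stack
#'
#' @param H k x n matrix of non-negative abundances, pixels row-major.
#' @param n_rows,n_cols Target grid.
#' @param names Component names; defaults to `rownames(H)`.
#' @return An `abundance_stack`.
#' @export
stack_from_h <- function(H, n_rows, n_cols, names = rownames(H)) {
  if (is.null(names)) names <- paste0("component_", seq_len(nrow(H)))
  if (ncol(H) != n_rows * n_cols) {
    rm_abort("H column count does not match the grid", "grid_mismatch")
  }
  maps <- array(0, dim = c(n_rows, n_cols, nrow(H)))
  for (j in seq_len(nrow(H))) {
    maps[, , j] <- matrix(H[j, ], n_rows, n_cols, byrow = TRUE)
  }
  abundance_stack(names, maps)
}

#' Construct a labelled spectral dataset
#'
#' Holds single spectra (rows) extracted from one or more maps, with the
#' per-spectrum labels the downstream statistics need.
#'
#' @param wavenumber Shared axis.
#' @param spectra n_s x m matrix, one spectrum per row.
#' @param labels data.frame with n_s rows; columns `group`, `region`,
#'   `species`, `animal_id`, `component` (missing ones are filled with "n/a").
#' @return An object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(wavenumber, spectra, labels) {
  wavenumber <- wavenumber_axis(wavenumber)
  spectra <- as.matrix(spectra)
  storage.mode(spectra) <- "double"
  if (ncol(spectra) != length(wavenumber)) {
    rm_abort("spectra and axis channel counts differ", "channel_mismatch")
  }
  if (nrow(spectra) < 1L) rm_abort("dataset needs at least one spectrum",
                                   "empty_dataset")
  check_finite(spectra, "dataset spectra")
  labels <- as.data.frame(labels, stringsAsFactors = FALSE)
  if (nrow(labels) != nrow(spectra)) {
    rm_abort("labels must have one row per spectrum", "bad_labels")
  }
  for (nm in c("group", "region", "species", "animal_id", "component")) {
    if (is.null(labels[[nm]])) labels[[nm]] <- "n/a"
    labels[[nm]] <- as.character(labels[[nm]])
  }
  structure(list(wavenumber = wavenumber, spectra = spectra,
                 labels = labels),
            class = "spectral_dataset")
}

#' Concatenate spectral datasets sharing an axis
#'
#' @param ... `spectral_dataset` objects on identical axes.
#' @return A single `spectral_dataset`.
#' @export
bind_datasets <- function(...) {
  ds <- list(...)
  if (length(ds) == 1L && is.list(ds[[1]]) &&
      !inherits(ds[[1]], "spectral_dataset")) ds <- ds[[1]]
  ax <- ds[[1]]$wavenumber
  for (d in ds) {
    if (!isTRUE(all.equal(d$wavenumber, ax))) {
      rm_abort("datasets are on different axes", "axis_mismatch")
    }
  }
  spectral_dataset(ax, do.call(rbind, lapply(ds, `[[`, "spectra")),
                   do.call(rbind, lapply(ds, `[[`, "labels")))
}

axes_equal <- function(a, b, tol = 1e-9) {
  length(a) == length(b) && all(abs(a - b) <= tol * pmax(1, abs(a)))
}
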