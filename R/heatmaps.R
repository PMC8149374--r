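# False-color rendering of abundance heatmaps. Each component name has a
# fixed color so the same structure is always drawn in the same color.

component_colors <- c(
  elastic_fiber = "#00c800", collagen_fiber = "#d00000", nuclei = "#0040ff",
  aggrecan = "#e6c800", versican = "#ff64c8", lipid = "#ff8000",
  residual_ecm = "#00c8c8", ce1_like = "#ff9616", cc6_like = "#ff6416",
  human_matrix = "#9664ff")

color_for_component <- function(name) {
  if (name %in% names(component_colors)) return(component_colors[[name]])
  palette <- c("#66c2a5", "#fc8d62", "#8da0cb", "#e78ac3", "#a6d854",
               "#ffd92f", "#e5c494", "#b3b3b3")
  idx <- sum(utf8ToInt(name)) %% length(palette) + 1
  palette[idx]
}

#' Find the local band maximum near an expected center
#'
#' Returns the wavenumber of the maximum intensity within
#' `center +/- window` — the standard way to read a band position off a
#' fitted component spectrum.
#'
#' @param x A `raman_spectrum`, or a numeric intensity vector (then supply
#'   `wavenumber`).
#' @param center Expected band center (cm^-1).
#' @param window Half-width of the search window (cm^-1).
#' @param wavenumber Axis when `x` is a bare vector.
#' @return Wavenumber (cm^-1) of the local maximum.
#' @export
find_band_center <- function(x, center, window = 20, wavenumber = NULL) {
  if (inherits(x, "raman_spectrum")) {
    wavenumber <- x$wavenumber
    x <- x$intensity
  }
  sel <- which(wavenumber >= center - window & wavenumber <= center + window)
  if (!length(sel)) rm_abort("search window outside the axis",
                             "bad_parameter")
  wavenumber[sel[which.max(x[sel])]]
}

#' Render abundance heatmaps to PNG images and CSV matrices
#'
#' One image and one CSV per component; the colormap is fixed per component
#' name. An all-zero heatmap renders as a uniform black image.
#'
#' @param stack An `abundance_stack`.
#' @param out_dir Output directory (created if missing).
#' @param prefix Optional file-name prefix.
#' @return Invisibly, a data.frame listing the files written.
#' @export
render_heatmaps <- function(stack, out_dir, prefix = "") {
  stopifnot(inherits(stack, "abundance_stack"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- lapply(seq_along(stack$names), function(j) {
    nm <- stack$names[j]
    h <- stack$maps[, , j]
    mx <- max(h)
    v <- if (mx > 0) h / mx else h
    rgb <- grDevices::col2rgb(color_for_component(nm)) / 255
    img <- array(0, dim = c(nrow(h), ncol(h), 3))
    for (ch in 1:3) img[, , ch] <- v * rgb[ch]
    stem <- file.path(out_dir, paste0(prefix, nm))
    png::writePNG(img, paste0(stem, ".png"))
    utils::write.csv(h, paste0(stem, ".csv"), row.names = FALSE)
    data.frame(component = nm, png = paste0(stem, ".png"),
               csv = paste0(stem, ".csv"), stringsAsFactors = FALSE)
  })
  invisible(do.call(rbind, files))
}
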