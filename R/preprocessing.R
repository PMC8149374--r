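# Preprocessing chain, order-fixed: cosmic-ray removal -> background
# subtraction -> fingerprint cropping -> total-intensity normalization.

#' Remove cosmic-ray spikes from a map
#'
#' Cosmic rays hit single detector channels, so a spike is a large deviation
#' of one channel from the running median of its pixel spectrum. Per pixel,
#' the detector computes the residual `r = y - runmed(y, window)` and flags
#' channels where `|r|` exceeds `z_threshold` robust SDs of the residuals.
#' The robust SD is floored at 10% of the smoothed-spectrum maximum so that
#' genuine Raman bands (whose residual under a short median filter is a
#' fraction of the band height) are never flagged, even on noiseless input.
#' Flagged channels are replaced by the median of the unflagged neighbors in
#' the window (one-sided at the spectrum edges).
#'
#' @param map A `raman_map`.
#' @param z_threshold Positive flagging threshold (robust z units).
#' @param window Odd window width in channels (>= 3).
#' @return List: `map` (cleaned `raman_map`), `n_spikes_removed` (flagged
#'   channel count over the whole map).
#' @export
remove_cosmic_rays <- function(map, z_threshold = 8, window = 5) {
  stopifnot(inherits(map, "raman_map"))
  if (z_threshold <= 0) rm_abort("z_threshold must be > 0", "bad_parameter")
  window <- as.integer(window)
  if (window < 3L) rm_abort("window must span at least 3 channels",
                            "bad_parameter")
  if (window %% 2L == 0L) window <- window + 1L
  data <- map$data
  m <- nrow(data)
  half <- window %/% 2L
  n_removed <- 0L
  for (p in seq_len(ncol(data))) {
    y <- data[, p]
    smooth <- stats::runmed(y, k = min(window, m - (1 - m %% 2)),
                            endrule = "median")
    r <- y - smooth
    scale <- max(1.4826 * stats::median(abs(r - stats::median(r))),
                 0.1 * max(smooth), .Machine$double.eps)
    flagged <- which(abs(r) > z_threshold * scale)
    if (length(flagged)) {
      n_removed <- n_removed + length(flagged)
      ok <- !(seq_len(m) %in% flagged)
      for (ch in flagged) {
        lo <- max(1L, ch - half); hi <- min(m, ch + half)
        nb <- y[lo:hi][ok[lo:hi]]
        if (!length(nb)) {          # widen until an unflagged neighbor exists
          w <- half
          while (!length(nb)) {
            w <- w + 1L
            lo <- max(1L, ch - w); hi <- min(m, ch + w)
            nb <- y[lo:hi][ok[lo:hi]]
          }
        }
        y[ch] <- stats::median(nb)
      }
      data[, p] <- y
    }
  }
  out <- map
  out$data <- data
  list(map = out, n_spikes_removed = n_removed)
}

#' Subtract the fluorescence background
#'
#' Asymmetric least squares (Whittaker smoother with asymmetric weights):
#' the baseline minimizes a weighted least-squares fit with a second
#' difference smoothness penalty `als_lambda`, where points above the current
#' baseline (peaks) get weight `als_p` and points below get `1 - als_p`.
#' Negative residuals after subtraction are clipped to 0 so downstream
#' non-negative factorizations stay well-posed.
#'
#' @param x A `raman_map` or `raman_spectrum`.
#' @param als_lambda Smoothness penalty (> 0); larger = stiffer baseline.
#' @param als_p Asymmetry in (0, 1); small values let peaks float above.
#' @param n_iter Reweighting iterations.
#' @return Same class as `x`, background-subtracted.
#' @export
subtract_baseline <- function(x, als_lambda = 1e5, als_p = 0.001,
                              n_iter = 10) {
  if (als_lambda <= 0 || als_p <= 0 || als_p >= 1 || n_iter < 1) {
    rm_abort("need als_lambda > 0, 0 < als_p < 1, n_iter >= 1",
             "bad_parameter")
  }
  if (inherits(x, "raman_spectrum")) {
    check_finite(x$intensity, "spectrum intensity")
    z <- als_baseline_cpp(matrix(x$intensity, ncol = 1), als_lambda, als_p,
                          as.integer(n_iter))
    return(raman_spectrum(x$wavenumber, pmax(x$intensity - z[, 1], 0)))
  }
  stopifnot(inherits(x, "raman_map"))
  check_finite(x$data, "map data")
  z <- als_baseline_cpp(x$data, als_lambda, als_p, as.integer(n_iter))
  out <- x
  out$data <- pmax(x$data - z, 0)
  out
}

#' Crop to the fingerprint region
#'
#' Retains channels with `lo <= wavenumber <= hi` (default 400-1800 cm^-1,
#' the biomolecular fingerprint region), preserving order.
#'
#' @param x A `raman_map`, `raman_spectrum` or `spectral_dataset`.
#' @param lo,hi Window bounds in cm^-1.
#' @return Same class as `x` on the cropped axis.
#' @export
crop_fingerprint <- function(x, lo = 400, hi = 1800) {
  if (lo >= hi) rm_abort("need lo < hi", "bad_parameter")
  keep <- which(x$wavenumber >= lo & x$wavenumber <= hi)
  if (length(keep) < 2L) {
    rm_abort("fewer than 2 channels survive the crop", "empty_crop")
  }
  if (inherits(x, "raman_spectrum")) {
    return(raman_spectrum(x$wavenumber[keep], x$intensity[keep]))
  }
  if (inherits(x, "spectral_dataset")) {
    return(spectral_dataset(x$wavenumber[keep],
                            x$spectra[, keep, drop = FALSE], x$labels))
  }
  stopifnot(inherits(x, "raman_map"))
  out <- x
  out$wavenumber <- x$wavenumber[keep]
  out$data <- x$data[keep, , drop = FALSE]
  out
}

#' Normalize each pixel spectrum to unit total intensity
#'
#' Divides every pixel spectrum by its channel sum so each spectrum sums
#' to 1 ("whole area intensity" normalization). Shape is preserved: pairwise
#' cosine similarity between pixel spectra is unchanged.
#'
#' @param map A `raman_map`.
#' @return Normalized `raman_map`.
#' @export
normalize_total_intensity <- function(map) {
  stopifnot(inherits(map, "raman_map"))
  s <- colSums(map$data)
  if (any(s <= 0)) {
    p <- which(s <= 0)[1]
    row <- (p - 1L) %/% map$n_cols + 1L
    col <- (p - 1L) %% map$n_cols + 1L
    rm_abort(sprintf("pixel (row %d, col %d) has zero total intensity",
                     row, col), "zero_sum_pixel")
  }
  out <- map
  out$data <- sweep(map$data, 2, s, "/")
  out
}

#' Resample onto a target wavenumber axis
#'
#' Linear interpolation; exact for affine spectra. The target axis must lie
#' within the source range (no extrapolation).
#'
#' @param x A `raman_map` or `raman_spectrum`.
#' @param target_axis Strictly increasing axis within the source range.
#' @return Same class as `x` on `target_axis`.
#' @export
resample_to_axis <- function(x, target_axis) {
  target_axis <- wavenumber_axis(target_axis)
  src <- x$wavenumber
  if (min(target_axis) < min(src) || max(target_axis) > max(src)) {
    rm_abort("target axis extends past the source axis (extrapolation)",
             "extrapolation")
  }
  if (inherits(x, "raman_spectrum")) {
    yi <- stats::approx(src, x$intensity, xout = target_axis)$y
    return(raman_spectrum(target_axis, yi))
  }
  stopifnot(inherits(x, "raman_map"))
  out <- x
  out$wavenumber <- target_axis
  out$data <- apply(x$data, 2, function(y) {
    stats::approx(src, y, xout = target_axis)$y
  })
  out
}

#' Run the full preprocessing chain on a map
#'
#' Fixed order: cosmic-ray removal, ALS background subtraction, fingerprint
#' cropping, per-pixel total-intensity normalization. Deterministic, and
#' idempotent on spike-free input up to the (idempotent) normalization.
#'
#' @param map A `raman_map`.
#' @param z_threshold,window Spike detector parameters
#'   ([remove_cosmic_rays()]).
#' @param als_lambda,als_p,n_iter Background parameters
#'   ([subtract_baseline()]).
#' @param crop_lo,crop_hi Fingerprint window (cm^-1).
#' @param spike_removal Set `FALSE` to skip the spike stage.
#' @return List: `map` (preprocessed), `n_spikes_removed`, `params`.
#' @export
preprocess_map <- function(map, z_threshold = 8, window = 5,
                           als_lambda = 1e5, als_p = 0.001, n_iter = 10,
                           crop_lo = 400, crop_hi = 1800,
                           spike_removal = TRUE) {
  n_spikes <- 0L
  if (spike_removal) {
    sr <- remove_cosmic_rays(map, z_threshold, window)
    map <- sr$map
    n_spikes <- sr$n_spikes_removed
  }
  map <- subtract_baseline(map, als_lambda, als_p, n_iter)
  map <- crop_fingerprint(map, crop_lo, crop_hi)
  map <- normalize_total_intensity(map)
  list(map = map, n_spikes_removed = n_spikes,
       params = list(z_threshold = z_threshold, window = window,
                     als_lambda = als_lambda, als_p = als_p,
                     n_iter = n_iter, crop = c(crop_lo, crop_hi),
                     spike_removal = spike_removal))
}
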