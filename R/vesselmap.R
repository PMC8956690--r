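#' Vessel region of interest
#'
#' A manually outlined hemivein mask (the superior or inferior half of the
#' central retinal vein tree on the optic disk). Vessel segmentation is
#' deliberately manual input, not computed.
#'
#' @param mask logical (or 0/1) matrix, non-empty.
#' @param hemifield `"superior"` or `"inferior"`.
#' @param eye `"right"` or `"left"`.
#' @return An object of class `"vessel_roi"`.
#' @export
vessel_roi <- function(mask, hemifield = c("superior", "inferior"),
                       eye = c("right", "left")) {
  hemifield <- match.arg(hemifield)
  eye <- match.arg(eye)
  mask <- as.matrix(mask) > 0
  if (!any(mask)) stop("vessel ROI mask is empty")
  structure(list(mask = mask, hemifield = hemifield, eye = eye),
            class = "vessel_roi")
}

#' Assemble the 2-D pulse-amplitude map
#'
#' Places significance-filtered per-pixel amplitudes from a harmonic fit
#' table onto the image raster: locations with `p_sin1` strictly below
#' `p_max` carry their amplitude, all others are invalid. The map mirrors
#' the anatomical distribution of pulsatile vessels and can be rendered as
#' a false-colour heat map with [plot.amplitude_map()].
#'
#' @param fit_table a data frame as returned by [fit_stack()] (columns
#'   `row`, `col`, `amplitude`, `p_sin1`; 1-based coordinates).
#' @param shape integer (height, width) of the raster.
#' @param disk_centre numeric (row, col) of the optic-disk centre.
#' @param mm_per_px spatial scale, mm per pixel (> 0).
#' @param p_max significance threshold (default 0.03, strict).
#' @return An object of class `"amplitude_map"`: `amplitudes` (H x W, `NA`
#'   where invalid), `valid` (logical H x W), `disk_centre`, `mm_per_px`.
#' @export
build_amplitude_map <- function(fit_table, shape, disk_centre, mm_per_px,
                                p_max = 0.03) {
  stopifnot(length(shape) == 2, length(disk_centre) == 2, mm_per_px > 0)
  h <- shape[1]; w <- shape[2]
  amplitudes <- matrix(NA_real_, h, w)
  valid <- matrix(FALSE, h, w)
  if (nrow(fit_table)) {
    if (any(fit_table$row < 1 | fit_table$row > h |
            fit_table$col < 1 | fit_table$col > w))
      stop("data error: fit-table coordinate out of bounds")
    keep <- !is.na(fit_table$p_sin1) & fit_table$p_sin1 < p_max &
      is.finite(fit_table$amplitude)
    idx <- cbind(fit_table$row[keep], fit_table$col[keep])
    amplitudes[idx] <- fit_table$amplitude[keep]
    valid[idx] <- TRUE
  }
  structure(
    list(amplitudes = amplitudes, valid = valid,
         disk_centre = as.numeric(disk_centre), mm_per_px = mm_per_px),
    class = "amplitude_map")
}

#' @export
print.amplitude_map <- function(x, ...) {
  cat(sprintf("Amplitude map %dx%d, %d valid pixels, disk centre (%.1f, %.1f), %.3g mm/px\n",
              nrow(x$amplitudes), ncol(x$amplitudes), sum(x$valid),
              x$disk_centre[1], x$disk_centre[2], x$mm_per_px))
  invisible(x)
}

#' False-colour rendering of an amplitude map
#'
#' @param x an [build_amplitude_map()] result.
#' @param y ignored.
#' @param ... passed to [graphics::image()].
#' @export
plot.amplitude_map <- function(x, y, ...) {
  z <- t(x$amplitudes[rev(seq_len(nrow(x$amplitudes))), , drop = FALSE])
  graphics::image(z, col = grDevices::hcl.colors(64, "viridis"),
                  axes = FALSE, asp = nrow(x$amplitudes) / ncol(x$amplitudes),
                  ...)
  invisible(x)
}

#' Maximum retained pulse amplitude of one hemivein
#'
#' Applies the spatial and retention filters and extracts the hemivein's
#' maximum pulse amplitude: only valid map locations inside the ROI mask
#' and within `radius_mm` (Euclidean, centre-to-centre, boundary inclusive)
#' of the disk centre are considered — signal-to-noise falls with
#' eccentricity due to pulse-wave attenuation. If fewer than `min_measures`
#' locations survive, the recording is rejected (a result, not an error).
#'
#' @param map an [build_amplitude_map()] result.
#' @param roi a [vessel_roi()] of the same shape.
#' @param radius_mm analysis radius around the disk centre (default 0.8).
#' @param min_measures minimum retained measures (default 20).
#' @return An object of class `"hemivein_measure"`: `amplitude` (au, `NA`
#'   when rejected), `n_measures`, `rejected`, `reason`.
#' @export
hemivein_max <- function(map, roi, radius_mm = 0.8, min_measures = 20) {
  stopifnot(inherits(map, "amplitude_map"), inherits(roi, "vessel_roi"))
  if (!identical(dim(map$amplitudes), dim(roi$mask)))
    stop("map and ROI shapes differ")
  d <- pixel_distance_mm(nrow(map$amplitudes), ncol(map$amplitudes),
                         map$disk_centre, map$mm_per_px)
  sel <- roi$mask & map$valid & d <= radius_mm
  n <- sum(sel)
  if (n < min_measures) {
    return(structure(
      list(amplitude = NA_real_, n_measures = n, rejected = TRUE,
           reason = "insufficient measures"),
      class = "hemivein_measure"))
  }
  structure(
    list(amplitude = max(map$amplitudes[sel]), n_measures = n,
         rejected = FALSE, reason = NA_character_),
    class = "hemivein_measure")
}

#' @export
print.hemivein_measure <- function(x, ...) {
  if (x$rejected)
    cat(sprintf("Hemivein measure: rejected (%s; %d retained measures)\n",
                x$reason, x$n_measures))
  else
    cat(sprintf("Hemivein measure: max amplitude %.4g au from %d measures\n",
                x$amplitude, x$n_measures))
  invisible(x)
}

#' Build a pressure series from a sequence of recordings
#'
#' Extracts one (induced IOP, maximum amplitude) pair per recording via
#' [hemivein_max()] and assembles the hemivein's pressure series, ordered
#' by ascending IOP (ties keep acquisition order). Rejected recordings are
#' listed with their reasons in the `rejections` attribute; if every
#' recording is rejected the empty series is flagged unusable.
#'
#' @param recordings list of `list(iop = , map = )` in acquisition order.
#' @param roi a [vessel_roi()].
#' @param radius_mm,min_measures retention filters, see [hemivein_max()].
#' @return A [pressure_series()] with attributes `rejections` (data frame
#'   `recording_id`, `iop`, `reason`) and `unusable` (logical).
#' @export
series_from_recordings <- function(recordings, roi, radius_mm = 0.8,
                                   min_measures = 20) {
  stopifnot(length(recordings) >= 1)
  iop <- numeric(0); amp <- numeric(0)
  rej <- data.frame(recording_id = integer(0), iop = numeric(0),
                    reason = character(0))
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    m <- hemivein_max(rec$map, roi, radius_mm, min_measures)
    if (m$rejected) {
      rej <- rbind(rej, data.frame(recording_id = i, iop = rec$iop,
                                   reason = m$reason))
    } else {
      iop <- c(iop, rec$iop)
      amp <- c(amp, m$amplitude)
    }
  }
  out <- pressure_series(iop, amp, eye = roi$eye, hemifield = roi$hemifield,
                         posture = "sitting")
  attr(out, "rejections") <- rej
  attr(out, "unusable") <- length(iop) == 0
  out
}
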