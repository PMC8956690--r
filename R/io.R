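#' Read and write pressure series as CSV
#'
#' Columns: `iop_mmHg`, `amplitude_au`, `eye`, `hemifield`, `posture`.
#'
#' @param series a [pressure_series()].
#' @param path file path.
#' @return `read_pressure_series()` returns a [pressure_series()];
#'   `write_pressure_series()` returns `path` invisibly.
#' @export
write_pressure_series <- function(series, path) {
  stopifnot(inherits(series, "pressure_series"))
  df <- data.frame(iop_mmHg = series$iop, amplitude_au = series$amplitude,
                   eye = attr(series, "eye"),
                   hemifield = attr(series, "hemifield"),
                   posture = attr(series, "posture"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pressure_series
#' @export
read_pressure_series <- function(path) {
  df <- utils::read.csv(path)
  pressure_series(df$iop_mmHg, df$amplitude_au,
                  eye = df$eye[1], hemifield = df$hemifield[1],
                  posture = df$posture[1])
}

#' Write a per-recording harmonic fit table as CSV
#'
#' @param fit_table a [fit_stack()] result.
#' @param path file path.
#' @export
write_fit_table <- function(fit_table, path) {
  utils::write.csv(fit_table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fit_table
#' @export
read_fit_table <- function(path) utils::read.csv(path)

#' Read and write a binary mask as PNG
#'
#' @param mask logical matrix.
#' @param path file path.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask > 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0.5
}

#' Write a frame stack to disk
#'
#' Two forms: a single lossless archive (RDS), and a directory of PNG
#' frames (8-bit, intensities rescaled to the recorded maximum; a sidecar
#' `frames_meta.csv` stores the scale, frame rate and posture and
#' `beats.csv` the beat times) for visual QC and interoperability. The
#' archive round-trips exactly; the PNG form is quantised.
#'
#' @param stack a `"frame_stack"`.
#' @param dir output directory (created if missing).
#' @param archive also write `stack.rds` (default TRUE).
#' @return `dir`, invisibly.
#' @export
write_frame_stack <- function(stack, dir, archive = TRUE) {
  stopifnot(inherits(stack, "frame_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (archive) saveRDS(stack, file.path(dir, "stack.rds"))
  d <- dim(stack$frames)
  scale <- max(stack$frames)
  for (i in seq_len(d[1])) {
    png::writePNG(stack$frames[i, , ] / scale,
                  file.path(dir, sprintf("frame_%04d.png", i)))
  }
  utils::write.csv(
    data.frame(n_frames = d[1], height = d[2], width = d[3],
               fps = stack$fps, intensity_scale = scale,
               posture = stack$posture),
    file.path(dir, "frames_meta.csv"), row.names = FALSE)
  utils::write.csv(data.frame(beat_time_s = stack$beat_times),
                   file.path(dir, "beats.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a frame stack written by [write_frame_stack()]
#'
#' Prefers the lossless archive when present, else reassembles from the
#' PNG frames and sidecar CSVs.
#'
#' @param dir directory written by [write_frame_stack()].
#' @return A `"frame_stack"`.
#' @export
read_frame_stack <- function(dir) {
  rds <- file.path(dir, "stack.rds")
  if (file.exists(rds)) return(readRDS(rds))
  meta <- utils::read.csv(file.path(dir, "frames_meta.csv"))
  beats <- utils::read.csv(file.path(dir, "beats.csv"))
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  frames <- array(0, dim = c(length(files), meta$height, meta$width))
  for (i in seq_along(files)) {
    img <- png::readPNG(files[i])
    if (length(dim(img)) == 3) img <- img[, , 1]
    frames[i, , ] <- img * meta$intensity_scale
  }
  structure(list(frames = frames, fps = meta$fps,
                 beat_times = beats$beat_time_s, posture = meta$posture),
            class = "frame_stack")
}

#' Write an amplitude map as CSV and false-colour PNG
#'
#' @param map an [build_amplitude_map()] result.
#' @param csv_path CSV path (long form: row, col, amplitude_au, valid).
#' @param png_path optional false-colour PNG path (viridis-like ramp,
#'   invalid pixels black).
#' @export
write_amplitude_map <- function(map, csv_path, png_path = NULL) {
  stopifnot(inherits(map, "amplitude_map"))
  h <- nrow(map$amplitudes); w <- ncol(map$amplitudes)
  df <- data.frame(row = rep(seq_len(h), times = w),
                   col = rep(seq_len(w), each = h),
                   amplitude_au = as.vector(map$amplitudes),
                   valid = as.vector(map$valid))
  utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(png_path)) {
    pal <- grDevices::hcl.colors(64, "viridis")
    amax <- max(map$amplitudes[map$valid], 1e-9)
    idx <- pmin(63L, pmax(0L, as.integer(63 * map$amplitudes / amax))) + 1L
    rgb <- grDevices::col2rgb(pal[idx]) / 255
    img <- array(0, dim = c(h, w, 3))
    for (k in 1:3) {
      ch <- matrix(rgb[k, ], h, w)
      ch[!map$valid] <- 0
      img[, , k] <- ch
    }
    png::writePNG(img, png_path)
  }
  invisible(csv_path)
}

#' Write cohort ground truth as CSV
#'
#' Columns: `subject_id`, `posture`, `icp_true_sitting`, `icp_true_ld`,
#' `invasive`.
#'
#' @param cohort a [synth_cohort()] result.
#' @param path file path.
#' @export
write_cohort_truth <- function(cohort, path) {
  stopifnot(inherits(cohort, "ppg_cohort"))
  utils::write.csv(cohort$truth[, c("subject_id", "posture",
                                    "icp_true_sitting", "icp_true_ld",
                                    "invasive")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read and write paired invasive/estimated ICP tables as CSV
#'
#' Columns `invasive_mmHg`, `estimated_mmHg` map to the `invasive` /
#' `estimated` columns used by [agreement()] and
#' [diagnostic_performance()]; extra columns (`subject_id`, `method`,
#' `posture`) pass through.
#'
#' @param pairs data frame with columns `invasive`, `estimated`.
#' @param path file path.
#' @export
write_paired_icp <- function(pairs, path) {
  df <- pairs
  names(df)[names(df) == "invasive"] <- "invasive_mmHg"
  names(df)[names(df) == "estimated"] <- "estimated_mmHg"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_paired_icp
#' @export
read_paired_icp <- function(path) {
  df <- utils::read.csv(path)
  names(df)[names(df) == "invasive_mmHg"] <- "invasive"
  names(df)[names(df) == "estimated_mmHg"] <- "estimated"
  df
}
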