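#' Evaluate the noiseless three-phase amplitude law
#'
#' The phantom generator's model of how maximum vein pulse amplitude
#' responds to induced IOP: flat at `baseline_amp` while IOP is at or below
#' the true sitting ICP (venous transmural pressure high, little pulsation),
#' rising linearly once IOP exceeds ICP, peaking at `peak_iop`, then falling
#' linearly, floored at zero. Continuous and piecewise linear.
#'
#' @param iop induced IOP values, mmHg (>= 0), vectorised.
#' @param params an [amplitude_law_params()] object.
#' @return Noiseless amplitudes in au, same length as `iop`.
#' @examples
#' p <- amplitude_law_params(icp_true = 19, baseline_amp = 0,
#'                           rising_slope = 1, peak_iop = 40)
#' amplitude_law(30, p)  # 1 * (30 - 19) = 11 au
#' @export
amplitude_law <- function(iop, params) {
  stopifnot(inherits(params, "amplitude_law_params"), is.numeric(iop))
  if (any(iop < 0)) stop("iop must be >= 0")
  peak_amp <- params$baseline_amp +
    params$rising_slope * (params$peak_iop - params$icp_true)
  amp <- ifelse(iop <= params$icp_true,
                params$baseline_amp,
         ifelse(iop <= params$peak_iop,
                params$baseline_amp + params$rising_slope * (iop - params$icp_true),
                peak_amp - params$fall_slope * (iop - params$peak_iop)))
  pmax(amp, 0)
}

#' Generate a synthetic amplitude-versus-IOP series with known ground truth
#'
#' Evaluates [amplitude_law()] on the protocol's IOP grid and adds
#' independent Gaussian noise of sd `params$noise_sd` — a curve-level
#' fixture that bypasses the video stage. Reproducible under a fixed seed.
#'
#' @param params an [amplitude_law_params()] object (holds the ground-truth
#'   sitting ICP in `icp_true`).
#' @param protocol a [protocol_params()] object.
#' @param seed optional integer seed; the global RNG state is restored
#'   afterwards.
#' @param eye,hemifield labels passed to [pressure_series()].
#' @return A [pressure_series()] with attribute `icp_true` (sitting, mmHg).
#' @export
synth_pressure_series <- function(params, protocol, seed = NULL,
                                  eye = NA_character_,
                                  hemifield = NA_character_) {
  stopifnot(inherits(params, "amplitude_law_params"),
            inherits(protocol, "protocol_params"))
  iop <- protocol_iop_grid(protocol)
  amp <- with_seed(seed,
    amplitude_law(iop, params) + rnorm(length(iop), 0, params$noise_sd))
  out <- pressure_series(iop, amp, eye = eye, hemifield = hemifield,
                         posture = "sitting")
  attr(out, "icp_true") <- params$icp_true
  out
}

#' Phantom fundus geometry
#'
#' Defines the pixel raster of the phantom: image size, optic-disk centre,
#' spatial scale, superior/inferior hemivein masks and a per-pixel
#' amplitude-weight map in \[0, 1\] (1 on vessel pixels, 0 elsewhere by
#' default). The default geometry draws a 3-pixel-wide vertical vein through
#' the disk centre, split into superior (above centre) and inferior (below)
#' hemiveins, each with well over 20 pixels inside the 0.8 mm analysis
#' radius so generated cases pass the retention filters unless deliberately
#' degraded. All coordinates are 1-based (row, col), origin top-left.
#'
#' @param height,width image size in pixels.
#' @param disk_centre numeric (row, col) of the optic-disk centre.
#' @param mm_per_px spatial scale, mm per pixel.
#' @param vein_halfwidth half-width of the default vein strip, pixels.
#' @return An object of class `"phantom_geometry"` with elements `height`,
#'   `width`, `disk_centre`, `mm_per_px`, `superior_mask`, `inferior_mask`
#'   (logical matrices, disjoint) and `weight` (numeric matrix in \[0, 1\]).
#' @export
phantom_geometry <- function(height = 48, width = 48,
                             disk_centre = c((height + 1) / 2, (width + 1) / 2),
                             mm_per_px = 0.05, vein_halfwidth = 1) {
  stopifnot(height >= 8, width >= 8, mm_per_px > 0,
            length(disk_centre) == 2)
  cc <- disk_centre[2]
  cr <- disk_centre[1]
  col_idx <- matrix(rep(seq_len(width), each = height), height, width)
  row_idx <- matrix(rep(seq_len(height), times = width), height, width)
  vein <- abs(col_idx - cc) <= vein_halfwidth
  superior <- vein & row_idx < cr
  inferior <- vein & row_idx > cr
  weight <- matrix(0, height, width)
  weight[superior | inferior] <- 1
  geom <- structure(
    list(height = height, width = width, disk_centre = disk_centre,
         mm_per_px = mm_per_px, superior_mask = superior,
         inferior_mask = inferior, weight = weight),
    class = "phantom_geometry")
  validate_phantom_geometry(geom)
  geom
}

validate_phantom_geometry <- function(geom, radius_mm = 0.8,
                                      min_measures = 20) {
  if (any(geom$superior_mask & geom$inferior_mask))
    stop("invalid geometry: hemivein masks must be disjoint")
  d <- pixel_distance_mm(geom$height, geom$width, geom$disk_centre,
                         geom$mm_per_px)
  for (m in c("superior_mask", "inferior_mask")) {
    n <- sum(geom[[m]] & d <= radius_mm)
    if (n < min_measures)
      warning(sprintf("%s has only %d pixels inside %.2g mm of disk centre",
                      m, n, radius_mm))
  }
  invisible(geom)
}

# mm distance of every pixel centre from the disk centre
pixel_distance_mm <- function(height, width, disk_centre, mm_per_px) {
  row_idx <- matrix(rep(seq_len(height), times = width), height, width)
  col_idx <- matrix(rep(seq_len(width), each = height), height, width)
  sqrt((row_idx - disk_centre[1])^2 + (col_idx - disk_centre[2])^2) * mm_per_px
}

# composite cardiac waveform: first + second harmonic, amplitude ratio 2:1,
# fixed phases, normalised to unit peak-to-trough; s is phase in cycles
cardiac_waveform <- function(s) {
  raw <- function(u) sin(2 * pi * u) + 0.5 * sin(4 * pi * u)
  grid <- raw(seq(0, 1, length.out = 4096))
  raw(s) / (max(grid) - min(grid))
}

#' Generate phantom fundus video at one induced IOP
#'
#' Emulates the measurement chain: on vessel pixels the optical density
#' oscillates at the cardiac frequency with a two-harmonic waveform
#' (first:second harmonic amplitude ratio 2:1, fixed phases) whose
#' peak-to-trough amplitude in au equals
#' `weight * amplitude_law(iop, params)`; intensity follows Beer-Lambert,
#' `I(t) = i0 * 10^(-OD(t))` with 1 au = 0.001 OD. Gaussian optical-density
#' noise of sd `params$noise_sd` (au) is added to every pixel and frame, so
#' non-vessel pixels carry noise only. Cardiac beat times are exact
#' multiples of the cardiac period starting at 0 s.
#'
#' @param geometry a [phantom_geometry()].
#' @param params an [amplitude_law_params()].
#' @param protocol a [protocol_params()] (frame rate, cycles, cardiac
#'   frequency).
#' @param iop the induced IOP (mmHg) of this recording step.
#' @param seed optional integer seed (RNG state restored afterwards).
#' @param i0 unattenuated intensity level (default 200 on an 8-bit-like
#'   scale).
#' @param scale_au au per unit optical density scaling (default 1000,
#'   matching [intensity_to_density()]).
#' @return A `"frame_stack"`: list with `frames` (T x H x W array), `fps`,
#'   `beat_times` (s), `posture` and attribute `iop`.
#' @export
synth_video <- function(geometry, params, protocol, iop, seed = NULL,
                        i0 = 200, scale_au = 1000) {
  stopifnot(inherits(geometry, "phantom_geometry"),
            inherits(params, "amplitude_law_params"),
            inherits(protocol, "protocol_params"),
            is.numeric(iop), length(iop) == 1L, iop >= 0)
  f <- protocol$cardiac_freq
  fps <- protocol$fps
  if (f >= fps / 4)
    stop("protocol mismatch: cardiac_freq must be below fps/4")
  n_frames <- as.integer(ceiling(protocol$n_cycles * fps / f))
  t <- (seq_len(n_frames) - 1) / fps
  w <- cardiac_waveform(f * t)                       # unit peak-to-trough
  amp_au <- geometry$weight * amplitude_law(iop, params)
  n_px <- geometry$height * geometry$width
  # OD in au, frames x pixels (pixels column-major as in the frame matrices)
  od_au <- outer(w, as.vector(amp_au))
  od_au <- od_au + with_seed(seed,
    matrix(rnorm(n_frames * n_px, 0, params$noise_sd), n_frames, n_px))
  intens <- i0 * 10^(-od_au / scale_au)
  frames <- array(intens, dim = c(n_frames, geometry$height, geometry$width))
  duration <- n_frames / fps
  beat_times <- seq(0, duration, by = 1 / f)
  structure(
    list(frames = frames, fps = fps, beat_times = beat_times,
         posture = "sitting"),
    iop = iop, class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Frame stack: %d frames of %dx%d @ %g fps, %d beats, %s posture\n",
              d[1], d[2], d[3], x$fps, length(x$beat_times), x$posture))
  invisible(x)
}

#' Generate a synthetic cohort with known ground-truth ICP
#'
#' Draws one true sitting ICP per subject from `icp_sampler`, then generates
#' up to four amplitude-versus-IOP series per subject (superior and inferior
#' hemiveins of both eyes) from the three-phase law with independent noise.
#' Ground truth is stored in both posture conventions to avoid sign errors:
#' the invasive reference is `icp_true_sitting + postural offset` for
#' lateral-decubitus lumbar puncture subjects, and `icp_true_sitting` itself
#' for subjects flagged as measured seated (e.g. by external ventricular
#' drain).
#'
#' @param n_subjects number of subjects (>= 1).
#' @param icp_sampler function of `n` returning `n` true sitting ICPs
#'   (mmHg).
#' @param law_defaults function of one sitting ICP returning an
#'   [amplitude_law_params()]; the default uses baseline 0 au, rising slope
#'   1.2 au/mmHg, peak 30 mmHg above the knee, fall 0.6 au/mmHg and noise
#'   sd 0.5 au.
#' @param protocol a [protocol_params()].
#' @param seed optional integer seed (RNG state restored afterwards).
#' @param posture invasive-measurement posture per subject, recycled:
#'   `"lateral_decubitus"` (lumbar puncture) or `"sitting"` (EVD).
#' @param postural_offset mmHg between conventions (default 10).
#' @return An object of class `"ppg_cohort"`: list with `subjects` (each a
#'   list of `subject_id`, `icp_true_sitting`, `icp_true_ld`, `posture`,
#'   `invasive` — the ground-truth invasive reading in its stated posture —
#'   and `datasets`, up to 4 [pressure_series()]) and `truth`, a data frame
#'   with one row per subject.
#' @export
synth_cohort <- function(n_subjects,
                         icp_sampler = function(n) runif(n, 5, 20),
                         law_defaults = function(icp)
                           amplitude_law_params(icp, noise_sd = 0.5),
                         protocol = protocol_params(),
                         seed = NULL,
                         posture = "lateral_decubitus",
                         postural_offset = 10) {
  stopifnot(n_subjects >= 1)
  posture <- rep_len(posture, n_subjects)
  if (!all(posture %in% c("lateral_decubitus", "sitting")))
    stop("posture must be 'lateral_decubitus' or 'sitting'")
  with_seed(seed, {
    icp_sitting <- icp_sampler(n_subjects)
    subjects <- vector("list", n_subjects)
    for (i in seq_len(n_subjects)) {
      params <- law_defaults(icp_sitting[i])
      datasets <- list()
      k <- 0
      for (eye in c("right", "left")) {
        for (hemi in c("superior", "inferior")) {
          k <- k + 1
          datasets[[k]] <- synth_pressure_series(params, protocol,
                                                 seed = NULL, eye = eye,
                                                 hemifield = hemi)
        }
      }
      icp_ld <- icp_sitting[i] + postural_offset
      subjects[[i]] <- list(
        subject_id = sprintf("S%03d", i),
        icp_true_sitting = icp_sitting[i],
        icp_true_ld = icp_ld,
        posture = posture[i],
        invasive = if (posture[i] == "lateral_decubitus") icp_ld
                   else icp_sitting[i],
        datasets = datasets)
    }
    truth <- data.frame(
      subject_id = vapply(subjects, `[[`, "", "subject_id"),
      icp_true_sitting = icp_sitting,
      icp_true_ld = icp_sitting + postural_offset,
      posture = posture,
      invasive = vapply(subjects, `[[`, 0, "invasive"))
    structure(list(subjects = subjects, truth = truth),
              class = "ppg_cohort")
  })
}

#' @export
print.ppg_cohort <- function(x, ...) {
  cat(sprintf("Synthetic PPG cohort: %d subjects, %d datasets each\n",
              length(x$subjects), length(x$subjects[[1]]$datasets)))
  print(utils::head(x$truth), ...)
  invisible(x)
}

#' Estimate ICP for every subject of a cohort
#'
#' Convenience wrapper: runs [icp_fit()] on each dataset of each subject and
#' [combine_subject()] across datasets, returning estimates alongside the
#' ground truth / invasive reference.
#'
#' @param cohort a [synth_cohort()] result (or a list with the same shape).
#' @param cal a [calibration_params()].
#' @return Data frame with one row per subject: `subject_id`, `invasive`,
#'   `posture`, `icp_sitting`, `icp_ld`, `estimated` (in the subject's
#'   invasive posture convention), `n_datasets_used`, `excluded`, `reason`.
#' @export
estimate_cohort <- function(cohort, cal = calibration_params()) {
  stopifnot(inherits(cohort, "ppg_cohort"))
  rows <- lapply(cohort$subjects, function(s) {
    fits <- lapply(s$datasets, icp_fit, cal = cal)
    target <- if (s$posture == "lateral_decubitus") "lateral_decubitus"
              else "sitting"
    est <- combine_subject(fits, target_posture = target, cal = cal)
    data.frame(
      subject_id = s$subject_id,
      invasive = s$invasive,
      posture = s$posture,
      icp_sitting = if (est$excluded) NA_real_ else est$icp_sitting,
      icp_ld = if (est$excluded) NA_real_ else est$icp_ld,
      estimated = if (est$excluded) NA_real_ else est$icp_estimate,
      n_datasets_used = est$n_datasets_used,
      excluded = est$excluded,
      reason = if (est$excluded) est$reason else NA_character_)
  })
  do.call(rbind, rows)
}
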