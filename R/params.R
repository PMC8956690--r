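#' Piecewise amplitude-law parameters
#'
#' Parameters of the three-phase pulse-amplitude law used by the synthetic
#' phantom module: amplitude is flat at `baseline_amp` while IOP is at or
#' below the true (sitting-posture) ICP, rises linearly with `rising_slope`
#' up to `peak_iop`, then falls linearly with `fall_slope`, floored at zero.
#' The noiseless law is continuous and piecewise linear in IOP.
#'
#' @param icp_true true intracranial pressure in mmHg, sitting-posture
#'   convention (the x-axis position of the knee between the flat and the
#'   rising phase).
#' @param baseline_amp amplitude (au) of the flat initial phase. The default
#'   0 matches the flow-discontinuity theory in which pulse amplitude tends
#'   to zero at the IOP/CSF balance point; no baseline magnitude is reported
#'   for real eyes, so this is a declared modelling assumption.
#' @param rising_slope slope of the rising phase in au/mmHg (> 0).
#' @param peak_iop IOP (mmHg) at which amplitude peaks; must exceed
#'   `icp_true`.
#' @param fall_slope magnitude of the falling-phase slope in au/mmHg
#'   (>= 0), applied above `peak_iop`.
#' @param noise_sd standard deviation (au) of additive Gaussian measurement
#'   noise applied by the stochastic generators.
#' @return An object of class `"amplitude_law_params"`.
#' @seealso [amplitude_law()], [synth_pressure_series()], [synth_cohort()]
#' @examples
#' p <- amplitude_law_params(icp_true = 19, rising_slope = 1, peak_iop = 40)
#' amplitude_law(c(10, 19, 30, 40, 45), p)
#' @export
amplitude_law_params <- function(icp_true,
                                 baseline_amp = 0,
                                 rising_slope = 1.2,
                                 peak_iop = icp_true + 30,
                                 fall_slope = 0.6,
                                 noise_sd = 0) {
  stopifnot(is.numeric(icp_true), length(icp_true) == 1L, is.finite(icp_true))
  if (!is.finite(rising_slope) || rising_slope <= 0)
    stop("invalid amplitude-law parameters: rising_slope must be > 0")
  if (!is.finite(peak_iop) || peak_iop <= icp_true)
    stop("invalid amplitude-law parameters: peak_iop must exceed icp_true")
  if (!is.finite(baseline_amp) || baseline_amp < 0)
    stop("invalid amplitude-law parameters: baseline_amp must be >= 0")
  if (!is.finite(fall_slope) || fall_slope < 0)
    stop("invalid amplitude-law parameters: fall_slope must be >= 0")
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("invalid amplitude-law parameters: noise_sd must be >= 0")
  structure(
    list(icp_true = icp_true, baseline_amp = baseline_amp,
         rising_slope = rising_slope, peak_iop = peak_iop,
         fall_slope = fall_slope, noise_sd = noise_sd),
    class = "amplitude_law_params")
}

#' Pressure-protocol parameters
#'
#' Describes the ophthalmodynamometric recording protocol: IOP is stepped
#' from `baseline_iop` to `max_iop` in `step` mmHg increments while, at each
#' setting, at least `n_cycles` consecutive cardiac cycles of fundus video
#' are recorded at `fps` frames per second.
#'
#' @param baseline_iop starting (uninduced) IOP in mmHg.
#' @param step IOP increment per recording step in mmHg.
#' @param max_iop final induced IOP in mmHg.
#' @param fps video frame rate, frames per second.
#' @param n_cycles number of cardiac cycles recorded per step (>= 3).
#' @param cardiac_freq cardiac frequency in Hz (default 1.2 Hz, i.e. 72 bpm).
#' @return An object of class `"protocol_params"`.
#' @export
protocol_params <- function(baseline_iop = 15, step = 5, max_iop = 45,
                            fps = 25, n_cycles = 3, cardiac_freq = 1.2) {
  if (!is.finite(baseline_iop) || !is.finite(max_iop) || baseline_iop >= max_iop)
    stop("invalid protocol: baseline_iop must be below max_iop")
  if (!is.finite(step) || step <= 0) stop("invalid protocol: step must be > 0")
  if (!is.finite(fps) || fps <= 0) stop("invalid protocol: fps must be > 0")
  if (!is.finite(n_cycles) || n_cycles < 3)
    stop("invalid protocol: n_cycles must be >= 3")
  if (!is.finite(cardiac_freq) || cardiac_freq <= 0)
    stop("invalid protocol: cardiac_freq must be > 0")
  structure(
    list(baseline_iop = baseline_iop, step = step, max_iop = max_iop,
         fps = fps, n_cycles = n_cycles, cardiac_freq = cardiac_freq),
    class = "protocol_params")
}

#' IOP grid implied by a protocol
#'
#' @param protocol a [protocol_params()] object.
#' @return Numeric vector of induced IOP settings, `baseline_iop` to
#'   `max_iop` by `step` (the last step is dropped if it would overshoot).
#' @export
protocol_iop_grid <- function(protocol) {
  stopifnot(inherits(protocol, "protocol_params"))
  seq(protocol$baseline_iop, protocol$max_iop, by = protocol$step)
}

#' Calibration and filtering parameters for ICP estimation
#'
#' Bundles every tunable constant of the estimation chain: the
#' ophthalmodynamometer force-to-IOP calibration, the sitting to
#' lateral-decubitus postural offset, the rising-segment retention filters,
#' the harmonic-fit significance cut, the spatial retention filters, and the
#' two diagnostic ICP cut-offs.
#'
#' @param force_coefficient mmHg of induced IOP per ophthalmodynamometer
#'   force unit (default 0.89).
#' @param postural_offset mmHg added to a sitting ICP to express it in the
#'   lateral-decubitus convention (default 10).
#' @param slope_min minimum acceptable rising-segment slope, au/mmHg
#'   (default 0.4); windows with smaller slope are discarded.
#' @param r_min minimum acceptable Pearson correlation within a candidate
#'   window (default 0.8, signed: negative-slope windows always fail).
#' @param amp_min minimum maximum-amplitude (au) a candidate window must
#'   contain (default 6).
#' @param min_window minimum number of consecutive (IOP, amplitude) pairs
#'   per candidate window (default 3).
#' @param p_max harmonic-fit significance threshold: a pixel is retained
#'   when the first-harmonic sine coefficient's p-value is strictly below
#'   this (default 0.03).
#' @param radius_mm amplitude measures are restricted to within this
#'   distance of the disk centre (default 0.8 mm, boundary inclusive).
#' @param min_measures minimum retained amplitude measures per hemivein
#'   (default 20); fewer rejects the recording.
#' @param borderline_cut invasive ICP cut-off (mmHg) for borderline
#'   elevation (default 14.7, i.e. 20 cmH2O).
#' @param elevated_cut invasive ICP cut-off (mmHg) for pathological
#'   elevation (default 18.4, i.e. 25 cmH2O).
#' @return An object of class `"calibration_params"`.
#' @export
calibration_params <- function(force_coefficient = 0.89,
                               postural_offset = 10,
                               slope_min = 0.4,
                               r_min = 0.8,
                               amp_min = 6,
                               min_window = 3,
                               p_max = 0.03,
                               radius_mm = 0.8,
                               min_measures = 20,
                               borderline_cut = 14.7,
                               elevated_cut = 18.4) {
  vals <- c(force_coefficient, postural_offset, slope_min, r_min, amp_min,
            min_window, p_max, radius_mm, min_measures,
            borderline_cut, elevated_cut)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("invalid calibration: all parameters must be positive and finite")
  if (min_window < 3) stop("invalid calibration: min_window must be >= 3")
  structure(
    list(force_coefficient = force_coefficient,
         postural_offset = postural_offset,
         slope_min = slope_min, r_min = r_min, amp_min = amp_min,
         min_window = as.integer(min_window), p_max = p_max,
         radius_mm = radius_mm, min_measures = as.integer(min_measures),
         borderline_cut = borderline_cut, elevated_cut = elevated_cut),
    class = "calibration_params")
}

#' @export
print.amplitude_law_params <- function(x, ...) {
  cat("Three-phase amplitude law:\n")
  cat(sprintf("  flat at %.3g au for IOP <= %.3g mmHg (true sitting ICP)\n",
              x$baseline_amp, x$icp_true))
  cat(sprintf("  rising %.3g au/mmHg up to peak at IOP %.3g mmHg\n",
              x$rising_slope, x$peak_iop))
  cat(sprintf("  falling %.3g au/mmHg above the peak (floored at 0)\n",
              x$fall_slope))
  cat(sprintf("  measurement noise sd %.3g au\n", x$noise_sd))
  invisible(x)
}

#' @export
print.protocol_params <- function(x, ...) {
  cat(sprintf(
    "IOP protocol: %g to %g mmHg by %g; %g cycles @ %g fps, cardiac %g Hz\n",
    x$baseline_iop, x$max_iop, x$step, x$n_cycles, x$fps, x$cardiac_freq))
  invisible(x)
}

#' @export
print.calibration_params <- function(x, ...) {
  cat("ICP estimation calibration:\n")
  cat(sprintf("  induced IOP = baseline + %.3g x force\n", x$force_coefficient))
  cat(sprintf("  segment filters: r >= %.3g, slope >= %.3g au/mmHg, max amp >= %.3g au, window >= %d\n",
              x$r_min, x$slope_min, x$amp_min, x$min_window))
  cat(sprintf("  pixel retention: p < %.3g, radius <= %.3g mm, >= %d measures\n",
              x$p_max, x$radius_mm, x$min_measures))
  cat(sprintf("  posture: ICP_LD = ICP_sitting + %.3g mmHg\n", x$postural_offset))
  cat(sprintf("  diagnostic cut-offs: %.3g / %.3g mmHg\n",
              x$borderline_cut, x$elevated_cut))
  invisible(x)
}

# run expr with a temporarily seeded RNG, restoring global state afterwards
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
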