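#' Convert an intensity series to optical density
#'
#' Beer-Lambert transformation of a pixel's green-channel intensity series:
#' `OD(t) = -log10(I(t) / i_ref) * scale_au`. The arbitrary-unit (au)
#' amplitude scale of the whole package is fixed here: `scale_au = 1000`,
#' i.e. an optical density of 0.001 maps to 1 au. Optical density is
#' monotone decreasing in intensity, so a darkening vessel (more absorbing
#' blood column) gives a rising OD.
#'
#' @param series intensity values (> 0).
#' @param i_ref reference intensity (> 0); the per-pixel temporal mean is
#'   used throughout the pipeline, which removes static illumination
#'   heterogeneity without a flat-field image.
#' @param scale_au au per unit optical density (default 1000; a declared
#'   package convention — the retention thresholds of
#'   [calibration_params()] are honoured on this scale).
#' @return Optical-density series in au.
#' @examples
#' intensity_to_density(c(100, 50, 100), i_ref = 100)  # 0, 301.03, 0
#' @export
intensity_to_density <- function(series, i_ref, scale_au = 1000) {
  if (any(!is.finite(series)) || any(series <= 0))
    stop("intensity data error: nonpositive or non-finite intensity")
  if (!is.finite(i_ref) || i_ref <= 0)
    stop("intensity data error: i_ref must be > 0")
  -log10(series / i_ref) * scale_au
}

#' Cardiac frequency from beat times
#'
#' Reciprocal of the mean inter-beat interval of the oximeter beat
#' timestamps recorded during photography.
#'
#' @param beat_times beat timestamps in seconds, strictly increasing,
#'   length >= 2.
#' @return Cardiac frequency in Hz.
#' @examples
#' cardiac_frequency(c(0, 0.8, 1.6))  # 1.25 Hz
#' @export
cardiac_frequency <- function(beat_times) {
  if (length(beat_times) < 2)
    stop("timing error: need at least 2 beat times")
  if (any(diff(beat_times) <= 0))
    stop("timing error: beat times must be strictly increasing")
  1 / mean(diff(beat_times))
}

# two-harmonic design matrix; x is time relative to the first beat
harmonic_design <- function(x, freq) {
  cbind(1, sin(2 * pi * freq * x), cos(2 * pi * freq * x),
        sin(4 * pi * freq * x), cos(4 * pi * freq * x))
}

# vectorised two-harmonic OLS over the columns of Y (one series per column)
# returns coefficients, amplitude (peak-to-trough of the fitted periodic
# component over one period) and the two-sided t-test p-value of the
# first-harmonic sine coefficient
harmonic_core <- function(Y, fps, freq, t0 = 0, grid_n = 2048) {
  n <- nrow(Y)
  if (n < 10) stop("fit error: series length must be >= 10")
  if (!is.finite(freq) || freq <= 0 || freq >= fps / 4)
    stop("fit error: freq must lie in (0, fps/4)")
  x <- (seq_len(n) - 1) / fps - t0
  X <- harmonic_design(x, freq)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("fit error: rank-deficient harmonic design (frequency aliasing?)")
  beta <- qr.coef(qx, Y)                       # 5 x P
  res <- Y - X %*% beta
  df <- n - ncol(X)
  s2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qx))
  se_a1 <- sqrt(s2 * xtx_inv[2, 2])
  tval <- beta[2, ] / se_a1
  p_sin1 <- 2 * stats::pt(-abs(tval), df)
  p_sin1[se_a1 == 0] <- ifelse(beta[2, se_a1 == 0] == 0, 1, 0)
  s <- seq(0, 1, length.out = grid_n)
  G <- cbind(sin(2 * pi * s), cos(2 * pi * s),
             sin(4 * pi * s), cos(4 * pi * s))
  recon <- G %*% beta[-1, , drop = FALSE]      # grid_n x P
  amplitude <- apply(recon, 2, max) - apply(recon, 2, min)
  list(beta = beta, amplitude = amplitude, p_sin1 = p_sin1, n_obs = n,
       sigma2 = s2, df = df)
}

#' Fit a cardiac-locked two-harmonic model to a density series
#'
#' Ordinary least squares of the optical-density series on
#' `{1, sin(2*pi*f*t), cos(2*pi*f*t), sin(4*pi*f*t), cos(4*pi*f*t)}` with
#' `f` the cardiac frequency. Pulse amplitude is defined as the
#' peak-to-trough excursion of the fitted periodic component evaluated on a
#' dense grid over one period (for a pure first harmonic this equals twice
#' the harmonic's coefficient magnitude). The quality probability `p_sin1`
#' is the standard two-sided OLS t-test p-value of the first-harmonic sine
#' coefficient; locations are retained downstream only when it falls below
#' the significance cut (see [pixel_amplitude()]).
#'
#' The cardiac phase origin is the first beat time: pass `t0` so that the
#' sine basis is phase-locked to the beat, which concentrates an in-phase
#' pulsation into the sine coefficient the significance filter tests.
#'
#' @param series optical-density series (au), length >= 10, sampled at
#'   `fps`.
#' @param fps sampling rate, frames/s.
#' @param freq cardiac frequency, Hz; must satisfy `0 < freq < fps/4` so
#'   both harmonics are below the Nyquist limit.
#' @param t0 time (s) of the first cardiac beat relative to the first frame
#'   (default 0).
#' @return An object of class `"harmonic_fit"`: `a0`, `a1`, `b1`, `a2`,
#'   `b2` (au), `amplitude` (au, peak-to-trough), `p_sin1`, `n_obs`.
#' @examples
#' t <- (0:99) / 25
#' fit <- fit_two_harmonics(5 + 3 * sin(2 * pi * 1.25 * t), fps = 25,
#'                          freq = 1.25)
#' fit$amplitude  # 6: peak-to-trough of a 3 au sine
#' @export
fit_two_harmonics <- function(series, fps, freq, t0 = 0) {
  stopifnot(is.numeric(series))
  core <- harmonic_core(matrix(series, ncol = 1), fps, freq, t0)
  b <- core$beta[, 1]
  structure(
    list(a0 = b[1], a1 = b[2], b1 = b[3], a2 = b[4], b2 = b[5],
         amplitude = core$amplitude[1], p_sin1 = core$p_sin1[1],
         n_obs = core$n_obs),
    class = "harmonic_fit")
}

#' @export
print.harmonic_fit <- function(x, ...) {
  cat(sprintf("Two-harmonic fit (n = %d): amplitude %.4g au, p_sin1 = %.3g\n",
              x$n_obs, x$amplitude, x$p_sin1))
  cat(sprintf("  a0 %.4g | first harmonic (%.4g, %.4g) | second (%.4g, %.4g)\n",
              x$a0, x$a1, x$b1, x$a2, x$b2))
  invisible(x)
}

#' Significance-filtered pulse amplitude of one location
#'
#' Applies the harmonic-quality filter: the amplitude is retained only when
#' the first-harmonic sine coefficient's p-value is strictly below `p_max`
#' (default 0.03); otherwise the location is invalid and `NA` is returned.
#'
#' @param fit a [fit_two_harmonics()] result.
#' @param p_max significance threshold (default 0.03, strict inequality).
#' @return The amplitude in au, or `NA_real_` when the location is invalid.
#' @export
pixel_amplitude <- function(fit, p_max = 0.03) {
  stopifnot(inherits(fit, "harmonic_fit"))
  if (is.finite(fit$p_sin1) && fit$p_sin1 < p_max) fit$amplitude
  else NA_real_
}

#' Per-pixel harmonic analysis of a frame stack
#'
#' Runs the full harmonic stage on every pixel of an aligned green-channel
#' frame stack: per-pixel Beer-Lambert conversion with the pixel's temporal
#' mean as reference intensity, then the cardiac-locked two-harmonic OLS
#' with frequency taken from the beat times and phase origin at the first
#' beat. Pixels with nonpositive intensity anywhere in the series are
#' marked invalid rather than fitted.
#'
#' @param stack a `"frame_stack"` (see [synth_video()]): `frames` is a
#'   T x H x W array, plus `fps` and `beat_times`.
#' @param p_max significance threshold for the `valid` flag (default 0.03).
#' @param scale_au au per unit optical density (default 1000).
#' @return A data frame with one row per pixel: `row`, `col` (1-based),
#'   `a0`, `a1`, `b1`, `a2`, `b2`, `amplitude` (au), `p_sin1`, `valid`.
#' @export
fit_stack <- function(stack, p_max = 0.03, scale_au = 1000) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  n_frames <- d[1]; h <- d[2]; w <- d[3]
  Y <- matrix(stack$frames, nrow = n_frames)      # pixels column-major
  ok <- colSums(Y <= 0 | !is.finite(Y)) == 0
  freq <- cardiac_frequency(stack$beat_times)
  i_ref <- colMeans(Y[, ok, drop = FALSE])
  OD <- -log10(sweep(Y[, ok, drop = FALSE], 2, i_ref, "/")) * scale_au
  core <- harmonic_core(OD, stack$fps, freq, t0 = stack$beat_times[1])
  n_px <- h * w
  out <- data.frame(
    row = ((seq_len(n_px) - 1) %% h) + 1L,
    col = ((seq_len(n_px) - 1) %/% h) + 1L,
    a0 = NA_real_, a1 = NA_real_, b1 = NA_real_, a2 = NA_real_,
    b2 = NA_real_, amplitude = NA_real_, p_sin1 = NA_real_,
    valid = FALSE)
  out$a0[ok] <- core$beta[1, ]
  out$a1[ok] <- core$beta[2, ]
  out$b1[ok] <- core$beta[3, ]
  out$a2[ok] <- core$beta[4, ]
  out$b2[ok] <- core$beta[5, ]
  out$amplitude[ok] <- core$amplitude
  out$p_sin1[ok] <- core$p_sin1
  out$valid <- !is.na(out$p_sin1) & out$p_sin1 < p_max
  out
}
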