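#' Induced IOP from ophthalmodynamometer force
#'
#' Linear calibration of the ring force transducer:
#' `induced IOP = baseline IOP + force_coefficient * force`
#' (default coefficient 0.89 mmHg per force unit).
#'
#' @param baseline_iop baseline (uninduced) IOP, mmHg (> 0).
#' @param force ophthalmodynamometer force output, force units (>= 0),
#'   vectorised.
#' @param cal a [calibration_params()].
#' @return Induced IOP in mmHg.
#' @examples
#' induced_iop(15, 10)  # 23.9
#' @export
induced_iop <- function(baseline_iop, force, cal = calibration_params()) {
  stopifnot(inherits(cal, "calibration_params"))
  if (!is.finite(baseline_iop) || baseline_iop <= 0)
    stop("parameter error: baseline_iop must be > 0")
  if (any(!is.finite(force)) || any(force < 0))
    stop("parameter error: force must be >= 0")
  baseline_iop + cal$force_coefficient * force
}

#' Truncate a pressure series at its amplitude peak
#'
#' First step of the three-phase algorithm: identify the IOP at the global
#' maximum pulse amplitude and eliminate every pair at higher IOP (the
#' plateau-to-falling phase). On amplitude ties the lowest such IOP is the
#' peak, a conservative choice that drops plateau points.
#'
#' @param series a [pressure_series()] (non-empty, IOP ascending).
#' @return The truncated [pressure_series()].
#' @export
truncate_at_peak <- function(series) {
  stopifnot(inherits(series, "pressure_series"))
  if (nrow(series) == 0) stop("data error: empty pressure series")
  peak_iop <- series$iop[which.max(series$amplitude)]  # first max = lowest IOP
  as_pressure_series(series[series$iop <= peak_iop, , drop = FALSE], series)
}

#' Enumerate candidate consecutive windows
#'
#' All contiguous index windows of at least `min_window` (IOP, amplitude)
#' pairs: for a series of length `n` there are
#' `sum over L = min_window..n of (n - L + 1)` windows.
#'
#' @param n series length (or a [pressure_series()], whose row count is
#'   used).
#' @param min_window minimum window length (default 3).
#' @return List of integer `c(start, end)` pairs (inclusive, 1-based);
#'   empty when `n < min_window`.
#' @export
enumerate_segments <- function(n, min_window = 3) {
  if (inherits(n, "pressure_series")) n <- nrow(n)
  stopifnot(is.numeric(n), length(n) == 1, min_window >= 2)
  n <- as.integer(n)
  if (n < min_window) return(list())
  out <- list()
  k <- 0
  for (start in seq_len(n - min_window + 1)) {
    for (end in seq(start + min_window - 1, n)) {
      k <- k + 1
      out[[k]] <- c(start = start, end = end)
    }
  }
  out
}

#' Least-squares fit of one candidate window
#'
#' Ordinary least squares of amplitude on IOP over a contiguous window,
#' with Pearson correlation and the zero-amplitude x-intercept
#' `-intercept / slope` (the quantity that, for the selected rising
#' segment, estimates sitting ICP).
#'
#' @param series a [pressure_series()].
#' @param window integer `c(start, end)`, inclusive 1-based indices.
#' @return An object of class `"segment_fit"`: `start_index`, `end_index`,
#'   `n_points`, `slope` (au/mmHg), `intercept` (au), `pearson_r`,
#'   `x_intercept` (mmHg, `NA` unless slope > 0), `max_amplitude` (au, the
#'   window's own maximum).
#' @examples
#' s <- pressure_series(c(20, 25, 30), c(5, 10, 15))
#' fit_segment(s, c(1, 3))  # slope 1, r 1, x-intercept 15
#' @export
fit_segment <- function(series, window) {
  stopifnot(inherits(series, "pressure_series"), length(window) == 2)
  i <- window[1]; j <- window[2]
  if (i < 1 || j > nrow(series) || i >= j)
    stop("invalid window")
  x <- series$iop[i:j]
  y <- series$amplitude[i:j]
  if (length(unique(x)) < 2)
    stop("degenerate-fit error: zero IOP variance in window")
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  r <- suppressWarnings(stats::cor(x, y))      # NA when amplitude variance 0
  structure(
    list(start_index = as.integer(i), end_index = as.integer(j),
         n_points = as.integer(j - i + 1), slope = slope,
         intercept = intercept, pearson_r = r,
         x_intercept = if (is.finite(slope) && slope > 0) -intercept / slope
                       else NA_real_,
         max_amplitude = max(y)),
    class = "segment_fit")
}

#' @export
print.segment_fit <- function(x, ...) {
  cat(sprintf(
    "Segment [%d..%d] (%d pts): slope %.4g au/mmHg, r %.4g, x-intercept %.4g mmHg\n",
    x$start_index, x$end_index, x$n_points, x$slope, x$pearson_r,
    x$x_intercept))
  invisible(x)
}

#' Select the rising segment among candidate window fits
#'
#' Applies the retention filters of the three-phase algorithm and picks
#' the winner: windows with Pearson correlation below `r_min` (signed;
#' undefined correlation also fails), slope below `slope_min`, or whose own
#' maximum amplitude is below `amp_min` are discarded; among the survivors
#' the fit with the highest slope is selected, ties broken by longer
#' window, then lower start index.
#'
#' @param fits list of [fit_segment()] results from the truncated series.
#' @param cal a [calibration_params()] (thresholds `r_min`, `slope_min`,
#'   `amp_min`).
#' @return The selected `"segment_fit"`; when no window survives, an
#'   object of class `"segment_rejection"` whose `reason` element is
#'   `"flat amplitude slope"` (nothing passed the slope/correlation
#'   filters) or `"max amplitude < <amp_min> au"` (no window reached the
#'   amplitude floor).
#' @export
select_rising_segment <- function(fits, cal = calibration_params()) {
  stopifnot(inherits(cal, "calibration_params"))
  if (length(fits) == 0)
    return(structure(list(reason = "flat amplitude slope"),
                     class = "segment_rejection"))
  slope <- vapply(fits, `[[`, 0, "slope")
  r <- vapply(fits, function(f) {
    v <- f$pearson_r
    if (is.na(v)) -Inf else v
  }, 0)
  max_amp <- vapply(fits, `[[`, 0, "max_amplitude")
  keep <- is.finite(slope) & slope >= cal$slope_min & r >= cal$r_min &
    max_amp >= cal$amp_min
  if (!any(keep)) {
    reason <- if (all(max_amp < cal$amp_min))
      sprintf("max amplitude < %g au", cal$amp_min)
    else "flat amplitude slope"
    return(structure(list(reason = reason), class = "segment_rejection"))
  }
  idx <- which(keep)
  n_points <- vapply(fits, function(f) as.numeric(f$n_points), 0)[idx]
  start <- vapply(fits, function(f) as.numeric(f$start_index), 0)[idx]
  ord <- order(-slope[idx], -n_points, start)
  fits[[idx[ord[1]]]]
}

#' @export
print.segment_rejection <- function(x, ...) {
  cat(sprintf("No rising segment retained: %s\n", x$reason))
  invisible(x)
}

#' Estimate sitting ICP from one amplitude-versus-IOP series
#'
#' The core estimator. The three-phase model of the amplitude curve — flat
#' while IOP is below ICP, rising once IOP exceeds ICP, plateau/falling at
#' high IOP — is handled in four steps: (1) truncate the series at its
#' amplitude peak, discarding the plateau-to-falling phase; (2) enumerate
#' every window of at least `min_window` consecutive pairs; (3) fit each by
#' ordinary least squares; (4) keep windows with Pearson r >= `r_min`,
#' slope >= `slope_min` au/mmHg and window maximum amplitude >= `amp_min`
#' au, and select the survivor with the highest slope. The selected rising
#' segment is extrapolated back to zero amplitude; its x-intercept is the
#' estimated sitting ICP (where pulse amplitude vanishes, IOP theoretically
#' equals the downstream CSF pressure).
#'
#' A series failing every filter is an exclusion, not an error: flat
#' amplitude slopes (typical of advanced papilloedema compressing the
#' central retinal vein, where elevated ICP is likely) or insufficient
#' amplitude are reported as the exclusion reason.
#'
#' @param series a [pressure_series()].
#' @param cal a [calibration_params()].
#' @return An object of class `"icp_fit"`: `series`, `truncated`, `fits`
#'   (all candidate window fits), `segment` (the selected
#'   [fit_segment()] or `NULL`), `x_intercept_sitting` (mmHg, `NA` when
#'   excluded), `excluded`, `reason`, `eye`, `hemifield`, `cal`.
#'   Methods: [print.icp_fit()], [summary.icp_fit()], [coef.icp_fit()],
#'   [predict.icp_fit()], [fitted.icp_fit()], [residuals.icp_fit()],
#'   [plot.icp_fit()].
#' @examples
#' law <- amplitude_law_params(icp_true = 24, baseline_amp = 0,
#'                             rising_slope = 1.2, peak_iop = 44)
#' s <- synth_pressure_series(law, protocol_params(), seed = 1)
#' fit <- icp_fit(s)
#' fit$x_intercept_sitting  # 24 exactly (noiseless generator)
#' @export
icp_fit <- function(series, cal = calibration_params()) {
  stopifnot(inherits(series, "pressure_series"),
            inherits(cal, "calibration_params"))
  exclude <- function(reason, truncated = NULL, fits = list()) {
    structure(
      list(series = series, truncated = truncated, fits = fits,
           segment = NULL, x_intercept_sitting = NA_real_,
           excluded = TRUE, reason = reason,
           eye = attr(series, "eye"), hemifield = attr(series, "hemifield"),
           cal = cal),
      class = "icp_fit")
  }
  if (nrow(series) == 0 || isTRUE(attr(series, "unusable")))
    return(exclude("unusable series: no retained recordings"))
  truncated <- truncate_at_peak(series)
  if (nrow(truncated) < cal$min_window) {
    # too few pairs at or below the amplitude peak: no usable rising phase.
    # Classify as the paper-style exclusion categories rather than a third
    # reason: a curve that never reaches the amplitude floor is a
    # low-amplitude exclusion, anything else is a flat-slope exclusion.
    reason <- if (max(series$amplitude) < cal$amp_min)
      sprintf("max amplitude < %g au", cal$amp_min)
    else "flat amplitude slope"
    return(exclude(reason, truncated))
  }
  windows <- enumerate_segments(nrow(truncated), cal$min_window)
  fits <- list()
  for (w in windows) {
    if (length(unique(truncated$iop[w[1]:w[2]])) < 2) next  # degenerate
    fits[[length(fits) + 1]] <- fit_segment(truncated, w)
  }
  sel <- select_rising_segment(fits, cal)
  if (inherits(sel, "segment_rejection"))
    return(exclude(sel$reason, truncated, fits))
  structure(
    list(series = series, truncated = truncated, fits = fits,
         segment = sel, x_intercept_sitting = sel$x_intercept,
         excluded = FALSE, reason = NA_character_,
         eye = attr(series, "eye"), hemifield = attr(series, "hemifield"),
         cal = cal),
    class = "icp_fit")
}

#' Convert a sitting ICP to the lateral-decubitus convention
#'
#' `ICP_LD = ICP_sitting + postural_offset` (default +10 mmHg): CSF
#' pressure at eye level is about 10 mmHg higher lying on the side — the
#' lumbar-puncture posture — than sitting.
#'
#' @param icp_sitting sitting-convention ICP, mmHg (vectorised).
#' @param cal a [calibration_params()].
#' @return Lateral-decubitus ICP in mmHg.
#' @examples
#' to_lateral_decubitus(c(1, 24))  # 11, 34
#' @export
to_lateral_decubitus <- function(icp_sitting, cal = calibration_params()) {
  stopifnot(inherits(cal, "calibration_params"))
  if (any(!is.finite(icp_sitting)))
    stop("icp_sitting must be finite")
  icp_sitting + cal$postural_offset
}

#' Combine up to four per-dataset estimates into one subject-level ICP
#'
#' Most subjects contribute four datasets (superior and inferior hemiveins
#' of both eyes); the subject-level estimate is the arithmetic mean of the
#' non-excluded x-intercepts. The result is reported in the requested
#' posture convention: `"lateral_decubitus"` adds the postural offset (for
#' comparison against lumbar puncture), `"sitting"` does not (for EVD
#' subjects measured seated). If every dataset is excluded the subject is
#' excluded; when the reason is a flat amplitude slope the report carries
#' an alert that elevated intracranial pressure is likely (papilloedema can
#' suppress vein pulsation).
#'
#' @param fits list of [icp_fit()] objects (or numeric sitting
#'   x-intercepts).
#' @param target_posture `"lateral_decubitus"` or `"sitting"`.
#' @param cal a [calibration_params()].
#' @return An object of class `"icp_subject"`: `per_dataset` (data frame
#'   `eye`, `hemifield`, `x_intercept_sitting`, `excluded`, `reason`),
#'   `icp_sitting`, `icp_ld`, `icp_estimate` (in the target convention),
#'   `target_posture`, `n_datasets_used`, `excluded`, `reason`, `alert`.
#' @examples
#' combine_subject(list(10, 12, 11, 13))$icp_ld  # mean 11.5 + 10 = 21.5
#' @export
combine_subject <- function(fits,
                            target_posture = c("lateral_decubitus", "sitting"),
                            cal = calibration_params()) {
  target_posture <- match.arg(target_posture)
  stopifnot(length(fits) >= 1, length(fits) <= 4)
  rows <- lapply(fits, function(f) {
    if (is.numeric(f)) {
      data.frame(eye = NA_character_, hemifield = NA_character_,
                 x_intercept_sitting = f, excluded = FALSE,
                 reason = NA_character_)
    } else {
      stopifnot(inherits(f, "icp_fit"))
      data.frame(eye = as.character(f$eye), hemifield = as.character(f$hemifield),
                 x_intercept_sitting = f$x_intercept_sitting,
                 excluded = f$excluded, reason = as.character(f$reason))
    }
  })
  per_dataset <- do.call(rbind, rows)
  used <- !per_dataset$excluded
  if (!any(used)) {
    flat <- grepl("flat amplitude slope", per_dataset$reason)
    return(structure(
      list(per_dataset = per_dataset, icp_sitting = NA_real_,
           icp_ld = NA_real_, icp_estimate = NA_real_,
           target_posture = target_posture,
           n_datasets_used = 0L, excluded = TRUE,
           reason = paste(unique(per_dataset$reason), collapse = "; "),
           alert = if (any(flat))
             "elevated intracranial pressure is likely" else NA_character_),
      class = "icp_subject"))
  }
  icp_sitting <- mean(per_dataset$x_intercept_sitting[used])
  icp_ld <- to_lateral_decubitus(icp_sitting, cal)
  structure(
    list(per_dataset = per_dataset, icp_sitting = icp_sitting,
         icp_ld = icp_ld,
         icp_estimate = if (target_posture == "lateral_decubitus") icp_ld
                        else icp_sitting,
         target_posture = target_posture,
         n_datasets_used = sum(used), excluded = FALSE,
         reason = NA_character_, alert = NA_character_),
    class = "icp_subject")
}

#' @export
print.icp_subject <- function(x, ...) {
  cat("Subject-level ICP estimate\n")
  if (x$excluded) {
    cat(sprintf("  excluded: %s\n", x$reason))
    if (!is.na(x$alert)) cat(sprintf("  alert: %s\n", x$alert))
  } else {
    cat(sprintf("  sitting %.2f mmHg | lateral decubitus %.2f mmHg (from %d dataset%s)\n",
                x$icp_sitting, x$icp_ld, x$n_datasets_used,
                if (x$n_datasets_used == 1) "" else "s"))
  }
  invisible(x)
}

# ---- icp_fit methods -------------------------------------------------------

#' @export
print.icp_fit <- function(x, ...) {
  cat("Retinal-vein PPG ICP fit\n")
  cat(sprintf("  series: %d pairs (%s eye, %s hemivein), %d after peak truncation\n",
              nrow(x$series), x$eye, x$hemifield,
              if (is.null(x$truncated)) 0L else nrow(x$truncated)))
  if (x$excluded) {
    cat(sprintf("  excluded: %s\n", x$reason))
  } else {
    s <- x$segment
    cat(sprintf("  rising segment [%d..%d]: slope %.3f au/mmHg, r = %.3f\n",
                s$start_index, s$end_index, s$slope, s$pearson_r))
    cat(sprintf("  estimated ICP: %.2f mmHg sitting (%.2f mmHg lateral decubitus)\n",
                x$x_intercept_sitting,
                to_lateral_decubitus(x$x_intercept_sitting, x$cal)))
  }
  invisible(x)
}

#' Summary of an ICP fit
#'
#' @param object an [icp_fit()] object.
#' @param ... unused.
#' @return Invisibly, a data frame of every candidate window fit with its
#'   filter outcome.
#' @export
summary.icp_fit <- function(object, ...) {
  print(object)
  if (length(object$fits)) {
    cal <- object$cal
    tab <- do.call(rbind, lapply(object$fits, function(f)
      data.frame(start = f$start_index, end = f$end_index, n = f$n_points,
                 slope = f$slope, r = f$pearson_r,
                 max_amp = f$max_amplitude, x_intercept = f$x_intercept)))
    tab$retained <- is.finite(tab$slope) & tab$slope >= cal$slope_min &
      !is.na(tab$r) & tab$r >= cal$r_min & tab$max_amp >= cal$amp_min
    cat(sprintf("  %d candidate windows, %d pass the filters (r >= %.2g, slope >= %.2g, max amp >= %.2g)\n",
                nrow(tab), sum(tab$retained), cal$r_min, cal$slope_min,
                cal$amp_min))
    invisible(tab)
  } else invisible(NULL)
}

#' @export
coef.icp_fit <- function(object, ...) {
  if (object$excluded) return(c(intercept = NA_real_, slope = NA_real_))
  c(intercept = object$segment$intercept, slope = object$segment$slope)
}

#' Predicted amplitude from the selected rising segment
#'
#' @param object an [icp_fit()] object.
#' @param newdata optional data frame with column `iop` (mmHg); default is
#'   the IOPs of the selected window.
#' @param ... unused.
#' @return Predicted amplitudes (au) on the rising-segment line.
#' @export
predict.icp_fit <- function(object, newdata = NULL, ...) {
  if (object$excluded) stop("no rising segment was selected")
  iop <- if (is.null(newdata)) {
    s <- object$segment
    object$truncated$iop[s$start_index:s$end_index]
  } else newdata$iop
  object$segment$intercept + object$segment$slope * iop
}

#' @export
fitted.icp_fit <- function(object, ...) predict(object)

#' @export
residuals.icp_fit <- function(object, ...) {
  if (object$excluded) stop("no rising segment was selected")
  s <- object$segment
  object$truncated$amplitude[s$start_index:s$end_index] - fitted(object)
}

#' Plot an ICP fit
#'
#' Amplitude against induced IOP with the peak-truncated points filled,
#' the selected rising segment highlighted, and its regression line
#' extrapolated (dashed) back through the x-axis; the x-intercept — the
#' estimated sitting ICP — is marked.
#'
#' @param x an [icp_fit()] object.
#' @param y ignored.
#' @param ... passed to [graphics::plot()].
#' @export
plot.icp_fit <- function(x, y, ...) {
  s <- x$series
  xlim <- range(c(s$iop, x$x_intercept_sitting), na.rm = TRUE)
  graphics::plot(s$iop, s$amplitude, xlim = xlim,
                 ylim = c(0, max(s$amplitude) * 1.05),
                 xlab = "Induced IOP (mmHg)",
                 ylab = "Max pulse amplitude (au)", pch = 1, ...)
  if (!is.null(x$truncated))
    graphics::points(x$truncated$iop, x$truncated$amplitude, pch = 19)
  if (!x$excluded) {
    seg <- x$segment
    sel_iop <- x$truncated$iop[seg$start_index:seg$end_index]
    graphics::points(sel_iop,
                     x$truncated$amplitude[seg$start_index:seg$end_index],
                     pch = 19, col = "red3")
    graphics::segments(x$x_intercept_sitting, 0, max(sel_iop),
                       seg$intercept + seg$slope * max(sel_iop),
                       lty = 2, col = "red3")
    graphics::points(x$x_intercept_sitting, 0, pch = 4, cex = 1.5,
                     col = "red3")
    graphics::mtext(sprintf("estimated ICP (sitting) = %.1f mmHg",
                            x$x_intercept_sitting), side = 3, line = 0.2,
                    cex = 0.9)
  } else {
    graphics::mtext(paste("excluded:", x$reason), side = 3, line = 0.2,
                    cex = 0.9)
  }
  invisible(x)
}
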