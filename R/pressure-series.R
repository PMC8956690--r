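#' Pressure series: maximum pulse amplitude against induced IOP
#'
#' One ordered series of (induced IOP, maximum hemivein pulse amplitude)
#' pairs for one hemivein of one eye — the input to [icp_fit()]. Pairs are
#' sorted by ascending IOP; ties keep acquisition order (duplicate IOP
#' settings are retained as independent observations).
#'
#' @param iop induced intraocular pressures, mmHg.
#' @param amplitude maximum pulse amplitudes, arbitrary units (au).
#' @param eye `"right"`, `"left"` or `NA`.
#' @param hemifield `"superior"`, `"inferior"` or `NA`.
#' @param posture posture of acquisition (default `"sitting"`; the PPG
#'   examination is performed seated at a slit lamp, so x-intercepts from
#'   these series are sitting-convention ICP estimates).
#' @return A data frame of class `"pressure_series"` with columns `iop` and
#'   `amplitude` and attributes `eye`, `hemifield`, `posture`.
#' @export
pressure_series <- function(iop, amplitude, eye = NA_character_,
                            hemifield = NA_character_, posture = "sitting") {
  stopifnot(is.numeric(iop), is.numeric(amplitude),
            length(iop) == length(amplitude))
  if (length(iop) && (any(!is.finite(iop)) || any(!is.finite(amplitude))))
    stop("pressure series values must be finite")
  ord <- order(iop)  # stable: ties keep acquisition order
  df <- data.frame(iop = as.numeric(iop[ord]),
                   amplitude = as.numeric(amplitude[ord]))
  structure(df, eye = eye, hemifield = hemifield, posture = posture,
            class = c("pressure_series", "data.frame"))
}

as_pressure_series <- function(df, template = NULL) {
  pressure_series(df$iop, df$amplitude,
                  eye = if (is.null(template)) NA_character_ else attr(template, "eye"),
                  hemifield = if (is.null(template)) NA_character_ else attr(template, "hemifield"),
                  posture = if (is.null(template)) "sitting" else attr(template, "posture"))
}

#' @export
print.pressure_series <- function(x, ...) {
  cat(sprintf("Pressure series (%s eye, %s hemivein, %s posture), %d pairs:\n",
              attr(x, "eye"), attr(x, "hemifield"), attr(x, "posture"),
              nrow(x)))
  print(data.frame(iop_mmHg = x$iop, amplitude_au = x$amplitude), ...)
  invisible(x)
}

#' @describeIn pressure_series scatter of amplitude against induced IOP.
#' @param x,y,... plot method arguments (`y` is ignored).
#' @export
plot.pressure_series <- function(x, y, ...) {
  plot(x$iop, x$amplitude, xlab = "Induced IOP (mmHg)",
       ylab = "Max pulse amplitude (au)", pch = 19, ...)
  invisible(x)
}
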