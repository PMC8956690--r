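# Independent brute-force / closed-form oracles. Deliberately written with
# different idioms (scalar loops, textbook formulas) than the package code
# they check.

# piecewise amplitude law, scalar, explicit branches
oracle_amplitude_law <- function(iop, p) {
  vapply(iop, function(x) {
    if (x <= p$icp_true) {
      a <- p$baseline_amp
    } else if (x <= p$peak_iop) {
      a <- p$baseline_amp + p$rising_slope * (x - p$icp_true)
    } else {
      peak <- p$baseline_amp + p$rising_slope * (p$peak_iop - p$icp_true)
      a <- peak - p$fall_slope * (x - p$peak_iop)
    }
    max(a, 0)
  }, 0)
}

# peak truncation by definition: drop every pair whose IOP exceeds the IOP
# of the global amplitude maximum (lowest such IOP on ties)
oracle_truncate <- function(iop, amp) {
  best <- which(amp == max(amp))
  peak_iop <- min(iop[best])
  keep <- iop <= peak_iop
  list(iop = iop[keep], amp = amp[keep])
}

# exhaustive window enumeration via expand.grid
oracle_windows <- function(n, min_window = 3) {
  if (n < min_window) return(matrix(numeric(0), ncol = 2))
  g <- expand.grid(start = seq_len(n), end = seq_len(n))
  g <- g[g$end - g$start + 1 >= min_window, ]
  g <- g[order(g$start, g$end), ]
  as.matrix(g)
}

# textbook OLS and Pearson r
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  r <- if (syy == 0) NA_real_ else sxy / sqrt(sxx * syy)
  list(slope = slope, intercept = intercept, r = r,
       x_intercept = if (slope > 0) -intercept / slope else NA_real_)
}

# filter-then-argmax selection over raw (iop, amp) data, independent of the
# package's segment_fit objects
oracle_select <- function(iop, amp, min_window = 3, r_min = 0.8,
                          slope_min = 0.4, amp_min = 6) {
  best <- NULL
  n <- length(iop)
  if (n >= min_window) {
    for (i in 1:(n - min_window + 1)) {
      for (j in (i + min_window - 1):n) {
        x <- iop[i:j]; y <- amp[i:j]
        if (length(unique(x)) < 2) next
        o <- oracle_ols(x, y)
        if (is.na(o$r) || o$r < r_min) next
        if (!is.finite(o$slope) || o$slope < slope_min) next
        if (max(y) < amp_min) next
        cand <- list(start = i, end = j, n = j - i + 1, slope = o$slope,
                     x_intercept = o$x_intercept)
        if (is.null(best) ||
            cand$slope > best$slope ||
            (cand$slope == best$slope && cand$n > best$n) ||
            (cand$slope == best$slope && cand$n == best$n &&
             cand$start < best$start)) {
          if (is.null(best) || cand$slope > best$slope ||
              (cand$slope == best$slope &&
               (cand$n > best$n ||
                (cand$n == best$n && cand$start < best$start))))
            best <- cand
        }
      }
    }
  }
  best
}

# brute-force hemivein maximum: scalar loop over every pixel
oracle_hemivein_max <- function(map, roi, radius_mm = 0.8,
                                min_measures = 20) {
  h <- nrow(map$amplitudes); w <- ncol(map$amplitudes)
  vals <- numeric(0)
  for (r in 1:h) for (c in 1:w) {
    if (!roi$mask[r, c] || !map$valid[r, c]) next
    d <- sqrt((r - map$disk_centre[1])^2 + (c - map$disk_centre[2])^2) *
      map$mm_per_px
    if (d > radius_mm) next
    vals <- c(vals, map$amplitudes[r, c])
  }
  if (length(vals) < min_measures) list(rejected = TRUE, n = length(vals))
  else list(rejected = FALSE, n = length(vals), max = max(vals))
}

# discrete Fourier projection on evenly sampled integer-cycle data
oracle_fourier <- function(y, fps, freq, t0 = 0) {
  n <- length(y)
  t <- (0:(n - 1)) / fps - t0
  c(a0 = mean(y),
    a1 = 2 * mean(y * sin(2 * pi * freq * t)),
    b1 = 2 * mean(y * cos(2 * pi * freq * t)),
    a2 = 2 * mean(y * sin(4 * pi * freq * t)),
    b2 = 2 * mean(y * cos(4 * pi * freq * t)))
}

# random pressure series for property tests
random_series <- function(n = NULL) {
  if (is.null(n)) n <- sample(3:10, 1)
  iop <- sort(runif(n, 10, 45))
  amp <- runif(n, 0, 25)
  pressure_series(iop, amp)
}

# random amplitude map + ROI pair
random_map_roi <- function(h = 20, w = 20) {
  amp <- matrix(runif(h * w, 0, 30), h, w)
  valid <- matrix(runif(h * w) < 0.6, h, w)
  amp[!valid] <- NA
  map <- structure(list(amplitudes = amp, valid = valid,
                        disk_centre = c(runif(1, 5, h - 4), runif(1, 5, w - 4)),
                        mm_per_px = runif(1, 0.03, 0.1)),
                   class = "amplitude_map")
  mask <- matrix(runif(h * w) < 0.5, h, w)
  mask[1, 1] <- TRUE  # never empty
  roi <- vessel_roi(mask, "superior", "right")
  list(map = map, roi = roi)
}
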