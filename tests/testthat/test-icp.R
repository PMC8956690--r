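test_that("force calibration is linear with the 0.89 coefficient", {
  expect_equal(induced_iop(15, 0), 15)
  expect_equal(induced_iop(15, 10), 23.9)
  expect_equal(induced_iop(12, 30), 38.7)
  expect_equal(induced_iop(10, c(0, 10, 20)), c(10, 18.9, 27.8))
  expect_error(induced_iop(15, -1), "force")
  expect_error(induced_iop(0, 1), "baseline_iop")
})

test_that("peak truncation drops the plateau-to-falling phase", {
  s <- pressure_series(seq(20, 45, by = 5), c(1, 2, 5, 9, 8, 6))
  tr <- truncate_at_peak(s)
  expect_equal(tr$iop, c(20, 25, 30, 35))
  expect_equal(tr$amplitude, c(1, 2, 5, 9))

  mono <- pressure_series(seq(20, 45, by = 5), 1:6)
  expect_equal(nrow(truncate_at_peak(mono)), 6)   # peak at last point

  # amplitude tie: the lowest IOP is the peak
  tie <- pressure_series(c(20, 25, 30, 35), c(2, 9, 9, 5))
  expect_equal(truncate_at_peak(tie)$iop, c(20, 25))

  expect_error(truncate_at_peak(pressure_series(numeric(0), numeric(0))),
               "empty")

  # random series against the definitional oracle
  set.seed(41)
  for (i in 1:200) {
    s <- random_series()
    tr <- truncate_at_peak(s)
    o <- oracle_truncate(s$iop, s$amplitude)
    expect_equal(tr$iop, o$iop)
    expect_equal(tr$amplitude, o$amp)
  }
})

test_that("window enumeration counts all consecutive combinations", {
  expect_length(enumerate_segments(3), 1)
  expect_length(enumerate_segments(5), 6)       # lengths 3:3, 4:2, 5:1
  expect_length(enumerate_segments(2), 0)
  for (n in 3:12) {
    wins <- enumerate_segments(n)
    expect_length(wins, (n - 2) * (n - 1) / 2)  # sum_{L=3}^{n} (n - L + 1)
    got <- do.call(rbind, wins)
    expect_equal(unname(got), unname(oracle_windows(n)))
  }
})

test_that("segment fits match the textbook least-squares formulas", {
  s <- pressure_series(c(20, 25, 30), c(5, 10, 15))
  f <- fit_segment(s, c(1, 3))
  expect_equal(f$slope, 1)
  expect_equal(f$pearson_r, 1)
  expect_equal(f$x_intercept, 15)               # amplitude = iop - 15

  flat <- fit_segment(pressure_series(c(20, 25, 30), c(6, 6, 6)), c(1, 3))
  expect_equal(flat$slope, 0)
  expect_true(is.na(flat$pearson_r))            # zero amplitude variance
  expect_true(is.na(flat$x_intercept))

  expect_error(fit_segment(pressure_series(c(20, 20, 20), c(1, 2, 3)),
                           c(1, 3)), "degenerate")

  set.seed(43)
  for (i in 1:200) {
    s <- random_series()
    n <- nrow(s)
    w <- sort(sample(n, 2)); if (w[2] - w[1] < 1) next
    f <- fit_segment(s, w)
    o <- oracle_ols(s$iop[w[1]:w[2]], s$amplitude[w[1]:w[2]])
    expect_equal(f$slope, o$slope, tolerance = 1e-10)
    expect_equal(f$intercept, o$intercept, tolerance = 1e-10)
    if (!is.na(o$r)) expect_equal(f$pearson_r, o$r, tolerance = 1e-10)
  }
})

test_that("rising-segment selection filters and tie-breaks as specified", {
  mk <- function(slope, r = 0.95, max_amp = 10, n = 3, start = 1)
    structure(list(start_index = start, end_index = start + n - 1,
                   n_points = n, slope = slope, intercept = 0,
                   pearson_r = r, x_intercept = 1, max_amplitude = max_amp),
              class = "segment_fit")

  res <- select_rising_segment(list(mk(0.39)))
  expect_s3_class(res, "segment_rejection")
  expect_equal(res$reason, "flat amplitude slope")

  res <- select_rising_segment(list(mk(0.5, max_amp = 4)))
  expect_equal(res$reason, "max amplitude < 6 au")

  res <- select_rising_segment(list(mk(0.5), mk(1.2), mk(0.9)))
  expect_equal(res$slope, 1.2)

  # boundary values pass (exclusions are strict: "less than")
  res <- select_rising_segment(list(mk(0.4, r = 0.8, max_amp = 6)))
  expect_s3_class(res, "segment_fit")

  # ties: longer window, then earlier start
  res <- select_rising_segment(list(mk(1, n = 3, start = 2),
                                    mk(1, n = 4, start = 3),
                                    mk(1, n = 4, start = 1)))
  expect_equal(c(res$n_points, res$start_index), c(4, 1))

  # negative-slope windows fail both filters consistently (signed r)
  res <- select_rising_segment(list(mk(-1, r = -0.99)))
  expect_s3_class(res, "segment_rejection")
})

test_that("the full estimator equals the filter-then-argmax oracle on random series", {
  cal <- calibration_params()
  set.seed(47)
  checked <- 0
  for (i in 1:300) {
    s <- random_series(sample(4:9, 1))
    fit <- icp_fit(s, cal)
    tr <- oracle_truncate(s$iop, s$amplitude)
    o <- oracle_select(tr$iop, tr$amp)
    if (is.null(o)) {
      expect_true(fit$excluded)
    } else {
      checked <- checked + 1
      expect_false(fit$excluded)
      expect_equal(fit$x_intercept_sitting, o$x_intercept, tolerance = 1e-9)
      expect_equal(fit$segment$slope, o$slope, tolerance = 1e-9)
    }
  }
  expect_gt(checked, 20)   # the random family must exercise the accept path
})

test_that("noiseless synthetic series are recovered exactly", {
  proto <- protocol_params()
  # scenario mirroring an elevated-ICP eye: x-intercept 24 sitting
  law <- amplitude_law_params(24, baseline_amp = 0, rising_slope = 1.2,
                              peak_iop = 44)
  fit <- icp_fit(synth_pressure_series(law, proto))
  expect_equal(fit$x_intercept_sitting, 24, tolerance = 1e-9)

  set.seed(53)
  for (i in 1:40) {
    icp <- runif(1, -4, 20)
    law <- amplitude_law_params(icp, baseline_amp = 0,
                                rising_slope = runif(1, 0.5, 2.5),
                                peak_iop = icp + runif(1, 28, 34))
    fit <- icp_fit(synth_pressure_series(law, proto))
    expect_false(fit$excluded)
    expect_equal(fit$x_intercept_sitting, icp, tolerance = 1e-6)
  }
})

test_that("estimates are translation-equivariant and monotone in true ICP", {
  proto <- protocol_params()
  base <- amplitude_law_params(12, baseline_amp = 0, rising_slope = 1.2,
                               peak_iop = 42)
  s <- synth_pressure_series(base, proto)
  f0 <- icp_fit(s)
  for (delta in c(-3, 2.5, 7)) {
    shifted <- pressure_series(s$iop + delta, s$amplitude)
    expect_equal(icp_fit(shifted)$x_intercept_sitting,
                 f0$x_intercept_sitting + delta, tolerance = 1e-9)
  }

  icps <- seq(0, 14, by = 2)
  ests <- vapply(icps, function(icp) {
    law <- amplitude_law_params(icp, baseline_amp = 0, rising_slope = 1.2,
                                peak_iop = icp + 31)
    icp_fit(synth_pressure_series(law, proto))$x_intercept_sitting
  }, 0)
  expect_true(all(diff(ests) >= -1e-9))
})

test_that("flat and low-amplitude series are excluded with the stated reasons", {
  iop <- seq(15, 45, by = 5)
  flat <- icp_fit(pressure_series(iop, rep(8, 7)))        # slope 0, amp ok
  expect_true(flat$excluded)
  expect_equal(flat$reason, "flat amplitude slope")

  # steep enough (0.5 au/mmHg, r = 1) but peaking at 5 au
  low <- icp_fit(pressure_series(c(15, 20, 25), c(0, 2.5, 5)))
  expect_true(low$excluded)
  expect_equal(low$reason, "max amplitude < 6 au")

  # flat series at 5 au fails both ways but is certainly excluded
  expect_true(icp_fit(pressure_series(iop, rep(5, 7)))$excluded)
})

test_that("noisy estimates stay close to truth (Monte-Carlo)", {
  proto <- protocol_params()
  set.seed(59)
  errs <- replicate(300, {
    icp <- runif(1, 2, 18)
    law <- amplitude_law_params(icp, baseline_amp = 0, rising_slope = 1.2,
                                peak_iop = icp + 30, noise_sd = 0.5)
    f <- icp_fit(synth_pressure_series(law, proto))
    if (f$excluded) NA_real_ else abs(f$x_intercept_sitting - icp)
  })
  expect_lt(mean(is.na(errs)), 0.05)
  expect_lt(median(errs, na.rm = TRUE), 1.5)
})

test_that("posture conversion adds the fixed 10 mmHg offset", {
  expect_equal(to_lateral_decubitus(1), 11)
  expect_equal(to_lateral_decubitus(24), 34)
  expect_equal(to_lateral_decubitus(0), 10)
  expect_equal(to_lateral_decubitus(c(1, 24)), c(11, 34))
})

test_that("subject-level combination averages available datasets per posture", {
  est <- combine_subject(list(10, 12, 11, 13),
                         target_posture = "lateral_decubitus")
  expect_equal(est$icp_sitting, 11.5)
  expect_equal(est$icp_estimate, 21.5)

  one <- combine_subject(list(24), target_posture = "sitting")
  expect_equal(one$icp_estimate, 24)            # seated EVD: no offset

  iop <- seq(15, 45, by = 5)
  good1 <- icp_fit(synth_pressure_series(
    amplitude_law_params(10, baseline_amp = 0, peak_iop = 41),
    protocol_params()))
  good2 <- icp_fit(synth_pressure_series(
    amplitude_law_params(14, baseline_amp = 0, peak_iop = 45),
    protocol_params()))
  bad <- icp_fit(pressure_series(iop, rep(8, 7)))
  mix <- combine_subject(list(good1, bad, good2, bad))
  expect_equal(mix$n_datasets_used, 2)
  expect_equal(mix$icp_sitting, 12, tolerance = 1e-6)

  allbad <- combine_subject(list(bad, bad))
  expect_true(allbad$excluded)
  expect_equal(allbad$alert, "elevated intracranial pressure is likely")
})
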