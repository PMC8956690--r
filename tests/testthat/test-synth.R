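test_that("amplitude law matches its piecewise definition", {
  p <- amplitude_law_params(icp_true = 19, baseline_amp = 0,
                            rising_slope = 1, peak_iop = 40)
  expect_equal(amplitude_law(19, p), 0)          # knee point
  expect_equal(amplitude_law(30, p), 11)         # 1 * (30 - 19)
  expect_equal(amplitude_law(0, p), 0)

  # full protocol grid against the independent piecewise evaluator,
  # across randomly drawn parameter sets
  set.seed(11)
  grid <- protocol_iop_grid(protocol_params())
  for (i in 1:50) {
    icp <- runif(1, -5, 25)
    p <- amplitude_law_params(icp, baseline_amp = runif(1, 0, 3),
                              rising_slope = runif(1, 0.2, 3),
                              peak_iop = icp + runif(1, 5, 35),
                              fall_slope = runif(1, 0, 2))
    expect_equal(amplitude_law(grid, p), oracle_amplitude_law(grid, p))
  }
})

test_that("amplitude law is continuous and non-decreasing on the rising phase", {
  set.seed(21)
  for (i in 1:25) {
    icp <- runif(1, 0, 25)
    p <- amplitude_law_params(icp, baseline_amp = runif(1, 0, 4),
                              rising_slope = runif(1, 0.2, 3),
                              peak_iop = icp + runif(1, 4, 30),
                              fall_slope = runif(1, 0, 2))
    # continuity at both knees
    eps <- 1e-9
    expect_equal(amplitude_law(icp + eps, p), amplitude_law(icp, p),
                 tolerance = 1e-6)
    expect_equal(amplitude_law(p$peak_iop + eps, p),
                 amplitude_law(p$peak_iop, p), tolerance = 1e-6)
    # non-decreasing between knee and peak
    x <- seq(icp, p$peak_iop, length.out = 40)
    expect_true(all(diff(amplitude_law(x, p)) >= -1e-12))
  }
})

test_that("amplitude-law parameter validation rejects invalid inputs", {
  expect_error(amplitude_law_params(10, rising_slope = 0), "rising_slope")
  expect_error(amplitude_law_params(10, peak_iop = 9), "peak_iop")
  expect_error(amplitude_law_params(10, baseline_amp = -1), "baseline_amp")
  expect_error(amplitude_law_params(10, noise_sd = -0.1), "noise_sd")
  p <- amplitude_law_params(10)
  expect_error(amplitude_law(-1, p), "iop")
})

test_that("synthetic pressure series is the law on the grid, reproducible, with calibrated noise", {
  proto <- protocol_params()
  p0 <- amplitude_law_params(18, noise_sd = 0)
  s0 <- synth_pressure_series(p0, proto)
  expect_s3_class(s0, "pressure_series")
  expect_equal(s0$iop, seq(15, 45, by = 5))
  expect_equal(s0$amplitude, amplitude_law(s0$iop, p0))   # noiseless: exact

  p <- amplitude_law_params(18, noise_sd = 0.5)
  a <- synth_pressure_series(p, proto, seed = 7)
  b <- synth_pressure_series(p, proto, seed = 7)
  expect_identical(a$amplitude, b$amplitude)              # bit-reproducible

  # Monte-Carlo: per-point sample sd of the noise within 10% of 0.5
  set.seed(5)
  reps <- replicate(1000, synth_pressure_series(p, proto)$amplitude)
  sds <- apply(reps, 1, sd)
  expect_true(all(abs(sds - 0.5) / 0.5 < 0.10))
})

test_that("phantom geometry satisfies the retention-friendly invariants", {
  g <- phantom_geometry()
  expect_false(any(g$superior_mask & g$inferior_mask))
  d <- sqrt(outer((seq_len(g$height) - g$disk_centre[1])^2,
                  (seq_len(g$width) - g$disk_centre[2])^2, "+")) * g$mm_per_px
  expect_gte(sum(g$superior_mask & d <= 0.8), 20)
  expect_gte(sum(g$inferior_mask & d <= 0.8), 20)
  expect_true(all(g$weight >= 0 & g$weight <= 1))
})

test_that("phantom video has the protocol frame count and exact beat times", {
  g <- suppressWarnings(phantom_geometry(height = 16, width = 16))
  p <- amplitude_law_params(15)
  proto <- protocol_params(fps = 25, n_cycles = 3, cardiac_freq = 1.25)
  st <- synth_video(g, p, proto, iop = 30, seed = 1)
  expect_equal(dim(st$frames)[1], 60)           # ceil(3 * 25 / 1.25)
  expect_equal(st$beat_times, seq(0, 60 / 25, by = 1 / 1.25))
  st2 <- synth_video(g, p, proto, iop = 30, seed = 1)
  expect_identical(st$frames, st2$frames)       # bit-reproducible
})

test_that("harmonic analysis recovers the amplitude injected into a phantom pixel", {
  g <- suppressWarnings(phantom_geometry(height = 12, width = 12, vein_halfwidth = 1))
  proto <- protocol_params(n_cycles = 4)
  p <- amplitude_law_params(icp_true = 15, rising_slope = 1, peak_iop = 45,
                            noise_sd = 0)
  iop <- 30
  st <- synth_video(g, p, proto, iop = iop)
  tab <- fit_stack(st)
  injected <- amplitude_law(iop, p)
  vessel <- g$weight > 0
  got <- tab$amplitude[tab$valid]
  # every vessel pixel carries weight 1: recovery within 1%
  expect_equal(sum(tab$valid), sum(vessel))
  expect_true(all(abs(got - injected) / injected < 0.01))
})

test_that("zero injected amplitude is rejected by the significance filter in >= 95% of seeds", {
  proto <- protocol_params(n_cycles = 4)
  g <- suppressWarnings(phantom_geometry(height = 8, width = 8))
  p <- amplitude_law_params(icp_true = 20, noise_sd = 0.5)
  # at IOP <= icp_true with baseline 0 the injected amplitude is zero:
  # a vessel pixel then carries pure noise
  set.seed(99)
  n_frames <- ceiling(proto$n_cycles * proto$fps / proto$cardiac_freq)
  rejected <- 0L
  n_seeds <- 400
  for (i in seq_len(n_seeds)) {
    series <- rnorm(n_frames, 0, 0.5)
    f <- fit_two_harmonics(series, proto$fps, proto$cardiac_freq)
    if (is.na(pixel_amplitude(f))) rejected <- rejected + 1L
  }
  expect_gte(rejected / n_seeds, 0.95)
})

test_that("synthetic cohorts are deterministic with both posture conventions stored", {
  coh <- synth_cohort(3, icp_sampler = function(n) rep(9, n), seed = 4)
  expect_equal(coh$truth$icp_true_sitting, rep(9, 3))
  expect_equal(coh$truth$icp_true_ld, rep(19, 3))      # +10 offset
  expect_equal(coh$truth$invasive, rep(19, 3))         # LP subjects in LD
  expect_length(coh$subjects[[1]]$datasets, 4)

  evd <- synth_cohort(2, icp_sampler = function(n) rep(9, n), seed = 4,
                      posture = "sitting")
  expect_equal(evd$truth$invasive, rep(9, 2))          # seated EVD: no offset

  c1 <- synth_cohort(2, seed = 12)
  c2 <- synth_cohort(2, seed = 12)
  expect_identical(c1$subjects[[2]]$datasets[[3]]$amplitude,
                   c2$subjects[[2]]$datasets[[3]]$amplitude)
})

test_that("seeded generators restore the caller's RNG state", {
  set.seed(1); before <- .Random.seed
  invisible(synth_pressure_series(amplitude_law_params(10, noise_sd = 1),
                                  protocol_params(), seed = 5))
  expect_identical(.Random.seed, before)
})
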