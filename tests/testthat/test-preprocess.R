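test_that("the HRF kernel has the canonical double-gamma shape", {
  k <- hrfKernel(10, 32)
  expect_length(k, 320L)
  expect_equal(sum(k), 1)

  # positive lobe peaks at the gamma(6, 1) mode, t ~ 5 s
  expect_equal((which.max(k) - 1) / 10, 5.0, tolerance = 0.1)

  # one sign change: positive lobe then a single undershoot
  s <- sign(k[abs(k) > 1e-12])
  expect_equal(sum(diff(s) != 0), 1L)

  expect_error(hrfKernel(0), "positive")
  expect_error(hrfKernel(10, -1), "positive")
})

test_that("HRF low-pass preserves constants and attenuates fast bands", {
  n <- 2000
  const <- asPreprocessed(matrix(3.7, n, 1))
  out <- recordingData(hrfLowpass(const))
  expect_equal(as.numeric(out), rep(3.7, n), tolerance = 1e-9)

  set.seed(1)
  noise <- asPreprocessed(matrix(rnorm(n), n, 1))
  expect_lt(var(recordingData(hrfLowpass(noise))), var(recordingData(noise)))

  # attenuation of a 1.2 Hz (cardiac band) sinusoid matches the kernel's
  # frequency response at 1.2 Hz
  fs <- 10; f0 <- 1.2
  tt <- (0:(n - 1)) / fs
  x <- sin(2 * pi * f0 * tt)
  y <- recordingData(hrfLowpass(asPreprocessed(matrix(x, n, 1))))
  k <- hrfKernel(fs)
  H <- abs(sum(k * exp(-2i * pi * f0 * (seq_along(k) - 1) / fs)))
  core <- 400:1600  # away from the padded edges
  fit <- lm(y[core] ~ sin(2 * pi * f0 * tt[core]) + cos(2 * pi * f0 * tt[core]))
  amp <- sqrt(sum(coef(fit)[-1]^2))
  expect_equal(amp, H, tolerance = 0.02 * max(H, 1e-6))
})

test_that("detrending removes slow drift but keeps the signal", {
  fs <- 10; n <- 6000
  tt <- (0:(n - 1)) / fs

  # pure linear ramp vanishes
  ramp <- asPreprocessed(matrix(seq(0, 5, length.out = n), n, 1))
  out <- recordingData(detrendRecording(ramp, cutoffS = 128))
  expect_lt(max(abs(out)), 0.01 * 5)

  # slow sinusoidal drift + VAR signal: lag-1 autocovariance preserved
  set.seed(2)
  clean <- generateVarSeries(matrix(0.5, 1, 1), n, seed = 11)
  drift <- 1.0 * sin(2 * pi * 0.004 * tt)
  dirty <- asPreprocessed(matrix(clean + drift, n, 1))
  det <- recordingData(detrendRecording(dirty, cutoffS = 128))
  acovClean <- cov(clean[-1], clean[-n])
  acovDet <- cov(det[-1], det[-n])
  expect_equal(acovDet, acovClean, tolerance = 0.05 * abs(acovClean))
  expect_lt(abs(mean(det)), 1e-8)

  # drift-free stationary input passes through nearly unchanged
  det2 <- recordingData(detrendRecording(asPreprocessed(matrix(clean, n, 1)),
                                         cutoffS = 128))
  expect_gt(cor(det2, clean), 0.99)

  expect_error(detrendRecording(ramp, cutoffS = 1000), "shorter than")
})

test_that("the wavelet-MDL-style detrend behaves like a drift remover", {
  fs <- 10; n <- 4000
  tt <- (0:(n - 1)) / fs
  set.seed(3)
  clean <- generateVarSeries(matrix(0.5, 1, 1), n, seed = 12)
  dirty <- asPreprocessed(matrix(clean + 3 * sin(2 * pi * 0.004 * tt) +
                                   seq(0, 4, length.out = n), n, 1))
  det <- recordingData(detrendRecording(dirty, method = "wavelet_mdl",
                                        cutoffS = 128))
  expect_lt(abs(mean(det)), 0.05)
  expect_gt(cor(det, clean), 0.9)
})

test_that("two-point baseline correction zeroes the reference windows", {
  fs <- 10; n <- 400

  const <- asPreprocessed(matrix(2.5, n, 1))
  expect_equal(as.numeric(recordingData(baselineCorrect(const))),
               rep(0, n), tolerance = 1e-12)

  ramp <- asPreprocessed(matrix(seq(-1, 7, length.out = n), n, 1))
  expect_equal(as.numeric(recordingData(baselineCorrect(ramp))),
               rep(0, n), tolerance = 1e-9)

  # a mid-session step survives; the jump equals the step height minus
  # one sample of the two-point line's slope h / (tPost - tPre)
  h <- 1.8
  w <- 2 * fs
  tPre <- mean(1:w); tPost <- mean((n - w + 1):n)
  x <- c(rep(0, n / 2), rep(h, n / 2))
  out <- as.numeric(recordingData(baselineCorrect(asPreprocessed(matrix(x, n, 1)))))
  expect_equal(out[n / 2 + 1] - out[n / 2], h - h / (tPost - tPre),
               tolerance = 1e-9)
  expect_lt(abs(mean(out[1:w])), 1e-9)
  expect_lt(abs(mean(out[(n - w + 1):n])), 1e-9)

  short <- asPreprocessed(matrix(1, 10, 1))
  expect_error(baselineCorrect(short), "baseline")
})

test_that("the chain runs in fixed order, once, and per channel", {
  set.seed(4)
  raw <- NirsRecording("p1", 7, "own", 10, matrix(rnorm(2000 * 3), 2000, 3))
  pp <- preprocessRecording(raw)
  expect_true(isPreprocessed(pp))
  steps <- vapply(provenance(pp), `[[`, character(1), "step")
  expect_equal(steps, c("hrf_lowpass", "detrend", "baseline_correct"))
  expect_error(preprocessRecording(pp), "already preprocessed")

  # permuting channels commutes with preprocessing (no spatial leakage)
  perm <- c(3, 1, 2)
  rawPerm <- NirsRecording("p1", 7, "own", 10, recordingData(raw)[, perm])
  expect_equal(recordingData(preprocessRecording(rawPerm)),
               recordingData(pp)[, perm], tolerance = 1e-12)
})
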