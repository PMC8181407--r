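test_that("the stimulation high-pass removes physiological-band content", {
  fs <- 2000
  t <- (0:9999) / fs
  x <- sin(2 * pi * 10 * t)
  y <- highpassStim(x, fs)
  expect_lt(mean(y^2) / mean(x^2), 0.01)
  expect_identical(highpassStim(numeric(100), fs), numeric(100))
  expect_warning(highpassStim(rnorm(100), fs = 800), "clamped")
})

test_that("the energy operator satisfies its algebraic identities", {
  # constant signal -> zero
  expect_true(all(nleo(rep(3.7, 100)) == 0))
  # sinusoid -> A^2 sin^2(omega) on interior samples
  A <- 1.4; om <- 0.3
  x <- A * sin(om * (1:200))
  e <- nleo(x)
  expect_equal(e[2:199], rep(A^2 * sin(om)^2, 198), tolerance = 1e-10)
  # unit impulse -> 1 at the impulse, 0 elsewhere
  imp <- numeric(101); imp[51] <- 1
  ei <- nleo(imp)
  expect_equal(ei[51], 1)
  expect_equal(sum(ei), 1)
  # quadratic amplitude scaling
  set.seed(2)
  z <- rnorm(500)
  expect_equal(nleo(3 * z), 9 * nleo(z), tolerance = 1e-12)
  expect_error(nleo(c(1, 2)), "3 samples")
})

test_that("wavelet segmentation finds stimuli and is scale-invariant", {
  wf <- waveformSpec()
  st <- stimulusTemplate(wf)
  x <- numeric(12000)
  onsets <- 1000 + (0:9) * 1000
  for (o in onsets) x[o + seq_along(st)] <- st
  det <- waveletSegments(x, k = 0.01)
  expect_true(all(det$detection >= 0))
  # every stimulus is covered by a segment with a nearby peak
  for (o in onsets) {
    expect_true(any(abs(det$segments$peak - o) <= 6))
  }
  # segment peaks attain the segment maximum
  for (r in seq_len(nrow(det$segments))) {
    seg <- det$segments[r, ]
    vals <- det$detection[(seg$start + 1):seg$end]
    expect_equal(det$detection[seg$peak + 1], max(vals))
  }
  # std-relative threshold: doubling the amplitude changes nothing
  det2 <- waveletSegments(2 * x, k = 0.01)
  expect_identical(det$segments, det2$segments)
  # zero signal -> no segments
  expect_equal(nrow(waveletSegments(numeric(1000), k = 0.01)$segments), 0)
})

test_that("NLEO segmentation isolates a lone activity from quiet noise", {
  set.seed(31)
  at <- atrialTemplate(waveformSpec())
  x <- rnorm(2000, sd = 0.002)           # noise floor far below the wave
  x[800 + seq_along(at)] <- x[800 + seq_along(at)] + at
  det <- nleoSegments(x, k = 0.01)
  lat_abs <- 800 + attr(at, "lat_ref")
  hit <- det$segments$start <= lat_abs & lat_abs < det$segments$end
  expect_true(any(hit))
  # all detected segments sit on the wave, none on the bare noise
  expect_true(all(det$segments$peak > 760 & det$segments$peak < 880))
  # zero signal reports no activity
  expect_equal(nrow(nleoSegments(numeric(500), k = 0.01)$segments), 0)
})

test_that("segment boundaries are invariant under amplitude scaling", {
  set.seed(4)
  at <- atrialTemplate(waveformSpec())
  x <- rnorm(1500, sd = 0.01)
  x[500 + seq_along(at)] <- x[500 + seq_along(at)] + at
  a <- nleoSegments(x, k = 0.05)$segments
  b <- nleoSegments(5 * x, k = 0.05)$segments
  expect_identical(a, b)
})

test_that("NLEO peak is stable within a sample at 20 dB SNR", {
  at <- atrialTemplate(waveformSpec())
  lat_abs <- 300 + attr(at, "lat_ref")
  p_sig <- mean((c(numeric(300), at, numeric(300)))^2)
  errs <- vapply(1:20, function(s) {
    nz <- noiseFromSpectrum(635, 1000, seed = s)
    nz <- scaleNoiseToSnr(c(numeric(300), at, numeric(300)), nz, 20,
                          signal_power = p_sig)
    x <- c(numeric(300), at, numeric(300)) + nz
    det <- nleoSegments(x, k = 0.01)
    pk <- det$segments[which.max(det$detection[det$segments$peak + 1]), ]
    ctr <- s1s2seg:::.energy_centroid(det$detection, pk$peak + 1L, 10L) - 1L
    ctr - lat_abs
  }, numeric(1))
  expect_true(all(abs(errs) <= 1))
})
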