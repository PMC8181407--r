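test_that("spectrum noise is seed-reproducible with seed-independent power", {
  n1 <- noiseFromSpectrum(4000, 1000, seed = 1)
  n1b <- noiseFromSpectrum(4000, 1000, seed = 1)
  n2 <- noiseFromSpectrum(4000, 1000, seed = 2)
  expect_identical(n1, n1b)
  expect_false(identical(n1, n2))
  # power is set by the magnitudes, not the phases
  pows <- vapply(1:10, function(s)
    mean(noiseFromSpectrum(4000, 1000, seed = s)^2), numeric(1))
  expect_lt(diff(range(pows)) / mean(pows), 0.05)
  expect_lt(abs(mean(n1)), 1e-12)
})

test_that("a pure-tone reference concentrates the output power there", {
  fs <- 1000
  ref <- sin(2 * pi * 50 * (0:1999) / fs)
  spec <- noiseSpec("reference_segment", reference = ref)
  x <- noiseFromSpectrum(4000, fs, spec, seed = 3)
  pg <- Mod(fft(x))^2
  f <- (seq_along(pg) - 1) * fs / length(pg)
  at50 <- sum(pg[abs(f - 50) < 2 | abs(f - (fs - 50)) < 2])
  expect_gt(at50 / sum(pg[-1]), 0.95)
  expect_error(noiseFromSpectrum(4000, fs,
                                 noiseSpec("reference_segment",
                                           reference = ref[1:500])),
               "1 s")
})

test_that("baseline wander has the specified band and peak amplitude", {
  fs <- 1000
  w <- baselineWander(60000, fs, atrial_amplitude = 2, seed = 5)
  expect_equal(max(abs(w)), 4, tolerance = 0.01)
  pg <- Mod(fft(w))^2
  f <- (seq_along(pg) - 1) * fs / length(pg)
  band <- f > 0 & f <= 5.5
  above <- f > 5.5 & f <= fs / 2
  expect_lt(10 * log10(sum(pg[above]) / sum(pg[band])), -40)
  expect_identical(baselineWander(1000, fs, 0, seed = 1), numeric(1000))
})

test_that("noise scaling hits the requested SNR", {
  set.seed(9)
  sig <- rnorm(5000)
  nz <- rnorm(5000, sd = 0.1)
  # equal powers, target 0 dB -> unit factor
  n1 <- scaleNoiseToSnr(sig, sig, 0)
  expect_equal(attr(n1, "scale"), 1, tolerance = 1e-12)
  # power ratio 100, target 0 dB -> amplitude factor 10
  nz100 <- sig * 0.1
  expect_equal(attr(scaleNoiseToSnr(sig, nz100, 0), "scale"), 10,
               tolerance = 1e-9)
  # target = current SNR -> identity
  cur <- 10 * log10(mean(sig^2) / mean(nz^2))
  expect_equal(attr(scaleNoiseToSnr(sig, nz, cur), "scale"), 1,
               tolerance = 1e-9)
  expect_error(scaleNoiseToSnr(sig, numeric(10), 0), "zero power")
})

test_that("post-scaling SNR equals the target within 0.1 dB", {
  for (s in 1:5) {
    set.seed(s)
    sig <- rnorm(3000) * runif(1, 0.5, 3)
    nz <- noiseFromSpectrum(3000, 1000, seed = s + 100)
    target <- runif(1, -10, 40)
    sc <- scaleNoiseToSnr(sig, nz, target)
    got <- 10 * log10(mean(sig^2) / mean(sc^2))
    expect_lt(abs(got - target), 0.1)
  }
})
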