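test_that("peak-to-peak voltage behaves on elementary signals", {
  expect_equal(peakToPeak(rep(2.5, 100)), 0)
  t <- (0:999) / 1000
  expect_equal(peakToPeak(1.3 * sin(2 * pi * 5 * t)), 2.6, tolerance = 1e-3)
  at <- atrialTemplate(waveformSpec())
  expect_equal(peakToPeak(as.numeric(at)), 2)
  expect_equal(peakToPeak(seq(0, 9), c(2, 5)), 2)  # half-open window
  expect_error(peakToPeak(1:10, c(5, 5)), "empty")
})

test_that("mesh reading and geodesic distances work on a flat plane", {
  path <- fx_flat_mesh_off()
  mesh <- readSurfaceMesh(path)
  expect_equal(ncol(mesh$vertices), 3)
  expect_true(all(mesh$triangles >= 1 & mesh$triangles <= nrow(mesh$vertices)))
  a <- c(0, 0, 0); b <- c(50, 50, 0)
  g <- s1s2seg:::.geodesic_distance(mesh, a, b)
  eu <- sqrt(sum((a - b)^2))
  # geodesic >= Euclidean, and near-Euclidean on a plane (edge-path excess)
  expect_gte(g, eu - 1e-9)
  expect_lt(g / eu, 1.5)
  # straight along a grid axis the edge path is exact
  g2 <- s1s2seg:::.geodesic_distance(mesh, c(0, 0, 0), c(50, 0, 0))
  expect_equal(g2, 50)
})

test_that("bipole distances pick the metric by catheter membership", {
  rec <- fx_sim0()$recording
  d12 <- bipoleDistance(rec, 1, 2)
  geo <- bipoleGeometry(catheterLayout())
  expect_equal(d12, sqrt(sum((geo$centers[1, ] - geo$centers[2, ])^2)))
  expect_equal(bipoleDistance(rec, 1, 10), 35)  # CS1 at 35 mm
  expect_error(bipoleDistance(rec, 1, 10, mode = "geodesic"),
               "requires a mesh")
})

test_that("propagation speed is distance over activation time", {
  expect_equal(propagationSpeed(35, 50), 700)
  expect_error(propagationSpeed(35, 0), "non-causal")
  expect_error(propagationSpeed(35, -2), "non-causal")
  p0 <- propagationSpeed(0, 10)
  expect_equal(as.numeric(p0), 0)
  expect_equal(attr(p0, "degenerate"), 1L)
  # homogeneity: doubling distances doubles speeds exactly
  expect_equal(propagationSpeed(2 * c(10, 20, 35), c(15, 30, 50)),
               2 * propagationSpeed(c(10, 20, 35), c(15, 30, 50)))
})

test_that("noise-free restitution curves reproduce the ground truth", {
  sim <- fx_sim0()
  run <- fx_run0()
  cv <- run$curves
  # amplitude curves match the configured decay within 0.05 mV
  amp <- cv[cv$quantity == "amplitude", ]
  truth_amp <- ampAt(sim$model, amp$s2_ms, sim$spec$erp)
  expect_true(all(abs(amp$value - truth_amp) <= 0.05))
  # refractory trains are absent, curves keyed by decreasing interval
  expect_true(all(amp$s2_ms >= 200))
  for (ch in unique(amp$channel))
    expect_true(all(diff(amp$s2_ms[amp$channel == ch]) < 0))
  # per-channel speed curves are monotone non-decreasing in the interval
  sp <- cv[cv$quantity == "propagation_speed", ]
  for (ch in unique(sp$channel)) {
    v <- sp$value[sp$channel == ch][order(sp$s2_ms[sp$channel == ch])]
    expect_true(all(diff(v) >= -1e-9))
  }
})

test_that("the two stretch-matched circular bipoles share a speed curve", {
  sp <- fx_run0()$curves
  sp <- sp[sp$quantity == "propagation_speed", ]
  v3 <- sp$value[sp$channel_name == "PV3"]
  v5 <- sp$value[sp$channel_name == "PV5"]
  # pointwise values differ by sampling quantization of the LAT; the
  # curve means agree within 1%
  expect_lt(abs(mean(v3) - mean(v5)) / mean(v3), 0.01)
})

test_that("speed asymptotes recover the model velocity within 2%", {
  sim <- fx_sim0()
  run <- fx_run0()
  geo <- bipoleGeometry(sim$layout)
  sp <- run$curves[run$curves$quantity == "propagation_speed", ]
  lats1 <- assignLats(sim$layout, sim$model, s2 = Inf)
  for (ch in unique(sp$channel)) {
    d <- sqrt(sum((geo$centers[ch, ] - geo$centers[1, ])^2))
    expected <- d / lats1[ch] * 1000   # cv0 adjusted for anisotropy
    got <- sp$value[sp$channel == ch][which.max(sp$s2_ms[sp$channel == ch])]
    # 2% plus the half-sample LAT quantization bound at 1 kHz
    tol <- 0.02 + 0.5 / lats1[ch]
    expect_lt(abs(got - expected) / expected, tol)
  }
  # amplitude asymptote recovers amp0 within 2%
  amp <- run$curves[run$curves$quantity == "amplitude", ]
  top <- amp$value[amp$s2_ms == 500]
  expect_true(all(abs(top - sim$model$amp0) / sim$model$amp0 < 0.02))
})

test_that("amplitude curves are unaffected by the artifact amplitude", {
  sim_big <- buildProtocol(waveforms = waveformSpec(stim_amplitude = 9.4))
  run_big <- runPipeline(sim_big$recording)
  a0 <- fx_run0()$curves
  a0 <- a0[a0$quantity == "amplitude", ]
  ab <- run_big$curves[run_big$curves$quantity == "amplitude", ]
  m <- merge(a0, ab, by = c("channel", "s2_ms"))
  expect_true(all(abs(m$value.x - m$value.y) < 0.02))
})

test_that("the stimulating channel and its neighbors are omitted by default", {
  # bipole 2 shares an electrode with the stimulating bipole; with nine
  # overlapping bipoles over ten electrodes the ring does not close, so
  # bipole 9 is not adjacent
  cvs <- fx_run0()$curves
  expect_false(any(cvs$channel_name %in% c("PV1", "PV2")))
  expect_true("PV9" %in% cvs$channel_name)
  # the neighbor is retained on request
  sim <- fx_sim0()
  run_all <- buildCurves(fx_run0()$detections, fx_run0()$protocol,
                         sim$recording, refractory = fx_run0()$erp$refractory,
                         exclude_neighbors = FALSE)
  expect_true("PV2" %in% run_all$channel_name)
})

test_that("the exponential fit recovers a curve's asymptote", {
  s2 <- seq(200, 500, 10)
  val <- 650 - 300 * exp(-s2 / 60)
  fit <- fitRestitution(s2, val)
  expect_equal(unname(fit["A"]), 650, tolerance = 1e-3)
})
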