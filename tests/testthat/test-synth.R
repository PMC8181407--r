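test_that("activation times follow the anisotropic conduction model", {
  layout <- catheterLayout()
  # isotropic limit: LAT = Euclidean distance / cv
  iso <- restitutionModel(anisotropy = 1)
  lats <- assignLats(layout, iso, s2 = Inf)
  geo <- bipoleGeometry(layout)
  d <- sqrt(colSums((t(geo$centers) - geo$centers[1, ])^2))
  expect_equal(unname(lats), unname(1000 * d / 650))
  # CS bipole at 35 mm on the fiber axis: 35 / 650 mm/s = 53.85 ms
  lats_a <- assignLats(layout, restitutionModel(), s2 = Inf)
  expect_equal(unname(lats_a["CS1"]), 35 / 650 * 1000, tolerance = 1e-6)
  # stimulating bipole has LAT 0 by convention
  expect_equal(unname(lats_a["PV1"]), 0)
  # the two bipoles with equal anisotropic stretch share one speed ratio
  expect_equal(unname(d[3] / lats_a[3]), unname(d[5] / lats_a[5]),
               tolerance = 1e-9)
})

test_that("restitution curves are monotone and asymptote to the baselines", {
  m <- restitutionModel()
  s2 <- seq(200, 800, 10)
  expect_true(all(diff(ampAt(m, s2, erp = 200)) >= 0))
  expect_true(all(diff(cvAt(m, s2, erp = 200)) >= 0))
  expect_equal(ampAt(m, 1e6, erp = 200), m$amp0)
  expect_equal(cvAt(m, 1e6, erp = 200), m$cv0)
})

test_that("default protocol has the reference structure", {
  sim <- fx_sim0()
  tr <- sim$truth
  expect_equal(length(unique(tr$train)), 21)         # 21 pacing trains
  expect_equal(length(sim$stim_times), 21 * 5)       # 4 S1 + 1 S2 each
  # capture iff the coupling interval reaches the ERP
  s2 <- tr[tr$label == "S2", ]
  expect_true(all(s2$capture == (s2$s2_ms >= 200)))
  # the last two trains produce no atrial activity
  expect_equal(sort(unique(s2$train[!s2$capture])), c(20, 21))
  # 171 captured channel x S2 response slots on the circular bipoles
  expect_equal(sum(s2$capture & s2$catheter == "PV") + 19, 171)
  # (the stimulating bipole carries no response row; its 19 slots counted)
})

test_that("overlap fractions match the geometric design", {
  tr <- fx_sim0()$truth
  ov <- tr[!is.na(tr$overlap), ]
  # no CS channel overlaps the stimulation artifact
  expect_true(all(ov$overlap[ov$catheter == "CS"] == 0))
  # exactly one circular channel exceeds 50% overlap
  per_ch <- tapply(ov$overlap[ov$catheter == "PV"],
                   ov$channel[ov$catheter == "PV"], max)
  expect_equal(sum(per_ch > 0.5), 1L)
  # overlap decreases for slower (shorter-coupling) responses
  pv2 <- ov[ov$channel == 2 & ov$label == "S2", ]
  expect_true(all(diff(pv2$overlap[order(-pv2$s2_ms)]) <= 0))
})

test_that("ground-truth amplitudes follow the restitution decay", {
  tr <- fx_sim0()$truth
  s2 <- tr[tr$label == "S2" & tr$capture %in% TRUE & tr$channel == 10, ]
  s2 <- s2[order(s2$s2_ms), ]
  expect_true(all(diff(s2$amplitude) >= 0))
  expect_equal(max(s2$amplitude), ampAt(restitutionModel(), 500, 200))
})

test_that("extra beats are placed away from existing events and labeled", {
  sim <- fx_sim0()
  expect_identical(insertExtraBeats(sim, 0)$truth, sim$truth)
  simx <- insertExtraBeats(sim, 20, seed = 11)
  extra <- simx$truth[simx$truth$label == "extra", ]
  expect_equal(nrow(extra), 20)
  busy <- c(sim$stim_times, sim$truth$t_act[!is.na(sim$truth$t_act)])
  expect_true(all(vapply(extra$t_act,
                         function(t) min(abs(t - busy)) > 50, logical(1))))
  # same seed reproduces the same placement
  simy <- insertExtraBeats(sim, 20, seed = 11)
  expect_identical(simy$truth$t_act, simx$truth$t_act)
  # an over-dense request fails after bounded retries
  short <- buildProtocol(protocolSpec(s2_intervals = c(500, 450)))
  expect_error(insertExtraBeats(short, 5000, seed = 1, max_tries = 10L),
               "too dense")
})
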