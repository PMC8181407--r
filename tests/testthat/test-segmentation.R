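test_that("the stimulating channel is found by amplitude plus adjacency", {
  sim <- fx_sim0()
  expect_equal(findStimChannel(sim$recording), 1L)
  # a one-off high-amplitude spike in a non-neighboring channel does not
  # hijack the ranking
  rec <- sim$recording
  rec@signals[5000, 7] <- rec@signals[5000, 7] + 10
  expect_equal(findStimChannel(rec), 1L)
  # two neighboring channels: the larger one wins
  rec2 <- fx_tiny_rec()
  rec2@signals[, 1] <- rec2@signals[, 1] * 5
  expect_equal(findStimChannel(rec2), 1L)
  rec3 <- fx_tiny_rec()
  rec3@positions <- rep(list(list()), 2)
  expect_error(findStimChannel(rec3), "geometry")
})

test_that("S1 cycle length is recovered exactly on the clean protocol", {
  est <- estimateS1Bcl(fx_sim0()$recording)
  expect_true(est$converged)
  expect_equal(est$s1_bcl_ms, 600)
  expect_gte(est$k, 0.01)
})

test_that("a uniform pulse train yields its interval as the cycle length", {
  st <- stimulusTemplate(waveformSpec())
  x <- numeric(20000)
  for (i in 0:20) x[1000 + i * 437 + seq_along(st)] <- st
  rec <- EgmRecording(cbind(a = x, b = 0.8 * x), kind = "unipolar",
                      positions = list(list(matrix(c(0, 0, 0), 1)),
                                       list(matrix(c(2, 0, 0), 1))))
  est <- estimateS1Bcl(rec, stim_channel = 1)
  expect_equal(est$s1_bcl_ms, 437)
})

test_that("extra beats do not disturb the cycle-length histogram", {
  for (nb in c(20, 80)) {
    sim <- insertExtraBeats(fx_sim0(), nb, seed = 7)
    est <- estimateS1Bcl(sim$recording)
    expect_equal(est$s1_bcl_ms, 600, tolerance = 1 / 600)  # within 1 sample
  }
})

test_that("protocol estimation uses nothing but the signal", {
  # shuffled channel metadata must not change the estimate
  sim <- fx_sim0()
  rec <- sim$recording
  colnames(rec@signals) <- rev(colnames(rec@signals))
  est <- estimateS1Bcl(rec, stim_channel = 1)
  expect_equal(est$s1_bcl_ms, 600)
})

test_that("two-means interval clustering splits pacing trains", {
  sp <- splitTrains(s1s2seg:::.smp2ms(sort(fx_protocol0()$annotations$peak),
                                      1000), 600)
  expect_length(sp$trains, 21)
  expect_equal(sp$n_s1_per_train, 4)
  expect_equal(sp$inter_train_gap_ms, 1200)
  # a constructed two-train protocol with 3 S1 each
  pt <- c(0, 600, 1200, 1650, 3650, 4250, 4850, 5300)
  sp2 <- splitTrains(pt, 600)
  expect_length(sp2$trains, 2)
  expect_equal(sp2$n_s1_per_train, 3)
  expect_equal(sp2$s2_intervals_ms, c(450, 450))
})

test_that("narrow train gaps trigger the unreliable-separation warning", {
  pt <- c(0, 600, 1200, 1800, 1800 + 660, 1800 + 660 + 600,
          1800 + 660 + 1200, 1800 + 660 + 1800)
  expect_warning(splitTrains(pt, 600), "unreliable train separation")
})

test_that("all genuine stimuli are trusted on the clean protocol", {
  sim <- fx_sim0()
  pe <- fx_protocol0()
  expect_equal(nrow(pe$annotations), 105)
  # every simulated stimulus has a trusted annotation nearby
  for (st in sim$stim_times)
    expect_true(any(abs(pe$annotations$peak - st) <= 6))
  # nothing spurious was trusted
  expect_true(all(vapply(pe$annotations$peak,
                         function(p) min(abs(p - sim$stim_times)) <= 6,
                         logical(1))))
})

test_that("a single-channel artifact fails the synchrony quorum", {
  sim <- fx_sim0()
  rec <- sim$recording
  st <- stimulusTemplate(sim$waveforms)
  at0 <- 35000L  # quiet spot between trains
  rec@signals[at0 + seq_along(st), 4] <- rec@signals[at0 + seq_along(st), 4] +
    st
  pe <- segmentProtocol(rec)
  expect_false(any(abs(pe$annotations$peak - at0) <= 20))
  expect_equal(nrow(pe$annotations), 105)
})

test_that("a stimulus off the cycle grid is discarded by the interval rule", {
  # synthetic artifact injected on ALL channels 15 samples off the S1 grid:
  # passes synchrony and amplitude conditions, fails C4
  sim <- fx_sim0()
  rec <- sim$recording
  st <- stimulusTemplate(sim$waveforms)
  off <- sim$stim_times[2] + 315L  # 600/2 + 15: inside a train, off-grid
  for (ch in seq_len(nChannels(rec)))
    rec@signals[off + seq_along(st), ch] <-
      rec@signals[off + seq_along(st), ch] + st
  pe <- segmentProtocol(rec)
  expect_false(any(abs(pe$annotations$peak - off) <= 10))
})

test_that("S1/S2 tagging labels one S2 per complete train", {
  pe <- fx_protocol0()
  expect_equal(sum(pe$annotations$label == "S2"), 21)
  expect_false(any(pe$incomplete))
  # per train: the S2 is the last stimulus
  for (tr in unique(pe$annotations$train_index)) {
    lab <- pe$annotations$label[pe$annotations$train_index == tr]
    expect_equal(lab, c(rep("S1", 4), "S2"))
  }
  # a single-train recording without S2 is flagged incomplete
  ann <- activityAnnotation(channel = 1, start = c(0, 600, 1200) * 1L,
                            peak = c(2, 602, 1202), end = c(10, 610, 1210),
                            label = "S1", train_index = NA, trusted = TRUE)
  sp <- list(trains = list(1:3), n_s1_per_train = 3L)
  tagged <- tagS1S2(ann, sp, 600)
  expect_true(attr(tagged, "incomplete")[1])
})

test_that("inferred S2 coupling intervals match the protocol exactly", {
  pe <- fx_protocol0()
  expect_equal(pe$s2_intervals_ms,
               c(seq(500, 350, -50), seq(340, 180, -10)))
  expect_equal(pe$n_trains, 21)
  expect_equal(pe$stim_channel, 1)
})

test_that("cycle length recovery is exact across a BCL grid", {
  for (bcl in c(400, 500, 800)) {
    spec <- protocolSpec(s1_bcl = bcl,
                         s2_intervals = seq(0.8 * bcl, 0.4 * bcl,
                                            -0.1 * bcl),
                         inter_train_gap = 2 * bcl, erp = 0.35 * bcl)
    sim <- buildProtocol(spec)
    pe <- segmentProtocol(sim$recording)
    expect_equal(pe$s1_bcl_ms, bcl)
    expect_equal(pe$n_trains, length(spec$s2_intervals))
    expect_equal(pe$s2_intervals_ms, spec$s2_intervals)
  }
})
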