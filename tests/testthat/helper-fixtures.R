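# Shared fixtures, built once per test run and cached. Everything is
# generated in code; no data files.

.fx <- new.env(parent = emptyenv())

fx_sim0 <- function() {
  if (is.null(.fx$sim0)) .fx$sim0 <- buildProtocol()
  .fx$sim0
}

fx_protocol0 <- function() {
  if (is.null(.fx$pe0)) .fx$pe0 <- segmentProtocol(fx_sim0()$recording)
  .fx$pe0
}

fx_run0 <- function() {
  if (is.null(.fx$run0)) .fx$run0 <- runPipeline(fx_sim0()$recording)
  .fx$run0
}

fx_score0 <- function() {
  if (is.null(.fx$score0)) {
    sim <- fx_sim0()
    .fx$score0 <- scoreRun(fx_run0()$detections, sim$truth,
                           exclude = overlapChannels(sim$truth))
  }
  .fx$score0
}

# reduced SNR sweep shared by the robustness criterion and the
# monotone-degradation property
fx_sweep <- function() {
  if (is.null(.fx$sweep)) {
    .fx$sweep <- snrSweep(snr_grid_db = c(40, 20, 10, 0, -10), seeds = 1:3)
  }
  .fx$sweep
}

# small two-catheter recording with unit geometry for IO tests
fx_tiny_rec <- function(n = 1000, fs = 1000, seed = 42) {
  set.seed(seed)
  sig <- cbind(a = rnorm(n, sd = 0.1), b = rnorm(n, sd = 0.1))
  EgmRecording(sig, samplingRate = fs, kind = "bipolar", catheter = "PV",
               positions = list(
                 list(matrix(c(0, 0, 0), 1), matrix(c(2, 0, 0), 1)),
                 list(matrix(c(2, 0, 0), 1), matrix(c(4, 0, 0), 1))))
}

# a flat square triangulated mesh written as ASCII OFF, returned as a path
fx_flat_mesh_off <- function(n = 6, spacing = 10) {
  path <- tempfile(fileext = ".off")
  grid <- expand.grid(x = seq_len(n), y = seq_len(n))
  verts <- cbind((grid$x - 1) * spacing, (grid$y - 1) * spacing, 0)
  id <- function(i, j) (j - 1) * n + i
  tris <- list()
  for (i in seq_len(n - 1)) for (j in seq_len(n - 1)) {
    tris[[length(tris) + 1]] <- c(id(i, j), id(i + 1, j), id(i, j + 1))
    tris[[length(tris) + 1]] <- c(id(i + 1, j), id(i + 1, j + 1), id(i, j + 1))
  }
  con <- file(path, "w")
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(verts), length(tris)), con)
  for (r in seq_len(nrow(verts)))
    writeLines(paste(verts[r, ], collapse = " "), con)
  for (t in tris) writeLines(paste(c(3, t - 1), collapse = " "), con)
  close(con)
  path
}
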