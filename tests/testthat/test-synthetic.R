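test_that("generation is deterministic for a fixed seed", {
  arch <- defaultArchetypes()
  seqs <- rep(c("sine", "biphasic"), 10)
  g1 <- generateRecording(arch, seqs, snrDb = 20, warpPct = 0.2, seed = 77)
  g2 <- generateRecording(arch, seqs, snrDb = 20, warpPct = 0.2, seed = 77)
  expect_identical(flowSamples(g1$recording), flowSamples(g2$recording))
  expect_identical(g1$truth, g2$truth)
  g3 <- generateRecording(arch, seqs, snrDb = 20, warpPct = 0.2, seed = 78)
  expect_false(identical(flowSamples(g1$recording),
                         flowSamples(g3$recording)))
})

test_that("noise-free half-sine cycles have exact duration and boundaries", {
  arch <- defaultArchetypes()
  g <- generateRecording(arch["sine"], rep("sine", 10), fs = 250, seed = 1)
  # nominal 3.0 s; each phase duration rounds to whole samples
  expect_lte(abs(durations(g$recording) - 3.0), 20 / 250)
  seg <- segmentRecording(g$recording)
  expect_equal(nCycles(seg), 10)
  idx <- matchTruth(seg, g$truth)
  expect_lte(max(abs(seg@tIn - g$truth$t_in[idx])), 1)
  expect_lte(max(abs(seg@tOut - g$truth$t_out[idx])), 1)
})

test_that("cycle counts survive noise at 20 dB SNR within one cycle", {
  arch <- defaultArchetypes()
  for (s in 1:3) {
    seqs <- withr::with_seed(s, sample(names(arch), 80, replace = TRUE))
    g <- generateRecording(arch, seqs, snrDb = 20, warpPct = 0.2,
                           seed = 300 + s)
    seg <- segmentRecording(g$recording)
    expect_lte(abs(nCycles(seg) - nrow(g$truth)), 1)
  }
})

test_that("each noise-free cycle has zero net volume", {
  arch <- defaultArchetypes()
  g <- generateRecording(arch, c("sine", "biphasic", "delayed",
                                 "pause_short", "pause_long"), seed = 2)
  fl <- flowSamples(g$recording)
  for (i in seq_len(nrow(g$truth))) {
    cyc <- fl[g$truth$t_in[i]:(g$truth$t_end[i] - 1)]
    niv <- sum(cyc[cyc > 0]) / 250
    expect_lte(abs(sum(cyc) / 250), 0.01 * niv)
  }
})

test_that("degenerate generator parameters are rejected", {
  arch <- defaultArchetypes()
  expect_error(generateRecording(arch, rep("sine", 3), warpPct = 0.7),
               "warpPct")
  expect_error(generateRecording(arch, c("sine", "nope")), "unknown")
  expect_error(generateRecording(arch, rep("sine", 3), noiseSd = 1,
                                 snrDb = 20), "either")
  expect_error(cycleArchetype("bad", ti = -1), "durations")
})

test_that("cohort mixtures reproduce their class fractions", {
  arch <- defaultArchetypes()
  mix <- c(sine = 0.5, biphasic = 0.3, pause_long = 0.2)
  coh <- generateCohort(3, "g", list(g = mix), arch,
                        cyclesPerRecording = 600, seed = 5)
  arcs <- unlist(lapply(coh, function(x) x$truth$archetype))
  n <- length(arcs)
  expect_equal(n, 1800)
  for (nm in names(mix)) {
    p <- mix[[nm]]
    tol <- 3 * sqrt(n * p * (1 - p))
    expect_lte(abs(sum(arcs == nm) - n * p), tol)
  }
  expect_error(generateCohort(2, "g", list(g = c(sine = 0.5)), arch),
               "sum to 1")
})

test_that("one-hot mixtures give a single archetype", {
  arch <- defaultArchetypes()
  coh <- generateCohort(2, "g", list(g = c(biphasic = 1)), arch,
                        cyclesPerRecording = 20, seed = 9)
  expect_true(all(unlist(lapply(coh, function(x)
    x$truth$archetype)) == "biphasic"))
})

test_that("subsampling saturates and spaces selections evenly in time", {
  arch <- defaultArchetypes()
  coh <- generateCohort(2, "g", list(g = c(sine = 1)), arch,
                        cyclesPerRecording = 120, seed = 13)
  # saturation: ask for more than available
  expect_message(
    trainAll <- subsampleTraining(coh, 500),
    "only")
  expect_equal(trainAll$nCycles, sum(trainAll$perRecording))
  expect_true(all(trainAll$perRecording <= 120))
  # even selection: max gap between selected start times bounded
  train <- subsampleTraining(coh, 40)
  expect_equal(train$nCycles, 80)
  for (sid in names(coh)) {
    sel <- sort(train$inspiration@startIndex[
      train$inspiration@sourceId == sid])
    gaps <- diff(sel)
    expect_lte(max(gaps), 2 * mean(gaps))
  }
  # pairing: inspiration and expiration sets are cycle-aligned
  expect_equal(length(train$inspiration), length(train$expiration))
  expect_identical(train$inspiration@sourceId, train$expiration@sourceId)
})

test_that("symbol accuracy evaluation matches an obvious case", {
  arch <- defaultArchetypes()
  g <- generateRecording(arch, rep("sine", 30), snrDb = 25, seed = 3)
  seg <- segmentRecording(g$recording)
  ph <- splitPhases(g$recording, seg)
  mi <- suppressMessages(fitKmeans(ph$inspiration, K = 1, nIter = 2,
                                   seed = 1))
  me <- suppressMessages(fitKmeans(ph$expiration, K = 1, nIter = 2,
                                   seed = 1))
  sym <- symbolize(g$recording, fitThresholds(mi, 1), fitThresholds(me, 1))
  acc <- symbolAccuracy(sym, g$truth, arch)
  expect_equal(acc$accuracy, 1)
  expect_equal(acc$classifiedFraction, 1)
})
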