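# A small fitted pair of models on a noise-free generated recording, shared
# across the tests below.
localModels <- local({
  arch <- defaultArchetypes()
  seqs <- withr::with_seed(2, sample(c("sine", "biphasic", "pause_long"),
                                     90, replace = TRUE))
  g <- generateRecording(arch, seqs, snrDb = 25, warpPct = 0.15, seed = 33)
  seg <- segmentRecording(g$recording)
  ph <- splitPhases(g$recording, seg)
  mi <- suppressMessages(fitKmeans(ph$inspiration, K = 2, radius = 0.01,
                                   nIter = 5, seed = 1))
  me <- suppressMessages(fitKmeans(ph$expiration, K = 2, radius = 0.01,
                                   nIter = 5, seed = 2))
  list(g = g, seg = seg, ph = ph, mi = mi, me = me)
})

test_that("thresholds at alpha = 1 are the per-cluster maxima", {
  m <- fitThresholds(localModels$mi, 1.0)
  expect_equal(unname(thresholds(m)),
               vapply(m@withinDistances, max, numeric(1)))
  # no training member exceeds its own threshold
  for (k in seq_along(m@withinDistances))
    expect_true(all(m@withinDistances[[k]] <= thresholds(m)[k] + 1e-12))
})

test_that("the quantile threshold leaves the expected count above it", {
  m <- localModels$mi
  m@withinDistances <- list(as.numeric(1:100), rep(2.5, 7))
  m@labels <- c("A", "B")
  m@references <- m@references[1:2]
  m <- fitThresholds(m, 0.95)
  expect_equal(sum(m@withinDistances[[1]] > m@thresholds[1]), 5)
  # degenerate distribution: threshold equals the common value
  expect_equal(m@thresholds[2], 2.5)
  expect_error(fitThresholds(m, 0), "alpha")
  expect_error(fitThresholds(m, 1.2), "alpha")
})

test_that("symbolizing the training recording is 1-NN consistent", {
  mi <- fitThresholds(localModels$mi, 1.0)
  me <- fitThresholds(localModels$me, 1.0)
  sym <- symbolize(localModels$g$recording, mi, me)
  cyc <- as.data.frame(sym)
  cl <- cyc[cyc$classified, ]
  expect_equal(nrow(cl), length(mi@assignments))
  # assigned letters equal the training clusters, and nothing is an outlier
  expect_equal(cl$insp_symbol, mi@labels[mi@assignments])
  expect_equal(cl$exp_symbol, me@labels[me@assignments])
  expect_false(any(cl$outlier))
})

test_that("training outlier fractions respect the quantile level", {
  alpha <- 0.95
  for (m in list(fitThresholds(localModels$mi, alpha),
                 fitThresholds(localModels$me, alpha))) {
    for (k in seq_along(m@withinDistances)) {
      d <- m@withinDistances[[k]]
      frac <- mean(d > m@thresholds[k])
      expect_lte(frac, (1 - alpha) + 1 / length(d))
    }
  }
})

test_that("symbols are invariant to uniform amplitude scaling", {
  mi <- fitThresholds(localModels$mi, 0.95)
  me <- fitThresholds(localModels$me, 0.95)
  rec <- localModels$g$recording
  scaled <- Recording(3 * flowSamples(rec), samplingRate(rec),
                      subjectId = subjectId(rec))
  s1 <- symbolize(rec, mi, me)
  s2 <- symbolize(scaled, mi, me)
  expect_equal(symbols(s1), symbols(s2))
})

test_that("shapes far from all references become outliers", {
  mi <- fitThresholds(localModels$mi, 0.95)
  me <- fitThresholds(localModels$me, 0.95)
  # square pulses: same cadence, very different shape
  fs <- 250
  one <- c(rep(1.5, 38), rep(-1.5, 38))
  rec <- Recording(rep(one, 40), fs, subjectId = "square")
  sym <- symbolize(rec, mi, me)
  cyc <- as.data.frame(sym)
  expect_gt(nrow(cyc), 0)
  expect_true(all(cyc$outlier))
})

test_that("an unsegmentable recording symbolizes to an empty table", {
  mi <- fitThresholds(localModels$mi, 0.95)
  me <- fitThresholds(localModels$me, 0.95)
  flat <- Recording(seq(0, 1, length.out = 400), 250, subjectId = "flat")
  expect_warning(sym <- symbolize(flat, mi, me), "segmented")
  expect_equal(nCycles(sym), 0)
})

test_that("descriptors match analytic values for half-sine phases", {
  A <- 2
  Ti <- 0.2
  fs <- 250
  arch <- cycleArchetype("s", "half_sine", "half_sine", ti = Ti, te = Ti,
                         amplitude = A)
  g <- generateRecording(list(s = arch), rep("s", 12), fs = fs, seed = 1)
  seg <- segmentRecording(g$recording)
  desc <- computeDescriptors(g$recording, seg)
  expect_equal(median(desc$Ti), Ti, tolerance = 0.02)
  expect_equal(median(desc$NIV), 2 * A * Ti / pi, tolerance = 0.02)
  # symmetric cycle: inspired and expired volumes agree exactly on the
  # ground-truth boundaries (the generator balances each cycle)
  tr <- g$truth
  segTrue <- CycleSegmentation(tr$t_in, tr$t_out, tr$t_end, fs)
  descTrue <- computeDescriptors(g$recording, segTrue)
  expect_equal(descTrue$NIV, descTrue$NEV, tolerance = 1e-9)
  # index arithmetic: 50 samples at 250 Hz is 0.2 s
  segToy <- CycleSegmentation(101L, 151L, 201L, fs = 250)
  rec <- Recording(rnorm(300), 250)
  expect_equal(computeDescriptors(rec, segToy)$Ti, 0.2)
})

test_that("symbolic recordings round-trip through CSV", {
  mi <- fitThresholds(localModels$mi, 0.95)
  me <- fitThresholds(localModels$me, 0.95)
  sym <- symbolize(localModels$g$recording, mi, me)
  f <- withr::local_tempfile(fileext = ".csv")
  writeSymbolicRecording(sym, f)
  sym2 <- readSymbolicRecording(f)
  expect_equal(symbols(sym2), symbols(sym))
  expect_equal(sym2@cycles$t_in_s, sym@cycles$t_in_s, tolerance = 1e-9)
  expect_equal(sym2@inspLabels, sym@inspLabels)
})
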