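test_that("constant flow integrates to the zero volume trace", {
  v <- integrateDetrended(Recording(rep(2.5, 500), fs = 250))
  expect_lt(max(abs(volumeSamples(v))), 1e-10)
})

test_that("detrending matches an independent least-squares fit", {
  fs <- 250
  x <- sin(2 * pi * 4 * (seq_len(4 * fs) - 1) / fs)  # integer periods
  v <- volumeSamples(integrateDetrended(Recording(x, fs = fs)))
  # oracle: lm() on the cumulative sum
  cs <- cumsum(x) / fs
  t <- seq_along(cs)
  fit <- lm(cs ~ t)
  expect_equal(v, unname(residuals(fit)), tolerance = 1e-9)
  expect_lt(abs(unname(coef(lm(v ~ t))[2])), 1e-9)
})

test_that("detrending constraints hold on arbitrary inputs", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(50:2000, 1)
    x <- rnorm(n, mean = runif(1, -2, 2), sd = runif(1, 0.1, 3))
    v <- volumeSamples(integrateDetrended(Recording(x, fs = 250)))
    tol <- 1e-6 * n * max(abs(v), 1e-12)
    expect_lt(abs(sum(v)), tol)
    expect_lt(abs(sum(seq_along(v) * v)), tol)
  }
})

test_that("boundaries of a sinusoidal volume trace sit at its minima", {
  rec <- sineRecording(freq = 3, dur = 10, fs = 250)
  vol <- integrateDetrended(rec)
  seg <- detectBoundaries(vol, prominence = 0.03, window = 2)
  expect_gte(nCycles(seg), 29)
  expect_lte(nCycles(seg), 30)
  # analytic minima of the integrated sine are at multiples of the period
  expected <- 1 + round((seq_len(nCycles(seg)) - 1) * 250 / 3)
  expect_lte(max(abs(seg@tIn - expected)), 1)
})

test_that("monotone volume traces yield an empty segmentation", {
  vol <- VolumeTrace(seq(-1, 1, length.out = 500), fs = 250)
  seg <- detectBoundaries(vol)
  expect_equal(nCycles(seg), 0)
})

test_that("cycles violating the duration bounds are discarded whole", {
  fs <- 250
  # one 3 s inspiration (rising volume) between two normal cycles
  arch <- defaultArchetypes()
  slow <- cycleArchetype("slow", "half_sine", "half_sine", ti = 3, te = 0.5)
  g <- generateRecording(c(arch["sine"], list(slow = slow)),
                         c("sine", "sine", "slow", "sine", "sine"),
                         fs = fs, seed = 1)
  seg <- segmentRecording(g$recording)
  desc <- computeDescriptors(g$recording, seg)
  expect_true(all(desc$Ti <= 2))
  expect_gte(nrow(seg@discarded), 1)
  # a discarded span overlaps the over-long cycle (the single giant cycle
  # also tilts the fitted trend, so its edges shift by design)
  slowRow <- g$truth[g$truth$archetype == "slow", ]
  hit <- any(seg@discarded$start < slowRow$t_end &
             seg@discarded$end > slowRow$t_in)
  expect_true(hit)
})

test_that("parameter validation catches bad boundary settings", {
  vol <- integrateDetrended(sineRecording())
  expect_error(detectBoundaries(vol, minDur = 2, maxDur = 1), "minDur")
  expect_error(detectBoundaries(vol, window = 1e-4), "window")
  expect_error(detectBoundaries(vol, prominence = -1), "prominence")
})

test_that("splitPhases slices half-open intervals with equal counts", {
  rec <- Recording(as.numeric(1:200), fs = 100)
  seg <- CycleSegmentation(tIn = c(1L, 101L), tOut = c(51L, 151L),
                           tEnd = c(101L, 181L), fs = 100)
  ph <- splitPhases(rec, seg)
  expect_equal(length(ph$inspiration), length(ph$expiration))
  expect_equal(ph$inspiration[[1]], as.numeric(1:50))
  expect_equal(ph$expiration[[1]], as.numeric(51:100))
  expect_equal(ph$inspiration[[2]], as.numeric(101:150))
  # concatenation reproduces the source between tIn[1] and tEnd[1]
  expect_equal(c(ph$inspiration[[1]], ph$expiration[[1]]),
               flowSamples(rec)[1:100])
})

test_that("noise-free sinusoid splits into signed phases", {
  rec <- sineRecording(freq = 3, dur = 5, fs = 250)
  seg <- segmentRecording(rec)
  ph <- splitPhases(rec, seg)
  for (i in seq_len(length(ph$inspiration))) {
    expect_gte(min(ph$inspiration[[i]]), -1e-9)
    expect_lte(max(ph$expiration[[i]]), 1e-9)
  }
  expect_gte(mean(ph$inspiration[[1]]), 0)
})

test_that("empty segmentations split into empty phase sets", {
  rec <- Recording(seq(0, 1, length.out = 100), fs = 100)
  seg <- CycleSegmentation(integer(), integer(), integer(), fs = 100)
  ph <- splitPhases(rec, seg)
  expect_equal(length(ph$inspiration), 0)
  expect_equal(length(ph$expiration), 0)
})

test_that("segmentation CSV export carries boundary times in seconds", {
  rec <- sineRecording(freq = 3, dur = 3, fs = 250)
  seg <- segmentRecording(rec)
  f <- withr::local_tempfile(fileext = ".csv")
  exportSegmentation(seg, f)
  tab <- read.csv(f)
  expect_named(tab, c("cycle_index", "t_in_s", "t_out_s", "t_next_in_s"))
  expect_equal(tab$t_in_s, (seg@tIn - 1) / 250)
})
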