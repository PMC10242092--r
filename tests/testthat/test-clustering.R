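test_that("z-normalization uses the population standard deviation", {
  z <- zNormalize(c(1, 2, 3))
  expect_equal(as.numeric(z), c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(as.numeric(z), c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-9)
})

test_that("z-normalization is invariant to amplitude offset and shift", {
  set.seed(5)
  for (rep in 1:10) {
    x <- rnorm(sample(5:50, 1))
    a <- runif(1, 0.1, 10)
    b <- runif(1, -5, 5)
    expect_equal(as.numeric(zNormalize(a * x + b)),
                 as.numeric(zNormalize(x)), tolerance = 1e-9)
  }
})

test_that("constant sequences are degenerate and flagged", {
  expect_message(z <- zNormalize(rep(4, 10)), "zero-variance")
  expect_equal(as.numeric(z), rep(0, 10))
  expect_true(attr(z, "degenerate"))
  expect_error(zNormalize(1), "length")
})

test_that("kmeans++ with K equal to the set size picks every sequence", {
  X <- lapply(1:6, function(i) rnorm(10) + 3 * i)
  centers <- kmeansppInit(X, K = 6, lSamples = 10, seed = 4)
  # each member chosen exactly once (as a resampled copy)
  matched <- vapply(centers, function(cc)
    which(vapply(X, function(x) isTRUE(all.equal(cc, x)), logical(1)))[1],
    integer(1))
  expect_setequal(matched, 1:6)
  expect_error(kmeansppInit(X, K = 7, lSamples = 10), "at least K")
})

test_that("kmeans++ seeds split two far-separated families", {
  baseA <- sin(seq(0, pi, length.out = 12))
  baseB <- -2 * baseA + 5
  hits <- 0L
  for (s in 1:200) {
    set.seed(s)
    X <- c(lapply(1:8, function(i) baseA + rnorm(12, sd = 0.05)),
           lapply(1:8, function(i) baseB + rnorm(12, sd = 0.05)))
    centers <- kmeansppInit(X, K = 2, lSamples = 12, seed = s)
    fam <- vapply(centers, function(cc) mean(cc) > 1.5, logical(1))
    if (sum(fam) == 1L) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.95)
})

test_that("kmeans++ with K = 1 chooses uniformly", {
  X <- lapply(1:5, function(i) rnorm(8) + i)
  counts <- integer(5)
  for (s in 1:1000) {
    cc <- kmeansppInit(X, K = 1, lSamples = 8, seed = s)[[1]]
    hit <- which(vapply(X, function(x) isTRUE(all.equal(cc, x)),
                        logical(1)))
    counts[hit] <- counts[hit] + 1L
  }
  # 4-sigma binomial band around 200
  expect_true(all(abs(counts - 200) <= 4 * sqrt(1000 * 0.2 * 0.8)))
})

test_that("a separable toy instance is recovered exactly", {
  shapeA <- sin(seq(0, pi, length.out = 20))
  shapeB <- c(rep(0.05, 10), sin(seq(0, pi, length.out = 15)))
  X <- c(replicate(3, shapeA, simplify = FALSE),
         replicate(3, shapeB, simplify = FALSE))
  ps <- PhaseSet(X, "inspiration", fs = 250)
  m <- fitKmeans(ps, K = 2, radius = 0.01, nIter = 3, lSamples = 20,
                 seed = 2, batchSize = 3)
  expect_equal(ariIndex(m@assignments, rep(1:2, each = 3)), 1)
  # labels ordered by mean duration: shapeA (20 samples) before shapeB (25)
  expect_equal(clusterLabels(m), c("A", "B"))
  expect_true(all(diff(m@meanDurations) >= 0))
})

test_that("K = 1 collapses to a single BS-DBA average", {
  X <- lapply(1:5, function(i) sin(seq(0, pi, length.out = 22)) +
                rnorm(22, sd = 0.05))
  ps <- PhaseSet(X, "expiration", fs = 250)
  m <- fitKmeans(ps, K = 1, nIter = 2, lSamples = 22, seed = 3,
                 batchSize = 5)
  expect_equal(length(references(m)), 1)
  expect_equal(unique(m@assignments), 1L)
  expect_equal(clusterLabels(m), "0")
})

test_that("reassignment never increases the inertia", {
  set.seed(31)
  X <- lapply(1:30, function(i) rnorm(sample(15:25, 1)))
  ps <- PhaseSet(X, "inspiration", fs = 250)
  m <- fitKmeans(ps, K = 3, nIter = 6, lSamples = 20, seed = 8,
                 batchSize = 8)
  tr <- m@inertiaTrace
  later <- tr[!is.na(tr$beforeReassign), ]
  expect_true(all(later$afterReassign <= later$beforeReassign + 1e-12))
})

test_that("fits are bit-for-bit reproducible for a fixed seed", {
  X <- lapply(1:12, function(i) sin(seq(0, pi, length.out = 20 + i %% 3)) +
                rnorm(20 + i %% 3, sd = 0.1))
  ps <- PhaseSet(X, "inspiration", fs = 250)
  m1 <- fitKmeans(ps, K = 2, nIter = 4, lSamples = 20, seed = 11,
                  batchSize = 4)
  m2 <- fitKmeans(ps, K = 2, nIter = 4, lSamples = 20, seed = 11,
                  batchSize = 4)
  expect_identical(m1@references, m2@references)
  expect_identical(m1@assignments, m2@assignments)
})

test_that("three generated archetypes are recovered with high ARI", {
  arch <- defaultArchetypes()
  aris <- vapply(1:3, function(s) {
    seqs <- withr::with_seed(s, sample(c("sine", "biphasic", "delayed"),
                                       120, replace = TRUE))
    g <- generateRecording(arch, seqs, snrDb = 20, warpPct = 0.2,
                           seed = 100 + s)
    seg <- segmentRecording(g$recording)
    ph <- splitPhases(g$recording, seg)
    m <- suppressMessages(fitKmeans(ph$inspiration, K = 3, radius = 0.01,
                                    nIter = 10, seed = s))
    ariIndex(g$truth$archetype[matchTruth(seg, g$truth)], m@assignments)
  }, numeric(1))
  expect_gte(median(aris), 0.9)
})
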