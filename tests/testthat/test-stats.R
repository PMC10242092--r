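test_that("a single-class recording concentrates all time in one cell", {
  sym <- mkSym(rep("A", 5), rep("0", 5), rep(0.3, 5))
  d <- rcDistribution(sym)
  expect_equal(rcMatrix(d)["A", "0"], 100)
  expect_equal(sum(rcMatrix(d)), 100)
  expect_equal(d@outlierTimeFraction, 0)
})

test_that("classes with equal total duration split 50/50", {
  sym <- mkSym(c("A", "B", "A", "B"), c("0", "1", "0", "1"),
               c(0.2, 0.3, 0.4, 0.3))
  d <- rcMatrix(rcDistribution(sym))
  expect_equal(d["A", "0"], 50)
  expect_equal(d["B", "1"], 50)
})

test_that("programmed durations are reproduced and outlier time is split out", {
  durs <- c(0.2, 0.2, 0.4, 0.2, 0.5)
  sym <- mkSym(c("A", "A", "B", "B", "A"), c("0", "0", "1", "0", "1"),
               durs, outlier = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  d <- rcDistribution(sym)
  m <- rcMatrix(d)
  expect_equal(m["A", "0"], 100 * 0.4 / 1.0, tolerance = 1e-9)
  expect_equal(m["B", "1"], 100 * 0.4 / 1.0, tolerance = 1e-9)
  expect_equal(m["B", "0"], 100 * 0.2 / 1.0, tolerance = 1e-9)
  expect_equal(m["A", "1"], 0)
  expect_equal(d@outlierTimeFraction, 0.5 / 1.5, tolerance = 1e-9)
  expect_equal(sum(m), 100, tolerance = 1e-9)
})

test_that("an all-outlier recording yields the zero matrix with a flag", {
  sym <- mkSym(c("A", "B"), c("0", "1"), c(0.3, 0.3),
               outlier = c(TRUE, TRUE))
  d <- rcDistribution(sym)
  expect_true(d@allOutliers)
  expect_equal(sum(rcMatrix(d)), 0)
  expect_equal(d@outlierTimeFraction, 1)
})

test_that("rc distributions are invariant to cycle-order reversal", {
  set.seed(8)
  insp <- sample(c("A", "B"), 20, replace = TRUE)
  expn <- sample(c("0", "1"), 20, replace = TRUE)
  durs <- runif(20, 0.2, 0.5)
  d1 <- rcMatrix(rcDistribution(mkSym(insp, expn, durs)))
  d2 <- rcMatrix(rcDistribution(mkSym(rev(insp), rev(expn), rev(durs))))
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("marginal profiles are row and column sums", {
  m <- matrix(4, 5, 5, dimnames = list(LETTERS[1:5], 0:4))
  prof <- marginalProfiles(m)
  expect_equal(unname(prof$inspiration), rep(20, 5))
  expect_equal(unname(prof$expiration), rep(20, 5))
  set.seed(3)
  r <- matrix(runif(25), 5, 5)
  r <- 100 * r / sum(r)
  prof <- marginalProfiles(r)
  expect_equal(prof$inspiration, rowSums(r))
  expect_equal(prof$expiration, colSums(r))
  oneHot <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("0", "1")))
  oneHot["B", "0"] <- 100
  expect_equal(unname(marginalProfiles(oneHot)$inspiration), c(0, 100))
})

test_that("the exact Mann-Whitney p-value matches the permutation oracle", {
  p <- respclust:::.mwCellP(c(1, 2, 3), c(4, 5, 6))
  expect_equal(p, 0.1, tolerance = 1e-12)
  expect_equal(p, permutationMannWhitneyP(c(1, 2, 3), c(4, 5, 6)),
               tolerance = 1e-12)
  set.seed(12)
  for (rep in 1:10) {
    a <- round(rnorm(4), 3)
    b <- round(rnorm(5) + runif(1, -1, 1), 3)
    expect_equal(respclust:::.mwCellP(a, b), permutationMannWhitneyP(a, b),
                 tolerance = 1e-10)
  }
})

test_that("identical groups produce no rejections", {
  set.seed(7)
  g <- lapply(1:6, function(i) {
    m <- matrix(rdirichletPct(rep(2, 4)), 2, 2,
                dimnames = list(c("A", "B"), c("0", "1")))
    asRCDist(m, subject = paste0("s", i))
  })
  tm <- suppressMessages(compareGroups(g, g))
  expect_equal(sum(tm@rejected), 0)
  expect_true(all(tm@adjustedP >= tm@rawP - 1e-12))
})

test_that("adjusted p-values are BH-monotone in the raw ordering", {
  set.seed(15)
  gA <- lapply(1:8, function(i) asRCDist(matrix(rdirichletPct(rep(2, 25)),
                                                5, 5)))
  gB <- lapply(1:8, function(i) asRCDist(matrix(rdirichletPct(rep(2, 25)),
                                                5, 5)))
  tm <- compareGroups(gA, gB)
  ord <- order(as.vector(tm@rawP))
  expect_true(all(diff(as.vector(tm@adjustedP)[ord]) >= -1e-12))
  expect_equal(as.vector(tm@adjustedP),
               p.adjust(as.vector(tm@rawP), method = "BH"))
})

test_that("constant cells get p = 1 and group size is validated", {
  m0 <- matrix(c(50, 50, 0, 0), 2, 2, dimnames = list(c("A", "B"),
                                                      c("0", "1")))
  mk <- function(jitter) {
    m <- m0
    m["A", "1"] <- m["A", "1"] + jitter
    m["A", "0"] <- m["A", "0"] - jitter
    asRCDist(m)
  }
  gA <- list(mk(1), mk(2), mk(3))
  gB <- list(mk(4), mk(5), mk(6))
  expect_message(tm <- compareGroups(gA, gB), "constant cell")
  expect_equal(tm@rawP["B", "1"], 1)  # cell is 0 for every subject
  expect_error(compareGroups(gA[1], gB), "at least 2")
})

test_that("a large single-cell shift is detected by the test map", {
  set.seed(99)
  base <- rep(2, 25)
  gA <- lapply(1:8, function(i) asRCDist(matrix(rdirichletPct(base), 5, 5,
    dimnames = list(LETTERS[1:5], 0:4))))
  gB <- lapply(1:8, function(i) {
    v <- rdirichletPct(base)
    v <- v * (100 - 30) / 100
    v[10] <- v[10] + 30  # cell (E, 1) in column-major order
    asRCDist(matrix(v, 5, 5, dimnames = list(LETTERS[1:5], 0:4)))
  })
  tm <- compareGroups(gA, gB)
  expect_true(tm@rejected["E", "1"])
})
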