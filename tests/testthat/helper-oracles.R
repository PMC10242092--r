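# Independent oracles and small fixture builders used across tests.

# Brute-force unbanded DTW by dynamic programming in plain R, written
# independently of the package's compiled implementation.
bruteDtw <- function(x, y) {
  m <- length(x)
  n <- length(y)
  D <- matrix(Inf, m + 1L, n + 1L)
  D[1, 1] <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      D[i + 1L, j + 1L] <- (x[i] - y[j])^2 +
        min(D[i, j], D[i, j + 1L], D[i + 1L, j])
    }
  }
  D[m + 1L, n + 1L]
}

# Cost of an alignment path recomputed directly from its index pairs.
pathCost <- function(x, y, path) {
  sum((x[path[, 1]] - y[path[, 2]])^2)
}

# All sequences of lengths 1..maxLen over a value alphabet.
enumerateSequences <- function(alphabet, maxLen) {
  out <- list()
  for (L in seq_len(maxLen)) {
    grid <- do.call(expand.grid, rep(list(alphabet), L))
    for (r in seq_len(nrow(grid))) out[[length(out) + 1L]] <-
        as.numeric(grid[r, ])
  }
  out
}

# Exact two-sided Mann-Whitney p-value by enumeration of all group
# relabelings (no ties assumed).
permutationMannWhitneyP <- function(a, b) {
  ab <- c(a, b)
  n <- length(a)
  combs <- utils::combn(length(ab), n)
  uStat <- function(g1, g2) {
    sum(outer(g1, g2, ">")) + 0.5 * sum(outer(g1, g2, "=="))
  }
  obs <- uStat(a, b)
  mid <- length(a) * length(b) / 2
  stats <- apply(combs, 2, function(idx) uStat(ab[idx], ab[-idx]))
  mean(abs(stats - mid) >= abs(obs - mid) - 1e-12)
}

# Dirichlet draw scaled to a percentage composition.
rdirichletPct <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  100 * g / sum(g)
}

# Wrap a percentage matrix as an RCDistribution (for statistics tests).
asRCDist <- function(m, subject = "s", group = "g", phase = "pre") {
  new("RCDistribution", matrix = m, outlierTimeFraction = 0,
      allOutliers = FALSE, subjectId = subject, group = group, phase = phase)
}

# Build a SymbolicRecording from a compact cycle description.
mkSym <- function(insp, expn, durs, outlier = rep(FALSE, length(insp)),
                  inspLabels = c("A", "B"), expLabels = c("0", "1"),
                  subject = "s", group = "g") {
  tin <- cumsum(c(0, durs[-length(durs)]))
  cyc <- data.frame(cycle = seq_along(insp), t_in_s = tin,
                    t_out_s = tin + durs / 2, t_end_s = tin + durs,
                    insp_symbol = insp, exp_symbol = expn,
                    insp_dist = 0.1, exp_dist = 0.1, outlier = outlier,
                    classified = TRUE)
  new("SymbolicRecording", cycles = cyc, subjectId = subject, group = group,
      phase = "pre", fs = 250, inspLabels = inspLabels,
      expLabels = expLabels)
}

# A noise-free sinusoidal recording with an integer number of cycles.
sineRecording <- function(freq = 3, dur = 10, fs = 250, amplitude = 1) {
  Recording(amplitude * sin(2 * pi * freq * (seq_len(dur * fs) - 1L) / fs),
            fs = fs, subjectId = "sine")
}

# Match detected cycles (by tIn sample index) to generator truth rows.
matchTruth <- function(seg, truth) {
  vapply(seg@tIn, function(t) which.min(abs(truth$t_in - t)), integer(1))
}

ariIndex <- function(a, b) mclust::adjustedRandIndex(a, b)
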