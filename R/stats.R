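#' @include symbolization.R
NULL

#' Referent-cycle time distribution of a recording
#'
#' Builds the K1 x K2 matrix whose cell (letter, digit) holds the
#' percentage of classified time the recording spends in that referent
#' cycle: `100 * (summed duration of cycles with that symbol pair) /
#' (summed duration of all classified, non-outlier cycles)`. Outlier and
#' unclassified time is reported separately as a fraction of the total
#' covered time. If every cycle is an outlier the matrix is zero and
#' flagged.
#'
#' @param sym a non-empty [SymbolicRecording-class].
#' @return An [RCDistribution-class].
#' @seealso [marginalProfiles()], [rcHeatmap()], [compareGroups()]
#' @export
rcDistribution <- function(sym) {
  stopifnot(is(sym, "SymbolicRecording"))
  cyc <- sym@cycles
  if (nrow(cyc) == 0L) stop("parameter error: empty symbolic recording")
  K1 <- length(sym@inspLabels)
  K2 <- length(sym@expLabels)
  m <- matrix(0, K1, K2, dimnames = list(sym@inspLabels, sym@expLabels))
  dur <- cyc$t_end_s - cyc$t_in_s
  ok <- !cyc$outlier
  totOk <- sum(dur[ok])
  allOut <- totOk <= 0
  if (!allOut) {
    for (i in which(ok)) {
      m[cyc$insp_symbol[i], cyc$exp_symbol[i]] <-
        m[cyc$insp_symbol[i], cyc$exp_symbol[i]] + dur[i]
    }
    m <- 100 * m / totOk
  }
  new("RCDistribution", matrix = m,
      outlierTimeFraction = sum(dur[!ok]) / sum(dur),
      allOutliers = allOut, subjectId = sym@subjectId, group = sym@group,
      phase = sym@phase)
}

#' Marginal inspiration/expiration time profiles
#'
#' Row sums (inspiration references) and column sums (expiration
#' references) of an RC distribution; each marginal sums to 100 for a
#' non-degenerate distribution. These are the values shown on the polar
#' plots.
#'
#' @param dist an [RCDistribution-class], or a plain matrix.
#' @return List with numeric vectors `inspiration` and `expiration`.
#' @export
marginalProfiles <- function(dist) {
  m <- if (is(dist, "RCDistribution")) dist@matrix else as.matrix(dist)
  list(inspiration = rowSums(m), expiration = colSums(m))
}

# Mann-Whitney p-value for one cell: exact distribution for small samples
# without ties, tie-corrected normal approximation (with continuity
# correction) otherwise; constant data in both groups gives p = 1.
.mwCellP <- function(a, b) {
  if (length(unique(c(a, b))) == 1L) {
    message("compareGroups: constant cell, p set to 1")
    return(1)
  }
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- min(length(a), length(b)) < 8L && !ties
  suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
}

#' Compare two groups of RC distributions cell by cell
#'
#' For every referent cycle class, tests whether the per-subject percentage
#' of classified time differs between the two groups with a two-sided
#' Mann-Whitney U test (exact null distribution when both groups have fewer
#' than 8 subjects and there are no ties; tie-corrected normal
#' approximation otherwise), then applies Benjamini-Hochberg false
#' discovery rate correction across all K1 x K2 cells. A paired Wilcoxon
#' signed-rank variant is available for within-subject pre/post designs.
#'
#' @param groupA,groupB lists of [RCDistribution-class] objects (>= 2
#'   subjects each) with identical dimensions.
#' @param level FDR level (default 0.05).
#' @param paired use the paired Wilcoxon signed-rank test (groups must then
#'   be equal-length and subject-aligned).
#' @return A [TestMap-class].
#' @examples
#' # U for {1,2,3} vs {4,5,6} is 0; exact two-sided p = 0.1
#' stats::wilcox.test(1:3, 4:6, exact = TRUE)$p.value
#' @export
compareGroups <- function(groupA, groupB, level = 0.05, paired = FALSE) {
  matA <- lapply(groupA, function(g)
    if (is(g, "RCDistribution")) g@matrix else as.matrix(g))
  matB <- lapply(groupB, function(g)
    if (is(g, "RCDistribution")) g@matrix else as.matrix(g))
  if (length(matA) < 2L || length(matB) < 2L)
    stop("parameter error: each group needs at least 2 subjects")
  dm <- dim(matA[[1]])
  if (!all(vapply(c(matA, matB), function(m) identical(dim(m), dm),
                  logical(1))))
    stop("parameter error: all matrices must share dimensions")
  if (paired && length(matA) != length(matB))
    stop("parameter error: paired groups must be equal-length")
  A <- simplify2array(matA)  # K1 x K2 x nA
  B <- simplify2array(matB)
  rawP <- matrix(NA_real_, dm[1], dm[2], dimnames = dimnames(matA[[1]]))
  for (i in seq_len(dm[1])) {
    for (j in seq_len(dm[2])) {
      a <- A[i, j, ]
      b <- B[i, j, ]
      rawP[i, j] <- if (paired) {
        if (all(a == b)) 1 else suppressWarnings(
          stats::wilcox.test(a, b, paired = TRUE, exact = FALSE,
                             correct = TRUE)$p.value)
      } else {
        .mwCellP(a, b)
      }
    }
  }
  adj <- matrix(stats::p.adjust(as.vector(rawP), method = "BH"),
                dm[1], dm[2], dimnames = dimnames(rawP))
  new("TestMap", rawP = rawP, adjustedP = adj, rejected = adj <= level,
      level = level, nA = length(matA), nB = length(matB))
}
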