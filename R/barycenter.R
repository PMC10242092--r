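#' @include dtw.R
NULL

.asSequenceList <- function(X) {
  if (is(X, "PhaseSet")) return(X@sequences)
  if (is.list(X)) return(lapply(X, as.numeric))
  stop("X must be a list of numeric sequences or a PhaseSet")
}

#' Sum of DTW costs from a candidate average to a sequence set
#'
#' The objective minimized by [bsDba()]: the sum over the set of the DTW
#' measure (already a squared-error quantity) between the candidate `y` and
#' each sequence.
#'
#' @param y numeric candidate sequence.
#' @param X list of numeric sequences or a [PhaseSet-class]; must be
#'   non-empty.
#' @param radius,fs band parameters passed to [dtwDistance()].
#' @return Nonnegative scalar.
#' @export
dbaObjective <- function(y, X, radius = Inf, fs = 1) {
  X <- .asSequenceList(X)
  if (length(X) == 0L) stop("parameter error: X must be non-empty")
  sum(vapply(X, function(x) dtwDistance(y, x, radius, fs), numeric(1)))
}

# Index of the medoid: the member minimizing the summed DTW cost to all
# members.
.medoidIndex <- function(X, radius, fs) {
  n <- length(X)
  if (n == 1L) return(1L)
  tot <- numeric(n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- dtwDistance(X[[i]], X[[j]], radius, fs)
      tot[i] <- tot[i] + d
      tot[j] <- tot[j] + d
    }
  }
  which.min(tot)
}

#' Batch stochastic DTW barycenter averaging (BS-DBA)
#'
#' Computes a fixed-length average sequence that (locally) minimizes the sum
#' of DTW costs to a set of sequences, by mini-batch stochastic subgradient
#' descent. Each epoch shuffles the set (seeded), partitions it into
#' batches, and for each batch moves every barycenter sample towards the
#' data samples its DTW path aligns it to:
#' `g[k] = sum over batch members x, over path pairs (k, j), of 2 (y[k] - x[j])`,
#' followed by `y <- y - eta_t g` with the decreasing schedule
#' `eta_t = eta0 / (1 + t)` over batch updates. The objective is evaluated
#' once per epoch and the best iterate seen (including the initialization)
#' is returned, so the final objective never exceeds the initial one.
#'
#' Initialization is the medoid of `X` (the member minimizing
#' [dbaObjective()]), linearly resampled to `lSamples`, unless an explicit
#' `init` is supplied (used e.g. for warm starts inside K-means).
#'
#' @param X list of numeric sequences or a [PhaseSet-class]; non-empty.
#' @param lSamples barycenter length in samples (>= 2). `NULL` uses the
#'   rounded average length of the sequences in `X`.
#' @param radius,fs band parameters passed to the DTW routines.
#' @param batchSize mini-batch size (default 32); values outside
#'   `[1, length(X)]` are clamped with a warning.
#' @param epochs number of passes over the data (default 5).
#' @param eta0 initial step size; default `1 / (2 * batchSize)`.
#' @param seed integer seed controlling the shuffles.
#' @param init optional numeric vector of length `lSamples` used as the
#'   starting iterate instead of the medoid.
#' @return A [Barycenter-class].
#' @examples
#' X <- replicate(5, sin(seq(0, pi, length.out = 30)), simplify = FALSE)
#' b <- bsDba(X, lSamples = 30, seed = 1)
#' b@objectiveTrace  # identical copies: objective 0 from the start
#' @export
bsDba <- function(X, lSamples = NULL, radius = Inf, fs = 1, batchSize = 32,
                  epochs = 5, eta0 = NULL, seed = 1, init = NULL) {
  X <- .asSequenceList(X)
  n <- length(X)
  if (n == 0L) stop("parameter error: X must be non-empty")
  if (is.null(lSamples))
    lSamples <- max(2L, as.integer(roundHalfUp(mean(lengths(X)))))
  lSamples <- as.integer(lSamples)
  if (lSamples < 2L) stop("parameter error: lSamples must be >= 2")
  if (batchSize < 1 || batchSize > n) {
    warning(sprintf("batchSize clamped to [1, %d]", n))
    batchSize <- min(max(1, batchSize), n)
  }
  batchSize <- as.integer(batchSize)
  if (is.null(eta0)) eta0 <- 1 / (2 * batchSize)
  if (n == 1L && is.null(init)) {
    # the average of a single sequence is the sequence itself
    y <- resampleLinear(X[[1]], lSamples)
    obj <- dbaObjective(y, X, radius, fs)
    return(new("Barycenter", samples = y,
               objectiveTrace = rep(obj, epochs + 1L),
               meta = list(seed = seed, epochs = epochs,
                           batchSize = batchSize, eta0 = eta0,
                           radius = radius, fs = fs, init = "singleton")))
  }
  if (is.null(init)) {
    y <- resampleLinear(X[[.medoidIndex(X, radius, fs)]], lSamples)
  } else {
    stopifnot(length(init) == lSamples)
    y <- as.numeric(init)
  }
  obj0 <- dbaObjective(y, X, radius, fs)
  trace <- obj0
  best <- y
  bestObj <- obj0
  withSeed(seed, {
    step <- 0L
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      starts <- seq.int(1L, n, by = batchSize)
      for (s in starts) {
        idx <- perm[s:min(s + batchSize - 1L, n)]
        g <- numeric(lSamples)
        for (i in idx) {
          x <- X[[i]]
          p <- cpp_dtw_path(y, x, sakoeChibaSamples(radius, fs))$path
          agg <- rowsum(cbind(1, x[p[, 2]]), p[, 1])
          rows <- as.integer(rownames(agg))
          g[rows] <- g[rows] + 2 * (y[rows] * agg[, 1] - agg[, 2])
        }
        y <- y - (eta0 / (1 + step)) * g
        step <- step + 1L
      }
      obj <- dbaObjective(y, X, radius, fs)
      trace <- c(trace, obj)
      if (obj < bestObj) {
        bestObj <- obj
        best <- y
      }
    }
  })
  # objectiveTrace tracks the best-so-far iterate per epoch (the returned
  # one), so it is non-increasing; raw per-epoch values are kept in meta.
  new("Barycenter", samples = best, objectiveTrace = cummin(trace),
      meta = list(seed = seed, epochs = epochs, batchSize = batchSize,
                  eta0 = eta0, radius = radius, fs = fs, rawTrace = trace,
                  init = if (is.null(init)) "medoid" else "warm"))
}
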