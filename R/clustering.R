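#' @include barycenter.R
NULL

#' Z-normalize a sequence
#'
#' Centers to zero mean and scales to unit variance using the population
#' (1/n) standard deviation, making downstream shape comparison invariant
#' to amplitude offset and amplitude shift:
#' `zNormalize(a * x + b)` equals `zNormalize(x)` for any `a > 0`.
#' Zero-variance sequences carry no shape; they are returned as all zeros
#' with the attribute `degenerate = TRUE` and a message.
#'
#' @param x numeric sequence of length >= 2.
#' @return Numeric sequence of the same length; attribute `degenerate` is
#'   `TRUE` for constant input.
#' @examples
#' zNormalize(c(1, 2, 3))          # [-1.2247, 0, 1.2247]
#' zNormalize(5 * c(1, 2, 3) + 3)  # identical
#' @export
zNormalize <- function(x) {
  if (length(x) < 2L) stop("parameter error: sequence must have length >= 2")
  x <- as.numeric(x)
  mu <- mean(x)
  sdp <- sqrt(mean((x - mu)^2))
  if (sdp < 1e-12 * max(1, abs(mu))) {
    message("zNormalize: zero-variance sequence, returning zeros")
    return(structure(rep(0, length(x)), degenerate = TRUE))
  }
  structure((x - mu) / sdp, degenerate = FALSE)
}

.isDegenerate <- function(x) {
  mu <- mean(x)
  sqrt(mean((x - mu)^2)) < 1e-12 * max(1, abs(mu))
}

# Distances from every sequence in X to each center (columns).
.distanceMatrix <- function(X, centers, radius, fs) {
  r <- sakoeChibaSamples(radius, fs)
  D <- matrix(0, length(X), length(centers))
  for (k in seq_along(centers)) {
    ck <- centers[[k]]
    D[, k] <- vapply(X, function(x) cpp_dtw_dist(x, ck, r), numeric(1))
  }
  D
}

#' K-means++ seeding over sequences under DTW
#'
#' Chooses `K` member sequences as initial centers: the first uniformly at
#' random, each subsequent one with probability proportional to the DTW
#' measure (a squared-error quantity) to the nearest center already chosen.
#' Already-chosen members are excluded; if all remaining candidates are at
#' distance zero the choice falls back to uniform. The chosen members are
#' returned linearly resampled to the reference length.
#'
#' @param X list of numeric sequences or a [PhaseSet-class] (assumed
#'   z-normalized); `length(X) >= K`.
#' @param K number of centers.
#' @param radius,fs band parameters for the DTW routines.
#' @param lSamples reference length in samples.
#' @param seed integer seed.
#' @return List of `K` numeric vectors of length `lSamples`.
#' @export
kmeansppInit <- function(X, K, radius = Inf, fs = 1, lSamples, seed = 1) {
  X <- .asSequenceList(X)
  n <- length(X)
  if (n < K) stop("parameter error: need at least K sequences")
  r <- sakoeChibaSamples(radius, fs)
  withSeed(seed, {
    chosen <- integer(K)
    chosen[1] <- sample.int(n, 1L)
    d2 <- vapply(X, function(x) cpp_dtw_dist(x, X[[chosen[1]]], r),
                 numeric(1))
    for (k in seq_len(K - 1L)) {
      prob <- d2
      prob[chosen[seq_len(k)]] <- 0
      if (sum(prob) <= 0) {
        avail <- setdiff(seq_len(n), chosen[seq_len(k)])
        nxt <- if (length(avail) == 1L) avail else sample(avail, 1L)
      } else {
        nxt <- sample.int(n, 1L, prob = prob)
      }
      chosen[k + 1L] <- nxt
      dn <- vapply(X, function(x) cpp_dtw_dist(x, X[[nxt]], r), numeric(1))
      d2 <- pmin(d2, dn)
    }
    lapply(X[chosen], resampleLinear, L = lSamples)
  })
}

#' DTW K-means with BS-DBA centroids
#'
#' Clusters variable-length sequences by K-means: sequences are
#' z-normalized, centers are seeded with K-means++, assignment uses the
#' banded DTW measure, and each centroid update runs [bsDba()] warm-started
#' from the current centroid. The iteration budget is fixed (no convergence
#' test). After the final update a last assignment pass fixes the reported
#' assignments and within-cluster distances. Clusters are then ordered by
#' increasing mean member duration and labelled `A`, `B`, ... for
#' inspiration or `0`, `1`, ... for expiration, so later labels always mean
#' longer phases.
#'
#' Zero-variance sequences are excluded from training (they carry no shape)
#' and reported via a message; an empty cluster is reseeded with the
#' sequence farthest from its centroid.
#'
#' @param X a [PhaseSet-class] (preferred: supplies durations and phase) or
#'   a list of numeric sequences.
#' @param K number of clusters.
#' @param radius,fs band parameters; when `X` is a `PhaseSet`, `fs` defaults
#'   to its sampling rate.
#' @param nIter number of assignment/update iterations (default 10).
#' @param lSamples reference length in samples; default
#'   `roundHalfUp(refLength * fs)` with `refLength = 0.2` s.
#' @param seed integer seed (seeding, shuffles, reseeding).
#' @param batchSize,epochs BS-DBA settings per centroid update.
#' @param phase `"inspiration"` or `"expiration"`; inferred from a
#'   `PhaseSet`.
#' @param refLength reference length in seconds, used when `lSamples` is
#'   missing.
#' @return A [ShapeModel-class].
#' @seealso [fitThresholds()], [symbolize()]
#' @export
fitKmeans <- function(X, K, radius = 0.01, fs = NULL, nIter = 10,
                      lSamples = NULL, seed = 1, batchSize = 32, epochs = 5,
                      phase = NULL, refLength = 0.2) {
  if (is(X, "PhaseSet")) {
    fs <- fs %||% X@fs
    phase <- phase %||% X@phase
    seqs <- X@sequences
    durs <- durations(X)
  } else {
    if (is.null(fs)) stop("fs is required when X is a plain list")
    phase <- phase %||% "inspiration"
    seqs <- lapply(X, as.numeric)
    durs <- lengths(seqs) / fs
  }
  if (is.null(lSamples)) lSamples <- as.integer(roundHalfUp(refLength * fs))
  lSamples <- as.integer(lSamples)
  keep <- !vapply(seqs, .isDegenerate, logical(1)) & lengths(seqs) >= 2L
  if (!all(keep))
    message(sprintf("fitKmeans: excluding %d degenerate sequence(s)",
                    sum(!keep)))
  Z <- lapply(seqs[keep], function(s) as.numeric(zNormalize(s)))
  durs <- durs[keep]
  n <- length(Z)
  if (n < K) stop("parameter error: need at least K non-degenerate sequences")
  centers <- kmeansppInit(Z, K, radius, fs, lSamples, seed = seed)
  assign <- rep(NA_integer_, n)
  inertia <- data.frame(iteration = integer(), beforeReassign = numeric(),
                        afterReassign = numeric())
  for (it in seq_len(nIter)) {
    D <- .distanceMatrix(Z, centers, radius, fs)
    newAssign <- max.col(-D, ties.method = "first")
    before <- if (all(is.na(assign))) NA_real_
              else sum(D[cbind(seq_len(n), assign)])
    after <- sum(D[cbind(seq_len(n), newAssign)])
    inertia <- rbind(inertia,
                     data.frame(iteration = it, beforeReassign = before,
                                afterReassign = after))
    assign <- newAssign
    # reseed empty clusters with the globally farthest sequence
    for (k in seq_len(K)) {
      if (!any(assign == k)) {
        far <- which.max(D[cbind(seq_len(n), assign)])
        message(sprintf("fitKmeans: reseeding empty cluster %d", k))
        centers[[k]] <- resampleLinear(Z[[far]], lSamples)
        assign[far] <- k
      }
    }
    for (k in seq_len(K)) {
      members <- Z[assign == k]
      centers[[k]] <- bsDba(members, lSamples, radius, fs,
                            batchSize = min(batchSize, length(members)),
                            epochs = epochs,
                            seed = childSeed(seed, it * K + k),
                            init = centers[[k]])@samples
    }
  }
  # final assignment pass for reported memberships and distances
  D <- .distanceMatrix(Z, centers, radius, fs)
  assign <- max.col(-D, ties.method = "first")
  dist <- D[cbind(seq_len(n), assign)]
  meanDur <- vapply(seq_len(K), function(k) mean(durs[assign == k]),
                    numeric(1))
  meanDur[is.nan(meanDur)] <- Inf  # empty cluster sorts last
  ord <- order(meanDur)
  relabel <- match(seq_len(K), ord)
  labels <- if (phase == "inspiration") LETTERS[seq_len(K)]
            else as.character(seq_len(K) - 1L)
  newAssign <- relabel[assign]
  within <- lapply(seq_len(K), function(k) unname(dist[newAssign == k]))
  new("ShapeModel", phase = phase, references = centers[ord],
      labels = labels, assignments = as.integer(newAssign),
      memberDistances = dist, memberDurations = durs,
      withinDistances = within, meanDurations = meanDur[ord],
      thresholds = rep(NA_real_, K), alpha = NA_real_,
      inertiaTrace = inertia,
      config = list(K = K, radius = radius, fs = fs, nIter = nIter,
                    lSamples = lSamples, seed = seed, batchSize = batchSize,
                    epochs = epochs, keep = which(keep)))
}
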