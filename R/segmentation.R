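#' @include signal_io.R
NULL

#' Reconstruct the detrended lung volume from airflow
#'
#' Integrates the airflow (cumulative sum divided by the sampling rate, so
#' the result is in mL) and removes the least-squares linear trend that the
#' integration of any flow offset produces. The residual trace `v` satisfies
#' `sum(v) == 0` and `sum(t * v) == 0` up to floating point, i.e. it is
#' orthogonal to constant and linear drift.
#'
#' @param rec a [Recording-class].
#' @return A [VolumeTrace-class] of the same length and sampling rate.
#' @examples
#' rec <- Recording(rep(1, 100), fs = 250)  # constant flow
#' v <- integrateDetrended(rec)
#' max(abs(volumeSamples(v)))               # ~0: affine ramp fully removed
#' @seealso [detectBoundaries()]
#' @export
integrateDetrended <- function(rec) {
  stopifnot(is(rec, "Recording"))
  v <- cumsum(rec@samples) / rec@fs
  n <- length(v)
  t <- seq_len(n)
  tc <- t - mean(t)
  slope <- sum(tc * v) / sum(tc * tc)
  resid <- v - mean(v) - slope * tc
  VolumeTrace(resid, rec@fs)
}

#' Detect inspiration/expiration boundaries on a volume trace
#'
#' Inspiration starts are local minima of the volume whose prominence,
#' evaluated within a sliding window, reaches `prominence`; the expiration
#' start of each cycle is the volume maximum between two consecutive
#' retained minima. Cycles in which either phase falls outside
#' `[minDur, maxDur]` are discarded whole and recorded as discarded spans.
#' Ties among equal extrema keep the earliest sample.
#'
#' @param vol a [VolumeTrace-class].
#' @param prominence minimum prominence in mL (default 0.03).
#' @param window prominence evaluation window in seconds (default 2),
#'   centred on the candidate.
#' @param minDur,maxDur admissible phase durations in seconds (defaults
#'   0.05 and 2).
#' @return A [CycleSegmentation-class]; empty (zero cycles) when no minima
#'   pass the prominence filter.
#' @seealso [integrateDetrended()], [splitPhases()]
#' @export
detectBoundaries <- function(vol, prominence = 0.03, window = 2,
                             minDur = 0.05, maxDur = 2) {
  stopifnot(is(vol, "VolumeTrace"))
  assertScalarPositive(prominence, "prominence")
  assertScalarPositive(window, "window")
  assertScalarPositive(minDur, "minDur")
  assertScalarPositive(maxDur, "maxDur")
  if (minDur >= maxDur) stop("parameter error: minDur must be < maxDur")
  fs <- vol@fs
  if (window < 2 / fs)
    stop("parameter error: window must be at least two samples", call. = FALSE)
  w <- as.integer(roundHalfUp(window * fs / 2))
  mins <- cpp_minima_prominence(vol@samples, prominence, w)
  empty <- CycleSegmentation(integer(), integer(), integer(), fs)
  if (length(mins) < 2L) return(empty)
  v <- vol@samples
  nb <- length(mins)
  tIn <- integer(0); tOut <- integer(0); tEnd <- integer(0)
  disc <- list()
  # v[t] includes the flow at t, so the volume extremum is the last sample
  # of the preceding phase; the phase itself starts one sample later
  for (k in seq_len(nb - 1L)) {
    p <- mins[k]; q <- mins[k + 1L]
    mx <- p - 1L + which.max(v[p:q])  # earliest maximum on ties
    ok <- mx > p && mx < q
    if (ok) {
      ti <- (mx - p) / fs
      te <- (q - mx) / fs
      ok <- ti >= minDur && ti <= maxDur && te >= minDur && te <= maxDur
    }
    if (ok) {
      tIn <- c(tIn, p + 1L); tOut <- c(tOut, mx + 1L); tEnd <- c(tEnd, q + 1L)
    } else {
      disc[[length(disc) + 1L]] <- c(p + 1L, q + 1L)
    }
  }
  discarded <- if (length(disc)) {
    m <- do.call(rbind, disc)
    data.frame(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
  } else data.frame(start = integer(), end = integer())
  CycleSegmentation(tIn, tOut, tEnd, fs, discarded)
}

#' Split a recording into inspiration and expiration sequences
#'
#' Uses the half-open interval convention: inspiration `k` covers samples
#' `[tIn[k], tOut[k])` and expiration `k` covers `[tOut[k], tEnd[k])`, so
#' concatenating the phases of a run of contiguous cycles reproduces the
#' original samples exactly. Counts of inspirations and expirations are
#' equal by construction; the trailing partial cycle after the last
#' detected inspiration start is never included.
#'
#' @param rec the source [Recording-class].
#' @param seg the [CycleSegmentation-class] derived from `rec`.
#' @return A list with elements `inspiration` and `expiration`, both
#'   [PhaseSet-class] objects of equal length.
#' @export
splitPhases <- function(rec, seg) {
  stopifnot(is(rec, "Recording"), is(seg, "CycleSegmentation"))
  n <- length(rec@samples)
  if (length(seg@tEnd) && max(seg@tEnd) > n + 1L)
    stop("validation error: segmentation indices exceed recording length")
  k <- length(seg@tIn)
  insp <- vector("list", k)
  expi <- vector("list", k)
  for (i in seq_len(k)) {
    insp[[i]] <- rec@samples[seg@tIn[i]:(seg@tOut[i] - 1L)]
    expi[[i]] <- rec@samples[seg@tOut[i]:(seg@tEnd[i] - 1L)]
  }
  list(
    inspiration = PhaseSet(insp, "inspiration", seg@tIn,
                           rep(rec@subjectId, k), rec@fs),
    expiration = PhaseSet(expi, "expiration", seg@tOut,
                          rep(rec@subjectId, k), rec@fs))
}

#' Segment a recording end to end
#'
#' Convenience wrapper: integrate and detrend the volume, detect boundaries
#' and return the segmentation.
#'
#' @param rec a [Recording-class].
#' @param config a [pipelineConfig()] supplying `prominence`, `window`,
#'   `minDur` and `maxDur`.
#' @return A [CycleSegmentation-class].
#' @export
segmentRecording <- function(rec, config = pipelineConfig()) {
  detectBoundaries(integrateDetrended(rec),
                   prominence = config@prominence, window = config@window,
                   minDur = config@minDur, maxDur = config@maxDur)
}

#' Export a segmentation as CSV
#'
#' Writes boundary times in seconds (columns `cycle_index`, `t_in_s`,
#' `t_out_s`, `t_next_in_s`) for interoperability with descriptor tooling.
#'
#' @param seg a [CycleSegmentation-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
exportSegmentation <- function(seg, path) {
  utils::write.csv(as.data.frame(seg), path, row.names = FALSE)
  invisible(path)
}
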