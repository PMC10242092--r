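#' @include utils.R
NULL

#' Sakoe-Chiba radius in samples
#'
#' Converts a temporal band radius to samples with deterministic
#' round-half-up, with a floor of one sample. At 250 Hz the default radius
#' of 0.01 s gives `round(2.5) = 3` samples.
#'
#' @param radius band radius in seconds; `Inf` means unconstrained.
#' @param fs sampling rate in Hz.
#' @return integer number of samples.
#' @export
sakoeChibaSamples <- function(radius, fs) {
  if (is.infinite(radius)) return(.Machine$integer.max %/% 4L)
  if (radius < 0) stop("parameter error: radius must be >= 0")
  max(1L, as.integer(roundHalfUp(radius * fs)))
}

#' Banded dynamic time warping distance
#'
#' Computes the DTW measure between two sequences: the minimum over
#' monotone alignment paths (steps down, right, diagonal) of the summed
#' squared gaps `(x[i] - y[j])^2`, without path-length normalization. The
#' admissible region is a Sakoe-Chiba corridor of the given temporal radius
#' around the corner-to-corner diagonal; for sequences of different lengths
#' the corridor follows the resampled diagonal and is widened just enough
#' to stay connected, so the corner cells are always reachable.
#'
#' @param x,y numeric sequences (non-empty).
#' @param radius Sakoe-Chiba band radius in seconds; `Inf` (default)
#'   disables the constraint.
#' @param fs sampling rate in Hz used to convert `radius` to samples.
#' @return Nonnegative scalar distance (a squared-error quantity).
#' @examples
#' dtwDistance(c(1, 2, 3), c(1, 2, 2, 3))  # 0: the repeated 2 is absorbed
#' dtwDistance(c(0, 0), c(1, 1))           # 2: two unit squared gaps
#' @seealso [dtwPath()], [sakoeChibaSamples()]
#' @export
dtwDistance <- function(x, y, radius = Inf, fs = 1) {
  if (length(x) == 0L || length(y) == 0L)
    stop("parameter error: sequences must be non-empty")
  cpp_dtw_dist(as.numeric(x), as.numeric(y), sakoeChibaSamples(radius, fs))
}

#' Banded DTW distance and optimal alignment path
#'
#' As [dtwDistance()], but also returns the optimal alignment: an ordered
#' matrix of 1-based `(i, j)` index pairs starting at `(1, 1)` and ending at
#' `(length(x), length(y))`. Recomputing the summed squared gaps along the
#' path reproduces the distance. Ties during backtracking prefer the
#' diagonal step, so the path is deterministic.
#'
#' @inheritParams dtwDistance
#' @return A list with `distance` (scalar) and `path` (two-column integer
#'   matrix of aligned index pairs).
#' @export
dtwPath <- function(x, y, radius = Inf, fs = 1) {
  if (length(x) == 0L || length(y) == 0L)
    stop("parameter error: sequences must be non-empty")
  res <- cpp_dtw_path(as.numeric(x), as.numeric(y),
                      sakoeChibaSamples(radius, fs))
  colnames(res$path) <- c("i", "j")
  res
}
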