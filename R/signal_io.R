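#' @include AllGenerics.R
NULL

# CSV dialect: comma-separated, '.' decimal, UTF-8; header comment lines
# prefixed '#' carrying key=value pairs (fs, subject_id, group, phase, t0),
# then columns time,flow.

.parseHeaderMeta <- function(path) {
  meta <- list()
  con <- file(path, "r", encoding = "UTF-8")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L || !startsWith(line, "#")) break
    body <- sub("^#\\s*", "", line)
    if (grepl("=", body, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", body))
      val <- trimws(sub("^[^=]*=", "", body))
      meta[[key]] <- val
    }
  }
  meta
}

#' Read an airflow recording from disk
#'
#' Reads the package's plain-text recording format: a CSV with two columns
#' (`time`, `flow`) preceded by `#`-prefixed header lines carrying
#' `key=value` metadata. The keys `fs` and `subject_id` are required;
#' `group`, `phase` and `t0` are optional.
#'
#' @param path path to the file.
#' @param format file format; only `"csv"` is supported.
#' @return A [Recording-class].
#' @examples
#' rec <- Recording(sin(seq(0, 10, by = 0.004)), fs = 250, subjectId = "m1")
#' f <- tempfile(fileext = ".csv")
#' writeRecording(rec, f)
#' rec2 <- readRecording(f)
#' stopifnot(all.equal(flowSamples(rec), flowSamples(rec2)))
#' @seealso [writeRecording()], [downsample()]
#' @export
readRecording <- function(path, format = c("csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- .parseHeaderMeta(path)
  if (is.null(meta$fs))
    stop("format error: header is missing the 'fs' key", call. = FALSE)
  fs <- suppressWarnings(as.numeric(meta$fs))
  if (!is.finite(fs) || fs <= 0)
    stop("format error: 'fs' must be a positive number", call. = FALSE)
  dat <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time", "flow") %in% names(dat)))
    stop("format error: expected columns 'time' and 'flow'", call. = FALSE)
  if (any(!is.finite(dat$flow)))
    stop("validation error: non-finite flow samples", call. = FALSE)
  Recording(dat$flow, fs = fs,
            subjectId = meta$subject_id %||% "subject",
            group = meta$group %||% "unspecified",
            phase = meta$phase %||% "unspecified",
            t0 = as.numeric(meta$t0 %||% 0))
}

#' Write an airflow recording to disk
#'
#' @param rec a [Recording-class].
#' @param path output path.
#' @param format file format; only `"csv"` is supported.
#' @return `path`, invisibly.
#' @seealso [readRecording()]
#' @export
writeRecording <- function(rec, path, format = c("csv")) {
  format <- match.arg(format)
  stopifnot(is(rec, "Recording"))
  hdr <- c(sprintf("# fs=%.17g", rec@fs),
           sprintf("# subject_id=%s", rec@subjectId),
           sprintf("# group=%s", rec@group),
           sprintf("# phase=%s", rec@phase),
           sprintf("# t0=%.17g", rec@t0))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("time,flow", con)
  tt <- rec@t0 + (seq_along(rec@samples) - 1L) / rec@fs
  writeLines(paste(sprintf("%.17g", tt), sprintf("%.17g", rec@samples),
                   sep = ","), con)
  invisible(path)
}

#' Down-sample a recording by an integer factor
#'
#' Applies a zero-phase low-pass anti-alias filter (4th-order Butterworth,
#' cutoff at 80% of the target Nyquist frequency, run forwards and backwards)
#' and then decimates. Zero-phase filtering is used so that cycle boundaries
#' are not shifted in time. The signal mean is removed before filtering and
#' restored afterwards, so constant signals pass through unchanged.
#'
#' @param rec a [Recording-class].
#' @param targetFs target sampling rate in Hz; `rec` must be at an integer
#'   multiple of `targetFs`.
#' @return A [Recording-class] at `targetFs`.
#' @examples
#' rec <- Recording(sin(2 * pi * 3 * seq(0, 2, by = 1 / 2000)), fs = 2000)
#' low <- downsample(rec, 250)
#' samplingRate(low)
#' @export
downsample <- function(rec, targetFs) {
  stopifnot(is(rec, "Recording"))
  assertScalarPositive(targetFs, "targetFs")
  factor <- rec@fs / targetFs
  if (abs(factor - round(factor)) > 1e-8)
    stop("parameter error: fs / targetFs must be an integer", call. = FALSE)
  factor <- as.integer(round(factor))
  if (factor == 1L) return(rec)
  x <- rec@samples
  mu <- mean(x)
  bw <- signal::butter(4, 0.8 / factor, type = "low")
  xf <- signal::filtfilt(bw, x - mu) + mu
  idx <- seq.int(1L, length(x), by = factor)
  Recording(xf[idx], fs = targetFs, subjectId = rec@subjectId,
            group = rec@group, phase = rec@phase, t0 = rec@t0)
}
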