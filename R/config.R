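#' @include utils.R
NULL

#' PipelineConfig: hyperparameters of the full pipeline
#'
#' Gathers the segmentation, clustering and symbolization settings with
#' their standard defaults: prominence 0.03 mL, window 2 s, phase duration
#' bounds 0.05-2 s, K = 5 references per phase, 10 K-means iterations,
#' Sakoe-Chiba radius 0.01 s, reference length 0.2 s and outlier quantile
#' 0.95, at a sampling rate of 250 Hz, plus the BS-DBA settings (batch size
#' 32, 5 epochs) and the master seed.
#'
#' @slot fs sampling rate in Hz.
#' @slot prominence minimum volume prominence (mL) for inspiration starts.
#' @slot window prominence evaluation window (s).
#' @slot minDur,maxDur admissible phase durations (s).
#' @slot kInspiration,kExpiration number of references per phase.
#' @slot kmeansIterations K-means iteration budget.
#' @slot sakoeChibaRadius DTW band radius (s).
#' @slot refLength reference sequence length (s).
#' @slot alpha outlier quantile level.
#' @slot batchSize,epochs BS-DBA settings.
#' @slot seed master seed.
#' @seealso [pipelineConfig()]
#' @export
setClass("PipelineConfig",
  representation(fs = "numeric", prominence = "numeric", window = "numeric",
                 minDur = "numeric", maxDur = "numeric",
                 kInspiration = "numeric", kExpiration = "numeric",
                 kmeansIterations = "numeric", sakoeChibaRadius = "numeric",
                 refLength = "numeric", alpha = "numeric",
                 batchSize = "numeric", epochs = "numeric",
                 seed = "numeric"))

setValidity("PipelineConfig", function(object) {
  msg <- character()
  for (f in c("fs", "prominence", "window", "minDur", "maxDur",
              "kInspiration", "kExpiration", "kmeansIterations",
              "sakoeChibaRadius", "refLength", "batchSize", "epochs")) {
    v <- slot(object, f)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("%s must be a positive scalar", f))
  }
  if (object@minDur >= object@maxDur) msg <- c(msg, "minDur must be < maxDur")
  if (object@alpha <= 0 || object@alpha > 1)
    msg <- c(msg, "alpha must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Build a pipeline configuration
#'
#' @param fs sampling rate in Hz (default 250).
#' @param prominence minimum volume prominence in mL (default 0.03).
#' @param window prominence evaluation window in s (default 2).
#' @param minDur,maxDur admissible phase durations in s (defaults 0.05, 2).
#' @param kInspiration,kExpiration number of reference shapes per phase
#'   (default 5 each).
#' @param kmeansIterations K-means iteration budget (default 10).
#' @param sakoeChibaRadius DTW band radius in s (default 0.01).
#' @param refLength reference sequence length in s (default 0.2).
#' @param alpha outlier quantile level (default 0.95).
#' @param batchSize,epochs BS-DBA settings (defaults 32, 5).
#' @param seed master seed (default 1).
#' @return A [PipelineConfig-class].
#' @export
pipelineConfig <- function(fs = 250, prominence = 0.03, window = 2,
                           minDur = 0.05, maxDur = 2, kInspiration = 5,
                           kExpiration = 5, kmeansIterations = 10,
                           sakoeChibaRadius = 0.01, refLength = 0.2,
                           alpha = 0.95, batchSize = 32, epochs = 5,
                           seed = 1) {
  new("PipelineConfig", fs = fs, prominence = prominence, window = window,
      minDur = minDur, maxDur = maxDur, kInspiration = kInspiration,
      kExpiration = kExpiration, kmeansIterations = kmeansIterations,
      sakoeChibaRadius = sakoeChibaRadius, refLength = refLength,
      alpha = alpha, batchSize = batchSize, epochs = epochs, seed = seed)
}

.configFields <- function() {
  c("fs", "prominence", "window", "minDur", "maxDur", "kInspiration",
    "kExpiration", "kmeansIterations", "sakoeChibaRadius", "refLength",
    "alpha", "batchSize", "epochs", "seed")
}

#' Convert a PipelineConfig to a named list
#' @param config a [PipelineConfig-class].
#' @return named list of parameter values.
#' @export
configAsList <- function(config) {
  stopifnot(is(config, "PipelineConfig"))
  stats::setNames(lapply(.configFields(), function(f) slot(config, f)),
                  .configFields())
}

#' Read / write a pipeline configuration as YAML
#'
#' `readPipelineConfig` applies the standard defaults for any omitted
#' field and rejects unknown fields, reporting the offending name.
#'
#' @param path YAML file path.
#' @return A [PipelineConfig-class] (read) or `path`, invisibly (write).
#' @export
readPipelineConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), .configFields())
  if (length(unknown))
    stop("config error: unknown field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  bad <- names(vals)[!vapply(vals, function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v), logical(1))]
  if (length(bad))
    stop("config error: non-numeric value for field(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  do.call(pipelineConfig, vals)
}

#' @rdname readPipelineConfig
#' @param config a [PipelineConfig-class].
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(configAsList(config), path)
  invisible(path)
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig:\n")
  for (f in .configFields())
    cat(sprintf("  %s = %g\n", f, slot(object, f)))
})
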