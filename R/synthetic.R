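#' @include segmentation.R config.R
NULL

#' Define a synthetic cycle archetype
#'
#' The generator composes recordings from parametric cycle archetypes
#' mirroring the shape families seen in rodent nasal airflow: sinusoidal
#' inspirations, biphasic inspirations (air entering in two phases),
#' delayed inspirations (pre-inspiratory pause), sinusoidal expirations and
#' expirations opening with a post-inspiratory pause of graded duration.
#'
#' @param name archetype name (used as the ground-truth label).
#' @param inspShape `"half_sine"`, `"biphasic"` or `"delayed"`.
#' @param expShape `"half_sine"` or `"post_insp_pause"`.
#' @param ti,te nominal inspiration/expiration durations in s (defaults
#'   0.15 each, i.e. the ~0.3 s murine cycle).
#' @param amplitude peak inspiratory flow in mL/s (default 1.5, giving a
#'   tidal volume of ~0.14 mL).
#' @param inspParam gap depth (biphasic, in (0, 1)) or pause fraction
#'   (delayed).
#' @param expPause post-inspiratory pause duration in s.
#' @return A [CycleArchetype-class].
#' @seealso [generateRecording()]
#' @export
cycleArchetype <- function(name, inspShape = "half_sine",
                           expShape = "half_sine", ti = 0.15, te = 0.15,
                           amplitude = 1.5, inspParam = 0.5, expPause = 0.1) {
  new("CycleArchetype", name = name, inspShape = inspShape,
      expShape = expShape, ti = ti, te = te, amplitude = amplitude,
      inspParam = inspParam, expPause = expPause)
}

#' A default set of six archetypes spanning the main shape families
#'
#' Three inspiration families (sinusoidal, biphasic, delayed) and
#' expiration families (sinusoidal, and post-inspiratory pauses of graded
#' duration), combined so that each archetype pairs one inspiration family
#' with one expiration family.
#'
#' @param amplitude peak inspiratory flow in mL/s.
#' @return Named list of [CycleArchetype-class] objects.
#' @export
defaultArchetypes <- function(amplitude = 1.5) {
  list(
    sine = cycleArchetype("sine", "half_sine", "half_sine",
                          amplitude = amplitude),
    biphasic = cycleArchetype("biphasic", "biphasic", "half_sine",
                              ti = 0.20, amplitude = amplitude,
                              inspParam = 0.8),
    delayed = cycleArchetype("delayed", "delayed", "half_sine",
                             ti = 0.25, amplitude = amplitude,
                             inspParam = 0.4),
    pause_short = cycleArchetype("pause_short", "half_sine",
                                 "post_insp_pause", te = 0.25,
                                 amplitude = amplitude, expPause = 0.1),
    pause_long = cycleArchetype("pause_long", "half_sine",
                                "post_insp_pause", te = 0.40,
                                amplitude = amplitude, expPause = 0.22)
  )
}

# Render one cycle of an archetype at the given duration scaling; the
# expiration amplitude is balanced so the cycle's net volume is exactly 0.
# Midpoint sampling keeps the first inspiration sample strictly positive so
# the volume minimum falls on the cycle boundary.
.renderCycle <- function(arch, fs, tiScale = 1, teScale = 1) {
  nIn <- max(3L, as.integer(roundHalfUp(arch@ti * tiScale * fs)))
  nEx <- max(3L, as.integer(roundHalfUp(arch@te * teScale * fs)))
  tauI <- (seq_len(nIn) - 0.5) / nIn
  insp <- switch(arch@inspShape,
    half_sine = sin(pi * tauI),
    biphasic = sin(pi * tauI) * (1 - arch@inspParam * sin(pi * tauI)^6),
    delayed = {
      # a small residual inflow during the pause keeps the volume minimum
      # pinned at the pause start, as in real recordings where flow is
      # never exactly zero
      pf <- arch@inspParam
      eps <- 0.06
      ifelse(tauI < pf, eps,
             eps + (1 - eps) * sin(pi * (tauI - pf) / (1 - pf)))
    })
  insp <- arch@amplitude * insp / max(insp)
  tauE <- (seq_len(nEx) - 0.5) / nEx
  expi <- switch(arch@expShape,
    half_sine = -sin(pi * tauE),
    post_insp_pause = {
      # small residual outflow during the post-inspiratory pause, so the
      # volume maximum stays pinned at the pause start under noise
      q <- arch@expPause / arch@te
      eps <- 0.06
      ifelse(tauE < q, -eps,
             -(eps + (1 - eps) * sin(pi * (tauE - q) / (1 - q))))
    })
  expi <- expi * sum(insp) / sum(-expi)  # balance inhaled/exhaled volume
  list(flow = c(insp, expi), nIn = nIn, nEx = nEx)
}

#' Generate a synthetic airflow recording with ground truth
#'
#' Concatenates archetype cycles with per-cycle random duration warping,
#' then adds white Gaussian noise and a slow sinusoidal baseline drift.
#' Each cycle is rendered with zero net volume (inspired volume equals
#' expired volume), so the noise-free volume trace returns to baseline at
#' every cycle boundary and segmentation recovers the programmed
#' boundaries.
#'
#' @param archetypes list of [CycleArchetype-class] objects (or a single
#'   one).
#' @param archetypeSequence character or integer vector naming the
#'   archetype of each successive cycle.
#' @param fs sampling rate in Hz (default 250).
#' @param noiseSd standard deviation of additive white noise in mL/s
#'   (default 0). Mutually exclusive with `snrDb`.
#' @param snrDb if given, sets the noise level so the clean-signal RMS to
#'   noise RMS ratio equals this many dB.
#' @param drift list with `freq` (Hz) and `amplitude` (mL/s) of the
#'   sinusoidal baseline drift; default amplitude 0 (no drift). The drift
#'   phase is drawn at random.
#' @param warpPct per-cycle uniform duration warp: each phase duration is
#'   scaled by `1 + U(-warpPct, warpPct)`; must be < 0.5.
#' @param seed integer seed; identical seeds give identical output.
#' @param subjectId,group,phase recording metadata.
#' @return List with `recording` (a [Recording-class]) and `truth` (a
#'   data.frame with per-cycle `cycle`, `archetype`, `t_in`, `t_out`,
#'   `t_end` sample indices and `t_in_s`, `t_out_s`, `t_end_s` seconds).
#' @examples
#' arch <- defaultArchetypes()
#' g <- generateRecording(arch, rep("sine", 10), seed = 1)
#' nrow(g$truth)
#' @export
generateRecording <- function(archetypes, archetypeSequence, fs = 250,
                              noiseSd = 0, snrDb = NULL,
                              drift = list(freq = 0.05, amplitude = 0),
                              warpPct = 0, seed = NULL,
                              subjectId = "synthetic", group = "unspecified",
                              phase = "unspecified") {
  if (is(archetypes, "CycleArchetype")) archetypes <- list(archetypes)
  if (is.null(names(archetypes)))
    names(archetypes) <- vapply(archetypes, function(a) a@name, character(1))
  if (warpPct < 0 || warpPct >= 0.5)
    stop("parameter error: warpPct must be in [0, 0.5)")
  archetypeSequence <- if (is.numeric(archetypeSequence))
    names(archetypes)[archetypeSequence] else as.character(archetypeSequence)
  if (!all(archetypeSequence %in% names(archetypes)))
    stop("parameter error: unknown archetype in sequence")
  withSeed(seed, {
    nc <- length(archetypeSequence)
    flows <- vector("list", nc)
    nIn <- integer(nc)
    nEx <- integer(nc)
    for (i in seq_len(nc)) {
      sc <- if (warpPct > 0) 1 + runif(2, -warpPct, warpPct) else c(1, 1)
      r <- .renderCycle(archetypes[[archetypeSequence[i]]], fs, sc[1], sc[2])
      flows[[i]] <- r$flow
      nIn[i] <- r$nIn
      nEx[i] <- r$nEx
    }
    flow <- unlist(flows)
    n <- length(flow)
    if (!is.null(snrDb)) {
      if (noiseSd != 0)
        stop("parameter error: give either noiseSd or snrDb, not both")
      noiseSd <- rmsValue(flow) / 10^(snrDb / 20)
    }
    if (noiseSd > 0) flow <- flow + rnorm(n, 0, noiseSd)
    if ((drift$amplitude %||% 0) > 0) {
      ph0 <- runif(1, 0, 2 * pi)
      flow <- flow + drift$amplitude *
        sin(2 * pi * drift$freq * (seq_len(n) - 1L) / fs + ph0)
    }
    tIn <- cumsum(c(1L, (nIn + nEx)[-nc]))
    tOut <- tIn + nIn
    tEnd <- tIn + nIn + nEx
    truth <- data.frame(cycle = seq_len(nc), archetype = archetypeSequence,
                        t_in = tIn, t_out = tOut, t_end = tEnd,
                        t_in_s = (tIn - 1L) / fs, t_out_s = (tOut - 1L) / fs,
                        t_end_s = (tEnd - 1L) / fs)
    list(recording = Recording(flow, fs, subjectId = subjectId,
                               group = group, phase = phase),
         truth = truth)
  })
}

#' Generate a cohort of synthetic recordings
#'
#' Draws, for every subject, a per-cycle archetype sequence from its
#' group's mixture and generates the recording. Per-subject seeds are
#' derived deterministically from the master seed.
#'
#' @param nPerGroup subjects per group.
#' @param groups character vector of group labels.
#' @param classMixtures named list (one element per group) of named
#'   probability vectors over archetype names; each must sum to 1.
#' @param archetypes list of [CycleArchetype-class] objects.
#' @param cyclesPerRecording number of cycles per recording.
#' @param fs,noiseSd,snrDb,drift,warpPct as in [generateRecording()].
#' @param phase experimental phase label for all recordings.
#' @param seed master seed.
#' @return List of per-subject lists, each with `recording` and `truth`.
#' @export
generateCohort <- function(nPerGroup, groups, classMixtures,
                           archetypes = defaultArchetypes(),
                           cyclesPerRecording = 200, fs = 250, noiseSd = 0,
                           snrDb = NULL, drift = list(freq = 0.05,
                                                      amplitude = 0),
                           warpPct = 0, phase = "pre", seed = 1) {
  if (is.null(names(archetypes)))
    names(archetypes) <- vapply(archetypes, function(a) a@name, character(1))
  stopifnot(all(groups %in% names(classMixtures)))
  for (g in groups) {
    mix <- classMixtures[[g]]
    if (abs(sum(mix) - 1) > 1e-8)
      stop("parameter error: mixture for group '", g, "' must sum to 1")
    if (!all(names(mix) %in% names(archetypes)))
      stop("parameter error: mixture for group '", g,
           "' names unknown archetypes")
  }
  out <- list()
  k <- 0L
  for (g in groups) {
    mix <- classMixtures[[g]]
    for (i in seq_len(nPerGroup)) {
      k <- k + 1L
      sid <- sprintf("%s_%d", g, i)
      seq_i <- withSeed(childSeed(seed, 7L * k),
                        sample(names(mix), cyclesPerRecording,
                               replace = TRUE, prob = mix))
      out[[sid]] <- generateRecording(archetypes, seq_i, fs = fs,
                                      noiseSd = noiseSd, snrDb = snrDb,
                                      drift = drift, warpPct = warpPct,
                                      seed = childSeed(seed, 7L * k + 3L),
                                      subjectId = sid, group = g,
                                      phase = phase)
    }
  }
  out
}

#' Subsample evenly spaced training cycles from recordings
#'
#' Segments every recording, ranks its cycles by inspiration start time and
#' picks `cyclesPerRecording` of them at positions nearest to an even time
#' grid over the recording span (all cycles are taken, with a message, when
#' fewer are available). The selected cycles are pooled into an
#' inspiration training set and an expiration training set of equal size,
#' with cycle pairing preserved (element i of both sets comes from the same
#' cycle).
#'
#' @param recordings list of [Recording-class] objects (or of lists with a
#'   `recording` element, as returned by [generateCohort()]).
#' @param cyclesPerRecording cycles to keep per recording.
#' @param config a [pipelineConfig()] for the segmentation parameters.
#' @return List with `inspiration` and `expiration` ([PhaseSet-class],
#'   cycle-aligned), `nCycles` (total selected) and `perRecording` (named
#'   integer vector).
#' @export
subsampleTraining <- function(recordings, cyclesPerRecording,
                              config = pipelineConfig()) {
  recs <- lapply(recordings, function(r)
    if (is(r, "Recording")) r else r$recording)
  inspAll <- list()
  expAll <- list()
  startI <- integer()
  startE <- integer()
  src <- character()
  per <- integer()
  for (rec in recs) {
    seg <- segmentRecording(rec, config)
    N <- length(seg@tIn)
    if (N == 0L) {
      per[rec@subjectId] <- 0L
      next
    }
    if (N <= cyclesPerRecording) {
      if (N < cyclesPerRecording)
        message(sprintf("subsampleTraining: %s has only %d cycles",
                        rec@subjectId, N))
      sel <- seq_len(N)
    } else {
      tins <- seg@tIn  # already time-ordered
      grid <- seq(tins[1], tins[N], length.out = cyclesPerRecording)
      sel <- integer(cyclesPerRecording)
      prev <- 0L
      for (j in seq_len(cyclesPerRecording)) {
        nearest <- which.min(abs(tins - grid[j]))
        cand <- max(prev + 1L, nearest)
        cand <- min(cand, N - (cyclesPerRecording - j))
        sel[j] <- cand
        prev <- cand
      }
    }
    phases <- splitPhases(rec, seg)
    inspAll <- c(inspAll, phases$inspiration@sequences[sel])
    expAll <- c(expAll, phases$expiration@sequences[sel])
    startI <- c(startI, seg@tIn[sel])
    startE <- c(startE, seg@tOut[sel])
    src <- c(src, rep(rec@subjectId, length(sel)))
    per[rec@subjectId] <- length(sel)
  }
  fs <- recs[[1]]@fs
  list(inspiration = PhaseSet(inspAll, "inspiration", startI, src, fs),
       expiration = PhaseSet(expAll, "expiration", startE, src, fs),
       nCycles = length(inspAll), perRecording = per)
}

#' Phase shape families of a set of archetypes
#'
#' Two archetypes belong to the same inspiration (expiration) family when
#' their inspiration (expiration) shapes and shape parameters coincide;
#' e.g. two archetypes sharing a sinusoidal expiration are one expiration
#' family, while pauses of different durations are distinct families.
#'
#' @param archetypes list of [CycleArchetype-class] objects.
#' @return data.frame with columns `name`, `inspFamily`, `expFamily`.
#' @export
phaseFamilies <- function(archetypes) {
  if (is.null(names(archetypes)))
    names(archetypes) <- vapply(archetypes, function(a) a@name, character(1))
  data.frame(
    name = names(archetypes),
    inspFamily = vapply(archetypes, function(a)
      sprintf("%s:%g", a@inspShape, a@inspParam), character(1)),
    expFamily = vapply(archetypes, function(a)
      sprintf("%s:%g", a@expShape, a@expPause), character(1)),
    row.names = NULL)
}

#' Per-cycle symbol accuracy against generator ground truth
#'
#' Matches each classified (non-outlier) cycle of a symbolization to the
#' nearest ground-truth cycle by inspiration start time, maps each
#' inspiration letter and expiration digit to a shape family by majority
#' vote, and scores a cycle as correct when both phases map to the true
#' families. Outlier and unclassified cycles are excluded from the
#' accuracy and reported through `classifiedFraction`.
#'
#' @param sym a [SymbolicRecording-class].
#' @param truth the ground-truth data.frame from [generateRecording()].
#' @param archetypes the archetype list used for generation.
#' @return List with `accuracy` (pair accuracy among classified cycles),
#'   `inspAccuracy`, `expAccuracy`, `classifiedFraction` and `n` (matched
#'   classified cycles).
#' @export
symbolAccuracy <- function(sym, truth, archetypes) {
  stopifnot(is(sym, "SymbolicRecording"))
  fam <- phaseFamilies(archetypes)
  cyc <- sym@cycles
  cyc <- cyc[cyc$classified & !cyc$outlier, , drop = FALSE]
  if (nrow(cyc) == 0L)
    return(list(accuracy = NA_real_, inspAccuracy = NA_real_,
                expAccuracy = NA_real_, classifiedFraction = 0, n = 0L))
  idx <- vapply(cyc$t_in_s, function(t)
    which.min(abs(truth$t_in_s - t)), integer(1))
  arcs <- truth$archetype[idx]
  trueI <- fam$inspFamily[match(arcs, fam$name)]
  trueE <- fam$expFamily[match(arcs, fam$name)]
  majorityMap <- function(pred, truth) {
    vapply(split(truth, pred), function(x)
      names(sort(table(x), decreasing = TRUE))[1], character(1))
  }
  mapI <- majorityMap(cyc$insp_symbol, trueI)
  mapE <- majorityMap(cyc$exp_symbol, trueE)
  okI <- mapI[cyc$insp_symbol] == trueI
  okE <- mapE[cyc$exp_symbol] == trueE
  allCyc <- sym@cycles
  list(accuracy = mean(okI & okE), inspAccuracy = mean(okI),
       expAccuracy = mean(okE),
       classifiedFraction = sum(!allCyc$outlier) / nrow(allCyc),
       n = nrow(cyc))
}

#' Write a ground-truth table as CSV
#'
#' @param truth the `truth` data.frame from [generateRecording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  utils::write.csv(truth[, c("cycle", "archetype", "t_in_s", "t_out_s",
                             "t_end_s")], path, row.names = FALSE)
  invisible(path)
}
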