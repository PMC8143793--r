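#' @title Outcome record of one induction attempt
#'
#' @description One row of the induction experiment: the outcome of the
#' rapid-pacing protocol delivered at one pacing site of one model.
#'
#' @slot model model identifier.
#' @slot site pacing-site identifier.
#' @slot outcome `"none"`, `"RD"`, or `"macroscopic_reentry"`.
#' @slot sustainedDuration ms of self-sustained activity post-pacing.
#' @slot rdEvents list of [RDEvent-class] detected post-pacing.
#' @slot valid FALSE if the solver diverged (record excluded from
#'   statistics, never counted as `"none"`).
#' @slot meta list (stimulus amplitude, timings, ambiguity flags).
#' @export
setClass("InducibilityRecord",
         representation(model = "character", site = "character",
                        outcome = "character", sustainedDuration = "numeric",
                        rdEvents = "list", valid = "logical", meta = "list"))

setValidity("InducibilityRecord", function(object) {
  if (!object@outcome %in% c("none", "RD", "macroscopic_reentry", "invalid"))
    return("unknown outcome label")
  if (object@outcome == "RD" && length(object@rdEvents) == 0)
    return("RD outcome requires at least one RDEvent")
  if (object@outcome %in% c("RD", "macroscopic_reentry") &&
      object@sustainedDuration < 5000)
    return("non-none outcomes require >= 5000 ms sustained activity")
  TRUE
})

#' @describeIn InducibilityRecord-class display method
#' @param object an `InducibilityRecord`
#' @export
setMethod("show", "InducibilityRecord", function(object) {
  cat(sprintf("InducibilityRecord %s @ %s: %s (sustained %g ms, %d RD events%s)\n",
              object@model, object@site, object@outcome,
              object@sustainedDuration, length(object@rdEvents),
              if (!object@valid) ", INVALID" else ""))
})

#' Build the clinical rapid-pacing stimulus train
#'
#' Twelve stimuli: two initial pulses at a 300 ms coupling interval, then
#' coupling intervals ramping down by 20 ms to 200 ms, with the remaining
#' intervals held at 200 ms so that the train totals 12 pulses
#' (intervals 300, 280, 260, 240, 220, then 200 repeated).
#'
#' @param nodes stimulated node set.
#' @param site site label.
#' @param amplitude pulse amplitude (pA/pF); NA to resolve later.
#' @param t0 onset of the first pulse (ms).
#' @param duration pulse duration (ms).
#' @return a [StimulusTrain-class] with 12 pulses (last onset `t0` + 2500).
#' @export
buildPacingTrain <- function(nodes, site = "site", amplitude = NA_real_,
                             t0 = 0, duration = 2) {
  intervals <- c(300, seq(280, 200, by = -20), rep(200, 5))
  onsets <- t0 + cumsum(c(0, intervals))
  stimulusTrain(nodes, onsets = onsets, duration = duration,
                amplitude = amplitude, site = site)
}

#' Run the arrhythmia-induction protocol at one pacing site
#'
#' Delivers the 12-pulse rapid-pacing train, then monitors for
#' self-sustaining activity for `observe` ms. Activity is self-sustaining
#' while at least one activation-threshold upstroke occurs anywhere in
#' every successive `quietWindow` ms; once sustained for the full horizon
#' the post-pacing voltage series is analyzed and the episode classified
#' as a reentrant driver (RD) or macroscopic (obstacle-anchored) reentry.
#' Tissue membrane states start from cell models paced to limit cycle at
#' BCL 500 ms.
#'
#' @param mesh substrate [BilayerMesh-class].
#' @param nodes pacing-site node set.
#' @param solver a [SolverConfig-class] (`duration` is managed internally).
#' @param cond a [ConductivityConfig-class].
#' @param amplitude stimulus amplitude (pA/pF); NA to bisect the capture
#'   threshold at this site and use twice that.
#' @param observe observation horizon post-pacing (ms).
#' @param quietWindow self-sustainment window (ms).
#' @param recordDt sampling of the analyzed post-pacing series (ms).
#' @param model model label stored in the record.
#' @param site site label.
#' @param op optional pre-assembled diffusion operator.
#' @param minRotations minimum rotor lifetime in rotations (see
#'   [detectPhaseSingularities()]).
#' @return an [InducibilityRecord-class].
#' @export
runInduction <- function(mesh, nodes, solver = solverConfig(dt = 0.05),
                         cond = conductivityConfig(), amplitude = NA_real_,
                         observe = 5000, quietWindow = 500, recordDt = 10,
                         model = "model", site = "site", op = NULL,
                         minRotations = 1) {
  if (is.null(op)) op <- assembleDiffusion(mesh, cond, solver@beta, solver@Cm)
  if (is.na(amplitude))
    amplitude <- 2 * captureThreshold(mesh, nodes, solver, cond)
  train <- buildPacingTrain(nodes, site = site, amplitude = amplitude)
  pacingEnd <- max(train@onsets) + train@duration
  sPace <- solver; sPace@duration <- pacingEnd
  r1 <- tryCatch(
    runSimulation(mesh, sPace, cond, list(train), op = op, recordVm = FALSE,
                  init = "limit_cycle"),
    error = function(e) e)
  if (inherits(r1, "error") || r1@diverged) {
    return(new("InducibilityRecord", model = model, site = site,
               outcome = "invalid", sustainedDuration = 0,
               rdEvents = list(), valid = FALSE,
               meta = list(error = if (inherits(r1, "error"))
                 conditionMessage(r1) else "divergence")))
  }
  sObs <- solver; sObs@duration <- observe + quietWindow
  sObs@outputStride <- max(1, round(recordDt / solver@dt))
  r2 <- tryCatch(
    runSimulation(mesh, sObs, cond, list(), op = op, recordVm = TRUE,
                  states = r1@finalState, t0 = pacingEnd,
                  actTref = pacingEnd,
                  quietStopAfter = quietWindow, quietMonitorFrom = pacingEnd),
    error = function(e) e)
  if (inherits(r2, "error") || r2@diverged) {
    return(new("InducibilityRecord", model = model, site = site,
               outcome = "invalid", sustainedDuration = 0,
               rdEvents = list(), valid = FALSE,
               meta = list(error = if (inherits(r2, "error"))
                 conditionMessage(r2) else "divergence")))
  }
  sustained <- (r2@tStop - pacingEnd) >= observe
  dur <- if (sustained) r2@tStop - pacingEnd else
    max(0, (if (is.na(r2@lastActivation)) pacingEnd else r2@lastActivation)
        - pacingEnd)
  if (!sustained) {
    return(new("InducibilityRecord", model = model, site = site,
               outcome = "none", sustainedDuration = dur,
               rdEvents = list(), valid = TRUE,
               meta = list(amplitude = amplitude, pacingEnd = pacingEnd)))
  }
  cls <- classifyArrhythmia(r2, mesh, minRotations = minRotations)
  new("InducibilityRecord", model = model, site = site,
      outcome = cls$outcome, sustainedDuration = dur,
      rdEvents = cls$events, valid = TRUE,
      meta = list(amplitude = amplitude, pacingEnd = pacingEnd,
                  ambiguous = cls$ambiguous))
}

#' Classify a sustained post-pacing episode
#'
#' Computes activation phase from the post-pacing voltage series and
#' searches for persistent phase singularities (rotor organizing centers).
#' If at least one persistent singularity exists the episode is a
#' reentrant driver (`"RD"`); otherwise, if the spatial phase winds by
#' +/- 2 pi around an interior boundary loop (an anatomical obstacle such
#' as a vein ostium or the mitral rim), it is `"macroscopic_reentry"`.
#' When both signatures are present the driver analysis takes precedence
#' and the ambiguity is flagged.
#'
#' @param result post-pacing [SimulationResult-class] with sampled voltage.
#' @param mesh the substrate mesh.
#' @param minRotations minimum rotor lifetime in rotations.
#' @return list with `outcome`, `events` (list of [RDEvent-class]),
#'   `ambiguous` flag.
#' @export
classifyArrhythmia <- function(result, mesh, minRotations = 1) {
  ph <- computePhase(result@vm, result@vmTimes)
  ev <- detectPhaseSingularities(ph, mesh, result@vmTimes,
                                 minRotations = minRotations)
  macro <- .holeCirculation(ph$phase, mesh)
  if (length(ev) > 0) {
    return(list(outcome = "RD", events = ev, ambiguous = macro))
  }
  if (macro)
    return(list(outcome = "macroscopic_reentry", events = list(),
                ambiguous = FALSE))
  # sustained activity with neither signature: repetitive activity whose
  # organizing center is off-mesh or unresolved; flagged, not counted as RD
  list(outcome = "macroscopic_reentry", events = list(), ambiguous = TRUE)
}

# TRUE if the spatial phase winds consistently around any interior
# boundary loop (macroscopic circulation around an obstacle)
.holeCirculation <- function(phase, mesh) {
  loops <- boundaryLoops(mesh)
  if (length(loops) == 0) return(FALSE)
  nT <- ncol(phase)
  frames <- unique(pmax(1, round(seq(0.25, 1, length.out = 8) * nT)))
  for (lp in loops) {
    w <- vapply(frames, function(f) {
      p <- phase[lp, f]
      if (anyNA(p)) return(NA_real_)
      d <- diff(c(p, p[1]))
      d <- (d + pi) %% (2 * pi) - pi
      sum(d)
    }, numeric(1))
    w <- w[!is.na(w)]
    if (length(w) >= 4 && median(abs(w)) > pi) return(TRUE)
  }
  FALSE
}
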