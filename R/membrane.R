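#' @title Human atrial membrane model with remodeling variants
#'
#' @description
#' `MembraneModel` wraps the Courtemanche-Ramirez-Nattel human atrial
#' action-potential model together with multiplicative conductance scalings
#' that encode electrical remodeling. Three variants are provided:
#' \describe{
#'   \item{`baseline`}{the published model, all scalings 1;}
#'   \item{`afib`}{AFib-remodeled: I_Kur and I_to reduced by 50\%, I_CaL by
#'     70\% (factors 0.5, 0.5, 0.3), fitted to clinical monophasic action
#'     potentials from AFib patients;}
#'   \item{`fibrotic`}{fibrotic-remodeled: the AFib scalings with a further
#'     50\% I_CaL reduction (net factor 0.15), 40\% I_Na reduction (0.6) and
#'     50\% I_K1 reduction (0.5), representing TGF-beta1-driven remodeling.}
#' }
#' Scalings compose multiplicatively with the baseline maximal conductances.
#'
#' @slot name variant label.
#' @slot scalings named numeric vector of multiplicative factors for
#'   `I_Kur`, `I_to`, `I_CaL`, `I_Na`, `I_K1`; all in (0, 1].
#'
#' @seealso [makeMembraneModel()], [paceToLimitCycle()], [measureAPMetrics()]
#' @export
setClass("MembraneModel",
         representation(name = "character", scalings = "numeric"))

setValidity("MembraneModel", function(object) {
  need <- c("I_Kur", "I_to", "I_CaL", "I_Na", "I_K1")
  if (!identical(sort(names(object@scalings)), sort(need)))
    return(sprintf("scalings must be named %s", paste(need, collapse = ", ")))
  s <- object@scalings
  if (any(s <= 0) || any(s > 1))
    return("all scaling factors must lie in (0, 1]")
  TRUE
})

#' Action-potential summary metrics
#'
#' @slot apd action-potential duration at the stated repolarization level (ms).
#' @slot dvdtMax maximum upstroke rate (mV/ms).
#' @slot vRest diastolic voltage (mV).
#' @slot vPeak peak voltage (mV).
#' @slot repolLevel repolarization fraction used for `apd`.
#' @export
setClass("APMetrics",
         representation(apd = "numeric", dvdtMax = "numeric",
                        vRest = "numeric", vPeak = "numeric",
                        repolLevel = "numeric"))

setValidity("APMetrics", function(object) {
  if (object@apd <= 0) return("apd must be positive")
  if (object@dvdtMax <= 0) return("dvdtMax must be positive")
  if (object@vPeak <= object@vRest) return("vPeak must exceed vRest")
  TRUE
})

#' @describeIn MembraneModel-class display method
#' @param object a `MembraneModel`
#' @export
setMethod("show", "MembraneModel", function(object) {
  cat("MembraneModel variant:", object@name, "\n")
  s <- object@scalings
  mod <- s[s != 1]
  if (length(mod) == 0) {
    cat("  published baseline conductances (no scaling)\n")
  } else {
    cat("  scaled currents:",
        paste(sprintf("%s x%g", names(mod), mod), collapse = ", "), "\n")
  }
})

#' @describeIn APMetrics-class display method
#' @param object an `APMetrics`
#' @export
setMethod("show", "APMetrics", function(object) {
  cat(sprintf("APMetrics: APD%d = %.2f ms, dV/dt_max = %.1f mV/ms, ",
              round(100 * object@repolLevel), object@apd, object@dvdtMax))
  cat(sprintf("V_rest = %.1f mV, V_peak = %.1f mV\n",
              object@vRest, object@vPeak))
})

#' Construct a membrane model variant
#'
#' @param variant one of `"baseline"`, `"afib"`, `"fibrotic"`.
#' @return a [MembraneModel-class] object.
#' @examples
#' makeMembraneModel("afib")
#' @export
makeMembraneModel <- function(variant = c("baseline", "afib", "fibrotic")) {
  if (length(variant) != 1 || !variant[1] %in% c("baseline", "afib", "fibrotic"))
    stop("unknown membrane model variant: ",
         paste(as.character(variant), collapse = ", "),
         " (expected one of baseline, afib, fibrotic)")
  variant <- variant[1]
  s <- c(I_Kur = 1, I_to = 1, I_CaL = 1, I_Na = 1, I_K1 = 1)
  if (variant %in% c("afib", "fibrotic")) {
    s["I_Kur"] <- 0.5
    s["I_to"]  <- 0.5
    s["I_CaL"] <- 0.3
  }
  if (variant == "fibrotic") {
    s["I_CaL"] <- s["I_CaL"] * 0.5   # net 0.15 of baseline
    s["I_Na"]  <- 0.6
    s["I_K1"]  <- 0.5
  }
  new("MembraneModel", name = variant, scalings = s)
}

#' Conductance scalings of a membrane model
#' @param model a [MembraneModel-class].
#' @return named numeric vector of multiplicative factors.
#' @export
conductanceScalings <- function(model) model@scalings

# scale vector in the order the C++ core expects: I_Na, I_K1, I_to, I_Kur, I_CaL
.scalesVec <- function(model) {
  s <- model@scalings
  unname(s[c("I_Na", "I_K1", "I_to", "I_Kur", "I_CaL")])
}

#' Initial (published resting) state vector of the ionic model
#' @return named numeric vector: voltage (mV), 12 voltage gates, fca/u/v
#'   release gates, and intracellular/SR concentrations (mM).
#' @export
initialMembraneState <- function() cpp_crn_initial_state()

#' Integrate the single-cell ionic model
#'
#' Runs the cell model for `duration` ms with rectangular current pulses at
#' `stimOnsets`. The default integrator is Rush-Larsen for gating variables
#' with forward-Euler concentration updates; `method = "rk4"` selects a
#' classical 4th-order Runge-Kutta integrator over the full system, intended
#' as a high-resolution reference (use a small `dt`, e.g. 0.005 ms).
#'
#' @param model a [MembraneModel-class].
#' @param duration simulated time (ms).
#' @param dt time step (ms).
#' @param state initial state; defaults to the published resting state.
#' @param stimOnsets numeric vector of pulse start times (ms).
#' @param stimDur pulse duration (ms).
#' @param stimAmp pulse amplitude (pA/pF, depolarizing positive).
#' @param recordDt sampling interval of the returned voltage trace (ms).
#' @param method `"rl"` (Rush-Larsen) or `"rk4"` (reference integrator).
#' @param useTables use tabulated voltage-dependent rates (Rush-Larsen only).
#' @return list with `time`, `vm`, `final_state`, `dvdt_max`, `t_dvdt_max`.
#' @export
cellRun <- function(model, duration, dt = 0.0125,
                    state = initialMembraneState(),
                    stimOnsets = 0, stimDur = 2, stimAmp = 20,
                    recordDt = 0.05, method = c("rl", "rk4"),
                    useTables = TRUE) {
  method <- match.arg(method)
  stopifnot(duration > 0, dt > 0, length(state) == 21L)
  cpp_cell_run(as.numeric(state), .scalesVec(model), dt, duration,
               as.numeric(stimOnsets), stimDur, stimAmp, recordDt,
               if (method == "rl") 0L else 1L, useTables)
}

#' Diastolic stimulus threshold of a cell model
#'
#' Bisects the amplitude of a 2 ms rectangular pulse until the smallest
#' amplitude eliciting an action potential (peak above 0 mV) is bracketed.
#'
#' @param model a [MembraneModel-class].
#' @param stimDur pulse duration (ms).
#' @param dt integration step (ms).
#' @param state starting state (defaults to published resting state).
#' @param iter number of bisection iterations.
#' @return threshold amplitude (pA/pF).
#' @export
diastolicThreshold <- function(model, stimDur = 2, dt = 0.0125,
                               state = initialMembraneState(), iter = 10) {
  fires <- function(amp) {
    r <- cellRun(model, duration = 50, dt = dt, state = state,
                 stimOnsets = 0, stimDur = stimDur, stimAmp = amp)
    max(r$vm) > 0
  }
  lo <- 0; hi <- 8
  while (!fires(hi)) {
    hi <- hi * 2
    if (hi > 512) stop("no measurable AP: cell does not fire at any amplitude")
  }
  for (k in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Pace a cell model to limit cycle
#'
#' Applies periodic stimulation at basic cycle length `bcl` until the
#' action-potential duration of successive beats changes by less than `tol`
#' ms, or `maxBeats` is reached. The stimulus is a 2 ms pulse at twice the
#' diastolic threshold unless `stimAmp` is given.
#'
#' @param model a [MembraneModel-class].
#' @param bcl basic cycle length (ms), must be positive.
#' @param maxBeats cap on the number of beats (at least 1).
#' @param tol successive-beat APD convergence tolerance (ms).
#' @param dt integration step (ms).
#' @param stimAmp stimulus amplitude (pA/pF); default 2x diastolic threshold.
#' @param repolLevel repolarization fraction for the APD used in the
#'   convergence criterion (default 0.9, i.e. APD90).
#' @param recordDt sampling of the returned final-beat trace (ms).
#' @return list with `state` (converged full state at end of last beat),
#'   `trace` (list `time`, `vm` of the final beat), `metrics`
#'   ([APMetrics-class] of the final beat), `apdHistory`, `converged`,
#'   `beats`, `stimAmp`.
#' @export
paceToLimitCycle <- function(model, bcl = 500, maxBeats = 200, tol = 0.1,
                             dt = 0.0125, stimAmp = NULL, repolLevel = 0.9,
                             recordDt = 0.05) {
  stopifnot(bcl > 0)
  if (maxBeats < 1) stop("maxBeats must be at least 1")
  if (is.null(stimAmp)) stimAmp <- 2 * diastolicThreshold(model, dt = dt)
  state <- initialMembraneState()
  apdPrev <- NA_real_
  apdHist <- numeric(0)
  converged <- FALSE
  trace <- NULL
  met <- NULL
  for (beat in seq_len(maxBeats)) {
    r <- cellRun(model, duration = bcl, dt = dt, state = state,
                 stimOnsets = 0, stimDur = 2, stimAmp = stimAmp,
                 recordDt = recordDt)
    state <- r$final_state
    met <- tryCatch(
      measureAPMetrics(r$time, r$vm, repolLevel = repolLevel),
      error = function(e) stop("no measurable AP during limit-cycle pacing (beat ",
                               beat, "): ", conditionMessage(e)))
    apdHist <- c(apdHist, met@apd)
    trace <- list(time = r$time, vm = r$vm)
    dvdtIon <- r$dvdt_ion_max
    if (!is.na(apdPrev) && abs(met@apd - apdPrev) < tol) {
      converged <- TRUE
      break
    }
    apdPrev <- met@apd
  }
  list(state = state, trace = trace, metrics = met, dvdtIon = dvdtIon,
       apdHistory = apdHist, converged = converged, beats = length(apdHist),
       stimAmp = stimAmp)
}

#' Measure action-potential metrics from a voltage trace
#'
#' The trace must contain exactly one stimulated upstroke. The upstroke
#' instant is the time of maximum dV/dt (finite differences); APD is the
#' time from that instant to the downward crossing of
#' `vPeak - repolLevel * (vPeak - vRest)` (linear interpolation between
#' samples). `vRest` is the trace minimum, `vPeak` the maximum.
#'
#' @param time sample times (ms), uniform spacing assumed for dV/dt.
#' @param vm sampled transmembrane voltage (mV).
#' @param repolLevel repolarization fraction in (0, 1); 0.9 gives APD90.
#' @return an [APMetrics-class] object.
#' @export
measureAPMetrics <- function(time, vm, repolLevel = 0.9) {
  stopifnot(length(time) == length(vm), length(vm) >= 3)
  if (repolLevel <= 0 || repolLevel >= 1)
    stop("repolLevel must lie in (0, 1)")
  dv <- diff(vm) / diff(time)
  iUp <- which.max(dv)
  dvdtMax <- dv[iUp]
  tUp <- (time[iUp] + time[iUp + 1]) / 2
  vRest <- min(vm)
  vPeak <- max(vm)
  if (dvdtMax <= 0 || vPeak - vRest < 5)
    stop("unrepolarized trace: no stimulated upstroke found")
  vCross <- vPeak - repolLevel * (vPeak - vRest)
  iPk <- which.max(vm)
  below <- which(vm[-seq_len(iPk)] <= vCross)
  if (length(below) == 0)
    stop("unrepolarized trace: no crossing of the repolarization level")
  i2 <- iPk + below[1]          # first sample at/below the level after peak
  i1 <- i2 - 1
  tCross <- if (vm[i1] == vm[i2]) time[i2] else
    time[i1] + (vm[i1] - vCross) / (vm[i1] - vm[i2]) * (time[i2] - time[i1])
  new("APMetrics", apd = tCross - tUp, dvdtMax = dvdtMax,
      vRest = vRest, vPeak = vPeak, repolLevel = repolLevel)
}

#' Cell-scale remodeling contrast between the fibrotic and AFib variants
#'
#' Paces the AFib-remodeled and fibrotic-remodeled variants at the same basic
#' cycle length until the successive-beat APD criterion of
#' [paceToLimitCycle()] is met for both; both models are then paced for that
#' common number of beats and compared on the final beat. Reported upstroke
#' velocity is the maximum ionic rate of rise of the membrane voltage (the
#' applied stimulus current is excluded so that the metric does not depend
#' on the pacing amplitude).
#'
#' @param bcl basic cycle length (ms).
#' @param tol successive-beat APD90 convergence tolerance (ms).
#' @param dt integration step (ms).
#' @return list with `apdIncreasePct` (percent APD90 prolongation of the
#'   fibrotic vs the AFib variant), `upstrokeReductionPct` (percent decrease
#'   in maximum upstroke velocity), per-variant `apd`, `dvdt`, `vRest`, and
#'   the common number of `beats`.
#' @export
remodelingContrast <- function(bcl = 500, tol = 0.1, dt = 0.0125) {
  pa <- paceToLimitCycle(makeMembraneModel("afib"), bcl = bcl, tol = tol,
                         dt = dt)
  pf <- paceToLimitCycle(makeMembraneModel("fibrotic"), bcl = bcl, tol = tol,
                         dt = dt)
  n <- max(pa$beats, pf$beats)
  rerun <- function(model, amp) {
    st <- initialMembraneState()
    r <- NULL
    for (b in seq_len(n)) {
      r <- cellRun(model, duration = bcl, dt = dt, state = st,
                   stimOnsets = 0, stimDur = 2, stimAmp = amp)
      st <- r$final_state
    }
    met <- measureAPMetrics(r$time, r$vm)
    list(apd = met@apd, dvdt = r$dvdt_ion_max, vRest = met@vRest)
  }
  a <- rerun(makeMembraneModel("afib"), pa$stimAmp)
  f <- rerun(makeMembraneModel("fibrotic"), pf$stimAmp)
  list(apdIncreasePct = 100 * (f$apd / a$apd - 1),
       upstrokeReductionPct = 100 * (1 - f$dvdt / a$dvdt),
       afib = a, fibrotic = f, beats = n,
       converged = pa$converged && pf$converged)
}

# converged limit-cycle state for a variant, cached per (variant, bcl, dt)
.limitCycleState <- function(variant, bcl = 500, dt = 0.0125) {
  key <- sprintf("lc_%s_%g_%g", variant, bcl, dt)
  if (is.null(.atrialRDCache[[key]])) {
    p <- paceToLimitCycle(makeMembraneModel(variant), bcl = bcl, dt = dt)
    .atrialRDCache[[key]] <- p$state
  }
  .atrialRDCache[[key]]
}

#' Write a voltage trace as CSV
#' @param trace list with `time` and `vm` (as returned in `$trace` by
#'   [paceToLimitCycle()] or by [cellRun()]).
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeTraceCSV <- function(trace, path) {
  df <- data.frame(time_ms = trace$time, Vm_mV = trace$vm)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
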