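#' @title Conductivity configuration
#'
#' @description
#' Monodomain conductivities (S/m) for healthy (AFib-remodeled) and fibrotic
#' tissue, plus the interlayer link conductivity of bilayer models. Healthy
#' tissue uses a 5:1 longitudinal:transverse anisotropy ratio
#' (0.409/0.0820 S/m, calibrated against effective conduction velocities of
#' 71.49 and 37.14 cm/s); fibrotic tissue uses reduced conductivities with
#' an exaggerated 8:1 ratio (0.177/0.0221 S/m) representing interstitial
#' fibrosis and gap-junction remodeling.
#'
#' @slot sigmaLHealthy,sigmaTHealthy healthy longitudinal/transverse (S/m).
#' @slot sigmaLFibrotic,sigmaTFibrotic fibrotic longitudinal/transverse (S/m).
#' @slot sigmaInterlayer interlayer link conductivity (S/m).
#' @export
setClass("ConductivityConfig",
         representation(sigmaLHealthy = "numeric", sigmaTHealthy = "numeric",
                        sigmaLFibrotic = "numeric", sigmaTFibrotic = "numeric",
                        sigmaInterlayer = "numeric"))

setValidity("ConductivityConfig", function(object) {
  v <- c(object@sigmaLHealthy, object@sigmaTHealthy, object@sigmaLFibrotic,
         object@sigmaTFibrotic, object@sigmaInterlayer)
  if (any(v <= 0)) return("all conductivities must be positive")
  if (object@sigmaLHealthy < object@sigmaTHealthy)
    return("healthy sigma_L must be >= sigma_T")
  if (object@sigmaLFibrotic < object@sigmaTFibrotic)
    return("fibrotic sigma_L must be >= sigma_T")
  TRUE
})

#' Construct a conductivity configuration
#' @param sigmaLHealthy,sigmaTHealthy,sigmaLFibrotic,sigmaTFibrotic,sigmaInterlayer
#'   conductivities in S/m; defaults are the calibrated atrial values.
#' @return a [ConductivityConfig-class].
#' @export
conductivityConfig <- function(sigmaLHealthy = 0.409, sigmaTHealthy = 0.0820,
                               sigmaLFibrotic = 0.177,
                               sigmaTFibrotic = 0.0221,
                               sigmaInterlayer = 0.8) {
  new("ConductivityConfig", sigmaLHealthy = sigmaLHealthy,
      sigmaTHealthy = sigmaTHealthy, sigmaLFibrotic = sigmaLFibrotic,
      sigmaTFibrotic = sigmaTFibrotic, sigmaInterlayer = sigmaInterlayer)
}

#' @title Monodomain solver configuration
#'
#' @description
#' Numerical settings of the operator-split monodomain solver. The membrane
#' capacitance and surface-to-volume ratio set the voltage diffusivity
#' D = sigma / (10 * beta * Cm) in mm^2/ms (sigma in S/m, beta in 1/um, Cm
#' in uF/cm^2).
#'
#' @slot Cm membrane capacitance (uF/cm^2).
#' @slot beta surface-to-volume ratio (1/um).
#' @slot dt time step (ms), at most 0.05.
#' @slot outputStride voltage sampling interval in steps.
#' @slot duration simulated time (ms).
#' @export
setClass("SolverConfig",
         representation(Cm = "numeric", beta = "numeric", dt = "numeric",
                        outputStride = "numeric", duration = "numeric"))

setValidity("SolverConfig", function(object) {
  if (object@dt > 0.05) return("dt must be <= 0.05 ms")
  if (any(c(object@Cm, object@beta, object@dt, object@outputStride,
            object@duration) <= 0))
    return("all solver parameters must be positive")
  TRUE
})

#' Construct a solver configuration
#' @param Cm membrane capacitance (uF/cm^2).
#' @param beta surface-to-volume ratio (1/um).
#' @param dt time step (ms).
#' @param outputStride sampling interval in steps.
#' @param duration simulated time (ms).
#' @return a [SolverConfig-class].
#' @export
solverConfig <- function(Cm = 1, beta = 0.14, dt = 0.025, outputStride = 40,
                         duration = 100) {
  new("SolverConfig", Cm = Cm, beta = beta, dt = dt,
      outputStride = outputStride, duration = duration)
}

#' @title Result of a monodomain tissue simulation
#'
#' @description
#' Per-node sampled voltage series, activation times (first upward crossing
#' of the activation threshold after a reference time), final full membrane
#' states, and bookkeeping from the run.
#'
#' @slot vm numeric matrix (N x T) of sampled voltages (mV); may be empty.
#' @slot vmTimes sample times (ms).
#' @slot activationTimes per-node first activation (ms; NA = unactivated).
#' @slot finalState full membrane state matrix (21 x N).
#' @slot lastActivation time of the last threshold crossing anywhere (ms).
#' @slot tStop time at which the run ended (ms).
#' @slot diverged TRUE if the voltage bound check tripped.
#' @slot meta list (solver settings, thresholds, stimulus description).
#' @export
setClass("SimulationResult",
         representation(vm = "matrix", vmTimes = "numeric",
                        activationTimes = "numeric", finalState = "matrix",
                        lastActivation = "numeric", tStop = "numeric",
                        diverged = "logical", meta = "list"))

#' @describeIn SimulationResult-class display method
#' @param object a `SimulationResult`
#' @export
setMethod("show", "SimulationResult", function(object) {
  cat(sprintf("SimulationResult: %d nodes, t = 0..%g ms%s\n",
              length(object@activationTimes), object@tStop,
              if (object@diverged) " [DIVERGED]" else ""))
  cat(sprintf("  activated nodes: %d/%d; last activation at %s ms\n",
              sum(!is.na(object@activationTimes)),
              length(object@activationTimes),
              format(object@lastActivation)))
  if (length(object@vmTimes))
    cat(sprintf("  vm sampled at %d times (every %g ms)\n",
                length(object@vmTimes),
                if (length(object@vmTimes) > 1)
                  diff(object@vmTimes[1:2]) else NA))
})

#' @rdname SimulationResult-class
#' @param result a `SimulationResult`
#' @export
activationTimes <- function(result) result@activationTimes

#' @title Stimulus train
#'
#' @description A train of rectangular current pulses delivered to a node
#' set. `amplitude` is in pA/pF (numerically uA/cm^2 at Cm = 1 uF/cm^2);
#' `NA` means "resolve to twice the tissue capture threshold at run time".
#'
#' @slot site pacing-site identifier.
#' @slot nodes stimulated node indices.
#' @slot onsets pulse onset times (ms), strictly increasing.
#' @slot duration pulse duration (ms).
#' @slot amplitude pulse amplitude (pA/pF) or NA.
#' @export
setClass("StimulusTrain",
         representation(site = "character", nodes = "integer",
                        onsets = "numeric", duration = "numeric",
                        amplitude = "numeric"))

setValidity("StimulusTrain", function(object) {
  if (length(object@onsets) > 1 && any(diff(object@onsets) <= 0))
    return("pulse onsets must be strictly increasing")
  if (length(object@nodes) == 0) return("empty stimulus node set")
  TRUE
})

#' Construct a stimulus train
#' @param nodes stimulated node indices.
#' @param onsets pulse onset times (ms).
#' @param duration pulse duration (ms).
#' @param amplitude amplitude (pA/pF); NA resolves to 2x capture threshold.
#' @param site site label.
#' @return a [StimulusTrain-class].
#' @export
stimulusTrain <- function(nodes, onsets = 0, duration = 2, amplitude = NA_real_,
                          site = "site") {
  new("StimulusTrain", site = as.character(site), nodes = as.integer(nodes),
      onsets = as.numeric(onsets), duration = duration,
      amplitude = as.numeric(amplitude))
}

# conversion S/m -> mm^2/ms given beta (1/um) and Cm (uF/cm^2)
.sigmaToD <- function(sigma, beta, Cm) sigma / (10 * beta * Cm)

#' Assemble the monodomain diffusion operator
#'
#' Linear-triangle finite-element stiffness assembly with a per-element
#' anisotropic diffusivity tensor D = D_T I + (D_L - D_T) f f' (f the unit
#' fiber direction projected into the element plane); fibrotic elements use
#' the fibrotic conductivities. The mass matrix is lumped. Interlayer links
#' are returned as pairwise exchange rates (1/ms), derived from a 1D
#' conductor whose cross-section is the node's lumped (Voronoi) area, which
#' makes the rate sigma_interlayer / (10 beta Cm L^2) independent of that
#' area.
#'
#' @param mesh a [BilayerMesh-class] with fibers and fibrosis labels.
#' @param cond a [ConductivityConfig-class].
#' @param beta surface-to-volume ratio (1/um).
#' @param Cm membrane capacitance (uF/cm^2).
#' @return list with sparse `K` (dgCMatrix, rows sum to 0), lumped mass
#'   vector `mass` (mm^2), link arrays `linkA`, `linkB`, `linkKa`, `linkKb`
#'   (rates in 1/ms).
#' @export
assembleDiffusion <- function(mesh, cond = conductivityConfig(), beta = 0.14,
                              Cm = 1) {
  p <- mesh@nodes; el <- mesh@elements
  E <- nrow(el); N <- nrow(p)
  v1 <- p[el[, 1], , drop = FALSE]
  e1 <- p[el[, 2], , drop = FALSE] - v1
  e2 <- p[el[, 3], , drop = FALSE] - v1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area2 <- sqrt(rowSums(nrm^2))           # 2 * area
  if (any(area2 <= 1e-12)) {
    bad <- which(area2 <= 1e-12)[1]
    stop("degenerate element with zero area: element ", bad)
  }
  area <- area2 / 2
  # local orthonormal in-plane basis (u along e1, w = n x u)
  l1 <- sqrt(rowSums(e1^2))
  u <- e1 / l1
  nhat <- nrm / area2
  w <- cbind(nhat[, 2] * u[, 3] - nhat[, 3] * u[, 2],
             nhat[, 3] * u[, 1] - nhat[, 1] * u[, 3],
             nhat[, 1] * u[, 2] - nhat[, 2] * u[, 1])
  # 2D vertex coordinates in (u, w)
  x1 <- 0; y1 <- 0
  x2 <- l1; y2 <- 0
  x3 <- rowSums(e2 * u); y3 <- rowSums(e2 * w)
  # shape-function gradients (constant per element)
  bx <- cbind(y2 - y3, y3 - y1, y1 - y2) / area2
  by <- cbind(x3 - x2, x1 - x3, x2 - x1) / area2
  # fiber direction in the local plane
  f <- mesh@fibers
  fu <- rowSums(f * u); fw <- rowSums(f * w)
  fl <- sqrt(fu^2 + fw^2)
  if (any(fl < 1e-8)) {
    bad <- which(fl < 1e-8)[1]
    stop("fiber vector perpendicular to element plane (zero in-plane ",
         "component): element ", bad)
  }
  fu <- fu / fl; fw <- fw / fl
  DL <- ifelse(mesh@fibrotic,
               .sigmaToD(cond@sigmaLFibrotic, beta, Cm),
               .sigmaToD(cond@sigmaLHealthy, beta, Cm))
  DT <- ifelse(mesh@fibrotic,
               .sigmaToD(cond@sigmaTFibrotic, beta, Cm),
               .sigmaToD(cond@sigmaTHealthy, beta, Cm))
  dla <- DL - DT
  Dxx <- DT + dla * fu * fu
  Dxy <- dla * fu * fw
  Dyy <- DT + dla * fw * fw
  # K_ij = -area * (bx_i Dxx bx_j + (bx_i by_j + by_i bx_j) Dxy + by_i Dyy by_j)
  ii <- jj <- integer(9 * E); xx <- numeric(9 * E)
  q <- 0L
  for (a in 1:3) for (b in 1:3) {
    val <- -area * (bx[, a] * Dxx * bx[, b] +
                    (bx[, a] * by[, b] + by[, a] * bx[, b]) * Dxy +
                    by[, a] * Dyy * by[, b])
    ii[q + seq_len(E)] <- el[, a]
    jj[q + seq_len(E)] <- el[, b]
    xx[q + seq_len(E)] <- val
    q <- q + E
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(N, N))
  mass <- numeric(N)
  for (a in 1:3) {
    acc <- rowsum(area / 3, group = el[, a])
    mass[as.integer(rownames(acc))] <- mass[as.integer(rownames(acc))] + acc
  }
  links <- mesh@links
  if (nrow(links) > 0) {
    L <- sqrt(rowSums((p[links[, 1], , drop = FALSE] -
                         p[links[, 2], , drop = FALSE])^2))
    kRate <- .sigmaToD(cond@sigmaInterlayer, beta, Cm) / L^2
    linkA <- links[, 1]; linkB <- links[, 2]
    linkKa <- kRate; linkKb <- kRate
  } else {
    linkA <- linkB <- integer(0)
    linkKa <- linkKb <- numeric(0)
  }
  list(K = methods::as(K, "CsparseMatrix"), mass = mass,
       linkA = linkA, linkB = linkB, linkKa = linkKa, linkKb = linkKb)
}

# area-weighted node classes: TRUE where more than half the incident
# element area is fibrotic
.nodeFibrotic <- function(mesh) {
  el <- mesh@elements
  ar <- elementAreas(mesh)
  N <- nrow(mesh@nodes)
  tot <- fib <- numeric(N)
  for (a in 1:3) {
    acc <- rowsum(ar, group = el[, a])
    tot[as.integer(rownames(acc))] <- tot[as.integer(rownames(acc))] + acc
    accf <- rowsum(ar * mesh@fibrotic, group = el[, a])
    fib[as.integer(rownames(accf))] <- fib[as.integer(rownames(accf))] + accf
  }
  tot > 0 & fib / pmax(tot, 1e-12) > 0.5
}

# initial state matrix (21 x N) from limit-cycle or resting cell states
.initialTissueStates <- function(mesh, healthyVariant = "afib",
                                 fibroticVariant = "fibrotic",
                                 init = c("limit_cycle", "rest")) {
  init <- match.arg(init)
  N <- nrow(mesh@nodes)
  nf <- .nodeFibrotic(mesh)
  if (init == "limit_cycle") {
    sh <- .limitCycleState(healthyVariant)
    sf <- .limitCycleState(fibroticVariant)
  } else {
    sh <- sf <- initialMembraneState()
  }
  states <- matrix(rep(as.numeric(sh), N), nrow = 21)
  if (any(nf)) states[, nf] <- as.numeric(sf)
  states
}

#' Run a monodomain tissue simulation
#'
#' Operator-split monodomain integration: a Rush-Larsen reaction step of the
#' membrane model at every node (healthy nodes use `healthyVariant`,
#' fibrotic nodes `fibroticVariant`), followed by an explicit diffusion step
#' through the assembled operator, with exact pairwise relaxation of
#' interlayer links. Deterministic for identical inputs.
#'
#' @param mesh a [BilayerMesh-class].
#' @param solver a [SolverConfig-class].
#' @param cond a [ConductivityConfig-class].
#' @param stimuli list of [StimulusTrain-class] objects.
#' @param healthyVariant,fibroticVariant membrane variant names for
#'   non-fibrotic and fibrotic nodes.
#' @param init `"limit_cycle"` (cell states paced to limit cycle at BCL 500
#'   ms) or `"rest"` (published resting state).
#' @param states optional 21 x N matrix of initial states (overrides `init`).
#' @param op optional pre-assembled operator from [assembleDiffusion()].
#' @param recordVm store the sampled voltage matrix (memory permitting).
#' @param actThreshold activation threshold (mV), upward crossing.
#' @param actTref reference time for activation maps (ms).
#' @param quietStopAfter if positive, stop when no activation anywhere for
#'   this long (ms) after `quietMonitorFrom`.
#' @param quietMonitorFrom time from which the quiescence monitor runs (ms).
#' @param t0 start time label (ms).
#' @return a [SimulationResult-class].
#' @export
runSimulation <- function(mesh, solver = solverConfig(),
                          cond = conductivityConfig(), stimuli = list(),
                          healthyVariant = "afib",
                          fibroticVariant = "fibrotic",
                          init = "limit_cycle", states = NULL, op = NULL,
                          recordVm = TRUE, actThreshold = -10, actTref = 0,
                          quietStopAfter = 0, quietMonitorFrom = 0,
                          t0 = 0) {
  if (is.null(op)) op <- assembleDiffusion(mesh, cond, solver@beta, solver@Cm)
  if (is.null(states))
    states <- .initialTissueStates(mesh, healthyVariant, fibroticVariant,
                                   init)
  N <- nrow(mesh@nodes)
  stopifnot(ncol(states) == N)
  nf <- .nodeFibrotic(mesh)
  scales2 <- rbind(.scalesVec(makeMembraneModel(healthyVariant)),
                   .scalesVec(makeMembraneModel(fibroticVariant)))
  K <- op$K
  # stimulus bookkeeping: resolve NA amplitudes to 2x capture threshold
  stimNodes <- list(); ampScale <- numeric(0)
  onsets <- numeric(0); trainOf <- integer(0)
  stimDur <- if (length(stimuli)) stimuli[[1]]@duration else 2
  stimAmp <- 1
  if (length(stimuli)) {
    amps <- vapply(stimuli, function(s) s@amplitude, numeric(1))
    if (anyNA(amps))
      stop("unresolved stimulus amplitude (NA); use captureThreshold() ",
           "or set amplitude explicitly")
    durs <- vapply(stimuli, function(s) s@duration, numeric(1))
    if (length(unique(durs)) > 1)
      stop("all stimulus trains must share one pulse duration")
    stimDur <- durs[1]
    stimAmp <- 1
    for (k in seq_along(stimuli)) {
      s <- stimuli[[k]]
      stimNodes[[k]] <- s@nodes - 1L
      ampScale <- c(ampScale, rep(s@amplitude, length(s@nodes)))
      onsets <- c(onsets, s@onsets)
      trainOf <- c(trainOf, rep(k - 1L, length(s@onsets)))
    }
  }
  res <- cpp_tissue_run(states, scales2, as.integer(nf),
                        K@p, K@i, K@x, 1 / op$mass,
                        as.integer(op$linkA - 1L), as.integer(op$linkB - 1L),
                        op$linkKa, op$linkKb,
                        solver@dt, solver@duration, t0,
                        stimNodes, ampScale,
                        matrix(onsets, ncol = 1), trainOf, stimDur, stimAmp,
                        solver@dt * solver@outputStride,
                        actThreshold, actTref,
                        quietStopAfter, quietMonitorFrom, recordVm)
  new("SimulationResult",
      vm = if (recordVm) res$vm else matrix(numeric(0), 0, 0),
      vmTimes = if (recordVm) as.numeric(res$vm_times) else numeric(0),
      activationTimes = as.numeric(res$activation_times),
      finalState = res$final_state,
      lastActivation = as.numeric(res$last_activation),
      tStop = res$t_stop, diverged = res$diverged,
      meta = list(solver = solver, cond = cond, actThreshold = actThreshold,
                  nStim = length(stimuli)))
}

#' Tissue capture threshold by bisection
#'
#' Smallest amplitude of a single 2 ms pulse at the given node set that
#' elicits a propagated activation (any node outside the stimulated set
#' crosses the activation threshold), bracketed by bisection.
#'
#' @param mesh a [BilayerMesh-class].
#' @param nodes stimulated node set.
#' @param solver a [SolverConfig-class] (duration is overridden).
#' @param cond a [ConductivityConfig-class].
#' @param iter bisection iterations.
#' @param ... passed to [runSimulation()].
#' @return threshold amplitude (pA/pF).
#' @export
captureThreshold <- function(mesh, nodes, solver = solverConfig(),
                             cond = conductivityConfig(), iter = 7, ...) {
  solver@duration <- 30
  op <- assembleDiffusion(mesh, cond, solver@beta, solver@Cm)
  others <- setdiff(seq_len(nrow(mesh@nodes)), nodes)
  fires <- function(amp) {
    s <- stimulusTrain(nodes, onsets = 0, amplitude = amp)
    r <- runSimulation(mesh, solver, cond, list(s), op = op,
                       recordVm = FALSE, ...)
    any(!is.na(r@activationTimes[others]))
  }
  lo <- 0; hi <- 20
  while (!fires(hi)) {
    hi <- hi * 2
    if (hi > 1280) stop("no capture at any amplitude")
  }
  for (k in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Measure conduction velocity on a strip
#'
#' For a planar wave launched from one edge of a rectangular strip, CV is
#' the distance between the 25% and 75% stations along the propagation
#' direction divided by the difference of mean activation times at those
#' stations.
#'
#' @param result a [SimulationResult-class] with activation times.
#' @param mesh the strip mesh (sheet geometry).
#' @param direction `"x"` or `"y"`: the propagation axis.
#' @param stations fractions along the axis (default 0.25, 0.75).
#' @return CV in cm/s, or `NA` with attribute `reason =
#'   "propagation failure"` if either station was not activated.
#' @export
measureCV <- function(result, mesh, direction = c("x", "y"),
                      stations = c(0.25, 0.75)) {
  direction <- match.arg(direction)
  coord <- mesh@nodes[, if (direction == "x") 1 else 2]
  span <- range(coord)
  at <- result@activationTimes
  h <- (mesh@meta$resolution %||% 200) / 1000
  stat <- vapply(stations, function(fr) {
    xs <- span[1] + fr * diff(span)
    sel <- abs(coord - xs) <= h / 2 + 1e-9
    ts <- at[sel]
    if (all(is.na(ts))) return(c(NA_real_, NA_real_))
    c(mean(ts, na.rm = TRUE), mean(coord[sel][!is.na(ts)]))
  }, numeric(2))
  if (anyNA(stat[1, ]) || diff(stat[1, ]) <= 0) {
    out <- NA_real_
    attr(out, "reason") <- "propagation failure"
    return(out)
  }
  100 * diff(stat[2, ]) / diff(stat[1, ])  # mm/ms -> cm/s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
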