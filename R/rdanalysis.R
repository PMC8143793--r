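#' @title Reentrant-driver event
#'
#' @description A tracked phase-singularity trajectory: the organizing
#' center of a rotor, with chirality, lifespan, time-averaged position and
#' the anatomical region it localizes to.
#'
#' @slot trajectory numeric matrix with columns `t`, `x`, `y`, `z` (ms, mm).
#' @slot chirality +1 or -1 (sign of the phase winding).
#' @slot lifespan trajectory duration (ms).
#' @slot meanPosition time-averaged position (mm).
#' @slot region region id at the mean position (0 if unassigned).
#' @slot morphology morphology cluster id (0 before clustering).
#' @export
setClass("RDEvent",
         representation(trajectory = "matrix", chirality = "numeric",
                        lifespan = "numeric", meanPosition = "numeric",
                        region = "integer", morphology = "integer"))

setValidity("RDEvent", function(object) {
  if (object@lifespan <= 0) return("lifespan must be positive")
  if (!object@chirality %in% c(-1, 1)) return("chirality must be +1 or -1")
  TRUE
})

#' @describeIn RDEvent-class display method
#' @param object an `RDEvent`
#' @export
setMethod("show", "RDEvent", function(object) {
  cat(sprintf("RDEvent: chirality %+d, lifespan %.0f ms, mean position (%.1f, %.1f, %.1f) mm, region %d\n",
              object@chirality, object@lifespan, object@meanPosition[1],
              object@meanPosition[2], object@meanPosition[3], object@region))
})

#' Activation phase from a voltage series
#'
#' Phase is the argument of the analytic signal (Hilbert transform) of the
#' mean-subtracted voltage, with a sliding-window mean removal to suppress
#' baseline drift. Quiescent nodes (no oscillation) get `NA` phase.
#'
#' @param vm N x T voltage matrix (mV), rows = nodes.
#' @param times sample times (ms), uniform spacing.
#' @param window sliding mean-removal window (ms).
#' @param minRange minimum peak-to-peak voltage (mV) for a node to count
#'   as oscillating.
#' @return list with `phase` (N x T, radians in (-pi, pi]), `active`
#'   logical per node, `period` (dominant cycle length estimate, ms).
#' @export
computePhase <- function(vm, times, window = 500, minRange = 20) {
  nT <- ncol(vm)
  if (nT < 8) stop("series too short for phase analysis")
  dtS <- times[2] - times[1]
  X <- t(vm)                                   # T x N
  wlen <- max(3L, min(nT - 1L, round(window / dtS)))
  if (wlen %% 2 == 0) wlen <- wlen + 1L
  kern <- rep(1 / wlen, wlen)
  mu <- stats::filter(X, kern, sides = 2)
  # extend the running mean into the window edges
  half <- (wlen - 1L) / 2L
  mu <- apply(mu, 2, function(c0) {
    c0[seq_len(half)] <- c0[half + 1]
    c0[(nT - half + 1):nT] <- c0[nT - half]
    c0
  })
  Y <- X - mu
  rng <- apply(vm, 1, function(v) diff(range(v)))
  active <- rng >= minRange
  # analytic signal per node via FFT (columns of Y)
  H <- numeric(nT)
  if (nT %% 2 == 0) {
    H[c(1, nT / 2 + 1)] <- 1
    H[2:(nT / 2)] <- 2
  } else {
    H[1] <- 1
    H[2:((nT + 1) / 2)] <- 2
  }
  Z <- stats::mvfft(Y) * H
  A <- stats::mvfft(Z, inverse = TRUE) / nT
  phase <- t(atan2(Im(A), Re(A)))              # N x T
  phase[!active, ] <- NA_real_
  # dominant period from the mean unwrapped phase advance of active nodes
  period <- NA_real_
  if (any(active)) {
    dp <- diff(t(phase[active, , drop = FALSE]))  # (T-1) x n
    dp <- (dp + pi) %% (2 * pi) - pi
    rate <- abs(mean(dp, na.rm = TRUE)) / dtS     # rad/ms
    if (is.finite(rate) && rate > 1e-6) period <- 2 * pi / rate
  }
  list(phase = phase, active = active, period = period, times = times)
}

# per-frame phase winding of every triangle; returns elements with |w|=2pi
.frameSingularities <- function(phase, mesh, frame) {
  el <- mesh@elements
  p <- phase[, frame]
  p1 <- p[el[, 1]]; p2 <- p[el[, 2]]; p3 <- p[el[, 3]]
  d1 <- (p2 - p1 + pi) %% (2 * pi) - pi
  d2 <- (p3 - p2 + pi) %% (2 * pi) - pi
  d3 <- (p1 - p3 + pi) %% (2 * pi) - pi
  w <- d1 + d2 + d3
  ok <- !is.na(w) & abs(abs(w) - 2 * pi) < 1e-6
  which(ok)
}

#' Detect and track phase singularities
#'
#' Per frame, triangles whose boundary phase difference winds by +/- 2 pi
#' are singular (topological charge +/- 1). Singular points are linked
#' frame-to-frame by nearest neighbor within `linkRadius`, and trajectories
#' shorter than `minRotations` rotation periods are discarded.
#'
#' @param phaseObj output of [computePhase()] (or an N x T phase matrix).
#' @param mesh the mesh.
#' @param times frame times (ms); taken from `phaseObj` if absent.
#' @param linkRadius per-frame linking radius (mm).
#' @param minRotations minimum lifetime in rotation periods.
#' @param partition optional [RegionPartition-class] for region assignment.
#' @return list of [RDEvent-class].
#' @export
detectPhaseSingularities <- function(phaseObj, mesh, times = NULL,
                                     linkRadius = 2, minRotations = 1,
                                     partition = NULL) {
  if (is.list(phaseObj)) {
    phase <- phaseObj$phase
    if (is.null(times)) times <- phaseObj$times
    period <- phaseObj$period
  } else {
    phase <- phaseObj
    period <- NA_real_
  }
  if (is.null(times)) stop("frame times required")
  cen <- elementCentroids(mesh)
  nT <- ncol(phase)
  # active trajectories: list(points = rows (t, x, y, z, elem), chir)
  open <- list()
  done <- list()
  for (f in seq_len(nT)) {
    sing <- .frameSingularities(phase, mesh, f)
    if (length(sing)) {
      p <- phase[, f]
      el <- mesh@elements[sing, , drop = FALSE]
      d1 <- (p[el[, 2]] - p[el[, 1]] + pi) %% (2 * pi) - pi
      d2 <- (p[el[, 3]] - p[el[, 2]] + pi) %% (2 * pi) - pi
      d3 <- (p[el[, 1]] - p[el[, 3]] + pi) %% (2 * pi) - pi
      chir <- sign(d1 + d2 + d3)
    } else chir <- numeric(0)
    pts <- cen[sing, , drop = FALSE]
    used <- rep(FALSE, length(sing))
    keepOpen <- list()
    for (tr in open) {
      last <- tr$points[nrow(tr$points), 2:4]
      best <- 0; bestD <- linkRadius
      for (q in seq_along(sing)) {
        if (used[q] || chir[q] != tr$chir) next
        d <- sqrt(sum((pts[q, ] - last)^2))
        if (d <= bestD) { best <- q; bestD <- d }
      }
      if (best > 0) {
        used[best] <- TRUE
        tr$points <- rbind(tr$points, c(times[f], pts[best, ], sing[best]))
        keepOpen[[length(keepOpen) + 1]] <- tr
      } else {
        done[[length(done) + 1]] <- tr
      }
    }
    for (q in seq_along(sing)) {
      if (used[q]) next
      keepOpen[[length(keepOpen) + 1]] <-
        list(points = matrix(c(times[f], pts[q, ], sing[q]), nrow = 1),
             chir = chir[q])
    }
    open <- keepOpen
  }
  done <- c(done, open)
  dtF <- if (nT > 1) times[2] - times[1] else 0
  minLife <- if (is.finite(period) && !is.na(period))
    minRotations * period else minRotations * 150
  out <- list()
  for (tr in done) {
    life <- tr$points[nrow(tr$points), 1] - tr$points[1, 1] + dtF
    if (life < minLife) next
    mp <- colMeans(tr$points[, 2:4, drop = FALSE])
    reg <- 0L
    if (!is.null(partition)) {
      cen2 <- cen
      j <- which.min(rowSums((cen2 - matrix(mp, nrow(cen2), 3,
                                            byrow = TRUE))^2))
      reg <- partition@region[j]
    } else if (any(mesh@region > 0)) {
      j <- which.min(rowSums((cen - matrix(mp, nrow(cen), 3,
                                           byrow = TRUE))^2))
      reg <- mesh@region[j]
    }
    traj <- tr$points[, 1:4, drop = FALSE]
    colnames(traj) <- c("t", "x", "y", "z")
    out[[length(out) + 1]] <-
      new("RDEvent", trajectory = traj, chirality = tr$chir,
          lifespan = life, meanPosition = mp, region = as.integer(reg),
          morphology = 0L)
  }
  out
}

#' Count unique reentrant morphologies
#'
#' Single-linkage clustering of trajectory mean positions; trajectories
#' closer than `mergeRadius` belong to one morphology.
#'
#' @param events list of [RDEvent-class] (one model, all sites).
#' @param mergeRadius merge radius (mm).
#' @return number of morphology clusters (0 for no events).
#' @export
countUniqueMorphologies <- function(events, mergeRadius = 10) {
  n <- length(events)
  if (n == 0) return(0L)
  if (n == 1) return(1L)
  pos <- t(vapply(events, function(e) e@meanPosition, numeric(3)))
  hc <- stats::hclust(stats::dist(pos), method = "single")
  length(unique(stats::cutree(hc, h = mergeRadius)))
}

#' @title Region-wise inducibility score table
#' @description IdS per region: RD inductions from the region's pacing
#'   sites summed across a cohort's models, divided by the number of
#'   pacing sites in that region; the raw numerator is kept alongside.
#' @slot table data.frame with columns `region`, `sites`, `inductions`,
#'   `ids`.
#' @slot cohort cohort label.
#' @export
setClass("IdSTable",
         representation(table = "data.frame", cohort = "character"))

#' @describeIn IdSTable-class display method
#' @param object an `IdSTable`
#' @export
setMethod("show", "IdSTable", function(object) {
  cat("IdSTable for cohort:", object@cohort, "\n")
  print(object@table, row.names = FALSE)
})

#' Region-wise inducibility scores
#'
#' @param records data.frame with one row per (model, site) induction
#'   attempt: columns `model`, `site`, `outcome`, `siteRegion`. Macroscopic
#'   reentry and invalid records never contribute to the numerator.
#' @param siteRegions named integer vector mapping site name to region id
#'   (used to count sites per region).
#' @param cohort cohort label.
#' @return an [IdSTable-class].
#' @export
computeIdS <- function(records, siteRegions, cohort = "cohort") {
  if (any(is.na(records$siteRegion)))
    stop("record with a site that has no region")
  regs <- sort(unique(as.integer(siteRegions)))
  tab <- do.call(rbind, lapply(regs, function(rg) {
    sitesIn <- names(siteRegions)[siteRegions == rg]
    ind <- sum(records$outcome == "RD" & records$site %in% sitesIn)
    data.frame(region = rg, sites = length(sitesIn), inductions = ind,
               ids = ind / length(sitesIn))
  }))
  new("IdSTable", table = tab, cohort = cohort)
}
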