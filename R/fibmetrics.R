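#' @title Fibrosis spatial-pattern metrics map
#'
#' @description Per-element local fibrosis density (FD), local fibrosis
#' entropy (FE), and the pro-reentry (pro-RD) classification flag derived
#' from the support-vector-machine decision polynomial.
#'
#' @slot fd per-element local fibrosis density in [0, 1].
#' @slot fe per-element local fibrosis entropy in [0, 1].
#' @slot proRD per-element logical pro-RD flag.
#' @slot radius neighborhood radius (mm).
#' @export
setClass("FibrosisMetricsMap",
         representation(fd = "numeric", fe = "numeric", proRD = "logical",
                        radius = "numeric"))

setValidity("FibrosisMetricsMap", function(object) {
  if (any(object@fd < 0 | object@fd > 1, na.rm = TRUE))
    return("FD out of [0, 1]")
  if (any(object@fe < 0 | object@fe > 1 + 1e-12, na.rm = TRUE))
    return("FE out of [0, 1]")
  TRUE
})

#' @describeIn FibrosisMetricsMap-class display method
#' @param object a `FibrosisMetricsMap`
#' @export
setMethod("show", "FibrosisMetricsMap", function(object) {
  cat(sprintf("FibrosisMetricsMap: %d elements, radius %.2f mm\n",
              length(object@fd), object@radius))
  cat(sprintf("  FD mean %.3f, FE mean %.3f, pro-RD fraction %.3f\n",
              mean(object@fd), mean(object@fe), mean(object@proRD)))
})

# element adjacency in CSR-ish arrays with centroid-distance weights
.adjacencyCSR <- function(mesh) {
  adj <- .elementAdjacency(mesh)
  cen <- elementCentroids(mesh)
  pr <- adj$pairs
  w <- sqrt(rowSums((cen[pr[, 1], , drop = FALSE] -
                       cen[pr[, 2], , drop = FALSE])^2))
  E <- nrow(mesh@elements)
  ii <- c(pr[, 1], pr[, 2]); jj <- c(pr[, 2], pr[, 1]); ww <- c(w, w)
  o <- order(ii, jj)
  ii <- ii[o]; jj <- jj[o]; ww <- ww[o]
  p <- c(0L, cumsum(tabulate(ii, nbins = E)))
  list(p = as.integer(p), i = as.integer(jj - 1L), w = ww)
}

#' Local fibrosis density field
#'
#' FD(e) is the area-weighted fraction of fibrotic elements within a
#' geodesic ball of the given radius around element e's centroid (distances
#' measured on the element-adjacency graph).
#'
#' @param mesh a [BilayerMesh-class] with fibrosis labels.
#' @param radius neighborhood radius (mm); must be at least twice the mean
#'   edge length.
#' @return numeric per-element FD vector.
#' @export
localFibrosisDensity <- function(mesh, radius = 2.5) {
  localFibrosisMetrics(mesh, radius)@fd
}

#' Local fibrosis entropy field
#'
#' Within each geodesic neighborhood, let q be the fraction of edge-adjacent
#' element pairs with discordant fibrosis labels; FE is the binary entropy
#' -q log2 q - (1-q) log2 (1-q) (0 log 0 = 0). FE is high where fibrotic
#' and non-fibrotic tissue interleave finely, and 0 in homogeneous or
#' perfectly separated neighborhoods.
#'
#' @inheritParams localFibrosisDensity
#' @return numeric per-element FE vector.
#' @export
localFibrosisEntropy <- function(mesh, radius = 2.5) {
  localFibrosisMetrics(mesh, radius)@fe
}

#' Local fibrosis density, entropy and pro-RD classification
#'
#' Computes FD and FE (see [localFibrosisDensity()],
#' [localFibrosisEntropy()]) in one pass and applies [classifyProRD()].
#'
#' @inheritParams localFibrosisDensity
#' @return a [FibrosisMetricsMap-class].
#' @export
localFibrosisMetrics <- function(mesh, radius = 2.5) {
  h <- sqrt(mean(elementAreas(mesh)) * 2)
  if (radius < 2 * h)
    stop("radius ", radius, " mm too small: must be at least twice the ",
         "mean edge length (", signif(h, 3), " mm)")
  csr <- .adjacencyCSR(mesh)
  r <- cpp_local_fd_fe(csr$p, csr$i, csr$w, elementAreas(mesh),
                       as.integer(mesh@fibrotic), radius)
  new("FibrosisMetricsMap", fd = r$fd, fe = pmin(r$fe, 1),
      proRD = classifyProRD(r$fd, pmin(r$fe, 1)), radius = radius)
}

#' Pro-reentry classification of (FD, FE) pairs
#'
#' Evaluates the support-vector-machine-derived decision polynomial
#' 0.4096 FD^2 + 3.28 FD FE - 0.1036 FE^2 - 0.7112 FD - FE + 0.0429
#' exactly as printed; an element is pro-RD when the value is positive
#' (high density and entropy side) and FD exceeds 0.01 (guarding the
#' positive constant term at zero density).
#'
#' @param fd,fe numeric vectors in [0, 1].
#' @param fdGuard minimum FD for a positive classification.
#' @return logical vector of pro-RD flags.
#' @export
classifyProRD <- function(fd, fe, fdGuard = 0.01) {
  if (any(fd < 0 | fd > 1 | fe < 0 | fe > 1))
    stop("FD and FE must lie in [0, 1]")
  val <- 0.4096 * fd^2 + 3.28 * fd * fe - 0.1036 * fe^2 -
    0.7112 * fd - fe + 0.0429
  (val > 0) & (fd > fdGuard)
}

#' Region-wise pro-RD tissue burden
#'
#' @param metrics a [FibrosisMetricsMap-class].
#' @param partition a [RegionPartition-class].
#' @param mesh the mesh the metrics were computed on.
#' @return named numeric vector: area-weighted fraction of pro-RD tissue
#'   per region.
#' @export
regionProRDBurden <- function(metrics, partition, mesh) {
  ar <- elementAreas(mesh)
  regs <- sort(unique(partition@region))
  out <- vapply(regs, function(rg) {
    sel <- partition@region == rg
    sum(ar[sel & metrics@proRD]) / sum(ar[sel])
  }, numeric(1))
  names(out) <- partition@names[regs]
  out
}

#' @title Quiescent resting-voltage summary
#' @description Pro-trigger surrogate analysis: the pooled 95th-percentile
#'   resting-voltage threshold and each model's fraction of abnormally
#'   depolarized tissue.
#' @slot threshold voltage threshold (mV).
#' @slot fractions per-model fraction of nodes above the threshold.
#' @slot percentile the percentile used.
#' @slot excluded indices of models excluded (still active at the end of
#'   their stimulus-free run).
#' @export
setClass("DepolarizationSummary",
         representation(threshold = "numeric", fractions = "numeric",
                        percentile = "numeric", excluded = "integer"))

#' @describeIn DepolarizationSummary-class display method
#' @param object a `DepolarizationSummary`
#' @export
setMethod("show", "DepolarizationSummary", function(object) {
  cat(sprintf("DepolarizationSummary: %gth percentile threshold %.2f mV\n",
              object@percentile, object@threshold))
  cat(sprintf("  %d models, depolarized fraction %.4f +/- %.4f%s\n",
              length(object@fractions), mean(object@fractions),
              stats::sd(object@fractions),
              if (length(object@excluded))
                sprintf(" (%d excluded)", length(object@excluded)) else ""))
})

#' Quiescent resting-voltage (pro-trigger) analysis
#'
#' Each model is let to reach quasi-equilibrium by a stimulus-free run
#' (1000 ms); final-time voltages are pooled across models, the stated
#' percentile of the pooled distribution (linear-interpolation convention)
#' is the abnormal-depolarization threshold, and each model's depolarized
#' fraction is the share of its nodes strictly above that threshold.
#' Models still showing activations at the end of their run are excluded
#' and reported.
#'
#' @param vmList list of per-model final-time voltage vectors (mV).
#' @param percentile percentile for the threshold (default 95).
#' @param stillActive logical per model: TRUE if the model had not reached
#'   quiescence (excluded from the analysis).
#' @return a [DepolarizationSummary-class].
#' @export
quiescentVmAnalysis <- function(vmList, percentile = 95,
                                stillActive = NULL) {
  if (is.null(stillActive)) stillActive <- rep(FALSE, length(vmList))
  excl <- which(stillActive)
  keep <- setdiff(seq_along(vmList), excl)
  if (length(keep) == 0) stop("no quiescent models to analyze")
  pooled <- unlist(vmList[keep])
  thr <- unname(quantile(pooled, percentile / 100, type = 7))
  fr <- vapply(vmList[keep], function(v) mean(v > thr), numeric(1))
  new("DepolarizationSummary", threshold = thr, fractions = fr,
      percentile = percentile, excluded = as.integer(excl))
}

#' Stimulus-free quasi-equilibrium run of a substrate
#'
#' Runs the tissue model without pacing for `duration` ms from limit-cycle
#' initial states and returns the final voltage per node, for
#' [quiescentVmAnalysis()].
#'
#' @param mesh a [BilayerMesh-class].
#' @param duration run length (ms).
#' @param solver,cond solver and conductivity configurations.
#' @return list with `vm` (final voltages), `stillActive` flag.
#' @export
quiescentRun <- function(mesh, duration = 1000,
                         solver = solverConfig(dt = 0.05),
                         cond = conductivityConfig()) {
  solver@duration <- duration
  r <- runSimulation(mesh, solver, cond, list(), recordVm = FALSE,
                     init = "limit_cycle")
  list(vm = r@finalState[1, ], stillActive = !is.na(r@lastActivation))
}
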