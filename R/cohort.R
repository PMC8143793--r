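#' @title Virtual-cohort specification
#'
#' @description Settings of the end-to-end virtual-cohort experiment:
#' number of models per group, the burden and texture distributions of the
#' synthetic substrates, the reduced-scale tissue geometry, pacing-site
#' count, and the master seed from which all per-model seeds derive.
#'
#' @slot nModels models per cohort group.
#' @slot groups cohort group labels.
#' @slot burdenRange global fibrosis burden range swept across models.
#' @slot correlationLength,patchiness fibrosis texture parameters.
#' @slot sheetSize,resolution sheet edge length (mm) and resolution (um).
#' @slot nSites pacing sites per model.
#' @slot observe post-pacing observation horizon (ms).
#' @slot stimAmplitude tissue stimulus amplitude (pA/pF); NA = bisect the
#'   capture threshold per model.
#' @slot masterSeed integer master seed.
#' @export
setClass("CohortSpec",
         representation(nModels = "integer", groups = "character",
                        burdenRange = "numeric",
                        correlationLength = "numeric", patchiness = "numeric",
                        sheetSize = "numeric", resolution = "numeric",
                        nSites = "integer", observe = "numeric",
                        stimAmplitude = "numeric", masterSeed = "integer"))

#' Construct a virtual-cohort specification
#'
#' Defaults give the reduced-scale study conditions: 20 models sweeping
#' global fibrosis burden 5-25% (the cohort range the generator emulates),
#' patch-structured texture, and rectangular sheets sized so that one
#' induction stays within a desktop time budget.
#'
#' @param nModels models per group.
#' @param groups group labels.
#' @param burdenRange burden sweep range (fractions).
#' @param correlationLength texture correlation length (mm).
#' @param patchiness smooth-component weight.
#' @param sheetSize sheet edge length (mm).
#' @param resolution mesh resolution (um).
#' @param nSites pacing sites per model.
#' @param observe observation horizon (ms).
#' @param stimAmplitude stimulus amplitude (pA/pF).
#' @param masterSeed master seed.
#' @return a [CohortSpec-class].
#' @export
cohortSpec <- function(nModels = 20, groups = "synthetic",
                       burdenRange = c(0.05, 0.25),
                       correlationLength = 2, patchiness = 0.7,
                       sheetSize = 32, resolution = 400, nSites = 3,
                       observe = 5000, stimAmplitude = 100,
                       masterSeed = 1L) {
  new("CohortSpec", nModels = as.integer(nModels), groups = groups,
      burdenRange = burdenRange, correlationLength = correlationLength,
      patchiness = patchiness, sheetSize = sheetSize,
      resolution = resolution, nSites = as.integer(nSites),
      observe = observe, stimAmplitude = stimAmplitude,
      masterSeed = as.integer(masterSeed))
}

# deterministic pacing sites on a sheet: discs along the left and bottom
# edges plus the center, in a fixed order
.sheetPacingSites <- function(mesh, nSites, radius = 1) {
  co <- meshNodes(mesh)
  w <- max(co[, 1]); h <- max(co[, 2])
  anchors <- rbind(c(0.06 * w, 0.5 * h), c(0.5 * w, 0.06 * h),
                   c(0.94 * w, 0.5 * h), c(0.5 * w, 0.94 * h),
                   c(0.5 * w, 0.5 * h), c(0.06 * w, 0.06 * h),
                   c(0.94 * w, 0.94 * h), c(0.06 * w, 0.94 * h),
                   c(0.94 * w, 0.06 * h))
  anchors <- anchors[seq_len(min(nSites, nrow(anchors))), , drop = FALSE]
  sites <- lapply(seq_len(nrow(anchors)), function(k) {
    d2 <- (co[, 1] - anchors[k, 1])^2 + (co[, 2] - anchors[k, 2])^2
    nd <- which(d2 < radius^2)
    if (length(nd) == 0) nd <- which.min(d2)
    nd
  })
  names(sites) <- paste0("site", seq_along(sites))
  sites
}

#' Run the virtual-cohort experiment
#'
#' For each model: generate a synthetic fibrotic substrate (burden swept
#' uniformly over `burdenRange`, seed derived from the master seed), run
#' the rapid-pacing induction protocol at each pacing site, analyze
#' reentrant drivers, compute fibrosis metrics and the quiescent
#' resting-voltage run. Bit-reproducible from (spec, masterSeed).
#'
#' @param spec a [CohortSpec-class].
#' @param verbose print per-model progress.
#' @return list with `table` (one row per model: burden, inducible,
#'   inducingSites, uniqueMorphologies, proRDBurden, depolarizedFraction,
#'   ...), `records` (data.frame of all induction attempts), `summary`
#'   (the [DepolarizationSummary-class]), `spec`.
#' @export
runVirtualCohort <- function(spec = cohortSpec(), verbose = interactive()) {
  nTot <- spec@nModels * length(spec@groups)
  if (nTot == 0)
    return(list(table = data.frame(), records = data.frame(), spec = spec))
  rows <- list(); recs <- list(); vms <- list(); act <- logical(nTot)
  solver <- solverConfig(dt = 0.05)
  m <- 0
  for (g in spec@groups) for (k in seq_len(spec@nModels)) {
    m <- m + 1
    burden <- spec@burdenRange[1] +
      (k - 1) / max(1, spec@nModels - 1) * diff(spec@burdenRange)
    seed <- spec@masterSeed * 10000L + m
    sspec <- substrateSpec("sheet", c(spec@sheetSize, spec@sheetSize),
                           spec@resolution, burden,
                           spec@correlationLength, spec@patchiness,
                           seed = seed)
    mesh <- generateSubstrate(sspec)
    op <- assembleDiffusion(mesh, conductivityConfig(), solver@beta,
                            solver@Cm)
    sites <- .sheetPacingSites(mesh, spec@nSites)
    modelId <- sprintf("%s_%02d", g, k)
    events <- list()
    nInd <- 0
    for (sn in names(sites)) {
      rec <- runInduction(mesh, sites[[sn]], solver, conductivityConfig(),
                          amplitude = spec@stimAmplitude,
                          observe = spec@observe, model = modelId,
                          site = sn, op = op)
      recs[[length(recs) + 1]] <- data.frame(
        group = g, model = modelId, site = sn, outcome = rec@outcome,
        sustained = rec@sustainedDuration, valid = rec@valid,
        siteRegion = 1L)
      if (rec@outcome == "RD") {
        nInd <- nInd + 1
        events <- c(events, rec@rdEvents)
      }
      if (verbose)
        message(sprintf("  %s %s: %s (%.0f ms)", modelId, sn, rec@outcome,
                        rec@sustainedDuration))
    }
    q <- quiescentRun(mesh, solver = solver)
    vms[[m]] <- q$vm
    act[m] <- q$stillActive
    met <- localFibrosisMetrics(mesh, radius = 2.5)
    rows[[m]] <- data.frame(
      group = g, model = modelId, seed = seed,
      burden = 100 * mesh@meta$achievedBurden,
      inducible = nInd > 0, inducingSites = nInd,
      uniqueMorphologies = countUniqueMorphologies(events),
      proRDBurden = mean(met@proRD),
      invalid = any(vapply(recs[vapply(recs, function(r)
        r$model[1] == modelId, logical(1))], function(r) !r$valid[1],
        logical(1))))
    if (verbose)
      message(sprintf("model %s: burden %.1f%%, inducible sites %d",
                      modelId, 100 * mesh@meta$achievedBurden, nInd))
  }
  tab <- do.call(rbind, rows)
  recdf <- do.call(rbind, recs)
  dep <- quiescentVmAnalysis(vms, stillActive = act)
  keep <- setdiff(seq_len(nTot), dep@excluded)
  tab$depolarizedFraction <- NA_real_
  tab$depolarizedFraction[keep] <- dep@fractions
  # invalid models are excluded from statistics downstream
  list(table = tab, records = recdf, summary = dep, spec = spec)
}

#' Quartile grouping of fibrosis burdens
#'
#' @param burdens numeric vector (percent or fraction).
#' @return list with `labels` (1-4 per entry), `cutoffs` (the three
#'   quartile cut-offs), `degenerate` flag (ties make fewer than 4
#'   distinct groups).
#' @export
quartileGrouping <- function(burdens) {
  cuts <- quantile(burdens, c(0.25, 0.5, 0.75), type = 7)
  lab <- findInterval(burdens, cuts, left.open = TRUE) + 1L
  list(labels = lab, cutoffs = unname(cuts),
       degenerate = length(unique(cuts)) < 3 ||
         length(unique(lab)) < 4)
}

#' Group comparison statistics
#'
#' Continuous variables: Wilcoxon rank-sum with normal approximation and
#' the Hodges-Lehmann-style 95% confidence interval for the location
#' shift; exact p for small samples without ties. Categorical variables:
#' chi-squared test with the Yates continuity correction (the convention
#' of base R's `chisq.test` for 2 x 2 tables, which reproduces the
#' published inducibility comparison); set `correct = FALSE` to disable.
#'
#' @param x,y the two groups (continuous), or for `categorical = TRUE` a
#'   2 x 2 contingency table passed as `x` (`y` ignored).
#' @param categorical use the chi-squared test.
#' @param correct apply the continuity correction (categorical case).
#' @return list with `statistic`, `p`, and (continuous case) `ci`.
#' @export
compareGroups <- function(x, y = NULL, categorical = FALSE, correct = TRUE) {
  if (categorical) {
    ct <- suppressWarnings(chisq.test(x, correct = correct))
    return(list(statistic = unname(ct$statistic), p = ct$p.value))
  }
  wt <- suppressWarnings(wilcox.test(x, y, conf.int = TRUE,
                                     conf.level = 0.95))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       ci = unname(wt$conf.int))
}

#' Correlation of a count variable with fibrosis burden
#'
#' Reports the product-moment correlation (R, p) of the count with burden
#' and, alongside, a logistic-regression fit of the binarized outcome
#' (count > 0) on burden.
#'
#' @param burden fibrosis burden per model.
#' @param counts count variable per model (inducing sites, unique
#'   morphologies, ...).
#' @return list with `R`, `p`, `logisticSlope`, `logisticP`.
#' @export
correlateWithFibrosis <- function(burden, counts) {
  if (sd(counts) == 0 || sd(burden) == 0) {
    out <- list(R = NA_real_, p = NA_real_, logisticSlope = NA_real_,
                logisticP = NA_real_)
    return(out)
  }
  ct <- cor.test(burden, counts)
  out <- list(R = unname(ct$estimate), p = ct$p.value,
              logisticSlope = NA_real_, logisticP = NA_real_)
  yb <- as.integer(counts > 0)
  if (length(unique(yb)) == 2) {
    fit <- suppressWarnings(glm(yb ~ burden, family = binomial()))
    sm <- summary(fit)$coefficients
    out$logisticSlope <- sm["burden", "Estimate"]
    out$logisticP <- sm["burden", "Pr(>|z|)"]
  }
  out
}

#' Cohort-level statistics report
#'
#' Computes the statistical battery on a cohort table: burden quartiles
#' and per-quartile inducible fractions, the inducible-vs-non-inducible
#' burden comparison, and correlations of inducing-site and
#' unique-morphology counts with burden.
#'
#' @param table cohort table from [runVirtualCohort()].
#' @return list of statistics (see details in the returned names).
#' @export
cohortStats <- function(table) {
  tab <- table[!table$invalid, , drop = FALSE]
  qg <- quartileGrouping(tab$burden)
  indFrac <- vapply(1:4, function(q) {
    sel <- qg$labels == q
    if (!any(sel)) return(NA_real_)
    mean(tab$inducible[sel])
  }, numeric(1))
  cmp <- if (any(tab$inducible) && any(!tab$inducible))
    compareGroups(tab$burden[tab$inducible], tab$burden[!tab$inducible])
  else list(statistic = NA_real_, p = NA_real_, ci = c(NA_real_, NA_real_))
  list(quartiles = qg, inducibleFractionByQuartile = indFrac,
       burdenInducibleVsNot = cmp,
       meanBurdenInducible = mean(tab$burden[tab$inducible]),
       meanBurdenNonInducible = mean(tab$burden[!tab$inducible]),
       corSites = correlateWithFibrosis(tab$burden, tab$inducingSites),
       corMorphologies = correlateWithFibrosis(tab$burden,
                                               tab$uniqueMorphologies))
}
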