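#' @title Synthetic substrate specification
#'
#' @description
#' Parameters of the synthetic-substrate generator, which stands in for
#' patient LGE-MRI-derived atrial meshes. Two geometries are supported: a
#' flat `sheet` and an idealized left-atrium-like shell (`la_surrogate`,
#' an ellipsoid with four pulmonary-vein ostia, an open appendage tip and a
#' mitral rim). Fibrosis patterns are thresholded smoothed random fields
#' with controllable global burden and texture; the default burden
#' distribution mirrors the imaging cohorts this generator emulates
#' (mean 13-14%).
#'
#' @slot geometry `"sheet"` or `"la_surrogate"`.
#' @slot dimensions sheet: c(width, height) mm; surrogate: equatorial
#'   radius (mm).
#' @slot resolution target edge length (um).
#' @slot fibrosisBurden target global fibrosis burden, fraction in [0, 1].
#' @slot correlationLength fibrosis texture correlation length (mm).
#' @slot patchiness weight of the smoothed field component in [0, 1]
#'   (1 = pure smooth patches, 0 = salt-and-pepper).
#' @slot fiberAngle sheet fiber angle (degrees).
#' @slot seed integer random seed.
#' @export
setClass("SubstrateSpec",
         representation(geometry = "character", dimensions = "numeric",
                        resolution = "numeric", fibrosisBurden = "numeric",
                        correlationLength = "numeric", patchiness = "numeric",
                        fiberAngle = "numeric", seed = "integer"))

setValidity("SubstrateSpec", function(object) {
  if (!object@geometry %in% c("sheet", "la_surrogate"))
    return("geometry must be 'sheet' or 'la_surrogate'")
  if (object@fibrosisBurden < 0 || object@fibrosisBurden > 1)
    return("fibrosisBurden must lie in [0, 1]")
  if (object@resolution <= 0) return("resolution must be positive")
  if (object@patchiness < 0 || object@patchiness > 1)
    return("patchiness must lie in [0, 1]")
  TRUE
})

#' Construct a substrate specification
#' @param geometry `"sheet"` or `"la_surrogate"`.
#' @param dimensions sheet c(width, height) in mm, or surrogate radius (mm).
#' @param resolution target edge length (um).
#' @param fibrosisBurden target burden fraction.
#' @param correlationLength texture correlation length (mm).
#' @param patchiness smooth-component weight in [0, 1].
#' @param fiberAngle sheet fiber angle (degrees).
#' @param seed integer seed; all generator outputs are pure functions of
#'   (spec, seed).
#' @return a [SubstrateSpec-class].
#' @export
substrateSpec <- function(geometry = "sheet", dimensions = c(20, 20),
                          resolution = 400, fibrosisBurden = 0.14,
                          correlationLength = 1.5, patchiness = 0.85,
                          fiberAngle = 0, seed = 1L) {
  new("SubstrateSpec", geometry = geometry,
      dimensions = as.numeric(dimensions), resolution = resolution,
      fibrosisBurden = fibrosisBurden,
      correlationLength = correlationLength, patchiness = patchiness,
      fiberAngle = fiberAngle, seed = as.integer(seed))
}

# evaluate expr with a private RNG stream seeded by `seed`
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# ---- la_surrogate geometry -------------------------------------------------

# canonical ostium/landmark positions in (theta, phi) surrogate coordinates;
# theta: longitude (0 = anterior, pi = posterior), phi: latitude from
# equator (mitral rim at phi ~ -0.95, roof near +pi/2)
.laLandmarks <- function() {
  list(
    ostia = data.frame(
      name = c("LSPV", "LIPV", "RSPV", "RIPV"),
      theta = c(2.30, 2.75, 0.85, 0.40) + 0.75,
      phi = c(0.55, 0.05, 0.55, 0.05),
      rad = c(0.28, 0.28, 0.28, 0.28)),  # angular hole radius
    laa = list(theta = 5.45, phi = 0.45, rad = 0.22),
    mitralPhi = -0.85)
}

#' Idealized left-atrium-like shell mesh
#'
#' An ellipsoidal shell (semi-axes `radius` x 0.85 `radius` x 0.9 `radius`)
#' parameterized by longitude/latitude, with the mitral cap removed, four
#' pulmonary-vein ostia and the appendage tip cut open (6 boundary loops),
#' and an outward appendage bulge. Surrogate (theta, phi) coordinates are
#' stored in `meta` and serve as the anatomical coordinate frame for
#' region assignment and pacing-site placement.
#'
#' @param radius equatorial radius (mm).
#' @param resolution target edge length (um).
#' @return a single-layer [BilayerMesh-class] with surrogate coordinates in
#'   `meta`.
#' @export
makeLASurrogateMesh <- function(radius = 30, resolution = 400) {
  lm <- .laLandmarks()
  h <- resolution / 1000
  a <- radius; b <- 0.85 * radius; cax <- 0.9 * radius
  phiTop <- pi / 2
  phi0 <- lm$mitralPhi
  nphi <- max(8L, ceiling((phiTop - phi0) * cax / h))
  nth <- max(12L, ceiling(2 * pi * a / h))
  phis <- seq(phi0, phiTop, length.out = nphi + 1)
  phis <- phis[-length(phis)]             # pole handled by a fan
  ths <- seq(0, 2 * pi, length.out = nth + 1)[-(nth + 1)]
  # grid nodes
  thetaG <- rep(ths, times = length(phis))
  phiG <- rep(phis, each = nth)
  # LAA bulge: radial scale-up with Gaussian falloff around the LAA center
  dl <- .angDist(thetaG, phiG, lm$laa$theta, lm$laa$phi)
  bulge <- 1 + 0.35 * exp(-(dl / (2.2 * lm$laa$rad))^2)
  x <- a * cos(phiG) * cos(thetaG) * bulge
  y <- b * cos(phiG) * sin(thetaG) * bulge
  z <- cax * sin(phiG) * bulge
  nodes <- cbind(x, y, z)
  npole <- nrow(nodes) + 1L
  nodes <- rbind(nodes, c(0, 0, cax))
  idx <- function(i, j) (j - 1L) * nth + ((i - 1L) %% nth) + 1L
  i <- rep(seq_len(nth), times = length(phis) - 1)
  j <- rep(seq_len(length(phis) - 1), each = nth)
  t1 <- cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L))
  t2 <- cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
  jt <- length(phis)
  fan <- cbind(idx(seq_len(nth), jt), idx(seq_len(nth) + 1L, jt), npole)
  elements <- rbind(t1, t2, fan)
  # element surrogate coordinates (mean of vertex coordinates; theta is
  # circular, use atan2 of mean unit vectors)
  thn <- c(thetaG, 0); phn <- c(phiG, pi / 2)
  ct <- cos(thn); st <- sin(thn)
  eTheta <- atan2(st[elements[, 1]] + st[elements[, 2]] + st[elements[, 3]],
                  ct[elements[, 1]] + ct[elements[, 2]] + ct[elements[, 3]])
  eTheta <- (eTheta + 2 * pi) %% (2 * pi)
  ePhi <- (phn[elements[, 1]] + phn[elements[, 2]] + phn[elements[, 3]]) / 3
  # cut PV ostia and LAA tip
  cut <- rep(FALSE, nrow(elements))
  holes <- rbind(
    data.frame(name = lm$ostia$name, theta = lm$ostia$theta,
               phi = lm$ostia$phi, rad = lm$ostia$rad),
    data.frame(name = "LAA_tip", theta = lm$laa$theta, phi = lm$laa$phi,
               rad = 0.45 * lm$laa$rad))
  for (k in seq_len(nrow(holes)))
    cut <- cut | .angDist(eTheta, ePhi, holes$theta[k], holes$phi[k]) <
      holes$rad[k]
  elements <- elements[!cut, , drop = FALSE]
  eTheta <- eTheta[!cut]; ePhi <- ePhi[!cut]
  # drop orphan nodes
  used <- sort(unique(as.vector(elements)))
  remap <- integer(nrow(nodes)); remap[used] <- seq_along(used)
  nodes <- nodes[used, , drop = FALSE]
  elements <- matrix(remap[elements], ncol = 3)
  thn <- thn[used]; phn <- phn[used]
  mesh <- bilayerMesh(nodes, elements,
                      meta = list(geometry = "la_surrogate", radius = radius,
                                  resolution = resolution,
                                  nodeTheta = thn, nodePhi = phn,
                                  elemTheta = eTheta, elemPhi = ePhi,
                                  holes = holes, landmarks = lm))
  fibrosisLabels(mesh) <- rep(FALSE, nrow(elements))
  mesh@fibers <- generateFibers(mesh)
  validObject(mesh)
  mesh
}

# great-circle-style angular distance in the (theta, phi) chart, with
# longitude wrap and latitude-weighted longitude spacing
.angDist <- function(th, ph, th0, ph0) {
  dth <- abs(th - th0)
  dth <- pmin(dth, 2 * pi - dth) * cos((ph + ph0) / 2)
  sqrt(dth^2 + (ph - ph0)^2)
}

#' Generate a substrate geometry from a specification
#'
#' Dispatches on `spec@geometry`: flat sheets via [makeSheetMesh()], the
#' left-atrium surrogate via [makeLASurrogateMesh()]. Output is
#' deterministic given the spec.
#'
#' @param spec a [SubstrateSpec-class].
#' @param bilayer duplicate into nested shells via [buildBilayer()].
#' @param offset bilayer interlayer distance (um).
#' @return a [BilayerMesh-class].
#' @export
generateGeometry <- function(spec, bilayer = FALSE, offset = 100) {
  mesh <- switch(spec@geometry,
    sheet = makeSheetMesh(spec@dimensions[1],
                          spec@dimensions[min(2, length(spec@dimensions))],
                          spec@resolution, spec@fiberAngle),
    la_surrogate = makeLASurrogateMesh(spec@dimensions[1], spec@resolution))
  minFeature <- if (spec@geometry == "la_surrogate")
    0.28 * 0.45 * spec@dimensions[1] else min(spec@dimensions)
  if (spec@resolution / 1000 > minFeature / 2)
    stop("resolution ", spec@resolution,
         " um is incompatible with the smallest geometric feature (",
         signif(minFeature, 3), " mm)")
  mesh@meta$spec <- spec
  if (bilayer) mesh <- buildBilayer(mesh, offset)
  mesh
}

# neighbor-averaging smoother on the element adjacency graph
.smoothField <- function(mesh, x, corrLen) {
  adj <- .elementAdjacency(mesh)
  h <- sqrt(mean(elementAreas(mesh)) * 2)   # ~ edge length
  nstep <- max(1L, round(2 * (corrLen / h)^2))
  nstep <- min(nstep, 4000L)
  A <- adj$A
  deg <- pmax(Matrix::rowSums(A), 1)
  for (k in seq_len(nstep)) x <- 0.5 * x + 0.5 * as.numeric(A %*% x) / deg
  x
}

# shared-edge element adjacency (sparse boolean matrix + edge pair list)
.elementAdjacency <- function(mesh) {
  key <- .edgeKeys(mesh)
  E <- nrow(mesh@elements)
  eid <- rep(seq_len(E), 3)
  o <- order(key)
  key <- key[o]; eid <- eid[o]
  same <- which(key[-1] == key[-length(key)])
  a <- eid[same]; b <- eid[same + 1]
  A <- Matrix::sparseMatrix(i = c(a, b), j = c(b, a), x = 1, dims = c(E, E))
  list(A = A, pairs = cbind(a, b))
}

.edgeKeys <- function(mesh) {
  el <- mesh@elements
  e <- rbind(el[, 1:2], el[, 2:3], el[, c(3, 1)])
  pmin(e[, 1], e[, 2]) * (max(el) + 1) + pmax(e[, 1], e[, 2])
}

#' Generate a binary fibrosis pattern
#'
#' Samples white noise per element, smooths it on the element adjacency
#' graph to the requested correlation length, mixes in a fine-grained
#' component (`1 - patchiness`), and thresholds at the area-weighted
#' quantile that yields the target burden. For bilayer meshes the pattern
#' is generated on the endocardial layer and copied to the epicardial
#' layer, so both shells share labels.
#'
#' @param mesh a [BilayerMesh-class].
#' @param spec a [SubstrateSpec-class] (burden, texture, seed).
#' @return logical per-element vector (also set on the returned mesh by
#'   [generateSubstrate()]).
#' @export
generateFibrosis <- function(mesh, spec) {
  E <- nrow(mesh@elements)
  if (E < 1) stop("target burden unreachable: mesh has no elements")
  target <- spec@fibrosisBurden
  if (target <= 0) return(rep(FALSE, E))
  if (target >= 1) return(rep(TRUE, E))
  twoLayer <- any(mesh@layer == 2L)
  if (twoLayer) {
    endoEl <- which(apply(mesh@elements, 1,
                          function(e) all(mesh@layer[e] == 1L)))
    sub <- .singleLayer(mesh)
    lab1 <- generateFibrosis(sub, spec)
    lab <- rep(FALSE, E)
    lab[endoEl] <- lab1
    lab[-endoEl] <- lab1  # epicardial elements mirror endocardial order
    return(lab)
  }
  x <- .withSeed(spec@seed, {
    z <- rnorm(E)
    s <- .smoothField(mesh, z, spec@correlationLength)
    s <- (s - mean(s)) / max(sd(s), 1e-12)
    zf <- rnorm(E)
    spec@patchiness * s + (1 - spec@patchiness) * zf
  })
  ar <- elementAreas(mesh)
  o <- order(x, decreasing = TRUE)
  cum <- cumsum(ar[o]) / sum(ar)
  ncut <- which(cum >= target)[1]
  lab <- rep(FALSE, E)
  lab[o[seq_len(ncut)]] <- TRUE
  lab
}

# endocardial sub-mesh of a bilayer (element order preserved)
.singleLayer <- function(mesh) {
  keep <- which(mesh@layer == 1L)
  el <- mesh@elements
  endoEl <- which(apply(el, 1, function(e) all(mesh@layer[e] == 1L)))
  remap <- integer(nrow(mesh@nodes)); remap[keep] <- seq_along(keep)
  bilayerMesh(mesh@nodes[keep, , drop = FALSE],
              matrix(remap[el[endoEl, ]], ncol = 3),
              fibers = mesh@fibers[endoEl, , drop = FALSE],
              fibrotic = mesh@fibrotic[endoEl],
              region = mesh@region[endoEl], meta = mesh@meta)
}

#' @title Anatomical region partition
#' @description Per-element region ids and per-region surface areas for the
#'   five-region left-atrium layout: 1 = floor, 2 = posterior wall,
#'   3 = anterior wall + appendage, 4 = left PVs, 5 = right PVs.
#' @slot region integer per-element region id.
#' @slot areas named numeric per-region surface area (cm^2).
#' @slot names region display names.
#' @export
setClass("RegionPartition",
         representation(region = "integer", areas = "numeric",
                        names = "character"))

#' @describeIn RegionPartition-class display method
#' @param object a `RegionPartition`
#' @export
setMethod("show", "RegionPartition", function(object) {
  cat("RegionPartition:\n")
  tot <- sum(object@areas)
  for (k in seq_along(object@areas))
    cat(sprintf("  %d %-22s %6.2f cm^2 (%4.1f%%)\n", k, object@names[k],
                object@areas[k], 100 * object@areas[k] / tot))
})

.regionNames <- c("floor", "posterior", "anterior+LAA", "LPV", "RPV")

#' Assign anatomical regions
#'
#' Sheets map to a single region. For the LA surrogate, the left and right
#' PV regions are grown from the ostium rims, accreting adjacent elements
#' by increasing distance until each holds 15% of the total surface area;
#' the remaining surface is split into floor, posterior and anterior+LAA
#' by surrogate-coordinate cutoffs.
#'
#' @param mesh a [BilayerMesh-class] (surrogate geometries need the
#'   surrogate coordinates in `meta`).
#' @param pvAreaFraction target area fraction per PV region.
#' @return a [RegionPartition-class]; use [`regionIds<-`] to attach it.
#' @export
assignRegions <- function(mesh, pvAreaFraction = 0.15) {
  ar <- elementAreas(mesh)
  E <- nrow(mesh@elements)
  geom <- mesh@meta$geometry %||% "sheet"
  if (geom != "la_surrogate") {
    reg <- rep(1L, E)
    return(new("RegionPartition", region = reg,
               areas = c(sheet = sum(ar) / 100), names = "sheet"))
  }
  if (is.null(mesh@meta$elemTheta)) stop("missing surrogate coordinates")
  if (is.null(mesh@meta$holes)) stop("missing ostia labels")
  th <- mesh@meta$elemTheta; ph <- mesh@meta$elemPhi
  holes <- mesh@meta$holes
  twoLayer <- any(mesh@layer == 2L)
  if (twoLayer) stop("assign regions on the single-layer mesh, then build ",
                     "the bilayer (labels are copied)")
  # distance of each element to nearest left / right ostium center
  dl <- rep(Inf, E); dr <- rep(Inf, E)
  for (k in seq_len(nrow(holes))) {
    if (holes$name[k] %in% c("LSPV", "LIPV"))
      dl <- pmin(dl, .angDist(th, ph, holes$theta[k], holes$phi[k]))
    if (holes$name[k] %in% c("RSPV", "RIPV"))
      dr <- pmin(dr, .angDist(th, ph, holes$theta[k], holes$phi[k]))
  }
  tot <- sum(ar)
  reg <- rep(0L, E)
  # grow each PV region to the target area by angular distance rank
  grow <- function(d, excl) {
    o <- order(d)
    o <- o[!(o %in% excl)]
    cum <- cumsum(ar[o]) / tot
    o[seq_len(which(cum >= pvAreaFraction)[1])]
  }
  lpv <- grow(dl, integer(0))
  rpv <- grow(dr, lpv)
  reg[lpv] <- 4L; reg[rpv] <- 5L
  rest <- which(reg == 0L)
  lm <- mesh@meta$landmarks
  floorSel <- rest[ph[rest] < lm$mitralPhi + 0.45]
  reg[floorSel] <- 1L
  rest <- which(reg == 0L)
  # posterior: longitudes around the PV side (theta in [pi/2, 3pi/2) of the
  # shifted frame); anterior+LAA: the remainder
  post <- rest[th[rest] > 1.05 & th[rest] < 4.0]
  reg[post] <- 2L
  reg[reg == 0L] <- 3L
  areas <- vapply(1:5, function(k) sum(ar[reg == k]), numeric(1)) / 100
  names(areas) <- .regionNames
  new("RegionPartition", region = reg, areas = areas, names = .regionNames)
}

#' Place the 15 pacing sites
#'
#' Sites follow clinically reported AFib trigger locations: the anterior
#' and posterior aspects of each of the four PV ostia (8), the appendage
#' base, the mitral annulus, the posterior wall, and four additional
#' distributed anterior/posterior wall sites, for 15 total. Each site is
#' the set of nodes within `radius` mm of its canonical surrogate
#' coordinate. The left-PV region contains exactly four sites
#' (anterior/posterior LSPV and LIPV).
#'
#' @param mesh a single-layer LA-surrogate [BilayerMesh-class] with regions
#'   assigned (see [assignRegions()]).
#' @param partition a [RegionPartition-class] for the mesh.
#' @param radius site radius (mm).
#' @return named list of integer node-index vectors, with a `data.frame`
#'   attribute `siteInfo` (name, region id).
#' @export
placePacingSites <- function(mesh, partition, radius = 1) {
  if (is.null(mesh@meta$nodeTheta)) stop("missing surrogate coordinates")
  if (missing(partition) || is.null(partition))
    stop("region partition absent: run assignRegions() first")
  lm <- mesh@meta$landmarks
  os <- lm$ostia
  defs <- NULL
  for (k in seq_len(nrow(os))) {
    # anterior/posterior aspects: offset in longitude on both sides of the
    # ostium, just outside the rim
    defs <- rbind(defs,
      data.frame(name = paste0(os$name[k], "_ant"),
                 theta = os$theta[k] - (os$rad[k] + 0.12),
                 phi = os$phi[k]),
      data.frame(name = paste0(os$name[k], "_post"),
                 theta = os$theta[k] + (os$rad[k] + 0.12),
                 phi = os$phi[k]))
  }
  defs <- rbind(defs,
    data.frame(name = "LAA_base",
               theta = lm$laa$theta - lm$laa$rad - 0.35, phi = lm$laa$phi),
    data.frame(name = "mitral_annulus", theta = 5.8,
               phi = lm$mitralPhi + 0.25),
    data.frame(name = "posterior_wall", theta = 2.0, phi = -0.35),
    data.frame(name = "posterior_wall_2", theta = 2.9, phi = -0.4),
    data.frame(name = "anterior_wall", theta = 0.1, phi = 0.05),
    data.frame(name = "anterior_wall_2", theta = 5.15, phi = -0.1),
    data.frame(name = "floor", theta = 4.7, phi = lm$mitralPhi + 0.3))
  defs$theta <- defs$theta %% (2 * pi)
  thn <- mesh@meta$nodeTheta; phn <- mesh@meta$nodePhi
  # convert the angular site radius to the chart metric via mesh radius
  R <- mesh@meta$radius %||% 30
  angRad <- radius / (0.9 * R)
  sites <- list()
  info <- NULL
  elTheta <- mesh@meta$elemTheta; elPhi <- mesh@meta$elemPhi
  # region of each node = region of the nearest element in the chart
  nodeRegion <- integer(length(thn))
  for (k in seq_len(nrow(defs))) {
    d <- .angDist(thn, phn, defs$theta[k], defs$phi[k])
    de <- .angDist(elTheta, elPhi, defs$theta[k], defs$phi[k])
    siteRegion <- partition@region[which.min(de)]
    nd <- which(d < angRad)
    if (length(nd) == 0) nd <- which.min(d)
    # keep the site inside one region only
    ndKeep <- nd[vapply(nd, function(n) {
      je <- which.min(.angDist(elTheta, elPhi, thn[n], phn[n]))
      partition@region[je] == siteRegion
    }, logical(1))]
    if (length(ndKeep) > 0) nd <- ndKeep
    sites[[defs$name[k]]] <- nd
    info <- rbind(info, data.frame(name = defs$name[k], region = siteRegion))
  }
  # enforce disjointness (a node belongs to its nearest site)
  all_nodes <- unlist(sites)
  if (anyDuplicated(all_nodes)) {
    for (n in unique(all_nodes[duplicated(all_nodes)])) {
      owners <- names(sites)[vapply(sites, function(s) n %in% s, logical(1))]
      dists <- vapply(owners, function(o) {
        k <- which(defs$name == o)
        .angDist(thn[n], phn[n], defs$theta[k], defs$phi[k])
      }, numeric(1))
      for (o in owners[-which.min(dists)])
        sites[[o]] <- setdiff(sites[[o]], n)
    }
  }
  attr(sites, "siteInfo") <- info
  sites
}

#' Generate a rule-based fiber field
#'
#' Sheets: a uniform in-plane direction (`spec` fiber angle, or the angles
#' given). Surrogate shells: circumferential orientation around each PV
#' ostium and the mitral rim, blending into an oblique wall direction, with
#' Gaussian falloff of each landmark's influence; all vectors are projected
#' into their element plane and normalized.
#'
#' @param mesh a [BilayerMesh-class].
#' @param endoAngle,epiAngle sheet fiber angles (degrees) for the
#'   endocardial and epicardial layers (bilayer sheets only).
#' @return E x 3 matrix of unit fiber vectors.
#' @export
generateFibers <- function(mesh, endoAngle = 0, epiAngle = endoAngle) {
  el <- mesh@elements
  E <- nrow(el)
  geom <- mesh@meta$geometry %||% "sheet"
  if (geom != "la_surrogate") {
    epi <- apply(el, 1, function(e) any(mesh@layer[e] == 2L))
    ang <- ifelse(epi, epiAngle, endoAngle) * pi / 180
    return(cbind(cos(ang), sin(ang), 0))
  }
  cen <- elementCentroids(mesh)
  p <- mesh@nodes
  a <- p[el[, 2], ] - p[el[, 1], ]; b <- p[el[, 3], ] - p[el[, 1], ]
  nrm <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
  nrm <- nrm / sqrt(rowSums(nrm^2))
  # oblique wall direction: 30 degrees off the longitude circles
  zax <- matrix(rep(c(0, 0, 1), each = E), ncol = 3)
  lon <- .cross3(zax, cen)                      # direction of increasing theta
  lon <- .projUnit(lon, nrm)
  lat <- .cross3(nrm, lon)                      # increasing latitude
  dirW <- .unit(cos(pi / 6) * lon + sin(pi / 6) * lat)
  th <- mesh@meta$elemTheta; ph <- mesh@meta$elemPhi
  lmk <- mesh@meta$landmarks
  circles <- rbind(
    data.frame(theta = lmk$ostia$theta, phi = lmk$ostia$phi,
               rad = lmk$ostia$rad),
    data.frame(theta = lmk$laa$theta, phi = lmk$laa$phi, rad = lmk$laa$rad))
  dirAll <- dirW
  wTot <- rep(0, E)
  for (k in seq_len(nrow(circles))) {
    d <- .angDist(th, ph, circles$theta[k], circles$phi[k])
    w <- exp(-(d / (1.8 * circles$rad[k]))^2)
    cxyz <- .chartPoint(mesh, circles$theta[k], circles$phi[k])
    rvec <- cen - matrix(cxyz, E, 3, byrow = TRUE)
    circ <- .projUnit(.cross3(nrm, rvec), nrm)
    # blend with sign alignment to avoid cancellation
    s <- sign(rowSums(circ * dirAll)); s[s == 0] <- 1
    dirAll <- .unit((1 - w) * dirAll + w * s * circ)
    wTot <- wTot + w
  }
  # mitral rim: circumferential (longitude) near the rim
  wm <- exp(-((ph - lmk$mitralPhi) / 0.25)^2)
  s <- sign(rowSums(lon * dirAll)); s[s == 0] <- 1
  dirAll <- .unit((1 - wm) * dirAll + wm * s * lon)
  .projUnit(dirAll, nrm)
}

.cross3 <- function(u, v)
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])

.unit <- function(v) v / pmax(sqrt(rowSums(v^2)), 1e-12)

.projUnit <- function(v, n) {
  v <- v - n * rowSums(v * n)
  .unit(v)
}

# 3D point of the surrogate chart (without bulge; adequate for directions)
.chartPoint <- function(mesh, theta, phi) {
  R <- mesh@meta$radius %||% 30
  c(R * cos(phi) * cos(theta), 0.85 * R * cos(phi) * sin(theta),
    0.9 * R * sin(phi))
}

#' Generate a complete synthetic substrate
#'
#' Convenience wrapper: geometry, fibrosis pattern, fibers, regions, and
#' (for surrogate geometries) pacing sites, all deterministic in
#' (spec, seed).
#'
#' @param spec a [SubstrateSpec-class].
#' @param bilayer build nested shells.
#' @return a [BilayerMesh-class] with labels set; pacing sites (if any) in
#'   `meta$pacingSites`, the partition in `meta$partition`, achieved burden
#'   in `meta$achievedBurden`.
#' @export
generateSubstrate <- function(spec, bilayer = FALSE) {
  mesh <- generateGeometry(spec, bilayer = FALSE)
  part <- assignRegions(mesh)
  regionIds(mesh) <- part@region
  if (spec@geometry == "la_surrogate") {
    mesh@fibers <- generateFibers(mesh)
    mesh@meta$pacingSites <- placePacingSites(mesh, part)
  }
  fibrosisLabels(mesh) <- generateFibrosis(mesh, spec)
  mesh@meta$partition <- part
  mesh@meta$achievedBurden <- fibrosisBurden(mesh)
  if (bilayer) mesh <- buildBilayer(mesh, 100)
  mesh
}
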