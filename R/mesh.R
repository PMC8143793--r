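#' @title Bilayer triangulated tissue mesh
#'
#' @description
#' `BilayerMesh` holds a triangulated atrial surface (one or two nested
#' layers), per-element fiber vectors, binary fibrosis labels, anatomical
#' region ids, and the 1D interlayer links that couple nested endocardial
#' and epicardial shells. Coordinates are in mm.
#'
#' @slot nodes numeric matrix (N x 3), node coordinates in mm.
#' @slot elements integer matrix (E x 3), 1-based triangle connectivity.
#' @slot fibers numeric matrix (E x 3), unit fiber vector per element.
#' @slot fibrotic logical vector (E), fibrosis label per element.
#' @slot region integer vector (E), anatomical region id (0 = unassigned).
#' @slot layer integer vector (N), 1 = endocardial, 2 = epicardial.
#' @slot links integer matrix (L x 2), interlayer node pairs (endo, epi).
#' @slot meta list of provenance (resolution, seed, generator spec, ...).
#' @export
setClass("BilayerMesh",
         representation(nodes = "matrix", elements = "matrix",
                        fibers = "matrix", fibrotic = "logical",
                        region = "integer", layer = "integer",
                        links = "matrix", meta = "list"))

setValidity("BilayerMesh", function(object) {
  N <- nrow(object@nodes); E <- nrow(object@elements)
  if (ncol(object@nodes) != 3) return("nodes must be N x 3")
  if (E > 0 && (min(object@elements) < 1 || max(object@elements) > N))
    return("element connectivity out of node range")
  if (nrow(object@fibers) != E) return("one fiber vector per element required")
  nrm <- sqrt(rowSums(object@fibers^2))
  if (E > 0 && any(abs(nrm - 1) > 1e-6))
    return("fiber vectors must have unit norm")
  if (length(object@fibrotic) != E) return("one fibrosis label per element")
  if (length(object@region) != E) return("one region id per element")
  if (length(object@layer) != N) return("one layer tag per node")
  if (nrow(object@links) > 0 &&
      (min(object@links) < 1 || max(object@links) > N))
    return("link node indices out of range")
  TRUE
})

#' @describeIn BilayerMesh-class display method
#' @param object a `BilayerMesh`
#' @export
setMethod("show", "BilayerMesh", function(object) {
  cat(sprintf("BilayerMesh: %d nodes, %d triangles, %d interlayer links\n",
              nrow(object@nodes), nrow(object@elements), nrow(object@links)))
  cat(sprintf("  layers: %s; fibrotic burden: %.1f%% of surface area\n",
              paste(sort(unique(object@layer)), collapse = "/"),
              100 * fibrosisBurden(object)))
  if (any(object@region > 0))
    cat("  regions:", paste(sort(unique(object@region[object@region > 0])),
                            collapse = ", "), "\n")
})

#' Construct a BilayerMesh
#' @param nodes N x 3 coordinates (mm).
#' @param elements E x 3 triangle connectivity (1-based).
#' @param fibers E x 3 unit fiber vectors; default along +x.
#' @param fibrotic logical per-element fibrosis labels; default all healthy.
#' @param region integer per-element region ids; default 0.
#' @param layer integer per-node layer tags; default all 1 (single layer).
#' @param links L x 2 interlayer node pairs; default none.
#' @param meta provenance list.
#' @return a [BilayerMesh-class].
#' @export
bilayerMesh <- function(nodes, elements, fibers = NULL, fibrotic = NULL,
                        region = NULL, layer = NULL, links = NULL,
                        meta = list()) {
  nodes <- as.matrix(nodes); storage.mode(nodes) <- "double"
  elements <- as.matrix(elements); storage.mode(elements) <- "integer"
  E <- nrow(elements); N <- nrow(nodes)
  if (is.null(fibers))
    fibers <- matrix(rep(c(1, 0, 0), each = E), ncol = 3)
  fibers <- as.matrix(fibers); storage.mode(fibers) <- "double"
  if (is.null(fibrotic)) fibrotic <- rep(FALSE, E)
  if (is.null(region)) region <- rep(0L, E)
  if (is.null(layer)) layer <- rep(1L, N)
  if (is.null(links)) links <- matrix(integer(0), ncol = 2)
  links <- as.matrix(links); storage.mode(links) <- "integer"
  new("BilayerMesh", nodes = nodes, elements = elements, fibers = fibers,
      fibrotic = as.logical(fibrotic), region = as.integer(region),
      layer = as.integer(layer), links = links, meta = meta)
}

#' @name mesh-accessors
#' @title Accessors for BilayerMesh components
#' @param mesh a [BilayerMesh-class].
#' @return the requested component.
NULL

#' @rdname mesh-accessors
#' @export
meshNodes <- function(mesh) mesh@nodes

#' @rdname mesh-accessors
#' @export
meshElements <- function(mesh) mesh@elements

#' @rdname mesh-accessors
#' @export
meshFibers <- function(mesh) mesh@fibers

#' @rdname mesh-accessors
#' @export
fibrosisLabels <- function(mesh) mesh@fibrotic

#' @rdname mesh-accessors
#' @export
regionIds <- function(mesh) mesh@region

#' @rdname mesh-accessors
#' @export
meshLinks <- function(mesh) mesh@links

#' @rdname mesh-accessors
#' @export
meshLayers <- function(mesh) mesh@layer

#' Replace the fibrosis labels of a mesh
#' @param mesh a [BilayerMesh-class].
#' @param value logical per-element vector.
#' @return the updated mesh.
#' @export
`fibrosisLabels<-` <- function(mesh, value) {
  mesh@fibrotic <- as.logical(value)
  validObject(mesh)
  mesh
}

#' Replace the region ids of a mesh
#' @param mesh a [BilayerMesh-class].
#' @param value integer per-element vector.
#' @return the updated mesh.
#' @export
`regionIds<-` <- function(mesh, value) {
  mesh@region <- as.integer(value)
  validObject(mesh)
  mesh
}

#' Triangle areas of a mesh
#' @param mesh a [BilayerMesh-class].
#' @return numeric vector of areas (mm^2).
#' @export
elementAreas <- function(mesh) {
  p <- mesh@nodes; el <- mesh@elements
  a <- p[el[, 2], , drop = FALSE] - p[el[, 1], , drop = FALSE]
  b <- p[el[, 3], , drop = FALSE] - p[el[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Triangle centroids of a mesh
#' @param mesh a [BilayerMesh-class].
#' @return E x 3 matrix of centroids (mm).
#' @export
elementCentroids <- function(mesh) {
  p <- mesh@nodes; el <- mesh@elements
  (p[el[, 1], , drop = FALSE] + p[el[, 2], , drop = FALSE] +
     p[el[, 3], , drop = FALSE]) / 3
}

#' Area-weighted global fibrosis burden of a mesh
#' @param mesh a [BilayerMesh-class].
#' @return fraction of surface area labeled fibrotic.
#' @export
fibrosisBurden <- function(mesh) {
  ar <- elementAreas(mesh)
  sum(ar[mesh@fibrotic]) / sum(ar)
}

# directed edge list (E*3 x 2) of a triangle mesh
.meshEdges <- function(mesh) {
  el <- mesh@elements
  rbind(el[, c(1, 2), drop = FALSE], el[, c(2, 3), drop = FALSE],
        el[, c(3, 1), drop = FALSE])
}

#' Boundary loops of a triangulated surface
#'
#' Boundary edges are edges used by exactly one triangle; they are chained
#' into closed loops. Used for topology checks (pulmonary-vein ostia,
#' mitral rim) and for macroscopic-reentry classification.
#'
#' @param mesh a [BilayerMesh-class]; for bilayer meshes only the
#'   endocardial layer is traversed.
#' @return list of integer vectors, each an ordered cycle of node indices.
#' @export
boundaryLoops <- function(mesh) {
  keep <- if (any(mesh@layer == 2)) {
    apply(mesh@elements, 1, function(e) all(mesh@layer[e] == 1L))
  } else rep(TRUE, nrow(mesh@elements))
  el <- mesh@elements[keep, , drop = FALSE]
  ed <- rbind(el[, 1:2], el[, 2:3], el[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  cnt <- table(key)
  bkey <- names(cnt)[cnt == 1]
  bed <- ed[key %in% bkey, , drop = FALSE]
  if (nrow(bed) == 0) return(list())
  nxt <- split(bed[, 2], bed[, 1])
  used <- rep(FALSE, nrow(bed))
  loops <- list()
  visited <- new.env(parent = emptyenv())
  remaining <- unique(bed[, 1])
  inloop <- logical(max(mesh@elements))
  for (start in remaining) {
    if (inloop[start]) next
    loop <- integer(0)
    cur <- start
    repeat {
      loop <- c(loop, cur)
      inloop[cur] <- TRUE
      nn <- nxt[[as.character(cur)]]
      nn <- nn[!inloop[nn]]
      if (length(nn) == 0) break
      cur <- nn[1]
    }
    if (length(loop) >= 3) loops[[length(loops) + 1]] <- loop
  }
  loops
}

#' Regular triangulated sheet mesh
#'
#' Builds a flat rectangular sheet in the z = 0 plane, triangulated from a
#' structured grid, with a uniform in-plane fiber direction.
#'
#' @param width,height sheet dimensions (mm).
#' @param resolution target edge length (um).
#' @param fiberAngle in-plane fiber angle in degrees (0 = +x).
#' @return a single-layer [BilayerMesh-class].
#' @export
makeSheetMesh <- function(width, height, resolution = 200, fiberAngle = 0) {
  h <- resolution / 1000  # mm
  nx <- max(2L, round(width / h) + 1L)
  ny <- max(2L, round(height / h) + 1L)
  xs <- seq(0, width, length.out = nx)
  ys <- seq(0, height, length.out = ny)
  nodes <- cbind(rep(xs, times = ny), rep(ys, each = nx), 0)
  idx <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1L), times = ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  # split each quad along the same diagonal
  t1 <- cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L))
  t2 <- cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
  elements <- rbind(t1, t2)
  ang <- fiberAngle * pi / 180
  E <- nrow(elements)
  fibers <- cbind(rep(cos(ang), E), rep(sin(ang), E), 0)
  bilayerMesh(nodes, elements, fibers = fibers,
              meta = list(geometry = "sheet", width = width, height = height,
                          resolution = resolution, nx = nx, ny = ny,
                          fiberAngle = fiberAngle))
}

#' Duplicate a surface into a bilayer by normal offset
#'
#' Endocardial nodes are duplicated and moved outward by `offset` along the
#' per-node surface normal (area-weighted average of incident triangle
#' normals) to form the epicardial shell; connectivity is mirrored and one
#' interlayer link is created per node pair. Fibrosis/region labels and
#' fibers are copied to the epicardial layer.
#'
#' @param mesh single-layer [BilayerMesh-class]; must be manifold (no edge
#'   shared by more than two triangles).
#' @param offset interlayer distance (um).
#' @return a two-layer [BilayerMesh-class].
#' @export
buildBilayer <- function(mesh, offset = 100) {
  if (any(mesh@layer == 2L)) stop("mesh is already a bilayer")
  el <- mesh@elements
  key <- paste(pmin(el[, c(1, 2, 3)], el[, c(2, 3, 1)]),
               pmax(el[, c(1, 2, 3)], el[, c(2, 3, 1)]))
  cnt <- table(key)
  if (any(cnt > 2))
    stop("non-manifold surface: an edge is shared by more than two triangles")
  p <- mesh@nodes
  a <- p[el[, 2], , drop = FALSE] - p[el[, 1], , drop = FALSE]
  b <- p[el[, 3], , drop = FALSE] - p[el[, 1], , drop = FALSE]
  fn <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])  # 2*area-weighted normals
  N <- nrow(p)
  # accumulate element normals onto vertices
  nn <- matrix(0, N, 3)
  for (k in 1:3) {
    for (d in 1:3) {
      acc <- rowsum(fn[, d], group = el[, k])
      nn[as.integer(rownames(acc)), d] <- nn[as.integer(rownames(acc)), d] + acc
    }
  }
  len <- sqrt(rowSums(nn^2))
  if (any(len == 0)) stop("isolated node with undefined normal")
  nn <- nn / len
  off <- offset / 1000  # mm
  epiNodes <- p + off * nn
  nodes2 <- rbind(p, epiNodes)
  epiEl <- el + N
  elements2 <- rbind(el, epiEl)
  fibers2 <- rbind(mesh@fibers, mesh@fibers)
  fibrotic2 <- c(mesh@fibrotic, mesh@fibrotic)
  region2 <- c(mesh@region, mesh@region)
  layer2 <- c(rep(1L, N), rep(2L, N))
  links <- cbind(seq_len(N), seq_len(N) + N)
  meta <- mesh@meta
  meta$bilayerOffset <- offset
  bilayerMesh(nodes2, elements2, fibers = fibers2, fibrotic = fibrotic2,
              region = region2, layer = layer2, links = links, meta = meta)
}
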