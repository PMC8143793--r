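#' Write a mesh in CARP-style plain text
#'
#' Writes `<base>.pts` (node count header, coordinates in um),
#' `<base>.elem` (element count header, `Tr n1 n2 n3 tag` with 0-based
#' node indices and the region id as tag; interlayer links as `Ln a b 0`),
#' `<base>.lon` (one fiber vector per surface element), a `<base>.labels`
#' CSV (fibrotic flag, region id, layer is per node in `<base>.layer`) and
#' a `<base>.json` sidecar with provenance (seed, achieved burden).
#'
#' @param mesh a [BilayerMesh-class].
#' @param base path prefix (without extension).
#' @return `base`, invisibly.
#' @export
writeMeshCARP <- function(mesh, base) {
  pts <- mesh@nodes * 1000  # mm -> um
  con <- file(paste0(base, ".pts"), "w")
  writeLines(as.character(nrow(pts)), con)
  write.table(format(pts, scientific = FALSE, trim = TRUE), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  close(con)
  el0 <- mesh@elements - 1L
  con <- file(paste0(base, ".elem"), "w")
  writeLines(as.character(nrow(el0) + nrow(mesh@links)), con)
  if (nrow(el0) > 0)
    writeLines(paste("Tr", el0[, 1], el0[, 2], el0[, 3], mesh@region), con)
  if (nrow(mesh@links) > 0)
    writeLines(paste("Ln", mesh@links[, 1] - 1L, mesh@links[, 2] - 1L, 0),
               con)
  close(con)
  con <- file(paste0(base, ".lon"), "w")
  writeLines("1", con)   # one direction per element
  write.table(format(mesh@fibers, scientific = FALSE, trim = TRUE), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  close(con)
  write.csv(data.frame(fibrotic = as.integer(mesh@fibrotic),
                       region = mesh@region),
            paste0(base, ".labels"), row.names = FALSE, quote = FALSE)
  writeLines(as.character(mesh@layer), paste0(base, ".layer"))
  meta <- mesh@meta
  side <- list(
    geometry = meta$geometry %||% "unknown",
    resolution_um = meta$resolution %||% NA,
    achieved_burden = meta$achievedBurden %||% fibrosisBurden(mesh),
    seed = if (!is.null(meta$spec)) meta$spec@seed else NA)
  jsonlite::write_json(side, paste0(base, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(base)
}

#' Read a CARP-style plain-text mesh
#'
#' Counterpart of [writeMeshCARP()]; the round trip preserves coordinates
#' (to 1e-6 um), connectivity, labels and fibers. Meshes mixing element
#' types other than `Tr` (triangles) and `Ln` (interlayer links) are
#' rejected.
#'
#' @param base path prefix (without extension).
#' @return a [BilayerMesh-class].
#' @export
readMeshCARP <- function(base) {
  f <- paste0(base, ".pts")
  if (!file.exists(f)) stop("missing file: ", f)
  n <- as.integer(readLines(f, n = 1))
  pts <- as.matrix(read.table(f, skip = 1, nrows = n))
  if (nrow(pts) != n) stop(f, ": node count mismatch at line ", n + 1)
  lines <- readLines(paste0(base, ".elem"))
  ne <- as.integer(lines[1])
  if (length(lines) - 1 != ne)
    stop(base, ".elem: element count mismatch (header ", ne, ", got ",
         length(lines) - 1, ")")
  toks <- strsplit(lines[-1], "[ \t]+")
  types <- vapply(toks, `[`, character(1), 1)
  bad <- which(!types %in% c("Tr", "Ln"))
  if (length(bad))
    stop(base, ".elem: unsupported element type '", types[bad[1]],
         "' at line ", bad[1] + 1)
  tri <- toks[types == "Tr"]
  el <- t(vapply(tri, function(x) as.integer(x[2:4]), integer(3))) + 1L
  region <- vapply(tri, function(x)
    if (length(x) >= 5) as.integer(x[5]) else 0L, integer(1))
  lnk <- toks[types == "Ln"]
  links <- if (length(lnk))
    t(vapply(lnk, function(x) as.integer(x[2:3]), integer(2))) + 1L
  else matrix(integer(0), ncol = 2)
  f <- paste0(base, ".lon")
  nlon <- as.integer(readLines(f, n = 1))
  fib <- as.matrix(read.table(f, skip = 1))
  if (nrow(fib) != nrow(el))
    stop(base, ".lon: fiber vector count (", nrow(fib),
         ") does not match surface element count (", nrow(el), ")")
  labf <- paste0(base, ".labels")
  fibrotic <- rep(FALSE, nrow(el))
  if (file.exists(labf)) {
    lab <- read.csv(labf)
    fibrotic <- as.logical(lab$fibrotic)
    if (all(region == 0) && !is.null(lab$region))
      region <- as.integer(lab$region)
  }
  layf <- paste0(base, ".layer")
  layer <- if (file.exists(layf)) as.integer(readLines(layf))
  else rep(1L, nrow(pts))
  bilayerMesh(pts / 1000, el, fibers = fib, fibrotic = fibrotic,
              region = region, layer = layer, links = links,
              meta = list(source = base))
}

#' Write a mesh (with optional fields) as legacy VTK ASCII
#'
#' Unstructured-grid legacy VTK (version 2.0) with triangle cells and
#' optional per-cell scalar fields (e.g. fibrosis labels, FD/FE maps) and
#' per-point scalars (e.g. activation times).
#'
#' @param mesh a [BilayerMesh-class].
#' @param path output `.vtk` file.
#' @param cellData named list of per-element numeric vectors.
#' @param pointData named list of per-node numeric vectors.
#' @return `path`, invisibly.
#' @export
writeMeshVTK <- function(mesh, path, cellData = list(), pointData = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 2.0", "atrialRD mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID"), con)
  N <- nrow(mesh@nodes); E <- nrow(mesh@elements)
  writeLines(sprintf("POINTS %d double", N), con)
  write.table(format(mesh@nodes, scientific = FALSE, trim = TRUE), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", E, 4 * E), con)
  writeLines(paste(3, mesh@elements[, 1] - 1L, mesh@elements[, 2] - 1L,
                   mesh@elements[, 3] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", E), con)
  writeLines(as.character(rep(5L, E)), con)
  cellData <- c(list(fibrotic = as.numeric(mesh@fibrotic),
                     region = as.numeric(mesh@region)), cellData)
  writeLines(sprintf("CELL_DATA %d", E), con)
  for (nm in names(cellData)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(cellData[[nm]], scientific = FALSE, trim = TRUE), con)
  }
  if (length(pointData)) {
    writeLines(sprintf("POINT_DATA %d", N), con)
    for (nm in names(pointData)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(pointData[[nm]], scientific = FALSE, trim = TRUE),
                 con)
    }
  }
  invisible(path)
}

#' Export rotor trajectories as VTK polylines
#'
#' @param events list of [RDEvent-class].
#' @param path output `.vtk` file.
#' @return `path`, invisibly.
#' @export
writeTrajectoriesVTK <- function(events, path) {
  pts <- do.call(rbind, lapply(events, function(e)
    e@trajectory[, c("x", "y", "z"), drop = FALSE]))
  if (is.null(pts)) pts <- matrix(numeric(0), ncol = 3)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 2.0", "rotor trajectories", "ASCII",
               "DATASET POLYDATA"), con)
  writeLines(sprintf("POINTS %d double", nrow(pts)), con)
  if (nrow(pts))
    write.table(format(pts, scientific = FALSE, trim = TRUE), con,
                row.names = FALSE, col.names = FALSE, quote = FALSE)
  sizes <- vapply(events, function(e) nrow(e@trajectory), integer(1))
  writeLines(sprintf("LINES %d %d", length(events),
                     length(events) + sum(sizes)), con)
  off <- 0L
  for (s in sizes) {
    writeLines(paste(c(s, seq.int(off, off + s - 1L)), collapse = " "), con)
    off <- off + s
  }
  invisible(path)
}

#' Read a run configuration (YAML or JSON)
#'
#' Validates the presence of the required top-level sections and returns
#' the configuration as a nested list. Every random procedure must
#' reference an explicit seed.
#'
#' @param path configuration file (`.yaml`/`.yml`/`.json`).
#' @return nested configuration list.
#' @export
readRunConfig <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  need <- c("substrate", "seed")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("run configuration missing required field(s): ",
         paste(miss, collapse = ", "))
  cfg
}

#' Build package objects from a run configuration
#' @param cfg configuration list from [readRunConfig()].
#' @return list with `spec` ([SubstrateSpec-class]), `solver`, `cond`.
#' @export
configToObjects <- function(cfg) {
  su <- cfg$substrate
  spec <- substrateSpec(
    geometry = su$geometry %||% "sheet",
    dimensions = su$dimensions %||% c(20, 20),
    resolution = su$resolution %||% 400,
    fibrosisBurden = su$fibrosis_burden %||% 0.14,
    correlationLength = su$correlation_length %||% 1.5,
    patchiness = su$patchiness %||% 0.85,
    seed = cfg$seed)
  so <- cfg$solver
  solver <- solverConfig(Cm = so$Cm %||% 1, beta = so$beta %||% 0.14,
                         dt = so$dt %||% 0.025,
                         outputStride = so$output_stride %||% 40,
                         duration = so$duration %||% 100)
  cd <- cfg$conductivity
  cond <- conductivityConfig(
    sigmaLHealthy = cd$sigma_l_healthy %||% 0.409,
    sigmaTHealthy = cd$sigma_t_healthy %||% 0.0820,
    sigmaLFibrotic = cd$sigma_l_fibrotic %||% 0.177,
    sigmaTFibrotic = cd$sigma_t_fibrotic %||% 0.0221,
    sigmaInterlayer = cd$sigma_interlayer %||% 0.8)
  list(spec = spec, solver = solver, cond = cond)
}
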