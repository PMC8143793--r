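# shared fixtures, all built in code

# one equilateral triangle in the z = 0 plane (edge 1 mm)
equilateralMesh <- function() {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  bilayerMesh(nodes, matrix(c(1, 2, 3), 1), meta = list(resolution = 1000))
}

# coarse UV-sphere (closed, manifold) of given radius
sphereMesh <- function(radius = 5, nTheta = 24, nPhi = 12) {
  phis <- seq(-pi / 2, pi / 2, length.out = nPhi + 1)
  phis <- phis[-c(1, nPhi + 1)]
  ths <- seq(0, 2 * pi, length.out = nTheta + 1)[-(nTheta + 1)]
  grid <- cbind(rep(ths, times = length(phis)), rep(phis, each = nTheta))
  nodes <- cbind(radius * cos(grid[, 2]) * cos(grid[, 1]),
                 radius * cos(grid[, 2]) * sin(grid[, 1]),
                 radius * sin(grid[, 2]))
  southI <- nrow(nodes) + 1L
  northI <- nrow(nodes) + 2L
  nodes <- rbind(nodes, c(0, 0, -radius), c(0, 0, radius))
  idx <- function(i, j) (j - 1L) * nTheta + ((i - 1L) %% nTheta) + 1L
  el <- NULL
  for (j in seq_len(length(phis) - 1))
    for (i in seq_len(nTheta))
      el <- rbind(el,
                  c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
                  c(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  for (i in seq_len(nTheta)) {
    el <- rbind(el, c(southI, idx(i + 1L, 1L), idx(i, 1L)))
    el <- rbind(el, c(northI, idx(i, length(phis)), idx(i + 1L, length(phis))))
  }
  bilayerMesh(nodes, el, meta = list(resolution = 1000))
}

# annulus (ring) mesh in the z = 0 plane: inner radius r0, outer r1
annulusMesh <- function(r0 = 4, r1 = 8, nTheta = 48, nR = 5) {
  rs <- seq(r0, r1, length.out = nR)
  ths <- seq(0, 2 * pi, length.out = nTheta + 1)[-(nTheta + 1)]
  nodes <- NULL
  for (r in rs) nodes <- rbind(nodes, cbind(r * cos(ths), r * sin(ths), 0))
  idx <- function(i, j) (j - 1L) * nTheta + ((i - 1L) %% nTheta) + 1L
  el <- NULL
  for (j in seq_len(nR - 1))
    for (i in seq_len(nTheta))
      el <- rbind(el,
                  c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
                  c(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  bilayerMesh(nodes, el, meta = list(resolution = 500))
}

# smooth double-spiral (figure-of-eight) phase field on a sheet: topological
# charge +1 at c1 and -1 at c2
fig8Phase <- function(co, times, c1 = c(5.3, 10.2), c2 = c(15.3, 10.2),
                      period = 150) {
  sapply(times, function(t) {
    p <- atan2(co[, 2] - c1[2], co[, 1] - c1[1]) -
      atan2(co[, 2] - c2[2], co[, 1] - c2[1]) - 2 * pi * t / period
    (p + pi) %% (2 * pi) - pi
  })
}

# single archimedean spiral phase field
spiralPhase <- function(co, times, core = c(10, 10), k = 0.5, period = 150) {
  sapply(times, function(t) {
    p <- atan2(co[, 2] - core[2], co[, 1] - core[1]) -
      k * sqrt((co[, 1] - core[1])^2 + (co[, 2] - core[2])^2) -
      2 * pi * t / period
    (p + pi) %% (2 * pi) - pi
  })
}

# brute-force winding-number oracle: charge of every element at one frame
windingOracle <- function(phase, mesh, frame) {
  el <- meshElements(mesh)
  p <- phase[, frame]
  vapply(seq_len(nrow(el)), function(e) {
    ph <- p[el[e, ]]
    if (anyNA(ph)) return(0)
    d <- c(ph[2] - ph[1], ph[3] - ph[2], ph[1] - ph[3])
    d <- (d + pi) %% (2 * pi) - pi
    round(sum(d) / (2 * pi))
  }, numeric(1))
}

# tiny healthy sheet for fast tissue runs
tinySheet <- function(size = 8, res = 400) makeSheetMesh(size, size, res)
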