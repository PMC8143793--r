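# monodomain solver: assembly, conservation, CV, bilayer construction

test_that("diffusion operator conserves charge (rows sum to zero)", {
  op <- assembleDiffusion(equilateralMesh(), conductivityConfig())
  expect_lt(max(abs(Matrix::rowSums(op$K))), 1e-12)
  mesh <- tinySheet()
  mesh@fibrotic[seq(1, nrow(meshElements(mesh)), by = 3)] <- TRUE
  op2 <- assembleDiffusion(mesh, conductivityConfig())
  expect_lt(max(abs(Matrix::rowSums(op2$K))), 1e-10)
})

test_that("interior stencil matches the closed-form five-point operator", {
  # on a right-triangle grid with lumped mass, an interior row reduces to
  # D (V_E + V_W - 2 V_C)/h^2 + D (V_N + V_S - 2 V_C)/h^2
  h <- 0.2
  mesh <- makeSheetMesh(2, 2, 1000 * h, fiberAngle = 0)
  cond <- conductivityConfig()
  beta <- 0.14; Cm <- 1
  op <- assembleDiffusion(mesh, cond, beta, Cm)
  nx <- mesh@meta$nx
  co <- meshNodes(mesh)
  ctr <- which(abs(co[, 1] - 1) < 1e-9 & abs(co[, 2] - 1) < 1e-9)
  row <- op$K[ctr, ] / op$mass[ctr]
  DL <- cond@sigmaLHealthy / (10 * beta * Cm)
  DT <- cond@sigmaTHealthy / (10 * beta * Cm)
  expect_equal(row[ctr], -2 * (DL + DT) / h^2, tolerance = 1e-10)
  expect_equal(row[ctr + 1], DL / h^2, tolerance = 1e-10)   # east
  expect_equal(row[ctr - 1], DL / h^2, tolerance = 1e-10)   # west
  expect_equal(row[ctr + nx], DT / h^2, tolerance = 1e-10)  # north
  expect_equal(row[ctr - nx], DT / h^2, tolerance = 1e-10)  # south
})

test_that("fibrotic elements use the fibrotic conductivity tensor", {
  mesh <- equilateralMesh()
  mesh@fibrotic <- TRUE
  cond <- conductivityConfig()
  # recover the tensor eigenvalues from the assembled operator by probing
  # linear fields: flux of V = x along the fiber gives D_L, V = y gives D_T
  op <- assembleDiffusion(mesh, cond, beta = 0.14, Cm = 1)
  # compare with healthy assembly: ratio of operators = ratio of sigmas
  mesh2 <- equilateralMesh()
  opH <- assembleDiffusion(mesh2, cond, beta = 0.14, Cm = 1)
  co <- meshNodes(mesh)
  vx <- co[, 1]
  # energy <v, K v> scales with the tensor component along grad v
  eF <- as.numeric(vx %*% (op$K %*% vx))
  eH <- as.numeric(vx %*% (opH$K %*% vx))
  expect_equal(eF / eH, cond@sigmaLFibrotic / cond@sigmaLHealthy,
               tolerance = 1e-10)
  vy <- co[, 2]
  eFt <- as.numeric(vy %*% (op$K %*% vy))
  eHt <- as.numeric(vy %*% (opH$K %*% vy))
  expect_equal(eFt / eHt, cond@sigmaTFibrotic / cond@sigmaTHealthy,
               tolerance = 1e-10)
})

test_that("degenerate elements are rejected with the element named", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  mesh <- bilayerMesh(nodes, matrix(c(1, 2, 3), 1))
  expect_error(assembleDiffusion(mesh, conductivityConfig()),
               "zero area.*element 1")
})

test_that("unstimulated resting tissue stays quiescent", {
  mesh <- tinySheet(6)
  r <- runSimulation(mesh, solverConfig(dt = 0.05, duration = 1000),
                     recordVm = TRUE, init = "rest")
  v0 <- r@vm[, 1]
  expect_lt(max(abs(r@vm - v0)), 0.5)
  expect_true(all(is.na(r@activationTimes)))
})

test_that("measureCV recovers an exact synthetic linear activation field", {
  mesh <- makeSheetMesh(10, 2, 400)
  co <- meshNodes(mesh)
  cv <- 0.6  # mm/ms
  res <- new("SimulationResult", vm = matrix(numeric(0), 0, 0),
             vmTimes = numeric(0), activationTimes = co[, 1] / cv,
             finalState = matrix(0, 0, 0), lastActivation = max(co[, 1]) / cv,
             tStop = 100, diverged = FALSE, meta = list())
  expect_equal(measureCV(res, mesh, "x"), 100 * cv, tolerance = 1e-12)
})

test_that("propagation failure is reported as a value, not an error", {
  mesh <- makeSheetMesh(10, 2, 400)
  at <- rep(NA_real_, nrow(meshNodes(mesh)))
  res <- new("SimulationResult", vm = matrix(numeric(0), 0, 0),
             vmTimes = numeric(0), activationTimes = at,
             finalState = matrix(0, 0, 0), lastActivation = NA_real_,
             tStop = 100, diverged = FALSE, meta = list())
  cv <- measureCV(res, mesh, "x")
  expect_true(is.na(cv))
  expect_equal(attr(cv, "reason"), "propagation failure")
})

cvStrip <- function(sigmaL, res = 200, dt = 0.025, dur = 40) {
  mesh <- makeSheetMesh(16, 2, res)
  cond <- conductivityConfig(sigmaLHealthy = sigmaL)
  co <- meshNodes(mesh)
  edge <- which(co[, 1] < 1e-9)
  r <- runSimulation(mesh, solverConfig(dt = dt, duration = dur), cond,
                     list(stimulusTrain(edge, 0, amplitude = 300)),
                     recordVm = FALSE)
  measureCV(r, mesh, "x")
}

test_that("conduction velocity scales with the square root of conductivity", {
  # continuous-limit law, checked along the well-resolved fiber direction
  # dt below the explicit-diffusion stability bound of the quadrupled case
  cv1 <- cvStrip(0.409, dt = 0.01)
  cv4 <- cvStrip(4 * 0.409, dt = 0.01, dur = 25)
  expect_false(is.na(cv1) || is.na(cv4))
  expect_equal(cv4 / cv1, 2, tolerance = 0.05)
})

test_that("time step refinement converges the measured CV below 1%", {
  # operator splitting is first-order in dt; at dt <= 6.25 us a further
  # halving moves CV by under 1%
  cv1 <- cvStrip(0.409, dt = 0.00625)
  cv2 <- cvStrip(0.409, dt = 0.003125)
  expect_lt(abs(cv1 / cv2 - 1), 0.01)
})

test_that("point stimulus produces elliptical isochrones with sqrt(5) axis ratio", {
  # 100 um so both wavefronts stay well resolved; stations away from the
  # source so curvature effects have decayed
  mesh <- makeSheetMesh(24, 12, 100)
  co <- meshNodes(mesh)
  d2 <- (co[, 1] - 12)^2 + (co[, 2] - 6)^2
  stimN <- which(d2 < 1.2^2)
  r <- runSimulation(mesh, solverConfig(dt = 0.0125, duration = 22),
                     stimuli = list(stimulusTrain(stimN, 0, amplitude = 80)),
                     recordVm = FALSE)
  at <- r@activationTimes
  tAt <- function(x, y) {
    sel <- which(abs(co[, 1] - x) < 0.06 & abs(co[, 2] - y) < 0.06)
    mean(at[sel], na.rm = TRUE)
  }
  cvL <- (10 - 6) / (tAt(22, 6) - tAt(18, 6))
  cvT <- (5 - 3) / (tAt(12, 11) - tAt(12, 9))
  expect_equal(cvL / cvT, sqrt(5), tolerance = 0.1 * sqrt(5))
})

test_that("a fully fibrotic strip conducts slower than healthy in both directions", {
  # 50 um resolution so that the very slow fibrotic transverse wavefront
  # stays spatially resolved (at >= 100 um it decrementally blocks)
  run <- function(fibrotic, dirn) {
    # longitudinal at 100 um; transverse at 50 um with dt under the
    # explicit stability bound of the healthy case
    mesh <- if (dirn == "x") makeSheetMesh(6, 0.4, 100)
            else makeSheetMesh(0.4, 6, 50)
    if (fibrotic) mesh@fibrotic[] <- TRUE
    co <- meshNodes(mesh)
    edge <- if (dirn == "x") which(co[, 1] < 1e-9) else which(co[, 2] < 1e-9)
    dt <- if (dirn == "x") 0.01 else 0.003
    r <- runSimulation(mesh, solverConfig(dt = dt, duration = 80),
                       stimuli = list(stimulusTrain(edge, 0, amplitude = 300)),
                       recordVm = FALSE)
    measureCV(r, mesh, dirn)
  }
  expect_lt(run(TRUE, "x"), run(FALSE, "x"))
  expect_lt(run(TRUE, "y"), run(FALSE, "y"))
})

test_that("simulation results are bit-identical across reruns", {
  mesh <- tinySheet(6)
  mesh@fibrotic[1:20] <- TRUE
  go <- function() {
    r <- runSimulation(mesh, solverConfig(dt = 0.05, duration = 60),
                       stimuli = list(stimulusTrain(1:5, 0, amplitude = 80)),
                       recordVm = TRUE)
    list(r@vm, r@finalState, r@activationTimes)
  }
  expect_identical(go(), go())
})

test_that("bilayer construction duplicates nodes, links and labels", {
  tri <- equilateralMesh()
  tri@fibrotic <- TRUE
  bl <- buildBilayer(tri, offset = 100)
  expect_equal(nrow(meshNodes(bl)), 6)
  expect_equal(nrow(meshElements(bl)), 2)
  expect_equal(nrow(meshLinks(bl)), 3)
  expect_true(all(fibrosisLabels(bl)))
  expect_equal(meshLayers(bl), c(1L, 1L, 1L, 2L, 2L, 2L))
  d <- sqrt(rowSums((meshNodes(bl)[4:6, ] - meshNodes(bl)[1:3, ])^2))
  expect_equal(d, rep(0.1, 3), tolerance = 1e-9)  # 100 um in mm
})

test_that("bilayer offset of a sphere scales surface area by (1 + off/R)^2", {
  sph <- sphereMesh(radius = 5)
  bl <- buildBilayer(sph, offset = 500)  # 0.5 mm for a visible effect
  endo <- apply(meshElements(bl), 1, function(e) all(meshLayers(bl)[e] == 1L))
  aEndo <- sum(elementAreas(bl)[endo])
  aEpi <- sum(elementAreas(bl)[!endo])
  expect_equal(aEpi / aEndo, (1 + 0.5 / 5)^2, tolerance = 0.01)
})

test_that("non-manifold surfaces are rejected", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 1, 0), c(0.5, -1, 0),
                 c(0.5, 0, 1))
  el <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5))  # edge 1-2 in 3 triangles
  mesh <- bilayerMesh(nodes, el)
  expect_error(buildBilayer(mesh), "non-manifold")
})

test_that("bilayer strips conduct at the faster layer's velocity", {
  # endo fibers along the strip, epi fibers across: the coupled bilayer is
  # driven by the fast layer, so CV approaches the longitudinal value
  endo <- makeSheetMesh(12, 2, 200, fiberAngle = 0)
  bl <- buildBilayer(endo, offset = 100)
  bl@fibers <- generateFibers(bl, endoAngle = 0, epiAngle = 90)
  co <- meshNodes(bl)
  edge <- which(co[, 1] < 1e-9 & meshLayers(bl) == 1L)
  r <- runSimulation(bl, solverConfig(dt = 0.025, duration = 60),
                     stimuli = list(stimulusTrain(edge, 0, amplitude = 300)),
                     recordVm = FALSE)
  at <- r@activationTimes
  epi <- meshLayers(bl) == 2L
  # epi activation essentially simultaneous with endo partner nodes
  expect_lt(max(abs(at[which(epi)] - at[seq_len(sum(!epi))]), na.rm = TRUE), 2)
})
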