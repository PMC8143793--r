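# phase computation, singularity detection/tracking, morphologies, IdS

test_that("phase of a sinusoidal voltage advances linearly", {
  times <- seq(0, 2000, by = 10)
  period <- 180
  vm <- matrix(rep(-60 + 30 * cos(2 * pi * times / period), 2),
               nrow = 2, byrow = TRUE)
  ph <- computePhase(vm, times)
  expect_true(all(ph$active))
  expect_equal(ph$period, period, tolerance = 0.02)
  dp <- diff(ph$phase[1, ])
  dp <- (dp + pi) %% (2 * pi) - pi
  # analytic signal of cos(w t) is exp(+i w t): phase advances at +w
  expect_equal(mean(dp), 2 * pi * 10 / period, tolerance = 0.02)
})

test_that("flat traces are masked as phase-undefined", {
  times <- seq(0, 500, by = 10)
  vm <- rbind(rep(-80, length(times)),
              -60 + 30 * cos(2 * pi * times / 150))
  ph <- computePhase(vm, times)
  expect_false(ph$active[1])
  expect_true(all(is.na(ph$phase[1, ])))
  expect_true(ph$active[2])
})

test_that("plane waves yield straight equal-phase contours and no singularities", {
  mesh <- makeSheetMesh(20, 20, 500)
  co <- meshNodes(mesh)
  times <- seq(0, 1000, by = 10)
  vm <- sapply(times, function(t)
    -80 + 50 * pmax(0, cos(2 * pi * (co[, 1] / 15 - t / 200))))
  ph <- computePhase(vm, times)
  # equal-phase contours: phase depends on x only
  f <- 50
  for (x0 in c(5, 10, 15)) {
    sel <- abs(co[, 1] - x0) < 1e-9
    expect_lt(diff(range(ph$phase[sel, f])), 0.02)
  }
  ev <- detectPhaseSingularities(ph, mesh, times)
  expect_length(ev, 0)
})

test_that("a spiral phase field yields one singularity at the core", {
  mesh <- makeSheetMesh(20, 20, 500)
  co <- meshNodes(mesh)
  times <- seq(0, 1000, by = 10)
  phase <- spiralPhase(co, times, core = c(10, 10))
  ev <- detectPhaseSingularities(phase, mesh, times)
  expect_length(ev, 1)
  expect_lt(sqrt(sum((ev[[1]]@meanPosition[1:2] - c(10, 10))^2)), 0.75)
  expect_equal(ev[[1]]@chirality, 1)
  expect_gte(ev[[1]]@lifespan, 1000)
})

test_that("a figure-of-eight field yields two singularities of opposite chirality", {
  mesh <- makeSheetMesh(20, 20, 500)
  co <- meshNodes(mesh)
  times <- seq(0, 1000, by = 10)
  phase <- fig8Phase(co, times)
  ev <- detectPhaseSingularities(phase, mesh, times)
  expect_length(ev, 2)
  expect_equal(sum(vapply(ev, function(e) e@chirality, numeric(1))), 0)
})

test_that("detector agrees with the brute-force winding oracle per frame", {
  mesh <- makeSheetMesh(20, 20, 500)
  co <- meshNodes(mesh)
  times <- seq(0, 200, by = 10)
  for (mk in list(function() spiralPhase(co, times),
                  function() fig8Phase(co, times),
                  function() sapply(times, function(t) {
                    p <- 2 * pi * (co[, 1] / 15 - t / 200)
                    (p + pi) %% (2 * pi) - pi
                  }))) {
    phase <- mk()
    for (f in c(1, 11, 21)) {
      oracle <- windingOracle(phase, mesh, f)
      det <- atrialRD:::.frameSingularities(phase, mesh, f)
      expect_setequal(det, which(oracle != 0))
      expect_equal(vapply(det, function(e) oracle[e], numeric(1)),
                   rep(sign(oracle[det]), length.out = length(det)))
    }
  }
})

test_that("singularities are tracked through core drift", {
  mesh <- makeSheetMesh(20, 20, 500)
  co <- meshNodes(mesh)
  times <- seq(0, 500, by = 10)
  # core drifts 0.02 mm/ms: within the 2 mm per-frame linking radius
  phase <- sapply(times, function(t) {
    cx <- 8 + 0.02 * t
    p <- atan2(co[, 2] - 10, co[, 1] - cx) -
      0.5 * sqrt((co[, 1] - cx)^2 + (co[, 2] - 10)^2) - 2 * pi * t / 150
    (p + pi) %% (2 * pi) - pi
  })
  ev <- detectPhaseSingularities(phase, mesh, times)
  expect_length(ev, 1)
  traj <- ev[[1]]@trajectory
  expect_gt(nrow(traj), 40)
  # mean position near the mid-drift core
  expect_equal(ev[[1]]@meanPosition[1], 8 + 0.02 * 250, tolerance = 0.1)
})

test_that("morphology counting merges nearby trajectories only", {
  mkEv <- function(x, y) new("RDEvent",
    trajectory = matrix(c(0, x, y, 0), 1,
                        dimnames = list(NULL, c("t", "x", "y", "z"))),
    chirality = 1, lifespan = 200, meanPosition = c(x, y, 0),
    region = 1L, morphology = 0L)
  expect_equal(countUniqueMorphologies(list()), 0L)
  expect_equal(countUniqueMorphologies(list(mkEv(0, 0))), 1L)
  expect_equal(countUniqueMorphologies(list(mkEv(0, 0), mkEv(3, 0))), 1L)
  expect_equal(countUniqueMorphologies(list(mkEv(0, 0), mkEv(30, 0))), 2L)
  # chains merge by single linkage: 0 - 8 - 16 is one morphology
  expect_equal(countUniqueMorphologies(list(mkEv(0, 0), mkEv(8, 0),
                                            mkEv(16, 0))), 1L)
})

test_that("IdS follows the printed counting rule", {
  siteRegions <- c(LSPV_ant = 4L, LSPV_post = 4L, LIPV_ant = 4L,
                   LIPV_post = 4L, posterior_wall = 2L, floor = 1L)
  # 3 models, each inducible from 2 of the 4 LPV sites -> IdS = 6/4
  recs <- do.call(rbind, lapply(1:3, function(m) data.frame(
    model = sprintf("m%d", m),
    site = c("LSPV_ant", "LIPV_post", "posterior_wall"),
    outcome = c("RD", "RD", "none"),
    siteRegion = c(4L, 4L, 2L))))
  ids <- computeIdS(recs, siteRegions, cohort = "test")
  tab <- ids@table
  expect_equal(tab$ids[tab$region == 4], 1.5)
  expect_equal(tab$inductions[tab$region == 4], 6)
  expect_equal(tab$ids[tab$region == 2], 0)
  # numerator over regions equals total RD records
  expect_equal(sum(tab$inductions), sum(recs$outcome == "RD"))
  # one model, one induction in a 2-site region -> 0.5
  sr <- c(a = 1L, b = 1L)
  r1 <- data.frame(model = "m", site = "a", outcome = "RD", siteRegion = 1L)
  expect_equal(computeIdS(r1, sr)@table$ids, 0.5)
  # all-none cohort: all zeros
  r0 <- data.frame(model = "m", site = "a", outcome = "none",
                   siteRegion = 1L)
  expect_true(all(computeIdS(r0, sr)@table$ids == 0))
  # macroscopic reentry never counts toward IdS
  r2 <- data.frame(model = "m", site = "a", outcome = "macroscopic_reentry",
                   siteRegion = 1L)
  expect_true(all(computeIdS(r2, sr)@table$ids == 0))
  # a site with no region is rejected
  r3 <- data.frame(model = "m", site = "a", outcome = "RD",
                   siteRegion = NA_integer_)
  expect_error(computeIdS(r3, sr), "no region")
})

test_that("macroscopic circulation around an annulus is classified as such", {
  mesh <- annulusMesh()
  co <- meshNodes(mesh)
  times <- seq(0, 1000, by = 10)
  # wave circulating the ring: phase = polar angle - omega t
  vm <- sapply(times, function(t) {
    th <- atan2(co[, 2], co[, 1])
    -60 + 35 * cos(th - 2 * pi * t / 200)
  })
  res <- new("SimulationResult", vm = vm, vmTimes = times,
             activationTimes = rep(0, nrow(co)),
             finalState = matrix(0, 0, 0), lastActivation = 1000,
             tStop = 1000, diverged = FALSE, meta = list())
  cls <- classifyArrhythmia(res, mesh)
  expect_equal(cls$outcome, "macroscopic_reentry")
  # a rotor on a simply-connected sheet is an RD
  sheet <- makeSheetMesh(20, 20, 500)
  cos2 <- meshNodes(sheet)
  vm2 <- sapply(times, function(t) {
    p <- atan2(cos2[, 2] - 10, cos2[, 1] - 10) -
      0.5 * sqrt((cos2[, 1] - 10)^2 + (cos2[, 2] - 10)^2) -
      2 * pi * t / 180
    -60 + 35 * cos(p)
  })
  res2 <- new("SimulationResult", vm = vm2, vmTimes = times,
              activationTimes = rep(0, nrow(cos2)),
              finalState = matrix(0, 0, 0), lastActivation = 1000,
              tStop = 1000, diverged = FALSE, meta = list())
  cls2 <- classifyArrhythmia(res2, sheet)
  expect_equal(cls2$outcome, "RD")
  expect_gte(length(cls2$events), 1)
})
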