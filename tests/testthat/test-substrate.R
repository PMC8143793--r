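# synthetic substrate generation: geometry, fibrosis patterns, regions,
# pacing sites, fibers

test_that("sheet geometry has the expected structured-grid size", {
  spec <- substrateSpec("sheet", c(20, 20), 200)
  mesh <- generateGeometry(spec)
  expect_equal(nrow(meshNodes(mesh)), 101 * 101)
  expect_equal(nrow(meshElements(mesh)), 2 * 100 * 100)
})

test_that("LA surrogate has exactly six boundary loops", {
  mesh <- makeLASurrogateMesh(30, 1200)
  loops <- boundaryLoops(mesh)
  expect_length(loops, 6)   # 4 PV ostia, LAA tip, mitral rim
})

test_that("generator outputs are pure functions of (spec, seed)", {
  spec <- substrateSpec("sheet", c(12, 12), 400, 0.2, seed = 42)
  m1 <- generateSubstrate(spec)
  m2 <- generateSubstrate(spec)
  expect_identical(meshNodes(m1), meshNodes(m2))
  expect_identical(fibrosisLabels(m1), fibrosisLabels(m2))
  spec2 <- substrateSpec("sheet", c(12, 12), 400, 0.2, seed = 43)
  m3 <- generateSubstrate(spec2)
  expect_false(identical(fibrosisLabels(m1), fibrosisLabels(m3)))
  # same burden, different layout
  expect_equal(fibrosisBurden(m1), fibrosisBurden(m3), tolerance = 0.01)
})

test_that("achieved burden hits the target within half a percent", {
  mesh <- makeSheetMesh(15, 15, 400)
  for (target in c(0.05, 0.2, 0.5)) {
    spec <- substrateSpec("sheet", c(15, 15), 400, target, seed = 7)
    lab <- generateFibrosis(mesh, spec)
    ar <- elementAreas(mesh)
    expect_lt(abs(sum(ar[lab]) / sum(ar) - target), 0.005)
  }
  z <- generateFibrosis(mesh, substrateSpec("sheet", c(15, 15), 400, 0))
  expect_false(any(z))
  o <- generateFibrosis(mesh, substrateSpec("sheet", c(15, 15), 400, 1))
  expect_true(all(o))
})

test_that("burden is unbiased across seeds", {
  mesh <- makeSheetMesh(10, 10, 500)
  ar <- elementAreas(mesh)
  achieved <- vapply(1:50, function(sd) {
    lab <- generateFibrosis(mesh, substrateSpec("sheet", c(10, 10), 500,
                                                0.15, seed = sd))
    sum(ar[lab]) / sum(ar)
  }, numeric(1))
  expect_lt(abs(mean(achieved) - 0.15), 0.001)
})

test_that("longer correlation length lowers fibrosis entropy at fixed burden", {
  mesh <- makeSheetMesh(15, 15, 400)
  meanFE <- vapply(c(0.5, 3), function(cl) {
    lab <- generateFibrosis(mesh, substrateSpec("sheet", c(15, 15), 400,
                                                0.25, cl, 1, seed = 5))
    m <- mesh; fibrosisLabels(m) <- lab
    mean(localFibrosisEntropy(m, 2.5))
  }, numeric(1))
  expect_lt(meanFE[2], meanFE[1])
})

test_that("bilayer substrates share fibrosis labels between shells", {
  spec <- substrateSpec("sheet", c(10, 10), 500, 0.3, seed = 2)
  bl <- generateSubstrate(spec, bilayer = TRUE)
  E <- nrow(meshElements(bl)) / 2
  expect_identical(fibrosisLabels(bl)[seq_len(E)],
                   fibrosisLabels(bl)[E + seq_len(E)])
})

test_that("region partition covers the mesh and meets the PV area targets", {
  mesh <- makeLASurrogateMesh(30, 1200)
  part <- assignRegions(mesh)
  expect_true(all(part@region %in% 1:5))
  ar <- elementAreas(mesh)
  tot <- sum(ar) / 100
  expect_equal(sum(part@areas), tot, tolerance = 1e-9)
  expect_equal(unname(part@areas["LPV"]) / tot, 0.15, tolerance = 1 / 15)
  expect_equal(unname(part@areas["RPV"]) / tot, 0.15, tolerance = 1 / 15)
  # sheets are one region
  sheetPart <- assignRegions(makeSheetMesh(10, 10, 500))
  expect_true(all(sheetPart@region == 1L))
})

test_that("pacing sites: 15 disjoint sets, four in the left-PV region", {
  mesh <- makeLASurrogateMesh(30, 1200)
  part <- assignRegions(mesh)
  regionIds(mesh) <- part@region
  sites <- placePacingSites(mesh, part)
  expect_length(sites, 15)
  allN <- unlist(sites)
  expect_equal(anyDuplicated(allN), 0)
  info <- attr(sites, "siteInfo")
  expect_equal(sum(info$region == 4), 4)   # ant/post LSPV + LIPV
  expect_error(placePacingSites(mesh, NULL), "partition")
})

test_that("generated fibers are unit vectors that respect landmarks", {
  mesh <- makeLASurrogateMesh(30, 1200)
  f <- generateFibers(mesh)
  expect_lt(max(abs(sqrt(rowSums(f^2)) - 1)), 1e-9)
  sheet <- makeSheetMesh(10, 10, 500)
  f0 <- generateFibers(sheet, endoAngle = 0)
  expect_true(all(abs(f0[, 1] - 1) < 1e-12))
  f45 <- generateFibers(sheet, endoAngle = 45)
  expect_equal(f45[1, 1:2], rep(sqrt(2) / 2, 2), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("incompatible resolution is rejected", {
  expect_error(generateGeometry(substrateSpec("la_surrogate", 30, 8000)),
               "resolution")
})
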