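# fibrosis density/entropy fields, pro-RD classification, quiescent-Vm

test_that("FD is 1 on all-fibrotic and 0 on all-healthy meshes", {
  mesh <- makeSheetMesh(8, 8, 500)
  mesh@fibrotic[] <- TRUE
  expect_true(all(localFibrosisDensity(mesh, 2.5) == 1))
  mesh@fibrotic[] <- FALSE
  expect_true(all(localFibrosisDensity(mesh, 2.5) == 0))
})

test_that("FD at a half-plane interface is one half", {
  mesh <- makeSheetMesh(12, 12, 400)
  cen <- elementCentroids(mesh)
  fibrosisLabels(mesh) <- cen[, 1] > 6
  fd <- localFibrosisDensity(mesh, 3)
  onIface <- abs(cen[, 1] - 6) < 0.21 & cen[, 2] > 3.2 & cen[, 2] < 8.8
  expect_lt(max(abs(fd[onIface] - 0.5)), 0.05)
  expect_lt(abs(mean(fd[onIface]) - 0.5), 0.01)
})

test_that("FE is zero in homogeneous or perfectly separated neighborhoods", {
  mesh <- makeSheetMesh(8, 8, 500)
  expect_true(all(localFibrosisEntropy(mesh, 2.5) == 0))
  mesh@fibrotic[] <- TRUE
  expect_true(all(localFibrosisEntropy(mesh, 2.5) == 0))
})

test_that("FE approaches 1 for independent random labels at p = 0.5", {
  mesh <- makeSheetMesh(14, 14, 400)
  set.seed(99)
  fibrosisLabels(mesh) <- runif(nrow(meshElements(mesh))) < 0.5
  fe <- localFibrosisEntropy(mesh, 3)
  expect_gt(mean(fe), 0.99)
})

test_that("a perfectly alternating one-element-pitch pattern has q = 1, FE = 0", {
  # the triangle adjacency of the structured grid is bipartite: labeling by
  # triangle type makes every edge-adjacent pair discordant (q = 1), and
  # the binary entropy of q = 1 is 0
  mesh <- makeSheetMesh(10, 10, 500)
  E <- nrow(meshElements(mesh))
  fibrosisLabels(mesh) <- c(rep(TRUE, E / 2), rep(FALSE, E / 2))
  fe <- localFibrosisEntropy(mesh, 2.5)
  expect_lt(max(fe), 1e-12)
})

test_that("pro-RD polynomial evaluates exactly as printed", {
  poly <- function(fd, fe)
    0.4096 * fd^2 + 3.28 * fd * fe - 0.1036 * fe^2 - 0.7112 * fd - fe +
      0.0429
  expect_equal(poly(1, 1), 1.9177)
  expect_equal(poly(1, 0), -0.2587)
  expect_true(classifyProRD(1, 1))
  expect_false(classifyProRD(1, 0))
  # FD guard neutralizes the positive constant term at the origin
  expect_equal(poly(0, 0), 0.0429)
  expect_false(classifyProRD(0, 0))
  expect_error(classifyProRD(1.2, 0.5), "must lie in")
})

test_that("classification matches brute-force evaluation on a dense grid", {
  g <- seq(0, 1, length.out = 100)
  fd <- rep(g, each = 100); fe <- rep(g, 100)
  got <- classifyProRD(fd, fe)
  want <- logical(length(fd))
  for (k in seq_along(fd)) {
    v <- 0.4096 * fd[k]^2 + 3.28 * fd[k] * fe[k] - 0.1036 * fe[k]^2 -
      0.7112 * fd[k] - fe[k] + 0.0429
    want[k] <- (v > 0) && (fd[k] > 0.01)
  }
  expect_identical(got, want)
})

test_that("region pro-RD burden localizes to the flagged region", {
  mesh <- makeSheetMesh(10, 10, 500)
  cen <- elementCentroids(mesh)
  part <- new("RegionPartition",
              region = ifelse(cen[, 1] < 5, 1L, 2L),
              areas = c(a = 0.5, b = 0.5), names = c("a", "b"))
  met <- new("FibrosisMetricsMap", fd = rep(0.5, nrow(cen)),
             fe = rep(0.5, nrow(cen)),
             proRD = cen[, 1] < 5, radius = 2.5)
  rb <- regionProRDBurden(met, part, mesh)
  expect_equal(unname(rb["a"]), 1)
  expect_equal(unname(rb["b"]), 0)
  met@proRD <- rep(FALSE, nrow(cen))
  expect_true(all(regionProRDBurden(met, part, mesh) == 0))
})

test_that("FD/FE are invariant under rigid motion of the mesh", {
  spec <- substrateSpec("sheet", c(10, 10), 500, 0.3, seed = 13)
  mesh <- generateSubstrate(spec)
  met1 <- localFibrosisMetrics(mesh, 2.5)
  th <- 30 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  mesh2 <- mesh
  mesh2@nodes <- meshNodes(mesh) %*% t(R) + matrix(c(3, -2, 1),
                                                  nrow(meshNodes(mesh)), 3,
                                                  byrow = TRUE)
  met2 <- localFibrosisMetrics(mesh2, 2.5)
  expect_equal(met1@fd, met2@fd, tolerance = 1e-10)
  expect_equal(met1@fe, met2@fe, tolerance = 1e-10)
})

test_that("too small a neighborhood radius is rejected", {
  mesh <- makeSheetMesh(10, 10, 500)
  expect_error(localFibrosisMetrics(mesh, 0.4), "radius")
})

test_that("pro-RD burden grows with global fibrosis burden", {
  mesh <- makeSheetMesh(12, 12, 500)
  burdens <- seq(0.05, 0.4, length.out = 12)
  pro <- vapply(seq_along(burdens), function(k) {
    spec <- substrateSpec("sheet", c(12, 12), 500, burdens[k],
                          correlationLength = 1.5, seed = 100 + k)
    m <- mesh; fibrosisLabels(m) <- generateFibrosis(mesh, spec)
    mean(localFibrosisMetrics(m, 2.5)@proRD)
  }, numeric(1))
  expect_gte(cor(burdens, pro, method = "spearman"), 0)
})

test_that("quiescent-Vm pooling follows the percentile convention", {
  # pooled values: 95 nodes at -80, 5 at -70; the 95th percentile by linear
  # interpolation lies between them
  vmA <- rep(-80, 95)
  vmB <- rep(-70, 5)
  pooled <- c(vmA, vmB)
  thr <- unname(quantile(pooled, 0.95, type = 7))
  s <- quiescentVmAnalysis(list(vmA, vmB), percentile = 95)
  expect_equal(s@threshold, thr)
  expect_equal(unname(s@fractions[1]), mean(vmA > thr))
  expect_equal(unname(s@fractions[2]), mean(vmB > thr))
  # degenerate single-model uniform distribution: nothing strictly above
  u <- quiescentVmAnalysis(list(rep(-80, 50)))
  expect_equal(unname(u@fractions), 0)
  # models still active are excluded and reported
  e <- quiescentVmAnalysis(list(vmA, vmB), stillActive = c(FALSE, TRUE))
  expect_equal(e@excluded, 2L)
  expect_length(e@fractions, 1)
})

test_that("fibrotic tissue rests depolarized relative to healthy in situ", {
  spec <- substrateSpec("sheet", c(8, 8), 400, 0.35,
                        correlationLength = 1.5, seed = 21)
  mesh <- generateSubstrate(spec)
  q <- quiescentRun(mesh, duration = 500)
  nf <- atrialRD:::.nodeFibrotic(mesh)
  expect_false(q$stillActive)
  expect_gt(mean(q$vm[nf]), mean(q$vm[!nf]))
})
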