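# cohort orchestration and statistics

test_that("an empty cohort yields an empty table", {
  res <- runVirtualCohort(cohortSpec(nModels = 0), verbose = FALSE)
  expect_equal(nrow(res$table), 0)
})

test_that("quartile grouping matches a sort-based oracle", {
  set.seed(31)
  x <- runif(40, 5, 25)
  qg <- quartileGrouping(x)
  xs <- sort(x)
  # oracle: type-7 order-statistic interpolation
  oracle <- vapply(c(0.25, 0.5, 0.75), function(p) {
    hidx <- (length(x) - 1) * p + 1
    lo <- floor(hidx)
    xs[lo] + (hidx - lo) * (xs[lo + 1] - xs[lo])
  }, numeric(1))
  expect_equal(qg$cutoffs, oracle)
  expect_false(qg$degenerate)
  # eight distinct values: two per quartile
  q8 <- quartileGrouping(1:8)
  expect_equal(unname(table(q8$labels)), rep(2L, 4), ignore_attr = TRUE)
  # constant vector: degenerate, all one group
  qc <- quartileGrouping(rep(7, 10))
  expect_true(qc$degenerate)
  expect_equal(length(unique(qc$labels)), 1)
})

test_that("group comparison reproduces the chi-squared closed forms", {
  tab <- matrix(c(22, 24, 23, 21), 2)  # inducible/non x group A/B
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  # Yates-corrected statistic (the 2 x 2 default)
  gotY <- compareGroups(tab, categorical = TRUE)
  X2y <- sum((abs(tab - E) - 0.5)^2 / E)
  expect_equal(gotY$statistic, X2y)
  expect_equal(gotY$p, 1 - pchisq(X2y, 1))
  # uncorrected Pearson statistic on request
  got <- compareGroups(tab, categorical = TRUE, correct = FALSE)
  X2 <- sum((tab - E)^2 / E)
  expect_equal(got$statistic, X2)
  expect_equal(got$p, 1 - pchisq(X2, 1))
})

test_that("identical groups compare as indistinguishable", {
  x <- c(1, 2, 3, 4, 5)
  got <- suppressWarnings(compareGroups(x, x))
  expect_equal(got$p, 1, tolerance = 0.01)
})

test_that("small-sample rank-sum p matches exact enumeration", {
  x <- c(1.2, 3.4, 2.2, 5.1)
  y <- c(2.8, 4.9, 6.3, 7.0)
  got <- wilcox.test(x, y)  # exact for n = 4 + 4, no ties
  # oracle: enumerate all assignments of ranks to the x-group
  pooled <- c(x, y)
  r <- rank(pooled)
  W <- sum(r[1:4]) - 4 * 5 / 2
  combs <- combn(8, 4)
  Ws <- apply(combs, 2, function(ix) sum(r[ix]) - 10)
  pEnum <- mean(abs(Ws - 8) >= abs(W - 8))  # center = n1 n2 / 2 = 8
  expect_equal(got$p.value, pEnum)
})

test_that("correlation utilities behave on known inputs", {
  b <- seq(5, 25, length.out = 12)
  cnt <- 2 * b + 3
  got <- correlateWithFibrosis(b, cnt)
  expect_equal(got$R, 1)
  set.seed(8)
  perm <- sample(cnt)
  got2 <- correlateWithFibrosis(b, perm)
  expect_lt(abs(got2$R), 0.6)
  # logistic fit reported alongside when the outcome is binary-mixed
  cnt3 <- as.numeric(b > 15) * 3
  got3 <- correlateWithFibrosis(b, cnt3)
  expect_gt(got3$logisticSlope, 0)
})

test_that("a miniature cohort run is bit-reproducible and well-formed", {
  spec <- cohortSpec(nModels = 2, burdenRange = c(0.1, 0.3), sheetSize = 8,
                     nSites = 1, observe = 600, masterSeed = 3L)
  r1 <- runVirtualCohort(spec, verbose = FALSE)
  r2 <- runVirtualCohort(spec, verbose = FALSE)
  expect_identical(r1$table, r2$table)
  expect_identical(r1$records, r2$records)
  expect_equal(nrow(r1$table), 2)
  expect_equal(nrow(r1$records), 2)  # one site per model
  expect_true(all(c("burden", "inducible", "inducingSites",
                    "uniqueMorphologies", "proRDBurden",
                    "depolarizedFraction") %in% names(r1$table)))
  expect_true(all(r1$table$inducible == (r1$table$inducingSites >= 1)))
  # burden sweep covers the requested range
  expect_equal(r1$table$burden, c(10, 30), tolerance = 0.06)
})

test_that("cohort statistics survive a degenerate all-noninducible table", {
  tab <- data.frame(burden = runif(8, 5, 25), inducible = FALSE,
                    inducingSites = 0L, uniqueMorphologies = 0L,
                    invalid = FALSE)
  st <- cohortStats(tab)
  expect_true(all(st$inducibleFractionByQuartile == 0))
  expect_true(is.na(st$burdenInducibleVsNot$p))
})
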