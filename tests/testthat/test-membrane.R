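# cell-scale membrane model: variants, metrics, pacing, integrator accuracy

test_that("remodeling variants carry the correct conductance scalings", {
  b <- makeMembraneModel("baseline")
  expect_true(all(conductanceScalings(b) == 1))
  a <- conductanceScalings(makeMembraneModel("afib"))
  expect_equal(unname(a[c("I_Kur", "I_to", "I_CaL")]), c(0.5, 0.5, 0.3))
  expect_equal(unname(a[c("I_Na", "I_K1")]), c(1, 1))
  f <- conductanceScalings(makeMembraneModel("fibrotic"))
  # fibrotic changes compose with the AFib scalings: net I_CaL 0.3 * 0.5
  expect_equal(unname(f["I_CaL"]), 0.15)
  expect_equal(unname(f["I_Na"]), 0.6)
  expect_equal(unname(f["I_K1"]), 0.5)
  expect_equal(unname(f[c("I_Kur", "I_to")]), c(0.5, 0.5))
  expect_error(makeMembraneModel("walrus"), "unknown membrane model variant")
})

test_that("AP metrics match closed forms on synthetic traces", {
  # trapezoidal pulse: rest -80, one-sample upstroke to +20 at t = 1,
  # plateau 100 ms, linear repolarization over 50 ms
  dt <- 0.05
  tt <- seq(0, 200, by = dt)
  vm <- ifelse(tt < 1, -80,
        ifelse(tt < 101, 20,
        ifelse(tt < 151, 20 - 100 * (tt - 101) / 50, -80)))
  met <- measureAPMetrics(tt, vm, repolLevel = 0.9)
  # analytic: upstroke at t = 1; 90% crossing at V = -70 on the linear
  # ramp => t = 101 + 45 = 146 ms; apd = 145 within one sample
  expect_equal(met@apd, 145, tolerance = 2 * dt / 145)
  expect_equal(met@vRest, -80)
  expect_equal(met@vPeak, 20)
  expect_equal(met@dvdtMax, 100 / dt, tolerance = 0.01)

  # instantaneous upstroke then exponential decay:
  # V = Vrest + (Vpeak - Vrest) exp(-t / tau); APD90 at tau ln(10)
  tau <- 30
  tt2 <- seq(0, 300, by = dt)
  vm2 <- -80 + 100 * exp(-pmax(tt2 - 1, 0) / tau)
  vm2[tt2 <= 1] <- -80 + 100 * tt2[tt2 <= 1]
  met2 <- measureAPMetrics(tt2, vm2, repolLevel = 0.9)
  expect_equal(met2@apd, tau * log(10), tolerance = 0.01)

  # unrepolarized trace is an error
  vm3 <- c(seq(-80, 20, length.out = 50), rep(20, 100))
  expect_error(measureAPMetrics(seq_along(vm3), vm3, 0.9), "unrepolarized")
})

test_that("baseline limit-cycle pacing converges and matches the RK4 oracle", {
  p <- paceToLimitCycle(makeMembraneModel("baseline"), bcl = 500,
                        maxBeats = 200, tol = 0.1)
  expect_true(p$converged)
  expect_lte(p$beats, 200)
  # oracle: classical RK4 at dt = 5 us from the same converged state
  r1 <- cellRun(makeMembraneModel("baseline"), 500, state = p$state,
                stimAmp = p$stimAmp)
  r2 <- cellRun(makeMembraneModel("baseline"), 500, dt = 0.005,
                state = p$state, stimAmp = p$stimAmp, method = "rk4")
  m1 <- measureAPMetrics(r1$time, r1$vm)
  m2 <- measureAPMetrics(r2$time, r2$vm)
  expect_lt(abs(m1@apd - m2@apd), 0.5)
  expect_lt(abs(m1@dvdtMax / m2@dvdtMax - 1), 0.05)
})

test_that("integrator matches the oracle for the remodeled variants too", {
  for (v in c("afib", "fibrotic")) {
    p <- paceToLimitCycle(makeMembraneModel(v), bcl = 500)
    r1 <- cellRun(makeMembraneModel(v), 500, state = p$state,
                  stimAmp = p$stimAmp)
    r2 <- cellRun(makeMembraneModel(v), 500, dt = 0.005, state = p$state,
                  stimAmp = p$stimAmp, method = "rk4")
    m1 <- measureAPMetrics(r1$time, r1$vm)
    m2 <- measureAPMetrics(r2$time, r2$vm)
    expect_lt(abs(m1@apd - m2@apd), 0.5)
    expect_lt(abs(m1@dvdtMax / m2@dvdtMax - 1), 0.05)
  }
})

test_that("tabulated rates reproduce the direct evaluation", {
  m <- makeMembraneModel("baseline")
  r1 <- cellRun(m, 400, useTables = TRUE)
  r2 <- cellRun(m, 400, useTables = FALSE)
  expect_lt(max(abs(r1$vm - r2$vm)), 0.05)
})

test_that("fibrotic resting voltage is depolarized relative to AFib", {
  pa <- paceToLimitCycle(makeMembraneModel("afib"), bcl = 500)
  pf <- paceToLimitCycle(makeMembraneModel("fibrotic"), bcl = 500)
  expect_gt(pf$metrics@vRest, pa$metrics@vRest)
})

test_that("limit-cycle preconditions are enforced", {
  expect_error(paceToLimitCycle(makeMembraneModel("baseline"), maxBeats = 0),
               "maxBeats")
  expect_error(paceToLimitCycle(makeMembraneModel("baseline"), bcl = -5))
})

test_that("smaller convergence tolerance never needs fewer beats", {
  beats <- vapply(c(1, 0.3, 0.1), function(tol)
    paceToLimitCycle(makeMembraneModel("afib"), bcl = 500,
                     tol = tol)$beats, numeric(1))
  expect_true(all(diff(beats) >= 0))
})
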