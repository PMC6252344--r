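# Tracer simulation, steady state and sojourn time.

test_that("no tracer reaches plasma before the delay elapses", {
  for (spec in list(spec_simplified_2p(), spec_full_2p())) {
    tt <- c(0.05, 0.1, 0.2, 0.299, 0.31, 0.5)
    fdp <- simulate_tracer(spec, tt)$fdp
    expect_equal(fdp[tt <= spec$DT3], rep(0, sum(tt <= spec$DT3)))
    expect_true(all(fdp[tt > spec$DT3] > 0))
  }
})

test_that("without recycling log FD_p declines at the plasma exit rate", {
  # fast hepatic turnover so the cascade transient is gone well before the
  # terminal window; recycling switched off by vanishing return coefficients
  lam <- 30 + 32                         # L(6,5) + L(7,5)
  spec <- model_spec("simplified", DT3 = 0.3, L54 = 500, L65 = 30,
                     L56 = 1e-12, L106 = 0.006, L75 = 32, L57 = 1e-12,
                     absorption = 0.8)
  tt <- c(0.5, 0.55, 0.6, 0.65)
  fdp <- simulate_tracer(spec, tt)$fdp
  slopes <- diff(log(fdp)) / diff(tt)
  expect_equal(slopes, rep(-lam, 3), tolerance = 0.01)
  # closed-form cascade solution as an independent oracle (early window,
  # before the vanishingly small recycled fraction becomes visible)
  Tshift <- tt[1:3] - 0.3
  oracle <- 0.8 * 500 / (500 - lam) * (exp(-lam * Tshift) - exp(-500 * Tshift))
  expect_lt(max(abs(fdp[1:3] / oracle - 1)), 1e-5)
})

test_that("matrix-exponential and adaptive-integrator routes agree to 1e-8", {
  tt <- reduced11()
  for (spec in list(spec_simplified_1p(), spec_simplified_2p(),
                    spec_full_2p())) {
    a <- simulate_tracer(spec, tt)$fdp
    b <- simulate_tracer(spec, tt, method = "ode")$fdp
    pos <- a > 1e-12
    expect_lt(max(abs(a[pos] - b[pos]) / a[pos]), 1e-8)
  }
})

test_that("dual-route agreement holds across random valid specifications", {
  set.seed(421)
  tt <- reduced11()
  for (k in 1:8) {
    spec <- random_spec()
    a <- simulate_tracer(spec, tt)$fdp
    b <- simulate_tracer(spec, tt, method = "ode")$fdp
    pos <- a > 1e-12
    expect_lt(max(abs(a[pos] - b[pos]) / a[pos]), 1e-8)
  }
})

test_that("the administered dose is conserved at every time", {
  set.seed(77)
  tt <- sort(c(reduced11(), 0.29, 0.31, 35, 56))
  specs <- c(list(spec_simplified_1p(), spec_simplified_2p(), spec_full_2p()),
             replicate(5, random_spec(), simplify = FALSE))
  for (spec in specs) {
    sim <- simulate_compartments(spec, tt)
    expect_lt(max(abs(sim$total - 1)), 1e-6)
    expect_equal(sim$f5, simulate_tracer(spec, tt)$fdp)
  }
})

test_that("late in the study nearly all of the dose has left the body pools", {
  spec <- spec_simplified_1p()
  sim <- simulate_compartments(spec, c(1, 5000))
  in_pools <- rowSums(sim[, paste0("f", 1:7)])
  expect_lt(in_pools[2], 1e-6)
  expect_equal(sim$disposal[2] + sim$unabsorbed[2], 1, tolerance = 1e-6)
})

test_that("steady state reproduces the published balance arithmetic", {
  ss <- steady_state(spec_simplified_2p(), M5 = 1.02)
  # fast-pool mass from direct balance: 31.9 * 1.02 / 1.67
  expect_equal(ss$masses[["7"]], 31.9 * 1.02 / 1.67, tolerance = 1e-12)
  expect_equal(ss$masses[["7"]], 19.3, tolerance = 0.02)
  # disposal rate L(10,6) * M(6) at the published storage mass
  expect_equal(0.00597 * 538, 3.21, tolerance = 1e-3)
  expect_equal(ss$disposal_rate, 0.00597 * ss$masses[["6"]])
  # balanced state: absorbed input equals disposal
  expect_equal(ss$dietary_input * 0.8, ss$disposal_rate, tolerance = 1e-9)
})

test_that("a one-pool model has an empty fast pool", {
  ss <- steady_state(spec_simplified_1p(), M5 = 1.02)
  expect_identical(ss$masses[["7"]], 0)
  expect_identical(unname(ss$fluxes["(7,5)"]), 0)
  expect_identical(unname(ss$fluxes["(5,7)"]), 0)
})

test_that("steady-state masses are a fixed point of the tracee dynamics", {
  for (spec in list(spec_simplified_2p(), spec_full_2p())) {
    ss <- steady_state(spec, M5 = 1.02)
    m <- ss$masses
    aU <- spec$absorption * ss$dietary_input
    L <- function(nm) if (nm %in% names(spec$L)) spec$L[[nm]] else 0
    d4 <- aU - L("L(5,4)") * m[["4"]]
    d5 <- L("L(5,4)") * m[["4"]] + L("L(5,6)") * m[["6"]] +
      L("L(5,7)") * m[["7"]] -
      (L("L(6,5)") + L("L(7,5)")) * m[["5"]]
    d6 <- L("L(6,5)") * m[["5"]] - (L("L(5,6)") + L("L(10,6)")) * m[["6"]]
    d7 <- L("L(7,5)") * m[["5"]] - L("L(5,7)") * m[["7"]]
    expect_equal(c(d4, d5, d6, d7), rep(0, 4), tolerance = 1e-9)
  }
})

test_that("mean sojourn time to plasma follows the turnover-time sum", {
  expect_equal(mst_rbp(model_spec("simplified", DT3 = 0.3, L54 = 5,
                                  L65 = 30, L56 = 0.05, L106 = 0.006)),
               0.5)
  expect_equal(mst_rbp(spec_full_2p()), 1 / 50 + 1 / 50 + 0.3 + 1 / 5)
})

test_that("invalid inputs are rejected with informative errors", {
  expect_error(model_spec("simplified", DT3 = 0.3, L65 = 30, L56 = 0.05,
                          L106 = 0.006),
               "L\\(5,4\\)")
  expect_error(model_spec("full", DT3 = 0.3, L54 = 5, L65 = 30, L56 = 0.05,
                          L106 = 0.006),
               "L\\(2,1\\)")
  expect_error(model_spec("simplified", DT3 = 0.3, L54 = 5, L65 = 30,
                          L56 = 0.05, L106 = 0.006, L75 = 30),
               "both")
  expect_error(simulate_tracer(spec_simplified_1p(), c(1, 1, 2)),
               "increasing")
  expect_error(simulate_tracer(spec_simplified_1p(), c(-1, 2)), "> 0")
  expect_error(steady_state(spec_simplified_1p(), -1), "M5")
})

test_that("one-pool encoding accepts explicit zeros for the fast pool", {
  spec <- model_spec("simplified", DT3 = 0.3, L54 = 5, L65 = 30.1,
                     L56 = 0.0502, L106 = 0.00597, L75 = 0, L57 = 0)
  expect_identical(spec$n_extravascular, 1L)
  expect_false("L(7,5)" %in% names(spec$L))
})
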