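# Weighted nonlinear least-squares population fitting.

test_that("the nested-model F statistic matches its closed form", {
  ft <- superchild:::.f_test(10, 2, 5, 7, 11)
  expect_equal(ft$F, ((10 - 2) / 2) / (2 / 4))
  expect_equal(ft$F, 8)
  expect_equal(ft$P, pf(8, 2, 4, lower.tail = FALSE))
  # equal fits: F = 0, P = 1
  ft0 <- superchild:::.f_test(3, 3, 5, 7, 11)
  expect_equal(ft0$F, 0)
  expect_equal(ft0$P, 1)
  expect_error(superchild:::.f_test(10, 2, 5, 7, 7), "degrees-of-freedom")
})

test_that("a noiseless single-subject curve is recovered to <0.1%", {
  truth <- spec_simplified_2p()
  truth$DT3 <- 0.18
  truth$L["L(5,4)"] <- 3.3
  curve <- simulate_tracer(truth, reduced11())
  curve$n <- 1L
  set.seed(101)
  fit <- fit_population(curve, fit_config("simplified", pools = "2",
                                          fsd_default = 0.01), M5_pop = 1.02)
  for (nm in names(truth$L))
    expect_equal(unname(fit$estimates[[nm]]), unname(truth$L[[nm]]),
                 tolerance = 1e-3, label = nm)
  expect_equal(unname(fit$estimates[["DT3"]]), truth$DT3, tolerance = 1e-3)
  truth_tbs <- steady_state(truth, 1.02)$masses[["6"]]
  expect_equal(fit$predicted_TBS, truth_tbs, tolerance = 1e-3)
  expect_lt(fit$wss, 1e-8)
})

test_that("the objective is invariant to rescaling all fractional SDs", {
  truth <- spec_simplified_2p()
  curve <- simulate_tracer(truth, reduced11())
  set.seed(11)
  fa <- fit_population(curve, fit_config("simplified", "2", 0.01), 1.02)
  set.seed(11)
  fb <- fit_population(curve, fit_config("simplified", "2", 0.03), 1.02)
  expect_equal(fa$estimates, fb$estimates, tolerance = 1e-3)
  expect_equal(fb$wss, fa$wss / 9, tolerance = 1e-2)
})

test_that("estimates are positive and the optimum is axis-wise minimal", {
  co <- generate_cohort(seed = 31)
  curve <- build_protocol2(co)
  M5p <- gm(co$children$m5_umol)
  set.seed(5)
  fit <- fit_population(curve, fit_config("simplified", "2", 0.01), M5p)
  expect_true(all(fit$estimates > 0))
  # perturbing any single parameter off the optimum cannot reduce the WSS
  wss_at <- function(est) {
    spec <- model_spec("simplified", DT3 = est[["DT3"]], absorption = 0.8,
                       L54 = est[["L(5,4)"]], L65 = est[["L(6,5)"]],
                       L56 = est[["L(5,6)"]], L106 = est[["L(10,6)"]],
                       L75 = est[["L(7,5)"]], L57 = est[["L(5,7)"]])
    pred <- simulate_tracer(spec, curve$time_d)$fdp
    sum(((curve$fdp - pred) / (0.01 * curve$fdp))^2)
  }
  w0 <- wss_at(fit$estimates)
  expect_equal(w0, fit$wss, tolerance = 1e-6)
  for (nm in names(fit$estimates)) {
    for (f in c(0.999, 1.001)) {
      est <- fit$estimates
      est[nm] <- est[nm] * f
      expect_gte(wss_at(est), w0 * (1 - 1e-7))
    }
  }
})

test_that("adding the second pool improves the fit to a mixed composite", {
  co <- generate_cohort(seed = 31)
  curve <- build_protocol2(co)
  M5p <- gm(co$children$m5_umol)
  set.seed(6)
  sel <- suppressWarnings(
    select_pools(curve, fit_config("simplified", "auto", 0.01), M5p))
  expect_lt(sel$decision$wss_2pool, sel$decision$wss_1pool)
  expect_true(sel$decision$rule %in% c("F-test", "parsimony"))
  # validation mode records the proximity rule
  set.seed(6)
  selv <- suppressWarnings(
    select_pools(curve, fit_config("simplified", "auto", 0.01), M5p,
                 known_tbs = gm(co$children$tbs_umol)))
  expect_identical(selv$decision$rule, "TBS-proximity")
  d1 <- abs(selv$fit_1pool$predicted_TBS - gm(co$children$tbs_umol))
  d2 <- abs(selv$fit_2pool$predicted_TBS - gm(co$children$tbs_umol))
  expect_identical(selv$fit$pools_used, if (d2 < d1) 2L else 1L)
})

test_that("the dietary-intake constraint is honoured exactly", {
  co <- generate_cohort(seed = 31)
  curve <- build_protocol2(co)
  M5p <- gm(co$children$m5_umol)
  Up <- gm(co$children$intake_umol_d)
  set.seed(7)
  fit <- suppressWarnings(fit_population(
    curve, fit_config("simplified", "2", 0.05, c("4" = 0.01),
                      constrain_L106_by_intake = Up), M5p))
  expect_equal(fit$dietary_input, Up, tolerance = 1e-9)
  expect_equal(fit$disposal_rate, 0.8 * Up, tolerance = 1e-9)
  expect_false("L(10,6)" %in% names(fit$fractional_sd))
  expect_true("L(10,6)" %in% names(fit$estimates))
})

test_that("population TBS is recovered within 5% on most seeded cohorts", {
  hits <- 0L
  for (s in 1:10) {
    co <- generate_cohort(seed = s)
    curve <- build_protocol2(co)
    M5p <- gm(co$children$m5_umol)
    known <- gm(co$children$tbs_umol)
    set.seed(1000 + s)
    fit <- suppressWarnings(
      select_pools(curve, fit_config("simplified", "auto", 0.01), M5p,
                   known_tbs = known)$fit)
    if (abs(fit$predicted_TBS - known) / known < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("fit summaries compare the population model with known values", {
  co <- generate_cohort(seed = 31)
  curve <- build_protocol2(co)
  M5p <- gm(co$children$m5_umol)
  set.seed(8)
  fit <- fit_population(curve, fit_config("simplified", "2", 0.01), M5p)
  tab <- summarize_fit(fit, co)
  expect_identical(tab$quantity[1:2], c("M(5)", "M(6)"))
  expect_equal(tab$known_gm[tab$quantity == "M(5)"], M5p)
  expect_equal(tab$rel_dev_pct[tab$quantity == "M(5)"], 0, tolerance = 1e-9)
  expect_true(all(c("known_lo", "known_hi", "fitted", "in_range") %in%
                    names(tab)))
})

test_that("underdetermined fits are rejected", {
  truth <- spec_simplified_2p()
  short <- simulate_tracer(truth, c(0.5, 1, 2, 4, 7, 11))
  expect_error(fit_population(short, fit_config("simplified", "2", 0.01),
                              1.02),
               "not enough observations")
})
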