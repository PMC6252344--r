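# Synthetic cohort generation and calibration.

test_that("the high-intake preset yields 50 children with a 23/27 pool split", {
  co <- generate_cohort("high_intake_50", seed = 11)
  ch <- co$children
  expect_identical(nrow(ch), 50L)
  expect_identical(sum(ch$variant_pools == 1L), 23L)
  expect_identical(sum(ch$variant_pools == 2L), 27L)
  expect_true(all(ch$tbs_umol >= 92 & ch$tbs_umol <= 1904))
  expect_true(all(ch$intake_ug_rae >= 658 & ch$intake_ug_rae <= 4862))
  expect_true(all(ch$m5_umol >= 0.345 & ch$m5_umol <= 2.62))
  expect_true(all(ch$l56 >= 0.0156 & ch$l56 <= 0.122))
  expect_true(all(ch$l106 >= 0.00201 & ch$l106 <= 0.210))
  expect_true(all(ch$mst_rbp_d >= 0.364 & ch$mst_rbp_d <= 1.08))
  two <- ch$variant_pools == 2L
  expect_true(all(ch$m7_umol[two] >= 5.24 & ch$m7_umol[two] <= 38.6))
  expect_true(all(ch$m7_umol[!two] == 0))
  expect_equal(ch$intake_umol_d, ch$intake_ug_rae / 286.45)
})

test_that("derived coefficients satisfy the steady-state identities exactly", {
  co <- generate_cohort(seed = 3)
  ch <- co$children
  expect_equal(ch$l106, ch$absorption * ch$intake_umol_d / ch$tbs_umol,
               tolerance = 1e-12)
  expect_equal(ch$l56, ch$l65 * ch$m5_umol / ch$tbs_umol - ch$l106,
               tolerance = 1e-12)
  # feeding each child's spec back through the steady-state solver must
  # reproduce the assigned masses
  for (id in ch$id) {
    ss <- steady_state(child_spec(co, id), ch$m5_umol[ch$id == id])
    expect_equal(ss$masses[["6"]], ch$tbs_umol[ch$id == id],
                 tolerance = 1e-9)
    expect_equal(ss$masses[["7"]], ch$m7_umol[ch$id == id],
                 tolerance = 1e-9)
  }
})

test_that("the assigned TBS distribution sits on the published centre", {
  for (s in c(1, 2, 3)) {
    ch <- generate_cohort(seed = s)$children
    expect_lt(abs(gm(ch$tbs_umol) / 538 - 1), 0.10)
  }
})

test_that("cohort geometric means are calibrated across seeds", {
  targets <- c(m5 = 1.02, tbs = 538, intake = 4.07, l65 = 30.1,
               l56 = 0.0502, l106 = 0.00597, l75 = 31.9, l57 = 1.67,
               mst = 0.522)
  for (s in 1:10) {
    ch <- generate_cohort(seed = s)$children
    two <- ch$variant_pools == 2L
    got <- c(m5 = gm(ch$m5_umol), tbs = gm(ch$tbs_umol),
             intake = gm(ch$intake_umol_d), l65 = gm(ch$l65),
             l56 = gm(ch$l56), l106 = gm(ch$l106),
             l75 = gm(ch$l75[two]), l57 = gm(ch$l57[two]),
             mst = gm(ch$mst_rbp_d))
    expect_true(all(abs(got / targets - 1) < 0.15),
                info = paste("seed", s, "max dev",
                             round(max(abs(got / targets - 1)), 3)))
  }
})

test_that("regeneration with the same seed is bit-identical", {
  expect_identical(generate_cohort(seed = 5), generate_cohort(seed = 5))
  expect_false(identical(generate_cohort(seed = 5)$children,
                         generate_cohort(seed = 6)$children))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  a <- runif(1)
  set.seed(99)
  invisible(generate_cohort(seed = 123))
  expect_identical(runif(1), a)
})

test_that("every child produces signal at the first sampling time", {
  co <- generate_cohort(seed = 7)
  expect_true(all(co$children$dt3_d < 0.25))
  fdp <- cohort_curves(co, 0.25)
  expect_true(all(fdp > 0))
})

test_that("child curves show the expected terminal and mixing behaviour", {
  co <- generate_cohort(seed = 2)
  ch <- co$children
  one <- ch$id[ch$variant_pools == 1L][1]
  two <- ch$id[ch$variant_pools == 2L][1]
  tt <- c(0.5, 1, 2, 4, 40, 48, 56)
  c1 <- child_truth_curve(co, one, tt)
  # terminal slope of a one-pool child approaches -L(10,6)
  slope <- (log(c1$fdp[7]) - log(c1$fdp[5])) / (56 - 40)
  expect_equal(slope, -ch$l106[ch$id == one], tolerance = 0.05)
  # two-pool child: early post-absorptive decline steeper than terminal
  c2 <- child_truth_curve(co, two, tt)
  early <- (log(c2$fdp[3]) - log(c2$fdp[2])) / 1
  late <- (log(c2$fdp[7]) - log(c2$fdp[6])) / 8
  expect_lt(early, late)
})

test_that("the low-intake preset matches its documented ranges", {
  co <- generate_cohort("low_intake_10", seed = 4)
  ch <- co$children
  expect_identical(nrow(ch), 10L)
  expect_true(all(ch$tbs_umol >= 54 & ch$tbs_umol <= 114))
  expect_true(all(ch$intake_ug_rae >= 234 & ch$intake_ug_rae <= 585))
  expect_true(all(ch$l56 > 0))
})

test_that("liver concentration follows the 3%-liver / 80%-storage rule", {
  expect_equal(liver_concentration(538, 12), 0.8 * 538 / (0.03 * 12 * 1000))
  expect_equal(liver_concentration(92, 8.76), 0.28, tolerance = 1e-3)
  expect_identical(liver_concentration(0, 10), 0)
  expect_error(liver_concentration(538, 0), "body_weight")
})

test_that("a seed is required and presets are validated", {
  expect_error(generate_cohort("high_intake_50"), "seed")
  expect_error(generate_cohort("nope", seed = 1))
})
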