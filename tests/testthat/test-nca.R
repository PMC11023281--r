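# Terminal fit, AUC/AUMC integration, extrapolation, and the full NCA chain.

test_that("terminal fit recovers an exact exponential decline", {
  # halving every 4 h from the first sample: slope -ln2/4, r^2 = 1
  p <- conc_profile("X", "oral", 15, c(8, 12, 24), c(10, 5, 0.625))
  f <- fit_terminal_phase(p)
  expect_equal(f$ke, log(2) / 4, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)
  expect_equal(f$points_used, 1:3)  # profile declining from its first sample
})

test_that("terminal fit rejects non-declining data and short profiles", {
  flat <- conc_profile("X", "oral", 15, c(8, 12, 24), c(4, 4, 4))
  expect_error(fit_terminal_phase(flat), class = "pk_nondeclining_terminal")
  short <- conc_profile("X", "oral", 15, c(8, 12), c(10, 5))
  expect_error(fit_terminal_phase(short), class = "pk_too_few_points")
})

test_that("terminal fit on the sparse post-peak oral schedule matches the OLS oracle", {
  # The noise-free one-compartment curve at the oral medians peaks at the 8 h
  # sample; absorption (ka - ke = 0.095/h) is still incomplete at 24 h, so
  # the fitted slope over the only available tail (8/12/24 h) is shallower
  # than ke. The oracle is the explicit normal-equations slope.
  p <- oral_params()
  prof <- simulate_profile(p)
  tt <- c(8, 12, 24)
  expected <- -ols_ref(tt, log(bateman_ref(tt, p$scale, p$ka, p$ke)))["slope"]
  f <- fit_terminal_phase(prof)
  expect_equal(f$ke, unname(expected), tolerance = 1e-10)
  expect_equal(f$ke, 0.09454, tolerance = 1e-3)
  expect_equal(prof$times[f$points_used], tt)
})

test_that("tail selection by adjusted r^2 drops early curved points", {
  # fast absorption: tails from 2 h onward are exactly log-linear, the tail
  # including 1 h is slightly curved, so the exact tail must win
  p <- simulation_params(ka = 5.729, cv = 0)
  prof <- simulate_profile(p, route = "subcutaneous")
  f <- fit_terminal_phase(prof)
  expect_equal(f$ke, p$ke, tolerance = 1e-5)
  expect_gt(min(prof$times[f$points_used]), 1)
})

test_that("half-life follows ln2/ke and rejects non-positive rates", {
  expect_equal(half_life(log(2)), 1)
  expect_equal(half_life(0.125), log(2) / 0.125)
  expect_equal(half_life(0.144), 4.823, tolerance = 0.05 / 4.823)
  expect_error(half_life(0), class = "pk_nonpositive_input")
  expect_error(half_life(-0.1), class = "pk_nonpositive_input")
})

test_that("Cmax/Tmax come from quantifiable samples with earliest-time ties", {
  p <- conc_profile("X", "oral", 15, c(1, 4, 8), c(1, 5, 3))
  expect_equal(cmax_tmax(p), list(cmax = 5, tmax = 4))
  tie <- conc_profile("X", "oral", 15, c(2, 4, 8), c(5, 5, 2))
  expect_equal(cmax_tmax(tie), list(cmax = 5, tmax = 2))
  allblq <- conc_profile("X", "oral", 15, c(1, 2), c(0.1, 0.2))
  expect_error(cmax_tmax(allblq), class = "pk_all_blq")
})

test_that("AUC segments follow the linear-up/log-down rules exactly", {
  flat <- conc_profile("X", "oral", 15, c(0, 1), c(10, 10))
  expect_equal(auc_trapezoid(flat, 1), 10)
  down <- conc_profile("X", "oral", 15, c(1, 2), c(10, 5))
  expect_equal(auc_trapezoid(down, 2), (10 - 5) / log(10 / 5), tolerance = 1e-12)
  # on an exactly exponential segment the log rule equals the analytic integral
  ke <- 0.3
  seg <- exp_profile(c(2, 6), 8, ke)
  expect_equal(auc_trapezoid(seg, 6),
               8 * exp(-2 * ke) / ke - 8 * exp(-6 * ke) / ke,
               tolerance = 1e-12)
})

test_that("trapezoidal AUC converges to the closed-form integral on dense grids", {
  k <- 0.6931
  analytic <- function(tend) 10 / k * (1 - exp(-k * tend))
  p <- exp_profile(seq(0, 12, by = 0.25), 10, k, lloq = 1e-9)
  expect_equal(auc_trapezoid(p, 12), analytic(12), tolerance = 0.002)
  # two refinement levels on a curve with a rising limb (where the linear
  # rule has genuine discretisation error): error shrinks with the grid
  scale <- 30; ka <- 0.22; ke <- 0.125
  bat_auc <- function(tend)
    scale * ka / (ka - ke) * ((1 - exp(-ke * tend)) / ke - (1 - exp(-ka * tend)) / ka)
  mk <- function(dt) {
    tt <- seq(0, 12, by = dt)
    conc_profile("B", "oral", 15, tt, bateman_ref(tt, scale, ka, ke), lloq = 1e-9)
  }
  err <- function(pr) abs(auc_trapezoid(pr, 12) - bat_auc(12))
  expect_lt(err(mk(0.25)), err(mk(0.5)))
})

test_that("pure-log integration variant is available and tighter on decays", {
  k <- 0.4
  p <- exp_profile(seq(1, 9, by = 2), 20, k, lloq = 1e-9)
  analytic <- 20 * (exp(-k) - exp(-9 * k)) / k
  expect_equal(auc_trapezoid(p, 9, method = "log"), analytic, tolerance = 1e-12)
})

test_that("AUC endpoint inside a segment is interpolated by the segment rule", {
  p <- conc_profile("X", "oral", 15, c(0, 2, 4), c(10, 5, 2.5))
  # log-down segment 0->2; concentration at t = 1 is 10 * (5/10)^(1/2)
  c1 <- 10 * sqrt(0.5)
  expect_equal(auc_trapezoid(p, 1), (10 - c1) / log(10 / c1) * 1,
               tolerance = 1e-12)
})

test_that("AUC rejects out-of-range integration limits", {
  p <- conc_profile("X", "oral", 15, c(0, 2, 4), c(10, 5, 2.5))
  expect_error(auc_trapezoid(p, 6), class = "pk_invalid_input")
  expect_error(auc_trapezoid(p, 0), class = "pk_invalid_input")
})

test_that("BLQ samples integrate as zero when leading, are dropped later", {
  p <- conc_profile("X", "oral", 15, c(0, 1, 2, 4), c(0.2, 1, 5, 2))
  # leading 0.2 < LLOQ counts as 0; segments: linear up, linear up, log down
  expected <- (0 + 1) / 2 + (1 + 5) / 2 + (5 - 2) / log(5 / 2) * 2
  expect_equal(auc_trapezoid(p, 4), expected, tolerance = 1e-12)
  tr <- conc_profile("X", "oral", 15, c(1, 2, 3, 5), c(1, 5, 3, 0.5))
  expect_error(auc_trapezoid(tr, 5), class = "pk_invalid_input")  # 0.5 is BLQ
  expect_silent(auc_trapezoid(tr, 3))
})

test_that("moment-curve integration is linear throughout", {
  flat <- conc_profile("X", "oral", 15, c(0, 1), c(10, 10))
  expect_equal(aumc_trapezoid(flat, 1), 5)  # integral of 10 t on [0, 1]
  one <- conc_profile("X", "oral", 15, c(1, 2), c(4, 2))
  expect_equal(aumc_trapezoid(one, 2), (1 * 4 + 2 * 2) / 2)
  k <- 0.6931
  dense <- exp_profile(seq(0, 20, by = 0.05), 10, k, lloq = 1e-12)
  expect_equal(aumc_trapezoid(dense, 20), 10 / k^2 * (1 - (1 + 20 * k) * exp(-20 * k)),
               tolerance = 0.01)
})

test_that("closed-form extrapolation tails follow the printed formulas", {
  expect_equal(auc_extrapolate(2, 0.1), 20)
  expect_equal(auc_extrapolate(0.625, 0.125), 5)
  expect_error(auc_extrapolate(0, 0.1), class = "pk_nonpositive_input")
  expect_equal(aumc_extrapolate(2, 24, 0.1), 2 * 24 / 0.1 + 2 / 0.01)
  expect_equal(aumc_extrapolate(1, 0, 1), 1)   # t_last = 0 leaves c/ke^2
  expect_equal(aumc_extrapolate(1, 1, 1), 2)
  expect_error(aumc_extrapolate(-1, 1, 1), class = "pk_nonpositive_input")
})

test_that("derived indices are simple quotients with unit bookkeeping", {
  expect_equal(mrt(2, 2), 1)
  expect_equal(clearance_over_f(1, 1000), 0.001)     # unit check
  expect_equal(volume_over_f(0.125, 0.125), 1)
  expect_error(mrt(0, 1), class = "pk_nonpositive_input")
  expect_error(clearance_over_f(15, 0), class = "pk_nonpositive_input")
})

test_that("method of residuals is exact on a true two-exponential curve", {
  t <- c(0.5, 1, 2, 4, 8, 12, 24, 36, 48)
  cc <- 30 * (exp(-0.1 * t) - exp(-1.0 * t))
  p <- conc_profile("E", "oral", 15, t, cc, lloq = 1e-9)
  f <- fit_terminal_phase(p)
  suppressWarnings(ka <- ka_method_of_residuals(p, f))
  expect_equal(as.numeric(ka), 1.0, tolerance = 1e-3)
})

test_that("method of residuals rejects uninformative pre-peak data", {
  # exact halving every 4 h over the terminal points 8/12/16 h; the
  # back-extrapolated line is 40 * exp(-ln2/4 * t)
  above <- conc_profile("X", "oral", 15, c(1, 2, 4, 8, 12, 16),
                        c(40, 42, 45, 10, 5, 2.5))
  f <- fit_terminal_phase(above)
  line <- function(t) exp(f$intercept - f$ke * t)
  expect_gt(max(above$conc[1:2] - line(1:2)), 0)  # both points above the line
  expect_error(ka_method_of_residuals(above, f),
               class = "pk_nonpositive_residual")
  # residuals declining slower than ke: apparent ka < ke is rejected
  slow <- conc_profile("X", "oral", 15, c(1, 2, 4, 8, 12, 16),
                       c(line(1) - 20 * exp(-0.05), line(2) - 20 * exp(-0.1),
                         45, 10, 5, 2.5))
  f2 <- fit_terminal_phase(slow)
  expect_error(suppressWarnings(ka_method_of_residuals(slow, f2)),
               class = "pk_unreliable_absorption")
})

test_that("full NCA satisfies its internal identities to 1e-9", {
  profs <- simulate_study(4, simulation_params(cv = 0.1), seed = 7)
  for (prof in profs) {
    r <- suppressWarnings(run_nca(prof))
    expect_equal(r$t_half * r$ke, log(2), tolerance = 1e-9)
    expect_equal(r$vz_f * r$ke, r$cl_f, tolerance = 1e-9)
    expect_equal(r$mrt * r$auc_0_inf, r$aumc_0_inf, tolerance = 1e-9)
    expect_equal(r$auc_ratio, r$auc_0_t / r$auc_0_inf, tolerance = 1e-12)
    expect_gt(r$auc_ratio, 0); expect_lte(r$auc_ratio, 1)
  }
})

test_that("NCA on noise-free curves recovers the generating kinetics", {
  # fast absorption: the post-peak samples are mono-exponential to machine
  # precision, so ke is recovered exactly and the AUC extrapolation is tight
  psc <- simulation_params(ka = 5.729, cv = 0)
  rsc <- suppressWarnings(run_nca(simulate_profile(psc, route = "subcutaneous")))
  expect_equal(rsc$ke, psc$ke, tolerance = 1e-5)
  # the 0-0.25 h sliver before the first sample and the steep rising limb
  # cost ~1.6% of the analytic exposure here
  expect_equal(rsc$auc_0_inf, bateman_auc_inf(psc$scale, psc$ka, psc$ke),
               tolerance = 0.03)
  # slow oral absorption: the biased terminal slope and the trapezoid errors
  # cancel to first order; total exposure is still recovered within 3%
  p <- oral_params()
  r <- suppressWarnings(run_nca(simulate_profile(p)))
  expect_equal(r$auc_0_inf, p$scale / p$ke, tolerance = 0.03)
  # sampled Tmax is the schedule time nearest the analytic peak at 5.95 h
  expect_true(r$tmax %in% c(4, 8))
})

test_that("NCA is invariant to input row permutation", {
  p <- simulation_params(cv = 0.1)
  base <- simulate_profile(p, seed = 3)
  ord <- c(5, 1, 8, 3, 7, 2, 4, 6)
  perm <- conc_profile(base$subject_id, base$route, base$dose,
                       base$times[ord], base$conc[ord], lloq = base$lloq)
  a <- suppressWarnings(run_nca(base))
  b <- suppressWarnings(run_nca(perm))
  expect_equal(a, b)
})

test_that("stage labels are attached to propagated NCA errors", {
  p <- conc_profile("X", "oral", 15, c(1, 2), c(10, 5))
  err <- tryCatch(run_nca(p), error = identity)
  expect_s3_class(err, "pk_too_few_points")
  expect_match(conditionMessage(err), "terminal fit", fixed = TRUE)
})
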