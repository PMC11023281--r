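# Substrate-depletion slope, in-vitro half-life and intrinsic clearance.

test_that("depletion slope is exact on exact halving", {
  a <- depletion_assay("possum", c(0, 30, 60), c(100, 50, 25))
  k <- depletion_slope(a)
  expect_equal(as.numeric(k), -log(2) / 30, tolerance = 1e-12)
  expect_equal(attr(k, "p_decline"), 0)  # perfect fit
})

test_that("flat time courses yield a no-depletion result downstream", {
  a <- depletion_assay("cat", c(0, 30, 60), c(100, 100, 100))
  k <- depletion_slope(a)
  expect_equal(as.numeric(k), 0)
  r <- analyze_depletion(a)
  expect_false(r$depleted)
  expect_true(is.na(r$t_half_vitro)); expect_true(is.na(r$clint))
  expect_true(is.na(invitro_half_life(0)))
})

test_that("slope recovery from noisy first-order depletion", {
  a <- simulate_depletion(0.00315, times = c(0, 30, 60), cv = 0.02, seed = 11)
  k <- as.numeric(depletion_slope(a))
  # the slope must be the OLS slope of the realised series
  expect_equal(k, unname(ols_ref(a$times, log(a$remaining))["slope"]),
               tolerance = 1e-12)
  # and lie within 3 standard errors of the generating rate (2% noise over
  # three points leaves ~15% sampling CV on the slope)
  se <- sqrt(log(1 + 0.02^2)) / sqrt(sum((a$times - mean(a$times))^2))
  expect_lt(abs(k - (-0.00315)), 3 * se)
})

test_that("depletion slope is invariant to rescaling the series", {
  # concentrations versus percent: the intercept absorbs the scale
  conc <- c(2.5, 1.9, 1.4)
  a_pct <- depletion_assay("koala", c(0, 30, 60), conc / conc[1] * 100)
  a_conc <- depletion_assay("koala", c(0, 30, 60), conc,
                            values_are = "concentration")
  expect_equal(as.numeric(depletion_slope(a_pct)),
               as.numeric(depletion_slope(a_conc)), tolerance = 1e-12)
})

test_that("in-vitro half-life and Clint follow the 0.693 formulas", {
  expect_equal(invitro_half_life(-0.693), 1)
  expect_equal(invitro_half_life(-log(2) / 30), 0.693 / (log(2) / 30))
  expect_equal(invitro_half_life(-0.00315), 0.693 / 0.00315)  # ~220 min
  expect_equal(intrinsic_clearance(693, 1000, 1), 1)
  expect_equal(intrinsic_clearance(220.05, 1000, 0.5), 6.30, tolerance = 1e-3)
  expect_equal(intrinsic_clearance(470.46, 1000, 0.5), 2.95, tolerance = 2e-3)
  expect_error(intrinsic_clearance(0, 1000, 0.5), class = "pk_nonpositive_input")
  # exact-log2 variant
  expect_equal(invitro_half_life(-log(2), exact_log2 = TRUE), 1)
})

test_that("Clint x t_half equals 0.693 V/m identically", {
  set.seed(4)
  for (i in 1:25) {
    th <- runif(1, 10, 2000); v <- runif(1, 100, 5000); m <- runif(1, 0.1, 5)
    expect_equal(intrinsic_clearance(th, v, m) * th, 0.693 * v / m,
                 tolerance = 1e-12)
  }
})

test_that("species summaries average per-replicate values", {
  # two replicates with exact half-lives 200 and 240 min
  mk <- function(th, rep) {
    k <- 0.693 / th
    depletion_assay("possum", c(0, 30, 60), 100 * exp(-k * c(0, 30, 60)),
                    replicate = rep)
  }
  s <- summarize_assays(list(mk(200, 1), mk(240, 2)))
  expect_equal(s$mean_t_half, 220)
  expect_equal(s$sd_t_half, sd(c(200, 240)))
  expect_true(s$depleted)
  # clint duplicates 6.0 and 6.8 -> mean 6.4, sd 0.566
  th_for <- function(clint, v = 1000, m = 0.5) 0.693 * v / m / clint
  s2 <- summarize_assays(list(mk2 <- {
    k <- 0.693 / th_for(6.0)
    depletion_assay("koala", c(0, 30, 60), 100 * exp(-k * c(0, 30, 60)), replicate = 1)
  }, {
    k <- 0.693 / th_for(6.8)
    depletion_assay("koala", c(0, 30, 60), 100 * exp(-k * c(0, 30, 60)), replicate = 2)
  }))
  expect_equal(s2$mean_clint, 6.4, tolerance = 1e-9)
  expect_equal(s2$sd_clint, sd(c(6.0, 6.8)), tolerance = 1e-9)
})

test_that("a non-depleting replicate marks the species as no depletion", {
  flat <- depletion_assay("cat", c(0, 30, 60), c(100, 100.5, 99.8))
  s <- summarize_assays(list(flat))
  expect_false(s$depleted)
  expect_true(is.na(s$mean_t_half))
  expect_error(summarize_assays(list()), class = "pk_empty_group")
})

test_that("assay construction validates its anchors", {
  expect_error(depletion_assay("x", c(10, 30), c(100, 50)),
               class = "pk_invalid_input")        # no t = 0
  expect_error(depletion_assay("x", c(0, 30), c(100, 0)),
               class = "pk_nonpositive_input")    # zero remaining
  expect_error(depletion_assay("x", c(0, 30), c(90, 50)),
               class = "pk_invalid_input")        # t = 0 not 100%
  a <- depletion_assay("x", c(0, 30), c(2.5, 1.4), values_are = "concentration")
  expect_equal(a$remaining[1], 100)
  expect_equal(a$protein_mg, 0.5)                 # 0.5 mg/mL x 1 mL
  expect_error(depletion_slope(a), class = "pk_too_few_points")
})
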