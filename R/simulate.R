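# Synthetic study-like data: one-compartment oral/s.c. profiles on the
# study sampling schedule with LLOQ censoring, multi-dose superposition,
# in-vitro depletion curves, and paired analyte panels.

#' Simulation parameters for study-like profiles
#'
#' Defaults emulate the single-dose oral study conditions: absorption and
#' elimination rate constants at the reported oral medians (ka = 0.22 /h,
#' ke = 0.125 /h), 10% lognormal residual error, the study sampling schedule
#' (0.25, 0.5, 1, 2, 4, 8, 12, 24 h), LLOQ censoring at 0.625 ug/mL, and the
#' lumped coefficient `scale` (= F*D/V, ug/mL) chosen so the analytic
#' single-dose peak is 17 ug/mL, the reported Cmax scale.
#'
#' @param scale lumped coefficient F*D/V in ug/mL; `NULL` (default) solves
#'   for the value giving `cmax_target` at the analytic peak.
#' @param ka,ke absorption/elimination rate constants in 1/h, `ka != ke`.
#' @param cv residual lognormal coefficient of variation (fraction).
#' @param schedule sampling times in hours.
#' @param lloq lower limit of quantification in ug/mL.
#' @param cmax_target analytic peak used to solve for `scale` when `scale`
#'   is `NULL`.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(scale = NULL, ka = 0.22, ke = 0.125, cv = 0.10,
                              schedule = c(0.25, 0.5, 1, 2, 4, 8, 12, 24),
                              lloq = 0.625, cmax_target = 17) {
  check_positive(ka, "ka"); check_positive(ke, "ke")
  check_nonnegative(cv, "cv", "pk_invalid_input")
  check_positive(lloq, "lloq", "pk_invalid_input")
  if (ka == ke) pk_stop("ka = ke is degenerate", "pk_degenerate_model")
  if (any(schedule < 0) || is.unsorted(schedule, strictly = TRUE))
    pk_stop("`schedule` must be strictly increasing and >= 0", "pk_invalid_input")
  if (is.null(scale)) {
    tpk <- log(ka / ke) / (ka - ke)
    peak_unit <- ka / (ka - ke) * (exp(-ke * tpk) - exp(-ka * tpk))
    scale <- cmax_target / peak_unit
  }
  check_positive(scale, "scale", "pk_invalid_input")
  structure(list(scale = scale, ka = ka, ke = ke, cv = cv,
                 schedule = schedule, lloq = lloq),
            class = "simulation_params")
}

#' One-compartment first-order-absorption (Bateman) curve
#'
#' `scale * ka/(ka - ke) * (exp(-ke t) - exp(-ka t))`: zero at t = 0, peak at
#' `log(ka/ke)/(ka - ke)`, terminal decline at rate `ke` (for `ka > ke`).
#'
#' @param t times in hours (vectorised, >= 0).
#' @param p a [simulation_params()] object.
#' @return Concentrations in ug/mL.
#' @export
bateman <- function(t, p) {
  stopifnot(inherits(p, "simulation_params"))
  if (any(t < 0)) pk_stop("`t` must be >= 0", "pk_invalid_input")
  p$scale * p$ka / (p$ka - p$ke) * (exp(-p$ke * t) - exp(-p$ka * t))
}

#' Simulate one concentration-time profile
#'
#' The noise-free Bateman curve at the schedule times multiplied by lognormal
#' noise `exp(N(0, sigma))` with `sigma = sqrt(log(1 + cv^2))` (so the
#' multiplicative CV is exactly `cv`). Values below the LLOQ are flagged BLQ.
#' Deterministic given `seed`; the caller's RNG state is untouched.
#'
#' @param p a [simulation_params()].
#' @param subject_id subject label.
#' @param route administration route recorded on the profile.
#' @param dose dose in mg/kg recorded on the profile.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return A [conc_profile()].
#' @export
simulate_profile <- function(p, subject_id = "S1", route = "oral", dose = 15,
                             seed = NULL) {
  stopifnot(inherits(p, "simulation_params"))
  with_seed(seed, {
    mu <- bateman(p$schedule, p)
    sigma <- sqrt(log(1 + p$cv^2))
    conc <- mu * exp(stats::rnorm(length(mu), 0, sigma))
    conc_profile(subject_id, route, dose, p$schedule, conc, lloq = p$lloq)
  })
}

#' Simulate a multi-subject study
#'
#' Per-subject random effects (lognormal, `bsv_cv` CV on `ka`, `ke` and
#' `scale`) on top of [simulate_profile()]. Each subject draws from its own
#' seed (`seed + subject index`), so adding subjects never perturbs earlier
#' subjects' data. With a [dose_regimen()] of several doses, profiles are
#' built by superposition and sampled at the first-day schedule plus the
#' trough/terminal times 48, 72 and 78 h, emulating the repeat-dose arm.
#'
#' @param n_subjects number of subjects (default 8, the study size).
#' @param p a [simulation_params()].
#' @param regimen a [dose_regimen()]; default is a single dose at time 0.
#' @param seed integer master seed.
#' @param bsv_cv between-subject lognormal CV (default 0.20).
#' @return A list of [conc_profile()] objects.
#' @export
simulate_study <- function(n_subjects = 8, p = simulation_params(),
                           regimen = NULL, seed = 1L, bsv_cv = 0.20) {
  stopifnot(inherits(p, "simulation_params"))
  if (is.null(regimen)) regimen <- dose_regimen(15, "oral", dose_times = 0)
  stopifnot(inherits(regimen, "dose_regimen"))
  multi <- length(regimen$dose_times) > 1L
  times <- if (multi) sort(unique(c(p$schedule, 48, 72, 78))) else p$schedule

  lapply(seq_len(n_subjects), function(i) {
    with_seed(seed + i, {
      sdev <- sqrt(log(1 + bsv_cv^2))
      eta <- exp(stats::rnorm(3, 0, sdev))
      ka_i <- p$ka * eta[1]; ke_i <- p$ke * eta[2]; scale_i <- p$scale * eta[3]
      if (ka_i == ke_i) ka_i <- ka_i * (1 + 1e-8)
      mu <- superpose(regimen, ka_i, ke_i, scale_i, times)
      sigma <- sqrt(log(1 + p$cv^2))
      conc <- mu * exp(stats::rnorm(length(mu), 0, sigma))
      keep <- times > 0 | conc > 0     # drop the degenerate t = 0 zero sample
      conc_profile(sprintf("S%d", i), regimen$route, regimen$dose,
                   times[keep], conc[keep], lloq = p$lloq)
    })
  })
}

#' Simulate an in-vitro depletion time course
#'
#' First-order substrate depletion `100 * exp(-k t)` with multiplicative
#' lognormal noise; the t = 0 anchor is fixed at exactly 100%.
#'
#' @param k depletion rate in 1/min (>= 0; 0 gives a flat no-depletion
#'   fixture).
#' @param times sampling times in minutes, starting at 0 (default the assay
#'   design 0/30/60 min).
#' @param cv lognormal noise CV (default 0.02).
#' @param seed integer seed.
#' @param species species label.
#' @param ... passed to [depletion_assay()] (protein and volume metadata).
#' @return A [depletion_assay()].
#' @export
simulate_depletion <- function(k, times = c(0, 30, 60), cv = 0.02,
                               seed = NULL, species = "simulated", ...) {
  check_nonnegative(k, "k", "pk_invalid_input")
  with_seed(seed, {
    rem <- 100 * exp(-k * times)
    if (cv > 0) {
      sigma <- sqrt(log(1 + cv^2))
      rem <- rem * exp(stats::rnorm(length(rem), 0, sigma))
    }
    rem[1] <- 100
    depletion_assay(species, times, rem, ...)
  })
}

#' Simulate a paired pre/post analyte panel
#'
#' Pre-treatment values from a normal baseline; post = pre + `shift` + noise.
#'
#' @param n number of subjects (default 6, the repeat-dose arm size).
#' @param shift systematic post-pre shift (analyte units).
#' @param noise_sd SD of the added noise.
#' @param seed integer seed.
#' @param baseline_mean,baseline_sd baseline distribution parameters.
#' @param analyte analyte label.
#' @return A data.frame with columns `analyte`, `subject_id`, `value_pre`,
#'   `value_post` (one row per subject), suitable for
#'   [paired_panel_tests()].
#' @export
simulate_paired_panel <- function(n = 6, shift = 4, noise_sd = 0.5,
                                  seed = NULL, baseline_mean = 50,
                                  baseline_sd = 5, analyte = "ALT") {
  if (n < 2) pk_stop("`n` must be >= 2", "pk_invalid_input")
  with_seed(seed, {
    pre <- stats::rnorm(n, baseline_mean, baseline_sd)
    post <- pre + shift + stats::rnorm(n, 0, noise_sd)
    data.frame(analyte = analyte, subject_id = sprintf("S%d", seq_len(n)),
               value_pre = pre, value_post = post, stringsAsFactors = FALSE)
  })
}
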