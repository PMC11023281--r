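# Non-compartmental analysis: terminal slope, half-life, Cmax/Tmax,
# linear-up/log-down trapezoidal AUC/AUMC, extrapolation to infinity, MRT,
# Cl/F, Vz/F, and the method of residuals for ka.

.ols <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  fitted <- my + slope * (x - mx)
  rss <- sum((y - fitted)^2)
  tss <- sum((y - my)^2)
  r2 <- if (tss == 0) 0 else max(0, min(1, 1 - rss / tss))
  list(slope = slope, intercept = my - slope * mx, r_squared = r2, n = n)
}

#' Fit the terminal elimination phase of a profile
#'
#' Ordinary least squares on (time, log concentration) over a contiguous tail
#' of quantifiable points, returning the elimination rate constant `ke` as the
#' negative slope. All contiguous tails of at least `min_points` quantifiable
#' points strictly after Tmax are evaluated and the tail with the largest
#' adjusted r-squared wins; ties go to the longer tail. When fewer than
#' `min_points` quantifiable points lie strictly after Tmax (sparse post-peak
#' schedules, or profiles already declining at the first sample), the Tmax
#' point itself anchors the single candidate tail.
#'
#' @param profile a [conc_profile()].
#' @param min_points minimum points in a terminal fit (default 3).
#' @return An object of class `terminal_fit` with elements `ke` (1/h),
#'   `intercept` (log ug/mL), `points_used` (indices into the profile),
#'   `r_squared`, `adj_r_squared`, and `n_points`.
#' @export
fit_terminal_phase <- function(profile, min_points = 3L) {
  stopifnot(inherits(profile, "conc_profile"))
  if (min_points < 3L)
    pk_stop("`min_points` must be at least 3", "pk_invalid_input")
  q <- quantifiable_points(profile, min_points)
  imax <- which.max(q$conc)  # first maximum = earliest Tmax
  post <- which(q$times > q$times[imax])

  if (length(post) >= min_points) {
    starts <- post[seq_len(length(post) - min_points + 1L)]
    candidates <- lapply(starts, function(s) seq(s, length(q$times)))
  } else if (length(post) + 1L >= min_points) {
    candidates <- list(seq(imax, length(q$times)))
  } else {
    pk_stop(sprintf(
      "only %d quantifiable points at or after Tmax; %d required for a terminal fit",
      length(post) + 1L, min_points), "pk_too_few_points")
  }

  fits <- lapply(candidates, function(sel) {
    cc <- q$conc[sel]
    if (any(cc <= 0)) return(NULL)
    f <- .ols(q$times[sel], log(cc))
    if (!is.finite(f$slope) || f$slope >= 0) return(NULL)
    f$adj_r_squared <- 1 - (1 - f$r_squared) * (f$n - 1) / (f$n - 2)
    f$sel <- sel
    f
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0L)
    pk_stop("no declining terminal phase: every candidate tail has slope >= 0",
            "pk_nondeclining_terminal")

  adj <- vapply(fits, `[[`, numeric(1), "adj_r_squared")
  npt <- vapply(fits, `[[`, numeric(1), "n")
  near_best <- which(adj >= max(adj) - 1e-9)
  best <- near_best[which.max(npt[near_best])]
  f <- fits[[best]]

  structure(
    list(ke = -f$slope, intercept = f$intercept,
         points_used = q$idx[f$sel], r_squared = f$r_squared,
         adj_r_squared = f$adj_r_squared, n_points = f$n),
    class = "terminal_fit")
}

#' @export
print.terminal_fit <- function(x, ...) {
  cat(sprintf("<terminal_fit> ke = %.5g /h (t1/2 %.4g h), %d points, r^2 = %.4f\n",
              x$ke, log(2) / x$ke, x$n_points, x$r_squared))
  invisible(x)
}

#' Elimination half-life from a rate constant
#'
#' @param ke first-order elimination rate constant in 1/h; must be positive.
#' @return Half-life ln(2)/ke in hours.
#' @export
half_life <- function(ke) {
  check_positive(ke, "ke")
  log(2) / ke
}

#' Observed maximal concentration and its time
#'
#' Taken directly from the quantifiable observations; ties in concentration
#' are broken by the earliest time.
#'
#' @param profile a [conc_profile()].
#' @return A list with elements `cmax` (ug/mL) and `tmax` (h).
#' @export
cmax_tmax <- function(profile) {
  stopifnot(inherits(profile, "conc_profile"))
  q <- quantifiable_points(profile, 1L)
  i <- which.max(q$conc)
  list(cmax = q$conc[i], tmax = q$times[i])
}

# Usable integration series: leading BLQ samples contribute zero
# concentration, BLQ samples after the first quantifiable one are dropped,
# and the series ends at the last quantifiable point.
.integration_series <- function(profile) {
  qi <- quantifiable_idx(profile)
  if (length(qi) == 0L) pk_stop("all samples are below the LLOQ", "pk_all_blq")
  first_q <- qi[1L]; last_q <- qi[length(qi)]
  lead <- seq_len(first_q - 1L)          # leading BLQ -> zero
  keep <- qi                             # embedded/trailing BLQ dropped
  times <- c(profile$times[lead], profile$times[keep])
  conc <- c(rep(0, length(lead)), profile$conc[keep])
  list(times = times, conc = conc, tlast = profile$times[last_q],
       clast = profile$conc[last_q])
}

.seg_auc <- function(t1, t2, c1, c2, method) {
  dt <- t2 - t1
  use_log <- switch(method,
    "linear-up/log-down" = c1 > 0 && c2 > 0 && c2 < c1,
    "log" = c1 > 0 && c2 > 0 && c1 != c2)
  if (use_log) (c1 - c2) / log(c1 / c2) * dt else (c1 + c2) / 2 * dt
}

# Concentration at time t inside [t1, t2], by the rule the segment uses.
.seg_interp <- function(t, t1, t2, c1, c2, method) {
  frac <- (t - t1) / (t2 - t1)
  use_log <- switch(method,
    "linear-up/log-down" = c1 > 0 && c2 > 0 && c2 < c1,
    "log" = c1 > 0 && c2 > 0 && c1 != c2,
    "linear" = FALSE)
  if (use_log) c1 * (c2 / c1)^frac else c1 + (c2 - c1) * frac
}

.integrate_profile <- function(profile, t_end, kind = c("conc", "moment"),
                               method = c("linear-up/log-down", "log")) {
  kind <- kind[1]; method <- match.arg(method)
  s <- .integration_series(profile)
  if (length(s$times) < 2L)
    pk_stop("at least 2 usable points are required for integration",
            "pk_too_few_points")
  check_positive(t_end, "t_end", "pk_invalid_input")
  if (t_end > s$tlast + 1e-9)
    pk_stop(sprintf("t_end = %g h is beyond the last quantifiable observation (%g h)",
                    t_end, s$tlast), "pk_invalid_input")
  if (t_end <= s$times[1L])
    pk_stop(sprintf("t_end = %g h does not exceed the first usable observation",
                    t_end), "pk_invalid_input")

  keep <- s$times <= t_end + 1e-12
  times <- s$times[keep]; conc <- s$conc[keep]
  if (max(times) < t_end) {           # cut the bracketing segment at t_end
    j <- sum(keep)                    # last kept index in the full series
    ct <- .seg_interp(t_end, s$times[j], s$times[j + 1L],
                      s$conc[j], s$conc[j + 1L],
                      if (kind == "moment") "linear" else method)
    times <- c(times, t_end); conc <- c(conc, ct)
  }

  n <- length(times)
  total <- 0
  for (i in seq_len(n - 1L)) {
    total <- total + if (kind == "moment") {
      # linear trapezoid on the first-moment curve t*C(t)
      (times[i] * conc[i] + times[i + 1L] * conc[i + 1L]) / 2 *
        (times[i + 1L] - times[i])
    } else {
      .seg_auc(times[i], times[i + 1L], conc[i], conc[i + 1L], method)
    }
  }
  list(value = total, t_end = t_end, c_end = conc[n])
}

#' Trapezoidal area under the concentration-time curve
#'
#' Piecewise integral of the observed profile up to `t_end`. The default
#' `"linear-up/log-down"` rule uses the linear trapezoid on non-decreasing
#' segments (and on any segment touching zero) and the logarithmic trapezoid
#' `(C1 - C2)/log(C1/C2) * dt` on strictly decreasing positive segments; the
#' `"log"` variant applies the logarithmic rule to every positive unequal
#' segment. If `t_end` falls inside a segment, the endpoint concentration is
#' interpolated by the same rule that segment uses.
#'
#' @param profile a [conc_profile()].
#' @param t_end upper integration limit in hours; at most the last
#'   quantifiable observation time.
#' @param method integration rule, see Details.
#' @return AUC from 0 to `t_end` in ug*h/mL.
#' @export
auc_trapezoid <- function(profile, t_end,
                          method = c("linear-up/log-down", "log")) {
  stopifnot(inherits(profile, "conc_profile"))
  .integrate_profile(profile, t_end, "conc", match.arg(method))$value
}

#' Trapezoidal area under the first-moment curve
#'
#' Linear trapezoidal integration of t*C(t) up to `t_end` (the logarithmic
#' rule is ill-defined on the moment curve at t = 0, so the moment integral is
#' always linear).
#'
#' @inheritParams auc_trapezoid
#' @return AUMC from 0 to `t_end` in ug*h^2/mL.
#' @export
aumc_trapezoid <- function(profile, t_end) {
  stopifnot(inherits(profile, "conc_profile"))
  .integrate_profile(profile, t_end, "moment")$value
}

#' Extrapolated AUC tail beyond the last observation
#'
#' @param c_last last quantifiable concentration (ug/mL, > 0).
#' @param ke terminal elimination rate constant (1/h, > 0).
#' @return `c_last / ke`, the AUC from the last observation to infinity.
#' @export
auc_extrapolate <- function(c_last, ke) {
  check_positive(c_last, "c_last")
  check_positive(ke, "ke")
  c_last / ke
}

#' Extrapolated AUMC tail beyond the last observation
#'
#' @inheritParams auc_extrapolate
#' @param t_last time of the last quantifiable observation (h, >= 0).
#' @return `(c_last * t_last / ke) + (c_last / ke^2)` in ug*h^2/mL.
#' @export
aumc_extrapolate <- function(c_last, t_last, ke) {
  check_positive(c_last, "c_last")
  check_nonnegative(t_last, "t_last")
  check_positive(ke, "ke")
  c_last * t_last / ke + c_last / ke^2
}

#' Mean residence time
#'
#' @param aumc_0_inf area under the first-moment curve to infinity.
#' @param auc_0_inf area under the curve to infinity.
#' @return `aumc_0_inf / auc_0_inf` in hours.
#' @export
mrt <- function(aumc_0_inf, auc_0_inf) {
  check_positive(aumc_0_inf, "aumc_0_inf")
  check_positive(auc_0_inf, "auc_0_inf")
  aumc_0_inf / auc_0_inf
}

#' Apparent clearance scaled by bioavailability
#'
#' Dose (mg/kg, converted internally to ug/kg) divided by AUC to infinity,
#' returned in L/(kg*h) so that a 15 mg/kg dose over 128.87 ug*h/mL gives
#' 0.116 L/kg/h.
#'
#' @param dose dose in mg per kg body weight.
#' @param auc_0_inf AUC to infinity in ug*h/mL.
#' @return Cl/F in L/(kg*h).
#' @export
clearance_over_f <- function(dose, auc_0_inf) {
  check_positive(dose, "dose")
  check_positive(auc_0_inf, "auc_0_inf")
  dose_ug_per_kg <- dose * 1000
  ml_per_kg_h <- dose_ug_per_kg / auc_0_inf
  ml_per_kg_h / 1000
}

#' Apparent volume of distribution scaled by bioavailability
#'
#' @param cl_f apparent clearance in L/(kg*h).
#' @param ke terminal elimination rate constant in 1/h.
#' @return Vz/F = Cl/F / ke in L/kg.
#' @export
volume_over_f <- function(cl_f, ke) {
  check_positive(cl_f, "cl_f")
  check_positive(ke, "ke")
  cl_f / ke
}

#' Absorption rate constant by the method of residuals
#'
#' The terminal line is back-extrapolated to the pre-peak times; the residual
#' `r(t) = exp(intercept - ke t) - C(t)` of each quantifiable pre-peak
#' observation is formed, and the negative slope of `log r(t)` versus `t` is
#' returned as `ka`. Pre-peak points whose observation lies on or above the
#' back-extrapolated line (non-positive residual) carry no absorption
#' information and are dropped with a warning; at least `min_points` positive
#' residuals are required. A fit with `ka <= ke` is rejected (flip-flop
#' kinetics are not modelled).
#'
#' @param profile a [conc_profile()].
#' @param terminal a [fit_terminal_phase()] result for the same profile.
#' @param min_points minimum positive-residual points (default 2, the most a
#'   fast-absorbing subcutaneous profile can offer; a warning is attached when
#'   only 2 are used).
#' @return `ka` in 1/h, with attributes `n_points` and `r_squared`.
#' @export
ka_method_of_residuals <- function(profile, terminal, min_points = 2L) {
  stopifnot(inherits(profile, "conc_profile"), inherits(terminal, "terminal_fit"))
  q <- quantifiable_points(profile, 1L)
  imax <- which.max(q$conc)
  pre <- which(q$times < q$times[imax])
  if (length(pre) < min_points)
    pk_stop(sprintf("only %d quantifiable pre-peak points; %d required",
                    length(pre), min_points), "pk_too_few_points")
  t_pre <- q$times[pre]
  res <- exp(terminal$intercept - terminal$ke * t_pre) - q$conc[pre]
  pos <- res > 0
  if (sum(pos) < min_points)
    pk_stop("fewer than the required pre-peak points lie below the back-extrapolated terminal line (non-positive residuals)",
            "pk_nonpositive_residual")
  if (any(!pos))
    pk_warn(sprintf("%d pre-peak point(s) with non-positive residuals dropped from the absorption fit",
                    sum(!pos)), "pk_dropped_residuals")
  f <- .ols(t_pre[pos], log(res[pos]))
  ka <- -f$slope
  if (!is.finite(ka) || ka <= terminal$ke)
    pk_stop(sprintf("residual fit gives ka = %.4g <= ke = %.4g; absorption estimate unreliable",
                    ka, terminal$ke), "pk_unreliable_absorption")
  if (sum(pos) == 2L)
    pk_warn("absorption fit uses only 2 residual points", "pk_sparse_residuals")
  structure(ka, n_points = sum(pos), r_squared = f$r_squared)
}

#' Full non-compartmental analysis of one profile
#'
#' Orchestrates [cmax_tmax()], [fit_terminal_phase()], the trapezoidal
#' integrals, the extrapolation formulas, and [ka_method_of_residuals()] into
#' the standard set of non-compartmental indices. AUC and AUMC run from 0 to
#' the earlier of `t_end` and the last quantifiable observation, then the
#' closed-form tails `Clast/ke` and `(Clast tlast/ke) + Clast/ke^2` are added
#' to reach infinity. A failed absorption fit (too few pre-peak points,
#' non-positive residuals, or `ka <= ke`) yields `ka = NA` with a warning
#' rather than aborting the analysis; every other stage error propagates with
#' a stage label.
#'
#' @param profile a [conc_profile()].
#' @param t_end upper limit of the observed-data integral in hours
#'   (default 24, the single-dose observation window of the study design).
#' @param method AUC integration rule, see [auc_trapezoid()].
#' @param min_points minimum points in the terminal fit.
#' @return An object of class `nca_result`; see Details for fields.
#' @export
run_nca <- function(profile, t_end = 24,
                    method = c("linear-up/log-down", "log"), min_points = 3L) {
  stopifnot(inherits(profile, "conc_profile"))
  method <- match.arg(method)

  ct <- with_stage("cmax/tmax", cmax_tmax(profile))
  fit <- with_stage("terminal fit", fit_terminal_phase(profile, min_points))
  t_half <- half_life(fit$ke)

  s <- .integration_series(profile)
  te <- min(t_end, s$tlast)
  auc_obs <- with_stage("AUC", .integrate_profile(profile, te, "conc", method))
  aumc_obs <- with_stage("AUMC", .integrate_profile(profile, te, "moment"))
  clast <- auc_obs$c_end; tlast <- auc_obs$t_end

  auc_inf <- auc_obs$value + with_stage("extrapolation", auc_extrapolate(clast, fit$ke))
  aumc_inf <- aumc_obs$value +
    with_stage("extrapolation", aumc_extrapolate(clast, tlast, fit$ke))
  cl_f <- with_stage("clearance", clearance_over_f(profile$dose, auc_inf))

  ka <- tryCatch(
    as.numeric(ka_method_of_residuals(profile, fit)),
    koalapk_error = function(e) {
      pk_warn(paste0("absorption rate not estimated: ", conditionMessage(e)),
              "pk_ka_failed")
      NA_real_
    })

  structure(
    list(subject_id = profile$subject_id, route = profile$route,
         dose = profile$dose, ka = ka, ke = fit$ke, t_half = t_half,
         tmax = ct$tmax, cmax = ct$cmax,
         auc_0_t = auc_obs$value, auc_0_inf = auc_inf,
         auc_ratio = auc_obs$value / auc_inf,
         aumc_0_t = aumc_obs$value, aumc_0_inf = aumc_inf,
         mrt = mrt(aumc_inf, auc_inf),
         cl_f = cl_f, vz_f = volume_over_f(cl_f, fit$ke),
         t_end = tlast, c_last = clast, terminal_fit = fit),
    class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("<nca_result> subject %s (%s, %g mg/kg)\n",
              x$subject_id, x$route, x$dose))
  cat(sprintf("  ka %.3f /h | ke %.3f /h | t1/2 %.3f h | Tmax %g h | Cmax %.2f ug/mL\n",
              x$ka, x$ke, x$t_half, x$tmax, x$cmax))
  cat(sprintf("  AUC0-%g %.2f | AUC0-inf %.2f ug*h/mL (ratio %.2f) | AUMC0-inf %.2f\n",
              x$t_end, x$auc_0_t, x$auc_0_inf, x$auc_ratio, x$aumc_0_inf))
  cat(sprintf("  MRT %.3f h | Cl/F %.3f L/kg/h | Vz/F %.3f L/kg\n",
              x$mrt, x$cl_f, x$vz_f))
  invisible(x)
}

#' @export
as.data.frame.nca_result <- function(x, ...) {
  data.frame(subject_id = x$subject_id, route = x$route,
             dose_mg_per_kg = x$dose,
             ka = x$ka, ke = x$ke, t_half = x$t_half, tmax = x$tmax,
             cmax = x$cmax, auc_0_t = x$auc_0_t, auc_0_inf = x$auc_0_inf,
             auc_ratio = x$auc_ratio, aumc_0_inf = x$aumc_0_inf,
             mrt = x$mrt, vz_f = x$vz_f, cl_f = x$cl_f,
             terminal_n = x$terminal_fit$n_points,
             terminal_r2 = x$terminal_fit$r_squared,
             stringsAsFactors = FALSE)
}

#' Run NCA over a list of profiles and bind the results
#'
#' @param profiles a list of [conc_profile()] objects.
#' @param ... passed to [run_nca()].
#' @return A data.frame with one row per profile.
#' @export
nca_table <- function(profiles, ...) {
  rows <- lapply(profiles, function(p) as.data.frame(run_nca(p, ...)))
  do.call(rbind, rows)
}
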