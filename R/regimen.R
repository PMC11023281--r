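# Multiple-dose reasoning: superposition, accumulation factor, time to
# steady state, and residence time inside a therapeutic window.

#' Dosing regimen
#'
#' @param dose dose in mg/kg given at each dose time.
#' @param route administration route.
#' @param dose_times dosing times in hours, strictly increasing, first at 0.
#' @param tau inter-dose interval of the regular part of the regimen, hours.
#' @return An object of class `dose_regimen`.
#' @export
dose_regimen <- function(dose, route = c("oral", "subcutaneous"),
                         dose_times = 0, tau = 12) {
  route <- match.arg(route)
  check_positive(dose, "dose", "pk_invalid_input")
  check_positive(tau, "tau", "pk_invalid_input")
  if (length(dose_times) == 0L || dose_times[1] != 0 ||
      any(diff(dose_times) <= 0))
    pk_stop("`dose_times` must be non-empty, strictly increasing, starting at 0",
            "pk_invalid_input")
  structure(list(dose = dose, route = route, dose_times = dose_times, tau = tau),
            class = "dose_regimen")
}

#' The study's repeat-dose regimen
#'
#' A first dose at time 0, then the same dose every 12 hours on five
#' occasions starting 24 hours after the first: doses at 0, 24, 36, 48, 60
#' and 72 hours.
#'
#' @inheritParams dose_regimen
#' @return A [dose_regimen()] with `dose_times = c(0, 24, 36, 48, 60, 72)`
#'   and `tau = 12`.
#' @export
study_regimen <- function(dose = 15, route = "oral") {
  dose_regimen(dose, route, dose_times = c(0, 24, 36, 48, 60, 72), tau = 12)
}

#' Therapeutic concentration window
#'
#' Defaults to the 4-20 ug/mL total-plasma range suggested to provide
#' analgesia in humans, the comparator used throughout the study.
#'
#' @param low,high window bounds in ug/mL, `0 < low < high`.
#' @return An object of class `therapeutic_window`.
#' @export
therapeutic_window <- function(low = 4, high = 20) {
  check_positive(low, "low", "pk_invalid_input")
  check_positive(high, "high", "pk_invalid_input")
  if (low >= high) pk_stop("`low` must be below `high`", "pk_invalid_input")
  structure(list(low = low, high = high), class = "therapeutic_window")
}

#' Multiple-dose accumulation factor
#'
#' `(1 - exp(-n ke tau)) / (1 - exp(-ke tau))`: the ratio of exposure after
#' the n-th of a series of doses given every `tau` hours to the single-dose
#' exposure, under first-order elimination. Non-decreasing in `n` and bounded
#' by its steady-state limit `1 / (1 - exp(-ke tau))`.
#'
#' @param ke elimination rate constant, 1/h.
#' @param tau inter-dose interval, hours.
#' @param n number of doses counted from the start of the regular interval
#'   (vectorised; `n = 1` always gives 1).
#' @return Dimensionless accumulation factor.
#' @export
#' @examples
#' accumulation_factor(0.125, 12, 2) # 1.22, i.e. 1.2 at one decimal
accumulation_factor <- function(ke, tau, n) {
  check_positive(ke, "ke")
  check_positive(tau, "tau")
  if (any(!is.finite(n) | n < 1)) pk_stop("`n` must be >= 1", "pk_invalid_input")
  (1 - exp(-n * ke * tau)) / (1 - exp(-ke * tau))
}

#' Time to reach steady state
#'
#' The usual engineering rule of thumb: steady state is declared after a
#' fixed number of elimination half-lives (default five, i.e. ~97% of the
#' asymptote).
#'
#' @param t_half elimination half-life in hours.
#' @param n_half_lives number of half-lives (default 5).
#' @return `n_half_lives * t_half` in hours.
#' @export
time_to_steady_state <- function(t_half, n_half_lives = 5) {
  check_positive(t_half, "t_half")
  check_positive(n_half_lives, "n_half_lives", "pk_invalid_input")
  n_half_lives * t_half
}

#' One-compartment multiple-dose concentration by superposition
#'
#' Sums the single-dose first-order-absorption (Bateman) curve shifted to
#' each dose time, each term zero before its dose. Linear in `scale`;
#' shifting every dose time by a constant shifts the whole curve by the same
#' amount.
#'
#' @param regimen a [dose_regimen()].
#' @param ka,ke absorption and elimination rate constants, 1/h, `ka != ke`.
#' @param scale lumped coefficient F*D/V in ug/mL (see [bateman()]).
#' @param t_grid sorted evaluation times in hours.
#' @return Concentrations in ug/mL at `t_grid`.
#' @export
superpose <- function(regimen, ka, ke, scale, t_grid) {
  stopifnot(inherits(regimen, "dose_regimen"))
  check_positive(ka, "ka"); check_positive(ke, "ke")
  check_positive(scale, "scale")
  if (ka == ke)
    pk_stop("ka = ke: the two-exponential model is degenerate", "pk_degenerate_model")
  if (is.unsorted(t_grid))
    pk_stop("`t_grid` must be sorted", "pk_invalid_input")
  out <- numeric(length(t_grid))
  for (td in regimen$dose_times) {
    dt <- t_grid - td
    live <- dt >= 0
    out[live] <- out[live] +
      scale * ka / (ka - ke) * (exp(-ke * dt[live]) - exp(-ka * dt[live]))
  }
  out
}

#' Time spent inside a therapeutic window
#'
#' Total duration for which the (linearly interpolated) concentration lies in
#' `[low, high]`, bounds inclusive. Crossing times are located by linear
#' interpolation between the bracketing samples; with
#' `interp = "log-down"`, crossings on strictly decreasing positive segments
#' are located on the log-concentration scale instead, consistent with
#' log-down AUC integration.
#'
#' @param times sorted sampling times in hours.
#' @param conc concentrations in ug/mL.
#' @param window a [therapeutic_window()].
#' @param interp crossing interpolation rule.
#' @return Hours with `low <= C <= high`.
#' @export
#' @examples
#' time_in_window(c(0, 2, 4), c(2, 6, 2), therapeutic_window(4, 20)) # 2 h
time_in_window <- function(times, conc, window = therapeutic_window(),
                           interp = c("linear", "log-down")) {
  stopifnot(inherits(window, "therapeutic_window"))
  interp <- match.arg(interp)
  if (length(times) < 2L || length(times) != length(conc))
    pk_stop("need >= 2 aligned (time, concentration) points", "pk_invalid_input")
  if (is.unsorted(times, strictly = TRUE))
    pk_stop("`times` must be strictly increasing", "pk_unsorted_times")

  use_log <- function(c1, c2) {
    interp == "log-down" && c1 > 0 && c2 > 0 && c2 < c1
  }
  cross <- function(t1, t2, c1, c2, level) {
    if (use_log(c1, c2) && level > 0)
      t1 + (t2 - t1) * log(c1 / level) / log(c1 / c2)
    else t1 + (t2 - t1) * (level - c1) / (c2 - c1)
  }
  # concentration at t by the same rule the crossings use
  value_at <- function(t, t1, t2, c1, c2) {
    frac <- (t - t1) / (t2 - t1)
    if (use_log(c1, c2)) c1 * (c2 / c1)^frac else c1 + (c2 - c1) * frac
  }

  total <- 0
  for (i in seq_len(length(times) - 1L)) {
    t1 <- times[i]; t2 <- times[i + 1L]
    c1 <- conc[i]; c2 <- conc[i + 1L]
    cuts <- c(t1, t2)
    for (level in c(window$low, window$high)) {
      if ((c1 - level) * (c2 - level) < 0)
        cuts <- c(cuts, cross(t1, t2, c1, c2, level))
    }
    cuts <- sort(unique(cuts))
    for (j in seq_len(length(cuts) - 1L)) {
      tm <- (cuts[j] + cuts[j + 1L]) / 2
      cm <- value_at(tm, t1, t2, c1, c2)
      if (cm >= window$low - 1e-12 && cm <= window$high + 1e-12)
        total <- total + (cuts[j + 1L] - cuts[j])
    }
  }
  total
}
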