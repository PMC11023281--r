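# Microsomal substrate-depletion kinetics: first-order depletion slope,
# in-vitro half-life, and intrinsic clearance.

#' In-vitro substrate-depletion time course
#'
#' One replicate of a microsomal depletion incubation. Substrate remaining is
#' expressed as percent of the t = 0 amount (t = 0 is defined as 100%); raw
#' concentrations may be supplied instead and are converted by dividing by
#' the t = 0 value.
#'
#' @param species species label for the microsome pool.
#' @param times incubation times in minutes, increasing, with t = 0 present.
#' @param values substrate remaining, percent (default) or raw concentration.
#' @param values_are `"percent"` or `"concentration"`.
#' @param protein_conc microsomal protein concentration in mg/mL.
#' @param volume_ul incubation volume in uL.
#' @param replicate replicate label.
#' @return An object of class `depletion_assay` with fields `species`,
#'   `times`, `remaining`, `protein_conc`, `volume_ul`, `protein_mg`
#'   (= protein_conc * volume_ul / 1000), `replicate`.
#' @export
depletion_assay <- function(species, times, values,
                            values_are = c("percent", "concentration"),
                            protein_conc = 0.5, volume_ul = 1000,
                            replicate = 1L) {
  values_are <- match.arg(values_are)
  check_positive(protein_conc, "protein_conc", "pk_invalid_input")
  check_positive(volume_ul, "volume_ul", "pk_invalid_input")
  if (length(times) != length(values))
    pk_stop("`times` and `values` must be aligned", "pk_length_mismatch")
  if (times[1] != 0 || any(diff(times) <= 0))
    pk_stop("`times` must start at 0 and be strictly increasing", "pk_invalid_input")
  if (any(!is.finite(values) | values <= 0))
    pk_stop("substrate values must be positive for the log transform",
            "pk_nonpositive_input")
  remaining <- if (values_are == "concentration") values / values[1] * 100 else values
  if (abs(remaining[1] - 100) > 1e-6)
    pk_stop("remaining percent at t = 0 must be 100", "pk_invalid_input")
  structure(
    list(species = as.character(species), times = times, remaining = remaining,
         protein_conc = protein_conc, volume_ul = volume_ul,
         protein_mg = protein_conc * volume_ul / 1000,
         replicate = replicate),
    class = "depletion_assay")
}

#' First-order depletion slope
#'
#' Least-squares slope of `log(remaining %)` versus incubation time. For a
#' depleting substrate the slope is negative; the one-sided p-value for
#' slope < 0 is attached for the no-depletion decision rule used by
#' [summarize_assays()].
#'
#' @param assay a [depletion_assay()].
#' @return The slope in 1/min, with attributes `p_decline` (one-sided
#'   p-value for slope < 0; NA when it cannot be computed) and `n`.
#' @export
depletion_slope <- function(assay) {
  stopifnot(inherits(assay, "depletion_assay"))
  if (length(assay$times) < 3L)
    pk_stop("at least 3 time points are required", "pk_too_few_points")
  fit <- stats::lm(log(assay$remaining) ~ assay$times)
  slope <- unname(stats::coef(fit)[2])
  # summary.lm warns on zero-residual (exact exponential) series; the se = 0
  # case is handled explicitly below
  sm <- suppressWarnings(summary(fit))$coefficients
  p_dec <- if (nrow(sm) == 2 && is.finite(sm[2, 3])) {
    stats::pt(sm[2, 3], df = fit$df.residual)  # P(T <= t): lower tail, decline
  } else if (slope < 0) 0 else NA_real_        # perfect fit: se = 0
  structure(slope, p_decline = p_dec, n = length(assay$times))
}

#' In-vitro half-life from a depletion slope
#'
#' `-0.693 / k` for a negative depletion slope `k`. The numerator is the
#' literal three-significant-figure constant 0.693 conventionally used in
#' substrate-depletion work (set `exact_log2 = TRUE` for ln 2). A
#' non-negative slope means no measurable depletion and returns `NA` rather
#' than an error, so that "no depletion" propagates as a result state.
#'
#' @param k depletion slope in 1/min (negative for depletion).
#' @param exact_log2 use ln 2 instead of 0.693.
#' @return Half-life in minutes, or `NA_real_` when `k >= 0`.
#' @export
invitro_half_life <- function(k, exact_log2 = FALSE) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k))
    pk_stop("`k` must be a single finite number", "pk_invalid_input")
  if (k >= 0) return(NA_real_)
  const <- if (exact_log2) log(2) else 0.693
  -const / k
}

#' Microsomal intrinsic clearance
#'
#' `(0.693 / t_half) * (volume_ul / protein_mg)`: depletion half-life scaled
#' to incubation volume per mg of microsomal protein. Uses the literal 0.693
#' constant by default (see [invitro_half_life()]); consequently
#' `clint * t_half = 0.693 * volume_ul / protein_mg` holds exactly.
#'
#' @param t_half_vitro in-vitro half-life in minutes.
#' @param volume_ul incubation volume in uL.
#' @param protein_mg microsomal protein in the incubation, mg.
#' @param exact_log2 use ln 2 instead of 0.693.
#' @return Intrinsic clearance in uL/(min * mg protein).
#' @export
intrinsic_clearance <- function(t_half_vitro, volume_ul, protein_mg,
                                exact_log2 = FALSE) {
  check_positive(t_half_vitro, "t_half_vitro")
  check_positive(volume_ul, "volume_ul")
  check_positive(protein_mg, "protein_mg")
  const <- if (exact_log2) log(2) else 0.693
  (const / t_half_vitro) * (volume_ul / protein_mg)
}

#' Analyse one depletion replicate
#'
#' Chains [depletion_slope()], [invitro_half_life()] and
#' [intrinsic_clearance()]. "No depletion" is declared when the slope is
#' non-negative or not significantly below zero at the 5% level.
#'
#' @param assay a [depletion_assay()].
#' @param exact_log2 use ln 2 instead of the conventional 0.693.
#' @return An object of class `clint_result`: `species`, `replicate`, `k`,
#'   `depleted` (logical), `t_half_vitro`, `clint` (both NA when not
#'   depleted).
#' @export
analyze_depletion <- function(assay, exact_log2 = FALSE) {
  k <- depletion_slope(assay)
  p <- attr(k, "p_decline")
  depleted <- is.finite(k) && k < 0 && !is.na(p) && p < 0.05
  t_half <- if (depleted) invitro_half_life(as.numeric(k), exact_log2) else NA_real_
  clint <- if (depleted)
    intrinsic_clearance(t_half, assay$volume_ul, assay$protein_mg, exact_log2)
  else NA_real_
  structure(
    list(species = assay$species, replicate = assay$replicate,
         k = as.numeric(k), depleted = depleted,
         t_half_vitro = t_half, clint = clint),
    class = "clint_result")
}

#' Summarise depletion assays by species
#'
#' Per-replicate half-life and intrinsic clearance are computed first and
#' then averaged (mean of per-replicate values, not a pooled fit), matching
#' duplicate-incubation reporting. A species with any non-depleting replicate
#' is reported as "no depletion".
#'
#' @param assays a list of [depletion_assay()] objects.
#' @param exact_log2 use ln 2 instead of 0.693.
#' @return A data.frame with one row per species: `species`, `n`,
#'   `depleted`, `mean_t_half`, `sd_t_half`, `mean_clint`, `sd_clint`
#'   (SDs NA for single replicates; means NA when not depleted).
#' @export
summarize_assays <- function(assays, exact_log2 = FALSE) {
  if (length(assays) == 0L) pk_stop("no assays supplied", "pk_empty_group")
  res <- lapply(assays, analyze_depletion, exact_log2 = exact_log2)
  species <- vapply(res, `[[`, character(1), "species")
  rows <- lapply(split(res, species), function(g) {
    th <- vapply(g, `[[`, numeric(1), "t_half_vitro")
    cl <- vapply(g, `[[`, numeric(1), "clint")
    dep <- all(vapply(g, `[[`, logical(1), "depleted"))
    data.frame(
      species = g[[1]]$species, n = length(g), depleted = dep,
      mean_t_half = if (dep) mean(th) else NA_real_,
      sd_t_half = if (dep && length(g) > 1L) stats::sd(th) else NA_real_,
      mean_clint = if (dep) mean(cl) else NA_real_,
      sd_clint = if (dep && length(g) > 1L) stats::sd(cl) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
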