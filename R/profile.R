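#' Plasma concentration-time profile for one subject
#'
#' Container for a single subject's plasma concentration-time series with the
#' dose and route metadata needed for non-compartmental analysis. Rows are
#' sorted by time on construction, so the row order of the input never affects
#' downstream results. Concentrations below the lower limit of quantification
#' (LLOQ) are flagged BLQ (below the limit of quantification) and handled by
#' the conventions described in [run_nca()]: leading BLQ samples count as zero
#' for integration, later BLQ samples are excluded.
#'
#' @param subject_id subject label (e.g. `"K1"`).
#' @param route administration route, `"oral"` or `"subcutaneous"`.
#' @param dose dose in mg per kg body weight.
#' @param times sampling times in hours; finite, non-negative, no duplicates.
#' @param conc plasma concentrations in ug/mL; non-negative.
#' @param blq optional logical vector flagging below-LLOQ samples; defaults to
#'   `conc < lloq`.
#' @param lloq lower limit of quantification in ug/mL (default 0.625, the
#'   assay LLOQ of the koala study this package accompanies).
#' @return An object of class `conc_profile`.
#' @export
#' @examples
#' conc_profile("K1", "oral", 15, times = c(1, 4, 8, 24),
#'              conc = c(5, 17, 12, 3))
conc_profile <- function(subject_id, route = c("oral", "subcutaneous"),
                         dose, times, conc, blq = NULL, lloq = 0.625) {
  route <- match.arg(route)
  check_positive(dose, "dose", "pk_invalid_input")
  check_positive(lloq, "lloq", "pk_invalid_input")
  if (!is.numeric(times) || !is.numeric(conc))
    pk_stop("`times` and `conc` must be numeric", "pk_invalid_input")
  if (length(times) != length(conc))
    pk_stop("`times` and `conc` must have the same length", "pk_length_mismatch")
  if (length(times) == 0L)
    pk_stop("profile must contain at least one observation", "pk_invalid_input")
  if (any(!is.finite(times)) || any(times < 0))
    pk_stop("`times` must be finite and >= 0", "pk_invalid_input")
  if (any(!is.finite(conc)) || any(conc < 0))
    pk_stop("concentrations must be finite and >= 0", "pk_invalid_input")
  if (anyDuplicated(times))
    pk_stop("duplicate sampling times in profile", "pk_invalid_input")
  if (is.null(blq)) blq <- conc < lloq
  if (!is.logical(blq) || length(blq) != length(conc) || anyNA(blq))
    pk_stop("`blq` must be a logical vector aligned with `conc`", "pk_invalid_input")

  ord <- order(times)
  structure(
    list(subject_id = as.character(subject_id), route = route, dose = dose,
         times = times[ord], conc = conc[ord], blq = blq[ord], lloq = lloq),
    class = "conc_profile")
}

#' @export
print.conc_profile <- function(x, ...) {
  cat(sprintf("<conc_profile> subject %s, %s %g mg/kg, %d samples (%d BLQ), LLOQ %g ug/mL\n",
              x$subject_id, x$route, x$dose, length(x$times), sum(x$blq), x$lloq))
  print(data.frame(time_h = x$times, conc_ug_per_ml = x$conc, blq = x$blq),
        row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.conc_profile <- function(x, ...) {
  data.frame(subject_id = x$subject_id, route = x$route,
             dose_mg_per_kg = x$dose, time_h = x$times,
             conc_ug_per_ml = x$conc, blq = as.integer(x$blq),
             stringsAsFactors = FALSE)
}

# Indices of quantifiable (non-BLQ) samples.
quantifiable_idx <- function(profile) which(!profile$blq)

# Quantifiable points as a two-column list, requiring at least `min_n`.
quantifiable_points <- function(profile, min_n = 1L) {
  i <- quantifiable_idx(profile)
  if (length(i) < min_n)
    pk_stop(sprintf("profile has %d quantifiable points; %d required",
                    length(i), min_n),
            if (length(i) == 0L) "pk_all_blq" else "pk_too_few_points")
  list(idx = i, times = profile$times[i], conc = profile$conc[i])
}
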