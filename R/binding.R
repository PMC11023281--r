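# Plasma-protein binding from ultrafiltration assay concentrations.

#' Percentage of drug bound to plasma proteins
#'
#' `100 - (free/total) * 100` from an ultrafiltration measurement: the total
#' concentration is measured in plasma before filtration and the free
#' concentration in the ultrafiltrate. Scale-invariant in the concentration
#' units. Vectorised over aligned `total`/`free`.
#'
#' @param total total drug concentration (ug/mL, > 0).
#' @param free free (ultrafiltrate) drug concentration (ug/mL, >= 0,
#'   at most `total`).
#' @return Percent bound, in `[0, 100]`.
#' @export
#' @examples
#' percent_bound(15, 5.82) # 61.2
percent_bound <- function(total, free) {
  if (length(total) != length(free))
    pk_stop("`total` and `free` must be aligned", "pk_length_mismatch")
  if (any(!is.finite(total) | total <= 0))
    pk_stop("total concentration must be positive", "pk_nonpositive_input")
  if (any(!is.finite(free) | free < 0))
    pk_stop("free concentration must be non-negative", "pk_invalid_input")
  if (any(free > total))
    pk_stop("free concentration exceeds total concentration", "pk_free_exceeds_total")
  100 - free / total * 100
}

#' Summarise an ultrafiltration binding assay
#'
#' Per nominal spiking concentration, the sample mean and SD (n-1
#' denominator) of percent bound across replicates. Plasma-matrix rows give
#' the protein-binding estimate; buffer-matrix rows measure non-specific
#' binding (NSB) of drug to the filtration membrane and are summarised
#' separately, with a flag for the conventional NSB < 5% acceptance check. No
#' NSB correction is applied to the plasma percentages.
#'
#' @param measurements a data.frame with columns `nominal_conc`, `matrix`
#'   (`"plasma"` or `"buffer"`), `drug_total`, `drug_free`.
#' @return A data.frame with one row per (matrix, nominal concentration):
#'   `matrix`, `nominal_conc`, `n`, `mean_percent_bound`, `sd_percent_bound`
#'   (NA for a single replicate), and `nsb_below_5` (NA for plasma rows).
#' @export
summarize_binding <- function(measurements) {
  req <- c("nominal_conc", "matrix", "drug_total", "drug_free")
  if (!is.data.frame(measurements) || !all(req %in% names(measurements)))
    pk_stop(paste("`measurements` needs columns", paste(req, collapse = ", ")),
            "pk_invalid_input")
  if (nrow(measurements) == 0L)
    pk_stop("no binding measurements supplied", "pk_empty_group")
  if (!all(measurements$matrix %in% c("plasma", "buffer")))
    pk_stop("`matrix` must be 'plasma' or 'buffer'", "pk_invalid_input")

  pb <- percent_bound(measurements$drug_total, measurements$drug_free)
  key <- interaction(measurements$matrix, measurements$nominal_conc, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(measurements)), key), function(i) {
    m <- measurements$matrix[i[1]]
    data.frame(
      matrix = m,
      nominal_conc = measurements$nominal_conc[i[1]],
      n = length(i),
      mean_percent_bound = mean(pb[i]),
      sd_percent_bound = if (length(i) > 1L) stats::sd(pb[i]) else NA_real_,
      nsb_below_5 = if (m == "buffer") mean(pb[i]) < 5 else NA,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$matrix, out$nominal_conc), , drop = FALSE]
  rownames(out) <- NULL
  out
}
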