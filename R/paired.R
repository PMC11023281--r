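# Exact matched-pairs Wilcoxon signed-rank testing and the median (range)
# summaries used for reporting.

# Exact null distribution of 2*W+ over all 2^n sign assignments of the
# realized (mid-)ranks, by count convolution. Mid-ranks are multiples of
# 0.5, so doubling them puts every achievable rank sum on an integer grid;
# the returned vector counts[s + 1] is the number of sign vectors with
# doubled rank sum s. Equivalent to full enumeration, feasible to n = 25.
.signrank_counts <- function(ranks2) {
  counts <- numeric(sum(ranks2) + 1L)
  counts[1L] <- 1
  for (r in ranks2) {
    shifted <- c(rep(0, r), counts[seq_len(length(counts) - r)])
    counts <- counts + shifted
  }
  counts
}

#' Exact Wilcoxon matched-pairs signed-rank test
#'
#' Differences `post - pre` are formed; zero differences are dropped
#' (Wilcoxon's original convention); absolute differences are ranked with
#' mid-ranks for ties; `W+` is the sum of ranks of positive differences. For
#' `n_effective <= exact_limit` the two-sided p-value is exact: the null
#' distribution of `W+` is enumerated over all `2^n` equiprobable sign
#' assignments of the realized rank vector, and the smaller one-sided tail is
#' doubled and capped at 1. Beyond the limit a normal approximation with
#' tie-corrected variance and continuity correction is used.
#'
#' @param pre,post aligned per-subject values (same length, >= 2).
#' @param exact_limit largest `n_effective` for exact enumeration
#'   (default 25).
#' @return An object of class `wilcoxon_result`: `w_plus`, `n_effective`,
#'   `p_two_sided`, `method` (`"exact"` or `"normal"`), `direction` (sign of
#'   the median difference).
#' @export
#' @examples
#' # six unanimous increases: p = 2/64 = 0.03125
#' wilcoxon_exact(pre = rep(0, 6), post = 1:6)$p_two_sided
wilcoxon_exact <- function(pre, post, exact_limit = 25L) {
  if (length(pre) != length(post))
    pk_stop("`pre` and `post` must be aligned", "pk_length_mismatch")
  if (length(pre) < 2L)
    pk_stop("at least 2 pairs are required", "pk_invalid_input")
  d <- post - pre
  if (anyNA(d)) pk_stop("missing values in differences", "pk_invalid_input")
  d <- d[d != 0]
  n <- length(d)
  if (n < 2L)
    pk_stop("fewer than 2 non-zero differences after zero removal",
            "pk_all_zero_differences")

  r <- rank(abs(d))                      # mid-ranks for ties
  w_plus <- sum(r[d > 0])

  if (n <= exact_limit) {
    r2 <- as.integer(round(2 * r))
    counts <- .signrank_counts(r2)
    total <- 2^n
    w2 <- round(2 * w_plus)
    s <- seq_along(counts) - 1L
    tail_ge <- sum(counts[s >= w2 - 1e-9]) / total
    tail_le <- sum(counts[s <= w2 + 1e-9]) / total
    p <- min(1, 2 * min(tail_ge, tail_le))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    sigma <- sqrt(sum(r^2) / 4)          # tie-corrected: sum of squared ranks
    z <- (w_plus - mu - sign(w_plus - mu) * 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }

  structure(
    list(w_plus = w_plus, n_effective = n, p_two_sided = p, method = method,
         direction = sign(stats::median(d))),
    class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("<wilcoxon_result> W+ = %g, n = %d, two-sided p = %.5g (%s)\n",
              x$w_plus, x$n_effective, x$p_two_sided, x$method))
  invisible(x)
}

#' Median and range
#'
#' The reporting convention used throughout small-sample PK tables: the
#' median (mean of the two central order statistics for even n) together with
#' the minimum and maximum.
#'
#' @param values numeric vector, non-empty.
#' @return Named numeric vector `c(median, min, max)`.
#' @export
#' @examples
#' median_range(c(5.658, 5.788, 6.449, 4.889, 7.669, 5.363, 4.661, 5.423))
median_range <- function(values) {
  if (length(values) == 0L || !is.numeric(values))
    pk_stop("`values` must be a non-empty numeric vector", "pk_invalid_input")
  if (anyNA(values)) pk_stop("`values` contains NA", "pk_invalid_input")
  c(median = stats::median(values), min = min(values), max = max(values))
}

#' Exact signed-rank tests for a panel of analytes
#'
#' Runs [wilcoxon_exact()] per analyte on a long-format pre/post table.
#'
#' @param panel data.frame with columns `analyte`, `subject_id`, `value_pre`,
#'   `value_post`.
#' @return data.frame with one row per analyte: `analyte`, `n_effective`,
#'   `w_plus`, `p_two_sided`, `direction`, `significant` (p < 0.05). No
#'   multiplicity adjustment is applied (analyte-by-analyte reporting);
#'   interpret accordingly.
#' @export
paired_panel_tests <- function(panel) {
  req <- c("analyte", "subject_id", "value_pre", "value_post")
  if (!is.data.frame(panel) || !all(req %in% names(panel)))
    pk_stop(paste("`panel` needs columns", paste(req, collapse = ", ")),
            "pk_invalid_input")
  rows <- lapply(split(panel, panel$analyte), function(g) {
    w <- wilcoxon_exact(g$value_pre, g$value_post)
    data.frame(analyte = g$analyte[1], n_effective = w$n_effective,
               w_plus = w$w_plus, p_two_sided = w$p_two_sided,
               direction = w$direction, significant = w$p_two_sided < 0.05,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
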