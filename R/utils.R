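# Shared helpers: classed conditions, reporting rounding, seeded evaluation.

pk_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "koalapk_error"), call = call))
}

pk_warn <- function(msg, class = "koalapk_warning") {
  warning(warningCondition(msg, class = c(class, "koalapk_warning")))
}

check_positive <- function(x, name, class = "pk_nonpositive_input") {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    pk_stop(sprintf("`%s` must be a single positive finite number", name), class)
  invisible(x)
}

check_nonnegative <- function(x, name, class = "pk_nonpositive_input") {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    pk_stop(sprintf("`%s` must be a single non-negative finite number", name), class)
  invisible(x)
}

#' Round half away from zero for report formatting
#'
#' Table-style PK reporting conventionally rounds half-values up (a median of
#' 16.925 ug/mL prints as 16.93), whereas [round()] rounds half to even.
#' Values are rounded half-up with a small tolerance so that decimal values
#' stored inexactly in binary (16.925 is held as 16.92499...) still round the
#' way their printed form suggests. Internal computations always keep full
#' precision; this is a formatting aid only.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals, halves away from zero.
#' @export
#' @examples
#' round_half_up(16.925, 2) # 16.93
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Re-raise errors from a pipeline stage with a stage label, keeping classes.
with_stage <- function(stage, expr) {
  tryCatch(expr, koalapk_error = function(e) {
    stop(errorCondition(paste0("[", stage, "] ", conditionMessage(e)),
                        class = setdiff(class(e), c("error", "condition"))))
  })
}
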