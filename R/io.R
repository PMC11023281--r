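# CSV readers/writers, the packaged published-indices table, and the
# study-report bundle.

#' Read concentration-time profiles from CSV
#'
#' Expects header columns `subject_id`, `route`, `dose_mg_per_kg`, `time_h`,
#' `conc_ug_per_ml` and optionally `blq` (0/1). Rows are grouped into one
#' profile per (subject, route). Malformed rows are reported with their line
#' numbers; out-of-order times are sorted with a warning; duplicate
#' (subject, time) rows are an error.
#'
#' @param path CSV file path.
#' @param lloq LLOQ in ug/mL applied when the file has no `blq` column.
#' @return A named list of [conc_profile()] objects.
#' @export
read_profiles <- function(path, lloq = 0.625) {
  if (!file.exists(path)) pk_stop(paste("no such file:", path), "pk_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "route", "dose_mg_per_kg", "time_h", "conc_ug_per_ml")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    pk_stop(paste("missing column(s):", paste(missing_cols, collapse = ", ")),
            "pk_missing_column")
  for (col in c("dose_mg_per_kg", "time_h", "conc_ug_per_ml")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad))
      pk_stop(sprintf("non-numeric or missing `%s` at data row(s) %s",
                      col, paste(bad, collapse = ", ")), "pk_non_numeric")
    df[[col]] <- as.numeric(df[[col]])
  }
  neg <- which(df$conc_ug_per_ml < 0)
  if (length(neg))
    pk_stop(sprintf("negative concentration at data row(s) %s",
                    paste(neg, collapse = ", ")), "pk_invalid_input")

  key <- interaction(df$subject_id, df$route, drop = TRUE)
  profiles <- lapply(split(df, key), function(g) {
    if (anyDuplicated(g$time_h))
      pk_stop(sprintf("duplicate (subject, time) rows for subject %s",
                      g$subject_id[1]), "pk_invalid_input")
    if (is.unsorted(g$time_h))
      pk_warn(sprintf("times out of order for subject %s; sorting", g$subject_id[1]),
              "pk_unsorted_times")
    blq <- if ("blq" %in% names(g)) as.logical(g$blq) else NULL
    conc_profile(g$subject_id[1], g$route[1], g$dose_mg_per_kg[1],
                 g$time_h, g$conc_ug_per_ml, blq = blq, lloq = lloq)
  })
  names(profiles) <- vapply(profiles, function(p)
    paste(p$subject_id, p$route, sep = "."), character(1))
  profiles
}

#' Write profiles to the CSV dialect [read_profiles()] reads
#'
#' @param profiles a list of [conc_profile()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  if (inherits(profiles, "conc_profile")) profiles <- list(profiles)
  df <- do.call(rbind, lapply(profiles, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Published per-subject PK indices of the koala paracetamol study
#'
#' The per-animal non-compartmental indices reported for the 15 mg/kg dose:
#' two subcutaneous profiles (K1, K2) and eight oral profiles (K3-K8 from the
#' repeat-dose arm plus second occasions of K2 and K4). These printed values
#' are inputs for the summary reproductions in the package examples and
#' acceptance checks; the underlying raw concentrations were not published.
#'
#' @return A data.frame with columns `subject_id`, `route`, `repeat_dosed`,
#'   `ka`, `ke`, `t_half`, `tmax`, `cmax`, `auc_0_24`, `auc_0_inf`,
#'   `auc_ratio`, `aumc_0_inf`, `mrt`, `vz_f`, `cl_f`.
#' @export
published_pk_indices <- function() {
  path <- system.file("extdata", "pk_indices_published.csv", package = "koalapk",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Assemble a study report
#'
#' Bundles the per-subject NCA table, its median/range summary by route, and
#' any binding, in-vitro and paired-panel summaries into one object whose
#' machine-readable export round-trips every number in the rendered text.
#'
#' @param profiles list of [conc_profile()] objects.
#' @param binding optional binding measurements data.frame
#'   (see [summarize_binding()]).
#' @param assays optional list of [depletion_assay()] objects.
#' @param panel optional paired panel data.frame (see
#'   [paired_panel_tests()]).
#' @param t_end NCA integration limit in hours.
#' @param seed seed recorded in provenance (the report itself is
#'   deterministic given its inputs).
#' @return An object of class `study_report`.
#' @export
study_report <- function(profiles, binding = NULL, assays = NULL,
                         panel = NULL, t_end = 24, seed = NULL) {
  nca <- nca_table(profiles, t_end = t_end)
  summarize_route <- function(g) {
    idx <- c("ka", "ke", "t_half", "tmax", "cmax", "auc_0_t", "auc_0_inf",
             "aumc_0_inf", "mrt", "vz_f", "cl_f")
    rows <- lapply(idx, function(v) {
      x <- g[[v]][is.finite(g[[v]])]
      if (length(x) == 0L) return(NULL)
      mr <- median_range(x)
      data.frame(index = v, n = length(x), median = unname(mr["median"]),
                 min = unname(mr["min"]), max = unname(mr["max"]),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  summaries <- lapply(split(nca, nca$route), summarize_route)

  structure(
    list(nca = nca, summary = summaries,
         binding = if (!is.null(binding)) summarize_binding(binding),
         invitro = if (!is.null(assays)) summarize_assays(assays),
         paired = if (!is.null(panel)) paired_panel_tests(panel),
         provenance = list(package = "koalapk",
                           version = as.character(utils::packageVersion("koalapk")),
                           n_profiles = length(profiles), t_end = t_end,
                           seed = seed)),
    class = "study_report")
}

#' Write a study report
#'
#' Deterministic, byte-stable output for identical inputs: JSON with sorted
#' keys and full-precision numbers, a CSV bundle (one file per table), or a
#' formatted text rendering using the reporting precisions of the study
#' tables (3 decimals for rate constants, half-lives and volumes; 2 for
#' concentrations and AUCs).
#'
#' @param report a [study_report()].
#' @param path output file (json/text) or directory (csv bundle).
#' @param format one of `"json"`, `"csv"`, `"text"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv", "text")) {
  stopifnot(inherits(report, "study_report"))
  format <- match.arg(format)
  ok <- switch(format,
    json = {
      keep <- !vapply(unclass(report), is.null, logical(1))
      jsonlite::write_json(unclass(report)[keep], path, dataframe = "rows",
                           auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE)
    },
    csv = {
      if (!dir.exists(path)) dir.create(path, recursive = TRUE)
      utils::write.csv(report$nca, file.path(path, "nca.csv"), row.names = FALSE)
      for (rt in names(report$summary))
        utils::write.csv(report$summary[[rt]],
                         file.path(path, paste0("summary_", rt, ".csv")),
                         row.names = FALSE)
      for (part in c("binding", "invitro", "paired"))
        if (!is.null(report[[part]]))
          utils::write.csv(report[[part]], file.path(path, paste0(part, ".csv")),
                           row.names = FALSE)
    },
    text = {
      con <- file(path, "w"); on.exit(close(con))
      w <- function(...) writeLines(sprintf(...), con)
      w("study report (koalapk %s; %d profiles; t_end %g h; seed %s)",
        report$provenance$version, report$provenance$n_profiles,
        report$provenance$t_end,
        if (is.null(report$provenance$seed)) "none" else report$provenance$seed)
      for (rt in names(report$summary)) {
        w("\n== %s: median (range) ==", rt)
        s <- report$summary[[rt]]
        d3 <- c("ka", "ke", "t_half", "mrt", "vz_f", "cl_f")
        for (i in seq_len(nrow(s))) {
          d <- if (s$index[i] %in% d3) 3 else 2
          w("%-10s %s (%s to %s)  [n=%d]", s$index[i],
            format(round_half_up(s$median[i], d), nsmall = d),
            format(round_half_up(s$min[i], d), nsmall = d),
            format(round_half_up(s$max[i], d), nsmall = d), s$n[i])
        }
      }
      if (!is.null(report$binding)) {
        w("\n== plasma protein binding ==")
        b <- report$binding
        for (i in seq_len(nrow(b)))
          w("%s %g ug/mL: %s%% bound (SD %s, n=%d)%s", b$matrix[i],
            b$nominal_conc[i], format(round_half_up(b$mean_percent_bound[i], 2)),
            ifelse(is.na(b$sd_percent_bound[i]), "NA",
                   format(round_half_up(b$sd_percent_bound[i], 2))), b$n[i],
            ifelse(isTRUE(b$nsb_below_5[i]), " [NSB < 5% pass]", ""))
      }
      if (!is.null(report$invitro)) {
        w("\n== in-vitro depletion ==")
        v <- report$invitro
        for (i in seq_len(nrow(v)))
          if (v$depleted[i])
            w("%s: t1/2 %s min, Clint %s uL/min/mg (n=%d)", v$species[i],
              format(round_half_up(v$mean_t_half[i], 2)),
              format(round_half_up(v$mean_clint[i], 2)), v$n[i])
          else w("%s: no depletion (n=%d)", v$species[i], v$n[i])
      }
      if (!is.null(report$paired)) {
        w("\n== paired pre/post tests (no multiplicity adjustment) ==")
        p <- report$paired
        for (i in seq_len(nrow(p)))
          w("%s: W+=%g n=%d p=%s %s", p$analyte[i], p$w_plus[i],
            p$n_effective[i], format(round_half_up(p$p_two_sided[i], 2)),
            ifelse(p$significant[i], "*", ""))
      }
    })
  invisible(path)
}

#' Plot a concentration-time profile
#'
#' Semi-log concentration-time plot with the LLOQ and an optional
#' therapeutic window shaded, the standard diagnostic view of these data.
#'
#' @param x a [conc_profile()].
#' @param window optional [therapeutic_window()] to shade.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.conc_profile <- function(x, window = NULL, ...) {
  q <- !x$blq
  graphics::plot(x$times[q], x$conc[q], log = "y", type = "b", pch = 16,
                 xlab = "time (h)", ylab = "concentration (ug/mL)",
                 main = sprintf("%s (%s, %g mg/kg)", x$subject_id, x$route, x$dose),
                 ...)
  graphics::abline(h = x$lloq, lty = 3)
  if (!is.null(window)) graphics::abline(h = c(window$low, window$high), lty = 2)
  invisible(x)
}

#' Read ultrafiltration binding measurements from CSV
#'
#' Columns: `nominal_conc_ug_per_ml`, `matrix`, `drug_total_ug_per_ml`,
#' `drug_free_ug_per_ml`.
#'
#' @param path CSV file path.
#' @return A data.frame suitable for [summarize_binding()].
#' @export
read_binding_measurements <- function(path) {
  if (!file.exists(path)) pk_stop(paste("no such file:", path), "pk_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("nominal_conc_ug_per_ml", "matrix", "drug_total_ug_per_ml",
           "drug_free_ug_per_ml")
  if (!all(req %in% names(df)))
    pk_stop(paste("missing column(s):", paste(setdiff(req, names(df)), collapse = ", ")),
            "pk_missing_column")
  data.frame(nominal_conc = df$nominal_conc_ug_per_ml, matrix = df$matrix,
             drug_total = df$drug_total_ug_per_ml,
             drug_free = df$drug_free_ug_per_ml, stringsAsFactors = FALSE)
}

#' Read in-vitro depletion assays from CSV
#'
#' Columns: `species`, `replicate`, `time_min`, `remaining_percent` (or
#' `conc`), `protein_mg_per_ml`, `volume_ul`; one assay per
#' (species, replicate).
#'
#' @param path CSV file path.
#' @return A list of [depletion_assay()] objects.
#' @export
read_depletion_assays <- function(path) {
  if (!file.exists(path)) pk_stop(paste("no such file:", path), "pk_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("species", "replicate", "time_min", "protein_mg_per_ml", "volume_ul")
  if (!all(req %in% names(df)))
    pk_stop(paste("missing column(s):", paste(setdiff(req, names(df)), collapse = ", ")),
            "pk_missing_column")
  value_col <- if ("remaining_percent" %in% names(df)) "remaining_percent"
               else if ("conc" %in% names(df)) "conc"
               else pk_stop("need a `remaining_percent` or `conc` column",
                            "pk_missing_column")
  key <- interaction(df$species, df$replicate, drop = TRUE)
  unname(lapply(split(df, key), function(g) {
    g <- g[order(g$time_min), , drop = FALSE]
    depletion_assay(g$species[1], g$time_min, g[[value_col]],
                    values_are = if (value_col == "conc") "concentration" else "percent",
                    protein_conc = g$protein_mg_per_ml[1],
                    volume_ul = g$volume_ul[1], replicate = g$replicate[1])
  }))
}

#' Read a paired pre/post analyte panel from CSV
#'
#' Columns: `analyte`, `subject_id`, `value_pre`, `value_post`.
#'
#' @param path CSV file path.
#' @return A data.frame suitable for [paired_panel_tests()].
#' @export
read_paired_panel <- function(path) {
  if (!file.exists(path)) pk_stop(paste("no such file:", path), "pk_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("analyte", "subject_id", "value_pre", "value_post")
  if (!all(req %in% names(df)))
    pk_stop(paste("missing column(s):", paste(setdiff(req, names(df)), collapse = ", ")),
            "pk_missing_column")
  df[req]
}
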