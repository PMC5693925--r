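# Table and configuration I/O. CSV schemas (headers normative):
#   fdnirs.csv:   subject_id, location, repetition, wavelength_nm, rho_cm,
#                 sample_index, ac_amplitude, phase_rad
#   dcs.csv:      subject_id, location, repetition, curve_index, tau_s, g2
#   subjects.csv: subject_id, sex, ga_weeks, postnatal_age_days, sao2_frac,
#                 hgb_g_dl (blank allowed)
#   results.csv:  one row per subject x location x repetition (wide; see
#                 run_pipeline)
# Units: cm, cm^-1, uM, fractions 0-1, cm^2/s; angles in radians.

.SCHEMAS <- list(
  fdnirs = list(
    required = c("subject_id", "location", "repetition", "wavelength_nm",
                 "rho_cm", "sample_index", "ac_amplitude", "phase_rad"),
    numeric = c("repetition", "wavelength_nm", "rho_cm", "sample_index",
                "ac_amplitude", "phase_rad")
  ),
  dcs = list(
    required = c("subject_id", "location", "repetition", "curve_index",
                 "tau_s", "g2"),
    numeric = c("repetition", "curve_index", "tau_s", "g2")
  ),
  subjects = list(
    required = c("subject_id", "sex", "ga_weeks", "postnatal_age_days",
                 "sao2_frac", "hgb_g_dl"),
    numeric = c("ga_weeks", "postnatal_age_days", "sao2_frac"),
    na_ok = "hgb_g_dl"
  ),
  results = list(
    required = c("subject_id", "location", "repetition"),
    numeric = character()
  )
)

read_table_checked <- function(path, schema_name) {
  schema <- .SCHEMAS[[schema_name]]
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0) {
    warning("empty ", schema_name, " table: ", path)
    return(tab)
  }
  missing <- setdiff(schema$required, names(tab))
  if (length(missing)) {
    stop(schema_name, " table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  for (col in schema$numeric) {
    v <- tab[[col]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(coerced) & !is.na(v) & v != "")
      if (length(bad)) {
        stop(schema_name, " table ", path, ": non-numeric '", col,
             "' at data row(s) ",
             paste(utils::head(bad, 10), collapse = ", "),
             if (length(bad) > 10) ", ..." else "")
      }
      tab[[col]] <- coerced
    }
    if (!identical(col, schema$na_ok) && anyNA(tab[[col]]) &&
        !col %in% schema$na_ok) {
      bad <- which(is.na(tab[[col]]))
      stop(schema_name, " table ", path, ": missing '", col,
           "' at data row(s) ", paste(utils::head(bad, 10), collapse = ", "))
    }
  }
  tab
}

#' Read / write pipeline tables
#'
#' CSV readers and writers for the four pipeline schemas (raw FDNIRS, raw
#' DCS, subjects, results). Readers validate required columns, coerce and
#' check numeric fields (reporting offending row numbers), preserve unknown
#' columns, and warn on empty files; write-then-read round trips are
#' lossless.
#'
#' @param path file path.
#' @param x table to write.
#' @return the table (readers), or \code{path} invisibly (writers).
#' @name pipeline_io
#' @export
read_fdnirs <- function(path) read_table_checked(path, "fdnirs")

#' @rdname pipeline_io
#' @export
read_dcs <- function(path) read_table_checked(path, "dcs")

#' @rdname pipeline_io
#' @export
read_subjects <- function(path) read_table_checked(path, "subjects")

#' @rdname pipeline_io
#' @export
read_results <- function(path) read_table_checked(path, "results")

write_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname pipeline_io
#' @export
write_fdnirs <- function(x, path) write_table(x, path)

#' @rdname pipeline_io
#' @export
write_dcs <- function(x, path) write_table(x, path)

#' @rdname pipeline_io
#' @export
write_subjects <- function(x, path) write_table(x, path)

#' @rdname pipeline_io
#' @export
write_results <- function(x, path) write_table(x, path)

#' Serialize a run configuration to / from JSON
#'
#' @param config a \code{\link{run_config}}.
#' @param path JSON file path.
#' @return \code{write_run_config}: the path, invisibly;
#'   \code{read_run_config}: a \code{run_config}.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$instrument <- unclass(x$instrument)
  x$cohort <- unclass(x$cohort)
  # named numeric vectors must become JSON objects, not nameless arrays
  x$thresholds <- as.list(x$thresholds)
  for (nm in c("sex_effects", "ga_slopes", "between_sd", "within_sd",
               "noise")) {
    x$cohort[[nm]] <- as.list(x$cohort[[nm]])
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  inst <- do.call(instrument_config, x$instrument)
  coh_args <- x$cohort
  coh_args$baseline <- as.list(coh_args$baseline)
  for (nm in c("sex_effects", "ga_slopes", "between_sd", "within_sd",
               "noise")) {
    coh_args[[nm]] <- unlist(coh_args[[nm]])
  }
  coh <- do.call(cohort_config, coh_args)
  run_config(instrument = inst, cohort = coh,
             thresholds = unlist(x$thresholds),
             water_fraction = x$water_fraction, gamma = x$gamma,
             kappa = x$kappa, fixed_musp_850 = x$fixed_musp_850,
             use_measured_musp = x$use_measured_musp, seed = x$seed)
}

#' Write a statistics report as JSON
#'
#' @param report a \code{\link{stats_report}}.
#' @param path output path.
#' @export
write_stats_json <- function(report, path) {
  strip <- function(x) {
    if (inherits(x, "stats_result")) unclass(x)
    else if (is.list(x)) lapply(x, strip)
    else x
  }
  jsonlite::write_json(strip(unclass(report)), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
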