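# Group-level inference: mixed-effects contrasts, correlations, t-tests.

stats_result <- function(parameter, contrast, estimate, se, p_value, n_obs,
                         model, singular = FALSE, fallback = FALSE) {
  structure(list(parameter = parameter, contrast = contrast,
                 estimate = estimate, se = se, p_value = p_value,
                 n_obs = n_obs, model = model, singular = singular,
                 fallback = fallback),
            class = "stats_result")
}

#' @export
print.stats_result <- function(x, ...) {
  cat(sprintf("%s [%s]: estimate = %.4g (SE %.3g), p = %.4g, n = %d\n",
              x$parameter, x$contrast, x$estimate, x$se, x$p_value, x$n_obs))
  cat(sprintf("  model: %s%s%s\n", x$model,
              if (isTRUE(x$singular)) "  [singular random effects]" else "",
              if (isTRUE(x$fallback)) "  [t-test fallback]" else ""))
  invisible(x)
}

# records must carry: subject_id, side, lobe, sex, ga_weeks and the parameter
check_records <- function(records, parameter, extra = character()) {
  need <- c("subject_id", "side", "lobe", parameter, extra)
  missing <- setdiff(need, names(records))
  if (length(missing)) stop("records lack column(s): ",
                            paste(missing, collapse = ", "))
  records[is.finite(records[[parameter]]), , drop = FALSE]
}

subject_means <- function(records, parameter, by = "subject_id") {
  agg <- stats::aggregate(records[[parameter]],
                          by = lapply(by, function(b) records[[b]]),
                          FUN = mean)
  names(agg) <- c(by, parameter)
  agg
}

#' Mixed-effects sex contrast
#'
#' Fits a linear mixed-effects model with sex as the fixed effect and random
#' intercepts for subject, hemisphere side and lobe — accounting for the
#' unequal numbers of repeated measurements per subject and location — and
#' returns the female-minus-male contrast with its Satterthwaite p-value.
#' Restricting \code{lobe} analyses the per-lobe subset (dropping the lobe
#' random intercept). If the solver fails outright, the function falls back
#' to a two-sample t-test on subject means (flagged in the result); a
#' singular random-effects fit (a variance component estimated at zero) is
#' retained and flagged, not discarded.
#'
#' @param records measurement-level data.frame with columns
#'   \code{subject_id}, \code{side}, \code{lobe}, \code{sex} and the
#'   response.
#' @param parameter name of the response column (e.g. \code{"hbt_um"}).
#' @param lobe optional lobe restriction (\code{"frontal"}, \code{"temporal"},
#'   \code{"parietal"}).
#' @return a \code{stats_result}: estimate (F - M), SE, p-value, n.
#' @export
lme_sex_contrast <- function(records, parameter, lobe = NULL) {
  records <- check_records(records, parameter, extra = "sex")
  if (!is.null(lobe)) records <- records[records$lobe == lobe, , drop = FALSE]
  if (length(unique(records$sex)) < 2) stop("need both sexes in records")
  records$sex <- factor(records$sex, levels = c("M", "F"))
  records$.y <- records[[parameter]]
  if (stats::var(records$.y) == 0) {
    return(stats_result(parameter, "F-M", 0, 0, 1, nrow(records),
                        "degenerate: constant response"))
  }
  form <- if (is.null(lobe)) {
    .y ~ sex + (1 | subject_id) + (1 | side) + (1 | lobe)
  } else {
    .y ~ sex + (1 | subject_id) + (1 | side)
  }
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(form, data = records)
    )),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    warning("mixed model failed (", conditionMessage(fit),
            "); falling back to t-test on subject means")
    sm <- subject_means(records, ".y")
    sm$sex <- records$sex[match(sm$subject_id, records$subject_id)]
    tt <- stats::t.test(.y ~ sex, data = sm)
    return(stats_result(parameter, "F-M",
                        unname(tt$estimate[2] - tt$estimate[1]),
                        unname(tt$stderr), tt$p.value, nrow(records),
                        "two-sample t-test on subject means",
                        fallback = TRUE))
  }
  co <- stats::coef(summary(fit))["sexF", ]
  stats_result(parameter, "F-M", unname(co["Estimate"]),
               unname(co["Std. Error"]), unname(co["Pr(>|t|)"]),
               nrow(records),
               paste("LME:", deparse(form)),
               singular = lme4::isSingular(fit))
}

#' Mixed-effects gestational-age trend
#'
#' Linear mixed model with gestational age (weeks) as the fixed effect and
#' random intercepts for subject, side, lobe and sex; returns the per-week
#' slope.
#'
#' @inheritParams lme_sex_contrast
#' @return a \code{stats_result} with the GA slope (units of the parameter
#'   per week).
#' @export
lme_ga_trend <- function(records, parameter) {
  records <- check_records(records, parameter, extra = c("sex", "ga_weeks"))
  if (stats::var(records$ga_weeks) == 0) {
    stop("gestational age does not vary in the cohort")
  }
  records$.y <- records[[parameter]]
  form <- .y ~ ga_weeks + (1 | subject_id) + (1 | side) + (1 | lobe) + (1 | sex)
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(form, data = records)
    )),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    warning("mixed model failed (", conditionMessage(fit),
            "); falling back to OLS on subject means")
    sm <- subject_means(records, ".y")
    sm$ga_weeks <- records$ga_weeks[match(sm$subject_id,
                                          records$subject_id)]
    lmfit <- stats::lm(.y ~ ga_weeks, data = sm)
    co <- stats::coef(summary(lmfit))["ga_weeks", ]
    return(stats_result(parameter, "GA slope", unname(co["Estimate"]),
                        unname(co["Std. Error"]), unname(co["Pr(>|t|)"]),
                        nrow(records), "OLS on subject means",
                        fallback = TRUE))
  }
  co <- stats::coef(summary(fit))["ga_weeks", ]
  stats_result(parameter, "GA slope", unname(co["Estimate"]),
               unname(co["Std. Error"]), unname(co["Pr(>|t|)"]),
               nrow(records), paste("LME:", deparse(form)),
               singular = lme4::isSingular(fit))
}

#' Pearson correlation between gestational age and a parameter
#'
#' Computed on subject-level means, as for the reported GA correlations.
#'
#' @inheritParams lme_sex_contrast
#' @param subjects subjects table providing \code{ga_weeks} (ignored if the
#'   records already carry it).
#' @return list with \code{r}, \code{p_value}, \code{n}.
#' @export
pearson_ga <- function(records, parameter, subjects = NULL) {
  if (!"ga_weeks" %in% names(records)) {
    if (is.null(subjects)) stop("records lack ga_weeks and no subjects table given")
    records$ga_weeks <- subjects$ga_weeks[
      match(records$subject_id, subjects$subject_id)]
  }
  records <- records[is.finite(records[[parameter]]), , drop = FALSE]
  sm <- subject_means(records, parameter)
  sm$ga_weeks <- records$ga_weeks[match(sm$subject_id, records$subject_id)]
  if (nrow(sm) < 3) stop("need at least 3 subjects")
  if (stats::var(sm[[parameter]]) == 0 || stats::var(sm$ga_weeks) == 0) {
    warning("zero variance: correlation undefined")
    return(list(r = NA_real_, p_value = NA_real_, n = nrow(sm)))
  }
  ct <- stats::cor.test(sm$ga_weeks, sm[[parameter]])
  list(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(sm))
}

#' Two-sample t-test on a demographic field
#'
#' Compares male and female subjects on one demographic/physical field
#' (Welch two-sample t-test).
#'
#' @param subjects subjects table with a \code{sex} column.
#' @param field column to compare.
#' @return a \code{stats_result}.
#' @export
demographics_ttest <- function(subjects, field) {
  if (!all(c("sex", field) %in% names(subjects))) {
    stop("subjects table lacks 'sex' or '", field, "'")
  }
  x <- subjects[[field]][subjects$sex == "M"]
  y <- subjects[[field]][subjects$sex == "F"]
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 subjects per sex")
  if (stats::var(c(x, y)) == 0) {
    return(stats_result(field, "F-M", 0, 0, 1, length(x) + length(y),
                        "degenerate: constant field"))
  }
  tt <- stats::t.test(y, x)
  stats_result(field, "F-M", unname(tt$estimate[1] - tt$estimate[2]),
               unname(tt$stderr), tt$p.value, length(x) + length(y),
               "Welch two-sample t-test")
}

#' Aggregate probe repetitions
#'
#' Collapses the repeated probe placements at each subject x location to
#' their median (across QC-passed repetitions only). Locations whose
#' repetitions all failed QC are dropped and listed in the
#' \code{"missing"} attribute.
#'
#' @param records per-repetition records.
#' @param parameters numeric columns to aggregate (default: all numeric
#'   except identifiers).
#' @param qc optional logical vector / column name marking usable rows.
#' @return per subject x location data.frame (median of each parameter),
#'   keeping \code{side}, \code{lobe}, \code{sex}, \code{ga_weeks},
#'   \code{sao2_frac} labels when present.
#' @export
aggregate_repetitions <- function(records, parameters = NULL, qc = NULL) {
  if (nrow(records) == 0) stop("no records")
  usable <- if (is.null(qc)) {
    rep(TRUE, nrow(records))
  } else if (is.character(qc)) {
    isTRUE_vec(records[[qc]])
  } else {
    isTRUE_vec(qc)
  }
  all_keys <- unique(records[, c("subject_id", "location")])
  kept <- records[usable, , drop = FALSE]
  if (nrow(kept) == 0) stop("all repetitions failed QC")
  if (is.null(parameters)) {
    skip <- c("repetition")
    parameters <- names(kept)[vapply(kept, is.numeric, logical(1))]
    parameters <- setdiff(parameters, skip)
  }
  key <- paste(kept$subject_id, kept$location, sep = "\r")
  idx <- split(seq_len(nrow(kept)), key)
  first <- vapply(idx, `[`, integer(1), 1L)
  out <- kept[first, setdiff(names(kept), c("repetition", parameters)),
              drop = FALSE]
  for (p in parameters) {
    out[[p]] <- vapply(idx, function(i) stats::median(kept[[p]][i]),
                       numeric(1))
  }
  rownames(out) <- NULL
  have <- unique(out[, c("subject_id", "location")])
  miss <- all_keys[!paste(all_keys$subject_id, all_keys$location) %in%
                     paste(have$subject_id, have$location), , drop = FALSE]
  attr(out, "missing") <- miss
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Hemispheric percent difference
#'
#' Percent right-minus-left difference of a parameter across the lateralized
#' sites: subject-level side means are averaged over the cohort and the
#' difference reported as \eqn{100\,(\bar{x}_R - \bar{x}_L)/\bar{x}_L}, with a
#' paired t-test over subjects with both sides available.
#'
#' @param records per-measurement or aggregated records with \code{side}.
#' @param parameter response column (default the flow index).
#' @return a \code{stats_result} whose estimate is the percent difference.
#' @export
hemisphere_percent_diff <- function(records, parameter = "cbfi_cm2s") {
  records <- check_records(records, parameter)
  records <- records[records$side %in% c("left", "right"), , drop = FALSE]
  if (nrow(records) == 0) stop("no lateralized records")
  sm <- subject_means(records, parameter, by = c("subject_id", "side"))
  mean_l <- mean(sm[[parameter]][sm$side == "left"])
  mean_r <- mean(sm[[parameter]][sm$side == "right"])
  pct <- 100 * (mean_r - mean_l) / mean_l
  wide <- merge(sm[sm$side == "left", c("subject_id", parameter)],
                sm[sm$side == "right", c("subject_id", parameter)],
                by = "subject_id", suffixes = c("_l", "_r"))
  p <- se <- NA_real_
  if (nrow(wide) >= 2) {
    d <- wide[[paste0(parameter, "_r")]] - wide[[paste0(parameter, "_l")]]
    if (stats::sd(d) > 0) {
      tt <- stats::t.test(d)
      p <- tt$p.value
      se <- 100 * unname(tt$stderr) / mean_l
    } else {
      p <- if (all(d == 0)) 1 else 0
      se <- 0
    }
  }
  stats_result(parameter, "right-left %", pct, se, p, nrow(records),
               "percent difference of cohort side means (paired t-test)")
}

#' Full statistics report
#'
#' Runs the study's statistical stage on a results table: sex contrasts
#' (overall and per lobe) and GA trends for HbT, SO2, CBFi and CMRO2i,
#' Pearson GA correlations for HbT and SO2 on subject means, the hemispheric
#' percent differences for CBFi and CMRO2i, and demographic t-tests.
#'
#' @param records measurement-level records carrying \code{subject_id},
#'   \code{location}, \code{side}, \code{lobe}, \code{sex}, \code{ga_weeks}
#'   and the hemodynamic columns.
#' @param subjects subjects table (for the demographic t-tests).
#' @param parameters hemodynamic columns to test.
#' @return list of class \code{stats_report} (JSON-serializable via
#'   \code{\link{write_stats_json}}).
#' @export
stats_report <- function(records, subjects,
                         parameters = c("hbt_um", "so2_frac",
                                        "cbfi_cm2s", "cmro2i")) {
  res <- list()
  res$sex <- lapply(setNames(parameters, parameters), function(p) {
    lme_sex_contrast(records, p)
  })
  lobes <- intersect(c("frontal", "temporal", "parietal"),
                     unique(records$lobe))
  res$sex_by_lobe <- lapply(setNames(lobes, lobes), function(lb) {
    lapply(setNames(parameters, parameters), function(p) {
      tryCatch(lme_sex_contrast(records, p, lobe = lb),
               error = function(e) NULL)
    })
  })
  res$ga <- lapply(setNames(parameters, parameters), function(p) {
    lme_ga_trend(records, p)
  })
  res$pearson_ga <- lapply(setNames(c("hbt_um", "so2_frac"),
                                    c("hbt_um", "so2_frac")), function(p) {
    pearson_ga(records, p)
  })
  res$hemisphere <- lapply(setNames(c("cbfi_cm2s", "cmro2i"),
                                    c("cbfi_cm2s", "cmro2i")), function(p) {
    hemisphere_percent_diff(records, p)
  })
  demo <- intersect(c("ga_weeks", "postnatal_age_days", "sao2_frac"),
                    names(subjects))
  res$demographics <- lapply(setNames(demo, demo), function(f) {
    demographics_ttest(subjects, f)
  })
  class(res) <- "stats_report"
  res
}
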