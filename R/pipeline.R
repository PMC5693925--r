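# End-to-end orchestration: simulate -> calibrate -> fit -> derive -> stats.

#' Pipeline run configuration
#'
#' Collects the instrument, cohort, QC thresholds and physiological constants
#' of one end-to-end run; serializable to a single JSON document via
#' \code{\link{write_run_config}}.
#'
#' @param instrument an \code{\link{instrument_config}}.
#' @param cohort a \code{\link{cohort_config}} (used when simulating).
#' @param thresholds named vector: \code{phase_noise} (rad),
#'   \code{slope_r2}, \code{spectral_p}, \code{spectral_r2}.
#' @param water_fraction assumed brain water fraction.
#' @param gamma venous fraction of the optical signal.
#' @param kappa oxygen per gram hemoglobin, mL O2/g.
#' @param fixed_musp_850 scattering coefficient assumed in the DCS fit,
#'   cm^-1 (study convention: the cohort-average 6.4).
#' @param use_measured_musp if \code{TRUE}, use each measurement's own
#'   extrapolated 850 nm scattering instead of \code{fixed_musp_850}.
#' @param phantom_mua,phantom_musp known optical properties of the
#'   calibration phantom, one per wavelength (defaults: a flat 0.1 cm^-1
#'   absorber with power-law scattering).
#' @param seed integer seed governing all randomness of the run.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(instrument = instrument_config(),
                       cohort = cohort_config(),
                       thresholds = c(phase_noise = 0.05, slope_r2 = 0.95,
                                      spectral_p = 0.03, spectral_r2 = 0.6),
                       water_fraction = 0.75,
                       gamma = 0.75,
                       kappa = 1.34,
                       fixed_musp_850 = 6.4,
                       use_measured_musp = FALSE,
                       phantom_mua = NULL,
                       phantom_musp = NULL,
                       seed = 1L) {
  stopifnot(thresholds[["phase_noise"]] > 0,
            thresholds[["slope_r2"]] >= 0, thresholds[["slope_r2"]] <= 1,
            thresholds[["spectral_p"]] >= 0, thresholds[["spectral_p"]] <= 1,
            thresholds[["spectral_r2"]] >= 0, thresholds[["spectral_r2"]] <= 1,
            water_fraction >= 0, water_fraction <= 1,
            gamma > 0, gamma <= 1, kappa > 0, fixed_musp_850 > 0)
  wl <- instrument$fdnirs_wavelengths
  if (is.null(phantom_mua)) phantom_mua <- rep(0.1, length(wl))
  if (is.null(phantom_musp)) phantom_musp <- evaluate_mie(10, 1.0, wl)
  stopifnot(length(phantom_mua) == length(wl),
            length(phantom_musp) == length(wl))
  cohort$seed <- as.integer(seed)
  structure(list(instrument = instrument, cohort = cohort,
                 thresholds = thresholds, water_fraction = water_fraction,
                 gamma = gamma, kappa = kappa,
                 fixed_musp_850 = fixed_musp_850,
                 use_measured_musp = use_measured_musp,
                 phantom_mua = phantom_mua, phantom_musp = phantom_musp,
                 seed = as.integer(seed)),
            class = "run_config")
}

# fast integer grouping id over parallel key columns
group_id <- function(...) {
  cols <- list(...)
  id <- rep(1L, length(cols[[1]]))
  stride <- 1
  for (col in cols) {
    f <- if (is.integer(col)) col else match(col, unique(col))
    id <- id + (f - 1L) * stride
    stride <- stride * max(f)
  }
  id
}

# split() without its factor-coercion overhead on large integer keys
split_fast <- function(n, key) {
  uk <- unique(key)
  f <- structure(match(key, uk), levels = as.character(uk), class = "factor")
  split(seq_len(n), f)
}

# Reduce raw FDNIRS rows to per-channel medians + phase noise.
reduce_fdnirs <- function(raw) {
  key <- group_id(match(raw$rho_cm, sort(unique(raw$rho_cm))),
                  match(raw$wavelength_nm, sort(unique(raw$wavelength_nm))),
                  as.integer(raw$repetition),
                  match(raw$location, unique(raw$location)),
                  match(raw$subject_id, unique(raw$subject_id)))
  idx <- split_fast(nrow(raw), key)
  first <- vapply(idx, `[`, integer(1), 1L)
  out <- raw[first, c("subject_id", "location", "repetition",
                      "wavelength_nm", "rho_cm")]
  out$ac_median <- vapply(idx, function(i) stats::median(raw$ac_amplitude[i]),
                          numeric(1))
  out$phase_median <- vapply(idx, function(i) stats::median(raw$phase_rad[i]),
                             numeric(1))
  out$phase_noise <- vapply(idx, function(i) {
    if (length(i) > 1) stats::sd(raw$phase_rad[i]) else 0
  }, numeric(1))
  rownames(out) <- NULL
  out[order(out$subject_id, out$location, out$repetition,
            out$wavelength_nm, out$rho_cm), ]
}

# Average the DCS curves of every measurement.
reduce_dcs <- function(dcs) {
  ord <- order(dcs$subject_id, dcs$location, dcs$repetition,
               dcs$curve_index, dcs$tau_s)
  dcs <- dcs[ord, ]
  key <- group_id(as.integer(dcs$repetition),
                  match(dcs$location, unique(dcs$location)),
                  match(dcs$subject_id, unique(dcs$subject_id)))
  idx <- split_fast(nrow(dcs), key)
  out <- lapply(idx, function(i) {
    tau <- unique(dcs$tau_s[i])
    ncv <- length(i) / length(tau)
    g2m <- matrix(dcs$g2[i], nrow = length(tau))
    list(subject_id = dcs$subject_id[i[1]],
         location = dcs$location[i[1]],
         repetition = dcs$repetition[i[1]],
         tau = tau, g2_mean = rowMeans(g2m), n_curves = ncv)
  })
  names(out) <- vapply(out, function(d) {
    paste(d$subject_id, d$location, d$repetition, sep = "\r")
  }, character(1))
  out
}

#' Fit all measurements of a cohort
#'
#' The per-measurement chain: temporal medians per channel, multi-distance
#' slope inversion per wavelength with QC, chromophore and scattering
#' spectral fits with QC, extrapolation to 850 nm, DCS curve averaging and
#' correlation-diffusion fitting, and hemodynamic derivation. Input FDNIRS
#' data should already be calibrated (\code{\link{apply_calibration}}).
#'
#' @param fdnirs calibrated raw FDNIRS table.
#' @param dcs raw DCS table.
#' @param subjects subjects table (supplies SaO2 per subject).
#' @param config a \code{\link{run_config}}.
#' @param table an \code{\link{extinction_table}}.
#' @return list with \code{results} (wide per-measurement data.frame) and
#'   \code{qc_log} (one row per QC rejection: measurement, stage, rule,
#'   value).
#' @export
fit_measurements <- function(fdnirs, dcs, subjects,
                             config = run_config(),
                             table = extinction_table()) {
  instrument <- config$instrument
  th <- config$thresholds
  wl <- instrument$fdnirs_wavelengths
  med <- reduce_fdnirs(fdnirs)
  dcs_means <- reduce_dcs(dcs)

  meas_key <- unique(med[, c("subject_id", "location", "repetition")])
  rownames(meas_key) <- NULL
  n <- nrow(meas_key)
  qc_rows <- list()
  log_qc <- function(id, stage, rule, value) {
    qc_rows[[length(qc_rows) + 1L]] <<- data.frame(
      measurement = id, stage = stage, rule = rule, value = value,
      stringsAsFactors = FALSE)
  }

  empty <- rep(NA_real_, n)
  res <- meas_key
  for (w in wl) {
    res[[paste0("mua_", w)]] <- empty
    res[[paste0("musp_", w)]] <- empty
  }
  res$a_500 <- empty; res$b_power <- empty
  res$hbo_um <- empty; res$hbr_um <- empty; res$hbt_um <- empty
  res$so2_frac <- empty
  res$mua850 <- empty; res$musp850 <- empty
  res$cbfi_cm2s <- empty; res$beta <- empty
  res$oef <- empty; res$cmro2i <- empty
  res$qc_fdnirs <- FALSE; res$qc_spectral <- FALSE; res$qc_dcs <- FALSE

  for (m in seq_len(n)) {
    id <- paste(meas_key$subject_id[m], meas_key$location[m],
                meas_key$repetition[m], sep = "/")
    rows_m <- med[med$subject_id == meas_key$subject_id[m] &
                    med$location == meas_key$location[m] &
                    med$repetition == meas_key$repetition[m], ]
    mua_w <- rep(NA_real_, length(wl))
    musp_w <- rep(NA_real_, length(wl))
    pass_w <- rep(FALSE, length(wl))
    for (j in seq_along(wl)) {
      ch <- rows_m[rows_m$wavelength_nm == wl[j], ]
      if (nrow(ch) < 3) next
      fit <- multidistance_fit(ch$ac_median, ch$phase_median, ch$rho_cm,
                               instrument,
                               phase_noise = max(ch$phase_noise))
      mua_w[j] <- fit$mua; musp_w[j] <- fit$musp
      ok <- fdnirs_qc(fit, th[["phase_noise"]], th[["slope_r2"]])
      if (!ok) {
        rule <- if (!isTRUE(fit$valid)) "unphysical slopes"
        else if (fit$phase_noise > th[["phase_noise"]]) "phase noise"
        else "slope R2"
        val <- if (identical(rule, "phase noise")) fit$phase_noise
        else min(fit$r2_ac, fit$r2_phase)
        log_qc(id, "fdnirs", paste0(rule, " @", wl[j], "nm"), val)
      }
      pass_w[j] <- ok
    }
    res[m, paste0("mua_", wl)] <- mua_w
    res[m, paste0("musp_", wl)] <- musp_w
    res$qc_fdnirs[m] <- sum(pass_w) >= 2

    chromo <- scatter <- NULL
    if (res$qc_fdnirs[m]) {
      chromo <- fit_chromophores(mua_w[pass_w], wl[pass_w], table,
                                 config$water_fraction)
      scatter <- fit_scattering_model(musp_w[pass_w], wl[pass_w])
      res$hbo_um[m] <- chromo$hbo; res$hbr_um[m] <- chromo$hbr
      res$hbt_um[m] <- chromo$hbt; res$so2_frac[m] <- chromo$so2
      res$a_500[m] <- scatter$a_500; res$b_power[m] <- scatter$b_power
      qc_c <- spectral_qc(chromo$fit_r2, chromo$fit_pvalue,
                          th[["spectral_p"]], th[["spectral_r2"]])
      qc_s <- spectral_qc(scatter$fit_r2, scatter$fit_pvalue,
                          th[["spectral_p"]], th[["spectral_r2"]])
      if (!qc_c) log_qc(id, "spectral", "chromophore fit quality",
                        chromo$fit_r2)
      if (!qc_s) log_qc(id, "spectral", "scattering fit quality",
                        scatter$fit_r2)
      res$qc_spectral[m] <- qc_c && qc_s
      if (res$qc_spectral[m]) {
        ext <- extrapolate_to_dcs(chromo, scatter, table,
                                  config$water_fraction,
                                  instrument$dcs_wavelength)
        res$mua850[m] <- ext$mua; res$musp850[m] <- ext$musp
      }
    } else {
      log_qc(id, "fdnirs", "fewer than 2 usable wavelengths", sum(pass_w))
    }

    dm <- dcs_means[[paste(meas_key$subject_id[m], meas_key$location[m],
                           meas_key$repetition[m], sep = "\r")]]
    if (!is.null(dm) && res$qc_spectral[m]) {
      musp_fit <- if (isTRUE(config$use_measured_musp)) res$musp850[m]
                  else config$fixed_musp_850
      dfit <- fit_cbfi(dm$g2_mean, mua = res$mua850[m], musp = musp_fit,
                       instrument = instrument, tau = dm$tau)
      res$cbfi_cm2s[m] <- dfit$cbfi
      res$beta[m] <- dfit$beta
      res$qc_dcs[m] <- dfit$converged && !dfit$degenerate &&
        dfit$beta > 0 && dfit$beta <= 1
      if (!res$qc_dcs[m]) {
        log_qc(id, "dcs",
               if (!dfit$converged) "non-convergence" else "degenerate fit",
               dfit$residual_ss)
      }
    } else if (is.null(dm)) {
      log_qc(id, "dcs", "no DCS curves", NA_real_)
    }
  }

  sao2 <- subjects$sao2_frac[match(res$subject_id, subjects$subject_id)]
  hemo <- derive_hemodynamics(res$so2_frac, res$cbfi_cm2s, sao2,
                              gamma = config$gamma, kappa = config$kappa)
  res$oef <- hemo$oef
  res$cmro2i <- hemo$cmro2i
  neg <- which(isTRUE_vec(hemo$negative_oef))
  for (m in neg) {
    log_qc(paste(res$subject_id[m], res$location[m], res$repetition[m],
                 sep = "/"),
           "hemodynamics", "SO2 exceeds SaO2 (negative OEF)", res$oef[m])
  }
  qc_log <- if (length(qc_rows)) do.call(rbind, qc_rows) else
    data.frame(measurement = character(), stage = character(),
               rule = character(), value = numeric())
  list(results = res, qc_log = qc_log)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Orchestrates, deterministically under \code{config$seed}: cohort and
#' phantom simulation (with shared per-channel instrument distortions),
#' phantom calibration, per-measurement fitting
#' (\code{\link{fit_measurements}}), hemodynamic derivation, and the group
#' statistics stage. Every QC rejection is recorded in the returned
#' \code{qc_log} with measurement id, rule and value.
#'
#' @param config a \code{\link{run_config}}.
#' @param out_dir optional directory; when given, writes
#'   \code{subjects.csv}, \code{results.csv}, \code{qc_log.csv},
#'   \code{stats.json} and \code{config.json} there.
#' @param run_stats set \code{FALSE} to skip the statistics stage.
#' @return object of class \code{neoflow_run}: list with \code{subjects},
#'   \code{truth}, \code{calibration}, \code{results}, \code{qc_log},
#'   \code{stats}, \code{config}.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         run_stats = TRUE) {
  table <- extinction_table()
  sim <- simulate_cohort(config$cohort, config$instrument, table)
  phantom <- simulate_phantom(config$phantom_mua, config$phantom_musp,
                              config$instrument, channels = sim$channels,
                              noise_ln_ac = config$cohort$noise[["fdnirs_ln_ac"]],
                              noise_phase = config$cohort$noise[["fdnirs_phase"]])
  cal <- calibrate(phantom, config$phantom_mua, config$phantom_musp,
                   config$instrument)
  fdnirs_cal <- apply_calibration(sim$fdnirs, cal)
  fitted <- fit_measurements(fdnirs_cal, sim$dcs, sim$subjects, config, table)
  results <- fitted$results
  results$side <- location_side(results$location)
  results$lobe <- location_lobe(results$location)
  results$sex <- sim$subjects$sex[match(results$subject_id,
                                        sim$subjects$subject_id)]
  results$ga_weeks <- sim$subjects$ga_weeks[match(results$subject_id,
                                                  sim$subjects$subject_id)]
  stats <- NULL
  if (run_stats) {
    usable <- results$qc_fdnirs & results$qc_spectral & results$qc_dcs
    stats <- stats_report(results[usable, , drop = FALSE], sim$subjects)
  }
  out <- structure(list(subjects = sim$subjects, truth = sim$truth,
                        calibration = cal, results = results,
                        qc_log = fitted$qc_log, stats = stats,
                        config = config),
                   class = "neoflow_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_subjects(sim$subjects, file.path(out_dir, "subjects.csv"))
    write_results(results, file.path(out_dir, "results.csv"))
    write_table(fitted$qc_log, file.path(out_dir, "qc_log.csv"))
    if (!is.null(stats)) write_stats_json(stats,
                                          file.path(out_dir, "stats.json"))
    write_run_config(config, file.path(out_dir, "config.json"))
  }
  out
}

#' @export
print.neoflow_run <- function(x, ...) {
  r <- x$results
  usable <- r$qc_fdnirs & r$qc_spectral & r$qc_dcs
  cat(sprintf("neoflow pipeline run (seed %d)\n", x$config$seed))
  cat(sprintf("  %d subjects, %d measurements, %d (%.0f%%) passing all QC\n",
              nrow(x$subjects), nrow(r), sum(usable),
              100 * mean(usable)))
  if (any(usable)) {
    cat(sprintf("  medians over usable measurements: HbT %.1f uM, SO2 %.1f%%, CBFi %.3g cm^2/s\n",
                stats::median(r$hbt_um[usable]),
                100 * stats::median(r$so2_frac[usable]),
                stats::median(r$cbfi_cm2s[usable])))
  }
  cat(sprintf("  QC rejections logged: %d\n", nrow(x$qc_log)))
  invisible(x)
}

#' @export
summary.neoflow_run <- function(object, ...) {
  r <- object$results
  usable <- r$qc_fdnirs & r$qc_spectral & r$qc_dcs
  u <- r[usable, , drop = FALSE]
  cat("Cohort parameter summary (usable measurements, mean +/- sd):\n")
  for (p in c("hbt_um", "so2_frac", "cbfi_cm2s", "a_500", "b_power",
              "oef", "cmro2i")) {
    cat(sprintf("  %-10s %.4g +/- %.3g\n", p, mean(u[[p]]),
                stats::sd(u[[p]])))
  }
  if (!is.null(object$stats)) {
    cat("\nHemispheric CBFi difference:\n  ")
    print(object$stats$hemisphere$cbfi_cm2s)
    cat("Sex contrasts (F-M):\n")
    for (s in object$stats$sex) { cat("  "); print(s) }
  }
  invisible(object)
}
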