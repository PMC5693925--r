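# Group statistics: mixed-effects contrasts, correlations, t-tests,
# aggregation.

test_that("sex contrast is zero for identical responses and recovers injected effects", {
  sim <- simulate_cohort(null_cohort_config(zero_noise = TRUE, seed = 3),
                         emit_raw = FALSE)
  rec <- truth_records(sim)
  r0 <- lme_sex_contrast(rec, "hbt_um")
  expect_equal(r0$estimate, 0)
  expect_equal(r0$p_value, 1)

  # deterministic injected effect: contrast = (factor - 1) * baseline exactly
  sim2 <- simulate_cohort(
    null_cohort_config(zero_noise = TRUE, sex_effects = c(hbt = 0.9, so2 = 1,
                                                          cbfi = 1),
                       seed = 3),
    emit_raw = FALSE)
  rec2 <- truth_records(sim2)
  r2 <- lme_sex_contrast(rec2, "hbt_um")
  expect_equal(r2$estimate, 54 * (0.9 - 1), tolerance = 1e-6)
})

test_that("injected sex effect direction is recovered in nearly all seeds", {
  signs <- vapply(1:40, function(s) {
    sim <- simulate_cohort(
      null_cohort_config(sex_effects = c(hbt = 1, so2 = 1, cbfi = 1.4),
                         seed = 400 + s),
      emit_raw = FALSE)
    sign(lme_sex_contrast(truth_records(sim), "cbfi_cm2s")$estimate)
  }, numeric(1))
  expect_gte(mean(signs > 0), 0.95)
})

test_that("GA trend recovers an injected slope on noise-free data", {
  sim <- simulate_cohort(
    null_cohort_config(zero_noise = TRUE, ga_slopes = c(hbt = 7, so2 = 0),
                       seed = 12),
    emit_raw = FALSE)
  rec <- truth_records(sim)
  r <- lme_ga_trend(rec, "hbt_um")
  expect_equal(r$estimate, 7, tolerance = 0.01)
  # degenerate design: constant GA
  rec$ga_weeks <- 39
  expect_error(lme_ga_trend(rec, "hbt_um"), "does not vary")
})

test_that("Pearson GA correlation behaves at the extremes and on simulated cohorts", {
  rec <- data.frame(subject_id = sprintf("S%02d", 1:10),
                    side = "left", lobe = "frontal",
                    ga_weeks = seq(37, 41, length.out = 10))
  rec$hbt_um <- 2 * rec$ga_weeks - 10
  expect_equal(pearson_ga(rec, "hbt_um")$r, 1, tolerance = 1e-12)
  rec$hbt_um <- -rec$hbt_um
  expect_equal(pearson_ga(rec, "hbt_um")$r, -1, tolerance = 1e-12)
  # cohort-level: configured GA effect and noise give R in a plausible band
  rs <- vapply(1:10, function(s) {
    sim <- simulate_cohort(cohort_config(seed = 700 + s), emit_raw = FALSE)
    pearson_ga(truth_records(sim), "hbt_um")$r
  }, numeric(1))
  expect_gt(mean(rs), 0.25)
  expect_lt(mean(rs), 0.75)
})

test_that("demographic t-test matches a permutation oracle on small samples", {
  set.seed(14)
  for (i in 1:10) {
    n_m <- 26; n_f <- 22
    subjects <- data.frame(
      subject_id = sprintf("S%02d", seq_len(n_m + n_f)),
      sex = rep(c("M", "F"), times = c(n_m, n_f)),
      ga_weeks = rnorm(n_m + n_f, 39, 1.2))
    r <- demographics_ttest(subjects, "ga_weeks")
    # permutation distribution of the mean difference
    obs <- abs(mean(subjects$ga_weeks[subjects$sex == "F"]) -
                 mean(subjects$ga_weeks[subjects$sex == "M"]))
    perm <- replicate(4000, {
      s <- sample(subjects$sex)
      abs(mean(subjects$ga_weeks[s == "F"]) -
            mean(subjects$ga_weeks[s == "M"]))
    })
    expect_lt(abs(r$p_value - mean(perm >= obs - 1e-12)), 0.02)
  }
})

test_that("t-test degenerate and shifted cases", {
  subjects <- data.frame(subject_id = 1:10,
                         sex = rep(c("M", "F"), each = 5),
                         w = rep(3.5, 10))
  r <- demographics_ttest(subjects, "w")
  expect_equal(r$estimate, 0)
  expect_equal(r$p_value, 1)
  subjects$w <- c(rnorm(5, 0, 0.01), rnorm(5, 10, 0.01))
  expect_lt(demographics_ttest(subjects, "w")$p_value, 1e-6)
  expect_error(demographics_ttest(subjects[c(1, 6:10), ], "w"), ">= 2")
})

test_that("repetition aggregation takes medians over QC-passed rows", {
  rec <- data.frame(
    subject_id = rep("S01", 5),
    location = c(rep("frontal_left", 3), rep("frontal_right", 2)),
    side = c(rep("left", 3), rep("right", 2)),
    lobe = "frontal",
    repetition = c(1, 2, 3, 1, 2),
    cbfi_cm2s = c(1, 2, 100, 4, 6),
    qc = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  agg <- aggregate_repetitions(rec, parameters = "cbfi_cm2s", qc = "qc")
  expect_equal(nrow(agg), 2)
  expect_equal(agg$cbfi_cm2s[agg$location == "frontal_left"], 2) # outlier-robust
  expect_equal(agg$cbfi_cm2s[agg$location == "frontal_right"], 4) # passthrough
  # all repetitions failing QC drops the location and reports it
  rec$qc[4:5] <- FALSE
  agg2 <- aggregate_repetitions(rec, parameters = "cbfi_cm2s", qc = "qc")
  expect_equal(nrow(agg2), 1)
  expect_equal(attr(agg2, "missing")$location, "frontal_right")
})

test_that("hemispheric percent difference recovers a deterministic injected ratio", {
  sim <- simulate_cohort(null_cohort_config(zero_noise = TRUE,
                                            hemisphere_effect = 1.152,
                                            seed = 6),
                         emit_raw = FALSE)
  r <- hemisphere_percent_diff(sim$truth, "cbfi_cm2s")
  expect_equal(r$estimate, 15.2, tolerance = 1e-10)
})

test_that("stats_report assembles all study analyses", {
  sim <- simulate_cohort(cohort_config(seed = 44), emit_raw = FALSE)
  rec <- truth_records(sim)
  rec$cmro2i <- rec$cbfi_cm2s * (rec$sao2_frac - rec$so2_frac)
  rep <- stats_report(rec, sim$subjects)
  expect_named(rep$sex, c("hbt_um", "so2_frac", "cbfi_cm2s", "cmro2i"))
  expect_true(all(vapply(rep$sex, function(x) x$p_value >= 0 &&
                           x$p_value <= 1, logical(1))))
  expect_named(rep$hemisphere, c("cbfi_cm2s", "cmro2i"))
  expect_gt(rep$hemisphere$cbfi_cm2s$estimate, 0)
  expect_named(rep$pearson_ga, c("hbt_um", "so2_frac"))
})
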