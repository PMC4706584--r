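test_that("planned sampling schedules match the per-patient totals", {
  expect_equal(length(sampling_schedule("SC")), 24L)
  expect_equal(length(sampling_schedule("IV")), 36L)
  expect_true(all(diff(sampling_schedule("SC")) > 0))
  expect_true(all(diff(sampling_schedule("IV")) > 0))
  # troughs at the end of each of the 13 cycles in both arms
  expect_true(all((21 * (1:13)) %in% sampling_schedule("SC")))
  expect_true(all((21 * (1:13)) %in% sampling_schedule("IV")))
})

test_that("generated covariates center on the study medians", {
  d <- generate_covariates(1e4, trial_design(), seed = 2)
  expect_equal(median(d$WT), 68, tolerance = 0.015)
  expect_equal(median(d$ALT), 19, tolerance = 0.03)
  # 1:1 randomization, exact split
  expect_equal(unname(table(d$ARM)[["SC"]]), 5000L)
  # weight quartile breaks near the published 58/67-68/79 kg
  q <- unname(quantile(d$WT, c(0.25, 0.5, 0.75)))
  expect_equal(q, c(58, 68, 79), tolerance = 0.04)
  # determinism and degenerate settings
  expect_identical(generate_covariates(50, trial_design(), seed = 3),
                   generate_covariates(50, trial_design(), seed = 3))
  d0 <- generate_covariates(5, trial_design(weight_cv = 0, alt_cv = 0),
                            seed = 4)
  expect_true(all(d0$WT == 68) && all(d0$ALT == 19))
  expect_error(generate_covariates(0, trial_design(), 1), "at least 1")
})

test_that("trial generation is deterministic and respects the design", {
  m <- ref_model()
  des <- trial_design(n_subjects = 20, seed = 5)
  t1 <- generate_trial(m, des)
  t2 <- generate_trial(m, des)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_identical(attr(t1, "subjects"), attr(t2, "subjects"))
  # planned per-subject observation counts
  obs_per <- table(t1$ID[t1$EVID == 0])
  arm_of <- tapply(t1$ARM, t1$ID, function(a) a[1])
  expect_true(all(obs_per[arm_of == "SC"] == 24))
  expect_true(all(obs_per[arm_of == "IV"] == 36))
  # doses: fixed 600 mg SC, weight-based IV
  doses <- as.data.frame(t1[t1$EVID == 1, ])
  expect_true(all(doses$AMT[doses$ARM == "SC"] == 600))
  first_iv <- doses[doses$ARM == "IV" & doses$TIME == 0, ]
  expect_equal(first_iv$AMT, 8 * first_iv$WT, tolerance = 1e-12)
})

test_that("population simulation degenerates correctly without variability", {
  m <- ref_model()
  subj <- data.frame(ID = 1:4, WT = 68, ALT = 19,
                     ARM = c("SC", "SC", "IV", "IV"))
  ds <- simulate_population(m, subj, n_cycles = 3,
                            schedule = list(SC = c(21, 42, 63),
                                            IV = c(21, 42, 63)),
                            seed = 6, variability = FALSE)
  obs <- analysis_set(ds)
  # identical covariates and no noise: identical profiles within arm
  sc <- obs[obs$ARM == "SC", ]
  expect_equal(sc$DV[sc$ID == 1], sc$DV[sc$ID == 2], tolerance = 1e-12)
  iv <- obs[obs$ARM == "IV", ]
  expect_equal(iv$DV[iv$ID == 3], iv$DV[iv$ID == 4], tolerance = 1e-12)
  # same seed twice with variability on: identical datasets
  a <- simulate_population(m, subj, n_cycles = 3,
                           schedule = list(SC = c(21), IV = c(21)), seed = 7)
  b <- simulate_population(m, subj, n_cycles = 3,
                           schedule = list(SC = c(21), IV = c(21)), seed = 7)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("simulated troughs center on the deterministic reference value", {
  m <- ref_model()
  subj <- data.frame(ID = 1:300, WT = 68, ALT = 19, ARM = "SC")
  ds <- simulate_population(m, subj, n_cycles = 7,
                            schedule = list(SC = 147, IV = 147), seed = 8)
  med <- median(analysis_set(ds)$DV)
  # median of multiplicative log-normal noise is 1, so the median trough
  # tracks the deterministic 75 ug/mL within sampling error
  expect_equal(med, 75, tolerance = 0.08)
})

test_that("outcome generation follows the logistic model and the seed", {
  rec <- data.frame(ID = 1:5000, WT = 68, ALT = 19, ARM = "SC",
                    cmin_ss = 75, auc_ss = 2300)
  out <- generate_outcomes(rec, seed = 9)
  expect_equal(mean(out$pcr), 0.43, tolerance = 0.05)
  expect_equal(mean(out$ae), 0.53, tolerance = 0.05)
  expect_identical(generate_outcomes(rec, seed = 10),
                   generate_outcomes(rec, seed = 10))
  # degenerate intercept: no events
  beta0 <- trial_design()$outcome_beta
  beta0$pcr[["intercept"]] <- -50
  expect_true(all(generate_outcomes(rec, beta = beta0, seed = 11)$pcr == 0))
})

test_that("below-quantification observations are flagged, not fabricated", {
  m <- ref_model()
  # tiny dose pushes much of the profile below the assay limit
  subj <- data.frame(ID = 1:2, WT = 68, ALT = 19, ARM = "SC")
  regs <- list(SC = function(w, nc) {
    r <- regimen_sc_600_q3w(nc); r$amount <- 0.05; r
  })
  ds <- simulate_population(m, subj, regimens = regs, n_cycles = 2,
                            schedule = list(SC = c(1, 21, 42)), seed = 12)
  expect_true(any(ds$BLQ))
  expect_lt(nrow(analysis_set(ds)), sum(ds$EVID == 0))
  # flagged rows stay in the table
  expect_equal(sum(ds$EVID == 0), 6L)
})

test_that("end-to-end: exposures feed the exposure-response pipeline", {
  m <- ref_model()
  tr <- generate_trial(m, trial_design(n_subjects = 120, seed = 13))
  er <- er_records(tr)
  expect_equal(nrow(er), 120L)
  expect_true(all(er$cmin_ss > 0) && all(er$auc_ss > er$cmin_ss))
  # fixed-dose SC exposure falls with weight, weight-based IV rises
  sc <- er[er$arm == "SC", ]
  iv <- er[er$arm == "IV", ]
  expect_lt(cor(sc$weight, sc$cmin_ss), 0)
  expect_gt(cor(iv$weight, iv$cmin_ss), -0.2)
  # default (null) outcome model: no significant exposure effect on pCR
  fit <- suppressWarnings(fit_logistic(er, "pcr", "cmin_ss"))
  if (fit$converged) {
    p <- fit$coefficients$p[fit$coefficients$term == "cmin_ss"]
    expect_gt(p, 0.01)
  }
})
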