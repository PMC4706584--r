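test_that("pk_rhs encodes the two-compartment saturable-elimination system", {
  p <- ref_params()
  # zero state with no input sits at equilibrium
  expect_equal(pk_rhs(c(0, 0, 0, 0), 0, p), rep(0, 4))
  # at C = Km the saturable pathway runs at half Vmax
  st <- c(0, p[["Vc"]] * p[["Km"]], 0, 0)
  d <- pk_rhs(st, 0, p)
  lin <- (p[["CL_lin"]] / p[["Vc"]]) * st[2]
  dist <- (p[["Q"]] / p[["Vc"]]) * st[2]
  expect_equal(d[2], -lin - p[["Vmax"]] / 2 - dist, tolerance = 1e-12)
  # AUC state integrates the central concentration
  expect_equal(d[4], p[["Km"]])
})

test_that("compiled solver agrees with an independent deSolve integration", {
  skip_if_not_installed("deSolve")
  p <- ref_params()
  grid <- seq(0, 63, by = 0.25)
  mine <- simulate_profile(p, regimen_sc_600_q3w(3), grid = grid)
  f_des <- function(t, A, parms) list(pk_rhs(A, t, p))
  ev <- data.frame(var = "A1", time = 21 * (0:2), value = 0.771 * 600,
                   method = "add")
  o <- deSolve::ode(c(A1 = 0, A2 = 0, A3 = 0, A4 = 0), grid, f_des, NULL,
                    rtol = 1e-10, atol = 1e-10, events = list(data = ev))
  expect_lt(max(abs(o[, 3] / p[["Vc"]] - mine$conc) /
                  pmax(mine$conc, 1e-3)), 1e-6)
  # and for an infusion regimen: integrate piecewise so the independent
  # solver also sees the rate discontinuities exactly
  grid_iv <- seq(0, 42, by = 0.25)
  mine_iv <- simulate_profile(p, regimen_iv_8_6_q3w(68, 2), grid = grid_iv)
  segs <- rbind(c(0, 0.0625, 544 / 0.0625),
                c(0.0625, 21, 0),
                c(21, 21 + 30 / 1440, 408 / (30 / 1440)),
                c(21 + 30 / 1440, 42, 0))
  state <- c(A1 = 0, A2 = 0, A3 = 0, A4 = 0)
  ref <- data.frame(time = 0, conc = 0)
  for (k in seq_len(nrow(segs))) {
    f_seg <- function(t, A, parms) list(pk_rhs(A, t, p, segs[k, 3]))
    tt <- sort(unique(c(segs[k, 1], grid_iv[grid_iv > segs[k, 1] &
                                              grid_iv <= segs[k, 2]],
                        segs[k, 2])))
    o2 <- deSolve::ode(state, tt, f_seg, NULL, rtol = 1e-10, atol = 1e-10)
    state <- setNames(as.numeric(o2[nrow(o2), -1]), names(state))
    keep <- tt %in% grid_iv & tt > segs[k, 1]
    ref <- rbind(ref, data.frame(time = tt[keep],
                                 conc = o2[keep, 3] / p[["Vc"]]))
  }
  ref <- ref[match(grid_iv, ref$time), ]
  expect_lt(max(abs(ref$conc - mine_iv$conc) / pmax(mine_iv$conc, 1e-3)),
            1e-6)
})

test_that("mass balance holds with elimination switched off", {
  p <- structural_parameters(CL_lin = 1e-12, Vmax = 0)
  reg <- rbind(regimen_sc_600_q3w(3)[1:3, ], dose_event(10, 300, "IV", 0.0625))
  prof <- simulate_profile(p, reg, grid = c(5, 15, 60), rtol = 1e-10,
                           atol = 1e-10)
  ev <- trastupk:::regimen_to_events(p, reg)
  sol <- trastupk:::pk_solve_cpp(
    as.numeric(p[c("Ka", "CL_lin", "Vmax", "Km", "Vc", "Q", "Vp")]),
    ev$bolus_time, ev$bolus_amt, ev$inf_start, ev$inf_dur, ev$inf_amt,
    c(5, 15, 60), 1e-10, 1e-10, FALSE, TRUE)
  total <- rowSums(sol$state[, 1:3])
  expected <- c(0.771 * 600, 0.771 * 600 + 300, 0.771 * 1800 + 300)
  expect_lt(max(abs(total - expected) / expected), 1e-6)
})

test_that("linear kinetics obey superposition and closed forms", {
  p <- structural_parameters(Vmax = 0)
  grid <- seq(0, 60, by = 0.5)
  one <- simulate_profile(p, regimen_sc_600_q3w(1), grid = grid)
  shifted <- simulate_profile(p, dose_event(21, 600, "SC"), grid = grid)
  two <- simulate_profile(p, regimen_sc_600_q3w(2), grid = grid)
  expect_lt(max(abs(one$conc + shifted$conc - two$conc) /
                  pmax(two$conc, 1e-6)), 1e-6)
  # AUC to infinity = F * dose / CL for a single linear-kinetics dose
  tail <- simulate_profile(p, regimen_sc_600_q3w(1), grid = 2000, tmax = 2000)
  expect_equal(tail$auc, 0.771 * 600 / 0.111, tolerance = 1e-6)
  # bolus-limit bi-exponential solution of the two-compartment model
  k10 <- p[["CL_lin"]] / p[["Vc"]]
  k12 <- p[["Q"]] / p[["Vc"]]
  k21 <- p[["Q"]] / p[["Vp"]]
  s <- k10 + k12 + k21
  l1 <- (s + sqrt(s^2 - 4 * k10 * k21)) / 2
  l2 <- (s - sqrt(s^2 - 4 * k10 * k21)) / 2
  cfun <- function(t) 544 / p[["Vc"]] *
    ((l1 - k21) / (l1 - l2) * exp(-l1 * t) +
     (k21 - l2) / (l1 - l2) * exp(-l2 * t))
  r <- simulate_profile(p, dose_event(0, 544, "IV", 1e-6), grid = c(1, 5, 20))
  expect_lt(max(abs(r$conc - cfun(c(1, 5, 20))) / cfun(c(1, 5, 20))), 1e-6)
})

test_that("profile edge cases behave", {
  p <- ref_params()
  # zero-dose regimen gives an identically zero profile
  z <- simulate_profile(p, dose_event(0, 0, "SC"), grid = seq(0, 21, 1))
  expect_true(all(z$conc == 0))
  # a near-instant IV infusion starts at amount/volume
  r <- simulate_profile(p, dose_event(0, 544, "IV", 1e-6),
                        grid = c(1e-6, 21))
  expect_equal(r$conc[1], 544 / 2.91, tolerance = 1e-3)
  # AUC is non-decreasing and concentrations non-negative
  prof <- simulate_profile(p, regimen_iv_8_6_q3w(68, 3))
  expect_true(all(prof$conc >= 0))
  expect_true(all(diff(prof$auc) >= 0))
})

test_that("steady-state metrics reproduce the published regimen comparison", {
  p <- ref_params()
  sc <- suppressWarnings(exposure_metrics(p, regimen_sc_600_q3w(20)))
  iv <- suppressWarnings(exposure_metrics(p, regimen_iv_8_6_q3w(68, 20)))
  qw <- suppressWarnings(exposure_metrics(p, regimen_iv_4_2_qw(68, 60)))
  expect_equal(sc$cmin_ss, 75, tolerance = 0.02)
  expect_equal(iv$cmin_ss, 57, tolerance = 0.02)
  expect_equal(qw$cmin_ss, 75, tolerance = 0.02)
  expect_equal(sc$cmax_ss, 149, tolerance = 0.02)
  expect_equal(iv$cmax_ss, 182, tolerance = 0.02)
  expect_equal(qw$cmax_ss, 116, tolerance = 0.02)
  expect_equal(sc$auc_ss, 2337, tolerance = 0.02)
  expect_equal(iv$auc_ss, 1994, tolerance = 0.02)
  expect_equal(qw$auc_ss, 1951, tolerance = 0.02)
  # SC peak around 4 days post-dose
  expect_equal(sc$tmax_ss, 4, tolerance = 0.15)
  # the exact refined peak exceeds the half-day-grid peak for short infusions
  iv_exact <- suppressWarnings(
    exposure_metrics(p, regimen_iv_8_6_q3w(68, 20), peak = "exact"))
  expect_gt(iv_exact$cmax_ss, iv$cmax_ss)
  expect_error(exposure_metrics(p, dose_event(0, 0, "SC")), "positive doses")
})

test_that("time to 90 percent of the steady-state trough is as published", {
  p <- ref_params()
  expect_equal(time_to_90ss(p, regimen_sc_600_q3w(20)), 126)
  expect_equal(time_to_90ss(p, regimen_iv_8_6_q3w(68, 20)), 105)
  # near-instant accumulation: fast elimination reaches its plateau in one cycle
  pf <- structural_parameters(Vmax = 0, CL_lin = 4)
  expect_equal(time_to_90ss(pf, regimen_sc_600_q3w(20)), 21)
})

test_that("trough trends with body weight reproduce the fixed-vs-weight-based contrast", {
  m <- ref_model()
  weights <- c(50, 68, 90, 110)
  cmin_sc <- cmin_iv <- numeric(length(weights))
  for (i in seq_along(weights)) {
    pi <- apply_covariates(m, individual_covariates(weights[i], 19))
    cmin_sc[i] <- simulate_profile(pi, regimen_sc_600_q3w(8),
                                   grid = 147)$conc
    cmin_iv[i] <- simulate_profile(pi, regimen_iv_8_6_q3w(weights[i], 8),
                                   grid = 147)$conc
  }
  # fixed SC dose: heavier patients have lower troughs; weight-based IV: higher
  expect_true(all(diff(cmin_sc) < 0))
  expect_true(all(diff(cmin_iv) > 0))
})

test_that("steady-state AUC times mean clearance matches the delivered dose", {
  p <- ref_params()
  # over a fully converged steady-state interval (cycle 20), the integral
  # of CL(C)*C dt equals the absorbed dose F*600
  reg <- regimen_sc_600_q3w(20)
  prof <- simulate_profile(p, reg, grid = seq(399, 420, by = 0.01))
  cl <- total_clearance(p, prof$conc)
  eliminated <- sum((cl * prof$conc)[-1] * diff(prof$time))
  expect_equal(eliminated, 0.771 * 600, tolerance = 0.01)
})

test_that("regimen constructors encode doses, routes and durations", {
  sc <- regimen_sc_600_q3w(20)
  expect_equal(nrow(sc), 20)
  expect_true(all(sc$amount == 600) && all(sc$duration == 0))
  iv <- regimen_iv_8_6_q3w(68, 20)
  expect_equal(iv$amount[1], 8 * 68)
  expect_true(all(iv$amount[-1] == 6 * 68))
  expect_equal(iv$duration[1], 0.0625)
  expect_true(all(iv$duration[-1] == 30 / 1440))
  qw <- regimen_iv_4_2_qw(68, 60)
  expect_equal(qw$amount[1:2], c(4, 2) * 68)
  expect_equal(regimen_interval(qw), 7)
  expect_error(dose_event(0, 100, "SC", duration = 1), "duration 0")
  expect_error(dose_event(0, 100, "IV", duration = 0), "positive duration")
})
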