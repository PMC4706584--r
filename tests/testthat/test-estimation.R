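# Oracles for the FOCEI objective: a model linear in the random effect has a
# closed-form marginal likelihood; a nonlinear toy model is integrated by
# direct numerical quadrature.

test_that("FOCEI equals the closed-form marginal -2LL for a linear mixed model", {
  set.seed(4)
  nsub <- 10; nobs <- 4
  theta <- 50; om <- 0.4; sig <- 2
  y_list <- lapply(seq_len(nsub),
                   function(i) theta + rnorm(1, 0, om) + rnorm(nobs, 0, sig))
  predfun <- function(eta, i) rep(theta + eta[1], nobs)
  got <- ofv_focei_generic(y_list, predfun, omega = om, sigma_prop = 0,
                           sigma_add = sig)
  V <- diag(sig^2, nobs) + om^2
  Vi <- solve(V)
  ld <- as.numeric(determinant(V)$modulus)
  exact <- sum(vapply(y_list, function(y) {
    r <- y - theta
    nobs * log(2 * pi) + ld + as.numeric(t(r) %*% Vi %*% r)
  }, 0))
  expect_equal(got$ofv, exact, tolerance = 1e-6)
  # conditional modes are the exact BLUPs
  blup <- vapply(y_list, function(y) om^2 * sum(y - theta) /
                   (sig^2 + nobs * om^2), 0)
  expect_equal(unname(got$eta_hat[, 1]), blup, tolerance = 1e-6)
})

test_that("FOCEI tracks a direct quadrature marginal likelihood on a nonlinear toy", {
  set.seed(9)
  nsub <- 8; nobs <- 6
  theta <- 10; om <- 0.15; sig <- 0.5
  y_list <- lapply(seq_len(nsub), function(i)
    theta * exp(rnorm(1, 0, om)) + rnorm(nobs, 0, sig))
  predfun <- function(eta, i) rep(theta * exp(eta[1]), nobs)
  got <- ofv_focei_generic(y_list, predfun, omega = om, sigma_prop = 0,
                           sigma_add = sig)
  quad <- sum(vapply(y_list, function(y) {
    f <- function(eta) {
      vapply(eta, function(e) {
        exp(sum(dnorm(y, theta * exp(e), sig, log = TRUE))) *
          dnorm(e, 0, om)
      }, 0)
    }
    -2 * log(integrate(f, -1, 1, rel.tol = 1e-10)$value)
  }, 0))
  expect_lt(abs(got$ofv - quad), 0.1)
})

test_that("compiled and reference engines agree on a PK dataset", {
  m <- ref_model()
  ds <- small_trial(m, n = 10, seed = 3, n_cycles = 4,
                    schedule = list(SC = c(21, 42, 63, 84),
                                    IV = c(0.0625, 21, 42, 63, 84)))
  tight <- list(rtol = 1e-10, atol = 1e-10, gtol = 1e-7)
  rc <- ofv_focei(m, ds, control = tight)
  ws <- focei_workspace(ds)
  dat <- trastupk:::ws_cpp(m, ws)
  y_list <- lapply(seq_along(ws$ids), function(i)
    ws$y[(ws$obs_ptr[i] + 1):ws$obs_ptr[i + 1]])
  predfun <- function(eta, i) {
    th <- dat$theta[i, ]
    sel <- (ws$dose_ptr[i] + 1):ws$dose_ptr[i + 1]
    sc <- ws$dose_route[sel] == 0
    p <- c(th[2], th[3] * exp(eta[2]), th[4], th[5], th[6] * exp(eta[3]),
           th[7], th[8] * exp(eta[4]))
    trastupk:::pk_solve_cpp(
      p, ws$dose_time[sel][sc], th[1] * exp(eta[1]) * ws$dose_amt[sel][sc],
      ws$dose_time[sel][!sc], pmax(ws$dose_dur[sel][!sc], 1e-6),
      ws$dose_amt[sel][!sc],
      ws$obs_time[(ws$obs_ptr[i] + 1):ws$obs_ptr[i + 1]],
      1e-10, 1e-10, FALSE, FALSE)$conc
  }
  rg <- ofv_focei_generic(y_list, predfun, omega = as.numeric(m$omega),
                          sigma_prop = m$sigma_prop, sigma_add = m$sigma_add)
  expect_equal(rc$ofv, rg$ofv, tolerance = 1e-5)
})

test_that("the objective is additive over subjects", {
  m <- ref_model()
  ds <- small_trial(m, n = 8, seed = 5, n_cycles = 4,
                    schedule = list(SC = c(21, 42, 63, 84),
                                    IV = c(0.0625, 21, 42, 63, 84)))
  r1 <- ofv_focei(m, ds)
  df2 <- as.data.frame(ds)
  df2$ID <- df2$ID + 1000
  doubled <- event_dataset(rbind(as.data.frame(ds), df2))
  r2 <- ofv_focei(m, doubled)
  expect_equal(r2$ofv, 2 * r1$ofv, tolerance = 1e-8)
})

test_that("with omega at zero the objective is the fixed-effects -2LL", {
  m <- ref_model()
  ds <- small_trial(m, n = 6, seed = 6, n_cycles = 3,
                    schedule = list(SC = c(21, 42, 63),
                                    IV = c(0.0625, 21, 42, 63)))
  m0 <- population_model(theta = m$theta, omega = c(CL_lin = 0),
                         sigma_prop = m$sigma_prop, sigma_add = m$sigma_add)
  got <- ofv_focei(m0, ds)
  # direct fixed-effects Gaussian -2LL at eta = 0
  ws <- focei_workspace(ds)
  dat <- trastupk:::ws_cpp(m0, ws)
  lin <- trastupk:::focei_linearize_cpp(dat, rep(0, 4), m0$sigma_prop,
                                        m0$sigma_add,
                                        matrix(0, length(ws$ids), 4),
                                        1e-8, 1e-8)
  direct <- sum(vapply(seq_along(ws$ids), function(i) {
    f <- as.numeric(lin[[i]]$f)
    y <- ws$y[(ws$obs_ptr[i] + 1):ws$obs_ptr[i + 1]]
    v <- m0$sigma_prop^2 * f^2 + m0$sigma_add^2
    sum(log(2 * pi * v) + (y - f)^2 / v)
  }, 0))
  expect_equal(got$ofv, direct, tolerance = 1e-8)
  expect_true(all(got$eta_hat == 0))
})

test_that("noiseless data identify the typical parameters", {
  m <- ref_model()
  subj <- generate_covariates(6, trial_design(), seed = 11)
  noiseless <- population_model(theta = m$theta,
                                covariate_effects = m$covariate_effects,
                                omega = c(CL_lin = 0), sigma_prop = 0,
                                sigma_add = 1)
  ds <- simulate_population(noiseless, subj, n_cycles = 3,
                            schedule = list(SC = c(10, 21, 42, 63),
                                            IV = c(0.0625, 10, 21, 42, 63)),
                            seed = 12, variability = FALSE)
  start <- noiseless
  start <- trastupk:::model_set_par(start, "CL_lin", 0.14)
  start <- trastupk:::model_set_par(start, "Vc", 2.2)
  fit <- fit_poppk(start, ds, free = c("CL_lin", "Vc"),
                   control = list(se = FALSE, reltol = 1e-12))
  expect_equal(fit$model$theta[["CL_lin"]], 0.111, tolerance = 1e-3)
  expect_equal(fit$model$theta[["Vc"]], 2.91, tolerance = 1e-3)
  # refitting from the optimum does not move the objective
  fit2 <- fit_poppk(fit$model, ds, free = c("CL_lin", "Vc"),
                    control = list(se = FALSE, reltol = 1e-12))
  expect_lt(abs(fit2$ofv - fit$ofv), 0.01)
})

test_that("likelihood-ratio arithmetic matches the chi-square thresholds", {
  expect_equal(lrt(106.63, 100, 1), 0.010, tolerance = 0.01)
  expect_equal(lrt(110.83, 100, 1), 0.001, tolerance = 0.01)
  expect_equal(lrt(100, 100, 1), 1)
  expect_error(lrt(99, 100, 1), "lower OFV")
  expect_error(lrt(110, 100, 0), "df")
})

test_that("an empty candidate list leaves the base model untouched", {
  m <- ref_model()
  ds <- small_trial(m, n = 6, seed = 13, n_cycles = 3,
                    schedule = list(SC = c(21, 42, 63),
                                    IV = c(0.0625, 21, 42, 63)))
  base <- base_model()
  cs <- covariate_search(base, ds, list(),
                         free = c("CL_lin"),
                         control = list(se = FALSE, reltol = 1e-6))
  expect_equal(length(cs$retained), 0L)
  expect_equal(length(cs$final_model$covariate_effects), 0L)
  # candidate referencing a missing covariate errors
  expect_error(covariate_search(base, ds,
    list(covariate_effect("CL_lin", "bogus", "power", 0.1, 1)),
    free = c("CL_lin")), "absent")
})

test_that("bootstrap stratification forces the identity with one subject per arm", {
  m <- ref_model()
  ds <- small_trial(m, n = 2, seed = 15, n_cycles = 3,
                    schedule = list(SC = c(10, 21, 42, 63),
                                    IV = c(0.0625, 10, 21, 42, 63)))
  fit <- fit_poppk(m, ds, free = "CL_lin",
                   control = list(se = FALSE, reltol = 1e-8))
  bs <- bootstrap_poppk(fit, ds, n_replicates = 1, seed = 42,
                        control = list(se = FALSE, reltol = 1e-8))
  # the lone replicate refits the same data; agreement up to optimizer noise
  expect_equal(bs$summary$median, fit$estimates$estimate, tolerance = 1e-3)
  expect_equal(bs$success_fraction, 1)
})

test_that("shrinkage arithmetic matches its definition", {
  eta <- cbind(F = rep(0, 5), CL_lin = c(-0.15, 0.15, -0.15, 0.15, 0),
               Vc = rep(0, 5), Vp = rep(0, 5))
  om <- c(F = 0, CL_lin = 0.30, Vc = 0, Vp = 0)
  got <- shrinkage(eta, om)
  expect_equal(unname(got$eta_pct["CL_lin"]),
               100 * (1 - sd(eta[, "CL_lin"]) / 0.30), tolerance = 1e-12)
  # all conditional modes at zero: complete shrinkage
  expect_equal(unname(shrinkage(0 * eta, om)$eta_pct["CL_lin"]), 100)
  # IWRES with unit spread: no epsilon shrinkage
  set.seed(1)
  iw <- rnorm(500)
  expect_equal(shrinkage(eta, om, iwres = iw)$eps_pct,
               100 * (1 - sd(iw)), tolerance = 1e-12)
  expect_error(shrinkage(eta[1, , drop = FALSE], om), "2 subjects")
})
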