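make_er <- function(n = 400, beta_exp = 0, beta_wt = 0, beta_arm = 0,
                    b0 = qlogis(0.43), seed = 1) {
  set.seed(seed)
  arm <- rep(c("SC", "IV"), length.out = n)
  weight <- 68 * exp(rnorm(n, 0, 0.2))
  cmin <- pmax(5, 75 - 0.9 * (weight - 68) * (arm == "SC") +
                 0.6 * (weight - 68) * (arm == "IV") + rnorm(n, 0, 15))
  p <- plogis(b0 + beta_exp * cmin + beta_wt * weight +
                beta_arm * (arm == "SC"))
  data.frame(arm = arm, weight = weight, cmin_ss = cmin,
             auc_ss = cmin * 30, pcr = rbinom(n, 1, p),
             ae = rbinom(n, 1, 0.5))
}

test_that("the arm log-odds ratio matches the 2x2 closed form", {
  # per-arm responder counts from the published efficacy summary
  n_sc <- 260; r_sc <- 118
  n_iv <- 263; r_iv <- 107
  d <- data.frame(
    arm = c(rep("SC", n_sc), rep("IV", n_iv)),
    weight = 68,
    cmin_ss = 62,
    pcr = c(rep(1, r_sc), rep(0, n_sc - r_sc),
            rep(1, r_iv), rep(0, n_iv - r_iv)))
  fit <- suppressWarnings(fit_logistic(d, "pcr", "cmin_ss"))
  beta_arm <- fit$coefficients$estimate[fit$coefficients$term == "armSC"]
  expect_equal(beta_arm, log((r_sc * (n_iv - r_iv)) / ((n_sc - r_sc) * r_iv)),
               tolerance = 1e-6)
})

test_that("an intercept-only pattern with half events gives log-odds zero", {
  d <- make_er(200, seed = 2)
  d$pcr <- rep(c(0, 1), 100)
  d$weight <- 68; d$cmin_ss <- 62   # constant covariates drop out
  fit <- suppressWarnings(
    stats::glm(pcr ~ 1, family = stats::binomial(), data = d))
  expect_equal(unname(coef(fit)[1]), 0, tolerance = 1e-9)
  expect_equal(mean(d$pcr), 0.5)
})

test_that("fitted deviance equals the direct Bernoulli log-likelihood", {
  d <- make_er(300, seed = 3)
  fit <- fit_logistic(d, "pcr", "cmin_ss")
  p_hat <- fitted(fit$glm)
  y <- d$pcr
  dev <- -2 * sum(y * log(p_hat) + (1 - y) * log(1 - p_hat))
  expect_equal(unname(deviance(fit$glm)), dev, tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("odds-ratio grids follow the published quartile layout", {
  d <- make_er(500, seed = 4)
  fit <- fit_logistic(d, "pcr", "cmin_ss")
  grid <- odds_ratio_grid(fit)
  expect_equal(nrow(grid), 9L)
  # the reference point (median weight, median exposure) has OR exactly 1
  ref <- grid[grid$weight == 68 & grid$exposure == 62, ]
  expect_equal(ref$or, 1)
  expect_true(all(grid$lo <= grid$or & grid$or <= grid$hi))
  # known coefficient: OR for 80 vs 59 kg equals exp(beta * 21) analytically
  b <- coef(fit$glm)
  arm_sc <- 1
  lp <- function(w, e) b[["(Intercept)"]] + b[["cmin_ss"]] * e +
    b[["weight"]] * w + b[["armSC"]] * arm_sc +
    b[["cmin_ss:armSC"]] * e * arm_sc + b[["weight:armSC"]] * w * arm_sc
  expect_equal(grid$or[grid$weight == 80 & grid$exposure == 62],
               exp(lp(80, 62) - lp(68, 62)), tolerance = 1e-10)
})

test_that("perfect separation is flagged without estimates", {
  d <- make_er(60, seed = 5)
  d$pcr <- as.integer(d$cmin_ss > median(d$cmin_ss))
  fit <- fit_logistic(d, "pcr", "cmin_ss")
  expect_true(fit$separation)
  expect_null(fit$coefficients)
  expect_error(odds_ratio_grid(fit), "converge")
})

test_that("rate tables reproduce the published response rates", {
  counts <- data.frame(
    arm = rep(c("SC", "IV"), each = 4),
    subgroup = rep(c("<58", ">=58,<67", ">=67,<79", ">=79"), 2),
    n = c(56, 63, 68, 73, 62, 74, 68, 59),
    responders = c(30, 28, 31, 29, 23, 32, 28, 24))
  rt <- rate_table(counts)
  expect_equal(rt$arm_rates[["SC"]], 45.4)
  expect_equal(rt$arm_rates[["IV"]], 40.7)
  expect_equal(rt$difference, 4.7)
  # zero responders give a zero rate; zero denominators error
  z <- rate_table(data.frame(arm = "SC", subgroup = "a", n = 10,
                             responders = 0))
  expect_equal(z$table$rate_pct, 0)
  expect_error(rate_table(data.frame(arm = "SC", subgroup = "a", n = 0,
                                     responders = 0)), "positive")
})

test_that("quartile bins use the inclusive-lower half-open convention", {
  br <- c(45.9, 61.5, 78.2)
  expect_equal(as.integer(quartile_bin(61.5, br)), 3L)
  expect_equal(as.integer(quartile_bin(61.499, br)), 2L)
  expect_equal(as.integer(quartile_bin(10, br)), 1L)
  expect_equal(as.integer(quartile_bin(100, br)), 4L)
  # empirical breaks: linear interpolation between order statistics
  b <- attr(quartile_bin(1:100), "breaks")
  expect_equal(b, c(25.75, 50.5, 75.25))
  expect_error(quartile_bin(1, c(3, 2, 1)), "sorted")
})

test_that("null exposure effects are rejected at the nominal rates", {
  # Wald test size ~5% and CI coverage of zero ~95% across replicates
  reject <- logical(200)
  for (r in seq_len(200)) {
    d <- make_er(300, seed = 1000 + r)
    fit <- suppressWarnings(fit_logistic(d, "pcr", "cmin_ss"))
    if (!fit$converged) next
    row <- fit$coefficients[fit$coefficients$term == "cmin_ss", ]
    reject[r] <- row$p < 0.05
  }
  expect_gt(mean(reject), 0.02)
  expect_lt(mean(reject), 0.10)
})

test_that("a strong simulated exposure effect is recovered with coverage", {
  beta1 <- 0.03
  cover <- logical(200)
  for (r in seq_len(200)) {
    d <- make_er(500, beta_exp = beta1, b0 = qlogis(0.43) - 0.03 * 62,
                 seed = 2000 + r)
    fit <- suppressWarnings(fit_logistic(d, "pcr", "cmin_ss"))
    if (!fit$converged) next
    row <- fit$coefficients[fit$coefficients$term == "cmin_ss", ]
    cover[r] <- abs(row$estimate - beta1) < 1.96 * row$se
  }
  expect_gt(mean(cover), 0.90)
})
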