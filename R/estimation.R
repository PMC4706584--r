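#' Build the flattened estimation workspace for a dataset
#'
#' Precomputes per-subject observation and dose structures in the layout the
#' compiled FOCEI engine consumes. The workspace is independent of the model
#' parameters except for the per-subject typical parameters, which are
#' recomputed from the model on each call to the objective.
#'
#' @param data an [event_dataset()].
#' @return A workspace list (internal layout).
#' @keywords internal
#' @export
focei_workspace <- function(data) {
  obs <- analysis_set(data)
  doses <- as.data.frame(data[data$EVID == 1, , drop = FALSE])
  ids <- unique(obs$ID)
  if (!length(ids)) stop("no usable observations in the dataset")
  obs_ptr <- c(0L)
  dose_ptr <- c(0L)
  obs_time <- numeric(0); y <- numeric(0)
  dose_time <- numeric(0); dose_amt <- numeric(0); dose_dur <- numeric(0)
  dose_route <- integer(0)
  covs <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    oi <- obs[obs$ID == ids[k], , drop = FALSE]
    di <- doses[doses$ID == ids[k], , drop = FALSE]
    if (!nrow(di)) stop("subject ", ids[k], " has observations but no doses")
    obs_time <- c(obs_time, oi$TIME); y <- c(y, oi$DV)
    obs_ptr <- c(obs_ptr, length(obs_time))
    dose_time <- c(dose_time, di$TIME)
    dose_amt <- c(dose_amt, di$AMT)
    rate <- if ("RATE" %in% names(di)) di$RATE else 0
    dur <- ifelse(!is.na(rate) & rate > 0, di$AMT / rate, 0)
    dose_dur <- c(dose_dur, dur)
    dose_route <- c(dose_route, as.integer(!is.na(rate) & rate > 0))
    dose_ptr <- c(dose_ptr, length(dose_time))
    covs[[k]] <- subject_covariates(data, ids[k])
  }
  list(ids = ids, obs_ptr = as.integer(obs_ptr), obs_time = obs_time, y = y,
       dose_ptr = as.integer(dose_ptr), dose_time = dose_time,
       dose_amt = dose_amt, dose_dur = dose_dur,
       dose_route = as.integer(dose_route), covariates = covs)
}

ws_theta_matrix <- function(model, ws) {
  t(vapply(ws$covariates, function(cov)
    as.numeric(apply_covariates(model, cov)), numeric(8)))
}

ws_cpp <- function(model, ws) {
  list(obs_ptr = ws$obs_ptr, obs_time = ws$obs_time, y = ws$y,
       dose_ptr = ws$dose_ptr, dose_time = ws$dose_time,
       dose_amt = ws$dose_amt, dose_dur = ws$dose_dur,
       dose_route = ws$dose_route, theta = ws_theta_matrix(model, ws))
}

#' FOCE-with-interaction objective function value
#'
#' Approximate marginal -2 log-likelihood of a population model for an event
#' dataset. For each subject the conditional mode of the random effects is
#' found by an inner quasi-Newton optimization (restarted from zero), the
#' model is linearized there, and the residual variance is evaluated at the
#' conditional predictions (the "interaction" part). The objective is
#' additive over subjects and exact for models linear in the random effects.
#'
#' @param model a [population_model()].
#' @param data an [event_dataset()] (every subject needs at least one usable
#'   observation), or a prebuilt [focei_workspace()].
#' @param eta_start optional matrix of starting conditional modes (subjects
#'   in workspace order) to warm-start the inner optimizations.
#' @param control list of numerical settings: `rtol`, `atol` (ODE), `gtol`
#'   (inner gradient tolerance), `inner_maxit`.
#' @return List with `ofv`, per-subject `ofv_i`, and the conditional modes
#'   `eta_hat` (one row per subject, columns F, CL_lin, Vc, Vp).
#' @export
ofv_focei <- function(model, data, eta_start = NULL, control = list()) {
  ws <- if (is.list(data) && !is.null(data$obs_ptr)) data else
    focei_workspace(data)
  ctl <- utils::modifyList(list(rtol = 1e-8, atol = 1e-8, gtol = 1e-6,
                                inner_maxit = 100L), control)
  n <- length(ws$ids)
  if (is.null(eta_start)) eta_start <- matrix(0, n, 4)
  res <- focei_ofv_cpp(ws_cpp(model, ws), as.numeric(model$omega),
                       model$sigma_prop, model$sigma_add, eta_start,
                       ctl$rtol, ctl$atol, ctl$gtol, as.integer(ctl$inner_maxit))
  if (!is.finite(res$ofv)) stop("non-finite FOCEI objective")
  dimnames(res$eta_hat) <- list(ws$ids, c("F", "CL_lin", "Vc", "Vp"))
  res
}

#' Reference FOCEI engine for arbitrary prediction functions
#'
#' A plain-R implementation of the same linearized FOCE-with-interaction
#' objective as [ofv_focei()], parameterized by an arbitrary prediction
#' function. Used for closed-form and quadrature cross-checks on toy models,
#' and to validate the compiled engine.
#'
#' @param y_list list of per-subject observation vectors.
#' @param predfun function `(eta, i)` returning the prediction vector for
#'   subject `i` at random-effect vector `eta`.
#' @param omega vector of random-effect standard deviations (length =
#'   dimension of `eta`); entries of 0 fix the corresponding effect.
#' @param sigma_prop,sigma_add residual error components.
#' @param gtol inner gradient tolerance.
#' @return List with `ofv`, `ofv_i` and `eta_hat`.
#' @export
ofv_focei_generic <- function(y_list, predfun, omega, sigma_prop, sigma_add,
                              gtol = 1e-8) {
  m <- length(omega)
  act <- which(omega > 0)
  n <- length(y_list)
  ofv_i <- numeric(n)
  eta_hat <- matrix(0, n, m)
  for (i in seq_len(n)) {
    y <- y_list[[i]]
    cond <- function(ea) {
      eta <- numeric(m); eta[act] <- ea
      f <- as.numeric(predfun(eta, i))
      v <- sigma_prop^2 * f^2 + sigma_add^2
      sum(log(2 * pi * v) + (y - f)^2 / v) + sum(ea^2 / omega[act]^2)
    }
    if (length(act)) {
      opt <- stats::optim(rep(0, length(act)), cond, method = "L-BFGS-B",
                          lower = -6, upper = 6,
                          control = list(factr = 1e4, pgtol = 1e-10,
                                         maxit = 500))
      eta_hat[i, act] <- opt$par
    }
    eta <- eta_hat[i, ]
    f <- as.numeric(predfun(eta, i))
    h <- 1e-5
    G <- matrix(0, length(f), m)
    for (k in act) {
      ep <- eta; em <- eta
      ep[k] <- ep[k] + h; em[k] <- em[k] - h
      G[, k] <- (as.numeric(predfun(ep, i)) - as.numeric(predfun(em, i))) / (2 * h)
    }
    v <- sigma_prop^2 * f^2 + sigma_add^2
    V <- diag(v, length(f))
    for (k in act) V <- V + omega[k]^2 * (G[, k] %o% G[, k])
    r <- y - f + as.numeric(G %*% eta)
    L <- t(chol(V))
    z <- forwardsolve(L, r)
    ofv_i[i] <- length(f) * log(2 * pi) + 2 * sum(log(diag(L))) + sum(z^2)
  }
  list(ofv = sum(ofv_i), ofv_i = ofv_i, eta_hat = eta_hat)
}

# --- parameter transformation machinery ------------------------------------

par_names_all <- function(model) {
  c(names(model$theta),
    paste0("omega_", c("F", "CL_lin", "Vc", "Vp")),
    "sigma_prop", "sigma_add",
    vapply(model$covariate_effects, function(ce)
      paste0("beta_", ce$parameter, ".", ce$covariate), ""))
}

model_get_par <- function(model, nm) {
  if (nm %in% names(model$theta)) return(model$theta[[nm]])
  if (startsWith(nm, "omega_")) return(model$omega[[sub("omega_", "", nm)]])
  if (nm == "sigma_prop") return(model$sigma_prop)
  if (nm == "sigma_add") return(model$sigma_add)
  if (startsWith(nm, "beta_")) {
    key <- sub("beta_", "", nm)
    for (ce in model$covariate_effects)
      if (paste0(ce$parameter, ".", ce$covariate) == key) return(ce$k_cov)
  }
  stop("unknown parameter: ", nm)
}

model_set_par <- function(model, nm, value) {
  if (nm %in% names(model$theta)) {
    th <- unclass(model$theta); th[nm] <- value
    model$theta <- structure(th, class = "structural_parameters")
  } else if (startsWith(nm, "omega_")) {
    model$omega[[sub("omega_", "", nm)]] <- value
  } else if (nm == "sigma_prop") {
    model$sigma_prop <- value
  } else if (nm == "sigma_add") {
    model$sigma_add <- value
  } else if (startsWith(nm, "beta_")) {
    key <- sub("beta_", "", nm)
    hit <- FALSE
    for (j in seq_along(model$covariate_effects)) {
      ce <- model$covariate_effects[[j]]
      if (paste0(ce$parameter, ".", ce$covariate) == key) {
        model$covariate_effects[[j]]$k_cov <- value
        hit <- TRUE
      }
    }
    if (!hit) stop("unknown covariate coefficient: ", nm)
  } else stop("unknown parameter: ", nm)
  model
}

is_log_scale <- function(nm) !startsWith(nm, "beta_")

to_trans <- function(value, nm) if (is_log_scale(nm)) log(value) else value
from_trans <- function(x, nm) if (is_log_scale(nm)) exp(x) else x

model_update_trans <- function(model, par, free) {
  for (k in seq_along(free))
    model <- model_set_par(model, free[k], from_trans(par[k], free[k]))
  model
}

#' Fit a population model by FOCEI
#'
#' Minimizes [ofv_focei()] over the chosen free parameters. Positive-scale
#' parameters (typical values, omegas, sigmas) are estimated on the log
#' scale; covariate coefficients are unconstrained. The inner conditional
#' modes are carried between outer iterations as warm starts. Standard
#' errors come from a finite-difference Hessian of the objective at the
#' optimum (relative steps 1e-4), transformed to the natural scale.
#'
#' @param model starting [population_model()]; also defines the free
#'   parameters' initial values.
#' @param data an [event_dataset()].
#' @param free character vector of parameters to estimate, e.g.
#'   `c("CL_lin", "Vc", "omega_CL_lin", "sigma_prop",
#'   "beta_CL_lin.weight")`. Everything else stays fixed.
#' @param control list: `maxit` (outer iterations), `reltol`, `se`
#'   (compute standard errors), plus [ofv_focei()] settings.
#' @return A `fit_result`: final `model`, `ofv`, `estimates` table with
#'   standard errors and RSE percent, conditional modes `eta_hat`,
#'   `convergence` flag.
#' @export
fit_poppk <- function(model, data, free = c("CL_lin", "Vc", "omega_CL_lin",
                                            "omega_Vc", "sigma_prop"),
                      control = list()) {
  ctl <- utils::modifyList(list(maxit = 200L, reltol = 1e-8, se = TRUE,
                                rtol = 1e-8, atol = 1e-8, gtol = 1e-6,
                                inner_maxit = 100L), control)
  ws <- focei_workspace(data)
  n <- length(ws$ids)
  bad <- setdiff(free, par_names_all(model))
  if (length(bad)) stop("unknown free parameter(s): ",
                        paste(bad, collapse = ", "))
  inits <- vapply(free, function(nm) model_get_par(model, nm), 0)
  if (any(!is.finite(inits)))
    stop("non-finite initial value among free parameters")
  logidx <- !startsWith(free, "beta_")
  if (any(inits[logidx] <= 0))
    stop("scale parameters need positive initial values")
  par0 <- mapply(to_trans, inits, free)
  # warm-start conditional modes from the best objective seen so far; updating
  # on every call would make finite-difference gradients path-dependent
  eta_env <- new.env()
  eta_env$eta <- matrix(0, n, 4)
  eta_env$best <- Inf
  fn <- function(par) {
    # keep the search inside a generous box around the start (5 log-units /
    # coefficient units); far outside it the ODE system only gets stiffer
    excess <- abs(par - par0)
    if (any(excess > 5)) return(1e10 * (1 + sum(pmax(excess - 5, 0))))
    m <- model_update_trans(model, par, free)
    res <- tryCatch(
      ofv_focei(m, ws, eta_start = eta_env$eta,
                control = ctl[c("rtol", "atol", "gtol", "inner_maxit")]),
      error = function(e) NULL)
    if (is.null(res)) return(1e10)
    if (res$ofv < eta_env$best) {
      eta_env$eta <- unname(res$eta_hat)
      eta_env$best <- res$ofv
    }
    res$ofv
  }
  opt <- stats::optim(par0, fn, method = "BFGS",
                      control = list(maxit = ctl$maxit, reltol = ctl$reltol,
                                     ndeps = rep(1e-4, length(par0))))
  final <- model_update_trans(model, opt$par, free)
  fit_eval <- ofv_focei(final, ws, eta_start = eta_env$eta,
                        control = ctl[c("rtol", "atol", "gtol", "inner_maxit")])
  est <- vapply(seq_along(free), function(k) from_trans(opt$par[k], free[k]), 0)
  se <- rep(NA_real_, length(free))
  if (isTRUE(ctl$se)) {
    H <- tryCatch(stats::optimHess(opt$par, fn,
                                   control = list(ndeps = rep(1e-3, length(par0)))),
                  error = function(e) NULL)
    if (!is.null(H)) {
      cov_t <- tryCatch(2 * solve(H), error = function(e) NULL)
      if (!is.null(cov_t)) {
        vd <- diag(cov_t)
        vd[vd < 0] <- NA
        se_t <- sqrt(vd)
        se <- ifelse(is_log_scale(free), se_t * est, se_t)
      }
    }
  }
  estimates <- data.frame(parameter = free, estimate = est, se = se,
                          rse_pct = 100 * se / abs(est))
  structure(list(model = final, ofv = fit_eval$ofv, estimates = estimates,
                 eta_hat = fit_eval$eta_hat, convergence = opt$convergence == 0,
                 free = free, n_subjects = n,
                 n_obs = length(ws$y), counts = opt$counts),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("FOCEI fit: %d subjects, %d observations, OFV = %.3f (%s)\n",
              x$n_subjects, x$n_obs, x$ofv,
              if (x$convergence) "converged" else "NOT converged"))
  print(transform(x$estimates, estimate = signif(estimate, 4),
                  se = signif(se, 3), rse_pct = round(rse_pct, 1)))
  invisible(x)
}

#' Likelihood-ratio test between nested fits
#'
#' @param ofv_reduced objective value of the reduced model.
#' @param ofv_full objective value of the full model.
#' @param df number of extra parameters in the full model.
#' @param tol numerical tolerance for a slightly negative difference.
#' @return p-value from the upper chi-square tail of `ofv_reduced - ofv_full`.
#' @examples
#' lrt(106.63, 100, 1)  # ~0.01
#' @export
lrt <- function(ofv_reduced, ofv_full, df = 1, tol = 1e-6) {
  if (df < 1) stop("df must be at least 1")
  delta <- ofv_reduced - ofv_full
  if (delta < -tol) stop("reduced model has lower OFV than the full model")
  stats::pchisq(max(delta, 0), df = df, lower.tail = FALSE)
}

#' Two-step covariate model selection
#'
#' Step 1 screens each candidate parameter-covariate relationship one at a
#' time against the base model and keeps those significant at
#' `alpha_screen` (chi-square on 1 df, threshold ΔOFV 6.63 at p = 0.01).
#' Step 2 starts from the full model containing all kept candidates and
#' repeatedly removes the least significant one until every remaining
#' covariate is significant at `alpha_retain` (ΔOFV 10.83 at p = 0.001).
#'
#' @param model base [population_model()] (no candidate effects).
#' @param data an [event_dataset()].
#' @param candidates list of [covariate_effect()] templates (their `k_cov`
#'   is the starting value for estimation).
#' @param free base free parameters passed to [fit_poppk()]; candidate
#'   coefficients are appended automatically.
#' @param alpha_screen univariate inclusion level (default 0.01).
#' @param alpha_retain backward-elimination retention level (default 0.001).
#' @param control fit control list.
#' @return A `covariate_search_result` with the screening table, elimination
#'   path, final fit and final model.
#' @export
covariate_search <- function(model, data, candidates,
                             free = c("CL_lin", "omega_CL_lin", "sigma_prop"),
                             alpha_screen = 0.01, alpha_retain = 0.001,
                             control = list()) {
  for (ce in candidates) {
    if (!ce$parameter %in% names(model$theta))
      stop("candidate targets unknown parameter: ", ce$parameter)
    probe <- tryCatch(subject_covariates(data, data$ID[1]),
                      error = function(e) NULL)
    if (is.null(probe[[ce$covariate]]))
      stop("candidate covariate absent from data: ", ce$covariate)
  }
  cand_name <- vapply(candidates, function(ce)
    paste0("beta_", ce$parameter, ".", ce$covariate), "")
  # every fitted submodel is cached by its candidate subset so the backward
  # elimination never refits a model the screening step already produced
  cache <- new.env()
  fit_subset <- function(idx) {
    key <- paste(sort(idx), collapse = ",")
    hit <- cache[[paste0("k", key)]]
    if (!is.null(hit)) return(hit)
    mj <- model
    mj$covariate_effects <- c(mj$covariate_effects, candidates[idx])
    fj <- fit_poppk(mj, data, free = c(free, cand_name[idx]),
                    control = control)
    cache[[paste0("k", key)]] <- fj
    fj
  }
  base_fit <- fit_subset(integer(0))
  screen <- data.frame(candidate = cand_name,
                       delta_ofv = rep(NA_real_, length(cand_name)),
                       p = rep(NA_real_, length(cand_name)),
                       kept = rep(FALSE, length(cand_name)))
  if (!length(candidates)) {
    return(structure(list(screening = screen, path = character(0),
                          final_fit = base_fit, final_model = base_fit$model,
                          retained = character(0)),
                     class = "covariate_search_result"))
  }
  for (j in seq_along(candidates)) {
    fj <- fit_subset(j)
    screen$delta_ofv[j] <- base_fit$ofv - fj$ofv
    screen$p[j] <- lrt(base_fit$ofv, fj$ofv, 1, tol = 0.5)
    screen$kept[j] <- screen$p[j] < alpha_screen
  }
  kept <- which(screen$kept)
  path <- character(0)
  current <- kept
  if (length(current)) {
    full_fit <- fit_subset(current)
    repeat {
      if (!length(current)) break
      pvals <- numeric(length(current))
      fits_wo <- vector("list", length(current))
      for (j in seq_along(current)) {
        fr <- fit_subset(current[-j])
        pvals[j] <- lrt(fr$ofv, full_fit$ofv, 1, tol = 0.5)
        fits_wo[[j]] <- fr
      }
      worst <- which.max(pvals)
      if (pvals[worst] >= alpha_retain) {
        path <- c(path, paste0("drop ", cand_name[current[worst]],
                               " (p = ", signif(pvals[worst], 3), ")"))
        full_fit <- fits_wo[[worst]]
        current <- current[-worst]
      } else break
    }
    final_fit <- full_fit
  } else {
    final_fit <- base_fit
  }
  structure(list(screening = screen, path = path, final_fit = final_fit,
                 final_model = final_fit$model,
                 retained = cand_name[current]),
            class = "covariate_search_result")
}

#' @export
print.covariate_search_result <- function(x, ...) {
  cat("Covariate search\n  Screening:\n")
  print(x$screening)
  if (length(x$path)) cat("  Elimination:", paste(x$path, collapse = "; "), "\n")
  cat("  Retained:", if (length(x$retained)) paste(x$retained, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' Nonparametric bootstrap of a population fit
#'
#' Resamples subjects with replacement (within treatment arm when
#' `stratify_by_arm`), refits the model to every replicate starting from the
#' point estimates, and summarizes the replicate estimates by median and
#' 2.5/97.5 percentiles.
#'
#' @param fit a [fit_poppk()] result.
#' @param data the [event_dataset()] the fit used.
#' @param n_replicates number of bootstrap datasets.
#' @param stratify_by_arm preserve per-arm sample sizes (default TRUE).
#' @param seed RNG seed.
#' @param control fit control list.
#' @return A `bootstrap_result` with per-replicate estimates, the summary
#'   table, and the fraction of successful minimizations.
#' @export
bootstrap_poppk <- function(fit, data, n_replicates = 100,
                            stratify_by_arm = TRUE, seed = 1,
                            control = list()) {
  if (n_replicates < 1) stop("n_replicates must be at least 1")
  set.seed(seed)
  arm_of <- tapply(data$ARM, data$ID, function(a) a[1])
  ids <- names(arm_of)
  strata <- if (stratify_by_arm) split(ids, unname(arm_of)) else list(all = ids)
  free <- fit$free
  reps <- matrix(NA_real_, n_replicates, length(free),
                 dimnames = list(NULL, free))
  ok <- logical(n_replicates)
  df <- as.data.frame(data)
  for (b in seq_len(n_replicates)) {
    pick <- unlist(lapply(strata, function(s)
      sample(s, length(s), replace = TRUE)), use.names = FALSE)
    parts <- lapply(seq_along(pick), function(k) {
      sub <- df[df$ID == pick[k], , drop = FALSE]
      sub$ID <- k
      sub
    })
    bdat <- event_dataset(do.call(rbind, parts), lloq = attr(data, "lloq"))
    fb <- tryCatch(fit_poppk(fit$model, bdat, free = free, control = control),
                   error = function(e) NULL)
    if (!is.null(fb) && all(is.finite(fb$estimates$estimate))) {
      reps[b, ] <- fb$estimates$estimate
      ok[b] <- fb$convergence
    }
  }
  if (!any(ok)) stop("all bootstrap replicates failed")
  used <- reps[ok, , drop = FALSE]
  summary <- data.frame(
    parameter = free,
    median = apply(used, 2, stats::median),
    p2.5 = apply(used, 2, stats::quantile, 0.025),
    p97.5 = apply(used, 2, stats::quantile, 0.975))
  structure(list(replicates = reps, summary = summary,
                 success_fraction = mean(ok)),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap: %.0f%% of %d replicates minimized successfully\n",
              100 * x$success_fraction, nrow(x$replicates)))
  print(transform(x$summary, median = signif(median, 4),
                  p2.5 = signif(p2.5, 4), p97.5 = signif(p97.5, 4)))
  invisible(x)
}

#' Shrinkage of empirical Bayes estimates and residuals
#'
#' `eta` shrinkage is `100 * (1 - SD(eta_hat)/omega)` per random effect;
#' `epsilon` shrinkage is `100 * (1 - SD(IWRES))`. Values above ~30 percent
#' flag individual estimates as poorly informed.
#'
#' @param eta_hat matrix of conditional modes (columns F, CL_lin, Vc, Vp).
#' @param omega named vector of between-subject SDs.
#' @param iwres optional vector of individual weighted residuals.
#' @return List with `eta_pct` (named vector) and `eps_pct` (or NA).
#' @export
shrinkage <- function(eta_hat, omega, iwres = NULL) {
  if (NROW(eta_hat) < 2) stop("shrinkage needs at least 2 subjects")
  act <- names(omega)[omega > 0]
  eta_pct <- vapply(act, function(nm)
    100 * (1 - stats::sd(eta_hat[, nm]) / omega[[nm]]), 0)
  eps_pct <- if (is.null(iwres)) NA_real_ else 100 * (1 - stats::sd(iwres))
  list(eta_pct = eta_pct, eps_pct = eps_pct)
}
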