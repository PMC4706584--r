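#' Population and individual residual diagnostics
#'
#' Computes, for every usable observation: the population prediction (model
#' at zero random effects), the individual prediction (at the conditional
#' modes), WRES (first-order linearization at eta = 0, decorrelated by the
#' implied marginal covariance), CWRES (the same construction linearized at
#' the conditional modes), and IWRES (individual residual scaled by the
#' residual SD). Observations with |WRES| > 3 or |CWRES| > 3 carry an
#' outlier flag.
#'
#' @param model a [population_model()].
#' @param data an [event_dataset()].
#' @param control numerical settings passed to [ofv_focei()].
#' @return A `residual_table` data frame: ID, TIME, DV, PRED, IPRED, WRES,
#'   CWRES, IWRES, outlier.
#' @export
compute_residuals <- function(model, data, control = list()) {
  ws <- focei_workspace(data)
  ctl <- utils::modifyList(list(rtol = 1e-8, atol = 1e-8, gtol = 1e-6,
                                inner_maxit = 100L), control)
  foc <- ofv_focei(model, ws, control = ctl)
  dat <- ws_cpp(model, ws)
  n <- length(ws$ids)
  om <- as.numeric(model$omega)
  lin0 <- focei_linearize_cpp(dat, om, model$sigma_prop, model$sigma_add,
                              matrix(0, n, 4), ctl$rtol, ctl$atol)
  linh <- focei_linearize_cpp(dat, om, model$sigma_prop, model$sigma_add,
                              unname(foc$eta_hat), ctl$rtol, ctl$atol)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sel <- (ws$obs_ptr[i] + 1):ws$obs_ptr[i + 1]
    y <- ws$y[sel]
    f0 <- as.numeric(lin0[[i]]$f); G0 <- lin0[[i]]$G
    fh <- as.numeric(linh[[i]]$f); Gh <- linh[[i]]$G
    eh <- as.numeric(foc$eta_hat[i, ])
    marg <- function(f, G) {
      V <- diag(model$sigma_prop^2 * f^2 + model$sigma_add^2, length(f))
      for (k in 1:4) if (om[k] > 0) V <- V + om[k]^2 * (G[, k] %o% G[, k])
      L <- tryCatch(t(chol(V)), error = function(e)
        stop("singular marginal covariance for subject ", ws$ids[i]))
      L
    }
    wres <- forwardsolve(marg(f0, G0), y - f0)
    cwres <- forwardsolve(marg(fh, Gh), y - fh + as.numeric(Gh %*% eh))
    iwres <- (y - fh) / sqrt(model$sigma_prop^2 * fh^2 + model$sigma_add^2)
    out[[i]] <- data.frame(ID = ws$ids[i], TIME = ws$obs_time[sel], DV = y,
                           PRED = f0, IPRED = fh, WRES = wres, CWRES = cwres,
                           IWRES = iwres)
  }
  tab <- do.call(rbind, out)
  tab$outlier <- abs(tab$WRES) > 3 | abs(tab$CWRES) > 3
  structure(tab, class = c("residual_table", "data.frame"))
}

#' Linear-elimination model for outlier screening
#'
#' The screening model for gross outliers: the same two-compartment model
#' with first-order SC absorption but `Vmax` fixed to 0 (linear elimination
#' only), as used before the final model is developed.
#'
#' @param model a [population_model()] whose structural part to linearize.
#' @return A [population_model()] with `Vmax = 0`.
#' @export
initial_linear_model <- function(model = reference_model()) {
  th <- unclass(model$theta)
  th["Vmax"] <- 0
  model$theta <- structure(th, class = "structural_parameters")
  model
}

#' Flag and remove outlying observations
#'
#' Applies the screening rule: residuals are computed under an initial
#' linear-elimination model (`Vmax = 0`); observations with |WRES| > 3 or
#' |CWRES| > 3 are flagged and removed, and any subject with more than 10
#' flagged samples is excluded entirely. Below-LLOQ observations keep their
#' separate flag and never enter the residual computation.
#'
#' @param data an [event_dataset()].
#' @param initial_model a [population_model()] with `Vmax` fixed to 0 (see
#'   [initial_linear_model()]).
#' @param max_flagged_per_subject subject exclusion threshold (default 10).
#' @param control numerical settings for the residual computation.
#' @return List: `data` (filtered dataset), `residuals` (the
#'   `residual_table` under the initial model), `excluded_subjects`,
#'   `counts` (flagged, removed rows, below-LLOQ).
#' @export
flag_outliers <- function(data, initial_model = initial_linear_model(),
                          max_flagged_per_subject = 10, control = list()) {
  if (initial_model$theta[["Vmax"]] != 0)
    stop("the outlier screening model must have Vmax fixed to 0")
  if (!nrow(analysis_set(data))) {
    return(list(data = data, residuals = NULL, excluded_subjects = character(0),
                counts = c(flagged = 0, removed_rows = 0,
                           below_lloq = sum(data$BLQ, na.rm = TRUE))))
  }
  res <- compute_residuals(initial_model, data, control = control)
  flagged <- res[res$outlier, c("ID", "TIME")]
  per_subj <- table(flagged$ID)
  excl_subj <- names(per_subj)[per_subj > max_flagged_per_subject]
  drop <- rep(FALSE, nrow(data))
  for (j in seq_len(nrow(flagged))) {
    drop <- drop | (data$ID == flagged$ID[j] & data$TIME == flagged$TIME[j] &
                    data$EVID == 0)
  }
  drop <- drop | data$ID %in% excl_subj
  filtered <- data[!drop, , drop = FALSE]
  filtered <- event_dataset(as.data.frame(filtered), lloq = attr(data, "lloq"))
  list(data = filtered, residuals = res,
       excluded_subjects = excl_subj,
       counts = c(flagged = nrow(flagged), removed_rows = sum(drop),
                  below_lloq = sum(data$BLQ, na.rm = TRUE)))
}

#' Visual and numerical predictive check
#'
#' Simulates `n_replicates` datasets at the observed design (same subjects,
#' covariates, doses and sampling times), then compares observed and
#' simulated percentiles per stratum and nominal time bin. The VPC table
#' reports, per bin, the observed 5/50/95 percentiles and the median and 95
#' percent interval of each percentile across replicates. The NPC table
#' reports, per stratum and nominal percentile (5/25/50/75/95), the fraction
#' of observations falling below the corresponding percentile of their bin's
#' simulated predictive distribution; `flag` marks fractions more than 10
#' points from nominal.
#'
#' @param model a [population_model()].
#' @param data an [event_dataset()].
#' @param n_replicates number of simulation replicates.
#' @param stratify_weight also stratify by baseline-weight quartile.
#' @param seed RNG seed.
#' @param min_obs strata-bins with fewer observations are dropped with a
#'   warning.
#' @param control numerical settings (ODE tolerances).
#' @return A `predictive_check_table`: list with `vpc` and `npc` data
#'   frames.
#' @export
predictive_check <- function(model, data, n_replicates = 200,
                             stratify_weight = FALSE, seed = 1,
                             min_obs = 10, control = list()) {
  if (n_replicates < 1) stop("n_replicates must be at least 1")
  set.seed(seed)
  ctl <- utils::modifyList(list(rtol = 1e-8, atol = 1e-8), control)
  ws <- focei_workspace(data)
  dat <- ws_cpp(model, ws)
  n <- length(ws$ids)
  nobs <- length(ws$y)
  subj_of_obs <- rep(seq_len(n), diff(ws$obs_ptr))
  arm_of <- vapply(ws$covariates, function(cc) cc$arm, "")
  wt_of <- vapply(ws$covariates, function(cc) cc$weight, 0)
  stratum <- arm_of[subj_of_obs]
  if (stratify_weight) {
    wq <- quartile_bin(wt_of)
    stratum <- paste(stratum, wq[subj_of_obs], sep = "/")
  }
  bin <- ws$obs_time
  sims <- matrix(NA_real_, nobs, n_replicates)
  for (b in seq_len(n_replicates)) {
    eta <- draw_eta(n, model)
    f <- unlist(pk_predict_batch_cpp(dat, unname(eta), ctl$rtol, ctl$atol))
    eps1 <- stats::rnorm(nobs, 0, model$sigma_prop)
    eps2 <- stats::rnorm(nobs, 0, model$sigma_add)
    sims[, b] <- f * (1 + eps1) + eps2
  }
  key <- paste(stratum, bin, sep = "@")
  groups <- split(seq_len(nobs), key)
  small <- vapply(groups, length, 0L) < min_obs
  if (any(small)) {
    warning(sum(small), " stratum/bin group(s) with fewer than ", min_obs,
            " observations excluded from the predictive check")
    groups <- groups[!small]
  }
  probs_vpc <- c(0.05, 0.5, 0.95)
  vpc <- do.call(rbind, lapply(names(groups), function(g) {
    idx <- groups[[g]]
    parts <- strsplit(g, "@", fixed = TRUE)[[1]]
    obs_q <- stats::quantile(ws$y[idx], probs_vpc, names = FALSE)
    sim_q <- apply(sims[idx, , drop = FALSE], 2, stats::quantile, probs_vpc,
                   names = FALSE)
    if (is.null(dim(sim_q))) sim_q <- matrix(sim_q, nrow = length(probs_vpc))
    data.frame(stratum = parts[1], time = as.numeric(parts[2]),
               n = length(idx),
               percentile = 100 * probs_vpc,
               observed = obs_q,
               sim_median = apply(sim_q, 1, stats::median),
               sim_lo = apply(sim_q, 1, stats::quantile, 0.025),
               sim_hi = apply(sim_q, 1, stats::quantile, 0.975))
  }))
  rownames(vpc) <- NULL
  probs_npc <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  below <- matrix(0, length(groups), length(probs_npc))
  wts <- vapply(groups, length, 0L)
  strat_of_group <- vapply(strsplit(names(groups), "@", fixed = TRUE),
                           `[`, "", 1)
  for (gi in seq_along(groups)) {
    idx <- groups[[gi]]
    predq <- stats::quantile(as.numeric(sims[idx, , drop = FALSE]), probs_npc,
                             names = FALSE)
    below[gi, ] <- vapply(predq, function(q) mean(ws$y[idx] < q), 0)
  }
  npc <- do.call(rbind, lapply(unique(strat_of_group), function(s) {
    gsel <- strat_of_group == s
    frac <- colSums(below[gsel, , drop = FALSE] * wts[gsel]) / sum(wts[gsel])
    data.frame(stratum = s, nominal = 100 * probs_npc,
               frac_below = 100 * frac,
               flag = abs(frac - probs_npc) > 0.10)
  }))
  rownames(npc) <- NULL
  structure(list(vpc = vpc, npc = npc, n_replicates = n_replicates),
            class = "predictive_check_table")
}

#' @export
print.predictive_check_table <- function(x, ...) {
  cat("Predictive check (", x$n_replicates, "replicates )\nNPC:\n")
  print(transform(x$npc, frac_below = round(frac_below, 1)))
  cat("VPC bins:", length(unique(paste(x$vpc$stratum, x$vpc$time))), "\n")
  invisible(x)
}
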