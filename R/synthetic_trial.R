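#' Design of a synthetic SC-versus-IV trastuzumab trial
#'
#' Collects the design constants of the emulated phase III study: ~595
#' subjects randomized 1:1 to a fixed 600 mg SC q3w regimen or weight-based
#' IV 8/6 mg/kg q3w; trough sampling at cycles 1-13 in both arms, peak
#' (end-of-infusion) samples in the IV arm, and richer sampling around
#' cycles 7 and 12, trimmed so the planned per-subject totals are 24 (SC)
#' and 36 (IV); assay quantification limit 0.156 ug/mL; body weight and ALT
#' log-normal around medians 68 kg and 19 IU/L.
#'
#' @param n_subjects total subjects (split 1:1).
#' @param n_cycles dosed/sampled cycles (21-day).
#' @param lloq assay lower limit of quantification (mg/L).
#' @param weight_median,weight_cv log-normal body-weight distribution
#'   (median kg, log-scale SD); the default spread reproduces the published
#'   weight quartile breaks (~58/68/79 kg) approximately.
#' @param alt_median,alt_cv log-normal ALT distribution (median IU/L,
#'   log-scale SD).
#' @param outlier_fraction fraction of IV-arm subjects whose trough and peak
#'   samples are swapped each cycle (the gross-error artifact the screening
#'   rule is designed to catch).
#' @param missing_fraction fraction of subjects with a missing ALT value (to
#'   exercise the imputation rule).
#' @param outcome_beta list of logistic coefficients for outcome generation,
#'   see [generate_outcomes()].
#' @param seed RNG seed for the whole trial generation.
#' @return A `trial_design` list.
#' @export
trial_design <- function(n_subjects = 595, n_cycles = 13, lloq = 0.156,
                         weight_median = 68, weight_cv = 0.20,
                         alt_median = 19, alt_cv = 0.50,
                         outlier_fraction = 0, missing_fraction = 0,
                         outcome_beta = NULL, seed = 20150917) {
  stopifnot(n_subjects >= 2, n_cycles >= 1, lloq > 0)
  if (is.null(outcome_beta))
    outcome_beta <- list(
      pcr = c(intercept = stats::qlogis(0.43), exposure = 0, weight = 0,
              arm = 0),
      ae = c(intercept = stats::qlogis(0.53), exposure = 0, weight = 0,
             arm = 0))
  structure(list(n_subjects = n_subjects, n_cycles = n_cycles, lloq = lloq,
                 weight_median = weight_median, weight_cv = weight_cv,
                 alt_median = alt_median, alt_cv = alt_cv,
                 outlier_fraction = outlier_fraction,
                 missing_fraction = missing_fraction,
                 outcome_beta = outcome_beta, seed = seed),
            class = "trial_design")
}

#' Per-arm planned sampling times
#'
#' Trough samples are taken pre-dose at the end of each cycle (day `21*n`);
#' IV peaks at the end of each infusion. The richer profiles at cycles 7 and
#' 12 use post-dose times from \{4 h, 1, 2, 4, 7, 14 d\}, trimmed so the
#' per-subject planned totals are exactly 24 (SC) and 36 (IV).
#'
#' @param arm "SC" or "IV".
#' @param n_cycles number of cycles (default 13).
#' @return Sorted vector of sampling times (days).
#' @export
sampling_schedule <- function(arm = c("SC", "IV"), n_cycles = 13) {
  arm <- match.arg(arm)
  troughs <- 21 * seq_len(n_cycles)
  rich7 <- 126 + c(4 / 24, 1, 2, 4, 7, 14)
  rich12 <- 231 + c(4 / 24, 1, 2, 4, 7)
  if (arm == "SC") {
    tt <- c(troughs, rich7, rich12)           # 13 + 6 + 5 = 24
  } else {
    peaks <- 21 * (seq_len(n_cycles) - 1) +
      c(90, rep(30, n_cycles - 1)) / 1440
    tt <- c(troughs, peaks, 126 + c(1, 2, 4, 7, 14),
            231 + c(1, 2, 4, 7, 14))          # 13 + 13 + 5 + 5 = 36
  }
  sort(tt)
}

#' Generate subject covariates
#'
#' Body weight and ALT are drawn log-normal around their medians; the arm is
#' assigned by 1:1 randomization (a random permutation of an equal split).
#' Deterministic given the seed.
#'
#' @param n number of subjects.
#' @param design a [trial_design()] (distribution settings).
#' @param seed RNG seed.
#' @return Data frame: ID, WT, ALT, ARM.
#' @export
generate_covariates <- function(n, design = trial_design(), seed = 1) {
  if (n < 1) stop("n must be at least 1")
  if (design$weight_cv < 0 || design$alt_cv < 0)
    stop("distribution spreads must be non-negative")
  set.seed(seed)
  wt <- design$weight_median * exp(stats::rnorm(n, 0, design$weight_cv))
  alt <- design$alt_median * exp(stats::rnorm(n, 0, design$alt_cv))
  arm <- sample(rep(c("SC", "IV"), length.out = n))
  data.frame(ID = seq_len(n), WT = wt, ALT = alt, ARM = arm,
             stringsAsFactors = FALSE)
}

#' Simulate a population of concentration profiles at a sampling design
#'
#' For each subject: realize individual parameters from the covariates and a
#' fresh random-effect draw, simulate the profile under the subject's
#' regimen, add combined proportional-plus-additive residual error, and flag
#' (not remove) observations below the quantification limit. Deterministic
#' given the seed.
#'
#' @param model a [population_model()].
#' @param subjects data frame with ID, WT, ALT, ARM.
#' @param regimens named list of functions `(weight, n_cycles)` returning
#'   the per-arm regimen; defaults to the fixed-SC and weight-based-IV
#'   constructors.
#' @param schedule named list of per-arm sampling-time vectors; defaults to
#'   [sampling_schedule()].
#' @param n_cycles dosed cycles.
#' @param lloq quantification limit (mg/L).
#' @param seed RNG seed.
#' @param variability draw between-subject and residual variability; when
#'   FALSE all subjects are typical and observations noiseless.
#' @return An [event_dataset()]; the drawn random effects are attached as a
#'   `eta` attribute (one row per subject).
#' @export
simulate_population <- function(model, subjects, regimens = NULL,
                                schedule = NULL, n_cycles = 13,
                                lloq = 0.156, seed = 1, variability = TRUE) {
  if (is.null(regimens))
    regimens <- list(SC = function(w, nc) regimen_sc_600_q3w(nc),
                     IV = function(w, nc) regimen_iv_8_6_q3w(w, nc))
  if (is.null(schedule))
    schedule <- list(SC = sampling_schedule("SC", n_cycles),
                     IV = sampling_schedule("IV", n_cycles))
  if (!length(schedule[[1]])) stop("sampling schedule must be nonempty")
  set.seed(seed)
  n <- nrow(subjects)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    arm <- subjects$ARM[i]
    reg <- regimens[[arm]](subjects$WT[i], n_cycles)
    tt <- schedule[[arm]]
    dose_rows <- data.frame(ID = subjects$ID[i], TIME = reg$time,
                            AMT = reg$amount,
                            RATE = ifelse(reg$duration > 0,
                                          reg$amount / reg$duration, 0),
                            DV = NA_real_, EVID = 1, MDV = 1,
                            CMT = ifelse(reg$route == "SC", 1, 2))
    obs_rows <- data.frame(ID = subjects$ID[i], TIME = tt, AMT = NA_real_,
                           RATE = 0, DV = 0, EVID = 0, MDV = 0, CMT = 2)
    dose_rows$BLQ <- obs_rows$BLQ <- FALSE
    sub <- rbind(dose_rows, obs_rows)
    sub$WT <- subjects$WT[i]; sub$ALT <- subjects$ALT[i]; sub$ARM <- arm
    for (extra in setdiff(names(subjects), c("ID", "WT", "ALT", "ARM")))
      sub[[extra]] <- subjects[[extra]][i]
    rows[[i]] <- sub
  }
  df <- do.call(rbind, rows)
  ds <- event_dataset(df, lloq = lloq)
  ws <- focei_workspace(ds)
  eta <- if (variability) draw_eta(n, model) else
    matrix(0, n, 4, dimnames = list(NULL, names(model$omega)))
  # workspace subject order may differ from input order; map by ID
  ord <- match(ws$ids, subjects$ID)
  f <- unlist(pk_predict_batch_cpp(ws_cpp(model, ws), unname(eta[ord, ,
                                                                 drop = FALSE]),
                                   1e-8, 1e-8))
  nobs <- length(f)
  if (variability) {
    eps1 <- stats::rnorm(nobs, 0, model$sigma_prop)
    eps2 <- stats::rnorm(nobs, 0, model$sigma_add)
    y <- f * (1 + eps1) + eps2
  } else y <- f
  # write back into the dataset rows (analysis-set order matches workspace)
  obs_idx <- which(ds$EVID == 0)
  stopifnot(length(obs_idx) == nobs)
  key_ds <- paste(ds$ID[obs_idx], ds$TIME[obs_idx])
  key_ws <- paste(rep(ws$ids, diff(ws$obs_ptr)), ws$obs_time)
  ds$DV[obs_idx[match(key_ws, key_ds)]] <- y
  ds$BLQ <- ds$EVID == 0 & !is.na(ds$DV) & ds$DV < lloq
  rownames(eta) <- subjects$ID
  attr(ds, "eta") <- eta
  ds
}

#' Steady-state exposure for each subject of a generated trial
#'
#' Deterministic cycle-7 window metrics (trough at day 147, AUC over days
#' 126-147) from each subject's realized individual parameters.
#'
#' @param model a [population_model()].
#' @param subjects data frame with ID, WT, ALT, ARM.
#' @param eta matrix of random effects (rows aligned with `subjects`).
#' @param n_cycles cycles to simulate (>= 7).
#' @return `subjects` with `cmin_ss` and `auc_ss` columns added.
#' @export
subject_exposures <- function(model, subjects, eta, n_cycles = 13) {
  om <- model$omega
  cmin <- auc <- numeric(nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    typ <- apply_covariates(model, list(weight = subjects$WT[i],
                                        alt = subjects$ALT[i],
                                        arm = subjects$ARM[i]))
    ind <- realize_individual(typ, eta[i, ], om)
    reg <- if (subjects$ARM[i] == "SC") regimen_sc_600_q3w(n_cycles) else
      regimen_iv_8_6_q3w(subjects$WT[i], n_cycles)
    prof <- simulate_profile(ind, reg, grid = c(126, 147), rtol = 1e-8)
    cmin[i] <- prof$conc[2]
    auc[i] <- prof$auc[2] - prof$auc[1]
  }
  subjects$cmin_ss <- cmin
  subjects$auc_ss <- auc
  subjects
}

#' Generate binary trial outcomes from exposure
#'
#' Bernoulli draws from `logit(p) = b0 + b1*exposure + b2*weight + b3*arm`
#' (arm coded SC = 1). The default coefficients are null slopes with
#' intercepts giving the observed base rates (~43 percent pathologic
#' complete response, ~53 percent grade >=3 adverse events).
#'
#' @param records data frame with `cmin_ss`, `auc_ss`, `WT`, `ARM`.
#' @param beta list with `pcr` and `ae` coefficient vectors
#'   (intercept, exposure, weight, arm); pCR uses `cmin_ss`, AE uses
#'   `auc_ss` as the exposure.
#' @param seed RNG seed.
#' @return `records` with 0/1 columns `pcr` and `ae` added.
#' @export
generate_outcomes <- function(records, beta = trial_design()$outcome_beta,
                              seed = 1) {
  set.seed(seed)
  armx <- as.numeric(records$ARM == "SC")
  lp_pcr <- beta$pcr[["intercept"]] + beta$pcr[["exposure"]] * records$cmin_ss +
    beta$pcr[["weight"]] * records$WT + beta$pcr[["arm"]] * armx
  lp_ae <- beta$ae[["intercept"]] + beta$ae[["exposure"]] * records$auc_ss +
    beta$ae[["weight"]] * records$WT + beta$ae[["arm"]] * armx
  records$pcr <- stats::rbinom(nrow(records), 1, stats::plogis(lp_pcr))
  records$ae <- stats::rbinom(nrow(records), 1, stats::plogis(lp_ae))
  records
}

#' Generate a complete synthetic trial
#'
#' Covariates, dosing, sampling, observations with residual error and
#' quantification-limit flags, optional gross-outlier injection (a fraction
#' of IV-arm subjects have their trough and peak values swapped each cycle),
#' optional covariate missingness, and exposure-linked binary outcomes.
#'
#' @param model a [population_model()]; defaults to [reference_model()].
#' @param design a [trial_design()].
#' @return An [event_dataset()] with a `subjects` attribute carrying the
#'   per-subject covariates, realized exposures and outcomes (see
#'   [er_records()]).
#' @export
generate_trial <- function(model = reference_model(), design = trial_design()) {
  subjects <- generate_covariates(design$n_subjects, design, design$seed)
  ds <- simulate_population(model, subjects, n_cycles = design$n_cycles,
                            lloq = design$lloq, seed = design$seed + 1)
  eta <- attr(ds, "eta")
  if (design$outlier_fraction > 0) {
    set.seed(design$seed + 2)
    iv_ids <- subjects$ID[subjects$ARM == "IV"]
    n_out <- round(design$outlier_fraction * length(iv_ids))
    if (n_out > 0) {
      culprits <- sample(iv_ids, n_out)
      for (id in culprits) {
        for (cyc in seq_len(design$n_cycles)) {
          t_tr <- 21 * cyc
          t_pk <- 21 * (cyc - 1) + (if (cyc == 1) 90 else 30) / 1440
          i_tr <- which(ds$ID == id & ds$EVID == 0 & abs(ds$TIME - t_tr) < 1e-9)
          i_pk <- which(ds$ID == id & ds$EVID == 0 & abs(ds$TIME - t_pk) < 1e-9)
          if (length(i_tr) == 1 && length(i_pk) == 1) {
            tmp <- ds$DV[i_tr]
            ds$DV[i_tr] <- ds$DV[i_pk]
            ds$DV[i_pk] <- tmp
          }
        }
      }
      attr(ds, "outlier_subjects") <- culprits
    }
  }
  if (design$missing_fraction > 0) {
    set.seed(design$seed + 3)
    drop_ids <- sample(subjects$ID,
                       round(design$missing_fraction * nrow(subjects)))
    ds$ALT[ds$ID %in% drop_ids] <- NA_real_
  }
  subjects <- subject_exposures(model, subjects, eta,
                                n_cycles = max(7, design$n_cycles))
  subjects <- generate_outcomes(subjects, design$outcome_beta,
                                seed = design$seed + 4)
  attr(ds, "subjects") <- subjects
  ds
}

#' Exposure-response records of a generated trial
#'
#' @param trial a [generate_trial()] dataset.
#' @return Data frame with columns id, arm, weight, cmin_ss, auc_ss, pcr,
#'   ae.
#' @export
er_records <- function(trial) {
  s <- attr(trial, "subjects")
  if (is.null(s)) stop("no subject-level records attached to this dataset")
  data.frame(id = s$ID, arm = s$ARM, weight = s$WT,
             cmin_ss = s$cmin_ss, auc_ss = s$auc_ss,
             pcr = s$pcr, ae = s$ae)
}
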