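#' Structural pharmacokinetic parameters
#'
#' Container for the typical-value parameters of the two-compartment
#' trastuzumab model with parallel linear and Michaelis-Menten elimination and
#' first-order absorption from a subcutaneous depot. Units: amounts in mg,
#' volumes in L, times in days, concentrations in mg/L (identical to ug/mL).
#'
#' @param F bioavailability of the subcutaneous dose (unitless, 0-1].
#' @param Ka first-order absorption rate constant (1/day).
#' @param CL_lin linear clearance (L/day).
#' @param Vmax maximum rate of the saturable (target-mediated) elimination
#'   pathway (mg/day).
#' @param Km concentration at which the saturable pathway runs at half its
#'   maximum rate (mg/L).
#' @param Vc central volume of distribution (L).
#' @param Q inter-compartmental clearance (L/day).
#' @param Vp peripheral volume of distribution (L).
#' @return An object of class `structural_parameters` (named numeric vector).
#' @examples
#' sp <- structural_parameters()
#' sp[["CL_lin"]]
#' @export
structural_parameters <- function(F = 0.771, Ka = 0.404, CL_lin = 0.111,
                                  Vmax = 11.9, Km = 33.9, Vc = 2.91,
                                  Q = 0.445, Vp = 3.06) {
  p <- c(F = F, Ka = Ka, CL_lin = CL_lin, Vmax = Vmax, Km = Km, Vc = Vc,
         Q = Q, Vp = Vp)
  if (any(!is.finite(p))) stop("structural parameters must be finite")
  if (any(p[setdiff(names(p), "Vmax")] <= 0))
    stop("structural parameters must be strictly positive (Vmax may be 0)")
  if (p[["Vmax"]] < 0) stop("Vmax must be non-negative")
  if (p[["F"]] > 1) stop("bioavailability F must not exceed 1")
  structure(p, class = "structural_parameters")
}

#' @export
print.structural_parameters <- function(x, ...) {
  cat("Structural PK parameters (mg, L, day):\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Covariate effect on a structural parameter
#'
#' A single parameter-covariate relationship. Continuous covariates act as a
#' power function of the covariate normalised to its reference value,
#' `theta * (cov/ref)^k`; categorical covariates act multiplicatively as
#' `theta * exp(k * x)` with `x` a 0/1 indicator.
#'
#' @param parameter name of the structural parameter affected (e.g. "CL_lin").
#' @param covariate name of the covariate column (e.g. "weight", "alt").
#' @param kind "power" for continuous covariates, "exponential" for
#'   categorical indicators.
#' @param k_cov exponent (power) or coefficient (exponential), unitless.
#' @param reference reference covariate value for the power form (68 kg for
#'   body weight, 19 IU/L for ALT in the shipped final model).
#' @return An object of class `covariate_effect`.
#' @export
covariate_effect <- function(parameter, covariate,
                             kind = c("power", "exponential"),
                             k_cov, reference = NULL) {
  kind <- match.arg(kind)
  if (kind == "power") {
    if (is.null(reference) || !is.finite(reference) || reference <= 0)
      stop("power-type covariate effects need a positive reference value")
  }
  structure(list(parameter = parameter, covariate = covariate, kind = kind,
                 k_cov = k_cov, reference = reference),
            class = "covariate_effect")
}

#' @export
print.covariate_effect <- function(x, ...) {
  if (x$kind == "power") {
    cat(sprintf("%s ~ (%s/%g)^%g\n", x$parameter, x$covariate, x$reference,
                x$k_cov))
  } else {
    cat(sprintf("%s ~ exp(%g * %s)\n", x$parameter, x$k_cov, x$covariate))
  }
  invisible(x)
}

#' Population pharmacokinetic model
#'
#' Bundles typical structural parameters, covariate effects, between-subject
#' variability (log-normal, diagonal) and the combined
#' proportional-plus-additive residual error model.
#'
#' @param theta a [structural_parameters()] object of typical values.
#' @param covariate_effects list of [covariate_effect()] objects.
#' @param omega named vector of between-subject standard deviations on the log
#'   scale; names among `F`, `CL_lin`, `Vc`, `Vp`. Published CV percentages
#'   are interpreted as `100 * omega` by default (see `cv_convention`).
#' @param sigma_prop proportional residual standard deviation (fraction).
#' @param sigma_add additive residual standard deviation (ug/mL).
#' @param cv_convention how `cv_percent()` converts omega to a CV: "sd"
#'   (CV% = 100*omega, the small-omega convention used for the published
#'   variability arithmetic) or "lognormal" (100*sqrt(exp(omega^2)-1)).
#' @param f_policy what to do when a sampled individual bioavailability
#'   exceeds 1: "resample" the random effect (default) or "truncate" at 1.
#' @return An object of class `population_model`.
#' @seealso [reference_model()] for the shipped final-model estimates.
#' @export
population_model <- function(theta = structural_parameters(),
                             covariate_effects = list(),
                             omega = c(F = 0.130, CL_lin = 0.300,
                                       Vc = 0.191, Vp = 0.504),
                             sigma_prop = 0.239, sigma_add = 4.48,
                             cv_convention = c("sd", "lognormal"),
                             f_policy = c("resample", "truncate")) {
  stopifnot(inherits(theta, "structural_parameters"))
  if (length(covariate_effects) &&
      !all(vapply(covariate_effects, inherits, TRUE, "covariate_effect")))
    stop("covariate_effects must be a list of covariate_effect objects")
  bad <- setdiff(names(omega), c("F", "CL_lin", "Vc", "Vp"))
  if (length(bad)) stop("omega allowed on F, CL_lin, Vc, Vp only; got: ",
                        paste(bad, collapse = ", "))
  if (any(omega < 0) || sigma_prop < 0 || sigma_add < 0)
    stop("variability magnitudes must be non-negative")
  for (ce in covariate_effects) {
    if (!ce$parameter %in% names(theta))
      stop("covariate effect targets unknown parameter: ", ce$parameter)
  }
  om <- c(F = 0, CL_lin = 0, Vc = 0, Vp = 0)
  om[names(omega)] <- omega
  structure(list(theta = theta, covariate_effects = covariate_effects,
                 omega = om, sigma_prop = sigma_prop, sigma_add = sigma_add,
                 cv_convention = match.arg(cv_convention),
                 f_policy = match.arg(f_policy)),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat("Population PK model\n")
  print(x$theta)
  if (length(x$covariate_effects)) {
    cat("Covariate effects:\n")
    for (ce in x$covariate_effects) print(ce)
  }
  cat("Between-subject SD (log scale):\n")
  print(round(x$omega, 4))
  cat(sprintf("Residual error: proportional %.1f%%, additive %.3g ug/mL\n",
              100 * x$sigma_prop, x$sigma_add))
  invisible(x)
}

#' Between-subject variability as CV percent
#'
#' @param model a [population_model()].
#' @return Named vector of CV percentages under the model's convention.
#' @export
cv_percent <- function(model) {
  om <- model$omega
  if (model$cv_convention == "sd") 100 * om else 100 * sqrt(exp(om^2) - 1)
}

#' Final published model for SC/IV trastuzumab
#'
#' Loads the shipped plain-text configuration holding the final
#' population-PK estimates for trastuzumab in early breast cancer (fixed
#' 600 mg SC or weight-based IV q3w dosing): typical values, body-weight
#' effects on linear clearance and both volumes, the ALT effect on clearance,
#' between-subject variability and the residual error magnitudes.
#'
#' @param path optional path to an alternative model configuration (JSON).
#' @return A [population_model()].
#' @examples
#' m <- reference_model()
#' apply_covariates(m, individual_covariates(weight = 68, alt = 19))
#' @export
reference_model <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "trastuzumab_final_model.json",
                        package = "trastupk", mustWork = TRUE)
  read_model_config(path)
}

#' Read a population model from a plain-text configuration
#'
#' @param path JSON file with `theta`, `covariate_effects`, `omega`,
#'   `sigma_prop`, `sigma_add` entries.
#' @return A [population_model()].
#' @export
read_model_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  th <- do.call(structural_parameters, as.list(cfg$theta))
  ces <- list()
  if (!is.null(cfg$covariate_effects) && NROW(cfg$covariate_effects)) {
    ce_df <- as.data.frame(cfg$covariate_effects)
    ces <- lapply(seq_len(nrow(ce_df)), function(i)
      covariate_effect(ce_df$parameter[i], ce_df$covariate[i], ce_df$kind[i],
                       ce_df$k_cov[i], ce_df$reference[i]))
  }
  population_model(theta = th, covariate_effects = ces,
                   omega = unlist(cfg$omega),
                   sigma_prop = cfg$sigma_prop, sigma_add = cfg$sigma_add)
}

#' Write a population model to a plain-text configuration
#'
#' @param model a [population_model()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(model, path) {
  ce <- if (length(model$covariate_effects)) {
    data.frame(
      parameter = vapply(model$covariate_effects, `[[`, "", "parameter"),
      covariate = vapply(model$covariate_effects, `[[`, "", "covariate"),
      kind = vapply(model$covariate_effects, `[[`, "", "kind"),
      k_cov = vapply(model$covariate_effects, `[[`, 0, "k_cov"),
      reference = vapply(model$covariate_effects, function(x)
        if (is.null(x$reference)) NA_real_ else x$reference, 0))
  } else NULL
  jsonlite::write_json(
    list(theta = as.list(unclass(model$theta)), covariate_effects = ce,
         omega = as.list(model$omega), sigma_prop = model$sigma_prop,
         sigma_add = model$sigma_add),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Individual covariate record
#'
#' @param weight baseline body weight (kg), required.
#' @param alt baseline alanine transaminase (IU/L), required.
#' @param arm treatment arm, "SC" or "IV".
#' @param ... optional screening covariates (age, race, albumin, ast,
#'   bilirubin, alk, crcl, ecog, her2, ata, aha, phase); may be NA.
#' @return An object of class `individual_covariates`.
#' @export
individual_covariates <- function(weight, alt, arm = c("SC", "IV"), ...) {
  arm <- match.arg(arm)
  if (!is.finite(weight) || weight <= 0) stop("weight must be positive")
  if (!is.finite(alt) || alt <= 0) stop("alt must be positive")
  structure(c(list(weight = weight, alt = alt, arm = arm), list(...)),
            class = "individual_covariates")
}

#' Apply covariate effects to the typical parameters
#'
#' Evaluates the multiplicative covariate model: each affected parameter is
#' `theta_pop * prod (cov/ref)^k * prod exp(k * x)`. Parameters without
#' effects are returned unchanged. With the shipped final model and the
#' reference covariates (weight 68 kg, ALT 19 IU/L) the result equals the
#' typical values exactly.
#'
#' @param model a [population_model()].
#' @param cov an [individual_covariates()] record (or a named list).
#' @return A [structural_parameters()] object of individual typical values.
#' @export
apply_covariates <- function(model, cov) {
  p <- unclass(model$theta)
  for (ce in model$covariate_effects) {
    val <- cov[[ce$covariate]]
    if (is.null(val) || (is.numeric(val) && !is.finite(val)))
      stop("missing required covariate: ", ce$covariate)
    fac <- if (ce$kind == "power") {
      if (!is.numeric(val) || val <= 0)
        stop("covariate ", ce$covariate, " must be positive for a power effect")
      (val / ce$reference)^ce$k_cov
    } else {
      exp(ce$k_cov * as.numeric(val))
    }
    p[ce$parameter] <- p[ce$parameter] * fac
  }
  structure(p, class = "structural_parameters")
}

#' Realize individual parameters from random effects
#'
#' Applies log-normal between-subject variability: `p_i = typical * exp(eta)`
#' for the parameters carrying variability (`F`, `CL_lin`, `Vc`, `Vp`).
#' Because bioavailability cannot exceed 1, a realized `F > 1` is handled per
#' the configured policy: truncation at 1 here; rejection-resampling is
#' applied at the sampling stage (see [draw_eta()]).
#'
#' @param typical a [structural_parameters()] object (after covariates).
#' @param eta named numeric vector of random effects (subset of
#'   `F`, `CL_lin`, `Vc`, `Vp`).
#' @param omega named vector of between-subject SDs; every nonzero `eta`
#'   must have a matching omega entry.
#' @return A [structural_parameters()] object.
#' @export
realize_individual <- function(typical, eta, omega) {
  p <- unclass(typical)
  bad <- setdiff(names(eta), c("F", "CL_lin", "Vc", "Vp"))
  if (length(bad)) stop("random effects allowed on F, CL_lin, Vc, Vp; got: ",
                        paste(bad, collapse = ", "))
  for (nm in names(eta)) {
    if (eta[[nm]] != 0 && (is.null(omega[[nm]]) || is.na(omega[nm]) ||
                           omega[[nm]] <= 0))
      stop("nonzero eta on ", nm, " without a matching omega entry")
    p[nm] <- p[nm] * exp(eta[[nm]])
  }
  if (p[["F"]] > 1) p[["F"]] <- 1
  structure(p, class = "structural_parameters")
}

#' Draw between-subject random effects
#'
#' Samples `eta ~ N(0, diag(omega^2))` for n subjects. Draws whose implied
#' bioavailability `F * exp(eta_F)` would exceed 1 are rejected and redrawn
#' (the model's default policy; about 2 percent of draws at the published
#' omega_F = 0.13), unless `f_policy = "truncate"`.
#'
#' @param n number of subjects.
#' @param model a [population_model()] (uses its omega, F and f_policy).
#' @return n x 4 matrix with columns F, CL_lin, Vc, Vp.
#' @export
draw_eta <- function(n, model) {
  om <- model$omega
  eta <- sapply(om, function(s) if (s > 0) stats::rnorm(n, 0, s) else rep(0, n))
  eta <- matrix(eta, nrow = n, dimnames = list(NULL, names(om)))
  if (om[["F"]] > 0 && model$f_policy == "resample") {
    fmax <- model$theta[["F"]]
    bad <- which(fmax * exp(eta[, "F"]) > 1)
    guard <- 0
    while (length(bad)) {
      eta[bad, "F"] <- stats::rnorm(length(bad), 0, om[["F"]])
      bad <- bad[fmax * exp(eta[bad, "F"]) > 1]
      if ((guard <- guard + 1) > 1000)
        stop("rejection sampling for F failed to terminate")
    }
  }
  eta
}

#' Total (concentration-dependent) clearance
#'
#' `CL_lin + Vmax / (Km + C)`: the sum of the linear pathway and the
#' saturable target-mediated pathway, strictly decreasing in concentration
#' with limits `CL_lin + Vmax/Km` at C = 0 and `CL_lin` at high C.
#'
#' @param params a [structural_parameters()] object.
#' @param conc serum concentration(s), mg/L; must be non-negative.
#' @return Total clearance (L/day), vectorised over `conc`.
#' @examples
#' total_clearance(structural_parameters(), c(75, 148))
#' @export
total_clearance <- function(params, conc) {
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("conc must be finite and non-negative")
  params[["CL_lin"]] + params[["Vmax"]] / (params[["Km"]] + conc)
}

#' Residual error standard deviation
#'
#' Combined proportional plus additive model:
#' `sd = sqrt(sigma_prop^2 * pred^2 + sigma_add^2)`.
#'
#' @param pred model-predicted concentration(s), mg/L.
#' @param model a [population_model()].
#' @return Residual SD (mg/L), vectorised over `pred`.
#' @export
residual_sd <- function(pred, model) {
  if (any(pred < 0, na.rm = TRUE)) stop("pred must be non-negative")
  sqrt(model$sigma_prop^2 * pred^2 + model$sigma_add^2)
}

#' Percent of between-subject variability explained by covariates
#'
#' Compares base-model and final-model CV percentages on the variance scale:
#' `100 * (cv_base^2 - cv_final^2) / cv_base^2`.
#'
#' @param cv_base CV percent under the model without covariates.
#' @param cv_final CV percent under the covariate model.
#' @return Percent of variability explained.
#' @examples
#' variance_explained(31.3, 30.0)  # linear clearance
#' variance_explained(59.4, 50.4)  # peripheral volume
#' @export
variance_explained <- function(cv_base, cv_final) {
  if (any(cv_final < 0) || any(cv_base < cv_final))
    stop("need cv_base >= cv_final >= 0")
  100 * (cv_base^2 - cv_final^2) / cv_base^2
}
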