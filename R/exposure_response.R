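#' Multiple logistic regression of outcome on exposure
#'
#' Fits `logit(p) = b0 + b1*exposure + b2*weight + b3*arm` plus all
#' interactions with arm, by maximum likelihood (iteratively reweighted
#' least squares). Used for pathologic complete response against the
#' steady-state trough and for grade >=3 adverse events against the
#' steady-state AUC.
#'
#' @param records data frame with columns `arm` ("SC"/"IV"), `weight`, the
#'   exposure column, and the outcome column (0/1).
#' @param outcome "pcr" or "ae" (name of the outcome column).
#' @param exposure "cmin_ss" or "auc_ss" (name of the exposure column).
#' @return A `logistic_fit`: coefficient table (estimate, SE, Wald z and p),
#'   covariance matrix, the fitted `glm`, `converged` and `separation`
#'   flags. With perfect separation no estimates are returned.
#' @export
fit_logistic <- function(records, outcome = c("pcr", "ae"),
                         exposure = c("cmin_ss", "auc_ss")) {
  outcome <- match.arg(outcome)
  exposure <- match.arg(exposure)
  need <- c(outcome, exposure, "weight", "arm")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack column(s): ", paste(miss, collapse = ", "))
  d <- records[stats::complete.cases(records[, need]), need]
  if (length(unique(d[[outcome]])) < 2)
    stop("both outcome classes must be present")
  d$arm <- factor(d$arm, levels = c("IV", "SC"))
  fml <- stats::as.formula(
    paste0(outcome, " ~ (", exposure, " + weight) * arm"))
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = d,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (separation) {
    return(structure(list(coefficients = NULL, vcov = NULL, glm = NULL,
                          outcome = outcome, exposure = exposure,
                          converged = FALSE, separation = TRUE),
                     class = "logistic_fit"))
  }
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      z = sm[, 3], p = sm[, 4], row.names = NULL)
  structure(list(coefficients = coefs, vcov = stats::vcov(fit), glm = fit,
                 outcome = outcome, exposure = exposure,
                 converged = fit$converged, separation = FALSE),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic exposure-response model: %s ~ (%s + weight) * arm\n",
              x$outcome, x$exposure))
  if (x$separation) {
    cat("  perfect separation detected - no estimates\n")
  } else {
    print(transform(x$coefficients, estimate = signif(estimate, 4),
                    se = signif(se, 3), z = round(z, 2), p = signif(p, 3)))
  }
  invisible(x)
}

#' Odds-ratio grid over weight and exposure values
#'
#' Odds ratios at each (weight, exposure) grid point relative to the
#' reference point (the median weight and median exposure by default), with
#' 95 percent confidence intervals from the delta method on the
#' linear-predictor contrast. The treatment arm is held fixed.
#'
#' @param fit a converged [fit_logistic()] result.
#' @param weights body-weight grid (kg); default the published quartile
#'   values 59/68/80.
#' @param exposures exposure grid; default the published trough quartile
#'   values 46/62/78 ug/mL.
#' @param arm arm at which the grid is evaluated ("SC" or "IV").
#' @param reference `c(weight, exposure)` of the reference point; defaults
#'   to the middle grid values.
#' @return Data frame: weight, exposure, or, lo, hi.
#' @export
odds_ratio_grid <- function(fit, weights = c(59, 68, 80),
                            exposures = c(46, 62, 78), arm = "SC",
                            reference = NULL) {
  if (!fit$converged) stop("logistic fit did not converge")
  if (is.null(reference))
    reference <- c(weights[ceiling(length(weights) / 2)],
                   exposures[ceiling(length(exposures) / 2)])
  grid <- expand.grid(weight = weights, exposure = exposures)
  newrow <- function(w, e) {
    nd <- data.frame(weight = w, arm = factor(arm, levels = c("IV", "SC")))
    nd[[fit$exposure]] <- e
    nd[[fit$outcome]] <- 0
    stats::model.matrix(stats::delete.response(stats::terms(fit$glm)), nd)
  }
  x0 <- newrow(reference[1], reference[2])
  beta <- stats::coef(fit$glm)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    ctr <- as.numeric(newrow(grid$weight[i], grid$exposure[i]) - x0)
    lp <- sum(ctr * beta)
    sev <- sqrt(as.numeric(t(ctr) %*% fit$vcov %*% ctr))
    data.frame(weight = grid$weight[i], exposure = grid$exposure[i],
               or = exp(lp), lo = exp(lp - 1.96 * sev),
               hi = exp(lp + 1.96 * sev))
  }))
  rownames(out) <- NULL
  out
}

#' Subgroup rate table
#'
#' Response rates per subgroup and per arm with the SC-minus-IV difference,
#' mirroring the published efficacy/safety quartile summaries.
#'
#' @param counts data frame with columns `arm`, `subgroup`, `n`,
#'   `responders`.
#' @return List: `table` (rates percent, 1 decimal), `arm_rates`,
#'   `difference` (SC minus IV, percentage points).
#' @examples
#' counts <- data.frame(arm = rep(c("SC", "IV"), each = 4),
#'                      subgroup = rep(1:4, 2),
#'                      n = c(56, 63, 68, 73, 62, 74, 68, 59),
#'                      responders = c(30, 28, 31, 29, 23, 32, 28, 24))
#' rate_table(counts)$arm_rates
#' @export
rate_table <- function(counts) {
  stopifnot(all(c("arm", "subgroup", "n", "responders") %in% names(counts)))
  if (any(counts$n <= 0)) stop("subgroup denominators must be positive")
  if (any(counts$responders < 0) || any(counts$responders > counts$n))
    stop("responder counts must lie in [0, n]")
  counts$rate_pct <- round(100 * counts$responders / counts$n, 1)
  arms <- split(counts, counts$arm)
  arm_rates <- vapply(arms, function(a)
    round(100 * sum(a$responders) / sum(a$n), 1), 0)
  diff <- if (all(c("SC", "IV") %in% names(arm_rates)))
    round(arm_rates[["SC"]] - arm_rates[["IV"]], 1) else NA_real_
  list(table = counts, arm_rates = arm_rates, difference = diff)
}

#' Quartile binning with half-open intervals
#'
#' Assigns values to bins `[low, high)` (lower bound inclusive), matching
#' the ">= a, < b" convention of the published quartile tables. When
#' `breaks` are not supplied, the empirical quartiles are used (linear
#' interpolation between order statistics, quantile type 7).
#'
#' @param values numeric vector.
#' @param breaks strictly increasing interior break points (3 values for
#'   quartiles); computed from `values` when NULL.
#' @return Integer bin labels 1..(length(breaks)+1), with the breaks as an
#'   attribute.
#' @examples
#' quartile_bin(61.5, breaks = c(45.9, 61.5, 78.2))  # third bin
#' @export
quartile_bin <- function(values, breaks = NULL) {
  if (is.null(breaks))
    breaks <- as.numeric(stats::quantile(values, c(0.25, 0.5, 0.75),
                                         type = 7, na.rm = TRUE))
  if (is.unsorted(breaks, strictly = TRUE)) stop("breaks must be sorted")
  bin <- findInterval(values, breaks, left.open = FALSE) + 1L
  structure(bin, breaks = breaks)
}
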