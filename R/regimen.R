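#' Dosing events and regimens
#'
#' A regimen is an ordered table of dose events. Subcutaneous doses are
#' instantaneous boluses into the absorption depot (the 5-minute manual
#' injection is negligible relative to the absorption half-life of
#' log(2)/0.404 = 1.7 days); intravenous doses are zero-order infusions into
#' the central compartment with an explicit duration in days.
#'
#' @param time dose time (day).
#' @param amount dose amount (mg).
#' @param route "SC" (depot bolus) or "IV" (central infusion).
#' @param duration infusion duration in days; must be 0 for SC and > 0 for IV.
#' @return A one-row `regimen` data frame; combine with [rbind()].
#' @export
dose_event <- function(time, amount, route = c("SC", "IV"), duration = 0) {
  route <- match.arg(route)
  if (amount < 0) stop("dose amount must be non-negative")
  if (duration < 0) stop("infusion duration must be non-negative")
  if (route == "SC" && duration != 0) stop("SC depot doses have duration 0")
  if (route == "IV" && duration <= 0) stop("IV doses need a positive duration")
  as_regimen(data.frame(time = time, amount = amount, route = route,
                        duration = duration))
}

as_regimen <- function(df, interval = NULL, label = NULL) {
  df <- df[order(df$time), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("regimen", "data.frame"),
            interval = interval, label = label)
}

#' @export
rbind.regimen <- function(..., deparse.level = 1) {
  parts <- lapply(list(...), function(x) as.data.frame(unclass(x)))
  as_regimen(do.call(rbind, parts))
}

#' @export
print.regimen <- function(x, ...) {
  lbl <- attr(x, "label")
  cat("Dosing regimen", if (!is.null(lbl)) paste0("(", lbl, ")"), "-",
      nrow(x), "events\n")
  print(utils::head(as.data.frame(unclass(x)), 8))
  if (nrow(x) > 8) cat("... and", nrow(x) - 8, "more events\n")
  invisible(x)
}

# Infusion durations: first dose 90 min, maintenance 30 min, converted
# exactly to days.
.DUR_90MIN <- 90 / 1440
.DUR_30MIN <- 30 / 1440

#' Fixed 600 mg subcutaneous dose every 3 weeks
#'
#' @param n_cycles number of 21-day cycles.
#' @return A `regimen`.
#' @export
regimen_sc_600_q3w <- function(n_cycles = 20) {
  stopifnot(n_cycles >= 1)
  as_regimen(data.frame(time = 21 * (seq_len(n_cycles) - 1), amount = 600,
                        route = "SC", duration = 0),
             interval = 21, label = "SC 600 mg q3w")
}

#' Weight-based IV regimen: 8 mg/kg loading, 6 mg/kg maintenance, q3w
#'
#' The loading dose is a 90-minute infusion, maintenance doses 30-minute
#' infusions.
#'
#' @param weight body weight (kg).
#' @param n_cycles number of 21-day cycles.
#' @return A `regimen`.
#' @export
regimen_iv_8_6_q3w <- function(weight, n_cycles = 20) {
  stopifnot(weight > 0, n_cycles >= 1)
  as_regimen(data.frame(time = 21 * (seq_len(n_cycles) - 1),
                        amount = c(8, rep(6, n_cycles - 1)) * weight,
                        route = "IV",
                        duration = c(.DUR_90MIN, rep(.DUR_30MIN, n_cycles - 1))),
             interval = 21, label = "IV 8/6 mg/kg q3w")
}

#' Weight-based IV regimen: 4 mg/kg loading, 2 mg/kg weekly maintenance
#'
#' @param weight body weight (kg).
#' @param n_weeks number of weekly doses.
#' @return A `regimen`.
#' @export
regimen_iv_4_2_qw <- function(weight, n_weeks = 60) {
  stopifnot(weight > 0, n_weeks >= 1)
  as_regimen(data.frame(time = 7 * (seq_len(n_weeks) - 1),
                        amount = c(4, rep(2, n_weeks - 1)) * weight,
                        route = "IV",
                        duration = c(.DUR_90MIN, rep(.DUR_30MIN, n_weeks - 1))),
             interval = 7, label = "IV 4/2 mg/kg qw")
}

#' Dosing interval of a regimen (days)
#'
#' Named constructors carry their interval; for hand-built regimens the
#' modal spacing between consecutive doses is used.
#'
#' @param regimen a `regimen`.
#' @return Interval in days.
#' @export
regimen_interval <- function(regimen) {
  iv <- attr(regimen, "interval")
  if (!is.null(iv)) return(iv)
  if (nrow(regimen) < 2) return(21)
  d <- diff(sort(unique(regimen$time)))
  as.numeric(names(sort(table(d), decreasing = TRUE))[1])
}

regimen_horizon <- function(regimen) {
  max(regimen$time + regimen$duration) + regimen_interval(regimen)
}
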