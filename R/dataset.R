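#' Pharmacometric event dataset
#'
#' Analysis-ready record table shared by simulation, estimation and
#' diagnostics. One row per event: dose rows (`EVID = 1`) carry `AMT` (mg)
#' and `RATE` (mg/day, 0 for depot boluses); observation rows (`EVID = 0`)
#' carry the measured concentration `DV` (mg/L) unless `MDV = 1`. `CMT` is 1
#' for the subcutaneous depot and 2 for the central compartment. Covariate
#' columns `WT` (kg), `ALT` (IU/L) and `ARM` ("SC"/"IV") are constant within
#' subject; further screening covariates may be present. A `BLQ` column
#' flags observations below the quantification limit; these stay in the
#' table but are excluded from the analysis set.
#'
#' @param df data frame with (at least) columns `ID`, `TIME`, `AMT`, `RATE`,
#'   `DV`, `EVID`, `MDV`, `CMT`, `WT`, `ALT`, `ARM`.
#' @param lloq lower limit of quantification (mg/L) used to set `BLQ` when
#'   the column is absent.
#' @return An `event_dataset` (data frame subclass).
#' @export
event_dataset <- function(df, lloq = 0.156) {
  req <- c("ID", "TIME", "AMT", "DV", "EVID", "MDV", "CMT", "WT", "ALT", "ARM")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  if (!"RATE" %in% names(df)) df$RATE <- 0
  if (anyNA(df$TIME)) stop("TIME must not be missing in an event_dataset")
  if (any(df$TIME < 0)) stop("TIME must be non-negative")
  if (!all(df$EVID %in% c(0, 1))) stop("EVID must be 0 or 1")
  ord <- order(df$ID, df$TIME, -df$EVID)
  df <- df[ord, , drop = FALSE]
  obs <- df$EVID == 0
  if (any(!is.na(df$AMT[obs]) & df$AMT[obs] > 0))
    stop("observation rows must not carry a dose amount")
  if (any(df$EVID == 1 & !is.na(df$DV)))
    stop("dose rows must not carry an observed value")
  if (any(df$EVID == 1 & (is.na(df$AMT) | df$AMT <= 0)))
    stop("dose rows must have AMT > 0")
  if (!"BLQ" %in% names(df))
    df$BLQ <- obs & !is.na(df$DV) & df$DV < lloq
  rownames(df) <- NULL
  structure(df, class = c("event_dataset", "data.frame"), lloq = lloq)
}

#' @export
print.event_dataset <- function(x, ...) {
  obs <- analysis_set(x)
  cat(sprintf(paste0("Event dataset: %d subjects, %d dose records, ",
                     "%d observations in the analysis set (%d below LLOQ ",
                     "%.3g mg/L excluded)\n"),
              length(unique(x$ID)), sum(x$EVID == 1), nrow(obs),
              sum(x$BLQ, na.rm = TRUE), attr(x, "lloq")))
  invisible(x)
}

#' Observation rows entering the likelihood
#'
#' Non-missing observations above the quantification limit.
#'
#' @param data an [event_dataset()].
#' @return Data frame of usable observation rows.
#' @export
analysis_set <- function(data) {
  keep <- data$EVID == 0 & data$MDV == 0 & !is.na(data$DV) & !data$BLQ
  as.data.frame(data[keep, , drop = FALSE])
}

#' Read an event dataset from CSV
#'
#' Applies the analysis data-handling rules: rows with a missing dose or
#' sample time are excluded (and counted), observations below the
#' quantification limit are flagged `BLQ` and excluded from the analysis set
#' but kept in the table. Dose rows may use "." for a missing `DV`.
#'
#' @param path CSV path (comma-separated, header, "." decimal point).
#' @param lloq lower limit of quantification, mg/L.
#' @return An [event_dataset()] with an `exclusions` attribute listing the
#'   counts of dropped/flagged rows.
#' @export
read_dataset <- function(path, lloq = 0.156) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, na.strings = c("NA", "."),
                        stringsAsFactors = FALSE)
  if (!nrow(df)) stop("empty dataset: ", path)
  n_in <- nrow(df)
  drop_time <- is.na(df$TIME)
  df <- df[!drop_time, , drop = FALSE]
  for (id in unique(df$ID)) {
    if (is.unsorted(df$TIME[df$ID == id], strictly = FALSE))
      stop("times are not monotone within subject ", id)
  }
  ds <- event_dataset(df, lloq = lloq)
  attr(ds, "exclusions") <- list(rows_in = n_in,
                                 missing_time = sum(drop_time),
                                 below_lloq = sum(ds$BLQ, na.rm = TRUE))
  ds
}

#' Write an event dataset to CSV
#'
#' Round-trips through [read_dataset()].
#'
#' @param data an [event_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, na = ".")
  invisible(path)
}

#' Impute missing covariates
#'
#' Continuous covariates are imputed as the study median, categorical ones as
#' the reference category; applies only while per-covariate missingness is at
#' most 10 percent. Imputed positions are recorded in an `imputed` attribute.
#'
#' @param data an [event_dataset()].
#' @param continuous names of continuous covariate columns to impute.
#' @param categorical named list: column name -> reference level.
#' @param max_missing maximum tolerated missing fraction per covariate.
#' @return The dataset with missing covariate values filled in.
#' @export
impute_covariates <- function(data, continuous = c("WT", "ALT"),
                              categorical = list(), max_missing = 0.1) {
  imputed <- list()
  per_subject <- !duplicated(data$ID)
  for (cc in continuous) {
    if (!cc %in% names(data)) next
    miss_frac <- mean(is.na(data[[cc]][per_subject]))
    if (miss_frac > max_missing)
      stop(sprintf("covariate %s missing for %.0f%% of subjects (limit %.0f%%)",
                   cc, 100 * miss_frac, 100 * max_missing))
    if (miss_frac > 0) {
      med <- stats::median(data[[cc]][per_subject], na.rm = TRUE)
      idx <- which(is.na(data[[cc]]))
      data[[cc]][idx] <- med
      imputed[[cc]] <- list(n = length(idx), value = med)
    }
  }
  for (cc in names(categorical)) {
    if (!cc %in% names(data)) next
    miss_frac <- mean(is.na(data[[cc]][per_subject]))
    if (miss_frac > max_missing)
      stop(sprintf("covariate %s missing for %.0f%% of subjects (limit %.0f%%)",
                   cc, 100 * miss_frac, 100 * max_missing))
    if (miss_frac > 0) {
      idx <- which(is.na(data[[cc]]))
      data[[cc]][idx] <- categorical[[cc]]
      imputed[[cc]] <- list(n = length(idx), value = categorical[[cc]])
    }
  }
  attr(data, "imputed") <- imputed
  data
}

# Covariate list for one subject from the dataset rows.
subject_covariates <- function(data, id) {
  row <- data[data$ID == id, , drop = FALSE][1, ]
  cov <- list(weight = row$WT, alt = row$ALT, arm = row$ARM)
  extra <- setdiff(names(data), c("ID", "TIME", "AMT", "RATE", "DV", "EVID",
                                  "MDV", "CMT", "WT", "ALT", "ARM", "BLQ"))
  for (e in extra) cov[[tolower(e)]] <- row[[e]]
  cov
}
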