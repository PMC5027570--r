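# Cohort construction: registry ingestion, exclusion rules, derivation of the
# analysis variables (Z, T_Z, S, Y), covariate normalization and descriptive
# summaries.

DAYS_PER_MONTH <- 30.4375

#' Read a longitudinal registry table into subject records
#'
#' Reads a delimited text file with one row per clinic visit and groups the
#' rows into per-subject records.  Day offsets are computed relative to each
#' subject's first visit (the baseline visit), so visit times may be supplied
#' either as integer day offsets or as ISO dates.
#'
#' @param path Path to a CSV (comma) or TSV (tab) file; the dialect is chosen
#'   from the file extension (`.csv` vs `.tsv`/`.txt`).  A header row is
#'   required.
#' @param schema Named list mapping logical names to column names.  Mandatory
#'   entries: `subject_id`, `visit_day`, `outcome`.  Optional: `fvc`,
#'   `treatment_day`, `death_day`, and `covariates`, a character vector of
#'   per-subject baseline covariate columns (optionally named to rename them).
#' @return A list of `subject_record` objects, each a list with elements
#'   `subject_id`, `covariates` (named numeric), `visits` (data frame with
#'   columns `day`, `outcome`, `fvc`, sorted by day), `treatment_day` and
#'   `death_day` (integer day offsets from baseline, or `NA`).
#' @seealso [apply_exclusions()], [derive_analysis_rows()]
#' @export
load_registry <- function(path, schema) {
  stopifnot(is.list(schema))
  for (key in c("subject_id", "visit_day", "outcome")) {
    if (is.null(schema[[key]])) {
      stop("schema is missing mandatory entry '", key, "'", call. = FALSE)
    }
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  used <- c(schema$subject_id, schema$visit_day, schema$outcome,
            schema$fvc, schema$treatment_day, schema$death_day,
            unname(schema$covariates))
  missing_cols <- setdiff(used, names(raw))
  if (length(missing_cols)) {
    stop("registry file lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }

  ids <- as.character(raw[[schema$subject_id]])
  day_raw <- .as_day(raw[[schema$visit_day]])
  records <- lapply(split(seq_len(nrow(raw)), factor(ids, levels = unique(ids))),
                    function(idx) {
    sub <- raw[idx, , drop = FALSE]
    days <- day_raw[idx]
    if (anyDuplicated(days)) {
      stop("duplicate visit day for subject ", ids[idx[1]], call. = FALSE)
    }
    ord <- order(days)
    sub <- sub[ord, , drop = FALSE]
    days <- days[ord]
    t0 <- days[1]

    cov_cols <- schema$covariates
    covs <- numeric(0)
    if (length(cov_cols)) {
      covs <- vapply(unname(cov_cols), function(cn) as.numeric(sub[[cn]][1]),
                     numeric(1))
      names(covs) <- if (is.null(names(cov_cols))) unname(cov_cols) else
        ifelse(names(cov_cols) == "", unname(cov_cols), names(cov_cols))
    }

    grab_day <- function(col) {
      if (is.null(col)) return(NA_real_)
      v <- .as_day(sub[[col]])[1]
      if (is.na(v)) NA_real_ else v - t0
    }
    new_subject_record(
      subject_id = ids[idx[1]],
      covariates = covs,
      visits = data.frame(
        day = days - t0,
        outcome = as.numeric(sub[[schema$outcome]]),
        fvc = if (is.null(schema$fvc)) NA_real_ else as.numeric(sub[[schema$fvc]])
      ),
      treatment_day = grab_day(schema$treatment_day),
      death_day = grab_day(schema$death_day)
    )
  })
  names(records) <- NULL
  records
}

# Accept integer day offsets or ISO dates.
.as_day <- function(x) {
  if (all(is.na(x))) return(rep(NA_real_, length(x)))
  if (is.numeric(x)) return(as.numeric(x))
  if (is.character(x) || inherits(x, "Date")) {
    blank <- is.na(x) | (is.character(x) & !nzchar(trimws(as.character(x))))
    out <- rep(NA_real_, length(x))
    suppressWarnings(num <- as.numeric(x))
    if (!anyNA(num[!blank])) {
      out[!blank] <- num[!blank]
      return(out)
    }
    d <- as.Date(as.character(x), format = "%Y-%m-%d")
    if (anyNA(d[!blank])) stop("cannot parse visit days/dates", call. = FALSE)
    out[!blank] <- as.numeric(d[!blank])
    return(out)
  }
  stop("cannot parse visit days/dates", call. = FALSE)
}

#' Construct a subject record
#'
#' Low-level constructor used by [load_registry()] and the synthetic-registry
#' generator; validates the record invariants (sorted visits, baseline visit
#' at day 0, death not before the last visit).
#'
#' @param subject_id Identifier (coerced to character).
#' @param covariates Named numeric vector of baseline covariates.
#' @param visits Data frame with columns `day`, `outcome`, `fvc`.
#' @param treatment_day,death_day Day offsets from baseline, or `NA`.
#' @return An object of class `subject_record`.
#' @export
new_subject_record <- function(subject_id, covariates, visits,
                               treatment_day = NA_real_, death_day = NA_real_) {
  visits <- visits[order(visits$day), , drop = FALSE]
  rownames(visits) <- NULL
  if (nrow(visits) == 0L) stop("subject ", subject_id, " has no visits")
  if (visits$day[1] != 0) {
    stop("first visit of subject ", subject_id, " must be at day 0")
  }
  if (!is.na(death_day) && death_day < visits$day[nrow(visits)]) {
    stop("subject ", subject_id, " has a visit after the recorded death day")
  }
  structure(list(subject_id = as.character(subject_id),
                 covariates = covariates, visits = visits,
                 treatment_day = as.numeric(treatment_day),
                 death_day = as.numeric(death_day)),
            class = "subject_record")
}

#' Apply the cohort exclusion rules
#'
#' Removes subjects, in order: (1) no follow-up visit within `horizon_days`
#' of baseline; (2) observed survival beyond `max_survival_days`; (3) alive
#' at the horizon but with no post-baseline outcome measurement within the
#' horizon.  A subject is counted only under the first rule it violates.
#'
#' @param records List of `subject_record` objects.
#' @param horizon_days Outcome-measurement horizon in days (default 365,
#'   i.e. one year post-baseline).
#' @param max_survival_days Longest admissible observed survival (default
#'   1826 days, five years).
#' @return A list with elements `records` (the retained subjects) and
#'   `report`, an `exclusion_report` with `n_input`, the per-rule `excluded`
#'   counts and `n_remaining`.
#' @export
apply_exclusions <- function(records, horizon_days = 365,
                             max_survival_days = 1826) {
  n_input <- length(records)
  rules <- c(no_followup = 0L, long_survival = 0L, no_outcome = 0L)
  keep <- logical(n_input)
  for (i in seq_along(records)) {
    r <- records[[i]]
    post <- r$visits[r$visits$day > 0, , drop = FALSE]
    if (!any(post$day <= horizon_days)) {
      rules[["no_followup"]] <- rules[["no_followup"]] + 1L
    } else if (!is.na(r$death_day) && r$death_day > max_survival_days) {
      rules[["long_survival"]] <- rules[["long_survival"]] + 1L
    } else {
      alive <- is.na(r$death_day) || r$death_day > horizon_days
      has_y <- any(post$day <= horizon_days & !is.na(post$outcome))
      if (alive && !has_y) {
        rules[["no_outcome"]] <- rules[["no_outcome"]] + 1L
      } else {
        keep[i] <- TRUE
      }
    }
  }
  report <- structure(list(n_input = n_input, excluded = rules,
                           n_remaining = sum(keep)),
                      class = "exclusion_report")
  stopifnot(report$n_input - sum(report$excluded) == report$n_remaining)
  list(records = records[keep], report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Exclusion report:", x$n_input, "subjects in\n")
  cat("  no follow-up visit within horizon:", x$excluded[["no_followup"]], "\n")
  cat("  survival beyond maximum:          ", x$excluded[["long_survival"]], "\n")
  cat("  no eligible outcome measurement:  ", x$excluded[["no_outcome"]], "\n")
  cat("  remaining:", x$n_remaining, "\n")
  invisible(x)
}

#' Derive the per-subject analysis variables
#'
#' Computes, for one subject, the treatment indicator `Z` (treated on or
#' before the horizon), survival indicator `S` (alive past the horizon), the
#' outcome `Y` taken from the latest visit at or before the horizon with a
#' non-missing outcome (undefined when `S = 0`: censoring by death), and the
#' time from treatment to the horizon in months (`0` for untreated subjects).
#'
#' @param record A `subject_record` that passed [apply_exclusions()].
#' @param horizon_days Outcome-measurement horizon in days.
#' @return One-row data frame with columns `subject_id`, `Z`, `T_Z_days`,
#'   `time_from_treatment_months`, `S`, `Y`, `death_day` (kept for the
#'   GPS risk-set construction), and one column per baseline covariate.
#' @export
derive_analysis_row <- function(record, horizon_days = 365) {
  z <- as.integer(!is.na(record$treatment_day) &&
                    record$treatment_day <= horizon_days)
  s <- as.integer(is.na(record$death_day) || record$death_day > horizon_days)
  y <- NA_real_
  if (s == 1L) {
    v <- record$visits
    elig <- which(v$day > 0 & v$day <= horizon_days & !is.na(v$outcome))
    if (!length(elig)) {
      stop("subject ", record$subject_id,
           " is alive at the horizon but has no eligible outcome visit ",
           "(should have been excluded)", call. = FALSE)
    }
    y <- v$outcome[elig[which.max(v$day[elig])]]
  }
  tz <- if (z == 1L) record$treatment_day else NA_real_
  tmonths <- if (z == 1L) (horizon_days - record$treatment_day) / DAYS_PER_MONTH else 0
  out <- data.frame(subject_id = record$subject_id, Z = z, T_Z_days = tz,
                    time_from_treatment_months = tmonths, S = s, Y = y,
                    death_day = record$death_day,
                    stringsAsFactors = FALSE)
  if (length(record$covariates)) {
    out <- cbind(out, as.data.frame(as.list(record$covariates)))
  }
  out
}

#' Derive the analysis table for a whole cohort
#'
#' @param records List of `subject_record` objects (post-exclusion).
#' @param horizon_days Outcome-measurement horizon in days.
#' @return Data frame with one row per subject; see [derive_analysis_row()].
#' @export
derive_analysis_rows <- function(records, horizon_days = 365) {
  rows <- do.call(rbind, lapply(records, derive_analysis_row,
                                horizon_days = horizon_days))
  rownames(rows) <- NULL
  rows
}

#' Standardize continuous covariates
#'
#' Replaces each listed covariate by `(x - mean) / sd` computed over the
#' analysis cohort.  The means and standard deviations are attached as the
#' `"scaling"` attribute so reports can state the original units.
#'
#' @param rows Analysis data frame.
#' @param which Character vector of covariate column names to standardize.
#' @return `rows` with the listed columns standardized.
#' @export
normalize_covariates <- function(rows, which) {
  scaling <- attr(rows, "scaling")
  if (is.null(scaling)) scaling <- list()
  for (nm in which) {
    if (!nm %in% names(rows)) stop("no covariate column '", nm, "'")
    x <- rows[[nm]]
    m <- mean(x, na.rm = TRUE)
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      stop("covariate '", nm, "' has zero spread; cannot standardize")
    }
    rows[[nm]] <- (x - m) / s
    scaling[[nm]] <- c(mean = m, sd = s)
  }
  attr(rows, "scaling") <- scaling
  rows
}

#' Compare treated and untreated arms at the horizon
#'
#' Produces the usual baseline table: per-arm mean (SD) for continuous
#' variables, proportion (count) for binary ones, the survival proportion,
#' and two-sample comparisons (Welch t test for continuous variables,
#' Pearson chi-squared for proportions).
#'
#' @param rows Analysis data frame.
#' @param continuous,binary Character vectors naming the covariate columns of
#'   each kind; sensible defaults cover the survival indicator only.
#' @return Data frame with columns `variable`, `type`, `treated_mean`,
#'   `treated_sd_or_n`, `untreated_mean`, `untreated_sd_or_n`, `p_value`.
#' @export
cohort_summary <- function(rows, continuous = character(0),
                           binary = character(0)) {
  trt <- rows[rows$Z == 1, , drop = FALSE]
  ctl <- rows[rows$Z == 0, , drop = FALSE]
  small <- nrow(trt) < 2 || nrow(ctl) < 2
  one <- function(nm, type) {
    a <- trt[[nm]]; b <- ctl[[nm]]
    if (type == "continuous") {
      p <- if (small) NA_real_ else
        tryCatch(stats::t.test(a, b)$p.value, error = function(e) NA_real_)
      data.frame(variable = nm, type = type,
                 treated_mean = mean(a, na.rm = TRUE),
                 treated_sd_or_n = stats::sd(a, na.rm = TRUE),
                 untreated_mean = mean(b, na.rm = TRUE),
                 untreated_sd_or_n = stats::sd(b, na.rm = TRUE),
                 p_value = p, stringsAsFactors = FALSE)
    } else {
      tab <- rbind(c(sum(a == 1, na.rm = TRUE), sum(a == 0, na.rm = TRUE)),
                   c(sum(b == 1, na.rm = TRUE), sum(b == 0, na.rm = TRUE)))
      p <- if (small || any(colSums(tab) == 0)) NA_real_ else
        tryCatch(stats::chisq.test(tab, correct = FALSE)$p.value,
                 error = function(e) NA_real_)
      data.frame(variable = nm, type = type,
                 treated_mean = mean(a, na.rm = TRUE),
                 treated_sd_or_n = sum(a == 1, na.rm = TRUE),
                 untreated_mean = mean(b, na.rm = TRUE),
                 untreated_sd_or_n = sum(b == 1, na.rm = TRUE),
                 p_value = p, stringsAsFactors = FALSE)
    }
  }
  surv <- one("S", "binary")
  surv$variable <- "proportion_surviving"
  parts <- c(lapply(continuous, one, type = "continuous"),
             lapply(binary, one, type = "binary"),
             list(surv))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
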