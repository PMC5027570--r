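# Synthetic registry generator.  Emits ALS-registry-like cohorts with known
# principal strata, a confounded (Weibull proportional-hazards) treatment
# time, and per-stratum normal outcomes with a known treatment effect in the
# always-survivor stratum, so the whole pipeline -- ingestion, propensity
# models, DA-MCMC, effect summaries -- can be exercised against known truth.

#' Construct a synthetic-truth specification
#'
#' Collects every generator parameter: covariate distributions, the
#' Weibull proportional-hazards model for latent time to treatment, the
#' multinomial-logit principal-strata model (on the covariates directly,
#' not on any propensity score, so propensity adjustment is a genuine
#' claim being tested), and the per-stratum outcome regressions.  The true
#' SACE at lag `delta` months is `eta_Z + eta_T * delta`.
#'
#' @param covariates List with `continuous` (named list of `c(mean, sd)`)
#'   and `binary` (named probability vector).
#' @param treatment List with Weibull `shape`, baseline `rate`, named
#'   coefficient vector `beta` on the model-scale covariates, and
#'   `horizon` in days.
#' @param alpha Coefficient matrix of the strata model: rows = intercept +
#'   model-scale covariates, columns = `LL`, `LD`, `DL` (reference DD).
#' @param outcome Named list per stratum `LL`, `LD`, `DL`: `eta0`
#'   (intercept), `gamma` (named covariate effects), `sigma2`; `LL` also
#'   has `eta_Z` and `eta_T`.
#' @return A `synthetic_truth` object; true effects in `$sace`.
#' @seealso [als_like_truth()] for the calibrated default preset.
#' @export
synthetic_truth <- function(covariates, treatment, alpha, outcome) {
  stopifnot(all(c("LL", "LD", "DL") %in% colnames(alpha)),
            all(vapply(outcome, function(o) o$sigma2 > 0, logical(1))))
  structure(list(covariates = covariates, treatment = treatment,
                 alpha = alpha, outcome = outcome,
                 sace = c(delta0 = outcome$LL$eta_Z,
                          slope = outcome$LL$eta_T)),
            class = "synthetic_truth")
}

#' ALS-registry-like truth preset
#'
#' Defaults emulate the gross composition of an ALS clinic registry:
#' roughly one third of subjects treated within the first year, roughly
#' half surviving to the one-year horizon, most subjects in the LL and DD
#' strata with LD and DL each under 5%, and treated subjects sicker at
#' baseline (lower FVC, older, less spinal onset) than untreated ones.
#' Baseline hazard and strata intercepts were calibrated once to those
#' marginal compositions.
#'
#' @param eta_Z True LL-stratum treatment effect at lag 0 (BMI units).
#' @param eta_T True per-month effect of time from treatment to horizon.
#' @param confounding Scales the covariate effects in the treatment-time
#'   model; 0 gives randomized treatment times.
#' @param sigma2_LL Residual outcome variance in LL.
#' @return A `synthetic_truth` object.
#' @export
als_like_truth <- function(eta_Z = 2.5, eta_T = -0.3, confounding = 1,
                           sigma2_LL = 4) {
  covs <- list(
    continuous = list(age = c(mean = 63, sd = 11.5),
                      bmi0 = c(mean = 25.4, sd = 5.7),
                      fvc0 = c(mean = 71, sd = 26)),
    binary = c(female = 0.45, spinal = 0.67, dtdx30 = 0.19))
  model_names <- c("age", "bmi0", "fvc0", "female", "spinal", "dtdx30")
  beta_t <- c(age = 0.30, bmi0 = -0.10, fvc0 = -0.50,
              female = 0.20, spinal = -0.40, dtdx30 = 0.10) * confounding
  # rows: intercept + model covariates; cols: LL, LD, DL (ref DD)
  alpha <- cbind(
    LL = c(-0.10, -0.35, 0.10, 0.60, -0.10, 0.30, -0.10),
    LD = c(-3.00, 0.10, 0.00, -0.20, 0.10, -0.10, 0.00),
    DL = c(-3.00, 0.00, 0.00, 0.15, 0.00, 0.10, 0.00))
  rownames(alpha) <- c("intercept", model_names)
  gamma_LL <- c(age = -0.4, bmi0 = 2.5, fvc0 = 0.8,
                female = 0.0, spinal = 0.2, dtdx30 = 0.0)
  outcome <- list(
    LL = list(eta0 = 25.0, eta_Z = eta_Z, eta_T = eta_T,
              gamma = gamma_LL, sigma2 = sigma2_LL),
    LD = list(eta0 = 22.0, gamma = 0.8 * gamma_LL, sigma2 = 6.25),
    DL = list(eta0 = 23.5, gamma = 0.8 * gamma_LL, sigma2 = 6.25))
  synthetic_truth(
    covariates = covs,
    treatment = list(shape = 1.2, rate = 3.5e-4, beta = beta_t,
                     horizon = 365),
    alpha = alpha, outcome = outcome)
}

# Model-scale covariate matrix: standardized continuous, raw 0/1 binaries.
.model_covariates <- function(truth, raw) {
  cont <- truth$covariates$continuous
  cols <- lapply(names(cont), function(nm)
    (raw[[nm]] - cont[[nm]][["mean"]]) / cont[[nm]][["sd"]])
  names(cols) <- names(cont)
  for (nm in names(truth$covariates$binary)) cols[[nm]] <- raw[[nm]]
  do.call(cbind, cols)
}

#' Generate a synthetic cohort with known strata
#'
#' Draws covariates, a latent Weibull time to treatment (treated iff at or
#' before the horizon), a latent principal stratum from the multinomial
#' logit, survival deterministically from the stratum and realized
#' treatment, and outcomes for survivors from the stratum's normal
#' regression.  Also lays the subjects out as a visit-level registry table
#' (3--8 visits each) so cohort ingestion can be exercised end to end; the
#' registry, passed through [derive_analysis_rows()], reproduces the
#' generated `(Z, S, Y)` exactly.
#'
#' @param truth A `synthetic_truth` object.
#' @param n Number of subjects.
#' @param seed RNG seed.
#' @param emit_registry Also lay the cohort out as a visit-level registry
#'   table (default `TRUE`; skipping it speeds up large simulation runs
#'   that work from the analysis rows directly).
#' @return List with `rows` (analysis data frame: `Z`, `T_Z_days`,
#'   `time_from_treatment_months`, `S`, `Y`, `death_day`, raw covariates),
#'   `registry` (visit-level data frame, or `NULL`), `latent` (subject id,
#'   true stratum, latent treatment time) and `truth`.
#' @export
generate_cohort <- function(truth, n, seed = 1L, emit_registry = TRUE) {
  set.seed(seed)
  stopifnot(n >= 1)
  horizon <- truth$treatment$horizon
  cont <- truth$covariates$continuous
  bin <- truth$covariates$binary
  raw <- data.frame(subject_id = sprintf("S%05d", seq_len(n)))
  for (nm in names(cont)) {
    raw[[nm]] <- stats::rnorm(n, cont[[nm]][["mean"]], cont[[nm]][["sd"]])
  }
  raw$fvc0 <- pmax(raw$fvc0, 10)       # FVC percent-predicted floor
  raw$bmi0 <- pmax(raw$bmi0, 13)
  for (nm in names(bin)) raw[[nm]] <- stats::rbinom(n, 1, bin[[nm]])
  Xm <- .model_covariates(truth, raw)

  # latent treatment time: Weibull PH
  lp_t <- drop(Xm %*% truth$treatment$beta[colnames(Xm)])
  u <- stats::runif(n)
  t_lat <- (-log(u) / (truth$treatment$rate * exp(lp_t)))^
    (1 / truth$treatment$shape)
  treatment_day <- ifelse(t_lat <= 500, pmin(pmax(round(t_lat), 1), 500),
                          NA_real_)
  Z <- as.integer(!is.na(treatment_day) & treatment_day <= horizon)

  # latent principal stratum
  X2 <- cbind(intercept = 1, Xm)
  params <- new_strata_parameters(truth$alpha[, c("LL", "LD", "DL")],
                                  monotonicity = FALSE)
  pi_mat <- strata_probs(params, X2)
  if (any(apply(pi_mat, 2, function(p) all(p >= 0.999)))) {
    warning("degenerate truth: one stratum has probability >= 0.999 ",
            "for every subject")
  }
  cum <- t(apply(pi_mat, 1, cumsum))
  G <- STRATA_ALL[max.col(cum >= stats::runif(n), ties.method = "first")]

  S <- as.integer(G == "LL" | (G == "LD" & Z == 1) | (G == "DL" & Z == 0))
  tmonths <- ifelse(Z == 1, (horizon - treatment_day) / DAYS_PER_MONTH, 0)

  Y <- rep(NA_real_, n)
  for (g in c("LL", "LD", "DL")) {
    idx <- which(S == 1 & G == g)
    if (!length(idx)) next
    o <- truth$outcome[[g]]
    mu <- o$eta0 + drop(Xm[idx, , drop = FALSE] %*% o$gamma[colnames(Xm)])
    if (g == "LL") mu <- mu + o$eta_Z * Z[idx] + o$eta_T * tmonths[idx]
    Y[idx] <- stats::rnorm(length(idx), mu, sqrt(o$sigma2))
  }

  death_day <- rep(NA_real_, n)
  dead <- which(S == 0)
  death_day[dead] <- sample(60:horizon, length(dead), replace = TRUE)
  late_death <- which(S == 1 & stats::runif(n) < 0.5)
  death_day[late_death] <- sample((horizon + 5):1800, length(late_death),
                                  replace = TRUE)

  rows <- data.frame(subject_id = raw$subject_id, Z = Z,
                     T_Z_days = ifelse(Z == 1, treatment_day, NA_real_),
                     time_from_treatment_months = tmonths, S = S, Y = Y,
                     death_day = death_day, stringsAsFactors = FALSE)
  for (nm in colnames(Xm)) rows[[nm]] <- raw[[nm]]

  registry <- if (emit_registry) {
    .emit_registry(rows, raw, treatment_day, horizon)
  }
  latent <- data.frame(subject_id = raw$subject_id, stratum = G,
                       latent_treatment_time = t_lat,
                       stringsAsFactors = FALSE)
  list(rows = rows, registry = registry, latent = latent, truth = truth)
}

# Visit-level registry table consistent with the generated (Z, S, Y):
# the latest non-missing outcome visit at or before the horizon carries Y.
.emit_registry <- function(rows, raw, treatment_day, horizon) {
  out <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    dd <- rows$death_day[i]
    last_day <- if (is.na(dd)) horizon + 90 else min(dd - 7, horizon + 90)
    n_extra <- sample(1:6, 1)
    in_horizon <- round(stats::runif(1, 25, min(horizon - 5, last_day)))
    days <- sort(unique(c(in_horizon, pmin(pmax(
      round(stats::runif(n_extra, 25, max(40, last_day))), 25), last_day))))
    days <- c(0, days)
    bmi_path <- raw$bmi0[i] + cumsum(c(0, stats::rnorm(length(days) - 1,
                                                       -0.15, 0.4)))
    fvc_path <- pmax(raw$fvc0[i] + cumsum(c(0, stats::rnorm(length(days) - 1,
                                                            -2.5, 3))), 5)
    outcome <- bmi_path
    # a sprinkling of missing outcome measurements at interior visits
    if (length(days) > 3) {
      miss <- sample(2:(length(days) - 1), 1)
      outcome[miss] <- NA_real_
    }
    if (rows$S[i] == 1) {
      elig <- which(days > 0 & days <= horizon & !is.na(outcome))
      if (!length(elig)) {
        k <- max(which(days > 0 & days <= horizon))
        outcome[k] <- bmi_path[k]
        elig <- k
      }
      outcome[max(elig)] <- rows$Y[i]
    }
    out[[i]] <- data.frame(
      subject_id = rows$subject_id[i], day = days, bmi = outcome,
      fvc = fvc_path,
      treatment_day = if (is.na(treatment_day[i])) NA_real_ else treatment_day[i],
      death_day = dd,
      age = raw$age[i], bmi0 = raw$bmi0[i], fvc0 = raw$fvc0[i],
      female = raw$female[i], spinal = raw$spinal[i],
      dtdx30 = raw$dtdx30[i], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Registry schema for generator output
#'
#' The [load_registry()] schema matching the columns written by
#' [generate_cohort()]`$registry`.
#'
#' @return Schema list.
#' @export
synthetic_schema <- function() {
  list(subject_id = "subject_id", visit_day = "day", outcome = "bmi",
       fvc = "fvc", treatment_day = "treatment_day", death_day = "death_day",
       covariates = c("age", "bmi0", "fvc0", "female", "spinal", "dtdx30"))
}

#' Time-to-treatment inputs for the GPS Cox model
#'
#' Treated subjects contribute their treatment day as an event; untreated
#' subjects are censored at the earlier of death and the horizon; subjects
#' treated after the horizon are censored at the horizon.
#'
#' @param rows Analysis data frame with `Z`, `T_Z_days`, `death_day`.
#' @param horizon_days Outcome horizon.
#' @return List with `time` and `event` vectors.
#' @export
gps_time_event <- function(rows, horizon_days = 365) {
  time <- ifelse(rows$Z == 1, pmax(rows$T_Z_days, 0.5),
                 pmin(ifelse(is.na(rows$death_day), horizon_days,
                             rows$death_day), horizon_days))
  list(time = as.numeric(time), event = as.integer(rows$Z))
}

#' Fit both propensity models and attach scores
#'
#' Convenience wrapper: fits the logistic PS and the Cox GPS on the named
#' covariates (continuous ones standardized first) and attaches `ps` and
#' `gps` columns to the rows.
#'
#' @param rows Analysis data frame.
#' @param covariates Covariate columns for both treatment models.
#' @param standardize Continuous columns to standardize before fitting.
#' @param horizon_days Outcome horizon for the censoring convention.
#' @return List with `rows` (scores attached), `ps_model`, `gps_model`.
#' @export
attach_scores <- function(rows,
                          covariates = c("age", "bmi0", "fvc0", "female",
                                         "spinal", "dtdx30"),
                          standardize = c("age", "bmi0", "fvc0"),
                          horizon_days = 365) {
  rows <- normalize_covariates(rows, intersect(standardize, covariates))
  D <- as.matrix(rows[, covariates, drop = FALSE])
  ps_model <- fit_logistic_ps(cbind(intercept = 1, D), rows$Z)
  te <- gps_time_event(rows, horizon_days)
  gps_model <- fit_cox_gps(D, te$time, te$event)
  rows$ps <- ps_model$scores
  rows$gps <- gps_model$scores
  list(rows = rows, ps_model = ps_model, gps_model = gps_model)
}

#' Parameter-recovery experiment
#'
#' Repeatedly generates a cohort from `truth`, runs the full pipeline
#' (propensity fits, DA-MCMC, SACE summary) plus the naive survivors-only
#' comparator, and aggregates bias, RMSE and empirical 95%-credible-interval
#' coverage of the treatment terms against the truth.
#'
#' @param truth A `synthetic_truth`.
#' @param n Cohort size per replicate (default 600).
#' @param replicates Number of replicates (default 50).
#' @param config `sampler_config` template; its seed is ignored (replicate
#'   `r` runs with `seed_base + r`).
#' @param seed_base Base seed.
#' @return A `recovery_result` list: `per_replicate` data frame and
#'   `aggregate` (bias, rmse, coverage per term, naive bias).
#' @export
recovery_experiment <- function(truth, n = 600, replicates = 50,
                                config = sampler_config(n_iter = 2000,
                                                        burn_in = 500,
                                                        model_type = "time",
                                                        monotonicity = TRUE),
                                seed_base = 1000L) {
  stopifnot(replicates >= 2)
  truth_vals <- c(Z = unname(truth$sace[["delta0"]]),
                  time = unname(truth$sace[["slope"]]))
  res <- vector("list", replicates)
  failures <- 0L
  for (r in seq_len(replicates)) {
    res[[r]] <- tryCatch({
      coh <- generate_cohort(truth, n, seed = seed_base + r,
                             emit_registry = FALSE)
      sc <- attach_scores(coh$rows)
      cfg <- config
      cfg$seed <- seed_base + r
      draws <- run_da_mcmc(sc$rows, cfg)
      sace <- compute_sace(draws)
      naive <- naive_analysis(sc$rows, model_type = cfg$model_type,
                              ps_order = cfg$ps_order)
      naive0 <- naive_analysis(sc$rows, model_type = cfg$model_type,
                               ps_order = 0)
      z <- sace[sace$term == "Z", ]
      nv <- naive[naive$term == "Z", ]
      nv0 <- naive0[naive0$term == "Z", ]
      row <- data.frame(replicate = r,
                        est_Z = z$mean, lower_Z = z$lower, upper_Z = z$upper,
                        covered_Z = z$lower <= truth_vals[["Z"]] &
                          truth_vals[["Z"]] <= z$upper,
                        naive_Z = nv$estimate,
                        naive_unadj_Z = nv0$estimate,
                        stringsAsFactors = FALSE)
      if (cfg$model_type == "time") {
        tt <- sace[sace$term == "time", ]
        row$est_time <- tt$mean
        row$covered_time <- tt$lower <= truth_vals[["time"]] &
          truth_vals[["time"]] <= tt$upper
      }
      row
    }, error = function(e) {
      failures <<- failures + 1L
      warning("replicate ", r, " failed: ", conditionMessage(e))
      NULL
    })
  }
  if (failures > 0.2 * replicates) {
    stop("more than 20% of recovery replicates failed", call. = FALSE)
  }
  per <- do.call(rbind, res)
  agg <- list(
    truth = truth_vals,
    bias_Z = mean(per$est_Z) - truth_vals[["Z"]],
    rmse_Z = sqrt(mean((per$est_Z - truth_vals[["Z"]])^2)),
    se_bias_Z = stats::sd(per$est_Z) / sqrt(nrow(per)),
    coverage_Z = mean(per$covered_Z),
    naive_bias_Z = mean(per$naive_Z) - truth_vals[["Z"]],
    naive_unadj_bias_Z = mean(per$naive_unadj_Z) - truth_vals[["Z"]],
    n_failures = failures)
  if (!is.null(per$est_time)) {
    agg$bias_time <- mean(per$est_time) - truth_vals[["time"]]
    agg$coverage_time <- mean(per$covered_time)
  }
  structure(list(per_replicate = per, aggregate = agg,
                 n = n, replicates = replicates),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  a <- x$aggregate
  cat("Recovery over", nrow(x$per_replicate), "replicates (n =", x$n, ")\n")
  cat(sprintf("  SACE bias %+0.3f (MC se %0.3f), RMSE %0.3f, coverage %0.2f\n",
              a$bias_Z, a$se_bias_Z, a$rmse_Z, a$coverage_Z))
  cat(sprintf("  naive survivors-only bias %+0.3f\n", a$naive_bias_Z))
  invisible(x)
}

#' Check imputation probabilities against latent strata
#'
#' Evaluates the conditional membership probabilities at the generator's
#' own (true) parameters and compares them with the latent strata: among
#' subjects assigned probability above `threshold` to some stratum, the
#' latent stratum should match; a calibration table of predicted
#' probability versus empirical frequency is also returned.
#'
#' @param cohort Output of [generate_cohort()].
#' @param threshold High-confidence cutoff (default 0.9).
#' @return List with `accuracy` (match rate among high-confidence
#'   subjects), `n_confident`, and `calibration` (data frame of binned
#'   predicted probability vs empirical frequency).
#' @export
strata_oracle_check <- function(cohort, threshold = 0.9) {
  truth <- cohort$truth
  rows <- cohort$rows
  Xm <- .model_covariates(truth, rows)
  X2 <- cbind(intercept = 1, Xm)
  params <- new_strata_parameters(truth$alpha[, c("LL", "LD", "DL")],
                                  monotonicity = FALSE)
  pi_mat <- strata_probs(params, X2)
  n <- nrow(rows)
  rho <- matrix(0, n, 4, dimnames = list(NULL, STRATA_ALL))
  for (i in seq_len(n)) {
    logd <- NULL
    if (rows$S[i] == 1) {
      logd <- sapply(c("LL", "LD", "DL"), function(g) {
        o <- truth$outcome[[g]]
        mu <- o$eta0 + sum(Xm[i, ] * o$gamma[colnames(Xm)])
        if (g == "LL") {
          mu <- mu + o$eta_Z * rows$Z[i] +
            o$eta_T * rows$time_from_treatment_months[i]
        }
        stats::dnorm(rows$Y[i], mu, sqrt(o$sigma2), log = TRUE)
      })
    }
    rho[i, ] <- membership_probs(rows$Z[i], rows$S[i],
                                 stats::setNames(pi_mat[i, ], STRATA_ALL),
                                 log_dens = logd)
  }
  lat <- cohort$latent$stratum
  conf <- apply(rho, 1, max) > threshold
  top <- STRATA_ALL[max.col(rho, ties.method = "first")]
  acc <- if (any(conf)) mean(top[conf] == lat[conf]) else NA_real_
  # calibration: predicted membership probability vs empirical frequency
  pr <- as.numeric(rho)
  hit <- as.numeric(outer(lat, STRATA_ALL, `==`))
  bins <- cut(pr, breaks = seq(0, 1, 0.1), include.lowest = TRUE)
  calib <- stats::aggregate(list(empirical = hit, predicted = pr),
                            by = list(bin = bins), FUN = mean)
  calib$n <- as.integer(table(bins)[as.character(calib$bin)])
  list(accuracy = acc, n_confident = sum(conf), calibration = calib)
}
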