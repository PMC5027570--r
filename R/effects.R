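# Posterior summaries: the SACE with equal-tailed 95% credible intervals,
# the effect-versus-time-from-treatment curve, the naive survivors-only
# comparator, and the model-grid report.

.eq_tail <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  stats::quantile(x, probs = c(a, 1 - a), names = FALSE, type = 7)
}

#' Summarize the survivor average causal effect
#'
#' Posterior mean and equal-tailed 95% credible interval of the LL-stratum
#' treatment coefficient(s): the binary treatment model yields one effect
#' (the SACE of treatment), the time-of-treatment model additionally the
#' per-month effect of time from treatment to the horizon.  An effect is
#' flagged significant when its interval excludes 0.
#'
#' @param draws A `sace_draws` object.
#' @param level Credible level (default 0.95).
#' @return A `sace_summary` data frame with one row per treatment term:
#'   `term`, `mean`, `lower`, `upper`, `significant`; model metadata in
#'   attributes.
#' @export
compute_sace <- function(draws, level = 0.95) {
  stopifnot(inherits(draws, "sace_draws"), nrow(draws$chain) > 0)
  terms <- c(Z = "eta_LL.Z")
  if (draws$config$model_type == "time") {
    terms <- c(terms, time = "eta_LL.time")
  }
  out <- do.call(rbind, lapply(names(terms), function(tn) {
    x <- draws$chain[, terms[[tn]]]
    ci <- .eq_tail(x, level)
    data.frame(term = tn, mean = mean(x), lower = ci[1], upper = ci[2],
               significant = ci[1] > 0 || ci[2] < 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "model_type") <- draws$config$model_type
  attr(out, "monotonicity") <- draws$config$monotonicity
  attr(out, "ps_order") <- draws$config$ps_order
  attr(out, "level") <- level
  class(out) <- c("sace_summary", class(out))
  out
}

#' Treatment effect over time from treatment
#'
#' Evaluates, draw by draw, the LL-stratum effect `eta_Z + eta_T * delta`
#' on a grid of lags `delta` (months from treatment to the outcome
#' horizon), and summarizes the pointwise posterior mean and equal-tailed
#' 95% band.  At `delta = 0` this reproduces the [compute_sace()] summary
#' of the treatment indicator on the same draws.
#'
#' @param draws A `sace_draws` object from the time-of-treatment model.
#' @param delta_grid Grid of lags in months (default 0 to 12 by 0.25).
#' @param level Credible level.
#' @return Data frame with columns `delta_months`, `mean`, `lower`, `upper`.
#' @export
effect_curve <- function(draws, delta_grid = seq(0, 12, by = 0.25),
                         level = 0.95) {
  stopifnot(inherits(draws, "sace_draws"))
  if (draws$config$model_type != "time") {
    stop("effect_curve requires draws from the time-of-treatment model",
         call. = FALSE)
  }
  ez <- draws$chain[, "eta_LL.Z"]
  et <- draws$chain[, "eta_LL.time"]
  out <- do.call(rbind, lapply(delta_grid, function(d) {
    eff <- ez + et * d
    ci <- .eq_tail(eff, level)
    data.frame(delta_months = d, mean = mean(eff),
               lower = ci[1], upper = ci[2])
  }))
  rownames(out) <- NULL
  out
}

#' Naive survivors-only analysis
#'
#' Ordinary least squares of the outcome on the LL-stratum design
#' (intercept, treatment term(s), optional propensity terms) restricted to
#' observed survivors, ignoring principal strata.  Reported with
#' normal-theory 95% confidence intervals; this is the comparator whose
#' bias the principal-stratification estimator is designed to remove when
#' survival differs by stratum and treatment is confounded.
#'
#' @param rows Analysis data frame (with `ps`/`gps` columns as required).
#' @param model_type `"binary"` or `"time"`.
#' @param ps_order Propensity polynomial order (0 = unadjusted).
#' @param level Confidence level.
#' @return Data frame with columns `term`, `estimate`, `lower`, `upper`,
#'   `se`; number of survivors used in attribute `"n"`.
#' @export
naive_analysis <- function(rows, model_type = c("binary", "time"),
                           ps_order = 1L, level = 0.95) {
  model_type <- match.arg(model_type)
  surv <- rows[rows$S == 1, , drop = FALSE]
  if (!nrow(surv)) stop("no survivors to analyze", call. = FALSE)
  if (ps_order >= 1L) {
    score_col <- if (model_type == "binary") "ps" else "gps"
    terms <- expand_ps_terms(surv[[score_col]], ps_order)
  } else {
    terms <- matrix(numeric(0), nrow = nrow(surv), ncol = 0)
  }
  X <- if (model_type == "binary") {
    cbind(intercept = 1, Z = surv$Z, terms)
  } else {
    cbind(intercept = 1, Z = surv$Z,
          time = surv$Z * surv$time_from_treatment_months, terms)
  }
  if (qr(X)$rank < ncol(X)) {
    stop("singular survivors-only design (columns: ",
         paste(colnames(X), collapse = ", "), ")", call. = FALSE)
  }
  fit <- stats::lm.fit(X, surv$Y)
  n <- nrow(X); p <- ncol(X)
  s2 <- sum(fit$residuals^2) / (n - p)
  XtX_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(s2 * diag(XtX_inv))
  tcrit <- stats::qt(1 - (1 - level) / 2, df = n - p)
  out <- data.frame(term = colnames(X), estimate = unname(fit$coefficients),
                    lower = unname(fit$coefficients - tcrit * se),
                    upper = unname(fit$coefficients + tcrit * se),
                    se = unname(se), stringsAsFactors = FALSE)
  attr(out, "n") <- n
  out
}

#' Plot the treatment effect over time from treatment
#'
#' Posterior mean with the shaded 95% band, and the null line at zero.
#'
#' @param curve Data frame from [effect_curve()].
#' @param ... Passed to [plot()].
#' @return Invisibly, `curve`.
#' @export
plot_effect_curve <- function(curve, ...) {
  plot(curve$delta_months, curve$mean, type = "n",
       ylim = range(curve$lower, curve$upper, 0),
       xlab = "Months from treatment to outcome horizon",
       ylab = "Treated - untreated outcome difference (LL stratum)", ...)
  graphics::polygon(c(curve$delta_months, rev(curve$delta_months)),
                    c(curve$lower, rev(curve$upper)),
                    col = grDevices::adjustcolor("steelblue", 0.25),
                    border = NA)
  graphics::lines(curve$delta_months, curve$mean, lwd = 2,
                  col = "steelblue4")
  graphics::abline(h = 0, lty = 2)
  invisible(curve)
}

#' Tabulate SACE estimates across model variants
#'
#' Collects fitted variants (2 treatment models x propensity orders 0-3 x
#' monotonicity on/off) into one comparison table; variants not supplied
#' appear as gaps, not errors.
#'
#' @param summaries List of `sace_summary` objects from [compute_sace()].
#' @return Data frame with one row per variant and treatment term:
#'   `model_type`, `ps_order`, `monotonicity`, `term`, `mean`, `lower`,
#'   `upper`, `significant`.
#' @export
results_report <- function(summaries) {
  if (!length(summaries)) {
    return(data.frame(model_type = character(0), ps_order = integer(0),
                      monotonicity = logical(0), term = character(0),
                      mean = numeric(0), lower = numeric(0),
                      upper = numeric(0), significant = logical(0)))
  }
  out <- do.call(rbind, lapply(summaries, function(s) {
    cbind(data.frame(model_type = attr(s, "model_type"),
                     ps_order = attr(s, "ps_order"),
                     monotonicity = attr(s, "monotonicity")),
          as.data.frame(s))
  }))
  rownames(out) <- NULL
  out[order(out$model_type, out$ps_order, out$monotonicity, out$term), ]
}
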