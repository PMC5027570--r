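# Propensity machinery: standard (logistic) propensity score for the binary
# treatment model, generalized propensity score (Cox PH linear predictor) for
# the time-of-treatment model, polynomial adjustment terms, and covariate
# balance diagnostics.

#' Fit the standard propensity score by logistic regression
#'
#' Maximum-likelihood logistic regression of the binary treatment indicator
#' on baseline covariates, fitted by iteratively reweighted least squares.
#' The fitted probabilities are the propensity scores.
#'
#' @param D Numeric covariate matrix including an intercept column.
#' @param Z Binary treatment indicator (0/1), one per row of `D`.
#' @return A `propensity_model` list: `kind = "logistic"`, named
#'   `coefficients`, `scores` (fitted probabilities in (0,1)), `iterations`
#'   and `gradient_norm` (score-equation norm at the MLE).
#' @export
fit_logistic_ps <- function(D, Z) {
  D <- as.matrix(D)
  stopifnot(nrow(D) == length(Z), all(Z %in% c(0, 1)))
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    dropped <- colnames(D)[qrD$pivot[(qrD$rank + 1):ncol(D)]]
    stop("singular design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  fit <- suppressWarnings(
    stats::glm.fit(x = D, y = Z, family = stats::binomial())
  )
  p <- fit$fitted.values
  if (any(abs(fit$coefficients) > 15) || any(p > 1 - 1e-10) || any(p < 1e-10)) {
    stop("(near-)perfect separation in the treatment model; ",
         "review the covariates entering the propensity score", call. = FALSE)
  }
  grad <- drop(crossprod(D, Z - p))
  structure(list(kind = "logistic",
                 coefficients = stats::setNames(fit$coefficients, colnames(D)),
                 scores = as.numeric(p),
                 iterations = fit$iter,
                 gradient_norm = sqrt(sum(grad^2)),
                 degenerate = FALSE),
            class = "propensity_model")
}

#' Fit the generalized propensity score by Cox proportional hazards
#'
#' Partial-likelihood fit (Breslow tie handling) of time to treatment on
#' baseline covariates; untreated subjects enter as censored observations.
#' The generalized propensity score is the linear predictor `D %*% beta` --
#' the baseline hazard is not estimated, so scores are defined only up to an
#' additive constant, which is immaterial because downstream models
#' standardize them.
#'
#' @param D Numeric covariate matrix (no intercept; the partial likelihood
#'   has none).
#' @param time Positive follow-up times (days to treatment, or censoring).
#' @param event 1 if treated at `time`, 0 if censored.
#' @return A `propensity_model` list: `kind = "cox"`, `coefficients`,
#'   `scores` (linear predictor), `iterations`, `gradient_norm`, and a
#'   `degenerate` flag set when no covariate varies.
#' @export
fit_cox_gps <- function(D, time, event) {
  D <- as.matrix(D)
  stopifnot(nrow(D) == length(time), length(time) == length(event),
            all(time > 0), all(event %in% c(0, 1)))
  if (sum(event) < 1) stop("no treatment events; cannot fit the GPS model",
                           call. = FALSE)
  sds <- apply(D, 2, stats::sd)
  if (all(sds == 0)) {
    return(structure(list(kind = "cox",
                          coefficients = stats::setNames(rep(0, ncol(D)),
                                                         colnames(D)),
                          scores = rep(0, nrow(D)),
                          iterations = 0L, gradient_norm = 0,
                          degenerate = TRUE),
                     class = "propensity_model"))
  }
  fit <- survival::coxph(survival::Surv(time, event) ~ D, ties = "breslow")
  beta <- unname(fit$coefficients)
  if (anyNA(beta) || any(!is.finite(beta))) {
    stop("Cox partial likelihood is monotone (non-finite MLE); ",
         "a covariate may perfectly order the treatment times", call. = FALSE)
  }
  grad <- .breslow_gradient(beta, D, time, event)
  structure(list(kind = "cox",
                 coefficients = stats::setNames(beta, colnames(D)),
                 scores = as.numeric(D %*% beta),
                 iterations = fit$iter,
                 gradient_norm = sqrt(sum(grad^2)),
                 degenerate = FALSE),
            class = "propensity_model")
}

#' @export
print.propensity_model <- function(x, ...) {
  cat("Propensity model (", x$kind, ")\n", sep = "")
  print(x$coefficients)
  cat("gradient norm at MLE:", format(x$gradient_norm, digits = 3), "\n")
  invisible(x)
}

# Breslow partial log-likelihood and gradient; ties share the risk set of
# their common event time.
.breslow_loglik <- function(beta, D, time, event) {
  eta <- drop(D %*% beta)
  ord <- order(time)
  eta <- eta[ord]; ev <- event[ord]; tt <- time[ord]
  # risk set of subject i (sorted): subjects with time >= t_i
  ll <- 0
  for (i in which(ev == 1)) {
    risk <- which(tt >= tt[i])
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}

.breslow_gradient <- function(beta, D, time, event) {
  eta <- drop(D %*% beta)
  g <- numeric(ncol(D))
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    w <- exp(eta[risk]); w <- w / sum(w)
    g <- g + D[i, ] - colSums(D[risk, , drop = FALSE] * w)
  }
  g
}

#' Polynomial propensity-score adjustment terms
#'
#' Standardizes the score vector (mean 0, sd 1) and returns the columns
#' `s, s^2, ..., s^order` used as regression adjustments in the outcome and
#' principal-strata models.  Raw powers of the standardized score are used
#' (not orthogonal polynomials); standardization is for numerical stability.
#'
#' @param scores Numeric propensity (or generalized propensity) scores.
#' @param order Polynomial order, 1, 2 or 3.
#' @return Matrix with `order` columns named `ps1`, `ps2`, `ps3`.
#' @export
expand_ps_terms <- function(scores, order = 1L) {
  stopifnot(order %in% 1:3)
  s <- stats::sd(scores)
  if (!is.finite(s) || s == 0) {
    stop("propensity scores are constant; no variation to adjust for",
         call. = FALSE)
  }
  z <- (scores - mean(scores)) / s
  out <- sapply(seq_len(order), function(k) z^k)
  out <- matrix(out, ncol = order)
  colnames(out) <- paste0("ps", seq_len(order))
  out
}

#' Covariate balance before and after propensity adjustment
#'
#' For each covariate, regresses the covariate on the treatment indicator
#' marginally, then with standard-propensity-score terms, then with
#' generalized-propensity-score terms, and reports the p-value of the
#' treatment coefficient in each fit.  Linear regression for continuous
#' covariates, logistic for binary ones.  Treatment-coefficient p-values
#' near or above conventional levels after adjustment indicate balance.
#'
#' @param rows Analysis data frame with a `Z` column.
#' @param covariates Character vector of continuous covariate columns.
#' @param binary Character vector of binary covariate columns.
#' @param ps_model Fitted `propensity_model` of kind `"logistic"`.
#' @param gps_model Fitted `propensity_model` of kind `"cox"`.
#' @param ps_order Polynomial order of the adjustment terms.
#' @return Data frame with columns `covariate`, `type`, `p_marginal`,
#'   `p_standard_ps`, `p_generalized_ps`.
#' @export
balance_table <- function(rows, covariates, binary = character(0),
                          ps_model, gps_model, ps_order = 1L) {
  ps_terms <- expand_ps_terms(ps_model$scores, ps_order)
  gps_terms <- expand_ps_terms(gps_model$scores, ps_order)
  z <- rows$Z
  pval <- function(x, type, adjust = NULL) {
    df <- data.frame(x = x, Z = z)
    if (!is.null(adjust)) df <- cbind(df, as.data.frame(adjust))
    fml <- stats::as.formula(paste("x ~", paste(setdiff(names(df), "x"),
                                                collapse = " + ")))
    fit <- tryCatch({
      if (type == "binary") stats::glm(fml, data = df, family = stats::binomial())
      else stats::lm(fml, data = df)
    }, error = function(e) NULL, warning = function(w) {
      suppressWarnings(
        if (type == "binary") stats::glm(fml, data = df,
                                         family = stats::binomial())
        else stats::lm(fml, data = df))
    })
    if (is.null(fit)) return(NA_real_)
    cf <- stats::coef(summary(fit))
    if (!"Z" %in% rownames(cf)) return(NA_real_)
    cf["Z", 4]
  }
  one <- function(nm, type) {
    x <- rows[[nm]]
    data.frame(covariate = nm, type = type,
               p_marginal = pval(x, type),
               p_standard_ps = pval(x, type, ps_terms),
               p_generalized_ps = pval(x, type, gps_terms),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(lapply(covariates, one, type = "continuous"),
                          lapply(binary, one, type = "binary")))
  rownames(out) <- NULL
  out
}
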