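# Per-stratum normal outcome regressions with conjugate priors.  Outcomes
# are observed only for survivors, so models exist for LL, LD and DL; the
# DD stratum never contributes outcome data.  The LL design carries the
# treatment term(s) -- both arms are observed there -- while LD members with
# outcomes are all treated and DL members all untreated, so those designs
# hold intercept and propensity terms only.

#' Outcome-model design vector for a stratum
#'
#' LL, binary treatment model: `[1, Z, PS terms]`.  LL, time-of-treatment
#' model: `[1, Z, Z * months from treatment to horizon, GPS terms]`, so the
#' SACE at a lag of `delta` months is `eta_Z + eta_T * delta`.  LD and DL:
#' `[1, PS terms]`.  DD has no outcome model.
#'
#' @param Z Treatment indicator.
#' @param time_months Months from treatment to the outcome horizon (0 for
#'   untreated subjects).
#' @param ps_terms Numeric vector of propensity adjustment terms for this
#'   subject (standard PS terms under the binary model, GPS terms under the
#'   time model); may be length 0.
#' @param stratum One of `"LL"`, `"LD"`, `"DL"`.
#' @param model_type `"binary"` or `"time"`.
#' @return Named numeric design vector.
#' @export
stratum_design <- function(Z, time_months, ps_terms, stratum,
                           model_type = c("binary", "time")) {
  model_type <- match.arg(model_type)
  if (stratum == "DD") {
    stop("the DD stratum has no outcome model (no observable outcomes)",
         call. = FALSE)
  }
  stopifnot(stratum %in% c("LL", "LD", "DL"))
  ps <- as.numeric(ps_terms)
  nm_ps <- if (length(ps)) paste0("ps", seq_along(ps)) else character(0)
  if (stratum == "LL") {
    if (model_type == "binary") {
      stats::setNames(c(1, Z, ps), c("intercept", "Z", nm_ps))
    } else {
      stats::setNames(c(1, Z, Z * time_months, ps),
                      c("intercept", "Z", "time", nm_ps))
    }
  } else {
    stats::setNames(c(1, ps), c("intercept", nm_ps))
  }
}

#' Normal outcome log-density
#'
#' `log N(y | design' eta, sigma2)`, the per-stratum outcome density entering
#' the observed-data mixture likelihood.
#'
#' @param y Observed outcome.
#' @param design Design vector (or matrix, one row per subject).
#' @param eta Coefficient vector.
#' @param sigma2 Positive residual variance.
#' @return Log density (vector if `design` is a matrix).
#' @export
normal_logdensity <- function(y, design, eta, sigma2) {
  stopifnot(sigma2 > 0)
  mu <- if (is.matrix(design)) drop(design %*% eta) else sum(design * eta)
  stats::dnorm(y, mean = mu, sd = sqrt(sigma2), log = TRUE)
}

#' Conjugate prior for one stratum's outcome regression
#'
#' Multivariate-normal prior on the coefficients and inverse-gamma prior on
#' the residual variance.  Defaults are weakly informative on standardized
#' covariates: `mu0 = 0`, `Sigma0 = 100 I`, and `a0 = 2`, `b0 = 4` (prior
#' mean residual variance 4, infinite prior variance).  The variance prior
#' is deliberately proper and on the outcome scale: strata can hold no
#' survivors for many iterations, and an arbitrarily diffuse
#' inverse-gamma (e.g. shape 0.01) then produces astronomical
#' prior draws whose near-zero outcome densities lock the imputation out
#' of the stratum permanently.
#'
#' @param p Number of design columns.
#' @param mu0 Prior mean vector (recycled scalar allowed).
#' @param v0 Prior variance of each coefficient (`Sigma0 = v0 * I`), or a
#'   full positive-definite matrix via `Sigma0`.
#' @param a0,b0 Inverse-gamma shape and scale for the residual variance.
#' @param Sigma0 Optional full prior covariance matrix, overrides `v0`.
#' @return A `prior_spec` list with `mu0`, `Sigma0`, `Sigma0_inv`, `a0`, `b0`.
#' @export
prior_spec <- function(p, mu0 = 0, v0 = 100, a0 = 2, b0 = 4,
                       Sigma0 = NULL) {
  stopifnot(a0 > 0, b0 > 0)
  if (is.null(Sigma0)) Sigma0 <- diag(v0, p)
  mu0 <- rep_len(mu0, p)
  structure(list(mu0 = mu0, Sigma0 = Sigma0,
                 Sigma0_inv = solve(Sigma0), a0 = a0, b0 = b0),
            class = "prior_spec")
}

#' Gibbs draw of outcome regression coefficients
#'
#' Full conditional of `eta` given the stratum's surviving members, their
#' designs, the current residual variance and the MVN prior:
#' `eta | . ~ MVN(V m, V)` with `V = (X'X / sigma2 + Sigma0^-1)^-1` and
#' `m = X'y / sigma2 + Sigma0^-1 mu0`.  With no members the draw is from
#' the prior.
#'
#' @param X Design matrix of the stratum's members with observed outcomes
#'   (may have zero rows).
#' @param y Their outcomes.
#' @param sigma2 Current residual variance.
#' @param prior A `prior_spec`.
#' @return Coefficient draw (numeric vector).
#' @export
gibbs_update_eta <- function(X, y, sigma2, prior) {
  p <- length(prior$mu0)
  if (is.null(dim(X))) X <- matrix(X, ncol = p)
  prec <- prior$Sigma0_inv
  m <- drop(prec %*% prior$mu0)
  if (nrow(X) > 0) {
    prec <- prec + crossprod(X) / sigma2
    m <- m + drop(crossprod(X, y)) / sigma2
  }
  R <- chol(prec)                       # prec = R'R
  mean_ <- backsolve(R, backsolve(R, m, transpose = TRUE))
  mean_ + backsolve(R, stats::rnorm(p))
}

#' Gibbs draw of the outcome residual variance
#'
#' Full conditional `sigma2 | . ~ InvGamma(a0 + n/2, b0 + RSS/2)` for the
#' residuals of the stratum's surviving members at the current coefficients.
#'
#' @param residuals Residual vector (may be length 0: prior draw).
#' @param prior A `prior_spec`.
#' @return Positive variance draw.
#' @export
gibbs_update_sigma2 <- function(residuals, prior) {
  n <- length(residuals)
  shape <- prior$a0 + n / 2
  rate <- prior$b0 + sum(residuals^2) / 2
  draw <- 1 / stats::rgamma(1, shape = shape, rate = rate)
  # guard against gamma underflow at small shapes
  min(max(draw, 1e-12), 1e12)
}
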