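# Principal-stratum machinery.  Strata are defined by the pair of potential
# survival statuses (S(1), S(0)) at the outcome horizon:
#   LL alive under both, LD alive only if treated, DL alive only if
#   untreated, DD dead under both.
# The SACE is the treated-vs-untreated outcome contrast within LL, the only
# stratum whose members survive (and hence have a defined outcome) under
# either treatment.

STRATA_ALL <- c("LL", "LD", "DL", "DD")

#' Active stratum labels
#'
#' @param monotonicity If `TRUE`, treatment is assumed never to cause a death
#'   that would not otherwise occur, so the DL stratum is removed.
#' @return Character vector of stratum labels, reference stratum (DD) last.
#' @export
active_strata <- function(monotonicity = FALSE) {
  if (monotonicity) c("LL", "LD", "DD") else STRATA_ALL
}

#' Construct multinomial-logit stratum parameters
#'
#' The stratum-membership model is a multinomial logit on the design row
#' `x2` (intercept + propensity terms, optionally baseline covariates):
#' `P(G = g | x2) = exp(x2' alpha_g) / sum_h exp(x2' alpha_h)` with the
#' reference stratum DD fixed at `alpha_DD = 0`.
#'
#' @param alpha Numeric matrix, one column per non-reference active stratum
#'   (in [active_strata()] order, DD omitted), one row per design column.
#' @param monotonicity Logical; see [active_strata()].
#' @return A `strata_parameters` object.
#' @export
new_strata_parameters <- function(alpha, monotonicity = FALSE) {
  alpha <- as.matrix(alpha)
  non_ref <- setdiff(active_strata(monotonicity), "DD")
  if (ncol(alpha) != length(non_ref)) {
    stop("alpha must have one column per non-reference stratum (",
         paste(non_ref, collapse = ", "), ")", call. = FALSE)
  }
  colnames(alpha) <- non_ref
  structure(list(alpha = alpha, reference = "DD",
                 monotonicity = monotonicity),
            class = "strata_parameters")
}

#' Stratum membership probabilities
#'
#' Softmax over the multinomial-logit linear predictors, reference stratum
#' DD fixed at zero.  Computed with max-subtraction so large predictors do
#' not overflow.
#'
#' @param params A `strata_parameters` object (or bare matrix as accepted by
#'   [new_strata_parameters()]).
#' @param x2 Design row (numeric vector) or matrix with one row per subject;
#'   must include the intercept column.
#' @param monotonicity Used only when `params` is a bare matrix.
#' @return Probability vector over the active strata (or a matrix, one row
#'   per subject); rows sum to one.
#' @export
strata_probs <- function(params, x2, monotonicity = FALSE) {
  if (!inherits(params, "strata_parameters")) {
    params <- new_strata_parameters(params, monotonicity)
  }
  lp <- .strata_logprobs(params, x2)
  out <- exp(lp)
  if (is.matrix(out)) out / rowSums(out) else out / sum(out)
}

# log softmax numerators (max-subtracted), columns = active strata
.strata_logprobs <- function(params, x2) {
  single <- !is.matrix(x2)
  X <- if (single) matrix(x2, nrow = 1) else as.matrix(x2)
  if (ncol(X) != nrow(params$alpha)) {
    stop("design width ", ncol(X), " does not match alpha (",
         nrow(params$alpha), " rows)", call. = FALSE)
  }
  eta <- cbind(X %*% params$alpha, 0)
  colnames(eta) <- c(colnames(params$alpha), params$reference)
  if (any(!is.finite(eta))) stop("non-finite stratum linear predictor",
                                 call. = FALSE)
  eta <- eta[, active_strata(params$monotonicity), drop = FALSE]
  m <- eta[, 1]
  for (j in seq_len(ncol(eta))[-1]) m <- pmax(m, eta[, j])
  lp <- eta - m
  if (single) lp[1, ] else lp
}

#' Classify a subject by observed treatment and survival
#'
#' Each observed group O(Z, S) is a known mixture of exactly two principal
#' strata (one, under monotonicity, for the O(1,0) and O(0,1) groups):
#' O(1,1) = LL or LD; O(1,0) = DL or DD; O(0,1) = LL or DL;
#' O(0,0) = LD or DD.
#'
#' @param Z,S Observed treatment and survival indicators (0/1).
#' @param monotonicity Logical; removes DL from the compatible sets.
#' @return List with `label` (e.g. `"O(1,1)"`) and `compatible`, the
#'   character vector of compatible strata.
#' @export
observed_group <- function(Z, S, monotonicity = FALSE) {
  stopifnot(Z %in% c(0, 1), S %in% c(0, 1))
  compatible <- if (Z == 1 && S == 1) c("LL", "LD")
  else if (Z == 1 && S == 0) c("DL", "DD")
  else if (Z == 0 && S == 1) c("LL", "DL")
  else c("LD", "DD")
  if (monotonicity) compatible <- setdiff(compatible, "DL")
  list(label = sprintf("O(%d,%d)", Z, S), compatible = compatible)
}

#' Conditional stratum-membership probabilities
#'
#' The probability that a subject belongs to each principal stratum given
#' the observed data and current parameter values: within the compatible
#' set, survivors weight the stratum prior probability by the stratum's
#' outcome density at the observed Y, while non-survivors (whose outcome is
#' censored by death) contribute through the stratum probabilities alone.
#' These are the imputation probabilities of the data-augmentation I-step.
#'
#' @param Z,S Observed treatment and survival indicators.
#' @param pi Named probability vector over the active strata.
#' @param log_dens Named vector of log outcome densities `log f_g(Y)` for
#'   the strata with observable outcomes; required when `S = 1`.
#' @param monotonicity Logical.
#' @return Named probability vector over the active strata; exactly zero on
#'   incompatible strata, sums to one.
#' @export
membership_probs <- function(Z, S, pi, log_dens = NULL,
                             monotonicity = FALSE) {
  acts <- active_strata(monotonicity)
  stopifnot(setequal(names(pi), acts))
  comp <- observed_group(Z, S, monotonicity)$compatible
  logw <- stats::setNames(rep(-Inf, length(acts)), acts)
  for (g in comp) {
    lw <- log(pi[[g]])
    if (S == 1) {
      if (is.null(log_dens) || is.null(log_dens[[g]]) || is.na(log_dens[[g]])) {
        stop("log outcome density for stratum ", g,
             " required for a survivor", call. = FALSE)
      }
      lw <- lw + log_dens[[g]]
    }
    logw[g] <- lw
  }
  m <- max(logw)
  if (!is.finite(m)) {
    stop("all compatible strata have zero posterior mass", call. = FALSE)
  }
  w <- exp(logw - m)
  w / sum(w)
}

#' Multinomial-logit log-likelihood of imputed strata
#'
#' `sum_i log P(G_i | x2_i; alpha)` for the current imputed stratum labels;
#' with the flat prior on `alpha` this is the Metropolis-Hastings target of
#' the P-step.
#'
#' @param params A `strata_parameters` object.
#' @param x2 Design matrix, one row per subject.
#' @param labels Character vector of imputed stratum labels.
#' @return Scalar log-likelihood.
#' @export
loglik_alpha <- function(params, x2, labels) {
  lp <- .strata_logprobs(params, as.matrix(x2))
  if (!is.matrix(lp)) lp <- matrix(lp, nrow = 1,
                                   dimnames = list(NULL, names(lp)))
  lse <- log(rowSums(exp(lp)))
  idx <- match(labels, colnames(lp))
  if (anyNA(idx)) stop("label outside the active stratum set", call. = FALSE)
  sum(lp[cbind(seq_along(idx), idx)] - lse)
}
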