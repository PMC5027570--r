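# Data-augmentation MCMC.  Alternates an I-step that imputes each subject's
# principal stratum from its conditional membership probabilities with a
# P-step that updates the outcome regressions by conjugate Gibbs draws and
# the multinomial-logit stratum coefficients by random-walk
# Metropolis-Hastings (flat prior).

#' Sampler configuration
#'
#' @param n_iter Total MCMC iterations (default 10000).
#' @param burn_in Discarded initial iterations (default 5000).
#' @param seed RNG seed; every random element of the run derives from it.
#' @param model_type `"binary"` (treatment indicator only, standard PS) or
#'   `"time"` (indicator + months from treatment to horizon, GPS).
#' @param monotonicity Assume the DL stratum empty.
#' @param ps_order Propensity polynomial order, 0 (no adjustment) to 3.
#' @param mh_step Initial random-walk proposal SD per alpha block.
#' @param alpha_prior_sd Prior SD of each stratum-model coefficient
#'   (independent normals centred at zero).  The default 5 is diffuse on
#'   the multinomial-logit scale while keeping the posterior proper: under
#'   a flat prior the posterior is improper, because the observed-data
#'   likelihood tends to a positive constant as any stratum's
#'   coefficients head to minus infinity (the stratum empties and the
#'   remaining mixture is unaffected).  `Inf` gives the flat target.
#' @param adapt_during_burnin Adapt proposal SDs toward 30% acceptance
#'   during burn-in (Robbins-Monro), frozen afterwards so the post-burn-in
#'   chain is Markov.
#' @param clamp_labels Optional character vector of stratum labels, one per
#'   subject; when supplied the I-step is clamped to these labels (used for
#'   oracle checks with known strata).
#' @return A `sampler_config` list.
#' @export
sampler_config <- function(n_iter = 10000L, burn_in = 5000L, seed = 1L,
                           model_type = c("binary", "time"),
                           monotonicity = FALSE, ps_order = 1L,
                           mh_step = 0.25, adapt_during_burnin = TRUE,
                           alpha_prior_sd = 5, clamp_labels = NULL) {
  model_type <- match.arg(model_type)
  stopifnot(burn_in < n_iter, mh_step > 0, ps_order %in% 0:3,
            alpha_prior_sd > 0)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 seed = as.integer(seed), model_type = model_type,
                 monotonicity = monotonicity, ps_order = as.integer(ps_order),
                 mh_step = mh_step, adapt_during_burnin = adapt_during_burnin,
                 alpha_prior_sd = alpha_prior_sd, clamp_labels = clamp_labels),
            class = "sampler_config")
}

# Precompute everything the iteration loop needs: designs, group indices.
.sampler_data <- function(rows, config) {
  n <- nrow(rows)
  stopifnot(all(rows$Z %in% c(0, 1)), all(rows$S %in% c(0, 1)))
  if (config$ps_order >= 1L) {
    score_col <- if (config$model_type == "binary") "ps" else "gps"
    if (is.null(rows[[score_col]])) {
      stop("rows lack the '", score_col, "' score column required for ",
           config$model_type, " model with ps_order >= 1", call. = FALSE)
    }
    ps_terms <- expand_ps_terms(rows[[score_col]], config$ps_order)
  } else {
    ps_terms <- matrix(numeric(0), nrow = n, ncol = 0)
  }
  tmonths <- rows$time_from_treatment_months
  if (is.null(tmonths)) tmonths <- rep(0, n)
  X_LL <- if (config$model_type == "binary") {
    cbind(intercept = 1, Z = rows$Z, ps_terms)
  } else {
    cbind(intercept = 1, Z = rows$Z, time = rows$Z * tmonths, ps_terms)
  }
  X_LDDL <- cbind(intercept = 1, ps_terms)
  X2 <- cbind(intercept = 1, ps_terms)
  acts <- active_strata(config$monotonicity)
  list(n = n, Z = rows$Z, S = rows$S, Y = rows$Y,
       X_LL = X_LL, X_LDDL = X_LDDL, X2 = X2, acts = acts,
       non_ref = setdiff(acts, "DD"),
       out_strata = intersect(c("LL", "LD", "DL"), acts),
       g11 = which(rows$Z == 1 & rows$S == 1),
       g10 = which(rows$Z == 1 & rows$S == 0),
       g01 = which(rows$Z == 0 & rows$S == 1),
       g00 = which(rows$Z == 0 & rows$S == 0))
}

.design_for <- function(dat, g) if (g == "LL") dat$X_LL else dat$X_LDDL

#' Initialize the sampler state
#'
#' Non-survivors are drawn uniformly over their compatible strata.
#' Survivor groups, when large enough, are split by outcome instead: the
#' lowest-outcome fifth of each arm's survivors starts in the arm's
#' frailer compatible stratum (LD for treated, DL for untreated) and the
#' rest in LL, so the stratum regressions start separated -- a uniform
#' split initializes every component at the common mixture mean, from
#' which the imputation step essentially never discovers a minority
#' stratum (the standard informed-initialization argument for mixture
#' fitting).  Small survivor groups (fewer than 10) fall back to the
#' uniform draw.  The stratum-model coefficients start at zero, and the
#' outcome coefficients and variances start at per-stratum OLS values on
#' the initial assignment (falling back to zeros / unit variance for
#' empty or rank-deficient strata).
#'
#' @param rows Analysis data frame (with score columns as required).
#' @param config A `sampler_config`.  The RNG state is taken as-is; callers
#'   wanting reproducibility should `set.seed()` first (as [run_da_mcmc()]
#'   does).
#' @return List with elements `G`, `alpha`, `eta`, `sigma2`.
#' @export
initialize_state <- function(rows, config) {
  dat <- .sampler_data(rows, config)
  G <- character(dat$n)
  for (i in seq_len(dat$n)) {
    comp <- observed_group(dat$Z[i], dat$S[i], config$monotonicity)$compatible
    G[i] <- if (length(comp) == 1L) comp else sample(comp, 1L)
  }
  # outcome-informed split of the survivor mixtures (see above)
  split_low <- function(idx, low_stratum) {
    if (length(idx) < 10L) return()
    cut <- stats::quantile(dat$Y[idx], 0.2, names = FALSE)
    G[idx] <<- ifelse(dat$Y[idx] <= cut, low_stratum, "LL")
  }
  split_low(dat$g11, "LD")
  if (!config$monotonicity) split_low(dat$g01, "DL")
  eta <- list(); sigma2 <- list()
  for (g in dat$out_strata) {
    X <- .design_for(dat, g)
    idx <- which(G == g & dat$S == 1)
    p <- ncol(X)
    eta[[g]] <- rep(0, p); sigma2[[g]] <- 1
    if (length(idx) > p) {
      fit <- stats::lm.fit(X[idx, , drop = FALSE], dat$Y[idx])
      if (!anyNA(fit$coefficients)) {
        eta[[g]] <- unname(fit$coefficients)
        rv <- sum(fit$residuals^2) / max(1, length(idx) - p)
        if (is.finite(rv) && rv > 0) sigma2[[g]] <- rv
      }
    }
    names(eta[[g]]) <- colnames(X)
  }
  alpha <- matrix(0, nrow = ncol(dat$X2), ncol = length(dat$non_ref),
                  dimnames = list(colnames(dat$X2), dat$non_ref))
  list(G = G, alpha = alpha, eta = eta, sigma2 = sigma2)
}

# Vectorized I-step: one categorical draw per subject over its compatible
# strata.  Every observed group has at most two compatible strata, so each
# draw is a Bernoulli on the log-weight difference.
.i_step_impl <- function(dat, state, config, log_pi) {
  G <- character(dat$n)
  pick2 <- function(idx, ga, gb, lwa, lwb) {
    if (!length(idx)) return()
    d <- lwb - lwa
    p_b <- 1 / (1 + exp(-d))            # P(choose gb)
    p_b[d == -Inf] <- 0; p_b[d == Inf] <- 1
    if (anyNA(p_b)) stop("non-finite membership weights", call. = FALSE)
    g <- rep(ga, length(idx))
    g[stats::runif(length(idx)) < p_b] <- gb
    G[idx] <<- g
  }
  ld <- function(g, idx) {
    X <- .design_for(dat, g)
    normal_logdensity(dat$Y[idx], X[idx, , drop = FALSE],
                      state$eta[[g]], state$sigma2[[g]])
  }
  # O(1,1): LL vs LD (outcome observed)
  i <- dat$g11
  pick2(i, "LL", "LD",
        log_pi[i, "LL"] + ld("LL", i),
        log_pi[i, "LD"] + ld("LD", i))
  # O(0,1): LL vs DL (LL only under monotonicity)
  i <- dat$g01
  if (config$monotonicity) G[i] <- "LL"
  else pick2(i, "LL", "DL",
             log_pi[i, "LL"] + ld("LL", i),
             log_pi[i, "DL"] + ld("DL", i))
  # O(1,0): DL vs DD (DD only under monotonicity); no outcome
  i <- dat$g10
  if (config$monotonicity) G[i] <- "DD"
  else pick2(i, "DL", "DD", log_pi[i, "DL"], log_pi[i, "DD"])
  # O(0,0): LD vs DD; no outcome
  i <- dat$g00
  pick2(i, "LD", "DD", log_pi[i, "LD"], log_pi[i, "DD"])
  G
}

#' One imputation step
#'
#' Draws every subject's principal stratum from its conditional membership
#' probabilities at the current parameter values.
#'
#' @param rows Analysis data frame.
#' @param state Sampler state (`G`, `alpha`, `eta`, `sigma2`).
#' @param config A `sampler_config`.
#' @return Character vector of imputed stratum labels.
#' @export
i_step <- function(rows, state, config) {
  dat <- .sampler_data(rows, config)
  params <- new_strata_parameters(state$alpha, config$monotonicity)
  log_pi <- .log_pi_matrix(params, dat$X2)
  .i_step_impl(dat, state, config, log_pi)
}

# normalized log stratum probabilities, n x K; columns follow the active
# stratum order (non-reference strata then DD)
.log_pi_matrix <- function(params, X2) {
  .fast_log_pi(params$alpha, X2,
               c(colnames(params$alpha), params$reference))
}

.fast_log_pi <- function(alpha_mat, X2, acts) {
  eta <- X2 %*% alpha_mat              # n x (K-1); reference predictor is 0
  m <- pmax(eta[, 1], 0)
  for (j in seq_len(ncol(eta))[-1]) m <- pmax(m, eta[, j])
  if (any(!is.finite(eta))) stop("non-finite stratum linear predictor",
                                 call. = FALSE)
  ez <- exp(eta - m)
  lp <- cbind(eta - m, -m) - log(exp(-m) + rowSums(ez))
  colnames(lp) <- acts
  lp
}

# loglik of labels given alpha (matrix form), shared by MH
.loglik_alpha_idx <- function(alpha_mat, X2, lab_idx, acts) {
  lp <- .fast_log_pi(alpha_mat, X2, acts)
  sum(lp[cbind(seq_along(lab_idx), lab_idx)])
}

#' One posterior step
#'
#' Conjugate Gibbs draws of each stratum's outcome coefficients and residual
#' variance given the imputed membership, followed by one random-walk
#' Metropolis-Hastings update per non-reference alpha block.
#'
#' @param rows Analysis data frame.
#' @param G Imputed stratum labels.
#' @param state Current sampler state.
#' @param priors Named list of `prior_spec` objects (one per outcome
#'   stratum) as built by [run_da_mcmc()].
#' @param config A `sampler_config`.
#' @return Updated state list (with `G = G` and MH `accepted` flags).
#' @export
p_step <- function(rows, G, state, priors, config) {
  dat <- .sampler_data(rows, config)
  steps <- rep(config$mh_step, length(dat$non_ref))
  names(steps) <- dat$non_ref
  .p_step_impl(dat, G, state, priors, config, steps)
}

.p_step_impl <- function(dat, G, state, priors, config, steps) {
  # Gibbs: outcome parameters per stratum with observable outcomes
  for (g in dat$out_strata) {
    X <- .design_for(dat, g)
    idx <- which(G == g & dat$S == 1)
    Xg <- X[idx, , drop = FALSE]
    yg <- dat$Y[idx]
    eta_new <- gibbs_update_eta(Xg, yg, state$sigma2[[g]], priors[[g]])
    names(eta_new) <- colnames(X)
    res <- if (length(idx)) yg - drop(Xg %*% eta_new) else numeric(0)
    state$eta[[g]] <- eta_new
    state$sigma2[[g]] <- gibbs_update_sigma2(res, priors[[g]])
  }
  # MH: one Gaussian random-walk update per alpha block; diffuse normal
  # prior on the coefficients (see sampler_config)
  sd0 <- config$alpha_prior_sd
  if (is.null(sd0)) sd0 <- 5
  logprior <- function(a) if (is.finite(sd0)) -sum(a^2) / (2 * sd0^2) else 0
  lab_idx <- match(G, dat$acts)
  cur_ll <- .loglik_alpha_idx(state$alpha, dat$X2, lab_idx, dat$acts) +
    logprior(state$alpha)
  accepted <- stats::setNames(logical(length(dat$non_ref)), dat$non_ref)
  for (g in dat$non_ref) {
    prop <- state$alpha
    prop[, g] <- prop[, g] + stats::rnorm(nrow(prop), 0, steps[[g]])
    prop_ll <- .loglik_alpha_idx(prop, dat$X2, lab_idx, dat$acts) +
      logprior(prop)
    if (is.finite(prop_ll) &&
        log(stats::runif(1)) < (prop_ll - cur_ll)) {
      state$alpha <- prop
      cur_ll <- prop_ll
      accepted[[g]] <- TRUE
    }
  }
  state$G <- G
  state$accepted <- accepted
  state
}

#' Run the data-augmentation MCMC
#'
#' Alternates the I-step and P-step for `config$n_iter` iterations,
#' discarding `config$burn_in`, and records the post-burn-in chains of all
#' parameters together with per-iteration imputed strata counts and MH
#' acceptance rates.  Fully reproducible from `config$seed`.
#'
#' @param rows Analysis data frame with columns `Z`, `S`, `Y`,
#'   `time_from_treatment_months`, and `ps`/`gps` score columns as required
#'   by the model type and `ps_order`.
#' @param config A `sampler_config`.
#' @param priors Optional named list of `prior_spec` objects for strata
#'   `LL`, `LD`, `DL`; defaults to [prior_spec()] defaults of matching
#'   dimension.
#' @return A `sace_draws` object: `chain` (matrix, one row per retained
#'   iteration, named columns `eta_<g>.<term>`, `sigma2_<g>`,
#'   `alpha_<g>.<term>`), `strata_counts`, `acceptance`, `mh_steps`,
#'   `config`.
#' @export
run_da_mcmc <- function(rows, config = sampler_config(), priors = NULL) {
  set.seed(config$seed)
  dat <- .sampler_data(rows, config)
  state <- initialize_state(rows, config)
  if (is.null(priors)) {
    # centre the intercept prior at the observed survivor mean outcome:
    # an emptied stratum then keeps appreciable density near the data and
    # can be repopulated by later imputation steps, instead of being
    # locked out by prior draws centred at zero on the outcome scale
    ybar <- mean(dat$Y[dat$S == 1], na.rm = TRUE)
    priors <- lapply(stats::setNames(dat$out_strata, dat$out_strata),
                     function(g) {
      p <- ncol(.design_for(dat, g))
      prior_spec(p, mu0 = c(ybar, rep(0, p - 1)))
    })
  }
  clamp <- config$clamp_labels
  if (!is.null(clamp)) {
    stopifnot(length(clamp) == dat$n, all(clamp %in% dat$acts))
  }
  steps <- rep(config$mh_step, length(dat$non_ref))
  names(steps) <- dat$non_ref
  acc_total <- stats::setNames(numeric(length(dat$non_ref)), dat$non_ref)

  keep <- config$n_iter - config$burn_in
  par_names <- c(
    unlist(lapply(dat$out_strata, function(g)
      paste0("eta_", g, ".", colnames(.design_for(dat, g))))),
    paste0("sigma2_", dat$out_strata),
    unlist(lapply(dat$non_ref, function(g)
      paste0("alpha_", g, ".", colnames(dat$X2)))))
  chain <- matrix(NA_real_, nrow = keep, ncol = length(par_names),
                  dimnames = list(NULL, par_names))
  counts <- matrix(0L, nrow = keep, ncol = length(dat$acts),
                   dimnames = list(NULL, dat$acts))

  for (it in seq_len(config$n_iter)) {
    params <- new_strata_parameters(state$alpha, config$monotonicity)
    log_pi <- .log_pi_matrix(params, dat$X2)
    G <- if (is.null(clamp)) .i_step_impl(dat, state, config, log_pi) else clamp
    state <- .p_step_impl(dat, G, state, priors, config, steps)
    in_burnin <- it <= config$burn_in
    if (in_burnin && config$adapt_during_burnin) {
      # Robbins-Monro drift of the log step toward 30% acceptance,
      # clamped: a nearly flat block target (e.g. a stratum with few
      # members) accepts at any scale and would otherwise drive the
      # step without bound
      gain <- 1 / it^0.6
      steps <- steps * exp(gain * (as.numeric(state$accepted) - 0.3))
      steps <- pmin(pmax(steps, 1e-3), 5)
    }
    if (!in_burnin) {
      acc_total <- acc_total + as.numeric(state$accepted)
      k <- it - config$burn_in
      vals <- c(
        unlist(state$eta[dat$out_strata], use.names = FALSE),
        unlist(state$sigma2[dat$out_strata], use.names = FALSE),
        as.numeric(state$alpha))
      chain[k, ] <- vals
      counts[k, ] <- tabulate(match(G, dat$acts), nbins = length(dat$acts))
    }
  }
  acceptance <- acc_total / keep
  if (any(acceptance < 0.05 | acceptance > 0.8)) {
    warning("MH acceptance rate outside [0.05, 0.8] for block(s): ",
            paste(names(acceptance)[acceptance < 0.05 | acceptance > 0.8],
                  collapse = ", "))
  }
  structure(list(chain = chain, strata_counts = counts,
                 acceptance = acceptance, mh_steps = steps,
                 out_strata = dat$out_strata, non_ref = dat$non_ref,
                 config = config),
            class = "sace_draws")
}

#' @export
print.sace_draws <- function(x, ...) {
  cat("DA-MCMC draws:", nrow(x$chain), "retained iterations (",
      x$config$model_type, "model, ps_order", x$config$ps_order,
      if (x$config$monotonicity) ", monotonicity" else "", ")\n")
  cat("MH acceptance:",
      paste(names(x$acceptance), format(x$acceptance, digits = 2),
            collapse = ", "), "\n")
  invisible(x)
}

#' Chain diagnostics
#'
#' Effective sample size per parameter (spectral estimate at frequency
#' zero), split-chain potential scale reduction, and the recorded MH
#' acceptance rates.
#'
#' @param draws A `sace_draws` object.
#' @return Data frame with columns `parameter`, `mean`, `sd`, `ess`,
#'   `split_rhat`, `degenerate`; acceptance rates are attached as the
#'   `"acceptance"` attribute.
#' @export
mcmc_diagnostics <- function(draws) {
  ch <- draws$chain
  stopifnot(nrow(ch) > 0)
  out <- do.call(rbind, lapply(colnames(ch), function(nm) {
    x <- ch[, nm]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      return(data.frame(parameter = nm, mean = mean(x), sd = s,
                        ess = NA_real_, split_rhat = NA_real_,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    }
    data.frame(parameter = nm, mean = mean(x), sd = s,
               ess = .ess(x), split_rhat = .split_rhat(x),
               degenerate = FALSE, stringsAsFactors = FALSE)
  }))
  if (any(out$degenerate)) {
    warning("degenerate (constant) chain for: ",
            paste(out$parameter[out$degenerate], collapse = ", "))
  }
  attr(out, "acceptance") <- draws$acceptance
  out
}

# ESS via AR-model spectral density at frequency zero
.ess <- function(x) {
  n <- length(x)
  fit <- tryCatch(stats::ar(x, aic = TRUE, order.max = min(50, n %/% 4)),
                  error = function(e) NULL)
  if (is.null(fit)) return(n)
  s0 <- fit$var.pred / (1 - sum(fit$ar))^2
  max(1, min(n, n * stats::var(x) / s0))
}

.split_rhat <- function(x) {
  n <- length(x) %/% 2
  halves <- list(x[seq_len(n)], x[(length(x) - n + 1):length(x)])
  m <- vapply(halves, mean, numeric(1))
  v <- vapply(halves, stats::var, numeric(1))
  W <- mean(v)
  B <- n * stats::var(m)
  sqrt(((n - 1) / n * W + B / n) / W)
}
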