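test_that("sampler defaults follow the standard run length", {
  cfg <- sampler_config()
  expect_equal(cfg$n_iter, 10000L)
  expect_equal(cfg$burn_in, 5000L)
  expect_error(sampler_config(n_iter = 100, burn_in = 100))
})

test_that("initialization respects compatibility and is seed-deterministic", {
  rows <- toy_rows(50)
  cfg <- sampler_config(n_iter = 10, burn_in = 2, monotonicity = TRUE)
  set.seed(1); s1 <- initialize_state(rows, cfg)
  set.seed(1); s2 <- initialize_state(rows, cfg)
  expect_identical(s1, s2)

  # monotonicity pins untreated survivors to LL, treated deaths to DD
  expect_true(all(s1$G[rows$Z == 0 & rows$S == 1] == "LL"))
  expect_true(all(s1$G[rows$Z == 1 & rows$S == 0] == "DD"))

  # four-strata init splits treated survivors evenly between LL and LD
  cfg4 <- sampler_config(n_iter = 10, burn_in = 2, ps_order = 0)
  one <- rows[rep(which(rows$Z == 1 & rows$S == 1)[1], 1), ]
  set.seed(2)
  inits <- replicate(4000, initialize_state(one, cfg4)$G)
  expect_equal(mean(inits == "LL"), 0.5, tolerance = 0.03)
})

test_that("imputation draws stay in the compatible set and match their probabilities", {
  rows <- toy_rows(12, seed = 5)
  cfg <- sampler_config(n_iter = 10, burn_in = 2, model_type = "binary")
  set.seed(3)
  state <- initialize_state(rows, cfg)
  set.seed(4)
  freq <- matrix(0, nrow(rows), 4, dimnames = list(NULL, STRATA_ALL))
  reps <- 4000
  for (k in seq_len(reps)) {
    G <- i_step(rows, state, cfg)
    for (i in seq_len(nrow(rows))) {
      comp <- observed_group(rows$Z[i], rows$S[i])$compatible
      expect_true(G[i] %in% comp)
    }
    freq[cbind(seq_len(nrow(rows)), match(G, STRATA_ALL))] <-
      freq[cbind(seq_len(nrow(rows)), match(G, STRATA_ALL))] + 1
  }
  freq <- freq / reps
  # compare against membership probabilities computed independently
  terms <- expand_ps_terms(rows$ps, cfg$ps_order)
  X2 <- cbind(1, terms)
  pi_mat <- strata_probs(state$alpha, X2)
  for (i in seq_len(nrow(rows))) {
    logd <- NULL
    if (rows$S[i] == 1) {
      logd <- sapply(c("LL", "LD", "DL"), function(g) {
        d <- stratum_design(rows$Z[i], rows$time_from_treatment_months[i],
                            terms[i, ], g, "binary")
        normal_logdensity(rows$Y[i], d, state$eta[[g]], state$sigma2[[g]])
      })
    }
    rho <- membership_probs(rows$Z[i], rows$S[i],
                            stats::setNames(pi_mat[i, ], STRATA_ALL), logd)
    mc_se <- sqrt(pmax(rho * (1 - rho), 1e-4) / reps)
    expect_true(all(abs(freq[i, ] - rho) < 5 * mc_se))
  }
})

test_that("vanishing MH step size accepts almost surely", {
  rows <- toy_rows(40, seed = 6)
  cfg <- sampler_config(n_iter = 220, burn_in = 20, mh_step = 1e-7,
                        adapt_during_burnin = FALSE, seed = 9)
  draws <- suppressWarnings(run_da_mcmc(rows, cfg))
  expect_true(all(draws$acceptance > 0.97))
})

test_that("chains are reproducible from the seed and satisfy structural invariants", {
  rows <- toy_rows(60, seed = 7)
  cfg <- sampler_config(n_iter = 300, burn_in = 100, seed = 42,
                        model_type = "time")
  d1 <- suppressWarnings(run_da_mcmc(rows, cfg))
  d2 <- suppressWarnings(run_da_mcmc(rows, cfg))
  expect_identical(d1$chain, d2$chain)
  expect_identical(d1$strata_counts, d2$strata_counts)

  expect_true(all(d1$chain[, grep("sigma2", colnames(d1$chain))] > 0))
  expect_true(all(rowSums(d1$strata_counts) == nrow(rows)))
  expect_true(all(d1$acceptance >= 0 & d1$acceptance <= 1))

  # monotonicity: DL never appears
  cfgm <- sampler_config(n_iter = 300, burn_in = 100, seed = 42,
                         model_type = "time", monotonicity = TRUE)
  dm <- suppressWarnings(run_da_mcmc(rows, cfgm))
  expect_false("DL" %in% colnames(dm$strata_counts))
  expect_true(all(rowSums(dm$strata_counts) == nrow(rows)))
})

test_that("clamping the I-step to the true strata recovers the LL treatment effect", {
  truth <- als_like_truth(eta_Z = 2.5, eta_T = -0.3)
  coh <- generate_cohort(truth, 500, seed = 31, emit_registry = FALSE)
  sc <- attach_scores(coh$rows)
  cfg <- sampler_config(n_iter = 1500, burn_in = 500, seed = 31,
                        model_type = "time",
                        clamp_labels = coh$latent$stratum)
  draws <- suppressWarnings(run_da_mcmc(sc$rows, cfg))
  z <- draws$chain[, "eta_LL.Z"]
  expect_lt(abs(mean(z) - 2.5), 3 * sd(z))
})

test_that("diagnostics flag degenerate chains and summarize healthy ones", {
  rows <- toy_rows(40, seed = 8)
  cfg <- sampler_config(n_iter = 400, burn_in = 100, seed = 5,
                        monotonicity = TRUE)
  draws <- suppressWarnings(run_da_mcmc(rows, cfg))
  dg <- suppressWarnings(mcmc_diagnostics(draws))
  expect_true(all(c("parameter", "ess", "split_rhat") %in% names(dg)))
  healthy <- dg[!dg$degenerate, ]
  expect_true(all(healthy$ess >= 1 & healthy$ess <= nrow(draws$chain)))

  draws$chain[, "eta_LL.Z"] <- 1.23
  expect_warning(mcmc_diagnostics(draws), "degenerate.*eta_LL.Z")
})
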