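test_that("logistic PS satisfies closed-form identities", {
  # intercept-only model: every score is the treated fraction
  Z <- rep(c(1, 0), c(7, 13))
  m <- fit_logistic_ps(matrix(1, 20, 1, dimnames = list(NULL, "intercept")), Z)
  expect_equal(m$scores, rep(7 / 20, 20), tolerance = 1e-9)

  # balanced +/-1 covariate independent of Z: its MLE coefficient is 0
  D <- cbind(intercept = 1, x = rep(c(1, -1, 1, -1), 5))
  Zb <- rep(c(1, 1, 0, 0), 5)
  mb <- fit_logistic_ps(D, Zb)
  expect_equal(unname(mb$coefficients["x"]), 0, tolerance = 1e-9)

  # score equation: mean fitted probability equals treated fraction
  set.seed(3)
  D2 <- cbind(intercept = 1, x = rnorm(80), w = rbinom(80, 1, 0.4))
  Z2 <- rbinom(80, 1, plogis(0.3 * D2[, "x"]))
  m2 <- fit_logistic_ps(D2, Z2)
  expect_equal(mean(m2$scores), mean(Z2), tolerance = 1e-8)
  expect_lt(m2$gradient_norm, 1e-6)
})

test_that("logistic MLE matches refined grid maximization on a small fixture", {
  set.seed(11)
  n <- 20
  x <- rnorm(n)
  Z <- rbinom(n, 1, plogis(-0.2 + 0.8 * x))
  D <- cbind(intercept = 1, x = x)
  fit <- fit_logistic_ps(D, Z)

  loglik <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(Z * eta - log1p(exp(eta)))
  }
  # coarse-to-fine grid search, independent of IRLS
  centre <- c(0, 0); width <- 4
  for (pass in 1:6) {
    b0s <- seq(centre[1] - width, centre[1] + width, length.out = 41)
    b1s <- seq(centre[2] - width, centre[2] + width, length.out = 41)
    ll <- outer(b0s, b1s, Vectorize(loglik))
    best <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    centre <- c(b0s[best[1]], b1s[best[2]])
    width <- width / 8
  }
  expect_equal(unname(fit$coefficients), centre, tolerance = 1e-4)
})

test_that("separation and collinearity are rejected with diagnostics", {
  x <- c(-(5:1), 1:5)
  Z <- as.integer(x > 0)
  expect_error(fit_logistic_ps(cbind(intercept = 1, x = x), Z), "separation")
  D <- cbind(intercept = 1, a = 1:10, b = 2 * (1:10))
  expect_error(fit_logistic_ps(D, rep(c(0, 1), 5)), "collinear.*b")
})

test_that("Cox GPS matches direct numerical maximization of the Breslow partial likelihood", {
  set.seed(5)
  n <- 10
  x <- rnorm(n)
  time <- round(rexp(n, exp(0.6 * x)) * 100) + 1   # day resolution, some ties
  event <- rbinom(n, 1, 0.8)
  event[1] <- 1
  fit <- fit_cox_gps(matrix(x, dimnames = list(NULL, "x")), time, event)

  # independent Breslow partial log-likelihood
  pl <- function(b) {
    eta <- b * x
    sum(vapply(which(event == 1), function(i) {
      eta[i] - log(sum(exp(eta[time >= time[i]])))
    }, numeric(1)))
  }
  opt <- optimize(pl, c(-5, 5), maximum = TRUE, tol = 1e-10)
  expect_equal(unname(fit$coefficients), opt$maximum, tolerance = 1e-6)
  expect_lt(fit$gradient_norm, 1e-4)
  expect_gte(pl(unname(fit$coefficients)), pl(0))
})

test_that("Cox GPS degenerate and invariance behavior", {
  D <- matrix(1, 12, 1, dimnames = list(NULL, "c"))
  fit <- fit_cox_gps(D, time = 1:12, event = rep(c(1, 0), 6))
  expect_true(fit$degenerate)
  expect_equal(unname(fit$coefficients), 0)

  set.seed(8)
  x <- rnorm(15)
  time <- rexp(15, exp(0.4 * x)) + 0.1
  event <- rbinom(15, 1, 0.7); event[2] <- 1
  f1 <- fit_cox_gps(matrix(x, dimnames = list(NULL, "x")), time, event)
  f2 <- fit_cox_gps(matrix(x + 10, dimnames = list(NULL, "x")), time, event)
  expect_equal(unname(f1$coefficients), unname(f2$coefficients),
               tolerance = 1e-6)
  d <- f2$scores - f1$scores
  expect_equal(max(d) - min(d), 0, tolerance = 1e-6)   # constant shift only

  expect_error(fit_cox_gps(matrix(x, dimnames = list(NULL, "x")),
                           time, rep(0, 15)), "no treatment events")
})

test_that("polynomial PS terms are standardized elementwise powers", {
  s <- c(10, 20, 30, 40, 20, 30)
  t1 <- expand_ps_terms(s, 1)
  expect_equal(ncol(t1), 1)
  expect_equal(mean(t1[, 1]), 0, tolerance = 1e-12)
  expect_equal(sd(t1[, 1]), 1, tolerance = 1e-12)
  t3 <- expand_ps_terms(s, 3)
  expect_equal(t3[, 2], t3[, 1]^2)
  expect_equal(t3[, 3], t3[, 1]^3)
  expect_true(is.finite(kappa(cbind(1, t3))))
  expect_error(expand_ps_terms(rep(2, 5), 1), "constant")
})

test_that("propensity adjustment balances a confounded covariate", {
  set.seed(42)
  n <- 4000
  # three confounders drive treatment; balance is assessed on the first
  x <- rnorm(n); w <- rnorm(n); v <- rnorm(n)
  lp <- 0.45 * (x + w + v)
  Z <- rbinom(n, 1, plogis(lp))
  rows <- data.frame(Z = Z, x = x, bin = rbinom(n, 1, plogis(0.6 * x)))
  ps <- fit_logistic_ps(cbind(intercept = 1, x, w, v), Z)
  tt <- ifelse(Z == 1, rexp(n, exp(lp)) + 0.01,
               quantile(rexp(n, exp(lp)), 0.9))
  gps <- fit_cox_gps(cbind(x, w, v), pmax(tt, 0.01), Z)
  bal <- balance_table(rows, covariates = "x", binary = "bin",
                       ps_model = ps, gps_model = gps, ps_order = 1)
  xrow <- bal[bal$covariate == "x", ]
  expect_lt(xrow$p_marginal, 0.05)
  expect_gt(xrow$p_standard_ps, 0.05)
  expect_gt(xrow$p_generalized_ps, 0.05)

  # within-quintile standardized differences shrink below 0.1
  q <- cut(ps$scores, quantile(ps$scores, seq(0, 1, 0.2)),
           include.lowest = TRUE)
  smd <- function(x, z) {
    (mean(x[z == 1]) - mean(x[z == 0])) /
      sqrt((var(x[z == 1]) + var(x[z == 0])) / 2)
  }
  marg <- abs(smd(x, Z))
  within <- sapply(levels(q), function(l) {
    i <- q == l
    if (length(unique(Z[i])) < 2) return(NA_real_)
    abs(smd(x[i], Z[i]))
  })
  expect_gt(marg, 0.3)
  expect_lt(mean(within, na.rm = TRUE), 0.1)
})

test_that("null p-values are roughly uniform for randomized treatment", {
  set.seed(9)
  n <- 2000
  Z <- rbinom(n, 1, 0.5)
  ps <- fit_logistic_ps(cbind(intercept = 1, x = rnorm(n)), Z)
  pvals <- replicate(200, {
    x <- rnorm(n)
    summary(lm(x ~ Z))$coefficients["Z", 4]
  })
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.035)
})
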