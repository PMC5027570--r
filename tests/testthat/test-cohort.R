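test_that("load_registry groups visits per subject, sorts them and computes offsets", {
  df <- visit_rows("A", c(0, 100, 200), c(24, 23.5, 23))
  rec <- load_registry(write_registry(df), synthetic_schema())
  expect_length(rec, 1)
  expect_s3_class(rec[[1]], "subject_record")
  expect_equal(rec[[1]]$visits$day, c(0, 100, 200))
  expect_equal(rec[[1]]$visits$outcome, c(24, 23.5, 23))

  # out-of-order visit rows produce the same record
  shuffled <- df[c(3, 1, 2), ]
  rec2 <- load_registry(write_registry(shuffled), synthetic_schema())
  expect_equal(rec2[[1]]$visits, rec[[1]]$visits)

  # offsets are relative to the first visit even for shifted raw days
  df3 <- visit_rows("B", c(0, 50), c(25, 24.5))
  df3$day <- df3$day + 1000
  rec3 <- load_registry(write_registry(df3), synthetic_schema())
  expect_equal(rec3[[1]]$visits$day, c(0, 50))
})

test_that("load_registry rejects bad schemas and duplicate visit days", {
  df <- visit_rows("A", c(0, 100), c(24, 23))
  expect_error(load_registry(write_registry(df), list(subject_id = "subject_id")),
               "mandatory")
  sch <- synthetic_schema()
  sch$outcome <- "not_a_column"
  expect_error(load_registry(write_registry(df), sch), "not_a_column")
  dup <- rbind(df, df[2, ])
  expect_error(load_registry(write_registry(dup), synthetic_schema()),
               "duplicate visit day.*A")
})

test_that("exclusion rules fire in order with first-rule-wins accounting", {
  baseline_only <- record_of("r1", days = 0, outcome = 24)
  long_surv <- record_of("r2", death_day = 2000)
  # alive at horizon, visits within horizon but no non-missing outcome there
  no_outcome <- record_of("r3", days = c(0, 100, 500),
                          outcome = c(24, NA, 23))
  # violates both rule 1 (no follow-up <= 365) and rule 2 (long survival)
  both <- new_subject_record("r4", c(age = 60),
                             data.frame(day = c(0, 400), outcome = c(24, 23),
                                        fvc = 60), death_day = 1900)
  keeper <- record_of("r5", treatment_day = 100)

  out <- apply_exclusions(list(baseline_only, long_surv, no_outcome, both,
                               keeper))
  expect_equal(unname(out$report$excluded),
               c(2L, 1L, 1L))          # r1+r4 under rule 1; r2 rule 2; r3 rule 3
  expect_equal(out$report$n_remaining, 1L)
  expect_equal(out$records[[1]]$subject_id, "r5")
  expect_equal(out$report$n_input - sum(out$report$excluded),
               out$report$n_remaining)

  empty <- apply_exclusions(list())
  expect_equal(empty$report$n_input, 0L)
  expect_equal(sum(empty$report$excluded), 0L)
})

test_that("exclusion accounting conserves counts on random cohorts", {
  coh <- generate_cohort(als_like_truth(), 120, seed = 99)
  f <- write_registry(coh$registry)
  rec <- load_registry(f, synthetic_schema())
  out <- apply_exclusions(rec)
  expect_equal(out$report$n_input,
               out$report$n_remaining + sum(out$report$excluded))
})

test_that("derive_analysis_row computes Z, S, Y and treatment lag", {
  r <- record_of("A", days = c(0, 180, 330), outcome = c(24, 23.5, 23),
                 treatment_day = 100)
  row <- derive_analysis_row(r, horizon_days = 365)
  expect_equal(row$Z, 1L)
  expect_equal(row$S, 1L)
  expect_equal(row$Y, 23)              # latest eligible visit, day 330
  expect_equal(row$time_from_treatment_months, (365 - 100) / 30.4375,
               tolerance = 1e-12)

  # censoring by death: no Y regardless of measurements
  rd <- record_of("B", days = c(0, 100), outcome = c(24, 23), death_day = 200)
  rowd <- derive_analysis_row(rd)
  expect_equal(rowd$S, 0L)
  expect_true(is.na(rowd$Y))

  # treatment past the horizon is untreated at the horizon
  rt <- record_of("C", treatment_day = 400)
  rowt <- derive_analysis_row(rt)
  expect_equal(rowt$Z, 0L)
  expect_equal(rowt$time_from_treatment_months, 0)
})

test_that("outcome-visit selection picks the latest eligible visit (brute force)", {
  set.seed(7)
  for (k in 1:25) {
    n_v <- sample(2:8, 1)
    days <- sort(sample(1:500, n_v))
    outcome <- ifelse(runif(n_v) < 0.3, NA, round(rnorm(n_v, 24, 2), 1))
    rec <- new_subject_record("x", c(age = 50),
                              data.frame(day = c(0, days),
                                         outcome = c(24, outcome), fvc = 60))
    elig <- which(days <= 365 & !is.na(outcome))
    if (!length(elig)) next
    row <- derive_analysis_row(rec)
    expect_equal(row$Y, outcome[max(elig)])
  }
})

test_that("covariate standardization is exact, shift-invariant and idempotent", {
  rows <- toy_rows(60)
  rows$age <- rnorm(60, 60, 10)
  z1 <- normalize_covariates(rows, "age")
  expect_equal(mean(z1$age), 0, tolerance = 1e-12)
  expect_equal(sd(z1$age), 1, tolerance = 1e-12)

  shifted <- rows
  shifted$age <- rows$age + 500
  z2 <- normalize_covariates(shifted, "age")
  expect_equal(z2$age, z1$age, tolerance = 1e-12)

  z3 <- normalize_covariates(z1, "age")
  expect_equal(z3$age, z1$age, tolerance = 1e-12)

  rows$flat <- 3
  expect_error(normalize_covariates(rows, "flat"), "flat")
})

test_that("cohort_summary reports arm survival and textbook chi-square p-values", {
  # 200 treated with 83 survivors, 380 untreated with 206 survivors
  rows <- data.frame(Z = rep(c(1, 0), c(200, 380)),
                     S = c(rep(c(1, 0), c(83, 117)),
                           rep(c(1, 0), c(206, 174))))
  rows$Y <- ifelse(rows$S == 1, 24, NA)
  summ <- cohort_summary(rows)
  surv <- summ[summ$variable == "proportion_surviving", ]
  expect_equal(round(100 * surv$treated_mean, 1), 41.5)
  expect_equal(surv$treated_sd_or_n, 83)

  # Pearson chi-square against the hand formula sum (O-E)^2/E
  tab <- rbind(c(83, 117), c(206, 174))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2 <- sum((tab - E)^2 / E)
  expect_equal(surv$p_value, pchisq(x2, df = 1, lower.tail = FALSE),
               tolerance = 1e-12)

  # identical arms: comparisons are null
  rows2 <- data.frame(Z = rep(c(1, 0), each = 50),
                      S = rep(1, 100), Y = rep(c(24, 25), 50),
                      age = rep(c(60, 62), 50))
  summ2 <- cohort_summary(rows2, continuous = "age")
  expect_equal(summ2$p_value[summ2$variable == "age"], 1, tolerance = 1e-9)
})
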