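# Fixtures built in code: tiny registries and analysis tables used across
# the test files.

# One-subject registry rows (visit-level) as written by an EMR export.
visit_rows <- function(id, days, bmi, fvc = NULL, treatment_day = NA,
                       death_day = NA) {
  if (is.null(fvc)) fvc <- rep(60, length(days))
  data.frame(subject_id = id, day = days, bmi = bmi, fvc = fvc,
             treatment_day = treatment_day, death_day = death_day,
             age = 60, bmi0 = bmi[1], fvc0 = fvc[1],
             female = 0, spinal = 1, dtdx30 = 0,
             stringsAsFactors = FALSE)
}

write_registry <- function(df) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE)
  f
}

# Minimal analysis table for sampler-level tests: n subjects with the four
# observed groups represented, plus ps/gps columns.
toy_rows <- function(n = 40, seed = 1) {
  set.seed(seed)
  Z <- rep(c(0, 1), length.out = n)
  S <- rbinom(n, 1, 0.6)
  tz <- ifelse(Z == 1, sample(30:330, n, replace = TRUE), NA)
  tm <- ifelse(Z == 1, (365 - tz) / 30.4375, 0)
  Y <- ifelse(S == 1, rnorm(n, 24 + 2 * Z, 2), NA)
  data.frame(subject_id = sprintf("T%03d", seq_len(n)), Z = Z, S = S,
             T_Z_days = tz, time_from_treatment_months = tm, Y = Y,
             death_day = ifelse(S == 0, 200, NA),
             ps = plogis(rnorm(n)), gps = rnorm(n),
             stringsAsFactors = FALSE)
}

# A subject record built directly (bypassing file IO).
record_of <- function(id = "A", days = c(0, 100, 200),
                      outcome = c(24, 23.5, 23), treatment_day = NA,
                      death_day = NA) {
  new_subject_record(id, c(age = 60),
                     data.frame(day = days, outcome = outcome,
                                fvc = rep(60, length(days))),
                     treatment_day = treatment_day, death_day = death_day)
}
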