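# Shared fixtures: all built in code at test time.

# A small hand-built cohort, deterministic and tie-free where it matters.
make_mini_cohort <- function(n = 12, seed = 42) {
  set.seed(seed)
  df <- data.frame(
    participant_id = sprintf("P%03d", seq_len(n)),
    age = rep(c(9, 11, 13, 15, 17, 18), length.out = n),
    gender = rep(c("male", "female"), length.out = n),
    race = rep(c("Hispanic", "non-Hispanic"), each = 2, length.out = n),
    education = rep(c("<9th grade", ">=9th grade"), length.out = n),
    family_pir = round(runif(n, 0.5, 4), 2),
    stimulant_use = rep(c(FALSE, FALSE, TRUE), length.out = n),
    stringsAsFactors = FALSE)
  for (v in obsbmd::dietary_components()) {
    df[[v]] <- round(runif(n, 1, 100), 3)
  }
  df$bmi <- round(runif(n, 15, 30), 1)
  df$cotinine <- round(runif(n, 0.01, 1), 3)
  df$alcohol <- 0
  df$pa_transport_sessions <- sample(0:5, n, replace = TRUE)
  df$pa_transport_minutes <- ifelse(df$pa_transport_sessions > 0, 20, 0)
  df$pa_moderate_sessions <- sample(0:7, n, replace = TRUE)
  df$pa_moderate_minutes <- ifelse(df$pa_moderate_sessions > 0, 45, 0)
  df$albumin <- round(runif(n, 4, 5), 2)
  df$vitd_25oh <- round(runif(n, 40, 70), 1)
  df$uric_acid <- round(runif(n, 3.5, 6.5), 2)
  df$ggt <- round(runif(n, 10, 20), 1)
  df$bmd_lumbar <- round(runif(n, 0.7, 1.0), 3)
  df$bmd_pelvis <- round(runif(n, 0.9, 1.2), 3)
  df$bmd_total <- round(runif(n, 0.8, 1.1), 3)
  df
}

# Generate a cohort, apply exclusions, score it, and return the merged
# analysis table (plus pieces) in one call.
make_analysis <- function(config) {
  sim <- obsbmd::generate_cohort(config)
  excl <- obsbmd::apply_exclusions(sim$cohort)
  obs <- obsbmd::compute_obs(excl$cohort)
  list(tab = obsbmd::analysis_table(excl$cohort, obs),
       cohort = excl$cohort, obs = obs, truth = sim$truth,
       tally = excl$tally)
}

# Independent brute-force oracle for type-7 (linear interpolation) sample
# quantiles, written directly from the definition.
oracle_quantile7 <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Brute-force tertile scorer: sort-based cutpoints, "value <= cutpoint =>
# lower tertile", reversal for pro-oxidants; per gender stratum.
oracle_tertile <- function(values, gender, direction) {
  out <- integer(length(values))
  for (g in unique(gender)) {
    idx <- gender == g
    v <- values[idx]
    c1 <- oracle_quantile7(v, 1 / 3)
    c2 <- oracle_quantile7(v, 2 / 3)
    sc <- ifelse(v <= c1, 0L, ifelse(v <= c2, 1L, 2L))
    if (direction == "pro-oxidant") sc <- 2L - sc
    out[idx] <- sc
  }
  out
}

cohort_columns_for_test <- function() names(make_mini_cohort())

# Mirror the package's fixed dummy-coding reference levels for oracle fits.
prepare_df_for_oracle <- function(df) {
  if ("gender" %in% names(df)) {
    df$gender <- factor(df$gender, levels = c("male", "female"))
  }
  if ("race" %in% names(df)) {
    df$race <- factor(df$race, levels = c("non-Hispanic", "Hispanic"))
  }
  df
}

# Closed-form OLS via the normal equations.
oracle_ols <- function(X, y) {
  as.numeric(solve(crossprod(X), crossprod(X, y)))
}
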