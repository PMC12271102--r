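test_that("gaussian-identity GLM equals the normal-equations oracle", {
  set.seed(55)
  for (i in 1:10) {
    n <- sample(30:60, 1)
    df <- data.frame(y = rnorm(n), x = rnorm(n), z = rnorm(n),
                     gender = sample(c("male", "female"), n, replace = TRUE))
    fit <- glm_fit(df, "y", "x", c("z", "gender"))
    X <- cbind(1, df$x, df$z, as.numeric(df$gender == "female"))
    expect_equal(fit$terms$estimate, oracle_ols(X, df$y), tolerance = 1e-10)
  }
})

test_that("a constant outcome yields a zero exposure slope with p = 1", {
  df <- data.frame(y = rep(2, 40), x = rnorm(40))
  fit <- glm_fit(df, "y", "x")
  row <- term_row(fit, "x")
  expect_equal(row$estimate, 0, tolerance = 1e-12)
  expect_equal(row$p, 1)
})

test_that("glm_fit recovers a planted slope and rejects rank deficiency", {
  set.seed(88)
  n <- 2000
  df <- data.frame(x = rnorm(n))
  df$y <- 0.02 * df$x + rnorm(n, 0, 0.1)
  row <- term_row(glm_fit(df, "y", "x"))
  expect_true(row$ci_low <= 0.02 && 0.02 <= row$ci_high)

  df$x2 <- 2 * df$x
  expect_error(glm_fit(df, "y", "x", "x2"), "collinear")
  expect_error(glm_fit(df[1:3, ], "y", "x"), "complete cases")
  expect_error(glm_fit(df, "y", "missing_col"), "missing_col")
})

test_that("leave-one-out sensitivity reproduces the full model for inert covariates", {
  set.seed(12)
  n <- 400
  # u is independent of exposure and outcome by construction (noiseless)
  df <- data.frame(x = rnorm(n), u = rnorm(n), v = rnorm(n))
  df$y <- 0.5 * df$x + 0.3 * df$v
  tabr <- sensitivity_loo(df, "y", "x", c("u", "v"))
  expect_equal(nrow(tabr), 2)
  full <- attr(tabr, "full")
  expect_equal(tabr$estimate[tabr$excluded == "u"], full$estimate,
               tolerance = 1e-6)

  # six covariates -> six rows
  an <- make_analysis(preset_paperlike(n = 400, seed = 6))
  st <- sensitivity_loo(an$tab, "bmd_total", "lifestyle_obs",
                        default_covariates())
  expect_equal(nrow(st), 6)
  expect_equal(st$excluded, default_covariates())
})

test_that("age exclusion alone flips the exposure sign under planted confounding", {
  an <- make_analysis(preset_paperlike(n = 1196, seed = 7))
  for (oc in bmd_outcomes()) {
    st <- sensitivity_loo(an$tab, oc, "lifestyle_obs", default_covariates())
    full_beta <- attr(st, "full")$estimate
    expect_lt(full_beta, 0)
    flipped <- st$estimate > 0
    expect_true(flipped[st$excluded == "age"], label = oc)
    expect_false(any(flipped[st$excluded != "age"]), label = oc)
  }
})

test_that("subgroup interaction recovers planted opposite-signed slopes", {
  cfg <- preset_paperlike(n = 4000, seed = 14, beta_young = 0.02,
                          beta_old = -0.015, mediation_b_uric = 0,
                          mediation_b_ggt = 0, mediation_b_albumin = 0)
  an <- make_analysis(cfg)
  sg <- subgroup_interaction(an$tab, "bmd_total", "lifestyle_obs", "age")
  expect_lt(sg$p_interaction[["adjusted"]], 0.001)
  expect_lt(sg$p_interaction[["unadjusted"]], 0.001)
  adj <- sg$strata[sg$strata$adjusted == TRUE, ]
  expect_gt(adj$estimate[adj$stratum == "low"], 0)
  expect_lt(adj$estimate[adj$stratum == "high"], 0)
  # with age itself in the stratum covariate sets (unlike the reported
  # procedure, which drops the stratifier) the planted slopes sit inside
  # their 95% CIs
  for (lev in c("low", "high")) {
    sub <- an$tab[as.character(median_split(an$tab$age)) == lev, ]
    f <- term_row(glm_fit(sub, "bmd_total", "lifestyle_obs",
                          c("age", "gender")))
    truth <- if (lev == "low") 0.02 else -0.015
    expect_true(f$ci_low <= truth && truth <= f$ci_high, label = lev)
  }

  # degenerate modifier: everyone in one stratum
  df <- an$tab
  df$onegrp <- "a"
  expect_error(subgroup_interaction(df, "bmd_total", "lifestyle_obs",
                                    "onegrp"), "2 levels")
})

test_that("interaction p-values are calibrated under the null", {
  reps <- 200
  pvals <- numeric(reps)
  for (r in seq_len(reps)) {
    cfg <- synthetic_config(n = 300, seed = 7000 + r,
                            obs_effect_mode = "none")
    an <- make_analysis(cfg)
    sg <- subgroup_interaction(an$tab, "bmd_total", "lifestyle_obs", "age",
                               covariates = c("gender"))
    pvals[r] <- sg$p_interaction[["adjusted"]]
  }
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("combined four-group comparison reflects the planted ordering", {
  # OBS helps only the young; no age trend or noise, so high-age groups are
  # comparable and the young high-OBS group clearly exceeds the young low-OBS
  cfg <- synthetic_config(n = 800, seed = 19, beta_young = 0.04,
                          beta_old = 0, age_bmd_slope = 0, noise_sd_bmd = 0.01,
                          mediation_b_uric = 0, mediation_b_ggt = 0,
                          mediation_b_albumin = 0)
  an <- make_analysis(cfg)
  cg <- combined_groups(an$tab, "bmd_total")
  s <- cg$summary
  mean_of <- function(g) s$mean[s$group == g]
  expect_gt(mean_of("age_low.obs_high"), mean_of("age_low.obs_low"))
  expect_lt(abs(mean_of("age_high.obs_high") - mean_of("age_high.obs_low")),
            0.02)
  expect_lt(cg$omnibus_p[["bmd_total"]], 0.001)
  expect_equal(nrow(cg$pairwise), 6)
  expect_true(all(cg$pairwise$p_bonferroni >= cg$pairwise$p_raw))

  # identical outcome in all groups -> omnibus p = 1
  flat <- an$tab
  flat$bmd_total <- 1
  expect_equal(combined_groups(flat, "bmd_total")$omnibus_p[["bmd_total"]], 1)

  # row shuffling leaves all statistics unchanged
  set.seed(2)
  shuf <- an$tab[sample(nrow(an$tab)), ]
  cg2 <- combined_groups(shuf, "bmd_total")
  expect_equal(cg2$summary, cg$summary)
  expect_equal(cg2$omnibus_p, cg$omnibus_p)
})

test_that("gender interaction model uses zero-coded references and matches OLS", {
  an <- make_analysis(preset_paperlike(n = 600, seed = 23))
  g <- gender_interaction_model(an$tab, "bmd_total", default_covariates())
  # treatment coding against low OBS / male: three estimated contrasts
  expect_true(any(grepl("obs_grouphigh$", g$terms$term)))
  expect_true(any(grepl("genderfemale$", g$terms$term)))
  expect_true(any(grepl("obs_grouphigh:genderfemale", g$terms$term)))
  expect_gt(g$scale_ml, 0)

  # coefficients equal the normal-equations oracle on the same design
  df <- an$tab
  df$obs_group <- median_split(df$lifestyle_obs)
  X <- model.matrix(~ obs_group * gender + age, prepare_df_for_oracle(df))
  fit2 <- gender_interaction_model(df, "bmd_total", "age")
  expect_equal(fit2$terms$estimate[match(colnames(X), fit2$terms$term)],
               oracle_ols(X, df$bmd_total), tolerance = 1e-8)

  # swapping the reference level flips signs but not fitted values
  df2 <- df
  df2$gender <- factor(df2$gender, levels = c("female", "male"))
  m1 <- lm(bmd_total ~ obs_group * gender, prepare_df_for_oracle(df))
  m2 <- lm(bmd_total ~ obs_group * gender, df2)
  expect_lt(max(abs(fitted(m1) - fitted(m2))), 1e-10)
})

test_that("no planted gender modification keeps the product term null-calibrated", {
  reps <- 200
  pvals <- numeric(reps)
  for (r in seq_len(reps)) {
    an <- make_analysis(synthetic_config(n = 300, seed = 11000 + r,
                                         obs_effect_mode = "none"))
    g <- gender_interaction_model(an$tab, "bmd_total")
    pvals[r] <- g$terms$p[grepl(":", g$terms$term)]
  }
  expect_gt(mean(pvals > 0.05), 0.90)
  expect_lte(mean(pvals > 0.05), 1)
})
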