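test_that("gam smooth of purely linear data stays essentially linear", {
  set.seed(41)
  n <- 400
  df <- data.frame(x = sample(0:8, n, replace = TRUE))
  df$y <- 0.9 + 0.02 * df$x + rnorm(n, 0, 0.05)
  gc <- gam_curve(df, "y", "x")
  expect_lte(gc$edf, 1.5)
  # monotone fitted curve
  expect_true(all(diff(gc$curve$fit) > -1e-8))
})

test_that("gam recovers a planted V-shaped vertex", {
  set.seed(43)
  n <- 600
  df <- data.frame(x = runif(n, 0, 8))
  df$y <- 0.9 + 0.05 * abs(df$x - 4.5)
  gc <- gam_curve(df, "y", "x", k = 8)
  vertex <- gc$curve$exposure[which.min(gc$curve$fit)]
  expect_lt(abs(vertex - 4.5), 0.25)

  # invariance to row shuffling
  gc2 <- gam_curve(df[sample(n), ], "y", "x", k = 8)
  expect_equal(gc2$curve$fit, gc$curve$fit, tolerance = 1e-8)

  # degenerate exposure support is refused
  df$x3 <- rep(1:3, length.out = n)
  expect_error(gam_curve(df, "y", "x3"), "5 distinct")
})

test_that("threshold fit recovers a noiseless planted breakpoint exactly", {
  cfg <- synthetic_config(n = 600, seed = 3, obs_effect_mode = "breakpoint",
                          breakpoint_k = 4.6, slope_below = -0.043,
                          slope_above = 0.066, noise_sd_bmd = 0,
                          age_bmd_slope = 0, mediation_b_uric = 0,
                          mediation_b_ggt = 0, mediation_b_albumin = 0)
  an <- make_analysis(cfg)
  suppressWarnings(
    tf <- threshold_fit(an$tab, "bmd_lumbar", "lifestyle_obs",
                        covariates = "gender", grid = seq(3, 7, by = 0.05))
  )
  expect_equal(tf$breakpoint, 4.6, tolerance = 1e-10)
  expect_equal(tf$slope_below$estimate, -0.043, tolerance = 1e-8)
  expect_equal(tf$slope_above$estimate, 0.066, tolerance = 1e-8)
  expect_lt(tf$lrt_p, 1e-10)

  # algebraic identity: slope_above - slope_below = hinge coefficient
  expect_equal(tf$slope_above$estimate - tf$slope_below$estimate,
               tf$hinge_coef, tolerance = 1e-12)

  # piecewise fitted mean is continuous at K
  cf <- coef(tf$model)
  eps <- 1e-9
  lhs <- cf[["lifestyle_obs"]] * (tf$breakpoint - eps)
  rhs <- cf[["lifestyle_obs"]] * (tf$breakpoint + eps) +
    cf[[".hinge"]] * eps
  expect_equal(lhs, rhs, tolerance = 1e-6)

  # profile log-likelihood is maximised at the selected K
  expect_true(all(tf$profile_loglik$loglik <=
                    tf$loglik_piecewise + 1e-9))
  # piecewise model never fits worse than the nested linear model
  expect_gte(tf$loglik_piecewise, tf$loglik_linear)
  expect_gte(tf$lrt, 0)
})

test_that("threshold fit on integer exposures uses the observed-value grid", {
  an <- make_analysis(preset_paperlike(n = 800, seed = 5,
                                       obs_effect_mode = "breakpoint"))
  tf <- threshold_fit(an$tab, "bmd_total", "lifestyle_obs",
                      default_covariates())
  expect_true(all(tf$grid %in% unique(an$tab$lifestyle_obs)))
  expect_true(tf$breakpoint >= min(tf$grid) && tf$breakpoint <= max(tf$grid))
  expect_lt(tf$lrt_p, 0.001)

  expect_error(threshold_fit(an$tab[1:10, ], "bmd_total", "lifestyle_obs"),
               ">= 30")
})

test_that("the LRT is calibrated on purely linear data", {
  reps <- 200
  alpha_hits <- logical(reps)
  for (r in seq_len(reps)) {
    set.seed(9000 + r)
    n <- 250
    df <- data.frame(x = sample(0:8, n, replace = TRUE))
    df$y <- 0.9 + 0.01 * df$x + rnorm(n, 0, 0.1)
    tf <- threshold_fit(df, "y", "x")
    alpha_hits[r] <- tf$lrt_p < 0.01
  }
  # non-significant at the 1% level in at least 95% of replicates
  expect_gte(mean(!alpha_hits), 0.95)
})

test_that("with no covariates, results are invariant to affine exposure shifts", {
  set.seed(77)
  n <- 300
  df <- data.frame(x = runif(n, 0, 8))
  df$y <- 1 - 0.04 * pmin(df$x, 4.5) + 0.05 * pmax(df$x - 4.5, 0) +
    rnorm(n, 0, 0.02)
  g <- seq(1, 7.5, by = 0.1)
  t1 <- threshold_fit(df, "y", "x", grid = g)
  df2 <- df
  df2$x <- df$x + 10
  t2 <- threshold_fit(df2, "y", "x", grid = g + 10)
  expect_equal(t2$breakpoint, t1$breakpoint + 10, tolerance = 1e-10)
  expect_equal(t2$slope_below$estimate, t1$slope_below$estimate,
               tolerance = 1e-10)
  expect_equal(t2$slope_above$estimate, t1$slope_above$estimate,
               tolerance = 1e-10)
  expect_equal(t2$lrt, t1$lrt, tolerance = 1e-8)
})

test_that("the parametric-bootstrap p-value agrees with chi-square under strong signal", {
  an <- make_analysis(synthetic_config(n = 400, seed = 27,
                                       obs_effect_mode = "breakpoint",
                                       noise_sd_bmd = 0.05,
                                       mediation_b_uric = 0,
                                       mediation_b_ggt = 0,
                                       mediation_b_albumin = 0))
  tf <- threshold_fit(an$tab, "bmd_total", "lifestyle_obs", "age",
                      p_method = "bootstrap", boot_reps = 99, boot_seed = 2)
  expect_lt(tf$lrt_p, 0.05)
  expect_equal(tf$p_method, "bootstrap")
})
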