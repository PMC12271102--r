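#' GAM dose-response curve
#'
#' Smooths the outcome on the exposure with a penalized thin-plate spline
#' (Gaussian family, identity link), covariates entering linearly, smoothing
#' parameter selected by GCV (mgcv's `GCV.Cp`). Returns the fitted curve with
#' a pointwise 95% confidence band on an evenly spaced exposure grid, holding
#' covariates at reference values (numeric covariates at their mean,
#' categorical at the reference level).
#'
#' @inheritParams glm_fit
#' @param grid_length Number of grid points.
#' @param k Spline basis dimension; default adapts to the number of distinct
#'   exposure values.
#' @return Object of class `gam_curve`: list with `curve` (data frame:
#'   `exposure`, `fit`, `se`, `ci_low`, `ci_high`), `edf` (effective degrees
#'   of freedom of the smooth), and the fitted `model`.
#' @export
gam_curve <- function(data, outcome, exposure, covariates = character(),
                      grid_length = 100, k = NULL) {
  df <- prepare_model_data(data)
  vars <- c(outcome, exposure, covariates)
  df <- df[stats::complete.cases(df[vars]), vars, drop = FALSE]
  if (nrow(df) < 50L) {
    stop("gam_curve: need >= 50 complete cases", call. = FALSE)
  }
  nvals <- length(unique(df[[exposure]]))
  if (nvals < 5L) {
    stop("gam_curve: exposure has fewer than 5 distinct values",
         call. = FALSE)
  }
  if (is.null(k)) k <- min(10L, nvals - 1L)
  rhs <- c(sprintf("s(%s, k = %d)", exposure, k), covariates)
  form <- stats::reformulate(rhs, response = outcome)
  fit <- mgcv::gam(form, data = df, family = stats::gaussian(),
                   method = "GCV.Cp")

  grid <- data.frame(seq(min(df[[exposure]]), max(df[[exposure]]),
                         length.out = grid_length))
  names(grid) <- exposure
  for (cv in covariates) {
    grid[[cv]] <- if (is.numeric(df[[cv]])) mean(df[[cv]])
      else factor(levels(df[[cv]])[1], levels = levels(df[[cv]]))
  }
  pr <- mgcv::predict.gam(fit, newdata = grid, se.fit = TRUE)
  q <- stats::qnorm(0.975)
  curve <- data.frame(exposure = grid[[exposure]], fit = as.numeric(pr$fit),
                      se = as.numeric(pr$se.fit))
  curve$ci_low <- curve$fit - q * curve$se
  curve$ci_high <- curve$fit + q * curve$se
  out <- list(outcome = outcome, exposure = exposure,
              covariates = covariates, n = nrow(df),
              edf = sum(summary(fit)$edf),
              curve = curve, model = fit)
  class(out) <- "gam_curve"
  out
}

#' @export
print.gam_curve <- function(x, ...) {
  cat(sprintf("<gam_curve> %s ~ s(%s)%s, n = %d, smooth edf = %.2f\n",
              x$outcome, x$exposure,
              if (length(x$covariates))
                paste0(" + ", paste(x$covariates, collapse = " + ")) else "",
              x$n, x$edf))
  invisible(x)
}

#' Two-segment threshold (inflection-point) regression
#'
#' Profiles a continuous piecewise-linear model over candidate breakpoints:
#' for each candidate K the model `outcome ~ covariates + x + (x - K)+` is
#' fitted, and the K maximizing the Gaussian log-likelihood is selected. The
#' slope below the breakpoint is the coefficient of `x`; the slope above is
#' the sum of the two exposure coefficients, with a delta-method 95% CI. The
#' likelihood-ratio statistic compares the selected piecewise model to the
#' covariate-adjusted linear model; its p-value uses a chi-square reference
#' with 2 degrees of freedom by default (the extra slope plus the profiled
#' breakpoint), with a parametric-bootstrap alternative since the breakpoint
#' is a non-regular parameter.
#'
#' @inheritParams glm_fit
#' @param grid Candidate breakpoints: `NULL` (default) uses all distinct
#'   observed exposure values between the 5th and 95th percentiles; a numeric
#'   vector supplies an explicit grid.
#' @param min_side Minimum observations strictly below and above a candidate
#'   for it to be eligible.
#' @param p_method `"chisq"` (default) or `"bootstrap"`.
#' @param boot_reps,boot_seed Parametric-bootstrap settings for
#'   `p_method = "bootstrap"` (data simulated from the fitted linear model).
#' @return Object of class `threshold_fit`: list with `breakpoint`,
#'   `slope_below`/`slope_above` (each with `se`, `ci_low`, `ci_high`, `p`),
#'   `loglik_linear`, `loglik_piecewise`, `lrt`, `lrt_p`, `grid`, `n`.
#' @export
threshold_fit <- function(data, outcome, exposure, covariates = character(),
                          grid = NULL, min_side = 3L,
                          p_method = c("chisq", "bootstrap"),
                          boot_reps = 200L, boot_seed = 1L) {
  p_method <- match.arg(p_method)
  df <- prepare_model_data(data)
  vars <- c(outcome, exposure, covariates)
  df <- df[stats::complete.cases(df[vars]), vars, drop = FALSE]
  if (nrow(df) < 30L) {
    stop("threshold_fit: need >= 30 complete cases", call. = FALSE)
  }
  x <- df[[exposure]]
  if (is.null(grid)) {
    qs <- stats::quantile(x, c(0.05, 0.95), type = 7, names = FALSE)
    grid <- sort(unique(x[x >= qs[1] & x <= qs[2]]))
  }
  ok <- vapply(grid, function(K) {
    sum(x < K) >= min_side && sum(x > K) >= min_side
  }, logical(1))
  grid <- grid[ok]
  if (!length(grid)) {
    stop("threshold_fit: no candidate breakpoint has >= ", min_side,
         " observations on both sides", call. = FALSE)
  }

  base_rhs <- c(covariates, exposure)
  lin <- stats::lm(stats::reformulate(base_rhs, response = outcome),
                   data = df)
  ll_lin <- as.numeric(stats::logLik(lin))

  fit_at <- function(K) {
    df$.hinge <- pmax(x - K, 0)
    stats::lm(stats::reformulate(c(base_rhs, ".hinge"), response = outcome),
              data = df)
  }
  profile_ll <- vapply(grid, function(K) {
    as.numeric(stats::logLik(fit_at(K)))
  }, numeric(1))
  best <- which.max(profile_ll)
  K <- grid[best]
  pw <- fit_at(K)
  ll_pw <- profile_ll[best]

  cf <- stats::coef(pw)
  V <- stats::vcov(pw)
  b_lo <- cf[[exposure]]
  b_hi <- cf[[exposure]] + cf[[".hinge"]]
  se_lo <- sqrt(V[exposure, exposure])
  se_hi <- sqrt(V[exposure, exposure] + V[".hinge", ".hinge"] +
                  2 * V[exposure, ".hinge"])
  q <- stats::qnorm(0.975)
  seg <- function(b, se) {
    z <- if (se == 0) ifelse(b == 0, 0, Inf) else b / se
    list(estimate = b, se = se, ci_low = b - q * se, ci_high = b + q * se,
         p = 2 * stats::pnorm(-abs(z)))
  }
  lrt <- max(0, 2 * (ll_pw - ll_lin))
  lrt_p <- if (p_method == "chisq") {
    stats::pchisq(lrt, df = 2, lower.tail = FALSE)
  } else {
    threshold_boot_p(df, outcome, exposure, covariates, grid, min_side,
                     lin, lrt, boot_reps, boot_seed)
  }
  out <- list(outcome = outcome, exposure = exposure,
              covariates = covariates, n = nrow(df),
              breakpoint = K, grid = grid,
              slope_below = seg(b_lo, se_lo),
              slope_above = seg(b_hi, se_hi),
              hinge_coef = cf[[".hinge"]],
              loglik_linear = ll_lin, loglik_piecewise = ll_pw,
              lrt = lrt, lrt_p = lrt_p, p_method = p_method,
              profile_loglik = data.frame(K = grid, loglik = profile_ll),
              model = pw)
  class(out) <- "threshold_fit"
  out
}

threshold_boot_p <- function(df, outcome, exposure, covariates, grid,
                             min_side, lin, lrt_obs, reps, seed) {
  mu <- stats::fitted(lin)
  sd_hat <- sqrt(sum(stats::residuals(lin)^2) / stats::df.residual(lin))
  x <- df[[exposure]]
  base_rhs <- c(covariates, exposure)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  stat <- numeric(reps)
  for (r in seq_len(reps)) {
    df[[outcome]] <- mu + stats::rnorm(length(mu), 0, sd_hat)
    l0 <- as.numeric(stats::logLik(
      stats::lm(stats::reformulate(base_rhs, response = outcome), df)))
    l1 <- max(vapply(grid, function(K) {
      df$.hinge <- pmax(x - K, 0)
      as.numeric(stats::logLik(
        stats::lm(stats::reformulate(c(base_rhs, ".hinge"),
                                     response = outcome), df)))
    }, numeric(1)))
    stat[r] <- max(0, 2 * (l1 - l0))
  }
  (1 + sum(stat >= lrt_obs)) / (1 + reps)
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat(sprintf("<threshold_fit> %s ~ %s, n = %d\n", x$outcome, x$exposure,
              x$n))
  cat(sprintf("  breakpoint K = %.3f (grid of %d candidates)\n",
              x$breakpoint, length(x$grid)))
  cat(sprintf("  slope below: %.4f (95%% CI %.4f, %.4f; p = %.3g)\n",
              x$slope_below$estimate, x$slope_below$ci_low,
              x$slope_below$ci_high, x$slope_below$p))
  cat(sprintf("  slope above: %.4f (95%% CI %.4f, %.4f; p = %.3g)\n",
              x$slope_above$estimate, x$slope_above$ci_low,
              x$slope_above$ci_high, x$slope_above$p))
  cat(sprintf("  LRT vs linear: %.2f, p = %.3g (%s)\n", x$lrt, x$lrt_p,
              x$p_method))
  invisible(x)
}
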