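#' Single-mediator linear mediation analysis
#'
#' Product-of-coefficients mediation with covariate adjustment on complete
#' cases: path `a` from `mediator ~ exposure + covariates`, paths `b` and
#' `c'` (direct effect) from `outcome ~ exposure + mediator + covariates`,
#' and the total effect `c` from `outcome ~ exposure + covariates`. The
#' indirect effect is `a * b`; on a common complete-case sample the linear
#' identity `c = c' + a * b` holds exactly. Inference on the indirect effect
#' uses a percentile bootstrap over participant resamples (default), with
#' the two-sided bootstrap p-value the smallest level at which the
#' percentile interval excludes zero; a Sobel normal-theory test is also
#' reported.
#'
#' @inheritParams glm_fit
#' @param mediator Mediator column name.
#' @param reps Bootstrap replicates; values below 500 warn and proceed.
#' @param seed Integer seed for the bootstrap resampling.
#' @return Object of class `mediation_result`: list with `a`, `b`, `c`,
#'   `c_prime`, `indirect`, `ci` (percentile 95%), `p_boot`, `p_sobel`,
#'   `proportion_mediated` (NA when total and indirect effects disagree in
#'   sign), `n`, `reps`, `seed`.
#' @export
mediate <- function(data, exposure, mediator, outcome,
                    covariates = default_covariates(),
                    reps = 1000L, seed = 1L) {
  df <- prepare_model_data(data)
  vars <- c(outcome, exposure, mediator, covariates)
  absent <- setdiff(vars, names(df))
  if (length(absent)) {
    stop("mediate: variable(s) not found: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  df <- df[stats::complete.cases(df[vars]), vars, drop = FALSE]
  if (stats::var(df[[mediator]]) == 0) {
    stop("mediate: mediator '", mediator, "' is constant", call. = FALSE)
  }
  if (reps < 500L) {
    warning("mediate: reps < 500 gives unstable bootstrap intervals; ",
            "proceeding", call. = FALSE)
  }

  Xa <- stats::model.matrix(stats::reformulate(c(exposure, covariates)), df)
  Xb <- stats::model.matrix(stats::reformulate(c(exposure, mediator,
                                                 covariates)), df)
  n <- nrow(df)
  p_model <- ncol(Xb)
  if (n < 10L * p_model) {
    stop("mediate: need >= 10 complete cases per parameter (have ", n,
         " for ", p_model, " parameters)", call. = FALSE)
  }
  m <- df[[mediator]]
  y <- df[[outcome]]

  paths <- function(idx) {
    fa <- stats::lm.fit(Xa[idx, , drop = FALSE], m[idx])
    fb <- stats::lm.fit(Xb[idx, , drop = FALSE], y[idx])
    c(a = fa$coefficients[[exposure]], b = fb$coefficients[[mediator]],
      c_prime = fb$coefficients[[exposure]])
  }
  full_a <- stats::lm(stats::reformulate(c(exposure, covariates),
                                         response = mediator), df)
  full_b <- stats::lm(stats::reformulate(c(exposure, mediator, covariates),
                                         response = outcome), df)
  full_c <- stats::lm(stats::reformulate(c(exposure, covariates),
                                         response = outcome), df)
  a <- stats::coef(full_a)[[exposure]]
  b <- stats::coef(full_b)[[mediator]]
  c_prime <- stats::coef(full_b)[[exposure]]
  c_total <- stats::coef(full_c)[[exposure]]
  indirect <- a * b

  se_a <- sqrt(stats::vcov(full_a)[exposure, exposure])
  se_b <- sqrt(stats::vcov(full_b)[mediator, mediator])
  sobel_se <- sqrt(a^2 * se_b^2 + b^2 * se_a^2)
  p_sobel <- 2 * stats::pnorm(-abs(indirect / sobel_se))

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  boot <- numeric(reps)
  for (r in seq_len(reps)) {
    idx <- sample.int(n, n, replace = TRUE)
    pr <- paths(idx)
    boot[r] <- pr[["a"]] * pr[["b"]]
  }
  ci <- stats::quantile(boot, c(0.025, 0.975), type = 7, names = FALSE)
  # smallest two-sided level at which the percentile interval excludes 0
  p_boot <- min(1, 2 * min(mean(boot <= 0), mean(boot >= 0)))

  prop <- if (indirect == 0 || c_total == 0 ||
              sign(indirect) != sign(c_total)) NA_real_
          else indirect / c_total
  out <- list(exposure = exposure, mediator = mediator, outcome = outcome,
              covariates = covariates,
              a = a, b = b, c = c_total, c_prime = c_prime,
              indirect = indirect,
              ci = c(lower = ci[1], upper = ci[2]),
              p_boot = p_boot, p_sobel = p_sobel,
              proportion_mediated = prop,
              n = n, reps = as.integer(reps), seed = as.integer(seed))
  class(out) <- "mediation_result"
  out
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> %s -> %s -> %s (n = %d)\n",
              x$exposure, x$mediator, x$outcome, x$n))
  cat(sprintf("  a = %.4g, b = %.4g, c = %.4g, c' = %.4g\n",
              x$a, x$b, x$c, x$c_prime))
  cat(sprintf("  indirect a*b = %.4g (bootstrap 95%% CI %.4g, %.4g; p = %.3g,",
              x$indirect, x$ci[["lower"]], x$ci[["upper"]], x$p_boot))
  cat(sprintf(" %d reps)\n", x$reps))
  if (!is.na(x$proportion_mediated)) {
    cat(sprintf("  proportion mediated = %.1f%%\n",
                100 * x$proportion_mediated))
  }
  invisible(x)
}

#' Mediation panel over mediator-outcome pairs
#'
#' Runs [mediate()] for every combination of the supplied mediators and
#' outcomes under a shared deterministic seed schedule (each cell gets
#' `seed + cell index`), mirroring the biomarker-by-BMD-site mediation grid.
#'
#' @inheritParams mediate
#' @param mediators,outcomes Character vectors of column names.
#' @return Object of class `mediation_panel`: list of `mediation_result`
#'   objects plus a `summary` data frame (one row per pair with all paths,
#'   CI, and p-values).
#' @export
mediate_panel <- function(data, exposure,
                          mediators = c("albumin", "uric_acid", "ggt"),
                          outcomes = bmd_outcomes(),
                          covariates = default_covariates(),
                          reps = 1000L, seed = 1L) {
  cells <- expand.grid(mediator = mediators, outcome = outcomes,
                       stringsAsFactors = FALSE)
  results <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    results[[i]] <- mediate(data, exposure, cells$mediator[i],
                            cells$outcome[i], covariates, reps,
                            seed = seed + i)
  }
  names(results) <- paste(cells$mediator, cells$outcome, sep = ".")
  summary <- do.call(rbind, lapply(results, function(r) {
    data.frame(mediator = r$mediator, outcome = r$outcome,
               a = r$a, b = r$b, c = r$c, c_prime = r$c_prime,
               indirect = r$indirect,
               ci_low = r$ci[["lower"]], ci_high = r$ci[["upper"]],
               p_boot = r$p_boot, p_sobel = r$p_sobel,
               proportion_mediated = r$proportion_mediated,
               n = r$n, stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  out <- list(results = results, summary = summary,
              reps = as.integer(reps), seed = as.integer(seed))
  class(out) <- "mediation_panel"
  out
}

#' @export
print.mediation_panel <- function(x, ...) {
  cat(sprintf("<mediation_panel> %d mediator-outcome pairs, %d bootstrap ",
              nrow(x$summary), x$reps))
  cat("reps\n")
  print(format(x$summary, digits = 3), row.names = FALSE)
  invisible(x)
}
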