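#' Default covariate adjustment set
#'
#' The six confounders adjusted for in the multivariable models: age, gender,
#' race, education, family poverty-income ratio, and stimulant use.
#'
#' @return Character vector of covariate names.
#' @export
default_covariates <- function() {
  c("age", "gender", "race", "education", "family_pir", "stimulant_use")
}

# Fix the dummy-coding reference levels used throughout: male, non-Hispanic,
# <9th grade, no stimulant use.
prepare_model_data <- function(data) {
  df <- as.data.frame(data)
  if ("gender" %in% names(df)) {
    df$gender <- factor(df$gender, levels = c("male", "female"))
  }
  if ("race" %in% names(df)) {
    df$race <- factor(df$race, levels = c("non-Hispanic", "Hispanic"))
  }
  if ("education" %in% names(df)) {
    df$education <- factor(df$education,
                           levels = c("<9th grade", ">=9th grade"))
  }
  if ("stimulant_use" %in% names(df)) {
    df$stimulant_use <- factor(ifelse(df$stimulant_use, "yes", "no"),
                               levels = c("no", "yes"))
  }
  df
}

#' Gaussian-identity GLM association fit
#'
#' Fits `outcome ~ exposure + covariates` with Gaussian family and identity
#' link (equivalently ordinary least squares) on complete cases, reporting
#' per-term coefficients with Wald 95% confidence intervals and p-values
#' (normal quantiles). Categorical covariates are dummy-coded against fixed
#' reference levels (male, non-Hispanic, <9th grade, no stimulant use).
#'
#' @param data Analysis data frame (see [analysis_table()]).
#' @param outcome,exposure Column names.
#' @param covariates Character vector of covariate names (possibly empty).
#' @return An object of class `glm_fit`: list with `outcome`, `exposure`,
#'   `covariates`, `n`, and `terms` (data frame: `term`, `estimate`,
#'   `se`, `ci_low`, `ci_high`, `p`).
#' @export
glm_fit <- function(data, outcome, exposure, covariates = character()) {
  df <- prepare_model_data(data)
  vars <- c(outcome, exposure, covariates)
  absent <- setdiff(vars, names(df))
  if (length(absent)) {
    stop("glm_fit: variable(s) not found: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  df <- df[stats::complete.cases(df[vars]), vars, drop = FALSE]
  rhs <- c(exposure, covariates)
  form <- stats::reformulate(rhs, response = outcome)
  X <- stats::model.matrix(form, df)
  if (nrow(df) < ncol(X) + 2L) {
    stop("glm_fit: too few complete cases (", nrow(df), ") for ",
         ncol(X), " parameters", call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("glm_fit: rank-deficient design; collinear term(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  fit <- stats::glm(form, family = stats::gaussian(), data = df)
  wald_terms(fit, outcome, exposure, covariates, nrow(df))
}

wald_terms <- function(fit, outcome, exposure, covariates, n) {
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  # degenerate (numerically zero-variance) outcome: coefficients at rounding
  # magnitude carry no signal, so report them as exact zeros with p = 1
  disp <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
  scale_ref <- mean(stats::fitted(fit)^2) + 1
  if (disp < 1e-20 * scale_ref) {
    tiny <- abs(est) < 1e-8 * sqrt(scale_ref)
    est[tiny] <- 0
    se[tiny] <- 0
  }
  z <- ifelse(se == 0, ifelse(est == 0, 0, Inf), est / se)
  p <- 2 * stats::pnorm(-abs(z))
  q <- stats::qnorm(0.975)
  terms <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se),
                      ci_low = unname(est - q * se),
                      ci_high = unname(est + q * se),
                      p = unname(p), stringsAsFactors = FALSE)
  out <- list(outcome = outcome, exposure = exposure,
              covariates = covariates, n = n, terms = terms, model = fit)
  class(out) <- "glm_fit"
  out
}

#' Extract one term's row from a `glm_fit`
#'
#' @param fit A `glm_fit`.
#' @param term Term name; defaults to the exposure term.
#' @return One-row data frame (`term`, `estimate`, `se`, `ci_low`,
#'   `ci_high`, `p`).
#' @export
term_row <- function(fit, term = fit$exposure) {
  i <- which(fit$terms$term == term)
  if (!length(i)) {
    stop("term_row: no term '", term, "' in fit", call. = FALSE)
  }
  fit$terms[i, , drop = FALSE]
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit> %s ~ %s%s (gaussian/identity, n = %d)\n",
              x$outcome, x$exposure,
              if (length(x$covariates))
                paste0(" + ", paste(x$covariates, collapse = " + ")) else "",
              x$n))
  print(format(x$terms, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Leave-one-covariate-out sensitivity analysis
#'
#' Refits the adjusted exposure model once per covariate, excluding that
#' covariate only, and reports the exposure coefficient each time. A reversal
#' of the exposure sign in a single row identifies that covariate as the
#' confounder responsible for a crude-vs-adjusted sign flip.
#'
#' @inheritParams glm_fit
#' @return Object of class `sensitivity_table`: data frame with one row per
#'   excluded covariate (`excluded`, `estimate`, `se`, `ci_low`, `ci_high`,
#'   `p`, `n`), plus the full-model row in attribute `"full"`.
#' @export
sensitivity_loo <- function(data, outcome, exposure,
                            covariates = default_covariates()) {
  if (length(covariates) < 2L) {
    stop("sensitivity_loo: need >= 2 covariates", call. = FALSE)
  }
  full <- glm_fit(data, outcome, exposure, covariates)
  rows <- lapply(covariates, function(cv) {
    f <- glm_fit(data, outcome, exposure, setdiff(covariates, cv))
    cbind(excluded = cv, term_row(f)[-1], n = f$n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "full") <- cbind(excluded = "(none)", term_row(full)[-1],
                             n = full$n)
  class(out) <- c("sensitivity_table", "data.frame")
  out
}

#' Effect-modification (interaction) and subgroup analysis
#'
#' Tests whether a modifier changes the exposure-outcome association: the
#' interaction p-value is the Wald test of the exposure x modifier product
#' term in the pooled model, and per-stratum exposure effects are estimated
#' both unadjusted and covariate-adjusted (the modifier is removed from its
#' own strata's covariate sets).
#'
#' @inheritParams glm_fit
#' @param modifier Column name of the modifier; continuous modifiers are
#'   binarized with [median_split()], two-level factors/characters are used
#'   as given.
#' @return Object of class `subgroup_result`: list with `modifier`,
#'   `p_interaction` (unadjusted and adjusted), `strata` (data frame of
#'   per-stratum exposure estimates), and the stratum sizes.
#' @export
subgroup_interaction <- function(data, outcome, exposure, modifier,
                                 covariates = default_covariates()) {
  df <- as.data.frame(data)
  mv <- df[[modifier]]
  if (is.numeric(mv) && length(unique(stats::na.omit(mv))) > 2L) {
    grp <- median_split(mv)
  } else {
    grp <- factor(mv)
    if (nlevels(grp) != 2L) {
      stop("subgroup_interaction: modifier must have exactly 2 levels",
           call. = FALSE)
    }
  }
  df$.modifier_group <- grp
  covs <- setdiff(covariates, modifier)

  p_int <- function(adjust) {
    rhs <- c(exposure, ".modifier_group",
             sprintf("%s:.modifier_group", exposure), if (adjust) covs)
    fit <- glm_fit_formula(df, outcome, rhs)
    pterm <- grep(":", fit$terms$term, fixed = TRUE, value = TRUE)
    fit$terms$p[fit$terms$term == pterm[1]]
  }

  strata <- list()
  for (lev in levels(grp)) {
    sub <- df[df$.modifier_group == lev & !is.na(df$.modifier_group), ,
              drop = FALSE]
    for (adj in c(FALSE, TRUE)) {
      cvs <- if (adj) covs else character()
      need <- length(cvs) + 4L
      if (nrow(sub) < need) {
        stop("subgroup_interaction: stratum '", lev, "' has too few ",
             "participants (", nrow(sub), ")", call. = FALSE)
      }
      f <- glm_fit(sub, outcome, exposure, cvs)
      strata[[length(strata) + 1L]] <-
        cbind(stratum = lev, adjusted = adj, term_row(f)[-1], n = f$n)
    }
  }
  strata <- do.call(rbind, strata)
  rownames(strata) <- NULL
  out <- list(outcome = outcome, exposure = exposure, modifier = modifier,
              split_median = attr(grp, "median"),
              p_interaction = c(unadjusted = p_int(FALSE),
                                adjusted = p_int(TRUE)),
              strata = strata,
              stratum_n = table(grp))
  class(out) <- "subgroup_result"
  out
}

# glm_fit over an arbitrary right-hand side (used for interaction models)
glm_fit_formula <- function(df, outcome, rhs) {
  df <- prepare_model_data(df)
  vars <- unique(c(outcome, unlist(strsplit(rhs, ":", fixed = TRUE))))
  df <- df[stats::complete.cases(df[vars]), , drop = FALSE]
  form <- stats::reformulate(rhs, response = outcome)
  fit <- stats::glm(form, family = stats::gaussian(), data = df)
  wald_terms(fit, outcome, rhs[1], rhs[-1], nrow(df))
}

#' @export
print.subgroup_result <- function(x, ...) {
  cat(sprintf("<subgroup_result> %s ~ %s, modified by %s (split at %s)\n",
              x$outcome, x$exposure, x$modifier,
              format(x$split_median)))
  cat(sprintf("  p for interaction: unadjusted %.3g, adjusted %.3g\n",
              x$p_interaction[["unadjusted"]],
              x$p_interaction[["adjusted"]]))
  print(format(x$strata, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Four-group comparison by age and lifestyle-OBS median splits
#'
#' Classifies participants into the four combinations of low/high age and
#' low/high lifestyle OBS (group 1: low age + low OBS, 2: low age + high
#' OBS, 3: high age + low OBS, 4: high age + high OBS), summarises each BMD
#' outcome per group, and compares groups with an omnibus Kruskal-Wallis
#' test plus pairwise Mann-Whitney tests, Bonferroni-corrected over the six
#' pairs.
#'
#' @param data Analysis data frame containing `age`, `lifestyle_obs`, and
#'   the outcomes.
#' @param outcomes Character vector of outcome columns.
#' @return Object of class `combined_groups`: list with `groups` (per
#'   participant), `summary` (per group x outcome median/IQR), `omnibus_p`
#'   per outcome, and `pairwise` (data frame of corrected p-values).
#' @export
combined_groups <- function(data, outcomes = bmd_outcomes()) {
  df <- as.data.frame(data)
  stopifnot(all(c("age", "lifestyle_obs") %in% names(df)))
  age_g <- median_split(df$age)
  obs_g <- median_split(df$lifestyle_obs)
  grp <- factor(paste0("age_", age_g, ".obs_", obs_g),
                levels = c("age_low.obs_low", "age_low.obs_high",
                           "age_high.obs_low", "age_high.obs_high"))
  if (any(table(grp) == 0L)) {
    stop("combined_groups: empty cell(s): ",
         paste(names(which(table(grp) == 0L)), collapse = ", "),
         call. = FALSE)
  }
  summ <- do.call(rbind, lapply(outcomes, function(oc) {
    do.call(rbind, lapply(levels(grp), function(g) {
      v <- df[[oc]][grp == g]
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7,
                           names = FALSE)
      data.frame(outcome = oc, group = g, n = sum(grp == g),
                 median = q[2], q1 = q[1], q3 = q[3], mean = mean(v,
                 na.rm = TRUE), stringsAsFactors = FALSE)
    }))
  }))
  omnibus <- vapply(outcomes, function(oc) {
    v <- df[[oc]]
    if (stats::var(v, na.rm = TRUE) == 0) return(1)
    stats::kruskal.test(v ~ grp)$p.value
  }, numeric(1))
  pairs <- utils::combn(levels(grp), 2)
  pairwise <- do.call(rbind, lapply(outcomes, function(oc) {
    p <- apply(pairs, 2, function(pr) {
      a <- df[[oc]][grp == pr[1]]
      b <- df[[oc]][grp == pr[2]]
      if (stats::var(c(a, b), na.rm = TRUE) == 0) return(1)
      stats::wilcox.test(a, b, exact = FALSE)$p.value
    })
    data.frame(outcome = oc, group1 = pairs[1, ], group2 = pairs[2, ],
               p_raw = p, p_bonferroni = pmin(p * ncol(pairs), 1),
               stringsAsFactors = FALSE)
  }))
  out <- list(groups = grp, age_median = attr(age_g, "median"),
              obs_median = attr(obs_g, "median"), summary = summ,
              omnibus_p = omnibus, pairwise = pairwise)
  class(out) <- "combined_groups"
  out
}

#' @export
print.combined_groups <- function(x, ...) {
  cat(sprintf("<combined_groups> age split at %s, lifestyle OBS split at %s\n",
              format(x$age_median), format(x$obs_median)))
  print(format(x$summary, digits = 3), row.names = FALSE)
  cat("omnibus Kruskal-Wallis p:\n")
  print(signif(x$omnibus_p, 3))
  invisible(x)
}

#' Lifestyle-OBS group by gender interaction model
#'
#' Fits `outcome ~ obs_group + gender + obs_group:gender (+ covariates)`
#' with the lifestyle OBS binarized at its median. Reference levels (low
#' OBS, male) are coded to zero, so the reported coefficients are the
#' high-OBS effect in males, the female effect in the low-OBS group, and
#' their interaction. The Gaussian scale (residual variance) is reported by
#' maximum likelihood.
#'
#' @param data Analysis data frame containing `lifestyle_obs` and `gender`.
#' @param outcome Outcome column name.
#' @param covariates Additional covariates (gender is removed from this set
#'   automatically).
#' @return A `glm_fit` with extra fields `scale_ml` (RSS/n) and
#'   `scale_ci` (95% chi-square interval).
#' @export
gender_interaction_model <- function(data, outcome,
                                     covariates = character()) {
  df <- as.data.frame(data)
  stopifnot(all(c("lifestyle_obs", "gender") %in% names(df)))
  df$obs_group <- median_split(df$lifestyle_obs)
  covs <- setdiff(covariates, "gender")
  rhs <- c("obs_group", "gender", "obs_group:gender", covs)
  fit <- glm_fit_formula(df, outcome, rhs)
  n <- fit$n
  rss <- sum(stats::residuals(fit$model)^2)
  fit$scale_ml <- rss / n
  fit$scale_ci <- c(rss / stats::qchisq(0.975, n - 1),
                    rss / stats::qchisq(0.025, n - 1))
  fit
}
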