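#' Baseline / group-comparison descriptive table
#'
#' Summarises variables by a grouping column with the study's test-selection
#' logic: categorical variables are reported as counts and percentages and
#' compared with the chi-square test (no continuity correction); continuous
#' variables are tested for normality (Shapiro-Wilk at alpha = 0.05 in every
#' group — any rejection selects the nonparametric branch) and reported as
#' mean (SD) with a t-test when normal, otherwise as median \[Q1, Q3\] with a
#' Mann-Whitney U test (two groups) or Kruskal-Wallis test (more than two).
#' Percentages use the group sizes as denominators; quantiles use linear
#' interpolation.
#'
#' @param data Data frame (e.g. a [cohort_table()] or [analysis_table()]).
#' @param group_by Name of the grouping column (>= 2 levels), or `NULL` for
#'   a single overall column.
#' @param variables Character vector of variables to summarise.
#' @param shapiro_alpha Normality-test level; rejection in any group selects
#'   the nonparametric branch (0 forces the parametric branch, values above
#'   1 force the nonparametric one).
#' @return Object of class `group_summary`: data frame with one row per
#'   continuous variable or per categorical level, columns `variable`,
#'   `level`, `kind` (`mean_sd`, `median_iqr`, `count_pct`), one
#'   `<group>` column per group (formatted summary), numeric companions in
#'   `stat_<group>` list-columns, `test`, `p_value`.
#' @export
summarize_cohort <- function(data, group_by = NULL, variables,
                             shapiro_alpha = 0.05) {
  df <- as.data.frame(data)
  absent <- setdiff(c(variables, group_by), names(df))
  if (length(absent)) {
    stop("summarize_cohort: variable(s) not found: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  grp <- if (is.null(group_by)) factor(rep("overall", nrow(df)))
         else factor(df[[group_by]])
  grp <- droplevels(grp)
  if (!is.null(group_by) && nlevels(grp) < 2L) {
    stop("summarize_cohort: grouping column must have >= 2 levels",
         call. = FALSE)
  }
  rows <- lapply(variables, function(v) {
    summarize_one(df[[v]], grp, v, shapiro_alpha,
                  n_groups = nlevels(grp))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("group_summary", "data.frame")
  out
}

summarize_one <- function(x, grp, name, alpha, n_groups) {
  categorical <- is.character(x) || is.factor(x) || is.logical(x)
  levs <- levels(grp)
  two_groups <- n_groups == 2L
  if (categorical) {
    x <- if (is.logical(x)) factor(ifelse(x, "yes", "no"),
                                   levels = c("no", "yes"))
         else factor(x)
    tab <- table(x, grp)
    p <- if (n_groups < 2L) NA_real_
         else if (stats::var(as.numeric(x), na.rm = TRUE) == 0 ||
                  nrow(tab) < 2L) 1
         else suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    out <- data.frame(variable = name, level = rownames(tab),
                      kind = "count_pct", stringsAsFactors = FALSE)
    for (g in levs) {
      cnt <- tab[, g]
      pct <- 100 * cnt / sum(cnt)
      out[[g]] <- sprintf("%d (%.3f)", cnt, pct)
      out[[paste0("n_", g)]] <- as.integer(cnt)
      out[[paste0("pct_", g)]] <- as.numeric(pct)
    }
    out$test <- "chi_square"
    out$p_value <- p
    return(out)
  }

  groups <- split(x, grp)
  vx <- stats::var(x, na.rm = TRUE)
  if (is.na(vx) || vx == 0) {
    normal <- TRUE
    p <- if (n_groups < 2L) NA_real_ else 1
    test <- if (n_groups < 2L) "none" else "t_test"
  } else if (n_groups < 2L) {
    normal <- all(vapply(groups, function(g) {
      g <- g[!is.na(g)]
      if (length(g) < 3L || stats::var(g) == 0) return(FALSE)
      n <- length(g)
      if (n > 5000L) g <- g[round(seq(1, n, length.out = 5000L))]
      stats::shapiro.test(g)$p.value >= alpha
    }, logical(1)))
    p <- NA_real_
    test <- "none"
  } else {
    normal <- all(vapply(groups, function(g) {
      g <- g[!is.na(g)]
      if (length(g) < 3L || stats::var(g) == 0) return(FALSE)
      n <- length(g)
      if (n > 5000L) g <- g[round(seq(1, n, length.out = 5000L))]
      stats::shapiro.test(g)$p.value >= alpha
    }, logical(1)))
    if (normal) {
      test <- "t_test"
      p <- if (two_groups) stats::t.test(x ~ grp)$p.value
           else summary(stats::aov(x ~ grp))[[1]][["Pr(>F)"]][1]
      if (!two_groups) test <- "anova"
    } else if (two_groups) {
      test <- "mann_whitney"
      p <- suppressWarnings(stats::wilcox.test(x ~ grp, exact = FALSE)$p.value)
    } else {
      test <- "kruskal_wallis"
      p <- stats::kruskal.test(x ~ grp)$p.value
    }
  }
  out <- data.frame(variable = name, level = NA_character_,
                    kind = if (normal) "mean_sd" else "median_iqr",
                    stringsAsFactors = FALSE)
  for (g in levels(grp)) {
    v <- groups[[g]]
    if (normal) {
      out[[g]] <- sprintf("%.3f (±%.3f)", mean(v, na.rm = TRUE),
                          stats::sd(v, na.rm = TRUE))
      out[[paste0("n_", g)]] <- sum(!is.na(v))
      out[[paste0("pct_", g)]] <- NA_real_
    } else {
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7,
                           names = FALSE)
      out[[g]] <- sprintf("%.3f [%.3f, %.3f]", q[2], q[1], q[3])
      out[[paste0("n_", g)]] <- sum(!is.na(v))
      out[[paste0("pct_", g)]] <- NA_real_
    }
  }
  out$test <- test
  out$p_value <- p
  out
}

#' Count and percentage of a planted two-level split
#'
#' Helper reproducing the `n (pct)` presentation used in the descriptive
#' tables: percentages are computed against the group total and printed to
#' three decimals.
#'
#' @param n Count in the category.
#' @param total Group size.
#' @return Numeric percentage (0-100).
#' @export
count_pct <- function(n, total) {
  stopifnot(total > 0, n >= 0, n <= total)
  100 * n / total
}

#' Share of participants engaging in active physical activity
#'
#' A participant is active when their weekly MET total reaches
#' [met_active_threshold] (2880 MET-min/week). Counts and percentages are
#' reported per group.
#'
#' @param data Data frame carrying a `met_total` column (e.g.
#'   [analysis_table()]) or an `obs_result`.
#' @param group Optional factor/vector of group labels (same length as rows
#'   of `data`); `NULL` summarises the whole sample.
#' @param threshold MET-min/week cutoff.
#' @return Data frame: `group`, `n`, `n_active`, `pct_active`.
#' @export
active_pa_share <- function(data, group = NULL,
                            threshold = met_active_threshold) {
  df <- as.data.frame(data)
  stopifnot("met_total" %in% names(df))
  grp <- if (is.null(group)) factor(rep("overall", nrow(df)))
         else factor(group)
  active <- df$met_total >= threshold
  out <- do.call(rbind, lapply(levels(grp), function(g) {
    sel <- grp == g
    data.frame(group = g, n = sum(sel), n_active = sum(active[sel]),
               pct_active = count_pct(sum(active[sel]), sum(sel)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
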