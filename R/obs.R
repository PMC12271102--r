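#' MET-min/week threshold for "active" physical activity
#'
#' Participants at or above 2880 MET-min/week are classified as engaging in
#' active physical activity in group descriptives.
#'
#' @export
met_active_threshold <- 2880

#' Default MET multipliers per activity class
#'
#' MET values assigned to the activity classes entering the weekly MET score.
#' Both transportation (walking/bicycling) and moderate-intensity activity
#' default to 4.0, the GPAQ convention for these classes; override by passing
#' an edited named vector to [compute_met()] / [compute_obs()].
#'
#' @return Named numeric vector of MET multipliers.
#' @export
default_met_values <- function() c(transport = 4.0, moderate = 4.0)

#' The OBS component registry
#'
#' Loads the declarative definition of the 20 oxidative-balance-score
#' components (16 dietary + 4 lifestyle) from a structured config file. Each
#' row gives the component `name`, its `klass` (dietary/lifestyle), its
#' `direction` (antioxidant or pro-oxidant), and its scoring `rule`
#' (`gender_tertile`, `met_then_tertile`, or `alcohol_category`). The
#' pro-oxidant set is exactly total fat, iron, BMI, alcohol, and smoking
#' exposure measured as serum cotinine; all other components are antioxidant.
#'
#' @param path Path to a registry CSV; default is the shipped registry.
#' @return Data frame of class `obs_registry`.
#' @export
component_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "obs_components.csv", package = "obsbmd")
  }
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_registry(reg)
}

validate_registry <- function(reg) {
  stopifnot(all(c("name", "klass", "direction", "rule") %in% names(reg)))
  expected <- c(dietary_components(), lifestyle_components())
  missing <- setdiff(expected, reg$name)
  extra <- setdiff(reg$name, expected)
  if (length(missing) || length(extra) || nrow(reg) != 20L) {
    stop("OBS registry configuration error: registry must define exactly the ",
         "20 default components; missing: {",
         paste(missing, collapse = ", "), "}, unexpected: {",
         paste(extra, collapse = ", "), "}", call. = FALSE)
  }
  if (!all(reg$direction %in% c("antioxidant", "pro-oxidant"))) {
    stop("OBS registry configuration error: direction must be ",
         "'antioxidant' or 'pro-oxidant'", call. = FALSE)
  }
  pro <- sort(reg$name[reg$direction == "pro-oxidant"])
  if (!identical(pro, sort(c("total_fat", "iron", "bmi", "alcohol",
                             "cotinine")))) {
    stop("OBS registry configuration error: pro-oxidant set must be exactly ",
         "{total_fat, iron, bmi, alcohol, cotinine}", call. = FALSE)
  }
  if (!all(reg$rule %in% c("gender_tertile", "met_then_tertile",
                           "alcohol_category"))) {
    stop("OBS registry configuration error: unknown scoring rule(s): ",
         paste(setdiff(reg$rule, c("gender_tertile", "met_then_tertile",
                                   "alcohol_category")), collapse = ", "),
         call. = FALSE)
  }
  class(reg) <- c("obs_registry", "data.frame")
  reg
}

#' Weekly MET score from physical-activity records
#'
#' MET score = sum over activity records of weekly frequency x duration per
#' session x the MET value assigned to the activity class. An empty record
#' set scores 0.
#'
#' @param records Data frame with columns `activity_class`, `sessions`
#'   (per week), `minutes` (per session), and optionally `participant_id`.
#' @param met_values Named numeric vector of MET multipliers per activity
#'   class; see [default_met_values()].
#' @return If `records` has a `participant_id` column, a data frame with
#'   `participant_id` and `met_total` (one row per participant, input order
#'   of first appearance); otherwise a single MET-min/week total.
#' @export
compute_met <- function(records, met_values = default_met_values()) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    if ("participant_id" %in% names(records)) {
      return(data.frame(participant_id = character(0), met_total = numeric(0)))
    }
    return(0)
  }
  stopifnot(all(c("activity_class", "sessions", "minutes") %in% names(records)))
  unknown <- setdiff(unique(records$activity_class), names(met_values))
  if (length(unknown)) {
    stop("compute_met: unknown activity class(es): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(records$sessions < 0 | records$minutes < 0, na.rm = TRUE)) {
    stop("compute_met: frequencies and durations must be >= 0", call. = FALSE)
  }
  contrib <- records$sessions * records$minutes *
    met_values[records$activity_class]
  if ("participant_id" %in% names(records)) {
    ids <- unique(records$participant_id)
    tot <- vapply(split(contrib, factor(records$participant_id, levels = ids)),
                  sum, numeric(1))
    return(data.frame(participant_id = ids, met_total = unname(tot),
                      stringsAsFactors = FALSE))
  }
  sum(contrib)
}

#' Alcohol component score
#'
#' Heavy drinkers (>= 15 g/day for females, >= 30 g/day for males) score 0,
#' non-heavy drinkers (above zero but below the gender threshold) score 1,
#' and non-drinkers (exactly 0 g/day) score 2.
#'
#' @param alcohol Numeric vector of intakes in g/day.
#' @param gender Character vector, `"male"`/`"female"`, recycled if length 1.
#' @return Integer vector of scores in \{0, 1, 2\}.
#' @export
score_alcohol <- function(alcohol, gender) {
  if (length(gender) == 1L) gender <- rep(gender, length(alcohol))
  stopifnot(length(alcohol) == length(gender),
            all(gender %in% c("male", "female")))
  if (any(alcohol < 0, na.rm = TRUE)) {
    stop("score_alcohol: alcohol intake must be >= 0", call. = FALSE)
  }
  thr <- ifelse(gender == "female", 15, 30)
  out <- ifelse(alcohol == 0, 2L, ifelse(alcohol >= thr, 0L, 1L))
  as.integer(out)
}

#' Gender-stratified tertile scores for one OBS component
#'
#' Within each gender stratum, cutpoints are the 1/3 and 2/3 sample quantiles
#' (linear interpolation, [stats::quantile()] type 7) of the analysis sample.
#' A value at or below a cutpoint falls in the lower tertile, so ties that
#' straddle a cutpoint all receive the lower tertile's score. Antioxidant
#' components score lowest-to-highest tertile 0, 1, 2; pro-oxidant components
#' score in the reverse order. A stratum whose values are all identical
#' cannot be split: every member scores 1 (the middle mass) with a warning.
#'
#' @param values Numeric component values, one per participant.
#' @param gender Character vector of `"male"`/`"female"` labels.
#' @param direction `"antioxidant"` or `"pro-oxidant"`.
#' @return Integer vector of scores in \{0, 1, 2\}.
#' @export
gender_tertile_scores <- function(values, gender,
                                  direction = c("antioxidant", "pro-oxidant")) {
  direction <- match.arg(direction)
  stopifnot(length(values) == length(gender),
            all(gender %in% c("male", "female")))
  out <- integer(length(values))
  for (g in unique(gender)) {
    idx <- which(gender == g)
    v <- values[idx]
    if (length(v) < 3L) {
      stop("gender_tertile_scores: need >= 3 participants per gender ",
           "stratum (", g, " has ", length(v), ")", call. = FALSE)
    }
    if (length(unique(v)) == 1L) {
      warning("gender_tertile_scores: all values identical in stratum '", g,
              "'; assigning middle score 1 to the whole stratum",
              call. = FALSE)
      out[idx] <- 1L
      next
    }
    cuts <- stats::quantile(v, probs = c(1, 2) / 3, type = 7, names = FALSE)
    tert <- ifelse(v <= cuts[1], 0L, ifelse(v <= cuts[2], 1L, 2L))
    out[idx] <- if (direction == "antioxidant") tert else 2L - tert
  }
  as.integer(out)
}

#' Compute the oxidative balance score
#'
#' Scores all 20 components for every participant of a (post-exclusion)
#' cohort and sums them into the lifestyle OBS (0-8: BMI, cotinine, physical
#' activity, alcohol), dietary OBS (0-32: the 16 nutrients), and total OBS
#' (0-40). Tertile cutpoints are computed per gender on the supplied analysis
#' sample.
#'
#' @param table A [cohort_table()] that has passed [apply_exclusions()]
#'   (component values must be complete).
#' @param registry Component registry; see [component_registry()].
#' @param met_values MET multipliers; see [default_met_values()].
#' @return Data frame of class `obs_result`: `participant_id`, `met_total`,
#'   one `score_<component>` column per component, `lifestyle_obs`,
#'   `dietary_obs`, `total_obs`.
#' @export
compute_obs <- function(table, registry = component_registry(),
                        met_values = default_met_values()) {
  stopifnot(inherits(table, "cohort_table"))
  registry <- validate_registry(as.data.frame(registry))
  comp_cols <- c(dietary_components(), "bmi", "cotinine", "alcohol",
                 pa_columns())
  if (anyNA(table[comp_cols])) {
    stop("compute_obs: component values contain missing entries; run ",
         "apply_exclusions() first", call. = FALSE)
  }

  met <- compute_met(pa_records(table), met_values)
  met_total <- met$met_total[match(table$participant_id, met$participant_id)]

  scores <- matrix(NA_integer_, nrow = nrow(table), ncol = nrow(registry),
                   dimnames = list(NULL, registry$name))
  for (i in seq_len(nrow(registry))) {
    spec <- registry[i, ]
    scores[, spec$name] <- switch(spec$rule,
      gender_tertile = gender_tertile_scores(table[[spec$name]], table$gender,
                                             spec$direction),
      met_then_tertile = gender_tertile_scores(met_total, table$gender,
                                               spec$direction),
      alcohol_category = score_alcohol(table$alcohol, table$gender)
    )
  }

  lifestyle <- rowSums(scores[, lifestyle_components(), drop = FALSE])
  dietary <- rowSums(scores[, dietary_components(), drop = FALSE])
  out <- data.frame(participant_id = table$participant_id,
                    met_total = met_total,
                    stringsAsFactors = FALSE)
  score_df <- as.data.frame(scores)
  names(score_df) <- paste0("score_", names(score_df))
  out <- cbind(out, score_df)
  out$lifestyle_obs <- as.integer(lifestyle)
  out$dietary_obs <- as.integer(dietary)
  out$total_obs <- as.integer(lifestyle + dietary)
  class(out) <- c("obs_result", "data.frame")
  out
}

#' Median split into low/high groups
#'
#' Values at or below the sample median are labelled low, values above it
#' high, matching the "<= 13 years" and "<= 5" group conventions used in the
#' age and lifestyle-OBS splits.
#'
#' @param x Numeric vector (>= 2 values).
#' @param labels Two labels, low then high.
#' @return Factor of group labels with attribute `"median"`.
#' @export
median_split <- function(x, labels = c("low", "high")) {
  stopifnot(length(x) >= 2L, length(labels) == 2L)
  m <- stats::median(x, na.rm = TRUE)
  f <- factor(ifelse(x <= m, labels[1], labels[2]), levels = labels)
  attr(f, "median") <- m
  f
}

#' Merge cohort and OBS results into one analysis table
#'
#' @param table A [cohort_table()].
#' @param obs An `obs_result` from [compute_obs()].
#' @return Data frame with the cohort columns plus `met_total`,
#'   `lifestyle_obs`, `dietary_obs`, `total_obs`.
#' @export
analysis_table <- function(table, obs) {
  stopifnot(inherits(table, "cohort_table"), inherits(obs, "obs_result"))
  keep <- c("participant_id", "met_total", "lifestyle_obs", "dietary_obs",
            "total_obs")
  merged <- merge(as.data.frame(table), as.data.frame(obs)[keep],
                  by = "participant_id", sort = FALSE)
  merged[match(table$participant_id, merged$participant_id), , drop = FALSE]
}

#' @export
print.obs_result <- function(x, ...) {
  cat(sprintf("<obs_result> %d participants\n", nrow(x)))
  cat(sprintf("  lifestyle OBS: median %s [range %s-%s]\n",
              format(stats::median(x$lifestyle_obs)),
              min(x$lifestyle_obs), max(x$lifestyle_obs)))
  cat(sprintf("  dietary OBS:   median %s [range %s-%s]\n",
              format(stats::median(x$dietary_obs)),
              min(x$dietary_obs), max(x$dietary_obs)))
  cat(sprintf("  total OBS:     median %s [range %s-%s]\n",
              format(stats::median(x$total_obs)),
              min(x$total_obs), max(x$total_obs)))
  invisible(x)
}
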