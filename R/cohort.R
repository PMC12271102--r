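#' Column groups of a cohort table
#'
#' The participant-level cohort schema used throughout the package: NHANES-like
#' demographics, 16 dietary nutrient intakes from 24-h recall, 4 lifestyle
#' exposures (BMI, serum cotinine, alcohol, physical activity), 4
#' oxidative-stress biomarkers, and 3 DXA bone-mineral-density outcomes.
#'
#' Physical activity is stored wide, as weekly session counts and
#' minutes-per-session for the two activity classes that enter the MET
#' computation (transportation and moderate-intensity activity); see
#' [pa_records()] for the long form.
#'
#' @return Character vector of column names.
#' @export
dietary_components <- function() {
  c("fiber", "total_fat", "carotene", "riboflavin", "niacin", "vitamin_b6",
    "total_folate", "vitamin_b12", "vitamin_c", "vitamin_e", "calcium",
    "magnesium", "iron", "zinc", "copper", "selenium")
}

#' @rdname dietary_components
#' @export
lifestyle_components <- function() c("bmi", "cotinine", "pa", "alcohol")

#' @rdname dietary_components
#' @export
bmd_outcomes <- function() c("bmd_lumbar", "bmd_pelvis", "bmd_total")

#' @rdname dietary_components
#' @export
oxidative_biomarkers <- function() c("albumin", "vitd_25oh", "uric_acid", "ggt")

pa_columns <- function() {
  c("pa_transport_sessions", "pa_transport_minutes",
    "pa_moderate_sessions", "pa_moderate_minutes")
}

demographic_columns <- function() {
  c("age", "gender", "race", "education", "family_pir", "stimulant_use")
}

cohort_columns <- function() {
  c("participant_id", demographic_columns(), dietary_components(),
    "bmi", "cotinine", "alcohol", pa_columns(),
    oxidative_biomarkers(), bmd_outcomes())
}

nonneg_columns <- function() {
  c("family_pir", dietary_components(), "bmi", "cotinine", "alcohol",
    pa_columns(), oxidative_biomarkers(), bmd_outcomes())
}

#' Construct and validate a cohort table
#'
#' Validates a participant-level data frame against the cohort schema and
#' returns it classed as `cohort_table`. Missing values are represented as
#' `NA` (never zero); categorical fields must come from their closed sets.
#'
#' @param data A data frame carrying the full cohort schema (see
#'   [dietary_components()] and friends for the column groups).
#' @return A validated `cohort_table` (a data frame).
#' @export
cohort_table <- function(data) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)

  missing_cols <- setdiff(cohort_columns(), names(data))
  if (length(missing_cols)) {
    stop("cohort schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  if (anyDuplicated(data$participant_id)) {
    dup <- unique(data$participant_id[duplicated(data$participant_id)])
    stop("cohort validation error: duplicate participant_id: ",
         paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
  }

  data$participant_id <- as.character(data$participant_id)
  check_level <- function(x, levels, what) {
    bad <- !is.na(x) & !(x %in% levels)
    if (any(bad)) {
      stop("cohort validation error: ", what, " must be one of {",
           paste(levels, collapse = ", "), "}; found: ",
           paste(unique(x[bad]), collapse = ", "), call. = FALSE)
    }
    x
  }
  data$gender <- check_level(as.character(data$gender),
                             c("male", "female"), "gender")
  data$race <- check_level(as.character(data$race),
                           c("Hispanic", "non-Hispanic"), "race")
  data$education <- check_level(as.character(data$education),
                                c("<9th grade", ">=9th grade"), "education")
  data$stimulant_use <- as.logical(data$stimulant_use)

  num_cols <- setdiff(cohort_columns(),
                      c("participant_id", "gender", "race", "education",
                        "stimulant_use"))
  for (cl in num_cols) data[[cl]] <- as.numeric(data[[cl]])

  for (cl in nonneg_columns()) {
    bad <- !is.na(data[[cl]]) & data[[cl]] < 0
    if (any(bad)) {
      stop("cohort validation error: negative values in column '", cl, "'",
           call. = FALSE)
    }
  }

  class(data) <- c("cohort_table", "data.frame")
  data
}

#' Read a cohort table from disk
#'
#' Reads a delimiter-separated text file (or a SAS XPORT transport file when
#' `format = "xpt"`), optionally renames columns through a schema map, coerces
#' columns to the schema types, and validates the result. Rows whose values
#' fail numeric coercion are retained with `NA` in the offending cells and
#' reported through a warning and the `"coercion_report"` attribute — they are
#' never silently dropped.
#'
#' @param path Path to the input file.
#' @param schema Optional named character vector mapping canonical column
#'   names (names) to source column names (values), e.g. as returned by
#'   [read_schema()] for the shipped NHANES variable map. `NULL` means the
#'   file already uses canonical names.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"`, or `"xpt"`
#'   (SAS XPORT, read via [foreign::read.xport()]).
#' @param na Strings treated as missing in text files.
#' @return A validated [cohort_table()], with attribute `coercion_report`
#'   (a named integer vector of coercion failures per column, if any).
#' @export
read_cohort <- function(path, schema = NULL,
                        format = c("auto", "csv", "tsv", "xpt"),
                        na = c("", "NA", ".")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, tsv = "tsv", txt = "tsv", xpt = "xpt", "csv")
  }
  raw <- switch(format,
    csv = utils::read.csv(path, na.strings = na, stringsAsFactors = FALSE,
                          check.names = FALSE),
    tsv = utils::read.delim(path, na.strings = na, stringsAsFactors = FALSE,
                            check.names = FALSE),
    xpt = foreign::read.xport(path)
  )
  raw <- apply_schema(raw, schema)
  coerce_cohort(raw)
}

#' @rdname read_cohort
#' @param data A data frame already in memory (e.g. from a SAS import) to be
#'   mapped and validated the same way as a file read by [read_cohort()].
#' @export
as_cohort_table <- function(data, schema = NULL) {
  coerce_cohort(apply_schema(data, schema))
}

apply_schema <- function(data, schema) {
  if (is.null(schema)) return(data)
  stopifnot(is.character(schema), !is.null(names(schema)))
  missing_src <- setdiff(unname(schema), names(data))
  if (length(missing_src)) {
    stop("cohort schema error: missing mandatory column(s): ",
         paste(names(schema)[match(missing_src, schema)], collapse = ", "),
         " (source: ", paste(missing_src, collapse = ", "), ")",
         call. = FALSE)
  }
  idx <- match(unname(schema), names(data))
  out <- data[idx]
  names(out) <- names(schema)
  out
}

coerce_cohort <- function(raw) {
  missing_cols <- setdiff(cohort_columns(), names(raw))
  if (length(missing_cols)) {
    stop("cohort schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num_cols <- setdiff(cohort_columns(),
                      c("participant_id", "gender", "race", "education",
                        "stimulant_use"))
  report <- integer(0)
  for (cl in num_cols) {
    before <- is.na(raw[[cl]])
    raw[[cl]] <- suppressWarnings(as.numeric(raw[[cl]]))
    failed <- sum(is.na(raw[[cl]]) & !before)
    if (failed > 0L) report[cl] <- failed
  }
  tab <- cohort_table(raw)
  if (length(report)) {
    warning("type coercion failed for ", sum(report), " cell(s) in column(s): ",
            paste(names(report), collapse = ", "),
            "; affected cells set to NA (rows retained)", call. = FALSE)
    attr(tab, "coercion_report") <- report
  }
  tab
}

#' Read a column-name schema map
#'
#' Reads a two-column CSV (`canonical`, `source`) into the named-vector form
#' expected by [read_cohort()]. The package ships an editable map from the
#' canonical schema to NHANES variable names at
#' `system.file("extdata", "nhanes_variable_map.csv", package = "obsbmd")`;
#' the core code never hardcodes NHANES names.
#'
#' @param path Path to the mapping CSV.
#' @return Named character vector (canonical name -> source name).
#' @export
read_schema <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("canonical", "source") %in% names(m)))
  stats::setNames(as.character(m$source), m$canonical)
}

#' Write a cohort table to disk
#'
#' @param table A [cohort_table()].
#' @param path Output path; `.tsv` extension selects tab delimiters.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  utils::write.table(as.data.frame(table), path, sep = sep,
                     row.names = FALSE, qmethod = "double", na = "")
  invisible(path)
}

#' Apply the study's sequential inclusion/exclusion criteria
#'
#' Filters a cohort to the analysis sample in the study's printed order:
#' (0) inclusion, age <= 18 years; (1) presence of all three BMD outcomes;
#' (2) presence of all 16 dietary OBS components; (3) presence of all four
#' lifestyle OBS components (BMI, cotinine, alcohol, and complete physical
#' activity records). Each criterion is applied to the survivors of the
#' previous one, so the tally is comparable to sequentially reported counts.
#'
#' @param table A [cohort_table()].
#' @return A list with elements `cohort` (the retained [cohort_table()]) and
#'   `tally` (data frame: `step`, `criterion`, `excluded`, `remaining`).
#' @export
apply_exclusions <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  df <- as.data.frame(table)
  steps <- list(
    age_over_18 = function(d) !is.na(d$age) & d$age <= 18,
    missing_bmd = function(d) stats::complete.cases(d[bmd_outcomes()]),
    missing_dietary = function(d) stats::complete.cases(d[dietary_components()]),
    missing_lifestyle = function(d)
      stats::complete.cases(d[c("bmi", "cotinine", "alcohol", pa_columns())])
  )
  tally <- data.frame(step = seq_along(steps),
                      criterion = names(steps),
                      excluded = NA_integer_,
                      remaining = NA_integer_)
  for (i in seq_along(steps)) {
    keep <- steps[[i]](df)
    tally$excluded[i] <- sum(!keep)
    df <- df[keep, , drop = FALSE]
    tally$remaining[i] <- nrow(df)
  }
  if (nrow(df) == 0L) {
    warning("apply_exclusions: no participants remain after exclusions",
            call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("cohort_table", "data.frame")
  list(cohort = df, tally = tally)
}

#' Physical-activity records in long form
#'
#' Converts the wide physical-activity columns into one row per participant
#' and activity class, the form consumed by [compute_met()].
#'
#' @param table A [cohort_table()].
#' @return Data frame with `participant_id`, `activity_class`
#'   (`"transport"` or `"moderate"`), `sessions` (per week), `minutes`
#'   (per session).
#' @export
pa_records <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  long <- rbind(
    data.frame(participant_id = table$participant_id,
               activity_class = "transport",
               sessions = table$pa_transport_sessions,
               minutes = table$pa_transport_minutes,
               stringsAsFactors = FALSE),
    data.frame(participant_id = table$participant_id,
               activity_class = "moderate",
               sessions = table$pa_moderate_sessions,
               minutes = table$pa_moderate_minutes,
               stringsAsFactors = FALSE)
  )
  long[order(match(long$participant_id, table$participant_id)), , drop = FALSE]
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d participants x %d variables\n",
              nrow(x), ncol(x)))
  if (nrow(x)) {
    cat(sprintf("  age: %s-%s y; gender: %d male / %d female\n",
                format(min(x$age, na.rm = TRUE)),
                format(max(x$age, na.rm = TRUE)),
                sum(x$gender == "male", na.rm = TRUE),
                sum(x$gender == "female", na.rm = TRUE)))
  }
  invisible(x)
}
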