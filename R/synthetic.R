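#' Configuration for the synthetic NHANES-like cohort generator
#'
#' Defines every planted quantity of the generator. The defaults describe the
#' study conditions the package's validation is run under: a cohort of 1196
#' children/adolescents aged 8-18, dietary intakes log-normal with a male
#' location shift, alcohol absent, zero-inflated physical activity and serum
#' cotinine both age-trending (which makes age a genuine confounder of the
#' lifestyle OBS-BMD relationship), an age-dependent lifestyle-OBS effect on
#' BMD that is positive at or below the age split and negative above it, and
#' partial mediation through uric acid and GGT (negative exposure-mediator
#' paths, positive mediator-outcome paths).
#'
#' @param n Number of complete analysis participants (>= 20).
#' @param seed Integer seed; the generator draws from a single stream in a
#'   fixed order, so equal configs give identical cohorts.
#' @param age_range Inclusive integer age range in years, within 0-18.
#' @param gender_balance Proportion male.
#' @param obs_effect_mode `"age_interaction"` (BMD slope on lifestyle OBS is
#'   `beta_young` for age <= `age_split`, `beta_old` above), `"breakpoint"`
#'   (continuous two-segment effect with knot `breakpoint_k`, slopes
#'   `slope_below`/`slope_above`), or `"none"`.
#' @param beta_young,beta_old g/cm^2 per lifestyle-OBS unit in the two age
#'   groups (age-interaction mode).
#' @param age_split Years; boundary between the two age groups.
#' @param breakpoint_k,slope_below,slope_above Breakpoint (OBS units) and
#'   segment slopes (g/cm^2 per OBS unit) for breakpoint mode.
#' @param mediation_a_uric,mediation_a_ggt,mediation_a_albumin
#'   Exposure-to-mediator path coefficients (mediator units per OBS unit).
#' @param mediation_b_uric,mediation_b_ggt,mediation_b_albumin
#'   Mediator-to-BMD path coefficients (g/cm^2 per mediator unit).
#' @param noise_sd_bmd Residual SD of BMD in g/cm^2.
#' @param age_bmd_slope BMD increase per year of age (g/cm^2).
#' @param cotinine_age_slope,pa_age_slope Log-scale/logit-scale age trends of
#'   cotinine and physical activity (per year, centred at 13 y); these carry
#'   the age-confounding of the lifestyle OBS.
#' @param noise_sd_uric,noise_sd_ggt,noise_sd_albumin Mediator residual SDs.
#' @param n_age_over,n_missing_bmd,n_missing_dietary,n_missing_lifestyle
#'   Planted invalid rows appended to the clean cohort (over-age; missing a
#'   BMD outcome; missing a dietary component; missing a lifestyle
#'   component), each designed to fail exactly one sequential exclusion step.
#' @return A validated `synthetic_config` list.
#' @seealso [generate_cohort()], [preset_paperlike()]
#' @export
synthetic_config <- function(n = 1196,
                             seed = 1L,
                             age_range = c(8L, 18L),
                             gender_balance = 0.516,
                             obs_effect_mode = c("age_interaction",
                                                 "breakpoint", "none"),
                             beta_young = 0.02,
                             beta_old = -0.035,
                             age_split = 13,
                             breakpoint_k = 4.6,
                             slope_below = -0.043,
                             slope_above = 0.066,
                             mediation_a_uric = -0.15,
                             mediation_b_uric = 0.02,
                             mediation_a_ggt = -0.8,
                             mediation_b_ggt = 0.0025,
                             mediation_a_albumin = 0.02,
                             mediation_b_albumin = 0,
                             noise_sd_bmd = 0.12,
                             age_bmd_slope = 0.03,
                             cotinine_age_slope = -0.18,
                             pa_age_slope = 0.25,
                             noise_sd_uric = 0.85,
                             noise_sd_ggt = 4,
                             noise_sd_albumin = 0.22,
                             n_age_over = 0L,
                             n_missing_bmd = 0L,
                             n_missing_dietary = 0L,
                             n_missing_lifestyle = 0L) {
  obs_effect_mode <- match.arg(obs_effect_mode)
  cfg <- list(n = as.integer(n), seed = as.integer(seed),
              age_range = as.integer(age_range),
              gender_balance = gender_balance,
              obs_effect_mode = obs_effect_mode,
              beta_young = beta_young, beta_old = beta_old,
              age_split = age_split,
              breakpoint_k = breakpoint_k, slope_below = slope_below,
              slope_above = slope_above,
              mediation_a_uric = mediation_a_uric,
              mediation_b_uric = mediation_b_uric,
              mediation_a_ggt = mediation_a_ggt,
              mediation_b_ggt = mediation_b_ggt,
              mediation_a_albumin = mediation_a_albumin,
              mediation_b_albumin = mediation_b_albumin,
              noise_sd_bmd = noise_sd_bmd, age_bmd_slope = age_bmd_slope,
              cotinine_age_slope = cotinine_age_slope,
              pa_age_slope = pa_age_slope,
              noise_sd_uric = noise_sd_uric, noise_sd_ggt = noise_sd_ggt,
              noise_sd_albumin = noise_sd_albumin,
              n_age_over = as.integer(n_age_over),
              n_missing_bmd = as.integer(n_missing_bmd),
              n_missing_dietary = as.integer(n_missing_dietary),
              n_missing_lifestyle = as.integer(n_missing_lifestyle))
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  if (cfg$n < 20L) {
    stop("synthetic_config: n must be >= 20", call. = FALSE)
  }
  if (length(cfg$age_range) != 2L || cfg$age_range[1] > cfg$age_range[2] ||
      cfg$age_range[1] < 0L || cfg$age_range[2] > 18L) {
    stop("synthetic_config: age_range must be within [0, 18]", call. = FALSE)
  }
  if (cfg$gender_balance <= 0 || cfg$gender_balance >= 1) {
    stop("synthetic_config: gender_balance must be in (0, 1)", call. = FALSE)
  }
  sds <- c(cfg$noise_sd_uric, cfg$noise_sd_ggt, cfg$noise_sd_albumin)
  if (any(sds <= 0) || cfg$noise_sd_bmd < 0) {
    stop("synthetic_config: mediator noise SDs must be > 0 and noise_sd_bmd ",
         ">= 0", call. = FALSE)
  }
  if (!cfg$obs_effect_mode %in% c("age_interaction", "breakpoint", "none")) {
    stop("synthetic_config: invalid obs_effect_mode", call. = FALSE)
  }
  if (cfg$obs_effect_mode == "breakpoint" &&
      (cfg$breakpoint_k <= 2 || cfg$breakpoint_k >= 8)) {
    stop("synthetic_config: configuration error - breakpoint mode needs ",
         "breakpoint_k strictly inside the attainable lifestyle OBS range ",
         "(2, 8)", call. = FALSE)
  }
  bad <- vapply(c("n_age_over", "n_missing_bmd", "n_missing_dietary",
                  "n_missing_lifestyle"),
                function(f) cfg[[f]] < 0L, logical(1))
  if (any(bad)) {
    stop("synthetic_config: planted exclusion counts must be >= 0",
         call. = FALSE)
  }
  class(cfg) <- "synthetic_config"
  cfg
}

#' Paper-magnitude preset configuration
#'
#' A documented convenience preset whose planted effects carry the signs and
#' orders of magnitude of the reported estimates: a positive lifestyle-OBS
#' effect on BMD in the young (`beta_young > 0`), a negative effect in the
#' old (`beta_old < 0`), age as the confounder that flips the crude positive
#' association negative after adjustment, and negative indirect effects
#' through uric acid and GGT of order -0.003 and -0.002 g/cm^2 per OBS unit.
#'
#' @param n Cohort size (default the analysis sample size, 1196).
#' @param seed Integer seed.
#' @param ... Overrides passed to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
preset_paperlike <- function(n = 1196, seed = 1L, ...) {
  synthetic_config(n = n, seed = seed, ...)
}

# Per-nutrient log-normal parameters for the 16 dietary intakes: location is
# the log overall median, male_shift is the male-female log-median gap
# (applied +/- half to each gender), spread is a common log-SD.
dietary_distribution <- function() {
  med <- c(fiber = 13.7, total_fat = 70.46, carotene = 49.708,
           riboflavin = 1.811, niacin = 21.138, vitamin_b6 = 1.646,
           total_folate = 342.5, vitamin_b12 = 4.22, vitamin_c = 56.7,
           vitamin_e = 6.66, calcium = 874.5, magnesium = 224.5,
           iron = 13.195, zinc = 9.405, copper = 0.868, selenium = 95.05)
  med_m <- c(14.55, 74.74, 50.375, 1.923, 23.943, 1.782, 375, 4.805, 58.6,
             7.075, 935.5, 236.5, 14.5, 10.485, 0.909, 105.9)
  med_f <- c(13.0, 65.6, 48.917, 1.695, 19.395, 1.505, 312.5, 3.7, 53.45,
             6.325, 809.5, 211.0, 11.785, 8.42, 0.815, 87.55)
  data.frame(name = names(med), meanlog = log(unname(med)),
             male_shift = log(med_m) - log(med_f), sdlog = 0.45,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic NHANES-like cohort
#'
#' Draws a cohort from the configured distributions in a single seeded
#' pseudo-random stream with a fixed draw order (demographics, dietary
#' intakes, lifestyle exposures, lifestyle-OBS scoring, mediators, BMD,
#' planted invalid rows, row shuffle), so identical configs yield identical
#' tables. BMD is built as baseline + age slope x age + the configured
#' lifestyle-OBS effect (age-conditional or two-segment) + mediator
#' contributions + Gaussian noise; mediators are linear in the realised
#' lifestyle OBS plus noise. Every planted coefficient is returned in the
#' ground-truth record.
#'
#' @param config A [synthetic_config()].
#' @return List with `cohort` (a [cohort_table()], including any planted
#'   invalid rows) and `truth` (list of planted parameters, the realised
#'   per-participant lifestyle OBS of the clean sample, and the planted
#'   exclusion counts).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  config <- validate_synthetic_config(unclass(config))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  n <- config$n
  age <- sample(seq(config$age_range[1], config$age_range[2]), n,
                replace = TRUE)
  gender <- ifelse(stats::runif(n) < config$gender_balance, "male", "female")
  race <- ifelse(stats::runif(n) < 0.359, "Hispanic", "non-Hispanic")
  # mild age link only: education must not proxy age, which is planted as
  # the sole sign-flipping confounder of the lifestyle OBS-BMD association
  education <- ifelse(stats::runif(n) < stats::plogis(0.35 * (age - 14)),
                      ">=9th grade", "<9th grade")
  family_pir <- pmin(stats::rlnorm(n, log(1.58), 0.86), 5)
  stim_p <- ifelse(gender == "male", 0.044, 0.012)
  stimulant_use <- stats::runif(n) < stim_p

  diet <- dietary_distribution()
  half <- ifelse(gender == "male", 0.5, -0.5)
  intake <- matrix(NA_real_, n, nrow(diet),
                   dimnames = list(NULL, diet$name))
  for (i in seq_len(nrow(diet))) {
    intake[, i] <- stats::rlnorm(n, diet$meanlog[i] +
                                   half * diet$male_shift[i], diet$sdlog[i])
  }

  bmi <- stats::rlnorm(n, log(21.4), 0.252)
  cotinine <- stats::rlnorm(n, log(0.03) +
                              config$cotinine_age_slope * (age - 13), 1.8)
  alcohol <- rep(0, n)  # absent in the whole study population

  p_tr <- stats::plogis(-0.3 + 0.4 * config$pa_age_slope * (age - 13))
  tr_any <- stats::runif(n) < p_tr
  pa_transport_sessions <- ifelse(tr_any, sample(1:7, n, replace = TRUE), 0)
  pa_transport_minutes <- ifelse(tr_any,
                                 round(stats::rlnorm(n, log(20), 0.6)), 0)
  p_mod <- stats::plogis(0.2 + config$pa_age_slope * (age - 13))
  mod_any <- stats::runif(n) < p_mod
  pa_moderate_sessions <- ifelse(mod_any, sample(1:7, n, replace = TRUE), 0)
  pa_moderate_minutes <- ifelse(mod_any,
                                round(stats::rlnorm(n, log(45) +
                                        0.5 * config$pa_age_slope * (age - 13),
                                      0.7)), 0)

  clean <- data.frame(
    participant_id = sprintf("S%05d", seq_len(n)),
    age = age, gender = gender, race = race, education = education,
    family_pir = family_pir, stimulant_use = stimulant_use,
    stringsAsFactors = FALSE)
  clean <- cbind(clean, as.data.frame(intake))
  clean$bmi <- bmi
  clean$cotinine <- cotinine
  clean$alcohol <- alcohol
  clean$pa_transport_sessions <- pa_transport_sessions
  clean$pa_transport_minutes <- pa_transport_minutes
  clean$pa_moderate_sessions <- pa_moderate_sessions
  clean$pa_moderate_minutes <- pa_moderate_minutes

  # realised lifestyle OBS of the clean sample (same tertiles the analysis
  # will compute after exclusions, since planted bad rows never survive them)
  proto <- clean
  proto[c(oxidative_biomarkers(), bmd_outcomes())] <- NA_real_
  obs <- compute_obs(cohort_table(proto))
  L <- obs$lifestyle_obs
  Lc <- L - 5  # centre at the attainable median

  uric_dev <- config$mediation_a_uric * Lc + stats::rnorm(n, 0,
                                                          config$noise_sd_uric)
  ggt_dev <- config$mediation_a_ggt * Lc + stats::rnorm(n, 0,
                                                        config$noise_sd_ggt)
  alb_dev <- config$mediation_a_albumin * Lc +
    stats::rnorm(n, 0, config$noise_sd_albumin)
  uric <- pmax(ifelse(gender == "male", 5.6, 4.3) + uric_dev, 0.5)
  ggt <- pmax(ifelse(gender == "male", 14, 12) + ggt_dev, 1)
  albumin <- pmax(ifelse(gender == "male", 4.6, 4.4) + alb_dev, 2)
  vitd <- pmax(stats::rnorm(n, 57, 16), 5)

  direct <- switch(config$obs_effect_mode,
    age_interaction = ifelse(age <= config$age_split,
                             config$beta_young, config$beta_old) * Lc,
    breakpoint = config$slope_below *
      (pmin(L, config$breakpoint_k) - config$breakpoint_k) +
      config$slope_above * pmax(L - config$breakpoint_k, 0),
    none = rep(0, n))
  med_part <- config$mediation_b_uric * uric_dev +
    config$mediation_b_ggt * ggt_dev +
    config$mediation_b_albumin * alb_dev
  base <- c(bmd_lumbar = 0.87, bmd_pelvis = 1.06, bmd_total = 0.95)
  fem <- c(bmd_lumbar = 0.045, bmd_pelvis = 0.02, bmd_total = 0)
  for (site in names(base)) {
    clean[[site]] <- base[[site]] + fem[[site]] * (gender == "female") +
      config$age_bmd_slope * (age - 13) + direct + med_part +
      stats::rnorm(n, 0, config$noise_sd_bmd)
  }
  clean$albumin <- albumin
  clean$vitd_25oh <- vitd
  clean$uric_acid <- uric
  clean$ggt <- ggt
  clean <- clean[cohort_columns()]

  planted <- plant_invalid_rows(config, n)
  full <- rbind(clean, planted)
  full <- full[sample.int(nrow(full)), , drop = FALSE]
  rownames(full) <- NULL

  truth <- list(
    mode = config$obs_effect_mode, n = n, seed = config$seed,
    beta_young = config$beta_young, beta_old = config$beta_old,
    age_split = config$age_split,
    breakpoint_k = config$breakpoint_k,
    slope_below = config$slope_below, slope_above = config$slope_above,
    a_uric = config$mediation_a_uric, b_uric = config$mediation_b_uric,
    a_ggt = config$mediation_a_ggt, b_ggt = config$mediation_b_ggt,
    a_albumin = config$mediation_a_albumin,
    b_albumin = config$mediation_b_albumin,
    indirect_uric = config$mediation_a_uric * config$mediation_b_uric,
    indirect_ggt = config$mediation_a_ggt * config$mediation_b_ggt,
    noise_sd_bmd = config$noise_sd_bmd,
    age_bmd_slope = config$age_bmd_slope,
    lifestyle_obs = stats::setNames(L, clean$participant_id),
    planted_exclusions = c(age_over_18 = config$n_age_over,
                           missing_bmd = config$n_missing_bmd,
                           missing_dietary = config$n_missing_dietary,
                           missing_lifestyle = config$n_missing_lifestyle))
  list(cohort = cohort_table(full), truth = truth)
}

# Rows designed to fail exactly one sequential exclusion step each: over-age
# rows are otherwise complete; missing-BMD rows pass the age check; missing
# dietary/lifestyle rows pass all earlier checks.
plant_invalid_rows <- function(config, n_clean) {
  counts <- c(config$n_age_over, config$n_missing_bmd,
              config$n_missing_dietary, config$n_missing_lifestyle)
  n_bad <- sum(counts)
  if (n_bad == 0L) {
    return(NULL)
  }
  tmpl <- data.frame(
    participant_id = sprintf("X%05d", seq_len(n_bad)),
    age = sample(8:18, n_bad, replace = TRUE),
    gender = sample(c("male", "female"), n_bad, replace = TRUE),
    race = "non-Hispanic", education = "<9th grade",
    family_pir = 1.5, stimulant_use = FALSE,
    stringsAsFactors = FALSE)
  diet <- dietary_distribution()
  for (i in seq_len(nrow(diet))) {
    tmpl[[diet$name[i]]] <- stats::rlnorm(n_bad, diet$meanlog[i],
                                          diet$sdlog[i])
  }
  tmpl$bmi <- stats::rlnorm(n_bad, log(21.4), 0.252)
  tmpl$cotinine <- stats::rlnorm(n_bad, log(0.03), 1.8)
  tmpl$alcohol <- 0
  tmpl$pa_transport_sessions <- 0
  tmpl$pa_transport_minutes <- 0
  tmpl$pa_moderate_sessions <- 3
  tmpl$pa_moderate_minutes <- 30
  tmpl$albumin <- 4.5
  tmpl$vitd_25oh <- 57
  tmpl$uric_acid <- 4.9
  tmpl$ggt <- 13
  for (site in bmd_outcomes()) tmpl[[site]] <- stats::rnorm(n_bad, 0.95, 0.1)

  idx <- rep(seq_along(counts), counts)
  tmpl$age[idx == 1L] <- sample(19:25, sum(idx == 1L), replace = TRUE)
  if (any(idx == 2L)) {
    which_bmd <- sample(bmd_outcomes(), sum(idx == 2L), replace = TRUE)
    rows <- which(idx == 2L)
    for (j in seq_along(rows)) tmpl[rows[j], which_bmd[j]] <- NA_real_
  }
  if (any(idx == 3L)) {
    which_diet <- sample(dietary_components(), sum(idx == 3L), replace = TRUE)
    rows <- which(idx == 3L)
    for (j in seq_along(rows)) tmpl[rows[j], which_diet[j]] <- NA_real_
  }
  if (any(idx == 4L)) {
    which_ls <- sample(c("bmi", "cotinine", "alcohol", "pa_moderate_minutes"),
                       sum(idx == 4L), replace = TRUE)
    rows <- which(idx == 4L)
    for (j in seq_along(rows)) tmpl[rows[j], which_ls[j]] <- NA_real_
  }
  tmpl[cohort_columns()]
}
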