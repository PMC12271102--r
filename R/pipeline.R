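#' Configuration for a full pipeline run
#'
#' @param input Path to a cohort file readable by [read_cohort()], or `NULL`
#'   to simulate a cohort from `synthetic` instead.
#' @param synthetic A [synthetic_config()] used when `input` is `NULL`.
#' @param schema Optional schema map for [read_cohort()].
#' @param exposure One of `lifestyle_obs`, `dietary_obs`, `total_obs`.
#' @param outcomes Subset of [bmd_outcomes()].
#' @param covariates Adjustment set; see [default_covariates()].
#' @param modifier Effect modifier for the interaction/subgroup stage.
#' @param mediators Biomarker mediators for the mediation stage.
#' @param reps Bootstrap replicates for mediation.
#' @param seed Integer seed governing simulation and bootstrap stages.
#' @param out_dir Output directory (created if needed).
#' @param stages Character vector of stages to run, in order, from
#'   `c("describe", "associate", "dose_response", "mediate")`; scoring and
#'   exclusions always run.
#' @return A validated `run_config` list.
#' @export
run_config <- function(input = NULL, synthetic = synthetic_config(),
                       schema = NULL,
                       exposure = "lifestyle_obs",
                       outcomes = bmd_outcomes(),
                       covariates = default_covariates(),
                       modifier = "age",
                       mediators = c("albumin", "uric_acid", "ggt"),
                       reps = 1000L, seed = 1L,
                       out_dir = tempfile("obsbmd_run_"),
                       stages = c("describe", "associate", "dose_response",
                                  "mediate")) {
  if (!exposure %in% c("lifestyle_obs", "dietary_obs", "total_obs")) {
    stop("run_config: unknown exposure '", exposure, "'", call. = FALSE)
  }
  bad <- setdiff(outcomes, bmd_outcomes())
  if (length(bad)) {
    stop("run_config: unknown outcome(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bad_stage <- setdiff(stages, c("describe", "associate", "dose_response",
                                 "mediate"))
  if (length(bad_stage)) {
    stop("run_config: unknown stage(s): ",
         paste(bad_stage, collapse = ", "), call. = FALSE)
  }
  cfg <- list(input = input, synthetic = synthetic, schema = schema,
              exposure = exposure, outcomes = outcomes,
              covariates = covariates, modifier = modifier,
              mediators = mediators, reps = as.integer(reps),
              seed = as.integer(seed), out_dir = out_dir, stages = stages)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the analysis stages in the study's order: cohort input (read or
#' simulate), sequential exclusions, OBS scoring, descriptive comparison,
#' association analysis (crude and adjusted GLM, leave-one-covariate-out
#' sensitivity, interaction/subgroup, combined four-group comparison, OBS
#' group x gender model), GAM + threshold dose-response, and biomarker
#' mediation. Each stage writes JSON (and the curve as TSV) under
#' `out_dir/tables/`; a manifest records the package version, seed, input
#' hash, and per-stage output paths. Stages are pure functions of the input
#' table, the configuration, and the seed.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with all stage results and `manifest`.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(file.path(config$out_dir, "tables"), recursive = TRUE,
             showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  outputs <- list()
  wjson <- function(obj, name) {
    path <- file.path(config$out_dir, "tables", paste0(name, ".json"))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE, na = "null")
    outputs[[name]] <<- path
    path
  }

  # -- input ----------------------------------------------------------------
  if (is.null(config$input)) {
    say("stage input: simulating cohort (n = %d, seed = %d)",
        config$synthetic$n, config$synthetic$seed)
    sim <- generate_cohort(config$synthetic)
    cohort <- sim$cohort
    truth <- sim$truth
    input_hash <- NA_character_
  } else {
    say("stage input: reading %s", config$input)
    cohort <- read_cohort(config$input, schema = config$schema)
    truth <- NULL
    input_hash <- unname(tools::md5sum(config$input))
  }

  # -- exclusions + scoring -------------------------------------------------
  excl <- apply_exclusions(cohort)
  say("stage exclusions: %d -> %d participants", nrow(cohort),
      nrow(excl$cohort))
  wjson(excl$tally, "exclusion_tally")
  obs <- compute_obs(excl$cohort)
  tab <- analysis_table(excl$cohort, obs)
  utils::write.table(as.data.frame(obs),
                     file.path(config$out_dir, "tables", "obs_scores.tsv"),
                     sep = "\t", row.names = FALSE)
  outputs[["obs_scores"]] <- file.path(config$out_dir, "tables",
                                       "obs_scores.tsv")

  results <- list(exclusions = excl$tally, obs = obs, truth = truth)

  # -- descriptives ---------------------------------------------------------
  if ("describe" %in% config$stages) {
    say("stage describe")
    vars <- c("age", "race", "education", "family_pir", "stimulant_use",
              oxidative_biomarkers(), "bmi", "cotinine", "alcohol",
              dietary_components(), "lifestyle_obs", "dietary_obs",
              "total_obs", bmd_outcomes())
    desc <- summarize_cohort(tab, "gender", vars)
    obs_grp <- median_split(tab$lifestyle_obs)
    tab$obs_group <- obs_grp
    desc_obs <- summarize_cohort(tab, "obs_group",
                                 c("bmi", "cotinine", "alcohol", "age",
                                   "gender", "race", "education",
                                   "family_pir", "stimulant_use",
                                   oxidative_biomarkers()))
    pa <- active_pa_share(tab, group = obs_grp)
    wjson(desc, "descriptives_by_gender")
    wjson(desc_obs, "descriptives_by_obs_group")
    wjson(pa, "active_pa_share")
    results$descriptives <- list(by_gender = desc, by_obs_group = desc_obs,
                                 active_pa = pa)
  }

  # -- association ----------------------------------------------------------
  if ("associate" %in% config$stages) {
    say("stage associate")
    crude <- lapply(config$outcomes, function(oc) {
      lapply(c("total_obs", "lifestyle_obs", "dietary_obs"), function(ex) {
        cbind(exposure = ex, term_row(glm_fit(tab, oc, ex)))
      })
    })
    crude <- do.call(rbind, lapply(crude, function(l) do.call(rbind, l)))
    crude <- cbind(outcome = rep(config$outcomes,
                                 each = nrow(crude) / length(config$outcomes)),
                   crude)
    adjusted <- do.call(rbind, lapply(config$outcomes, function(oc) {
      f <- glm_fit(tab, oc, config$exposure, config$covariates)
      cbind(outcome = oc, term_row(f), n = f$n)
    }))
    sens <- lapply(config$outcomes, function(oc) {
      sensitivity_loo(tab, oc, config$exposure, config$covariates)
    })
    names(sens) <- config$outcomes
    subgrp <- lapply(config$outcomes, function(oc) {
      subgroup_interaction(tab, oc, config$exposure, config$modifier,
                           config$covariates)
    })
    names(subgrp) <- config$outcomes
    cg <- combined_groups(tab, config$outcomes)
    gint <- lapply(config$outcomes, function(oc) {
      gender_interaction_model(tab, oc, config$covariates)
    })
    names(gint) <- config$outcomes

    wjson(crude, "association_crude")
    wjson(adjusted, "association_adjusted")
    wjson(lapply(sens, as.data.frame), "sensitivity_loo")
    wjson(lapply(subgrp, function(s)
      list(p_interaction = s$p_interaction, strata = s$strata)),
      "subgroup_interaction")
    wjson(list(summary = cg$summary, omnibus_p = as.list(cg$omnibus_p),
               pairwise = cg$pairwise), "combined_groups")
    wjson(lapply(gint, function(g)
      list(terms = g$terms, scale_ml = g$scale_ml, scale_ci = g$scale_ci)),
      "gender_interaction")
    results$association <- list(crude = crude, adjusted = adjusted,
                                sensitivity = sens, subgroup = subgrp,
                                combined_groups = cg,
                                gender_interaction = gint)
  }

  # -- dose-response --------------------------------------------------------
  if ("dose_response" %in% config$stages) {
    say("stage dose_response")
    curves <- list()
    thresholds <- list()
    for (oc in config$outcomes) {
      gc <- gam_curve(tab, oc, config$exposure, config$covariates)
      tf <- threshold_fit(tab, oc, config$exposure, config$covariates)
      curves[[oc]] <- gc
      thresholds[[oc]] <- tf
      utils::write.table(gc$curve,
                         file.path(config$out_dir, "tables",
                                   paste0("gam_curve_", oc, ".tsv")),
                         sep = "\t", row.names = FALSE)
    }
    wjson(lapply(thresholds, function(tf) {
      list(breakpoint = tf$breakpoint, slope_below = tf$slope_below,
           slope_above = tf$slope_above, lrt = tf$lrt, lrt_p = tf$lrt_p,
           loglik_linear = tf$loglik_linear,
           loglik_piecewise = tf$loglik_piecewise, n = tf$n)
    }), "threshold_fit")
    results$dose_response <- list(curves = curves, thresholds = thresholds)
  }

  # -- mediation ------------------------------------------------------------
  if ("mediate" %in% config$stages) {
    say("stage mediate")
    panel <- mediate_panel(tab, config$exposure,
                           mediators = config$mediators,
                           outcomes = config$outcomes,
                           covariates = config$covariates,
                           reps = config$reps, seed = config$seed)
    wjson(panel$summary, "mediation_panel")
    results$mediation <- panel
  }

  manifest <- list(
    package = "obsbmd",
    version = as.character(utils::packageVersion("obsbmd")),
    seed = config$seed,
    input = if (is.null(config$input)) "simulated" else config$input,
    input_md5 = input_hash,
    n_input = nrow(cohort), n_analysis = nrow(tab),
    exposure = config$exposure, outcomes = config$outcomes,
    covariates = config$covariates, stages = config$stages,
    outputs = outputs,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- manifest
  say("pipeline complete in %.1fs; outputs in %s", manifest$elapsed_s,
      config$out_dir)
  invisible(results)
}
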