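# End-to-end orchestration: simulate -> score -> extract -> model ->
# classify -> report, as one reproducible run with a manifest.

week_model_outcomes <- function() {
  list(
    list(outcome = "event_stress", family = "gaussian", epa = FALSE),
    list(outcome = "activity_stress", family = "gaussian", epa = FALSE),
    list(outcome = "social_stress", family = "gaussian", epa = FALSE),
    list(outcome = "physical_stress", family = "gaussian", epa = FALSE),
    list(outcome = "na", family = "gaussian", epa = FALSE),
    list(outcome = "pa", family = "gaussian", epa = FALSE),
    list(outcome = "scr_count", family = "poisson", epa = TRUE),
    list(outcome = "hr_max", family = "gaussian", epa = TRUE)
  )
}

#' Run the complete analysis pipeline
#'
#' Generates (or scores) a cohort, extracts physiological features, fits the
#' week-type models for every outcome, the momentary stress-affect models,
#' the positive-affect mediation of the skin-conductance magnitude, the
#' median-split incongruence summary and (optionally) the LOBO/LOSO
#' classification, then writes tidy CSV results and a JSON run manifest with
#' row counts and file checksums. Reruns with the same configuration and
#' seed are byte-identical.
#'
#' @param config An [study_config()].
#' @param effects An [effect_config()].
#' @param out_dir Output directory.
#' @param classify Run the classification stage (the slowest one).
#' @param n_null Bootstrap-null resamples per participant when classifying.
#' @param n_boot Mediation bootstrap resamples.
#' @param momentary List of `c(outcome, predictor)` pairs for the momentary
#'   models.
#' @return Invisibly, a list with all stage outputs and the `manifest`.
#' @export
run_pipeline <- function(config = study_config(), effects = default_effects(),
                         out_dir, classify = FALSE, n_null = 2000,
                         n_boot = 5000,
                         momentary = list(c("na", "social_stress"),
                                          c("pa", "social_stress"))) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0)
    stop("output directory is not writable: ", out_dir)
  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("stressweek")),
                   stages = list(), counts = list(), files = list())
  finish <- function(status) {
    manifest$status <- status
    path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    manifest
  }
  result <- tryCatch({
    cohort <- generate_cohort(config, effects)
    manifest$stages$simulate <- "ok"
    manifest$counts$scheduled <- nrow(cohort$ema)

    tab <- analysis_table(cohort)
    manifest$stages$score <- "ok"
    manifest$counts$compliant <- nrow(tab)

    feats <- extract_epa_features(cohort)
    tab_epa <- dplyr::left_join(tab, feats, by = c("participant_id", "beep_id"))
    manifest$stages$extract <- "ok"
    manifest$counts$epa_valid <- sum(tab_epa$epa_valid, na.rm = TRUE)

    week_tbls <- lapply(week_model_outcomes(), function(m)
      fit_week_model(tab_epa, m$outcome, family = m$family, epa = m$epa))
    week_fx <- dplyr::bind_rows(week_tbls)
    week_fx$p_fdr <- fdr_correct(week_fx$p, week_fx$model_id)
    mom_fx <- dplyr::bind_rows(lapply(momentary, function(mp)
      fit_momentary_model(tab_epa, mp[1], mp[2])))
    mom_fx$p_fdr <- fdr_correct(mom_fx$p, mom_fx$model_id)
    manifest$stages$models <- "ok"

    med <- mediate(tab_epa, n_boot = n_boot, seed = config$seed)
    manifest$stages$mediation <- "ok"

    incon <- median_split_incongruence(tab)

    clf <- NULL
    if (classify) {
      clf <- classify_cohort(tab_epa, n_null = n_null, seed = config$seed)
      manifest$stages$classify <- "ok"
    }

    write_out <- function(obj, name) {
      path <- file.path(out_dir, name)
      utils::write.csv(obj, path, row.names = FALSE)
      manifest$files[[name]] <<- unname(tools::md5sum(path))
    }
    write_out(week_fx, "week_effects.csv")
    write_out(mom_fx, "momentary_effects.csv")
    write_out(tibble::tibble(
      quantity = c("path_a", "path_b", "indirect", "indirect_ci_low",
                   "indirect_ci_high", "indirect_p", "direct",
                   "direct_ci_low", "direct_ci_high", "direct_p", "total",
                   "proportion_mediated_pct"),
      value = c(med$path_a, med$path_b, med$indirect, med$indirect_ci,
                med$indirect_p, med$direct, med$direct_ci, med$direct_p,
                med$total, med$proportion_mediated)),
      "mediation.csv")
    write_out(incon$by_participant, "incongruence.csv")
    if (!is.null(clf)) {
      write_out(clf$results, "classification.csv")
      if (!is.null(clf$comparisons))
        write_out(clf$comparisons, "classification_comparisons.csv")
    }
    manifest <- finish("complete")
    list(cohort = cohort, analysis = tab_epa, features = feats,
         week_effects = week_fx, momentary_effects = mom_fx,
         mediation = med, incongruence = incon, classification = clf,
         manifest = manifest)
  }, error = function(e) {
    finish(paste("failed:", conditionMessage(e)))
    stop(e)
  })
  invisible(result)
}
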