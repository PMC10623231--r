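# Generalized linear mixed-effects models for week-type and momentary
# effects, with a maximal-to-simpler random-effects ladder, Wald intervals
# and Benjamini-Hochberg FDR correction.

#' Covariate sets for the mixed models
#'
#' Subject-level covariates (sex, study program, week order), day-level
#' covariates (day index, beep number, sleep duration, previous-night
#' alcohol) and beep-level covariates (hunger, caffeine, exercise, sexual
#' activity); physiology models additionally adjust for ambient temperature
#' and accelerometer movement.
#'
#' @param epa Include the physiology-model covariates.
#' @return Character vector of column names.
#' @export
default_covariates <- function(epa = FALSE) {
  base <- c("sex", "program", "stress_week_first", "day_index",
            "beep_index_in_day", "sleep_duration", "alcohol_units", "hunger",
            "caffeine", "exercise", "sexual_activity")
  if (epa) c(base, "ambient_temperature", "acc_rmsd") else base
}

#' Build the per-beep analysis table of a cohort
#'
#' Applies compliance filtering, scale scoring and person-centering, keeps
#' compliant beeps, and carries the model covariates. When a feature table
#' is supplied the physiological features are joined and rows without valid
#' physiology are flagged (not dropped).
#'
#' @param cohort An `sw_cohort`.
#' @param features Optional output of [extract_epa_features()].
#' @return Tibble, one row per compliant beep.
#' @export
analysis_table <- function(cohort, features = NULL) {
  rec <- filter_compliance(cohort$ema, cohort$config$beep_window)
  scores <- score_scales(rec, cohort$scale_map)
  scores <- suppressWarnings(person_center(scores, ema_scales()))
  covars <- rec[, c("participant_id", "beep_id",
                    setdiff(c(default_covariates(epa = FALSE),
                              "ambient_temperature"), names(scores)))]
  out <- dplyr::inner_join(scores, covars,
                           by = c("participant_id", "beep_id"))
  out <- out[out$compliance_flag, , drop = FALSE]
  if (!is.null(features))
    out <- dplyr::left_join(out, features, by = c("participant_id", "beep_id"))
  out
}

zscore <- function(x) (x - mean(x, na.rm = TRUE)) / stats::sd(x, na.rm = TRUE)

# drop covariates that are constant on the analysis rows (degenerate in
# small synthetic cohorts); returns the kept set
usable_covariates <- function(data, covariates) {
  keep <- vapply(covariates, function(cv) {
    v <- data[[cv]]
    !is.null(v) && length(unique(v[!is.na(v)])) > 1
  }, logical(1))
  covariates[keep]
}

# fit with the random-effects ladder: by-participant intercept + slope of
# the focal predictor, falling back to intercept-only on singular or failed
# fits; returns the merMod plus the realized structure
fit_ladder <- function(formula_max, formula_int, data, family) {
  fits <- list(
    list(f = formula_max, re = "intercept+slope"),
    list(f = formula_int, re = "intercept")
  )
  for (cand in fits) {
    fit <- tryCatch({
      if (family == "gaussian")
        lme4::lmer(cand$f, data = data, REML = FALSE,
                   control = lme4::lmerControl(calc.derivs = FALSE))
      else
        lme4::glmer(cand$f, data = data, family = stats::poisson(),
                    control = lme4::glmerControl(calc.derivs = FALSE))
    }, error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-5))
      return(list(fit = fit, re = cand$re, converged = TRUE))
    if (!is.null(fit) && cand$re == "intercept")
      return(list(fit = fit, re = cand$re, converged = FALSE))
    last <- fit
  }
  if (is.null(last)) stop("mixed model failed to fit under every structure")
  list(fit = last, re = "intercept+slope", converged = FALSE)
}

fixed_effect_table <- function(fit, model_id, family, re, converged,
                               conf_level = 0.95) {
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- est / se
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    model_id = model_id,
    term = sub("^week_type", "week_type:", names(est)),
    estimate = unname(est), se = unname(se),
    ci_low = unname(est - q * se), ci_high = unname(est + q * se),
    p = unname(2 * stats::pnorm(-abs(z))),
    family = family, re_structure = re, converged = converged,
    n_obs = stats::nobs(fit),
    n_participants = length(unique(
      stats::model.frame(fit)$participant_id))
  )
}

#' Fit the week-type model for one outcome
#'
#' Regresses the outcome on week type (stress vs control) plus the standard
#' covariate set, with a by-participant random intercept and week slope
#' (falling back to intercept-only on singular fits). Gaussian outcomes are
#' z-scored on the full two-week sample, so the week coefficient is a
#' standardized beta; counts use a Poisson log link, so it is a log-mean
#' difference. Intervals are Wald at `conf_level`.
#'
#' @param data Analysis table (see [analysis_table()]).
#' @param outcome Outcome column name.
#' @param family `"gaussian"` or `"poisson"`.
#' @param covariates Covariate columns; default [default_covariates()] with
#'   `epa` as given.
#' @param epa Use the physiology covariate set.
#' @param standardize Z-score gaussian outcomes (default `TRUE`).
#' @param conf_level Confidence level for Wald intervals.
#' @return Tibble of fixed effects (term, estimate, se, ci, p, fit notes);
#'   the focal row has `term == "week_type:stress"`.
#' @export
fit_week_model <- function(data, outcome, family = c("gaussian", "poisson"),
                           covariates = NULL, epa = FALSE,
                           standardize = TRUE, conf_level = 0.95) {
  family <- match.arg(family)
  if (length(unique(data$participant_id)) < 2)
    stop("week model requires at least 2 participants")
  covariates <- covariates %||% default_covariates(epa = epa)
  miss <- setdiff(c(outcome, "week_type", "participant_id", covariates),
                  names(data))
  if (length(miss))
    stop("columns missing from data: ", paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[, c(outcome, "week_type", covariates)]), ]
  d$week_type <- factor(d$week_type, levels = c("control", "stress"))
  if (family == "poisson") {
    y <- d[[outcome]]
    if (any(y < 0 | y != round(y)))
      stop("poisson family requires non-negative integer outcome")
    d$.y <- y
  } else {
    d$.y <- if (standardize) zscore(d[[outcome]]) else d[[outcome]]
  }
  covariates <- usable_covariates(d, covariates)
  rhs <- paste(c("week_type", covariates), collapse = " + ")
  f_max <- stats::as.formula(
    paste(".y ~", rhs, "+ (1 + week_type | participant_id)"))
  f_int <- stats::as.formula(paste(".y ~", rhs, "+ (1 | participant_id)"))
  res <- fit_ladder(f_max, f_int, d, family)
  fixed_effect_table(res$fit, paste0("week:", outcome), family, res$re,
                     res$converged, conf_level)
}

#' Fit a momentary within-beep association model
#'
#' Regresses the outcome on the person-centered (and z-scored) momentary
#' predictor, adjusting for week type and the covariate set, with a
#' by-participant random intercept and predictor slope (ladder as in
#' [fit_week_model()]).
#'
#' @param data Analysis table.
#' @param outcome Outcome column (z-scored when gaussian).
#' @param predictor Scale whose person-centered column (`<predictor>_pc`)
#'   is the focal term.
#' @inheritParams fit_week_model
#' @return Tibble of fixed effects; the focal row has `term == predictor`.
#' @export
fit_momentary_model <- function(data, outcome, predictor,
                                family = c("gaussian", "poisson"),
                                covariates = NULL, epa = FALSE,
                                standardize = TRUE, conf_level = 0.95) {
  family <- match.arg(family)
  pc <- paste0(predictor, "_pc")
  if (!pc %in% names(data))
    stop("person-centered predictor column missing: ", pc)
  covariates <- covariates %||% default_covariates(epa = epa)
  d <- data[stats::complete.cases(
    data[, c(outcome, pc, "week_type", covariates)]), ]
  d$week_type <- factor(d$week_type, levels = c("control", "stress"))
  d$.x <- zscore(d[[pc]])
  if (family == "poisson") d$.y <- d[[outcome]]
  else d$.y <- if (standardize) zscore(d[[outcome]]) else d[[outcome]]
  covariates <- usable_covariates(d, covariates)
  rhs <- paste(c(".x", "week_type", covariates), collapse = " + ")
  f_max <- stats::as.formula(paste(".y ~", rhs, "+ (1 + .x | participant_id)"))
  f_int <- stats::as.formula(paste(".y ~", rhs, "+ (1 | participant_id)"))
  res <- fit_ladder(f_max, f_int, d, family)
  tb <- fixed_effect_table(res$fit, paste0("momentary:", outcome, "~", predictor),
                           family, res$re, res$converged, conf_level)
  tb$term[tb$term == ".x"] <- predictor
  tb
}

#' Benjamini-Hochberg FDR correction within model families
#'
#' @param p Numeric vector of p values.
#' @param groups Optional grouping (one correction family per level); `NULL`
#'   treats all p values as one family.
#' @return Vector of adjusted p values (`p_fdr >= p`, ranking preserved).
#' @export
fdr_correct <- function(p, groups = NULL) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p values must lie in [0, 1]")
  if (is.null(groups)) return(stats::p.adjust(p, method = "BH"))
  stats::ave(p, groups, FUN = function(v) stats::p.adjust(v, method = "BH"))
}
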