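# Mediation of the week-type effect on skin-conductance arousal by positive
# affect: product-of-coefficients decomposition with a participant-level
# (cluster) bootstrap.

#' Mediation of a week-type effect through a momentary mediator
#'
#' Decomposes the effect of week type on a physiological outcome into the
#' indirect path through the mediator (product of coefficients: week-to-
#' mediator `a` times mediator-to-outcome `b`) and the direct path (week
#' coefficient given the mediator). Point estimates come from random-
#' intercept mixed models; confidence intervals from a nonparametric
#' bootstrap that resamples participants with replacement (respecting the
#' repeated-measures structure) and refits both models by least squares.
#' The mediator and gaussian outcomes are z-scored, so paths are on the
#' standardized scale. For an `scr_magnitude` outcome, windows with zero
#' detected responses are excluded from the outcome model (magnitude is
#' undefined there).
#'
#' @param data Analysis table joined with physiological features.
#' @param mediator Mediator column (default `"pa"`, rescaled positive
#'   affect).
#' @param outcome Outcome column (default `"scr_magnitude"`).
#' @param covariates Covariates for the mediator model; the outcome model
#'   adds the physiology covariates.
#' @param n_boot Bootstrap resamples (default 5000).
#' @param seed Seed for the bootstrap.
#' @param conf_level Confidence level.
#' @return An object of class `sw_mediation`: estimates `indirect`,
#'   `direct`, `total` (= indirect + direct), `proportion_mediated` (%),
#'   paths `a` and `b`, bootstrap CIs and p values, and an `unstable` flag
#'   when the total is too close to zero for the proportion to be
#'   meaningful.
#' @export
mediate <- function(data, mediator = "pa", outcome = "scr_magnitude",
                    covariates = NULL, n_boot = 5000, seed = 1L,
                    conf_level = 0.95) {
  covs_m <- covariates %||% default_covariates(epa = FALSE)
  covs_o <- covariates %||% default_covariates(epa = TRUE)

  dm <- data[stats::complete.cases(
    data[, c(mediator, "week_type", covs_m)]), ]
  dm$week_type <- factor(dm$week_type, levels = c("control", "stress"))
  med_mu <- mean(dm[[mediator]])
  med_sd <- stats::sd(dm[[mediator]])
  dm$.m <- (dm[[mediator]] - med_mu) / med_sd

  keep_o <- stats::complete.cases(
    data[, c(outcome, mediator, "week_type", covs_o)])
  if (outcome == "scr_magnitude" && "scr_count" %in% names(data))
    keep_o <- keep_o & !is.na(data$scr_count) & data$scr_count > 0
  do <- data[keep_o, ]
  do$week_type <- factor(do$week_type, levels = c("control", "stress"))
  do$.m <- (do[[mediator]] - med_mu) / med_sd
  do$.y <- zscore(do[[outcome]])

  covs_m <- usable_covariates(dm, covs_m)
  covs_o <- usable_covariates(do, covs_o)
  f_m <- stats::as.formula(paste(
    ".m ~ week_type +", paste(covs_m, collapse = " + "),
    "+ (1 | participant_id)"))
  f_o <- stats::as.formula(paste(
    ".y ~ week_type + .m +", paste(covs_o, collapse = " + "),
    "+ (1 | participant_id)"))
  fit_m <- lme4::lmer(f_m, data = dm, REML = FALSE,
                      control = lme4::lmerControl(calc.derivs = FALSE))
  fit_o <- lme4::lmer(f_o, data = do, REML = FALSE,
                      control = lme4::lmerControl(calc.derivs = FALSE))
  a <- unname(lme4::fixef(fit_m)["week_typestress"])
  b <- unname(lme4::fixef(fit_o)[".m"])
  direct <- unname(lme4::fixef(fit_o)["week_typestress"])
  indirect <- a * b
  total <- indirect + direct

  # cluster bootstrap: resample participants once per replicate, refit both
  # models by OLS on the resampled rows
  Xm <- stats::model.matrix(
    stats::as.formula(paste("~ week_type +", paste(covs_m, collapse = " + "))),
    dm)
  Xo <- stats::model.matrix(
    stats::as.formula(paste("~ week_type + .m +",
                            paste(covs_o, collapse = " + "))), do)
  ym <- dm$.m
  yo <- do$.y
  ids <- unique(c(dm$participant_id, do$participant_id))
  rows_m <- split(seq_len(nrow(dm)), factor(dm$participant_id, levels = ids))
  rows_o <- split(seq_len(nrow(do)), factor(do$participant_id, levels = ids))
  boot <- withr::with_seed(derive_seed(seed, "mediate-boot"), {
    out <- matrix(NA_real_, n_boot, 3,
                  dimnames = list(NULL, c("indirect", "direct", "total")))
    for (bb in seq_len(n_boot)) {
      take <- sample(length(ids), replace = TRUE)
      im <- unlist(rows_m[take], use.names = FALSE)
      io <- unlist(rows_o[take], use.names = FALSE)
      cm <- stats::lm.fit(Xm[im, , drop = FALSE], ym[im])$coefficients
      co <- stats::lm.fit(Xo[io, , drop = FALSE], yo[io])$coefficients
      ab <- unname(cm["week_typestress"]) * unname(co[".m"])
      dd <- unname(co["week_typestress"])
      out[bb, ] <- c(ab, dd, ab + dd)
    }
    out
  })
  alpha <- 1 - conf_level
  ci <- apply(boot, 2, stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2), na.rm = TRUE)
  boot_p <- function(v) min(1, 2 * min(mean(v <= 0, na.rm = TRUE),
                                       mean(v >= 0, na.rm = TRUE)))
  structure(list(
    path_a = a, path_b = b,
    indirect = indirect, indirect_ci = unname(ci[, "indirect"]),
    indirect_p = boot_p(boot[, "indirect"]),
    direct = direct, direct_ci = unname(ci[, "direct"]),
    direct_p = boot_p(boot[, "direct"]),
    total = total,
    proportion_mediated = 100 * indirect / total,
    unstable = abs(total) < 0.02,
    n_boot = n_boot,
    n_obs_mediator = nrow(dm), n_obs_outcome = nrow(do)
  ), class = "sw_mediation")
}

#' @export
print.sw_mediation <- function(x, ...) {
  cat(sprintf(
    paste0("<sw_mediation> indirect %.4f [%.4f, %.4f] (p=%.3g), ",
           "direct %.4f [%.4f, %.4f] (p=%.3g)\n",
           "  total %.4f, proportion mediated %.1f%%%s\n"),
    x$indirect, x$indirect_ci[1], x$indirect_ci[2], x$indirect_p,
    x$direct, x$direct_ci[1], x$direct_ci[2], x$direct_p,
    x$total, x$proportion_mediated,
    if (x$unstable) " (unstable: total near zero)" else ""))
  invisible(x)
}
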