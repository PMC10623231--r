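# Random-forest classification of beeps into stress vs control week, under
# individualized leave-one-beep-out (LOBO) and group leave-one-subject-out
# (LOSO) cross-validation, with bootstrap null distributions and paired
# model comparisons.

#' Feature sets for week-type classification
#'
#' Model 1 classifies from person-centered positive and negative affect,
#' Model 2 from the ten physiological features, Model 3 from their union.
#'
#' @param data Analysis table joined with physiological features.
#' @return List with the joined `data` and character vectors `m1`, `m2`,
#'   `m3` of feature columns.
#' @export
build_feature_sets <- function(data) {
  m1 <- c("pa_pc", "na_pc")
  m2 <- c("scr_count", "scr_magnitude", "scr_auc", "tonic_mean",
          "hr_mean", "hr_min", "hr_max", "temp_mean", "temp_slope",
          "acc_rmsd")
  miss <- setdiff(c(m1, m2), names(data))
  if (length(miss))
    stop("feature columns missing from data: ", paste(miss, collapse = ", "))
  list(data = data, m1 = m1, m2 = m2, m3 = c(m1, m2))
}

#' Random-forest settings
#'
#' @param num_trees Trees per forest (default 500).
#' @param mtry Features per split; default `floor(sqrt(p))`.
#' @return List of class `sw_forest_config`.
#' @export
forest_config <- function(num_trees = 500, mtry = NULL) {
  structure(list(num_trees = check_count(num_trees, "num_trees"),
                 mtry = mtry), class = "sw_forest_config")
}

complete_rows <- function(data, feature_cols) {
  data[stats::complete.cases(data[, feature_cols, drop = FALSE]) &
         !is.na(data$week_type), , drop = FALSE]
}

fit_forest <- function(x, y, config, seed) {
  set.seed(seed)
  randomForest::randomForest(
    x = x, y = y, ntree = config$num_trees,
    mtry = config$mtry %||% max(1, floor(sqrt(ncol(x)))))
}

#' Individualized leave-one-beep-out classification
#'
#' For every participant, fits one random forest per beep on that
#' participant's remaining beeps and classifies the held-out beep; the
#' participant's error is the misclassified fraction. Participants with
#' fewer than `min_beeps` complete beeps or with beeps from only one week
#' are excluded (recorded in the `excluded` attribute).
#'
#' @param data Analysis table with features and `week_type`.
#' @param feature_cols Feature column names.
#' @param config A [forest_config()].
#' @param seed Base seed; each fold's forest is seeded from
#'   (participant, beep).
#' @param min_beeps Minimum complete beeps per participant (default 10).
#' @return Tibble `participant_id`, `n_beeps`, `error`, plus per-beep
#'   predictions in the `predictions` attribute (for the bootstrap null).
#' @export
lobo_classify <- function(data, feature_cols, config = forest_config(),
                          seed = 1L, min_beeps = 10) {
  d <- complete_rows(data, feature_cols)
  ids <- unique(d$participant_id)
  res <- list()
  preds <- list()
  excluded <- character(0)
  for (pid in ids) {
    di <- d[d$participant_id == pid, , drop = FALSE]
    y <- factor(di$week_type, levels = c("control", "stress"))
    if (nrow(di) < min_beeps || length(unique(di$week_type)) < 2) {
      excluded <- c(excluded, pid)
      next
    }
    x <- as.data.frame(di[, feature_cols, drop = FALSE])
    pred <- factor(rep(NA_character_, nrow(di)), levels = levels(y))
    for (i in seq_len(nrow(di))) {
      fit <- fit_forest(x[-i, , drop = FALSE], y[-i], config,
                        derive_seed(seed, "lobo", pid, di$beep_id[i]))
      pred[i] <- stats::predict(fit, x[i, , drop = FALSE])
    }
    res[[pid]] <- tibble::tibble(participant_id = pid, n_beeps = nrow(di),
                                 error = mean(pred != y))
    preds[[pid]] <- tibble::tibble(participant_id = pid, beep_id = di$beep_id,
                                   truth = as.character(y),
                                   pred = as.character(pred))
  }
  out <- dplyr::bind_rows(res)
  attr(out, "predictions") <- dplyr::bind_rows(preds)
  attr(out, "excluded") <- excluded
  out
}

#' Group-level leave-one-subject-out classification
#'
#' Fits one random forest per held-out participant on all other
#' participants' beeps and scores the held-out participant's beeps. Mood
#' features are person-centered upstream; physiological features enter
#' as-is.
#'
#' @inheritParams lobo_classify
#' @return Tibble as in [lobo_classify()] with per-beep predictions in the
#'   `predictions` attribute.
#' @export
loso_classify <- function(data, feature_cols, config = forest_config(),
                          seed = 1L, min_beeps = 10) {
  d <- complete_rows(data, feature_cols)
  ids <- unique(d$participant_id)
  if (length(ids) < 3) stop("LOSO requires at least 3 participants")
  y_all <- factor(d$week_type, levels = c("control", "stress"))
  x_all <- as.data.frame(d[, feature_cols, drop = FALSE])
  res <- list()
  preds <- list()
  excluded <- character(0)
  for (pid in ids) {
    test <- d$participant_id == pid
    if (sum(test) < min_beeps ||
        length(unique(d$week_type[test])) < 2) {
      excluded <- c(excluded, pid)
      next
    }
    fit <- fit_forest(x_all[!test, , drop = FALSE], y_all[!test], config,
                      derive_seed(seed, "loso", pid))
    pred <- stats::predict(fit, x_all[test, , drop = FALSE])
    res[[pid]] <- tibble::tibble(participant_id = pid, n_beeps = sum(test),
                                 error = mean(pred != y_all[test]))
    preds[[pid]] <- tibble::tibble(participant_id = pid,
                                   beep_id = d$beep_id[test],
                                   truth = as.character(y_all[test]),
                                   pred = as.character(pred))
  }
  out <- dplyr::bind_rows(res)
  attr(out, "predictions") <- dplyr::bind_rows(preds)
  attr(out, "excluded") <- excluded
  out
}

#' Bootstrap null distribution of the classification error
#'
#' Resamples predicted labels i.i.d. from the observed predicted-class
#' frequencies and scores them against the true labels, yielding the error
#' distribution expected when predictions carry no information beyond class
#' frequencies. The p value is the fraction of null errors at or below the
#' observed error (one-sided, better than chance).
#'
#' @param predictions Character/factor vector of predicted labels.
#' @param labels True labels, same length.
#' @param n Resamples (default 10000; a warning below 100).
#' @param seed Seed.
#' @return List with `null` (the resampled errors), `null_mean`, `null_sd`,
#'   the central-95% band `q025`/`q975`, `observed`, `p`, `p_display`
#'   (`"<1e-4"` style when the observed error undercuts every resample) and
#'   `degenerate` (single-class predictions).
#' @export
bootstrap_null <- function(predictions, labels, n = 10000, seed = 1L) {
  stopifnot(length(predictions) == length(labels))
  if (n < 100) warning("bootstrap null with n < 100 resamples is unreliable")
  predictions <- as.character(predictions)
  labels <- as.character(labels)
  observed <- mean(predictions != labels)
  lev <- sort(unique(labels))
  degenerate <- length(unique(predictions)) < 2
  p1 <- mean(predictions == lev[1])
  nb <- length(labels)
  null <- withr::with_seed(derive_seed(seed, "bootnull"), {
    draws <- matrix(stats::runif(nb * n) < p1, nb, n)
    colMeans(draws != (labels == lev[1]))
  })
  p <- mean(null <= observed)
  if (degenerate) p <- 1
  list(null = null, null_mean = mean(null), null_sd = stats::sd(null),
       q025 = stats::quantile(null, 0.025, names = FALSE),
       q975 = stats::quantile(null, 0.975, names = FALSE),
       observed = observed,
       p = p,
       p_display = if (!degenerate && p == 0) sprintf("<%.0e", 1 / n)
                   else format(p, digits = 3),
       degenerate = degenerate)
}

paired_t_row <- function(comparison, a, b) {
  d <- a - b
  n <- length(d)
  if (n < 3) stop("paired comparison requires at least 3 pairs")
  mean_diff <- mean(d) * 100          # percentage points
  if (stats::sd(d) == 0) {
    return(tibble::tibble(
      comparison = comparison, n = n, mean_diff = mean_diff,
      t = if (mean_diff == 0) 0 else Inf * sign(mean_diff),
      p = if (mean_diff == 0) 1 else 0,
      exact_difference = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  tibble::tibble(comparison = comparison, n = n, mean_diff = mean_diff,
                 t = unname(tt$statistic), p = tt$p.value,
                 exact_difference = FALSE)
}

#' Paired comparisons between classification models
#'
#' Two-tailed paired t tests on within-participant error rates: each model
#' against its mean bootstrap-null error, the combined model against the
#' affect model, affect against physiology, and each individualized (LOBO)
#' model against its group (LOSO) counterpart; BH-FDR across the family.
#' Mean differences are in percentage points.
#'
#' @param results Tibble with columns `participant_id`, `scheme`
#'   (`"lobo"`/`"loso"`), `model` (`"m1"`/`"m2"`/`"m3"`), `error`, and
#'   `null_mean` (per-participant bootstrap-null mean error).
#' @return Tibble of comparisons with `mean_diff`, `t`, `p`, `p_fdr`.
#' @export
compare_models <- function(results) {
  need <- c("participant_id", "scheme", "model", "error", "null_mean")
  miss <- setdiff(need, names(results))
  if (length(miss)) stop("results lacks columns: ", paste(miss, collapse = ", "))
  rows <- list()
  get <- function(scheme, model) {
    r <- results[results$scheme == scheme & results$model == model, ]
    r[order(r$participant_id), ]
  }
  align <- function(a, b) {
    ids <- intersect(a$participant_id, b$participant_id)
    list(a = a[match(ids, a$participant_id), ],
         b = b[match(ids, b$participant_id), ])
  }
  for (scheme in unique(results$scheme))
    for (model in unique(results$model)) {
      r <- get(scheme, model)
      if (nrow(r))
        rows[[paste(scheme, model, "vs_null")]] <- paired_t_row(
          paste0(scheme, ":", model, " vs null"), r$error, r$null_mean)
    }
  for (scheme in unique(results$scheme)) {
    for (pair in list(c("m3", "m1"), c("m1", "m2"))) {
      a <- get(scheme, pair[1]); b <- get(scheme, pair[2])
      if (nrow(a) && nrow(b)) {
        al <- align(a, b)
        rows[[paste(scheme, pair[1], pair[2])]] <- paired_t_row(
          paste0(scheme, ":", pair[1], " vs ", pair[2]),
          al$a$error, al$b$error)
      }
    }
  }
  if (all(c("lobo", "loso") %in% results$scheme))
    for (model in unique(results$model)) {
      a <- get("lobo", model); b <- get("loso", model)
      if (nrow(a) && nrow(b)) {
        al <- align(a, b)
        rows[[paste("lobo_loso", model)]] <- paired_t_row(
          paste0("lobo vs loso:", model), al$a$error, al$b$error)
      }
    }
  out <- dplyr::bind_rows(rows)
  out$p_fdr <- fdr_correct(out$p)
  out
}

#' Run the full classification analysis of a cohort
#'
#' Convenience wrapper: builds the three feature sets, runs LOBO and/or
#' LOSO per set, attaches each participant's bootstrap null, and returns the
#' long results table plus the paired comparisons.
#'
#' @param data Analysis table with features.
#' @param schemes Subset of `c("lobo", "loso")`.
#' @param models Subset of `c("m1", "m2", "m3")`.
#' @param config A [forest_config()].
#' @param n_null Bootstrap-null resamples per participant.
#' @param seed Seed.
#' @return List with `results` (long tibble incl. `null_mean`, `null_q025`,
#'   `null_q975`, `p_vs_null`) and `comparisons` (from [compare_models()]
#'   when both schemes and 3+ participants are present).
#' @export
classify_cohort <- function(data, schemes = c("lobo", "loso"),
                            models = c("m1", "m2", "m3"),
                            config = forest_config(), n_null = 10000,
                            seed = 1L) {
  fs <- build_feature_sets(data)
  rows <- list()
  for (scheme in schemes) {
    fun <- if (scheme == "lobo") lobo_classify else loso_classify
    for (model in models) {
      r <- fun(fs$data, fs[[model]], config, seed = derive_seed(seed, scheme, model))
      pr <- attr(r, "predictions")
      nulls <- lapply(r$participant_id, function(pid) {
        pi <- pr[pr$participant_id == pid, ]
        bootstrap_null(pi$pred, pi$truth, n = n_null,
                       seed = derive_seed(seed, "null", scheme, model, pid))
      })
      r$scheme <- scheme
      r$model <- model
      r$null_mean <- vapply(nulls, `[[`, numeric(1), "null_mean")
      r$null_q025 <- vapply(nulls, `[[`, numeric(1), "q025")
      r$null_q975 <- vapply(nulls, `[[`, numeric(1), "q975")
      r$p_vs_null <- vapply(nulls, `[[`, numeric(1), "p")
      rows[[paste(scheme, model)]] <- r
    }
  }
  results <- dplyr::bind_rows(rows)
  comparisons <- tryCatch(compare_models(results), error = function(e) NULL)
  list(results = results, comparisons = comparisons)
}

#' Label-permutation null for a classification scheme
#'
#' The slow cross-check of [bootstrap_null()]: permutes week labels within
#' each participant, reruns the chosen cross-validation scheme, and collects
#' the resulting error rates — the chance-level band of the full refitting
#' pipeline rather than of resampled predictions. Expensive (each
#' permutation refits every fold); intended for small `n_perm` sanity runs
#' and for estimating chance bands in reports.
#'
#' @param data Analysis table with features.
#' @param feature_cols Feature columns.
#' @param scheme `"lobo"` or `"loso"`.
#' @param n_perm Number of label permutations (default 200; use far fewer
#'   for interactive checks).
#' @param config A [forest_config()].
#' @param seed Seed (labels and forests).
#' @return List with `errors` (n_perm x participants matrix of error rates)
#'   and `band` (2.5% and 97.5% quantiles of the pooled mean error).
#' @export
permutation_null <- function(data, feature_cols, scheme = c("lobo", "loso"),
                             n_perm = 200, config = forest_config(),
                             seed = 1L) {
  scheme <- match.arg(scheme)
  fun <- if (scheme == "lobo") lobo_classify else loso_classify
  means <- numeric(n_perm)
  errs <- list()
  for (b in seq_len(n_perm)) {
    d <- data
    d$week_type <- withr::with_seed(
      derive_seed(seed, "perm", b),
      unlist(lapply(split(d$week_type, d$participant_id), sample),
             use.names = FALSE)[order(order(d$participant_id))])
    r <- fun(d, feature_cols, config, seed = derive_seed(seed, "permfit", b))
    errs[[b]] <- r$error
    means[b] <- mean(r$error)
  }
  list(errors = do.call(rbind, errs),
       band = stats::quantile(means, c(0.025, 0.975), names = FALSE))
}
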