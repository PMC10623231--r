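# LOBO/LOSO random-forest classification, bootstrap nulls, comparisons.

# small synthetic classification table: per-participant week separation d,
# optionally sign-flipped per participant
clf_table <- function(n_part = 5, n_beep = 30, d = 0, seed = 1,
                      sign_flip = FALSE) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_part), function(i) {
      wk <- rep(c("control", "stress"), each = n_beep / 2)
      s <- if (sign_flip) sample(c(-1, 1), 1) else 1
      tibble::tibble(
        participant_id = sprintf("P%02d", i),
        beep_id = sprintf("P%02d_b%d", i, seq_len(n_beep)),
        week_type = wk,
        pa_pc = rnorm(n_beep) + s * d * (wk == "stress"),
        na_pc = rnorm(n_beep) - s * d * (wk == "stress"))
    })
    dplyr::bind_rows(rows)
  })
}

test_that("leakage control: a label-copy feature classifies perfectly", {
  d <- clf_table(3, 20)
  d$leak <- as.numeric(d$week_type == "stress")
  res <- lobo_classify(d, c("pa_pc", "leak"), forest_config(num_trees = 100),
                       seed = 2)
  expect_true(all(res$error <= 0.05))
})

test_that("pure-noise features classify at the bootstrap-null chance level", {
  d <- clf_table(4, 40, d = 0, seed = 7)
  res <- lobo_classify(d, c("pa_pc", "na_pc"),
                       forest_config(num_trees = 200), seed = 3)
  pr <- attr(res, "predictions")
  for (pid in res$participant_id) {
    pi <- pr[pr$participant_id == pid, ]
    bn <- bootstrap_null(pi$pred, pi$truth, n = 2000, seed = 11)
    expect_gt(res$error[res$participant_id == pid], bn$q025 - 0.05)
  }
  expect_gt(mean(res$error), 0.35)
})

test_that("single-week participants are excluded with a recorded reason", {
  d <- clf_table(3, 20)
  d$week_type[d$participant_id == "P01"] <- "stress"
  res <- lobo_classify(d, c("pa_pc", "na_pc"),
                       forest_config(num_trees = 50), seed = 1)
  expect_false("P01" %in% res$participant_id)
  expect_true("P01" %in% attr(res, "excluded"))
})

test_that("classification is deterministic under a fixed seed", {
  d <- clf_table(3, 20, d = 1)
  r1 <- lobo_classify(d, c("pa_pc", "na_pc"), forest_config(num_trees = 100),
                      seed = 5)
  r2 <- lobo_classify(d, c("pa_pc", "na_pc"), forest_config(num_trees = 100),
                      seed = 5)
  expect_identical(r1$error, r2$error)
})

test_that("LOSO approaches LOBO when the cohort is exchangeable replicas of
           one participant's generating process", {
  copies <- dplyr::bind_rows(lapply(1:3, function(i) {
    b <- clf_table(1, 40, d = 1.2, seed = 13 + i)
    b$participant_id <- sprintf("C%02d", i)
    b$beep_id <- paste0(b$participant_id, "_", seq_len(nrow(b)))
    b
  }))
  lobo <- lobo_classify(copies, c("pa_pc", "na_pc"),
                        forest_config(num_trees = 300), seed = 4)
  loso <- loso_classify(copies, c("pa_pc", "na_pc"),
                        forest_config(num_trees = 300), seed = 4)
  expect_equal(mean(loso$error), mean(lobo$error), tolerance = 0.12)
})

test_that("bootstrap null matches the binomial closed form and flags extremes", {
  labels <- rep(c("control", "stress"), 40)
  preds <- withr::with_seed(3, sample(labels))
  bn <- bootstrap_null(preds, labels, n = 10000, seed = 5)
  expect_equal(bn$null_mean, 0.5, tolerance = 0.01)
  # SD of the null error at e = 0.5, n = 80 beeps: sqrt(0.25 / 80)
  expect_equal(bn$null_sd, sqrt(0.25 / 80), tolerance = 0.005)
  # perfect predictions: p below the bootstrap resolution
  bp <- bootstrap_null(labels, labels, n = 10000, seed = 5)
  expect_equal(bp$p, 0)
  expect_match(bp$p_display, "<1e-04")
  # degenerate single-class predictions -> p = 1 with flag
  bd <- bootstrap_null(rep("stress", 80), labels, n = 1000, seed = 5)
  expect_true(bd$degenerate)
  expect_equal(bd$p, 1)
  expect_warning(bootstrap_null(preds, labels, n = 50, seed = 1), "unreliable")
})

test_that("paired model comparisons handle identical and degenerate cases", {
  res <- tibble::tibble(
    participant_id = rep(sprintf("P%d", 1:5), 2),
    scheme = "lobo",
    model = rep(c("m1", "m2"), each = 5),
    error = c(rep(0.30, 5), rep(0.35, 5)),
    null_mean = 0.5)
  cmp <- compare_models(res)
  r12 <- cmp[cmp$comparison == "lobo:m1 vs m2", ]
  expect_equal(r12$mean_diff, -5)
  expect_true(r12$exact_difference)
  # identical error vectors: zero difference, t = 0
  res2 <- res
  res2$error <- 0.3
  cmp2 <- compare_models(res2)
  expect_equal(cmp2$mean_diff[cmp2$comparison == "lobo:m1 vs m2"], 0)
  expect_equal(cmp2$t[cmp2$comparison == "lobo:m1 vs m2"], 0)
  expect_true(all(cmp2$p_fdr >= cmp2$p - 1e-12))
  expect_error(compare_models(res[c(1, 6), ]), "3 pairs")
})

test_that("constructed heterogeneity: individual signal, no group signal", {
  # strong per-participant effects with random signs: LOBO finds structure,
  # LOSO cannot generalize across participants
  d <- clf_table(6, 40, d = 1.5, seed = 23, sign_flip = TRUE)
  lobo <- lobo_classify(d, c("pa_pc", "na_pc"),
                        forest_config(num_trees = 200), seed = 6)
  loso <- loso_classify(d, c("pa_pc", "na_pc"),
                        forest_config(num_trees = 200), seed = 6)
  expect_lt(mean(lobo$error), 0.35)
  expect_gt(mean(loso$error), mean(lobo$error))
})

test_that("label-permutation null centres on chance", {
  d <- clf_table(3, 12, d = 2, seed = 9)
  pn <- permutation_null(d, c("pa_pc", "na_pc"), scheme = "lobo",
                         n_perm = 4, config = forest_config(num_trees = 50),
                         seed = 2)
  expect_equal(dim(pn$errors), c(4, 3))
  expect_gt(mean(pn$errors), 0.3)   # permuted labels carry no signal
  expect_lt(pn$band[1], pn$band[2])
})
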