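test_that("holdout masks the requested fraction of observed ratio cells", {
  g <- generate_cohort(cohort_spec(missing_rate = c(tsh = 0.05)), seed = 1)
  fm <- encode_features(g$cohort)
  n_obs <- sum(fm$M[, "chol_hdl"])
  expect_equal(n_obs, 300L)  # no MCAR on the ratio in this spec
  ho <- holdout_chol_hdl(fm, fraction = 0.2, seed = 1)
  expect_equal(nrow(ho$heldout), 60L)
  expect_true(all(ho$fm_train$M[ho$heldout$row, "chol_hdl"] == 0))
  expect_true(all(fm$M[ho$heldout$row, "chol_hdl"] == 1))
  # placeholder never equals the truth it replaced
  expect_true(all(ho$fm_train$X[ho$heldout$row, "chol_hdl"] !=
                    ho$heldout$scaled_truth))
  # held-out clinical values invert the affine map of the encoding
  d <- g$cohort$data
  expect_equal(ho$heldout$clinical_truth, d$chol_hdl[ho$heldout$row],
               tolerance = 1e-9)

  # different seeds give different sets with roughly hypergeometric overlap
  ho2 <- holdout_chol_hdl(fm, fraction = 0.2, seed = 2)
  ov <- length(intersect(ho$heldout$row, ho2$heldout$row))
  expect_false(identical(ho$heldout$row, ho2$heldout$row))
  expect_lt(abs(ov - 60 * 60 / 300), 12)  # mean 12, generous band
  expect_error(holdout_chol_hdl(fm, fraction = 0.001), "zero held-out")
})

test_that("risk accuracy scores exact category matches and fills the confusion table", {
  lf <- lowrank_feature_matrix(n = 60, p = 8, k = 2, seed = 7)
  fm <- lf$fm
  ho <- holdout_chol_hdl(fm, fraction = 0.2, seed = 7)
  sex <- rep(c("M", "F"), length.out = 60)
  # a perfect oracle fit: the ground-truth factors reproduce X exactly
  oracle <- structure(list(U = lf$truth$U, V = lf$truth$V, k = 2,
                           trace = data.frame(iteration = 1, objective = 0,
                                              step_error = 0),
                           converged = TRUE, iterations = 1L,
                           snapshots = NULL, config = list()),
                      class = "ognmf_fit")
  res <- risk_accuracy(oracle, fm, ho$heldout, sex)
  expect_equal(res$accuracy, 1.0)
  expect_equal(sum(diag(res$confusion)), nrow(ho$heldout))
  expect_equal(sum(res$confusion), nrow(ho$heldout))

  # shifting every imputed ratio one category up zeroes the accuracy
  # (construct truth in level 2 and predictions in level 3 for males)
  fm2 <- fm
  fm2$scaling$chol_hdl <- list(kind = "continuous", offset = 5.0, scale = 0)
  # offset 5, scale 0: every decoded value is 5.0 -> level 2 for males
  ho2 <- ho
  ho2$heldout$clinical_truth <- rep(8.0, nrow(ho$heldout))  # level 3 (M)
  res2 <- risk_accuracy(oracle, fm2, ho2$heldout, rep("M", 60))
  expect_equal(res2$accuracy, 0.0)
  expect_equal(sum(diag(res2$confusion)), 0)
  expect_equal(sum(res2$confusion["3", ]), nrow(ho$heldout))

  expect_error(risk_accuracy(oracle, fm, ho$heldout,
                             rep(NA_character_, 60)), "missing sex")
})

test_that("near-exact reconstruction gives >= 90% held-out risk accuracy", {
  lf <- lowrank_feature_matrix(n = 100, p = 10, k = 2, seed = 11)
  fm <- lf$fm
  ho <- holdout_chol_hdl(fm, fraction = 0.1, seed = 11)
  fit <- fit_ognmf(ho$fm_train$X, ho$fm_train$M, k = 2, epsilon = 1e-10,
                   max_iter = 4000, ortho_weight = 0, seed = 11)
  sex <- rep(c("M", "F"), length.out = 100)
  res <- risk_accuracy(fit, fm, ho$heldout, sex)
  expect_gte(res$accuracy, 0.9)
})

test_that("factorization beats mean imputation on structured (low-rank) cohorts", {
  wins <- 0L
  losses <- 0L
  diffs <- numeric(20)
  for (s in 1:20) {
    lf <- lowrank_feature_matrix(n = 60, p = 10, k = 2, seed = 100 + s)
    fm <- lf$fm
    ho <- holdout_chol_hdl(fm, fraction = 0.2, seed = s)
    fit <- fit_ognmf(ho$fm_train$X, ho$fm_train$M, k = 2, epsilon = 1e-8,
                     max_iter = 1500, ortho_weight = 0, seed = s)
    sex <- rep(c("M", "F"), length.out = 60)
    a_nmf <- risk_accuracy(fit, fm, ho$heldout, sex)$accuracy
    a_mean <- mean_imputation_accuracy(ho$fm_train, ho$heldout, sex)
    wins <- wins + (a_nmf > a_mean)
    losses <- losses + (a_nmf < a_mean)
    diffs[s] <- a_nmf - a_mean
  }
  # paired over seeds: never worse, and clearly better in aggregate (ties
  # occur when the held-out ratios happen to fall in a single band, where
  # the constant imputer is already perfect)
  expect_equal(losses, 0L)
  expect_gte(wins, 10L)
  expect_gt(mean(diffs), 0.1)
})

test_that("relative accuracy differences follow the printed convention", {
  expect_equal(compare_models(0.6759, 0.6159), 9.7)
  expect_equal(compare_models(0.5, 0.5), 0.0)
  expect_equal(compare_models(0.5, 0.25), 100.0)
  expect_equal(compare_models(0.25, 0.5), -50.0)
  expect_error(compare_models(0, 0.5), "0, 1")
  expect_error(compare_models(1.2, 0.5), "0, 1")
})

test_that("cohort summary: identical groups are indistinguishable", {
  d <- tiny_cohort()$data
  d2 <- d
  d2$ssn_status <- rev(c("SSN-", "SSN-", "SSN+", "SSN+"))
  both <- rbind(d, d, d2, d2)  # identical composition in the two groups
  both$ssn_status <- rep(c("SSN-", "SSN+"), each = 8)
  s <- suppressWarnings(cohort_summary(cohort_table(both)))
  expect_true(all(abs(s$continuous$mean_1 - s$continuous$mean_2) < 1e-12))
  ok <- !is.na(s$continuous$p_welch)
  expect_true(all(s$continuous$p_welch[ok] > 0.999))
  expect_true(all(s$binary$p_chisq > 0.999))
})

test_that("cohort summary reproduces the two-proportion arithmetic of printed counts", {
  # 104/199 vs 39/101 seropositive: 52% vs 39%, significant without correction
  n1 <- 199; n2 <- 101; x1 <- 104; x2 <- 39
  d <- data.frame(
    ssn_status = rep(c("SSN-", "SSN+"), c(n1, n2)),
    account_number = as.character(seq_len(n1 + n2)),
    gender = "M", age = 50, race = "chinese", tsh = 2, psa = 1,
    hbsab = c(rep(c("pos", "neg"), c(x1, n1 - x1)),
              rep(c("pos", "neg"), c(x2, n2 - x2))),
    hbsag = "neg", glu = 90, chol = 200, tg = 150, hdl = 50,
    ldl = 120, chol_hdl = 4, stringsAsFactors = FALSE
  )
  s <- suppressWarnings(cohort_summary(cohort_table(d)))
  row <- s$binary[s$binary$variable == "hbsab", ]
  expect_equal(round(row$pct_1), 52)
  expect_equal(round(row$pct_2), 39)
  expect_lt(row$p_chisq, 0.05)
  expect_equal(row$p_chisq,
               prop.test(c(x1, x2), c(n1, n2), correct = FALSE)$p.value)
})

test_that("summaries of default synthetic cohorts point the printed directions", {
  correct <- 0L
  for (s in 1:20) {
    g <- generate_cohort(cohort_spec(), seed = 300 + s)
    d <- g$truth$data
    neg <- d$ssn_status == "SSN-"
    dir_ok <- mean(d$chol[neg]) > mean(d$chol[!neg]) &&
      mean(d$tg[neg]) > mean(d$tg[!neg]) &&
      mean(d$age[neg]) > mean(d$age[!neg])
    correct <- correct + dir_ok
  }
  expect_gte(correct, 18L)
  # and the group means sit near the configured targets
  g <- generate_cohort(cohort_spec(), seed = 321)
  s <- suppressWarnings(cohort_summary(g$cohort))
  chol <- s$continuous[s$continuous$variable == "chol", ]
  expect_lt(abs(chol$mean_1 - 219.6), 3 * 41.1 / sqrt(180))
  expect_lt(abs(chol$mean_2 - 208.9), 3 * 39 / sqrt(90))
})

test_that("figure export writes deterministic backing data", {
  g <- generate_cohort(cohort_spec(n_ssn_neg = 60, n_ssn_pos = 40), seed = 5)
  ex <- run_risk_experiment(g$cohort, seed = 5, max_iter = 60,
                            epsilon = 1e-3, snapshots = TRUE)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  f1 <- export_figures(ex$result, dir1)
  f2 <- export_figures(ex$result, dir2)
  for (nm in c("step_error_csv", "accuracy_csv", "bands_csv")) {
    expect_true(file.exists(f1[[nm]]))
    expect_identical(readLines(f1[[nm]]), readLines(f2[[nm]]))
  }
  expect_true(all(file.exists(f1[c("step_error_png", "accuracy_png",
                                   "bands_png")])))
  # without snapshots there is nothing to plot
  ex0 <- run_risk_experiment(g$cohort, seed = 5, max_iter = 10,
                             epsilon = 1e-3)
  expect_error(export_figures(ex0$result, dir1), "snapshots")
})

test_that("the experiment wrapper wires the pipeline together", {
  g <- generate_cohort(cohort_spec(n_ssn_neg = 80, n_ssn_pos = 40), seed = 9)
  ex <- run_risk_experiment(g$cohort, seed = 9, epsilon = 1e-4,
                            max_iter = 400, mlr = TRUE)
  expect_true(ex$result$accuracy >= 0 && ex$result$accuracy <= 1)
  expect_true(ex$mean_baseline_accuracy >= 0 &&
                ex$mean_baseline_accuracy <= 1)
  expect_true(ex$mlr_accuracy >= 0 && ex$mlr_accuracy <= 1)
  expect_equal(sum(ex$result$confusion), nrow(ex$heldout))
})
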