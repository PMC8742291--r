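#' Hold out observed CHOL/HDL cells for evaluation
#'
#' Masks a seeded random fraction of the observed CHOL/HDL cells in the
#' feature matrix, recording their true values so that imputation accuracy
#' can be scored. Held-out cells receive the training column mean (scaled
#' space) as a placeholder and \code{M = 0}, so the solver never sees the
#' truth.
#'
#' @param fm a \code{\link{encode_features}} result.
#' @param fraction fraction of observed CHOL/HDL cells to hold out,
#'   in (0, 1).
#' @param seed integer seed.
#' @return List with \code{fm_train} (masked copy) and \code{heldout}
#'   (data frame: row, scaled_truth, clinical_truth).
#' @export
holdout_chol_hdl <- function(fm, fraction = 0.2, seed = 1) {
  stopifnot(inherits(fm, "feature_matrix"), fraction > 0, fraction < 1)
  col <- "chol_hdl"
  obs <- which(fm$M[, col] == 1)
  n_hold <- floor(fraction * length(obs))
  if (n_hold < 1L) stop("fraction leaves zero held-out cells", call. = FALSE)
  .with_seed(seed, {
    held <- sort(sample(obs, n_hold))
    fm_train <- fm
    fm_train$M[held, col] <- 0
    remaining <- setdiff(obs, held)
    if (length(remaining) == 0L) {
      stop("holdout would empty the CHOL/HDL column", call. = FALSE)
    }
    fm_train$X[held, col] <- mean(fm$X[remaining, col])
    sc <- fm$scaling[[col]]
    scaled <- fm$X[held, col]
    list(fm_train = fm_train,
         heldout = data.frame(row = held, scaled_truth = scaled,
                              clinical_truth = sc$offset + scaled * sc$scale))
  })
}

#' Risk-prediction accuracy on held-out CHOL/HDL cells
#'
#' Imputes every held-out CHOL/HDL cell from the factorization, classifies
#' the imputed ratio into the four risk levels, and scores exact-match
#' accuracy against the category of the true ratio. When the fit carries
#' per-iteration snapshots, the same scoring is repeated at every iteration,
#' yielding the accuracy-vs-iteration trajectory and the per-level
#' soft-membership mass ("band width") trajectory alongside the step-error
#' series.
#'
#' @param fit an \code{ognmf_fit} (trained on the held-out mask).
#' @param fm the \emph{training} \code{feature_matrix} (scaling metadata is
#'   what matters; it is shared with the original).
#' @param heldout held-out table from \code{\link{holdout_chol_hdl}}.
#' @param sex per-row sex vector (\code{"M"}/\code{"F"}) for the whole
#'   cohort; must be non-missing for every held-out row.
#' @param thresholds a \code{\link{risk_thresholds}}.
#' @return An object of class \code{eval_result}: \code{accuracy},
#'   \code{confusion} (4 x 4), \code{predicted}, \code{truth},
#'   \code{accuracy_series}, \code{step_error_series}, \code{soft_series}
#'   (iterations x 4 mean membership, when snapshots exist), and the
#'   held-out table.
#' @export
risk_accuracy <- function(fit, fm, heldout, sex,
                          thresholds = risk_thresholds()) {
  stopifnot(inherits(fit, "ognmf_fit"), nrow(heldout) > 0)
  sx <- sex[heldout$row]
  if (any(is.na(sx))) {
    stop("missing sex for held-out row(s) ",
         paste(heldout$row[is.na(sx)], collapse = ", "), call. = FALSE)
  }
  truth <- classify_ratio(sx, heldout$clinical_truth, thresholds)
  score <- function(U, V) {
    j <- match("chol_hdl", fm$features)
    xhat <- as.numeric(U[heldout$row, , drop = FALSE] %*% V[, j, drop = FALSE])
    val <- decode_column(fm, xhat, "chol_hdl")
    val <- pmax(val, .Machine$double.eps)  # classification needs ratio > 0
    classify_ratio(sx, val, thresholds)
  }
  predicted <- score(fit$U, fit$V)
  confusion <- table(factor(truth, 1:4), factor(predicted, 1:4))
  acc <- mean(predicted == truth)

  acc_series <- soft_series <- NULL
  if (!is.null(fit$snapshots)) {
    acc_series <- vapply(fit$snapshots,
                         function(s) mean(score(s$U, s$V) == truth),
                         numeric(1))
    j <- match("chol_hdl", fm$features)
    soft_series <- t(vapply(fit$snapshots, function(s) {
      xhat <- as.numeric(s$U[heldout$row, , drop = FALSE] %*%
                           s$V[, j, drop = FALSE])
      val <- pmax(decode_column(fm, xhat, "chol_hdl"), .Machine$double.eps)
      w <- matrix(0, length(val), 4L)
      for (g in unique(sx)) {
        sel <- sx == g
        w[sel, ] <- soft_assign(g, val[sel], thresholds)
      }
      colMeans(w)
    }, numeric(4)))
    colnames(soft_series) <- paste0("level", 1:4)
  }
  structure(list(accuracy = acc, confusion = confusion,
                 predicted = predicted, truth = truth,
                 accuracy_series = acc_series,
                 step_error_series = fit$trace$step_error,
                 soft_series = soft_series, heldout = heldout),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("eval_result: %.2f%% exact-match risk accuracy on %d held-out cells\n",
              100 * x$accuracy, nrow(x$heldout)))
  invisible(x)
}

#' Column-mean-imputation baseline accuracy
#'
#' Scores the trivial imputer that predicts, for every held-out cell, the
#' mean of the training-observed CHOL/HDL column; the natural floor any
#' model-based imputer must beat.
#'
#' @inheritParams risk_accuracy
#' @param fm_train the training feature matrix (held-out cells masked).
#' @return Exact-match accuracy in \[0, 1\].
#' @export
mean_imputation_accuracy <- function(fm_train, heldout, sex,
                                     thresholds = risk_thresholds()) {
  col <- "chol_hdl"
  obs <- fm_train$M[, col] == 1
  pred_scaled <- mean(fm_train$X[obs, col])
  val <- decode_column(fm_train, rep(pred_scaled, nrow(heldout)), col)
  val <- pmax(val, .Machine$double.eps)
  sx <- sex[heldout$row]
  truth <- classify_ratio(sx, heldout$clinical_truth, thresholds)
  mean(classify_ratio(sx, val, thresholds) == truth)
}

#' Multinomial-logistic-regression baseline accuracy
#'
#' Trains \code{\link{fit_mlr}} on the rows whose CHOL/HDL was available
#' during training (labels = risk category of the observed ratio; features =
#' every encoded column except CHOL/HDL, with unobserved cells as
#' \code{NA}), then predicts the risk category of the held-out rows.
#'
#' @inheritParams mean_imputation_accuracy
#' @param lambda ridge penalty for the baseline.
#' @return Exact-match accuracy in \[0, 1\].
#' @export
mlr_risk_accuracy <- function(fm_train, heldout, sex,
                              thresholds = risk_thresholds(),
                              lambda = 1e-3) {
  col <- "chol_hdl"
  feats <- setdiff(fm_train$features, col)
  X <- fm_train$X[, feats, drop = FALSE]
  X[fm_train$M[, feats] == 0] <- NA
  train_rows <- setdiff(which(fm_train$M[, col] == 1), heldout$row)
  sc <- fm_train$scaling[[col]]
  train_ratio <- sc$offset + fm_train$X[train_rows, col] * sc$scale
  y_train <- classify_ratio(sex[train_rows], pmax(train_ratio, 1e-9),
                            thresholds)
  model <- fit_mlr(X[train_rows, , drop = FALSE], y_train, lambda = lambda)
  pred <- predict_mlr(model, X[heldout$row, , drop = FALSE])$class
  truth <- classify_ratio(sex[heldout$row], heldout$clinical_truth,
                          thresholds)
  mean(pred == truth)
}

#' Relative accuracy difference between two models
#'
#' \eqn{100 (a_1 - a_2) / a_2}, reported to one decimal — e.g. accuracies
#' 0.6759 vs 0.6159 give 9.7, i.e. the second model is 9.7\% less accurate.
#'
#' @param acc1,acc2 accuracies as fractions in (0, 1].
#' @return Signed percent difference, rounded to one decimal.
#' @export
compare_models <- function(acc1, acc2) {
  stopifnot(length(acc1) == 1L, length(acc2) == 1L)
  if (!is.finite(acc1) || !is.finite(acc2) || acc1 <= 0 || acc1 > 1 ||
      acc2 <= 0 || acc2 > 1) {
    stop("accuracies must be fractions in (0, 1]", call. = FALSE)
  }
  round(100 * (acc1 - acc2) / acc2, 1)
}

#' Group-stratified cohort summary with tests
#'
#' The standard screening-cohort comparison table: per-group mean, SD, min
#' and max for each continuous variable with two-sample t-test p-values
#' (both Welch and pooled-variance, so either convention can be read off),
#' and per-group counts and percentages for binary variables with
#' two-proportion chi-square p-values (with and without continuity
#' correction). A variable with fewer than two observations in a group has
#' its test skipped with a warning.
#'
#' @param cohort a \code{cohort_table}.
#' @param group_by grouping feature, default SSN status.
#' @return An object of class \code{cohort_summary} with elements
#'   \code{continuous} and \code{binary} (data frames).
#' @export
cohort_summary <- function(cohort, group_by = "ssn_status") {
  stopifnot(inherits(cohort, "cohort_table"))
  d <- cohort$data
  cb <- cohort$codebook
  g <- d[[group_by]]
  lev <- cb[[group_by]]$levels
  if (any(table(factor(g, lev)) == 0)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  cont_vars <- names(cb)[vapply(cb, function(x) x$kind == "continuous",
                                logical(1))]
  rows <- lapply(cont_vars, function(v) {
    a <- d[[v]][g == lev[1L]]; a <- a[!is.na(a)]
    b <- d[[v]][g == lev[2L]]; b <- b[!is.na(b)]
    p_welch <- p_pooled <- NA_real_
    if (length(a) < 2L || length(b) < 2L) {
      warning("skipping t-test for '", v, "': a group has <2 observations",
              call. = FALSE)
    } else if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
      p_welch <- p_pooled <- 1   # identical degenerate groups
    } else {
      p_welch <- stats::t.test(a, b)$p.value
      p_pooled <- stats::t.test(a, b, var.equal = TRUE)$p.value
    }
    data.frame(variable = v,
               mean_1 = mean(a), sd_1 = stats::sd(a),
               min_1 = suppressWarnings(min(a)),
               max_1 = suppressWarnings(max(a)),
               mean_2 = mean(b), sd_2 = stats::sd(b),
               min_2 = suppressWarnings(min(b)),
               max_2 = suppressWarnings(max(b)),
               p_welch = p_welch, p_pooled = p_pooled)
  })
  continuous <- do.call(rbind, rows)

  bin_vars <- setdiff(
    names(cb)[vapply(cb, function(x) x$kind == "binary", logical(1))],
    group_by)
  brows <- lapply(bin_vars, function(v) {
    pos_level <- cb[[v]]$levels[2L]
    a <- d[[v]][g == lev[1L]]; a <- a[!is.na(a)]
    b <- d[[v]][g == lev[2L]]; b <- b[!is.na(b)]
    x1 <- sum(a == pos_level); n1 <- length(a)
    x2 <- sum(b == pos_level); n2 <- length(b)
    p_cor <- p_unc <- NA_real_
    if (n1 >= 2L && n2 >= 2L) {
      p_cor <- suppressWarnings(
        stats::prop.test(c(x1, x2), c(n1, n2))$p.value)
      p_unc <- suppressWarnings(
        stats::prop.test(c(x1, x2), c(n1, n2), correct = FALSE)$p.value)
    } else {
      warning("skipping proportion test for '", v, "'", call. = FALSE)
    }
    data.frame(variable = v, level = pos_level,
               count_1 = x1, n_1 = n1, pct_1 = 100 * x1 / n1,
               count_2 = x2, n_2 = n2, pct_2 = 100 * x2 / n2,
               p_chisq_corrected = p_cor, p_chisq = p_unc)
  })
  binary <- do.call(rbind, brows)
  structure(list(continuous = continuous, binary = binary,
                 groups = lev, group_by = group_by),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, digits = 3, ...) {
  cat(sprintf("cohort_summary by %s (%s vs %s)\n", x$group_by,
              x$groups[1L], x$groups[2L]))
  print(format(x$continuous, digits = digits), row.names = FALSE)
  print(format(x$binary, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Export convergence and band figures
#'
#' Writes the three standard diagnostic figures for a fitted evaluation —
#' per-level soft-membership band widths across iterations (stacked area),
#' step error vs iteration, and held-out risk accuracy vs iteration — plus
#' the plain-CSV data behind each plot (the CSVs are byte-deterministic for
#' identical inputs).
#'
#' @param result an \code{eval_result} carrying iteration series (fit with
#'   \code{keep_snapshots = TRUE}).
#' @param dir output directory, created if needed.
#' @return Named character vector of the files written, invisibly.
#' @export
export_figures <- function(result, dir) {
  stopifnot(inherits(result, "eval_result"))
  if (is.null(result$accuracy_series) || is.null(result$soft_series)) {
    stop("result carries no iteration series; fit with keep_snapshots = TRUE",
         call. = FALSE)
  }
  if (length(result$step_error_series) == 0L) {
    stop("empty result", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  it <- seq_along(result$step_error_series)

  files <- c()
  wr <- function(df, name) {
    path <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(df, path, row.names = FALSE)
    files[[paste0(name, "_csv")]] <<- path
    path
  }

  err_df <- data.frame(iteration = it, step_error = result$step_error_series)
  wr(err_df, "step_error")
  p1 <- ggplot2::ggplot(err_df, ggplot2::aes(x = iteration, y = step_error)) +
    ggplot2::geom_line() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "step error (relative)",
                  title = "Convergence of the masked factorization")
  files[["step_error_png"]] <- file.path(dir, "step_error.png")
  ggplot2::ggsave(files[["step_error_png"]], p1, width = 5, height = 3.5,
                  dpi = 150)

  acc_df <- data.frame(iteration = it, accuracy = result$accuracy_series)
  wr(acc_df, "accuracy")
  p2 <- ggplot2::ggplot(acc_df, ggplot2::aes(x = iteration, y = accuracy)) +
    ggplot2::geom_line() + ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "iteration", y = "held-out risk accuracy",
                  title = "Accuracy trajectory")
  files[["accuracy_png"]] <- file.path(dir, "accuracy.png")
  ggplot2::ggsave(files[["accuracy_png"]], p2, width = 5, height = 3.5,
                  dpi = 150)

  sb <- as.data.frame(result$soft_series)
  sb$iteration <- it
  long <- stats::reshape(sb, direction = "long",
                         varying = paste0("level", 1:4), v.names = "weight",
                         timevar = "level", times = paste0("level", 1:4),
                         idvar = "iteration")
  wr(long[order(long$iteration, long$level),
          c("iteration", "level", "weight")], "bands")
  p3 <- ggplot2::ggplot(long, ggplot2::aes(x = iteration, y = weight,
                                           fill = level)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::labs(x = "iteration", y = "mean soft membership",
                  title = "Risk-level band widths across iterations")
  files[["bands_png"]] <- file.path(dir, "bands.png")
  ggplot2::ggsave(files[["bands_png"]], p3, width = 5, height = 3.5,
                  dpi = 150)
  invisible(unlist(files))
}

#' Run the full imputation-and-risk experiment on a cohort
#'
#' Convenience wrapper chaining the pipeline: encode the cohort, hold out a
#' fraction of observed CHOL/HDL cells, fit the masked factorization on the
#' thinned mask, and score held-out risk accuracy against the column-mean
#' and (optionally) multinomial-logistic-regression baselines.
#'
#' @param cohort a \code{cohort_table} with non-missing gender.
#' @param fraction CHOL/HDL holdout fraction.
#' @param k,epsilon,max_iter,ortho_weight solver configuration
#'   (see \code{\link{fit_ognmf}}).
#' @param seed integer seed driving holdout and initialization.
#' @param snapshots keep per-iteration factors for trajectory curves.
#' @param mlr also fit the logistic-regression baseline.
#' @param thresholds a \code{\link{risk_thresholds}}.
#' @return List: \code{fit}, \code{fm}, \code{fm_train}, \code{heldout},
#'   \code{result} (\code{eval_result}), \code{mean_baseline_accuracy},
#'   and \code{mlr_accuracy} (or \code{NA}).
#' @export
run_risk_experiment <- function(cohort, fraction = 0.2, k = 4,
                                epsilon = 1e-5, max_iter = 500,
                                ortho_weight = 0.1, seed = 1,
                                snapshots = FALSE, mlr = FALSE,
                                thresholds = risk_thresholds()) {
  fm <- encode_features(cohort)
  ho <- holdout_chol_hdl(fm, fraction = fraction, seed = seed)
  fit <- fit_ognmf(ho$fm_train$X, ho$fm_train$M, k = k, epsilon = epsilon,
                   max_iter = max_iter, ortho_weight = ortho_weight,
                   seed = seed, keep_snapshots = snapshots)
  sex <- cohort$data$gender
  res <- risk_accuracy(fit, fm, ho$heldout, sex, thresholds)
  mean_acc <- mean_imputation_accuracy(ho$fm_train, ho$heldout, sex,
                                       thresholds)
  mlr_acc <- if (mlr) {
    mlr_risk_accuracy(ho$fm_train, ho$heldout, sex, thresholds)
  } else NA_real_
  list(fit = fit, fm = fm, fm_train = ho$fm_train, heldout = ho$heldout,
       result = res, mean_baseline_accuracy = mean_acc,
       mlr_accuracy = mlr_acc)
}
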