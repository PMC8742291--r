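#' Fit the multinomial logistic regression baseline
#'
#' The comparison model: softmax regression predicting the four-level risk
#' category from the encoded features. Minimizes the L2-regularized
#' multinomial cross-entropy
#' \deqn{L(W) = -\tfrac1n \sum_i \log p_{i, y_i} + \tfrac\lambda2 \|W\|_F^2}
#' (intercepts unpenalized) by gradient descent with backtracking line
#' search, stopping when the gradient norm falls below \code{tol} or at
#' \code{max_iter}. Missing feature values are mean-imputed and features
#' standardized internally; non-negativity does not apply here.
#'
#' @param x numeric feature matrix (n x p); may contain \code{NA}.
#' @param y integer risk labels in 1..4 (at least two distinct values).
#' @param lambda ridge penalty, default \code{1e-3}.
#' @param max_iter gradient-step cap.
#' @param tol gradient-norm stopping tolerance.
#' @param seed kept for interface symmetry; the objective is convex and the
#'   zero initialization deterministic, so it is unused.
#' @return An object of class \code{mlr_model}.
#' @export
fit_mlr <- function(x, y, lambda = 1e-3, max_iter = 2000, tol = 1e-6,
                    seed = 1) {
  x <- as.matrix(x)
  y <- as.integer(y)
  stopifnot(nrow(x) == length(y), all(y >= 1L), all(y <= 4L))
  if (length(unique(y)) < 2L) {
    stop("need at least two distinct labels", call. = FALSE)
  }
  n <- nrow(x); p <- ncol(x); C <- 4L
  col_means <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(p)) x[is.na(x[, j]), j] <- col_means[j]
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  xs <- scale(x, center = ctr, scale = scl)
  Z <- cbind(1, xs)                       # intercept first
  Y <- matrix(0, n, C); Y[cbind(seq_len(n), y)] <- 1

  W <- matrix(0, p + 1L, C)
  pen_mask <- rbind(0, matrix(1, p, C))   # intercept unpenalized
  loss_fn <- function(W) {
    P <- .softmax(Z %*% W)
    -sum(Y * log(pmax(P, 1e-300))) / n + lambda / 2 * sum((pen_mask * W)^2)
  }
  grad_fn <- function(W) {
    P <- .softmax(Z %*% W)
    crossprod(Z, P - Y) / n + lambda * (pen_mask * W)
  }
  loss <- loss_fn(W)
  trace <- numeric(0)
  step <- 1
  for (it in seq_len(max_iter)) {
    G <- grad_fn(W)
    gn <- sqrt(sum(G^2))
    if (gn < tol) break
    # backtracking line search: never accept an increase
    repeat {
      W_new <- W - step * G
      loss_new <- loss_fn(W_new)
      if (loss_new <= loss - 1e-4 * step * gn^2 || step < 1e-12) break
      step <- step / 2
    }
    W <- W_new
    loss <- loss_new
    trace <- c(trace, loss)
    step <- min(step * 2, 1e3)           # cautious growth
  }
  structure(list(W = W, lambda = lambda, col_means = col_means,
                 center = ctr, scale = scl, levels = 1:4,
                 loss_trace = trace, n_features = p),
            class = "mlr_model")
}

.softmax <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

#' Predict risk categories with the baseline model
#'
#' Applies the trained softmax model: mean-imputes missing features with the
#' training means, standardizes with the training moments, and returns the
#' class probabilities and the argmax class, with probability ties broken
#' toward the lower risk level.
#'
#' @param model an \code{mlr_model}.
#' @param x feature matrix with the training dimensionality.
#' @return List with \code{class} (integer vector) and \code{prob}
#'   (n x 4 matrix, rows summing to one).
#' @export
predict_mlr <- function(model, x) {
  stopifnot(inherits(model, "mlr_model"))
  x <- as.matrix(x)
  if (ncol(x) != model$n_features) {
    stop("feature dimension mismatch: model expects ", model$n_features,
         call. = FALSE)
  }
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- model$col_means[j]
  xs <- scale(x, center = model$center, scale = model$scale)
  P <- .softmax(cbind(1, xs) %*% model$W)
  cls <- apply(P, 1, which.max)          # first max = lower risk level
  colnames(P) <- paste0("level", 1:4)
  list(class = as.integer(cls), prob = P)
}

#' @export
print.mlr_model <- function(x, ...) {
  cat(sprintf("mlr_model: %d features, lambda = %g, %d gradient steps\n",
              x$n_features, x$lambda, length(x$loss_trace)))
  invisible(x)
}
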