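#' Masked Frobenius objective
#'
#' The reconstruction loss evaluated only on observed cells:
#' \deqn{f(U, V) = \tfrac12 \sum_{ij : M_{ij}=1} (X_{ij} - (UV)_{ij})^2.}
#' Cells with \eqn{M_{ij} = 0} contribute nothing, which is what makes the
#' factorization usable for imputation.
#'
#' @param X non-negative target matrix (n x p).
#' @param M binary observation mask, same shape.
#' @param U,V non-negative factors (n x k and k x p).
#' @return Non-negative scalar.
#' @export
masked_objective <- function(X, M, U, V) {
  .check_shapes(X, M, U, V)
  R <- X - U %*% V
  0.5 * sum((M * R)^2)
}

.check_shapes <- function(X, M, U, V) {
  if (!all(dim(X) == dim(M))) stop("X and M shapes differ", call. = FALSE)
  if (nrow(U) != nrow(X) || ncol(V) != ncol(X) || ncol(U) != nrow(V)) {
    stop("factor shapes inconsistent with X", call. = FALSE)
  }
  invisible(TRUE)
}

#' One multiplicative update sweep
#'
#' Masked Lee-Seung multiplicative updates with an orthogonality-promoting
#' penalty \eqn{\lambda \|U^\top U - I\|_F^2} on the patient factors, whose
#' gradient is folded into the denominator of the U update:
#' \deqn{U \leftarrow U \circ \frac{(M \circ X) V^\top}
#'   {(M \circ (UV)) V^\top + \lambda U (U^\top U - I) + \delta}}
#' then the analogous masked update for \eqn{V} using the new \eqn{U}.
#' Denominators are floored at \eqn{\delta} and factors clipped at zero after
#' the (possibly negative) orthogonality term, so non-negativity is preserved.
#' With \eqn{\lambda = 0} and a full mask this is the classical
#' multiplicative update, which never increases the objective.
#'
#' @param X,M,U,V as in \code{\link{masked_objective}}.
#' @param ortho_weight penalty weight \eqn{\lambda \ge 0}; 0 gives plain
#'   masked NMF.
#' @param delta small positive guard for divisions.
#' @return List with updated factors \code{U} and \code{V}.
#' @export
update_step <- function(X, M, U, V, ortho_weight = 0.1, delta = 1e-12) {
  .check_shapes(X, M, U, V)
  if (!all(is.finite(U)) || !all(is.finite(V))) {
    stop("non-finite entries in factors", call. = FALSE)
  }
  k <- ncol(U)
  MR <- M * (U %*% V)
  numU <- (M * X) %*% t(V)
  denU <- MR %*% t(V)
  if (ortho_weight > 0) {
    denU <- denU + ortho_weight * U %*% (crossprod(U) - diag(k))
  }
  U2 <- pmax(U * numU / pmax(denU, delta), 0)

  MR2 <- M * (U2 %*% V)
  numV <- crossprod(U2, M * X)
  denV <- crossprod(U2, MR2)
  V2 <- pmax(V * numV / pmax(denV, delta), 0)
  if (!all(is.finite(U2)) || !all(is.finite(V2))) {
    stop("update produced non-finite entries", call. = FALSE)
  }
  list(U = U2, V = V2)
}

#' Relative step error between consecutive objective values
#'
#' \eqn{|f_t - f_{t-1}| / \max(f_{t-1}, \delta)}; convergence is declared
#' once this falls below the stopping criterion \eqn{\varepsilon}.
#'
#' @param f_t,f_prev consecutive objective values.
#' @param delta division guard.
#' @return Non-negative scalar.
#' @export
step_error <- function(f_t, f_prev, delta = 1e-12) {
  abs(f_t - f_prev) / max(f_prev, delta)
}

# seeded |N(0,1)| initialization scaled so E[UV] is on the order of mean(X)
.init_random <- function(n, p, k, xbar) {
  s <- sqrt(max(xbar, .Machine$double.eps) / k)
  list(U = matrix(abs(stats::rnorm(n * k)), n, k) * s,
       V = matrix(abs(stats::rnorm(k * p)), k, p) * s)
}

# NNDSVD-style: positive parts of the leading singular vectors
.init_nndsvd <- function(X, k) {
  sv <- svd(X, nu = k, nv = k)
  U <- pmax(sv$u[, seq_len(k), drop = FALSE], 0) %*%
    diag(sqrt(sv$d[seq_len(k)]), k)
  V <- diag(sqrt(sv$d[seq_len(k)]), k) %*%
    t(pmax(sv$v[, seq_len(k), drop = FALSE], 0))
  eps <- mean(X) * 1e-4
  list(U = pmax(U, eps), V = pmax(V, eps))
}

#' Fit a masked non-negative matrix factorization
#'
#' Factorizes the observed cells of a non-negative target matrix as
#' \eqn{X \approx UV} with \eqn{U, V \ge 0}, by iterating
#' \code{\link{update_step}} from a seeded random non-negative
#' initialization until the relative objective change drops below
#' \code{epsilon} or \code{max_iter} is reached. The default rank
#' \eqn{k = 4} mirrors the four ordinal risk levels the reconstruction is
#' read against. The full per-iteration trace (objective, step error) is
#' returned; non-convergence at \code{max_iter} is reported via the
#' \code{converged} flag, not an error, so the trace can be inspected.
#'
#' @param X non-negative matrix (n x p), e.g. \code{feature_matrix$X}.
#' @param M binary mask; every row and column must have at least one
#'   observed cell.
#' @param k latent rank.
#' @param epsilon stopping criterion on the relative objective change.
#' @param max_iter iteration cap.
#' @param ortho_weight orthogonality penalty weight (0 = plain masked NMF).
#' @param seed integer seed for the initialization.
#' @param init \code{"random"} or \code{"nndsvd"}.
#' @param keep_snapshots store \code{U}, \code{V} at every iteration
#'   (needed for accuracy-vs-iteration curves).
#' @param delta division guard.
#' @return An object of class \code{ognmf_fit}: factors \code{U}, \code{V},
#'   \code{trace} (data frame: iteration, objective, step_error),
#'   \code{converged}, \code{iterations}, the configuration, and optionally
#'   \code{snapshots}.
#' @export
fit_ognmf <- function(X, M, k = 4, epsilon = 1e-5, max_iter = 500,
                      ortho_weight = 0.1, seed = 1,
                      init = c("random", "nndsvd"),
                      keep_snapshots = FALSE, delta = 1e-12) {
  init <- match.arg(init)
  stopifnot(is.matrix(X), is.matrix(M), all(dim(X) == dim(M)),
            epsilon > 0, k >= 1, max_iter >= 1, ortho_weight >= 0)
  if (any(X < 0)) stop("X must be non-negative", call. = FALSE)
  if (!all(M %in% c(0, 1))) stop("M must be binary", call. = FALSE)
  if (any(rowSums(M) == 0)) stop("mask has an empty row", call. = FALSE)
  if (any(colSums(M) == 0)) stop("mask has an empty column", call. = FALSE)
  n <- nrow(X); p <- ncol(X)

  fac <- .with_seed(seed, {
    if (init == "random") {
      .init_random(n, p, k, mean(X[M == 1]))
    } else {
      .init_nndsvd(X, k)
    }
  })
  U <- fac$U; V <- fac$V

  f_prev <- masked_objective(X, M, U, V)
  objective0 <- f_prev
  obj <- err <- numeric(max_iter)
  snapshots <- if (keep_snapshots) vector("list", max_iter) else NULL
  converged <- FALSE
  t <- 0L
  while (t < max_iter) {
    t <- t + 1L
    upd <- update_step(X, M, U, V, ortho_weight = ortho_weight, delta = delta)
    U <- upd$U; V <- upd$V
    stopifnot(min(U) >= 0, min(V) >= 0)
    f_t <- masked_objective(X, M, U, V)
    obj[t] <- f_t
    err[t] <- step_error(f_t, f_prev, delta)
    if (keep_snapshots) snapshots[[t]] <- list(U = U, V = V)
    f_prev <- f_t
    if (err[t] < epsilon) { converged <- TRUE; break }
  }
  trace <- data.frame(iteration = seq_len(t), objective = obj[seq_len(t)],
                      step_error = err[seq_len(t)])
  structure(list(U = U, V = V, k = k, trace = trace,
                 objective0 = objective0, converged = converged,
                 iterations = t,
                 snapshots = if (keep_snapshots) snapshots[seq_len(t)],
                 config = list(k = k, epsilon = epsilon, max_iter = max_iter,
                               ortho_weight = ortho_weight, seed = seed,
                               init = init, delta = delta)),
            class = "ognmf_fit")
}

#' @export
print.ognmf_fit <- function(x, ...) {
  cat(sprintf(
    "ognmf_fit: rank %d, %d iteration(s), %s (final objective %.6g, step error %.3g)\n",
    x$k, x$iterations,
    if (x$converged) "converged" else "NOT converged",
    utils::tail(x$trace$objective, 1L), utils::tail(x$trace$step_error, 1L)))
  invisible(x)
}

# run expr under a local RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Read imputed values off a factorization, in clinical units
#'
#' Evaluates the reconstruction \eqn{UV} at the requested cells of a
#' continuous column and inverts the column's affine encoding
#' (\code{\link{decode_column}}); this is how a missing lab value such as the
#' CHOL/HDL ratio is imputed from the remaining features.
#'
#' @param fit an \code{ognmf_fit}.
#' @param fm the \code{feature_matrix} the fit was trained on.
#' @param cells data frame with columns \code{row} (integer) and
#'   \code{feature} (column name), one imputed cell per line.
#' @return Numeric vector of imputed values in clinical units.
#' @export
impute <- function(fit, fm, cells) {
  stopifnot(inherits(fit, "ognmf_fit"), inherits(fm, "feature_matrix"),
            is.data.frame(cells), all(c("row", "feature") %in% names(cells)))
  n <- nrow(fm$X)
  if (any(cells$row < 1L | cells$row > n)) {
    stop("cell row outside the matrix", call. = FALSE)
  }
  if (!all(cells$feature %in% fm$features)) {
    stop("unknown feature in cells", call. = FALSE)
  }
  out <- numeric(nrow(cells))
  for (f in unique(cells$feature)) {
    sel <- cells$feature == f
    j <- match(f, fm$features)
    rows <- cells$row[sel]
    xhat <- as.numeric(fit$U[rows, , drop = FALSE] %*%
                         fit$V[, j, drop = FALSE])
    out[sel] <- decode_column(fm, xhat, f)
  }
  out
}
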