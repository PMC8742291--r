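test_that("masked objective sums only over observed cells", {
  U <- matrix(abs(rnorm(12)), 4, 3)
  V <- matrix(abs(rnorm(15)), 3, 5)
  X <- U %*% V
  M1 <- matrix(1, 4, 5)
  expect_equal(masked_objective(X, M1, U, V), 0)
  expect_equal(masked_objective(X + 1, matrix(0, 4, 5), U, V), 0)
  # hand evaluation: 1/2 (2 - 1)^2
  expect_equal(masked_objective(matrix(2), matrix(1), matrix(1), matrix(1)),
               0.5)
  expect_error(masked_objective(X, M1[, 1:4], U, V), "shape")
  expect_error(masked_objective(X, M1, U[, 1:2], V), "shape")
})

test_that("multiplicative update is monotone at lambda = 0 and fixes exact factorizations", {
  set.seed(42)
  for (rep in 1:20) {
    d <- generate_lowrank(30, 16, 5, noise_sd = 0.3, seed = rep)
    U <- matrix(abs(rnorm(30 * 4)), 30, 4)
    V <- matrix(abs(rnorm(4 * 16)), 4, 16)
    f <- masked_objective(d$X, d$M, U, V)
    for (t in 1:50) {
      up <- update_step(d$X, d$M, U, V, ortho_weight = 0)
      U <- up$U; V <- up$V
      f2 <- masked_objective(d$X, d$M, U, V)
      expect_lte(f2, f + 1e-10 * max(f, 1))
      f <- f2
    }
    expect_gte(min(U), 0)
    expect_gte(min(V), 0)
  }
  # exact factorization with full mask is a fixed point
  d <- generate_lowrank(20, 10, 3, seed = 99)
  up <- update_step(d$X, matrix(1, 20, 10), d$truth$U, d$truth$V,
                    ortho_weight = 0)
  expect_lt(max(abs(up$U - d$truth$U)), 1e-12)
  expect_lt(max(abs(up$V - d$truth$V)), 1e-12)
  expect_error(update_step(d$X, matrix(1, 20, 10), d$truth$U * NA,
                           d$truth$V), "non-finite")
})

test_that("step error is the relative objective change", {
  expect_equal(step_error(1, 1), 0)
  expect_equal(step_error(0.5, 1.0), 0.5)
  expect_equal(step_error(1.5, 1.0), 0.5)
  expect_equal(step_error(1, 0), 1 / 1e-12 * 1)  # guarded division
})

test_that("fitting recovers noiseless low-rank structure and imputes masked cells", {
  for (k in 1:3) {
    d <- generate_lowrank(60, 16, k, seed = k)
    fit <- fit_ognmf(d$X, d$M, k = k, epsilon = 1e-9, max_iter = 2000,
                     ortho_weight = 0, seed = k)
    rel <- norm(d$X - fit$U %*% fit$V, "F") / norm(d$X, "F")
    expect_lt(rel, 1e-2)
  }
  d <- generate_lowrank(60, 16, 3, missing_rate = 0.2, seed = 5)
  fit <- fit_ognmf(d$X, d$M, k = 3, epsilon = 1e-9, max_iter = 2000,
                   ortho_weight = 0, seed = 5)
  held <- d$M == 0
  Xh <- fit$U %*% fit$V
  rel_held <- sqrt(sum((Xh[held] - d$truth$X0[held])^2)) /
    sqrt(sum(d$truth$X0[held]^2))
  expect_lt(rel_held, 0.1)
})

test_that("trace is deterministic, non-negative, and the stopping rule is nested in epsilon", {
  d <- generate_lowrank(40, 12, 3, noise_sd = 0.2, missing_rate = 0.1,
                        seed = 8)
  f1 <- fit_ognmf(d$X, d$M, k = 3, epsilon = 1e-4, seed = 21)
  f2 <- fit_ognmf(d$X, d$M, k = 3, epsilon = 1e-4, seed = 21)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$U, f2$U)
  expect_true(all(is.finite(f1$trace$objective)))
  expect_true(all(f1$trace$objective >= 0))
  expect_true(all(f1$trace$step_error >= 0))
  expect_gte(min(f1$U), 0)
  expect_gte(min(f1$V), 0)

  iters <- sapply(c(1e-2, 1e-3, 1e-4, 1e-5), function(eps) {
    fit_ognmf(d$X, d$M, k = 3, epsilon = eps, max_iter = 3000,
              seed = 21)$iterations
  })
  expect_true(all(diff(iters) >= 0))  # tighter epsilon never needs fewer

  # orthogonality penalty keeps factors non-negative too
  f3 <- fit_ognmf(d$X, d$M, k = 3, epsilon = 1e-5, ortho_weight = 0.5,
                  seed = 21)
  expect_gte(min(f3$U), 0)

  short <- fit_ognmf(d$X, d$M, k = 3, epsilon = 1e-12, max_iter = 3,
                     seed = 21)
  expect_false(short$converged)       # reported, not an error
  expect_equal(short$iterations, 3L)
})

test_that("degenerate masks are rejected", {
  d <- generate_lowrank(10, 6, 2, seed = 1)
  M <- matrix(1, 10, 6); M[3, ] <- 0
  expect_error(fit_ognmf(d$X, M, k = 2), "empty row")
  M <- matrix(1, 10, 6); M[, 4] <- 0
  expect_error(fit_ognmf(d$X, M, k = 2), "empty column")
  expect_error(fit_ognmf(-d$X, matrix(1, 10, 6), k = 2), "non-negative")
})

test_that("imputation decodes reconstruction cells into clinical units", {
  lf <- lowrank_feature_matrix(n = 80, p = 8, k = 2, seed = 4)
  fm <- lf$fm
  fit <- fit_ognmf(fm$X, fm$M, k = 2, epsilon = 1e-10, max_iter = 3000,
                   ortho_weight = 0, seed = 4)
  cells <- data.frame(row = c(1L, 7L, 50L),
                      feature = rep("chol_hdl", 3))
  vals <- impute(fit, fm, cells)
  truth <- 1.0 + 2.5 * fm$X[cells$row, "chol_hdl"]  # stored affine map
  expect_true(all(abs(vals - truth) / truth < 0.1))
  # deterministic under identical config
  fit2 <- fit_ognmf(fm$X, fm$M, k = 2, epsilon = 1e-10, max_iter = 3000,
                    ortho_weight = 0, seed = 4)
  expect_identical(impute(fit2, fm, cells), vals)
  # composition with the risk rules stays in the four levels
  lv <- classify_ratio("M", pmax(vals, 1e-9))
  expect_true(all(lv %in% 1:4))
  expect_error(impute(fit, fm, data.frame(row = 999L, feature = "chol_hdl")),
               "outside")
  expect_error(impute(fit, fm, data.frame(row = 1L, feature = "xyz")),
               "unknown feature")
})
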