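test_that("lasso returns the all-zero solution above the critical penalty", {
  set.seed(1)
  n <- 60; p <- 4; d <- 2
  M <- matrix(rnorm(n * p), n, p)
  X <- cbind(rnorm(n), rbinom(n, 1, 0.5))
  Z <- dagmm:::node_design(M, X, 1)
  lam_max <- max(abs(2 * crossprod(Z, M[, 1])))
  f <- fit_beta_penalized(1, M, X, lam_max * 1.0001)
  expect_true(all(f$beta == 0))
  f2 <- fit_beta_penalized(1, M, X, lam_max * 0.95)
  expect_gt(sum(f2$beta != 0), 0)
})

test_that("lasso approaches ordinary least squares as the penalty vanishes", {
  set.seed(2)
  n <- 200; p <- 5; d <- 2
  truth <- make_setting(1, n = n, p = 15, seed = 21)
  dat <- simulate_data(truth)
  M <- dat$M[, 1:p]; X <- dat$X[, 1:d]
  Z <- dagmm:::node_design(M, X, 1)
  f <- fit_beta_penalized(1, M, X, 1e-8)
  ols <- qr.solve(crossprod(Z), crossprod(Z, M[, 1]))
  expect_equal(as.numeric(f$beta[, , 1]), as.numeric(ols), tolerance = 1e-4)
})

test_that("lasso solutions satisfy the KKT stationarity conditions", {
  set.seed(3)
  truth <- make_setting(3, n = 300, p = 15, seed = 31)
  dat <- simulate_data(truth)
  M <- dat$M; X <- dat$X
  Z <- dagmm:::node_design(M, X, 2)
  lam_max <- max(abs(2 * crossprod(Z, M[, 2])))
  lams <- lam_max * c(0.3, 0.05, 0.01)
  f <- fit_beta_penalized(2, M, X, lams)
  for (li in seq_along(lams)) {
    b <- as.numeric(f$beta[, , li])
    g <- as.numeric(2 * crossprod(Z, M[, 2] - Z %*% b))
    viol <- ifelse(b == 0, pmax(abs(g) - lams[li], 0),
                   abs(g - lams[li] * sign(b)))
    expect_lt(max(viol) / lam_max, 1e-6)
  }
})

test_that("lasso agrees with an independent solver", {
  set.seed(4)
  truth <- make_setting(1, n = 250, p = 15, seed = 41)
  dat <- simulate_data(truth)
  M <- dat$M; X <- dat$X
  Z <- dagmm:::node_design(M, X, 1)
  n <- nrow(Z)
  lam <- max(abs(2 * crossprod(Z, M[, 1]))) * 0.02
  f <- fit_beta_penalized(1, M, X, lam)
  # glmnet minimises RSS/(2n) + lambda ||b||_1: lambda_glmnet = lam / (2n)
  g <- glmnet::glmnet(Z, M[, 1], lambda = lam / (2 * n), standardize = FALSE,
                      intercept = FALSE, thresh = 1e-12)
  expect_equal(as.numeric(f$beta[, , 1]), as.numeric(g$beta),
               tolerance = 1e-4)
})

test_that("variance regression returns the null model under heavy penalties", {
  set.seed(5)
  n <- 300
  M <- matrix(rnorm(n * 4), n, 4)
  r <- rnorm(n, sd = 1.3)
  A <- M[, -1]^2
  b2 <- r^2
  lam_max <- max(c(2 * crossprod(A, b2 - mean(b2)), 0))
  f <- fit_sigma_penalized(1, r, M, lam_max * 1.001)
  expect_true(all(f$sigma2 == 0))
  expect_equal(f$error_var, mean(r^2), tolerance = 1e-6)
})

test_that("variance regression recovers a planted moment structure", {
  # squared residuals built as 0.5 * M_2^2 + 1.0 + noise
  set.seed(6)
  n <- 5000
  M <- matrix(rnorm(n * 3), n, 3)
  r <- rnorm(n, sd = sqrt(0.5 * M[, 2]^2 + 1.0))
  f <- fit_sigma_penalized(1, r, M, 1e-6)
  sig <- f$sigma2[, 1]
  names(sig) <- f$parents
  expect_lt(abs(sig[["2"]] - 0.5), 0.1)
  expect_lt(abs(f$error_var[1] - 1.0), 0.15)
  expect_lt(sig[["3"]], 0.1)
})

test_that("variance solutions satisfy the projected KKT conditions", {
  set.seed(7)
  n <- 400
  M <- matrix(rnorm(n * 5), n, 5)
  r <- rnorm(n, sd = sqrt(0.4 * M[, 3]^2 + 0.8))
  A <- M[, -1]^2
  b2 <- r^2
  lam_max <- max(c(2 * crossprod(A, b2 - mean(b2)), 0))
  for (lam in lam_max * c(0.5, 0.05)) {
    f <- fit_sigma_penalized(1, r, M, lam)
    cc <- f$sigma2[, 1]; c0 <- f$error_var[1]
    res <- b2 - c0 - drop(A %*% cc)
    g <- -2 * crossprod(A, res) + lam
    viol <- max(ifelse(cc > 0, abs(g), pmax(-g, 0)))
    viol <- max(viol, abs(-2 * sum(res)))
    expect_lt(viol / max(lam_max, 1), 1e-6)
  }
})

test_that("nonzero count shrinks along the penalty path", {
  truth <- make_setting(1, n = 300, p = 15, seed = 71)
  dat <- simulate_data(truth)
  Z <- dagmm:::node_design(dat$M, dat$X, 1)
  lam_max <- max(abs(2 * crossprod(Z, dat$M[, 1])))
  lams <- exp(seq(log(lam_max), log(lam_max * 1e-4), length.out = 25))
  f <- fit_beta_penalized(1, dat$M, dat$X, lams)
  counts <- vapply(seq_along(lams), function(li) sum(f$beta[, , li] != 0), 0L)
  # counts grow as lambda decreases, up to the occasional single feature
  # leaving the active set (exact lasso paths are not strictly monotone)
  expect_true(all(diff(counts) >= -2))
  expect_gt(counts[length(counts)], counts[1])
  expect_true(mean(diff(counts) >= 0) > 0.8)
})

test_that("single-value grids are selected as-is", {
  truth <- make_setting(1, n = 150, p = 15, seed = 72)
  dat <- simulate_data(truth)
  ctrl <- dagmm_control(lambda1_grid = 50, lambda2_grid = 80)
  sel <- select_lambdas(dat$M, dat$X, ctrl)
  expect_equal(sel$lambda1, 50)
  expect_equal(sel$lambda2, 80)
})

test_that("skeleton estimates are non-negative and error variances floored", {
  truth <- make_setting(2, n = 300, p = 15, seed = 73)
  dat <- simulate_data(truth)
  sk <- initial_skeleton(dat$M, dat$X, quick_ctrl())
  for (j in 1:15) expect_true(all(sk$sigma2_tilde[[j]] >= 0))
  expect_true(all(sk$sigma2_eps_tilde >= 1e-8))
  expect_true(all(sk$fit$error_vars > 0))
  # support has no self-loops and matches the fitted parents
  expect_true(all(sk$support[, 1] != sk$support[, 2]))
})

test_that("skeleton recovers the true pairs on fixed-effect data", {
  truth <- make_setting(1, n = 500, p = 20, seed = 74)
  dat <- simulate_data(truth)
  sk <- initial_skeleton(dat$M, dat$X)
  conf <- edge_confusion(sk$support, truth)
  expect_gte(conf$tp, 11)
})

test_that("the skeleton support stays sparse on pure-noise data", {
  set.seed(8)
  n <- 400; p <- 15
  M <- matrix(rnorm(n * p), n, p)
  X <- cbind(rnorm(n), rnorm(n), rbinom(n, 1, 0.5))
  sk <- initial_skeleton(M, X, quick_ctrl())
  expect_lt(NROW(sk$support), 0.05 * p * (p - 1))
})

test_that("a zero-variance node acquires no incident support edges", {
  truth <- make_setting(1, n = 300, p = 16, seed = 75)
  dat <- simulate_data(truth)
  M <- dat$M
  M[, 16] <- 0
  sk <- initial_skeleton(M, dat$X, quick_ctrl())
  if (NROW(sk$support) > 0) {
    expect_false(any(sk$support == 16L))
  }
})

test_that("the skeleton contains every true pair at large n in nearly all seeds", {
  hits <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    truth <- make_setting(3, n = 2000, p = 20, seed = 900 + s)
    dat <- simulate_data(truth)
    sk <- initial_skeleton(dat$M, dat$X)
    if (edge_confusion(sk$support, truth)$tp == 12L) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.95)
})
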