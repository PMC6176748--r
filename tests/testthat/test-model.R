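test_that("likelihood collapses to iid Gaussian quadratic form with empty support", {
  set.seed(1)
  m <- matrix(rnorm(30), 30, 1)
  v <- 2.5
  fit <- model_fit(matrix(integer(0), 0, 2), list(), numeric(0),
                   error_vars = v, d = 1)
  expect_equal(neg_log_likelihood(m, matrix(1, 30, 1), fit),
               sum(m^2) / v + 30 * log(v))
})

test_that("zero random-effect edge reduces to a weighted regression objective", {
  set.seed(2)
  n <- 40
  M <- cbind(rnorm(n), rnorm(n))
  X <- cbind(rnorm(n), rbinom(n, 1, 0.5))
  beta <- c(0.7, -0.3)
  ev <- c(1.3, 0.8)
  fit <- model_fit(cbind(1L, 2L), list(beta), sigma2 = 0,
                   error_vars = ev, d = 2)
  r <- M[, 1] - drop(X %*% beta) * M[, 2]
  expect_equal(neg_log_likelihood(M, X, fit),
               sum(r^2) / ev[1] + n * log(ev[1]) +
                 sum(M[, 2]^2) / ev[2] + n * log(ev[2]))
})

test_that("likelihood is separable across nodes for arbitrary supports", {
  set.seed(3)
  n <- 60; p <- 6; d <- 2
  M <- matrix(rnorm(n * p), n, p)
  X <- cbind(rnorm(n), rbinom(n, 1, 0.5))
  sup <- random_dag_support(p, 7, seed = 33)
  beta <- lapply(seq_len(nrow(sup)), function(i) rnorm(d))
  sig <- runif(nrow(sup), 0, 0.6)
  ev <- runif(p, 0.5, 2)
  fit <- model_fit(sup, beta, sig, ev, d = d)
  total <- 0
  for (j in seq_len(p)) {
    total <- total + node_objective_direct(M, X, j, fit$parents[[j]],
                                           fit$beta[[j]], fit$sigma2[[j]],
                                           ev[j])
  }
  expect_equal(neg_log_likelihood(M, X, fit), total, tolerance = 1e-10)
})

test_that("quadrature oracle equals the closed-form density when all variances are zero", {
  set.seed(4)
  n <- 5
  M <- cbind(rnorm(n), rnorm(n))
  X <- matrix(rnorm(n), n, 1)
  beta <- 0.9
  ev <- c(1.2, 0.7)
  fit <- model_fit(cbind(1L, 2L), list(beta), sigma2 = 0,
                   error_vars = ev, d = 1)
  for (i in seq_len(n)) {
    r1 <- M[i, 1] - beta * X[i, 1] * M[i, 2]
    expect_equal(marginal_density_oracle(M[i, ], X[i, ], fit),
                 dnorm(r1, 0, sqrt(ev[1])) * dnorm(M[i, 2], 0, sqrt(ev[2])))
  }
})

test_that("one random-effect edge: quadrature matches the closed-form node factor", {
  set.seed(5)
  X <- matrix(rnorm(1), 1, 1)
  m <- c(0.4, -1.1)
  beta <- 0.6; s2 <- 0.5; ev <- c(1.0, 0.5)
  fit <- model_fit(cbind(1L, 2L), list(beta), sigma2 = s2,
                   error_vars = ev, d = 1)
  w1 <- s2 * m[2]^2 + ev[1]
  closed <- dnorm(m[1], beta * X[1, 1] * m[2], sqrt(w1)) *
    dnorm(m[2], 0, sqrt(ev[2]))
  expect_equal(marginal_density_oracle(m, X[1, ], fit, quad_points = 64),
               closed, tolerance = 1e-6)
})

test_that("likelihood matches the quadrature oracle on random 3-node models", {
  # Eq-6-style closed form vs direct integration over the random effects:
  # nll = -2 * sum(log f_i) - n * p * log(2*pi)
  cases <- list(list(seed = 11, sig = c(0.4, 0.3, 0), n = 10, q = 32),
                list(seed = 12, sig = c(0.4, 0.3, 0.25), n = 6, q = 16))
  for (cs in cases) {
    set.seed(cs$seed)
    n <- cs$n; p <- 3
    sup <- rbind(c(2L, 1L), c(3L, 1L), c(3L, 2L))
    beta <- lapply(1:3, function(i) rnorm(2, sd = 0.6))
    ev <- c(1.0, 0.6, 0.8)
    fit <- model_fit(sup, beta, cs$sig, ev, d = 2)
    X <- cbind(rnorm(n), rbinom(n, 1, 0.5))
    M <- matrix(rnorm(n * p), n, p)  # any values; density identity is pointwise
    nll <- neg_log_likelihood(M, X, fit)
    logf <- vapply(seq_len(n), function(i)
      log(marginal_density_oracle(M[i, ], X[i, ], fit, quad_points = cs$q)), 0)
    expect_equal(nll, -2 * sum(logf) - n * p * log(2 * pi),
                 tolerance = 1e-4)
  }
})

test_that("parentless node fit is the closed-form variance estimate", {
  set.seed(6)
  m <- matrix(rnorm(80, sd = 1.4), 80, 2)
  x <- matrix(rnorm(80), 80, 1)
  f <- fit_node(1, integer(0), m, x)
  expect_equal(f$error_var, mean(m[, 1]^2))
  expect_equal(f$nll, sum(m[, 1]^2) / f$error_var + 80 * log(f$error_var))
})

test_that("node fit recovers the generating parameters at large n", {
  truth <- make_setting(3, n = 5000, p = 20, seed = 91)
  dat <- simulate_data(truth)
  f <- fit_node(1, c(2, 3, 4), dat$M, dat$X)
  for (t in 1:3) {
    expect_true(all(abs(f$beta[, t] - c(-0.5, 1.0, -1.5)) < 0.1))
    expect_lt(abs(f$sigma2[t] - 0.5), 0.15)
  }
  expect_lt(abs(f$error_var - 1.0), 0.2)
})

test_that("node fit attains the optimum found by a general-purpose minimizer", {
  truth <- make_setting(3, n = 800, p = 20, seed = 92)
  dat <- simulate_data(truth)
  M <- dat$M; X <- dat$X
  f <- fit_node(2, 3L, M, X)
  obj <- function(par) {
    node_objective_direct(M, X, 2L, 3L, matrix(par[1:3], 3, 1),
                          exp(par[4]), exp(par[5]))
  }
  start <- c(-0.5, 1.0, -1.5, log(0.5), log(0.5))
  o <- optim(start, obj, method = "BFGS", control = list(maxit = 500,
                                                         reltol = 1e-12))
  expect_lte(f$nll, o$value + 1e-6 * abs(o$value))
  expect_equal(f$nll, o$value, tolerance = 1e-5)
})

test_that("BIC is the deviance-scale criterion", {
  expect_equal(dagmm_bic(list(nll = 10, n_params = 3), exp(2)), 16)
  expect_error(dagmm_bic(list(nll = 0, n_params = 0), 1), "exceed")
  # nested supports: difference equals d_nll + d_k * log(n)
  truth <- make_setting(3, n = 300, p = 15, seed = 93)
  dat <- simulate_data(truth)
  pa_full <- dagmm:::parents_from_support(truth$edges, 15)
  fit_full <- dagmm:::fit_support_model(dat$M, dat$X, pa_full)
  pa_sub <- pa_full
  pa_sub[[1]] <- setdiff(pa_sub[[1]], 2L)
  fit_sub <- dagmm:::fit_support_model(dat$M, dat$X, pa_sub)
  expect_equal(dagmm_bic(fit_full, 300) - dagmm_bic(fit_sub, 300),
               (fit_full$nll - fit_sub$nll) + 4 * log(300))
})

test_that("removing a support edge never decreases the minimized likelihood", {
  truth <- make_setting(3, n = 400, p = 15, seed = 94)
  dat <- simulate_data(truth)
  pa <- dagmm:::parents_from_support(truth$edges, 15)
  full <- dagmm:::fit_support_model(dat$M, dat$X, pa)
  for (j in c(1L, 2L, 8L)) {
    drop1 <- pa
    drop1[[j]] <- pa[[j]][-1]
    sub <- dagmm:::fit_support_model(dat$M, dat$X, drop1)
    expect_gte(sub$nll, full$nll - 1e-6 * abs(full$nll))
  }
})

test_that("det(I - B(X) - Gamma) is one for any DAG-compatible support", {
  for (seed in 1:20) {
    p <- sample(3:8, 1)
    sup <- random_dag_support(p, sample(2:(2 * p), 1), seed = 100 + seed)
    B <- matrix(0, p, p)
    set.seed(seed)
    for (i in seq_len(nrow(sup)))
      B[sup[i, 1L], sup[i, 2L]] <- rnorm(1, sd = 2)
    expect_equal(det(diag(p) - B), 1, tolerance = 1e-8)
  }
})

test_that("true orientation has lower minimized objective under effect heterogeneity", {
  wins <- 0L
  n_seeds <- 8L
  for (s in seq_len(n_seeds)) {
    truth <- two_node_truth(n = 5000, seed = 7000 + s)
    dat <- simulate_data(truth)
    fwd <- fit_node(1, 2L, dat$M, dat$X)$nll +
      fit_node(2, integer(0), dat$M, dat$X)$nll
    rev <- fit_node(2, 1L, dat$M, dat$X)$nll +
      fit_node(1, integer(0), dat$M, dat$X)$nll
    if (fwd < rev) wins <- wins + 1L
  }
  expect_gte(wins, n_seeds - 1L)
})

test_that("model fit serializes to JSON and back unchanged", {
  truth <- make_setting(1, n = 200, p = 15, seed = 95)
  dat <- simulate_data(truth)
  pa <- dagmm:::parents_from_support(truth$edges, 15)
  fit <- dagmm:::fit_support_model(dat$M, dat$X, pa)
  dir <- tempfile(); dir.create(dir)
  write_fit(fit, dir)
  back <- read_fit(file.path(dir, "model.json"))
  expect_equal(back$support, fit$support)
  expect_equal(back$beta, fit$beta, tolerance = 1e-12)
  expect_equal(back$sigma2, fit$sigma2, tolerance = 1e-12)
  expect_equal(back$error_vars, fit$error_vars, tolerance = 1e-12)
  expect_equal(back$nll, fit$nll)
  expect_equal(back$bic, fit$bic)
})
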