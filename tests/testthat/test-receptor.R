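test_that("Qexp follows the degrees-of-freedom formula", {
  expect_equal(q_expected(2622, 26, 7), 49636)    # 68172 - 18536, by hand
  expect_equal(q_expected(10, 5, 0), 50)
  qs <- vapply(0:3, function(k) q_expected(20, 6, k), 0)
  expect_true(all(diff(qs) < 0))
  expect_error(q_expected(5, 5, 3), "over-parameterized")
})

test_that("the objective never increases across iterations (both solvers)", {
  set.seed(42)
  x <- matrix(abs(rnorm(30 * 6, 50, 20)), 30, 6)
  u <- matrix(runif(180, 2, 6), 30, 6)
  for (method in c("als", "mu")) {
    fit <- pmf_fit(x, u, k = 3, seed = 1, method = method, max_iter = 300)
    expect_true(all(diff(fit$q_trace) <= 1e-8 * (fit$q_trace[1] + 1)),
                info = method)
  }
})

test_that("noiseless data at the true rank is recovered exactly", {
  set.seed(7)
  g0 <- matrix(abs(rnorm(60 * 3, 5, 2)), 60, 3)
  f0 <- rbind(c(5, 1, 0, 0, 0, 1, 0, 2),
              c(0, 0, 4, 1, 0, 0, 1, 0),
              c(1, 0, 0, 0, 6, 0, 0, 1))
  x <- g0 %*% f0
  u <- matrix(1, 60, 8)
  fit <- pmf_fit(x, u, k = 3, seed = 5, n_starts = 5)
  expect_lt(fit$Q, 1e-6 * fit$Qexp)
  # rank-1 exactness
  x1 <- matrix(abs(rnorm(20, 4, 1)), 20, 1) %*% matrix(c(2, 5, 1), 1, 3)
  f1 <- pmf_fit(x1, matrix(1, 20, 3), k = 1, seed = 2)
  expect_lt(max(abs(f1$G %*% f1$F - x1)) / max(x1), 1e-6)
})

test_that("tiny-instance fits match an independent random-restart oracle", {
  # oracle: box-constrained quasi-Newton on a squared parameterization,
  # restarted many times; shares no code with the package's solvers
  set.seed(99)
  n <- 20; m <- 4; k <- 2
  g0 <- matrix(abs(rnorm(n * k, 3, 1)), n, k)
  f0 <- rbind(c(4, 1, 0.2, 0), c(0.3, 0, 3, 1.5))
  x <- g0 %*% f0 + matrix(rnorm(n * m, 0, 0.5), n, m)
  x[x < 0] <- 0
  u <- matrix(0.5, n, m)
  w <- 1 / u^2

  obj <- function(theta) {
    G <- matrix(theta[1:(n * k)]^2, n, k)
    F <- matrix(theta[-(1:(n * k))]^2, k, m)
    sum(w * (x - G %*% F)^2)
  }
  best_oracle <- Inf
  for (r in 1:500) {
    th0 <- rnorm(n * k + k * m, 0, 2)
    res <- tryCatch(optim(th0, obj, method = "L-BFGS-B",
                          control = list(maxit = 400)),
                    error = function(e) list(value = Inf))
    best_oracle <- min(best_oracle, res$value)
  }

  fit <- pmf_fit(x, u, k = k, seed = 3, n_starts = 10)
  expect_lt(abs(fit$Q - best_oracle) / best_oracle, 0.01)
})

test_that("fits are deterministic given data, K and seed", {
  sim <- tiny_campaign(n = 80)
  u <- uncertainty_matrix(sim$data, tiny_unc_spec())
  f1 <- pmf_fit(sim$data, u, k = 3, seed = 17, n_starts = 2)
  f2 <- pmf_fit(sim$data, u, k = 3, seed = 17, n_starts = 2)
  expect_identical(f1$G, f2$G)
  expect_identical(f1$F, f2$F)
  expect_identical(f1$Q, f2$Q)
})

test_that("profile rows are normalized over mass species with scale in G", {
  sim <- tiny_campaign(n = 60)
  u <- uncertainty_matrix(sim$data, tiny_unc_spec())
  fit <- pmf_fit(sim$data, u, k = 3, seed = 1, n_starts = 3)
  expect_equal(unname(rowSums(fit$F)), rep(1, 3), tolerance = 1e-12)
  expect_true(all(fit$G >= 0))
  expect_true(all(fit$F >= 0))
})

test_that("rescaling a species and its uncertainties leaves Q unchanged", {
  sim <- tiny_campaign(n = 60)
  x <- species_matrix(sim$data)
  u <- uncertainty_matrix(sim$data, tiny_unc_spec())
  s <- 1000
  x2 <- x; x2[, 3] <- s * x2[, 3]
  u2 <- u; u2[, 3] <- s * u2[, 3]
  f1 <- pmf_fit(x, u, k = 3, seed = 8, n_starts = 5)
  f2 <- pmf_fit(x2, u2, k = 3, seed = 8, n_starts = 5)
  expect_lt(abs(f1$Q - f2$Q) / f1$Q, 0.01)
})

test_that("factor scan yields nested fits and finds the true elbow", {
  sim <- tiny_campaign(n = 250, seed = 31)
  u <- uncertainty_matrix(sim$data, tiny_unc_spec())
  scan <- scan_factors(sim$data, u, k_min = 1, k_max = 5, n_starts = 10,
                       seed = 2)
  expect_true(all(diff(scan$summary$Q) <= 1e-6 * scan$summary$Q[-5]))
  expect_equal(scan$suggested_k, 3)   # campaign is built from 3 sources
  expect_true(all(scan$summary$n_converged >= 1))
  td <- tidy(scan)
  expect_identical(td, scan$summary)
  expect_equal(glance(scan)$suggested_k, 3)
})

test_that("reconstruction diagnostics report slope and R-squared", {
  sim <- tiny_campaign(n = 60)
  u <- uncertainty_matrix(sim$data, tiny_unc_spec())
  fit <- pmf_fit(sim$data, u, k = 3, seed = 4, n_starts = 3)
  x <- species_matrix(sim$data)

  perfect <- fake_fit(x[, 1, drop = FALSE], diag(1)[, rep(1, 1), drop = FALSE])
  # reconstructed equals input exactly
  perfect$G <- x; perfect$F <- diag(ncol(x))
  st <- model_fit_stats(x, perfect)
  expect_equal(st$slope, 1, tolerance = 1e-10)
  expect_equal(st$r_squared, 1, tolerance = 1e-10)

  half <- perfect; half$G <- 0.5 * x
  st2 <- model_fit_stats(x, half)
  expect_equal(st2$slope, 0.5, tolerance = 1e-10)
  expect_equal(st2$r_squared, 1, tolerance = 1e-10)

  st3 <- model_fit_stats(sim$data, fit)
  expect_gt(st3$slope, 0.9)
  expect_gt(st3$r_squared, 0.9)

  expect_error(model_fit_stats(matrix(1, 5, 2), perfect), "variance")
})

test_that("factor matching recovers permutations and reports similarity", {
  set.seed(12)
  f <- matrix(abs(rnorm(4 * 6)), 4, 6)
  rownames(f) <- paste0("s", 1:4)
  self <- match_factors(f, f)
  expect_equal(self$reference, 1:4)
  expect_equal(self$cosine, rep(1, 4), tolerance = 1e-12)

  perm <- c(3, 1, 4, 2)
  mm <- match_factors(f[perm, ], f)
  expect_equal(mm$reference, perm)
  expect_equal(mm$cosine, rep(1, 4), tolerance = 1e-12)

  other <- matrix(abs(rnorm(4 * 6)), 4, 6)
  rnd <- match_factors(other, f)
  expect_equal(sort(rnd$reference), 1:4)
  expect_true(all(rnd$cosine >= 0 & rnd$cosine <= 1))
})

test_that("tidy and glance expose the fit in broom style", {
  sim <- tiny_campaign(n = 50)
  u <- uncertainty_matrix(sim$data, tiny_unc_spec())
  fit <- pmf_fit(sim$data, u, k = 2, seed = 1)
  td <- tidy(fit)
  expect_equal(nrow(td), 2 * 8)
  expect_true(all(c("factor", "species", "profile", "explained_variation")
                  %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$k, 2)
  expect_equal(gl$q_ratio, fit$Q / fit$Qexp)
})

test_that("invalid inputs to the solver are rejected", {
  x <- matrix(1, 5, 3)
  expect_error(pmf_fit(x, matrix(1, 5, 2), k = 2), "shape")
  expect_error(pmf_fit(x, matrix(0, 5, 3), k = 2), "strictly positive")
  xna <- x; xna[1] <- NA
  expect_error(pmf_fit(xna, matrix(1, 5, 3), k = 2), "non-finite")
  expect_error(pmf_fit(x, matrix(1, 5, 3), k = 4), "k must be")
})
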