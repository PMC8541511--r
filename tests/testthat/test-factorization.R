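test_that("soft threshold follows both branches and rejects negative lam", {
  expect_equal(soft_threshold_nonneg(0.5, 0.2), 0.3)
  expect_equal(soft_threshold_nonneg(0.1, 0.2), 0)
  expect_equal(soft_threshold_nonneg(-0.3, 0.2), 0)
  m <- matrix(c(-1, 0.05, 0.3, 2), 2)
  expect_equal(soft_threshold_nonneg(m, 0.1),
               matrix(c(0, 0, 0.2, 1.9), 2))
  expect_error(soft_threshold_nonneg(1, -0.1),
               class = "valveseg_validation_error")
})

test_that("multiplicative NMF: fixed point, convergence, degenerate input", {
  set.seed(3)
  W0 <- matrix(runif(20), 10, 2)
  H0 <- matrix(runif(10), 2, 5)
  X <- W0 %*% H0
  # exact product with exact initialization is a fixed point
  r <- nmf_multiplicative(X, 2, n_iters = 5L, W0 = W0, H0 = H0)
  expect_equal(r$W %*% r$H, X, tolerance = 1e-10)
  # rank-1 outer product is recovered
  X2 <- outer(c(1, 2), c(1, 1, 1))
  r2 <- nmf_multiplicative(X2, 1, n_iters = 500L, seed = 3L)
  expect_lt(sqrt(sum((X2 - r2$W %*% r2$H)^2) / sum(X2^2)), 1e-3)
  # objective is non-increasing (denominator-guard slack)
  expect_lte(max(diff(r2$objective_trace)), 1e-8)
  # all-zero data drives WH to zero
  r3 <- nmf_multiplicative(matrix(0, 10, 5), 2, n_iters = 50L, seed = 1L)
  expect_lt(sqrt(sum((r3$W %*% r3$H)^2)), 1e-6)
  expect_error(nmf_multiplicative(matrix(1, 4, 3), 3),
               class = "valveseg_validation_error")
})

test_that("Bregman RNMF handles zero and exactly low-rank inputs", {
  z <- bregman_rnmf(matrix(0, 20, 8),
                    fast_fact_cfg(rank = 2L, lam = 0.1, seed = 1L))
  expect_lt(max(abs(z$W %*% z$H)), 1e-6)
  expect_identical(max(z$S), 0)
  set.seed(1)
  X <- outer(runif(100), runif(30))
  r <- bregman_rnmf(X, factorization_config(rank = 1L, lam = 0.1, seed = 11L))
  expect_lt(max(r$S), 0.01 * max(X))
  expect_lt(sqrt(sum((X - r$W %*% r$H)^2) / sum(X^2)), 1e-2)
})

test_that("factors stay nonnegative and p = 1 on the support of S", {
  set.seed(42)
  B <- matrix(runif(100 * 2), 100, 2) %*% matrix(runif(2 * 30), 2, 30)
  B <- B / max(B)
  X <- B
  X[sample(3000, 50)] <- X[sample(3000, 50)] + 1
  r <- bregman_rnmf(X, factorization_config(rank = 2L, lam = 0.1, seed = 7L))
  expect_gte(min(r$diagnostics$min_entries), 0)
  expect_lt(max(r$diagnostics$subgradient_deviation), 1e-9)
  pos <- r$S > 0
  expect_true(any(pos))
  expect_lt(max(abs(r$p[pos] - 1)), 1e-9)
})

test_that("Bregman debiasing beats the frozen-p baseline on planted spikes", {
  set.seed(42)
  B <- matrix(runif(100 * 2), 100, 2) %*% matrix(runif(2 * 30), 2, 30)
  B <- B / max(B)
  idx <- sample(3000, 50)
  X <- B
  X[idx] <- X[idx] + 1.0
  cfg <- factorization_config(rank = 2L, lam = 0.1, seed = 7L)
  fb <- bregman_rnmf(X, cfg, keep_diagnostics = FALSE)
  ff <- bregman_rnmf(X, cfg, freeze_p = TRUE, keep_diagnostics = FALSE)
  expect_lt(abs(mean(fb$S[idx]) - 1.0), 0.05)        # debiased
  expect_lt(abs(mean(ff$S[idx]) - (1 - 0.1)), 0.05)  # shrunk by lam
  expect_lt(mean(abs(fb$S[idx] - 1)), mean(abs(ff$S[idx] - 1)))
})

test_that("exclusion variant reduces to the plain one at mu2 = 0", {
  set.seed(9)
  X <- matrix(runif(50 * 10), 50, 10)
  cfg <- fast_fact_cfg(rank = 2L, lam = 1, mu1 = 1, mu2 = 0, seed = 4L)
  e <- exclusion_rnmf(X, cfg)
  b <- bregman_rnmf(X, cfg)
  expect_lt(max(abs(e$S - b$S)), 1e-10)
  expect_lt(max(abs(e$W - b$W)), 1e-10)
  expect_lt(max(abs(e$H - b$H)), 1e-10)
  z <- exclusion_rnmf(matrix(0, 20, 8), fast_fact_cfg(rank = 2L, seed = 1L))
  expect_lt(max(abs(z$W %*% z$H)) + max(z$S), 1e-6)
})

test_that("exclusion term suppresses co-occurrence of WH and S", {
  ph <- generate_phantom(small_phantom_spec())
  X <- video_to_matrix(ph$video)
  eA <- exclusion_rnmf(X, factorization_config(rank = 5L, mu1 = 1, mu2 = 0.4,
                                               seed = 5L),
                       keep_diagnostics = FALSE)
  eB <- exclusion_rnmf(X, factorization_config(rank = 5L, mu1 = 1, mu2 = 0,
                                               seed = 5L),
                       keep_diagnostics = FALSE)
  expect_lt(mean((eA$W %*% eA$H) * eA$S), mean((eB$W %*% eB$H) * eB$S))
})

test_that("lam = 0 proceeds with a warning about unconstrained S", {
  X <- matrix(runif(30), 10, 3)
  expect_warning(
    bregman_rnmf(X, fast_fact_cfg(rank = 1L, lam = 0, seed = 1L)),
    "unconstrained"
  )
})
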