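test_that("threshold map implements Theta + 2 * lam3 * WH", {
  WH <- matrix(0, 4, 4)
  expect_equal(build_threshold_map(0.3, 2, WH), matrix(0.3, 4, 4))
  WH2 <- matrix(0, 2, 2); WH2[1, 1] <- 0.5
  expect_equal(build_threshold_map(0.01, 1.0, WH2)[1, 1], 1.01)
  set.seed(1)
  WH3 <- matrix(runif(9), 3, 3)
  expect_equal(build_threshold_map(0.2, 0, WH3), matrix(0.2, 3, 3))
  expect_error(build_threshold_map(0.01, 1, matrix(-1, 2, 2)),
               class = "valveseg_validation_error")
  expect_error(build_threshold_map(0, 1, WH3),
               class = "valveseg_validation_error")
})

test_that("isotropic TV matches the forward-difference definition", {
  expect_equal(tv_isotropic(matrix(3, 3, 3)), 0)
  expect_equal(tv_isotropic(matrix(c(0, 0, 1, 1), 2, 2)), 2.0)
  set.seed(2)
  b <- matrix(runif(30), 5, 6)
  expect_equal(tv_isotropic(b + 4.2), tv_isotropic(b))
  # 3-D input: per-frame sums
  arr <- array(c(b, b), c(5, 6, 2))
  expect_equal(tv_isotropic(arr), 2 * tv_isotropic(b))
})

test_that("energy forms agree and match hand-computed values", {
  cfg <- segmentation_config(lam1 = 0, lam2 = 0, lam3 = 1)
  z <- array(0, c(3, 3, 1))
  expect_equal(energy(z, z, z, cfg), 0)
  B <- z; B[2, 2, 1] <- 1
  S <- z; S[2, 2, 1] <- 1
  expect_equal(energy(B, S, z, cfg), 0.5 * (0.01 - 1))
  # Eq-(8)-style and threshold forms are algebraically identical
  set.seed(10)
  for (k in 1:100) {
    d <- c(sample(2:5, 1), sample(2:5, 1), sample(1:3, 1))
    B <- array(runif(prod(d)), d)
    S <- array(runif(prod(d), 0, 1.5), d)
    WH <- array(runif(prod(d), 0, 0.6), d)
    cfgk <- segmentation_config(theta = runif(1, 0.005, 0.1),
                                lam1 = runif(1, 0, 0.1),
                                lam2 = runif(1, 0, 0.2),
                                lam3 = runif(1, 0, 2))
    expect_equal(energy(B, S, WH, cfgk, form = "model"),
                 energy(B, S, WH, cfgk, form = "threshold"),
                 tolerance = 1e-10)
  }
})

test_that("PDHG solves degenerate instances in closed form", {
  # zero sparse component: every pixel's linear coefficient is positive
  sm <- pdhg_segment(array(0, c(4, 4, 2)), array(0, c(4, 4, 2)),
                     fast_seg_cfg())
  expect_identical(max(sm), 0)
  # lam1 = 0: pointwise minimizer is 1 where (theta2 - S)/2 + lam2 < 0
  S1 <- array(0, c(3, 3, 1)); S1[2, 2, 1] <- 1
  smp <- pdhg_segment(S1, array(0, c(3, 3, 1)),
                      segmentation_config(lam1 = 0, n_iters = 400L))
  expect_equal(matrix_to_video(smp, 3, 3)[2, 2, 1], 1, tolerance = 1e-8)
  expect_equal(sum(matrix_to_video(smp, 3, 3)) , 1, tolerance = 1e-6)
})

test_that("PDHG iterates stay in [0,1] and the energy settles", {
  set.seed(5)
  S <- array(runif(6 * 6 * 3, 0, 1.2), c(6, 6, 3))
  WH <- array(runif(6 * 6 * 3, 0, 0.4), c(6, 6, 3))
  sm <- pdhg_segment(S, WH, segmentation_config(n_iters = 600L),
                     trace_every = 1L)
  expect_gte(min(sm), 0)
  expect_lte(max(sm), 1)
  tr <- attr(sm, "energy_trace")
  tail_tr <- tr[seq(541, 600)]
  expect_lt(max(diff(tail_tr)), 1e-6 * max(1, abs(tail_tr[1L])))
})

test_that("large area weight or threshold drives the mask to zero", {
  ph <- generate_phantom(small_phantom_spec())
  f <- bregman_rnmf(video_to_matrix(ph$video), fast_fact_cfg(seed = 2L),
                    keep_diagnostics = FALSE)
  WH <- f$W %*% f$H
  expect_identical(max(pdhg_segment(f$S, WH, fast_seg_cfg(lam2 = 10))), 0)
  expect_identical(max(pdhg_segment(f$S, WH, fast_seg_cfg(theta = 10))), 0)
})

test_that("step sizes violating the operator-norm bound are rejected", {
  expect_error(segmentation_config(tau = 1, sigma_dual = 1),
               class = "valveseg_validation_error")
})

test_that("binarize thresholds strictly at 0.5", {
  m <- matrix(0.9, 2, 2)
  expect_true(all(binarize(m) == 1))
  expect_true(all(binarize(matrix(0.5, 2, 2)) == 0))
  expect_equal(as.vector(binarize(matrix(c(0.2, 0.7), 1))), c(0, 1))
})
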