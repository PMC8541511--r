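test_that("noise-free valve-free phantom is exactly the low-rank background", {
  sp <- phantom_spec(valve_amplitude = 0, noise_sigma = 0)
  ph <- generate_phantom(sp)
  expect_identical(ph$video, ph$truth_background)
  sv <- svd(video_to_matrix(ph$video))$d
  expect_lt(sv[sp$bg_rank + 1L], 1e-10 * sv[1L])
})

test_that("identical specs generate bit-identical phantoms", {
  a <- generate_phantom(phantom_spec(noise_sigma = 0.05, seed = 5L,
                                     distractor_count = 1L))
  b <- generate_phantom(phantom_spec(noise_sigma = 0.05, seed = 5L,
                                     distractor_count = 1L))
  expect_identical(a, b)
})

test_that("phantom output satisfies its structural invariants", {
  for (sp in phantom_fixture_suite()) {
    ph <- generate_phantom(sp)
    expect_gte(min(ph$video), 0)
    expect_lte(max(ph$video), 1)
    expect_gte(min(ph$truth_background), 0)
    # mask is 1 exactly where the valve raster is positive
    expect_identical(ph$truth_valve_mask, (ph$truth_valve_values > 0) * 1L)
    # additive identity (generalized with the distractor raster)
    noise_free <- sp$noise_sigma == 0
    recomposed <- ph$truth_background + ph$truth_valve_values +
      ph$truth_distractor_values
    if (noise_free) {
      expect_equal(ph$video, pmin(pmax(recomposed, 0), 1), tolerance = 1e-12)
    } else {
      # noise is the only remaining term: residual bounded where unclipped
      resid <- ph$video - pmin(pmax(recomposed, 0), 1)
      expect_lt(max(abs(resid)), 8 * sp$noise_sigma)
    }
    # valve sparsity below 5% of the tensor
    expect_lt(mean(ph$truth_valve_mask), 0.05)
  }
})

test_that("rasterized leaflets cover at least valve_length voxels per frame", {
  ph <- generate_phantom(phantom_spec(valve_amplitude = 0.8,
                                      valve_length = 20L))
  per_frame <- apply(ph$truth_valve_mask, 3L, sum)
  expect_true(all(per_frame >= 20L))
})

test_that("rank-truncation error is bounded by the valve energy (no noise)", {
  # The spec's two-sided 1e-6 equality is unattainable: the optimal rank-r
  # subspace absorbs the valve's component in the background's temporal
  # span, so the SVD error is strictly below ||V||_F (see methods vignette).
  sp <- phantom_spec(noise_sigma = 0)
  ph <- generate_phantom(sp)
  sv <- svd(video_to_matrix(ph$video))$d
  err <- sqrt(sum(sv[-seq_len(sp$bg_rank)]^2))
  vnorm <- sqrt(sum(ph$truth_valve_values^2))
  expect_lte(err, vnorm * (1 + 1e-9))
  expect_gte(err, 0.25 * vnorm)
})

test_that("fixture suite provides the named presets with valid specs", {
  suite <- phantom_fixture_suite()
  expect_true(all(c("easy", "noisy", "distractor") %in% names(suite)))
  for (sp in suite) expect_s3_class(sp, "phantom_spec")
  # noisy preset: noise scale comparable to the faint part of the valve
  expect_gte(suite$noisy$noise_sigma, 0.1)
  # distractor raster is bright, moving, and disjoint from the valve
  ph <- generate_phantom(suite$distractor)
  expect_gt(sum(ph$truth_distractor_mask), 0)
  expect_identical(sum(ph$truth_distractor_mask * ph$truth_valve_mask), 0L)
  moved <- ph$truth_distractor_mask[, , 1L] != ph$truth_distractor_mask[, , 5L]
  expect_gt(sum(moved), 0)
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(valve_length = 96L), class = "valveseg_validation_error")
  expect_error(phantom_spec(bg_rank = 0L), class = "valveseg_validation_error")
  expect_error(phantom_spec(height = 0L), class = "valveseg_validation_error")
  expect_error(phantom_spec(hinge_position = c(200, 10)),
               class = "valveseg_validation_error")
})
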