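test_that("template formation is the entrywise memory-minus-reference difference", {
  a <- make_ir(matrix(c(5, 2, 0), 1), intensity = 1)
  b <- make_ir(matrix(c(1, 2, 3), 1))
  tpl <- make_template(a, b)
  expect_equal(tpl$values, matrix(c(4, 0, -3), 1))
  expect_equal(tpl$source_intensity, 1)

  expect_equal(make_template(b, b)$values, matrix(0, 1, 3))

  wide <- make_ir(matrix(0, 1, 4))
  expect_error(make_template(a, wide), class = "softafc_invalid_argument")
  noisy <- add_noise(b, 0.5, seed = 1)
  expect_error(make_template(a, noisy), class = "softafc_invalid_argument")
})

test_that("relative noise scaling follows sigma_w = sigma * x", {
  expect_equal(noise_std(0.009, 2.0), 0.018)
  expect_equal(noise_std(0, 5), 0)
  expect_equal(noise_std(0.3, 4), 2 * noise_std(0.3, 2))
  expect_error(noise_std(-0.1, 1), class = "softafc_invalid_argument")
  expect_error(noise_std(0.1, -1), class = "softafc_invalid_argument")
})

test_that("Gaussian internal noise has the requested level and is seed-reproducible", {
  ir <- make_ir(matrix(2, 100, 1000))
  expect_identical(add_noise(ir, 0)$values, ir$values)
  expect_false(add_noise(ir, 0)$noisy)

  nz <- add_noise(ir, 0.7, seed = 99)
  expect_true(nz$noisy)
  expect_equal(sd(nz$values - ir$values), 0.7, tolerance = 0.03)
  expect_identical(add_noise(ir, 0.7, seed = 99)$values, nz$values)
  expect_error(add_noise(ir, -1), class = "softafc_invalid_argument")
})

test_that("band scores are zero-lag correlations of interval differences with the template", {
  # noiseless trial where the odd interval IS the memory stimulus:
  # dot-product scores are sum(S^2) for RT and 0 for the R intervals
  ir_r <- make_ir(matrix(c(1, 2, 3, 4, 2, 0, 1, 1), 2, 4))
  ir_rt <- make_ir(ir_r$values + matrix(c(0, 3, 0, -1, 2, 0, 0, 1), 2, 4))
  tpl <- make_template(ir_rt, ir_r)
  z <- band_scores(list(ir_r, ir_rt, ir_r), ir_r, tpl, "dot")
  expect_equal(z[, 2], rowSums(tpl$values^2))
  expect_equal(z[, 1], c(0, 0))
  expect_equal(z[, 3], c(0, 0))

  # all-zero template scores 0 everywhere under both normalizations
  tpl0 <- make_template(ir_r, ir_r)
  expect_true(all(band_scores(list(ir_rt, ir_r, ir_rt), ir_r, tpl0, "dot") == 0))
  expect_true(all(band_scores(list(ir_rt, ir_r, ir_rt), ir_r, tpl0, "pearson") == 0))

  # 1-band hand case: d = [1,0,-1], S = [2,0,-2], dot product 4,
  # cross-checked by an independent brute-force loop
  ir_r1 <- make_ir(matrix(c(1, 1, 1), 1))
  nir <- make_ir(matrix(c(2, 1, 0), 1))
  tpl1 <- make_template(make_ir(matrix(c(3, 1, -1), 1)), ir_r1)
  z1 <- band_scores(list(nir, ir_r1, ir_r1), ir_r1, tpl1, "dot")
  brute <- 0
  for (k in 1:3) brute <- brute + (nir$values[1, k] - ir_r1$values[1, k]) *
      tpl1$values[1, k]
  expect_equal(z1[1, 1], 4)
  expect_equal(z1[1, 1], brute)

  # Pearson scores are scale-invariant and bounded
  zp <- band_scores(list(nir, ir_r1, ir_r1), ir_r1, tpl1, "pearson")
  nir_scaled <- nir
  nir_scaled$values <- ir_r1$values + 7 * (nir$values - ir_r1$values)
  zp2 <- band_scores(list(nir_scaled, ir_r1, ir_r1), ir_r1, tpl1, "pearson")
  expect_equal(zp[1, 1], zp2[1, 1], tolerance = 1e-12)
  expect_true(all(abs(zp) <= 1 + 1e-12))
})

test_that("softmax is a valid, temperature-controlled probability map", {
  expect_equal(softmax(c(5, 5, 5), 2), rep(1 / 3, 3))
  expect_equal(softmax(c(log(2), 0, 0), 1), c(0.5, 0.25, 0.25))

  z <- c(0.9, 0.5, 0.2)
  expect_equal(softmax(z, 1e-4 * diff(range(z))), c(1, 0, 0), tolerance = 1e-12)
  expect_equal(softmax(z, 1e8 * diff(range(z))), rep(1 / 3, 3),
               tolerance = 1e-6)

  # no overflow for any finite scores
  expect_equal(sum(softmax(c(1e8, -1e8, 0), 1e-6)), 1)

  expect_error(softmax(z, 0), class = "softafc_invalid_argument")
  expect_error(softmax(c(1, NA, 0), 1), class = "softafc_invalid_argument")

  # property: sums to 1 and stays in [0, 1] over random draws; strictly
  # interior whenever the scaled scores cannot underflow exp()
  for (s in 1:200) {
    zz <- withr::with_seed(s, rnorm(3, sd = 10^runif(1, -3, 3)))
    tt <- withr::with_seed(s + 1000, 10^runif(1, -4, 4))
    p <- softmax(zz, tt)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0 & p <= 1))
    if (diff(range(zz / tt)) < log(2^52)) {
      expect_true(all(p > 0 & p < 1))
    }
  }
})

test_that("trial probability averages the odd-interval probability over included bands", {
  bp <- matrix(1 / 3, 4, 3)
  expect_equal(trial_probability(bp, 2), 1 / 3)

  bp2 <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(trial_probability(bp2, 1), 0.5)

  # excluding a band recomputes the mean over the retained subset
  bp3 <- rbind(c(0.8, 0.1, 0.1), c(1 / 3, 1 / 3, 1 / 3), c(0.2, 0.4, 0.4))
  keep <- c(TRUE, FALSE, TRUE)
  expect_equal(trial_probability(bp3, 1, keep), mean(c(0.8, 0.2)))
  expect_error(trial_probability(bp3, 1, rep(FALSE, 3)),
               class = "softafc_invalid_state")
})

test_that("the legacy argmax decision picks the global maximum and breaks ties fairly", {
  z <- rbind(c(0.1, 0.9, 0.2), c(0.1, 0.3, 0.4))
  expect_equal(argmax_decision(z, 2), 1L)
  expect_equal(argmax_decision(z, 3), 0L)

  ties <- matrix(1, 2, 3)
  hits <- vapply(1:3000, function(i) {
    argmax_decision(ties, 1, seed = derive_seed(3, i))
  }, integer(1))
  expect_gt(mean(hits), 0.303)
  expect_lt(mean(hits), 0.364)
})

test_that("run_point is deterministic and degenerates correctly without randomness", {
  det <- deterministic_frontend()
  cfg <- detection_config(sigma_rel = 0, temperature = 0.5, n_trials = 8,
                          seed = 4, memory_reps = 1)
  pt <- run_point(cfg, det, "amplitude_modulation", 0.5,
                  rt_max_intensity = 1, sample_rate = 8000)
  # no frontend or internal noise: per-trial probabilities identical
  expect_equal(pt$se, 0)
  pt2 <- run_point(cfg, det, "amplitude_modulation", 0.5,
                   rt_max_intensity = 1, sample_rate = 8000)
  expect_equal(pt, pt2)
  # the deterministic RT spikes are discoverable: above chance
  expect_gt(pt$p_correct, 1 / 3)
})

test_that("run_curve validates its grid and keys substreams by intensity", {
  det <- deterministic_frontend()
  cfg <- detection_config(sigma_rel = 0.1, temperature = 0.5, n_trials = 4,
                          seed = 12, memory_reps = 1)
  cv <- run_curve(cfg, det, "amplitude_modulation", c(0.2, 0.5, 1),
                  sample_rate = 8000)
  expect_equal(nrow(cv$points), 3)
  expect_true(all(diff(cv$points$intensity) > 0))

  # a point's value does not depend on which other intensities were swept,
  # provided the sweep maximum (the memory stimulus) is shared
  cv2 <- run_curve(cfg, det, "amplitude_modulation", c(0.5, 1),
                   sample_rate = 8000)
  expect_equal(cv$points$p_correct[cv$points$intensity == 0.5],
               cv2$points$p_correct[cv2$points$intensity == 0.5])

  expect_error(run_curve(cfg, det, "amplitude_modulation", c(0.5, 0.2)),
               class = "softafc_invalid_argument")
  expect_error(run_curve(cfg, det, "amplitude_modulation", 0.5),
               class = "softafc_invalid_argument")
})
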