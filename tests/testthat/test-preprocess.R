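test_that("border-trend subtraction removes a shared additive time course", {
  acq <- tiny_acq()
  spec <- activation_spec(c(15, 15), sigma_major = 3, amplitude = -0.01)
  with_art <- generate_trial_stack(acq, spec, noise_sd = 0,
                                   border_artifact_amp = 0.02, seed = 1)
  without <- generate_trial_stack(acq, spec, noise_sd = 0,
                                  border_artifact_amp = 0, seed = 1)
  fixed <- subtract_border_trend(with_art, 2)
  # interior recovers the artifact-free stack up to the blob's tiny tail
  # leaking into the border estimate
  expect_equal(fixed$data[, , 5:25, 5:25], without$data[, , 5:25, 5:25],
               tolerance = 1e-6)
  # artifact-free constant stack passes through unchanged
  flat <- generate_trial_stack(acq, activation_spec(c(15, 15), amplitude = 0),
                               noise_sd = 0, seed = 1)
  expect_equal(subtract_border_trend(flat, 2)$data - 1, flat$data * 0,
               tolerance = 1e-12)
  expect_error(subtract_border_trend(with_art, 0), "positive")
  expect_error(subtract_border_trend(with_art, 20), "too small")
})

test_that("blob amplitude survives artifact removal", {
  acq <- small_acq()
  spec <- activation_spec(c(20, 20), sigma_major = 4, amplitude = -0.01)
  ref <- generate_trial_stack(acq, spec, noise_sd = 0, seed = 3)
  art <- generate_trial_stack(acq, spec, noise_sd = 0,
                              border_artifact_amp = 0.05, seed = 3)
  amp_ref <- min(ref$data) - 1
  amp_fix <- min(subtract_border_trend(art, 2)$data) - 1
  expect_equal(amp_fix, amp_ref, tolerance = abs(amp_ref) * 0.01)
})

test_that("frame-0 normalization yields exactly zero-mean unit-sd pre-stimulus windows", {
  acq <- tiny_acq()
  st <- generate_trial_stack(acq, activation_spec(c(15, 15), amplitude = -0.01),
                             noise_sd = 0.01, border_artifact_amp = 0.01,
                             seed = 5)
  nz <- temporal_normalize(st)
  pre <- prestim_frames(acq)
  for (tr in seq_len(dim(nz$data)[1])) {
    m <- matrix(nz$data[tr, pre, , ], length(pre))
    expect_equal(max(abs(colMeans(m))), 0, tolerance = 1e-10)
    expect_equal(range(apply(m, 2, sd)), c(1, 1), tolerance = 1e-10)
  }
})

test_that("constant pixels are masked, not infinite, and the result is affine-invariant", {
  acq <- tiny_acq()
  st <- generate_trial_stack(acq, activation_spec(c(15, 15), amplitude = -0.01),
                             noise_sd = 0.01, seed = 6)
  st$data[, , 1, 1] <- 7   # flat pixel
  expect_warning(nz <- temporal_normalize(st), "masked")
  expect_true(all(is.finite(nz$data)))
  expect_true(attr(nz, "masked")[1, 1])
  expect_true(all(nz$data[, , 1, 1] == 0))

  # per-pixel affine rescaling a*x + b leaves the normalized stack unchanged
  st2 <- st
  d <- dim(st2$data)
  a <- matrix(runif(d[3] * d[4], 0.5, 2), d[3], d[4])
  b <- matrix(rnorm(d[3] * d[4]), d[3], d[4])
  for (tr in seq_len(d[1])) for (f in seq_len(d[2]))
    st2$data[tr, f, , ] <- a * st$data[tr, f, , ] + b
  n1 <- suppressWarnings(temporal_normalize(st))
  n2 <- suppressWarnings(temporal_normalize(st2))
  expect_equal(n2$data, n1$data, tolerance = 1e-8)
})

test_that("z-score map obeys its closed forms", {
  acq <- tiny_acq()
  # stim identical to blank: exactly zero
  blank <- generate_trial_stack(acq, activation_spec(c(15, 15), amplitude = 0),
                                noise_sd = 0.01, seed = 8)
  z0 <- compute_static_zscore_map(blank, blank)
  expect_true(all(z0$values == 0))

  # stim = blank + constant offset: z = offset / spatial sd everywhere
  d <- dim(blank$data)
  spatial_vals <- rnorm(d[3] * d[4])
  spatial <- aperm(array(spatial_vals, c(d[3], d[4], d[1], d[2])),
                   c(3, 4, 1, 2))
  base <- trial_stack(1 + spatial, acq)
  delta <- 0.3
  stim <- trial_stack(base$data + delta, acq)
  # blank static map is exactly 1 + spatial, so its spatial sd is known
  s <- sd(spatial_vals)
  z <- compute_static_zscore_map(stim, base)
  expect_equal(range(z$values), rep(delta / s, 2), tolerance = 1e-9)

  # peak |z| grows monotonically with dip amplitude
  peaks <- vapply(c(-0.005, -0.01, -0.02), function(a) {
    st <- generate_trial_stack(acq, activation_spec(c(15, 15), sigma_major = 3,
                                                    amplitude = a),
                               noise_sd = 0.002, seed = 11)
    -min(compute_static_zscore_map(preprocess_stack(st),
                                   preprocess_stack(blank))$values)
  }, 0)
  expect_true(all(diff(peaks) > 0))

  bad <- generate_trial_stack(small_acq(), activation_spec(c(15, 15)), seed = 1)
  expect_error(compute_static_zscore_map(bad, blank), "geometry")
})

test_that("DI/I map recovers the fractional dip and correlates with the z map", {
  acq <- tiny_acq()
  spec <- activation_spec(c(15, 15), sigma_major = 3, amplitude = -0.01)
  stim <- generate_trial_stack(acq, spec, noise_sd = 0, seed = 2)
  blank <- generate_trial_stack(acq, activation_spec(c(15, 15), amplitude = 0),
                                noise_sd = 0, seed = 3)
  dii <- compute_dii_map(stim, blank)
  expect_equal(min(dii), -0.01, tolerance = 1e-10)
  expect_equal(dii[1, 1], 0, tolerance = 1e-10)
  expect_equal(max(abs(compute_dii_map(blank, blank))), 0, tolerance = 1e-12)

  # at recording-like noise the two normalizations agree (r^2 well above 0.7)
  acq2 <- small_acq()
  spec2 <- activation_spec(c(20, 20), sigma_major = 5, amplitude = -0.015)
  stim2 <- generate_trial_stack(acq2, spec2, noise_sd = 0.003, seed = 4)
  blank2 <- generate_trial_stack(acq2, activation_spec(c(20, 20), amplitude = 0),
                                 noise_sd = 0.003, seed = 5)
  z <- compute_static_zscore_map(preprocess_stack(stim2),
                                 preprocess_stack(blank2))
  d2 <- compute_dii_map(stim2, blank2)
  expect_gt(cor(as.vector(z$values), as.vector(d2))^2, 0.7)
})

test_that("activation extraction finds real blobs and rejects pure noise", {
  acq <- small_acq()
  spec <- activation_spec(c(20, 26), sigma_major = 5, amplitude = -0.015)
  stim <- generate_trial_stack(acq, spec, noise_sd = 0.003, seed = 21)
  blank <- generate_trial_stack(acq, activation_spec(c(20, 20), amplitude = 0),
                                noise_sd = 0.003, seed = 22)
  z <- compute_static_zscore_map(preprocess_stack(stim), preprocess_stack(blank))
  reg <- extract_activation(z)
  expect_false(is_empty(reg))
  expect_true(reg$mask[20, 26])
  expect_equal(reg$component_count, 1)

  # false positives: blank-vs-blank sessions almost never yield a region
  hits <- vapply(1:100, function(s) {
    a <- generate_trial_stack(tiny_acq(), activation_spec(c(15, 15), amplitude = 0),
                              noise_sd = 0.003, seed = 1000 + s)
    b <- generate_trial_stack(tiny_acq(), activation_spec(c(15, 15), amplitude = 0),
                              noise_sd = 0.003, seed = 5000 + s)
    zz <- compute_static_zscore_map(preprocess_stack(a), preprocess_stack(b))
    !is_empty(extract_activation(zz))
  }, TRUE)
  expect_lte(mean(hits), 0.01)
})

test_that("smoothing matches a brute-force renormalized box filter and thresholding counts pixels exactly", {
  set.seed(31)
  m <- matrix(rnorm(20 * 24), 20, 24)
  k <- 5
  brute <- matrix(0, 20, 24)
  for (r in 1:20) for (c in 1:24) {
    rs <- max(1, r - 2):min(20, r + 2)
    cs <- max(1, c - 2):min(24, c + 2)
    brute[r, c] <- mean(m[rs, cs])
  }
  expect_equal(smooth_flat(m, k), brute, tolerance = 1e-12)

  zm <- zscore_map(m * 2, c(1.5, 2.5))
  cfg <- analysis_config(smooth_kernel = 5)
  k_pixels <- sum(brute * 2 <= cfg$z_threshold)
  reg <- extract_activation(zm, cfg)
  expect_equal(sum(reg$labels > 0), k_pixels)
})

test_that("region extraction is monotone in the threshold", {
  set.seed(32)
  m <- matrix(rnorm(30 * 30, sd = 2), 30, 30)
  zm <- zscore_map(m, c(1.5, 2.5))
  sizes <- vapply(c(-4, -3.09, -2, -1), function(thr) {
    reg <- extract_activation(zm, analysis_config(z_threshold = thr,
                                                  smooth_kernel = 5))
    if (is.null(reg$labels)) 0L else sum(reg$labels > 0)
  }, 0L)
  expect_true(all(diff(sizes) >= 0))
})
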