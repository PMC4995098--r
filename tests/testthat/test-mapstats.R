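test_that("center of mass is the |z|-weighted centroid", {
  m <- matrix(0, 9, 9)
  m[3, 2] <- -1; m[3, 6] <- -3            # weights 1 and 3, 4 columns apart
  zm <- zscore_map(m, c(1.5, 2.5))
  reg <- activation_region(m < 0)
  com <- center_of_mass(zm, reg)
  expect_equal(com[["col"]], 5)           # hand-computed weighted mean
  expect_equal(com[["row"]], 3)

  single <- activation_region(m == -1)
  expect_equal(unname(center_of_mass(zm, single)), c(3, 2))

  # symmetric blob: centroid at its center
  g <- -outer(dnorm(1:21, 11, 3), dnorm(1:21, 11, 3))
  zg <- zscore_map(g / max(abs(g)) * 8, c(1.5, 2.5))
  rg <- activation_region(zg$values < -0.5)
  expect_equal(unname(center_of_mass(zg, rg)), c(11, 11), tolerance = 1e-9)

  expect_warning(res <- center_of_mass(zm, activation_region(m > 1)),
                 "empty")
  expect_null(res)
})

test_that("equivalent ellipse matches known shapes", {
  d <- disc_mask(41, c(21, 21), 10)
  e <- equivalent_ellipse(d, pixel_pitch = 1)
  expect_equal(e$aspect_ratio, 1, tolerance = 0.02)
  expect_equal(e$major_axis_len, 20, tolerance = 0.03 * 20)
  expect_equal(e$equivalent_diameter, 20, tolerance = 0.03 * 20)

  rect <- matrix(FALSE, 50, 60)
  rect[21:30, 11:50] <- TRUE              # 10 rows x 40 cols
  er <- equivalent_ellipse(rect, pixel_pitch = 1)
  expect_equal(er$aspect_ratio, 4, tolerance = 1e-9)
  expect_equal(er$orientation, 0, tolerance = 1e-9)   # long axis along +col
  expect_equal(er$major_axis_len, 4 * sqrt(1600 / 12), tolerance = 1e-9)
  expect_equal(unname(er$geometric_center), c(25.5, 30.5))

  expect_error(equivalent_ellipse(matrix(FALSE, 5, 5)), "3 pixels")
})

test_that("equivalent ellipse agrees with a brute-force second-moment oracle", {
  shapes <- list(ellipse_mask(50, c(25, 25), 14, 6, 0),
                 ellipse_mask(50, c(25, 25), 14, 6, 30),
                 ellipse_mask(50, c(20, 30), 10, 9, 120),
                 disc_mask(50, c(30, 20), 8))
  for (mask in shapes) {
    got <- equivalent_ellipse(mask, pixel_pitch = 1)
    ora <- ellipse_oracle(mask)
    expect_equal(got$major_axis_len, ora$major, tolerance = 1e-8)
    expect_equal(got$minor_axis_len, ora$minor, tolerance = 1e-8)
    expect_equal(got$aspect_ratio, ora$ar, tolerance = 1e-8)
    if (ora$ar > 1.05)
      expect_lt(axial_difference(got$orientation, ora$orientation), 1e-6)
  }
})

test_that("ellipse descriptors transform correctly under translation, rotation and scaling", {
  base <- ellipse_mask(60, c(30, 30), 15, 6, 20)
  e0 <- equivalent_ellipse(base, pixel_pitch = 1)
  shifted <- ellipse_mask(60, c(38, 22), 15, 6, 20)
  es <- equivalent_ellipse(shifted, pixel_pitch = 1)
  expect_equal(es$aspect_ratio, e0$aspect_ratio, tolerance = 0.02)
  expect_equal(es$orientation, e0$orientation, tolerance = 0.5)
  expect_equal(es$major_axis_len, e0$major_axis_len, tolerance = 0.01 * 15)

  rotated <- ellipse_mask(60, c(30, 30), 15, 6, 50)
  er <- equivalent_ellipse(rotated, pixel_pitch = 1)
  expect_equal(axial_difference(er$orientation, e0$orientation + 30), 0,
               tolerance = 1)
  expect_equal(er$aspect_ratio, e0$aspect_ratio, tolerance = 0.03)

  half <- ellipse_mask(60, c(30, 30), 7.5, 3, 20)
  eh <- equivalent_ellipse(half, pixel_pitch = 1)
  expect_equal(eh$aspect_ratio, e0$aspect_ratio, tolerance = 0.08)
})

test_that("polar maps put single-stimulus responses at the stimulus position", {
  mk <- function(v) zscore_map(v, c(1.5, 2.5), pixel_pitch = 0.1)
  z1 <- matrix(0, 5, 5); z1[2, 2] <- -5           # responds only to stim 1
  z2 <- matrix(0, 5, 5); z2[2, 2] <- -5; z2[4, 4] <- -2
  pos <- data.frame(position_deg_x = c(20, 40), position_deg_y = c(0, 0))
  pm <- build_polar_maps(list(mk(z1), mk(z2)), pos)
  expect_equal(pm$azimuth_pref[4, 4], 40)          # only stim 2 drives it
  expect_equal(pm$elevation_pref[4, 4], 0)
  # equal responses to 20 and 40 degrees average to 30
  z3 <- matrix(0, 5, 5); z3[3, 3] <- -4
  z4 <- matrix(0, 5, 5); z4[3, 3] <- -4
  pm2 <- build_polar_maps(list(mk(z3), mk(z4)), pos)
  expect_equal(pm2$azimuth_pref[3, 3], 30)
  expect_true(is.na(pm2$azimuth_pref[1, 1]))       # unresponsive: masked
})

test_that("polar-map intersection round-trips a low-noise non-overlapping session", {
  acq <- small_acq()
  # narrow blobs (below the grid spacing) so receptive fields do not overlap
  ses <- generate_retinotopy_session(acq, size_slope = 0.02,
                                     noise_sd = eps_noise, seed = 2)
  zs <- lapply(seq_along(ses$stacks), function(k)
    compute_static_zscore_map(preprocess_stack(ses$stacks[[k]]),
                              preprocess_stack(ses$blank)))
  pm <- build_polar_maps(zs, ses$metadata)
  errs <- vapply(seq_along(zs), function(k) {
    truth <- ses$stacks[[k]]$truth$center
    got <- expected_cortical_position(
      pm, c(ses$metadata$position_deg_x[k], ses$metadata$position_deg_y[k]))
    sqrt(sum((got - truth)^2))
  }, 0)
  expect_lt(median(errs), 1)                      # within a pixel
  expect_error(expected_cortical_position(pm, c(500, 0)), "span")

  # two queries 20 degrees apart land ~0.44 mm apart at 0.022 mm/deg
  p1 <- expected_cortical_position(pm, c(0, 10))
  p2 <- expected_cortical_position(pm, c(20, 10))
  d_mm <- sqrt(sum((p1 - p2)^2)) * acq$pixel_pitch
  expect_lt(abs(d_mm - 0.44), acq$pixel_pitch + 1e-9)   # within one pixel

  # median positional error of measured centers stays below the blob sigma
  cfg5 <- analysis_config(smooth_kernel = 5)
  sigma_px <- ses$stacks[[1]]$truth$sigma_major
  perr <- vapply(seq_along(zs), function(k) {
    reg <- extract_activation(zs[[k]], cfg5)
    if (is_empty(reg)) return(NA_real_)
    com <- center_of_mass(zs[[k]], reg)
    sqrt(sum((com - ses$stacks[[k]]$truth$center)^2))
  }, 0)
  expect_lt(median(perr, na.rm = TRUE), sigma_px)
})

test_that("positional error behaves like a metric and converts to degrees", {
  expect_equal(positional_error(c(1, 2), c(1, 2), 0.022)$error_mm, 0)
  pe <- positional_error(c(0, 0), c(0.3, 0.4), 0.022)
  expect_equal(pe$error_mm, 0.5)                  # 3-4-5 triangle
  pe2 <- positional_error(c(0, 0), c(0, 0.44), 0.022)
  expect_equal(pe2$error_deg_eq, 20)              # 0.44 mm at 22 um/deg
  expect_error(positional_error(c(0, 0), c(1, 1), 0), "positive")

  set.seed(40)
  for (i in 1:20) {
    a <- rnorm(2); b <- rnorm(2); c <- rnorm(2)
    expect_equal(positional_error(a, b, 1)$error_mm,
                 positional_error(b, a, 1)$error_mm)
    expect_lte(positional_error(a, c, 1)$error_mm,
               positional_error(a, b, 1)$error_mm +
                 positional_error(b, c, 1)$error_mm + 1e-12)
  }
})

test_that("magnification fit recovers exact and simulated slopes", {
  v <- c(10, 20, 30, 40)
  expect_equal(fit_magnification(v, 0.022 * v)$slope, 0.022,
               tolerance = 1e-12)
  expect_error(fit_magnification(c(10, 10), c(1, 2)), "distinct")

  # round trip through the imaging pipeline at very low noise
  acq <- small_acq()
  ses <- generate_retinotopy_session(acq, size_slope = 0.02,
                                     noise_sd = eps_noise, seed = 3)
  cfg5 <- analysis_config(smooth_kernel = 5)
  zs <- lapply(seq_along(ses$stacks), function(k)
    compute_static_zscore_map(preprocess_stack(ses$stacks[[k]]),
                              preprocess_stack(ses$blank)))
  met <- proximap:::measure_zmaps(zs, ses$metadata, cfg5, acq$pixel_pitch)
  slope <- proximap:::magnification_from_metrics(met, ses$metadata,
                                                 acq$pixel_pitch)
  expect_equal(slope, 0.022, tolerance = 0.01 * 0.022)

  # noisy session: slope within 15%
  ses_n <- generate_retinotopy_session(acq, size_slope = 0.02,
                                       noise_sd = 0.003, seed = 4)
  zs_n <- lapply(seq_along(ses_n$stacks), function(k)
    compute_static_zscore_map(preprocess_stack(ses_n$stacks[[k]]),
                              preprocess_stack(ses_n$blank)))
  met_n <- proximap:::measure_zmaps(zs_n, ses_n$metadata, cfg5,
                                    acq$pixel_pitch)
  slope_n <- proximap:::magnification_from_metrics(met_n, ses_n$metadata,
                                                   acq$pixel_pitch)
  expect_equal(slope_n, 0.022, tolerance = 0.15 * 0.022)
})

test_that("size tuning fits and inverts consistently", {
  sizes <- c(5, 10, 15, 20)
  fit <- fit_size_tuning(sizes, 0.081 * sizes + 0.2)
  expect_equal(fit$slope, 0.081, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.2, tolerance = 1e-12)
  ext <- predict(fit$fit, data.frame(sizes_deg = 12))
  expect_equal(as.numeric(equivalent_visual_size(fit, ext)), 12,
               tolerance = 1e-9)
  expect_warning(equivalent_visual_size(fit, 10), "extrapolates")
  expect_error(fit_size_tuning(c(5, 5), c(1, 2)), "distinct")
})
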