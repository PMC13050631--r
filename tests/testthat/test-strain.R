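test_that("phase-cycle combination isolates the stimulated echo", {
  pc <- tiny_phantom_config()
  coils <- coil_model(pc$n_coils, pc$grid_size, pc$fov_mm)
  ph <- render_dense_images(pc, coils)
  ph_pure <- render_dense_images(tiny_phantom_config(artifact_amplitude = 0),
                                 coils)
  comb <- combine_phase_cycles(ph$images)
  expect_equal(dim(comb$images)[5], 1L)
  pure <- ph_pure$images$images[, , , , 1, , drop = FALSE]
  # artifact cancels exactly: combined equals the pure stimulated echo
  expect_lt(max(Mod(comb$images - pure)), 1e-12)
  # with no artifact, combination reproduces the single-cycle magnitude
  comb_pure <- combine_phase_cycles(ph_pure$images)
  expect_equal(Mod(comb_pure$images), Mod(pure), tolerance = 1e-12)
  # single-cycle data pass through
  img1 <- dense_images(pure, pixel_mm = pc$pixel_mm,
                       ke_cyc_per_mm = pc$ke_cyc_per_mm)
  expect_identical(combine_phase_cycles(img1), img1)
})

test_that("coil combination preserves the encoded phase", {
  n <- 16
  set.seed(7)
  base <- matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)), n, n)
  arr <- array(0 + 0i, dim = c(n, n, 1, 2, 1, 1))
  arr[, , 1, 1, 1, 1] <- base; arr[, , 1, 2, 1, 1] <- 2 * base
  img <- dense_images(arr, pixel_mm = 1, ke_cyc_per_mm = 0.1)
  s1 <- array(1 + 0i, dim = c(n, n, 1))
  out <- coil_combine(img, s1)
  expect_lt(max(Mod(out$images[, , , 1] - arr[, , 1, , 1, 1])), 1e-12)

  # two coils, equal data, sensitivities 1 and i: phase preserved
  arr2 <- array(0 + 0i, dim = c(n, n, 2, 1, 1, 1))
  arr2[, , 1, 1, 1, 1] <- base
  arr2[, , 2, 1, 1, 1] <- 1i * base
  img2 <- dense_images(arr2, pixel_mm = 1, ke_cyc_per_mm = 0.1)
  s2 <- array(c(rep(1 + 0i, n^2), rep(1i, n^2)), dim = c(n, n, 2))
  out2 <- coil_combine(img2, s2)
  expect_lt(max(abs(Arg(out2$images[, , 1, 1] * Conj(base)))), 1e-12)

  # noise-free phantom: combined phase equals the encoded phase
  pc <- tiny_phantom_config()
  coils <- coil_model(pc$n_coils, pc$grid_size, pc$fov_mm)
  ph <- render_dense_images(pc, coils)
  comb <- coil_combine(combine_phase_cycles(ph$images), coils$sensitivities)
  f <- 3
  enc <- Arg(comb$images[, , f, 2] * Conj(comb$images[, , f, 1]))
  truth <- 2 * pi * pc$ke_cyc_per_mm * ph$displacement[, , 1, f]
  mk <- ph$mask[, , f]
  dphi <- (enc - truth)[mk]
  expect_lt(max(abs(Arg(exp(1i * dphi)))), 1e-6)

  expect_error(coil_combine(img, array(0 + 0i, dim = c(n, n, 1))), "zero")
})

test_that("phase unwrapping recovers smooth fields modulo 2 pi", {
  # already-unwrapped input is returned unchanged
  n <- 24
  mask <- matrix(TRUE, n, n)
  ph0 <- matrix(seq(-1, 1, length.out = n), n, n)
  expect_equal(unwrap_phase(ph0, mask), ph0, tolerance = 1e-12)

  # linear ramp 0 -> 3 pi across the mask
  ramp <- matrix(seq(0, 3 * pi, length.out = n), n, n, byrow = TRUE)
  wrapped <- Arg(exp(1i * ramp))
  unw <- unwrap_phase(wrapped, mask)
  expect_lt(max(abs(unw - ramp)), 1e-3)
  # output differs from input by exact multiples of 2 pi
  k <- (unw - wrapped) / (2 * pi)
  expect_lt(max(abs(k - round(k))), 1e-6)

  # disconnected regions warn and unwrap independently
  mask2 <- mask; mask2[, 12:13] <- FALSE
  expect_warning(unwrap_phase(wrapped, mask2), "disconnected")
})

test_that("displacement maps recover a known translation", {
  expect_equal(phase_to_displacement(pi, 0.10), 5)
  expect_equal(phase_to_displacement(0, 0.2), 0)
  expect_error(phase_to_displacement(1, 0), "positive")

  # phantom with a pure 3 mm x-translation, no recon: sub-0.05 mm recovery
  pc <- tiny_phantom_config(peak_contraction_fraction = 0,
                            peak_twist_deg = 0,
                            bulk_translation_mm = c(3, 0),
                            systole_fraction = 0.5)
  coils <- coil_model(pc$n_coils, pc$grid_size, pc$fov_mm)
  ph <- render_dense_images(pc, coils)
  comb <- coil_combine(combine_phase_cycles(ph$images), coils$sensitivities)
  disp <- displacement_maps(comb, ph$mask)
  err <- disp - ph$displacement
  expect_lt(rms(err), 0.05)
})

test_that("E_cc estimation matches closed forms", {
  # rigid translation: zero strain
  n <- 48
  u <- array(0, dim = c(n, n, 2)); u[, , 1] <- 2.5; u[, , 2] <- -1
  mask <- matrix(FALSE, n, n); mask[10:38, 10:38] <- TRUE
  ecc <- compute_ecc(u, mask, center = c(0, 0), pixel_mm = 2)
  expect_lt(max(abs(ecc), na.rm = TRUE), 1e-3)

  # rigid rotation + translation with exact derivatives: zero strain
  pr <- phantom_config(grid_size = 48, fov_mm = 96, n_phases = 8,
                       n_coils = 4, peak_contraction_fraction = 0,
                       peak_twist_deg = 8, epicardial_radius_mm = 20,
                       endocardial_radius_mm = 10)
  mf <- make_motion_field(pr, 4)
  eccr <- compute_ecc(simplify2array(list(mf$ux, mf$uy)), mf$mask,
                      pixel_mm = 2, smooth_sigma = 0)
  em <- densemp:::erode_mask(mf$mask, 1)
  expect_lt(max(abs(eccr[em]), na.rm = TRUE), 1e-3)

  # uniform contraction lambda = 0.9: E_cc = -0.095 across the wall
  pcc <- phantom_config(grid_size = 48, fov_mm = 96, n_phases = 8,
                        n_coils = 4, peak_contraction_fraction = 0.1,
                        peak_twist_deg = 0, bulk_translation_mm = c(0, 0),
                        transmural_falloff = 0, systole_fraction = 0.5,
                        epicardial_radius_mm = 20,
                        endocardial_radius_mm = 10)
  mfc <- make_motion_field(pcc, 4)
  eccc <- compute_ecc(simplify2array(list(mfc$ux, mfc$uy)), mfc$mask,
                      pixel_mm = 2)
  emc <- densemp:::erode_mask(mfc$mask, 1)
  expect_equal(mean(eccc[emc], na.rm = TRUE), -0.095, tolerance = 0.01)
  expect_lt(max(abs(eccc[emc] - (-0.095)), na.rm = TRUE), 0.01)

  # full phantom motion, analytic field: RMS error < 0.01
  pcf <- ablation_phantom_config()
  for (f in c(3, 5)) {
    mff <- make_motion_field(pcf, f)
    e <- compute_ecc(simplify2array(list(mff$ux, mff$uy)), mff$mask,
                     pixel_mm = pcf$pixel_mm)
    emf <- densemp:::erode_mask(mff$mask, 1)
    truthf <- (mff$lambda^2 - 1) / 2
    expect_lt(rms((e - truthf)[emf]), 0.01)
  }
  expect_error(compute_ecc(u, mask, center = c(1e4, 0), pixel_mm = 2),
               "outside")
})

test_that("segmental statistics follow the AHA sector conventions", {
  n <- 48
  pcc <- phantom_config(grid_size = n, fov_mm = 96, n_phases = 8,
                        n_coils = 4, epicardial_radius_mm = 20,
                        endocardial_radius_mm = 10)
  mf <- make_motion_field(pcc, 0)
  mask <- mf$mask
  uni <- matrix(-0.1, n, n)
  st <- segment_stats(uni, mask, pixel_mm = 2)
  expect_equal(unname(st$segment_means[, 1]), rep(-0.1, 6))
  expect_equal(unname(st$segment_sds[, 1]), rep(0, 6))
  expect_equal(st$segment_labels[1], "anterior")

  # rotating the angular reference by 60 degrees permutes segments cyclically
  set.seed(10)
  field <- matrix(rnorm(n^2), n, n)
  s0 <- segment_stats(field, mask, rv_insertion_angle = 0, pixel_mm = 2)
  s1 <- segment_stats(field, mask, rv_insertion_angle = pi / 3, pixel_mm = 2)
  expect_equal(unname(s1$segment_means[1:5, 1]),
               unname(s0$segment_means[2:6, 1]))
  expect_equal(unname(s1$segment_means[6, 1]),
               unname(s0$segment_means[1, 1]))

  # empty segments are flagged missing, not zero
  half <- mask
  half[, 1:(n / 2)] <- FALSE  # keep only y > 0 pixels
  sh <- segment_stats(field, half, pixel_mm = 2)
  expect_true(any(is.na(sh$segment_means[, 1])))
  expect_false(any(sh$segment_means[, 1] == 0, na.rm = TRUE))
})
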