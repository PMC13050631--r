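test_that("motion field matches closed-form displacements", {
  # identity motion
  pc0 <- phantom_config(grid_size = 64, fov_mm = 128, n_phases = 8,
                        n_coils = 4, peak_contraction_fraction = 0,
                        peak_twist_deg = 0, bulk_translation_mm = c(0, 0))
  for (f in c(0, 3, 7)) {
    mf <- make_motion_field(pc0, f)
    expect_lt(max(abs(c(mf$ux, mf$uy)), na.rm = TRUE), 1e-10)
  }

  # pure rigid rotation: chord length 2 R sin(tau/2) at R = 30 mm, 6 deg
  pcr <- phantom_config(grid_size = 64, fov_mm = 128, n_phases = 8,
                        n_coils = 4, peak_contraction_fraction = 0,
                        peak_twist_deg = 6, bulk_translation_mm = c(0, 0),
                        systole_fraction = 0.5,
                        epicardial_radius_mm = 34,
                        endocardial_radius_mm = 22)
  mf <- make_motion_field(pcr, 4, grid = "reference")  # t = 0.5: full twist
  # grid point exactly at (30, 0) mm
  i30 <- which(abs(grid_coords_mm_test(64, 128) - 30) < 1e-9)
  ic <- which(abs(grid_coords_mm_test(64, 128)) < 1e-9)
  u <- c(mf$ux[i30, ic], mf$uy[i30, ic])
  expect_equal(sqrt(sum(u^2)), 2 * 30 * sin(3 * pi / 180), tolerance = 1e-6)

  # uniform contraction c = 0.1: radial displacement -3 mm at R = 30
  pcc <- phantom_config(grid_size = 64, fov_mm = 128, n_phases = 8,
                        n_coils = 4, peak_contraction_fraction = 0.1,
                        peak_twist_deg = 0, bulk_translation_mm = c(0, 0),
                        transmural_falloff = 0, systole_fraction = 0.5,
                        epicardial_radius_mm = 34,
                        endocardial_radius_mm = 22)
  mf <- make_motion_field(pcc, 4, grid = "reference")
  expect_equal(mf$ux[i30, ic], -3, tolerance = 1e-9)
  expect_equal(mf$uy[i30, ic], 0, tolerance = 1e-9)

  expect_error(make_motion_field(pc0, 8), "out of range")
})

test_that("analytic E_cc matches its closed forms", {
  pcc <- phantom_config(grid_size = 48, fov_mm = 96, n_phases = 8,
                        n_coils = 4, peak_contraction_fraction = 0.1,
                        peak_twist_deg = 0, bulk_translation_mm = c(0, 0),
                        transmural_falloff = 0, systole_fraction = 0.5,
                        epicardial_radius_mm = 20,
                        endocardial_radius_mm = 10)
  # lambda = 1 at frame 0
  e0 <- analytic_ecc(pcc, 0)
  expect_lt(max(abs(e0), na.rm = TRUE), 1e-12)
  # lambda = 0.9 at peak: E_cc = (0.81 - 1)/2 = -0.095 everywhere
  e <- analytic_ecc(pcc, 4)
  expect_equal(mean(e, na.rm = TRUE), -0.095, tolerance = 1e-9)
  expect_lt(stats::sd(e[is.finite(e)]), 1e-12)
  # rigid rotation only: zero strain
  pcr <- phantom_config(grid_size = 48, fov_mm = 96, n_phases = 8,
                        n_coils = 4, peak_contraction_fraction = 0,
                        peak_twist_deg = 8, bulk_translation_mm = c(0, 0),
                        epicardial_radius_mm = 20,
                        endocardial_radius_mm = 10)
  expect_lt(max(abs(analytic_ecc(pcr, 4)), na.rm = TRUE), 1e-12)
})

test_that("analytic E_cc agrees with finite-difference Green-Lagrange", {
  pc <- phantom_config(grid_size = 96, fov_mm = 96, n_phases = 8,
                       n_coils = 4, epicardial_radius_mm = 20,
                       endocardial_radius_mm = 10)
  h <- pc$pixel_mm
  for (f in c(2, 4)) {
    mf <- make_motion_field(pc, f, grid = "reference")
    # deformed position x = X + u on the reference grid
    n <- pc$grid_size
    xv <- grid_coords_mm_test(n, pc$fov_mm)
    px <- matrix(xv, n, n) + mf$ux
    py <- matrix(xv, n, n, byrow = TRUE) + mf$uy
    ddx <- function(m) (m[3:n, ] - m[1:(n - 2), ]) / (2 * h)
    ddy <- function(m) (m[, 3:n] - m[, 1:(n - 2)]) / (2 * h)
    mid <- function(m) m[2:(n - 1), 2:(n - 1)]
    f11 <- ddx(px)[, 2:(n - 1)]; f12 <- ddy(px)[2:(n - 1), ]
    f21 <- ddx(py)[, 2:(n - 1)]; f22 <- ddy(py)[2:(n - 1), ]
    # circumferential direction at the reference position
    Xr <- mid(matrix(xv, n, n)); Yr <- mid(matrix(xv, n, n, byrow = TRUE))
    a <- atan2(Yr, Xr); sa <- sin(a); ca <- cos(a)
    c11 <- f11^2 + f21^2; c12 <- f11 * f12 + f21 * f22
    c22 <- f12^2 + f22^2
    ecc_fd <- ((c11 - 1) / 2) * sa^2 - c12 * sa * ca + ((c22 - 1) / 2) * ca^2
    truth <- mid((make_motion_field(pc, f, grid = "reference")$lambda^2 - 1) / 2)
    em <- mid(densemp:::erode_mask(mf$mask, 2))
    err <- (ecc_fd - truth)[em]
    expect_lt(rms(err), 1e-3)
  }
})

test_that("deformed mask area tracks the analytic annulus area", {
  pc <- phantom_config()  # full 128^2 study geometry
  ab <- densemp:::transmural_coefs(pc)
  for (f in c(0, 4, 8)) {
    mv <- densemp:::motion_at_frame(pc, f)
    mf <- make_motion_field(pc, f)
    r_endo <- densemp:::deform_radius(pc$endocardial_radius_mm, mv$cc, ab)
    r_epi <- densemp:::deform_radius(pc$epicardial_radius_mm, mv$cc, ab)
    analytic <- pi * (r_epi^2 - r_endo^2)
    measured <- sum(mf$mask) * pc$pixel_mm^2
    expect_lt(abs(measured - analytic) / analytic, 0.02)
  }
})

test_that("rendered images obey the encoding and phase-cycling model", {
  pc <- tiny_phantom_config()
  coils <- coil_model(pc$n_coils, pc$grid_size, pc$fov_mm)
  ph <- render_dense_images(pc, coils)

  # frame 0: zero displacement, so all encodings identical
  for (e in 2:3) {
    expect_equal(ph$ideal[, , 1, , e], ph$ideal[, , 1, , 1], tolerance = 1e-12)
  }

  # cycle combination cancels the artifact echo exactly
  pc_noart <- tiny_phantom_config(artifact_amplitude = 0)
  ph_noart <- render_dense_images(pc_noart, coils)
  comb <- (ph$ideal[, , , 1, ] - ph$ideal[, , , 2, ]) / 2
  pure <- ph_noart$ideal[, , , 1, ]
  expect_lt(max(Mod(comb - pure)), 1e-12)

  # single-cycle image differs from the stimulated echo when artifact > 0
  expect_gt(max(Mod(ph$ideal[, , , 1, ] - pure)), 0.1)

  # uniform 5 mm x-translation at ke = 0.1 encodes phase pi (wrapped)
  pct <- tiny_phantom_config(peak_contraction_fraction = 0,
                             peak_twist_deg = 0,
                             bulk_translation_mm = c(5, 0),
                             systole_fraction = 0.5)
  pht <- render_dense_images(pct, coils)
  f_pk <- 3  # frame 2 (0-based) at t = 0.5: full translation
  dphi <- Arg(pht$ideal[, , f_pk, 1, 2] * Conj(pht$ideal[, , f_pk, 1, 1]))
  msk <- pht$mask[, , f_pk] & Mod(pht$ideal[, , f_pk, 1, 1]) > 0.5
  expect_lt(max(abs(cos(dphi[msk]) + 1)), 1e-9)  # phase = pi mod 2 pi

  # zero motion, no artifact: reference-subtracted phase is zero in mask
  pc00 <- tiny_phantom_config(peak_contraction_fraction = 0,
                              peak_twist_deg = 0,
                              bulk_translation_mm = c(0, 0),
                              artifact_amplitude = 0)
  ph00 <- render_dense_images(pc00, coils)
  d0 <- Arg(ph00$ideal[, , 2, 1, 2] * Conj(ph00$ideal[, , 2, 1, 1]))
  expect_lt(max(abs(d0[ph00$mask[, , 2]])), 1e-12)

  expect_error(phantom_config(endocardial_radius_mm = 40,
                              epicardial_radius_mm = 30))
})
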