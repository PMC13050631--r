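test_that("spiral design satisfies the stated geometry", {
  traj <- design_spiral(128, 156, 4, n_points = 2784)
  expect_equal(traj$n_turns, 16)  # 128 / (2 * 4)
  # every interleaf starts at k = 0
  expect_equal(unname(traj$kx[1, ]), rep(0, 4))
  expect_equal(unname(traj$ky[1, ]), rep(0, 4))
  # Nyquist radius
  kr <- sqrt(traj$kx^2 + traj$ky^2)
  expect_equal(max(kr), 128 / (2 * 156), tolerance = 1e-12)
  expect_lt(abs(max(kr) - 0.410), 5e-3)
  # interleaf m is interleaf 0 rotated by 2 pi m / N_sp
  rot <- pi / 2
  expect_equal(traj$kx[, 2],
               cos(rot) * traj$kx[, 1] - sin(rot) * traj$ky[, 1],
               tolerance = 1e-10)
  expect_error(design_spiral(128, 156, 4, n_points = 1500), "undersampled")
  expect_s3_class(design_spiral(128, 156, 4, n_points = 1500,
                                allow_undersampled = TRUE), "spiral_traj")
  expect_error(design_spiral(128, 156, 4, n_points = 100), "matrix_size")
})

test_that("forward model is an exact nonuniform Fourier evaluation", {
  n <- 32
  traj <- design_spiral(n, 64, 4)
  # delta at centre: constant magnitude samples
  d <- matrix(0 + 0i, n, n); d[n / 2 + 1, n / 2 + 1] <- 1
  ks <- forward_sample(d, traj)
  expect_equal(range(Mod(ks$samples)), c(1, 1), tolerance = 1e-12)
  # linearity
  set.seed(4)
  img <- matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)), n, n)
  s1 <- forward_sample(img, traj)$samples
  s2 <- forward_sample(2 * img, traj)$samples
  expect_equal(s2, 2 * s1, tolerance = 1e-12)
  # shift theorem: delta at x0 gives phase -2 pi k.x0
  off <- c(5, -3)  # pixels
  x0 <- off * (64 / n)
  d2 <- matrix(0 + 0i, n, n)
  d2[n / 2 + 1 + off[1], n / 2 + 1 + off[2]] <- 1
  s <- forward_sample(d2, traj)$samples[, , 1, 1, 1, 1]
  expected <- exp(-2i * pi * (traj$kx * x0[1] + traj$ky * x0[2]))
  expect_lt(max(Mod(s - expected)), 1e-9)
})

test_that("forward model of a uniform disk matches the jinc transform", {
  n <- 64; fov <- 128
  traj <- design_spiral(n, fov, 4)
  a <- 20  # disk radius, mm
  # antialiased disk (4x subpixel averaging) to suppress pixelation error
  xv <- grid_coords_mm_test(n, fov)
  m <- 8
  sub <- ((seq_len(m) - 0.5) / m - 0.5) * (fov / n)
  disk <- matrix(0, n, n)
  for (dx in sub) for (dy in sub) {
    disk <- disk + outer(xv + dx, xv + dy,
                         function(x, y) (x^2 + y^2 <= a^2) + 0)
  }
  disk <- disk / m^2
  s <- forward_sample(disk + 0i, traj)$samples[, , 1, 1, 1, 1]
  kr <- sqrt(traj$kx^2 + traj$ky^2)
  px <- fov / n
  # closed form for the pixel-integrated disk: jinc times the pixel-box sinc
  sincf <- function(u) ifelse(abs(u) < 1e-12, 1, sin(pi * u) / (pi * u))
  analytic <- ifelse(kr > 1e-12,
                     a * besselJ(2 * pi * a * kr, 1) / kr, pi * a^2) / px^2 *
    sincf(traj$kx * px) * sincf(traj$ky * px)
  band <- kr > 0.1 * max(kr) & kr < 0.5 * max(kr)
  scale <- max(Mod(analytic[band]))
  expect_lt(max(Mod(s[band] - analytic[band])) / scale, 0.01)
})

test_that("k-space noise has the requested coil covariance and scale", {
  traj <- design_spiral(32, 64, 4)
  nch <- 4
  dims <- c(nch, 8, 2, 3)
  ks0 <- kspace_set(array(1 + 2i, dim = c(traj$n_points, 4, dims)), traj)
  # sigma = 0 is the identity
  expect_identical(add_noise(ks0, 0, seed = 1)$samples, ks0$samples)
  # determinism under a fixed seed
  n1 <- add_noise(ks0, 1.5, seed = 9)$samples
  n2 <- add_noise(ks0, 1.5, seed = 9)$samples
  expect_identical(n1, n2)
  # per-coil variance within 1% at large n (Sigma = I)
  z <- n1 - ks0$samples
  for (c_ in seq_len(nch)) {
    v <- mean(Mod(z[, , c_, , , ])^2)
    expect_lt(abs(v - 1.5^2) / 1.5^2, 0.01)
  }
  # injected energy matches sigma^2 trace(Sigma) n_samples
  rho <- 0.4
  Sig <- rho^abs(outer(1:nch, 1:nch, "-"))
  nso <- noise_only_kspace(dims, traj, noise_cov = Sig, sigma = 2, seed = 3)
  e <- sum(Mod(nso$samples)^2)
  expected <- 4 * sum(diag(Sig)) * prod(dim(nso$samples)) / nch
  expect_lt(abs(e - expected) / expected, 0.02)
})

test_that("noise-only k-space is zero-mean with the identity coil covariance", {
  traj <- design_spiral(32, 64, 4)
  nch <- 4
  ks <- noise_only_kspace(c(nch, 8, 2, 3), traj, sigma = 1, seed = 12)
  d <- dim(ks$samples)
  zm <- aperm(ks$samples, c(1, 2, 4, 5, 6, 3))
  dim(zm) <- c(prod(d[-3]), d[3])
  expect_lt(max(Mod(colMeans(zm))), 3 / sqrt(nrow(zm)) * 1.2)
  emp <- crossprod(zm, Conj(zm)) / nrow(zm)
  expect_lt(max(Mod(emp - diag(nch))), 0.05)
  # disjoint seeds give independent realizations
  ks2 <- noise_only_kspace(c(nch, 8, 2, 3), traj, sigma = 1, seed = 77)
  r <- cor(Re(as.vector(ks$samples)), Re(as.vector(ks2$samples)))
  expect_lt(abs(r), 0.01)
  expect_error(noise_only_kspace(c(nch, 8, 2, 3), traj,
                                 noise_cov = matrix(0, nch, nch), sigma = 1),
               "positive definite")
})
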