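test_that("pre-whitening decorrelates the coil noise", {
  # diagonal covariance has a closed-form whitener
  set.seed(8)
  x <- cbind(2 * rcnorm_test(5000), rcnorm_test(5000))
  W <- estimate_prewhitener(x)
  expect_equal(Mod(W), diag(c(0.5, 1)), tolerance = 0.05,
               ignore_attr = TRUE)

  # random PD covariance: whitened empirical covariance close to identity
  nch <- 6
  A <- matrix(complex(real = rnorm(nch^2), imaginary = rnorm(nch^2)), nch)
  Sig <- A %*% Conj(t(A)) + 0.5 * diag(nch)
  L <- densemp:::chol_lower(Sig)
  z <- matrix(rcnorm_test(1e5 * nch), ncol = nch) %*% t(L)
  W <- estimate_prewhitener(z)
  zw <- z %*% t(W)
  emp <- crossprod(zw, Conj(zw)) / nrow(zw)
  expect_lt(max(Mod(emp - diag(nch))), 0.05)

  # Sigma = I: W = I up to phase convention
  zi <- matrix(rcnorm_test(5e4 * 3), ncol = 3)
  expect_equal(Mod(estimate_prewhitener(zi)), diag(3), tolerance = 0.05,
               ignore_attr = TRUE)

  expect_error(estimate_prewhitener(zi[1:20, ]), "10")
  sing <- cbind(zi[, 1], zi[, 1], zi[, 2])  # rank-deficient coils
  expect_error(estimate_prewhitener(sing), "singular|conditioned")
})

test_that("whitening transform application is invertible and shape-safe", {
  traj <- design_spiral(32, 64, 4)
  ks <- noise_only_kspace(c(3, 2, 2, 3), traj, sigma = 1, seed = 2)
  expect_equal(apply_prewhitening(ks, diag(3) + 0i)$samples, ks$samples)
  set.seed(9)
  W <- matrix(complex(real = rnorm(9), imaginary = rnorm(9)), 3) + 2 * diag(3)
  back <- apply_prewhitening(apply_prewhitening(ks, W), solve(W))
  expect_lt(max(Mod(back$samples - ks$samples)), 1e-10)
  expect_error(apply_prewhitening(ks, diag(4) + 0i), "coil")
})

test_that("density compensation is a regularized normalized ramp", {
  traj <- design_spiral(64, 128, 4)
  w <- density_compensation(traj)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(w > 0))
  kr <- sqrt(traj$kx^2 + traj$ky^2)
  # proportional to |k| above the regularization floor
  above <- kr > 1 / traj$fov_mm
  expect_lt(diff(range((w / kr)[above])) / mean((w / kr)[above]), 1e-9)
  # the k = 0 sample sits at the floor
  expect_equal(w[1, 1], min(w), tolerance = 1e-15)
})

test_that("adjoint reconstruction focuses deltas and annihilates zeros", {
  n <- 32
  traj <- design_spiral(n, 64, 4)
  ctr <- n / 2 + 1
  d <- matrix(0 + 0i, n, n); d[ctr, ctr] <- 1
  rec <- adjoint_nufft_recon(forward_sample(d, traj))$images[, , 1, 1, 1, 1]
  expect_equal(Mod(rec[ctr, ctr]), 1, tolerance = 0.05)
  ii <- matrix(seq_len(n), n, n); jj <- t(ii)
  far <- sqrt((ii - ctr)^2 + (jj - ctr)^2) > 3
  expect_gt(Mod(rec[ctr, ctr]) / max(Mod(rec[far])), 10)
  # offset delta focuses within one pixel of the offset
  d2 <- matrix(0 + 0i, n, n); d2[ctr + 10, ctr - 5] <- 1
  r2 <- Mod(adjoint_nufft_recon(forward_sample(d2, traj))$images[, , 1, 1, 1, 1])
  pk <- which(r2 == max(r2), arr.ind = TRUE)
  expect_lte(max(abs(pk - c(ctr + 10, ctr - 5))), 1)
  # zero in, zero out
  z <- kspace_set(array(0 + 0i, dim = c(traj$n_points, 4, 1, 1, 1, 1)), traj)
  expect_equal(max(Mod(adjoint_nufft_recon(z)$images)), 0)
})

test_that("forward and adjoint satisfy the inner-product identity", {
  n <- 32
  traj <- design_spiral(n, 64, 4)
  set.seed(11)
  for (rep in 1:3) {
    x <- matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)), n, n)
    y <- array(complex(real = rnorm(traj$n_points * 4),
                       imaginary = rnorm(traj$n_points * 4)),
               dim = c(traj$n_points, 4, 1, 1, 1, 1))
    Ax <- forward_sample(x, traj)$samples
    AHy <- adjoint_nufft_recon(kspace_set(y, traj),
                               weights = 1)$images[, , 1, 1, 1, 1]
    ip1 <- sum(as.vector(Ax) * Conj(as.vector(y)))
    ip2 <- sum(as.vector(x) * Conj(as.vector(AHy)))
    expect_lt(Mod(ip1 - ip2) / Mod(ip1), 1e-6)
  }
})

test_that("reconstructed whitened noise has Gaussian pixel marginals", {
  traj <- design_spiral(32, 64, 4)
  ks <- noise_only_kspace(c(4, 4, 2, 3), traj, sigma = 1, seed = 30)
  ks$whitened <- TRUE
  rec <- adjoint_nufft_recon(ks)$images
  ctr <- 16 + (-3:3)
  vals <- c(Re(rec[ctr, ctr, 1, , , ]), Im(rec[ctr, ctr, 2, , , ]))
  expect_gt(stats::shapiro.test(sample(vals, min(4000, length(vals))))$p.value,
            0.01)
})

test_that("correction hooks are identity by default and run in order", {
  traj <- design_spiral(32, 64, 4)
  ks <- noise_only_kspace(c(2, 1, 1, 1), traj, sigma = 1, seed = 5)
  expect_identical(correction_hooks(ks)$samples, ks$samples)
  calls <- character(0)
  h1 <- function(k) { calls <<- c(calls, "delay"); k$samples <- k$samples * 2; k }
  h2 <- function(k) { calls <<- c(calls, "offres"); k$samples <- k$samples + 1; k }
  out <- correction_hooks(ks, list(h1, h2))
  expect_identical(calls, c("delay", "offres"))
  expect_equal(out$samples, ks$samples * 2 + 1)
  expect_error(correction_hooks(ks, list(function(k) NULL)), "kspace_set")
})
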