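#' Estimate the coil noise pre-whitening transform
#'
#' From noise-only coil samples, forms the empirical coil covariance
#' `Sigma_hat = X^H X / n` and returns `W = L^{-1}` with `L` the
#' lower-triangular Cholesky factor, so that `W Sigma_hat W^H = I`.
#'
#' @param noise_samples complex matrix (samples x Nch) of noise-only data
#' @param max_condition error if the empirical covariance condition number
#'   exceeds this (ill-conditioned / singular coil covariance)
#' @return Nch x Nch whitening matrix with attribute `"sigma_hat"`
#' @export
estimate_prewhitener <- function(noise_samples, max_condition = 1e8) {
  stopifnot(is.matrix(noise_samples))
  n <- nrow(noise_samples)
  nch <- ncol(noise_samples)
  if (n < 10 * nch) stop("need at least 10 * Nch noise samples")
  # Sigma_hat = (1/n) sum_s n_s n_s^H with n_s the coil vector of sample s
  sigma_hat <- crossprod(noise_samples, Conj(noise_samples)) / n
  ev <- eigen(sigma_hat, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > max_condition) {
    stop("empirical coil covariance is singular or ill-conditioned")
  }
  L <- chol_lower(sigma_hat)
  W <- solve(L)
  attr(W, "sigma_hat") <- sigma_hat
  W
}

#' Apply a pre-whitening transform to multicoil k-space
#'
#' Transforms the coil dimension by `W` at every sample.
#'
#' @param kspace a [kspace_set()]
#' @param W Nch x Nch whitening matrix from [estimate_prewhitener()]
#' @return the whitened [kspace_set()]
#' @export
apply_prewhitening <- function(kspace, W) {
  stopifnot(inherits(kspace, "kspace_set"), is.matrix(W))
  d <- dim(kspace$samples)
  if (nrow(W) != d[3] || ncol(W) != d[3]) {
    stop("whitening matrix does not match the coil dimension")
  }
  zm <- aperm(kspace$samples, c(3, 1, 2, 4, 5, 6))
  dim(zm) <- c(d[3], prod(d[-3]))
  zm <- W %*% zm
  dim(zm) <- c(d[3], d[1], d[2], d[4], d[5], d[6])
  out <- kspace
  out$samples <- aperm(zm, c(2, 3, 1, 4, 5, 6))
  out$whitened <- TRUE
  out
}

#' Analytic ramp density compensation for the Archimedean spiral
#'
#' Uniform-density (linear radius) spirals have sampling density inversely
#' proportional to `|k|`, so the compensation weight is a ramp `w ~ |k|`,
#' regularised at the k-space centre by half the radial arm spacing, and
#' normalised to sum to 1 across all samples so that a unit delta at the FOV
#' centre reconstructs to peak 1.
#'
#' @param traj a [design_spiral()] trajectory
#' @return weight matrix (n_points x n_interleaves), summing to 1
#' @export
density_compensation <- function(traj) {
  stopifnot(inherits(traj, "spiral_traj"))
  kr <- sqrt(traj$kx^2 + traj$ky^2)
  floor_k <- 0.5 / traj$fov_mm  # half the radial Nyquist spacing
  w <- pmax(kr, floor_k)
  w / sum(w)
}

#' Adjoint NUFFT reconstruction of the 6D image set
#'
#' Maps density-compensated spiral samples onto the Cartesian grid with the
#' exact adjoint nonuniform Fourier transform, per (coil, phase, cycle,
#' encoding). Linear in the samples. This is the same transform used by the
#' Monte-Carlo noise calibration, as the threshold ratios absorb whatever
#' correlations it introduces.
#'
#' @param kspace a [kspace_set()]
#' @param weights per-sample density weights, default
#'   [density_compensation()] of the trajectory; pass a scalar 1 for the
#'   pure (unweighted) adjoint
#' @return a [dense_images] container (Nx, Ny, Nch, Nph, Npc, Nenc)
#' @export
adjoint_nufft_recon <- function(kspace, weights = NULL) {
  stopifnot(inherits(kspace, "kspace_set"))
  traj <- kspace$traj
  if (is.null(weights)) weights <- density_compensation(traj)
  d <- dim(kspace$samples)
  S <- kspace$samples * as.vector(weights)  # recycles over (pts, interleaf)
  dim(S) <- c(d[1] * d[2], prod(d[3:6]))
  img <- ndft_adjoint_mat(S, traj)
  dim(img) <- c(traj$matrix_size, traj$matrix_size, d[3:6])
  dense_images(img, pixel_mm = traj$fov_mm / traj$matrix_size,
               ke_cyc_per_mm = kspace$ke_cyc_per_mm,
               whitened = kspace$whitened, traj_id = traj$id)
}

#' Pass-through correction hooks
#'
#' Slots for externally supplied k-space corrections (gradient delay,
#' off-resonance, ...). Each registered callable receives the k-space set and
#' must return one; hooks are applied exactly once each, in registration
#' order. With no hooks this is the identity.
#'
#' @param kspace a [kspace_set()]
#' @param hooks list of functions `kspace_set -> kspace_set`
#' @return the (possibly corrected) [kspace_set()]
#' @export
correction_hooks <- function(kspace, hooks = list()) {
  stopifnot(inherits(kspace, "kspace_set"), is.list(hooks))
  for (h in hooks) {
    stopifnot(is.function(h))
    kspace <- h(kspace)
    if (!inherits(kspace, "kspace_set")) {
      stop("a correction hook did not return a kspace_set")
    }
  }
  kspace
}
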