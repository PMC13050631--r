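#' Design a uniform-density Archimedean spiral k-space trajectory
#'
#' Interleaf m samples
#' \deqn{k(\tau) = k_{max} \tau [\cos, \sin](2\pi n_{turns} \tau + 2\pi m / N_{sp})}
#' for `tau` in \[0, 1\], with `k_max = matrix_size / (2 fov_mm)` (the Nyquist
#' radius, cycles/mm) and `n_turns = matrix_size / (2 n_interleaves)` so that
#' the combined interleaves satisfy the radial Nyquist criterion (adjacent
#' arms 1/FOV apart). Every interleaf starts at k = 0.
#'
#' @param matrix_size reconstruction matrix size (pixels)
#' @param fov_mm field of view (mm)
#' @param n_interleaves number of spiral interleaves (N_sp)
#' @param n_points readout points per interleaf; default gives approximately
#'   azimuthally Nyquist-spaced samples along the arm
#' @param allow_undersampled permit designs below ~85% of the azimuthal
#'   Nyquist sample count instead of erroring
#' @return object of class `spiral_traj` with `kx`, `ky`
#'   (n_points x n_interleaves, cycles/mm)
#' @export
design_spiral <- function(matrix_size, fov_mm, n_interleaves = 4L,
                          n_points = NULL, allow_undersampled = FALSE) {
  stopifnot(matrix_size >= 8, fov_mm > 0, n_interleaves >= 1)
  nyquist_pts <- ceiling(pi / 4 * matrix_size^2 / n_interleaves)
  if (is.null(n_points)) n_points <- nyquist_pts
  n_points <- as.integer(n_points)
  if (n_points < matrix_size) stop("n_points must be >= matrix_size")
  if (!allow_undersampled && n_points < 0.85 * nyquist_pts) {
    stop(sprintf(
      "undersampled spiral: %d points/interleaf < 85%% of the ~%d needed; ",
      n_points, nyquist_pts),
      "pass allow_undersampled = TRUE to override")
  }
  k_max <- matrix_size / (2 * fov_mm)
  n_turns <- matrix_size / (2 * n_interleaves)
  tau <- seq(0, 1, length.out = n_points)
  kx <- matrix(0, n_points, n_interleaves)
  ky <- matrix(0, n_points, n_interleaves)
  for (m in seq_len(n_interleaves)) {
    ang <- 2 * pi * n_turns * tau + 2 * pi * (m - 1) / n_interleaves
    kx[, m] <- k_max * tau * cos(ang)
    ky[, m] <- k_max * tau * sin(ang)
  }
  structure(list(
    kx = kx, ky = ky, n_interleaves = as.integer(n_interleaves),
    n_points = n_points, fov_mm = fov_mm,
    matrix_size = as.integer(matrix_size), k_max = k_max,
    n_turns = n_turns,
    id = sprintf("spiral_%d_%g_%d_%d", matrix_size, fov_mm,
                 n_interleaves, n_points)
  ), class = "spiral_traj")
}

#' @export
print.spiral_traj <- function(x, ...) {
  cat(sprintf(
    "spiral_traj: %d interleaves x %d points, %d turns, k_max %.3f cyc/mm\n",
    x$n_interleaves, x$n_points, round(x$n_turns), x$k_max))
  invisible(x)
}

# ---- exact nonuniform DFT (type 2 forward / type 1 adjoint) ----------------
#
# The forward model evaluates S(k) = sum_x I(x) exp(-2 pi i k.x) at the
# spiral sample locations; the adjoint maps samples back onto the Cartesian
# grid with the conjugate-transposed matrix, so the <Ax, y> = <x, A^H y>
# identity holds to machine precision. The transform matrix is built in row
# chunks to bound memory, and cached when small. Calibration and
# reconstruction share exactly this code path.

ndft_pixel_coords <- function(traj) {
  xv <- grid_coords_mm(traj$matrix_size, traj$fov_mm)
  list(x = rep(xv, times = traj$matrix_size),
       y = rep(xv, each = traj$matrix_size))
}

ndft_chunk <- function(traj, px, rows) {
  kx <- as.vector(traj$kx)[rows]
  ky <- as.vector(traj$ky)[rows]
  exp(-2i * pi * (outer(kx, px$x) + outer(ky, px$y)))
}

ndft_matrix_cached <- function(traj) {
  n_samp <- traj$n_points * traj$n_interleaves
  n_pix <- traj$matrix_size^2
  if (as.numeric(n_samp) * n_pix > 3.2e7) return(NULL)  # > ~512 MB: chunk
  key <- traj$id
  if (is.null(.densemp_cache[[key]])) {
    px <- ndft_pixel_coords(traj)
    .densemp_cache[[key]] <- ndft_chunk(traj, px, seq_len(n_samp))
  }
  .densemp_cache[[key]]
}

# X: (Npix x K) complex -> (Nsamp x K)
ndft_forward_mat <- function(X, traj) {
  E <- ndft_matrix_cached(traj)
  if (!is.null(E)) return(E %*% X)
  n_samp <- traj$n_points * traj$n_interleaves
  px <- ndft_pixel_coords(traj)
  out <- matrix(0 + 0i, n_samp, ncol(X))
  chunk <- max(64L, floor(4e6 / nrow(X)))
  i <- 1L
  while (i <= n_samp) {
    rows <- i:min(i + chunk - 1L, n_samp)
    out[rows, ] <- ndft_chunk(traj, px, rows) %*% X
    i <- i + chunk
  }
  out
}

# S: (Nsamp x K) complex -> (Npix x K), pure (unweighted) adjoint
ndft_adjoint_mat <- function(S, traj) {
  E <- ndft_matrix_cached(traj)
  if (!is.null(E)) return(crossprod(Conj(E), S))
  n_samp <- traj$n_points * traj$n_interleaves
  n_pix <- traj$matrix_size^2
  px <- ndft_pixel_coords(traj)
  out <- matrix(0 + 0i, n_pix, ncol(S))
  chunk <- max(64L, floor(4e6 / n_pix))
  i <- 1L
  while (i <= n_samp) {
    rows <- i:min(i + chunk - 1L, n_samp)
    out <- out + crossprod(Conj(ndft_chunk(traj, px, rows)),
                           S[rows, , drop = FALSE])
    i <- i + chunk
  }
  out
}

#' Multicoil k-space container
#'
#' @param samples complex array (Npts, Nsp, Nch, Nph, Npc, Nenc)
#' @param traj the [design_spiral()] trajectory that produced the samples
#' @param noise_sigma noise level recorded for provenance (a.u.)
#' @param ke_cyc_per_mm displacement-encoding frequency carried as metadata
#' @param whitened logical: has coil pre-whitening been applied
#' @return object of class `kspace_set`
#' @export
kspace_set <- function(samples, traj, noise_sigma = 0,
                       ke_cyc_per_mm = NA_real_, whitened = FALSE) {
  stopifnot(is.array(samples), length(dim(samples)) == 6,
            inherits(traj, "spiral_traj"))
  d <- dim(samples)
  if (d[1] != traj$n_points || d[2] != traj$n_interleaves) {
    stop("sample dimensions inconsistent with trajectory")
  }
  if (any(!is.finite(Re(samples))) || any(!is.finite(Im(samples)))) {
    stop("non-finite k-space values")
  }
  structure(list(samples = samples, traj = traj, noise_sigma = noise_sigma,
                 ke_cyc_per_mm = ke_cyc_per_mm, whitened = whitened),
            class = "kspace_set")
}

#' @export
print.kspace_set <- function(x, ...) {
  cat(sprintf("kspace_set %s (Npts,Nsp,Nch,Nph,Npc,Nenc)%s, sigma = %g\n",
              paste(dim(x$samples), collapse = " x "),
              if (x$whitened) ", whitened" else "", x$noise_sigma))
  invisible(x)
}

#' Sample images through the spiral multicoil forward model
#'
#' Evaluates the exact nonuniform discrete Fourier transform
#' `S_c(k) = sum_x sens_c(x) I(x) exp(-2 pi i k.x)` at every trajectory
#' sample, for every (coil, phase, cycle, encoding). Linear in the image.
#'
#' @param images a `dense_phantom`, a [dense_images] container (coil
#'   dimension already present), or a plain complex matrix (single image,
#'   single coil)
#' @param traj a [design_spiral()] trajectory matching the image grid
#' @param coils optional [coil_model()]: required when `images` has no coil
#'   dimension, ignored otherwise
#' @return a [kspace_set()]
#' @export
forward_sample <- function(images, traj, coils = NULL) {
  stopifnot(inherits(traj, "spiral_traj"))
  ke <- NA_real_
  if (inherits(images, "dense_phantom")) {
    ke <- images$config$ke_cyc_per_mm
    images <- images$images
  }
  if (inherits(images, "dense_images")) {
    ke <- images$ke_cyc_per_mm
    arr <- images$images
  } else if (is.matrix(images)) {
    arr <- array(as.complex(images), dim = c(dim(images), 1, 1, 1, 1))
    if (!is.null(coils)) {
      nch <- dim(coils$sensitivities)[3]
      a6 <- array(0 + 0i, dim = c(dim(images), nch, 1, 1, 1))
      for (c_ in seq_len(nch)) {
        a6[, , c_, 1, 1, 1] <- images * coils$sensitivities[, , c_]
      }
      arr <- a6
    }
  } else {
    stop("images must be a dense_phantom, dense_images, or a matrix")
  }
  d <- dim(arr)
  if (d[1] != traj$matrix_size || d[2] != traj$matrix_size) {
    stop("image grid does not match trajectory matrix size")
  }
  X <- arr
  dim(X) <- c(d[1] * d[2], prod(d[3:6]))
  S <- ndft_forward_mat(X, traj)
  dim(S) <- c(traj$n_points, traj$n_interleaves, d[3:6])
  kspace_set(S, traj, noise_sigma = 0, ke_cyc_per_mm = ke)
}

#' Add correlated complex Gaussian noise to k-space
#'
#' Per k-space sample the coil noise vector is complex Gaussian with
#' covariance `sigma^2 * noise_cov` (`E n n^H`), independent across samples,
#' phases, cycles and encodings. Deterministic under a fixed seed.
#'
#' @param kspace a [kspace_set()]
#' @param sigma noise standard deviation per coil (a.u., `E|n|^2 = sigma^2`
#'   when `noise_cov` has unit diagonal)
#' @param noise_cov Nch x Nch Hermitian positive-definite coil covariance;
#'   `NULL` for independent coils
#' @param seed integer seed
#' @return a [kspace_set()] with noise added and `noise_sigma` updated
#' @export
add_noise <- function(kspace, sigma, noise_cov = NULL, seed = 1L) {
  stopifnot(inherits(kspace, "kspace_set"), sigma >= 0)
  if (sigma == 0) return(kspace)
  d <- dim(kspace$samples)
  nch <- d[3]
  if (!is.null(noise_cov)) check_hermitian_pd(noise_cov, nch)
  noise <- with_seed(seed, {
    z <- array(rcnorm(prod(d)), dim = d)
    if (!is.null(noise_cov)) {
      L <- chol_lower(noise_cov)
      zm <- aperm(z, c(3, 1, 2, 4, 5, 6))
      dim(zm) <- c(nch, prod(d[-3]))
      zm <- L %*% zm
      dim(zm) <- c(nch, d[1], d[2], d[4], d[5], d[6])
      z <- aperm(zm, c(2, 3, 1, 4, 5, 6))
    }
    z
  })
  out <- kspace
  out$samples <- kspace$samples + sigma * noise
  out$noise_sigma <- sqrt(kspace$noise_sigma^2 + sigma^2)
  out
}

#' Noise-only k-space with the acquisition's dimensions
#'
#' Equivalent to [add_noise()] applied to an all-zero signal; used for the
#' Monte-Carlo calibration of the correlated-noise eigenvalue bounds.
#'
#' @param dims integer vector (Nch, Nph, Npc, Nenc)
#' @inheritParams add_noise
#' @param traj a [design_spiral()] trajectory
#' @return a [kspace_set()]
#' @export
noise_only_kspace <- function(dims, traj, noise_cov = NULL, sigma = 1,
                              seed = 1L) {
  stopifnot(length(dims) == 4, all(dims >= 1))
  zero <- array(0 + 0i,
                dim = c(traj$n_points, traj$n_interleaves, dims))
  ks <- kspace_set(zero, traj, noise_sigma = 0)
  add_noise(ks, sigma = sigma, noise_cov = noise_cov, seed = seed)
}
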