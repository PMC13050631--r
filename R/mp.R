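#' Marchenko-Pastur eigenvalue support bounds
#'
#' For a p x q matrix (orientation normalised so gamma = min(p,q)/max(p,q))
#' of i.i.d. zero-mean Gaussian entries with variance `sigma2`, the
#' eigenvalues of the scaled Gram matrix `B B^T / q` are asymptotically
#' supported on \[a, b\] with
#' `a = sigma2 (1 - sqrt(gamma))^2`, `b = sigma2 (1 + sqrt(gamma))^2`.
#'
#' @param sigma2 noise variance (> 0)
#' @param p,q matrix dimensions
#' @return object of class `mp_bounds`: list(sigma2, gamma, a, b)
#' @export
mp_bounds <- function(sigma2, p, q) {
  stopifnot(sigma2 > 0, p >= 1, q >= 1)
  gamma <- min(p, q) / max(p, q)
  a <- sigma2 * (1 - sqrt(gamma))^2
  b <- sigma2 * (1 + sqrt(gamma))^2
  structure(list(sigma2 = sigma2, gamma = gamma, a = a, b = b),
            class = "mp_bounds")
}

#' @export
print.mp_bounds <- function(x, ...) {
  cat(sprintf("mp_bounds: sigma2 = %g, gamma = %.4f, [a, b] = [%g, %g]\n",
              x$sigma2, x$gamma, x$a, x$b))
  invisible(x)
}

#' Marchenko-Pastur eigenvalue density
#'
#' \deqn{p(\lambda) = \frac{\sqrt{(b-\lambda)(\lambda-a)}}{2\pi\gamma\lambda\sigma^2}}
#' for `a <= lambda <= b`, and 0 otherwise (including at the endpoints,
#' where the radicand vanishes).
#'
#' @param lambda eigenvalue(s)
#' @param sigma2 noise variance
#' @param gamma aspect ratio in (0, 1]
#' @return density value(s)
#' @export
mp_pdf <- function(lambda, sigma2, gamma) {
  stopifnot(sigma2 > 0, gamma > 0, gamma <= 1)
  a <- sigma2 * (1 - sqrt(gamma))^2
  b <- sigma2 * (1 + sqrt(gamma))^2
  out <- numeric(length(lambda))
  inside <- lambda >= a & lambda <= b & lambda > 0
  out[inside] <- sqrt((b - lambda[inside]) * (lambda[inside] - a)) /
    (2 * pi * gamma * lambda[inside] * sigma2)
  out
}

#' Eigenvalue spectrum of a Casorati matrix's scaled Gram matrix
#'
#' Eigenvalues of `(1/q) B B^T` where the Gram matrix is formed over the
#' smaller dimension and `q = max(p, q)`; identical to (singular values)^2/q.
#'
#' @param casorati real 2D matrix (a [to_casorati()] output or any matrix)
#' @return object of class `spectrum_result`: list(eigenvalues
#'   (descending), p, q)
#' @export
eigen_spectrum <- function(casorati) {
  stopifnot(is.matrix(casorati), nrow(casorati) >= 1, ncol(casorati) >= 1)
  B <- unclass(casorati)
  p <- nrow(B); q <- ncol(B)
  G <- if (p <= q) tcrossprod(B) else crossprod(B)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values / max(p, q)
  ev <- sort(pmax(ev, 0), decreasing = TRUE)
  structure(list(eigenvalues = ev, p = p, q = q),
            class = "spectrum_result")
}

# the bound ratio chain: b_hat_B = r_upper * (b/a) * r_lower * a_hat_B,
# with b/a = (1 + sqrt(gamma))^2 / (1 - sqrt(gamma))^2
mp_ratio_chain <- function(a_hat_B, p, q, r_upper, r_lower) {
  gamma <- min(p, q) / max(p, q)
  if (gamma >= 1) {
    stop("gamma = 1: b/a is undefined; use a non-square dimension grouping")
  }
  b_over_a <- (1 + sqrt(gamma))^2 / (1 - sqrt(gamma))^2
  r_upper * b_over_a * r_lower * a_hat_B
}

#' Acquisition specification for noise calibration
#'
#' Identifies the reconstruction path whose image-domain noise correlations
#' a [calibrate_ratios()] table describes: the trajectory (or a Cartesian
#' FFT identity reconstruction), the data dimensions, and whether the
#' k-space is coil pre-whitened.
#'
#' @param dims integer vector (Nch, Nph, Npc, Nenc)
#' @param traj a [design_spiral()] trajectory, or `NULL` for a Cartesian
#'   FFT reconstruction of fully sampled k-space
#' @param matrix_size required when `traj` is `NULL`
#' @param whitened logical: calibration assumes unit coil covariance
#'   (pre-whitened data)
#' @return object of class `acquisition_spec`
#' @export
acquisition_spec <- function(dims, traj = NULL, matrix_size = NULL,
                             whitened = TRUE) {
  stopifnot(length(dims) == 4, all(dims >= 1))
  if (is.null(traj)) {
    stopifnot(!is.null(matrix_size))
    id <- sprintf("cartesian_%d", as.integer(matrix_size))
    matrix_size <- as.integer(matrix_size)
  } else {
    stopifnot(inherits(traj, "spiral_traj"))
    id <- traj$id
    matrix_size <- traj$matrix_size
  }
  structure(list(dims = as.integer(dims), traj = traj,
                 matrix_size = matrix_size, whitened = isTRUE(whitened),
                 id = id),
            class = "acquisition_spec")
}

# canonical string key tying a ratio table to acquisition + patch spec
calibration_key <- function(recon_id, matrix_size, dims, spec, whitened) {
  sprintf("%s|N%d|dims%s|patch%dx%ds%d|%s|ri%d|wh%d",
          recon_id, matrix_size, paste(dims, collapse = "-"),
          spec$px, spec$py, spec$stride, spec$grouping, spec$realimag_side,
          as.integer(whitened))
}

# one noise-only image-domain realization through the calibrated recon path
calibration_noise_images <- function(acq, sigma_cal, seed) {
  n <- acq$matrix_size
  if (is.null(acq$traj)) {
    # Cartesian: unitary inverse FFT of fully sampled i.i.d. k-space noise
    d <- c(n, n, acq$dims)
    with_seed(seed, {
      z <- array(rcnorm(prod(d)), dim = d) * sigma_cal
      zm <- matrix(z, n * n, prod(acq$dims))
      out <- vapply(seq_len(ncol(zm)), function(k) {
        m <- matrix(zm[, k], n, n)
        as.vector(fft(m, inverse = TRUE)) / n
      }, complex(n * n))
      array(out, dim = d)
    })
  } else {
    ks <- noise_only_kspace(acq$dims, acq$traj, noise_cov = NULL,
                            sigma = sigma_cal, seed = seed)
    adjoint_nufft_recon(ks)$images
  }
}

#' Monte-Carlo calibration of the correlated-noise bound ratios
#'
#' Gridding of non-Cartesian k-space correlates image-domain noise, so the
#' empirical eigenvalue support \[a_B, b_B\] of noise-only Casorati matrices
#' deviates from the i.i.d. Marchenko-Pastur bounds \[a, b\]. The two ratios
#' `r_upper = b_B / b` and `r_lower = a / a_B` depend on the (intractable)
#' covariance, but are fixed for a given acquisition geometry and patch
#' spec, so they are estimated by simulation: `n_mc` noise-only k-space
#' realizations are reconstructed through the same path as the data, every
#' patch's Gram spectrum extremes are measured, and the ratios (against MP
#' bounds computed from that realization's empirical image-domain noise
#' variance) are averaged per patch location.
#'
#' @param acq an [acquisition_spec()]
#' @param spec a [patch_spec()]
#' @param n_mc number of noise-only realizations (>= 2; default 10)
#' @param sigma_cal k-space noise standard deviation used in calibration
#'   (the ratios are scale-free)
#' @param seed integer seed
#' @return object of class `ratio_table`: per-location matrices `r_upper`,
#'   `r_lower` (patch-grid shaped), their means, the calibration key, and
#'   the Casorati dimensions `p`, `q`
#' @export
calibrate_ratios <- function(acq, spec, n_mc = 10L, sigma_cal = 1,
                             seed = 1L) {
  stopifnot(inherits(acq, "acquisition_spec"), inherits(spec, "patch_spec"))
  if (n_mc < 2) stop("n_mc must be >= 2")
  n <- acq$matrix_size
  g <- patch_grid(n, n, spec)
  ni <- length(g$i); nj <- length(g$j)
  dims6 <- c(n, n, acq$dims)
  geo <- casorati_geometry(spec, dims6)
  qmax <- max(geo$p, geo$q)
  bounds_ref <- mp_bounds(1, geo$p, geo$q)  # scaled by sigma_eff2 below
  r_up <- matrix(0, ni, nj)
  r_lo <- matrix(0, ni, nj)
  for (m in seq_len(n_mc)) {
    arr <- calibration_noise_images(acq, sigma_cal, seed = seed + m)
    sigma_eff2 <- (stats::var(as.vector(Re(arr))) +
                     stats::var(as.vector(Im(arr)))) / 2
    a <- bounds_ref$a * sigma_eff2
    b <- bounds_ref$b * sigma_eff2
    prep <- casorati_prep(arr, spec)
    small_first <- geo$p <= geo$q
    for (jj in seq_len(nj)) {
      for (ii in seq_len(ni)) {
        M <- casorati_at(prep, g$i[ii], g$j[jj])
        B <- if (spec$realimag_side == 1L) rbind(Re(M), Im(M)) else
          cbind(Re(M), Im(M))
        G <- if (small_first) tcrossprod(B) else crossprod(B)
        ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values / qmax
        r_up[ii, jj] <- r_up[ii, jj] + max(ev) / b
        r_lo[ii, jj] <- r_lo[ii, jj] + a / max(min(ev), 1e-300)
      }
    }
  }
  r_up <- r_up / n_mc
  r_lo <- r_lo / n_mc
  structure(list(
    key = calibration_key(acq$id, n, acq$dims, spec, acq$whitened),
    r_upper = r_up, r_lower = r_lo,
    r_upper_mean = mean(r_up), r_lower_mean = mean(r_lo),
    n_mc = as.integer(n_mc), sigma_cal = sigma_cal,
    p = geo$p, q = geo$q, grid = g, spec = spec
  ), class = "ratio_table")
}

#' @export
print.ratio_table <- function(x, ...) {
  cat(sprintf("ratio_table (%d x %d locations, n_mc = %d)\n",
              nrow(x$r_upper), ncol(x$r_upper), x$n_mc))
  cat(sprintf("  key: %s\n", x$key))
  cat(sprintf("  mean r_upper = %.4f, mean r_lower = %.4f (p = %d, q = %d)\n",
              x$r_upper_mean, x$r_lower_mean, x$p, x$q))
  invisible(x)
}

#' Noise eigenvalue threshold for one data patch
#'
#' Estimates the patch's empirical lower noise bound `a_hat_B` from the
#' smallest eigenvalue of its scaled Gram matrix (optionally the mean of the
#' 3 smallest, for robustness), then follows the ratio chain
#' `b_hat_B = r_upper * (b/a) * r_lower * a_hat_B` to the upper noise
#' eigenvalue bound, and converts it to the singular-value cutoff
#' `s* = sqrt(q * b_hat_B)`.
#'
#' @param casorati real Casorati matrix of the data patch
#' @param ratios numeric length-2 vector `c(r_upper, r_lower)` for this
#'   patch location (from a [calibrate_ratios()] table)
#' @param trimmed use the mean of the 3 smallest eigenvalues for `a_hat_B`
#'   instead of the single smallest (default FALSE)
#' @return list with `a_hat_B`, `b_hat_B` (eigenvalue threshold) and
#'   `cutoff_s` (singular-value cutoff)
#' @export
threshold_from_data <- function(casorati, ratios, trimmed = FALSE) {
  stopifnot(is.matrix(casorati), length(ratios) == 2, all(is.finite(ratios)))
  B <- unclass(casorati)
  p <- nrow(B); q <- ncol(B)
  qmax <- max(p, q)
  sv <- svd(B, nu = 0, nv = 0)$d
  ev <- sv^2 / qmax
  a_hat <- if (trimmed) mean(utils::tail(ev, 3)) else min(ev)
  b_hat <- mp_ratio_chain(a_hat, p, q, ratios[1], ratios[2])
  list(a_hat_B = a_hat, b_hat_B = b_hat, cutoff_s = sqrt(qmax * b_hat))
}
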