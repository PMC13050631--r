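# Internal numeric helpers shared across modules.

#' Pixel-centre coordinates (mm) of an Nx-by-Ny grid centred on the FOV centre
#'
#' Index (floor(N/2) + 1) sits exactly at 0 mm, matching the DFT centre
#' convention used by the nonuniform Fourier model.
#' @param n grid size (pixels)
#' @param fov_mm field of view (mm)
#' @return numeric vector of length `n`
#' @keywords internal
grid_coords_mm <- function(n, fov_mm) {
  dx <- fov_mm / n
  (seq_len(n) - 1 - floor(n / 2)) * dx
}

#' Lower-triangular Cholesky factor of a Hermitian positive-definite matrix
#'
#' Base `chol()` does not accept complex input; this is the standard
#' outer-product algorithm, adequate for coil-count sized matrices.
#' @param sigma Hermitian positive-definite matrix (real or complex)
#' @return lower-triangular matrix L with L %*% Conj(t(L)) = sigma
#' @keywords internal
chol_lower <- function(sigma) {
  n <- nrow(sigma)
  stopifnot(ncol(sigma) == n)
  L <- matrix(0 + 0i, n, n)
  for (j in seq_len(n)) {
    djj <- Re(sigma[j, j]) - sum(Mod(L[j, seq_len(j - 1)])^2)
    if (djj <= 0) stop("matrix is not positive definite")
    L[j, j] <- sqrt(djj)
    if (j < n) {
      idx <- (j + 1):n
      if (j > 1) {
        prior <- seq_len(j - 1)
        L[idx, j] <- (sigma[idx, j] - L[idx, prior, drop = FALSE] %*%
                        Conj(L[j, prior])) / L[j, j]
      } else {
        L[idx, j] <- sigma[idx, j] / L[j, j]
      }
    }
  }
  if (is.numeric(sigma)) Re(L) else L
}

#' Draw standard circular complex Gaussian deviates, E|z|^2 = 1
#' @keywords internal
rcnorm <- function(n) {
  complex(real = stats::rnorm(n, sd = sqrt(0.5)),
          imaginary = stats::rnorm(n, sd = sqrt(0.5)))
}

#' Separable Gaussian smoothing of a matrix, optionally mask-normalised
#'
#' With a mask, values outside it do not bleed in: both `x * mask` and `mask`
#' are smoothed and the ratio returned; pixels whose smoothed mask weight is
#' below `min_weight` become NA.
#' @keywords internal
gauss_smooth <- function(x, sigma, mask = NULL, min_weight = 1e-3) {
  if (sigma <= 0) {
    if (!is.null(mask)) x[!mask] <- NA_real_
    return(x)
  }
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-half):half / sigma)^2)
  k <- k / sum(k)
  conv_sep <- function(m) {
    # zero-padded separable convolution via embedding
    nr <- nrow(m); nc <- ncol(m)
    pad <- matrix(0, nr + 2 * half, nc + 2 * half)
    pad[half + seq_len(nr), half + seq_len(nc)] <- m
    # rows
    out <- matrix(0, nr + 2 * half, nc)
    for (t in seq_along(k)) {
      out <- out + k[t] * pad[, (t - 1) + seq_len(nc)]
    }
    res <- matrix(0, nr, nc)
    for (t in seq_along(k)) {
      res <- res + k[t] * out[(t - 1) + seq_len(nr), ]
    }
    res
  }
  if (is.null(mask)) return(conv_sep(x))
  m <- 1 * mask
  xm <- x
  xm[!mask] <- 0
  num <- conv_sep(xm)
  den <- conv_sep(m)
  out <- num / den
  out[den < min_weight] <- NA_real_
  out
}

#' Binary erosion of a mask by a square structuring element
#' @param mask logical matrix
#' @param r erosion radius in pixels (Chebyshev)
#' @keywords internal
erode_mask <- function(mask, r = 1L) {
  if (r <= 0) return(mask)
  m <- mask
  nr <- nrow(mask); nc <- ncol(mask)
  for (dx in -r:r) {
    for (dy in -r:r) {
      shifted <- matrix(FALSE, nr, nc)
      xs <- seq_len(nr) + dx
      ys <- seq_len(nc) + dy
      okx <- xs >= 1 & xs <= nr
      oky <- ys >= 1 & ys <= nc
      shifted[okx, oky] <- mask[xs[okx], ys[oky]]
      m <- m & shifted
    }
  }
  m
}

#' Evaluate an expression with a temporarily fixed RNG seed
#'
#' Restores (or removes) the caller's `.Random.seed`, so library code never
#' perturbs user RNG state. All stochastic operations in the package funnel
#' through this.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(as.integer(seed %% .Machine$integer.max))
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
  }
  force(expr)
}

# cache for nonuniform DFT matrices keyed by trajectory/grid identity
.densemp_cache <- new.env(parent = emptyenv())
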