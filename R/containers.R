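#' 6D cine DENSE image container
#'
#' Thin S3 container around the complex image array with dimensions
#' (Nx, Ny, Nch, Nph, Npc, Nenc) plus the acquisition metadata the denoising
#' and strain stages need, and provenance flags recording what has been done
#' to the data.
#'
#' @param images complex array (Nx, Ny, Nch, Nph, Npc, Nenc)
#' @param pixel_mm pixel size (mm)
#' @param ke_cyc_per_mm displacement-encoding frequency (cycles/mm)
#' @param whitened,denoised logical provenance flags
#' @param traj_id identifier of the trajectory/reconstruction path that
#'   produced the images (used to match calibration tables); NA if unknown
#' @return object of class `dense_images`
#' @export
dense_images <- function(images, pixel_mm, ke_cyc_per_mm,
                         whitened = FALSE, denoised = FALSE,
                         traj_id = NA_character_) {
  stopifnot(is.array(images), length(dim(images)) == 6)
  if (dim(images)[1] != dim(images)[2]) {
    stop("dense_images requires Nx == Ny")
  }
  if (any(!is.finite(Re(images))) || any(!is.finite(Im(images)))) {
    stop("non-finite image values")
  }
  structure(
    list(images = images, pixel_mm = pixel_mm,
         ke_cyc_per_mm = ke_cyc_per_mm,
         whitened = whitened, denoised = denoised, traj_id = traj_id),
    class = "dense_images"
  )
}

#' @export
print.dense_images <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf(
    "dense_images %s (Nx,Ny,Nch,Nph,Npc,Nenc), %.2f mm pixels%s%s\n",
    paste(d, collapse = " x "), x$pixel_mm,
    if (x$whitened) ", whitened" else "",
    if (x$denoised) ", denoised" else ""))
  invisible(x)
}

#' @export
dim.dense_images <- function(x) dim(x$images)

#' Multicoil receive model: sensitivity maps and coil noise covariance
#'
#' Coils are placed on a ring just outside the field of view with Gaussian
#' magnitude profiles wide enough that the sum-of-squares sensitivity is
#' strictly positive everywhere, and smooth per-coil phase. The coil noise
#' covariance defaults to an AR(1)-type Toeplitz matrix
#' `Sigma[i,j] = rho^|i-j|`, Hermitian positive definite, modelling nearest
#' coil coupling.
#'
#' @param n_coils number of coils
#' @param grid_size image matrix size
#' @param fov_mm field of view (mm)
#' @param noise_rho inter-coil noise correlation decay (0 = independent)
#' @param noise_cov optional explicit Hermitian positive-definite covariance
#'   (overrides `noise_rho`)
#' @return object of class `coil_model` with `sensitivities`
#'   (Nx, Ny, Nch complex) and `noise_cov` (Nch x Nch)
#' @export
coil_model <- function(n_coils, grid_size, fov_mm, noise_rho = 0.3,
                       noise_cov = NULL) {
  stopifnot(n_coils >= 1, grid_size >= 8, fov_mm > 0,
            noise_rho >= 0, noise_rho < 1)
  xv <- grid_coords_mm(grid_size, fov_mm)
  X <- matrix(xv, grid_size, grid_size)
  Y <- matrix(xv, grid_size, grid_size, byrow = TRUE)
  ring <- 0.55 * fov_mm
  width <- 0.6 * fov_mm
  sens <- array(0 + 0i, dim = c(grid_size, grid_size, n_coils))
  for (c_ in seq_len(n_coils)) {
    ang <- 2 * pi * (c_ - 1) / n_coils
    px <- ring * cos(ang); py <- ring * sin(ang)
    mag <- exp(-((X - px)^2 + (Y - py)^2) / (2 * width^2))
    # smooth spatial phase, distinct per coil
    ph <- 1.7 * ang + 0.6 * pi * (cos(ang) * X + sin(ang) * Y) / fov_mm
    sens[, , c_] <- mag * exp(1i * ph)
  }
  sos <- apply(abs(sens)^2, c(1, 2), sum)
  if (min(sos) <= 0) stop("sum-of-squares sensitivity vanishes inside FOV")
  if (is.null(noise_cov)) {
    noise_cov <- noise_rho^abs(outer(seq_len(n_coils), seq_len(n_coils), "-"))
  }
  check_hermitian_pd(noise_cov, n_coils)
  structure(list(sensitivities = sens, noise_cov = noise_cov,
                 fov_mm = fov_mm),
            class = "coil_model")
}

check_hermitian_pd <- function(sigma, n) {
  if (!is.matrix(sigma) || nrow(sigma) != n || ncol(sigma) != n) {
    stop("noise covariance must be Nch x Nch")
  }
  if (max(Mod(sigma - Conj(t(sigma)))) > 1e-8 * max(Mod(sigma))) {
    stop("noise covariance must be Hermitian")
  }
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("noise covariance must be positive definite")
  invisible(TRUE)
}

#' @export
print.coil_model <- function(x, ...) {
  d <- dim(x$sensitivities)
  cat(sprintf("coil_model: %d coils on a %d x %d grid\n", d[3], d[1], d[2]))
  invisible(x)
}
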