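#' Configuration of the numerical cine DENSE phantom
#'
#' The phantom is a contracting, twisting annulus (a mid-ventricular
#' short-axis left ventricle) imaged with a 2D spiral cine DENSE protocol.
#' A material point at reference polar coordinates (R, Theta) moves to
#' \deqn{r(R,t) = R (1 - c(t) w(R)), \quad \theta = \Theta + \tau(t)}
#' where `c(t)` is a smooth systole/diastole time course peaking at
#' `peak_contraction_fraction`, `w(R)` a linear transmural weighting equal to
#' 1 at the endocardium falling to `1 - transmural_falloff` at the epicardium,
#' and `tau(t)` the twist time course. Because the motion is axisymmetric the
#' circumferential Green-Lagrange strain is known in closed form,
#' `E_cc = (lambda^2 - 1)/2` with `lambda = r/R`, which makes the phantom an
#' exact oracle for the downstream strain analysis.
#'
#' Defaults follow the high-resolution spiral cine DENSE protocol:
#' 128 x 128 matrix over a 156 mm field of view, 20 cardiac phases, 24 coils,
#' 2 phase-cycling acquisitions, 3 displacement encodings (phase reference,
#' x-encode, y-encode) and a displacement-encoding frequency of
#' 0.10 cycles/mm. Peak mid-wall contraction of 0.18 gives a peak mid-wall
#' E_cc of about -0.16, typical of a healthy left ventricle.
#'
#' @param grid_size image matrix size (Nx = Ny pixels)
#' @param fov_mm field of view (mm)
#' @param n_phases number of cardiac phases (Nph)
#' @param n_coils number of receive coils (Nch)
#' @param n_phase_cycles number of phase-cycling acquisitions (Npc, 1 or 2)
#' @param n_encodings number of displacement encodings (Nenc >= 3)
#' @param epicardial_radius_mm,endocardial_radius_mm annulus radii at
#'   end-diastole (mm)
#' @param peak_contraction_fraction fraction by which the endocardial radius
#'   shrinks at end-systole (dimensionless, in \[0, 1))
#' @param peak_twist_deg peak rigid twist (degrees)
#' @param bulk_translation_mm length-2 rigid in-plane translation of the
#'   ventricle at peak systole (mm), following the same time course as the
#'   contraction; rigid, so it contributes displacement and encoded phase
#'   but no strain
#' @param systole_fraction fraction of the cycle at which contraction peaks
#' @param transmural_falloff linear falloff of the contraction weighting from
#'   endocardium (1) to epicardium (1 - falloff)
#' @param ke_cyc_per_mm displacement-encoding frequency (cycles/mm)
#' @param kd_cyc_per_mm through-plane dephasing frequency (cycles/mm;
#'   metadata only, a 2D phantom has no through-plane structure)
#' @param ste_amplitude stimulated-echo amplitude (a.u.)
#' @param artifact_amplitude amplitude of the non-phase-cycled (T1-recovery)
#'   artifact echo (a.u.)
#' @param t1_decay_per_phase exponential amplitude decay rate per cardiac
#'   phase, mimicking stimulated-echo decay (later phases have lower SNR)
#' @param seed integer seed recorded with the configuration
#' @return an object of class `phantom_config`
#' @export
phantom_config <- function(grid_size = 128L,
                           fov_mm = 156,
                           n_phases = 20L,
                           n_coils = 24L,
                           n_phase_cycles = 2L,
                           n_encodings = 3L,
                           epicardial_radius_mm = 32,
                           endocardial_radius_mm = 22,
                           peak_contraction_fraction = 0.18,
                           peak_twist_deg = 6,
                           bulk_translation_mm = c(2, 1),
                           systole_fraction = 0.4,
                           transmural_falloff = 0.25,
                           ke_cyc_per_mm = 0.10,
                           kd_cyc_per_mm = 0.08,
                           ste_amplitude = 1,
                           artifact_amplitude = 0.3,
                           t1_decay_per_phase = 0.04,
                           seed = 1L) {
  stopifnot(
    grid_size >= 8, fov_mm > 0, n_phases >= 1, n_coils >= 1,
    n_phase_cycles %in% c(1L, 2L), n_encodings >= 3,
    endocardial_radius_mm > 0,
    endocardial_radius_mm < epicardial_radius_mm,
    epicardial_radius_mm < fov_mm / 2,
    peak_contraction_fraction >= 0, peak_contraction_fraction < 1,
    peak_twist_deg >= -90, peak_twist_deg <= 90,
    length(bulk_translation_mm) == 2,
    systole_fraction > 0, systole_fraction < 1,
    transmural_falloff >= 0, transmural_falloff < 1,
    ke_cyc_per_mm > 0, ste_amplitude > 0, artifact_amplitude >= 0,
    t1_decay_per_phase >= 0
  )
  cfg <- list(
    grid_size = as.integer(grid_size), fov_mm = fov_mm,
    n_phases = as.integer(n_phases), n_coils = as.integer(n_coils),
    n_phase_cycles = as.integer(n_phase_cycles),
    n_encodings = as.integer(n_encodings),
    epicardial_radius_mm = epicardial_radius_mm,
    endocardial_radius_mm = endocardial_radius_mm,
    peak_contraction_fraction = peak_contraction_fraction,
    peak_twist_deg = peak_twist_deg,
    bulk_translation_mm = bulk_translation_mm,
    systole_fraction = systole_fraction,
    transmural_falloff = transmural_falloff,
    ke_cyc_per_mm = ke_cyc_per_mm, kd_cyc_per_mm = kd_cyc_per_mm,
    ste_amplitude = ste_amplitude, artifact_amplitude = artifact_amplitude,
    t1_decay_per_phase = t1_decay_per_phase,
    pixel_mm = fov_mm / grid_size,
    seed = as.integer(seed)
  )
  class(cfg) <- "phantom_config"
  cfg
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf(
    "cine DENSE phantom: %d x %d over %g mm FOV (%.2f mm pixels)\n",
    x$grid_size, x$grid_size, x$fov_mm, x$pixel_mm))
  cat(sprintf("  dims: Nch=%d Nph=%d Npc=%d Nenc=%d\n",
              x$n_coils, x$n_phases, x$n_phase_cycles, x$n_encodings))
  cat(sprintf("  annulus %g-%g mm, peak contraction %.2f, twist %g deg\n",
              x$endocardial_radius_mm, x$epicardial_radius_mm,
              x$peak_contraction_fraction, x$peak_twist_deg))
  cat(sprintf("  ke = %g cycles/mm\n", x$ke_cyc_per_mm))
  invisible(x)
}

# smooth 0 -> 1 -> 0 contraction time course over the cycle, peaking at ts
motion_course <- function(t, ts) {
  s <- ifelse(t <= ts,
              sin(pi * t / (2 * ts))^2,
              cos(pi * (t - ts) / (2 * (1 - ts)))^2)
  pmin(pmax(s, 0), 1)
}

# deform a reference radius under contraction level c with transmural
# weighting w(R) = alpha - beta R (alpha, beta from the config)
transmural_coefs <- function(config) {
  dr <- config$epicardial_radius_mm - config$endocardial_radius_mm
  f <- config$transmural_falloff
  list(alpha = 1 + f * config$endocardial_radius_mm / dr, beta = f / dr)
}

deform_radius <- function(R, cc, ab) {
  R * (1 - cc * (ab$alpha - ab$beta * R))
}

# invert r = (1 - cc*alpha) R + cc*beta R^2 for R >= 0
invert_radius <- function(r, cc, ab) {
  A <- cc * ab$beta
  B <- 1 - cc * ab$alpha
  if (abs(A) < 1e-12) return(r / B)
  (-B + sqrt(B^2 + 4 * A * r)) / (2 * A)
}

# contraction level and twist (radians) at a given frame
motion_at_frame <- function(config, frame) {
  t <- frame / config$n_phases
  s <- motion_course(t, config$systole_fraction)
  list(cc = config$peak_contraction_fraction * s,
       tau = config$peak_twist_deg * pi / 180 * s,
       tx = config$bulk_translation_mm[1] * s,
       ty = config$bulk_translation_mm[2] * s)
}

#' Phantom motion field at one cardiac phase
#'
#' Returns the in-plane displacement (mm) of the material point found at each
#' pixel, together with the deformed myocardial mask. With
#' `grid = "deformed"` (default; the quantity a DENSE phase image encodes)
#' the displacement is reported at the pixel's current position; with
#' `grid = "reference"` it is reported on the end-diastolic grid.
#'
#' @param config a [phantom_config()]
#' @param frame cardiac phase index, 0-based, `0 <= frame < n_phases`
#' @param grid `"deformed"` or `"reference"`
#' @return list with matrices `ux`, `uy` (mm, NA outside the annulus),
#'   logical `mask`, `lambda` (circumferential stretch r/R) and `R`
#'   (reference radius, mm)
#' @export
make_motion_field <- function(config, frame, grid = c("deformed", "reference")) {
  stopifnot(inherits(config, "phantom_config"))
  if (frame < 0 || frame >= config$n_phases) {
    stop("frame out of range [0, n_phases)")
  }
  grid <- match.arg(grid)
  mv <- motion_at_frame(config, frame)
  ab <- transmural_coefs(config)
  xv <- grid_coords_mm(config$grid_size, config$fov_mm)
  X <- matrix(xv, config$grid_size, config$grid_size)
  Y <- matrix(xv, config$grid_size, config$grid_size, byrow = TRUE)

  if (grid == "reference") {
    Rr <- sqrt(X^2 + Y^2)
    Th <- atan2(Y, X)
    mask <- Rr >= config$endocardial_radius_mm &
      Rr <= config$epicardial_radius_mm
    r <- deform_radius(Rr, mv$cc, ab)
    th <- Th + mv$tau
    ux <- r * cos(th) + mv$tx - X
    uy <- r * sin(th) + mv$ty - Y
    lambda <- ifelse(Rr > 0, r / Rr, 1)
    ux[!mask] <- NA_real_; uy[!mask] <- NA_real_; lambda[!mask] <- NA_real_
    return(list(ux = ux, uy = uy, mask = mask, lambda = lambda, R = Rr))
  }

  Xc <- X - mv$tx
  Yc <- Y - mv$ty
  r <- sqrt(Xc^2 + Yc^2)
  th <- atan2(Yc, Xc)
  r_endo <- deform_radius(config$endocardial_radius_mm, mv$cc, ab)
  r_epi <- deform_radius(config$epicardial_radius_mm, mv$cc, ab)
  mask <- r >= r_endo & r <= r_epi
  Rr <- invert_radius(r, mv$cc, ab)
  Th <- th - mv$tau
  ux <- X - Rr * cos(Th)
  uy <- Y - Rr * sin(Th)
  lambda <- ifelse(Rr > 0, r / Rr, 1)
  ux[!mask] <- NA_real_; uy[!mask] <- NA_real_; lambda[!mask] <- NA_real_
  list(ux = ux, uy = uy, mask = mask, lambda = lambda, R = Rr)
}

#' Analytic circumferential Green-Lagrange strain of the phantom
#'
#' For the axisymmetric mapping `r = R (1 - c w(R))`, `theta = Theta + tau`,
#' the circumferential stretch of a material fibre is `lambda = r/R` and
#' `E_cc = (lambda^2 - 1)/2`, independent of the (R-uniform) twist.
#'
#' @inheritParams make_motion_field
#' @return matrix of E_cc values at pixels of the deformed annulus
#'   (NA outside)
#' @export
analytic_ecc <- function(config, frame) {
  mf <- make_motion_field(config, frame, grid = "deformed")
  (mf$lambda^2 - 1) / 2
}

# soft-edged annulus amplitude at radius r, edge width ~1 pixel
annulus_amplitude <- function(r, r_in, r_out, edge) {
  step <- function(z) {
    z <- pmin(pmax(z, 0), 1)
    z * z * (3 - 2 * z)
  }
  step((r - r_in) / edge + 0.5) * step((r_out - r) / edge + 0.5)
}

# smooth static background phase field (radians), shared by all echoes
background_phase <- function(config) {
  xv <- grid_coords_mm(config$grid_size, config$fov_mm)
  X <- matrix(xv, config$grid_size, config$grid_size)
  Y <- matrix(xv, config$grid_size, config$grid_size, byrow = TRUE)
  0.3 + 1.2 * X / config$fov_mm + 0.9 * Y / config$fov_mm +
    0.4 * sin(pi * X / config$fov_mm) * cos(pi * Y / config$fov_mm)
}

#' Render the noise-free 6D cine DENSE phantom
#'
#' Builds the complex image array (Nx, Ny, Nch, Nph, Npc, Nenc) together with
#' ground-truth displacement, strain and masks. Each pixel is
#' \deqn{S = sens_c [ A_{ste} d(t) e^{i(\phi_{bg} + \phi_{enc})} s_{pc}
#'        + A_{art} e^{i \phi_{bg}} ]}
#' where `phi_enc` is 0 for the phase-reference encoding and
#' `2 pi ke u_{x|y}` for the x/y encodings (`u` the displacement of the
#' tissue at the pixel), `s_pc = +1/-1` alternates the stimulated-echo sign
#' across the two phase-cycling acquisitions, and the artifact (T1-recovery)
#' echo is static: identical across cycles, frames and encodings, anchored at
#' the end-diastolic annulus position. Subtracting the two cycles therefore
#' cancels the artifact exactly and retains the stimulated echo; subtracting
#' the reference-encoding phase removes `phi_bg`.
#'
#' @param config a [phantom_config()]
#' @param coils a [coil_model()]; its grid must match `config`
#' @return object of class `dense_phantom` with elements `config`, `coils`,
#'   `images` (a [dense_images] container), `ideal` (coil-less complex array
#'   Nx, Ny, Nph, Npc, Nenc), `displacement` (Nx, Ny, 2, Nph; mm, Eulerian),
#'   `ecc` (Nx, Ny, Nph), `mask` (Nx, Ny, Nph)
#' @export
render_dense_images <- function(config, coils) {
  stopifnot(inherits(config, "phantom_config"), inherits(coils, "coil_model"))
  n <- config$grid_size
  if (dim(coils$sensitivities)[1] != n) {
    stop("coil maps do not match the phantom grid size")
  }
  nph <- config$n_phases; npc <- config$n_phase_cycles
  nenc <- config$n_encodings; nch <- config$n_coils
  xv <- grid_coords_mm(n, config$fov_mm)
  X <- matrix(xv, n, n)
  Y <- matrix(xv, n, n, byrow = TRUE)
  r <- sqrt(X^2 + Y^2)
  edge <- config$pixel_mm
  phi_bg <- background_phase(config)
  ab <- transmural_coefs(config)

  # static artifact echo: annulus frozen at the reference position
  art <- config$artifact_amplitude *
    annulus_amplitude(r, config$endocardial_radius_mm,
                      config$epicardial_radius_mm, edge) *
    exp(1i * phi_bg)

  ideal <- array(0 + 0i, dim = c(n, n, nph, npc, nenc))
  displacement <- array(NA_real_, dim = c(n, n, 2, nph))
  ecc <- array(NA_real_, dim = c(n, n, nph))
  mask <- array(FALSE, dim = c(n, n, nph))

  for (f in seq_len(nph) - 1L) {
    mv <- motion_at_frame(config, f)
    mf <- make_motion_field(config, f, grid = "deformed")
    r_endo <- deform_radius(config$endocardial_radius_mm, mv$cc, ab)
    r_epi <- deform_radius(config$epicardial_radius_mm, mv$cc, ab)
    r_def <- sqrt((X - mv$tx)^2 + (Y - mv$ty)^2)
    amp <- config$ste_amplitude * exp(-config$t1_decay_per_phase * f) *
      annulus_amplitude(r_def, r_endo, r_epi, edge)
    ux <- mf$ux; uy <- mf$uy
    ux[is.na(ux)] <- 0; uy[is.na(uy)] <- 0
    displacement[, , 1, f + 1] <- mf$ux
    displacement[, , 2, f + 1] <- mf$uy
    ecc[, , f + 1] <- (mf$lambda^2 - 1) / 2
    mask[, , f + 1] <- mf$mask
    for (e in seq_len(nenc)) {
      # encoding basis: 1 = phase reference, 2 = x-encode, 3 = y-encode;
      # any further encodings carry no displacement phase
      phi_enc <- if (e == 2) {
        2 * pi * config$ke_cyc_per_mm * ux
      } else if (e == 3) {
        2 * pi * config$ke_cyc_per_mm * uy
      } else {
        0 * ux
      }
      ste <- amp * exp(1i * (phi_bg + phi_enc))
      for (p in seq_len(npc)) {
        s_pc <- if (p == 1) 1 else -1
        ideal[, , f + 1, p, e] <- s_pc * ste + art
      }
    }
  }

  images <- array(0 + 0i, dim = c(n, n, nch, nph, npc, nenc))
  for (c_ in seq_len(nch)) {
    sens <- coils$sensitivities[, , c_]
    images[, , c_, , , ] <- array(rep(as.vector(sens), nph * npc * nenc),
                                  dim = c(n, n, nph, npc, nenc)) *
      ideal
  }

  out <- list(
    config = config, coils = coils,
    images = dense_images(images, pixel_mm = config$pixel_mm,
                          ke_cyc_per_mm = config$ke_cyc_per_mm),
    ideal = ideal, displacement = displacement, ecc = ecc, mask = mask
  )
  class(out) <- "dense_phantom"
  out
}

#' @export
print.dense_phantom <- function(x, ...) {
  d <- dim(x$images$images)
  cat(sprintf("dense_phantom: images %s, %d frames with ground truth\n",
              paste(d, collapse = " x "), x$config$n_phases))
  invisible(x)
}
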