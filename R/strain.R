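#' Combine phase-cycling acquisitions
#'
#' The stimulated echo flips sign between the two cycles while the
#' T1-recovery artifact echo is unchanged, so the complex half-difference
#' `(cycle1 - cycle2)/2` cancels the artifact exactly (in the noise-free
#' case) and retains the stimulated echo. With a single cycle this is a
#' pass-through.
#'
#' @param images a [dense_images] container with Npc = 1 or 2
#' @return a [dense_images] with the phase-cycling dimension collapsed to 1
#' @export
combine_phase_cycles <- function(images) {
  stopifnot(inherits(images, "dense_images"))
  d <- dim(images$images)
  if (d[5] == 1) return(images)
  if (d[5] != 2) stop("only 1 or 2 phase cycles supported")
  comb <- (images$images[, , , , 1, , drop = FALSE] -
             images$images[, , , , 2, , drop = FALSE]) / 2
  out <- dense_images(comb, pixel_mm = images$pixel_mm,
                      ke_cyc_per_mm = images$ke_cyc_per_mm,
                      whitened = images$whitened,
                      denoised = images$denoised,
                      traj_id = images$traj_id)
  out
}

#' Phase-preserving coil combination
#'
#' `I = sum_c conj(S_c) I_c / sum_c |S_c|^2`, removing the coil sensitivity
#' phase so the combined phase is the encoded phase. If the data were
#' pre-whitened, pass sensitivities transformed by the same whitening matrix
#' (see [whiten_sensitivities()]).
#'
#' @param images a [dense_images] with the phase-cycling dimension already
#'   combined (Npc = 1)
#' @param sensitivities complex array (Nx, Ny, Nch), matched to the data's
#'   coil basis
#' @return object of class `combined_images`: list with complex `images`
#'   (Nx, Ny, Nph, Nenc), `pixel_mm`, `ke_cyc_per_mm`
#' @export
coil_combine <- function(images, sensitivities) {
  stopifnot(inherits(images, "dense_images"), is.array(sensitivities))
  d <- dim(images$images)
  if (d[5] != 1) stop("combine phase cycles before coil combination")
  if (!all(dim(sensitivities) == c(d[1], d[2], d[3]))) {
    stop("sensitivity maps do not match the image dimensions")
  }
  den <- apply(abs(sensitivities)^2, c(1, 2), sum)
  if (min(den) <= 0) stop("zero sensitivity norm inside the field of view")
  out <- array(0 + 0i, dim = c(d[1], d[2], d[4], d[6]))
  npix <- d[1] * d[2]
  for (c_ in seq_len(d[3])) {
    sc <- as.vector(Conj(sensitivities[, , c_]))
    m <- images$images[, , c_, , 1, , drop = FALSE]
    dim(m) <- c(npix, d[4] * d[6])
    out <- out + array(m * sc, dim = dim(out))
  }
  out <- out / as.vector(den)
  structure(list(images = out, pixel_mm = images$pixel_mm,
                 ke_cyc_per_mm = images$ke_cyc_per_mm,
                 denoised = images$denoised),
            class = "combined_images")
}

#' Transform coil sensitivities into the pre-whitened coil basis
#'
#' @param sensitivities complex array (Nx, Ny, Nch)
#' @param W whitening matrix from [estimate_prewhitener()]
#' @return transformed sensitivity array
#' @export
whiten_sensitivities <- function(sensitivities, W) {
  d <- dim(sensitivities)
  m <- matrix(sensitivities, d[1] * d[2], d[3])
  array(m %*% t(W), dim = d)
}

#' @export
print.combined_images <- function(x, ...) {
  cat(sprintf("combined_images %s (Nx,Ny,Nph,Nenc)%s\n",
              paste(dim(x$images), collapse = " x "),
              if (isTRUE(x$denoised)) ", denoised" else ""))
  invisible(x)
}

# 4-connected components of a mask; returns integer label matrix (0 outside)
mask_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      k <- queue[[1]]; queue <- queue[-1]
      i <- (k - 1L) %% nr + 1L
      j <- (k - 1L) %/% nr + 1L
      for (nb in c(if (i > 1) k - 1L, if (i < nr) k + 1L,
                   if (j > 1) k - nr, if (j < nc) k + nr)) {
        if (mask[nb] && lab[nb] == 0L) {
          lab[nb] <- cur
          queue <- c(queue, nb)
        }
      }
    }
  }
  lab
}

# quality-guided region-growing unwrapping of one 2D frame
unwrap_frame <- function(phase, mask, quality) {
  nr <- nrow(phase); nc <- ncol(phase)
  out <- phase
  lab <- mask_components(mask)
  ncomp <- max(lab)
  if (ncomp > 1) {
    warning("mask has ", ncomp,
            " disconnected regions; each unwrapped independently")
  }
  done <- matrix(FALSE, nr, nc)
  for (comp in seq_len(ncomp)) {
    pix <- which(lab == comp)
    seed <- pix[which.max(quality[pix])]
    done[seed] <- TRUE
    infront <- matrix(FALSE, nr, nc)
    frontier <- integer(0)
    push_nbrs <- function(k, frontier) {
      i <- (k - 1L) %% nr + 1L
      j <- (k - 1L) %/% nr + 1L
      for (nb in c(if (i > 1) k - 1L, if (i < nr) k + 1L,
                   if (j > 1) k - nr, if (j < nc) k + nr)) {
        if (lab[nb] == comp && !done[nb] && !infront[nb]) {
          infront[nb] <<- TRUE
          frontier <- c(frontier, nb)
        }
      }
      frontier
    }
    frontier <- push_nbrs(seed, frontier)
    while (length(frontier)) {
      pick <- which.max(quality[frontier])
      k <- frontier[pick]
      frontier <- frontier[-pick]
      infront[k] <- FALSE
      i <- (k - 1L) %% nr + 1L
      j <- (k - 1L) %/% nr + 1L
      nbrs <- c(if (i > 1) k - 1L, if (i < nr) k + 1L,
                if (j > 1) k - nr, if (j < nc) k + nr)
      nbrs <- nbrs[done[nbrs]]
      ref <- out[nbrs[which.max(quality[nbrs])]]
      out[k] <- phase[k] + 2 * pi * round((ref - phase[k]) / (2 * pi))
      done[k] <- TRUE
      frontier <- push_nbrs(k, frontier)
    }
  }
  out[!mask] <- NA_real_
  out
}

#' Quality-guided phase unwrapping
#'
#' Spatial 2D unwrapping within the mask by quality-guided region growing
#' (quality defaults to the magnitude when supplied, else a constant), with
#' disconnected mask regions unwrapped independently (with a warning). For a
#' cine stack (3D input) a temporal consistency pass follows: each frame is
#' shifted by the integer multiple of 2*pi that best matches the previous
#' frame's mean phase over the shared mask, seeded at frame 1 where
#' displacement, and hence phase, is near zero. The output differs from the
#' wrapped input by integer multiples of 2*pi pixelwise.
#'
#' @param phase wrapped phase: matrix (one frame) or 3D array (Nx, Ny, Nph)
#' @param mask logical mask, same spatial shape (per-frame for 3D)
#' @param quality optional guidance map (e.g. magnitude), same shape
#' @return unwrapped phase, NA outside the mask
#' @export
unwrap_phase <- function(phase, mask, quality = NULL) {
  if (is.matrix(phase)) {
    q <- if (is.null(quality)) matrix(1, nrow(phase), ncol(phase)) else quality
    return(unwrap_frame(phase, mask, q))
  }
  stopifnot(length(dim(phase)) == 3)
  nph <- dim(phase)[3]
  out <- array(NA_real_, dim = dim(phase))
  prev_mean <- 0  # frame 1 anchored at zero phase
  prev_mask <- NULL
  for (f in seq_len(nph)) {
    mk <- if (length(dim(mask)) == 3) mask[, , f] else mask
    q <- if (is.null(quality)) {
      matrix(1, dim(phase)[1], dim(phase)[2])
    } else if (length(dim(quality)) == 3) quality[, , f] else quality
    uf <- unwrap_frame(phase[, , f], mk, q)
    common <- if (is.null(prev_mask)) mk else mk & prev_mask
    if (!any(common)) common <- mk
    mu <- mean(uf[common], na.rm = TRUE)
    shift <- 2 * pi * round((prev_mean - mu) / (2 * pi))
    uf <- uf + shift
    out[, , f] <- uf
    prev_mean <- mean(uf[mk], na.rm = TRUE)
    prev_mask <- mk
  }
  out
}

#' Convert unwrapped displacement-encoded phase to displacement
#'
#' `u = delta_phi / (2 pi ke)`; the reference-encoding phase must already be
#' subtracted.
#'
#' @param unwrapped unwrapped phase difference (radians)
#' @param ke_cyc_per_mm displacement-encoding frequency (> 0, cycles/mm)
#' @return displacement in mm, same shape
#' @export
phase_to_displacement <- function(unwrapped, ke_cyc_per_mm) {
  if (ke_cyc_per_mm <= 0) stop("ke must be positive")
  unwrapped / (2 * pi * ke_cyc_per_mm)
}

#' Displacement maps from combined DENSE images
#'
#' Convenience wrapper over the spec'd steps: per encoding, the wrapped
#' phase difference to the reference encoding is unwrapped
#' (magnitude-guided, with the temporal pass) and scaled by
#' `1 / (2 pi ke)`.
#'
#' @param combined a [coil_combine()] output with encodings (ref, x, y)
#' @param mask logical (Nx, Ny, Nph) myocardial masks
#' @return displacement array (Nx, Ny, 2, Nph) in mm (NA outside mask)
#' @export
displacement_maps <- function(combined, mask) {
  stopifnot(inherits(combined, "combined_images"))
  d <- dim(combined$images)
  if (d[4] < 3) stop("need reference, x and y encodings")
  out <- array(NA_real_, dim = c(d[1], d[2], 2, d[3]))
  for (e in 2:3) {
    wrapped <- Arg(combined$images[, , , e] *
                     Conj(combined$images[, , , 1]))
    unw <- unwrap_phase(wrapped, mask,
                        quality = Mod(combined$images[, , , e]))
    out[, , e - 1, ] <- phase_to_displacement(unw, combined$ke_cyc_per_mm)
  }
  out
}

# central differences with NA propagation; h = grid spacing
diff_central <- function(m, h, along) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  if (along == 1) {
    out[2:(nr - 1), ] <- (m[3:nr, ] - m[1:(nr - 2), ]) / (2 * h)
  } else {
    out[, 2:(nc - 1)] <- (m[, 3:nc] - m[, 1:(nc - 2)]) / (2 * h)
  }
  out
}

#' Circumferential Green-Lagrange strain from a displacement field
#'
#' The displacement is interpreted in the standard DENSE sense: the value at
#' a pixel is the displacement of the tissue currently there, relative to
#' its reference position. The inverse-deformation gradient
#' `G = d X / d x = I - grad(u)` is estimated from Gaussian-smoothed central
#' differences on the pixel grid, inverted per pixel to the deformation
#' gradient `F = G^{-1}`, and the Green-Lagrange tensor
#' `E = (F^T F - I)/2` is projected on the circumferential unit vector at
#' the reference position `X = x - u` about the ventricular `center`.
#'
#' @param displacement array (Nx, Ny, 2) for one frame or (Nx, Ny, 2, Nph)
#' @param mask logical (Nx, Ny) or (Nx, Ny, Nph)
#' @param center LV centre in mm, default c(0, 0) (the phantom's centre)
#' @param pixel_mm pixel size (mm)
#' @param smooth_sigma Gaussian derivative smoothing in pixels (default 1)
#' @param engineering return engineering strain `sqrt(2 E_cc + 1) - 1`
#'   instead of Green-Lagrange
#' @return E_cc map(s), NA where not computable
#' @export
compute_ecc <- function(displacement, mask, center = c(0, 0), pixel_mm,
                        smooth_sigma = 1, engineering = FALSE) {
  dd <- dim(displacement)
  if (length(dd) == 4) {
    out <- array(NA_real_, dim = dd[c(1, 2, 4)])
    for (f in seq_len(dd[4])) {
      mk <- if (length(dim(mask)) == 3) mask[, , f] else mask
      out[, , f] <- compute_ecc(displacement[, , , f], mk, center, pixel_mm,
                                smooth_sigma, engineering)
    }
    return(out)
  }
  stopifnot(length(dd) == 3, dd[3] == 2)
  n <- dd[1]
  xv <- grid_coords_mm(n, pixel_mm * n)
  if (center[1] < min(xv) || center[1] > max(xv) ||
      center[2] < min(xv) || center[2] > max(xv)) {
    stop("center lies outside the image")
  }
  interior <- sum(erode_mask(mask, 1L))
  if (interior < 4) {
    warning("mask too thin for spatial derivatives; increasing smoothing")
    smooth_sigma <- max(smooth_sigma, 2)
  }
  ux <- gauss_smooth(displacement[, , 1], smooth_sigma, mask)
  uy <- gauss_smooth(displacement[, , 2], smooth_sigma, mask)
  h <- pixel_mm
  g11 <- 1 - diff_central(ux, h, 1)
  g12 <- -diff_central(ux, h, 2)
  g21 <- -diff_central(uy, h, 1)
  g22 <- 1 - diff_central(uy, h, 2)
  det <- g11 * g22 - g12 * g21
  f11 <- g22 / det; f12 <- -g12 / det
  f21 <- -g21 / det; f22 <- g11 / det
  c11 <- f11 * f11 + f21 * f21
  c12 <- f11 * f12 + f21 * f22
  c22 <- f12 * f12 + f22 * f22
  e11 <- (c11 - 1) / 2; e12 <- c12 / 2; e22 <- (c22 - 1) / 2
  X <- matrix(xv, n, n) - ux - center[1]
  Y <- matrix(xv, n, n, byrow = TRUE) - uy - center[2]
  alpha <- atan2(Y, X)
  sa <- sin(alpha); ca <- cos(alpha)
  ecc <- e11 * sa^2 - 2 * e12 * sa * ca + e22 * ca^2
  ecc[!mask] <- NA_real_
  if (engineering) ecc <- sqrt(pmax(2 * ecc + 1, 0)) - 1
  ecc
}

#' AHA mid-level segmental strain statistics
#'
#' Partitions the mask into six equal 60-degree sectors about `center`,
#' counter-clockwise from `rv_insertion_angle` (radians; default 0, the
#' phantom's +x axis), labelled in the AHA mid-cavity order. Per-segment,
#' per-frame mean and standard deviation of E_cc over mask pixels; empty
#' segments are NA, not zero.
#'
#' @param ecc_map matrix (Nx, Ny) or array (Nx, Ny, Nph)
#' @param mask logical, same spatial shape
#' @param center LV centre (mm)
#' @param rv_insertion_angle angular reference (radians)
#' @param pixel_mm pixel size (mm)
#' @return object of class `strain_result` with `segment_means`,
#'   `segment_sds` (6 x Nph) and `segment_labels`
#' @export
segment_stats <- function(ecc_map, mask, center = c(0, 0),
                          rv_insertion_angle = 0, pixel_mm) {
  if (is.matrix(ecc_map)) ecc_map <- array(ecc_map, dim = c(dim(ecc_map), 1))
  d <- dim(ecc_map)
  nph <- d[3]
  n <- d[1]
  xv <- grid_coords_mm(n, pixel_mm * n)
  X <- matrix(xv, n, n) - center[1]
  Y <- matrix(xv, n, n, byrow = TRUE) - center[2]
  ang <- (atan2(Y, X) - rv_insertion_angle) %% (2 * pi)
  sector <- pmin(floor(ang / (pi / 3)) + 1L, 6L)
  labels <- c("anterior", "anteroseptal", "inferoseptal",
              "inferior", "inferolateral", "anterolateral")
  means <- matrix(NA_real_, 6, nph, dimnames = list(labels, NULL))
  sds <- matrix(NA_real_, 6, nph, dimnames = list(labels, NULL))
  for (f in seq_len(nph)) {
    mk <- if (length(dim(mask)) == 3) mask[, , f] else mask
    vals <- ecc_map[, , f]
    for (s in 1:6) {
      v <- vals[mk & sector == s]
      v <- v[is.finite(v)]
      if (length(v) >= 1) means[s, f] <- mean(v)
      if (length(v) >= 2) sds[s, f] <- stats::sd(v)
    }
  }
  structure(list(segment_means = means, segment_sds = sds,
                 segment_labels = labels, n_phases = nph),
            class = "strain_result")
}

#' @export
print.strain_result <- function(x, ...) {
  cat(sprintf("strain_result: 6 segments x %d frames\n", x$n_phases))
  pk <- apply(x$segment_means, 1, function(r) min(r, na.rm = TRUE))
  cat("  peak segmental E_cc:\n")
  for (s in seq_along(pk)) {
    cat(sprintf("    %-14s %6.3f\n", x$segment_labels[s], pk[s]))
  }
  invisible(x)
}

#' @export
as.data.frame.strain_result <- function(x, ...) {
  nph <- x$n_phases
  data.frame(
    segment = rep(x$segment_labels, nph),
    frame = rep(seq_len(nph) - 1L, each = 6),
    ecc_mean = as.vector(x$segment_means),
    ecc_sd = as.vector(x$segment_sds)
  )
}

#' Plot segmental strain-time curves
#'
#' @param x a `strain_result`
#' @param ... passed to [graphics::matplot()]
#' @export
plot.strain_result <- function(x, ...) {
  graphics::matplot(t(x$segment_means), type = "l", lty = 1,
                    xlab = "cardiac phase", ylab = expression(E[cc]), ...)
  graphics::legend("bottomleft", legend = x$segment_labels, col = 1:6,
                   lty = 1, cex = 0.7, bty = "n")
  invisible(x)
}
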