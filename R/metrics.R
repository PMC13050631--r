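#' Region-of-interest specification for image metrics
#'
#' @param myocardium_mask logical (Nx, Ny) or (Nx, Ny, Nph) myocardial mask
#' @param background_center,background_radius circular background ROI
#'   (pixel units, centre as c(i, j)); must be disjoint from the object
#' @param mid_diastolic_frame,end_diastolic_frame 1-based frame indices used
#'   by the phase SNR (defaults: last and first frame of the cycle)
#' @return object of class `roi_spec`
#' @export
roi_spec <- function(myocardium_mask, background_center, background_radius,
                     mid_diastolic_frame = NULL, end_diastolic_frame = 1L) {
  structure(list(myocardium_mask = myocardium_mask,
                 background_center = background_center,
                 background_radius = background_radius,
                 mid_diastolic_frame = mid_diastolic_frame,
                 end_diastolic_frame = as.integer(end_diastolic_frame)),
            class = "roi_spec")
}

background_mask <- function(nx, ny, roi) {
  ii <- matrix(seq_len(nx), nx, ny)
  jj <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  (ii - roi$background_center[1])^2 + (jj - roi$background_center[2])^2 <=
    roi$background_radius^2
}

#' Place a background ROI in a corner quadrant, disjoint from the object
#'
#' @param object_mask logical map of the object support (any frame TRUE)
#' @param radius ROI radius in pixels
#' @return c(i, j) centre of a corner-quadrant circle that avoids the object
#' @export
auto_background_roi <- function(object_mask, radius = 6) {
  nx <- nrow(object_mask); ny <- ncol(object_mask)
  off <- ceiling(radius) + 2
  corners <- rbind(c(off, off), c(nx - off, off),
                   c(off, ny - off), c(nx - off, ny - off))
  for (k in seq_len(nrow(corners))) {
    roi <- roi_spec(NULL, corners[k, ], radius)
    bg <- background_mask(nx, ny, roi)
    if (!any(bg & object_mask)) return(corners[k, ])
  }
  stop("no corner quadrant is free of the object support")
}

#' Apparent magnitude SNR
#'
#' Mean myocardial magnitude divided by the standard deviation of the
#' background magnitude, per frame, plus the across-frame mean. Invariant to
#' global image scaling.
#'
#' @param magnitude array (Nx, Ny, Nph) of magnitude images (a matrix is
#'   treated as one frame)
#' @param roi a [roi_spec()]
#' @return list with `per_frame` (length Nph) and `mean`
#' @export
apparent_snr <- function(magnitude, roi) {
  if (is.matrix(magnitude)) {
    magnitude <- array(magnitude, dim = c(dim(magnitude), 1))
  }
  d <- dim(magnitude)
  bg <- background_mask(d[1], d[2], roi)
  per <- vapply(seq_len(d[3]), function(f) {
    mk <- if (length(dim(roi$myocardium_mask)) == 3) {
      roi$myocardium_mask[, , f]
    } else {
      roi$myocardium_mask
    }
    mu <- mean(magnitude[, , f][mk])
    sdv <- stats::sd(magnitude[, , f][bg])
    if (sdv == 0) stop("zero background standard deviation")
    mu / sdv
  }, numeric(1))
  list(per_frame = per, mean = mean(per))
}

#' Phase SNR of unwrapped displacement-encoded phase
#'
#' Mean unwrapped phase in the myocardial ROI at the mid-diastolic frame
#' divided by the standard deviation of the unwrapped phase in the ROI at
#' the end-diastolic frame.
#'
#' @param unwrapped_phase array (Nx, Ny, Nph)
#' @param roi a [roi_spec()]; its mid-/end-diastolic frames are used
#'   (defaults: last and first frame)
#' @return phase SNR value
#' @export
phase_snr <- function(unwrapped_phase, roi) {
  d <- dim(unwrapped_phase)
  mid <- if (is.null(roi$mid_diastolic_frame)) d[3] else
    roi$mid_diastolic_frame
  endd <- roi$end_diastolic_frame
  mask_at <- function(f) {
    if (length(dim(roi$myocardium_mask)) == 3) {
      roi$myocardium_mask[, , f]
    } else {
      roi$myocardium_mask
    }
  }
  num <- mean(unwrapped_phase[, , mid][mask_at(mid)], na.rm = TRUE)
  den <- stats::sd(unwrapped_phase[, , endd][mask_at(endd)], na.rm = TRUE)
  if (!is.finite(den) || den == 0) stop("zero phase standard deviation")
  num / den
}

#' Scan efficiency
#'
#' Apparent magnitude SNR divided by acquisition time (heartbeats) and voxel
#' volume (mm^3).
#'
#' @param apparent_snr apparent magnitude SNR (scalar)
#' @param n_heartbeats acquisition time in heartbeats
#' @param voxel_mm3 voxel volume (mm^3)
#' @return efficiency (per heartbeat per mm^3)
#' @export
scan_efficiency <- function(apparent_snr, n_heartbeats, voxel_mm3) {
  stopifnot(apparent_snr > 0, n_heartbeats > 0, voxel_mm3 > 0)
  apparent_snr / (n_heartbeats * voxel_mm3)
}

#' Normalized root-mean-square error
#'
#' `||x - ref||_2 / ||ref||_2` over all (complex) elements of the arrays.
#'
#' @param images,reference equal-shaped arrays (complex or real)
#' @return NRMSE value
#' @export
nrmse <- function(images, reference) {
  if (inherits(images, "dense_images")) images <- images$images
  if (inherits(reference, "dense_images")) reference <- reference$images
  if (inherits(images, "combined_images")) images <- images$images
  if (inherits(reference, "combined_images")) reference <- reference$images
  if (!all(dim(images) == dim(reference))) stop("shape mismatch")
  refn <- sqrt(sum(Mod(reference)^2))
  if (refn == 0) stop("zero reference norm")
  sqrt(sum(Mod(images - reference)^2)) / refn
}

#' Normalized image gradient (border sharpness)
#'
#' From a 1D intensity profile across the epicardial border:
#' `(Im - Ia) / (Im * d)` with `Im` the myocardial intensity (profile
#' maximum), `Ia` the background intensity (profile minimum) and `d` the
#' separation between the two points. Larger is sharper.
#'
#' @param profile_values intensities sampled along the profile
#' @param d_points separation between the myocardial and background points
#'   (same length unit as desired for the result)
#' @return normalized gradient
#' @export
normalized_gradient <- function(profile_values, d_points) {
  stopifnot(length(profile_values) >= 2, d_points > 0)
  im <- max(profile_values)
  ia <- min(profile_values)
  if (im <= 0) stop("nonpositive myocardial intensity")
  (im - ia) / (im * d_points)
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = x - y`; mean difference MD and limits of agreement
#' `MD +/- 1.96 sd(d)` (sample SD, n - 1 denominator).
#'
#' @param x_values,y_values paired measurements
#' @return list with `md`, `loa_low`, `loa_high`, `sd`, `n`
#' @export
bland_altman <- function(x_values, y_values) {
  stopifnot(length(x_values) == length(y_values))
  d <- x_values - y_values
  d <- d[is.finite(d)]
  if (length(d) < 2) stop("need at least 2 finite paired values")
  md <- mean(d)
  s <- stats::sd(d)
  list(md = md, loa_low = md - 1.96 * s, loa_high = md + 1.96 * s,
       sd = s, n = length(d))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped. Exact p-value for n <= 25 without ties,
#' normal approximation with tie/continuity correction otherwise
#' (delegating to [stats::wilcox.test()]).
#'
#' @param x,y paired samples
#' @param alternative as in [stats::wilcox.test()]
#' @return list with `statistic` (V), `p_value`, `n` (nonzero pairs)
#' @export
wilcoxon_signed_rank <- function(x, y, alternative = "two.sided") {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[is.finite(d)]
  nz <- d != 0
  if (!any(nz)) stop("all paired differences are zero")
  d <- d[nz]
  n <- length(d)
  ht <- suppressWarnings(
    stats::wilcox.test(d, alternative = alternative,
                       exact = n <= 25, correct = TRUE)
  )
  list(statistic = unname(ht$statistic), p_value = ht$p.value, n = n)
}
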