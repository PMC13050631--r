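#' Hard-threshold the singular values of one Casorati matrix
#'
#' Singular values `s <= cutoff_s` are set to zero; retained components are
#' unchanged (hard thresholding, the default of the pipeline; `"soft"`
#' subtracts the cutoff from retained values instead).
#'
#' @param casorati real Casorati matrix
#' @param cutoff_s singular-value cutoff (>= 0)
#' @param method `"hard"` (default) or `"soft"`
#' @return list with `denoised` (matrix, attributes preserved) and `rank`
#'   (number of retained components)
#' @export
denoise_patch <- function(casorati, cutoff_s, method = c("hard", "soft")) {
  stopifnot(is.matrix(casorati), cutoff_s >= 0)
  method <- match.arg(method)
  B <- unclass(casorati)
  sv <- tryCatch(svd(B),
                 error = function(e) stop("SVD failed to converge: ",
                                          conditionMessage(e)))
  keep <- sv$d > cutoff_s
  rank <- sum(keep)
  d2 <- sv$d
  if (method == "soft") d2 <- pmax(d2 - cutoff_s, 0)
  d2[!keep] <- 0
  out <- if (rank == 0) {
    matrix(0, nrow(B), ncol(B))
  } else {
    sv$u[, keep, drop = FALSE] %*%
      (d2[keep] * t(sv$v[, keep, drop = FALSE]))
  }
  keep_attrs <- attributes(casorati)[c("p", "q", "patch_dims", "spec",
                                       "class")]
  for (nm in names(keep_attrs)) {
    if (!is.null(keep_attrs[[nm]])) attr(out, nm) <- keep_attrs[[nm]]
  }
  list(denoised = out, rank = rank)
}

#' Locally low-rank denoising of a 6D DENSE image set
#'
#' For every overlapping patch: reshape to the real Casorati matrix, estimate
#' the patch's noise eigenvalue threshold from its own smallest Gram
#' eigenvalue via the calibrated Marchenko-Pastur ratio chain, hard-threshold
#' the singular values, reshape back, and average the overlapping denoised
#' patches (uniform weights per pixel coverage count).
#'
#' @param images a [dense_images] container (typically pre-whitened,
#'   reconstructed spiral data)
#' @param spec the [patch_spec()] — must match the one calibrated
#' @param ratio_table a [calibrate_ratios()] table for this acquisition
#' @param method thresholding rule passed to [denoise_patch()]
#' @param trimmed robust `a_hat_B` estimator (mean of 3 smallest
#'   eigenvalues), default FALSE
#' @param ratio_fallback use the table's global mean ratios everywhere
#'   instead of per-location values
#' @param cutoff_override fixed singular-value cutoff applied to every patch
#'   instead of the data-driven threshold (0 isolates the patch-averaging
#'   bookkeeping, which must then reproduce the input exactly)
#' @return denoised [dense_images]; attribute `"mean_rank"` records the
#'   average retained rank per patch
#' @export
denoise_volume <- function(images, spec, ratio_table,
                           method = c("hard", "soft"), trimmed = FALSE,
                           ratio_fallback = FALSE, cutoff_override = NULL) {
  stopifnot(inherits(images, "dense_images"), inherits(spec, "patch_spec"),
            inherits(ratio_table, "ratio_table"))
  method <- match.arg(method)
  arr <- images$images
  d <- dim(arr)
  recon_id <- if (is.null(images$traj_id) || is.na(images$traj_id)) {
    "unknown"
  } else {
    images$traj_id
  }
  expected <- calibration_key(recon_id, d[1], d[3:6], spec, images$whitened)
  if (!identical(expected, ratio_table$key)) {
    stop("no calibration entry for this acquisition/patch spec;\n  needed: ",
         expected, "\n  table:  ", ratio_table$key)
  }
  g <- patch_grid(d[1], d[2], spec)
  if (!identical(g, ratio_table$grid)) {
    stop("ratio table patch grid does not match the image grid")
  }
  geo <- casorati_geometry(spec, d)
  qmax <- max(geo$p, geo$q)
  gamma <- min(geo$p, geo$q) / max(geo$p, geo$q)
  if (gamma >= 1) {
    stop("gamma = 1: b/a is undefined; use a non-square dimension grouping")
  }
  b_over_a <- (1 + sqrt(gamma))^2 / (1 - sqrt(gamma))^2
  prep <- casorati_prep(arr, spec)
  acc <- array(0 + 0i, dim = dim(prep$arr))
  counts <- matrix(0L, d[1], d[2])
  n1 <- geo$n1
  side1 <- spec$realimag_side == 1L
  rank_sum <- 0
  for (jj in seq_along(g$j)) {
    for (ii in seq_along(g$i)) {
      i <- g$i[ii]; j <- g$j[jj]
      M <- casorati_at(prep, i, j)
      B <- if (side1) rbind(Re(M), Im(M)) else cbind(Re(M), Im(M))
      sv <- tryCatch(svd(B),
                     error = function(e) stop("SVD failed to converge: ",
                                              conditionMessage(e)))
      ev <- sv$d^2 / qmax
      a_hat <- if (trimmed) mean(utils::tail(ev, 3)) else ev[length(ev)]
      r_up <- if (ratio_fallback) ratio_table$r_upper_mean else
        ratio_table$r_upper[ii, jj]
      r_lo <- if (ratio_fallback) ratio_table$r_lower_mean else
        ratio_table$r_lower[ii, jj]
      cutoff <- if (is.null(cutoff_override)) {
        sqrt(qmax * r_up * b_over_a * r_lo * a_hat)
      } else {
        cutoff_override
      }
      keep <- sv$d > cutoff
      rank_sum <- rank_sum + sum(keep)
      d2 <- sv$d
      if (method == "soft") d2 <- pmax(d2 - cutoff, 0)
      d2[!keep] <- 0
      Bd <- if (any(keep)) {
        sv$u[, keep, drop = FALSE] %*%
          (d2[keep] * t(sv$v[, keep, drop = FALSE]))
      } else {
        matrix(0, nrow(B), ncol(B))
      }
      Md <- if (side1) {
        Bd[seq_len(n1), , drop = FALSE] +
          1i * Bd[n1 + seq_len(n1), , drop = FALSE]
      } else {
        Bd[, seq_len(geo$n2), drop = FALSE] +
          1i * Bd[, geo$n2 + seq_len(geo$n2), drop = FALSE]
      }
      ix <- i:(i + spec$px - 1L)
      iy <- j:(j + spec$py - 1L)
      acc[ix, iy, , , , ] <- acc[ix, iy, , , , ] + as.vector(Md)
      counts[ix, iy] <- counts[ix, iy] + 1L
    }
  }
  covered <- counts > 0L
  cdiv <- counts
  cdiv[!covered] <- 1L
  acc <- acc / as.vector(cdiv)
  if (!all(covered)) {
    # pixels never covered by a patch (possible with stride > 1) pass through
    pass <- array(rep(!covered, length.out = length(acc)), dim = dim(acc))
    acc[pass] <- prep$arr[pass]
  }
  out_arr <- aperm(acc, order(geo$perm))
  out <- dense_images(out_arr, pixel_mm = images$pixel_mm,
                      ke_cyc_per_mm = images$ke_cyc_per_mm,
                      whitened = images$whitened, denoised = TRUE)
  out$traj_id <- images$traj_id
  attr(out, "mean_rank") <- rank_sum / (length(g$i) * length(g$j))
  out
}
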