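#' Full-run configuration
#'
#' Bundles the per-stage parameters of the simulate - calibrate -
#' reconstruct - denoise - analyze - report workflow. The master `seed`
#' determinizes the entire run: every stage derives its own seed from it by
#' a fixed offset.
#'
#' @param phantom a [phantom_config()]
#' @param n_interleaves spiral interleaves
#' @param n_points readout points per interleaf (NULL = Nyquist default)
#' @param target_snr apparent magnitude SNR operating point; the injected
#'   k-space noise sigma is calibrated (not hardcoded) to reach it
#' @param noise_rho inter-coil noise correlation of the simulated array
#' @param patch a [patch_spec()]
#' @param n_mc Monte-Carlo realizations for threshold calibration
#' @param denoise run the denoising stage (FALSE = paired outputs omit it)
#' @param rv_insertion_angle angular reference for segmentation (radians)
#' @param smooth_sigma strain derivative smoothing (pixels)
#' @param n_heartbeats acquisition duration used for scan efficiency
#' @param slice_mm slice thickness used for scan efficiency
#' @param ratio_table optional precomputed [calibrate_ratios()] table
#'   (reused across runs of the same geometry)
#' @param table_cache_dir optional directory for key-addressed ratio-table
#'   caching
#' @param seed master seed
#' @return object of class `run_config`
#' @export
run_config <- function(phantom = phantom_config(),
                       n_interleaves = 4L, n_points = NULL,
                       target_snr = 25, noise_rho = 0.3,
                       patch = patch_spec(), n_mc = 10L,
                       denoise = TRUE, rv_insertion_angle = 0,
                       smooth_sigma = 1, n_heartbeats = 14,
                       slice_mm = 8, ratio_table = NULL,
                       table_cache_dir = NULL, seed = 1L) {
  structure(list(phantom = phantom, n_interleaves = as.integer(n_interleaves),
                 n_points = n_points, target_snr = target_snr,
                 noise_rho = noise_rho, patch = patch,
                 n_mc = as.integer(n_mc), denoise = isTRUE(denoise),
                 rv_insertion_angle = rv_insertion_angle,
                 smooth_sigma = smooth_sigma, n_heartbeats = n_heartbeats,
                 slice_mm = slice_mm, ratio_table = ratio_table,
                 table_cache_dir = table_cache_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Calibrate the k-space noise level for a target apparent SNR
#'
#' The reconstruction is linear, so the background magnitude SD contributed
#' by k-space noise scales linearly with sigma; the background of the
#' noise-free reference is not exactly zero (ringing/aliasing of the object
#' through the spiral point-spread function), so the total background SD is
#' modelled as `sqrt(ring^2 + sigma^2 noise^2)` per frame and the sigma
#' reaching the requested across-frame mean apparent SNR is found by
#' root-finding.
#'
#' @param mu_per_frame mean myocardial magnitude of the noise-free combined
#'   reference, per frame
#' @param bg_sd_per_frame background magnitude SD of a unit-sigma noise-only
#'   combined reconstruction, per frame
#' @param target_snr requested across-frame mean apparent SNR
#' @param ring_sd_per_frame background magnitude SD of the noise-free
#'   combined reference, per frame (default 0)
#' @return the k-space noise sigma
#' @export
sigma_for_target_snr <- function(mu_per_frame, bg_sd_per_frame, target_snr,
                                 ring_sd_per_frame = 0) {
  stopifnot(length(mu_per_frame) == length(bg_sd_per_frame), target_snr > 0)
  snr_at <- function(s) {
    mean(mu_per_frame /
           sqrt(ring_sd_per_frame^2 + s^2 * bg_sd_per_frame^2))
  }
  if (snr_at(0) <= target_snr) {
    stop("target apparent SNR unreachable: reference background already ",
         "too bright")
  }
  upper <- mean(mu_per_frame / bg_sd_per_frame) / target_snr
  stats::uniroot(function(s) snr_at(s) - target_snr,
                 lower = 0, upper = upper, tol = 1e-10)$root
}

#' Ratio-table lookup with key-addressed caching
#'
#' Computes (or loads) the Monte-Carlo ratio table for an acquisition/patch
#' spec. With `cache_dir` set, tables are stored in files addressed by a
#' sanitised form of the calibration key and reused.
#'
#' @inheritParams calibrate_ratios
#' @param cache_dir optional cache directory (created if missing)
#' @return a `ratio_table`
#' @export
cached_ratio_table <- function(acq, spec, n_mc = 10L, sigma_cal = 1,
                               seed = 1L, cache_dir = NULL) {
  if (is.null(cache_dir)) {
    return(calibrate_ratios(acq, spec, n_mc, sigma_cal, seed))
  }
  key <- calibration_key(acq$id, acq$matrix_size, acq$dims, spec,
                         acq$whitened)
  if (!dir.exists(cache_dir)) dir.create(cache_dir, recursive = TRUE)
  path <- file.path(cache_dir,
                    paste0(gsub("[^A-Za-z0-9._-]", "_", key),
                           "_mc", n_mc, ".rds"))
  if (file.exists(path)) {
    tab <- read_container(path, "ratio_table")
    if (identical(tab$key, key)) return(tab)
  }
  tab <- calibrate_ratios(acq, spec, n_mc, sigma_cal, seed)
  write_container(path, list(ratio_table = tab))
  tab
}

analyze_images <- function(recon6, phantom, sens_eff, cfg) {
  comb <- coil_combine(combine_phase_cycles(recon6), sens_eff)
  mask <- phantom$mask
  disp <- displacement_maps(comb, mask)
  ecc <- compute_ecc(disp, mask, center = c(0, 0),
                     pixel_mm = comb$pixel_mm,
                     smooth_sigma = cfg$smooth_sigma)
  seg <- segment_stats(ecc, mask, center = c(0, 0),
                       rv_insertion_angle = cfg$rv_insertion_angle,
                       pixel_mm = comb$pixel_mm)
  list(combined = comb, displacement = disp, ecc = ecc, segments = seg)
}

#' Run the full simulation / reconstruction / denoising / strain pipeline
#'
#' Executes simulate, calibrate (or load a table), reconstruct, denoise,
#' analyze and report on the analytic phantom, producing paired
#' non-denoised / denoised outputs for every metric. Bit-reproducible under
#' a fixed master seed.
#'
#' @param cfg a [run_config()]
#' @param keep_images keep the 6D image sets in the result (large); the 4D
#'   combined images are always kept
#' @return object of class `dense_run`
#' @export
run_pipeline <- function(cfg, keep_images = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  pc <- cfg$phantom
  seed <- cfg$seed
  coils <- coil_model(pc$n_coils, pc$grid_size, pc$fov_mm,
                      noise_rho = cfg$noise_rho)
  phantom <- render_dense_images(pc, coils)
  traj <- design_spiral(pc$grid_size, pc$fov_mm, cfg$n_interleaves,
                        cfg$n_points)
  dims <- c(pc$n_coils, pc$n_phases, pc$n_phase_cycles, pc$n_encodings)

  # noise pre-scan -> whitening transform
  prescan <- noise_only_kspace(dims = c(pc$n_coils, 1L, 1L, 1L), traj,
                               noise_cov = coils$noise_cov, sigma = 1,
                               seed = seed + 101L)
  nsamp <- matrix(prescan$samples, ncol = pc$n_coils)
  W <- estimate_prewhitener(nsamp)
  sens_eff <- whiten_sensitivities(coils$sensitivities, W)

  ks_clean <- forward_sample(phantom, traj)
  ks_clean_w <- apply_prewhitening(ks_clean, W)
  recon_ref <- adjoint_nufft_recon(ks_clean_w)
  ref <- analyze_images(recon_ref, phantom, sens_eff, cfg)

  # calibrate injected noise to the target apparent SNR
  bg_center <- auto_background_roi(apply(phantom$mask, c(1, 2), any),
                                   radius = max(4, pc$grid_size %/% 12))
  # phase-SNR frames: end-diastole = frame 1 (zero phase); mid-diastole =
  # midway between peak systole and the end of the cycle, where the encoded
  # phase is substantial
  mid_frame <- min(pc$n_phases,
                   1L + round(pc$n_phases * (pc$systole_fraction + 1) / 2))
  roi <- roi_spec(phantom$mask, bg_center,
                  max(4, pc$grid_size %/% 12),
                  mid_diastolic_frame = mid_frame,
                  end_diastolic_frame = 1L)
  unit_noise <- noise_only_kspace(dims, traj, noise_cov = NULL, sigma = 1,
                                  seed = seed + 202L)
  unit_noise$whitened <- TRUE  # unit covariance: models post-whitening noise
  noise_comb <- coil_combine(combine_phase_cycles(
    adjoint_nufft_recon(unit_noise)), sens_eff)
  bg <- background_mask(pc$grid_size, pc$grid_size, roi)
  mu_f <- vapply(seq_len(pc$n_phases), function(f) {
    mean(Mod(ref$combined$images[, , f, 1])[phantom$mask[, , f]])
  }, numeric(1))
  sd_f <- vapply(seq_len(pc$n_phases), function(f) {
    stats::sd(Mod(noise_comb$images[, , f, 1])[bg])
  }, numeric(1))
  ring_f <- vapply(seq_len(pc$n_phases), function(f) {
    stats::sd(Mod(ref$combined$images[, , f, 1])[bg])
  }, numeric(1))
  sigma_k <- sigma_for_target_snr(mu_f, sd_f, cfg$target_snr, ring_f)

  ks_noisy <- add_noise(ks_clean, sigma_k, noise_cov = coils$noise_cov,
                        seed = seed + 303L)
  ks_noisy_w <- apply_prewhitening(ks_noisy, W)
  recon_noisy <- adjoint_nufft_recon(ks_noisy_w)
  noisy <- analyze_images(recon_noisy, phantom, sens_eff, cfg)

  denoised <- NULL
  recon_den <- NULL
  tab <- cfg$ratio_table
  if (cfg$denoise) {
    if (is.null(tab)) {
      acq <- acquisition_spec(dims, traj, whitened = TRUE)
      tab <- cached_ratio_table(acq, cfg$patch, n_mc = cfg$n_mc,
                                sigma_cal = 1, seed = seed + 404L,
                                cache_dir = cfg$table_cache_dir)
    }
    recon_den <- denoise_volume(recon_noisy, cfg$patch, tab)
    denoised <- analyze_images(recon_den, phantom, sens_eff, cfg)
  }

  metrics <- pipeline_metrics(ref, noisy, denoised, phantom, roi, cfg)

  out <- list(config = cfg, sigma_k = sigma_k, roi = roi,
              ratio_table = tab, whitener = W,
              reference = ref, noisy = noisy, denoised = denoised,
              truth = list(ecc = phantom$ecc, mask = phantom$mask,
                           displacement = phantom$displacement),
              metrics = metrics)
  if (keep_images) {
    out$images <- list(recon_ref = recon_ref, recon_noisy = recon_noisy,
                       recon_denoised = recon_den, kspace_noisy = ks_noisy_w)
  }
  class(out) <- "dense_run"
  out
}

pipeline_metrics <- function(ref, noisy, denoised, phantom, roi, cfg) {
  voxel <- ref$combined$pixel_mm^2 * cfg$slice_mm
  one <- function(res) {
    if (is.null(res)) return(NULL)
    mag <- Mod(res$combined$images[, , , 1])
    asnr <- apparent_snr(mag, roi)
    # unwrapped x/y phase from the displacement maps (u * 2 pi ke)
    ph_x <- res$displacement[, , 1, ] * 2 * pi * res$combined$ke_cyc_per_mm
    ph_y <- res$displacement[, , 2, ] * 2 * pi * res$combined$ke_cyc_per_mm
    err <- abs(res$ecc - phantom$ecc)
    list(nrmse = nrmse(res$combined, ref$combined),
         apparent_snr = asnr$mean,
         apparent_snr_per_frame = asnr$per_frame,
         phase_snr_x = phase_snr(ph_x, roi),
         phase_snr_y = phase_snr(ph_y, roi),
         scan_efficiency = scan_efficiency(asnr$mean, cfg$n_heartbeats,
                                           voxel),
         mean_abs_ecc_error = mean(err[phantom$mask & is.finite(err)]),
         segment_sds = res$segments$segment_sds)
  }
  list(noisy = one(noisy), denoised = one(denoised))
}

#' @export
print.dense_run <- function(x, ...) {
  cat("dense_run (paired non-denoised / denoised results)\n")
  cat(sprintf("  injected k-space sigma: %.4g (target apparent SNR %g)\n",
              x$sigma_k, x$config$target_snr))
  print(summary(x))
  invisible(x)
}

#' @export
summary.dense_run <- function(object, ...) {
  m <- object$metrics
  grab <- function(res, what) if (is.null(res)) NA_real_ else res[[what]]
  fields <- c("nrmse", "apparent_snr", "phase_snr_x", "phase_snr_y",
              "scan_efficiency", "mean_abs_ecc_error")
  df <- data.frame(
    metric = fields,
    non_denoised = vapply(fields, function(f) grab(m$noisy, f), numeric(1)),
    denoised = vapply(fields, function(f) grab(m$denoised, f), numeric(1)),
    row.names = NULL
  )
  df
}

# ---- container I/O ---------------------------------------------------------

CONTAINER_SCHEMA <- "densemp-container"
CONTAINER_VERSION <- 1L

#' Write a result bundle to a container file
#'
#' A single-file, versioned, schema-checked serialisation (RDS payload) of
#' any list of arrays, masks, tables and metadata; complex arrays round-trip
#' losslessly.
#'
#' @param path file path
#' @param bundle a named list
#' @export
write_container <- function(path, bundle) {
  stopifnot(is.list(bundle))
  saveRDS(list(schema = CONTAINER_SCHEMA, version = CONTAINER_VERSION,
               written = format(Sys.time(), tz = "UTC"),
               bundle = bundle),
          path)
  invisible(path)
}

#' Read a container file (optionally a single dataset)
#'
#' @param path file path
#' @param dataset optional name of a single element to extract
#' @return the bundle list, or the requested element
#' @export
read_container <- function(path, dataset = NULL) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$schema, CONTAINER_SCHEMA)) {
    stop("not a densemp container")
  }
  if (!identical(obj$version, CONTAINER_VERSION)) {
    stop("unsupported container schema version: ", obj$version)
  }
  if (is.null(dataset)) return(obj$bundle)
  if (!dataset %in% names(obj$bundle)) {
    stop("dataset not present in container: ", dataset)
  }
  obj$bundle[[dataset]]
}

#' Write the paired metrics table of a run as CSV
#'
#' @param run a `dense_run`
#' @param path output CSV path
#' @export
write_metrics_csv <- function(run, path) {
  utils::write.csv(summary(run), path, row.names = FALSE)
  invisible(path)
}

#' Write per-segment per-frame strain tables as CSV
#'
#' @param run a `dense_run`
#' @param path output CSV path
#' @export
write_strain_csv <- function(run, path) {
  dfs <- list()
  if (!is.null(run$noisy)) {
    d <- as.data.frame(run$noisy$segments)
    d$pipeline <- "non-denoised"
    dfs <- c(dfs, list(d))
  }
  if (!is.null(run$denoised)) {
    d <- as.data.frame(run$denoised$segments)
    d$pipeline <- "denoised"
    dfs <- c(dfs, list(d))
  }
  utils::write.csv(do.call(rbind, dfs), path, row.names = FALSE)
  invisible(path)
}
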