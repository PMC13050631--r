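# Shared, lazily built fixtures. The heavy objects (ratio tables, pipeline
# runs) are computed once per test session and reused across files.

fixture_env <- new.env(parent = emptyenv())

# main study conditions, scaled down: 2 mm pixels with the wall ~8 px thick
# (as in the high-resolution protocol), 8 coils, 10 cardiac phases
main_phantom_config <- function(...) {
  phantom_config(grid_size = 64L, fov_mm = 128, n_phases = 10L,
                 n_coils = 8L, epicardial_radius_mm = 30,
                 endocardial_radius_mm = 14, ...)
}

MAIN_SMOOTH_SIGMA <- 0.6  # 1.2 mm at the 2 mm fixture pixels

fx_main <- function() {
  if (!is.null(fixture_env$main)) return(fixture_env$main)
  pc <- main_phantom_config()
  traj <- design_spiral(pc$grid_size, pc$fov_mm, 4L)
  acq <- acquisition_spec(c(pc$n_coils, pc$n_phases, pc$n_phase_cycles,
                            pc$n_encodings), traj, whitened = TRUE)
  tab <- calibrate_ratios(acq, patch_spec(), n_mc = 10L, seed = 11L)
  runs <- lapply(1:3, function(s) {
    run_pipeline(run_config(phantom = pc, target_snr = 25, seed = s,
                            ratio_table = tab,
                            smooth_sigma = MAIN_SMOOTH_SIGMA),
                 keep_images = (s == 1))
  })
  fixture_env$main <- list(pc = pc, traj = traj, acq = acq, tab = tab,
                           runs = runs)
  fixture_env$main
}

# reduced conditions for the grouping / patch-size ablation
ablation_phantom_config <- function() {
  phantom_config(grid_size = 48L, fov_mm = 96, n_phases = 8L, n_coils = 6L,
                 epicardial_radius_mm = 20, endocardial_radius_mm = 10)
}

fx_ablation <- function() {
  if (!is.null(fixture_env$ablation)) return(fixture_env$ablation)
  pc <- ablation_phantom_config()
  traj <- design_spiral(pc$grid_size, pc$fov_mm, 4L)
  acq <- acquisition_spec(c(pc$n_coils, pc$n_phases, pc$n_phase_cycles,
                            pc$n_encodings), traj, whitened = TRUE)
  runs <- lapply(1:3, function(s) {
    run_pipeline(run_config(phantom = pc, target_snr = 25, seed = s,
                            denoise = FALSE,
                            smooth_sigma = MAIN_SMOOTH_SIGMA),
                 keep_images = TRUE)
  })
  fixture_env$ablation <- list(pc = pc, traj = traj, acq = acq, runs = runs)
  fixture_env$ablation
}

# per-(patch, grouping) ratio table for the ablation geometry, cached
fx_ablation_table <- function(spec) {
  ab <- fx_ablation()
  key <- paste("abtab", spec$px, spec$py, spec$grouping, sep = "_")
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <- calibrate_ratios(ab$acq, spec, n_mc = 10L,
                                           seed = 21L)
  }
  fixture_env[[key]]
}

# very small end-to-end configuration for determinism / plumbing tests
tiny_phantom_config <- function(...) {
  phantom_config(grid_size = 32L, fov_mm = 64, n_phases = 4L, n_coils = 4L,
                 epicardial_radius_mm = 15, endocardial_radius_mm = 7, ...)
}

fx_tiny_run <- function(seed = 5L, denoise = TRUE) {
  key <- sprintf("tiny_%d_%d", seed, denoise)
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <- run_pipeline(
      run_config(phantom = tiny_phantom_config(), target_snr = 25,
                 seed = seed, n_mc = 2L, denoise = denoise),
      keep_images = TRUE)
  }
  fixture_env[[key]]
}

# eroded per-frame masks
erode_frames <- function(mask, r = 1L) {
  out <- mask
  for (f in seq_len(dim(mask)[3])) {
    out[, , f] <- densemp:::erode_mask(mask[, , f], r)
  }
  out
}

rms <- function(x) sqrt(mean(x[is.finite(x)]^2))

grid_coords_mm_test <- function(n, fov) densemp:::grid_coords_mm(n, fov)

rcnorm_test <- function(n) densemp:::rcnorm(n)
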