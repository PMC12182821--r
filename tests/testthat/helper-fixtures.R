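# shared fixtures, all generated in code

.cache <- new.env(parent = emptyenv())

# the full desk-scale experiment (scanner protocol, 6 vessels incl. a
# bifurcation); computed once and shared by the end-to-end tests
desk_run_cached <- function() {
  if (is.null(.cache$desk)) {
    cfg <- desk_experiment_config(seed = 1,
                                  output_dir = file.path(tempdir(), "svrflow-desk"))
    .cache$desk <- suppressWarnings(run_experiment(cfg))
    .cache$desk_config <- cfg
  }
  list(run = .cache$desk, config = .cache$desk_config)
}

# a small straight-tube phantom along z
tube_phantom_config <- function(grid = c(40, 40, 32), voxel = 1.2, radius = 6,
                                peak = 100, waveform = waveform_spec("steady"),
                                jitter = 0) {
  zext <- grid[3] * voxel / 2
  phantom_config(
    grid_shape = grid, voxel_size_mm = voxel, cardiac_period_ms = 800,
    rr_jitter_frac = jitter,
    vessels = list(vessel_spec("tube", rbind(c(0, 0, -zext), c(0, 0, zext)),
                               radius_mm = radius, peak_velocity_cm_s = peak,
                               waveform = waveform)))
}

# brute-force non-uniform DFT, the independent oracle for the operator tests
ndft_bruteforce <- function(img, k, x, y) {
  n <- nrow(k)
  out <- complex(n)
  for (j in seq_len(n)) {
    ph <- outer(k[j, 1] * x, rep(1, length(y))) +
      outer(rep(1, length(x)), k[j, 2] * y)
    out[j] <- sum(img * exp(-2i * pi * ph))
  }
  out / sqrt(length(x) * length(y))
}

# lumen mask of a phantom's first vessel at the axial slice nearest z_mm
lumen_mask_at <- function(phantom, z_mm, vessel_index = 1) {
  crd <- phantom_grid(phantom$config)
  zi <- which.min(abs(crd$z - z_mm))
  list(mask = phantom$labels[, , zi] == 2L + vessel_index, zi = zi)
}
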