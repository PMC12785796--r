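# Shared synthetic fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

# a 128x128x40 field of 3 small adherent cells, 20 particles each; the
# desk-scale analogue of one imaging ROI
toy_field_config <- function(n_timepoints = 3L, seed = 7L, noise = TRUE,
                             particles = c(inside = 4L, boundary = 2L,
                                           perinuclear = 0L,
                                           cytoplasmic = 14L),
                             drift = c(0L, 2L, 3L)) {
  simulation_config(
    grid_shape = c(z = 40, y = 128, x = 128),
    n_timepoints = n_timepoints, n_cells = 3L,
    particles_per_cell = particles,
    cell_radius_xy = c(1.0, 1.3), cell_radius_z = c(2.2, 2.8),
    poisson_gain = if (noise) 1 else 0,
    read_noise_sd = if (noise) 5 else 0,
    drift = drift, seed = seed)
}

toy_seg_params <- function() {
  segmentation_params(downscale_factor = 2, gaussian_sigma = 1.5,
                      min_nucleus_volume = 300, min_cell_volume = 1000)
}

# one large flattened elongated cell in which the perinuclear band
# (1% of the max nucleus-to-membrane distance) spans more than one voxel,
# so all four spatial classes are placeable
flat_cell_config <- function(seed = 11L,
                             particles = c(inside = 12L, boundary = 6L,
                                           perinuclear = 3L,
                                           cytoplasmic = 39L)) {
  simulation_config(
    grid_shape = c(z = 14, y = 288, x = 624),
    n_timepoints = 1L, n_cells = 1L,
    particles_per_cell = particles,
    cell_radius_xy = c(18.0, 18.6), cell_radius_y = c(7.2, 7.6),
    cell_radius_z = c(2.2, 2.5), rotate_cells = FALSE,
    nucleus_scale = c(0.5, 0.18, 0.18),
    spot_sigma = c(z = 0.5, y = 1.0, x = 1.0), blur_sigma = c(0, 0, 0),
    drift = c(0L, 0L, 0L), seed = seed)
}

flat_seg_params <- function() {
  segmentation_params(downscale_factor = 1, gaussian_sigma = 1,
                      planar_sigma = 2,
                      min_nucleus_volume = 5000, min_cell_volume = 10000)
}

toy_sim <- function() cached_fixture("toy", generate_timelapse(toy_field_config()))
toy_sim_clean <- function() cached_fixture(
  "toy_clean", generate_timelapse(toy_field_config(noise = FALSE)))
flat_sim <- function() cached_fixture("flat", generate_timelapse(flat_cell_config()))

toy_result <- function() cached_fixture(
  "toy_res", process_timelapse(toy_sim()$stack, toy_seg_params()))
flat_result <- function() cached_fixture(
  "flat_res", process_timelapse(flat_sim()$stack, flat_seg_params()))

# greedy matching of detected against true particle positions within a
# physical tolerance; returns precision/recall/F1
match_particles <- function(det_pos, true_pos, spacing, tol_um = 0.4) {
  if (nrow(det_pos) == 0L)
    return(list(tp = 0L, fp = 0L, fn = nrow(true_pos), f1 = 0))
  used <- rep(FALSE, nrow(det_pos))
  tp <- 0L
  for (i in seq_len(nrow(true_pos))) {
    dd <- sqrt(colSums(((t(det_pos) - true_pos[i, ]) * spacing)^2))
    dd[used] <- Inf
    j <- which.min(dd)
    if (dd[j] <= tol_um) {
      used[j] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- nrow(det_pos) - tp
  fn <- nrow(true_pos) - tp
  f1 <- if (tp == 0L) 0 else 2 * tp / (2 * tp + fp + fn)
  list(tp = tp, fp = fp, fn = fn, f1 = f1)
}
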