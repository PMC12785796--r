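small_cfg <- function(...) {
  defaults <- list(
    grid_shape = c(z = 20, y = 72, x = 72), n_timepoints = 2L, n_cells = 1L,
    particles_per_cell = c(inside = 1L, boundary = 1L, perinuclear = 0L,
                           cytoplasmic = 3L),
    cell_radius_xy = c(1.2, 1.4), cell_radius_z = c(2.2, 2.6),
    drift = c(0L, 1L, 2L), seed = 5L)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

test_that("generation is bit-identical under a fixed seed", {
  s1 <- generate_timelapse(small_cfg())
  s2 <- generate_timelapse(small_cfg())
  expect_identical(s1$stack$data, s2$stack$data)
  expect_identical(s1$truth$particles, s2$truth$particles)
  expect_identical(s1$truth$cell_labels, s2$truth$cell_labels)
  s3 <- generate_timelapse(small_cfg(seed = 6L))
  expect_false(identical(s1$stack$data, s3$stack$data))
})

test_that("zero particles leave only background noise in the channel", {
  cfg <- small_cfg(particles_per_cell = c(inside = 0L, boundary = 0L,
                                          perinuclear = 0L, cytoplasmic = 0L),
                   poisson_gain = 0, read_noise_sd = 5)
  sim <- generate_timelapse(cfg)
  expect_equal(nrow(sim$truth$particles), 0L)
  pv <- get_channel(sim$stack, "particles", 1)
  expect_lte(max(pv), cfg$background[["particles"]] + 5 * cfg$read_noise_sd)
})

test_that("ground-truth bookkeeping matches the requested class counts", {
  sim <- flat_sim()
  cfg <- flat_cell_config()
  t1 <- sim$truth$particles[sim$truth$particles$timepoint == 1, ]
  expect_equal(nrow(t1), sum(cfg$particles_per_cell))
  got <- table(t1$class)
  expect_equal(as.integer(got[c("inside_nucleus", "nuclear_boundary",
                                "perinuclear", "cytoplasmic")]),
               unname(cfg$particles_per_cell))
  # every particle centroid lies inside its owning cell mask
  cl <- sim$truth$cell_labels[[1]]
  for (i in seq_len(nrow(t1))) {
    rc <- round(c(t1$z[i], t1$y[i], t1$x[i])) + 1
    expect_equal(cl[rc[1], rc[2], rc[3]], t1$cell[i])
  }
})

test_that("placement respects class geometry", {
  sim <- toy_sim()
  nuc <- sim$truth$nucleus_labels[[1]]
  t1 <- sim$truth$particles[sim$truth$particles$timepoint == 1, ]
  for (i in seq_len(nrow(t1))) {
    rc <- round(c(t1$z[i], t1$y[i], t1$x[i])) + 1
    in_nuc <- nuc[rc[1], rc[2], rc[3]] > 0
    if (t1$class[i] == "inside_nucleus") expect_true(in_nuc)
    if (t1$class[i] == "cytoplasmic") expect_false(in_nuc)
  }
})

test_that("explicit errors on infeasible geometry", {
  # too many cells for the grid
  expect_error(generate_timelapse(small_cfg(n_cells = 40L)),
               "placement failed")
  # the perinuclear band is empty in a small rounded cell
  nuc_small <- small_cfg(particles_per_cell = c(inside = 0L, boundary = 0L,
                                                perinuclear = 2L,
                                                cytoplasmic = 0L))
  expect_error(generate_timelapse(nuc_small), "infeasible")
})

test_that("place_particles postconditions: containment and partial overlap", {
  set.seed(50)
  sim <- flat_sim()
  nuc <- sim$truth$nucleus_labels[[1]] > 0
  cell <- sim$truth$cell_labels[[1]] > 0
  cfg <- flat_cell_config()
  p <- place_particles(cell, nuc, c(inside = 1L, boundary = 1L,
                                    perinuclear = 0L, cytoplasmic = 1L),
                       spacing = cfg$voxel_spacing, config = cfg)
  expect_equal(nrow(p), 3L)
  # rasterized footprint of the boundary particle overlaps partially (voxel
  # count oracle on the verification footprint)
  fp <- virotrace3d:::verify_spot_class(
    as.numeric(p[p$class == "boundary", c("z", "y", "x")]),
    list(nucleus = nuc,
         bco = which(virotrace3d:::boundary_voxels(nuc), arr.ind = TRUE),
         dmax = attr(p, "d_max")),
    cfg)
  expect_gt(fp$nr, 0)
  expect_lt(fp$nr, 1)
  # the inside particle's footprint is wholly inside the nucleus
  fi <- virotrace3d:::verify_spot_class(
    as.numeric(p[p$class == "inside", c("z", "y", "x")]),
    list(nucleus = nuc,
         bco = which(virotrace3d:::boundary_voxels(nuc), arr.ind = TRUE),
         dmax = attr(p, "d_max")),
    cfg)
  expect_equal(fi$nr, 1)
  # cytoplasmic particle lies beyond the perinuclear cut
  fc <- virotrace3d:::verify_spot_class(
    as.numeric(p[p$class == "cytoplasmic", c("z", "y", "x")]),
    list(nucleus = nuc,
         bco = which(virotrace3d:::boundary_voxels(nuc), arr.ind = TRUE),
         dmax = attr(p, "d_max")),
    cfg)
  expect_gt(fc$x_norm, 0.01)
})

test_that("optics and noise behave as configured", {
  geom <- array(0, c(8, 16, 16, 1, 1))
  geom[4, 8, 8, 1, 1] <- 1000.4
  cfg <- small_cfg(blur_sigma = c(0, 0, 0), poisson_gain = 0,
                   read_noise_sd = 0)
  out <- apply_optics_and_noise(geom, cfg)
  expect_equal(out, round(geom))
  # Poisson-only flat field: variance within 10% of the mean
  flat <- array(500, c(20, 50, 50, 1, 1))
  cfgp <- small_cfg(blur_sigma = c(0, 0, 0), poisson_gain = 1,
                    read_noise_sd = 0)
  withr::with_seed(1, outp <- apply_optics_and_noise(flat, cfgp))
  expect_lt(abs(var(as.vector(outp)) - 500) / 500, 0.1)
  expect_lt(abs(mean(outp) - 500) / 500, 0.01)
  # 8-bit quantization bound
  cfg8 <- small_cfg(bit_depth = 8L, blur_sigma = c(0, 0, 0))
  big <- array(1000, c(4, 8, 8, 1, 1))
  withr::with_seed(1, out8 <- apply_optics_and_noise(big, cfg8))
  expect_lte(max(out8), 255)
})

test_that("nucleus drift between consecutive timepoints equals the config", {
  sim <- toy_sim_clean()
  cfg <- toy_field_config(noise = FALSE)
  tr <- sim$truth$tracks
  for (id in unique(tr$track_id)) {
    tt <- tr[tr$track_id == id, ]
    tt <- tt[order(tt$timepoint), ]
    expect_true(all(abs(diff(tt$z) - cfg$drift[1]) <= 1))
    expect_true(all(abs(diff(tt$y) - cfg$drift[2]) <= 1))
    expect_true(all(abs(diff(tt$x) - cfg$drift[3]) <= 1))
  }
})

test_that("class fidelity: noiseless measurement against ground-truth masks", {
  sim <- flat_sim()
  st <- sim$stack
  gt <- sim$truth
  assoc <- associate_nuclei_cells(gt$nucleus_labels[[1]], gt$cell_labels[[1]])
  pv <- get_channel(st, "particles", 1)
  cts <- detect_centroids(pv)
  plab <- segment_particles(pv, cts, 600)
  m <- measure_particles(plab, pv, gt$nucleus_labels[[1]], gt$cell_labels[[1]],
                         assoc, st$spacing)
  truth_t <- gt$particles[gt$particles$timepoint == 1, ]
  expect_equal(nrow(m), nrow(truth_t))
  # match each measured particle to its true twin and compare the class
  tru <- as.matrix(truth_t[, c("z", "y", "x")]) + 1
  det <- as.matrix(m[, c("z", "y", "x")]) + 1
  for (i in seq_len(nrow(tru))) {
    dd <- sqrt(colSums(((t(det) - tru[i, ]) * st$spacing)^2))
    j <- which.min(dd)
    expect_lt(dd[j], 0.4)
    expect_equal(as.character(m$spatial_class[j]),
                 as.character(truth_t$class[i]))
  }
})
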