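# render an isolated Gaussian spot volume on flat background
spot_volume <- function(dim3 = c(11, 41, 41), pos = (dim3 + 1) / 2,
                        peak = 800, bg = 0,
                        sigma = c(0.6, 1.7, 1.7)) {
  rs <- virotrace3d:::render_spot_crop(dim3, pos, peak, sigma,
                                       pad = max(dim3))
  vol <- array(bg, dim3)
  vol[rs$zi, rs$yi, rs$xi] <- vol[rs$zi, rs$yi, rs$xi] + rs$crop
  vol
}

test_that("LoG detection finds isolated spots and nothing in blank volumes", {
  expect_equal(nrow(detect_centroids(array(0, c(8, 20, 20)))), 0L)
  vol <- spot_volume(pos = c(6, 21, 19))
  ct <- detect_centroids(vol, particle_params(response_floor = 0.5))
  expect_equal(nrow(ct), 1L)
  expect_true(all(abs(ct[1, ] - c(6, 21, 19)) <= 1))
  # two spots > 4 sigma apart give two centroids
  v2 <- spot_volume(pos = c(6, 12, 12)) + spot_volume(pos = c(6, 30, 30))
  ct2 <- detect_centroids(v2, particle_params(response_floor = 0.5))
  expect_equal(nrow(ct2), 2L)
})

test_that("seeded watershed reproduces the super-level set at the threshold", {
  vol <- spot_volume(pos = c(6, 21, 21), peak = 800)
  ct <- detect_centroids(vol, particle_params(response_floor = 0.5))
  lab <- segment_particles(vol, ct, 600)
  expect_equal(sort(which(lab > 0)), sort(which(vol >= 600)))
  # sub-threshold spot is not detected
  weak <- spot_volume(pos = c(6, 21, 21), peak = 400)
  ctw <- detect_centroids(weak, particle_params(response_floor = 0.5))
  expect_gte(nrow(ctw), 1L)
  labw <- segment_particles(weak, ctw, 600)
  expect_equal(sum(labw > 0), 0L)
  # two touching spots with two seeds partition the joint super-level set
  v2 <- spot_volume(pos = c(6, 21, 18), peak = 900) +
        spot_volume(pos = c(6, 21, 26), peak = 900)
  ct2 <- detect_centroids(v2, particle_params(response_floor = 0.5))
  expect_equal(nrow(ct2), 2L)
  lab2 <- segment_particles(v2, ct2, 600)
  expect_setequal(unique(lab2[lab2 > 0]), 1:2)
  expect_equal(sort(which(lab2 > 0)), sort(which(v2 >= 600)))
})

test_that("threshold sweep counts are non-increasing and zero on mock fields", {
  pp <- particle_params(response_floor = 0.5)
  # mock: background noise only, no labeled virus present
  set.seed(77)
  mock <- array(rpois(8 * 30 * 30, 100), c(8, 30, 30))
  ctm <- detect_centroids(mock, pp)
  swm <- sweep_thresholds(mock, ctm, params = pp)
  expect_true(all(swm$n_particles == 0L))
  # a single 800-peak spot is caught at every calibration threshold
  vol <- spot_volume(pos = c(6, 21, 21), peak = 801)
  ct <- detect_centroids(vol, pp)
  sw <- sweep_thresholds(vol, ct, params = pp)
  expect_equal(sw$threshold, c(300, 400, 500, 600, 700, 800))
  expect_true(all(sw$n_particles == 1L))
  # random multi-spot field: counts never increase with the threshold
  set.seed(5)
  v <- array(50, c(10, 50, 50))
  for (i in 1:6)
    v <- v + spot_volume(c(10, 50, 50), pos = c(sample(3:8, 1), sample(5:45, 1),
                                                sample(5:45, 1)),
                         peak = sample(c(350, 500, 650, 900), 1))
  ct <- detect_centroids(v, pp)
  sw <- sweep_thresholds(v, ct, params = pp)
  expect_true(all(diff(sw$n_particles) <= 0))
})

test_that("nuclear ratio equals brute-force voxel counting", {
  nuc <- array(FALSE, c(6, 12, 12)); nuc[2:5, 3:9, 3:9] <- TRUE
  inside <- array(FALSE, c(6, 12, 12)); inside[3:4, 5:6, 5:6] <- TRUE
  expect_equal(compute_nuclear_ratio(inside, nuc), 1)
  straddle <- array(FALSE, c(6, 12, 12)); straddle[3, 2:3, 2:5] <- TRUE
  expect_equal(compute_nuclear_ratio(straddle, nuc),
               sum(straddle & nuc) / sum(straddle))
  halfspace <- array(FALSE, c(6, 12, 12)); halfspace[, , 5:12] <- TRUE
  half <- array(FALSE, c(6, 12, 12)); half[3, 3, 1:8] <- TRUE  # 4 of 8 in
  expect_equal(sum(half), 8)
  expect_equal(compute_nuclear_ratio(half, halfspace), 0.5)
  out <- array(FALSE, c(6, 12, 12)); out[1, 11:12, 11:12] <- TRUE
  expect_equal(compute_nuclear_ratio(out, nuc), 0)
  expect_warning(r <- compute_nuclear_ratio(array(FALSE, c(6, 12, 12)), nuc),
                 "empty")
  expect_true(is.na(r))
  set.seed(33)
  for (i in 1:25) {
    p <- array(runif(32^3) < 0.1, c(32, 32, 32))
    n <- array(runif(32^3) < 0.3, c(32, 32, 32))
    if (!any(p)) next
    expect_equal(compute_nuclear_ratio(p, n), bf_nuclear_ratio(p, n))
  }
})

test_that("distances match the exhaustive anisotropic minimum", {
  sp <- c(0.762, 0.0618, 0.0618)
  g <- random_cell_geometry()
  # centroid on the nucleus surface -> zero
  surf <- which(virotrace3d:::boundary_voxels(g$nucleus), arr.ind = TRUE)[1, ]
  d0 <- compute_distances(as.numeric(surf), g$nucleus, g$cell, sp)
  expect_equal(d0$x_raw, 0)
  expect_equal(d0$x_norm, 0)
  # the cell voxel realizing D_max normalizes to 1
  dt <- virotrace3d:::cpp_edt3(g$nucleus, sp)
  dmax_idx <- which(g$cell & dt == max(dt[g$cell]), arr.ind = TRUE)[1, ]
  d1 <- compute_distances(as.numeric(dmax_idx), g$nucleus, g$cell, sp)
  expect_equal(d1$x_norm, 1, tolerance = 1e-9)
  # random centroids vs exhaustive minimum over every nucleus voxel
  set.seed(14)
  for (i in 1:10) {
    g <- random_cell_geometry()
    pool <- which(g$cell & !g$nucleus)
    for (lin in sample(pool, 5)) {
      ctr <- as.numeric(arrayInd(lin, g$dim)) + runif(3, -0.4, 0.4)
      rc <- pmin(pmax(round(ctr), 1), g$dim)
      if (g$nucleus[rc[1], rc[2], rc[3]]) next
      got <- compute_distances(ctr, g$nucleus, g$cell, sp)
      expect_equal(got$x_raw, bf_min_dist(ctr, g$nucleus, sp),
                   tolerance = 1e-9)
      expect_gte(got$x_norm, 0)
      expect_lte(got$x_norm, 1)
    }
  }
  # degenerate cell identical to nucleus
  expect_warning(
    dd <- compute_distances(c(1, 1, 1), g$nucleus, g$nucleus, sp),
    "degenerate")
  expect_equal(dd$x_norm, 0)
})

test_that("particles belong to the cell containing their centroid", {
  cells <- array(0L, c(4, 20, 20))
  cells[, 1:20, 1:9] <- 1L
  cells[, 1:20, 12:20] <- 2L
  plab <- array(0L, c(4, 20, 20))
  plab[2, 5:6, 4:5] <- 1L    # inside cell 1
  plab[3, 10, 15] <- 2L      # inside cell 2
  plab[2, 3, 10:11] <- 3L    # background gap
  own <- assign_particles_to_cells(plab, cells)
  expect_equal(own$cell[own$particle == 1], 1L)
  expect_equal(own$cell[own$particle == 2], 2L)
  expect_true(is.na(own$cell[own$particle == 3]))
  expect_equal(attr(own, "n_unassigned"), 1L)
})

test_that("per-cell particle counts match ground truth at high SNR", {
  sim <- toy_sim()
  res <- toy_result()
  truth_t1 <- sim$truth$particles[sim$truth$particles$timepoint == 1, ]
  got_t1 <- res$particles[res$particles$timepoint == 1, ]
  expect_equal(nrow(got_t1), nrow(truth_t1))
  # per ground-truth cell: 20 particles each
  det <- as.matrix(got_t1[, c("z", "y", "x")]) + 1
  tru <- as.matrix(truth_t1[, c("z", "y", "x")]) + 1
  m <- match_particles(det, tru, sim$stack$spacing)
  expect_gte(m$f1, 0.95)
  counts <- table(got_t1$cell)
  expect_true(all(counts == 20))
})
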