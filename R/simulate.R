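#' Simulation configuration
#'
#' Study conditions of the synthetic multi-channel 3D time-lapse generator:
#' convex cells (randomly oriented ellipsoids) each holding one interior
#' ellipsoidal nucleus, diffraction-limited particle spots placed at
#' controlled spatial classes, the acquisition voxel anisotropy
#' (0.0618 um XY / 0.762 um Z), Gaussian optics blur, Poisson photon noise
#' plus Gaussian read noise, a small rigid drift per timepoint, and
#' quantized output.
#'
#' Intensities live on a conventional post-deconvolution 16-bit scale chosen
#' so that the standard particle detection thresholds (300-800) are
#' meaningful: spots peak well above the final threshold of 600.
#'
#' @param grid_shape voxels `c(z, y, x)`.
#' @param voxel_spacing micrometers per voxel `c(z, y, x)`.
#' @param n_timepoints number of timepoints.
#' @param n_cells number of cells in the field.
#' @param particles_per_cell named counts
#'   `c(inside, boundary, perinuclear, cytoplasmic)` per cell.
#' @param cell_radius_xy range (um) of the in-plane ellipsoid semi-axes.
#' @param cell_radius_y optional separate range for the y semi-axis
#'   (elongated cells); defaults to `cell_radius_xy`.
#' @param cell_radius_z range (um) of the axial semi-axis.
#' @param rotate_cells randomly rotate cells in the XY plane; disable for
#'   axis-aligned geometries that must use the full field extent.
#' @param nucleus_scale nucleus semi-axes as a fraction of the cell's;
#'   scalar or per-axis `c(z, y, x)` (flattened cells have laterally small
#'   but axially proportionate nuclei).
#' @param background per-channel background level.
#' @param amplitude per-channel object amplitude above background; for the
#'   particle channel this is the spot peak before optics blur.
#' @param egfp_range per-cell eGFP amplitude is drawn uniformly from this
#'   range, giving a spread of transgene expression across cells.
#' @param spot_sigma rendered particle spot sigma in voxels `c(z, y, x)`.
#' @param blur_sigma optics blur sigma in voxels `c(z, y, x)`.
#' @param poisson_gain photons per intensity unit (0 disables Poisson noise).
#' @param read_noise_sd Gaussian read noise standard deviation.
#' @param drift rigid translation per timepoint step, integer voxels
#'   `c(z, y, x)`; must stay below the tracking search range.
#' @param bit_depth output quantization, 8 or 16.
#' @param class_ref_threshold intensity threshold at which placement
#'   verifies the intended spatial class (the final detection threshold).
#' @param min_particle_separation minimum lateral distance between particle
#'   centers (um), so spots remain individually resolvable; on each axis the
#'   effective floor is never below four effective sigmas of the rendered
#'   spot (axial neighbors one z-plane apart are unresolvable).
#' @param seed RNG seed; a fixed seed makes the output bit-identical.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(grid_shape = c(z = 40, y = 256, x = 256),
                              voxel_spacing = .default_spacing,
                              n_timepoints = 5L,
                              n_cells = 3L,
                              particles_per_cell = c(inside = 2L, boundary = 1L,
                                                     perinuclear = 0L,
                                                     cytoplasmic = 9L),
                              cell_radius_xy = c(1.8, 2.4),
                              cell_radius_y = NULL,
                              cell_radius_z = c(2.2, 3.0),
                              rotate_cells = TRUE,
                              nucleus_scale = 0.55,
                              background = c(membrane = 100, particles = 100,
                                             egfp = 100, nuclei = 100),
                              amplitude = c(membrane = 3000, particles = 1500,
                                            egfp = 3000, nuclei = 5000),
                              egfp_range = c(500, 5000),
                              spot_sigma = c(z = 0.5, y = 1.7, x = 1.7),
                              blur_sigma = c(z = 0.3, y = 1.0, x = 1.0),
                              poisson_gain = 1,
                              read_noise_sd = 5,
                              drift = c(z = 0L, y = 2L, x = 3L),
                              bit_depth = 16L,
                              class_ref_threshold = 600,
                              min_particle_separation = 0.5,
                              seed = 1L) {
  stopifnot(all(grid_shape > 0), all(voxel_spacing > 0),
            n_timepoints >= 1, n_cells >= 1,
            all(particles_per_cell >= 0), length(particles_per_cell) == 4L,
            all(nucleus_scale > 0), all(nucleus_scale < 0.95),
            length(nucleus_scale) %in% c(1L, 3L),
            bit_depth %in% c(8L, 16L),
            poisson_gain >= 0, read_noise_sd >= 0)
  names(grid_shape) <- c("z", "y", "x")
  names(voxel_spacing) <- c("z", "y", "x")
  names(particles_per_cell) <- c("inside", "boundary", "perinuclear",
                                 "cytoplasmic")
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_spacing = voxel_spacing,
                 n_timepoints = as.integer(n_timepoints),
                 n_cells = as.integer(n_cells),
                 particles_per_cell = setNames(as.integer(particles_per_cell),
                                               names(particles_per_cell)),
                 cell_radius_xy = cell_radius_xy,
                 cell_radius_y = cell_radius_y,
                 cell_radius_z = cell_radius_z,
                 rotate_cells = isTRUE(rotate_cells),
                 nucleus_scale = nucleus_scale,
                 background = background, amplitude = amplitude,
                 egfp_range = egfp_range,
                 spot_sigma = spot_sigma, blur_sigma = blur_sigma,
                 poisson_gain = poisson_gain, read_noise_sd = read_noise_sd,
                 drift = as.integer(round(drift)),
                 bit_depth = as.integer(bit_depth),
                 class_ref_threshold = class_ref_threshold,
                 min_particle_separation = min_particle_separation,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# rasterize an ellipsoid: voxel centers at (index-1)*spacing, XY-plane
# rotation theta, semi-axes in micrometers (axes = c(z, y, x))
ellipsoid_mask <- function(dim3, spacing, center, axes, theta = 0) {
  nz <- dim3[1L]; ny <- dim3[2L]; nx <- dim3[3L]
  dz <- rep((seq_len(nz) - 1) * spacing[1L] - center[1L], times = ny * nx)
  dy <- rep(rep((seq_len(ny) - 1) * spacing[2L] - center[2L], each = nz),
            times = nx)
  dx <- rep((seq_len(nx) - 1) * spacing[3L] - center[3L], each = nz * ny)
  u <- cos(theta) * dy + sin(theta) * dx
  v <- -sin(theta) * dy + cos(theta) * dx
  q <- (dz / axes[1L])^2 + (u / axes[2L])^2 + (v / axes[3L])^2
  array(q <= 1, dim3)
}

# integer-voxel translation of an array, zero/FALSE fill
shift_array <- function(a, d3) {
  if (all(d3 == 0L)) return(a)
  dm <- dim(a)
  out <- array(if (is.logical(a)) FALSE else 0L, dm)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    s <- d3[ax]
    src[[ax]] <- seq_len(dm[ax]) - s
    keep <- src[[ax]] >= 1L & src[[ax]] <= dm[ax]
    src[[ax]] <- src[[ax]][keep]
    dst[[ax]] <- seq_len(dm[ax])[keep]
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# place non-overlapping cells (each with one interior nucleus); bounded
# retries, explicit error when the field cannot hold n_cells
place_cells <- function(config) {
  d <- config$grid_shape
  sp <- config$voxel_spacing
  fov <- (d - 1) * sp
  drift_tot <- abs(config$drift) * (config$n_timepoints - 1L) * sp
  # adherent monolayer: projected cell footprints must be disjoint, or the
  # planar instance segmentation could not tell the cells apart
  occupied2d <- matrix(FALSE, d[2L], d[3L])
  cells <- vector("list", config$n_cells)
  for (i in seq_len(config$n_cells)) {
    placed <- FALSE
    ry_range <- if (is.null(config$cell_radius_y)) config$cell_radius_xy else
      config$cell_radius_y
    nscale <- rep(config$nucleus_scale, length.out = 3L)
    for (attempt in 1:400) {
      ax <- runif(1, config$cell_radius_xy[1], config$cell_radius_xy[2])
      ay <- runif(1, ry_range[1], ry_range[2])
      az <- runif(1, config$cell_radius_z[1], config$cell_radius_z[2])
      theta <- if (isTRUE(config$rotate_cells)) runif(1, 0, pi) else 0
      axes <- c(az, ay, ax)
      rxy <- if (isTRUE(config$rotate_cells)) rep(max(ax, ay), 2L) else c(ay, ax)
      margin <- c(az, rxy) + drift_tot + 2 * sp
      if (any(fov - 2 * margin <= 0)) next
      center <- margin + runif(3) * (fov - 2 * margin)
      cmask <- ellipsoid_mask(d, sp, center, axes, theta)
      fp2 <- matrix(mip(cmask * 1) > 0, d[2L], d[3L])
      if (any(fp2 & occupied2d)) next
      off_mag <- 0.2 * (0.95 - max(nscale)) * axes
      ncenter <- center + runif(3, -1, 1) * off_mag
      nmask <- ellipsoid_mask(d, sp, ncenter, axes * nscale, theta)
      if (!any(nmask) || any(nmask & !cmask)) next
      occupied2d <- occupied2d | fp2
      cells[[i]] <- list(id = i, center = center, axes = axes, theta = theta,
                         ncenter = ncenter, cell = cmask, nucleus = nmask)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("cell placement failed: n_cells too large for the grid ",
           "(no non-overlapping position found after bounded retries)")
  }
  cells
}

# render one particle spot (pre-optics Gaussian) into a local crop; returns
# the crop values plus its global index ranges
render_spot_crop <- function(dim3, pos, amp, spot_sigma, pad) {
  lo <- pmax(1L, floor(pos - pad))
  hi <- pmin(dim3, ceiling(pos + pad))
  zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
  gz <- exp(-0.5 * ((zi - pos[1]) / max(spot_sigma[1], 1e-6))^2)
  gy <- exp(-0.5 * ((yi - pos[2]) / max(spot_sigma[2], 1e-6))^2)
  gx <- exp(-0.5 * ((xi - pos[3]) / max(spot_sigma[3], 1e-6))^2)
  crop <- amp * outer(outer(gz, gy), gx)
  list(crop = array(crop, c(length(zi), length(yi), length(xi))),
       zi = zi, yi = yi, xi = xi)
}

# noiseless render -> optics blur -> threshold of one spot, measured exactly
# as the particle module would at infinite SNR; returns NR, x_norm, class
verify_spot_class <- function(pos, cellinfo, config) {
  ss <- config$spot_sigma; bs <- config$blur_sigma
  pad <- ceiling(3 * (ss + bs)) + 2L
  sp <- config$voxel_spacing
  d <- config$grid_shape
  rs <- render_spot_crop(d, pos, config$amplitude[["particles"]], ss, pad)
  crop <- gauss_blur(rs$crop, bs)
  vthr <- config$class_ref_threshold - config$background[["particles"]]
  sel <- which(crop >= vthr, arr.ind = TRUE)
  if (!nrow(sel)) return(NULL)
  gz <- rs$zi[sel[, 1]]; gy <- rs$yi[sel[, 2]]; gx <- rs$xi[sel[, 3]]
  lin <- gz + d[1L] * ((gy - 1L) + d[2L] * (gx - 1L))
  nr <- sum(cellinfo$nucleus[lin]) / length(lin)
  cen <- c(mean(gz), mean(gy), mean(gx))
  if (nr > 0) {
    x_raw <- 0
  } else {
    rc <- pmin(pmax(round(cen), 1L), d)
    if (cellinfo$nucleus[rc[1], rc[2], rc[3]]) {
      x_raw <- 0
    } else {
      dz <- (cellinfo$bco[, 1] - cen[1]) * sp[1]
      dy <- (cellinfo$bco[, 2] - cen[2]) * sp[2]
      dx <- (cellinfo$bco[, 3] - cen[3]) * sp[3]
      x_raw <- sqrt(min(dz^2 + dy^2 + dx^2))
    }
  }
  x_norm <- if (cellinfo$dmax > 0) min(1, x_raw / cellinfo$dmax) else 0
  list(nr = nr, x_norm = x_norm, mask_lin = lin,
       class = as.character(classify_particle(nr, x_norm)))
}

# half-extent (voxels per axis) of a spot's super-level set at the
# class-verification threshold, measured on a free-space render
spot_footprint <- function(config) {
  ss <- config$spot_sigma; bs <- config$blur_sigma
  pad <- ceiling(3 * (ss + bs)) + 2L
  dimc <- 2L * pad + 1L
  ctr <- pad + 1L
  rs <- render_spot_crop(dimc, as.numeric(ctr), config$amplitude[["particles"]],
                         ss, pad)
  crop <- gauss_blur(rs$crop, bs)
  vthr <- max(config$class_ref_threshold - config$background[["particles"]], 1)
  sel <- which(crop >= vthr, arr.ind = TRUE)
  if (!nrow(sel))
    stop("particle amplitude below the class-verification threshold: ",
         "no spot would be detected")
  vapply(1:3, function(ax) max(abs(sel[, ax] - ctr[ax])), numeric(1))
}

# interior placement bands per class (stricter than the class boundaries, so
# the measured class is stable under noise)
class_band_ok <- function(class_requested, v) {
  switch(class_requested,
    inside = v$nr >= 1,
    boundary = v$nr >= 0.1 && v$nr <= 0.9,
    perinuclear = v$nr == 0 && v$x_norm > 0 && v$x_norm <= 0.009,
    cytoplasmic = v$nr == 0 && v$x_norm >= 0.03)
}

#' Place particles of requested spatial classes inside one cell
#'
#' Candidate voxels for each class are drawn from the cell geometry
#' (nucleus interior depth, nuclear surface, perinuclear shell, cytoplasm)
#' and every placement is verified by rendering the spot through the same
#' optics and measuring it with the same nuclear-ratio/distance code used by
#' the measurement module, so simulator and measurer cannot disagree.
#'
#' Uses the current RNG state.
#'
#' @param cell_mask,nucleus_mask logical volumes, nucleus strictly inside cell.
#' @param class_counts named counts
#'   `c(inside, boundary, perinuclear, cytoplasmic)`.
#' @param spacing voxel spacing `c(z, y, x)` micrometers.
#' @param config a [simulation_config()] providing optics and amplitudes.
#' @return tibble `(class, z, y, x)` (1-based voxel centers) with attribute
#'   `d_max`; errors when a class is infeasible for the geometry.
#' @export
place_particles <- function(cell_mask, nucleus_mask, class_counts,
                            spacing = .default_spacing,
                            config = simulation_config()) {
  stopifnot(!any(nucleus_mask & !cell_mask))
  d <- dim(cell_mask)
  depth_n <- cpp_edt3(!nucleus_mask, as.numeric(spacing)) # depth inside nucleus
  dist_n <- cpp_edt3(nucleus_mask, as.numeric(spacing))   # distance to nucleus
  depth_c <- cpp_edt3(!cell_mask, as.numeric(spacing))
  dmax <- max(dist_n[cell_mask])
  bco <- arrayInd(which(boundary_voxels(nucleus_mask)), d)
  info <- list(nucleus = nucleus_mask, bco = bco, dmax = dmax)
  # measured half-extent (um per axis) of the thresholded spot mask
  e_phys <- spot_footprint(config) * spacing
  inside_pool <- which(nucleus_mask & depth_n >= max(e_phys))
  if (!length(inside_pool)) inside_pool <- which(nucleus_mask)
  cand <- list(
    inside = inside_pool,
    boundary = which(boundary_voxels(nucleus_mask)),
    perinuclear = which(cell_mask & !nucleus_mask & dist_n > 0 &
                          dist_n <= 0.01 * dmax),
    cytoplasmic = which(cell_mask & !nucleus_mask & depth_c >= min(spacing) &
                          dist_n >= max(0.03 * dmax, max(e_phys))))
  placed <- list()
  accepted_pos <- matrix(numeric(), 0L, 3L)
  # per-axis separation floor: the configured distance laterally, but never
  # below ~3 effective sigmas on any axis (spots one z-plane apart are not
  # axially resolvable at this anisotropy)
  sepv <- pmax(config$min_particle_separation,
               3 * sqrt(config$spot_sigma^2 + config$blur_sigma^2) * spacing)
  for (cl in names(class_counts)) {
    need <- class_counts[[cl]]
    if (need == 0L) next
    pool <- cand[[cl]]
    if (!length(pool))
      stop(sprintf("particle placement infeasible: no candidate voxels for class '%s' (geometry too small for this class)", cl))
    pool <- pool[sample.int(length(pool))]
    got <- 0L
    for (lin in pool) {
      if (got >= need) break
      pos <- as.numeric(arrayInd(lin, d))
      if (nrow(accepted_pos)) {
        dd <- sqrt(colSums(((t(accepted_pos) - pos) * spacing / sepv)^2))
        if (min(dd) < 1) next
      }
      v <- verify_spot_class(pos, info, config)
      if (is.null(v) || !isTRUE(class_band_ok(cl, v))) next
      got <- got + 1L
      accepted_pos <- rbind(accepted_pos, pos)
      placed[[length(placed) + 1L]] <-
        tibble::tibble(class = cl, z = pos[1], y = pos[2], x = pos[3])
    }
    if (got < need)
      stop(sprintf("particle placement infeasible: placed %d of %d '%s' particles before exhausting candidates", got, need, cl))
  }
  out <- if (length(placed)) dplyr::bind_rows(placed) else
    tibble::tibble(class = character(), z = numeric(), y = numeric(),
                   x = numeric())
  attr(out, "d_max") <- dmax
  out
}

#' Apply optics and noise to a rendered geometry
#'
#' Per channel: anisotropic Gaussian blur, Poisson noise on the signal,
#' additive Gaussian read noise, then clipping and quantization to the
#' configured bit depth. Uses the current RNG state.
#'
#' @param geometry 5D array `(z, y, x, channel, time)` of noiseless
#'   intensities.
#' @param config a [simulation_config()].
#' @return quantized 5D array of the same shape.
#' @export
apply_optics_and_noise <- function(geometry, config) {
  d <- dim(geometry)
  maxval <- 2^config$bit_depth - 1
  out <- array(0, d)
  for (t in seq_len(d[5L])) {
    for (ch in seq_len(d[4L])) {
      v <- array(geometry[, , , ch, t], d[1:3])
      if (any(config$blur_sigma > 0)) v <- gauss_blur(v, config$blur_sigma)
      if (config$poisson_gain > 0) {
        g <- config$poisson_gain
        v <- array(rpois(length(v), pmax(v, 0) * g) / g, d[1:3])
      }
      if (config$read_noise_sd > 0)
        v <- v + rnorm(length(v), 0, config$read_noise_sd)
      out[, , , ch, t] <- round(pmin(pmax(v, 0), maxval))
    }
  }
  out
}

#' Generate a synthetic multi-channel 3D time-lapse with ground truth
#'
#' Renders `n_cells` convex cells (membrane/cytoplasmic fill, nuclear fill,
#' per-cell eGFP fill) plus class-controlled particle spots across
#' `n_timepoints` with a rigid drift, then applies optics and noise. With a
#' fixed seed the output is bit-identical across calls.
#'
#' @param config a [simulation_config()].
#' @return list with `stack` (a [channel_stack()]) and `truth`, which holds
#'   per-timepoint `cell_labels` and `nucleus_labels`, a `particles` table
#'   (timepoint, cell, class, 0-based voxel centroid), a `tracks` table of
#'   true nucleus tracks, and the per-cell `egfp_amplitude`.
#' @export
generate_timelapse <- function(config = simulation_config()) {
  withr::with_seed(config$seed, generate_timelapse_impl(config))
}

generate_timelapse_impl <- function(config) {
  d <- config$grid_shape
  sp <- config$voxel_spacing
  nt <- config$n_timepoints
  cells <- place_cells(config)
  egfp_amp <- runif(length(cells), config$egfp_range[1], config$egfp_range[2])
  parts <- lapply(cells, function(ci) {
    p <- place_particles(ci$cell, ci$nucleus, config$particles_per_cell,
                         sp, config)
    if (nrow(p)) p$cell <- ci$id
    p
  })
  parts <- dplyr::bind_rows(parts)
  geom <- array(0, c(d, 4L, nt))
  cell_labels <- nucleus_labels <- vector("list", nt)
  ptab <- vector("list", nt)
  trk <- vector("list", nt)
  bg <- config$background
  amp <- config$amplitude
  for (t in seq_len(nt)) {
    dr <- config$drift * (t - 1L)
    cl <- array(0L, d); nl <- array(0L, d)
    egfp <- array(bg[["egfp"]], d)
    for (ci in cells) {
      cm <- shift_array(ci$cell, dr)
      nm <- shift_array(ci$nucleus, dr)
      cl[cm] <- ci$id
      nl[nm] <- ci$id
      egfp[cm] <- egfp[cm] + egfp_amp[ci$id]
    }
    geom[, , , .default_roles[["membrane"]], t] <-
      bg[["membrane"]] + amp[["membrane"]] * (cl > 0)
    geom[, , , .default_roles[["nuclei"]], t] <-
      bg[["nuclei"]] + amp[["nuclei"]] * (nl > 0)
    geom[, , , .default_roles[["egfp"]], t] <- egfp
    pch <- array(bg[["particles"]], d)
    if (nrow(parts)) {
      for (i in seq_len(nrow(parts))) {
        pos <- c(parts$z[i], parts$y[i], parts$x[i]) + dr
        rs <- render_spot_crop(d, pos, amp[["particles"]], config$spot_sigma,
                               ceiling(4 * pmax(config$spot_sigma, 0.5)))
        pch[rs$zi, rs$yi, rs$xi] <- pch[rs$zi, rs$yi, rs$xi] + rs$crop
      }
    }
    geom[, , , .default_roles[["particles"]], t] <- pch
    cell_labels[[t]] <- cl
    nucleus_labels[[t]] <- nl
    if (nrow(parts))
      ptab[[t]] <- tibble::tibble(timepoint = t, cell = parts$cell,
                                  class = factor(.class_name_map[parts$class],
                                                 levels = spatial_classes()),
                                  z = parts$z + dr[1] - 1,
                                  y = parts$y + dr[2] - 1,
                                  x = parts$x + dr[3] - 1)
    trk[[t]] <- dplyr::bind_rows(lapply(cells, function(ci) {
      co <- arrayInd(which(shift_array(ci$nucleus, dr)), d)
      tibble::tibble(timepoint = t, track_id = ci$id,
                     z = mean(co[, 1]) - 1, y = mean(co[, 2]) - 1,
                     x = mean(co[, 3]) - 1)
    }))
  }
  noisy <- apply_optics_and_noise(geom, config)
  stack <- channel_stack(noisy, spacing = sp, roles = .default_roles,
                         bit_depth = config$bit_depth)
  truth <- list(cell_labels = cell_labels, nucleus_labels = nucleus_labels,
                particles = dplyr::bind_rows(ptab),
                tracks = dplyr::bind_rows(trk),
                egfp_amplitude = egfp_amp,
                config = config)
  list(stack = stack, truth = truth)
}

# generator class-count names -> measured spatial class codes
.class_name_map <- c(inside = "inside_nucleus", boundary = "nuclear_boundary",
                     perinuclear = "perinuclear", cytoplasmic = "cytoplasmic")
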