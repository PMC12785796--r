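#' Particle detection parameters
#'
#' @param log_sigma Laplacian-of-Gaussian scale in voxels per axis
#'   `c(z, y, x)`. The default matches a diffraction-limited spot at the
#'   acquisition voxel spacing (~106 nm lateral / ~300 nm axial sigma).
#' @param threshold final detection threshold on the particle channel
#'   (voxel >= threshold is foreground); default 600.
#' @param calibration_thresholds threshold sweep used on control samples;
#'   default `c(300, 400, 500, 600, 700, 800)`.
#' @param response_floor minimum LoG response for a centroid; default 1.
#'   Spurious low-contrast maxima are harmless: they are discarded at the
#'   watershed threshold.
#' @param min_particle_volume minimum particle volume in voxels; default 1.
#' @return list of class `particle_params`.
#' @export
particle_params <- function(log_sigma = c(z = 0.5, y = 1.7, x = 1.7),
                            threshold = 600,
                            calibration_thresholds = c(300, 400, 500, 600, 700, 800),
                            response_floor = 1,
                            min_particle_volume = 1L) {
  stopifnot(all(log_sigma >= 0), threshold > 0,
            length(calibration_thresholds) >= 1, all(calibration_thresholds > 0),
            min_particle_volume >= 1)
  structure(list(log_sigma = log_sigma, threshold = threshold,
                 calibration_thresholds = sort(calibration_thresholds),
                 response_floor = response_floor,
                 min_particle_volume = as.integer(min_particle_volume)),
            class = "particle_params")
}

# negative Laplacian (6-neighbor second differences, edge-replicated) of a
# blurred volume, scale-normalized by the lateral sigma^2
log_response <- function(vol, sigma) {
  b <- gauss_blur(vol, sigma)
  d <- dim(b)
  lap <- array(0, d)
  shift <- function(a, ax, by) {
    idx <- lapply(d, seq_len)
    idx[[ax]] <- pmin(pmax(idx[[ax]] + by, 1L), d[ax])
    do.call(`[`, c(list(a), idx))
  }
  for (ax in 1:3) {
    if (d[ax] < 2L || sigma[ax] <= 0) next
    lap <- lap + shift(b, ax, 1L) + shift(b, ax, -1L) - 2 * b
  }
  -lap * max(sigma)^2
}

#' Detect particle centroids by Laplacian-of-Gaussian filtering
#'
#' Local maxima (26-connectivity, deterministic plateau tie-break) of the
#' scale-normalized LoG response above the response floor.
#'
#' @param vol 3D particle-channel volume `(z, y, x)`.
#' @param params a [particle_params()].
#' @return integer matrix with columns `z`, `y`, `x` (1-based voxel indices),
#'   ordered by linear index; zero rows when nothing is found.
#' @export
detect_centroids <- function(vol, params = particle_params()) {
  resp <- log_response(vol, params$log_sigma)
  idx <- cpp_local_max3(resp, params$response_floor)
  if (!length(idx))
    return(matrix(integer(), 0L, 3L, dimnames = list(NULL, c("z", "y", "x"))))
  out <- arrayInd(idx, dim(vol))
  colnames(out) <- c("z", "y", "x")
  out
}

#' Seeded watershed segmentation of particles
#'
#' Floods the super-level set `vol >= threshold` from the detected centroids
#' in order of decreasing intensity; each surviving seed yields one labeled
#' particle. Seeds below the threshold, and thresholded voxels unreachable
#' from any seed, are discarded.
#'
#' @param vol 3D particle-channel volume.
#' @param centroids matrix from [detect_centroids()].
#' @param threshold foreground threshold (voxel >= threshold).
#' @param params a [particle_params()] (minimum particle volume).
#' @return integer 3D label volume; labels follow seed order.
#' @export
segment_particles <- function(vol, centroids, threshold,
                              params = particle_params()) {
  d <- dim(vol)
  mask <- vol >= threshold
  seeds <- array(0L, d)
  if (nrow(centroids)) {
    centroids <- snap_seeds(vol, centroids)
    lin <- centroids[, "z"] + d[1L] * ((centroids[, "y"] - 1L) +
            d[2L] * (centroids[, "x"] - 1L))
    lin <- lin[!duplicated(lin)]
    keep <- mask[lin]
    lin <- lin[keep]
    if (length(lin)) seeds[lin] <- seq_along(lin)
  }
  lab <- cpp_watershed_seeded(vol, seeds, mask, 26L)
  lab <- filter_small_labels(lab, params$min_particle_volume)
  array(lab, d)
}

# snap each seed to the highest-intensity voxel within +/- 1 voxel: the LoG
# maximum can land one plane off the intensity peak when the axial sigma is
# below one voxel, which would park the seed under the threshold
snap_seeds <- function(vol, centroids, radius = 1L) {
  d <- dim(vol)
  for (i in seq_len(nrow(centroids))) {
    lo <- pmax(centroids[i, ] - radius, 1L)
    hi <- pmin(centroids[i, ] + radius, d)
    sub <- vol[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L]]
    j <- arrayInd(which.max(sub), hi - lo + 1L)
    centroids[i, ] <- lo + as.integer(j) - 1L
  }
  centroids
}

#' Threshold sweep report
#'
#' Particle counts at each calibration threshold using a common centroid set,
#' the control-sample calibration that fixes the final detection threshold.
#' Counts are non-increasing in the threshold (super-level sets nest).
#'
#' @param vol 3D particle-channel volume.
#' @param centroids matrix from [detect_centroids()].
#' @param thresholds calibration thresholds.
#' @param params a [particle_params()].
#' @return tibble `(threshold, n_particles)`.
#' @export
sweep_thresholds <- function(vol, centroids,
                             thresholds = particle_params()$calibration_thresholds,
                             params = particle_params()) {
  stopifnot(length(thresholds) >= 1)
  counts <- vapply(sort(thresholds), function(th) {
    lab <- segment_particles(vol, centroids, th, params)
    length(unique(lab[lab > 0L]))
  }, integer(1))
  tibble::tibble(threshold = sort(thresholds), n_particles = counts)
}

#' Nuclear ratio of a particle
#'
#' Fraction of the particle's voxel volume lying inside the nucleus mask:
#' `|particle & nucleus| / |particle|`.
#'
#' @param particle_mask,nucleus_mask logical arrays on the same grid.
#' @return NR in `[0, 1]`; `NA` with a warning for an empty particle mask.
#' @export
compute_nuclear_ratio <- function(particle_mask, nucleus_mask) {
  stopifnot(all(dim(particle_mask) == dim(nucleus_mask)))
  n <- sum(particle_mask)
  if (n == 0L) {
    warning("empty particle mask: nuclear ratio undefined")
    return(NA_real_)
  }
  sum(particle_mask & nucleus_mask) / n
}

# boundary voxels of a labeled/binary volume: foreground with a 6-neighbor
# background (or volume edge)
boundary_voxels <- function(mask) {
  d <- dim(mask)
  er <- mask
  shift_and <- function(acc, ax, by) {
    idx <- lapply(d, seq_len)
    idx[[ax]] <- idx[[ax]] + by
    pad <- idx[[ax]] < 1L | idx[[ax]] > d[ax]
    idx[[ax]] <- pmin(pmax(idx[[ax]], 1L), d[ax])
    nb <- do.call(`[`, c(list(mask), idx))
    if (any(pad)) {
      sel <- lapply(d, seq_len)
      sel[[ax]] <- which(pad)
      nb <- do.call(`[<-`, c(list(nb), sel, list(FALSE)))
    }
    acc & nb
  }
  for (ax in 1:3) for (by in c(-1L, 1L)) er <- shift_and(er, ax, by)
  mask & !er
}

#' Particle-to-nucleus distances
#'
#' `x_raw` is the anisotropic Euclidean distance (micrometers) from the
#' particle centroid to the nearest nucleus voxel, forced to 0 whenever the
#' particle overlaps the nucleus (`nr > 0`) or the centroid falls inside it.
#' `x_norm` divides by the maximum nucleus-to-membrane distance within the
#' same cell (the maximum over the cell's voxels of the distance to the
#' nucleus), clipped to `[0, 1]`.
#'
#' @param centroid numeric `(z, y, x)` voxel coordinates (1-based, may be
#'   fractional).
#' @param nucleus_mask,cell_mask logical arrays on the same grid.
#' @param spacing voxel spacing `c(z, y, x)` in micrometers.
#' @param nr the particle's nuclear ratio (default 0).
#' @param d_max optional precomputed normalization distance.
#' @return list with `x_raw`, `x_norm`, `d_max` (micrometers).
#' @export
compute_distances <- function(centroid, nucleus_mask, cell_mask, spacing,
                              nr = 0, d_max = NULL) {
  stopifnot(all(dim(nucleus_mask) == dim(cell_mask)))
  spacing <- as.numeric(spacing)
  if (is.null(d_max)) d_max <- max_nucleus_to_membrane(nucleus_mask, cell_mask, spacing)
  if (!any(nucleus_mask)) stop("empty nucleus mask")
  x_raw <- 0
  rc <- pmin(pmax(round(centroid), 1L), dim(nucleus_mask))
  inside <- nucleus_mask[rc[1L], rc[2L], rc[3L]]
  if (nr <= 0 && !inside) {
    bv <- which(boundary_voxels(nucleus_mask))
    co <- arrayInd(bv, dim(nucleus_mask))
    dz <- (co[, 1L] - centroid[1L]) * spacing[1L]
    dy <- (co[, 2L] - centroid[2L]) * spacing[2L]
    dx <- (co[, 3L] - centroid[3L]) * spacing[3L]
    x_raw <- sqrt(min(dz^2 + dy^2 + dx^2))
  }
  if (d_max <= 0) {
    if (x_raw > 0) warning("degenerate cell (d_max = 0): x_norm set to 0")
    x_norm <- 0
  } else {
    x_norm <- min(1, max(0, x_raw / d_max))
  }
  list(x_raw = x_raw, x_norm = x_norm, d_max = d_max)
}

#' Maximum nucleus-to-membrane distance within a cell
#'
#' The normalization constant of the normalized distance scale: the maximum
#' over the cell's voxels of the anisotropic distance to the nucleus.
#'
#' @inheritParams compute_distances
#' @return distance in micrometers (0 when cell and nucleus coincide).
#' @export
max_nucleus_to_membrane <- function(nucleus_mask, cell_mask, spacing) {
  if (!any(nucleus_mask) || !any(cell_mask)) return(0)
  dt <- cpp_edt3(nucleus_mask, as.numeric(spacing))
  m <- max(dt[cell_mask])
  if (!is.finite(m)) 0 else m
}

#' Assign particles to cells by centroid
#'
#' Each particle belongs to the cell containing its (rounded) centroid;
#' particles in background are excluded from per-cell analyses and tallied.
#'
#' @param particle_labels integer particle label volume.
#' @param cells integer cell label volume.
#' @return tibble `(particle, cell)` with `cell = NA` for unassigned; the
#'   attribute `n_unassigned` carries the QC tally.
#' @export
assign_particles_to_cells <- function(particle_labels, cells) {
  stopifnot(all(dim(particle_labels) == dim(cells)))
  ids <- sort(unique(particle_labels[particle_labels > 0L]))
  if (!length(ids)) {
    out <- tibble::tibble(particle = integer(), cell = integer())
    attr(out, "n_unassigned") <- 0L
    return(out)
  }
  d <- dim(particle_labels)
  cellv <- vapply(ids, function(p) {
    vox <- which(particle_labels == p)
    co <- arrayInd(vox, d)
    ce <- pmin(pmax(round(colMeans(co)), 1), d)
    as.integer(cells[ce[1L], ce[2L], ce[3L]])
  }, integer(1))
  out <- tibble::tibble(particle = ids,
                        cell = ifelse(cellv > 0L, cellv, NA_integer_))
  attr(out, "n_unassigned") <- sum(cellv == 0L)
  out
}

#' Measure detected particles
#'
#' Computes, per labeled particle: voxel volume, centroid, intensity,
#' owning cell (by centroid), nuclear ratio against the owning cell's
#' nucleus, raw and normalized distances to the nuclear boundary, and the
#' spatial class.
#'
#' @param particle_labels integer particle label volume.
#' @param vol particle-channel intensity volume.
#' @param nuclei,cells label volumes of the same timepoint.
#' @param assoc association table from [associate_nuclei_cells()].
#' @param spacing voxel spacing `c(z, y, x)` micrometers.
#' @return tibble of particle records (`particle`, `cell`, `nucleus`,
#'   `z`, `y`, `x` 0-based voxel coords, `volume_vox`, `mean_intensity`,
#'   `total_intensity`, `nr`, `x_raw_um`, `x_norm`, `spatial_class`).
#'   Unassigned particles are omitted; their count is in attribute
#'   `n_unassigned`.
#' @export
measure_particles <- function(particle_labels, vol, nuclei, cells, assoc,
                              spacing = .default_spacing) {
  d <- dim(particle_labels)
  own <- assign_particles_to_cells(particle_labels, cells)
  n_un <- attr(own, "n_unassigned")
  a <- assoc[assoc$assigned, , drop = FALSE]
  nuc_of_cell <- setNames(a$nucleus, a$cell)
  # per-cell caches
  cell_ids <- unique(own$cell[!is.na(own$cell)])
  cache <- list()
  for (cid in cell_ids) {
    nid <- nuc_of_cell[as.character(cid)]
    if (is.na(nid)) next
    nmask <- nuclei == nid
    cmask <- cells == cid
    dmax <- max_nucleus_to_membrane(nmask, cmask, spacing)
    bidx <- which(boundary_voxels(nmask))
    cache[[as.character(cid)]] <- list(nid = nid, nmask = nmask,
                                       dmax = dmax,
                                       bco = arrayInd(bidx, d))
  }
  rows <- vector("list", nrow(own))
  for (i in seq_len(nrow(own))) {
    pid <- own$particle[i]
    cid <- own$cell[i]
    if (is.na(cid)) next
    cc <- cache[[as.character(cid)]]
    if (is.null(cc)) next # cell without associated nucleus
    vox <- which(particle_labels == pid)
    co <- arrayInd(vox, d)
    cen <- colMeans(co)
    nrat <- sum(cc$nmask[vox]) / length(vox)
    if (nrat > 0) {
      x_raw <- 0
    } else {
      rc <- pmin(pmax(round(cen), 1L), d)
      if (cc$nmask[rc[1L], rc[2L], rc[3L]]) {
        x_raw <- 0
      } else {
        dz <- (cc$bco[, 1L] - cen[1L]) * spacing[1L]
        dy <- (cc$bco[, 2L] - cen[2L]) * spacing[2L]
        dx <- (cc$bco[, 3L] - cen[3L]) * spacing[3L]
        x_raw <- sqrt(min(dz^2 + dy^2 + dx^2))
      }
    }
    x_norm <- if (cc$dmax > 0) min(1, x_raw / cc$dmax) else 0
    rows[[i]] <- tibble::tibble(
      particle = pid, cell = cid, nucleus = cc$nid,
      z = cen[1L] - 1, y = cen[2L] - 1, x = cen[3L] - 1,
      volume_vox = length(vox),
      mean_intensity = mean(vol[vox]),
      total_intensity = sum(vol[vox]),
      nr = nrat, x_raw_um = x_raw, x_norm = x_norm,
      spatial_class = classify_particle(nrat, x_norm))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "n_unassigned") <- n_un
  out
}
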