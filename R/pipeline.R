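#' Run the full quantification pipeline on one time-lapse stack
#'
#' Per timepoint: planar nucleus segmentation on the nuclei-channel maximum
#' projection, 3D refinement, cell segmentation from the cytoplasmic marker,
#' nucleus-cell association, LoG particle detection with seeded watershed at
#' the detection threshold, and per-particle measurement. Nuclei are then
#' tracked across timepoints and track identities propagated to cells and
#' particles.
#'
#' @param stack a [channel_stack()].
#' @param seg_params a [segmentation_params()].
#' @param trk_params a [track_params()].
#' @param part_params a [particle_params()].
#' @param planar_backend optional planar backend override, see
#'   [segment_nuclei_planar()].
#' @return list of class `vt_result` with per-timepoint label volumes
#'   (`nuclei_by_t`, `cells_by_t`, `particles_by_t`), the association tables,
#'   the nucleus `tracks`, the cell-to-track `cell_map`, the measured
#'   `particles` table (with `track_id`) and the per-cell-timepoint `cells`
#'   aggregate table.
#' @export
process_timelapse <- function(stack,
                              seg_params = segmentation_params(),
                              trk_params = track_params(),
                              part_params = particle_params(),
                              planar_backend = NULL) {
  nt <- n_timepoints(stack)
  nuclei_by_t <- cells_by_t <- particles_by_t <- vector("list", nt)
  assoc_by_t <- vector("list", nt)
  cent <- vector("list", nt)
  meas <- vector("list", nt)
  for (t in seq_len(nt)) {
    mipn <- max_project(stack, "nuclei", t)
    lab2 <- segment_nuclei_planar(mipn, seg_params, backend = planar_backend)
    nuc3 <- refine_nuclei_3d(get_channel(stack, "nuclei", t), lab2, seg_params)
    cells3 <- segment_cells(get_channel(stack, "membrane", t), nuc3, lab2,
                            seg_params)
    assoc <- associate_nuclei_cells(nuc3, cells3)
    nuclei_by_t[[t]] <- nuc3
    cells_by_t[[t]] <- cells3
    assoc_by_t[[t]] <- assoc
    cent[[t]] <- nucleus_centroids(nuc3, t)
    pvol <- get_channel(stack, "particles", t)
    cts <- detect_centroids(pvol, part_params)
    plab <- segment_particles(pvol, cts, part_params$threshold, part_params)
    particles_by_t[[t]] <- plab
    m <- measure_particles(plab, pvol, nuc3, cells3, assoc, stack$spacing)
    if (nrow(m)) m$timepoint <- t
    meas[[t]] <- m
  }
  names(assoc_by_t) <- as.character(seq_len(nt))
  tracks <- link_nuclei(dplyr::bind_rows(cent), trk_params)
  cell_map <- relabel_cells_by_track(assoc_by_t, tracks)
  particles <- dplyr::bind_rows(meas)
  if (nrow(particles)) {
    particles <- merge(particles,
                       cell_map[, c("timepoint", "cell", "track_id")],
                       by = c("timepoint", "cell"), all.x = TRUE)
    particles <- tibble::as_tibble(
      particles[order(particles$timepoint, particles$particle), ])
  }
  cells <- aggregate_cells(particles, cell_map, nuclei_by_t, cells_by_t, stack)
  structure(list(nuclei_by_t = nuclei_by_t, cells_by_t = cells_by_t,
                 particles_by_t = particles_by_t, assoc_by_t = assoc_by_t,
                 tracks = tracks, cell_map = cell_map,
                 particles = particles, cells = cells),
            class = "vt_result")
}

# projected (y, x) centroids of 3D nucleus labels, for tracking
nucleus_centroids <- function(nuclei3d, t) {
  ids <- sort(unique(nuclei3d[nuclei3d > 0L]))
  if (!length(ids))
    return(tibble::tibble(timepoint = numeric(), label = integer(),
                          y = numeric(), x = numeric()))
  d <- dim(nuclei3d)
  rows <- lapply(ids, function(n) {
    co <- arrayInd(which(nuclei3d == n), d)
    tibble::tibble(timepoint = t, label = n,
                   y = mean(co[, 2L]), x = mean(co[, 3L]))
  })
  dplyr::bind_rows(rows)
}

#' Aggregate particle measurements to per-cell, per-timepoint records
#'
#' One row per tracked cell and timepoint: cell and nucleus volumes (voxels
#' and cubic micrometers), particle counts per spatial class, total count,
#' nuclear particle count and nuclear fraction (flagged when the cell has no
#' particles), and mean eGFP intensity over the cell mask.
#'
#' @param particles measured particle table with `track_id`.
#' @param cell_map table from [relabel_cells_by_track()].
#' @param nuclei_by_t,cells_by_t per-timepoint label volumes.
#' @param stack the source [channel_stack()] (for the eGFP channel and
#'   voxel spacing).
#' @return tibble of cell-timepoint records.
#' @export
aggregate_cells <- function(particles, cell_map, nuclei_by_t, cells_by_t,
                            stack) {
  if (!nrow(cell_map)) return(tibble::tibble())
  vox_um3 <- prod(stack$spacing)
  rows <- vector("list", nrow(cell_map))
  for (i in seq_len(nrow(cell_map))) {
    t <- cell_map$timepoint[i]
    cid <- cell_map$cell[i]
    nid <- cell_map$nucleus[i]
    cmask <- cells_by_t[[t]] == cid
    nvol <- sum(nuclei_by_t[[t]] == nid)
    egfp <- get_channel(stack, "egfp", t)
    pp <- if (nrow(particles))
      particles[!is.na(particles$track_id) &
                particles$track_id == cell_map$track_id[i] &
                particles$timepoint == t, , drop = FALSE]
    else particles
    counts <- if (nrow(pp)) table(pp$spatial_class) else
      setNames(rep(0L, 4L), spatial_classes())
    n_in <- as.integer(counts[["inside_nucleus"]])
    n_bd <- as.integer(counts[["nuclear_boundary"]])
    n_pn <- as.integer(counts[["perinuclear"]])
    n_cy <- as.integer(counts[["cytoplasmic"]])
    total <- n_in + n_bd + n_pn + n_cy
    rows[[i]] <- tibble::tibble(
      timepoint = t, track_id = cell_map$track_id[i], cell = cid,
      nucleus = nid,
      cell_volume_vox = sum(cmask), cell_volume_um3 = sum(cmask) * vox_um3,
      nucleus_volume_vox = nvol, nucleus_volume_um3 = nvol * vox_um3,
      n_inside = n_in, n_boundary = n_bd, n_perinuclear = n_pn,
      n_cytoplasmic = n_cy, n_total = total,
      n_nuclear = n_in + n_bd,
      nuclear_fraction = if (total > 0) (n_in + n_bd) / total else 0,
      nuclear_fraction_defined = total > 0,
      mean_egfp = mean(egfp[cmask]))
  }
  dplyr::bind_rows(rows)
}

#' @export
print.vt_result <- function(x, ...) {
  cat(sprintf("vt_result: %d timepoint(s), %d track(s), %d particle(s) measured\n",
              length(x$nuclei_by_t),
              length(unique(x$tracks$track_id)),
              nrow(x$particles)))
  invisible(x)
}

#' Attach condition/ROI metadata to result tables
#'
#' @param result a `vt_result`.
#' @param condition,roi experiment metadata labels.
#' @param timepoint_hours mapping from stack timepoint index to hours
#'   post-VES; default `c(4, 6, 8, 10, 12)`.
#' @return the result with annotated `cells` and `particles` tables.
#' @export
annotate_result <- function(result, condition, roi,
                            timepoint_hours = c(4, 6, 8, 10, 12)) {
  stamp <- function(tab) {
    if (!nrow(tab)) return(tab)
    tab$condition <- condition
    tab$roi <- roi
    tab$timepoint_h <- timepoint_hours[tab$timepoint]
    tab
  }
  result$cells <- stamp(result$cells)
  result$particles <- stamp(result$particles)
  result
}
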