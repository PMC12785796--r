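#' Tracking parameters
#'
#' @param search_range maximum centroid displacement (XY pixels of the
#'   projected image) allowed between linked observations; default 400.
#' @param memory maximum number of consecutive missed timepoints before a
#'   track is terminated; default 3.
#' @return list of class `track_params`.
#' @export
track_params <- function(search_range = 400, memory = 3L) {
  stopifnot(search_range > 0, memory >= 0)
  structure(list(search_range = search_range, memory = as.integer(memory)),
            class = "track_params")
}

#' Minimum-cost linear assignment (Hungarian / Jonker-Volgenant potentials)
#'
#' Solves the square assignment problem minimizing the total cost. O(n^3).
#'
#' @param cost numeric cost matrix, `nrow <= ncol`; entries may be large
#'   finite penalties but not `Inf`.
#' @return integer vector: `result[i]` is the column assigned to row `i`.
#' @export
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m, all(is.finite(cost)))
  # indices 1..m+1 where 1 is the virtual column
  u <- numeric(n + 1L); v <- numeric(m + 1L)
  p <- integer(m + 1L); way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(Inf, m + 1L)
    used <- logical(m + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf; j1 <- 0L
      for (j in 2L:(m + 1L)) {
        if (used[j]) next
        cur <- cost[i0, j - 1L] - u[i0 + 0L] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in 1L:(m + 1L)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  out <- integer(n)
  for (j in 2L:(m + 1L)) if (p[j] > 0L) out[p[j]] <- j - 1L
  out
}

# one frame-pair LAP link with no-link penalty (Jaqaman-style square matrix):
# rows = active tracks, cols = detections; d_ij if <= search_range else BIG;
# diagonal no-link blocks at cost = search_range.
link_frame_pair <- function(track_pos, det_pos, search_range) {
  nt <- nrow(track_pos); nd <- nrow(det_pos)
  if (nt == 0L || nd == 0L)
    return(list(track_to_det = rep(NA_integer_, nt)))
  d <- sqrt(outer(track_pos[, 1L], det_pos[, 1L], "-")^2 +
            outer(track_pos[, 2L], det_pos[, 2L], "-")^2)
  BIG <- 1e9
  A <- matrix(BIG, nt + nd, nd + nt)
  A[seq_len(nt), seq_len(nd)] <- ifelse(d <= search_range, d, BIG)
  for (i in seq_len(nt)) A[i, nd + i] <- search_range
  for (j in seq_len(nd)) A[nt + j, j] <- search_range
  A[nt + seq_len(nd), nd + seq_len(nt)] <- t(A[seq_len(nt), seq_len(nd)]) * 0
  asn <- solve_assignment(A)
  t2d <- rep(NA_integer_, nt)
  for (i in seq_len(nt)) if (asn[i] <= nd && d[i, asn[i]] <= search_range)
    t2d[i] <- asn[i]
  list(track_to_det = t2d)
}

#' Link nucleus centroids across timepoints
#'
#' Frame-to-frame optimal assignment (minimum total displacement subject to
#' the search-range bound), with gap closing: an object missing for at most
#' `memory` consecutive timepoints is re-linked to its track; unmatched
#' detections open new tracks. New track ids are assigned in (timepoint,
#' label) order, so the result is deterministic.
#'
#' @param centroids tibble/data.frame with columns `timepoint`, `label`,
#'   `y`, `x` (projected centroid coordinates in pixels).
#' @param params a [track_params()].
#' @return tibble `(timepoint, label, track_id, y, x)`.
#' @export
link_nuclei <- function(centroids, params = track_params()) {
  stopifnot(all(c("timepoint", "label", "y", "x") %in% names(centroids)))
  centroids <- centroids[order(centroids$timepoint, centroids$label), ]
  tps <- sort(unique(centroids$timepoint))
  if (!length(tps)) {
    return(tibble::tibble(timepoint = integer(), label = integer(),
                          track_id = integer(), y = numeric(), x = numeric()))
  }
  # active tracks: id, y, x, last_t
  act <- data.frame(id = integer(), y = numeric(), x = numeric(),
                    last_t = numeric())
  next_id <- 1L
  out <- vector("list", length(tps))
  for (k in seq_along(tps)) {
    t <- tps[k]
    det <- centroids[centroids$timepoint == t, , drop = FALSE]
    cand <- act[(t - act$last_t) <= (params$memory + 1L), , drop = FALSE]
    assigned_det <- rep(NA_integer_, nrow(det)) # track id per detection
    if (nrow(cand) && nrow(det)) {
      lk <- link_frame_pair(as.matrix(cand[, c("y", "x")]),
                            as.matrix(det[, c("y", "x")]),
                            params$search_range)
      for (i in seq_len(nrow(cand))) {
        j <- lk$track_to_det[i]
        if (!is.na(j)) assigned_det[j] <- cand$id[i]
      }
    }
    for (j in seq_len(nrow(det))) {
      if (is.na(assigned_det[j])) {
        assigned_det[j] <- next_id
        next_id <- next_id + 1L
      }
    }
    if (nrow(det)) {
      upd <- data.frame(id = assigned_det, y = det$y, x = det$x, last_t = t)
      act <- act[!(act$id %in% assigned_det), , drop = FALSE]
      act <- rbind(act, upd)
      out[[k]] <- tibble::tibble(timepoint = det$timepoint, label = det$label,
                                 track_id = assigned_det, y = det$y, x = det$x)
    }
  }
  dplyr::bind_rows(out)
}

#' Relabel cells by their nucleus track
#'
#' Propagates nucleus track identities to cells so that a cell carries its
#' nucleus's track id at every timepoint. Cells matched by two nuclei with
#' different tracks at the same timepoint are flagged multi-nucleated and
#' excluded with a warning; cells whose nucleus is untracked at a timepoint
#' are dropped at that timepoint.
#'
#' @param assoc_by_t named list (one element per timepoint, names = timepoint
#'   values) of association tables from [associate_nuclei_cells()].
#' @param tracks track table from [link_nuclei()].
#' @return tibble `(timepoint, nucleus, cell, track_id)`, one row per
#'   retained cell-timepoint.
#' @export
relabel_cells_by_track <- function(assoc_by_t, tracks) {
  rows <- lapply(names(assoc_by_t), function(tn) {
    t <- as.numeric(tn)
    a <- assoc_by_t[[tn]]
    a <- a[a$assigned, , drop = FALSE]
    if (!nrow(a)) return(NULL)
    tr <- tracks[tracks$timepoint == t, c("label", "track_id")]
    m <- merge(a, tr, by.x = "nucleus", by.y = "label")
    if (!nrow(m)) return(NULL)
    # multi-nucleated conflict: one cell, > 1 distinct track
    ncell <- tapply(m$track_id, m$cell, function(v) length(unique(v)))
    bad <- as.integer(names(ncell)[ncell > 1L])
    if (length(bad)) {
      warning(sprintf("timepoint %s: %d multi-nucleated cell(s) excluded", tn,
                      length(bad)))
      m <- m[!(m$cell %in% bad), , drop = FALSE]
    }
    tibble::tibble(timepoint = t, nucleus = m$nucleus, cell = m$cell,
                   track_id = m$track_id)
  })
  dplyr::bind_rows(rows)
}

#' Apply a label-to-track mapping to a label volume
#'
#' @param labels integer label volume.
#' @param map data.frame with columns `cell` (old label) and `track_id`.
#' @return relabeled volume; labels absent from the map become background.
#' @export
relabel_volume <- function(labels, map) {
  out <- array(0L, dim(labels))
  for (i in seq_len(nrow(map)))
    out[labels == map$cell[i]] <- map$track_id[i]
  out
}
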