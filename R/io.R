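#' Write a channel stack to disk
#'
#' Writes a multi-page TIFF (page order T-major, then channel, then z) plus
#' a JSON sidecar (`<path>.json`) holding axes, shape, voxel spacing,
#' channel roles and bit depth, so a write/read round trip is
#' voxel-identical.
#'
#' @param stack a [channel_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack$data)
  maxval <- 2^stack$bit_depth - 1
  pages <- list()
  k <- 1L
  for (t in seq_len(d[5L])) for (ch in seq_len(d[4L])) for (z in seq_len(d[1L])) {
    pages[[k]] <- matrix(stack$data[z, , , ch, t], d[2L], d[3L]) / maxval
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth,
                  compression = "deflate")
  meta <- list(axes = "TCZYX",
               shape = as.list(c(T = d[5L], C = d[4L], Z = d[1L], Y = d[2L],
                                 X = d[3L])),
               spacing_um = as.list(stack$spacing),
               roles = as.list(stack$roles),
               bit_depth = stack$bit_depth)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a channel stack from disk
#'
#' Reads a multi-page TIFF written by [write_stack()] (or any T/C/Z-ordered
#' plain TIFF with the JSON sidecar). Voxel spacing and channel roles come
#' from the sidecar; a missing sidecar requires the `spacing`/`roles`/`shape`
#' overrides and logs a warning.
#'
#' @param path TIFF path.
#' @param spacing,roles,shape,bit_depth overrides used (with a warning) when
#'   the sidecar is absent; `shape` must then be `c(T=, C=, Z=)`.
#' @return a [channel_stack()].
#' @export
read_stack <- function(path, spacing = NULL, roles = NULL, shape = NULL,
                       bit_depth = 16L) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!identical(meta$axes, "TCZYX"))
      stop("format error: unsupported axis order '", meta$axes,
           "' (axis T/C/Z/Y/X unresolvable)")
    sh <- unlist(meta$shape)
    spacing <- unlist(meta$spacing_um)[c("z", "y", "x")]
    roles <- vapply(meta$roles, as.integer, integer(1))
    bit_depth <- meta$bit_depth
  } else {
    if (is.null(spacing) || is.null(shape))
      stop("format error: no sidecar metadata and no spacing/shape override ",
           "(axes unresolvable)")
    warning("sidecar metadata missing for ", path,
            ": using spacing/shape overrides")
    sh <- c(shape, Y = nrow(pages[[1L]]), X = ncol(pages[[1L]]))
    if (is.null(roles)) roles <- .default_roles
  }
  nT <- sh[["T"]]; nC <- sh[["C"]]; nZ <- sh[["Z"]]
  if (length(pages) != nT * nC * nZ)
    stop("format error: page count ", length(pages), " does not match T*C*Z")
  maxval <- 2^bit_depth - 1
  data <- array(0, c(nZ, sh[["Y"]], sh[["X"]], nC, nT))
  k <- 1L
  for (t in seq_len(nT)) for (ch in seq_len(nC)) for (z in seq_len(nZ)) {
    data[z, , , ch, t] <- round(pages[[k]] * maxval)
    k <- k + 1L
  }
  channel_stack(data, spacing = spacing, roles = roles, bit_depth = bit_depth)
}

#' Write / read an integer label volume as 16-bit TIFF
#'
#' @param labels integer 3D array `(z, y, x)` with labels below 65536.
#' @param path file path.
#' @return `path` / the label array.
#' @export
write_labels <- function(labels, path) {
  stopifnot(max(labels) < 65536)
  d <- dim(labels)
  pages <- lapply(seq_len(d[1L]), function(z)
    matrix(labels[z, , ], d[2L], d[3L]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "deflate")
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(length(pages), nrow(pages[[1L]]), ncol(pages[[1L]]))
  out <- array(0L, d)
  for (z in seq_len(d[1L])) out[z, , ] <- as.integer(round(pages[[z]] * 65535))
  out
}

# columns every per-cell measurement file must carry
.measurement_schema <- c("condition", "roi", "timepoint", "track_id")

#' Merge per-ROI, per-timepoint measurement files
#'
#' Combines individual CSV measurement files into one long-format dataset
#' with standardized condition/ROI/timepoint columns. Timepoint tokens such
#' as `"4h"`, `"t06"` or `"10 h"` are parsed to integer hours post-VES.
#' Duplicate (condition, ROI, timepoint, track) keys are an error.
#'
#' @param files character vector of CSV paths sharing the record schema.
#' @param timepoint_levels allowed hour values; default `c(4, 6, 8, 10, 12)`.
#' @return a tibble, canonically sorted; row count equals the sum of inputs.
#' @export
merge_measurements <- function(files, timepoint_levels = c(4, 6, 8, 10, 12)) {
  stopifnot(length(files) >= 1)
  tabs <- lapply(files, function(f) {
    tab <- read.csv(f, stringsAsFactors = FALSE)
    missing_cols <- setdiff(.measurement_schema, names(tab))
    if (length(missing_cols))
      stop("schema mismatch in ", f, ": missing columns ",
           paste(missing_cols, collapse = ", "))
    tab
  })
  all_cols <- Reduce(union, lapply(tabs, names))
  for (i in seq_along(tabs)) {
    miss <- setdiff(all_cols, names(tabs[[i]]))
    if (length(miss))
      stop("schema mismatch in ", files[i], ": missing columns ",
           paste(miss, collapse = ", "))
  }
  out <- dplyr::bind_rows(tabs)
  out$timepoint <- parse_timepoint(out$timepoint, timepoint_levels)
  key <- paste(out$condition, out$roi, out$timepoint, out$track_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (condition, ROI, timepoint, cell) keys in merged dataset")
  out <- out[order(out$condition, out$roi, out$timepoint, out$track_id), ]
  tibble::as_tibble(out)
}

#' Parse timepoint tokens to hours post-VES
#'
#' @param x vector of tokens (`"4h"`, `"t06"`, `6`, ...).
#' @param levels allowed hour values.
#' @return integer hours.
#' @export
parse_timepoint <- function(x, levels = c(4, 6, 8, 10, 12)) {
  h <- suppressWarnings(as.integer(gsub("[^0-9]", "", as.character(x))))
  bad <- is.na(h) | !(h %in% levels)
  if (any(bad))
    stop("unparseable or out-of-range timepoint token(s): ",
         paste(unique(x[bad]), collapse = ", "))
  h
}

#' Apply a manual curation list
#'
#' Removes all records (cell-level rows and the excluded cells' particles)
#' for curated-out cells at every timepoint; the expert curation step that
#' excludes mitotic, apoptotic or poorly segmented cells. Idempotent.
#'
#' @param cells per-cell table with `condition`, `roi`, `track_id`.
#' @param particles per-particle table with the same keys (may be `NULL`).
#' @param curation tibble `(condition, roi, track_id, reason)` with reason in
#'   mitosis / apoptosis / segmentation_error / other.
#' @return list with filtered `cells`, `particles` and an `audit` tibble of
#'   removal counts by reason; unknown keys produce a warning, not an error.
#' @export
apply_curation <- function(cells, particles = NULL, curation) {
  if (!nrow(curation)) {
    return(list(cells = cells, particles = particles,
                audit = tibble::tibble(reason = character(),
                                       cells_removed = integer(),
                                       particles_removed = integer())))
  }
  stopifnot(all(c("condition", "roi", "track_id", "reason") %in% names(curation)))
  keyc <- function(d) paste(d$condition, d$roi, d$track_id, sep = "\r")
  ck <- keyc(cells)
  audit <- vector("list", 0L)
  for (i in seq_len(nrow(curation))) {
    k <- keyc(curation[i, ])
    hit <- ck == k
    if (!any(hit))
      warning("curation key not found in dataset: ",
              gsub("\r", "/", k))
    np <- 0L
    if (!is.null(particles)) {
      ph <- keyc(particles) == k
      np <- sum(ph)
      particles <- particles[!ph, , drop = FALSE]
    }
    audit[[i]] <- tibble::tibble(reason = curation$reason[i],
                                 cells_removed = sum(hit),
                                 particles_removed = np)
    cells <- cells[!hit, , drop = FALSE]
    ck <- ck[!hit]
  }
  audit <- dplyr::bind_rows(audit)
  audit <- dplyr::summarise(dplyr::group_by(audit, .data$reason),
                            cells_removed = sum(.data$cells_removed),
                            particles_removed = sum(.data$particles_removed),
                            .groups = "drop")
  list(cells = cells, particles = particles, audit = audit)
}

#' Render per-timepoint QC overlays
#'
#' For each timepoint: the nuclei-channel maximum projection with cell and
#' nucleus contours, particle markers colored by spatial class, and the
#' track id printed at each nucleus centroid. These are the images the
#' expert curates.
#'
#' @param stack a [channel_stack()].
#' @param nuclei_by_t,cells_by_t lists of label volumes per timepoint.
#' @param particles per-particle table with `timepoint`, `y`, `x`,
#'   `spatial_class` (0-based voxel coordinates), or `NULL`.
#' @param tracks track table (`timepoint`, `y`, `x`, `track_id`), or `NULL`.
#' @param out_dir output directory for `overlay_t<k>.png`.
#' @return character vector of written file paths.
#' @export
render_qc_overlays <- function(stack, nuclei_by_t, cells_by_t,
                               particles = NULL, tracks = NULL, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  nt <- n_timepoints(stack)
  cls_col <- setNames(c("#d62728", "#ff7f0e", "#e6e600", "#1f77b4"),
                      spatial_classes())
  paths <- character(nt)
  for (t in seq_len(nt)) {
    m <- max_project(stack, "nuclei", t)
    m <- m / max(m, 1)
    f <- file.path(out_dir, sprintf("overlay_t%02d.png", t))
    grDevices::png(f, width = ncol(m), height = nrow(m))
    op <- par(mar = c(0, 0, 0, 0))
    image(t(m)[, nrow(m):1], col = gray(seq(0, 1, length.out = 256)),
          axes = FALSE, useRaster = TRUE)
    # contours as boundary points in normalized plot coordinates
    draw_contour <- function(lab, col) {
      if (is.null(lab) || !any(lab > 0)) return(invisible())
      fp <- matrix(mip((lab > 0) * 1) > 0, dim(lab)[2L], dim(lab)[3L])
      edge <- fp & !(fp &
        rbind(FALSE, fp[-nrow(fp), ]) & rbind(fp[-1, ], FALSE) &
        cbind(FALSE, fp[, -ncol(fp)]) & cbind(fp[, -1], FALSE))
      idx <- which(edge, arr.ind = TRUE)
      points((idx[, 2] - 1) / (ncol(fp) - 1),
             1 - (idx[, 1] - 1) / (nrow(fp) - 1), pch = ".", col = col)
    }
    draw_contour(cells_by_t[[t]], "#00ff00")
    draw_contour(nuclei_by_t[[t]], "#00ccff")
    if (!is.null(particles) && nrow(particles)) {
      pp <- particles[particles$timepoint == t, , drop = FALSE]
      if (nrow(pp))
        points(pp$x / (ncol(m) - 1), 1 - pp$y / (nrow(m) - 1), pch = 4,
               col = cls_col[as.character(pp$spatial_class)], cex = 0.8)
    }
    if (!is.null(tracks) && nrow(tracks)) {
      tt <- tracks[tracks$timepoint == t, , drop = FALSE]
      if (nrow(tt))
        text(tt$x / (ncol(m) - 1), 1 - tt$y / (nrow(m) - 1),
             labels = tt$track_id, col = "#ffff00", cex = 1.2)
    }
    par(op)
    grDevices::dev.off()
    paths[t] <- f
  }
  paths
}
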