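#' Segmentation parameters
#'
#' Parameters of the nucleus/cell segmentation chain: planar instance
#' segmentation on the maximum-intensity projection, fused with a 3D
#' threshold-based refinement (local-mean downscale, Gaussian blur,
#' Otsu threshold, resize, hole filling along z).
#'
#' @param gaussian_sigma blur sigma (pixels) of the refinement chain; default 3.
#' @param downscale_factor local-mean downscale factor in Y/X; default 4.
#' @param min_nucleus_volume minimum 3D nucleus volume in voxels; objects
#'   strictly below this are excluded. Default 10000.
#' @param min_cell_volume minimum 3D cell volume in voxels; default 10000,
#'   mirroring the nucleus filter.
#' @param planar_sigma blur sigma for the classical planar backend; default 3.
#' @return list of class `segmentation_params`.
#' @export
segmentation_params <- function(gaussian_sigma = 3,
                                downscale_factor = 4L,
                                min_nucleus_volume = 10000L,
                                min_cell_volume = 10000L,
                                planar_sigma = 3) {
  stopifnot(gaussian_sigma > 0, downscale_factor >= 1,
            min_nucleus_volume >= 0, min_cell_volume >= 0, planar_sigma > 0)
  structure(list(gaussian_sigma = gaussian_sigma,
                 downscale_factor = as.integer(downscale_factor),
                 min_nucleus_volume = min_nucleus_volume,
                 min_cell_volume = min_cell_volume,
                 planar_sigma = planar_sigma),
            class = "segmentation_params")
}

#' Otsu threshold of a numeric image or volume
#'
#' Gray level maximizing the between-class variance of the intensity
#' histogram. Integer-valued data with at most `levels` distinct values are
#' thresholded on their exact gray levels; otherwise intensities are binned.
#' Foreground is `x > threshold`.
#'
#' @param x numeric vector, matrix or array.
#' @param levels number of histogram bins for non-integer data; default 256.
#' @return threshold on the intensity scale of `x`, or `NA` when the input is
#'   constant (threshold undefined).
#' @export
otsu_threshold <- function(x, levels = 256L) {
  v <- as.vector(x)
  r <- range(v)
  if (!is.finite(r[1]) || r[1] == r[2]) return(NA_real_)
  ux <- sort(unique(v))
  if (length(ux) <= levels) {
    counts <- tabulate(match(v, ux), nbins = length(ux))
    vals <- ux
  } else {
    breaks <- seq(r[1], r[2], length.out = levels + 1L)
    bin <- findInterval(v, breaks, rightmost.closed = TRUE)
    counts <- tabulate(bin, nbins = levels)
    vals <- (breaks[-1] + breaks[-length(breaks)]) / 2
  }
  otsu_from_counts(counts, vals)
}

#' Otsu threshold from a histogram
#'
#' @param counts non-negative counts per gray level.
#' @param values gray level of each bin (ascending).
#' @return the gray level ending the background class at the between-class
#'   variance maximum (first maximizer on ties).
#' @export
otsu_from_counts <- function(counts, values) {
  stopifnot(length(counts) == length(values), all(counts >= 0))
  p <- counts / sum(counts)
  w0 <- cumsum(p)
  m <- cumsum(p * values)
  mT <- m[length(m)]
  w1 <- 1 - w0
  sb <- rep(-Inf, length(p))
  ok <- w0 > 0 & w1 > 0
  sb[ok] <- (mT * w0[ok] - m[ok])^2 / (w0[ok] * w1[ok])
  values[which.max(sb)]
}

# ---- resampling helpers ----------------------------------------------------

# block-mean downscale of a 2D matrix by integer factor f (edge-replicated
# padding when the size is not a multiple of f)
downscale_local_mean <- function(m, f) {
  f <- as.integer(f)
  if (f == 1L) return(m)
  pad <- function(mm, n, axis) {
    extra <- (ceiling(n / f) * f) - n
    if (extra == 0L) return(mm)
    if (axis == 1L) mm[c(seq_len(n), rep(n, extra)), , drop = FALSE]
    else mm[, c(seq_len(n), rep(n, extra)), drop = FALSE]
  }
  m <- pad(m, nrow(m), 1L)
  m <- pad(m, ncol(m), 2L)
  red1 <- function(mm) { # mean over blocks of f along rows
    a <- array(mm, c(f, nrow(mm) / f, ncol(mm)))
    matrix(colMeans(a), nrow(mm) / f, ncol(mm))
  }
  t(red1(t(red1(m))))
}

# nearest-neighbor upscale of a 2D matrix back to (ny, nx)
upscale_nearest <- function(m, f, ny, nx) {
  m[rep(seq_len(nrow(m)), each = f)[seq_len(ny)],
    rep(seq_len(ncol(m)), each = f)[seq_len(nx)], drop = FALSE]
}

#' Fill holes along the z-dimension
#'
#' Per (y, x) column, background runs bounded above and below by foreground
#' are set to foreground. In-plane holes are untouched.
#'
#' @param mask logical 3D array `(z, y, x)`.
#' @return logical array of the same shape.
#' @export
fill_holes_z <- function(mask) {
  d <- dim(mask)
  nz <- d[1L]
  if (nz == 1L) return(mask)
  M <- matrix(mask, nz, d[2L] * d[3L])
  up <- M
  for (z in 2:nz) up[z, ] <- up[z, ] | up[z - 1L, ]
  dn <- M
  for (z in (nz - 1L):1L) dn[z, ] <- dn[z, ] | dn[z + 1L, ]
  array(up & dn, d)
}

#' Remove small labeled objects
#'
#' Labels whose total voxel volume is strictly below `min_volume` are set to
#' background. This is the "small objects with a volume below 10,000 pixels
#' were excluded" rule: an object of exactly `min_volume` voxels is kept.
#'
#' @param labels integer label array (0 = background).
#' @param min_volume minimum voxel volume to keep.
#' @return label array with small objects removed.
#' @export
filter_small_labels <- function(labels, min_volume) {
  if (min_volume <= 1 || !any(labels > 0)) return(labels)
  counts <- tabulate(labels[labels > 0])
  drop <- which(counts > 0 & counts < min_volume)
  if (length(drop)) labels[labels %in% drop] <- 0L
  labels
}

# shared 3D threshold-refinement chain: per-slice local-mean downscale,
# in-plane Gaussian blur, global Otsu, nearest-neighbor resize, z hole fill
threshold_refine_mask <- function(vol, params) {
  d <- dim(vol)
  f <- params$downscale_factor
  nyd <- ceiling(d[2L] / f); nxd <- ceiling(d[3L] / f)
  dvol <- array(0, c(d[1L], nyd, nxd))
  for (z in seq_len(d[1L]))
    dvol[z, , ] <- downscale_local_mean(matrix(vol[z, , ], d[2L], d[3L]), f)
  b <- gauss_blur(dvol, c(0, params$gaussian_sigma, params$gaussian_sigma))
  thr <- otsu_threshold(b)
  if (is.na(thr)) {
    warning("constant volume: Otsu threshold undefined, returning empty mask")
    return(array(FALSE, d))
  }
  mk <- b > thr
  mask <- array(FALSE, d)
  for (z in seq_len(d[1L]))
    mask[z, , ] <- upscale_nearest(matrix(mk[z, , ], nyd, nxd), f, d[2L], d[3L])
  fill_holes_z(mask)
}

#' Planar nucleus instance segmentation on a maximum-intensity projection
#'
#' The default classical backend blurs the projection, thresholds it with
#' Otsu's method, fills holes, and splits touching nuclei by a topographic
#' watershed on the Euclidean distance map. The backend is pluggable: pass a
#' function `f(mip) -> integer label matrix` to substitute an external
#' instance-segmentation model.
#'
#' @param mip_img 2D numeric matrix `(y, x)`.
#' @param params a [segmentation_params()].
#' @param backend `NULL` for the classical backend, or a function.
#' @return integer label matrix (0 = background); all zeros for a blank image.
#' @export
segment_nuclei_planar <- function(mip_img, params = segmentation_params(),
                                  backend = NULL) {
  stopifnot(is.matrix(mip_img))
  if (!is.null(backend)) {
    lab <- backend(mip_img)
    storage.mode(lab) <- "integer"
    return(lab)
  }
  if (diff(range(mip_img)) == 0)
    return(matrix(0L, nrow(mip_img), ncol(mip_img)))
  b <- gauss_blur(mip_img, c(params$planar_sigma, params$planar_sigma))
  thr <- otsu_threshold(b)
  fg <- b > thr
  if (!any(fg)) return(matrix(0L, nrow(mip_img), ncol(mip_img)))
  fg <- EBImage::fillHull(fg)
  dm <- EBImage::distmap(fg)
  ws <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  lab <- matrix(as.integer(EBImage::imageData(ws)), nrow(mip_img), ncol(mip_img))
  lab
}

#' 3D refinement of planar nucleus labels
#'
#' Builds a 3D nucleus mask from the nuclei channel via the threshold
#' refinement chain, intersects it with the planar label footprint extruded
#' along z, transfers to each 3D connected region the planar label covering
#' the majority of its voxels, and removes objects below the minimum volume.
#'
#' @param vol 3D nuclei-channel volume `(z, y, x)`.
#' @param labels2d planar instance labels aligned to the `(y, x)` grid.
#' @param params a [segmentation_params()].
#' @return integer 3D label volume carrying the planar label ids.
#' @export
refine_nuclei_3d <- function(vol, labels2d, params = segmentation_params()) {
  d <- dim(vol)
  stopifnot(all(dim(labels2d) == d[2:3]))
  mask <- threshold_refine_mask(vol, params)
  nz <- d[1L]
  lab2_ext <- array(rep(as.integer(labels2d), each = nz), d)
  mask <- mask & (lab2_ext > 0L)
  out <- array(0L, d)
  if (any(mask)) {
    comps <- cpp_label3(mask, 26L)
    idx <- which(comps > 0L)
    maj <- vapply(split(lab2_ext[idx], comps[idx]), function(v) {
      tt <- tabulate(v)
      which.max(tt)
    }, integer(1))
    lut <- integer(max(comps))
    lut[as.integer(names(maj))] <- maj
    out[idx] <- lut[comps[idx]]
  }
  filter_small_labels(out, params$min_nucleus_volume)
}

#' 3D cell segmentation from the cytoplasmic marker channel
#'
#' Applies the same threshold refinement chain to the membrane/cytoplasmic
#' channel, partitions the planar footprint among nuclei by a seeded
#' watershed on the footprint's distance map, extrudes the partition through
#' the 3D mask, and force-unions each nucleus into its cell so that the
#' nucleus-inside-cell invariant holds. Cells without any nucleus are
#' removed, then the minimum-volume filter is applied.
#'
#' @param vol 3D membrane-channel volume `(z, y, x)`.
#' @param nuclei3d 3D nucleus label volume (output of [refine_nuclei_3d()]).
#' @param labels2d planar nucleus labels used as watershed seeds.
#' @param params a [segmentation_params()].
#' @return integer 3D cell label volume; cell labels equal their nucleus's id.
#' @export
segment_cells <- function(vol, nuclei3d, labels2d,
                          params = segmentation_params()) {
  d <- dim(vol)
  nz <- d[1L]
  mask3 <- threshold_refine_mask(vol, params) | (nuclei3d > 0L)
  fg2 <- matrix(mip(mask3 * 1) > 0, d[2L], d[3L])
  seeds2 <- labels2d
  m2 <- fg2 | seeds2 > 0L # seeds kept even where the membrane mask misses them
  dm2 <- as.matrix(EBImage::distmap(m2))
  seeds3 <- array(as.integer(seeds2), c(1L, d[2L], d[3L]))
  topo3 <- array(as.numeric(dm2), c(1L, d[2L], d[3L]))
  m3 <- array(m2, c(1L, d[2L], d[3L]))
  cells2 <- matrix(cpp_watershed_seeded(topo3, seeds3, m3, 26L), d[2L], d[3L])
  cells3 <- array(rep(as.integer(cells2), each = nz), d)
  cells3[!mask3] <- 0L
  nin <- nuclei3d > 0L
  cells3[nin] <- nuclei3d[nin]
  keep <- sort(unique(nuclei3d[nin]))
  cells3[!(cells3 %in% c(0L, keep))] <- 0L
  filter_small_labels(cells3, params$min_cell_volume)
}

#' Associate nuclei with cells
#'
#' Maps each nucleus to the cell with maximal voxel overlap; nuclei without
#' any cell overlap are flagged unassigned and excluded downstream.
#'
#' @param nuclei,cells integer label volumes on the same grid.
#' @return tibble with columns `nucleus`, `cell` (`NA` if unassigned),
#'   `overlap` (voxels) and `assigned`.
#' @export
associate_nuclei_cells <- function(nuclei, cells) {
  stopifnot(all(dim(nuclei) == dim(cells)))
  idx <- which(nuclei > 0L)
  nl <- sort(unique(nuclei[idx]))
  if (!length(nl))
    return(tibble::tibble(nucleus = integer(), cell = integer(),
                          overlap = integer(), assigned = logical()))
  rows <- lapply(nl, function(n) {
    cv <- cells[idx[nuclei[idx] == n]]
    cv <- cv[cv > 0L]
    if (!length(cv))
      return(tibble::tibble(nucleus = n, cell = NA_integer_,
                            overlap = 0L, assigned = FALSE))
    tt <- tabulate(cv)
    best <- which.max(tt) # lowest cell id on ties
    tibble::tibble(nucleus = n, cell = as.integer(best),
                   overlap = tt[best], assigned = TRUE)
  })
  dplyr::bind_rows(rows)
}
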