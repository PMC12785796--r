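#' Multi-channel 3D time-lapse container
#'
#' A `channel_stack` holds a 5D intensity array together with its physical
#' voxel spacing and a channel-role map. The array is stored with dimensions
#' `(z, y, x, channel, time)`; all exported tables use 0-based `(z, y, x)`
#' voxel indices plus physical micrometer columns.
#'
#' @param data 5D numeric array with dim `(z, y, x, channel, time)`, or a 4D
#'   array `(z, y, x, channel)` for a single timepoint.
#' @param spacing named numeric vector `c(z=, y=, x=)`, micrometers per voxel.
#'   Defaults to the acquisition geometry 0.762 / 0.0618 / 0.0618.
#' @param roles named integer vector mapping the roles
#'   `membrane`, `particles`, `egfp`, `nuclei` to channel indices (1-based).
#' @param bit_depth intensity quantization of the source data (8 or 16).
#'
#' @return An object of class `channel_stack`.
#' @export
channel_stack <- function(data,
                          spacing = .default_spacing,
                          roles = .default_roles,
                          bit_depth = 16L) {
  if (length(dim(data)) == 4L) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 5L)
  if (any(data < 0)) stop("intensities must be non-negative")
  spacing <- spacing[c("z", "y", "x")]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("voxel spacing must be positive")
  needed <- c("membrane", "particles", "egfp", "nuclei")
  if (!all(needed %in% names(roles)))
    stop("channel roles must cover: ", paste(needed, collapse = ", "))
  if (any(roles[needed] > dim(data)[4L]))
    stop("channel role map refers to channel beyond the stack's channel axis")
  structure(
    list(data = data, spacing = spacing, roles = roles,
         bit_depth = as.integer(bit_depth)),
    class = "channel_stack"
  )
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("channel_stack: %d timepoint(s), %d channel(s), volume %dx%dx%d (z,y,x)\n",
              d[5], d[4], d[1], d[2], d[3]))
  cat(sprintf("  spacing (um): z=%.4g y=%.4g x=%.4g; bit depth %d\n",
              x$spacing["z"], x$spacing["y"], x$spacing["x"], x$bit_depth))
  cat("  roles: ", paste(sprintf("%s=%d", names(x$roles), x$roles), collapse = ", "), "\n")
  invisible(x)
}

#' Number of timepoints in a stack
#' @param stack a [channel_stack()].
#' @return integer count.
#' @export
n_timepoints <- function(stack) dim(stack$data)[5L]

#' Extract one channel volume at one timepoint
#'
#' @param stack a [channel_stack()].
#' @param channel a role name (`"membrane"`, `"particles"`, `"egfp"`,
#'   `"nuclei"`) or a channel index.
#' @param t timepoint index (1-based).
#' @return 3D numeric array `(z, y, x)`.
#' @export
get_channel <- function(stack, channel, t = 1L) {
  d <- dim(stack$data)
  if (is.character(channel)) {
    if (!channel %in% names(stack$roles))
      stop("unknown channel role: ", channel)
    channel <- stack$roles[[channel]]
  }
  if (channel < 1L || channel > d[4L]) stop("channel index out of range")
  if (t < 1L || t > d[5L]) stop("timepoint index out of range")
  array(stack$data[, , , channel, t], dim = d[1:3])
}

#' Maximum intensity projection along z
#'
#' Pixelwise maximum over all optical sections of one channel at one
#' timepoint; the planar image feeding 2D instance segmentation.
#'
#' @inheritParams get_channel
#' @return 2D numeric matrix `(y, x)`.
#' @export
max_project <- function(stack, channel, t = 1L) {
  vol <- get_channel(stack, channel, t)
  mip(vol)
}

#' Maximum projection of a plain volume
#' @param vol 3D array `(z, y, x)`.
#' @return matrix `(y, x)`.
#' @export
mip <- function(vol) {
  stopifnot(length(dim(vol)) == 3L)
  nz <- dim(vol)[1L]
  out <- vol[1, , ]
  if (nz > 1L) for (z in 2:nz) out <- pmax(out, vol[z, , ])
  matrix(out, dim(vol)[2L], dim(vol)[3L])
}

# separable anisotropic Gaussian blur of a (z,y,x) volume or (y,x) matrix;
# sigma given per axis in voxel units, 0 disables an axis.
gauss_blur <- function(vol, sigma) {
  was2d <- length(dim(vol)) == 2L
  if (was2d) {
    dim(vol) <- c(1L, dim(vol))
    sigma <- c(0, sigma)
  }
  out <- cpp_gauss_blur3(vol, as.numeric(sigma))
  if (was2d) {
    d <- dim(out)
    out <- matrix(out, d[2L], d[3L])
  }
  out
}
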