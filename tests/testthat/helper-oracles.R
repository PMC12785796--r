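# Independent brute-force oracles used to validate the implementation.

# exhaustive between-class variance maximizer over all gray levels
bf_otsu <- function(counts, values) {
  n <- length(counts)
  total <- sum(counts)
  best <- -Inf
  best_k <- NA_integer_
  for (k in seq_len(n - 1L)) {
    i0 <- seq_len(k)
    w0 <- sum(counts[i0]) / total
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[i0] * values[i0]) / sum(counts[i0])
    mu1 <- sum(counts[-i0] * values[-i0]) / sum(counts[-i0])
    sb <- w0 * w1 * (mu0 - mu1)^2
    if (sb > best) { best <- sb; best_k <- k }
  }
  values[best_k]
}

# exhaustive minimum anisotropic distance from a point to every TRUE voxel
bf_min_dist <- function(centroid, mask, spacing) {
  co <- which(mask, arr.ind = TRUE)
  sqrt(min(((co[, 1] - centroid[1]) * spacing[1])^2 +
           ((co[, 2] - centroid[2]) * spacing[2])^2 +
           ((co[, 3] - centroid[3]) * spacing[3])^2))
}

# voxel-counting nuclear ratio
bf_nuclear_ratio <- function(pmask, nmask) {
  inside <- 0L
  tot <- 0L
  for (i in which(pmask)) {
    tot <- tot + 1L
    if (nmask[i]) inside <- inside + 1L
  }
  inside / tot
}

# brute-force minimum-total-cost assignment over all permutations
bf_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  best <- Inf
  best_p <- NULL
  for (p in perms(seq_len(n))) {
    cst <- sum(cost[cbind(seq_len(n), p)])
    if (cst < best - 1e-12) { best <- cst; best_p <- p }
  }
  list(cost = best, assignment = best_p)
}

# random ellipsoidal cell + interior nucleus on a small anisotropic grid
random_cell_geometry <- function(dim3 = c(12L, 48L, 48L),
                                 spacing = c(0.762, 0.0618, 0.0618)) {
  fov <- (dim3 - 1) * spacing
  ctr <- fov / 2 + runif(3, -0.05, 0.05) * fov
  axes <- c(runif(1, 0.30, 0.42) * fov[1],
            runif(1, 0.30, 0.42) * fov[2],
            runif(1, 0.30, 0.42) * fov[3])
  cell <- virotrace3d:::ellipsoid_mask(dim3, spacing, ctr, axes,
                                       runif(1, 0, pi))
  nuc <- virotrace3d:::ellipsoid_mask(dim3, spacing, ctr, axes * 0.5,
                                      runif(1, 0, pi))
  list(cell = cell, nucleus = nuc, spacing = spacing, dim = dim3)
}
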