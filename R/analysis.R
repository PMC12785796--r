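#' Spatial class labels
#' @return character vector of the four class codes, in order.
#' @export
spatial_classes <- function() {
  c("inside_nucleus", "nuclear_boundary", "perinuclear", "cytoplasmic")
}

#' Classify a particle by nuclear ratio and normalized distance
#'
#' Four-class scheme: completely inside the nucleus (NR = 1, x = 0),
#' at the nuclear membrane boundary (0 < NR < 1, x = 0), perinuclear
#' (NR = 0, 0 <= x <= 0.01 AU) and cytoplasmic (NR = 0, 0.01 < x <= 1 AU).
#' The perinuclear cut 0.01 AU is 1% of the maximal nucleus-to-membrane
#' distance within the same cell.
#'
#' Vectorized. Inputs must satisfy the consistency precondition
#' `NR > 0 => x = 0` (overlap forces zero distance); violations are an error.
#'
#' @param nr nuclear ratio in `[0, 1]`.
#' @param x_norm normalized distance in `[0, 1]` AU.
#' @param perinuclear_cut class-c upper bound, default 0.01 AU.
#' @return factor with levels [spatial_classes()].
#' @export
classify_particle <- function(nr, x_norm, perinuclear_cut = 0.01) {
  stopifnot(length(nr) == length(x_norm))
  if (any(nr < 0 | nr > 1) || any(x_norm < 0 | x_norm > 1))
    stop("nr and x_norm must lie in [0, 1]")
  if (any(nr > 0 & x_norm > 0))
    stop("inconsistent input: NR > 0 requires x_norm = 0")
  cls <- ifelse(nr >= 1, "inside_nucleus",
         ifelse(nr > 0, "nuclear_boundary",
         ifelse(x_norm <= perinuclear_cut, "perinuclear", "cytoplasmic")))
  factor(cls, levels = spatial_classes())
}

#' Nuclear fraction of viral particles
#'
#' Ratio of nuclear particles (inside the nucleus plus at the nuclear
#' membrane boundary) to total cellular particles; defined 0 (flagged via
#' the `defined` field) when the cell has no particles.
#'
#' @param inside,boundary,perinuclear,cytoplasmic per-class particle counts.
#' @return tibble with `nuclear_fraction`, `total` and `defined`.
#' @export
nuclear_fraction <- function(inside, boundary, perinuclear = 0, cytoplasmic = 0) {
  total <- inside + boundary + perinuclear + cytoplasmic
  tibble::tibble(
    nuclear_fraction = ifelse(total > 0, (inside + boundary) / total, 0),
    total = total,
    defined = total > 0)
}

#' Empirical cumulative distance curve
#'
#' The fraction of a group's particles that have accumulated within a
#' normalized distance of x AU or less from the nucleus.
#'
#' @param x_norm normalized distances of one group (nonempty).
#' @return object of class `cumulative_curve` with sorted `x` and
#'   cumulative fractions `frac`.
#' @export
cumulative_curve <- function(x_norm) {
  if (!length(x_norm)) {
    return(structure(list(x = numeric(), frac = numeric(), n = 0L),
                     class = "cumulative_curve"))
  }
  xs <- sort(x_norm)
  structure(list(x = xs, frac = seq_along(xs) / length(xs), n = length(xs)),
            class = "cumulative_curve")
}

#' Evaluate a cumulative curve
#' @param curve a [cumulative_curve()].
#' @param x0 distances at which to evaluate (<= semantics).
#' @return fraction of particles with `x_norm <= x0`.
#' @export
curve_at <- function(curve, x0) {
  stopifnot(inherits(curve, "cumulative_curve"))
  if (curve$n == 0L) return(rep(NA_real_, length(x0)))
  vapply(x0, function(v) sum(curve$x <= v) / curve$n, numeric(1))
}

#' @export
print.cumulative_curve <- function(x, ...) {
  cat(sprintf("cumulative_curve over %d particles", x$n))
  if (x$n) cat(sprintf("; x in [%.4g, %.4g]", min(x$x), max(x$x)))
  cat("\n")
  invisible(x)
}

#' Categorize cells by transgene (eGFP) expression
#'
#' Pools mean eGFP intensities of all cells over all timepoints within each
#' condition, takes the 50th and 75th percentiles (linear interpolation
#' between order statistics), and labels each cell-timepoint:
#' non (0-50th, intensity <= p50), low (50th-75th, p50 < intensity <= p75),
#' high (75th-100th, > p75). The category used for longitudinal grouping is
#' the one at each track's final timepoint (`category_final`).
#'
#' @param cells tibble with columns `condition`, `track_id`, `timepoint`,
#'   `mean_egfp`.
#' @return list with `data` (input plus `egfp_category`, `category_final`)
#'   and `thresholds` (tibble `condition`, `p50`, `p75`).
#' @export
categorize_expression <- function(cells) {
  need <- c("condition", "track_id", "timepoint", "mean_egfp")
  stopifnot(all(need %in% names(cells)))
  lv <- c("non", "low", "high")
  out <- vector("list", 0L)
  thr <- vector("list", 0L)
  for (cond in unique(cells$condition)) {
    cc <- cells[cells$condition == cond, , drop = FALSE]
    if (nrow(cc) < 4L)
      stop("need at least 4 cell-timepoint intensities per condition")
    p <- quantile(cc$mean_egfp, c(0.5, 0.75), type = 7, names = FALSE)
    cat_of <- function(v) ifelse(v <= p[1], "non", ifelse(v <= p[2], "low", "high"))
    cc$egfp_category <- factor(cat_of(cc$mean_egfp), levels = lv)
    fin <- cc[order(cc$track_id, cc$timepoint), ]
    fin <- fin[!duplicated(fin$track_id, fromLast = TRUE),
               c("track_id", "egfp_category")]
    names(fin)[2] <- "category_final"
    cc <- merge(cc, fin, by = "track_id", sort = FALSE)
    out[[length(out) + 1L]] <- cc
    thr[[length(thr) + 1L]] <- tibble::tibble(condition = cond,
                                              p50 = p[1], p75 = p[2])
  }
  list(data = tibble::as_tibble(dplyr::bind_rows(out)),
       thresholds = dplyr::bind_rows(thr))
}

#' Two-sample Mann-Whitney U test
#'
#' U from rank sums with midrank ties. Exact two-sided p-value by complete
#' enumeration of rank allocations when `n1 + n2 <= 16` and there are no
#' ties; otherwise the normal approximation with tie correction and
#' continuity correction. Two-sided p is twice the smaller tail, capped at 1.
#'
#' @param a,b numeric samples (both nonempty).
#' @return list of class `mwu_result`: `n1`, `n2`, `U` (of the first group),
#'   `p_value`, `method`, and `summary` (per-group median, quartiles and
#'   10th/90th percentiles).
#' @export
mann_whitney_u <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(a, b)))
  if (N <= 16 && !ties) {
    # enumerate every allocation of n1 ranks among 1..N
    allo <- combn(N, n1)
    Us <- colSums(allo) - n1 * (n1 + 1) / 2
    p_lo <- mean(Us <= U1)
    p_hi <- mean(Us >= U1)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact enumeration"
  } else {
    p <- mwu_asymptotic_p(a, b)
    method <- "normal approximation with tie and continuity correction"
  }
  structure(list(n1 = n1, n2 = n2, U = U1, p_value = p, method = method,
                 summary = dplyr::bind_rows(
                   cbind(group = "a", boxplot_summary(a)),
                   cbind(group = "b", boxplot_summary(b)))),
            class = "mwu_result")
}

# normal approximation with midrank tie correction and continuity correction
mwu_asymptotic_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  tt <- table(c(a, b))
  tiecor <- sum(tt^3 - tt) / (N * (N - 1))
  s <- sqrt(n1 * n2 / 12 * ((N + 1) - tiecor))
  z <- (U1 - mu - sign(U1 - mu) * 0.5) / s
  min(1, 2 * pnorm(-abs(z)))
}

#' @export
print.mwu_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U (two-tailed): U = %.6g, n = %d + %d, p = %.6g\n",
              x$U, x$n1, x$n2, x$p_value))
  cat("  method:", x$method, "\n")
  print(x$summary)
  invisible(x)
}

#' Five-number boxplot summary
#'
#' Median, lower/upper quartiles and 10th/90th percentiles (linear
#' interpolation between order statistics, `quantile` type 7), the summary
#' drawn as solid line, box and whiskers in the trafficking boxplots.
#'
#' @param values nonempty numeric vector.
#' @return one-row tibble `p10`, `p25`, `median`, `p75`, `p90`, `n`.
#' @export
boxplot_summary <- function(values) {
  if (!length(values)) stop("empty sample")
  q <- quantile(values, c(0.1, 0.25, 0.5, 0.75, 0.9), type = 7, names = FALSE)
  tibble::tibble(p10 = q[1], p25 = q[2], median = q[3], p75 = q[4], p90 = q[5],
                 n = length(values))
}

#' Spatiotemporal particle distribution table
#'
#' Per condition and timepoint, the percentage of particles that are
#' cytoplasmic, perinuclear or nuclear (inside + boundary), plus the
#' difference in absolute percentages against a reference condition at the
#' matching timepoint.
#'
#' @param particles tibble with columns `condition`, `timepoint`,
#'   `spatial_class`.
#' @param reference reference condition name.
#' @return tibble with percentage and delta columns; rows sum to 100.
#' @export
distribution_table <- function(particles, reference) {
  stopifnot(all(c("condition", "timepoint", "spatial_class") %in% names(particles)))
  if (!reference %in% particles$condition)
    stop("reference condition absent: ", reference)
  grp <- dplyr::group_by(particles, .data$condition, .data$timepoint)
  tab <- dplyr::summarise(grp,
    pct_cytoplasmic = 100 * mean(.data$spatial_class == "cytoplasmic"),
    pct_perinuclear = 100 * mean(.data$spatial_class == "perinuclear"),
    pct_nuclear = 100 * mean(.data$spatial_class %in%
                               c("inside_nucleus", "nuclear_boundary")),
    n = dplyr::n(), .groups = "drop")
  ref <- tab[tab$condition == reference,
             c("timepoint", "pct_cytoplasmic", "pct_perinuclear", "pct_nuclear")]
  names(ref)[-1] <- paste0("ref_", names(ref)[-1])
  tab <- merge(tab, ref, by = "timepoint", all.x = TRUE, sort = FALSE)
  tab$delta_cytoplasmic <- tab$pct_cytoplasmic - tab$ref_pct_cytoplasmic
  tab$delta_perinuclear <- tab$pct_perinuclear - tab$ref_pct_perinuclear
  tab$delta_nuclear <- tab$pct_nuclear - tab$ref_pct_nuclear
  tibble::as_tibble(tab[order(tab$condition, tab$timepoint),
                        c("condition", "timepoint", "n",
                          "pct_cytoplasmic", "pct_perinuclear", "pct_nuclear",
                          "delta_cytoplasmic", "delta_perinuclear",
                          "delta_nuclear")])
}

#' Plot cumulative distance curves
#'
#' @param particles tibble with `x_norm` and a grouping column.
#' @param group name of the grouping column (e.g. `"timepoint"`).
#' @return a ggplot object.
#' @export
plot_cumulative_curves <- function(particles, group = "timepoint") {
  stopifnot("x_norm" %in% names(particles), group %in% names(particles))
  df <- particles[order(particles[[group]], particles$x_norm), ]
  df <- dplyr::group_by(df, .data[[group]])
  df <- dplyr::mutate(df, frac = dplyr::row_number() / dplyr::n())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_norm, y = .data$frac,
                                   colour = factor(.data[[group]]))) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "distance to nucleus (AU)",
                  y = "cumulative fraction of particles",
                  colour = group) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}
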