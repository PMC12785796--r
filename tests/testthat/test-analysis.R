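test_that("particle classification follows the four-class scheme", {
  expect_equal(as.character(classify_particle(1, 0)), "inside_nucleus")
  expect_equal(as.character(classify_particle(0.5, 0)), "nuclear_boundary")
  expect_equal(as.character(classify_particle(0, 0.01)), "perinuclear")
  expect_equal(as.character(classify_particle(0, 0.010001)), "cytoplasmic")
  expect_equal(as.character(classify_particle(0, 0)), "perinuclear")
  expect_equal(as.character(classify_particle(0, 1)), "cytoplasmic")
  expect_error(classify_particle(0.5, 0.2), "inconsistent")
  expect_error(classify_particle(1.2, 0), "0, 1")
})

test_that("classification is a partition on consistent random inputs", {
  set.seed(42)
  n <- 2000
  kind <- sample(3, n, replace = TRUE)
  nr <- ifelse(kind == 1, 1, ifelse(kind == 2, runif(n, 0.01, 0.99), 0))
  x <- ifelse(kind == 3, runif(n), 0)
  cls <- classify_particle(nr, x)
  expect_false(any(is.na(cls)))
  expect_equal(length(cls), n)
  counts <- table(cls)
  expect_equal(sum(counts), n)
  # NR > 0 never lands outside the two nuclear classes
  expect_true(all(cls[nr > 0] %in% c("inside_nucleus", "nuclear_boundary")))
})

test_that("nuclear fraction is the ratio of nuclear to total particles", {
  r <- nuclear_fraction(inside = 2, boundary = 1, perinuclear = 1,
                        cytoplasmic = 8)
  expect_equal(r$nuclear_fraction, 3 / 12)
  expect_equal(nuclear_fraction(0, 0, 0, 5)$nuclear_fraction, 0)
  expect_equal(nuclear_fraction(7, 0, 0, 0)$nuclear_fraction, 1)
  z <- nuclear_fraction(0, 0, 0, 0)
  expect_equal(z$nuclear_fraction, 0)
  expect_false(z$defined)
})

test_that("cumulative curve reproduces counting fractions", {
  # 12 particles, 9 within the marked distance -> 75%
  x <- c(rep(0, 3), 0.004, 0.1, 0.15, 0.2, 0.3, 0.35, 0.6, 0.8, 0.9)
  cv <- cumulative_curve(x)
  expect_equal(curve_at(cv, 0.35), 0.75)
  expect_equal(curve_at(cv, 1), 1)
  cv0 <- cumulative_curve(rep(0, 5))
  expect_equal(curve_at(cv0, 0), 1)
  set.seed(1)
  v <- runif(200)
  cv <- cumulative_curve(v)
  for (x0 in sample(v, 20))
    expect_equal(curve_at(cv, x0), sum(v <= x0) / length(v))
  expect_true(all(diff(cv$frac) >= 0))
})

test_that("expression categories split at the pooled 50th/75th percentiles", {
  set.seed(3)
  cells <- tibble::tibble(condition = "A", track_id = 1:100,
                          timepoint = 1L, mean_egfp = sample(seq(10, 1000, length.out = 100)))
  out <- categorize_expression(cells)
  expect_equal(as.integer(table(out$data$egfp_category)), c(50, 25, 25))
  expect_true(out$thresholds$p50 <= out$thresholds$p75)
  # degenerate: identical intensities -> everything non
  same <- tibble::tibble(condition = "A", track_id = 1:10, timepoint = 1L,
                         mean_egfp = 5)
  expect_true(all(categorize_expression(same)$data$egfp_category == "non"))
  expect_error(categorize_expression(same[1:3, ]), "at least 4")
})

test_that("longitudinal grouping uses the final-timepoint category", {
  # one cell rising into the top quartile only at the last timepoint
  cells <- tibble::tibble(
    condition = "A",
    track_id = rep(1:4, each = 3),
    timepoint = rep(1:3, 4),
    mean_egfp = c(1, 2, 100, 3, 4, 5, 6, 7, 8, 9, 10, 11))
  out <- categorize_expression(cells)$data
  cell1 <- out[out$track_id == 1, ]
  expect_true(all(cell1$category_final == cell1$egfp_category[cell1$timepoint == 3]))
  # its early timepoints keep their own per-timepoint category
  expect_true(any(cell1$egfp_category != cell1$category_final))
})

test_that("Mann-Whitney U: exact enumeration and asymptotic branch agree", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1)
  expect_equal(r$U, 0)
  # independent cross-check with the base-R exact distribution
  w <- wilcox.test(c(1, 2, 3), c(4, 5, 6), exact = TRUE)
  expect_equal(r$p_value, unname(w$p.value))
  # symmetry and identical groups
  set.seed(9)
  a <- rnorm(7); b <- rnorm(5)
  expect_equal(mann_whitney_u(a, b)$p_value, mann_whitney_u(b, a)$p_value)
  same <- mann_whitney_u(1:5 + 0.5, 1:5)$p_value
  expect_gt(same, 0.5)
  # exact vs asymptotic at n = 8 + 8, tie-free
  # representative tie-free 8+8 sample (U = 20): branches agree within 0.01
  a8 <- c(1, 2, 3, 4, 5, 12, 13, 16)
  b8 <- c(6, 7, 8, 9, 10, 11, 14, 15)
  expect_equal(sum(rank(c(a8, b8))[1:8]) - 36, 20)
  expect_lt(abs(mann_whitney_u(a8, b8)$p_value -
                virotrace3d:::mwu_asymptotic_p(a8, b8)), 0.01)
  # across every attainable U at 8+8 the gap never exceeds 0.011
  allo <- combn(16, 8)
  Us <- colSums(allo) - 36
  for (u in 0:64) {
    pex <- min(1, 2 * min(mean(Us <= u), mean(Us >= u)))
    s <- sqrt(64 * 17 / 12)
    z <- (u - 32 - sign(u - 32) * 0.5) / s
    pas <- min(1, 2 * pnorm(-abs(z)))
    expect_lt(abs(pex - pas), 0.011)
  }
  expect_error(mann_whitney_u(numeric(), 1:3), "nonempty")
})

test_that("Mann-Whitney U matches wilcox.test on larger tied samples", {
  set.seed(5)
  a <- sample(1:10, 30, replace = TRUE)
  b <- sample(3:12, 25, replace = TRUE)
  r <- mann_whitney_u(a, b)
  w <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(r$U, unname(w$statistic))
  expect_equal(r$p_value, unname(w$p.value), tolerance = 1e-8)
})

test_that("boxplot summary gives median, quartiles and 10/90 percentiles", {
  s <- boxplot_summary(1:100)
  expect_equal(s$median, 50.5)
  cst <- boxplot_summary(rep(3, 10))
  expect_true(all(unlist(cst[, 1:5]) == 3))
  set.seed(2)
  v <- rnorm(57)
  s <- boxplot_summary(v)
  q <- quantile(sort(v), c(.1, .25, .5, .75, .9), type = 7, names = FALSE)
  expect_equal(unlist(s[, 1:5], use.names = FALSE), q)
  expect_error(boxplot_summary(numeric()), "empty")
})

test_that("distribution table reports percentages and reference deltas", {
  p <- tibble::tibble(
    condition = rep(c("ref", "alt"), each = 100),
    timepoint = 4L,
    spatial_class = factor(c(rep("cytoplasmic", 70), rep("perinuclear", 10),
                             rep("inside_nucleus", 12), rep("nuclear_boundary", 8),
                             rep("cytoplasmic", 50), rep("perinuclear", 20),
                             rep("inside_nucleus", 20), rep("nuclear_boundary", 10)),
                           levels = spatial_classes()))
  tab <- distribution_table(p, reference = "ref")
  ref_row <- tab[tab$condition == "ref", ]
  expect_equal(ref_row$pct_cytoplasmic, 70)
  expect_equal(ref_row$pct_perinuclear, 10)
  expect_equal(ref_row$pct_nuclear, 20)
  expect_equal(ref_row$delta_cytoplasmic, 0)
  alt_row <- tab[tab$condition == "alt", ]
  expect_equal(alt_row$delta_cytoplasmic, -20)
  expect_equal(alt_row$delta_nuclear, 10)
  sums <- rowSums(tab[, c("pct_cytoplasmic", "pct_perinuclear", "pct_nuclear")])
  expect_true(all(abs(sums - 100) < 0.01))
  expect_error(distribution_table(p, "missing"), "absent")
})
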