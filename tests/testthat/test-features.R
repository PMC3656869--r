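# Brute-force GLCM oracle: explicit double loop over pixel pairs.
oracle_glcm <- function(q, off, levels) {
  P <- matrix(0, levels, levels)
  for (i in seq_len(nrow(q))) for (j in seq_len(ncol(q))) {
    i2 <- i + off[1]; j2 <- j + off[2]
    if (i2 >= 1 && i2 <= nrow(q) && j2 >= 1 && j2 <= ncol(q) &&
        !is.na(q[i, j]) && !is.na(q[i2, j2])) {
      P[q[i, j], q[i2, j2]] <- P[q[i, j], q[i2, j2]] + 1
    }
  }
  P <- P + t(P)
  P / sum(P)
}

test_that("the default catalogue has 73 uniquely named features", {
  cat73 <- feature_catalog()
  expect_identical(nrow(cat73), 73L)
  expect_identical(anyDuplicated(cat73$name), 0L)
  expect_identical(as.integer(table(cat73$family)[c(
    "morphology", "intensity", "haralick", "gabor", "granularity",
    "radial")]), c(12L, 9L, 13L, 12L, 16L, 11L))
})

test_that("granularity spectrum matches constructed images analytically", {
  # constant patch: opening of a constant is itself
  expect_true(all(granularity_spectrum(matrix(1, 12, 12), 1:4) == 0))
  # isolated bright pixels vanish at radius 1
  p <- matrix(0, 20, 20)
  p[cbind(seq(3, 18, 4), seq(3, 18, 4))] <- 1
  g <- granularity_spectrum(p, 1:6)
  expect_gt(g[1], 99)
  expect_true(all(g[-1] < 1))
  # a radius-5 blob keeps its mass until the disk reaches its size
  b <- matrix(0, 24, 24)
  for (i in 1:24) for (j in 1:24) if ((i - 12)^2 + (j - 12)^2 <= 25) b[i, j] <- 1
  gb <- granularity_spectrum(b, 1:8)
  expect_lt(sum(gb[1:4]), 10)
  expect_gt(sum(gb[5:6]), 90)
  expect_lte(sum(gb), 100 + 1e-9)
  # zero patch flagged degenerate
  gz <- granularity_spectrum(matrix(0, 5, 5), 1:3)
  expect_true(all(gz == 0))
  expect_true(attr(gz, "degenerate"))
})

test_that("haralick statistics have their closed-form anchors", {
  hc <- haralick_features(matrix(5, 6, 6))
  expect_equal(unname(hc["har_contrast"]), 0)
  expect_equal(unname(hc["har_asm"]), 1)
  expect_true(attr(hc, "degenerate"))
  # checkerboard at 2 levels: contrast 1 on axial offsets, 0 on diagonals
  cb <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  h <- haralick_features(cb, levels = 2)
  expect_equal(unname(h["har_contrast"]), 0.5, tolerance = 1e-12)
})

test_that("haralick statistics match the brute-force pair-counting oracle", {
  set.seed(12)
  offsets <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
  for (rep in 1:10) {
    nr <- sample(6:16, 1); nc <- sample(6:16, 1)
    patch <- matrix(runif(nr * nc), nr, nc)
    mask <- matrix(runif(nr * nc) > 0.2, nr, nc)
    if (sum(mask) < 8) next
    h <- haralick_features(patch, mask, levels = 8)
    vals <- patch[mask]
    q <- matrix(NA_integer_, nr, nc)
    q[mask] <- pmin(floor((patch[mask] - min(vals)) /
                            (max(vals) - min(vals)) * 8) + 1, 8)
    acc <- 0
    for (off in offsets) {
      acc <- acc + melmark:::haralick_from_glcm(oracle_glcm(q, off, 8))
    }
    expect_equal(unname(h), acc / 4, tolerance = 1e-10)
  }
})

test_that("co-occurrence counting itself matches the naive loop", {
  set.seed(13)
  q <- matrix(sample(1:4, 100, replace = TRUE), 10, 10)
  q[sample(100, 15)] <- NA
  for (off in list(c(0L, 1L), c(-1L, 1L))) {
    expect_equal(melmark:::glcm_offset(q, off, 4L), oracle_glcm(q, off, 4),
                 tolerance = 1e-12)
  }
})

test_that("gabor responses are orientation selective and zero on flat input", {
  expect_true(all(gabor_features(matrix(0, 24, 24)) == 0))
  x <- outer(rep(1, 32), 1:32)
  grating <- 0.5 + 0.5 * sin(2 * pi * 0.2 * x)
  g <- gabor_features(grating, frequencies = 0.2, orientations = c(0, 90))
  expect_gt(g[1] / max(g[2], 1e-12), 5)
  # rotating the patch by 90 degrees permutes the orientation responses
  g2 <- gabor_features(t(grating), frequencies = 0.2, orientations = c(0, 90))
  expect_equal(unname(g[1]), unname(g2[2]), tolerance = 1e-6)
  expect_equal(unname(g[2]), unname(g2[1]), tolerance = 1e-6)
})

test_that("equivalent-ellipse axes match simple shapes", {
  m <- matrix(FALSE, 30, 30)
  for (i in 1:30) for (j in 1:30) if ((i - 15)^2 + (j - 15)^2 <= 64) m[i, j] <- TRUE
  ax <- ellipse_axes(m)
  expect_lt(abs(ax["major"] - 16) / 16, 0.05)
  expect_lt(abs(ax["minor"] - 16) / 16, 0.05)
  line <- matrix(FALSE, 3, 22); line[2, 2:21] <- TRUE
  axl <- ellipse_axes(line)
  expect_gt(axl["major"] / axl["minor"], 10)
  expect_gt(sqrt(1 - (axl["minor"] / axl["major"])^2), 0.99)
  expect_equal(unname(ellipse_axes(t(line))), unname(axl), tolerance = 1e-12)
  single <- matrix(c(TRUE), 1, 1)
  expect_true(attr(ellipse_axes(single), "degenerate"))
})

test_that("extracted features are finite, complete and translation invariant", {
  s <- small_core(7)
  dec <- deconvolve(rgb_to_od(s$image))
  lab <- segment_nuclei(dec$hematoxylin)
  ft <- extract_features(lab, dec$hematoxylin)
  expect_identical(nrow(ft), max(lab))
  expect_identical(ncol(ft), 4L + 73L)
  expect_true(all(vapply(ft[, -(1:4)], function(c) all(is.finite(c)), TRUE)))
  # integrated intensity equals the naive per-pixel sum
  id <- 5L
  brute <- sum(dec$hematoxylin[lab == id])
  expect_equal(ft$int_integrated[id], brute, tolerance = 1e-10)
  # translating an object leaves its features unchanged
  idx <- which(lab == id)
  rows <- (idx - 1) %% nrow(lab) + 1; cols <- (idx - 1) %/% nrow(lab) + 1
  sub_l <- matrix(0L, 40, 40); sub_h <- matrix(0, 40, 40)
  sub_l2 <- matrix(0L, 40, 40); sub_h2 <- matrix(0, 40, 40)
  r0 <- min(rows); c0 <- min(cols)
  sub_l[cbind(rows - r0 + 3, cols - c0 + 3)] <- 1L
  sub_h[cbind(rows - r0 + 3, cols - c0 + 3)] <- dec$hematoxylin[idx]
  sub_l2[cbind(rows - r0 + 15, cols - c0 + 12)] <- 1L
  sub_h2[cbind(rows - r0 + 15, cols - c0 + 12)] <- dec$hematoxylin[idx]
  f1 <- extract_features(sub_l, sub_h)
  f2 <- extract_features(sub_l2, sub_h2)
  expect_equal(f1[, -(1:4)], f2[, -(1:4)], tolerance = 1e-8)
})

test_that("constant-intensity disks collapse to degenerate texture values", {
  lab <- matrix(0L, 30, 30)
  h <- matrix(0, 30, 30)
  for (i in 1:30) for (j in 1:30) if ((i - 15)^2 + (j - 15)^2 <= 49) {
    lab[i, j] <- 1L; h[i, j] <- 0.5
  }
  ft <- extract_features(lab, h)
  expect_equal(ft$har_contrast, 0)
  expect_true(all(ft[, sprintf("gran_r%d", 1:6)] == 0))
  expect_lt(ft$eccentricity, 0.2)
  expect_true(ft$qc_degenerate)
})
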