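two_nuclei_scene <- function() {
  lab <- matrix(0L, 40, 60)
  for (i in 1:40) for (j in 1:60) {
    if ((i - 20)^2 + (j - 20)^2 <= 36) lab[i, j] <- 1L
    if ((i - 20)^2 + (j - 40)^2 <= 36) lab[i, j] <- 2L
  }
  lab
}

test_that("cell expansion respects its boundary contracts", {
  lab <- two_nuclei_scene()
  dab <- matrix(0.1, 40, 60)  # uniform: no gradient anywhere
  expect_identical(expand_to_cell(lab, dab, max_ring = 0), lab)
  cells <- expand_to_cell(lab, dab, max_ring = 10)
  # nucleus pixels keep their labels; cells partition their territory
  expect_true(all(cells[lab > 0] == lab[lab > 0]))
  expect_identical(sort(unique(as.integer(cells[cells > 0]))), c(1L, 2L))
  # in the uniform case the boundary is equidistant: the midline column
  # between the two nuclei splits the territory symmetrically
  expect_lt(abs(sum(cells == 1) - sum(cells == 2)) / sum(cells > 0), 0.06)
  left <- cells[, 1:29]; right <- cells[, 32:60]
  expect_false(any(left == 2))
  expect_false(any(right == 1))
})

test_that("a sharp DAB ring halts the expansion within a pixel", {
  lab <- matrix(0L, 50, 50)
  for (i in 1:50) for (j in 1:50) if ((i - 25)^2 + (j - 25)^2 <= 16) lab[i, j] <- 1L
  dab <- matrix(0, 50, 50)
  d <- 6  # ring at distance ~6 px outside the r=4 nucleus
  for (i in 1:50) for (j in 1:50) {
    rr <- sqrt((i - 25)^2 + (j - 25)^2)
    if (rr >= 4 + d & rr <= 4 + d + 1.5) dab[i, j] <- 0.8
  }
  cells <- expand_to_cell(lab, dab, max_ring = 12)
  dist_out <- max(sqrt((which(cells == 1, arr.ind = TRUE)[, 1] - 25)^2 +
                       (which(cells == 1, arr.ind = TRUE)[, 2] - 25)^2))
  expect_lte(dist_out, 4 + d + 1)
})

test_that("positivity scoring honours rules, ties and degenerate inputs", {
  lab <- two_nuclei_scene()
  zero <- matrix(0, 40, 60)
  sc <- score_positivity(lab, zero)
  expect_false(any(sc$positive))
  # fixed rule with an inclusive cutoff
  lab3 <- matrix(0L, 6, 18)
  lab3[2:5, 1:5] <- 1L; lab3[2:5, 7:11] <- 2L; lab3[2:5, 13:17] <- 3L
  dab3 <- matrix(0, 6, 18)
  dab3[lab3 == 1] <- 0.1; dab3[lab3 == 2] <- 0.2; dab3[lab3 == 3] <- 0.3
  sf <- score_positivity(lab3, dab3, rule = "fixed", cutoff = 0.2)
  expect_identical(sf$positive, c(FALSE, TRUE, TRUE))
  # bimodal means under the adaptive rule match the construction exactly
  dabb <- matrix(0, 40, 60)
  dabb[lab == 1] <- 0.05; dabb[lab == 2] <- 0.6
  sa <- score_positivity(lab, dabb, rule = "adaptive")
  expect_identical(sa$positive, c(FALSE, TRUE))
  expect_identical(nrow(score_positivity(matrix(0L, 5, 5), matrix(0, 5, 5))),
                   0L)
})

test_that("the adaptive ratio is invariant to image-wide DAB rescaling", {
  lab <- two_nuclei_scene()
  dab <- matrix(0, 40, 60)
  dab[lab == 1] <- 0.04; dab[lab == 2] <- 0.5
  s1 <- score_positivity(lab, dab, rule = "adaptive")
  s2 <- score_positivity(lab, dab * 2.5, rule = "adaptive")
  expect_identical(s1$positive, s2$positive)
})

test_that("quantification recovers the truth fraction with truth labels", {
  # with ground-truth labels substituted for a model, the pipeline reduces
  # to segmentation + positivity and must recover the generator's fraction
  sb <- generate_biomarker_scene(
    scene_params(width = 340, height = 340, n_melanoma = 25, n_other = 25,
                 seed = 55, preset = "biomarker"), 0.4)
  dens <- deconvolve(rgb_to_od(sb$image))
  lab <- segment_nuclei(dens$hematoxylin)
  nt <- nuclei_table(lab)
  truth_mel <- vapply(seq_len(nrow(nt)), function(i) {
    d <- sqrt((sb$nuclei$x - nt$x[i])^2 + (sb$nuclei$y - nt$y[i])^2)
    sb$nuclei$class[which.min(d)] == "melanoma"
  }, logical(1))
  sc <- score_positivity(lab, dens$dab, rule = "adaptive")
  ratio <- mean(sc$positive[truth_mel])
  expect_lt(abs(ratio - 0.4), 0.05)
  expect_false(any(sc$positive[!truth_mel]))
})
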