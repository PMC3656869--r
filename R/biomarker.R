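#' Expand nucleus labels to whole-cell regions
#'
#' Grows each nucleus outward by geodesic propagation up to `max_ring`
#' pixels, stopping where the local DAB gradient magnitude exceeds a stop
#' threshold (the cytoplasm boundary is fixed on the staining gradient
#' outside the nucleus) or where a competing cell is met. Cell regions
#' partition the claimed territory; every nucleus pixel keeps its label.
#'
#' @param nuclei integer label matrix from [segment_nuclei()].
#' @param dab DAB density matrix of the same shape.
#' @param max_ring maximum expansion distance in px (0 returns the nuclei
#'   unchanged).
#' @param grad_quantile quantile of the in-ring gradient magnitudes used as
#'   the stop threshold.
#' @return integer cell label matrix (same ids as `nuclei`).
#' @export
expand_to_cell <- function(nuclei, dab, max_ring = 8, grad_quantile = 0.75) {
  stopifnot_shape(nuclei, dab, "labels and DAB")
  if (max_ring <= 0 || max(nuclei) == 0) return(nuclei)
  d <- eb_mat(EBImage::distmap(EBImage::Image((nuclei == 0) * 1)))
  ring <- d > 0 & d <= max_ring
  # Sobel gradient magnitude of the DAB density
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gx <- eb_mat(EBImage::filter2(EBImage::Image(dab), sx))
  gy <- eb_mat(EBImage::filter2(EBImage::Image(dab), t(sx)))
  grad <- sqrt(gx^2 + gy^2)
  stop_thr <- if (any(ring)) {
    stats::quantile(grad[ring], grad_quantile, names = FALSE)
  } else Inf
  blocked <- ring & grad > stop_thr & stop_thr > 0
  # seal one-pixel discretization gaps so the barrier is watertight
  if (any(blocked)) blocked <- dilate3x3(blocked * 1) > 0.5
  allowed <- (nuclei > 0) | (ring & !blocked)
  cells <- EBImage::propagate(EBImage::Image(dab),
                              EBImage::Image(matrix(as.integer(nuclei),
                                                    nrow(nuclei))),
                              mask = EBImage::Image(allowed * 1),
                              lambda = 1e4)
  out <- matrix(as.integer(cells), nrow(nuclei), ncol(nuclei))
  out[nuclei > 0] <- nuclei[nuclei > 0]  # nucleus pixels keep their label
  out
}

#' Score per-cell biomarker positivity from DAB density
#'
#' Computes the mean DAB density of each cell region and flags cells as
#' positive:
#' * `rule = "fixed"` — positive iff mean density >= `cutoff` (inclusive).
#' * `rule = "adaptive"` — Otsu split over the per-cell means, accepted only
#'   when the split is decisively bimodal (between-group mean gap at least
#'   half the upper group mean, a scale-free criterion); otherwise the
#'   population is treated as unimodal and called all-positive or
#'   all-negative against `floor_od`.
#'
#' @param cells integer cell label matrix.
#' @param dab DAB density matrix.
#' @param rule `"adaptive"` or `"fixed"`.
#' @param cutoff fixed-rule cutoff (OD).
#' @param floor_od minimum mean OD that can count as stained.
#' @return data frame `id`, `mean_dab`, `positive`.
#' @export
score_positivity <- function(cells, dab, rule = c("adaptive", "fixed"),
                             cutoff = 0.2, floor_od = 0.1) {
  rule <- match.arg(rule)
  stopifnot_shape(cells, dab, "cells and DAB")
  n <- max(cells)
  if (n == 0) {
    return(data.frame(id = integer(0), mean_dab = numeric(0),
                      positive = logical(0)))
  }
  idx <- cells > 0
  mm <- tapply(dab[idx], cells[idx], mean)
  means <- rep(0, n)
  means[as.integer(names(mm))] <- as.numeric(mm)
  positive <- if (rule == "fixed") {
    means >= cutoff
  } else {
    classify_means_adaptive(means, floor_od)
  }
  data.frame(id = seq_len(n), mean_dab = means, positive = positive)
}

#' Quantify biomarker positivity of melanoma cells in one image
#'
#' The full scoring chain: colour deconvolution, nucleus segmentation,
#' feature extraction, melanoma classification with a trained model,
#' nucleus-to-cell expansion, and per-cell DAB positivity. Only
#' model-predicted melanoma cells enter the positive-cell ratio.
#'
#' @param image RGB array (h x w x 3) of a stained tissue core, or a
#'   `synthetic_scene`.
#' @param model a `cell_classifier` whose `transform` and `features` were
#'   stored at training time.
#' @param config list of stage parameters; see [quantification_config()].
#' @return a `biomarker_score`: `image_id`, `melanoma_count`,
#'   `positive_count`, `ratio` (NA with `undefined = TRUE` when no melanoma
#'   cell is found), and the per-cell table (`nucleus_id`, `class`,
#'   `prob_melanoma`, `mean_nuclear_dab`, `mean_cell_dab`, `positive`).
#' @export
quantify_image <- function(image, model, config = quantification_config()) {
  if (inherits(image, "synthetic_scene")) image <- image$image
  od <- rgb_to_od(image, config$background_intensity, config$eps)
  dens <- deconvolve(od, config$stain_matrix)
  labels <- segment_nuclei(dens$hematoxylin, config$segmentation)
  score_from_densities(dens, labels, model, config)
}

# Core of quantify_image, reusable when densities/labels already exist.
score_from_densities <- function(dens, labels, model, config) {
  n <- max(labels)
  if (n == 0) {
    out <- list(image_id = config$image_id, melanoma_count = 0L,
                positive_count = 0L, ratio = NA_real_, undefined = TRUE,
                cells = data.frame())
    class(out) <- "biomarker_score"
    return(out)
  }
  ft <- extract_features(labels, dens$hematoxylin, config$catalog,
                         image_id = config$image_id)
  x <- as.matrix(ft[, model$features, drop = FALSE])
  if (!is.null(model$transform)) {
    x <- apply_standardization(model$transform, x)
  }
  prob <- predict_prob(model, x)
  is_mel <- prob >= config$prob_threshold
  cells <- expand_to_cell(labels, dens$dab, config$max_ring,
                          config$grad_quantile)
  nuc_mean <- score_positivity(labels, dens$dab, rule = "fixed",
                               cutoff = Inf)$mean_dab
  cell_means <- {
    idx <- cells > 0
    mm <- tapply(dens$dab[idx], cells[idx], mean)
    v <- rep(0, n); v[as.integer(names(mm))] <- as.numeric(mm); v
  }
  score_means <- if (config$positivity_source == "nucleus") {
    nuc_mean
  } else {
    cell_means
  }
  positive <- rep(FALSE, n)
  if (any(is_mel)) {
    mel_ids <- which(is_mel)
    if (config$positivity_rule == "fixed") {
      positive[mel_ids] <- score_means[mel_ids] >= config$positivity_cutoff
    } else {
      positive[mel_ids] <- classify_means_adaptive(score_means[mel_ids],
                                                   config$positivity_floor)
    }
  }
  tab <- data.frame(
    nucleus_id = seq_len(n),
    class = ifelse(is_mel, "melanoma", "other"),
    prob_melanoma = prob,
    mean_nuclear_dab = nuc_mean,
    mean_cell_dab = cell_means,
    positive = positive
  )
  mc <- sum(is_mel)
  out <- list(
    image_id = config$image_id,
    melanoma_count = mc,
    positive_count = sum(positive),
    ratio = if (mc > 0) sum(positive) / mc else NA_real_,
    undefined = mc == 0,
    cells = tab
  )
  class(out) <- "biomarker_score"
  out
}

# Adaptive (scale-free bimodality-guarded Otsu) positivity over a vector of
# per-cell means; shared with score_positivity.
classify_means_adaptive <- function(means, floor_od = 0.1) {
  if (length(means) == 0) return(logical(0))
  thr <- otsu_threshold(means)
  if (is.na(thr)) return(rep(means[1] >= floor_od, length(means)))
  lo <- means[means < thr]; hi <- means[means >= thr]
  decisive <- length(lo) > 0 && length(hi) > 0 &&
    (mean(hi) - mean(lo)) >= 0.5 * mean(hi)
  if (decisive) means >= thr else rep(mean(means) >= floor_od, length(means))
}

#' Configuration for biomarker quantification
#'
#' @param stain_matrix a `stain_matrix`.
#' @param segmentation list from [segmentation_params()].
#' @param catalog a [feature_catalog()].
#' @param background_intensity,eps see [rgb_to_od()].
#' @param prob_threshold melanoma probability cutoff.
#' @param max_ring,grad_quantile see [expand_to_cell()].
#' @param positivity_rule,positivity_cutoff,positivity_floor see
#'   [score_positivity()].
#' @param positivity_source `"nucleus"` scores the mean DAB over the
#'   nucleus region (appropriate for nuclear markers such as Ki67, whose
#'   staining the whole-cell mean would dilute by the expansion area);
#'   `"cell"` scores the expanded cell-region mean (cytoplasmic markers).
#' @param image_id identifier used in outputs.
#' @return a named list.
#' @export
quantification_config <- function(stain_matrix = default_stain_matrix(),
                                  segmentation = segmentation_params(),
                                  catalog = feature_catalog(),
                                  background_intensity = 255, eps = 1,
                                  prob_threshold = 0.5,
                                  max_ring = 8, grad_quantile = 0.75,
                                  positivity_rule = c("adaptive", "fixed"),
                                  positivity_cutoff = 0.2,
                                  positivity_floor = 0.1,
                                  positivity_source = c("nucleus", "cell"),
                                  image_id = "image") {
  cfg <- as.list(environment())
  cfg$positivity_rule <- match.arg(positivity_rule)
  cfg$positivity_source <- match.arg(positivity_source)
  cfg
}

#' @export
print.biomarker_score <- function(x, ...) {
  cat(sprintf("Biomarker score [%s]: %d melanoma cells, %d positive (%s)\n",
              x$image_id, x$melanoma_count, x$positive_count,
              if (x$undefined) "ratio undefined"
              else sprintf("ratio %.3f", x$ratio)))
  invisible(x)
}
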