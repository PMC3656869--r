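#' Pre-process the hematoxylin channel for nucleus segmentation
#'
#' Gaussian smoothing followed by unsharp masking, clipping the result at
#' zero. With `smooth_sigma = 0` and `sharpen_amount = 0` this is the
#' identity.
#'
#' @param hema nonnegative hematoxylin density matrix.
#' @param smooth_sigma Gaussian sigma in px (0 disables smoothing).
#' @param sharpen_amount unsharp-mask gain (0 disables sharpening).
#' @param sharpen_sigma sigma of the blur subtracted by the unsharp mask.
#' @return processed density matrix (>= 0).
#' @export
preprocess_h_channel <- function(hema, smooth_sigma = 1, sharpen_amount = 0.5,
                                 sharpen_sigma = 2) {
  x <- hema
  if (smooth_sigma > 0) {
    x <- eb_mat(EBImage::gblur(EBImage::Image(x), sigma = smooth_sigma))
  }
  if (sharpen_amount > 0) {
    blur <- eb_mat(EBImage::gblur(EBImage::Image(x), sigma = sharpen_sigma))
    x <- x + sharpen_amount * (x - blur)
  }
  pmax(x, 0)
}

#' Robust background threshold
#'
#' Computes `mean + k_sd * SD` of the pixel values after discarding the
#' lowest `trim_low` and highest `trim_high` fractions — the robust
#' background rule used to separate dim background from stained objects.
#'
#' @param image numeric matrix.
#' @param trim_low,trim_high trimmed fractions (`trim_low + trim_high < 1`).
#' @param k_sd number of SDs above the trimmed mean.
#' @return scalar threshold.
#' @export
robust_background_threshold <- function(image, trim_low = 0.05,
                                        trim_high = 0.05, k_sd = 2) {
  v <- as.numeric(image)
  v <- v[is.finite(v)]
  if (length(v) == 0) stop("robust background threshold of an empty image")
  stopifnot(trim_low >= 0, trim_high >= 0, trim_low + trim_high < 1)
  v <- sort(v)
  n <- length(v)
  lo <- floor(n * trim_low) + 1L
  hi <- n - floor(n * trim_high)
  v <- v[lo:hi]
  m <- mean(v)
  s <- if (length(v) > 1) sd(v) else 0
  m + k_sd * s
}

#' Default nucleus segmentation parameters
#'
#' @param smooth_sigma,sharpen_amount,sharpen_sigma see
#'   [preprocess_h_channel()].
#' @param trim_low,trim_high,k_sd see [robust_background_threshold()].
#' @param dist_smooth Gaussian sigma applied to the distance transform
#'   before watershed declumping.
#' @param tolerance,ext watershed parameters (minimum seed prominence and
#'   local-maximum search radius).
#' @param min_area,max_area object size gate (px^2).
#' @param remove_border drop objects touching the image border.
#' @return a named list.
#' @export
segmentation_params <- function(smooth_sigma = 1, sharpen_amount = 0.5,
                                sharpen_sigma = 2,
                                trim_low = 0.05, trim_high = 0.25, k_sd = 3.5,
                                dist_smooth = 0.5, tolerance = 0.35, ext = 1,
                                min_area = 40, max_area = 2000,
                                remove_border = FALSE) {
  as.list(environment())
}

#' Segment individual cell nuclei from a hematoxylin density image
#'
#' Three-step strategy: (1) foreground by the robust background threshold on
#' the pre-processed H channel; (2) declumping seeds from local maxima of
#' the smoothed distance transform; (3) watershed assignment of foreground
#' pixels to seeds. Holes are filled, border objects optionally removed, and
#' objects outside the size gate dropped. Labels are renumbered 1..N in
#' deterministic (top-left-first) order. The procedure has no randomness.
#'
#' @param hema nonnegative hematoxylin density matrix.
#' @param params list from [segmentation_params()].
#' @return integer label matrix (0 = background) of class `label_image`.
#' @export
segment_nuclei <- function(hema, params = segmentation_params()) {
  p <- params
  pp <- preprocess_h_channel(hema, p$smooth_sigma, p$sharpen_amount,
                             p$sharpen_sigma)
  thr <- robust_background_threshold(pp, p$trim_low, p$trim_high, p$k_sd)
  fg <- pp > thr
  if (!any(fg)) {
    out <- matrix(0L, nrow(hema), ncol(hema))
    class(out) <- c("label_image", class(out))
    return(out)
  }
  fg <- eb_mat(EBImage::fillHull(EBImage::Image(fg * 1))) > 0.5
  dm <- eb_mat(EBImage::distmap(EBImage::Image(fg * 1)))
  if (p$dist_smooth > 0) {
    dm <- eb_mat(EBImage::gblur(EBImage::Image(dm), sigma = p$dist_smooth))
  }
  dm[!fg] <- 0
  ws <- EBImage::watershed(EBImage::Image(dm), tolerance = p$tolerance,
                           ext = p$ext)
  lab <- matrix(as.integer(ws), nrow(hema), ncol(hema))
  if (p$remove_border) {
    border_ids <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1],
                           lab[, ncol(lab)]))
    lab[lab %in% setdiff(border_ids, 0L)] <- 0L
  }
  tab <- tabulate(lab[lab > 0])
  drop <- which(tab < p$min_area | tab > p$max_area)
  if (length(drop) > 0) lab[lab %in% drop] <- 0L
  out <- relabel_ordered(lab)
  class(out) <- c("label_image", class(out))
  out
}

#' Assign a melanoma / other class to each segmented nucleus
#'
#' A nucleus is labelled melanoma when at least `min_overlap` of its pixels
#' fall inside the marker mask (the rule is inclusive: overlap exactly equal
#' to `min_overlap` counts as melanoma). These marker-derived labels are the
#' automatic training labels of the marker-guided learning scheme.
#'
#' @param nuclei integer label matrix from [segment_nuclei()].
#' @param marker_mask logical matrix of the same shape.
#' @param min_overlap overlap fraction in `(0, 1]` (default 0.5).
#' @return factor vector of length `max(nuclei)` with levels
#'   `c("melanoma", "other")`, named by label id.
#' @export
assign_labels <- function(nuclei, marker_mask, min_overlap = 0.5) {
  stopifnot_shape(nuclei, marker_mask, "labels and mask")
  stopifnot(min_overlap > 0, min_overlap <= 1)
  n <- max(nuclei)
  if (n == 0) {
    return(factor(character(0), levels = c("melanoma", "other")))
  }
  idx <- nuclei > 0
  ov <- tapply(marker_mask[idx], nuclei[idx], mean)
  frac <- rep(0, n)
  frac[as.integer(names(ov))] <- as.numeric(ov)
  cls <- ifelse(frac >= min_overlap, "melanoma", "other")
  stats::setNames(factor(cls, levels = c("melanoma", "other")),
                  as.character(seq_len(n)))
}

#' Per-nucleus geometry table of a label image
#'
#' @param labels integer label matrix.
#' @return data frame with `id`, centroid `x` (column), `y` (row), `area`.
#' @export
nuclei_table <- function(labels) {
  n <- max(labels)
  if (n == 0) {
    return(data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                      area = integer(0)))
  }
  idx <- which(labels > 0)
  ids <- labels[idx]
  rows <- (idx - 1L) %% nrow(labels) + 1L
  cols <- (idx - 1L) %/% nrow(labels) + 1L
  data.frame(
    id = seq_len(n),
    x = as.numeric(tapply(cols, ids, mean)),
    y = as.numeric(tapply(rows, ids, mean)),
    area = as.integer(tabulate(ids, n))
  )
}
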