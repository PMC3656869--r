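#' Segment the marker (Melan-A-style) binary mask from a DAB density image
#'
#' Thresholds the DAB density image, cleans it morphologically, removes small
#' components (the pigmentation guard: isolated melanin speckles and single
#' melanocytes are smaller than melanoma cell clusters), then grows the
#' retained clusters outward over a secondary, lower density threshold and
#' fills small holes. The result marks contiguous marker-positive tumour
#' regions.
#'
#' Pipeline order is fixed: threshold, close (disk r = 2), remove small
#' objects, region-grow, fill small holes.
#'
#' @param dab nonnegative DAB density matrix (OD units).
#' @param min_cluster_area minimum retained component area (px^2); acts as
#'   the pigment guard.
#' @param grow_radius region-growing radius (px).
#' @param threshold_method `"otsu"` (on nonzero densities) or `"fixed"`.
#' @param threshold fixed primary threshold when `threshold_method = "fixed"`.
#' @param grow_factor secondary (growth) threshold as a fraction of the
#'   primary threshold.
#' @return a logical matrix of class `binary_mask` with attributes
#'   `provenance` and `parameters`.
#' @export
segment_marker_mask <- function(dab, min_cluster_area = 400, grow_radius = 4,
                                threshold_method = c("otsu", "fixed"),
                                threshold = NULL, grow_factor = 0.5) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(all(dab >= 0))
  nz <- dab[dab > 1e-9]
  empty <- matrix(FALSE, nrow(dab), ncol(dab))
  if (length(nz) == 0) return(as_binary_mask(empty, "melan_a", list()))
  thr <- if (threshold_method == "fixed") threshold else otsu_threshold(nz)
  if (is.na(thr)) thr <- min(nz) / 2  # constant positive density: keep all
  bw <- dab >= thr
  bw <- eb_mat(EBImage::closing(EBImage::Image(bw * 1),
                                   EBImage::makeBrush(5, "disc"))) > 0.5
  bw <- remove_small_components(bw, min_cluster_area)
  if (grow_radius > 0 && any(bw)) {
    brush <- EBImage::makeBrush(2L * as.integer(grow_radius) + 1L, "disc")
    grown <- eb_mat(EBImage::dilate(EBImage::Image(bw * 1), brush)) > 0.5
    bw <- bw | (grown & dab >= grow_factor * thr)
  }
  bw <- fill_small_holes(bw, min_cluster_area)
  as_binary_mask(bw, "melan_a",
                 list(threshold = thr, min_cluster_area = min_cluster_area,
                      grow_radius = grow_radius, grow_factor = grow_factor))
}

#' Segment the tissue mask from a hematoxylin density image
#'
#' Marks all pixels with appreciable hematoxylin density (tissue) after a
#' morphological closing and small-object removal. The default is a fixed
#' low OD threshold (0.02): any measurable counterstain is tissue, while
#' blank glass deconvolves to essentially zero density; this keeps faintly
#' counterstained cytoplasm inside the mask, which object-level thresholds
#' (Otsu, robust background) would discard.
#'
#' @param hema nonnegative hematoxylin density matrix.
#' @param threshold_method `"fixed"`, `"robust_background"` or `"otsu"`.
#' @param threshold threshold when `threshold_method = "fixed"` (OD).
#' @param min_area small-object removal limit (px^2).
#' @return a logical `binary_mask`.
#' @export
segment_tissue_mask <- function(hema,
                                threshold_method = c("fixed",
                                                     "robust_background",
                                                     "otsu"),
                                threshold = 0.02, min_area = 64) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(all(hema >= 0))
  empty <- matrix(FALSE, nrow(hema), ncol(hema))
  if (all(hema <= 1e-9)) return(as_binary_mask(empty, "tissue", list()))
  thr <- switch(threshold_method,
    robust_background = robust_background_threshold(hema),
    otsu = otsu_threshold(hema[hema > 1e-9]),
    fixed = threshold)
  if (is.na(thr)) thr <- 1e-9
  bw <- hema > thr
  bw <- eb_mat(EBImage::closing(EBImage::Image(bw * 1),
                                   EBImage::makeBrush(5, "disc"))) > 0.5
  bw <- remove_small_components(bw, min_area)
  as_binary_mask(bw, "tissue", list(threshold = thr, min_area = min_area))
}

#' Summarise stain density inside a region of interest
#'
#' @param density density matrix.
#' @param mask logical matrix of the same shape.
#' @return list with `mean` (NA with `undefined = TRUE` for an empty mask),
#'   `total` and `area`.
#' @export
roi_intensity_summary <- function(density, mask) {
  stopifnot_shape(density, mask, "density and mask")
  area <- as.integer(sum(mask))
  if (area == 0) {
    return(list(mean = NA_real_, total = 0, area = 0L, undefined = TRUE))
  }
  total <- sum(density[mask])
  list(mean = total / area, total = total, area = area, undefined = FALSE)
}

#' Marker-positive area as a fraction of tissue area
#'
#' @param marker_mask,tissue_mask logical matrices of equal shape.
#' @return proportion `|marker intersect tissue| / |tissue|` in `[0, 1]`.
#' @export
area_ratio <- function(marker_mask, tissue_mask) {
  stopifnot_shape(marker_mask, tissue_mask, "masks")
  ta <- sum(tissue_mask)
  if (ta == 0) stop("undefined area ratio: empty tissue mask")
  sum(marker_mask & tissue_mask) / ta
}

as_binary_mask <- function(bw, provenance, parameters) {
  attr(bw, "provenance") <- provenance
  attr(bw, "parameters") <- parameters
  class(bw) <- c("binary_mask", class(bw))
  bw
}

remove_small_components <- function(bw, min_area) {
  if (!any(bw)) return(bw)
  lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
  tab <- tabulate(as.integer(lab[lab > 0]))
  keep <- which(tab >= min_area)
  matrix(as.integer(lab) %in% keep, nrow(bw), ncol(bw))
}

# Fill background holes (components of the complement not touching the image
# border) smaller than max_hole_area.
fill_small_holes <- function(bw, max_hole_area) {
  if (!any(!bw)) return(bw)
  lab <- EBImage::bwlabel(EBImage::Image((!bw) * 1))
  labm <- matrix(as.integer(lab), nrow(bw), ncol(bw))
  border_ids <- unique(c(labm[1, ], labm[nrow(bw), ], labm[, 1],
                         labm[, ncol(bw)]))
  tab <- tabulate(labm[labm > 0])
  fill <- setdiff(which(tab < max_hole_area), border_ids)
  out <- bw | (labm %in% fill)
  matrix(out, nrow(bw), ncol(bw))
}
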