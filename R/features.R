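#' The default per-nucleus feature catalogue (73 features)
#'
#' Defines the ordered feature set measured on each segmented nucleus from
#' the hematoxylin density channel: 12 morphology, 9 intensity, 13 Haralick,
#' 12 Gabor (3 frequencies x 4 orientations), 16 granularity (radii 1-16)
#' and 11 radial/edge-intensity features, 73 in total.
#'
#' @param gabor_frequencies spatial frequencies (cycles/px) of the Gabor
#'   bank.
#' @param gabor_orientations orientations in degrees.
#' @param granularity_radii strictly increasing structuring-element radii.
#' @param haralick_levels gray levels for co-occurrence quantization.
#' @param radial_zones number of concentric intensity zones.
#' @return a `feature_catalog` data frame with columns `name`, `family`.
#' @export
feature_catalog <- function(gabor_frequencies = c(0.1, 0.2, 0.4),
                            gabor_orientations = c(0, 45, 90, 135),
                            granularity_radii = 1:16,
                            haralick_levels = 8L,
                            radial_zones = 9L) {
  stopifnot(all(diff(granularity_radii) > 0), all(granularity_radii >= 1),
            haralick_levels >= 2, all(gabor_frequencies > 0))
  morph <- c("area", "perimeter", "form_factor", "eccentricity", "solidity",
             "extent", "major_axis", "minor_axis", "aspect_ratio",
             "compactness", "equiv_diameter", "convex_area")
  intens <- c("int_mean", "int_sd", "int_min", "int_max", "int_integrated",
              "int_median", "int_mad", "int_q1", "int_q3")
  har <- paste0("har_", c("asm", "contrast", "correlation", "variance",
                          "idm", "sum_avg", "sum_var", "sum_entropy",
                          "entropy", "diff_var", "diff_entropy",
                          "imc1", "imc2"))
  gab <- as.vector(outer(gabor_frequencies, gabor_orientations,
                         function(f, o) sprintf("gabor_f%03d_o%03d",
                                                round(f * 100), o)))
  gran <- sprintf("gran_r%d", granularity_radii)
  radial <- c("edge_mean", "mass_displacement",
              sprintf("radial_z%d", seq_len(radial_zones)))
  cat_df <- data.frame(
    name = c(morph, intens, har, gab, gran, radial),
    family = c(rep("morphology", length(morph)),
               rep("intensity", length(intens)),
               rep("haralick", length(har)),
               rep("gabor", length(gab)),
               rep("granularity", length(gran)),
               rep("radial", length(radial))),
    stringsAsFactors = FALSE
  )
  stopifnot(!anyDuplicated(cat_df$name))
  attr(cat_df, "gabor_frequencies") <- gabor_frequencies
  attr(cat_df, "gabor_orientations") <- gabor_orientations
  attr(cat_df, "granularity_radii") <- granularity_radii
  attr(cat_df, "haralick_levels") <- as.integer(haralick_levels)
  attr(cat_df, "radial_zones") <- as.integer(radial_zones)
  class(cat_df) <- c("feature_catalog", class(cat_df))
  cat_df
}

#' Granularity spectrum of a masked patch
#'
#' Morphological granulometry: the fraction (in percent) of image mass
#' removed between successive openings by reconstruction with disks of
#' increasing radius,
#' `g_i = 100 * (sum(O_{r[i-1]}) - sum(O_{r[i]})) / sum(patch)`
#' with `O_{r[0]} = patch`. Fine-grained (chromatin-like) texture loses its
#' mass at small radii; coarse blobs survive until the disk exceeds their
#' size. The structuring element is an octagonal approximation of the
#' Euclidean disk. `sum(g) <= 100`, with equality once the radii exceed the
#' largest structure.
#'
#' @param patch nonnegative matrix, zero outside the object.
#' @param radii strictly increasing positive integer radii.
#' @return numeric vector of length `length(radii)` (percentages). A
#'   zero-total patch yields an all-zero spectrum with attribute
#'   `degenerate = TRUE`.
#' @export
granularity_spectrum <- function(patch, radii = 1:16) {
  stopifnot(all(diff(radii) > 0), all(radii >= 1))
  total <- sum(patch)
  g <- numeric(length(radii))
  if (total <= 0) {
    attr(g, "degenerate") <- TRUE
    return(g)
  }
  prev_sum <- total
  empty_from <- FALSE
  for (i in seq_along(radii)) {
    if (empty_from) break  # later openings stay empty
    opened <- open_reconstruct(patch, radii[i])
    s <- sum(opened)
    g[i] <- 100 * (prev_sum - s) / total
    prev_sum <- s
    empty_from <- all(opened <= 0)
  }
  g
}

#' Haralick texture statistics of a masked patch
#'
#' Builds a symmetric, normalised gray-level co-occurrence matrix (GLCM)
#' after linear per-object quantization to `levels` bins, for each of the
#' four unit offsets (0, 45, 90, 135 degrees), and averages the 13 classic
#' Haralick statistics over offsets. Only pixel pairs lying entirely inside
#' the object contribute.
#'
#' A constant (single-level) patch returns the degenerate convention:
#' contrast and entropies 0, angular second moment 1, correlation 0, with
#' attribute `degenerate = TRUE`.
#'
#' @param patch numeric matrix of intensities.
#' @param mask logical matrix, `TRUE` inside the object (default: all).
#' @param levels number of gray levels (>= 2).
#' @return named numeric vector of 13 statistics.
#' @export
haralick_features <- function(patch, mask = NULL, levels = 8L) {
  stopifnot(levels >= 2)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(patch), ncol(patch))
  stopifnot_shape(patch, mask, "patch and mask")
  nm <- paste0("har_", c("asm", "contrast", "correlation", "variance", "idm",
                         "sum_avg", "sum_var", "sum_entropy", "entropy",
                         "diff_var", "diff_entropy", "imc1", "imc2"))
  vals <- patch[mask]
  lo <- min(vals); hi <- max(vals)
  if (hi - lo <= .Machine$double.eps * max(1, abs(hi))) {
    out <- stats::setNames(c(1, 0, 0, 0, 1, 2, 0, 0, 0, 0, 0, 0, 0), nm)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  q <- matrix(NA_integer_, nrow(patch), ncol(patch))
  q[mask] <- pmin(as.integer(floor((patch[mask] - lo) / (hi - lo) * levels)) +
                    1L, as.integer(levels))
  offsets <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
  acc <- matrix(0, length(nm), length(offsets))
  for (k in seq_along(offsets)) {
    P <- glcm_offset(q, offsets[[k]], as.integer(levels))
    acc[, k] <- haralick_from_glcm(P)
  }
  stats::setNames(rowMeans(acc), nm)
}

# Symmetric normalised GLCM for one offset, vectorized via index shifting.
glcm_offset <- function(q, off, levels) {
  nr <- nrow(q); nc <- ncol(q)
  di <- off[1]; dj <- off[2]
  i0 <- max(1L, 1L - di); i1 <- min(nr, nr - di)
  j0 <- max(1L, 1L - dj); j1 <- min(nc, nc - dj)
  a <- q[i0:i1, j0:j1]
  b <- q[(i0 + di):(i1 + di), (j0 + dj):(j1 + dj)]
  keep <- !is.na(a) & !is.na(b)
  P <- matrix(0, levels, levels)
  if (any(keep)) {
    idx <- (b[keep] - 1L) * levels + a[keep]
    tab <- tabulate(idx, levels * levels)
    P <- matrix(tab, levels, levels)
    P <- P + t(P)
    P <- P / sum(P)
  }
  P
}

.melmark_cache <- new.env(parent = emptyenv())

# Precomputed index matrices for an N-level GLCM (memoized: the statistics
# are evaluated for thousands of nuclei at a fixed level count).
glcm_geometry <- function(N) {
  key <- as.character(N)
  g <- .melmark_cache[[paste0("glcm", key)]]
  if (is.null(g)) {
    i <- matrix(seq_len(N), N, N)
    j <- t(i)
    g <- list(
      i = i, j = j,
      dij2 = (i - j)^2,
      idm_w = 1 / (1 + (i - j)^2),
      sum_groups = lapply(2:(2 * N), function(k) which(i + j == k)),
      sum_k = 2:(2 * N),
      diff_groups = lapply(0:(N - 1), function(k) which(abs(i - j) == k)),
      diff_k = 0:(N - 1)
    )
    .melmark_cache[[paste0("glcm", key)]] <- g
  }
  g
}

# The 13 Haralick statistics from one normalised symmetric GLCM.
haralick_from_glcm <- function(P) {
  N <- nrow(P)
  g <- glcm_geometry(N)
  px <- rowSums(P)
  mu <- sum(seq_len(N) * px)
  sg2 <- sum((seq_len(N) - mu)^2 * px)
  asm <- sum(P * P)
  contrast <- sum(g$dij2 * P)
  correlation <- if (sg2 > 1e-12) {
    sum((g$i - mu) * (g$j - mu) * P) / sg2
  } else 0
  variance <- sg2
  idm <- sum(g$idm_w * P)
  p_sum <- vapply(g$sum_groups, function(ix) sum(P[ix]), 0)
  sum_avg <- sum(g$sum_k * p_sum)
  sum_var <- sum((g$sum_k - sum_avg)^2 * p_sum)
  sum_entropy <- -sum(p_sum[p_sum > 0] * log(p_sum[p_sum > 0]))
  entropy <- -sum(P[P > 0] * log(P[P > 0]))
  p_diff <- vapply(g$diff_groups, function(ix) sum(P[ix]), 0)
  diff_avg <- sum(g$diff_k * p_diff)
  diff_var <- sum((g$diff_k - diff_avg)^2 * p_diff)
  diff_entropy <- -sum(p_diff[p_diff > 0] * log(p_diff[p_diff > 0]))
  # information measures of correlation
  pxy <- outer(px, px)
  hxy <- entropy
  pos <- P > 0 & pxy > 0
  hxy1 <- -sum(P[pos] * log(pxy[pos]))
  hxy2 <- -sum(pxy[pxy > 0] * log(pxy[pxy > 0]))
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  imc1 <- if (hx > 1e-12) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0))
  c(asm, contrast, correlation, variance, idm, sum_avg, sum_var,
    sum_entropy, entropy, diff_var, diff_entropy, imc1, imc2)
}

# Complex Gabor kernel, DC-free (zero sum), at frequency f (cycles/px) and
# orientation theta (radians).
gabor_kernel <- function(f, theta, gamma = 1, sigma = NULL) {
  if (is.null(sigma)) sigma <- 0.56 / f
  half <- max(2L, ceiling(2.5 * sigma))
  g <- expand.grid(y = -half:half, x = -half:half)
  xr <- g$x * cos(theta) + g$y * sin(theta)
  yr <- -g$x * sin(theta) + g$y * cos(theta)
  env <- exp(-(xr^2 + gamma^2 * yr^2) / (2 * sigma^2))
  carrier <- exp(2i * pi * f * xr)
  k <- env * carrier
  k <- k - sum(k) / sum(env) * env  # remove DC so flat patches respond 0
  matrix(k, 2L * half + 1L, 2L * half + 1L)
}

#' Gabor filter-bank responses of a masked patch
#'
#' Mean complex magnitude of the response of DC-free Gabor filters over the
#' object pixels, for each (frequency, orientation) pair.
#'
#' @param patch numeric matrix (zero outside the object).
#' @param mask logical matrix (default: all pixels).
#' @param frequencies cycles/px (> 0).
#' @param orientations degrees.
#' @return named numeric vector of length
#'   `length(frequencies) * length(orientations)`.
#' @export
gabor_features <- function(patch, mask = NULL,
                           frequencies = c(0.1, 0.2, 0.4),
                           orientations = c(0, 45, 90, 135)) {
  stopifnot(all(frequencies > 0))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(patch), ncol(patch))
  out <- numeric(0)
  for (f in frequencies) for (o in orientations) {
    k <- gabor_kernel(f, o * pi / 180)
    resp <- conv2_same(patch, k)
    out[sprintf("gabor_f%03d_o%03d", round(f * 100), o)] <-
      mean(Mod(resp)[mask])
  }
  out
}

# "Same"-size 2D convolution via zero-padded FFT (complex kernels allowed).
conv2_same <- function(x, k) {
  nr <- nrow(x) + nrow(k) - 1L
  nc <- ncol(x) + ncol(k) - 1L
  X <- matrix(0, nr, nc); X[seq_len(nrow(x)), seq_len(ncol(x))] <- x
  K <- matrix(0, nr, nc); K[seq_len(nrow(k)), seq_len(ncol(k))] <- k
  full <- stats::fft(stats::fft(X) * stats::fft(K), inverse = TRUE) / (nr * nc)
  r0 <- (nrow(k) - 1L) %/% 2L
  c0 <- (ncol(k) - 1L) %/% 2L
  full[r0 + seq_len(nrow(x)), c0 + seq_len(ncol(x))]
}

#' Equivalent-ellipse axes of a binary object
#'
#' Full axis lengths of the second-moment-equivalent ellipse of the pixel
#' set (a disk of radius r yields axes close to 2r). A single-pixel object
#' returns axes (1, 1) with attribute `degenerate = TRUE`.
#'
#' @param object_mask logical matrix.
#' @return named vector `c(major, minor)` in px, `major >= minor > 0`.
#' @export
ellipse_axes <- function(object_mask) {
  idx <- which(object_mask)
  if (length(idx) == 0) stop("empty object")
  if (length(idx) == 1) {
    out <- c(major = 1, minor = 1)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  rows <- (idx - 1L) %% nrow(object_mask) + 1L
  cols <- (idx - 1L) %/% nrow(object_mask) + 1L
  n <- length(idx)
  cy <- mean(rows); cx <- mean(cols)
  # population second moments with the 1/12 pixel-extent correction
  syy <- sum((rows - cy)^2) / n + 1 / 12
  sxx <- sum((cols - cx)^2) / n + 1 / 12
  sxy <- sum((rows - cy) * (cols - cx)) / n
  tr <- sxx + syy
  dt <- sxx * syy - sxy^2
  disc <- sqrt(pmax(tr^2 / 4 - dt, 0))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  c(major = 4 * sqrt(pmax(l1, 1e-12)), minor = 4 * sqrt(pmax(l2, 1e-12)))
}

# --- per-object feature computation -------------------------------------

object_perimeter <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- mask
  core <- p[2:(nr + 1L), 2:(nc + 1L)]
  exposed <- (core & !p[1:nr, 2:(nc + 1L)]) + (core & !p[3:(nr + 2L), 2:(nc + 1L)]) +
    (core & !p[2:(nr + 1L), 1:nc]) + (core & !p[2:(nr + 1L), 3:(nc + 2L)])
  sum(exposed)
}

convex_hull_area <- function(rows, cols) {
  if (length(rows) < 3) return(length(rows))
  pts <- unique(cbind(cols, rows))
  if (nrow(pts) < 3) return(length(rows))
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  n <- nrow(hp)
  x <- hp[, 1]; y <- hp[, 2]
  area <- abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
  per <- sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
  area + per / 2 + 1  # lattice-polygon pixel-count estimate
}

morphology_features <- function(mask) {
  idx <- which(mask)
  area <- length(idx)
  rows <- (idx - 1L) %% nrow(mask) + 1L
  cols <- (idx - 1L) %/% nrow(mask) + 1L
  per <- object_perimeter(mask)
  ax <- ellipse_axes(mask)
  conv <- max(convex_hull_area(rows, cols), area)
  bbox_area <- (diff(range(rows)) + 1) * (diff(range(cols)) + 1)
  c(area = area,
    perimeter = per,
    form_factor = 4 * pi * area / per^2,
    eccentricity = sqrt(pmax(1 - (ax["minor"] / ax["major"])^2, 0)),
    solidity = min(area / conv, 1),
    extent = area / bbox_area,
    major_axis = unname(ax["major"]),
    minor_axis = unname(ax["minor"]),
    aspect_ratio = unname(ax["major"] / ax["minor"]),
    compactness = per^2 / (4 * pi * area),
    equiv_diameter = 2 * sqrt(area / pi),
    convex_area = conv)
}

intensity_features <- function(vals) {
  qs <- stats::quantile(vals, c(0.25, 0.5, 0.75), names = FALSE)
  c(int_mean = mean(vals), int_sd = if (length(vals) > 1) sd(vals) else 0,
    int_min = min(vals), int_max = max(vals), int_integrated = sum(vals),
    int_median = qs[2], int_mad = stats::mad(vals),
    int_q1 = qs[1], int_q3 = qs[3])
}

radial_features <- function(patch, mask, zones = 9L) {
  idx <- which(mask)
  rows <- (idx - 1L) %% nrow(mask) + 1L
  cols <- (idx - 1L) %/% nrow(mask) + 1L
  vals <- patch[idx]
  total <- sum(vals)
  # mass displacement: intensity centroid vs binary centroid
  md <- if (total > 0) {
    sqrt((sum(rows * vals) / total - mean(rows))^2 +
         (sum(cols * vals) / total - mean(cols))^2)
  } else 0
  dm <- eb_mat(EBImage::distmap(EBImage::Image(mask * 1)))
  d <- dm[idx]
  dmax <- max(d)
  edge_mean <- mean(vals[d <= 1])
  zone_means <- numeric(zones)
  if (dmax > 0) {
    z <- pmin(floor((d - 0.5) / dmax * zones) + 1L, zones)  # 1 = edge ring
    zm <- tapply(vals, z, mean)
    zone_means[as.integer(names(zm))] <- as.numeric(zm)
  } else {
    zone_means[1] <- mean(vals)
  }
  c(edge_mean = edge_mean, mass_displacement = md,
    stats::setNames(zone_means, sprintf("radial_z%d", seq_len(zones))))
}

#' Extract the per-nucleus feature table
#'
#' Computes the full catalogue for every object of a label image from the
#' hematoxylin density channel. Texture families operate on the object's
#' bounding box with out-of-object pixels masked out; every feature is
#' computed strictly from that object's pixels. Degenerate statistics
#' (constant or tiny objects) are set to the documented conventions, never
#' NaN, and flagged in the `qc_degenerate` column.
#'
#' @param labels integer label matrix from [segment_nuclei()].
#' @param hema hematoxylin density matrix (typically the pre-processed
#'   H channel, see [preprocess_h_channel()]).
#' @param catalog a [feature_catalog()].
#' @param classes optional factor of per-nucleus class labels (from
#'   [assign_labels()]) copied into the table.
#' @param image_id identifier copied into the table.
#' @return data frame: `image_id`, `nucleus_id`, `class` (NA when no
#'   `classes` given), `qc_degenerate`, then one column per catalogue
#'   feature. All feature values are finite.
#' @export
extract_features <- function(labels, hema, catalog = feature_catalog(),
                             classes = NULL, image_id = "image") {
  stopifnot_shape(labels, hema, "labels and density")
  n <- max(labels)
  freqs <- attr(catalog, "gabor_frequencies")
  orients <- attr(catalog, "gabor_orientations")
  radii <- attr(catalog, "granularity_radii")
  levels <- attr(catalog, "haralick_levels")
  zones <- attr(catalog, "radial_zones")
  p <- nrow(catalog)
  out <- matrix(0, n, p, dimnames = list(NULL, catalog$name))
  degen <- logical(n)
  if (n > 0) {
    idx_all <- which(labels > 0)
    ids <- labels[idx_all]
    rows_all <- (idx_all - 1L) %% nrow(labels) + 1L
    cols_all <- (idx_all - 1L) %/% nrow(labels) + 1L
    by_id <- split(seq_along(ids), ids)
    # shared padded-FFT Gabor bank across objects of this image
    kernels <- list()
    knames <- character(0)
    for (f in freqs) for (o in orients) {
      kernels[[length(kernels) + 1L]] <- gabor_kernel(f, o * pi / 180)
      knames <- c(knames, sprintf("gabor_f%03d_o%03d", round(f * 100), o))
    }
    bbh <- vapply(by_id, function(s) diff(range(rows_all[s])) + 1L, 0L)
    bbw <- vapply(by_id, function(s) diff(range(cols_all[s])) + 1L, 0L)
    kmax <- max(vapply(kernels, nrow, 0L))
    P1 <- max(bbh) + kmax - 1L
    P2 <- max(bbw) + kmax - 1L
    KF <- lapply(kernels, function(k) {
      K <- matrix(0 + 0i, P1, P2)
      K[seq_len(nrow(k)), seq_len(ncol(k))] <- k
      stats::fft(K)
    })
    koff <- vapply(kernels, function(k) (nrow(k) - 1L) %/% 2L, 0L)
    for (id in seq_len(n)) {
      sel <- by_id[[as.character(id)]]
      r <- rows_all[sel]; cc <- cols_all[sel]
      r0 <- min(r); r1 <- max(r); c0 <- min(cc); c1 <- max(cc)
      mask <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
      mask[cbind(r - r0 + 1L, cc - c0 + 1L)] <- TRUE
      patch <- hema[r0:r1, c0:c1, drop = FALSE]
      patch[!mask] <- 0
      vals <- patch[mask]
      f_mor <- morphology_features(mask)
      f_int <- intensity_features(vals)
      f_har <- haralick_features(patch, mask, levels)
      X <- matrix(0, P1, P2)
      X[seq_len(nrow(patch)), seq_len(ncol(patch))] <- patch
      FX <- stats::fft(X)
      f_gab <- numeric(length(KF))
      for (k in seq_along(KF)) {
        full <- stats::fft(FX * KF[[k]], inverse = TRUE) / (P1 * P2)
        resp <- full[koff[k] + seq_len(nrow(patch)),
                     koff[k] + seq_len(ncol(patch))]
        f_gab[k] <- mean(Mod(resp)[mask])
      }
      names(f_gab) <- knames
      f_gra <- stats::setNames(granularity_spectrum(patch, radii),
                               sprintf("gran_r%d", radii))
      f_rad <- radial_features(patch, mask, zones)
      v <- c(f_mor, f_int, f_har, f_gab, f_gra, f_rad)
      degen[id] <- isTRUE(attr(f_har, "degenerate")) ||
        isTRUE(attr(f_gra, "degenerate")) || length(vals) < 4
      out[id, ] <- v[catalog$name]
    }
  }
  out[!is.finite(out)] <- 0
  res <- data.frame(
    image_id = rep(image_id, n),
    nucleus_id = seq_len(n),
    class = if (is.null(classes)) factor(rep(NA_character_, n),
                                         levels = c("melanoma", "other"))
            else classes[seq_len(n)],
    qc_degenerate = degen,
    stringsAsFactors = FALSE
  )
  cbind(res, as.data.frame(out))
}
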