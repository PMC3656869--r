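#' Parameters for synthetic IHC tissue-core scenes
#'
#' Bundles the knobs of the synthetic brightfield generator: image geometry,
#' per-class nucleus counts and sizes, the per-class chromatin grain radius
#' driving intra-nuclear texture, stain-density amplitudes (OD units), the
#' melanin-pigment speckle confounder, and packing behaviour.
#'
#' Presets:
#' * `"separable"` — fine-grained melanoma (grain 1.5 px) vs coarse other
#'   nuclei (grain 4 px), non-touching packing (centre spacing 1.2x the sum
#'   of radii).
#' * `"touching"` — same texture contrast but spacing 0.8x, so nuclei clump
#'   and declumping is exercised.
#' * `"hard"` — weak texture contrast (grain 2.5 vs 3 px) and touching
#'   packing.
#' * `"biomarker"` — separable texture, no pigment speckles; intended for
#'   [generate_biomarker_scene()].
#'
#' @param width,height image size in pixels.
#' @param n_melanoma,n_other nucleus count per class.
#' @param radius_mean,radius_sd mean/SD of nucleus semi-major radius (px).
#' @param aspect_max maximum major/minor axis ratio (axes drawn uniformly
#'   in `[1, aspect_max]`).
#' @param grain_melanoma,grain_other class texture grain radius (px).
#' @param hema_amp peak hematoxylin nuclear density (OD).
#' @param texture_sd intra-nuclear texture SD as a fraction of `hema_amp`.
#' @param dab_amp DAB density amplitude (OD) of marker-positive regions.
#' @param n_speckles,speckle_area_max pigment speckle count and maximum
#'   speckle area (px^2).
#' @param n_clusters number of melanoma cluster regions.
#' @param spacing minimum centre distance as a multiple of the sum of the
#'   two nuclei's radii (1.2 non-touching, 0.8 touching).
#' @param background blank-slide intensity (default 255).
#' @param seed integer RNG seed.
#' @param preset optional preset name (see Details); explicit arguments
#'   override preset values.
#' @return a `scene_params` list.
#' @export
scene_params <- function(width = 512, height = 512,
                         n_melanoma = 150, n_other = 150,
                         radius_mean = 6, radius_sd = 1,
                         aspect_max = 1.5,
                         grain_melanoma = 1.5, grain_other = 4,
                         hema_amp = 0.85, texture_sd = 0.22,
                         dab_amp = 0.4,
                         n_speckles = 6, speckle_area_max = 40,
                         n_clusters = 3,
                         spacing = 1.2,
                         background = 255,
                         seed = 1,
                         preset = NULL) {
  p <- as.list(environment())
  p$preset <- NULL
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("separable", "touching", "hard", "biomarker"))
    mc <- names(as.list(match.call()))  # explicitly supplied args win
    override <- function(name, value) {
      if (!(name %in% mc)) p[[name]] <<- value
    }
    if (preset == "touching") override("spacing", 0.8)
    if (preset == "hard") {
      override("spacing", 0.8)
      override("grain_melanoma", 2.5)
      override("grain_other", 3)
    }
    if (preset == "biomarker") {
      override("n_speckles", 0L)
    }
  }
  stopifnot(p$width >= 32, p$height >= 32,
            p$n_melanoma >= 0, p$n_other >= 0,
            p$hema_amp >= 0, p$dab_amp >= 0, p$texture_sd >= 0,
            p$background > 0, p$spacing > 0)
  class(p) <- "scene_params"
  p
}

# Dart-throw nucleus centres subject to the pairwise spacing rule.
# region_fn(n) draws n candidate (x, y); accept if inside image margin and
# spaced; error after bounded retries.
place_nuclei <- function(n, radii, spacing, width, height, region_fn,
                         placed = NULL, max_tries = 400L) {
  xs <- numeric(0); ys <- numeric(0); rs <- numeric(0)
  if (!is.null(placed) && nrow(placed) > 0) {
    xs <- placed$x; ys <- placed$y; rs <- placed$r
  }
  n_prior <- length(xs)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      xy <- region_fn(1L)
      x <- xy[1]; y <- xy[2]; r <- radii[i]
      if (x < r + 2 || x > width - r - 1 || y < r + 2 || y > height - r - 1) next
      if (length(xs) > 0) {
        mind <- sqrt((xs - x)^2 + (ys - y)^2) - spacing * (rs + r)
        if (any(mind < 0)) next
      }
      xs <- c(xs, x); ys <- c(ys, y); rs <- c(rs, r)
      ok <- TRUE
      break
    }
    if (!ok) {
      stop(sprintf(paste0("packing failure: could not place nucleus %d of %d ",
                          "after %d tries; reduce counts or image density"),
                   i, n, max_tries))
    }
  }
  data.frame(x = xs, y = ys, r = rs)[seq_len(n) + n_prior, , drop = FALSE]
}

# Smooth standardized noise field (unit SD) with blob scale ~ grain px.
noise_field <- function(height, width, grain) {
  z <- matrix(rnorm(height * width), height, width)
  sigma <- max(grain / 1.6, 0.35)
  z <- eb_mat(EBImage::gblur(EBImage::Image(z), sigma = sigma))
  z / max(sd(z), 1e-9)
}

# Paint one elliptical nucleus into the hematoxylin density matrix.
paint_nucleus <- function(hema, x, y, a, b, angle, amp, texture_sd, tex_field) {
  h <- nrow(hema); w <- ncol(hema)
  r <- ceiling(max(a, b)) + 1L
  i0 <- max(1L, floor(y - r)); i1 <- min(h, ceiling(y + r))
  j0 <- max(1L, floor(x - r)); j1 <- min(w, ceiling(x + r))
  ii <- i0:i1; jj <- j0:j1
  dy <- outer(ii - y, rep(1, length(jj)))
  dx <- outer(rep(1, length(ii)), jj - x)
  u <- (dx * cos(angle) + dy * sin(angle)) / a
  v <- (-dx * sin(angle) + dy * cos(angle)) / b
  rho2 <- u^2 + v^2
  inside <- rho2 <= 1
  if (!any(inside)) return(hema)
  base <- amp * (0.62 + 0.13 * (1 - rho2))
  tex <- amp * texture_sd * tex_field[ii, jj, drop = FALSE]
  dens <- pmin(pmax(base + tex, 0.1 * amp), amp)
  patch <- hema[ii, jj, drop = FALSE]
  patch[inside] <- pmax(patch[inside], dens[inside])
  hema[ii, jj] <- patch
  hema
}

disk_mask_into <- function(mask, x, y, r, value = TRUE) {
  h <- nrow(mask); w <- ncol(mask)
  i0 <- max(1L, floor(y - r)); i1 <- min(h, ceiling(y + r))
  j0 <- max(1L, floor(x - r)); j1 <- min(w, ceiling(x + r))
  ii <- i0:i1; jj <- j0:j1
  dy <- outer(ii - y, rep(1, length(jj)))
  dx <- outer(rep(1, length(ii)), jj - x)
  inside <- (dx^2 + dy^2) <= r^2
  sub <- mask[ii, jj, drop = FALSE]
  sub[inside] <- value
  mask[ii, jj] <- sub
  mask
}

# Core scene construction shared by the two generators.
build_scene <- function(params, cluster_dab = TRUE, positive_fraction = NULL) {
  p <- params
  with_seed(p$seed, {
    h <- p$height; w <- p$width
    hema <- matrix(0, h, w)
    dab <- matrix(0, h, w)
    marker_mask <- matrix(FALSE, h, w)

    # --- melanoma cluster geometry -------------------------------------
    # Fewer, larger clusters are used when the requested count does not fit.
    nuc_area <- pi * p$radius_mean^2
    centers <- NULL
    R <- 0
    if (p$n_melanoma > 0) {
      ok <- FALSE
      for (k in rev(seq_len(max(1L, p$n_clusters)))) {
        per_cluster <- ceiling(p$n_melanoma / k)
        R <- sqrt(per_cluster * nuc_area * max(p$spacing, 1)^2 * 3.2 / pi) +
          p$radius_mean + 4
        if (2 * R + 4 >= min(w, h)) next
        for (t in 1:300) {
          cx <- runif(k, R + 2, w - R - 1)
          cy <- runif(k, R + 2, h - R - 1)
          if (k == 1 ||
              min(dist(cbind(cx, cy))) > 2 * R + 3 * p$radius_mean) {
            ok <- TRUE; break
          }
        }
        if (ok) break
      }
      if (!ok) stop("packing failure: could not place melanoma clusters; enlarge image")
      centers <- cbind(cx, cy)
      for (q in seq_len(k)) {
        marker_mask <- disk_mask_into(marker_mask, cx[q], cy[q], R)
      }
    }

    # --- nucleus placement ---------------------------------------------
    rmax <- p$radius_mean + 3 * p$radius_sd
    # lower clamp keeps every nucleus above the detectable size floor
    # (a < 4 px semi-axis at this scale is not a credible nucleus)
    draw_radii <- function(n) pmax(pmin(rnorm(n, p$radius_mean, p$radius_sd),
                                        rmax), 4.2)
    mel <- NULL
    if (p$n_melanoma > 0) {
      radii <- draw_radii(p$n_melanoma)
      in_cluster <- function(n) {
        q <- sample.int(k, 1L)
        rr <- (R - rmax - 2) * sqrt(runif(1)); th <- runif(1, 0, 2 * pi)
        c(centers[q, 1] + rr * cos(th), centers[q, 2] + rr * sin(th))
      }
      mel <- place_nuclei(p$n_melanoma, radii, p$spacing, w, h, in_cluster)
    }
    oth <- NULL
    if (p$n_other > 0) {
      radii <- draw_radii(p$n_other)
      outside <- function(n) {
        for (t in 1:200) {
          x <- runif(1, 1, w); y <- runif(1, 1, h)
          if (is.null(centers)) return(c(x, y))
          dd <- sqrt((centers[, 1] - x)^2 + (centers[, 2] - y)^2)
          if (all(dd > R + rmax + 2)) return(c(x, y))
        }
        c(-1, -1)  # rejected by bounds check
      }
      oth <- place_nuclei(p$n_other, radii, p$spacing, w, h, outside,
                          placed = mel)
    }

    nuclei <- data.frame(x = numeric(0), y = numeric(0))
    rows <- list()
    if (!is.null(mel)) rows$mel <- cbind(mel, class = "melanoma")
    if (!is.null(oth)) rows$oth <- cbind(oth, class = "other")
    if (length(rows) > 0) {
      nuclei <- do.call(rbind, rows)
      rownames(nuclei) <- NULL
      n <- nrow(nuclei)
      nuclei$aspect <- runif(n, 1, p$aspect_max)
      nuclei$angle <- runif(n, 0, pi)
      nuclei$a <- nuclei$r
      nuclei$b <- pmax(nuclei$r / nuclei$aspect, 3.4)
      nuclei$id <- seq_len(n)
      nuclei$biomarker_positive <- FALSE
    }

    # --- intra-nuclear texture ------------------------------------------
    if (nrow(nuclei) > 0) {
      tex_mel <- noise_field(h, w, p$grain_melanoma)
      tex_oth <- noise_field(h, w, p$grain_other)
      for (i in seq_len(nrow(nuclei))) {
        tf <- if (nuclei$class[i] == "melanoma") tex_mel else tex_oth
        hema <- paint_nucleus(hema, nuclei$x[i], nuclei$y[i],
                              nuclei$a[i], nuclei$b[i], nuclei$angle[i],
                              p$hema_amp, p$texture_sd, tf)
      }
    }

    # --- faint diffuse counterstain -------------------------------------
    # Cropped TMA core images are filled by tissue carrying a light
    # cytoplasmic hematoxylin blush; it also makes the tissue mask a
    # superset of the marker clusters. Blank scenes stay blank.
    if (nrow(nuclei) > 0 || any(marker_mask)) {
      blush <- 0.03 * p$hema_amp * (1 + 0.35 * noise_field(h, w, 1))
      hema <- pmax(hema, pmax(blush, 0.005 * p$hema_amp))
    }

    # --- DAB placement ---------------------------------------------------
    if (cluster_dab && p$n_melanoma > 0 && p$dab_amp > 0) {
      mod <- noise_field(h, w, 8)
      dab[marker_mask] <- p$dab_amp *
        pmin(pmax(0.85 + 0.1 * mod[marker_mask], 0.6), 1)
    }
    if (!is.null(positive_fraction) && nrow(nuclei) > 0) {
      midx <- which(nuclei$class == "melanoma")
      npos <- round(positive_fraction * length(midx))
      pos <- if (npos > 0) sample(midx, npos) else integer(0)
      nuclei$biomarker_positive[pos] <- TRUE
      for (i in pos) {
        # nuclear/perinuclear marker staining
        dab <- paint_dab_ellipse(dab, nuclei$x[i], nuclei$y[i],
                                 1.25 * nuclei$a[i], 1.25 * nuclei$b[i],
                                 nuclei$angle[i], p$dab_amp)
      }
    }
    if (cluster_dab && p$n_speckles > 0 && p$dab_amp > 0) {
      rmax_sp <- max(1, floor(sqrt(p$speckle_area_max / pi)))
      placed_sp <- 0L; tries <- 0L
      while (placed_sp < p$n_speckles && tries < 400L * p$n_speckles) {
        tries <- tries + 1L
        x <- runif(1, 4, w - 3); y <- runif(1, 4, h - 3)
        if (!is.null(centers)) {
          dd <- sqrt((centers[, 1] - x)^2 + (centers[, 2] - y)^2)
          if (any(dd < R + rmax_sp + 4)) next
        }
        r <- runif(1, 1, rmax_sp)
        spmask <- matrix(FALSE, h, w)
        spmask <- disk_mask_into(spmask, x, y, r)
        dab[spmask] <- pmax(dab[spmask], 1.2 * p$dab_amp)
        placed_sp <- placed_sp + 1L
      }
    }

    image <- render_rgb(hema, dab, default_stain_matrix(),
                        background_intensity = p$background)
    scene <- list(
      image = image,
      nuclei = nuclei,
      marker_mask_truth = marker_mask,
      stain_densities_truth = list(hematoxylin = hema, dab = dab),
      params = p,
      seed = p$seed
    )
    class(scene) <- "synthetic_scene"
    scene
  })
}

paint_dab_ellipse <- function(dab, x, y, a, b, angle, amp) {
  h <- nrow(dab); w <- ncol(dab)
  r <- ceiling(max(a, b)) + 1L
  i0 <- max(1L, floor(y - r)); i1 <- min(h, ceiling(y + r))
  j0 <- max(1L, floor(x - r)); j1 <- min(w, ceiling(x + r))
  ii <- i0:i1; jj <- j0:j1
  dy <- outer(ii - y, rep(1, length(jj)))
  dx <- outer(rep(1, length(ii)), jj - x)
  u <- (dx * cos(angle) + dy * sin(angle)) / a
  v <- (-dx * sin(angle) + dy * cos(angle)) / b
  inside <- (u^2 + v^2) <= 1
  sub <- dab[ii, jj, drop = FALSE]
  sub[inside] <- pmax(sub[inside], amp)
  dab[ii, jj] <- sub
  dab
}

#' Generate a synthetic IHC tissue-core scene
#'
#' Builds a two-stain (hematoxylin + DAB) brightfield image under the
#' Beer-Lambert model with full ground truth. Melanoma nuclei lie inside
#' contiguous cluster regions that also carry DAB (marker) density, emulating
#' Melan-A staining; other nuclei lie outside. The two classes differ in
#' intra-nuclear chromatin texture grain. Optional small isolated DAB blobs
#' outside clusters emulate melanin pigment.
#'
#' @param params a [scene_params()] object.
#' @return a `synthetic_scene`: list with `image` (h x w x 3, 8-bit levels),
#'   `nuclei` (data frame: id, centre x/y, semi-axes a/b, angle, class,
#'   biomarker_positive), `marker_mask_truth` (logical matrix),
#'   `stain_densities_truth` (list of `hematoxylin`, `dab` matrices),
#'   `params` and `seed`.
#' @examples
#' sc <- generate_tma_core(scene_params(width = 128, height = 128,
#'                                      n_melanoma = 8, n_other = 8, seed = 1))
#' dim(sc$image)
#' @export
generate_tma_core <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  build_scene(params, cluster_dab = TRUE)
}

#' Generate a synthetic biomarker (Ki67-style) scene
#'
#' Like [generate_tma_core()] but DAB is deposited as nuclear/perinuclear
#' staining on an exact-count random subset of melanoma nuclei rather than as
#' a tumour-area mask: `round(positive_fraction * n_melanoma)` nuclei are
#' drawn without replacement and flagged positive in the truth table.
#'
#' @param params a [scene_params()] object (preset `"biomarker"` recommended).
#' @param positive_fraction proportion in `[0, 1]` of melanoma nuclei that
#'   carry marker staining.
#' @return a `synthetic_scene` (see [generate_tma_core()]).
#' @export
generate_biomarker_scene <- function(params, positive_fraction) {
  stopifnot(inherits(params, "scene_params"),
            positive_fraction >= 0, positive_fraction <= 1)
  build_scene(params, cluster_dab = FALSE,
              positive_fraction = positive_fraction)
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "Synthetic scene %dx%d: %d melanoma + %d other nuclei (seed %d)\n",
    dim(x$image)[1], dim(x$image)[2],
    sum(x$nuclei$class == "melanoma"), sum(x$nuclei$class == "other"),
    x$seed))
  invisible(x)
}

#' Write a synthetic scene to disk
#'
#' Writes the RGB image and truth mask as lossless PNG and the nucleus truth
#' table as CSV. Requires the `png` package.
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return invisibly, the paths written.
#' @export
write_scene <- function(scene, dir, prefix = "scene") {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required to write scenes")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img <- aperm(scene$image / scene$params$background, c(1, 2, 3))
  p_img <- file.path(dir, paste0(prefix, ".png"))
  png::writePNG(img, p_img)
  p_mask <- file.path(dir, paste0(prefix, "_marker_mask.png"))
  png::writePNG(scene$marker_mask_truth * 1, p_mask)
  p_csv <- file.path(dir, paste0(prefix, "_nuclei.csv"))
  utils::write.csv(scene$nuclei, p_csv, row.names = FALSE)
  invisible(c(image = p_img, mask = p_mask, nuclei = p_csv))
}
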