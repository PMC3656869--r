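#' Build a stain matrix from hematoxylin and DAB colour vectors
#'
#' Constructs the 3x3 orthonormal-style colour deconvolution matrix used to
#' unmix a brightfield RGB image into hematoxylin, DAB and residual
#' optical-density (OD) channels. Rows are L2-normalised; the residual row is
#' the normalised cross product of the two stain rows, hence orthogonal to
#' both.
#'
#' @param hema_vector length-3 numeric, OD components (R, G, B) of the
#'   hematoxylin stain.
#' @param dab_vector length-3 numeric, OD components of the DAB stain
#'   (the channel carrying the immunohistochemical marker signal).
#' @return a `stain_matrix`: 3x3 numeric matrix with rows
#'   `hematoxylin`, `dab`, `residual` and columns `R`, `G`, `B`.
#' @examples
#' M <- build_stain_matrix(c(0.575, 0.681, 0.453), c(0.269, 0.570, 0.776))
#' rowSums(M^2)  # all 1
#' @export
build_stain_matrix <- function(hema_vector, dab_vector) {
  stopifnot(length(hema_vector) == 3L, length(dab_vector) == 3L)
  nh <- sqrt(sum(hema_vector^2)); nd <- sqrt(sum(dab_vector^2))
  if (nh == 0 || nd == 0) stop("stain vectors must be nonzero")
  h <- hema_vector / nh
  d <- dab_vector / nd
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  nr <- sqrt(sum(r^2))
  if (nr < 1e-8) stop("degenerate stain matrix: stain vectors are parallel")
  M <- rbind(hematoxylin = h, dab = d, residual = r / nr)
  colnames(M) <- c("R", "G", "B")
  class(M) <- c("stain_matrix", class(M))
  M
}

#' Default stain matrix (calibrated hematoxylin + DAB vectors)
#'
#' The shipped calibration uses hematoxylin (R = 0.575, G = 0.681, B = 0.453)
#' and DAB (R = 0.269, G = 0.570, B = 0.776) unit OD vectors, appropriate for
#' Melan-A / hematoxylin double-stained melanoma tissue cores.
#'
#' @return a `stain_matrix`.
#' @export
default_stain_matrix <- function() {
  build_stain_matrix(c(0.575, 0.681, 0.453), c(0.269, 0.570, 0.776))
}

#' Convert RGB intensities to optical density
#'
#' Applies the Beer-Lambert transform `OD = -log10(max(I, eps) / I0)` per
#' channel. The `eps` floor (default one gray level) guards `log(0)` for
#' saturated-black pixels without biasing mid-range densities; OD is clipped
#' at 0 so that pixels at (or above) the background intensity map to zero
#' density.
#'
#' @param image numeric array `h x w x 3` (or matrix for a single channel)
#'   of intensities in `[0, I0]`.
#' @param background_intensity `I0`, scalar or per-channel vector (> 0).
#' @param eps intensity floor in gray levels.
#' @return array of the same shape holding per-channel OD (>= 0).
#' @export
rgb_to_od <- function(image, background_intensity = 255, eps = 1) {
  if (any(background_intensity <= 0)) {
    stop("background intensity must be positive")
  }
  d <- dim(image)
  nch <- if (length(d) == 3L) d[3] else 1L
  I0 <- rep_len(background_intensity, nch)
  od <- array(0, dim = dim(image))
  for (c in seq_len(nch)) {
    ch <- if (length(d) == 3L) image[, , c] else image
    v <- pmax(-log10(pmax(ch, eps) / I0[c]), 0)
    if (length(d) == 3L) od[, , c] <- v else od <- v
  }
  od
}

#' Convert optical density back to RGB intensities
#'
#' Inverse of [rgb_to_od()] (up to quantization): `I = I0 * 10^(-OD)`.
#'
#' @param od array of per-channel OD values (>= 0).
#' @param background_intensity `I0`, scalar or per-channel.
#' @param quantize round to integer 8-bit gray levels.
#' @return intensity array of the same shape.
#' @export
od_to_rgb <- function(od, background_intensity = 255, quantize = TRUE) {
  d <- dim(od)
  nch <- if (length(d) == 3L) d[3] else 1L
  I0 <- rep_len(background_intensity, nch)
  img <- array(0, dim = dim(od))
  for (c in seq_len(nch)) {
    ch <- if (length(d) == 3L) od[, , c] else od
    v <- I0[c] * 10^(-ch)
    if (quantize) v <- pmin(pmax(round(v), 0), I0[c])
    if (length(d) == 3L) img[, , c] <- v else img <- v
  }
  img
}

#' Unmix an OD image into per-stain density images
#'
#' Solves, per pixel, `OD = density %*% M` for the density triple
#' (hematoxylin, DAB, residual). Negative solutions are clipped to zero after
#' solving; the clipped fraction is reported as a QC metric.
#'
#' @param od_image `h x w x 3` array of per-channel OD (from [rgb_to_od()]).
#' @param matrix a `stain_matrix`.
#' @param clip clip negative densities to zero (default `TRUE`).
#' @return a `stain_densities` list with matrices `hematoxylin`, `dab`,
#'   `residual`, plus `clip_fraction`.
#' @export
deconvolve <- function(od_image, matrix = default_stain_matrix(), clip = TRUE) {
  stopifnot(length(dim(od_image)) == 3L, dim(od_image)[3] == 3L)
  M <- unclass(matrix)
  if (abs(det(M)) < 1e-8) stop("degenerate stain matrix: not invertible")
  Minv <- solve(M)
  d <- dim(od_image)
  odm <- cbind(as.vector(od_image[, , 1]),
               as.vector(od_image[, , 2]),
               as.vector(od_image[, , 3]))
  dens <- odm %*% Minv
  clip_fraction <- mean(dens < -1e-12)
  if (clip) dens[dens < 0] <- 0
  out <- list(
    hematoxylin = matrix(dens[, 1], d[1], d[2]),
    dab         = matrix(dens[, 2], d[1], d[2]),
    residual    = matrix(dens[, 3], d[1], d[2]),
    clip_fraction = clip_fraction,
    stain_matrix = matrix
  )
  class(out) <- "stain_densities"
  out
}

#' Compose per-stain densities into an OD image
#'
#' Beer-Lambert forward model: `OD_c = sum_s density_s * M[s, c]`. This is
#' the exact inverse of [deconvolve()] on the float path.
#'
#' @param hema,dab matrices of stain densities (>= 0); `residual` optional.
#' @param matrix a `stain_matrix`.
#' @param residual optional residual-channel density matrix.
#' @return `h x w x 3` OD array.
#' @export
compose_od <- function(hema, dab, matrix = default_stain_matrix(),
                       residual = NULL) {
  stopifnot_shape(hema, dab, "stain densities")
  M <- unclass(matrix)
  d <- c(dim(hema), 3L)
  res <- if (is.null(residual)) 0 else as.vector(residual)
  od <- array(0, dim = d)
  for (c in 1:3) {
    od[, , c] <- hema * M[1, c] + dab * M[2, c] +
      matrix(res * M[3, c], d[1], d[2])
  }
  od
}

#' Render per-stain densities as an RGB brightfield image
#'
#' Composes densities into OD with [compose_od()] and exponentiates back to
#' quantized 8-bit intensities, simulating a scanned brightfield image.
#'
#' @inheritParams compose_od
#' @param background_intensity blank-slide intensity `I0`.
#' @param quantize round to integer gray levels (default `TRUE`).
#' @return `h x w x 3` intensity array.
#' @export
render_rgb <- function(hema, dab, matrix = default_stain_matrix(),
                       background_intensity = 255, quantize = TRUE) {
  od_to_rgb(compose_od(hema, dab, matrix),
            background_intensity = background_intensity, quantize = quantize)
}

#' @export
print.stain_matrix <- function(x, ...) {
  cat("Stain matrix (unit OD rows):\n")
  print(unclass(x), ...)
  invisible(x)
}

#' @export
print.stain_densities <- function(x, ...) {
  cat(sprintf("Stain densities %dx%d; clip fraction %.4f\n",
              nrow(x$hematoxylin), ncol(x$hematoxylin), x$clip_fraction))
  invisible(x)
}
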