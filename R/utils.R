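#' @keywords internal
"_PACKAGE"

#' @import stats
#' @import utils
NULL

# Run an expression under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a stage-specific seed from one global seed; keeps results < 2^31.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647L)
}

#' Otsu threshold of a numeric vector or matrix
#'
#' Thin wrapper around [EBImage::otsu()] that accepts arbitrary nonnegative
#' numeric data, rescales it to `[0, 1]`, and returns the threshold on the
#' original scale.
#'
#' @param x numeric vector or matrix of values.
#' @param levels number of histogram levels.
#' @return threshold on the scale of `x`; `NA` if `x` is constant or empty.
#' @export
otsu_threshold <- function(x, levels = 256L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  if (length(v) < 2L) return(NA_real_)
  lo <- min(v); hi <- max(v)
  if (hi - lo <= .Machine$double.eps * max(1, abs(hi))) return(NA_real_)
  img <- EBImage::Image(matrix((v - lo) / (hi - lo), ncol = 1L))
  thr <- EBImage::otsu(img, range = c(0, 1), levels = levels)
  lo + thr * (hi - lo)
}

# 3x3 (8-neighbour) grayscale dilation of a matrix, zero-padded; separable
# (vertical then horizontal max) to minimise R-level overhead.
dilate3x3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  v <- m
  if (nr > 1) {
    v[-nr, ] <- pmax.int(v[-nr, ], m[-1, ])
    v[-1, ] <- pmax.int(v[-1, ], m[-nr, ])
  }
  out <- v
  if (nc > 1) {
    out[, -nc] <- pmax.int(out[, -nc], v[, -1])
    out[, -1] <- pmax.int(out[, -1], v[, -nc])
  }
  dim(out) <- dim(m)
  out
}

# Grayscale erosion with an octagonal approximation of a disk of radius r:
# alternating 4- and 8-neighbourhood min filters. The patch is zero-padded
# once so object pixels on the bounding-box edge erode against background.
erode_disk <- function(m, r) {
  if (r <= 0) return(m)
  nr0 <- nrow(m); nc0 <- ncol(m)
  pad <- r + 1L
  x <- matrix(0, nr0 + 2L * pad, nc0 + 2L * pad)
  x[pad + seq_len(nr0), pad + seq_len(nc0)] <- m
  nr <- nrow(x); nc <- ncol(x)
  for (k in seq_len(r)) {
    v <- x
    v[-nr, ] <- pmin.int(v[-nr, ], x[-1, ])
    v[-1, ] <- pmin.int(v[-1, ], x[-nr, ])
    dim(v) <- dim(x)
    if (k %% 2L == 0L) {
      # square (8-neighbour) step: separable horizontal min of vertical min
      out <- v
      out[, -nc] <- pmin.int(out[, -nc], v[, -1])
      out[, -1] <- pmin.int(out[, -1], v[, -nc])
    } else {
      # cross (4-neighbour) step: centre row/column mins
      out <- v
      out[, -nc] <- pmin.int(out[, -nc], x[, -1])
      out[, -1] <- pmin.int(out[, -1], x[, -nc])
    }
    dim(out) <- dim(x)
    x <- out
  }
  x[pad + seq_len(nr0), pad + seq_len(nc0)]
}

# Morphological opening by reconstruction: erode by (approximate) disk of
# radius r, then geodesically dilate under the original until stable.
open_reconstruct <- function(m, r, max_iter = 200L) {
  marker <- erode_disk(m, r)
  if (all(marker <= 0)) return(marker * 0)
  for (i in seq_len(max_iter)) {
    nxt <- pmin(dilate3x3(marker), m)
    if (identical(nxt, marker) || max(abs(nxt - marker)) < 1e-12) break
    marker <- nxt
  }
  marker
}

# Deterministic relabeling of a label image: labels ordered by the
# column-major index of each object's first pixel (top-left-most).
relabel_ordered <- function(lab) {
  lab <- round(lab)
  ids <- sort(unique(as.integer(lab[lab > 0])))
  if (length(ids) == 0L) return(lab)
  first <- vapply(ids, function(i) which(lab == i)[1L], integer(1))
  ord <- ids[order(first)]
  out <- array(0L, dim = dim(lab))
  for (k in seq_along(ord)) out[lab == ord[k]] <- k
  out
}

stopifnot_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a)[1:2], dim(b)[1:2])) {
    stop(sprintf("shape mismatch between %s: %s vs %s", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  }
}

# Strip EBImage's S4 container: plain base matrix of the pixel data.
eb_mat <- function(img) {
  m <- EBImage::imageData(img)
  dim(m) <- dim(m)[1:2]
  as.matrix(m)
}
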