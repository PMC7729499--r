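# Pixel-level preprocessing: flat-field correction, opening-based background
# estimation, thresholding, labeling and the cytoskeleton-elaboration
# filters. All operators take and return plain numeric matrices
# (rows = image rows); border handling is replicate padding throughout, so
# background estimates carry no dark rim.

# block mean over f x f tiles (trailing partial tiles averaged over what fits)
.block_mean <- function(m, f) {
  nr <- nrow(m); nc <- ncol(m)
  nr2 <- ceiling(nr / f); nc2 <- ceiling(nc / f)
  ri <- rep(seq_len(nr2), each = f, length.out = nr)
  ci <- rep(seq_len(nc2), each = f, length.out = nc)
  sums <- rowsum(t(rowsum(m, ri)), ci)      # nc2 x nr2
  cnts <- rowsum(t(rowsum(matrix(1, nr, nc), ri)), ci)
  t(sums / cnts)
}

# bilinear resize of a matrix to target dimensions (pixel-centre aligned)
.resize_bilinear <- function(m, nr, nc) {
  sr <- nrow(m) / nr; sc <- ncol(m) / nc
  y <- pmin(pmax((seq_len(nr) - 0.5) * sr + 0.5, 1), nrow(m))
  x <- pmin(pmax((seq_len(nc) - 0.5) * sc + 0.5, 1), ncol(m))
  y0 <- pmax(pmin(floor(y), nrow(m) - 1L), 1L)
  x0 <- pmax(pmin(floor(x), ncol(m) - 1L), 1L)
  wy <- y - y0; wx <- x - x0
  a <- m[y0, x0, drop = FALSE]; b <- m[y0, x0 + 1, drop = FALSE]
  c_ <- m[y0 + 1, x0, drop = FALSE]; d <- m[y0 + 1, x0 + 1, drop = FALSE]
  top <- a * (1 - wx)[col(a)] + b * wx[col(b)]
  bot <- c_ * (1 - wx)[col(c_)] + d * wx[col(d)]
  top * (1 - wy)[row(top)] + bot * wy[row(bot)]
}

# replicate-pad a matrix by `p` pixels on every side
.pad_replicate <- function(m, p) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rep(1L, p), seq_len(nr), rep(nr, p))
  ci <- c(rep(1L, p), seq_len(nc), rep(nc, p))
  m[ri, ci, drop = FALSE]
}

#' Estimate and remove smooth multiplicative shading (flat-field correction)
#'
#' The shading field is estimated by large-scale Gaussian smoothing of the
#' image itself (scale far above the object size), the image is divided by
#' the normalized field, and the result is rescaled so the global mean is
#' exactly preserved.
#'
#' @param image numeric matrix.
#' @param smoothing_scale_px Gaussian sigma in pixels; should greatly exceed
#'   the typical object size (default 100).
#' @param prefilter_diameter_px optional disk diameter: when set, the shading
#'   field is estimated from the grayscale opening of the image (bright
#'   features narrower than the disk removed first), so sparse bright cells
#'   do not inflate the local estimate. `NULL` (default) smooths the raw
#'   image.
#' @param iterations number of estimate-and-divide passes (default 2): the
#'   smoothing that produces the estimate also flattens the shading bump
#'   itself a little, leaving a small residual; a second pass removes the
#'   residual of the first quadratically.
#' @return The corrected matrix, with the (combined) shading estimate attached
#'   as attribute `"shading"` and the smoothing scale as
#'   `"smoothing_scale_px"`. An all-zero image is returned unchanged with a
#'   warning (documented convention: empty fields must not crash a pipeline).
#' @export
flatfield_correct <- function(image, smoothing_scale_px = 100,
                              prefilter_diameter_px = NULL,
                              iterations = 2L) {
  stopifnot(is.matrix(image), smoothing_scale_px > 0, iterations >= 1)
  if (all(image == 0)) {
    warning("flatfield_correct: all-zero image returned unchanged")
    attr(image, "shading") <- matrix(1, nrow(image), ncol(image))
    attr(image, "smoothing_scale_px") <- smoothing_scale_px
    return(image)
  }
  sigma <- smoothing_scale_px
  corrected <- image
  shading_total <- matrix(1, nrow(image), ncol(image))
  for (pass in seq_len(iterations)) {
    base <- corrected
    # bright compact features inflate the local estimate: strip them first
    if (!is.null(prefilter_diameter_px))
      base <- opening_background(base, prefilter_diameter_px)$background
    shading <- .smooth_large_scale(base, sigma)
    if (any(!is.finite(shading)) || any(shading <= 0))
      stop("flatfield_correct: degenerate (non-positive) shading estimate")
    corrected <- corrected / (shading / mean(shading))
    shading_total <- shading_total * (shading / mean(shading))
  }
  corrected <- corrected * (mean(image) / mean(corrected))
  attr(corrected, "shading") <- shading_total
  attr(corrected, "smoothing_scale_px") <- smoothing_scale_px
  corrected
}

# Large-scale Gaussian smoothing with replicate borders. The field sought is
# smooth by assumption, so for large sigmas the blur runs on a block-mean
# downsampled image (sigma scaled accordingly) and is resized back: the same
# estimate to within a fraction of a percent, at a fraction of the cost.
.smooth_large_scale <- function(base, sigma) {
  f <- if (sigma >= 32) 4L else 1L
  small <- if (f > 1L) .block_mean(base, f) else base
  sig_s <- sigma / f
  rad <- ceiling(2.5 * sig_s)                # pad so the FFT never wraps
  pad <- .pad_replicate(small, rad)
  sm <- EBImage::gblur(EBImage::Image(t(pad)), sigma = sig_s,
                       radius = 2L * rad + 1L)
  sm <- t(EBImage::imageData(sm))
  sm <- sm[(rad + 1):(rad + nrow(small)), (rad + 1):(rad + ncol(small)),
           drop = FALSE]
  if (f > 1L) .resize_bilinear(sm, nrow(base), ncol(base)) else sm
}

# rasterized disk structuring element for a stated diameter: radius d/2,
# sampled on the smallest odd-sized grid that holds it
disk_se <- function(diameter_px) {
  stopifnot(diameter_px >= 3)
  r <- diameter_px / 2
  k <- floor(diameter_px / 2)
  ix <- seq(-k, k)
  d2 <- outer(ix^2, ix^2, "+")
  matrix(as.numeric(d2 <= r^2 + 1e-9), 2 * k + 1, 2 * k + 1)
}

#' Morphological-opening background estimation
#'
#' Grayscale opening (erosion followed by dilation) with a rasterized disk
#' structuring element estimates the smooth background lying under bright
#' features narrower than the disk. The result is anti-extensive (pointwise
#' at most the input) and idempotent.
#'
#' @param image numeric matrix.
#' @param disk_diameter_px disk diameter in pixels (default 20, i.e. a
#'   radius-10 rasterized disk).
#' @return Object of class `background_image`: list with `background` (numeric
#'   matrix) and `disk_diameter_px`.
#' @export
opening_background <- function(image, disk_diameter_px = 20) {
  stopifnot(is.matrix(image), disk_diameter_px >= 3)
  k <- disk_se(disk_diameter_px)
  # EBImage grayscale morphology expects intensities in [0, 1]; erosion and
  # dilation commute with increasing affine maps, so rescale in and out.
  # Its neighbourhood clipping at the frame equals replicate padding for a
  # disk structuring element.
  rg <- range(image)
  if (rg[1] == rg[2]) {
    return(structure(list(background = image,
                          disk_diameter_px = disk_diameter_px),
                     class = "background_image"))
  }
  x01 <- (image - rg[1]) / (rg[2] - rg[1])
  e <- EBImage::erode(EBImage::Image(t(x01)), k)
  d <- EBImage::dilate(e, k)
  op <- t(EBImage::imageData(d)) * (rg[2] - rg[1]) + rg[1]
  structure(list(background = op,
                 disk_diameter_px = disk_diameter_px),
            class = "background_image")
}

#' Subtract a background image, clamping at zero
#'
#' @param image numeric matrix.
#' @param background a `background_image` from [opening_background()] or a
#'   plain matrix of the same shape.
#' @return `pmax(image - background, 0)`, same shape.
#' @export
subtract_background <- function(image, background) {
  bg <- if (inherits(background, "background_image")) background$background
        else background
  if (!all(dim(image) == dim(bg)))
    stop("subtract_background: shape mismatch")
  pmax(image - bg, 0)
}

#' Threshold an image into a foreground mask
#'
#' @param image numeric matrix with at least two distinct values for
#'   automatic methods.
#' @param method `"otsu"` (default) or `"manual"`.
#' @param value threshold for `method = "manual"`.
#' @return Logical mask (`TRUE` = foreground, pixels strictly above the
#'   threshold) with the threshold attached as attribute `"threshold"`.
#' @export
threshold_mask <- function(image, method = c("otsu", "manual"), value = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(image))
  if (method == "manual") {
    if (is.null(value)) stop("threshold_mask: manual method needs `value`")
    th <- value
  } else {
    rg <- range(image)
    if (rg[1] == rg[2])
      stop("threshold_mask: constant image, automatic threshold is undefined")
    th <- EBImage::otsu(EBImage::Image(t(image)), range = rg, levels = 256)
  }
  mask <- image > th
  attr(mask, "threshold") <- th
  mask
}

#' Label connected foreground regions (8-connectivity)
#'
#' Components are 8-connected (diagonal contact joins regions); components
#' smaller than `min_area_px` are removed and the survivors relabelled
#' `1..K` in raster order of their first pixel, so labels are stable under
#' fixed input.
#'
#' @param mask logical matrix.
#' @param min_area_px minimum component area in pixels (smaller removed).
#' @return Integer matrix of labels, 0 = background.
#' @export
label_regions <- function(mask, min_area_px = 0) {
  stopifnot(is.matrix(mask))
  mask <- mask != 0
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask))))
  lab <- t(lab)
  nlab <- max(lab)
  if (nlab > 0) {
    # bwlabel is 4-connected; merge labels that touch diagonally
    parent <- seq_len(nlab)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    unite <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
    nr <- nrow(lab); nc <- ncol(lab)
    a <- lab[-nr, -nc]; b <- lab[-1, -1]
    for (k in which(a > 0 & b > 0 & a != b)) unite(a[k], b[k])
    a <- lab[-1, -nc]; b <- lab[-nr, -1]
    for (k in which(a > 0 & b > 0 & a != b)) unite(a[k], b[k])
    roots <- vapply(seq_len(nlab), find, 0L)
    lab[lab > 0] <- roots[lab[lab > 0]]
    # drop small components
    if (min_area_px > 0) {
      tab <- tabulate(lab[lab > 0], nbins = nlab)
      drop <- which(tab > 0 & tab < min_area_px)
      if (length(drop)) lab[lab %in% drop] <- 0L
    }
    # relabel consecutively in raster order of first occurrence
    present <- unique(as.vector(t(lab))[as.vector(t(lab)) > 0])
    if (length(present)) {
      remap <- integer(nlab); remap[present] <- seq_along(present)
      lab[lab > 0] <- remap[lab[lab > 0]]
    }
  }
  storage.mode(lab) <- "integer"
  lab
}

# true 2-D convolution (kernel flipped) with replicate padding, by shift-sum
.convolve2_replicate <- function(image, kernel) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  if (kr %% 2 == 0 || kc %% 2 == 0)
    stop("convolution kernel must have odd dimensions")
  pr <- (kr - 1) %/% 2; pc <- (kc - 1) %/% 2
  p <- max(pr, pc)
  pad <- .pad_replicate(image, p)
  nr <- nrow(image); nc <- ncol(image)
  out <- matrix(0, nr, nc)
  for (i in seq_len(kr)) for (j in seq_len(kc)) {
    w <- kernel[i, j]
    if (w == 0) next
    # convolution: output(r,c) += k(i,j) * x(r - (i - centre), c - (j - centre))
    di <- pr - (i - 1); dj <- pc - (j - 1)
    out <- out + w * pad[(p + 1 + di):(p + nr + di), (p + 1 + dj):(p + nc + dj)]
  }
  out
}

#' North-emboss ("north shadow") filter
#'
#' 3x3 convolution with the unit-sum north-emboss kernel
#' `rbind(c(1,2,1), c(0,1,0), c(-1,-2,-1))` under replicate padding:
#' constant images are left fixed and horizontal edges get a signed relief
#' response. This is the directional-shadow elaboration applied to
#' cytoskeleton images before merging with a colorized convolved copy.
#'
#' @param image numeric matrix.
#' @param kernel override the default emboss kernel (odd-sized).
#' @return Filtered matrix (same shape; values may be signed).
#' @export
north_shadow <- function(image,
                         kernel = rbind(c(1, 2, 1), c(0, 1, 0), c(-1, -2, -1))) {
  stopifnot(is.matrix(image))
  .convolve2_replicate(image, kernel)
}

#' Convolve a grayscale image and map it into one color channel
#'
#' @param image numeric matrix (expected scaled to `[0, 1]`).
#' @param kernel odd-sized numeric convolution kernel.
#' @param color `"red"`, `"green"` or `"blue"`.
#' @return `nrow x ncol x 3` array; the stated channel holds the clipped
#'   convolution result, the others are zero.
#' @export
convolve_colorize <- function(image, kernel, color = c("green", "red", "blue")) {
  color <- match.arg(color)
  conv <- pmin(pmax(.convolve2_replicate(image, kernel), 0), 1)
  out <- array(0, c(nrow(image), ncol(image), 3))
  out[, , match(color, c("red", "green", "blue"))] <- conv
  out
}

#' Merge the two elaborated cytoskeleton images
#'
#' Screen blend (`1 - (1 - a) * (1 - b)` per channel) of the grayscale
#' shadow image (replicated to RGB) with the colorized convolved image; both
#' inputs are expected in `[0, 1]` and are clipped before blending. Screen
#' blending is commutative and keeps either layer visible where the other is
#' dark, matching the overlay use of the two elaborations.
#'
#' @param shadow_image numeric matrix (grayscale).
#' @param colorized_image `nrow x ncol x 3` array.
#' @return `nrow x ncol x 3` array in `[0, 1]`.
#' @export
merge_elaborated <- function(shadow_image, colorized_image) {
  if (!all(dim(shadow_image) == dim(colorized_image)[1:2]))
    stop("merge_elaborated: shape mismatch")
  a <- pmin(pmax(shadow_image, 0), 1)
  out <- array(0, dim(colorized_image))
  for (ch in 1:3) {
    b <- pmin(pmax(colorized_image[, , ch], 0), 1)
    out[, , ch] <- 1 - (1 - a) * (1 - b)
  }
  out
}
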