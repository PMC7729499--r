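# Corrected total cell fluorescence (CTCF): per-cell integrated intensity
# corrected by an area-scaled background term estimated from five
# automatically sampled background regions.

#' Integrated density and area of a masked cell
#'
#' @param image numeric matrix.
#' @param mask logical matrix (nonempty) selecting one cell.
#' @return List with `cfid` (sum of pixel intensities under the mask) and
#'   `area_px2` (pixel count).
#' @export
measure_cfid <- function(image, mask) {
  if (!all(dim(image) == dim(mask))) stop("measure_cfid: shape mismatch")
  mask <- mask != 0
  if (!any(mask)) stop("measure_cfid: empty mask")
  list(cfid = sum(image[mask]), area_px2 = sum(mask))
}

#' Sample five disjoint background regions of interest
#'
#' Rectangular ROIs are placed by seeded rejection sampling so that they are
#' pairwise disjoint and free of foreground; the mean background fluorescence
#' `MFB` is the mean of the five ROI means, and `MAb` the mean ROI area.
#' Automated, seeded placement replaces the hand-drawn background boxes of a
#' manual workflow so runs are reproducible.
#'
#' @param image numeric matrix.
#' @param foreground_mask logical matrix of everything that is not background
#'   (all cell masks, typically slightly dilated).
#' @param roi_size ROI side length in pixels (default 30).
#' @param n_rois number of ROIs (default 5).
#' @param seed integer seed for placement.
#' @param max_tries bounded rejection-sampling budget.
#' @return Object of class `background_rois`: list with `rois` (data frame of
#'   `x0, y0, width, height, mean, area`), `MFB`, `MAb`.
#' @export
sample_background_rois <- function(image, foreground_mask, roi_size = 30,
                                   n_rois = 5, seed = 1L, max_tries = 2000L) {
  stopifnot(all(dim(image) == dim(foreground_mask)))
  nr <- nrow(image); nc <- ncol(image)
  if (roi_size >= nr || roi_size >= nc)
    stop("sample_background_rois: ROI larger than the image")
  fg <- foreground_mask != 0
  taken <- matrix(FALSE, nr, nc)
  rois <- list()
  with_seed(seed, {
    tries <- 0L
    while (length(rois) < n_rois && tries < max_tries) {
      tries <- tries + 1L
      r0 <- sample.int(nr - roi_size + 1L, 1L)
      c0 <- sample.int(nc - roi_size + 1L, 1L)
      rr <- r0:(r0 + roi_size - 1L); cc <- c0:(c0 + roi_size - 1L)
      if (any(fg[rr, cc]) || any(taken[rr, cc])) next
      taken[rr, cc] <- TRUE
      rois[[length(rois) + 1L]] <- data.frame(
        x0 = c0, y0 = r0, width = roi_size, height = roi_size,
        mean = mean(image[rr, cc]), area = length(rr) * length(cc))
    }
  })
  if (length(rois) < n_rois)
    stop(sprintf(paste0("sample_background_rois: could not place %d disjoint ",
                        "foreground-free ROIs of side %d (insufficient ",
                        "background area)"), n_rois, roi_size))
  rois <- do.call(rbind, rois)
  structure(list(rois = rois, MFB = mean(rois$mean), MAb = mean(rois$area)),
            class = "background_rois")
}

#' Corrected total cell fluorescence
#'
#' The default (`mode = "standard"`) computes
#' `CTCF = cFID - Ac * MFB`, the integrated cell intensity minus the mean
#' per-pixel background scaled by the cell area. `mode = "literal"` computes
#' the triple product `CTCF = cFID - Ac * MAb * MFB`, reproducing letter for
#' letter a published variant of the formula in which the mean background-ROI
#' area also enters; it is dimensionally inconsistent as an intensity
#' correction and is provided for fidelity only.
#'
#' @param cfid integrated cell intensity (a.u. * px^2).
#' @param ac masked cell area (px^2, > 0).
#' @param mfb mean background fluorescence per pixel (>= 0).
#' @param mab mean background-ROI area (px^2); required for `mode = "literal"`.
#' @param mode `"standard"` (default) or `"literal"`.
#' @return CTCF value with the mode attached as attribute `"mode"`.
#' @export
ctcf <- function(cfid, ac, mfb, mab = NULL, mode = c("standard", "literal")) {
  mode <- match.arg(mode)
  if (cfid < 0 || ac <= 0 || mfb < 0) stop("ctcf: negative or degenerate inputs")
  out <- if (mode == "standard") cfid - ac * mfb
  else {
    if (is.null(mab) || mab < 0) stop("ctcf: literal mode requires mab >= 0")
    cfid - ac * mab * mfb
  }
  attr(out, "mode") <- mode
  out
}

#' Per-cell CTCF quantification of one marker channel
#'
#' The full intensity-quantification chain: flat-field correction (optional),
#' opening-based background estimation and subtraction, per-cell integrated
#' density, seeded background-ROI sampling on the same preprocessed image,
#' and the CTCF formula.
#'
#' @param image numeric matrix (one marker channel).
#' @param cell_labels integer label matrix of the cells to quantify.
#' @param flatfield apply [flatfield_correct()] first (default `TRUE`).
#' @param smoothing_scale_px flat-field smoothing scale (default 100).
#' @param disk_diameter_px opening structuring-element diameter (default 20).
#' @param roi_size,seed background-ROI parameters, see
#'   [sample_background_rois()].
#' @param mode CTCF mode, see [ctcf()].
#' @param scene_id,channel identifiers recorded in the output.
#' @return Data frame with one row per cell: `scene_id`, `cell_id`, `channel`,
#'   `cFID`, `Ac`, `MFB`, `MAb`, `CTCF`, `mode`; the ROI table is attached as
#'   attribute `"rois"`.
#' @export
quantify_marker <- function(image, cell_labels, flatfield = TRUE,
                            smoothing_scale_px = 100, disk_diameter_px = 20,
                            roi_size = 30, seed = 1L,
                            mode = c("standard", "literal"),
                            scene_id = "scene", channel = "marker") {
  mode <- match.arg(mode)
  stopifnot(all(dim(image) == dim(cell_labels)))
  img <- image
  if (flatfield) img <- flatfield_correct(img, smoothing_scale_px,
                                          prefilter_diameter_px = disk_diameter_px)
  bg <- opening_background(img, disk_diameter_px)
  img <- subtract_background(img, bg)
  fg <- cell_labels > 0
  # keep ROIs clear of cell rims: dilate the foreground by the SE radius
  fgd <- EBImage::imageData(EBImage::dilate(
    EBImage::Image(t(fg)), disk_se(max(5, disk_diameter_px %/% 2))))
  rois <- sample_background_rois(img, t(fgd) > 0.5, roi_size = roi_size,
                                 seed = seed)
  labs <- sort(unique(cell_labels[cell_labels > 0]))
  rows <- lapply(labs, function(l) {
    m <- measure_cfid(img, cell_labels == l)
    v <- ctcf(m$cfid, m$area_px2, rois$MFB, rois$MAb, mode = mode)
    data.frame(scene_id = scene_id, cell_id = l, channel = channel,
               cFID = m$cfid, Ac = m$area_px2, MFB = rois$MFB,
               MAb = rois$MAb, CTCF = as.numeric(v), mode = mode)
  })
  out <- do.call(rbind, rows)
  attr(out, "rois") <- rois$rois
  out
}
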