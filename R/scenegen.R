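#' @useDynLib cytomorph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- RNG hygiene -----------------------------------------------------------

#' Evaluate an expression under a local, seeded RNG state
#'
#' Saves and restores `.Random.seed` so that seeded package internals never
#' disturb the caller's random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# ---- parameter containers --------------------------------------------------

#' Per-cell geometric and intensity parameters
#'
#' Describes one synthetic cell: either a spread fibroblast-like
#' ("mesenchymal") ellipse or a "polarized" cell, an elliptical body
#' enlargement with a single long, tapering protrusion emanating from one
#' pole. The nucleus is an ellipse that can be displaced along the cell axis
#' toward the protrusion neck, emulating the nuclear repositioning seen when
#' cells polarize.
#'
#' @param phenotype `"mesenchymal"` or `"polarized"`.
#' @param body_major_px,body_minor_px full axis lengths of the cell body
#'   ellipse in pixels (`body_major_px >= body_minor_px > 0`).
#' @param protrusion_length_px,protrusion_width_px protrusion length and neck
#'   width in pixels; must be positive iff `phenotype == "polarized"`.
#' @param orientation_deg orientation of the body major axis, degrees in
#'   `[0, 180)`; the protrusion points along `orientation_deg`.
#' @param nucleus_major_px,nucleus_minor_px nucleus ellipse axes in pixels,
#'   smaller than the corresponding body axes.
#' @param nucleus_offset_frac displacement of the nucleus centre toward the
#'   protrusion-side pole, as a fraction in `[0, 1]` of the body semi-major
#'   axis (0 = centred).
#' @param channel_levels named numeric vector of mean marker intensities
#'   (arbitrary units, >= 0), one entry per imaging channel.
#' @return An object of class `cell_params` (a validated list).
#' @export
cell_params <- function(phenotype = c("mesenchymal", "polarized"),
                        body_major_px, body_minor_px,
                        protrusion_length_px = 0, protrusion_width_px = 0,
                        orientation_deg = 0,
                        nucleus_major_px, nucleus_minor_px,
                        nucleus_offset_frac = 0,
                        channel_levels = c(marker = 100)) {
  phenotype <- match.arg(phenotype)
  stopifnot(is.numeric(body_major_px), is.numeric(body_minor_px))
  if (!(body_major_px >= body_minor_px && body_minor_px > 0))
    stop("cell_params: need body_major_px >= body_minor_px > 0")
  if (phenotype == "polarized") {
    if (!(protrusion_length_px > 0 && protrusion_width_px > 0))
      stop("cell_params: polarized phenotype requires positive protrusion length and width")
  } else if (protrusion_length_px != 0 || protrusion_width_px != 0) {
    stop("cell_params: mesenchymal phenotype must have zero protrusion fields")
  }
  if (!(nucleus_major_px < body_major_px && nucleus_minor_px < body_minor_px &&
        nucleus_minor_px > 0 && nucleus_major_px >= nucleus_minor_px))
    stop("cell_params: nucleus axes must be positive and smaller than body axes")
  if (nucleus_offset_frac < 0 || nucleus_offset_frac > 1)
    stop("cell_params: nucleus_offset_frac must lie in [0, 1]")
  orientation_deg <- orientation_deg %% 180
  if (is.null(names(channel_levels)) || any(channel_levels < 0))
    stop("cell_params: channel_levels must be a named, nonnegative vector")
  structure(list(
    phenotype = phenotype,
    body_major_px = body_major_px, body_minor_px = body_minor_px,
    protrusion_length_px = protrusion_length_px,
    protrusion_width_px = protrusion_width_px,
    orientation_deg = orientation_deg,
    nucleus_major_px = nucleus_major_px, nucleus_minor_px = nucleus_minor_px,
    nucleus_offset_frac = nucleus_offset_frac,
    channel_levels = channel_levels
  ), class = "cell_params")
}

#' Configuration of a synthetic fluorescence scene
#'
#' Collects everything needed to render one multi-channel field of view:
#' frame size, cell count and phenotype mixture, the sampling ranges for
#' per-cell parameters, the smooth multiplicative shading field, additive
#' background and pixel noise, the pixel-size calibration and the seed.
#' A fixed configuration (including its seed) renders bit-identically.
#'
#' @param width_px,height_px frame size in pixels.
#' @param n_cells number of cells to place (without body-mask overlap).
#' @param polarized_fraction probability in `[0, 1]` that a cell is polarized.
#' @param param_ranges named list of `c(min, max)` sampling ranges for the
#'   `cell_params` fields (see defaults in the function signature).
#' @param channels named list, one entry per channel; each entry is a list
#'   with `level = c(min, max)` mean-intensity range and `nuclear = TRUE`
#'   if the channel stains nuclei instead of the cell body.
#' @param shading list with `amplitude` (fraction of the mean, e.g. 0.3 for a
#'   30 percent bump) and `sigma_frac` (Gaussian sigma as a fraction of the
#'   frame diagonal). `amplitude = 0` gives a flat field.
#' @param background_level additive background intensity (a.u.).
#' @param noise list with `gaussian_sd` (a.u.) and logical `poisson`.
#' @param scale_um_per_px pixel size in micrometres per pixel.
#' @param seed integer seed controlling all sampling and noise.
#' @param max_place_tries bounded retry count for non-overlapping placement.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(width_px = 1388, height_px = 1040,
                         n_cells = 20, polarized_fraction = 0.5,
                         param_ranges = list(
                           body_major_px = c(60, 100),
                           body_aspect = c(1.2, 2.0),
                           protrusion_length_px = c(80, 220),
                           protrusion_width_px = c(6, 10),
                           nucleus_major_px = c(24, 34),
                           nucleus_aspect = c(1.0, 1.6),
                           nucleus_offset_frac = c(0.3, 0.7)
                         ),
                         channels = list(
                           marker = list(level = c(80, 120), nuclear = FALSE),
                           dapi   = list(level = c(150, 200), nuclear = TRUE)
                         ),
                         shading = list(amplitude = 0.2, sigma_frac = 0.4),
                         background_level = 20,
                         noise = list(gaussian_sd = 4, poisson = FALSE),
                         scale_um_per_px = 0.32,
                         seed = 1L,
                         max_place_tries = 100L) {
  stopifnot(width_px >= 16, height_px >= 16, n_cells >= 0,
            polarized_fraction >= 0, polarized_fraction <= 1,
            scale_um_per_px > 0, background_level >= 0)
  structure(list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    n_cells = as.integer(n_cells), polarized_fraction = polarized_fraction,
    param_ranges = param_ranges, channels = channels, shading = shading,
    background_level = background_level, noise = noise,
    scale_um_per_px = scale_um_per_px, seed = as.integer(seed),
    max_place_tries = as.integer(max_place_tries)
  ), class = "scene_config")
}

# ---- mask rasterization ----------------------------------------------------

# Pixel-centre coordinate grids for a frame; x runs along columns, y along
# rows (image convention, y increasing downward).
.coord_grid <- function(frame) {
  nr <- frame[1]; nc <- frame[2]
  list(x = matrix(rep(seq_len(nc), each = nr), nr, nc),
       y = matrix(rep(seq_len(nr), times = nc), nr, nc))
}

# Low-frequency radial ripple factor (bounded by amp_frac) for boundary
# perturbation; phases drawn from the current RNG stream.
.ripple_fun <- function(amp_frac) {
  ph <- stats::runif(2, 0, 2 * pi)
  function(theta) {
    amp_frac * (sin(3 * theta + ph[1]) + 0.6 * sin(5 * theta + ph[2])) / 1.6
  }
}

#' Rasterize a spread (mesenchymal) cell mask
#'
#' Renders a filled ellipse with full axes `body_major_px` x `body_minor_px`
#' at `center`, optionally perturbed by a seeded low-frequency radial ripple
#' whose boundary displacement stays below 10 percent of the minor axis.
#'
#' @param params a [cell_params()] object (phenotype `"mesenchymal"`).
#' @param frame integer `c(height_px, width_px)` of the target frame.
#' @param center numeric `c(x, y)` pixel position; defaults to frame centre.
#' @param ripple logical; perturb the boundary.
#' @param seed optional seed for the ripple phases.
#' @return Logical matrix of dimension `frame`; `TRUE` inside the cell.
#'   Errors if the mask would be clipped by the frame.
#' @export
make_mesenchymal_mask <- function(params, frame, center = NULL,
                                  ripple = FALSE, seed = NULL) {
  stopifnot(inherits(params, "cell_params"))
  mask <- with_seed(seed, .rasterize_cell(params, frame, center,
                                          ripple = ripple))
  if (.mask_clipped(mask)) stop("cell mask clipped by frame boundary")
  mask
}

#' Rasterize a polarized cell mask (body plus one tapering protrusion)
#'
#' The cell body is an ellipse; a single straight protrusion emanates from
#' the pole at `orientation_deg`, its half-width tapering linearly from
#' `protrusion_width_px / 2` at the neck to 1 px at the tip, so the tip stays
#' at least 2 px wide. The Euclidean distance from the protrusion tip to the
#' far body pole is `body_major_px + protrusion_length_px`.
#'
#' @inheritParams make_mesenchymal_mask
#' @return Logical mask matrix; errors if clipped or if the phenotype has no
#'   protrusion.
#' @export
make_polarized_mask <- function(params, frame, center = NULL,
                                ripple = FALSE, seed = NULL) {
  stopifnot(inherits(params, "cell_params"))
  if (params$protrusion_length_px <= 0)
    stop("make_polarized_mask: protrusion_length_px must be positive")
  mask <- with_seed(seed, .rasterize_cell(params, frame, center,
                                          ripple = ripple))
  if (.mask_clipped(mask)) stop("cell mask clipped by frame boundary")
  mask
}

.mask_clipped <- function(mask) {
  any(mask[1, ]) || any(mask[nrow(mask), ]) ||
    any(mask[, 1]) || any(mask[, ncol(mask)])
}

# Core rasterizer shared by both phenotypes. Returns a logical matrix over
# the full frame (cheap: evaluated only inside the cell's bounding box).
.rasterize_cell <- function(params, frame, center = NULL, ripple = FALSE) {
  nr <- frame[1]; nc <- frame[2]
  if (is.null(center)) center <- c(nc / 2, nr / 2)
  a2 <- params$body_major_px / 2
  b2 <- params$body_minor_px / 2
  th <- params$orientation_deg * pi / 180
  L <- params$protrusion_length_px
  wn <- params$protrusion_width_px / 2
  # bounding box: body radius plus protrusion extent, with slack
  ext <- a2 + max(L, 0) + max(b2, wn) + 3
  r0 <- max(1L, floor(center[2] - ext)); r1 <- min(nr, ceiling(center[2] + ext))
  c0 <- max(1L, floor(center[1] - ext)); c1 <- min(nc, ceiling(center[1] + ext))
  xs <- seq.int(c0, c1); ys <- seq.int(r0, r1)
  x <- matrix(rep(xs, each = length(ys)), length(ys), length(xs))
  y <- matrix(rep(ys, times = length(xs)), length(ys), length(xs))
  dx <- x - center[1]; dy <- y - center[2]
  # body-frame coordinates: u along the major axis (protrusion side positive)
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  rad2 <- (u / a2)^2 + (v / b2)^2
  if (ripple) {
    amp <- 0.08 * (b2 / a2)            # keeps boundary shift <= ~10% of minor axis
    rip <- .ripple_fun(amp)
    inside <- rad2 <= (1 + rip(atan2(v / b2, u / a2)))^2
  } else {
    inside <- rad2 <= 1
  }
  if (params$phenotype == "polarized" && L > 0) {
    # protrusion along +u from the pole at u = a2; embed the neck slightly
    # into the body so the union is connected after rasterization
    t <- (u - a2) / L
    hw <- wn * (1 - pmax(pmin(t, 1), 0)) + 1 * pmax(pmin(t, 1), 0)
    prot <- (u >= a2 - 2) & (u <= a2 + L) & (abs(v) <= hw)
    inside <- inside | prot
  }
  mask <- matrix(FALSE, nr, nc)
  mask[ys, xs] <- inside
  mask
}

# Nucleus mask for a placed cell: ellipse displaced along +u (toward the
# protrusion neck) by nucleus_offset_frac * semi-major body axis.
.rasterize_nucleus <- function(params, frame, center) {
  th <- params$orientation_deg * pi / 180
  off <- params$nucleus_offset_frac * params$body_major_px / 2
  ncenter <- center + off * c(cos(th), sin(th))
  np <- cell_params(
    phenotype = "mesenchymal",
    body_major_px = params$nucleus_major_px,
    body_minor_px = params$nucleus_minor_px,
    orientation_deg = params$orientation_deg,
    nucleus_major_px = params$nucleus_major_px / 2,
    nucleus_minor_px = params$nucleus_minor_px / 2,
    channel_levels = params$channel_levels
  )
  .rasterize_cell(np, frame, ncenter)
}

# ---- scene rendering -------------------------------------------------------

.sample_range <- function(rng) stats::runif(1, rng[1], rng[2])

.sample_cell_params <- function(cfg) {
  pr <- cfg$param_ranges
  polarized <- stats::runif(1) < cfg$polarized_fraction
  a <- .sample_range(pr$body_major_px)
  b <- a / .sample_range(pr$body_aspect)
  na <- .sample_range(pr$nucleus_major_px)
  nb <- na / .sample_range(pr$nucleus_aspect)
  nb <- min(nb, 0.9 * b)
  na <- max(na, nb)
  levels <- vapply(cfg$channels, function(ch) .sample_range(ch$level), 0.0)
  cell_params(
    phenotype = if (polarized) "polarized" else "mesenchymal",
    body_major_px = a, body_minor_px = b,
    protrusion_length_px = if (polarized) .sample_range(pr$protrusion_length_px) else 0,
    protrusion_width_px = if (polarized) .sample_range(pr$protrusion_width_px) else 0,
    orientation_deg = stats::runif(1, 0, 180),
    nucleus_major_px = na, nucleus_minor_px = nb,
    nucleus_offset_frac = if (polarized) .sample_range(pr$nucleus_offset_frac) else 0,
    channel_levels = levels
  )
}

.shading_field <- function(cfg) {
  nr <- cfg$height_px; nc <- cfg$width_px
  amp <- cfg$shading$amplitude
  if (is.null(amp) || amp == 0) return(matrix(1, nr, nc))
  sig <- cfg$shading$sigma_frac * sqrt(nr^2 + nc^2)
  cx <- stats::runif(1, 0.25, 0.75) * nc
  cy <- stats::runif(1, 0.25, 0.75) * nr
  g <- .coord_grid(c(nr, nc))
  f <- 1 + amp * exp(-(((g$x - cx)^2 + (g$y - cy)^2) / (2 * sig^2)))
  f / mean(f)
}

#' Render a synthetic multi-channel fluorescence scene with ground truth
#'
#' Places `n_cells` non-overlapping cells (rejection sampling with a bounded
#' retry count), renders each imaging channel as
#' `(signal + background) * shading + noise`, and returns the channel images
#' together with the full ground truth (per-cell parameters, labelled cell
#' and nucleus masks, the true shading field and the noise-free channels).
#' Channels flagged `nuclear = TRUE` render the displaced nuclei; all other
#' channels render the whole-cell mask at the cell's channel level.
#'
#' @param config a [scene_config()].
#' @return A list of class `scene` with elements `channels` (named list of
#'   numeric matrices, arbitrary units, clipped to `[0, 65535]`), `truth`
#'   (list: `cells`, `cell_labels`, `nucleus_labels`, `shading`,
#'   `clean_channels`), and `config`.
#' @export
render_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$seed, .render_scene_impl(config))
}

.render_scene_impl <- function(cfg) {
  nr <- cfg$height_px; nc <- cfg$width_px
  frame <- c(nr, nc)
  shading <- .shading_field(cfg)
  cell_labels <- matrix(0L, nr, nc)
  nucleus_labels <- matrix(0L, nr, nc)
  cells <- list()
  occupied <- matrix(FALSE, nr, nc)
  if (cfg$n_cells > 0) {
    for (i in seq_len(cfg$n_cells)) {
      p <- .sample_cell_params(cfg)
      ext <- p$body_major_px / 2 + p$protrusion_length_px + p$body_minor_px / 2 + 4
      if (2 * ext >= min(nr, nc))
        stop("render_scene: cell extent exceeds frame; enlarge the frame or shrink cells")
      placed <- FALSE
      for (try in seq_len(cfg$max_place_tries)) {
        center <- c(stats::runif(1, ext + 1, nc - ext - 1),
                    stats::runif(1, ext + 1, nr - ext - 1))
        m <- .rasterize_cell(p, frame, center)
        if (.mask_clipped(m) || any(occupied & m)) next
        # reserve a 3-px moat around the accepted mask so neighbouring cells
        # never touch (adjacent masks would fuse under 8-connected labeling)
        md <- t(EBImage::imageData(EBImage::dilate(EBImage::Image(t(m)),
                                                   disk_se(7)))) > 0.5
        occupied <- occupied | md
        cell_labels[m] <- i
        nm <- .rasterize_nucleus(p, frame, center) & m
        nucleus_labels[nm] <- i
        cells[[i]] <- c(p, list(center = center, id = i))
        placed <- TRUE
        break
      }
      if (!placed)
        stop(sprintf(paste0("render_scene: could not place cell %d without ",
                            "overlap after %d tries (frame too crowded)"),
                     i, cfg$max_place_tries))
    }
  }
  clean <- list()
  for (ch in names(cfg$channels)) {
    sig <- matrix(0, nr, nc)
    nuclear <- isTRUE(cfg$channels[[ch]]$nuclear)
    for (cell in cells) {
      lev <- cell$channel_levels[[ch]]
      if (nuclear) sig[nucleus_labels == cell$id] <- sig[nucleus_labels == cell$id] + lev
      else sig[cell_labels == cell$id] <- sig[cell_labels == cell$id] + lev
    }
    clean[[ch]] <- (sig + cfg$background_level) * shading
  }
  channels <- clean
  sd <- cfg$noise$gaussian_sd
  for (ch in names(channels)) {
    img <- channels[[ch]]
    if (isTRUE(cfg$noise$poisson)) img <- matrix(stats::rpois(length(img), pmax(img, 0)),
                                                 nr, nc)
    if (!is.null(sd) && sd > 0) img <- img + stats::rnorm(length(img), 0, sd)
    channels[[ch]] <- pmin(pmax(img, 0), 65535)
  }
  structure(list(
    channels = channels,
    truth = list(cells = cells, cell_labels = cell_labels,
                 nucleus_labels = nucleus_labels, shading = shading,
                 clean_channels = clean),
    config = cfg
  ), class = "scene")
}

# ---- scene I/O -------------------------------------------------------------

#' Write a rendered scene to disk
#'
#' Channels are written as single-page 16-bit grayscale TIFFs (intensities
#' clipped to `[0, 65535]`), the labelled cell and nucleus masks as 16-bit
#' TIFFs, the per-cell ground-truth parameters as JSON and the configuration
#' as YAML.
#'
#' @param scene a `scene` from [render_scene()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (ch in names(scene$channels)) {
    f <- file.path(dir, paste0("channel_", ch, ".tif"))
    EBImage::writeImage(EBImage::Image(t(round(scene$channels[[ch]]) / 65535)),
                        f, type = "tiff", bits.per.sample = 16L)
    files <- c(files, f)
  }
  for (nm in c("cell_labels", "nucleus_labels")) {
    f <- file.path(dir, paste0(nm, ".tif"))
    EBImage::writeImage(EBImage::Image(t(scene$truth[[nm]]) / 65535), f,
                        type = "tiff", bits.per.sample = 16L)
    files <- c(files, f)
  }
  truth <- lapply(scene$truth$cells, function(cell) {
    cell$channel_levels <- as.list(cell$channel_levels)
    cell
  })
  f <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(truth, f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  f <- file.path(dir, "scene_config.yaml")
  yaml::write_yaml(unclass(scene$config), f)
  files <- c(files, f)
  invisible(files)
}

#' Read a scene configuration from a YAML file
#'
#' The file holds the fields of [scene_config()] as plain keys; missing keys
#' fall back to the defaults.
#'
#' @param path path to a YAML config.
#' @return A `scene_config` object.
#' @export
read_scene_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(scene_config))
  do.call(scene_config, raw[intersect(names(raw), known)])
}

#' Read a grayscale image from TIFF or PNG
#'
#' Returns a plain numeric matrix in the original intensity units
#' (rescaled from EBImage's `[0, 1]` convention back to 16-bit counts when
#' `rescale_16bit = TRUE`).
#'
#' @param path image file path.
#' @param rescale_16bit multiply by 65535 (default, matches [write_scene()]).
#' @return Numeric matrix (rows = image rows).
#' @export
read_gray_image <- function(path, rescale_16bit = TRUE) {
  img <- EBImage::readImage(path)
  m <- t(EBImage::imageData(img))
  if (length(dim(m)) > 2) m <- m[, , 1]
  if (rescale_16bit) m <- m * 65535
  m
}
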