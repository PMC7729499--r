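# Shared fixtures and independent oracles, all built in code.

# ---- raster shapes ----------------------------------------------------------

raster_circle <- function(r, pad = 4) {
  n <- 2 * r + 2 * pad + 1
  ctr <- r + pad + 1
  g <- expand.grid(y = 1:n, x = 1:n)
  m <- matrix(FALSE, n, n)
  m[(g$y - ctr)^2 + (g$x - ctr)^2 <= r^2] <- TRUE
  m
}

raster_rect <- function(w, h, pad = 5) {
  m <- matrix(FALSE, h + 2 * pad, w + 2 * pad)
  m[(pad + 1):(pad + h), (pad + 1):(pad + w)] <- TRUE
  m
}

# horizontal rod (length L, thickness t) for nuclear-positioning toys
raster_rod <- function(L, t = 7, pad = 5) raster_rect(L, t, pad)

# random blob: union of a few random discs, first connected component
random_blob <- function(n = 40) {
  m <- matrix(FALSE, n, n)
  for (k in seq_len(sample(2:4, 1))) {
    cx <- stats::runif(1, n * 0.3, n * 0.7)
    cy <- stats::runif(1, n * 0.3, n * 0.7)
    r <- stats::runif(1, 3, n / 5)
    g <- expand.grid(y = 1:n, x = 1:n)
    m[(g$y - cy)^2 + (g$x - cx)^2 <= r^2] <- TRUE
  }
  label_regions(m) == 1
}

# ---- independent oracles ----------------------------------------------------

# brute-force max pairwise distance over all boundary-pixel corner points
oracle_feret <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  core <- pad[2:(nr + 1), 2:(nc + 1)] &
    pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  b <- which(mask & !core, arr.ind = TRUE)
  pts <- unique(cbind(c(b[, 2] - .5, b[, 2] - .5, b[, 2] + .5, b[, 2] + .5),
                      c(b[, 1] - .5, b[, 1] + .5, b[, 1] - .5, b[, 1] + .5)))
  d2 <- outer(pts[, 1], pts[, 1], "-")^2 + outer(pts[, 2], pts[, 2], "-")^2
  sqrt(max(d2))
}

# brute-force grayscale opening: min-then-max over the disk neighbourhood,
# with replicate (clamped) borders
oracle_opening <- function(x, diameter) {
  k <- floor(diameter / 2)
  ix <- seq(-k, k)
  d2 <- outer(ix^2, ix^2, "+")
  off <- which(d2 <= (diameter / 2)^2 + 1e-9, arr.ind = TRUE) - (k + 1)
  nr <- nrow(x); nc <- ncol(x)
  cl <- function(i, n) pmin(pmax(i, 1), n)
  ero <- matrix(0, nr, nc); dil <- matrix(0, nr, nc)
  for (i in 1:nr) for (j in 1:nc)
    ero[i, j] <- min(x[cbind(cl(i + off[, 1], nr), cl(j + off[, 2], nc))])
  for (i in 1:nr) for (j in 1:nc)
    dil[i, j] <- max(ero[cbind(cl(i + off[, 1], nr), cl(j + off[, 2], nc))])
  dil
}

# brute-force 2-D convolution (kernel flipped) with replicate borders
oracle_convolve <- function(x, kernel) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  pr <- (kr - 1) %/% 2; pc <- (kc - 1) %/% 2
  nr <- nrow(x); nc <- ncol(x)
  cl <- function(i, n) pmin(pmax(i, 1), n)
  out <- matrix(0, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    acc <- 0
    for (a in seq_len(kr)) for (b in seq_len(kc)) {
      di <- a - 1 - pr; dj <- b - 1 - pc
      acc <- acc + kernel[a, b] * x[cl(i - di, nr), cl(j - dj, nc)]
    }
    out[i, j] <- acc
  }
  out
}

# Ramanujan approximation of an ellipse perimeter (semi-axes a, b)
ramanujan_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

# ---- shared synthetic populations (expensive; built once per session) -------

.fixture_env <- new.env(parent = emptyenv())

# standard generator conditions used across the recovery tests: frame large
# enough for the default cell sizes, mixture half polarized, 1 um/px so
# lengths read directly in pixels
fixture_scene_config <- function(seed, n_cells = 5, noise = FALSE,
                                 polarized_fraction = 0.5) {
  scene_config(
    width_px = 1000, height_px = 1000, n_cells = n_cells,
    polarized_fraction = polarized_fraction,
    shading = if (noise) list(amplitude = 0.2, sigma_frac = 0.4)
              else list(amplitude = 0, sigma_frac = 0.4),
    noise = list(gaussian_sd = if (noise) 4 else 0, poisson = FALSE),
    scale_um_per_px = 1, seed = seed)
}

# 400 noise-free cells measured on ground-truth masks, with matched truth
recovery_population <- function() {
  if (!is.null(.fixture_env$pop)) return(.fixture_env$pop)
  cal <- calibration(1)
  cells <- list(); truth <- list()
  for (s in 1:80) {
    sc <- render_scene(fixture_scene_config(seed = 1000 + s))
    m <- measure_cells(sc$truth$cell_labels, sc$truth$nucleus_labels, cal,
                       scene_id = s)
    m$key <- paste(s, m$cell_id)
    for (cc in sc$truth$cells) truth[[paste(s, cc$id)]] <- cc
    cells[[s]] <- m
  }
  cells <- do.call(rbind, cells)
  tr <- truth[cells$key]
  cells$true_phenotype <- vapply(tr, function(x) x$phenotype, "")
  cells$true_ar <- vapply(tr, function(x) x$body_major_px / x$body_minor_px, 0)
  cells$true_cl <- vapply(tr, function(x) x$body_major_px + x$protrusion_length_px, 0)
  cells$true_protrusion <- vapply(tr, function(x) x$protrusion_length_px, 0)
  cells$true_orientation <- vapply(tr, function(x) x$orientation_deg, 0)
  .fixture_env$pop <- cells
  cells
}

# ~100 cells at default noise and shading, measured through segmentation,
# matched to ground truth by mask overlap
noisy_population <- function() {
  if (!is.null(.fixture_env$noisy)) return(.fixture_env$noisy)
  cal <- calibration(1)
  out <- list()
  for (s in 1:20) {
    sc <- render_scene(fixture_scene_config(seed = 5000 + s, noise = TRUE))
    seg <- segment_scene(sc)
    if (max(seg$cell_labels) == 0) next
    m <- measure_cells(seg$cell_labels, seg$nucleus_labels, cal, scene_id = s)
    tl <- sc$truth$cell_labels
    m$true_cl <- NA_real_; m$true_protrusion <- NA_real_; m$true_phenotype <- NA
    for (i in seq_len(nrow(m))) {
      inter <- tl[seg$cell_labels == m$cell_id[i]]
      tid <- as.integer(names(which.max(table(inter[inter > 0]))))
      if (length(tid) != 1) next
      tc <- sc$truth$cells[[tid]]
      ov <- sum(tl == tid & seg$cell_labels == m$cell_id[i]) /
        sum(tl == tid | seg$cell_labels == m$cell_id[i])
      if (ov < 0.5) next
      m$true_cl[i] <- tc$body_major_px + tc$protrusion_length_px
      m$true_protrusion[i] <- tc$protrusion_length_px
      m$true_phenotype[i] <- tc$phenotype
    }
    out[[s]] <- m
  }
  .fixture_env$noisy <- do.call(rbind, out)
  .fixture_env$noisy
}
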