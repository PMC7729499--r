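# Corrected total cell fluorescence: formula, background ROIs, end-to-end
# properties on synthetic scenes.

# small-bodied cells (narrower than the default opening disk) so the opening
# background model is exact: features narrower than the structuring element
# are removed completely
ctcf_scene <- function(levels = c(60, 120), amp = 0, sd = 0, seed = 5,
                       n = 8, polarized_fraction = 0) {
  scene_config(
    width_px = 384, height_px = 384, n_cells = n,
    polarized_fraction = polarized_fraction,
    param_ranges = list(body_major_px = c(13, 16), body_aspect = c(1.1, 1.3),
                        protrusion_length_px = c(0, 0),
                        protrusion_width_px = c(0, 0),
                        nucleus_major_px = c(6, 8), nucleus_aspect = c(1, 1.2),
                        nucleus_offset_frac = c(0, 0)),
    channels = list(marker = list(level = levels, nuclear = FALSE)),
    shading = list(amplitude = amp, sigma_frac = 0.4), background_level = 20,
    noise = list(gaussian_sd = sd, poisson = FALSE),
    scale_um_per_px = 1, seed = seed)
}

truth_levels <- function(sc) vapply(sc$truth$cells,
                                    function(x) x$channel_levels[["marker"]], 0)
truth_areas <- function(sc) vapply(seq_along(sc$truth$cells),
                                   function(l) sum(sc$truth$cell_labels == l), 0)

test_that("integrated density and area follow their definitions", {
  img <- matrix(0, 20, 20); mask <- matrix(FALSE, 20, 20)
  mask[3:7, 3:12] <- TRUE
  img[mask] <- 10
  m <- measure_cfid(img, mask)
  expect_equal(m$cfid, 500)
  expect_equal(m$area_px2, 50)
  expect_equal(measure_cfid(matrix(0, 20, 20), mask)$cfid, 0)
  expect_error(measure_cfid(img, matrix(FALSE, 20, 20)), "empty")
  # rendered noise-free cell: cFID = Ac * (level + background) exactly
  sc <- render_scene(ctcf_scene(seed = 9))
  l1 <- sc$truth$cell_labels == 1
  m1 <- measure_cfid(sc$channels$marker, l1)
  expect_equal(m1$cfid, sum(l1) * (truth_levels(sc)[1] + 20), tolerance = 1e-9)
})

test_that("background ROI sampling is seeded, disjoint and foreground-free", {
  img <- matrix(7, 200, 200)
  fg <- matrix(FALSE, 200, 200); fg[90:110, 90:110] <- TRUE
  r1 <- sample_background_rois(img, fg, roi_size = 30, seed = 4)
  r2 <- sample_background_rois(img, fg, roi_size = 30, seed = 4)
  expect_identical(r1$rois, r2$rois)
  expect_equal(r1$MFB, 7)
  expect_equal(r1$MAb, 900)
  expect_equal(nrow(r1$rois), 5)
  # disjointness and foreground avoidance
  hits <- matrix(0, 200, 200)
  for (i in 1:5) {
    rr <- r1$rois$y0[i]:(r1$rois$y0[i] + 29); cc <- r1$rois$x0[i]:(r1$rois$x0[i] + 29)
    hits[rr, cc] <- hits[rr, cc] + 1
    expect_false(any(fg[rr, cc]))
  }
  expect_lte(max(hits), 1)
  # gradient background: MFB bounded by the field's range
  grad <- matrix(rep(1:200, each = 200), 200, 200)
  rg <- sample_background_rois(grad, fg, roi_size = 30, seed = 4)
  expect_true(rg$MFB >= 1 && rg$MFB <= 200)
  # insufficient background errors with the constraint named
  expect_error(sample_background_rois(matrix(1, 40, 40),
                                      matrix(TRUE, 40, 40), roi_size = 30),
               "background")
})

test_that("the CTCF formula matches hand arithmetic in both modes", {
  expect_equal(as.numeric(ctcf(1000, 100, 2)), 800)
  expect_equal(as.numeric(ctcf(1000, 100, 0)), 1000)
  expect_equal(as.numeric(ctcf(1000, 100, 0, mab = 900, mode = "literal")), 1000)
  expect_equal(as.numeric(ctcf(1000, 10, 0.05, mab = 2, mode = "literal")),
               1000 - 10 * 2 * 0.05)
  expect_identical(attr(ctcf(10, 1, 1), "mode"), "standard")
  expect_error(ctcf(-1, 10, 1), "negative|degenerate")
  expect_error(ctcf(10, 10, 1, mode = "literal"), "mab")
})

test_that("end-to-end CTCF equals area x marker level on clean scenes", {
  sc <- render_scene(ctcf_scene())
  q <- quantify_marker(sc$channels$marker, sc$truth$cell_labels,
                       flatfield = FALSE, seed = 3)
  expect_equal(q$CTCF, truth_areas(sc) * truth_levels(sc), tolerance = 1e-6)
  # deterministic given the seed
  q2 <- quantify_marker(sc$channels$marker, sc$truth$cell_labels,
                        flatfield = FALSE, seed = 3)
  expect_identical(q, q2)
})

test_that("CTCF is linear in marker level (R^2 >= 0.99 noise-free)", {
  sc <- render_scene(ctcf_scene(levels = c(20, 200), seed = 21, n = 10))
  q <- quantify_marker(sc$channels$marker, sc$truth$cell_labels,
                       flatfield = FALSE, seed = 3)
  x <- truth_areas(sc) * truth_levels(sc)
  r2 <- suppressWarnings(summary(stats::lm(q$CTCF ~ x)))$r.squared
  expect_gte(r2, 0.99)
  # two subpopulations at levels c and 2c: mean CTCF-per-area ratio is 2
  sc2 <- render_scene(ctcf_scene(levels = c(50, 50), seed = 22, n = 4))
  sc3 <- render_scene(ctcf_scene(levels = c(100, 100), seed = 23, n = 4))
  qa <- quantify_marker(sc2$channels$marker, sc2$truth$cell_labels,
                        flatfield = FALSE, seed = 3)
  qb <- quantify_marker(sc3$channels$marker, sc3$truth$cell_labels,
                        flatfield = FALSE, seed = 3)
  expect_lt(abs(mean(qb$CTCF / qb$Ac) / mean(qa$CTCF / qa$Ac) - 2), 0.04)
})

test_that("CTCF ignores a constant intensity offset (absorbed by the background)", {
  sc <- render_scene(ctcf_scene(seed = 31))
  q0 <- quantify_marker(sc$channels$marker, sc$truth$cell_labels,
                        flatfield = FALSE, seed = 3)
  q1 <- quantify_marker(sc$channels$marker + 37, sc$truth$cell_labels,
                        flatfield = FALSE, seed = 3)
  expect_lt(max(abs(q1$CTCF / q0$CTCF - 1)), 0.02)
})

test_that("flat-fielding makes CTCF robust to multiplicative shading; skipping it does not", {
  sc <- render_scene(ctcf_scene(amp = 0.3, seed = 6))
  target <- truth_areas(sc) * truth_levels(sc)
  qon <- quantify_marker(sc$channels$marker, sc$truth$cell_labels,
                         flatfield = TRUE, smoothing_scale_px = 60, seed = 3)
  qoff <- quantify_marker(sc$channels$marker, sc$truth$cell_labels,
                          flatfield = FALSE, seed = 3)
  err_on <- max(abs(qon$CTCF / target - 1))
  err_off <- max(abs(qoff$CTCF / target - 1))
  expect_lt(err_on, 0.05)     # invariant with correction enabled
  expect_gt(err_off, err_on)  # and biased without it
})

test_that("a null marker yields CTCF at the noise floor", {
  sc <- render_scene(ctcf_scene(levels = c(0, 0), sd = 2, seed = 41))
  q <- quantify_marker(sc$channels$marker, sc$truth$cell_labels,
                       flatfield = FALSE, seed = 3)
  noise_floor <- 2 * sqrt(q$Ac)         # sd of a sum of Ac iid pixels
  expect_true(all(abs(q$CTCF) < 3 * noise_floor + 3 * q$Ac * 2 / sqrt(900)))
})
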