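# Shape descriptors and their analytic / brute-force oracles.

test_that("shape indices hit the circle, square and ellipse oracles", {
  for (r in c(30, 40, 50)) {
    expect_lt(abs(csi(region_properties(raster_circle(r))) - 1), 0.05)
  }
  expect_lt(abs(csi(region_properties(raster_rect(100, 100))) - pi / 4), 0.05)
  # rasterized 120 x 30 ellipse against the Ramanujan-perimeter analytic CSI
  p <- cell_params("mesenchymal", 120, 30, nucleus_major_px = 20,
                   nucleus_minor_px = 10)
  m <- make_mesenchymal_mask(p, c(160, 160))
  csi_analytic <- 4 * pi * (pi * 60 * 15) / ramanujan_perimeter(60, 15)^2
  expect_lt(abs(csi(region_properties(m)) / csi_analytic - 1), 0.05)
})

test_that("NSI is the same index as CSI and decreases with nucleus elongation", {
  pr <- region_properties(raster_circle(20))
  expect_identical(nsi(pr), csi(pr))
  thin <- region_properties(raster_rect(40, 10))
  fat <- region_properties(raster_rect(40, 30))
  expect_lt(nsi(thin), nsi(fat))
})

test_that("CSI is invariant under rotation and translation within 2%", {
  p0 <- cell_params("mesenchymal", 120, 30, nucleus_major_px = 20,
                    nucleus_minor_px = 10)
  vals <- vapply(c(0, 45, 90, 135), function(ang) {
    p <- cell_params("mesenchymal", 120, 30, orientation_deg = ang,
                     nucleus_major_px = 20, nucleus_minor_px = 10)
    csi(region_properties(make_mesenchymal_mask(p, c(180, 180))))
  }, 0.0)
  expect_lt(diff(range(vals)) / mean(vals), 0.02)
  shifted <- make_mesenchymal_mask(p0, c(200, 200), center = c(61.3, 122.7))
  expect_equal(csi(region_properties(shifted)),
               csi(region_properties(make_mesenchymal_mask(p0, c(200, 200)))),
               tolerance = 0.02)
})

test_that("aspect ratio matches axis ratios of ellipses and circles", {
  p <- cell_params("mesenchymal", 80, 20, nucleus_major_px = 12,
                   nucleus_minor_px = 8)
  m <- make_mesenchymal_mask(p, c(110, 110))
  expect_lt(abs(aspect_ratio(region_properties(m)) / 4 - 1), 0.03)
  expect_lt(abs(aspect_ratio(region_properties(raster_circle(35))) - 1), 0.03)
})

test_that("Feret estimator equals the brute-force pairwise oracle on random masks", {
  set.seed(2024)
  for (i in 1:40) {
    m <- random_blob(40)
    expect_equal(region_properties(m)$feret_max_px, oracle_feret(m),
                 tolerance = 1e-9)
  }
})

test_that("Feret diameter and angle of a rectangle match its diagonal", {
  pr <- region_properties(raster_rect(100, 20))
  expect_lt(abs(pr$feret_max_px / sqrt(100^2 + 20^2) - 1), 0.02)
  ang <- atan2(20, 100) * 180 / pi
  expect_lt(min(abs(pr$feret_angle_deg - ang),
                abs(pr$feret_angle_deg - (180 - ang))), 3)
})

test_that("cell length is the calibrated Feret diameter and validates the scale", {
  fake <- data.frame(feret_max_px = 500)
  expect_equal(cell_length(fake, calibration(0.32)), 160)
  expect_error(calibration(0), "positive")
  # generator ground truth: tip-to-far-pole distance in calibrated units
  p <- cell_params("polarized", 50, 30, 150, 8, orientation_deg = 25,
                   nucleus_major_px = 20, nucleus_minor_px = 12,
                   nucleus_offset_frac = 0.5)
  m <- make_polarized_mask(p, c(330, 330))
  expect_lt(abs(cell_length(region_properties(m), calibration(1)) - 200), 10)
})

test_that("nuclear positioning hits the rod oracles and stays in [1, 2]", {
  rod <- raster_rod(101)
  expect_equal(nuclear_positioning(rod, c(56, 8)), 2, tolerance = 0.01)
  expect_equal(nuclear_positioning(rod, c(6.5, 8)), 1, tolerance = 0.02)
  expect_equal(nuclear_positioning(rod, c(31, 8)), 4 / 3, tolerance = 0.02)
  expect_error(nuclear_positioning(rod, c(2, 2)), "outside")
  pop <- recovery_population()
  np <- pop$NP[is.finite(pop$NP)]
  expect_gt(length(np), 300)
  expect_true(all(np >= 1 & np <= 2))
})

test_that("protrusion measurement recovers straight protrusions and flags their absence", {
  p <- cell_params("polarized", 50, 30, 150, 8, orientation_deg = 35,
                   nucleus_major_px = 20, nucleus_minor_px = 12,
                   nucleus_offset_frac = 0.5)
  m <- make_polarized_mask(p, c(330, 330))
  pl <- protrusion_length(m, calibration(1))
  expect_lt(abs(as.numeric(pl) - 150), 8)
  expect_true(attr(pl, "detected"))
  expect_equal(attr(pl, "n_protrusions"), 1L)
  # plain ellipse: no neck, zero with flag
  e <- make_mesenchymal_mask(cell_params("mesenchymal", 80, 40,
                                         nucleus_major_px = 20,
                                         nucleus_minor_px = 12), c(120, 120))
  pe <- protrusion_length(e, calibration(1))
  expect_equal(as.numeric(pe), 0)
  expect_false(attr(pe, "detected"))
  # rotation by 90 degrees changes the measurement by < 2%
  p90 <- cell_params("polarized", 50, 30, 150, 8, orientation_deg = 125,
                     nucleus_major_px = 20, nucleus_minor_px = 12,
                     nucleus_offset_frac = 0.5)
  pl90 <- protrusion_length(make_polarized_mask(p90, c(330, 330)), calibration(1))
  expect_lt(abs(as.numeric(pl90) / as.numeric(pl) - 1), 0.02)
})

test_that("descriptors recover generator ground truth on noise-free cells (MARE <= 5%)", {
  pop <- recovery_population()
  expect_gte(nrow(pop), 300)
  mes <- pop$true_phenotype == "mesenchymal"
  pol <- !mes
  expect_lte(mean(abs(pop$AR[mes] - pop$true_ar[mes]) / pop$true_ar[mes]), 0.05)
  expect_lte(mean(abs(pop$CL_um - pop$true_cl) / pop$true_cl), 0.05)
  expect_lte(mean(abs(pop$protrusion_um[pol] - pop$true_protrusion[pol]) /
                    pop$true_protrusion[pol]), 0.05)
})

test_that("descriptors recover ground truth through segmentation at default noise (MARE <= 10%)", {
  pop <- noisy_population()
  ok <- is.finite(pop$true_cl)
  expect_gt(sum(ok), 60)
  expect_lte(mean(abs(pop$CL_um[ok] - pop$true_cl[ok]) / pop$true_cl[ok]), 0.10)
  pol <- ok & !is.na(pop$true_phenotype) & pop$true_phenotype == "polarized"
  expect_lte(mean(abs(pop$protrusion_um[pol] - pop$true_protrusion[pol]) /
                    pop$true_protrusion[pol]), 0.10)
})

test_that("phenotype classification agrees with the generator mixture", {
  pop <- recovery_population()
  # toy contracts
  round_cell <- data.frame(AR = 1.05, protrusion_um = 0, n_protrusions = 0L,
                           minor_axis_px = 40)
  expect_equal(classify_phenotype(round_cell, calibration(1)), "mesenchymal")
  # generator polarized cells classified as such (ground-truth agreement)
  pol <- pop$true_phenotype == "polarized"
  expect_gt(mean(pop$phenotype[pol] == "elongated_polarized"), 0.9)
  expect_gt(mean(pop$phenotype[!pol] == "mesenchymal"), 0.98)
  # mixture recovery at n = 400 within 3 binomial SE
  n <- nrow(pop)
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(mean(pop$phenotype == "elongated_polarized") - 0.5), 3 * se)
})

test_that("Feret angles of an isotropic population are uniform on [0, 180)", {
  pop <- recovery_population()
  angles <- pop$feret_angle_deg
  counts <- table(cut(angles, breaks = seq(0, 180, by = 20),
                      include.lowest = TRUE))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("a polarized cell has strictly larger AR than its body alone", {
  body <- cell_params("mesenchymal", 50, 30, nucleus_major_px = 20,
                      nucleus_minor_px = 12)
  full <- cell_params("polarized", 50, 30, 120, 8, nucleus_major_px = 20,
                      nucleus_minor_px = 12, nucleus_offset_frac = 0.5)
  ar_body <- aspect_ratio(region_properties(make_mesenchymal_mask(body, c(90, 90))))
  ar_full <- aspect_ratio(region_properties(make_polarized_mask(full, c(420, 420))))
  expect_gt(ar_full, ar_body)
})
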