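# Synthetic generators: determinism, calibration recovery, ground truth.

test_that("presets load, validate, and reject out-of-range calibrations", {
  expect_true(all(c("u2os_control", "u2os_capsaicin", "u2os_capsaicin_amg",
                    "saos2_control") %in% list_presets()))
  p <- get_preset("u2os_capsaicin")
  expect_s3_class(p, "generator_preset")
  expect_equal(p$nuclear_area_mean, 749.1)
  expect_equal(p$target_fd, 1.272)
  expect_equal(p$nc_ratio_mean, 0.4376)
  expect_error(get_preset("no_such_condition"), "unknown preset")
  expect_error(generator_preset("bad", nuclear_area_mean = -5))
  expect_error(generator_preset("bad", nuclear_area_mean = 500,
                                target_fd = 1.6))
  expect_error(generator_preset("bad", nuclear_area_mean = 500,
                                nc_ratio_mean = 1.2))
})

test_that("identical preset and seed give bit-identical output", {
  a <- make_nucleus_field("u2os_control", n = 10, seed = 5)
  b <- make_nucleus_field("u2os_control", n = 10, seed = 5)
  expect_identical(a, b)
  c1 <- make_fractal_contour(target_fd = 1.1, grid_size = 256, seed = 9)
  c2 <- make_fractal_contour(target_fd = 1.1, grid_size = 256, seed = 9)
  expect_identical(c1, c2)
  f1 <- make_fluor_cell("u2os_capsaicin", seed = 2)
  f2 <- make_fluor_cell("u2os_capsaicin", seed = 2)
  expect_identical(f1, f2)
  # different seeds differ
  expect_false(identical(a$labels,
                         make_nucleus_field("u2os_control", n = 10,
                                            seed = 6)$labels))
  # the caller's RNG stream is not consumed
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(make_nucleus_field("u2os_control", 3, seed = 1))
  expect_identical(runif(1), before)
})

test_that("nucleus fields honour the preset's area calibration", {
  f <- make_nucleus_field("u2os_control", n = 100, seed = 31)
  expect_equal(nrow(f$truth), 100)
  expect_equal(max(f$labels), 100)
  sem <- sd(f$truth$area_um2) / sqrt(100)
  expect_lt(abs(mean(f$truth$area_um2) - 553.7), 3 * sem)
  # rendered label areas match the drawn ellipses (no overlap clipping)
  px <- tabulate(f$labels[f$labels > 0], nbins = 100)
  expect_equal(px, pi * f$truth$a_px * f$truth$b_px, tolerance = 0.03)
})

test_that("a circular preset yields undefined orientation", {
  p <- generator_preset("circ", nuclear_area_mean = 300,
                        aspect_ratio_mean = 1, noise_sd = 0)
  f <- make_nucleus_field(p, n = 1, seed = 1)
  rec <- measure_nuclei(f$labels, p$pixel_size)
  expect_equal(as.character(rec$orientation_class), "undefined")
})

test_that("perpendicular-biased orientations match the von Mises class mass", {
  kappa <- 6
  p <- generator_preset("stretch", nuclear_area_mean = 400,
                        orientation_model = "perpendicular_biased",
                        kappa = kappa)
  f <- make_nucleus_field(p, n = 500, seed = 11)
  frac <- mean(orientation_parameter(f$truth$phi_deg) <= -0.5)
  expected <- vm_perpendicular_mass(kappa)
  expect_lt(abs(frac - expected),
            3 * sqrt(expected * (1 - expected) / 500))
  # strong concentration pushes essentially everything perpendicular
  p12 <- generator_preset("stretch12", nuclear_area_mean = 400,
                          orientation_model = "perpendicular_biased",
                          kappa = 12)
  f12 <- make_nucleus_field(p12, n = 500, seed = 12)
  expect_gt(mean(orientation_parameter(f12$truth$phi_deg) <= -0.5), 0.9)
})

test_that("overcrowded fields fail with a density error", {
  expect_error(
    make_nucleus_field("u2os_control", n = 30, seed = 1, field_size = 260,
                       max_retries = 50),
    "too dense")
})

test_that("fractal contours are closed, star-shaped, and seed-stable", {
  ct <- make_fractal_contour(target_fd = 1.15, grid_size = 512, seed = 4)
  expect_true(all(dim(ct$mask) == c(512, 512)))
  # edge is one pixel wide: no edge pixel survives erosion of the fill
  expect_false(any(ct$edge & mechmorph:::erode8(ct$mask)))
  # every edge pixel has a neighbour (no isolated pixels)
  expect_identical(ct$edge, mechmorph:::mask_to_edge(ct$mask))
  # radial polygon stays positive and bounded
  r <- sqrt((ct$polygon[, 1] - ct$truth$cx)^2 +
            (ct$polygon[, 2] - ct$truth$cy)^2)
  expect_true(all(r > 0.05 * 512 & r < 0.5 * 512))
  expect_error(make_fractal_contour(target_fd = 1.48, seed = 1),
               "calibrated range")
})

test_that("measured FD increases with the roughness of the spectrum", {
  targets <- c(1.05, 1.15, 1.25, 1.35)
  means <- vapply(targets, function(tf) {
    mean(vapply(1:8, function(s)
      box_count(make_fractal_contour(target_fd = tf, grid_size = 512,
                                     seed = 600 + s)$edge)$fd, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("height maps confine texture to the peripheral band", {
  ct <- make_fractal_contour(target_fd = 1.05, grid_size = 256, seed = 3)
  flat <- make_height_map(ct, interior_height = 500, seed = 1)
  expect_equal(unique(flat$height[!flat$mask]), 0)
  expect_equal(unique(flat$height[flat$mask]), 500)
  expect_equal(peripheral_roughness(flat$height, flat$mask)$peripheral_rms, 0)
  tex <- make_height_map(ct, interior_height = 500,
                         peripheral_texture_sd = 20, seed = 1)
  # texture only in the band
  inner <- tex$mask & !tex$band
  expect_equal(unique(tex$height[inner]), 500)
  expect_gt(sd(tex$height[tex$band]), 0)
  # same parameters, different seed: different pixels, same summary
  tex2 <- make_height_map(ct, interior_height = 500,
                          peripheral_texture_sd = 20, seed = 2)
  expect_false(identical(tex$height, tex2$height))
  r1 <- peripheral_roughness(tex$height, tex$mask)$peripheral_rms
  r2 <- peripheral_roughness(tex2$height, tex2$mask)$peripheral_rms
  expect_equal(r1, r2, tolerance = 0.15)
})

test_that("fluorescence cells record exact compartment levels", {
  p <- generator_preset("clean", nuclear_area_mean = 500,
                        nc_ratio_mean = 0.4, nuclear_src_fold = 2,
                        noise_sd = 0)
  cell <- make_fluor_cell(p, seed = 8, cyt_increment = 40)
  expect_true(all(cell$nuclear_mask <= cell$cell_mask))
  expect_equal(unique(cell$src[cell$nuclear_mask]), 100 + 2 * 40)
  expect_equal(unique(cell$src[cell$cell_mask & !cell$nuclear_mask]),
               100 + 40)
  expect_equal(unique(cell$src[!cell$cell_mask]), 100)
  expect_equal(cell$truth$expected_ctcf, 2 * 40 * cell$truth$nuclear_area_px)
})
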