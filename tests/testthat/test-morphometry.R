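# Ellipse morphometry: moment fit, orientation statistic, classes, N/C.

test_that("orientation parameter hits the exact reference angles", {
  expect_equal(orientation_parameter(c(0, 45, 60, 90)), c(1, 0, -0.5, -1))
  # 180-degree axis ambiguity
  expect_equal(orientation_parameter(120), orientation_parameter(-60))
  expect_error(orientation_parameter(NA_real_))
})

test_that("orientation classes follow the published cos(2phi) ranges", {
  expect_equal(as.character(classify_orientation(-0.7)), "perpendicular")
  expect_equal(as.character(classify_orientation(0.8)), "parallel")
  expect_equal(as.character(classify_orientation(0)), "oblique")
  # band edges are inclusive
  expect_equal(as.character(classify_orientation(c(-0.5, 0.5, -1, 1))),
               c("perpendicular", "parallel", "perpendicular", "parallel"))
  # low eccentricity overrides the statistic
  expect_equal(as.character(classify_orientation(-0.9, eccentricity = 0.1)),
               "undefined")
  expect_error(classify_orientation(1.2), "must lie")
  # partition: every value maps to exactly one class
  grid <- seq(-1, 1, by = 0.01)
  cls <- classify_orientation(grid)
  expect_false(anyNA(cls))
  expect_equal(sum(table(cls)), length(grid))
})

test_that("moment fit recovers a rendered circle's area and flags it undefined", {
  m <- render_disk_mask(20)
  rec <- fit_ellipse(m, pixel_size = 0.5)
  expect_equal(rec$area_um2, pi * (20 * 0.5)^2, tolerance = 0.02)
  expect_equal(as.character(rec$orientation_class), "undefined")
  expect_lt(rec$eccentricity, 0.2)
})

test_that("moment fit recovers axes and angle over an (a, b, phi) grid", {
  cases <- expand.grid(a = c(30, 22), b = c(15, 11),
                       phi = c(-60, -30, 0, 30, 75, 90))
  for (i in seq_len(nrow(cases))) {
    a <- cases$a[i]; b <- cases$b[i]; phi <- cases$phi[i]
    rec <- fit_ellipse(render_ellipse_mask(a, b, phi), pixel_size = 1)
    dphi <- abs(((rec$phi_deg - phi + 90) %% 180) - 90)
    expect_lt(dphi, 2)
    expect_equal(rec$a_px / rec$b_px, a / b, tolerance = 0.05)
    expect_equal(rec$area_um2, pi * a * b, tolerance = 0.03)
  }
})

test_that("rotating an ellipse by 90 degrees flips the sign of cos(2phi)", {
  r30 <- fit_ellipse(render_ellipse_mask(30, 15, 30), pixel_size = 1)
  r120 <- fit_ellipse(render_ellipse_mask(30, 15, 120), pixel_size = 1)
  expect_equal(r120$cos2phi, -r30$cos2phi, tolerance = 0.05)
  expect_equal(abs(((r120$phi_deg - r30$phi_deg + 90) %% 180) - 90), 90,
               tolerance = 2)
})

test_that("pixel size scales area quadratically and nothing else", {
  m <- render_ellipse_mask(25, 12, 40)
  r1 <- fit_ellipse(m, pixel_size = 0.25)
  r2 <- fit_ellipse(m, pixel_size = 0.5)
  expect_equal(r2$area_um2, 4 * r1$area_um2)
  expect_equal(r2$phi_deg, r1$phi_deg)
  expect_equal(r2$cos2phi, r1$cos2phi)
})

test_that("degenerate regions are rejected or flagged", {
  expect_error(fit_ellipse(matrix(FALSE, 5, 5), 1), "empty")
  two <- matrix(FALSE, 20, 20)
  two[2:5, 2:5] <- TRUE; two[12:15, 12:15] <- TRUE
  expect_error(fit_ellipse(two, 1), "single connected component")
  small <- matrix(FALSE, 8, 8); small[3:5, 3:5] <- TRUE
  expect_false(fit_ellipse(small, 1)$valid)
})

test_that("N/C ratio is the area quotient with containment enforced", {
  cell <- matrix(0, 20, 20); cell[1:20, 1:20] <- 1
  nuc <- matrix(0, 20, 20); nuc[6:15, 6:15] <- 1
  expect_equal(nc_ratio(nuc, cell)$nc_ratio, 0.25)
  # unit invariance
  expect_equal(nc_ratio(nuc, cell, pixel_size = 0.025)$nc_ratio, 0.25)
  expect_warning(r1 <- nc_ratio(cell, cell), "N/C ratio = 1")
  expect_equal(r1$nc_ratio, 1)
  outside <- matrix(0, 20, 20); outside[1:3, 1:3] <- 1
  small_cell <- matrix(0, 20, 20); small_cell[10:20, 10:20] <- 1
  expect_error(nc_ratio(outside, small_cell), "not contained")
})

test_that("measure_nuclei reproduces the generator's ground truth per label", {
  f <- make_nucleus_field("u2os_control", n = 30, seed = 42)
  rec <- measure_nuclei(f$labels, f$pixel_size)
  expect_equal(nrow(rec), 30)
  expect_equal(rec$label, f$truth$label)
  dphi <- abs(((rec$phi_deg - f$truth$phi_deg + 90) %% 180) - 90)
  ecc_ok <- rec$eccentricity >= 0.3  # angle comparison meaningless near circles
  expect_lt(max(dphi[ecc_ok]), 2)
  drawn_px <- pi * f$truth$a_px * f$truth$b_px
  expect_equal(rec$area_px, drawn_px, tolerance = 0.03)
})
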