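# Edge extraction, box counting, roughness.

test_that("contrast enhancement clips at the requested percentiles", {
  ramp <- matrix(seq(0, 1, length.out = 64 * 64), 64, 64)
  out <- enhance_contrast(ramp, 0, 100)
  expect_equal(out, (ramp - min(ramp)) / (max(ramp) - min(ramp)))
  # idempotent at the same percentiles
  expect_equal(enhance_contrast(out, 0, 100), out)
  expect_warning(z <- enhance_contrast(matrix(5, 10, 10)), "constant")
  expect_true(all(z == 0))
  # salt outliers: 1% extreme pixels clipped, interior mapping preserved
  salted <- ramp
  set.seed(1)
  idx <- sample(length(salted), length(salted) %/% 100)
  salted[idx] <- 100
  enh <- enhance_contrast(salted, 1, 99)
  q <- quantile(salted, c(0.01, 0.99), names = FALSE)
  interior <- salted > q[1] & salted < q[2]
  expect_equal(enh[interior], (salted[interior] - q[1]) / (q[2] - q[1]),
               tolerance = 1e-12)
  expect_true(all(enh[salted >= q[2]] == 1))
})

test_that("edge masks are one pixel wide with exact perimeter on a square", {
  img <- matrix(0, 120, 120); img[11:110, 11:110] <- 1
  edge <- extract_edge_mask(img)
  expect_equal(sum(edge), 4 * 99)  # discrete perimeter of a 100 px square
  fg <- img > 0
  expect_false(any(edge & mechmorph:::erode8(fg)))  # no interior pixels
  expect_equal(sum(edge), brute_force_edge_count(fg))
})

test_that("disk edges match the brute-force boundary enumeration", {
  for (r in c(15, 30)) {
    m <- render_disk_mask(r)
    edge <- extract_edge_mask(m * 1)
    expect_equal(sum(edge), brute_force_edge_count(m))
    # the 8-exit inner boundary over-counts diagonal runs by up to sqrt(2),
    # so the pixel count sits between the continuous perimeter and ~1.35x it
    expect_gt(sum(edge), 2 * pi * r)
    expect_lt(sum(edge), 1.35 * 2 * pi * r)
  }
})

test_that("only the largest component contributes to the edge mask", {
  img <- matrix(0, 100, 100)
  img[11:60, 11:60] <- 1   # 50 px square
  img[81:90, 81:90] <- 1   # 10 px square
  edge <- extract_edge_mask(img)
  expect_equal(sum(edge), 4 * 49)
  expect_false(any(edge[81:90, 81:90]))
  # holes are filled before edge extraction
  holed <- img
  holed[30:40, 30:40] <- 0
  expect_equal(sum(extract_edge_mask(holed)), 4 * 49)
  expect_error(extract_edge_mask(matrix(0, 50, 50)), "constant|foreground")
})

test_that("fixed thresholds are honoured", {
  img <- matrix(50, 60, 60); img[21:40, 21:40] <- 200
  e1 <- extract_edge_mask(img, method = 100)
  expect_equal(attr(e1, "method"), "fixed")
  expect_equal(attr(e1, "threshold"), 100)
  expect_equal(sum(e1), 4 * 19)
  expect_error(extract_edge_mask(img, method = 300), "no foreground")
})

test_that("box counts equal the brute-force double loop exactly", {
  set.seed(99)
  for (i in 1:20) {
    h <- sample(40:128, 1); w <- sample(40:128, 1)
    mask <- matrix(runif(h * w) < runif(1, 0.01, 0.2), h, w)
    if (!any(mask)) mask[sample(h * w, 5)] <- TRUE
    sizes <- 2^(1:floor(log2(min(h, w))))
    bc <- box_count(mask, sizes = sizes, fit_range = range(sizes))
    for (k in seq_along(bc$box_sizes)) {
      expect_identical(bc$counts[k],
                       brute_force_box_count(mask, bc$box_sizes[k]))
    }
  }
})

test_that("analytic dimensions are recovered: line and Koch curve", {
  line <- matrix(FALSE, 512, 512); line[256, ] <- TRUE
  fd_line <- box_count(line)$fd
  expect_gt(fd_line, 0.97); expect_lt(fd_line, 1.03)
  koch <- koch_curve_mask(iterations = 4, base_px = 729)
  fd_koch <- box_count(koch)$fd
  expect_lt(abs(fd_koch - log(4) / log(3)), 0.05)
})

test_that("FD is stable under integer translations and scale trimming", {
  ct <- make_fractal_contour(target_fd = 1.2, grid_size = 512, seed = 21)
  base <- box_count(ct$edge)
  for (shift in list(c(3, 7), c(11, 2))) {
    big <- matrix(FALSE, 512 + 16, 512 + 16)
    big[shift[1] + (1:512), shift[2] + (1:512)] <- ct$edge
    moved <- box_count(big[1:512, 1:512])
    expect_lt(abs(moved$fd - base$fd), 0.03)
  }
  # dropping the smallest scale from the fit barely moves a resolved mask
  sizes <- base$box_sizes
  trimmed <- box_count(ct$edge, sizes = sizes,
                       fit_range = c(8, max(sizes[sizes <= 128])))
  expect_lt(abs(trimmed$fd - base$fd), 0.05)
})

test_that("degenerate box-count inputs raise typed errors", {
  expect_error(box_count(matrix(FALSE, 64, 64)), "empty edge mask")
  tiny <- matrix(FALSE, 24, 24); tiny[12, ] <- TRUE
  expect_error(box_count(tiny), "insufficient scale range")
})

test_that("peripheral roughness recovers the generated texture SD", {
  ct <- make_fractal_contour(target_fd = 1.05, grid_size = 256, seed = 13)
  hm <- make_height_map(ct, interior_height = 400,
                        peripheral_texture_sd = 25, seed = 5)
  res <- peripheral_roughness(hm$height, hm$mask, band_width = 10)
  expect_equal(res$peripheral_rms, sd(hm$height[hm$band]), tolerance = 0.02)
  expect_equal(res$peripheral_rms, 25, tolerance = 0.10)
  expect_equal(res$max_height, max(hm$height[hm$mask]))
  # a band wider than the cell radius degenerates to the global statistic
  wide <- peripheral_roughness(hm$height, hm$mask, band_width = 300)
  expect_equal(wide$peripheral_rms, wide$global_rms)
  expect_error(peripheral_roughness(hm$height, hm$mask * 0), "empty mask")
})
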