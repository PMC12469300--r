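# Synthetic closed cell contours with tunable box-counting fractal
# dimension, plus pseudo-AFM height maps built on them.
#
# Construction: radial spectral synthesis about a centre,
#   r(theta) = R0 * (1 + sigma * s(theta)),
#   s(theta) = sum_k k^(-beta/2) (a_k cos k theta + b_k sin k theta),
# with a_k, b_k iid standard normal and s normalized to unit SD, so sigma is
# the exact relative roughness amplitude. The spectral slope beta controls
# how energy falls off with harmonic number and hence the measured box-
# counting dimension of the rasterized curve; a star-shaped r(theta) > 0
# guarantees a closed, non-self-intersecting contour.

# beta -> measured FD calibration, estimated once by generating contours
# over a beta grid (30 seeds each, 1024-px grid, sigma = 0.10, harmonics
# 2..256) and measuring them with extract-edge + box_count at the default
# dyadic fit range. Monotone decreasing in beta; inverted by interpolation.
fd_beta_calibration <- function() {
  data.frame(
    beta = c(3.60, 3.20, 2.90, 2.70, 2.50, 2.30, 2.10, 1.90,
             1.70, 1.50, 1.30, 1.10, 0.90, 0.70, 0.50),
    fd   = c(0.9740, 0.9867, 0.9932, 1.0078, 1.0311, 1.0557, 1.1052, 1.1517,
             1.1941, 1.2614, 1.2998, 1.3508, 1.3987, 1.4303, 1.4588)
  )
}

fd_to_beta <- function(target_fd) {
  cal <- fd_beta_calibration()
  if (target_fd < min(cal$fd) - 0.02 || target_fd > max(cal$fd) + 0.005)
    stop("target_fd = ", target_fd, " outside the calibrated range [",
         round(min(cal$fd), 3), ", ", round(max(cal$fd), 3), "]",
         call. = FALSE)
  target_fd <- min(max(target_fd, min(cal$fd)), max(cal$fd))
  approx(cal$fd, cal$beta, xout = target_fd, rule = 2)$y
}

# Evaluate the normalized radial perturbation on a fine theta grid.
radial_profile <- function(beta, n_harmonics = 256L, n_theta = 16384L,
                           k_min = 2L) {
  k <- k_min:n_harmonics
  amp <- k^(-beta / 2)
  a <- rnorm(length(k)) * amp
  b <- rnorm(length(k)) * amp
  theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  s <- as.vector(cos(outer(theta, k)) %*% a + sin(outer(theta, k)) %*% b)
  s / sd(s)
}

#' Generate a closed cell contour with a prescribed fractal dimension
#'
#' Synthesizes a star-shaped closed contour by randomizing the phases and
#' amplitudes of a power-law radial spectrum, with the spectral slope chosen
#' from a stored monotone calibration so that the box-counting dimension
#' measured by [box_count()] on the rasterized edge matches `target_fd`
#' (within about +/-0.05 for single contours; tighter for means over seeds).
#'
#' @param preset a [generator_preset()] or preset name (supplies
#'   `target_fd`), or `NULL` when `target_fd` is given directly.
#' @param grid_size raster side length in pixels (default 1024).
#' @param seed integer seed; output is bit-identical per (arguments, seed).
#' @param target_fd overrides the preset's target dimension.
#' @param sigma relative roughness amplitude of the radial perturbation
#'   (fixed at calibration time; changing it invalidates the calibration).
#' @return List: `polygon` (two-column matrix of x, y vertices, closed
#'   implicitly), `mask` (logical filled-cell raster), `edge` (logical
#'   one-pixel edge mask), `truth` (data.frame with `target_fd`, `beta`,
#'   `sigma`, `R0_px`, centre coordinates).
#' @examples
#' ct <- make_fractal_contour(target_fd = 1.1, grid_size = 256, seed = 1)
#' box_count(ct$edge)$fd
#' @export
make_fractal_contour <- function(preset = NULL, grid_size = 1024, seed = 1,
                                 target_fd = NULL, sigma = 0.10) {
  if (is.null(target_fd)) {
    if (is.null(preset)) stop("supply a preset or target_fd", call. = FALSE)
    target_fd <- as_preset(preset)$target_fd
  }
  stopifnot(grid_size >= 128)
  beta <- fd_to_beta(target_fd)
  out <- contour_from_beta(beta, grid_size, seed, sigma)
  out$truth <- cbind(data.frame(target_fd = target_fd), out$truth)
  out
}

# Raw generator parameterized by the spectral slope beta directly; used by
# make_fractal_contour (via the calibrated lookup) and by the calibration
# itself.
contour_from_beta <- function(beta, grid_size, seed, sigma = 0.10) {
  with_rng_seed(seed, {
    n_theta <- 16384L
    s <- radial_profile(beta, n_theta = n_theta)
    R0 <- 0.30 * grid_size
    r <- R0 * (1 + sigma * s)
    r <- pmin(pmax(r, 0.08 * grid_size), 0.47 * grid_size)
    cx <- cy <- (grid_size + 1) / 2
    theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]

    # rasterize the star-shaped region: pixel inside iff its radius is below
    # the (linearly interpolated) boundary radius at its polar angle
    xs <- rep(seq_len(grid_size) - cx, each = grid_size)
    ys <- rep(-(seq_len(grid_size) - cy), times = grid_size)
    ang <- atan2(ys, xs) %% (2 * pi)
    idx <- ang / (2 * pi) * n_theta
    i0 <- floor(idx)
    frac <- idx - i0
    i0 <- (as.integer(i0) %% n_theta) + 1L
    i1 <- (i0 %% n_theta) + 1L
    rb <- r[i0] * (1 - frac) + r[i1] * frac
    inside <- (xs * xs + ys * ys) <= rb * rb
    mask <- matrix(inside, nrow = grid_size)

    truth <- data.frame(beta = beta, sigma = sigma,
                        R0_px = R0, cx = cx, cy = cy)
    list(
      polygon = cbind(x = cx + r * cos(theta), y = cy - r * sin(theta)),
      mask = mask,
      edge = mask_to_edge(mask),
      truth = truth
    )
  })
}

#' Generate a pseudo-AFM height map from a cell contour
#'
#' Renders a plateau of constant height inside the contour, adds Gaussian
#' texture confined to a peripheral band of given width (emulating edge
#' protrusions), and optional global pixel noise. Height is 0 outside the
#' cell.
#'
#' @param contour a result of [make_fractal_contour()] or a logical cell
#'   mask.
#' @param interior_height plateau height (nm), > 0.
#' @param peripheral_texture_sd SD of the band-confined texture (nm).
#' @param noise_sd SD of global additive noise (nm).
#' @param band_width band width in pixels (default 10; matches the default
#'   of [peripheral_roughness()]).
#' @param seed integer seed.
#' @return List: `height` (numeric matrix, nm), `mask` (logical),
#'   `band` (logical peripheral band actually textured).
#' @export
make_height_map <- function(contour, interior_height = 500,
                            peripheral_texture_sd = 0, noise_sd = 0,
                            band_width = 10, seed = 1) {
  mask <- if (is.list(contour)) contour$mask else contour
  stopifnot(is.matrix(mask), interior_height > 0,
            peripheral_texture_sd >= 0, noise_sd >= 0, band_width >= 1)
  fg <- mask > 0
  with_rng_seed(seed, {
    d <- EBImage::imageData(EBImage::distmap(EBImage::Image(fg * 1)))
    band <- fg & d <= band_width
    height <- matrix(0, nrow(mask), ncol(mask))
    height[fg] <- interior_height
    if (peripheral_texture_sd > 0)
      height[band] <- height[band] +
        rnorm(sum(band), 0, peripheral_texture_sd)
    if (noise_sd > 0)
      height <- height + matrix(rnorm(length(height), 0, noise_sd),
                                nrow(height))
    list(height = height, mask = fg, band = band)
  })
}
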