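# Cell-edge complexity: contrast enhancement, one-pixel edge-mask
# extraction, box-counting fractal dimension, and AFM roughness summaries.

#' Percentile contrast enhancement
#'
#' Linearly rescales intensities to [0, 1], clipping below the `p_low` and
#' above the `p_high` intensity percentiles. Idempotent on already-rescaled
#' input with the same percentiles.
#'
#' @param image numeric matrix.
#' @param p_low,p_high percentiles in [0, 100], `p_low < p_high`.
#' @return Numeric matrix in [0, 1]. A constant image yields all zeros with
#'   a warning.
#' @export
enhance_contrast <- function(image, p_low = 1, p_high = 99) {
  stopifnot(is.matrix(image), is.numeric(image),
            p_low >= 0, p_high <= 100, p_low < p_high)
  q <- quantile(image, c(p_low, p_high) / 100, names = FALSE, type = 7)
  if (q[2] <= q[1]) {
    warning("constant image: contrast enhancement returns zeros", call. = FALSE)
    return(matrix(0, nrow(image), ncol(image)))
  }
  pmin(pmax((image - q[1]) / (q[2] - q[1]), 0), 1)
}

# 8-connectivity binary erosion by one pixel via matrix shifts: a pixel
# survives iff all 8 neighbours (and itself) are foreground. Border pixels
# never survive, so edge pixels on the image border are retained in the mask.
erode8 <- function(fg) {
  h <- nrow(fg); w <- ncol(fg)
  out <- matrix(FALSE, h, w)
  if (h < 3 || w < 3) return(out)
  i <- 2:(h - 1); j <- 2:(w - 1)
  acc <- fg[i, j]
  for (dr in -1:1) for (dc in -1:1)
    if (dr || dc) acc <- acc & fg[i + dr, j + dc]
  out[i, j] <- acc
  out
}

# One-pixel inner boundary of a filled mask: foreground minus its
# 8-connectivity erosion, with isolated single pixels dropped.
mask_to_edge <- function(fg) {
  fg <- fg > 0
  edge <- fg & !erode8(fg)
  # cleanup: drop pixels with no foreground 8-neighbour
  h <- nrow(edge); w <- ncol(edge)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- edge
  nb <- matrix(0L, h, w)
  for (dr in -1:1) for (dc in -1:1)
    if (dr || dc) nb <- nb + pad[2:(h + 1) + dr, 2:(w + 1) + dc]
  edge & (nb > 0)
}

#' Extract a one-pixel cell-edge mask
#'
#' Thresholds the image (Otsu by default), keeps the largest connected
#' component, fills its holes, and returns the one-pixel inner boundary
#' (foreground minus its 8-connectivity erosion) — the substrate of
#' [box_count()].
#'
#' @param image numeric matrix (fluorescence intensity or AFM height);
#'   typically pre-processed with [enhance_contrast()].
#' @param method `"otsu"` or a fixed numeric threshold on the image scale.
#' @return Logical matrix (the edge mask) with attributes `threshold` and
#'   `method`.
#' @examples
#' img <- matrix(0, 64, 64); img[17:48, 17:48] <- 1
#' sum(extract_edge_mask(img))  # perimeter pixels of a 32x32 square
#' @export
extract_edge_mask <- function(image, method = "otsu") {
  stopifnot(is.matrix(image), is.numeric(image))
  if (identical(method, "otsu")) {
    rng <- range(image)
    if (rng[1] == rng[2]) stop("constant image: no foreground", call. = FALSE)
    norm <- (image - rng[1]) / (rng[2] - rng[1])
    thr_norm <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    thr <- rng[1] + thr_norm * (rng[2] - rng[1])
  } else {
    stopifnot(is.numeric(method), length(method) == 1L)
    thr <- method
  }
  fg <- image > thr
  if (!any(fg)) stop("no foreground after thresholding at ", signif(thr, 4),
                     call. = FALSE)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(fg * 1)))
  counts <- tabulate(lab[lab > 0])
  fg <- lab == which.max(counts)
  fg <- EBImage::imageData(EBImage::fillHull(EBImage::Image(fg * 1))) > 0
  edge <- mask_to_edge(fg)
  attr(edge, "threshold") <- unname(thr)
  attr(edge, "method") <- if (identical(method, "otsu")) "otsu" else "fixed"
  edge
}

# Dyadic box sizes 2, 4, ..., <= floor(min(h, w)/4)
dyadic_sizes <- function(h, w) {
  emax <- floor(min(h, w) / 4)
  if (emax < 2) stop("image too small for box counting", call. = FALSE)
  2^(1:floor(log2(emax)))
}

#' Box-counting fractal dimension of an edge mask
#'
#' For each box size `eps` the mask is overlaid with a grid of `eps x eps`
#' boxes anchored at the image origin, and the number `N(eps)` of boxes
#' containing at least one edge pixel is counted. The fractal dimension is
#' the least-squares slope of `log N` versus `log(1/eps)` over the fit
#' range. Counts are exact and bit-reproducible (single grid offset).
#'
#' @param edge logical or 0/1 matrix, a one-pixel edge mask from
#'   [extract_edge_mask()] or [make_fractal_contour()].
#' @param sizes dyadic box sizes in pixels; default `2, 4, ...` up to
#'   `min(dim)/4`.
#' @param fit_range length-2 numeric: smallest and largest box size entering
#'   the regression. Default `c(4, min(dim)/4)`; `eps = 2` is counted but
#'   excluded from the fit because it saturates at pixel noise.
#' @return List of class `"box_count_result"`: `box_sizes` (descending),
#'   `counts`, `fd`, `fit_range`, `r_squared`.
#' @examples
#' edge <- matrix(FALSE, 256, 256); edge[128, ] <- TRUE  # straight line
#' box_count(edge)$fd  # ~1
#' @export
box_count <- function(edge, sizes = NULL, fit_range = NULL) {
  stopifnot(is.matrix(edge))
  fg <- which(edge > 0, arr.ind = TRUE)
  if (!nrow(fg)) stop("empty edge mask", call. = FALSE)
  h <- nrow(edge); w <- ncol(edge)
  if (is.null(sizes)) sizes <- dyadic_sizes(h, w)
  sizes <- sort(unique(as.integer(sizes)), decreasing = TRUE)
  r0 <- fg[, 1] - 1L; c0 <- fg[, 2] - 1L   # 0-based grid anchored at origin
  counts <- vapply(sizes, function(eps) {
    nbc <- (w + eps - 1L) %/% eps
    length(unique((r0 %/% eps) * nbc + (c0 %/% eps)))
  }, integer(1))
  if (is.null(fit_range)) fit_range <- c(4, floor(min(h, w) / 4))
  use <- sizes >= fit_range[1] & sizes <= fit_range[2]
  if (sum(use) < 4)
    stop("insufficient scale range: only ", sum(use),
         " box sizes in the fit range", call. = FALSE)
  x <- log(1 / sizes[use]); y <- log(counts[use])
  # closed-form least squares; R^2 defined as 1 for an exact fit so that
  # degenerate perfect cases (straight lines) do not warn
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  resid <- y - mean(y) - slope * (x - mean(x))
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else 1
  structure(list(
    box_sizes = sizes, counts = counts,
    fd = slope,
    fit_range = c(min(sizes[use]), max(sizes[use])),
    r_squared = r2
  ), class = "box_count_result")
}

#' @export
print.box_count_result <- function(x, ...) {
  cat(sprintf("<box_count_result> FD = %.4f (R^2 = %.4f), fit range %d-%d px\n",
              x$fd, x$r_squared, x$fit_range[1], x$fit_range[2]))
  print(data.frame(eps = x$box_sizes, N = x$counts))
  invisible(x)
}

#' Peripheral and global roughness of an AFM height map
#'
#' The peripheral band is the set of mask pixels within `band_width` pixels
#' of the cell boundary (Euclidean distance transform). Roughness is the RMS
#' deviation of height from the band's median level; the same statistic over
#' the full mask gives the global roughness.
#'
#' @param height numeric matrix of heights (nm or image units).
#' @param mask logical or 0/1 cell mask of the same dimension.
#' @param band_width band width in pixels (default 10, i.e. 100 nm at
#'   10 nm/pixel).
#' @return One-row data.frame: `peripheral_rms`, `global_rms`, `max_height`,
#'   `band_width`, `band_pixels`.
#' @export
peripheral_roughness <- function(height, mask, band_width = 10) {
  stopifnot(is.matrix(height), is.matrix(mask),
            all(dim(height) == dim(mask)), band_width >= 1)
  fg <- mask > 0
  if (!any(fg)) stop("empty mask", call. = FALSE)
  d <- EBImage::imageData(EBImage::distmap(EBImage::Image(fg * 1)))
  band <- fg & d <= band_width
  if (!any(band)) stop("empty peripheral band", call. = FALSE)
  hb <- height[band]; hm <- height[fg]
  data.frame(
    peripheral_rms = sqrt(mean((hb - median(hb))^2)),
    global_rms = sqrt(mean((hm - median(hm))^2)),
    max_height = max(hm),
    band_width = band_width,
    band_pixels = sum(band)
  )
}

#' Rasterized Koch-curve phantom
#'
#' Triadic Koch curve (analytic fractal dimension `log 4 / log 3 = 1.2619`)
#' rasterized onto a pixel grid — a standard phantom for validating
#' box-counting estimators.
#'
#' @param iterations number of subdivision rounds (4 gives 256 segments).
#' @param base_px horizontal extent in pixels (default `3^6 = 729` so that
#'   every 4-iteration segment spans 9 pixels).
#' @return Logical edge-mask matrix containing the rasterized curve.
#' @export
koch_curve_mask <- function(iterations = 4, base_px = 729) {
  stopifnot(iterations >= 0, base_px >= 3^iterations)
  p <- matrix(c(0, 0, 1, 0), ncol = 2, byrow = TRUE)  # unit segment, y up
  for (it in seq_len(iterations)) {
    np <- matrix(0, nrow = 4 * (nrow(p) - 1) + 1, ncol = 2)
    k <- 1L
    for (s in seq_len(nrow(p) - 1)) {
      a <- p[s, ]; b <- p[s + 1, ]; v <- (b - a) / 3
      peak <- a + 1.5 * v + c(-v[2], v[1]) * sqrt(3) / 2
      np[k, ] <- a
      np[k + 1, ] <- a + v
      np[k + 2, ] <- peak
      np[k + 3, ] <- a + 2 * v
      k <- k + 4L
    }
    np[nrow(np), ] <- p[nrow(p), ]
    p <- np
  }
  # rasterize polyline: dense parameter sampling, round to pixel centres
  x <- p[, 1] * (base_px - 1) + 1
  y <- p[, 2] * (base_px - 1)
  h <- base_px  # square canvas so the fit range is not limited by curve height
  mask <- matrix(FALSE, h, base_px)
  for (s in seq_len(length(x) - 1)) {
    len <- max(abs(x[s + 1] - x[s]), abs(y[s + 1] - y[s]))
    t <- seq(0, 1, length.out = max(2L, ceiling(2 * len)))
    px <- round(x[s] + t * (x[s + 1] - x[s]))
    py <- h - 1L - round(y[s] + t * (y[s + 1] - y[s]))
    mask[cbind(py + 1L, px)] <- TRUE
  }
  mask
}
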