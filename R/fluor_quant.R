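# Corrected total cell fluorescence (CTCF) of nuclear Src: ring-based
# background estimation and the exact CTCF arithmetic
#   integrated density = mean intensity x area
#   CTCF = integrated density - background mean x area.

disc_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

dilate_mask <- function(fg, radius) {
  if (radius == 0) return(fg)
  EBImage::imageData(EBImage::dilate(EBImage::Image(fg * 1),
                                     disc_brush(radius))) > 0
}

#' Background ring around a cell
#'
#' Builds an annular background region just outside the cell: the
#' morphological dilation of the cell mask by `gap + width` minus its
#' dilation by `gap`, excluding the cell itself and any pixels belonging to
#' other cells.
#'
#' @param cell_mask logical or 0/1 mask of the cell of interest.
#' @param gap pixels between the cell boundary and the inner ring edge
#'   (>= 0, default 2).
#' @param width radial thickness of the ring in pixels (>= 1, default 5).
#' @param other_cells optional mask (same dimension) of all remaining cells;
#'   their pixels are excluded from the ring.
#' @return Logical ring mask.
#' @examples
#' cell <- matrix(0, 50, 50); cell[21:30, 21:30] <- 1
#' sum(background_ring(cell, gap = 2, width = 4))
#' @export
background_ring <- function(cell_mask, gap = 2, width = 5,
                            other_cells = NULL) {
  stopifnot(is.matrix(cell_mask), gap >= 0, width >= 1)
  fg <- cell_mask > 0
  if (!any(fg)) stop("empty cell mask", call. = FALSE)
  ring <- dilate_mask(fg, gap + width) & !dilate_mask(fg, gap)
  if (!is.null(other_cells)) {
    stopifnot(all(dim(other_cells) == dim(cell_mask)))
    ring <- ring & !(other_cells > 0)
  }
  if (!any(ring))
    stop("background ring is empty (clipped by image border or neighbours)",
         call. = FALSE)
  ring
}

#' Corrected total cell fluorescence of a nuclear region
#'
#' Computes, with no smoothing or outlier rejection,
#' `integrated_density = nuclear mean intensity x nuclear area` and
#' `ctcf = integrated_density - background mean intensity x nuclear area`.
#' Areas are pixel counts unless `pixel_size` is supplied, in which case
#' both terms are scaled consistently (CTCF scales by `pixel_size^2`).
#'
#' @param src numeric matrix, the Src channel.
#' @param nuclear_mask logical or 0/1 nuclear mask.
#' @param background_mask logical or 0/1 background region, e.g. from
#'   [background_ring()].
#' @param id object identifier carried into the record.
#' @param pixel_size optional micrometres per pixel; default areas in
#'   pixels.
#' @return One-row data.frame: `id`, `nuclear_area`,
#'   `nuclear_mean_intensity`, `integrated_density`, `background_mean`,
#'   `ctcf`.
#' @examples
#' img <- matrix(10, 30, 30); nuc <- matrix(0, 30, 30); nuc[11:20, 11:20] <- 1
#' img[nuc > 0] <- 60
#' ring <- background_ring(nuc, gap = 2, width = 4)
#' ctcf(img, nuc, ring)$ctcf  # 50 * 100 = 5000
#' @export
ctcf <- function(src, nuclear_mask, background_mask, id = 1L,
                 pixel_size = NULL) {
  stopifnot(is.matrix(src), is.matrix(nuclear_mask),
            is.matrix(background_mask),
            all(dim(src) == dim(nuclear_mask)),
            all(dim(src) == dim(background_mask)))
  nuc <- nuclear_mask > 0; bgm <- background_mask > 0
  if (!any(nuc)) stop("empty nuclear mask", call. = FALSE)
  if (!any(bgm)) stop("empty background mask", call. = FALSE)
  scale2 <- if (is.null(pixel_size)) 1 else pixel_size^2
  area <- sum(nuc) * scale2
  nuc_mean <- mean(src[nuc])
  bg_mean <- mean(src[bgm])
  int_den <- nuc_mean * area
  data.frame(
    id = id,
    nuclear_area = area,
    nuclear_mean_intensity = nuc_mean,
    integrated_density = int_den,
    background_mean = bg_mean,
    ctcf = int_den - bg_mean * area
  )
}

#' Fold change between two CTCF groups
#'
#' Ratio of group means, reported with group sizes and SEMs. CTCF values can
#' be negative after background subtraction; the ratio is only meaningful
#' for positive means, so non-positive means are an error and callers must
#' screen their inputs.
#'
#' @param ctcf_values_a,ctcf_values_b numeric vectors of per-cell CTCF
#'   values (numerator group first).
#' @return One-row data.frame: `fold`, `n_a`, `n_b`, `mean_a`, `mean_b`,
#'   `sem_a`, `sem_b`.
#' @examples
#' condition_fold_change(c(200, 220, 180), c(100, 90, 110))
#' @export
condition_fold_change <- function(ctcf_values_a, ctcf_values_b) {
  stopifnot(is.numeric(ctcf_values_a), is.numeric(ctcf_values_b),
            length(ctcf_values_a) >= 1, length(ctcf_values_b) >= 1)
  ma <- mean(ctcf_values_a); mb <- mean(ctcf_values_b)
  if (ma <= 0 || mb <= 0)
    stop("fold change requires positive group means (got ",
         signif(ma, 4), " and ", signif(mb, 4), ")", call. = FALSE)
  sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  data.frame(
    fold = ma / mb,
    n_a = length(ctcf_values_a), n_b = length(ctcf_values_b),
    mean_a = ma, mean_b = mb,
    sem_a = sem(ctcf_values_a), sem_b = sem(ctcf_values_b)
  )
}
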