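# Per-nucleus ellipse morphometry: moment-equivalent ellipse fit, the
# orientation statistic cos(2*phi), orientation classes, and the N/C ratio.

# Fold angles (degrees) into (-90, 90]; the major axis has a 180-degree
# ambiguity that cos(2*phi) is invariant to.
fold_angle <- function(phi) {
  phi <- (phi + 90) %% 180 - 90
  phi[phi == -90] <- 90
  phi
}

#' Orientation parameter cos(2*phi)
#'
#' Transforms the angle `phi` between a nucleus's major axis and the stretch
#' (x) axis into the alignment statistic \eqn{\cos 2\varphi}: +1 for parallel,
#' -1 for perpendicular alignment, invariant to the 180-degree axis ambiguity.
#'
#' @param phi angle in degrees; any finite value (folded internally).
#' @return Numeric in [-1, 1].
#' @examples
#' orientation_parameter(c(0, 45, 60, 90))  # 1, 0, -0.5, -1
#' @export
orientation_parameter <- function(phi) {
  stopifnot(is.numeric(phi), all(is.finite(phi)))
  cospi(2 * phi / 180)
}

#' Classify nuclear alignment from cos(2*phi)
#'
#' Classes follow the published ranges: perpendicular for
#' \eqn{-1 \le \cos 2\varphi \le -0.5}, parallel for
#' \eqn{0.5 \le \cos 2\varphi \le 1}, oblique otherwise. Near-circular
#' objects (eccentricity below `circularity_threshold`) have no meaningful
#' major axis and are classified `undefined` regardless of the statistic.
#'
#' @param cos2phi numeric in [-1, 1].
#' @param eccentricity optional eccentricity of the fitted ellipse
#'   (`sqrt(1 - (b/a)^2)`); when supplied, low values force `undefined`.
#' @param circularity_threshold eccentricity below which orientation is
#'   undefined (default 0.2).
#' @return Factor with levels perpendicular, oblique, parallel, undefined.
#' @examples
#' classify_orientation(c(-0.7, 0, 0.8))
#' @export
classify_orientation <- function(cos2phi, eccentricity = NULL,
                                 circularity_threshold = 0.2) {
  stopifnot(is.numeric(cos2phi))
  if (any(!is.finite(cos2phi)) || any(cos2phi < -1) || any(cos2phi > 1))
    stop("cos2phi must lie in [-1, 1]", call. = FALSE)
  cls <- ifelse(cos2phi <= -0.5, "perpendicular",
                ifelse(cos2phi >= 0.5, "parallel", "oblique"))
  if (!is.null(eccentricity)) {
    stopifnot(length(eccentricity) %in% c(1L, length(cos2phi)))
    cls[rep_len(eccentricity, length(cls)) < circularity_threshold] <- "undefined"
  }
  factor(cls, levels = c("perpendicular", "oblique", "parallel", "undefined"))
}

#' Fit the moment-equivalent ellipse to one segmented nucleus
#'
#' Computes the ellipse sharing the region's centroid and normalized second
#' central moments (the construction behind ImageJ's Fit Ellipse): semi-axes
#' \eqn{a = 2\sqrt{\lambda_1}}, \eqn{b = 2\sqrt{\lambda_2}} from the
#' eigenvalues of the pixel covariance matrix, orientation from its principal
#' axis. Area is the pixel count times `pixel_size^2` (not \eqn{\pi a b}).
#'
#' The angle convention is x = column axis (stretch direction), y pointing
#' up, `phi` in degrees CCW from +x folded to (-90, 90].
#'
#' @param region logical or 0/1 matrix containing exactly one 8-connected
#'   component.
#' @param pixel_size micrometres per pixel.
#' @param min_size regions below this pixel count are flagged
#'   (`valid = FALSE`) and should be excluded from summaries.
#' @param circularity_threshold passed to [classify_orientation()].
#' @param check_connectivity verify the region is one 8-connected component
#'   (disable when the caller already guarantees it, e.g. per-label crops).
#' @return One-row data.frame: `centroid_x`, `centroid_y` (pixels, x = col,
#'   y = row), `a_px`, `b_px`, `phi_deg`, `cos2phi`, `eccentricity`,
#'   `area_px`, `area_um2`, `orientation_class`, `valid`.
#' @export
fit_ellipse <- function(region, pixel_size, min_size = 25,
                        circularity_threshold = 0.2,
                        check_connectivity = TRUE) {
  stopifnot(is.matrix(region), pixel_size > 0)
  fg <- region > 0
  npx <- sum(fg)
  if (npx == 0) stop("empty region", call. = FALSE)
  if (check_connectivity) {
    ncomp <- max(EBImage::bwlabel(EBImage::Image(fg * 1)))
    if (ncomp != 1)
      stop("region must be a single connected component (found ", ncomp, ")",
           call. = FALSE)
  }
  idx <- which(fg, arr.ind = TRUE)
  x <- idx[, 2]          # column = x
  y <- -idx[, 1]         # y up
  mx <- mean(x); my <- mean(y)
  dx <- x - mx; dy <- y - my
  mu20 <- mean(dx * dx); mu02 <- mean(dy * dy); mu11 <- mean(dx * dy)
  # eigenvalues of the second-moment matrix; 1/12 restores the variance a
  # single pixel contributes (a point set has none)
  mu20 <- mu20 + 1 / 12; mu02 <- mu02 + 1 / 12
  tr2 <- (mu20 + mu02) / 2
  det_root <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- tr2 + det_root; l2 <- max(tr2 - det_root, 1e-12)
  a <- 2 * sqrt(l1); b <- 2 * sqrt(l2)
  phi <- fold_angle(0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi)
  ecc <- sqrt(max(0, 1 - (b / a)^2))
  c2p <- orientation_parameter(phi)
  data.frame(
    centroid_x = mx, centroid_y = -my,
    a_px = a, b_px = b, phi_deg = phi, cos2phi = c2p,
    eccentricity = ecc,
    area_px = npx, area_um2 = npx * pixel_size^2,
    orientation_class = classify_orientation(c2p, ecc, circularity_threshold),
    valid = npx >= min_size
  )
}

#' Ellipse morphometry for every object in a label mask
#'
#' Applies [fit_ellipse()] to each labelled object and stacks the records.
#' Sub-threshold objects are kept with `valid = FALSE` so callers can audit
#' exclusions.
#'
#' @param labels integer label matrix (0 = background), e.g. from
#'   [make_nucleus_field()] or `EBImage::bwlabel()`.
#' @inheritParams fit_ellipse
#' @return data.frame with one row per label, columns as in [fit_ellipse()]
#'   plus `label`.
#' @examples
#' f <- make_nucleus_field("u2os_control", n = 4, seed = 2)
#' measure_nuclei(f$labels, f$pixel_size)
#' @export
measure_nuclei <- function(labels, pixel_size, min_size = 25,
                           circularity_threshold = 0.2) {
  stopifnot(is.matrix(labels))
  lin <- which(labels > 0)
  if (!length(lin)) stop("label mask contains no objects", call. = FALSE)
  h <- nrow(labels)
  rows <- ((lin - 1L) %% h) + 1L
  cols <- ((lin - 1L) %/% h) + 1L
  by_label <- split(seq_along(lin), labels[lin])
  recs <- lapply(names(by_label), function(k) {
    sel <- by_label[[k]]
    r <- rows[sel]; cc <- cols[sel]
    r0 <- min(r); c0 <- min(cc)
    crop <- matrix(FALSE, max(r) - r0 + 1L, max(cc) - c0 + 1L)
    crop[cbind(r - r0 + 1L, cc - c0 + 1L)] <- TRUE
    rec <- fit_ellipse(crop, pixel_size, min_size, circularity_threshold,
                       check_connectivity = FALSE)
    rec$centroid_x <- rec$centroid_x + c0 - 1
    rec$centroid_y <- rec$centroid_y + r0 - 1
    cbind(label = as.integer(k), rec)
  })
  out <- do.call(rbind, recs)
  out[order(out$label), , drop = FALSE]
}

#' Nuclear-to-cytoplasmic area ratio
#'
#' Ratio of nuclear to total cell area; areas are pixel counts scaled by
#' `pixel_size^2`, so the ratio itself is unit-free.
#'
#' @param nuclear_mask,cell_mask logical or 0/1 matrices of equal dimension;
#'   the nucleus must be contained in the cell.
#' @param pixel_size micrometres per pixel.
#' @return One-row data.frame: `cell_area_um2`, `nuclear_area_um2`,
#'   `nc_ratio`. A ratio of exactly 1 (nucleus fills the cell) triggers a
#'   containment warning.
#' @examples
#' cell <- matrix(1, 20, 20); nuc <- matrix(0, 20, 20); nuc[6:15, 6:15] <- 1
#' nc_ratio(nuc, cell, pixel_size = 0.25)
#' @export
nc_ratio <- function(nuclear_mask, cell_mask, pixel_size = 1) {
  stopifnot(is.matrix(nuclear_mask), is.matrix(cell_mask),
            all(dim(nuclear_mask) == dim(cell_mask)), pixel_size > 0)
  nuc <- nuclear_mask > 0; cell <- cell_mask > 0
  if (!sum(nuc) || !sum(cell)) stop("empty mask", call. = FALSE)
  if (any(nuc & !cell))
    stop("nuclear mask is not contained in the cell mask", call. = FALSE)
  r <- sum(nuc) / sum(cell)
  if (r == 1)
    warning("nuclear mask equals the cell mask (N/C ratio = 1)", call. = FALSE)
  data.frame(cell_area_um2 = sum(cell) * pixel_size^2,
             nuclear_area_um2 = sum(nuc) * pixel_size^2,
             nc_ratio = r)
}
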