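# Synthetic two-channel fluorescence cells (DNA + Src) with closed-form
# ground truth for CTCF validation.

#' Generate a synthetic two-channel fluorescence cell
#'
#' Renders one cell as a pair of concentric ellipses (cell body and nucleus,
#' the nuclear area drawn from the preset's distribution and the cell area
#' set by the drawn N/C ratio). The Src channel is
#' `background + cytoplasmic increment` inside the cell and
#' `background + nuclear_src_fold * cytoplasmic increment` inside the
#' nucleus, plus Gaussian noise; the DNA channel marks the nucleus. The
#' ground-truth table records the exact per-compartment means, so CTCF has
#' the closed-form expectation
#' `(nuclear_src_fold * cyt_increment) * nuclear_area`.
#'
#' @param preset a [generator_preset()] or preset name.
#' @param seed integer seed; bit-identical output per (preset, seed).
#' @param cyt_increment cytoplasmic intensity above background in the Src
#'   channel.
#' @param margin_px background margin around the cell (room for the
#'   background ring).
#' @return List: `dna`, `src` (numeric matrices), `cell_mask`,
#'   `nuclear_mask` (logical), `truth` (one-row data.frame: drawn
#'   `nuclear_area_um2`, `nc_ratio`, areas in pixels, `background`,
#'   `cyt_level`, `nuc_level`, `expected_ctcf`), `pixel_size`.
#' @examples
#' cell <- make_fluor_cell("u2os_capsaicin", seed = 3)
#' cell$truth$nc_ratio
#' @export
make_fluor_cell <- function(preset, seed, cyt_increment = 40,
                            margin_px = 30) {
  preset <- as_preset(preset)
  stopifnot(cyt_increment > 0, margin_px >= 0)
  with_rng_seed(seed, {
    ps <- preset$pixel_size
    nuc_area_um2 <- rnorm_trunc(1, preset$nuclear_area_mean,
                                preset$nuclear_area_sd,
                                lower = max(25 * ps^2,
                                            0.2 * preset$nuclear_area_mean))
    nc <- rnorm_trunc(1, preset$nc_ratio_mean, preset$nc_ratio_sd,
                      lower = 0.05, upper = 0.90)
    ar <- if (preset$aspect_ratio_mean == 1) 1 else
      rnorm_trunc(1, preset$aspect_ratio_mean,
                  0.1 * preset$aspect_ratio_mean, lower = 1)
    phi <- draw_orientations(1, preset$orientation_model, preset$kappa)

    nuc_area_px <- nuc_area_um2 / ps^2
    cell_area_px <- nuc_area_px / nc
    a_cell <- sqrt(cell_area_px * ar / pi); b_cell <- a_cell / ar
    a_nuc <- sqrt(nuc_area_px * ar / pi); b_nuc <- a_nuc / ar

    side <- ceiling(2 * a_cell + 2 * margin_px + 4)
    cx <- cy <- (side + 1) / 2
    cell_lab <- paint_ellipse(matrix(0L, side, side), cx, cy,
                              a_cell, b_cell, phi, 1L)
    nuc_lab <- paint_ellipse(matrix(0L, side, side), cx, cy,
                             a_nuc, b_nuc, phi, 1L)
    cell_mask <- cell_lab > 0
    nuclear_mask <- nuc_lab > 0
    if (any(nuclear_mask & !cell_mask))
      stop("nuclear mask not strictly inside the cell mask", call. = FALSE)

    bg <- preset$background_level
    cyt_level <- bg + cyt_increment
    nuc_level <- bg + preset$nuclear_src_fold * cyt_increment
    src <- matrix(bg, side, side)
    src[cell_mask] <- cyt_level
    src[nuclear_mask] <- nuc_level
    dna <- matrix(bg, side, side)
    dna[nuclear_mask] <- bg + 4 * max(bg, 25)
    if (preset$noise_sd > 0) {
      src <- src + matrix(rnorm(side^2, 0, preset$noise_sd), side)
      dna <- dna + matrix(rnorm(side^2, 0, preset$noise_sd), side)
    }

    truth <- data.frame(
      nuclear_area_um2 = nuc_area_um2,
      nc_ratio = nc,
      nuclear_area_px = sum(nuclear_mask),
      cell_area_px = sum(cell_mask),
      phi_deg = phi,
      background = bg,
      cyt_level = cyt_level,
      nuc_level = nuc_level,
      expected_ctcf = (nuc_level - bg) * sum(nuclear_mask)
    )
    list(dna = dna, src = src, cell_mask = cell_mask,
         nuclear_mask = nuclear_mask, truth = truth, pixel_size = ps)
  })
}
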