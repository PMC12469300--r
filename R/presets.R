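#' Construct a synthetic-image generator preset
#'
#' A preset bundles every knob the generators ([make_nucleus_field()],
#' [make_fractal_contour()], [make_fluor_cell()]) need: the target
#' distribution of nuclear areas, the nuclear orientation law, the target
#' boundary fractal dimension, the nuclear-to-cytoplasmic area ratio, the
#' nuclear Src enrichment fold, and imaging parameters (background level,
#' noise SD, pixel size).
#'
#' The shipped preset library (see [list_presets()]) calibrates these knobs to
#' published per-condition means for U-2 OS and SAOS-2 osteosarcoma cells with
#' and without TRPV1 agonist/antagonist treatment. Dispersion parameters that
#' were not published (per-cell SD of nuclear area and of the N/C ratio) are
#' generator choices, not claims about the data.
#'
#' @param name label for the preset.
#' @param nuclear_area_mean,nuclear_area_sd mean and SD of per-nucleus area,
#'   in square micrometres. Mean must be positive.
#' @param aspect_ratio_mean mean major/minor axis ratio of nuclei (>= 1).
#' @param orientation_model `"uniform"` (angles uniform on (-90, 90]) or
#'   `"perpendicular_biased"` (a von Mises law on the doubled angle
#'   \eqn{2\varphi}, centred at 180 degrees so that \eqn{\cos 2\varphi}
#'   concentrates near -1).
#' @param kappa von Mises concentration for `"perpendicular_biased"`;
#'   ignored (treated as 0) for `"uniform"`.
#' @param target_fd target box-counting fractal dimension of generated cell
#'   contours, in [1, 1.45].
#' @param nc_ratio_mean mean nuclear-to-cytoplasmic area ratio, in (0, 1).
#' @param nc_ratio_sd per-cell SD of the N/C ratio.
#' @param nuclear_src_fold nuclear Src level as a multiple of the cytoplasmic
#'   increment above background (> 0); 1 means no nuclear enrichment.
#' @param background_level,noise_sd camera background and Gaussian noise SD,
#'   in intensity units.
#' @param pixel_size micrometres per pixel.
#' @return An object of class `"generator_preset"` (a validated list).
#' @seealso [list_presets()], [get_preset()]
#' @export
generator_preset <- function(name,
                             nuclear_area_mean,
                             nuclear_area_sd = 0.2 * nuclear_area_mean,
                             aspect_ratio_mean = 1.5,
                             orientation_model = c("uniform", "perpendicular_biased"),
                             kappa = 0,
                             target_fd = 1.1,
                             nc_ratio_mean = 0.3,
                             nc_ratio_sd = 0.05,
                             nuclear_src_fold = 1,
                             background_level = 100,
                             noise_sd = 5,
                             pixel_size = 0.25) {
  orientation_model <- match.arg(orientation_model)
  stopifnot(
    is.character(name), length(name) == 1L,
    nuclear_area_mean > 0, nuclear_area_sd >= 0,
    aspect_ratio_mean >= 1,
    kappa >= 0,
    target_fd >= 1.0, target_fd < 1.5,
    nc_ratio_mean > 0, nc_ratio_mean < 1, nc_ratio_sd >= 0,
    nuclear_src_fold > 0,
    background_level >= 0, noise_sd >= 0,
    pixel_size > 0
  )
  structure(list(
    name = name,
    nuclear_area_mean = nuclear_area_mean,
    nuclear_area_sd = nuclear_area_sd,
    aspect_ratio_mean = aspect_ratio_mean,
    orientation_model = orientation_model,
    kappa = if (orientation_model == "uniform") 0 else kappa,
    target_fd = target_fd,
    nc_ratio_mean = nc_ratio_mean,
    nc_ratio_sd = nc_ratio_sd,
    nuclear_src_fold = nuclear_src_fold,
    background_level = background_level,
    noise_sd = noise_sd,
    pixel_size = pixel_size
  ), class = "generator_preset")
}

#' @export
print.generator_preset <- function(x, ...) {
  cat(sprintf(
    paste0("<generator_preset '%s'>\n",
           "  nuclear area: %.1f +/- %.1f um^2, aspect %.2f, orientation %s",
           "%s\n  target FD %.3f | N/C %.4f +/- %.3f | Src fold %.2f\n",
           "  background %.1f, noise SD %.1f, pixel size %.3f um/px\n"),
    x$name, x$nuclear_area_mean, x$nuclear_area_sd, x$aspect_ratio_mean,
    x$orientation_model,
    if (x$orientation_model == "perpendicular_biased")
      sprintf(" (kappa = %.1f)", x$kappa) else "",
    x$target_fd, x$nc_ratio_mean, x$nc_ratio_sd, x$nuclear_src_fold,
    x$background_level, x$noise_sd, x$pixel_size))
  invisible(x)
}

preset_library_path <- function() {
  system.file("extdata", "presets.json", package = "mechmorph", mustWork = TRUE)
}

#' Shipped condition presets
#'
#' `list_presets()` returns the names of the preset library shipped with the
#' package (a versioned JSON file under `extdata/`); `get_preset()` retrieves
#' one as a validated [generator_preset()].
#'
#' @param name preset name, one of `list_presets()`.
#' @param path optional path to an alternative preset JSON file with the same
#'   layout as the shipped one.
#' @return `list_presets()`: a character vector; `get_preset()`: a
#'   `generator_preset`.
#' @examples
#' list_presets()
#' get_preset("u2os_capsaicin")
#' @export
list_presets <- function(path = preset_library_path()) {
  names(jsonlite::read_json(path)$presets)
}

#' @rdname list_presets
#' @export
get_preset <- function(name, path = preset_library_path()) {
  lib <- jsonlite::read_json(path, simplifyVector = TRUE)$presets
  if (!name %in% names(lib))
    stop("unknown preset '", name, "'; available: ",
         paste(names(lib), collapse = ", "), call. = FALSE)
  p <- lib[[name]]
  generator_preset(
    name = name,
    nuclear_area_mean = p$nuclear_area_mean,
    nuclear_area_sd = p$nuclear_area_sd,
    aspect_ratio_mean = p$aspect_ratio_mean,
    orientation_model = p$orientation_model,
    kappa = p$kappa,
    target_fd = p$target_fd,
    nc_ratio_mean = p$nc_ratio_mean,
    nuclear_src_fold = p$nuclear_src_fold,
    background_level = p$background_level,
    noise_sd = p$noise_sd,
    pixel_size = p$pixel_size
  )
}

as_preset <- function(preset) {
  if (inherits(preset, "generator_preset")) return(preset)
  if (is.character(preset) && length(preset) == 1L) return(get_preset(preset))
  stop("`preset` must be a generator_preset or a preset name", call. = FALSE)
}
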