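# Run configuration and the umbrella pipeline driver: every stage runs from
# one serializable config + seed, logs its parameters, and writes a manifest
# so a run can be reproduced bit-identically.

#' Build a run configuration
#'
#' Bundles every tunable the pipeline stages read. Defaults mirror the
#' acquisition settings the analyses assume: 0.025 um/pixel for confocal
#' fluorescence, 0.010 um (10 nm) per pixel for AFM height maps.
#'
#' @param pixel_size micrometres per pixel for fluorescence images.
#' @param afm_pixel_size micrometres per pixel for AFM height maps.
#' @param seed integer seed for generator stages.
#' @param preset preset name for generator stages (see [list_presets()]).
#' @param n object count for generator stages.
#' @param grid_size raster size for contour generation.
#' @param min_size,circularity_threshold morphometry thresholds
#'   (see [fit_ellipse()]).
#' @param band_width roughness band width in pixels.
#' @param ring_gap,ring_width background-ring geometry in pixels.
#' @param out_dir output directory.
#' @param log_level `"quiet"` or `"info"`.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(pixel_size = 0.025, afm_pixel_size = 0.010,
                       seed = 1L, preset = "u2os_control", n = 50L,
                       grid_size = 1024L, min_size = 25L,
                       circularity_threshold = 0.2, band_width = 10L,
                       ring_gap = 2L, ring_width = 5L,
                       out_dir = ".", log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  cfg <- list(pixel_size = pixel_size, afm_pixel_size = afm_pixel_size,
              seed = as.integer(seed), preset = preset, n = as.integer(n),
              grid_size = as.integer(grid_size),
              min_size = as.integer(min_size),
              circularity_threshold = circularity_threshold,
              band_width = as.integer(band_width),
              ring_gap = as.integer(ring_gap),
              ring_width = as.integer(ring_width),
              out_dir = out_dir, log_level = log_level)
  stopifnot(pixel_size > 0, afm_pixel_size > 0, cfg$n >= 1,
            cfg$grid_size >= 128)
  structure(cfg, class = "run_config")
}

#' Read and write run configurations (YAML or JSON)
#'
#' Serialization round-trips: `read_run_config(write_run_config(cfg, p))`
#' reproduces `cfg` exactly.
#'
#' @param config a [run_config()].
#' @param path file ending in `.yaml`, `.yml`, or `.json`.
#' @return `write_run_config()`: the path, invisibly;
#'   `read_run_config()`: a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml"))
    yaml::write_yaml(unclass(config), path)
  else if (ext == "json")
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  else stop("config path must end in .yaml/.yml/.json", call. = FALSE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path,
                                                     simplifyVector = TRUE)
         else stop("config path must end in .yaml/.yml/.json", call. = FALSE)
  do.call(run_config, raw)
}

pipeline_log <- function(config, ...) {
  if (config$log_level == "info")
    message("[mechmorph] ", ...)
  invisible(NULL)
}

#' Run one pipeline stage from a configuration
#'
#' Stages: `"simulate_nuclei"` (nucleus field + per-nucleus morphometry +
#' orientation summary), `"simulate_contour"` (fractal contours + measured
#' FD per contour), `"simulate_fluorcell"` (fluorescence cells + CTCF +
#' N/C). Each stage writes its CSV outputs plus a `manifest.json` recording
#' the full config, a config hash, package version, and output checksums;
#' identical config + seed reproduce identical outputs and manifest hashes.
#' On failure, partial outputs of the stage are removed.
#'
#' @param config a [run_config()].
#' @param stage stage name.
#' @return Invisibly, a list with the output paths and the in-memory result
#'   tables.
#' @export
run_pipeline <- function(config,
                         stage = c("simulate_nuclei", "simulate_contour",
                                   "simulate_fluorcell")) {
  stopifnot(inherits(config, "run_config"))
  stage <- match.arg(stage)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  }
  out <- tryCatch({
    pipeline_log(config, "stage ", stage, " | preset ", config$preset,
                 " | seed ", config$seed, " | n ", config$n)
    preset <- get_preset(config$preset)
    tables <- list()
    if (stage == "simulate_nuclei") {
      field <- make_nucleus_field(preset, n = config$n, seed = config$seed)
      rec <- measure_nuclei(field$labels, field$pixel_size,
                            min_size = config$min_size,
                            circularity_threshold = config$circularity_threshold)
      tables$nuclei <- rec
      tables$orientation <- orientation_summary(rec[rec$valid, ])
      tables$truth <- field$truth
    } else if (stage == "simulate_contour") {
      rows <- lapply(seq_len(config$n), function(i) {
        ct <- make_fractal_contour(preset, grid_size = config$grid_size,
                                   seed = config$seed + i - 1L)
        bc <- box_count(ct$edge)
        data.frame(contour = i, seed = config$seed + i - 1L,
                   target_fd = ct$truth$target_fd, fd = bc$fd,
                   r_squared = bc$r_squared,
                   fit_min = bc$fit_range[1], fit_max = bc$fit_range[2])
      })
      tables$fd <- do.call(rbind, rows)
    } else {
      rows <- lapply(seq_len(config$n), function(i) {
        cell <- make_fluor_cell(preset, seed = config$seed + i - 1L)
        ring <- background_ring(cell$cell_mask, gap = config$ring_gap,
                                width = config$ring_width)
        cbind(ctcf(cell$src, cell$nuclear_mask, ring, id = i),
              nc_ratio(cell$nuclear_mask, cell$cell_mask, cell$pixel_size))
      })
      tables$ctcf <- do.call(rbind, rows)
    }
    for (nm in names(tables)) {
      p <- file.path(config$out_dir,
                     paste0(stage, "_", nm, "_seed", config$seed, ".csv"))
      write_results(tables[[nm]], p)
      written <- c(written, p)
    }
    cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                 digits = NA)
    manifest <- list(
      stage = stage,
      config = unclass(config),
      config_hash = unname(md5_string(cfg_json)),
      package_version = as.character(utils::packageVersion("mechmorph")),
      outputs = as.list(stats::setNames(unname(tools::md5sum(written)),
                                        basename(written)))
    )
    mp <- file.path(config$out_dir,
                    paste0(stage, "_manifest_seed", config$seed, ".json"))
    jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <- c(written, mp)
    pipeline_log(config, "wrote ", length(written), " files to ",
                 config$out_dir)
    invisible(list(paths = written, tables = tables, manifest = manifest))
  }, error = on_fail)
  out
}

md5_string <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(x), tf)
  unname(tools::md5sum(tf))
}
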