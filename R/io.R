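# Readers and writers: TIFF/PNG rasters, ASCII height-map matrices, CSV and
# JSON result tables. Pixel sizes always come from the caller or a config,
# never from image metadata tags.

#' Read a grayscale image, mask, or ASCII height map
#'
#' Supported kinds: `"tiff"` (8/16-bit grayscale, returned on the original
#' integer scale), `"png_mask"` (binarized at > 0), and `"ascii_matrix"`
#' (whitespace-delimited numbers, `#`-prefixed header/comment lines
#' skipped — the common AFM ASCII export dialect). `"auto"` dispatches on
#' the file extension.
#'
#' @param path file path.
#' @param kind `"auto"`, `"tiff"`, `"ascii_matrix"`, or `"png_mask"`.
#' @param pixel_size optional micrometres (or nm) per pixel, attached as the
#'   `pixel_size` attribute.
#' @return Numeric matrix (logical for `png_mask`) with attributes
#'   `pixel_size` and, for TIFF, `bits_per_sample`.
#' @export
read_image <- function(path, kind = c("auto", "tiff", "ascii_matrix",
                                      "png_mask"),
                       pixel_size = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (kind == "auto") {
    ext <- tolower(tools::file_ext(path))
    kind <- switch(ext,
                   tif = , tiff = "tiff",
                   png = "png_mask",
                   txt = , asc = , dat = "ascii_matrix",
                   stop("cannot infer image kind from extension '.", ext,
                        "' for ", path, call. = FALSE))
  }
  img <- switch(kind,
    tiff = {
      raw <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
      if (length(dim(raw)) == 3L) {
        if (dim(raw)[3] != 1L)
          stop("multi-channel TIFF not supported: ", path, call. = FALSE)
        raw <- raw[, , 1L]
      }
      m <- matrix(as.numeric(raw), nrow(raw), ncol(raw))
      attr(m, "bits_per_sample") <- attr(raw, "bits.per.sample")
      m
    },
    png_mask = {
      raw <- png::readPNG(path)
      if (length(dim(raw)) == 3L) raw <- raw[, , 1L]
      matrix(raw > 0, nrow(raw), ncol(raw))
    },
    ascii_matrix = {
      lines <- readLines(path, warn = FALSE)
      keep <- !grepl("^\\s*(#|$)", lines)
      if (!any(keep)) stop("empty ASCII matrix file: ", path, call. = FALSE)
      rows <- strsplit(trimws(lines[keep]), "\\s+")
      lens <- lengths(rows)
      if (length(unique(lens)) != 1L) {
        bad <- which(keep)[which(lens != lens[1])[1]]
        stop("ragged ASCII matrix in ", path, ": line ", bad, " has ",
             lens[lens != lens[1]][1], " values, expected ", lens[1],
             call. = FALSE)
      }
      vals <- suppressWarnings(as.numeric(unlist(rows)))
      if (anyNA(vals))
        stop("non-numeric values in ASCII matrix ", path, call. = FALSE)
      matrix(vals, nrow = length(rows), byrow = TRUE)
    })
  if (!is.null(pixel_size)) attr(img, "pixel_size") <- pixel_size
  img
}

#' Write a grayscale image or mask
#'
#' TIFF output stores integer intensities at the stated bit depth; PNG
#' output stores masks as 0/1. Values outside the representable range are
#' an error, not a silent clip.
#'
#' @param image numeric matrix (TIFF) or logical/0-1 matrix (PNG).
#' @param path destination; extension selects the format (`.tif`/`.tiff`
#'   or `.png`).
#' @param bits 8 or 16 (TIFF only).
#' @return Invisibly, `path`.
#' @export
write_image <- function(image, path, bits = 16L) {
  stopifnot(is.matrix(image))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    stopifnot(bits %in% c(8L, 16L))
    maxval <- 2^bits - 1
    if (min(image) < 0 || max(image) > maxval)
      stop("intensities outside [0, ", maxval, "] cannot be written at ",
           bits, " bits", call. = FALSE)
    tiff::writeTIFF(round(image) / maxval, path,
                    bits.per.sample = as.integer(bits))
  } else if (ext == "png") {
    png::writePNG((image > 0) * 1, path)
  } else {
    stop("unsupported image extension '.", ext, "'", call. = FALSE)
  }
  invisible(path)
}

#' Write result records to CSV or JSON
#'
#' Round-trip stable at full double precision; column order is preserved
#' as-is. An empty record set yields a header-only CSV (or empty JSON
#' array).
#'
#' @param records data.frame.
#' @param path destination path.
#' @param format `"auto"` (by extension), `"csv"`, or `"json"`.
#' @return Invisibly, `path`.
#' @seealso [read_results()]
#' @export
write_results <- function(records, path, format = c("auto", "csv", "json")) {
  stopifnot(is.data.frame(records))
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", json = "json",
                     stop("cannot infer format from extension of ", path,
                          call. = FALSE))
  if (format == "csv") {
    out <- records
    for (j in seq_along(out))
      if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
    write.csv(out, path, row.names = FALSE, quote = TRUE)
  } else {
    jsonlite::write_json(records, path, dataframe = "rows", digits = NA,
                         factor = "string", pretty = TRUE)
  }
  invisible(path)
}

#' Read back a results table written by [write_results()]
#'
#' @param path CSV or JSON path.
#' @return data.frame.
#' @export
read_results <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") read.csv(path, stringsAsFactors = FALSE)
  else if (ext == "json")
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  else stop("unsupported results extension '.", ext, "'", call. = FALSE)
}
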