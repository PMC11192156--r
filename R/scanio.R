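#' Construct a scan image
#'
#' A `scan_image` is one calibrated scanner pass: an integer pixel grid with
#' its resolution (dots per inch), a polarity flag stating whether seeds are
#' dark-on-light (the default for seeds scanned on a white platen) or
#' light-on-dark, and the originating file name ("tag") that carries the
#' collection metadata.
#'
#' @param pixels Integer matrix of intensities, rows = image rows (y
#'   downward), columns = x. Values must lie in `0:max_value`.
#' @param dpi Scan resolution in dots per inch. Must be positive.
#' @param polarity `"dark_on_light"` or `"light_on_dark"`.
#' @param source_tag File name the scan came from (may be `""`).
#' @param max_value Largest representable intensity: `1L` for bilevel scans,
#'   `255L` for 8-bit.
#' @return An object of class `scan_image`.
#' @export
scan_image <- function(pixels, dpi, polarity = c("dark_on_light", "light_on_dark"),
                       source_tag = "", max_value = 255L) {
  polarity <- match.arg(polarity)
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  storage.mode(pixels) <- "integer"
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) stop("image must be at least 1x1")
  if (!is.numeric(dpi) || length(dpi) != 1L || is.na(dpi) || dpi <= 0)
    stop("`dpi` must be a single positive number")
  rng <- range(pixels)
  if (rng[1] < 0L || rng[2] > max_value)
    stop("pixel intensities outside declared range 0..", max_value)
  structure(list(pixels = pixels, width_px = ncol(pixels), height_px = nrow(pixels),
                 dpi = as.numeric(dpi), polarity = polarity,
                 source_tag = source_tag, max_value = as.integer(max_value)),
            class = "scan_image")
}

#' @export
print.scan_image <- function(x, ...) {
  cat(sprintf("scan_image %dx%d px, %g dpi (%.4g x %.4g mm), %s, max %d%s\n",
              x$width_px, x$height_px, x$dpi,
              x$width_px * pixel_size_mm(x$dpi),
              x$height_px * pixel_size_mm(x$dpi),
              x$polarity, x$max_value,
              if (nzchar(x$source_tag)) paste0(", tag '", x$source_tag, "'") else ""))
  invisible(x)
}

#' Physical size of one pixel
#'
#' @param dpi Dots per inch; must be positive.
#' @return Pixel edge length in mm (`25.4 / dpi`). One pixel covers
#'   `pixel_size_mm(dpi)^2` square millimetres.
#' @examples
#' pixel_size_mm(600)   # 0.04233 mm at the protocol's scan resolution
#' @export
pixel_size_mm <- function(dpi) {
  if (!is.numeric(dpi) || any(is.na(dpi)) || any(dpi <= 0))
    stop("`dpi` must be positive")
  25.4 / dpi
}

#' Read a scan image from disk
#'
#' Reads an uncompressed TIFF (1-bit bilevel, 8-bit grayscale, or 8-bit RGB,
#' which is converted to luminance). The resolution is taken from the file's
#' embedded resolution tags unless `dpi_override` is given, which always wins.
#'
#' @param path Path to the TIFF file.
#' @param dpi_override Optional resolution to use instead of (or in the
#'   absence of) the embedded value.
#' @param polarity Seed polarity, passed to [scan_image()].
#' @return A [scan_image()]. 1-bit files yield intensities in `{0, 1}`.
#' @export
read_scan <- function(path, dpi_override = NULL,
                      polarity = c("dark_on_light", "light_on_dark")) {
  polarity <- match.arg(polarity)
  if (!file.exists(path)) stop("scan file does not exist: ", path)
  img <- read_tiff_gray(path)
  dpi <- if (!is.null(dpi_override)) dpi_override else img$dpi
  if (is.null(dpi) || is.na(dpi))
    stop("no resolution metadata in ", path, " and no `dpi_override` given")
  scan_image(img$pixels, dpi = dpi, polarity = polarity,
             source_tag = basename(path), max_value = img$max_value)
}

#' Write a scan image to disk
#'
#' Writes an uncompressed grayscale TIFF (1-bit when `max_value == 1`),
#' embedding the resolution so that [read_scan()] round-trips pixels and dpi.
#'
#' @param scan A [scan_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path) {
  stopifnot(inherits(scan, "scan_image"))
  write_tiff_gray(path, scan$pixels, dpi = scan$dpi, max_value = scan$max_value)
}

#' Parse collection metadata from a scan file name
#'
#' Scans are named `SITE_TRAP_DATE_SPECIES_FILL_repN.tif` (fields
#' underscore-delimited): collection site code, trap identifier, ISO
#' collection date, species code (`NA` for unknown field samples), fill
#' status (`filled`, `unfilled`, or `NA` for unknown), and replicate index
#' (`rep1`, `rep2`, ... for the duplicate arrangements of the same seeds).
#'
#' @param filename Scan file name (a leading directory and the `.tif`/
#'   `.tiff`/`.png` extension are stripped).
#' @param mode `"strict"` requires the full grammar; `"site_only"` takes the
#'   first underscore-delimited token as the site and leaves the rest
#'   unknown.
#' @return A one-row `data.frame` with columns `site`, `trap_id`,
#'   `collection_date`, `species_label` (`NA` when unknown), `fill_status`,
#'   `replicate_index`, `batch_id` and `source_tag`.
#' @examples
#' parse_tag("S05_T12_2019-10-01_TSHE_filled_rep1.tif")
#' @export
parse_tag <- function(filename, mode = c("strict", "site_only")) {
  mode <- match.arg(mode)
  tag <- basename(filename)
  stem <- sub("\\.(tif|tiff|png)$", "", tag, ignore.case = TRUE)
  parts <- strsplit(stem, "_", fixed = TRUE)[[1]]
  if (mode == "site_only") {
    if (length(parts) < 1L || !nzchar(parts[1]))
      stop("cannot extract a site code from '", tag, "'")
    return(data.frame(site = parts[1], trap_id = NA_character_,
                      collection_date = NA_character_,
                      species_label = NA_character_, fill_status = "unknown",
                      replicate_index = 1L, batch_id = NA_character_,
                      source_tag = tag, stringsAsFactors = FALSE))
  }
  if (length(parts) != 6L || !grepl("^rep[0-9]+$", parts[6]) || !all(nzchar(parts)))
    stop("file name '", tag, "' does not match the tag grammar ",
         "SITE_TRAP_DATE_SPECIES_FILL_repN (e.g. ",
         "'S05_T12_2019-10-01_TSHE_filled_rep1.tif')")
  rep_idx <- as.integer(sub("^rep", "", parts[6]))
  if (rep_idx < 1L) stop("replicate index must be >= 1 in '", tag, "'")
  fill <- parts[5]
  if (!(fill %in% c("filled", "unfilled", "NA", "unknown")))
    stop("fill status must be 'filled', 'unfilled' or 'NA' in '", tag, "'")
  data.frame(site = parts[1], trap_id = parts[2], collection_date = parts[3],
             species_label = if (parts[4] == "NA") NA_character_ else parts[4],
             fill_status = if (fill %in% c("NA", "unknown")) "unknown" else fill,
             replicate_index = rep_idx,
             batch_id = paste(parts[1], parts[2], parts[3], parts[5], sep = "_"),
             source_tag = tag, stringsAsFactors = FALSE)
}

#' Parse metadata for several scan file names
#'
#' @param filenames Character vector of scan file names.
#' @inheritParams parse_tag
#' @return A `data.frame` with one row per file name; see [parse_tag()].
#' @export
parse_tags <- function(filenames, mode = c("strict", "site_only")) {
  mode <- match.arg(mode)
  do.call(rbind, lapply(filenames, parse_tag, mode = mode))
}
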