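## Data model: calibrated images, ROIs, quantification parameters,
## measurement tables, and standard-format readers/writers.

.channel_roles <- c("surface_reporter", "presyn_marker", "postsyn_marker",
                    "ais_marker", "tag", "nuclear", "process")

#' Recognized channel roles
#'
#' @return Character vector of the channel roles a [calibrated_image()] may
#'   carry: surface reporter (e.g. GFP/tdTomato fill), presynaptic marker
#'   (GAD65, GAD67, CB1R, Syt2, VGlut1), postsynaptic marker (Gephyrin,
#'   PSD95), AIS marker (pIkBa), epitope tag (HA), nuclear stain, and a
#'   labeled-process (axon) channel.
#' @export
channel_roles <- function() .channel_roles

#' Calibrated single-channel image
#'
#' A 2D intensity grid with physical pixel size, bit depth and channel role.
#' Intensities must be non-negative and within the bit range.  The raster
#' convention is row = y, column = x, origin at the top-left pixel, 0-based
#' when expressed as coordinates.
#'
#' @param pixels Numeric matrix of intensities.
#' @param pixel_size_um Pixel edge length in micrometres (> 0).
#' @param bit_depth One of 8, 12, 16.
#' @param channel_role One of [channel_roles()].
#' @return An object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, pixel_size_um, bit_depth = 8L,
                             channel_role = "surface_reporter") {
  if (!is.matrix(pixels) || length(pixels) == 0)
    stop("`pixels` must be a non-empty matrix")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      is.na(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number")
  if (!bit_depth %in% c(8L, 12L, 16L))
    stop("`bit_depth` must be 8, 12 or 16")
  channel_role <- match.arg(channel_role, .channel_roles)
  if (anyNA(pixels) || min(pixels) < 0)
    stop("intensities must be non-negative and non-missing")
  if (max(pixels) > 2^bit_depth - 1)
    stop("intensities exceed 2^bit_depth - 1")
  structure(
    list(pixels = pixels, pixel_size_um = as.numeric(pixel_size_um),
         bit_depth = as.integer(bit_depth), channel_role = channel_role),
    class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image> %d x %d px, %.4g um/px, %d-bit, role: %s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um, x$bit_depth,
              x$channel_role))
  invisible(x)
}

#' @rdname calibrated_image
#' @param x Object to test.
#' @export
is_calibrated_image <- function(x) inherits(x, "calibrated_image")

## Extract a numeric pixel matrix from an image or matrix.
.px <- function(x) {
  if (is_calibrated_image(x)) x$pixels
  else if (is.matrix(x)) x
  else stop("expected a calibrated_image or a matrix")
}

## Pixel size lookup with fallback.
.ps <- function(x, default = NULL) {
  if (is_calibrated_image(x) || (is.list(x) && !is.null(x$pixel_size_um)))
    x$pixel_size_um
  else default
}

#' Rectangular region of interest
#'
#' 0-based, half-open rectangle `[x0, x0 + width) x [y0, y0 + height)` in
#' pixel coordinates (x = column, y = row, origin top-left).
#'
#' @param x0,y0 Top-left corner, 0-based pixels.
#' @param width,height Extent in pixels (> 0).
#' @param pixel_size_um Pixel size used to derive `area_um2`.
#' @return An object of class `roi` with derived `area_um2`.
#' @export
roi <- function(x0, y0, width, height, pixel_size_um) {
  stopifnot(width > 0, height > 0, x0 >= 0, y0 >= 0, pixel_size_um > 0)
  structure(list(x0 = x0, y0 = y0, width = width, height = height,
                 pixel_size_um = pixel_size_um,
                 area_um2 = width * height * pixel_size_um^2),
            class = "roi")
}

#' Check that an ROI lies fully inside an image
#' @param r An [roi()].
#' @param image A [calibrated_image()] or matrix.
#' @return `TRUE` invisibly, or an error.
#' @export
roi_inside <- function(r, image) {
  px <- .px(image)
  if (r$x0 + r$width > ncol(px) || r$y0 + r$height > nrow(px))
    stop("ROI extends outside the image")
  invisible(TRUE)
}

#' Quantification parameters
#'
#' Minimum particle sizes per marker class, circularity range, and the
#' mask-overlap criteria used to call appositions: a punctum contacts a soma
#' or AIS when >= 0.04 um^2 of its area colocalizes with the structure mask;
#' a presynaptic bouton and postsynaptic cluster form a synapse when their
#' masks colocalize by >= 0.03 um^2; a synapse originates from a labeled
#' axon when >= 0.025 um^2 colocalizes with the process mask.  All
#' comparisons use >= semantics against exact pixel-count areas.
#'
#' @param min_punctum_area_um2 Named vector of per-class minimum areas
#'   (um^2).  Defaults: 0.06 for GAD67/GAD65/CB1R boutons; 0.05 for
#'   Syt2/VGlut1 boutons and Gephyrin/PSD95 clusters.
#' @param circularity_range Inclusive `[lo, hi]` bounds on 4*pi*area/perim^2.
#' @param contact_min_overlap_um2 Punctum-on-structure criterion (um^2).
#' @param pair_min_overlap_um2 Pre/post pairing criterion (um^2).
#' @param process_min_overlap_um2 Axon-of-origin criterion (um^2).
#' @param min_soma_area_um2 Minimum soma size retained by [segment_somata()].
#' @param alpha Significance level for the statistics module.
#' @return An object of class `quant_params`.
#' @export
quant_params <- function(min_punctum_area_um2 = c(GAD67 = 0.06, GAD65 = 0.06,
                                                  CB1R = 0.06, Syt2 = 0.05,
                                                  VGlut1 = 0.05,
                                                  Gephyrin = 0.05,
                                                  PSD95 = 0.05),
                         circularity_range = c(0, 1),
                         contact_min_overlap_um2 = 0.04,
                         pair_min_overlap_um2 = 0.03,
                         process_min_overlap_um2 = 0.025,
                         min_soma_area_um2 = 50,
                         alpha = 0.05) {
  stopifnot(all(min_punctum_area_um2 > 0),
            length(circularity_range) == 2,
            circularity_range[1] >= 0, circularity_range[2] <= 1,
            circularity_range[1] <= circularity_range[2],
            contact_min_overlap_um2 > 0, pair_min_overlap_um2 > 0,
            process_min_overlap_um2 > 0, min_soma_area_um2 > 0,
            alpha > 0, alpha < 1)
  if (is.null(names(min_punctum_area_um2)))
    stop("`min_punctum_area_um2` must be a named vector of marker classes")
  structure(list(min_punctum_area_um2 = min_punctum_area_um2,
                 circularity_range = circularity_range,
                 contact_min_overlap_um2 = contact_min_overlap_um2,
                 pair_min_overlap_um2 = pair_min_overlap_um2,
                 process_min_overlap_um2 = process_min_overlap_um2,
                 min_soma_area_um2 = min_soma_area_um2,
                 alpha = alpha),
            class = "quant_params")
}

#' Load a single- or multi-page TIFF as calibrated images
#'
#' @param path TIFF file path.
#' @param pixel_size_um Pixel size in um/px (required; objective and zoom do
#'   not determine it unambiguously, so no default is offered).
#' @param channel_map Character vector assigning a role from
#'   [channel_roles()] to every page, in page order.  Names, if present, are
#'   kept as channel names.
#' @param bit_depth Bit depth at which intensities are interpreted.
#' @return Named list of [calibrated_image()], one per page, identical
#'   geometry.
#' @export
load_image <- function(path, pixel_size_um, channel_map, bit_depth = 8L) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != length(channel_map))
    stop(sprintf("channel count (%d) != channel_map length (%d) in %s",
                 length(pages), length(channel_map), path))
  scale <- 2^bit_depth - 1
  out <- lapply(seq_along(pages), function(i) {
    m <- pages[[i]]
    if (length(dim(m)) == 3) m <- m[, , 1]  # grayscale stored with 1 sample
    calibrated_image(round(m * scale), pixel_size_um, bit_depth,
                     channel_map[[i]])
  })
  names(out) <- if (!is.null(names(channel_map))) names(channel_map)
                else unname(channel_map)
  out
}

#' Write calibrated image(s) to a TIFF file
#'
#' Intensities are stored at the image bit depth (rounded to the nearest
#' representable level); a round trip through [load_image()] is lossless for
#' integer-valued images.
#'
#' @param images A [calibrated_image()] or list of them (multi-page output).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(images, path) {
  if (is_calibrated_image(images)) images <- list(images)
  stopifnot(all(vapply(images, is_calibrated_image, logical(1))))
  bits <- unique(vapply(images, function(x) x$bit_depth, integer(1)))
  if (length(bits) != 1) stop("all pages must share one bit depth")
  store_bits <- if (bits == 8L) 8L else 16L  # TIFF has no 12-bit container
  scale <- 2^bits - 1
  pages <- lapply(images, function(x) {
    m <- pmin(pmax(x$pixels, 0), scale) / scale
    ## quantize exactly to the stored integer levels
    round(m * (2^store_bits - 1)) / (2^store_bits - 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = store_bits)
  invisible(path)
}

#' Cell-level measurement table
#'
#' Tidy table of one value per cell with its sample key (cell, animal,
#' group), the unit of the hierarchical statistics.  `(cell_id, animal_id)`
#' must be unique.
#'
#' @param value Numeric cell-level measurements.
#' @param cell_id,animal_id,group_label Sample key vectors (recycled if
#'   length 1).
#' @param layer_depth_um Optional depth of the cell below the L1/L2 border.
#' @return A `data.frame` with class `measurement_table`.
#' @export
measurement_table <- function(value, cell_id, animal_id, group_label,
                              layer_depth_um = NULL) {
  n <- length(value)
  if (n == 0) stop("empty measurement table")
  if (!is.numeric(value) || anyNA(value)) stop("`value` must be numeric, no NA")
  tab <- data.frame(value = value,
                    cell_id = as.character(rep_len(cell_id, n)),
                    animal_id = as.character(rep_len(animal_id, n)),
                    group_label = as.character(rep_len(group_label, n)),
                    stringsAsFactors = FALSE)
  if (anyNA(tab$group_label) || any(tab$group_label == ""))
    stop("missing group labels")
  if (anyDuplicated(tab[c("cell_id", "animal_id")]))
    stop("duplicate (cell_id, animal_id) keys")
  if (!is.null(layer_depth_um)) tab$layer_depth_um <- rep_len(layer_depth_um, n)
  class(tab) <- c("measurement_table", "data.frame")
  tab
}

#' Write a measurement table to CSV
#'
#' One row per cell; columns `value, cell_id, animal_id, group_label`
#' (plus `layer_depth_um` when present).  Re-reading with
#' [read_measurements()] is lossless.
#'
#' @param table A [measurement_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(table, path) {
  if (!inherits(table, "measurement_table")) {
    table <- measurement_table(table$value, table$cell_id, table$animal_id,
                               table$group_label, table$layer_depth_um)
  }
  if (nrow(table) == 0) stop("empty measurement table")
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  measurement_table(d$value, d$cell_id, d$animal_id, d$group_label,
                    layer_depth_um = d$layer_depth_um)
}

#' Cell density from a count and a cortical area
#'
#' @param count Non-negative integer number of cells.
#' @param area_um2 Area of cortex analyzed, in um^2 (> 0).
#' @return Named numeric vector `c(per_um2, per_mm2)`;
#'   `per_mm2 = per_um2 * 1e6`.
#' @export
cell_density <- function(count, area_um2) {
  if (length(area_um2) != 1 || is.na(area_um2) || area_um2 <= 0)
    stop("`area_um2` must be a single positive number")
  if (any(count < 0)) stop("`count` must be non-negative")
  per_um2 <- count / area_um2
  c(per_um2 = per_um2, per_mm2 = per_um2 * 1e6)
}

#' Read a YAML run configuration
#'
#' Parses the config consumed by [run_pipeline()]; `quant:` and
#' `preprocess:` blocks are converted to [quant_params()] and
#' [preproc_params()] with defaults for unset fields.
#'
#' @param path YAML file path.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$quant)) cfg$quant <- do.call(quant_params, cfg$quant)
  if (!is.null(cfg$preprocess))
    cfg$preprocess <- do.call(preproc_params, cfg$preprocess)
  cfg
}
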