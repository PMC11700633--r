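#' Grayscale image container
#'
#' A `gray_image` holds a 2-D intensity raster in raw camera counts
#' (`0 .. 2^bit_depth - 1`) together with its bit depth. Rows index the
#' vertical (y) axis, columns the horizontal (x) axis; pixel coordinates are
#' 0-based, so pixel `(x, y)` lives at `pixels[y + 1, x + 1]`. Intensities
#' may be non-integer (e.g. noise-free rendered scenes keep continuous
#' values); quantization to integers happens only when an image is written
#' to disk.
#'
#' @param pixels numeric matrix of intensities (rows = height, cols = width).
#' @param bit_depth integer, 8 or 16.
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(pixels, bit_depth = 16L) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L))
    stop("`bit_depth` must be 8 or 16", call. = FALSE)
  maxval <- 2^bit_depth - 1
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > maxval))
    stop("intensities must lie in [0, ", maxval, "]", call. = FALSE)
  structure(list(pixels = pixels, bit_depth = bit_depth),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, %d-bit, range [%.1f, %.1f]>\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

#' Maximum representable intensity of an image
#' @param img a `gray_image`.
#' @return `2^bit_depth - 1`.
#' @export
dynamic_range <- function(img) 2^img$bit_depth - 1

#' Read a grayscale image
#'
#' Reads a single-plane grayscale TIFF (8- or 16-bit) or PNG (8-bit) into a
#' [gray_image]. Intensities are returned as raw counts; the bit depth is
#' inferred from the file. Multi-channel (RGB/RGBA) inputs are rejected.
#'
#' @param path file path ending in `.tif`, `.tiff` or `.png`.
#' @return A [gray_image].
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    info <- tiff::readTIFF(path, payload = FALSE)
    if (info$samples.per.pixel[1] != 1L)
      stop("multi-channel TIFF not supported (grayscale only): ", path,
           call. = FALSE)
    bd <- as.integer(info$bits.per.sample[1])
    if (!bd %in% c(8L, 16L))
      stop("unsupported TIFF bit depth ", bd, ": ", path, call. = FALSE)
    px <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(px)) == 3L) px <- px[, , 1, drop = TRUE]
    storage.mode(px) <- "double"
    gray_image(px, bd)
  } else if (ext == "png") {
    px <- png::readPNG(path)
    if (length(dim(px)) == 3L)
      stop("multi-channel PNG not supported (grayscale only): ", path,
           call. = FALSE)
    # png::readPNG rescales to [0,1]; this reader handles the 8-bit contract
    gray_image(round(px * 255), 8L)
  } else {
    stop("unsupported image format '.", ext, "' (use TIFF or PNG)",
         call. = FALSE)
  }
}

#' Write a grayscale image
#'
#' Writes a [gray_image] losslessly at its native bit depth. TIFF supports
#' 8- and 16-bit; PNG is restricted to 8-bit. Non-integer intensities are
#' rounded at this point.
#'
#' @param img a [gray_image].
#' @param path destination path (`.tif`/`.tiff` or `.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "gray_image"))
  ext <- tolower(tools::file_ext(path))
  maxval <- dynamic_range(img)
  px <- round(img$pixels) / maxval
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(px, path, bits.per.sample = img$bit_depth)
  } else if (ext == "png") {
    if (img$bit_depth != 8L)
      stop("PNG output is 8-bit only; use TIFF for 16-bit images",
           call. = FALSE)
    png::writePNG(px, path)
  } else {
    stop("unsupported image format '.", ext, "'", call. = FALSE)
  }
  invisible(path)
}

#' Validate a sample/control image pair
#'
#' A transmitted-light sample image and its blank control must share
#' dimensions and bit depth before any per-pixel arithmetic.
#'
#' @param sample,control [gray_image] objects.
#' @return `TRUE`, invisibly; errors on mismatch.
#' @export
validate_pair <- function(sample, control) {
  stopifnot(inherits(sample, "gray_image"), inherits(control, "gray_image"))
  if (!identical(dim(sample$pixels), dim(control$pixels)))
    stop("image pair dimensions differ: ",
         paste(dim(sample$pixels), collapse = "x"), " vs ",
         paste(dim(control$pixels), collapse = "x"), call. = FALSE)
  if (sample$bit_depth != control$bit_depth)
    stop("image pair bit depths differ: ", sample$bit_depth, " vs ",
         control$bit_depth, call. = FALSE)
  invisible(TRUE)
}

# Point-in-polygon rasterization (even-odd rule) evaluated at pixel centers
# (x + 0.5, y + 0.5), 0-based coordinates. An axis-aligned rectangle with
# corners (x0,y0)..(x1,y1) therefore covers columns x0..x1-1 and rows
# y0..y1-1: the half-open convention used package-wide.
rasterize_polygon <- function(vertices, width, height) {
  v <- as.matrix(vertices)
  if (ncol(v) != 2L || nrow(v) < 3L)
    stop("a polygon needs >= 3 (x, y) vertices", call. = FALSE)
  px <- matrix(rep(seq_len(width) - 0.5, each = height), nrow = height)
  py <- matrix(rep(seq_len(height) - 0.5, times = width), nrow = height)
  inside <- matrix(FALSE, height, width)
  n <- nrow(v)
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- (yi > py) != (yj > py)
    if (any(crosses)) {
      xint <- (xj - xi) * (py - yi) / (yj - yi) + xi
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  inside
}

#' Region-of-interest set
#'
#' Named boolean masks over an image grid. Three regions are required by the
#' quantification workflow: two sample-free peripheral calibration areas
#' (`peripheral_1`, `peripheral_2`) used to cancel acquisition-to-acquisition
#' illumination drift, and one `measurement` area over the tissue. The
#' measurement region must be disjoint from both peripheral regions.
#'
#' @param masks named list of logical matrices sharing one dimension.
#' @param require_standard if `TRUE` (default), enforce the presence of the
#'   three required regions and their disjointness.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(masks, require_standard = TRUE) {
  if (is.null(names(masks)) || any(names(masks) == ""))
    stop("all regions must be named", call. = FALSE)
  dims <- unique(lapply(masks, dim))
  if (length(dims) != 1L)
    stop("all region masks must share dimensions", call. = FALSE)
  if (require_standard) {
    need <- c("peripheral_1", "peripheral_2", "measurement")
    missing <- setdiff(need, names(masks))
    if (length(missing))
      stop("missing required region(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    if (any(masks$measurement & (masks$peripheral_1 | masks$peripheral_2)))
      stop("measurement region overlaps a peripheral calibration area",
           call. = FALSE)
  }
  structure(list(masks = masks), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat("<roi_set>\n")
  for (nm in names(x$masks))
    cat(sprintf("  %-14s %d px\n", nm, sum(x$masks[[nm]])))
  invisible(x)
}

#' Load regions of interest from a JSON polygon file
#'
#' The ROI file is a JSON object mapping region names to polygons, each
#' polygon an array of `[x, y]` vertices in 0-based pixel coordinates.
#' Polygons are rasterized with the even-odd rule at pixel centers under the
#' half-open convention (see [roi_set] for required region names).
#'
#' @param path JSON file path.
#' @param image the [gray_image] the regions refer to (sets the grid).
#' @param require_standard passed to [roi_set].
#' @return An `roi_set`.
#' @export
load_rois <- function(path, image, require_standard = TRUE) {
  stopifnot(inherits(image, "gray_image"))
  if (!file.exists(path))
    stop("ROI file not found: ", path, call. = FALSE)
  spec <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  h <- nrow(image$pixels); w <- ncol(image$pixels)
  masks <- lapply(spec, function(poly) {
    poly <- as.matrix(poly)
    if (any(poly[, 1] < 0) || any(poly[, 1] > w) ||
        any(poly[, 2] < 0) || any(poly[, 2] > h))
      stop("polygon vertex outside image bounds (", w, " x ", h, ")",
           call. = FALSE)
    rasterize_polygon(poly, w, h)
  })
  roi_set(masks, require_standard = require_standard)
}

#' Write regions of interest to a JSON polygon file
#'
#' Inverse companion of [load_rois] for rectangle-based ROI sets created by
#' the scene generator: writes a name -> vertex-list JSON object.
#'
#' @param polygons named list of vertex matrices (columns x, y; 0-based).
#' @param path destination JSON path.
#' @return `path`, invisibly.
#' @export
write_rois <- function(polygons, path) {
  jsonlite::write_json(lapply(polygons, function(p) unname(as.matrix(p))),
                       path, matrix = "rowmajor")
  invisible(path)
}

# Rectangle polygon helper: corners (x0, y0) .. (x1, y1), half-open.
rect_polygon <- function(x0, y0, x1, y1) {
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}
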