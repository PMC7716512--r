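# Pixel class codes used in the `class` matrix of a pixel_grid.
.WALL <- 0L
.INTERIOR <- 1L
.EXCLUDED <- 2L

.CLASS_NAMES <- c(wall = .WALL, interior = .INTERIOR, excluded = .EXCLUDED)

#' Construct a classified pixel grid
#'
#' A `pixel_grid` is the raw substrate of the pipeline: a raster in which
#' every pixel is classified as cell-wall, cell-interior, or excluded tissue
#' (tissue present in the image but left out of the simulated layout).
#'
#' @param class_matrix integer matrix (rows x cols) with values 0 (wall),
#'   1 (interior) or 2 (excluded). Character matrices with values
#'   `"wall"`, `"interior"`, `"excluded"` are also accepted.
#' @param pixel_size physical side length of one pixel, in micrometres per
#'   pixel. Defaults to 1 (i.e. work in pixel units).
#' @return an object of class `pixel_grid` with elements `class`
#'   (integer matrix), `height`, `width` and `pixel_size`.
#' @export
pixel_grid <- function(class_matrix, pixel_size = 1) {
  if (is.character(class_matrix)) {
    m <- matrix(.CLASS_NAMES[class_matrix], nrow(class_matrix), ncol(class_matrix))
    if (anyNA(m)) stop("unknown pixel class name in class_matrix")
    class_matrix <- m
  }
  if (!is.matrix(class_matrix)) stop("class_matrix must be a matrix")
  storage.mode(class_matrix) <- "integer"
  if (nrow(class_matrix) < 1L || ncol(class_matrix) < 1L)
    stop("grid must have at least one pixel")
  if (!all(class_matrix %in% c(.WALL, .INTERIOR, .EXCLUDED)))
    stop("pixel classes must be 0 (wall), 1 (interior) or 2 (excluded)")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a single positive number")
  structure(
    list(class = class_matrix, height = nrow(class_matrix),
         width = ncol(class_matrix), pixel_size = as.numeric(pixel_size)),
    class = "pixel_grid")
}

#' @export
print.pixel_grid <- function(x, ...) {
  tab <- table(factor(x$class, levels = c(.WALL, .INTERIOR, .EXCLUDED),
                      labels = names(.CLASS_NAMES)))
  cat(sprintf("pixel_grid: %d x %d px (%.4g um/px)\n", x$height, x$width,
              x$pixel_size))
  cat(sprintf("  wall: %d  interior: %d  excluded: %d\n",
              tab[["wall"]], tab[["interior"]], tab[["excluded"]]))
  invisible(x)
}

#' Load a preprocessed layout image
#'
#' Reads a PNG or TIFF raster in which pixel values encode the wall /
#' interior / excluded classification, and returns a [pixel_grid].
#' The raster must be single-channel, or RGB with identical channels
#' (a grayscale image saved as RGB).
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @param pixel_size micrometres per pixel (default 1).
#' @param class_map named character vector mapping 8-bit pixel values to
#'   classes; the default is `c("0" = "wall", "255" = "interior",
#'   "128" = "excluded")`. Every distinct value in the image must appear.
#' @return a [pixel_grid].
#' @export
load_layout_image <- function(path, pixel_size = 1,
                              class_map = c("0" = "wall", "255" = "interior",
                                            "128" = "excluded")) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)"))
  if (length(dim(img)) == 3L) {
    nch <- dim(img)[3L]
    rgb <- img[, , seq_len(min(nch, 3L)), drop = FALSE]
    if (max(abs(sweep(rgb, c(1, 2), rgb[, , 1L]))) > 0)
      stop("RGB image channels differ; supply a grayscale layout image")
    img <- img[, , 1L]
  }
  vals <- as.integer(round(img * 255))
  uniq <- sort(unique(vals))
  known <- as.integer(names(class_map))
  if (anyNA(known)) stop("class_map names must be integer pixel values")
  missing_vals <- setdiff(uniq, known)
  if (length(missing_vals))
    stop("pixel value(s) not in class_map: ",
         paste(missing_vals, collapse = ", "))
  codes <- .CLASS_NAMES[match(class_map, names(.CLASS_NAMES))]
  if (anyNA(codes)) stop("class_map values must be wall/interior/excluded")
  cls <- matrix(codes[match(vals, known)], nrow(img), ncol(img))
  pixel_grid(cls, pixel_size = pixel_size)
}

#' Write a pixel grid as an 8-bit grayscale PNG
#'
#' Inverse of [load_layout_image] under the default class map.
#'
#' @param grid a [pixel_grid].
#' @param path output `.png` path.
#' @param class_values named numeric vector giving the 8-bit value written
#'   for each class.
#' @return `path`, invisibly.
#' @export
write_layout_image <- function(grid, path,
                               class_values = c(wall = 0, interior = 255,
                                                excluded = 128)) {
  stopifnot(inherits(grid, "pixel_grid"))
  vals <- class_values[names(.CLASS_NAMES)[match(grid$class, .CLASS_NAMES)]]
  png::writePNG(matrix(vals / 255, grid$height, grid$width), target = path)
  invisible(path)
}

# 16-bit label raster IO: 0 = wall pixel, otherwise the region id.
#' Write a region-label raster as a 16-bit TIFF
#' @param labels integer matrix of region ids (0 on wall pixels).
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  if (max(labels) > 65535L) stop("more than 65535 regions")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a 16-bit label raster written by [write_labels]
#' @param path a `.tif` path.
#' @return integer matrix of region ids.
#' @export
read_labels <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}
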