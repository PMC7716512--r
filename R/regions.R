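# Connected-component labeling on a logical pixel mask via the pixel
# adjacency graph. Returns an integer matrix: 0 outside the mask, else a
# component label; labels are renumbered so that label order follows the
# raster-scan (row-major) order of each component's first pixel.
.label_components <- function(mask, connectivity = 4L) {
  stopifnot(connectivity %in% c(4L, 8L))
  H <- nrow(mask); W <- ncol(mask)
  idx <- which(mask)                      # column-major linear indices
  n <- length(idx)
  lab <- matrix(0L, H, W)
  if (n == 0L) return(lab)
  vid <- matrix(0L, H, W)
  vid[idx] <- seq_len(n)
  r <- ((idx - 1L) %% H) + 1L
  c <- ((idx - 1L) %/% H) + 1L
  offs <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  from <- integer(0); to <- integer(0)
  for (o in offs) {
    rr <- r + o[1L]; cc <- c + o[2L]
    ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
    ok[ok] <- mask[cbind(rr[ok], cc[ok])]
    from <- c(from, vid[cbind(r[ok], c[ok])])
    to <- c(to, vid[cbind(rr[ok], cc[ok])])
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to))
  memb <- igraph::components(g)$membership
  # renumber by raster-scan order of first pixel per component
  rank_rm <- (r - 1L) * W + c
  first <- tapply(rank_rm, memb, min)
  new_id <- integer(length(first))
  new_id[order(first)] <- seq_along(first)
  lab[idx] <- new_id[memb]
  lab
}

#' Construct a pixel region
#'
#' A `region` is a set of pixels of one connected component together with
#' its integer index and the dimensions of the parent image (needed for the
#' y-up coordinate convention).
#'
#' @param pixels two-column integer matrix of (row, col) pixel coordinates,
#'   1-based.
#' @param id integer region index.
#' @param dim `c(height, width)` of the parent image.
#' @return an object of class `region`.
#' @export
region <- function(pixels, id, dim) {
  pixels <- matrix(as.integer(pixels), ncol = 2L,
                   dimnames = list(NULL, c("row", "col")))
  if (nrow(pixels) == 0L) stop("region must contain at least one pixel")
  ord <- order((pixels[, 1L] - 1L) * dim[2L] + pixels[, 2L])
  structure(list(pixels = pixels[ord, , drop = FALSE], id = as.integer(id),
                 height = as.integer(dim[1L]), width = as.integer(dim[2L])),
            class = "region")
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("region id %d: %d px in a %d x %d image\n",
              x$id, nrow(x$pixels), x$height, x$width))
  invisible(x)
}

#' Identify cells, exterior and excluded tissue as connected components
#'
#' Partitions all non-wall pixels into connected components and applies the
#' index scheme of the structural model: every excluded-tissue component
#' receives index 2, every interior component touching the image border
#' receives index 1 (the external environment), and the remaining N interior
#' components — the cells — receive indices 3..N+2 in raster-scan order of
#' each component's first pixel. Components sharing index 1 or 2 are merged
#' into a single region.
#'
#' @param grid a [pixel_grid].
#' @param connectivity pixel connectivity for the components, 4 (default)
#'   or 8. Cells use 4-connectivity so that they cannot leak diagonally
#'   through one-pixel walls.
#' @return a list with elements `regions` (list of [region]s keyed by id as
#'   character), `labels` (integer matrix, 0 on wall pixels) and `n_cells`.
#' @export
find_regions <- function(grid, connectivity = 4L) {
  stopifnot(inherits(grid, "pixel_grid"))
  H <- grid$height; W <- grid$width
  int_lab <- .label_components(grid$class == .INTERIOR, connectivity)
  exc_lab <- .label_components(grid$class == .EXCLUDED, connectivity)
  labels <- matrix(0L, H, W)
  regions <- list()

  if (max(exc_lab) > 0L) {
    px <- which(exc_lab > 0L)
    labels[px] <- 2L
    regions[["2"]] <- region(cbind(((px - 1L) %% H) + 1L,
                                   ((px - 1L) %/% H) + 1L), 2L, c(H, W))
  }

  n_int <- max(int_lab)
  if (n_int > 0L) {
    border_labs <- unique(c(int_lab[1L, ], int_lab[H, ],
                            int_lab[, 1L], int_lab[, W]))
    border_labs <- border_labs[border_labs > 0L]
    if (length(border_labs)) {
      px <- which(matrix(int_lab %in% border_labs, H, W))
      labels[px] <- 1L
      regions[["1"]] <- region(cbind(((px - 1L) %% H) + 1L,
                                     ((px - 1L) %/% H) + 1L), 1L, c(H, W))
    }
    cell_labs <- setdiff(seq_len(n_int), border_labs)
    # .label_components already orders labels by raster-scan first pixel
    next_id <- 3L
    for (cl in cell_labs) {
      px <- which(int_lab == cl)
      labels[px] <- next_id
      regions[[as.character(next_id)]] <-
        region(cbind(((px - 1L) %% H) + 1L, ((px - 1L) %/% H) + 1L),
               next_id, c(H, W))
      next_id <- next_id + 1L
    }
  }
  n_cells <- sum(as.integer(names(regions)) >= 3L)
  if (n_cells == 0L) stop("no cells found in the layout image")
  list(regions = regions, labels = labels, n_cells = n_cells)
}

# --- per-region geometry -----------------------------------------------

# image coordinates: x = col - 1, y = height - row (y increases upward)
.region_xy <- function(region) {
  cbind(x = region$pixels[, "col"] - 1, y = region$height - region$pixels[, "row"])
}

#' Centroid of a region
#'
#' The arithmetic mean of the region's pixel coordinates in the y-up image
#' frame (x = column, y = height - 1 - row, both 0-based).
#'
#' @param region a [region].
#' @return named numeric vector `c(x, y)` in pixels.
#' @export
region_centroid <- function(region) {
  xy <- .region_xy(region)
  c(x = mean(xy[, "x"]), y = mean(xy[, "y"]))
}

#' Cross-sectional area of a region
#'
#' @param region a [region].
#' @param pixel_size micrometres per pixel.
#' @return area in square micrometres: pixel count times `pixel_size^2`.
#' @export
region_area <- function(region, pixel_size = 1) {
  stopifnot(pixel_size > 0)
  nrow(region$pixels) * pixel_size^2
}

#' Crack-length perimeter of a region
#'
#' Counts the unit pixel edges separating a region pixel from a non-region
#' pixel (image boundary included), times `pixel_size`. A single pixel has
#' perimeter 4, a 2x2 square 8.
#'
#' @inheritParams region_area
#' @return perimeter in micrometres.
#' @export
region_perimeter <- function(region, pixel_size = 1) {
  H <- region$height; W <- region$width
  m <- matrix(FALSE, H + 2L, W + 2L)
  m[cbind(region$pixels[, "row"] + 1L, region$pixels[, "col"] + 1L)] <- TRUE
  inner <- m[2:(H + 1L), 2:(W + 1L), drop = FALSE]
  edges <- sum(inner & !m[1:H, 2:(W + 1L), drop = FALSE]) +
    sum(inner & !m[3:(H + 2L), 2:(W + 1L), drop = FALSE]) +
    sum(inner & !m[2:(H + 1L), 1:W, drop = FALSE]) +
    sum(inner & !m[2:(H + 1L), 3:(W + 2L), drop = FALSE])
  edges * pixel_size
}

#' Axis-aligned bounding rectangle of a region
#'
#' The smallest axis-aligned rectangle containing all pixel centers, in the
#' y-up frame.
#'
#' @param region a [region].
#' @return named numeric vector `c(x_min, x_max, y_min, y_max)` in pixels.
#' @export
bounding_rectangle <- function(region) {
  xy <- .region_xy(region)
  c(x_min = min(xy[, "x"]), x_max = max(xy[, "x"]),
    y_min = min(xy[, "y"]), y_max = max(xy[, "y"]))
}

#' Characteristic ellipse of a region
#'
#' The ellipse with the same normalized second central moments as the
#' region. Each pixel contributes a 1/12 moment of its own unit square, so
#' single pixels and one-pixel-wide lines receive non-degenerate ellipses.
#' With centered pixel coordinates the moments are
#' mu20 = mean((x - xbar)^2) + 1/12, mu02 = mean((y - ybar)^2) + 1/12,
#' mu11 = mean((x - xbar)(y - ybar)); the axes are 4 sqrt(lambda) for the
#' two eigenvalues of the moment matrix, and the orientation angle is
#' atan2(2 mu11, mu20 - mu02) / 2, measured counter-clockwise from the
#' x-axis in the y-up frame.
#'
#' @param region a [region].
#' @return a list of class `ellipse` with `major_axis_length`,
#'   `minor_axis_length` (pixels) and `angle_deg` in (-90, 90].
#' @export
characteristic_ellipse <- function(region) {
  xy <- .region_xy(region)
  dx <- xy[, "x"] - mean(xy[, "x"])
  dy <- xy[, "y"] - mean(xy[, "y"])
  mu20 <- mean(dx^2) + 1 / 12
  mu02 <- mean(dy^2) + 1 / 12
  mu11 <- mean(dx * dy)
  common <- (mu20 + mu02) / 2
  diff <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  angle <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  structure(list(major_axis_length = 4 * sqrt(common + diff),
                 minor_axis_length = 4 * sqrt(common - diff),
                 angle_deg = angle),
            class = "ellipse")
}

#' @export
print.ellipse <- function(x, ...) {
  cat(sprintf("ellipse: major %.4g px, minor %.4g px, angle %.4g deg\n",
              x$major_axis_length, x$minor_axis_length, x$angle_deg))
  invisible(x)
}
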