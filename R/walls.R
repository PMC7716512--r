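# Cell and wall records: indexed regions plus their geometric features.

.make_cell_record <- function(region, pixel_size, cell_type = "default") {
  structure(list(
    id = region$id,
    region = region,
    area = region_area(region, pixel_size),
    perimeter = region_perimeter(region, pixel_size),
    centroid = region_centroid(region),
    bounding_rect = bounding_rectangle(region),
    ellipse = characteristic_ellipse(region),
    cell_type = cell_type), class = "cell_record")
}

#' Assign every wall pixel to its separating cell pair
#'
#' Each wall pixel receives the two distinct region indices whose pixels
#' are nearest to it by Euclidean distance (nearest-label propagation).
#' When three or more indices tie at equal distance, the two smallest
#' indices are taken, giving the lexicographically smallest pair. Pixels
#' for which only one region exists in the whole image stay unassigned.
#'
#' @param grid a [pixel_grid].
#' @param labels integer label matrix from [find_regions] (0 on wall
#'   pixels, region id elsewhere).
#' @return data frame with one row per wall pixel: `row`, `col` (1-based),
#'   `i`, `j` (the separating pair, `i < j`; `NA` if unassigned).
#' @export
assign_wall_pixels <- function(grid, labels) {
  stopifnot(inherits(grid, "pixel_grid"))
  H <- grid$height; W <- grid$width
  widx <- which(grid$class == .WALL)
  if (!length(widx))
    return(data.frame(row = integer(), col = integer(),
                      i = integer(), j = integer()))
  wr <- ((widx - 1L) %% H) + 1L
  wc <- ((widx - 1L) %/% H) + 1L
  n <- length(widx)
  res_i <- rep(NA_integer_, n)
  res_j <- rep(NA_integer_, n)
  pending <- seq_len(n)
  radius <- 3L
  max_radius <- max(H, W)
  repeat {
    dr <- rep(-radius:radius, times = 2L * radius + 1L)
    dc <- rep(-radius:radius, each = 2L * radius + 1L)
    keep <- !(dr == 0L & dc == 0L)
    dr <- dr[keep]; dc <- dc[keep]
    dist <- sqrt(dr^2 + dc^2)
    m <- length(dr)
    np <- length(pending)
    rr <- rep(wr[pending], times = m) + rep(dr, each = np)
    cc <- rep(wc[pending], times = m) + rep(dc, each = np)
    dd <- rep(dist, each = np)
    pp <- rep(pending, times = m)
    ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
    lab <- integer(length(rr))
    lab[ok] <- labels[cbind(rr[ok], cc[ok])]
    ok <- ok & lab > 0L
    pp <- pp[ok]; lab <- lab[ok]; dd <- dd[ok]
    still <- integer(0)
    if (length(pp)) {
      # min distance per (pixel, label), then two nearest labels per pixel
      ord <- order(pp, lab, dd)
      pp <- pp[ord]; lab <- lab[ord]; dd <- dd[ord]
      keep1 <- !duplicated(cbind(pp, lab))
      pp <- pp[keep1]; lab <- lab[keep1]; dd <- dd[keep1]
      ord <- order(pp, dd, lab)
      pp <- pp[ord]; lab <- lab[ord]; dd <- dd[ord]
      rank <- sequence(rle(pp)$lengths)
      first <- rank == 1L
      second <- rank == 2L
      got2 <- pp[second]
      # exact only if the 2nd distance is covered by the scanned square
      exact <- dd[second] <= radius
      res_i[got2[exact]] <- lab[first][match(got2[exact], pp[first])]
      res_j[got2[exact]] <- lab[second][exact]
      still <- c(pp[first][!pp[first] %in% got2], got2[!exact])
    } else {
      still <- pending
    }
    # pixels that saw < 2 labels keep waiting for a larger radius
    pending <- sort(unique(c(still, setdiff(pending, pp))))
    pending <- pending[is.na(res_i[pending])]
    if (!length(pending) || radius >= max_radius) break
    radius <- min(max_radius, radius * 2L)
  }
  ii <- pmin(res_i, res_j)
  jj <- pmax(res_i, res_j)
  data.frame(row = wr, col = wc, i = ii, j = jj)
}

# projection extent of one connected wall component on its own major axis
.segment_length_px <- function(region) {
  e <- characteristic_ellipse(region)
  th <- e$angle_deg * pi / 180
  xy <- .region_xy(region)
  p <- xy[, "x"] * cos(th) + xy[, "y"] * sin(th)
  max(p) - min(p) + 1
}

#' Wall length estimator
#'
#' The wall's pixels are split into 8-connected components; each component
#' contributes the extent of its pixel centers projected on its own
#' characteristic-ellipse major axis, plus one pixel. Component lengths are
#' summed (a pair of cells touching in two places has one wall record whose
#' length is the total contact).
#'
#' @param wall a wall record from [extract_wall_segments].
#' @param pixel_size micrometres per pixel.
#' @return length in micrometres.
#' @export
wall_length <- function(wall, pixel_size = 1) {
  reg <- wall$region
  mask <- matrix(FALSE, reg$height, reg$width)
  mask[reg$pixels] <- TRUE
  lab <- .label_components(mask, 8L)
  comp <- lab[reg$pixels]
  total <- 0
  for (k in unique(comp)) {
    sub <- region(reg$pixels[comp == k, , drop = FALSE], reg$id,
                  c(reg$height, reg$width))
    total <- total + .segment_length_px(sub)
  }
  total * pixel_size
}

#' Wall width estimator
#'
#' Width is the wall's area divided by its length, clamped from below by
#' one pixel: `max(pixel_count * pixel_size^2 / length, pixel_size)`.
#'
#' @inheritParams wall_length
#' @return width in micrometres.
#' @export
wall_width <- function(wall, pixel_size = 1) {
  len <- if (!is.null(wall$length)) wall$length else wall_length(wall, pixel_size)
  max(nrow(wall$region$pixels) * pixel_size^2 / len, pixel_size)
}

#' Group assigned wall pixels into per-pair wall segments
#'
#' For every cell pair \{i, j\} present in the assignment, all pixels
#' assigned to that pair are collected into one wall record (disjoint
#' contact patches between the same two cells are merged; the length sums
#' the patch lengths, other features are computed on the union).
#'
#' @param assignment data frame from [assign_wall_pixels].
#' @param grid the [pixel_grid] the assignment was computed on.
#' @return list of wall records, each with elements `i`, `j`, `region`,
#'   `length`, `width`, `centroid`, `bounding_rect`, `ellipse` and
#'   `orientation` (0 = not yet determined).
#' @export
extract_wall_segments <- function(assignment, grid) {
  stopifnot(inherits(grid, "pixel_grid"))
  ps <- grid$pixel_size
  a <- assignment[!is.na(assignment$i), , drop = FALSE]
  if (!nrow(a)) return(list())
  key <- paste(a$i, a$j, sep = "-")
  out <- list()
  for (k in sort(unique(key))) {
    rows <- a[key == k, , drop = FALSE]
    reg <- region(cbind(rows$row, rows$col), 0L, c(grid$height, grid$width))
    w <- list(i = rows$i[1L], j = rows$j[1L], region = reg)
    w$length <- wall_length(w, ps)
    w$width <- wall_width(w, ps)
    w$centroid <- region_centroid(reg)
    w$bounding_rect <- bounding_rectangle(reg)
    w$ellipse <- characteristic_ellipse(reg)
    w$orientation <- 0L
    out[[k]] <- structure(w, class = "wall_record")
  }
  out
}

#' @export
print.wall_record <- function(x, ...) {
  cat(sprintf("wall (%d, %d): %d px, length %.4g, width %.4g\n",
              x$i, x$j, nrow(x$region$pixels), x$length, x$width))
  invisible(x)
}
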