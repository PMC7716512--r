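#' Assemble the indexed structural model of the tissue
#'
#' Collects cell and wall records into the (N+2)-indexed structural model:
#' index 1 is the external environment, index 2 the excluded tissue, and
#' indices 3..N+2 the N cells. Wall lengths and widths are stored in
#' symmetric (N+2) x (N+2) matrices with zeros exactly where two regions
#' share no wall; the orientation matrix starts at 0 (undetermined
#' everywhere) and is antisymmetric under the code/opposite pairing once
#' filled by [orient_all].
#'
#' @param cells list of cell records (internal structure; usually built by
#'   [extract_structural_model]).
#' @param walls list of wall records from [extract_wall_segments].
#' @param pixel_size micrometres per pixel.
#' @param labels optional integer label raster (kept for rendering).
#' @return an object of class `structural_model`.
#' @export
build_structural_model <- function(cells, walls, pixel_size = 1,
                                   labels = NULL) {
  ids <- unname(vapply(cells, function(x) x$id, integer(1)))
  cell_ids <- sort(ids[ids >= 3L])
  n <- length(cell_ids)
  if (n == 0L) stop("no cells found in the layout image")
  if (!identical(cell_ids, 3L:(n + 2L)))
    stop("cell ids must be consecutive from 3 to N + 2")
  dim_n <- n + 2L
  adjacency <- matrix(FALSE, dim_n, dim_n)
  length_matrix <- matrix(0, dim_n, dim_n)
  width_matrix <- matrix(0, dim_n, dim_n)
  orientation_matrix <- matrix(0L, dim_n, dim_n)
  seen <- character(0)
  for (w in walls) {
    key <- paste(w$i, w$j, sep = "-")
    if (key %in% seen) stop("duplicate wall pair (", w$i, ", ", w$j, ")")
    seen <- c(seen, key)
    adjacency[w$i, w$j] <- adjacency[w$j, w$i] <- TRUE
    length_matrix[w$i, w$j] <- length_matrix[w$j, w$i] <- w$length
    width_matrix[w$i, w$j] <- width_matrix[w$j, w$i] <- w$width
  }
  names(cells) <- vapply(cells, function(x) as.character(x$id), character(1))
  names(walls) <- vapply(walls, function(w) paste(w$i, w$j, sep = "-"),
                         character(1))
  structure(list(
    n_cells = n, cells = cells, walls = walls,
    adjacency = adjacency, length_matrix = length_matrix,
    width_matrix = width_matrix, orientation_matrix = orientation_matrix,
    pixel_size = pixel_size, labels = labels), class = "structural_model")
}

#' Build the full structural model from a classified pixel grid
#'
#' Convenience pipeline: [find_regions], then [assign_wall_pixels] and
#' [extract_wall_segments], then [build_structural_model]. Orientation
#' codes are left undetermined; call [orient_all] next.
#'
#' @param grid a [pixel_grid].
#' @param connectivity cell connectivity, 4 (default) or 8.
#' @return a `structural_model`.
#' @export
extract_structural_model <- function(grid, connectivity = 4L) {
  fr <- find_regions(grid, connectivity)
  cells <- lapply(fr$regions, .make_cell_record, pixel_size = grid$pixel_size)
  assignment <- assign_wall_pixels(grid, fr$labels)
  walls <- extract_wall_segments(assignment, grid)
  build_structural_model(cells, walls, grid$pixel_size, labels = fr$labels)
}

#' @export
print.structural_model <- function(x, ...) {
  cat(sprintf("structural_model: %d cells (ids 3..%d), %d wall segments\n",
              x$n_cells, x$n_cells + 2L, length(x$walls)))
  cat(sprintf("  pixel size %.4g um/px; exterior %spresent; excluded %spresent\n",
              x$pixel_size,
              if ("1" %in% names(x$cells)) "" else "not ",
              if ("2" %in% names(x$cells)) "" else "not "))
  nres <- sum(x$orientation_matrix[upper.tri(x$orientation_matrix)] > 0L)
  cat(sprintf("  oriented wall pairs: %d / %d\n", nres, length(x$walls)))
  invisible(x)
}

#' @export
summary.structural_model <- function(object, ...) {
  ct <- cells_table(object)
  cat(sprintf("structural_model with %d cells\n", object$n_cells))
  print(summary(ct[ct$id >= 3L, c("area", "perimeter")]))
  invisible(object)
}

#' @export
plot.structural_model <- function(x, ...) {
  if (is.null(x$labels)) stop("model carries no label raster")
  img <- x$labels
  graphics::image(t(img)[, nrow(img):1], asp = nrow(img) / ncol(img),
                  axes = FALSE, col = grDevices::hcl.colors(max(img) + 1L), ...)
  invisible(x)
}

#' Tabulate per-cell features
#'
#' @param model a `structural_model`.
#' @return data frame with one row per region (including indices 1 and 2
#'   when present): id, area, perimeter, centroid, bounding rectangle,
#'   ellipse axes and angle, and cell type.
#' @export
cells_table <- function(model) {
  rows <- lapply(model$cells, function(cc) {
    data.frame(id = cc$id, area = cc$area, perimeter = cc$perimeter,
               centroid_x = cc$centroid[["x"]], centroid_y = cc$centroid[["y"]],
               bbox_xmin = cc$bounding_rect[["x_min"]],
               bbox_xmax = cc$bounding_rect[["x_max"]],
               bbox_ymin = cc$bounding_rect[["y_min"]],
               bbox_ymax = cc$bounding_rect[["y_max"]],
               ellipse_major = cc$ellipse$major_axis_length,
               ellipse_minor = cc$ellipse$minor_axis_length,
               ellipse_angle_deg = cc$ellipse$angle_deg,
               cell_type = cc$cell_type)
  })
  out <- do.call(rbind, rows)
  out[order(out$id), , drop = FALSE]
}

#' Tabulate per-wall features
#'
#' @param model a `structural_model`.
#' @return data frame with one row per wall pair: i, j, length, width,
#'   centroid, bounding rectangle, ellipse angle and orientation code.
#' @export
walls_table <- function(model) {
  rows <- lapply(model$walls, function(w) {
    data.frame(i = w$i, j = w$j, length = w$length, width = w$width,
               centroid_x = w$centroid[["x"]], centroid_y = w$centroid[["y"]],
               bbox_xmin = w$bounding_rect[["x_min"]],
               bbox_xmax = w$bounding_rect[["x_max"]],
               bbox_ymin = w$bounding_rect[["y_min"]],
               bbox_ymax = w$bounding_rect[["y_max"]],
               ellipse_angle_deg = w$ellipse$angle_deg,
               orientation_code = model$orientation_matrix[w$i, w$j])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$i, out$j), , drop = FALSE]
}

#' Neighbours of a cell
#'
#' @param model a `structural_model`.
#' @param id region index.
#' @return integer vector of adjacent region indices.
#' @export
cell_neighbors <- function(model, id) {
  which(model$adjacency[id, ])
}

# --- serialization ------------------------------------------------------

.write_mtx <- function(m, path) {
  Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                          "generalMatrix"), "TsparseMatrix"),
                  path)
}

.read_mtx <- function(path) {
  as.matrix(Matrix::readMM(path))
}

#' Write a structural model to a directory
#'
#' Writes `cells.csv`, `walls.csv`, the four (N+2) x (N+2) matrices as
#' Matrix Market files (`adjacency.mtx`, `length.mtx`, `width.mtx`,
#' `orientation.mtx`) and, when the model carries a label raster,
#' `labels.tif` (16-bit: 0 = wall pixel, else region id).
#'
#' @param model a `structural_model`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_structural_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cells_table(model), file.path(dir, "cells.csv"),
                   row.names = FALSE)
  utils::write.csv(walls_table(model), file.path(dir, "walls.csv"),
                   row.names = FALSE)
  .write_mtx(model$adjacency * 1, file.path(dir, "adjacency.mtx"))
  .write_mtx(model$length_matrix, file.path(dir, "length.mtx"))
  .write_mtx(model$width_matrix, file.path(dir, "width.mtx"))
  .write_mtx(model$orientation_matrix, file.path(dir, "orientation.mtx"))
  meta <- list(n_cells = model$n_cells, pixel_size = model$pixel_size)
  writeLines(yaml::as.yaml(meta), file.path(dir, "model.yaml"))
  if (!is.null(model$labels))
    write_labels(model$labels, file.path(dir, "labels.tif"))
  invisible(dir)
}

#' Read a structural model written by [write_structural_model]
#'
#' Reconstructs the matrices, feature tables and label raster. Pixel sets
#' of cells are recovered from the label raster; wall pixel sets are not
#' stored and the wall records carry features only.
#'
#' @param dir directory written by [write_structural_model].
#' @return a `structural_model`.
#' @export
read_structural_model <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "model.yaml"))
  ct <- utils::read.csv(file.path(dir, "cells.csv"),
                        colClasses = c(cell_type = "character"))
  wt <- utils::read.csv(file.path(dir, "walls.csv"))
  labels <- NULL
  labf <- file.path(dir, "labels.tif")
  if (file.exists(labf)) labels <- read_labels(labf)
  cells <- lapply(seq_len(nrow(ct)), function(k) {
    row <- ct[k, ]
    reg <- NULL
    if (!is.null(labels)) {
      px <- which(labels == row$id)
      if (length(px))
        reg <- region(cbind(((px - 1L) %% nrow(labels)) + 1L,
                            ((px - 1L) %/% nrow(labels)) + 1L),
                      row$id, dim(labels))
    }
    structure(list(
      id = row$id, region = reg, area = row$area, perimeter = row$perimeter,
      centroid = c(x = row$centroid_x, y = row$centroid_y),
      bounding_rect = c(x_min = row$bbox_xmin, x_max = row$bbox_xmax,
                        y_min = row$bbox_ymin, y_max = row$bbox_ymax),
      ellipse = structure(list(major_axis_length = row$ellipse_major,
                               minor_axis_length = row$ellipse_minor,
                               angle_deg = row$ellipse_angle_deg),
                          class = "ellipse"),
      cell_type = row$cell_type), class = "cell_record")
  })
  names(cells) <- as.character(ct$id)
  walls <- lapply(seq_len(nrow(wt)), function(k) {
    row <- wt[k, ]
    structure(list(
      i = row$i, j = row$j, region = NULL, length = row$length,
      width = row$width,
      centroid = c(x = row$centroid_x, y = row$centroid_y),
      bounding_rect = c(x_min = row$bbox_xmin, x_max = row$bbox_xmax,
                        y_min = row$bbox_ymin, y_max = row$bbox_ymax),
      ellipse = structure(list(major_axis_length = NA_real_,
                               minor_axis_length = NA_real_,
                               angle_deg = row$ellipse_angle_deg),
                          class = "ellipse"),
      orientation = row$orientation_code), class = "wall_record")
  })
  names(walls) <- paste(wt$i, wt$j, sep = "-")
  model <- structure(list(
    n_cells = meta$n_cells, cells = cells, walls = walls,
    adjacency = .read_mtx(file.path(dir, "adjacency.mtx")) > 0,
    length_matrix = .read_mtx(file.path(dir, "length.mtx")),
    width_matrix = .read_mtx(file.path(dir, "width.mtx")),
    orientation_matrix = {
      m <- .read_mtx(file.path(dir, "orientation.mtx"))
      storage.mode(m) <- "integer"
      m
    },
    pixel_size = meta$pixel_size, labels = labels),
    class = "structural_model")
  model
}
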