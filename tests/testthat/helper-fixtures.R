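# Build a pixel_grid from string art: '#' = wall, '.' = interior,
# 'x' = excluded. One string per pixel row.
grid_from_art <- function(art, pixel_size = 1) {
  rows <- strsplit(art, "")
  m <- do.call(rbind, rows)
  cls <- matrix("interior", nrow(m), ncol(m))
  cls[m == "#"] <- "wall"
  cls[m == "x"] <- "excluded"
  pixel_grid(cls, pixel_size = pixel_size)
}

# A hand-built wall record carrying just the geometry the orientation
# rules read (bounding rectangle in y-up coords, ellipse angle).
fake_wall <- function(i, j, bbox, angle_deg) {
  structure(list(i = i, j = j,
                 bounding_rect = c(x_min = bbox[1], x_max = bbox[2],
                                   y_min = bbox[3], y_max = bbox[4]),
                 ellipse = structure(list(major_axis_length = 10,
                                          minor_axis_length = 1,
                                          angle_deg = angle_deg),
                                     class = "ellipse")),
            class = "wall_record")
}

fake_cell <- function(id, x, y, type = "default") {
  structure(list(id = as.integer(id), centroid = c(x = x, y = y),
                 cell_type = type),
            class = "cell_record")
}

# Minimal hand-built structural model for neighbour-resolution tests:
# cells is a list of fake_cell, adjacency a list of pairs, codes a list
# of c(i, j, code) already-resolved entries.
fake_model <- function(cells, adjacency, codes = list()) {
  ids <- vapply(cells, function(x) x$id, integer(1))
  dim_n <- max(ids)
  A <- matrix(FALSE, dim_n, dim_n)
  for (p in adjacency) A[p[1], p[2]] <- A[p[2], p[1]] <- TRUE
  M <- matrix(0L, dim_n, dim_n)
  for (p in codes) {
    M[p[1], p[2]] <- as.integer(p[3])
    M[p[2], p[1]] <- opposite_code(as.integer(p[3]))
  }
  names(cells) <- as.character(ids)
  structure(list(n_cells = sum(ids >= 3L), cells = cells, walls = list(),
                 adjacency = A, orientation_matrix = M,
                 length_matrix = matrix(0, dim_n, dim_n),
                 width_matrix = matrix(0, dim_n, dim_n),
                 pixel_size = 1, labels = NULL),
            class = "structural_model")
}

# region built directly from (row, col) pairs
region_from_pixels <- function(px, dim, id = 0L) {
  region(matrix(as.integer(px), ncol = 2, byrow = TRUE), id, dim)
}

# independent brute-force characteristic ellipse: assemble the moment
# matrix and use eigen(), bypassing the closed-form eigenvalue algebra
brute_force_ellipse <- function(px, H) {
  x <- px[, 2] - 1
  y <- H - px[, 1]
  C <- cov_m <- matrix(0, 2, 2)
  dx <- x - mean(x); dy <- y - mean(y)
  cov_m[1, 1] <- mean(dx^2) + 1 / 12
  cov_m[2, 2] <- mean(dy^2) + 1 / 12
  cov_m[1, 2] <- cov_m[2, 1] <- mean(dx * dy)
  ev <- eigen(cov_m, symmetric = TRUE)
  ang <- atan2(ev$vectors[2, 1], ev$vectors[1, 1]) * 180 / pi
  if (ang <= -90) ang <- ang + 180
  if (ang > 90) ang <- ang - 180
  list(major = 4 * sqrt(ev$values[1]), minor = 4 * sqrt(ev$values[2]),
       angle = ang)
}

# pure-diffusion single-substance spec
diffusion_spec <- function(P = 1, init = 0) {
  model_spec(substances = data.frame(name = "A", mobile = TRUE),
             transport = list(A = list(P = P, k_act = 0)),
             initial = list(A = init))
}

annotate_default <- function(model) {
  ids <- 3:(model$n_cells + 2L)
  annotate_cell_types(model, stats::setNames(rep("default", length(ids)), ids))
}
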