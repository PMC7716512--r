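# Synthetic labeled layouts with exhaustive ground truth. Layouts are
# rasterized from a junction lattice: cells are the quadrilaterals between
# four junction points and walls are straight thick segments joining
# adjacent junctions, so the same code path produces regular and jittered
# tissues and the ground truth (ids, adjacency, orientations, types) is
# known by construction, independently of the extraction pipeline.

# distance-to-segment rasterizer: marks pixels whose center lies closer
# than wall_px / 2 to the segment A-B (in continuous (row, col) coords)
.paint_segment <- function(wall, A, B, wall_px) {
  H <- nrow(wall); W <- ncol(wall)
  half <- wall_px / 2
  r0 <- max(1L, floor(min(A[1], B[1]) - half)); r1 <- min(H, ceiling(max(A[1], B[1]) + half))
  c0 <- max(1L, floor(min(A[2], B[2]) - half)); c1 <- min(W, ceiling(max(A[2], B[2]) + half))
  R <- matrix(r0:r1, r1 - r0 + 1L, c1 - c0 + 1L)
  C <- matrix(c0:c1, r1 - r0 + 1L, c1 - c0 + 1L, byrow = TRUE)
  dr <- B[1] - A[1]; dc <- B[2] - A[2]
  len2 <- dr^2 + dc^2
  t <- if (len2 > 0) pmin(pmax(((R - A[1]) * dr + (C - A[2]) * dc) / len2, 0), 1) else 0
  d2 <- (R - (A[1] + t * dr))^2 + (C - (A[2] + t * dc))^2
  hit <- d2 < half^2
  wall[r0:r1, c0:c1] <- wall[r0:r1, c0:c1] | hit
  wall
}

# point-in-convex-quad test; corners ordered around the quad
.in_quad <- function(R, C, quad) {
  # polygon orientation from the shoelace sum
  sa <- 0
  for (k in 1:4) {
    p <- quad[k, ]; q <- quad[(k %% 4L) + 1L, ]
    sa <- sa + p[1] * q[2] - q[1] * p[2]
  }
  sgn <- sign(sa)
  inside <- rep(TRUE, length(R))
  for (k in 1:4) {
    p <- quad[k, ]; q <- quad[(k %% 4L) + 1L, ]
    cr <- (q[1] - p[1]) * (C - p[2]) - (q[2] - p[2]) * (R - p[1])
    inside <- inside & (sgn * cr >= 0)
  }
  inside
}

.make_lattice_layout <- function(rows, cols, cell_px, wall_px, border_px,
                                 offsets = NULL, pixel_size = 1,
                                 max_px = 4e6) {
  stopifnot(rows >= 1L, cols >= 1L, cell_px >= 3L, wall_px >= 1L,
            border_px >= 0L)
  pitch <- cell_px + wall_px
  H <- rows * pitch + wall_px + 2L * border_px
  W <- cols * pitch + wall_px + 2L * border_px
  if (as.numeric(H) * W > max_px)
    stop("layout image of ", H, " x ", W, " px exceeds the size cap")
  # junction centers, (rows+1) x (cols+1), in continuous (row, col) coords
  jr <- matrix(border_px + (0:rows) * pitch + (wall_px + 1) / 2,
               rows + 1L, cols + 1L)
  jc <- matrix(border_px + (0:cols) * pitch + (wall_px + 1) / 2,
               rows + 1L, cols + 1L, byrow = TRUE)
  if (!is.null(offsets)) {
    jr <- jr + offsets$dr
    jc <- jc + offsets$dc
  }
  wall <- matrix(FALSE, H, W)
  for (b in 1:(rows + 1L)) for (k in 1:cols)
    wall <- .paint_segment(wall, c(jr[b, k], jc[b, k]),
                           c(jr[b, k + 1L], jc[b, k + 1L]), wall_px)
  for (b in 1:rows) for (k in 1:(cols + 1L))
    wall <- .paint_segment(wall, c(jr[b, k], jc[b, k]),
                           c(jr[b + 1L, k], jc[b + 1L, k]), wall_px)
  cls <- matrix(.INTERIOR, H, W)
  cls[wall] <- .WALL
  grid <- pixel_grid(cls, pixel_size = pixel_size)

  # ground-truth cell masks from the quadrilaterals
  gt_labels <- matrix(0L, H, W)
  first_px <- matrix(NA_real_, rows, cols)
  for (r in 1:rows) for (c in 1:cols) {
    quad <- rbind(c(jr[r, c], jc[r, c]), c(jr[r, c + 1L], jc[r, c + 1L]),
                  c(jr[r + 1L, c + 1L], jc[r + 1L, c + 1L]),
                  c(jr[r + 1L, c], jc[r + 1L, c]))
    r0 <- max(1L, floor(min(quad[, 1]))); r1 <- min(H, ceiling(max(quad[, 1])))
    c0 <- max(1L, floor(min(quad[, 2]))); c1 <- min(W, ceiling(max(quad[, 2])))
    R <- rep(r0:r1, times = c1 - c0 + 1L)
    C <- rep(c0:c1, each = r1 - r0 + 1L)
    ok <- .in_quad(R, C, quad) & !wall[cbind(R, C)]
    if (!any(ok)) stop("degenerate cell (", r, ", ", c, ") in layout")
    sub <- cbind(R[ok], C[ok])
    if (any(gt_labels[sub] != 0L)) stop("overlapping cells in layout")
    cell_code <- (r - 1L) * cols + c
    gt_labels[sub] <- cell_code
    first_px[r, c] <- min((sub[, 1L] - 1L) * W + sub[, 2L])
    mask <- matrix(FALSE, H, W); mask[sub] <- TRUE
    if (max(.label_components(mask, 4L)) != 1L)
      stop("cell (", r, ", ", c, ") not 4-connected after jitter")
  }
  # id assignment: raster-scan order of each cell's first pixel
  ord <- order(as.vector(t(first_px)))      # row-major over (r, c)
  id_grid <- matrix(0L, rows, cols)
  rc <- cbind(rep(1:rows, each = cols), rep(1:cols, times = rows))
  for (k in seq_along(ord))
    id_grid[rc[ord[k], 1L], rc[ord[k], 2L]] <- k + 2L

  # ground-truth neighbour pairs with orientation codes (side of the
  # lower-indexed cell): y-up frame, so the cell in the next grid row is
  # the "bottom" neighbour
  pairs <- NULL
  add_pair <- function(a, b, code_ab) {
    # store with i < j; flip the code when the stored order is (b, a)
    if (a < b) c(a, b, code_ab) else c(b, a, opposite_code(code_ab))
  }
  for (r in 1:rows) for (c in 1:cols) {
    if (c < cols)
      pairs <- rbind(pairs, add_pair(id_grid[r, c], id_grid[r, c + 1L], 3L))
    if (r < rows)
      pairs <- rbind(pairs, add_pair(id_grid[r, c], id_grid[r + 1L, c], 2L))
  }
  if (is.null(pairs)) pairs <- matrix(integer(0), ncol = 3L)
  pairs <- as.data.frame(pairs)
  names(pairs) <- c("i", "j", "code")
  pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
  rownames(pairs) <- NULL
  exterior <- integer(0)
  if (border_px >= 1L)
    exterior <- sort(unique(c(id_grid[1L, ], id_grid[rows, ],
                              id_grid[, 1L], id_grid[, cols])))
  truth <- structure(list(
    n_cells = rows * cols, id_grid = id_grid, pairs = pairs,
    exterior_cells = exterior, types = NULL,
    params = list(rows = rows, cols = cols, cell_px = cell_px,
                  wall_px = wall_px, border_px = border_px)),
    class = "layout_truth")
  list(grid = grid, truth = truth)
}

#' Generate a rectangular grid layout with ground truth
#'
#' A tissue of `rows` x `cols` rectangular cells of `cell_px` pixels,
#' separated by walls `wall_px` thick and surrounded by a wall and then
#' `border_px` of external environment. The returned ground truth lists
#' the cell count, the id of each grid position (ids 3..N+2 in raster-scan
#' order), every neighbour pair with its true orientation code, and the
#' cells adjacent to the exterior.
#'
#' @param rows,cols grid dimensions (>= 1).
#' @param cell_px cell side length in pixels (>= 3).
#' @param wall_px wall thickness in pixels (>= 1).
#' @param border_px exterior margin in pixels.
#' @param pixel_size micrometres per pixel.
#' @return list with `grid` (a [pixel_grid]) and `truth`.
#' @export
make_grid_layout <- function(rows, cols, cell_px = 20L, wall_px = 2L,
                             border_px = 3L, pixel_size = 1) {
  .make_lattice_layout(rows, cols, cell_px, wall_px, border_px,
                       pixel_size = pixel_size)
}

#' Generate a jittered grid layout with ground truth
#'
#' As [make_grid_layout], but every internal wall junction is displaced
#' by a seeded uniform offset of up to `jitter_frac * cell_px` in each
#' direction before the straight wall segments are rasterized. The
#' topology — and hence the ground-truth adjacency and orientations — is
#' preserved; if a displacement merges or disconnects a cell the
#' generator retries with a derived seed and errors after five attempts.
#' The same parameters and seed always produce the identical image.
#'
#' @inheritParams make_grid_layout
#' @param jitter_frac junction displacement bound as a fraction of
#'   `cell_px`, in \[0, 0.3\].
#' @param seed integer seed for the displacement draws.
#' @return list with `grid` and `truth`.
#' @export
make_jittered_layout <- function(rows, cols, cell_px = 20L, wall_px = 2L,
                                 jitter_frac = 0.15, seed = 1L,
                                 border_px = 3L, pixel_size = 1) {
  stopifnot(jitter_frac >= 0, jitter_frac <= 0.3)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  amp <- jitter_frac * cell_px
  for (attempt in 0:4) {
    set.seed(seed + attempt * 100003L)
    dr <- matrix(0, rows + 1L, cols + 1L)
    dc <- matrix(0, rows + 1L, cols + 1L)
    if (rows > 1L && cols > 1L && amp > 0) {
      ir <- 2:rows; ic <- 2:cols
      dr[ir, ic] <- stats::runif(length(ir) * length(ic), -amp, amp)
      dc[ir, ic] <- stats::runif(length(ir) * length(ic), -amp, amp)
    }
    out <- try(.make_lattice_layout(rows, cols, cell_px, wall_px, border_px,
                                    offsets = list(dr = dr, dc = dc),
                                    pixel_size = pixel_size), silent = TRUE)
    if (!inherits(out, "try-error")) {
      out$truth$params$jitter_frac <- jitter_frac
      out$truth$params$seed <- seed
      return(out)
    }
  }
  stop("jitter repeatedly broke the layout topology: ",
       attr(out, "condition")$message)
}

#' Generate a root-tip-like layout with cell types
#'
#' A grid layout whose columns carry tissue-type labels (for example
#' epidermis | cortex | vascular | cortex | epidermis, mirror-symmetric)
#' and whose bottom `cap_rows` rows form a root-cap ("columella") band, so
#' that polarity-dependent transport models can address files and cap
#' separately. The tissue is a full rectangle of
#' `(rows + cap_rows) x length(columns_spec)` cells.
#'
#' @param columns_spec character vector of type labels, one per column.
#' @param rows number of non-cap cell rows.
#' @param cap_rows number of bottom rows labeled `"columella"` (>= 1).
#' @inheritParams make_grid_layout
#' @return list with `grid` and `truth`; `truth$types` is a named vector
#'   mapping cell id to type label.
#' @export
make_roottip_layout <- function(columns_spec = c("epidermis", "cortex",
                                                 "vascular", "cortex",
                                                 "epidermis"),
                                rows = 8L, cap_rows = 2L, cell_px = 20L,
                                wall_px = 2L, border_px = 3L,
                                pixel_size = 1) {
  stopifnot(cap_rows >= 1L, rows >= 1L)
  cols <- length(columns_spec)
  out <- make_grid_layout(rows + cap_rows, cols, cell_px, wall_px,
                          border_px, pixel_size)
  id_grid <- out$truth$id_grid
  types <- character(out$truth$n_cells)
  names(types) <- as.character(3:(out$truth$n_cells + 2L))
  for (r in seq_len(rows + cap_rows)) for (c in seq_len(cols)) {
    lab <- if (r > rows) "columella" else columns_spec[c]
    types[as.character(id_grid[r, c])] <- lab
  }
  out$truth$types <- types
  out$truth$params$columns_spec <- columns_spec
  out$truth$params$cap_rows <- cap_rows
  out
}

#' Demonstration polar-transport model specification
#'
#' A minimal reflected-flow auxin model on a root-tip layout: every cell
#' synthesizes auxin at a constant rate and degrades it linearly; auxin
#' diffuses passively between neighbours and is pumped by efflux carriers
#' whose wall placement depends on cell type — vascular cells pump toward
#' their bottom walls (down the central files), columella cells toward
#' their left and right walls (sideways at the cap), and epidermis and
#' cortex cells toward their top walls (back up the outer files). With
#' closed boundaries and uniform initial data this wiring self-organizes
#' an interior concentration maximum at the vascular-tip/cap junction.
#'
#' Carrier strengths differ by type, mirroring the polarity of the known
#' efflux-carrier families: strong rootward pumping in the stele, weaker
#' shootward pumping in the outer files, weak redistribution at the cap.
#'
#' @param truth ground truth of a [make_roottip_layout] (types must
#'   include epidermis, cortex, vascular and columella).
#' @param synthesis,decay,P,k_act model parameters (model units).
#' @param carriers named numeric vector of carrier concentrations per
#'   cell type.
#' @return a [model_spec] with one mobile substance `"auxin"`.
#' @export
demo_polar_transport_spec <- function(truth, synthesis = 0.1, decay = 0.01,
                                      P = 1.0, k_act = 0.5,
                                      carriers = c(vascular = 2.0,
                                                   epidermis = 0.2,
                                                   cortex = 0.2,
                                                   columella = 0.3)) {
  need <- c("epidermis", "cortex", "vascular", "columella")
  have <- unique(truth$types)
  if (is.null(truth$types) || !all(need %in% have))
    stop("root-tip truth must carry cell types: ",
         paste(setdiff(need, have), collapse = ", "))
  model_spec(
    substances = data.frame(name = "auxin", mobile = TRUE),
    cell_types = need,
    equations = list(default = list(auxin = list(
      list(kind = "constant", c0 = synthesis),
      list(kind = "linear_decay", k = decay)))),
    transport = list(auxin = list(
      P = P, k_act = k_act,
      carriers = list(
        vascular = list(bottom = carriers[["vascular"]]),
        epidermis = list(top = carriers[["epidermis"]]),
        cortex = list(top = carriers[["cortex"]]),
        columella = list(left = carriers[["columella"]],
                         right = carriers[["columella"]])))),
    boundary = list("1" = "closed", "2" = "closed"),
    initial = list(auxin = 1.0))
}
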