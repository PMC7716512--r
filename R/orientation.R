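# Wall orientation codes: the side of cell i on which the wall (i, j)
# lies, equivalently the direction from cell i toward cell j.
#   0 undetermined, 1 top, 2 bottom, 3 right, 4 left.

.SIDE_NAMES <- c("top", "bottom", "right", "left")

#' Opposite of an orientation code
#'
#' top <-> bottom, right <-> left; 0 (undetermined) maps to itself. The
#' orientation matrix stores `code(j, i) = opposite_code(code(i, j))`.
#'
#' @param code integer vector of codes in 0..4.
#' @return integer vector of opposite codes.
#' @export
opposite_code <- function(code) {
  c(0L, 2L, 1L, 4L, 3L)[code + 1L]
}

.is_vertical <- function(code) code %in% c(3L, 4L)    # wall is vertical
.is_horizontal <- function(code) code %in% c(1L, 2L)  # wall is horizontal

#' Orientation rule: wall extent between centroids
#'
#' If both extremes of the wall's y-extent lie strictly between the two
#' cell centroids' y-coordinates (and the x-extent does not do the same in
#' x), the wall separates the cells vertically and is "bottom" or "top"
#' according to which cell is lower; symmetrically for the x-extent. When
#' both or neither extent condition holds, the rule does not decide.
#'
#' @param wall wall record joining cells i and j.
#' @param cell_i,cell_j cell records for i and j.
#' @return orientation code for direction (i, j), 0 when undecided.
#' @export
rule_extent <- function(wall, cell_i, cell_j) {
  bb <- wall$bounding_rect
  yi <- cell_i$centroid[["y"]]; yj <- cell_j$centroid[["y"]]
  xi <- cell_i$centroid[["x"]]; xj <- cell_j$centroid[["x"]]
  V <- bb[["y_min"]] > min(yi, yj) && bb[["y_max"]] < max(yi, yj)
  H <- bb[["x_min"]] > min(xi, xj) && bb[["x_max"]] < max(xi, xj)
  if (V && !H) return(if (yj < yi) 2L else 1L)
  if (H && !V) return(if (xj > xi) 3L else 4L)
  0L
}

#' Orientation rule: characteristic-ellipse axis angle
#'
#' A wall whose ellipse major axis makes more than 45 degrees with the
#' x-axis is vertical, so the wall is "right" or "left" according to the
#' centroids' x-order; less than 45 degrees means a horizontal wall,
#' decided by the centroids' y-order. Exactly 45 degrees does not decide.
#'
#' @inheritParams rule_extent
#' @return orientation code for direction (i, j), 0 when undecided.
#' @export
rule_axis <- function(wall, cell_i, cell_j) {
  theta <- abs(wall$ellipse$angle_deg)
  yi <- cell_i$centroid[["y"]]; yj <- cell_j$centroid[["y"]]
  xi <- cell_i$centroid[["x"]]; xj <- cell_j$centroid[["x"]]
  if (theta > 45) {
    if (xj > xi) return(3L)
    if (xj < xi) return(4L)
  } else if (theta < 45) {
    if (yj > yi) return(1L)
    if (yj < yi) return(2L)
  }
  0L
}

#' Orientation rule: bounding rectangle separation
#'
#' If cell i's centroid lies entirely above the wall's bounding rectangle
#' and cell j's below it, the wall is on the "bottom" side of i; the other
#' three sides are analogous. When none or several configurations hold the
#' rule does not decide.
#'
#' @inheritParams rule_extent
#' @return orientation code for direction (i, j), 0 when undecided.
#' @export
rule_rectangle <- function(wall, cell_i, cell_j) {
  bb <- wall$bounding_rect
  yi <- cell_i$centroid[["y"]]; yj <- cell_j$centroid[["y"]]
  xi <- cell_i$centroid[["x"]]; xj <- cell_j$centroid[["x"]]
  hits <- c(
    bottom = yi > bb[["y_max"]] && yj < bb[["y_min"]],
    top    = yi < bb[["y_min"]] && yj > bb[["y_max"]],
    right  = xi < bb[["x_min"]] && xj > bb[["x_max"]],
    left   = xi > bb[["x_max"]] && xj < bb[["x_min"]])
  if (sum(hits) != 1L) return(0L)
  c(bottom = 2L, top = 1L, right = 3L, left = 4L)[[names(which(hits))]]
}

#' Direct orientation of a wall from the three geometric rules
#'
#' Collects the verdicts of [rule_extent], [rule_axis] and
#' [rule_rectangle]; the wall is oriented when at least one rule decides
#' and all deciding rules agree.
#'
#' @inheritParams rule_extent
#' @return orientation code for direction (i, j), 0 when ambiguous.
#' @export
direct_orientation <- function(wall, cell_i, cell_j) {
  v <- c(rule_extent(wall, cell_i, cell_j),
         rule_axis(wall, cell_i, cell_j),
         rule_rectangle(wall, cell_i, cell_j))
  nz <- v[v != 0L]
  if (length(nz) && all(nz == nz[1L])) nz[1L] else 0L
}

# verdicts implied for the ordered pair (i, j) by one common neighbour q,
# given the current orientation matrix M and centroids
.neighbor_verdicts <- function(M, i, j, q, xc, yc) {
  out <- integer(0)
  ciq <- M[i, q]; cjq <- M[j, q]
  if (ciq != 0L && cjq != 0L) {
    if (.is_vertical(ciq) && .is_vertical(cjq)) {
      if (yc[j] > yc[i]) out <- c(out, 1L)
      else if (yc[j] < yc[i]) out <- c(out, 2L)
    } else if (.is_horizontal(ciq) && .is_horizontal(cjq)) {
      if (xc[j] > xc[i]) out <- c(out, 3L)
      else if (xc[j] < xc[i]) out <- c(out, 4L)
    }
  }
  cqj <- M[q, j]
  if (ciq != 0L && cqj != 0L && .is_vertical(ciq) && .is_horizontal(cqj)) {
    if (yc[i] > yc[j] && cqj == 2L) out <- c(out, 2L)
    if (yc[i] < yc[j] && cqj == 1L) out <- c(out, 1L)
    if (xc[i] > xc[j] && ciq == 4L) out <- c(out, 4L)
    if (xc[i] < xc[j] && ciq == 3L) out <- c(out, 3L)
  }
  out
}

#' Resolve undetermined walls through common neighbours
#'
#' Iterates to a fixpoint over the still-undetermined wall pairs, in
#' lexicographic (i, j) order within each sweep. For a pair (i, j) and a
#' common neighbour q with both shared walls already oriented: if walls
#' (i, q) and (j, q) are both vertical (right/left), the wall (i, j) is
#' perpendicular to them and its top/bottom direction follows the
#' centroids; both horizontal is symmetric. If (i, q) is vertical and
#' (q, j) horizontal, the centroid order of i and j combined with the
#' codes of the known walls can force the code directly. Conflicting
#' neighbour verdicts leave the pair unresolved (flagged ambiguous) for
#' manual correction; already-resolved codes are never changed.
#'
#' @param model a `structural_model` whose orientation matrix holds the
#'   direct verdicts.
#' @param unresolved two-column matrix of unresolved pairs (i < j).
#' @return list with the updated `model`, the remaining `unresolved`
#'   pairs, and `ambiguous` (pairs with conflicting neighbour evidence).
#' @export
resolve_via_neighbors <- function(model, unresolved) {
  M <- model$orientation_matrix
  dim_n <- nrow(M)
  xc <- rep(NA_real_, dim_n); yc <- rep(NA_real_, dim_n)
  for (cc in model$cells) {
    xc[cc$id] <- cc$centroid[["x"]]; yc[cc$id] <- cc$centroid[["y"]]
  }
  if (is.null(dim(unresolved)))
    unresolved <- matrix(unresolved, ncol = 2L)
  pend <- unresolved[order(unresolved[, 1L], unresolved[, 2L]), , drop = FALSE]
  ambiguous <- matrix(integer(0), ncol = 2L)
  repeat {
    changed <- FALSE
    keep <- rep(TRUE, nrow(pend))
    for (k in seq_len(nrow(pend))) {
      i <- pend[k, 1L]; j <- pend[k, 2L]
      qs <- which(model$adjacency[i, ] & model$adjacency[j, ])
      qs <- setdiff(qs, c(i, j))
      verdicts <- integer(0)
      for (q in qs) {
        verdicts <- c(verdicts, .neighbor_verdicts(M, i, j, q, xc, yc))
        verdicts <- c(verdicts,
                      opposite_code(.neighbor_verdicts(M, j, i, q, xc, yc)))
      }
      verdicts <- unique(verdicts[verdicts != 0L])
      if (length(verdicts) == 1L) {
        M[i, j] <- verdicts
        M[j, i] <- opposite_code(verdicts)
        keep[k] <- FALSE
        changed <- TRUE
      } else if (length(verdicts) > 1L) {
        ambiguous <- rbind(ambiguous, c(i, j))
        keep[k] <- FALSE
      }
    }
    pend <- pend[keep, , drop = FALSE]
    if (!changed || nrow(pend) == 0L) break
  }
  model$orientation_matrix <- M
  remaining <- rbind(pend, ambiguous)
  remaining <- remaining[order(remaining[, 1L], remaining[, 2L]), , drop = FALSE]
  list(model = model, unresolved = remaining, ambiguous = ambiguous)
}

#' Apply a manual orientation correction table
#'
#' @param model a `structural_model`.
#' @param corrections data frame with columns `i`, `j`, `code` (1-4). Each
#'   pair must be adjacent in the model; the matrix receives the code at
#'   (i, j) and its opposite at (j, i).
#' @return the corrected model.
#' @export
apply_corrections <- function(model, corrections) {
  if (is.null(corrections) || nrow(corrections) == 0L) return(model)
  stopifnot(all(c("i", "j", "code") %in% names(corrections)))
  if (anyDuplicated(corrections[, c("i", "j")]))
    stop("duplicate correction pairs")
  if (!all(corrections$code %in% 1:4))
    stop("correction codes must be in 1..4")
  bad <- !model$adjacency[cbind(corrections$i, corrections$j)]
  if (any(bad))
    stop("corrections reference non-adjacent pairs: ",
         paste(sprintf("(%d, %d)", corrections$i[bad], corrections$j[bad]),
               collapse = ", "))
  for (k in seq_len(nrow(corrections))) {
    i <- corrections$i[k]; j <- corrections$j[k]
    code <- as.integer(corrections$code[k])
    model$orientation_matrix[i, j] <- code
    model$orientation_matrix[j, i] <- opposite_code(code)
  }
  model
}

#' Orient every wall of a structural model
#'
#' Runs [direct_orientation] on every wall pair, then
#' [resolve_via_neighbors] to a fixpoint, then [apply_corrections]. The
#' resulting orientation matrix is antisymmetric under the code/opposite
#' pairing on all resolved pairs.
#'
#' @param model a `structural_model`.
#' @param corrections optional correction data frame (see
#'   [apply_corrections]).
#' @param strict if `TRUE`, error when any pair remains unresolved.
#' @return the model, with attribute `"orientation_report"` (a list with
#'   `unresolved` and `ambiguous` pair matrices).
#' @export
orient_all <- function(model, corrections = NULL, strict = FALSE) {
  M <- model$orientation_matrix
  unresolved <- matrix(integer(0), ncol = 2L)
  keys <- names(model$walls)
  keys <- keys[order(vapply(model$walls, `[[`, 0, "i")[keys],
                     vapply(model$walls, `[[`, 0, "j")[keys])]
  for (k in keys) {
    w <- model$walls[[k]]
    code <- direct_orientation(w, model$cells[[as.character(w$i)]],
                               model$cells[[as.character(w$j)]])
    if (code != 0L) {
      M[w$i, w$j] <- code
      M[w$j, w$i] <- opposite_code(code)
    } else {
      unresolved <- rbind(unresolved, c(w$i, w$j))
    }
  }
  model$orientation_matrix <- M
  res <- resolve_via_neighbors(model, unresolved)
  model <- res$model
  model <- apply_corrections(model, corrections)
  if (!is.null(corrections) && nrow(res$unresolved)) {
    fixed <- paste(corrections$i, corrections$j) |>
      c(paste(corrections$j, corrections$i))
    keep <- !(paste(res$unresolved[, 1L], res$unresolved[, 2L]) %in% fixed)
    res$unresolved <- res$unresolved[keep, , drop = FALSE]
  }
  for (k in names(model$walls)) {
    w <- model$walls[[k]]
    model$walls[[k]]$orientation <- model$orientation_matrix[w$i, w$j]
  }
  if (strict && nrow(res$unresolved))
    stop("unresolved wall orientations: ",
         paste(sprintf("(%d, %d)", res$unresolved[, 1L],
                       res$unresolved[, 2L]), collapse = ", "))
  attr(model, "orientation_report") <-
    list(unresolved = res$unresolved, ambiguous = res$ambiguous)
  model
}
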