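test_that("opposite codes pair top/bottom and right/left", {
  expect_equal(opposite_code(0:4), c(0L, 2L, 1L, 4L, 3L))
  expect_equal(opposite_code(opposite_code(0:4)), 0:4)
})

test_that("extent rule decides only when one extent lies between centroids", {
  ci <- fake_cell(3, 5, 10); cj <- fake_cell(4, 5, 0)  # j below i
  # horizontal wall strictly between the centroids in y
  w <- fake_wall(3, 4, c(0, 10, 4, 5), 0)
  expect_equal(rule_extent(w, ci, cj), 2L)
  expect_equal(rule_extent(w, cj, ci), 1L)
  # wall y-extent exceeding both centroids: no decision
  w2 <- fake_wall(3, 4, c(0, 10, -2, 12), 0)
  expect_equal(rule_extent(w2, ci, cj), 0L)
  # both extents between centroids (diagonally offset cells): no decision
  ck <- fake_cell(5, 0, 10); cl <- fake_cell(6, 10, 0)
  w3 <- fake_wall(5, 6, c(4, 6, 4, 6), 45)
  expect_equal(rule_extent(w3, ck, cl), 0L)
})

test_that("axis rule uses the 45-degree threshold and centroid order", {
  ci <- fake_cell(3, 0, 0)
  # vertical wall, j to the right -> right
  expect_equal(rule_axis(fake_wall(3, 4, c(4, 5, -5, 5), 90),
                         ci, fake_cell(4, 10, 0)), 3L)
  expect_equal(rule_axis(fake_wall(3, 4, c(4, 5, -5, 5), 90),
                         ci, fake_cell(4, -10, 0)), 4L)
  # horizontal wall, j above -> top
  expect_equal(rule_axis(fake_wall(3, 4, c(-5, 5, 4, 5), 0),
                         ci, fake_cell(4, 0, 10)), 1L)
  expect_equal(rule_axis(fake_wall(3, 4, c(-5, 5, 4, 5), 10),
                         ci, fake_cell(4, 0, -10)), 2L)
  # exactly 45 degrees: excluded by the strict inequalities
  expect_equal(rule_axis(fake_wall(3, 4, c(0, 5, 0, 5), 45),
                         ci, fake_cell(4, 10, 0)), 0L)
  # aligned centroids: no decision
  expect_equal(rule_axis(fake_wall(3, 4, c(4, 5, -5, 5), 90),
                         ci, fake_cell(4, 0, 7)), 0L)
})

test_that("rectangle rule requires full separation on one side each", {
  w <- fake_wall(3, 4, c(0, 10, 4, 6), 0)
  expect_equal(rule_rectangle(w, fake_cell(3, 5, 10), fake_cell(4, 5, 0)), 2L)
  expect_equal(rule_rectangle(w, fake_cell(3, 5, 0), fake_cell(4, 5, 10)), 1L)
  wv <- fake_wall(3, 4, c(4, 6, 0, 10), 90)
  expect_equal(rule_rectangle(wv, fake_cell(3, 0, 5), fake_cell(4, 10, 5)), 3L)
  expect_equal(rule_rectangle(wv, fake_cell(3, 10, 5), fake_cell(4, 0, 5)), 4L)
  # both centroids on the same side: no decision
  expect_equal(rule_rectangle(w, fake_cell(3, 5, 10), fake_cell(4, 5, 8)), 0L)
  # rectangle containing both centroids (L-shaped wall): no decision
  wL <- fake_wall(3, 4, c(0, 10, 0, 10), 45)
  expect_equal(rule_rectangle(wL, fake_cell(3, 3, 3), fake_cell(4, 7, 7)), 0L)
})

test_that("direct orientation requires agreement of the firing rules", {
  # all three rules fire and agree (vertical wall between side-by-side
  # cells, as in a grid)
  ci <- fake_cell(3, 2, 5); cj <- fake_cell(4, 8, 5)
  w <- fake_wall(3, 4, c(4.4, 5.6, 0, 10), 90)
  expect_equal(rule_extent(w, ci, cj), 3L)
  expect_equal(rule_axis(w, ci, cj), 3L)
  expect_equal(rule_rectangle(w, ci, cj), 3L)
  expect_equal(direct_orientation(w, ci, cj), 3L)

  # axis rule silent at exactly 45 degrees, others agree: still decided
  w45 <- fake_wall(3, 4, c(4.4, 5.6, 0, 10), 45)
  expect_equal(rule_axis(w45, ci, cj), 0L)
  expect_equal(direct_orientation(w45, ci, cj), 3L)

  # disagreement: extent and rectangle say right, axis says top
  ci2 <- fake_cell(3, 2, 4); cj2 <- fake_cell(4, 8, 6)
  wd <- fake_wall(3, 4, c(4.4, 5.6, -10, 10), 0)
  expect_equal(rule_extent(wd, ci2, cj2), 3L)
  expect_equal(rule_axis(wd, ci2, cj2), 1L)
  expect_equal(direct_orientation(wd, ci2, cj2), 0L)
})

test_that("common neighbours resolve perpendicular and mixed configurations", {
  # i over j, common neighbour q to the right, both walls to q vertical
  m <- fake_model(
    list(fake_cell(3, 0, 10), fake_cell(4, 0, 0), fake_cell(5, 10, 5)),
    adjacency = list(c(3, 4), c(3, 5), c(4, 5)),
    codes = list(c(3, 5, 3), c(4, 5, 3)))
  res <- resolve_via_neighbors(m, cbind(3L, 4L))
  expect_equal(res$model$orientation_matrix[3, 4], 2L)  # j below i
  expect_equal(res$model$orientation_matrix[4, 3], 1L)
  expect_equal(nrow(res$unresolved), 0L)

  # both walls to q horizontal: the unresolved wall becomes vertical
  m2 <- fake_model(
    list(fake_cell(3, 0, 0), fake_cell(4, 10, 0), fake_cell(5, 5, 10)),
    adjacency = list(c(3, 4), c(3, 5), c(4, 5)),
    codes = list(c(3, 5, 1), c(4, 5, 1)))
  res2 <- resolve_via_neighbors(m2, cbind(3L, 4L))
  expect_equal(res2$model$orientation_matrix[3, 4], 3L)  # j right of i

  # mixed: (i, q) vertical, (q, j) horizontal with code bottom, i above j
  m3 <- fake_model(
    list(fake_cell(3, 10, 10), fake_cell(4, 0, 0), fake_cell(5, 20, 10)),
    adjacency = list(c(3, 4), c(3, 5), c(4, 5)),
    codes = list(c(3, 5, 3), c(5, 4, 2)))
  res3 <- resolve_via_neighbors(m3, cbind(3L, 4L))
  expect_equal(res3$model$orientation_matrix[3, 4], 2L)
})

test_that("conflicting neighbour verdicts leave the pair unresolved", {
  # q1 (perpendicular configuration) implies bottom; q2 (mixed
  # configuration, x-clause) implies right
  m <- fake_model(
    list(fake_cell(3, 0, 10), fake_cell(4, 10, 0),
         fake_cell(5, 10, 5), fake_cell(6, 0, 20)),
    adjacency = list(c(3, 4), c(3, 5), c(4, 5), c(3, 6), c(4, 6)),
    codes = list(c(3, 5, 3), c(4, 5, 3), c(3, 6, 3), c(6, 4, 1)))
  res <- resolve_via_neighbors(m, cbind(3L, 4L))
  expect_equal(res$model$orientation_matrix[3, 4], 0L)
  expect_equal(nrow(res$unresolved), 1L)
  expect_gte(nrow(res$ambiguous), 1L)
})

test_that("neighbour resolution never changes an already-resolved code", {
  g <- make_grid_layout(3, 3, cell_px = 8, wall_px = 2)
  m <- extract_structural_model(g$grid)
  # direct pass only
  direct <- m
  for (k in names(direct$walls)) {
    w <- direct$walls[[k]]
    code <- direct_orientation(w, direct$cells[[as.character(w$i)]],
                               direct$cells[[as.character(w$j)]])
    direct$orientation_matrix[w$i, w$j] <- code
    direct$orientation_matrix[w$j, w$i] <- opposite_code(code)
  }
  full <- orient_all(m)
  fixed <- direct$orientation_matrix != 0L
  expect_identical(full$orientation_matrix[fixed],
                   direct$orientation_matrix[fixed])
})

test_that("manual corrections are applied antisymmetrically and validated", {
  g <- make_grid_layout(2, 3, cell_px = 6, wall_px = 2)
  m <- extract_structural_model(g$grid)
  m2 <- apply_corrections(m, data.frame(i = 3, j = 4, code = 1))
  expect_equal(m2$orientation_matrix[3, 4], 1L)
  expect_equal(m2$orientation_matrix[4, 3], 2L)
  # non-adjacent pair (3 and 8 are diagonal in the 2x3 grid)
  expect_error(apply_corrections(m, data.frame(i = 3, j = 8, code = 1)),
               "non-adjacent")
  # empty table is the identity
  m3 <- apply_corrections(m, data.frame(i = integer(), j = integer(),
                                        code = integer()))
  expect_identical(m3$orientation_matrix, m$orientation_matrix)
})

test_that("grids orient completely and match the generator ground truth", {
  for (dims in list(c(2, 2), c(3, 5), c(4, 4))) {
    g <- make_grid_layout(dims[1], dims[2], cell_px = 8, wall_px = 2)
    m <- orient_all(extract_structural_model(g$grid))
    tr <- g$truth$pairs
    expect_identical(unname(m$orientation_matrix[cbind(tr$i, tr$j)]),
                     as.integer(tr$code))
    # antisymmetry everywhere
    M <- m$orientation_matrix
    expect_identical(t(M)[M != 0L], opposite_code(M[M != 0L]))
    # report contains no internal pair
    rep <- attr(m, "orientation_report")
    if (nrow(rep$unresolved)) expect_true(all(rep$unresolved[, 1] < 3))
  }
})

test_that("orientation is deterministic and strict mode names leftovers", {
  g <- make_grid_layout(2, 2, cell_px = 8, wall_px = 2)
  m1 <- orient_all(extract_structural_model(g$grid))
  m2 <- orient_all(extract_structural_model(g$grid))
  expect_identical(m1$orientation_matrix, m2$orientation_matrix)
  # the corner exterior walls of a 2x2 grid are genuinely ambiguous
  rep <- attr(m1, "orientation_report")
  expect_gt(nrow(rep$unresolved), 0L)
  expect_error(orient_all(extract_structural_model(g$grid), strict = TRUE),
               "unresolved")
})

test_that("jittered layouts never get a wrong direct orientation", {
  for (s in c(7L, 11L)) {
    g <- make_jittered_layout(4, 4, cell_px = 12, wall_px = 2,
                              jitter_frac = 0.2, seed = s)
    m <- extract_structural_model(g$grid)
    tr <- g$truth$pairs
    for (k in seq_len(nrow(tr))) {
      w <- m$walls[[paste(tr$i[k], tr$j[k], sep = "-")]]
      expect_false(is.null(w))
      code <- direct_orientation(w, m$cells[[as.character(tr$i[k])]],
                                 m$cells[[as.character(tr$j[k])]])
      if (code != 0L) expect_equal(code, tr$code[k])
    }
  }
})
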