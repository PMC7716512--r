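test_that("cell-type annotation accepts maps, rules and functions", {
  g <- make_grid_layout(2, 2, cell_px = 6, wall_px = 2)
  m <- extract_structural_model(g$grid)
  m1 <- annotate_cell_types(m, c("3" = "vascular", "4" = "epidermis",
                                 "5" = "vascular", "6" = "epidermis"))
  expect_equal(m1$cells[["4"]]$cell_type, "epidermis")
  # rule over centroid coordinates: left column vs right column
  mid <- mean(vapply(3:6, function(i) m$cells[[as.character(i)]]$centroid[["x"]], 0))
  m2 <- annotate_cell_types(m, function(x, y)
    if (x < mid) "epidermis" else "vascular")
  expect_equal(m2$cells[["3"]]$cell_type, "epidermis")
  expect_equal(m2$cells[["4"]]$cell_type, "vascular")
  # YAML-style where rules
  m3 <- annotate_cell_types(m, list(
    epidermis = list(where = sprintf("x < %f", mid)),
    vascular = list(where = "TRUE")))
  expect_equal(m3$cells[["5"]]$cell_type, "epidermis")
  expect_equal(m3$cells[["6"]]$cell_type, "vascular")
  # missing coverage names the ids
  expect_error(annotate_cell_types(m, c("3" = "a", "4" = "a", "6" = "a")),
               "5")
})

test_that("unit rescaling follows the length and area scaling laws", {
  g <- make_grid_layout(2, 2, cell_px = 6, wall_px = 2)
  m <- extract_structural_model(g$grid)
  m1 <- rescale_units(m, 1)
  expect_equal(m1$length_matrix, m$length_matrix)
  expect_equal(m1$cells[["3"]]$area, m$cells[["3"]]$area)
  m5 <- rescale_units(m, 0.5)
  expect_equal(m5$cells[["3"]]$area, m$cells[["3"]]$area * 0.25)
  expect_equal(m5$length_matrix, m$length_matrix * 0.5)
  back <- rescale_units(m5, 2)
  expect_equal(back$length_matrix, m$length_matrix, tolerance = 1e-12)
  expect_equal(back$cells[["3"]]$area, m$cells[["3"]]$area, tolerance = 1e-12)
  expect_error(rescale_units(m, 0), "positive")
})

test_that("spec validation rejects inconsistent definitions", {
  expect_error(model_spec(
    substances = data.frame(name = "A", mobile = TRUE),
    equations = list(ghost = list(A = list())),
    transport = list(A = list(P = 1))), "unknown cell types")
  expect_error(model_spec(
    substances = data.frame(name = "A", mobile = TRUE)),
    "lack transport")
  expect_error(model_spec(
    substances = data.frame(name = "A", mobile = FALSE),
    equations = list(default = list(B = list()))), "unknown substances")
})

test_that("uniform diffusion-only state has zero derivative", {
  g <- make_grid_layout(2, 3, cell_px = 6, wall_px = 2)
  m <- annotate_default(orient_all(extract_structural_model(g$grid)))
  sys <- compile_rhs(diffusion_spec(), m)
  y <- rep(2.5, sys$n)
  expect_equal(max(abs(sys$rhs(0, y)[[1]])), 0)
})

test_that("two-cell diffusion matches the analytic exponential", {
  g <- make_grid_layout(1, 2, cell_px = 20, wall_px = 2)
  m <- annotate_default(orient_all(extract_structural_model(g$grid)))
  sys <- compile_rhs(diffusion_spec(P = 0.8), m)
  V <- sys$volumes
  s <- m$length_matrix[3, 4]
  lam <- 0.8 * s * (1 / V[1] + 1 / V[2])
  y0 <- c(3, 1)
  mn <- sum(V * y0) / sum(V)
  ts <- seq(0, 4 / lam, length.out = 21)
  traj <- integrate_system(sys, y0 = y0, times = ts,
                           rtol = 1e-10, atol = 1e-13)
  exact <- mn + (y0[1] - mn) * exp(-lam * ts)
  expect_lt(max(abs(traj$states[, 1] - exact) / exact), 1e-7)
})

test_that("immobile substances stay local to their cell", {
  g <- make_grid_layout(1, 5, cell_px = 6, wall_px = 2)
  m <- annotate_default(orient_all(extract_structural_model(g$grid)))
  spec <- model_spec(
    substances = data.frame(name = "X", mobile = FALSE),
    equations = list(default = list(X = list(
      list(kind = "constant", c0 = 0.3),
      list(kind = "linear_decay", k = 0.2)))),
    initial = list(X = 1))
  sys <- compile_rhs(spec, m)
  y <- runif(5, 0, 2)
  base <- sys$rhs(0, y)[[1]]
  # perturbing cell 5's state must not change cell 1's derivative
  y2 <- y; y2[5] <- y2[5] + 1
  pert <- sys$rhs(0, y2)[[1]]
  expect_equal(pert[1:4], base[1:4])
  expect_false(pert[5] == base[5])
  expect_equal(base, 0.3 - 0.2 * y)
})

test_that("compiled rhs is equivariant under cell relabeling", {
  g <- make_grid_layout(2, 2, cell_px = 6, wall_px = 2)
  m <- annotate_default(orient_all(extract_structural_model(g$grid)))
  spec <- model_spec(
    substances = data.frame(name = "A", mobile = TRUE),
    equations = list(default = list(A = list(
      list(kind = "linear_decay", k = 0.1)))),
    transport = list(A = list(P = 1, k_act = 0)),
    initial = list(A = 1))
  sys <- compile_rhs(spec, m)
  # permute cells 3..6 by p (positions): new id of old cell i
  p <- c(2L, 4L, 1L, 3L)   # old cell k (position) -> new position p[k]
  perm <- c(1L, 2L, p + 2L) # full index map on 1..6
  m2 <- m
  m2$adjacency[perm, perm] <- m$adjacency
  m2$length_matrix[perm, perm] <- m$length_matrix
  m2$width_matrix[perm, perm] <- m$width_matrix
  m2$orientation_matrix[perm, perm] <- m$orientation_matrix
  cells2 <- m$cells
  for (k in 1:4) {
    cells2[[as.character(p[k] + 2L)]] <- m$cells[[as.character(k + 2L)]]
    cells2[[as.character(p[k] + 2L)]]$id <- p[k] + 2L
  }
  m2$cells <- cells2
  sys2 <- compile_rhs(spec, m2)
  y <- runif(4, 0, 2)
  y2 <- numeric(4); y2[p] <- y
  d1 <- sys$rhs(0, y)[[1]]
  d2 <- sys2$rhs(0, y2)[[1]]
  expect_equal(d2[p], d1)
})

test_that("carrier placement on unresolved walls is a compilation error", {
  g <- make_grid_layout(2, 2, cell_px = 6, wall_px = 2)
  m <- annotate_default(extract_structural_model(g$grid))  # not oriented
  spec <- model_spec(
    substances = data.frame(name = "A", mobile = TRUE),
    cell_types = "default",
    transport = list(A = list(P = 1, k_act = 0.5,
                              carriers = list(default = list(top = 1)))),
    initial = list(A = 1))
  expect_error(compile_rhs(spec, m), "unresolved")
  # resolved model compiles
  expect_s3_class(compile_rhs(spec, orient_all(m) |> annotate_default()),
                  "compiled_system")
})

test_that("fixed-concentration boundaries pull cells to the boundary value", {
  g <- make_grid_layout(1, 1, cell_px = 8, wall_px = 2)
  m <- annotate_default(orient_all(extract_structural_model(g$grid)))
  spec <- model_spec(
    substances = data.frame(name = "A", mobile = TRUE),
    transport = list(A = list(P = 1, k_act = 0)),
    boundary = list("1" = list(A = 0.75)),
    initial = list(A = 0))
  sys <- compile_rhs(spec, m)
  ss <- find_steady_state(sys)
  expect_true(ss$converged)
  expect_equal(unname(ss$state), 0.75, tolerance = 1e-6)
})

test_that("closed transport-only systems conserve total amount", {
  g <- make_grid_layout(3, 3, cell_px = 8, wall_px = 2)
  m <- annotate_default(orient_all(extract_structural_model(g$grid)))
  spec <- model_spec(
    substances = data.frame(name = "A", mobile = TRUE),
    transport = list(A = list(P = 0.5, k_act = 0.3,
                              carriers = list(default = list(top = 1)))),
    initial = list(A = 1))
  sys <- compile_rhs(spec, m)
  y0 <- seq(0.5, 2, length.out = sys$n)
  traj <- integrate_system(sys, y0 = y0, times = seq(0, 100, 25),
                           rtol = 1e-10, atol = 1e-12)
  tot <- traj$states %*% sys$volumes
  expect_lt(max(abs(tot / tot[1] - 1)), 1e-8)
})
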