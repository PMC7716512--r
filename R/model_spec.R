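`%||%` <- function(a, b) if (is.null(a)) b else a

#' Define a morphogen model specification
#'
#' A `model_spec` declares the substances of the model, the cell types,
#' the per-type reaction terms, the transport parameters of the mobile
#' substances, the boundary handling toward the external environment
#' (index 1) and the excluded tissue (index 2), and the initial
#' concentrations.
#'
#' Reaction terms are lists with a `kind` and named parameters:
#' \describe{
#'   \item{constant}{synthesis at fixed rate `c0` (conc/time).}
#'   \item{linear_decay}{first-order removal `-k * x` of the substance
#'     itself.}
#'   \item{michaelis_menten}{saturating conversion `Vmax * x/(Km + x)` of
#'     `regulator` (default: the substance itself, counted as removal;
#'     another substance counts as production). `sign` overrides.}
#'   \item{hill_activation, hill_repression}{production
#'     `Vmax * f(x_regulator; K, h)` with the Generalized Hill factor `f`.}
#'   \item{product}{`Vmax` times a product of Hill factors given in
#'     `factors`, each `list(regulator, K, h, mode)`.}
#' }
#'
#' @param substances data frame with columns `name` and `mobile`, or a
#'   named logical vector (names = substances, values = mobile flag).
#' @param cell_types character vector of admissible type labels.
#' @param equations nested list: `equations[[type]][[substance]]` is a
#'   list of reaction terms. The type `"default"` applies to any cell
#'   type without its own entry.
#' @param transport named list per mobile substance:
#'   `list(P =, k_act =, carriers = list(type = list(top =, bottom =,
#'   left =, right =)))`. Carrier values are concentrations (numbers) or
#'   the name of an immobile substance acting as a dynamic carrier.
#' @param boundary named list for regions `"1"` and `"2"`: `"closed"`
#'   (default, zero flux) or a named list of fixed concentrations per
#'   substance.
#' @param initial named list of initial concentrations, either
#'   `list(substance = value)` (uniform) or nested per cell type.
#' @param parameters optional named scalars kept with the spec.
#' @param unit_scale micrometres per pixel used when embedding into a
#'   structural model (see [rescale_units]).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(substances, cell_types = "default",
                       equations = list(), transport = list(),
                       boundary = list(), initial = list(),
                       parameters = list(), unit_scale = 1) {
  if (is.logical(substances) && !is.null(names(substances)))
    substances <- data.frame(name = names(substances), mobile = unname(substances))
  stopifnot(is.data.frame(substances),
            all(c("name", "mobile") %in% names(substances)))
  spec <- structure(list(
    substances = substances, cell_types = cell_types,
    equations = equations, transport = transport, boundary = boundary,
    initial = initial, parameters = parameters,
    unit_scale = unit_scale), class = "model_spec")
  validate_model_spec(spec)
  spec
}

#' Validate a model specification
#'
#' Checks that equation types are admissible, that every mobile substance
#' has transport parameters, and that fixed boundary concentrations are
#' non-negative.
#'
#' @param spec a [model_spec].
#' @return `spec`, invisibly; errors describe the first violation found.
#' @export
validate_model_spec <- function(spec) {
  subs <- spec$substances$name
  bad_t <- setdiff(names(spec$equations), c(spec$cell_types, "default"))
  if (length(bad_t))
    stop("equations reference unknown cell types: ",
         paste(bad_t, collapse = ", "))
  for (tp in names(spec$equations)) {
    bad_s <- setdiff(names(spec$equations[[tp]]), subs)
    if (length(bad_s))
      stop("equations reference unknown substances: ",
           paste(bad_s, collapse = ", "))
  }
  mobile <- subs[spec$substances$mobile]
  missing_tr <- setdiff(mobile, names(spec$transport))
  if (length(missing_tr))
    stop("mobile substances lack transport parameters: ",
         paste(missing_tr, collapse = ", "))
  for (b in names(spec$boundary)) {
    v <- spec$boundary[[b]]
    if (is.list(v) && any(unlist(v) < 0))
      stop("fixed boundary concentrations must be non-negative")
  }
  invisible(spec)
}

#' @export
print.model_spec <- function(x, ...) {
  mob <- x$substances$name[x$substances$mobile]
  cat(sprintf("model_spec: %d substance(s) (%d mobile), %d cell type(s)\n",
              nrow(x$substances), length(mob), length(x$cell_types)))
  if (length(mob)) cat("  mobile:", paste(mob, collapse = ", "), "\n")
  invisible(x)
}

#' Read a model specification from a YAML file
#'
#' The file mirrors the [model_spec] arguments: blocks `substances`
#' (list of `{name, mobile}`), `cell_types` (list of labels, or a map
#' `label: {ids: [...]}` / `label: {where: "x < 30"}` whose rules are kept
#' for [annotate_cell_types]), `equations`, `transport`, `boundary`,
#' `initial`, `parameters` and `units: {um_per_px}`.
#'
#' @param path YAML file path.
#' @return a [model_spec]; any cell-type rules are attached as attribute
#'   `"type_rules"`.
#' @export
read_model_spec <- function(path) {
  y <- yaml::read_yaml(path)
  subs <- do.call(rbind, lapply(y$substances, function(s)
    data.frame(name = s$name, mobile = isTRUE(s$mobile))))
  rules <- NULL
  ct <- y$cell_types
  if (is.list(ct) && !is.null(names(ct))) {
    rules <- ct
    ct <- names(ct)
  } else {
    ct <- unlist(ct)
  }
  spec <- model_spec(
    substances = subs, cell_types = ct %||% "default",
    equations = y$equations %||% list(),
    transport = y$transport %||% list(),
    boundary = y$boundary %||% list(),
    initial = y$initial %||% list(),
    parameters = y$parameters %||% list(),
    unit_scale = y$units$um_per_px %||% 1)
  attr(spec, "type_rules") <- rules
  spec
}

#' Write a model specification to YAML
#'
#' @param spec a [model_spec].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_spec <- function(spec, path) {
  y <- list(
    substances = lapply(seq_len(nrow(spec$substances)), function(k)
      list(name = spec$substances$name[k],
           mobile = spec$substances$mobile[k])),
    cell_types = attr(spec, "type_rules") %||% as.list(spec$cell_types),
    equations = spec$equations, transport = spec$transport,
    boundary = spec$boundary, initial = spec$initial,
    parameters = spec$parameters,
    units = list(um_per_px = spec$unit_scale))
  writeLines(yaml::as.yaml(y), path)
  invisible(path)
}

#' Annotate the cells of a structural model with type labels
#'
#' @param model a `structural_model`.
#' @param annotation one of: a named vector/list mapping cell ids
#'   (3..N+2) to labels; a function `f(x, y)` of centroid coordinates
#'   returning a label; or a named list of rules
#'   `label = list(ids = c(...))` / `label = list(where = "x < 30")`
#'   (as from a YAML spec), applied in order with the first match
#'   winning.
#' @return the model with `cell_type` set on every cell record.
#' @export
annotate_cell_types <- function(model, annotation) {
  ids <- 3:(model$n_cells + 2L)
  types <- rep(NA_character_, length(ids))
  xs <- vapply(ids, function(i) model$cells[[as.character(i)]]$centroid[["x"]], 0)
  ys <- vapply(ids, function(i) model$cells[[as.character(i)]]$centroid[["y"]], 0)
  if (is.function(annotation)) {
    types <- vapply(seq_along(ids),
                    function(k) as.character(annotation(xs[k], ys[k])),
                    character(1))
  } else if (is.list(annotation) &&
             any(vapply(annotation, function(a)
               is.list(a) && (!is.null(a$ids) || !is.null(a$where)), TRUE))) {
    for (lab in names(annotation)) {
      ru <- annotation[[lab]]
      hit <- rep(FALSE, length(ids))
      if (!is.null(ru$ids)) hit <- hit | ids %in% ru$ids
      if (!is.null(ru$where)) {
        expr <- parse(text = ru$where)[[1]]
        hit <- hit | vapply(seq_along(ids), function(k)
          isTRUE(eval(expr, list(x = xs[k], y = ys[k]))), TRUE)
      }
      types[is.na(types) & hit] <- lab
    }
  } else {
    map <- unlist(annotation)
    types <- unname(map[as.character(ids)])
  }
  if (anyNA(types))
    stop("cell type annotation does not cover cell id(s): ",
         paste(ids[is.na(types)], collapse = ", "))
  for (k in seq_along(ids))
    model$cells[[as.character(ids[k])]]$cell_type <- types[k]
  model
}

#' Rescale the structural model to physical units
#'
#' Multiplies all lengths by `um_per_px` and all areas by its square:
#' cell areas and perimeters, wall lengths and widths, and the
#' length/width matrices. Centroids and bounding rectangles stay in
#' pixels. A factor of 1 leaves the model unchanged.
#'
#' @param model a `structural_model`.
#' @param um_per_px positive scale factor (micrometres per pixel).
#' @return the rescaled model; `model$pixel_size` is multiplied by the
#'   factor.
#' @export
rescale_units <- function(model, um_per_px) {
  if (!is.numeric(um_per_px) || length(um_per_px) != 1L || um_per_px <= 0)
    stop("um_per_px must be a single positive number")
  f <- um_per_px
  for (k in names(model$cells)) {
    model$cells[[k]]$area <- model$cells[[k]]$area * f^2
    model$cells[[k]]$perimeter <- model$cells[[k]]$perimeter * f
  }
  for (k in names(model$walls)) {
    model$walls[[k]]$length <- model$walls[[k]]$length * f
    model$walls[[k]]$width <- model$walls[[k]]$width * f
  }
  model$length_matrix <- model$length_matrix * f
  model$width_matrix <- model$width_matrix * f
  model$pixel_size <- model$pixel_size * f
  model
}
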