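# Reaction-term evaluation on a concentration matrix X (cells x
# substances, columns named). `self` is the substance whose equation the
# term belongs to. Regulator concentrations are clamped at 0 so that the
# tiny negative excursions a stiff solver may produce stay evaluable.
.eval_term <- function(term, X, self) {
  n <- nrow(X)
  conc <- function(name) pmax(X[, name], 0)
  switch(term$kind,
    constant = rep(term$c0, n),
    linear_decay = -term$k * X[, self],
    michaelis_menten = {
      reg <- term$regulator %||% self
      sign <- term$sign %||% (if (identical(reg, self)) -1 else 1)
      sign * michaelis_menten(conc(reg), term$Vmax, term$Km)
    },
    hill_activation = ,
    hill_repression = {
      mode <- if (term$kind == "hill_activation") "activation" else "repression"
      (term$sign %||% 1) * term$Vmax *
        generalized_hill(conc(term$regulator), term$K, term$h, mode)
    },
    product = {
      val <- rep((term$sign %||% 1) * term$Vmax, n)
      for (f in term$factors)
        val <- val * generalized_hill(conc(f$regulator), f$K, f$h,
                                      f$mode %||% "activation")
      val
    },
    stop("unknown reaction term kind: ", term$kind))
}

.boundary_setting <- function(spec, id) {
  b <- spec$boundary[[as.character(id)]]
  if (is.null(b) || identical(b, "closed")) return(NULL)
  b  # named list of fixed concentrations per substance
}

#' Compile the right-hand side of the tissue ODE system
#'
#' Binds a [model_spec] to a `structural_model` and builds the derivative
#' function of the full system. For a mobile substance A in cell i of
#' type tau with cell area V_i (the 2D volume proxy):
#' \deqn{dA_i/dt = \sum terms_{tau,A} + (1/V_i) \sum_j [ P s_{ij} (A_j - A_i)
#'   + k_{act} s_{ij} (c_{ji} A_j - c_{ij} A_i) ]}
#' where `s_ij` is the shared wall length and `c_ij` the carrier
#' concentration of cell i on its (i, j) wall, resolved from the carrier
#' placement map via cell i's type and the wall's orientation code.
#' Immobile substances keep only their reaction terms. Walls toward the
#' external environment (1) and excluded tissue (2) follow the boundary
#' setting: closed boundaries contribute nothing; fixed boundaries act as
#' a neighbour at constant concentration (with active efflux toward them
#' when a carrier sits on that wall).
#'
#' The state vector is laid out substances-outermost, cells ascending by
#' id within each substance.
#'
#' @param spec a [model_spec].
#' @param model an annotated, oriented `structural_model`.
#' @return an object of class `compiled_system` with elements
#'   `rhs(t, y)` (deSolve-compatible: returns `list(dy)`), `cell_ids`,
#'   `substances`, `volumes`, `state_names` and the index helper
#'   `index(cell, substance)`.
#' @export
compile_rhs <- function(spec, model) {
  validate_model_spec(spec)
  n <- model$n_cells
  ids <- 3:(n + 2L)
  types <- vapply(ids, function(i) model$cells[[as.character(i)]]$cell_type,
                  character(1))
  bad <- setdiff(unique(types), c(spec$cell_types, "default"))
  if (length(bad))
    stop("model contains cell types unknown to the spec: ",
         paste(bad, collapse = ", "))
  volumes <- vapply(ids, function(i) model$cells[[as.character(i)]]$area, 0)
  subs <- spec$substances$name
  mobile <- spec$substances$mobile
  nS <- length(subs)

  eq_for <- function(type, substance) {
    eqs <- spec$equations[[type]] %||% spec$equations[["default"]]
    eqs[[substance]]
  }

  # per-substance transport operators
  transport_ops <- vector("list", nS)
  names(transport_ops) <- subs
  S <- model$length_matrix[ids, ids, drop = FALSE]
  for (s in subs[mobile]) {
    tr <- spec$transport[[s]]
    P <- tr$P %||% 0
    k_act <- tr$k_act %||% 0
    carriers <- tr$carriers %||% list()
    L <- P * (S - diag(rowSums(S), n))
    bvec <- numeric(n)
    # fixed-concentration boundaries enter as constant neighbours
    for (b in 1:2) {
      fixed <- .boundary_setting(spec, b)
      if (is.null(fixed)) next
      a_fix <- fixed[[s]] %||% 0
      s_ib <- model$length_matrix[ids, b]
      L <- L - diag(P * s_ib, n)
      bvec <- bvec + P * s_ib * a_fix
    }
    # carrier resolution: c_ij for every directed adjacent pair
    E_static <- matrix(0, n, n)      # E[i,j] = k_act * s_ij * c_ji (static)
    dyn <- list()                    # dynamic carrier edges
    bad_walls <- character(0)
    if (k_act > 0 && length(carriers)) {
      for (ii in seq_len(n)) {
        cmap <- carriers[[types[ii]]]
        if (is.null(cmap) || !length(cmap)) next
        nb <- which(model$adjacency[ids[ii], ])
        for (jj in nb) {
          active_wall <- jj >= 3L || !is.null(.boundary_setting(spec, jj))
          if (!active_wall) next
          code <- model$orientation_matrix[ids[ii], jj]
          if (code == 0L) {
            bad_walls <- c(bad_walls, sprintf("(%d, %d)", ids[ii], jj))
            next
          }
          cval <- cmap[[.SIDE_NAMES[code]]]
          if (is.null(cval)) next
          sij <- model$length_matrix[ids[ii], jj]
          if (jj >= 3L) {
            jpos <- jj - 2L
            if (is.character(cval)) {
              dyn[[length(dyn) + 1L]] <-
                list(donor = ii, receiver = jpos, coef = k_act * sij,
                     var = cval)
            } else {
              E_static[jpos, ii] <- E_static[jpos, ii] + k_act * sij * cval
            }
          } else {
            # efflux into a fixed boundary: pure removal from the donor
            if (is.character(cval)) {
              dyn[[length(dyn) + 1L]] <-
                list(donor = ii, receiver = NA_integer_,
                     coef = k_act * sij, var = cval)
            } else {
              L[ii, ii] <- L[ii, ii] - k_act * sij * cval
            }
          }
        }
      }
    }
    if (length(bad_walls))
      stop("carrier placement needs orientations, but these walls are ",
           "unresolved: ", paste(unique(bad_walls), collapse = ", "))
    out_static <- colSums(E_static)
    transport_ops[[s]] <- list(L = L, E = E_static, out = out_static,
                               bvec = bvec, dyn = dyn)
  }

  type_groups <- split(seq_len(n), types)
  state_names <- as.vector(outer(ids, subs,
                                 function(i, s) paste(s, i, sep = ".")))
  rhs <- function(t, y, parms = NULL) {
    X <- matrix(y, nrow = n, ncol = nS, dimnames = list(NULL, subs))
    dX <- matrix(0, n, nS, dimnames = list(NULL, subs))
    for (tp in names(type_groups)) {
      rows <- type_groups[[tp]]
      for (s in subs) {
        terms <- eq_for(tp, s)
        if (is.null(terms)) next
        Xg <- X[rows, , drop = FALSE]
        for (term in terms)
          dX[rows, s] <- dX[rows, s] + .eval_term(term, Xg, s)
      }
    }
    for (s in subs) {
      op <- transport_ops[[s]]
      if (is.null(op)) next
      a <- X[, s]
      flux <- op$L %*% a + op$E %*% a - op$out * a + op$bvec
      for (d in op$dyn) {
        c_d <- pmax(X[d$donor, d$var], 0)
        amount <- d$coef * c_d * a[d$donor]
        flux[d$donor] <- flux[d$donor] - amount
        if (!is.na(d$receiver)) flux[d$receiver] <- flux[d$receiver] + amount
      }
      dX[, s] <- dX[, s] + as.vector(flux) / volumes
    }
    list(as.vector(dX))
  }

  system <- structure(list(
    rhs = rhs, cell_ids = ids, substances = subs, mobile = mobile,
    volumes = volumes, n = n, state_names = state_names,
    index = function(cell, substance)
      (match(substance, subs) - 1L) * n + match(cell, ids),
    spec = spec, model = model), class = "compiled_system")
  # the compiled system must be evaluable at the initial state
  y0 <- initial_state(system)
  test <- rhs(0, y0)
  if (length(test[[1L]]) != length(y0))
    stop("internal error: rhs output length mismatch")
  system
}

#' Initial state vector of a compiled system
#'
#' Built from the spec's `initial` block: either uniform per substance or
#' nested per cell type; substances without an entry start at 0.
#'
#' @param system a `compiled_system`.
#' @return named numeric state vector.
#' @export
initial_state <- function(system) {
  spec <- system$spec
  n <- system$n
  subs <- system$substances
  types <- vapply(system$cell_ids, function(i)
    system$model$cells[[as.character(i)]]$cell_type, character(1))
  y0 <- numeric(n * length(subs))
  names(y0) <- system$state_names
  init <- spec$initial
  per_substance <- length(init) && all(names(init) %in% subs) &&
    !any(vapply(init, is.list, TRUE))
  for (k in seq_along(subs)) {
    s <- subs[k]
    pos <- (k - 1L) * n + seq_len(n)
    if (per_substance) {
      y0[pos] <- init[[s]] %||% 0
    } else {
      for (tp in unique(types)) {
        v <- init[[tp]][[s]] %||% 0
        y0[pos[types == tp]] <- v
      }
    }
  }
  y0
}

#' @export
print.compiled_system <- function(x, ...) {
  cat(sprintf("compiled_system: %d cells x %d substance(s) = %d states\n",
              x$n, length(x$substances), x$n * length(x$substances)))
  invisible(x)
}
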