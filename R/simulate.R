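#' Integrate a compiled tissue ODE system
#'
#' Uses the stiff variable-order backward-differentiation (BDF) method of
#' [deSolve::ode], the standard choice for the sharply differing
#' timescales of reaction versus transport on a cell layout.
#'
#' @param system a `compiled_system`.
#' @param t_end final time (model time units).
#' @param y0 initial state; defaults to [initial_state] of the system.
#' @param times explicit output times (overrides `t_end`).
#' @param rtol,atol relative / absolute solver tolerances.
#' @param method any [deSolve::ode] method name; default `"bdf"`.
#' @return an object of class `tissue_trajectory` with `times`, `states`
#'   (one row per time), `converged` (`NA`; see [find_steady_state]) and
#'   `final_residual` (max-norm of the rhs at the final state).
#' @export
integrate_system <- function(system, t_end, y0 = NULL, times = NULL,
                             rtol = 1e-6, atol = 1e-9, method = "bdf") {
  stopifnot(inherits(system, "compiled_system"))
  if (is.null(y0)) y0 <- initial_state(system)
  if (length(y0) != system$n * length(system$substances))
    stop("y0 length does not match the compiled system")
  if (is.null(times)) {
    stopifnot(t_end > 0)
    times <- seq(0, t_end, length.out = 101L)
  }
  stopifnot(rtol > 0, atol > 0)
  sol <- deSolve::ode(y = y0, times = times, func = system$rhs,
                      parms = NULL, method = method,
                      rtol = rtol, atol = atol)
  istate <- attr(sol, "istate")
  if (!is.null(istate) && istate[1L] < 0)
    stop("ODE integration failed (istate = ", istate[1L], ")")
  states <- unname(sol[, -1L, drop = FALSE])
  colnames(states) <- system$state_names
  final <- states[nrow(states), ]
  res <- max(abs(system$rhs(times[length(times)], final)[[1L]]))
  structure(list(times = sol[, 1L], states = states, converged = NA,
                 final_residual = res, system = system),
            class = "tissue_trajectory")
}

#' @export
print.tissue_trajectory <- function(x, ...) {
  cat(sprintf("tissue_trajectory: %d time points over [%g, %g], %d states\n",
              length(x$times), min(x$times), max(x$times), ncol(x$states)))
  cat(sprintf("  final rhs max-norm: %.3g; converged: %s\n",
              x$final_residual, format(x$converged)))
  invisible(x)
}

#' @export
plot.tissue_trajectory <- function(x, substance = NULL, ...) {
  sel <- seq_len(ncol(x$states))
  if (!is.null(substance))
    sel <- grep(paste0("^", substance, "\\."), colnames(x$states))
  graphics::matplot(x$times, x$states[, sel, drop = FALSE], type = "l",
                    lty = 1, xlab = "time", ylab = "concentration", ...)
  invisible(x)
}

#' Find the steady state of a compiled system
#'
#' Integrates over doubling time windows until the max-norm of the rhs
#' falls below `tol_rel * max(max|y|, atol)`, or `t_max` is reached. This
#' residual test detects the fixed point without root-finding and is
#' robust for stiff relaxation.
#'
#' @param system a `compiled_system`.
#' @param y0 initial state; defaults to [initial_state].
#' @param tol_rel relative residual tolerance (default 1e-8).
#' @param t_max give up beyond this total integration time.
#' @param rtol,atol solver tolerances passed to [integrate_system].
#' @return list of class `steady_state`: `state` (named vector),
#'   `converged`, `residual`, `t_reached`.
#' @export
find_steady_state <- function(system, y0 = NULL, tol_rel = 1e-8,
                              t_max = 1e6, rtol = 1e-8, atol = 1e-10) {
  if (is.null(y0)) y0 <- initial_state(system)
  y <- y0
  t_done <- 0
  window <- 1
  repeat {
    res <- max(abs(system$rhs(t_done, y)[[1L]]))
    thresh <- tol_rel * max(max(abs(y)), atol)
    if (res < thresh)
      return(structure(list(state = y, converged = TRUE, residual = res,
                            t_reached = t_done, system = system),
                       class = "steady_state"))
    if (t_done >= t_max) break
    if (max(abs(y)) > 1e12)
      stop("state diverged during steady-state search")
    window <- min(window, t_max - t_done)
    traj <- integrate_system(system, y0 = y, times = c(0, window),
                             rtol = rtol, atol = atol)
    y <- traj$states[nrow(traj$states), ]
    t_done <- t_done + window
    window <- window * 2
  }
  res <- max(abs(system$rhs(t_done, y)[[1L]]))
  structure(list(state = y, converged = FALSE, residual = res,
                 t_reached = t_done, system = system),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("steady_state: converged = %s at t = %g (residual %.3g)\n",
              format(x$converged), x$t_reached, x$residual))
  invisible(x)
}

# extract the per-cell vector of one substance from a state vector,
# trajectory or steady_state
.substance_state <- function(state, system, substance) {
  if (inherits(state, "steady_state")) state <- state$state
  if (inherits(state, "tissue_trajectory"))
    state <- state$states[nrow(state$states), ]
  if (!substance %in% system$substances)
    stop("unknown substance: ", substance)
  k <- match(substance, system$substances)
  state[(k - 1L) * system$n + seq_len(system$n)]
}

#' Render per-cell concentrations on the cell layout
#'
#' Paints every cell's pixels with a colormap value at its concentration,
#' normalized from the minimum to the maximum across cells (or a fixed
#' range for comparing different states). Wall pixels are black; the
#' external environment and excluded tissue are neutral gray.
#'
#' @param model a `structural_model` carrying its label raster.
#' @param state numeric vector of concentrations for cells 3..N+2 (in id
#'   order), or a `steady_state` / `tissue_trajectory` together with
#'   `system` and `substance`.
#' @param system the `compiled_system` (required when `state` is not
#'   already a per-cell vector).
#' @param substance substance name to render.
#' @param colormap palette name passed to [grDevices::hcl.colors]
#'   (default `"viridis"`).
#' @param range optional fixed `c(lo, hi)` normalization range.
#' @param out_path optional PNG output path.
#' @return the H x W x 3 image array, invisibly.
#' @export
render_concentrations <- function(model, state, system = NULL,
                                  substance = NULL, colormap = "viridis",
                                  range = NULL, out_path = NULL) {
  if (is.null(model$labels)) stop("model carries no label raster")
  if (!is.numeric(state) || !is.null(substance)) {
    if (is.null(system) || is.null(substance))
      stop("supply `system` and `substance` to extract concentrations")
    state <- .substance_state(state, system, substance)
  }
  n <- model$n_cells
  if (length(state) != n)
    stop("state has ", length(state), " values for ", n, " cells")
  pal <- grDevices::hcl.colors(256L, colormap)
  lo <- if (is.null(range)) min(state) else range[1L]
  hi <- if (is.null(range)) max(state) else range[2L]
  idx <- if (hi > lo) {
    pmin(pmax(floor((state - lo) / (hi - lo) * 255) + 1L, 1L), 256L)
  } else {
    rep(1L, n)
  }
  cols <- grDevices::col2rgb(pal[idx]) / 255
  lab <- model$labels
  H <- nrow(lab); W <- ncol(lab)
  img <- array(0, dim = c(H, W, 3L))        # walls black
  gray <- lab == 1L | lab == 2L
  for (ch in 1:3) {
    plane <- matrix(0, H, W)
    plane[gray] <- 0.5
    for (k in seq_len(n)) plane[lab == k + 2L] <- cols[ch, k]
    img[, , ch] <- plane
  }
  if (!is.null(out_path)) png::writePNG(img, target = out_path)
  invisible(img)
}
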