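#' Michaelis-Menten rate
#'
#' `Vmax * x / (Km + x)`: saturating enzymatic conversion of a substrate
#' at concentration `x`, with maximal rate `Vmax` (concentration/time) and
#' half-saturation constant `Km` (concentration).
#'
#' @param x substrate concentration(s), non-negative.
#' @param Vmax maximal rate, non-negative.
#' @param Km half-saturation concentration, positive.
#' @return rate(s), same length as `x`.
#' @export
michaelis_menten <- function(x, Vmax, Km) {
  if (any(x < 0)) stop("concentration must be non-negative")
  stopifnot(Vmax >= 0, Km > 0)
  Vmax * x / (Km + x)
}

#' Generalized Hill regulation factor
#'
#' A monotone saturating factor in \[0, 1\]: activation
#' `(x/K)^h / (1 + (x/K)^h)`, repression `1 / (1 + (x/K)^h)`. The two
#' modes are complementary (they sum to 1), the factor equals 1/2 at
#' `x = K`, and multi-regulator terms are products of such factors.
#'
#' @param x regulator concentration(s), non-negative.
#' @param K threshold concentration, positive.
#' @param h Hill coefficient (steepness), positive.
#' @param mode `"activation"` or `"repression"`.
#' @return dimensionless factor(s) in \[0, 1\].
#' @export
generalized_hill <- function(x, K, h, mode = c("activation", "repression")) {
  mode <- match.arg(mode)
  if (any(x < 0)) stop("concentration must be non-negative")
  stopifnot(K > 0, h > 0)
  r <- (x / K)^h
  if (mode == "activation") r / (1 + r) else 1 / (1 + r)
}

#' Passive (Fick) flux across a shared wall
#'
#' Amount per time entering cell i across the wall it shares with cell j:
#' `P * s_ij * (a_j - a_i)`, proportional to the concentration difference,
#' the membrane permeability `P` (um/time) and the contact length `s_ij`
#' (um). Antisymmetric in the two cells, so pairwise amounts are conserved
#' exactly.
#'
#' @param a_i,a_j concentrations in cells i and j.
#' @param P permeability, non-negative.
#' @param s_ij contact (wall) length, positive.
#' @return flux into cell i (amount/time).
#' @export
passive_flux <- function(a_i, a_j, P, s_ij) {
  stopifnot(P >= 0, s_ij > 0)
  P * s_ij * (a_j - a_i)
}

#' Active carrier-mediated flux across a wall
#'
#' Mass-action efflux out of the donor cell, proportional to the donor
#' concentration, the carrier concentration on the donor's side of the
#' wall, the rate constant `k_act` and the contact length:
#' `k_act * carrier * s_ij * a_donor`. The net active exchange for cell i
#' across wall (i, j) is `k_act * s_ij * (c_ji * a_j - c_ij * a_i)` where
#' `c_ij` is cell i's carrier on that wall.
#'
#' @param a_donor donor-cell concentration, non-negative.
#' @param carrier carrier concentration on the donor's wall, non-negative.
#' @param k_act mass-action rate constant, non-negative.
#' @param s_ij contact length, positive.
#' @return flux out of the donor cell (amount/time).
#' @export
active_flux <- function(a_donor, carrier, k_act, s_ij) {
  stopifnot(all(a_donor >= 0), all(carrier >= 0), k_act >= 0, s_ij > 0)
  k_act * carrier * s_ij * a_donor
}
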