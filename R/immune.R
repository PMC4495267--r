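# Immune response and vessel interactions: T-cells extravasate at the vessel
# points with a probability saturating in the local chemokine concentration,
# chase tumor cells up the chemokine gradient, and engulf them on contact.
# Tumor cells that press hard enough against a vessel intravasate and may
# seed distant sites.

#' Per-step T-cell extravasation probability at a vessel point
#'
#' \deqn{P_T(\Delta t) = 1 - \Big(1 - \frac{A\,c^2}{B + c^2}\Big)^{\Delta t}}
#' with `c` the chemokine concentration at the vessel point and the exponent
#' in seconds. Saturates at \eqn{1-(1-A)^{\Delta t}} (i.e. at `A` per second)
#' for strong tumor signals and vanishes without one.
#'
#' @param c_b Chemokine concentration at the vessel point, `>= 0`.
#' @param dt Time step (s), `> 0`.
#' @param A Saturation probability per second, in `[0, 1]`.
#' @param B Half-saturation constant (concentration^2 units).
#' @return Probability, vectorized over `c_b`.
#' @export
extravasation_prob <- function(c_b, dt, A, B) {
  stopifnot(dt > 0, all(c_b >= 0))
  1 - (1 - A * c_b^2 / (B + c_b^2))^dt
}

#' Chemotactic drift of a T-cell
#'
#' Adds the chemotactic term \eqn{\mu \nabla c} to the mechanically driven
#' drift, with sensitivity \eqn{\mu} proportional to the cell's mobility
#' (\eqn{\mu = \mathrm{mu\_factor}\,\alpha_i}).
#'
#' @param mech_drift Mechanical drift vector (um/s).
#' @param grad_c Chemokine gradient at the T-cell (concentration/um).
#' @param mu Chemotactic sensitivity.
#' @return Drift vector (um/s).
#' @export
tcell_drift <- function(mech_drift, grad_c, mu) {
  mech_drift + mu * grad_c
}

#' Tumor cells engulfed by a T-cell
#'
#' Every tumor cell whose center lies within `R_tcell + R_tumor` of the
#' T-cell center is removed (engulfment is instantaneous on contact); other
#' phenotypes are never touched.
#'
#' @param cells Cell tibble.
#' @param i_tcell Row index of the T-cell.
#' @return Integer row indices of the engulfed tumor cells.
#' @export
engulfed_indices <- function(cells, i_tcell) {
  P <- cell_positions(cells)
  d <- sqrt(colSums((t(P) - P[i_tcell, ])^2))
  which(cells$phenotype == "tumor" & d < cells$R[i_tcell] + cells$R)
}

#' Intravasation criterion for a tumor cell
#'
#' A tumor cell enters a small blood vessel when it is in geometric contact
#' with a vessel sphere (`dist < R_b + R_cell`) and the strain energy density
#' it senses exceeds the wall threshold \eqn{M > M_b^*}. The energy
#' criterion alone has no locality, so vessel contact is required as well.
#'
#' @param M Sensed strain energy density at the cell (kPa).
#' @param dist_to_vessel Distance from the cell center to the nearest vessel
#'   point (um).
#' @param R_cell Cell radius (um).
#' @param R_b Vessel radius (um).
#' @param M_b_star Intravasation threshold (kPa).
#' @return Logical, vectorized.
#' @export
intravasation_criterion <- function(M, dist_to_vessel, R_cell, R_b, M_b_star) {
  (dist_to_vessel < R_b + R_cell) & (M > M_b_star)
}

# Place a newly extravasated T-cell just inside the boundary at a vessel
# point, jittering tangentially until it does not overlap an existing cell;
# returns NULL if no admissible position is found within `max_tries`.
place_tcell <- function(vp, domain, R_tcell, cells, max_tries = 20L) {
  dimn <- length(vp)
  base <- vp * (domain$radius - R_tcell) / domain$radius
  P <- if (nrow(cells)) cell_positions(cells) else NULL
  for (k in seq_len(max_tries)) {
    jitter <- if (k == 1L) rep(0, dimn) else {
      j <- rnorm(dimn) * R_tcell
      # keep the candidate inside the domain
      j
    }
    cand <- base + jitter
    nr <- sqrt(sum(cand^2))
    if (nr > domain$radius - R_tcell) {
      cand <- cand * (domain$radius - R_tcell) / nr
    }
    if (is.null(P)) return(cand)
    d <- sqrt(colSums((t(P) - cand)^2))
    if (all(d >= 0.95 * (cells$R + R_tcell))) return(cand)
  }
  NULL
}
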