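# Mechanical signalling: cells pull on the matrix and sense each other's
# strain energy density (mechanotaxis), repel on overlap via Hertz contact
# energies, and move with a mobility set by their traction force and
# viability. The domain wall and the small blood vessels enter as contact
# bodies by the same rules (mirror cell across the wall, spheres of radius
# R_b at the vessel points).

#' Strain energy density induced at a cell's own position
#'
#' A cell pulling on the substrate with traction force `F` stores
#' \deqn{M^0 = F^2 / (2 \pi^2 E_s R^4)} of elastic energy density (kPa) in
#' the matrix, the source strength of its mechanotactic signal.
#'
#' @param F Traction force (nN).
#' @param E_s Substrate elastic modulus (kPa).
#' @param R Cell radius (um).
#' @return Energy density (kPa), vectorized.
#' @export
source_strength <- function(F, E_s, R) {
  stopifnot(all(E_s > 0), all(R > 0))
  F^2 / (2 * pi^2 * E_s * R^4)
}

#' Total sensed strain energy density at a point
#'
#' Sum over all cells of their source strength attenuated exponentially with
#' distance, \eqn{M_j^0 \exp(-\lambda \lVert x - x_j \rVert / R_j)}, zeroed
#' beyond the sensing cutoff `L` and (optionally) below the sensing floor
#' `M_min`. The cutoff makes the field discontinuous across the sphere of
#' radius `L` around each source; this is a property of the model, not an
#' artifact.
#'
#' @param x Evaluation point (length-`dim` vector).
#' @param cells A cell tibble (columns `x`, `y`, optionally `z`, `R`, `F`).
#' @param mech Mechanics parameter list.
#' @param exclude Optional row index of a cell to leave out (a cell does not
#'   chase its own signal).
#' @return Sensed energy density (kPa).
#' @export
sensed_energy <- function(x, cells, mech, exclude = NULL) {
  if (!nrow(cells)) return(0)
  P <- cell_positions(cells)
  keep <- rep(TRUE, nrow(P))
  if (!is.null(exclude)) keep[exclude] <- FALSE
  if (!any(keep)) return(0)
  P <- P[keep, , drop = FALSE]
  R <- cells$R[keep]
  F <- cells$F[keep]
  d <- sqrt(colSums((t(P) - x)^2))
  contrib <- source_strength(F, mech$E_s, R) * exp(-mech$lambda * d / R)
  contrib[d >= mech$L] <- 0
  contrib[contrib < mech$M_min] <- 0
  sum(contrib)
}

#' Penetration depth of two overlapping spheres
#'
#' \deqn{h = \tfrac12 \max(0, R_i + R_j - \lVert x_j - x_i \rVert)}
#'
#' @param x_i,x_j Center positions.
#' @param R_i,R_j Radii (um).
#' @return Penetration depth (um).
#' @export
penetration_depth <- function(x_i, x_j, R_i, R_j) {
  d <- sqrt(sum((x_j - x_i)^2))
  if (d == 0) abort("penetration_depth: coincident cell centers")
  0.5 * max(0, R_i + R_j - d)
}

#' Hertz contact strain energy density
#'
#' Energy density stored when a sphere of radius `R_i` presses in by depth
#' `h`: \eqn{\frac{16}{25}\frac{E_c}{\sqrt2 \pi}(h/R_i)^{5/2}} in 2D and
#' \eqn{\frac{2}{5}\frac{E_c}{\sqrt2 \pi}(h/R_i)^{5/2}} in 3D. `R_i` is the
#' radius of the pushing body.
#'
#' @param h Penetration depth (um), `>= 0`.
#' @param R_i Radius of the pushing body (um).
#' @param E_c Cell elastic modulus (kPa).
#' @param dim Spatial dimension, 2 or 3.
#' @return Contact energy density (kPa), vectorized over `h` and `R_i`.
#' @export
contact_energy <- function(h, R_i, E_c, dim) {
  stopifnot(dim %in% c(2, 3), all(h >= 0))
  pref <- if (dim == 2) 16 / 25 else 2 / 5
  pref * E_c / (sqrt(2) * pi) * (h / R_i)^(5 / 2)
}

#' Contact pressure experienced by one cell
#'
#' The scalar entering the pressure responses of the cell cycle and the death
#' rate: the sum of Hertz contact energies from every overlapping neighbor,
#' the domain wall (a mirror cell of equal radius across the boundary) and
#' the vessel spheres.
#'
#' @param cells Cell tibble.
#' @param i Row index of the cell.
#' @param domain Domain parameter list.
#' @param mech Mechanics parameter list.
#' @param vessels Optional vessel-point matrix (defaults to
#'   [vessel_points()] of `domain`).
#' @return Pressure proxy (kPa).
#' @export
cell_pressure <- function(cells, i, domain, mech, vessels = NULL) {
  if (is.null(vessels)) vessels <- vessel_points(domain)
  mf <- mech_field(cell_positions(cells), cells$R, cells$F,
                   rep(FALSE, nrow(cells)), mech, domain, vessels)
  mf$p[i]
}

#' Deterministic migration direction of one cell
#'
#' Remote (sub-cutoff) strain-energy signals attract with weight equal to the
#' sensed contribution; contact terms (cells, wall, vessels) repel with
#' weight equal to the contact energy. Returns the normalized direction, or
#' `NULL` when the net vector is numerically zero (e.g. perfect symmetry).
#'
#' @inheritParams cell_pressure
#' @return Unit vector (length `dim`) or `NULL`.
#' @export
migration_direction <- function(cells, i, mech, domain = NULL, vessels = NULL) {
  if (is.null(vessels)) {
    vessels <- if (is.null(domain)) {
      matrix(numeric(0), ncol = ncol(cell_positions(cells)))
    } else {
      vessel_points(domain)
    }
  }
  mf <- mech_field(cell_positions(cells), cells$R, cells$F,
                   rep(FALSE, nrow(cells)), mech, domain, vessels)
  z <- mf$z[i, ]
  nz <- sqrt(sum(z^2))
  # the attenuation makes legitimate remote signals extremely small, so only
  # an exactly vanishing resultant (e.g. perfect symmetry) counts as "none"
  if (nz == 0) return(NULL)
  z / nz
}

#' Mobility coefficient of a cell
#'
#' The phenomenological mobility \eqn{\alpha = (F/\hat F)^2 \beta R^3 / f}
#' (um kPa^-1 s^-1 in the internal unit system), multiplied by viability:
#' dead cells do not migrate actively.
#'
#' @param F Traction force (nN).
#' @param F_hat Reference traction force (nN).
#' @param beta Rate constant (1/s).
#' @param R Cell radius (um).
#' @param f Friction coefficient (dimensionless), `> 0`.
#' @param alive Viability flag(s).
#' @return Mobility, vectorized.
#' @export
mobility_alpha <- function(F, F_hat, beta, R, f, alive = TRUE) {
  stopifnot(all(f > 0))
  (F / F_hat)^2 * beta * R^3 / f * as.numeric(alive)
}

# ---- vectorized field evaluation used by the engine ------------------------

cell_positions <- function(cells) {
  # a z column is present exactly when the state is 3D
  if ("z" %in% names(cells)) {
    cbind(cells$x, cells$y, cells$z)
  } else {
    cbind(cells$x, cells$y)
  }
}

# Full mechanical state for all cells at positions P (n x d):
#  M      drift magnitude (remote + contact for ordinary cells; contact-only
#         for M-phase cells, which do not migrate actively)
#  z      unnormalized direction vectors (n x d)
#  p      contact pressure (cell-cell + wall + vessel contact energies)
#  M_sens total sensed energy (remote + contact), the intravasation criterion
mech_field <- function(P, R, F, mphase, mech, domain, vessels) {
  n <- nrow(P)
  d <- ncol(P)
  z <- matrix(0, n, d)
  p <- numeric(n)
  M_remote <- numeric(n)
  M_contact <- numeric(n)
  if (n == 0) {
    return(list(M = numeric(0), z = z, p = p, M_sens = numeric(0)))
  }

  pref <- if (d == 2) 16 / 25 else 2 / 5
  hertz <- function(h, Rpush) pref * mech$E_c / (sqrt(2) * pi) * (h / Rpush)^(5 / 2)

  if (n > 1) {
    dm <- as.matrix(stats::dist(P))
    M0 <- source_strength(F, mech$E_s, R)
    # remote attraction: signal of cell j sensed at cell i (i rows)
    att <- t(M0 * exp(-mech$lambda * t(dm) / R))      # att[i, j]
    att[dm >= mech$L] <- 0
    att[att < mech$M_min] <- 0
    diag(att) <- 0
    # contact repulsion: neighbor j pushing on i uses the pusher radius R_j
    hh <- (outer(R, R, `+`) - dm) / 2
    hh[hh < 0] <- 0
    diag(hh) <- 0
    con <- t(hertz(t(hh), R))                          # con[i, j], pusher j
    con[hh == 0] <- 0
    diag(con) <- 0

    M_remote <- rowSums(att)
    M_contact <- rowSums(con)
    p <- p + rowSums(con)

    # unit vectors v_ij = (x_j - x_i)/d_ij; weight w[i, j] signed
    w <- att - con
    w[dm == 0] <- 0
    inv <- 1 / dm
    diag(inv) <- 0
    inv[!is.finite(inv)] <- 0
    for (k in seq_len(d)) {
      dxk <- outer(P[, k], P[, k], function(a, b) b - a)   # x_j - x_i
      z[, k] <- z[, k] + rowSums(w * dxk * inv)
    }
    # M-phase cells only feel contact terms
    if (any(mphase)) {
      wc <- -con
      for (k in seq_len(d)) {
        dxk <- outer(P[, k], P[, k], function(a, b) b - a)
        z[mphase, k] <- rowSums((wc * dxk * inv)[mphase, , drop = FALSE])
      }
    }
  }

  # wall contact: mirror cell of equal radius across the boundary sphere
  if (!is.null(domain)) {
    rad <- sqrt(rowSums(P^2))
    hw <- pmax(0, R - (domain$radius - rad))
    hit <- hw > 0
    if (any(hit)) {
      ew <- hertz(hw[hit], R[hit])
      M_contact[hit] <- M_contact[hit] + ew
      p[hit] <- p[hit] + ew
      xhat <- P[hit, , drop = FALSE] / pmax(rad[hit], 1e-12)
      z[hit, ] <- z[hit, ] - ew * xhat
    }
  }

  # vessel contact: spheres of radius R_b at the vessel points
  if (!is.null(vessels) && nrow(vessels) > 0 && !is.null(domain)) {
    for (vi in seq_len(nrow(vessels))) {
      dv <- sqrt(colSums((t(P) - vessels[vi, ])^2))
      hv <- pmax(0, (R + domain$R_b - dv) / 2)
      hit <- hv > 0
      if (any(hit)) {
        ev <- hertz(hv[hit], domain$R_b)
        M_contact[hit] <- M_contact[hit] + ev
        p[hit] <- p[hit] + ev
        # direction away from the vessel point
        vhat <- sweep(P[hit, , drop = FALSE], 2, vessels[vi, ]) /
          pmax(dv[hit], 1e-12)
        z[hit, ] <- z[hit, ] + ev * vhat
      }
    }
  }

  M <- M_remote + M_contact
  if (any(mphase)) M[mphase] <- M_contact[mphase]
  list(M = unname(M), z = unname(z), p = unname(p),
       M_sens = unname(M_remote + M_contact))
}
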