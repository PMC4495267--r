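# Shared fixtures: a cell-table builder and an independent fine-quadrature
# oracle for the chemokine integrals (linear interpolation of the source
# path + pracma::trapz on a fine grid; independent of the package's
# trapezoid/tail implementation).

make_cells <- function(pos, R = 3, phenotype = "epithelial", F = 1,
                       phase = "G1") {
  pos <- matrix(unlist(pos), ncol = length(pos[[1]]), byrow = TRUE)
  n <- nrow(pos)
  out <- tibble::tibble(
    id = seq_len(n),
    phenotype = rep_len(phenotype, n),
    x = pos[, 1],
    y = pos[, 2]
  )
  if (ncol(pos) == 3) out$z <- pos[, 3]
  out$R <- rep_len(R, n)
  out$phase <- rep_len(phase, n)
  out$phase_age <- 0
  out$birth_time <- 0
  out$F <- rep_len(F, n)
  out
}

open_domain <- function(dim = 2) {
  list(dim = dim, radius = 1e6, n_vessels = 0L, R_b = 4)
}

conc_oracle <- function(x, t, times, pos, gamma, D, dim, dt_fine) {
  s <- seq(times[1], min(t, times[length(times)]), by = dt_fine)
  px <- vapply(seq_len(dim),
               function(k) stats::approx(times, pos[, k], xout = s)$y,
               numeric(length(s)))
  tau <- t - s
  r2 <- rowSums((px - matrix(x, length(s), dim, byrow = TRUE))^2)
  f <- ifelse(tau > 0, exp(-r2 / (4 * D * tau)) / (4 * pi * D * tau)^(dim / 2), 0)
  gamma * pracma::trapz(s, f)
}

field_params <- function(...) {
  utils::modifyList(
    list(D = 100, gamma = 2, t_tilde = 1e12, t_star = 1e12,
         dt_quad = 1, eps_r = 0.1),
    list(...)
  )
}
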