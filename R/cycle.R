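# Cell cycle, growth, division, mutation and death. Dividing cells pass
# through G1 -> S -> G2 -> M. G1, G2 and M have fixed durations; the S-phase
# is exited each step with a fixed probability, so its residence time is
# geometric with mean T_S (Hill-modified under pressure). Death is calibrated
# so that an unconstrained colony doubles in the observed time T_2.

#' Deterministic radius growth rate
#'
#' \deqn{\kappa = (R_{max} - R_0) / (T_{G1} + T_{G2})} (um/s): growth is
#' active in G1 and G2 only, and carries the radius from \eqn{R_0} to
#' \eqn{R_{max}} over the two growth phases.
#'
#' @param params A phenotype parameter list ([phenotype_params()]).
#' @return Growth constant (um/s).
#' @export
growth_constant <- function(params) {
  denom <- params$T_G1 + params$T_G2
  if (denom <= 0) abort("growth_constant: T_G1 + T_G2 must be > 0")
  (params$R_max - params$R0) / denom
}

#' Stochastic radius update over one step
#'
#' \deqn{dR = \gamma_{phase}\,\kappa\,dt + \sigma_g\,dW} where the growth
#' indicator \eqn{\gamma_{phase}} is 1 in G1 and G2 and 0 otherwise; the
#' result is clamped to \eqn{[R_0, R_{max}]}.
#'
#' @param R Current radius/radii (um).
#' @param phase Phase label(s): `"G1"`, `"S"`, `"G2"`, `"M"` or `"none"`.
#' @param dt Time step (s), `> 0`.
#' @param kappa Growth constant(s) (um/s).
#' @param R0,R_max Radius bounds (um).
#' @param sigma_g Growth noise magnitude (um s^-1/2).
#' @return Updated radius vector.
#' @export
grow_radius <- function(R, phase, dt, kappa, R0, R_max, sigma_g = 0) {
  stopifnot(dt > 0)
  gam <- as.numeric(phase %in% c("G1", "G2"))
  noise <- if (sigma_g > 0) sigma_g * sqrt(dt) * rnorm(length(R)) else 0
  pmin(pmax(R + gam * kappa * dt + noise, R0), R_max)
}

#' Pressure response factors of the cycle and of death
#'
#' `pressure_growth_factor()` is the Hill-type multiplier
#' \eqn{F(p) = c_1/(1 + c_2 e^{c_3 p})} applied to the S-to-G2 transition
#' probability; with the default constants \eqn{F(0) = 1.1} (an unloaded cell
#' cycles slightly faster than average) and \eqn{F \to 0} under high pressure
#' (proliferation shut down). `pressure_death_factor()` is
#' \eqn{G(p) = c_4/(1 + e^{-c_5 p})}, which scales the death-rate exponent
#' and increases with pressure.
#'
#' @param p Contact pressure (kPa).
#' @param c1,c2,c3,c4,c5 Response constants.
#' @return Dimensionless factor, vectorized over `p`.
#' @export
pressure_growth_factor <- function(p, c1 = 11, c2 = 9, c3 = 1) {
  c1 / (1 + c2 * exp(c3 * p))
}

#' @rdname pressure_growth_factor
#' @export
pressure_death_factor <- function(p, c4 = 9, c5 = 10) {
  c4 / (1 + exp(-c5 * p))
}

#' Per-step probability of leaving the S-phase
#'
#' \deqn{P_{S\to G2} = \frac{\Delta t}{T_S} F(p)} (capped at 1), giving a
#' geometric residence time with mean \eqn{T_S / F(p)}. A phenotype with
#' `T_S = 0` skips the S-phase entirely (probability 1).
#'
#' @param dt Time step (s).
#' @param T_S Mean S-phase residence time (s).
#' @param p Contact pressure (kPa).
#' @inheritParams pressure_growth_factor
#' @return Probability in `[0, 1]`.
#' @export
transition_prob_S_to_G2 <- function(dt, T_S, p = 0, c1 = 11, c2 = 9, c3 = 1) {
  if (T_S <= 0) return(rep(1, length(p)))
  pmin(1, dt / T_S * pressure_growth_factor(p, c1, c2, c3))
}

#' Per-step probability of cell death
#'
#' \deqn{P_D(\Delta t) = 1 - 2^{(1/T_2 - 1/T_C)\,\Delta t\,G(p)}.}
#' With `G` identically 1 (the default, when `c4` is `NULL`) this is the
#' baseline calibration: survival compounds exactly so that an unconstrained
#' colony that divides every `T_C` doubles in `T_2`. Supplying `c4`, `c5`
#' applies the pressure response `G(p)`; `normalize = TRUE` rescales it to
#' `G(p)/G(0)` so the zero-pressure rate still matches the `T_2` calibration
#' (the engine's default treatment, see the methods vignette).
#'
#' @param dt Time step (s).
#' @param T_C Mean cycle time (s).
#' @param T_2 Observed colony doubling time (s), `> T_C`.
#' @param p Contact pressure (kPa).
#' @param c4,c5 Death response constants, or `NULL` for the baseline `G == 1`.
#' @param normalize Rescale `G` by its zero-pressure value.
#' @return Probability in `[0, 1]`, vectorized over `p`.
#' @export
death_prob <- function(dt, T_C, T_2, p = 0, c4 = NULL, c5 = NULL,
                       normalize = FALSE) {
  G <- if (is.null(c4)) rep(1, length(p)) else pressure_death_factor(p, c4, c5)
  if (normalize && !is.null(c4)) G <- G / pressure_death_factor(0, c4, c5)
  pmin(1, pmax(0, 1 - 2^((1 / T_2 - 1 / T_C) * dt * G)))
}

#' Expected total cycle duration
#'
#' The analytic mean of one full cycle: fixed G1, G2 and M durations plus the
#' geometric S-phase mean \eqn{T_S / F(p)}. With the pressure response off
#' (`pressure_response = FALSE`, the default) this is exactly
#' \eqn{T_{G1} + T_S + T_{G2} + T_M = T_C}.
#'
#' @param params Phenotype parameter list.
#' @param p Contact pressure (kPa).
#' @param c1,c2,c3 Cycle response constants.
#' @param pressure_response Apply `F(p)` to the S-phase mean.
#' @return Expected duration (s).
#' @export
expected_cycle_duration <- function(params, p = 0, c1 = 11, c2 = 9, c3 = 1,
                                    pressure_response = FALSE) {
  s_mean <- if (pressure_response && params$T_S > 0) {
    params$T_S / pressure_growth_factor(p, c1, c2, c3)
  } else {
    params$T_S
  }
  params$T_G1 + s_mean + params$T_G2 + params$T_M
}

#' Division geometry
#'
#' Splits a mother cell into two daughters of radius `R0` displaced along a
#' uniformly random unit direction so that their contact point coincides with
#' the mother's center (center separation exactly \eqn{2 R_0}); in 3D the two
#' daughter volumes sum to the mother volume at \eqn{R_{max} = 2^{1/3} R_0}.
#'
#' @param x Mother center (length-`dim` vector).
#' @param R0 Daughter radius (um).
#' @param dim Spatial dimension.
#' @return A list with `x1`, `x2` (daughter centers) and `u` (the direction).
#' @export
divide_cell <- function(x, R0, dim = length(x)) {
  u <- random_unit_vector(dim)
  list(x1 = x + R0 * u, x2 = x - R0 * u, u = u)
}

random_unit_vector <- function(dim) {
  repeat {
    v <- rnorm(dim)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}

#' Mutation decision at mitosis
#'
#' At the end of an epithelial division the daughter becomes a tumor cell
#' with probability `P_M`.
#'
#' @param n Number of division events.
#' @param P_M Mutation probability per division.
#' @return Logical vector of length `n`.
#' @export
maybe_mutate <- function(n, P_M) {
  if (n == 0) return(logical(0))
  runif(n) < P_M
}

# ---- calibration simulators ------------------------------------------------

#' Simulate S-phase residence times
#'
#' Runs `n` cells through the per-step Bernoulli exit rule (the same rule the
#' engine applies) and returns their realized S-phase residence times. With
#' the pressure response off the sample mean converges to `T_S`.
#'
#' @param n Number of cells.
#' @param dt Time step (s).
#' @param T_S Mean S-phase residence (s).
#' @param p Contact pressure (kPa).
#' @param c1,c2,c3 Cycle response constants (used only when
#'   `pressure_response = TRUE`).
#' @param pressure_response Apply `F(p)`.
#' @param max_steps Safety cap on the per-cell step count.
#' @return Numeric vector of residence times (s).
#' @export
simulate_s_residence <- function(n, dt = 1, T_S = 400, p = 0,
                                 c1 = 11, c2 = 9, c3 = 1,
                                 pressure_response = FALSE,
                                 max_steps = 1e6) {
  prob <- if (pressure_response) {
    transition_prob_S_to_G2(dt, T_S, p, c1, c2, c3)
  } else {
    min(1, dt / T_S)
  }
  steps <- integer(n)
  remaining <- seq_len(n)
  k <- 0L
  while (length(remaining) && k < max_steps) {
    k <- k + 1L
    exit <- runif(length(remaining)) < prob
    steps[remaining[exit]] <- k
    remaining <- remaining[!exit]
  }
  steps[steps == 0L] <- max_steps
  steps * dt
}

#' Doubling time of a non-spatial branching colony
#'
#' Starts `n0` cells, kills each with the per-step baseline death probability
#' (G = 1), and divides each survivor into two at the end of every cycle of
#' length `T_C`; returns the first time the population reaches `target`
#' (default `2 n0`). With the published calibration the expected doubling
#' time is `T_2`.
#'
#' The doubling-time calibration describes a colony in steady exponential
#' growth, so by default the initial ages are drawn from the stationary age
#' profile \eqn{\rho(a) \propto 2^{-a/T_C}} of that regime. A synchronized
#' start (`age_init = "synchronized"`, all ages 0) makes the population
#' divide in waves and distorts the first-passage time by a large sawtooth;
#' see the methods vignette.
#'
#' @param n0 Initial population.
#' @param T_C Cycle time (s).
#' @param T_2 Calibrated doubling time (s).
#' @param dt Time step (s).
#' @param target Population size to reach.
#' @param t_max Give-up horizon (s); `NA` is returned if never reached.
#' @param age_init `"stationary"` (default), `"uniform"` or `"synchronized"`.
#' @return First-passage time (s).
#' @export
simulate_doubling_time <- function(n0 = 2000, T_C = 21, T_2 = 4000, dt = 1,
                                   target = 2 * n0, t_max = 10 * T_2,
                                   age_init = c("stationary", "uniform",
                                                "synchronized")) {
  age_init <- match.arg(age_init)
  pd <- death_prob(dt, T_C, T_2)
  age <- switch(age_init,
    stationary = floor(-T_C * log2(1 - runif(n0) / 2)),
    uniform = floor(runif(n0, 0, T_C)),
    synchronized = numeric(n0)
  )
  t <- 0
  while (t < t_max) {
    t <- t + dt
    age <- age[runif(length(age)) >= pd]
    if (!length(age)) return(NA_real_)
    age <- age + dt
    div <- age >= T_C
    if (any(div)) {
      age <- c(age[!div], numeric(2 * sum(div)))
    }
    if (length(age) >= target) return(t)
  }
  NA_real_
}
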