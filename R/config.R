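#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn %||%
#' @importFrom stats runif rnorm
#' @importFrom utils modifyList head tail
NULL

# Internal unit system (fixed): length um, time s, pressure / energy density
# kPa, force nN, concentration in scaled amount per um^d. All parameters are
# stored and consumed in these units; conversions happen only at config load.

PHENOTYPES <- c("epithelial", "tumor", "tcell")

#' Default simulation configuration
#'
#' Builds the full nested parameter set of the model: domain geometry, the
#' chemokine transport field, mechanics (traction, Hertz contact, sensing),
#' immune-response parameters, the three cell phenotypes (epithelial, tumor,
#' T-cell) and engine controls. All defaults are the model's published
#' reference values; quantities use the fixed internal unit system
#' (\eqn{\mu m}, s, kPa, nN).
#'
#' Phenotype residence times (s): epithelial G1/S/G2/M = 300/400/300/1
#' (cycle 1001, observed colony doubling time \eqn{T_2 = 10^7}); tumor
#' 10/0/10/1 (cycle 21, \eqn{T_2 = 4000}). The tumor S-phase duration of 0
#' means tumor cells skip the stochastic S-phase residence entirely.
#'
#' @param dim Spatial dimension, 2 or 3.
#' @param ... Named overrides applied recursively on top of the defaults,
#'   e.g. `field = list(D = 50)`.
#' @return A nested list of class `oncosim_config`.
#' @examples
#' cfg <- default_config()
#' cfg$field$D            # 100 um^2/s
#' cfg$phenotypes$epithelial$T_C  # 1001 s
#' @export
default_config <- function(dim = 2, ...) {
  stopifnot(dim %in% c(2, 3))
  r0 <- 3
  cfg <- list(
    seed = 1L,
    domain = list(
      dim = dim,
      radius = 40,                      # um
      n_vessels = if (dim == 2) 4L else 6L,
      R_b = 4                           # vessel radius, um
    ),
    field = list(
      D = 100,        # chemokine diffusivity, um^2/s
      gamma = 2,      # secretion rate per tumor cell (scaled amount / s)
      t_tilde = 80,   # drop dead-source contributions once t - tau_D >= t_tilde (s)
      t_star = 80,    # switch to the closed-form long-time tail beyond t - t_star (s)
      dt_quad = 5,    # trace sampling / quadrature step (s)
      eps_r = 0.5     # minimum source-evaluation distance guard (um)
    ),
    mech = list(
      E_s = 5,        # substrate (ECM) elastic modulus, kPa
      E_c = 0.5,      # cell elastic modulus, kPa
      F_hat = 1,      # reference traction force, nN
      lambda = 10,    # dimensionless attenuation of the strain-energy signal
      L = 30,         # mechanical sensing cutoff, um
      f = 0.2,        # dimensionless cell-substrate friction
      M_b_star = 0.1, # strain-energy threshold for intravasation, kPa
      M_min = 0,      # optional sensing floor on remote signals, kPa (0 = off)
      c1 = 11, c2 = 9, c3 = 1,  # S->G2 pressure response F(p)
      c4 = 9, c5 = 10           # death pressure response G(p)
    ),
    immune = list(
      A = 0.05,        # extravasation saturation probability per second
      B = 200,         # half-saturation constant (concentration^2 units)
      mu_factor = 1e4, # chemotactic sensitivity mu = mu_factor * alpha_i
      R_tcell = 4.5,   # T-cell radius, um
      P_M = 0.25,      # mutation probability per epithelial division
      P_S = 0.01       # seeding probability per intravasated tumor cell
    ),
    phenotypes = list(
      epithelial = phenotype_params(
        "epithelial", T_G1 = 300, T_S = 400, T_G2 = 300, T_M = 1, T_2 = 1e7,
        R0 = r0, can_divide = TRUE, can_mutate = TRUE
      ),
      tumor = phenotype_params(
        "tumor", T_G1 = 10, T_S = 0, T_G2 = 10, T_M = 1, T_2 = 4000,
        R0 = r0, can_divide = TRUE, can_mutate = FALSE
      ),
      # T-cells do not proliferate; they only need the death calibration,
      # which reuses the epithelial reference values.
      tcell = phenotype_params(
        "tcell", T_G1 = 300, T_S = 400, T_G2 = 300, T_M = 1, T_2 = 1e7,
        R0 = 4.5, R_max = 4.5, can_divide = FALSE, can_mutate = FALSE
      )
    ),
    engine = list(
      t_end = 400,             # s
      dt_max = 1,              # s
      dt_min = 1e-3,           # s, floor under the quarter-diameter rule
      stop_fraction = 0.5,     # stop once tumor fraction reaches this
      sigma = 0.1,             # random-walk magnitude, um s^-1/2
      sigma_g = 0.01,          # radius growth noise, um s^-1/2
      v_max = 1,               # cap on active drift speed, um/s (Inf = off)
      death_response = "normalized",  # "normalized", "raw" or "off"
      synchronized_start = FALSE,
      initial_tumor = 0L,      # tumor cells seeded at t = 0 (center cluster)
      packing_fraction = 0.72, # initial coverage; random packings jam ~0.82
      counts_every = 1,        # record a counts row at least every this many s
      max_cells = 5000L
    )
  )
  dots <- list(...)
  if (length(dots)) {
    stopifnot(!is.null(names(dots)), all(names(dots) != ""))
    cfg <- modifyList(cfg, dots)
  }
  structure(cfg, class = "oncosim_config")
}

#' Per-phenotype cycle and mechanics parameters
#'
#' @param name One of `"epithelial"`, `"tumor"`, `"tcell"`.
#' @param T_G1,T_S,T_G2,T_M Mean residence times of the cycle phases (s).
#' @param T_2 Observed colony doubling time (s) used to calibrate death.
#' @param R0 Radius right after division (um).
#' @param R_max Radius at mitosis (um); default \eqn{2^{1/3} R_0} so that in
#'   3D the mother volume equals the two daughter volumes.
#' @param F Traction force (nN).
#' @param beta Mobility rate constant (1/s).
#' @param can_divide,can_mutate Capability flags.
#' @return A named list; the derived total cycle time `T_C` is the sum of the
#'   four phase times.
#' @export
phenotype_params <- function(name, T_G1, T_S, T_G2, T_M, T_2,
                             R0 = 3, R_max = 2^(1 / 3) * R0,
                             F = 1, beta = 10,
                             can_divide = TRUE, can_mutate = FALSE) {
  name <- match.arg(name, PHENOTYPES)
  list(
    name = name,
    T_G1 = T_G1, T_S = T_S, T_G2 = T_G2, T_M = T_M,
    T_C = T_G1 + T_S + T_G2 + T_M,
    T_2 = T_2,
    R0 = R0, R_max = R_max,
    F = F, beta = beta,
    can_divide = isTRUE(can_divide), can_mutate = isTRUE(can_mutate)
  )
}

fail_invariant <- function(what, detail) {
  abort(sprintf("invalid configuration: %s (%s)", what, detail),
        class = "oncosim_config_error")
}

#' Validate a simulation configuration
#'
#' Checks every structural invariant the engine relies on: positivity of
#' physical constants, probability bounds, `T_C` equal to the sum of the phase
#' times, `T_2 > T_C` (a doubling time equal to the cycle time would make the
#' death-rate calibration degenerate, i.e. immortal cells), radius ordering
#' and domain geometry.
#'
#' @param config An `oncosim_config` list.
#' @return The config, invisibly, if valid; otherwise an error naming the
#'   violated invariant.
#' @export
validate_config <- function(config) {
  cfg <- config
  dm <- cfg$domain
  if (!dm$dim %in% c(2, 3)) fail_invariant("domain$dim must be 2 or 3", dm$dim)
  if (!is.numeric(dm$radius) || dm$radius <= 0)
    fail_invariant("domain$radius must be > 0", dm$radius)
  if (dm$n_vessels < 0) fail_invariant("domain$n_vessels must be >= 0", dm$n_vessels)
  if (dm$R_b <= 0) fail_invariant("domain$R_b must be > 0", dm$R_b)

  fd <- cfg$field
  for (nm in c("D", "t_tilde", "t_star", "dt_quad", "eps_r")) {
    if (!is.numeric(fd[[nm]]) || fd[[nm]] <= 0)
      fail_invariant(sprintf("field$%s must be > 0", nm), fd[[nm]])
  }
  if (fd$gamma < 0) fail_invariant("field$gamma must be >= 0", fd$gamma)

  mc <- cfg$mech
  for (nm in c("E_s", "E_c", "F_hat", "lambda", "L", "f", "M_b_star",
               "c1", "c2", "c3", "c4", "c5")) {
    if (!is.numeric(mc[[nm]]) || mc[[nm]] <= 0)
      fail_invariant(sprintf("mech$%s must be > 0", nm), mc[[nm]])
  }
  if (mc$M_min < 0) fail_invariant("mech$M_min must be >= 0", mc$M_min)

  im <- cfg$immune
  if (im$A < 0 || im$A > 1) fail_invariant("immune$A must be in [0, 1]", im$A)
  if (im$B <= 0) fail_invariant("immune$B must be > 0", im$B)
  if (im$P_M < 0 || im$P_M > 1) fail_invariant("immune$P_M must be in [0, 1]", im$P_M)
  if (im$P_S < 0 || im$P_S > 1) fail_invariant("immune$P_S must be in [0, 1]", im$P_S)
  if (im$R_tcell <= 0) fail_invariant("immune$R_tcell must be > 0", im$R_tcell)
  if (im$mu_factor < 0) fail_invariant("immune$mu_factor must be >= 0", im$mu_factor)

  for (ph in names(cfg$phenotypes)) {
    pp <- cfg$phenotypes[[ph]]
    for (nm in c("T_G1", "T_S", "T_G2", "T_M")) {
      if (pp[[nm]] < 0) fail_invariant(sprintf("%s$%s must be >= 0", ph, nm), pp[[nm]])
    }
    if (!isTRUE(all.equal(pp$T_C, pp$T_G1 + pp$T_S + pp$T_G2 + pp$T_M)))
      fail_invariant(sprintf("%s: T_C must equal T_G1 + T_S + T_G2 + T_M", ph),
                     sprintf("T_C = %g, sum = %g", pp$T_C,
                             pp$T_G1 + pp$T_S + pp$T_G2 + pp$T_M))
    if (pp$T_2 <= pp$T_C)
      fail_invariant(sprintf("%s: T_2 must exceed T_C", ph),
                     "T_2 = T_C makes the death exponent zero, i.e. immortal cells")
    if (pp$R0 <= 0) fail_invariant(sprintf("%s$R0 must be > 0", ph), pp$R0)
    if (pp$R_max < pp$R0)
      fail_invariant(sprintf("%s: R_max must be >= R0", ph),
                     sprintf("R_max = %g, R0 = %g", pp$R_max, pp$R0))
    if (pp$F < 0) fail_invariant(sprintf("%s$F must be >= 0", ph), pp$F)
    if (pp$beta <= 0) fail_invariant(sprintf("%s$beta must be > 0", ph), pp$beta)
  }

  en <- cfg$engine
  if (en$t_end <= 0) fail_invariant("engine$t_end must be > 0", en$t_end)
  if (en$dt_max <= 0) fail_invariant("engine$dt_max must be > 0", en$dt_max)
  if (en$dt_min <= 0 || en$dt_min > en$dt_max)
    fail_invariant("engine$dt_min must be in (0, dt_max]", en$dt_min)
  if (en$stop_fraction <= 0 || en$stop_fraction > 1)
    fail_invariant("engine$stop_fraction must be in (0, 1]", en$stop_fraction)
  if (en$sigma < 0) fail_invariant("engine$sigma must be >= 0", en$sigma)
  if (en$sigma_g < 0) fail_invariant("engine$sigma_g must be >= 0", en$sigma_g)
  if (en$v_max <= 0) fail_invariant("engine$v_max must be > 0 (use Inf to disable)", en$v_max)
  if (!en$death_response %in% c("normalized", "raw", "off"))
    fail_invariant("engine$death_response must be 'normalized', 'raw' or 'off'",
                   en$death_response)
  if (en$packing_fraction <= 0 || en$packing_fraction > 0.9069)
    fail_invariant("engine$packing_fraction must be in (0, 0.9069]",
                   "hexagonal close packing bounds achievable 2D coverage")
  if (en$initial_tumor < 0) fail_invariant("engine$initial_tumor must be >= 0",
                                           en$initial_tumor)
  invisible(config)
}

#' Write / read a configuration file
#'
#' Configurations are stored as JSON with full numeric precision so that a
#' write/read round trip reproduces every field bit-identically; a run is
#' therefore reproducible from the file (plus its embedded seed) alone.
#'
#' @param config An `oncosim_config` list.
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()` returns
#'   a validated `oncosim_config`.
#' @export
write_config <- function(config, path) {
  # 17 significant digits makes double round-trips exact
  jsonlite::write_json(unclass(config), path,
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  # JSON has one number type; restore doubles first, then the integer fields
  cfg <- rapply(cfg, as.numeric, classes = "integer", how = "replace")
  cfg$seed <- as.integer(cfg$seed)
  cfg$domain$n_vessels <- as.integer(cfg$domain$n_vessels)
  cfg$engine$initial_tumor <- as.integer(cfg$engine$initial_tumor)
  cfg$engine$max_cells <- as.integer(cfg$engine$max_cells)
  cfg <- structure(cfg, class = "oncosim_config")
  validate_config(cfg)
  cfg
}

#' @export
print.oncosim_config <- function(x, ...) {
  cat(sprintf("<oncosim_config> %dD domain, radius %g um, %d vessel points\n",
              x$domain$dim, x$domain$radius, x$domain$n_vessels))
  cat(sprintf("  field: D = %g um^2/s, gamma = %g, t_tilde = %g s\n",
              x$field$D, x$field$gamma, x$field$t_tilde))
  cat(sprintf("  immune: A = %g, B = %g, mu = %g alpha, P_M = %g\n",
              x$immune$A, x$immune$B, x$immune$mu_factor, x$immune$P_M))
  cat(sprintf("  engine: t_end = %g s, stop at tumor fraction %g, seed %d\n",
              x$engine$t_end, x$engine$stop_fraction, x$seed))
  invisible(x)
}

#' Vessel points on the domain boundary
#'
#' Equally spaced points on the boundary circle in 2D (4 by default) or the
#' octahedral vertices of the boundary sphere in 3D (6 by default). These are
#' the sites where T-cells extravasate and tumor cells may intravasate.
#'
#' @param domain The `domain` section of a config.
#' @return A matrix with one row per vessel point (`dim` columns).
#' @export
vessel_points <- function(domain) {
  n <- domain$n_vessels
  R <- domain$radius
  if (n == 0L) {
    return(matrix(numeric(0), ncol = domain$dim))
  }
  if (domain$dim == 2) {
    ang <- 2 * pi * (seq_len(n) - 1) / n
    cbind(R * cos(ang), R * sin(ang))
  } else {
    if (n == 6L) {
      R * rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
    } else {
      # Fibonacci spiral for other counts
      i <- seq_len(n)
      phi <- acos(1 - 2 * (i - 0.5) / n)
      theta <- pi * (1 + sqrt(5)) * i
      R * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
    }
  }
}
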