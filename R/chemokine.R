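# Chemokine transport without a mesh: tumor cells are moving point sources of
# a diffusing chemokine, and the concentration at any point is the Duhamel
# superposition of free-space heat kernels over each source's recorded
# trajectory. Traces of dead cells are kept: their chemokine is still
# dispersing through the tissue after the cell is gone.

#' Free-space heat kernel of the diffusion equation
#'
#' Density at distance `r` and time lag `tau` after a unit point release:
#' \deqn{K(r, \tau) = \frac{\exp(-r^2 / (4 D \tau))}{(4 \pi D \tau)^{d/2}}.}
#' As \eqn{\tau \to 0} with \eqn{r > 0} the value tends to 0 (the exponential
#' dominates the algebraic singularity).
#'
#' @param r Distance(s) from the source (um), `>= 0`.
#' @param tau Time lag(s) since release (s), `>= 0`.
#' @param D Diffusivity (um^2/s).
#' @param dim Spatial dimension, 2 or 3.
#' @return Kernel density, vectorized over `r` and `tau`.
#' @export
kernel_value <- function(r, tau, D, dim) {
  stopifnot(dim %in% c(2, 3), D > 0)
  n <- max(length(r), length(tau))
  r <- rep_len(r, n)
  tau <- rep_len(tau, n)
  if (any(tau < 0)) abort("kernel_value: tau must be >= 0")
  if (any(tau == 0 & r == 0))
    abort("kernel_value: singular evaluation at r = 0, tau = 0")
  out <- numeric(n)
  pos <- tau > 0
  out[pos] <- exp(-r[pos]^2 / (4 * D * tau[pos])) /
    (4 * pi * D * tau[pos])^(dim / 2)
  out
}

#' Closed-form long-time tail of a source's concentration integral
#'
#' For history older than `t - t_star` the kernel's spatial factor is close to
#' one at tissue-scale distances, and the remaining time integral has the
#' closed forms
#' \deqn{\frac{\gamma}{4\pi D}\log\frac{t-\tau_B}{t^*} \quad (d = 2), \qquad
#'       \frac{\gamma}{2\pi D}\Big(\frac{1}{\sqrt{t^*}} -
#'       \frac{1}{\sqrt{t-\tau_B}}\Big) \quad (d = 3),}
#' with the secretion rate \eqn{\gamma} constant over the interval. The 3D
#' form is the published coarse long-time approximation (an upper-bound-style
#' estimate); the 2D form is exact once the spatial factor is dropped.
#'
#' @param t Evaluation time (s).
#' @param tau_B Source birth time (s); requires `t - tau_B >= t_star`.
#' @param field Field parameter list (`D`, `gamma`, `t_star`).
#' @param dim Spatial dimension, 2 or 3.
#' @return Tail contribution to the concentration.
#' @export
tail_integral <- function(t, tau_B, field, dim) {
  if (t - tau_B < field$t_star)
    abort("tail_integral: requires t - tau_B >= t_star")
  tail_integral_range(t, tau_B, t - field$t_star, field$gamma, field$D, dim)
}

# integral of the spatially collapsed long-time integrand over [s0, s1]
tail_integral_range <- function(t, s0, s1, gamma, D, dim) {
  if (s1 <= s0) return(0)
  if (dim == 2) {
    gamma / (4 * pi * D) * log((t - s0) / (t - s1))
  } else {
    gamma / (2 * pi * D) * (1 / sqrt(t - s1) - 1 / sqrt(t - s0))
  }
}

# ---- source traces ---------------------------------------------------------

#' Source traces: time-stamped trajectories of tumor cells
#'
#' Each tumor cell carries one trace holding its birth time, its (possibly
#' open) death time and its position history sampled at the quadrature
#' resolution `dt_quad`. Traces of dead cells are retained for the lifetime of
#' the simulation.
#'
#' @param cell_id Integer id of the tumor cell.
#' @param t Time (s).
#' @param x Position (numeric vector of length `dim`).
#' @return `trace_new()` returns a `source_trace` list with fields `cell_id`,
#'   `tau_B`, `tau_D` (`NA` while alive), `times` and `pos` (matrix, one row
#'   per sample).
#' @export
trace_new <- function(cell_id, t, x) {
  structure(
    list(cell_id = cell_id, tau_B = t, tau_D = NA_real_,
         times = t, pos = matrix(x, nrow = 1)),
    class = "source_trace"
  )
}

#' @rdname trace_new
#' @param trace A `source_trace`.
#' @export
trace_append <- function(trace, t, x) {
  if (!is.na(trace$tau_D)) abort("trace_append: trace is closed")
  if (t <= trace$times[length(trace$times)]) return(trace)
  trace$times <- c(trace$times, t)
  trace$pos <- rbind(trace$pos, x)
  trace
}

#' @rdname trace_new
#' @export
trace_close <- function(trace, t, x) {
  if (!is.na(trace$tau_D)) abort("trace_close: trace already closed")
  trace <- trace_append(trace, t, x)
  trace$tau_D <- t
  trace
}

#' Chemokine concentration and gradient at arbitrary points
#'
#' Superposes, over every live trace and every retained dead trace, the
#' trapezoidal-rule integral of \eqn{\gamma K(\lVert x - x_j(s)\rVert, t-s)}
#' along the recorded trajectory. Three published economies are applied:
#' dead traces are skipped entirely once `t - tau_D >= t_tilde` (their
#' contribution decays monotonically to zero); history older than
#' `t - t_star` is replaced by [tail_integral()]'s closed form; and no node is
#' evaluated at `s = t` (the most recent node is the last recorded sample).
#' Evaluations closer than `eps_r` to a source sample are clamped to `eps_r`.
#'
#' @param x Evaluation point(s): a numeric vector of length `dim` or a matrix
#'   with one point per row.
#' @param t Evaluation time (s).
#' @param traces List of `source_trace` objects.
#' @param field Field parameter list (see [default_config()]`$field`).
#' @param dim Spatial dimension, 2 or 3.
#' @return `chemokine_concentration()`: numeric vector, one value per point.
#'   `chemokine_gradient()`: matrix of gradients, one row per point.
#' @export
chemokine_concentration <- function(x, t, traces, field, dim) {
  x <- as_points(x, dim)
  out <- numeric(nrow(x))
  for (tr in traces) {
    out <- out + trace_contribution(x, t, tr, field, dim, gradient = FALSE)
  }
  out
}

#' @rdname chemokine_concentration
#' @export
chemokine_gradient <- function(x, t, traces, field, dim) {
  x <- as_points(x, dim)
  out <- matrix(0, nrow(x), dim)
  for (tr in traces) {
    out <- out + trace_contribution(x, t, tr, field, dim, gradient = TRUE)
  }
  out
}

as_points <- function(x, dim) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == dim)
    x
  } else {
    matrix(x, ncol = dim, byrow = TRUE)
  }
}

# concentration (or gradient) at points `x` due to one trace
trace_contribution <- function(x, t, tr, field, dim, gradient = FALSE) {
  zero <- if (gradient) matrix(0, nrow(x), dim) else numeric(nrow(x))
  dead <- !is.na(tr$tau_D)
  if (dead && t - tr$tau_D >= field$t_tilde) return(zero)
  if (t <= tr$tau_B) return(zero)

  keep <- tr$times <= t
  times <- tr$times[keep]
  pos <- tr$pos[keep, , drop = FALSE]
  if (!length(times)) return(zero)

  out <- zero
  s_cut <- t - field$t_star

  # closed-form tail for history older than t - t_star (no spatial factor,
  # hence no gradient contribution)
  if (!gradient && times[1] < s_cut) {
    s1 <- min(s_cut, times[length(times)])
    out <- out + tail_integral_range(t, times[1], s1, field$gamma, field$D, dim)
  }
  recent <- times >= s_cut
  if (sum(recent) < 2) return(out)
  times <- times[recent]
  pos <- pos[recent, , drop = FALSE]

  # pairwise distances: points x (rows) vs trace samples (rows of pos)
  tau <- t - times                                  # m lags
  dx <- array(0, c(nrow(x), length(times), dim))
  for (k in seq_len(dim)) {
    dx[, , k] <- outer(x[, k], pos[, k], `-`)
  }
  r2 <- matrix(0, nrow(x), length(times))
  for (k in seq_len(dim)) r2 <- r2 + dx[, , k]^2
  clamp <- r2 < field$eps_r^2
  if (any(clamp)) {
    warn("chemokine evaluation clamped to eps_r near an active source")
    r2[clamp] <- field$eps_r^2
  }
  taum <- matrix(tau, nrow(x), length(times), byrow = TRUE)
  K <- matrix(0, nrow(x), length(times))
  posl <- taum > 0
  K[posl] <- exp(-r2[posl] / (4 * field$D * taum[posl])) /
    (4 * pi * field$D * taum[posl])^(dim / 2)

  w <- trapezoid_weights(times)
  if (!gradient) {
    out + field$gamma * drop(K %*% w)
  } else {
    # grad_x K = -K (x - x_j(s)) / (2 D tau)
    g <- matrix(0, nrow(x), dim)
    fac <- K / (2 * field$D * taum)
    fac[!posl] <- 0
    for (k in seq_len(dim)) {
      g[, k] <- -field$gamma * drop((fac * dx[, , k]) %*% w)
    }
    out + g
  }
}

trapezoid_weights <- function(s) {
  m <- length(s)
  if (m < 2) return(rep(0, m))
  d <- diff(s)
  w <- numeric(m)
  w[1] <- d[1] / 2
  w[m] <- d[m - 1] / 2
  if (m > 2) w[2:(m - 1)] <- (d[-1] + d[-(m - 1)]) / 2
  w
}
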