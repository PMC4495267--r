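# Time stepping. Each step, in fixed order: (1) refresh source traces;
# (2) mechanics on the pre-move configuration; (3) chemokine field at the
# T-cells and vessel points; (4) motion: RK4 on the deterministic drift with
# the noise and the chemokine gradient frozen across substeps, plus the
# Maruyama noise increment, under the quarter-diameter displacement cap;
# (5) cycle events (growth, S-exit, division + mutation, death);
# (6) immune events (extravasation, engulfment); (7) intravasation checks;
# (8) boundary projection. Single-threaded and fully determined by the seed.

new_cell_rows <- function(ids, phenotype, pos, R, phase, phase_age,
                          birth_time, F) {
  d <- ncol(pos)
  out <- tibble::tibble(
    id = as.integer(ids),
    phenotype = phenotype,
    x = pos[, 1],
    y = pos[, 2]
  )
  if (d == 3) out$z <- pos[, 3]
  out$R <- R
  out$phase <- phase
  out$phase_age <- phase_age
  out$birth_time <- birth_time
  out$F <- F
  out
}

ph_vec <- function(config, phenotype, field) {
  tab <- vapply(config$phenotypes, function(p) p[[field]], numeric(1))
  unname(tab[phenotype])
}

#' Initialize the simulation state
#'
#' Fills the disc (2D) or ball (3D) of the configured radius with
#' non-overlapping epithelial cells by random sequential placement followed
#' by contact-relaxation sweeps, places the vessel points on the boundary,
#' and (optionally) converts the `engine$initial_tumor` cells nearest the
#' center into tumor cells with open source traces. Unless
#' `engine$synchronized_start` is set, cells start in G1 with a uniformly
#' random phase age (with the matching radius), which desynchronizes the
#' first division wave.
#'
#' @param config A validated `oncosim_config`.
#' @return An `oncosim_state` list: time, cell tibble, trace store, vessel
#'   points, counters and event log.
#' @export
initialize_state <- function(config) {
  validate_config(config)
  dm <- config$domain
  en <- config$engine
  dimn <- dm$dim
  Rd <- dm$radius
  pe <- config$phenotypes$epithelial

  # cells start at radius R0; phase ages are desynchronized unless asked
  n <- max(1L, floor(en$packing_fraction * (Rd / pe$R0)^dimn))
  ages <- if (en$synchronized_start) numeric(n) else runif(n, 0, pe$T_G1)
  radii <- rep(pe$R0, n)

  # random sequential placement (uniform in the admissible ball)
  P <- matrix(0, n, dimn)
  for (i in seq_len(n)) {
    u <- random_unit_vector(dimn)
    P[i, ] <- u * (Rd - radii[i]) * runif(1)^(1 / dimn)
  }
  P <- relax_packing(P, radii, Rd, tol = 1e-3 * pe$R0)

  cells <- new_cell_rows(seq_len(n), rep("epithelial", n), P, radii,
                         rep("G1", n), ages, rep(0, n), rep(pe$F, n))

  traces <- list()
  k <- min(en$initial_tumor, n)
  if (k > 0) {
    pt <- config$phenotypes$tumor
    ctr <- order(sqrt(rowSums(P^2)))[seq_len(k)]
    cells$phenotype[ctr] <- "tumor"
    cells$F[ctr] <- pt$F
    cells$R[ctr] <- pt$R0
    cells$phase_age[ctr] <- if (en$synchronized_start) 0 else
      runif(k, 0, pt$T_G1)
    for (i in ctr) {
      traces[[as.character(cells$id[i])]] <-
        trace_new(cells$id[i], 0, P[i, ])
    }
  }

  structure(
    list(
      t = 0,
      dim = dimn,
      cells = cells,
      traces = traces,
      vessels = vessel_points(dm),
      next_id = n + 1L,
      counters = list(divisions = 0L, mutations = 0L, deaths = 0L,
                      intravasations = 0L, seedings = 0L,
                      tcell_entries = 0L, engulfments = 0L,
                      displacement_clamps = 0L),
      events = list(),
      config = config
    ),
    class = "oncosim_state"
  )
}

# Push overlapping cells apart (and back inside the wall) until the largest
# pairwise overlap is below tol. The radii are grown in stages from 70% of
# their target so the packing relaxes instead of jamming.
relax_packing <- function(P, R, Rd, tol, omega = 1.5, max_sweeps = 4000L) {
  n <- nrow(P)
  d <- ncol(P)
  if (n == 1) return(P)
  converged <- FALSE
  for (sc in seq(0.7, 1, by = 0.05)) {
    Rs <- R * sc
    for (s in seq_len(max_sweeps)) {
      dm <- as.matrix(stats::dist(P))
      ov <- outer(Rs, Rs, `+`) - dm
      diag(ov) <- 0
      ov[ov < 0] <- 0
      rad <- sqrt(rowSums(P^2))
      wov <- pmax(0, rad - (Rd - Rs))
      converged <- max(ov) < tol && max(wov) < tol
      if (converged) break
      inv <- 1 / dm
      diag(inv) <- 0
      inv[!is.finite(inv)] <- 0
      W <- omega * ov / 4 * inv
      for (k in seq_len(d)) {
        dxk <- outer(P[, k], P[, k], function(a, b) b - a)
        P[, k] <- P[, k] - rowSums(W * dxk)
      }
      rad <- sqrt(rowSums(P^2))
      out <- rad > (Rd - Rs)
      if (any(out)) {
        P[out, ] <- P[out, , drop = FALSE] * ((Rd - Rs[out]) / rad[out])
      }
    }
  }
  if (!converged) {
    abort("initial packing failed to relax; lower engine$packing_fraction")
  }
  P
}

#' Adaptive time step from the quarter-diameter rule
#'
#' The step is limited so that the predicted displacement of every cell --
#' its current drift speed plus a 3-sigma random-walk allowance -- stays
#' below a quarter of its diameter (R/2).
#'
#' @param speeds Current drift speeds (um/s).
#' @param R Cell radii (um).
#' @param engine Engine parameter list (`dt_max`, `dt_min`, `sigma`).
#' @return Time step (s).
#' @export
compute_dt <- function(speeds, R, engine) {
  if (!length(speeds)) return(engine$dt_max)
  allowance <- 3 * engine$sigma / sqrt(engine$dt_max)
  dt <- min(engine$dt_max, (R / 2) / (speeds + allowance + 1e-12))
  max(engine$dt_min, dt)
}

#' Classical fourth-order Runge-Kutta step for an autonomous field
#'
#' @param x State (numeric vector or matrix of positions).
#' @param dt Step size.
#' @param f Velocity field, `f(x)` returning an object shaped like `x`.
#' @return Updated state.
#' @export
rk4_step <- function(x, dt, f) {
  k1 <- f(x)
  k2 <- f(x + dt / 2 * k1)
  k3 <- f(x + dt / 2 * k2)
  k4 <- f(x + dt * k3)
  x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

# deterministic drift of every cell at positions P (frozen gradient term)
drift_field <- function(P, R, F, alpha, mphase, chemo_add, config, vessels) {
  mf <- mech_field(P, R, F, mphase, config$mech, config$domain, vessels)
  zn <- sqrt(rowSums(mf$z^2))
  zhat <- mf$z / ifelse(zn > 0, zn, 1)
  v <- alpha * mf$M * zhat
  if (!is.null(chemo_add)) v <- v + chemo_add
  # cap the active drift speed
  sp <- sqrt(rowSums(v^2))
  over <- sp > config$engine$v_max
  if (any(over)) v[over, ] <- v[over, , drop = FALSE] *
      (config$engine$v_max / sp[over])
  v
}

log_event <- function(state, event, cell_id = NA_integer_,
                      vessel_index = NA_integer_) {
  state$events[[length(state$events) + 1L]] <-
    list(time = state$t, event = event, cell_id = as.integer(cell_id),
         vessel_index = as.integer(vessel_index))
  state
}

#' Advance the simulation by one adaptive step
#'
#' @param state An `oncosim_state`.
#' @param config Configuration (defaults to the one stored in the state).
#' @return The updated state; the realized step size is available as
#'   `attr(, "dt")`.
#' @export
sim_step <- function(state, config = state$config) {
  en <- config$engine
  fdp <- config$field
  im <- config$immune
  dimn <- state$dim
  cells <- state$cells
  n <- nrow(cells)
  if (n == 0) {
    state$t <- state$t + en$dt_max
    attr(state, "dt") <- en$dt_max
    return(state)
  }

  # (1) refresh trace samples of live tumor cells at the quadrature cadence
  for (id in names(state$traces)) {
    tr <- state$traces[[id]]
    if (!is.na(tr$tau_D)) next
    if (state$t - tr$times[length(tr$times)] >= fdp$dt_quad - 1e-9) {
      i <- match(as.integer(id), cells$id)
      if (!is.na(i)) {
        state$traces[[id]] <-
          trace_append(tr, state$t, cell_positions(cells)[i, ])
      }
    }
  }

  P <- cell_positions(cells)
  mphase <- cells$phase == "M"
  alpha <- mobility_alpha(cells$F, config$mech$F_hat,
                          ph_vec(config, cells$phenotype, "beta"),
                          cells$R, config$mech$f)

  # (2) mechanics on the pre-move configuration
  mf0 <- mech_field(P, cells$R, cells$F, mphase, config$mech,
                    config$domain, state$vessels)

  # (3) chemokine field: concentration at vessel points, gradient at T-cells
  have_traces <- length(state$traces) > 0
  c_vessels <- if (have_traces && nrow(state$vessels)) {
    chemokine_concentration(state$vessels, state$t, state$traces, fdp, dimn)
  } else {
    rep(0, nrow(state$vessels))
  }
  is_tcell <- cells$phenotype == "tcell"
  chemo_add <- NULL
  if (any(is_tcell) && have_traces) {
    gc <- chemokine_gradient(P[is_tcell, , drop = FALSE], state$t,
                             state$traces, fdp, dimn)
    chemo_add <- matrix(0, n, dimn)
    chemo_add[is_tcell, ] <- im$mu_factor * alpha[is_tcell] * gc
  }

  # (4) motion: RK4 drift + Maruyama noise under the displacement cap
  vel <- function(Q) drift_field(Q, cells$R, cells$F, alpha, mphase,
                                 chemo_add, config, state$vessels)
  v0 <- vel(P)
  dt <- compute_dt(sqrt(rowSums(v0^2)), cells$R, en)
  Z <- matrix(rnorm(n * dimn), n, dimn)
  Z[mphase, ] <- 0  # M-phase cells: contact drift only, no random walk
  for (attempt in 1:6) {
    Pdet <- rk4_step(P, dt, vel)
    disp <- Pdet - P + en$sigma * sqrt(dt) * Z
    dnorm_ <- sqrt(rowSums(disp^2))
    cap <- cells$R / 2
    if (all(dnorm_ <= cap) || dt <= en$dt_min) break
    dt <- max(en$dt_min, dt / 2)
  }
  over <- dnorm_ > cap
  if (any(over)) {
    disp[over, ] <- disp[over, , drop = FALSE] * (cap[over] / dnorm_[over])
    state$counters$displacement_clamps <-
      state$counters$displacement_clamps + sum(over)
  }
  P <- P + disp
  t_new <- state$t + dt

  # (8a) boundary projection for any center that left the domain
  rad <- sqrt(rowSums(P^2))
  outside <- rad > config$domain$radius
  if (any(outside)) {
    P[outside, ] <- P[outside, , drop = FALSE] *
      ((config$domain$radius - cells$R[outside]) / rad[outside])
  }
  cells$x <- P[, 1]; cells$y <- P[, 2]
  if (dimn == 3) cells$z <- P[, 3]

  # (5) cycle events, using the pre-move pressures
  p <- mf0$p
  mc <- config$mech
  dividing <- ph_vec_l(config, cells$phenotype, "can_divide")

  kap <- vapply(config$phenotypes, function(q) {
    if ((q$T_G1 + q$T_G2) > 0) growth_constant(q) else 0
  }, numeric(1))
  kv <- unname(kap[cells$phenotype])
  grow <- cells$phase %in% c("G1", "G2")
  noise <- if (en$sigma_g > 0) en$sigma_g * sqrt(dt) * rnorm(n) else 0
  Rnew <- cells$R + as.numeric(grow) * kv * dt +
    as.numeric(cells$phase != "none") * noise
  cells$R <- pmin(pmax(Rnew, ph_vec(config, cells$phenotype, "R0")),
                  ph_vec(config, cells$phenotype, "R_max"))

  cells$phase_age <- cells$phase_age + dt
  tg1 <- ph_vec(config, cells$phenotype, "T_G1")
  adv <- dividing & cells$phase == "G1" & cells$phase_age >= tg1
  cells$phase[adv] <- "S"
  cells$phase_age[adv] <- cells$phase_age[adv] - tg1[adv]

  inS <- dividing & cells$phase == "S"
  if (any(inS)) {
    ts <- ph_vec(config, cells$phenotype, "T_S")
    pr <- numeric(n)
    pr[inS] <- ifelse(ts[inS] <= 0, 1,
                      pmin(1, dt / ts[inS] *
                             pressure_growth_factor(p[inS], mc$c1, mc$c2, mc$c3)))
    exit <- inS & runif(n) < pr
    cells$phase[exit] <- "G2"
    cells$phase_age[exit] <- 0
  }

  tg2 <- ph_vec(config, cells$phenotype, "T_G2")
  adv <- dividing & cells$phase == "G2" & cells$phase_age >= tg2
  cells$phase[adv] <- "M"
  cells$phase_age[adv] <- cells$phase_age[adv] - tg2[adv]

  # division + mutation
  tm <- ph_vec(config, cells$phenotype, "T_M")
  mothers <- which(dividing & cells$phase == "M" & cells$phase_age >= tm)
  if (length(mothers)) {
    Pn <- cell_positions(cells)
    daughters <- list()
    for (i in mothers) {
      ph <- cells$phenotype[i]
      pp <- config$phenotypes[[ph]]
      geom <- divide_cell(Pn[i, ], pp$R0, dimn)
      cells$x[i] <- geom$x1[1]; cells$y[i] <- geom$x1[2]
      if (dimn == 3) cells$z[i] <- geom$x1[3]
      cells$R[i] <- pp$R0
      cells$phase[i] <- "G1"
      cells$phase_age[i] <- 0
      did <- state$next_id
      state$next_id <- state$next_id + 1L
      dph <- ph
      if (ph == "epithelial" && maybe_mutate(1, im$P_M)) {
        dph <- "tumor"
        state$counters$mutations <- state$counters$mutations + 1L
        state <- log_event(state, "mutation", did)
      }
      daughters[[length(daughters) + 1L]] <- new_cell_rows(
        did, dph, matrix(geom$x2, 1), config$phenotypes[[dph]]$R0,
        "G1", 0, t_new, config$phenotypes[[dph]]$F
      )
      if (dph == "tumor") {
        state$traces[[as.character(did)]] <- trace_new(did, t_new, geom$x2)
      }
      if (ph == "tumor") {
        # the mother's trace continues from its new position
        tr <- state$traces[[as.character(cells$id[i])]]
        if (!is.null(tr) && is.na(tr$tau_D)) {
          state$traces[[as.character(cells$id[i])]] <-
            trace_append(tr, t_new, geom$x1)
        }
      }
      state$counters$divisions <- state$counters$divisions + 1L
      state <- log_event(state, "division", cells$id[i])
    }
    cells <- dplyr::bind_rows(cells, dplyr::bind_rows(daughters))
    n <- nrow(cells)
    p <- c(p, rep(0, n - length(p)))  # newborns carry no accumulated pressure
  }

  # death, all phenotypes, pressure response per engine$death_response
  tc <- ph_vec(config, cells$phenotype, "T_C")
  t2 <- ph_vec(config, cells$phenotype, "T_2")
  pd <- switch(en$death_response,
    off = death_prob(dt, tc, t2),
    raw = death_prob(dt, tc, t2, p, mc$c4, mc$c5),
    normalized = death_prob(dt, tc, t2, p, mc$c4, mc$c5, normalize = TRUE)
  )
  dies <- runif(n) < pd
  if (any(dies)) {
    state$counters$deaths <- state$counters$deaths + sum(dies)
    Pn <- cell_positions(cells)
    for (i in which(dies)) {
      state <- close_trace_if_open(state, cells$id[i], t_new, Pn[i, ])
      state <- log_event(state, "death", cells$id[i])
    }
    cells <- cells[!dies, , drop = FALSE]
    p <- p[!dies]
    n <- nrow(cells)
  }

  # (6) immune events: extravasation at each vessel point, then engulfment
  if (nrow(state$vessels)) {
    for (vi in seq_len(nrow(state$vessels))) {
      if (runif(1) < extravasation_prob(c_vessels[vi], dt, im$A, im$B)) {
        pos <- place_tcell(state$vessels[vi, ], config$domain, im$R_tcell,
                           cells)
        if (!is.null(pos)) {
          tid <- state$next_id
          state$next_id <- state$next_id + 1L
          cells <- dplyr::bind_rows(
            cells,
            new_cell_rows(tid, "tcell", matrix(pos, 1), im$R_tcell,
                          "none", 0, t_new, config$phenotypes$tcell$F)
          )
          p <- c(p, 0)
          n <- n + 1L
          state$counters$tcell_entries <- state$counters$tcell_entries + 1L
          state <- log_event(state, "tcell_entry", tid, vi)
        }
      }
    }
  }
  tcells <- which(cells$phenotype == "tcell")
  if (length(tcells)) {
    gone <- integer(0)
    Pn <- cell_positions(cells)
    for (i in tcells) {
      eaten <- setdiff(engulfed_indices(cells, i), gone)
      for (j in eaten) {
        state <- close_trace_if_open(state, cells$id[j], t_new, Pn[j, ])
        state <- log_event(state, "engulfment", cells$id[j])
      }
      gone <- c(gone, eaten)
    }
    if (length(gone)) {
      state$counters$engulfments <- state$counters$engulfments + length(gone)
      cells <- cells[-gone, , drop = FALSE]
      p <- p[-gone]
      n <- nrow(cells)
    }
  }

  # (7) intravasation: vessel contact plus the strain-energy criterion
  tum <- which(cells$phenotype == "tumor")
  if (length(tum) && nrow(state$vessels)) {
    Pn <- cell_positions(cells)
    mfn <- mech_field(Pn, cells$R, cells$F, cells$phase == "M",
                      config$mech, config$domain, state$vessels)
    dvmin <- apply(Pn[tum, , drop = FALSE], 1, function(q) {
      min(sqrt(rowSums(sweep(state$vessels, 2, q)^2)))
    })
    hit <- intravasation_criterion(mfn$M_sens[tum], dvmin, cells$R[tum],
                                   config$domain$R_b, config$mech$M_b_star)
    if (any(hit)) {
      gone <- tum[hit]
      for (i in gone) {
        state <- close_trace_if_open(state, cells$id[i], t_new, Pn[i, ])
        state$counters$intravasations <- state$counters$intravasations + 1L
        state <- log_event(state, "intravasation", cells$id[i])
        if (runif(1) < im$P_S) {
          state$counters$seedings <- state$counters$seedings + 1L
          state <- log_event(state, "seeding", cells$id[i])
        }
      }
      cells <- cells[-gone, , drop = FALSE]
    }
  }

  state$cells <- cells
  state$t <- t_new
  attr(state, "dt") <- dt
  state
}

close_trace_if_open <- function(state, id, t, x) {
  key <- as.character(id)
  tr <- state$traces[[key]]
  if (!is.null(tr) && is.na(tr$tau_D)) {
    state$traces[[key]] <- trace_close(tr, t, x)
  }
  state
}

ph_vec_l <- function(config, phenotype, field) {
  tab <- vapply(config$phenotypes, function(p) p[[field]], logical(1))
  unname(tab[phenotype])
}

counts_row <- function(state) {
  ph <- state$cells$phenotype
  ne <- sum(ph == "epithelial")
  nt <- sum(ph == "tumor")
  nw <- sum(ph == "tcell")
  tot <- ne + nt + nw
  tibble::tibble(
    t = state$t,
    n_epithelial = ne, n_tumor = nt, n_tcell = nw,
    tumor_fraction = if (tot > 0) nt / tot else 0,
    cum_intravasated = state$counters$intravasations
  )
}

#' Run a simulation
#'
#' Validates the configuration, seeds the generator, initializes the state
#' and steps until `engine$t_end` is reached, the tumor fraction hits
#' `engine$stop_fraction`, or the tissue is empty. Identical configuration
#' and seed give bit-identical outputs.
#'
#' @param config An `oncosim_config`.
#' @param seed Integer seed (defaults to `config$seed`).
#' @param verbose Print a progress line every ~50 steps.
#' @return An `oncosim_sim` object with elements `counts` (tibble time
#'   series), `events` (tibble event log), `state` (final `oncosim_state`),
#'   `config` and `seed`. Supports [tidy()], [glance()] and
#'   [ggplot2::autoplot()].
#' @export
sim_run <- function(config = default_config(), seed = config$seed,
                    verbose = FALSE) {
  validate_config(config)
  set.seed(seed)
  state <- initialize_state(config)
  sim_loop(state, config, seed = seed, verbose = verbose)
}

# shared stepping loop for fresh and resumed runs
sim_loop <- function(state, config = state$config, seed = NA_integer_,
                     verbose = FALSE) {
  en <- config$engine
  counts <- list(counts_row(state))
  last_rec <- state$t
  step <- 0L
  while (state$t < en$t_end) {
    state <- sim_step(state, config)
    step <- step + 1L
    if (state$t - last_rec >= en$counts_every - 1e-9) {
      counts[[length(counts) + 1L]] <- counts_row(state)
      last_rec <- state$t
    }
    cr <- counts_row(state)
    if (cr$tumor_fraction >= en$stop_fraction) break
    if (nrow(state$cells) == 0L) break
    if (nrow(state$cells) > en$max_cells) {
      warn("cell count exceeded engine$max_cells; stopping early")
      break
    }
    if (verbose && step %% 50L == 0L) {
      message(sprintf("t = %.1f s, cells = %d (tumor %d, tcell %d)",
                      state$t, nrow(state$cells), cr$n_tumor, cr$n_tcell))
    }
  }
  final <- counts_row(state)
  if (counts[[length(counts)]]$t < state$t) {
    counts[[length(counts) + 1L]] <- final
  }
  ev <- if (length(state$events)) {
    dplyr::bind_rows(lapply(state$events, tibble::as_tibble))
  } else {
    tibble::tibble(time = numeric(0), event = character(0),
                   cell_id = integer(0), vessel_index = integer(0))
  }
  structure(
    list(counts = dplyr::bind_rows(counts), events = ev, state = state,
         config = config, seed = seed),
    class = "oncosim_sim"
  )
}

#' @export
print.oncosim_state <- function(x, ...) {
  cat(sprintf("<oncosim_state> t = %.2f s, %d cells (%s)\n", x$t,
              nrow(x$cells),
              paste(sprintf("%s %d", PHENOTYPES,
                            vapply(PHENOTYPES,
                                   function(p) sum(x$cells$phenotype == p),
                                   integer(1))), collapse = ", ")))
  invisible(x)
}

#' @export
print.oncosim_sim <- function(x, ...) {
  fin <- x$counts[nrow(x$counts), ]
  cat(sprintf("<oncosim_sim> %d counts rows to t = %.2f s (seed %d)\n",
              nrow(x$counts), fin$t, x$seed))
  cat(sprintf("  final: %d epithelial, %d tumor, %d T-cells, tumor fraction %.3f\n",
              fin$n_epithelial, fin$n_tumor, fin$n_tcell, fin$tumor_fraction))
  cat(sprintf("  cumulative: %d divisions, %d mutations, %d deaths, %d intravasations\n",
              x$state$counters$divisions, x$state$counters$mutations,
              x$state$counters$deaths, x$state$counters$intravasations))
  invisible(x)
}
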