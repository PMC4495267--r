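small_config <- function(...) {
  default_config(
    domain = list(radius = 15),
    engine = list(t_end = 10, dt_max = 1, counts_every = 1),
    ...
  )
}

test_that("the adaptive step honors the quarter-diameter rule", {
  en <- list(dt_max = 2, dt_min = 1e-3, sigma = 0)
  expect_equal(compute_dt(numeric(0), numeric(0), en), 2)
  expect_equal(compute_dt(c(0, 0), c(3, 3), en), 2)
  # a cell predicted to move a half diameter in dt_max halves the step
  expect_equal(compute_dt(3 / 2, 3, en), 1, tolerance = 1e-9)
  # the noise allowance shrinks the step even at zero drift
  en$sigma <- 0.5
  expect_lt(compute_dt(0, 3, en), 2)
  expect_gte(compute_dt(1e9, 3, en), en$dt_min)
})

test_that("RK4 is exact for constant drift and fourth-order accurate", {
  # constant drift: no integration error at any step size
  f_const <- function(x) matrix(c(1, -2), nrow(x), 2, byrow = TRUE)
  x0 <- matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE)
  expect_equal(rk4_step(x0, 3.7, f_const), x0 + 3.7 * matrix(c(1, -2), 2, 2, byrow = TRUE))
  # manufactured smooth field dx/dt = -x: global error drops ~16x per halving
  integrate_to <- function(dt) {
    x <- 1
    for (i in seq_len(round(1 / dt))) x <- rk4_step(x, dt, function(y) -y)
    x
  }
  e1 <- abs(integrate_to(0.1) - exp(-1))
  e2 <- abs(integrate_to(0.05) - exp(-1))
  e3 <- abs(integrate_to(0.025) - exp(-1))
  expect_gt(e1 / e2, 12); expect_lt(e1 / e2, 20)
  expect_gt(e2 / e3, 12); expect_lt(e2 / e3, 20)
})

test_that("initialization fills the disc per the published setup", {
  cfg <- default_config()
  withr::with_seed(2, st <- initialize_state(cfg))
  n <- nrow(st$cells)
  expect_gte(n, 100)
  expect_lte(n, 160)
  expect_true(all(st$cells$phenotype == "epithelial"))
  expect_true(all(st$cells$phase == "G1"))
  expect_true(all(st$cells$phase_age >= 0 & st$cells$phase_age <= 300))
  # no overlaps beyond tolerance, everything inside the domain
  P <- cbind(st$cells$x, st$cells$y)
  dm <- as.matrix(dist(P))
  ov <- outer(st$cells$R, st$cells$R, `+`) - dm
  diag(ov) <- 0
  expect_lt(max(ov), 1e-3 * 3 + 1e-9)
  expect_true(all(sqrt(rowSums(P^2)) <= cfg$domain$radius - st$cells$R + 1e-6))
  expect_identical(nrow(st$vessels), 4L)
  # seeded tumor cells cluster at the center and carry open traces
  cfg2 <- default_config(engine = list(initial_tumor = 6L))
  withr::with_seed(2, st2 <- initialize_state(cfg2))
  tum <- st2$cells$phenotype == "tumor"
  expect_identical(sum(tum), 6L)
  expect_length(st2$traces, 6L)
  expect_true(all(vapply(st2$traces, function(tr) is.na(tr$tau_D), logical(1))))
  expect_lt(max(sqrt(rowSums(cbind(st2$cells$x, st2$cells$y)[tum, ]^2))),
            mean(sqrt(rowSums(P^2))))
})

test_that("identical seed and config give bit-identical runs", {
  cfg <- small_config(engine = list(initial_tumor = 3L, t_end = 8))
  a <- sim_run(cfg, seed = 42)
  b <- sim_run(cfg, seed = 42)
  expect_identical(a$counts, b$counts)
  expect_identical(a$events, b$events)
  expect_identical(a$state$cells, b$state$cells)
  c <- sim_run(cfg, seed = 43)
  expect_false(identical(a$state$cells, c$state$cells))
})

test_that("per-step displacements never exceed a quarter diameter", {
  cfg <- small_config(engine = list(initial_tumor = 4L, t_end = 10))
  set.seed(9)
  st <- initialize_state(cfg)
  for (k in 1:12) {
    before <- st$cells
    st <- sim_step(st)
    common <- intersect(before$id, st$cells$id)
    # only cells that did not divide this step keep their pre-step radius cap
    i0 <- match(common, before$id)
    i1 <- match(common, st$cells$id)
    moved <- sqrt((before$x[i0] - st$cells$x[i1])^2 +
                    (before$y[i0] - st$cells$y[i1])^2)
    fresh <- st$cells$phase_age[i1] < attr(st, "dt") - 1e-12
    expect_true(all(moved[!fresh] <= before$R[i0][!fresh] / 2 + 1e-9))
  }
})

test_that("phenotype bookkeeping and containment hold along a run", {
  cfg <- small_config(engine = list(initial_tumor = 4L, t_end = 12))
  sim <- sim_run(cfg, seed = 5)
  ct <- sim$counts
  expect_true(all(ct$n_epithelial + ct$n_tumor + ct$n_tcell >= 0))
  expect_true(all(diff(ct$cum_intravasated) >= 0))
  expect_true(all(abs(ct$tumor_fraction * (ct$n_epithelial + ct$n_tumor + ct$n_tcell)
                      - ct$n_tumor) < 1e-9))
  st <- sim$state
  expect_true(all(sqrt(st$cells$x^2 + st$cells$y^2) <= cfg$domain$radius + 1e-9))
  # every live tumor cell has exactly one open trace; closed traces immutable
  tum_ids <- st$cells$id[st$cells$phenotype == "tumor"]
  for (id in tum_ids) {
    tr <- st$traces[[as.character(id)]]
    expect_false(is.null(tr))
    expect_true(is.na(tr$tau_D))
  }
  closed <- Filter(function(tr) !is.na(tr$tau_D), st$traces)
  for (tr in closed) {
    expect_lte(tr$times[length(tr$times)], tr$tau_D)
    expect_true(all(diff(tr$times) > 0))
  }
})

test_that("without tumor cells the immune loop stays closed", {
  cfg <- small_config(engine = list(t_end = 15), immune = list(P_M = 0))
  sim <- sim_run(cfg, seed = 8)
  expect_true(all(sim$counts$n_tumor == 0))
  expect_true(all(sim$counts$n_tcell == 0))
  expect_length(sim$state$traces, 0)
  cv <- chemokine_concentration(sim$state$vessels, sim$state$t,
                                sim$state$traces, cfg$field, 2)
  expect_equal(cv, rep(0, 4))
})

test_that("the engine also runs in three dimensions", {
  cfg <- default_config(
    dim = 3,
    domain = list(radius = 12),
    engine = list(t_end = 3, initial_tumor = 2L, packing_fraction = 0.4)
  )
  sim <- sim_run(cfg, seed = 4)
  st <- sim$state
  expect_true("z" %in% names(st$cells))
  expect_identical(nrow(st$vessels), 6L)
  expect_true(all(sqrt(st$cells$x^2 + st$cells$y^2 + st$cells$z^2) <=
                    cfg$domain$radius + 1e-9))
  expect_gt(nrow(sim$counts), 1)
})

test_that("a run stops once the tumor fraction reaches the stop threshold", {
  # tiny tissue where seeded tumor cells are already at the threshold
  cfg <- default_config(
    domain = list(radius = 9),
    engine = list(t_end = 50, initial_tumor = 4L, stop_fraction = 0.4,
                  packing_fraction = 0.5)
  )
  sim <- sim_run(cfg, seed = 21)
  fin <- sim$counts[nrow(sim$counts), ]
  expect_true(fin$tumor_fraction >= 0.4 || fin$t >= 50 ||
                nrow(sim$state$cells) == 0)
  if (fin$tumor_fraction >= 0.4) expect_lt(fin$t, 50)
})
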