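test_that("heat kernel has the right values, limits and normalization", {
  expect_equal(kernel_value(0, 1, 100, 2), 1 / (400 * pi))
  expect_equal(kernel_value(5, 1e-12, 100, 2), 0)
  expect_equal(kernel_value(5, 0, 100, 3), 0)
  expect_error(kernel_value(0, 0, 100, 2), "singular")

  # unit mass at any positive lag, by radial quadrature
  for (tau in c(0.5, 5)) {
    r <- seq(0, 300, by = 0.05)
    k2 <- kernel_value(r, tau, 100, 2)
    expect_equal(pracma::trapz(r, k2 * 2 * pi * r), 1, tolerance = 1e-4)
    k3 <- kernel_value(r, tau, 100, 3)
    expect_equal(pracma::trapz(r, k3 * 4 * pi * r^2), 1, tolerance = 1e-4)
  }
})

test_that("long-time tail matches its closed forms and contract", {
  fld <- field_params(t_star = 1)
  expect_equal(tail_integral(2, 1, fld, 2), 0)                 # log(1)
  expect_equal(tail_integral(1 + exp(1), 1, fld, 2), 2 / (400 * pi))
  # 3D published limit as t - tau_B -> infinity
  expect_equal(tail_integral(1e12, 0, fld, 3),
               fld$gamma / (2 * pi * fld$D * sqrt(fld$t_star)),
               tolerance = 1e-5)
  expect_error(tail_integral(1.5, 1, fld, 2), "t_star")
})

test_that("a stationary 3D source reaches the diffusive steady state", {
  # gamma / (4 pi D r), checked against the trace quadrature at long time
  D <- 100; g <- 2; r <- 10; t_end <- 2e4
  tr <- trace_new(1L, 0, c(0, 0, 0))
  for (s in seq(5, t_end - 10, by = 5)) tr <- trace_append(tr, s, c(0, 0, 0))
  for (s in seq(t_end - 10 + 0.01, t_end, by = 0.01)) {
    tr <- trace_append(tr, s, c(0, 0, 0))
  }
  fld <- field_params()
  cc <- chemokine_concentration(c(r, 0, 0), t_end, list(tr), fld, 3)
  expect_equal(cc, g / (4 * pi * D * r), tolerance = 0.01)
})

test_that("gradients agree with finite differences and with symmetry", {
  # two sources with linear motion
  fld <- field_params()
  t1 <- seq(0, 50, by = 0.5)
  tr1 <- trace_new(1L, 0, c(0, 0))
  for (s in t1[-1]) tr1 <- trace_append(tr1, s, c(0.1 * s, 0))
  tr2 <- trace_new(2L, 0, c(30, 10))
  for (s in t1[-1]) tr2 <- trace_append(tr2, s, c(30, 10 - 0.05 * s))
  traces <- list(tr1, tr2)
  x0 <- c(15, 18)
  g <- chemokine_gradient(x0, 50, traces, fld, 2)
  h <- 0.02
  for (k in 1:2) {
    e <- c(0, 0); e[k] <- h
    fd <- (chemokine_concentration(x0 + e, 50, traces, fld, 2) -
             chemokine_concentration(x0 - e, 50, traces, fld, 2)) / (2 * h)
    expect_equal(g[k], fd, tolerance = 1e-6)
  }

  # midpoint between two identical stationary sources: zero gradient
  trA <- trace_new(3L, 0, c(-10, 0))
  trB <- trace_new(4L, 0, c(10, 0))
  for (s in seq(1, 40)) {
    trA <- trace_append(trA, s, c(-10, 0))
    trB <- trace_append(trB, s, c(10, 0))
  }
  gm <- chemokine_gradient(c(0, 0), 40, list(trA, trB), fld, 2)
  expect_equal(drop(gm), c(0, 0), tolerance = 1e-15)

  # single stationary 3D source at long time: gamma/(4 pi D r^2) toward it
  D <- 100; g3 <- 2; r <- 12; t_end <- 2e4
  tr <- trace_new(5L, 0, c(0, 0, 0))
  for (s in seq(5, t_end - 10, by = 5)) tr <- trace_append(tr, s, c(0, 0, 0))
  for (s in seq(t_end - 10 + 0.01, t_end, by = 0.01)) {
    tr <- trace_append(tr, s, c(0, 0, 0))
  }
  gv <- chemokine_gradient(c(r, 0, 0), t_end, list(tr), fld, 3)
  expect_equal(gv[1], -g3 / (4 * pi * D * r^2), tolerance = 0.02)
  expect_equal(gv[2:3], c(0, 0))
})

test_that("no sources means no chemokine; concentration is nonnegative", {
  fld <- field_params()
  expect_equal(chemokine_concentration(c(0, 0), 10, list(), fld, 2), 0)
  tr <- trace_new(1L, 0, c(0, 0))
  for (s in seq(0.5, 20, by = 0.5)) tr <- trace_append(tr, s, c(s, 0))
  pts <- cbind(seq(-40, 40, by = 5), 3 + seq(-40, 40, by = 5))
  expect_true(all(chemokine_concentration(pts, 20, list(tr), fld, 2) >= 0))
  # evaluating on top of an active source is guarded by the eps_r clamp
  expect_warning(chemokine_concentration(c(5, 0), 20, list(tr), fld, 2),
                 "clamped")
})

test_that("a dead source's contribution decays monotonically to zero", {
  fld <- field_params(t_tilde = 150)
  tr <- trace_new(1L, 0, c(0, 0))
  for (s in seq(1, 30)) tr <- trace_append(tr, s, c(0.2 * s, 0))
  tr <- trace_close(tr, 30, c(6, 0))
  x <- c(10, 5)
  ts <- seq(31, 170, by = 3)
  cc <- vapply(ts, function(t) chemokine_concentration(x, t, list(tr), fld, 2),
               numeric(1))
  expect_true(all(diff(cc) < 0))
  # dropped entirely once t - tau_D >= t_tilde
  expect_equal(chemokine_concentration(x, 30 + 150, list(tr), fld, 2), 0)
  expect_gt(chemokine_concentration(x, 30 + 149, list(tr), fld, 2), 0)
})

test_that("trace quadrature agrees with a 1000x finer independent oracle", {
  fld <- field_params(dt_quad = 1)
  times <- seq(0, 40, by = 1)
  pos <- cbind(0.15 * times, 0.05 * times)
  tr <- trace_new(1L, 0, pos[1, ])
  for (i in 2:length(times)) tr <- trace_append(tr, times[i], pos[i, ])
  x <- c(45, 0)  # far enough that the omitted [t - dt, t] sliver is < 1%
  mine <- chemokine_concentration(x, 40, list(tr), fld, 2)
  fine <- conc_oracle(x, 40, times, pos, fld$gamma, fld$D, 2, dt_fine = 0.001)
  expect_equal(mine, fine, tolerance = 0.01)
})

test_that("halving the quadrature step converges at second order", {
  x <- c(50, 0)
  t_end <- 64
  conc_at <- function(dt) {
    times <- seq(0, t_end, by = dt)
    tr <- trace_new(1L, 0, c(0, 0))
    for (s in times[-1]) tr <- trace_append(tr, s, c(0.1 * s, 0.02 * s))
    chemokine_concentration(x, t_end, list(tr), field_params(dt_quad = dt), 2)
  }
  ref <- conc_at(0.05)
  e4 <- abs(conc_at(4) - ref)
  e1 <- abs(conc_at(1) - ref)
  # observed order over a 4x step refinement is at least 2
  expect_gt(log(e4 / e1) / log(4), 1.8)
})

test_that("total released mass equals rate times emission time", {
  # integrate c over all space: each kernel carries unit mass, so the total
  # equals gamma * (live duration), independent of the motion of the source
  fld <- field_params(dt_quad = 0.25)
  dur <- 8
  times <- seq(0, dur, by = 0.25)
  tr <- trace_new(1L, 0, c(0, 0))
  for (s in times[-1]) tr <- trace_append(tr, s, c(0.5 * s, 0))
  tr <- trace_close(tr, dur, c(0.5 * dur, 0))
  t_eval <- 12
  r <- seq(0, 250, by = 0.5)
  # angular average via a ring of evaluation points
  ang <- seq(0, 2 * pi, length.out = 13)[-13]
  ring_mean <- vapply(r, function(rr) {
    pts <- cbind(rr * cos(ang), rr * sin(ang))
    # rings near the origin intersect the source path: the eps_r clamp is
    # expected there and immaterial at this tolerance
    suppressWarnings(
      mean(chemokine_concentration(pts, t_eval, list(tr), fld, 2))
    )
  }, numeric(1))
  total <- pracma::trapz(r, ring_mean * 2 * pi * r)
  expect_equal(total, fld$gamma * dur, tolerance = 0.02)
})
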