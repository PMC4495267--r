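test_that("growth constants carry R0 to R_max over the growth phases", {
  cfg <- default_config()
  kap_e <- growth_constant(cfg$phenotypes$epithelial)
  kap_t <- growth_constant(cfg$phenotypes$tumor)
  expect_equal(kap_e, (2^(1 / 3) - 1) * 3 / 600)
  expect_equal(kap_t, (2^(1 / 3) - 1) * 3 / 20)
  degen <- cfg$phenotypes$epithelial
  degen$R_max <- degen$R0
  expect_equal(growth_constant(degen), 0)
  degen$T_G1 <- 0
  degen$T_G2 <- 0
  expect_error(growth_constant(degen), "T_G1")
})

test_that("radius growth is phase-gated, deterministic without noise, clamped", {
  cfg <- default_config()
  pe <- cfg$phenotypes$epithelial
  kap <- growth_constant(pe)
  # S phase: no deterministic growth
  expect_equal(grow_radius(3.1, "S", 1, kap, pe$R0, pe$R_max), 3.1)
  # integrating G1 for T_G1 seconds reaches half the total growth
  R <- pe$R0
  for (i in seq_len(pe$T_G1)) R <- grow_radius(R, "G1", 1, kap, pe$R0, pe$R_max)
  expect_equal(R, pe$R0 + kap * pe$T_G1)
  expect_equal(R, (pe$R0 + pe$R_max) / 2)
  # clamping at both ends
  expect_equal(grow_radius(pe$R_max, "G2", 1000, kap, pe$R0, pe$R_max), pe$R_max)
  expect_equal(grow_radius(pe$R0, "S", 1, kap, pe$R0, pe$R_max, sigma_g = 0), pe$R0)
  # zero-mean noise: the average increment is the deterministic one
  withr::with_seed(42, {
    rr <- grow_radius(rep(3.2, 2e4), "G1", 1, kap, 0, 10, sigma_g = 0.05)
    expect_equal(mean(rr - 3.2), kap, tolerance = 0.05)
  })
})

test_that("S-exit probability follows the Hill-modified geometric rule", {
  expect_equal(pressure_growth_factor(0), 1.1)
  expect_equal(transition_prob_S_to_G2(1, 400, 0), 1.1 / 400)
  expect_equal(transition_prob_S_to_G2(1, 400, 1e6), 0)
  expect_equal(transition_prob_S_to_G2(1, 0, 0), 1)   # no S phase: skip
  # mean residence of the simulated geometric law is T_S when F == 1
  withr::with_seed(7, {
    res <- simulate_s_residence(4000, dt = 1, T_S = 50)
    expect_equal(mean(res), 50, tolerance = 0.05)
  })
  # E(N) = 1 / P
  expect_equal(1 / transition_prob_S_to_G2(1, 400, 0) * 1, 400 / 1.1)
})

test_that("death probability reproduces the doubling-time calibration", {
  expect_equal(death_prob(0, 21, 4000), 0)
  expect_equal(death_prob(1, 21, 21 + 1e-9), 0, tolerance = 1e-6)
  expect_equal(death_prob(1, 21, 4000), 1 - 2^(1 / 4000 - 1 / 21))
  expect_equal(pressure_death_factor(0), 4.5)
  # survival compounds exactly across step sizes (exponent arithmetic)
  for (dt in c(1, 7, 21)) {
    pd <- death_prob(dt, 21, 4000)
    expect_equal((1 - pd)^(21 / dt), 1 - death_prob(21, 21, 4000))
  }
  # pressure raises death; normalization restores the zero-pressure rate
  expect_gt(death_prob(1, 21, 4000, p = 1, c4 = 9, c5 = 10),
            death_prob(1, 21, 4000, p = 0, c4 = 9, c5 = 10))
  expect_equal(death_prob(1, 21, 4000, p = 0, c4 = 9, c5 = 10, normalize = TRUE),
               death_prob(1, 21, 4000))
  expect_equal(death_prob(1, 21, 4000, p = 0, c4 = 9, c5 = 10),
               1 - 2^((1 / 4000 - 1 / 21) * 4.5))
})

test_that("expected cycle duration is the sum of phase means", {
  cfg <- default_config()
  expect_equal(expected_cycle_duration(cfg$phenotypes$epithelial), 1001)
  expect_equal(expected_cycle_duration(cfg$phenotypes$tumor), 21)
  # with the pressure response on, an unloaded cell cycles faster
  expect_equal(expected_cycle_duration(cfg$phenotypes$epithelial,
                                       pressure_response = TRUE),
               300 + 400 / 1.1 + 300 + 1)
})

test_that("division geometry: touching daughters, volume conservation, isotropy", {
  R0 <- 3
  withr::with_seed(11, {
    for (dim in 2:3) {
      g <- divide_cell(rep(1, dim), R0, dim)
      expect_equal(sqrt(sum((g$x1 - g$x2)^2)), 2 * R0)
      expect_equal((g$x1 + g$x2) / 2, rep(1, dim))
    }
    # 3D: mother volume at R_max equals the two daughter volumes
    expect_equal(2 * R0^3, (2^(1 / 3) * R0)^3)
    # orientation is isotropic: mean of many directions is near zero
    U <- t(replicate(1e4, divide_cell(c(0, 0, 0), R0, 3)$u))
    expect_true(all(abs(colMeans(U)) < 3 * sqrt(1 / 3) / sqrt(1e4)))
  })
})

test_that("mutation decisions follow the per-division probability", {
  withr::with_seed(3, {
    expect_false(any(maybe_mutate(500, 0)))
    expect_true(all(maybe_mutate(500, 1)))
  })
})

test_that("a calibrated branching colony doubles in about T_2", {
  withr::with_seed(19, {
    ft <- replicate(6, simulate_doubling_time(n0 = 500, target = 1000))
    expect_equal(mean(ft), 4000, tolerance = 0.35)
  })
})
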