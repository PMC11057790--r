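test_that("pre-treatment step is the forward-Euler exponential update", {
  g <- grid_spec(3, 3, 430)
  cfg <- solver_config()
  N <- matrix(0, 3, 3); N[2, 2] <- 100
  out <- step_pretreatment(N, pretreatment_params(g0 = 0.03, D0 = 0), cfg, g)
  expect_equal(out[2, 2], 103)
  # 48 steps of pure growth compound exactly
  N <- matrix(2000 / 9, 3, 3)
  p <- pretreatment_params(g0 = 0.03, D0 = 0)
  for (k in 1:48) N <- step_pretreatment(N, p, cfg, g)
  expect_equal(N, matrix(2000 / 9 * 1.03^48, 3, 3), tolerance = 1e-12)
})

test_that("diffusion conserves total cell count under no-flux boundaries", {
  g <- grid_spec(5, 5, 430)
  cfg <- solver_config()
  set.seed(21)
  N <- matrix(runif(25, 0, 500), 5, 5)
  p <- pretreatment_params(g0 = 0, D0 = 0.005)
  tot0 <- sum(N)
  for (k in 1:50) {
    N <- step_pretreatment(N, p, cfg, g)
    expect_lt(abs(sum(N) - tot0) / tot0, 1e-12)
  }
})

test_that("population split conserves mass and respects the fraction", {
  N <- matrix(80, 4, 4)
  st <- split_population(N, 0.5, time = 48)
  expect_equal(st$Ns, matrix(40, 4, 4))
  expect_equal(st$Nd, matrix(40, 4, 4))
  st1 <- split_population(N, 1)
  expect_equal(st1$Nd, matrix(0, 4, 4))
  expect_equal(st1$Ns, N)
  set.seed(5)
  for (fs in runif(5)) {
    st <- split_population(N, fs)
    expect_equal(st$Ns + st$Nd - N, matrix(0, 4, 4))
  }
  expect_error(split_population(N, 1.2), "\\[0, 1\\]")
})

test_that("damaged net rate follows the delayed-death curve", {
  p <- treatment_params(gs = 0.01, fs = 0.5, gd = 0.01, kd = 0.008,
                        gamma_d = 0.05, theta = 89000)
  expect_equal(damaged_net_rate(48, p, t_dox = 48), 0.01)
  expect_equal(damaged_net_rate(48 + 20, p, t_dox = 48),
               0.01 + 0.008 * exp(-1) - 0.008)
  # long-time limit
  expect_equal(damaged_net_rate(48 + 5000, p, t_dox = 48), 0.01 - 0.008,
               tolerance = 1e-10)
  expect_error(damaged_net_rate(40, p, t_dox = 48), "t_dox")
})

test_that("post-treatment step freezes at carrying capacity and grows at gs", {
  g <- grid_spec(3, 3, 430)
  cfg <- solver_config(theta_scope = "pixel")
  p <- treatment_params(gs = 0.02, fs = 0.5, gd = 0.005, kd = 0.004,
                        gamma_d = 0.05, theta = 500, Ds = 0, Dd = 0)
  # at capacity the logistic factor vanishes for both populations
  st <- two_pop_state(matrix(300, 3, 3), matrix(200, 3, 3), time = 48)
  out <- step_posttreatment(st, p, cfg, g)
  expect_equal(out$Ns, st$Ns)
  expect_equal(out$Nd, st$Nd)
  # far below capacity the surviving population compounds at gs
  p2 <- treatment_params(gs = 0.02, fs = 1, gd = 0.005, kd = 1e-4,
                         gamma_d = 1, theta = 1e12, Ds = 0, Dd = 0)
  st <- two_pop_state(matrix(10, 3, 3), matrix(0, 3, 3), time = 48)
  for (k in 1:30) st <- step_posttreatment(st, p2, cfg, g)
  expect_equal(st$Ns[1, 1] / (10 * (1 + 0.02)^30), 1, tolerance = 1e-9)
})

test_that("zero-diffusion trajectories match an independent scalar oracle", {
  g <- grid_spec(4, 4, 430)
  cfg <- solver_config(theta_scope = "pixel")
  set.seed(31)
  gs_field <- matrix(runif(16, 0.001, 0.03), 4, 4)
  p <- treatment_params(gs = gs_field, fs = 0.4, gd = 0.004, kd = 0.008,
                        gamma_d = 1 / 30, theta = 400, Ds = 0, Dd = 0)
  N0 <- matrix(runif(16, 10, 120), 4, 4)
  st <- split_population(N0, 0.4, time = 48)
  for (k in 1:100) st <- step_posttreatment(st, p, cfg, g)
  for (px in seq_len(16)) {
    oracle <- scalar_post_oracle(0.4 * N0[px], 0.6 * N0[px], gs_field[px],
                                 NA, 0.004, 0.008, 1 / 30, 400, 1, 100)
    expect_equal(st$Ns[px], unname(oracle["ns"]), tolerance = 1e-12)
    expect_equal(st$Nd[px], unname(oracle["nd"]), tolerance = 1e-12)
  }
})

test_that("increasing the death rate never increases the damaged count", {
  g <- grid_spec(3, 3, 430)
  cfg <- solver_config(theta_scope = "pixel")
  nd_final <- vapply(seq(1e-4, 0.01, length.out = 8), function(kd) {
    p <- treatment_params(gs = 0.01, fs = 0.3, gd = 0.004, kd = kd,
                          gamma_d = 1 / 30, theta = 500, Ds = 0, Dd = 0)
    st <- split_population(matrix(100, 3, 3), 0.3, time = 48)
    for (k in 1:200) st <- step_posttreatment(st, p, cfg, g)
    st$Nd[1, 1]
  }, numeric(1))
  expect_true(all(diff(nd_final) <= 1e-12))
})

test_that("simulate_well composes phases, conventions and conservation", {
  g <- coarse_grid()
  pre <- pretreatment_params(g0 = 0.0275, D0 = 0.002)
  post <- treatment_params(gs = 0.01, fs = 0.4, gd = 0.004, kd = 0.008,
                           gamma_d = 1 / 30, theta = 89000,
                           Ds = 0.002, Dd = 0.002)
  cfg <- solver_config(t_dox = 48)
  sim <- simulate_well(matrix(80, 5, 5), pre, post, cfg, g, t_end = 96,
                       sample_times = seq(0, 96, by = 8))
  # pre-treatment convention: all mass in Ns
  expect_equal(sim$Nd[[2]], matrix(0, 5, 5))
  # at t_dox the state is freshly split
  i_dox <- which(sim$times == 48)
  expect_equal(sim$Nd[[i_dox]] / (sim$Ns[[i_dox]] + sim$Nd[[i_dox]]),
               matrix(0.6, 5, 5), tolerance = 1e-12)
  # all rates zero, no diffusion: every sampled state equals N0
  null_pre <- pretreatment_params(g0 = 0, D0 = 0)
  null_post <- treatment_params(gs = 0, fs = 1, gd = 0, kd = 1e-9,
                                gamma_d = 1, theta = 89000, Ds = 0, Dd = 0)
  sim0 <- simulate_well(matrix(80, 5, 5), null_pre, null_post, cfg, g,
                        t_end = 96, sample_times = seq(0, 96, by = 8))
  for (i in seq_along(sim0$times)) {
    expect_equal(sim0$Ns[[i]] + sim0$Nd[[i]], matrix(80, 5, 5),
                 tolerance = 1e-9)
  }
  expect_error(simulate_well(matrix(80, 5, 5), pre, post, cfg, g, 96,
                             sample_times = c(8, 4)), "sorted")
})

test_that("treatment time at the horizon reduces to a pre-treatment run", {
  g <- coarse_grid()
  pre <- pretreatment_params(g0 = 0.02, D0 = 0.001)
  post <- treatment_params(gs = 0.03, fs = 0.25, gd = 0.02, kd = 0.005,
                           gamma_d = 0.05, theta = 89000, Ds = 0.001)
  cfg <- solver_config(t_dox = 48)
  sim <- simulate_well(matrix(80, 5, 5), pre, post, cfg, g, t_end = 48,
                       sample_times = c(0, 24, 48))
  N <- matrix(80, 5, 5)
  for (k in 1:24) N <- step_pretreatment(N, pre, cfg, g)
  expect_equal(sim$Ns[[2]], N, tolerance = 1e-12)
  # final state carries the split of the pre-treatment endpoint
  for (k in 25:48) N <- step_pretreatment(N, pre, cfg, g)
  expect_equal(sim$Ns[[3]], 0.25 * N, tolerance = 1e-12)
  expect_equal(sim$Nd[[3]], 0.75 * N, tolerance = 1e-12)
})

test_that("halving the time step converges with first order", {
  g <- coarse_grid()
  pre <- pretreatment_params(g0 = 0.0275, D0 = 0.002)
  post <- treatment_params(gs = 0.02, fs = 0.4, gd = 0.004, kd = 0.008,
                           gamma_d = 1 / 30, theta = 89000,
                           Ds = 0.002, Dd = 0.002)
  finals <- vapply(c(1, 0.5, 0.25, 0.125), function(dt) {
    cfg <- solver_config(dt = dt, t_dox = 48)
    sim <- simulate_well(matrix(80, 5, 5), pre, post, cfg, g, t_end = 200,
                         sample_times = c(200))
    sum(sim$Ns[[1]] + sim$Nd[[1]])
  }, numeric(1))
  gaps <- abs(diff(finals))
  orders <- log2(gaps[-length(gaps)] / gaps[-1])
  expect_true(all(orders > 0.8 & orders < 1.2))
})

test_that("unstable diffusion settings are rejected", {
  g <- grid_spec(5, 5, 100)  # 0.1 mm pixels
  cfg <- solver_config(dt = 1)
  expect_error(
    step_pretreatment(matrix(1, 5, 5), pretreatment_params(D0 = 0.005),
                      cfg, g),
    "unstable")
})
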