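test_that("training prior is the pixelwise mean of the calibrations", {
  g <- grid_spec(2, 2, 430)
  mk <- function(gs, fs) param_grid(gs = matrix(gs, 2, 2), fs = fs,
                                    gd = 0.002, kd = 0.005, gamma_d = 0.04,
                                    theta = 89000, grid = g)
  grids <- list(mk(0.01, 0.2), mk(0.02, 0.4), mk(0.03, 0.6),
                mk(0.04, 0.8), mk(0.05, 1.0))
  prior <- build_training_prior(grids)
  expect_equal(prior$gs, matrix(0.03, 2, 2))
  expect_equal(prior$fs, matrix(0.6, 2, 2))
  # five identical grids reproduce that grid
  same <- build_training_prior(rep(list(mk(0.02, 0.5)), 5))
  expect_equal(same$gs, matrix(0.02, 2, 2))
  # hand-computed per-pixel mean on a heterogeneous toy
  a <- mk(0.01, 0.2); a$gs[1, 1] <- 0.03
  b <- mk(0.03, 0.2)
  expect_equal(build_training_prior(list(a, b))$gs[1, 1], 0.03)
  expect_equal(build_training_prior(list(a, b))$gs[2, 2], 0.02)
  bad <- param_grid(gs = 0.01, fs = 1, gd = 0.002, kd = 0.005,
                    gamma_d = 0.04, theta = 89000, grid = grid_spec(3, 3, 430))
  expect_error(build_training_prior(list(a, bad)), "mismatch")
})

test_that("similarity ranking selects the 25% most concordant courses", {
  set.seed(71)
  K <- 5 * 15 * 15
  courses <- matrix(rnorm(K * 10, mean = 50, sd = 10), K, 10)
  test_course <- as.numeric(courses[17, ])
  r <- rank_similar_pixels(test_course, courses)
  expect_equal(r$n_selected, 282)  # ceiling(0.25 * 1125)
  expect_equal(r$ranking$rank[17], 1L)
  expect_equal(r$ranking$ccc[17], 1)
  expect_equal(sum(r$ranking$weight), 1, tolerance = 1e-12)
  expect_false(r$degenerate)
  # zero-variance test course falls back to uniform weights
  r0 <- rank_similar_pixels(rep(5, 10), courses)
  expect_true(r0$degenerate)
  w <- r0$ranking$weight[r0$ranking$selected]
  expect_equal(w, rep(1 / r0$n_selected, r0$n_selected))
})

test_that("parameter transfer reproduces hand-computed weighted means", {
  g <- grid_spec(1, 1, 430)
  # three training pixels with CCCs 0.9, 0.6, 0.3 among the selected
  tp <- rbind(c(0.01, 0.2, 0.002, 0.004, 0.03, 88500),
              c(0.02, 0.4, 0.004, 0.006, 0.05, 89000),
              c(0.03, 0.6, 0.006, 0.008, 0.07, 89500))
  colnames(tp) <- c("gs", "fs", "gd", "kd", "gamma_d", "theta")
  ranking <- structure(list(
    ranking = tibble::tibble(pixel_id = 1:3, ccc = c(0.9, 0.6, 0.3),
                             rank = 1:3, selected = TRUE,
                             weight = c(0.9, 0.6, 0.3) / 1.8),
    n_selected = 3L, degenerate = FALSE), class = "similarity_ranking")
  out <- transfer_parameters(list(ranking), tp, g)
  expect_equal(ranking$ranking$weight, c(0.5, 1 / 3, 1 / 6))
  expect_equal(out$gs[1, 1], sum(c(0.5, 1 / 3, 1 / 6) * tp[, "gs"]))
  expect_equal(out$fs[1, 1], sum(c(0.5, 1 / 3, 1 / 6) * tp[, "fs"]))
  # equal similarities give the unweighted mean
  ranking$ranking$weight <- rep(1 / 3, 3)
  out_eq <- transfer_parameters(list(ranking), tp, g)
  expect_equal(out_eq$gs[1, 1], mean(tp[, "gs"]))
  # identical parameter sets are returned unchanged (convexity)
  tp_same <- tp; tp_same[] <- rep(tp[1, ], each = 3)
  out_same <- transfer_parameters(list(ranking), tp_same, g)
  expect_equal(out_same$kd[1, 1], unname(tp[1, "kd"]))
})

test_that("omega schedule matches its closed form and is decreasing", {
  expect_equal(omega_weight(0), 1)
  expect_equal(omega_weight(1), 0.4)
  expect_equal(omega_weight(0.5), 0.55)
  t_hat <- seq(0, 1, by = 0.01)
  w <- omega_weight(t_hat)
  expect_true(all(diff(w) < 0))
  expect_true(all(w >= 0.4 & w <= 1))
  expect_error(omega_weight(1.1), "\\[0, 1\\]")
})

test_that("parameter blending is the omega-weighted convex combination", {
  g <- grid_spec(2, 2, 430)
  Pt <- param_grid(gs = 2, fs = 0.2, gd = 2, kd = 2, gamma_d = 2,
                   theta = 88000, grid = g)
  Pm <- param_grid(gs = 4, fs = 0.8, gd = 4, kd = 4, gamma_d = 4,
                   theta = 90000, grid = g)
  expect_equal(blend_parameters(Pt, Pm, 0)$gs, Pt$gs)
  out <- blend_parameters(Pt, Pm, 0.5)  # omega = 0.55
  expect_equal(out$gs, matrix(0.55 * 2 + 0.45 * 4, 2, 2))
  expect_equal(out$fs[1, 1], 0.55 * 0.2 + 0.45 * 0.8)
  # blending identical grids is the identity for any t_hat
  expect_equal(blend_parameters(Pt, Pt, 0.77)$kd, Pt$kd)
  # blends stay inside the interval spanned by the inputs
  for (t_hat in seq(0, 1, by = 0.2)) {
    out <- blend_parameters(Pt, Pm, t_hat)
    expect_true(all(out$theta >= 88000 & out$theta <= 90000))
  }
  bad <- param_grid(gs = 1, fs = 1, gd = 1, kd = 1, gamma_d = 1,
                    theta = 89000, grid = grid_spec(3, 3, 430))
  expect_error(blend_parameters(Pt, bad, 0.5), "mismatch")
})

test_that("weekly forecast agrees with the reference solver on uniform grids", {
  g <- coarse_grid()
  cfg <- solver_config(t_dox = 48)
  pg <- param_grid(gs = 0.012, fs = 0.4, gd = 0.0015, kd = 0.008,
                   gamma_d = 1 / 24, theta = 89000, grid = g)
  N48 <- matrix(300, 5, 5)
  times <- seq(52, 216, by = 4)
  pred <- predict_week(N48, pg, from_time = 48, sample_times = times,
                       cfg = cfg, D0 = 0.0025)
  post <- treatment_params(gs = 0.012, fs = 0.4, gd = 0.0015, kd = 0.008,
                           gamma_d = 1 / 24, theta = 89000,
                           Ds = 0.0025, Dd = 0.0025)
  sim <- simulate_well(N48, pretreatment_params(), post,
                       solver_config(t_dox = 0), g, t_end = 168,
                       sample_times = times - 48)
  for (i in seq_along(times)) {
    expect_equal(pred$maps[[i]], sim$Ns[[i]] + sim$Nd[[i]],
                 tolerance = 1e-10)
  }
  # zero initial map forecasts zero
  z <- predict_week(matrix(0, 5, 5), pg, 48, times, cfg)
  expect_true(all(vapply(z$maps, sum, numeric(1)) == 0))
})

test_that("a high-gs pixel attains the terminal maximum without diffusion", {
  g <- coarse_grid()
  gs <- matrix(0.003, 5, 5); gs[3, 3] <- 0.03
  pg <- param_grid(gs = gs, fs = 0.5, gd = 0.0015, kd = 0.008,
                   gamma_d = 1 / 24, theta = 89000, grid = g)
  pred <- predict_week(matrix(100, 5, 5), pg, 48, seq(52, 400, 4),
                       solver_config(t_dox = 48), D0 = 0)
  final <- pred$maps[[length(pred$maps)]]
  expect_equal(which.max(final), 13L)  # column-major index of (3,3)
  # and matches the scalar oracle pixelwise
  oracle <- scalar_post_oracle(50, 50, 0.03, NA, 0.0015, 0.008, 1 / 24,
                               89000 / 25, 1, 352)
  expect_equal(final[3, 3], sum(oracle), tolerance = 1e-12)
})

test_that("prediction bands degenerate to the point forecast", {
  g <- coarse_grid(3)
  pg <- param_grid(gs = 0.01, fs = 0.5, gd = 0.002, kd = 0.006,
                   gamma_d = 0.04, theta = 89000, grid = g)
  draws <- rep(list(pg), 8)
  band <- sample_prediction_band(draws, NULL, 0, matrix(50, 3, 3), 48,
                                 c(100, 150), solver_config(t_dox = 48),
                                 D0 = 0.0025)
  point <- predict_week(matrix(50, 3, 3), pg, 48, c(100, 150),
                        solver_config(t_dox = 48), D0 = 0.0025)
  expect_equal(band$mean[[1]], point$maps[[1]])
  expect_equal(band$lower[[2]], band$upper[[2]])
  expect_error(sample_prediction_band(draws[1:2], NULL, 0,
                                      matrix(50, 3, 3), 48, 100,
                                      solver_config()), "at least 4")
})
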