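test_that("dose truths encode the treated regimes within bounds", {
  g <- coarse_grid()
  b <- param_bounds()
  ctrl <- sample_dose_truth(0, 1, g)
  expect_equal(ctrl$post$fs, 1)
  expect_equal(ctrl$post$kd, 1e-4)
  expect_equal(length(unique(as.vector(ctrl$post$gs))), 1L)

  high <- sample_dose_truth(300, 1, g)
  expect_lt(high$post$fs, 0.05)
  expect_equal(length(unique(as.vector(high$post$gs))), 1L)

  med <- sample_dose_truth(100, 1, g)
  expect_gt(length(unique(as.vector(med$post$gs))), 1L)
  expect_gte(nrow(med$clusters), 2)
  expect_lte(nrow(med$clusters), 5)

  for (dose in c(0, 10, 35, 50, 100, 150, 300)) {
    tr <- sample_dose_truth(dose, 3, g)
    expect_true(all(tr$post$gs >= 1e-4 & tr$post$gs <= 0.035))
    expect_true(tr$post$fs >= 0 && tr$post$fs <= 1)
    expect_true(tr$post$kd >= 1e-4 && tr$post$kd <= 0.01)
    expect_true(tr$post$gamma_d >= 1 / 120 && tr$post$gamma_d <= 1 / 10)
    expect_true(tr$post$theta >= 88000 && tr$post$theta <= 90000)
  }
  # surviving fraction decreases with dose
  fs_curve <- vapply(c(10, 35, 75, 150, 300),
                     function(d) sample_dose_truth(d, 1, g)$post$fs,
                     numeric(1))
  expect_true(all(diff(fs_curve) < 0))
  # seed only moves cluster placement, not the dose-level parameters
  t1 <- sample_dose_truth(100, 1, g)
  t2 <- sample_dose_truth(100, 2, g)
  expect_equal(t1$post$fs, t2$post$fs)
  expect_false(identical(t1$post$gs, t2$post$gs))
})

test_that("synthetic series reproduce the solver exactly without noise", {
  g <- coarse_grid()
  des <- short_design()
  tr <- sample_dose_truth(100, 5, g)
  tr$noise_frac <- 0; tr$noise_floor <- 0
  s <- simulate_truth_series(tr, des, 100, 9, g)
  sim <- simulate_well(s$maps[[1]], tr$pre, tr$post,
                       solver_config(t_dox = des$t_dox), g,
                       t_end = max(s$times), sample_times = s$times)
  for (i in seq_along(s$times)) {
    expect_equal(s$maps[[i]], sim$Ns[[i]] + sim$Nd[[i]], tolerance = 1e-12)
  }
})

test_that("noisy generation is reproducible and unbiased", {
  g <- coarse_grid(3)
  des <- short_design(t_end = 100, interval = 4)
  tr <- sample_dose_truth(35, 5, g)
  a <- simulate_truth_series(tr, des, 35, 11, g)
  b <- simulate_truth_series(tr, des, 35, 11, g)
  expect_identical(a$maps, b$maps)
  c2 <- simulate_truth_series(tr, des, 35, 12, g)
  expect_false(identical(a$maps, c2$maps))
  # Monte-Carlo mean of the added noise is zero: pair each noisy draw with
  # the noiseless run of the same seed (identical multinomial seeding)
  tr0 <- tr; tr0$noise_frac <- 0; tr0$noise_floor <- 0
  i <- 13
  diffs <- unlist(lapply(1:150, function(k) {
    noisy <- simulate_truth_series(tr, des, 35, 1000 + k, g)$maps[[i]]
    clean <- simulate_truth_series(tr0, des, 35, 1000 + k, g)$maps[[i]]
    as.vector(noisy - clean)
  }))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 4 * se + 1e-9)
})

test_that("centroid scatter/bin round trip preserves integer maps", {
  g <- coarse_grid()
  set.seed(61)
  m <- matrix(rpois(25, 30), 5, 5)
  tab <- scatter_centroids(m, g, time = 100, rng_seed = 3)
  expect_equal(nrow(tab), sum(m))
  expect_equal(bin_centroids_to_density(tab, g), m + 0)
  # empty map
  empty <- scatter_centroids(matrix(0, 5, 5), g)
  expect_equal(nrow(empty), 0)
  # one pixel's centroids stay inside its bounds
  one <- matrix(0, 5, 5); one[2, 3] <- 5
  tab1 <- scatter_centroids(one, g, rng_seed = 4)
  expect_true(all(tab1$x_um >= 2 * g$pixel_size & tab1$x_um < 3 * g$pixel_size))
  expect_true(all(tab1$y_um >= 1 * g$pixel_size & tab1$y_um < 2 * g$pixel_size))
})

test_that("binning uses half-open pixels and rejects out-of-range points", {
  g <- grid_spec()
  tab <- tibble::tibble(time_h = 0, x_um = c(0, 430), y_um = c(0, 0))
  m <- bin_centroids_to_density(tab, g)
  expect_equal(m[1, 1], 1)  # exactly 0 goes to the first pixel
  expect_equal(m[1, 2], 1)  # exactly 430 um goes to column 2, not 1
  bad <- tibble::tibble(time_h = 0, x_um = 6450, y_um = 10)
  expect_error(bin_centroids_to_density(bad, g), "record 1")
})

test_that("confluence truncation drops only post-threshold timepoints", {
  g <- coarse_grid()
  s <- noiseless_series(0, seed = 2, grid = g)  # control grows to capacity
  tr <- truncate_at_confluence(s, threshold_fraction = 0.5)
  totals <- well_totals(s)$total_count
  k <- which(totals >= 0.5 * 89000)[1]
  expect_equal(length(tr$times), k)
  # decaying high-dose series is never truncated
  s300 <- noiseless_series(300, seed = 2, grid = g,
                           design = short_design(t_end = 300))
  expect_equal(length(truncate_at_confluence(s300)$times),
               length(s300$times))
  expect_error(truncate_at_confluence(s, threshold_fraction = 0), ">")
})

test_that("pre-treatment maps are spatially homogeneous in expectation", {
  g <- coarse_grid()
  wells <- generate_experiment(short_design(t_end = 200), master_seed = 3,
                               grid = g, doses = c(100),
                               include_controls = FALSE)
  for (s in wells$series) {
    idx <- which(s$times <= s$t_dox_h)
    px_mean <- rowMeans(vapply(idx, function(i) as.vector(s$maps[[i]]),
                               numeric(25)))
    cv <- sd(px_mean) / mean(px_mean)
    expect_lt(cv, 0.5)
  }
})

test_that("dose regimes shape the total-count courses", {
  g <- coarse_grid()
  # medium dose: decline then relapse (local minimum strictly after t_dox)
  s <- noiseless_series(100, seed = 7, grid = g)
  v <- well_totals(s)$total_count
  th <- s$times
  post <- which(th >= s$t_dox_h)
  pk <- post[which.max(v[post[1:30]])]
  mn <- pk - 1 + which.min(v[pk:max(post)])
  expect_gt(th[mn], s$t_dox_h)
  expect_lt(v[mn], 0.95 * v[pk])            # a real decline
  expect_gt(v[length(v)], 1.5 * v[mn])      # a real relapse
  # high dose: homogeneous decay after the initial transient, no recovery
  s300 <- noiseless_series(300, seed = 7, grid = g)
  v300 <- well_totals(s300)$total_count
  k_min <- which.min(v300)
  window <- which(s300$times >= s300$t_dox_h + 50 &
                    s300$times <= s300$times[k_min])
  expect_true(all(diff(v300[window]) <= 0))
  expect_lt(min(v300), 0.1 * max(v300))
  expect_lt(v300[length(v300)], 1.1 * min(v300))  # no meaningful relapse
})

test_that("well series containers validate their invariants", {
  g <- coarse_grid()
  expect_error(well_series(list(matrix(1, 5, 5)), c(0, 4), g))
  expect_error(well_series(list(matrix(-1, 5, 5)), 0, g))
  s <- noiseless_series(35, seed = 1, grid = g,
                        design = short_design(t_end = 100))
  td <- tidy(s)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), length(s$times) * 25)
  expect_equal(sum(td$count[td$time_h == s$times[3]]), sum(s$maps[[3]]))
  gl <- glance(s)
  expect_equal(gl$n_times, length(s$times))
})
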