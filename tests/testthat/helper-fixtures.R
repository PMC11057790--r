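# shared miniature fixtures: a coarse 5x5 grid over the standard field of
# view keeps the solver and calibration fast while preserving the physics
coarse_grid <- function(n = 5) grid_spec(n, n, 6450 / n)

# noiseless synthetic series for a given dose on the coarse grid
noiseless_series <- function(dose = 100, seed = 7, grid = coarse_grid(),
                             replicate_id = 1L,
                             design = experiment_design()) {
  truth <- sample_dose_truth(dose, rng_seed = seed, grid = grid)
  truth$noise_frac <- 0
  truth$noise_floor <- 0
  simulate_truth_series(truth, design, dose, rng_seed = seed + 1000L,
                        grid = grid, replicate_id = replicate_id)
}

# short experiment design for fast end-to-end runs (3 post-treatment weeks)
short_design <- function(t_end = 400, interval = 4) {
  experiment_design(
    imaging_interval = interval,
    t_end_by_dose = c("0" = t_end, "10" = t_end, "20" = t_end, "35" = t_end,
                      "50" = t_end, "75" = t_end, "100" = t_end,
                      "125" = t_end, "150" = t_end, "300" = t_end))
}

# independent scalar forward-Euler oracle for zero-diffusion dynamics,
# written against the update equations directly (no package solver code)
scalar_post_oracle <- function(ns0, nd0, gs, fs_unused, gd, kd, gamma_d,
                               th_pix, dt, n_steps, drug_age0 = 0) {
  ns <- ns0; nd <- nd0
  for (k in seq_len(n_steps)) {
    age <- drug_age0 + (k - 1) * dt
    crowd <- 1 - (ns + nd) / th_pix
    rate_d <- gd + kd * exp(-gamma_d * age) - kd
    ns_new <- ns + dt * gs * ns * crowd
    nd_new <- nd + dt * rate_d * nd * crowd
    ns <- max(ns_new, 0); nd <- max(nd_new, 0)
  }
  c(ns = ns, nd = nd)
}
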