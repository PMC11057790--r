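#' Design of a synthetic well-plate experiment
#'
#' Mirrors the layout of the doxorubicin time-resolved microscopy experiment
#' the package emulates: nine doses with six replicates each plus six
#' untreated controls, 2000 cells seeded per well, treatment at 48 h, imaging
#' every 4 h, and dose-dependent experiment durations ranging from 277 h at
#' the lowest dose to 963 h at the highest.
#'
#' @param doses Doxorubicin concentrations in nM.
#' @param replicates_per_dose Replicate wells per dose.
#' @param n_controls Untreated control wells (dose 0).
#' @param seed_cells Cells seeded per well at `t = 0`.
#' @param t_dox Treatment time, hours.
#' @param imaging_interval Hours between density maps (the instrument images
#'   every 2-4 h; 4 h is the default here).
#' @param t_end_by_dose Named vector mapping dose (as character) to the last
#'   imaging time in hours.
#' @return An `experiment_design` object.
#' @export
experiment_design <- function(
    doses = c(10, 20, 35, 50, 75, 100, 125, 150, 300),
    replicates_per_dose = 6L,
    n_controls = 6L,
    seed_cells = 2000L,
    t_dox = 48,
    imaging_interval = 4,
    t_end_by_dose = c("0" = 400, "10" = 277, "20" = 350, "35" = 497,
                      "50" = 575, "75" = 650, "100" = 782, "125" = 850,
                      "150" = 900, "300" = 963)) {
  stopifnot(imaging_interval > 0, seed_cells > 0, t_dox >= 0)
  structure(
    list(doses = doses, replicates_per_dose = as.integer(replicates_per_dose),
         n_controls = as.integer(n_controls), seed_cells = as.integer(seed_cells),
         t_dox = t_dox, imaging_interval = imaging_interval,
         t_end_by_dose = t_end_by_dose),
    class = "experiment_design"
  )
}

design_t_end <- function(design, dose) {
  key <- as.character(dose)
  if (key %in% names(design$t_end_by_dose)) {
    unname(design$t_end_by_dose[key])
  } else {
    # interpolate on log(dose + 1) between the declared endpoints
    kn <- as.numeric(names(design$t_end_by_dose))
    stats::approx(log1p(kn), design$t_end_by_dose, xout = log1p(dose),
                  rule = 2)$y
  }
}

#' Ground-truth parameters of a synthetic well
#'
#' Container for the generating parameters of a synthetic experiment: the
#' pre- and post-treatment model parameters (the latter with a spatially
#' structured `gs` field for medium doses), the noise model and the cluster
#' layout. Retained on generated series so recovery tests can compare
#' estimates against it.
#'
#' @param pre A [pretreatment_params()].
#' @param post A [treatment_params()] (its `gs` may be a matrix).
#' @param noise_frac Per-map noise standard deviation as a fraction of the
#'   map's mean pixel count.
#' @param noise_floor Minimum noise standard deviation, cells.
#' @param clusters Tibble of high-`gs` foci (`row`, `col`, `sigma_px`,
#'   `peak_gs`), empty when `gs` is uniform.
#' @return A `ground_truth` object.
#' @export
ground_truth <- function(pre, post, noise_frac = 0.05, noise_floor = 1,
                         clusters = NULL) {
  stopifnot(noise_frac >= 0, noise_floor >= 0)
  structure(list(pre = pre, post = post, noise_frac = noise_frac,
                 noise_floor = noise_floor,
                 clusters = clusters %||% tibble::tibble(
                   row = numeric(), col = numeric(),
                   sigma_px = numeric(), peak_gs = numeric())),
            class = "ground_truth")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# dose-response curves behind the synthetic truths; all values stay inside
# the calibration bounds
dose_fs <- function(dose) if (dose <= 0) 1 else 1 / (1 + (dose / 45)^1.9)
dose_kd <- function(dose) {
  if (dose <= 0) return(1e-4)
  1e-4 + 0.0093 * (dose / 45)^2 / (1 + (dose / 45)^2)
}
dose_gs_base <- function(dose, g0) {
  if (dose <= 0) return(g0)
  max(1e-4, 1e-4 + (g0 - 1e-4) / (1 + (dose / 25)^1.6))
}

#' Draw the ground truth for one well at a given dose
#'
#' Encodes the qualitative dose regimes of the experiment: untreated and
#' low-dose wells keep a spatially uniform surviving proliferation field and
#' a surviving fraction near one (homogeneous growth); high doses give a
#' near-zero surviving fraction and a uniformly low `gs` (homogeneous
#' decay); medium doses (50-150 nM) produce 2-5 localized high-`gs` foci —
#' Gaussian bumps on the `gs` field — from which clustered relapse emerges.
#' Cluster placement is randomized per well; the dose-level parameters are
#' deterministic functions of dose.
#'
#' @param dose Dose in nM (0 for control).
#' @param rng_seed Integer seed for cluster placement.
#' @param grid A [grid_spec()].
#' @return A [ground_truth()].
#' @export
sample_dose_truth <- function(dose, rng_seed = 1L, grid = grid_spec()) {
  g0 <- 0.0275; D0 <- 0.0025
  pre <- pretreatment_params(g0 = g0, D0 = D0)
  fs <- dose_fs(dose)
  kd <- dose_kd(dose)
  gd <- 0.0015
  gamma_d <- 1 / 24
  theta <- 89000
  base <- dose_gs_base(dose, g0)
  clusters <- tibble::tibble(row = numeric(), col = numeric(),
                             sigma_px = numeric(), peak_gs = numeric())
  gs <- matrix(base, grid$n_rows, grid$n_cols)
  if (dose >= 50 && dose <= 150) {
    rng <- local_rng(rng_seed)
    n_cl <- rng$sample_int(2:5)
    clusters <- tibble::tibble(
      row = rng$runif(n_cl, 1, grid$n_rows),
      col = rng$runif(n_cl, 1, grid$n_cols),
      sigma_px = rng$runif(n_cl, 0.8, 1.3) * grid$n_rows / 15,
      peak_gs = rng$runif(n_cl, 0.018, 0.026)
    )
    rr <- matrix(seq_len(grid$n_rows), grid$n_rows, grid$n_cols)
    cc <- matrix(seq_len(grid$n_cols), grid$n_rows, grid$n_cols, byrow = TRUE)
    for (i in seq_len(n_cl)) {
      d2 <- (rr - clusters$row[i])^2 + (cc - clusters$col[i])^2
      bump <- (clusters$peak_gs[i] - base) *
        exp(-d2 / (2 * clusters$sigma_px[i]^2))
      gs <- pmax(gs, base + bump)
    }
    gs <- pmin(pmax(gs, 1e-4), 0.035)
  }
  post <- treatment_params(gs = gs, fs = fs, gd = gd, kd = kd,
                           gamma_d = gamma_d, theta = theta,
                           Ds = D0, Dd = D0)
  ground_truth(pre = pre, post = post, clusters = clusters)
}

# a tiny isolated RNG so synthetic draws never disturb the caller's stream
local_rng <- function(seed) {
  env <- new.env()
  env$state <- NULL
  run <- function(expr_fun) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    if (is.null(env$state)) set.seed(seed) else assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    expr_fun()
  }
  list(
    runif = function(n, a = 0, b = 1) run(function() stats::runif(n, a, b)),
    rnorm = function(n, mean = 0, sd = 1) run(function() stats::rnorm(n, mean, sd)),
    sample_int = function(x) run(function() sample(x, 1L)),
    rmultinom = function(n, size, prob) run(function() stats::rmultinom(n, size, prob))
  )
}

#' Simulate a noisy measured time course from a ground truth
#'
#' Seeds `design$seed_cells` cells multinomially across the grid, runs the
#' forward model at the imaging times, then adds independent Gaussian pixel
#' noise (standard deviation `noise_frac` of each pixel's own count, floored
#' at `noise_floor` cells — segmentation noise scales with local density)
#' and clips at zero. With `noise_frac = 0` and
#' `noise_floor = 0` the series equals the solver output exactly.
#'
#' @param truth A [ground_truth()].
#' @param design An [experiment_design()].
#' @param dose Dose in nM.
#' @param rng_seed Integer seed (seeding scatter + measurement noise).
#' @param grid A [grid_spec()].
#' @param replicate_id Identifier stored on the series.
#' @return A [well_series()] with `truth` attached.
#' @export
simulate_truth_series <- function(truth, design = experiment_design(),
                                  dose = 100, rng_seed = 1L,
                                  grid = grid_spec(), replicate_id = 1L) {
  rng <- local_rng(rng_seed)
  npx <- n_pixels(grid)
  N0 <- matrix(rng$rmultinom(1, design$seed_cells, rep(1 / npx, npx))[, 1],
               grid$n_rows, grid$n_cols)
  t_end <- design_t_end(design, dose)
  times <- seq(0, t_end, by = design$imaging_interval)
  cfg <- solver_config(dt = 1, t_dox = design$t_dox)
  sim <- simulate_well(N0, truth$pre, truth$post, cfg, grid,
                       t_end = t_end, sample_times = times)
  maps <- series_ntot_maps(sim)
  if (truth$noise_frac > 0 || truth$noise_floor > 0) {
    maps <- lapply(maps, function(m) {
      sd_px <- pmax(truth$noise_frac * m, truth$noise_floor)
      pmax(m + matrix(rng$rnorm(length(m)), nrow(m), ncol(m)) * sd_px, 0)
    })
  }
  well_series(maps, sim$times, grid, dose_nM = dose, t_dox_h = design$t_dox,
              replicate_id = replicate_id, truth = truth)
}

#' Scatter a density map back into cell centroids
#'
#' Inverse of [bin_centroids_to_density()]: emits `round(count)` centroids
#' per pixel, placed uniformly at random within the pixel's micrometre
#' extent. Useful for end-to-end I/O tests; binning the result recovers the
#' rounded map exactly.
#'
#' @param map Cell-count matrix.
#' @param grid A [grid_spec()].
#' @param time Imaging time recorded on each centroid, hours.
#' @param rng_seed Integer seed.
#' @return Tibble with columns `time_h`, `x_um`, `y_um`.
#' @export
scatter_centroids <- function(map, grid = grid_spec(), time = 0, rng_seed = 1L) {
  rng <- local_rng(rng_seed)
  counts <- round(map)
  idx <- which(counts > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(tibble::tibble(time_h = numeric(), x_um = numeric(), y_um = numeric()))
  }
  rows <- rep(idx[, 1], counts[idx])
  cols <- rep(idx[, 2], counts[idx])
  n <- length(rows)
  px <- grid$pixel_size
  u <- rng$runif(2 * n)
  tibble::tibble(
    time_h = rep(time, n),
    x_um = (cols - 1 + u[seq_len(n)]) * px,
    y_um = (rows - 1 + u[n + seq_len(n)]) * px
  )
}

#' Bin cell centroids into a density map
#'
#' Counts centroids per half-open pixel cell: a centroid at exactly a pixel
#' boundary belongs to the higher-index pixel, and coordinates must satisfy
#' `0 <= x, y < field_of_view`. Total count is preserved.
#'
#' @param table Tibble/data frame with columns `x_um`, `y_um` (and optionally
#'   `time_h`, ignored here).
#' @param grid A [grid_spec()].
#' @return Cell-count matrix of the grid's shape.
#' @export
bin_centroids_to_density <- function(table, grid = grid_spec()) {
  x <- table$x_um; y <- table$y_um
  bad <- which(x < 0 | y < 0 | x >= grid$field_of_view |
                 y >= grid$n_rows * grid$pixel_size)
  if (length(bad)) {
    stop(sprintf("centroid record %d is outside the field of view", bad[1]),
         call. = FALSE)
  }
  col <- floor(x / grid$pixel_size) + 1L
  row <- floor(y / grid$pixel_size) + 1L
  m <- matrix(0, grid$n_rows, grid$n_cols)
  for (i in seq_along(row)) m[row[i], col[i]] <- m[row[i], col[i]] + 1
  m
}

#' Truncate a series once the well reaches confluence
#'
#' Drops every time point after the first at which the total cell count
#' reaches `threshold_fraction` of the carrying capacity, mirroring how
#' measured time courses are cut when the monolayer becomes confluent and
#' counting unreliable.
#'
#' @param series A [well_series()].
#' @param threshold_fraction Fraction of `theta` in (0, 1].
#' @param theta Carrying capacity, cells per well; defaults to the series'
#'   ground-truth value when available, else 89000.
#' @return The (possibly shortened) [well_series()].
#' @export
truncate_at_confluence <- function(series, threshold_fraction = 0.95,
                                   theta = NULL) {
  stopifnot(threshold_fraction > 0, threshold_fraction <= 1)
  theta <- theta %||%
    (if (!is.null(series$truth)) series$truth$post$theta else 89000)
  totals <- well_totals(series)$total_count
  hit <- which(totals >= threshold_fraction * theta)
  if (length(hit) == 0) return(series)
  keep <- seq_len(hit[1])
  well_series(series$maps[keep], series$times[keep], series$grid,
              dose_nM = series$dose_nM, t_dox_h = series$t_dox_h,
              replicate_id = series$replicate_id, truth = series$truth)
}

well_seed <- function(master_seed, dose, replicate) {
  as.integer((as.double(master_seed) * 100003 + round(dose * 10) * 101 +
                replicate * 7919) %% 2147483629)
}

#' Generate a full synthetic experiment
#'
#' One [well_series()] per well of the design: `replicates_per_dose`
#' replicates at each dose plus `n_controls` untreated wells, each generated
#' from its own dose-level ground truth with per-well cluster placement and
#' noise, on independent per-well RNG streams derived from `master_seed`.
#'
#' @param design An [experiment_design()].
#' @param master_seed Integer master seed.
#' @param grid A [grid_spec()].
#' @param noise_frac,noise_floor Noise model overrides applied to every
#'   truth (defaults: 5% of map mean, floor 1 cell).
#' @param doses Optional subset of doses to generate (plus controls if
#'   `include_controls`).
#' @param include_controls Generate the untreated wells too?
#' @return A tibble with columns `dose_nM`, `replicate`, `series`
#'   (list-column of [well_series()]).
#' @export
generate_experiment <- function(design = experiment_design(), master_seed = 1L,
                                grid = grid_spec(), noise_frac = 0.05,
                                noise_floor = 1, doses = design$doses,
                                include_controls = TRUE) {
  wells <- list()
  dose_list <- c(if (include_controls) rep(0, design$n_controls),
                 rep(doses, each = design$replicates_per_dose))
  rep_list <- c(if (include_controls) seq_len(design$n_controls),
                rep(seq_len(design$replicates_per_dose), times = length(doses)))
  series <- purrr::map2(dose_list, rep_list, function(dose, rep_i) {
    seed_i <- well_seed(master_seed, dose, rep_i)
    truth <- sample_dose_truth(dose, rng_seed = seed_i, grid = grid)
    truth$noise_frac <- noise_frac
    truth$noise_floor <- noise_floor
    simulate_truth_series(truth, design, dose, rng_seed = seed_i + 1L,
                          grid = grid, replicate_id = rep_i)
  })
  tibble::tibble(dose_nM = dose_list, replicate = rep_list, series = series)
}
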