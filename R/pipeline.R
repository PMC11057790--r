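#' Leave-one-out weekly data assimilation-prediction pipeline
#'
#' The full forecasting workflow for one dose group: the replicates other
#' than `test_index` form the training set and are fully calibrated; their
#' parameter grids average into the population prior that forecasts the
#' held-out replicate's first post-treatment week. Each subsequent week the
#' test replicate is recalibrated on all data from the treatment time to the
#' current week (warm-started at the previous fit, giving `P_measure`),
#' training pixels are ranked by concordance with each test pixel's course
#' and their parameters transferred with similarity weights (`P_training`),
#' the two are blended with the omega schedule evaluated at the segment's
#' start time, the measured map at the boundary is split by the blended
#' surviving fraction, and the model runs forward one week. With
#' `n_boot > 0` and `n_samples > 0`, bootstrap parameter distributions are
#' propagated through the blend to give per-pixel forecast mean and
#' interquartile bands.
#'
#' @param replicates List of [well_series()] for one dose (canonically 6),
#'   aligned times, shared grid.
#' @param test_index Which replicate to hold out.
#' @param rng_seed Integer seed (bootstrap + band draws).
#' @param bounds A [param_bounds()] tibble.
#' @param n_boot Bootstrap samples per calibration (0 disables bands).
#' @param n_samples Forward draws for the forecast bands (canonically 1000).
#' @param week_h Update interval, hours (168 = weekly).
#' @param t_ref Reference horizon for the omega schedule, hours.
#' @param frac Similarity selection fraction.
#' @param maxiter Optimizer iteration cap for each calibration.
#' @param polish Run the coordinate-profile polish on the training and
#'   weekly calibrations (forecast quality rarely needs it; off by
#'   default).
#' @return A `prediction_trace`: per-week segments with predicted maps,
#'   optional uncertainty bands, per-week concordance scores, the parameter
#'   grids used, plus the training fits.
#' @export
run_pipeline <- function(replicates, test_index = 1L, rng_seed = 1L,
                         bounds = param_bounds(), n_boot = 0, n_samples = 0,
                         week_h = 168, t_ref = 963, frac = 0.25,
                         maxiter = 200, polish = FALSE) {
  if (length(replicates) < 2) {
    stop("need at least 2 replicates (canonical design has 6)", call. = FALSE)
  }
  grid <- replicates[[1]]$grid
  test <- replicates[[test_index]]
  training <- replicates[-test_index]
  t_dox <- test$t_dox_h
  cfg <- solver_config(t_dox = t_dox)
  rng <- local_rng(rng_seed)

  # --- training set: full calibrations (+ bootstrap when banding) ----------
  train_fits <- lapply(training, function(s) {
    pre <- calibrate_pretreatment(s, bounds)
    calibrate_posttreatment(s, bounds, pre$pre, maxiter = maxiter,
                            polish = polish)
  })
  train_boots <- if (n_boot > 0) {
    lapply(seq_along(training), function(i)
      bootstrap_calibration(training[[i]], train_fits[[i]], n_boot = n_boot,
                            rng_seed = well_seed(rng_seed, 1, i)))
  } else NULL
  prior <- build_training_prior(train_fits)
  train_param_mat <- do.call(rbind, lapply(train_fits, function(f)
    grid_to_matrix(fit_to_grid(f))))

  pre_test <- calibrate_pretreatment(test, bounds)
  D0 <- pre_test$pre$D0

  # measured training pixel courses from the treatment time onward
  t_all <- test$times
  post_all <- which(t_all >= t_dox)
  train_courses_full <- do.call(rbind, lapply(training, function(s) {
    stopifnot(length(s$times) >= max(post_all))
    pixel_courses(s, post_all)
  }))

  boundaries <- seq(t_dox, max(t_all), by = week_h)
  if (max(boundaries) < max(t_all)) boundaries <- c(boundaries, max(t_all))
  n_weeks <- length(boundaries) - 1L

  segments <- vector("list", n_weeks)
  prev_fit <- NULL
  for (w in seq_len(n_weeks)) {
    t_w <- boundaries[w]; t_next <- boundaries[w + 1]
    seg_idx <- which(t_all > t_w + 1e-8 & t_all <= t_next + 1e-8)
    if (!length(seg_idx)) next
    seg_times <- t_all[seg_idx]
    init_idx <- max(which(t_all <= t_w + 1e-8))
    init_map <- test$maps[[init_idx]]
    init_time <- t_all[init_idx]

    if (w == 1L) {
      P_pred <- prior
      P_measure <- NULL
      rankings <- NULL
      t_hat <- min(t_w / t_ref, 1)
    } else {
      cal_idx <- which(t_all <= t_w + 1e-8)
      cal_series <- well_series(test$maps[cal_idx], t_all[cal_idx], grid,
                                dose_nM = test$dose_nM, t_dox_h = t_dox,
                                replicate_id = test$replicate_id)
      fit_w <- calibrate_posttreatment(cal_series, bounds, pre_test$pre,
                                       init = prev_fit, maxiter = maxiter,
                                       polish = polish, polish_cycles = 1)
      prev_fit <- fit_w
      P_measure <- fit_to_grid(fit_w)
      win_cols <- which(t_all[post_all] <= t_w + 1e-8)
      test_courses <- pixel_courses(test, post_all[win_cols])
      rankings <- lapply(seq_len(n_pixels(grid)), function(p)
        rank_similar_pixels(test_courses[p, ],
                            train_courses_full[, win_cols, drop = FALSE],
                            frac = frac))
      P_training <- transfer_parameters(rankings, train_param_mat, grid)
      t_hat <- min(t_w / t_ref, 1)
      P_pred <- blend_parameters(P_training, P_measure, t_hat)
      init_map <- test$maps[[init_idx]]
    }

    split_ratio <- if (w == 1L) NULL else
      fit_split_ratio(prev_fit, init_time)
    pred <- predict_week(init_map, P_pred, init_time, seg_times, cfg, D0,
                         split_ratio = split_ratio)
    meas <- well_series(test$maps[seg_idx], seg_times, grid,
                        dose_nM = test$dose_nM, t_dox_h = t_dox,
                        replicate_id = test$replicate_id)
    px <- ccc_pixel(pred, meas)

    band <- NULL
    if (n_boot > 0 && n_samples > 0) {
      boot_w <- if (w == 1L) NULL else
        bootstrap_calibration(cal_series, prev_fit, n_boot = n_boot,
                              rng_seed = well_seed(rng_seed, 2, w))
      prior_draws <- lapply(seq_len(n_samples), function(s)
        draw_prior_grid(train_fits, train_boots, rng,
                        rankings = rankings, grid = grid))
      measure_draws <- if (is.null(boot_w)) NULL else
        lapply(seq_len(n_samples), function(s)
          draw_fit_grid(prev_fit, boot_w, rng))
      band <- sample_prediction_band(
        prior_draws, measure_draws, t_hat, init_map, init_time, seg_times,
        cfg, D0, rng_seed = well_seed(rng_seed, 3, w),
        split_ratio = split_ratio)
    }

    segments[[w]] <- list(
      week = w, t_start = t_w, t_end = t_next, times = seg_times,
      omega = omega_weight(t_hat),
      predicted = pred, measured = meas, band = band,
      P_prediction = P_pred, P_measure = P_measure,
      ccc_well = ccc_well(pred, meas), ccc_pixel = px$ccc_pixel)
  }
  segments <- segments[!vapply(segments, is.null, logical(1))]
  structure(
    list(segments = segments, test_index = test_index,
         dose_nM = test$dose_nM, grid = grid, prior = prior,
         train_fits = train_fits, pre_test = pre_test$pre,
         boundaries = boundaries),
    class = "prediction_trace"
  )
}

# surviving share of a calibrated model's state at a restart time: the
# calibration run (split by fs at the treatment time) is advanced to
# t_target and the per-pixel Ns/(Ns+Nd) ratio extracted. Empty pixels fall
# back to the fitted fs.
fit_split_ratio <- function(fit, t_target) {
  cfg <- fit$cfg
  grid <- fit$grid
  st <- split_population(fit$t0_map, as_field(fit$post$fs, grid),
                         time = fit$t0)
  n_steps <- round((t_target - fit$t0) / cfg$dt)
  for (k in seq_len(n_steps)) {
    st <- step_posttreatment(st, fit$post, cfg, grid)
  }
  tot <- st$Ns + st$Nd
  ratio <- ifelse(tot > 0, st$Ns / pmax(tot, 1e-300), fit$post$fs)
  matrix(pmin(pmax(ratio, 0), 1), grid$n_rows, grid$n_cols)
}

# one random draw from the training prior: one bootstrap parameter set per
# training replicate, averaged (or similarity-transferred) pixelwise
draw_prior_grid <- function(train_fits, train_boots, rng, rankings = NULL,
                            grid = train_fits[[1]]$grid) {
  grids <- lapply(seq_along(train_fits), function(i) {
    f <- train_fits[[i]]
    if (is.null(train_boots)) return(fit_to_grid(f))
    b <- train_boots[[i]]
    j <- max(1L, ceiling(rng$runif(1) * b$n_boot))
    row <- b$samples[j, ]
    param_grid(gs = matrix(b$gs_samples[j, ], grid$n_rows, grid$n_cols),
               fs = row$fs, gd = row$gd, kd = row$kd,
               gamma_d = row$gamma_d, theta = row$theta, grid = grid)
  })
  if (is.null(rankings)) return(build_training_prior(grids))
  mat <- do.call(rbind, lapply(grids, grid_to_matrix))
  transfer_parameters(rankings, mat, grid)
}

draw_fit_grid <- function(fit, boot, rng) {
  grid <- fit$grid
  j <- max(1L, ceiling(rng$runif(1) * boot$n_boot))
  row <- boot$samples[j, ]
  param_grid(gs = matrix(boot$gs_samples[j, ], grid$n_rows, grid$n_cols),
             fs = row$fs, gd = row$gd, kd = row$kd, gamma_d = row$gamma_d,
             theta = row$theta, grid = grid)
}

#' Forecast uncertainty band from sampled parameter grids
#'
#' Draws pairs from the supplied prior and measurement parameter-grid
#' samples, blends each pair with the omega weight at `t_hat`, runs the
#' model forward, and summarizes the per-pixel, per-time forecasts by their
#' mean and 25th-75th percentile band. With degenerate (zero-spread)
#' distributions the band width is zero and the mean equals the point
#' forecast.
#'
#' @param prior_draws List of [param_grid()] samples for the training prior.
#' @param measure_draws List of [param_grid()] samples for the
#'   replicate-specific calibration, or `NULL` (first week: prior only).
#' @param t_hat Normalized time for the blend.
#' @param initial_map,from_time Initial condition of the segment.
#' @param sample_times Times to record.
#' @param cfg A [solver_config()].
#' @param D0 Frozen diffusion coefficient.
#' @param rng_seed Integer seed for pairing the draws.
#' @param split_ratio Optional surviving-share matrix passed to
#'   [predict_week()].
#' @return List with `mean`, `lower`, `upper`: lists of matrices per time.
#' @export
sample_prediction_band <- function(prior_draws, measure_draws, t_hat,
                                   initial_map, from_time, sample_times,
                                   cfg = solver_config(), D0 = 0.0025,
                                   rng_seed = 1L, split_ratio = NULL) {
  n <- length(prior_draws)
  if (n < 4) stop("need at least 4 samples for a band", call. = FALSE)
  grid <- prior_draws[[1]]$grid
  preds <- array(NA_real_, c(n, n_pixels(grid), length(sample_times)))
  for (s in seq_len(n)) {
    pg <- if (is.null(measure_draws)) prior_draws[[s]] else
      blend_parameters(prior_draws[[s]], measure_draws[[s]], t_hat)
    pred <- predict_week(initial_map, pg, from_time, sample_times, cfg, D0,
                         split_ratio = split_ratio)
    preds[s, , ] <- pixel_courses(pred)
  }
  to_maps <- function(m) lapply(seq_len(ncol(m)), function(j)
    matrix(m[, j], grid$n_rows, grid$n_cols))
  list(
    mean = to_maps(apply(preds, c(2, 3), mean)),
    lower = to_maps(apply(preds, c(2, 3), stats::quantile, probs = 0.25)),
    upper = to_maps(apply(preds, c(2, 3), stats::quantile, probs = 0.75)),
    n_samples = n
  )
}

#' @export
print.prediction_trace <- function(x, ...) {
  cat(sprintf("<prediction_trace> dose %g nM, test replicate %d, %d weekly segments\n",
              x$dose_nM, x$test_index, length(x$segments)))
  print(glance(x))
  invisible(x)
}

#' Per-week summary of a prediction trace
#'
#' @param x A `prediction_trace`.
#' @param ... Unused.
#' @return Tibble with one row per weekly segment: start/end times, omega,
#'   and well/pixel concordance of the forecast against the held-out data.
#' @export
tidy.prediction_trace <- function(x, ...) {
  purrr::map_dfr(x$segments, function(s) tibble::tibble(
    week = s$week, t_start_h = s$t_start, t_end_h = s$t_end,
    omega = s$omega, ccc_well = s$ccc_well, ccc_pixel = s$ccc_pixel))
}

#' @export
glance.prediction_trace <- function(x, ...) {
  tw <- tidy(x)
  tibble::tibble(
    dose_nM = x$dose_nM, test_index = x$test_index,
    n_segments = nrow(tw),
    median_ccc_well = stats::median(tw$ccc_well),
    min_ccc_well = min(tw$ccc_well),
    median_ccc_pixel = stats::median(tw$ccc_pixel, na.rm = TRUE))
}

#' Long per-pixel forecasts of a prediction trace
#'
#' @param trace A `prediction_trace`.
#' @return Tibble with `week`, `time_h`, `row`, `col`, `predicted`,
#'   `measured`, and band columns when available.
#' @export
trace_pixels <- function(trace) {
  purrr::map_dfr(trace$segments, function(s) {
    td <- tidy(s$predicted)
    names(td)[names(td) == "count"] <- "predicted"
    td$measured <- tidy(s$measured)$count
    if (!is.null(s$band)) {
      g <- trace$grid
      td$band_lower <- unlist(lapply(s$band$lower, as.vector))
      td$band_upper <- unlist(lapply(s$band$upper, as.vector))
      td$band_mean <- unlist(lapply(s$band$mean, as.vector))
    }
    td$week <- s$week
    td
  })
}
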