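#' Per-pixel treatment-parameter grid
#'
#' The prediction stage lets all six post-treatment parameters vary
#' pixelwise: a parameter grid holds one matrix per parameter over the pixel
#' lattice (scalars are broadcast).
#'
#' @param gs,fs,gd,kd,gamma_d,theta Scalar or matrix parameter fields.
#' @param grid A [grid_spec()].
#' @return A `param_grid` object (named list of matrices + the grid).
#' @export
param_grid <- function(gs, fs, gd, kd, gamma_d, theta, grid = grid_spec()) {
  out <- lapply(list(gs = gs, fs = fs, gd = gd, kd = kd,
                     gamma_d = gamma_d, theta = theta),
                as_field, grid = grid)
  out$grid <- grid
  structure(out, class = "param_grid")
}

#' @export
print.param_grid <- function(x, ...) {
  cat(sprintf("<param_grid> %d x %d pixels; field means:\n",
              x$grid$n_rows, x$grid$n_cols))
  print(vapply(treatment_param_names, function(p) mean(x[[p]]), numeric(1)))
  invisible(x)
}

# expand a calibration fit (local gs + global rest) to a full grid
fit_to_grid <- function(fit) {
  param_grid(gs = fit$post$gs, fs = fit$post$fs, gd = fit$post$gd,
             kd = fit$post$kd, gamma_d = fit$post$gamma_d,
             theta = fit$post$theta, grid = fit$grid)
}

# param_grid -> K x 6 matrix of per-pixel parameter sets (column-major pixels)
grid_to_matrix <- function(pg) {
  vapply(treatment_param_names, function(p) as.vector(pg[[p]]),
         numeric(n_pixels(pg$grid)))
}

matrix_to_grid <- function(m, grid) {
  args <- lapply(treatment_param_names, function(p)
    matrix(m[, p], grid$n_rows, grid$n_cols))
  names(args) <- treatment_param_names
  do.call(param_grid, c(args, list(grid = grid)))
}

#' Average training calibrations into a population prior
#'
#' Pixelwise arithmetic mean, parameter by parameter, of the parameter grids
#' of the training-set calibrations (one fully calibrated replicate each).
#' The result is the population parameter set used to forecast the held-out
#' replicate's first post-treatment week.
#'
#' @param fits List of `calibration_fit` objects (or `param_grid`s) on a
#'   shared grid; the canonical training set has five.
#' @return A [param_grid()].
#' @export
build_training_prior <- function(fits) {
  grids <- lapply(fits, function(f)
    if (inherits(f, "calibration_fit")) fit_to_grid(f) else f)
  g0 <- grids[[1]]$grid
  for (g in grids) {
    if (g$grid$n_rows != g0$n_rows || g$grid$n_cols != g0$n_cols) {
      stop("training calibrations are on mismatched grids", call. = FALSE)
    }
  }
  mats <- lapply(treatment_param_names, function(p)
    Reduce(`+`, lapply(grids, `[[`, p)) / length(grids))
  names(mats) <- treatment_param_names
  do.call(param_grid, c(mats, list(grid = g0)))
}

#' Forecast one weekly segment
#'
#' Runs the two-phenotype model forward from a measured total map with a
#' fully pixelwise parameter grid: the map is split into surviving/damaged
#' compartments by the grid's `fs` field, and the death-delay clock stays
#' anchored at the treatment time.
#'
#' @param initial_map Measured total cell-count matrix at `from_time`.
#' @param params A [param_grid()].
#' @param from_time Start of the segment, hours.
#' @param sample_times Times at which to record predictions (all
#'   `> from_time`... or equal).
#' @param cfg A [solver_config()] (provides `dt` and `t_dox`).
#' @param D0 Diffusion coefficient (frozen pre-treatment estimate), mm^2/h.
#' @param split_ratio Optional matrix of the surviving share of
#'   `initial_map` at `from_time`. At the treatment time the share is the
#'   parameter grid's `fs` (the default); at later restart times the
#'   surviving share has evolved away from `fs`, and callers (the weekly
#'   pipeline) supply the calibrated model state's ratio instead.
#' @return A [well_series()] of predicted total maps at `sample_times`.
#' @export
predict_week <- function(initial_map, params, from_time, sample_times,
                         cfg = solver_config(), D0 = 0.0025,
                         split_ratio = NULL) {
  grid <- params$grid
  tp <- treatment_params(gs = params$gs, fs = params$fs, gd = params$gd,
                         kd = params$kd, gamma_d = params$gamma_d,
                         theta = params$theta, Ds = D0, Dd = D0)
  if (!is.null(split_ratio)) tp$fs <- split_ratio
  pred <- post_sim_ntot(initial_map, tp, from_time, sample_times, cfg,
                        grid, drug_age0 = from_time - cfg$t_dox)
  well_series(lapply(seq_along(sample_times), function(j)
    matrix(pred[, j], grid$n_rows, grid$n_cols)),
    sample_times, grid, t_dox_h = cfg$t_dox)
}


#' Rank training pixels by concordance with a test pixel's time course
#'
#' Computes the concordance correlation coefficient between the test pixel's
#' cell-count course and every training pixel's course over the shared
#' window, sorts descending (stable: ties keep training-pixel order, which
#' encodes replicate then row then column), selects the top 25% (ceiling),
#' and assigns similarity weights proportional to CCC. If the test course
#' has zero variance, or the selected CCCs sum to a non-positive value, the
#' ranking is flagged degenerate and uniform weights are used.
#'
#' @param test_course Numeric vector: the test pixel's counts over the
#'   window.
#' @param training_courses Matrix, one row per training pixel, columns
#'   aligned with `test_course`.
#' @param frac Selection fraction (0.25: a 5-replicate 15 x 15 training set
#'   gives ceiling(0.25 * 1125) = 282 selected pixels).
#' @return A `similarity_ranking`: tibble (`pixel_id`, `ccc`, `rank`,
#'   `selected`, `weight`) plus `n_selected` and `degenerate` fields.
#' @export
rank_similar_pixels <- function(test_course, training_courses, frac = 0.25) {
  stopifnot(length(test_course) >= 2,
            ncol(training_courses) == length(test_course))
  K <- nrow(training_courses)
  scores <- ccc_rows(training_courses, test_course)
  scores[is.na(scores)] <- 0
  degenerate <- stats::var(test_course) == 0
  ord <- order(-scores)  # stable: ties keep ascending pixel_id
  n_sel <- as.integer(ceiling(frac * K))
  sel_ids <- ord[seq_len(n_sel)]
  w <- rep(0, K)
  sel_sum <- sum(scores[sel_ids])
  if (degenerate || sel_sum <= 0) {
    degenerate <- TRUE
    w[sel_ids] <- 1 / n_sel
  } else {
    w[sel_ids] <- scores[sel_ids] / sel_sum
  }
  ranking <- tibble::tibble(
    pixel_id = seq_len(K), ccc = scores,
    rank = match(seq_len(K), ord),
    selected = seq_len(K) %in% sel_ids,
    weight = w)
  structure(list(ranking = ranking, n_selected = n_sel,
                 degenerate = degenerate),
            class = "similarity_ranking")
}

#' @export
print.similarity_ranking <- function(x, ...) {
  cat(sprintf("<similarity_ranking> %d of %d training pixels selected%s\n",
              x$n_selected, nrow(x$ranking),
              if (x$degenerate) " (degenerate: uniform weights)" else ""))
  invisible(x)
}

#' Transfer training parameters to test pixels by similarity weights
#'
#' For each test pixel, the selected training pixels' parameter sets are
#' averaged with the similarity weights, giving a fully pixelwise parameter
#' grid for the next weekly forecast.
#'
#' @param rankings List of [rank_similar_pixels()] results, one per test
#'   pixel in column-major order.
#' @param training_params Matrix of training per-pixel parameter sets
#'   (rows = training pixels, columns gs, fs, gd, kd, gamma_d, theta), e.g.
#'   stacked [grid_to_matrix()] outputs of the training fits.
#' @param grid The test replicate's [grid_spec()].
#' @return A [param_grid()].
#' @export
transfer_parameters <- function(rankings, training_params,
                                grid = grid_spec()) {
  stopifnot(length(rankings) == n_pixels(grid))
  W <- t(vapply(rankings, function(r) r$ranking$weight,
                numeric(nrow(training_params))))
  if (any(abs(rowSums(W) - 1) > 1e-8)) {
    stop("similarity weights must sum to 1 for every test pixel",
         call. = FALSE)
  }
  matrix_to_grid(W %*% training_params, grid)
}

#' Assimilation blending weight
#'
#' The quadratic schedule `omega(t_hat) = 0.6 t_hat^2 - 1.2 t_hat + 1`,
#' strictly decreasing from 1 at the treatment time to 0.4 at the reference
#' end time, shifting trust from the population prior to the
#' replicate-specific calibration as the experiment progresses.
#'
#' @param t_hat Normalized time in \[0, 1\] (hours divided by the reference
#'   horizon, 963 h for the longest experiment).
#' @return The blending weight in \[0.4, 1\].
#' @export
omega_weight <- function(t_hat) {
  if (any(t_hat < 0 | t_hat > 1)) {
    stop("`t_hat` must lie in [0, 1]", call. = FALSE)
  }
  0.6 * t_hat^2 - 1.2 * t_hat + 1.0
}

#' Blend the training prior with the replicate-specific estimate
#'
#' Elementwise convex combination
#' `P_prediction = omega * P_training + (1 - omega) * P_measure`, so blended
#' parameters always lie between the two inputs (and hence within bounds).
#'
#' @param P_training,P_measure [param_grid()]s of identical shape.
#' @param t_hat Normalized time passed to [omega_weight()].
#' @return The blended [param_grid()].
#' @export
blend_parameters <- function(P_training, P_measure, t_hat) {
  if (P_training$grid$n_rows != P_measure$grid$n_rows ||
      P_training$grid$n_cols != P_measure$grid$n_cols) {
    stop("parameter grids have mismatched shapes", call. = FALSE)
  }
  w <- omega_weight(t_hat)
  mats <- lapply(treatment_param_names, function(p)
    w * P_training[[p]] + (1 - w) * P_measure[[p]])
  names(mats) <- treatment_param_names
  do.call(param_grid, c(mats, list(grid = P_training$grid)))
}
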