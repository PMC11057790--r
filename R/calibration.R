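# ---- internal: unit-scaled parameterization -------------------------------
# Optimization runs on [0,1]^k; parameters map affinely onto their bounds.

unit_to_nat <- function(x, lower, upper) lower + x * (upper - lower)
nat_to_unit <- function(p, lower, upper) (p - lower) / (upper - lower)

# fast post-treatment forward run (compiled core) recording total maps at
# measurement times; t0 is the initial-condition time and drug_age0 =
# t0 - t_dox keeps the death-delay clock anchored at the treatment time
# across weekly restarts. Every parameter field may be scalar or pixelwise.
post_sim_ntot <- function(N0, params, t0, times, cfg, grid, drug_age0 = 0) {
  assert_stable(max(params$Ds, params$Dd), cfg, grid)
  th <- as_field(theta_pixel(params$theta, grid, cfg), grid)
  Ns0 <- as_field(params$fs, grid) * N0
  Nd0 <- N0 - Ns0
  snapped <- as.integer(round((times - t0) / cfg$dt))
  cpp_post_sim(Ns0, Nd0, as_field(params$gs, grid), as_field(params$gd, grid),
               as_field(params$kd, grid), as_field(params$gamma_d, grid),
               th, params$Ds, params$Dd, grid$pixel_size / 1000, cfg$dt,
               max(snapped, 0L), snapped, drug_age0, cfg$clip_negative)
}

# index of the measurement used as post-treatment initial condition
t0_index <- function(series) {
  idx <- which(series$times <= series$t_dox_h + 1e-8)
  if (!length(idx)) stop("no measurement at or before t_dox", call. = FALSE)
  max(idx)
}

#' Calibrate the pre-treatment growth parameters
#'
#' Joint bounded least-squares fit of the global proliferation rate `g0` and
#' diffusion coefficient `D0` to all pixel time courses measured before the
#' treatment time. The first pre-treatment map provides the initial
#' condition. `D0` is subsequently frozen: diffusion is calibrated in the
#' pre-treatment phase only and fixed afterwards.
#'
#' @param series A [well_series()] with at least three pre-treatment
#'   time points.
#' @param bounds A [param_bounds()] tibble.
#' @param cfg A [solver_config()].
#' @return A list with `pre` (a [pretreatment_params()]), `residuals`,
#'   `converged` and `n_iter`.
#' @export
calibrate_pretreatment <- function(series, bounds = param_bounds(),
                                   cfg = solver_config(t_dox = series$t_dox_h)) {
  idx <- pre_idx(series)
  if (length(idx) < 3L) {
    stop("need at least 3 pre-treatment time points", call. = FALSE)
  }
  N0 <- series$maps[[idx[1]]]
  t0 <- series$times[idx[1]]
  fit_times <- series$times[idx[-1]]
  data_mat <- pixel_courses(series, idx[-1])
  grid <- series$grid
  lo <- c(bounds_for(bounds, "g0")[1], bounds_for(bounds, "D0")[1])
  hi <- c(bounds_for(bounds, "g0")[2], bounds_for(bounds, "D0")[2])
  snapped <- as.integer(round((fit_times - t0) / cfg$dt))
  resid_fn <- function(x) {
    p <- unit_to_nat(x, lo, hi)
    out <- cpp_pre_sim(N0, p[1], p[2], grid$pixel_size / 1000, cfg$dt,
                       max(snapped), snapped, cfg$clip_negative)
    as.vector(out - data_mat)
  }
  fit <- minpack.lm::nls.lm(
    par = rep(0.5, 2), lower = rep(0, 2), upper = rep(1, 2), fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10,
                                         ptol = 1e-10))
  p <- unit_to_nat(fit$par, lo, hi)
  list(pre = pretreatment_params(g0 = p[1], D0 = p[2]),
       residuals = fit$fvec, converged = fit$info %in% 1:4,
       n_iter = fit$niter)
}

# assemble a treatment_params from the flat free-parameter vector
build_post_params <- function(par, free_px, gs_fixed, frozen, grid, bounds) {
  npx <- n_pixels(grid)
  gs_vec <- rep(bounds_for(bounds, "gs")[1], npx)
  gs_vec[free_px] <- par[seq_along(free_px)]
  if (length(gs_fixed)) gs_vec[gs_fixed$px] <- gs_fixed$value
  gl <- par[length(free_px) + 1:5]
  treatment_params(
    gs = matrix(gs_vec, grid$n_rows, grid$n_cols),
    fs = gl[1], kd = gl[2], gd = gl[3], gamma_d = gl[4], theta = gl[5],
    Ds = frozen$D0, Dd = frozen$D0)
}

#' Residual vector of the post-treatment least-squares objective
#'
#' Concatenated (model - data) misfit over every pixel and every measurement
#' time strictly after the treatment time. The model run starts from the
#' measured map at the treatment time, split by `fs`, with diffusion frozen
#' at the pre-treatment estimate. Only the total count enters: the
#' surviving/damaged split is latent.
#'
#' @param par Flat parameter vector in natural units: the free per-pixel
#'   `gs` values followed by `(fs, kd, gd, gamma_d, theta)`.
#' @param series A [well_series()].
#' @param frozen A [pretreatment_params()] providing the frozen `D0`.
#' @param cfg A [solver_config()].
#' @param free_px Indices (column-major) of pixels whose `gs` is free;
#'   defaults to all pixels with a non-constant-zero course.
#' @param bounds A [param_bounds()] tibble.
#' @return Numeric residual vector of length `n_pixels * n_post_times`.
#' @export
objective_residuals <- function(par, series, frozen,
                                cfg = solver_config(t_dox = series$t_dox_h),
                                free_px = free_pixels(series),
                                bounds = param_bounds()) {
  i0 <- t0_index(series)
  idx <- post_idx(series)
  params <- build_post_params(par, free_px, NULL, frozen, series$grid, bounds)
  model <- post_sim_ntot(series$maps[[i0]], params, series$times[i0],
                         series$times[idx], cfg, series$grid)
  as.vector(model - pixel_courses(series, idx))
}

# pixels with any signal after treatment (all-zero courses get gs pinned at
# the lower bound and are excluded from the fit and from CCC_pixel)
free_pixels <- function(series) {
  idx <- post_idx(series, include_tdox = TRUE)
  courses <- pixel_courses(series, idx)
  which(rowSums(courses) > 0)
}

#' Calibrate the post-treatment two-phenotype model
#'
#' Bounded nonlinear least squares over the per-pixel surviving
#' proliferation rates `gs` (the only locally calibrated parameter) plus the
#' five global parameters `(fs, kd, gd, gamma_d, theta)`, the carrying
#' capacity restricted to its narrow physical range. The optimizer is a
#' box-constrained Levenberg-Marquardt run on unit-scaled parameters;
#' initial guesses are the bound midpoints for the globals and the
#' pre-treatment `g0` for every pixel's `gs`.
#'
#' @param series A [well_series()] with post-treatment measurements.
#' @param bounds A [param_bounds()] tibble.
#' @param frozen A [pretreatment_params()] (from
#'   [calibrate_pretreatment()]); its `D0` is fixed during this fit.
#' @param cfg A [solver_config()].
#' @param init Optional `calibration_fit` or flat natural-unit vector used
#'   to warm-start the optimizer (used by the bootstrap and the weekly
#'   assimilation refits).
#' @param maxiter Iteration cap.
#' @param polish Run the coordinate-profile polish after the joint fit: the
#'   damaged-population parameters ride a curved compensation ridge on which
#'   Levenberg-Marquardt stalls short of the optimum, so each of
#'   `gamma_d, kd, gd, theta, fs` is swept over a small bracket with all
#'   other parameters re-fitted warm, following the valley floor. Defaults
#'   to `TRUE` for cold fits and `FALSE` for warm-started refits.
#' @param polish_cycles Maximum polish sweeps.
#' @return A `calibration_fit` object: fitted `pre`/`post` parameters,
#'   residuals, fitted model maps, `ccc_well`/`ccc_pixel` scores,
#'   convergence flag, iteration count and the objective trace.
#' @export
calibrate_posttreatment <- function(series, bounds = param_bounds(),
                                    frozen,
                                    cfg = solver_config(t_dox = series$t_dox_h),
                                    init = NULL, maxiter = 500,
                                    polish = is.null(init),
                                    polish_cycles = 2) {
  idx <- post_idx(series)
  if (!length(idx)) stop("no post-treatment time points", call. = FALSE)
  grid <- series$grid
  free_px <- free_pixels(series)
  n_free <- length(free_px)
  gs_b <- bounds_for(bounds, "gs")
  glob <- c("fs", "kd", "gd", "gamma_d", "theta")
  glob_b <- vapply(glob, function(p) bounds_for(bounds, p), numeric(2))
  lo <- c(rep(gs_b[1], n_free), glob_b[1, ])
  hi <- c(rep(gs_b[2], n_free), glob_b[2, ])

  i0 <- t0_index(series)
  data_mat <- pixel_courses(series, idx)
  resid_fn <- function(x) {
    par <- unit_to_nat(x, lo, hi)
    params <- build_post_params(par, free_px, NULL, frozen, grid, bounds)
    model <- post_sim_ntot(series$maps[[i0]], params, series$times[i0],
                           series$times[idx], cfg, grid)
    as.vector(model - data_mat)
  }

  run_lm <- function(x0, iter = maxiter) {
    # iteration-cap chatter is expected for capped warm refits; the
    # `converged` flag on the result records it
    suppressWarnings(minpack.lm::nls.lm(
      par = x0, lower = rep(0, length(x0)), upper = rep(1, length(x0)),
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = iter, ftol = 1e-8,
                                           ptol = 1e-8, gtol = 1e-8)))
  }
  if (is.null(init)) {
    # Stage 1 — coarse global search. The least-squares surface has a broad
    # degenerate basin (all cells surviving, fs = 1) that captures local
    # optimizers started from generic guesses, so the globals are screened on
    # a deterministic grid: for each (fs, kd, gamma_d) candidate the local gs
    # field is composed pixel by pixel from a ladder of uniform-gs forward
    # runs (pixels decouple at the small diffusion rates of this system),
    # and the best-scoring candidates seed the full local fit.
    cand <- stage_a_search(series, frozen, bounds, cfg, free_px,
                           data_mat, idx, i0)
    fits <- lapply(cand, function(par0) run_lm(nat_to_unit(par0, lo, hi)))
    devs <- vapply(fits, `[[`, numeric(1), "deviance")
    # same parsimony tie-break as the screen: equal-fit solutions resolve
    # to the largest surviving fraction
    tied <- devs <= min(devs) * (1 + 1e-6) + 1e-6 * mean(data_mat^2)
    fs_vals <- vapply(fits, function(f)
      unit_to_nat(f$par, lo, hi)[n_free + 1], numeric(1))
    fit <- fits[tied][[which.max(fs_vals[tied])]]
  } else {
    par0 <- if (inherits(init, "calibration_fit")) flat_par(init, free_px) else init
    fit <- run_lm(pmin(pmax(nat_to_unit(par0, lo, hi), 0), 1))
  }
  if (polish) {
    x <- fit$par
    dev <- fit$deviance
    dev_floor <- 1e-16 * sum(data_mat^2)
    min_gain <- function(d) 1e-9 * d
    prof_ids <- n_free + c(4, 2, 3, 5, 1)  # gamma_d, kd, gd, theta, fs
    for (cycle in seq_len(polish_cycles)) {
      dev_in <- dev
      for (pid in prof_ids) {
        if (dev < dev_floor) break
        for (cu in unique(pmin(pmax(x[pid] + c(-0.12, -0.05, 0.05, 0.12), 0), 1))) {
          xx <- x
          xx[pid] <- cu
          mask <- seq_along(x) != pid
          rfix <- function(xm) {
            xs <- xx
            xs[mask] <- xm
            resid_fn(xs)
          }
          f2 <- suppressWarnings(minpack.lm::nls.lm(
            par = xx[mask], lower = rep(0, sum(mask)),
            upper = rep(1, sum(mask)), fn = rfix,
            control = minpack.lm::nls.lm.control(maxiter = 25, ftol = 1e-10,
                                                 ptol = 1e-10)))
          if (dev - f2$deviance > min_gain(dev)) {
            dev <- f2$deviance
            x <- xx
            x[mask] <- f2$par
          }
        }
      }
      if (dev < dev_floor || dev > dev_in * (1 - 1e-6)) break
    }
    f3 <- suppressWarnings(run_lm(x, iter = 100))
    if (f3$deviance <= dev) {
      fit <- f3
    } else {
      fit$par <- x
      fit$fvec <- resid_fn(x)
      fit$deviance <- dev
      fit$rsstrace <- c(fit$rsstrace, dev)
    }
  }
  par <- unit_to_nat(fit$par, lo, hi)
  post <- build_post_params(par, free_px, NULL, frozen, grid, bounds)
  model <- post_sim_ntot(series$maps[[i0]], post, series$times[i0],
                         series$times[idx], cfg, grid)
  model_series <- well_series(
    lapply(seq_along(idx), function(j) matrix(model[, j], grid$n_rows, grid$n_cols)),
    series$times[idx], grid, dose_nM = series$dose_nM,
    t_dox_h = series$t_dox_h, replicate_id = series$replicate_id)
  data_series <- well_series(series$maps[idx], series$times[idx], grid,
                             dose_nM = series$dose_nM,
                             t_dox_h = series$t_dox_h,
                             replicate_id = series$replicate_id)
  px <- ccc_pixel(model_series, data_series)
  structure(
    list(pre = frozen, post = post, residuals = fit$fvec,
         fitted = model, fit_times = series$times[idx],
         t0 = series$times[i0], t0_map = series$maps[[i0]],
         free_px = free_px, bounds = bounds, cfg = cfg, grid = grid,
         ccc_well = ccc_well(model_series, data_series),
         ccc_pixel = px$ccc_pixel, n_pixels_included = px$n_included,
         converged = fit$info %in% 1:4, n_iter = fit$niter,
         rss_trace = fit$rsstrace, deviance = fit$deviance,
         series_meta = list(dose_nM = series$dose_nM,
                            replicate_id = series$replicate_id,
                            t_dox_h = series$t_dox_h)),
    class = "calibration_fit"
  )
}

# Stage-A global search over the post-treatment parameters.
#
# The joint least-squares surface has a broad degenerate basin (fs = 1, all
# cells surviving) plus a curved compensation ridge between the damaged-
# population parameters (gd, kd, gamma_d), so a purely local optimizer from
# generic starts is unreliable. The search proceeds in three cheap phases,
# all built on the compiled forward solver:
#   1. screen a deterministic candidate grid covering the (fs, kd, gamma_d,
#      gd) bounds; for each candidate the local gs field is composed pixel
#      by pixel from a ladder of uniform-gs forward runs (pixels are nearly
#      decoupled at this system's small diffusion coefficients);
#   2. refine the best candidates by block-coordinate descent, alternating
#      a bounded LM fit of the five globals (gs frozen) with a
#      multiplicative per-pixel refinement of the gs field;
#   3. return the top few as warm starts for the joint local fit.
stage_a_search <- function(series, frozen, bounds, cfg, free_px,
                           data_mat, idx, i0, n_screen = 6, n_keep = 2) {
  grid <- series$grid
  gs_b <- bounds_for(bounds, "gs")
  th_b <- bounds_for(bounds, "theta")
  th_mid <- mean(th_b)
  gamma_b <- bounds_for(bounds, "gamma_d")
  npx <- n_pixels(grid)

  sim_rss <- function(gs_field, fs, kd, gd, gamma_d, theta) {
    params <- treatment_params(gs = gs_field, fs = fs, gd = gd, kd = kd,
                               gamma_d = gamma_d, theta = theta,
                               Ds = frozen$D0, Dd = frozen$D0)
    model <- post_sim_ntot(series$maps[[i0]], params, series$times[i0],
                           series$times[idx], cfg, grid)
    rowSums((model - data_mat)^2)
  }

  # phase 1: candidate screen with ladder-composed gs fields; the frozen
  # pre-treatment g0 joins the ladder (surviving cells continuing at their
  # untreated rate is the natural reference point)
  gs_ladder <- sort(unique(c(
    exp(seq(log(gs_b[1]), log(gs_b[2]), length.out = 16)),
    min(max(frozen$g0, gs_b[1]), gs_b[2]))))
  cand <- expand.grid(
    fs = c(0.05, 0.2, 0.35, 0.5, 0.65, 0.8, 0.95, 1),
    kd = c(0.001, 0.0037, 0.0065, 0.0095),
    gamma_d = exp(seq(log(gamma_b[1]), log(gamma_b[2]), length.out = 4)),
    gd = c(0.002, 0.008))
  scored <- lapply(seq_len(nrow(cand)), function(ci) {
    cc <- cand[ci, ]
    per_px <- vapply(gs_ladder, function(gsv)
      sim_rss(matrix(gsv, grid$n_rows, grid$n_cols), cc$fs, cc$kd, cc$gd,
              cc$gamma_d, th_mid), numeric(npx))
    best_j <- max.col(-per_px, ties.method = "first")
    gs_field <- matrix(gs_b[1], grid$n_rows, grid$n_cols)
    gs_field[free_px] <- gs_ladder[best_j][free_px]
    list(rss = sum(per_px[cbind(seq_len(npx), best_j)]),
         gs = gs_field, glob = c(cc$fs, cc$kd, cc$gd, cc$gamma_d, th_mid))
  })
  # ordering with a parsimony tie-break: when candidates fit equally well
  # (untreated wells, where the damaged compartment can mimic the surviving
  # one), prefer the largest surviving fraction — no drug effect is invoked
  # without evidence
  order_cand <- function(items) {
    rss <- vapply(items, `[[`, numeric(1), "rss")
    fs_of <- vapply(items, function(s) s$glob[1], numeric(1))
    thresh <- min(rss) * (1 + 1e-6) + 1e-6 * mean(data_mat^2)
    order(rss > thresh, rss * (rss > thresh) - fs_of * (rss <= thresh))
  }
  top <- scored[order_cand(scored)[seq_len(min(n_screen, length(scored)))]]

  # phase 2: block-coordinate refinement of the screened candidates
  glob_names <- c("fs", "kd", "gd", "gamma_d", "theta")
  g_lo <- vapply(glob_names, function(p) bounds_for(bounds, p)[1], numeric(1))
  g_hi <- vapply(glob_names, function(p) bounds_for(bounds, p)[2], numeric(1))
  refined <- lapply(top, function(s) {
    gs_field <- s$gs
    glob <- s$glob
    for (round in 1:2) {
      rg <- function(xu) {
        p <- unit_to_nat(xu, g_lo, g_hi)
        params <- treatment_params(gs = gs_field, fs = p[1], kd = p[2],
                                   gd = p[3], gamma_d = p[4], theta = p[5],
                                   Ds = frozen$D0, Dd = frozen$D0)
        model <- post_sim_ntot(series$maps[[i0]], params, series$times[i0],
                               series$times[idx], cfg, grid)
        as.vector(model - data_mat)
      }
      fb <- suppressWarnings(minpack.lm::nls.lm(
        par = pmin(pmax(nat_to_unit(c(glob[1], glob[2], glob[3], glob[4],
                                      glob[5]), g_lo, g_hi), 0), 1),
        lower = rep(0, 5), upper = rep(1, 5), fn = rg,
        control = minpack.lm::nls.lm.control(maxiter = 80, ftol = 1e-10,
                                             ptol = 1e-10)))
      glob <- unit_to_nat(fb$par, g_lo, g_hi)
      for (it in 1:3) {
        fac <- c(0.7, 0.85, 0.95, 1, 1.05, 1.15, 1.4)
        rssmat <- vapply(fac, function(f)
          sim_rss(pmin(pmax(gs_field * f, gs_b[1]), gs_b[2]), glob[1],
                  glob[2], glob[3], glob[4], glob[5]), numeric(npx))
        gs_field[] <- pmin(pmax(gs_field * fac[max.col(-rssmat, ties.method = "first")],
                                gs_b[1]), gs_b[2])
      }
      gs_field[-free_px] <- gs_b[1]
      if (length(free_px) == npx) gs_field <- pmin(pmax(gs_field, gs_b[1]), gs_b[2])
    }
    rss <- sum(sim_rss(gs_field, glob[1], glob[2], glob[3], glob[4], glob[5]))
    list(rss = rss, gs = gs_field, glob = glob)
  })
  ord2 <- order_cand(refined)
  lapply(refined[ord2[seq_len(min(n_keep, length(refined)))]], function(s)
    c(as.vector(s$gs)[free_px], s$glob))
}

flat_par <- function(fit, free_px = fit$free_px) {
  c(as.vector(fit$post$gs)[free_px],
    fit$post$fs, fit$post$kd, fit$post$gd, fit$post$gamma_d, fit$post$theta)
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "<calibration_fit> %g nM replicate %s: CCC_well %.4f, CCC_pixel %.4f",
    " (%d px), %sconverged in %d iterations\n"),
    x$series_meta$dose_nM, as.character(x$series_meta$replicate_id),
    x$ccc_well, x$ccc_pixel, x$n_pixels_included,
    if (x$converged) "" else "NOT ", x$n_iter))
  invisible(x)
}

#' Residual-bootstrap uncertainty of a calibration
#'
#' Estimates a single pooled Gaussian noise level from the calibration
#' residuals, repeatedly adds freshly sampled noise to the fitted model
#' curve, refits (warm-started at the original fit), and collects the
#' resulting parameter sets. Precision is summarized per parameter by the
#' mean, interquartile range and normalized standard deviation
#' (NSD = sd / mean); the local `gs` field is summarized through its
#' spatial mean.
#'
#' @param series The calibrated [well_series()].
#' @param result The [calibrate_posttreatment()] fit.
#' @param n_boot Number of bootstrap samples (>= 2; 100 by default).
#' @param rng_seed Integer seed.
#' @param maxiter Iteration cap of each refit.
#' @return A `bootstrap_dist`: `samples` tibble (one row per bootstrap
#'   sample: fs, kd, gd, gamma_d, theta, gs_mean), `gs_samples` matrix
#'   (sample x pixel), and a `summary` tibble with mean/IQR/NSD.
#' @export
bootstrap_calibration <- function(series, result, n_boot = 100, rng_seed = 1L,
                                  maxiter = 50) {
  if (n_boot < 2) stop("`n_boot` must be >= 2", call. = FALSE)
  if (!result$converged) {
    warning("bootstrapping a non-converged calibration", call. = FALSE)
  }
  rng <- local_rng(rng_seed)
  sigma <- stats::sd(result$residuals)
  idx <- post_idx(series)
  grid <- series$grid
  npx <- n_pixels(grid)
  samples <- vector("list", n_boot)
  gs_samples <- matrix(NA_real_, n_boot, npx)
  for (b in seq_len(n_boot)) {
    noisy <- result$fitted +
      matrix(rng$rnorm(length(result$fitted), 0, sigma),
             nrow(result$fitted), ncol(result$fitted))
    noisy <- pmax(noisy, 0)
    maps <- c(list(result$t0_map),
              lapply(seq_along(idx), function(j)
                matrix(noisy[, j], grid$n_rows, grid$n_cols)))
    boot_series <- well_series(maps, c(result$t0, series$times[idx]), grid,
                               dose_nM = series$dose_nM,
                               t_dox_h = series$t_dox_h,
                               replicate_id = series$replicate_id)
    refit <- calibrate_posttreatment(boot_series, result$bounds, result$pre,
                                     result$cfg, init = result,
                                     maxiter = maxiter)
    gs_samples[b, ] <- as.vector(refit$post$gs)
    samples[[b]] <- tibble::tibble(
      sample = b, fs = refit$post$fs, kd = refit$post$kd, gd = refit$post$gd,
      gamma_d = refit$post$gamma_d, theta = refit$post$theta,
      gs_mean = mean(as.vector(refit$post$gs)[result$free_px]))
  }
  samples <- dplyr::bind_rows(samples)
  long <- tidyr::pivot_longer(samples, -"sample",
                              names_to = "parameter", values_to = "value")
  summary <- dplyr::summarise(
    dplyr::group_by(long, .data$parameter),
    mean = mean(.data$value),
    iqr = stats::IQR(.data$value),
    nsd = stats::sd(.data$value) / abs(mean(.data$value)),
    .groups = "drop")
  structure(list(samples = samples, gs_samples = gs_samples,
                 summary = summary, sigma = sigma, n_boot = n_boot),
            class = "bootstrap_dist")
}

#' @export
print.bootstrap_dist <- function(x, ...) {
  cat(sprintf("<bootstrap_dist> %d samples, pooled residual sd %.3g\n",
              x$n_boot, x$sigma))
  print(x$summary)
  invisible(x)
}
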