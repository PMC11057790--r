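# scalar quality-of-interest: terminal total well count of the model run
# with every post-treatment parameter spatially uniform. Uniform fields make
# diffusion a no-op, so each evaluation reduces to a scalar forward-Euler
# recurrence and thousands of evaluations vectorize across one time loop.
qoi_terminal_count <- function(X, pre = pretreatment_params(),
                               grid = grid_spec(), cfg = solver_config(),
                               seed_cells = 2000, t_end = 500) {
  npx <- n_pixels(grid)
  n_pre <- round(cfg$t_dox / cfg$dt)
  n_post <- round((t_end - cfg$t_dox) / cfg$dt)
  N_px <- (seed_cells / npx) * (1 + pre$g0 * cfg$dt)^n_pre
  gs <- X[, "gs"]; fs <- X[, "fs"]; gd <- X[, "gd"]; kd <- X[, "kd"]
  gamma_d <- X[, "gamma_d"]; th <- X[, "theta"] / npx
  Ns <- fs * N_px
  Nd <- (1 - fs) * N_px
  for (k in 0:(n_post - 1)) {
    crowd <- 1 - (Ns + Nd) / th
    rate_d <- gd + kd * exp(-gamma_d * k * cfg$dt) - kd
    Ns <- pmax(Ns + cfg$dt * gs * Ns * crowd, 0)
    Nd <- pmax(Nd + cfg$dt * rate_d * Nd * crowd, 0)
  }
  npx * (Ns + Nd)
}

#' Variance-based total-effect sensitivity indices
#'
#' Sobol total-effect indices S_T of the post-treatment model output with
#' respect to its six parameters, estimated with the Jansen formula on a
#' Saltelli-style design: two independent uniform sample matrices A and B of
#' `n_base` rows each plus the six hybrid matrices AB_i, for a total budget
#' of `n_base * 8` model evaluations (the default `n_base = 625` gives 5000).
#' The model output is the terminal total well count with all parameters
#' spatially uniform. This is the screening that justified calibrating only
#' the surviving proliferation rate locally: `gs` and the carrying capacity
#' `theta` dominate the output variance when `theta` is sampled over its
#' wide screening range.
#'
#' @param bounds Bounds tibble (rows for gs, fs, gd, kd, gamma_d, theta);
#'   the default samples `theta` wide, see [param_bounds()].
#' @param n_base Base sample size (>= 64 recommended; smaller budgets
#'   trigger a wide-confidence-interval warning).
#' @param rng_seed Integer seed.
#' @param model_fn Function mapping an `n x 6` parameter matrix (columns
#'   gs, fs, gd, kd, gamma_d, theta) to a numeric output vector. Defaults to
#'   the terminal-count model above; tests substitute analytic toys here to
#'   validate the estimator.
#' @param ... Passed to the default `model_fn`
#'   (`pre`, `grid`, `cfg`, `seed_cells`, `t_end`).
#' @return A `sensitivity_result`: tibble of indices, evaluation count and
#'   output definition.
#' @export
total_effect_indices <- function(bounds = param_bounds(wide_theta = TRUE),
                                 n_base = 625, rng_seed = 1L,
                                 model_fn = NULL, ...) {
  pars <- treatment_param_names
  stopifnot(all(pars %in% bounds$parameter))
  if (n_base < 2) stop("`n_base` must be >= 2", call. = FALSE)
  low_ci <- n_base < 64
  k <- length(pars)
  rng <- local_rng(rng_seed)
  lo <- vapply(pars, function(p) bounds_for(bounds, p)[1], numeric(1))
  hi <- vapply(pars, function(p) bounds_for(bounds, p)[2], numeric(1))
  draw <- function() {
    m <- matrix(rng$runif(n_base * k), n_base, k)
    m <- sweep(sweep(m, 2, hi - lo, `*`), 2, lo, `+`)
    colnames(m) <- pars
    m
  }
  A <- draw(); B <- draw()
  f <- if (is.null(model_fn)) {
    function(X) qoi_terminal_count(X, ...)
  } else {
    model_fn
  }
  fA <- f(A); fB <- f(B)
  V <- stats::var(c(fA, fB))
  st <- vapply(seq_len(k), function(i) {
    ABi <- A
    ABi[, i] <- B[, i]
    fABi <- f(ABi)
    mean((fA - fABi)^2) / (2 * V)
  }, numeric(1))
  n_eval <- n_base * (k + 2)
  if (low_ci) {
    warning(sprintf(
      "n_base = %d is small; total-effect estimates will have wide Monte-Carlo confidence intervals",
      n_base), call. = FALSE)
  }
  structure(
    list(indices = tibble::tibble(parameter = pars, total_effect = st),
         n_evaluations = n_eval, n_base = n_base,
         output_definition = "terminal total cell count of the well",
         low_confidence = low_ci),
    class = "sensitivity_result"
  )
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("<sensitivity_result> %d model evaluations; output: %s\n",
              x$n_evaluations, x$output_definition))
  print(dplyr::arrange(x$indices, dplyr::desc(.data$total_effect)))
  invisible(x)
}

#' @export
tidy.sensitivity_result <- function(x, ...) {
  dplyr::arrange(x$indices, dplyr::desc(.data$total_effect))
}

#' @export
glance.sensitivity_result <- function(x, ...) {
  tibble::tibble(n_evaluations = x$n_evaluations, n_base = x$n_base,
                 top_parameter = x$indices$parameter[
                   which.max(x$indices$total_effect)],
                 low_confidence = x$low_confidence)
}
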