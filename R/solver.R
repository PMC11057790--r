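#' Two-population state of a well
#'
#' Cell-density maps of the surviving (`Ns`) and irreversibly damaged (`Nd`)
#' subpopulations at one time. Before treatment the population is
#' phenotypically homogeneous and the convention `Ns = Ntot`, `Nd = 0` is
#' used so that one state type serves both phases. The total map is always
#' `Ns + Nd`.
#'
#' @param Ns,Nd Non-negative matrices of cell counts, same shape.
#' @param time Hours since seeding.
#' @return A `two_pop_state` object.
#' @export
two_pop_state <- function(Ns, Nd, time) {
  stopifnot(is.matrix(Ns), is.matrix(Nd), all(dim(Ns) == dim(Nd)),
            all(Ns >= 0), all(Nd >= 0), is.finite(time))
  structure(list(Ns = Ns, Nd = Nd, time = time), class = "two_pop_state")
}

#' @export
print.two_pop_state <- function(x, ...) {
  cat(sprintf("<two_pop_state> t = %g h, Ns total %.1f, Nd total %.1f\n",
              x$time, sum(x$Ns), sum(x$Nd)))
  invisible(x)
}

total_map <- function(state) state$Ns + state$Nd

clip0 <- function(m, cfg) if (cfg$clip_negative) pmax(m, 0) else m

assert_stable <- function(d_coeff, cfg, grid) {
  diag <- check_stability(d_coeff, cfg, grid)
  if (!diag$pass) {
    stop(sprintf("explicit scheme unstable: CFL %.4f > 0.25 (reduce dt or D)",
                 diag$cfl), call. = FALSE)
  }
  invisible(diag)
}

#' One forward-Euler step of the pre-treatment model
#'
#' Exponential reaction-diffusion update of the homogeneous untreated
#' population: `N(t + dt) = N + dt * (D0 * Laplacian(N) + g0 * N)`, with
#' no-flux boundaries and optional clipping of negative densities.
#'
#' @param N Matrix of cell counts.
#' @param p A [pretreatment_params()].
#' @param cfg A [solver_config()].
#' @param grid A [grid_spec()] matching `N`.
#' @return Updated matrix of cell counts.
#' @export
step_pretreatment <- function(N, p, cfg = solver_config(), grid = grid_spec()) {
  assert_stable(p$D0, cfg, grid)
  dx_mm <- grid$pixel_size / 1000
  out <- N + cfg$dt * (p$D0 * laplacian_noflux(N, dx_mm) + p$g0 * N)
  clip0(out, cfg)
}

#' Split the population into surviving and damaged fractions
#'
#' At the time of treatment the (until then homogeneous) population is
#' divided into a surviving fraction `fs` and a damaged fraction `1 - fs`,
#' pixel by pixel. The two maps sum back to the input exactly.
#'
#' @param N Total cell-count matrix at the treatment time.
#' @param fs Surviving fraction in \[0, 1\] (scalar or matrix).
#' @param time Hours since seeding (stored on the returned state).
#' @return A [two_pop_state()] with `Ns = fs * N`, `Nd = (1 - fs) * N`.
#' @export
split_population <- function(N, fs, time = 48) {
  if (any(fs < 0) || any(fs > 1)) {
    stop("`fs` must lie in [0, 1]", call. = FALSE)
  }
  if (is.matrix(fs)) stopifnot(all(dim(fs) == dim(N)))
  two_pop_state(Ns = fs * N, Nd = (1 - fs) * N, time = time)
}

#' Net per-capita rate of the damaged population
#'
#' The damaged cells initially follow logistic growth at rate `gd` and
#' progressively transition into drug-induced death: the per-capita rate
#' multiplying `Nd * (1 - Ntot / theta)` is
#' `gd + kd * exp(-gamma_d * (t - t_dox)) - kd`, which starts at `gd` when
#' the drug is applied and decays towards `gd - kd` with delay rate
#' `gamma_d`.
#'
#' @param t Time in hours (must be `>= t_dox`).
#' @param p A [treatment_params()] (scalar fields).
#' @param t_dox Treatment time in hours.
#' @return The net rate in 1/h.
#' @export
damaged_net_rate <- function(t, p, t_dox = 48) {
  if (any(t < t_dox)) stop("`t` must be >= t_dox", call. = FALSE)
  p$gd + p$kd * exp(-p$gamma_d * (t - t_dox)) - p$kd
}

#' One forward-Euler step of the post-treatment two-phenotype model
#'
#' Logistic reaction-diffusion update of both subpopulations. The surviving
#' population grows at its (possibly pixelwise) rate `gs`, the damaged
#' population at the delayed net rate of [damaged_net_rate()]; both share the
#' logistic crowding factor `1 - Ntot / theta` with `Ntot = Ns + Nd`
#' recomputed at every step.
#'
#' @param state A [two_pop_state()] at time `>= t_dox`.
#' @param p A [treatment_params()]; each field scalar or matrix.
#' @param cfg A [solver_config()].
#' @param grid A [grid_spec()] matching the state.
#' @return The updated [two_pop_state()] at `state$time + dt`.
#' @export
step_posttreatment <- function(state, p, cfg = solver_config(),
                               grid = grid_spec()) {
  stopifnot(state$time >= cfg$t_dox)
  assert_stable(max(p$Ds, p$Dd), cfg, grid)
  dx_mm <- grid$pixel_size / 1000
  Ns <- state$Ns; Nd <- state$Nd
  Ntot <- Ns + Nd
  th <- theta_pixel(p$theta, grid, cfg)
  crowd <- 1 - Ntot / th
  gs <- p$gs
  rate_d <- p$gd + p$kd * exp(-p$gamma_d * (state$time - cfg$t_dox)) - p$kd
  Ns2 <- Ns + cfg$dt * (p$Ds * laplacian_noflux(Ns, dx_mm) + gs * Ns * crowd)
  Nd2 <- Nd + cfg$dt * (p$Dd * laplacian_noflux(Nd, dx_mm) + rate_d * Nd * crowd)
  two_pop_state(clip0(Ns2, cfg), clip0(Nd2, cfg), state$time + cfg$dt)
}

snap_times <- function(times, dt) round(times / dt) * dt

#' Simulate a full well experiment
#'
#' Runs the pre-treatment exponential model from the seeding map `N0` until
#' the treatment time, splits the population into surviving/damaged fractions
#' by `post$fs`, then runs the post-treatment two-phenotype model to `t_end`.
#' States are recorded at `sample_times` (snapped to the nearest internal
#' step, never interpolated); pre-treatment states use the `Ns = Ntot`,
#' `Nd = 0` convention, and the state at the treatment time itself is the
#' freshly split one.
#'
#' @param N0 Initial cell-count matrix at `t = 0`.
#' @param pre A [pretreatment_params()].
#' @param post A [treatment_params()].
#' @param cfg A [solver_config()] (carries `dt` and `t_dox`).
#' @param grid A [grid_spec()].
#' @param t_end Final time, hours.
#' @param sample_times Sorted vector of recording times in `[0, t_end]`.
#' @return A `two_pop_series`: list with `times` and parallel lists of
#'   states' `Ns`, `Nd` matrices, plus the grid and config used.
#' @export
simulate_well <- function(N0, pre, post, cfg = solver_config(),
                          grid = grid_spec(), t_end = 500,
                          sample_times = seq(0, t_end, by = 4)) {
  if (is.unsorted(sample_times, strictly = FALSE)) {
    stop("`sample_times` must be sorted increasingly", call. = FALSE)
  }
  stopifnot(all(sample_times >= 0), all(sample_times <= t_end),
            cfg$t_dox >= 0, cfg$t_dox <= t_end)
  snapped <- snap_times(sample_times, cfg$dt)
  n_steps <- round(t_end / cfg$dt)
  n_pre <- round(cfg$t_dox / cfg$dt)
  fs_field <- if (is.matrix(post$fs)) post$fs else as_field(post$fs, grid)

  Ns <- N0; Nd <- matrix(0, grid$n_rows, grid$n_cols)
  out_Ns <- vector("list", length(snapped))
  out_Nd <- vector("list", length(snapped))
  record <- function(k, Ns, Nd) {
    hits <- which(abs(snapped - k * cfg$dt) < cfg$dt / 2)
    for (h in hits) { out_Ns[[h]] <<- Ns; out_Nd[[h]] <<- Nd }
  }
  state <- NULL
  for (k in 0:n_steps) {
    t_k <- k * cfg$dt
    if (k == n_pre) {
      st <- split_population(Ns + Nd, fs_field, time = t_k)
      Ns <- st$Ns; Nd <- st$Nd
    }
    record(k, Ns, Nd)
    if (k == n_steps) break
    if (k < n_pre) {
      Ns <- step_pretreatment(Ns, pre, cfg, grid)
    } else {
      st <- step_posttreatment(two_pop_state(Ns, Nd, t_k), post, cfg, grid)
      Ns <- st$Ns; Nd <- st$Nd
    }
  }
  structure(
    list(times = snapped, Ns = out_Ns, Nd = out_Nd, grid = grid, cfg = cfg),
    class = "two_pop_series"
  )
}

#' @export
print.two_pop_series <- function(x, ...) {
  cat(sprintf("<two_pop_series> %d states, t = %g..%g h on a %d x %d grid\n",
              length(x$times), min(x$times), max(x$times),
              x$grid$n_rows, x$grid$n_cols))
  invisible(x)
}

series_totals <- function(sim) {
  vapply(seq_along(sim$times),
         function(i) sum(sim$Ns[[i]]) + sum(sim$Nd[[i]]), numeric(1))
}

series_ntot_maps <- function(sim) {
  lapply(seq_along(sim$times), function(i) sim$Ns[[i]] + sim$Nd[[i]])
}
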