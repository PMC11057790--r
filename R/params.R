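#' Default calibration bounds for all model parameters
#'
#' Lower/upper box constraints used by the calibration and sensitivity
#' modules: the pre-treatment proliferation rate `g0` and diffusion `D0`, the
#' per-pixel surviving proliferation rate `gs`, the surviving fraction `fs`,
#' the drug-induced death rate `kd`, the damaged proliferation rate `gd`, the
#' death-delay rate `gamma_d` and the carrying capacity `theta`. The carrying
#' capacity is a physical property of the well and is constrained to a narrow
#' band; all rates are in 1/h, diffusion in mm^2/h, theta in cells per well.
#'
#' @param wide_theta If `TRUE`, widen theta's range to \[10000, 90000\] —
#'   the screening-stage range used by the sensitivity analysis, before the
#'   decision to restrict theta to its narrow physical band.
#' @return A tibble with columns `parameter`, `lower`, `upper`.
#' @export
param_bounds <- function(wide_theta = FALSE) {
  tibble::tibble(
    parameter = c("g0", "D0", "gs", "fs", "kd", "gd", "gamma_d", "theta"),
    lower = c(0.02, 0,     1e-4, 0, 1e-4, 1e-3, 1 / 120, 88000),
    upper = c(0.035, 0.005, 0.035, 1, 0.01, 0.05, 1 / 10, 90000)
  ) -> b
  if (wide_theta) {
    b$lower[b$parameter == "theta"] <- 10000
  }
  b
}

bounds_for <- function(bounds, parameter) {
  row <- bounds[bounds$parameter == parameter, ]
  if (nrow(row) != 1L) stop("no bounds for parameter ", parameter, call. = FALSE)
  c(row$lower, row$upper)
}

#' Pre-treatment model parameters
#'
#' Exponential reaction-diffusion growth of the untreated, phenotypically
#' homogeneous population: proliferation rate `g0` (1/h) and diffusion
#' coefficient `D0` (mm^2/h), both spatially uniform.
#'
#' @param g0 Proliferation rate, 1/h.
#' @param D0 Diffusion coefficient, mm^2/h.
#' @return A `pretreatment_params` object.
#' @export
pretreatment_params <- function(g0 = 0.0275, D0 = 0.0025) {
  stopifnot(is.finite(g0), is.finite(D0), D0 >= 0)
  structure(list(g0 = g0, D0 = D0), class = "pretreatment_params")
}

#' Post-treatment model parameters
#'
#' Parameters of the two-phenotype logistic reaction-diffusion model that
#' takes over once the drug is applied. The surviving proliferation rate `gs`
#' is the only locally calibrated parameter and may be a scalar or a matrix
#' over the pixel grid; in the prediction stage all six parameters may vary
#' pixelwise, so each field accepts a scalar or a matrix.
#'
#' @param gs Surviving proliferation rate(s), 1/h (scalar or matrix).
#' @param fs Surviving fraction at the time of treatment, in \[0, 1\].
#' @param gd Damaged-population proliferation rate, 1/h.
#' @param kd Drug-induced death rate, 1/h.
#' @param gamma_d Death-delay rate, 1/h: how fast the damaged population's net
#'   growth decays from `gd` towards `gd - kd` after treatment.
#' @param theta Carrying capacity (cells; well-level by default, see
#'   [solver_config()]).
#' @param Ds,Dd Diffusion coefficients of the two phenotypes, mm^2/h. By
#'   model assumption both equal the pre-treatment `D0`.
#' @return A `treatment_params` object.
#' @export
treatment_params <- function(gs, fs, gd, kd, gamma_d, theta,
                             Ds = 0.0025, Dd = Ds) {
  stopifnot(all(fs >= 0), all(fs <= 1), all(gs >= 0), all(kd >= 0),
            all(gamma_d > 0), all(theta > 0), all(Ds >= 0), all(Dd >= 0))
  structure(
    list(gs = gs, fs = fs, gd = gd, kd = kd, gamma_d = gamma_d,
         theta = theta, Ds = Ds, Dd = Dd),
    class = "treatment_params"
  )
}

treatment_param_names <- c("gs", "fs", "gd", "kd", "gamma_d", "theta")

#' Solver settings for the explicit finite-difference scheme
#'
#' @param dt Internal time step in hours (forward Euler).
#' @param t_dox Treatment time in hours since seeding.
#' @param clip_negative Clip any negative density produced by the explicit
#'   update back to zero (counts are physical).
#' @param theta_scope Either `"well"` (the carrying capacity is a whole-well
#'   count; the per-pixel logistic factor uses `theta / n_pixels`) or
#'   `"pixel"` (theta is already per pixel).
#' @return A `solver_config` object.
#' @export
solver_config <- function(dt = 1, t_dox = 48, clip_negative = TRUE,
                          theta_scope = c("well", "pixel")) {
  stopifnot(dt > 0, t_dox >= 0)
  theta_scope <- match.arg(theta_scope)
  structure(list(dt = dt, t_dox = t_dox, clip_negative = clip_negative,
                 theta_scope = theta_scope),
            class = "solver_config")
}

# per-pixel carrying capacity implied by the config
theta_pixel <- function(theta, grid, cfg) {
  if (cfg$theta_scope == "well") theta / n_pixels(grid) else theta
}

# broadcast a scalar-or-matrix parameter field to the grid
as_field <- function(x, grid) {
  if (is.matrix(x)) {
    stopifnot(nrow(x) == grid$n_rows, ncol(x) == grid$n_cols)
    x
  } else {
    matrix(x, grid$n_rows, grid$n_cols)
  }
}
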