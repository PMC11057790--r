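#' A measured (or synthetic) well time course
#'
#' The full record of one replicate well: an ordered sequence of total
#' cell-density maps with their imaging times, the dose received and the
#' treatment time. Synthetic series may carry the generating ground truth.
#'
#' @param maps List of non-negative cell-count matrices, one per time point.
#' @param times Strictly increasing imaging times, hours since seeding.
#' @param grid The shared [grid_spec()].
#' @param dose_nM Doxorubicin dose in nM (0 for untreated controls).
#' @param t_dox_h Treatment time, hours.
#' @param replicate_id Identifier of the replicate.
#' @param truth Optional generating `ground_truth` (synthetic series only).
#' @return A `well_series` object.
#' @export
well_series <- function(maps, times, grid = grid_spec(), dose_nM = 0,
                        t_dox_h = 48, replicate_id = 1L, truth = NULL) {
  stopifnot(is.list(maps), length(maps) == length(times),
            !is.unsorted(times, strictly = TRUE))
  for (m in maps) {
    stopifnot(is.matrix(m), nrow(m) == grid$n_rows, ncol(m) == grid$n_cols,
              all(is.finite(m)), all(m >= 0))
  }
  structure(
    list(maps = maps, times = times, grid = grid, dose_nM = dose_nM,
         t_dox_h = t_dox_h, replicate_id = replicate_id, truth = truth),
    class = "well_series"
  )
}

#' @export
print.well_series <- function(x, ...) {
  cat(sprintf(
    "<well_series> replicate %s, %g nM, %d maps (t = %g..%g h), %d x %d grid\n",
    as.character(x$replicate_id), x$dose_nM, length(x$times),
    min(x$times), max(x$times), x$grid$n_rows, x$grid$n_cols))
  invisible(x)
}

#' Total well cell count over time
#'
#' @param series A [well_series()].
#' @return Tibble with columns `time_h`, `total_count`.
#' @export
well_totals <- function(series) {
  tibble::tibble(
    time_h = series$times,
    total_count = vapply(series$maps, sum, numeric(1))
  )
}

#' Convert a simulated two-population series to a well series
#'
#' Collapses surviving + damaged maps into measured-style total maps.
#'
#' @param sim A `two_pop_series` from [simulate_well()].
#' @param dose_nM,replicate_id,truth Metadata to attach.
#' @return A [well_series()].
#' @export
as_well_series <- function(sim, dose_nM = 0, replicate_id = 1L, truth = NULL) {
  well_series(series_ntot_maps(sim), sim$times, sim$grid,
              dose_nM = dose_nM, t_dox_h = sim$cfg$t_dox,
              replicate_id = replicate_id, truth = truth)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a well series into long per-pixel records
#'
#' @param x A [well_series()].
#' @param ... Unused.
#' @return Tibble with columns `time_h`, `row`, `col`, `count`.
#' @export
tidy.well_series <- function(x, ...) {
  g <- x$grid
  purrr::map2_dfr(x$maps, x$times, function(m, t) {
    tibble::tibble(
      time_h = t,
      row = rep(seq_len(g$n_rows), times = g$n_cols),
      col = rep(seq_len(g$n_cols), each = g$n_rows),
      count = as.vector(m)
    )
  })
}

#' @export
glance.well_series <- function(x, ...) {
  tot <- well_totals(x)$total_count
  tibble::tibble(
    dose_nM = x$dose_nM, replicate_id = x$replicate_id,
    n_times = length(x$times), t_first_h = min(x$times),
    t_last_h = max(x$times), t_dox_h = x$t_dox_h,
    initial_count = tot[1], final_count = tot[length(tot)],
    peak_count = max(tot)
  )
}

#' Tidy a simulated two-population series
#'
#' @param x A `two_pop_series` from [simulate_well()].
#' @param ... Unused.
#' @return Long tibble with `time_h`, `row`, `col`, `Ns`, `Nd`, `Ntot`.
#' @export
tidy.two_pop_series <- function(x, ...) {
  g <- x$grid
  purrr::map_dfr(seq_along(x$times), function(i) {
    tibble::tibble(
      time_h = x$times[i],
      row = rep(seq_len(g$n_rows), times = g$n_cols),
      col = rep(seq_len(g$n_cols), each = g$n_rows),
      Ns = as.vector(x$Ns[[i]]),
      Nd = as.vector(x$Nd[[i]]),
      Ntot = as.vector(x$Ns[[i]] + x$Nd[[i]])
    )
  })
}

# time indices strictly after (or from) the treatment time
post_idx <- function(series, include_tdox = FALSE) {
  if (include_tdox) which(series$times >= series$t_dox_h)
  else which(series$times > series$t_dox_h)
}

pre_idx <- function(series) which(series$times <= series$t_dox_h)

# matrix of pixel time courses: n_pixels x n_times (column-major pixel order)
pixel_courses <- function(series, idx = seq_along(series$times)) {
  vapply(idx, function(i) as.vector(series$maps[[i]]),
         numeric(n_pixels(series$grid)))
}
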