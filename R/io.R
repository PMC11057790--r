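#' Read and write well series containers
#'
#' Well time courses are stored in a hierarchical JSON container with one
#' group per well (`well_<id>`), each holding a `times` vector, an `Ntot`
#' stack of density maps (and optionally `Ns`/`Nd` stacks for simulated
#' series), and the attributes `dose_nM`, `t_dox_h`, `pixel_size_um` and
#' `replicate_id`. A top-level `version` attribute tags the schema. Values
#' round-trip losslessly.
#'
#' @param series A [well_series()] or list of them.
#' @param path File path of the container.
#' @return `write_well_series()` returns `path` invisibly;
#'   `read_well_series()` returns a [well_series()] (or a list of them when
#'   the container holds several wells).
#' @export
write_well_series <- function(series, path) {
  if (inherits(series, "well_series")) series <- list(series)
  wells <- list()
  for (i in seq_along(series)) {
    s <- series[[i]]
    wells[[paste0("well_", i)]] <- list(
      attrs = list(dose_nM = s$dose_nM, t_dox_h = s$t_dox_h,
                   pixel_size_um = s$grid$pixel_size,
                   replicate_id = s$replicate_id),
      times = s$times,
      Ntot = s$maps
    )
  }
  obj <- list(
    format = "wellforecast-container", version = 1L,
    grid = list(n_rows = series[[1]]$grid$n_rows,
                n_cols = series[[1]]$grid$n_cols,
                pixel_size = series[[1]]$grid$pixel_size,
                field_of_view = series[[1]]$grid$field_of_view),
    wells = wells
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

need_field <- function(x, name, where) {
  if (is.null(x[[name]])) {
    stop(sprintf("container is missing '%s' in %s", name, where),
         call. = FALSE)
  }
  x[[name]]
}

#' @rdname write_well_series
#' @export
read_well_series <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyMatrix = TRUE)
  g <- need_field(obj, "grid", "the container root")
  grid <- grid_spec(g$n_rows, g$n_cols, g$pixel_size, g$field_of_view)
  wells <- need_field(obj, "wells", "the container root")
  out <- lapply(names(wells), function(wname) {
    w <- wells[[wname]]
    attrs <- need_field(w, "attrs", wname)
    for (a in c("dose_nM", "t_dox_h", "pixel_size_um")) need_field(attrs, a, wname)
    times <- need_field(w, "times", wname)
    ntot <- need_field(w, "Ntot", wname)
    maps <- if (is.array(ntot) && length(dim(ntot)) == 3L) {
      lapply(seq_len(dim(ntot)[1]), function(i) ntot[i, , ])
    } else if (is.list(ntot)) {
      lapply(ntot, function(m) matrix(unlist(m), grid$n_rows, grid$n_cols,
                                      byrow = TRUE))
    } else {
      list(ntot)
    }
    well_series(maps, times, grid, dose_nM = attrs$dose_nM,
                t_dox_h = attrs$t_dox_h,
                replicate_id = attrs$replicate_id %||% 1L)
  })
  if (length(out) == 1L) out[[1]] else out
}

#' Delimited-text fallback for density maps and centroid tables
#'
#' `write_density_csv()`/`read_density_csv()` store a single density map as
#' a headerless comma-separated matrix (exact for integer maps).
#' `write_centroids_csv()`/`read_centroids_csv()` store a centroid table
#' with the header `time_h,x_um,y_um`.
#'
#' @param map Cell-count matrix.
#' @param table Centroid tibble with columns `time_h`, `x_um`, `y_um`.
#' @param path File path.
#' @return Readers return the matrix / tibble; writers return `path`
#'   invisibly.
#' @export
write_density_csv <- function(map, path) {
  utils::write.table(map, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_density_csv
#' @export
read_density_csv <- function(path) {
  unname(as.matrix(utils::read.table(path, sep = ",", header = FALSE)))
}

#' @rdname write_density_csv
#' @export
write_centroids_csv <- function(table, path) {
  stopifnot(all(c("time_h", "x_um", "y_um") %in% names(table)))
  utils::write.csv(table[, c("time_h", "x_um", "y_um")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_density_csv
#' @export
read_centroids_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}
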