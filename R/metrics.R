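#' Lin's concordance correlation coefficient
#'
#' Agreement between two series, combining correlation and accuracy:
#' `2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)`, with population
#' (1/n) moments as in Lin's original definition. Symmetric in its arguments
#' and bounded by the Pearson correlation in absolute value. If both series
#' are constant the coefficient is undefined and `NA` is returned (callers
#' exclude such pixels from averages).
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return A score in \[-1, 1\], or `NA` if both series are constant.
#' @examples
#' ccc(1:3, c(3, 4, 5))  # 0.25: perfectly correlated but shifted
#' @export
ccc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  if (vx == 0 && vy == 0) return(NA_real_)
  2 * mean((x - mx) * (y - my)) / (vx + vy + (mx - my)^2)
}

# vectorised CCC of one course against the rows of a matrix
ccc_rows <- function(courses, y) {
  n <- length(y)
  my <- mean(y); vy <- mean((y - my)^2)
  mx <- rowMeans(courses)
  cx <- courses - mx
  vx <- rowMeans(cx^2)
  covxy <- as.vector(cx %*% (y - my)) / n
  denom <- vx + vy + (mx - my)^2
  ifelse(vx == 0 & vy == 0, NA_real_, 2 * covxy / denom)
}

align_times <- function(a, b) {
  if (length(a$times) != length(b$times) ||
      any(abs(a$times - b$times) > 1e-8)) {
    stop("series times are not aligned", call. = FALSE)
  }
  invisible(TRUE)
}

#' Well-level concordance of two series
#'
#' CCC between the total (grid-summed) cell-count time courses of a model
#' series and a data series with aligned times.
#'
#' @param model_series,data_series [well_series()] objects on aligned times.
#' @return A score in \[-1, 1\].
#' @export
ccc_well <- function(model_series, data_series) {
  align_times(model_series, data_series)
  ccc(well_totals(model_series)$total_count,
      well_totals(data_series)$total_count)
}

#' Pixel-level concordance of two series
#'
#' Unweighted mean over pixels of the per-pixel CCC between the two series'
#' pixel time courses. Pixels where both courses are constant (typically
#' empty corners) have no defined score and are excluded; the exclusion count
#' is reported.
#'
#' @param model_series,data_series [well_series()] objects on aligned times.
#' @return A list with `ccc_pixel` (mean score), `n_included`, `n_excluded`,
#'   and `per_pixel` (vector of per-pixel scores, `NA` where degenerate).
#' @export
ccc_pixel <- function(model_series, data_series) {
  align_times(model_series, data_series)
  xm <- pixel_courses(model_series)
  xd <- pixel_courses(data_series)
  scores <- vapply(seq_len(nrow(xm)),
                   function(i) ccc(xm[i, ], xd[i, ]), numeric(1))
  inc <- which(!is.na(scores))
  list(
    ccc_pixel = if (length(inc)) mean(scores[inc]) else NA_real_,
    n_included = length(inc),
    n_excluded = nrow(xm) - length(inc),
    per_pixel = scores
  )
}
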