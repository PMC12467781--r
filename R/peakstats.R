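#' Default peak assignment table with extraction windows
#'
#' The fourteen serum SERS band positions with assignments and the half-width
#' of the window used for intensity extraction (default +/- 5 cm^-1, robust
#' to small calibration shifts).
#'
#' @param window_halfwidth Extraction window half-width (cm^-1).
#' @return data.frame with `position`, `assignment`, `window_halfwidth`.
#' @export
peak_assignment_table <- function(window_halfwidth = 5) {
  pt <- default_peak_table()
  data.frame(position = pt$center, assignment = pt$assignment,
             window_halfwidth = window_halfwidth, stringsAsFactors = FALSE)
}

#' Extract a band intensity from a spectrum
#'
#' Maximum intensity over the grid points within `position +/-
#' window_halfwidth`; ties resolve to the lowest wavenumber.
#'
#' @param spectrum A `processed_spectrum`/`sample_spectrum` (or a list with
#'   `grid` and `intensities`).
#' @param position Band center (cm^-1).
#' @param window_halfwidth Window half-width (cm^-1).
#' @return The extracted intensity (scalar).
#' @export
extract_peak_intensity <- function(spectrum, position, window_halfwidth = 5) {
  wn <- wavenumbers(spectrum$grid)
  idx <- which(abs(wn - position) <= window_halfwidth)
  if (length(idx) == 0) {
    stop("extraction window [", position - window_halfwidth, ", ",
         position + window_halfwidth, "] contains no grid point")
  }
  y <- spectrum$intensities[idx]
  unname(y[which.max(y)])  # first maximum = lowest wavenumber on ties
}

#' Build the samples x peaks intensity matrix
#'
#' @param samples List of `sample_spectrum` on a common grid.
#' @param table Peak assignment table (see [peak_assignment_table()]).
#' @return A `peak_matrix`: list with `intensity` (samples x peaks matrix,
#'   columns named by position), `sample_id`, `group`, `positions`.
#' @export
build_peak_matrix <- function(samples, table = peak_assignment_table()) {
  stopifnot(length(samples) >= 1)
  M <- matrix(NA_real_, nrow = length(samples), ncol = nrow(table),
              dimnames = list(NULL, as.character(table$position)))
  for (i in seq_along(samples)) {
    for (j in seq_len(nrow(table))) {
      M[i, j] <- extract_peak_intensity(samples[[i]], table$position[j],
                                        table$window_halfwidth[j])
    }
  }
  structure(list(
    intensity = M,
    sample_id = vapply(samples, function(s) s$sample_id, character(1)),
    group = vapply(samples, function(s) s$group, character(1)),
    positions = table$position
  ), class = "peak_matrix")
}

#' Group mean/SD spectra and a pairwise difference spectrum
#'
#' @param samples List of `sample_spectrum`.
#' @param group_a,group_b Group labels; the difference is mean(a) - mean(b).
#' @return List with `groups` (per-group list of `mean`, `sd`, `n`),
#'   `difference` (list with `grid`, `delta`, `group_a`, `group_b`), `grid`.
#' @export
mean_and_difference_spectra <- function(samples, group_a, group_b) {
  sm <- sample_matrix(samples)
  for (g in c(group_a, group_b)) {
    if (sum(sm$group == g) < 2) {
      stop("group '", g, "' has fewer than 2 samples (or is unknown)")
    }
  }
  per_group <- lapply(unique(sm$group), function(g) {
    Xg <- sm$X[sm$group == g, , drop = FALSE]
    list(group = g, n = nrow(Xg), mean = colMeans(Xg),
         sd = apply(Xg, 2, stats::sd))
  })
  names(per_group) <- unique(sm$group)
  delta <- per_group[[group_a]]$mean - per_group[[group_b]]$mean
  list(groups = per_group,
       difference = list(grid = sm$grid, delta = unname(delta),
                         group_a = group_a, group_b = group_b),
       grid = sm$grid)
}
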