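#' Area-normalize a spectrum
#'
#' Divides the intensity at each grid point by the trapezoid-rule integral of
#' the spectrum over the wavenumber axis, so the normalized spectrum is a
#' density per cm^-1 integrating to 1.
#'
#' @param spectrum Numeric intensity vector, or a `raw_spectrum`.
#' @param grid A `spectral_grid` (required for a bare vector).
#' @param label Identifier used in error messages.
#' @return A `processed_spectrum`: list with `grid`, `intensities`.
#' @export
normalize_area <- function(spectrum, grid = NULL, label = "spectrum") {
  if (inherits(spectrum, "raw_spectrum") ||
      inherits(spectrum, "processed_spectrum")) {
    y <- spectrum$intensities
    grid <- spectrum$grid
  } else {
    y <- as.numeric(spectrum)
    if (is.null(grid)) stop("normalize_area: 'grid' required for a bare vector")
  }
  x <- wavenumbers(grid)
  area <- trapz_integral(x, y)
  if (!is.finite(area) || area <= 0) {
    stop("normalize_area: non-positive integrated intensity for ", label,
         " (area = ", format(area), ")")
  }
  structure(list(grid = grid, intensities = y / area),
            class = "processed_spectrum")
}

#' Average replicate spectra into one sample spectrum
#'
#' Pointwise arithmetic mean of processed replicate spectra acquired from the
#' same serum sample; invariant to replicate order.
#'
#' @param replicates List of `processed_spectrum` on a common grid.
#' @param sample_id,group Labels attached to the result.
#' @return A `sample_spectrum`: list with `sample_id`, `group`, `grid`,
#'   `intensities`, `n_replicates_used`.
#' @export
average_replicates <- function(replicates, sample_id = NA_character_,
                               group = NA_character_) {
  if (length(replicates) == 0) {
    stop("average_replicates: empty replicate collection")
  }
  g0 <- replicates[[1]]$grid
  for (i in seq_along(replicates)) {
    if (!grids_identical(replicates[[i]]$grid, g0)) {
      stop("average_replicates: replicate ", i, " is on a different grid")
    }
  }
  Y <- vapply(replicates, function(s) s$intensities,
              numeric(length(wavenumbers(g0))))
  m <- if (is.matrix(Y)) rowMeans(Y) else Y
  structure(list(sample_id = sample_id, group = group, grid = g0,
                 intensities = m,
                 n_replicates_used = length(replicates)),
            class = "sample_spectrum")
}

#' Preprocess a cohort into per-sample spectra
#'
#' For every replicate: baseline removal then area normalization; for every
#' sample: replicate averaging. By default each replicate is normalized
#' before averaging so a bright replicate cannot dominate its sample's mean;
#' set `normalize_after_average = TRUE` to average corrected replicates first
#' and normalize the mean instead.
#'
#' @param cohort A `sers_cohort` (from [generate_cohort()] or [read_cohort()])
#'   or a path to a manifest CSV.
#' @param order,tolerance,max_iterations Baseline-removal settings
#'   (see [remove_baseline()]).
#' @param normalize_after_average Processing-order switch (default FALSE).
#' @param clip_negative Set negative baseline-corrected intensities to zero
#'   before normalization (default FALSE; clipping breaks linearity).
#' @return List of `sample_spectrum`, one per distinct sample, in manifest
#'   order, with a `processing_log` attribute (per-sample baseline iteration
#'   counts and convergence flags).
#' @export
preprocess_cohort <- function(cohort, order = 5, tolerance = 0.005,
                              max_iterations = 100,
                              normalize_after_average = FALSE,
                              clip_negative = FALSE) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "sers_cohort"))
  man <- cohort$manifest
  g0 <- cohort$spectra[[1]]$grid
  for (i in seq_along(cohort$spectra)) {
    if (!grids_identical(cohort$spectra[[i]]$grid, g0)) {
      stop("preprocess_cohort: manifest row ", i, " (sample ",
           man$sample_id[i], "): grid differs from the cohort grid")
    }
  }
  sample_ids <- unique(man$sample_id)
  out <- vector("list", length(sample_ids))
  log <- vector("list", length(sample_ids))
  for (k in seq_along(sample_ids)) {
    sid <- sample_ids[k]
    idx <- which(man$sample_id == sid)
    grp <- unique(man$group[idx])
    if (length(grp) != 1) {
      stop("preprocess_cohort: sample ", sid, " maps to multiple groups")
    }
    reps <- vector("list", length(idx))
    iters <- integer(length(idx)); conv <- logical(length(idx))
    for (j in seq_along(idx)) {
      br <- remove_baseline(cohort$spectra[[idx[j]]], order = order,
                            tolerance = tolerance,
                            max_iterations = max_iterations)
      iters[j] <- br$iterations; conv[j] <- br$converged
      y <- br$corrected
      if (clip_negative) y <- pmax(y, 0)
      reps[[j]] <- if (normalize_after_average) {
        structure(list(grid = g0, intensities = y),
                  class = "processed_spectrum")
      } else {
        normalize_area(y, grid = g0,
                       label = paste0(sid, " replicate ", man$replicate[idx[j]]))
      }
    }
    avg <- average_replicates(reps, sample_id = sid, group = grp)
    if (normalize_after_average) {
      ns <- normalize_area(avg$intensities, grid = g0, label = sid)
      avg$intensities <- ns$intensities
    }
    out[[k]] <- avg
    log[[k]] <- data.frame(sample_id = sid, n_replicates = length(idx),
                           mean_iterations = mean(iters),
                           all_converged = all(conv),
                           stringsAsFactors = FALSE)
  }
  attr(out, "processing_log") <- do.call(rbind, log)
  out
}

#' Stack sample spectra into a matrix
#'
#' @param samples List of `sample_spectrum`.
#' @return List with `X` (samples x wavenumbers matrix, columns named by
#'   wavenumber), `sample_id`, `group`, `grid`.
#' @export
sample_matrix <- function(samples) {
  stopifnot(length(samples) >= 1)
  g0 <- samples[[1]]$grid
  wn <- wavenumbers(g0)
  X <- t(vapply(samples, function(s) s$intensities, numeric(length(wn))))
  colnames(X) <- as.character(wn)
  list(X = X,
       sample_id = vapply(samples, function(s) s$sample_id, character(1)),
       group = vapply(samples, function(s) s$group, character(1)),
       grid = g0)
}
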