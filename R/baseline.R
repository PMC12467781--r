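#' Remove the fluorescence background (Vancouver Raman Algorithm)
#'
#' Iterative modified multi-polynomial fitting: a polynomial is least-squares
#' fitted to the working signal, the residual noise level is estimated from
#' the negative residuals (signal - fit < 0) over points not yet stripped --
#' positive residuals are peak-contaminated, so the negative side gives an
#' uncontaminated noise scale -- every working-signal point above
#' fit + `strip_factor` x noise is replaced by the fit value (peak
#' stripping), and the cycle repeats until the fitted curve's RMS change
#' falls below `tolerance` x its dynamic range or a fixed point is reached
#' (no point stripped). The final fit is the fluorescence baseline; the
#' corrected spectrum is input minus baseline.
#'
#' @param spectrum A `raw_spectrum`, or a numeric intensity vector together
#'   with `grid`.
#' @param order Polynomial order (default 5).
#' @param tolerance Convergence threshold: RMS change of the fitted curve
#'   between iterations, relative to the curve's dynamic range (default
#'   0.005, i.e. 0.5%).
#' @param max_iterations Iteration cap (default 100); hitting it returns
#'   `converged = FALSE` rather than an error.
#' @param strip_factor Multiple of the noise level added to the fit to form
#'   the stripping threshold (default 1).
#' @param grid A `spectral_grid`, required when `spectrum` is a bare vector.
#' @return A `baseline_result`: list with `baseline`, `corrected`,
#'   `iterations`, `converged`, `polynomial_order`.
#' @export
#' @examples
#' cfg <- cohort_config(noise_sd = 0, sample_sd = 0, replicate_sd = 0)
#' sp <- generate_spectrum(cfg, "Sham", 1, 1)
#' br <- remove_baseline(sp)
#' br$converged
remove_baseline <- function(spectrum, order = 5, tolerance = 0.005,
                            max_iterations = 100, strip_factor = 1,
                            grid = NULL) {
  if (inherits(spectrum, "raw_spectrum")) {
    y <- spectrum$intensities
    grid <- spectrum$grid
  } else {
    y <- as.numeric(spectrum)
    if (is.null(grid)) stop("remove_baseline: 'grid' required for a bare vector")
  }
  if (any(!is.finite(y))) stop("remove_baseline: non-finite intensities")
  stopifnot(order >= 1)
  n <- length(y)
  if (n < order + 2) stop("remove_baseline: need at least order + 2 points")

  x <- wavenumbers(grid)
  if (length(x) != n) stop("remove_baseline: grid/intensity length mismatch")
  # Orthogonal polynomial basis, QR-factored once; each iteration's
  # least-squares fit is then a single projection.
  basis <- cbind(1, stats::poly(x, degree = order))
  qrb <- qr(basis)

  w <- y
  stripped <- rep(FALSE, n)
  fit_prev <- NULL
  noise_prev <- Inf
  converged <- FALSE
  iter <- 0L
  while (iter < max_iterations) {
    iter <- iter + 1L
    fit <- qr.fitted(qrb, w)
    resid <- w - fit
    neg <- resid[!stripped & resid < 0]
    noise <- if (length(neg) > 1) sqrt(mean(neg^2)) else 0
    if (!is.finite(noise)) noise <- 0
    above <- w > fit + strip_factor * noise
    if (!is.null(fit_prev)) {
      denom <- diff(range(fit))
      rel <- if (denom > 0) sqrt(mean((fit - fit_prev)^2)) / denom else
        sqrt(mean((fit - fit_prev)^2))
      # the curve change alone goes quiet while the fit is still descending;
      # require the residual noise scale to have stabilized as well
      rel_noise <- abs(noise - noise_prev) / max(noise, noise_prev, 1e-12)
      if (rel < tolerance && rel_noise < tolerance) { converged <- TRUE; break }
    }
    if (!any(above)) { converged <- TRUE; break }  # fixed point
    w[above] <- fit[above]
    stripped <- stripped | above
    fit_prev <- fit
    noise_prev <- noise
  }
  baseline <- qr.fitted(qrb, w)
  structure(list(baseline = as.numeric(baseline),
                 corrected = y - as.numeric(baseline),
                 iterations = iter,
                 converged = converged,
                 polynomial_order = order),
            class = "baseline_result")
}
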