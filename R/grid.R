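#' Wavenumber grid for Raman spectra
#'
#' A regular Raman-shift axis. The default covers 400--1800 cm^-1 at a
#' 2 cm^-1 step (701 points), the range and resolution typical of serum
#' SERS acquisitions with a dispersive spectrometer.
#'
#' @param start First wavenumber (cm^-1).
#' @param stop Last wavenumber (cm^-1); must exceed `start` and be reachable
#'   from `start` in whole steps.
#' @param step Grid spacing (cm^-1), positive.
#' @return An object of class `spectral_grid`.
#' @export
#' @examples
#' g <- spectral_grid()
#' length(wavenumbers(g))  # 701
spectral_grid <- function(start = 400, stop = 1800, step = 2) {
  stopifnot(is.numeric(start), is.numeric(stop), is.numeric(step))
  if (!(start < stop)) stop("spectral_grid: 'start' must be < 'stop'")
  if (!(step > 0)) stop("spectral_grid: 'step' must be > 0")
  n <- (stop - start) / step
  if (abs(n - round(n)) > 1e-8) {
    stop("spectral_grid: 'stop' must equal 'start' plus a whole number of steps")
  }
  structure(list(start = start, stop = stop, step = step),
            class = "spectral_grid")
}

#' Grid points of a spectral grid
#'
#' @param grid A `spectral_grid`.
#' @return Numeric vector of wavenumbers (cm^-1), strictly increasing.
#' @export
wavenumbers <- function(grid) {
  stopifnot(inherits(grid, "spectral_grid"))
  seq(grid$start, grid$stop, by = grid$step)
}

#' @export
print.spectral_grid <- function(x, ...) {
  cat(sprintf("<spectral_grid> %g-%g cm^-1, step %g (%d points)\n",
              x$start, x$stop, x$step, length(wavenumbers(x))))
  invisible(x)
}

grids_identical <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-12))
}

#' Trapezoidal integral over a wavenumber grid
#'
#' @param x Wavenumber vector (strictly increasing).
#' @param y Intensity vector of the same length.
#' @return The trapezoid-rule integral (intensity x cm^-1).
#' @keywords internal
trapz_integral <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 2, length(y) == n)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}
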