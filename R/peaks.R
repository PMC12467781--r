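#' Default serum SERS band template
#'
#' The fourteen bands observed in serum SERS spectra of the rat osteoporosis
#' model, with their tentative biochemical assignments. Amplitudes and widths
#' are generator choices (arbitrary intensity counts; Lorentzian half-width at
#' half-maximum in cm^-1) sized so that the phenylalanine ring-breathing band
#' at 1004 cm^-1 dominates, as in typical serum spectra.
#'
#' @return A data.frame with columns `center`, `amplitude`, `width`,
#'   `assignment`.
#' @export
#' @examples
#' default_peak_table()$center
default_peak_table <- function() {
  data.frame(
    center = c(490, 524, 588, 635, 802, 883, 1004,
               1064, 1127, 1197, 1323, 1379, 1575, 1647),
    amplitude = c(40, 35, 30, 45, 30, 35, 100,
                  55, 40, 35, 45, 50, 40, 60),
    width = 6,
    assignment = c(
      "Arginine: S-S stretching vibration",
      "Cysteine: S-S stretching mode",
      "Ascorbic acid, Amide VI",
      "Tyrosine: C-S stretching vibration",
      "Uracil-based ring breathing mode",
      "CH2, protein",
      "Phenylalanine: ring breathing",
      "Lipids: skeletal C-C stretch",
      "D-mannose: C-N stretching vibration",
      "Tryptophan: ring vibration",
      "Collagen: CH3CH2 wagging mode",
      "Lipids: CH3 symmetric",
      "DNA/RNA bases: ring breathing modes",
      "Collagen, Amide I: alpha-helix"
    ),
    stringsAsFactors = FALSE
  )
}

#' Band positions with group-wise intensity differences
#'
#' The seven bands whose intensities separate the disease (OVX) group from the
#' sham-operated controls: tyrosine at 635 cm^-1 is elevated in OVX, the other
#' six (arginine, lipids, tryptophan, collagen) are depressed.
#'
#' @return Named list with elements `up` and `down` (wavenumbers, cm^-1).
#' @export
effect_bands <- function() {
  list(up = 635, down = c(490, 1064, 1197, 1323, 1379, 1647))
}

#' Evaluate a sum of Lorentzian bands
#'
#' Each band contributes `amplitude * width^2 / ((x - center)^2 + width^2)`,
#' i.e. the stated amplitude is attained exactly at the band center and
#' `width` is the half-width at half-maximum.
#'
#' @param x Wavenumber vector.
#' @param centers,amplitudes,widths Parallel band parameter vectors.
#' @return Intensity vector of `length(x)`.
#' @keywords internal
lorentzian_sum <- function(x, centers, amplitudes, widths) {
  y <- numeric(length(x))
  for (i in seq_along(centers)) {
    y <- y + amplitudes[i] * widths[i]^2 / ((x - centers[i])^2 + widths[i]^2)
  }
  y
}

validate_peak_table <- function(peaks, grid) {
  stopifnot(is.data.frame(peaks),
            all(c("center", "amplitude", "width") %in% names(peaks)))
  if (nrow(peaks) == 0) stop("peak table is empty")
  if (any(peaks$width <= 0)) stop("peak widths must be positive")
  if (any(peaks$amplitude < 0)) stop("peak amplitudes must be non-negative")
  wn <- wavenumbers(grid)
  if (any(peaks$center < min(wn) | peaks$center > max(wn))) {
    stop("peak centers must lie within the spectral grid")
  }
  invisible(peaks)
}
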