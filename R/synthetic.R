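#' Default group effect profiles
#'
#' Multiplicative band-amplitude profiles for the three study arms. The
#' sham-operated group is the reference (all multipliers 1). The
#' ovariectomized (OVX) group has the tyrosine band at 635 cm^-1 raised and
#' the bands at 490, 1064, 1197, 1323, 1379 and 1647 cm^-1 lowered; the
#' icariin-treated (ICA) group lies strictly between the two, reflecting
#' partial restoration of the serum biochemistry under treatment.
#'
#' @param ovx_up Multiplier applied to the 635 cm^-1 band in the OVX group.
#' @param ovx_down Multiplier applied to the six depressed bands in OVX.
#' @param ica_fraction Position of the ICA profile between Sham (0) and
#'   OVX (1) on each affected band.
#' @return Named list of named numeric vectors (`Sham`, `OVX`, `ICA`);
#'   vector names are band centers, values are amplitude multipliers.
#' @export
default_group_effects <- function(ovx_up = 1.35, ovx_down = 0.72,
                                  ica_fraction = 0.45) {
  bands <- effect_bands()
  centers <- as.character(c(bands$up, bands$down))
  sham <- stats::setNames(rep(1, length(centers)), centers)
  ovx <- stats::setNames(c(ovx_up, rep(ovx_down, length(bands$down))), centers)
  ica <- sham + ica_fraction * (ovx - sham)
  list(Sham = sham, OVX = ovx, ICA = ica)
}

#' Configuration for a synthetic SERS cohort
#'
#' Bundles everything `generate_cohort()` needs: the wavenumber grid, the
#' band template, per-group effect profiles, cohort shape (samples per group,
#' replicate spectra per sample), the smooth autofluorescence background, and
#' the three noise scales. Defaults mirror the study design: 3 groups x 30
#' serum samples x 10 replicate acquisitions on a 400--1800 cm^-1 grid.
#'
#' The autofluorescence background is a degree-4 polynomial evaluated on the
#' scaled coordinate u = (wavenumber - mid) / halfspan in [-1, 1];
#' `baseline_coefficients` are the coefficients of 1, u, ..., u^4. The default
#' background is positive everywhere and comparable in height to the strongest
#' band, which is what makes baseline removal a meaningful step.
#'
#' @param grid A `spectral_grid`.
#' @param peaks Band template data.frame (see [default_peak_table()]).
#' @param effects Named list of multiplier vectors per group
#'   (see [default_group_effects()]).
#' @param n_samples_per_group Serum samples per group (>= 2).
#' @param n_replicates Replicate spectra per sample (>= 1).
#' @param baseline_coefficients Numeric vector, background polynomial
#'   coefficients on the scaled coordinate (constant first).
#' @param noise_sd Additive Gaussian noise SD per grid point (counts).
#' @param sample_sd Log-SD of the multiplicative between-sample amplitude
#'   factor (shared by all of a sample's replicates).
#' @param replicate_sd Log-SD of the multiplicative between-replicate factor.
#' @param seed Root seed; every spectrum draws from a sub-stream derived from
#'   (seed, group, sample, replicate), so any subset regenerates identically.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(grid = spectral_grid(),
                          peaks = default_peak_table(),
                          effects = default_group_effects(),
                          n_samples_per_group = 30,
                          n_replicates = 10,
                          baseline_coefficients = c(200, 80, -50, -30, 20),
                          noise_sd = 2,
                          sample_sd = 0.08,
                          replicate_sd = 0.05,
                          seed = 1L) {
  validate_peak_table(peaks, grid)
  stopifnot(is.list(effects), length(effects) >= 1, !is.null(names(effects)))
  if (n_samples_per_group < 2) stop("n_samples_per_group must be >= 2")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (sample_sd < 0 || replicate_sd < 0) stop("variability SDs must be >= 0")
  for (g in names(effects)) {
    m <- effects[[g]]
    if (any(m <= 0)) stop("effect multipliers must be positive (group ", g, ")")
  }
  structure(list(
    grid = grid, peaks = peaks, effects = effects,
    n_samples_per_group = as.integer(n_samples_per_group),
    n_replicates = as.integer(n_replicates),
    baseline_coefficients = baseline_coefficients,
    noise_sd = noise_sd, sample_sd = sample_sd, replicate_sd = replicate_sd,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# Deterministic sub-stream seed from a root seed and integer indices.
# Linear congruential mixing modulo 2^31 - 1; all arithmetic stays below
# 2^53 so it is exact in doubles.
substream_seed <- function(root, ...) {
  m <- 2147483647
  s <- (abs(as.double(root)) %% m) + 1
  for (k in c(...)) {
    s <- (s * 48271 + (as.double(k) + 1) * 2654435) %% m
  }
  as.integer(s)
}

group_index <- function(config, group) {
  idx <- match(group, names(config$effects))
  if (is.na(idx)) {
    stop("unknown group label '", group, "'; configured groups: ",
         paste(names(config$effects), collapse = ", "))
  }
  idx
}

baseline_curve <- function(config) {
  wn <- wavenumbers(config$grid)
  u <- (wn - mean(range(wn))) / (diff(range(wn)) / 2)
  coef <- config$baseline_coefficients
  y <- numeric(length(u))
  for (j in seq_along(coef)) y <- y + coef[j] * u^(j - 1)
  y
}

# Save/restore helper for the global RNG state.
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    saved <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", saved, envir = globalenv())
  } else {
    function() {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }
  }
}

#' Generate one synthetic raw SERS spectrum
#'
#' Intensity at each grid point is the autofluorescence background plus a sum
#' of Lorentzian bands, each band's amplitude scaled by the group's effect
#' multiplier, a log-normal sample factor (shared by all replicates of the
#' sample) and a log-normal replicate factor, plus i.i.d. Gaussian noise.
#' Deterministic given (config seed, group, sample_index, replicate_index).
#'
#' @param config A [cohort_config()].
#' @param group Group label present in `config$effects`.
#' @param sample_index Sample number within the group (1-based).
#' @param replicate_index Replicate number within the sample (1-based).
#' @return A `raw_spectrum`: list with `grid`, `intensities`, `meta`.
#' @export
#' @examples
#' cfg <- cohort_config(n_samples_per_group = 2, n_replicates = 1)
#' sp <- generate_spectrum(cfg, "Sham", 1, 1)
#' range(sp$intensities)
generate_spectrum <- function(config, group, sample_index, replicate_index) {
  stopifnot(inherits(config, "cohort_config"))
  gidx <- group_index(config, group)
  if (sample_index < 1 || sample_index > config$n_samples_per_group) {
    stop("sample_index out of range")
  }
  if (replicate_index < 1 || replicate_index > config$n_replicates) {
    stop("replicate_index out of range")
  }
  validate_peak_table(config$peaks, config$grid)
  wn <- wavenumbers(config$grid)

  mult <- rep(1, nrow(config$peaks))
  prof <- config$effects[[gidx]]
  hit <- match(as.character(config$peaks$center), names(prof))
  mult[!is.na(hit)] <- prof[hit[!is.na(hit)]]

  restore <- .Random.seed_exists()
  on.exit(restore(), add = TRUE)

  set.seed(substream_seed(config$seed, 1L, gidx, sample_index))
  s_fac <- if (config$sample_sd > 0) {
    stats::rlnorm(1, 0, config$sample_sd)
  } else 1

  set.seed(substream_seed(config$seed, 2L, gidx, sample_index, replicate_index))
  r_fac <- if (config$replicate_sd > 0) {
    stats::rlnorm(1, 0, config$replicate_sd)
  } else 1
  noise <- if (config$noise_sd > 0) {
    stats::rnorm(length(wn), 0, config$noise_sd)
  } else 0

  signal <- lorentzian_sum(wn, config$peaks$center,
                           config$peaks$amplitude * mult * s_fac * r_fac,
                           config$peaks$width)
  y <- baseline_curve(config) + signal + noise
  structure(list(
    grid = config$grid,
    intensities = y,
    meta = list(group = group, sample_index = sample_index,
                replicate_index = replicate_index,
                sample_factor = s_fac, replicate_factor = r_fac)
  ), class = "raw_spectrum")
}

#' Generate a full synthetic cohort
#'
#' @param config A [cohort_config()].
#' @return A `sers_cohort`: list with `spectra` (list of `raw_spectrum`),
#'   `manifest` (data.frame: `sample_id`, `group`, `replicate`), and the
#'   `config`. Sample IDs are `<group><two-digit index>`, e.g. `OVX07`.
#' @export
#' @examples
#' cfg <- cohort_config(n_samples_per_group = 2, n_replicates = 2, seed = 42)
#' coh <- generate_cohort(cfg)
#' nrow(coh$manifest)  # 3 groups x 2 samples x 2 replicates = 12
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- names(config$effects)
  spectra <- list()
  rows <- list()
  k <- 0L
  for (g in groups) {
    for (s in seq_len(config$n_samples_per_group)) {
      sid <- sprintf("%s%02d", g, s)
      for (r in seq_len(config$n_replicates)) {
        k <- k + 1L
        spectra[[k]] <- generate_spectrum(config, g, s, r)
        rows[[k]] <- data.frame(sample_id = sid, group = g, replicate = r,
                                stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(spectra = spectra,
                 manifest = do.call(rbind, rows),
                 config = config),
            class = "sers_cohort")
}

#' True (background- and noise-free) band intensity of the generator
#'
#' Evaluates the generator's pure Lorentzian signal for a group at a band
#' center, with sample and replicate factors at their median (1). Used as the
#' oracle for baseline-recovery and effect-direction checks.
#'
#' @param config A [cohort_config()].
#' @param group Group label.
#' @return Named numeric vector: noiseless signal intensity at each template
#'   band center.
#' @export
true_band_intensity <- function(config, group) {
  gidx <- group_index(config, group)
  mult <- rep(1, nrow(config$peaks))
  prof <- config$effects[[gidx]]
  hit <- match(as.character(config$peaks$center), names(prof))
  mult[!is.na(hit)] <- prof[hit[!is.na(hit)]]
  centers <- config$peaks$center
  y <- lorentzian_sum(centers, centers, config$peaks$amplitude * mult,
                      config$peaks$width)
  stats::setNames(y, as.character(centers))
}

#' Generate a 4-MBA probe concentration series
#'
#' Probe-molecule spectra with the two aromatic-ring bands of
#' 4-mercaptobenzoic acid at 1075 and 1583 cm^-1, whose amplitudes increase
#' monotonically with log10 concentration. Used to exercise the substrate
#' quality-control computations (peak RSD, enhancement factor).
#'
#' @param concentrations Molar concentrations, all positive.
#' @param grid A `spectral_grid`.
#' @param seed Integer seed for the additive noise.
#' @param noise_sd Gaussian noise SD (0 for noiseless templates).
#' @param base_amplitude Amplitude of the 1075 cm^-1 band at 1e-9 M.
#' @param slope Amplitude gain per decade of concentration.
#' @return List with one element per concentration: `spectrum`
#'   (a `raw_spectrum`) and `concentration`.
#' @export
#' @examples
#' ps <- generate_probe_series(10^-(4:9), seed = 1, noise_sd = 0)
#' length(ps)  # 6
generate_probe_series <- function(concentrations, grid = spectral_grid(),
                                  seed = 1L, noise_sd = 1,
                                  base_amplitude = 50, slope = 40) {
  if (length(concentrations) == 0) return(list())
  if (any(concentrations <= 0)) {
    stop("probe concentrations must be positive (molar)")
  }
  wn <- wavenumbers(grid)
  restore <- .Random.seed_exists()
  on.exit(restore(), add = TRUE)
  out <- vector("list", length(concentrations))
  for (i in seq_along(concentrations)) {
    conc <- concentrations[i]
    amp <- base_amplitude + slope * (log10(conc) + 9)  # anchored at 1e-9 M
    if (amp <= 0) stop("probe response amplitude non-positive at ", conc, " M")
    set.seed(substream_seed(seed, 3L, i))
    noise <- if (noise_sd > 0) stats::rnorm(length(wn), 0, noise_sd) else 0
    y <- lorentzian_sum(wn, c(1075, 1583), c(amp, 0.85 * amp), c(6, 6)) + noise
    out[[i]] <- list(
      spectrum = structure(list(grid = grid, intensities = y,
                                meta = list(concentration = conc)),
                           class = "raw_spectrum"),
      concentration = conc
    )
  }
  out
}

#' Generate a cohort with planted latent factors
#'
#' A labeled feature matrix X = T P' + noise in which the class information
#' lives in exactly `n_factors` orthogonal latent directions of decreasing
#' strength. Classes are `n_factors + 1` groups whose means in latent space
#' are scaled orthogonal (Helmert) contrasts, so the centered one-hot response
#' has rank `n_factors` and each planted factor carries an independent
#' response dimension. Used to validate MSEP-based component selection: the
#' cross-validated MSEP curve should elbow at `n_factors`.
#'
#' @param n_factors Number of planted latent factors (default 3).
#' @param n_per_group Samples per class.
#' @param n_features Feature (wavenumber) count.
#' @param factor_scale Between-class strength of each factor, decreasing.
#' @param within_sd Within-class SD of each latent score.
#' @param noise_sd Feature-level Gaussian noise SD.
#' @param seed Integer seed.
#' @return List with `X` (matrix), `y` (factor), `n_factors`.
#' @export
generate_latent_cohort <- function(n_factors = 3, n_per_group = 20,
                                   n_features = 200,
                                   factor_scale = c(8, 5, 3),
                                   within_sd = 1, noise_sd = 0.3,
                                   seed = 1L) {
  stopifnot(n_factors >= 1, length(factor_scale) == n_factors)
  n_groups <- n_factors + 1
  n <- n_groups * n_per_group
  restore <- .Random.seed_exists()
  on.exit(restore(), add = TRUE)
  set.seed(substream_seed(seed, 4L))
  y <- factor(rep(paste0("G", seq_len(n_groups)), each = n_per_group))
  # Helmert contrasts: orthogonal class-mean directions in latent space
  H <- stats::contr.helmert(n_groups)           # n_groups x n_factors
  H <- scale(H, center = FALSE, scale = sqrt(colSums(H^2)))
  Tmat <- H[as.integer(y), , drop = FALSE] %*% diag(factor_scale, n_factors) +
    matrix(stats::rnorm(n * n_factors, 0, within_sd), n, n_factors)
  P <- qr.Q(qr(matrix(stats::rnorm(n_features * n_factors), n_features)))
  P <- P[, seq_len(n_factors), drop = FALSE]
  X <- Tmat %*% t(P) +
    matrix(stats::rnorm(n * n_features, 0, noise_sd), n, n_features)
  list(X = X, y = y, n_factors = n_factors)
}
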