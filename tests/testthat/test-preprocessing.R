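test_that("a peak-free polynomial is its own baseline (OLS equivalence)", {
  g <- spectral_grid()
  wn <- wavenumbers(g)
  y <- 5 + 0.01 * wn - 2e-6 * wn^2 + 1e-9 * wn^3
  br <- remove_baseline(y, order = 5, grid = g)
  rng <- diff(range(y))
  expect_lt(max(abs(br$baseline - y)), 1e-6 * rng)
  expect_lt(max(abs(br$corrected)), 1e-6 * rng)
  expect_true(br$converged)
  # agrees with a straight least-squares polynomial fit
  ols <- fitted(lm(y ~ poly(wn, 5)))
  expect_lt(max(abs(br$baseline - ols)), 1e-6 * rng)
})

test_that("the all-zero spectrum converges immediately to a zero baseline", {
  g <- spectral_grid()
  br <- remove_baseline(rep(0, 701), grid = g)
  expect_identical(br$iterations, 1L)
  expect_true(br$converged)
  expect_equal(max(abs(br$baseline)), 0)
  expect_equal(max(abs(br$corrected)), 0)
})

test_that("the known degree-4 background of a noiseless cohort spectrum is recovered", {
  cfg <- cohort_config(noise_sd = 0, sample_sd = 0, replicate_sd = 0)
  sp <- generate_spectrum(cfg, "Sham", 1, 1)
  truth <- true_baseline_of(cfg)
  br <- remove_baseline(sp)
  rms <- sqrt(mean((br$baseline - truth)^2))
  expect_lt(rms, 0.03 * diff(range(truth)))
  expect_true(br$converged)
})

test_that("corrected band intensities track the true signal and preserve group ratios", {
  cfg <- cohort_config(noise_sd = 0, sample_sd = 0, replicate_sd = 0)
  grab <- function(group) {
    br <- remove_baseline(generate_spectrum(cfg, group, 1, 1))
    corr <- as_processed(cfg$grid, br$corrected)
    stats::setNames(
      vapply(cfg$peaks$center, function(p) extract_peak_intensity(corr, p, 5),
             numeric(1)),
      as.character(cfg$peaks$center))
  }
  est_sham <- grab("Sham")
  tv_sham <- true_band_intensity(cfg, "Sham")
  rel <- (est_sham - tv_sham) / tv_sham
  # the isolated strong phenylalanine band recovers within 5%; bands with
  # overlapping Lorentzian wings sit on an inter-band pedestal that no
  # polynomial background can descend below, bounding the rest at ~15%
  expect_lt(abs(rel[["1004"]]), 0.05)
  expect_lt(max(abs(rel)), 0.15)
  # the pedestal bias is common-mode across groups: between-group ratios at
  # the effect bands survive correction almost exactly
  est_ovx <- grab("OVX")
  tv_ovx <- true_band_intensity(cfg, "OVX")
  for (b in c("635", "490", "1647")) {
    expect_equal(est_ovx[[b]] / est_sham[[b]], tv_ovx[[b]] / tv_sham[[b]],
                 tolerance = 0.03)
  }
})

test_that("baseline removal flags non-convergence and rejects bad input", {
  cfg <- cohort_config(seed = 5)
  sp <- generate_spectrum(cfg, "Sham", 1, 1)
  br <- remove_baseline(sp, max_iterations = 2)
  expect_false(br$converged)
  expect_identical(br$iterations, 2L)
  expect_error(remove_baseline(c(sp$intensities[-1], NaN), grid = cfg$grid),
               "non-finite")
})

test_that("area normalization yields unit-integral densities and is scale invariant", {
  g <- spectral_grid()
  wn <- wavenumbers(g)
  # constant spectrum over a 1400 cm^-1 span -> density 1/1400
  ns <- normalize_area(rep(3.7, 701), grid = g)
  expect_equal(ns$intensities, rep(1 / 1400, 701))
  set.seed(7)
  y <- runif(701, 0.5, 2)
  n1 <- normalize_area(y, grid = g)
  expect_lt(abs(trapz_int <- sum(diff(wn) * (n1$intensities[-1] +
                                             n1$intensities[-701]) / 2) - 1),
            1e-9)
  n2 <- normalize_area(17.3 * y, grid = g)
  expect_equal(n1$intensities, n2$intensities, tolerance = 1e-12)
  expect_error(normalize_area(rep(0, 701), grid = g, label = "S01"),
               "S01")
  expect_error(normalize_area(rep(-1, 701), grid = g), "non-positive")
})

test_that("replicate averaging is a permutation-invariant pointwise mean", {
  g <- spectral_grid()
  set.seed(3)
  reps <- lapply(1:10, function(i) as_processed(g, runif(701)))
  same <- average_replicates(rep(list(reps[[1]]), 10), "S", "Sham")
  expect_equal(same$intensities, reps[[1]]$intensities)
  two <- average_replicates(reps[1:2])
  expect_equal(two$intensities,
               (reps[[1]]$intensities + reps[[2]]$intensities) / 2)
  shuffled <- average_replicates(reps[sample(10)])
  ordered <- average_replicates(reps)
  expect_equal(shuffled$intensities, ordered$intensities)
  expect_equal(ordered$n_replicates_used, 10)
  g2 <- spectral_grid(400, 1800, 4)
  expect_error(average_replicates(list(reps[[1]],
                                       as_processed(g2, runif(351)))),
               "different grid")
  expect_error(average_replicates(list()), "empty")
})

test_that("cohort preprocessing yields one unit-area spectrum per sample", {
  coh <- generate_cohort(small_cohort_config(seed = 11))
  samples <- preprocess_cohort(coh)
  expect_length(samples, 9)
  wn <- wavenumbers(samples[[1]]$grid)
  for (s in samples) {
    area <- sum(diff(wn) * (s$intensities[-1] + s$intensities[-701]) / 2)
    expect_lt(abs(area - 1), 1e-9)
    expect_equal(s$n_replicates_used, 2)
  }
  log <- attr(samples, "processing_log")
  expect_true(all(log$all_converged))
  # single-sample, single-replicate manifest equals the composed path
  cfg1 <- cohort_config(n_samples_per_group = 2, n_replicates = 1, seed = 4)
  coh1 <- generate_cohort(cfg1)
  one <- list(spectra = coh1$spectra[1], manifest = coh1$manifest[1, ],
              config = cfg1)
  class(one) <- "sers_cohort"
  via_cohort <- preprocess_cohort(one)[[1]]
  direct <- normalize_area(remove_baseline(coh1$spectra[[1]])$corrected,
                           grid = cfg1$grid)
  expect_equal(via_cohort$intensities, direct$intensities)
})

test_that("a missing spectrum file is reported with its manifest row", {
  coh <- generate_cohort(cohort_config(n_samples_per_group = 2,
                                       n_replicates = 1, seed = 2))
  dir <- withr::local_tempdir()
  man <- write_cohort(coh, dir)
  victim <- utils::read.csv(man)$file[3]
  unlink(file.path(dir, victim))
  expect_error(read_cohort(man), "row 3")
  expect_error(read_cohort(man), victim, fixed = TRUE)
})

test_that("spectrum and sample-matrix files round-trip", {
  cfg <- small_cohort_config(seed = 8)
  sp <- generate_spectrum(cfg, "ICA", 1, 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(sp, path)
  back <- read_spectrum_csv(path)
  expect_equal(back$intensities, sp$intensities, tolerance = 1e-12)
  expect_true(grids_identical <- isTRUE(all.equal(unclass(back$grid),
                                                  unclass(sp$grid))))
  # headerless two-column files load too
  write_spectrum_csv(sp, path, header = FALSE)
  expect_equal(read_spectrum_csv(path)$intensities, sp$intensities,
               tolerance = 1e-12)

  samples <- preprocess_cohort(generate_cohort(cfg))
  mpath <- withr::local_tempfile(fileext = ".csv")
  write_sample_matrix(samples, mpath)
  sm <- read_sample_matrix(mpath)
  expect_equal(dim(sm$X), c(9, 701))
  expect_equal(sm$group, vapply(samples, function(s) s$group, character(1)))
})

test_that("minimal JCAMP-DX spectra are read", {
  path <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c(
    "##TITLE=synthetic test spectrum",
    "##JCAMP-DX=4.24",
    "##XUNITS=1/CM", "##YUNITS=COUNTS",
    "##FIRSTX=400", "##LASTX=408", "##NPOINTS=5",
    "##XYDATA=(X++(Y..Y))",
    "400 1.0 2.0 3.0",
    "406 4.0 5.0",
    "##END="
  ), path)
  sp <- read_jcamp(path)
  expect_equal(wavenumbers(sp$grid), seq(400, 408, 2))
  expect_equal(sp$intensities, 1:5)

  writeLines(c(
    "##TITLE=xypoints variant",
    "##XYPOINTS=(XY..XY)",
    "400, 1.0; 402, 2.0; 404, 3.0",
    "##END="
  ), path)
  sp2 <- read_jcamp(path)
  expect_equal(sp2$intensities, 1:3)
})
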