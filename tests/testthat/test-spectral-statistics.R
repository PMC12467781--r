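test_that("peak extraction is the in-window maximum with low-wavenumber ties", {
  g <- spectral_grid()
  wn <- wavenumbers(g)
  cfg <- cohort_config(peaks = single_peak_table(1004, 80, 5),
                       baseline_coefficients = 0,
                       noise_sd = 0, sample_sd = 0, replicate_sd = 0)
  sp <- generate_spectrum(cfg, "Sham", 1, 1)
  expect_equal(extract_peak_intensity(sp, 1004, 5), 80)
  expect_equal(extract_peak_intensity(as_processed(g, rep(2.5, 701)), 700, 5),
               2.5)
  # exhaustive-scan oracle on a random spectrum
  set.seed(21)
  y <- rnorm(701)
  spx <- as_processed(g, y)
  for (pos in c(500, 635, 1197, 1799)) {
    idx <- which(wn >= pos - 5 & wn <= pos + 5)
    expect_identical(extract_peak_intensity(spx, pos, 5), max(y[idx]))
  }
  # tie goes to the lowest wavenumber
  ytie <- rep(0, 701); ytie[c(100, 102)] <- 7
  expect_identical(extract_peak_intensity(as_processed(g, ytie), wn[101], 5),
                   7)
  expect_error(extract_peak_intensity(spx, 3000, 5), "window")
})

test_that("the peak matrix has one row per sample and one column per band", {
  samples <- preprocess_cohort(generate_cohort(small_cohort_config(seed = 6)))
  pm <- build_peak_matrix(samples)
  expect_equal(dim(pm$intensity), c(9, 14))
  expect_equal(colnames(pm$intensity), as.character(default_peak_table()$center))
  expect_equal(pm$sample_id,
               vapply(samples, function(s) s$sample_id, character(1)))
  # single sample, single band reduces to the scalar extraction
  tab1 <- peak_assignment_table()[7, ]
  pm1 <- build_peak_matrix(samples[1], tab1)
  expect_equal(dim(pm1$intensity), c(1, 1))
  expect_equal(unname(pm1$intensity[1, 1]),
               extract_peak_intensity(samples[[1]], tab1$position,
                                      tab1$window_halfwidth))
  # row order follows input order
  pm_rev <- build_peak_matrix(rev(samples))
  expect_equal(pm_rev$intensity[9, ], pm$intensity[1, ])
})

test_that("difference spectra are antisymmetric and vanish for identical groups", {
  samples <- preprocess_cohort(generate_cohort(small_cohort_config(seed = 9)))
  ab <- mean_and_difference_spectra(samples, "OVX", "Sham")
  ba <- mean_and_difference_spectra(samples, "Sham", "OVX")
  expect_equal(ab$difference$delta, -ba$difference$delta)
  # two copies of the same group
  twin <- samples[vapply(samples, function(s) s$group == "Sham", logical(1))]
  twin2 <- lapply(twin, function(s) { s$group <- "ShamCopy"; s })
  zz <- mean_and_difference_spectra(c(twin, twin2), "Sham", "ShamCopy")
  expect_equal(max(abs(zz$difference$delta)), 0)
  expect_error(mean_and_difference_spectra(samples, "OVX", "Placebo"),
               "Placebo")
})

test_that("noiseless OVX-Sham difference follows the published band directions", {
  cfg <- cohort_config(n_samples_per_group = 3, n_replicates = 1,
                       noise_sd = 0, sample_sd = 0, replicate_sd = 0)
  samples <- preprocess_cohort(generate_cohort(cfg))
  d <- mean_and_difference_spectra(samples, "OVX", "Sham")$difference
  wn <- wavenumbers(samples[[1]]$grid)
  at <- function(b) d$delta[which.min(abs(wn - b))]
  expect_gt(at(635), 0)
  for (b in c(490, 1064, 1197, 1323, 1379, 1647)) expect_lt(at(b), 0)
})

test_that("the statistical decision tree routes on the assumption tests", {
  # all normal, equal variances -> one-way ANOVA
  set.seed(101)
  eq <- list(A = rnorm(30), B = rnorm(30, 0.2), C = rnorm(30, 0.4))
  r1 <- compare_groups(eq)
  expect_true(all(r1$normality_p >= 0.05))
  expect_gte(r1$variance_homogeneity_p, 0.05)
  expect_identical(r1$test_used, "one-way ANOVA")

  # normal but 10x variance ratio -> Welch ANOVA
  set.seed(202)
  het <- list(A = rnorm(30, 0, 1), B = rnorm(30, 0.2, sqrt(10)),
              C = rnorm(30, 0.4, 1))
  r2 <- compare_groups(het)
  expect_true(all(r2$normality_p >= 0.05))
  expect_lt(r2$variance_homogeneity_p, 0.05)
  expect_identical(r2$test_used, "Welch ANOVA")

  # heavy right skew -> Kruskal-Wallis
  set.seed(303)
  skewed <- list(A = rlnorm(30, 0, 1.5), B = rlnorm(30, 0.3, 1.5),
                 C = rlnorm(30, 0.6, 1.5))
  r3 <- compare_groups(skewed)
  expect_true(any(r3$normality_p < 0.05))
  expect_identical(r3$test_used, "Kruskal-Wallis")
  expect_true(is.na(r3$variance_homogeneity_p))

  # routing is a pure function of the assumption outcomes
  for (r in list(r1, r2, r3)) {
    expected <- if (any(r$normality_p < 0.05)) "Kruskal-Wallis"
      else if (r$variance_homogeneity_p >= 0.05) "one-way ANOVA"
      else "Welch ANOVA"
    expect_identical(r$test_used, expected)
    expect_identical(r$significant, r$p_value < 0.05)
  }
  expect_error(compare_groups(list(A = 1:2, B = rnorm(5))), ">= 3")
})

test_that("band-wise comparisons over a cohort return one routed test per band", {
  samples <- preprocess_cohort(generate_cohort(small_cohort_config(seed = 3)))
  pm <- build_peak_matrix(samples)
  cmp <- compare_peak_groups(pm)
  expect_equal(nrow(cmp), 14)
  expect_true(all(cmp$test_used %in%
                  c("one-way ANOVA", "Welch ANOVA", "Kruskal-Wallis")))
  expect_identical(cmp$significant, cmp$p_value < 0.05)
  cmpBH <- compare_peak_groups(pm, p_adjust = "BH")
  expect_true(all(cmpBH$p_adjusted >= cmpBH$p_value - 1e-15))
})

test_that("relative standard deviation matches hand arithmetic", {
  expect_equal(relative_standard_deviation(rep(4.2, 10)), 0)
  expect_equal(relative_standard_deviation(c(1, 3)), 100 * sqrt(2) / 2,
               tolerance = 1e-12)  # 70.71%
  set.seed(5)
  v <- runif(20, 1, 2)
  expect_equal(relative_standard_deviation(v),
               relative_standard_deviation(37 * v), tolerance = 1e-12)
  expect_error(relative_standard_deviation(c(-3, 1)), "positive")
  expect_error(relative_standard_deviation(5), "2 values")
})

test_that("enhancement factor is the concentration-normalized intensity ratio", {
  expect_equal(enhancement_factor(10, 1e-5, 10, 1e-5), 1)
  expect_equal(enhancement_factor(100, 1e-9, 10, 1e-4), 1e6)
  expect_equal(enhancement_factor(200, 1e-9, 20, 1e-4), 1e6)
  expect_error(enhancement_factor(-1, 1e-9, 10, 1e-4), "i_sers")
})

test_that("probe-series QC reproduces film-uniformity statistics", {
  ps <- generate_probe_series(rep(1e-4, 10), seed = 42, noise_sd = 1)
  i1075 <- vapply(ps, function(p) extract_peak_intensity(p$spectrum, 1075, 5),
                  numeric(1))
  rsd <- relative_standard_deviation(i1075)
  expect_lt(rsd, 10)   # a uniform substrate: replicate RSD in the few-% range
  expect_gt(rsd, 0)
})
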