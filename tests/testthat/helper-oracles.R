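# Independent oracles and shared fixtures for the test suite.

# Textbook NIPALS PLS2, written loop-by-loop and kept deliberately naive so it
# shares no code with the package implementation.
naive_nipals <- function(X, Y, A) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  W <- NULL; P <- NULL; Q <- NULL; S <- NULL
  for (a in seq_len(A)) {
    u <- Yc[, 1]
    for (i in 1:1000) {
      w <- as.numeric(t(Xc) %*% u)
      w <- w / sqrt(sum(w * w))
      tt <- as.numeric(Xc %*% w)
      q <- as.numeric(t(Yc) %*% tt) / sum(tt * tt)
      unew <- as.numeric(Yc %*% q) / sum(q * q)
      if (sqrt(sum((unew - u)^2)) < 1e-14) { u <- unew; break }
      u <- unew
    }
    p <- as.numeric(t(Xc) %*% tt) / sum(tt * tt)
    Xc <- Xc - outer(tt, p)
    Yc <- Yc - outer(tt, q)
    W <- cbind(W, w); P <- cbind(P, p); Q <- cbind(Q, q); S <- cbind(S, tt)
  }
  list(W = W, P = P, Q = Q, scores = S)
}

# True autofluorescence background of a cohort config, evaluated on its grid.
true_baseline_of <- function(config) {
  wn <- sersdx::wavenumbers(config$grid)
  u <- (wn - mean(range(wn))) / (diff(range(wn)) / 2)
  coef <- config$baseline_coefficients
  y <- numeric(length(u))
  for (j in seq_along(coef)) y <- y + coef[j] * u^(j - 1)
  y
}

# Small cohort used by unit tests (3 groups x 3 samples x 2 replicates).
small_cohort_config <- function(seed = 1, ...) {
  sersdx::cohort_config(n_samples_per_group = 3, n_replicates = 2,
                        seed = seed, ...)
}

# Effect profiles with every multiplier at 1 (no group signal).
null_effects <- function() {
  list(Sham = c("635" = 1), OVX = c("635" = 1), ICA = c("635" = 1))
}

# Single-band template for closed-form checks.
single_peak_table <- function(center = 1004, amplitude = 100, width = 5) {
  data.frame(center = center, amplitude = amplitude, width = width,
             assignment = "test band", stringsAsFactors = FALSE)
}

as_processed <- function(grid, intensities) {
  structure(list(grid = grid, intensities = intensities),
            class = "processed_spectrum")
}
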