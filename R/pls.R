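one_hot <- function(y) {
  f <- factor(y)
  if (nlevels(f) < 2) {
    stop("response has a single class; classification undefined")
  }
  Y <- stats::model.matrix(~ f - 1)
  colnames(Y) <- levels(f)
  attr(Y, "assign") <- NULL
  attr(Y, "contrasts") <- NULL
  Y
}

#' Fit a PLS (NIPALS) model on labeled spectra
#'
#' Partial least squares with the class membership coded as one-hot indicator
#' columns (PLS-DA). X and the indicator matrix are mean-centered (no
#' unit-variance scaling: normalized spectra already share a common scale).
#' Components are extracted by the NIPALS algorithm: each weight vector is the
#' dominant covariance direction between the deflated X and response, scores
#' are mutually orthogonal by construction.
#'
#' @param X Samples x wavenumbers matrix.
#' @param y Class labels (>= 2 distinct).
#' @param n_components_max Number of latent components to extract; capped at
#'   `min(nrow(X) - 1, ncol(X))`.
#' @return A `pls_fit`: list with `weights` (W), `loadings` (P), `y_loadings`
#'   (Q), `scores` (T), `x_mean`, `y_mean`, `classes`, `n_components`,
#'   `cumulative_proportion` (explained fraction of response variance).
#' @export
fit_pls <- function(X, y, n_components_max = 10) {
  X <- as.matrix(X)
  Y <- one_hot(y)
  stopifnot(nrow(X) == nrow(Y), n_components_max >= 1)
  A <- min(n_components_max, nrow(X) - 1, ncol(X))
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2, xm); Yc <- sweep(Y, 2, ym)
  ssY <- sum(Yc^2)
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)

  W <- matrix(0, p, A); P <- matrix(0, p, A)
  Q <- matrix(0, m, A); Tm <- matrix(0, n, A)
  explained <- numeric(A)
  ss0 <- sum(Xc^2)  # original scale, the yardstick for rank deficiency
  a <- 0L
  for (k in seq_len(A)) {
    u <- Yc[, which.max(colSums(Yc^2))]
    t_old <- NULL
    tt <- NULL
    for (it in 1:500) {
      w <- crossprod(Xc, u)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-12) break
      w <- w / nw
      tt <- Xc %*% w
      q <- crossprod(Yc, tt) / sum(tt^2)
      u <- Yc %*% q / sum(q^2)
      if (!is.null(t_old) &&
          sum((tt - t_old)^2) < 1e-24 * max(sum(tt^2), 1e-300)) break
      t_old <- tt
    }
    ss_t <- if (is.null(tt)) 0 else sum(tt^2)
    if (!is.finite(ss_t) || ss_t < 1e-12 * max(ss0, 1e-300)) {
      warning("PLS extraction stopped early at ", k - 1,
              " components (rank deficiency)")
      break
    }
    pvec <- crossprod(Xc, tt) / ss_t
    Xc <- Xc - tt %*% t(pvec)
    Yc <- Yc - tt %*% t(q)
    a <- k
    W[, k] <- w; P[, k] <- pvec; Q[, k] <- q; Tm[, k] <- tt
    explained[k] <- ss_t * sum(q^2)
  }
  if (a == 0L) stop("PLS could not extract any component")
  keep <- seq_len(a)
  structure(list(
    weights = W[, keep, drop = FALSE],
    loadings = P[, keep, drop = FALSE],
    y_loadings = Q[, keep, drop = FALSE],
    scores = Tm[, keep, drop = FALSE],
    x_mean = xm, y_mean = ym,
    classes = colnames(Y),
    n_components = a,
    cumulative_proportion = pmin(cumsum(explained[keep]) / ssY, 1)
  ), class = "pls_fit")
}

#' Predict class-indicator values from a PLS fit
#'
#' @param object A `pls_fit`.
#' @param newdata Samples x wavenumbers matrix on the training wavenumber set.
#' @param n_components Components to use (default: all extracted). 0 returns
#'   the training class-mean prediction.
#' @param ... Unused.
#' @return Matrix of predicted indicator values (samples x classes) with a
#'   `"class"` attribute holding the argmax labels.
#' @export
predict.pls_fit <- function(object, newdata, n_components = NULL, ...) {
  newdata <- as.matrix(newdata)
  A <- object$n_components
  nc <- if (is.null(n_components)) A else n_components
  stopifnot(nc >= 0, nc <= A)
  n <- nrow(newdata)
  if (nc == 0) {
    Yhat <- matrix(object$y_mean, n, length(object$y_mean), byrow = TRUE)
  } else {
    idx <- seq_len(nc)
    W <- object$weights[, idx, drop = FALSE]
    P <- object$loadings[, idx, drop = FALSE]
    Q <- object$y_loadings[, idx, drop = FALSE]
    B <- W %*% solve(crossprod(P, W), t(Q))
    Yhat <- sweep(newdata, 2, object$x_mean) %*% B
    Yhat <- sweep(Yhat, 2, object$y_mean, `+`)
  }
  colnames(Yhat) <- object$classes
  attr(Yhat, "class_label") <- object$classes[max.col(Yhat, ties.method = "first")]
  Yhat
}

#' Project new spectra onto the latent-score space of a fit
#'
#' @param fit A `pls_fit`.
#' @param newdata Samples x wavenumbers matrix.
#' @param n_components Components to keep.
#' @return Samples x components score matrix.
#' @export
project_scores <- function(fit, newdata, n_components = fit$n_components) {
  idx <- seq_len(n_components)
  W <- fit$weights[, idx, drop = FALSE]
  P <- fit$loadings[, idx, drop = FALSE]
  R <- W %*% solve(crossprod(P, W))
  sweep(as.matrix(newdata), 2, fit$x_mean) %*% R
}

#' Stratified cross-validation folds
#'
#' Deals each class's (seeded, shuffled) samples round-robin across folds, so
#' fold class proportions match the cohort's within one sample.
#'
#' @param y Class labels.
#' @param folds Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer vector of fold assignments in 1..folds.
#' @export
stratified_folds <- function(y, folds = 10, seed = 1L) {
  stopifnot(folds >= 2)
  f <- factor(y)
  if (any(table(f) < folds)) {
    warning("some class has fewer members than folds; ",
            "those classes will be absent from some folds")
  }
  restore <- .Random.seed_exists()
  on.exit(restore(), add = TRUE)
  set.seed(substream_seed(seed, 5L))
  assign <- integer(length(y))
  offset <- 0L
  for (lv in levels(f)) {
    idx <- sample(which(f == lv))
    assign[idx] <- ((seq_along(idx) - 1 + offset) %% folds) + 1L
    offset <- offset + length(idx)
  }
  assign
}

#' Cross-validated MSEP curve over candidate component counts
#'
#' For each fold, a PLS model fitted on the training split predicts the
#' held-out one-hot responses with N = 0, 1, ..., `n_components_max`
#' components (N = 0 is the training class-mean baseline); the mean squared
#' error of prediction pools all held-out entries.
#'
#' @param X Samples x wavenumbers matrix.
#' @param y Class labels.
#' @param n_components_max Largest candidate component count.
#' @param folds CV folds (default 10, stratified).
#' @param seed Integer seed for the fold split.
#' @return A `component_selection`: list with `msep` (named vector, N = 0..max),
#'   `relative_improvement` (per added component), `folds`, `seed`;
#'   `n_selected` is filled by [select_components()].
#' @export
compute_msep_curve <- function(X, y, n_components_max = 10, folds = 10,
                               seed = 1L) {
  X <- as.matrix(X)
  Y <- one_hot(y)
  fold_id <- stratified_folds(y, folds, seed)
  A <- min(n_components_max, nrow(X) - ceiling(nrow(X) / folds) - 1, ncol(X))
  sse <- numeric(A + 1)
  count <- 0
  for (k in sort(unique(fold_id))) {
    test <- fold_id == k
    fit <- fit_pls(X[!test, , drop = FALSE], factor(y[!test]),
                   n_components_max = A)
    contrib <- numeric(A + 1)
    for (N in 0:fit$n_components) {
      Yhat <- predict(fit, X[test, , drop = FALSE], n_components = N)
      # align columns in case a class is absent from the training split
      Yh <- matrix(0, sum(test), ncol(Y), dimnames = list(NULL, colnames(Y)))
      Yh[, colnames(Yhat)] <- Yhat
      contrib[N + 1] <- sum((Y[test, , drop = FALSE] - Yh)^2)
    }
    if (fit$n_components < A) {
      # rank-deficient training split: later counts reuse the last fit
      contrib[(fit$n_components + 2):(A + 1)] <- contrib[fit$n_components + 1]
    }
    sse <- sse + contrib
    count <- count + sum(test) * ncol(Y)
  }
  msep <- sse / count
  names(msep) <- as.character(0:A)
  rel <- if (A >= 1) {
    (msep[-length(msep)] - msep[-1]) / msep[-length(msep)]
  } else numeric(0)
  names(rel) <- as.character(seq_len(A))
  structure(list(msep = msep, relative_improvement = rel,
                 folds = folds, seed = seed, n_selected = NA_integer_),
            class = "component_selection")
}

#' Choose the number of PLS components (adjusted Wold's rule)
#'
#' Walks N = 1, 2, ...: a component is accepted while it improves the
#' cross-validated MSEP by at least `threshold` relative to the previous
#' value, i.e. while (MSEP[N-1] - MSEP[N]) / MSEP[N-1] >= threshold
#' (equivalently, while MSEP[N]/MSEP[N-1] <= 1 - threshold). The first
#' component that fails stops the walk; at least one component is always
#' selected.
#'
#' @param selection A `component_selection` from [compute_msep_curve()], or a
#'   bare numeric MSEP vector starting at N = 0.
#' @param threshold Minimum relative improvement (default 0.05).
#' @return The selected component count. When given a `component_selection`,
#'   returns it with `n_selected` (and the threshold) filled in.
#' @export
#' @examples
#' select_components(c(1.00, 0.40, 0.20, 0.15, 0.149))  # 3
select_components <- function(selection, threshold = 0.05) {
  stopifnot(threshold > 0, threshold < 1)
  msep <- if (inherits(selection, "component_selection")) {
    selection$msep
  } else as.numeric(selection)
  if (length(msep) < 1) stop("empty MSEP curve")
  n_sel <- 0L
  for (N in seq_len(length(msep) - 1)) {
    prev <- msep[N]
    impr <- if (is.finite(prev) && prev > 0) (prev - msep[N + 1]) / prev else 0
    if (impr >= threshold) n_sel <- N else break
  }
  n_sel <- max(n_sel, 1L)
  if (inherits(selection, "component_selection")) {
    selection$n_selected <- n_sel
    selection$improvement_threshold <- threshold
    selection
  } else {
    n_sel
  }
}
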