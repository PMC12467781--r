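#' Default hyper-parameter grids for the RBF-SVM search
#'
#' Log-spaced candidates: penalty C in 2^-5 .. 2^15 (steps of 2 in the
#' exponent), Gaussian radial width sigma in 2^-4 .. 2^4.
#'
#' @return List with numeric vectors `C` and `sigma`.
#' @export
default_svm_grid <- function() {
  list(C = 2^seq(-5, 15, by = 2), sigma = 2^seq(-4, 4, by = 1))
}

svm_gamma <- function(sigma) 1 / (2 * sigma^2)  # K(u,v)=exp(-||u-v||^2/(2 sigma^2))

fit_rbf_svm <- function(X, y, C, sigma) {
  e1071::svm(x = X, y = factor(y), type = "C-classification",
             kernel = "radial", cost = C, gamma = svm_gamma(sigma),
             scale = FALSE)
}

# Out-of-fold predictions with one-vs-one vote aggregation done explicitly so
# the tie-break rule is under our control: majority vote over pairwise
# decisions; vote ties go to the largest summed signed decision value, then to
# class-level order. Also returns the positive-vs-rest decision score (sum of
# signed pairwise decision values involving the positive class).
oof_predict <- function(X, y, C, sigma, fold_id, positive_class) {
  f <- factor(y)
  lev <- levels(f)
  n <- nrow(X)
  pred <- character(n)
  score <- numeric(n)
  for (k in sort(unique(fold_id))) {
    test <- fold_id == k
    ytr <- factor(y[!test])
    if (nlevels(droplevels(ytr)) < 2) {
      stop("fold ", k, " training split contains a single class; ",
           "use stratified folds or fewer folds")
    }
    model <- fit_rbf_svm(X[!test, , drop = FALSE], droplevels(ytr), C, sigma)
    pr <- stats::predict(model, X[test, , drop = FALSE],
                         decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    pairs <- strsplit(colnames(dv), "/", fixed = TRUE)
    mlev <- model$levels
    votes <- matrix(0L, nrow(dv), length(mlev), dimnames = list(NULL, mlev))
    sums <- matrix(0, nrow(dv), length(mlev), dimnames = list(NULL, mlev))
    for (j in seq_along(pairs)) {
      a <- pairs[[j]][1]; b <- pairs[[j]][2]
      pos <- dv[, j] > 0
      votes[, a] <- votes[, a] + as.integer(pos)
      votes[, b] <- votes[, b] + as.integer(!pos)
      sums[, a] <- sums[, a] + dv[, j]
      sums[, b] <- sums[, b] - dv[, j]
    }
    lab <- character(nrow(dv))
    for (i in seq_len(nrow(dv))) {
      top <- which(votes[i, ] == max(votes[i, ]))
      if (length(top) > 1) {
        top <- top[sums[i, top] == max(sums[i, top])]
      }
      lab[i] <- mlev[top[1]]  # remaining ties: class order
    }
    pred[test] <- lab
    if (positive_class %in% mlev) {
      s <- numeric(nrow(dv))
      for (j in seq_along(pairs)) {
        if (pairs[[j]][1] == positive_class) s <- s + dv[, j]
        if (pairs[[j]][2] == positive_class) s <- s - dv[, j]
      }
      score[test] <- s
    } else {
      score[test] <- -Inf  # positive class absent from this training split
    }
  }
  list(pred = factor(pred, levels = lev), score = score, levels = lev)
}

#' Grid search for RBF-SVM hyper-parameters
#'
#' Cross-validated accuracy over every (C, sigma) candidate pair, with the
#' same stratified, seeded folds reused across the grid. Ties on accuracy
#' resolve to the smallest C, then the smallest sigma.
#'
#' @param scores Samples x features matrix (typically selected PLS scores).
#' @param y Class labels.
#' @param C_grid,sigma_grid Candidate values (positive).
#' @param folds CV folds (default 10).
#' @param seed Integer seed for the fold split.
#' @return A `cv_result`: list with `surface` (data.frame C, sigma, accuracy),
#'   `best` (list C, sigma, accuracy), `fold_id`, `folds`, `seed`.
#' @export
grid_search_svm <- function(scores, y, C_grid = default_svm_grid()$C,
                            sigma_grid = default_svm_grid()$sigma,
                            folds = 10, seed = 1L) {
  stopifnot(length(C_grid) >= 1, length(sigma_grid) >= 1,
            all(C_grid > 0), all(sigma_grid > 0), folds >= 2)
  scores <- as.matrix(scores)
  fold_id <- stratified_folds(y, folds, seed)
  C_grid <- sort(C_grid); sigma_grid <- sort(sigma_grid)
  surface <- expand.grid(C = C_grid, sigma = sigma_grid,
                         KEEP.OUT.ATTRS = FALSE)
  surface$accuracy <- NA_real_
  pos <- as.character(y[1])
  for (r in seq_len(nrow(surface))) {
    oof <- oof_predict(scores, y, surface$C[r], surface$sigma[r], fold_id, pos)
    surface$accuracy[r] <- mean(oof$pred == y)
  }
  ord <- order(surface$C, surface$sigma)   # tie-break scan order
  scan <- surface[ord, ]
  best_row <- scan[which.max(scan$accuracy), ]
  structure(list(surface = surface,
                 best = list(C = best_row$C, sigma = best_row$sigma,
                             accuracy = best_row$accuracy),
                 fold_id = fold_id, folds = folds, seed = seed),
            class = "cv_result")
}

#' ROC curve and AUC from decision scores
#'
#' Builds the ROC staircase over the unique score thresholds (ties grouped,
#' so the curve takes the diagonal through tied blocks) and integrates by the
#' trapezoid rule; the result equals the rank-based (Mann-Whitney) AUC and is
#' invariant under monotone transformations of the scores.
#'
#' @param score Numeric decision values (larger = more positive).
#' @param is_positive Logical vector: TRUE for positive-class samples.
#' @return List with `points` (data.frame `fpr`, `tpr`, `threshold`) and `auc`.
#' @export
roc_curve <- function(score, is_positive) {
  stopifnot(length(score) == length(is_positive))
  is_positive <- as.logical(is_positive)
  P <- sum(is_positive); N <- sum(!is_positive)
  if (P == 0 || N == 0) stop("ROC needs both positive and negative samples")
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; pos <- is_positive[ord]
  grp <- cumsum(!duplicated(s))
  tp <- tapply(pos, grp, sum); fp <- tapply(!pos, grp, sum)
  tpr <- c(0, cumsum(tp) / P); fpr <- c(0, cumsum(fp) / N)
  thr <- c(Inf, unique(s))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(points = data.frame(fpr = as.numeric(fpr), tpr = as.numeric(tpr),
                           threshold = thr),
       auc = auc)
}

#' Cross-validated classification report
#'
#' Trains the RBF-SVM at fixed hyper-parameters, aggregates out-of-fold
#' predictions into a confusion matrix, and computes overall accuracy,
#' one-vs-rest sensitivity/specificity per class, and the ROC/AUC of the
#' designated positive class from out-of-fold decision values.
#'
#' @param scores Samples x features matrix.
#' @param y True class labels.
#' @param C,sigma RBF-SVM hyper-parameters (positive).
#' @param folds CV folds.
#' @param seed Fold seed.
#' @param positive_class Class whose ROC is reported.
#' @param fold_id Optional precomputed fold assignment (overrides
#'   `folds`/`seed`), used to share folds with a grid search.
#' @return A `classification_report`: `confusion` (true x predicted),
#'   `accuracy`, `sensitivity`/`specificity` (named, per class), `roc`, `auc`,
#'   `positive_class`, `params`, plus the out-of-fold `predictions` and
#'   decision `scores`.
#' @export
classify_and_report <- function(scores, y, C, sigma, folds = 10, seed = 1L,
                                positive_class, fold_id = NULL) {
  stopifnot(C > 0, sigma > 0)
  scores <- as.matrix(scores)
  f <- factor(y)
  if (!positive_class %in% levels(f)) {
    stop("positive_class '", positive_class, "' not among labels: ",
         paste(levels(f), collapse = ", "))
  }
  if (is.null(fold_id)) fold_id <- stratified_folds(y, folds, seed)
  oof <- oof_predict(scores, y, C, sigma, fold_id, positive_class)
  report_from_predictions(f, oof$pred, oof$score, positive_class,
                          params = list(C = C, sigma = sigma,
                                        folds = length(unique(fold_id)),
                                        seed = seed))
}

report_from_predictions <- function(truth, pred, score, positive_class,
                                    params = list()) {
  truth <- factor(truth)
  pred <- factor(pred, levels = levels(truth))
  confusion <- table(true = truth, predicted = pred)
  total <- sum(confusion)
  accuracy <- sum(diag(confusion)) / total
  lev <- levels(truth)
  sens <- spec <- stats::setNames(numeric(length(lev)), lev)
  for (cl in lev) {
    tp <- confusion[cl, cl]
    fn <- sum(confusion[cl, ]) - tp
    fp <- sum(confusion[, cl]) - tp
    tn <- total - tp - fn - fp
    sens[cl] <- tp / (tp + fn)
    spec[cl] <- tn / (tn + fp)
  }
  roc <- roc_curve(score, truth == positive_class)
  structure(list(confusion = confusion,
                 accuracy = accuracy,
                 sensitivity = sens,
                 specificity = spec,
                 roc = roc$points,
                 auc = roc$auc,
                 positive_class = positive_class,
                 params = params,
                 predictions = pred,
                 scores = score),
            class = "classification_report")
}

#' Confusion-matrix metrics
#'
#' Overall accuracy and one-vs-rest sensitivity/specificity computed from a
#' (true x predicted) count matrix.
#'
#' @param confusion Square count matrix with matching row/column class order.
#' @return List with `accuracy`, `sensitivity`, `specificity` (per class).
#' @export
#' @examples
#' cm <- diag(c(28, 28, 26)); cm[1, 2] <- 2; cm[2, 3] <- 2
#' cm[3, 1] <- 2; cm[3, 2] <- 2
#' confusion_metrics(cm)$accuracy * 100  # 91.11
confusion_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion), all(confusion >= 0))
  lev <- rownames(confusion)
  if (is.null(lev)) lev <- paste0("class", seq_len(nrow(confusion)))
  total <- sum(confusion)
  sens <- spec <- stats::setNames(numeric(length(lev)), lev)
  for (i in seq_along(lev)) {
    tp <- confusion[i, i]
    fn <- sum(confusion[i, ]) - tp
    fp <- sum(confusion[, i]) - tp
    tn <- total - tp - fn - fp
    sens[i] <- tp / (tp + fn)
    spec[i] <- tn / (tn + fp)
  }
  list(accuracy = sum(diag(confusion)) / total,
       sensitivity = sens, specificity = spec)
}

#' @export
print.classification_report <- function(x, ...) {
  cat("Cross-validated classification report\n")
  print(x$confusion)
  cat(sprintf("accuracy: %.2f%%   AUC(%s vs rest): %.3f\n",
              100 * x$accuracy, x$positive_class, x$auc))
  invisible(x)
}

#' Run the full PLS + RBF-SVM workflow
#'
#' Composition of the modelling stages: cross-validated MSEP curve ->
#' component selection (adjusted Wold's rule) -> projection to the selected
#' latent scores -> stratified grid search over (C, sigma) -> cross-validated
#' classification report. By default (`nested = FALSE`) the PLS model and
#' scores come from the full data set and the report reuses the grid-search
#' folds, the single-level protocol typical of chemometric studies; with
#' `nested = TRUE` every stage (PLS fit, component count, grid search) is
#' redone inside each outer training fold, yielding an unbiased
#' generalization estimate.
#'
#' @param X Samples x wavenumbers matrix (or a list of `sample_spectrum`).
#' @param y Class labels (ignored when `X` is a sample list).
#' @param n_components_max Candidate PLS component ceiling.
#' @param threshold Component-selection improvement threshold.
#' @param C_grid,sigma_grid Hyper-parameter candidates.
#' @param folds CV folds (outer folds when nested).
#' @param inner_folds Inner folds for the nested protocol.
#' @param seed Root seed for all fold splits.
#' @param positive_class ROC class (default `"OVX"` when present, else the
#'   first level).
#' @param nested Use the nested protocol (default FALSE).
#' @return List with `pls_fit`, `selection`, `cv` (grid search; per-fold
#'   choices when nested), and `report`.
#' @export
run_pls_svm <- function(X, y = NULL, n_components_max = 10, threshold = 0.05,
                        C_grid = default_svm_grid()$C,
                        sigma_grid = default_svm_grid()$sigma,
                        folds = 10, inner_folds = 5, seed = 1L,
                        positive_class = NULL, nested = FALSE) {
  if (is.list(X) && !is.matrix(X) && inherits(X[[1]], "sample_spectrum")) {
    sm <- sample_matrix(X)
    X <- sm$X; y <- sm$group
  }
  X <- as.matrix(X)
  f <- factor(y)
  if (is.null(positive_class)) {
    positive_class <- if ("OVX" %in% levels(f)) "OVX" else levels(f)[1]
  }

  if (!nested) {
    selection <- compute_msep_curve(X, y, n_components_max, folds, seed)
    selection <- select_components(selection, threshold)
    n_sel <- selection$n_selected
    fit <- fit_pls(X, y, n_components_max = n_sel)
    S <- fit$scores[, seq_len(fit$n_components), drop = FALSE]
    cv <- grid_search_svm(S, y, C_grid, sigma_grid, folds, seed)
    report <- classify_and_report(S, y, cv$best$C, cv$best$sigma,
                                  seed = seed, positive_class = positive_class,
                                  fold_id = cv$fold_id)
    return(list(pls_fit = fit, selection = selection, cv = cv,
                report = report))
  }

  # Nested protocol: component count, PLS projection and hyper-parameters are
  # all chosen inside each outer training split.
  fold_id <- stratified_folds(y, folds, seed)
  pred <- factor(rep(NA_character_, length(y)), levels = levels(f))
  score <- numeric(length(y))
  per_fold <- list()
  for (k in sort(unique(fold_id))) {
    test <- fold_id == k
    Xtr <- X[!test, , drop = FALSE]; ytr <- droplevels(f[!test])
    sel <- select_components(
      compute_msep_curve(Xtr, ytr, n_components_max, inner_folds,
                         substream_seed(seed, 6L, k)),
      threshold)
    fit <- fit_pls(Xtr, ytr, n_components_max = sel$n_selected)
    Str <- fit$scores
    cv <- grid_search_svm(Str, ytr, C_grid, sigma_grid, inner_folds,
                          substream_seed(seed, 7L, k))
    model <- fit_rbf_svm(Str, ytr, cv$best$C, cv$best$sigma)
    Ste <- project_scores(fit, X[test, , drop = FALSE])
    pr <- stats::predict(model, Ste, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    pred[test] <- factor(as.character(pr), levels = levels(f))
    s <- numeric(sum(test))
    pairs <- strsplit(colnames(dv), "/", fixed = TRUE)
    for (j in seq_along(pairs)) {
      if (pairs[[j]][1] == positive_class) s <- s + dv[, j]
      if (pairs[[j]][2] == positive_class) s <- s - dv[, j]
    }
    score[test] <- s
    per_fold[[as.character(k)]] <- list(n_selected = sel$n_selected,
                                        C = cv$best$C, sigma = cv$best$sigma)
  }
  report <- report_from_predictions(f, pred, score, positive_class,
                                    params = list(nested = TRUE, folds = folds,
                                                  inner_folds = inner_folds,
                                                  seed = seed))
  list(pls_fit = NULL, selection = NULL, cv = per_fold, report = report)
}
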