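test_that("PLS matches an independent textbook NIPALS oracle", {
  set.seed(11)
  X <- matrix(rnorm(20 * 50), 20, 50)
  y <- rep(c("A", "B"), each = 10)
  fit <- fit_pls(X, y, 5)
  Y <- stats::model.matrix(~ factor(y) - 1)
  ora <- naive_nipals(X, Y, 5)
  sgn <- sign(colSums(fit$weights * ora$W))
  expect_lt(max(abs(sweep(ora$W, 2, sgn, `*`) - fit$weights)), 1e-6)
  expect_lt(max(abs(sweep(ora$scores, 2, sgn, `*`) - fit$scores)), 1e-6)
  expect_lt(max(abs(sweep(ora$P, 2, sgn, `*`) - fit$loadings)), 1e-6)
  # closed form: first weight is the top left singular vector of X'Y (centered)
  w1 <- svd(crossprod(scale(X, scale = FALSE), scale(Y, scale = FALSE)))$u[, 1]
  expect_lt(min(max(abs(w1 - fit$weights[, 1])),
                max(abs(w1 + fit$weights[, 1]))), 1e-8)
})

test_that("PLS scores are orthogonal and explained proportion is monotone in [0, 1]", {
  set.seed(12)
  X <- matrix(rnorm(30 * 40), 30, 40)
  y <- rep(c("A", "B", "C"), each = 10)
  fit <- fit_pls(X, y, 6)
  G <- crossprod(fit$scores)
  offdiag <- G - diag(diag(G))
  expect_lt(max(abs(offdiag)), 1e-8 * max(diag(G)))
  expect_true(all(diff(fit$cumulative_proportion) >= -1e-12))
  expect_true(all(fit$cumulative_proportion >= 0 &
                  fit$cumulative_proportion <= 1 + 1e-12))
})

test_that("a rank-1 class separation is captured by one component", {
  set.seed(13)
  dir <- rnorm(25); dir <- dir / sqrt(sum(dir^2))
  t_scores <- c(rnorm(10, -3, 0.1), rnorm(10, 3, 0.1))
  X <- outer(t_scores, dir)
  y <- rep(c("A", "B"), each = 10)
  # rank deficiency past the first component is flagged, not fatal
  expect_warning(fit <- fit_pls(X, y, 3), "rank")
  expect_identical(fit$n_components, 1L)
  expect_gt(fit$cumulative_proportion[1], 0.99)
  sel <- suppressWarnings(compute_msep_curve(X, y, 3, folds = 5, seed = 1))
  expect_lt(sel$msep[["1"]], 0.1 * sel$msep[["0"]])
  expect_error(fit_pls(X, rep("A", 20), 2), "single class")
})

test_that("the MSEP curve is seed-deterministic and elbows at the planted rank", {
  lc <- generate_latent_cohort(seed = 7)
  s1 <- compute_msep_curve(lc$X, lc$y, 8, folds = 10, seed = 7)
  s2 <- compute_msep_curve(lc$X, lc$y, 8, folds = 10, seed = 7)
  expect_identical(s1$msep, s2$msep)
  sel <- select_components(s1)
  expect_identical(sel$n_selected, 3L)
})

test_that("component selection implements the relative-improvement walk", {
  expect_identical(select_components(c(1.00, 0.40, 0.20, 0.15, 0.149)), 3L)
  expect_identical(select_components(rep(0.5, 6)), 1L)
  expect_identical(select_components(c(1, 0.5, 0.25, 0.125)), 3L)
  # improvement below threshold at the first step still yields one component
  expect_identical(select_components(c(1, 0.999)), 1L)
  # monotone in the threshold: larger thresholds never select more
  set.seed(31)
  for (i in 1:20) {
    curve <- cumprod(c(1, runif(6, 0.5, 1.05)))
    picks <- vapply(c(0.01, 0.05, 0.1, 0.3),
                    function(th) select_components(curve, th), integer(1))
    expect_true(all(diff(picks) <= 0))
  }
})

test_that("stratified folds cover every sample once and balance classes", {
  y <- rep(c("A", "B", "C"), each = 30)
  f <- stratified_folds(y, 10, seed = 4)
  expect_equal(sort(unique(f)), 1:10)
  expect_true(all(table(f) == 9))
  tab <- table(f, y)
  expect_true(all(abs(tab - 3) <= 1))
  expect_identical(f, stratified_folds(y, 10, seed = 4))
})

test_that("grid search finds a perfect band for separable clouds and is deterministic", {
  set.seed(14)
  X <- rbind(matrix(rnorm(40, 0, 0.2), 20, 2),
             matrix(rnorm(40, 10, 0.2), 20, 2))
  y <- rep(c("A", "B"), each = 20)
  cv <- grid_search_svm(X, y, C_grid = 2^seq(-3, 7, 2),
                        sigma_grid = 2^seq(-2, 4, 2), folds = 5, seed = 2)
  expect_equal(cv$best$accuracy, 1)
  expect_gt(sum(cv$surface$accuracy == 1), 5)  # a wide band of the grid
  cv2 <- grid_search_svm(X, y, C_grid = 2^seq(-3, 7, 2),
                         sigma_grid = 2^seq(-2, 4, 2), folds = 5, seed = 2)
  expect_identical(cv$surface, cv2$surface)
  expect_identical(cv$best, cv2$best)
})

test_that("the RBF kernel solves XOR where any linear threshold fails", {
  set.seed(15)
  n <- 25
  X <- rbind(
    cbind(rnorm(n, 0, 0.15), rnorm(n, 0, 0.15)),
    cbind(rnorm(n, 1, 0.15), rnorm(n, 1, 0.15)),
    cbind(rnorm(n, 0, 0.15), rnorm(n, 1, 0.15)),
    cbind(rnorm(n, 1, 0.15), rnorm(n, 0, 0.15))
  )
  y <- rep(c("same", "same", "diff", "diff"), each = n)
  cv <- grid_search_svm(X, y, C_grid = 2^seq(-1, 9, 2),
                        sigma_grid = 2^seq(-3, 1, 1), folds = 5, seed = 3)
  expect_gt(cv$best$accuracy, 0.9)
  # exhaustive linear baseline: best single-feature threshold on either axis
  lin_acc <- 0
  for (j in 1:2) for (thr in sort(X[, j])) for (dir in c(1, -1)) {
    pred <- ifelse(dir * X[, j] > dir * thr, "same", "diff")
    lin_acc <- max(lin_acc, mean(pred == y))
  }
  expect_lt(lin_acc, 0.65)
})

test_that("confusion-matrix identities hold on cross-validated reports", {
  set.seed(16)
  X <- rbind(matrix(rnorm(60, 0, 1.5), 30, 2),
             matrix(rnorm(60, 2, 1.5), 30, 2))
  y <- rep(c("neg", "pos"), each = 30)
  rp <- classify_and_report(X, y, C = 1, sigma = 1, folds = 5, seed = 9,
                            positive_class = "pos")
  expect_equal(rowSums(rp$confusion), c(neg = 30, pos = 30))
  expect_equal(rp$accuracy, sum(diag(rp$confusion)) / sum(rp$confusion))
  cm <- rp$confusion
  expect_equal(rp$sensitivity[["pos"]], cm["pos", "pos"] / sum(cm["pos", ]))
  expect_equal(rp$specificity[["pos"]], cm["neg", "neg"] / sum(cm["neg", ]))
  expect_true(rp$auc >= 0 && rp$auc <= 1)
  expect_error(classify_and_report(X, y, 1, 1, positive_class = "missing"),
               "positive_class")
})

test_that("confusion metrics reproduce the degenerate all-wrong case", {
  cm <- matrix(c(0, 10, 10, 0), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  m <- confusion_metrics(cm)
  expect_equal(m$accuracy, 0)
  expect_equal(unname(m$sensitivity), c(0, 0))
})

test_that("AUC identities: perfect ranking, label swap, monotone invariance", {
  set.seed(17)
  pos <- c(rep(TRUE, 12), rep(FALSE, 20))
  perfect <- c(runif(12, 1, 2), runif(20, -2, 0))
  expect_equal(roc_curve(perfect, pos)$auc, 1)
  expect_equal(roc_curve(-perfect, pos)$auc, 0)
  mixed <- rnorm(32)
  a <- roc_curve(mixed, pos)$auc
  expect_equal(roc_curve(mixed, !pos)$auc, 1 - a)
  expect_equal(roc_curve(exp(3 * mixed), pos)$auc, a)
  # cross-check against an independent ROC implementation
  skip_if_not_installed("pROC")
  pr <- suppressMessages(pROC::auc(pROC::roc(response = pos,
                                             predictor = mixed,
                                             direction = "<", quiet = TRUE)))
  expect_equal(a, as.numeric(pr), tolerance = 1e-12)
})

test_that("the end-to-end PLS-SVM run is deterministic and reports its stages", {
  cfg <- small_cohort_config(seed = 19)
  sm <- sample_matrix(preprocess_cohort(generate_cohort(cfg)))
  grid <- list(C = 2^c(0, 4), sigma = 2^c(-1, 1))
  r1 <- run_pls_svm(sm$X, sm$group, n_components_max = 4, folds = 3,
                    C_grid = grid$C, sigma_grid = grid$sigma, seed = 19)
  r2 <- run_pls_svm(sm$X, sm$group, n_components_max = 4, folds = 3,
                    C_grid = grid$C, sigma_grid = grid$sigma, seed = 19)
  expect_identical(r1$report$confusion, r2$report$confusion)
  expect_identical(r1$report$auc, r2$report$auc)
  expect_identical(r1$selection$msep, r2$selection$msep)
  expect_identical(r1$report$positive_class, "OVX")
  expect_gte(r1$selection$n_selected, 1L)
})
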