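#' Compare groups with the assumption-routed decision tree
#'
#' Shapiro-Wilk normality is tested per group; if every group passes at
#' `alpha`, Levene's test (classic, mean-centered by default) checks variance
#' homogeneity. Routing: all normal and homogeneous -> one-way ANOVA; all
#' normal but heterogeneous -> Welch's ANOVA; any group non-normal ->
#' Kruskal-Wallis. `significant` is `p_value < alpha`.
#'
#' @param values Named list of numeric vectors, one per group (each n >= 3),
#'   or a numeric vector together with `groups`.
#' @param groups Optional grouping vector when `values` is numeric.
#' @param alpha Significance level used both for the assumption tests and the
#'   final call (default 0.05).
#' @param levene_center `"mean"` (classic) or `"median"` (Brown-Forsythe).
#' @return A `group_comparison`: list with per-group `n`, `mean`, `sd`,
#'   `normality_p`, `variance_homogeneity_p` (NA when not reached),
#'   `test_used`, `p_value`, `significant`.
#' @export
#' @examples
#' set.seed(1)
#' compare_groups(list(A = rnorm(10), B = rnorm(10), C = rnorm(10)))$test_used
compare_groups <- function(values, groups = NULL, alpha = 0.05,
                           levene_center = c("mean", "median")) {
  levene_center <- match.arg(levene_center)
  if (is.numeric(values) && !is.null(groups)) {
    values <- split(as.numeric(values), groups)
  }
  stopifnot(is.list(values), length(values) >= 2)
  if (is.null(names(values)) || any(names(values) == "")) {
    names(values) <- paste0("G", seq_along(values))
  }
  ns <- vapply(values, length, integer(1))
  if (any(ns < 3)) {
    stop("compare_groups: every group needs >= 3 values (normality test ",
         "undefined below that); offending group(s): ",
         paste(names(values)[ns < 3], collapse = ", "))
  }
  normality_p <- vapply(values, function(v) stats::shapiro.test(v)$p.value,
                        numeric(1))
  all_normal <- all(normality_p >= alpha)

  x <- unlist(values, use.names = FALSE)
  g <- factor(rep(names(values), ns), levels = names(values))

  levene_p <- NA_real_
  if (all_normal) {
    center_fun <- if (levene_center == "mean") mean else stats::median
    z <- abs(x - stats::ave(x, g, FUN = center_fun))
    levene_p <- stats::anova(stats::lm(z ~ g))[["Pr(>F)"]][1]
  }

  if (!all_normal) {
    test_used <- "Kruskal-Wallis"
    p <- stats::kruskal.test(x, g)$p.value
  } else if (levene_p >= alpha) {
    test_used <- "one-way ANOVA"
    p <- stats::oneway.test(x ~ g, var.equal = TRUE)$p.value
  } else {
    test_used <- "Welch ANOVA"
    p <- stats::oneway.test(x ~ g, var.equal = FALSE)$p.value
  }

  structure(list(
    n = ns,
    mean = vapply(values, mean, numeric(1)),
    sd = vapply(values, stats::sd, numeric(1)),
    normality_p = normality_p,
    variance_homogeneity_p = levene_p,
    test_used = test_used,
    p_value = p,
    significant = p < alpha,
    alpha = alpha
  ), class = "group_comparison")
}

#' Band-wise group comparisons over a peak matrix
#'
#' Runs [compare_groups()] on every band of a peak intensity matrix.
#'
#' @param pm A `peak_matrix` from [build_peak_matrix()].
#' @param alpha Significance level.
#' @param p_adjust Multiple-testing correction across bands applied to the
#'   routed p-values (`"none"`, the default, or `"BH"`).
#' @return data.frame, one row per band: `position`, `test_used`, `p_value`,
#'   `p_adjusted`, `significant`, and per-group mean/SD columns.
#' @export
compare_peak_groups <- function(pm, alpha = 0.05,
                                p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(inherits(pm, "peak_matrix"))
  groups <- unique(pm$group)
  rows <- lapply(seq_along(pm$positions), function(j) {
    vals <- split(pm$intensity[, j], factor(pm$group, levels = groups))
    cmp <- compare_groups(vals, alpha = alpha)
    stats <- unlist(lapply(groups, function(g) {
      stats::setNames(c(cmp$mean[[g]], cmp$sd[[g]]),
                      paste0(g, c("_mean", "_sd")))
    }))
    c(list(position = pm$positions[j], test_used = cmp$test_used,
           p_value = cmp$p_value), as.list(stats))
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  df$p_adjusted <- if (p_adjust == "BH") {
    stats::p.adjust(df$p_value, "BH")
  } else df$p_value
  df$significant <- df$p_adjusted < alpha
  df
}

#' Relative standard deviation (percent)
#'
#' 100 x sample SD (n - 1 denominator) / mean — the substrate-uniformity
#' statistic used to QC SERS films.
#'
#' @param intensities Numeric vector (>= 2 values, positive mean).
#' @return RSD in percent.
#' @export
#' @examples
#' relative_standard_deviation(c(1, 3))  # 70.71%
relative_standard_deviation <- function(intensities) {
  if (length(intensities) < 2) stop("RSD needs at least 2 values")
  m <- mean(intensities)
  if (!is.finite(m) || m <= 0) {
    stop("RSD undefined: mean intensity must be positive (got ", format(m), ")")
  }
  100 * stats::sd(intensities) / m
}

#' SERS enhancement factor
#'
#' Concentration-normalized intensity ratio
#' (I_SERS / c_SERS) / (I_ref / c_ref) comparing a band intensity on the
#' enhancing substrate at concentration `c_sers` to the normal-Raman
#' reference at `c_ref`.
#'
#' @param i_sers,c_sers Band intensity and molar concentration on the
#'   SERS substrate.
#' @param i_ref,c_ref Band intensity and molar concentration of the
#'   reference measurement.
#' @return Dimensionless enhancement factor.
#' @export
#' @examples
#' enhancement_factor(100, 1e-9, 10, 1e-4)  # 1e6
enhancement_factor <- function(i_sers, c_sers, i_ref, c_ref) {
  vals <- c(i_sers = i_sers, c_sers = c_sers, i_ref = i_ref, c_ref = c_ref)
  bad <- !is.finite(vals) | vals <= 0
  if (any(bad)) {
    stop("enhancement_factor: all inputs must be positive; offending: ",
         paste(names(vals)[bad], collapse = ", "))
  }
  (i_sers / c_sers) / (i_ref / c_ref)
}
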