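pipeline_defaults <- function() {
  list(
    seed = 1L,
    cohort = list(
      n_samples_per_group = 30L, n_replicates = 10L,
      noise_sd = 2, sample_sd = 0.08, replicate_sd = 0.05,
      baseline_coefficients = c(200, 80, -50, -30, 20),
      ovx_up = 1.35, ovx_down = 0.72, ica_fraction = 0.45
    ),
    preprocessing = list(
      order = 5L, tolerance = 0.005, max_iterations = 100L,
      normalize_after_average = FALSE, clip_negative = FALSE
    ),
    statistics = list(
      alpha = 0.05, window_halfwidth = 5, p_adjust = "none"
    ),
    chemometrics = list(
      n_components_max = 10L, threshold = 0.05, folds = 10L,
      inner_folds = 5L, nested = FALSE, positive_class = "OVX",
      C_grid = 2^seq(-5, 15, by = 2), sigma_grid = 2^seq(-4, 4, by = 1)
    )
  )
}

check_numeric <- function(value, key, min = -Inf, integer = FALSE) {
  if (!is.numeric(value) || any(!is.finite(value))) {
    stop("config key '", key, "' must be numeric and finite")
  }
  if (any(value < min)) {
    stop("config key '", key, "' must be >= ", min, " (got ",
         paste(value, collapse = ", "), ")")
  }
  if (integer && any(value != round(value))) {
    stop("config key '", key, "' must be a whole number")
  }
  value
}

merge_section <- function(defaults, user, section) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    warning("ignoring unknown config key(s) under '", section, "': ",
            paste(unknown, collapse = ", "))
  }
  for (k in intersect(names(user), names(defaults))) defaults[[k]] <- user[[k]]
  defaults
}

#' Validate and default a pipeline run configuration
#'
#' Accepts a YAML/JSON file path or a nested list with (all optional)
#' sections `cohort`, `preprocessing`, `statistics`, `chemometrics` and a
#' top-level `seed`. Unknown keys warn and are ignored; type and range errors
#' fail naming the offending key.
#'
#' @param config Path to a YAML/JSON config file, a nested list, or NULL for
#'   all defaults.
#' @return A fully defaulted `run_config` list.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)  # YAML superset: also parses JSON
  }
  if (is.null(config)) config <- list()
  stopifnot(is.list(config))
  defs <- pipeline_defaults()
  unknown <- setdiff(names(config), c(names(defs), "outdir"))
  if (length(unknown)) {
    warning("ignoring unknown top-level config key(s): ",
            paste(unknown, collapse = ", "))
  }
  out <- defs
  if (!is.null(config$seed)) {
    out$seed <- as.integer(check_numeric(config$seed, "seed", integer = TRUE))
  }
  for (sec in c("cohort", "preprocessing", "statistics", "chemometrics")) {
    out[[sec]] <- merge_section(defs[[sec]], config[[sec]], sec)
  }
  with(out$cohort, {
    check_numeric(n_samples_per_group, "cohort.n_samples_per_group", min = 2,
                  integer = TRUE)
    check_numeric(n_replicates, "cohort.n_replicates", min = 1, integer = TRUE)
    check_numeric(noise_sd, "cohort.noise_sd", min = 0)
    check_numeric(sample_sd, "cohort.sample_sd", min = 0)
    check_numeric(replicate_sd, "cohort.replicate_sd", min = 0)
  })
  with(out$preprocessing, {
    check_numeric(order, "preprocessing.order", min = 1, integer = TRUE)
    check_numeric(tolerance, "preprocessing.tolerance", min = 0)
    check_numeric(max_iterations, "preprocessing.max_iterations", min = 1,
                  integer = TRUE)
  })
  check_numeric(out$statistics$alpha, "statistics.alpha", min = 0)
  with(out$chemometrics, {
    check_numeric(n_components_max, "chemometrics.n_components_max", min = 1,
                  integer = TRUE)
    check_numeric(threshold, "chemometrics.threshold", min = 0)
    check_numeric(folds, "chemometrics.folds", min = 2, integer = TRUE)
    check_numeric(C_grid, "chemometrics.C_grid", min = 1e-12)
    check_numeric(sigma_grid, "chemometrics.sigma_grid", min = 1e-12)
  })
  class(out) <- "run_config"
  out
}

config_to_cohort <- function(config) {
  cc <- config$cohort
  cohort_config(
    effects = default_group_effects(ovx_up = cc$ovx_up,
                                    ovx_down = cc$ovx_down,
                                    ica_fraction = cc$ica_fraction),
    n_samples_per_group = cc$n_samples_per_group,
    n_replicates = cc$n_replicates,
    baseline_coefficients = cc$baseline_coefficients,
    noise_sd = cc$noise_sd, sample_sd = cc$sample_sd,
    replicate_sd = cc$replicate_sd,
    seed = config$seed
  )
}

#' Run the full analysis pipeline
#'
#' simulate -> preprocess -> band statistics -> PLS-SVM classification, each
#' stage writing its artifacts under `outdir`: the cohort manifest and
#' spectrum files, the processed sample matrix, the peak intensity matrix,
#' the band comparison table, the difference spectra, the MSEP curve, the
#' selected-component loadings, the hyper-parameter accuracy surface, a
#' metrics JSON (sensitivity/specificity/accuracy/AUC for the three binary
#' tasks and the three-class task), and a run manifest recording parameters,
#' seed, package version and artifact checksums.
#'
#' @param config A `run_config` (see [validate_config()]), a config file
#'   path, or NULL for defaults.
#' @param outdir Output directory, created if needed.
#' @param stages Subset of `c("simulate", "preprocess", "stats", "classify")`
#'   to run; later stages read earlier stages' files if not run together.
#' @param write_spectra Write the individual spectrum CSVs (default TRUE for
#'   the simulate stage).
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list with stage results and artifact paths.
#' @export
run_pipeline <- function(config = NULL, outdir,
                         stages = c("simulate", "preprocess", "stats",
                                    "classify"),
                         write_spectra = TRUE, quiet = FALSE) {
  config <- if (inherits(config, "run_config")) config else
    validate_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  paths <- list()
  res <- list(config = config)

  cohort <- NULL
  if ("simulate" %in% stages) {
    say("[simulate] generating cohort (seed ", config$seed, ")")
    cohort <- generate_cohort(config_to_cohort(config))
    if (write_spectra) {
      paths$cohort_manifest <- write_cohort(cohort, file.path(outdir, "cohort"))
    } else {
      dir.create(file.path(outdir, "cohort"), showWarnings = FALSE)
      man_path <- file.path(outdir, "cohort", "manifest.csv")
      utils::write.csv(cohort$manifest, man_path, row.names = FALSE,
                       quote = FALSE)
      paths$cohort_manifest <- man_path
    }
    res$cohort <- cohort
  }

  samples <- NULL
  if ("preprocess" %in% stages) {
    if (is.null(cohort)) {
      cohort <- read_cohort(file.path(outdir, "cohort", "manifest.csv"))
    }
    pp <- config$preprocessing
    say("[preprocess] baseline removal (order ", pp$order,
        "), area normalization, replicate averaging")
    samples <- preprocess_cohort(cohort, order = pp$order,
                                 tolerance = pp$tolerance,
                                 max_iterations = pp$max_iterations,
                                 normalize_after_average =
                                   pp$normalize_after_average,
                                 clip_negative = pp$clip_negative)
    paths$processed_matrix <- file.path(outdir, "processed_matrix.csv")
    write_sample_matrix(samples, paths$processed_matrix)
    res$samples <- samples
  }

  read_samples <- function() {
    sm <- read_sample_matrix(file.path(outdir, "processed_matrix.csv"))
    wn <- as.numeric(colnames(sm$X))
    grid <- spectral_grid(wn[1], wn[length(wn)], wn[2] - wn[1])
    lapply(seq_along(sm$sample_id), function(i) {
      structure(list(sample_id = sm$sample_id[i], group = sm$group[i],
                     grid = grid, intensities = sm$X[i, ],
                     n_replicates_used = NA_integer_),
                class = "sample_spectrum")
    })
  }

  if ("stats" %in% stages) {
    if (is.null(samples)) samples <- read_samples()
    st <- config$statistics
    say("[stats] band intensities, group comparisons, difference spectra")
    table <- peak_assignment_table(st$window_halfwidth)
    pm <- build_peak_matrix(samples, table)
    paths$peak_matrix <- file.path(outdir, "peak_matrix.csv")
    utils::write.csv(
      cbind(data.frame(sample_id = pm$sample_id, group = pm$group,
                       stringsAsFactors = FALSE),
            as.data.frame(pm$intensity, check.names = FALSE)),
      paths$peak_matrix, row.names = FALSE, quote = FALSE)

    cmp <- compare_peak_groups(pm, alpha = st$alpha, p_adjust = st$p_adjust)
    paths$comparisons <- file.path(outdir, "comparisons.csv")
    utils::write.csv(cmp, paths$comparisons, row.names = FALSE)

    groups <- unique(pm$group)
    dif_list <- list(wavenumber = wavenumbers(samples[[1]]$grid))
    if (all(c("OVX", "Sham") %in% groups)) {
      dif_list[["OVX_minus_Sham"]] <-
        mean_and_difference_spectra(samples, "OVX", "Sham")$difference$delta
    }
    if (all(c("ICA", "OVX") %in% groups)) {
      dif_list[["ICA_minus_OVX"]] <-
        mean_and_difference_spectra(samples, "ICA", "OVX")$difference$delta
    }
    paths$difference_spectra <- file.path(outdir, "difference_spectra.csv")
    utils::write.csv(as.data.frame(dif_list), paths$difference_spectra,
                     row.names = FALSE)
    res$peak_matrix <- pm
    res$comparisons <- cmp
  }

  if ("classify" %in% stages) {
    if (is.null(samples)) samples <- read_samples()
    ch <- config$chemometrics
    sm <- sample_matrix(samples)
    say("[classify] PLS-SVM with ", ch$folds, "-fold CV")
    tasks <- list()
    groups <- unique(sm$group)
    if (length(groups) >= 3) {
      combos <- utils::combn(groups, 2, simplify = FALSE)
    } else combos <- list(groups)
    for (cb in combos) {
      keep <- sm$group %in% cb
      pos <- if (ch$positive_class %in% cb) ch$positive_class else cb[2]
      tasks[[paste(cb, collapse = "_vs_")]] <-
        run_pls_svm(sm$X[keep, , drop = FALSE], sm$group[keep],
                    n_components_max = ch$n_components_max,
                    threshold = ch$threshold, C_grid = ch$C_grid,
                    sigma_grid = ch$sigma_grid, folds = ch$folds,
                    inner_folds = ch$inner_folds, seed = config$seed,
                    positive_class = pos, nested = ch$nested)
    }
    if (length(groups) >= 3) {
      tasks[[paste(groups, collapse = "_vs_")]] <-
        run_pls_svm(sm$X, sm$group,
                    n_components_max = ch$n_components_max,
                    threshold = ch$threshold, C_grid = ch$C_grid,
                    sigma_grid = ch$sigma_grid, folds = ch$folds,
                    inner_folds = ch$inner_folds, seed = config$seed,
                    positive_class = ch$positive_class, nested = ch$nested)
    }
    main <- tasks[[length(tasks)]]

    if (!ch$nested) {
      paths$msep_curve <- file.path(outdir, "msep_curve.csv")
      utils::write.csv(
        data.frame(n_components = as.integer(names(main$selection$msep)),
                   msep = as.numeric(main$selection$msep)),
        paths$msep_curve, row.names = FALSE)
      paths$loadings <- file.path(outdir, "loadings.csv")
      ld <- as.data.frame(main$pls_fit$loadings)
      names(ld) <- paste0("PC", seq_len(ncol(ld)))
      utils::write.csv(cbind(wavenumber = wavenumbers(samples[[1]]$grid), ld),
                       paths$loadings, row.names = FALSE)
      paths$grid_surface <- file.path(outdir, "grid_surface.csv")
      utils::write.csv(main$cv$surface, paths$grid_surface, row.names = FALSE)
      paths$roc_points <- file.path(outdir, "roc_points.csv")
      utils::write.csv(main$report$roc, paths$roc_points, row.names = FALSE)
    }

    metrics <- lapply(tasks, function(tk) {
      rp <- tk$report
      pos <- rp$positive_class
      list(positive_class = pos,
           sensitivity_pct = round(100 * rp$sensitivity[[pos]], 2),
           specificity_pct = round(100 * rp$specificity[[pos]], 2),
           accuracy_pct = round(100 * rp$accuracy, 2),
           auc = round(rp$auc, 4),
           n_components = if (!is.null(tk$selection))
             tk$selection$n_selected else NA,
           confusion = unclass(rp$confusion))
    })
    paths$metrics <- file.path(outdir, "metrics.json")
    jsonlite::write_json(metrics, paths$metrics, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    res$tasks <- tasks
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("sersdx")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    stages = stages,
    parameters = unclass(config),
    artifact_md5 = as.list(tools::md5sum(unlist(paths)))
  )
  paths$run_manifest <- file.path(outdir, "run_manifest.json")
  jsonlite::write_json(manifest, paths$run_manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  res$paths <- paths
  invisible(res)
}
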