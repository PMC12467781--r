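#' Write one spectrum as a two-column CSV
#'
#' @param spectrum A `raw_spectrum` (or any list with `grid`, `intensities`).
#' @param path Output file path.
#' @param header Write a `wavenumber,intensity` header line (default TRUE).
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path, header = TRUE) {
  df <- data.frame(wavenumber = wavenumbers(spectrum$grid),
                   intensity = spectrum$intensities)
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = header, quote = FALSE)
  invisible(path)
}

#' Read a two-column wavenumber/intensity CSV
#'
#' Accepts files with or without a header line; the wavenumber column must be
#' a regular, strictly increasing grid.
#'
#' @param path File path.
#' @return A `raw_spectrum`.
#' @export
read_spectrum_csv <- function(path) {
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  first <- readLines(path, n = 1)
  has_header <- grepl("[A-Za-z]", first)
  df <- utils::read.csv(path, header = has_header,
                        col.names = c("wavenumber", "intensity"))
  spectrum_from_xy(df$wavenumber, df$intensity, source = path)
}

spectrum_from_xy <- function(x, y, source = "") {
  if (length(x) < 2) stop("spectrum has fewer than 2 points: ", source)
  steps <- diff(x)
  if (any(steps <= 0) || diff(range(steps)) > 1e-6 * steps[1]) {
    stop("wavenumber axis is not a regular increasing grid: ", source)
  }
  if (any(!is.finite(y))) stop("non-finite intensities in ", source)
  grid <- spectral_grid(x[1], x[length(x)], steps[1])
  structure(list(grid = grid, intensities = y, meta = list(source = source)),
            class = "raw_spectrum")
}

#' Write a cohort to disk
#'
#' One two-column CSV per spectrum plus a manifest CSV with columns
#' `file`, `sample_id`, `group`, `replicate`.
#'
#' @param cohort A `sers_cohort` from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sers_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  files <- sprintf("%s_r%02d.csv", man$sample_id, man$replicate)
  for (i in seq_along(cohort$spectra)) {
    write_spectrum_csv(cohort$spectra[[i]], file.path(dir, files[i]))
  }
  man_out <- cbind(data.frame(file = files, stringsAsFactors = FALSE), man)
  man_path <- file.path(dir, "manifest.csv")
  utils::write.csv(man_out, man_path, row.names = FALSE, quote = FALSE)
  invisible(man_path)
}

#' Read a cohort manifest and its spectra
#'
#' @param manifest_path Path to a manifest CSV (`file,sample_id,group,replicate`);
#'   spectrum files are resolved relative to the manifest's directory.
#' @return A `sers_cohort` (without a generator config).
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path)
  }
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("file", "sample_id", "group", "replicate")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  base <- dirname(manifest_path)
  spectra <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    p <- file.path(base, man$file[i])
    if (!file.exists(p)) {
      stop("manifest row ", i, " (sample ", man$sample_id[i],
           ", replicate ", man$replicate[i], "): file not found: ", p)
    }
    spectra[[i]] <- read_spectrum_csv(p)
  }
  structure(list(spectra = spectra,
                 manifest = man[, c("sample_id", "group", "replicate")],
                 config = NULL),
            class = "sers_cohort")
}

#' Read a single-spectrum JCAMP-DX file
#'
#' Minimal reader for uncompressed JCAMP-DX: `##XYPOINTS=(XY..XY)` pairs or
#' `##XYDATA=(X++(Y..Y))` tables with plain (AFFN) numbers. Compressed
#' (SQZ/DIF/DUP) encodings are not supported.
#'
#' @param path File path.
#' @return A `raw_spectrum`.
#' @export
read_jcamp <- function(path) {
  if (!file.exists(path)) stop("JCAMP file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  ldr <- function(name) {
    hit <- grep(paste0("^##", name, "\\s*="), lines, ignore.case = TRUE)
    if (length(hit) == 0) return(NULL)
    sub(paste0("^##", name, "\\s*=\\s*"), "", lines[hit[1]], ignore.case = TRUE)
  }
  data_start <- grep("^##(XYDATA|XYPOINTS)", lines, ignore.case = TRUE)
  if (length(data_start) == 0) stop("no XYDATA/XYPOINTS record in ", path)
  i0 <- data_start[1]
  mode <- toupper(sub("^##([A-Za-z]+).*", "\\1", lines[i0]))
  end <- grep("^##END", lines, ignore.case = TRUE)
  end <- if (length(end)) min(end[end > i0]) else length(lines) + 1
  body <- lines[(i0 + 1):(end - 1)]
  body <- body[!grepl("^\\$\\$|^##", body)]
  nums <- lapply(body, function(l) {
    as.numeric(regmatches(l, gregexpr("[-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?",
                                      l))[[1]])
  })
  if (mode == "XYPOINTS") {
    v <- unlist(nums)
    if (length(v) %% 2 != 0) stop("odd number of values in XYPOINTS of ", path)
    x <- v[seq(1, length(v), 2)]
    y <- v[seq(2, length(v), 2)]
  } else {
    x <- numeric(0); y <- numeric(0)
    for (v in nums) {
      if (length(v) < 2) next
      x <- c(x, v[1])  # placeholder start; step filled below
      y <- c(y, v[-1])
    }
    # X column gives the first abscissa of each row; rebuild the full axis
    xf <- as.numeric(ldr("FIRSTX")); xl <- as.numeric(ldr("LASTX"))
    if (length(xf) == 0 || is.na(xf)) xf <- x[1]
    n <- length(y)
    if (length(xl) == 0 || is.na(xl)) {
      step_guess <- if (length(x) > 1) (x[2] - x[1]) / (length(nums[[1]]) - 1) else 1
      xl <- xf + step_guess * (n - 1)
    }
    yfac <- as.numeric(ldr("YFACTOR"))
    if (length(yfac) == 1 && !is.na(yfac)) y <- y * yfac
    x <- seq(xf, xl, length.out = n)
  }
  spectrum_from_xy(x, y, source = path)
}

#' Write the processed sample matrix as CSV
#'
#' Rows are samples; the first two columns are `sample_id` and `group`,
#' followed by one column per wavenumber.
#'
#' @param samples List of `sample_spectrum` from [preprocess_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sample_matrix <- function(samples, path) {
  sm <- sample_matrix(samples)
  df <- cbind(data.frame(sample_id = sm$sample_id, group = sm$group,
                         stringsAsFactors = FALSE),
              as.data.frame(sm$X))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a processed sample matrix CSV
#'
#' @param path CSV written by [write_sample_matrix()].
#' @return List with `X` (samples x wavenumbers matrix, columns named by
#'   wavenumber), `sample_id`, `group`.
#' @export
read_sample_matrix <- function(path) {
  if (!file.exists(path)) stop("sample matrix not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  X <- as.matrix(df[, setdiff(names(df), c("sample_id", "group")), drop = FALSE])
  storage.mode(X) <- "double"
  list(X = X, sample_id = df$sample_id, group = df$group)
}
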