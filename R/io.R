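#' Read a pull-coordinate time series (xvg dialect)
#'
#' Parses the two-column text format written by GROMACS pull output: lines
#' starting with `#` or `@` are comments/metadata; data rows hold time (ps)
#' and the reaction coordinate (nm).
#'
#' @param path file path.
#' @param dialect only `"xvg"` is supported.
#' @return Data frame with columns `time` (ps) and `coordinate` (nm).
#' @export
read_pull_series <- function(path, dialect = "xvg") {
  dialect <- match.arg(dialect, "xvg")
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))
  if (!any(keep))
    stop("no data rows in ", path, call. = FALSE)
  rows <- which(keep)
  parts <- strsplit(trimws(lines[rows]), "\\s+")
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop(sprintf("malformed data line %d in %s (need two columns)",
                 rows[bad[1]], path), call. = FALSE)
  t_col <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  x_col <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  bad <- which(is.na(t_col) | is.na(x_col))
  if (length(bad))
    stop(sprintf("malformed numeric value on line %d in %s",
                 rows[bad[1]], path), call. = FALSE)
  data.frame(time = t_col, coordinate = x_col)
}

#' Write a window's coordinate series in the xvg dialect
#'
#' @param window an `umbrella_window` (or any list with `time` and
#'   `samples`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pull_series <- function(window, path) {
  header <- c(sprintf("# umbrella window: center %.6g nm, spring %.6g kJ/mol/nm^2",
                      window$center, window$spring),
              "@ title \"pull coordinate\"",
              "@ xaxis label \"time (ps)\"",
              "@ yaxis label \"r (nm)\"")
  writeLines(c(header,
               sprintf("%.4f %.9f", window$time, window$samples)),
             path)
  invisible(path)
}

#' Write per-frame component energies as CSV
#'
#' Columns: `time`, `e_ww`, `e_aaw`, `e_aaaa` (kJ/mol). The total is not
#' stored; it is reconstructed as the exact per-frame sum on read, which
#' preserves the bookkeeping identity.
#'
#' @param window an `umbrella_window` carrying energies.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_window_energies <- function(window, path) {
  if (is.null(window$energies))
    stop("window carries no energies", call. = FALSE)
  df <- data.frame(time = window$time,
                   e_ww = window$energies$e_ww,
                   e_aaw = window$energies$e_aaw,
                   e_aaaa = window$energies$e_aaaa)
  write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a set of umbrella windows plus a JSON manifest
#'
#' Each window's coordinate series goes to `<label>.xvg` and its energies
#' (if present) to `<label>_energies.csv`; the manifest records centre,
#' spring constant, seed and file paths.
#'
#' @param windows list of `umbrella_window` objects.
#' @param dir output directory (created if needed).
#' @param manifest manifest filename within `dir`.
#' @return Path to the manifest, invisibly.
#' @export
write_umbrella_windows <- function(windows, dir,
                                   manifest = "windows_manifest.json") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(windows, function(w) {
    series_file <- sprintf("window_%s.xvg", w$label)
    write_pull_series(w, file.path(dir, series_file))
    energy_file <- NULL
    if (!is.null(w$energies)) {
      energy_file <- sprintf("window_%s_energies.csv", w$label)
      write_window_energies(w, file.path(dir, energy_file))
    }
    list(label = w$label, center = w$center, spring = w$spring,
         seed = w$seed, series_file = series_file,
         energy_file = energy_file)
  })
  path <- file.path(dir, manifest)
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read umbrella windows from a manifest
#'
#' @param manifest_path path to a manifest written by
#'   [write_umbrella_windows()].
#' @return List of `umbrella_window` objects.
#' @export
read_umbrella_windows <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path, call. = FALSE)
  dir <- dirname(manifest_path)
  entries <- jsonlite::read_json(manifest_path)
  lapply(entries, function(e) {
    series_path <- file.path(dir, e$series_file)
    if (!file.exists(series_path))
      stop(sprintf("window '%s': series file missing (%s)", e$label,
                   e$series_file), call. = FALSE)
    series <- read_pull_series(series_path)
    energies <- NULL
    if (!is.null(e$energy_file)) {
      epath <- file.path(dir, e$energy_file)
      if (!file.exists(epath))
        stop(sprintf("window '%s': energy file missing (%s)", e$label,
                     e$energy_file), call. = FALSE)
      edf <- read.csv(epath)
      if (nrow(edf) != nrow(series))
        stop(sprintf("window '%s': energy length %d != series length %d",
                     e$label, nrow(edf), nrow(series)), call. = FALSE)
      energies <- data.frame(e_ww = edf$e_ww, e_aaw = edf$e_aaw,
                             e_aaaa = edf$e_aaaa,
                             e_total = edf$e_ww + edf$e_aaw + edf$e_aaaa)
    }
    structure(list(center = e$center, spring = e$spring,
                   time = series$time, samples = series$coordinate,
                   energies = energies, label = e$label, seed = e$seed),
              class = "umbrella_window")
  })
}
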