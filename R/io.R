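#' Read a two-column spectrum file
#'
#' Parses delimited text with one `wavenumber<sep>intensity` pair per line.
#' Comma, tab and whitespace delimiters are accepted.  Lines starting with
#' `#` are comments; comments of the form `# key: value` are collected into
#' the spectrum metadata.  Rows are sorted by wavenumber; duplicate
#' wavenumbers and non-numeric cells are rejected with the offending line
#' number.
#'
#' @param path Path to the file.
#' @return An [ir_spectrum()].
#' @seealso [write_spectrum()]
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  wn <- numeric(0)
  it <- numeric(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      body <- trimws(sub("^#+", "", ln))
      if (grepl(":", body, fixed = TRUE)) {
        key <- trimws(sub(":.*$", "", body))
        val <- trimws(sub("^[^:]*:", "", body))
        if (nzchar(key)) meta[[key]] <- val
      }
      next
    }
    cells <- strsplit(ln, "[,\t ]+")[[1]]
    cells <- cells[nzchar(cells)]
    if (length(cells) < 2L) {
      stop(sprintf("parse error at line %d of '%s': expected two columns", i, path))
    }
    vals <- suppressWarnings(as.numeric(cells[1:2]))
    if (anyNA(vals)) {
      stop(sprintf("parse error at line %d of '%s': non-numeric cell", i, path))
    }
    wn <- c(wn, vals[1])
    it <- c(it, vals[2])
  }
  if (length(wn) == 0L) stop(sprintf("no data rows in '%s'", path))
  if (anyDuplicated(wn)) {
    stop(sprintf("format error in '%s': duplicate wavenumber %g", path,
                 wn[anyDuplicated(wn)]))
  }
  ir_spectrum(wn, it, meta = meta)
}

#' Write a spectrum to a two-column delimited file
#'
#' Metadata are serialized as `# key: value` comment lines, followed by
#' comma-separated `wavenumber,intensity` rows printed with 15 significant
#' digits so that values round-trip through [read_spectrum()].
#'
#' @param spectrum An [ir_spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "ir_spectrum"))
  if (length(spectrum$wavenumbers) == 0L) stop("empty spectrum")
  hdr <- character(0)
  if (length(spectrum$meta)) {
    hdr <- sprintf("# %s: %s", names(spectrum$meta),
                   vapply(spectrum$meta, function(v)
                     paste(format(v, digits = 15), collapse = " "), ""))
  }
  rows <- sprintf("%.15g,%.15g", spectrum$wavenumbers, spectrum$intensities)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a peak-list file
#'
#' Three delimited columns (band center in cm-1, relative intensity, full
#' width at half maximum in cm-1) with one header line.
#'
#' @param path Path to the file.
#' @return A data frame with columns `center`, `intensity`, `fwhm`.
#' @seealso [write_peaklist()], [read_isomer_library()]
#' @export
read_peaklist <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "", fill = FALSE,
                          col.names = c("center", "intensity", "fwhm"))
  peak_bands(df$center, df$intensity, df$fwhm)
}

#' Write a peak-list file
#'
#' @param bands A data frame of bands as returned by [peak_bands()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(bands, path) {
  bands <- peak_bands(bands$center, bands$intensity, bands$fwhm)
  utils::write.table(
    data.frame(center_cm1 = bands$center, intensity = bands$intensity,
               fwhm_cm1 = bands$fwhm),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an isomer library from a structured config
#'
#' The config is a YAML file mapping isomer names to peak-list paths
#' (relative paths are resolved against the config's directory), with an
#' optional `window: [lo, hi]` entry:
#'
#' ```yaml
#' window: [1000, 1150]
#' isomers:
#'   alpha-Gal-phytosphingosine: alpha_gal.tsv
#'   beta-Gal-phytosphingosine: beta_gal.tsv
#' ```
#'
#' @param path Path to the YAML config.
#' @return An [isomer_library()].
#' @export
read_isomer_library <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$isomers)) stop("library config lacks an 'isomers' mapping")
  window <- if (is.null(cfg$window)) c(1000, 1150) else as.numeric(cfg$window)
  dir <- dirname(path)
  models <- lapply(names(cfg$isomers), function(nm) {
    p <- cfg$isomers[[nm]]
    if (!file.exists(p)) p <- file.path(dir, p)
    isomer_model(nm, read_peaklist(p))
  })
  isomer_library(models, window = window)
}

#' Snapshot of a pipeline run for reproducibility
#'
#' Records the configuration, every random seed used, input-file checksums
#' and a timestamp, so a study can be re-executed bit-for-bit.
#'
#' @param config Named list describing the run configuration.
#' @param seeds Named list or vector of all random seeds used.
#' @param files Character vector of input file paths to checksum (optional).
#' @return An object of class `run_manifest`.
#' @export
run_manifest <- function(config = list(), seeds = list(), files = character(0)) {
  checksums <- if (length(files)) tools::md5sum(files) else character(0)
  structure(list(
    config = config,
    seeds = seeds,
    checksums = as.list(checksums),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    r_version = R.version.string
  ), class = "run_manifest")
}

#' Write a run manifest as YAML
#'
#' @param manifest A [run_manifest()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "run_manifest"))
  yaml::write_yaml(unclass(manifest), path)
  invisible(path)
}

#' Write an abundance table as delimited text
#'
#' Columns: `spectrum_id`, `isomer`, `percent`, `truth_percent`,
#' `abs_error` (the last two are `NA` when the composition is unknown).
#'
#' @param table A data frame as returned by [weights_to_percentages()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
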