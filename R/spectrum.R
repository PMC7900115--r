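#' Infrared spectrum
#'
#' The universal currency of the pipeline: paired wavenumber/intensity
#' vectors plus free-form provenance metadata (species, adduct, m/z,
#' generating composition, ...).  Wavenumbers must be strictly increasing;
#' intensities are in arbitrary absorbance / ion-yield units and may be
#' negative (noise is not clipped at generation time).
#'
#' @param wavenumbers Strictly increasing numeric vector, cm-1.
#' @param intensities Numeric vector of the same length.
#' @param meta Named list of provenance metadata.
#' @return An object of class `ir_spectrum` with fields `wavenumbers`,
#'   `intensities`, `meta`.
#' @examples
#' s <- ir_spectrum(c(1000, 1002, 1004), c(0, 1, 0))
#' @export
ir_spectrum <- function(wavenumbers, intensities, meta = list()) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) != length(intensities)) {
    stop("wavenumbers and intensities must have equal length")
  }
  if (length(wavenumbers) == 0L) stop("empty spectrum")
  if (anyNA(wavenumbers) || anyNA(intensities)) stop("NA values in spectrum")
  if (anyDuplicated(wavenumbers)) stop("duplicate wavenumber")
  if (is.unsorted(wavenumbers, strictly = TRUE)) {
    o <- order(wavenumbers)
    wavenumbers <- wavenumbers[o]
    intensities <- intensities[o]
  }
  stopifnot(is.list(meta))
  structure(list(wavenumbers = wavenumbers, intensities = intensities,
                 meta = meta),
            class = "ir_spectrum")
}

#' @export
print.ir_spectrum <- function(x, ...) {
  cat(sprintf("<ir_spectrum> %d points, %g..%g cm-1\n",
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers)))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, function(v)
      paste(format(v), collapse = " "))), sep = "=", collapse = "; "), "\n")
  }
  invisible(x)
}

#' @export
#' @importFrom graphics plot
plot.ir_spectrum <- function(x, ...,
                             xlab = expression(tilde(nu) ~ (cm^-1)),
                             ylab = "intensity (arb. u.)", type = "l") {
  plot(x$wavenumbers, x$intensities, type = type, xlab = xlab, ylab = ylab,
       ...)
}

#' @export
length.ir_spectrum <- function(x) length(x$wavenumbers)

# indices of grid points inside a closed window [lo, hi]
window_idx <- function(spectrum, window) {
  if (is.null(window)) return(seq_along(spectrum$wavenumbers))
  stopifnot(length(window) == 2L, window[2] > window[1])
  which(spectrum$wavenumbers >= window[1] & spectrum$wavenumbers <= window[2])
}

same_grid <- function(a, b) {
  length(a$wavenumbers) == length(b$wavenumbers) &&
    all(a$wavenumbers == b$wavenumbers)
}
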