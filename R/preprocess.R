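# trapezoidal quadrature on (x, y)
trapz_area <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-n] + y[-1]) / 2)
}

#' Bin a raw spectrum onto a fixed-step grid
#'
#' Bin `b`, centered at `c_b`, collects raw points with wavenumber in the
#' half-open window `[c_b - step/2, c_b + step/2)` (lower-inclusive, so
#' every raw point lands in exactly one bin).  The bin value is the
#' arithmetic mean of the collected intensities, which keeps bin values on
#' the intensity scale regardless of raw sampling density.  Empty interior
#' bins are filled by linear interpolation between the neighboring
#' non-empty bins; empty bins at the edges take the nearest non-empty bin
#' value.  Negative intensities pass through unchanged.
#'
#' @param spectrum An [ir_spectrum()].
#' @param grid A [wavenumber_grid()].
#' @return An [ir_spectrum()] on the grid centers.
#' @export
bin_spectrum <- function(spectrum, grid) {
  stopifnot(inherits(spectrum, "ir_spectrum"),
            inherits(grid, "wavenumber_grid"))
  centers <- grid$centers
  step <- grid$step
  idx <- floor((spectrum$wavenumbers - (grid$start - step / 2)) / step) + 1
  keep <- idx >= 1 & idx <= length(centers)
  if (!any(keep)) stop("no overlap with grid")
  means <- tapply(spectrum$intensities[keep], idx[keep], mean)
  vals <- rep(NA_real_, length(centers))
  vals[as.integer(names(means))] <- as.numeric(means)
  if (anyNA(vals)) {
    filled <- which(!is.na(vals))
    vals <- stats::approx(centers[filled], vals[filled], xout = centers,
                          method = "linear", rule = 2)$y
  }
  ir_spectrum(centers, vals, meta = spectrum$meta)
}

#' Normalize a spectrum to unit area over a window
#'
#' Divides all intensities by the trapezoidal integral of the intensity
#' over the window, so that the post-normalization integral over the window
#' is exactly 1.  Idempotent and invariant under positive rescaling of the
#' input.
#'
#' @param spectrum An [ir_spectrum()].
#' @param window Length-2 interval in cm-1; defaults to the spectrum's full
#'   range.
#' @return The rescaled [ir_spectrum()].
#' @export
normalize_area <- function(spectrum, window = NULL) {
  stopifnot(inherits(spectrum, "ir_spectrum"))
  i <- window_idx(spectrum, window)
  if (length(i) < 2L) stop("degenerate spectrum: window covers < 2 points")
  a <- trapz_area(spectrum$wavenumbers[i], spectrum$intensities[i])
  if (!(a > 0)) stop("degenerate spectrum: non-positive area over window")
  ir_spectrum(spectrum$wavenumbers, spectrum$intensities / a,
              meta = spectrum$meta)
}
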