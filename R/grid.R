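#' Number of bins of a fixed-step wavenumber grid
#'
#' Closed form `(stop - start) / step + 1` for a grid whose first and last
#' bin centers coincide with `start` and `stop`.  The canonical fingerprint
#' grid 1000--1150 cm-1 at 2 cm-1 steps has 76 points; the extended
#' 952--1150 cm-1 grid has 100.
#'
#' @param start,stop Window limits in cm-1 (`stop > start`).
#' @param step Bin width in cm-1 (`step > 0`).
#' @return Integer number of bin centers.
#' @examples
#' n_bins(1000, 1150, 2) # 76
#' n_bins(952, 1150, 2)  # 100
#' @export
n_bins <- function(start, stop, step) {
  g <- wavenumber_grid(start, stop, step)
  length(g$centers)
}

#' Fixed-step wavenumber grid
#'
#' Defines the bin centers `start, start + step, ..., stop` used for binning
#' and for rendering synthetic spectra.  The range must be an integer
#' multiple of the step (within a relative tolerance of 1e-9), otherwise the
#' grid is rejected with a "grid misalignment" error.
#'
#' @inheritParams n_bins
#' @return An object of class `wavenumber_grid` with fields `start`, `stop`,
#'   `step` and the derived strictly increasing vector `centers`.
#' @examples
#' g <- wavenumber_grid(1000, 1150, 2)
#' length(g$centers)
#' @export
wavenumber_grid <- function(start, stop, step) {
  stopifnot(is.numeric(start), is.numeric(stop), is.numeric(step))
  if (stop <= start) stop("grid misalignment: 'stop' must exceed 'start'")
  if (step <= 0) stop("grid misalignment: 'step' must be positive")
  n <- (stop - start) / step
  if (abs(n - round(n)) > 1e-9 * max(1, abs(n))) {
    stop("grid misalignment: (stop - start) is not divisible by step")
  }
  n <- round(n)
  structure(
    list(start = start, stop = stop, step = step,
         centers = start + step * (0:n)),
    class = "wavenumber_grid"
  )
}

#' @export
print.wavenumber_grid <- function(x, ...) {
  cat(sprintf("<wavenumber_grid> %g..%g cm-1, step %g (%d points)\n",
              x$start, x$stop, x$step, length(x$centers)))
  invisible(x)
}

# Accept either a wavenumber_grid or a bare numeric vector of centers.
grid_centers <- function(grid) {
  if (inherits(grid, "wavenumber_grid")) return(grid$centers)
  if (is.numeric(grid)) {
    if (is.unsorted(grid, strictly = TRUE)) {
      stop("grid centers must be strictly increasing")
    }
    return(as.numeric(grid))
  }
  stop("'grid' must be a wavenumber_grid or a numeric vector")
}
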