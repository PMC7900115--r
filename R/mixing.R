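#' Mixing ratio of an isomeric mixture
#'
#' @param labels Character vector of isomer names.
#' @param weights Non-negative weights of the same length, summing to 1
#'   within 1e-9.
#' @return An object of class `mixing_ratio`.
#' @export
mixing_ratio <- function(labels, weights) {
  stopifnot(is.character(labels), length(labels) == length(weights))
  weights <- as.numeric(weights)
  if (any(weights < 0)) stop("weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  if (anyDuplicated(labels)) stop("duplicate labels in mixing ratio")
  structure(list(labels = labels, weights = weights), class = "mixing_ratio")
}

#' @export
print.mixing_ratio <- function(x, ...) {
  cat("<mixing_ratio>", paste(sprintf("%s=%.4g", x$labels, x$weights),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Ratio-weighted average of pure spectra
#'
#' Models a mixture spectrum as the weighted average of area-normalized
#' pure-isomer spectra: each input is first normalized to unit area over
#' the analysis window, the elementwise sum `sum_i w_i * I_i(nu)` is
#' formed, and the result is normalized again.  Because the weights act on
#' normalized spectra they represent fractional spectral contributions,
#' which equal molar fractions only under the equal-response assumption
#' (all isomers have the same integrated intensity per mole).
#'
#' @param spectra List of [ir_spectrum()] objects on a common grid, in the
#'   order of `ratio$labels`.
#' @param ratio A [mixing_ratio()] (or bare numeric weight vector).
#' @param window Normalization window; defaults to the full common grid.
#' @return An [ir_spectrum()], area-normalized over `window`.
#' @export
weighted_average_spectra <- function(spectra, ratio, window = NULL) {
  if (inherits(ratio, "mixing_ratio")) {
    w <- ratio$weights
  } else {
    w <- as.numeric(ratio)
    if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
      stop("weights must be non-negative and sum to 1")
    }
  }
  stopifnot(is.list(spectra), length(spectra) == length(w))
  for (s in spectra) {
    if (!inherits(s, "ir_spectrum")) stop("'spectra' must contain ir_spectrum objects")
    if (!same_grid(s, spectra[[1]])) stop("mismatched grids")
  }
  nu <- spectra[[1]]$wavenumbers
  y <- numeric(length(nu))
  for (i in seq_along(spectra)) {
    y <- y + w[i] * normalize_area(spectra[[i]], window)$intensities
  }
  normalize_area(ir_spectrum(nu, y, meta = list(source = "weighted_average")),
                 window)
}

#' Agreement metrics between two spectra
#'
#' @param a,b [ir_spectrum()] objects on a common grid.
#' @param window Optional window restricting the comparison.
#' @return A list with `rms` (root-mean-square difference), `cosine`
#'   (inner-product similarity) and `max_abs` (maximum absolute
#'   difference).
#' @export
compare_spectra <- function(a, b, window = NULL) {
  stopifnot(inherits(a, "ir_spectrum"), inherits(b, "ir_spectrum"))
  if (!same_grid(a, b)) stop("mismatched grids")
  i <- window_idx(a, window)
  x <- a$intensities[i]
  y <- b$intensities[i]
  d <- x - y
  na <- sqrt(sum(x^2))
  nb <- sqrt(sum(y^2))
  list(rms = sqrt(mean(d^2)),
       cosine = if (na > 0 && nb > 0) sum(x * y) / (na * nb) else NA_real_,
       max_abs = max(abs(d)))
}
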