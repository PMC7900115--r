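#' Validated table of absorption bands
#'
#' A band is a Gaussian line with a center (cm-1, > 0), a relative
#' intensity (arbitrary units, >= 0) and a full width at half maximum
#' (cm-1, > 0).
#'
#' @param center,intensity,fwhm Numeric vectors of equal length.
#' @return A data frame with columns `center`, `intensity`, `fwhm`.
#' @export
peak_bands <- function(center, intensity, fwhm) {
  center <- as.numeric(center)
  intensity <- as.numeric(intensity)
  fwhm <- as.numeric(fwhm)
  n <- length(center)
  if (length(intensity) != n || length(fwhm) != n) {
    stop("band columns must have equal length")
  }
  if (any(center <= 0)) stop("band centers must be positive")
  if (any(intensity < 0)) stop("band intensities must be non-negative")
  if (any(fwhm <= 0)) stop("band widths must be positive")
  data.frame(center = center, intensity = intensity, fwhm = fwhm)
}

#' Fingerprint model of a single isomer
#'
#' Ties an isomer name (and optionally the adduct under which its spectrum
#' was recorded) to an ordered list of absorption bands.  Bands typically
#' cover the 1000--1150 cm-1 glycan fingerprint window and may extend into
#' the amide (> 1450 cm-1) and ester carbonyl (1700--1800 cm-1) regions.
#'
#' @param name Isomer identifier, e.g. `"alpha-Gal-phytosphingosine"`.
#' @param bands A band table from [peak_bands()] (or a data frame with
#'   columns `center`, `intensity`, `fwhm`).
#' @param adduct Adduct label, e.g. `"[M+H]+"`.
#' @return An object of class `isomer_model`.
#' @export
isomer_model <- function(name, bands, adduct = "[M+H]+") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  bands <- peak_bands(bands$center, bands$intensity, bands$fwhm)
  if (nrow(bands) == 0L) stop("empty model")
  structure(list(name = name, adduct = adduct, bands = bands),
            class = "isomer_model")
}

#' @export
print.isomer_model <- function(x, ...) {
  cat(sprintf("<isomer_model> %s (%s), %d bands at %s cm-1\n", x$name,
              x$adduct, nrow(x$bands),
              paste(x$bands$center, collapse = ", ")))
  invisible(x)
}

#' Named collection of isomer fingerprint models
#'
#' @param models List of [isomer_model()] objects with pairwise distinct
#'   names; every model must have at least one band inside `window` so that
#'   it renders a nonzero spectrum there.
#' @param window Analysis wavenumber interval, cm-1.
#' @return An object of class `isomer_library` with fields `models` (a
#'   named list) and `window`.
#' @export
isomer_library <- function(models, window = c(1000, 1150)) {
  stopifnot(is.list(models), length(models) >= 1L,
            length(window) == 2L, window[2] > window[1])
  ok <- vapply(models, inherits, TRUE, what = "isomer_model")
  if (!all(ok)) stop("all elements of 'models' must be isomer_model objects")
  nms <- vapply(models, function(m) m$name, "")
  if (anyDuplicated(nms)) stop("isomer names must be pairwise distinct")
  in_win <- vapply(models, function(m) {
    any(m$bands$center >= window[1] & m$bands$center <= window[2] &
          m$bands$intensity > 0)
  }, TRUE)
  if (!all(in_win)) {
    stop("model(s) without a nonzero band inside the analysis window: ",
         paste(nms[!in_win], collapse = ", "))
  }
  names(models) <- nms
  structure(list(models = models, window = as.numeric(window)),
            class = "isomer_library")
}

#' @export
print.isomer_library <- function(x, ...) {
  cat(sprintf("<isomer_library> %d models on %g..%g cm-1: %s\n",
              length(x$models), x$window[1], x$window[2],
              paste(names(x$models), collapse = ", ")))
  invisible(x)
}

# unit-height Gaussian line shape
gauss_line <- function(nu, center, fwhm) {
  exp(-4 * log(2) * ((nu - center) / fwhm)^2)
}

#' Render an isomer fingerprint onto a wavenumber grid
#'
#' The intensity at wavenumber nu is the superposition
#' `sum_b intensity_b * G(nu; center_b, fwhm_b)` over the model's bands,
#' with `G` a unit-height Gaussian.  Deterministic and non-negative.
#'
#' @param model An [isomer_model()].
#' @param grid A [wavenumber_grid()] or numeric vector of grid points.
#' @return An [ir_spectrum()] on the grid.
#' @export
render_fingerprint <- function(model, grid) {
  stopifnot(inherits(model, "isomer_model"))
  nu <- grid_centers(grid)
  if (nrow(model$bands) == 0L) stop("empty model")
  y <- numeric(length(nu))
  for (b in seq_len(nrow(model$bands))) {
    y <- y + model$bands$intensity[b] *
      gauss_line(nu, model$bands$center[b], model$bands$fwhm[b])
  }
  ir_spectrum(nu, y, meta = list(species = model$name, adduct = model$adduct,
                                 source = "render_fingerprint"))
}

#' Stick spectrum from a frequency calculation
#'
#' Holds computed line positions and intensities together with the
#' post-processing applied before comparison with experiment: a
#' dimensionless multiplicative frequency scale factor (e.g. 0.965 for
#' harmonic frequencies) and a signed additive shift in cm-1 (e.g. +20 cm-1
#' for an anharmonic spectrum).
#'
#' @param frequencies Wavenumbers, cm-1.
#' @param intensities Non-negative intensities, same length.
#' @param scale_factor Multiplier applied to `frequencies`.
#' @param shift Additive offset in cm-1, applied after scaling.
#' @return An object of class `stick_spectrum`.
#' @export
stick_spectrum <- function(frequencies, intensities, scale_factor = 1,
                           shift = 0) {
  frequencies <- as.numeric(frequencies)
  intensities <- as.numeric(intensities)
  if (length(frequencies) != length(intensities)) {
    stop("frequencies and intensities must have equal length")
  }
  if (any(intensities < 0)) stop("stick intensities must be non-negative")
  stopifnot(is.numeric(scale_factor), length(scale_factor) == 1L,
            is.numeric(shift), length(shift) == 1L)
  structure(list(frequencies = frequencies, intensities = intensities,
                 scale_factor = scale_factor, shift = shift),
            class = "stick_spectrum")
}

#' Broaden a stick spectrum onto a grid
#'
#' Each stick is moved to `scale_factor * frequency + shift` and convolved
#' with a unit-height Gaussian of the given width.  Sticks outside the grid
#' contribute only their in-window tails.  The integrated area is
#' proportional to the summed stick intensities (all lines share one
#' width).
#'
#' @param sticks A [stick_spectrum()].
#' @param grid A [wavenumber_grid()] or numeric vector.
#' @param fwhm Gaussian full width at half maximum, cm-1 (> 0).
#' @return An [ir_spectrum()].
#' @export
broaden_sticks <- function(sticks, grid, fwhm = 8) {
  stopifnot(inherits(sticks, "stick_spectrum"))
  if (fwhm <= 0) stop("fwhm must be positive")
  nu <- grid_centers(grid)
  pos <- sticks$scale_factor * sticks$frequencies + sticks$shift
  y <- numeric(length(nu))
  for (i in seq_along(pos)) {
    y <- y + sticks$intensities[i] * gauss_line(nu, pos[i], fwhm)
  }
  ir_spectrum(nu, y, meta = list(source = "broaden_sticks",
                                 scale_factor = sticks$scale_factor,
                                 shift = sticks$shift, fwhm = fwhm))
}

#' Additive-noise model for synthetic spectra
#'
#' Noise is zero-mean Gaussian with standard deviation
#' `max(clean intensity) / snr`, drawn with the stated seed.  `snr = Inf`
#' gives a noise-free spectrum.
#'
#' @param snr Target signal-to-noise ratio (> 0), defined as the maximum
#'   clean intensity in the window divided by the noise standard deviation.
#' @param seed Integer random seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(snr = Inf, seed = 1L) {
  stopifnot(is.numeric(snr), length(snr) == 1L)
  if (!(snr > 0)) stop("snr must be positive")
  seed <- as.integer(seed)
  stopifnot(length(seed) == 1L, !is.na(seed))
  structure(list(snr = snr, seed = seed), class = "noise_model")
}

#' Simulate the spectrum of an isomeric mixture
#'
#' The clean spectrum is the molar-fraction-weighted sum of the rendered
#' pure fingerprints (band intensities scale linearly with molar fraction).
#' Zero-mean Gaussian noise with standard deviation `max(clean)/snr` is
#' added, drawn with the noise model's seed; negative intensities are kept
#' (clipping happens only when the NMF input matrix is built).
#' Reproducible: identical inputs and seed give identical output.
#'
#' @param library An [isomer_library()].
#' @param fractions Named numeric vector of molar fractions (>= 0, summing
#'   to 1 within 1e-9); names must be isomer names in `library`.
#' @param grid A [wavenumber_grid()] or numeric vector.
#' @param noise A [noise_model()]; default is noise-free.
#' @return An [ir_spectrum()] with the generating composition, snr and seed
#'   in its metadata.
#' @export
simulate_mixture_spectrum <- function(library, fractions, grid,
                                      noise = noise_model()) {
  stopifnot(inherits(library, "isomer_library"),
            inherits(noise, "noise_model"))
  if (is.null(names(fractions)) || any(!nzchar(names(fractions)))) {
    stop("'fractions' must be a named vector")
  }
  unknown <- setdiff(names(fractions), names(library$models))
  if (length(unknown)) {
    stop("unknown isomer name(s): ", paste(unknown, collapse = ", "))
  }
  if (any(fractions < 0)) stop("fractions must be non-negative")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  nu <- grid_centers(grid)
  clean <- numeric(length(nu))
  for (nm in names(fractions)) {
    if (fractions[[nm]] == 0) next
    clean <- clean +
      fractions[[nm]] * render_fingerprint(library$models[[nm]], nu)$intensities
  }
  y <- clean
  if (is.finite(noise$snr)) {
    sd <- max(clean) / noise$snr
    y <- clean + withr::with_seed(noise$seed, stats::rnorm(length(nu), 0, sd))
  }
  ir_spectrum(nu, y, meta = list(
    source = "simulate_mixture_spectrum",
    fractions = fractions, snr = noise$snr, seed = noise$seed))
}

#' Default four-isomer fingerprint library
#'
#' A synthetic stand-in for the two alpha/beta anomeric pairs of Gal- and
#' Glc-phytosphingosine on the 1000--1150 cm-1 analysis window.  All four
#' models share two backbone C-O stretching bands (1048 and 1078 cm-1), as
#' hexose fingerprints do, and each carries one strong diagnostic band at
#' least 6 cm-1 away from every band of every other model, which guarantees
#' identifiability on a 2 cm-1 grid: 1065 cm-1 (unique to the alpha-Gal
#' model), 1120, 1058 and 1128 cm-1.  The Glc diagnostics sit close to
#' their Gal counterparts (1058 vs 1065, 1128 vs 1120), so the four-isomer
#' unmixing problem is substantially more congested than the binary
#' alpha/beta-Gal one.  Band intensities are chosen so all models have
#' identical integrated intensity in the window (equal spectral response
#' per mole), and each model carries weak amide II/I bands outside the
#' analysis window.
#'
#' @return An [isomer_library()] of 4 models on 1000--1150 cm-1.
#' @export
default_library <- function() {
  amide <- data.frame(center = c(1545, 1655), intensity = c(0.35, 0.45),
                      fwhm = c(14, 16))
  shared <- data.frame(center = c(1048, 1078), intensity = c(0.70, 0.75),
                       fwhm = c(8, 8))
  model <- function(name, diag_center) {
    isomer_model(name, rbind(shared,
                             data.frame(center = diag_center, intensity = 1.0,
                                        fwhm = 8),
                             amide))
  }
  isomer_library(list(
    model("alpha-Gal-phytosphingosine", 1065),
    model("beta-Gal-phytosphingosine", 1120),
    model("alpha-Glc-phytosphingosine", 1058),
    model("beta-Glc-phytosphingosine", 1128)
  ), window = c(1000, 1150))
}
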