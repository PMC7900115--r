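# Two-isomer library with well-separated bands and equal integrated
# intensity; spectrally much easier than default_library(), used where a
# test targets the algorithm rather than the congested study fixture.
separated_library <- function() {
  isomer_library(list(
    isomer_model("iso-A", peak_bands(c(1065, 1040, 1110),
                                     c(1.0, 0.7, 0.7), c(8, 8, 8))),
    isomer_model("iso-B", peak_bands(c(1030, 1078, 1120),
                                     c(0.9, 1.0, 0.5), c(8, 8, 8)))
  ), window = c(1000, 1150))
}

# Random two-isomer library: band centers drawn with >= 18 cm-1 separation
# across models, equal total intensity per model.
random_pair_library <- function(seed) {
  withr::with_seed(seed, {
    repeat {
      centers <- sort(sample(seq(1010, 1140, by = 2), 6))
      a <- centers[c(1, 3, 5)]
      b <- centers[c(2, 4, 6)]
      if (min(abs(outer(a, b, "-"))) >= 18) break
    }
    ia <- stats::runif(3, 0.5, 1)
    ib <- stats::runif(3, 0.5, 1)
    ia <- ia / sum(ia)
    ib <- ib / sum(ib)
    isomer_library(list(
      isomer_model("iso-A", peak_bands(a, ia, rep(8, 3))),
      isomer_model("iso-B", peak_bands(b, ib, rep(8, 3)))
    ), window = c(1000, 1150))
  })
}

# binned + clipped + unit-area row on a grid, as build_input_matrix does
prep_row <- function(spectrum, grid) {
  b <- bin_spectrum(spectrum, grid)
  y <- pmax(b$intensities, 0)
  y / irmix:::trapz_area(b$wavenumbers, y)
}

fingerprint_grid <- function() wavenumber_grid(1000, 1150, 2)
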