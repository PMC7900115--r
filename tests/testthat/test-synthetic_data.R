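test_that("rendered single band peaks at the grid point nearest its center", {
  m <- isomer_model("x", peak_bands(1065, 1.0, 8))
  s <- render_fingerprint(m, fingerprint_grid())
  peak <- s$wavenumbers[which.max(s$intensities)]
  expect_true(peak %in% c(1064, 1066))
  # symmetric decay around 1065: equidistant grid points match
  at <- function(w) s$intensities[s$wavenumbers == w]
  for (d in c(1, 3, 5, 11)) expect_equal(at(1065 - d), at(1065 + d))
  expect_true(all(s$intensities >= 0))
})

test_that("rendering is linear in band intensities", {
  g <- fingerprint_grid()
  zero <- render_fingerprint(
    isomer_model("z", peak_bands(c(1040, 1100), c(0, 0), c(8, 8))), g)
  expect_true(all(zero$intensities == 0))

  halves <- render_fingerprint(
    isomer_model("h", peak_bands(c(1065, 1065), c(0.5, 0.5), c(8, 8))), g)
  full <- render_fingerprint(isomer_model("f", peak_bands(1065, 1, 8)), g)
  expect_equal(halves$intensities, full$intensities)
})

test_that("models must carry at least one band", {
  expect_error(isomer_model("bad", peak_bands(numeric(0), numeric(0),
                                              numeric(0))),
               "empty model")
})

test_that("stick broadening applies frequency scaling and shift", {
  g <- wavenumber_grid(900, 1150, 1)
  s1 <- broaden_sticks(stick_spectrum(1000, 1, scale_factor = 0.965), g)
  expect_equal(s1$wavenumbers[which.max(s1$intensities)], 965)

  s2 <- broaden_sticks(stick_spectrum(1100, 1, shift = 20), g)
  expect_equal(s2$wavenumbers[which.max(s2$intensities)], 1120)

  # identity post-processing reproduces the equivalent band model
  st <- stick_spectrum(c(1040, 1090), c(0.4, 1.1))
  eq <- isomer_model("eq", peak_bands(c(1040, 1090), c(0.4, 1.1), c(6, 6)))
  expect_equal(broaden_sticks(st, g, fwhm = 6)$intensities,
               render_fingerprint(eq, g)$intensities)

  # area proportional to summed stick intensities
  wide <- wavenumber_grid(800, 1400, 0.5)
  a1 <- irmix:::trapz_area(wide$centers,
                           broaden_sticks(stick_spectrum(1000, 1), wide)$intensities)
  a3 <- irmix:::trapz_area(wide$centers,
                           broaden_sticks(stick_spectrum(c(1000, 1200), c(1, 2)),
                                          wide)$intensities)
  expect_equal(a3 / a1, 3, tolerance = 1e-6)

  expect_error(broaden_sticks(stick_spectrum(1000, 1), g, fwhm = 0))
})

test_that("mixture simulation is linear superposition plus seeded noise", {
  lib <- separated_library()
  g <- fingerprint_grid()
  pureA <- render_fingerprint(lib$models[["iso-A"]], g)

  only_a <- simulate_mixture_spectrum(lib, c("iso-A" = 1), g)
  expect_equal(only_a$intensities, pureA$intensities)

  pureB <- render_fingerprint(lib$models[["iso-B"]], g)
  half <- simulate_mixture_spectrum(lib, c("iso-A" = .5, "iso-B" = .5), g)
  expect_equal(half$intensities,
               (pureA$intensities + pureB$intensities) / 2, tolerance = 1e-12)

  n <- noise_model(snr = 20, seed = 42)
  s1 <- simulate_mixture_spectrum(lib, c("iso-A" = .3, "iso-B" = .7), g, n)
  s2 <- simulate_mixture_spectrum(lib, c("iso-A" = .3, "iso-B" = .7), g, n)
  expect_identical(s1$intensities, s2$intensities)

  expect_error(simulate_mixture_spectrum(lib, c("iso-A" = .6, "iso-B" = .6), g),
               "sum to 1")
  expect_error(simulate_mixture_spectrum(lib, c("iso-C" = 1), g), "unknown")
})

test_that("noise amplitude matches the declared signal-to-noise ratio", {
  lib <- separated_library()
  fine <- wavenumber_grid(1000, 1150, 0.1)  # 1501 points
  fr <- c("iso-A" = .5, "iso-B" = .5)
  clean <- simulate_mixture_spectrum(lib, fr, fine)
  for (snr in c(10, 50)) {
    noisy <- simulate_mixture_spectrum(lib, fr, fine, noise_model(snr, 7))
    emp_sd <- stats::sd(noisy$intensities - clean$intensities)
    expect_equal(emp_sd, max(clean$intensities) / snr, tolerance = 0.1)
  }
  # negatives are preserved, not clipped
  loud <- simulate_mixture_spectrum(lib, fr, fine, noise_model(3, 7))
  expect_true(any(loud$intensities < 0))
})

test_that("default library has four identifiable isomer models", {
  lib <- default_library()
  expect_length(lib$models, 4)
  expect_identical(lib$window, c(1000, 1150))

  g <- fingerprint_grid()
  rendered <- lapply(lib$models, function(m)
    normalize_area(render_fingerprint(m, g)))
  for (i in 1:3) for (j in (i + 1):4) {
    cs <- compare_spectra(rendered[[i]], rendered[[j]])$cosine
    expect_lt(cs, 0.99)
  }

  has_1065 <- vapply(lib$models, function(m)
    any(m$bands$center == 1065 & m$bands$intensity > 0), TRUE)
  expect_equal(sum(has_1065), 1L)

  # each model has a diagnostic band >= 6 cm-1 from all other models' bands
  centers <- lapply(lib$models, function(m) m$bands$center)
  for (i in 1:4) {
    others <- unlist(centers[-i])
    expect_true(any(vapply(centers[[i]], function(cc)
      min(abs(cc - others)) >= 6, TRUE)))
  }

  # equal spectral response: identical integrated intensity in the window
  areas <- vapply(lib$models, function(m) {
    s <- render_fingerprint(m, g)
    irmix:::trapz_area(s$wavenumbers, s$intensities)
  }, 0)
  expect_equal(max(areas) / min(areas), 1, tolerance = 1e-3)
})
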