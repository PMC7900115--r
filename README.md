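# irmix

Identification and relative quantification of isomeric glycolipids from
cryogenic gas-phase infrared (IR) fingerprint spectra.

Glycolipid isomers that differ only in their monosaccharide (Gal vs Glc) or
in the anomeric configuration of the glycosidic bond (α vs β) have identical
masses and are invisible to mass spectrometry alone, yet they can have
radically different biological activity. Cryogenic IR spectroscopy of
m/z-selected ions resolves them: each isomer shows a unique pattern of
narrow C–O/C–C stretching bands in the 1000–1150 cm⁻¹ fingerprint window,
and a mixture spectrum is, to good approximation, the molar-fraction
weighted superposition of the pure-isomer spectra. `irmix` implements the
analysis chain that turns such spectra into compositions:

- **Synthetic fingerprints and mixtures** — Gaussian band models per isomer
  (`default_library()`, `render_fingerprint()`), broadened theory spectra
  (`broaden_sticks()`, frequency scaling and shifting), and seeded
  noisy mixtures (`simulate_mixture_spectrum()`), since the underlying
  experiments deposit no machine-readable spectra.
- **Preprocessing** — fixed-step binning (76 points on 1000–1150 cm⁻¹ at
  2 cm⁻¹; 100 points on 952–1150 cm⁻¹) and unit-area normalization
  (`bin_spectrum()`, `normalize_area()`).
- **Deconvolution** — the core: from-scratch non-negative matrix
  factorization `X ≈ W·H` by alternating multiplicative updates

  ½‖X − WH‖²_F + α[ρ(‖W‖₁+‖H‖₁) + (1−ρ)/2(‖W‖²_F+‖H‖²_F)]

  with seeded random initialization, recorded non-increasing objective,
  unit-area canonicalization of the basis rows, reference-anchored
  component assignment, and conversion of weighting factors to
  percentages (`nmf_factorize()`, `assign_components()`,
  `weights_to_percentages()`), cross-validated against an independent
  non-negative least-squares solver (`nnls_fractions()`).
- **Studies** — seeded pipelines reproducing the accuracy and
  detection-limit experiments: binary ratio series, the 15-row
  four-isomer combinatorial design, the minor-isomer detection limit,
  and an extract-style deconvolution against standards
  (`binary_ratio_study()`, `multicomponent_study()`,
  `detection_limit_study()`, `extract_style_study()`).
- **Ion utilities** — monoisotopic masses, [M+H]⁺/[M+Na]⁺/[M+Ag]⁺ adduct
  m/z, and Mason–Schamp collision cross sections
  (`monoisotopic_mass()`, `adduct_mz()`, `ccs_mason_schamp()`).

See `vignettes/spectral-deconvolution.Rmd` for the model, the numerical
conventions and the design decisions.

## Worked example

Deconvolve a noisy synthetic 25:75 α:β-Gal mixture against the two pure
references:

```r
library(irmix)

lib  <- default_library()
grid <- wavenumber_grid(1000, 1150, 2)
fr   <- c("alpha-Gal-phytosphingosine" = 0.25,
          "beta-Gal-phytosphingosine"  = 0.75)

mix  <- simulate_mixture_spectrum(lib, fr, grid, noise_model(snr = 50, seed = 7))
refs <- lapply(names(fr), \(nm) simulate_mixture_spectrum(lib, setNames(1, nm), grid))
names(refs) <- names(fr)

X   <- build_input_matrix(list(mix_25_75 = mix), refs, grid)
res <- nmf_factorize(X, nmf_config(2, alpha = 0, seed = 0))
asg <- assign_components(res, X)
weights_to_percentages(res, asg, X, truth = list(mix_25_75 = fr))
#>   spectrum_id                     isomer percent truth_percent abs_error
#> 1   mix_25_75 alpha-Gal-phytosphingosine   24.84            25    0.1605
#> 2   mix_25_75  beta-Gal-phytosphingosine   75.16            75    0.1605
```

The 3×76 input matrix holds the binned, clipped, area-normalized mixture
and pure spectra; the factorization recovers the composition to 0.16
percentage points at snr 50. With noise-free input the error drops below
0.1 points, and `nnls_fractions()` gives the same percentages within one
point — the two quantification routes are independent.

At the study level, `binary_ratio_study()` (snr 50, seeds 0–9) recovers
the 1:1 / 1:3 / 1:9 / 1:19 series with a maximum absolute error of about
3 percentage points, `multicomponent_study()` calls isomer presence
correctly in all 11 multi-component mixtures, and
`detection_limit_study()` finds a 5% minor isomer but not a 1% one.

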