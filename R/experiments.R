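# shared defaults for the desk-scale studies
default_grid <- function() wavenumber_grid(1000, 1150, 2)

# render and name the pure reference spectra for a set of isomers
pure_references <- function(library, isomers, grid, snr = Inf,
                            seed_base = NULL) {
  refs <- lapply(seq_along(isomers), function(i) {
    noise <- if (is.finite(snr) && !is.null(seed_base)) {
      noise_model(snr, seed_base + i)
    } else {
      noise_model()
    }
    fr <- stats::setNames(1, isomers[i])
    simulate_mixture_spectrum(library, fr, grid, noise)
  })
  names(refs) <- isomers
  refs
}

run_deconvolution <- function(mixtures, refs, grid, config, truth,
                              order = "mixtures_first") {
  X <- build_input_matrix(mixtures, refs, grid, order = order)
  res <- nmf_factorize(X, config)
  asg <- assign_components(res, X)
  weights_to_percentages(res, asg, X, truth = truth)
}

#' Binary-mixture quantification study
#'
#' Simulates binary isomer mixtures at a series of mixing ratios, runs the
#' full deconvolution pipeline (bin, clip, normalize, factorize with the
#' pure spectra included, assign, convert to percentages), and scores the
#' recovered percentages against the generating ratios.  Each simulated
#' mixture is also compared against the ratio-weighted average of the pure
#' spectra ([weighted_average_spectra()]), the simple linear model for
#' mixture spectra.
#'
#' @param library An [isomer_library()]; the first two of `isomers` are
#'   used.
#' @param isomers Length-2 character vector `(minor, major)`; defaults to
#'   the alpha/beta-Gal pair of [default_library()].
#' @param minor_fractions Molar fractions of the first (minor) isomer,
#'   default `c(0.5, 0.25, 0.10, 0.05)` (the 1:1, 1:3, 1:9, 1:19 series).
#' @param snr Signal-to-noise ratio of the simulated mixtures (`Inf` for
#'   noise-free).
#' @param seeds Integer vector; the study is replicated once per seed with
#'   per-mixture noise seeds derived as `seed * 100 + mixture index`.
#' @param config An [nmf_config()] with `n_components = 2`.
#' @return A list with `abundance` (per-seed abundance data frame),
#'   `max_abs_error`, `mean_abs_error`, `comparison` (per-mixture rms /
#'   cosine / max_abs against the weighted-average model) and `manifest`.
#' @export
binary_ratio_study <- function(library = default_library(),
                               isomers = names(library$models)[1:2],
                               minor_fractions = c(0.5, 0.25, 0.10, 0.05),
                               snr = 50,
                               seeds = 0:9,
                               config = nmf_config(2)) {
  stopifnot(length(isomers) == 2L, config$n_components == 2L)
  grid <- wavenumber_grid(library$window[1], library$window[2], 2)
  refs <- pure_references(library, isomers, grid)
  tabs <- list()
  comparison <- list()
  for (s in seeds) {
    mixtures <- list()
    truth <- list()
    for (i in seq_along(minor_fractions)) {
      f <- minor_fractions[i]
      fr <- stats::setNames(c(f, 1 - f), isomers)
      id <- sprintf("seed%d_minor%g", s, 100 * f)
      mixtures[[id]] <- simulate_mixture_spectrum(
        library, fr, grid, noise_model(snr, as.integer(s * 100 + i)))
      truth[[id]] <- fr
      wavg <- weighted_average_spectra(unname(refs), fr)
      cmp <- compare_spectra(normalize_area(mixtures[[id]]), wavg)
      comparison[[id]] <- data.frame(spectrum_id = id, rms = cmp$rms,
                                     cosine = cmp$cosine,
                                     max_abs = cmp$max_abs)
    }
    tab <- run_deconvolution(mixtures, refs, grid, config, truth)
    tab$seed <- s
    tabs[[as.character(s)]] <- tab
  }
  abundance <- do.call(rbind, tabs)
  rownames(abundance) <- NULL
  list(abundance = abundance,
       max_abs_error = max(abundance$abs_error),
       mean_abs_error = mean(abundance$abs_error),
       comparison = do.call(rbind, comparison),
       manifest = run_manifest(
         config = list(study = "binary_ratio", isomers = isomers,
                       minor_fractions = minor_fractions, snr = snr,
                       nmf = unclass(config)),
         seeds = list(study_seeds = seeds)))
}

#' Enumerate equimolar multi-component mixture designs
#'
#' All subsets of size >= 2 of the given isomers, each with equal molar
#' fractions; for `n` isomers there are `2^n - n - 1` such designs (11 for
#' n = 4: six 2-component, four 3-component, one 4-component).
#'
#' @param isomers Character vector of >= 2 isomer names.
#' @return List of [mixing_ratio()] objects.
#' @export
enumerate_mixture_designs <- function(isomers) {
  stopifnot(is.character(isomers), length(isomers) >= 2L)
  n <- length(isomers)
  designs <- list()
  for (size in 2:n) {
    for (idx in utils::combn(n, size, simplify = FALSE)) {
      designs[[length(designs) + 1L]] <-
        mixing_ratio(isomers[idx], rep(1 / size, size))
    }
  }
  designs
}

#' Multi-component retrieval study
#'
#' Builds the full 4-isomer study matrix -- the four single-component
#' spectra plus all 11 equimolar 2-, 3- and 4-component mixtures, 15 rows
#' in total -- runs a k = 4 deconvolution, and declares an isomer present
#' in a mixture when its recovered percentage exceeds the presence
#' threshold (default 10%, well below the 25% equimolar floor).
#'
#' @param library A 4-isomer [isomer_library()].
#' @param snr Signal-to-noise ratio applied to every row (`Inf` for
#'   noise-free).
#' @param seeds Replication seeds; noise seeds are derived per row.
#' @param threshold Presence threshold in percent.
#' @param config An [nmf_config()] with `n_components = 4`.
#' @return A list with `abundance`, `presence` / `truth_presence` (logical
#'   seed x mixture x isomer arrays flattened to data frames),
#'   `presence_accuracy` (fraction of correct present/absent calls over
#'   the 11 mixtures), `max_abs_error`, `mean_abs_error`, `manifest`.
#' @export
multicomponent_study <- function(library = default_library(),
                                 snr = 50,
                                 seeds = 0:9,
                                 threshold = 10,
                                 config = nmf_config(4)) {
  isomers <- names(library$models)
  stopifnot(length(isomers) == 4L, config$n_components == 4L)
  grid <- wavenumber_grid(library$window[1], library$window[2], 2)
  designs <- enumerate_mixture_designs(isomers)
  tabs <- list()
  calls <- list()
  for (s in seeds) {
    refs <- pure_references(library, isomers, grid, snr = snr,
                            seed_base = as.integer(s * 1000))
    mixtures <- list()
    truth <- list()
    for (j in seq_along(designs)) {
      d <- designs[[j]]
      fr <- stats::setNames(d$weights, d$labels)
      id <- sprintf("seed%d_mix%02d_%s", s, j,
                    paste(substr(d$labels, 1, 9), collapse = "+"))
      mixtures[[id]] <- simulate_mixture_spectrum(
        library, fr, grid, noise_model(snr, as.integer(s * 1000 + 100 + j)))
      truth[[id]] <- fr
    }
    tab <- run_deconvolution(mixtures, refs, grid, config, truth,
                             order = "references_first")
    tab$seed <- s
    tab$present_call <- tab$percent > threshold
    tab$present_truth <- tab$truth_percent > 0
    tabs[[as.character(s)]] <- tab
  }
  abundance <- do.call(rbind, tabs)
  rownames(abundance) <- NULL
  list(abundance = abundance,
       presence_accuracy = mean(abundance$present_call ==
                                  abundance$present_truth),
       max_abs_error = max(abundance$abs_error),
       mean_abs_error = mean(abundance$abs_error),
       threshold = threshold,
       manifest = run_manifest(
         config = list(study = "multicomponent", snr = snr,
                       threshold = threshold, nmf = unclass(config)),
         seeds = list(study_seeds = seeds)))
}

#' Calibrate the mixture signal-to-noise ratio to a target accuracy
#'
#' Walks the snr geometrically, starting from the synthetic-standard
#' regime, until the binary-series maximum absolute percentage error falls
#' inside `target` (default 3--5 percentage points): when the series is
#' more accurate than the target the snr is lowered by `step_factor`, when
#' it is less accurate the snr is raised.  Because the calibration
#' statistic is a worst case (a maximum over the series), it is estimated
#' over many replicate series -- a short run would make the calibrated snr
#' jump between reruns.  The walk starts high, so the calibrated snr is
#' the largest probed value consistent with the target band.
#'
#' @inheritParams binary_ratio_study
#' @param target Length-2 interval of acceptable maximum absolute errors,
#'   percentage points.
#' @param seeds Replicate-series seeds used to estimate the worst-case
#'   error (default 50 series).
#' @param snr_start Starting value of the walk.
#' @param step_factor Geometric step (0 < factor < 1).
#' @param max_eval Maximum number of error evaluations.
#' @return A list with `snr`, `achieved_error` and the evaluation `trace`.
#' @export
calibrate_snr <- function(library = default_library(),
                          isomers = names(library$models)[1:2],
                          target = c(3, 5),
                          seeds = 0:49,
                          snr_start = 50,
                          step_factor = 0.75,
                          max_eval = 10,
                          config = nmf_config(2)) {
  stopifnot(target[2] > target[1], step_factor > 0, step_factor < 1)
  err_at <- function(snr) {
    binary_ratio_study(library, isomers, snr = snr, seeds = seeds,
                       config = config)$max_abs_error
  }
  snr <- snr_start
  trace <- data.frame(snr = numeric(0), max_abs_error = numeric(0))
  for (i in seq_len(max_eval)) {
    e <- err_at(snr)
    trace[nrow(trace) + 1L, ] <- c(snr, e)
    if (e >= target[1] && e <= target[2]) {
      return(list(snr = snr, achieved_error = e, trace = trace))
    }
    snr <- if (e < target[1]) snr * step_factor else snr / step_factor
  }
  best <- trace[which.min(abs(trace$max_abs_error - mean(target))), ]
  list(snr = best$snr, achieved_error = best$max_abs_error, trace = trace)
}

#' Detection-limit study for a minor isomer
#'
#' For each tested minor fraction (which must include 0 as the blank
#' control) the study simulates `replicates` independent binary mixtures,
#' deconvolves each against the two pure references, and records the
#' recovered minor percentage.  A fraction is declared detected when its
#' mean recovered minor percentage exceeds the control mean by three
#' control standard deviations.  Detection should be monotone in the
#' fraction; violations are flagged as instability.
#'
#' @inheritParams binary_ratio_study
#' @param minor_fractions Minor-isomer molar fractions including 0,
#'   default `c(0.50, 0.25, 0.10, 0.05, 0.01, 0)`.
#' @param replicates Replicates per fraction (>= 2).
#' @param seed Base seed; replicate noise seeds are derived from it.
#' @return A list with `decisions` (data frame: fraction, mean, sd,
#'   detected), `smallest_detected` (percent, `NA` if none),
#'   `monotone` flag and `manifest`.
#' @export
detection_limit_study <- function(library = default_library(),
                                  isomers = names(library$models)[1:2],
                                  minor_fractions = c(0.50, 0.25, 0.10,
                                                      0.05, 0.01, 0),
                                  snr = 50,
                                  replicates = 20,
                                  seed = 0,
                                  config = nmf_config(2)) {
  stopifnot(length(isomers) == 2L)
  if (!any(minor_fractions == 0)) {
    stop("minor_fractions must include 0 (the blank control)")
  }
  if (replicates < 2) stop("at least 2 replicates are required")
  grid <- wavenumber_grid(library$window[1], library$window[2], 2)
  refs <- pure_references(library, isomers, grid)
  minor <- isomers[1]
  recovered <- function(f, rep_i) {
    fr <- stats::setNames(c(f, 1 - f), isomers)
    noise_seed <- as.integer(seed + round(f * 1000) * 100 + rep_i)
    mix <- list(mixture = simulate_mixture_spectrum(
      library, fr, grid, noise_model(snr, noise_seed)))
    tab <- run_deconvolution(mix, refs, grid, config,
                             truth = list(mixture = fr))
    tab$percent[tab$isomer == minor]
  }
  stats_at <- lapply(minor_fractions, function(f) {
    v <- vapply(seq_len(replicates), function(r) recovered(f, r), 0)
    c(mean = mean(v), sd = stats::sd(v))
  })
  decisions <- data.frame(
    minor_fraction_percent = 100 * minor_fractions,
    mean_recovered_percent = vapply(stats_at, `[[`, 0, "mean"),
    sd_recovered_percent = vapply(stats_at, `[[`, 0, "sd"))
  ctrl <- decisions[decisions$minor_fraction_percent == 0, ][1, ]
  threshold <- ctrl$mean_recovered_percent + 3 * ctrl$sd_recovered_percent
  decisions$detected <- decisions$mean_recovered_percent > threshold &
    decisions$minor_fraction_percent > 0
  decisions <- decisions[order(-decisions$minor_fraction_percent), ]
  rownames(decisions) <- NULL
  det <- decisions$detected
  monotone <- !any(!det[-length(det)] & det[-1] &
                     decisions$minor_fraction_percent[-1] > 0)
  smallest <- if (any(det)) min(decisions$minor_fraction_percent[det]) else NA
  list(decisions = decisions,
       control_threshold = threshold,
       smallest_detected = smallest,
       monotone = monotone,
       manifest = run_manifest(
         config = list(study = "detection_limit", isomers = isomers,
                       snr = snr, replicates = replicates,
                       nmf = unclass(config)),
         seeds = list(base_seed = seed)))
}

#' Biological-extract style deconvolution study
#'
#' Emulates the deconvolution of glycolipid extracts against synthetic
#' standards: the four pure standards are recorded at high signal-to-noise
#' while the "extract" unknowns are synthetic mixtures at low
#' signal-to-noise, all on the extended 952--1150 cm-1, 100-bin window.
#' A k = 4 deconvolution yields per-unknown isomer percentages and a
#' dominant-isomer call.
#'
#' @param library A 4-isomer [isomer_library()] providing the standards.
#' @param unknowns Named list of named fraction vectors generating the
#'   unknown spectra; the default emulates one pure-beta extract and one
#'   extract with a minor alpha fraction.
#' @param snr_extract,snr_standard Signal-to-noise of the unknowns and the
#'   standards.
#' @param seed Base seed.
#' @param config An [nmf_config()] with `n_components = 4`.
#' @return A list with `abundance`, `dominant` (named character vector of
#'   dominant-isomer calls) and `manifest`.
#' @export
extract_style_study <- function(library = default_library(),
                                unknowns = list(
                                  extract_1 = c("beta-Glc-phytosphingosine" = 1),
                                  extract_2 = c("beta-Glc-phytosphingosine" = 0.85,
                                                "alpha-Glc-phytosphingosine" = 0.15)),
                                snr_extract = 10,
                                snr_standard = 50,
                                seed = 0,
                                config = nmf_config(4)) {
  isomers <- names(library$models)
  stopifnot(length(isomers) == 4L, config$n_components == 4L)
  grid <- wavenumber_grid(952, 1150, 2)
  refs <- pure_references(library, isomers, grid, snr = snr_standard,
                          seed_base = as.integer(seed * 1000))
  mixtures <- list()
  truth <- list()
  for (i in seq_along(unknowns)) {
    id <- names(unknowns)[i]
    mixtures[[id]] <- simulate_mixture_spectrum(
      library, unknowns[[i]], grid,
      noise_model(snr_extract, as.integer(seed * 1000 + 500 + i)))
    truth[[id]] <- unknowns[[i]]
  }
  tab <- run_deconvolution(mixtures, refs, grid, config, truth,
                           order = "references_first")
  dominant <- vapply(split(tab, tab$spectrum_id), function(d) {
    d$isomer[which.max(d$percent)]
  }, "")
  list(abundance = tab, dominant = dominant,
       manifest = run_manifest(
         config = list(study = "extract_style", snr_extract = snr_extract,
                       snr_standard = snr_standard, nmf = unclass(config)),
         seeds = list(base_seed = seed)))
}
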