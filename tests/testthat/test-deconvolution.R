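sim_binary_matrix <- function(lib, minor_fracs, grid, snr = Inf, seed = 0) {
  isomers <- names(lib$models)
  refs <- lapply(isomers, function(nm)
    simulate_mixture_spectrum(lib, stats::setNames(1, nm), grid))
  names(refs) <- isomers
  mixtures <- list()
  truth <- list()
  for (i in seq_along(minor_fracs)) {
    fr <- stats::setNames(c(minor_fracs[i], 1 - minor_fracs[i]), isomers)
    id <- sprintf("m%02d", i)
    noise <- if (is.finite(snr)) noise_model(snr, seed * 100 + i)
             else noise_model()
    mixtures[[id]] <- simulate_mixture_spectrum(lib, fr, grid, noise)
    truth[[id]] <- fr
  }
  list(X = build_input_matrix(mixtures, refs, grid), truth = truth)
}

test_that("input matrices have the documented shapes", {
  lib <- default_library()
  g76 <- fingerprint_grid()

  two <- isomer_library(lib$models[1:2], lib$window)
  d <- sim_binary_matrix(two, c(.5, .25, .1, .05, .01), g76)
  expect_equal(dim(d$X$X), c(7, 76))
  expect_equal(sum(d$X$row_labels$role == "reference"), 2)

  designs <- enumerate_mixture_designs(names(lib$models))
  mixtures <- lapply(designs, function(dd)
    simulate_mixture_spectrum(lib, stats::setNames(dd$weights, dd$labels), g76))
  refs <- lapply(names(lib$models), function(nm)
    simulate_mixture_spectrum(lib, stats::setNames(1, nm), g76))
  names(refs) <- names(lib$models)
  X15 <- build_input_matrix(mixtures, refs, g76)
  expect_equal(dim(X15$X), c(15, 76))

  g100 <- wavenumber_grid(952, 1150, 2)
  extracts <- list(
    e1 = simulate_mixture_spectrum(lib, c("beta-Glc-phytosphingosine" = 1), g100),
    e2 = simulate_mixture_spectrum(lib, c("beta-Glc-phytosphingosine" = .85,
                                          "alpha-Glc-phytosphingosine" = .15),
                                   g100))
  refs100 <- lapply(names(lib$models), function(nm)
    simulate_mixture_spectrum(lib, stats::setNames(1, nm), g100))
  names(refs100) <- names(lib$models)
  X6 <- build_input_matrix(extracts, refs100, g100)
  expect_equal(dim(X6$X), c(6, 100))

  expect_true(all(X6$X >= 0))
  expect_equal(max(X6$X), 1)
})

test_that("a rank-1 non-negative matrix is factorized exactly", {
  withr::with_seed(3, {
    w <- stats::runif(9)
    h <- stats::runif(40)
  })
  X <- outer(w, h)
  res <- nmf_factorize(X, nmf_config(1, alpha = 0, seed = 0))
  rel <- norm(X - res$W %*% res$H, "F") / norm(X, "F")
  expect_lt(rel, 1e-6)
})

test_that("multiplicative updates keep factors non-negative and the objective non-increasing", {
  for (s in 1:100) {
    dims <- withr::with_seed(s, {
      list(n = sample(3:8, 1), m = sample(10:30, 1), k = sample(1:3, 1),
           alpha = sample(c(0, 0.1, 1), 1), l1r = sample(c(0, 0.5, 1), 1),
           A = matrix(stats::runif(8 * 30), 8, 30))
    })
    A <- dims$A[seq_len(dims$n), seq_len(dims$m), drop = FALSE]
    res <- nmf_factorize(A, nmf_config(dims$k, alpha = dims$alpha,
                                       l1_ratio = dims$l1r, seed = s,
                                       max_iter = 150))
    expect_true(all(res$W >= 0))
    expect_true(all(res$H >= 0))
    tr <- res$objective_trace
    expect_true(all(diff(tr) <= 1e-9 * max(1, tr[1])))
  }
})

test_that("degenerate factorization inputs are rejected", {
  expect_error(nmf_factorize(matrix(0, 3, 5), nmf_config(2)), "all-zero")
  expect_error(nmf_factorize(matrix(1, 3, 5), nmf_config(4)),
               "n_components")
})

test_that("noise-free binary designs are recovered and agree with the NNLS oracle", {
  lib <- separated_library()
  g <- fingerprint_grid()
  d <- sim_binary_matrix(lib, c(.5, .25, .10, .05), g)
  res <- nmf_factorize(d$X, nmf_config(2, alpha = 0, seed = 0))
  asg <- assign_components(res, d$X)
  tab <- weights_to_percentages(res, asg, d$X, truth = d$truth)

  expect_lt(max(tab$abs_error), 1)          # truth within 0.01 fraction
  expect_equal(sum(tab$percent[tab$spectrum_id == "m01"]), 100,
               tolerance = 1e-6)

  ref_rows <- d$X$X[d$X$row_labels$role == "reference", ]
  rownames(ref_rows) <- d$X$isomer[d$X$row_labels$role == "reference"]
  for (i in 1:4) {
    f <- nnls_fractions(d$X$X[i, ], ref_rows)
    nmf_f <- tab$percent[tab$spectrum_id == sprintf("m%02d", i)] / 100
    names(nmf_f) <- tab$isomer[tab$spectrum_id == sprintf("m%02d", i)]
    expect_equal(nmf_f[names(f)], f, tolerance = 1e-4)
  }
})

test_that("exact recovery holds across random libraries and interior fractions", {
  g <- fingerprint_grid()
  for (s in 1:20) {
    lib <- random_pair_library(100 + s)
    fr <- withr::with_seed(200 + s, stats::runif(3, 0.2, 0.8))
    d <- sim_binary_matrix(lib, fr, g)
    res <- nmf_factorize(d$X, nmf_config(2, alpha = 0, seed = s))
    asg <- assign_components(res, d$X)
    tab <- weights_to_percentages(res, asg, d$X, truth = d$truth)
    expect_lt(max(tab$abs_error), 1)        # 0.01 on the fraction scale
  }
})

fake_result <- function(W, k = ncol(W)) {
  structure(list(W = W, H = NULL, config = list(n_components = k)),
            class = "nmf_result")
}

fake_matrix <- function(n_mix, isomers) {
  n <- n_mix + length(isomers)
  structure(list(
    X = matrix(1, n, 4),
    row_labels = data.frame(
      id = c(sprintf("mix%d", seq_len(n_mix)), isomers),
      role = c(rep("mixture", n_mix), rep("reference", length(isomers)))),
    isomer = c(rep(NA_character_, n_mix), isomers),
    bin_centers = 1:4), class = "spectra_matrix")
}

test_that("component assignment resolves the permutation via pure rows", {
  X <- fake_matrix(1, c("A", "B"))
  res <- fake_result(rbind(c(.5, .5), c(.99, .01), c(.02, .98)))
  asg <- assign_components(res, X)
  expect_identical(asg$mapping, c(A = 1L, B = 2L))

  # permuted components give the inverse permutation
  res2 <- fake_result(res$W[, 2:1])
  expect_identical(assign_components(res2, X)$mapping, c(A = 2L, B = 1L))

  # symmetric references are ambiguous
  res3 <- fake_result(rbind(c(.5, .5), c(.5, .5), c(.5, .5)))
  expect_error(assign_components(res3, X), "ambiguous assignment")

  # a diffuse reference row triggers the weak-reference warning
  X3 <- fake_matrix(0, c("A", "B", "C"))
  W3 <- rbind(c(.45, .30, .25), c(.05, .90, .05), c(.05, .05, .90))
  expect_warning(assign_components(fake_result(W3), X3), "weak reference")
})

test_that("four-component assignment matches the generator labels", {
  lib <- default_library()
  g <- fingerprint_grid()
  isomers <- names(lib$models)
  refs <- lapply(isomers, function(nm)
    simulate_mixture_spectrum(lib, stats::setNames(1, nm), g))
  names(refs) <- isomers
  X <- build_input_matrix(list(), refs, g)
  res <- nmf_factorize(X, nmf_config(4, alpha = 0, seed = 0))
  asg <- assign_components(res, X)
  expect_setequal(names(asg$mapping), isomers)
  expect_setequal(asg$mapping, 1:4)
  # each pure row loads dominantly on its assigned component
  tab <- weights_to_percentages(res, asg, X, rows = "all")
  for (iso in isomers) {
    own <- tab[tab$spectrum_id == iso, ]
    expect_identical(own$isomer[which.max(own$percent)], iso)
    expect_gt(own$percent[own$isomer == iso], 80)
  }
})

test_that("weighting factors convert to row-normalized percentages", {
  X <- fake_matrix(2, c("A", "B"))
  res <- fake_result(rbind(c(.25, .75), c(.10, .40), c(1, 0), c(0, 1)))
  asg <- assign_components(res, X)
  tab <- weights_to_percentages(res, asg, X)
  expect_equal(tab$percent[tab$spectrum_id == "mix1"], c(25, 75))
  expect_equal(tab$percent[tab$spectrum_id == "mix2"], c(20, 80))
  sums <- tapply(tab$percent, tab$spectrum_id, sum)
  expect_true(all(abs(sums - 100) < 1e-6))

  res0 <- fake_result(rbind(c(0, 0), c(1, 0), c(0, 1)))
  X0 <- fake_matrix(1, c("A", "B"))
  asg0 <- assign_components(res0, X0)
  expect_error(weights_to_percentages(res0, asg0, X0), "zero row-sum")
})

test_that("NNLS fractions recover convex combinations", {
  lib <- default_library()
  g <- fingerprint_grid()
  R <- t(vapply(lib$models, function(m)
    prep_row(render_fingerprint(m, g), g), numeric(76)))

  m <- 0.3 * R[1, ] + 0.7 * R[2, ]
  f <- nnls_fractions(m, R[1:2, ])
  expect_equal(unname(f), c(0.3, 0.7), tolerance = 1e-9)

  expect_equal(unname(nnls_fractions(R[1, ], R[1:2, ])), c(1, 0),
               tolerance = 1e-9)

  withr::with_seed(5, {
    for (r in 1:5) {
      w <- stats::runif(4)
      w <- w / sum(w)
      mix <- drop(w %*% R)
      expect_equal(unname(nnls_fractions(mix, R)), w, tolerance = 1e-6)
    }
  })

  # pairwise solutions agree with a 1e-4 grid-search oracle
  mix <- 0.37 * R[3, ] + 0.63 * R[4, ]
  fs <- seq(0, 1, by = 1e-4)
  sse <- vapply(fs, function(f)
    sum((mix - f * R[3, ] - (1 - f) * R[4, ])^2), 0)
  expect_equal(nnls_fractions(mix, R[3:4, ])[[1]], fs[which.min(sse)],
               tolerance = 1e-4)

  expect_error(nnls_fractions(m, rbind(R[1, ], R[1, ])),
               "degenerate references")
})

test_that("NMF and NNLS percentages agree within tolerance under noise", {
  lib <- default_library()
  two <- isomer_library(lib$models[1:2], lib$window)
  g <- fingerprint_grid()
  for (s in 0:2) {
    d <- sim_binary_matrix(two, c(.5, .25, .10, .05), g, snr = 50, seed = s)
    res <- nmf_factorize(d$X, nmf_config(2, alpha = 0, seed = 0))
    asg <- assign_components(res, d$X)
    tab <- weights_to_percentages(res, asg, d$X, truth = d$truth)
    ref_rows <- d$X$X[d$X$row_labels$role == "reference", ]
    rownames(ref_rows) <- d$X$isomer[d$X$row_labels$role == "reference"]
    for (i in 1:4) {
      id <- sprintf("m%02d", i)
      f <- 100 * nnls_fractions(d$X$X[i, ], ref_rows)
      nmf_p <- stats::setNames(tab$percent[tab$spectrum_id == id],
                               tab$isomer[tab$spectrum_id == id])
      expect_lt(max(abs(nmf_p[names(f)] - f)), 3)
    }
  }
})

test_that("quantification error grows as the signal-to-noise ratio drops", {
  lib <- default_library()
  errs <- vapply(c(200, 50, 20, 10), function(snr) {
    binary_ratio_study(lib, snr = snr, seeds = 1:20)$mean_abs_error
  }, 0)
  expect_true(all(diff(errs) >= 0))
})

test_that("regularization induces systematic per-isomer biases", {
  m <- multicomponent_study(snr = Inf, seeds = 0,
                            config = nmf_config(4, alpha = 1))
  signed <- tapply(m$abundance$percent - m$abundance$truth_percent,
                   m$abundance$isomer, mean)
  expect_gt(max(signed), 0.5)   # some isomers overestimated
  expect_lt(min(signed), -0.5)  # others underestimated
})
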