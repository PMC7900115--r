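#' Stacked, binned, normalized spectra ready for factorization
#'
#' Rows are spectra (mixtures first, then pure references), columns are
#' wavenumber bins.  Each spectrum is binned to the grid, clipped at zero
#' (NMF requires non-negative entries, an inherent property of IR data;
#' noise may have produced small negative values), and normalized to unit
#' area over the window.  The stacked matrix is finally rescaled by a
#' single global factor so its largest entry is 1; this leaves every
#' between-row and between-column ratio intact and only fixes the overall
#' intensity unit, which matters when the factorization is regularized.
#'
#' @param mixtures List of [ir_spectrum()] mixture spectra.
#' @param references Named list of [ir_spectrum()] pure-isomer spectra
#'   (names are the isomer identities).
#' @param grid A [wavenumber_grid()].
#' @param window Normalization window; defaults to the grid limits.
#' @param order Row order of the stacked matrix: `"mixtures_first"`
#'   (binary-series convention) or `"references_first"` (multi-component
#'   study convention, single-component spectra on top).  The order does
#'   not change any contract -- roles are tracked per row -- but a
#'   fixed-seed factorization is only reproducible for a fixed row order.
#' @return An object of class `spectra_matrix` with fields `X` (matrix),
#'   `row_labels` (data frame with `id` and `role`, role in
#'   `"mixture"`/`"reference"`), `isomer` (per-row isomer name, `NA` for
#'   mixtures) and `bin_centers`.
#' @export
build_input_matrix <- function(mixtures, references, grid,
                               window = NULL,
                               order = c("mixtures_first",
                                         "references_first")) {
  order <- match.arg(order)
  stopifnot(inherits(grid, "wavenumber_grid"))
  if (is.null(window)) window <- c(grid$start, grid$stop)
  if (length(mixtures) && is.null(names(mixtures))) {
    names(mixtures) <- sprintf("mixture_%02d", seq_along(mixtures))
  }
  if (length(references) == 0L) stop("at least one pure reference is required")
  if (is.null(names(references)) || any(!nzchar(names(references)))) {
    stop("'references' must be a named list (isomer -> spectrum)")
  }
  prep <- function(s, id) {
    b <- bin_spectrum(s, grid)
    y <- pmax(b$intensities, 0)
    a <- trapz_area(b$wavenumbers, y)
    if (!(a > 0)) stop("non-positive area after clipping for spectrum '", id, "'")
    y / a
  }
  if (order == "mixtures_first") {
    ids <- c(names(mixtures), names(references))
    roles <- c(rep("mixture", length(mixtures)),
               rep("reference", length(references)))
    isomer <- c(rep(NA_character_, length(mixtures)), names(references))
    rows <- c(mixtures, references)
  } else {
    ids <- c(names(references), names(mixtures))
    roles <- c(rep("reference", length(references)),
               rep("mixture", length(mixtures)))
    isomer <- c(names(references), rep(NA_character_, length(mixtures)))
    rows <- c(references, mixtures)
  }
  X <- t(vapply(seq_along(rows), function(i) prep(rows[[i]], ids[i]),
                numeric(length(grid$centers))))
  X <- X / max(X)
  rownames(X) <- ids
  structure(list(X = X,
                 row_labels = data.frame(id = ids, role = roles,
                                         stringsAsFactors = FALSE),
                 isomer = isomer,
                 bin_centers = grid$centers),
            class = "spectra_matrix")
}

#' @export
print.spectra_matrix <- function(x, ...) {
  cat(sprintf("<spectra_matrix> %d x %d (%d mixtures, %d references)\n",
              nrow(x$X), ncol(x$X), sum(x$row_labels$role == "mixture"),
              sum(x$row_labels$role == "reference")))
  invisible(x)
}

#' Configuration of the NMF solver
#'
#' Defaults mirror a fixed-iteration random-initialization setup:
#' `max_iter = 2000`, `tol = 0` (always run to the iteration cap),
#' `init = "random"`.  The penalty `alpha` multiplies both factor
#' matrices, with `l1_ratio` splitting it between L1 and L2 parts
#' (default 0, pure L2).  Quantification studies in this package use
#' `alpha = 0`; see the vignette for the scale considerations behind
#' nonzero `alpha`.
#'
#' @param n_components Number of components `k` (>= 1), normally the
#'   number of isomers in the matrix.
#' @param init Initialization scheme; only `"random"` (seeded uniform
#'   entries scaled by `sqrt(mean(X)/k)`) is implemented.
#' @param seed Integer seed fixing the initialization.
#' @param max_iter Iteration cap (>= 1).
#' @param alpha Regularization strength (>= 0).
#' @param l1_ratio L1 fraction of the penalty, in \[0, 1\].
#' @param tol Relative objective-change stopping threshold (0 disables
#'   early stopping).
#' @return An object of class `nmf_config`.
#' @export
nmf_config <- function(n_components, init = "random", seed = 0L,
                       max_iter = 2000L, alpha = 0, l1_ratio = 0, tol = 0) {
  stopifnot(n_components >= 1, max_iter >= 1, alpha >= 0,
            l1_ratio >= 0, l1_ratio <= 1, tol >= 0)
  init <- match.arg(init, "random")
  structure(list(n_components = as.integer(n_components), init = init,
                 seed = as.integer(seed), max_iter = as.integer(max_iter),
                 alpha = alpha, l1_ratio = l1_ratio, tol = tol),
            class = "nmf_config")
}

nmf_objective <- function(A, W, H, l1, l2) {
  0.5 * sum((A - W %*% H)^2) +
    l1 * (sum(W) + sum(H)) +
    0.5 * l2 * (sum(W^2) + sum(H^2))
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes `X ~ W H` with all entries non-negative, minimizing
#' \deqn{\tfrac12\|X - WH\|_F^2 + \alpha\left[\rho(\|W\|_1+\|H\|_1)
#'   + \tfrac{1-\rho}{2}(\|W\|_F^2+\|H\|_F^2)\right]}
#' (with \eqn{\rho} = `l1_ratio`) by alternating multiplicative updates.
#' Update denominators are floored at 1e-12, so entries cannot become
#' exactly zero mid-run.  The per-iteration objective is recorded and is
#' non-increasing (within numerical slack).  Runs are fully reproducible
#' given the config seed.
#'
#' On return the factors are put in a canonical scale: each row of `H`
#' (basis spectrum) is normalized to unit area over the bin grid and the
#' corresponding column of `W` is rescaled inversely, leaving `W %*% H`
#' unchanged.  Because the input rows are unit-area too, the weighting
#' factors in `W` are then directly comparable across components, which is
#' what makes the percentage conversion in [weights_to_percentages()]
#' meaningful.
#'
#' @param X A `spectra_matrix` from [build_input_matrix()], or a plain
#'   non-negative matrix.
#' @param config An [nmf_config()].
#' @return An object of class `nmf_result` with fields `W` (rows x k
#'   weighting factors), `H` (k x bins basis spectra), `objective_trace`,
#'   `n_iter`, `converged`, and the `config`.
#' @export
nmf_factorize <- function(X, config) {
  stopifnot(inherits(config, "nmf_config"))
  if (inherits(X, "spectra_matrix")) {
    A <- X$X
    centers <- X$bin_centers
  } else {
    A <- as.matrix(X)
    centers <- NULL
  }
  if (any(A < 0)) stop("input matrix must be non-negative")
  if (all(A == 0)) stop("all-zero input matrix")
  k <- config$n_components
  n <- nrow(A)
  m <- ncol(A)
  if (k > min(n, m)) stop("n_components exceeds min(rows, cols)")
  l1 <- config$alpha * config$l1_ratio
  l2 <- config$alpha * (1 - config$l1_ratio)
  sc <- sqrt(mean(A) / k)
  init <- withr::with_seed(config$seed, {
    list(W = matrix(stats::runif(n * k), n, k) * sc,
         H = matrix(stats::runif(k * m), k, m) * sc)
  })
  W <- init$W
  H <- init$H
  eps <- 1e-12
  trace <- numeric(config$max_iter)
  prev <- nmf_objective(A, W, H, l1, l2)
  converged <- FALSE
  it <- 0L
  while (it < config$max_iter) {
    it <- it + 1L
    W <- W * (A %*% t(H)) / pmax(W %*% (H %*% t(H)) + l1 + l2 * W, eps)
    H <- H * (t(W) %*% A) / pmax((t(W) %*% W) %*% H + l1 + l2 * H, eps)
    obj <- nmf_objective(A, W, H, l1, l2)
    trace[it] <- obj
    if (config$tol > 0 && prev > 0 &&
        (prev - obj) / prev < config$tol) {
      converged <- TRUE
      break
    }
    prev <- obj
  }
  # canonical scale: unit-area (or unit-sum) basis rows, W rescaled inversely
  s <- if (is.null(centers)) rowSums(H) else
    apply(H, 1, function(h) trapz_area(centers, h))
  s[s <= 0] <- 1
  H <- H / s
  W <- W * rep(s, each = n)
  rownames(W) <- rownames(A)
  structure(list(W = W, H = H, objective_trace = trace[seq_len(it)],
                 n_iter = it, converged = converged, config = config),
            class = "nmf_result")
}

#' @export
print.nmf_result <- function(x, ...) {
  cat(sprintf(
    "<nmf_result> k=%d, %d iterations (%s), final objective %.6g\n",
    x$config$n_components, x$n_iter,
    if (x$converged) "converged" else "iteration cap",
    utils::tail(x$objective_trace, 1)))
  invisible(x)
}

# all permutations of 1..n (n small)
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

#' Assign NMF components to isomers via the pure-reference rows
#'
#' NMF is invariant under permutation of its components; the mapping to
#' isomer identities is recovered from the pure-reference rows included in
#' the input matrix.  The score of component `c` for an isomer is the
#' row-normalized weight of `c` in that isomer's reference row (averaged
#' if several reference rows share an isomer), and the assignment is the
#' bijection maximizing the total score, found by exhaustive search over
#' the k! permutations (k <= 6).
#'
#' @param result An [nmf_result()].
#' @param X The `spectra_matrix` that was factorized; must contain at
#'   least one `reference` row per expected isomer.
#' @return An object of class `component_assignment`: `mapping` (named
#'   integer vector, isomer -> component index) and `scores` (the isomer x
#'   component score matrix used).
#' @section Diagnostics: an error is raised if the best assignment is not
#'   unique within 1e-9; a `"weak reference"` warning is given when a pure
#'   row's top component carries less than half of that row's weight.
#' @export
assign_components <- function(result, X) {
  stopifnot(inherits(result, "nmf_result"), inherits(X, "spectra_matrix"))
  ref <- which(X$row_labels$role == "reference")
  if (length(ref) == 0L) stop("no reference rows in input matrix")
  isomers <- unique(X$isomer[ref])
  k <- result$config$n_components
  if (length(isomers) != k) {
    stop(sprintf("expected %d distinct reference isomers, found %d", k,
                 length(isomers)))
  }
  if (k > 6L) stop("exhaustive assignment supported for k <= 6 only")
  Wn <- result$W[ref, , drop = FALSE]
  Wn <- Wn / pmax(rowSums(Wn), 1e-300)
  scores <- t(vapply(isomers, function(iso) {
    colMeans(Wn[X$isomer[ref] == iso, , drop = FALSE])
  }, numeric(k)))
  rownames(scores) <- isomers
  weak <- apply(scores, 1, max) < 0.5
  if (any(weak)) {
    warning("weak reference: ", paste(isomers[weak], collapse = ", "))
  }
  perms <- all_permutations(k)
  totals <- vapply(perms, function(p) sum(scores[cbind(seq_len(k), p)]), 0)
  o <- order(totals, decreasing = TRUE)
  if (length(perms) > 1L && totals[o[1]] - totals[o[2]] <= 1e-9) {
    stop("ambiguous assignment")
  }
  mapping <- as.integer(perms[[o[1]]])
  names(mapping) <- isomers
  structure(list(mapping = mapping, scores = scores),
            class = "component_assignment")
}

#' @export
print.component_assignment <- function(x, ...) {
  cat("<component_assignment>",
      paste(sprintf("%s->%d", names(x$mapping), x$mapping), collapse = ", "),
      "\n")
  invisible(x)
}

#' Convert weighting factors to isomer percentages
#'
#' For each mixture row the percentage of isomer `i` is
#' `100 * W[row, c_i] / sum_j W[row, c_j]` over the assigned components,
#' so the per-row percentages sum to 100.  When the generating composition
#' is known it is attached together with absolute errors.
#'
#' @param result An [nmf_result()].
#' @param assignment A [assign_components()] result.
#' @param X The factorized `spectra_matrix`.
#' @param truth Optional: named list mapping mixture row ids to named
#'   vectors of true molar fractions (on the 0--1 scale).
#' @param rows Which row role to report: `"mixture"` (default) or
#'   `"all"`.
#' @return A data frame (one row per spectrum x isomer) with columns
#'   `spectrum_id`, `isomer`, `percent`, `truth_percent`, `abs_error`.
#' @export
weights_to_percentages <- function(result, assignment, X, truth = NULL,
                                   rows = c("mixture", "all")) {
  stopifnot(inherits(result, "nmf_result"),
            inherits(assignment, "component_assignment"),
            inherits(X, "spectra_matrix"))
  rows <- match.arg(rows)
  sel <- if (rows == "mixture") which(X$row_labels$role == "mixture")
         else seq_len(nrow(X$X))
  isomers <- names(assignment$mapping)
  W <- result$W[sel, assignment$mapping, drop = FALSE]
  rs <- rowSums(W)
  if (any(rs <= 0)) stop("zero row-sum of W")
  P <- 100 * W / rs
  out <- do.call(rbind, lapply(seq_along(sel), function(r) {
    id <- X$row_labels$id[sel[r]]
    tp <- rep(NA_real_, length(isomers))
    if (!is.null(truth) && !is.null(truth[[id]])) {
      tv <- truth[[id]]
      tp <- 100 * ifelse(is.na(match(isomers, names(tv))), 0,
                         tv[match(isomers, names(tv))])
    }
    data.frame(spectrum_id = id, isomer = isomers, percent = P[r, ],
               truth_percent = tp, abs_error = abs(P[r, ] - tp),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  out
}

#' Non-negative least-squares mixture fractions
#'
#' Independent of the NMF path: solves `min || mixture - f' R ||^2`
#' subject to `f >= 0` with an active-set solver, then normalizes `f` to
#' sum 1.  Used as the quantification oracle for validating NMF-derived
#' percentages.
#'
#' @param mixture_row Numeric vector (a binned, normalized mixture
#'   spectrum).
#' @param reference_rows Matrix with one reference spectrum per row
#'   (linearly independent).
#' @return Named numeric vector of fractions summing to 1 (names taken
#'   from `rownames(reference_rows)` when present).
#' @export
nnls_fractions <- function(mixture_row, reference_rows) {
  R <- as.matrix(reference_rows)
  m <- as.numeric(mixture_row)
  stopifnot(ncol(R) == length(m))
  if (qr(R)$rank < nrow(R)) stop("degenerate references")
  f <- pracma::lsqnonneg(t(R), m)$x
  if (sum(f) <= 0) stop("degenerate references: zero fit")
  f <- f / sum(f)
  names(f) <- rownames(R)
  f
}
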