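# most-abundant-isotope masses, Da
ISOTOPE_MASS <- c(
  C = 12.000000,
  H = 1.007825032,
  N = 14.003074004,
  O = 15.994914620,
  P = 30.973761998,
  S = 31.972071174,
  Na = 22.989769282,
  Ag = 106.905091600
)

# charge-carrier mass deltas, Da (electron mass already removed)
ADDUCT_DELTA <- c(
  "[M+H]+" = 1.007276467,
  "[M+Na]+" = 22.989218000,
  "[M+Ag]+" = 106.904548000
)

#' Parse an elemental formula string
#'
#' @param formula A string such as `"C48H91NO8"`, or an already-named
#'   integer vector of element counts.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula)) {
    counts <- formula
    if (is.null(names(counts))) stop("numeric formula must be named")
  } else {
    stopifnot(is.character(formula), length(formula) == 1L)
    m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
    toks <- regmatches(formula, list(m))[[1]]
    if (sum(attr(m, "match.length")) != nchar(formula)) {
      stop("cannot parse formula: ", formula)
    }
    el <- sub("[0-9]+$", "", toks)
    n <- sub("^[A-Z][a-z]?", "", toks)
    counts <- stats::setNames(ifelse(nzchar(n), as.integer(n), 1L), el)
    counts <- tapply(counts, names(counts), sum)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("element counts must be non-negative integers")
  }
  bad <- setdiff(names(counts), names(ISOTOPE_MASS))
  if (length(bad)) stop("unsupported element(s): ", paste(bad, collapse = ", "))
  counts
}

#' Monoisotopic mass of an elemental formula
#'
#' Sum of most-abundant-isotope masses (C 12 exactly, H 1.007825,
#' N 14.003074, O 15.994915, ...), in Da.
#'
#' @inheritParams parse_formula
#' @return Mass in Da (0 for the empty formula).
#' @examples
#' monoisotopic_mass("C48H91NO8") # hexosyl-ceramide d18:1/24:1, 809.67
#' @export
monoisotopic_mass <- function(formula) {
  if (is.character(formula) && !nzchar(formula)) return(0)
  counts <- parse_formula(formula)
  if (length(counts) == 0L) return(0)
  sum(ISOTOPE_MASS[names(counts)] * counts)
}

#' Adduct specification
#'
#' Supported singly charged adducts: `[M+H]+`, `[M+Na]+` and `[M+Ag]+`
#' (the most abundant 107Ag isotope).  Mass deltas are charge-carrier
#' masses, i.e. the electron is already removed.
#'
#' @param name One of `"[M+H]+"`, `"[M+Na]+"`, `"[M+Ag]+"`; the short
#'   forms `"H"`, `"Na"`, `"Ag"` are also accepted.
#' @return A list with `name`, `delta` (Da) and `charge` (always 1).
#' @export
adduct_spec <- function(name) {
  full <- c(H = "[M+H]+", Na = "[M+Na]+", Ag = "[M+Ag]+")
  if (name %in% names(full)) name <- full[[name]]
  if (!name %in% names(ADDUCT_DELTA)) {
    stop("unsupported adduct: ", name,
         " (supported: ", paste(names(ADDUCT_DELTA), collapse = ", "), ")")
  }
  list(name = name, delta = ADDUCT_DELTA[[name]], charge = 1L)
}

#' m/z of an adduct ion
#'
#' `(mass + delta) / charge`, strictly increasing in the neutral mass.
#'
#' @param monoisotopic_mass Neutral monoisotopic mass, Da (> 0).
#' @param adduct An [adduct_spec()] or an adduct name.
#' @return m/z value (Th).
#' @examples
#' adduct_mz(monoisotopic_mass("C48H91NO8"), "Na") # ~832.7
#' @export
adduct_mz <- function(monoisotopic_mass, adduct) {
  stopifnot(is.numeric(monoisotopic_mass), monoisotopic_mass > 0)
  if (is.character(adduct)) adduct <- adduct_spec(adduct)
  (monoisotopic_mass + adduct$delta) / adduct$charge
}

#' Conditions of an ion-mobility measurement
#'
#' @param k0 Reduced mobility, cm^2 V^-1 s^-1 (referenced to 273.15 K and
#'   760 Torr).
#' @param temperature Drift-gas temperature, K.
#' @param gas_mass Buffer-gas mass, Da (He 4.002602, N2 28.013406), or the
#'   shorthand `"He"` / `"N2"`.
#' @param ion_mass Ion mass, Da.
#' @param charge Integer charge state (>= 1).
#' @return A list of validated conditions.
#' @export
mobility_conditions <- function(k0, temperature, gas_mass, ion_mass,
                                charge = 1L) {
  if (is.character(gas_mass)) {
    gas_mass <- switch(gas_mass, He = 4.002602, N2 = 28.013406,
                       stop("unknown buffer gas: ", gas_mass))
  }
  vals <- c(k0, temperature, gas_mass, ion_mass, charge)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all mobility conditions must be positive")
  }
  list(k0 = k0, temperature = temperature, gas_mass = gas_mass,
       ion_mass = ion_mass, charge = as.integer(charge))
}

#' Collision cross section from reduced mobility (Mason-Schamp)
#'
#' \deqn{\Omega = \frac{3 z e}{16 N_0}
#'   \sqrt{\frac{2\pi}{\mu k_B T}} \frac{1}{K_0}}
#' with \eqn{\mu} the ion-gas reduced mass and \eqn{N_0} the buffer-gas
#' number density at standard conditions (273.15 K, 760 Torr), to which
#' the reduced mobility is referenced.  Exactly inversely proportional to
#' `K_0`.
#'
#' @param cond A [mobility_conditions()] object, or the `k0` value if the
#'   remaining conditions are given as named arguments.
#' @param ... Passed to [mobility_conditions()] when `cond` is numeric.
#' @return Collision cross section in square Angstrom.
#' @export
ccs_mason_schamp <- function(cond, ...) {
  if (is.numeric(cond)) cond <- mobility_conditions(cond, ...)
  e <- 1.602176634e-19      # C
  kB <- 1.380649e-23        # J/K
  amu <- 1.66053906660e-27  # kg
  N0 <- 101325 / (kB * 273.15)  # m^-3, Loschmidt number density
  mu <- cond$ion_mass * cond$gas_mass / (cond$ion_mass + cond$gas_mass) * amu
  k0_si <- cond$k0 * 1e-4   # cm^2/V/s -> m^2/V/s
  omega <- 3 * cond$charge * e / (16 * N0) *
    sqrt(2 * pi / (mu * kB * cond$temperature)) / k0_si
  omega * 1e20              # m^2 -> A^2
}
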