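#' Atomic reference data
#'
#' Immutable per-element constants used throughout the package:
#' IUPAC 2021 standard atomic weights (conventional values for elements
#' with an interval), monoisotopic masses of the principal (most abundant)
#' isotope, atomic numbers, Bondi van der Waals radii and single-bond
#' covalent radii.
#'
#' @return A data frame with one row per supported element and columns
#'   `symbol`, `weight` (u), `mono` (u), `z` (electrons), `vdw` (Angstrom)
#'   and `covalent` (Angstrom).
#' @examples
#' atomic_data()[atomic_data()$symbol == "C", ]
#' @export
atomic_data <- function() .foldmimic_atomic

# weight: IUPAC 2021 conventional standard atomic weight
# mono:   principal-isotope mass (most abundant isotope)
# vdw:    Bondi (1964); covalent: Cordero et al. (2008) single-bond radii
.foldmimic_atomic <- data.frame(
  symbol = c("H",  "B",  "C",  "N",  "O",  "F",  "Na", "Mg", "Si", "P",
             "S",  "Cl", "K",  "Ca", "Br", "I"),
  weight = c(1.008, 10.81, 12.011, 14.007, 15.999, 18.998403163,
             22.98976928, 24.305, 28.085, 30.973761998,
             32.06, 35.45, 39.0983, 40.078, 79.904, 126.90447),
  mono   = c(1.00782503, 11.00930536, 12.0, 14.003074, 15.99491462,
             18.99840316, 22.98976928, 23.98504170, 27.97692653,
             30.97376200, 31.97207117, 34.96885268, 38.96370649,
             39.96259086, 78.9183376, 126.9044719),
  z      = c(1L, 5L, 6L, 7L, 8L, 9L, 11L, 12L, 14L, 15L,
             16L, 17L, 19L, 20L, 35L, 53L),
  vdw    = c(1.20, 1.92, 1.70, 1.55, 1.52, 1.47, 2.27, 1.73, 2.10, 1.80,
             1.80, 1.75, 2.75, 2.31, 1.85, 1.98),
  covalent = c(0.31, 0.84, 0.76, 0.71, 0.66, 0.57, 1.66, 1.41, 1.11, 1.07,
               1.05, 1.02, 2.03, 1.76, 1.20, 1.39),
  stringsAsFactors = FALSE
)

.atomic_row <- function(symbol) {
  i <- match(symbol, .foldmimic_atomic$symbol)
  if (anyNA(i)) {
    bad <- unique(symbol[is.na(i)])
    stop("unknown element symbol: ", paste(dQuote(bad, FALSE), collapse = ", "))
  }
  .foldmimic_atomic[i, , drop = FALSE]
}

#' van der Waals radius of an element
#'
#' @param symbol Character vector of element symbols.
#' @return Numeric vector of Bondi radii in Angstrom.
#' @export
vdw_radius <- function(symbol) .atomic_row(symbol)$vdw
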