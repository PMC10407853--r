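#' Parse a Hill-notation molecular formula
#'
#' Turns a formula string such as `"C39H35ClN4O4"` into a named integer
#' vector of element counts. An absent count means one atom.
#'
#' @param text A single formula string (element symbols with optional
#'   integer multiplicities). The empty-formula case is rejected.
#' @return A named integer vector of class `"molformula"`; names are
#'   element symbols, values are counts.
#' @examples
#' parse_formula("C39H35ClN4O4")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) stop("empty formula string")
  tokens <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  matched <- regmatches(text, gregexpr("([A-Z][a-z]?)([0-9]*)", text))[[1]]
  if (sum(nchar(matched)) != nchar(text))
    stop("malformed formula string: ", dQuote(text, FALSE))
  sym <- sub("[0-9]*$", "", matched)
  cnt <- sub("^[A-Za-z]+", "", matched)
  cnt <- ifelse(nzchar(cnt), as.integer(cnt), 1L)
  known <- .foldmimic_atomic$symbol
  if (any(!sym %in% known))
    stop("unknown element symbol: ",
         paste(dQuote(unique(sym[!sym %in% known]), FALSE), collapse = ", "))
  if (any(cnt < 1L)) stop("element counts must be >= 1")
  counts <- tapply(cnt, factor(sym, levels = unique(sym)), sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  structure(out, class = "molformula")
}

as_formula <- function(f) {
  if (inherits(f, "molformula")) return(f)
  if (is.character(f)) return(parse_formula(f))
  stopifnot(is.numeric(f), !is.null(names(f)))
  structure(as.integer(f), names = names(f), class = "molformula")
}

#' @export
print.molformula <- function(x, ...) {
  cat("<molformula> ",
      paste0(names(x), ifelse(unclass(x) > 1L, unclass(x), ""), collapse = ""),
      "\n", sep = "")
  invisible(x)
}

#' Average (standard atomic weight) molecular mass
#'
#' @param f A formula string or a [parse_formula()] result.
#' @return Molecular mass in u, from IUPAC 2021 standard atomic weights.
#' @examples
#' average_mass("C39H35ClN4O4") # ~659.18, printed Mr 659.16
#' @export
average_mass <- function(f) {
  f <- as_formula(f)
  sum(unclass(f) * .atomic_row(names(f))$weight)
}

#' Monoisotopic molecular mass
#'
#' Sum of principal-isotope masses; the neutral-molecule `[M]+` value
#' quoted as "calcd" in ESI-MS characterization (to 1 decimal the
#' electron mass is immaterial).
#'
#' @inheritParams average_mass
#' @return Monoisotopic mass in u.
#' @examples
#' monoisotopic_mass("C26H34N4O4") # 466.3 to 1 d.p.
#' @export
monoisotopic_mass <- function(f) {
  f <- as_formula(f)
  sum(unclass(f) * .atomic_row(names(f))$mono)
}

#' Calculated elemental analysis
#'
#' Mass percentage of each element, as in "anal. calcd" lines.
#'
#' @inheritParams average_mass
#' @return Named numeric vector of mass percentages summing to 100.
#' @examples
#' round(elemental_percentages("C39H35ClN4O4"), 2) # C 71.06 H 5.35 N 8.50
#' @export
elemental_percentages <- function(f) {
  f <- as_formula(f)
  if (length(f) == 0L) stop("empty formula")
  w <- unclass(f) * .atomic_row(names(f))$weight
  100 * w / sum(w)
}

#' Total electron count of a neutral formula
#'
#' @inheritParams average_mass
#' @return Integer: sum of atomic numbers over all atoms.
#' @export
electron_count <- function(f) {
  if (is.character(f) && length(f) == 1L && !nzchar(f)) return(0L)
  f <- as_formula(f)
  if (length(f) == 0L) return(0L)
  sum(unclass(f) * .atomic_row(names(f))$z)
}

#' F(000) structure factor
#'
#' Neutral-atom zero-angle structure factor: electrons per unit cell,
#' `Z` formula units times the formula electron count. No anomalous
#' dispersion correction is applied, so the value is an integer.
#'
#' @inheritParams average_mass
#' @param z Formula units per unit cell (positive integer).
#' @return Integer electron count per cell.
#' @examples
#' f000("C39H35ClN4O4", z = 4) # 1384
#' @export
f000 <- function(f, z) {
  stopifnot(is.numeric(z), length(z) == 1L)
  if (z < 1 || z != round(z)) stop("z must be a positive integer")
  as.integer(round(z)) * electron_count(f)
}

#' Construct a crystal unit cell
#'
#' @param a,b,c Cell lengths in Angstrom.
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @param z Formula units per cell (optional, positive integer).
#' @param space_group Space-group label (optional text, e.g. `"C2"`).
#' @return An object of class `"crystal_cell"`.
#' @examples
#' crystal_cell(33.471, 9.5152, 10.877, beta = 99.48, z = 4, space_group = "C2")
#' @export
crystal_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90,
                         z = NA_integer_, space_group = NA_character_) {
  len <- c(a = a, b = b, c = c)
  ang <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(len)) || any(len <= 0)) stop("cell lengths must be positive")
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180))
    stop("cell angles must lie in (0, 180) degrees")
  if (!is.na(z) && (z < 1 || z != round(z))) stop("z must be a positive integer")
  structure(list(a = a, b = b, c = c,
                 alpha = alpha, beta = beta, gamma = gamma,
                 z = if (is.na(z)) NA_integer_ else as.integer(z),
                 space_group = space_group),
            class = "crystal_cell")
}

#' @export
print.crystal_cell <- function(x, ...) {
  cat(sprintf("<crystal_cell> a=%.4g b=%.4g c=%.4g A, alpha=%.4g beta=%.4g gamma=%.4g deg",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  if (!is.na(x$z)) cat(" Z=", x$z, sep = "")
  if (!is.na(x$space_group)) cat(" [", x$space_group, "]", sep = "")
  cat("  V=", sprintf("%.1f", cell_volume(x)), " A^3\n", sep = "")
  invisible(x)
}

#' Unit-cell volume
#'
#' General triclinic formula
#' `V = abc * sqrt(1 - cos^2(alpha) - cos^2(beta) - cos^2(gamma)
#'  + 2 cos(alpha) cos(beta) cos(gamma))`,
#' which reduces to `abc sin(beta)` for monoclinic cells.
#'
#' @param cell A [crystal_cell()].
#' @return Volume in cubic Angstrom.
#' @examples
#' cell_volume(crystal_cell(33.471, 9.5152, 10.877, beta = 99.48)) # 3416.9
#' @export
cell_volume <- function(cell) {
  stopifnot(inherits(cell, "crystal_cell"))
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  disc <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (disc <= 0) stop("degenerate cell: angle combination gives non-positive volume")
  cell$a * cell$b * cell$c * sqrt(disc)
}

#' Calculated crystal density
#'
#' `rho = Z * Mr * 1.66054 / V`, with `Mr` the average molecular mass in u
#' and `V` the cell volume in cubic Angstrom; 1.66054 converts u/A^3 to
#' g/cm^3.
#'
#' @param cell A [crystal_cell()] carrying `z`, or supply `z` explicitly.
#' @param f Formula string or [parse_formula()] result.
#' @param z Formula units per cell; defaults to `cell$z`.
#' @return Density in g/cm^3.
#' @examples
#' crystal_density(crystal_cell(33.471, 9.5152, 10.877, beta = 99.48),
#'                 "C39H35ClN4O4", z = 4) # 1.281
#' @export
crystal_density <- function(cell, f, z = cell$z) {
  if (is.na(z)) stop("z not set on the cell and not supplied")
  if (z < 1 || z != round(z)) stop("z must be a positive integer")
  z * average_mass(f) * 1.66054 / cell_volume(cell)
}

# journal-style rounding: half away from zero at `digits` decimals
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
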