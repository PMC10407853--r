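# Hirshfeld-surface contact statistics and crystal-packing tables.
# The surface itself (promolecule partition, d_i/d_e mapping) comes from
# upstream tools; here its composition and contact tables are the input.

#' Hirshfeld-surface contact table
#'
#' Surface composition `S_X` (percent of the surface closest to element
#' X) together with merged contact proportions `C_XY` (percent of the
#' surface where the inside/outside nearest elements are X and Y;
#' reciprocal contacts X...Y and Y...X are merged). Both parts must sum
#' to 100 within 0.2.
#'
#' @param surface Named numeric vector of `S_X` percentages.
#' @param contacts Data frame with columns `x`, `y` (element symbols) and
#'   `pct`; pairs are unordered.
#' @return Object of class `"contact_table"`.
#' @export
contact_table <- function(surface, contacts) {
  stopifnot(is.numeric(surface), !is.null(names(surface)))
  if (any(surface < 0)) stop("negative surface fraction")
  if (abs(sum(surface) - 100) > 0.2)
    stop("surface fractions must sum to 100 (got ", round(sum(surface), 2), ")")
  contacts <- as.data.frame(contacts)
  stopifnot(all(c("x", "y", "pct") %in% names(contacts)))
  if (any(contacts$pct < 0)) stop("negative contact fraction")
  if (abs(sum(contacts$pct) - 100) > 0.2)
    stop("contact fractions must sum to 100 (got ", round(sum(contacts$pct), 2), ")")
  els <- names(surface)
  if (!all(c(contacts$x, contacts$y) %in% els))
    stop("contact rows name elements absent from the surface composition")
  # canonical pair order: the order of the surface composition
  swap <- match(contacts$x, els) > match(contacts$y, els)
  tmp <- contacts$x[swap]; contacts$x[swap] <- contacts$y[swap]; contacts$y[swap] <- tmp
  key <- paste(contacts$x, contacts$y)
  if (anyDuplicated(key)) stop("duplicate contact pair")
  structure(list(elements = els, surface = surface,
                 contacts = contacts[, c("x", "y", "pct")]),
            class = "contact_table")
}

#' @export
print.contact_table <- function(x, ...) {
  cat("<contact_table> surface (%):",
      paste(sprintf("%s %.1f", names(x$surface), x$surface), collapse = ", "), "\n")
  cat("  contacts (%):",
      paste(sprintf("%s-%s %.1f", x$contacts$x, x$contacts$y, x$contacts$pct),
            collapse = ", "), "\n")
  invisible(x)
}

#' Random-contact proportions from a surface composition
#'
#' The proportions expected if contacts formed at random across the
#' surface: with `s_X = S_X / 100`, `R_XX = 100 s_X^2` and
#' `R_XY = 100 * 2 s_X s_Y` for merged unordered pairs.
#'
#' @param surface Named numeric vector of `S_X` percentages (or a
#'   [contact_table()]).
#' @return Data frame with columns `x`, `y`, `r` (percent) over all
#'   unordered element pairs.
#' @export
random_contacts <- function(surface) {
  if (inherits(surface, "contact_table")) surface <- surface$surface
  stopifnot(is.numeric(surface), !is.null(names(surface)))
  if (any(surface < 0)) stop("negative surface fraction")
  s <- surface / 100
  els <- names(surface)
  out <- NULL
  for (i in seq_along(els)) for (j in i:length(els)) {
    r <- if (i == j) 100 * s[i]^2 else 100 * 2 * s[i] * s[j]
    out <- rbind(out, data.frame(x = els[i], y = els[j], r = unname(r)))
  }
  out
}

#' Contact enrichment ratios
#'
#' `E_XY = C_XY / R_XY`: the observed contact proportion relative to the
#' random expectation from the surface composition. Following standard
#' practice, `E` is not reported when the random contact `R_XY` falls
#' below 0.9 percent (the ratio of two small numbers is noise); a ratio
#' of at least 1 marks an enriched contact.
#'
#' @param tab A [contact_table()].
#' @param r_min Masking threshold on `R_XY` (percent).
#' @return Object of class `"enrichment_result"`: data frame with
#'   columns `x`, `y`, `c` (observed), `r` (random), `e` (raw ratio,
#'   `NA` when masked), `e_report` (half-up to 1 decimal) and `enriched`.
#' @examples
#' enrichment(contact_table_8r())
#' @export
enrichment <- function(tab, r_min = 0.9) {
  stopifnot(inherits(tab, "contact_table"))
  rnd <- random_contacts(tab$surface)
  key <- function(x, y) paste(x, y)
  cmap <- stats::setNames(tab$contacts$pct, key(tab$contacts$x, tab$contacts$y))
  out <- rnd
  out$c <- unname(cmap[key(out$x, out$y)])
  out$c[is.na(out$c)] <- 0
  out$masked <- out$r < r_min
  zero_r <- out$r == 0 & out$c > 0
  if (any(zero_r)) {
    warning("contacts observed for pairs with zero random expectation; masked")
    out$masked <- out$masked | zero_r
  }
  out$e <- ifelse(out$masked, NA_real_, out$c / out$r)
  out$e_report <- round_half_up(out$e, 1)
  out$enriched <- !is.na(out$e_report) & out$e_report >= 1
  out <- out[, c("x", "y", "c", "r", "e", "e_report", "masked", "enriched")]
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' @export
print.enrichment_result <- function(x, ...) {
  df <- as.data.frame(x)
  df$e <- NULL
  df$e_report <- ifelse(df$masked, "-", sprintf("%.1f", df$e_report))
  print(df, row.names = FALSE)
  invisible(x)
}

#' The printed Hirshfeld contact table of the 8r crystal
#'
#' The published surface composition and merged contact proportions of
#' the hydantoin peptidomimetic crystal structure (elements H, C, N, O,
#' Cl), as a ready-made [contact_table()] for enrichment analysis.
#'
#' @return A [contact_table()].
#' @export
contact_table_8r <- function() {
  contact_table(
    surface = c(H = 72.2, C = 15.2, N = 0.5, O = 7.8, Cl = 4.4),
    contacts = data.frame(
      x = c("H", "H", "C", "H", "C", "N", "H", "C", "N", "O",
            "H", "C", "N", "O", "Cl"),
      y = c("H", "C", "C", "N", "N", "N", "O", "O", "O", "O",
            "Cl", "Cl", "Cl", "Cl", "Cl"),
      pct = c(49.1, 24.7, 1.6, 0.3, 0.6, 0.0, 13.3, 1.0, 0.0, 0.6,
              7.9, 0.9, 0.0, 0.0, 0.0)))
}

#' Read a contact table from CSV
#'
#' Expects columns `record` (`"surface"` or `"contact"`), `x`, `y`
#' (empty for surface rows) and `pct`, as written by
#' [write_contact_table()].
#'
#' @param path CSV file.
#' @return A [contact_table()].
#' @export
read_contact_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("record", "x", "pct") %in% names(df)))
  s <- df[df$record == "surface", ]
  ct <- df[df$record == "contact", ]
  contact_table(stats::setNames(s$pct, s$x),
                data.frame(x = ct$x, y = ct$y, pct = ct$pct))
}

#' Write a contact table to CSV
#'
#' @param tab A [contact_table()].
#' @param path Output file.
#' @export
write_contact_table <- function(tab, path) {
  stopifnot(inherits(tab, "contact_table"))
  df <- rbind(
    data.frame(record = "surface", x = names(tab$surface), y = "",
               pct = unname(tab$surface)),
    data.frame(record = "contact", x = tab$contacts$x, y = tab$contacts$y,
               pct = tab$contacts$pct))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Globularity of a closed surface
#'
#' `G = (36 pi)^(1/3) V^(2/3) / A`: the area of the sphere with the same
#' volume divided by the actual area. 1 for a sphere, smaller for any
#' other closed surface.
#'
#' @param v Enclosed volume (cubic Angstrom).
#' @param a Surface area (square Angstrom).
#' @return Dimensionless globularity.
#' @examples
#' globularity(845.05, 641.95) # 0.673
#' @export
globularity <- function(v, a) {
  if (!is.finite(v) || !is.finite(a) || v <= 0 || a <= 0)
    stop("volume and area must be positive")
  (36 * pi)^(1 / 3) * v^(2 / 3) / a
}

#' Normalized contact distance d_norm
#'
#' `d_norm = (d_i - r_i) / r_i + (d_e - r_e) / r_e` with `d_i`/`d_e` the
#' distances from the surface to the nearest nucleus inside/outside and
#' `r_i`/`r_e` the corresponding van der Waals radii. Negative values
#' mark contacts shorter than the van der Waals sum.
#'
#' @param d_i,d_e Internal and external nearest-nucleus distances
#'   (Angstrom), positive.
#' @param r_i,r_e Van der Waals radii (Angstrom) or element symbols.
#' @return Numeric d_norm (vectorized).
#' @examples
#' dnorm_contact(1.2, 1.0, "H", "O")
#' @export
dnorm_contact <- function(d_i, d_e, r_i, r_e) {
  if (is.character(r_i)) r_i <- vdw_radius(r_i)
  if (is.character(r_e)) r_e <- vdw_radius(r_e)
  if (any(r_i <= 0) || any(r_e <= 0)) stop("van der Waals radii must be positive")
  if (any(d_i <= 0) || any(d_e <= 0)) stop("contact distances must be positive")
  (d_i - r_i) / r_i + (d_e - r_e) / r_e
}

#' Two-dimensional fingerprint histogram
#'
#' Bins (d_i, d_e) surface points on a square grid with half-open bins
#' `[lo, lo + w)`; the axis ranges are extended when points fall outside
#' the requested range, so counts always conserve the number of points.
#'
#' @param points Data frame (or matrix) with columns `d_i` and `d_e`.
#' @param bin_width Bin width in Angstrom.
#' @param range Minimum axis extent `c(lo, hi)`, both axes.
#' @return Integer matrix of counts (rows = d_i bins, columns = d_e
#'   bins) with `breaks_i`/`breaks_e` attributes.
#' @export
fingerprint_hist <- function(points, bin_width = 0.01, range = c(0.4, 3.0)) {
  if (bin_width <= 0) stop("bin width must be positive")
  points <- as.data.frame(points)
  if (nrow(points) == 0) {
    br <- seq(range[1], range[2] + bin_width, by = bin_width)
    m <- matrix(0L, length(br) - 1, length(br) - 1)
    attr(m, "breaks_i") <- br; attr(m, "breaks_e") <- br
    return(m)
  }
  stopifnot(all(c("d_i", "d_e") %in% names(points)))
  if (any(points$d_i <= 0) || any(points$d_e <= 0))
    stop("fingerprint distances must be positive")
  lo <- min(range[1], points$d_i, points$d_e)
  hi <- max(range[2], points$d_i, points$d_e)
  lo <- bin_width * floor(lo / bin_width)
  br <- seq(lo, hi + bin_width, by = bin_width)
  bi <- findInterval(points$d_i, br, rightmost.closed = FALSE)
  be <- findInterval(points$d_e, br, rightmost.closed = FALSE)
  m <- matrix(0L, length(br) - 1, length(br) - 1)
  for (k in seq_along(bi)) m[bi[k], be[k]] <- m[bi[k], be[k]] + 1L
  attr(m, "breaks_i") <- br; attr(m, "breaks_e") <- br
  m
}

# format a rotation/translation pair back to "x, y-1, z" notation
.symop_string <- function(rot, trans) {
  axis <- c("x", "y", "z")
  parts <- vapply(1:3, function(k) {
    s <- ""
    for (m in 1:3) {
      co <- rot[k, m]
      if (co == 0) next
      sgn <- if (co > 0) (if (nzchar(s)) "+" else "") else "-"
      s <- paste0(s, sgn, if (abs(co) != 1) paste0(abs(co), "*") else "", axis[m])
    }
    t <- trans[k]
    if (abs(t) > 1e-9) {
      frac <- c(`0.5` = "1/2", `0.25` = "1/4", `0.75` = "3/4")
      key <- as.character(abs(t))
      tstr <- if (key %in% names(frac)) frac[[key]] else format(abs(t))
      s <- paste0(s, if (t > 0) "+" else "-", tstr)
    }
    if (!nzchar(s)) "0" else s
  }, character(1))
  paste(parts, collapse = ", ")
}

#' Hydrogen-bond table of a crystal structure
#'
#' Enumerates D-H...A contacts between the asymmetric unit and its
#' symmetry- plus lattice-translated images. Donors are N/O atoms with a
#' covalently attached hydrogen; acceptors default to N, O and Cl. A
#' contact is kept when H...A and D...A are within the cutoffs and the
#' D-H...A angle reaches the minimum. Contacts with the identity
#' operator and zero translation are intramolecular.
#'
#' @param s A [crystal_structure()] with explicit hydrogens.
#' @param d_ha_max,d_da_max,angle_min Geometric cutoffs (Angstrom,
#'   Angstrom, degrees).
#' @param acceptor_elements Element symbols accepted as A.
#' @param shell Lattice-translation shell for the neighbour search.
#' @return Data frame with one row per contact: `donor`, `h`, `acceptor`
#'   labels, `d_da`, `d_ha`, `angle_dha`, `symop` (composed operator
#'   string, `"."` for the identity) and `intramolecular`.
#' @export
hbond_table <- function(s, d_ha_max = 2.5, d_da_max = 3.5, angle_min = 120,
                        acceptor_elements = c("N", "O", "Cl"), shell = 1) {
  stopifnot(inherits(s, "crystal_structure"))
  mol <- s$molecule
  if (!any(mol$atoms$element == "H"))
    stop("crystal structure carries no hydrogen atoms")
  xyz <- coords(mol)
  bnd <- rbind(as.matrix(mol$bonds[, c("i", "j")]),
               as.matrix(mol$bonds[, c("j", "i")]))
  donors <- NULL
  for (h in which(mol$atoms$element == "H")) {
    heavy <- bnd[bnd[, 1] == h, 2]
    heavy <- heavy[mol$atoms$element[heavy] %in% c("N", "O")]
    if (length(heavy) == 1)
      donors <- rbind(donors, c(heavy, h))
  }
  if (is.null(donors)) return(data.frame())
  env <- expand_symmetry(s, shell)
  env <- env[env$element %in% acceptor_elements, , drop = FALSE]
  ident <- vapply(s$symops, .is_identity_symop, logical(1))
  out <- NULL
  for (k in seq_len(nrow(donors))) {
    d <- donors[k, 1]; h <- donors[k, 2]
    excl <- c(d, h, bnd[bnd[, 1] == d, 2])  # the donor group itself
    for (r in seq_len(nrow(env))) {
      self_image <- ident[env$op[r]] && env$tx[r] == 0 && env$ty[r] == 0 &&
        env$tz[r] == 0
      if (self_image && env$src[r] %in% excl) next
      a <- c(env$x[r], env$y[r], env$z[r])
      g <- hbond_geometry(xyz[d, ], xyz[h, ], a)
      if (g$d_ha > d_ha_max || g$d_da > d_da_max || g$angle_dha < angle_min)
        next
      p <- parse_symop(s$symops[env$op[r]])
      code <- if (self_image) "." else
        .symop_string(p$rot, p$trans + c(env$tx[r], env$ty[r], env$tz[r]))
      out <- rbind(out, data.frame(
        donor = mol$atoms$label[d], h = mol$atoms$label[h],
        acceptor = env$label[r],
        d_da = g$d_da, d_ha = g$d_ha, angle_dha = g$angle_dha,
        symop = code, intramolecular = self_image))
    }
  }
  out %||% data.frame()
}
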