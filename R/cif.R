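# Crystal structures: CIF input, fractional/Cartesian conversion and
# symmetry expansion. The CIF reader is deliberately minimal (cell,
# symmetry-operator loop, atom_site loop with fractional coordinates);
# no R package on hand parses CIF.

#' Crystallographic basis matrix
#'
#' Matrix `M` whose columns are the lattice vectors in a standard
#' Cartesian frame (`a` along x, `b` in the xy plane), so that
#' `cartesian = M %*% fractional`.
#'
#' @param cell A [crystal_cell()].
#' @return 3 x 3 numeric matrix (Angstrom).
#' @export
cell_matrix <- function(cell) {
  stopifnot(inherits(cell, "crystal_cell"))
  ca <- cos(cell$alpha * pi / 180); cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180); sg <- sin(cell$gamma * pi / 180)
  disc <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (disc <= 0) stop("degenerate cell")
  matrix(c(cell$a, 0, 0,
           cell$b * cg, cell$b * sg, 0,
           cell$c * cb, cell$c * (ca - cb * cg) / sg, cell$c * sqrt(disc) / sg),
         nrow = 3)
}

#' Convert fractional to Cartesian coordinates
#'
#' @param frac n x 3 matrix of fractional coordinates.
#' @param cell A [crystal_cell()].
#' @return n x 3 matrix of Cartesian coordinates (Angstrom).
#' @export
frac_to_cart <- function(frac, cell) {
  frac <- matrix(as.numeric(frac), ncol = 3)
  frac %*% t(cell_matrix(cell))
}

#' Convert Cartesian to fractional coordinates
#'
#' @param cart n x 3 matrix of Cartesian coordinates (Angstrom).
#' @param cell A [crystal_cell()].
#' @return n x 3 matrix of fractional coordinates.
#' @export
cart_to_frac <- function(cart, cell) {
  cart <- matrix(as.numeric(cart), ncol = 3)
  cart %*% t(solve(cell_matrix(cell)))
}

#' Construct a crystal structure
#'
#' @param cell A [crystal_cell()].
#' @param frac n x 3 fractional coordinates of the asymmetric unit.
#' @param elements Element symbols, length n.
#' @param labels Atom labels (e.g. `"N3"`, `"O4"`); default element+serial.
#' @param symops Character vector of symmetry operators
#'   (`"x, y, z"`-style); the identity is added if absent.
#' @param bonds Optional bond data frame for the asymmetric unit; when
#'   `NULL`, bonds are perceived from the Cartesian geometry.
#' @return Object of class `"crystal_structure"` with the asymmetric unit
#'   as a Cartesian [molecule()] plus fractional coordinates and
#'   operators.
#' @export
crystal_structure <- function(cell, frac, elements, labels = NULL,
                              symops = "x, y, z", bonds = NULL) {
  stopifnot(inherits(cell, "crystal_cell"))
  frac <- matrix(as.numeric(frac), ncol = 3)
  stopifnot(nrow(frac) == length(elements))
  lapply(symops, parse_symop)  # validates
  if (!any(vapply(symops, .is_identity_symop, logical(1))))
    symops <- c("x, y, z", symops)
  cart <- frac_to_cart(frac, cell)
  mol <- molecule(data.frame(element = elements,
                             label = labels %||% paste0(elements, seq_along(elements)),
                             x = cart[, 1], y = cart[, 2], z = cart[, 3]))
  if (is.null(bonds)) bonds <- perceive_bonds(mol)
  mol <- molecule(mol$atoms, bonds)
  structure(list(cell = cell, molecule = mol, frac = frac, symops = symops),
            class = "crystal_structure")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.crystal_structure <- function(x, ...) {
  cat(sprintf("<crystal_structure> %d atoms in asymmetric unit, %d symmetry operators\n",
              nrow(x$molecule$atoms), length(x$symops)))
  print(x$cell)
  invisible(x)
}

.is_identity_symop <- function(op) {
  p <- parse_symop(op)
  isTRUE(all.equal(p$rot, diag(3))) && isTRUE(all.equal(p$trans, c(0, 0, 0)))
}

#' Parse a crystallographic symmetry-operator string
#'
#' Accepts the conventional `"x, y, z"` notation with integer or
#' fractional translations, e.g. `"-x+1/2, y+1/2, -z"` or `"x, y-1, z"`.
#'
#' @param op Operator string.
#' @return List with `rot` (3 x 3 matrix) and `trans` (length-3 vector),
#'   acting on fractional coordinates as `rot %*% f + trans`.
#' @export
parse_symop <- function(op) {
  parts <- strsplit(op, ",")[[1]]
  if (length(parts) != 3) stop("unparseable symmetry operator: ", dQuote(op, FALSE))
  rot <- matrix(0, 3, 3); trans <- numeric(3)
  for (k in 1:3) {
    expr <- gsub("[[:space:]]", "", tolower(parts[k]))
    terms <- regmatches(expr,
      gregexpr("[+-]?([0-9]+/[0-9]+|[0-9]*\\.?[0-9]+|[xyz])", expr))[[1]]
    if (!nzchar(expr) || sum(nchar(terms)) != nchar(expr))
      stop("unparseable symmetry operator: ", dQuote(op, FALSE))
    for (t in terms) {
      sgn <- if (startsWith(t, "-")) -1 else 1
      t <- sub("^[+-]", "", t)
      if (t %in% c("x", "y", "z")) {
        rot[k, match(t, c("x", "y", "z"))] <-
          rot[k, match(t, c("x", "y", "z"))] + sgn
      } else if (grepl("/", t)) {
        nm <- as.numeric(strsplit(t, "/")[[1]])
        trans[k] <- trans[k] + sgn * nm[1] / nm[2]
      } else {
        trans[k] <- trans[k] + sgn * as.numeric(t)
      }
    }
  }
  list(rot = rot, trans = trans)
}

.cif_num <- function(x) as.numeric(sub("\\(.*\\)", "", x))

.cif_tokens <- function(line) {
  # split a CIF data line, honouring single/double quotes
  out <- character(); i <- 1; n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (grepl("[[:space:]]", ch)) { i <- i + 1; next }
    if (ch %in% c("'", '"')) {
      j <- i + 1
      while (j <= n && substr(line, j, j) != ch) j <- j + 1
      out <- c(out, substr(line, i + 1, j - 1)); i <- j + 1
    } else {
      j <- i
      while (j <= n && !grepl("[[:space:]]", substr(line, j, j))) j <- j + 1
      out <- c(out, substr(line, i, j - 1)); i <- j
    }
  }
  out
}

#' Read a crystal structure from a CIF file
#'
#' Minimal CIF support: cell parameters, the space-group label, the
#' symmetry-operator loop (`_symmetry_equiv_pos_as_xyz` or
#' `_space_group_symop_operation_xyz`) and the `_atom_site` loop with
#' fractional coordinates. Labels are preserved verbatim; Cartesian
#' coordinates use the standard crystallographic basis ([cell_matrix()]).
#'
#' @param path CIF file.
#' @return A [crystal_structure()].
#' @export
read_cif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^[[:space:]]*#", lines)]
  txt <- trimws(lines)

  getval <- function(tag) {
    hit <- grep(paste0("^", tag, "([[:space:]]|$)"), txt)
    if (!length(hit)) return(NA_character_)
    tok <- .cif_tokens(txt[hit[1]])
    if (length(tok) >= 2) tok[2] else NA_character_
  }
  need <- function(tag) {
    v <- getval(tag)
    if (is.na(v)) stop("CIF is missing ", tag)
    v
  }
  cellpar <- unname(vapply(c("_cell_length_a", "_cell_length_b", "_cell_length_c",
                             "_cell_angle_alpha", "_cell_angle_beta", "_cell_angle_gamma"),
                           function(t) .cif_num(need(t)), numeric(1)))
  zval <- getval("_cell_formula_units_Z")
  sg <- getval("_symmetry_space_group_name_H-M")
  if (is.na(sg)) sg <- getval("_space_group_name_H-M_alt")
  cell <- crystal_cell(cellpar[1], cellpar[2], cellpar[3],
                       cellpar[4], cellpar[5], cellpar[6],
                       z = if (is.na(zval)) NA_integer_ else as.integer(.cif_num(zval)),
                       space_group = if (is.na(sg)) NA_character_ else sg)

  # collect loops: list(tags, rows)
  loops <- list(); i <- 1
  while (i <= length(txt)) {
    if (tolower(txt[i]) == "loop_") {
      j <- i + 1; tags <- character()
      while (j <= length(txt) && startsWith(txt[j], "_")) {
        tags <- c(tags, .cif_tokens(txt[j])[1]); j <- j + 1
      }
      rows <- list()
      while (j <= length(txt) && nzchar(txt[j]) &&
             !startsWith(txt[j], "_") && tolower(txt[j]) != "loop_" &&
             !startsWith(tolower(txt[j]), "data_")) {
        rows[[length(rows) + 1]] <- .cif_tokens(txt[j]); j <- j + 1
      }
      loops[[length(loops) + 1]] <- list(tags = tolower(tags), rows = rows)
      i <- j
    } else i <- i + 1
  }

  symops <- "x, y, z"
  for (lp in loops) {
    k <- which(lp$tags %in% c("_symmetry_equiv_pos_as_xyz",
                              "_space_group_symop_operation_xyz"))
    if (length(k)) {
      symops <- vapply(lp$rows, function(r) r[k[1]], character(1))
      break
    }
  }

  atoms <- NULL
  for (lp in loops) {
    if (all(c("_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z")
            %in% lp$tags)) {
      get <- function(tag) {
        k <- match(tag, lp$tags)
        if (is.na(k)) return(NULL)
        vapply(lp$rows, function(r) r[k], character(1))
      }
      lab <- get("_atom_site_label")
      el <- get("_atom_site_type_symbol")
      if (is.null(el)) el <- sub("[0-9'].*$", "", lab)
      atoms <- data.frame(
        element = el, label = lab %||% el,
        fx = .cif_num(get("_atom_site_fract_x")),
        fy = .cif_num(get("_atom_site_fract_y")),
        fz = .cif_num(get("_atom_site_fract_z")))
      break
    }
  }
  if (is.null(atoms)) stop("CIF is missing an _atom_site loop")
  crystal_structure(cell, as.matrix(atoms[, c("fx", "fy", "fz")]),
                    atoms$element, atoms$label, symops)
}

#' Write a crystal structure to a minimal CIF file
#'
#' @param s A [crystal_structure()].
#' @param path Output file.
#' @param data_name CIF data block name.
#' @export
write_cif <- function(s, path, data_name = "foldmimic") {
  stopifnot(inherits(s, "crystal_structure"))
  cl <- s$cell
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste0("data_", data_name),
               sprintf("_cell_length_a %.6f", cl$a),
               sprintf("_cell_length_b %.6f", cl$b),
               sprintf("_cell_length_c %.6f", cl$c),
               sprintf("_cell_angle_alpha %.4f", cl$alpha),
               sprintf("_cell_angle_beta %.4f", cl$beta),
               sprintf("_cell_angle_gamma %.4f", cl$gamma)), con)
  if (!is.na(cl$z))
    writeLines(sprintf("_cell_formula_units_Z %d", cl$z), con)
  if (!is.na(cl$space_group))
    writeLines(sprintf("_symmetry_space_group_name_H-M '%s'", cl$space_group), con)
  writeLines(c("loop_", "_symmetry_equiv_pos_as_xyz",
               sprintf("'%s'", s$symops)), con)
  writeLines(c("loop_", "_atom_site_label", "_atom_site_type_symbol",
               "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z"),
             con)
  writeLines(sprintf("%s %s %.6f %.6f %.6f",
                     s$molecule$atoms$label, s$molecule$atoms$element,
                     s$frac[, 1], s$frac[, 2], s$frac[, 3]), con)
  invisible(path)
}

#' Expand a crystal structure by symmetry and lattice translations
#'
#' Applies every symmetry operator plus all lattice translations within
#' `-shell..shell` cells along each axis. No deduplication is performed,
#' so the output has `n_atoms * n_ops * (2*shell+1)^3` rows; each row is
#' tagged with its operator, translation and source atom.
#'
#' @param s A [crystal_structure()].
#' @param shell Non-negative integer translation shell.
#' @return Data frame with columns `element`, `label`, `x`, `y`, `z`
#'   (Cartesian), `op` (operator index), `symop` (string), `tx`, `ty`,
#'   `tz` (lattice translation) and `src` (asymmetric-unit atom index).
#' @export
expand_symmetry <- function(s, shell = 1) {
  stopifnot(inherits(s, "crystal_structure"), shell >= 0, shell == round(shell))
  ops <- lapply(s$symops, parse_symop)
  tr <- expand.grid(tx = -shell:shell, ty = -shell:shell, tz = -shell:shell)
  n <- nrow(s$frac)
  out <- vector("list", length(ops) * nrow(tr))
  k <- 0
  for (io in seq_along(ops)) {
    base <- t(ops[[io]]$rot %*% t(s$frac) + ops[[io]]$trans)
    for (it in seq_len(nrow(tr))) {
      f <- sweep(base, 2, as.numeric(tr[it, ]), "+")
      cart <- frac_to_cart(f, s$cell)
      k <- k + 1
      out[[k]] <- data.frame(
        element = s$molecule$atoms$element, label = s$molecule$atoms$label,
        x = cart[, 1], y = cart[, 2], z = cart[, 3],
        op = io, symop = s$symops[io],
        tx = tr$tx[it], ty = tr$ty[it], tz = tr$tz[it],
        src = seq_len(n))
    }
  }
  do.call(rbind, out)
}
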