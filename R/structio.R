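#' Build a molecule container
#'
#' @param atoms Data frame with columns `element`, `label`, `x`, `y`, `z`
#'   (Cartesian Angstrom). `label` defaults to `element` + serial.
#' @param bonds Data frame with columns `i`, `j` (1-based atom indices)
#'   and `order`, or `NULL` for no bonds.
#' @return Object of class `"fm_molecule"`.
#' @export
molecule <- function(atoms, bonds = NULL) {
  atoms <- as.data.frame(atoms)
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)))
  if (is.null(atoms$label))
    atoms$label <- paste0(atoms$element, seq_len(nrow(atoms)))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  .atomic_row(atoms$element)  # validates symbols
  if (is.null(bonds)) {
    bonds <- data.frame(i = integer(), j = integer(), order = integer())
  } else {
    bonds <- as.data.frame(bonds)
    if (is.null(bonds$order)) bonds$order <- 1L
    stopifnot(all(c("i", "j") %in% names(bonds)))
    n <- nrow(atoms)
    if (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n))
      stop("bond endpoint out of range")
    if (any(bonds$i == bonds$j)) stop("bond with identical endpoints")
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key)) stop("duplicate bond")
  }
  structure(list(atoms = atoms[, c("element", "label", "x", "y", "z")],
                 bonds = bonds[, c("i", "j", "order")]),
            class = "fm_molecule")
}

#' @export
print.fm_molecule <- function(x, ...) {
  cat(sprintf("<molecule> %d atoms, %d bonds (%s)\n",
              nrow(x$atoms), nrow(x$bonds),
              paste0(names(sort(-table(x$atoms$element))), collapse = "")))
  invisible(x)
}

coords <- function(mol) as.matrix(mol$atoms[, c("x", "y", "z")])

#' Build a conformer ensemble
#'
#' One molecular topology shared by N conformers, each a coordinate set
#' with an optional energy in kcal/mol.
#'
#' @param mol A [molecule()] providing elements and bonds.
#' @param xyz List of n_atoms x 3 coordinate matrices, one per conformer.
#' @param energies Numeric vector of conformer energies (kcal/mol), or
#'   `NULL`; `NA` marks a missing energy.
#' @param ids Conformer identifiers (default `conf1`, `conf2`, ...).
#' @param energy_method Free-text tag for the energy model.
#' @return Object of class `"fm_ensemble"`.
#' @export
ensemble <- function(mol, xyz, energies = NULL, ids = NULL,
                     energy_method = "unknown") {
  stopifnot(inherits(mol, "fm_molecule"), is.list(xyz), length(xyz) >= 1)
  n <- nrow(mol$atoms)
  xyz <- lapply(xyz, function(m) {
    m <- as.matrix(m)
    if (nrow(m) != n || ncol(m) != 3)
      stop("conformer coordinate block does not match the molecule")
    unname(m)
  })
  if (is.null(ids)) ids <- paste0("conf", seq_along(xyz))
  if (is.null(energies)) energies <- rep(NA_real_, length(xyz))
  stopifnot(length(ids) == length(xyz), length(energies) == length(xyz))
  structure(list(molecule = mol, xyz = xyz, energies = as.numeric(energies),
                 ids = as.character(ids), energy_method = energy_method),
            class = "fm_ensemble")
}

#' @export
print.fm_ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> %d conformers of %d atoms; energies: %s\n",
              length(x$xyz), nrow(x$molecule$atoms),
              if (all(is.na(x$energies))) "absent"
              else sprintf("%.2f .. %.2f kcal/mol (%s)",
                           min(x$energies, na.rm = TRUE),
                           max(x$energies, na.rm = TRUE), x$energy_method)))
  invisible(x)
}

#' @export
length.fm_ensemble <- function(x) length(x$xyz)

#' Extract one conformer's molecule
#'
#' @param e An [ensemble()].
#' @param i Conformer index.
#' @return A [molecule()] with that conformer's coordinates.
#' @export
conformer_molecule <- function(e, i) {
  stopifnot(inherits(e, "fm_ensemble"), i >= 1, i <= length(e$xyz))
  a <- e$molecule$atoms
  a[, c("x", "y", "z")] <- e$xyz[[i]]
  molecule(a, e$molecule$bonds)
}

.sdf_element <- function(rowname) sub("_[0-9]+$", "", rowname)

#' Read a multi-record SDF as a conformer ensemble
#'
#' All records must share one topology (atom count and element sequence).
#' Energies are taken from the named SDF data field when present; a
#' record lacking the field (or carrying a non-numeric value, with a
#' warning) gets `NA`.
#'
#' @param path SDF file (V2000/V3000, one record per conformer).
#' @param energy_field Name of the per-record energy property.
#' @return An [ensemble()].
#' @export
read_sdf <- function(path, energy_field = "E_kcal") {
  sdfs <- ChemmineR::read.SDFset(path)
  n <- length(sdfs)
  if (n == 0) stop("no records in SDF file")
  rec <- lapply(seq_len(n), function(i) sdfs[[i]])
  elements <- lapply(rec, function(r) .sdf_element(rownames(ChemmineR::atomblock(r))))
  for (i in seq_len(n))
    if (!identical(elements[[i]], elements[[1]]))
      stop("inconsistent topology across SDF records (record ", i, ")")
  ab1 <- ChemmineR::atomblock(rec[[1]])
  bb <- ChemmineR::bondblock(rec[[1]])
  bonds <- if (is.matrix(bb) && nrow(bb) > 0 && ncol(bb) >= 3)
    data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  else NULL
  mol <- molecule(data.frame(element = elements[[1]],
                             x = ab1[, 1], y = ab1[, 2], z = ab1[, 3]),
                  bonds)
  xyz <- lapply(rec, function(r) unname(ChemmineR::atomblock(r)[, 1:3, drop = FALSE]))
  energies <- vapply(rec, function(r) {
    db <- ChemmineR::datablock(r)
    if (!energy_field %in% names(db)) return(NA_real_)
    v <- suppressWarnings(as.numeric(db[[energy_field]]))
    if (is.na(v)) warning("unparseable energy in SDF record; treated as missing")
    v
  }, numeric(1))
  ids <- vapply(rec, function(r) ChemmineR::header(r)[["Molecule_Name"]], character(1))
  ids[!nzchar(ids)] <- paste0("conf", which(!nzchar(ids)))
  ensemble(mol, xyz, energies, ids, energy_method = energy_field)
}

#' Write a conformer ensemble as a multi-record SDF
#'
#' @param e An [ensemble()].
#' @param path Output file.
#' @param energy_field Data-field name for conformer energies; conformers
#'   with `NA` energy get no field.
#'
#' @details An SDF record needs a connection table; when the molecule
#'   carries no bonds they are perceived from the first conformer's
#'   geometry ([perceive_bonds()]) before writing.
#' @export
write_sdf <- function(e, path, energy_field = "E_kcal") {
  stopifnot(inherits(e, "fm_ensemble"))
  mol <- e$molecule
  if (nrow(mol$bonds) == 0) mol <- molecule(mol$atoms, perceive_bonds(mol))
  na <- nrow(mol$atoms); nb <- nrow(mol$bonds)
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb)
  bb <- NULL
  if (nb > 0) {
    bb <- cbind(as.matrix(mol$bonds[, c("i", "j", "order")]),
                matrix(0L, nb, 4))
    colnames(bb) <- paste0("C", 1:7)
    rownames(bb) <- seq_len(nb)
  } else {
    bb <- matrix(0L, 0, 7, dimnames = list(NULL, paste0("C", 1:7)))
  }
  sdflist <- lapply(seq_along(e$xyz), function(i) {
    ab <- cbind(e$xyz[[i]], matrix(0, na, 12))
    rownames(ab) <- paste0(mol$atoms$element, "_", seq_len(na))
    colnames(ab) <- c("C1", "C2", "C3", paste0("C", 5:16))
    db <- if (is.na(e$energies[i])) character(0)
    else stats::setNames(sprintf("%.6f", e$energies[i]), energy_field)
    methods::new("SDF",
                 header = c(Molecule_Name = e$ids[i], Source = "  foldmimic",
                            Comment = "", Counts_Line = counts),
                 atomblock = ab, bondblock = bb, datablock = db)
  })
  sdfset <- methods::new("SDFset", SDF = sdflist, ID = e$ids)
  ChemmineR::write.SDF(sdfset, path, cid = TRUE)
  invisible(path)
}

#' Read a (multi-frame) XYZ file as a conformer ensemble
#'
#' The comment line of each frame may carry an energy as
#' `E_kcal = <value>` (or a bare number). Bonds are perceived from the
#' first frame with a covalent-radius criterion (see [perceive_bonds()]).
#'
#' @param path XYZ file.
#' @return An [ensemble()].
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0))]
  frames <- list(); energies <- numeric(); pos <- 1
  while (pos <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(nat)) stop("malformed XYZ: expected atom count at line ", pos)
    comment <- lines[pos + 1]
    block <- lines[pos + 1 + seq_len(nat)]
    tok <- strsplit(trimws(block), "[[:space:]]+")
    frames[[length(frames) + 1]] <- data.frame(
      element = vapply(tok, `[`, "", 1),
      x = as.numeric(vapply(tok, `[`, "", 2)),
      y = as.numeric(vapply(tok, `[`, "", 3)),
      z = as.numeric(vapply(tok, `[`, "", 4)))
    num <- "-?[0-9]+\\.?[0-9]*([eE]-?[0-9]+)?"
    em <- regmatches(comment,
                     regexpr(paste0("E_kcal[[:space:]]*=[[:space:]]*", num), comment))
    e_val <- if (length(em)) as.numeric(sub(".*=", "", em[1]))
    else if (grepl(paste0("^[[:space:]]*", num, "[[:space:]]*$"), comment))
      as.numeric(trimws(comment))
    else NA_real_
    energies <- c(energies, e_val)
    pos <- pos + 2 + nat
  }
  ref <- frames[[1]]
  for (f in frames)
    if (!identical(f$element, ref$element)) stop("inconsistent topology across XYZ frames")
  mol <- molecule(ref)
  mol <- molecule(mol$atoms, perceive_bonds(mol))
  ensemble(mol, lapply(frames, function(f) as.matrix(f[, c("x", "y", "z")])),
           energies, energy_method = "xyz_comment")
}

#' Write a conformer ensemble as a multi-frame XYZ file
#'
#' @param e An [ensemble()].
#' @param path Output file.
#' @export
write_xyz <- function(e, path) {
  stopifnot(inherits(e, "fm_ensemble"))
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(e$xyz)) {
    writeLines(as.character(nrow(e$molecule$atoms)), con)
    writeLines(if (is.na(e$energies[i])) e$ids[i]
               else sprintf("%s E_kcal = %.6f", e$ids[i], e$energies[i]), con)
    writeLines(sprintf("%-2s %12.6f %12.6f %12.6f", e$molecule$atoms$element,
                       e$xyz[[i]][, 1], e$xyz[[i]][, 2], e$xyz[[i]][, 3]), con)
  }
  invisible(path)
}

#' Read a multi-model PDB file as a conformer ensemble
#'
#' Each MODEL becomes one conformer (energies absent; PDB carries none).
#' Bonds are perceived by the covalent-radius criterion.
#'
#' @param path PDB file.
#' @return An [ensemble()].
#' @export
read_pdb_ensemble <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  el <- pdb$atom$elesy
  if (is.null(el) || all(!nzchar(trimws(el))))
    el <- substr(trimws(pdb$atom$elety), 1, 1)
  el <- trimws(el)
  el <- paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, 2)))
  nm <- nrow(pdb$xyz)
  xyz <- lapply(seq_len(nm), function(i) matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE))
  mol <- molecule(data.frame(element = el, label = trimws(pdb$atom$elety),
                             x = xyz[[1]][, 1], y = xyz[[1]][, 2], z = xyz[[1]][, 3]))
  mol <- molecule(mol$atoms, perceive_bonds(mol))
  ensemble(mol, xyz, energy_method = "none")
}

#' Perceive covalent bonds from interatomic distances
#'
#' Two atoms are bonded when their distance is below the sum of their
#' covalent radii plus `slack`. Intended for formats without a bond block
#' (XYZ, PDB, CIF) where only connectivity, not bond order, is needed.
#'
#' @param mol A [molecule()].
#' @param slack Additive tolerance in Angstrom.
#' @return Data frame of bonds (`i`, `j`, `order = 1`).
#' @export
perceive_bonds <- function(mol, slack = 0.4) {
  stopifnot(inherits(mol, "fm_molecule"))
  xyz <- coords(mol)
  r <- .atomic_row(mol$atoms$element)$covalent
  n <- nrow(xyz)
  if (n < 2) return(data.frame(i = integer(), j = integer(), order = integer()))
  d <- as.matrix(stats::dist(xyz))
  cut <- outer(r, r, "+") + slack
  hit <- which(d < cut & upper.tri(d), arr.ind = TRUE)
  hit <- hit[d[hit] > 0.4, , drop = FALSE]  # guard against coincident atoms
  data.frame(i = as.integer(hit[, 1]), j = as.integer(hit[, 2]),
             order = rep(1L, nrow(hit)))
}
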