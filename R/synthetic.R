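# Planted synthetic inputs: conformer ensembles with known motif labels,
# a toy crystal with an engineered hydrogen bond, and contact tables.
# Everything is a pure function of (spec, seed).

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification for a planted conformer ensemble
#'
#' @param n Number of conformers.
#' @param fractions Named fractions in \[0, 1\] of conformers planted at
#'   each motif geometry (`alpha`, `beta`, `three10`); overlaps are
#'   permitted (labels are drawn independently), so they may sum past 1.
#' @param sigma Isotropic Gaussian coordinate noise (Angstrom) applied
#'   after template placement.
#' @param global_min Which motif owns the lowest-energy conformer
#'   (`"alpha"`, `"beta"`, `"three10"`, or `"none"` for an unstructured
#'   minimum). Must be consistent with the fractions.
#' @param spread Energies of non-minimum conformers are uniform in
#'   (0, spread\] kcal/mol; default 9 keeps everything inside a
#'   10 kcal/mol window.
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return Object of class `"plant_spec"`.
#' @export
plant_spec <- function(n = 100,
                       fractions = c(alpha = 0.5, beta = 0.3, three10 = 0.2),
                       sigma = 0.05, global_min = NULL, spread = 9,
                       seed = 1) {
  fr <- c(alpha = 0, beta = 0, three10 = 0)
  fr[names(fractions)] <- fractions
  if (n < 1 || any(fr < 0) || any(fr > 1) || sigma < 0 || spread <= 0)
    stop("invalid plant specification")
  if (is.null(global_min))
    global_min <- if (all(fr == 0)) "none" else names(which.max(fr))
  global_min <- match.arg(global_min, c("alpha", "beta", "three10", "none"))
  if (global_min != "none" && fr[global_min] == 0)
    stop("global-minimum motif ", dQuote(global_min, FALSE),
         " has zero planted fraction")
  structure(list(n = as.integer(n), fractions = fr, sigma = sigma,
                 global_min = global_min, spread = spread,
                 seed = as.integer(seed)),
            class = "plant_spec")
}

# triangle with prescribed side lengths d12, d13, d23, in the xy plane
.triangle <- function(d) {
  x3 <- (d[2]^2 + d[1]^2 - d[3]^2) / (2 * d[1])
  y3 <- sqrt(max(0, d[2]^2 - x3^2))
  rbind(c(0, 0, 0), c(d[1], 0, 0), c(x3, y3, 0))
}

# quadratic Bezier interpolation for chain filler atoms
.bezier_chain <- function(p0, p1, k, sag = 4) {
  mid <- (p0 + p1) / 2 + c(0, -sag, 0)
  t <- seq_len(k) / (k + 1)
  t(vapply(t, function(u) (1 - u)^2 * p0 + 2 * u * (1 - u) * mid + u^2 * p1,
           numeric(3)))
}

# acceptor position giving the requested H...A distance and D-H...A angle,
# for a donor at `d` with hydrogen at `h` (geometry laid out in-plane)
.acceptor_at <- function(h, d_ha, angle_deg, flip = 1) {
  ang <- angle_deg * pi / 180
  h + d_ha * c(-cos(ang), flip * sin(ang), 0)
}

# the synthetic anchor molecule: disjoint anchor groups, one per criterion
.synthetic_layout <- function() {
  list(
    helix = 1:3, three10 = 4:6, quartet = 7:10, dpair = 11:12,
    ob = 13L, bchain = 14:20, nb = 21L, hb = 22L,
    oa = 23L, gchain = 24:27, na_ = 28L, ha = 29L, ob2 = 30L,
    elements = c(rep("C", 3), rep("C", 3), "C", "C", "C", "N", "C", "C",
                 "O", rep("C", 7), "N", "H",
                 "O", rep("C", 4), "N", "H", "O"),
    bonds = data.frame(
      i = c(7, 8, 9, 13, 14, 15, 16, 17, 18, 19, 20, 21,
            23, 24, 25, 26, 27, 28, 30),
      j = c(8, 9, 10, 14, 15, 16, 17, 18, 19, 20, 21, 22,
            24, 25, 26, 27, 28, 29, 17),
      order = 1L))
}

# coordinates for one conformer given its planted labels
.plant_conformer <- function(lab, lay) {
  xyz <- matrix(0, 30, 3)
  scale_a <- if (lab["alpha"]) 1 else 1.6
  xyz[lay$helix, ] <- .triangle(scale_a * helix_reference_distances("alpha"))
  scale_t <- if (lab["three10"]) 1 else 1.6
  xyz[lay$three10, ] <- sweep(.triangle(scale_t * helix_reference_distances("three10")),
                              2, c(0, 30, 0), "+")
  # turn quartet: chain with a controlled central dihedral
  beta_tau <- if (lab["beta"]) 30 else 130
  q <- matrix(0, 4, 3)
  q[1, ] <- c(0, 0, 0); q[2, ] <- c(1.5, 0, 0)
  q[3, ] <- .place_atom(c(-1, 1, 0), q[1, ], q[2, ], 1.5, 112, 60)
  q[4, ] <- .place_atom(q[1, ], q[2, ], q[3, ], 1.5, 112, beta_tau)
  xyz[lay$quartet, ] <- sweep(q, 2, c(30, 0, 0), "+")
  dpd <- if (lab["beta"]) 5.5 else 9.5
  xyz[lay$dpair, ] <- rbind(c(30, 30, 0), c(30 + dpd, 30, 0))
  # NH_B assembly: C10 acceptor OB, gamma acceptor OB2
  nb <- c(60, 0, 0); hb <- nb + c(0.86, 0, 0)
  xyz[lay$nb, ] <- nb; xyz[lay$hb, ] <- hb
  xyz[lay$ob, ] <- .acceptor_at(hb, if (lab["beta"]) 1.965 else 4.5, 147.2)
  xyz[lay$bchain, ] <- .bezier_chain(xyz[lay$ob, ], nb, length(lay$bchain))
  xyz[lay$ob2, ] <- .acceptor_at(hb, if (lab["alpha"]) 2.0 else 4.5, 150,
                                 flip = -1)
  # NH_A assembly: gamma acceptor OA
  na_ <- c(60, 30, 0); ha <- na_ + c(0.86, 0, 0)
  xyz[lay$na_, ] <- na_; xyz[lay$ha, ] <- ha
  xyz[lay$oa, ] <- .acceptor_at(ha, if (lab["alpha"]) 2.0 else 4.5, 150)
  xyz[lay$gchain, ] <- .bezier_chain(xyz[lay$oa, ], na_, length(lay$gchain))
  xyz
}

#' Generate a planted conformer ensemble with ground truth
#'
#' Builds a synthetic anchor molecule whose criterion groups (helix
#' anchors, 3-10 anchors, turn quartet, d_alpha pair, two amide donors
#' with their pseudo-cycle chains) are geometrically independent, so any
#' combination of motif labels can be planted per conformer. Planted
#' groups sit exactly on their reference geometry (C10 hydrogen bond at
#' H...A 1.965 Angstrom, 147.2 degrees; gamma bonds at 2.0 Angstrom,
#' 150 degrees); unplanted groups are pushed well outside every
#' threshold. Isotropic Gaussian noise `sigma` is added afterwards.
#' Exactly `round(f * n)` conformers receive each motif label; the label
#' subsets are drawn independently, so overlaps occur. Energies: the
#' designated global-minimum conformer gets 0, the rest are uniform in
#' (0, spread].
#'
#' @param spec A [plant_spec()].
#' @return List with `ensemble`, `anchors` (the matching [anchor_set()])
#'   and `truth` (logical data frame `alpha`, `beta`, `three10`).
#' @export
gen_ensemble <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  lay <- .synthetic_layout()
  with_seed(spec$seed, {
    n <- spec$n
    truth <- data.frame(alpha = logical(n), beta = logical(n),
                        three10 = logical(n))
    for (m in names(spec$fractions)) {
      k <- round(spec$fractions[[m]] * n)
      truth[[m]][sample.int(n, k)] <- TRUE
    }
    gm <- spec$global_min
    cand <- if (gm == "none") which(!truth$alpha & !truth$beta & !truth$three10)
    else which(truth[[gm]])
    if (!length(cand))
      stop("no conformer carries the designated global-minimum motif")
    # prefer a conformer carrying only the designated motif
    pure <- cand[rowSums(truth[cand, , drop = FALSE]) <= 1]
    imin <- if (length(pure)) pure[1] else cand[1]
    energies <- stats::runif(n, min = 1e-6, max = spec$spread)
    energies[imin] <- 0
    xyz <- lapply(seq_len(n), function(i) {
      base <- .plant_conformer(unlist(truth[i, ]), lay)
      if (spec$sigma > 0)
        base <- base + matrix(stats::rnorm(length(base), sd = spec$sigma),
                              nrow(base), 3)
      base
    })
    mol <- molecule(data.frame(element = lay$elements,
                               x = xyz[[1]][, 1], y = xyz[[1]][, 2],
                               z = xyz[[1]][, 3]),
                    lay$bonds)
    anchors <- anchor_set(helix = lay$helix, turn_quartet = lay$quartet,
                          d_alpha_pair = lay$dpair, three10 = lay$three10,
                          nh_b_donor = c(lay$nb, lay$hb),
                          nh_b_acceptors = c(lay$ob, lay$ob2),
                          nh_a_donor = c(lay$na_, lay$ha),
                          nh_a_acceptors = lay$oa)
    list(ensemble = ensemble(mol, xyz, energies,
                             energy_method = "planted"),
         anchors = anchors, truth = truth)
  })
}

#' Generate a toy crystal with engineered hydrogen bonds
#'
#' A small P1 cell holding one molecule with an intramolecular N-H...O
#' contact at the requested D...A distance and D-H...A angle (N-H fixed
#' at 0.86 Angstrom, the riding-model convention), plus a second donor
#' whose acceptor sits one lattice translation away so that
#' [hbond_table()] reports one intermolecular contact with symmetry code
#' `x, y-1, z`.
#'
#' @param dda Intramolecular donor...acceptor distance (Angstrom).
#' @param angle Intramolecular D-H...A angle (degrees).
#' @param inter_dda,inter_angle Geometry of the engineered intermolecular
#'   contact.
#' @return A [crystal_structure()].
#' @export
gen_toy_crystal <- function(dda = 2.727, angle = 147.2,
                            inter_dda = 2.843, inter_angle = 166.1) {
  dh <- 0.86
  solve_ha <- function(d, theta) {
    ct <- cos(theta * pi / 180)
    disc <- dh^2 * ct^2 - dh^2 + d^2
    if (disc < 0) stop("infeasible hydrogen-bond geometry")
    ha <- dh * ct + sqrt(disc)
    if (ha < 1.2) stop("infeasible hydrogen-bond geometry: atoms would clash")
    ha
  }
  ha_intra <- solve_ha(dda, angle)
  ha_inter <- solve_ha(inter_dda, inter_angle)
  cell <- crystal_cell(14, 8, 12, z = 1, space_group = "P1")
  n3 <- c(3, 4, 6); h3 <- n3 + c(dh, 0, 0)
  o4 <- .acceptor_at(h3, ha_intra, angle)
  n4 <- c(8, 1.5, 6); h4 <- n4 + c(0, -dh, 0)
  dlt <- (180 - inter_angle) * pi / 180
  astar <- h4 + ha_inter * c(sin(dlt), -cos(dlt), 0)
  o3 <- astar + c(0, cell$b, 0)   # one lattice translation along b
  cart <- rbind(n3, h3, o4, n4, h4, o3)
  crystal_structure(cell, cart_to_frac(cart, cell),
                    elements = c("N", "H", "O", "N", "H", "O"),
                    labels = c("N3", "H3N", "O4", "N4", "H4N", "O3"))
}

#' Generate a synthetic Hirshfeld contact table
#'
#' @param elements Element symbols on the surface.
#' @param seed Integer seed.
#' @param mode `"random"` draws independent surface and contact
#'   compositions (both summing to 100 exactly); `"consistent"` sets the
#'   contacts equal to the random expectation of the drawn surface, so
#'   every unmasked enrichment ratio is 1.
#' @return A [contact_table()].
#' @export
gen_contact_table <- function(elements = c("H", "C", "N", "O"), seed = 1,
                              mode = c("random", "consistent")) {
  mode <- match.arg(mode)
  stopifnot(length(elements) >= 1)
  with_seed(seed, {
    s <- stats::runif(length(elements), 0.05, 1)
    s <- 100 * s / sum(s)
    names(s) <- elements
    rnd <- random_contacts(s)
    if (mode == "consistent") {
      ct <- data.frame(x = rnd$x, y = rnd$y, pct = rnd$r)
    } else {
      w <- stats::runif(nrow(rnd), 0.01, 1)
      ct <- data.frame(x = rnd$x, y = rnd$y, pct = 100 * w / sum(w))
    }
    contact_table(s, ct)
  })
}
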