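# Conformer classification: does a conformer project its anchor atoms
# like the side chains of an alpha-helix, a beta-turn, or a 3-10 helix?

#' Classification thresholds for secondary-structure mimicry
#'
#' Bundles every tunable threshold of the classifier. Defaults: ideal
#' helix anchor spacings with a +-1.0 Angstrom tolerance; beta-turn
#' condition d_alpha < 7 Angstrom and |turn dihedral| < 60 degrees;
#' hydrogen-bond acceptance at H...A <= 2.5 Angstrom, D...A <= 3.5
#' Angstrom, D-H...A >= 120 degrees (standard crystallographic practice);
#' 10 kcal/mol energy window. The C10 hydrogen bond is evaluated and
#' reported for every conformer but required for the beta flag only when
#' `require_c10 = TRUE`.
#'
#' @param helix_ref,helix_tol Alpha anchor reference distances (Angstrom)
#'   and tolerance.
#' @param three10_ref,three10_tol 3-10 anchor references and tolerance.
#' @param d_alpha_max Maximum anchor-pair distance for a turn (Angstrom).
#' @param beta_dihedral_max Maximum |C1-C2-C3-N4| dihedral (degrees).
#' @param hbond_d_ha_max,hbond_d_da_max,hbond_angle_min H-bond cutoffs.
#' @param require_c10 Require the C10 hydrogen bond for the beta flag.
#' @param energy_window Energy window above the minimum (kcal/mol).
#' @return Object of class `"motif_criteria"`.
#' @export
motif_criteria <- function(helix_ref = helix_reference_distances("alpha"),
                           helix_tol = 1.0,
                           three10_ref = helix_reference_distances("three10"),
                           three10_tol = 1.0,
                           d_alpha_max = 7.0,
                           beta_dihedral_max = 60,
                           hbond_d_ha_max = 2.5,
                           hbond_d_da_max = 3.5,
                           hbond_angle_min = 120,
                           require_c10 = FALSE,
                           energy_window = 10) {
  vals <- c(helix_ref, helix_tol, three10_ref, three10_tol, d_alpha_max,
            beta_dihedral_max, hbond_d_ha_max, hbond_d_da_max,
            hbond_angle_min, energy_window)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all thresholds must be positive and finite")
  if (helix_tol >= min(helix_ref) || three10_tol >= min(three10_ref))
    stop("tolerance must be smaller than the smallest reference distance")
  structure(list(helix_ref = helix_ref, helix_tol = helix_tol,
                 three10_ref = three10_ref, three10_tol = three10_tol,
                 d_alpha_max = d_alpha_max,
                 beta_dihedral_max = beta_dihedral_max,
                 hbond_d_ha_max = hbond_d_ha_max,
                 hbond_d_da_max = hbond_d_da_max,
                 hbond_angle_min = hbond_angle_min,
                 require_c10 = isTRUE(require_c10),
                 energy_window = energy_window),
            class = "motif_criteria")
}

#' Anchor-atom selection for the mimicry classifier
#'
#' Names the atoms (1-based indices into the molecule) each criterion
#' measures. Any component may be `NULL`; the corresponding classifier
#' then refuses to run. Hydrogen-bond donors are `c(heavy, H)` pairs.
#'
#' @param helix Indices of the three alpha anchors (i, i+4, i+7
#'   side-chain carbons).
#' @param turn_quartet Indices of the four atoms C1, C2, C3, N4 defining
#'   the turn dihedral.
#' @param d_alpha_pair Index pair for the turn distance d_alpha.
#' @param three10 Indices of the three 3-10 anchors (i, i+2, i+4).
#' @param nh_b_donor,nh_a_donor Length-2 vectors `c(heavy, H)` for the
#'   two amide donors.
#' @param nh_b_acceptors,nh_a_acceptors Candidate acceptor indices for
#'   each donor.
#' @return Object of class `"anchor_set"`.
#' @export
anchor_set <- function(helix = NULL, turn_quartet = NULL, d_alpha_pair = NULL,
                       three10 = NULL,
                       nh_b_donor = NULL, nh_b_acceptors = NULL,
                       nh_a_donor = NULL, nh_a_acceptors = NULL) {
  chk_len <- function(x, n, what) {
    if (!is.null(x) && length(x) != n)
      stop(what, " must have exactly ", n, " indices")
    if (!is.null(x)) as.integer(x) else NULL
  }
  helix <- chk_len(helix, 3, "helix anchors")
  turn_quartet <- chk_len(turn_quartet, 4, "turn quartet")
  if (!is.null(turn_quartet) && anyDuplicated(turn_quartet))
    stop("turn quartet indices must be distinct")
  structure(list(helix = helix,
                 turn_quartet = turn_quartet,
                 d_alpha_pair = chk_len(d_alpha_pair, 2, "d_alpha pair"),
                 three10 = chk_len(three10, 3, "3-10 anchors"),
                 nh_b_donor = chk_len(nh_b_donor, 2, "NH_B donor"),
                 nh_b_acceptors = if (is.null(nh_b_acceptors)) NULL else as.integer(nh_b_acceptors),
                 nh_a_donor = chk_len(nh_a_donor, 2, "NH_A donor"),
                 nh_a_acceptors = if (is.null(nh_a_acceptors)) NULL else as.integer(nh_a_acceptors)),
            class = "anchor_set")
}

.check_anchor_indices <- function(a, n) {
  idx <- unlist(a[!vapply(a, is.null, logical(1))])
  if (length(idx) && (any(idx < 1) || any(idx > n)))
    stop("anchor index out of range for this molecule (n = ", n, ")")
}

#' Retain conformers within an energy window of the minimum
#'
#' @param e An [ensemble()] in which every conformer carries an energy.
#' @param window Window above the minimum energy, kcal/mol (boundary
#'   inclusive); the minimum itself is always retained.
#' @return The filtered [ensemble()].
#' @export
filter_energy_window <- function(e, window = 10) {
  stopifnot(inherits(e, "fm_ensemble"))
  if (anyNA(e$energies)) stop("every conformer needs an energy to filter")
  keep <- e$energies - min(e$energies) <= window
  ensemble(e$molecule, e$xyz[keep], e$energies[keep], e$ids[keep],
           e$energy_method)
}

.pair_dist <- function(xyz, i, j) vnorm(xyz[i, ] - xyz[j, ])

#' Alpha-helix mimicry test for one conformer
#'
#' True when all three anchor distances (i/i+4, i/i+7, i+4/i+7) lie
#' within the tolerance of the ideal references.
#'
#' @param xyz n x 3 conformer coordinates (or a [molecule()]).
#' @param anchors An [anchor_set()] with `helix` set.
#' @param criteria A [motif_criteria()].
#' @return List with `flag` and the three measured `distances`.
#' @export
classify_alpha <- function(xyz, anchors, criteria = motif_criteria()) {
  if (inherits(xyz, "fm_molecule")) xyz <- coords(xyz)
  if (is.null(anchors$helix)) stop("helix anchors are not set")
  .check_anchor_indices(anchors["helix"], nrow(xyz))
  h <- anchors$helix
  d <- c(.pair_dist(xyz, h[1], h[2]), .pair_dist(xyz, h[1], h[3]),
         .pair_dist(xyz, h[2], h[3]))
  names(d) <- names(criteria$helix_ref)
  list(flag = all(abs(d - criteria$helix_ref) <= criteria$helix_tol),
       distances = d)
}

#' 3-10-helix mimicry test for one conformer
#'
#' True when the three i/i+2/i+4 anchor distances match the frozen 3-10
#' template references within the tolerance.
#'
#' @inheritParams classify_alpha
#' @return List with `flag` and measured `distances`.
#' @export
classify_310 <- function(xyz, anchors, criteria = motif_criteria()) {
  if (inherits(xyz, "fm_molecule")) xyz <- coords(xyz)
  if (is.null(anchors$three10)) stop("3-10 anchors are not set")
  .check_anchor_indices(anchors["three10"], nrow(xyz))
  h <- anchors$three10
  d <- c(.pair_dist(xyz, h[1], h[2]), .pair_dist(xyz, h[1], h[3]),
         .pair_dist(xyz, h[2], h[3]))
  names(d) <- names(criteria$three10_ref)
  list(flag = all(abs(d - criteria$three10_ref) <= criteria$three10_tol),
       distances = d)
}

# all acceptor candidates satisfying the cutoffs, best (smallest H...A)
# first, each with its pseudo-cycle size
.hbond_candidates <- function(mol, xyz, donor, acceptors, criteria) {
  if (is.null(donor) || is.null(acceptors)) return(list())
  if (mol$atoms$element[donor[2]] != "H")
    stop("hydrogen-bond donor H index is not a hydrogen")
  cands <- list()
  for (a in acceptors) {
    g <- hbond_geometry(xyz[donor[1], ], xyz[donor[2], ], xyz[a, ])
    ok <- g$d_ha <= criteria$hbond_d_ha_max &&
      g$d_da <= criteria$hbond_d_da_max &&
      g$angle_dha >= criteria$hbond_angle_min
    if (!ok) next
    ring <- tryCatch(hbond_ring_size(mol, donor[2], a),
                     error = function(e) NA_integer_)
    cands[[length(cands) + 1]] <- list(acceptor = a, geometry = g,
                                       ring_size = ring)
  }
  if (length(cands) > 1)
    cands <- cands[order(vapply(cands, function(x) x$geometry$d_ha, numeric(1)))]
  cands
}

# first candidate with the requested pseudo-cycle size (any size if NULL)
.pick_pattern <- function(cands, ring = NULL) {
  for (cd in cands)
    if (is.null(ring) || identical(cd$ring_size, as.integer(ring)))
      return(list(present = TRUE, geometry = cd$geometry,
                  acceptor = cd$acceptor, ring_size = cd$ring_size))
  list(present = FALSE, geometry = NULL, acceptor = NA_integer_,
       ring_size = NA_integer_)
}

.eval_hbond <- function(mol, xyz, donor, acceptors, criteria, ring = NULL) {
  m2 <- mol; m2$atoms[, c("x", "y", "z")] <- xyz
  .pick_pattern(.hbond_candidates(m2, xyz, donor, acceptors, criteria), ring)
}

#' Intramolecular hydrogen-bond patterns of one conformer
#'
#' Evaluates the two diagnostic patterns: the C10 bond donated by NH_B
#' (a 10-membered pseudo-cycle, the beta-turn signature) and the pair of
#' gamma-turn bonds donated by NH_A and NH_B (7-membered cycles, the
#' helix signature). A bond is accepted when H...A and D...A are within
#' their cutoffs and the D-H...A angle is at least the minimum.
#'
#' @param mol A [molecule()] with explicit hydrogens and bonds.
#' @param xyz Conformer coordinates (defaults to the molecule's own).
#' @param anchors An [anchor_set()] with the donor/acceptor components.
#' @param criteria A [motif_criteria()].
#' @return List with components `c10` (the 10-ring bond via NH_B:
#'   presence, geometry, acceptor, ring size) and `gamma` (the 7-ring
#'   records for each donor plus the joint flag `pair_present`).
#' @export
detect_hbond_patterns <- function(mol, anchors, criteria = motif_criteria(),
                                  xyz = coords(mol)) {
  stopifnot(inherits(mol, "fm_molecule"))
  .check_anchor_indices(anchors[c("nh_b_donor", "nh_b_acceptors",
                                  "nh_a_donor", "nh_a_acceptors")],
                        nrow(mol$atoms))
  m2 <- mol; m2$atoms[, c("x", "y", "z")] <- xyz
  cb <- .hbond_candidates(m2, xyz, anchors$nh_b_donor, anchors$nh_b_acceptors,
                          criteria)
  ca <- .hbond_candidates(m2, xyz, anchors$nh_a_donor, anchors$nh_a_acceptors,
                          criteria)
  ga <- .pick_pattern(ca, 7L)
  gb <- .pick_pattern(cb, 7L)
  list(c10 = .pick_pattern(cb, 10L),
       gamma = list(nh_a = ga, nh_b = gb,
                    pair_present = ga$present && gb$present))
}

#' Beta-turn mimicry test for one conformer
#'
#' True when d_alpha < 7 Angstrom and the absolute turn dihedral
#' |C1-C2-C3-N4| < 60 degrees. The C10 hydrogen bond is evaluated and
#' reported whenever the donor anchors are available, and additionally
#' required when `criteria$require_c10` is set.
#'
#' @inheritParams classify_alpha
#' @param mol The parent [molecule()] (needed only for the C10 ring-size
#'   evaluation; may be `NULL` to skip hydrogen-bond reporting).
#' @return List with `flag`, `d_alpha`, `beta_dihedral` and `c10`.
#' @export
classify_beta <- function(xyz, anchors, criteria = motif_criteria(),
                          mol = NULL) {
  if (inherits(xyz, "fm_molecule")) { mol <- xyz; xyz <- coords(xyz) }
  if (is.null(anchors$turn_quartet) || is.null(anchors$d_alpha_pair))
    stop("turn quartet and d_alpha pair anchors are not set")
  .check_anchor_indices(anchors[c("turn_quartet", "d_alpha_pair")], nrow(xyz))
  q <- anchors$turn_quartet
  beta <- dihedral_angle(xyz[q[1], ], xyz[q[2], ], xyz[q[3], ], xyz[q[4], ])
  da <- .pair_dist(xyz, anchors$d_alpha_pair[1], anchors$d_alpha_pair[2])
  c10 <- if (!is.null(mol) && !is.null(anchors$nh_b_donor))
    .eval_hbond(mol, xyz, anchors$nh_b_donor, anchors$nh_b_acceptors, criteria,
                ring = 10L)
  else list(present = NA, geometry = NULL, ring_size = NA_integer_)
  flag <- da < criteria$d_alpha_max && abs(beta) < criteria$beta_dihedral_max
  if (criteria$require_c10) flag <- flag && isTRUE(c10$present)
  list(flag = flag, d_alpha = da, beta_dihedral = beta, c10 = c10)
}

#' Classify a conformer ensemble for secondary-structure mimicry
#'
#' The main analysis entry point. Filters the ensemble to the energy
#' window (when energies are present), applies the alpha-helix, beta-turn
#' and 3-10-helix criteria to every retained conformer and evaluates the
#' diagnostic hydrogen-bond patterns. The three flags are not mutually
#' exclusive, so the summary percentages need not sum to 100.
#'
#' @param e An [ensemble()].
#' @param anchors An [anchor_set()]; classifiers whose anchors are absent
#'   are skipped (reported as `NA`).
#' @param criteria A [motif_criteria()].
#' @param filter Apply [filter_energy_window()] first (requires
#'   energies). Default `TRUE` when all energies are present.
#' @param compound Compound identifier carried into the summary.
#' @return Object of class `"mimicry"`: the per-conformer label table
#'   (`$labels`), the filtered ensemble, anchors and criteria. Use
#'   [summary.mimicry()] for the ensemble-level percentages.
#' @examples
#' gen <- gen_ensemble(plant_spec(n = 20, fractions = c(alpha = 0.5, beta = 0.5),
#'                                sigma = 0, seed = 1))
#' fit <- mimicry(gen$ensemble, gen$anchors)
#' summary(fit)
#' @export
mimicry <- function(e, anchors, criteria = motif_criteria(),
                    filter = !anyNA(e$energies), compound = "compound") {
  stopifnot(inherits(e, "fm_ensemble"), inherits(anchors, "anchor_set"),
            inherits(criteria, "motif_criteria"))
  if (filter) e <- filter_energy_window(e, criteria$energy_window)
  if (length(e$xyz) == 0) stop("empty ensemble")
  n <- length(e$xyz)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    xyz <- e$xyz[[i]]
    al <- if (!is.null(anchors$helix))
      classify_alpha(xyz, anchors, criteria) else NULL
    be <- if (!is.null(anchors$turn_quartet) && !is.null(anchors$d_alpha_pair))
      classify_beta(xyz, anchors, criteria, mol = e$molecule) else NULL
    th <- if (!is.null(anchors$three10))
      classify_310(xyz, anchors, criteria) else NULL
    hb <- if (!is.null(anchors$nh_b_donor) || !is.null(anchors$nh_a_donor))
      detect_hbond_patterns(e$molecule, anchors, criteria, xyz) else NULL
    rows[[i]] <- data.frame(
      id = e$ids[i], energy = e$energies[i],
      is_alpha = if (is.null(al)) NA else al$flag,
      is_beta = if (is.null(be)) NA else be$flag,
      is_310 = if (is.null(th)) NA else th$flag,
      d_i_ip4 = if (is.null(al)) NA_real_ else al$distances[1],
      d_i_ip7 = if (is.null(al)) NA_real_ else al$distances[2],
      d_ip4_ip7 = if (is.null(al)) NA_real_ else al$distances[3],
      d_alpha = if (is.null(be)) NA_real_ else be$d_alpha,
      beta_dihedral = if (is.null(be)) NA_real_ else be$beta_dihedral,
      c10_present = if (is.null(be) || is.na(be$c10$present[1])) NA else be$c10$present,
      c10_ring = if (is.null(be)) NA_integer_ else be$c10$ring_size,
      gamma_pair = if (is.null(hb)) NA else hb$gamma$pair_present)
  }
  labels <- do.call(rbind, rows)
  rownames(labels) <- NULL
  structure(list(labels = labels, ensemble = e, anchors = anchors,
                 criteria = criteria, compound = compound),
            class = "mimicry")
}

#' @export
print.mimicry <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("<mimicry> %s: %d conformers in window\n", x$compound, s$n))
  cat(sprintf("  beta-turn %d%%  alpha-helix %d%%  3-10-helix %d%%  global minimum: %s\n",
              s$pct_beta, s$pct_alpha, s$pct_310, s$global_min))
  invisible(x)
}

#' Ensemble-level mimicry summary
#'
#' Percentages of conformers carrying each motif flag (rounded half-up to
#' integers, as conventionally reported) and the motif of the
#' lowest-energy conformer. The global-minimum label is `"n.d."` when the
#' minimum carries no flag or when conformers tie for the minimum (within
#' 1e-6 kcal/mol) with conflicting labels; when one conformer carries
#' several flags the label follows the precedence beta-turn, alpha-helix,
#' 3-10-helix.
#'
#' @param object A [mimicry()] result.
#' @param ... Unused.
#' @return Object of class `"mimicry_summary"`: `compound`, `n`,
#'   `pct_beta`, `pct_alpha`, `pct_310` (integers), the unrounded
#'   `raw_pct`, and `global_min`.
#' @export
summary.mimicry <- function(object, ...) {
  lb <- object$labels
  n <- nrow(lb)
  pct <- function(f) 100 * sum(f, na.rm = TRUE) / n
  raw <- c(beta = pct(lb$is_beta), alpha = pct(lb$is_alpha),
           three10 = pct(lb$is_310))
  conf_label <- function(row) {
    if (isTRUE(row$is_beta)) return("beta-turn")
    if (isTRUE(row$is_alpha)) return("alpha-helix")
    if (isTRUE(row$is_310)) return("3-10-helix")
    "n.d."
  }
  gm <- "n.d."
  if (!anyNA(lb$energy)) {
    emin <- min(lb$energy)
    tied <- which(lb$energy - emin < 1e-6)
    labs <- unique(vapply(tied, function(i) conf_label(lb[i, ]), character(1)))
    gm <- if (length(labs) == 1) labs else "n.d."
  }
  structure(list(compound = object$compound, n = n,
                 pct_beta = round_half_up(raw["beta"]),
                 pct_alpha = round_half_up(raw["alpha"]),
                 pct_310 = round_half_up(raw["three10"]),
                 raw_pct = raw, global_min = gm),
            class = "mimicry_summary")
}

#' @export
print.mimicry_summary <- function(x, ...) {
  cat(sprintf("%s: n = %d | beta-turn %d%% | alpha-helix %d%% | 3-10-helix %d%% | global min: %s\n",
              x$compound, x$n, x$pct_beta, x$pct_alpha, x$pct_310, x$global_min))
  invisible(x)
}

#' @export
as.data.frame.mimicry_summary <- function(x, ...) {
  data.frame(compound = x$compound, n = x$n,
             pct_beta = as.integer(x$pct_beta),
             pct_alpha = as.integer(x$pct_alpha),
             pct_310 = as.integer(x$pct_310),
             global_min = x$global_min)
}

#' Plot a mimicry classification
#'
#' Left: motif percentages. Right: the beta-turn plane (d_alpha against
#' the absolute turn dihedral) with the acceptance box.
#'
#' @param x A [mimicry()] result.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.mimicry <- function(x, ...) {
  s <- summary(x)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::barplot(c(`beta-turn` = s$pct_beta, `alpha-helix` = s$pct_alpha,
                      `3-10` = s$pct_310),
                    ylab = "% of conformers in window", ylim = c(0, 100), ...)
  lb <- x$labels
  if (!all(is.na(lb$d_alpha))) {
    graphics::plot(abs(lb$beta_dihedral), lb$d_alpha,
                   xlab = "|turn dihedral| (deg)", ylab = "d_alpha (A)",
                   pch = ifelse(isTRUE(lb$is_beta) | lb$is_beta %in% TRUE, 19, 1))
    graphics::abline(h = x$criteria$d_alpha_max, lty = 2)
    graphics::abline(v = x$criteria$beta_dihedral_max, lty = 2)
  }
  invisible(x)
}
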