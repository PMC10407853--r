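---
title: "Secondary-structure mimicry analysis: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Secondary-structure mimicry analysis: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldmimic)
```

## The problem

Flexible small scaffolds — here the motivating case is a hydantoin
(imidazolidine-2,4-dione) bearing three substituents — can act as
*universal peptidomimetics*: by rotating a few bonds they project their
substituents the way protein side chains are projected by an α-helix, a
β-turn or a 3~10~-helix. Deciding which secondary structure a given
conformer mimics is a purely geometric question, asked of every member
of a conformer ensemble produced by an upstream conformational search.
`foldmimic` implements that decision, the ensemble bookkeeping around
it, RMSD fitting against ideal turn templates, and the crystallographic
and Hirshfeld-surface arithmetic used to characterize the solid state
of such compounds. Conformer generation itself (force-field or DFT) is
out of scope; the package consumes ensembles (SDF/XYZ/PDB) or generates
synthetic ones with planted ground truth.

## The classification model

A conformer is tested independently against three motifs. All
thresholds live in `motif_criteria()` and every atom selection in
`anchor_set()`; nothing is inferred from connectivity, because which
atoms play the role of the *i*, *i*+4, *i*+7 side chains is a chemical
judgement that differs per compound and must be stated explicitly.

**α-helix.** Three anchor atoms are compared with the side-chain
spacing of an ideal helix: d(i, i+4) = 6.2 Å, d(i, i+7) = 10.3 Å,
d(i+4, i+7) = 5.8 Å. The conformer passes when all three measured
distances fall within a tolerance (default ±1.0 Å) of the references.
The references are the standard design distances for i/i+4/i+7
projection; the tolerance is our choice — published ensemble
percentages computed this way depend on both the search engine and the
(usually unstated) tolerance, so they are engine-dependent quantities,
not constants of nature. Tightening the tolerance can only shrink the
α percentage; this monotonicity is asserted in the test suite.

**β-turn.** Two conditions: the anchor-pair distance d~α~ < 7 Å, and
the absolute central dihedral |C1–C2–C3–N4| < 60°. The absolute value
matters — a −75° dihedral fails even though its magnitude-75 mirror
image would also fail; only the band (−60°, 60°) passes. The signature
intramolecular hydrogen bond closing a 10-membered pseudo-cycle (C10)
is always evaluated and reported alongside, but by default it is *not*
required for the flag, because the distance/dihedral pair is the stated
condition and the H-bond is diagnostic. `motif_criteria(require_c10 =
TRUE)` switches to the strict reading.

**3~10~-helix.** Same construction as the α test with i/i+2/i+4
anchors. No reference distances for this motif are in common
circulation, so they are measured once on the package's own ideal
3~10~ template (Cβ markers of residues 1, 3, 5) and frozen as
documented constants: 6.502, 9.486, 6.502 Å. A test asserts the frozen
values still agree with the template that defines them.

**Hydrogen-bond patterns.** A donor–H···acceptor contact is accepted
when H···A ≤ 2.5 Å, D···A ≤ 3.5 Å and the D–H···A angle ≥ 120°
(standard crystallographic practice; all configurable). The size of
the pseudo-cycle closed by the contact is computed as the number of
atoms on the shortest covalent path from acceptor to donor hydrogen,
inclusive — 10 for the classical β-turn C10 ring, 7 for a γ-turn.
We deliberately count the hydrogen, so "10-membered ring" lands exactly
on the classical C10 nomenclature. A contact only counts as the C10
pattern when its cycle has exactly 10 atoms, and as a γ-turn bond when
it has exactly 7; the α-helix-like pattern is the *pair* of γ bonds
donated by both amide NH groups. Shortest paths use breadth-first
search; path length is unique even when the path itself is not, so the
result does not depend on bond-list order.

**Energy window and summary.** Conformers above 10 kcal/mol (default)
over the ensemble minimum are discarded first, boundary inclusive, the
minimum always retained. Percentages are counts of flags over the
retained conformers, rounded half-up to integers as conventionally
reported; the three flags are not mutually exclusive, so percentages
need not sum to 100. The global-minimum label is the motif of the
lowest-energy conformer; when conformers tie (ΔE < 10⁻⁶ kcal/mol) with
conflicting labels, or the minimum carries no flag, the label is
"n.d.". When a single conformer carries several flags the label follows
a fixed precedence (β-turn, α-helix, 3~10~) — a tie-break we chose for
determinism and report openly rather than hide.

## Ideal templates and turn fitting

Templates are built by sequential internal-coordinate (NeRF) placement
with fixed backbone geometry: bond lengths N–Cα 1.458, Cα–C 1.525,
C–N 1.329 Å; angles N–Cα–C 111°, Cα–C–N 116°, C–N–Cα 121°; carbonyl
O trans to the following N; a Cβ marker at the tetrahedral position of
each Cα. Rebuilt chains reproduce requested dihedrals within 0.5°
(tested on random chains).

The four β-turn types use the classical central dihedrals
(φ₂, ψ₂, φ₃, ψ₃): I (−60, −30, −90, 0); II (−60, 120, 80, 0); the
primed types are exact sign inversions. Terminal residues are extended
(φ = ψ = 180°) and ω is 180° throughout. The backbone of I′ is the
exact mirror image of I — verified to rmsd < 10⁻⁶ — while the
full-atom templates are not mirror pairs, because the Cβ markers keep
one chirality (as they do in real peptides, where a type I′ turn is
still built from L-residues).

Helix templates: 3~10~ at (φ, ψ) = (−49, −26). For the α template the
textbook dihedral range spans roughly (−57, −47) to (−62, −41); within
that range we fixed (−60, −47), the value at which the template's Cβ
i/i+4/i+7 spacing reproduces the standard design references
(6.20, 10.61, 5.85 Å measured against 6.2, 10.3, 5.8) — the template
and the classifier's reference distances must describe the same ideal
helix or the self-consistency checks in the test suite would be
meaningless. The helix rise per residue (1.54 Å by axis fit) is within
3% of the canonical 1.5 Å.

`fit_turn_types()` superposes user-mapped conformer atoms onto the
backbone of each turn type with the Kabsch algorithm. The SVD sign
correction excludes reflections, so a left-handed fold is never
silently mirrored onto a right-handed template — the primed templates
exist precisely to probe the opposite chirality explicitly. Which
conformer atoms correspond to which backbone atoms is configuration,
not inference: for a non-peptide scaffold there is no canonical answer,
so the mapping is supplied per compound. The implementation is
cross-checked in the tests against an independent quaternion
(Horn eigenvalue) oracle to 10⁻⁸.

## Chemical and crystallographic arithmetic

Formula parsing accepts Hill-notation strings over a fixed light-element
table. Average masses use IUPAC 2021 standard atomic weights;
monoisotopic masses use the principal (most abundant) isotope. Printed
M~r~ values in older literature reflect earlier weight tables; sums can
differ by a few 0.01 u, which is why average-mass comparisons in the
tests carry a ±0.05 u band while count-based quantities (electrons,
F(000)) are exact. F(000) is the neutral-atom electron count per cell,
Z · Σ(count × Z~atom~), with no dispersion correction — that convention
reproduces printed integers exactly. Cell volume uses the general
triclinic closed form (checked against an explicit lattice-vector
triple product to 10⁻¹⁰ on 1000 random cells); density is
ρ = Z · M~r~ · 1.66054 / V. Rounding for comparison with printed values
is half-up at the printed number of decimals, the journal convention,
implemented once as an internal helper rather than `round()`'s
banker's rounding.

## Hirshfeld-surface statistics

The Hirshfeld surface itself is produced by upstream tools; this
package takes its *composition* as input. For a surface composition
S~X~ (percent of surface nearest to element X), random contacts are
R~XX~ = S~X~²/100 and R~XY~ = 2 S~X~ S~Y~/100 with reciprocal contacts
merged; enrichment is E~XY~ = C~XY~/R~XY~, reported half-up to one
decimal, and masked when R~XY~ < 0.9 % — the ratio of two sub-percent
quantities carries no information. Globularity is
G = (36π)^{1/3} V^{2/3} / A (1 for a sphere); the normalized contact
distance is d~norm~ = (d~i~ − r~i~)/r~i~ + (d~e~ − r~e~)/r~e~ with
Bondi van der Waals radii (H 1.20, C 1.70, N 1.55, O 1.52, Cl 1.75 Å,
the convention of the common Hirshfeld tools). Fingerprint histograms
use half-open 0.01 Å bins over [0.4, 3.0] Å by default, extending the
grid when points fall outside so the count is always conserved.

The crystal hydrogen-bond table enumerates D–H···A contacts between
the asymmetric unit and its symmetry- plus lattice-translated images
(shell ±1 by default); a contact generated by the identity operator
with zero translation is intramolecular. Symmetry operators are parsed
from, and composed back into, the conventional "x, y−1, z" notation so
records can be read against published packing descriptions.

## The synthetic generator

`gen_ensemble()` exists so every stage is testable offline with known
ground truth. It builds an artificial molecule whose criterion groups —
helix anchor triple, 3~10~ triple, turn quartet, d~α~ pair, and two
amide donors each with a covalent chain closing the 10- and 7-membered
pseudo-cycles — are geometrically independent, so *any* combination of
motif labels can be planted per conformer (published ensembles show
exactly such overlaps, e.g. 44/54/35 percentages summing past 100).
Planted groups sit exactly on their reference geometry (the C10 bond at
H···A 1.965 Å, 147.2°, mirroring a published crystal contact);
unplanted groups are pushed ~60 % past every threshold. Isotropic
Gaussian noise (default σ = 0.05 Å) is added afterwards; label subsets
have exactly round(f·n) members; energies put the designated motif at
0 kcal/mol and the rest uniform in (0, 9], inside the default
10 kcal/mol window. Generators are pure functions of (spec, seed) and
restore the global RNG state.

What this does *not* emulate: real torsional correlation between
criterion groups (in a real molecule the same atoms serve several
criteria), force-field energy–geometry coupling, anisotropic
vibrations, and conformer clustering. Passing the recovery tests
therefore shows the classifier applies its definitions correctly and
degrades gracefully with coordinate noise — it does not validate any
claim about real ensembles, whose percentages depend on the upstream
search.

`gen_toy_crystal()` inverts the hydrogen-bond geometry problem: given a
target D···A distance and D–H···A angle (N–H fixed at 0.86 Å, the
X-ray riding-model convention), it solves the triangle for H···A,
refuses geometrically impossible or clashing requests (H···A < 1.2 Å),
and places a second donor/acceptor pair across a lattice translation so
the hydrogen-bond table shows exactly one intramolecular and one
intermolecular contact with symmetry code "x, y−1, z".

## Numerical choices and degenerate inputs

- Torsions follow the IUPAC sign convention (clockwise positive viewed
  along the bond), range (−180°, 180°], validated against an
  independent implementation; collinear segments are an error, not 0.
- Least-squares planes come from the smallest principal component;
  collinear point sets are rejected.
- Kabsch superposition requires ≥ 3 non-collinear pairs and never
  reflects (det = +1 enforced).
- Energy-window filtering is boundary-inclusive and always retains the
  minimum, so a filtered ensemble is never empty.
- Distance-based bond perception (for XYZ/PDB/CIF input) uses covalent
  radii + 0.4 Å, needed only where a format carries no bond block.
- Problem sizes in the test suite (ensembles of 100–200 conformers,
  10 seeds for noisy recovery, 50 replicates for the turn-ranking
  check, 1000 random cells for the volume oracle) were chosen so the
  whole suite completes in well under a minute while keeping the
  Monte-Carlo checks far from their decision boundaries.

## Known limitations

- Anchor selection is explicit configuration; there is no substructure
  matching to find the i/i+4/i+7 carbons automatically.
- The CIF reader is minimal (cell, symmetry loop, atom_site loop); no
  disorder, anisotropic displacement or multi-block support.
- Elemental coverage is the light-element table in `atomic_data()`.
- Hirshfeld surfaces are consumed, never generated; asphericity and
  curvature maps are out of scope.
- Published ensemble percentages and DFT-geometry RMSD tables are
  reproducible only given the original engines' geometries; this
  package reproduces the *definitions*, verified on planted data.
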