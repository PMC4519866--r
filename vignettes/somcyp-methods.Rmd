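---
title: "Mechanism-based prediction of CYP3A4 sites of metabolism: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanism-based prediction of CYP3A4 sites of metabolism: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somcyp)
```

## The problem and the model

Cytochrome P450 3A4 is the dominant human hepatic drug-metabolizing enzyme.
Its active cavity is large and promiscuous, so a substrate — especially a
rigid steroid — can bind in many orientations, and predicting *which* carbon
is oxidized (the site of metabolism, SoM) is hard from either the ligand or
the protein side alone.

`somcyp` implements a mechanism-based model that mirrors the two stages of
the catalytic event:

1. **Binding accessibility.** Oxidation happens at the heme; a carbon can
   only react if docked poses place it near the heme iron.  Candidate sites
   are screened by the iron–carbon distance over an ordered ensemble of
   docked poses, and by the key interaction features that anchor productive
   binding modes: hydrogen bonds to Arg105, Arg106, Ser119, Ile301, Glu308
   or to the ordered active-site waters (619, 623, 637), and lipophilic
   contacts with the phenylalanine cluster (Phe57/108/219/220/241/304) that
   roofs the cavity or with the heme itself.
2. **Chemical reactivity.** Both reaction classes in scope — aliphatic
   hydroxylation and N-dealkylation — are initiated by hydrogen abstraction,
   whose barrier correlates with the homolytic reaction energy

   $$\Delta H_\mathrm{rxn} = \Delta H_2 - \Delta H_1,$$

   the energy difference between the substrate radical (plus a free hydrogen
   atom) and the parent substrate.  Qualified sites are ranked by
   $\Delta H_\mathrm{rxn}$, most labile hydrogen first, and the top three
   ranks constitute the prediction.

A substrate prediction is scored correct when any experimentally observed
site appears among the top three ranks (one hit suffices for
multi-metabolite substrates).  `aggregate_verdicts()` reproduces that
protocol's accuracy tables from per-substrate verdicts.

## Candidate sites and hydrogen classes

Candidates for aliphatic hydroxylation are sp3 carbons (all incident bonds
single) carrying at least one explicit hydrogen; candidates for
N-dealkylation are hydrogen-bearing, non-aromatic carbons alpha to a
nitrogen.  Aromatic hydroxylation, O-dealkylation and heteroatom oxidation
are out of scope.  Both reaction types are ranked jointly: the enzyme
chemistry selects a hydrogen, not a reaction label.

Hydrogens on the same carbon yield the same radical, so the unit of
reactivity is the *per-carbon hydrogen class*
(`hydrogen_equivalence_classes()`).  A class's energy is the minimum over
its member hydrogens: the most labile accessible hydrogen governs the
abstraction.  Morgan-style neighbourhood refinement additionally labels
topologically equivalent carbons; the labels are used only to skip duplicate
energy evaluations (`elide_symmetry = TRUE`) or for reporting, never to
merge classes — with frozen 3D geometries, topologically equivalent carbons
are not guaranteed to be geometrically equivalent.

Explicit hydrogens are **required** in all inputs.  The energies depend on
individual hydrogen atoms, and a silent protonation engine would hide that
modelling choice; a carbon whose bond orders cannot account for its valence
is a contract error at parse time.

## Pose qualification

For each of the kept poses (default: the top 10, assuming a score-sorted
pose file) a candidate qualifies in that pose when

* its iron–carbon distance lies in the closed window **[2.5, 7.5] Å** — the
  wide upper cutoff (chosen over 6.5 and 7.0 Å alternatives) reflects the
  unusually large CYP3A4 cavity and ligand-induced flexibility; and
* the pose shows at least one key feature (any qualifying hydrogen bond or
  lipophilic contact, anywhere on the ligand).  Feature attribution is
  pose-level, not atom-level, because the features describe whole-pose
  anchoring.  Set `require_feature = FALSE` to screen on distance alone.

A site qualifies overall when at least one pose qualifies it.  Carbons one
bond from a qualified site are then admitted too (`expand_adjacent_sites()`),
flagged `adjacency_derived` and inheriting the parent's accessibility score;
expansion runs exactly one round from directly qualified seeds, which makes
it idempotent.  Every candidate inside the window is treated as a preferred
site (not only the closest per pose): the inclusive reading is monotone in
the window and auditable from the per-site flags.

Accessibility is summarised as the *pose fraction*
(`qualifying_pose_fraction()`): the weight-sum of in-window poses with
weights normalised over the kept set.  The default weighting is uniform —
the reproducible choice when the provenance of pose scores is unknown — and
a linear-rank scheme ($w_i \propto n+1-i$) is available by configuration.

Geometric criteria (the literature gives standard values; none are fitted
here):

| parameter | default | meaning |
|---|---|---|
| H-bond donor–acceptor distance | ≤ 3.5 Å | ligand N/O vs residue polar atom |
| H-bond donor angle | ≥ 120° | donor–H…acceptor, when ligand donates |
| water contacts | ≤ 3.5 Å, distance only | crystallographic waters carry no H |
| lipophilic C…C contact | ≤ 4.5 Å | ligand carbon vs Phe ring carbon / heme heavy atom |
| lipophilic contact count | ≥ 3 pairs | pooled over the Phe-cluster (or heme) |

Protein hydrogens are absent from crystal structures, so the protein-donor
direction is evaluated by distance alone for atoms that can donate (Arg
NE/NH1/NH2, Ser OG, backbone N); pure acceptors (Glu OE1/OE2, backbone O)
require the ligand-donor angle test.  For "hydrophobic toward the heme" the
ligand atom set is restricted to the candidate carbons themselves.

## The CNDO/2 reactivity engine

Reaction energies come from a self-contained CNDO/2 semi-empirical SCF over
valence Slater orbitals (H: 1s with ζ = 1.2; C, N, O, F: 2s2p with Slater
exponents 1.625/1.950/2.275/2.600; S, Cl in an sp-only third-row extension).
Orbital electronegativities −½(I+A), bonding parameters β°, and the
conventions β_AB = ½(β°_A+β°_B)S_μν and point-charge core repulsion
Z_A Z_B/R_AB follow the canonical CNDO/2 parameterization
(`cndo_parameters()`; every entry is overridable).

Numerical choices:

* **Overlaps** are analytic, via prolate-spheroidal A/B auxiliary functions
  with generic polynomial bookkeeping, valid for any (n ≤ 3, l ≤ 1) pair and
  unequal exponents.  Tests pin them to the equal-exponent 1s closed form
  and to a high-order numerical quadrature oracle.
* **Two-centre Coulomb integrals** γ_AB are computed from the s-orbital
  densities' closed-form electrostatic potentials (regularized incomplete
  gamma functions) integrated with 120-point Gauss–Legendre quadrature;
  agreement with the 1s/1s closed forms is ≈1e-10 hartree.
* **SCF controls:** linear density damping 0.4, convergence at
  max|ΔP| ≤ 1e-6, 200-iteration cap, initial guess a diagonal neutral-atom
  density.  The energy functional is stationary at the SCF solution, so a
  1e-6 density error leaves energies reproducible well below 1e-8 hartree;
  non-convergence is a hard error carrying the iteration trace, never a
  silent result.
* **Open shells** (the radicals) use spin-unrestricted SCF for doublets with
  no spin-projection; parents are closed-shell.
* **Determinism:** identical inputs give identical outputs; eigenvector sign
  ambiguity cannot affect densities (P = CC').

The radical is the parent geometry minus the abstracted hydrogen, evaluated
as a single point: no geometry relaxation is applied to either species, and
gradients are deliberately out of scope.  Relaxation would lower all radical
energies by roughly similar amounts within one substrate; rankings compare
classes within a single parent geometry, which is the quantity the model
consumes.  Likewise the engine reports total-energy differences rather than
heats of formation — the two differ by atomic constants, so within-molecule
rankings are unchanged, and E(H·) is itself an engine constant computed from
the same parameters (`hydrogen_atom_energy()`).  Absolute ΔH values are
therefore engine-specific (CNDO/2 famously overbinds); only orderings and
differences are meaningful, which is why the external-energy mode
(`energy_table=`) lets results from any other quantum package drive the
predictor unchanged.

Ties (exactly symmetric classes) are broken by higher pose fraction, then
lower carbon index, and the tie-break is recorded in the output ordering.

## The synthetic fixtures and what tests do (and do not) show

`reference_molecules()` builds six molecules from ideal internal coordinates
— methane with machine-exact Td symmetry, exactly eclipsed ethane, propane,
trimethylamine, toluene and chair cyclohexanone — so that symmetry
invariants (equal per-hydrogen energies on methane, equal methyl classes on
ethane) hold to numerical precision rather than approximately.
`make_toy_active_site()` emits a minimal PDB with a heme group and
ideal-geometry residue templates anchored at requested positions, and
`make_pose_set()` places rigid transforms of a substrate at exact iron
distances.  All fixtures are pure functions of their arguments, so the
end-to-end demo (`som_demo()`) is byte-for-byte reproducible.

These fixtures emulate the *geometry* of the problem (distances, angles,
contact counts, pose ensembles) but not its *biophysics*: there is no
docking energy landscape, no induced fit, no solvent, and the toy site is
not a CYP3A4 mimic.  Passing tests therefore demonstrate that the
implementation honours its contracts and arithmetic, not that the model's
published accuracy transfers to arbitrary chemistry.  Reproducing the
benchmark accuracies from scratch would require the 50 experimental
substrates, a commercial docking engine and curated metabolite annotations;
the package instead ships the per-reaction-type outcome counts
(`reported_accuracy_counts()`) and reproduces the accuracy arithmetic
exactly through the same `aggregate_verdicts()` code path used for new
predictions.

Problem sizes used by the test suite and the acceptance script were chosen
to exercise every code path at desk scale: molecules of 5–17 atoms, pose
ensembles of 1–50, one demo prediction end to end.

## Degenerate inputs and edge cases

* A molecule with no candidate site (e.g. CF4) yields an empty prediction
  with a warning, not an error.
* Configured residues or waters missing from a PDB are recorded in the
  model's provenance and skipped; a missing heme iron is fatal.
* Pose records failing the atom-count/element check name the offending
  record; malformed SDF lines carry line numbers; V3000 files are rejected.
* An empty pose set is a contract error everywhere it is accepted.

## Known limitations

* Two reaction classes only; stereochemical face labels (6β vs 6α) are not
  predicted, only carbon positions.
* The CNDO/2 parameter set is fixed (H, C, N, O, F, S, Cl; no d orbitals);
  substrates with other elements need the external-energy mode.
* The per-substrate evaluation requires a user-supplied map from positional
  carbon labels (C-6, C-7) to atom indices; no automatic structure
  alignment is attempted.
* Docking is out of scope: pose generation quality bounds the whole model,
  and the package deliberately treats the pose file as ground truth.
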