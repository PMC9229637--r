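---
title: "Methods: reactivity descriptors, contact profiling, and stability metrics for halogenated inhibitor series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reactivity descriptors, contact profiling, and stability metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halbind)
```

halbind implements the analysis chain used to screen halogen-substituted
inhibitor series against a protein target: global reactivity descriptors
from frontier orbitals, geometric profiling of noncovalent contacts in
docked poses, docking-energy bookkeeping, trajectory stability metrics, and
descriptor–activity correlation. This vignette explains the models, their
assumptions, the tunable parameters, and what the synthetic-data generators
do and do not emulate.

## Conceptual-DFT descriptors

All descriptors derive from the HOMO/LUMO eigenvalues in eV (inputs in
hartree must be pre-converted with `EV_PER_HARTREE` = 27.211386). Under the
Koopmans approximation IE = −ε(HOMO) and EA = −ε(LUMO), and the finite
operational forms are

- µ = (ε(HOMO) + ε(LUMO))/2, χ = −µ,
- η = (IE − EA)/2, S = 1/(IE − EA),
- ω = µ²/2η, E(g) = 2η.

Signs follow the Koopmans convention even where it produces a negative EA
for unbound LUMOs. The derivative definitions of µ and η (with respect to
electron number at fixed external potential) are conceptual background only;
nothing numerical depends on them. A zero or inverted gap is rejected — S is
undefined there and such an input indicates mis-ordered orbitals rather than
a physical closed-shell molecule. Text output rounds to 2 decimals, the
convention for published descriptor tables; full precision is kept
internally.

```{r}
descriptors_from_orbitals(-5.74, -2.66)
```

These identities are exact by construction and the test suite checks them to
1e-10 over 10^4 random orbital pairs: E(g) = 2η, χ = −µ, S·2η = 1, ω ≥ 0
with equality only at µ = 0.

## Contact profiling of docked complexes

`read_complex()` parses fixed-column PDB through bio3d, keeps the first
MODEL, drops waters (HOH/WAT/H2O) and alternate locations other than
blank/'A', and splits polymer ATOM records (receptor) from the HETATM
residue named as the ligand. Elements come from PDB columns 77–78 when
present; otherwise a documented inference rule applies (strip digits; in
standard amino acids the first letter wins, so " CA " is carbon; elsewhere
two-letter symbols Cl/Br/Se/Si are recognized first). Ligand bonds follow a
covalent-radius rule (≤ 1.3 × radius sum for heavy pairs, H within 1.2 Å of
a heavy atom) and aromatic rings are 5/6-cycles of C/N/O/S atoms within
0.15 Å of their best-fit plane. Both tolerances are configurable; the
defaults are conventional cheminformatics values, and the planarity test is
what separates an aromatic ring from, e.g., a cyclohexane chair (±0.25 Å
puckering).

Three detectors produce typed contacts with per-residue labels:

- **Halogen contacts** (default mode): one contact per receptor hydrogen
  strictly within 4 Å of a ligand halogen. This distance-only,
  protein-H-centric criterion is the screening definition this pipeline
  targets; it deliberately differs from the crystallographic σ-hole
  definition, which is available as `mode = "sigma-hole"` (C–X···acceptor
  ≥ 140°, acceptor N/O/S within the cutoff) for comparison. The strictness
  matters: a pair at exactly 4.0 Å is not a contact. A receptor without
  explicit hydrogens cannot satisfy the default criterion, so the profiler
  returns an empty set plus a warning rather than silently reporting zero.
- **Hydrogen bonds**: donors and acceptors typed by element (N/O/S), donors
  requiring an explicit hydrogen within 1.2 Å; a bond needs heavy-atom
  distance ≤ 3.5 Å and best D–H···A angle ≥ 120°. United-atom receptors
  therefore contribute acceptors only — the warning above flags the likely
  undercount. Weak C–H donors are excluded. The thresholds are Discovery-
  Studio-like defaults, configurable and embedded verbatim in every report.
- **π interactions**: receptor rings come from PHE/TYR/TRP/HIS side chains
  by canonical atom names, ligand rings from perception. π–π requires
  centroid distance ≤ 5.5 Å and interplanar tilt ≤ 30° (or within 30° of
  perpendicular, the T-shaped window); π–alkyl pairs a ring centroid with an
  sp3 carbon (aliphatic side-chain carbon on the receptor side, or a ligand
  carbon bearing ≥ 3 hydrogens) within the same cutoff. Rarer subtypes
  (π–cation, amide–π) are out of scope since only aggregate π counts are
  analyzed.

All detectors are plain all-pairs scans — no spatial indexing — so results
are exactly reproducible and equal to a brute-force oracle by construction.
Contacts sort by (kind, distance, residue number, serial) so reports are
byte-stable; each unordered pair appears once per kind. Reports expose two
totals (unique contacts, and unique kind-by-residue pairs) because summary
counts in the literature are ambiguous between the two.

## Docking metrics

K(i) = exp(ΔG/RT) with R = 1.98720425864e-3 kcal mol⁻¹ K⁻¹ and T defaulting
to 298.15 K (the docking-engine convention; the temperature used is recorded
in every output). The inverse `dg_from_ki()` recovers ΔG to 1e-12 relative.
Ranking is ascending in signed ΔG with lexicographic tie-breaks, so it is a
deterministic permutation. `halogen_trend()` tests strict ordering of
class means F > Cl > Br > I in signed kcal/mol — iodine most negative —
and returns NA rather than a guess when a class is absent.

## Superposition and trajectory metrics

`superpose_kabsch()` computes the least-squares optimal proper rotation via
SVD of the weighted covariance matrix, correcting the sign of the smallest
singular direction so reflections are never returned (det R = +1 to 1e-10 in
tests). Degenerate references (collinear atoms) are rejected because the
rotation is then underdetermined. Fitted RMSD is never larger than the
no-fit `rmsd_plain()`.

Trajectories are multi-model PDB only — desk-scale and dependency-free;
binary MD formats are out of scope. Defaults: protein metrics on Cα atoms,
reference frame 1, equilibration skip 0 (all configurable).
`trajectory_rmsf()` fits every frame to the first, then takes per-atom
RMSF = sqrt(mean ‖x(t) − ⟨x⟩‖²) and averages within residues. For isotropic
Gaussian jitter with per-axis σ the expectation is RMSF = σ√3. Two numerical
caveats are inherent rather than implementation artifacts: the population
(1/F) variance form is used, so comparisons against sample-variance
implementations need a √(F/(F−1)) factor; and per-frame fitting removes six
rigid-body degrees of freedom, shrinking RMSF by roughly √(1 − 6/3N) — about
1% at N = 80 atoms, but 5% at N = 20, which is why recovery checks run on
the full 80-residue synthetic trace.

## Descriptor–activity correlation

`pearson_r()` validates (equal length ≥ 3, finite, nonzero variance — a
zero-variance input errors rather than returning 0) and delegates to
`stats::cor()`. `correlation_matrix()` correlates each descriptor column
against the signed binding energy; a `negate_score` switch flips every sign
for workflows that report positive score magnitudes. Rows with missing
values are dropped with a message, never imputed. p-values (two-sided,
t-based) are off by default since the screening analysis is effect-size
driven at small n.

## What the generators emulate — and what they do not

The generators reproduce the *structure* the analysis assumes, not the
underlying physics:

- `gen_orbital_table()`: HOMO ≈ constant (−5.74 eV + 0.01 eV noise), LUMO
  lowered by 0.29 eV × halogen rank (F=1 … I=4) × substitution count from a
  −1.50 eV reference — i.e., a reference gap of 4.24 eV (hardness 2.12 eV)
  and a 1.16 eV LUMO drop for a single iodine substitution. The linear
  rank-by-count law is a deliberate idealization; it exaggerates the
  softening of tri-substituted iodine compounds (gap 0.76 eV) relative to
  real chemistry, where the effect saturates.
- `gen_docking_table()`: ΔG = −9.8 − 0.35·rank − 0.15·(subs − 1) ± 0.05
  kcal/mol, spanning ≈ −10.3 to −11.95 with a class-mean separation (0.35)
  seven times the noise on a class mean, so the F < Cl < Br < I flag holds
  for every seed.
- `gen_complex()`: four spatially separated "stations" (25 Å apart, all
  cutoffs ≤ 5.5 Å) each realize one contact class at exact target
  geometries — halogens on a ligand ring with receptor hydrogens placed
  along the C–X axis, a hydroxyl donor with acceptors positioned by solving
  the distance/angle constraints in closed form, parallel PHE rings, and
  LEU side-chain carbons. Decoys sit just outside each cutoff. The
  generator re-verifies the halogen plant by brute force and rejects
  unsatisfiable requests. Residue labels mimic a real steroid-binding
  pocket so reports read naturally, but the pocket is geometric scaffolding,
  not a protein: no sterics, no electrostatics, no conformational coupling.
- `gen_trajectory()`: an ideal α-helical Cα trace with per-residue Gaussian
  jitter, quiet (σ = 0.3 Å) in residues 140–160 and 180–200 and louder
  (0.8 Å) elsewhere, plus optional rigid drift to exercise fitting. Frames
  are independent — there is no autocorrelation, solvent, or force field.
- `gen_property_table()`: (µ, ΔG) drawn from a bivariate normal at the
  planted correlation; the remaining descriptor columns are derived exactly
  from the implied orbitals so internal identities stay intact.

Passing tests on these fixtures therefore demonstrates that the *measurement
machinery* is correct — detectors recover exactly what was planted,
estimators recover generator parameters within sampling error — not that
any physical prediction about a real compound series is accurate. Quantities
that require the external engines (per-compound docking energies,
experimental interaction counts, redocking RMSD against a crystal pose,
100 ns RMSD ranges, correlations over a real descriptor table) are quoted in
documentation as context only and are never asserted.

## Problem sizes and determinism

The shipped checks use 10^4 random orbital pairs, 100 generated complexes
(~60 atoms each), trajectories of 10^4 frames × 80 residues for σ-recovery,
and 20 seeds × n = 1000 for correlation recovery — sizes chosen so the full
suite completes in well under a minute while keeping sampling error far
below the tolerances (5% for RMSF recovery, ±0.05 on a mean correlation).
Every stochastic step flows from one explicit seed; identical
configuration + seed gives byte-identical generator output, pipeline
reruns over unchanged inputs are byte-identical (timestamps aside), and
`scripts/acceptance.R --seed N` is fully reproducible.

## Known limitations

- Element inference without the PDB element column is heuristic; exotic
  ligand atom names (e.g., a calcium named "CA" inside a nonstandard
  residue) can misresolve. Supplying the element column avoids this.
- Ring perception is geometric (planarity), not electronic: a planar
  non-aromatic ring would be accepted, a strongly puckered aromatic-like
  ring rejected.
- The hydrogen-bond detector needs explicit donor hydrogens; united-atom
  structures undercount, which the profiler flags but cannot repair.
- CONECT records are ignored by design; bonds are always re-inferred.
- Trajectory I/O is multi-model PDB only, with constant atom ordering
  assumed across frames.
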