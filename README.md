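# halbind

Reactivity descriptors and binding analysis for halogenated enzyme-inhibitor
series.

## What this is for

Halogen substitution (F, Cl, Br, I) is a recurring design move in inhibitor
optimization — for example in nonsteroidal (hydroxyphenyl-naphthol
"steroidomimetic") inhibitors of 17β-hydroxysteroid dehydrogenase type 1,
the enzyme that catalyzes the last step of estradiol biosynthesis. Screening
such a series computationally involves a fixed sequence of analyses:

1. **Conceptual-DFT reactivity descriptors** from frontier-orbital energies.
   With the Koopmans approximation IE = −ε(HOMO), EA = −ε(LUMO):

   - chemical potential µ = (ε(HOMO) + ε(LUMO))/2, electronegativity χ = −µ
   - global hardness η = (IE − EA)/2, softness S = 1/(IE − EA)
   - electrophilicity index ω = µ²/2η
   - frontier gap E(g) = ε(LUMO) − ε(HOMO) = 2η

   Heavier halogens and higher substitution counts lower the LUMO, shrinking
   the gap and raising ω.

2. **Noncovalent-contact profiling** of docked complexes: hydrogen bonds
   (donor–acceptor ≤ 3.5 Å, D–H···A ≥ 120°), π–π / π–alkyl contacts (ring
   centroids ≤ 5.5 Å, tilt ≤ 30° or T-shaped), and a halogen-contact
   criterion — a receptor hydrogen strictly within 4 Å of a ligand halogen —
   with per-residue attribution (Val143, Gly186, ... style labels). An
   optional σ-hole mode (C–X···A ≥ 140°) implements the crystallographic
   halogen-bond definition instead.

3. **Docking metrics**: K(i) = exp(ΔG/RT), deterministic ranking, and the
   class-mean binding trend F < Cl < Br < I expected of a halogen series.

4. **Stability metrics**: Kabsch least-squares superposition RMSD
   (proper rotations only) and per-residue RMSF over multi-model PDB
   trajectories.

5. **Structure–property correlation**: Pearson r of each descriptor against
   the binding energy.

Because quantum-chemistry, docking, and MD engines are not part of the
package, seeded synthetic generators (`gen_orbital_table()`,
`gen_docking_table()`, `gen_complex()`, `gen_trajectory()`,
`gen_property_table()`) produce inputs with the same statistical and
geometric structure — including planted, exactly-known ground truth — so
every stage is testable end to end.

## Worked example

```r
library(halbind)

# descriptors: a 3.08 eV gap implies hardness 1.54 eV
descriptors_from_orbitals(-5.74, -2.66)
#>     ie   ea chi   mu  eta  softness    omega  gap
#> 1 5.74 2.66 4.2 -4.2 1.54 0.3246753 5.727273 3.08

# docking free energy to inhibition constant
format_ki(ki_from_binding_energy(-11.94))
#> [1] "1.77 nM"

# profile a docked complex with planted contacts
cx <- gen_complex(seed = 1, planted = list(halogen = c(3.2, 3.8),
                                           hbond = 3.0, pi_pi = 3.8))
profile_complex(cx)
#> interaction_report: 4 contacts ( hbond=1, pi_pi=1, pi_alkyl=0, halogen=2 )
#>   hbond: Gly186
#>   pi_pi: Phe226
#>   halogen: Val143, Val144
```

The numbers mean: the ligand's frontier gap of 3.08 eV puts its hardness at
1.54 eV (soft, reactive); a −11.94 kcal/mol pose corresponds to
low-nanomolar predicted inhibition; and the profiler recovered exactly the
two sub-4-Å halogen contacts, one hydrogen bond, and one π-stack that were
built into the synthetic pocket.

## The analysis workflow

The `analysis/` directory holds the numbered drivers, run from the
repository root after installing the package:

```sh
Rscript analysis/01_simulate.R      # synthetic inputs + ground-truth sidecars
Rscript analysis/02_descriptors.R   # descriptor table for the series
Rscript analysis/03_interactions.R  # contact profile vs planted truth
Rscript analysis/04_docking.R       # ranking, Ki, halogen trend
Rscript analysis/05_trajectory.R    # RMSD range, RMSF, stable residues
Rscript analysis/06_correlation.R   # descriptor-activity Pearson table
```

Each script states what it found and writes its tables under `results/`.
`run_pipeline()` wraps the same stages behind a single call with a JSON run
manifest.

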