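---
title: "Methods: end-state energetics and cyclic peptide design in pepcycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: end-state energetics and cyclic peptide design in pepcycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepcycle)
```

# Scope and model

`pepcycle` implements the computational layer of an interface-directed
cyclic peptide design campaign: characterize a two-chain protein–protein
interface over a conformational ensemble, score binding with an
end-state MM-PBSA model, find hot-spot residues by alanine scanning, cut
linear candidate peptides out of the interface, close them head-to-tail
(GP amide or CC disulfide), re-score point mutants, and process the
assay-side readouts (viability, saturation binding). Docking and
physical MD are out of scope — ensembles come in as multi-model PDB
files or from the package's own synthetic generators.

## Energy model

For a complex C = R·L over frames of a single trajectory:

$$\Delta G_{bind} = \Delta E_{MM} + \Delta G_{solv}, \qquad
  \Delta E_{MM} = \Delta E_{ele} + \Delta E_{vdw} + \Delta E_{int}, \qquad
  \Delta G_{solv} = \Delta G_{PB} + \Delta G_{nonp}$$

Because receptor and ligand coordinates are taken from the same complex
frame, all bonded contributions cancel ($\Delta E_{int}=0$) and the
gas-phase differences reduce to cross-chain pairwise sums. Coulomb uses
$k\,q_iq_j/(\varepsilon_{in} r_{ij})$ with $k = 332.0637$
kcal·mol⁻¹·Å·e⁻²; Lennard-Jones is the 12-6 form with
Lorentz–Berthelot-style combination (arithmetic $r_{min}/2$, geometric
$\varepsilon$). No distance cutoff is applied anywhere in rescoring: an
8 Å cutoff is an MD-engine economy, not a scoring convention, and the
systems here are small.

The nonpolar term is linear in solvent-accessible surface area,
$\Delta G_{nonp} = \gamma\,\mathrm{SASA} + \beta$ with defaults
$\gamma = 0.00542$ kcal·mol⁻¹·Å⁻², $\beta = 0.92$ kcal·mol⁻¹ and a
1.4 Å probe. Note that in the complex-minus-parts difference the
constant $\beta$ enters as $\beta(1-1-1) = -\beta$.

The polar term solves the linearized Poisson–Boltzmann equation by
finite differences (successive over-relaxation on a 7-point stencil).
Dielectric values sit on cell faces, assigned from the face midpoint
(inside any atom's solvation sphere → $\varepsilon_{in}$, default 1;
else $\varepsilon_{out}$, default 80). Debye–Hückel screening
($\kappa^2 \propto I/\varepsilon_{out} RT$, default $I$ = 0.15 M) applies
outside a 2 Å Stern-adjusted solute. Charges spread trilinearly onto the
eight surrounding nodes; Dirichlet boundary values are Debye-screened
Coulomb sums. The reaction-field energy is
$\tfrac12\sum_i q_i(\phi^{solv}_i-\phi^{vac}_i)$, with the vacuum
reference solved on the *identical* grid so the dominant discretization
artifact — the grid self-energy — cancels exactly. The solver lives in
one C++ file; non-convergence raises an error carrying the residual.

**Numerical behaviour.** Against the Born closed form for a unit charge
in a 2 Å sphere the solver is within ~4% at 0.5 Å spacing and ~1.5% at
0.25 Å. Convergence in spacing is first order but not monotone from very
coarse grids (error cancellation can make a 1 Å grid fortuitously
accurate), which is why the convergence test compares 0.5 Å against
0.25 Å. We use a single grid with an analytic screened-Coulomb boundary
at a generous margin (default 8 Å) instead of a coarse-to-fine focusing
pass; at the peptide scale of this package the boundary error at that
margin is far below the discretization error, and one grid keeps the
vacuum-reference cancellation exact.

**Error bars** are standard errors of the per-frame means, matching the
spirit of "±" columns in end-state energy tables; no claim of
statistical independence between frames is made.

## Per-residue decomposition

Gas-phase cross-pair energies are halved onto the two residues of each
pair, which makes residue sums reproduce the complex totals *exactly*.
Solvation shares are per-atom: $\gamma\,\Delta\mathrm{SASA}_a$ for the
nonpolar part (with the $-\beta$ offset spread proportionally to each
atom's share, so the residue table still sums to the total) and
$\tfrac12 q_a \Delta\phi_a$ reaction-field differences for the polar
part. The polar sharing rule is a declared convention — decomposition
of a field energy onto atoms is not unique — and is tested for
self-consistency (sums equal totals), not against an external standard.

## Alanine scanning and mutation

Scanning is single-trajectory: the mutant is rebuilt on the *existing*
frames by truncating the side chain beyond Cβ, with no re-sampling, so a
residue that is already alanine gives ΔΔG = 0 exactly, and the scan is
deterministic. Glycine is skipped with a warning (nothing to truncate;
building a Cβ would *add* atoms and break the truncation-only
invariant); proline is scanned but flagged, because removing its ring
leaves a backbone strain the model does not relax.

Sign convention: ΔΔG = ΔG(wild) − ΔG(mutant). A stabilizing wild-type
side chain therefore gives ΔΔG < 0, and hot spots are classified by
ΔΔG ≤ −2 kcal·mol⁻¹. Published hot-spot rules state this inequality in
both directions depending on whether the author speaks of the residue's
"contribution" or the mutation's "change"; `classify_hotspots()`
exposes `direction` so either reading is available, with the
stabilizing-wild-type reading as default.

Point mutation (`point_mutation("L16R")`) replaces the side chain with
an extended internal template grown along the existing Cα→Cβ direction,
then runs 50 steepest-descent steps of clash relief moving only the new
atoms. There is deliberately no rotamer search: determinism and
rank-ordering on toy systems are the goals, not refined geometry; an
unresolved contact below 1.5 Å sets a `clash` attribute and warns.

## Design layer

Truncation candidates are contiguous windows ranked by (key residues
covered, then shorter length, then lower start); non-contiguous splices
— e.g. a loop plus one adjacent residue — are accepted only as explicit
user ranges through `extract_fragment()`, because geometric splicing of
distant fragments is not modelled.

Cyclization follows two fixed conventions, both forced by the naming
arithmetic of the field's examples: CC *prepends and appends* a
cysteine, so a 17-mer base yields Cys1…Cys19 with the base shifted by
one (Thr2, Tyr10, Lys13…); GP *appends* Gly then Pro at the C-terminus
and closes the amide from the proline carboxyl back to residue 1. The
source literature spells the GP pair both ways in different places; the
C-terminal G-then-P order used here is a package convention, and the
closure descriptor records it. Names follow `{R1|α}_{GP|CC}{serial}`
with serials user-assigned (0 reserved for literature controls, which
ship flagged `external_control`; note the classic disulfide control
peptide closes through *internal* cysteines, a different closure
descriptor, and is excluded from enumeration counts).

3-D ring building lays the full sequence on a circle with 3.8 Å of arc
per residue and backbone N/Cα/C at arc offsets 0/1.46/2.47 Å, so the
closing C→N gap is ~1.33 Å *by construction*; a short steepest-descent
pass then refines the closure bond (amide C–N 1.33 Å, disulfide S–S
2.05 Å, both within 0.2 Å or an error is raised). An extended chain
cannot close without a global search, so the circle is the deterministic
ideal-geometry choice; with a template the base residues take template
coordinates (superposed Cα-wise onto the ring) before the same
relaxation.

## Synthetic data: what it emulates, what it does not

The ensemble generator adds independent per-atom isotropic Gaussian
displacements (optionally plus shared per-group displacement streams) to
a reference structure. This is a *statistical* stand-in for MD, chosen
because every downstream analysis consumes only statistical structure:

- RMSF of an isotropic σ displacement is σ√3, so a per-residue σ profile
  is recovered exactly in expectation (the 2000-frame recovery test
  checks the 5:1 ratio to 10%);
- shared displacement streams give DCCM entries of ±1 by construction;
- hydrogen-bond occupancy is exact: a designed donor–acceptor pair sits
  at 2.9 Å in exactly `round(p·n)` frames and 7.9 Å otherwise, and no
  other N/O cross pair ever satisfies the 3.5 Å criterion;
- the toy complex places two antiparallel extended chains and solves for
  the inter-chain offset so the closest heavy-atom distance equals the
  requested gap within 0.1 Å.

What a green test on this world does *not* establish: force-field
realism (the packaged parameter table is a reduced, self-authored set —
charges in 0.05 e steps summing exactly to formal residue charges, one
LJ class per element, Bondi-like radii), conformational realism
(no bonded physics, no correlation times), or agreement with
published absolute binding energies, which depend on long MD of the real
complex. The package's acceptance layer therefore checks *identities*
(aggregation of published component tables must return the published
totals), *closed forms* (Born, sphere areas, LJ minima), and *parameter
recovery* — never absolute desk-scale reproductions of MD-scale numbers.

Binding-curve synthesis follows the one-site model with Gaussian noise
on a 5-fold dilution series from 4 µM (six points), the standard ELISA
design; the KD recovery study (200 seeded fits at 2% noise) checks
median recovery within 15%.

## Numerical choices and degenerate inputs

- Superposition is Kabsch SVD with determinant correction; fewer than 3
  atoms or a collinear selection is a hard error. RMSD fits and measures
  on the same selection (heavy atoms by default).
- The trailing-fraction parameter (default 0.25) generalizes
  "average over the equilibrated tail" of a trajectory.
- Hydrogen-bond criterion: donor–acceptor ≤ 3.5 Å and D–H⋯A ≥ 135° when
  hydrogens are present, distance-only otherwise; both configurable.
- Shrake–Rupley quadrature uses a deterministic golden-spiral point set
  (default 960 points). Because the point set is fixed in the global
  frame, SASA — and anything containing it — is rotation-invariant only
  to O(1/n_points); tests compare rigid-motion invariants at that
  tolerance, and exact invariance claims are restricted to gas-phase
  terms.
- KD fitting is nonlinear least squares on the *linear* concentration
  scale (a log axis changes the plot, not the likelihood), with a
  deterministic multi-start over a log-spaced KD grid; all-equal
  responses or a single concentration raise a degenerate-fit error, and
  a span under two orders of magnitude warns.
- One-letter/three-letter conversion flags nonstandard residues rather
  than guessing; HETATM records parse but are excluded from energetics
  and interface selections.
- Fragments keep interior parameters at their termini: because every
  residue's charges sum exactly to its formal charge, any fragment is
  integer-charged without a capping protocol.

## Configuration and reproducibility

The pipeline driver takes a single JSON config (JSON rather than YAML
because the target environment ships no YAML reader; the schema mirrors
`pb_settings()` plus selections and seeds). Seeds are explicit arguments
everywhere — generators never touch the global RNG stream — and a rerun
with the same config and seed is byte-identical, which the manifest's
md5 checksums make checkable at a glance.

## Known limitations

- The PB solver is linear, single-grid, with sharp face dielectrics: no
  nonlinear salt, no smoothed boundaries, no multigrid. It is accurate
  to a few percent at peptide scale, not a production electrostatics
  engine.
- Mutant side chains come from one extended template; packing effects
  and rotamer preferences are invisible to the scan.
- Ring building optimizes closure geometry only; macrocycle
  conformational sampling is explicitly out of scope.
- The reduced force field supports the 20 standard residues; anything
  else parameterizes by element fallback with zero charge.
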