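---
title: "Selecting docking poses by SAR congruency: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting docking poses by SAR congruency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PoseSAR)
```

## The problem and the statistic

Given an ensemble of docking poses of one reference compound from a
congeneric series, PoseSAR asks which pose best explains the measured
potencies of the *whole* series. Each reference pose is expanded into 3D
poses of every analog by substituent replacement on the shared scaffold,
every derived complex is scored, and the pose is summarized by the SAR
congruency coefficient

$$R_\mathrm{SAR}(p) \;=\; \mathrm{cor}\big(\Delta G_{\mathrm{bind}, i}(p),\; \mathrm{pEC}_{50,i}\big)_{i \in \text{series}},$$

the Pearson correlation between predicted binding energies and measured
potencies across the series built on pose $p$. Because lower (more
negative) energy should accompany higher potency, a *strongly negative*
$R_\mathrm{SAR}$ marks a SAR-consistent pose; poses are ranked by
$R_\mathrm{SAR}$ ascending, ties broken by lower regression RMSE and then
pose id.

The correlation set includes the reference compound itself plus its
analogs ($n = 19$ for the packaged pyrazoloquinolinone series). This is a
deliberate choice — the reference's own energy/potency pair carries the
same information as any analog's — and can be switched off with
`includeReference = FALSE` in `assessPoses()`.

Validation statistics per pose:

* $r^2$, reported as the exact square of the (full-precision)
  $R_\mathrm{SAR}$;
* RMSE of the OLS regression of activity on energy (log units);
* leave-one-out $q^2 = 1 - \mathrm{PRESS}/\mathrm{SS}_{tot}$, where PRESS
  is computed through the exact OLS leverage identity
  $e_{(i)} = e_i/(1-h_i)$ — algebraically identical to refitting $n$
  times (the test suite verifies this against an explicit refit loop to
  $10^{-12}$), but fast enough to sit inside the permutation loop;
* Y-scrambling: the activities are permuted uniformly without replacement
  (1000 iterations by default, seeded Mersenne-Twister), $r^2$ and $q^2$
  recomputed each time. The empirical p-value uses the add-one rule
  $p = (1 + \#\{r^2_{scr} \ge r^2_{obs}\})/(N+1)$, so it can never be 0.
  Under the null the mean scrambled $r^2$ converges to $1/(n-1)$, which is
  0.056 for $n = 19$. The null mean of the LOO $q^2$ sits at or below
  zero; both the raw mean and a clamped-at-zero variant are reported, and
  neither is asserted against any external value.

Missing activities are dropped pairwise per pose with the effective $n$
reported; compounds excluded for outlier re-assessment
(`reassessWithout()`) are recorded in the output.

## The binding-energy surrogate

Production MM-GBSA rescoring rests on proprietary force fields and
solvation models. PoseSAR instead defines its own documented scorer whose
*contract* matches that stage — an energy decomposition, restrained local
minimization, and a ligand-strain term — while making no claim that its
absolute kcal/mol values match any published ones. Only ranking and
correlation behaviour is claimed, which is all the congruency statistic
consumes.

The total energy is a sum of:

* **Lennard-Jones 12-6** with per-element parameters
  (σ: H 2.50, C 3.55, N 3.25, O 2.96, F 2.94, S 3.55, Cl 3.40, Br 3.47 Å;
  ε: 0.03/0.07/0.17/0.21/0.06/0.25/0.30/0.47 kcal/mol), geometric
  combining. Polar hydrogens (those bonded to N/O/S) carry no LJ well, the
  standard convention that lets hydrogen bonds reach their short optimum
  distances.
* **Screened Coulomb** with a distance-dependent dielectric
  $\varepsilon(r) = 4r$, i.e. $E = 332.06\,q_iq_j/(4r^2)$ — the classic
  implicit-screening shortcut for pocket electrostatics.
* **Born-style desolvation**: a pairwise penalty
  $0.05\,(q_i^2+q_j^2)\exp(-r^2/2\sigma_s^2)$ with $\sigma_s = 3.5$ Å,
  charging for burying polar atoms against each other. The prefactor is
  deliberately small: its job is to keep polar contacts at their optimum
  distance, not to dominate the balance.
* **Directional hydrogen bond**: a 10-12 well on the donor–acceptor heavy
  distance ($r_0 = 2.9$ Å, depth 2.5 kcal/mol) gated by
  $\cos^2\theta_{\mathrm{D\text{-}H\cdots A}}$, active only when the angle
  exceeds 90°.
* **Valence terms** (needed because minimization moves side chains and
  ligand internal degrees of freedom): harmonic bonds
  (k = 300 kcal·mol⁻¹·Å⁻²) with equilibrium lengths snapped to the nearest
  canonical value for the element pair (so single/aromatic/double flavors
  are distinguished without a full typing engine); harmonic angles
  (k = 60 kcal·mol⁻¹·rad⁻²) with 109.47°/120°/180° equilibria by inferred
  hybridization; cosine torsions (3-fold 0.25 kcal/mol about sp³ bonds,
  2-fold 2.0 kcal/mol planarizing conjugated bonds, divided by the number
  of paths per central bond).
* Nonbonded interactions are switched off smoothly between 10 and 12 Å
  (cubic switch); 1-2 and 1-3 pairs are excluded, 1-4 pairs scaled by 0.5.
  Coincident atoms (r < 0.1 Å) raise an error naming the pair.

Partial charges are read from MOL2 when present; otherwise a documented
rule set assigns them from element and bonded neighborhood (carboxylates
−0.80/+0.70, carbonyls −0.50/+0.45, hydroxyl O −0.60 with H +0.40, amide
or aromatic N −0.50, amine N −0.70, N-H +0.35, halogens −0.10 to −0.20,
C-H pairs ±0.06). A reproduction of the original per-atom charges is not
possible, so this fallback is an explicit approximation.

$\Delta G_\mathrm{bind} = G_\mathrm{complex} - G_\mathrm{protein} -
G_\mathrm{ligand}$, the standard convention. Because the three terms are
evaluated on identical geometries, all intramolecular contributions cancel
exactly and the decomposition (vdW, electrostatic, solvation, H-bond) sums
to the total to $10^{-9}$, which the tests assert. Ligand strain is the
bound-geometry ligand energy minus the energy of the same ligand minimized
free of the receptor, starting from the bound geometry; it is non-negative
up to the convergence tolerance. Energies are exported both raw and
strain-corrected, since either convention may be wanted downstream.

### Minimization

The minimizer is a Polak–Ribière conjugate gradient with Armijo
backtracking over analytic gradients (compiled). The contract follows the
protocol's printed parameters: the ligand and the side chains of residues
within 5 Å of any ligand heavy atom are mobile; every other atom is
harmonically restrained to its start with 200 kcal·mol⁻¹·Å⁻²; termination
when the largest gradient component falls below 0.05 kcal·mol⁻¹·Å⁻¹ or
after 2500 accepted steps. Mobile-set membership is decided once from the
starting geometry (re-listing during minimization would make the objective
discontinuous). Accepted steps strictly decrease the energy, so the trace
is non-increasing by construction. The nonbonded pair list is built once
per minimization with a 2 Å margin over the 12 Å cutoff — displacements
under these restraints stay well inside the margin.

`relaxLigand()` is the in-situ variant — ligand mobile, receptor rigid —
used after point mutations (`mutateResidue()`, side-chain truncation to
C-β with ideally completed hydrogens) and by the synthetic generator.

## Derivatization geometry

The analog-expansion step is this package's own construction (the original
utility's internals are not described anywhere):

1. The branch currently attached at the position (a hydrogen on a bare
   scaffold, or a whole substituent if the reference compound carries one)
   is deleted; the attachment direction is the former core–branch bond
   vector.
2. The fragment's link atom is placed along that vector at the tabulated
   bond length (C(ar)–Cl 1.73, –Br 1.88, –F 1.35, –C(sp³) 1.51, –O 1.36,
   –N 1.40, –C(sp) 1.43, –H 1.09 Å; user-overridable via
   `options(PoseSAR.bond_lengths=)`).
3. The fragment is rotated so its open-valence direction — the ideal
   missing-valence direction at the link atom given its neighbors and
   hybridization — points back at the core atom. For a singly-bonded sp³
   link (e.g. the ether oxygen of OMe) this is a cone position; the
   residual roll freedom is exactly the torsion about the new bond.
4. That torsion is scanned over `torsionSteps` (default 12) evenly spaced
   angles; the angle minimizing a truncated repulsive clash score
   (capped $((0.89(v_i+v_j)/r)^{12}$ against receptor + remaining ligand
   atoms) wins, ties to the smallest angle. The score is purely repulsive
   on purpose: placement must avoid clashes, not optimize attraction —
   that is the scorer's job. Deeper rotors of multi-rotor groups (COOEt,
   tBu, OMe) keep their ideal internal geometry; downstream minimization
   relaxes them.

Core-atom coordinates are bitwise unchanged, the construction is fully
deterministic, and a placement whose best angle still exceeds a hard
clash ceiling is flagged (never silently dropped). Expanding $n_p$
reference poses over an $n_c$-compound table yields exactly
$n_p \times n_c$ poses, the reference pose passing through unchanged.

## Pose-space analytics

Scaffold RMSD uses fixed atom correspondence and no superposition: all
poses live in the common receptor frame, so superposition would erase
exactly the differences being measured. This also makes the RMSD a scaled
Euclidean metric (the triangle inequality is property-tested), and
classical (Torgerson) MDS — double-centering, eigendecomposition,
coordinates scaled by $\sqrt{\lambda}$ — is then exact for the embedded
dimensions. Negative eigenvalues are truncated at zero with a warning;
axis signs are fixed by making each axis's largest-magnitude coordinate
positive, and points are centered.

Binding-mode labels operationalize the visual "scaffold flipped by ~180°"
grouping: poses are single-linkage clustered on scaffold RMSD at 2.0 Å
(matching the observed >2 Å spread among top-ranked poses), and each
cluster is labelled by the majority sign of the projection of the scaffold
axis (e.g. ring nitrogen → R8 carbon) onto the inter-subunit axis (the
unit vector between the two chain centroids — frame-invariant by
construction). Center-of-mass distances default to unit masses (heavy-atom
centroid) with a mass-weighted switch, since the convention is rarely
stated in the literature.

## Interaction fingerprints

Only the 5 Å heavy-atom binding-site cutoff is protocol-fixed; the
remaining criteria are standard literature values exposed as arguments:
hydrogen bond at donor–acceptor ≤ 3.5 Å with D-H···A ≥ 120°; hydrophobic
contact between apolar carbons (not bonded to N/O/F) ≤ 4.5 Å; π-π for
ring centroids ≤ 5.5 Å with interplanar angle ≤ 30° (parallel) or
60–120° at ≤ 5.0 Å (T-shaped); salt bridge between formally charged N/O
≤ 4.0 Å. Cutoffs behave half-open (strictly greater ⇒ absent). Aromatic
rings are perceived from the bond graph plus a planarity check for
ligands, and from residue-name templates for the receptor. If a structure
lacks polar hydrogens they are completed at ideal geometry and the output
is flagged. Cation-π is not emitted.

## The synthetic study generator

`makeToySystem()` emulates the statistical structure the protocol assumes
— potency linear in the true-pose binding energy — inside a geometry small
enough to run thousands of times in tests. What it builds:

* a planar fused-bicyclic scaffold (two fused six-rings, one ring nitrogen
  carrying an H-bond-donor hydrogen, one ring carbon carrying a carbonyl
  acceptor) with all five attachment positions mapped;
* a pocket of 12 pseudo-residues (configurable 10–30) built from real
  amino-acid templates so interaction detection and mutation work
  unmodified: a glutamine whose amide N-H points at the scaffold carbonyl
  (N···O 2.95 Å, D-H···A ≈ 160°), an aspartate 6.2 Å off the R4' position,
  tyrosine/phenylalanine rings stacking the scaffold at 3.6–3.9 Å, a
  phenylalanine wall edge-on 5.6 Å off the R8 carbon, and aliphatic
  fillers placed along a fixed set of directions chosen once by a
  deterministic clash-free search that also keeps the substituent growth
  zones open. The residues are split over two chains to mimic a
  two-subunit interface;
* the planted pose: the hand-built ligand relaxed in the rigid pocket
  (`relaxLigand`), so that "true pose" means a genuine local minimum of
  the scoring function rather than an arbitrary geometry. Decoys are then
  seeded rigid perturbations (rotations to 180°, translations to
  `decoySpread`, default 2 Å), rejected on hard clash or on falling within
  1 Å RMSD of the planted pose; about a fifth are flipped ~180° about the
  scaffold normal before jittering, a stand-in for a second binding-mode
  family;
* activities: $\mathrm{pEC}_{50,i} = a + s\,\Delta G_i + \mathcal N(0,
  \sigma)$ with slope $s = -0.2$ log units per kcal/mol and noise
  $\sigma = 0.2$ log units by default, the intercept centering the values
  near 5.5. The slope was chosen so that the analog energy spread of the
  default system (~12 kcal/mol) maps to a realistic 2–3 log-unit potency
  range inside the plausible (3, 9) window.

The default analog table probes several positions with direction-specific
effects (a linear alkyne clashing at R8, methoxy penalized at R8 and R4',
halogens rewarded at R6) precisely so that the SAR signal is not
one-dimensional: a series whose activity is driven by a single "bulky =
bad" axis would let geometrically wrong poses correlate almost as well as
the true one, which defeats the point of the fixture.

What the generator does **not** emulate: real receptor flexibility,
solvent, tautomers/protonation, the actual pocket geometry of any
receptor, or measurement error structure beyond i.i.d. Gaussian noise.
Passing the end-to-end tests therefore demonstrates that the pipeline's
statistics and geometry are implemented correctly and that the protocol
recovers a planted truth under its own assumptions — not that it will
rank poses correctly on any particular real system.

## Numerical choices and degenerate inputs

* All randomness flows through explicit seeds (local RNG streams that
  restore the caller's state); per-stage substreams derive from one root
  seed in `runReport()`.
* Pearson/OLS operations refuse constant vectors ("zero variance") and
  fewer than 3 complete pairs (4 for LOO).
* A derivatized decoy can land a rigid substituent exactly on a receptor
  atom; `scorePoses()` flags such poses (`clash = TRUE`) with a hard
  score of 10⁴ kcal/mol instead of aborting, while direct energy calls
  still error on coincident atoms.
* Eigen-decomposition ties in MDS are resolved by the deterministic solver
  order plus the sign convention above; a degenerate (zero-length)
  scaffold axis is an error.
* PDB dialect: single model enforced (the model count is reported),
  ANISOU/TER ignored, altlocs resolved by highest occupancy then
  alphabetical id, insertion codes appended to the residue number as text.
  Atom indices are 1-based everywhere inside the package; interchange
  formats keep their native conventions (the scaffold-map JSON is 0-based
  on disk).

## Problem sizes used by the test suite

The packaged checks run the full protocol at deliberately small scale: the
derivatization count check expands 100 synthetic poses over the packaged
19-compound table (1900 complexes); the recovery check runs 25 seeded
replicates of a 20-pose, 8-analog study without minimization (activities
are generated from unminimized true-pose energies, so scoring without
minimization is the matched estimator); minimization contract checks use
single complexes of ~250 atoms. These sizes are the package's own choice
of a fast, fully reproducible demonstration scale; the same code paths
accept arbitrarily larger ensembles.

## Known limitations

* The scorer is a surrogate: no polarization, no explicit or
  surface-area solvation, no entropy; absolute energies are not
  transferable.
* Bond/angle equilibria come from canonical-value snapping, not a force
  field's atom typing; unusual chemistry (charged heterocycles,
  organometallics) is out of scope, as are elements beyond
  H/C/N/O/F/S/Cl/Br.
* R-group chemistry is single-attachment only — no ring replacement or
  linkers — and the scaffold map is explicit input; there is no
  substructure auto-detection.
* Multiple-testing correction across poses and bootstrap confidence
  intervals are intentionally absent from the assessment.
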