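# PoseSAR

Docking programs are usually good at *sampling* plausible ligand poses and
bad at *ranking* them. When the ligand belongs to a congeneric series with
measured potencies, the series itself can arbitrate: the correct pose should
reproduce the structure-activity relationship (SAR) of the whole series,
not just score well on its own. PoseSAR implements this SAR-congruency
protocol for selecting protein-ligand binding hypotheses from docking-pose
ensembles. It is aimed at structural bioinformaticians and computational
chemists who have (1) a receptor structure, (2) docking poses of one
reference compound, and (3) an activity table for its analogs.

## The method

For every docking pose *p* of the reference compound:

1. **Post-docking derivatization** builds 3D poses of all analogs on the
   coordinates of *p*: the branch at each attachment position (R6, R7, R8,
   R3', R4') is replaced by the analog's substituent, placed along the
   former bond vector at the standard bond length, with the dihedral about
   the new bond chosen by a steric-clash scan. Core atoms never move.
2. **Binding-energy estimation** scores every derivatized complex with a
   molecular-mechanics function (Lennard-Jones, screened Coulomb with
   ε(r) = 4r, a Born-style desolvation term, a directional hydrogen-bond
   term and valence terms), optionally after restrained local minimization
   (ligand + side chains within 5 Å mobile; everything else restrained at
   200 kcal·mol⁻¹·Å⁻²; convergence at 0.05 kcal·mol⁻¹·Å⁻¹ or 2500 steps).
   ΔG\_bind = G\_complex − G\_protein − G\_ligand; ligand strain is the bound-
   geometry ligand energy minus the freely minimized one.
3. **SAR congruency** computes the Pearson correlation R\_SAR between the
   per-analog ΔG\_bind and the measured potencies (pEC₅₀). Strongly
   *negative* R\_SAR marks a SAR-consistent pose. Each pose also gets an
   OLS r², RMSE, leave-one-out q² = 1 − PRESS/SS\_tot, and a Y-scrambling
   null (1000 seeded permutations of the activities, add-one empirical
   p-value). Poses are ranked by most-negative R\_SAR.
4. **Pose-space and interaction analysis**: scaffold RMSD matrices (fixed
   correspondence, no superposition), classical (Torgerson) MDS of the pose
   space, binding-mode assignment by the signed orientation of the scaffold
   axis against the receptor inter-subunit axis, center-of-mass distances,
   and structural interaction fingerprints (SIFt: H-bond, hydrophobic,
   π-π, salt-bridge bits per binding-site residue at a 5 Å heavy-atom site
   cutoff).

The packaged data set is the 19-compound pyrazoloquinolinone (PQ) series
with pEC₅₀ at the GABA-A receptor α1+/β3− interface and pKi at α1+/γ2−
(`pqTable()`), the series for which this protocol was developed. The
scoring function is a documented surrogate: absolute kcal/mol values are
not comparable to commercial MM-GBSA implementations; only rank/correlation
behaviour is claimed. Externally computed energies can be dropped in via
`importScores()`.

A synthetic module (`makeToySystem()`, `makeDecoys()`,
`generateActivities()`, `simulateStudy()`) builds a small rigid pocket from
amino-acid pseudo-residues with a planted true pose and activities linear
in the true-pose binding energy, so the whole protocol is testable end to
end without any external data.

## Worked example

```r
library(PoseSAR)

# the packaged potency table
tab <- pqTable()
relativePotency(tab, 1L, "pEC50_a1b3")[["19"]]   # 1.74 log units
meanSiteDifference(tab)$mean                     # 4.08 (over 16 compounds)

# a synthetic study: 10 poses (1 planted + 9 decoys), 8 analogs
sim <- simulateStudy(syntheticSpec(seed = 1, nPoses = 10))
expanded <- list()
for (p in sim$poses) {
  expanded <- c(expanded, expandPose(p, sim$scaffold, sim$records,
                                     sim$library, sim$receptor,
                                     referenceId = "1"))
}
energies <- scorePoses(sim$receptor, expanded)
assessment <- assessPoses(energies, sim$records,
                          nIterations = 1000, seed = 42)
head(assessment[, c("rank", "pose_id", "R_SAR", "r2", "RMSE", "q2_loo",
                    "p_value")], 3)
#   rank pose_id  R_SAR    r2  RMSE    q2_loo  p_value
# 1    1 planted -0.962 0.925 0.187     0.900 0.000999
# 2    2      p8 -0.760 0.578 0.444 -3362.467 0.124875
# 3    3      p2 -0.730 0.532 0.467     0.135 0.039960
```

The planted pose is ranked first with R\_SAR = −0.96: its analog energies
track the generated potencies almost perfectly, while decoy orientations
correlate weakly (p8 is a flagged clash pose, which is why its
cross-validated q² collapses). `runReport()` chains
derivatize → score → rank → pose space → SIFt into one output directory
with a markdown summary, and `inst/scripts/posesar` exposes the same steps
as shell subcommands.

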