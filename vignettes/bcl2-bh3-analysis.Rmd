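---
title: "Methods: structural and biophysical analysis of Bcl-2:BH3 complexes"
author: "bh3struct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural and biophysical analysis of Bcl-2:BH3 complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bh3struct)
```

# Scope

Pro-survival Bcl-2 family proteins carry a hydrophobic surface groove
(helices 2-5 of the Bcl-2 fold) that captures the amphipathic BH3 helix
of pro-apoptotic relatives. Characterising such a receptor:peptide
system computationally involves a recurring set of analyses, and this
package implements them as one coherent toolkit:

* rigid-body superposition and Calpha RMSD (`kabsch`,
  `alignStructures`);
* structure-based phylogenetics from pairwise RMSD matrices
  (`rmsdMatrix`, `clusterStructures`, `toNewick`);
* solvent-accessible surface area and interface characterisation —
  buried area, hydrogen bonds, salt bridges, hot-spot pocket burial
  (`sasa`, `buriedSurface`, `findHBonds`, `findSaltBridges`,
  `hotspotBurial`);
* BH3 motif scanning in sequences (`scanBH3`, `peptideWindow`);
* single-site isothermal titration calorimetry simulation and fitting
  (`simulateTitration`, `fitSingleSite`, `aggregateReplicates`);
* crystallographic arithmetic — cell volume, Matthews coefficient,
  solvent content, unique-reflection counts (`cellVolume`,
  `solventContent`, `countUniqueReflections`).

Everything is exercised offline by parametric generators
(`makeHelix`, `makeBundle`, `makeGrooveComplex`, `makeBH3Sequence`)
whose ground truth is known by construction.

# Coordinate handling

PDB fixed-width records are parsed directly. Design choices a user
should know:

* **Alternate locations** are collapsed deterministically: highest
  occupancy wins, ties go to the alphabetically first altloc code. The
  result is independent of record order.
* **Models**: one model per `PDBStructure`; the default is model 1
  (crystal structures have a single model).
* **Numbering** is preserved exactly as deposited. Author numbering vs
  UniProt numbering differ in most entries of this family (constructs
  are truncated, peptides renumbered); any mapping is the caller's
  responsibility.
* **Classification**: every atom is protein / water / hetero. Surface
  and interface calculations use protein atoms only by default;
  hydrogens are always excluded (the geometry below is heavy-atom
  based, as appropriate for crystal structures without hydrogens).
* Coordinates are Angstrom throughout; writing rejects values that do
  not fit the 8.3 fixed-width field rather than corrupting columns.

# Superposition and the iterative aligner

`kabsch` minimises the coordinate RMSD over a fixed pairing via SVD of
the cross-covariance matrix, with the determinant correction that
prevents an improper (reflecting) "rotation" in degenerate cases. The
test suite holds it to the closed-form quaternion solution at 1e-9 A
over a thousand random instances, and to exact rigid-motion invariance.

`alignStructures` handles chains without a shared numbering, the
situation of any cross-species comparison: a correspondence seed comes
from a global BLOSUM62 sequence alignment (falling back to the best
gapless sliding-window seed below 20% identity), then superposition and
re-pairing of mutually nearest Calphas within a cutoff alternate until
the pair set is stable.

* **Cutoff** 4.5 A (configurable): a common structure-alignment choice;
  large enough to keep genuinely equivalent residues across a ~2 A
  divergence, small enough to shed rearranged loops.
* **Convergence**: identical pair set on consecutive iterations;
  oscillating sets stop at the recurrence (or at `maxIter`, 50) with a
  warning rather than silently looping.
* **Tie-breaks** in pairing are by smallest residue index, so runs are
  reproducible.
* The reported pair count is a property of this algorithm; different
  aligners (DALI-style servers included) count differently, so only the
  RMSD — not `nPairs` — should be compared across programs.

A useful calibration: for a structure perturbed by iid per-axis
Gaussian noise of SD sigma, the expected unsuperposed RMSD is
sigma\*sqrt(3) (sqrt(6) when both copies are noised). After optimal
superposition the expectation drops by a factor of about
sqrt(1 - 2/N), the six rigid-body degrees of freedom the fit absorbs;
the tests use a 200-residue fixture and account for exactly this
correction, no more.

# Structure-based phylogeny

`rmsdMatrix` consumes a `StructureAlignment`: a gapped alignment whose
rows are the sequences of the *modelled* residues of each mapped chain.
The package deliberately consumes rather than produces this alignment —
structure-guided MSAs are a solved problem in dedicated tools, and the
modelled-residue convention makes column-to-Calpha mapping exact. A row
whose ungapped length disagrees with the chain's Calpha count is an
error; per-residue letter mismatches are a warning (they usually mean
an author-numbering offset).

Each matrix entry is an independent pairwise superposition (no common
reference frame), over the columns where both rows are ungapped and
both structures resolve the residue. Clustering is agglomerative via
`stats::hclust`; **average linkage (UPGMA)** is the default because it
reproduces ultrametric input exactly and is the customary choice for
distance trees when no model of rate variation is intended. Single,
complete and Ward linkage are available. Newick export uses the
ultrametric convention (leaf depth = merge height / 2), so the toy
matrix d(A,B)=2, d(A,C)=d(B,C)=6 serialises as `((A:1,B:1):2,C:3);`.

Missing pairwise entries (insufficient overlap) are an error by
default; imputation is out of scope.

# Surfaces and the interface report

`sasa` is a Shrake-Rupley quadrature: each atom's solvent-expanded
sphere (radius r + probe) carries a deterministic golden-section spiral
of test points; the accessible fraction times 4 pi (r+probe)^2 is the
atom's area.

* **Radii** (NACCESS-like): aliphatic C 1.87, carbonyl/aromatic C 1.76,
  N 1.65, O 1.40, S 1.85, default 1.80 A. **Probe** 1.4 A.
* **Points**: 960 by default. An unoccluded sphere is exact by
  construction; overlapping-sphere cases sit within 0.5% of the
  spherical-cap closed form, and doubling the point count moves
  molecular totals by <0.3% (both are asserted in the tests).
* **Orientation**: the point set is expressed in a molecule-intrinsic
  frame (Gram-Schmidt over vectors between intrinsic reference atoms),
  which rotates exactly with the molecule — SASA is therefore invariant
  under rigid motion to 1e-6 A^2. Principal axes were rejected for this
  job: helical molecules have near-degenerate covariance eigenvalues,
  making eigenvectors (and hence the quadrature) unstable.
* **Differences share one frame.** Buried areas and burial fractions
  are differences of SASA evaluations; all terms of a difference are
  computed in the frame of the full complex so quadrature error cancels
  exactly. Without this, chains 50 A apart "bury" a few square Angstrom
  of pure quadrature noise.

`buriedSurface` reports SASA(A) + SASA(B) - SASA(AB) (isolated partners
at complex coordinates). Published "buried surface" figures use either
this total or its half (the PISA-style interface area); both are
reported, and comparisons against literature values should try both
conventions.

Polar contacts are heavy-atom geometric criteria, defaults being common
practice where the underlying studies state none:

* **Hydrogen bonds**: donor-acceptor distance <= 3.5 A and
  antecedent-donor-acceptor angle >= 90 deg, over curated donor and
  acceptor atom sets (backbone N except proline, side-chain N/O/S
  donors; backbone O and side-chain O/N/S acceptors). When a donor's
  antecedent atom is missing from the model, the angle criterion is
  waived and reported as NA rather than silently discarding the pair.
* **Salt bridges**: Arg NH1/NH2/NE, Lys NZ, His ND1/NE2 against
  Asp OD1/OD2, Glu OE1/OE2 at <= 4.0 A.

`hotspotBurial` quantifies the four BH3 hydrophobic positions: for each
hot-spot residue, side-chain SASA free (isolated peptide, complex
coordinates) and complexed, burial fraction = 1 - complexed/free. The
"engaged" flag at burial >= 0.7 is exposed as data, not a claim — the
interesting biology is in the ranking (a BH3 hydrophobic that stays
solvent-exposed signals a missing pocket), and the threshold is
configurable. Glycine hot spots report zero areas with a warning.

# BH3 motif scanning

The motif model is the fixed spacing of the four conserved hydrophobics
plus the invariant acid: h1, h2 = h1+4 (the conserved leucine),
h3 = h1+7, Asp/Glu at h1+9, h4 = h1+11 — a 12-residue template (the
V71/L75/F78/D80/V82 register of a Bak-like BH3). Scoring is an additive
position weight scheme: +2 for any of {A,I,L,M,F,V,W,Y} at h1/h3/h4;
+3 for Leu at h2 (else +1 for another hydrophobic); +3 Asp / +2 Glu at
the acid position; maximum 12, default acceptance 10. The weights were
chosen once so canonical BH3 sequences score >= 10 and featureless
sequences (poly-Ala scores 7) do not; they are configurable and no
claim of proteome-scale sensitivity is made — genuinely divergent BH3
sequences can score below any fixed threshold, which is precisely why
sequence scanning alone under-detects remote homologs. Hits are
non-overlapping, best-first, ties leftmost; coordinates are 1-based
inclusive.

`peptideWindow` frames a hit the way synthetic BH3 peptides are
designed: h1 at window position 10, default length 28 (the 62-89
spanning peptide of a Bak-like sequence), 26 being the common length
for human BH3 peptides.

# ITC: model, simulation, fitting

The single-site (Wiseman) model with the MicroCal perfusion dilution
convention for an overfilled cell of working volume V0 = 204.4 ul
(nominal iTC200 working volume; configurable):

* after cumulative injected volume dV:
  [M] = M0 (1 - dV/2V0) / (1 + dV/2V0),
  [X] = X0 (dV/V0) / (1 + dV/2V0);
* cumulative heat Q = N [M] dH V0 / 2 (b - sqrt(b^2 - 4 Xr)) with
  Xr = [X]/(N [M]), b = 1 + Xr + 1/(N Ka [M]);
* measured per-injection heat
  dq_i = Q_i - Q_{i-1} + (dV_i/V0)(Q_i + Q_{i-1})/2.

One consequence worth stating: because the convention dilutes [M], the
saturating-regime cumulative heat tends to N dH [M]_final V0, not
N dH M0 V0; the textbook limit is recovered as injection volumes
shrink. The tests assert the exact identity.

The default protocol (19 x 2.0 ul of 200 uM ligand into 20 uM
macromolecule) gives c = N M0/Kd of about 308 at Kd = 65 nM — a sharp
sigmoid ideal for fitting — and about 5 at Kd = 3.76 uM, the flat low-c
regime where Kd estimates carry visibly wider spread. Simulation noise
defaults to Gaussian with SD equal to 2% of the largest clean injection
heat when `relativeNoise = 0.02` is used (instrument noise magnitudes
are rarely published; 2% keeps the strong-binder curve visually clean
while measurably widening low-c estimates).

`fitSingleSite` is Levenberg-Marquardt (minpack.lm) over
(log N, log Ka, dH, baseline) — logs enforce positivity without
constraints. Initialisation is geometric: baseline from the last three
injections, amplitude from the first, N from the molar ratio at
half-amplitude, dH from amplitude per mole injected, combined with a
Ka grid (1e5..1e8 /M) and five seeded jittered restarts; the lowest
residual sum wins. Convergence is the optimizer's info code; on top of
it a **no-binding verdict** compares the fitted curve against a flat
baseline by partial F-test (p > 0.01 means the thermogram carries no
binding signal) — this is how flat thermograms in a binding panel end
up as "NB" rows instead of absurd point estimates. Discarding the first
injection, a common instrument practice, removes its residual from the
objective while keeping its volume in the dilution bookkeeping.

Replicates aggregate as arithmetic mean +/- sample SD of Kd in nM, the
convention of binding-panel figures.

# Crystallographic arithmetic

`cellVolume` is the triclinic closed form. `solventContent` computes
the Matthews coefficient Vm = V/(z_asu MW_asu) and solvent fraction
1 - 1.23/Vm (1.23 Da/A^3 protein density convention); chain molecular
weights come from average residue masses plus one water per chain.
Vm <= 1.23 is flagged implausible rather than returned silently.

`countUniqueReflections` enumerates integer (h,k,l) against the general
reciprocal metric, applies the resolution window and centring
extinction (h+k+l even for I, h+k even for C), and merges each
Laue-group orbit (Friedel pairs included; 2/m for the monoclinic
groups, -1 for P1) to one representative before scaling by
completeness. The representative is the lexicographic extreme of the
orbit under an injective integer encoding; the count is asserted to be
identical under the "min" and "max" rules, and the P1 path is checked
against an exhaustive hemisphere enumeration. Supported groups are P1,
P2, C2, I2 — the monoclinic territory of this package's use case; other
groups raise a clear not-implemented error.

# Synthetic data: what it does and does not emulate

The generators provide geometry, not physics:

* `makeHelix` / `makeBundle`: ideal alpha-helical parameters (rise
  1.5 A, twist 100 deg, radius 2.3 A -> Calpha-Calpha 3.8 A); bundles
  place alternating-direction helices on a circle as a stand-in for the
  all-alpha Bcl-2 fold. Side chains, when requested, are idealised
  head-to-tail chains pointing radially outward with correct atom
  names — sufficient for contact detection and burial, with no
  rotamer realism.
* `makeGrooveComplex` realises a contact plan (donor-acceptor pairs,
  salt bridges, enclosed "pockets") at exact target distances and
  returns the plan as ground truth, so interface tests never re-derive
  expectations from the code under test. Placements clashing below
  1.5 A abort.
* `makeBH3Sequence` embeds the consensus template in flanks drawn from
  an alphabet that scores zero at every template position.
* ITC simulation is the exact forward model plus iid Gaussian noise.

Consequences: passing tests demonstrate correctness of the algorithms
on known geometry — they do not certify behaviour on real structures
with alternate conformations, lattice contacts, ions in the interface,
or non-ideal helices, and the ITC noise model has no baseline drift or
injection artefacts. Real-data runs reuse exactly the same code paths
(`readStructure` / `runInterface` / `runPhylo` accept any PDB file),
so the synthetic suite is evidence of implementation, not of every
property of experimental data.

Problem sizes used by the test and acceptance runs were chosen to keep
the whole suite in the tens of seconds on a single core while leaving
the statistics meaningful: 100 fitting replicates per affinity,
100-150 noise seeds for the RMSD laws, 1000 random instances for the
superposition oracle, 60-200-residue fixtures for alignment and
surfaces.

# Known limitations

* No flexible or fragment-based structural alignment; no similarity
  Z-scores. Pair counts are aligner-specific.
* SASA has no analytic derivatives and no per-atom weighting schemes;
  no electrostatics or binding-energy estimates anywhere.
* The BH3 scanner is a fixed-spacing position-weight template, not a
  trained profile; sensitivity for divergent motifs is limited by
  design.
* Reflection counting handles centring but no other systematic
  absences (screw axes affect only axial rows — a handful of
  reflections — hence the per-mille agreement observed in practice).
* The MSA contract requires modelled-residue sequences; alignments of
  full-length UniProt sequences must be trimmed by the caller first.
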