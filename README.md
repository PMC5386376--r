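# bh3struct

Structural bioinformatics and binding biophysics of Bcl-2 family
proteins in complex with BH3-motif peptides, for structural biologists
characterising receptor:peptide systems: how tightly a pro-survival
Bcl-2 fold binds a BH3 peptide (ITC), how its fold relates to other
family members (superposition and RMSD-based trees), what the bound
interface looks like (buried surface, hydrogen bonds, salt bridges,
hot-spot pockets), where BH3 motifs sit in a sequence, and whether the
crystallographic bookkeeping of such a structure adds up.

## What it computes

* **Kabsch superposition & Cα RMSD** — the optimal rigid transform
  minimising RMSD = sqrt(mean ||R x_i + t − y_i||²), plus a
  sequence-independent iterative aligner (sequence-seeded
  correspondence, mutual-nearest re-pairing within 4.5 Å).
* **Structure-based phylogeny** — pairwise Cα RMSD over equivalent
  alignment columns → distance matrix → UPGMA dendrogram → newick.
* **Shrake–Rupley SASA & interfaces** — per-atom accessible area with
  a 1.4 Å probe and NACCESS-like radii; buried area
  ΔSASA = SASA(A) + SASA(B) − SASA(AB) reported under both the total
  and the total/2 ("interface area") conventions; heavy-atom H-bond
  (≤3.5 Å, donor angle ≥90°) and salt-bridge (≤4.0 Å) detection;
  side-chain burial fractions of the four BH3 hot spots h1–h4.
* **BH3 motif scanning** — position-weight scoring of the
  h1 / h1+4 (Leu) / h1+7 / h1+9 (Asp/Glu) / h1+11 spacing template.
* **Single-site ITC** — Wiseman isotherm with the MicroCal perfusion
  dilution convention; simulation, Levenberg–Marquardt fitting of
  (N, K_a, ΔH, baseline), K_D = 1/K_a in nM, no-binding verdicts,
  replicate aggregation (mean ± SD).
* **Crystal arithmetic** — triclinic cell volume, Matthews coefficient
  V_m = V/(z·MW) and solvent content 1 − 1.23/V_m, and unique
  reflection counts by Laue-orbit merging with centring extinctions.

Synthetic generators (ideal helices, helix bundles, peptide-in-groove
complexes with planned contacts, motif-bearing sequences, simulated
titrations) make the entire suite runnable offline.

## Worked example

Fit three simulated titration replicates of a ~65 nM binder under a
19 × 2.0 µl protocol (20 µM cell, 200 µM syringe), then characterise a
toy groove complex and a monoclinic cell:

```r
library(bh3struct)

protocol   <- itcProtocol()   # 19 x 2.0 ul, 204.4 ul cell, 20/200 uM
replicates <- lapply(1:3, function(s)
  simulateTitration(itcModelParams(N = 1, kdNano = 65, dH = -10000),
                    protocol, relativeNoise = 0.02, seed = s))
fits <- lapply(replicates, fitSingleSite)
fits[[1]]
#> ITCFit: Kd 62.2 nM, N 0.998, dH -9979 cal/mol (converged)
agg <- aggregateReplicates(fits)
sprintf("Kd = %.0f +/- %.0f nM (n = %d)", agg$meanKd, agg$sdKd, agg$n)
#> "Kd = 70 +/- 7 nM (n = 3)"

g <- makeGrooveComplex("GSVAGLSAFDGVAGS", plan = list(
  list(type = "hbond",  peptideRes = 7,  dist = 2.9),
  list(type = "salt",   peptideRes = 10, dist = 3.2),
  list(type = "pocket", peptideRes = 12)))
interfaceReport(g$structure, "A", "B", hotspots = c(3, 6, 9, 12))
#> InterfaceReport: buried 890.4 A^2 (interface-area convention 445.2)
#>   2 H-bonds, 2 salt bridges, 4 hot-spot residues
```

The hot-spot table ranks side-chain burial: the planned pocket residue
(Val12) is fully enclosed (burial 1.00, engaged), the untouched
hot spots stay exposed — the same ranking logic that flags a BH3
hydrophobic left outside the groove in a real complex. The numbers are
the ones this code prints; `fitSingleSite` recovers the simulated
65 nM truth within the noise of each replicate, and the mean ± SD row
is how a binding panel reports triplicates.

Crystallographic bookkeeping for a monoclinic I-centred cell:

```r
cell <- unitCell(68.31, 51.59, 107.80, 90, 96.34, 90, spaceGroup = "I2")
cellVolume(cell)
#> 377575.9
countUniqueReflections(cell, dMin = 1.85, dMax = 41.08,
                       completeness = 0.997)
#> 31971
```

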