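# hydrokin

Analysis of how local hydration-structure changes couple to collective
domain motions in multi-domain proteins.

Large-amplitude domain motions — the opening and closing of an active-site
cleft between a mobile nucleotide-binding domain and a rigid core domain —
are driven not only by protein conformational energetics but by discrete
changes in the water structure deep inside the cleft: *wetting/drying* of a
hydrophobic pocket and stepwise *adsorption/dissociation* of individual
water molecules at a hydrophilic crevice. `hydrokin` implements the full
trajectory-analysis chain needed to quantify this coupling from molecular
dynamics (MD) trajectories, together with synthetic-trajectory generators
with known ground truth for validating every step. It is aimed at
structural bioinformaticians and simulators who want these analyses as
tested, reusable components rather than one-off scripts.

## What it computes

- **Domain PCA.** Conformations are rigid-body superposed (Kabsch) on a
  core-domain Cα set; the covariance of a mobile-domain Cα set is
  eigendecomposed. The projection on the first principal component (PC1,
  in Å, positive = open cleft) is the collective open/close coordinate;
  frames with projection > +15 Å are *open*, < −15 Å *closed*. A
  simplified screw-axis (Chasles) decomposition between the extreme
  conformations extracts the hinge axis.
- **Per-residue packing/hydration changes.** For residue *i*,
  R<sub>i</sub> = (⟨X⟩<sub>closed</sub> − ⟨X⟩<sub>open</sub>) /
  ⟨X⟩<sub>open</sub>, where X is either the side-chain
  solvent-accessible surface area (Shrake–Rupley, probe 1.4 Å) or the
  number of water molecules within 3.5 Å of any side-chain atom. Residues
  with ⟨ASA⟩<sub>open</sub> < 10 Å² are buried and excluded. Negative R
  flags packing/dehydration upon closing.
- **Solvent density maps and hydration charge Q.** Water-atom electrons
  (O = 8 e, H = 1 e) are accumulated in 1-Å voxels over a sliding 50-ps
  window (1-ps stride), after locally superposing each frame on an anchor
  helix so bulk motion does not smear the map. Q is the density summed
  over a region mask — ~10 e per fully resident water, so a crevice
  holding 3/4/5 waters plateaus at 30/40/50 e.
- **State classification and kinetics.** Snapshots are classified from
  the pocket gauges (d, Q) into wet-open / wet-half-open / dry-half-open /
  closed (or from Q alone into occupancy states); unclassifiable
  snapshots take the temporally nearest state. Residence times
  t<sub>res</sub> > 5 ps are fitted by 1 − exp(−t<sub>res</sub>/τ); 1/τ is
  the transition rate constant.
- **Height distributions.** The mobile-domain tip height along a surface
  normal (the AFM-comparable observable) is modelled as a two-Gaussian
  common-σ mixture fitted to the binned histogram.

## Worked example

```r
library(hydrokin)

# 1. synthetic two-domain protein: rigid hinge + Markov pocket hydration
template <- buildTemplateProtein()
hinge <- hingeConfig(nFrames = 300, angleOpen = 0, angleClosed = 18,
                     dwellTauOpen = 60, dwellTauClosed = 60,
                     atomNoiseSigma = 0.05, seed = 7)
protein <- genHingeTrajectory(hinge, template)
protein
#> Trajectory: 160 atoms x 300 frames, t = 0..299 ps

# 2. domain PCA: superpose on the fixed domain, analyse the mobile one
model <- fitPCA(protein, selectAtoms(protein, chain = "C"),
                selectAtoms(protein, chain = "N", elety = "CA"))
model
#> PCAModel: 16 analysis atoms, 48 components; PC1 fraction 0.998
proj <- projectPCA(model, protein)
summary(proj[, 1])
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#> -15.869 -15.404   5.347   0.000   5.444   5.665

# 3. residence-time kinetics from synthetic dwell samples
dwells <- genDwellTimes(57, 5000, tMin = 5, seed = 7)
fitRate(dwells, "wet_half_open", "dry_half_open", tMin = 5)
#> RateEstimate wet_half_open -> dry_half_open: tau = 57.53 ps
#>   (rate 0.01738 ps^-1, n = 5000)
```

The one-degree-of-freedom hinge concentrates 99.8% of the analysed
variance in PC1; the projection is bimodal (closed frames near −15.6 Å,
open frames near +5.4 Å, the two telegraph states), and the fitted
residence time recovers the generating 57 ps within one standard error
(57/√5000 ≈ 0.8 ps).

`runPipeline()` chains all stages (simulation → PCA → density/Q →
kinetics → heights) from one (optionally YAML) config, writes per-stage
TSV plus a JSON summary carrying the seed and a config hash, and is
bit-reproducible under a fixed seed.

## Scope notes

- The crystal-ensemble PCA check needs the PDB entry `1EUZ`, which is not
  redistributed here; place `1EUZ.pdb` under `inst/extdata/` before
  installing to enable it.
- MD itself (force fields, solvation, PME) and raw AFM image processing
  are out of scope; see the methods vignette
  (`vignettes/hydration-dynamics.Rmd`) for the model details, parameter
  choices and known limitations.
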