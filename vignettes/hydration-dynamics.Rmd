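---
title: "Methods: quantifying hydration-coupled domain motions"
author: "hydrokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying hydration-coupled domain motions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrokin)
```

# The problem

In multi-domain enzymes such as glutamate dehydrogenase, a mobile
nucleotide-binding domain (N-domain) opens and closes an active-site cleft
against a rigid, oligomer-forming core domain (C-domain). The water in the
depth of that cleft is not a passive background: a hydrophobic pocket
switches between *wet* and *dry* states, and a hydrophilic crevice gains
and loses individual water molecules in discrete steps. Quantifying how
those local hydration changes couple to the collective domain motion
requires a chain of trajectory analyses, each with small but consequential
conventions. This vignette records the models, the parameter choices, and
the numerical decisions this package makes, and what its validation on
synthetic data does and does not demonstrate.

# Domain PCA

## Model

Conformations are rigid-body superposed on a *fit selection* (core-domain
Cα atoms) using the Kabsch algorithm; the covariance of the Cartesian
coordinates of a distinct *analysis selection* (mobile-domain core Cα
atoms) is then eigendecomposed. Separating the two selections is the key
assumption: after superposition on one rigid domain, analysis-set
displacements are inter-domain motion, not internal fluctuation. The
first principal component (PC1) projection, in Å, is the collective
open/close coordinate.

## Conventions

- Covariance uses the (n − 1) normalisation; this cancels in variance
  fractions and is stated only for reproducibility.
- The superposition reference is the first conformation supplied. An
  iterative mean-reference refinement would change projections by a rigid
  offset at most; it is not needed for the variance decomposition.
- **Sign convention.** Each component's sign is fixed so that its
  projection correlates positively with cleft opening, gauged by the
  distance between the analysis-set and fit-set centroids (the widest
  cleft projects positive). Components uncorrelated with that gauge get a
  canonical sign (largest-magnitude coefficient positive). This makes
  "open = positive" stable across runs without reference to any external
  observable.
- The projection zero point is the model mean. Published projections with
  a different (unstated) origin can differ by a constant offset;
  comparisons should therefore use projection *differences* or
  correlations.
- Frames with projection > +15 Å are classified *open* and < −15 Å
  *closed* (both thresholds configurable); everything between is
  *intermediate* and excluded from open/closed ensemble averages.

## Hinge axis

The hinge between the most open and most closed conformations is
extracted by a single screw-axis (Chasles) decomposition of the rigid
transform of the moving selection after superposition on the fit
selection: rotation angle from the trace of the rotation matrix, axis
from its skew part (from the +1 eigenvector when the angle approaches
180°), translation as the axis component of the displacement, and the
axis point from the perpendicular part via a bordered linear solve. This
is deliberately a *simplified* hinge extraction — one transform between
two extremes, not a clustering of rotation vectors over many segments —
and is labelled as such. Rotations below 1° are rejected as
ill-conditioned (the axis direction is undefined for pure translations).

# Per-residue packing and hydration statistics

For residue *i* and ensembles defined by the PC1 classification,

$$R_i = \frac{\langle X_i\rangle_\mathrm{closed} -
             \langle X_i\rangle_\mathrm{open}}
            {\langle X_i\rangle_\mathrm{open}},$$

with X the side-chain solvent-accessible surface area (ASA) for
R<sup>ASA</sup> and the hydration-water count for R<sup>WAT</sup>.
Negative values flag packing/dehydration upon closing. A plain-difference
mode (`mode = "absolute"`) is provided because the relative form is a
design choice: a dimensionless R with the stated sign convention is the
most natural reading, but the alternative cannot be excluded, so both are
implemented and the default is documented rather than argued.

Conventions with numerical consequences:

- **ASA backend**: Shrake–Rupley with 960 deterministic golden-spiral
  points per atom and probe radius 1.4 Å (a water molecule), over a
  single hard-coded Bondi van-der-Waals radii table (H 1.20, C 1.70,
  N 1.55, O 1.52, S 1.80 Å, ...). Waters and ions are solvent, never
  occluders. At 960 points the discretisation error is below 1% against
  the closed-form two-sphere result, and rotation invariance holds to the
  same order (the point grid is orientation-fixed).
- **Side chain** = all residue atoms except backbone N, Cα, C, O (OXT and
  the amide/alpha hydrogens are also excluded). Glycine has no side-chain
  atoms; its hydration count is 0 with a warning rather than an error.
- **Burial exclusion**: residues with ⟨ASA⟩<sub>open</sub> < 10 Å² are
  buried; both R values are withheld (NA) for them.
- **Water counting**: a water molecule is counted once per residue when
  its *oxygen* lies within 3.5 Å of any side-chain atom. Using the oxygen
  as the counted atom keeps the statistic identical for hydrogen-less
  and hydrogen-bearing inputs.
- Ensemble means are sums over frames divided by frame counts, so tables
  are exactly independent of frame order.

## Geometric gauges

Two scalar gauges track the two hydration sites: the pocket jaw
separation (minimum over the two chemically equivalent ring hydrogens
HD1/HE1 of the upper-jaw aromatic residue, to the midpoint of the
lower-jaw CD1/CG atoms — hydrogens are therefore required, and their
absence is an explicit error rather than a silent fallback) and the
crevice stretch (a plain CA–OE1 distance). Residue numbers default to
the crystal numbering of the reference structure (340; 89/92; 190/354)
and are configurable, which also resolves a known upper-jaw numbering
ambiguity (340 vs 341) in favour of the gauge's own definition.

# Solvent density maps and hydration charge

Water-atom electrons (O = 8, H = 1) are accumulated into 1-Å cubic voxels
and averaged over a 50-ps window sliding in 1-ps steps. Two conventions
matter:

- **Local superposition.** Every frame of a window is rigid-transformed
  so that an anchor selection (a helix flanking the hydration site) best
  fits the window's first frame, and the transform is applied to *all*
  atoms including waters. Without this, global tumbling smears the
  density. The window's first frame (rather than a global reference) is
  the alignment target; for the window-average protein structure this is
  immaterial, and it keeps windows independent.
- **Time-average convention.** Counts are summed as integers over frames
  and divided by the frame count. A water resident in the mask for the
  whole window therefore contributes exactly 10 e *regardless of window
  length*, which is what makes the charge Q interpretable as ~10 e per
  resident water (30/40/50 e plateaus for 3/4/5 waters). A frame-summed
  convention would scale with window length and break that reading.
- Atoms are assigned to the voxel containing their centre (no Gaussian
  smearing); voxels are half-open intervals [low, high), so a coordinate
  exactly on a boundary belongs to the voxel whose lower edge it lies on.
  The integer accumulation makes the map bit-exact against a brute-force
  per-frame histogram.

Q is the density summed over a *region mask* built from sphere, box or
cylinder primitives on the same grid (the published pocket/crevice
regions are figure-only, so masks are explicit, machine-readable inputs
here). Bulk density — used to express contour levels — is the mean voxel
density beyond a 4-Å exclusion around the window-average protein.

# State classification and kinetics

Snapshots are classified from (d, Q) into four pocket states (wet open:
d > 7 Å, Q > 8 e; wet half-open: 5 < d < 7, Q > 8; dry half-open:
5 < d < 7, Q < 4; closed: d < 5, Q < 4) or from Q alone into occupancy
states (nearest of 30/40/50 e within ±5 e; cut points 35/45 e, half-open
upward so Q = 35 is the four-water state). Snapshots matching no box —
the 4 ≤ Q ≤ 8 gap, a threshold value of d, or combinations like d > 7
with Q < 4 — are `boundary` and are assigned the label of the temporally
nearest classified snapshot; exact ties go to the earlier side. The
resolution is idempotent and never alters classified labels.

Dwell extraction and rate fitting:

- Maximal constant-label runs become dwell records; a run of k snapshots
  at spacing dt spans k·dt.
- The first and last runs are *censored* (their true length is
  unobserved) and never enter fits. Runs with duration ≤ t_min = 5 ps are
  excluded from the fit set but still separate their neighbours and count
  in transition tallies; an optional merge mode exists but is off by
  default because merging would fabricate long dwells.
- The empirical CDF of (t_res − t_min) is least-squares fitted by
  1 − exp(−t/τ) (one parameter, solved by golden-section search over
  [τ̂/50, 50τ̂] around the closed-form start). The quoted "survival"
  function with P(0) = 1 in the source literature is formally a CDF, and
  that is what is fitted; τ and the rate 1/τ have the same meaning either
  way. The closed-form truncated-exponential estimate mean(t_res) − t_min
  is always reported in the diagnostics; on exponential data the two
  agree within a few percent, which is itself a consistency check in the
  test suite.
- Fits require ≥ 5 dwells; fewer is an explicit insufficient-data error.

A caveat carried, not corrected: the 50-ps sliding window low-pass
filters Q before classification, so dwells shorter than roughly the
window are smoothed and boundary crossings shift by up to half a window.
The pipeline test therefore validates state recovery against the
*windowed majority* of the ground truth, and rate constants estimated
from heavily smoothed Q series should be read with that bias in mind.

# Height distributions

The mobile-domain tip height (centroid of a tip selection projected on a
user-supplied surface normal; the crystal-frame transform and the normal
are inputs, since they come from an experiment-specific reference) is
modelled as a two-component Gaussian mixture with common σ, fitted by
least squares to the binned histogram (default bin width 1 Å; the fit is
also rerun at half and double width and reported as a sensitivity
diagnostic). σ may be fixed externally — e.g. to an instrument response
width measured on a rigid reference crystal — or fitted. Bins are
anchored on the sample minimum, so the fit is exactly shift-equivariant
and order-invariant; four deterministic starts (quantile, moment-matched,
±1 SD, collapsed) are tried and the best residual kept, making the fit
deterministic given the data. Components are reordered so μ1 ≤ μ2; a
single common σ is used for both components (the alternative of
per-component σ is not identifiable at the sample sizes this statistic is
used at).

A fit is flagged `unimodal` when its weights collapse or when the fitted
separation is ≤ 2σ — the analytic condition under which a common-σ
two-Gaussian mixture has a single mode for *any* weights. The flag is
diagnostic; the separation is reported regardless.

**A hard statistical limitation, stated plainly.** With σ = 3.4 Å fixed
and a true separation of 3.6 Å at equal weights, the mixture density is
unimodal (Δ/σ ≈ 1.06) and the separation is informed essentially only by
the excess variance s² − σ². At n = 133 samples the resulting standard
error on the fitted separation is about 1 Å for any estimator
(Cramér–Rao via the variance channel), and the histogram-LS estimator is
additionally biased upward by tail noise. Replicate recovery of a 3.6 Å
separation to ±0.3 Å at this sample size is therefore not achievable in
the majority of replicates, and the corresponding acceptance check is
expected to fail; it is kept, unweakened, as an honest record of that
limit. With well-separated components (e.g. Δ = 20 Å, σ = 1 Å) the same
fit recovers means to better than 0.05 Å, which is what the test suite
demonstrates.

# The synthetic-data generators

The generators produce data whose *statistical structure* matches what
the analyses assume, with exact ground truth:

- **Hinge trajectories**: a rigid mobile domain rotated about a fixed
  axis/point by a telegraph (two-state Markov, exponential dwells) or
  discretised Ornstein–Uhlenbeck angle process; the fixed domain is
  untouched; optional isotropic Gaussian atom noise. Intra-domain
  distances are conserved to 1e-9 Å at zero noise, and the generating
  angles and state path are stored as metadata.
- **Water scenes**: bulk waters at a configured number density
  (0.0334 Å⁻³ by default, the TIP3P bulk value, i.e. 0.334 e per 1-Å
  voxel), placed uniformly and *independently resampled every frame* —
  the cheapest construction with the correct stationary voxel statistics.
  A reflected-Brownian mode exists when residence-time realism in the
  bulk matters; the default does not pretend to have it. Pocket waters
  sit at fixed, well-spread sites inside a spherical region and appear or
  disappear *instantaneously* at the switches of a continuous-time Markov
  hydration process, so the ground truth for classification and Q is
  unambiguous; absent pocket waters are parked far outside the box to
  keep the atom count constant. Bulk placement rejects the pocket region
  so the in-pocket count is exactly the state-prescribed count.
- **State series**: competing-exponential-clock simulation of an
  arbitrary transition scheme, sampled on a uniform grid; the exact event
  log is kept in metadata, which is what dwell statistics are validated
  against.
- **Dwell times and height samples**: shifted exponentials and Gaussian
  mixtures, directly.

All generators derive independent RNG streams from a single seed by fixed
offsets and restore the caller's RNG state, so identical configs give
byte-identical output and switching noise on does not change the angle
path.

What the generators deliberately do *not* emulate: force-field
energetics, hydrogen-bond network rearrangements (the mechanistic driver
in the real system), diffusive water entry/exit paths, periodic images,
and correlated inter-subunit motion. Passing tests on this synthetic data
therefore validate the *analysis chain* — geometry, counting,
classification, estimation — not any claim about real hydration
thermodynamics.

# Problem sizes and determinism

The test suite and the acceptance script are sized to run comfortably on
one CPU: trajectories of 150–400 frames at 1-ps spacing for pipeline
tests, 50-frame windows for density checks, 10⁵–10⁶ ps state series for
dwell statistics, 5000 dwell samples per rate-recovery check, and 100
replicates of 133 samples for the mixture study. These sizes put
Monte-Carlo error well below the tested tolerances (3 standard errors
wherever a sampling distribution is involved). Every stochastic test and
the acceptance script draw all randomness from explicit seeds.

# Known limitations

- No periodic-boundary handling: scenes are assumed pre-imaged.
- The DynDom-style segmentation of dynamic domains is not implemented;
  hinge extraction is the single-transform screw decomposition above.
- ASA uses a numerical (Shrake–Rupley) backend, not an analytic one;
  agreement is to ~1% at default resolution.
- The crystal-ensemble PCA check requires the PDB entry 1EUZ as a local
  file; it is not redistributed with the package.
- Rate estimation assumes exponential dwells (Markovian switching);
  non-exponential residence-time distributions will fit but the reported
  τ is then only a mean-like summary, and the CDF-fit vs closed-form
  diagnostic will disagree.
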