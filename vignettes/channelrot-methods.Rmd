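---
title: "Methods: contacts, rotation, fluctuations and the fitting stack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contacts, rotation, fluctuations and the fitting stack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(channelrot)
```

`channelrot` analyses structural ensembles of C4-symmetric
homotetrameric channels — HCN pacemaker channels being the motivating
case — together with the patch-clamp and cPCF fitting procedures used
alongside them. This vignette explains each method, its assumptions,
the tunable parameters and their defaults, the numerical choices, and
what the synthetic-data generators do and do not emulate.

## The ensemble model

An ensemble couples a *topology* (atom names in PDB convention, residue
numbers, subunit indices 0–3) with a stack of coordinate frames and a
replica id per frame. Subunits are mapped from chain IDs by an explicit
user map (default A→0 … D→3): structure files do not record which chain
plays which role in a published figure, and for a C4 tetramer only the
relative relations matter — the opposite subunit of *i* is (*i*+2) mod
4, the adjacent one (*i*+1) mod 4. Frames carry no absolute time:
no analysis here uses time units, so frame spacing (e.g. 200 ps in a
typical production run) is left as external metadata. Coordinates are
always in Ångström; multi-model PDB is read and written at the format's
3-decimal precision, one file per replica with the replica id in a
`_rep<k>` suffix.

## Contact occurrence frequencies

A hydrogen bond is scored per frame by the common geometric criterion:
donor–acceptor heavy-atom distance ≤ 3.5 Å *and* donor–H–acceptor
angle ≥ 120°. Both cutoffs are parameters of `contact_definition()`;
the defaults are the field-standard values and were not tuned.
Hydrogens are attached to their donor by the PDB naming convention
(donor `NZ` owns `HZ1…HZ3`), with a geometric fallback (any hydrogen of
the residue within 1.2 Å). Three deliberate semantics:

* **"Any combination" counting.** A frame is bonded when at least one
  (donor atom, hydrogen, acceptor atom) triple passes. This matches
  residue-level occupancy reporting; per-atom occupancy matrices are a
  non-goal.
* **Four symmetric placements.** Every contact is scored for all four
  donor subunits against their role partner (i+1 or i+2), giving
  4 × replicas values; the summary mean ± SEM uses that n.
* **Degenerate geometry.** A hydrogen coincident with its donor makes
  the angle undefined; the criterion then fails for that hydrogen.

Salt bridges reuse the same machinery on the charged groups (side-chain
N donors of Lys/Arg/His, carboxylate O acceptors of Asp/Glu). Whether a
salt-bridge criterion should include the angle term is genuinely open;
both modes are provided (`angle = FALSE` drops it) and the mode is
flagged in the result. Models without hydrogens are handled by a
distance-only mode, also flagged.

## The CL–CNBD rotation metric

The rotation of the intracellular C-linker/CNBD layer about the pore
axis is quantified as a four-point dihedral between centroids
("centre of mass" is computed as the unweighted Cα centroid — over
selections of four identical residues, mass weighting changes nothing
material):

* **I** (static, per subunit): centroid of the Cα atoms of the elbow
  terminal residues, default 460–463 (the A′-helix tip in mHCN2
  numbering), taken from the starting structure;
* **II/III** (static): centroids of the Cα atoms of the upper (436)
  and lower (432) pore residues over all four subunits — for a
  symmetric channel these sit on the pore axis;
* **IV** (dynamic): the same elbow centroid evaluated per frame.

Point I must be per subunit: pooling it over the four subunits would
put it on the axis and a C4-symmetric rotation would cancel out of the
metric. Before measuring, each frame is superimposed onto the starting
structure by a least-squares rigid fit (rotation + translation, no
scaling or reflection; SVD formulation with determinant correction)
over the pore Cα atoms. The pore selection defaults to the S6 stretch
spanning the gate region, residues 428–444 on all subunits, and is
configurable — the method only needs a rigid, state-insensitive
anchor. The dihedral itself uses the atan2 formulation, stable near 0°
and 180°.

**Sign convention.** The raw I–II–III–IV dihedral (with II the upper
pore point) returns −θ for a rotation by +θ about the outward
(extracellular) axis. The reported angle is the negated dihedral, so
that rotations appearing clockwise when viewed from the intracellular
side are positive; `clockwise_positive = FALSE` restores the raw
dihedral. The convention is pinned by a generator closure test: an
exact +5° axial rotation of the elbow block must measure +5.000°.

Per-frame angles are averaged within each (subunit, replica) and the
grand mean ± SEM is taken over those n = 4 × replicas values. Treating
the four subunits of one trajectory as independent is a
pseudo-replication choice inherited from common practice; the
statistics module exposes a replica-collapsed variant
(`summarize_sample(collapse_replicas = TRUE)`, n = replicas) so the
choice stays visible. Angles can be measured against any user-chosen
reference structure; which differences (to the starting structure, or
between state averages) to report is left to the caller.

## RMSF and significance-masked ΔRMSF

Side-chain mobility is the residue-wise RMSF over all heavy side-chain
atoms. Frames are aligned per replica onto the replica-average
structure (two-pass: align to the first frame, average, re-align to
the average) over the pore Cα selection — the same frame of reference
as the rotation analysis. Whether the reference positions should be
per-replica or pooled across the ensemble is open; per-replica is
primary here, consistent with treating replicas as independent
measurements. A residue's RMSF is the unweighted mean of its atoms'
RMSF values rather than a pooled-atom RMS: it is less dominated by
large side chains. Glycine and residues without selected atoms are
omitted, not zero-filled.

ΔRMSF between a reference state and another state is computed per
residue from the subunit × replica samples: a two-sample t-test
(Welch by default; the pooled-variance Student variant is available to
match legacy tooling), and the difference of means
RMSF_ref − RMSF_other is reset to zero when p ≥ α (default 0.05, raw
per-residue p-values, no multiplicity correction — the masking is a
display filter, not an inference claim). Negative unmasked values mean
the residue is more mobile in the other state. Antisymmetry (swapping
the arguments flips unmasked signs and preserves the mask) and the
null calibration (≈ 1 − α of residues masked on same-noise ensembles)
are tested properties.

Gate geometry uses the Cβ–Cβ distances of the two opposite pairs of
each gate residue (I432, T436, Q440), n = 2 pairs × replicas, plus the
gate residues' side-chain RMSF.

## The fitting stack

All nonlinear fits use unweighted Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`); no robust loss is applied by default since the
generators and typical recordings have homoscedastic noise.

* **Boltzmann.** I/I_max = amp / (1 + exp(zδF(V−V_1/2)/RT)), V in mV,
  fitted per recording after normalising tail currents by the
  largest-magnitude amplitude (which keeps inward, negative currents
  well-defined). The temperature is not identifiable from the data and
  defaults to 293.15 K (room-temperature oocyte recordings); the
  fitted zδ equals slope × RT/F and scales proportionally with the
  assumed T, so the value used is recorded in every fit. Parameters of
  separate recordings are averaged afterwards; ΔV_1/2 is the
  difference of mean V_1/2 with SEM propagated as the root sum of
  squares (a paired-patch mode is not provided; patches are
  independent here).
* **Exponential.** I(t) = I_inf + A·exp(−(t−delay)/τ) on t ≥ delay.
  The auto delay policy detects the first crossing of 10% of the
  signal span and then back-extrapolates the fitted exponential to the
  pre-delay baseline, which removes the threshold lag exactly for
  noiseless traces. A fixed numeric delay can be given instead.
* **Hill.** F/F_max = 1/(1 + (BC_50/c)^H), amplitude fixed at 1, fitted
  once to the *averaged* concentration–binding relationship (not per
  patch) — binding data are typically too sparse per patch for stable
  individual fits. The model equals 0.5 at BC_50 by construction.
* **cPCF subtraction.** The scale factor s = mean(green)/mean(red)
  over bath ∪ pipette (free-dye regions only) is applied to the red
  reference image before subtraction; the mean corrected dome
  intensity over F_max is the bound fraction. The result is invariant
  to rescaling the red channel and to adding any multiple of red to
  green; negative raw ratios are reported as 0 with a `clipped` flag
  and the raw value retained.

## The synthetic-data generators

The generators exist so that every analysis stage has a closure test —
analyse(generate(truth)) ≈ truth — without any external downloads.

`build_toy_tetramer()` constructs a miniature C4-symmetric tetramer of
~39 residues per subunit. It keeps the mHCN2 residue numbers for the
labelled residues (M155; E243/D244/E247; the S6 stretch 428–444 with
gate residues 432/436/440; the elbow 458–464 with K464) inside a
sparse chain, so analyses run unchanged on toy and real numbering. The
gate Cβ ring sits exactly at `pore_radius` (opposite distance = 2
`pore_radius`), and K464's NZ (with a collinear HZ1) faces the
backbone O of M155 of the opposite subunit at `contact_distance`
(default 2.9 Å). The full 515-residue architecture, secondary
structure, and physical packing are deliberately absent: analysis code
is size-agnostic and the tests must run in seconds.

`generate_rotated_ensemble()` rotates each subunit's CL block about
the pore axis by angles drawn independently per (frame, subunit) from
N(mean, sd) and adds isotropic per-atom Gaussian noise with
per-residue amplitudes; pore atoms receive noise only. The noise model
has no covariance structure and no physical dynamics — it is exactly
what the RMSF/rotation closure tests need and no more, so a passing
test demonstrates correctness of the estimators, not realism of the
dynamics. `generate_contact_trajectory()` scripts Bernoulli contact
occupancy by placing the acceptor either in bonded geometry (2.9 Å,
170° by exact construction) or at 6 Å. The ephys generators draw
Boltzmann tail amplitudes, delayed-exponential traces and Hill
binding data with Gaussian noise, and the cPCF generator composes
green = s·red + dome-only bound signal + noise.

Default generator conditions mirror the study design they emulate: 20
replicas, 9 command voltages from −150 to −70 mV in 10 mV steps, 2%
relative noise on tail amplitudes and binding data, saturating
concentration 2.5 µM. Frame counts per replica (100 for rotation
recovery, 2000 for Bernoulli/RMSF convergence) were chosen once so
that stochastic recovery tolerances (3 SEM; binomial 99% CI; 2% on the
RMSF closed form) are meaningful at desk scale. Random streams are
split per replica (seed × 10⁴ + replica), keeping replicas independent
yet bit-reproducible.

## Numerical choices and degenerate inputs

* Superposition needs ≥ 3 non-collinear atoms; collinear selections
  raise a geometry error rather than returning a reflected fit.
* A dihedral with point IV on the II–III axis is undefined and raises
  an error, as does a zero-length axis (point II = point III).
* Two zero-variance samples with equal means give p = 1 by convention
  (no evidence of difference); with unequal means, p = 0.
* Multi-model PDB files are pre-validated: models with differing atom
  counts are rejected with the offending model index.
* Boltzmann fits on data rising toward depolarisation emit a
  sign-convention warning; Hill fits on constant responses error.

## Known limitations

* The toy generator's Gaussian noise cannot produce correlated
  backbone/side-chain motion, anharmonicity, or state transitions;
  recovery tests bound estimator error, not force-field fidelity.
* Contact criteria are purely geometric; π-stacking, cation–π and
  water-mediated bridges are out of scope.
* The n = 4 × replicas convention treats subunits as independent;
  use the replica-collapsed summaries when that assumption is in
  doubt.
* No multiple-testing correction is applied in ΔRMSF masking; with
  ~500 residues, ~25 false positives at α = 0.05 are expected and the
  masked table should be read accordingly.
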