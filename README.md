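# channelrot

Quantitative post-processing for structural ensembles of homotetrameric
HCN-type pacemaker channels, together with the electrophysiology and
confocal patch-clamp fluorometry (cPCF) fitting stack that accompanies
such studies. The package is aimed at people analysing MD ensembles of
C4-symmetric ion channels (stored as multi-model PDB, one model per
frame, one file per replica) and the matching oocyte patch-clamp /
cPCF recordings.

## What it computes

**Inter-subunit contact occurrence frequencies.** A hydrogen bond (or
salt bridge) between a donor residue on subunit *i* and an acceptor on
the adjacent (*i*+1) or opposite (*i*+2) subunit is scored per frame
with the standard geometric criteria

> d(D, A) ≤ 3.5 Å and ∠(D, H, A) ≥ 120°,

a frame counting as bonded when any donor-atom/hydrogen/acceptor-atom
combination passes. The occurrence frequency is the bonded fraction of
frames, reported per symmetric placement (4 per tetramer) and replica,
and summarised as mean ± SEM over n = 4 × replicas.

**CL–CNBD rotation angle.** The rotation of the C-linker/cyclic
nucleotide-binding domain about the pore axis is measured as the
four-point dihedral I–II–III–IV, where I is the static per-subunit
centroid of the Cα atoms of the A′-helix terminal residues (460–463 in
mHCN2 numbering) in the starting structure, II and III are the static
centroids of the Cα atoms of the upper/lower pore residues (T436, I432)
over all four subunits, and IV is the per-frame elbow centroid after
superimposing the channel pore (least-squares rigid fit on pore Cα
atoms) onto the starting structure. Positive angles are clockwise
viewed from the intracellular side.

**Significance-masked ΔRMSF.** Residue-wise side-chain RMSF (all heavy
side-chain atoms, frames aligned per replica to the replica-average
structure) is compared between states per residue by a two-sample
t-test over the subunit × replica values;

> ΔRMSF = RMSF_ref − RMSF_other, reset to 0 where p ≥ α (α = 0.05),

so only significant mobility changes survive.

**Gate metrics.** Opposite-subunit Cβ–Cβ distances of the gate-forming
residues (I432, T436, Q440), two pairs per frame, n = 2 × replicas;
plus side-chain RMSF of the gate residues.

**Fitting stack.** Steady-state activation: Boltzmann
I/I_max = I/I_max,satV / [1 + exp(zδF(V−V_1/2)/RT)] fitted per
recording; ΔV_1/2 with propagated SEM. Activation/deactivation time
courses: delayed single exponential I(t) = A·exp(−t/τ). Concentration–
binding: Hill F/F_max = 1/[1 + (BC_50/[agonist])^H] fitted to averaged
data. cPCF: the red reference-dye image is scaled on the green channel
over bath + pipette and subtracted; the corrected dome intensity over
F_max gives the bound fraction.

A synthetic-data module generates miniature C4-symmetric tetramers,
ensembles with prescribed rotation/noise/contact occupancy, and
Boltzmann/exponential/Hill-governed recordings with known ground truth,
so every stage has a closure test.

## Worked example

```r
library(channelrot)

start <- build_toy_tetramer()                    # miniature C4 tetramer
apo   <- generate_rotated_ensemble(start, n_replicas = 6, n_frames = 25,
                                   rotation_mean = 3.45, rotation_sd = 1,
                                   noise_amplitude = 0.05, seed = 111)
k464e <- generate_rotated_ensemble(start, n_replicas = 6, n_frames = 25,
                                   rotation_mean = 0.52, rotation_sd = 1,
                                   noise_amplitude = 0.05, seed = 112)

rep <- run_compare(
  states   = list(apo = apo, k464e = k464e),
  starts   = list(apo = start, k464e = start),
  contacts = list(list(donor_res = 464, donor_atoms = "sidechain-N",
                       acceptor_res = 155, acceptor_atoms = "backbone-O")))
rep
#> compare_report (reference state: apo )
#>  state              metric       mean         sem  n
#>    apo        rotation_deg   3.531487 0.043888874 24
#>    apo contact_464_155_pct  99.000000 0.496363588 24
#>    apo  gate_432_cb_dist_A   9.997834 0.003917316 12
#>    apo  gate_436_cb_dist_A  10.002351 0.005660156 12
#>    apo  gate_440_cb_dist_A  10.005050 0.003052258 12
#>  k464e        rotation_deg   0.507072 0.038486150 24
#>  k464e contact_464_155_pct 100.000000 0.000000000 24
#>  k464e  gate_432_cb_dist_A  10.001293 0.003216189 12
#>  k464e  gate_436_cb_dist_A  10.001573 0.003939165 12
#>  k464e  gate_440_cb_dist_A  10.004404 0.002741016 12
#> apo vs k464e: rotation p = 6.4e-42 (*); 3 residues unmasked in dRMSF
```

The rotation rows recover the generator truths (3.45° and 0.52°; mean ±
SEM over n = 4 subunits × 6 replicas) and the t-test flags the ~2.9°
difference. The built-in K464→M155 hydrogen bond (placed at 2.9 Å in
the starting structure) survives these few-degree elbow rotations in
both states — contact loss is scripted explicitly through
`generate_contact_trajectory()` when a prescribed occupancy is wanted.
Gate Cβ–Cβ distances sit at the constructed 10 Å diameter. ΔRMSF
unmasks 3 of 39 residues, the expected false-positive count at
α = 0.05 for two states sharing one noise amplitude.

```r
g <- generate_activation_traces(V_half = -100.6, z_delta = 4,
                                noise_sd = 0.02, n_recordings = 1, seed = 1)
fit_boltzmann(g$recordings[[1]]$voltage_mV,
              normalize_tail_currents(g$recordings[[1]]$rel_tail))
#> Boltzmann fit: V1/2 = -100.62 mV, z_delta = 4.02, amp = 0.999 (T = 293.15 K)
```

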