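# strucdyn

Quantitative structural-dynamics analysis for multi-domain protein
complexes, written in base R.

Hsp70 chaperones such as human mitochondrial mortalin (HSPA9) release
ADP and substrate with the help of a GrpE-family nucleotide exchange
factor (GrpEL1). Understanding that mechanism from cryoEM models and MD
simulations requires a recurring set of measurements: how far a
subdomain rotates between two conformations, how much a long α-helical
stalk bends, which residues form an interface and how much surface it
buries, which low-frequency collective motions an elastic network
predicts, and how an anchor-defined angle in a trajectory partitions
into conformational substates. `strucdyn` packages exactly that
workflow for structural biologists and simulators working on Hsp70/NEF
systems (or any multi-domain complex), with seeded synthetic generators
so every stage can be validated against known ground truth.

## What it computes

* **Superposition and RMSD.** Kabsch least-squares fitting: for paired
  coordinate sets *P*, *Q* the proper rotation *R* and translation *t*
  minimizing `RMSD = sqrt(mean ||R p_i + t − q_i||²)`, via SVD of the
  covariance matrix with the reflection branch corrected. Per-domain
  RMSD series over trajectories align each frame on the domain itself
  (removing collective motion so internal flexibility is measured), as
  in the standard per-subdomain stability analysis of Hsp70/NEF
  simulations.
* **Rotation, bend and displacement.** After aligning two structures on
  a reference region, subdomain rotation is the rotation-magnitude
  `θ = acos((tr R − 1)/2)` of the rigid fit between probe selections
  (or the angle between the probe helices' principal axes); stalk bends
  are angles between segment principal axes; centroid displacement is
  measured after the same alignment.
* **Interfaces.** Shrake–Rupley solvent-accessible surface area with a
  deterministic golden-spiral point lattice; buried surface area
  `BSA = SASA(A) + SASA(B) − SASA(A∪B)` (reported both as the total and
  the per-interface half); residue contacts classified as salt-bridge
  (≤ 4.0 Å between oppositely charged side-chain groups),
  hbond-capable (N/O ≤ 3.5 Å) or van der Waals (≤ 4.5 Å).
* **Anisotropic network model.** From-scratch Cα ANM: Hessian with
  off-diagonal super-elements `−γ (r_ij r_ijᵀ)/|r_ij|²` for pairs
  within a 10 Å cutoff, eigendecomposition with the six rigid-body
  modes excluded, the 10 lowest non-rigid modes retained by default,
  all-atom mode extension, mean-square fluctuations
  `MSF_i = Σ_k |u_{k,i}|²/λ_k` and normalized cross-correlations.
* **Trajectory angle analysis.** Per-frame angles between anchor-atom
  vectors (e.g. the Cα 569→597 lid vector against the Cα 569→98 vector
  into the partner β-wing), Gaussian-kernel density curves, and
  substate occupancies over published angular ranges, with printed
  gapped ranges (… 95.9 | 96 …) converted to contiguous bins at gap
  midpoints.

## Worked example

Generate a 5000-frame synthetic trajectory whose lid-motion angle
occupies three substates at 55/30/15 %, then recover the substate
structure, the domain RMSD, and an elastic-network model:

```r
library(strucdyn)

top <- make_two_domain_complex(25, 25, 30, seed = 1)
v1 <- vector_definition("v1", c("A", 3, "CA"), c("A", 23, "CA"))
v3 <- vector_definition("v3", c("A", 3, "CA"), c("B", 12, "CA"))
spec <- substate_gen_spec(centers = c(87, 100.5, 119.5),
                          widths = c(1.5, 1.5, 1.5),
                          occupancies = c(0.55, 0.30, 0.15),
                          n_frames = 5000, seed = 1)
traj <- make_angle_trajectory(top, list(v1, v3), spec)

ser <- angle_series(traj, v1, v3)
regions <- region_boundaries_from_printed(
  list(c(78, 95.9), c(96, 105), c(105.1, 134)))
substate_occupancy(ser, regions)
#> substate occupancy (5000 frames):
#>   region1       55.40 % (2770 frames)
#>   region2       30.00 % (1500 frames)
#>   region3       14.60 % (730 frames)
kde_mode(angle_kde(ser))
#> [1] 86.83038

dom <- domain_definition("partner_B", "B", c(1, 25))
rms <- domain_rmsd_series(traj, select_atoms(traj$topology, dom))
sprintf("%.2f +/- %.2f A", attr(rms, "mean"), attr(rms, "sd"))
#> [1] "1.07 +/- 0.49 A"
```

The recovered occupancies sit within binomial sampling noise of the
prescribed 55/30/15 %, the density mode lands within a degree of the
87° substate center, and the 0.3 Å positional noise appears as a
~1 Å internal RMSD of the rigid partner domain.

```r
stalk <- make_bent_stalk(60, bend = 13, split = 30)
anm(stalk, cutoff = 10, gamma = 1, n_modes = 10)
#> Anisotropic network model
#>   nodes: 60  cutoff: 10 A  gamma: 1
#>   retained modes: 10  rigid modes skipped: 6
#>   eigenvalues: 0.00102, 0.001261, 0.006702, 0.006819, 0.01324, 0.02481 ...
stalk_bend_angle(stalk, domain_definition("stalk", "A", c(1, 60)), 30)
#> [1] 12.40134
```

Exactly six rigid-body modes are skipped (the network is connected),
the softest retained modes are the stalk's two near-degenerate bending
directions, and the bend measurement recovers the constructed 13° kink
to within the axis-estimation tolerance.

Configuration-driven runs (`run_analysis("config.json")`) execute a
task list (simulate / angles / occupancy / kde / domain-rmsd /
anchor-rmsd / anm / rotation / bend / interface / displacement), write
CSV/JSON outputs plus a run log with the configuration hash and every
default used, and are byte-identical when re-run with the same seed.
For deposited mortalin–GrpEL1 models, editable NBD lobe and IIB-helix
annotations ship in `inst/extdata/nbd_annotations.json`.

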