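---
title: "Methods: quantifying structural dynamics with strucdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying structural dynamics with strucdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`strucdyn` implements the measurement layer used to characterize
conformational change in Hsp70 / nucleotide-exchange-factor complexes:
rigid-body superposition and domain RMSD, subdomain rotations and stalk
bends, interface contacts and buried surface area, an anisotropic
network model (ANM), and substate analysis of anchor-defined trajectory
angles. This vignette records the models, the parameters that matter,
the numerical choices, and what the synthetic validation does and does
not demonstrate.

## Coordinates, numbering and selections

Structures are atom tables plus one or more coordinate models in
Angstrom. Residue numbering is author-assigned (PDB `auth` numbering)
throughout, because published domain boundaries for these complexes
are quoted in author numbering — e.g. the GrpEL1-B β-wing (160–217),
the mortalin SBDα lid (556–639), SBDβ (440–555) and the combined SBD
(440–639), which ship as `builtin_domains()`. Ranges are 1-based and
inclusive and match on residue number while ignoring insertion codes;
insertion-coded residues are otherwise distinct atoms. Alternate
locations keep the highest-occupancy conformer (ties: first in file).
Domain selections default to the backbone atoms N, CA, C, O — the atom
set used for the per-domain RMSD analyses — and a residue in range that
is missing some of those atoms is kept partially, with a warning,
rather than failing; only an entirely empty selection is an error.
Trajectory analyses assume protein-only coordinates; solvent is never
represented.

## Superposition and RMSD

`kabsch_fit()` is the closed-form least-squares fit: SVD of the 3×3
covariance of the centered point sets, with the reflection branch
corrected so the returned rotation is proper (det +1). Weighting is
uniform; the workflow specifies atom subsets but no weights, and mass
weighting would change none of the synthetic validations. Collinear
point sets are rejected (the in-plane rotation would be undefined).

`domain_rmsd_series()` aligns every frame *on the domain itself* before
measuring, so the series reports internal flexibility with collective
motion removed; the reference is frame 1 (the initial structure) unless
overridden. `per_atom_deviation_series()` measures anchor-atom
deviations after aligning on a separate selection. The alignment
context for anchor-atom deviations is genuinely a free choice — the
published analysis does not state one — so the default (all backbone
atoms of the complex) is deliberately global and is configurable; the
choice changes how much collective motion contaminates single-atom
deviations, and both conventions can be computed.

## Rotations, bends, displacements

Two structures are first superposed on an `align` selection (for NBD
lobe rotations: lobes IA+IB, so the IIB motion is expressed in the
fixed-lobe frame). The rotation of a `probe` region is then either

* **axis-angle** (default): the rotation magnitude
  `acos((tr R − 1)/2)` of the Kabsch fit between the paired probe
  coordinates — exact for rigid probes, which is why synthetic
  recovery is tested to 0.1° across 1–179°; or
* **helix-axis**: the angle between the probes' first principal
  directions — closer to the visual "helix tilt" but limited by axis
  estimation (below).

Principal axes are the first right-singular vector of the centered
coordinates, sign-oriented from first to last atom (N→C). An ideal
α-helix Cα trace (2.3 Å radius, 1.5 Å rise) estimates its construction
axis to ~0.4° for 20-residue segments; the residual comes from the
incomplete final turn. This sets the ~1° honesty limit quoted for
bend measurements, and is why degenerate (isotropic) point sets are an
error rather than an arbitrary axis.

`stalk_bend_angle()` splits a stalk at a residue boundary and measures
the inter-segment axis angle, requiring ≥ 6 residues per side for a
stable axis. When a straight reference structure is available (the
published comparison is against a predicted straight dimer), proximal
segments are superposed first and the distal axes compared; without
one, `reference = "self"` measures the internal kink directly — an
approximation that agrees with the external-reference route on
synthetic stalks because the generator's proximal segment is straight
by construction.

## Interfaces: SASA, buried area, contacts

SASA is Shrake–Rupley with a 1.4 Å water probe and Bondi-style van der
Waals radii (C 1.70, N 1.55, O 1.52, S 1.80 …; unknown elements fall
back to 1.70 Å with a warning, or an error if configured). Test points
are a deterministic golden-spiral lattice (default 960 points/atom), so
areas are bit-for-bit reproducible at fixed parameters; 960 points give
≤ 2 % per-atom agreement with a 10 000-point reference on moderately
packed test clouds, and the single-sphere value is exact by
construction. Buried surface area is
`SASA(A) + SASA(B) − SASA(A∪B)` computed with only the named partners
present. Published buried areas for these complexes (on the order of
100–220 Å² per interface) do not state their convention, and
per-interface vs total differ by exactly 2×, with further ~10–20 %
sensitivity to radii and probe choices across tools; the default here
is per-interface (half the total, the common interface-server
convention) and both values are always attached to the result.

Contacts are residue pairs with any heavy-atom distance ≤ 4.5 Å (van
der Waals), upgraded to hbond-capable for N/O pairs ≤ 3.5 Å and to
salt-bridge for oppositely charged side-chain groups (Arg/Lys/His
nitrogens vs Asp/Glu carboxylate oxygens) ≤ 4.0 Å — standard
literature cutoffs, all configurable. π-stacking is not detected
geometrically; a cation-π pair will appear as a vdW/hbond-class
contact.

For deposited mortalin–GrpEL1 models, NBD lobe boundaries and the
inward-facing IIB helix are not published; `inst/extdata/`
ships an editable annotation file with approximate mortalin-numbering
spans derived from canonical DnaK lobe definitions via the
K250→K316 correspondence. All rotation measurements on real models
depend on these spans and should be read with that in mind.

## Anisotropic network model

Nodes are one Cα per residue (residues lacking a Cα are dropped with a
warning). The Hessian uses the standard ANM form: for node pairs
within the cutoff, the off-diagonal 3×3 super-element is
`−γ (r_ij r_ijᵀ)/|r_ij|²`; diagonal blocks make every block row sum to
zero, which holds exactly in the implementation (it is a test
invariant). Defaults are the study parameters: 10 Å cutoff, γ = 1
(arbitrary units — eigenvalues scale linearly in γ and modes are
γ-invariant), 10 retained modes. "10 modes" is interpreted as 10
*non-rigid* modes, the convention of the usual ANM toolchain; the six
zero modes of a connected network are always excluded, and a rigid-mode
count other than six is an error because it diagnoses a disconnected or
degenerate network rather than a result. The rigid tolerance is
relative (1e-8 of the largest eigenvalue); eigenvector signs are fixed
(first non-zero component positive) for reproducibility. Each
conformation is modelled separately. A dense LAPACK eigensolver is
used at all sizes; systems of the size studied here (~1200 nodes,
3600×3600) decompose in seconds-to-minutes, and the validation suite
uses 5–512 nodes so the whole suite runs in seconds.

Mean-square fluctuations and cross-correlations follow from the
retained-mode spectrum (`MSF_i = Σ_k |u_{k,i}|²/λ_k`; correlations
normalized so the diagonal is exactly 1). With *all* non-rigid modes
retained both match the Hessian pseudo-inverse to 1e-8, which is the
test oracle. No temperature or mass scaling is applied: fluctuations
are in γ⁻¹-proportional units and are meant for relative comparison,
not absolute B-factors. All-atom extension copies each residue's node
vector to all its atoms and renormalizes columns — adequate for
visualization (NMD export) and residue-level interpretation, not for
atomic-detail directionality within residues.

## Trajectory angles and substates

Anchor vectors are defined by chain/residue/atom triples (the lateral
and medial lid-motion vectors use the Cα of mortalin residues 569 and
597 and GrpEL1-B residues 98 and 200). Angles are
`acos` of the clamped normalized dot product, in [0°, 180°]
(vectors are undirected); zero-length vectors are an error naming the
frame. Every saved frame is analyzed (stride 1) unless the caller
subsets.

Published substate ranges are printed with 0.1° gaps (… 95.9 | 96 …);
`region_boundaries_from_printed()` closes them at gap midpoints so no
frame is unassigned. Occupancy bins are half-open [lo, hi) with the
last bin closed; frames outside the spec are counted separately rather
than silently dropped, and percentages are always relative to all
frames. The KDE uses a Gaussian kernel with Silverman's rule by
default — neither kernel nor bandwidth is stated in the source
workflow, and Silverman is the standard neutral choice — with a fixed
bandwidth available for constant or heavily discretized series. The
grid spans the data ±5° at a configurable step (0.5° default), so
reported modes are quantized at half the step.

## Synthetic generators: what they emulate, and what they do not

The generators are pure functions of their arguments including the
seed; each derives an independent RNG stream from (seed,
generator-name), so adding a generator never shifts another's output.
They emulate the *geometric* content of the study's data: multi-chain
complexes with controllable interfaces, domain pairs differing by an
exact known rotation, helical stalks with an exact known kink, and
trajectories whose anchor angle follows a prescribed substate mixture.

The angle-trajectory generator draws a region per frame (independent
draws, or a Markov chain when a transition matrix is supplied), samples
a target angle from the region's Gaussian, repositions the second
vector's tip so the angle is *exact*, then adds isotropic Gaussian
positional noise to every atom. Defaults are chosen to mirror the
study's conditions at desk scale: three substates over the published
lateral ranges with centers at the range midpoints, 1.5° substate
widths (narrow enough that each substate's distribution is contained
well inside its range, as in the published density curves where region
boundaries sit in density minima — this is what makes the prescribed
occupancy the true bin probability up to multinomial noise), 0.3 Å
positional noise (which adds ~1° of angular jitter at the ~30 Å anchor
distances used), and 5000 frames — enough for 3-binomial-sd occupancy
recovery in under a minute, versus the 75 000 frames of the original
450 ns of simulation.

What passing these tests shows: the analysis chain is correct — it
recovers known rotations to 0.1°, known bends to 1°, known occupancies
to sampling noise, and matches its analytic oracles. What it does not
show: anything about force-field realism. The generators have no
physics — no side chains, no realistic backbone geometry (dummy N/C/O
atoms sit at fixed offsets from Cα), no temporal correlation unless a
Markov chain is requested, and no attempt to mimic the real sequences.
Conclusions about the real complexes still require the real
trajectories and deposited models.

## Numerical choices and degenerate inputs

* Dot products are clamped to [−1, 1] before `acos`; angles are
  reported in [0°, 180°].
* Kabsch requires ≥ 3 non-collinear points; the returned rotation is
  orthonormal to 1e-8 and proper.
* Rigid-mode classification, eigenvector sign conventions and the
  golden-spiral lattice make every decomposition reproducible
  bit-for-bit.
* PDB coordinates are written at the format's 1e-3 Å precision; a
  write→read round trip preserves identity exactly and coordinates to
  that precision. Multi-model files must share one atom table; a
  mismatched model is an error naming the model, as is a malformed
  coordinate field (by line number) or a trajectory frame with the
  wrong atom count (by frame index).
* mmCIF input is not supported (PDB only); binary trajectory formats
  are out of scope for the core readers.
* CSV outputs are written at 6 significant digits; JSON carries full
  precision; pipeline runs are byte-identical at fixed config + seed,
  and the run log records the configuration hash and every default
  actually applied.

## Known limitations

Axis-based angles inherit the ~0.4° principal-axis bias of finite
helices; rotations measured by axis-angle avoid this but require
paired selections of identical atoms, so comparing non-identical
proteins needs externally supplied equivalences (no sequence
alignment is performed). Buried-area values carry the convention and
radii sensitivities noted above. The ANM is Cα-isotropic with a
uniform spring constant: it predicts mode geometry, not amplitudes or
timescales. The substate generator's occupancy ground truth is only as
sharp as the separation between substate width and bin width; heavily
overlapping substates make "occupancy" itself ill-defined, for the
generator exactly as for real trajectories.
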