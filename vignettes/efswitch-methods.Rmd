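---
title: "Methods: quantifying the troponin-C calcium switch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the troponin-C calcium switch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efswitch)
```

## Scope and model

`efswitch` quantifies the conformational switch of the troponin-C (TnC)
N-lobe along the coordinates that characterise Ca²⁺ release: the A/B-helix
hydrophobic pocket aperture, the geometry of the two EF-hand binding loops,
the hydrogen-bond network that locks the loops and the β-scaffold, backbone
flexibility, hydrophobic repacking, and the inter-lobe rotation. All metrics
are pure functions of a `Trajectory` — a fixed atom topology plus F frames
of coordinates — read from multi-MODEL PDB or a plain xyz table. Author
(PDB) residue numbering is used everywhere, with no renumbering: the
metrics' anchor residues (GLU16, LEU48, loops 29–40 and 65–76, virtual
dihedral anchors 15/54/73/104/131) are chicken fast-skeletal isoform
numbers, and every anchor is configurable.

The assumptions are minimal and structural: distances are Euclidean in Å;
rigid-body superposition is unweighted least squares (Kabsch via SVD, with
the sign correction that excludes reflections); dihedral angles follow the
IUPAC atan2 convention and are reported in degrees on (−180°, 180°].

## Pocket openness and state labels

The pocket coordinate is `d = |Cα(16) − Cα(48)|`, the distance between the
first A-helix and last B-helix residue. Windowed statistics use the
arithmetic mean and the sample (n−1) SD; windows are specified in frames
because PDB trajectories rarely carry reliable time stamps (a `frame_times`
slot exists for when they do). State labels are a three-way threshold on
the windowed mean:

* closed: `d ≤ closed_max` (default 14.5 Å)
* semi-closed: `d ≤ semi_closed_max` (default 18.0 Å)
* open: otherwise.

The defaults sit between the reported cluster means for the three regimes
(≈13.2–13.7 Å closed, ≈15.2–16.5 Å semi-closed, ≈23.8–23.9 Å open) with
roughly symmetric margins; they are configuration on
`pocket_state_thresholds()` and never hard-coded in analysis logic.

## Prong interaction and hydrogen bonds

The prong metric reports, per frame and per site, the minimum distance from
the backbone N at loop positions 2 and 9 to the position-12 glutamate
carboxylate oxygens OE1/OE2, plus the N–CD distances. Both the OE and CD
variants are always computed because published descriptions quote the
contact both ways; the formed criterion defaults to N–OE ≤ 3.5 Å, the
standard heavy-atom hydrogen-bond cutoff, comfortably outside the bound
state's sub-3 Å contact. Residue identity at the site positions is resolved
by residue *number*; names are informational (reported residue names for
the same positions vary between sources).

Hydrogen-mode bond monitoring places the amide hydrogen geometrically: 1.01
Å from N, opposite the bisector of the C(prev)–N and CA–N bonds, in their
plane. Placement is recomputed from each frame's backbone rather than
carrying frame-0 hydrogens along, so HN follows backbone motion exactly;
prolines and chain N-termini are skipped. The bond criterion is
distance-only (HN–O ≤ 2.5 Å formed, in line with the sub-2.5 Å distances
quoted for consolidated scaffold bonds; N–O ≤ 3.5 Å in heavy mode). A
donor-angle term was deliberately left out: the source observations are
distance curves, and an angle cutoff would add a parameter nothing in the
data constrains.

Transition events use dwell-filtered thresholding without hysteresis: a
crossing counts only if the new state persists for `min_dwell` frames
(default 5 in the pipeline). This makes the breakage/reformation count
robust on bonds that fluctuate over a 2–8 Å range, guarantees alternating
event kinds, and leaves the count invariant to prepending non-crossing
frames. Frames are 1-based, and the event frame is the first frame of the
new state.

## RMSF

`rmsf_profile()` superposes every frame onto a reference via Kabsch fitting
on a fit selection, then reports per-atom
`RMSF_i = sqrt(mean_f |r_i − mean(r_i)|²)`. Two open choices had to be made
explicitly because standard presentations leave them unstated:

* **Fit selection.** Default: the analysed Cα set itself (residues 5–80 of
  the TnC chain). Fitting on the flexible region slightly deflates absolute
  RMSF but makes profiles comparable across conditions without assuming a
  rigid core; both the fit and the reference are exposed arguments, and
  `fit = NULL` disables superposition entirely (used for analytic checks).
* **Reference.** Default: the post-fit mean structure (two-pass: align to
  frame 1, average, re-align to the average), which is the textbook RMSF
  definition; `"frame1"` is available.

For isotropic per-coordinate Gaussian noise of SD σ the expected RMSF is
σ√3; the test suite checks convergence to within 2% at F = 10000 frames.
Fold-change profiles floor both inputs at 0.05 Å before dividing so that
numerically rigid residues do not produce unbounded ratios, and report
contiguous runs above a ratio cutoff (default 2.0) as peaks with the
maximum-ratio residue as the centre.

## Rotation

Inter-lobe rotation is measured as virtual dihedrals over four Cα anchors:
VD1 = 131–104–73–15 and VD2 = 131–104–73–54, spanning C-lobe, central
helix, and the A/C helix starts. Both are always reported, since a single
quoted rotation magnitude cannot be attributed to one of them. The sign
convention is inherited from the IUPAC dihedral, so cross-state comparisons
should use magnitudes; `rotation_between_states()` wraps the difference to
(−180°, 180°]. Unwrapping of series (±360° jump removal) exists but is off
by default, matching the usual raw-dihedral presentation.

## Hydrophobic packing and exposure

Contacts are minimum pairwise distances between residues' heavy atoms
(optionally side-chain heavy atoms only), with persistence = fraction of
frames at or below 4.5 Å. The 4.5 Å hydrophobic-contact convention is ours —
no numeric definition accompanies the qualitative descriptions — and it is
recorded in every output table. The default panel covers the named sets of
the repacking narrative: the PHE25/74/77 scaffold, PHE28 against
PHE77/LEU41/VAL44, VAL44 against PHE77/PHE25/ALA24, the MET45/80/81 triad,
MET27–MET47, and ILE60–MET80 / MET81–LEU48.

Solvent-accessible surface area is Shrake–Rupley: quasi-uniform points on
each atom's solvent-expanded sphere (vdW radius + 1.4 Å probe), accessible
fraction times expanded-sphere area. The point set is a golden-section
spiral — deterministic and seedless, so results are reproducible
bit-for-bit — with 960 points by default (≈0.3% error on an isolated atom;
the two-sphere case is checked against a 10⁵-node quadrature oracle at 2%).
Neighbour search is restricted to atoms within `r_i + r_j + 2·probe`.
Radii: C 1.70, N 1.55, O 1.52, S 1.80, Ca 2.31, H 1.20, P 1.80 Å,
config-exposed. Relative side-chain exposure divides a residue's side-chain
SASA in context by the same conformation's SASA with every atom outside the
residue deleted, giving 1 in isolation and near 0 when enclosed.

## The synthetic generators: what they emulate, and what they do not

The trajectories behind the published observations came from hundreds of
nanoseconds of explicit-solvent MD and are not deposited, so the package
ships generators whose defaults *are* the study conditions the metrics are
tested under:

* `build_toy_two_state_lobe()` builds an idealised N-lobe: ideal α-helices
  (1.5 Å rise, 100°/residue, 2.3 Å radius) for helices N/A/B/C/D, the two
  12-residue loops as circular arcs with 3.8 Å Cα spacing, and approximate
  backbone N/C/O placed around the Cα trace with realistic bond lengths.
  The open conformer pins the pocket at d = 23.9 Å and the closed at
  13.4 Å — the two reported extreme-state means — by solving the B-helix
  placement exactly; prong pseudo-side-chains are formed (2.8/2.9 Å) when
  open and released (6 Å) when closed; both loops expand on closure. A
  Cα-only stub (residues 86–135) extends the D helix through the central
  linker so the default virtual-dihedral anchors (104, 131) resolve; this
  goes beyond the backbone range a minimal lobe needs, and exists purely so
  the rotation metric runs on the toy. Construction is deterministic and
  self-checks for steric clashes (non-bonded heavy atoms < 1.5 Å is a
  construction error).
* `morph_trajectory()` interpolates linearly between conformers plus
  i.i.d. isotropic Gaussian coordinate noise — chosen over correlated noise
  because it makes the RMSF expectation analytic (σ√3).
* `noisy_static_trajectory()` emulates prescribed per-atom fluctuation
  amplitudes (e.g. tripled SD on a depleted site, mirroring the reported
  up-to-3-fold RMSF increase).
* `rigid_rotation_trajectory()` and `step_displacement_trajectory()`
  prescribe exact rotations and exact event frames.
* `ou_two_probe_trajectory()` is an Euler–Maruyama Ornstein–Uhlenbeck
  distance with known stationary law (SD = σ/√(2θ)); the discretisation is
  refused when θ·dt ≥ 2.
* `build_beta_bridge()` is a small antiparallel two-strand sheet carrying
  the β-scaffold numbering, constructed so all four scaffold bonds sit at
  exactly 2.0 Å HN–O; a splay parameter displaces the flanking residues to
  break only the flanking bonds.

Every stochastic generator takes a mandatory seed and is a pure function of
(inputs, seed). What the toys do **not** emulate: force-field energetics,
solvent, Ca²⁺ electrostatics, realistic side-chain rotamers, correlated
backbone motion, or realistic loop geometry beyond spacing and the
prescribed anchors. Passing tests on these generators therefore
demonstrates that the *metrics* recover prescribed geometry and statistics
exactly or within their analytic tolerances — not that any biological claim
is reproduced from MD. Conversely, nothing in the metrics depends on the
toys; they run unchanged on real PDB trajectories.

## Numerical choices and degenerate inputs

* Kabsch refuses < 3 points and collinear/coincident sets (second singular
  value below 1e−10 of the largest) rather than returning an arbitrary
  rotation; the proper-rotation branch is enforced by the determinant sign
  correction.
* Dihedrals with collinear consecutive anchors raise an undefined-dihedral
  error (with the frame index, in series); wrapped angles map −180° to
  +180°.
* Alternate locations collapse to the highest-occupancy conformer, ties
  broken toward altLoc 'A', so topologies are deterministic.
* Elements missing from the PDB element columns are inferred from the
  atom-name columns; a name starting in column 13 whose trimmed form is a
  known two-letter symbol is a metal/two-letter element, which is what
  distinguishes a calcium HETATM "CA" from an alpha-carbon " CA ".
* PDB coordinates are written at the fixed-width 3-decimal convention;
  values that cannot fit the 8-column field are an error, never silently
  truncated. The xyz-table dialect prints 6 decimals and round-trips at
  that precision.
* Windows are clipped to the series and empty windows are errors; a
  single-frame window reports SD 0.
* Selections resolve in topology order regardless of request order;
  requested residues absent from the structure are skipped with a warning
  carrying the count (crystal structures have missing residues), and an
  empty resolution is distinguishable from an error unless the caller
  requires atoms.

## Problem sizes

The test and acceptance runs use deliberately small, fixed sizes chosen to
make stochastic tolerances comfortable: 120-frame morphs with 0.05 Å noise
for state classification, 10000 frames for the RMSF analytic limit (2%
tolerance), 50 seeded replicates at 0.3 Å noise for event-frame recovery
(±2 frames), 5·10⁴ Ornstein–Uhlenbeck steps at θ·dt = 0.04 for the
stationary law (5%), and 960-point SASA lattices (1–2% against oracles).

## Known limitations

* The pipeline analyses one TnC chain per run; multi-chain (full troponin
  core) trajectories work for any metric that takes a chain argument, but
  no cross-chain metrics (e.g. TnC–TnI contacts) are included.
* No binary trajectory formats (DCD/XTC); conversion to multi-MODEL PDB or
  the xyz table is up to the caller.
* Hydrogen placement covers backbone amides only; side-chain donors are out
  of scope, as are DSSP-style secondary-structure assignment, Ca²⁺
  coordination-geometry scoring, rotamer classification and any free-energy
  estimate of the transition.
* The crystal-derived bounds (ion counts, open/closed classification of the
  deposited holo/apo structures) require the PDB entries 1YTZ and 5TNC; the
  package does not download them, and which chain letters carry TnC/TnI/TnT
  is deliberately mandatory user configuration (`chain_map()`), since the
  assignment is not stated alongside the residue numbering.
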