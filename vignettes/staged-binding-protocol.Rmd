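---
title: "Staged restrained dynamics and fly-casting analysis with flycast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staged restrained dynamics and fly-casting analysis with flycast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Many signalling interactions couple folding and binding: one partner
carries an intrinsically disordered region (IDR) that only adopts its
final conformation while docking onto a structured receptor. The
fly-casting picture describes how such a segment profits from its
disorder — a large *capture radius* lets it make weak first contacts
far from the final pose, after which it reels itself in. A canonical
example is the phosphothreonine-reader scaffold 14-3-3ζ binding its
partner AANAT: phosphorylation of a single ligand residue (Thr31) gates
the whole process, and conserved basic residues in the receptor groove
(Lys49, Arg56, Arg127) read the phosphate in the final complex.

`flycast` implements, at desk scale, the staged restrained-dynamics
protocol used to study this kind of binding event, together with the
complete analysis suite needed to characterise it: Kabsch-superposition
RMSD and RMSF, per-segment RMSD, Shrake–Rupley solvent-accessible
surface area (SASA) with a normalised-complex convention, polar contact
counting, and the capture radius (mass-weighted radius of gyration of a
residue selection, tracked per frame).

## The model

### Coarse-grained representation

All dynamics run on a one-bead-per-residue Gō-type model:

* **bead** = the residue's Cα position, carrying the full residue mass
  (Da);
* **bonds**: consecutive residues within a chain, harmonic
  `½ k_b (r − r₀)²` with `r₀` the observed Cα–Cα distance;
* **native contacts**: intra-chain residue pairs at sequence separation
  ≥ 3 whose Cα distance in the reference structure is below the contact
  cutoff, modelled as 12-10 wells
  `ε (5 (r₀/r)¹² − 6 (r₀/r)¹⁰)` with minimum `−ε` at `r₀`;
* **excluded volume**: every other pair repels as
  `ε_rep ((σ/r)¹² − 1)`, truncated (continuously) at `σ`.

Energies are in reduced units with `k_B T = 1` at the reference
temperature, so the physical reference state maps to `T* = 1`. Defaults
(`cg_params()`): `k_b = 100 kBT/Å²`, `ε = 1 kBT`, `ε_rep = 1 kBT`,
`σ = 4 Å`, contact cutoff `8 Å`. These are conventional Gō-model
scales: stiff enough that chains keep their fold at `T* = 1`, soft
enough that terminal segments can make the large excursions the
fly-casting analysis is about. No claim is made that they reproduce any
specific protein's energetics; every constant is exposed.

A *disordered segment* flag removes all native contacts of a chosen
residue range (an IDR keeps connectivity and excluded volume only). A
*phosphorylation* flag does two things to the flagged residue: it
removes that residue's remaining local native contacts within a
configurable window (± 2 residues by default), emulating the local
release of structure, and it can add attractive inter-chain contacts
from the site to a configured set of receptor "pocket" beads —
expressing the experimentally motivated mechanism (the phosphate
targets a basic pocket) as explicit configuration rather than hidden
constants.

### Dynamics

The integrator is overdamped (Brownian) Langevin dynamics,

```
r ← r + (dt/γ) F + sqrt(2 T* dt/γ) ξ,   ξ ~ N(0, 1) per coordinate,
```

with defaults `dt = 0.002`, `γ = 1`. The choice of the overdamped limit
is deliberate: the quantities this package is specified to reproduce
are protocol behaviour (where do restrained collective variables
settle, with what variance) and analysis mathematics, which depend on
the stationary distribution, not on inertial kinetics. With
`k_b dt/γ = 0.2` the stiffest mode is well inside the stable regime of
the Euler–Maruyama update, and the discretisation bias on a restrained
CV's variance at the default restraint stiffness (`k = 10`) is about
1%, far below the statistical tolerances used in the tests. All
randomness flows from one integer seed; Gaussian draws are made in a
fixed coordinate order, so a run is bitwise reproducible.

### Collective variables and the three-region protocol

The only CV used is the distance between the mass-weighted centres of
mass (COM) of two residue groups. Two bias shapes exist:

* **two-sided harmonic** `½ k (d − d₀)²` — used to hold a CV *at* a
  crystallographic target;
* **one-sided upper wall** — the same spring active only for `d > d₀` —
  used to impose an *approach* condition ("come within 5 Å") without
  dictating the exact geometry.

Bias forces are distributed over group members by mass fraction (the
chain rule of the mass-weighted COM), so the total force on one group
is exactly minus that on the other.

The protocol has three regions mirroring the 10/90/10 proportion of the
staged simulations it reproduces (default desk-scale lengths
10,000 / 90,000 / 10,000 steps):

* **Region I — pseudo-native capture.** Two upper walls at
  `d₀ = 5 Å` pull the ligand's two anchor residues to their partner
  groups on the receptor, forcing an encounter complex. For the
  14-3-3/AANAT system the mapping is built in
  (`anchor_map_14_3_3()`): Glu87 → {Lys49, Arg56, Arg127, Asn173} and
  Arg89 → {His164, Pro165, Ile166}. Region I is specified as an
  approach condition, hence walls rather than two-sided springs.
* **Region II — free exploration.** No bias at all; the recorded bias
  energy is identically zero. This is where fly-casting excursions are
  measured.
* **Region III — native-complex formation.** Six simultaneous two-sided
  harmonics guide the pair to the reference pose. Targets come either
  verbatim from a distance table — the built-in
  `native_distance_table_14_3_3()` carries the six published pairs
  (Glu39–Gln132 10.7 Å, Gln15–Arg142 8.95 Å, Gln219–Glu43 7.86 Å,
  Asn42–Asn35 6.54 Å, Leu216–Arg38 7.06 Å, Arg56–Thr31 10.2 Å) — or are
  measured from a supplied reference complex with `com_distance()`.

The restraint stiffness is nowhere published; the default
`k = 10 kBT/Å²` gives an equilibrium CV standard deviation of
`sqrt(T*/k) ≈ 0.32 Å`, tight enough to pin the pose and loose enough to
leave thermal motion visible. Region boundaries are pure configuration:
the sources describing the original protocol state the region spans
inconsistently in places, so the package treats only the 10/90/10
proportion as the default and leaves the rest to config.

Because a CV under a `k = 10` spring fluctuates with σ ≈ 0.32 Å,
single-frame checks of "is the CV at its target" would be coin flips by
construction. All end-of-region conditions in this package are
therefore evaluated as time averages over the final 10% of the
region's frames — the same convention used for the reported capture
quantity.

### Initial placement

A binding run starts from the two apo chains with COMs separated by
60 Å along x (configurable). The relative orientation of the ligand is
not part of the protocol definition; it is drawn uniformly from the
seeded RNG and recorded through the seed, so a run is reproducible but
orientation is not hand-picked.

## Analysis suite

* `rmsd_series()` — per frame, least-squares (Kabsch) superposition on
  a fit selection, then RMSD over a measure selection, against a
  reference structure. The Kabsch implementation excludes reflections
  by sign-correcting the smallest singular vector, and superposition is
  mass-unweighted over Cα positions (the standard convention when no
  weights are specified).
* `rmsd_by_segments()` — several segments measured after one common
  global fit; segment values recompose exactly (atom-count-weighted
  mean of squares) into the whole-selection RMSD.
* `rmsf()` — per-residue fluctuation about the time-mean position after
  per-frame superposition; a frame window restricts the analysis (e.g.
  to the free-exploration region).
* `sasa()` — Shrake–Rupley with a deterministic golden-spiral point set
  (default 960 points, probe 1.4 Å) and a fixed element radius table
  (C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, H 1.10 Å). Points are
  weighted with a linear ramp over one point-spacing of signed distance
  to the nearest covering sphere. This anti-aliasing is unbiased to
  first order and removes most of the orientation jitter of the binary
  in/out count: totals are rigid-motion stable to well under 0.1% at
  the default point count, which the binary test alone does not
  achieve.
* `normalized_complex_sasa()` — `100 × SASA(complex) / (SASA(half 1) +
  SASA(half 2))`, the monomer-sum convention. 100% means no buried
  interface and burial can only lower the value. This convention is the
  package's declared interpretation of "normalized SASA"; the published
  crystal value of 81.02% for the 14-3-3ζ/AANAT complex is its
  validation probe (see the crystal checks below).
* `contact_count()` — hydrogen bonds approximated as heavy-atom N/O
  pairs within 3.5 Å (0.35 nm), no angle term, so crystal structures
  without hydrogens work unchanged. Side-specific element patterns
  support asymmetric counts (phosphate oxygens against basic
  nitrogens), and counting is per atom pair or per contacted residue —
  both exposed because published contact counts rarely state their
  convention.
* `capture_radius_series()` — the per-frame mass-weighted radius of
  gyration of a selection. A single bead has Rg ≡ 0, so single-residue
  selections are rejected with advice to use a window (site ± 2
  residues) — in an all-atom setting the residue's own atoms make the
  quantity well defined, in a CG model they do not.

On CG trajectories, SASA treats beads as uniform 3.0 Å spheres and
contact counting treats every bead as a polar centre. Both are
stand-ins that make the metrics well defined on bead models; their
absolute values are not comparable to all-atom results and are labelled
as such in the output metadata.

## Synthetic data: what it emulates, and what it does not

`make_toy_dimer()` builds the study system at toy scale: a 40-residue
receptor and a 30-residue ligand whose first 8 residues form a
disordered tail carrying a phospho-site (Thr-like residue at tail
position 4), as compact self-avoiding Cα walks with 3.8 Å steps. The
native pose is constructed by the package's own physics: the ligand is
placed outside the receptor's most exposed surface patch and relaxed
under the two Region-I walls at low temperature, so the native complex
is clash-free and satisfies the capture conditions by construction
rather than by rejection sampling. From that pose the generator derives
the full protocol configuration — the two 5 Å walls and a six-pair
native distance table measured from the pose itself (hence satisfied
exactly at the native coordinates, to < 1e-6 Å). Initial separation
defaults to 60 Å, matching the protocol's starting condition.

`make_jitter_trajectory()` adds iid Gaussian noise (σ per coordinate)
to a base structure, giving frames whose RMSF is exactly σ√3 in
expectation. `make_breathing_helix()` produces an ideal Cα helix
(rise 1.5 Å, 100°/residue, 29 residues by default — the length of a
long regulatory helix such as 14-3-3's helix 9) whose coordinates are
scaled uniformly about the centroid so that the radius of gyration is
`Rg₀ + a·sin(2πt/period)`. The uniform-scaling construction was chosen
over scaling the helical radius alone because it makes the
capture-radius oracle exact: the excursion is 2a and doubles exactly
with a.

What the toy dimer does **not** emulate: real sequence, secondary
structure, electrostatics, solvent, or the energetic asymmetry between
the phosphorylated and unphosphorylated states. Tests passing on it
demonstrate that the protocol machinery, restraint algebra and metrics
behave as specified — not that the model reproduces 14-3-3/AANAT
thermodynamics. In particular, the headline all-atom observations
(final RMSD(Cα) ≈ 3.5 Å to the crystal complex, a ~40% capture-radius
increase on phosphorylation, SASA minima near 86–88.5%) require
hundreds of nanoseconds of all-atom MD across replicas and are outside
what the desk-scale model can or should reproduce.

## Crystal-structure checks

`crystal_complex_checks()` recomputes three deterministic quantities
from a user-supplied crystallographic complex of 14-3-3ζ with
phospho-AANAT (PDB accession 1IB1; one receptor monomer and one ligand
chain): the six native-table COM distances (heavy-atom, mass-weighted —
crystal structures carry no hydrogens, which is why the heavy-atom
convention is declared for all COM work), the residue-level count of
phosphate contacts from pThr31 to the conserved triad, and the
normalised complex SASA. The package ships no crystallographic data;
the checks run when the user provides the file, and the test suite
reports them as failing (not skipped) when it is absent. The code path
itself is validated against a synthetic stand-in complex built in code.

## Numerical choices and degenerate inputs

* Altloc resolution keeps the highest-occupancy variant, ties broken
  by altloc letter — deterministic and standard.
* Kabsch requires ≥ 3 non-collinear fit points; collinear sets raise a
  degenerate-fit error rather than returning an arbitrary rotation.
* Residue numbering is author numbering throughout; selections never
  silently broaden (unknown chain is an error, an empty match is an
  empty result).
* The integrator aborts with the step number if any coordinate leaves
  a configurable bound (default 10⁴ Å) or becomes non-finite.
* Phosphothreonine (TPO) is retained as a polymer residue on input, so
  phospho-site selections work on real structures.

## Problem sizes

The shipped tests and the acceptance script use the toy dimer
(70 beads), protocol runs of 4–20 thousand steps for behavioural
checks and a full 110,000-step staged run for the reported capture
quantity, 10⁵-step runs for statistical recovery (CV variance, free
diffusion), 10⁴-frame jitter trajectories for RMSF calibration, and a
10⁶-point Monte-Carlo oracle for SASA. These sizes were chosen so each
statistical tolerance (5–15%) sits several standard errors above the
estimator noise.

## Limitations

* The CG model has no electrostatics and no solvent; phosphorylation
  is a topological flag, not an energy model.
* Overdamped dynamics gives no kinetic observables (rates, diffusion-
  limited association times) — only stationary and protocol-driven
  behaviour.
* CG SASA and CG contact counts are conventions, not physical areas or
  hydrogen bonds.
* The normalised-SASA monomer-sum convention is a declared
  interpretation; its crystal-structure probe is the way to falsify it.
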