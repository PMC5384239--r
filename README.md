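# flycast

Staged restrained dynamics and fly-casting analysis for protein–protein
binding, in R.

Binding between a structured receptor and a partner carrying an
intrinsically disordered region (IDR) often proceeds by *fly-casting*:
the disordered segment, with its large capture radius, makes weak first
contacts far from the final pose and folds while reeling in. The
canonical case this package is built around is the phospho-reader
scaffold 14-3-3ζ binding AANAT, where phosphorylation of a single
ligand residue (Thr31) gates the whole process.

`flycast` provides, for computational structural biologists who want
this machinery at desk scale rather than on an all-atom MD cluster:

* a one-bead-per-residue Gō-type model (Cα beads, harmonic bonds, 12-10
  native-contact wells, truncated r⁻¹² excluded volume) with a seeded
  overdamped Langevin integrator, `r ← r + (dt/γ)F + √(2T*dt/γ)ξ`;
* centre-of-mass distance restraints — two-sided harmonics
  `½k(d−d₀)²` and one-sided upper walls — arranged into the
  three-region protocol: **I** pseudo-native capture (two 5 Å wall
  conditions on anchor residues, e.g. AANAT Glu87 → 14-3-3
  {Lys49, Arg56, Arg127, Asn173}), **II** unrestrained exploration,
  **III** native-complex formation under six simultaneous harmonics
  with crystallographic targets (built-in table: 10.7, 8.95, 7.86,
  6.54, 7.06, 10.2 Å);
* the analysis suite: Kabsch superposition RMSD/RMSF and per-segment
  RMSD, Shrake–Rupley SASA and normalised complex SASA
  (`100·SASA(AB)/(SASA(A)+SASA(B))`), polar contact counts (heavy-atom
  N/O pairs within 3.5 Å), and the capture radius — the per-frame
  mass-weighted radius of gyration `√(Σmᵢ|rᵢ−r_COM|²/Σmᵢ)` of a residue
  selection;
* synthetic generators with known ground truth (toy dimers with a
  self-consistent native pose, jitter trajectories with RMSF = σ√3,
  breathing helices with an exact capture-radius oscillation);
* PDB I/O (single and multi-model), tidy tibble outputs with
  `tidy()`/`glance()`/`autoplot()` methods, and a small CLI
  (`inst/cli/flycast` with `fixtures`, `run`, `analyze` subcommands).

## Worked example

```r
library(flycast)

dimer <- make_toy_dimer(toy_dimer_spec(seed = 7))
dimer$native
#> <structure> 70 atoms, 70 residues, chain(s) A,B - toy dimer native

config <- protocol_config(
  anchors      = dimer$config$anchors,      # two 5 A wall conditions
  native_table = dimer$config$native_table, # six harmonic targets
  disordered   = dimer$config$disordered,   # the ligand's IDR tail
  region_steps = c(I = 5000, II = 5000, III = 5000),
  dynamics     = dynamics_params(stride = 10, seed = 7))

traj <- run_binding_protocol(dimer$apo_a, dimer$apo_b, config)
glance(traj)
#> # A tibble: 1 x 6
#>   n_frames n_beads n_regions final_potential final_bias  seed
#>      <int>   <int>     <int>           <dbl>      <dbl> <int>
#> 1     1501      70         3           -39.5       1.23     7

walls <- pseudo_native_restraints(dimer$config$anchors)
for (w in walls) {
  s  <- restraint_distance_series(traj, w)
  sI <- s$value[s$region == "I"]
  cat(sprintf("%s: start %.1f A, end-of-region-I mean %.2f A\n",
              w$label, sI[1], mean(tail(sI, 50))))
}
#> anchor1: start 42.2 A, end-of-region-I mean 5.35 A
#> anchor2: start 49.8 A, end-of-region-I mean 5.47 A
```

The chains start with centres of mass 60 Å apart (the anchor CVs start
at 42–50 Å because the anchors sit off-centre); by the end of Region I
both wall conditions hold — the time-averaged CVs sit at the 5 Å wall,
within its thermal width √(T*/k) ≈ 0.32 Å. Region II then records zero
bias while the IDR tail explores, and Region III pulls all six native
CVs to within half an angstrom of their targets. Per-frame metrics
chain straight into the analysis:

```r
capture_radius_series(traj, atom_selection("B", 1:8))  # the IDR tail
#> <metric_series> capture_radius [angstrom] ..., 1501 points
autoplot(rmsd_series(traj, dimer$native,
                     fit = atom_selection("B", atoms = "calpha")))
```

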