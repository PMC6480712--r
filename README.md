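# rotadimer

Residue-level analysis of molecular-dynamics trajectories of class-A
G protein-coupled receptors, built around one scientific question: how do
different bound antagonists select sidechain rotamer conformations on
transmembrane helices TM5 and TM6, and how do those rotamers stabilize a
symmetric TM5–TM6–TM5–TM6 homodimer interface?

The package is for computational structural biologists who have receptor
trajectories (multi-MODEL PDB) and want reproducible, scriptable versions
of the standard residue-level analyses:

* **χ1 rotamer classification** — the N–CA–CB–CG torsion on [0°, 360°),
  split into the two aromatic pseudo-states *cis* (centre ≈ 300°) and
  *trans* (centre ≈ 180°) at a 240° threshold (cis iff χ1 > 240°), with
  windowed occupancy statistics using circular means/SDs for angles.
* **Ligand-pose stability windows** — RMSD to the final conformation in
  the receptor frame (Kabsch superposition on the transmembrane backbone,
  no ligand re-fit); a pose is stable from the earliest time after which
  RMSD stays < 3.0 Å.
* **Contact fingerprints** — residues with any heavy-atom pair strictly
  within 3.5 Å of the ligand, per frame or as frequencies over a window,
  and the common/unique partition of contact sets across ligands
  (categories (I)–(IV) for the three-ligand case).
* **Dimer interface characterization** — inter-protomer
  centre-of-geometry and minimum-distance traces, geometric hydrogen-bond
  occupancy (D···A ≤ 3.5 Å, D–H···A ≥ 150° when hydrogens exist), and a
  simplified pairwise interaction energy
  `E = Σ_pairs q_iq_j·332.0636/(4r²) + 4ε_ij[(σ_ij/r)¹² − (σ_ij/r)⁶]`
  (r < 12 Å, screened Coulomb with ε(r) = 4r, Lorentz–Berthelot mixing).
* **Computational alanine scanning** — sidechain truncation to Cβ on
  identical frames; a mutation's interface contribution is
  `E_wt − E_mut`, exactly the pair terms the truncation removed.
* **A synthetic trajectory generator** with exact ground truth (two-state
  Markov χ1 dynamics, scripted ligand contacts, scripted dimer
  separations and H-bond fractions), so every stage is testable with no
  external data.

Residues are addressed by author numbering or by Ballesteros–Weinstein
generic labels ("5.48", "6.52") through a tab-separated residue map. All
user-facing functions take/return tibbles and plug into the tidyverse;
result objects have `tidy()`/`glance()` methods and `autoplot()` plots.

## Worked example

Generate a 400-frame homodimer toy (3 ns/frame; protomer-specific trans
occupancies 0.94/0.90 and 0.04/0.93, 4% scripted Tyr–Tyr H-bond frames,
TM5/TM6 faces in van-der-Waals contact) and run the dimer pipeline:

```r
library(rotadimer)

spec <- synthetic_spec(n_frames = 400, dt = 3, seed = 7)
gen  <- generate_dimer_trajectory(spec)
rep  <- run_dimer(analysis_config(trajectory = gen$traj, bw = gen$bw,
                                  mode = "dimer"))

state_occupancy(rotamer_states(chi1_trace(gen$traj, "A", 199, bw = gen$bw)))
#> # A tibble: 1 × 11
#>   resName resSeq bw    n_frames fraction_cis fraction_trans ...
#> 1 TYR        199 5.48       400       0.0625          0.938

rep$hbond
#> # A tibble: 1 × 6
#>   n_frames n_bonded occupancy dist_cutoff angle_cutoff symmetric
#> 1      400       16      0.04         3.5          150 TRUE

glance(rep$residue_pair_distance)   # cross-protomer 5.48/6.52 min distance
#> # A tibble: 1 × 3
#>    mean    sd     n
#> 1  4.80 0.693   400

rep$energy
#> <interface_energy_report> 400 frame(s): mean -1.011 kcal/mol (sd 0.905), cutoff 12 A

rep$alascan
#> <ala_scan_result> 4 residue(s): E_wt -1.011, E_mut -0.008, contribution -1.004 kcal/mol
```

Reading the numbers: protomer A's Tyr199 (generic position 5.48) sits in
the trans χ1 state 93.8% of frames (its scripted stationary probability is
0.94); the Tyr–Tyr hydroxyl hydrogen bond is occupied in exactly the
scripted 4% of frames and the criterion that produced that number is
echoed beside it; the tracked cross-protomer aromatic pair sits ~4.8 Å
apart on average; and truncating Tyr199/Phe390 on both protomers to
alanine removes essentially the whole attractive interface energy
(contribution −1.0 of −1.01 kcal/mol) — on this toy, those four sidechains
*are* the interface. The energy scale is the package's simplified
surrogate and is only comparable to itself.

`autoplot()` works on every trace:

```r
autoplot(chi1_trace(gen$traj, "A", 199, bw = gen$bw))   # χ1 vs time, 240° line
autoplot(rep$interface_distances)
autoplot(rep$energy)
```

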