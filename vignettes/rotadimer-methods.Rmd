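---
title: "Methods: rotamer and dimer-interface analysis in rotadimer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rotamer and dimer-interface analysis in rotadimer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotadimer)
```

rotadimer analyses molecular-dynamics output of class-A G protein-coupled
receptors at residue resolution: how a bound antagonist selects sidechain
rotamers on the transmembrane helices TM5 and TM6, and how those rotamers
shape a TM5–TM6–TM5–TM6 homodimer interface. This vignette is the package's
own account of the underlying models, the tunable parameters, what the
synthetic generator does and does not emulate, and the numerical decisions
taken where the design was genuinely open.

## Containers and residue numbering

Structures are atom tables (`md_structure`); trajectories add a `T × N × 3`
coordinate array with strictly increasing frame times in nanoseconds
(`md_trajectory`). Multi-MODEL PDB is the on-disk trajectory format;
coordinates are Ångström throughout, and frame atom-count constancy is
enforced at construction. Hydrogens are optional everywhere and all default
selections are heavy-atom-only, because crystal-derived inputs carry no
hydrogens and mixed comparisons (crystal fingerprint vs simulation
fingerprint) must be like-for-like.

Residues keep their author/PDB numbering (Tyr199 stays 199). A
Ballesteros–Weinstein map (`bw_map`) attaches generic helix.position labels —
"5.48" is position 48 of TM5 — and a segment tag (TM1..TM7, loops) to each
residue, so analyses can be requested by generic label (`bw 5.48`) and loop
residues without a generic number report their segment (e.g. ECL2) instead.
Chains define protomer identity in dimers: the first two protein chains are
the two protomers.

## RMSD, stability windows, and superposition

`kabsch_superpose()` is the SVD solution of the orthogonal Procrustes
problem with the determinant correction that forbids reflections; the test
suite pins it against an independent quaternion-eigenvalue oracle to
10⁻⁶ Å. `rmsd_trace()` superposes each frame on a fit selection and measures
RMSD on a report selection. Two conventions matter:

* **Receptor drift** uses the transmembrane-domain (TMD) backbone — atoms N,
  CA, C, O of residues labelled TM1–TM7. Which backbone atom set a published
  trace used is often unstated, so the atom list is a config knob
  (`backbone_atoms`); `"CA"` gives CA-only traces.
* **Ligand pose drift** superposes frames on the TMD backbone and then
  measures the ligand RMSD *without* re-fitting the ligand, i.e. drift in
  the receptor frame. The reference is the final frame, so a pose is
  "stable from t onward" when its RMSD to its final conformation stays
  below a threshold (default 3.0 Å) for every later frame.
  `stability_onset()` returns the earliest such time; the final frame
  qualifies trivially, so an onset always exists.

## χ1 rotamers: the cis/trans pseudo-states

χ1 is the N–CA–CB–CG torsion, computed with the IUPAC sign convention and
mapped from (−180°, 180°] to [0°, 360°) — the range in which the two
pseudo-stable aromatic-sidechain conformations of interest sit at centres
near 300° and 180°. Following the nomenclature used in this line of work,
these are called **cis** (≈300°, outward-facing on TM5/TM6) and **trans**
(≈180°); this is a pseudo-state labelling, not the rotamer-chemistry
gauche−/trans naming, and it is kept deliberately. Classification is a
fixed threshold: cis **iff χ1 > 240°**, with the tie at exactly 240°
assigned to trans (strict inequality), `ROTAMER_THRESHOLD` documents the
constant. Angles must be wrapped to [0, 360) before classification —
`classify_rotamer()` refuses out-of-range input rather than silently
wrapping, because a silent wrap can hide unit bugs upstream.

Occupancies are frame counts within an explicit time window divided by the
window's frame count, so `fraction_cis + fraction_trans == 1` exactly.
The window is always an argument: published occupancies are sometimes taken
over the full run and sometimes over the ligand's stable window, and the
pipeline reports both bases side by side rather than guessing. No smoothing
or debouncing is applied to the state sequence; rapid χ1 fluctuations count
frame by frame.

Angle traces are summarised with circular statistics (circular mean mapped
to [0, 360), circular SD), since naïve means are wrong near the 0/360 seam;
plain traces (RMSD, distances, energies) use the arithmetic mean and
population SD.

## Contact fingerprints and the common/unique partition

A receptor residue is in close contact with a ligand when any heavy-atom
pair distance is **strictly below 3.5 Å**; distances of exactly 3.5 Å are
excluded. `contact_frequency()` turns this into a per-residue fraction of
frames over a window, and `frequent_contacts()` thresholds that fraction to
define the ligand-specific pocket. "Frequently in contact" has no canonical
definition, so the threshold defaults to 0.5 (a median-occupancy
convention), is recorded in the result's metadata, and is exposed as
config; a threshold of 0 degenerates to the union of ever-contacting
residues, which is also the single-frame crystal-structure mode.

`partition_contacts()` takes named per-ligand residue sets and groups every
residue by the exact combination of ligands contacting it. With the
three-ligand convention (first/second/third, e.g. risperidone, clozapine,
spiperone) the categories are tagged (I) common to all, (II) first+second,
(III) first+third, (IV) second+third, and "unique". Membership sets are the
canonical representation and the two-column unique/common rendering is
derived from them, which guarantees the categories are pairwise disjoint
and cover each ligand's set exactly — a property the test suite asserts on
random sets. A reference table of contact assignments for the three
antipsychotics is packaged under `extdata/d2r_ligand_contacts.tsv` and its
re-partition is part of the acceptance checks.

## The dimer interface

`interface_distance_trace()` reports two distance definitions per frame —
centre-of-geometry distance and minimum heavy-atom distance — because the
two answer different questions (helix packing vs closest approach) and
published traces use both. `residue_pair_min_distance()` vectorises the
minimum heavy-atom distance between a residue group on each protomer
(default: the tracked 5.48/6.52 pair, cross-protomer) and summarises
mean ± population SD over a window.

**Hydrogen bonds** use a geometric criterion: donor–acceptor heavy-atom
distance ≤ 3.5 Å, plus a D–H···A angle ≥ 150° that is applied only when an
explicit hydrogen is present on the donor; heavy-atom-only inputs fall back
to the distance test. The criterion was an open choice (the convention is
common but not unique); both cutoffs live in `hbond_criterion()` and are
echoed in every report. For Tyr–Tyr hydroxyl pairs the symmetric mode lets
either partner donate.

**Interface energy** is a deliberately simple, fully self-consistent
surrogate, not a force field:

E = Σ over inter-protomer heavy-atom pairs with r < 12 Å of
q_i·q_j·332.0636 / (4r·r) + 4ε_ij[(σ_ij/r)¹² − (σ_ij/r)⁶]

with a distance-dependent dielectric ε(r) = 4r screening the Coulomb term,
Lorentz–Berthelot combination of per-element Lennard-Jones parameters, and
per-residue formal charges (neutral sidechains except Asp/Glu carboxylates,
Lys/Arg, protonated His). Parameters ship as plain TSV tables under
`extdata/` so results are bit-stable and auditable. The model's purpose is
bookkeeping that is exactly decomposable over pairs: absolute values are
not comparable to any production force field or empirical energy function,
and no such comparability is claimed. Intra-protomer terms are excluded;
the report always embeds the model descriptor and cutoff.

**Alanine scanning** truncates a residue to its Cβ (backbone and CB kept,
residue renamed ALA) and re-evaluates the interface energy on identical
frames — single-point scanning with no repacking or minimisation, which
keeps the result deterministic and makes the contribution
`E_wt − E_mut` *exactly* the sum of the inter-protomer pair terms the
truncation removed (asserted against a brute-force double loop). Glycine
has no Cβ and is refused; truncating an alanine is the identity. An
externally computed protein–protein docking interface score ("I_sc") can be
annotated against the conventional −5.0 satisfactory threshold
(`annotate_interface_score()`); the package never computes docking scores
itself.

## The synthetic generator: what it emulates, and what it does not

Every analysis stage is exercised on generated toys with exact ground
truth (`generate_monomer_trajectory()`, `generate_dimer_trajectory()`).
The generator emulates the *statistical structure* of the real study
conditions, not the physics:

* **Rotamers** follow a two-state Markov chain per tracked residue with a
  requested stationary P(trans) and persistence `p_stay` = P(trans→trans);
  the cis→trans rate is derived to hit the stationary target, and
  infeasible combinations error. `p_stay` equal to the stationary
  probability gives the i.i.d. special case. Angles are the state centre
  (180° trans / 300° cis) plus wrapped Gaussian noise, σ = 15° by default
  so that 3σ stays well inside each side of the 240° boundary and state
  labels are unambiguous; boundary-straddling noise is a stress-test
  setting, not the default. Estimator checks use an
  autocorrelation-corrected standard error (`rotamer_recovery_se()`):
  n_eff = n·(1−λ)/(1+λ) with λ the chain's second eigenvalue.
* **Geometry** is two ideal α-helices per protomer (φ = −57°, ψ = −47°,
  giving 1.5 Å rise and ~100°/turn; CA–CA ≈ 3.8 Å), glycine backbones
  except a full-atom Tyr199 (TM5) and Phe390 (TM6) rebuilt each frame by
  internal coordinates so the χ1 read back from coordinates equals the
  scripted value to machine precision.
* **The pseudo-ligand** is a rigid 5-atom cluster placed each frame at
  `target − 0.3` Å (contact frames) or `target + 2` Å (otherwise) from a
  backbone-only glycine site. Anchoring on a backbone site — rather than
  on a flipping sidechain — keeps scripted contacts exact *and* the pose
  stable under the 3.0 Å criterion, emulating a stably bound ligand. A
  scripted 6 Å excursion before a chosen frame makes the stability onset
  a known quantity; without an excursion the onset is not scripted and
  the ground truth records NA for it.
* **The dimer** places protomer B as a z-rotated copy of A offset along x,
  so the scripted separation *is* the centre-of-geometry distance by
  construction (the recorded truth stores the realised values, which
  differ from the script only through the hydroxyl posing, < 0.2 Å). The
  default 15 Å separation puts the TM5/TM6 faces in van-der-Waals contact
  so the interface energy is attractive and the alanine scan removes real
  pair terms. Tyr hydroxyls are posed at 2.8 Å O–O in exactly the
  requested fraction of frames (default 4%) and pushed beyond 4 Å when a
  non-scripted frame would satisfy the criterion by accident.
* A global **rigid-body jitter** (random rotation up to 8°, 1 Å
  translation SD) is applied per frame to exercise superposition.

Defaults mirror the emulated study conditions: 1000 frames × 3 ns
(a 3 µs-equivalent run), monomer P(trans) = 0.99 for both tracked residues
(the clozapine-like condition), ligand contact fraction 0.30, dimer
protomer occupancies 0.94/0.90 and 0.04/0.93, H-bond fraction 0.04.
Generation is a deterministic function of the spec seed (per-residue
sub-seeding, so a standalone `generate_rotamer_sequence()` call reproduces
exactly the sequence embedded in a generated trajectory), and identical
specs produce bit-identical PDB files.

What the toys do **not** have: membrane, solvent, force-field dynamics,
realistic receptor topology (7 helices, loops), correlated backbone motion,
or any coupling between ligand pose and sidechain states. Passing the
recovery suites therefore demonstrates that the *analysis operations* are
correct and self-consistent — it says nothing about whether a particular
real simulation reproduces any published number.

## Numerical choices and edge cases

* Dihedrals: IUPAC sign via plane normals; collinear triples error. Note
  that torsion angles are invariant under atom-order reversal — the test
  suite pins this identity against an independent axis-projection oracle.
* Equality tolerances: 10⁻⁶ Å/degrees for geometric oracle agreement,
  10⁻⁸ kcal/mol (absolute) for energy-vs-brute-force on non-overlapping
  geometry (pair distances ≥ 1.2 Å; closer approaches amplify the r⁻¹²
  term beyond what double precision can hold to an absolute tolerance).
* Windows are closed intervals on frame times in ns; empty windows error
  rather than returning NaN.
* `read_pdb()` errors name the offending MODEL index (atom-count
  mismatch) or line number (unparsable coordinate); `write_pdb()` refuses
  coordinates that do not fit the fixed `%8.3f` columns.
* Reports format numbers to 3 decimals (1 for percentages), making reruns
  on identical inputs byte-identical; provenance embeds every cutoff that
  shaped a number, plus the package version — and no timestamps.

## Problem sizes in the shipped checks

The test suite and the acceptance script run entirely on generated data:
occupancy recovery uses 10⁴-frame chains across stationary P(trans) from
0.04 to 0.99; trajectory-level checks use 100–400 frames of the ~190-atom
toy dimer (the scales at which the scripted quantities are already exact
and stochastic bands are tight); oracle-equivalence suites use 100 random
small instances per kernel. These sizes were chosen as the package's
standing verification scale.

## Known limitations

* The energy surrogate ranks and decomposes; it does not predict
  experimental or force-field energetics.
* The selection mini-language covers conjunctions of simple clauses only
  (no `or`, no parentheses); compose in R for anything richer.
* No periodic-boundary imaging, mass-weighted RMSD, or unequal-atom-set
  alignment; trajectories must share a topology.
* χ2 and higher sidechain torsions, rotamer-library comparison, and
  dwell-time/kinetic fitting are out of scope (the generator scripts χ2
  at a fixed 90°).
* mmCIF, PSF topologies, velocities and box vectors are not read.
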