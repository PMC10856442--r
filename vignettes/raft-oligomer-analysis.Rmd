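---
title: "Methods: oligomer binding analysis on phase-separated raft membranes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oligomer binding analysis on phase-separated raft membranes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raftbind)
```

## Scope and model

`raftbind` analyses trajectories of amyloidogenic oligomers — tau, amylin,
and cross-seeded tau–amylin aggregates — interacting with model raft
bilayers. The membranes of interest are four-component, leaflet-asymmetric
bilayers: saturated DPPC and cholesterol enrich a liquid-ordered (Lo)
domain, unsaturated DLPC forms the liquid-disordered (Ld) phase, and an
anionic species (POPS or ganglioside GM1) clusters inside the Lo domain of
exactly one leaflet, mimicking the inner- and outer-leaflet nanodomains of
the neuronal plasma membrane. The package does not run molecular dynamics:
it consumes structures and trajectories (GRO/PDB, multi-frame GRO) or
generates synthetic ones with planted ground truth, and implements the
downstream analyses.

Units are nm and kJ/mol throughout; PDB ångströms are converted on read.
Boxes are orthorhombic; the minimum-image convention applies laterally
(x, y) always and in z only on request, because the bilayer normal is a
fixed axis (z) rather than a periodic direction.

## Domain classification

All phosphatidylcholines are classified per frame by an atom-proximity
rule with threshold $d = 0.5$ nm: a DPPC with any atom within $d$ of any
DLPC atom is a boundary (Lod) lipid, otherwise Lo; a DLPC with any atom
within $d$ of any DPPC atom is Lod, otherwise Ld. Cholesterol inherits the
domain of the PC lipids it contacts within the same threshold; a CHOL
contacting PCs of two or more domain classes is assigned Lod — it
straddles the boundary, which is what the Lod class means — and a CHOL
contacting no PC takes the class of the nearest PC molecule. Three choices
here were genuinely open and are fixed as follows:

* the threshold comparison is **inclusive** (`dist <= 0.5`);
* the multi-domain CHOL tie-break is **Lod** (boundary semantics), not
  majority contact;
* classification uses 3D distances over **both leaflets** jointly — the
  rule says "any atoms", and bilayer thickness excludes spurious
  inter-leaflet contacts in practice.

Compositions are reported as two percentage triples that each sum to 100:
CHOL in Lo/Ld/Lod (of total CHOL) and Lo-DPPC / Ld-DLPC / Lod-PC (each of
total DPPC+DLPC, with Lod-PC pooling both species). The neighbour search
uses spatial binning at the cutoff length and is validated against an
exhaustive $O(N^2)$ oracle in the test suite; results are identical, only
the complexity differs.

## Binding kinetics and spectra

The *mindist* of two atom groups is the minimum over all cross pairs of
the minimum-image distance. Contact counts use an interaction threshold of
2.0 nm — unusually large, but kept as the published convention and
configurable. The **lipid-binding time** is the onset of the persistent
low-mindist plateau. Two detectors are provided and expected to agree:

* `persistent_suffix`: the earliest frame from which mindist stays at or
  below `d_bind` until the end of the run (primary rule; bound oligomers
  stay bound in the systems emulated here);
* `contact_onset`: the first frame of the trailing run of nonzero contact
  counts.

`d_bind` defaults to 0.6 nm for coarse-grained series, sitting above the
~0.5 nm stable plateau, and ~0.35 nm is recommended for all-atom series
with their ~0.2 nm plateau. A trajectory whose suffix never qualifies is
reported unbound (`NA`) rather than given a fictitious time.

The per-residue **mindist spectrum** averages, for each residue, the
per-frame residue-to-target minimum distance over an analysis window
(convention: the last 5 µs of a CG run or last 50 ns of an AA run), then
over equivalent chains, then over replicates (SEM across replicates). A
5-point moving average is available for presentation only; all statistics
are computed on unsmoothed values. The window is configuration-exposed
because "stable-binding interval" and "last 5 µs" coincide only when
binding completes early.

Annular lipids (AL) are those with any atom within 0.5 nm (inclusive) of
any protein atom; the complement is the nAL region. Shell membership is
re-evaluated every frame.

## Chain order profiles

For acyl carbon $n$ the local axis is the vector from carbon $n-1$ to
$n+1$ — the tilt of three sequentially connected carbons — and the profile
reports the second-Legendre order parameter
$S(n) = \langle (3\cos^2\theta_n - 1)/2 \rangle$ against the bilayer
normal, for interior carbons $2 \ldots N-1$. Note carefully: this is the
**chain-axis** order parameter of that three-carbon construction, not the
deuterium order parameter $S_{CD}$; the two differ in sign and scale, so
profiles from this package should not be overlaid on NMR $S_{CD}$ data.
The normal is the fixed z axis (planar membranes; no local-normal
estimation), double-bond positions receive no special treatment, and
$-0.5 \le S \le 1$ holds by construction.

## Nonbonded energetics

Group–group energies sum 12-6 Lennard-Jones and Coulomb terms over all
cross pairs within a plain 1.2 nm cutoff (inclusive), with
Lorentz–Berthelot combining and the CODATA-derived electrostatic prefactor
$f = 138.935458$ kJ·mol⁻¹·nm·e⁻². There is no shift, switch, long-range
correction, reaction field or PME: the quantities are raw truncated
interaction energies — deterministic in the positions but discontinuous at
the cutoff — not free energies, and they scale with the number of
interacting atoms. Interchain energies sum over all unordered chain pairs;
a monomer has no interchain energy and is reported not-applicable rather
than zero.

## Protein structure accounting

Hydropathy profiles use the Kyte–Doolittle scale with a centered 5-point
moving average; at the termini the window truncates rather than padding,
so no sequence is invented and a constant profile is preserved exactly.

DSSP codes are an **input** (the package never runs DSSP). Regrouping
follows the standard four-category scheme: E/B → beta, H/G/I → alpha,
T → turn, S/C → random. Blank or `~` codes are treated as coil and folded
into random — the conventional reading of DSSP output, flagged here
because the source convention is not fully specified. Category counts
partition the residues in every frame.

Residue contact maps hold the time mean and per-entry standard deviation
of the per-frame minimum atom-pair distance for every residue pair. The SD
is the population SD over frames (a single frame gives an exactly zero SD
matrix, via Welford accumulation rather than a cancellation-prone moment
difference). No pairs are excluded — the diagonal is zero and
sequence-adjacent pairs are present; consumers may mask. Interface blocks
(e.g. the 130 × 37 tau–amylin block of the hetero-dimer) are rectangular
sub-matrices over disjoint residue sets.

## The synthetic generator: what it emulates, and what it does not

The generator stands in for the MD campaigns the analyses were designed
around. Its defaults are the stated world of those campaigns:

* **Compositions**: PS-raft 162 POPS / 666 DPPC / 540 DLPC / 576 CHOL
  (65,365 waters when requested); GM-raft 36 GM1 / 709 DPPC / 407 DLPC /
  410 CHOL (56,114 waters). Tests default to a 1/8-scale raft for desk
  runtimes; the full scale is one flag away. No per-leaflet split is
  published, so non-anionic species split evenly between leaflets (odd
  lipid to the lower leaflet) — a documented convention.
* **Layout**: lipids sit on a jittered lattice at 0.64 nm² per lipid,
  headgroup planes 2 nm apart; lattice sites are ranked by distance to the
  Lo disc centre, the anionic cluster takes the innermost sites of its
  leaflet, DPPC and CHOL interleave through the rest of the disc, DLPC
  fills the outside. Leaflet asymmetry is preserved by construction (no
  flip-flop), and lipids are coarse bead chains — one headgroup reference
  bead plus ordered chain beads at 0.15 nm spacing — because the analyses
  need geometry, not chemistry.
* **Binding schedule**: the oligomer hovers between 3 and 6 nm above the
  surface while unbound (above the 2 nm contact threshold, so contact
  counts are zero), then at `t_bind` locks over its anchor — the anionic
  headgroup nearest the Lo centre — at a stable mindist of 0.5 nm plus
  Gaussian noise truncated at 1.96 sd. The truncation is deliberate: the
  emulated bound state is "firmly attached", so the plateau must not
  produce detachment excursions that would make the strict
  persistent-suffix detector disagree with the planted time. With zero
  noise the post-binding mindist equals the stable value exactly. Bound
  poses compress the protein's internal z extent (factor 0.4) to emulate
  an adsorbed, spread oligomer rather than a point contact.
* **Chain order**: per frame, every acyl chain is re-oriented as a rigid
  rod at a polar angle drawn from a two-component mixture — a delta at the
  pole (or, for negative targets, in the membrane plane) with weight
  chosen so the second-Legendre mean equals `s_target` exactly, plus an
  isotropic component contributing zero. The mixture is not a physical
  tilt distribution; it is the simplest seed-deterministic sampler whose
  order parameter is exact in expectation, which is what the recovery
  tests need.
* **Secondary structure**: each residue–frame cell draws its regrouped
  category from planted fractions, then a concrete DSSP letter uniformly
  within the category, so recovered category counts are multinomial around
  the planted values.
* **Sequences**: amylin is the canonical 37-residue human IAPP, whose
  smoothed hydropathy profile peaks at the expected anchors C7, L16, I26,
  V32. The 130-residue tau construct is a **synthetic stand-in** — a fixed
  polar background with hydrophobic patches planted at residues 6, 35, 66,
  86, 112, 121 — because the specific tau fragment is not identifiable
  from the available description. Analyses that depend on the tau
  sequence's identity beyond its length and hydropathy shape should not be
  read against the literature.
* **Force field**: a toy table over the generator's bead types. Molecule
  charges sum to formal charges (PS and GM1 −1 e; PC, CHOL, water 0);
  protein beads carry a uniform +0.1 e so anionic contacts are
  electrostatically favourable.

What a green test on synthetic data establishes is parameter recovery and
internal consistency — planted binding times, order parameters, layouts,
and fractions are recovered by the corresponding analyses within stated
tolerances. It does **not** establish agreement with the emergent results
of microsecond MD: domain compositions, binding times and energy
magnitudes of the real systems arise from dynamics this generator does not
contain. Two known fixture limitations are worth naming: the uniform
positive protein bead charge makes synthetic **interchain** Coulomb terms
repulsive (real aggregates pair mixed charges at their interfaces, giving
attractive totals), and the single-anchor binding pose keeps
annular-shell statistics much sparser than a real adsorbed oligomer
footprint would be.

## Campaign execution

`campaign_config()` defaults to the hetero-oligomer design — 1tam and 2tam
on the PS- and GM-raft, three replicates each: 12 runs, 180 µs of emulated
CG time, ~720 µs effective at the 4× diffusion speed-up of coarse-grained
water. Replicates differ in initial lateral placement (0, +2, −2 nm along
x) and in their derived seeds: each run's seed comes from a stable string
hash of the run id combined with the master seed, so runs are mutually
independent but individually reproducible. Per-run failures are caught,
logged and isolated; replicate aggregation reports mean ± SEM and flags
conditions with no completed runs. The analysis window defaults to the
last 5 µs of the emulated run. Desk-scale trajectories use 60 frames at
0.25 µs spacing — coarser than the emulated campaigns, which matters only
through the ± one-frame-spacing resolution of binding-time recovery.

## Numerical choices

* Distance thresholds are inclusive everywhere (`<=`).
* The cell-list neighbour search bins at the cutoff length; lateral cells
  wrap, z cells clamp to the data extent. It is exact, not approximate.
* Leaflet assignment ties (reference atom exactly on the midplane) resolve
  to the upper leaflet.
* SEM is `sd/sqrt(n)` over replicates and reported `NA` for a single
  replicate, never 0.
* GRO coordinates round-trip at the format's fixed precision (0.001 nm);
  frame times live in a `t=` token of the title line.
* Degenerate inputs fail loudly: empty selections, empty analysis windows,
  unknown residue names, missing force-field types and non-orthorhombic
  boxes are errors, not warnings. An empty annular shell reports absent
  percentages (`NA`), and an unbound trajectory reports `NA` rather than a
  time.

## Worked example

```{r example, eval = FALSE}
membrane <- build_raft(raft_spec("PS", "reduced", seed = 7))
complex <- build_complex(membrane, build_oligomer("1tam", seed = 7))
traj <- generate_binding_trajectory(
  complex, trajectory_spec(n_frames = 60, frame_spacing = 0.25,
                           t_bind = 3, seed = 7))

prot <- select_atoms(complex, molecule_type = "PROTEIN")
lip <- select_atoms(complex, molecule_type = c("DPPC", "DLPC", "CHOL",
                                               "POPS"))
detect_binding_time(mindist_series(traj, prot, lip), d_bind = 0.6)
domain_composition(traj, window = c(10, 14.75))
order_profile(traj, "DPPC", "sn1", shell = "AL", window = c(10, 14.75))
protein_lipidtype_energy(traj, emit_forcefield_table(),
                         window = c(10, 14.75))
```

The `analysis/` directory of the source repository chains these steps into
the full campaign narrative (fixtures → campaign → spectra → domains and
order → energetics and folding), writing tab-separated tables under
`results/`.
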