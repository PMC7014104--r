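---
title: "Methods: mapping and comparing nuclear-receptor allosteric sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping and comparing nuclear-receptor allosteric sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allosite)
```

`allosite` analyzes the two superficial allosteric sites of nuclear-receptor
ligand-binding domains — the AF-2 coactivator groove and the adjacent BF-3
site — from four angles: sequence conservation across a receptor panel,
cosolvent-probe density hotspots, conserved hydration sites, and
docking-score enrichment, plus the conformational adaptation connecting
them. This vignette explains each model, its assumptions, the parameters
that matter, and the numerical choices behind the implementation. The
upstream engines (MD, hydration thermodynamics, docking) are out of scope:
their outputs are consumed as files, and seeded synthetic generators stand
in for them during testing.

## Site definition and conservation scoring

A binding site is defined geometrically as the **contact shell**: every
protein residue with at least one heavy atom within `radius` (default
5.0 Å) of any heavy atom of a chosen cocrystallized ligand
(`select_site_residues()`). We read the "spherical zone" as a per-atom
contact shell rather than a single sphere about the ligand centroid:
centroid spheres over-select for elongated ligands, and the contact-shell
reading is the standard one for a "5 Å range" site. Hydrogens are ignored
on both sides because crystal structures usually lack them.

Conservation between receptors A and B is scored over the alignment
columns holding the site residues: a column contributes 1.0 when the two
residues are identical, 0.5 when they differ but share a physicochemical
group, and 0.0 otherwise. The percentage divides by the **site residue
count**, not by the number of gap-free pairs — it is a percentage of the
maximally achievable score, so gaps in either row count against the pair
(they contribute 0.0 but stay in the denominator). The shipped group
scheme is

```{r}
default_group_scheme()
```

chosen as the conventional five-class partition (aliphatic-hydrophobic,
aromatic, polar/small, basic, acidic); any complete partition of the 20
amino acids can be supplied instead, because published conservation
figures are sensitive to this table and reproducing a specific one may
require a specific grouping. Gap-versus-residue pairs score 0.0 — a gap
shares no group with anything.

Mapping site residues to alignment columns
(`map_site_to_alignment()`) assumes the reference receptor's ungapped
aligned sequence contains the structure-derived residue sequence as a
contiguous substring; residue identity is keyed by chain, author residue
number and insertion code throughout, since site residues are cited by
author numbering.

## Cosolvent density grids and hotspots

`compute_density_grid()` converts trajectory frames of probe molecules
into a voxel field of **bulk-normalized density**: the mean per-frame probe
heavy-atom count in a voxel divided by `voxel volume × ρ_bulk`, with
`ρ_bulk = N_probe / V_box`. The normalization fixes the unit: a voxel
sampled at bulk concentration reads 1.0, so an isovalue of 12 means
twelve times bulk — the threshold at which maps are inspected. Binning
all probe heavy atoms (rather than molecular centers of mass) matches the
atom-density maps one renders at an isovalue; a center-of-mass mode is
available. Probes outside the grid are ignored, and the construction
satisfies an exact mass-conservation identity (integrated density ×
ρ_bulk = mean in-grid atom count per frame) that the tests assert to
1e-9.

Default voxel spacing is 0.5 Å for production maps; the examples and
checks in this package use 1 Å voxels, which keeps per-voxel Poisson
noise manageable at desk-scale frame counts without moving hotspot
centroids by more than a fraction of a voxel. No periodic re-imaging is
performed — input frames are assumed wrapped.

`extract_hotspots()` takes the face-connected (6-neighbor) components of
voxels at or above the isovalue; 18- or 26-neighbor connectivity would
merge diagonal contacts that a viewer would see as separate lobes.
Components report a value-weighted centroid, volume, peak and mean, sorted
by peak with lexicographic-centroid tie-breaks for determinism. A
`min_voxels` filter (2 in our pipelines) suppresses single-voxel Poisson
satellites. Raising the isovalue provably never enlarges a component.
Maps round-trip through OpenDX exactly; the CNS dialect quantizes the
origin to integer grid units in its numeric records (a format
limitation), so the writer also emits the exact origin in a REMARKS title
line which our reader prefers and PyMOL ignores.

## Hydration sites

Water-oxygen positions from many sources — MD snapshots or superimposed
crystal structures (`extract_md_waters()`, `extract_crystal_waters()`) —
are clustered with DBSCAN at ε = 0.9 Å and `min_pts = 2`
(`dbscan_cluster()`). The neighbor count **includes the query point**, the
common convention under which `min_pts = 2` means "at least one other
water within ε"; the alternative reading would demand two other waters
and markedly thin the clusters. Border points join the first core cluster
that reaches them in input order — the classic DBSCAN order dependence —
so results are deterministic for a given point order, and the tests
compare labelings as partitions of core points rather than by border
ownership.

A cluster becomes a hydration site with centroid = unweighted member mean
and **occupancy** = distinct contributing sources / total sources. The
conserved-site filter uses a step schedule on the source count (default:
occupancy ≥ 0.5 below 10 sources, ≥ 0.4 for 10–29, ≥ 0.3 at 30 or more),
reflecting that a site seen in half of six structures is weak evidence
while 30% of fifty structures is strong; the schedule is fully
configurable because published protocols tabulate it differently.

MD-derived and crystal-derived sites are merged by **greedy
globally-closest matching** at a 1.4 Å threshold (`consensus_match()`):
repeatedly pair the closest unmatched pair, each site used once, consensus
centroid at the midpoint. Greedy matching is reproducible and essentially
optimal at hydration-site densities (sites are rarely closer than ε to
each other); a Hungarian assignment would differ only in contrived
near-tie geometries. Enthalpy and entropy per site are **inputs**
(`attach_site_energies()`), estimated upstream; sites with ΔH below
−1.0 kcal/mol are flagged favorable — waters whose displacement by a
ligand is enthalpically penalized.

## Conformational adaptation

`kabsch_superpose()` computes the least-squares rigid transform via SVD of
the weighted cross-covariance, with the determinant sign fixed so only
proper rotations are returned; near-collinear point sets raise a
degeneracy error rather than returning an arbitrary rotation.
Representative structures are selected as the **RMSD medoid**
(`select_representative()`): the member minimizing total pairwise
post-superposition RMSD, which is what a mutual-similarity jury ranking
reduces to under an RMSD similarity; contact-map-based jury variants are
deliberately out of scope. Ties break to the lowest index.

Per-residue adaptation (`per_residue_rmsd()`) superimposes the two
representatives once on their **whole shared backbone** (N, CA, C, O) and
then measures each site residue's heavy-atom RMSD in that global frame,
with no per-residue refit — the quantity of interest is how far the
residue moved within the site, displacement and rotamer change included,
not its internal geometry. Site-only superposition was the alternative;
whole-backbone fitting was chosen so that site-wide rigid shifts are
counted as adaptation rather than removed. Residues missing from either
structure (truncated termini, unresolved loops) are flagged, never
silently scored zero.

## Docking enrichment

Scores are kcal/mol with lower = better (the sign convention is stated
rather than inferred, to avoid silent inversion). `roc_auc()` is the
probability that a random active outranks a random decoy, computed by the
Mann–Whitney rank-sum formula with half-credit ties; the tests verify it
against full pair enumeration on a thousand random instances, including
heavily tied ones. `score_shift()` is `mean(others) − mean(actives)`, so
+1.0 kcal/mol means actives score better by one kcal/mol.
`pose_rmsd()` is the in-place heavy-atom RMSD between a redocked pose and
the native pose — no re-superposition, as both live in the receptor
frame — and takes the minimum over user-supplied automorphic atom-name
mappings for symmetric ligands (automated graph-isomorphism detection is
out of scope; reversed binding orientations of quasi-symmetric inhibitors
are a documented real phenomenon). Distribution summaries use shared
0.5 kcal/mol bins and report the histogram overlap coefficient
Σ min(p_i, q_i) alongside bin-free statistics.

## Synthetic data and what the tests show

The generators emulate the statistical structure of the upstream outputs,
not their physics:

- `gen_probe_trajectory()` places a fixed count of single-atom probe
  pseudo-molecules uniformly per frame — the count set by the 5% v/v
  loading through nominal molecular volumes (isopropanol 127.7,
  acetonitrile 86.8, pyrimidine 130.9 Å³) — plus, per planted hotspot, a
  fixed number of Gaussian-distributed extras chosen so the central
  density is `factor × bulk`:
  `n_extra = round((factor−1) ρ_bulk (2πσ²)^{3/2})`. Fixed counts keep
  the frame roster constant (a trajectory invariant); real cosolvent
  density fluctuates, aggregates and excludes volume around the protein,
  none of which is modeled.
- `gen_water_observations()` plants sites that appear in each source with
  the stated occupancy and isotropic jitter (σ = 0.25 Å in the study
  conditions, the scale of coordinate uncertainty in good crystal
  structures), over two uniform background waters per source to exercise
  noise rejection.
- `gen_alignment()` plants exact per-pair identical/same-group column
  counts against a reference row (so 0.5/0.5 over 20 columns gives
  exactly 75%), or samples categories per column.
- `gen_score_table()` draws Gaussian scores per class and returns the
  analytic AUC `Φ(Δμ/√(σ₁²+σ₂²))` as ground truth.

Passing tests therefore demonstrate that the *analyses* are correct —
normalization, clustering, matching, scoring, superposition — under known
ground truth; they say nothing about force fields, docking accuracy or
real solvent structure, which enter only through the input files.

Problem sizes were chosen to make the checks sharp but quick: 500 frames
of 200 probes in a 40 Å box for grid calibration (voxel mean 1.00 within
sampling error, zero spurious hotspots at 12× bulk), 800 frames for
planted-hotspot recovery (centroid within one voxel), 100 random 60-point
sets for DBSCAN-versus-oracle equivalence, 100 random ensembles of up to
10 structures for medoid agreement, and 2000 scores per class for
analytic-AUC recovery within ±0.02. The whole suite runs in well under a
minute.

Simulation-plan accounting (`simulation_plan()`, `plan_total_time()`)
tabulates protocol bookkeeping: the hydration protocol (8 receptors × 2
sites × (2 + 20) ns) totals 352 ns, and together with three 40 ns
pure-water replicates per receptor and a cumulative 1.2 μs of cosolvent
simulation per receptor the campaign exceeds 10 μs. The cosolvent
per-receptor total is an input to `cosolvent_plan()` rather than a
product of run counts, because the decomposition into probes × replicates
× durations × apo/holo variants is a campaign choice that does not
determine the stated cumulative time.

## Known limitations

- PDB only (via bio3d); no mmCIF, no binary trajectory formats, no
  crystal-symmetry expansion — merged crystal-water files must already be
  superimposed and symmetry-expanded upstream.
- Engineered residues in docking structures keep their file numbering;
  no renumbering to the wild-type sequence is attempted.
- The CNS map origin is exact only through the REMARKS side-channel;
  third-party readers see it quantized to the grid spacing.
- DBSCAN border-point ownership is order-dependent (documented above);
  greedy consensus matching is not guaranteed optimal for adversarial
  near-tie geometries.
- The conservation percentage depends on the residue-group table; results
  are only comparable across runs sharing one scheme.
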