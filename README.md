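# allosite

Analysis toolkit for the two superficial allosteric sites on nuclear-receptor
ligand-binding domains (LBDs): the activation function-2 (AF-2) coactivator
groove and the adjacent binding function-3 (BF-3) site. Allosteric inhibitors
targeting these sites promise to side-step the resistance and selectivity
problems of orthosteric nuclear-receptor drugs, but the sites are well
conserved across the hormonal receptor panel (AR, ERα, ERβ, GR, MR, PR, TRα,
TRβ), so off-target binding is a real design risk. `allosite` implements the
downstream analyses used to characterize these sites, for computational
chemists who already have structures, trajectories and docking tables in
hand:

- **Site conservation.** Site residues are the 5 Å heavy-atom contact shell
  around a cocrystallized ligand. For receptors A and B over the site's
  alignment columns, each column scores 1.0 (identical residues), 0.5 (same
  physicochemical group) or 0.0 (different group or gap), and the
  conservation percentage is `100 · Σ s_k / N` with N the site residue
  count — a percentage of the maximally achievable score.
- **Cosolvent hotspots.** Probe positions from mixed-solvent MD frames are
  binned on a voxel grid and normalized by the bulk probe density
  ρ_bulk = N_probe / V_box, so voxel values are dimensionless multiples of
  bulk; hotspots are face-connected components with value ≥ an isovalue
  (default 12× bulk). Maps write to OpenDX and CNS (PyMOL-compatible).
- **Hydration sites.** Water-oxygen positions from MD snapshots or merged
  crystal structures are clustered with DBSCAN (ε = 0.9 Å, min_pts = 2);
  each cluster's occupancy is the fraction of distinct sources contributing
  a water. Clusters passing a source-count-dependent occupancy criterion
  are conserved, MD and crystal predictions are merged by greedy
  closest-pair matching at 1.4 Å, and sites with ΔH < −1.0 kcal/mol are
  flagged enthalpically favorable.
- **Conformational adaptation.** Kabsch superposition, RMSD-medoid
  representative selection from an ensemble (the mutual-similarity "jury"
  criterion), per-residue heavy-atom RMSD between cosolvent and pure-water
  representatives in a shared backbone frame, and backbone RMSD series.
- **Docking enrichment.** ROC AUC of actives vs decoys (rank-sum statistic,
  ties half-credit), mean score shift of actives vs the library,
  symmetry-aware in-place pose RMSD, and score-distribution summaries.
- **Synthetic data.** Seeded generators with machine-readable ground truth
  emulate the upstream engines: probe trajectories with planted Gaussian
  enrichment hotspots over a uniform bulk at 5% v/v, water observation sets
  with planted conserved sites, site alignments with planted pairwise
  identity/group fractions, Gaussian docking-score tables with an analytic
  AUC, and simulation-plan accounting.

## Worked example

```r
library(allosite)

# conservation on a synthetic 4-receptor site alignment with planted
# 0.5 identical / 0.5 same-group columns versus the reference R1
aln <- gen_alignment(n_receptors = 4, n_columns = 20,
                     identical_frac = 0.5, group_frac = 0.5, seed = 7)
build_conservation_matrix(aln$alignment, 1:20)
#> conservation_matrix (% of maximally achievable score):
#>     R1    R2    R3    R4
#> R1 100  75.0  75.0  75.0
#> R2  75 100.0  62.5  65.0
#> R3  75  62.5 100.0  67.5
#> R4  75  65.0  67.5 100.0
```

Row R1's off-diagonal entries are exactly 75%: ten identical columns
(10 × 1.0) plus ten same-group columns (10 × 0.5) out of twenty.

```r
# a 20x-enriched probe blob planted at (20, 20, 20) in a 40 A box
tr <- gen_probe_trajectory(n_frames = 800, box = c(40, 40, 40),
                           n_probes = 200,
                           hotspots = data.frame(x = 20, y = 20, z = 20,
                                                 sigma = 2.5, factor = 20),
                           seed = 7)
grid <- compute_density_grid(tr$frames, "IPA", origin = c(0, 0, 0),
                             dims = c(40, 40, 40), spacing = 1,
                             bulk_density = tr$truth$bulk_density)
extract_hotspots(grid, isovalue = 12, min_voxels = 2)
#>   hotspot n_voxels volume peak     mean       x        y        z
#> 1       1       79     79 24.4 15.03291 19.7644 19.89138 20.06686
```

One hotspot, centroid within a quarter Angstrom of the planted center, peak
near the planted 20× enrichment (the maximum over voxels sits slightly
above 20 by selection).

```r
# conserved hydration sites from 30 noisy sources, then an enrichment report
w <- gen_water_observations(n_sources = 30,
                            sites = data.frame(x = c(8, 22), y = c(12, 28),
                                               z = c(30, 14),
                                               occupancy = c(0.9, 0.7),
                                               jitter = 0.25),
                            seed = 7)
filter_conserved(find_hydration_sites(w$obs, eps = 0.9, min_pts = 2,
                                      provenance = "crystal"),
                 w$obs$n_sources)
#>   provenance         x        y        z members occupancy dH mTdS
#> 1    crystal  7.977798 11.96471 30.03887      27 0.9000000 NA   NA
#> 2    crystal 21.997808 28.05363 13.95543      19 0.6333333 NA   NA

sc <- gen_score_table(seed = 7)   # planted 1.0 kcal/mol active-vs-library shift
enrichment_report(sc$records, receptor = "AR", site = "BF3")
#> enrichment_report [AR BF3]: 50 actives / 500 library / 500 decoys
#>   ROC AUC vs decoys: 0.714
#>   mean score shift vs library: +0.76 kcal/mol
```

Both planted waters come back within 0.1 Å at their planted occupancies
(0.90 and 0.63 observed of 0.9/0.7 planted); the score table's AUC and
shift estimates carry the expected sampling error at 50 actives.

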