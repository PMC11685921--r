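# kelpraft

Linking host dispersal to microbiome change in rafting bull kelp.

Detached southern bull kelp (*Durvillaea* spp.) rafts can drift for weeks
across strong oceanographic gradients before stranding. Their microbiomes
are reshaped along the way: the host-selected core erodes, fast-growing
water-column colonists invade, community dispersion rises, and alpha
diversity responds to the environmental variability experienced en route.
`kelpraft` re-implements, as one tested R pipeline, the inference chain
needed to study that process when only the collection endpoint is observed:

1. **Host genomics → source zones.** SNP panels are filtered (depth ≥ 5,
   MAC ≥ 2, missingness ≤ 0.2, ≥ 5000 SNPs/individual), a neighbour-joining
   tree with locus-bootstrap supports is built, and each raft is assigned by
   ascending its tip path to the first clade with bootstrap support > 80;
   the coastline spanned by that clade's reference individuals becomes the
   raft's target zone.
2. **Backward leeway drift.** Particles are seeded within 1 km and ± 1 day
   of the collection point and advected backward with an hourly Euler step
   through current + wind-leeway forcing (no added diffusion), terminating
   when they come within 2 km of the target zone, leave the domain, or have
   drifted for two years. The ensemble yields the rafting-time distribution
   and representative SST statistics.
3. **Environmental variability.** σ-SST — the standard deviation of sea
   surface temperature along a trajectory, or at a fixed point over the
   11 days (the median rafting period) before collection — is the proxy for
   environmental predictability. Modelled trajectories are validated against
   surrogate drifters with paired TOST equivalence tests (dz bound 0.25).
4. **Community analyses.** Rarefaction to 4000 reads, richness / Pielou
   evenness / Bray–Curtis, a core microbiome ranked by occupancy and cut by
   the last-3%-gain in explained Bray–Curtis (core taxa occupy ≥ 80% of
   samples), core/abundant/rare read partitions (abundant: mean non-raft
   abundance > 0.1%), PCoA dysbiosis scores (distance-to-non-raft-centroid
   minus distance-to-raft-centroid; > 0 is dysbiotic), and a
   community-weighted mean rRNA operon count as a growth-rate trait.
5. **Assembly processes.** iCAMP-style partitioning in phylogenetic bins of
   24: βNTI (abundance-weighted βMNTD standardized against within-bin tip
   shuffles) calls heterogeneous/homogeneous selection; otherwise
   Raup–Crick–Bray–Curtis (±0.95) calls dispersal limitation or homogenizing
   dispersal, else drift. Non-raft turnover is computed within populations.
6. **Statistical layer.** Generalized dissimilarity models with monotone
   I-splines (3 per predictor, non-negative least squares under the
   1 − exp(−η) link) and permutation importance; negative-binomial richness
   and beta-family evenness GAMs (mgcv) with AIC/concurvity selection;
   Wilcoxon rank-sum Z and Welch t tests.

Because the original field data are restricted-access, the package ships a
first-class synthetic-scenario generator (`scenario_config()`,
`gen_environment()`, `gen_host_populations()`, `gen_microbiomes()`,
`gen_drifter_tracks()`) that plants known truth — source populations under
isolation-by-distance, a 14-taxon core under strong homogeneous selection, a
hump of richness at intermediate σ-SST, and rising dispersion with
perturbation — so every stage is testable offline.

## Worked example

```r
library(kelpraft)
report <- run_pipeline(demo_config(seed = 1), out_dir = "demo_run")
```

The demo scenario (8 rafts, 25 particles each, 24 non-rafts, 100 ASVs)
completes in a few seconds and writes its artifacts (trajectories, trees,
tables, tidy CSVs) plus a `report.json`. With seed 1 it prints, among
others:

```
assign:    accuracy 1.00 (8/8 query rafts assigned to a zone containing
           their true source population)
drift:     mean fraction reached 0.985, median rafting time 5.27 days
community: core size 14, Jaccard vs planted truth 1.00
           mean dysbiosis score: rafts +0.057 vs non-rafts -0.087
           mean weighted rRNA operon count: rafts 2.24 vs non-rafts 1.69
stats:     GDM deviance explained 35.1%
```

i.e. the genetic assignment recovers every planted source, the drift stage
reconstructs rafting times, the core-microbiome walk recovers the planted
14-taxon core exactly, rafts score as dysbiotic relative to non-rafts and
carry faster-growing (higher rRNA operon count) communities — the
qualitative signature the pipeline is designed to detect. Re-running with
the same seed reproduces the report byte for byte.

The same stages are available individually (`seed_particles()`,
`advect_backward()`, `assign_source()`, `core_taxa()`,
`partition_processes()`, `fit_gdm()`, `tost_paired()`, ...) and from the
command line:

```sh
./exec/kelpraft all --out demo_run --seed 1
# or with a JSON configuration overriding scenario / stage controls:
./exec/kelpraft all --config my_scenario.json --out demo_run --seed 1
```

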