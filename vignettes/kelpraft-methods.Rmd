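---
title: "Models and design choices in kelpraft"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in kelpraft}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`kelpraft` chains four models — a Lagrangian leeway drift model, a
phylogenomic source-assignment rule, a family of community statistics, and
a null-model assembly partition — into one pipeline for rafting-macroalgae
microbiome studies. This vignette documents each model, its assumptions and
tunable parameters, the numerical choices made where the method description
left the design open, and what the synthetic scenarios do and do not
establish.

## 1. Backward leeway drift

A raft's state is its position, time, crosswind jibing sign, and a pair of
per-particle leeway slopes. The velocity at each step is

    v_total = v_current + dw * w + sign * cw * rot90(w)

where `w` is the 10-m wind vector, `dw` and `cw` are the downwind and
crosswind slopes (fractions of wind speed, drawn once per particle from
truncated normal distributions around the class coefficients), and `rot90`
rotates the wind 90° counter-clockwise. Integration is explicit Euler with
an hourly default step; for backward runs the total velocity is negated and
time stepped backward, sampling the forcing at the (earlier-moving) current
time with linear interpolation between daily slices — daily forcing with
hourly steps is smooth sampling without inventing sub-daily structure.
Metres convert to degrees on a spherical Earth (R = 6371 km) with the local
cos(latitude) for longitude; the 2-km target hit test uses haversine
distance to the zone's coastal points.

Termination follows three rules checked each step: within the hit radius of
the target zone (default 2 km), outside the domain box (default 20–50° S,
120–179° E), or drifting longer than `max_days` (default 730). Particles
touching non-target coast are *not* deactivated; land cells are handled by
the SST mask rule (nearest valid corner within the enclosing cell, else
error), mirroring the assumption that grounded rafts refloat when forcing
allows.

Numerical notes:

* Explicit Euler is first-order; the acceptance suite verifies that
  endpoint changes shrink roughly linearly as the step halves through
  120/60/30/15 minutes.
* Backward-then-forward reversibility is exact only when the return path
  samples the same velocities as the outbound one — in practice a uniform
  zonal flow. With a meridional component, the cos(latitude) factor is
  evaluated at slightly different latitudes in the two directions, leaving
  an O(dt²) residue; the reversibility check therefore uses a static zonal
  current.
* Crosswind sign is fixed per particle (no jibing events); the per-run
  leeway-class mix, and the PIW-1/5/6 default coefficients, are
  configuration — the published class tables are not reproduced here, so
  the shipped values are documented approximations and synthetic scenarios
  define their own classes.

## 2. σ-SST: environmental variability

`trajectory_env_stats()` interpolates SST (bilinear in space, linear in
time) at every trajectory state and returns the mean and *sample* standard
deviation; `static_point_stats()` does the same at a fixed point over the
trailing window `[end − w + 1, end]` sampled at the field's native daily
resolution, with `w = 11` days — the median successful rafting period — as
the default. A raft ensemble is summarised by the median across successful
trajectories of the per-trajectory mean SST and σ-SST ("successful only" is
the default; a switch includes all particles, since the original method
description does not say which set the medians are over).

## 3. Source assignment from SNPs

Filtering applies depth masking (< 5 reads → missing), then locus rules
(missingness > 0.2 or MAC < 2 dropped), then the individual rule (< 5000
called SNPs dropped) — in that order, so low-depth loci can die by
missingness. The tree is neighbour joining on the mean co-called dosage
distance `mean(|g_i − g_j|)/2`, midpoint-rooted, with supports from
locus-resampled bootstrap trees. NJ + bootstrap stands in for
maximum-likelihood inference deliberately: the assignment rule consumes
only topology and supports, and NJ is deterministic and desk-scale.

Assignment ascends from the query tip and anchors at the first internal
node with support > 80 whose clade contains a reference individual; the
spanned reference coordinates are the inferred source. Confidence tiers map
the clade's spatial extent: one population → `population`; span ≤ 150 km
(configurable — the original tiers are qualitative region names) →
`localized_region`; otherwise `broad_region`. Root reached without a
qualifying node → `unassigned`, and the drift stage is skipped for that
raft. Ties in "two most distant locations" break by first occurrence in tip
order, for determinism.

## 4. Community statistics

* **Rarefaction** draws exactly `depth = 4000` reads without replacement;
  shallower samples are dropped.
* **Core microbiome.** Taxa are ranked by a site-weighted occupancy index —
  the mean of overall occupancy and mean per-population occupancy, ties
  broken by mean relative abundance then label. The cited "spatial method"
  is identified only by reference, so this ranking is an isolated,
  documented stand-in behind one function. Walking the ranking, the
  explained proportion at rank *i* is the mean over sample pairs of the
  Bray–Curtis numerator restricted to the top-*i* taxa over the full-taxa
  denominator, normalised by the mean full Bray–Curtis; the core is the
  prefix up to the last rank whose marginal gain is ≥ 3 percentage points.
  The ≥ 80% occupancy expectation is checked post hoc (a warning, not a
  filter) — on the planted scenarios it is an emergent property, as the
  original description implies.
* **Dysbiosis.** Principal-coordinates embedding of Bray–Curtis keeping
  positive-eigenvalue axes (no negative-eigenvalue correction — only
  centroid distances are needed); score = distance to the non-raft centroid
  minus distance to the raft centroid, with the non-raft reference
  restrictable to populations overlapping raft sources.
* **rRNA trait.** Counts aggregate to genus; the community-weighted mean of
  genus mean rRNA operon counts uses only genera with a known count,
  renormalising the weights (case-insensitive exact genus matching, no
  fuzzy matching).

## 5. Assembly partitioning

Tips are binned bottom-up: the first clade whose unassigned tips reach 24
becomes a bin; root leftovers merge into the nearest bin by mean cophenetic
distance. Per sample pair and bin, abundance-weighted βMNTD is standardised
against `n_null` shuffles of the bin's taxa across the bin's own tips.

**Null-model choice.** The two communities receive *independent* tip
shuffles. The classical shared-shuffle null leaves identical communities
with a degenerate (zero-variance) null; under independent shuffles,
identical partial communities — whose observed βMNTD of zero is the minimum
of the null support — score strongly negative, which is the behaviour the
recovery tests require. The degenerate case still exists (both samples
occupying every bin tip) and is flagged, with βNTI defined as 0. Selection
is called in `confidence` mode (observed outside the central 95% of the
null; `ses` mode with |βNTI| > 1.96 is retained as an option), signed
heterogeneous (+) / homogeneous (−). Otherwise RCbray — the observed
Bray–Curtis's position within a null preserving each sample's richness and
total abundance, colonists weighted by pool occupancy then abundance,
rescaled to [−1, 1] with ties counted half — calls dispersal limitation
(> 0.95), homogenizing dispersal (< −0.95), or drift. Bin calls aggregate
to group fractions weighting bins by the mean relative abundance of their
taxa across the pair; non-raft pairs are restricted to within-population
comparisons by default. `n_null` defaults to 1000 for analyses and 100 in
tests; the 1.96/0.95 thresholds follow the framework conventions since none
are stated.

## 6. Statistical layer

**GDM.** Dissimilarity is modelled as `d = 1 − exp(−(a0 + Σ_k β_k
|f_k(x_a) − f_k(x_b)|))` with order-2 (piecewise-quadratic) I-splines —
three per predictor, knots at the predictor min/median/max — and
non-negative coefficients fitted by bound-constrained least squares
(L-BFGS-B, analytic gradient) on the untransformed dissimilarity. Deviance
explained is `1 − SSE/SSE_null` against the intercept-only fit. This is
faithful in form, not bit-identical, to the reference implementation, whose
objective is not printed. Permutation importance permutes each predictor's
*sample-level* values, refits, and reports the mean drop in deviance
explained normalised to 100 across predictors; p is the fraction of
permuted fits matching the observed deviance.

**Smooth GLMs.** Richness uses a negative-binomial family and evenness a
beta family with smooths of rafting time, SST and σ-SST plus a linear raft
status term. Fitting is delegated to `mgcv::gam` (REML) rather than the
originally sketched fixed-basis surrogate: mgcv is the method's reference
implementation and is available, so a surrogate would only add distance.
Evenness values of exactly 0/1 are nudged by `(y(n − 1) + 0.5)/n`.
Backward selection (optional) drops smooths with worst-case concurvity
above 0.9 or whose removal lowers AIC.

**TOST.** The paired equivalence bound is standardized (Cohen's dz, default
0.25): raw bounds ±`dz`·sd(d), two one-sided t tests with df = n − 1, p =
max of the two, 90% CI reported; a raw-unit bound is available. Note a
structural consequence: with dz = 0.25 and n = 21 the attainable |t| is at
most 0.25·√21 ≈ 1.15, so equivalence can never be declared at α = 0.05 no
matter how tight the differences — the acceptance tests assert this closed
form rather than pretending otherwise. **Wilcoxon** uses the tie-corrected
normal approximation with continuity correction (switchable), Z < 0 when
the first group ranks lower; **Welch** uses Satterthwaite df.

## 7. The synthetic world

The generator's defaults are the stated study conditions wherever the study
states them: 1 km / ±1 day seeding, 2 km hit radius, two-year cap, 11-day
windows, depth 4000, six structured source populations, a 14-taxon planted
core, bins of 24, 21 drifters. Where it is silent, values were chosen once
for realism: three latitudinal water masses (10/13/16 °C) with AR(1)
temperature anomalies (innovation sd 0.4–1.0 °C), a shore-parallel 0.35 m/s
jet with a 0.08 m/s offshore component (so backward trajectories converge
on the coast), stepping-stone allele-frequency drift of sd 0.15 per
population step (bull kelp populations are strongly structured),
Dirichlet-multinomial communities with non-raft concentration 400 (strong
homogeneous selection), a water-colonist mixing weight `t/(t + 20)` in
rafting days, concentration shrinking as `1/(1 + 1.2 σ)` (the
Anna-Karenina dispersion direction), and a Gaussian richness hump centred
at σ-SST 1.5 °C with width 0.8 (base 40, amplitude 45 taxa). Host genera
draw rRNA operon counts around 2 copies, water colonists around 5 —
colonists are the faster growers.

What a green test establishes: that each stage recovers the specific planted
structure under the generator's assumptions — Dirichlet-multinomial noise,
binomial genotypes, smooth idealised forcing. What it does not: performance
under real oceanographic complexity (eddies, Stokes drift, stranding), real
sequence evolution or taxonomic structure, contamination, or library-size
artefacts. The demo pipeline additionally scales everything down (25
particles/raft, widened 15-km hit radius, small null counts) to run in
seconds; its report is descriptive, and direction-of-effect claims are
asserted only on the full-size acceptance scenarios whose covariates span
the planted ranges.

## Known limitations

* No NetCDF reader is bundled (none is available in the supported
  dependency set); gridded fields use the documented long-format CSV
  dialect.
* The Euler scheme and the leeway-class defaults are adequate for
  desk-scale inference, not operational search-and-rescue accuracy.
* The GDM reports deviance on its least-squares objective; values are
  comparable within this package, not numerically interchangeable with
  other implementations.
* Bootstrap supports on very short internal branches are conservative;
  queries from admixed or unsampled populations surface as broader tiers or
  `unassigned`, never as false precision.
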