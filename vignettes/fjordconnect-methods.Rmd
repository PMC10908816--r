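---
title: "Linking oceanographic connectivity to picoplankton community structure: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking oceanographic connectivity to picoplankton community structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`fjordconnect` implements an inference chain that asks how much of the
between-site structure of fjord picoplankton communities (prokaryotes via
16S rRNA ASV tables, picoeukaryotes via 18S) is explained by physical
transport in the coastal ocean, and how much by environmental barriers —
above all temperature. The chain has five stages:

1. **Lagrangian transport**: virtual drifters released in cohorts at fjord-mouth
   sites and advected through a gridded daily-mean velocity field;
2. **Connectivity**: drifter-age-binned ensemble concentration fields, windowed
   release-to-receive connectivity matrices, and a normalised
   *hydrodynamic distance* between site pairs;
3. **Composition**: ASV-table hygiene, Bayesian-multiplicative zero replacement,
   centred log-ratio (CLR) transform and Aitchison distances;
4. **Diversity statistics**: Hill-number alpha diversity, PERMANOVA, redundancy
   analysis (RDA) with forward permutation selection, and univariate group
   tests;
5. **Coupling**: representative-site pairing, per-age-bin correlations of
   hydrodynamic with Aitchison distance, Aitchison-vs-dT regressions, and
   trophic functional-group profiles.

Everything runs on synthetic data from a parameterised scenario generator, so
the full chain is testable offline; the same functions accept real ASV tables,
metadata and velocity fields through the readers in `read_asv_table()`,
`read_sample_metadata()` and `read_velocity_field()`.

# The synthetic scenario

## Physical domain

`generate_velocity_field()` builds a rectangular grid (default 96 x 24 cells of
4 km, matching the horizontal resolution of regional ocean models for this
kind of coastline) whose top edge is a land band with one-cell-wide,
three-cell-deep fjord indentations. The open channel carries a uniform
along-coast boundary current (default 15 km/day, about 0.17 m/s) plus an
optional travelling cross-stream meander; fjord cells are quiescent, which
models fjord retention — drifters seeded inside a fjord stay there until the
channel flow or the meander picks them up, and drifters pushed into the coast
beach and freeze (coastal retention). Because the along-coast component varies
only across the channel and the meander has no cross-stream gradient, the
interior flow is non-divergent by construction, and all speeds are bounded by
twice the current speed.

A deliberate design choice: a single 2-D layer stands in for the 5–20 m
depth band that field studies track; connectivity logic at these scales is
insensitive to the vertical structure, and a single layer keeps the whole
chain runnable in seconds.

## Sites, temperature and subzones

`generate_site_network()` places `n_fjords` fjords along the current path,
each with head / middle / mouth sites. Surface temperature decreases
monotonically downstream from the warm to the cold end of `temp_range`
(default 12 degC to 0 degC), with a single sharp step (`barrier_step`,
default 3 degC) at `barrier_position` — the temperature barrier between
bioclimatic subzones. Subzone labels (temperate, subarctic, low Arctic,
high Arctic) follow path-position quartiles; nutrient covariates are drawn
with fjord-head enrichment, mimicking terrestrial and glacial inputs.

## Planted community structure

`generate_asv_tables()` builds, per domain, latent per-site
log-relative-abundance vectors and draws counts multinomially at `seq_depth`
reads (row sums exact). The latent model is logistic-normal: a Gaussian
random walk along the representative-site chain in CLR space, with step
variance `decay_rate^2 * hd` for the measured hydrodynamic distance `hd`
between consecutive mouths, plus a temperature loading scaled so the expected
Aitchison contribution is `temp_sensitivity * |dT|`. Since
`clr(softmax(v)) = v - mean(v)`, expected (noise-free) pairwise Aitchison
distances are exactly the Euclidean distances of the centred latents; the
`truth` record stores them so every planted divergence can be recomputed
without rerunning generation (`truth_aitchison()`).

Three further planted features mirror the field patterns the chain is meant
to detect:

* **Cold-site prokaryotic richness penalty**: a temperature-scaled fraction
  (up to `richness_cold_penalty_pro` at the coldest site) of 16S ASVs has
  occupancy forced to zero, in nested order, so cold sites are poorer.
* **Temperature-sensitivity contrast**: default
  `temp_sensitivity_pro = 2.4` vs `temp_sensitivity_euk = 1.2` degC^-1,
  a two-to-one contrast of the kind reported for prokaryotes vs
  picoeukaryotes.
* **Trophic cold shift**: named-group (autotroph/mixotroph/heterotroph)
  eukaryotic ASVs gain, and named-group prokaryotic ASVs lose,
  `trophic_cold_shift` CLR units times site coldness, planting eukaryote
  dominance within each trophic group at Arctic sites.

## Calibration of the planted magnitudes

The divergence scales are set so the synthetic data resemble real amplicon
surveys in the one respect that matters for the statistics: the ratio of
planted signal to compositional sampling noise. With 300–400 ASVs whose base
log-abundances have s.d. 1.5 and 5,000–10,000 reads per sample, two multinomial
draws from the *same* composition sit about 20–25 Aitchison units apart once
zeros are imputed — the replicate-level noise floor familiar from real
datasets. Planted between-site divergences must therefore span tens of units
across the whole gradient, as they do in real surveys; the defaults
(`decay_rate = 50` per unit hydrodynamic distance, temperature sensitivities
of a few units per degC over a 12-degC gradient) give full-gradient planted
distances of 30–60 units. These were fixed from this noise-floor argument,
not fitted to any test outcome.

The same argument sizes the trophic planting. A trophic-group x domain
cell's profile mean inherits noise from the spatial random walk at roughly
`walk sd / sqrt(n_ASVs in the cell)`, so the smallest cell (mixotrophic
prokaryotes, 10% of 16S ASVs — photoheterotrophy is common enough in
marine bacteria to justify the share) sets the floor: `trophic_cold_shift`
defaults to 6 CLR units at full coldness, about three times that smallest
cell's group-mean walk noise, so the planted eukaryote dominance carries
the right sign in essentially every scenario draw.

## What the generator does not emulate

No sequencing-error or chimera model, no primer bias, no inter-annual
revisits by default (real surveys show year-to-year outliers at revisited
sites), no sea ice, tides or 3-D shear, and taxonomically flat lineages.
Passing recovery tests therefore demonstrate that the *statistical chain*
detects planted transport and temperature structure at realistic
signal-to-noise — not that any particular ocean behaves this way.

# Transport and connectivity

`advect()` integrates drifters with classical RK4 at `dt = 0.25` day
(piecewise-constant daily fields, bilinear in space, land velocities zero),
storing daily positions indexed by drifter age so cohorts released every 10
days align by age. Against closed-form solutions, constant flow is recovered
to machine precision and solid-body-rotation radii to relative error below
1e-6 over a full period at `dt = 0.1` (the linear rotation field is exact
under bilinear interpolation, so this isolates time-stepping error).
Beached drifters freeze at their beaching cell and keep counting toward
concentrations (retention); out-of-domain drifters count only in
denominators.

`concentration_field()` pools every daily snapshot of every drifter whose age
falls in a cumulative bin ((0,30], (0,90], (0,180], (0,365] days by default)
and normalises by total observations, so the domain-wide sum is exactly 1
while no drifter has left. `connectivity_matrix()` averages a release site's
concentration over a 15 x 15-cell window centred on each receiving site (land
cells count in the denominator; windows clip at edges). The window matches
the averaging area used at 4-km resolution in regional studies; on toy grids
the clipping caps it automatically.

`hydrodynamic_distance()` symmetrises directed entries (default: the larger
direction — transport either way can homogenise communities; `"mean"` is
available), marks zero-concentration pairs *unconnected* rather than
maximally distant, takes `-log10` of concentration, and min–max normalises
within each age bin over connected pairs. Negation is the only reading of an
"inverse" log-scale distance that is bounded and monotone on (0,1]
concentrations; a literal reciprocal `1/log10(C)` is kept behind a flag.
Normalisation is per bin because the downstream correlations are computed per
bin. Cumulative bins make connectivity monotone: widening a bin can only add
connected pairs.

# Compositional stack

`filter_asvs()` removes ASVs with table-wide totals of 1 or 0, organelle
(16S) and metazoan (18S) ASVs, and reports-then-drops samples left empty;
silent drops are forbidden. `replace_zeros()` implements the
Bayesian-multiplicative treatment with a square-root Dirichlet prior
(`s_i = sqrt(n_i)`), prior proportions from column geometric means ("GBM");
imputed values are capped below 65% of each sample's smallest observed
proportion, re-closing iteratively. Simple multiplicative replacement — whose
output is a one-line closed form — is retained both as an option and as the
oracle the tests check against. `clr()` uses natural logarithms (the
compositional-literature convention; a base change only rescales distances)
and `aitchison()` is Euclidean distance on CLR rows, verified to 1e-10
against a brute-force pairwise log-ratio oracle.

# Diversity statistics

Hill numbers are computed directly: q=0 is observed richness, q=1
`exp(Shannon)`, with multinomial bootstrap standard errors (default 100
resamples) at observed depth. Coverage-based rarefaction/extrapolation is
deliberately out of scope; observed Hill numbers plus bootstrap error are
reported instead. Evenness is reported in two variants because protocols
differ: the literal `H / S` (default here, matching the source protocol's
wording) and classical Pielou `H / ln S`; with equal abundances the former is
`ln(S)/S`, the latter exactly 1.

PERMANOVA, RDA and forward selection run through vegan (`adonis2`, `rda`,
`anova.cca`) — the same machinery practitioners use — behind a stable
package interface; p-values use the add-one convention and free (unrestricted)
permutation, seeded explicitly so every result is reproducible. PERMANOVA
R2 and pseudo-F are additionally verified against a brute-force
sums-of-squared-pairwise-distance oracle at every test run.

Forward selection (`forward_select()`) is a greedy adjusted-R2 maximiser with
two gates per step: the marginal permutation p-value must fall below `alpha`
(at most `perm_max` permutations), and the running adjusted R2 must stay
within the full-model adjusted-R2 scope. The scope carries a finite-sample
allowance `(1 - R2adj_full) * p/(n - p - 1)` — the expected share of residual
variance absorbed by `p` uninformative predictors — because without it a
single strong predictor is rejected whenever noise covariates drag the full
model's adjusted R2 below the single-predictor value, which happens about
half the time by construction in the planted-signal regime. This is the one
place the package deviates from the plain `ordiR2step` stopping rule, and it
only ever *admits* candidates the plain rule would reject for being too good.

Group comparisons follow the ANOVA + pairwise Welch t-test scheme
(`var.equal = FALSE`) with Bonferroni adjustment across each pairwise family,
with Kruskal–Wallis + Wilcoxon as the non-parametric alternative. Pairs in
which both groups are exactly constant are treated as a null result (t = 0,
p = 1) rather than an error.

# Coupling and trophic profiles

Each fjord enters the between-fjord analyses through one *representative*
site — the one closest to the fjord mouth (ties broken by site id, logged);
mouth stations the flow model cannot resolve can be excluded, removing their
fjords (23 candidate stations minus 2 exclusions leave 21 sites and 210
unordered pairs). The pair table keeps unconnected pairs as rows; they are
excluded only inside correlations, never silently dropped.

Pearson correlations of hydrodynamic vs Aitchison distance are computed per
age bin on connected pairs (bins with fewer than 3 connected pairs are
skipped; constant hydrodynamic distances are flagged as undefined rather
than returned as r = NA silently). Aitchison-vs-dT regressions are ordinary
least squares with 95% slope intervals, fitted for all pairs, within-subzone
pairs, and each subzone-crossing class.

Trophic profiles resolve a genuine ambiguity in how concatenated CLR tables
can be "normalised to 1": CLR values are signed, so the package shifts each
sample's concatenated CLR vector by its minimum and divides by the total —
the only reading that yields non-negative fractions summing to 1 — then sums
within trophic-group x domain cells, keeping unannotated signal as an
explicit `unknown` cell to preserve the normalisation. A consequence worth
knowing: the *domain totals* of such profiles are fixed by the ASV counts of
each domain, so between-site trophic signal lives in the within-group
domain balance (`trophic_euk_share()`), which is what the group tests
examine. High and low Arctic are merged into one Arctic group by default
before testing, as Arctic subzones are individually small.

# Numerical and design choices, in brief

* RK4 with `dt` dividing 1 day exactly; storage at daily ages; RNG only in
  seeding, advection deterministic.
* Permutation p-values never exactly 0 (add-one); all permutation seeds are
  derived from one scenario/pipeline seed, so a run is one pure function of
  its configuration.
* Zero-variance guards: constant predictors are rejected for z-scoring;
  constant `delta_T` or hydrodynamic distances are flagged undefined.
* Degenerate inputs: samples with fewer than two non-zero ASVs are a hard
  error for zero replacement; empty age bins return zero fields with
  `n_obs = 0` and a warning.
* Problem sizes for the replicated recovery studies (`recovery_study()`):
  12 fjords on a 48 x 16 grid, 300 drifters per site over one year, 300
  ASVs per domain at 5,000 reads, 20 replicates — the smallest sizes at
  which the planted effects are comfortably inside working signal-to-noise,
  chosen once as the package's study conditions.

# Known limitations

The synthetic coastline is a single straight band, so connectivity is
essentially one-dimensional; real archipelagos have branching pathways that
make hydrodynamic distance genuinely two-dimensional. The latent model
plants divergence in CLR space directly, so it cannot probe taxon-level
mechanisms (selection vs drift), only the statistical detectability of
transport and temperature structure. The pipeline's PERMANOVA/RDA stage
treats samples as exchangeable; temporal pseudo-replication at revisited
sites, if present in real data, must be handled by the user.
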