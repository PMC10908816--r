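# fjordconnect

Do ocean currents or temperature barriers structure the smallest plankton?
`fjordconnect` is an R package for linking modelled oceanographic
connectivity between fjord sites to the community structure of marine
picoplankton (prokaryotes from 16S rRNA ASV tables, picoeukaryotes from
18S). It is written for microbial ecologists and biological oceanographers
who want to run — or stress-test — the full inference chain from Lagrangian
particle transport to compositional community statistics on one desk.

## What it computes

**Transport.** Virtual drifter cohorts are seeded around fjord-mouth sites
and advected through a gridded daily-mean velocity field (RK4, bilinear
interpolation, beaching as coastal retention). Drifter-age-binned ensemble
concentration fields yield a release x receive connectivity matrix
(windowed means around each receiving site), and from it the
**hydrodynamic distance** between sites *p, q* per age bin *b*:

    HD_b(p, q) = minmax_b( -log10 C_b(p, q) )   on connected pairs,

where `C_b` is the symmetrised windowed drifter concentration and
`minmax_b` rescales to [0, 1] within the bin; unconnected pairs are
excluded, not set to 1.

**Composition.** ASV tables are filtered (singletons, organelles,
metazoans), zeros are imputed by the Bayesian-multiplicative method
(square-root Dirichlet prior), and samples are compared in Aitchison
geometry: `d(x, y) = || clr(x) - clr(y) ||_2` with
`clr(x) = ln(x / g(x))`.

**Statistics.** Hill-number alpha diversity (q = 0, 1) with bootstrap
errors; PERMANOVA (`R2 = SS_between / SS_total`, free permutations,
add-one p-values); RDA with forward permutation selection of z-scored
environmental predictors; Pearson correlations of hydrodynamic vs
Aitchison distance per age bin over representative (fjord-mouth) site
pairs; Aitchison-vs-|dT| regressions within and across bioclimatic
subzones; and trophic functional-group profiles from concatenated CLR
tables with Welch-t/Bonferroni group tests.

**Synthetic scenarios.** A generator plants all of this structure —
boundary-current connectivity, a temperature gradient with a sharp
inter-subzone step, compositional distance-decay, a two-to-one
prokaryote/eukaryote temperature-sensitivity contrast, cold-site
prokaryotic richness loss, and cold-site eukaryote dominance per trophic
group — with known parameters, so every stage is testable without any
download.

## Worked example

```r
library(fjordconnect)

sc <- generate_scenario(scenario_config(seed = 5))
sc
#> Synthetic scenario: 21 fjords / 63 sites, 21 representative
#>   ASV tables: 16S 63 x 400, 18S 63 x 400 (depth 10000)
#>   connected pairs (longest bin): 210 / 210

c16 <- aitchison_from_counts(sc$asv_pro)   # filter -> impute -> CLR -> dist
c18 <- aitchison_from_counts(sc$asv_euk)

reps <- select_representative_sites(sc$metadata)
pt <- build_pair_table(reps, c16$dist, c18$dist, sc$hydro)
correlate_hd_beta(pt, "16S")
#>   bin_lo bin_hi      r         p n_pairs
#> 1      0     30 0.6906 4.268e-31     210
#> 2      0     90 0.6920 2.937e-31     210
#> 3      0    180 0.6881 8.513e-31     210
#> 4      0    365 0.6821 4.270e-30     210
```

The correlation says that the further apart two fjords are in drifter
transport terms, the more dissimilar their prokaryotic communities — here
r is approximately 0.69 in every drifter-age bin because the scenario
planted exactly that distance-decay. A one-call orchestrator runs the
whole chain and writes every table plus a machine-readable summary:

```r
res <- run_pipeline(pipeline_config(synthetic = scenario_config(), seed = 1))
res$summary$permanova$subzone_16S
#> $r2
#> [1] 0.434823     # fraction of Aitchison variance between bioclimatic subzones
#> $p
#> [1] 0.001
res$summary$forward_selection$predictors_16S
#> [1] "temperature"   "sun_elevation"
```

The PERMANOVA says 43% of the prokaryotic compositional variance lies
between bioclimatic subzones (p at the permutation floor), and forward
selection picks `temperature` first — the planted dominant driver —
followed by `sun_elevation`, which co-varies with the along-path gradient.

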