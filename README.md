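# pdaccum

Tracking how known phylogenetic diversity accumulates over the history
of species discovery.

## The problem

Faith's phylogenetic diversity (PD) of a species set is the sum of
branch lengths of the subtree spanning those species on a dated
phylogeny (units here: millions of years, Myr). *Known* PD at a date is
the PD of the species formally described up to that date. Each new
description adds a marginal contribution — the branch length that
species brings to the already-known tree — so the history of taxonomy
traces an accumulation curve of known PD. If recent discoveries add
little PD, our picture of a clade's evolutionary history is essentially
complete even while species descriptions continue; if the curve is
still climbing steeply, much evolutionary novelty remains undescribed.

`pdaccum` provides the full pipeline for this analysis, for anyone with
a dated species-level phylogeny and a table of formal description
years:

- **Supertree assembly** — build a species-level time tree from an
  order-level backbone and donor trees by clade extraction (with the
  stem edge), branch-length rescaling to the backbone depth, and
  grafting; insert orders missing from the backbone using stem-length
  ratios from a reference tree; repair non-monophyletic families by
  reattaching misplaced species as basal polytomies at the family
  crown; and prune tips not recognized by the reference taxonomy.
- **Marginal PD contributions** — for a discovery order
  \(s_1, s_2, \dots, s_n\), species \(s_k\) contributes
  \(\Delta_k = \mathrm{PD}(\{s_1..s_k\}) - \mathrm{PD}(\{s_1..s_{k-1}\})\),
  the path from its tip to its attachment point on the known tree (the
  first species is credited its root-to-tip depth). Species sharing a
  description year are removed in random order; means and empirical
  95% intervals are taken over permutations (and over tree samples).
  Contributions conserve: \(\sum_k \Delta_k = \mathrm{PD}\) exactly.
- **Counterfactual orders** — a null model that permutes which species
  carries which description year (uniformly random discovery order on
  the same time axis), a reversed discovery order, and pointwise
  difference curves.
- **Trend estimation** — ordinary least squares of
  \(\log \bar\Delta_i\) on description year or discovery count; the
  per-unit percent decline is \(100\,(1-e^{\beta})\) with delta-method
  standard error \(100\,e^{\beta}\,\mathrm{SE}(\beta)\). Plus per-order
  curves, decade-by-order PD fractions, most-distinctive discovery per
  decade, and the recent per-discovery PD increment.
- **Synthetic data** — birth–death time trees with nested
  order/family taxonomies, discovery years with a Linnaean-style
  initial burst and an optional bias toward evolutionarily distinct
  species (fair-proportion weights), plus fixture sets that exercise
  the whole merge pipeline against a known truth tree.

## Worked example

```r
library(pdaccum)

cfg <- sim_config(n_species = 300, n_orders = 10, distinctness_bias = 2,
                  initial_burst_fraction = 0.1, seed = 42)
phy <- simulate_tree(cfg)                 # ultrametric tree + taxonomy
tab <- assign_discovery_years(phy, cfg)   # species,order,family,year

cc <- mean_contributions(phy, tab, n_perm = 100, seed = 42)
total_pd(phy)
#> [1] 4719.042

head(cc[order(-cc$mean_pd), c("species","order","year","mean_pd")], 2)
#>     species order year  mean_pd
#> 21   sp0021 Ord02 1758 76.86037
#> 279  sp0279 Ord03 1758 72.81818

cy <- accumulation_curve(cc, "year")
milestone_year(cy, 0.5, "pd");  milestone_year(cy, 0.5, "richness")
#> [1] 1786
#> [1] 1872

fit_decline(cc, "year")
#> Log-linear decline of PD contributions on year:
#>   slope -0.0125358 (SE 0.000721), n = 300, R^2 = 0.503
#>   decline per unit: 1.246% (SE 0.0712%)

recent_increment(cc, 50)
#> [1] 3.112985
```

Half of present-day PD in this simulated world was known by 1786 —
almost a century before half of the species were (1872), because the
biased discovery process found the evolutionarily distinct lineages
first. The average contribution of a new discovery shrinks by about
1.25% per year, and a discovery in the last half-century adds about
3 Myr of branch length on average.

With real data, replace the simulated inputs with your own files:

```r
res <- run_pipeline(run_config(trees = "merged.nwk",
                               species = "species.csv",
                               out_dir = "out", n_perm = 100,
                               n_rand = 100, seed = 1))
```

which writes `contributions.csv`, year/count curves, null and reversed
curves, difference curves, `trend.json`, per-order summaries and a
manifest with input/output checksums. A thin command-line wrapper with
`simulate`, `merge`, `accumulate`, `trend` and `run` subcommands is
installed at `inst/cli/pdaccum.R`.

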