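---
title: "Methods: known-PD accumulation over species discovery history"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: known-PD accumulation over species discovery history}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdaccum)
```

This vignette records the model, the conventions, and the design
choices behind `pdaccum`, in the spirit of a statistical methods
section: what is computed, under what assumptions, and where the
genuinely open decisions were made.

## The quantity of interest

Phylogenetic diversity (PD) is used in its strict sense: the sum of
branch lengths, in Myr, of a dated phylogeny or of the subtree spanned
by a species set *and the root*. Known PD at date $t$ is the PD of the
set of species formally described by $t$. The analysis decomposes
total PD into per-species marginal contributions: order the species by
description date, and credit species $s_k$ with

$$\Delta_k \;=\; \mathrm{PD}(\{s_1,\dots,s_k\}) -
                 \mathrm{PD}(\{s_1,\dots,s_{k-1}\}),$$

the length of the path from its tip to its attachment point on the
subtree spanned by the earlier species plus the root.

**First-species convention.** The source literature is silent on what
the very first described species contributes. We define the PD of a
single-species set as that species' root-to-tip depth, so the first
discovery is credited its full path and the decomposition telescopes:
$\sum_k \Delta_k = \mathrm{PD}$ *exactly*, for every ordering. This
conservation identity is the backbone of the test suite.

**Algorithm.** Rather than pruning and re-summing the tree $n$ times
($O(n^2)$), `contribution_sequence()` marks edges: walk from each newly
discovered tip toward the root, credit every not-yet-marked edge to
that species, and stop at the first marked node. Each edge is traversed
once, so a whole discovery order costs $O(n)$; the tests verify exact
agreement with a brute-force remove-and-recompute oracle built on an
independent descendant-set computation (phangorn), including
exhaustively over all $720$ orderings of a 6-tip tree.

**Within-year ties.** Description dates are resolved to years, so ties
are common. Species sharing a year are removed in uniformly random
order; `mean_contributions()` averages over `n_perm` permutations per
tree (default 100, the convention of the discovery-record literature)
and, when several tree samples are supplied, pools over trees ×
permutations. 95% intervals are empirical 2.5/97.5% quantiles across
replicates, not normal approximations — the replicate distributions
are strongly skewed (a species drawn first in its year can collect a
long shared branch). Whether the intervals should pool over trees,
permutations, or both is not decidable from the source material; we
pool over both, and the replicate matrices are kept as attributes so a
user can re-summarize differently.

Cumulative known PD at the end of a year is the PD of a fixed species
set, so the year-axis curve is invariant to within-year order; only the
count-axis curve and per-species values have within-year spread.

**RNG.** One master seed; per-replicate seeds are drawn from it up
front, so replicate $r$ is reproducible in isolation and results are
byte-identical under a fixed seed.

## Supertree assembly

The merge machinery emulates how a species-level time tree is built
from published trees of different ranks: take an order-level backbone,
and for each order extract that order's clade from a species-level
donor *with its stem edge*, rescale, and graft over the backbone
placeholder.

- **Rescaling semantics.** The target of `rescale_clade()` is the
  clade's *stem-to-tip depth* (stem age), not its summed branch length.
  Grafting time trees must preserve tip contemporaneity; matching
  summed lengths instead would destroy ultrametricity. All edges are
  multiplied by one factor, so edge-length ratios are preserved
  exactly.
- **Missing groups.** When the backbone lacks an order,
  `place_missing_groups()` reads the order's sister from one reference
  tree and sets its stem from the ratio of missing-to-sister stem
  lengths in a second reference, applied to the sister's backbone stem
  *before* insertion; the group is inserted on the sister's stem edge
  at that age, keeping tips at the present. The reference trees carry
  the ratio via *stem-length pendants* (each order collapsed to a tip
  at its crown): with full-depth placeholder pendants the ratio would
  be identically 1 for ultrametric sisters and carry no information.
  If the inferred stem is not shorter than the sister's stem the
  placement is reported as unresolvable rather than silently clamped.
- **Non-monophyly repair.** A species known to be misplaced is ignored
  during extraction and rescaling (so it cannot inflate its family's
  apparent depth), then reattached at its true family's crown node as
  an additional child — a basal polytomy — with pendant length equal
  to the family's crown age: the maximum value that keeps it inside
  the family crown with its tip at the present. This deliberately
  overstates that species' own branch length in exchange for keeping
  the rest of the family's branch lengths intact. For a family reduced
  to a single tip no crown exists; we attach at the midpoint of that
  tip's pendant edge, the choice that preserves family monophyly
  without asserting an unknowable divergence age.
- **Reconciliation.** Tips not recognized by the reference taxonomy
  are pruned, with degree-2 nodes suppressed by summing their incident
  edges, which preserves all pairwise path lengths among retained tips
  exactly. Polytomies are accepted everywhere and never arbitrarily
  resolved.

## Counterfactual discovery orders

The null model re-assigns the observed multiset of description years
to species uniformly at random (year labels permuted, remaining ties
randomized). This keeps the historical tempo of taxonomy — the number
of descriptions per year — fixed, so null and observed curves share
the same time axis; an alternative null drawing years independently
would confound order randomization with tempo changes. The reversed
order treats the latest-described species as the first discovery.
Difference curves are computed pointwise on the observed grid, with
the reference carried over by stepwise-constant interpolation
(cumulative curves are step functions); when both curves carry
replicate matrices on the same grid, the envelope comes from
replicate-level differences with replicates paired cyclically.

Because every ordering conserves total PD, all counterfactual curves
end at the observed total and every difference curve ends at exactly
zero. Under a discovery process biased toward evolutionarily distinct
species, the observed curve stochastically dominates the null at
essentially every rank: the difference is positive early and at most
of the grid, shrinking to zero only near the end. A transient phase
with the null *above* the observed curve — as seen in empirical
discovery records during the earliest collecting era — requires
spatially or logistically clustered early effort, which the synthetic
generator deliberately does not model (see Limitations).

## Trend statistics

`fit_decline()` regresses $\log \bar\Delta_i$ (one point per species,
cross-replicate mean contribution) on description year or on discovery
count. The log transform both stabilizes the fit and keeps predicted
contributions positive. The reported quantity is the per-unit percent
decline $100\,(1 - e^{\beta})$ — the multiplicative "percent lower
than the previous unit's value" reading — with delta-method standard
error $100\,e^{\beta}\,\mathrm{SE}(\beta)$. It is invariant to
rescaling all contributions by a constant. The `from_x` cutoff (1780
by convention) excludes the opening burst of descriptions, which is a
single-year mass at the range start and would otherwise lever the fit.
For the count axis, tied years receive their average rank — the
expected rank under within-year randomization — so the regressor is
deterministic. A species' full marginal contribution is attributed to
its own order in the per-order summaries even when part of the added
path lies on shared backbone edges: the marginal contribution is
indivisible, and the order-wise sums still add up to the overall curve
exactly.

Decades are calendar decades from 1750 (`[1750, 1760)`, …); a final
partial decade is kept as-is. Most-distinctive-per-decade ties break
by earlier year, then name. The recent per-discovery increment is the
mean contribution over the trailing 50 years of descriptions, an
estimate of the floor divergence a newly recognized species carries.

## The synthetic generator

`simulate_tree()` draws a constant-rate birth–death tree conditioned
on $n$ extant tips (`ape::rphylo`), rescaled to a root depth of
100 Myr — the order of magnitude of a vertebrate class radiation — so
branch lengths are in Myr. Orders are cut at the $k-1$ oldest internal
nodes (guaranteeing monophyly of the synthetic taxonomy), families by
the same cut within orders. Defaults: 200 species, birth 0.1/Myr,
death 0.03/Myr, description years 1758–2013, a 10% first-year burst
(the Linnaean start), and `distinctness_bias = 0`.

Discovery order is drawn by successive weighted sampling with weights
$e^{b z_i}$, where $z_i$ is the standardized fair-proportion
evolutionary distinctness of tip $i$ and $b$ is `distinctness_bias`.
This exponential-weight sampler is a modeling stand-in, not an
inference claim: the empirical literature documents *that* early
discoveries were phylogenetically distinct, not a mechanism. $b = 0$
gives an exchangeable uniform order (verified by rank-uniformity
tests); $b \approx 2$ produces the qualitative features of the real
record (PD milestone decades before the richness milestone); the
acceptance tests use $b = 8$ where a strong, unambiguous signal is
needed.

`simulate_source_trees()` manufactures a merge problem whose answer is
known: a truth tree; a backbone with one order deliberately omitted;
stem-pendant reference trees on a 0.7× time scale (so only ratios are
informative); species-level donors with branch lengths uniformly
inflated (1.5×, 1.7×, …), one species moved into the wrong order, and
one unrecognized tip. Recovering the truth topology (Robinson–Foulds
distance 0 on shared tips, misplaced species excluded) while staying
ultrametric is the merge module's acceptance bar.

`simulate_contributions()` bypasses the tree entirely and draws
$\log c = \log c_0 - r\,(t - t_0) + \varepsilon$,
$\varepsilon \sim N(0, \sigma)$ — exactly the model `fit_decline()`
estimates — for parameter-recovery tests (defaults $r = 0.008$/yr,
$\sigma = 0.5$, matching the scale of decline seen in real discovery
records).

**What passing tests do and do not show.** The generator reproduces
the statistical skeleton the analysis relies on — ultrametric dated
trees, nested monophyletic taxonomies, a burst-plus-biased-order
discovery process, log-linear contribution decay — so green tests
demonstrate the pipeline's correctness and calibration under those
assumptions. It does not emulate biogeography, collector effort,
body-size-mediated detectability, taxonomic lumping/splitting, or
non-monophyly arising from genuine phylogenetic conflict; conclusions
about any real clade require real trees and real description dates.

## Numerical conventions and problem sizes

Ultrametricity is asserted to $10^{-9}$ relative tip-depth spread for
simulated trees and $10^{-6}$ after grafting chains; conservation to
$10^{-9}$ relative, and agreement between the incremental algorithm
and the brute-force oracle to $10^{-12}$ (identical edge sets, summed
in different orders). Degenerate inputs fail loudly: empty clades,
zero-depth rescaling targets, non-monophyletic extraction sets (with
intruders named), unplaceable missing groups, undated tips and
tip/table mismatches (after normalizing case, spaces and underscores)
are all errors, never silent repairs. The test and acceptance suites
run at deliberately modest sizes — trees of 10–80 tips for exhaustive
and ensemble checks, 2000 species × 100 seeds for trend recovery, 20
independent worlds for null-envelope calibration — chosen so the full
suite completes in well under a minute while every assertion retains
its discriminating power; all sizes are plain function arguments, and
nothing in the package caps them.

## Known limitations

- The null-envelope calibration check is pointwise; envelopes are not
  simultaneous confidence bands.
- `run_merge()` expects backbone groups to be placeholder tips (the
  natural representation after collapsing orders); grafting into a
  backbone where a group is already a multi-tip clade is supported by
  `graft_clade()` directly but not orchestrated by the plan runner.
- Missing-group placement requires the inferred stem to be shorter
  than the sister's backbone stem; deeper placements (missing group
  older than the sister's attachment) are reported as errors.
- Description years are integers; sub-annual ordering information, if
  known, must be encoded by the caller via distinct pseudo-years.
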