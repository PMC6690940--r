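---
title: "Insular phylogenetic endemism: models, null tests and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Insular phylogenetic endemism: models, null tests and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(islandpe)
```

## The problem

Islands concentrate evolutionary history: a lineage may survive on an island
after going extinct on its source landmass (relictualization), or may have
diverged recently in isolation. Phylogenetic endemism (PE) quantifies this
concentration for presence/absence data on a dated phylogeny. `islandpe`
computes PE for islands-by-genera incidence data, tests it against a
randomization null model, and classifies islands as areas of paleo-, neo-,
mixed- or super-endemism.

## The metrics

Let the phylogeny have branches $c$ with lengths $l_c$ (millions of years),
and for an island $i$ let $C_i$ be the set of branches on the paths joining
the genera present on $i$ to the root. Each branch has an island range
$R_c$: the number of islands harboring at least one of its descendant
genera. Then

$$\mathrm{PE}(i) = \sum_{c \in C_i} \frac{l_c}{R_c},$$

so a branch contributes much to an island only when it is both long and
geographically rare. With all $R_c = 1$ (an island holding every branch
alone) PE reduces to Faith's phylogenetic diversity.

Two variants differ in how genera that also occur on continents are
weighted:

* **Expanded (PE~E~)** uses the island counts $R_c$ as-is, treating all
  genera native to islands equally.
* **Restricted (PE~R~)** sets the denominator of any branch supporting a
  continent-occurring genus (terminal or internal, with at least one
  continental descendant) to `n_max`, the maximum number of islands a genus
  could occupy — by default the number of islands in the incidence matrix.
  Continental lineages thus carry almost no weight, and PE~R~ approximates
  the PE of island-restricted genera without actually excluding continental
  genera (which would distort deep branches shared by both). An
  alternative reading — applying the rule only to terminal branches of
  continental genera — is available via `terminal_only = TRUE` but is not
  the default, since the stated intent is that continental lineages as a
  whole have very little influence. Whenever `n_max` is at least the
  maximum observed range, PE~R~(i) $\le$ PE~E~(i) everywhere: the rule can
  only shrink weights.

**PEalt** recomputes the same sum with every branch length replaced by a
single value $l$, by default the arithmetic mean of all branch lengths of
the input tree. It keeps the topology and range structure but removes
branch-length variation, so it measures the concentration of *rarity*
regardless of branch age. The ratio

$$\mathrm{RPE}(i) = \mathrm{PE}(i) / \mathrm{PEalt}(i)$$

is dimensionless and invariant under a global rescaling of branch lengths;
RPE $> 1$ means the rare branches on the island are unusually long (old),
RPE $< 1$ unusually short (young). If a Newick file supplies a root edge it
is ignored both in the sums and in the mean: it belongs to every island's
root path and would only add a constant. Zero-length branches are retained
(they contribute 0 to PE but $l$ to PEalt, by the uniform-topology intent).

## The null model and the categories

PE, PEalt and RPE all grow with richness, so observed values are compared
with a fixed-marginal randomization: genus occurrences are shuffled among
islands such that each island keeps its number of genera and each genus
keeps its number of islands. The sampler is the curveball algorithm
(pairwise row trades of non-shared presences; `vegan`'s sequential
implementation), with a burn-in of 5 times the number of presences and one
sample every "number of presences" trades. Curveball mixes quickly on
sparse binary matrices and preserves both marginals exactly; the package
verifies marginal conservation on every emitted matrix in its tests, plus
uniformity on an exhaustively enumerable fiber. A consequence of the fixed
marginals is that the *total* PE summed over islands is identical in every
randomization for the expanded variant — the null redistributes
evolutionary history but never creates it — which the test suite asserts to
1e-9. (Under restricted weighting the continental branches contribute
$l_c R_c / n_{max}$, and $R_c$ varies across randomizations, so exact
conservation holds only for the expanded variant.)

For each island and metric, 1,000 randomizations (by default) yield tail
frequencies: the proportion of simulations in which the observed value is
strictly greater (or strictly less) than the simulated one. Ties count in
neither tail — the conservative choice toward non-significance. RPE under
the null is the ratio of the simulated PE and PEalt of the same randomized
matrix, so each metric is tested row-wise against its own null.

Categories are assigned at a two-tailed level `alpha` (default 0.05), with
`super_alpha` (default 0.01) for the extreme subdivision. An island is
**significant** when PE or PEalt exceeds a fraction $1-\alpha$ of its null
values. Significant islands are then classified, in this order:

1. **paleo** — RPE significantly high;
2. **neo** — RPE significantly low;
3. **super** — PE *and* PEalt in the highest `super_alpha` fraction;
4. **mixed** — PE and PEalt both significantly high, RPE in neither tail;
5. **significant_other** — significant via the OR rule but matching none of
   the four categories (e.g. only PEalt high with mid RPE).

The RPE-tail rules precede super/mixed, resolving the formal overlap: an
island with extreme PE and PEalt *and* a significant RPE tail is paleo (or
neo), because mixed endemism is by definition the case where neither
dominates. Thresholds are inclusive ($\ge 0.95$, $\le 0.05$). No
multiple-testing correction is applied across islands. The four named
categories do not exhaust the significance region, so `significant_other`
islands are reported but excluded from four-category counts. Under the
restricted variant, islands harboring no island-specific genus are excluded
from testing (they cannot be areas of restricted endemism by construction);
the null model still randomizes across all islands.

## Occurrence cleaning and sampling coverage

Upstream of the metrics, `filter_native_status()` discards records of
genera flagged non-native in their island's region polygon (unknown status
passes through), and `filter_bounding_box()` discards records outside the
genus's native-range bounding box. Boundary points are retained ("outside"
is read strictly). Boxes crossing the antimeridian are encoded with
`lon_min > lon_max` and treated as the union of two longitude segments — a
naive min/max box would invert Pacific ranges. All exclusions are counted
per rule.

Under-sampled islands are flagged with a species–area model:
`fit_richness_model()` regresses $\log_{10}$ richness on $\log_{10}$ area
(optionally plus isolation), and `exclude_undersampled()` drops islands
whose observed richness falls below the prediction divided by a factor
(default 5, boundary-inclusive retention). The species–area power law is
the standard island richness baseline, and the exclusion rule needs only a
prediction, not a particular model, so the model is pluggable behind
`predict_richness()`.

Sampling completeness per island is scored with the incidence-based
coverage estimator (ICE) over caller-defined sampling units, infrequent
cutoff 10:
$S_{ice} = S_{freq} + S_{infreq}/C_{ice} + Q_1\gamma^2/C_{ice}$ with
$C_{ice} = 1 - Q_1/N_{infreq}$, and the relative coverage
$ICE_r = S_{obs}/S_{ice} \in (0, 1]$. When every infrequent incidence is a
singleton ($C_{ice} = 0$) the estimate falls back to a Chao2-type form and
is flagged unstable; islands without sampling units are flagged undefined.
How $ICE_r$ should *correct* the metrics is genuinely open, so the package
exposes modes rather than guessing: `off` (default), `divide_observed`, and
`divide_both`. Note that `divide_both` — an island-specific multiplier
applied to observed and null values alike — cannot change any category,
because the tail frequencies are rank statistics, invariant under monotone
transforms applied to both sides; the tests assert this. The main
coverage-based analysis is `sensitivity_sweep()`, which re-runs the
categorization on nested island subsets with $ICE_r \ge t$ for a grid of
thresholds and reports per-island category stability.

## The synthetic-data generator

Real-world occurrence corpora for this analysis are not redistributable at
package scale, so `islandpe` ships a generator whose outputs exercise every
stage, including the real parsers (Newick + delimited text).

* **Tree**: pure-birth (Yule) with genus tips. A designated fraction of
  tips form a long-branch pool (terminal lengths multiplied by `m_long`,
  default 5) and a short-branch pool (`m_short`, default 0.2). Pure birth
  with post-hoc terminal scaling was chosen over a birth–death model
  because it gives direct, interpretable control of the rare-long and
  rare-short pools that define the paleo/neo signal.
* **Occupancy**: islands-per-genus follows a power law truncated at the
  island count (default exponent 2, under which most genera occupy one or
  two islands) — natural-history occurrence data are strongly right-skewed,
  and rarity (low $R_c$) is the lever of phylogenetic endemism. Pool genera
  are capped at `pool_max_islands` (default 2).
* **Planting**: designated paleo/neo/mixed islands receive pool genera
  (round-robin, `genera_per_planted` each) with concentration probability
  `kappa`; at `kappa = 0` planted islands are indistinguishable from
  background. Continental flags go to the most widespread non-pool genera.
* **Records**: islands are points on a synthetic globe; each presence emits
  1–3 jittered records; native boxes derive from the generating positions
  plus a margin. Configurable fractions of out-of-box and non-native noise
  records are injected with bookkeeping, so tests can assert that the
  cleaning filters remove *exactly* the noise and recover the clean
  incidence.

Everything is deterministic given the scenario seed (per-stage seeds are
derived from it).

What passing these tests shows — and does not. The generator emulates the
statistical shape the analysis assumes: skewed occupancy, heterogeneous
branch lengths, plantable rare-branch concentrations. It does not mimic
spatial autocorrelation of real archipelagos, taxonomic structure,
collection-effort gradients, or name-resolution noise. Recovery of planted
signal therefore validates the machinery (metrics, null, categorization),
not the field performance of the method on any particular corpus.

## Problem sizes, calibration benchmarks and numerical choices

The packaged benchmarks use desk-scale worlds chosen to give stable Monte
Carlo behavior:

* *Type-I calibration*: 20 signal-free worlds of 40 islands x 100 genera,
  500 randomizations. The per-island significance rate is the OR of two
  level-$\alpha$ tail tests, hence bounded by $[\alpha, 2\alpha]$; the test
  asserts the empirical rate inside that interval with a 3-sigma binomial
  allowance.
* *Recovery benchmark* ("strong scenario"): 60 islands, 200 genera,
  occupancy exponent 1.2, four planted paleo and four planted neo islands,
  each seeded with 14 single-island pool genera (`m_long = 10`,
  `m_short = 0.1`, `kappa = 1`), 500 randomizations, 10 replicate worlds.
  Strict recall (a planted paleo island counts only when labeled paleo) is
  0.8 for paleo and 1.0 for neo, with false positives at the alpha-driven
  baseline. The paleo misses are labeled super or mixed: planted islands
  also accumulate rare background branches, which is genuinely mixed signal
  — a real feature of the category system, not a defect of the test. A
  flatter occupancy background (exponent 1.2 rather than 2) is used here
  because a background saturated with power-law singletons is itself full
  of rare branches, diluting the contrast the benchmark is meant to plant.
* *Null exactness*: on a 3x3 incidence whose fixed-marginal fiber is small
  enough to enumerate, sampled null means at 10,000 draws match the
  exhaustive fiber averages within 3 Monte Carlo standard errors.

Numerical conventions: tail counts use strict inequalities; category
thresholds are inclusive; PE conservation is asserted to 1e-9 relative;
the toy worked example is asserted to 1e-12; results tables serialize
floats with 12 significant digits; longitudes are normalized to
[-180, 180]; genus-to-tip matching is exact after whitespace trimming
(case-sensitive — unmatched names are surfaced, never guessed); duplicate
occurrence records collapse silently to presence; percentages in category
summaries are reported to 2 significant figures.

## Known limitations

* The analysis is presence-only and island-count-based; no range-area or
  abundance weighting.
* No spatially structured null (neighborhood constraints) and no
  frequency-weighted null are provided.
* The ICE variance term uses the caller-supplied unit count (or a
  lower-bound default); with very few sampling units the estimator is
  unstable and flagged rather than silently trusted.
* `significant_other` islands show that the four categories do not
  partition the significance region; they are reported separately.

## A minimal session

```{r example, eval = FALSE}
sc <- endemism_scenario(n_genera = 120, n_islands = 40, seed = 1,
                        paleo_islands = 1:2, neo_islands = 3:4,
                        f_paleo = 0.3, f_neo = 0.3, m_long = 10,
                        m_short = 0.1, occupancy_exponent = 1.2,
                        pool_max_islands = 1, genera_per_planted = 9)
d <- synthesize_dataset(sc)
res <- run_endemism(d$tree, d$incidence, d$annotations, n_sims = 500, seed = 1)
res
tidy(res)
summarize_categories(res$assignments[res$assignments$variant == "expanded", ],
                     total_islands = nrow(d$incidence))
autoplot(res)
```
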