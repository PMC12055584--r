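---
title: "Models and methods behind rhizotrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rhizotrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizotrace)
```

rhizotrace analyses serial-propagation rhizosphere experiments: a soil
microbiome and seed-borne rhizosphere bacteria (SbRB) coalesce, over repeated
plant-passage cycles, into a stable rhizosphere community. This vignette
documents the models the package implements, the parameters that matter, the
numerical choices, and what the synthetic study can and cannot tell you about
real data.

## The synthetic study

### Community model

The simulator holds a fixed universe of taxa split into two source pools: a
taxon-rich soil pool and a small seed pool, with an optional overlap
(`n_shared_taxa`). Within-pool relative frequencies are log-normal
(`freq_sdlog`, default 1), giving the uneven rank-abundance profiles typical
of 16S surveys. Every taxon carries a constant positive fitness drawn
log-normally (`fitness_sdlog`, default 0.3); seed-pool members are shifted up
by a factor `2^fitness_advantage_seed` per generation, encoding the premise
that heritable seed-borne bacteria are pre-adapted to the rhizosphere while
most soil taxa are not.

Within a cycle the community grows by a **discrete replicator** map,

$$x_i' = \frac{x_i\, w_i^{g}}{\sum_j x_j\, w_j^{g}},$$

with `g = generations_per_cycle` (default 5). There are no interaction terms:
selection is frequency-independent, which keeps the mapping between planted
parameters and outcomes identifiable. Facilitation and cross-feeding are
represented only in the planted MAG/function structure, not in the dynamics.

### Propagation design

Each cycle's inoculum mixes the carried community with fresh seed input,
linearly in frequencies:

```
inoculum = transfer_fraction * carried + seed_input_load * seed_freq   (renormalized)
```

Cycle 1 carries the soil wash; later cycles carry the mean of the previous
cycle's observed replicate compositions, so sampling noise propagates as it
would through real serial transfers. Defaults are 6 cycles x 4 replicates
with `transfer_fraction = 0.1` and `seed_input_load = 0.05` (seeds are
present in every new plant, so seed input recurs at every cycle). Sequencing
is a multinomial draw per replicate; the default depth of 1e5 reads per
sample is a free choice of the synthetic design — real depth varies by run
and the analyses operate on relative quantities. A "recovered" sample set is
re-drawn from the final cycle's frequencies, modelling a thawed, re-grown
community without freeze–thaw mortality (observed recovered communities
closely match the final cycle).

With the default seed advantage (1 log2 unit per generation, i.e. 32x per
cycle) selection is front-loaded: most of the sorting happens during the
first cycles and the seed-pool taxa dominate the final community. This
matches the qualitative signatures such experiments report — an early strong
shift away from the soil composition, taxa selected early being maintained,
and a net loss of Shannon diversity — but it compresses the *progressive*
part of the decline into fewer cycles than a real succession.

### Planted truth in the companion tables

* **Functions**: seven classes (enriched in one of the three communities,
  suppressed in one, balanced), NB-distributed counts (`dispersion = 0.2`)
  around a log-normal baseline (`base_mean = 200`). The planted fold change
  defaults to 16 (log2FC = 4): with triplicate metagenomes and the
  |log2FC| >= 2.5 significance floor, a planted log2FC of 3 would sit about
  one standard error from the decision boundary, so even a perfect estimator
  would miss a third of planted functions; 16 keeps the planted effect
  comfortably detectable so that recovery measures classification logic, not
  boundary luck.
* **MAGs**: completeness/contamination drawn across all quality tiers; each
  MAG's TPM profile either satisfies the 1.5x single-community rule or is
  deliberately placed inside the 1.5x band (`frac_multi = 0.2`);
  lower-pathway sugar reactions are planted in ~90% of all MAGs, while
  complete upper-disaccharide and vitamin (nicotinate, riboflavin) routes are
  planted preferentially in seed-community MAGs. The riboflavin and
  nicotinate route definitions use the conventional KEGG reaction IDs; the
  upper disaccharide hydrolysis rules use representative hydrolase reactions
  and are overridable via `pathway_complete()`'s rule argument.
* **Growth**: focal strains grow on monosaccharides alone but poorly on
  disaccharides; co-culture with the helper strain boosts disaccharide growth
  8-fold, planting facilitation exactly where hydrolysis capability is
  seed-specific.

### What passing tests do and do not show

The simulator produces multinomial noise around smooth replicator dynamics.
Real amplicon data additionally contain compositional artefacts, chimeras,
run effects, taxa arriving from outside both sources, and interaction-driven
dynamics. Ground-truth recovery on simulator output therefore validates the
*bookkeeping* — filtering, matching, accounting, classification rules — and
the statistical calibration of the tests, not the biological completeness of
the model.

## Analysis methods

### CSS normalization

The per-sample scaling factor is the sum of the sample's counts at or below
its empirical quantile (computed over nonzero counts, type-7), times a
constant (default 1000). The `"auto"` quantile follows the published
heuristic: per-sample quantile profiles are compared to their median
reference profile and the chosen quantile is the smallest at which the
relative instability of the median deviation between successive grid
quantiles exceeds 0.1, falling back to 0.5 when instability already appears
below the 0.5 quantile (without this floor the heuristic degenerates to the
lowest grid point on overdispersed tables). CSS rescales samples, so
within-sample ratios of nonzero features are preserved exactly.

### Diversity, ordination, group tests

Shannon diversity uses natural logs (the common ecology default; the base is
an argument). Faith's PD sums the branch lengths of the minimal subtree
spanning the present tips and includes the root path by default, matching
the convention of the standard PD implementation (verified against it in the
tests); `include_root = FALSE` restricts to the subtree below the tips' MRCA.
PCoA is classical scaling of the double-centred distance matrix; negative
eigenvalues are reported unaltered, since downstream interpretation should
see them. ANOSIM and PERMANOVA delegate to vegan — the implementation such
studies actually cite — wrapped with a seedable permutation stream; with
9,999 permutations the smallest attainable p is 1e-4. The Spearman trend
p value uses the t-approximation by default; an exact small-sample p is
available through `exact = TRUE` (no ties).

### Source tracing

The sink universe is the set of features with nonzero mean abundance in the
sink community. Features are linked across tables by **exact full-length
sequence identity** — no mismatch tolerance, since ASVs are already denoised
sequence variants and the question is identity, not similarity. Presence in
a source is a nonzero mean across its replicates; for non-negative data this
coincides with "present in any replicate", so the `presence` flag changes
nothing numerically and exists for interface clarity. Emergence curves count
a feature as *new* at the first cycle where its mean relative abundance
reaches the threshold, with the inoculum included as cycle 0 by default — a
feature already present in the soil wash did not emerge during succession.
Note that per-cycle new counts can shift between cycles as the threshold
rises (a trajectory straddling two thresholds is first detected later); the
quantity that is provably monotone in the threshold is the cumulative number
of features emerged by each cycle, and that is what the tests assert.

### Negative-binomial Wald test

A deliberate re-implementation, not a port, of the standard
NB-Wald/median-of-ratios analysis:

1. **Size factors**: arithmetic median, per sample, of count/geometric-mean
   ratios over features positive in all samples (positive-count geometric
   means as a logged fallback), normalized to geometric mean 1.
2. **Dispersion**: per-feature method-of-moments estimates
   `(var - mu * mean(1/s)) / mu^2` averaged over the two groups, floored at
   1e-8, then shrunk on the log scale toward a trend `a/mu + b` fitted by
   least squares with positive-part truncation. The shrinkage weight
   (default 0.85) was chosen by a calibration study at the package's null
   design (mu 50, dispersion 0.2, 4 vs 4): weaker shrinkage leaves the
   normal-referenced Wald test anticonservative (type-I error ~0.065–0.078
   at nominal 0.05), while 0.85 brings it into the 0.05 band without
   sacrificing >= 0.8 power for planted log2FC = 3 at dispersion 0.1.
   Features whose moment estimate collapses (sub-Poisson variance) take the
   trend value.
3. **Group means**: the mean of size-factor-normalized counts. For equal
   factors within a group this *is* the NB maximum-likelihood solution, and
   unlike an offset-weighted ML fit it makes the log2 fold change exactly
   invariant to rescaling any sample's counts — the property the
   normalization exists to provide. Standard errors come from the Fisher
   information of the log mean at the fixed dispersion; all-zero groups are
   floored at half a count over the group's total size factor.
4. **Decision rule**: two-sided normal p, BH adjustment across tested
   features (missing p values excluded from the ranking), significance =
   |log2FC| >= 2.5 and adjusted p < 0.01 — the rule conventional in this
   literature. No Cook's-distance outlier handling, no independent
   filtering, no LFC shrinkage: at the package's scale these mainly trade
   transparency for small power gains, and their absence is part of the
   package's contract (the reference tool remains the cross-check in the
   test suite, not the implementation).

The minimum-total-count filter for metagenome functions (>= 1000 summed
counts across samples) is exposed as `min_total` and applied before testing.

### Dominance classification

Each function's three pairwise DA outcomes feed a total, deterministic rule:
a community is **enriched** if it is significantly higher in *both*
comparisons involving it; **suppressed** if it is significantly lower in
both of its comparisons and no community is enriched; everything else is
**balanced**. With consistent pairwise outcomes at most one community can be
enriched and at most one suppressed (two simultaneous suppressions would
require contradictory outcomes in their shared pair), so the seven
categories are mutually exclusive — this per-community reading of
"suppressed" is the one that makes the category system coherent; a global
reading ("not significantly more abundant in any comparison") would collapse
the per-community suppressed categories and is not implemented. The
"significantly higher" predicate inherits the full significance rule,
fold-change floor included, for consistency with the single stated rule.
Ternary coordinates divide each function's per-community mean TPM by the
triple's sum, after excluding functions with mean TPM <= 0.5.

### MAG rules

Quality tiers apply contamination first (>= 10% discards regardless of
completeness), then the highest completeness tier whose strict bounds hold.
Community assignment: a MAG belongs to a single community when its mean TPM
percentage is >= 1.5x that of *each* other community; otherwise it belongs
to every community within a factor 1.5 of the maximum (ratios, not
arithmetic differences — the two clauses are complementary only on the
ratio scale; zero-TPM communities are excluded). A value at exactly 1.5x
satisfies the >= of the singleton clause, so exact-boundary ties assign
singly. Pathway completeness treats a rule as alternative routes of jointly
required reactions: complete iff some route is a subset of the MAG's
reactions, with the best route's coverage fraction reported either way.
Kruskal-Wallis category comparisons count a multi-assigned MAG once per
assigned community by default (`count_multi = "first"` keeps only the first
listed assignment), and report NaN instead of a p value when every MAG has
the same count (no variability to test).

### Rank statistics and growth

Kruskal-Wallis uses the tie-corrected statistic; the post hoc letters come
from Fisher's LSD applied to mean ranks with pooled rank variance
`S2 (N - 1 - H) / (N - k)` and t-referenced pairwise p values,
BH-adjusted. The compact letter display uses insert-and-absorb: start from
one set of all groups, split on each significant pair, absorb subsets, and
letter the surviving sets alphabetically — groups sharing a letter are not
significantly different. Wilcoxon rank-sum tests are exact for
`min(n) <= 8` without ties and normal-approximated (tie-corrected)
otherwise; with triplicates the one-sided exact p cannot go below 1/20, so
perfect separation yields exactly p = 0.05. Growth normalization subtracts
each strain set's mean no-carbon control; negative normalized values are
kept and flagged rather than truncated, since truncation would bias the
facilitation tests.

## Determinism and problem sizes

Every generator draws from one RNG stream seeded from its config
(sub-generators at documented offsets), so identical configs give
byte-identical datasets, and `run_pipeline()` writes byte-identical report
directories for the same seed (the config serialization excludes the output
path). The packaged demo and test suite run at desk scale by design: 40–90
taxa, 4 replicates, 2e4–1e5 reads per sample, 140–280 functions, 45 MAGs —
sizes at which every brute-force oracle in the test suite can recompute the
analysis exactly, while all thresholds stay at their field-standard values
(prevalence 0.05, |log2FC| 2.5, adjusted p 0.01, min TPM 0.5, min total
1000, assignment ratio 1.5, 9,999 permutations).

## Known limitations

- The replicator model has no interactions, no spatial structure, no
  plant feedback, and no explicit exudate chemistry; it is a testbed for the
  analysis chain, not a fitted model of any real succession.
- The NB Wald test is intentionally minimal; for production differential
  abundance on real data the reference tool offers outlier handling and
  shrinkage this package deliberately omits.
- TPM values are consumed as provided; computing TPMs from reads, and all
  upstream assembly/binning/annotation, are out of scope.
- Exact matching cannot trace features that mutated or were mis-denoised
  between source and sink; untraced features are reported, not explained.
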