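---
title: "Models and methods behind perenniome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind perenniome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perenniome)
```

`perenniome` compares rhizosphere and root-endosphere bacterial
communities between a perennial grain (Kernza) and an annual cereal
(wheat) sampled across countries, years and soil depths. This vignette
explains each statistic the package computes, the assumptions behind
it, the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the numerical choices made
where the design was genuinely open.

## Input model and normalization

The unit of observation is a sequencing library: a vector of ASV
counts. Libraries differ in depth for technical reasons, so analyses
run on counts per thousand (CPT): each sample row is scaled to sum to
1000. CPT is a pure rescaling of the compositional information; rank
tests and Bray–Curtis distances are unaffected by the choice of 1000
versus proportions.

Two filters precede analysis:

- **Sparsity** (`filter_sparsity()`, default `min_samples = 3`): ASVs
  detected (count > 0) in fewer than three samples are removed.
  Detection means any nonzero count; no minimum-count notion of
  presence is used anywhere in the package, so occupancy statistics
  and the sparsity filter agree.
- **Low abundance** (`filter_low_abundance()`): removes ASVs below a
  fraction of the grand total. The default is 0 (no filtering):
  literal thresholds of the order of 1% would eliminate nearly every
  ASV in a realistically diverse table, so the value used in a run is
  an explicit analysis decision, recorded in the table's provenance
  attribute and the pipeline manifest rather than silently applied.

Chao1 is computed on raw integer counts even when other metrics use
CPT, because singleton and doubleton counts are undefined on scaled
reals; passing a normalized table is an error, not a warning.

## Beta diversity and the variance partition

Bray–Curtis dissimilarities feed a sequential (Type I) PERMANOVA via
`vegan::adonis2` with `by = "terms"`: each factor is attributed the
variance left after the factors before it, in the user-given order.
The package default order is year, country, crop, depth. Interaction
terms are out of scope. Permutation p-values follow the
`(1 + #{F* ≥ F}) / (1 + n_perm)` convention with a user seed; marginal
(Type II/III) attribution is not offered because the sequential
partition keeps the r² values summing to 1 with the residual, which is
what the downstream reporting assumes.

## Homogeneity: µ_D

For any grouping of samples, every unordered sample pair falls in
exactly one cell: within one group or between two groups. µ_D is the
mean pairwise Bray–Curtis dissimilarity of a cell; a group of n
samples contributes n(n−1)/2 within-pairs, and the pair-count-weighted
mean of all cell µ_D values equals the overall mean dissimilarity (a
conservation property the tests assert). Cells are compared with
unpaired Wilcoxon rank-sum tests on the pairwise-distance lists,
BH-adjusted across the family. Pairs sharing a sample are not
independent, so these p-values are a conventional screen rather than
an exact test — a caveat inherited from standard practice with
distance-based group comparisons. Comparisons never mix compartments:
when a `compartment` column is present the rhizosphere is analysed
unless another compartment is requested explicitly.

## Inter-annual stability: ∆RA

For one crop, each ASV's mean relative abundance is computed per year
and the ratio `(RA_y2 + ε)/(RA_y1 + ε)` taken, with pseudocount ε
defaulting to half the smallest nonzero normalized value. The default
inclusion rule keeps ASVs detected in both years (`detected_both_years`);
`detected_either_year` is available but requires ε > 0. Ratios can be
formed on the crop's pooled samples (default) or per stratum (e.g. per
country) and then averaged per ASV — both orders are exposed because
the aggregation order is a genuine analysis choice with no canonical
answer.

One property of ∆RA deserves emphasis. Relative abundances close to a
constant sum, so when a community reshuffles between years the
up-ratios and down-ratios largely cancel in the mean: the mean ratio
sits near 1 for stable and unstable communities alike, and comparing
mean ∆RA between crops is uninformative about stability. What does
respond to turnover is the *dispersion* of the per-ASV ratios. The
summary therefore reports, alongside the mean and s.d., the
scale-symmetric `mean_abs_log_ratio`; the package's stability
comparisons (and its tests) rank crops by ratio dispersion, not by the
mean's distance from 1.

## Core membership

An ASV is core to a crop when it holds at least `min_total_ra`
(default 0.001, i.e. 0.1%) of the crop's summed reads and occurs in at
least `min_occupancy` (default 0.90) of the crop's samples, pooled
over countries, years and depths. "Share of total reads" is the
default reading of the abundance threshold; a per-sample-mean mode
(`abundance = "mean_ra"`) is provided because the phrase is ambiguous
in common usage. Core sets are antitone in both thresholds (tested),
and `core_overlap()` reports the Venn partition of two crops' sets.

## Indicator species analysis

IndVal combines specificity `A` — an ASV's mean relative abundance in
a group divided by the sum of its group means — with fidelity `B`, the
fraction of the group's samples in which it is detected:
`stat = √(A·B)`, reported for the best group only. The mean-based `A`
corrects for unequal group sizes (the groups here are unbalanced:
64 libraries split across an incomplete factorial); a raw group-total
variant (`specificity = "total"`) is provided, and the two coincide on
balanced designs. Significance comes from a permutation null: one
shuffled label vector scores all ASVs per iteration (labels are
exchangeable under the null, and sharing shuffles makes 10,000
iterations cheap), with `p = (1 + #{stat* ≥ stat}) / (1 + n_perm)`.
The conventional screen keeps `stat ≥ 0.35` and `p < 0.05`.

## Recruitment

Each endosphere library is linked by `pair_id` to the single
rhizosphere library from the same sampling spot (one rhizosphere
library can serve many endosphere libraries). Per endosphere library,
recruitment is the number and fraction of its detected ASVs also
detected in its paired rhizosphere library; the fraction's denominator
is the endosphere library's richness by default (recruitment *of* the
endophyte community), with a rhizosphere-denominator mode behind a
flag. Crop-level summaries are means over libraries and the union
partition of recruited ASVs. The preferential-recruitment screen
flags ASVs whose rhizosphere abundance shows no crop difference
(BH-adjusted Wilcoxon p ≥ α) while their endosphere abundance does
(p < α), the signature of root-level selection. The candidate
endophyte set is an input: differential-abundance calling on raw
counts is the province of dedicated count-model tools, and the
built-in `rank_da_screen()` (CPT fold-change + Wilcoxon + BH) is
plumbing for self-contained runs, not a substitute model.

## Environment-wide association

Study ASVs are matched to an indicator database by exact,
case-insensitive string equality after trimming the first five
nucleotides (databases built from differently primed studies share the
inner V4 region, not the primer-proximal bases). No mismatch tolerance
is applied: both sides are denoised fixed-region ASVs, where a
single-base difference is a different variant by definition. Matched
ASVs' CPT abundances are summed per sample within each category; the
database's indicator values are carried through but not used as
weights, since the quantity of interest is community share. Crops are
contrasted per category with rank-sum tests, BH-corrected across the
categories of one invocation.

## The synthetic generator

`synthetic_design()` encodes the study conditions: 2 crops × 3
countries (plot counts 4, 4 and 1) × 2 years × 2 depths with the
deepest layer missing in one country's first year — 64 rhizosphere
libraries — and, per surface library, 3 endosphere libraries at
reduced depth. Compositions are log-normal (base s.d. 1.2) perturbed
multiplicatively by per-ASV country, year, depth and crop effects,
plus per-library log-normal noise (s.d. 1.0) and Dirichlet-multinomial
sampling (concentration 1000, depth 20,000).

Numerical choices worth knowing:

- **Calibration to field scale.** The effect sizes (country 0.45,
  year 0.08/0.65 by crop, depth 0.35, crop 0.02, library noise 1.0)
  were chosen so a generated study's PERMANOVA partition lands where
  multi-site field surveys land: country R² near 0.09, year and depth
  a few percent, crop smallest and marginal. The per-crop year effect
  is the stability differential: the perennial crop's year
  perturbation is several-fold smaller.
- **Symmetric year application.** The year perturbation is applied as
  −half in year 1 and +half in year 2. Applying it to one year only
  would make each crop's *mean* composition depend on its turnover
  magnitude, leaking a spurious crop signal into every ASV through
  compositional closure; the symmetric form cancels that first-order
  shift while leaving between-year distances and ∆RA ratios unchanged.
- **Pinned plants.** Planted cores, indicators, preferential recruits
  and the boosted database categories are planted at exact expected
  shares (cores 0.35%, indicators 0.075% base with 4-fold lift,
  database categories 0.05% base with 2-fold lift in one crop,
  preferential recruits 0.1% with a 10-fold endosphere recruitment
  weight), rather than at random log-normal abundances. Recovery tests
  should measure the detection machinery, not the luck of an
  abundance draw; core ASVs additionally receive damped library noise,
  which is the construct being planted — core taxa are the
  consistently present, consistently abundant fraction.
- **Endosphere assembly.** Each endosphere library reweights its
  paired rhizosphere composition (preferential ASVs upweighted in
  their crop), mixes in a per-crop fraction of seed-borne ASVs absent
  from the rhizosphere (0.2 perennial vs 0.4 annual — the recruitment
  differential), and samples multinomially.

What the generator does **not** emulate: taxonomy and phylogeny,
sequencing error and chimeras (inputs are assumed denoised), depth
variation between libraries, temporal autocorrelation beyond two
years, and genuine ecological co-occurrence structure (ASVs are
conditionally independent given the factors). Passing recovery tests
therefore demonstrates that the statistics detect the structures they
target at realistic effect and noise scales — not that real data meet
the generator's independence assumptions.

Problem sizes used by the test-suite recovery checks: the full design
(64 libraries, 400 ASVs, depth 20,000) for single-design recovery and
100 seeded replicates for the ordering properties (between-year µ_D,
∆RA dispersion, recruitment fraction), with reduced designs (150 ASVs,
depth 8,000) in the per-module smoke versions.

## Rank tests and ties

Group comparisons use two-sided Wilcoxon tests with midranks. For
small samples the p-value comes from exact enumeration over all label
assignments (unpaired) or sign assignments (paired) whenever that
enumeration is tractable (at most 20,000 arrangements); this remains
exact under ties, where the classical exact distribution is undefined
and the normal approximation can be badly off (fully separated 3 vs 3
groups with internal ties: enumeration gives p = 0.1, the
approximation 0.047). Larger samples use the normal approximation.
BH correction is applied within one explicit family per call — all
pairwise cell comparisons, all categories of an EWAS run, each
compartment of the preferential screen — never silently across calls.

## Known limitations

- µ_D cell comparisons inherit the non-independence of shared-sample
  pairs (above); treat the BH-adjusted p-values as a screen.
- The ∆RA mean is reported for completeness but is nearly
  uninformative about stability under compositional closure; use the
  dispersion summaries.
- Sequential PERMANOVA r² values depend on factor order; the default
  order is a convention, and order sensitivity should be checked when
  factors are strongly confounded.
- Exact-sequence database matching requires both datasets to cover the
  identical trimmed region; off-by-one trimming produces zero matches
  rather than degraded matches, which is detectable but unforgiving.
- The built-in differential-abundance screen is rank-based plumbing;
  for endophyte-set construction from raw counts, a negative-binomial
  count model is the appropriate tool and its output can be supplied
  as the `endophyte_set` input.
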