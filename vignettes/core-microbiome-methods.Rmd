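---
title: "Electing core microbiome members and comparing cohorts with ubicore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electing core microbiome members and comparing cohorts with ubicore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ubicore)
library(dplyr)
set.seed(1)
```

## The problem

A 16S taxonomic survey of a cohort yields, per donor, read counts over taxa
(genera or OTUs). Which taxa belong to the cohort's *core* microbiome?
All-or-nothing presence/absence answers are misleading: detection of a
low-abundance taxon depends on sequencing depth, and abundances are
compositional (per-donor proportions summing to 1), so discarding
low-abundance taxa distorts the remaining proportions. ubicore implements a
two-parameter probabilistic treatment of this question, plus a statistic for
asking whether two cohorts differ.

## Abundance, ubiquity, and the two-parameter model

Per donor $i$, the abundance of taxon $t$ is the proportion of the donor's
reads assigned to $t$ ([`normalize_profile()`]). The *ubiquity* of $t$ at
abundance cutoff $a$ in a cohort of $n$ donors is

$$\mathrm{Ubiq}(t, a) = \frac{1}{n}\sum_{i=1}^{n}
  I\big(\mathrm{Abund}(t, i) > a\big),$$

the survival function of the per-donor abundance distribution: monotone
non-increasing in $a$, with strict exceedance. A taxon is elected to the
**core** at cutoff pair $(a^*, u^*)$ when $\mathrm{Ubiq}(t, a^*) > u^*$ —
strict on both parameters, so ties exclude. `elect_core()` implements this;
`ubiquity_curve()` returns the exact step-function representation that
`plot_ubab()` draws.

There is no single "right" cutoff pair; the election is usually examined
along the conventional ladder 10%|75%, 1%|80%, 0.1%|85%, 0.01%|90%
(`conventional_cutoffs()`). The package deliberately provides no automatic
cutoff optimiser.

```{r toy}
counts <- tibble::tibble(
  donor = rep(paste0("d", 1:4), each = 3),
  taxon = rep(c("A", "B", "C"), 4),
  count = c(60, 30, 10, 50, 50, 0, 90, 5, 5, 20, 80, 0)
)
prof <- normalize_profile(counts)
elect_core(prof, abundance_cutoff = 0.1, ubiquity_cutoff = 0.75)
```

Taxon B's ubiquity at 10% abundance is exactly 0.75 here and is excluded by
strictness — a deliberate convention, documented because it matters for taxa
sitting exactly on a cutoff.

### Detection qualification

Whether a low-abundance taxon is "present" at all depends on depth: at depth
$n$ and true proportion $p$, the probability of seeing zero reads is
$(1-p)^n$ (`prob_no_detection()`). `qualify_presence()` calls a taxon present
only when that miss probability is at most 0.05 (redetection in at least 95%
of resamples). The binomial gate is exposed as an optional, off-by-default
filter: ubiquity curves are normally drawn from the $10^{-4}$ floor without
it, and the gate is available for presence calls where depth varies across
samples.

### Minor core

Inverting the abundance restriction exposes the **minor core**: taxa present
(abundance at or above a detection floor, default $10^{-4}$) in strictly more
than half the cohort, yet never exceeding a 1% abundance ceiling in any
donor. `elect_minor_core()` uses `>= floor` for presence (the curve
*originates* at the floor) but strict `>` for the ceiling, with a
`ceiling_tolerance` (fraction of donors allowed above the ceiling) defaulting
to 0 — the strictest reading of "terminates below the ceiling", made explicit
because the original criterion is graphical rather than numeric.

### Bootstrap confidence intervals on core counts

Because the election is a hard threshold on noisy data, core *counts* get
confidence intervals by a two-level bootstrap (`bootstrap_core_counts()`,
default B = 160, 95% CI): donors are resampled with replacement, and each
drawn donor's reads are redrawn as a multinomial of its depth over its
observed proportions. The observed count is always computed on the
unperturbed table. Summaries are nearest-rank percentiles — with B = 160 the
bootstrap distribution is too coarse for interpolation to add information,
so the reported median/LB/UB are always realized counts.

## Variation versus abundance

Core taxa should be *stable*: low variation of abundance across donors.
`varab_table()` summarises each taxon by the mean and sample standard
deviation (n−1 denominator) of its log10 abundances over *responding* donors
— zeros are treated as non-response and excluded rather than imputed,
because $\log_{10} 0$ is undefined and pseudo-counts distort the scale; the
response floor defaults to $10^{-4}$. Log base 10 is used throughout. A taxon
responding in a single donor keeps its record with `sd = NA` so plots can
still show the glyph. The theoretical sampling variance of a proportion,
$p(1-p)/(n-1)$ (`proportion_variance()`), explains part of the trend, but no
correction by it is applied — read depth varies and amplification bias is
unmeasurable, so `plot_varab()` visualises the raw scatter instead, sized by
ubiquity, with core (blue) and minor-core (green) taxa highlighted.

## Body regions

Habitat-level ubiquities combine into body-region cores two ways
(`region_ubiquity()`): the arithmetic **mean** answers "how likely is a
habitat from this region to carry the taxon?", while the product (**and**)
answers "how likely is the taxon to be present in *every* habitat of the
region?". A taxon absent from any habitat has ubiquity 0 there and is
annihilated by the product — absence anywhere excludes it from the "and"
core. Since the product over more habitats can only shrink, region core
sizes are not comparable across regions with different habitat counts.

## Comparing two cohorts: the AWKS test

For one taxon, the Kolmogorov–Smirnov distance between cohorts X and Y is
the maximum absolute difference of their ubiquities at matched abundance
cutoffs. Both curves are step functions, so the supremum is attained on
$\{0\} \cup$ all observed abundances and `ks_taxon()` evaluates it exactly
there (a dense-grid brute force is kept as an independent oracle in the test
suite). The **abundance-weighted KS** statistic aggregates over the union
taxa set $T$:

$$\mathrm{AWKS}(X, Y) = \sum_{t \in T} w_t \, \mathrm{KS}_t,
  \qquad w_t = \tfrac{1}{2}\big(\overline{\mathrm{Abund}}_X(t) +
  \overline{\mathrm{Abund}}_Y(t)\big),$$

with cohort-average abundances including zeros. By compositional closure the
weights sum to 1, so $\mathrm{AWKS} \in [0, 1]$, is symmetric, and is 0 iff
every taxon's curves coincide on the union breakpoints.

`awks_test()` performs inference with a bootstrap null (default B = 1000):
donors from both cohorts are pooled (exchangeable under the no-difference
null), pseudo-cohorts of the original sizes are drawn with replacement, each
drawn donor's reads are redrawn multinomially, and AWKS is recomputed. The
empirical null is used directly — bootstrap AWKS nulls are visibly
non-Gaussian, so no normal approximation is fitted. The one-tailed p-value
is the fraction of null draws at or above the observed statistic, displayed
as `< 1/B` when no draw reaches it; an add-one `(count+1)/(B+1)` convention
is available via `p_method`. Because the pooled reading of "resample the
donors and their reads" is not the only one, `null = "within_first"`
bootstraps both pseudo-cohorts from cohort X alone; pooled is the default
and neither is asserted as uniquely correct. The KS maximisation includes
$a = 0$ by default (taxa absent from one cohort then contribute their full
presence difference).

Across many habitat comparisons, `bh_adjust()` applies Benjamini–Hochberg
step-up control of the false discovery rate: p-values ranked ascending,
per-rank thresholds $i\,\alpha/m$, rejection of all ranks up to the largest
rank whose p-value is at or below its threshold. Decisions use unrounded
thresholds; a 3-decimal `threshold_reported` column mirrors the conventional
display. Censored inputs like `"<0.001"` are resolved to the interval
midpoint for ranking, which cannot change decisions when the bound is below
the smallest threshold.

```{r bh}
visits <- visit_awks_genera() # shipped 18-habitat visit-1 vs visit-2 table
bh_adjust(visits$p_value, alpha = 0.05) |>
  mutate(habitat = visits$body_habitat[index]) |>
  select(habitat, p_value, rank, threshold_reported, reject)
```

## The synthetic cohort generator

Real cohort data at this scale are not shipped, so `cohort_spec()` /
`generate_cohort()` produce cohorts with the structure the analyses assume,
and every claim in the test suite is made against them. Per donor: Bernoulli
presence per taxon, lognormal perturbation of base log10 abundances
(`sigma`, default 0.1), renormalization to closure, then one multinomial
read draw at the donor's depth — simple random sampling, matching the
assumption behind $p(1-p)/(n-1)$; no amplification-bias model is attempted
because none is identifiable from a single profile.

Defaults, chosen once as a realistic mid-size 16S study and used as the
package's reference conditions: 100 donors at depth 5000; five major-core
taxa with base abundances 0.25/0.15/0.10/0.06/0.04 present in every donor;
ten minor-core taxa log-spaced from $2\times10^{-3}$ down to
$2\times10^{-4}$ with presence probability 0.8; fifty sporadic taxa with
power-law bases (rank $r \propto r^{-\gamma}$, $\gamma = 1.5$, the shape of
observed rank-abundance tails) and presence probability 0.3.
`generate_pair()` plants fold-change effects on named taxa for power
studies; `planted_taxa()` exposes the ground truth.

What the generator does *not* emulate: sequencing error and chimeras,
phylogenetic correlation among taxa, donor covariates/biome subtypes, and
amplification bias. Tests passing on these cohorts therefore demonstrate
correctness of the statistical machinery under its own sampling assumptions,
not robustness to those artefacts.

Note the resolution constraint: observing a minor-core taxon at the
$10^{-4}$ floor needs on the order of $10/10^{-4} = 10^5$ reads per donor;
`generate_cohort()` warns when minor taxa are planted below that depth.

## Numerical and design choices

* **Strict inequalities** everywhere in the election (abundance indicator
  and ubiquity cutoff); presence at the minor-core detection floor is the
  one deliberate `>=`.
* **Nearest-rank percentiles** for bootstrap summaries (B = 160 is too small
  to interpolate); ties in the KS argmax resolve to the smallest abundance.
* **Weights**: taxa with zero mean abundance in both cohorts get weight 0
  and contribute nothing to AWKS.
* **Zero-depth donors** are dropped at ingest with a warning (non-response),
  not an error; fractional counts are rejected because the multinomial
  bootstrap and binomial detection model require integer reads.
* **Problem sizes** used by the shipped checks (chosen as desk-scale study
  conditions): type-I behaviour of `awks_test()` on 40+40 donors at depth
  2000 with B = 200 over 50 trials; major-core recovery on 40 cohorts of
  100 donors at depth 5000; the KS brute-force cross-check on 200 random
  small cohort pairs against a 100,001-point grid.

## Limitations

* AWKS compares cohorts, not paired donors: a paired visit-1/visit-2 design
  where individuals shift states while cohort composition stays constant is
  invisible to it by construction.
* The bootstrap null quantifies within-cohort variance under exchangeability;
  stratified or covariate-adjusted resampling is not implemented.
* The Ub-Ab machinery treats taxon labels as opaque strings; collapsing OTUs
  to genera is delegated to a caller-supplied extractor because lineage
  formats vary.
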