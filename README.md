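# ubicore

Core microbiome election and cohort comparison for 16S taxonomic count
tables, built for microbial ecologists asking two questions of a cohort of
donors: *which taxa form the cohort's core microbiome?* and *do two cohorts
(body habitats, visits, treatment arms) differ in taxonomic structure?*

## The model

Per donor, read counts are normalized to compositional abundances. The
**ubiquity** of taxon *t* at abundance cutoff *a* in a cohort of *n* donors
is the survival function

```
Ubiq(t, a) = (1/n) Σ_i I( Abund(t, i) > a )
```

and the **two-parameter model** elects *t* to the core at a cutoff pair
(a\*, u\*) when `Ubiq(t, a*) > u*`, strict on both parameters. Inverting the
abundance restriction yields the **minor core**: taxa present above a
detection floor (default 1e-4) in a majority of donors but never exceeding a
1% ceiling in any donor. Core counts receive bootstrap confidence intervals
by resampling both the donors and each donor's reads (multinomial at the
donor's depth).

Two cohorts X and Y are compared with the **abundance-weighted
Kolmogorov–Smirnov (AWKS)** statistic

```
AWKS(X, Y) = Σ_{t ∈ T} w_t · KS_t ,   w_t = (meanAbund_X(t) + meanAbund_Y(t)) / 2
```

where `KS_t` is the exact maximum absolute difference between the two
ubiquity curves of *t* over matched abundance cutoffs and *T* is the union
taxa set; the weights sum to 1 by compositional closure. Significance comes
from a pooled donor/read bootstrap null (the empirical distribution is used
directly), and multi-habitat families of tests are controlled with
Benjamini–Hochberg step-up FDR. A seeded synthetic cohort generator with
planted major-core / minor-core / sporadic (power-law) taxa makes all of
this testable offline, and ggplot2 functions render the Ub-Ab, Var-Ab and
U-U representations.

## Worked example

```r
library(ubicore)

# a synthetic cohort: 60 donors, depth 5000, 5 planted major-core taxa
spec <- cohort_spec(n_donors = 60, depth = 5000, n_minor = 0)
counts <- generate_cohort(spec, seed = 20)

# core counts along the conventional cutoff ladder, with bootstrap CIs
tidy(bootstrap_core_counts(counts, seed = 21))
#> # A tibble: 4 × 6
#>   abundance_cutoff ubiquity_cutoff observed boot_median    lb    ub
#>              <dbl>           <dbl>    <dbl>       <dbl> <dbl> <dbl>
#> 1           0.1               0.75        3           3     2     3
#> 2           0.01              0.8         5           5     5     5
#> 3           0.001             0.85        5           5     5     5
#> 4           0.0001            0.9         5           5     5     5
```

At 10%|75% only the three most abundant planted taxa clear the abundance
bar (observed 3, CI [2, 3]); relaxing abundance to 1% while tightening
ubiquity to 80% recovers all five planted major-core taxa, stably down the
rest of the ladder.

```r
# compare two cohorts: cohort Y carries an 8-fold boost of one core taxon
pair <- generate_pair(spec, effect = c(major_core_002 = 8), seed = 22)
awks_test(pair$x, pair$y, B = 500, seed = 23)
#> Abundance-weighted Kolmogorov-Smirnov test
#>   AWKS = 0.8981, one-tailed p = < 0.002 (B = 500 pooled bootstrap replicates)
#>   cohort sizes: n_x = 60, n_y = 60 donors
```

The boosted taxon dominates the statistic (its KS is 1 with weight 0.45 in
`tidy()` of the fit), and no null replicate reaches the observed AWKS, so
the p-value is censored at 1/B. On the shipped 18-habitat visit-1 vs
visit-2 table, `bh_adjust(visit_awks_genera()$p_value)` rejects the
no-change null for exactly 10 habitats at FDR 0.05.

A command-line wrapper around the same functions is installed at
`inst/cli/ubicore.R` (subcommands `simulate`, `core`, `minor-core`,
`region-core`, `varab`, `compare`, `bh`, `plot`), and
`vignettes/core-microbiome-methods.Rmd` documents the model, conventions
and generator in detail.

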