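# snakemap

Municipality-level analysis of snakebite surveillance data where reporting is
incomplete. Incidence maps drawn from passively reported cases suffer from
case detection bias: the most remote and deprived municipalities report the
fewest cases precisely where access to care is worst, so a naive map directs
antivenom and staff away from the places that need them most. `snakemap` is
for epidemiologists and health planners who must read such a map critically.
It flags the municipalities where low reported incidence is plausibly an
artefact of underreporting rather than of low snakebite risk, using only
publicly available municipality covariates.

## What it computes

Two detection layers, supported by a regression model and descriptives:

1. **Underreporting index.** Each of *n* municipalities is ranked on six
   deprivation / health-access variables (distance to hospital, % households
   > 5 km from a health centre, % poverty, % illiteracy, % area > 1 km from a
   road, out-of-system births per inhabitant), with rank *n* for the most
   favourable value. The equal-weight rank sum lies in \[6, 6*n*\] and is cut
   into five categories (best / good / medium / bad / worst) with deliberately
   small extreme categories. The worst-scoring municipalities are the first
   detection layer.

2. **Low-reporters.** Within each environmental region (municipalities of
   assumed similar snake prevalence, clustered on altitude, precipitation and
   location under a spatial-contiguity constraint), a municipality is flagged
   when it sits in the top 40% of the rural-population ranking **and** the
   bottom 40% of the reported-incidence ranking: a large at-risk rural
   population with little reported disease.

3. **Incidence model.** Reported counts are modelled as
   `cases_m ~ Poisson(pop_m · exp(x_m' β))` — Poisson regression with
   log-population offset, fitted by IRLS. Exponentiated coefficients are
   incidence ratios (IR) with Wald 95% CIs. Environmental region and index
   category enter as categorical terms (references: the largest region and
   the "good" category); % rural, % under 15 and % male surplus enter as
   untransformed continuous terms. A non-linear index–incidence relationship
   — IRs rising with deprivation and then dipping in the worst category — is
   the model signature of underreporting at the extreme end.

4. **Descriptives.** Cumulative and annual incidence per 100,000, mortality,
   case fatality rate, per-region incidence, and weekly seasonal profiles
   smoothed with a centred five-week sliding mean (circular over the year).

A synthetic-country generator produces municipality tables and weekly case
series with exactly this structure — Poisson true counts, binomially thinned
by a deprivation-dependent reporting probability — together with the ground
truth of which municipalities underreport, so every stage is testable without
any confidential surveillance extract.

## Worked example

```r
library(snakemap)
res <- run_pipeline(pipeline_config(out_dir = "snakemap_out", seed = 7))
res$summary
#> 3249 reported cases, 32 deaths among 5,967,842 inhabitants over 5 years
#> 5-year incidence: 54 per 100,000 (10.9 per year)
#> mortality: 0.5 per 100,000 in 5 years; case fatality rate: 1%
```

The model comparison (`res$comparison`) aligns the three fitted columns —
each term entered separately, adjusted for region + demographics, fully
adjusted. In the single-term column the index categories show the
characteristic shape (IRs relative to "good"):

```
index_category   best     0.84 (0.76-0.92)
index_category   good     1 (reference)
index_category   medium   1.23 (1.13-1.34)
index_category   bad      1.06 (0.94-1.20)
index_category   worst    0.91 (0.77-1.06)
```

reported incidence first rises with deprivation (more rural population, more
bites) and then falls at the extreme end, where reporting loss overtakes the
rise. The report bundle lists the two detection layers and, in synthetic
mode, scores them against the simulated truth:

```r
res$report$worst_index_municipalities   # 10 worst index scores
res$report$low_reporters                # dual-rank flags
res$report$truth_evaluation$worst_index
#> $sensitivity [1] 1        $specificity [1] 0.979
```

Outputs (`regions.csv`, `index.csv`, `low_reporters.csv`,
`model_comparison.csv`, `summary.json`, `seasonal_curves.csv`,
`report.json`, …) are written to `out_dir`; re-running with the same seed
reproduces them byte for byte. A thin command-line wrapper with
`run` / `simulate` / `regions` / `index` / `lowreporters` / `fit` /
`describe` subcommands is installed at `inst/cli/snakemap.R`.

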