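---
title: "Detecting snakebite underreporting from municipality-level surveillance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting snakebite underreporting from municipality-level surveillance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snakemap)
```

## The problem

Passive surveillance counts only the snakebite victims who reach, and are
recorded by, the health system. In a country where the most rural and
deprived municipalities have the worst access to care, a map of reported
incidence confounds two things: where snakes bite people, and where bitten
people are counted. `snakemap` implements a municipality-level workflow that
makes this confounding visible: it models reported incidence, constructs a
deprivation-based underreporting index, and flags municipalities whose
reported incidence is implausibly low given their rural population.

Everything operates on two tables: a municipality table (population,
demographic percentages, altitude, precipitation, centroid coordinates, and
six deprivation / health-access variables) and a long weekly case series
(municipality, year, week, cases, deaths).

## The incidence model

Reported five-year counts are modelled as

$$y_m \sim \text{Poisson}\!\left(P_m \, e^{x_m'\beta}\right),$$

with $P_m$ the municipality population entering as a rate multiplier
(log-population offset with fixed coefficient 1). Exponentiated coefficients
are incidence ratios. The model is estimated by iteratively reweighted least
squares, initialized at the pooled rate
$\hat\beta_0 = \log(\sum y / \sum P)$ with all other coefficients zero, and
declared converged when the largest absolute coefficient change falls below
`tol` ($10^{-8}$ by default, within 100 iterations). Standard errors come
from the inverse expected information at the optimum; confidence intervals
are Wald, $\exp(\hat\beta \pm 1.96\,\widehat{SE})$. Profile-likelihood
intervals and overdispersion corrections are deliberately out of scope — the
analysis this package supports uses plain Poisson — though a sandwich
variance is available via `robust = TRUE` for sensitivity analyses.
Non-convergence yields a flagged fit with diagnostics rather than an error;
a rank-deficient design is an error that names the collinear columns.

Terms follow the ecological design: environmental region and
underreporting-index category are categorical (the region with the most
municipalities and the second-best, largest index category "good" are the
references, so every IR is interpretable against the most populous stratum);
percentage rural, percentage under 15 years and percentage male surplus are
continuous and untransformed, so their IRs read "per percentage point".
`fit_incidence_model()` exposes the three standard columns: every term in
its own single-term model, region + demographics, and fully adjusted.

## The two detection layers

**Rank-sum index.** `rank_variables()` ranks all municipalities on each of
six variables, orienting ranks so the most favourable value receives rank
$n$; `compute_index()` sums them with equal weight (no defensible basis for
differential weights exists), giving an integer index in $[6, 6n]$. Ties are
resolved ordinally, by ascending municipality id — average ranks would break
the integer bounds, and a documented deterministic rule matters more here
than any particular choice. `categorize_index()` sorts by the index and cuts
five categories sized `round(fraction * n)`, with the rounding remainder
absorbed by the reference category "good"; the default fractions reproduce
sizes 32/45/45/20/10 at $n = 152$. Extreme categories are kept small on
purpose: underreporting is hypothesized to be a phenomenon of the tail, and
a wide "worst" category would dilute it.

**Dual-rank low-reporters.** Within each region,
`detect_low_reporters()` ranks municipalities by reported incidence
(ascending) and rural percentage (descending) and flags those in the first
$\lceil q\,n_r\rceil$ positions of both, $q = 0.4$. Ceiling rounding lets
small regions flag at least one municipality; regions with fewer than three
municipalities are skipped with a warning because a 40% cut is degenerate
there. The rule is monotone (reporting fewer cases can never un-flag a
municipality) and region-closed (changes in one region cannot affect
another's flags).

## Environmental regions

The regions are meant to hold snake prevalence roughly constant so that
within-region incidence contrasts reflect reporting, not ecology. The
package replaces a manual GIS delineation with a reproducible rule:
Ward-style agglomerative clustering on z-scored altitude and precipitation,
where only clusters adjacent in a symmetric 4-nearest-neighbour graph of the
municipality centroids may merge. Contiguity therefore holds by
construction, the greedy criterion minimizes within-region environmental
variance, and determinism is guaranteed by breaking cost ties on the
smallest municipality ids; the result is invariant to input row order. The
default of seven regions matches the national delineation the workflow is
modelled on. The algorithm is $O(n^3)$ in the worst case, immaterial at
$n \approx 150$; for thousands of municipalities a nearest-neighbour-chain
implementation would be the natural upgrade.

## The synthetic country

`simulate_country()` generates the study conditions every test runs under:
152 municipalities in 7 regions with the national per-region counts
(11, 19, 12, 14, 56, 22, 18), five years of 52 weeks, and a national true
rate of 56 bites per 100,000 over the period. Populations are log-normal
around 30,000; the six deprivation variables load on a latent shared with
the logit of percentage rural, giving rank correlations with rurality well
above 0.3. Region multipliers default to the observed relative regional
incidence profile (the wet lowland east-coast region at roughly 3.4 times
the national rate); the rural effect defaults to +1% rate per percentage
point; the seasonal forcing is a single-harmonic sinusoid with amplitude 0.5
peaking in week 49, so expected incidence roughly triples between trough and
peak, as the eastern seasonal pattern suggests. The weekly sinusoid averages
exactly 1 over the year and municipal weights are rescaled so the expected
national true count equals `baseline_rate` exactly — which gives the tests a
closed-form oracle for the national total.

Reporting is where the ground truth lives. Each municipality's reporting
probability is 1 up to the knee quantile of the deprivation ranking and then
decays linearly to `reporting_floor` (0.5) at the most deprived
municipality; observed counts are a binomial thinning of true counts at that
probability, and municipalities with reporting probability below 0.7 are
recorded as true underreporters. The knee defaults to 0.9: the reported
phenomenon this mechanism emulates is a drop confined to the worst index
category (10 of 152 municipalities, the top ~7% of deprivation), so the
decay must be localized in the extreme tail; placing the knee lower would
smear reporting loss across a third of the country and move the incidence
dip into the middle categories, which is not the phenomenon of interest.
The floor, knee and flag cutoff are simulation choices, not empirical
estimates — no measurement of the true reporting deficit exists.

Two numerical choices are worth noting. The generator uses two
deterministic substreams of one seed (seed for the municipality table,
seed + 1 for the case series) so that either stage can be re-run
reproducibly on its own. And thinning draws observed counts by inverse-CDF
(`qbinom` applied to stored uniforms) rather than `rbinom`: the marginal
distribution is identical, but runs differing only in reporting parameters
then share their uniforms, making the observed national count pointwise
monotone in the reporting floor — an exact, testable comparative statement
instead of a stochastic one.

What the generator does *not* emulate: spatial autocorrelation of risk
beyond region membership, hospital-catchment referral (cases booked to the
hospital's municipality), census projection error, within-municipality
heterogeneity, and any direct effect of deprivation on true (as opposed to
reported) incidence. The last point has a visible consequence: in the
synthetic world the true rate depends on deprivation only through rurality,
so the fully adjusted model — which includes percentage rural — absorbs the
rise and shows only the thinning dip; the characteristic rise-then-dip of
the index IRs is assessed on the single-term index fit, where it operates
through the index–rurality correlation. Real data can show the rise even
after adjustment, because deprivation there proxies agricultural exposure
beyond rurality. Passing tests therefore demonstrate that the machinery
detects the mechanism it models, not that the mechanism is the only one
shaping real surveillance data.

## Descriptives and seasonality

`incidence_summary()` keeps exact values and rounds only at print time
(incidence to the nearest integer per 100,000, mortality to one decimal,
case fatality to the nearest percent, matching the precision such results
are usually reported at). The seasonal profile is computed as the mean count
per ISO week across years — week 53, when present, is folded into week 52 —
and then smoothed with a centred five-week sliding mean that wraps
circularly, so week 1 neighbours week 52 and the smoother preserves the
annual mean exactly; smoothing acts on counts (within a fixed region,
smoothing rates would differ only by a population constant). The window must
be odd; an even window has no centre and is rejected.

## Test problem sizes

The test and acceptance suites run the generator at its default size
(152 municipalities, 5 x 52 weeks) with 50 replicates for parameter
recovery and 20 for the pattern and detector checks — sizes chosen so the
Monte-Carlo standard errors of the checked proportions are small relative to
their margins, while the whole suite completes in well under a minute.
Parameter recovery under full reporting covers the true log region
multipliers and the rural effect at +/- 2 SE; the detector check requires the
flagged-given-truth proportion to beat the $q^2$ independence baseline.

## Known limitations

The index is an ordinal aggregate: equal weights are an assumption of
ignorance, and a municipality can score "worst" by moderate deprivation on
all six variables or extreme deprivation on three. The low-reporter rule
conditions on region quality — if the clustering groups ecologically
dissimilar municipalities, flags inherit that error. The Poisson model
ignores overdispersion and spatial correlation; with strong clustering of
unmeasured risk, Wald intervals are anti-conservative. And the whole
workflow is ecological: it identifies municipalities whose *reporting* looks
anomalous, and says nothing about individual risk.
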