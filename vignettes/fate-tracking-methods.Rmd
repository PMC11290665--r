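---
title: "Methods: fate tracking of coral genets through repeated bleaching events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fate tracking of coral genets through repeated bleaching events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coralfate)
```

## The scientific problem

Reef-building corals are clonal: a colony can split into fragments
(fission, via partial mortality) and fragments can regrow into a single
contiguous patch (fusion). A *genet* — a putative genetic individual — is
therefore not one patch of tissue but a network of patches linked through
time. Counting colonies per survey misses this structure entirely: apparent
"mortality" may be fission and apparent "recruitment" may be a surviving
fragment. Fate tracking reconstructs genets from repeated photomosaic
surveys so that survival, growth, and — centrally here — *bleaching
responses to repeated marine heatwaves* can be measured at the level of
genetic individuals.

The analysis this package implements asks: when the same genets experience
two bleaching events a few years apart, do their bleaching scores
systematically decrease (evidence of acclimatization), increase, or stay
put — and does the answer differ by site and taxon?

## Genet assembly

Input data are two plain tables: a patch table (one row per contiguous
tissue patch per survey, with planar area, bleaching extent and severity,
and optional centroid) and a link table connecting patches in consecutive
surveys (a one-to-many link records fission, many-to-one records fusion).
`assembleGenets()` treats patches as vertices and links as undirected
edges; connected components are genets. Components are a deliberate choice
over any lineage-aware structure: the questions asked downstream (did the
genet survive? what was its total area? how bleached was it?) only need
membership, and components are the weakest — hence most robust —
assumption consistent with "same genet".

Genet ids are assigned deterministically (by site, first appearance year,
then smallest patch id), so reruns and row shuffles produce identical
outputs. In strict mode (default) a genet absent at an interior survey but
present before and after is rejected as a data error, since tissue cannot
reappear from nothing; `strict = FALSE` downgrades this to a warning for
exploratory use.

Survivorship over the timeseries is defined as having live tissue at both
the first and the last survey; genets that recruit after the first survey
are excluded from the survivor cohort by `cohortFilter()`.

## Bleaching scoring

Each patch carries two visual scores: *extent*, the percent of its area
showing any paling (0–100), and *severity*, an ordinal 0–3 degree of
pigmentation loss on the bleached tissue only. The two are combined into
five ordered categories (none/very minor, minor, moderate, severe,
extreme) through a bleaching index `I = extent × severity` and a threshold
table (`defaultRubric()`). The index form was chosen because it is the
simplest combination that is monotone in both inputs and anchors both
labelled corners: no paling at all must score 1 and a fully stark-white
patch must score 5. Extent below 5% always scores category 1, reflecting
the "very minor paling" convention. The rubric is data (`category`,
`index_min`, `index_max`), not code: a different calibration can be
supplied as a CSV via `readRubric()` without touching the scoring logic.

Genet-level scores come in two flavours, both exposed because they
genuinely differ on heterogeneous genets:

* **modal** (default): each member patch is scored, and the genet takes
  the category holding the largest summed patch area; ties break toward
  the worse category, which is conservative when testing for
  acclimatization.
* **aggregate**: the rubric is applied to the genet's area-weighted extent
  and its bleached-area-weighted severity (severity is defined only on
  bleached tissue, so weighting by raw area would dilute it).

## Response classification

For each genet surviving both bleaching events, the change statistic is
the second-event category minus the first (an integer in −4…+4). Genets
with |Δ| ≥ 2 have a *decreased* or *increased* bleaching response; genets
that changed at most one step are stable and are split by peak bleaching:
*high susceptibility* if the worse of the two event scores was moderate or
higher (category ≥ 3), otherwise *thermally tolerant*. "Moderate or higher
in at least one event" is interpreted as `max(c1, c2) ≥ 3`: a stable genet
that bleached moderately in either event demonstrated susceptibility, and
this reading makes the four classes an exhaustive partition of the 5 × 5
category grid (see the decision-table test in the package suite).

## The bootstrap acclimatization test

For each population (one taxon at one site), `acclimTest()` resamples the
observed per-genet changes with replacement 100,000 times and computes the
median of each resample; the one-sided p value is the proportion of
resample medians ≥ 0, *inclusive*. Inclusivity matters: with integer-valued
changes the resample median frequently lands exactly on 0, and counting
those resamples against acclimatization is the conservative choice. The
median of an even-length resample is the mean of the two middle order
statistics (R's default convention).

Internally each resample is drawn as one multinomial count vector over the
distinct observed values rather than `n` individual draws — distributionally
identical, but it turns 100,000 resamples into a single `rmultinom()` call
and a cumulative-count median lookup. The package also ships an exact
oracle, `enumerateExactP()`, which enumerates all `n^n` resamples (via
count compositions with multinomial weights) for `n ≤ 8`; the test suite
requires the bootstrap to agree with it to ±0.01.

Populations with fewer than 10 surviving genets are reported but marked
ineligible, with no p value. Each population draws from its own RNG
substream derived from the master seed and a stable hash of (site, taxon),
so results are independent of iteration order and reproducible in
isolation.

## Population statistics

* **Response-distribution comparisons.** Sites (or taxa) are compared by
  Fisher's exact test on the groups × response-classes table, all pairs,
  Bonferroni-corrected over the `choose(k, 2)` family. `fisherExact()`
  switches to seeded Monte Carlo only when the table space (bounded via
  column-margin compositions) exceeds 10^6 tables, and flags it.
  `compactLetters()` renders the pairwise pattern as a letter display
  satisfying the defining invariant — two groups share a letter iff their
  comparison is non-significant — via insert-and-absorb; letter-count
  minimality is not guaranteed and not needed.
* **Size-dependent bleaching and survivorship.** Logistic regressions use
  the natural log of planar area, since colony areas span orders of
  magnitude and proportional size effects are the biologically natural
  scale. The IRLS fitter (`logisticFit()`) guards its deviance with step
  halving, reports the per-iteration trace, and flags quasi-complete
  separation (diverging coefficients with still-improving likelihood)
  instead of reporting meaningless Wald p values. The survivorship model
  includes site × size interactions; `pairwiseSiteContrasts()` excludes
  sites whose interaction is significant (their slopes differ, so a single
  main-effect contrast is not interpretable) and Bonferroni-corrects over
  the pairs actually tested.
* **Growth ANCOVA.** ln final area is regressed on ln initial area plus a
  factor (response class or site). Term tests use sequential (Type I) sums
  of squares with the covariate entered first — the factor is tested after
  adjusting for initial size, which is the ANCOVA question being asked.
  Factor levels with fewer than 10 genets are dropped. Diagnostics are
  Shapiro–Wilk on residuals and Cochran's C for variance homogeneity; the
  C p value uses the classical Bonferroni-bound F approximation with the
  average group degrees of freedom for unbalanced groups, an approximation
  the tests calibrate under the null rather than assume.

## The synthetic community generator

Field annotation tables are not redistributable, so validation rests on a
simulator with per-genet ground truth. Each genet receives an a-priori
bleaching phenotype (tolerant / decreased / increased / susceptible) that
drives its category pair at the two events — inverting the paper-style
observational direction, but the standard construction that makes
classification testable. Per inter-survey interval a genet survives a
size-dependent Bernoulli trial (`logit(p) = a + b·ln(area)`), grows by a
lognormal multiplier, may fission (uniform 0.2–0.8 split, single level)
and re-fuse, and may show sub-threshold paling noise in non-event years.
Patch areas always sum exactly to the truth-table genet area.

Defaults emulate a leeward-Maui-style study: five surveys
(2014–2021) with events in 2015 and 2019, six sites, four taxa totalling
1830 genets, with survival parameters chosen so full-timeseries
survivorship at median colony size is roughly 54%, 51%, 16% and 63% and
the *Pocillopora*-like taxon has a negative size–survival slope. The
defaults were set from those study conditions once and never tuned against
the package's own tests. Out of scope: time-varying mortality, nested
fission trees, recruitment dynamics, environmental covariates, and symbiont
dynamics. `nullScenario()` replaces the phenotype machinery with i.i.d.
uniform category draws, making the change statistic exactly symmetric —
the type-I calibration harness for the bootstrap test.

Typical problem sizes are small: thousands of patches, hundreds of genets
per taxon, 24 site × taxon populations. Everything runs in seconds on one
CPU except the 100,000-resample bootstrap over all populations (a few
seconds) and the simulator at ~10^5 genets (half a minute).

## A worked example

```{r example, eval = FALSE}
cfg <- simConfig(seed = 1)
sim <- simulateCommunity(cfg)
genets <- cohortFilter(assembleGenets(simulationSurvey(sim, cfg)))
responses <- classifyGenets(genets, cfg$event_years)
acclim <- acclimTestAll(responses, seed = 1)
acclim[acclim$eligible & acclim$p < 0.05, ]
```

The full pipeline — including the logistic models, ANCOVA and letter
displays, with all outputs written to disk — is one call:

```{r pipeline, eval = FALSE}
runPipeline(runConfig(seed = 1, outDir = "out"),
            survey = simulationSurvey(sim, cfg))
```
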