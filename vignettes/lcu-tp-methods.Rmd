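---
title: "Littoral carbon use and trophic position: models, diagnostics, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Littoral carbon use and trophic position: models, diagnostics, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcutools)
```

## The mixing model and its scalings

A lake consumer's δ¹³C is modelled as a two-source mixture of the littoral
and pelagic food-web bases. Because δ¹³C changes little (< 1 ‰) between
trophic levels, inverting the mixture against habitat baseline means gives
the proportion of littoral carbon:

$$\mathrm{LCU} = \frac{\delta^{13}C_{consumer} - \delta^{13}C_{P}}
                     {\delta^{13}C_{L/B} - \delta^{13}C_{P}}$$

The model assumes (1) the two baselines are the isotopic extremes of the
system, (2) spatial homogeneity within the scope the baselines were
aggregated over, (3) temporal homogeneity at the timescale of the
consumer's tissue turnover. Each assumption fails routinely in the field,
and consumers then fall outside [0, 1]. The package keeps all three
responses to that failure side by side:

* `lcu` — the raw value, unclipped, so violations stay visible;
* `lcu_adj` — clipped into [0, 1]; simple, but it piles mass on the bounds
  and is biased toward the extremes whenever the truth lies outside them;
* `lcu_r` — rescaled to the observed min/max of the analysis group, which
  reinterprets the metric as position along the observed isotopic gradient
  rather than a strict source proportion.

Values exactly 0 or 1 count as *inside* the bounds throughout (closed
interval); the violation percentage uses strict inequalities.

## Nine trophic positions

δ¹⁵N increases by Δn per trophic step (default 3.4 ‰, the conventional
freshwater value). Three equation families, crossed with baseline/α
choices, give nine variants:

| family | variants | α | λ |
|---|---|---|---|
| one-source | `tp1_lb`, `tp1_p`, `tp1_lbp` | — | `lambda_default` (2) |
| two-source | `tp2`, `tp2_adj`, `tp2_r` | lcu / lcu_adj / lcu_r | `lambda_default` (2) |
| absolute-λ | `tp2abs`, `tp2abs_adj`, `tp2abs_r` | lcu / lcu_adj / lcu_r | per-baseline λ |

Out-of-bound α values propagate into the two-source equations *unclipped*:
only the `_adj` variants see clipped α. This keeps the raw variant an
honest reflection of the data; the identity
`tp2abs − tp2 = α(λ_L − λ) + (1 − α)(λ_P − λ)` is verified numerically in
the test suite.

The pooled one-source baseline (`tp1_lbp`) defaults to the unweighted mean
over all individual baseline specimens, so a habitat sampled more heavily
weighs more; a mean-of-habitat-means option (`pooling = "habitat_means"`)
is available when balanced influence is wanted.

## Baseline construction and matching policy

Endmember sets are per-habitat arithmetic means with sample counts and
assumed baseline trophic positions (λ ≥ 1; strict primary consumers at 2,
omnivorous macroinvertebrates higher — mayfly 2.25, oligochaete 2.5 are
the conventional assignments for those taxa). Matching is governed by a
`grouping_policy()`:

* **stratum matching** (default on): consumers are paired with endmembers
  from their own basin, because basal isotope values shift across basins;
* **season matching by tissue**: liver turns over in weeks and is matched
  to same-season baselines; muscle and fin integrate months and use
  season-pooled baselines. The defaults encode exactly that.

Two screens inform the policy. `test_habitat_distinctness()` runs
two-sided Wilcoxon rank-sum tests per isotope; exact enumeration is used
only when both groups have ≤ 8 tie-free values, otherwise the
tie-corrected normal approximation — the exact and approximate branches
agree within 0.05 for n ≥ 8, which the tests verify by simulation.
`screen_grouping_factors()` applies Kruskal–Wallis plus Dunn's post hoc
z-tests (Bonferroni-adjusted) for factors with > 2 levels and Wilcoxon for
2 levels. Bonferroni is applied uniformly across screens for consistency,
though it is strictly required only where many pairwise tissue contrasts
are made. Shapiro–Wilk and Levene screens are advisory only: the pipeline
is nonparametric throughout, so a "pass" never switches it to parametric
tests.

Dunn's test is implemented in the package (pairwise z on pooled mid-ranks
with tie correction) and validated against the hand-computable oracle
H = 12/42·16 ≈ 4.571, z = 4/√3.5 ≈ 2.138 for the groups {1,2}, {3,4},
{5,6}.

## The decision engine

`recommend_equations()` is a pure rule chain over three diagnostics:

1. baselines **not distinct in δ¹³C** → resource use not applicable,
   one-source TP with pooled baseline;
2. otherwise, **> 5 %** (configurable) of raw LCU outside [0, 1] → use
   `lcu_r` as the metric and as α; within the threshold → raw `lcu`;
3. **equal baseline λ** → `tp2`; unequal → `tp2_abs`.

When δ¹³C is distinct but δ¹⁵N is not, the two-source path is retained and
a caution is appended to the rationale — δ¹⁵N similarity degrades the
benefit of two baselines but does not invalidate the carbon mixing model.
Every fired rule is recorded with its input values, so divergent
recommendations are auditable.

`compare_equation_variants()` deliberately treats the per-individual
values of each variant as independent groups in the Kruskal–Wallis /
Dunn's analysis, although they come from the same fish — this mirrors the
convention of the comparison it replicates. A paired alternative
(Friedman omnibus + paired signed-rank follow-ups) is available behind
`paired = TRUE`, off by default. A wholly degenerate input (identical
values everywhere) is mapped to statistic 0, p = 1, since the tie
correction otherwise divides by zero.

## The synthetic generator

`generate_system()` builds datasets by running the model forward:
baselines are drawn from per-habitat normal distributions; each consumer
receives a true α (uniform or grid over a species-specific range) and a
true TP, then δ¹³C comes from the mixture of the scope's expected
endmember means and δ¹⁵N from the α-weighted baseline mixture plus
(TP − λ_weighted)·Δn. Structure is injected exactly where real lakes
inject it:

* **basin offsets** shift baselines *and* consumers of a stratum on both
  isotopes, so basin-matched analysis recovers α exactly in the noise-free
  limit;
* **season offsets** shift baselines and liver only — muscle and fin
  integrate over seasons and track the annual mean;
* **tissue offsets** default to liver −1.0 ‰ δ¹³C / −0.5 ‰ δ¹⁵N versus
  muscle, fin ≈ muscle (generator conventions chosen to make the screens'
  expected outcomes unambiguous, not measured values);
* noise is independent Gaussian per isotope, default SD 0.2 ‰, the order
  of typical instrument precision. The same Δn generates and estimates
  δ¹⁵N by default, so noise-free recovery is exact; mismatched-Δn
  scenarios can be built by overriding `delta_n` on either side.

Three presets mirror common study designs: `simple` (one basin, one
season, muscle only; mayfly/unionid baselines, λ 2.25/2.0; species α
ranges jointly spanning 0–1), `spatial` (three basins, ±2 ‰ offsets ≫
0.5 ‰ baseline SD; oligochaete/dreissenid baselines, λ 2.5/2.0; two
species with α ranges extending above 1 so raw LCU spills out of bounds),
and `temporal_tissue` (two seasons × three tissues, 1.0/0.8 ‰ August
shift expressed in liver but not muscle). Sample sizes (15–30 baselines
per habitat and scope, 15–30 fish per species and scope) are typical field
efforts and keep the full suite fast.

What passing recovery tests shows — and what it does not: the generator
draws from the same two-endmember family the estimators assume, so
recovery checks the *arithmetic chain*, not ecological realism. Real data
add unsampled carbon sources, δ¹³C trophic discrimination, within-habitat
baseline heterogeneity and tissue-specific Δn, none of which the generator
emulates; conclusions about estimator bias under those violations require
scenario-specific extensions (the α-ranges-above-1 presets are the one
such violation built in).

## Numerical choices and degenerate inputs

* Equal endmember δ¹³C means raise an explicit error recommending the
  one-source path, never infinities.
* Range rescaling with all-equal inputs errors (undefined); a single
  consumer yields `lcu_r = NA` rather than a fabricated 0 or 1.
* `LCU_R`'s min/max is taken over the consumers of the analysis group
  (baselines excluded) — the observed range should reflect the organisms
  whose feeding is being scaled; `rescale_scope = "per_stratum"` confines
  it within basins, the default `"per_system"` spans the system.
* Equality tests use absolute tolerance 1e−9 unless the property is exact
  by construction (round-trip and linearity hold to 1e−12).
* Rows with unparseable isotope values are dropped and counted, never
  imputed; implausible values (δ¹³C outside [−50, 0] ‰, δ¹⁵N outside
  [−10, 30] ‰) warn but never abort.
* All output tables are written at 4 decimal places, comfortably beyond
  the 0.1–0.2 ‰ measurement precision.

## Known limitations

* Only two carbon endmembers; no Bayesian multi-source mixing.
* Fixed Δn; scaled diet-tissue discrimination models are out of scope.
* Seasons and strata are unordered labels — no interpolation between them.
* The variant comparison's independence convention (above) inflates
  neither the omnibus nor the pairwise error rates conservatively; use the
  paired mode when inference about the same individuals matters.
* Mobile species that forage across strata violate basin matching; the
  policy object lets the user disable stratum matching for such species,
  but no automatic detection is attempted.
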