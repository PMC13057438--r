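# lcutools

Quantify **littoral carbon use (LCU)** and **trophic position (TP)** of lake
consumers from carbon (δ¹³C) and nitrogen (δ¹⁵N) stable isotope data.

## The problem

In lakes, carbon at the base of the littoral (nearshore/benthic) food web is
typically enriched in ¹³C relative to the pelagic (open-water) base, while
δ¹⁵N increases by a predictable step with each trophic level. Matching a
consumer's isotope values to habitat-specific baseline organisms (mayfly
larvae, mussels, oligochaetes, ...) therefore yields two standard food-web
metrics: the proportion of its carbon drawn from littoral sources, and its
continuous trophic position. In practice the baselines rarely bracket the
consumers perfectly, systems vary across basins and seasons, and fish
tissues integrate diet over different timescales — so the several published
equations for LCU and TP can disagree substantially on the same data.

`lcutools` is for isotope ecologists who want all the standard variants
computed consistently, the baseline diagnostics that justify choosing among
them, and a simulation harness that checks the whole chain against known
ground truth.

## The model

Littoral carbon use is the two-endmember mixing model

    LCU = (δ13C_consumer − δ13C_P) / (δ13C_LB − δ13C_P)

with three scalings: raw `LCU` (unbounded), `LCU_adj` (clipped into [0, 1]),
and `LCU_R` (rescaled to the observed system range,
`(LCU − min) / (max − min)`). Trophic position comes in nine variants:

* one-source `TP1 = λ + (δ15N_consumer − δ15N_base) / Δn` using the
  littoral, pelagic, or pooled baseline;
* two-source `TP2 = λ + (δ15N_consumer − (α·δ15N_LB + (1−α)·δ15N_P)) / Δn`
  with α set to each of the three LCU scalings;
* absolute-λ two-source
  `TP2abs = (α·λ_LB + (1−α)·λ_P) + (δ15N_consumer − (α·δ15N_LB + (1−α)·δ15N_P)) / Δn`
  for baselines occupying different assumed trophic positions, again with
  all three α choices.

Δn is the diet–tissue discrimination factor (default 3.4 ‰ per trophic
step); λ is the assumed trophic position of a baseline taxon (default 2).

Around the equations the package provides baseline habitat-distinctness
tests (Wilcoxon rank-sum), grouping screens for basin/season/tissue
structure (Kruskal–Wallis + Dunn's post hoc with Bonferroni correction), a
decision engine that recommends an LCU scaling and TP equation from those
diagnostics, a synthetic lake generator with known true α and TP, and a
pipeline/CLI tying it together.

## Worked example

```r
library(lcutools)

em <- endmember_set(
  d13c_littoral = -20, d13c_pelagic = -28,
  d15n_littoral = 6, d15n_pelagic = 4,
  lambda_littoral = 2.25, lambda_pelagic = 2   # mayfly vs mussel
)
fish <- tibble::tibble(
  specimen_id = c("lt_01", "lt_02", "smb_01", "smb_02"),
  d13c = c(-26.1, -25.4, -19.2, -21.0),
  d15n = c(12.1, 11.8, 10.4, 10.9)
)
compute_metric_suite(fish, em)
#>   specimen_id   lcu lcu_adj lcu_r tp1_lb tp1_p tp1_lbp   tp2 ... tp2abs
#> 1       lt_01 0.237   0.237 0.000  3.794 4.382   4.088 4.243 ...  4.302
#> 2       lt_02 0.325   0.325 0.101  3.706 4.294   4.000 4.103 ...  4.184
#> 3      smb_01 1.100   1.000 1.000  3.294 3.882   3.588 3.235 ...  3.510
#> 4      smb_02 0.875   0.875 0.739  3.441 4.029   3.735 3.515 ...  3.733
```

The two lake trout read as mostly pelagic feeders (LCU ≈ 0.2–0.3) around
trophic position 4; the first smallmouth bass has raw LCU = 1.10 — its δ¹³C
exceeds the littoral endmember — which clipping forces to 1 and range
rescaling maps to the top of the observed gradient:

```r
boundary_violation_stats(compute_metric_suite(fish, em)$lcu)
#> <violation_summary> n = 4 | >1: 1 | <0: 0 | outside: 25.0% | flag: exceeds threshold
```

On a full dataset the pipeline runs the diagnostics and recommends an
equation pair, with the fired rules recorded:

```r
spec <- scenario_presets()$simple          # synthetic one-basin lake
sys  <- generate_system(spec, seed = 7)
res  <- run_pipeline(sys$measurements, run_config(lambdas = spec$lambda))
res$recommendation
#> <ru_recommendation>
#>   resource use: lcu | TP equation: tp2_abs | alpha source: lcu
#>   rationale:
#>    - Baselines distinct in d13C (p = 0.0000 < 0.05): two-source mixing model supported.
#>    - 1.2% of raw LCU outside [0, 1] (<= 5% threshold): raw LCU acceptable.
#>    - Assumed baseline trophic positions differ: absolute-lambda two-source TP (tp2_abs).
```

## Command line

A thin CLI wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/lcutools.R", package = "lcutools"))')
Rscript "$CLI" simulate --preset spatial --seed 7 --out run1
Rscript "$CLI" diagnose --input run1/measurements.csv --out run1 \
    --lambda-littoral 2.5 --lambda-pelagic 2.0
```

Commands: `simulate`, `compute`, `diagnose`, `compare`, `report`.

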