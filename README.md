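# microstatr

EEG microstate analysis for two-condition cue-reactivity designs, with a
ground-truth synthetic cohort generator.

Drug-related cues elicit craving in dependent individuals, and the brain
networks they engage leave a signature in the sub-second dynamics of the
scalp EEG: the topography of the field stays quasi-stable for ~80–120 ms
("microstates", canonically four classes A–D) before switching. Comparing
how long each class lasts (duration), how often it recurs (occurrence) and
how much time it covers (contribution) between a neutral and a smoking-cue
condition — and relating those changes to craving ratings and posterior
alpha power — is the analysis this package implements end to end, for
researchers in EEG/addiction neuroscience who want a tested, reproducible,
scriptable version of that pipeline.

## What it computes

- **Global field power**: $GFP_t = \sqrt{\frac{1}{N}\sum_i(\mu_i-\bar\mu)^2}$
  — the population SD of potentials across the $N$ electrodes; maps at GFP
  peaks are the clustering material.
- **Polarity-invariant modified k-means** over unit-normalised GFP-peak
  maps (assignment by squared spatial correlation, template update by
  principal eigenvector), with the **Krzanowski–Lai criterion** choosing
  the number of classes over k = 2–8.
- **Permutation averaging** of individual template sets into condition-level
  and overall maps (label permutations + polarity signs aligned before
  averaging), then **back-fitting**: each GFP peak takes the class of
  maximal |spatial correlation|, other samples inherit the nearest peak's
  label.
- **Parameters** per class and subject/condition: duration (ms), occurrence
  (1/s), contribution (fraction; `contribution = occurrence × duration`
  exactly), and GFP-weighted global explained variance (GEV).
- **Statistics**: paired t contrasts; 2×4 repeated-measures ANOVA
  (condition × microstate class) with Greenhouse–Geisser epsilon and
  interaction-gated, Benjamini–Hochberg-corrected per-class post-hoc tests;
  Pearson correlations of condition differences with craving and addiction
  covariates; and a percentile-bootstrap simple mediation model
  (class-C duration change → posterior 8–12 Hz alpha-power change →
  craving change).
- **Synthetic cohorts** with known ground truth (semi-Markov microstate
  sequences with gamma dwell times, spatially correlated pink noise,
  posterior alpha injection, full-mediation behavioural linkage) so every
  stage is testable against a recoverable truth.

## Worked example

A scaled-down cohort (10 subjects, 2 × 20 s trials per condition instead of
the 40-subject, 4 × 90 s study default) runs the whole pipeline in a couple
of minutes:

```r
library(microstatr)
library(dplyr)

cfg <- default_config(
  simulate   = list(n_subjects = 10, n_trials = 2, trial_s = 20),
  microstate = list(select_subjects = 4, n_restarts = 10),
  stats      = list(n_boot = 2000)
)
res <- run_pipeline(cfg, out_dir = "microstate-demo")

res$chosen_k
#> [1] 4

res$params |>
  distinct(subject, condition, gev) |>
  group_by(condition) |>
  summarise(mean_gev = mean(gev))
#> # A tibble: 2 × 2
#>   condition mean_gev
#>   <chr>        <dbl>
#> 1 neutral      0.949
#> 2 smoking      0.944

res$report
```

The Krzanowski–Lai criterion selects four microstate classes from the
individual GFP-peak maps, and the four fitted templates explain ~94% of the
GFP-weighted topographic variance in both conditions. The printed report
then walks through the analysis blocks (abridged):

```
<ms_report> n = 10 subjects
-- condition contrasts (neutral vs smoking) --
     measure estimate statistic df   p.value
     craving  -2.9360   -11.689  9 9.624e-07
   vividness  -0.5777    -1.087  9 3.054e-01
 alpha_power  -0.4749    -3.743  9 4.603e-03
-- duration_ms: interaction p = 8.454e-05 --
 class estimate statistic df   p.value     p.fdr significant
     A    2.224    0.7218  9 4.888e-01 4.888e-01       FALSE
     B    9.923    3.8933  9 3.657e-03 4.876e-03        TRUE
     C   16.294    5.5186  9 3.711e-04 7.423e-04        TRUE
     D   23.757   10.8394  9 1.822e-06 7.289e-06        TRUE
```

Craving is ~2.9 rating points higher after smoking cues (paired t, df = 9),
vividness does not differ (the cue manipulation, not imagery ability, drives
the effect), and the condition × class interaction for duration is followed
by FDR-corrected per-class contrasts: classes B, C and D dwell significantly
longer under smoking cues while A is unchanged — the estimates column is the
smoking − neutral difference in ms. Occurrence, contribution, the craving
correlations, covariate correlations and the mediation verdict follow in the
same report object (`res$report$mediation`, `tidy()`/`glance()` methods
included), and everything is also written to `microstate-demo/` as CSV/JSON
artifacts (`params.csv`, `report.json`, templates, segmentations, log).

With these small simulated cohorts the correlation/mediation block is
underpowered at n = 10; the acceptance script below runs n = 20 cohorts
where the full-mediation structure is recovered.

`autoplot()` methods show template topographies, segmentations over the GFP
trace, and the mediation path diagram; `plot_parameters()` compares the
parameter sets between conditions.

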