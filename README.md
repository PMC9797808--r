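# sysseg

Resting-state brain networks are organized into segregated modules:
within-network functional connectivity is high, between-network
connectivity low. **System segregation** quantifies this per network as

```
SyS = (W - B) / W
```

where `W` is the mean Fisher-z connectivity over within-network ROI pairs
and `B` the mean over pairs linking the network to the rest of the cortex.
`sysseg` implements the full analysis chain used to relate repetitive
negative thinking (RNT — the trait-like tendency toward worry and
rumination) to segregation of executive-control, salience and default-mode
networks in healthy adult cohorts:

* **Connectivity**: ROI-to-ROI Pearson correlation → Fisher-z
  (`atanh`), negatives set to zero, diagonal excluded; per-network `W`,
  `B`, `SyS` and pairwise network means.
* **Psychometrics**: questionnaire scoring (reverse-scored scales,
  subscales), within-sample z-scores, the RNT composite
  `z(PTQ) + z(PSWQ) + z(RRS)`, Cronbach's alpha.
* **Inference**: forward stepwise OLS with an alpha-to-enter of 0.05 and
  99% confidence intervals on unstandardized coefficients, a per-step
  adjusted-R² trace, fixed-set post-hoc models, the reversed
  (DASS-as-outcome) model, and a pooled two-sample t test.
* **Synthetic cohorts**: a documented generative model — block-correlated
  multivariate normal ROI signals with subject heterogeneity, plus
  behavioural scores generated from true segregation — so every stage is
  verifiable by parameter recovery (no subject data ship with the
  package).

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` methods for fitted objects, and `autoplot()` for connectivity
matrices, network summaries and fitted models.

## Worked example

Simulate a 120-subject cohort (five studied networks plus one pooled
network, 150 timepoints per subject) with the default planted behavioural
model, then run the main stepwise regression of the RNT composite:

```r
library(sysseg)

cfg <- simulation_config(seed = 42, n_subjects = 120,
                         parc = compact_parcellation(), t_points = 150)
sim <- simulate_cohort(cfg)

fit <- forward_stepwise(
  sim$cohort, "rnt",
  c("age", "sex", "dass", "emotional_stability", "cognitive_complaints",
    "sys_asn", "sys_ddmn", "sys_vdmn", "sys_lecn", "sys_recn"))
fit
#> <stepwise_fit> outcome: rnt
#>   retained (6/10): dass, cognitive_complaints, emotional_stability, sys_lecn, sys_asn, age
#> # A tibble: 6 × 6
#>    step action variable             adj_r_squared statistic  p_value
#>   <int> <chr>  <chr>                        <dbl>     <dbl>    <dbl>
#> 1     1 enter  dass                         0.472     10.4  2.67e-18
#> 2     2 enter  cognitive_complaints         0.587      5.82 5.22e- 8
#> 3     3 enter  emotional_stability          0.634     -4.01 1.09e- 4
#> 4     4 enter  sys_lecn                     0.661      3.17 1.98e- 3
#> 5     5 enter  sys_asn                      0.722     -5.12 1.24e- 6
#> 6     6 enter  age                          0.738     -2.82 5.75e- 3
```

The trace reads like the field's stepwise tables: depression/anxiety/stress
enters first and explains most of the variance, and the planted pattern —
positive LECN segregation, negative ASN segregation, negative age and
emotional stability — is recovered. The final model:

```r
tidy(fit)
#> # A tibble: 7 × 7
#>   term                 estimate std_error statistic  p_value conf_low conf_high
#>   <chr>                   <dbl>     <dbl>     <dbl>    <dbl>    <dbl>     <dbl>
#> 1 (Intercept)            2.80      2.07        1.35 1.79e- 1  -2.63     8.22
#> 2 dass                   0.217     0.0171     12.7  1.46e-23   0.172    0.262
#> 3 cognitive_complaints   0.0711    0.0113      6.26 6.99e- 9   0.0414   0.101
#> 4 emotional_stability   -0.0820    0.0141     -5.80 6.11e- 8  -0.119   -0.0450
#> 5 sys_lecn              11.5       2.05        5.60 1.50e- 7   6.11    16.8
#> 6 sys_asn              -11.0       2.13       -5.18 9.95e- 7 -16.6     -5.45
#> 7 age                   -0.0524    0.0186     -2.82 5.75e- 3  -0.101   -0.00363

glance(fit)$adj_r_squared
#> [1] 0.7382613
```

`conf_low`/`conf_high` are 99% intervals; coefficients are unstandardized
(e.g. `sys_lecn = 11.5` means +11.5 composite units per unit of LECN
segregation). The whole battery — per-questionnaire models, post-hoc
connectivity models, reversed DASS model, sex t test — runs in one call
via `run_pipeline(run_config(seed = 42), "out/")`, which persists every
intermediate table (per-subject segregation, cohort, one CSV per model, a
step trace, a JSON manifest) deterministically: same config + seed gives
byte-identical files.

Real data enter through `run_config(input = "files", ...)` with
per-subject time-series CSVs, a two-column `roi,network` parcellation CSV
and a behavioural cohort CSV.

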