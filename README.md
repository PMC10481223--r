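# milksense

Tracking human milk **secretory activation** from handheld conductivity
measurements.

During lactogenesis II the electrolyte content of milk -- chiefly sodium --
falls steeply as the mammary epithelium tightens, so the electrical
conductivity of a small milk sample is an objective, instant biomarker of
how far a mother has progressed from colostrum to mature milk. Delayed
progression is an early warning for low milk supply, the leading reason
mothers stop breastfeeding in the first weeks. `milksense` is for
biostatisticians and mHealth researchers working with such sensor data: it
implements the device model, the maturation score, the normative reference
charts and the screening analysis as composable, pipe-friendly functions,
plus a seedable cohort simulator so the entire pipeline is testable without
clinical data.

## The model

**Sensor.** A conductivity cell with cell constant K (1/cm, here K = 1)
converts conductance G (mS) to conductivity σ = K·G (mS/cm). Temperature is
compensated linearly, σ₂₅ = σ_T / (1 + α(T − 25)) with α = 0.020 /°C, and
each device carries an affine calibration m = g·σ + o fitted by least
squares to two KCl standards (1.413 and 12.88 mS/cm) and inverted at use.

**MM% score.** Milk maturation percent maps conductivity onto [0, 100]
between two anchors, σ_colostrum → 0% and σ_mature → 100% (linear by
default, logistic optional), strictly decreasing in σ and clipped with a
flag outside the range.

**Reference chart.** From scans of the "normal" breastfeeding class,
empirical 15th/50th/85th percentiles of MM% are computed per day-postpartum
bin (daily for days 0–20, then coarser), with a ±24 h smoothing window on
the first 3 days and a trailing −24 h window thereafter.

**Screening.** A scan is flagged when its MM% is *strictly below* the
day-matched 15th percentile. Over a day window (default days 6–20),
sensitivity = 100 · n_below / n_positive-class and specificity =
100 · (1 − n_below / n_reference-class). Group separation is quantified by
a two-factor ANOVA (class × day range) with Tukey-adjusted class contrasts
per range.

**Simulator.** Latent per-breast conductivity decays exponentially,
σ(t) = σ_mature + (σ_colostrum − σ_mature)·exp(−max(t − onset, 0)/τ), with
class-dependent kinetics (τ = 1.5/3/5 d, onset = 0.5/1/2 d for
normal / problems / low supply), log-normal individual variability,
per-breast asymmetry, 5% multiplicative measurement noise, device
distortions and realistic scan schedules.

## Worked example

```r
library(milksense)
library(dplyr)

coh <- simulate_cohort(cohort_config(n_mothers = 300), seed = 42)
classified <- classify_scans(coh$scans)
chart      <- classified |> filter(class_label == "normal") |> build_reference()
flagged    <- flag_scans(classified, chart, level = 15)
evaluate_threshold(flagged, window = c(6, 21))
#> Threshold evaluation, days [6, 21)
#>   Sensitivity (low_supply): 67% (59/88 below the line)
#>   Specificity (normal): 87% (41/326 below the line)
```

Of the 88 low-supply scans recorded on days 6–20, 59 fall strictly below
the day-matched 15th-percentile line of the normal reference population
(sensitivity 67%), while 87% of normal-class scans stay at or above it --
close to the 85% expected by construction of a 15th-percentile threshold.
The chart itself shows the canonical shape, a steep early rise to a plateau
near 100%:

```r
chart
#> <reference_chart> 26 bins, percentiles p15/p50/p85, built from 736 records
#> # A tibble: 26 × 6
#>   bin_start bin_end     n   p15   p50   p85
#>       <dbl>   <dbl> <int> <dbl> <dbl> <dbl>
#> 1         0       1    70  16.4  37.5  63.8
#> 2         1       2   116  23.2  54.5  81.0
#> 3         2       3   142  33.6  68.0  89.2
#> 4         3       4    84  59.7  81.3  92.9
#> # …
autoplot(chart, max_day = 30)

glance(compare_groups(flagged, classes = c("normal", "bf_problems", "low_supply")))
#> # A tibble: 1 × 4
#>       n  p_class p_day_range p_interaction
#>   <int>    <dbl>       <dbl>         <dbl>
#> 1  1328 1.99e-92   9.01e-264      3.77e-49
```

The class effect is overwhelming: mean MM% orders
normal > bf_problems > low_supply throughout days 5–20, the window where
delayed secretory activation is clinically actionable.

`run_pipeline(pipeline_config(seed = 1), "runs/demo")` executes the whole
chain (simulate → calibrate → MM% → classify → build reference → flag →
evaluate) into a run directory with per-stage CSVs, a `run.log` with row
accounting, and a deterministic `report.json`. A thin CLI wrapper with
`simulate`, `run` and `evaluate` subcommands is installed at
`inst/cli/milksense`.

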