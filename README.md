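# boutscan

Physical activity in chronic respiratory disease is usually summarised as
steps per day, but two people with identical step counts can accumulate them
very differently: many short bursts of movement, or fewer prolonged bouts.
After pulmonary rehabilitation (PR) this *pattern* of accumulation — not
just the total — is where intervention responses tend to show up.
`boutscan` derives activity-pattern outcomes from minute-epoch accelerometer
exports (MET-per-minute plus step counts, as produced by SenseWear-style
devices) for two-arm baseline/discharge trials, and provides the matching
statistics layer and a synthetic cohort simulator for validating the whole
chain against planted ground truth.

## What it computes

**Wear validity.** A calendar day is valid with ≥ 480 worn minutes (8 h);
a participant-timepoint enters analysis with ≥ 4 valid days. Non-worn
minutes contribute to nothing.

**Intensity classes.** Each worn minute is classified by its MET value
(1 MET ≈ 3.5 mL O₂/kg/min at rest):

| class | METs |
|---|---|
| sedentary or below | ≤ 1.5 |
| light | (1.5, 3) |
| moderate | [3, 6] |
| vigorous | > 6 |

Exactly 6.0 METs is moderate; exactly 1.5 is sedentary.

**MVPA bouts.** A bout is a *maximal run* of consecutive worn minutes at
moderate-to-vigorous intensity (≥ 3 METs; vigorous minutes do not break a
bout). By default a single sub-moderate minute ends a bout (an optional
interruption tolerance `max_break_min` is available). The bout-accumulation
spectrum reports mean bouts per valid day lasting ≥ 2, ≥ 5, ≥ 10 and ≥ 20
minutes, mean bout length, and total MVPA minutes per valid day.

**Participant summaries.** Per participant-timepoint: steps/day, daily MET
level (worn-minute MET mean pooled over valid days), % of wear time in the
moderate class, the bout spectrum fields.

**Statistics.** Two-tailed paired t (within-arm change), pooled-variance
independent t, two-way mixed-design repeated-measures ANOVA
(arm × timepoint, with the subjects-within-group and
time-by-subjects-within-group error strata), and tie-aware (mid-rank)
Spearman correlation for screening clinical covariates (age, BMI, FEV₁ %
predicted) against activity outcomes. No multiplicity adjustment is
applied; the run log reports the number of tests performed alongside α.

**Simulator.** `simulate_cohort()` generates a two-arm (web n = 20,
conventional n = 34), two-timepoint minute-epoch cohort with planted wear
windows, Poisson bouts with geometric lengths, class-specific step rates,
arm-specific intervention effects, and a planted-truth ledger used by the
test suite as an oracle.

## Worked example

```r
library(boutscan)

sim <- simulate_cohort(n_web = 6, n_conventional = 8, n_days = 7, seed = 42)
res <- run_pipeline(sim$epochs, sim$manifest, out_dir = "results")

gs <- res$group_summary
gs[gs$metric == "steps_per_day",
   c("arm", "baseline_mean", "discharge_mean", "pct_change")]
#>            arm baseline_mean discharge_mean pct_change
#> 1          web        5448.0         6116.9    12.2786
#> 2 conventional        5283.9         5521.2     4.4914
```

The web arm's planted short-bout intervention effect raises its steps/day
by ~12% while the conventional arm moves ~2–4%; with only 6 + 8
participants the interaction does not reach significance:

```r
st <- res$stats
st[st$test == "mixed_anova" & st$metric == "steps_per_day",
   c("effect", "statistic", "df", "error_df", "p_value")]
#>       effect statistic df error_df  p_value
#> 1      group     5.748  1       12 0.033673
#> 2       time    10.629  1       12 0.006825
#> 3 group:time     2.719  1       12 0.125056
```

`run_pipeline()` writes `participant_summaries.csv`, `group_summary.csv`,
`stats.csv` and a `run_log.txt` recording criteria, exclusions with
reasons, and the test count. A thin command-line wrapper lives at
`inst/cli/boutscan.R` (`simulate` and `run` subcommands).

### Epoch CSV schema

`participant_id,timepoint,timestamp,mets,steps[,worn]` — comma-separated,
header row, ISO-8601 UTC timestamps at 1-minute resolution; `timepoint` is
`baseline` or `discharge`. When `worn` is absent, an epoch is non-worn iff
`mets` is blank. Manifest:
`participant_id,arm,age,bmi,fev1_pct_pred,sex[,iswt_m,eswt_s]` with `arm`
∈ {`web`, `conventional`}.

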