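# proxinet

Social-network inference from animal-borne proximity sensors, built for
the fission–fusion societies of roosting bats. Proximity loggers record
every dyadic meeting between tagged animals (start time, duration, peak
signal strength) and contacts with fixed base stations; from these
streams proxinet reconstructs daytime roosting association networks and
nighttime foraging encounter networks, and tests whether cooperative
relationships inside the roost — association, kinship, grooming, food
sharing — predict who reunites outside it.

The motivating system is a wild colony of female common vampire bats
(*Desmodus rotundus*): 50 tagged bats (27 never-captive controls plus 23
females released after 21 months in captivity, whose dyadic grooming,
food-sharing, and co-feeding histories are known), tracked over 9
nights. The package ships a synthetic colony generator that emulates the
whole study design with known ground truth, so every stage is testable
without the field data.

## What it computes

**Processing.** Beacon-convention duration normalization (< 2 s → 1 s);
nested proximity classes from signal thresholds (association ≈ 50 cm,
close contact ≈ 2 cm); departure/return detection from roost base
station contact loss plus the drop of the associate count to 0–3;
foraging-encounter classification with the 1-minute transition margins
and the near-roost contact exclusion; co-departure counting.

**Networks.** Roosting association and close-contact rates (encounter
seconds over co-presence time, per day and aggregate); foraging
encounter seconds and nights-with-encounter (0–9) responses; hourly
co-foraging presence/absence counts; bout-overlap covariate; captive
co-feeding counts; per-period degree centrality with the
missing-if-absent rule.

**Inference** — the package's core, all permutation-based with one
p-value convention, `p = (1 + #exceedances) / (1 + n_perm)`:

- *Social differentiation*: coefficient of variation of dyadic
  co-foraging rates, with a data-stream null that rewrites one member of
  every encounter record to a random other bat outside the roost in the
  same day and hour.
- *QAP / MRQAP (double semi-partialling)*: network regression of a
  dyadic response on predictor matrices, with within-period constrained
  node-label permutations that preserve daily/nightly structure and each
  bat's presence pattern.
- *Day→night paired QAP* with a bootstrapped mean slope across days.
- *Centrality consistency*: within-night permutation test of the slope
  of foraging degree on mean roosting degree, one-tailed against a null
  whose center need not be zero.
- *Double permutation*: co-feeding rates adjusted by their median under
  within-hour identity permutations, then correlated with a predictor
  under node-label permutations.
- *Mantel tests* and *unadjusted repeatability* (one-way-ANOVA ICC with
  truncation at zero).

## Worked example

```r
library(proxinet)

study <- simulate_study(colony_params(n_bats = 20, n_nights = 9, seed = 7),
                        cofeed_nights = 30, cofeed_hours = 10)
study
#> <synthetic_study> 20 bats | 7116 proximity events | 155 true bouts | 8 co-feeding events

cfg  <- process_config(calendar = study$truth$calendar)
proc <- process_sensors(study$events, study$stations, cfg,
                        bats = study$truth$bats$bat_id)
table(proc$encounters$context)
#> excluded_transition            foraging            roosting
#>                   8                  26                7082

cofor <- hourly_coforaging(proc$encounters, proc$bouts, cfg)
differentiation_test(cofor, n_perm = 5000, seed = 7)
#> <perm_result> social differentiation (CV) = 3.645 | centered = 0.6525 | p (greater) = 0.004199 | 5000 permutations

nights <- foraging_seconds_network(proc$encounters, study$truth$bats$bat_id,
                                   per_night = TRUE, bouts = proc$bouts,
                                   cfg = cfg)
qap_regression(nights, list(relationship = study$truth$relationship),
               n_perm = 5000, seed = 7)
#> <qap_result> mode = node_label_constrained | 5000 permutations | 190 dyads, 20 bats
#>   relationship       beta =      4.204   p (two_sided) = 0.0003999
```

Reading the output: of 7,116 logged meetings, 26 qualify as foraging
encounters after the transition and near-roost exclusions. Co-foraging
is far more concentrated in specific pairs than the constrained null
expects (CV 3.65, p ≈ 0.004), and a dyad's nightly encounter time rises
by about 4.2 s per unit of latent relationship weight (p ≈ 4e-4 under
within-night node-label permutations) — the generator's embedded
preference structure, recovered from the sensor streams alone.

`run_pipeline(run_config(seed = 1))` chains the whole
simulate → process → networks → test sequence and emits one structured
JSON report.

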