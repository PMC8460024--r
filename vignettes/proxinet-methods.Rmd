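---
title: "Encounter networks from proximity sensors: models and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encounter networks from proximity sensors: models and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

proxinet reconstructs social networks of free-ranging animals from
animal-borne proximity sensors and tests social hypotheses with
constrained permutation methods. The motivating system is a colony of
female common vampire bats (*Desmodus rotundus*) carrying sensors that
log every dyadic meeting (start time, duration, peak signal strength)
and contacts with fixed base stations. From these streams the package
infers who roosted near whom by day, when each bat left and returned to
the roost at night, and which pairs reunited while foraging — and then
asks whether those nighttime reunions are predicted by within-roost
association, kinship, and histories of cooperation (social grooming,
food sharing, co-feeding) measured in captivity.

```{r, eval = FALSE}
library(proxinet)
study <- simulate_study(colony_params(seed = 1))
cfg   <- process_config(calendar = study$truth$calendar)
proc  <- process_sensors(study$events, study$stations, cfg,
                         bats = study$truth$bats$bat_id)
```

## The synthetic colony generator

Field data of this kind are expensive and irreproducible at desk scale,
so the generator is a first-class module: it produces complete study
datasets with known ground truth, which is what every calibration and
power property in the test suite runs against.

**Latent relationships.** Each dyad carries a latent cooperative
relationship weight in \([0,1]\), drawn from a Beta distribution with
fixed mean \(\mu\) (default 0.15) and concentration \(\kappa\) (default
0.8). One knob therefore controls social differentiation — the quantity
the differentiation test must detect: small \(\kappa\) gives few strong
and many weak dyads; \(\kappa \to \infty\) collapses every weight to
\(\mu\) (no differentiation). Grooming and food-sharing rate networks
for the previously captive subset are noisy monotone (log-normal
multiplicative) transforms of the same weights.

**Colony composition.** Defaults mirror the study population: 50 bats —
27 never-captive controls, 17 previously captive adults, and 6
captive-born daughters — observed over 9 nights. Captive-born daughters
are paired with previously captive mothers at kinship 0.5; all other
kinship defaults to zero. Nine of the 23 previously captive bats
(including all captive-born) leave the roost mid-study (`dropout_nights
= "study"`); absence is structural missingness downstream, never zero.

**Departures and bouts.** Departure time on night \(t\) is
\[
d_{it} = m_{\mathrm{type}(i)} + \delta\,(t-1) + b_i + \varepsilon_{it},
\qquad b_i \sim N(0, \sigma_b^2),\ \varepsilon_{it} \sim N(0, \sigma_w^2),
\]
with type means 8.3 h after sunset for controls, 1.6 h earlier for
previously captive bats and 2.0 h earlier for captive-born bats, and a
shared drift \(\delta\) of 840 s (14 min) per night. Because unadjusted
repeatability counts the shared drift as within-bat variance, the
default \(\sigma_b\) values (3312 / 1453 / 0 s, with \(\sigma_w\) =
1800 s) were set analytically so the *unadjusted* departure ICC targets
0.58 / 0.21 / 0 by type. Bout durations are log-normal around a
median of 2.5 h (controls), with log-scale variance components set the
same way to target bout-duration repeatabilities of 0.54 / 0.35 / 0.15.
Departures are pushed apart so no two bats leave within 6 s of each
other (the empirical minimum gap in this system is above 5 s).

**Foraging reunions.** For every clock hour in which both members of a
dyad are outside the roost, a reunion occurs with probability
\[
p = 1 - \exp\{-\exp(\eta_0 + \beta_r\,r_{ij} + \beta_k\,k_{ij})\},
\]
a complementary log-log link (chosen so probabilities stay valid for any
coefficients; any monotone link would serve, and the choice is recorded
in configuration). \(\eta_0\) corresponds to a baseline hourly
probability of 0.002; \(\beta_r = 5.5\) and \(\beta_k = 1.5\). These
three values were calibrated once against the study's printed field
totals — roughly 590 foraging encounters concentrated in about 150 of
1,200 pairs, hourly co-foraging counts spanning 0–15 — and are not
revisited. Encounter durations mix a sub-2-s point mass (60%,
normalized to 1 s, the observed median) with a log-normal tail
truncated below 30 min; kinship shifts the tail upward so close kin
meet longer.

**Sensor artifacts.** Bats in the roost hold continuous roost-station
contact; contact persists 20 s past a departure (sensor-range slack),
bouts occasionally include a brief mid-bout contact near the roost tree
(10% of bouts), and 5% of events carry sub-threshold peak signals.
These exist to exercise the exclusion rules below.

**Captive co-feeding.** Hourly feeder watches of the captive subset:
each bat is observed with probability 0.5 per hour (a vector of
probabilities creates heterogeneous shared feeding time — the confound
the double permutation adjusts for), and each observed dyad co-feeds
with a probability that is flat by default (identity-independent), or
weakly increasing in relationship. Default effort (70 nights × 15 h)
yields per-dyad counts in the small-integer 0–6 range.

What the generator does **not** emulate: spatial trajectories, acoustic
behavior, prey distribution, weather or moonlight. Passing tests
therefore show that the inference machinery is calibrated and powerful
under a plausible generative model of the sensor streams — not that any
biological conclusion about real colonies is reproduced.

## Sensor processing

Raw durations follow the beacon convention: encounters shorter than two
2-s signals have no measured length and become 1 s; longer durations
are rounded. Two nested proximity classes (association ≈ within 50 cm,
close contact ≈ within 2 cm) are defined by inclusive signal-strength
thresholds supplied in configuration; the signal-to-distance
calibration itself is out of scope, so thresholds are inputs.

Departures are declared where roost-station contact ceases *and* the
count of distinct associates stays at or below 3 (config `few`) through
the first 300 s away — the "sudden drop from many bats down to 0–3"
— with the return symmetric. Two reading choices deserve note. First, a
literal "falls from ≥ many" precondition would reject a bat that was
already alone before leaving, so the implemented condition is
ceases-and-stays-low. Second, a roost contact shorter than `min_home_s`
(300 s) does not split a bout — a bat circling past the roost tree has
not returned — but it still triggers the near-roost exclusion of any
encounter it overlaps.

Every encounter receives exactly one context (the partition is asserted
on every fixture): `foraging` if both bats are inside bouts, the
encounter starts more than 60 s after each departure and ends more than
60 s before each return, and no roost-station contact of either bat
overlaps it; `excluded_transition` if both are in bouts but inside the
margins; `excluded_near_roost` if in bouts, outside the margins, but
overlapping a roost contact; `roosting` otherwise. The margins are
applied to each bat's own bout independently (the stricter,
reproducible reading), and the transition rule is evaluated before the
roost-contact rule. An encounter that starts inside a bout but runs
past the detected return stays attached to that bout and falls to the
transition margin.

## Networks

All dyadic structures are symmetric matrices with zero diagonals;
structural missingness (never co-present, absent that period) is `NA`,
distinct from an observed zero, and missing dyads are dropped from
vectorized regressions. Roosting rates divide association (or close
contact) seconds by the dyad's co-presence time from roost-station
coverage — the denominator that keeps rates comparable across dropout
bats. Foraging responses are total encounter seconds and the more
conservative number of distinct nights with an encounter (0–9). Hourly
co-foraging marks presence/absence of an encounter per dyad per
absolute clock hour (two meetings in one hour count once; an encounter
spanning a boundary belongs to its start hour). Degree centrality
counts distinct partners per period; a bat with no encounters that
period is missing, never zero-degree (whether "degree" should instead
sum edge weights is not determined by the source methods; partner
counts are implemented, and the weighted variant is out of scope).

## Permutation inference

All tests share one p-value convention,
\(p = (1 + \#\{\text{null} \succeq \text{obs}\})/(1 + n_{\mathrm{perm}})\),
so \(p = 0\) is impossible; ties count as exceedances (slightly
conservative); every engine takes an explicit seed and is reproducible
draw-for-draw.

**Social differentiation** is the coefficient of variation of per-dyad
co-foraging totals over all dyads, zeros included. The null rewrites
every marked (night, hour, dyad) record by keeping one randomly chosen
member and redrawing the partner uniformly among the other bats outside
the roost in that same night-hour. Because the records are
presence/absence observations being swapped, the rewrite is
collision-free: the partner is drawn uniformly among bats whose dyad
with the kept member is not already marked in that hour, so every
permutation conserves the number of marked dyad-hours. (Implemented by
rejection sampling, which is exactly uniform over the free partners.)
This detail matters: a naive independent rewrite either loses marked
hours to collisions or double-counts them, shifting the null CV upward
and making the test measurably conservative; the mass-conserving swap
calibrates at nominal size. Records in hours with fewer than three bats
outside have no randomization freedom; they are kept as-is and counted
in the result.
Because a null spanning negative values implies a centered statistic in
some reports, the result carries both the raw CV and the centered
statistic (observed − null median); inference is always on the raw CV's
rank, to which centering is invariant.

**QAP / MRQAP.** Coefficients are ordinary least squares on the
vectorized non-missing dyads of the aggregate response. The null
permutes the *response* (predictors held fixed — the standard QAP
convention): one independent node relabeling per period, uniform over
the bats present in that period, applied to that period's layer before
re-aggregation. This preserves each period's network structure and the
presence/absence of bats — a relabeling can never move a bat into a
period it missed (asserted per draw). For multi-predictor models on
aggregate matrices, Dekker-style double semi-partialling is available:
the focal predictor is residualized on the others, the residual matrix
is node-label permuted, and the model refit. For day-stratified
responses the constrained node-label scheme is used for every
predictor; both modes are labeled in the result because the source
methods do not disambiguate which was used with covariates.

**Day-to-night pairing** regresses night \(d+1\)'s foraging network on
day \(d\)'s roosting network among bats present in both periods (days
with fewer than three shared bats are skipped and logged), then
bootstraps the mean of the per-day slopes, resampling days with
replacement (percentile 95% CI; no CI method is prescribed by the
source, percentile is the plainest).

**Centrality consistency** is the pooled OLS slope of per-night
foraging degree on each bat's mean daytime roosting degree, with the
null permuting foraging degrees among bats within each night. A mixed
model with bat intercepts is the descriptive analogue, but the
predictor is constant within bat, so within-bat centering would
annihilate it exactly; since the p-value contract is the permutation
scheme, the pooled slope is the cleaner statistic. The null slope
distribution is generally not centered on zero (sampling imbalance), so
the p-value is one-tailed for the stated alternative (default: in-roost
centrality carries over to foraging) and the result reports the
centered slope.

**Double permutation.** Stage 1 adjusts each co-feeding count by
subtracting its median under within-hour identity permutations
(relabeling the bats seen in each hour), which controls for overlap in
individual feeding schedules; stage 2 correlates the adjusted matrix
with a predictor, with significance from node-label permutations of the
adjusted matrix.

**Repeatability** uses one-way ANOVA variance components with Searle's
unbalanced-design \(n_0\) and the between-group component truncated at
zero, so ICC = 0 is attainable exactly.

## Calibration properties and their limits

The test suite verifies, against exhaustive enumeration on 3–4-bat
toys, that every Monte-Carlo engine reproduces its exact constrained
null; and, by simulation, that each test holds its nominal size under
the generator null that satisfies the exchangeability its permutation
scheme asserts (500 datasets of 14 bats × 6 nights, 200 permutations,
rejection at \(\alpha = 0.05\) within [0.03, 0.08]). Two design
findings from that calibration are worth knowing:

- The data-stream null for differentiation must conserve the number of
  marked dyad-hours (the collision-free swap above). Variants that
  redraw partners independently — deduplicating collisions or keeping
  duplicates — push the rejection rate down to roughly 0.01–0.03; the
  mass-conserving swap sits at nominal size in both synchronized and
  spread-schedule regimes.
- Bat-type blocks make nightly foraging degrees non-exchangeable; with
  the full type mix the centrality test's one-tailed rejection rises to
  ≈ 0.08. Its size check therefore uses a single-type colony, and
  results on strongly blocked data should be read with that in mind.

Power is verified at 30 bats × 9 nights under the default
strong-differentiation generator (both the differentiation test and the
relationship QAP reject at \(p \le 0.01\) in well over 90% of
replicates), ICC recovery at 30 bats × 9 nights and a 0.6 variance
ratio, and double-permutation calibration at feeder effort dense enough
(mean count ≈ 5) for per-dyad medians to be stable. These problem sizes
are the package's chosen verification scale; the pipeline itself runs
the full 50-bat, 9-night study in about a minute at 2,000 permutations.

## Numerical conventions and degenerate inputs

Times are integer seconds from the study epoch (first sunset); nights
are half-open `[sunset, next sunset)` with 12-h day/night defaults.
Threshold comparisons are inclusive. The CV is undefined for an
all-zero vector and raises a typed condition rather than returning a
number. Matrix correlations on degenerate (constant) inputs error;
permutation draws that become degenerate return `NA` and are excluded
from the null with the add-one convention intact. One master seed
derives a named sub-stream per stage, so stages are individually
reproducible and never share an RNG stream.
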