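---
title: "Personalized early-warning-sign monitoring: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized early-warning-sign monitoring: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ewsmonitor)
```

## The monitoring problem

People with schizophrenia and related psychoses typically see a clinician
only every few weeks, so the early warning signs of relapse — a rise in
dysphoric symptoms such as anxious mood, followed over roughly 1–5 days by
attenuated psychotic symptoms — are often noticed too late for prompt
intervention. Ecological momentary assessment (EMA) closes this gap: a
handset prompts the user semi-randomly a few times a day to rate 12–14
branching symptom items in the moment, and an alerting algorithm watches
the resulting time series for a personalized early-warning signature.

`ewsmonitor` implements that monitoring engine end to end: the prompt
scheduler, the personalized weighted score and its two alert rules,
adherence and retention metrics, alert-performance evaluation against
annotated or simulated episodes, and the design statistics of a
feasibility trial of such a system. Because raw patient streams are
confidential, the package ships a synthetic trajectory simulator with
ground-truth relapse prodromes; everything downstream of the simulator is
the same code that would run on real streams.

## The EWS score and alert rules

Each catalogue item $i$ receives a clinician-assigned relevance score
$r_i \in \{0, 1, 2, 3\}$ describing how strongly it featured in the
participant's historical relapse signature. Weights are tiered: items with
relevance 1 collectively carry 20% of the total score, relevance-2 items
30%, and relevance-3 items 50%, shared equally within a tier; relevance-0
items are still rated but carry zero weight. When a tier is unoccupied its
share is redistributed *proportionally* across the occupied tiers (e.g.
with tiers 3 and 2 only, weights become $0.5/0.8$ and $0.3/0.8$). We chose
proportional renormalization because it keeps the weights summing to 1
without arbitrarily inflating a single remaining tier; `compute_weights()`
is exact in this sense for every relevance assignment, which the test
suite verifies exhaustively for catalogues of up to six items.

The composite score at a completed prompt with ratings $x_i(t)$ is the
convex combination

$$S(t) = \sum_i w_i\, x_i(t), \qquad \sum_i w_i = 1 ,$$

so $S(t)$ stays on the rating scale (1–7 by default, mirroring the item
range of the clinician-rated instrument the self-report items were
validated against; the bounds are configurable). A weighted sum was chosen
over alternatives (e.g. a max or a count of elevated items) as the natural
reading of a "total score" with percentage tier contributions. Items
skipped by branching are imputed at the scale minimum: a skipped follow-up
probe encodes absence of the stem symptom.

The baseline $B$ is the mean of $S(t)$ over the first `baseline_days`
(default 3) *calendar* days of recording, and is frozen thereafter. Two
rules then fire on post-baseline scores:

* **single-point**: $S(t) \ge 1.4\,B$ (a 40% rise over baseline);
* **two-consecutive**: $S(t) \ge 1.25\,B$ at two successive completed
  prompts no more than `max_gap_hours` (default 24) apart.

Thresholds are attained at equality ("rose to 40% higher" reads as
attainment). "Consecutive" is restricted to prompts within 24 hours so
that a single elevated reading cannot pair with another one several days
later across a non-response gap. When both rules fire at the same prompt
the single-point rule is recorded, being the stronger statement. After any
alert a 24-hour refractory period suppresses further alerts; a clinical
team alerted once does not need an alert storm while they respond.
Baseline-window points never trigger alerts. An empty baseline window is
an error rather than a silent extension — callers decide how to handle
participants who never responded in their first days.

All of these choices are parameters of `ews_profile()` /
`ews_monitor()`, so sensitivity to any of them can be examined directly.
`detect_alerts()` is verified against a brute-force checker that tests
every point and every adjacent completed pair against the two
inequalities on a thousand random series.

## Prompt scheduling

"Semi-random" prompting is implemented as stratified-uniform bins, the
standard experience-sampling design: the daily window (default
09:00–21:00) is split into `prompts_per_day` equal bins and one instant is
drawn uniformly per bin, subject to a minimum same-day gap (default 2 h).
This guarantees coverage of the day and a minimum spacing while remaining
unpredictable to the participant. The default is 2 prompts/day, with 2–4
supported; published descriptions of such systems vary between
twice-daily and four-times-daily cadences, and twice-daily is the most
conservative for burden. Note one numerical subtlety: the min-gap
constraint truncates the feasible range of later bins' draws, so within-bin
offsets are exactly uniform only when the gap constraint is inactive; the
uniformity property is tested in that regime.

## Adherence and retention

Adherence is judged at the prompt level: one completed prompt equals one
symptom self-rating set. *Acceptable* adherence is a response rate
strictly above 1/3 of issued prompts, *good* strictly above 1/2 — both
thresholds are strict, so a rate of exactly one third is not acceptable.
"Retained at study end" is operationalized as at least one completed
prompt in the final 7 days of the study window, since "continued to use
the system" has no standard operational definition.

## The synthetic cohort simulator

`simulate_cohort()` generates what the engine needs to be testable
without patient data, and nothing more:

* **Latent dynamics.** Each item follows an AR(1) process at the prompt
  time scale, $x_{k+1} = \mu_{k+1} + \rho (x_k - \mu_k) + \varepsilon_k$,
  clipped to the scale and rounded to integers at observation time — the
  simplest process with realistic short-range autocorrelation in symptom
  self-reports. Defaults: $\mu_i = 2$, $\rho = 0.7$,
  innovation sd 0.5.
* **Prodromes.** Relapse events arrive Poisson (default rate 1 per
  12-week study, an illustrative figure — true relapse base rates are not
  identifiable from published summaries). Each event has a prodrome of
  uniform length 1–5 days; dysphoric item means ramp linearly from
  prodrome onset and psychotic means ramp after a lead (default 1 day),
  both peaking at the relapse day — the minimal parameterization of the
  two-stage dysphoric-then-psychotic signature. Amplitudes default to +2
  (dysphoric) and +3 (psychotic) scale points. A configured lead longer
  than the longest possible prodrome is rejected; for a drawn prodrome
  shorter than the lead, the psychotic rise collapses onto the relapse
  day.
* **Missingness.** Each prompt is completed with probability `p_resp`
  (default 0.7, in the range of observed EMA completion in psychosis
  cohorts), missing completely at random; an optional severity-linked
  (MNAR) decrement is available but off by default, so that detection
  properties are not confounded with informative missingness unless
  requested.
* **Reproducibility.** One master seed spawns per-participant substreams
  governing schedule, dynamics and missingness.

`scripted_stream()` complements the stochastic simulator: it inverts the
weighting for one designated root item so that the composite score equals
a prescribed trajectory *exactly*, which is how the threshold-attainment
and refractory cases are tested without tolerance games.

What the simulator does **not** emulate: medication effects, time-varying
adherence, measurement reactivity, within-day circadian structure, or
floor/ceiling pile-ups beyond clipping. Passing tests on simulated
cohorts therefore demonstrate the *engine's* correctness and calibration,
not clinical performance on real streams — the evaluation module exists
precisely so that real, chart-annotated episodes can be substituted for
simulated ones.

## Evaluating alerts

Published alert-accuracy figures for monitoring systems of this kind
rarely state their unit of analysis. We default to a window-based unit:
each participant's span is partitioned into consecutive 7-day windows; a
window is *positive* if it overlaps any episode (prodrome onset through
relapse day — alerting during the prodrome is the entire point, so such
alerts are true positives) and *alerted* if it contains at least one
alert. Sensitivity, specificity and PPV follow from the window confusion
table; a rate with an empty denominator is reported as `NA`, never 0.
An episode-level alternative (`episode_sensitivity()`, at least one alert
inside the episode, with an optional lead margin) is provided for
detection-power experiments.

`ppv_from_rates()` implements the Bayes identity
$\mathrm{PPV} = \mathrm{sens}\cdot\pi \,/\, (\mathrm{sens}\cdot\pi +
(1-\mathrm{spec})(1-\pi))$, which links any reported
sensitivity/specificity/PPV triple to the episode prevalence $\pi$; for
sensitivity 75%, specificity 8% and prevalence 33% it yields 28.6%,
i.e. the printed triple "75% / 8% / 29%" is internally consistent at an
early-warning prevalence of one third.

## Trial design statistics

`power_two_proportions()` uses the unpooled-variance normal approximation
for a one-sided two-sample proportion test, without continuity
correction, with dropout handled by analyzing $n_\mathrm{total}(1-d)/2$
per arm (kept fractional, as in design calculations):

$$\mathrm{power} = \Phi\!\left(\frac{|p_1-p_2|}{\sqrt{p_1 q_1 / n + p_2 q_2 / n}} - z_{1-\alpha}\right).$$

For a 40% → 20% reduction at one-sided $\alpha = 0.2$ with 72
participants and 10% dropout this gives 83.1% — consistent with the
standard feasibility-trial claim that such a design has (at least) 80%
power. Other classical formulas (pooled variance, arcsine
transformation) also clear 80% at this design; the unpooled normal form
was chosen as the most common default and is cross-validated in the test
suite against a 500,000-replicate Monte-Carlo simulation of the z-test.
The null case $p_1 = p_2$ returns power $= \alpha$ by construction.
`sample_size_two_proportions()` inverts the formula to the smallest even
total.

`ews_ancova()` estimates the trial endpoint: follow-up symptom score
regressed by OLS on allocation group, site, and the baseline score. The
adjusted mean difference is the group coefficient (active − control),
with 95% CI and p-values from the t distribution on the residual df.
The one-tailed p is half the two-tailed p when the estimate favors the
active arm, and $1 - p/2$ otherwise. A single-site data set drops the
site term with a warning; group confounded with site is an error. A
site-by-group interaction is available but off by default. The
implementation is checked against a direct normal-equations solve and
against `stats::lm`, holds its one-sided 20% type-I error to within half
a percentage point over 100,000 simulated null trials, and recovers an
injected −3.0 treatment effect to within Monte-Carlo error over 1,000
replicates (`simulate_endpoint_trial()` generates the trial data for
these checks).

## Numerical and interface choices

* Timestamps are UTC `POSIXct` throughout; all windows are half-open
  $[\mathrm{start}, \mathrm{end})$; day boundaries at midnight UTC.
* CSV artifacts are RFC 4180 (comma, UTF-8, header); streams are long
  format with one row per answered item and a single `missed` row for
  unanswered prompts; writer–reader round trips are byte-identical.
* The validator (`validate_stream()`) reports violations instead of
  throwing, so malformed field data can be triaged.
* Ratings are validated for range but not integrality: the slider scale
  is ordinal, but fractional ratings are permitted so that engineered
  test trajectories can hit thresholds exactly.
* The default catalogue (12 items: 7 psychotic, 5 dysphoric, 3 branch
  children) is explicitly illustrative — real deployments configure their
  own validated item set via `ema_catalogue()`.

Test problem sizes were fixed in advance at the scales the properties
call for: exhaustive weight checks to 6 items, 1,000-stream alert-oracle
comparison, 500,000 Monte-Carlo trials for power, 100,000 null trials for
type-I calibration, and 1,000 replicates for effect recovery.

## Known limitations

* The tier-share alert design is a fixed heuristic, not a learned risk
  model; adaptive thresholds are out of scope by design.
* Chart-annotated episode matching in real services involves a time
  tolerance and rating process this package does not model; only the
  arithmetic of the resulting confusion table is reproduced.
* Group-level adherence percentages from any particular trial depend on
  that trial's raw streams and cannot be reproduced from summaries; the
  package reproduces the *computation*, not the numbers.
* Offline buffering of handset uploads (mistimed alerts without network
  coverage) is not modeled; prompt times are taken at face value.
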