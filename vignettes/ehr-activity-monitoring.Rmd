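---
title: "Monitoring coded clinical activity across general practices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring coded clinical activity across general practices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehrmonitor)
```

## The problem

Primary-care electronic health records produce one coded entry for every
diagnosis, investigation, examination or administrative act. When a shock
hits the health system -- the archetype being the suspension of
non-urgent work in English general practice in spring 2020 -- the volume
of this coded activity drops abruptly and recovers unevenly across
clinical areas. `ehrmonitor` implements the descriptive surveillance
pipeline used to quantify such disruptions at the practice level:

1. **count** coded events per practice, clinical code, and calendar
   month;
2. **discover** the high-volume codes worth monitoring, and organise
   them into groups and clinical topics with a CTV3-style terminology;
3. **measure** each code/group as a monthly rate per 1000 registered
   patients, summarised as the median and deciles across practices, with
   year-on-year percentage change;
4. **classify** each subject's disruption-and-recovery pattern;
5. **report** decile charts, key-month tables, and a reproducibility
   manifest.

Because patient-level EHR data cannot be redistributed, the package
ships a fully seeded synthetic-data generator that plays the role of the
data source in all examples, tests, and validation experiments. The
generator is first-class, tested code: its purpose is parameter
recovery -- inject a known disruption, run the pipeline, and check the
measured disruption matches.

## The measures

For practice $p$ with registered list size $L_p$ and count $n_{pst}$ of
subject $s$ (a code or code group) in month $t$, the rate is

$$ r_{pst} = 1000 \, n_{pst} / L_p . $$

The denominator is the **index-date list size**: the population
registered at the study end date, held fixed for all months. This
mirrors cohort construction in the source systems, and has a known
side-effect -- patients who died or deregistered before the index date
are missing, so early months undercount true activity by a few percent.
The generator emulates this (see below). A monthly-denominator mode
exists but is off by default.

Practices with no events contribute an explicit rate of zero: published
April medians of 0.0 for, e.g., screening activity are only obtainable
when zero-activity practices are included.

Per subject and month the package reports the 10th-90th percentiles of
$r_{pst}$ across practices (the 50th being the median), using linear
interpolation between order statistics (R's default quantile type 7).
No published convention pins the quantile rule down, so it is
configurable and recorded on the output; the tests pin the default
against an independent sort-and-interpolate implementation to 1e-12.

The disruption metric is the year-on-year change of the median series,

$$ \Delta_t = 100 \, (m_t - m_{t-12}) / m_{t-12}, $$

computed at full precision and rounded (half-up, one decimal) only at
reporting time, where key-month cells are rendered as
`"19.8 (-86.9%)"`. A zero baseline makes $\Delta_t$ undefined; it is
flagged, never emitted as 0 or infinity. A positive baseline with a
current median of zero is a well-defined -100%.

### Recovery classification

Reports of service restoration use a small qualitative vocabulary --
activity was *maintained*, *recovered*, showed a *sustained drop*, or
*increased*. `classify_recovery()` operationalises it from two numbers
per subject: the nadir change (most negative $\Delta_t$ within a
disruption window) and the terminal change (at the final study month).
Default thresholds, all configurable:

| category         | rule (percent)                    |
|------------------|-----------------------------------|
| maintained       | nadir > -20                       |
| increase         | terminal > +10                    |
| recovered        | terminal in (-10, +10]            |
| partial_recovery | terminal in (-30, -10]            |
| sustained_drop   | terminal <= -30                   |

The thresholds were fixed by inspection of the published vocabulary
(e.g. an HbA1c-style pattern of -86% in April and -0.6% in December
must come out *recovered*; a depression-review pattern of -56% and
-42% must come out *sustained_drop*) and are not fitted to data.

The disruption window deserves a note. For field data the trough month
is unknown, so the classifier defaults to a 3-month window from the
disruption month. In the synthetic parameter-recovery experiments the
generator places the trough of the disruption multiplier exactly at the
disruption month, so `recovery_experiment()` uses a 1-month window:
with a trajectory that keeps declining toward a terminal level below
the initial drop, a wide window would by construction measure the
terminal deficit rather than the injected drop.

## The synthetic generator

One count is simulated per (practice, code, month) as

$$ n_{pct} \sim \mathrm{NB}\!\left(\mu_{pct},\ k\right), \qquad
   \mu_{pct} = \frac{L_p}{1000}\, \beta_c\, e_p\, s(t)\, m_c(t), $$

with variance $\mu + \mu^2/k$. The components, their defaults, and the
reasoning:

* **List sizes** $L_p$: log-normal, median ~8000 patients
  (`sdlog = 0.45`), the scale of English practice lists; floored at 1.
* **Baseline rates** $\beta_c$ (events per 1000 patients per month):
  log-normal with `sdlog = 1`, giving the heavy-tailed frequency
  profile of coded activity, where a handful of codes dominate volume.
* **Practice effect** $e_p$: log-normal with log-scale SD 0.35 and mean
  1, constant over time -- the simplest mechanism producing the
  persistent between-practice decile spread seen in real charts.
* **Seasonality** $s(t)$: a single sinusoid (default amplitude 0.1,
  January peak). Because the change metric compares the same calendar
  month across years, seasonality cancels from $\Delta_t$ exactly;
  richer seasonal shapes are deliberately out of scope.
* **Overdispersion** $k = 15$ by default: monthly practice-level counts
  are more variable than Poisson (coding drives, staff absence,
  batching); `dispersion = Inf` gives exact Poisson for tight tests.
* **Disruption multiplier** $m_c(t)$: 1 before the disruption month,
  $1 - d$ at it, then an approach to the terminal level over a
  configurable horizon with `none`, `linear`, `exponential`, or
  `overshoot` shape. Terminal level 1 is full recovery; 0.6 a sustained
  40% deficit; 1.2 an increase.
* **Index-date attrition**: counts in month $t$ are binomially thinned
  with loss declining linearly from `attrition_fraction_start` (0.07 in
  the demo configuration, the midpoint of the reported 6-8% early
  undercount) at the first study month to zero at the index month. The
  linear-in-time form is a modelling convenience: only the aggregate
  undercount, not its mechanism, is observable.

All generators draw from fixed, seed-derived RNG streams, so identical
configuration and seed reproduce every object exactly -- the pipeline's
CSV outputs are byte-identical across reruns, which the tests assert.

What the generator does **not** emulate: patient-level records (the
pipeline operates on counts), demographic or geographic structure,
correlated shocks across codes beyond the shared disruption profile,
code-usage drift or replacement (e.g. terminology migrations), and the
absolute volumes of specific real codes. Passing parameter-recovery
tests therefore demonstrates that the *measurement machinery* is
unbiased and correctly calibrated under realistic noise, not that any
particular real-world estimate is right.

## Validation by parameter recovery

The central validation generates studies of 200 practices x 60 codes x
24 months, injects an April-2020-style disruption with drop fraction
$d \in \{0.3, 0.6, 0.87\}$ and terminal level
$\ell \in \{0.6, 1.0, 1.2\}$, and checks that the measured nadir change
is within 5 percentage points of $-100d$, the terminal change within 5
points of $100(\ell - 1)$, and the classification the one implied, in
at least 95% of 100 seeded replicates per combination.

One combination is injected per replicate study, into every code. A
single code's measured change carries sampling noise of 3-6 percentage
points (medians of overdispersed counts across 200 practices), so the
replicate-level measurement is the **median across the study's codes**
of the code-level changes, with the modal category -- the natural
summary of "what did this study measure for the injected disruption",
and the one reported by `summarize_recovery_experiment()`. Codes too
sparse to measure are excluded just as they would be in the real
pipeline: below the frequency threshold, or with a zero baseline median
at a measurement month (no percentage change exists for them).

```{r recovery-example, eval = FALSE}
combo <- data.frame(drop_fraction = 0.87, terminal_level = 1)
res <- recovery_experiment(combo, synthetic_config(seed = 1))
summarize_recovery_experiment(res)
#>   drop_fraction terminal_level drop_pct terminal_pct  category ...
#> 1          0.87              1   -87.04        -0.21 recovered
```

## Numerical and boundary choices

* **Frequency threshold**: a code is retained when its annual total is
  at or above the threshold (default 1000 occurrences in the threshold
  year); only strictly smaller totals are excluded. The filter is
  monotone in the threshold and invariant to partitioning practices.
* **Quantile ties and duplication**: type-7 interpolation is exactly
  reproduced by the oracle; duplicating every practice changes deciles
  only at O(1/n), which the tests bound rather than assert away.
* **Rounding**: half-up at one decimal for reported rates and percent
  (so 0.05 renders "0.1", unlike banker's rounding); never applied
  before computing changes. The ambiguity of published "0.0 (-100.0%)"
  rows is resolved as: compute at full precision, then round.
* **Degenerate inputs**: empty practice vectors, unknown codes or
  subjects, malformed months (reported with row numbers), negative
  counts, cyclic or orphaned terminologies, zero list sizes, and
  practices missing from the registry all raise immediate, named
  errors rather than propagating silently.
* **Code strings** are case-sensitive (CTV3 distinguishes `XaF8d` from
  `Xaf8d`); description keyword matching is case-insensitive. Prefix
  groups match the literal code string, not tree position -- the two
  notions only approximately coincide in CTV3, so prefix and subtree
  groupings are separate, explicit definitions.

## Problem sizes

The bundled demo configuration runs 50 practices x 20 codes x 24
months in a few seconds. The validation experiments use 200 practices x
60 codes x 24 months per replicate, 100 replicates per disruption
combination, chosen as the smallest scale at which between-practice
decile spread, overdispersion, and median-based measurement interact
realistically while a full grid of conditions remains comfortable to
re-run; the acceptance script reports means over 10 such replicates per
condition.

## Limitations

Occurrences are counted, not unique patients or episodes; changes in
coding behaviour are indistinguishable from changes in activity; the
classification thresholds are descriptive conventions, not inferential
statements (no interrupted-time-series model, no significance testing
-- deliberately, as the method is a descriptive observatory); and the
log-normal choices for practice heterogeneity and code rates are
conveniences the real data do not directly constrain.
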