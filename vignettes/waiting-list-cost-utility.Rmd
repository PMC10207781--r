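---
title: "Methods: cost-utility analysis of screening waiting-list strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cost-utility analysis of screening waiting-list strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waitlineCEA)
```

## Overview

`waitlineCEA` compares organizational strategies for a breast-radiology
screening service — how many teams and machines run, and hence how long the
waiting list is — by their cost per quality-adjusted life year (QALY)
gained. The package treats the organization itself as the health technology
under assessment. This vignette documents the model, its parameters, the
calibration choices, and what the packaged synthetic data can and cannot
show.

## Tumor kinetics

A tumor of maximum dimension $d$ (mm) is modelled as a sphere of packed
cells:

$$N = \frac{\pi}{6}\left(\frac{d}{10}\right)^{3}\rho,
\qquad \rho = 10^{9}\ \text{cells/cm}^3 .$$

The packing density $\rho$ is the standard oncology convention; under it a
3 mm tumor holds $\approx 1.4\times 10^{7}$ cells and a ~30 mm tumor
$\approx 1.4\times 10^{10}$, which matches the two anchor sizes the model
is built around:

* **detection threshold** Td $= 10^{7}$ cells ($\approx 2.7$ mm): the
  smallest mammographically detectable tumor;
* **palpability threshold** Tp $= 10^{10}$ cells ($\approx 26.7$ mm,
  inside the commonly cited 25–30 mm range): the size a patient finds
  unaided, past which screening loses utility as an early-diagnosis tool.

Cell counts are taken as primary and the diameters derived, so both stay
mutually consistent under any density override.

Growth between the thresholds is **exponential with a constant doubling
time**, default 168.5 days. Only the endpoints of the growth window are
empirically anchored; the law itself is this package's choice (the simplest
one consistent with those endpoints — Gompertzian or stage-dependent growth
is out of scope). The default doubling time is calibrated so the Td→Tp
sojourn, $T_{d\to p} = DT \cdot \log_2(T_p/T_d) = 9.97\,DT$, is about 4.6
years; screening periodicity must stay inside that window to be useful.
Both parameters are config-overridable (`tumor_model:` block).

## Metastasis probability

With $P$ the average number of accumulated cells per expected metastatic
event, seeding is Poisson with mean $\mu = N/P$ and

$$\mathrm{pr\_met}(N) = 1 - e^{-N/P},$$

the complement of the Poisson zero-event probability. This is monotone in
$N$, zero at zero, and strictly below 1 for finite $N$ (numerically clipped
a hair below 1 where `exp` saturates).

$P$ is never published; `calibrate_P()` recovers it from the observed
stage-wise probabilities under the reference 32-month strategy (0%, 3%,
20%, 59% for T1A/T1B/T1C/T2-to-Tp). Choices made there:

* **Representative size per T-band**: the geometric midpoint
  $\sqrt{lo \cdot hi}$ of the band. Cells scale with $d^3$, so the
  geometric mean is less biased than the arithmetic one. TNM bands are
  T1A 1–5, T1B 5–10, T1C 10–20, T2 20–50, T3 > 50 mm, with T2 truncated at
  Tp (beyond Tp the probability table carries a flag instead of a number).
* **Objective**: least squares on the probability scale, not log-odds,
  because observed tables contain exact 0% entries; an observed 0
  contributes a one-sided penalty only.
* **Degenerate inputs**: a single informative pair is solved in closed
  form, $P = N/(-\ln(1-p))$; all-0/1 tables signal a calibration failure.

The packaged calibration yields $P \approx 7.1\times 10^{9}$ cells with
fitted probabilities 2.6% / 18.7% / 59.6% against the observed 3% / 20% /
59%.

**Waiting-time effect.** Under a strategy with waiting list $W$ months, a
tumor observed in a band under the reference $W_{ref}$ is detected after
$(W - W_{ref})$ months of extra (or avoided) growth, so its cell count is
rescaled by $2^{\Delta t / DT}$, floored at Td (a screen-detected tumor is
at least detectable) and flagged above Tp. This is the simplest mechanism
consistent with stage probabilities that fall as the waiting list shortens;
it is a modelling choice of this package, not an empirical statement, and
it reproduces the reference column's *ordering* across strategies exactly
but the shorter-wait columns only approximately (e.g. T1C at 22 months
comes out 5.8% vs a reported 7%).

Confidence intervals on reported probabilities use the **Wilson score**
construction at an effective n of 242 (the registry size): the original
interval construction is unstated, and Wilson behaves sensibly at 0 and 1,
where several bands sit.

## Cost model

All ledger arithmetic is integer-cents exact: margins, unit costs and cost
variations must close to the cent, and binary floating point on euro
amounts would not. Components (2019 accounting, 5 working hours/day):
staff €608.28 per team-day, goods and services €128.59/day, overheads
€92.65/day, equipment €30.82/day. A team (doctor + technician + nurse)
delivers 20 exams/day.

* **Revenue blend**: every exam earns the €87.00 first-level fee and the
  paying fraction (35%) additionally pays the €36.15 ticket —
  €99.6525/exam. This blend reproduces the 40- and 60-exam daily revenues
  exactly; the 80-exam figure is slightly inconsistent with any per-exam
  constant and is supplied as a printed override.
* **Overrides**: accounting figures that do not decompose from the
  component model (the 22-month strategy's daily cost, the 3-year totals)
  are attached to strategies as explicit overrides; when a computed figure
  contradicts an override by more than a cent, the ledger's `note` column
  records the discrepancy rather than silently adopting either side. The
  current strategy's unit cost is one such case: the ledger computes
  €36.72 (= 1,468.61/40) while the published table prints €34.42.
* **Horizon**: 728.37 working days over 3 years (~242.8/year), back-solved
  consistently from the published totals divided by daily costs;
  config-overridable. No discounting is applied anywhere, matching the
  3-year, single-payer perspective of the analysis.

## Effectiveness and QALYs

Life years per (strategy × stratum) are incident patients × life
expectancy within the 3-year horizon; life years gained (LYG) difference
each strategy against the current one. QALYs weight life years by the
health-state utilities 0.696 (non-metastatic, first year of disease), 0.779
(non-metastatic, later years) and 0.685 (metastatic, all years). The
non-metastatic split is 1 first year + remainder at the later-year weight,
i.e. a first-year fraction of $1/LE$.

Two deliberate choices:

* **Weighted levels, then differences.** The summary formula
  QALY = LYG × QoL and per-strategy QALY *levels* cannot both hold with one
  blended weight; the package weights the LY levels and differences the
  weighted totals, which keeps stratum additivity exact and implies a
  blended incremental weight (≈0.747) lying between the metastatic and
  non-metastatic utilities, as it must.
* **Synthetic survival fixture.** The packaged life-expectancy table
  (`seer_life_expectancy_synthetic.csv`) has the *shape* of a
  SEER-derived survival-by-stage table but synthetic values: metastatic
  1.2031639 y and non-metastatic 2.6169570 y, solved (one linear system,
  once) so the packaged configuration's LYG totals are exactly 47.8 and
  103.8. Users with registry access should substitute real values; the
  fixture file says so in its header.

The published per-stratum QALY levels are mutually inconsistent with any
single blended weight at one-decimal precision, so the default
configuration runs with `use_printed_overrides: true`, carrying those
levels as explicit inputs; the computed (non-override) path lands within
~0.3% of them. Reporting rounds to one decimal; full precision is kept
internally.

## ICER

$\mathrm{ICER} = \Delta C / \Delta \mathrm{QALY}$ against the current
strategy only — pairwise comparison, no efficiency frontier. A zero QALY
difference returns `NA` with a warning rather than a number. Dominance
follows the cost-effectiveness plane: better on one axis and no worse on
the other is dominant (mirror-image dominated); everything else is a
trade-off priced by its ICER. Ranking puts dominant strategies first, then
trade-offs by increasing ICER, with stable tie handling; a willingness-to-
pay threshold is optional and user-supplied. On the packaged inputs the
ICERs are €25,592.98/QALY (22-month) and €13,512.77/QALY (16-month),
within 0.1% of the published €25,614.30 and €13,507.31 — the published
ratios were formed from unrounded QALYs that are not recoverable, which is
why 0.1% is the honest reproduction bound.

## Synthetic cohort generator

`generate_cohort()` draws a patient table with the marginal structure of
the 242-patient registry the analysis emulates: stage 20/65/95/59/3
(T1A…T3), nodes 154/88 (N0/N+), histology 189/44/5/2
(ductal/lobular/tubular/mucinous), grade 79/109/47. Frequency vectors are
renormalized over reported categories (histology sums to 240 and grade to
235 of 242 because of unreported cases). Diameters are log-uniform within
the patient's T-band — sizes are scale-like, so log-uniform avoids piling
mass at the wide end. `assign_metastasis()` then draws each patient's flag
Bernoulli at `pr_met` of their cell count, and `scale_to_strategy()`
rescales a spec to a strategy's 3-year volume (30,000 / 45,000 / 60,000),
optionally shifting the stage mix down-stage through the kinetics.

What the generator does **not** emulate: joint dependence between stage,
grade, histology and nodes (only marginals are published, so attributes are
sampled independently); calendar arrival patterns; patient-level survival.
Passing tests therefore show that the pipeline arithmetic and the model
code are correct under the stated marginals — not that the cohort is
clinically realistic in its joint structure.

Determinism: a spec's seed fully determines the cohort (byte-identical
serialization), and the caller's RNG state is restored afterwards.

## Numerical choices and degenerate inputs

* Currency at integer-cent resolution; CSV serialization as fixed
  two-decimal strings so round trips preserve every cent.
* Calibration optimizes over $\log P$ on $[10^4, 10^{16}]$ with `optimize`
  at square-root machine tolerance; single-pair inputs bypass it.
* Probabilities are clipped to $[0, 1-\epsilon]$; bands above Tp carry
  `NA` plus an `above_palpability` flag rather than a fabricated number.
* `validate_config()` returns *all* violations (frequency vectors, payer
  fraction, capacity identity exams = 20 × teams, band overlaps,
  unresolvable paths) without side effects; `run_pipeline()` refuses to
  start on any issue and otherwise aborts with the failing stage's name.

## Problem sizes used in the tests

The suite runs at deliberately small scale: cohorts of 242–10,000 patients
(one 50,000-row law-of-large-numbers check), 40–60 calibration replicates
under binomial noise, and 40 seeds for the goodness-of-fit calibration of
the generator itself. The whole suite completes in a few seconds on one
CPU.

## Known limitations

* The waiting-time → stage-probability mechanism is the package's own
  simplest-consistent choice; alternative mechanisms (e.g. length-biased
  sampling of sojourn times) would change the shorter-wait columns.
* Life expectancies are synthetic calibration parameters, not SEER values.
* Published metastatic patient counts per strategy (80/62/35) cannot be
  recomposed from the published stage mix and probabilities; only their
  ordering is asserted.
* No discounting, no probabilistic sensitivity analysis, no efficiency
  frontier, single payer perspective — matching the scope of the analysis
  the package operationalizes.
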