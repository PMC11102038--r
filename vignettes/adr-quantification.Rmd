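---
title: "Quantitative ADR characterization: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative ADR characterization: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adrquant)
```

## The problem

Spontaneous-reporting systems such as FAERS collect adverse drug event
(ADE) reports filed during post-marketing drug use. Each report names one
or more drugs, one or more adverse drug reactions (ADRs, coded as
MedDRA-style preferred terms under system organ classes), a reporter
class, and — since 2012 — a treatment outcome per reaction: recovered,
recovering, not recovered, resolved with sequelae, or fatal (coded O1–O5
here). Routine pharmacovigilance reduces this to a binary question — is
the drug associated with the ADR? `adrquant` implements a quantitative
extension: for every drug–ADR pair it estimates *how severe* the reaction
tends to be, and *how often* it occurs per prescription, then uses those
features to screen drug–ADR–target associations.

## Disproportionality screening

For a drug $D_i$ and reaction $A_j$, reports are cross-classified at
report granularity: $a$ reports mention both, $b$ the drug with other
reactions, $c$ the reaction with other drugs, $d$ neither. The reporting
odds ratio is

$$\mathrm{ROR} = \frac{a\,d}{b\,c},$$

with the Woolf (log-normal) interval
$\exp\{\ln \mathrm{ROR} \pm z\,\sqrt{1/a+1/b+1/c+1/d}\}$. Tables
containing a zero cell receive the Haldane–Anscombe 0.5 correction in
every cell (on by default; with it off, tables with $bc = 0$ return `NA`
rather than an infinite estimate).

A pair is retained as a reliable association when the one-sided
hypothesis $\mathrm{ROR} > 1$ is significant at $P < .05$
(equivalently, the lower bound of the 90% interval exceeds 1), while the
reported `ci_low`/`ci_high` columns remain the conventional 95% interval.
We chose the one-sided construction deliberately: "ROR above 1 flags a
risk factor" is a directional claim, and the one-sided test gives the
filter an exactly nominal 5% type-I error under the independence null —
a property the test suite verifies by simulation. Screening instead on
"95% CI lower bound above 1" would be a 2.5% one-sided test; users who
prefer that stricter convention can filter on `ci_low > 1` directly.

Before disproportionality, reports are qualified: nonprofessional
(consumer/patient) reports are dropped as unreliable; reaction mentions
under five drug-unrelated system organ classes (congenital/familial/
genetic disorders, surgical and medical procedures, social circumstances,
product issues, and injury/poisoning/procedural complications) are
removed, a report surviving only if some reaction remains; and only
single-ingredient small-molecule drug reports are kept. Support
thresholds then discard rarely observed units: ADRs reported fewer than
2 times, drugs fewer than 26 times, and pairs observed in fewer than 2
distinct reports. All three support conditions are evaluated on
pre-filter totals, so their order cannot matter. The drug threshold
counts distinct reports mentioning the drug (not drug mentions); both
interpretations are defensible and the threshold is configurable in
`qualification_rules()`.

## The penalized severity model

Treatment outcomes are the observable trace of severity: a reaction whose
cases mostly resolve is milder than one that kills. The model scores a
pair by penalizing outcomes *reciprocally* — the mildest outcome gets the
largest penalty, so that dividing by a function of the penalty rewards
severe outcomes:

$$\mathrm{Severity} \;=\; \sigma(\mathrm{ROR}) \sum_{k=1}^{5}
\frac{w_k \; P(O_k)}{\log_2\!\big(\mathrm{Penalty}(O_k)+1\big)},$$

with $\mathrm{Penalty} = (5,4,3,2,1)$ and emphasis weights
$w = (1,2,3,4,5)$ for O1–O5. $P(O_k)$ is the conditional outcome
distribution estimated from the pair's outcome-bearing reports, and

$$\sigma(\mathrm{ROR}) = \frac{1}{1 + e^{-\log_2 \mathrm{ROR}}}$$

maps association strength onto $(0.5, 1]$: exactly $0.5$ at
$\mathrm{ROR}=1$, approaching 1 as $\mathrm{ROR}\to\infty$. The score
therefore lies in $[0, 5]$.

### Grade boundaries from extreme cases

Setting $P(O_k) = 1$ for a single $k$ with $\sigma$ at its supremum 1
gives the five *pure-outcome* scores

$$\frac{1}{\log_2 6},\; \frac{2}{\log_2 5},\; \frac{3}{\log_2 4},\;
\frac{4}{\log_2 3},\; \frac{5}{\log_2 2}
\;=\; 0.387,\; 0.861,\; 1.500,\; 2.524,\; 5.000 \;(3\ \mathrm{dp}),$$

which partition the score axis into the five grades mild, moderate,
severe, life-threatening, death:

```{r boundaries}
grade_boundaries()
```

This identity is the model's central check and is asserted by the test
suite and the acceptance script. Because the pure scores must increase
strictly with outcome severity for the zones to be well ordered,
`grade_boundaries()` rejects parameter sets (equal penalties, reversed
weights, ...) that break monotonicity.

Three numerical conventions matter here:

* **Zone closure.** Grade intervals are lower-open/upper-closed, with 0
  included in mild, so each pure-outcome extreme lands in its own grade.
* **Printed precision.** Scores and edges are compared after rounding to
  3 decimals (`digits` argument of `assign_grade()`), the precision at
  which boundaries are conventionally quoted; a score of exactly 0.387
  grades as mild.
* **Conditioning scope.** $P(O_k)$ is estimated per pair by default.
  Pooling outcomes per ADR across all drugs (`scope = "per_adr"`) is
  available, but under pooled conditioning two pairs of the same ADR
  could differ only through $\sigma$, capping the per-drug score spread
  of an ADR at 2-fold; observed per-drug spreads are wider, so per-pair
  conditioning is the default.

Pairs with no outcome-bearing reports cannot be scored; they are retained
with `NA` and an explicit `excluded_reason` audit column rather than
silently dropped. The attainable minimum with default parameters is
$0.5 \times 0.387 = 0.193$ (all cases recovered, ROR at its infimum).

## Underreporting-corrected frequency

The naive frequency — reports divided by prescriptions — is biased by
severe underreporting of spontaneous systems: roughly 94% of events are
never reported, dropping to about 77% for very serious events. With the
underreporting rate (URR) keyed to the pair's assigned grade:

$$\mathrm{Freq}_{D_i-A_j} \;=\;
\frac{\mathrm{count}(D_i\!-\!A_j)}{(1-\mathrm{URR}) \times
\mathrm{AAP}_{D_i} \times \mathrm{yr}},$$

where AAP is the drug's average annual prescriptions and
$\mathrm{yr}$ the length of the observation window (default 8 years,
matching a 2012–2019 window; configurable since windows rarely fall on
exact year counts). The URR dependence on grade is why severity
estimation *must* precede frequency estimation in the pipeline DAG.
Estimates above 1 — possible since the estimator is not
probability-bounded — are clamped to 1 with a warning. Frequencies fall
into the conventional classes very rare ($<10^{-4}$), rare, uncommon,
common, very common ($\ge 10^{-1}$); the published convention leaves the
cut points unassigned (strict inequalities on both sides), so we close
the bins on the left.

AAP comes from person-weighted prescription survey records
(MEPS-style): each drug's person-weight sum over the period, divided by
the number of period years. Raw survey drug names resolve through the
same three-route dictionary resolver as report mentions — product code,
exact synonym, then cleaned-name synonym after stripping dosage/form stop
tokens ("mg", "ophthalmic", "tablets", "chewable", ...; the shipped list
is editable because such vocabularies are inherently open-ended). Drugs
absent from the survey inherit the mean (optionally median; the central
tendency is not conventionally fixed, so the milder mean is the default)
of the direct AAPs in their ATC level-2 therapeutic subgroup; drugs with
no ATC code or an empty subgroup stay `unavailable` and are reported in
the audit trail rather than guessed.

## Evaluating the grading against an expert table

Because an ADR may carry different grades under different drugs, both
the model and an expert system (CTCAE-style) assign grade *sets* per
preferred term. On the mutual preferred terms, each term is classified
as **consistent** (expert grades fully matched or covered by the model's,
i.e. expert $\subseteq$ model), **partially consistent** (overlap without
coverage), or **inconsistent** (disjoint sets). Coverage rather than
equality defines consistency because the model legitimately observes more
drug contexts than an expert table fixes; strict equality is still
reported per term (`identical` column) for transparency.

## Drug–ADR–target association

Joining scored pairs with each drug's therapeutic targets yields distinct
drug–ADR–target entries. Singleton entries — an ADR linked to exactly one
target, or a target to exactly one ADR — are excluded in a single pass on
the pre-exclusion counts (iterating the exclusion to a fixed point would
be a different, stricter operation; one pass is the documented choice).
Association between an ADR (or the fatal group: grades life-threatening
and death) and a target is an odds ratio over entries with a Woolf 95%
interval, zero cells corrected as above; significance here is two-sided
(the 95% CI excludes 1), the natural convention when no direction is
privileged.

Relations are classified into four mechanism zones by OR and ADR
frequency: zone 1 (high OR, low frequency; on-target, controlled by
dosage design), zone 2 (high OR, high frequency; dose-dependent), zone 3
(low OR, low frequency) and zone 4 (low OR, high frequency; off-target).
No published numeric zone thresholds exist; the defaults
(`or_threshold = 2`, `freq_threshold = 1e-3`) are artifact defaults of
this package, and both comparisons use $\ge$. The fatal-risk screen
reports targets whose fatal-group OR exceeds 2 (the conventional cut),
ranked by OR with ties broken by target id.

## What the simulator emulates — and what it does not

`sim_config()` + `simulate_ade_reports()` generate the statistical
skeleton of a spontaneous-reporting corpus:

* true events per (drug, ADR, year) are Binomial(prescriptions,
  incidence);
* each event draws one treatment outcome from the pair's outcome
  profile (one outcome per reaction mention — the minimal reading of how
  outcomes attach to reactions in reports);
* events are thinned into reports with probability 0.23 when the drawn
  outcome is O4/O5 and 0.06 otherwise, the severity-stratified reporting
  rates implied by the 77%/94% underreporting estimates;
* reports carry reporter class, SOC labels and product codes, and the
  companion `simulate_prescriptions()` emits person-weighted records
  whose annual weight sums equal the configured prescription volume,
  with optional messy name variants exercising the resolver.

Defaults were fixed once as the simulated study conditions: 2012–2019,
per-pair incidence log-uniform on $10^{-4}$–$10^{-2}$ (most ADRs are
rare), outcome profiles Dirichlet(8, 4, 2, 1, 0.5) (recovery-dominant,
with realistic mass on fatal outcomes), and a 25% nonprofessional
reporter share (consumer reporting is substantial in real systems; the
true mix is unknown and configurable).

The simulator does **not** emulate: duplicate report submission, drug
interactions or co-prescription structure (each report carries one
suspect drug), reporting-rate drift over calendar time, region or age
strata, or correlated reporting across ADRs of one patient. Passing tests
therefore demonstrate that the estimators recover the generative
parameters they target under honest sampling noise — not that real-world
biases beyond severity-stratified underreporting are corrected.

Ground truth (incidence, outcome profiles, annual volumes, event/report
tallies) is emitted for every simulated key, so estimator-consistency
tests — e.g. frequency recovery of a known incidence of 0.005 at a 6%
reporting rate over 8 simulated years, within 10% relative error across
20 replicates — are exact-by-construction rather than approximate
fixtures.

## Problem sizes and runtime

The shipped tests run desk-scale scenarios chosen as the smallest sizes
at which each property is statistically decisive: pipelines on 8–20
drugs × 12–30 ADRs at 3,000–10,000 prescriptions/drug/year; null
calibrations on 1,000 simulated 2×2 tables; planted-association recovery
over 100 seeds; frequency recovery at 100,000 prescriptions/year where
the expected report count (240) makes a 10% relative-error check
non-trivial. The full suite completes in well under a minute on a single
core.

## Known limitations

* Severity is estimated from *reported* outcomes; because severe events
  are over-reported, severity of serious ADRs is overestimated — an
  inherent property of the data source, partially mitigated (for
  frequency, not severity) by the URR correction.
* The Woolf interval is asymptotic; at very small cell counts the 0.5
  correction keeps it defined but approximate.
* The frequency estimator assumes the reporting rate equals
  $1-\mathrm{URR}$ uniformly within a grade group.
* Name resolution is dictionary-bound: coverage of the synonym table is
  the ceiling on resolution, and ambiguous cleaned names are deliberately
  left unresolved rather than guessed.
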