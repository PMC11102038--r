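# adrquant

Quantitative characterization of adverse drug reactions (ADRs) from
spontaneous adverse-event reports and person-weighted prescription
records.

Pharmacovigilance typically stops at a binary signal: drug *D* is (or is
not) disproportionally associated with reaction *A*. `adrquant` is for
drug-safety analysts and method developers who need the next two
dimensions — **how severe** a drug–ADR pair tends to be, and **how
often** it occurs per prescription — plus downstream screens that use
those features to rank drug–ADR–target associations and flag targets
enriched for fatal reactions.

## The models

**Disproportionality.** For each drug–ADR pair, the report-level 2×2
table (a, b, c, d) gives the reporting odds ratio `ROR = ad/bc`, with a
Woolf log-normal 95% CI and Haldane–Anscombe 0.5 correction for zero
cells. Pairs are retained when the one-sided test of ROR > 1 is
significant at P < .05.

**Severity.** Each pair's treatment-outcome distribution
P(O₁..O₅) over {recovered, recovering, not recovered, resolved with
sequelae, fatal} is scored by a penalized, outcome-weighted sum
modulated by association strength:

    Severity = σ(ROR) · Σₖ wₖ · P(Oₖ) / log2(Penalty(Oₖ) + 1)

with Penalty = (5, 4, 3, 2, 1), w = (1, ..., 5), and
σ(ROR) = 1 / (1 + e^(−log2 ROR)) ∈ (0.5, 1]. The pure-outcome extreme
cases (P(Oₖ) = 1, σ → 1) analytically fix the five grade boundaries:

    mild             (0.000, 0.387]
    moderate         (0.387, 0.861]
    severe           (0.861, 1.500]
    life_threatening (1.500, 2.524]
    death            (2.524, 5.000]

**Frequency.** Reported pair counts are corrected for the severe
underreporting of spontaneous systems (URR 0.94, or 0.77 for
life-threatening/death grades) and normalized by prescription volume:
`Freq = count / ((1 − URR) · AAP · yr)`, where AAP is the drug's average
annual prescriptions from person-weighted survey records (with ATC
level-2 inference for unsurveyed drugs) and yr the observation window
(default 8 years). Frequencies classify into very rare / rare / uncommon
/ common / very common at the conventional 10⁻⁴ ... 10⁻¹ cut points.

**Association.** Drug–ADR–target entries (singletons excluded) are
screened by odds ratio, mapped onto four OR × frequency mechanism zones
(on-target/dose-controlled, dose-dependent, and two off-target zones),
and targets with fatal-group OR > 2 are ranked as fatal-risk targets.

A seeded simulator (`sim_config()`, `simulate_ade_reports()`,
`simulate_prescriptions()`, `simulate_expert_grades()`,
`simulate_target_map()`) generates FAERS-like reports and MEPS-like
prescription records with full ground truth, so every estimator is
testable end to end without external data.

## Worked example

```r
library(adrquant)

cfg <- pipeline_config(
  sim = sim_config(n_drugs = 12, n_adrs = 20,
                   n_patients_per_drug_year = 8000, seed = 42))
bundle <- run_pipeline(cfg)

dplyr::select(bundle$pairs, drug_id, adr_id, n_reports, ror,
              severity_score, severity_grade, frequency, freq_class) |>
  head(5)
#>   drug_id adr_id  n_reports   ror severity_score severity_grade   frequency
#> 1 D001    ADR0004        23  2.48          0.836 moderate           0.00599
#> 2 D001    ADR0007        33  2.51          1.60  life_threatening   0.00224
#> 3 D001    ADR0009        24  1.51          0.929 severe             0.00625
#> 4 D001    ADR0014        29  3.81          0.927 severe             0.00755
#> 5 D001    ADR0018        20  2.55          2.30  life_threatening   0.00136
```

58 of the simulated pairs survive qualification, support and
significance filtering. Each row reads: the pair was reported
`n_reports` times; `ror` is its disproportionality (all > 1 after
filtering); `severity_score` places it on the 0–5 axis and
`severity_grade` in the corresponding zone; `frequency` is the
underreporting-corrected occurrence per prescription (here ~10⁻³–10⁻²,
i.e. mostly "uncommon" — the simulation draws incidences of 10⁻⁴–10⁻²).

The evaluation stage compares the model's per-term grade sets against a
(here simulated) expert table with planted agreement fractions:

```r
bundle$evaluation$summary
#>   state                    n   pct
#> 1 consistent               9  50
#> 2 partially_consistent     5  27.8
#> 3 inconsistent             4  22.2
```

and the association stage ranks targets by their odds ratio against the
fatal ADR group:

```r
head(bundle$fatal_targets, 3)
#>   target_id    or ci_low ci_high
#> 1 T006       5.09  0.514   50.5
#> 2 T007       2.39  0.770    7.39
#> 3 T019       2.25  0.481   10.6
```

A thin command-line wrapper over the same functions ships in
`inst/cli/adrquant.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "adrquant.R", package = "adrquant"))')" \
  run-all --config demo.yaml --seed 7 --out results/
```

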