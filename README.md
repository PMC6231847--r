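# dqspc

Data-quality scoring and statistical process control for clinical encounter
records.

Primary-care organisations (for example Ontario family health teams) require
allied health professionals to log every clinical encounter in a structured
reporting system, and the value of that data depends on how it is entered:
promptly, completely, and with logically consistent dates. `dqspc` is an R
implementation of the standard monitoring pipeline for these data-entry
behaviours:

* **Rule engine** — classifies each record on three dimensions:
  *same-day entry* (`entry_date == appointment_date`), *completeness*
  (all required fields present, visit reason not `"other"`, referral source
  and a *known* referral date for initial encounters — the system's
  `1900-01-01` "I do not know the referral date" sentinel counts as
  missing), and *validity* (appointment ≤ entry, appointment after
  2008-01-01, entry under 4 calendar months after the appointment,
  referral-to-appointment gap at most 6 calendar months).
* **Measure series** — percentages by user, by calendar month, or by
  8-week pre/post intervention window.
* **XmR control charts** — for a monthly series with moving ranges
  mR<sub>i</sub> = |x<sub>i+1</sub> − x<sub>i</sub>|, the individuals chart
  uses limits x̄ ± 2.66·m̄R and the moving-range chart 3.267·m̄R; points
  strictly outside the limits are assignable-cause signals.
* **Paired pre-post analysis** — per-user paired *t* test, Cohen's
  *d* = d̄/s<sub>d</sub> (so *t* = *d*·√n), and post hoc power
  Φ(|d|·√n − z<sub>1−α/2</sub>), plus an entry-volume comparison.
* **Synthetic cohort generator** — seeded, calibrated simulation of
  per-user entry behaviour (volumes, delays, sentinel spikes, quarter-end
  seasonality, injected date errors, a step-change intervention) so the
  whole pipeline is testable without any organisational data.

## Worked example

Simulate a study-scale cohort (53 users, Apr 2016 – Feb 2017, intervention
in the last week of November 2016), score it, chart the timeliness measure,
and run the pre-post analysis:

```r
library(dqspc)

cfg <- scenario_paper_like()
records <- generate_cohort(cfg)       # ~106,000 encounter records
flags <- score_dataset(records)

monthly <- aggregate_measures(flags, records, "by_month")
chart <- xmr_from_measures(monthly, "same_day", from = "2016-04",
                           to = "2017-02",
                           annotation_date = cfg$intervention_date)
print(chart)
#> XmR chart (11 points, limits from all points)
#>   X : centre 66.147, limits [61.657, 70.637], 3 signal(s)
#>   mR: centre 1.688, upper limit 5.515, 1 signal(s)
#>   X signals at: 2016-12, 2017-01, 2017-02
#>   annotation: 'UI CHANGE' at 2016-11

prepost_table(records, cfg$intervention_date)
#> same_day  n=53 (excl 0)  pre   64.10  post   71.98  change   +7.88  t=  4.73  p=1.74e-05  d=0.650  power=0.997
#> complete  n=53 (excl 0)  pre   84.68  post   81.40  change   -3.28  t= -2.57  p=0.013  d=-0.353  power=0.730
#> valid     n=53 (excl 0)  pre   99.40  post   99.42  change   +0.01  t=  0.15  p=0.879  d=0.021  power=0.035
#> volume    n=53 (excl 0)  pre  336.96  post  334.19  change   -2.77  t= -0.73  p=0.469  d=-0.100  power=0.109
```

Reading the output: every monthly timeliness point after the intervention
sits above the upper control limit — an assignable-cause signal, not
routine noise — and the paired analysis quantifies the step (+7.9
percentage points for this seed; the generator's true step is +10.4 and a
single 53-user cohort has a between-user SE of ~2.2 points). Completeness
*drops* after the intervention (users initially sacrifice the referral date
for speed, then recover), validity is unchanged, and entry volume is
comparable across windows, so the timeliness change is not an artefact of
workload. `plot(chart)` renders the two-panel chart with the annotation
line; `xmr_table(chart)` exports its numeric content.

A command-line interface over the same functions is installed at
`inst/cli/dqspc` (subcommands `simulate`, `score`, `xmr`, `prepost`,
`report`; exit codes 2/3/4 for config, schema and insufficient-data
errors).

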