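# dipa

Scoring and longitudinal reporting for post-operative pain management with
the **Detroit Interventional Pain Assessment (DIPA)** scale.

Orthopedic patients are followed in clinic at two weeks, six weeks, three
months and six months after surgery. At each visit the patient reports pain
on the three-level **IPA** scale (0 no pain, 1 tolerable pain, 2 intolerable
pain), and their controlled-substance prescriptions are converted to a daily
**morphine milligram equivalent (MME)** dose,

```
daily MME = Σ over opioid prescriptions of strength_mg × doses_per_day × conversion factor
```

using a versioned CDC-style oral conversion-factor table (morphine 1 by
definition, hydrocodone 1, oxycodone 1.5, tramadol 0.1, tiered factors for
methadone, ...). The daily MME maps to a five-level medication class

| class | meaning | daily MME |
|-------|---------|-----------|
| A | no pain medication | 0 |
| B | over-the-counter only | 0 |
| C | occasional short-acting narcotics | (0, 30] |
| D | consistent short-acting narcotics | (30, 80) |
| E | long-acting / stronger narcotics | [80, ∞) |

and the class letter concatenated with the IPA digit is the DIPA rating:
a patient on occasional Norco 5 mg with tolerable pain is a **C1**. Per
period, the **provider efficiency score** is the percentage of surveyed
patients with IPA ≤ 1, and the percent-on-narcotics is the share of visits
in classes C–E. The narcotic class cutoffs can also be re-derived from
observed MME data by hierarchical (Ward) clustering followed by K-means,
taking each cluster's observed extremes as cutoff points, and the package
ships the scale's nonparametric validation battery (Shapiro–Wilk,
Kruskal–Wallis, Mann–Whitney with exact small-sample enumeration, Spearman
rank correlation).

Intended users: orthopedic/pain researchers and clinic analysts who want to
score registry-style prescription exports, and methodologists who want a
reproducible, seeded synthetic cohort to exercise the full pipeline.

## Worked example

```r
library(dipa)

# one patient: Norco 5 mg (hydrocodone) three times daily as needed,
# reporting tolerable pain
tab <- load_conversion_table()
rx  <- tibble::tibble(drug = "Norco", strength_mg = 5, doses_per_day = 3,
                      usage = "occasional", is_otc = FALSE)
mme <- compute_daily_mme(rx, tab)
mme
#> [1] 15
cl <- classify_visit(mme, has_any_medication = TRUE, has_opioid = TRUE)
make_dipa_rating(cl, ipa = 1)
#> [1] "C1"
```

15 MME/day falls in (0, 30], so the visit is class C, and with tolerable
pain the DIPA rating is C1.

A full cohort run on the packaged synthetic default (502 patients, four
periods, seed 20231109):

```r
cohort <- generate_cohort(seed = 20231109)
dipa_report(cohort)
#> DIPA longitudinal report (2008 visits, table v1)
#>
#>  period   n efficiency on_narcotics mean_MME
#>     2wk 502     64.34%       64.54%    22.89
#>     6wk 502     82.87%       53.59%    18.06
#>     3mo 502     74.10%       41.83%    14.17
#>     6mo 502     58.96%       34.26%    12.40
```

Efficiency peaks at six weeks and dips at two weeks (patients discharged
with too few pills) and six months, while the share of patients on
narcotics roughly halves from two weeks to six months — the longitudinal
signature the DIPA graph is designed to surface. `render_dipa_graph()`
draws that figure (stacked class shares, efficiency line, mean-MME trace);
`render_class_boxplot()` draws the per-class MME box plot; and
`validate_cohort()` runs the statistical battery, e.g. the Kruskal–Wallis
separation of classes C/D/E and the Mann–Whitney decline in narcotic use
both reject at p < 0.001 on the default cohort.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/scripts/dipa simulate --out cohort.csv --seed 7
Rscript inst/scripts/dipa score    --cohort cohort.csv
Rscript inst/scripts/dipa report   --cohort cohort.csv --out report.json --graph dipa.png
```

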