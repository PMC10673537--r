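---
title: "Methods: the DIPA scale, its synthetic cohort, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the DIPA scale, its synthetic cohort, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dipa)
```

## The scale

The DIPA scale answers two questions per clinic visit: *what is the patient
taking?* and *how do they feel on it?* The first is standardized as a daily
morphine milligram equivalent (MME) — the sum over opioid prescriptions of
`strength_mg × doses_per_day × factor`, with factors from a versioned oral
conversion table — and discretized into five medication classes:

* **A** — no pain medication (0 MME),
* **B** — over-the-counter analgesics only (0 MME),
* **C** — occasional short-acting narcotics, (0, 30] MME/day,
* **D** — consistent short-acting narcotics, (30, 80) MME/day,
* **E** — long-acting or stronger narcotics, [80, ∞) MME/day.

The second is the three-level IPA report (0 no pain, 1 tolerable,
2 intolerable). The rating concatenates both (`"C1"`). Per post-operative
period (2 weeks, 6 weeks, 3 months, 6 months) the provider **efficiency
score** is `100 × #{IPA ≤ 1} / n`, i.e. the percentage of surveyed patients
whose pain is adequately managed; it equals 100 minus the intolerable-pain
percentage, an identity the tests exercise.

### Boundary conventions

Published descriptions of the narcotic classes use integer cutoffs
(1–30, 31–79, 80+) while observed class ranges leave gaps (e.g. nothing
between 30 and 33.75). To classify *every* positive dose unambiguously the
operational classifier uses contiguous half-open intervals **C = (0, 30],
D = (30, 80), E = [80, ∞)**: this agrees with every printed integer cutoff,
covers the real line, and makes classification monotone in MME. A and B are
both 0 MME and are distinguished by medication presence, which is why
`classify_visit()` takes a `has_any_medication` flag rather than the dose
alone.

Class C is *described* as occasional use and D as consistent use, but the
classifier is MME-driven: a patient at 25 MME/day taken consistently is
class C with a `usage_mismatch` annotation (`flag_usage_mismatch()`), not
silently promoted to D. The usage pattern is therefore descriptive
metadata, never an input to the class decision.

### The conversion table

The packaged table (`mme_conversion_v1.csv`) transcribes the CDC oral-MME
factor set: morphine 1 (the unit's definition, enforced at load time),
hydrocodone 1, oxycodone 1.5, codeine 0.15, tramadol 0.1, hydromorphone 4,
oxymorphone 3, tapentadol 0.4, a single documented row for transdermal
fentanyl (2.4 per µg/h), and tiered methadone factors (4/8/10/12 per the
20/40/60 mg/day tiers) selected by the drug's *total* daily mg across all
of its records. Brand names (Norco, Percocet, OxyContin, Dilaudid, …)
resolve through a synonym column; combination products enter only the
opioid component's mg. Common OTC analgesics are present with factor 0 so
that brand-name OTC entries resolve instead of erroring. The table version
(from the `_v1` file-name suffix) is propagated into every report so scored
cohorts are traceable to the factor set used.

## Cluster-derived boundaries

`derive_boundaries()` reproduces the two-stage derivation of the class
cutoffs from observed narcotic MMEs:

1. **Hierarchical step** — Ward linkage (`ward.D2`) on Euclidean distances
   proposes the number of classes; in `k = "auto"` mode k ∈ 2..6 is chosen
   by maximum average silhouette width.
2. **K-means step** — seeded K-means with 10 restarts fixes centers and
   assignments; clusters are relabeled in ascending center order.
3. Each cluster's observed minimum and maximum become the cutoff points,
   mirroring the "highest and lowest extreme values" convention; with
   k ≥ 3 the two lowest clusters' ranges become the C and D intervals and
   the top cluster's minimum becomes the E threshold.

The original derivation was run in SPSS whose exact settings are not
public; Ward/Euclidean, 10 restarts, silhouette-based k and a fixed default
seed (1976) are this package's committed choices for reproducibility, and
raw per-cluster extremes are used without any outlier trimming. In one
dimension K-means clusters are contiguous intervals, so derived boundaries
are always ordered and disjoint. Determinism: the seed is applied in a
scope that restores the caller's RNG state, and permuting the input order
does not change centers or boundaries.

## The statistical battery

All tests are two-sided (sidedness is never stated in the scale's
validation; two-sided is the conservative default).

* **Shapiro–Wilk** (`stats::shapiro.test`) checks per-class MME normality.
* **Kruskal–Wallis** (`stats::kruskal.test`, tie-corrected H, chi-square
  reference) tests C/D/E separation.
* **Mann–Whitney U** is implemented in the package: for groups of at most
  8 the two-sided p is computed by *exact enumeration* of all C(n₁+n₂, n₁)
  assignments of the pooled observations (a permutation test on U, so ties
  are exact as well; p = 2·min(tails), capped at 1 — the "distance from the
  null mean" formulation degenerates when n₁n₂ is odd); larger groups use
  the normal approximation with tie and continuity corrections. The exact
  branch doubles as the oracle for the approximation in the tests, and is
  cross-checked against `stats::wilcox.test` on tie-free data.
* **Spearman ρ** (`stats::cor.test`, t approximation — the AS 89 exact
  method is unreliable under ties) with class letters mapped to ordinals
  A=0..E=4. Because "ρ" for ordinal data could equally be Kendall's τ,
  `verbose = TRUE` reports τ alongside.
* The gender-vs-pain-tolerability comparison has no named test in the
  scale's validation; consistent with the rest of the toolkit it defaults
  to Mann–Whitney on IPA by gender, with a 2×3 chi-square alternative
  behind `gender_test = "chisq"`.

Type-I calibration of the whole battery is asserted in the tests: at
α = 0.05 each test rejects in 5% ± 1.5 points of 2000 null replicates
(group sizes 25–30, where the Mann–Whitney normal branch applies; at very
small n its discrete exact p makes the nominal level unattainable by
construction).

## The synthetic cohort generator

`default_cohort_config()` encodes the study conditions: n = 502 patients,
225/502 male, ages truncated-normal 50 ± 16 on [18, 87], procedures
210/138/154 fracture/spine/joint, all four periods attended. Per period the
satisfaction probabilities are 0.625 / 0.805 / 0.7565 / 0.609 and the
narcotic share declines from 0.652 (2 wk) to 0.326 (6 mo); the interior
shares are linearly interpolated between those endpoints — an invented
default, as are the C/D/E mix among narcotic users (0.60/0.25/0.15,
reflecting that occasional short-acting use dominates after orthopedic
surgery), the OTC share among non-narcotic visits (0.5) and the IPA 0-vs-1
split among satisfied patients (0.5). None of these three splits is
identified by the published marginals, so they are explicit config fields
rather than hidden constants.

Per-class daily MMEs are drawn from normals truncated to the published
class ranges (C: mean 16.34 on [2.3, 30]; D: 45.39 on [33.75, 67.5];
E: 94.09 on [80, 135]) by inverse-CDF sampling. The "±" figures printed
next to those class means are treated as standard errors, not SDs (an SD
of 0.08 is incompatible with a 2.3–30 range); the generator instead sets
each SD so ~99% of the untruncated mass lies within the range
(SD = min(mean − lo, hi − mean)/z₀.₉₉₅ ≈ 5.3 / 4.5 / 5.5).

Each medicated visit is then **back-filled** with a concrete prescription:
a drug drawn from the class's set (C: codeine, tramadol, hydrocodone 5 mg,
oxycodone 5 mg; D: hydrocodone or oxycodone 10 mg; E: hydromorphone,
morphine, OxyContin) at a standard unit strength, with `doses_per_day`
solved from the sampled MME. Re-deriving MME and class from the
prescriptions therefore reproduces the sampled class for every visit — a
round-trip invariant the tests assert at 100%. Methadone is supported by
the MME engine but not used for back-filling: its tiered factors make most
target MMEs unreachable at standard strengths.

What the generator does *not* emulate: within-patient dose tapering
(period marginals are independent across visits), class-conditional
satisfaction (independent by default; a conditional table can be supplied),
pre-operative chronic opioid use, and real registry artifacts (overlapping
fills, missing records). Consequently, passing pipeline tests show the
*scoring machinery* is correct under the published marginals, not that the
generator reproduces individual-level clinical trajectories. Two visible
consequences: per-class MMEs are near-normal within their ranges (the real
cohort was non-normal, which is what motivated the nonparametric battery),
and the class-vs-MME and frequency-vs-MME Spearman correlations come out
higher (~0.93) than the clinically observed 0.721/0.661, because back-filled
dosing is deterministic in MME.

## Numerical and design choices

* Daily MME is kept at full precision internally; reports print 2 decimals.
* Truncated-normal sampling is inverse-CDF (exact, vectorized, seed-stable).
* Seeds: every stochastic entry point takes a `seed` argument, applied in
  a scope that preserves the caller's RNG state; clustering defaults to
  seed 1976, and the packaged demo cohort uses seed 20231109.
* Problem sizes in the tests (200 draws/class for cluster recovery, the
  full 502-patient cohort for pipeline checks, 2000 replicates for
  calibration) keep Monte-Carlo error well below the asserted tolerances:
  3 standard errors for recovered centers, ±4 percentage points (≈1.9
  binomial SEs at n = 502) for period marginals, ±1.5 points (≈3 binomial
  SEs) for rejection rates.
* Missing IPA responses drop out of the efficiency denominator (surveyed
  patients only); they still count in class distributions.
* Figure 2's mean-MME trace is ambiguous about its denominator, so both an
  all-visits mean (A/B zeros included; the default trace) and a
  narcotics-only mean are computed and labeled.
* Periods are canonical labels (`2wk`, `6wk`, `3mo`, `6mo`); when raw
  dates are used upstream, the documented windows are 10–21, 35–56,
  75–105 and 160–200 days post-op.
* Whether the original 502 participants were followed longitudinally or
  surveyed cross-sectionally is ambiguous; the generator supports both
  (`cross_sectional`), defaulting to longitudinal (every patient at every
  period), plus an optional attrition rate.
* The command-line front end (`inst/scripts/dipa`) is a thin wrapper over
  the exported functions; the functions themselves are the stable API.

## Known limitations

* The operational C/D boundary at exactly 30 MME is inclusive-C by
  convention; data observed *between* published class ranges (e.g. 31 MME)
  are classified by the contiguous scheme, not flagged.
* Exact Mann–Whitney enumeration is limited to 8 per group
  (C(16,8) = 12 870 assignments); beyond that the corrected normal
  approximation is used, which the tests show agrees to |Δp| ≤ 0.02 at the
  branch point.
* The conversion table covers the drugs of the orthopedic post-operative
  formulary plus common OTC analgesics; unlisted opioids fail loudly
  rather than silently contributing 0.
* No multiple-testing correction is applied in the battery (none is used
  in the scale's validation); interpret the report's p-values accordingly.
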