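---
title: "Auditing ethnicity coding against a census gold standard: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing ethnicity coding against a census gold standard: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethnoconcord)
```

## The problem

Episodic health-administrative sources — primary-care extracts (GDPPR, with
its GP-Journal clinical-code table and GP-Patient fixed-field table),
hospital episodes (HES, split into admitted care, emergency care and
outpatients), talking-therapies returns (TT, organised by supplier and
reporting year) and single-record assets (ECIA) — record a patient's ethnic
category many times, inconsistently, and often as a missing-data code. A
census, in contrast, records one self-reported category per person and is
the closest available gold standard. Auditing the health sources therefore
requires four steps, each of which this package implements as a tested,
reusable operation:

1. **harmonise** the sources' differing category systems onto a common
   comparison scheme;
2. **derive** one category per person per source from their episodic
   records, under explicit recency or modal rules with deterministic
   tie-breaking;
3. optionally **reallocate** missing-data and over-coded derivations using
   the person's wider record history; and
4. **crosstabulate** against the census and summarise concordance as
   agreement, sensitivity and positive predictive value (PPV), with
   statistical disclosure control (SDC) for publication.

Because the real linked data are confidential, the package ships a
synthetic linked-data generator with *known* misclassification structure,
so every stage can be validated end-to-end against closed-form expectations.

## Category systems and harmonisation

Three vocabularies are packaged, with codes as stable machine tokens and
display labels kept separate (three different wordings exist across
sources; labels must never be join keys):

* `census21_19` — 19 substantive census categories, including Roma;
* `nhs_18` — the 18-category system used by GDPPR and ECIA (no Roma);
* `nhs_16` — the 16-category system used by HES and TT, which additionally
  lacks Gypsy or Irish Traveller and Arab.

Every substantive health-source code aligns to exactly one census
category; Roma is explicitly declared to have no health-source counterpart
(the sentinel `NONE` in the shipped mapping, surfacing as an absent
harmonised code). Five special codes (`NOT_STATED`, `NOT_KNOWN`,
`UNRESOLVED`, `DATA_NOT_RECORDED`, `VALUE_OUTSIDE_NATIONAL_CODE`) never
align to a substantive category. A total map collapses the 18 harmonised
categories onto the 5 broad groups (White, Mixed, Asian, Black, Other);
Chinese collapses under Asian, following the census-2021 alignment, even
though health-source raw layouts still file it under "Other". Cardinalities
and mapping totality are asserted at load time, and users may override any
vocabulary with their own CSV validated against the same invariants.

GP-Journal rows carry clinical codes rather than category codes. The
packaged lookup (`load_code_lookup()`) is a small synthetic illustration —
the codes are invented — because real clinical terminologies are licensed
and irrelevant to the pipeline's logic; deployments supply their own table.
Unknown codes are an error, never silently dropped.

## Derivation rules

All rules operate on date-only records: the tie-breaking hierarchy exists
precisely because no finer-than-daily resolution is available. Whenever a
rule chain cannot select a unique category, the person is `UNRESOLVED`.

* **GDPPR recency** — take the single latest date across both tables; if
  that date carries conflicting categories, the GP-Journal recording wins;
  a conflict persisting within the winning table is `UNRESOLVED`. The
  priority applies only *on* the latest date: an older journal record never
  outranks a newer patient record.
* **GDPPR modal** — the most frequent category within GP-Journal; only a
  person with *no* journal recording at all falls back to the most
  frequent GP-Patient category (table-level, not record-level, fallback —
  pooled counting would contradict the two-stage rule). Occurrences of the
  *resolved* category are counted, so two different clinical codes mapping
  to one category reinforce it. A tie for the maximum is `UNRESOLVED`.
* **HES recency** — latest date; same-date conflicts resolved in the order
  admitted care, emergency care, outpatients; remaining same-date
  same-sub-dataset conflicts are `UNRESOLVED`.
* **HES modal** — most frequent category pooled across sub-datasets with no
  priority; ties are `UNRESOLVED`.
* **TT recency** — restrict to the most recent reporting year, then to the
  latest record date within it (thereby selecting the most recent
  supplier); if the records at that date disagree, `UNRESOLVED`; if they
  agree — even across suppliers — that category is returned, which is
  forced by the unanimity invariant (a person whose records all carry one
  category must receive it under every method). `DATA_NOT_RECORDED` and
  `VALUE_OUTSIDE_NATIONAL_CODE` are treated as `NOT_KNOWN` throughout. The
  extract structure that motivates this rule also rules out a modal
  definition for TT.
* **ECIA** — one record per person by construction; it is returned as-is
  and a second record is an error.

Missing-data codes are ordinary candidates during derivation — they can win
a recency or modal contest — and are only treated specially later, by
reallocation and by the metrics.

Every rule is implemented twice in this project: vectorised (data.table
grouping, used by the package) and as a brute-force single-person oracle
(plain sorting and counting, in the test suite). The suite requires exact
agreement on 10,000 randomly generated collision-heavy record sets per
rule, drawn from a deliberately tiny alphabet of categories, dates,
sub-sources, years and suppliers so that every tie and priority path is
exercised many times.

## The reallocation cascade

Three cumulative levels replace a derivation when the derived code is
"reallocatable" and an alternative exists anywhere in the person's history,
however old or infrequent:

| level | reallocatable codes |
|---|---|
| `l1` | Not Known |
| `l2` | Not Known, Any Other Ethnic Group |
| `l3` | Not Known, Any Other Ethnic Group, Not Stated |

Each level is applied to the *un-reallocated* derivation (the levels differ
in their trigger sets, they are not chained), `UNRESOLVED` is never a
trigger, and ECIA — single-record by construction — is never reallocated.
"An alternative is available" is operationalised as: delete every history
record carrying a reallocatable code and re-run the same derivation method
on the remainder. A tie in that re-derivation yields `UNRESOLVED`, and that
outcome stands — no secondary tie rule exists. If nothing remains, the
destination rules apply: at `l2`/`l3` a history containing Any Other Ethnic
Group receives `ANY_OTHER`; otherwise the original derivation is retained
(in particular, a person recorded only ever as Not Known keeps Not Known).

Two consequences of the retention rule are worth stating because they are
easy to mis-assume. First, monotonicity: the Not Known head-count is
provably non-increasing from no reallocation through `l1` to `l2`, and the
`l3` count never exceeds the un-reallocated count — but `l3` can exceed
`l2`, because a person with history {Not Known, Not Stated} is rescued into
Not Stated at `l1`/`l2` and falls back to a retained Not Known at `l3`,
where Not Stated joins the removal set and no destination is named. Second,
nestedness holds in trigger form: a person whose derivation is not
reallocatable at `l3` is untouched at every level; a *triggered* person may
change at `l1` yet be retained at `l3`. The tests assert exactly these
provable forms, alongside idempotence (reallocating an already-reallocated
table is a no-op) and a six-person hand-worked fixture covering both
footnote destinations.

## Concordance metrics

The crosstab rows are census categories (Roma keeps its own row even
though no source can match it) and the columns are the source's categories
aligned to the census scheme. Persons derived as Not Stated, Not Known or
Unresolved are excluded from the table — no census equivalent exists — and
tallied separately; persons absent from a source are excluded from that
source's audit entirely, so each source is compared on its own linked
population.

With counts $n_{ck}$ (census category $c$, source category $k$):

* per-category agreement$(k) = 100\, n_{kk} / n_{\cdot k}$ (source-side
  denominator) — identical to PPV by construction;
* sensitivity$(k) = 100\, n_{kk} / n_{k \cdot}$ (census-side denominator);
* overall agreement $= 100 \sum_k n_{kk} / n_{\cdot\cdot}$.

Zero denominators give `NA`, never 0 — a zero would masquerade as measured
disagreement — and categories absent from a source's vocabulary (Arab and
Gypsy or Irish Traveller for HES/TT; Roma everywhere) yield no entry at
all. Collapsing to 5 categories cannot break a concordant pair, so overall
agreement at 5 categories is never below overall agreement at 18; the suite
asserts this on every fixture. Two population restrictions mirror the
published sensitivity analyses: a back-series start date filter and a
complete-case restriction to persons with substantive categories in both
episodic sources and the census.

## Statistical disclosure control

Cell counts below 10 are suppressed; counts of 10 or above are rounded to
the nearest 5 (no integer is equidistant between two multiples of 5, so the
rule never ties and distorts any published cell by at most 2); zeros pass
through. The rule is idempotent. Published-style percentages are computed
from the rounded and suppressed values with suppressed cells contributing
zero to numerators and denominators — the only computation possible without
the raw value; raw-count metrics remain available for research use, and the
pre-SDC counts are retained in the object (never serialised) so distortion
is testable. Marginals are rounded independently of cells, matching common
publication practice. On tables whose cells are all at least 200, SDC moves
overall agreement by well under one percentage point.

## The synthetic generator

`simulation_spec()` describes a linked population: a census category
distribution; per source, a census-row confusion matrix over recorded
categories (including Not Stated / Not Known mass), a records-per-person
distribution (mass at zero makes a person absent from that source), and
sub-source assignment probabilities; a within-person consistency
probability $\rho$ (each record after the first repeats the person's first
recorded category with probability $\rho$, else re-draws); a date range
over which record dates are uniform (the derivation rules depend only on
date order, not spacing); and a mandatory seed. Dates, suppliers and
reporting years are drawn consistently for TT; GP-Journal rows are emitted
as clinical codes through the synthetic lookup.

Three presets define the study conditions:

* **clean** — identity confusion, no missingness, full coverage, $\rho = 1$,
  over the 16 categories common to all vocabularies: the identity limit in
  which every defined agreement, sensitivity and PPV must be exactly 100%
  at every source, method, reallocation level and resolution.
* **paper_like** (default 100,000 persons) — census-2021-like population
  shares; accuracies high for White British (0.96) and the South Asian
  categories, low for Mixed/Other, very low for Gypsy or Irish Traveller
  (0.05) and Other Black (0.15); misrecorded mass preferentially lands
  within the same 5-category group, with a share routed to Any Other Ethnic
  Group to emulate its over-coding; missingness heavy in HES (12% Not
  Stated, 10% Not Known) and light in GDPPR; TT small (70% absent). These
  are qualitative shapes, deliberately *not* calibrated to reproduce any
  published figure — those depend on confidential linked records.
* **adversarial** — four categories, 31 days of dates, up to six records
  per person, $\rho = 0.2$, high missing-data mass: a stress test that
  drives every Unresolved path and makes reallocation genuinely active.

With $\rho = 1$ every person's history is unanimous, so each derivation
method returns the person's single confusion draw and closed forms exist
(`expected_metrics()`): sensitivity of category $k$ is
$C_{kk} / \sum_{j \in S} C_{kj}$ renormalised over substantive outcomes
$S$, and PPV follows from Bayes' rule,
$\pi_k C_{kk} / \sum_r \pi_r C_{rk}$. The headline validation property is
parameter recovery: generate at $n = 100{,}000$, derive by recency, build
the crosstabs, and compare every per-category empirical sensitivity and PPV
with its closed form.

### Calibration of the recovery check

Each comparison is a binomial proportion, so the natural unit is the
z-score $(\hat p - p)/\sqrt{p(1-p)/n}$. Roughly 136 such comparisons are
made (two metrics, four sources, up to 18 categories), and a naive
"every z within 3" rule would reject a *correct* implementation for about
30% of seeds — with 136 draws, one |z| slightly above 3 is expected
behaviour, as we verified empirically (deviations do not grow with $n$ and
move category and sign across seeds). The test therefore holds every
deviation to the Šidák family-wise threshold equivalent to a single
3-standard-error check ($z^\ast \approx 4.3$ for this family size) and
additionally bounds the mean |z| below 1 — under correct calibration the
mean is $\sqrt{2/\pi} \approx 0.80$, and a mean bound is far more sensitive
to systematic bias than any single-comparison threshold.

### What the generator does not emulate

Real linked data differ in ways the generator deliberately ignores:
linkage error (synthetic persons share one identifier across sources by
construction), category-dependent coverage (absence from a source is
independent of ethnicity here), temporal drift in recording practice,
within-person category *change* as opposed to noise, and correlated
recording across sources. Passing the identity-limit and recovery tests
therefore demonstrates that the pipeline's algebra is right, not that any
particular published figure would be reproduced.

## Numerical and design choices

* Seeds: one seeded generator drives each simulation; generation is
  vectorised rather than per-person sub-streamed (an earlier design), which
  keeps 100,000-person draws in a few seconds while retaining exact
  fixed-seed reproducibility — the tested contract. Changing `n_persons`
  reshuffles the draw.
* Problem sizes: 10,000 record sets per derivation rule for the oracle
  check; 100,000 persons for parameter recovery; 2,000 for the identity
  limit; a few hundred per trial for cascade and collapse laws. The full
  suite runs in well under a minute on one CPU.
* TT reporting years are treated as opaque ordered integers (whether they
  are calendar or financial years does not affect any rule).
* A derived table is keyed by (person, source, method, level); every
  operation is invariant to row order and duplicates are rejected.
* The SDC suppression token (`"[c]"`) is configurable at serialisation.

## Limitations

The Not Known / Not Stated destination gap at `l3` (discussed above) is
inherent to the rule set, not an implementation artefact. The shipped
census alignment follows the standard harmonisation rather than any
specific deployment's local mapping — override it where a deployment
differs. The complete-case restriction is provided for GDPPR+HES+census;
other combinations are a one-line `restrict_complete_case()` call away but
are not pre-wired into the pipeline orchestration.
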