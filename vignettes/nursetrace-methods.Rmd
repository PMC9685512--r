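---
title: "Inferring nurse-patient assignments from charting metadata: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring nurse-patient assignments from charting metadata: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nursetrace)
```

## The problem and the model

ICU nurses leave a dense trail of timestamped electronic signatures in the
EHR — on sedation scores, rhythm checks, neurological assessments, and each
medication administration. `nursetrace` treats that trail as a noisy
observation of an unobserved roster: during any 12-hour shift, exactly one
(or no) primary nurse is responsible for a patient, and that nurse should
both sign more often than anyone else and sign across most of the shift.

Two statistics summarize nurse $j$'s trail within a patient shift: the
count $c_j$ of unique charting times (a nurse can co-sign many items in one
second; only distinct seconds carry information) and the span
$w_j = t^{\max}_j - t^{\min}_j$ between the first and last signature. The
selection rule is deliberately minimal:

1. **Step 1** — pick $\arg\max_j c_j$; break a count tie by the largest
   $w_j$; if the tie survives both statistics, report *no primary nurse*.
   Resolving a residual tie any further would require randomness, which the
   algorithm refuses: a retrospective assignment method must be auditable
   and reproducible.
2. **Step 2** — repeat step 1 after deleting the step-1 primary of the
   patient's immediately preceding contiguous shift from the candidate set.
   The mechanism this guards against is real and specific: an outgoing
   nurse finishing an extensive backlog of documentation after handoff can
   out-chart the incoming nurse in the first hours of the next window.

Each patient shift receives one of six mutually exclusive outcome
categories; 1–3 (sole charter / unique max count / tie broken) carry a
nurse, 4–6 (no charter / unbroken tie / only charter was the excluded prior
primary) do not. Categories are judged on the *post-exclusion* candidate
set — "one nurse charted" means one candidate remained after the exclusion
— except category 6, which by construction describes the excluded nurse.
This makes the six classes a true partition and keeps 1–3 descriptive of
whichever comparison was actually decisive.

### Prior-shift semantics

"Prior shift" means the immediately preceding contiguous 12-hour window for
the same patient. Two consequences were genuinely open design choices:

- **Step-1 priors, unchained.** The exclusion always consults the *step-1*
  result of the prior shift, never the step-2 output. Chaining step-2
  outputs would make the exclusion self-referential along a stay and could
  cascade a single odd window through many shifts.
- **Gaps reset.** After an ICU discharge and readmission, no exclusion
  applies: the late-charting mechanism is only plausible across adjacent
  windows. A nurse can legitimately be the primary before and after a
  multi-day gap.

One documented corner case follows from the rule as written: a patient
whose only charter across three consecutive windows is the same nurse gets
that nurse in window 1 and *no* nurse (category 6) in windows 2 and 3,
because the step-1 prior in every window is that nurse. This is the
faithful reading of an unconditional exclusion; real rosters rarely assign
the same nurse back-to-back-to-back, which is exactly why the exclusion
exists.

## Time handling

All timestamps are naive wall-clock datetimes, carried internally as
POSIXct pinned to UTC, floored to whole seconds. Shift boundaries are
wall-clock anchors (07:00:00 / 19:00:00), implemented as half-open windows
`[07:00, 19:00)` and `[19:00, 07:00 next day)` — identical to the inclusive
"…:59:59" phrasing at second resolution and unambiguous at finer
resolution. Night shifts are labelled by their start date, so 00:00–06:59:59
belongs to the previous date's night shift.

Because the representation is zone-free there is no daylight-saving
arithmetic anywhere: every window is exactly 12 wall-clock hours, which is
how charting timestamps read on the chart. A deployment feeding zoned
timestamps should render them to local wall-clock text before ingestion.

Events are attached to whichever enumerated patient shift's window contains
them, and are *not* clipped to the ICU-stay interval: charting stamped
minutes before the recorded ICU admission or after discharge, inside an
enumerated window, stays visible. Observed misclassification causes
(operating-room or floor nurses being picked up around transfers) imply the
original data behaved this way, and silently clipping would change the
algorithm's behavior on precisely the hard cases. Assessment and medication
signatures are pooled with equal weight; the two sources are distinguished
in the data model but nothing in the selection rule weighs them.

Overlapping ICU stays for one patient (common around in-hospital transfers)
are retained with a warning; patient-shift enumeration unions their
windows, and the overlap duration is measured against the union so nothing
is double-counted.

## Validation machinery

Against chart-review labels, a reviewed shift is TP (algorithm and review
name the same nurse), FP (algorithm names a nurse; review names a different
one or none), FN (algorithm says none; review identifies a nurse — including
nurses found in record elements the algorithm cannot see), or TN (both say
none). Accuracy $(TP+TN)/n$ and precision $TP/(TP+FP)$ are reported with
exact two-sided 95% Clopper–Pearson intervals, computed by the beta-quantile
identity

$$\mathrm{low} = B^{-1}(\alpha/2;\, x,\, n-x+1), \qquad
  \mathrm{high} = B^{-1}(1-\alpha/2;\, x+1,\, n-x),$$

with the boundary conventions $\mathrm{low}=0$ at $x=0$ and
$\mathrm{high}=1$ at $x=n$. The test suite verifies this against an
independent bisection inversion of the binomial tail sums to $10^{-9}$ for
every $(x, n)$ with $n \le 500$.

Review samples are stratified by the six categories with largest-remainder
quotas: floor each exact quota $n \cdot \mathrm{share}_k$, then hand out
the remaining units by largest fractional remainder (ties to the lower
category number), so quotas always sum to the requested $n$. The published
validation design sampled 200 shifts this way. A useful arithmetic fact:
whenever $n$ does not exceed the table size, a category's quota can never
exceed its population (it is bounded by $\lceil c_k \, n/N \rceil \le c_k$),
so the "category smaller than its quota" error can only fire on
over-sized requests.

## The synthetic world

The simulator exists because no real charting metadata can ship with the
package. It states a world and stays there:

| parameter | default | meaning |
|---|---|---|
| `los_meanlog`, `los_sdlog` | `log(36)`, `1.2` | log-normal ICU length of stay in hours: median 36 h, long right tail, and a realistic trickle (~1%) of sub-2-hour boundary stays |
| `assessment_rate` | 2 /h | primary nurse's assessment signatures, a Poisson process over window ∩ stay |
| `medication_rate` | 1 /h | medication signatures, pooled with assessments |
| `p_cross_coverage`, `lambda_cross` | 0.10, 2 | a second nurse charts a small Poisson count inside one half-hour — low count, short interval, distinguishable by both input variables |
| `p_late_charting`, `lambda_late` | 0.05, 3 | the outgoing primary signs into the first hour of the next window — the exact mechanism step 2 exists for |
| `p_orientee` | 0.02 | an orientee co-signs at exactly the primary's times, producing an unbreakable count-and-interval tie |
| `p_no_documentation`, `boundary_hours` | 0.5, 1 | a shift overlapping the stay by under an hour has its documentation suppressed — the dominant real-world cause of "no nurse" shifts |

Rates are stated assumptions, not estimates: the source study reports no
distributional facts about charting frequency, so the defaults encode what
an ICU nurse would call ordinary (an assessment roughly every half hour,
about one medication pass an hour). Scheduling honors 12-hour rostering:
the scheduled primary of adjacent shifts always differs, which is also why
a clean (contamination-free) simulation is recovered *exactly* — the
primary is the sole charter, so step 1 selects them, and the adjacent-shift
rule makes the step-2 exclusion a no-op. That derivation, not tuning, is
what the clean-recovery acceptance test asserts.

Ground truth records the scheduled primary, or *none* for shifts that end
with zero charting events — with no signatures there is no digital evidence
of any nurse, mirroring the chart-review finding that truly undocumented
short stays have no identifiable primary even manually.

Reproducibility is by a single seed feeding counter-derived substreams per
patient and per patient shift, so regeneration is independent of loop
order. Within a shift the scenario-decision uniforms are drawn first in a
fixed order and the orientee injection last; under a common seed the set of
shifts where a scenario fires therefore grows monotonically with its
probability, which the recovery-monotonicity property test relies on.

What the simulator does **not** emulate: real charting-frequency
distributions, per-unit documentation culture, irregular (8- or 16-hour)
shifts, emergent multi-nurse events, or the source study's category shares
— those are dataset-specific. A green simulation test therefore establishes
algorithmic correctness (the rule computes what it claims on a known
world), not clinical performance; the published 93% accuracy / 94.4%
precision came from chart review of real data, and this package reproduces
those numbers only as arithmetic on the published confusion matrix.

## Numerical and degenerate-input choices

- Interval ties compare at second resolution; equal spans are a true tie.
- An empty event table is valid input: every patient shift is category 4.
- An empty candidate set after exclusion with a non-empty pre-exclusion set
  is category 6; with an empty pre-exclusion set, category 4.
- `precision()` on a table with zero positive calls is an error, not NaN.
- Stays must satisfy `icu_in < icu_out` strictly; zero-length stays are
  rejected at read time.
- Duplicate event rows are kept by the reader and collapsed by
  `attach_events()`; dedup is a documented algorithm step, so round-trips
  through files are lossless.

## Known limitations

The algorithm sees only assessment and medication signatures; nurses
documented elsewhere (transfer forms, pain reassessments, post-mortem
care) are invisible, which in validation surfaces as false negatives. The
exclusion rule deliberately sacrifices genuine back-to-back assignments
(rare under 12-hour rostering) to suppress late charting. And synthetic
recovery rates are statements about the simulator's world, not estimates of
performance on any hospital's data.
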