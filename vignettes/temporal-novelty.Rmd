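---
title: "Temporal novelty scoring for target-disease associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal novelty scoring for target-disease associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdnovelty)
```

## The problem

Roughly one in five newly approved drugs acts through a human target that no
previous drug had exploited. Spotting such targets early requires watching
how the evidence linking a gene to a disease accumulates over time, not just
how much of it exists today. `tdnovelty` reconstructs that history from
timestamped evidence records -- one scored row per GWAS hit, publication,
clinical trial, animal-model phenotype, and so on, in the layout popularized
by the Open Targets Platform -- and quantifies the moments when the evidence
base visibly strengthened.

## The scoring model

Every piece of evidence carries a confidence score $s \in (0,1]$ assigned by
its source. For one association and one source, the **source association
score** is the normalized harmonic sum of the evidence scores: with the
scores sorted in descending order and truncated to the top $c = 1000$,

$$A = \frac{1}{H_c}\sum_{i} \frac{s_{(i)}}{i^{2}}, \qquad
  H_c = \sum_{i=1}^{c} \frac{1}{i^{2}} \approx 1.644 .$$

The rank-squared damping rewards repetition with rapidly diminishing
returns, and dividing by $H_c$ -- the sum attained by a vector of $c$ ones,
within $10^{-3}$ of $\pi^2/6$ -- maps the result onto $[0,1]$. The
**overall association score** applies the same kernel a second time to the
vector of per-source scores, each multiplied by a source weight
(`source_weights()`; uniform 1 by default, since production weighting
schemes are deployment-specific and configurable here per source).
`harmonic_norm_constant()` is always recomputed from the cap rather than
hard-coded, so a non-default cap stays self-consistent. Equal scores tie in
the descending sort, but the sum is invariant to their order, so no
tie-break rule is needed.

## From static scores to temporal profiles

Each record is first resolved to a single calendar year
(`resolve_timestamps()`): trial start years for clinical evidence, curation
submission years for expert-curated genetic sources (they mark when the
resource became aware of the finding), project release years for pathway
evidence, and the primary publication year otherwise. Dates are handled at
year granularity throughout, matching the annual recalculation grid;
sub-year precision would add nothing to a metric whose decay constant is
measured in years. Records with no usable year are counted and excluded --
never imputed.

`yearly_source_scores()` then recomputes the association score for every
grid year using only evidence resolved to that year or earlier. The grid
starts in 1995 by default; evidence older than the grid contributes from the
first grid year onward, which censors (rather than invents) its true onset.

## The novelty metric

A year-over-year increase of a cumulative score is a **shift** of magnitude
$S$. Novelty at year $t$ is a logistic decay applied to the shifts seen so
far:

$$N(t) = \max_{t_0 \le t}\; \frac{S(t_0)}{1 + e^{\,k\,(W - m)}},
  \qquad W = t - t_0,$$

with steepness $k = 2$ and midpoint $m = 3$ years. A fresh shift ($W = 0$)
keeps essentially its magnitude, the value halves exactly at $W = m$, and by
$W = 6$ it is below $0.0025\,S$ -- zero at the two-decimal display
precision used in reports (`display_novelty()`, half-even rounding). The
maximum is taken over *all* registered shifts, not only consecutive-year
ones: with the default decay any shift older than about six years
contributes negligibly, so this generalization is harmless and simpler to
reason about. Because cumulative scores never decrease, $S > 0$ always, and
novelty is never negative; no floor truncation is applied since the
logistic never reaches zero.

Each shift year is reported as a **peak** (`detect_peaks()`) whose value is
the novelty at that year. Peaks below the cutoff (0.1 by default) are kept
but flagged sub-threshold; the cutoff separates signals worth ranking from
background trickle. Shifts at the very first grid year are flagged
`grid_start` and excluded from peak reports by default -- they reflect
left-censoring, not dated novelty -- with a flag to include them. The
overall novelty series mirrors the overall score: a weighted harmonic sum
of the per-source novelty values.

## A worked example

The association between TSLP and asthma illustrates the machinery. Its GWAS
source score was 0 until a 2011 genome-wide study raised it to 0.53, and
additional genetic evidence lifted it to 0.70 in 2017
(`tslp_reference_series()` stores this published history):

```{r}
ref <- tslp_reference_series()
peaks <- detect_peaks(novelty_series(ref))
transform(peaks[c("year", "value")], display = display_novelty(value))
```

The 2017 peak displays as 0.17: by then the 2011 shift has decayed to
0.0013, so the fresh 0.17 shift dominates the maximum. The 2011 peak
evaluates to 0.5287, which displays as 0.53; the published account of this
example rounds it to 0.52, a one-ulp display difference whose origin
(truncation, or a slightly different underlying 2011 score) is not
documented -- the package follows the formula literally and notes the
discrepancy here rather than special-casing it.

The seven printed evidence records for this pair ship as both a fixture
file (`inst/extdata/tslp_asthma_evidence.tsv`) and a constructor
(`tslp_fixture()`). The fixture deliberately separates the printed
*evidence* scores from the printed *source-score* anchors: the production
corpus holds more evidence for this pair than the examples printed with it,
so the anchors are not derivable from the seven records (a single 0.70
evidence normalizes to 0.43, not 0.53) and are stored as reference display
values only.

## Retrospective analysis against drug approvals

For targets of approved drugs, `top_peak_per_category()` selects the
highest peak per association and evidence category (earliest year on
ties), and `approval_deltas()` computes
`first_approval_year - top_peak_year`: positive when supporting evidence
peaked before the approval. Matching is restricted to the approval's own
indication -- no ontology expansion, hence a conservative notion of direct
support. "First approval" is per target, the earliest across its drugs.
Clinical development itself is handled separately
(`clinical_phase_deltas()`) from the earliest phase I/II and phase III
trial years, since trial-driven peaks track the regulatory pathway rather
than independent biomedical support. `yearly_novelty_counts()` assigns each
association to the year of its top above-cutoff peak per category and each
target to the earliest such year among its associations (which guarantees
the per-year target count never exceeds the association count), optionally
dropping non-disease therapeutic areas (phenotypes, measurements, biological
processes, animal diseases, medical procedures) when a disease-to-area map
is supplied. Whether the cutoff should apply to this cohort selection is
genuinely open; the functions expose it as a parameter and default to 0.1
for consistency with the counting analysis.

## The synthetic corpus generator

`generate_corpus()` emulates per-source yearly evidence arrival: for every
(target, disease, source, year) cell a Poisson number of records at the
configured rate, each scored from a Beta distribution truncated into
$(0,1]$ (defaults shape 2, 5 -- right-skewed like the bulk of
low-confidence literature evidence). These are the minimal standard choices
for count arrivals and bounded scores, and every parameter is configurable
per source. Generation is a pure function of the configuration including
its seed, and restores the caller's RNG state. Scores are rounded to six
decimals so corpora survive text serialization exactly.

What the generator does *not* emulate: real per-source score distributions
(ChEMBL's phase-dependent scoring, text-mining score inflation), correlation
between sources, evidence retraction, or ontology structure among diseases.
Tests passing on synthetic corpora therefore validate the arithmetic and
the pipeline's bookkeeping, not corpus-level claims about real biomedical
data. `inject_shift()` plants a high-scoring record at a known year; the
planted year must come back as the association's top peak, which is the
package's end-to-end correctness probe.

## Numerical choices and test scale

Internal computation is double precision throughout; only display rounds
(half-even, two decimals). The yearly recomputation is cross-checked in the
test suite against an independent loop oracle at $10^{-12}$, and the
max-over-shifts rule against brute-force enumeration of every (shift, year)
pair. Property tests run on deliberately small corpora -- a few targets and
sources over one or two decades, 200 random corpora for the oracle
equivalence and 50 seeded injection-recovery corpora -- sizes chosen so the
whole suite completes in well under a minute while still exercising every
code path; the statistics being checked (medians, stationarity, recovery
rates) stabilize at these sizes.

## Limitations

Corpus-scale results reported for the full 28-million-record Open Targets
release (cohort percentages, per-category counts) require that corpus and
are out of scope here. Disease identifiers are treated as opaque strings;
no EFO traversal or indirect-evidence propagation is performed. The decay
kernel is fixed to the logistic form; alternative kernels would slot in at
`logistic_novelty()` but are not provided.
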