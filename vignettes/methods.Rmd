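---
title: "Methods: rule-based CSA phenotyping and its validation on synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based CSA phenotyping and its validation on synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csascreenr)
```

This vignette is the package's account of its science: the detection rules
and their assumptions, the outcome derivations, the statistical layer, what
the synthetic-data generator does and does not emulate, and the design
decisions taken where the problem was genuinely open.

## 1. The detection model

Childhood sexual abuse (CSA) is identified from free text by literal phrase
matching, not statistical NLP. The assumption is that clinicians record the
exposure in a small, fairly stereotyped vocabulary, so a curated lexicon
with explicit negation handling achieves high positive predictive value at
the cost of unknown sensitivity. The pipeline is:

1. **Normalization** (`normalize_text()`): case folding and collapsing of
   whitespace runs to single spaces, with an offset map so every match can
   be reported as a 0-based half-open span on the raw text. Nothing else is
   normalized — no stemming, no spelling correction — because the method's
   claim to auditability rests on matches being verbatim.
2. **Candidate matching** (`scan_note()`): each lexicon surface becomes a
   literal pattern anchored at non-alphanumeric boundaries (so `csa` never
   fires inside another token). The `{AGE}` slot matches a 1–2-digit
   integer or an integer range (`6-9`, `6 to 9`, including the hyphen
   variants that survive copy-pasting); range endpoints are both extracted.
3. **Precedence resolution**: candidates are placed greedily — exclusions
   and indeterminates before inclusions, longer matches before shorter,
   earlier before later — and a candidate overlapping an already-placed
   span is dropped. An inclusion inside "denied a childhood history of
   sexual abuse" is therefore blocked by the longer exclusion. Ties cannot
   arise: two candidates with identical class, length and start would be
   the same span from two identical surfaces, which lexicon validation
   forbids.
4. **Patient classification** (`classify_patient()`): a patient is
   *exposed* if any surviving include span has all extracted ages (if any)
   below the childhood cutoff; an include span with any age at or above the
   cutoff is demoted (adult abuse). With no childhood evidence but an
   indeterminate "historical sexual abuse" span, the patient is
   *removed* from the analytic cohort — the age at abuse cannot be
   confirmed, so neither exposure status is defensible. Everyone else is
   *unexposed*.

Two decisions here were open and are worth recording. First, the childhood
cutoff defaults to **18 years**, the convention of the trauma-prevalence
literature; the sources this method descends from never define "child", so
the cutoff is an explicit argument everywhere it matters. Second, evidence
aggregation across notes lets **any effective include span dominate**: a
negation in one note does not override a disclosure in another. The
alternative (most-recent-note wins) would make classification depend on
note ordering, which routine data do not reliably support.

The shipped lexicon (`default_lexicon()`) contains every phrase with a
documented role in the detection strategy plus systematic inflectional
variants (denies/denied, experience/experiences), 34 patterns in total. It
is deliberately a versioned CSV, not code: coverage beyond the documented
phrases is a lexicon-file concern, and users extending it get load-time
validation (unique ids, legal polarities, balanced age-slot braces) rather
than scan-time surprises.

## 2. Outcome derivations

**Eligibility** (`filter_cohort()`): an SMI diagnosis (ICD-10 F20–F29 or
F30–F31, checked on the 3-character category with optional 4th character),
first contact inside the 2009-01-01 – 2017-12-31 study window with at
least 365 days to the window end, and at least one HoNOS assessment.
Patients with a missing first-contact date are removed because follow-up
cannot be computed. The follow-up denominator is first contact to window
end — the only definition supported by per-patient dates alone.

**HoNOS dichotomization** (`dichotomize_honos()`): an item is flagged when
any assessment scores it at or above the threshold. The default threshold
is **3**, matching the scale's "moderately severe" anchor; 2 is also used
in routine-outcome research, so the cut is a parameter. Flags are
monotone in the threshold by construction, and the tests assert it.

**Admissions** (`derive_admission_outcomes()`): overlapping or abutting
episodes are merged, and day counting is inclusive — admission and
discharge days both count, so a same-day stay is one day and splitting an
episode into adjacent sub-episodes never changes the total. Days per year
divides by follow-up years; the above-median flag uses the median among
admitted patients only and is undefined for the never-admitted.

**Antipsychotic dosing** (`extract_medications()`): a deliberately
simplified gazetteer + dose-pattern matcher. Drug names (generic and
trade) are matched case-insensitively within sentences; a dose is
`<number> mg` with an optional frequency token (od/mane/nocte = 1, bd = 2,
tds = 3, qds = 4 administrations per day; unstated frequency defaults to
once daily — conservative and deterministic). Each dose number attaches to
the nearest drug on its left in the same sentence. The analysis quantity is
the patient's **maximum percentage of the maximum recommended daily dose**;
records above **200%** are excluded first, as dosage-entry or parsing
errors, and the exclusion-before-maximum order is fixed and tested. The
maximum-dose table is editable YAML covering eight common antipsychotics —
reference values belong in configuration, not code. Depot formulations and
dose-equivalence conversions are out of scope; an undosed mention still
counts as antipsychotic receipt. Where several drugs are mentioned,
percentages are computed per drug and the per-patient maximum is taken
across them.

**Median splits** (`dichotomize_at_median()`): the median is the empirical
50th percentile (mid-pair average for even n) and "above" is strict, so
ties sit in the lower stratum and the split is well defined even with
heavily tied data.

## 3. The statistical layer

Group comparisons use the **uncorrected Pearson chi-square** on r×2 tables
with `Unknown` categories retained as rows (differential missingness is
itself informative; a `drop_unknown` switch exists). No Yates correction is
applied anywhere — the published statistics this layer replays are only
reproducible without it — and no multiple-testing correction is applied,
matching the analysis being operationalized; both facts are stated rather
than hidden.

Odds ratios use the Woolf log-normal interval; a zero cell triggers a 0.5
continuity addition to all cells with a warning. When only rounded
percentages and group sizes are available (published-table replay), cell
counts are reconstructed as `round(p × n)` before the odds ratio is
computed (`odds_ratio_from_props()`); the discrepancy against an odds
ratio taken directly on the proportions is a rounding artifact of order
0.01 and is documented, not corrected.

Adjusted estimates come from maximum-likelihood logistic regression with
sex, age at first presentation and ethnicity as covariates; reference
levels are the largest groups (male, White). Non-convergence or separation
(|log-OR| > 10) raises an explicit diagnostic; inside the report pipeline
a separated outcome keeps its unadjusted estimate and reports the adjusted
one as missing, with a warning, rather than aborting the other outcomes.
On a saturated (exposure-only) model the logistic odds ratio reproduces
the closed-form 2×2 value, and the tests hold this to 1e-8.

Two published comorbidity chi-squares (PTSD and personality disorder)
cannot be replayed: the printed group counts do not sum to the stated
denominators, and no uncorrected Pearson statistic computed from the
printed cells reproduces the printed values. These rows are excluded from
the replay checks and flagged here instead of guessed at.

## 4. What the synthetic generator emulates

`generate_cohort()` draws, in order: true exposure (Bernoulli at the
configured prevalence, default 8.8%); demographics from whole-cohort
marginals with per-category log-odds tilts for exposed patients (the
published sources report margins, not a generative model, so conditional
structure is induced only through these configurable shifts, with
directions matching the observed differences); diagnoses, HoNOS scores and
the binary clinical outcomes from logistic models with configured exposure
log-odds-ratios (admission: baseline 0.511, log-OR 0.67; antipsychotic
receipt: baseline 0.895, log-OR 0.91 — chosen to match the observed
unadjusted odds ratios); admissions as log-normal episode lengths; and
notes.

Notes carry exactly one mention label each — `positive`, `negated`,
`uncertain`, `adult_onset`, `hearsay` or `none` — so audit ground truth is
unambiguous. Every true-CSA patient gets one guaranteed positive note
(detector sensitivity on the template bank is 1 by construction); each
further note repeats the disclosure with probability 0.15. Distractors are
drawn per non-exposed patient: negated 0.05, uncertain 0.01 (of which 20%
are the indeterminate "historical sexual abuse" phrasing that removes the
patient, calibrated so a 7000-patient cohort loses about 15 patients this
way, alongside a 15/7030 missing-first-contact rate), adult-onset 0.01,
and hearsay 0.002. Hearsay — abuse of a relative, phrased with the same
vocabulary — is the one channel a phrase lexicon cannot distinguish, and
it exists precisely so the chart-review audit (`ppv_audit()`) measures
something: without it the audit would be trivially 100%. Its rate was set
a priori for an expected PPV near 98%, reflecting a refined rule set in
which residual false positives are rare third-party mentions.

Dose sentences place per-administration amounts on each drug's tablet
grid, constrained so plausible prescriptions stay at or below 150% of the
daily maximum; a 1% data-entry error rate produces doses far above it, so
the 200% exclusion filter is exercised and *only* errors cross it —
making the excluded fraction an estimate of the error rate, which the
tests check binomially. Exposed patients are tilted toward higher grid
doses (log-scale tilt 0.4), giving the above-median dose contrast its
direction.

What the generator does **not** emulate: real clinical language (template
realism only), correlation between outcomes beyond their shared dependence
on exposure (no published joint distribution exists to copy), informative
note timing, and lexicon coverage gaps other than hearsay. Passing tests
therefore demonstrate that the rules compute what they claim on text whose
vocabulary the lexicon covers — not that the shipped lexicon is sensitive
on any particular real record system.

## 5. Numerical and testing choices

Determinism: all generation flows from a single integer seed; rerunning
with the same configuration produces byte-identical files, asserted by
checksum in the tests. Degenerate inputs fail loudly at the edge where
they are detectable: malformed lexicon templates at load time, zero-margin
tables and sub-2×2 tables before testing, empty audit sets, non-positive
doses, episodes ending before they start.

Verification is dual-route throughout: the scanner against an exhaustive
substring search with a hand-written age parser (1000 random 200-character
notes built from colliding phrase fragments); admission-day merging
against materialized day sets (500 random episode sets); the chi-square
against the direct Σ(O−E)²/E formula (1000 random tables, tolerance
1e-10); and the generator's outcome models by refitting on a
50,000-patient cohort, recovering the configured log-odds-ratios within
±0.1. Published-value replays (chi-squares to 2 decimals, reconstructed
odds ratios to ±0.02) and a 100-note PPV audit on a default-rate corpus
complete the acceptance suite. Cohort sizes in routine tests (1500–2000
patients for corpus-level checks, 50,000 only for parameter recovery) were
chosen to keep binomial error small relative to the tolerances while the
full suite runs in about a minute.

## 6. Known limitations

* Sensitivity is unknowable from within: the detector finds what the
  lexicon names, and recorded prevalence in notes under-represents true
  prevalence for reasons no string matcher can fix.
* Negation handling is phrase-level, not scope-level: an exclusion blocks
  only what it overlaps. Novel negation phrasings outside the lexicon
  produce false positives by design (that is what the audit estimates).
* The dose extractor assumes dose follows drug within a sentence and does
  not parse titration schedules, depot intervals or compound regimens.
* Comorbidity is lifetime (any recorded code); whether a within-window
  definition would change the contrasts cannot be decided from the data
  model.
* The hearsay rate, demographic tilts and HoNOS baselines are generator
  choices, not estimates; conclusions about detector behaviour on real
  text require a real annotated sample.
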