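---
title: "pragmap: models, conventions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pragmap: models, conventions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pragmap)
```

This vignette is the package's own account of its science: what each stage
computes, the conventions and defaults it fixes where the underlying
methodology left them open, what the synthetic-data generator does and does
not emulate, and the known limitations.

## 1. The annotation scheme

The scheme is a flat tagset with heading structure: 159 tag types under 16
headings (ideational and interpersonal metafunctions), backed by 15
annotation dictionaries. Auxiliary verbs appear as two headings — the
ideational stative/compound group (32 tags) and the interpersonal
benefactive group (10 tags) — that share one dictionary; modelling them as
distinct headings preserves the published per-heading counts, while the
shared `dictionary_name` preserves the count of 15 dictionaries. The
textual metafunction is deliberately out of scope and is *rejected* at load
rather than silently dropped, so a scheme file that smuggles textual tags
fails loudly.

Tag ids are ASCII slugs (`negparticle.ne`, `ergativity.middle`), not
surface forms: they are stable keys for channels, dictionaries, and files;
display names carry the original labels. The 42 auxiliary-verb subtypes are
counted but not enumerated in the source inventory, so the bundled scheme
carries placeholder names for them, marked as such in the `notes` column.
All other 117 tag names are transcribed from the published enumeration.

The negotiating-particle heading has 12 tag types (7 sentence-final, 4
non-final, 1 "other") while the group-comparison table reports 6 particles;
the mapping is not stated in the source. This package targets the table:
the six *sentence-final* tags (`negparticle.kana/kane/sa/ne/yo/yona`) are
the default comparison set and the planted-rate defaults.

## 2. Transcripts and coordinates

Transcripts are consumed *after* morphological analysis (the upstream
analyzer has a ~2% segmentation error rate that is assumed manually
reviewed), in a plain-text dialect with one morpheme per line (surface,
lemma, coarse POS, POS detail, speaker) and `#key=value` document headers.
Canonical serialization fixes UTF-8, LF, sorted header keys, and one blank
line per sentence, so `write_corpus(read_corpus(f))` is byte-stable and
golden-file tests are exact.

One convention is stated once and used everywhere: span coordinates are
**0-based, half-open `[start, end)` over morphemes, per sentence**. Only
subject-speaker morphemes count toward analysis denominators; examiner
turns are retained for concordance context only, because the object of
measurement is the subject's lexicogrammatical choices.

## 3. Dictionary matching

A lexicon entry is a contiguous sequence of morpheme patterns, each an
exact-equality constraint on any subset of {surface, lemma, pos}.
Comparison happens after Unicode NFKC normalization; there are no regular
expressions. The matching policy per channel is **leftmost-longest**: scan
left to right, take the longest entry matching at the current position,
resume at its end. The source tool does not state its policy; this is the
standard gazetteer convention, makes output deterministic, and guarantees
within-channel non-overlap by construction (the property the IOB2 encoding
needs). Channels are matched independently, so spans from different
channels overlap freely — the worked six-morpheme example has *middle* and
*usuality* spans sharing tokens. Discontiguous constructions must be
encoded as multiple entries; contiguity keeps matching `O(T × entries)`.
The matcher is property-tested against a brute-force enumeration oracle on
all inputs up to 8 morphemes × 4 entries.

## 4. IOB2 label matrices

Each sentence's annotation is a C × T matrix: one row per tag channel, one
column per morpheme, cells in {O, B, I}. Within a channel IOB2 forbids
overlap; across channels overlap is representable because rows are
independent — this is why the multi-channel representation was chosen over
a joint label alphabet. Model output can be invalid (an I with no B/I
before it); the decoder repairs an orphan I by **promoting it to B** rather
than dropping it — the recall-preserving choice — and reports every repair,
so prediction consumers can monitor how often the learner emits
ill-formed sequences.

## 5. Span-level evaluation

A predicted span is correct iff a gold span with the identical (document,
sentence, channel, start, end) exists — exact boundary, exact channel, no
partial credit. This is the only matching rule consistent with the worked
example, where a predicted *middle* span on a token covered by gold spans
of other extents earns nothing: precision 2/4 = 0.5, recall 2/3, F1 ≈ 0.571.
Zero-denominator conventions (no predictions → precision 0; no gold →
recall 0; P = R = 0 → F1 = 0) are the conservative chunking-evaluation
standard; each is flagged `undefined` in the report rather than silently
folded in. Micro-averaged aggregate is the default report, with macro
available, since the source does not state which its corpus-level figures
used. Human-readable output truncates to two decimals, mirroring the
display convention in which 2/3 prints as 0.66; machine output (JSON) is
full precision.

## 6. The sequence labeler

The reference pipeline trains a one-layer Bi-LSTM over randomly initialized
300-dimensional surface embeddings (50 epochs, batch 32, Adam, lr 0.001).
No deep-learning backend exists in this package's supported dependency set,
so the shipped labeler is the dependency-light model planned as the
fallback: a **per-channel averaged margin perceptron** over a ±1-token
window of surface forms plus the current lemma and POS. The window features
are the stand-in for bidirectional recurrent context; each channel is an
independent 3-way {O, B, I} token classifier (matching the C × T output
head; the loss is a sum of independent per-channel terms), and argmax
output is repaired into valid IOB2 at decode time. The `labeler_config()`
surface keeps the reference hyperparameters — `epochs`, `batch_size`
(sentences per update), `learning_rate`, `seed` are live; `embed_dim`,
`hidden_dim`, `optimizer` are accepted but inert — so configurations remain
portable to a neural backend.

Decisions the methodology left open, fixed here:

- **Split granularity**: whole documents (8:1:1 by count, floors, remainder
  assigned train-first), preventing a subject's sentences from leaking
  across sets.
- **Model selection**: the checkpoint with the best development-set span
  F1, ties resolved to the later (more trained) epoch; no early stopping.
- **Determinism**: batch order is drawn from the config seed per epoch;
  weights start at zero; two runs with one seed produce identical logs and
  models.
- The per-epoch `loss` logged is the summed multiclass hinge
  (margin-violation) loss, which decreases smoothly during memorization and
  backs the overfit smoke test.

What a green labeler test establishes — and what it does not: on synthetic
corpora whose gold spans are dictionary-generated, the mapping from
morpheme context to label is deterministic and memorizable, so the held-out
F1 ≥ 0.95 criterion checks the *machinery* (features, training loop,
decoding, evaluation), not linguistic generalization. The reference
corpus-level scores (F1 0.88 on human-annotated data) are not reproducible
here because that corpus is not public; no claim of parity is made.

## 7. Occurrence rates and group comparison

The unit of analysis is the **subject**: one pooled rate per subject per
tag, `count / subject-speaker morphemes` over the filtered documents. A
per-morpheme denominator (rather than per-utterance) is consistent with
published group means of order 10⁻³ for common particles; the source gives
no formula. Welch's unequal-variance t-test with Welch–Satterthwaite
degrees of freedom and two-sided p is computed identically from raw samples
and from summary statistics (`welch_from_samples()` /
`welch_from_summary()` agree exactly, by construction and by property
test); the summary path exists so printed tables can be re-checked without
subject-level data. Sign convention: group A minus group B, TD first by
default. Raw per-tag p-values are the primary report, matching the
replication target; Holm adjustment is available by flag.

Two numerical notes, reported as found rather than "fixed":

- Recomputing t from the published rounded means/SDs with n = 57/50 gives
  values ~1–1.5% larger than the printed statistics (e.g. 3.069 vs 3.024
  for the *ne* row); the original per-subject aggregation or effective n
  evidently differed slightly. The acceptance tests assert the 2% band, not
  equality.
- A tag absent in both groups (both variances zero) has no defined t; such
  tags are emitted with missing t/df/p and listed in an exclusion
  attribute, never silently dropped.

The age filter for the "late adolescents and adults" comparison is a
configurable threshold; the default lower bound used in examples is 13
years, since the source ties the cutoff to puberty without stating a
number. Group selector `"ASD"` covers both ASD subgroups, since the
composition of the published n = 50 is unstated.

## 8. The synthetic world

The generator emulates the *statistical* structure of the study corpus —
group sizes, document lengths, planted per-morpheme tag rates — and nothing
linguistic. Defaults state the emulated world once: TD n = 57 and ASD
n = 50 subjects, one task-A document each, ages 16–45 (all past the ≥ 13
cutoff), document length negative-binomial with mean 1000 morphemes and
dispersion `size = 20` (a realistic overdispersion for task transcripts;
chosen once), sentences averaging 12 morphemes, and the six sentence-final
particle rates set to the published group means. A document is a uniform
shuffle of distractor morphemes and tag-bearing sequence units, with
per-tag counts Binomial(T, rate): the realized expected per-morpheme rate
equals the planted rate exactly, and within-channel overlap is impossible
by construction. Gold spans are recorded where units land, and the emitted
lexicon is exactly the planted sequences, so dictionary annotation
reproduces gold with F1 = 1.0 — the closure property the CLI smoke test
asserts.

Because distractor and tag vocabularies are disjoint and sequences unique,
a trained labeler can memorize the mapping perfectly; see §6 for what that
does and does not establish. Rate-recovery and calibration use the real
`compare_groups()` pipeline per replicate: with equal planted rates the
rejection frequency sits at the nominal 5% level (binomial CI over 200
seeded replicates), and with planted TD = 0.010 vs ASD = 0.005 at
study-scale n the power exceeds 0.8 — consistent with the analytic
approximation (per-subject binomial SE ≈ 0.003 at T = 1000 gives a
standardized difference near 9).

For test-budget reasons the default *test-suite* runs scale document counts
or lengths down where the criterion permits (e.g. the 200-document labeler
criterion runs at mean length 300); the stated world above is unchanged and
is what `synth_spec()` defaults produce.

## 9. Command-line interface

The CLI mirrors the annotate → verify → train → evaluate → compare
workflow. Seeds are mandatory flags wherever randomness exists (no
wall-clock defaults); every command logs a reproducibility header (package
and R versions, seed, input MD5 digests) to stderr and writes data only to
declared outputs, so identical inputs and seeds give byte-identical
outputs. The manual verification step of the original web tool is
represented by the `verified` column of span TSVs, editable in place.

## 10. Known limitations

- The labeler is not a recurrent network; long-range context beyond the
  feature window is invisible to it. On real (non-memorizable) data its
  scores would not be comparable to the reference Bi-LSTM's.
- Bundled dictionaries are faithful only where the published inventory
  enumerates lexis (fillers, negotiating particles); the other 13 are
  fixture-scale, because the production dictionaries are not distributed.
- Sentence-final vs non-final particle disambiguation is expressible only
  through POS conventions in lexicon entries; the matcher itself has no
  positional predicates.
- The statistics layer tests each tag marginally; no multivariate or
  mixed-effects modelling (subjects contribute one pooled rate each, so no
  repeated-measures structure exists after pooling).
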