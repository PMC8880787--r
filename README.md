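# pragmap

Corpus annotation and group statistics for mapping pragmatic language
impairment in spoken-language transcripts.

## The problem

Pragmatic impairment (PI) — difficulty using language appropriately in
social context — is a core feature of autism spectrum disorder (ASD), but it
is hard to quantify from clinical impressions. One operationalization:
transcribe semi-structured spoken-language tasks, annotate each morpheme
stream with the lexicogrammatical choices the speaker made (in the sense of
systemic functional linguistics, where speech is a stream of choices from a
system network), and compare how often diagnostic groups choose particular
resources. Where ASD and TD (typically developed) speakers differ reliably —
for instance in Japanese sentence-final *negotiating particles* such as
*ne* and *yo*, which manage joint attention and ownership of information —
the annotation layer localizes PI to a specific region of the grammar.

`pragmap` is the computational machinery for that workflow:

- **Annotation scheme** — a bundled inventory of 159 tag types in 15
  dictionaries across the ideational and interpersonal metafunctions
  (`load_scheme()`, `summarize_scheme()`).
- **Transcript I/O** — a plain-text dialect (PRAGMA-TSV) for morphologically
  analyzed, metadata-bearing transcripts: one morpheme per line
  (surface / lemma / POS), `#key=value` document headers for subject id,
  diagnostic group (ASD-1 / ASD-2 / TD), age and task code
  (`read_corpus()`, `write_corpus()`, `mecab_to_document()`).
- **Dictionary tagging** — leftmost-longest span matching of lexicon entries
  (surface / lemma / POS constraints) per tag channel
  (`load_lexicon()`, `annotate_document()`).
- **IOB2 encoding** — each sentence's annotation as a C × T label matrix,
  one IOB2 row per tag channel, so spans may overlap across channels but
  never within one (`encode_spans()`, `decode_matrix()`,
  `validate_matrix()`).
- **Trainable labeler** — a seeded sequence labeler (per-channel averaged
  margin perceptron over windowed features) with an 8:1:1
  train/dev/test protocol (`split_corpus()`, `train_labeler()`,
  `predict_corpus()`).
- **Evaluation** — span-level precision / recall / F1 with exact-boundary,
  exact-channel matching (`score_spans()`).
- **Statistics** — per-subject occurrence rates (tag count over
  subject-speaker morphemes) compared between groups with Welch's
  unequal-variance t-test, `t = (x̄_A − x̄_B) / √(s²_A/n_A + s²_B/n_B)`,
  Welch–Satterthwaite df, two-sided p (`occurrence_rates()`,
  `welch_from_samples()`, `welch_from_summary()`, `compare_groups()`),
  plus KWIC concordance and frequency tables (`kwic()`, `freq_table()`).
- **Synthetic corpora** — a seeded generator that plants group-specific
  per-morpheme tag rates, emitting gold spans and a matching lexicon, so
  the full pipeline is testable without clinical data
  (`synth_spec()`, `generate_corpus()`, `recovery_report()`).

## Worked example

A six-morpheme sentence, *oko ttari nanka suru koto aru* ("there are
occasions when I get mad"), annotated with the bundled dictionaries:

```r
library(pragmap)
sch <- load_scheme()
sch
#> <annotation_scheme> 159 tag types, 16 headings, 15 dictionaries

lex <- load_lexicon(scheme = sch)
surf <- c("oko", "ttari", "nanka", "suru", "koto", "aru")
doc <- new_document("ex1", "subj01", "TD", 25, "A",
  data.frame(sentence_id = 1L, index = 0:5, surface = surf, lemma = surf,
             pos = "verb", pos_detail = "", speaker = "subject"))
spans <- annotate_document(doc, lex)
spans[spans$tag_id %in% c("ergativity.middle", "modality.usuality"), ]
#>   doc_id sentence_id            tag_id start end     source verified
#> 1    ex1           1 ergativity.middle     0   1 dictionary    FALSE
#> 2    ex1           1 ergativity.middle     4   6 dictionary    FALSE
#> 4    ex1           1 modality.usuality     3   6 dictionary    FALSE
```

The *middle* spans (*oko*; *koto aru*) and the *usuality* span (*suru koto
aru*) overlap across channels; the IOB2 matrix keeps them on separate rows:

```r
encode_spans(spans[spans$tag_id %in% c("ergativity.middle", "modality.usuality"), ],
             6, c("ergativity.middle", "modality.usuality"))
#>                   [,1] [,2] [,3] [,4] [,5] [,6]
#> ergativity.middle "B"  "O"  "O"  "O"  "B"  "I"
#> modality.usuality "O"  "O"  "O"  "B"  "I"  "I"
```

Scoring a hypothetical model output (*middle* on tokens 1 and 4, *usuality*
on token 1 and tokens 4–6) against that gold: two of four predictions have
an exactly matching gold span, and two of three gold spans are found.

```r
pred <- data.frame(doc_id = "ex1", sentence_id = 1L,
  tag_id = c("ergativity.middle", "ergativity.middle",
             "modality.usuality", "modality.usuality"),
  start = c(0L, 3L, 0L, 3L), end = c(1L, 4L, 1L, 6L))
score_spans(spans[spans$tag_id %in% c("ergativity.middle", "modality.usuality"), ], pred)
#> spans: gold=3 pred=4 correct=2
#> precision 0.50  recall 0.66  F1 0.57
```

(Display truncates to two decimals — recall is 2/3.)

Group comparison from published-style summary statistics — the *ne* row of
a TD (n = 57) vs ASD (n = 50) comparison of per-morpheme particle rates:

```r
w <- welch_from_summary(0.010057, 0.008505, 57, 0.005572, 0.006585, 50)
sprintf("t = %.3f, df = %.1f, p = %.4f", w$t, w$df, w$p)
#> "t = 3.069, df = 103.5, p = 0.0027"
```

TD speakers use *ne* significantly more often — the direction interpreted
as PI in the ASD group's particle choices.

## Command line

An installed wrapper (`inst/exec/pragmap`) ties the stages together; every
seed is an explicit flag:

```sh
pragmap simulate --seed 11 --out corp/
pragmap annotate --corpus corp/corpus.tsv --lexicon corp/lexicon.tsv --out corp/pred.tsv
pragmap eval     --gold corp/gold.tsv --pred corp/pred.tsv
pragmap train    --corpus corp/corpus.tsv --gold corp/gold.tsv --out corp/model --seed 11
pragmap compare  --corpus corp/corpus.tsv --spans corp/gold.tsv \
                 --tags 'negparticle.*' --task A --min-age 13 --out corp/table.tsv
```

Exit codes: 0 success, 1 domain error, 2 usage error.

## Scope

The package is the annotation/statistics machinery only: no audio or
transcription handling, no textual-metafunction tags, no dependency-parse
views, and no clinical interpretation. The study corpus this design derives
from is not publicly distributable; bundled dictionaries carry the
enumerated lexis where the tag inventory enumerates it (fillers,
negotiating particles) and small fixture entries elsewhere, and the
synthetic generator stands in for corpus-scale data.
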