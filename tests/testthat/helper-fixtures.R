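# Shared fixtures, built in code.

# The six-morpheme worked-example sentence with overlapping channels:
# middle on token 1 and tokens 5-6, usuality on tokens 4-6.
example_tokens <- function(speaker = "subject") {
  surf <- c("oko", "ttari", "nanka", "suru", "koto", "aru")
  data.frame(sentence_id = 1L, index = 0:5, surface = surf, lemma = surf,
             pos = "verb", pos_detail = "", speaker = speaker,
             stringsAsFactors = FALSE)
}

example_document <- function(doc_id = "d1", subject_id = "s1", group = "TD",
                             age = 25L, task = "A") {
  new_document(doc_id, subject_id, group, age, task, example_tokens())
}

example_gold_spans <- function(doc_id = "") {
  data.frame(
    doc_id = doc_id, sentence_id = 1L,
    tag_id = c("ergativity.middle", "ergativity.middle", "modality.usuality"),
    start = c(0L, 4L, 3L), end = c(1L, 6L, 6L),
    source = "manual", verified = TRUE, stringsAsFactors = FALSE)
}

example_pred_spans <- function(doc_id = "") {
  data.frame(
    doc_id = doc_id, sentence_id = 1L,
    tag_id = c("ergativity.middle", "ergativity.middle",
               "modality.usuality", "modality.usuality"),
    start = c(0L, 3L, 0L, 3L), end = c(1L, 4L, 1L, 6L),
    source = "model", verified = FALSE, stringsAsFactors = FALSE)
}

# tiny two-document corpus with both speakers and two subjects
tiny_corpus <- function() {
  tok1 <- data.frame(
    sentence_id = c(1L, 1L, 1L, 2L, 2L),
    index = c(0L, 1L, 2L, 0L, 1L),
    surface = c("kyou", "wa", "ne", "sou", "ne"),
    lemma = c("kyou", "wa", "ne", "sou", "ne"),
    pos = c("noun", "particle", "particle", "adv", "particle"),
    pos_detail = "", speaker = c("subject", "subject", "subject",
                                 "examiner", "subject"),
    stringsAsFactors = FALSE)
  tok2 <- data.frame(
    sentence_id = 1L, index = 0:2,
    surface = c("ano", "iku", "yo"), lemma = c("ano", "iku", "yo"),
    pos = c("filler", "verb", "particle"), pos_detail = "",
    speaker = "subject", stringsAsFactors = FALSE)
  new_corpus(list(
    new_document("doc1", "subjA", "TD", 20L, "A", tok1),
    new_document("doc2", "subjB", "ASD-1", 23L, "A", tok2)))
}

# small fast synthetic world for module tests
small_spec <- function(...) {
  synth_spec(n_subjects = c(TD = 15L, "ASD-1" = 15L),
             doc_length_mean = 200, doc_length_dispersion = 20,
             tag_rates = data.frame(
               group = c("TD", "TD", "ASD", "ASD"),
               tag_id = rep(c("negparticle.ne", "modality.usuality"), 2),
               rate = c(0.03, 0.015, 0.02, 0.015)),
             sequences = list(
               negparticle.ne = "ne",
               modality.usuality = c("suru", "koto", "aru")),
             ...)
}
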